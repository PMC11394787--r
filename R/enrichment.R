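#' Hypergeometric pathway enrichment of a cluster
#'
#' Upper-tail hypergeometric test per pathway: p = P(X >= overlap) for X ~
#' Hypergeometric(universe_size, set_size, cluster_size), with catalog sets
#' intersected with the universe first and BH adjustment over all pathways
#' tested for the cluster.
#'
#' @param cluster_genes Character vector, a subset of `universe`.
#' @param universe Character vector, the sampling frame (all transcripts
#'   tested in the bin's network).
#' @param catalog An `lnc_catalog` (or list with a `sets` element).
#' @return Tibble `pathway`, `overlap`, `cluster_size`, `set_size`,
#'   `universe_size`, `p`, `padj`, sorted by `padj`.
#' @export
hypergeom_enrich <- function(cluster_genes, universe, catalog) {
  if (length(universe) == 0) abort_arg("`universe` is empty")
  cluster_genes <- intersect(cluster_genes, universe)
  N <- length(universe)
  k <- length(cluster_genes)
  out <- purrr::imap_dfr(catalog$sets, function(genes, name) {
    set <- intersect(genes, universe)
    K <- length(set)
    ov <- length(intersect(set, cluster_genes))
    p <- if (K == 0) 1 else phyper(ov - 1, K, N - K, k, lower.tail = FALSE)
    tibble(pathway = name, overlap = ov, cluster_size = k, set_size = K,
           universe_size = N, p = p)
  })
  out$padj <- bh_adjust(out$p)
  arrange(out, .data$padj, .data$pathway)
}

#' Count enriched pathways per bin, category and direction
#'
#' Distinct pathways passing `padj_thresh` are counted once per bin,
#' category and up/down direction (a pathway enriched in two clusters of
#' the same bin is counted once). Pathways missing from the category map
#' fall into an `"uncategorized"` bucket with a warning.
#'
#' @param results Tibble of enrichment results carrying at least `bin`,
#'   `pathway`, `padj` and `direction` (`"up"`/`"down"`/`NA`).
#' @param catalog An `lnc_catalog` with a `categories` map.
#' @param padj_thresh Adjusted-p threshold, default 0.05.
#' @return Tibble `bin`, `category`, `direction`, `n_pathways`.
#' @export
categorize_counts <- function(results, catalog, padj_thresh = 0.05) {
  enriched <- filter(results, .data$padj < padj_thresh)
  if (nrow(enriched) == 0) {
    return(tibble(bin = integer(0), category = character(0),
                  direction = character(0), n_pathways = integer(0)))
  }
  cat_map <- catalog$categories
  enriched$category <- unname(cat_map[enriched$pathway])
  if (anyNA(enriched$category)) {
    warn("pathways missing from the category map assigned 'uncategorized'")
    enriched$category[is.na(enriched$category)] <- "uncategorized"
  }
  enriched %>%
    distinct(.data$bin, .data$category, .data$direction, .data$pathway) %>%
    count(.data$bin, .data$category, .data$direction, name = "n_pathways")
}

#' Single-sample ECDF gene-set score (ssGSEA style)
#'
#' Genes are ranked descending by expression (rank 1 = highest). Walking
#' down the ranked list, the score accumulates the difference between the
#' in-set ECDF weighted by (expression rank)^alpha, i.e. (N - position +
#' 1)^alpha, and the unweighted out-of-set ECDF. Positive scores mean the
#' set concentrates among highly ranked genes. The score is left
#' unnormalized. The score depends on the data only through ranks, so it is
#' invariant under strictly increasing transforms of the expression values.
#'
#' @param expression Named numeric vector: one sample's expression values.
#' @param gene_set Character vector; must intersect the measured genes and
#'   must not cover all of them.
#' @param alpha Rank-weighting exponent, default 0.25.
#' @return A one-row tibble `score`, `alpha`, `n_in`, `n_out`.
#' @export
ssgsea_score <- function(expression, gene_set, alpha = 0.25) {
  stopifnot(!is.null(names(expression)))
  genes <- names(expression)
  inset <- genes %in% gene_set
  if (!any(inset)) abort_arg("`gene_set` does not intersect the measured genes")
  if (all(inset)) abort_arg("`gene_set` covers all measured genes")
  N <- length(genes)
  rk <- rank(expression, ties.method = "average")   # N = highest expression
  ord <- order(rk, genes, decreasing = TRUE)
  inset <- inset[ord]
  w <- rk[ord]^alpha
  num <- cumsum(ifelse(inset, w, 0)) / sum(w[inset])
  den <- cumsum(!inset) / sum(!inset)
  tibble(score = sum(num - den), alpha = alpha,
         n_in = sum(inset), n_out = sum(!inset))
}

#' ssGSEA score matrix for all samples and catalog sets
#'
#' @param normalized Normalized counts tibble.
#' @param catalog An `lnc_catalog`.
#' @param alpha Rank-weighting exponent, default 0.25.
#' @return Tibble `sample_id`, `pathway`, `score`.
#' @export
ssgsea_matrix <- function(normalized, catalog, alpha = 0.25) {
  m <- counts_matrix(normalized)
  purrr::imap_dfr(catalog$sets, function(genes, name) {
    if (length(intersect(genes, rownames(m))) == 0) return(NULL)
    tibble(
      sample_id = colnames(m),
      pathway = name,
      score = vapply(colnames(m), function(s) {
        ssgsea_score(setNames(m[, s], rownames(m)), genes, alpha)$score
      }, numeric(1))
    )
  })
}

#' Read a GMT gene-set file
#'
#' @param path GMT file: one set per line, tab-separated `name`,
#'   `description`, then gene ids.
#' @param categories Optional path to a two-column TSV (`pathway`,
#'   `category`).
#' @return An `lnc_catalog`.
#' @export
read_gmt <- function(path, categories = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    sets[[parts[1]]] <- parts[-(1:2)]
  }
  cats <- setNames(rep(NA_character_, length(sets)), names(sets))
  if (!is.null(categories)) {
    tb <- readr::read_tsv(categories, show_col_types = FALSE)
    cats[tb$pathway] <- tb$category
  }
  structure(list(sets = sets, categories = cats), class = "lnc_catalog")
}

#' Write a catalog as GMT plus a category map TSV
#'
#' @param catalog An `lnc_catalog`.
#' @param path Output GMT path.
#' @param categories Optional output TSV path for the category map.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(catalog, path, categories = NULL) {
  lines <- vapply(names(catalog$sets), function(nm) {
    paste(c(nm, "na", catalog$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  if (!is.null(categories)) {
    readr::write_tsv(
      tibble(pathway = names(catalog$categories),
             category = unname(catalog$categories)),
      categories
    )
  }
  invisible(path)
}
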