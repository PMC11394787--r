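#' Genes within the cis window of a lncRNA
#'
#' Same-chromosome genes whose span lies within `window` bp of the lncRNA
#' span (closest-span distance, inclusive boundary; 0 on overlap; strand
#' ignored).
#'
#' @param lnc One-row annotation tibble (the lncRNA).
#' @param genes Annotation tibble of candidate genes.
#' @param window Distance cutoff in bp, default 100000.
#' @return Tibble `transcript_id`, `gene_id`, `distance`, ascending
#'   distance.
#' @export
cis_candidates <- function(lnc, genes, window = 100000) {
  stopifnot(nrow(lnc) == 1)
  d <- ifelse(genes$chrom != lnc$chrom, Inf,
              pmax(0, pmax(genes$start, lnc$start) - pmin(genes$end, lnc$end)))
  out <- tibble(transcript_id = genes$transcript_id,
                gene_id = genes$gene_id, distance = d)
  out <- filter(out, .data$distance <= window,
                .data$transcript_id != lnc$transcript_id)
  arrange(out, .data$distance, .data$transcript_id)
}

#' Default scoring for the duplex pseudo-energy
#'
#' Pseudo-kcal/mol contributions: Watson-Crick pair -0.5, G.U wobble
#' -0.25, mismatch +1.0, gap (open or extend) +2.0.
#'
#' @return Named list `wc`, `wobble`, `mismatch`, `gap`.
#' @export
duplex_scoring <- function() {
  list(wc = -0.5, wobble = -0.25, mismatch = 1.0, gap = 2.0)
}

.clean_seq <- function(x, what) {
  s <- toupper(x)
  s <- chartr("U", "T", s)
  if (grepl("[^ACGT]", s)) {
    abort_arg(paste0("`", what, "` contains characters outside {A,C,G,U/T}"))
  }
  s
}

#' Minimum local duplex pseudo-energy between two transcripts
#'
#' Dynamic program over the lncRNA sequence versus the reverse of the
#' target (duplexes are antiparallel), minimizing the summed pair scores
#' from [duplex_scoring()]; the empty duplex scores 0, so the result is
#' always <= 0. A planted perfect `L`-nt complement scores `-0.5 * L`.
#' Stands in for RIsearch with the same `< -10` calling threshold; an
#' externally computed energy table can replace it in
#' [assign_regulators()].
#'
#' @param lnc_seq,target_seq Nucleotide strings over A/C/G/T/U.
#' @param scoring Scoring list, default [duplex_scoring()].
#' @param seed_len `NULL` (default) for the exact DP over the full
#'   sequences; an integer k switches to a seed-and-extend screen that
#'   scores only windows around exact complementary k-mers (0 when no seed
#'   exists) — much faster for transcriptome-scale batches, at the cost of
#'   missing duplexes with no perfect k-mer core.
#' @param window Half-width (nt) of the DP window around each seed hit.
#' @return Scalar pseudo-energy (<= 0).
#' @export
trans_energy <- function(lnc_seq, target_seq, scoring = duplex_scoring(),
                         seed_len = NULL, window = 50) {
  a <- .clean_seq(lnc_seq, "lnc_seq")
  b <- .clean_seq(target_seq, "target_seq")
  b_rev <- paste(rev(strsplit(b, "")[[1]]), collapse = "")
  if (is.null(seed_len)) {
    duplex_energy_cpp(a, b_rev, scoring$wc, scoring$wobble,
                      scoring$mismatch, scoring$gap)
  } else {
    duplex_energy_seeded_cpp(a, b_rev, as.integer(seed_len),
                             as.integer(window), scoring$wc, scoring$wobble,
                             scoring$mismatch, scoring$gap)
  }
}

#' Principal components of a pathway's expression submatrix
#'
#' PCA of the per-transcript standardized expression of the pathway's
#' genes over the given samples; retains the minimal leading set of
#' components whose cumulative variance fraction reaches `var_threshold`.
#' Component signs are fixed so the largest-magnitude loading is positive.
#'
#' @param normalized Normalized counts tibble.
#' @param gene_set Character vector of transcript ids.
#' @param samples Character vector of >= 3 sample ids.
#' @param var_threshold Cumulative variance target, default 0.6.
#' @return An `lnc_pcmodel`: `scores` (samples x retained components),
#'   `loadings`, `var_explained` (all components), `n_components`, `genes`.
#' @export
pathway_pcs <- function(normalized, gene_set, samples, var_threshold = 0.6) {
  if (length(samples) < 3) abort_arg("need >= 3 samples")
  m <- counts_matrix(normalized)
  genes <- intersect(gene_set, rownames(m))
  if (length(genes) == 0) abort_arg("`gene_set` does not intersect the matrix")
  X <- t(m[genes, samples, drop = FALSE])
  keep <- apply(X, 2, function(x) var(x) > 0)
  if (!any(keep)) abort("degenerate input: all pathway genes constant")
  X <- X[, keep, drop = FALSE]
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  n_comp <- which(cumsum(ve) >= var_threshold)[1]
  scores <- pc$x[, seq_len(n_comp), drop = FALSE]
  loadings <- pc$rotation[, seq_len(n_comp), drop = FALSE]
  for (j in seq_len(n_comp)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(scores = scores, loadings = loadings, var_explained = ve,
                 n_components = n_comp, var_threshold = var_threshold,
                 genes = colnames(X)),
            class = "lnc_pcmodel")
}

#' Regress a lncRNA's expression on a pathway's principal components
#'
#' Ordinary least squares of the lncRNA expression on the retained PCs
#' with an intercept (centering drives the intercept toward zero; the
#' fitted |beta0| is reported so callers can filter on it). `p` is the
#' overall F-test p-value.
#'
#' @param lnc_expr Named numeric vector over the same samples as `pcs`.
#' @param pcs An `lnc_pcmodel`.
#' @return An `lnc_pcfit`: `coefficients` tibble, `intercept`, `r2`, `p`,
#'   `n_components`.
#' @export
fit_lnc_pathway_regression <- function(lnc_expr, pcs) {
  X <- pcs$scores
  stopifnot(!is.null(names(lnc_expr)))
  if (!all(rownames(X) %in% names(lnc_expr))) {
    abort_arg("`lnc_expr` must cover the samples of `pcs`")
  }
  y <- lnc_expr[rownames(X)]
  n <- length(y)
  k <- ncol(X)
  if (n < k + 2) abort("rank deficiency: fewer samples than components + 2")
  fit <- lm(y ~ X)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  p <- if (is.null(fstat)) 1 else unname(pf(fstat[1], fstat[2], fstat[3],
                                            lower.tail = FALSE))
  beta <- stats::coef(fit)
  structure(list(
    coefficients = tibble(term = colnames(X), estimate = unname(beta[-1])),
    intercept = unname(beta[1]),
    r2 = sm$r.squared,
    p = p,
    n_components = k
  ), class = "lnc_pcfit")
}

#' @method glance lnc_pcfit
#' @export
glance.lnc_pcfit <- function(x, ...) {
  tibble(r2 = x$r2, p = x$p, intercept = x$intercept,
         n_components = x$n_components)
}

#' @method tidy lnc_pcfit
#' @export
tidy.lnc_pcfit <- function(x, ...) x$coefficients

#' Gene-level cis and trans target calls
#'
#' Every significant co-expression edge of the network is tested for the
#' two mechanisms: cis when the lncRNA and gene spans lie within `window`
#' bp on the same chromosome; trans when the duplex pseudo-energy (or the
#' supplied external energy table) falls below `energy_threshold`.
#'
#' @param network An `lnc_bicolor` network (edges already filtered at
#'   |SCC| > 0 and adjusted p < 0.05).
#' @param annotation Annotation tibble covering the network's nodes.
#' @param sequences Named character vector of spliced sequences (needed
#'   unless `energy_table` is given).
#' @param window Cis window in bp, default 100000.
#' @param energy_threshold Trans energy cutoff, default -10.
#' @param energy_table Optional tibble `lncRNA`, `mRNA`, `energy`
#'   replacing the built-in scorer (e.g. RIsearch output).
#' @param scoring Duplex scoring, default [duplex_scoring()].
#' @param trans_seed_len,trans_window Seed length and extension window for
#'   the batch duplex screen (see [trans_energy()]); `trans_seed_len =
#'   NULL` forces the exact full DP on every pair (slow at scale).
#' @return Tibble `lncRNA`, `target_gene`, `mode`, `evidence`, `scc`,
#'   `scc_padj`.
#' @export
lnc_gene_targets <- function(network, annotation, sequences = NULL,
                             window = 100000, energy_threshold = -10,
                             energy_table = NULL,
                             scoring = duplex_scoring(),
                             trans_seed_len = 12, trans_window = 50) {
  e <- network$edges
  if (nrow(e) == 0) {
    return(tibble(lncRNA = character(0), target_gene = character(0),
                  mode = character(0), evidence = numeric(0),
                  scc = numeric(0), scc_padj = numeric(0)))
  }
  ann <- annotation
  idx <- match(e$lncRNA, ann$transcript_id)
  jdx <- match(e$mRNA, ann$transcript_id)
  dist <- ifelse(ann$chrom[idx] != ann$chrom[jdx], Inf,
                 pmax(0, pmax(ann$start[idx], ann$start[jdx]) -
                        pmin(ann$end[idx], ann$end[jdx])))
  cis <- tibble(lncRNA = e$lncRNA, target_gene = e$mRNA, mode = "cis",
                evidence = dist, scc = e$scc, scc_padj = e$padj) %>%
    filter(is.finite(.data$evidence), .data$evidence <= window)

  if (!is.null(energy_table)) {
    en <- left_join(e, energy_table, by = c("lncRNA", "mRNA"))$energy
    en[is.na(en)] <- 0
  } else {
    if (is.null(sequences)) abort_arg("need `sequences` or `energy_table`")
    en <- purrr::map2_dbl(e$lncRNA, e$mRNA, function(l, m) {
      trans_energy(sequences[[l]], sequences[[m]], scoring,
                   seed_len = trans_seed_len, window = trans_window)
    })
  }
  trans <- tibble(lncRNA = e$lncRNA, target_gene = e$mRNA, mode = "trans",
                  evidence = en, scc = e$scc, scc_padj = e$padj) %>%
    filter(.data$evidence < energy_threshold)
  bind_rows(cis, trans) %>% arrange(.data$lncRNA, .data$target_gene)
}

#' Assign lncRNAs as pathway regulators
#'
#' A lncRNA is called a regulator of a pathway when (a) the PC regression
#' of its expression on the pathway's retained components reaches
#' `r2_threshold` with BH-adjusted overall-F p < 0.05 (adjustment over all
#' candidate lncRNA x pathway fits), (b) it is a cis or trans target
#' caller of at least one pathway gene (per [lnc_gene_targets()], which
#' already requires a significant co-expression edge), and (c) its
#' Spearman correlation with the pathway's first PC is significant after
#' the same BH adjustment. Direction is `promote` when that correlation is
#' positive, else `inhibit`.
#'
#' @param normalized Normalized counts tibble.
#' @param samples Character vector of sample ids (the bin).
#' @param network An `lnc_bicolor` network built on those samples.
#' @param annotation Annotation tibble.
#' @param sequences Named character vector of spliced sequences.
#' @param catalog An `lnc_catalog`.
#' @param r2_threshold Minimum regression R^2, default 0.5.
#' @param padj_thresh BH-adjusted p cutoff, default 0.05.
#' @param var_threshold Cumulative PC variance target, default 0.6.
#' @inheritParams lnc_gene_targets
#' @return Tibble `lncRNA`, `pathway`, `mode`, `evidence`, `scc`,
#'   `scc_padj`, `r2`, `intercept`, `direction` (one row per lncRNA,
#'   pathway and mode).
#' @export
assign_regulators <- function(normalized, samples, network, annotation,
                              sequences, catalog, r2_threshold = 0.5,
                              padj_thresh = 0.05, var_threshold = 0.6,
                              window = 100000, energy_threshold = -10,
                              energy_table = NULL,
                              scoring = duplex_scoring(),
                              trans_seed_len = 12, trans_window = 50) {
  targets <- lnc_gene_targets(network, annotation, sequences, window,
                              energy_threshold, energy_table, scoring,
                              trans_seed_len, trans_window)
  empty <- tibble(lncRNA = character(0), pathway = character(0),
                  mode = character(0), evidence = numeric(0),
                  scc = numeric(0), scc_padj = numeric(0), r2 = numeric(0),
                  intercept = numeric(0), direction = character(0))
  if (nrow(targets) == 0) return(empty)
  m <- counts_matrix(normalized)

  set_tbl <- purrr::imap_dfr(catalog$sets, function(genes, name) {
    tibble(pathway = name, target_gene = genes)
  })
  cand <- inner_join(targets, set_tbl, by = "target_gene",
                     relationship = "many-to-many")
  if (nrow(cand) == 0) return(empty)

  pairs <- distinct(cand, .data$lncRNA, .data$pathway)
  pc_cache <- list()
  rows <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    lnc <- pairs$lncRNA[i]
    pw <- pairs$pathway[i]
    if (is.null(pc_cache[[pw]])) {
      pc_cache[[pw]] <<- tryCatch(
        pathway_pcs(normalized, catalog$sets[[pw]], samples, var_threshold),
        error = function(e) NA)
    }
    pcs <- pc_cache[[pw]]
    if (!inherits(pcs, "lnc_pcmodel")) return(NULL)
    y <- setNames(m[lnc, samples], samples)
    fit <- tryCatch(fit_lnc_pathway_regression(y, pcs), error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    ct <- suppressWarnings(cor.test(y[rownames(pcs$scores)], pcs$scores[, 1],
                                    method = "spearman"))
    tibble(lncRNA = lnc, pathway = pw, r2 = fit$r2, fit_p = fit$p,
           intercept = fit$intercept,
           pc1_scc = unname(ct$estimate), pc1_p = ct$p.value)
  })
  if (nrow(rows) == 0) return(empty)
  rows$fit_padj <- bh_adjust(rows$fit_p)
  rows$pc1_padj <- bh_adjust(rows$pc1_p)
  called <- filter(rows, .data$r2 >= r2_threshold,
                   .data$fit_padj < padj_thresh,
                   .data$pc1_padj < padj_thresh) %>%
    mutate(direction = if_else(.data$pc1_scc > 0, "promote", "inhibit"))
  if (nrow(called) == 0) return(empty)
  inner_join(
    distinct(cand, .data$lncRNA, .data$pathway, .data$mode,
             .keep_all = TRUE),
    select(called, "lncRNA", "pathway", "r2", "intercept", "direction"),
    by = c("lncRNA", "pathway")
  ) %>%
    select("lncRNA", "pathway", "mode", "evidence", "scc", "scc_padj",
           "r2", "intercept", "direction") %>%
    arrange(.data$lncRNA, .data$pathway, .data$mode)
}
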