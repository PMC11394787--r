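#' Build the bi-color lncRNA-mRNA co-expression network for a sample bin
#'
#' For every lncRNA x mRNA pair, the Spearman correlation over the bin's
#' samples with a two-sided p (t approximation; exact null for n <= 9
#' without ties) is computed; edges are kept when the coefficient is
#' nonzero and the BH-adjusted p (over all non-constant pairs tested in the
#' bin) is below `padj_thresh`. Pairs where either transcript is constant
#' across the bin are skipped.
#'
#' @param normalized Normalized counts tibble.
#' @param lnc_ids,mrna_ids Disjoint transcript id sets (the two colors).
#' @param samples Character vector of >= 5 sample ids (the bin).
#' @param padj_thresh Adjusted-p threshold, default 0.05.
#' @return An object of class `lnc_bicolor`: list with `nodes` (tibble
#'   `id`, `color`) and `edges` (tibble `lncRNA`, `mRNA`, `scc`, `p`,
#'   `padj`).
#' @export
spearman_edges <- function(normalized, lnc_ids, mrna_ids, samples,
                           padj_thresh = 0.05) {
  if (length(samples) < 5) abort_arg("need >= 5 samples for rank correlation")
  if (length(intersect(lnc_ids, mrna_ids)) > 0) abort_arg("id sets overlap")
  m <- counts_matrix(normalized)
  lnc_ids <- intersect(lnc_ids, rownames(m))
  mrna_ids <- intersect(mrna_ids, rownames(m))
  sub <- m[c(lnc_ids, mrna_ids), samples, drop = FALSE]
  keep <- apply(sub, 1, function(x) var(x) > 0)
  lnc_use <- intersect(lnc_ids, rownames(sub)[keep])
  mrna_use <- intersect(mrna_ids, rownames(sub)[keep])
  n <- length(samples)

  edges <- tibble(lncRNA = character(0), mRNA = character(0),
                  scc = numeric(0), p = numeric(0), padj = numeric(0))
  if (length(lnc_use) > 0 && length(mrna_use) > 0) {
    rk <- t(apply(sub[c(lnc_use, mrna_use), , drop = FALSE], 1, rank))
    rk <- rk - (n + 1) / 2
    rk <- rk / sqrt(rowSums(rk^2))
    r <- rk[lnc_use, , drop = FALSE] %*% t(rk[mrna_use, , drop = FALSE])
    r[r > 1] <- 1; r[r < -1] <- -1
    if (n <= 9) {
      pv <- matrix(NA_real_, nrow(r), ncol(r), dimnames = dimnames(r))
      for (i in seq_along(lnc_use)) for (j in seq_along(mrna_use)) {
        pv[i, j] <- suppressWarnings(
          cor.test(sub[lnc_use[i], ], sub[mrna_use[j], ],
                   method = "spearman")$p.value)
      }
    } else {
      tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
      pv <- 2 * pt(-abs(tt), n - 2)
      pv[abs(r) >= 1] <- 0
    }
    edges <- tibble(
      lncRNA = rep(lnc_use, times = length(mrna_use)),
      mRNA = rep(mrna_use, each = length(lnc_use)),
      scc = as.vector(r),
      p = as.vector(pv)
    )
    edges$padj <- bh_adjust(edges$p)
    edges <- filter(edges, .data$scc != 0, .data$padj < padj_thresh)
  }
  nodes <- bind_rows(
    tibble(id = lnc_ids, color = "lncRNA"),
    tibble(id = mrna_ids, color = "mRNA")
  )
  new_bicolor(nodes, edges)
}

new_bicolor <- function(nodes, edges) {
  color <- setNames(nodes$color, nodes$id)
  if (nrow(edges) > 0) {
    if (any(color[edges$lncRNA] != "lncRNA") ||
        any(color[edges$mRNA] != "mRNA")) {
      abort("bipartiteness violated: an edge connects same-colored nodes")
    }
    if (anyDuplicated(paste(edges$lncRNA, edges$mRNA))) {
      abort("duplicate edges in bi-color network")
    }
  }
  structure(list(nodes = nodes, edges = edges), class = "lnc_bicolor")
}

#' @export
print.lnc_bicolor <- function(x, ...) {
  cat("Bi-color network:", nrow(x$nodes), "nodes (",
      sum(x$nodes$color == "lncRNA"), "lncRNA /",
      sum(x$nodes$color == "mRNA"), "mRNA ),",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Markov clustering of the bi-color network
#'
#' Runs MCL on the |SCC| edge weights: self-loops are added with weight
#' equal to the node's maximum incident weight (1 for isolated nodes),
#' columns are normalized to stochastic, and expansion (matrix square) and
#' inflation (entrywise power then renormalization) alternate until the
#' largest entry change falls below `tol` or `max_iter` is hit. Clusters
#' are the connected components of the limit matrix's support; singletons
#' are reported.
#'
#' @param network An `lnc_bicolor` network, or a plain undirected edge
#'   table with columns `from`, `to` and optionally `weight` (MCL itself is
#'   agnostic to node colors).
#' @param inflation Inflation exponent, must exceed 1; default 2.
#' @param max_iter Iteration cap, default 100.
#' @param tol Convergence tolerance on the max entry change, default 1e-6.
#' @return An object of class `lnc_clusterset`: `membership` tibble
#'   (`cluster_id`, `id`, `color`), plus `inflation`, `iterations`,
#'   `converged`.
#' @export
mcl_cluster <- function(network, inflation = 2, max_iter = 100, tol = 1e-6) {
  if (inflation <= 1) abort_arg("`inflation` must exceed 1")
  if (inherits(network, "lnc_bicolor")) {
    nodes <- network$nodes
    e <- network$edges
    from <- e$lncRNA; to <- e$mRNA
    w <- abs(e$scc)
  } else if (is.data.frame(network) && all(c("from", "to") %in% names(network))) {
    from <- as.character(network$from); to <- as.character(network$to)
    w <- if ("weight" %in% names(network)) abs(network$weight) else
      rep(1, length(from))
    nodes <- tibble(id = sort(unique(c(from, to))), color = NA_character_)
  } else {
    abort_arg("`network` must be an lnc_bicolor or an edge table with from/to")
  }
  if (nrow(nodes) == 0) abort_arg("network is empty")
  n <- nrow(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes$id, nodes$id))
  if (length(from) > 0) {
    A[cbind(from, to)] <- w
    A[cbind(to, from)] <- w
  }
  loop <- apply(A, 2, max)
  loop[loop == 0] <- 1
  diag(A) <- loop
  M <- sweep(A, 2, colSums(A), "/")

  iterations <- 0
  converged <- FALSE
  col_sum_dev <- numeric(0)
  for (it in seq_len(max_iter)) {
    iterations <- it
    Mx <- M %*% M
    Mx <- Mx^inflation
    Mx <- sweep(Mx, 2, colSums(Mx), "/")
    Mx[Mx < 1e-12] <- 0
    cs <- colSums(Mx)
    Mx <- sweep(Mx, 2, cs, "/")
    col_sum_dev <- c(col_sum_dev, max(abs(colSums(Mx) - 1)))
    delta <- max(abs(Mx - M))
    M <- Mx
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }

  support <- (M + t(M)) > 1e-8
  g <- igraph::graph_from_adjacency_matrix(support, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  membership <- tibble(
    cluster_id = as.integer(comp),
    id = nodes$id,
    color = nodes$color
  ) %>% arrange(.data$cluster_id, .data$id)
  structure(list(membership = membership, inflation = inflation,
                 iterations = iterations, converged = converged,
                 col_sum_dev = col_sum_dev),
            class = "lnc_clusterset")
}

#' @export
print.lnc_clusterset <- function(x, ...) {
  cat("MCL clustering:", max(x$membership$cluster_id), "clusters over",
      nrow(x$membership), "nodes;", x$iterations, "iterations, converged =",
      x$converged, "\n")
  invisible(x)
}

#' @method tidy lnc_clusterset
#' @export
tidy.lnc_clusterset <- function(x, ...) x$membership

#' Retain clusters by cumulative lncRNA mass
#'
#' Sorts clusters by descending lncRNA count (ties: larger cluster first,
#' then lexicographically smallest member) and keeps the minimal prefix
#' whose cumulative lncRNA count reaches `mass` of all lncRNAs in clusters.
#'
#' @param clusters An `lnc_clusterset`.
#' @param mass Fraction in (0, 1], default 0.95.
#' @return An `lnc_clusterset` restricted to the retained clusters.
#' @export
filter_clusters_by_lncrna_mass <- function(clusters, mass = 0.95) {
  if (mass <= 0 || mass > 1) abort_arg("`mass` must lie in (0, 1]")
  mem <- clusters$membership
  stats <- mem %>%
    group_by(.data$cluster_id) %>%
    summarise(n_lnc = sum(.data$color == "lncRNA"), size = n(),
              first_member = min(.data$id), .groups = "drop") %>%
    arrange(desc(.data$n_lnc), desc(.data$size), .data$first_member)
  total <- sum(stats$n_lnc)
  if (total == 0) {
    keep_ids <- integer(0)
  } else {
    cum <- cumsum(stats$n_lnc)
    k <- which(cum >= mass * total)[1]
    keep_ids <- stats$cluster_id[seq_len(k)]
  }
  out <- clusters
  out$membership <- filter(mem, .data$cluster_id %in% keep_ids)
  out
}
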