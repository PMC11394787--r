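#' Threshold grid for the pseudo-time optimization
#'
#' Enumerates the fold-change / adjusted-p grid searched by
#' [optimize_ordering()]. Both ranges are open intervals, so enumeration
#' starts one step inside each: fc = fc_min + j * fc_step while < fc_max,
#' p = p_min + j * p_step while < p_max. Defaults give fc in 1.2..3.9 and
#' p in 0.0006..0.0499.
#'
#' @param fc_min,fc_max,fc_step Open fold-change interval and increment.
#' @param p_min,p_max,p_step Open adjusted-p interval and increment.
#' @return List of class `lnc_grid` with numeric vectors `fc` and `p`.
#' @export
grid_spec <- function(fc_min = 1.1, fc_max = 4.0, fc_step = 0.1,
                      p_min = 0.0005, p_max = 0.05, p_step = 0.0001) {
  if (fc_step <= 0 || p_step <= 0) abort_arg("grid steps must be positive")
  fc <- round(seq(fc_min + fc_step, fc_max, by = fc_step), 10)
  fc <- fc[fc < fc_max]
  p <- round(seq(p_min + p_step, p_max, by = p_step), 10)
  p <- p[p < p_max]
  if (length(fc) == 0 || length(p) == 0) abort_arg("grid is empty")
  structure(list(fc = fc, p = p), class = "lnc_grid")
}

# normalize per-sample DE results to a named list of tibbles
.as_result_list <- function(per_sample_results) {
  if (is.data.frame(per_sample_results)) {
    stopifnot("sample_id" %in% names(per_sample_results))
    per_sample_results <- split(
      per_sample_results[setdiff(names(per_sample_results), "sample_id")],
      per_sample_results$sample_id
    )
  }
  if (!is.list(per_sample_results) || is.null(names(per_sample_results))) {
    abort_arg("`per_sample_results` must be a named list or a long tibble")
  }
  per_sample_results
}

# feasibility of an ordered label sequence under the two gamma windows:
# (a) among the first n_mci positions, >= gamma% are MCI;
# (b) among the last n_mci + floor(n_ad / 2) positions, >= gamma% are AD.
.windows_feasible <- function(ordered_groups, gamma) {
  n_mci <- sum(ordered_groups == "MCI")
  n_ad <- sum(ordered_groups == "AD")
  if (n_mci == 0 || n_ad == 0) return(FALSE)
  w1 <- ordered_groups[seq_len(n_mci)]
  wb <- n_mci + floor(n_ad / 2)
  w2 <- tail(ordered_groups, wb)
  mean(w1 == "MCI") >= gamma / 100 && mean(w2 == "AD") >= gamma / 100
}

#' Check the gamma window constraints on an ordered label sequence
#'
#' @param ordered_groups Character vector of `"MCI"`/`"AD"` labels in
#'   pseudo-time order (ascending differential intensity).
#' @param gamma Required percentage, default 55.
#' @return Logical.
#' @export
feasibility_check <- function(ordered_groups, gamma = 55) {
  .windows_feasible(ordered_groups, gamma)
}

.solution <- function(v_tbl, fc, p, gamma) {
  v_tbl <- arrange(v_tbl, .data$v, .data$sample_id)
  structure(list(
    order = v_tbl$sample_id,
    v = v_tbl,
    fc_star = fc, p_star = p,
    objective = sum(v_tbl$v),
    feasible = .windows_feasible(v_tbl$group, gamma),
    gamma = gamma
  ), class = "lnc_ordering")
}

#' Evaluate one (fold change, adjusted p) grid point
#'
#' Calls DETs per disease sample at the given thresholds, computes each
#' sample's differential intensity V, sorts samples ascending by V (ties by
#' sample id), and checks the two gamma window constraints.
#'
#' @param per_sample_results Named list (sample id -> DE tibble from
#'   [sample_de()]) or one long tibble with a `sample_id` column.
#' @param fc Linear fold-change threshold (> 1).
#' @param p Adjusted-p threshold in (0, 1).
#' @param labels Tibble `sample_id`, `group` with groups `"MCI"`/`"AD"`.
#' @param gamma Window percentage, default 55.
#' @return An `lnc_ordering` object: `order`, `v`, `fc_star`, `p_star`,
#'   `objective`, `feasible`, `gamma`.
#' @export
evaluate_setting <- function(per_sample_results, fc, p, labels, gamma = 55) {
  if (fc <= 1) abort_arg("`fc` must exceed 1")
  if (p <= 0 || p >= 1) abort_arg("`p` must lie in (0, 1)")
  res <- .as_result_list(per_sample_results)
  groups <- sample_groups(labels)
  missing <- setdiff(names(groups), names(res))
  if (length(missing)) {
    abort_arg(paste("missing DE results for:", paste(missing, collapse = ", ")))
  }
  v <- vapply(names(groups), function(s) {
    differential_intensity(call_dets(res[[s]], fc_thresh = fc, padj_thresh = p))
  }, numeric(1))
  v_tbl <- tibble(sample_id = names(groups), group = unname(groups), v = unname(v))
  .solution(v_tbl, fc, p, gamma)
}

#' Optimize the pseudo-time ordering over the threshold grid
#'
#' Maximizes the total differential intensity over all (fc, p) grid points
#' subject to the gamma window constraints; ties broken by smaller fc, then
#' smaller p. If no grid point is feasible, the infeasible maximizer is
#' returned with `feasible = FALSE` and a warning.
#'
#' The sweep computes per-transcript statistics once per sample and applies
#' thresholds as filters via a two-dimensional cumulative sum, so a grid
#' point evaluated alone and in the sweep yield identical V values.
#'
#' @inheritParams evaluate_setting
#' @param grid A [grid_spec()].
#' @return An `lnc_ordering` object.
#' @export
optimize_ordering <- function(per_sample_results, labels, grid = grid_spec(),
                              gamma = 55) {
  res <- .as_result_list(per_sample_results)
  if (length(res) == 0) abort_arg("`per_sample_results` is empty")
  groups <- sample_groups(labels)
  missing <- setdiff(names(groups), names(res))
  if (length(missing)) {
    abort_arg(paste("missing DE results for:", paste(missing, collapse = ", ")))
  }
  sids <- names(groups)
  t_fc <- log2(grid$fc)
  p_grid <- grid$p
  nF <- length(t_fc)
  nP <- length(p_grid)

  # V for every grid point, per sample, by binned 2-D cumulative sums
  vs <- vapply(sids, function(s) {
    r <- res[[s]]
    keep <- r$base_mean >= 1
    alfc <- abs(r$log2fc[keep])
    padj <- r$padj[keep]
    nf <- findInterval(alfc, t_fc)          # passes fc index i iff i <= nf
    np <- findInterval(padj, p_grid)        # passes p index j iff j > np
    sel <- nf >= 1 & np < nP
    M <- matrix(0, nF, nP)
    if (any(sel)) {
      idx <- nf[sel] + (np[sel]) * nF       # cell (nf, np + 1)
      s2 <- rowsum(alfc[sel], idx)
      M[as.integer(rownames(s2))] <- s2
    }
    suffix <- apply(M, 2, function(col) rev(cumsum(rev(col))))
    if (nP == 1) suffix <- matrix(suffix, ncol = 1)
    V <- t(apply(suffix, 1, cumsum))
    if (nF == 1) V <- matrix(V, nrow = 1)
    as.vector(V)                            # column-major: (i, j) -> i + (j-1)*nF
  }, numeric(nF * nP))
  vs <- t(vs)                               # samples x grid points

  objective <- colSums(vs)
  feasible <- vapply(seq_len(ncol(vs)), function(k) {
    o <- order(vs[, k], sids)
    .windows_feasible(groups[sids[o]], gamma)
  }, logical(1))

  pick_from <- if (any(feasible)) which(feasible) else seq_len(ncol(vs))
  if (!any(feasible)) {
    warn("no grid point satisfies the gamma constraints; returning the infeasible maximizer")
  }
  best <- pick_from[objective[pick_from] == max(objective[pick_from])]
  # tie-break: smaller fc, then smaller p (column-major index: i + (j-1)*nF)
  i_fc <- (best - 1) %% nF + 1
  j_p <- (best - 1) %/% nF + 1
  sel <- order(i_fc, j_p)[1]
  fc_star <- grid$fc[i_fc[sel]]
  p_star <- p_grid[j_p[sel]]
  k <- best[sel]
  v_tbl <- tibble(sample_id = sids, group = unname(groups), v = unname(vs[, k]))
  .solution(v_tbl, fc_star, p_star, gamma)
}

#' Partition the pseudo-time order into contiguous bins
#'
#' The first `k - 1` bins take `ceiling(n / k)` samples each; the last bin
#' takes the remainder.
#'
#' @param solution An `lnc_ordering`.
#' @param k Number of bins, default 4.
#' @return Tibble `sample_id`, `rank`, `bin` in pseudo-time order.
#' @export
assign_bins <- function(solution, k = 4) {
  n <- length(solution$order)
  if (n < k) abort_arg("fewer samples than bins")
  size <- ceiling(n / k)
  bin <- pmin(((seq_len(n) - 1) %/% size) + 1, k)
  tibble(sample_id = solution$order, rank = seq_len(n), bin = as.integer(bin))
}

#' @method tidy lnc_ordering
#' @export
tidy.lnc_ordering <- function(x, ...) {
  mutate(x$v, rank = row_number())
}

#' @method glance lnc_ordering
#' @export
glance.lnc_ordering <- function(x, ...) {
  tibble(fc_star = x$fc_star, p_star = x$p_star, objective = x$objective,
         feasible = x$feasible, gamma = x$gamma, n_samples = length(x$order))
}

#' @export
print.lnc_ordering <- function(x, ...) {
  cat("Pseudo-time ordering of", length(x$order), "disease samples\n")
  cat(sprintf("  fc* = %.2f, p* = %.4f, objective = %.2f, feasible = %s (gamma = %g)\n",
              x$fc_star, x$p_star, x$objective, x$feasible, x$gamma))
  invisible(x)
}
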