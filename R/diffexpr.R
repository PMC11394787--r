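#' Median-of-ratios count normalization
#'
#' Size factor per sample = median, over transcripts with no zero count in
#' any sample, of the ratio of the sample's count to that transcript's
#' geometric mean across samples; normalized value = count / size factor.
#' When every transcript contains a zero the function falls back to
#' upper-quartile factors (scaled to geometric mean 1) with a warning.
#'
#' @param counts Counts tibble (`transcript_id` + sample columns),
#'   nonnegative, >= 2 samples.
#' @return List with `normalized` (tibble, same layout) and `size_factors`
#'   (tibble `sample_id`, `size_factor`).
#' @export
normalize_counts <- function(counts) {
  m <- counts_matrix(counts)
  if (ncol(m) < 2) abort_arg("need at least two samples")
  if (any(m < 0)) abort_arg("counts must be nonnegative")
  usable <- rowSums(m == 0) == 0
  if (any(usable)) {
    logm <- log(m[usable, , drop = FALSE])
    geo <- exp(rowMeans(logm))
    sf <- apply(m[usable, , drop = FALSE] / geo, 2, median)
  } else {
    warn("no transcript is zero-free; falling back to upper-quartile size factors")
    uq <- apply(m, 2, function(x) {
      nz <- x[x > 0]
      if (length(nz) == 0) NA_real_ else quantile(nz, 0.75, names = FALSE)
    })
    if (all(is.na(uq))) {
      warn("all-zero count matrix; size factors set to 1")
      sf <- rep(1, ncol(m))
    } else {
      uq[is.na(uq)] <- exp(mean(log(uq[!is.na(uq)])))
      sf <- uq / exp(mean(log(uq)))
    }
    names(sf) <- colnames(m)
  }
  norm <- sweep(m, 2, sf, "/")
  list(normalized = counts_tibble(norm),
       size_factors = tibble(sample_id = colnames(m), size_factor = unname(sf)))
}

#' Group-level differential expression (Welch test on log2 counts)
#'
#' Per transcript: `log2fc` = mean log2(normalized + 1) in `group_a` minus
#' `group_b`; two-sided Welch t-test p on the same transformed values;
#' Benjamini-Hochberg adjustment over all transcripts. Transcripts constant
#' across all compared samples get p = 1 by convention.
#'
#' @param normalized Normalized counts tibble.
#' @param group_a,group_b Disjoint character vectors of sample ids, each of
#'   size >= 2. `group_a` is the disease/numerator side.
#' @return Tibble `transcript_id`, `log2fc`, `p`, `padj`, `base_mean`.
#' @export
group_de <- function(normalized, group_a, group_b) {
  m <- counts_matrix(normalized)
  if (length(intersect(group_a, group_b)) > 0) abort_arg("groups overlap")
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort_arg("each group needs >= 2 samples")
  }
  missing <- setdiff(c(group_a, group_b), colnames(m))
  if (length(missing)) abort_arg(paste("unknown samples:", paste(missing, collapse = ", ")))
  la <- log2(m[, group_a, drop = FALSE] + 1)
  lb <- log2(m[, group_b, drop = FALSE] + 1)
  na <- ncol(la); nb <- ncol(lb)
  ma <- rowMeans(la); mb <- rowMeans(lb)
  va <- apply(la, 1, var); vb <- apply(lb, 1, var)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(tstat), df)
  p[!is.finite(tstat) | se2 == 0] <- 1
  tibble(
    transcript_id = rownames(m),
    log2fc = unname(ma - mb),
    p = unname(p),
    padj = bh_adjust(unname(p)),
    base_mean = unname(rowMeans(m[, c(group_a, group_b), drop = FALSE]))
  )
}

#' Per-sample differential expression against the control set
#'
#' `log2fc` = log2(normalized + 1) of the sample minus the control mean of
#' the same transform; p from the two-sided normal tail of the sample's
#' z-score against the control mean/sd; BH adjustment over transcripts.
#' Zero-sd control transcripts get p = 1 when the sample matches the control
#' mean, otherwise the minimum representable tail with a warning.
#'
#' @param normalized Normalized counts tibble.
#' @param sample One sample id, not in `controls`.
#' @param controls Character vector of >= 3 control sample ids.
#' @return Tibble `transcript_id`, `log2fc`, `p`, `padj`, `base_mean`.
#' @export
sample_de <- function(normalized, sample, controls) {
  m <- counts_matrix(normalized)
  if (sample %in% controls) abort_arg("`sample` must not be a control")
  if (length(controls) < 3) abort_arg("need >= 3 controls")
  lc <- log2(m[, controls, drop = FALSE] + 1)
  ls <- log2(m[, sample] + 1)
  mu <- rowMeans(lc)
  s <- apply(lc, 1, sd)
  z <- (ls - mu) / s
  p <- 2 * pnorm(-abs(z))
  degen <- s == 0
  if (any(degen)) {
    diffs <- degen & (ls != mu)
    p[degen] <- 1
    if (any(diffs)) {
      warn("zero control sd with a deviating sample value; p set to minimum tail")
      p[diffs] <- .Machine$double.xmin
    }
  }
  tibble(
    transcript_id = rownames(m),
    log2fc = unname(ls - mu),
    p = unname(p),
    padj = bh_adjust(unname(p)),
    base_mean = unname(rowMeans(m[, c(sample, controls), drop = FALSE]))
  )
}

#' Call differentially expressed transcripts (DETs)
#'
#' Retains results with linear fold change at least `fc_thresh` in either
#' direction (|log2fc| >= log2(fc_thresh)), adjusted p below `padj_thresh`,
#' and mean normalized count of at least 1.
#'
#' @param results DE result tibble (from [group_de()] or [sample_de()]).
#' @param fc_thresh Linear fold-change threshold (> 1), default 1.3.
#' @param padj_thresh Adjusted-p threshold, default 0.05.
#' @return The surviving rows with attributes `fc_thresh`/`padj_thresh` and
#'   class `lnc_detset`.
#' @export
call_dets <- function(results, fc_thresh = 1.3, padj_thresh = 0.05) {
  if (fc_thresh <= 0 || padj_thresh <= 0) abort_arg("thresholds must be positive")
  out <- filter(results,
                abs(.data$log2fc) >= log2(fc_thresh),
                .data$padj < padj_thresh,
                .data$base_mean >= 1)
  structure(out, fc_thresh = fc_thresh, padj_thresh = padj_thresh,
            class = c("lnc_detset", class(out)))
}

#' Differential intensity of a DET set
#'
#' V = sum of |log2 fold change| over the set's members; the per-sample
#' quantity whose ordering defines the pseudo-time axis.
#'
#' @param dets A DET tibble from [call_dets()].
#' @return Nonnegative scalar; 0 for an empty set.
#' @export
differential_intensity <- function(dets) {
  if (nrow(dets) == 0) return(0)
  sum(abs(dets$log2fc))
}
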