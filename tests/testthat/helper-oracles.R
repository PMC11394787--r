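# Independent oracles used across the suite. Each is deliberately coded
# from the textbook definition, not by calling the implementation under
# test.

# Benjamini-Hochberg step-up, straight from the definition: sort p, scale
# by m/rank, take the cumulative minimum from the largest rank, cap at 1.
bh_textbook <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Upper-tail hypergeometric P(X >= ov) by exhaustive enumeration of all
# size-k draws from a universe of N elements of which the first K are
# marked. Only usable for small N.
hyper_enum <- function(N, K, k, ov) {
  if (k == 0) return(as.numeric(ov <= 0))
  draws <- combn(N, k)
  mean(apply(draws, 2, function(d) sum(d <= K) >= ov))
}

# Adjusted Rand index between two labelings.
ari <- function(a, b) {
  t <- table(a, b)
  n <- sum(t)
  sum_comb <- sum(choose(t, 2))
  comb_a <- sum(choose(rowSums(t), 2))
  comb_b <- sum(choose(colSums(t), 2))
  expected <- comb_a * comb_b / choose(n, 2)
  maximum <- (comb_a + comb_b) / 2
  (sum_comb - expected) / (maximum - expected)
}

# Reference ssGSEA ECDF score, written as an explicit walk down the ranked
# list (the package implementation is vectorized).
ssgsea_ref <- function(expression, gene_set, alpha) {
  genes <- names(expression)
  N <- length(genes)
  r <- rank(expression, ties.method = "average")
  ord <- order(r, genes, decreasing = TRUE)
  wsum <- 0
  for (g in ord) if (genes[g] %in% gene_set) wsum <- wsum + r[g]^alpha
  n_out <- sum(!genes %in% gene_set)
  score <- 0
  ecdf_in <- 0
  ecdf_out <- 0
  for (g in ord) {
    if (genes[g] %in% gene_set) {
      ecdf_in <- ecdf_in + r[g]^alpha / wsum
    } else {
      ecdf_out <- ecdf_out + 1 / n_out
    }
    score <- score + (ecdf_in - ecdf_out)
  }
  unname(score)
}

# Duplex scoring shared by the oracles below.
.osc <- function(a, b, sc) {
  if ((a == "A" && b == "T") || (a == "T" && b == "A") ||
      (a == "C" && b == "G") || (a == "G" && b == "C")) return(sc$wc)
  if ((a == "G" && b == "T") || (a == "T" && b == "G")) return(sc$wobble)
  sc$mismatch
}

# Exhaustive enumeration of every local duplex between `a` and the
# reverse of `b`: all monotone sets of aligned positions, with every
# skipped internal position costing a gap. Exponential; short inputs only.
duplex_enum <- function(a, b, sc = duplex_scoring()) {
  av <- strsplit(a, "")[[1]]
  bv <- rev(strsplit(b, "")[[1]])
  m <- length(av); n <- length(bv)
  best <- 0
  recurse <- function(i, j, cur) {
    best <<- min(best, cur)
    for (i2 in (i + 1):m) {
      if (i2 > m) break
      for (j2 in (j + 1):n) {
        if (j2 > n) break
        cost <- cur + .osc(av[i2], bv[j2], sc) +
          sc$gap * ((i2 - i - 1) + (j2 - j - 1))
        recurse(i2, j2, cost)
      }
    }
  }
  for (i in seq_len(m)) for (j in seq_len(n)) {
    recurse(i, j, .osc(av[i], bv[j], sc))
  }
  best
}

# Independent top-down memoized recursion over duplex prefixes (the
# package kernel is a bottom-up iterative DP in C++).
duplex_memo <- function(a, b, sc = duplex_scoring()) {
  av <- strsplit(a, "")[[1]]
  bv <- rev(strsplit(b, "")[[1]])
  m <- length(av); n <- length(bv)
  memo <- array(NA_real_, c(m + 1, n + 1))
  e <- function(i, j) {
    if (i == 0 || j == 0) return(0)
    if (!is.na(memo[i + 1, j + 1])) return(memo[i + 1, j + 1])
    v <- min(0,
             e(i - 1, j - 1) + .osc(av[i], bv[j], sc),
             e(i - 1, j) + sc$gap,
             e(i, j - 1) + sc$gap)
    memo[i + 1, j + 1] <<- v
    v
  }
  best <- 0
  for (i in seq_len(m)) for (j in seq_len(n)) best <- min(best, e(i, j))
  best
}

# Brute-force direction search for the generalized Rayleigh quotient
# w'SBw / w'SWw (the objective the eigenproblem solves): random unit
# directions plus a Nelder-Mead polish of the best candidate. Returns both
# the maximal quotient and DS = F/(1+F) evaluated at the maximizing
# direction under the population-variance convention.
brute_fisher <- function(x1, x2, n_dir = 1e5) {
  s <- ncol(x1)
  mu1 <- colMeans(x1); mu2 <- colMeans(x2)
  d <- mu1 - mu2
  sw <- crossprod(sweep(x1, 2, mu1)) + crossprod(sweep(x2, 2, mu2))
  rayleigh <- function(w) {
    den <- drop(crossprod(w, sw %*% w))
    num <- drop(sum(w * d))^2
    if (den == 0) return(if (num == 0) 0 else Inf)
    num / den
  }
  W <- matrix(rnorm(n_dir * s), n_dir)
  W <- W / sqrt(rowSums(W^2))
  num <- drop(W %*% d)^2
  den <- rowSums((W %*% sw) * W)
  q <- ifelse(den == 0, ifelse(num == 0, 0, Inf), num / den)
  w0 <- W[which.max(q), ]
  qmax <- max(q)
  wbest <- w0
  if (s > 1 && is.finite(qmax)) {
    opt <- optim(w0, function(w) {
      if (sum(w^2) == 0) return(0)
      -rayleigh(w / sqrt(sum(w^2)))
    }, control = list(maxit = 5000, reltol = 1e-15))
    if (-opt$value > qmax) {
      qmax <- -opt$value
      wbest <- opt$par / sqrt(sum(opt$par^2))
    }
  }
  p1 <- drop(x1 %*% wbest); p2 <- drop(x2 %*% wbest)
  v1 <- mean((p1 - mean(p1))^2); v2 <- mean((p2 - mean(p2))^2)
  numf <- (mean(p1) - mean(p2))^2
  f <- if (v1 + v2 == 0) {
    if (numf == 0) 0 else Inf
  } else numf / (v1 + v2)
  list(lambda = qmax, ds = if (is.finite(f)) f / (1 + f) else 1)
}

brute_ds <- function(x1, x2, n_dir = 1e5) brute_fisher(x1, x2, n_dir)$ds

# small NB counts tibble helper: rows transcripts, cols samples
nb_counts <- function(mu, n_samples, dispersion = 0.1, prefix = "s") {
  m <- matrix(rnbinom(length(mu) * n_samples, mu = rep(mu, n_samples),
                      size = 1 / dispersion),
              nrow = length(mu))
  rownames(m) <- sprintf("t%03d", seq_along(mu))
  colnames(m) <- sprintf("%s%03d", prefix, seq_len(n_samples))
  counts_tibble(m)
}

# tiny synthetic config used where full scale is unnecessary
tiny_config <- function(seed = 1, ...) {
  synthetic_config(n_control = 8, n_mci = 8, n_ad = 8, n_mrna = 120,
                   n_lncrna = 30, n_pathways = 2, genes_per_pathway = 10,
                   n_cis_pairs = 3, n_trans_pairs = 3, seed = seed, ...)
}
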