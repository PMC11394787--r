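mk_span <- function(id, chrom, start, end, gene = NULL) {
  if (is.null(gene)) gene <- paste0("g_", id)
  tibble::tibble(transcript_id = id, gene_id = gene, chrom = chrom,
                 start = start, end = end, strand = "+")
}

test_that("cis window is inclusive, span-based and chromosome-gated", {
  lnc <- mk_span("lnc", "c1", 500000, 501000)
  genes <- dplyr::bind_rows(
    mk_span("boundary_up", "c1", 399000, 400000),    # ends exactly 100 kb before
    mk_span("inside", "c1", 450000, 455000),
    mk_span("overlap", "c1", 500500, 502000),
    mk_span("far", "c1", 700000, 705000),            # 199,000 bp away
    mk_span("other_chrom", "c2", 500000, 501000)
  )
  out <- cis_candidates(lnc, genes)
  expect_setequal(out$transcript_id, c("boundary_up", "inside", "overlap"))
  expect_equal(out$distance[out$transcript_id == "overlap"], 0)
  expect_equal(out$distance[out$transcript_id == "boundary_up"], 100000)

  # agreement with a brute-force all-pairs scan on random placements
  set.seed(6)
  genes_r <- dplyr::bind_rows(lapply(1:100, function(i) {
    s <- sample(1:2e6, 1)
    mk_span(sprintf("G%03d", i), sample(c("c1", "c2"), 1), s, s + sample(500:5000, 1))
  }))
  got <- cis_candidates(lnc, genes_r)$transcript_id
  brute <- genes_r$transcript_id[vapply(seq_len(nrow(genes_r)), function(i) {
    g <- genes_r[i, ]
    g$chrom == lnc$chrom &&
      max(0, max(g$start, lnc$start) - min(g$end, lnc$end)) <= 100000
  }, logical(1))]
  expect_setequal(got, brute)
})

test_that("duplex energy scores planted complements and rejects junk", {
  s <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = "")
  lnc <- paste0("GGGG", lncprog:::revcomp(s), "CCCC")
  target <- paste0("TTTT", s, "AAAA")
  expect_equal(trans_energy(lnc, target), -15)
  # no complementarity at all: A cannot pair with A
  expect_equal(trans_energy(strrep("A", 40), strrep("A", 40)), 0)
  # RNA alphabet accepted; invalid characters rejected
  expect_equal(trans_energy("ACGU", "ACGU"), trans_energy("ACGT", "ACGT"))
  expect_error(trans_energy("ACGN", "ACGT"), class = "lncprog_argument_error")
})

test_that("duplex DP equals exhaustive enumeration and is swap-symmetric", {
  set.seed(7)
  bases <- c("A", "C", "G", "T")
  # full path enumeration on short pairs
  for (i in 1:12) {
    a <- paste(sample(bases, sample(4:7, 1), replace = TRUE), collapse = "")
    b <- paste(sample(bases, sample(4:7, 1), replace = TRUE), collapse = "")
    expect_equal(trans_energy(a, b), duplex_enum(a, b), label = paste(a, b))
  }
  # independent memoized recursion at the 12-nt scale
  for (i in 1:15) {
    a <- paste(sample(bases, 12, replace = TRUE), collapse = "")
    b <- paste(sample(bases, sample(10:12, 1), replace = TRUE), collapse = "")
    expect_equal(trans_energy(a, b), duplex_memo(a, b), label = paste(a, b))
  }
  # energy invariant under swapping the two sequences
  for (i in 1:20) {
    a <- paste(sample(bases, sample(8:15, 1), replace = TRUE), collapse = "")
    b <- paste(sample(bases, sample(8:15, 1), replace = TRUE), collapse = "")
    expect_equal(trans_energy(a, b), trans_energy(b, a))
  }
})

test_that("pathway PCs satisfy the variance contracts", {
  set.seed(8)
  n <- 20
  samples <- sprintf("s%02d", 1:n)
  m <- matrix(rnorm(8 * n), nrow = 8,
              dimnames = list(sprintf("g%d", 1:8), samples))
  # single-gene set: one component, 100% of variance
  pc1 <- pathway_pcs(counts_tibble(m), "g1", samples)
  expect_equal(pc1$n_components, 1)
  expect_equal(pc1$var_explained[1], 1)
  # two perfectly correlated genes: first component carries everything
  m2 <- m
  m2["g2", ] <- 3 * m2["g1", ] + 5
  pc2 <- pathway_pcs(counts_tibble(m2), c("g1", "g2"), samples)
  expect_equal(pc2$n_components, 1)
  expect_equal(pc2$var_explained[1], 1, tolerance = 1e-12)
  # retained cumulative variance >= 0.6 on random data
  pcs <- pathway_pcs(counts_tibble(m), rownames(m), samples)
  expect_gte(sum(pcs$var_explained[seq_len(pcs$n_components)]), 0.6)
  # all-constant set is degenerate
  mc <- matrix(7, 2, n, dimnames = list(c("c1", "c2"), samples))
  expect_error(pathway_pcs(counts_tibble(mc), c("c1", "c2"), samples),
               "degenerate")
})

test_that("PC regression recovers exact and null relationships", {
  set.seed(9)
  n <- 50
  samples <- sprintf("s%02d", 1:n)
  f <- rnorm(n)
  genes <- t(vapply(1:6, function(i) 2 * f + rnorm(n, sd = 0.1), numeric(n)))
  rownames(genes) <- sprintf("g%d", 1:6)
  colnames(genes) <- samples
  pcs <- pathway_pcs(counts_tibble(genes), rownames(genes), samples)
  # the shared factor is PC1; regressing it on the PCs gives r2 ~ 1
  fit <- fit_lnc_pathway_regression(setNames(f, samples), pcs)
  expect_gt(fit$r2, 0.99)
  # lnc equal to PC1 exactly: r2 = 1, unit loading on PC1, zero elsewhere
  y <- setNames(pcs$scores[, 1], rownames(pcs$scores))
  fit2 <- suppressWarnings(fit_lnc_pathway_regression(y, pcs))
  expect_equal(fit2$r2, 1, tolerance = 1e-9)
  expect_equal(fit2$coefficients$estimate[1], 1, tolerance = 1e-9)
  if (nrow(fit2$coefficients) > 1) {
    expect_equal(fit2$coefficients$estimate[-1],
                 rep(0, nrow(fit2$coefficients) - 1), tolerance = 1e-9)
  }
  expect_lt(abs(fit2$intercept), 1e-9)
  # white-noise null: overall F-test p approximately uniform
  sig <- replicate(100, {
    fit_lnc_pathway_regression(setNames(rnorm(n), samples), pcs)$p < 0.05
  })
  expect_lte(sum(sig), 12)
})

test_that("planted cis and trans regulators are recovered on one seed", {
  cfg <- synthetic_config(seed = 31)
  w <- simulate_cohort(cfg)
  norm <- normalize_counts(w$counts)$normalized
  disease <- w$samples$sample_id[w$samples$group != "control"]
  lnc_ids <- w$annotation$transcript_id[w$annotation$biotype == "lncRNA"]
  mrna_ids <- w$annotation$transcript_id[w$annotation$biotype == "mRNA"]
  net <- spearman_edges(norm, lnc_ids, mrna_ids, disease)
  targets <- lnc_gene_targets(net, w$annotation, w$sequences)
  truth_cis <- with(w$truth$cis_pairs, paste(lncRNA, mRNA))
  truth_trans <- with(w$truth$trans_pairs, paste(lncRNA, mRNA))
  got_cis <- with(dplyr::filter(targets, mode == "cis"),
                  paste(lncRNA, target_gene))
  got_trans <- with(dplyr::filter(targets, mode == "trans"),
                    paste(lncRNA, target_gene))
  prec <- function(got, truth) length(intersect(got, truth)) / length(got)
  rec <- function(got, truth) length(intersect(got, truth)) / length(truth)
  expect_gte(prec(got_cis, truth_cis), 0.8)
  expect_gte(rec(got_cis, truth_cis), 0.8)
  expect_gte(prec(got_trans, truth_trans), 0.8)
  expect_gte(rec(got_trans, truth_trans), 0.8)

  # pathway-level assignment finds planted regulators with promote direction
  reg <- assign_regulators(norm, disease, net, w$annotation, w$sequences,
                           w$catalog)
  expect_gt(nrow(reg), 0)
  planted <- w$truth$regulators
  called <- dplyr::semi_join(
    planted, reg, by = c(lncRNA = "lncRNA", pathway = "pathway"))
  expect_gte(nrow(called) / nrow(planted), 0.8)
  expect_true(all(reg$direction %in% c("promote", "inhibit")))
  dirs <- dplyr::inner_join(reg, planted, by = c("lncRNA", "pathway"))
  expect_gte(mean(dirs$direction == "promote"), 0.8)
})

test_that("an external energy table replaces the built-in scorer", {
  nodes <- tibble::tibble(id = c("l1", "m1"), color = c("lncRNA", "mRNA"))
  edges <- tibble::tibble(lncRNA = "l1", mRNA = "m1", scc = 0.9,
                          p = 1e-5, padj = 1e-4)
  net <- lncprog:::new_bicolor(nodes, edges)
  ann <- dplyr::bind_rows(mk_span("l1", "c1", 1e6, 1.001e6),
                          mk_span("m1", "c2", 1e6, 1.002e6))
  tab <- tibble::tibble(lncRNA = "l1", mRNA = "m1", energy = -42)
  out <- lnc_gene_targets(net, ann, energy_table = tab)
  expect_equal(out$mode, "trans")
  expect_equal(out$evidence, -42)
})
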