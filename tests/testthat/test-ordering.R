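# fabricate a per-sample DE table whose V at lenient thresholds equals `v`
fake_result <- function(v) {
  tibble::tibble(transcript_id = "t1", log2fc = v, p = 1e-6, padj = 1e-6,
                 base_mean = 10)
}

test_that("the default grid honors the open intervals and increments", {
  g <- grid_spec()
  expect_equal(length(g$fc), 28)
  expect_equal(min(g$fc), 1.2)
  expect_equal(max(g$fc), 3.9)
  expect_equal(length(g$p), 494)
  expect_equal(min(g$p), 0.0006)
  expect_equal(max(g$p), 0.0499)
  expect_true(all(diff(g$fc) - 0.1 < 1e-9))
  expect_true(all(diff(g$p) - 0.0001 < 1e-9))
})

test_that("evaluate_setting reproduces the worked toy ordering", {
  res <- list(M1 = fake_result(1), M2 = fake_result(2),
              A1 = fake_result(10), A2 = fake_result(20))
  labels <- tibble::tibble(sample_id = c("M1", "M2", "A1", "A2"),
                           group = c("MCI", "MCI", "AD", "AD"))
  sol <- evaluate_setting(res, fc = 1.2, p = 0.001, labels, gamma = 55)
  expect_equal(sol$order, c("M1", "M2", "A1", "A2"))
  expect_equal(sol$objective, 33)
  # first-2 window 100% MCI; last-3 window 2/3 AD >= 55%
  expect_true(sol$feasible)
  # doubling every V doubles the objective and preserves order/feasibility
  res2 <- lapply(res, function(r) dplyr::mutate(r, log2fc = 2 * log2fc))
  sol2 <- evaluate_setting(res2, fc = 1.2, p = 0.001, labels, gamma = 55)
  expect_equal(sol2$order, sol$order)
  expect_equal(sol2$objective, 66)
  expect_true(sol2$feasible)
})

test_that("an all-MCI cohort can never satisfy the AD window", {
  res <- list(M1 = fake_result(1), M2 = fake_result(2), M3 = fake_result(3))
  labels <- tibble::tibble(sample_id = c("M1", "M2", "M3"), group = "MCI")
  sol <- evaluate_setting(res, 1.2, 0.001, labels)
  expect_false(sol$feasible)
})

test_that("feasibility agrees with a brute-force recount on random labelings", {
  set.seed(7)
  for (i in 1:300) {
    n_mci <- sample(2:15, 1)
    n_ad <- sample(2:15, 1)
    groups <- sample(c(rep("MCI", n_mci), rep("AD", n_ad)))
    gamma <- sample(c(40, 55, 70), 1)
    w1 <- groups[1:n_mci]
    w2 <- groups[(n_mci + n_ad - (n_mci + floor(n_ad / 2)) + 1):(n_mci + n_ad)]
    brute <- (100 * sum(w1 == "MCI") / length(w1) >= gamma) &&
      (100 * sum(w2 == "AD") / length(w2) >= gamma)
    expect_equal(feasibility_check(groups, gamma), brute)
  }
})

test_that("sweep and single-point evaluation give identical solutions", {
  set.seed(11)
  sids <- sprintf("s%02d", 1:10)
  res <- lapply(setNames(sids, sids), function(s) {
    tibble::tibble(
      transcript_id = sprintf("t%03d", 1:60),
      log2fc = rnorm(60, 0, 1.2),
      p = runif(60),
      padj = runif(60)^0.5,
      base_mean = sample(c(0.4, 5), 60, replace = TRUE)
    )
  })
  labels <- tibble::tibble(sample_id = sids,
                           group = rep(c("MCI", "AD"), each = 5))
  grid <- grid_spec(fc_min = 1.1, fc_max = 2.0, fc_step = 0.2,
                    p_min = 0.005, p_max = 0.5, p_step = 0.1)
  sol <- optimize_ordering(res, labels, grid, gamma = 40)
  # the returned optimum re-evaluated in isolation is identical
  single <- evaluate_setting(res, sol$fc_star, sol$p_star, labels, gamma = 40)
  expect_equal(single$v, sol$v)
  expect_equal(single$objective, sol$objective)
  expect_equal(single$feasible, sol$feasible)
  # exhaustive agreement over the whole grid, and optimality of the pick
  best_obj <- -Inf
  for (fc in grid$fc) for (p in grid$p) {
    s <- evaluate_setting(res, fc, p, labels, gamma = 40)
    if (s$feasible) best_obj <- max(best_obj, s$objective)
  }
  if (is.finite(best_obj)) {
    expect_true(sol$feasible)
    expect_equal(sol$objective, best_obj)
  } else {
    expect_false(sol$feasible)
  }
})

test_that("grid bounds are honored and ties break toward smaller thresholds", {
  g <- grid_spec()
  expect_true(all(g$fc > 1.1 & g$fc < 4.0))
  expect_true(all(g$p > 0.0005 & g$p < 0.05))
  # a flat landscape (identical V everywhere) must pick the smallest fc then p
  res <- list(M1 = fake_result(1), M2 = fake_result(2),
              A1 = fake_result(3), A2 = fake_result(4))
  labels <- tibble::tibble(sample_id = names(res),
                           group = c("MCI", "MCI", "AD", "AD"))
  grid <- grid_spec(fc_min = 1.1, fc_max = 1.6, fc_step = 0.1,
                    p_min = 0.005, p_max = 0.05, p_step = 0.01)
  sol <- optimize_ordering(res, labels, grid)
  expect_equal(sol$fc_star, min(grid$fc))
  expect_equal(sol$p_star, min(grid$p))
})

test_that("bin partition follows the ceiling rule", {
  mk_sol <- function(n) {
    v <- tibble::tibble(sample_id = sprintf("x%02d", 1:n),
                        group = rep(c("MCI", "AD"), length.out = n),
                        v = seq_len(n))
    evaluate_setting(
      lapply(setNames(v$sample_id, v$sample_id),
             function(s) fake_result(v$v[v$sample_id == s])),
      1.2, 0.001, v[c("sample_id", "group")])
  }
  b11 <- assign_bins(mk_sol(11), 4)
  expect_equal(as.integer(table(b11$bin)), c(3L, 3L, 3L, 2L))
  b12 <- assign_bins(mk_sol(12), 4)
  expect_equal(as.integer(table(b12$bin)), c(3L, 3L, 3L, 3L))
  expect_error(assign_bins(mk_sol(3), 4), class = "lncprog_argument_error")
  # contiguity in pseudo-time order
  expect_true(all(diff(b11$bin) >= 0))
})

test_that("pseudo-time recovery works on a reduced synthetic cohort", {
  cfg <- synthetic_config(n_control = 12, n_mci = 15, n_ad = 15,
                          n_mrna = 500, n_lncrna = 100, n_pathways = 2,
                          genes_per_pathway = 15, n_cis_pairs = 3,
                          n_trans_pairs = 3, seed = 21)
  w <- simulate_cohort(cfg)
  norm <- normalize_counts(w$counts)$normalized
  groups <- setNames(w$samples$group, w$samples$sample_id)
  controls <- names(groups)[groups == "control"]
  disease <- names(groups)[groups != "control"]
  per <- lapply(setNames(disease, disease),
                function(s) sample_de(norm, s, controls))
  sol <- optimize_ordering(per, dplyr::filter(w$samples, group != "control"),
                           grid = grid_spec(p_step = 0.001))
  tt <- setNames(w$truth$true_t$true_t, w$truth$true_t$sample_id)
  rho <- cor(seq_along(sol$order), tt[sol$order], method = "spearman")
  expect_gt(rho, 0.7)
})
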