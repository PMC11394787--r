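mk_expr <- function(mat) counts_tibble(mat)

test_that("a perfect monotone pair gets an edge; constants are skipped", {
  set.seed(1)
  x <- runif(8, 1, 100)
  m <- rbind(lnc1 = 2 * x, lnc2 = rep(5, 8), mrna1 = x,
             mrna2 = runif(8, 1, 100))
  colnames(m) <- sprintf("s%d", 1:8)
  net <- spearman_edges(mk_expr(m), c("lnc1", "lnc2"), c("mrna1", "mrna2"),
                        colnames(m))
  e <- net$edges
  perfect <- dplyr::filter(e, lncRNA == "lnc1", mRNA == "mrna1")
  expect_equal(nrow(perfect), 1)
  expect_equal(perfect$scc, 1)
  # the constant lncRNA is skipped entirely
  expect_false(any(e$lncRNA == "lnc2"))
  expect_error(spearman_edges(mk_expr(m), "lnc1", "mrna1", colnames(m)[1:4]),
               class = "lncprog_argument_error")
  expect_error(spearman_edges(mk_expr(m), c("lnc1", "x"), c("x", "mrna1"),
                              colnames(m)),
               class = "lncprog_argument_error")
})

test_that("independent white-noise pairs rarely form edges", {
  set.seed(2)
  absent <- replicate(200, {
    m <- rbind(l = rnorm(10), g = rnorm(10))
    colnames(m) <- sprintf("s%d", 1:10)
    rownames(m) <- c("l", "g")
    net <- spearman_edges(mk_expr(m), "l", "g", colnames(m))
    nrow(net$edges) == 0
  })
  expect_gte(sum(absent), 185)   # nominal 95% at alpha 0.05
})

test_that("Spearman p-values match cor.test on larger bins", {
  set.seed(3)
  m <- matrix(rnorm(15 * 12), nrow = 15)
  rownames(m) <- c(sprintf("l%02d", 1:5), sprintf("g%02d", 1:10))
  colnames(m) <- sprintf("s%02d", 1:12)
  net <- spearman_edges(mk_expr(m), sprintf("l%02d", 1:5),
                        sprintf("g%02d", 1:10), colnames(m), padj_thresh = 1)
  for (i in sample(nrow(net$edges), 10)) {
    e <- net$edges[i, ]
    ct <- cor.test(m[e$lncRNA, ], m[e$mRNA, ], method = "spearman")
    expect_equal(e$scc, unname(ct$estimate), tolerance = 1e-10)
  }
})

test_that("MCL separates two disjoint triangles and leaves singletons alone", {
  tri <- tibble::tibble(
    from = c("a1", "a2", "a3", "b1", "b2", "b3"),
    to = c("a2", "a3", "a1", "b2", "b3", "b1")
  )
  cl <- mcl_cluster(tri)
  expect_equal(max(cl$membership$cluster_id), 2)
  sets <- split(cl$membership$id, cl$membership$cluster_id)
  expect_setequal(vapply(sets, function(s) paste(sort(s), collapse = ","),
                         character(1)),
                  c("a1,a2,a3", "b1,b2,b3"))
  expect_true(all(cl$col_sum_dev <= 1e-9))

  # edgeless bi-color network: all singletons
  nodes <- tibble::tibble(id = sprintf("n%d", 1:6),
                          color = rep(c("lncRNA", "mRNA"), 3))
  empty <- lncprog:::new_bicolor(nodes, tibble::tibble(
    lncRNA = character(0), mRNA = character(0), scc = numeric(0),
    p = numeric(0), padj = numeric(0)))
  cl0 <- mcl_cluster(empty)
  expect_equal(max(cl0$membership$cluster_id), 6)
  expect_error(mcl_cluster(tri, inflation = 1),
               class = "lncprog_argument_error")
})

test_that("MCL clusters are equivariant under node relabeling", {
  set.seed(4)
  edges <- tibble::tibble(
    from = c("a", "a", "b", "d", "d", "e", "c"),
    to = c("b", "c", "c", "e", "f", "f", "d"),
    weight = c(0.9, 0.8, 0.85, 0.9, 0.8, 0.85, 0.1)
  )
  cl1 <- mcl_cluster(edges)
  perm <- setNames(c("z", "y", "x", "w", "v", "u"),
                   c("a", "b", "c", "d", "e", "f"))
  edges2 <- dplyr::mutate(edges, from = unname(perm[from]),
                          to = unname(perm[to]))
  cl2 <- mcl_cluster(edges2)
  part1 <- split(cl1$membership$id, cl1$membership$cluster_id)
  part2 <- split(cl2$membership$id, cl2$membership$cluster_id)
  canon <- function(part, map = identity) {
    sort(unname(vapply(part, function(s) paste(sort(map(s)), collapse = ","),
                       character(1))))
  }
  expect_equal(canon(part1, function(s) unname(perm[s])), canon(part2))
})

test_that("planted two-module bipartite networks are recovered (ARI >= 0.9)", {
  set.seed(5)
  n <- 30
  make_module <- function(tag, n_l, n_m) {
    f <- rnorm(n)
    vals <- t(vapply(seq_len(n_l + n_m),
                     function(i) 2 * f + rnorm(n), numeric(n)))
    rownames(vals) <- c(sprintf("%s_l%02d", tag, seq_len(n_l)),
                        sprintf("%s_m%02d", tag, seq_len(n_m)))
    vals
  }
  m <- rbind(make_module("A", 5, 10), make_module("B", 5, 10))
  colnames(m) <- sprintf("s%02d", 1:n)
  lnc <- grep("_l", rownames(m), value = TRUE)
  mrna <- grep("_m", rownames(m), value = TRUE)
  net <- spearman_edges(mk_expr(m - min(m) + 1), lnc, mrna, colnames(m))
  cl <- mcl_cluster(net)
  clustered <- cl$membership
  truth <- ifelse(grepl("^A", clustered$id), "A", "B")
  expect_gte(ari(clustered$cluster_id, truth), 0.9)
  # bipartite invariant: every edge connects a lncRNA to an mRNA
  expect_true(all(net$edges$lncRNA %in% lnc))
  expect_true(all(net$edges$mRNA %in% mrna))
})

test_that("cluster retention by cumulative lncRNA mass follows the prefix rule", {
  mk_cluster <- function(cid, n_lnc, n_mrna) {
    tibble::tibble(
      cluster_id = cid,
      id = c(sprintf("c%d_l%03d", cid, seq_len(n_lnc)),
             sprintf("c%d_m%03d", cid, seq_len(n_mrna))),
      color = c(rep("lncRNA", n_lnc), rep("mRNA", n_mrna))
    )
  }
  cs <- structure(list(membership = dplyr::bind_rows(
    mk_cluster(1, 50, 10), mk_cluster(2, 30, 10),
    mk_cluster(3, 15, 10), mk_cluster(4, 5, 10)
  ), inflation = 2, iterations = 1, converged = TRUE),
  class = "lnc_clusterset")
  kept <- filter_clusters_by_lncrna_mass(cs, 0.95)
  expect_setequal(unique(kept$membership$cluster_id), 1:3)   # 95 of 100 lncRNAs
  one <- structure(list(membership = mk_cluster(1, 2, 2)),
                   class = "lnc_clusterset")
  expect_equal(unique(filter_clusters_by_lncrna_mass(one, 0.95)$membership$cluster_id), 1)
  full <- filter_clusters_by_lncrna_mass(cs, 1.0)
  expect_setequal(unique(full$membership$cluster_id), 1:4)
  expect_error(filter_clusters_by_lncrna_mass(cs, 0),
               class = "lncprog_argument_error")
})

test_that("same-color edges are a hard failure", {
  nodes <- tibble::tibble(id = c("l1", "l2", "m1"),
                          color = c("lncRNA", "lncRNA", "mRNA"))
  bad <- tibble::tibble(lncRNA = "l1", mRNA = "l2", scc = 0.9, p = 0.001,
                        padj = 0.001)
  expect_error(lncprog:::new_bicolor(nodes, bad), "bipartite")
})
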