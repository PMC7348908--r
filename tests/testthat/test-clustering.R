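test_that("kappa agreement statistic matches the 2x2-table definition", {
  univ <- sprintf("G%03d", 1:100)
  # identical sets
  expect_equal(kappa_stat(univ[1:10], univ[1:10], univ), 1)
  # complementary halves: a = 0, d = 0 -> kappa = -1
  expect_equal(kappa_stat(univ[1:50], univ[51:100], univ), -1)
  # worked 2x2 example: |A| = |B| = 10, overlap 5 in a 100-gene universe
  k <- kappa_stat(univ[1:10], univ[6:15], univ)
  expect_equal(k, (0.90 - 0.82) / (1 - 0.82), tolerance = 1e-12)  # 0.4444
  # both sets equal to the universe
  expect_equal(kappa_stat(univ, univ, univ), 1)
  # random pairs vs generic Cohen kappa of membership vectors
  set.seed(51)
  for (r in 1:100) {
    A <- sample(univ, sample(5:60, 1))
    B <- sample(univ, sample(5:60, 1))
    expect_equal(kappa_stat(A, B, univ),
                 cohen_kappa_bruteforce(univ %in% A, univ %in% B),
                 tolerance = 1e-12)
  }
})

test_that("the kappa matrix is symmetric, unit-diagonal, and elementwise exact", {
  set.seed(52)
  genes <- sprintf("G%03d", 1:150)
  coll <- gene_set_collection(paste0("P", 1:8),
                              replicate(8, sample(genes, sample(10:40, 1)),
                                        simplify = FALSE),
                              universe = genes)
  km <- kappa_matrix(coll, universe = genes)
  expect_equal(km, t(km))
  expect_equal(unname(diag(km)), rep(1, 8))
  for (i in 1:7) for (j in (i + 1):8)
    expect_equal(km[i, j],
                 kappa_stat(coll$genes[[i]], coll$genes[[j]], genes),
                 tolerance = 1e-12)
})

test_that("consensus clustering resolves planted blocks and finds K by delta area", {
  bf <- block_dissim(c(8, 8))
  cons <- consensus_cluster(bf$dissim, K_range = 2:5, n_resamples = 200,
                            seed = 1)
  expect_equal(cons$chosen_K, 2L)
  cm <- cons$consensus[["2"]]
  same <- outer(bf$blocks, bf$blocks, `==`)
  expect_true(all(cm[same] > 0.95))
  expect_true(all(cm[!same] < 0.05))
  # entries converge across seeds
  cons2 <- consensus_cluster(bf$dissim, K_range = 2, n_resamples = 500,
                             seed = 2)
  cons3 <- consensus_cluster(bf$dissim, K_range = 2, n_resamples = 500,
                             seed = 3)
  expect_lt(max(abs(cons2$consensus[["2"]] - cons3$consensus[["2"]]),
                na.rm = TRUE), 0.05)
  # degenerate settings: one resample of everything = 0/1 co-membership
  c1 <- consensus_cluster(bf$dissim, K_range = 2, n_resamples = 1,
                          subsample_frac = 1, seed = 4)
  expect_true(all(c1$consensus[["2"]] %in% c(0, 1)))
})

test_that("cluster assignment recovers blocks and is order-invariant", {
  bf <- block_dissim(c(6, 6, 6))
  lab <- assign_clusters(bf$dissim, 3, n_resamples = 200, seed = 5)
  expect_equal(length(unique(lab)), 3L)
  expect_true(all(table(bf$blocks, lab) %in% c(0, 6)))
  # permuting input order changes nothing up to label renaming
  perm <- sample(nrow(bf$dissim))
  lab_p <- assign_clusters(bf$dissim[perm, perm], 3, n_resamples = 200,
                           seed = 5)
  agree <- outer(lab[perm], lab[perm], `==`) ==
    outer(lab_p, lab_p, `==`)
  expect_true(all(agree))
  # K = n - 1 merges at least one pair
  labn <- assign_clusters(bf$dissim, nrow(bf$dissim) - 1, n_resamples = 50,
                          seed = 6)
  expect_lt(length(unique(labn)), nrow(bf$dissim))
})

test_that("silhouette widths match the definition and the cluster-package oracle", {
  bf <- block_dissim(c(5, 5))
  lab <- rep(1:2, each = 5)
  s <- silhouette_widths(bf$dissim, lab)
  expect_true(all(s > 0.8))
  # item equidistant to its own and the other cluster has silhouette 0
  d3 <- matrix(0.5, 4, 4); diag(d3) <- 0
  dimnames(d3) <- list(paste0("x", 1:4), paste0("x", 1:4))
  expect_equal(unname(silhouette_widths(d3, c(1, 1, 2, 2))),
               rep(0, 4))
  # random instances vs the independent cluster::silhouette implementation
  skip_if_not_installed("cluster")
  set.seed(61)
  for (r in 1:10) {
    n <- sample(8:15, 1)
    d <- matrix(runif(n * n), n); d <- (d + t(d)) / 2; diag(d) <- 0
    dimnames(d) <- list(paste0("i", 1:n), paste0("i", 1:n))
    lab <- sample(1:3, n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    mine <- silhouette_widths(d, lab)
    ref <- cluster::silhouette(lab, dmatrix = d)
    # cluster:: assigns s(i) = 0 to singleton clusters; ours uses a(i) = 0
    multi <- lab %in% as.integer(names(table(lab)[table(lab) > 1]))
    expect_equal(unname(mine[multi]), unname(ref[multi, "sil_width"]),
                 tolerance = 1e-12)
  }
  expect_error(silhouette_widths(d3, c(1, 1, 1, 1)), "2 clusters")
})

test_that("silhouette tightening scatters outliers and enforces the cutoff", {
  bf <- block_dissim(c(6, 6))
  lab <- rep(1:2, each = 6)
  # clean blocks: nothing removed
  tight <- silhouette_tighten(bf$dissim, lab, cutoff = 0.1)
  expect_length(tight$scattered, 0)
  expect_true(all(tight$silhouettes >= 0.1))
  # add an outlier equidistant to both blocks: scattered in iteration 1
  n <- nrow(bf$dissim)
  d2 <- rbind(cbind(bf$dissim, out = 0.5), out = c(rep(0.5, n), 0))
  dimnames(d2) <- list(c(rownames(bf$dissim), "OUT"),
                       c(rownames(bf$dissim), "OUT"))
  tight2 <- silhouette_tighten(d2, c(lab, 1), cutoff = 0.1)
  expect_identical(tight2$scattered, "OUT")
  expect_true(all(tight2$silhouettes >= 0.1))
  # cutoff -1 is the identity on multi-member clusters
  tight3 <- silhouette_tighten(d2, c(lab, 2), cutoff = -1)
  expect_length(tight3$scattered, 0)
  # a size-1 cluster is dissolved into the scattered set
  tight4 <- silhouette_tighten(d2, c(lab, 3), cutoff = 0.1)
  expect_identical(tight4$scattered, "OUT")
})
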