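test_that("weighted Fisher statistic and its chi-square significance are exact", {
  expect_equal(fisher_statistic(c(.5, .5), c(1, 1)), -2 * 2 * log(.5),
               tolerance = 1e-12)                       # 2.772589
  expect_equal(fisher_statistic(rep(1, 4), c(1, 0, 1, 1)), 0)
  expect_equal(fisher_statistic(c(exp(-1), .3), c(1, 0)), 2)
  # single-study weight: U equals the study p-value exactly
  expect_equal(observed_significance(c(.123, .9), c(1, 0)), .123,
               tolerance = 1e-12)
  expect_equal(observed_significance(c(.5, .5), c(1, 1)),
               pchisq(-4 * log(.5), df = 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(observed_significance(c(1, 1), c(1, 1)), 1)
  # all-ones restriction reproduces classical Fisher's method
  set.seed(41)
  for (r in 1:20) {
    p <- runif(sample(2:6, 1))
    expect_equal(observed_significance(p, rep(1, length(p))),
                 pchisq(-2 * sum(log(p)), df = 2 * length(p),
                        lower.tail = FALSE), tolerance = 1e-12)
  }
  expect_error(fisher_statistic(c(0, .5), c(1, 1)), "> 0")
})

test_that("adaptive weight search matches exhaustive enumeration and known cases", {
  # the six-study kinase-activity example: weights (0,0,1,1,1,1)
  ws <- weight_search(worked_example_pvec())
  expect_identical(ws$weights, c(0L, 0L, 1L, 1L, 1L, 1L))
  # K = 1
  expect_identical(weight_search(0.2)$weights, 1L)
  expect_equal(weight_search(0.2)$T_obs, 0.2)
  # two studies, one clearly null: sparse weight wins
  ws2 <- weight_search(c(0.001, 0.9))
  expect_identical(ws2$weights, c(1L, 0L))
  expect_equal(ws2$T_obs, 0.001)
  # nested-subset reduction equals brute force over all 2^K - 1 vectors
  set.seed(42)
  for (r in 1:200) {
    K <- sample(1:8, 1)
    p <- runif(K)^sample(1:3, 1)
    got <- weight_search(p)
    ref <- aw_bruteforce(p)
    expect_equal(got$T_obs, ref$T_obs, tolerance = 1e-12)
    expect_identical(got$weights, ref$weights)
  }
})

test_that("Monte-Carlo combined p-value agrees with grid integration and is monotone", {
  # K = 1: combined p equals the p-value itself
  expect_equal(aw_pvalue(0.37)$p_combined, 0.37)
  # K = 2 cross-validation: Monte Carlo vs deterministic grid integration
  p2 <- c(0.01, 0.5)
  exact <- aw_pvalue(p2, method = "exact_smallK")$p_combined
  mc <- aw_pvalue(p2, method = "montecarlo", B = 1e6, seed = 7)$p_combined
  se <- sqrt(exact * (1 - exact) / 1e6)
  expect_lt(abs(mc - exact), 3 * se + 2e-6)
  # monotonicity: decreasing any single p_k never increases the combined p
  set.seed(43)
  for (r in 1:5) {
    p <- runif(3, 0.05, 0.9)
    base <- aw_pvalue(p, B = 1e5, seed = 100 + r)$p_combined
    k <- sample(3, 1)
    p2 <- p; p2[k] <- p[k] / 10
    better <- aw_pvalue(p2, B = 1e5, seed = 100 + r)$p_combined
    expect_lte(better, base + 3 * sqrt(base / 1e5))
  }
  # too few expected hits triggers a warning
  expect_warning(aw_pvalue(c(1e-6, 1e-6), B = 1e4, seed = 1),
                 "fewer than 10 null hits")
})

test_that("BH adjustment and significance selection behave as specified", {
  expect_equal(bh_adjust(c(.2, .2, .2)), c(.2, .2, .2))
  expect_equal(bh_adjust(c(.01, .02, .03)), c(.03, .03, .03))
  expect_equal(bh_adjust(.07), .07)
  # selection tags consensual vs differential and errors when empty
  pmat <- rbind(sig = c(1e-8, 1e-8, 1e-9), null1 = c(.5, .6, .7),
                mixed = c(1e-10, .8, .9), null2 = c(.3, .4, .5))
  colnames(pmat) <- paste0("s", 1:3)
  meta <- aw_meta(pmat, B = 1e4, seed = 5)
  expect_equal(meta$q, bh_adjust(meta$p_combined))
  sig <- select_significant(meta, q_cutoff = 0.01)
  expect_setequal(sig$pathway, c("sig", "mixed"))
  expect_identical(sig$pattern[sig$pathway == "sig"], "consensual")
  expect_identical(sig$pattern[sig$pathway == "mixed"], "differential")
  expect_error(select_significant(meta, q_cutoff = 1e-12), "cutoff")
})

test_that("matrix-level meta-analysis reproduces per-vector results deterministically", {
  set.seed(44)
  pmat <- matrix(runif(40), 10, 4,
                 dimnames = list(paste0("P", 1:10), paste0("s", 1:4)))
  m1 <- aw_meta(pmat, B = 1e4, seed = 9)
  m2 <- aw_meta(pmat, B = 1e4, seed = 9)
  expect_identical(m1, m2)                      # bit-for-bit reproducible
  # weights identical to scalar weight_search
  for (i in 1:10)
    expect_identical(unname(unlist(m1[i, paste0("w_s", 1:4)])),
                     weight_search(pmat[i, ])$weights)
})
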