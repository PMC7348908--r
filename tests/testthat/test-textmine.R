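test_that("the rule-based chunker extracts content runs between stop words", {
  res <- cpi_text_resources()
  expect_identical(extract_noun_phrases("", res), character(0))
  expect_identical(extract_noun_phrases("NADH dehydrogenase complex", res),
                   "NADH dehydrogenase complex")
  got <- extract_noun_phrases(
    "It catalyzes the transfer of a pair of electrons from NADH to a quinone",
    res)
  for (ph in c("transfer", "pair", "electrons", "NADH", "quinone"))
    expect_true(ph %in% got)
  # a pluggable extractor overrides the default
  expect_identical(extract_noun_phrases("anything", res,
                                        extractor = function(t) c("x", "x")),
                   "x")
})

test_that("phrase normalization lowercases, strips stop words and singularizes the head", {
  res <- cpi_text_resources()
  expect_identical(normalize_phrase("the electron transport chains", res),
                   "electron transport chain")
  expect_identical(normalize_phrase("a that", res), NA_character_)
  # single common English word is dropped, uncommon kept
  expect_true("cell" %in% res$common_words)
  expect_identical(normalize_phrase("cells", res), NA_character_)
  expect_identical(normalize_phrase("apoptosis", res), "apoptosis")
  # head-only lemmatization with exceptions
  expect_identical(singularize("mitochondria"), "mitochondrion")
  expect_identical(singularize("analyses"), "analysis")
  expect_identical(singularize("viruses"), "virus")
  expect_identical(singularize("diseases"), "disease")
  expect_identical(singularize("complexes"), "complex")
  expect_identical(singularize("process"), "process")
})

test_that("incidence matrices count pathway presence, not occurrences", {
  res <- cpi_text_resources()
  coll <- gene_set_collection(
    ids = paste0("P", 1:4),
    genes = replicate(4, sprintf("G%02d", 1:15), simplify = FALSE),
    names = c("T cell activation signal", "T cell exhaustion",
              "ribosome assembly", "spindle checkpoint"),
    descriptions = c(
      "T cell recruitment. T cell recruitment. T cell recruitment",
      "controls the T cell recruitment",
      "",                                                      # empty
      "ribosome assembly. also ribosome assembly"))
  mats <- build_phrase_matrices(coll, res)
  # repeated occurrence within one description is a single presence
  expect_true(all(mats$v@x <= 1) && all(mats$w@x <= 1))
  expect_equal(unname(mats$w["t cell recruitment", 1]), 1)
  expect_equal(sum(mats$w["t cell recruitment", ]), 2)   # pathways, not hits
  expect_equal(unname(mats$desc_len[3]), 0)        # empty description
  expect_equal(sum(mats$w[, 3]), 0)
  expect_equal(unname(mats$w["ribosome assembly", 4]), 1)
  expect_equal(unname(mats$v["ribosome assembly", 3]), 1)

  # pruning: support counted on OR of name/description presence
  pruned <- prune_rare_phrases(mats)
  expect_true("ribosome assembly" %in% pruned$phrases)   # name P3 + desc P4
  supp <- Matrix::rowSums((mats$v + mats$w) > 0)
  expect_true(all(Matrix::rowSums((pruned$v + pruned$w) > 0) >= 2))
  expect_false(any(names(supp[supp < 2]) %in% pruned$phrases))
})

test_that("synonym rows merge into the more frequent phrase", {
  res <- cpi_text_resources()
  coll <- gene_set_collection(
    ids = paste0("P", 1:7),
    genes = replicate(7, sprintf("G%02d", 1:15), simplify = FALSE),
    names = c(rep("tumor suppressor", 5), rep("tumour suppressor", 2)),
    descriptions = rep("", 7))
  mats <- build_phrase_matrices(coll, res)
  merged <- merge_synonyms(mats, data.frame(a = "tumour suppressor",
                                            b = "tumor suppressor"))
  expect_false("tumour suppressor" %in% merged$phrases)
  expect_equal(sum(merged$v["tumor suppressor", ]), 7)
  # no synonyms: identity
  expect_identical(merge_synonyms(mats, NULL)$phrases, mats$phrases)
  # equal occurrence: lexicographically smaller phrase kept
  coll2 <- gene_set_collection(
    ids = paste0("Q", 1:4),
    genes = replicate(4, sprintf("G%02d", 1:15), simplify = FALSE),
    names = c("beta fold", "beta fold", "zeta fold", "zeta fold"),
    descriptions = rep("", 4))
  m2 <- merge_synonyms(build_phrase_matrices(coll2, res),
                       data.frame(a = "zeta fold", b = "beta fold"))
  expect_true("beta fold" %in% m2$phrases)
  expect_false("zeta fold" %in% m2$phrases)
})

test_that("penalized scores follow the piecewise definition and its limits", {
  res <- cpi_text_resources()
  n_filler <- 19
  fillers <- paste("zq", sprintf("fill%02d", 1:n_filler))
  coll <- gene_set_collection(
    ids = c("NAMEHIT", "DESCHIT", "MISS"),
    genes = replicate(3, sprintf("G%02d", 1:15), simplify = FALSE),
    names = c("proteasome degradation", "unrelated title", "other title"),
    descriptions = c("short note",
                     paste(c("proteasome degradation", fillers),
                           collapse = " and "),
                     ""))
  mats <- build_phrase_matrices(coll, res)
  expect_equal(unname(mats$desc_len["DESCHIT"]), 20)
  sc <- penalized_scores(mats, alpha = 0.05)
  expect_equal(unname(sc$x["proteasome degradation", "NAMEHIT"]), 1)
  expect_equal(unname(sc$x["proteasome degradation", "DESCHIT"]),
               exp(-1), tolerance = 1e-12)              # exp(-0.05 * 20)
  expect_equal(unname(sc$x["proteasome degradation", "MISS"]), 0)
  # alpha = 0: description hits score 1 (counting regime)
  sc0 <- penalized_scores(mats, alpha = 0)
  expect_equal(unname(sc0$x["proteasome degradation", "DESCHIT"]), 1)
  # score is non-increasing in description length and alpha, always in [0,1]
  expect_true(all(sc$x >= 0 & sc$x <= 1))
  sc2 <- penalized_scores(mats, alpha = 0.1)
  expect_true(all(sc2$x <= sc$x + 1e-15))
  # cluster statistic is the plain sum over members
  T1 <- cluster_statistic(sc, c("NAMEHIT", "DESCHIT"))
  expect_equal(unname(T1["proteasome degradation"]), 1 + exp(-1),
               tolerance = 1e-12)
  expect_equal(unname(cluster_statistic(sc, "MISS")["proteasome degradation"]),
               0)
  expect_error(cluster_statistic(sc, character(0)), "empty")
})

test_that("permutation p-values hit their analytic anchors", {
  res <- cpi_text_resources()
  coll <- names_only_collection(40)
  # give the first 8 pathways an exclusive marker phrase in their names
  coll$names[1:8] <- paste(coll$names[1:8], "and zq exclusive marker")
  mats <- prune_rare_phrases(build_phrase_matrices(coll, res))
  sc <- penalized_scores(mats, alpha = 0.05)
  B <- 2000
  p <- permutation_test(sc, coll$ids[1:8], B = B, seed = 77)
  expect_equal(unname(p["zq exclusive marker"]), 1 / (B + 1))
  # a phrase absent from the cluster and rare outside: p = 1 is allowed;
  # all p-values live in [1/(B+1), 1]
  expect_true(all(p >= 1 / (B + 1) & p <= 1))
  # reproducible bit-for-bit under the same seed
  p2 <- permutation_test(sc, coll$ids[1:8], B = B, seed = 77)
  expect_identical(p, p2)
  expect_error(permutation_test(sc, c(coll$ids[1], "nope"), B = B), "subset")
})

test_that("at alpha 0 on a names-only corpus the permutation test matches the hypergeometric tail", {
  res <- cpi_text_resources()
  coll <- names_only_collection(50)
  mats <- prune_rare_phrases(build_phrase_matrices(coll, res))
  sc <- penalized_scores(mats, alpha = 0)
  cluster <- coll$ids[1:10]
  B <- 1e4
  p_hat <- permutation_test(sc, cluster, B = B, seed = 78)
  x <- (sc$v + sc$w) > 0
  n_bg <- length(coll$ids)
  # joint bound over all phrases: 4 binomial SEs keeps the familywise
  # false-alarm rate of this check below ~0.1% across the ~10 phrases
  for (ph in rownames(x)) {
    m <- sum(x[ph, ])                       # phrase support in background
    k <- sum(x[ph, cluster])                # observed cluster hits
    p_exact <- hyper_tail_bruteforce(k, n_bg, m, length(cluster))
    tol <- 4 * sqrt(p_exact * (1 - p_exact) / B) + 2 / (B + 1)
    expect_lt(abs(p_hat[ph] - p_exact), tol + 1e-12)
  }
})

test_that("keyword annotation finds injected cluster keywords and ranks by q", {
  res <- cpi_text_resources()
  set.seed(80)
  n <- 60
  coll <- names_only_collection(n, seed = 80)
  # inject a keyword into 8 of 10 cluster member names; ~2% elsewhere
  cluster <- coll$ids[1:10]
  coll$names[1:8] <- paste(coll$names[1:8], "and synaptic pruning")
  coll$names[30] <- paste(coll$names[30], "and synaptic pruning")
  mats <- prune_rare_phrases(build_phrase_matrices(coll, res))
  sc <- penalized_scores(mats, alpha = 0.05)
  labels <- stats::setNames(rep(1:2, c(10, 10)), coll$ids[1:20])
  ann <- annotate_clusters(sc, labels, B = 1e4, seed = 81)
  hit <- ann[ann$cluster == "1" & ann$phrase == "synaptic pruning", ]
  expect_lt(hit$q, 0.05)
  expect_true(hit$significant)
  expect_equal(hit$support, 8)
  # within each cluster rows are sorted by (q, then statistic descending)
  for (g in unique(ann$cluster)) {
    sub <- ann[ann$cluster == g, ]
    expect_true(!is.unsorted(sub$q))
  }
  # a cluster with no signal yields no keywords but no error
  expect_true(all(!ann$significant[ann$cluster == "2" &
                                     ann$phrase == "synaptic pruning"]))
  # keyword summary table mirrors cluster -> keyword layout
  kt <- keyword_table(ann)
  expect_identical(names(kt), c("cluster", "keywords"))
  expect_match(kt$keywords[kt$cluster == "1"], "synaptic pruning")
})

test_that("the length penalty promotes name hits over long-description noise", {
  res <- cpi_text_resources()
  fillers <- paste("zz", sprintf("fill%03d", 1:100))
  long_desc <- paste(c("spurious verbiage", fillers), collapse = " and ")
  ids <- c(sprintf("SHORT%d", 1:5), sprintf("LONG%d", 1:5),
           sprintf("BG%02d", 1:40))
  nms <- c(rep("apoptosis induction", 5), rep("unrelated heading", 5),
           vapply(1:40, function(i) paste("background title", letters[i %% 24 + 1]), ""))
  dsc <- c(rep("brief remark", 5), rep(long_desc, 5), rep("", 40))
  coll <- gene_set_collection(ids,
                              replicate(50, sprintf("G%02d", 1:15),
                                        simplify = FALSE),
                              names = nms, descriptions = dsc)
  mats <- prune_rare_phrases(build_phrase_matrices(coll, res))
  cluster <- c(sprintf("SHORT%d", 1:5), sprintf("LONG%d", 1:5))
  # raw counting (alpha = 0) ties the name phrase with the description phrase
  sc0 <- penalized_scores(mats, alpha = 0)
  T0 <- cluster_statistic(sc0, cluster)
  expect_equal(unname(T0["apoptosis induction"]), unname(T0["spurious verbiage"]))
  # the penalty (alpha = 0.05) ranks the name phrase strictly higher
  sc <- penalized_scores(mats, alpha = 0.05)
  Tp <- cluster_statistic(sc, cluster)
  expect_gt(unname(Tp["apoptosis induction"]), unname(Tp["spurious verbiage"]))
  expect_lt(unname(Tp["spurious verbiage"]), 0.05)     # 5 * exp(-0.05 * |w_j|), |w_j| > 100
})
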