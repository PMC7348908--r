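# Independent oracles and fixture builders shared across tests.

# Brute-force hypergeometric upper tail P(X >= k) by pmf summation.
hyper_tail_bruteforce <- function(k, N, K, n) {
  xs <- k:min(K, n)
  xs <- xs[xs >= max(0L, n - (N - K))]
  if (!length(xs)) return(0)
  sum(choose(K, xs) * choose(N - K, n - xs) / choose(N, n))
}

# Exhaustive AW weight search over all 2^K - 1 nonzero binary weight vectors.
aw_bruteforce <- function(pvec) {
  K <- length(pvec)
  best_u <- Inf; best_w <- NULL
  for (code in 1:(2^K - 1)) {
    w <- as.integer(intToBits(code)[1:K])
    u <- stats::pchisq(-2 * sum(w * log(pvec)), df = 2 * sum(w),
                      lower.tail = FALSE)
    if (u < best_u * (1 - 1e-12) ||
        (u <= best_u * (1 + 1e-12) && sum(w) < sum(best_w))) {
      best_u <- u; best_w <- w
    }
  }
  list(weights = best_w, T_obs = best_u)
}

# Cohen kappa of two binary membership vectors via the generic 2x2 table.
cohen_kappa_bruteforce <- function(membA, membB) {
  a <- sum(membA & membB); b <- sum(membA & !membB)
  c_ <- sum(!membA & membB); d <- sum(!membA & !membB)
  n <- a + b + c_ + d
  po <- (a + d) / n
  pe <- ((a + b) * (a + c_) + (c_ + d) * (b + d)) / n^2
  (po - pe) / (1 - pe)
}

# Block-structured dissimilarity: items in the same block are close,
# items in different blocks far; small deterministic jitter breaks ties.
block_dissim <- function(sizes, within = 0.05, between = 0.95) {
  n <- sum(sizes)
  blk <- rep(seq_along(sizes), sizes)
  d <- ifelse(outer(blk, blk, `==`), within, between)
  set.seed(99)
  jit <- matrix(stats::runif(n * n, 0, 0.02), n)
  jit <- (jit + t(jit)) / 2
  d <- d + jit
  diag(d) <- 0
  dimnames(d) <- list(paste0("P", seq_len(n)), paste0("P", seq_len(n)))
  list(dissim = d, blocks = blk)
}

# Write a toy GMT file from a named list of gene vectors.
write_toy_gmt <- function(sets, descs = NULL) {
  path <- tempfile(fileext = ".gmt")
  if (is.null(descs)) descs <- rep("na", length(sets))
  writeLines(vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descs[i], sets[[i]]), collapse = "\t"), ""),
    path)
  path
}

# Names-only phrase corpus: n pathways, phrase vocabulary assigned to names
# with given per-pathway support; descriptions empty.
names_only_collection <- function(n = 50L, seed = 5L) {
  set.seed(seed)
  vocab <- c("apoptosis", "kinase signaling", "membrane fusion",
             "dna repair", "proton gradient", "ribosome biogenesis",
             "lipid droplet", "immune synapse")
  nm <- vapply(seq_len(n), function(i)
    paste(sample(vocab, sample(2:3, 1)), collapse = " and "), "")
  gene_set_collection(ids = sprintf("PW%02d", seq_len(n)),
                      genes = replicate(n, sample(sprintf("G%03d", 1:300), 20),
                                        simplify = FALSE),
                      names = nm,
                      descriptions = rep("", n))
}
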