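#' Weighted Fisher statistic
#'
#' `V(w) = -2 * sum_k w_k * log(p_k)` for a 0/1 study weight vector `w`.
#'
#' @param pvec numeric vector of per-study p-values in (0, 1].
#' @param w 0/1 weight vector of the same length, at least one 1.
#' @return the statistic `V(w)`.
#' @export
fisher_statistic <- function(pvec, w) {
  check_pvec(pvec)
  w <- check_weights(w, length(pvec))
  -2 * sum(w * log(pvec))
}

#' Observed significance of a weighted Fisher statistic
#'
#' `U(w)`: upper-tail probability of a chi-square distribution with
#' `2 * sum(w)` degrees of freedom evaluated at `V(w)`. With a single-study
#' weight this is exactly that study's p-value.
#'
#' @inheritParams fisher_statistic
#' @return `U(w)` in (0, 1].
#' @export
observed_significance <- function(pvec, w) {
  check_pvec(pvec)
  w <- check_weights(w, length(pvec))
  stats::pchisq(fisher_statistic(pvec, w), df = 2 * sum(w),
                lower.tail = FALSE)
}

#' Adaptive weight search
#'
#' Finds the 0/1 study weight vector minimizing the observed significance
#' `U(w)` over all `2^K - 1` nonzero weight vectors. By monotone optimality
#' the minimum is attained on one of the K nested subsets formed by the `s`
#' smallest p-values (`s = 1..K`), so only those are evaluated. Ties are
#' broken toward the smaller weight sum (the sparser explanation).
#'
#' @param pvec numeric vector of per-study p-values in (0, 1].
#' @return list with `weights` (0/1 integer vector in the original study
#'   order), `T_obs` (the minimized `U`), and `n_selected` (`sum(weights)`).
#' @export
weight_search <- function(pvec) {
  check_pvec(pvec)
  K <- length(pvec)
  ord <- order(pvec, method = "radix")
  cum <- cumsum(-2 * log(pvec[ord]))
  u <- stats::pchisq(cum, df = 2 * seq_len(K), lower.tail = FALSE)
  s_best <- which.min(u)          # which.min returns the first (smallest s)
  w <- integer(K)
  w[ord[seq_len(s_best)]] <- 1L
  list(weights = w, T_obs = u[s_best], n_selected = s_best)
}

#' Adaptively weighted Fisher combined p-value
#'
#' Combines per-study p-values into one meta-analytic p-value:
#' `P(min_w U(W) <= T_obs)` under K i.i.d. Uniform(0,1) null p-values, where
#' `T_obs` is the minimized observed significance of `pvec` (see
#' [weight_search]).
#'
#' `method = "montecarlo"` draws `B` null p-vectors (compiled, vectorized)
#' and applies the +1-corrected estimator `(1 + hits) / (B + 1)`, which never
#' returns 0. `method = "exact_smallK"` (K <= 3 only) integrates the event
#' region deterministically: in closed form for K = 2, and for K = 3 on a
#' midpoint grid (the third coordinate handled analytically) refined until
#' two successive refinements agree to 0.5% relative; it serves as a small-K
#' oracle independent of the sampler.
#'
#' @param pvec numeric vector of per-study p-values in (0, 1].
#' @param method `"montecarlo"` or `"exact_smallK"`.
#' @param B number of Monte-Carlo draws (>= 1e4).
#' @param seed optional integer seed applied before drawing.
#' @return list with `p_combined`, `weights`, `T_obs`, `method`, `B`.
#' @export
aw_pvalue <- function(pvec, method = c("montecarlo", "exact_smallK"),
                      B = 1e4, seed = NULL) {
  method <- match.arg(method)
  ws <- weight_search(pvec)
  K <- length(pvec)
  if (K == 1L) {
    p <- pvec[1L]
  } else if (method == "montecarlo") {
    if (B < 1e4) stop("B must be >= 1e4 for the Monte-Carlo method")
    if (!is.null(seed)) set.seed(seed)
    hits <- aw_null_count_le(B, K, ws$T_obs)
    if (hits < 10)
      warning("fewer than 10 null hits at B = ", format(B),
              "; increase B for a stable estimate")
    p <- (1 + hits) / (B + 1)
  } else {
    if (K > 3L) stop("exact_smallK requires K <= 3")
    p <- aw_exact_smallK(ws$T_obs, K)
  }
  list(p_combined = unname(p), weights = ws$weights, T_obs = ws$T_obs,
       method = if (K == 1L) "trivial" else method, B = B)
}

# Deterministic integration of P(min_w U(W) <= t) for K <= 3, used as the
# small-K oracle. The event {min_w U <= t} is, for fixed values of the other
# p-values, monotone in the last coordinate: it holds exactly when that
# coordinate lies below a computable threshold r(.). Integrating the last
# coordinate analytically leaves a smooth(ish) 1-D (K = 2) or 2-D (K = 3)
# midpoint integral over the remaining uniforms, refined (grid doubling)
# until two successive estimates agree to `rel_tol` relative.
#
# With c_s = exp(-qchisq(t, 2s, upper)/2), the nested-subset conditions are
# p_(1) <= t, p_(1)p_(2) <= c_2, p_(1)p_(2)p_(3) <= c_3.
aw_exact_smallK <- function(t_obs, K, rel_tol = 0.005, m_start = 512L,
                            m_max = 4096L) {
  stopifnot(K %in% 1:3)
  if (K == 1L) return(t_obs)
  c2 <- exp(-stats::qchisq(t_obs, df = 4, lower.tail = FALSE) / 2)
  if (K == 2L) {
    # closed form: P = t + int_t^1 max(t, min(1, c2/x)) dx
    x1 <- min(max(c2, t_obs), 1)          # below x1 the pair condition is sure
    x2 <- min(max(c2 / t_obs, t_obs), 1)  # above x2 only the singleton helps
    return(t_obs + (x1 - t_obs) + c2 * (log(x2) - log(x1)) +
             (1 - x2) * t_obs)
  }
  c3 <- exp(-stats::qchisq(t_obs, df = 6, lower.tail = FALSE) / 2)
  est_for <- function(m) {
    mid <- (seq_len(m) - 0.5) / m
    a <- rep(mid, each = m); b <- rep.int(mid, m)
    lo <- pmin(a, b); hi <- pmax(a, b)
    r <- ifelse(lo <= t_obs | lo * hi <= c2, 1,
                pmin(1, pmax(t_obs, pmax(c2 / lo, c3 / (lo * hi)))))
    mean(r)
  }
  m <- min(m_start, m_max)
  prev <- est_for(m)
  repeat {
    if (2L * m > m_max) {
      warning("grid integration did not reach ", rel_tol,
              " relative agreement; t_obs may be too extreme for the ",
              "exact_smallK method")
      return(prev)
    }
    m <- 2L * m
    cur <- est_for(m)
    if (cur > 0 && abs(cur - prev) <= rel_tol * cur) return(cur)
    prev <- cur
  }
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH with enforced monotonicity, delegated to [stats::p.adjust].
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  stopifnot(is.numeric(pvals), all(pvals >= 0 & pvals <= 1))
  stats::p.adjust(pvals, method = "BH")
}

#' Meta-analyze a pathway x study p-value matrix
#'
#' Runs the adaptive weight search per pathway, estimates the combined
#' p-values against a single shared Monte-Carlo null sample (the null
#' distribution of the minimum observed significance does not depend on the
#' data, so one sample of `B` draws serves every pathway), and applies BH
#' correction across pathways.
#'
#' @param pmat numeric matrix pathways x studies of raw enrichment p-values
#'   in (0, 1].
#' @param B number of Monte-Carlo null draws (default 1e4).
#' @param seed optional integer seed.
#' @return data frame with one row per pathway: `pathway`, per-study raw
#'   p-value columns `p_<study>`, weight columns `w_<study>`, `T_obs`,
#'   `p_combined`, `q`, and `pattern` (`"consensual"` if all weights are 1,
#'   `"differential"` otherwise). Attribute `"B"` and `"seed"` record the
#'   Monte-Carlo settings.
#' @export
aw_meta <- function(pmat, B = 1e4, seed = NULL) {
  validate_pvalue_matrix(pmat, "enrichment p-value")
  K <- ncol(pmat)
  if (!is.null(seed)) set.seed(seed)
  searches <- apply(pmat, 1L, weight_search)
  T_obs <- vapply(searches, `[[`, 0, "T_obs")
  W <- t(vapply(searches, `[[`, integer(K), "weights"))
  null_sorted <- sort(aw_null_sample(as.integer(B), K))
  hits <- findInterval(T_obs, null_sorted)   # #{T_b <= T_obs}
  p_comb <- (1 + hits) / (B + 1)
  q <- bh_adjust(p_comb)
  studies <- colnames(pmat)
  out <- data.frame(pathway = rownames(pmat), pmat, W,
                    T_obs = unname(T_obs), p_combined = unname(p_comb),
                    q = unname(q),
                    pattern = ifelse(rowSums(W) == K, "consensual",
                                     "differential"),
                    check.names = FALSE, stringsAsFactors = FALSE,
                    row.names = NULL)
  names(out)[2:(K + 1)] <- paste0("p_", studies)
  names(out)[(K + 2):(2 * K + 1)] <- paste0("w_", studies)
  attr(out, "B") <- B
  attr(out, "seed") <- seed
  attr(out, "studies") <- studies
  out
}

#' Select significant pathways from a meta-analysis table
#'
#' @param meta data frame from [aw_meta].
#' @param q_cutoff q-value threshold; pathways with `q < q_cutoff` are kept
#'   (default 0.0005).
#' @return the selected rows of `meta`, still carrying the `pattern` tag.
#' @export
select_significant <- function(meta, q_cutoff = 5e-4) {
  stopifnot(is.data.frame(meta), q_cutoff > 0, q_cutoff < 1)
  keep <- meta$q < q_cutoff
  if (!any(keep))
    stop("no pathway with q < ", q_cutoff,
         "; consider a larger q-value cutoff")
  meta[keep, , drop = FALSE]
}

check_pvec <- function(pvec) {
  if (!is.numeric(pvec) || !length(pvec))
    stop("pvec must be a non-empty numeric vector")
  if (anyNA(pvec)) stop("missing p-values")
  if (any(pvec <= 0))
    stop("p-values must be > 0 (floor underflowed values upstream)")
  if (any(pvec > 1)) stop("p-values must be <= 1")
  invisible(pvec)
}

check_weights <- function(w, K) {
  if (length(w) != K) stop("weight vector length must equal length(pvec)")
  if (!all(w %in% c(0, 1))) stop("weights must be 0/1")
  if (sum(w) < 1) stop("at least one weight must be 1")
  as.integer(w)
}
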