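#' Cohen's kappa between two gene sets
#'
#' Chance-corrected agreement of the two binary gene-membership vectors over
#' a background universe. With the 2x2 table `a = |A∩B|`, `b = |A\\B|`,
#' `c = |B\\A|`, `d = n - a - b - c`, `n = |universe|`:
#' `Po = (a + d) / n`, `Pe = ((a+b)(a+c) + (c+d)(b+d)) / n^2`,
#' `kappa = (Po - Pe) / (1 - Pe)`.
#'
#' @param setA,setB character vectors of gene symbols, subsets of `universe`.
#' @param universe background gene universe (>= 2 genes).
#' @return kappa in \[-1, 1\].
#' @export
kappa_stat <- function(setA, setB, universe) {
  universe <- unique(universe)
  n <- length(universe)
  if (n < 2L) stop("universe must contain at least 2 genes")
  setA <- unique(setA); setB <- unique(setB)
  if (!all(setA %in% universe) || !all(setB %in% universe))
    stop("sets must be subsets of the universe")
  a <- length(intersect(setA, setB))
  b <- length(setA) - a
  c_ <- length(setB) - a
  d <- n - a - b - c_
  po <- (a + d) / n
  pe <- ((a + b) * (a + c_) + (c_ + d) * (b + d)) / n^2
  if (pe >= 1) {
    if (b == 0L && c_ == 0L) return(1)   # identical sets (incl. both = universe)
    stop("kappa undefined: expected agreement is 1 for non-identical sets")
  }
  (po - pe) / (1 - pe)
}

#' Pairwise kappa matrix of a collection
#'
#' @param coll a [gene_set_collection] (typically restricted to the
#'   significant pathways).
#' @param universe background for the membership vectors; by default the
#'   union of genes across the collection's sets (configurable to the full
#'   collection universe).
#' @return symmetric matrix of kappa values with unit diagonal, dimnames =
#'   pathway ids.
#' @export
kappa_matrix <- function(coll, universe = NULL) {
  stopifnot(inherits(coll, "gene_set_collection"))
  n <- length(coll$ids)
  if (n < 2L) stop("need at least 2 pathways")
  if (is.null(universe))
    universe <- unique(unlist(coll$genes, use.names = FALSE))
  universe <- unique(universe)
  # membership matrix: genes x pathways
  memb <- vapply(coll$genes, function(g) universe %in% g,
                 logical(length(universe)))
  sizes <- colSums(memb)
  inter <- crossprod(memb * 1)             # a for each pair
  N <- length(universe)
  A <- matrix(sizes, n, n)                  # |setA| per row
  B <- t(A)                                 # |setB|
  a <- inter
  b <- A - a
  c_ <- B - a
  d <- N - a - b - c_
  po <- (a + d) / N
  pe <- ((a + b) * (a + c_) + (c_ + d) * (b + d)) / N^2
  k <- (po - pe) / (1 - pe)
  k[pe >= 1] <- 1                           # identical-to-universe pairs
  diag(k) <- 1
  dimnames(k) <- list(coll$ids, coll$ids)
  k
}

#' Kappa dissimilarity
#'
#' @param kappa symmetric kappa matrix.
#' @return `1 - kappa`, with zero diagonal.
#' @export
kappa_dissimilarity <- function(kappa) {
  d <- 1 - kappa
  diag(d) <- 0
  d
}

#' Consensus clustering over a range of cluster numbers
#'
#' Resampling-based clustering stability: for each candidate `K`, repeatedly
#' subsample the items, cluster the subsample (average-linkage hierarchical
#' clustering on the subsampled dissimilarity), and record co-membership.
#' The consensus matrix entry for a pair is its co-clustering count divided
#' by its co-sampling count. The empirical CDF of off-diagonal consensus
#' entries and its area, together with the relative increase of that area
#' (`delta area`) as `K` grows, are computed as the standard diagnostics
#' (the elbow and CDF plots). Because a numerical elbow threshold on the
#' delta-area curve is fragile, the automatic choice of `K` instead takes
#' the candidate whose consensus partition maximizes the average silhouette
#' width on the input dissimilarity (members of size-1 clusters count 0);
#' it is best-effort — inspect the diagnostic plots and override `K` for
#' fidelity.
#'
#' @param dissim symmetric dissimilarity matrix (e.g. `1 - kappa`).
#' @param K_range integer candidates, within `[2, n - 1]` (default `2:10`,
#'   truncated to the feasible range).
#' @param n_resamples subsampling repetitions per K (default 500).
#' @param subsample_frac fraction of items per subsample (default 0.8).
#' @param seed optional integer seed.
#' @return object of class `cpi_consensus`: list with `consensus` (list of
#'   consensus matrices, one per K), `areas`, `delta_area`, `mean_silhouette`
#'   (per candidate partition), `chosen_K`, `K_range`, `cdf_grid`, `cdfs`.
#' @export
consensus_cluster <- function(dissim, K_range = 2:10, n_resamples = 500L,
                              subsample_frac = 0.8, seed = NULL) {
  stopifnot(is.matrix(dissim), nrow(dissim) == ncol(dissim))
  n <- nrow(dissim)
  K_range <- sort(unique(as.integer(K_range)))
  K_range <- K_range[K_range >= 2L & K_range <= n - 1L]
  if (!length(K_range)) stop("K_range has no feasible candidate in [2, n-1]")
  if (subsample_frac <= 0 || subsample_frac > 1)
    stop("subsample_frac must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  m <- max(2L, round(subsample_frac * n))
  # precompute subsamples shared across K so K comparisons are paired
  subsamples <- replicate(n_resamples, sort(sample.int(n, m)),
                          simplify = FALSE)
  co_sampled <- matrix(0, n, n)
  for (s in subsamples) co_sampled[s, s] <- co_sampled[s, s] + 1
  grid <- seq(0, 1, by = 0.01)
  consensus <- vector("list", length(K_range))
  names(consensus) <- as.character(K_range)
  cdfs <- matrix(NA_real_, length(K_range), length(grid),
                 dimnames = list(as.character(K_range), NULL))
  areas <- numeric(length(K_range))
  hcs <- lapply(subsamples, function(s)
    stats::hclust(stats::as.dist(dissim[s, s, drop = FALSE]),
                  method = "average"))
  for (ki in seq_along(K_range)) {
    K <- K_range[ki]
    co_clustered <- matrix(0, n, n)
    for (b in seq_len(n_resamples)) {
      s <- subsamples[[b]]
      lab <- stats::cutree(hcs[[b]], k = min(K, length(s)))
      same <- outer(lab, lab, `==`) * 1
      co_clustered[s, s] <- co_clustered[s, s] + same
    }
    cons <- co_clustered / co_sampled
    never <- co_sampled == 0
    if (any(never[upper.tri(never)]))
      warning(sum(never[upper.tri(never)]),
              " pair(s) never co-sampled; consensus entries flagged NA ",
              "and excluded from the CDF")
    cons[never] <- NA_real_
    diag(cons) <- 1
    dimnames(cons) <- dimnames(dissim)
    consensus[[ki]] <- cons
    off <- cons[upper.tri(cons)]
    off <- off[!is.na(off)]
    cdf <- stats::ecdf(off)(grid)
    cdfs[ki, ] <- cdf
    areas[ki] <- sum(diff(grid) * cdf[-1L])
  }
  delta <- numeric(length(K_range))
  delta[1L] <- areas[1L]
  if (length(K_range) > 1L)
    delta[-1L] <- diff(areas) / areas[-length(areas)]
  # K choice: quality of each candidate consensus partition on the input
  # dissimilarity, scored by mean silhouette with singleton clusters at 0
  mean_sil <- vapply(seq_along(K_range), function(ki) {
    cons <- consensus[[ki]]
    cons[is.na(cons)] <- 0
    lab <- stats::cutree(stats::hclust(stats::as.dist(1 - cons),
                                       method = "average"),
                         k = K_range[ki])
    s <- silhouette_widths(dissim, lab)
    s[lab %in% which(tabulate(lab) == 1L)] <- 0
    mean(s)
  }, 0)
  chosen <- K_range[which.max(mean_sil)]
  structure(list(consensus = consensus, areas = areas, delta_area = delta,
                 mean_silhouette = mean_sil, chosen_K = chosen,
                 K_range = K_range, cdf_grid = grid,
                 cdfs = cdfs, n_resamples = n_resamples,
                 subsample_frac = subsample_frac),
            class = "cpi_consensus")
}

#' @export
print.cpi_consensus <- function(x, ...) {
  cat("Consensus clustering over K = ",
      paste(range(x$K_range), collapse = ".."), " (",
      x$n_resamples, " resamples, frac ", x$subsample_frac, ")\n", sep = "")
  tab <- data.frame(K = x$K_range, area = round(x$areas, 3),
                    delta_area = round(x$delta_area, 3),
                    mean_silhouette = round(x$mean_silhouette, 3))
  print(tab, row.names = FALSE)
  cat("chosen K:", x$chosen_K, "\n")
  invisible(x)
}

#' Assign items to K clusters from a consensus matrix
#'
#' Average-linkage hierarchical clustering of `1 - consensus`, cut into `K`
#' groups. If no consensus result is supplied, one is computed for the single
#' candidate `K` from `dissim`.
#'
#' @param dissim symmetric dissimilarity matrix.
#' @param K number of clusters, `2 <= K < n`.
#' @param consensus optional `cpi_consensus` containing `K` among its
#'   candidates.
#' @param ... passed to [consensus_cluster] when `consensus` is NULL.
#' @return integer vector of cluster labels `1..K`, named by item.
#' @export
assign_clusters <- function(dissim, K, consensus = NULL, ...) {
  n <- nrow(dissim)
  K <- as.integer(K)
  if (K < 2L || K >= n) stop("K must satisfy 2 <= K < n")
  if (is.null(consensus))
    consensus <- consensus_cluster(dissim, K_range = K, ...)
  cons <- consensus$consensus[[as.character(K)]]
  if (is.null(cons)) stop("consensus result lacks K = ", K)
  cons[is.na(cons)] <- 0
  lab <- stats::cutree(stats::hclust(stats::as.dist(1 - cons),
                                     method = "average"), k = K)
  if (length(unique(lab)) < K) stop("empty cluster after cut at K = ", K)
  names(lab) <- rownames(dissim)
  lab
}

#' Silhouette widths on a dissimilarity matrix
#'
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with `a(i)` the mean
#' dissimilarity of item `i` to its own cluster (excluding itself; 0 for a
#' singleton cluster) and `b(i)` the minimum over other clusters of the mean
#' dissimilarity to that cluster.
#'
#' @param dissim symmetric dissimilarity matrix.
#' @param labels integer cluster labels (>= 2 distinct values).
#' @return numeric vector of silhouette widths, named like `labels`.
#' @export
silhouette_widths <- function(dissim, labels) {
  stopifnot(is.matrix(dissim), length(labels) == nrow(dissim))
  cl <- unique(labels)
  if (length(cl) < 2L) stop("silhouette needs at least 2 clusters")
  n <- nrow(dissim)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- if (sum(own) == 1L) 0 else mean(dissim[i, own & seq_len(n) != i])
    b <- min(vapply(cl[cl != labels[i]],
                    function(k) mean(dissim[i, labels == k]), 0))
    s[i] <- if (a == b) 0 else (b - a) / max(a, b)
  }
  names(s) <- rownames(dissim)
  s
}

#' Iterative silhouette-based cluster tightening
#'
#' Repeatedly computes silhouette widths on the retained items and moves
#' every item with `s(i) < cutoff` to the scattered set, until all retained
#' silhouettes reach the cutoff. Size-1 clusters are dissolved into the
#' scattered set whenever they arise (a lone pathway is a scattered
#' pathway, not a tight cluster; this also avoids the degenerate `a(i) = 0`
#' silhouette of singleton clusters). Scattered pathways are retained for
#' secondary inspection, never discarded. Terminates in at most `n`
#' iterations.
#'
#' @param dissim symmetric dissimilarity matrix over all selected items.
#' @param labels initial integer cluster labels (from [assign_clusters]).
#' @param cutoff silhouette cutoff in \[-1, 1) (default 0.1; -1 removes
#'   nothing by silhouette, though size-1 clusters still dissolve).
#' @return object of class `cpi_clusters`: list with `labels` (named integer
#'   vector over retained items), `scattered` (character vector of item ids),
#'   `silhouettes` (named, retained items, all >= cutoff), `cutoff`,
#'   `n_iter`.
#' @export
silhouette_tighten <- function(dissim, labels, cutoff = 0.1) {
  stopifnot(is.matrix(dissim), length(labels) == nrow(dissim),
            cutoff >= -1, cutoff < 1)
  ids <- rownames(dissim)
  if (is.null(ids)) ids <- as.character(seq_along(labels))
  names(labels) <- ids
  retained <- rep(TRUE, length(labels))
  names(retained) <- ids
  n_iter <- 0L
  sil <- NULL
  repeat {
    n_iter <- n_iter + 1L
    # dissolve size-1 clusters into the scattered set
    sizes <- table(labels[retained])
    lone <- names(sizes)[sizes == 1L]
    if (length(lone))
      retained[retained & as.character(labels) %in% lone] <- FALSE
    cur <- which(retained)
    if (length(cur) < 2L || length(unique(labels[cur])) < 2L) {
      # fewer than 2 clusters left: silhouettes undefined; dissolve the rest
      if (length(cur)) retained[cur] <- FALSE
      sil <- numeric(0)
      break
    }
    sil <- silhouette_widths(dissim[cur, cur, drop = FALSE], labels[cur])
    low <- sil < cutoff
    if (!any(low)) break
    retained[cur[low]] <- FALSE
    if (n_iter > length(labels)) break   # safety; cannot trigger in theory
  }
  if (!any(retained))
    warning("all items scattered; empty tight clustering returned")
  out_labels <- labels[retained]
  structure(list(labels = out_labels,
                 scattered = ids[!retained],
                 silhouettes = if (length(sil)) sil[names(out_labels)]
                               else numeric(0),
                 cutoff = cutoff, n_iter = n_iter),
            class = "cpi_clusters")
}

#' @export
print.cpi_clusters <- function(x, ...) {
  tab <- table(x$labels)
  cat("Tight clusters: ", length(tab), " (sizes ",
      paste(as.integer(tab), collapse = ", "), "); scattered: ",
      length(x$scattered), "\n", sep = "")
  if (length(x$silhouettes))
    cat("min retained silhouette: ", round(min(x$silhouettes), 3),
        " (cutoff ", x$cutoff, ")\n", sep = "")
  invisible(x)
}
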