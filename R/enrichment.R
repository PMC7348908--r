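#' Select the top differentially expressed genes of a study
#'
#' Returns the `n` genes with smallest p-values. Ties at the selection
#' boundary are broken by lexicographic gene id so the selection is
#' reproducible across platforms and orderings.
#'
#' @param study_pvals named numeric vector of gene-level p-values.
#' @param n number of genes to select (default 400).
#' @return character vector of `n` gene ids.
#' @export
select_top_de_genes <- function(study_pvals, n = 400L) {
  stopifnot(is.numeric(study_pvals), !is.null(names(study_pvals)))
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  if (n > length(study_pvals))
    stop("n (", n, ") exceeds the number of genes (", length(study_pvals), ")")
  ord <- order(study_pvals, names(study_pvals), method = "radix")
  names(study_pvals)[ord][seq_len(n)]
}

#' Over-representation p-value for one pathway (hypergeometric)
#'
#' One-sided tail probability `P(X >= k)` that a uniformly drawn gene list of
#' the same size overlaps the pathway at least as much as observed, with
#' `X ~ Hypergeometric(N = |universe|, K = |pathway ∩ universe|,
#' n = |de_genes|)` and `k = |de_genes ∩ pathway|`.
#'
#' @param de_genes character vector of selected genes (must lie in universe).
#' @param pathway_genes character vector, the pathway's gene set.
#' @param universe background gene universe.
#' @return p-value in (0, 1].
#' @export
fisher_enrichment <- function(de_genes, pathway_genes, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  de_genes <- unique(de_genes)
  if (!length(de_genes)) stop("empty DE gene list")
  if (!all(de_genes %in% universe))
    stop("DE genes outside the universe")
  path_in <- unique(pathway_genes[pathway_genes %in% universe])
  k <- sum(de_genes %in% path_in)
  # P(X >= k) = upper tail at k-1
  stats::phyper(k - 1L, length(path_in),
                length(universe) - length(path_in),
                length(de_genes), lower.tail = FALSE)
}

#' Kolmogorov-Smirnov enrichment p-value for one pathway
#'
#' Two-sample one-sided KS test that the gene-level p-values inside the
#' pathway are stochastically smaller than those outside it (enrichment makes
#' the in-pathway empirical CDF lie above the out-pathway CDF).
#'
#' @param study_pvals named numeric vector of gene-level p-values (the
#'   measured universe).
#' @param pathway_genes character vector, the pathway's gene set.
#' @return p-value in (0, 1].
#' @export
ks_enrichment <- function(study_pvals, pathway_genes) {
  stopifnot(is.numeric(study_pvals), !is.null(names(study_pvals)))
  inside <- names(study_pvals) %in% pathway_genes
  if (!any(inside) || all(inside))
    stop("degenerate split: need at least one gene inside and one outside ",
         "the pathway")
  suppressWarnings(
    stats::ks.test(study_pvals[inside], study_pvals[!inside],
                   alternative = "greater")$p.value
  )
}

#' Per-study pathway enrichment matrix
#'
#' Runs one enrichment test per (pathway, study) pair, producing the pathway
#' x study raw p-value matrix that feeds the meta-analysis. With
#' `method = "fisher"` the top `n_top` DE genes of each study are tested by
#' hypergeometric over-representation against a background of the study's
#' measured genes intersected with the collection universe (only testable
#' genes can form the background). With `method = "ks"` all gene-level
#' p-values are used directly.
#'
#' Exact zeros (possible only through underflow) are floored at `1e-300`
#' because the meta-analysis takes logarithms; any flooring is reported.
#'
#' @param gene_pvals numeric matrix genes x studies of DE p-values in (0, 1].
#' @param coll a [gene_set_collection] (size-filter it first).
#' @param method `"fisher"` (over-representation) or `"ks"`.
#' @param n_top number of top DE genes for the Fisher branch (default 400).
#' @return numeric matrix pathways x studies of raw enrichment p-values.
#' @export
enrich_all <- function(gene_pvals, coll, method = c("fisher", "ks"),
                       n_top = 400L) {
  method <- match.arg(method)
  validate_pvalue_matrix(gene_pvals, "gene p-value")
  stopifnot(inherits(coll, "gene_set_collection"))
  measured <- rownames(gene_pvals)
  background <- intersect(measured, coll$universe)
  if (length(background) < 2L)
    stop("fewer than 2 measured genes overlap the collection universe")
  out <- matrix(NA_real_, nrow = length(coll$ids), ncol = ncol(gene_pvals),
                dimnames = list(coll$ids, colnames(gene_pvals)))
  for (s in seq_len(ncol(gene_pvals))) {
    pv <- gene_pvals[, s]
    names(pv) <- measured
    pv_bg <- pv[background]
    if (method == "fisher") {
      de <- select_top_de_genes(pv_bg, n = min(n_top, length(pv_bg)))
      for (i in seq_along(coll$ids))
        out[i, s] <- fisher_enrichment(de, coll$genes[[i]], background)
    } else {
      for (i in seq_along(coll$ids))
        out[i, s] <- ks_enrichment(pv_bg, coll$genes[[i]])
    }
  }
  n_floor <- sum(out < 1e-300)
  if (n_floor > 0L) {
    message(n_floor, " enrichment p-value(s) floored at 1e-300")
    out[out < 1e-300] <- 1e-300
  }
  validate_pvalue_matrix(out, "enrichment p-value")
}
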