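#' Comparative pathway integration across studies
#'
#' Runs the three-step pipeline on a gene-set collection and per-study
#' p-values: (1) per-study pathway enrichment (skipped when pathway-level
#' p-values are supplied directly) followed by adaptively weighted Fisher
#' meta-analysis and q-value selection; (2) kappa-based consensus clustering
#' of the significant pathways with iterative silhouette tightening into
#' tight clusters plus a scattered set; (3) length-penalized permutation
#' text mining annotating each cluster with keywords.
#'
#' @param collection a [gene_set_collection] with descriptions attached.
#' @param gene_pvalues numeric matrix genes x studies of DE p-values
#'   (input mode 1), or NULL.
#' @param pathway_pvalues numeric matrix pathways x studies of enrichment
#'   p-values (input mode 2, bypasses the enrichment stage), or NULL.
#'   Exactly one of the two inputs must be given; pathway ids must exist in
#'   the collection.
#' @param method per-study enrichment test, `"fisher"` (hypergeometric
#'   over-representation of the top `top_n` DE genes) or `"ks"`.
#' @param top_n DE genes per study for the Fisher branch (default 400).
#' @param min_size,max_size inclusive pathway size bounds (defaults 15, 500).
#' @param q_cutoff meta-analysis q-value cutoff selecting significant
#'   pathways (default 0.0005).
#' @param k number of pathway clusters: `"auto"` (consensus delta-area
#'   elbow) or an integer.
#' @param k_range candidate cluster numbers for the automatic choice
#'   (default 2:10).
#' @param n_resamples,subsample_frac consensus-clustering resampling
#'   settings (defaults 500 and 0.8).
#' @param silhouette_cutoff silhouette width below which pathways are moved
#'   to the scattered set (default 0.1).
#' @param silhouette_on dissimilarity used for silhouettes: `"kappa"`
#'   (1 - kappa, default) or `"consensus"` (1 - consensus).
#' @param alpha description-length penalty of the text-mining score
#'   (default 0.05).
#' @param B_meta Monte-Carlo draws for the combined p-value null
#'   (default 1e4).
#' @param B_text permutations per cluster in the keyword test
#'   (default 1e4).
#' @param q_keywords keyword q-value threshold (default 0.05).
#' @param text_background pathways the keyword permutations sample from:
#'   `"collection"` (all size-filtered pathways, default) or
#'   `"significant"`.
#' @param resources a [cpi_text_resources] object.
#' @param seed integer master seed; stage seeds are derived from it so each
#'   stage is individually reproducible.
#' @param verbose print one structured log line per stage.
#' @return An object of class `cpi`: list with elements `collection`
#'   (size-filtered), `pmatrix`, `meta`, `significant`, `kappa`,
#'   `consensus`, `assignment`, `annotation`, `keyword_summary`,
#'   `manifest`, `call`.
#' @seealso [write_cpi], [plot.cpi], [study_dendrograms], [cpi_demo]
#' @export
cpi <- function(collection, gene_pvalues = NULL, pathway_pvalues = NULL,
                method = c("fisher", "ks"), top_n = 400L,
                min_size = 15L, max_size = 500L, q_cutoff = 5e-4,
                k = "auto", k_range = 2:10, n_resamples = 500L,
                subsample_frac = 0.8, silhouette_cutoff = 0.1,
                silhouette_on = c("kappa", "consensus"),
                alpha = 0.05, B_meta = 1e4, B_text = 1e4,
                q_keywords = 0.05,
                text_background = c("collection", "significant"),
                resources = cpi_text_resources(), seed = 1L,
                verbose = TRUE) {
  t_start <- Sys.time()
  method <- match.arg(method)
  silhouette_on <- match.arg(silhouette_on)
  text_background <- match.arg(text_background)
  # validate the full configuration before any computation
  stopifnot(inherits(collection, "gene_set_collection"))
  if (is.null(gene_pvalues) == is.null(pathway_pvalues))
    stop("supply exactly one of gene_pvalues or pathway_pvalues")
  if (alpha < 0) stop("alpha must be >= 0")
  if (q_cutoff <= 0 || q_cutoff >= 1) stop("q_cutoff must be in (0, 1)")
  if (silhouette_cutoff <= -1 || silhouette_cutoff >= 1)
    stop("silhouette_cutoff must be in (-1, 1)")
  if (!identical(k, "auto")) {
    k <- as.integer(k)
    if (is.na(k) || k < 2L) stop("k must be \"auto\" or an integer >= 2")
  }
  seed <- as.integer(seed)
  log_stage <- function(...) if (verbose) message("[cpi] ", ...)

  # stage 1a: size filter + enrichment
  gene_mode <- !is.null(gene_pvalues)
  if (gene_mode) {
    validate_pvalue_matrix(gene_pvalues, "gene p-value")
    coll <- filter_by_size(collection, min_size, max_size)
    log_stage("filter: ", length(coll), "/", length(collection),
              " pathways within [", min_size, ", ", max_size, "] genes")
    pmat <- enrich_all(gene_pvalues, coll, method = method, n_top = top_n)
    log_stage("enrich: method=", method, " top_n=", top_n, " -> ",
              nrow(pmat), " pathways x ", ncol(pmat), " studies")
  } else {
    validate_pvalue_matrix(pathway_pvalues, "pathway p-value")
    missing <- setdiff(rownames(pathway_pvalues), collection$ids)
    if (length(missing))
      stop("pathway p-value ids absent from the collection: ",
           paste(utils::head(missing, 5L), collapse = ", "))
    coll <- subset_collection(collection, rownames(pathway_pvalues))
    coll <- filter_by_size(coll, min_size, max_size)
    pmat <- pathway_pvalues[coll$ids, , drop = FALSE]
    log_stage("enrich: skipped (pathway p-values supplied); ",
              nrow(pmat), " pathways x ", ncol(pmat), " studies")
  }

  # stage 1b: AW-Fisher meta-analysis and selection
  meta <- aw_meta(pmat, B = B_meta, seed = seed + 1L)
  sig <- select_significant(meta, q_cutoff = q_cutoff)
  log_stage("meta: B=", format(B_meta), " -> ", nrow(sig),
            " pathways with q < ", q_cutoff, " (",
            sum(sig$pattern == "consensual"), " consensual, ",
            sum(sig$pattern == "differential"), " differential)")

  # stage 2: kappa clustering + tightening
  sig_coll <- subset_collection(coll, sig$pathway)
  if (length(sig_coll) < 4L)
    stop("clustering needs at least 4 significant pathways; got ",
         length(sig_coll))
  kap <- kappa_matrix(sig_coll)
  dis <- kappa_dissimilarity(kap)
  K_cand <- if (identical(k, "auto")) k_range else k
  cons <- consensus_cluster(dis, K_range = K_cand,
                            n_resamples = n_resamples,
                            subsample_frac = subsample_frac,
                            seed = seed + 2L)
  K <- if (identical(k, "auto")) cons$chosen_K else k
  labels <- assign_clusters(dis, K, consensus = cons)
  sil_dis <- if (silhouette_on == "kappa") dis else {
    cm <- cons$consensus[[as.character(K)]]
    cm[is.na(cm)] <- 0
    1 - cm
  }
  assignment <- silhouette_tighten(sil_dis, labels,
                                   cutoff = silhouette_cutoff)
  log_stage("cluster: K=", K, if (identical(k, "auto")) " (auto)" else "",
            ", ", length(unique(assignment$labels)), " tight clusters, ",
            length(assignment$scattered), " scattered, ",
            assignment$n_iter, " tightening iteration(s)")

  # stage 3: text mining
  mats <- build_phrase_matrices(coll, resources)
  mats <- merge_synonyms(mats, resources$synonyms)
  mats <- prune_rare_phrases(mats)
  scores <- penalized_scores(mats, alpha = alpha)
  background <- if (text_background == "collection") coll$ids
                else sig$pathway
  annotation <- annotate_clusters(scores, assignment, B = B_text,
                                  q_cutoff = q_keywords, seed = seed + 3L,
                                  background = background)
  log_stage("annotate: ", length(mats$phrases), " phrases, B=",
            format(B_text), ", ", sum(annotation$significant),
            " keyword hits at q < ", q_keywords)

  manifest <- list(
    package = "cpi", version = as.character(utils::packageVersion("cpi")),
    input_mode = if (gene_mode) "gene_pvalues" else "pathway_pvalues",
    method = method, top_n = top_n, min_size = min_size,
    max_size = max_size, q_cutoff = q_cutoff,
    k = if (identical(k, "auto")) "auto" else k, k_chosen = K,
    k_range = k_range, n_resamples = n_resamples,
    subsample_frac = subsample_frac,
    silhouette_cutoff = silhouette_cutoff, silhouette_on = silhouette_on,
    alpha = alpha, B_meta = B_meta, B_text = B_text,
    q_keywords = q_keywords, text_background = text_background,
    seed = seed,
    elapsed_sec = round(as.numeric(Sys.time() - t_start, units = "secs"), 2))
  log_stage("done in ", manifest$elapsed_sec, " s")
  structure(list(collection = coll, pmatrix = pmat, meta = meta,
                 significant = sig, kappa = kap, consensus = cons,
                 assignment = assignment, annotation = annotation,
                 keyword_summary = keyword_table(annotation),
                 manifest = manifest, call = match.call()),
            class = "cpi")
}

#' @export
print.cpi <- function(x, ...) {
  m <- x$manifest
  cat("Comparative pathway integration\n")
  cat("  input: ", m$input_mode, ", ", nrow(x$pmatrix), " pathways x ",
      ncol(x$pmatrix), " studies\n", sep = "")
  cat("  significant (q < ", m$q_cutoff, "): ", nrow(x$significant),
      " (", sum(x$significant$pattern == "consensual"), " consensual, ",
      sum(x$significant$pattern == "differential"), " differential)\n",
      sep = "")
  tab <- table(x$assignment$labels)
  cat("  clusters: K = ", m$k_chosen, " -> ", length(tab),
      " tight (sizes ", paste(as.integer(tab), collapse = ", "),
      "), ", length(x$assignment$scattered), " scattered\n", sep = "")
  cat("  keywords at q < ", m$q_keywords, ": ",
      sum(x$annotation$significant), "\n", sep = "")
  invisible(x)
}

#' @export
summary.cpi <- function(object, n_keywords = 10L, ...) {
  structure(list(manifest = object$manifest,
                 significant = object$significant,
                 cluster_sizes = table(object$assignment$labels),
                 scattered = object$assignment$scattered,
                 keywords = keyword_table(object$annotation, n_keywords)),
            class = "summary.cpi")
}

#' @export
print.summary.cpi <- function(x, ...) {
  cat("Significant pathways:", nrow(x$significant), "\n")
  pat <- table(x$significant$pattern)
  for (p in names(pat)) cat("  ", p, ": ", pat[[p]], "\n", sep = "")
  cat("Cluster sizes:\n")
  print(x$cluster_sizes)
  cat("Scattered:", length(x$scattered), "\n\nKeywords per cluster:\n")
  print(x$keywords, row.names = FALSE)
  invisible(x)
}

#' Per-cluster study dendrograms
#'
#' For each tight cluster with at least 2 pathways, hierarchically clusters
#' the *studies* (average linkage) using Euclidean distance between their
#' log10 enrichment p-value vectors restricted to the cluster's pathways.
#' Clusters with a single pathway are skipped with a notice.
#'
#' @param pmatrix pathways x studies enrichment p-value matrix.
#' @param assignment a `cpi_clusters` object or named label vector.
#' @return named list of `phylo` trees (one per eligible cluster); use
#'   [ape::write.tree] to serialize as newick.
#' @export
study_dendrograms <- function(pmatrix, assignment) {
  labels <- if (inherits(assignment, "cpi_clusters")) assignment$labels
            else assignment
  out <- list()
  for (g in sort(unique(labels))) {
    members <- names(labels)[labels == g]
    if (length(members) < 2L) {
      message("cluster ", g, " has a single pathway; dendrogram skipped")
      next
    }
    lp <- log10(pmatrix[members, , drop = FALSE])
    hc <- stats::hclust(stats::dist(t(lp)), method = "average")
    out[[as.character(g)]] <- ape::as.phylo(hc)
  }
  out
}

#' Run the pipeline end to end on a synthetic demo
#'
#' Generates the synthetic six-study fixture (planted consensual and
#' differential pathway families with injected name keywords) and runs
#' [cpi] on it with the default parameters.
#'
#' @param seed integer seed for both the generator and the pipeline.
#' @param spec a [cpi_fixture_spec].
#' @param ... passed on to [cpi].
#' @return a `cpi` object; the generating collection carries the planted
#'   truth in its attributes.
#' @export
cpi_demo <- function(seed = 1L, spec = cpi_fixture_spec(), ...) {
  coll <- sim_collection(spec, seed = seed)
  gp <- sim_gene_pvalues(coll, seed = seed + 1L)
  args <- list(collection = coll, gene_pvalues = gp, seed = seed, ...)
  if (is.null(args$k_range)) args$k_range <- 2:6
  fit <- do.call(cpi, args)
  fit$truth <- list(family = attr(coll, "family"),
                    role = attr(coll, "role"),
                    spec = spec)
  fit
}
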