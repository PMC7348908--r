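#' Write all pipeline outputs to a directory
#'
#' Emits the spreadsheet outputs (TSV), per-cluster study dendrograms
#' (newick), the diagnostic and result plots (PDF) and a JSON run manifest.
#' Tables are always written; a plotting failure is logged and skipped.
#'
#' @param x a `cpi` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written file paths.
#' @export
write_cpi <- function(x, dir) {
  stopifnot(inherits(x, "cpi"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(obj, name, ...) {
    path <- file.path(dir, name)
    write_tsv_matrix(obj, path, ...)
    written <<- c(written, path)
  }
  emit(x$meta, "meta_analysis.tsv")
  emit(x$significant, "significant_pathways.tsv")
  ord <- order(x$assignment$labels)
  clusters_df <- data.frame(
    pathway = c(names(x$assignment$labels)[ord], x$assignment$scattered),
    cluster = c(as.character(x$assignment$labels)[ord],
                rep("scattered", length(x$assignment$scattered))),
    silhouette = c(unname(x$assignment$silhouettes)[ord],
                   rep(NA_real_, length(x$assignment$scattered))),
    stringsAsFactors = FALSE)
  emit(clusters_df, "cluster_assignment.tsv")
  emit(as.data.frame(x$annotation), "keyword_tests.tsv")
  emit(x$keyword_summary, "keywords_per_cluster.tsv")
  emit(x$kappa, "kappa_matrix.tsv", id_col = "pathway")
  emit(x$pmatrix, "enrichment_pvalues.tsv", id_col = "pathway")
  trees <- study_dendrograms(x$pmatrix, x$assignment)
  for (g in names(trees)) {
    path <- file.path(dir, paste0("study_dendrogram_cluster", g, ".nwk"))
    ape::write.tree(trees[[g]], file = path)
    written <- c(written, path)
  }
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(x$manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  written <- c(written, manifest_path)
  for (type in c("kappa", "pvalue", "mds", "consensus")) {
    path <- file.path(dir, paste0("plot_", type, ".pdf"))
    ok <- tryCatch({
      grDevices::pdf(path, width = 7, height = 7)
      on.exit(grDevices::dev.off(), add = TRUE, after = FALSE)
      plot(x, type = type)
      TRUE
    }, error = function(e) {
      message("plot '", type, "' failed: ", conditionMessage(e))
      FALSE
    })
    if (ok) written <- c(written, path)
  }
  invisible(written)
}

cluster_order <- function(assignment) {
  c(names(assignment$labels)[order(assignment$labels)],
    assignment$scattered)
}

#' Plot pipeline results
#'
#' Four plot families: `"kappa"` — heatmap of the pairwise kappa matrix
#' with pathways ordered by cluster and the scattered set last; `"pvalue"`
#' — heatmap of -log10 enrichment p-values (capped at 10 for readability),
#' pathways sorted by cluster, studies on the columns; `"mds"` — classical
#' (metric) multidimensional scaling of the kappa dissimilarity, colored by
#' cluster; `"consensus"` — consensus CDF curves and the delta-area elbow
#' diagnostic.
#'
#' @param x a `cpi` object.
#' @param type one of `"kappa"`, `"pvalue"`, `"mds"`, `"consensus"`.
#' @param cap cap for -log10 p in the p-value heatmap (default 10).
#' @param ... ignored.
#' @return invisibly, `x`.
#' @export
plot.cpi <- function(x, type = c("kappa", "pvalue", "mds", "consensus"),
                     cap = 10, ...) {
  type <- match.arg(type)
  ord <- cluster_order(x$assignment)
  lab_all <- c(x$assignment$labels,
               stats::setNames(rep(NA_integer_,
                                   length(x$assignment$scattered)),
                               x$assignment$scattered))[ord]
  if (type == "kappa") {
    m <- x$kappa[ord, rev(ord)]
    pal <- grDevices::hcl.colors(64, "Blue-Red 2")
    graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), m,
                    zlim = c(-1, 1), col = pal, axes = FALSE,
                    xlab = "pathways (by cluster; scattered last)",
                    ylab = "", main = "Pairwise kappa")
    boundaries <- cumsum(table(x$assignment$labels))
    graphics::abline(v = boundaries + 0.5,
                     h = length(ord) - boundaries + 0.5, col = "black")
    graphics::box()
  } else if (type == "pvalue") {
    m <- -log10(x$pmatrix[ord, , drop = FALSE])
    m[m > cap] <- cap
    pal <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
    graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m[rev(seq_len(nrow(m))), ]),
                    zlim = c(0, cap), col = pal, axes = FALSE,
                    xlab = "study", ylab = "pathways (by cluster)",
                    main = "-log10 enrichment p (capped)")
    graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m),
                   las = 2, cex.axis = 0.7)
    graphics::box()
  } else if (type == "mds") {
    d <- kappa_dissimilarity(x$kappa)
    xy <- stats::cmdscale(stats::as.dist(d), k = 2)
    col <- ifelse(is.na(lab_all[rownames(xy)]), "grey40",
                  lab_all[rownames(xy)] + 1L)
    pch <- ifelse(is.na(lab_all[rownames(xy)]), 4L, 19L)
    graphics::plot(xy, col = col, pch = pch, xlab = "MDS 1", ylab = "MDS 2",
                   main = "MDS of kappa dissimilarity")
    graphics::legend("topright", bty = "n", pch = c(19, 4),
                     col = c("black", "grey40"),
                     legend = c("clustered", "scattered"), cex = 0.8)
  } else {
    cons <- x$consensus
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op), add = TRUE)
    graphics::matplot(cons$cdf_grid, t(cons$cdfs), type = "l", lty = 1,
                      col = seq_along(cons$K_range) + 1L,
                      xlab = "consensus index", ylab = "CDF",
                      main = "Consensus CDF")
    graphics::legend("bottomright", bty = "n", lty = 1, cex = 0.8,
                     col = seq_along(cons$K_range) + 1L,
                     legend = paste0("K=", cons$K_range))
    graphics::plot(cons$K_range, cons$delta_area, type = "b", pch = 19,
                   xlab = "K", ylab = "relative delta area",
                   main = "Delta-area elbow")
    graphics::abline(v = cons$chosen_K, lty = 2)
  }
  invisible(x)
}

#' Read a pipeline run configuration
#'
#' Structured text configuration (YAML) for the command-line interface:
#' keys mirror the arguments of [cpi] plus `gmt`, `descriptions`,
#' `gene_pvalues` / `pathway_pvalues` input paths and `output_dir`.
#'
#' @param path YAML file path.
#' @return named list of class `cpi_config`.
#' @export
read_cpi_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read configurations")
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "cpi_config")
}

#' Run the full pipeline from a configuration
#'
#' Loads the inputs named in the configuration, executes [cpi], and writes
#' the results bundle to `output_dir`. Re-running with the written
#' `manifest.json` settings and the same inputs reproduces every table.
#'
#' @param config a `cpi_config` list (see [read_cpi_config]) or a path to a
#'   YAML configuration.
#' @return the fitted `cpi` object, invisibly.
#' @export
run_cpi <- function(config) {
  if (is.character(config)) config <- read_cpi_config(config)
  if (is.null(config$gmt)) stop("config needs a 'gmt' input path")
  if (is.null(config$output_dir)) stop("config needs 'output_dir'")
  coll <- read_gmt(config$gmt)
  if (!is.null(config$descriptions))
    coll <- attach_descriptions(coll, read_descriptions(config$descriptions))
  args <- list(collection = coll)
  if (!is.null(config$gene_pvalues))
    args$gene_pvalues <- read_pvalue_matrix(config$gene_pvalues)
  if (!is.null(config$pathway_pvalues))
    args$pathway_pvalues <- read_pvalue_matrix(config$pathway_pvalues,
                                               uppercase_ids = FALSE)
  for (key in c("method", "top_n", "min_size", "max_size", "q_cutoff", "k",
                "k_range", "n_resamples", "subsample_frac",
                "silhouette_cutoff", "silhouette_on", "alpha", "B_meta",
                "B_text", "q_keywords", "text_background", "seed",
                "verbose"))
    if (!is.null(config[[key]])) args[[key]] <- config[[key]]
  fit <- do.call(cpi, args)
  write_cpi(fit, config$output_dir)
  invisible(fit)
}
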