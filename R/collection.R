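#' Gene-set collections
#'
#' A `gene_set_collection` holds an ordered list of gene sets (pathways) with
#' identifiers, short names, free-text descriptions and gene memberships,
#' together with a background gene universe. Gene symbols are normalized to
#' upper case on construction so that sets drawn from different databases can
#' be joined; collisions introduced by case-folding are counted and reported.
#'
#' @param ids character vector of unique pathway identifiers.
#' @param genes list of character vectors, one per pathway; each vector is the
#'   gene membership of the set (deduplicated, upper-cased).
#' @param names character vector of short pathway names (defaults to `ids`).
#' @param descriptions character vector of free-text descriptions (may be
#'   empty strings).
#' @param universe background gene universe; defaults to the union of all set
#'   members. Every gene of every set must belong to it.
#'
#' @return An object of class `gene_set_collection`: a list with elements
#'   `ids`, `names`, `descriptions`, `genes` (named list) and `universe`.
#' @export
gene_set_collection <- function(ids, genes, names = ids,
                                descriptions = rep("", length(ids)),
                                universe = NULL) {
  stopifnot(is.character(ids), is.list(genes),
            length(ids) == length(genes),
            length(names) == length(ids),
            length(descriptions) == length(ids))
  if (anyDuplicated(ids))
    stop("duplicate pathway ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  genes <- lapply(genes, function(g) {
    g <- unique(toupper(as.character(g)))
    if (!length(g)) stop("gene sets must be non-empty")
    g
  })
  names(genes) <- ids
  if (is.null(universe)) {
    universe <- sort(unique(unlist(genes, use.names = FALSE)))
  } else {
    universe <- unique(toupper(as.character(universe)))
    missing <- setdiff(unlist(genes, use.names = FALSE), universe)
    if (length(missing))
      stop("genes outside the universe: ",
           paste(utils::head(missing, 5L), collapse = ", "))
  }
  structure(list(ids = ids, names = as.character(names),
                 descriptions = as.character(descriptions),
                 genes = genes, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- lengths(x$genes)
  cat("Gene-set collection: ", length(x$ids), " sets, ",
      length(x$universe), " genes in universe\n", sep = "")
  cat("  set sizes: ", min(sizes), "-", max(sizes),
      " (median ", stats::median(sizes), ")\n", sep = "")
  n_desc <- sum(nzchar(x$descriptions))
  cat("  descriptions attached: ", n_desc, "/", length(x$ids), "\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$ids)

#' Read a gene-set collection from a GMT file
#'
#' GMT is the de-facto tab-separated gene-set format: one set per line, first
#' field the identifier, second a description or URL, remaining fields the
#' member genes. Duplicate genes within a line are removed with a warning;
#' duplicate identifiers across lines are an error. The initial background
#' universe is the union of all member genes.
#'
#' @param path path to a GMT file.
#' @return A [gene_set_collection].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("malformed GMT line ", bad[1L], ": fewer than 3 tab-separated fields")
  ids <- vapply(fields, `[[`, "", 1L)
  descs <- vapply(fields, `[[`, "", 2L)
  genes <- lapply(fields, function(f) f[-(1:2)])
  n_dup <- sum(vapply(genes, function(g) length(g) - length(unique(toupper(g))),
                      0L))
  if (n_dup > 0L)
    warning(n_dup, " duplicate gene entr",
            if (n_dup == 1L) "y" else "ies",
            " removed within GMT lines (including case-fold collisions)")
  gene_set_collection(ids = ids, genes = genes, descriptions = descs)
}

#' Write a gene-set collection to a GMT file
#'
#' The second GMT field is the stored description (empty descriptions are
#' written as `"NA"` placeholders are avoided; an empty string is kept).
#'
#' @param coll a [gene_set_collection].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(coll, path) {
  stopifnot(inherits(coll, "gene_set_collection"))
  lines <- vapply(seq_along(coll$ids), function(i) {
    paste(c(coll$ids[i], coll$descriptions[i], coll$genes[[i]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Attach names and descriptions to a collection
#'
#' @param coll a [gene_set_collection].
#' @param table data frame with columns `id`, `name`, `description`. Every id
#'   must exist in the collection; collection sets absent from the table keep
#'   an empty description (reported, since keyword annotation works poorly on
#'   description-less databases).
#' @return The collection with `names`/`descriptions` populated.
#' @export
attach_descriptions <- function(coll, table) {
  stopifnot(inherits(coll, "gene_set_collection"), is.data.frame(table))
  if (!all(c("id", "name", "description") %in% names(table)))
    stop("description table needs columns id, name, description")
  unknown <- setdiff(table$id, coll$ids)
  if (length(unknown))
    stop("description table ids not in the collection: ",
         paste(unknown, collapse = ", "))
  idx <- match(coll$ids, table$id)
  hit <- !is.na(idx)
  coll$names[hit] <- as.character(table$name[idx[hit]])
  coll$descriptions[hit] <- as.character(table$description[idx[hit]])
  n_missing <- sum(!hit)
  if (n_missing && nrow(table))
    message(n_missing, " pathway(s) without a description entry; ",
            "their descriptions stay empty")
  coll
}

#' Read a pathway description table (TSV: id, name, description)
#'
#' @param path tab-separated file with a header row `id name description`.
#' @return data frame with character columns.
#' @export
read_descriptions <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character", check.names = FALSE)
  if (!all(c("id", "name", "description") %in% names(tab)))
    stop("description TSV needs columns id, name, description")
  tab
}

#' Filter gene sets by size
#'
#' Keeps sets whose gene count lies in `[min_genes, max_genes]` (inclusive
#' bounds: sets with fewer than `min_genes` or more than `max_genes` genes are
#' excluded). When `restrict_to` is given, sizes are counted after
#' intersecting each set with it, e.g. to count only genes actually measured
#' in the studies.
#'
#' @param coll a [gene_set_collection].
#' @param min_genes,max_genes inclusive size bounds (defaults 15 and 500).
#' @param restrict_to optional character vector of genes; sizes are counted
#'   within this set.
#' @return The filtered collection (order preserved).
#' @export
filter_by_size <- function(coll, min_genes = 15L, max_genes = 500L,
                           restrict_to = NULL) {
  stopifnot(inherits(coll, "gene_set_collection"),
            min_genes >= 1L, min_genes <= max_genes)
  sizes <- if (is.null(restrict_to)) {
    lengths(coll$genes)
  } else {
    restrict_to <- unique(toupper(restrict_to))
    vapply(coll$genes, function(g) sum(g %in% restrict_to), 0L)
  }
  keep <- sizes >= min_genes & sizes <= max_genes
  if (!any(keep))
    stop("no gene set within size bounds [", min_genes, ", ", max_genes,
         "]; loosen the bounds")
  subset_collection(coll, which(keep))
}

#' Restrict a collection to a subset of pathways
#'
#' @param coll a [gene_set_collection].
#' @param idx integer positions or character ids to keep.
#' @param universe optional replacement universe for the subset; by default
#'   the original universe is retained.
#' @return A [gene_set_collection].
#' @export
subset_collection <- function(coll, idx, universe = NULL) {
  if (is.character(idx)) {
    pos <- match(idx, coll$ids)
    if (anyNA(pos)) stop("unknown pathway ids: ",
                         paste(idx[is.na(pos)], collapse = ", "))
    idx <- pos
  }
  gene_set_collection(ids = coll$ids[idx], genes = coll$genes[idx],
                      names = coll$names[idx],
                      descriptions = coll$descriptions[idx],
                      universe = if (is.null(universe)) coll$universe
                                 else universe)
}

# --- p-value matrix I/O ------------------------------------------------------

validate_pvalue_matrix <- function(m, what = "p-value") {
  if (!is.matrix(m) || !is.numeric(m)) stop(what, " matrix must be numeric")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop(what, " matrix needs row and column names")
  if (anyDuplicated(rownames(m))) stop("duplicate row ids in ", what, " matrix")
  if (anyNA(m)) stop("missing values in ", what, " matrix")
  if (any(m <= 0 | m > 1)) stop(what, " values must lie in (0, 1]")
  m
}

#' Read a p-value matrix from TSV
#'
#' Expected layout: header row of study labels, first column of gene (or
#' pathway) identifiers, remaining columns numeric p-values in (0, 1]. Gene
#' identifiers are upper-cased to match collection handling.
#'
#' @param path TSV file path.
#' @param uppercase_ids upper-case the row identifiers (default TRUE; set to
#'   FALSE for pathway-level matrices whose ids are case-sensitive).
#' @return numeric matrix, rows = genes/pathways, columns = studies.
#' @export
read_pvalue_matrix <- function(path, uppercase_ids = TRUE) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE)
  ids <- as.character(tab[[1L]])
  if (uppercase_ids) ids <- toupper(ids)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  validate_pvalue_matrix(m)
}

#' Write a matrix (or data frame) as TSV with an id column
#'
#' @param m matrix with row names, or a data frame.
#' @param path output path.
#' @param id_col name of the identifier column written first.
#' @return `path`, invisibly.
#' @export
write_tsv_matrix <- function(m, path, id_col = "id") {
  if (is.matrix(m)) {
    df <- data.frame(rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df)[1L] <- id_col
  } else df <- m
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
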