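#' Text-mining resources
#'
#' Bundled plain-text word lists and an optional synonym table used by the
#' phrase pipeline: an English stop-word list (chunk boundaries, removed from
#' phrases) and a curated common-English-word list (length-one phrases found
#' in it are dropped). A synonym source may be supplied as a two-column data
#' frame of unordered phrase pairs.
#'
#' @param stopwords optional character vector replacing the bundled list.
#' @param common_words optional character vector replacing the bundled list.
#' @param synonyms optional data frame with two character columns of synonym
#'   phrase pairs (already normalized).
#' @return object of class `cpi_resources`.
#' @export
cpi_text_resources <- function(stopwords = NULL, common_words = NULL,
                               synonyms = NULL) {
  read_list <- function(file) {
    x <- readLines(system.file("extdata", file, package = "cpi",
                               mustWork = TRUE), warn = FALSE)
    x <- trimws(x[!startsWith(x, "#")])
    unique(tolower(x[nzchar(x)]))
  }
  if (is.null(stopwords)) stopwords <- read_list("stopwords_en.txt")
  if (is.null(common_words)) common_words <- read_list("common_words_en.txt")
  if (!is.null(synonyms)) {
    stopifnot(is.data.frame(synonyms), ncol(synonyms) >= 2L)
    synonyms <- data.frame(a = tolower(as.character(synonyms[[1L]])),
                           b = tolower(as.character(synonyms[[2L]])),
                           stringsAsFactors = FALSE)
  }
  structure(list(stopwords = tolower(stopwords),
                 common_words = tolower(common_words),
                 synonyms = synonyms),
            class = "cpi_resources")
}

tokenize_text <- function(text) {
  # words may contain internal hyphens, slashes and apostrophes (APC/C, 26s)
  tok <- unlist(strsplit(text, "[^[:alnum:]'/-]+"), use.names = FALSE)
  tok[nzchar(tok)]
}

# split text into punctuation-delimited segments; chunking never crosses them
segment_text <- function(text) {
  seg <- unlist(strsplit(text, "[][(){};:!?,.\"]+"), use.names = FALSE)
  seg[nzchar(trimws(seg))]
}

#' Extract candidate noun phrases from text
#'
#' Deterministic rule-based chunker: the text is tokenized, and maximal runs
#' of content tokens between boundaries are taken as candidate phrases.
#' Boundary tokens are stop words, punctuation and pure numbers. Word order
#' within a phrase is preserved; phrases are deduplicated per text. A
#' different extractor (e.g. an industrial NLP chunker) can be plugged in as
#' a function `text -> character vector`; its output feeds the same
#' normalization.
#'
#' @param text a single character string.
#' @param resources a [cpi_text_resources] object.
#' @param extractor optional replacement function `text -> phrases`.
#' @return character vector of unique raw phrases (possibly empty).
#' @export
extract_noun_phrases <- function(text, resources = cpi_text_resources(),
                                 extractor = NULL) {
  stopifnot(length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(character(0))
  if (!is.null(extractor)) return(unique(extractor(text)))
  phrases <- unlist(lapply(segment_text(text), function(seg) {
    tok <- tokenize_text(seg)
    if (!length(tok)) return(character(0))
    boundary <- tolower(tok) %in% resources$stopwords |
      grepl("^[0-9]+$", tok)
    runs <- split(tok[!boundary], cumsum(boundary)[!boundary])
    vapply(runs, paste, "", collapse = " ")
  }), use.names = FALSE)
  unique(phrases)
}

# plural -> singular for the final (head) token of a phrase;
# exception table first, then ordered suffix rules
lemma_exceptions <- c(
  analyses = "analysis", bases = "basis", hypotheses = "hypothesis",
  syntheses = "synthesis", diagnoses = "diagnosis", prognoses = "prognosis",
  metastases = "metastasis", apoptoses = "apoptosis",
  mitochondria = "mitochondrion", bacteria = "bacterium",
  nuclei = "nucleus", stimuli = "stimulus", loci = "locus", fungi = "fungus",
  genera = "genus", corpora = "corpus", mice = "mouse", children = "child",
  people = "person", feet = "foot", teeth = "tooth", viruses = "virus",
  matrices = "matrix", indices = "index", vertices = "vertex",
  axes = "axis", criteria = "criterion", phenomena = "phenomenon",
  media = "medium", data = "datum", genes = "gene", species = "species")

#' Singularize an English word
#'
#' Rule-based plural-to-singular conversion with an exception table, applied
#' to the head (final) token of normalized phrases.
#'
#' @param word a single lowercase word.
#' @return the singular form.
#' @export
singularize <- function(word) {
  if (word %in% names(lemma_exceptions))
    return(unname(lemma_exceptions[word]))
  n <- nchar(word)
  if (n > 4L && endsWith(word, "ies"))
    return(paste0(substr(word, 1L, n - 3L), "y"))
  if (n > 4L && grepl("(xes|zes|ches|shes|sses)$", word))
    return(substr(word, 1L, n - 2L))
  if (n > 3L && endsWith(word, "s") &&
      !grepl("(ss|us|is)$", word))
    return(substr(word, 1L, n - 1L))
  word
}

#' Normalize a raw phrase
#'
#' Lowercases, removes stop-word tokens, singularizes the last remaining
#' token, and drops (returns `NA`) phrases that are empty after stop-word
#' removal or that consist of a single common English word.
#'
#' @param phrase a single character string.
#' @param resources a [cpi_text_resources] object.
#' @return the normalized phrase, or `NA_character_` for a dropped phrase.
#' @export
normalize_phrase <- function(phrase, resources = cpi_text_resources()) {
  tok <- tolower(tokenize_text(phrase))
  tok <- tok[!(tok %in% resources$stopwords) & !grepl("^[0-9]+$", tok)]
  if (!length(tok)) return(NA_character_)
  tok[length(tok)] <- singularize(tok[length(tok)])
  out <- paste(tok, collapse = " ")
  if (length(tok) == 1L && out %in% resources$common_words)
    return(NA_character_)
  out
}

phrases_of <- function(text, resources, extractor = NULL) {
  raw <- extract_noun_phrases(text, resources, extractor)
  if (!length(raw)) return(character(0))
  norm <- vapply(raw, normalize_phrase, "", resources = resources,
                 USE.NAMES = FALSE)
  unique(norm[!is.na(norm)])
}

#' Build pathway-phrase incidence matrices
#'
#' Extracts and normalizes noun phrases from every pathway name and
#' description of a collection and builds two binary incidence matrices over
#' the union of phrases: `v` (phrase i occurs in pathway j's *name*) and `w`
#' (phrase i occurs in pathway j's *description*). Entries record presence
#' per pathway, never occurrence multiplicity. `desc_len[j]` is the number
#' of unique phrases in pathway j's description (the column sum of `w`).
#'
#' @param coll a [gene_set_collection] with names/descriptions attached
#'   (descriptions may be empty strings).
#' @param resources a [cpi_text_resources] object.
#' @param extractor optional phrase extractor override (see
#'   [extract_noun_phrases]).
#' @return object of class `cpi_phrases`: list with `phrases`, sparse binary
#'   matrices `v` and `w` (phrases x pathways), and `desc_len`.
#' @export
build_phrase_matrices <- function(coll, resources = cpi_text_resources(),
                                  extractor = NULL) {
  stopifnot(inherits(coll, "gene_set_collection"))
  name_ph <- lapply(coll$names, phrases_of, resources = resources,
                    extractor = extractor)
  desc_ph <- lapply(coll$descriptions, phrases_of, resources = resources,
                    extractor = extractor)
  phrases <- sort(unique(c(unlist(name_ph), unlist(desc_ph))))
  n_path <- length(coll$ids)
  make_mat <- function(ph_list) {
    i <- match(unlist(ph_list), phrases)
    j <- rep(seq_len(n_path), lengths(ph_list))
    Matrix::sparseMatrix(i = i, j = j, x = 1,
                         dims = c(length(phrases), n_path),
                         dimnames = list(phrases, coll$ids))
  }
  v <- make_mat(name_ph)
  w <- make_mat(desc_ph)
  new_cpi_phrases(phrases, v, w)
}

new_cpi_phrases <- function(phrases, v, w) {
  structure(list(phrases = phrases, v = v, w = w,
                 desc_len = Matrix::colSums(w)),
            class = "cpi_phrases")
}

#' @export
print.cpi_phrases <- function(x, ...) {
  cat("Pathway-phrase matrices: ", length(x$phrases), " phrases x ",
      ncol(x$v), " pathways\n", sep = "")
  cat("  name hits: ", sum(x$v), "; description hits: ", sum(x$w), "\n",
      sep = "")
  invisible(x)
}

#' Merge synonymous phrase rows
#'
#' For each synonym pair present among the phrases, the row with the lower
#' total occurrence (pathway support over name and description presence) is
#' OR-merged into the higher-occurrence row and then deleted. On equal
#' occurrence the lexicographically smaller phrase is kept. `v` and `w` are
#' merged consistently.
#'
#' @param mats a `cpi_phrases` object.
#' @param synonyms data frame of two character columns (normalized phrase
#'   pairs); defaults to the resource table.
#' @return a `cpi_phrases` object.
#' @export
merge_synonyms <- function(mats, synonyms) {
  stopifnot(inherits(mats, "cpi_phrases"))
  if (is.null(synonyms) || !nrow(synonyms)) return(mats)
  v <- mats$v; w <- mats$w
  support <- function(ph) sum((v[ph, ] + w[ph, ]) > 0)
  for (r in seq_len(nrow(synonyms))) {
    a <- synonyms[[1L]][r]; b <- synonyms[[2L]][r]
    if (!(a %in% rownames(v)) || !(b %in% rownames(v)) || a == b) next
    sa <- support(a); sb <- support(b)
    keep <- if (sa > sb) a else if (sb > sa) b else min(a, b)
    drop <- if (keep == a) b else a
    v[keep, ] <- pmin(v[keep, ] + v[drop, ], 1)
    w[keep, ] <- pmin(w[keep, ] + w[drop, ], 1)
    rows <- rownames(v) != drop
    v <- v[rows, , drop = FALSE]
    w <- w[rows, , drop = FALSE]
  }
  new_cpi_phrases(rownames(v), v, w)
}

#' Remove phrases supported by fewer than two pathways
#'
#' Support counts pathways in which the phrase occurs in the name OR the
#' description (presence, not multiplicity).
#'
#' @param mats a `cpi_phrases` object.
#' @return a `cpi_phrases` object with rare rows removed.
#' @export
prune_rare_phrases <- function(mats) {
  stopifnot(inherits(mats, "cpi_phrases"))
  support <- Matrix::rowSums((mats$v + mats$w) > 0)
  keep <- support >= 2
  if (!any(keep))
    stop("degenerate corpus: every phrase occurs in fewer than 2 pathways")
  new_cpi_phrases(mats$phrases[keep],
                  mats$v[keep, , drop = FALSE],
                  mats$w[keep, , drop = FALSE])
}

#' Length-penalized phrase scores
#'
#' `x_ij = 1` if phrase i occurs in pathway j's name; `exp(-alpha *
#' desc_len[j])` if it occurs only in the description; 0 otherwise. The
#' penalty discounts hits in long descriptions, where a phrase is more
#' likely by chance; `alpha = 0` removes the penalty, reducing the test to
#' the simple-counting (Fisher-exact) regime.
#'
#' @param mats a `cpi_phrases` object.
#' @param alpha penalty parameter >= 0 (default 0.05). Note `desc_len` is
#'   the number of unique phrases in each description *after* any synonym
#'   merging/pruning applied to `mats`.
#' @return object of class `cpi_scores`: list with dense matrix `x`
#'   (phrases x pathways), `alpha`, and the incidence matrices.
#' @export
penalized_scores <- function(mats, alpha = 0.05) {
  stopifnot(inherits(mats, "cpi_phrases"), alpha >= 0)
  v <- as.matrix(mats$v); w <- as.matrix(mats$w)
  pen <- exp(-alpha * mats$desc_len)
  x <- v + (v == 0) * w * rep(pen, each = nrow(w))
  structure(list(x = x, alpha = alpha, v = mats$v, w = mats$w,
                 desc_len = mats$desc_len),
            class = "cpi_scores")
}

#' Cluster statistic for one or all phrases
#'
#' `T_i(C) = sum_{j in C} x_ij`, the summed penalized scores of the cluster's
#' pathways.
#'
#' @param scores a `cpi_scores` object.
#' @param cluster character vector of pathway ids (non-empty, must be score
#'   columns).
#' @return named numeric vector of `T_i(C)` over all phrases.
#' @export
cluster_statistic <- function(scores, cluster) {
  stopifnot(inherits(scores, "cpi_scores"))
  if (!length(cluster)) stop("empty cluster")
  if (!all(cluster %in% colnames(scores$x)))
    stop("cluster contains unknown pathway ids")
  rowSums(scores$x[, cluster, drop = FALSE])
}

#' Permutation test for phrase enrichment in a cluster
#'
#' Draws `B` random pathway subsets of the cluster's size (without
#' replacement, uniformly from the background) and compares each phrase's
#' observed statistic `T_i(C)` with the permuted statistics `T_i(S_b)`. One
#' shared permutation stream serves all phrases. The p-value is the
#' +1-smoothed upper tail `p_i = (1 + #{b: T_i(S_b) >= T_i(C)}) / (B + 1)`,
#' so large observed statistics (phrase unusually frequent in the cluster)
#' give small p-values.
#'
#' @param scores a `cpi_scores` object.
#' @param cluster character vector of pathway ids forming the cluster.
#' @param B number of permutations (default 1e4, minimum 100).
#' @param seed optional integer seed.
#' @param background character vector of pathway ids sampled from; defaults
#'   to all score columns; must strictly contain the cluster.
#' @return named numeric vector of p-values in `[1/(B+1), 1]`.
#' @export
permutation_test <- function(scores, cluster, B = 1e4, seed = NULL,
                             background = NULL) {
  stopifnot(inherits(scores, "cpi_scores"), B >= 100)
  if (is.null(background)) background <- colnames(scores$x)
  if (!all(cluster %in% background))
    stop("cluster must be a subset of the background")
  if (length(background) <= length(cluster))
    stop("background must strictly contain the cluster")
  if (!is.null(seed)) set.seed(seed)
  B <- as.integer(B)
  x <- scores$x[, background, drop = FALSE]
  T_obs <- cluster_statistic(scores, cluster)
  n_bg <- length(background)
  csize <- length(cluster)
  draws <- vapply(seq_len(B), function(b) sample.int(n_bg, csize),
                  integer(csize))
  ind <- Matrix::sparseMatrix(i = as.vector(draws),
                              j = rep(seq_len(B), each = csize), x = 1,
                              dims = c(n_bg, B))
  T_perm <- as.matrix(x %*% ind)                   # phrases x B
  hits <- rowSums(T_perm >= T_obs - 1e-9)
  p <- (1 + hits) / (B + 1)
  names(p) <- rownames(x)
  p
}

#' Annotate pathway clusters with significant keywords
#'
#' Runs the permutation test per tight cluster (and, flagged secondary, on
#' the scattered set when it has at least 2 members), applies BH correction
#' within each cluster, and reports phrases ranked by (q, then statistic
#' descending).
#'
#' @param scores a `cpi_scores` object.
#' @param assignment a `cpi_clusters` object (see [silhouette_tighten]), or
#'   a named vector of cluster labels.
#' @param B permutations per cluster (default 1e4).
#' @param q_cutoff keyword q-value threshold used for the `significant`
#'   column (default 0.05); all phrases are returned, filtering is the
#'   caller's choice.
#' @param seed optional integer seed.
#' @param background pathway ids sampled from (default: all score columns).
#' @return data frame of class `cpi_annotation` with columns `cluster`,
#'   `phrase`, `T`, `p`, `q`, `support` (pathways of the cluster containing
#'   the phrase in name or description), `significant`, `secondary`.
#' @export
annotate_clusters <- function(scores, assignment, B = 1e4, q_cutoff = 0.05,
                              seed = NULL, background = NULL) {
  labels <- if (inherits(assignment, "cpi_clusters")) assignment$labels
            else assignment
  scattered <- if (inherits(assignment, "cpi_clusters"))
    assignment$scattered else character(0)
  if (!length(labels)) stop("assignment has no tight cluster")
  if (!is.null(seed)) set.seed(seed)
  groups <- split(names(labels), labels)
  if (length(scattered) >= 2L) groups[["scattered"]] <- scattered
  present <- (scores$v + scores$w) > 0
  res <- lapply(names(groups), function(g) {
    members <- groups[[g]]
    p <- permutation_test(scores, members, B = B, background = background)
    T_obs <- cluster_statistic(scores, members)
    q <- bh_adjust(p)
    supp <- Matrix::rowSums(present[, members, drop = FALSE])
    df <- data.frame(cluster = g, phrase = names(p), T = unname(T_obs),
                     p = unname(p), q = unname(q), support = unname(supp),
                     significant = unname(q < q_cutoff),
                     secondary = g == "scattered",
                     stringsAsFactors = FALSE)
    df[order(df$q, -df$T, df$phrase), , drop = FALSE]
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("cpi_annotation", "data.frame")
  attr(out, "B") <- B
  attr(out, "q_cutoff") <- q_cutoff
  out
}

#' Table of top keywords per cluster
#'
#' Compact summary: the top `n` significant keywords of each cluster,
#' comma-separated, mirroring a keyword-per-cluster spreadsheet.
#'
#' @param annotation a `cpi_annotation` data frame.
#' @param n maximum keywords per cluster (default 10).
#' @return data frame with columns `cluster`, `keywords`.
#' @export
keyword_table <- function(annotation, n = 10L) {
  stopifnot(inherits(annotation, "cpi_annotation"))
  sig <- annotation[annotation$significant, , drop = FALSE]
  clusters <- unique(annotation$cluster)
  kws <- vapply(clusters, function(g) {
    ph <- sig$phrase[sig$cluster == g]
    paste(utils::head(ph, n), collapse = ", ")
  }, "")
  data.frame(cluster = clusters, keywords = kws, stringsAsFactors = FALSE,
             row.names = NULL)
}
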