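#' Specification of a synthetic multi-study fixture
#'
#' Describes the study design the generators emulate: several studies, a
#' gene universe, pathway families with controlled within-family gene
#' sharing (planted truth for the kappa clustering), unrelated singleton and
#' background pathways, an enrichment design saying which family is enriched
#' in which studies, and keyword-bearing names/descriptions per family.
#'
#' Defaults mirror a six-study design with one consensually enriched family,
#' one differentially enriched family (last four studies only, the worked
#' weight pattern 0,0,1,1,1,1), one family enriched in the first three
#' studies, and five consensually enriched unrelated singletons that supply
#' a scattered set.
#'
#' @param n_studies number of studies (default 6).
#' @param n_genes gene universe size (default 2000).
#' @param n_families number of gene-sharing pathway families (default 3).
#' @param family_size pathways per family (default 10).
#' @param n_singletons unrelated enriched singleton pathways (default 5).
#' @param n_background unrelated null pathways (default 25).
#' @param pathway_size genes per pathway (default 30).
#' @param shared_frac fraction of each family member's genes drawn from the
#'   family core pool (default 0.6).
#' @param family_studies list of integer vectors: studies in which each
#'   family is enriched. Default: all studies; studies 3..K; studies 1..3.
#' @param singleton_studies studies in which singletons are enriched
#'   (default all).
#' @param de_frac fraction of a pathway's genes made DE in an enriched
#'   (pathway, study) cell (default 0.5).
#' @param beta_a Beta(a, 1) shape for DE p-values, a < 1 (default 0.1).
#' @param keywords family keyword phrases injected into member names
#'   (defaults supplied).
#' @param keyword_frac fraction of family members whose *name* carries the
#'   keyword (default 0.9).
#' @param desc_len_range range of background phrases per description
#'   (default c(5, 15)).
#' @return a list of class `cpi_fixture_spec`.
#' @export
cpi_fixture_spec <- function(n_studies = 6L, n_genes = 2000L,
                             n_families = 3L, family_size = 10L,
                             n_singletons = 5L, n_background = 25L,
                             pathway_size = 30L, shared_frac = 0.6,
                             family_studies = NULL,
                             singleton_studies = NULL,
                             de_frac = 0.5, beta_a = 0.1,
                             keywords = NULL, keyword_frac = 0.9,
                             desc_len_range = c(5L, 15L)) {
  if (is.null(family_studies)) {
    family_studies <- list(seq_len(n_studies),
                           seq(3L, n_studies),
                           seq_len(min(3L, n_studies)))
    family_studies <- family_studies[seq_len(n_families)]
  }
  stopifnot(length(family_studies) == n_families,
            shared_frac > 0, shared_frac < 1,
            de_frac > 0, de_frac <= 1, beta_a > 0, beta_a < 1,
            keyword_frac > 0, keyword_frac <= 1)
  if (is.null(singleton_studies)) singleton_studies <- seq_len(n_studies)
  if (is.null(keywords))
    keywords <- c("apoptosis", "oxidative phosphorylation",
                  "synaptic vesicle", "chromatin remodeling",
                  "ubiquitin ligase", "ion channel")[seq_len(n_families)]
  structure(list(n_studies = n_studies, n_genes = n_genes,
                 n_families = n_families, family_size = family_size,
                 n_singletons = n_singletons, n_background = n_background,
                 pathway_size = pathway_size, shared_frac = shared_frac,
                 family_studies = family_studies,
                 singleton_studies = singleton_studies,
                 de_frac = de_frac, beta_a = beta_a, keywords = keywords,
                 keyword_frac = keyword_frac,
                 desc_len_range = desc_len_range),
            class = "cpi_fixture_spec")
}

# background vocabulary for synthetic descriptions; uncommon multi-word-safe
# tokens so they survive normalization as distinct noun phrases
fixture_vocabulary <- function() {
  c("kinase cascade", "membrane receptor", "ligand binding",
    "transcription factor", "signal transduction", "metabolic flux",
    "protein folding", "lipid metabolism", "vesicle transport",
    "cytoskeleton dynamics", "calcium signaling", "receptor trafficking",
    "gene silencing", "histone modification", "nucleotide excision",
    "ribosome assembly", "translation initiation", "proteasome complex",
    "glycolysis intermediate", "electron carrier", "redox balance",
    "autophagy flux", "mitotic spindle", "cell cycle checkpoint",
    "growth factor", "cytokine release", "immune response",
    "axon guidance", "dendritic spine", "neurotransmitter release",
    "myelin sheath", "glial activation", "stress granule",
    "rna splicing", "polyadenylation site", "codon usage",
    "chaperone activity", "substrate recognition", "phosphatase activity")
}

#' Generate a synthetic gene-set collection with descriptions
#'
#' Families of gene sets share a family core gene pool (each member draws
#' `shared_frac` of its genes from the core, the rest at random), giving the
#' clustering a planted truth; singleton and background pathways are drawn
#' uniformly. Family member names carry the family keyword in at least
#' `keyword_frac` of members; descriptions mix the keyword with background
#' vocabulary, with lengths drawn from `desc_len_range`.
#'
#' @param spec a [cpi_fixture_spec].
#' @param seed integer seed.
#' @return a [gene_set_collection] with names and descriptions attached and
#'   attributes `family` (integer vector, NA for non-family pathways) and
#'   `role` (`"family"`, `"singleton"`, `"background"`).
#' @export
sim_collection <- function(spec = cpi_fixture_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cpi_fixture_spec"))
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(spec$n_genes))
  n_core <- ceiling(spec$pathway_size * spec$shared_frac * 1.5)
  if (spec$n_families * n_core > spec$n_genes)
    stop("infeasible overlap target: family cores exceed the gene universe")
  core_pool <- split(sample(genes, spec$n_families * n_core),
                     rep(seq_len(spec$n_families), each = n_core))
  vocab <- fixture_vocabulary()
  ids <- character(0); sets <- list(); nm <- character(0); ds <- character(0)
  family <- integer(0); role <- character(0)
  n_shared <- round(spec$pathway_size * spec$shared_frac)
  for (f in seq_len(spec$n_families)) {
    kw <- spec$keywords[f]
    with_kw <- seq_len(spec$family_size) <=
      ceiling(spec$keyword_frac * spec$family_size)
    for (m in seq_len(spec$family_size)) {
      id <- sprintf("FAM%d_P%02d", f, m)
      core <- sample(core_pool[[f]], n_shared)
      rest <- sample(setdiff(genes, core), spec$pathway_size - n_shared)
      ids <- c(ids, id); sets <- c(sets, list(c(core, rest)))
      nm <- c(nm, if (with_kw[m]) paste(kw, "pathway", m)
              else paste("family", f, "member", m, "pathway"))
      len <- sample(spec$desc_len_range[1L]:spec$desc_len_range[2L], 1L)
      ds <- c(ds, paste(c(kw, sample(vocab, len, replace = FALSE)),
                        collapse = ". "))
      family <- c(family, f); role <- c(role, "family")
    }
  }
  extra <- c(rep("singleton", spec$n_singletons),
             rep("background", spec$n_background))
  for (e in seq_along(extra)) {
    id <- sprintf("%s_P%02d", toupper(extra[e]), e)
    ids <- c(ids, id)
    sets <- c(sets, list(sample(genes, spec$pathway_size)))
    nm <- c(nm, paste(sample(vocab, 1L), "pathway", e))
    len <- sample(spec$desc_len_range[1L]:spec$desc_len_range[2L], 1L)
    ds <- c(ds, paste(sample(vocab, len, replace = FALSE), collapse = ". "))
    family <- c(family, NA_integer_); role <- c(role, extra[e])
  }
  coll <- gene_set_collection(ids = ids, genes = sets, names = nm,
                              descriptions = ds, universe = genes)
  attr(coll, "family") <- family
  attr(coll, "role") <- role
  attr(coll, "spec") <- spec
  coll
}

#' Generate synthetic gene-level p-value matrices
#'
#' Null genes draw i.i.d. Uniform(0,1) p-values. In each enriched (pathway,
#' study) cell of the design, a fraction `de_frac` of the pathway's genes is
#' made DE with p ~ Beta(a, 1), a < 1 (stochastically small), so the planted
#' adaptive-weight patterns are recoverable in expectation.
#'
#' @param coll a collection from [sim_collection] (carries the spec).
#' @param seed integer seed.
#' @return numeric matrix genes x studies of p-values in (0, 1].
#' @export
sim_gene_pvalues <- function(coll, seed = 1L) {
  spec <- attr(coll, "spec")
  if (is.null(spec)) stop("collection was not produced by sim_collection")
  set.seed(seed)
  genes <- coll$universe
  K <- spec$n_studies
  m <- matrix(stats::runif(length(genes) * K), ncol = K,
              dimnames = list(genes, paste0("study", seq_len(K))))
  family <- attr(coll, "family")
  role <- attr(coll, "role")
  enriched_in <- function(i) {
    if (role[i] == "family") spec$family_studies[[family[i]]]
    else if (role[i] == "singleton") spec$singleton_studies
    else integer(0)
  }
  for (i in seq_along(coll$ids)) {
    studies <- enriched_in(i)
    if (!length(studies)) next
    g <- coll$genes[[i]]
    n_de <- round(spec$de_frac * length(g))
    for (s in studies) {
      de <- sample(g, n_de)
      m[de, s] <- pmin(m[de, s], stats::rbeta(n_de, spec$beta_a, 1))
    }
  }
  m[m <= 0] <- .Machine$double.xmin
  validate_pvalue_matrix(m, "simulated gene p-value")
}

#' The six-study worked-example p-value vector
#'
#' Per-study raw enrichment p-values of a kinase-activity pathway used
#' throughout as a regression fixture: adaptive weights (0,0,1,1,1,1) and a
#' combined p-value near 5.5e-6.
#'
#' @return numeric vector of length 6.
#' @export
worked_example_pvec <- function() {
  c(0.26922, 0.17773, 0.06485, 2.04e-5, 0.00449, 0.018922)
}

#' Materialize a demo workspace on disk
#'
#' Writes the synthetic collection (GMT + description TSV) and per-study
#' gene p-value matrix (TSV) for a seed, ready to feed the pipeline or the
#' command-line interface.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @param spec a [cpi_fixture_spec].
#' @return invisibly, a named list of the written file paths.
#' @export
cpi_demo_workspace <- function(dir, seed = 1L, spec = cpi_fixture_spec()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  coll <- sim_collection(spec, seed = seed)
  gp <- sim_gene_pvalues(coll, seed = seed + 1L)
  paths <- list(gmt = file.path(dir, "collection.gmt"),
                descriptions = file.path(dir, "descriptions.tsv"),
                gene_pvalues = file.path(dir, "gene_pvalues.tsv"))
  write_gmt(coll, paths$gmt)
  write_tsv_matrix(data.frame(id = coll$ids, name = coll$names,
                              description = coll$descriptions,
                              stringsAsFactors = FALSE),
                   paths$descriptions)
  write_tsv_matrix(gp, paths$gene_pvalues, id_col = "gene")
  invisible(paths)
}
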