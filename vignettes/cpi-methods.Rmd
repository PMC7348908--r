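---
title: "Methods: meta-analytic pathway integration, tight clustering and penalized keyword mining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: meta-analytic pathway integration, tight clustering and penalized keyword mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpi)
```

This vignette is the package's account of the statistics it implements: the
models and their assumptions, the parameters that matter, the numerical
choices, and the places where the design was genuinely open and a choice had
to be made.

## 1. Per-study enrichment

Input is a genes × studies matrix of differential-expression p-values (or,
alternatively, a ready-made pathways × studies enrichment p-value matrix,
which skips this stage entirely — useful when enrichment was computed
externally with a method this package does not provide, e.g. a
functional-class-scoring test).

Two per-study tests are provided:

* **Over-representation** (`method = "fisher"`): the `top_n` genes with the
  smallest p-values (default **400**; ties at the boundary broken by
  lexicographic gene id so selection is reproducible) are tested against
  each pathway with the one-sided hypergeometric tail
  `P(X >= k)`. The background is the study's *measured* genes intersected
  with the collection universe: a gene that could never have been selected
  must not inflate the background. This assumes DE evidence is summarized
  adequately by membership in the top list; the cutoff is the classical
  hard-threshold compromise.
* **Kolmogorov–Smirnov** (`method = "ks"`): two-sample, one-sided, testing
  that in-pathway gene p-values are stochastically smaller than out-pathway
  p-values. No threshold is needed; the asymptotic p-value is used. A
  one-sample variant against the uniform would be an alternative reading;
  the two-sample form is implemented because it conditions on the study's
  overall p-value distribution.

Pathways are size-filtered first with inclusive bounds (default **[15,
500]** genes): below, tests are unstable; above, sets are too generic to
interpret. Sizes can optionally be counted after intersection with the
measured genes (`restrict_to`), since a 600-gene pathway of which 80 are
measured behaves like an 80-gene pathway.

Both tests yield *valid but conservative* null p-values — the
hypergeometric is discrete and the KS p-value asymptotic — so their null
distribution is super-uniform rather than exactly uniform. The test suite
asserts exactly that (type-I error control at several thresholds), not
exact uniformity. Exact zeros (possible only by underflow) are floored at
`1e-300` because the next stage takes logarithms.

## 2. Adaptively weighted Fisher meta-analysis

For a pathway with per-study p-values $p_1,\dots,p_K$ and a 0/1 weight
vector $w$, the weighted Fisher statistic is $V(w) = -2\sum_k w_k \log
p_k$, with observed significance $U(w)$ = the upper tail of $\chi^2_{2\sum
w_k}$ at $V(w)$. The adaptive weights are the nonzero $w$ minimizing
$U(w)$; because including a study with a smaller p-value always helps
before one with a larger p-value, the minimum over all $2^K-1$ vectors is
attained on one of the $K$ nested subsets of the $s$ smallest p-values, and
only those are scanned (the test suite verifies this equivalence against
exhaustive enumeration). Ties break toward the smaller weight sum — the
sparser explanation — though exact ties have measure zero.

The combined p-value is $P(\min_w U(W) \le U_{obs})$ under $K$ i.i.d.
Uniform(0,1) p-values. It is estimated by Monte Carlo in compiled code
(R's RNG stream, so `set.seed` governs everything) with the +1-corrected
estimator $(1+\text{hits})/(B+1)$, which is never zero. Defaults: **B =
10⁴** for screening; the worked-example reproduction uses **B = 10⁷** so a
combined p-value of order $5\times10^{-6}$ has ~50 expected hits. A
warning is raised when fewer than 10 hits were observed. For a whole
pathway matrix (`aw_meta`) one null sample is shared by all pathways — the
null does not depend on the data — making the matrix version cheap; the
scalar `aw_pvalue` draws its own sample.

For $K \le 3$, `method = "exact_smallK"` provides a deterministic oracle:
the event $\{\min_w U \le t\}$ is monotone in each coordinate, so the last
coordinate integrates analytically to a threshold; $K=2$ then has a closed
form and $K=3$ a 2-D midpoint integral refined until two successive grid
doublings agree to 0.5% relative. This exists to cross-check the sampler,
not to replace it.

All-ones weights reproduce classical Fisher's method exactly; a single
selected study reproduces that study's p-value exactly. BH q-values are
computed across pathways (`stats::p.adjust`), and pathways with `q <
q_cutoff` (default **0.0005**) are carried forward, tagged *consensual*
(all weights 1) or *differential*.

## 3. Kappa tight clustering

Similarity between two significant pathways is Cohen's kappa of their gene
membership vectors over a background universe — by default the union of
genes across the significant pathways (configurable to the full collection
universe; the choice shifts the marginal agreement `Pe` but not the
ordering much). Dissimilarity is $1-\kappa$.

**Consensus clustering.** For each candidate $K$ (default range 2–10), the
items are subsampled (**fraction 0.8**, **500 resamples** — standard
consensus-clustering practice), each subsample is clustered by
average-linkage hierarchical clustering on the subsampled dissimilarity
(deterministic, no extra RNG per run), and the consensus matrix records
co-clustering proportions among co-sampled pairs (never co-sampled pairs
are flagged and excluded from the CDF). The empirical CDF of off-diagonal
consensus entries, its area, and the relative delta-area per added cluster
are produced as the standard diagnostics (`plot(fit, "consensus")`).

**Choice of K.** A fixed numerical threshold on the delta-area curve turned
out to be fragile in both directions: on cleanly separated blocks,
hierarchical sub-splits of a true cluster can be stable enough under
subsampling that the area keeps growing past the true $K$; on data with a
few unrelated "noise" pathways, the delta-area keeps earning credit for
isolating them one cluster too late. The automatic choice therefore scores
each candidate consensus partition by its **mean silhouette width on the
input dissimilarity** (members of size-1 clusters scored 0, so isolating
noise is not rewarded) and takes the maximizer. The delta-area elbow
remains available visually, and a fixed `k` overrides the automatic choice
— recommended whenever an expected cluster count exists.

**Assignment and tightening.** The final partition cuts an average-linkage
tree of $1-\text{consensus}$ at $K$. Silhouette widths
$s(i) = (b_i - a_i)/\max(a_i, b_i)$ are then computed on $1-\kappa$ (the
quantity the clustering optimizes; `silhouette_on = "consensus"` switches
to the consensus scale) and every pathway with $s(i)$ below the cutoff
(default **0.1**) is moved to the *scattered set*; this repeats until all
retained silhouettes clear the cutoff, which takes at most $n$ iterations
since each round removes at least one item. All below-cutoff items move
per iteration (order-independent and faster than one-at-a-time). Size-1
clusters are dissolved into the scattered set whenever they arise,
including in the initial cut: a lone pathway *is* a scattered pathway, and
the $a(i)=0$ silhouette convention would otherwise pin it at $s=1$
forever. The scattered set is part of the output — annotated too, flagged
secondary — because pathways with unusual gene content are often exactly
the interesting ones.

## 4. Penalized keyword mining

Phrases are extracted from pathway names and descriptions by a
deterministic rule-based chunker: text is split at punctuation, then
maximal runs of content tokens between boundaries (stop words, pure
numbers) become candidate phrases. An industrial NP extractor can be
plugged in as a function `text -> phrases`; the default needs no model
download and is fully reproducible. Normalization lowercases, drops
stop-word tokens, singularizes the head (final) token by rule with an
exception table, and discards single-token phrases found in a bundled,
versioned common-English-word list (a curated list of ~1050 words shipped
as plain text; it only affects length-one phrases). Synonym pairs, if
supplied, are OR-merged into the more frequent row (lexicographic
tie-break); phrases supported by fewer than two pathways (name-or-
description presence) are pruned.

Incidence is per pathway, never per occurrence: a phrase appearing six
times across three descriptions counts three. The penalized score is

$$x_{ij} = \begin{cases} 1 & \text{name hit} \\ e^{-\alpha |w_j|} &
\text{description-only hit} \\ 0 & \text{otherwise,} \end{cases}$$

with $|w_j|$ the number of unique phrases in description $j$ (computed on
the current, pruned matrix) and $\alpha$ defaulting to **0.05** — at 20
description phrases the discount is $e^{-1}$; at 100 it is below 0.01,
which is what neutralizes boilerplate phrases that haunt long
descriptions. $\alpha = 0$ removes the penalty and the test collapses to
simple counting, where the permutation p-value provably matches the
one-sided hypergeometric tail (asserted in the tests).

Cluster statistics $T_i(C) = \sum_{j \in C} x_{ij}$ are compared with
$T_i(S_b)$ on $B$ (default **10⁴**) random same-size pathway subsets drawn
without replacement from the background — by default the whole loaded
collection, configurable to the significant set. One shared permutation
stream serves all phrases (exchangeability holds and it is an order of
magnitude cheaper). The p-value is the +1-smoothed *upper* tail
$(1 + \#\{T_i(S_b) \ge T_i(C)\})/(B+1)$: large observed statistics mean
enrichment. (A literal lower-tail reading would call *frequent* phrases
*less* significant; the upper tail implements the stated meaning of the
test.) BH runs within each cluster — each cluster is its own annotation
problem; a global variant across (cluster, phrase) pairs would mix
clusters of very different sizes — and phrases are reported ranked by
(q, then statistic), with the default keyword threshold `q < 0.05`.

## 5. The synthetic-data generator

`cpi_fixture_spec()` encodes the study design the generators emulate: **6
studies, 2000 genes, 60 pathways** — three families of 10 pathways drawing
60% of their 30 genes from a family core pool (planted kappa structure),
five enriched but unrelated singletons (they reach significance yet belong
to no family, populating the scattered set), and 25 null pathways. Family
1 is enriched in all six studies (consensual), family 2 in studies 3–6
(the canonical differential pattern), family 3 in studies 1–3; enrichment
makes 50% of a pathway's genes DE with p-values drawn from Beta(0.1, 1),
null p-values i.i.d. Uniform(0,1). Family keywords are injected into 90%
of member names and all member descriptions; background vocabulary fills
the rest, with 5–15 phrases per description.

These sizes keep a full pipeline run under ~3 s and the entire test suite
(including a 20-seed end-to-end study and a 5000-replicate null
calibration) around two minutes, while leaving every stage's signal
recoverable rather than trivial.

What the generator does *not* emulate: gene–gene correlation, realistic
expression-intensity noise, hierarchically nested pathway ontologies,
natural-language descriptions with grammar (descriptions are phrase lists),
or study heterogeneity in measured gene panels. Passing tests therefore
demonstrate the pipeline's statistical machinery — weight recovery,
cluster recovery, keyword calibration — not robustness to those real-data
features.

## 6. Numerical and degenerate-input conventions

* p-values are validated into $(0, 1]$; exact zeros are floored at
  `1e-300` (logged) before any logarithm.
* Gene symbols are upper-cased on read; case-fold collisions are counted
  in the GMT parser's warning.
* Top-list ties, synonym ties and weight-search ties all have
  deterministic lexicographic / sparsity tie-breaks.
* `kappa` with `Pe = 1` (both sets equal to the universe) is defined as 1
  for identical sets and an error otherwise.
* Equidistant silhouette cases ($a = b$) score 0.
* An empty significant set, an empty phrase corpus after pruning, an
  all-scattered tightening and a `K` outside $[2, n-1]$ are errors or
  warnings with actionable messages, raised before expensive work where
  possible.
* Every stochastic stage takes an explicit seed; `cpi()` derives stage
  seeds (`seed + 1, 2, 3`) so stages can be rerun individually, and the
  run manifest records all parameters plus the seed, which is sufficient
  to reproduce every output table byte-identically.

## 7. Known limitations

* Monte-Carlo combined p-values cannot resolve below $1/(B+1)$; very small
  targets need large `B` (the worked-example reproduction uses $10^7$,
  with ~13% relative sampling error at a true value near $5.6\times
  10^{-6}$).
* The KS branch uses asymptotic p-values; with heavy ties among gene
  p-values the test is conservative.
* The automatic cluster number is a heuristic; when an expected count
  exists, set `k` explicitly and use the consensus diagnostics.
* The rule-based chunker is deliberately simple: it does not parse grammar
  and will emit verbs as "phrases" occasionally; downstream pruning and
  the permutation test tolerate this noise, and a better extractor can be
  plugged in without touching the statistics.
* Keyword annotation is only as good as the descriptions: collections
  without descriptions fall back to name phrases alone.
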