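---
title: "Pathway-based consensus subtyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-based consensus subtyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathsubtype)
```

# Overview

`pathsubtype` implements a pathway-level subtyping pipeline for bulk tumour
expression cohorts, of the kind used to stratify glioblastoma patients into
prognostically distinct molecular groups. The pipeline runs in stages, each
usable on its own:

1. **Pathway-activity scoring** (`score_enrichment`): a per-sample,
   rank-based enrichment score for each gene set of a collection.
2. **Signature de-duplication** (`dedup_collection`): greedy removal of
   near-duplicate gene sets at a Jaccard threshold.
3. **Consensus subtyping** (`consensus_cluster`, `select_k`,
   `silhouette_refine`): resampled PAM clustering of the score matrix,
   stability-based choice of the number of subtypes, and silhouette-guided
   label refinement.
4. **Mutational signatures** (`build_context_matrix`,
   `extract_signatures`, `match_reference`, `refit_exposures`):
   96-trinucleotide-context catalogs, de novo KL-NMF signatures, cosine
   matching to a reference catalogue, and bootstrap-stabilized exposure
   refitting.
5. **Hub genes** (`build_tom`, `detect_modules`, `module_stats`,
   `select_hub_genes`): co-expression modules by topological overlap and
   per-subtype hub selection on gene significance (GS) and module
   membership (MM).
6. **Subtype classifier** (`train_classifier`, `predict_subtypes`,
   `evaluate_classifier`): a small feedforward network over hub-gene
   z-scores, transferable to external cohorts.
7. **Statistical screens and survival analysis** (`deg_one_vs_rest`,
   `anova_screen`, `fisher_pair_patterns`, `correlation_screen`,
   `survival_compare`, `cox_univariate`, `maxstat_cutpoint`).
8. **Pharmacogenomics and immunophenotyping** (`stratify_drugs`,
   `sbs_drug_match`, `immunophenotype`).

Every stage is exercised end-to-end on synthetic cohorts produced by the
generator functions (`make_cohort` and friends), which plant the exact
statistical structure each stage assumes. This vignette documents the models,
the tunable parameters, the numerical choices, and what the synthetic tests
do and do not demonstrate about real data.

# The enrichment score

For a sample with expression vector $x$ over $N$ genes, genes are ranked
within the sample (average ranks on ties, residual ties broken by gene name
so the result cannot depend on file order). Walking down the list ordered by
decreasing rank, a gene set $S$ accumulates weight $r_g^\tau$ when the gene
is in $S$ and the complement accumulates $1/(N-|S|)$ otherwise; the score is

$$\mathrm{ES}(S) = \frac{1}{N} \sum_{i=1}^{N}
  \left( P_{\mathrm{in}}(i) - P_{\mathrm{out}}(i) \right),$$

the mean gap between the two cumulative fractions. With the default weight
exponent $\tau = 1$ this is the single-sample (ssGSEA-style) weighted
Kolmogorov–Smirnov random walk, normalized by the universe size. Because it
is a pure function of within-sample ranks, the score is invariant under any
strictly monotone per-sample transform — FPKM vs. TPM scaling, log
transforms, and library-size factors all cancel. That invariance is what
makes the rank-based variant preferable here to a kernel-density variant:
it is deterministic, assumption-free, and directly testable (the test suite
checks order- and monotone-invariance explicitly, plus agreement with an
independently coded walk).

Set-size bounds (`min_size = 5`, `max_size = 5000`, applied after
intersecting each set with the expression universe) drop sets too small to
score stably or so large they blanket the transcriptome; dropped sets are
logged, never silently discarded.

# Redundancy filtering

Public gene-set collections contain heavily overlapping signatures, which
makes the score matrix nearly collinear. `dedup_collection` removes
redundancy greedily at a pairwise Jaccard threshold (default 0.60). Because
a greedy procedure depends on its visitation order, the order is fixed and
documented: descending set size, ties lexicographic by name. When two sets
conflict, the representative is the one with more unique content (genes the
other lacks), ties broken by a user-supplied canonical-source rank, then by
name. The result satisfies a checkable postcondition — all retained pairwise
similarities are strictly below the threshold — and the operation is
idempotent, both asserted in the tests against a brute-force replay.

# Consensus subtyping

Samples are clustered by PAM (partitioning around medoids, BUILD + SWAP via
the `cluster` package) on the Minkowski distance between score columns. The
Minkowski exponent is exposed (`minkowski_p`, default 2 = Euclidean, the
conventional choice). Stability is assessed by resampling: a fraction
(default 0.8) of samples is drawn without replacement, PAM is re-run, and
the consensus matrix entry for a pair is the fraction of co-clustered runs
among runs where both were drawn. Pairs never co-drawn get consensus 0 plus
a coverage warning — the same denominator convention as the standard
consensus-clustering implementation, but with the under-sampling surfaced.
The default `reps = 10` mirrors common practice but is statistically thin;
the package's own tests use 50.

Internally samples are canonicalized by name before the resampling stream is
drawn, so permuting the input columns permutes the consensus matrix
identically — an equivariance property the tests assert.

**Choosing k.** For each candidate k the package reports every cluster's
mean internal consensus and the area under the CDF of consensus values.
`select_k` picks the largest k such that

* the *minimum* per-cluster mean consensus reaches the floor (default
  0.85), and
* the relative gain in CDF area over k−1 exceeds `delta_epsilon`
  (default 0.05).

Two design notes. First, the floor is applied per cluster, not averaged:
when a genuinely k-cluster structure is forced into k+1 clusters, one tight
cluster splits into two moderately stable halves while all others stay at
consensus ≈ 1, so the *average* can remain above any reasonable floor while
the *minimum* drops — the per-cluster reading is the one that actually
discriminates, and simulations with planted structure confirm it (planted
k = 5 recovered in 20/20 acceptance runs; planted k = 2 recovered in the
test suite). Second, `delta_epsilon = 0.05` encodes the usual CDF-elbow
judgement — relative area gains below about 5% mean the consensus CDF is
flattening and additional clusters only fragment stable groups. Both values
are configuration, not magic: the full per-k decision trace is returned so
the choice can be audited.

**Silhouette refinement.** After k is fixed, samples with negative
silhouette width are offered a move to their neighbouring cluster (the
cluster minimizing the mean between-cluster dissimilarity b(i)). A move is
accepted only if it raises that sample's width, does not empty its source
cluster, and does not lower the overall mean width; consequently the mean
silhouette is non-decreasing across iterations *by construction*, which the
tests assert on random data. Every accepted and rejected move is logged.
Refinement reassigns rather than removes samples; removal of persistently
negative samples can be done by the caller from the returned report.

# Mutational signatures

Single-base substitutions are strand-collapsed to the pyrimidine frame
(purine-reference records are reverse-complemented, flanks included),
yielding the canonical 96 classes: 6 substitutions × 16 flank combinations.
The catalog carries its context in a `ref_context` column, so no reference
genome is needed. Doublet substitutions are summarized separately and kept
out of the 96-context matrix. Conservation (column sums equal per-sample
collapsed SNV counts) is asserted on every build.

**Extraction.** De novo signatures come from NMF under the generalized
Kullback–Leibler divergence — the standard model for count catalogs — by
multiplicative updates, whose objective is non-increasing per iteration
(asserted every run). Each rank is fitted from `restarts` random
initializations (default 30); the best restart by final objective is kept.
Rank selection uses the cophenetic coefficient of the restart-consensus
matrix (samples co-assigned when they share a dominant signature, the
classic consensus construction): the chosen rank is the largest k before the
first drop exceeding `coph_delta = 0.02`. The 0.02 default separates the
plateau (planted-rank simulations hold cophenetic ≈ 0.99 up to the true
rank) from the post-rank decay; it is configurable and the full per-k
diagnostics are returned.

**Matching and refitting.** Extracted profiles are matched to a reference
catalogue (COSMIC-layout TSV, validated to the canonical row order) by
argmax cosine similarity, independently per signature as is common practice;
an exhaustive one-to-one assignment is available behind `bipartite = TRUE`.
Exposures are refit by non-negative least squares per sample; each of
`n_boot = 100` bootstrap replicates resamples every sample's mutations
multinomially at its observed depth and refits, giving per-signature
standard deviations and presence frequencies. Exposures are reported both
on the count scale and as per-sample fractions (contribution percentages).

# Co-expression modules and hub genes

The network is unsigned: adjacency $a_{ij} = |\mathrm{cor}(x_i, x_j)|^\beta$.
The soft threshold $\beta$ is chosen as the smallest power whose
connectivity distribution fits a scale-free log–log line with $R^2 \ge 0.8$
and negative slope, falling back to the argmax $R^2$; the full fit table is
returned. Adjacency is smoothed into the topological overlap matrix

$$\mathrm{TOM}_{ij} = \frac{\sum_{u \ne i,j} a_{iu} a_{uj} + a_{ij}}
  {\min(k_i, k_j) + 1 - a_{ij}},$$

bounds-checked in $[0, 1]$ and verified against a hand-computed oracle in
the tests. Modules are average-linkage clusters of $1 - \mathrm{TOM}$ under
a static cut (default 0.99 of the maximum merge height; the dynamic hybrid
cut is out of scope), with clusters below `min_module_size = 30` assigned
to "grey". Module labels use the conventional colour names ordered by
module size, anchored by the lexicographically smallest member so labels do
not depend on gene input order.

Each module's eigengene is the first principal component of its
standardized expression, sign-anchored so the mean gene loading is positive
(removing the SVD sign ambiguity deterministically). Module membership is
the gene–eigengene correlation; gene significance is the gene–subtype
correlation against one-hot subtype indicators. Hub genes per subtype pass
|GS| > 0.3 and |MM| > 0.8 and are ranked by |GS|, ties by |MM| then name,
keeping the top 10 by default.

# The subtype classifier

A deliberately small model: per-gene z-scores (training-set mean/SD, frozen
into the model) feed one hidden layer of 6 logistic units and a softmax
output, trained full-batch on the cross-entropy for 2000 epochs at learning
rate 0.01. The step is halved whenever it would increase the loss, so the
training loss is non-increasing by construction and, with a fixed seed,
training is bit-reproducible — both asserted in the tests. With ~10 input
genes this configuration trains in under a second and has no need for
regularization or minibatching.

External cohorts are harmonized by per-gene z-scoring *within the external
dataset*, which cancels platform scale differences but assumes comparable
within-cohort subtype composition; this is an assumption, not a guarantee,
and it is the documented default (`harmonize = "model_scalers"` exists for
same-platform data). Model genes missing externally are imputed at the
standardized mean (0) and logged; below 80% gene overlap prediction is
refused with the missing list. Evaluation offers a stratified held-out
split (default 8:2) and stratified 5-fold cross-validation, with accuracy,
per-class/macro/weighted F1, and one-vs-rest AUC by the Mann–Whitney rank
statistic.

# Statistical screens

* **Differential expression** (one vs. rest): Welch t on log2(x+1);
  log2 fold change on the log2(mean+1) scale. Gene lists use the raw-p
  threshold convention of the screening literature; BH-adjusted values are
  always computed alongside so FDR control is one column away.
* **Differential enrichment**: "fold change" is ill-defined for signed
  enrichment scores, so the ratio test applies only when both group means
  are positive; otherwise the absolute difference is thresholded, and the
  mode used is recorded per row. On the score scale differences rarely reach
  a ratio-scale threshold, so difference-mode rows seldom pass — the mode
  column makes this visible rather than hiding it.
* **ANOVA screen**: classic equal-variance one-way F per feature (reduces
  exactly to the pooled t² at two groups, tested); degenerate zero-variance
  features are flagged with p = 0 rather than dropped.
* **Mutation pair patterns**: two-sided Fisher exact tests on the 2×2
  co-mutation table, direction by the sample odds ratio (co-occurrence vs.
  mutual exclusivity); equivalence with exhaustive hypergeometric
  enumeration is asserted for every table up to n = 30.
* **Correlation screens**: one engine serves the CNV–mRNA cis screen
  (positive r), the CNV–mRNA–protein triple (intersection of pairwise
  screens), the methylation–expression screen (absolute r) and the
  signature–expression screen (r > 0.2), with constant features skipped and
  logged.
* **Survival**: Kaplan–Meier curves with k-group log-rank (via the
  `survival` package), univariate Cox with Breslow ties (constant
  covariates are rejected outright — no variation, no information), and
  maximally selected cutpoints: all thresholds keeping both groups above
  `min_group_frac` are scanned with a fast internal two-group log-rank
  statistic (verified against `survdiff`), and significance comes from a
  score-permutation null (default 1000 permutations) because the naive
  best-split p is anti-conservative — a fact the test suite demonstrates
  rather than assumes.

# Drug sensitivity and immunophenotypes

Drug-response tables are filtered at AUC > 0.7; the direction convention
(higher = sensitive) differs between database releases, so it is a flag with
a loud log line rather than an assumption. A drug is "sensitive for a
subtype" when at least one cell line of that subtype passes — presence-based
counting, matching how per-subtype drug sets are usually tallied — with a
`min_fraction` option for stricter calls. The universal / subtype-specific /
shared partition is asserted to tile the sensitive set disjointly.
Signature–drug markers are joined to per-sample exposure fractions above an
activity floor, separating recommendations from contraindications.
Immunophenotyping z-scores a cell-type score matrix, consensus-clusters the
samples at k = 2, and names the class with the higher aggregate score
"immune-inflamed" and the other "immune-desert".

# The synthetic cohort generator

The generator is the package's test bed and defines the conditions under
which the pipeline's recovery claims are made:

* **Expression**: per-gene baseline log2 means ~ N(3, 1), unit-variance
  Gaussian noise on the log2 scale, exponentiated to an FPKM-like positive
  scale. Each subtype adds a mean shift of `effect` (in noise-SD units) on
  its own disjoint block of `n_marker = 20` marker genes. Log-normal noise
  is the natural choice when the downstream scoring is rank-based: the
  exponentiation changes nothing downstream while keeping the data
  FPKM-shaped.
* **Cohort size**: defaults of 160 samples and k = 5 subtypes mirror a
  typical single-site bulk cohort.
* **Survival**: exponential with per-subtype hazards, default
  `seq(0.0015, 0.0035)` per day — medians of roughly 200–460 days,
  bracketing the ~1-year median overall survival typical of glioblastoma
  cohorts. Censoring is independent uniform on [0, max_time], the simplest
  non-informative mechanism, with max_time solved numerically so the
  expected censored fraction equals `censor_rate`.
* **Mutations**: per-sample multinomial draws over the 96 classes from
  exposure-weighted mixtures of planted profiles; contexts are emitted
  directly, removing any reference-genome dependency.
* **Paired omics**: cis genes get CNV correlated with expression and
  protein correlated with CNV at a target Pearson r (exact in expectation
  by the mixing construction); methylation betas are probit-bounded to
  [0, 1] and negatively correlated with their target gene's expression.
  The probit transform preserves the correlation's sign but shrinks its
  magnitude, which the screening tests account for.

**What passing tests show — and don't.** The synthetic model plants clean,
disjoint marker blocks, spherical noise, exponential survival and
non-informative censoring. Real cohorts have correlated noise, batch
effects, overlapping programs, informative censoring and label noise, none
of which the generator emulates. Recovery results (ARI ≥ 0.9 at a 2 SD
effect, classifier accuracy ≥ 0.9 at 3 SD) therefore certify the
*correctness of the machinery* under its stated assumptions — they are not
performance claims about any real dataset.

# Problem sizes and reproducibility

The packaged property checks run at deliberately modest sizes chosen as the
smallest scales at which the planted structure is identifiable with margin:
subtype recovery uses 20 cohorts of 150 samples × 500 genes with 50
consensus repetitions; signature recovery uses 150 samples × 500 mutations;
calibration checks use 50–200 simulation replicates. Every stochastic
function takes an explicit seed, derives its internal streams from it, and
is bit-reproducible; the command-line layer (`run_cli`, or the installed
`inst/cli/pathsubtype` script) writes byte-identical outputs on rerun with
the same config and seed.

# Known limitations

* Scoring after vs. before de-duplication is a pipeline-order choice left
  to the caller; both orders are supported and neither is privileged.
* The consensus default of 10 repetitions is paper-parity, not a
  recommendation; use 50+ for stable consensus values.
* The static tree cut cannot resolve nested modules the way the dynamic
  hybrid cut can; module claims at small sizes should be checked against
  the returned merge heights.
* The classifier is intentionally tiny and linear-ish; it will not model
  interactions among hub genes that a larger model could, and its external
  transfer rests on the within-dataset z-score assumption above.
* `maxstat_cutpoint`'s permutation p is exact only up to Monte Carlo error;
  the Lausen–Schumacher analytic approximation is not implemented.
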