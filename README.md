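# pathsubtype

Pathway-based consensus subtyping and multi-omics characterization of tumour
expression cohorts.

Bulk tumour cohorts — glioblastoma being the motivating case — are
heterogeneous in ways single genes capture poorly. `pathsubtype` stratifies
patients at the *pathway* level: it scores every sample against a gene-set
collection with a rank-based single-sample enrichment statistic, removes
redundant signatures, clusters samples by resampled PAM consensus with
silhouette refinement, and then characterizes the resulting subtypes with
the standard downstream machinery — de novo mutational signatures (KL-NMF
over 96 trinucleotide contexts, cosine matching to a reference catalogue,
bootstrap-refit exposures), co-expression hub genes (topological overlap
modules, |GS| > .3 / |MM| > .8 selection), a small neural-network subtype
classifier transferable to external cohorts, mutation co-occurrence and
cis-regulation screens, Kaplan–Meier / Cox / maximally-selected-cutpoint
survival analysis, and drug-sensitivity set logic. A synthetic-cohort
generator plants every structure the pipeline assumes, so the whole chain is
testable offline.

It is aimed at computational biologists who want each stage as an auditable,
seed-deterministic function rather than a monolithic script.

## The core statistics

**Pathway activity.** For a sample with within-sample gene ranks
`r_g` (average ranks on ties), a gene set `S` is scored by the weighted
Kolmogorov–Smirnov random walk

    ES(S) = (1/N) * sum_i [ P_in(i) − P_out(i) ]

with in-set steps proportional to `r_g^tau` (default `tau = 1`) and uniform
out-of-set steps — invariant under any monotone per-sample transform of
expression.

**Consensus subtyping.** Entry (i, j) of the consensus matrix at a given k
is the fraction of co-clustered runs among resampled PAM runs (80% sample
draws) where both samples appeared. `select_k` takes the largest k whose
*minimum* per-cluster mean consensus clears 0.85 and whose CDF delta-area
gain still exceeds 5%; silhouette refinement then reassigns negative-width
samples, never decreasing the mean width.

**Mutational signatures.** Strand-collapsed 96-context counts `V` are
factorized as `V ≈ W H` by multiplicative-update NMF under generalized KL
divergence (objective non-increasing per iteration, asserted); rank is
chosen at the cophenetic-coefficient drop across restarts; exposures are
refit against a reference catalogue by non-negative least squares with
multinomial-bootstrap stability.

## Worked example

```r
library(pathsubtype)

# a synthetic cohort with five planted subtypes at 2 SD separation
co   <- make_cohort(n_samples = 160, n_genes = 500, k = 5, effect = 2, seed = 1)
coll <- cohort_marker_sets(co, n_decoy = 20, seed = 1)

E   <- score_enrichment(co$expression, coll)      # 25 signatures x 160 samples
res <- consensus_cluster(E, k_range = 2:7, reps = 50, seed = 1)
sel <- select_k(res)
sel$k
#> [1] 5
sel$trace[, c("k", "min_cluster_consensus", "delta_area")]
#>  k min_cluster_consensus delta_area
#>  2             0.7249524 0.50047830
#>  3             0.6091608 0.33061829
#>  4             0.9038725 0.12972289
#>  5             0.9384563 0.06952219
#>  6             0.7830959 0.02643509
#>  7             0.7564790 0.02411533

D   <- as.matrix(dist(t(E$scores)))
ref <- silhouette_refine(D, res$per_k[["5"]]$labels)
round(ref$report$overall_mean, 3)
#> [1] 0.258
adjusted_rand_index(ref$labels, co$labels)
#> [1] 1

# train the 6-unit subtype classifier on two markers per subtype
hub <- co$expression[sapply(co$markers, `[`, 1:2), ]
m   <- train_classifier(hub, ref$labels, seed = 1)
round(m$holdout$accuracy, 3)
#> [1] 0.867
```

Reading the output: k = 5 is the largest solution whose least-stable cluster
still has mean consensus ≥ 0.85 (0.938) before the CDF gain collapses (2.6%
at k = 6); the refined labels reproduce the planted subtypes exactly
(ARI = 1), and a 10-gene classifier recovers them on a held-out 20% split
with 0.867 accuracy at this separation (it passes 0.9 at 3 SD).

The same stages are available from the shell via the thin CLI at
`inst/cli/pathsubtype` (subcommands `simulate`, `enrich`, `dedup`,
`cluster`, `signatures`, `hubs`, `screen`, `survive`, `train`, `predict`,
`drugs`); every subcommand is seed-deterministic and reruns byte-identically.

## Scope notes

The package consumes precomputed cell-type score matrices for
immunophenotyping (deconvolution itself is out of scope), treats reference
signature catalogues and drug-response tables as inputs in their standard
text layouts (COSMIC-style 96-row TSV; GDSC-style CSV), and does not attempt
trajectory inference, ORA/GSEA enrichment of gene lists, or proteomic
validation. See `vignettes/pathway-subtyping.Rmd` for the models,
parameter defaults and design decisions, and for what the synthetic tests
do and do not establish about real data.
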