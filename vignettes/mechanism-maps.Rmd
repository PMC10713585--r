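---
title: "Generating inter-organ mechanism maps from multi-modal disease omics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating inter-organ mechanism maps from multi-modal disease omics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossorgan)
```

`crossorgan` chains seven components — synthetic-data generation,
multi-modal topic modeling, organ/cell enrichment, negative-binomial
differential expression, ligand–receptor bridging, KGML pathway mining,
and map assembly — into a pipeline that proposes an inter-organ disease
mechanism. This vignette is the package's methodological account: the
models, the parameters that matter, the numerical choices, and what the
synthetic data can and cannot tell you.

## The multi-modal topic model

Diseases are documents; gene symbols are words; the three disease-omics
modalities (altered expression `Ae`, biomarker `Bm`, genetic variation
`Gv`) are separate vocabularies. The model is a multi-field LDA: one
Dirichlet-distributed topic mixture `theta[d]` *shared by all modalities
of a disease*, and an independent topic–gene distribution `phi[k, m]` per
topic and modality. Sharing `theta` across modalities is the modeling
commitment that makes imputation possible: the topics inferred from a
disease's biomarkers and variants parameterize the distribution of its
unseen expression genes. This is the minimal model consistent with a
"multi-modal generative" design; richer couplings (per-modality topic
mixtures with a shared prior, correlated topics) would also fit that
description but add parameters the desk-scale corpus cannot constrain.

Inference is collapsed Gibbs sampling, implemented in C++ (Rcpp). The
sampler draws from

    P(z = k) ~ (n_dk + alpha) * (n_mkw + beta_m) / (n_mk + beta_m * V_m)

and reports `theta` and `phi` as means over post-burn-in sweeps. All
randomness flows through R's RNG, so `set.seed()` makes fits, fold-ins,
and the whole pipeline reproducible. Functions also accept `seed = NULL`
to continue the current RNG stream, which is how `evaluate_auc()` keeps
one deterministic stream across many fold-ins.

Defaults: `alpha = 1/K`, `beta = 0.01`, `n_iter = 500`, `burn_in = 250`
(standard LDA practice; fold-ins use half). On synthetic corpora `K` is
set to the number of planted topics; on real data `K` would be a model
selection problem that this package deliberately does not solve (no
hyperparameter optimization is attempted).

### Imputation and its evaluation

A query disease lacking modality `m*` is folded in: Gibbs over the query
tokens only, `phi` frozen. Every gene of the missing vocabulary is scored
as `sum_k theta_q[k] * phi[k, m*][g]`; the scores sum to one. Evaluation
deletes one modality of a held-out disease (all evaluation diseases are
excluded from the training fit), imputes it, and computes the rank
(Mann–Whitney) AUC of the scores against membership of the deleted set;
per-modality macro-averages are reported.

Two nulls calibrate this number. An oracle scorer gives AUC 1; random
scores give 0.5. The package's stronger null permutes, independently per
modality, which disease each gene set belongs to
(`permute_corpus_modalities()`): marginals are preserved but the
cross-modality association the model exploits is destroyed. A subtlety
worth knowing: this null is *slightly below* 0.5 on sharply planted
corpora, not centred on it. The fold-in still infers some topic from the
(now unrelated) observed modalities and inflates the scores of that
topic's genes — which are almost all negatives after permutation — so
the null AUC is depressed by a few hundredths. Individual
(seed, modality) values scatter roughly ±0.05 around that mean at the
evaluation sizes used here; averaged over the three-seed experiment the
null sits within 0.05 of 0.5 while the planted corpora stay above 0.8.

### Latent features and relatedness

Imputed genes become latent disease features after three filters: keep
the `top_fraction` of the ranking (default 0.01 of the vocabulary; the
pipeline uses 0.05 on its small synthetic vocabularies — the original
analysis' cutoff is not a portable constant and is treated as a user
parameter); drop genes already present in any of the query's own
modality sets; and drop features whose *entire* source-disease set is
name-excluded. Name exclusion is case-insensitive substring matching on
the disease name, with the respiratory fragments
(`r paste(DEFAULT_EXCLUSION_PATTERNS, collapse = ", ")`) as defaults;
`Respir` and `Pneumo` act as prefix wildcards. The "entire set" rule is
the conservative reading of removing features derived from obviously
related diseases: evidence from even one retained disease keeps the
feature, with the excluded diseases struck from its source set. The
alternative (drop on *any* excluded source) would also be defensible but
discards more; the choice matters only for features with mixed sources,
and the retained source sets — not the dropped ones — feed the
relatedness counts, so totals stay conserved either way.

Disease relatedness is then direct counting: for each corpus disease,
the number of latent features listing it among their retained sources,
sorted descending (ties by name); a display filter `count > 20`
reproduces the published figure's rule.

## Enrichment

Organ and cell-type enrichment uses, per context, the 2×2 table of
feature membership × context annotation over the annotation background,
Pearson's chi-square *without* continuity correction, and BH adjustment
across contexts of the same kind. BH was chosen for the q-values because
it is the minimal standard procedure when no method is named; Storey's
q-value would differ only in power, not ordering. The test is two-sided
as stated; direction is reported via the odds ratio. Degenerate contexts
(zero margin) are defined as `chi2 = 0, p = 1` rather than `NaN`. Genes
outside the background are dropped with a warning rather than silently
shrinking the universe.

## Differential expression

The DE stage is a deliberately simplified DESeq2-style test, not a call
to DESeq2: per-gene NB GLM with log link and size-factor offsets,
method-of-moments dispersion floored at `1e-8` (group means floored at
`1e-6`, mirroring a minimal-mean safeguard), no dispersion shrinkage
trend, no independent filtering, no outlier replacement. The original
analysis also disabled outlier replacement; shrinkage and filtering are
power optimizations that matter at the margins of real cohorts but
would make the desk-scale behavior harder to reason about. The GLM
itself is fitted by `stats::glm` with a fixed-theta
`MASS::negative.binomial` family — established machinery; only the
testing logic above it is bespoke. One numerical point: Wald standard
errors come from `summary.glm(fit, dispersion = 1)`, because the default
`vcov.glm` rescales by the Pearson dispersion estimate, which collapses
to zero for zero-residual (constant-count) genes and would fabricate
significance; a fixed-dispersion NB model has scale 1.

Bulk mode tests the group coefficient by Wald with a normal reference.
Single-cell mode uses the likelihood-ratio statistic referred, as a
signed square root, to a t distribution with `n - 2` degrees of freedom
— a t-reference echo of the `useT`-style small-sample correction; the
LRT is also what keeps power in the separated case (a gene with all-zero
counts in one condition), where Wald statistics degenerate. DEgenes are
`|log2FC| >= 1` and `padj < 0.05`. Group labels are canonicalised
internally (sorted levels, sign flipped to the requested contrast), so
swapping the contrast negates every fold change *exactly*.

Size factors: bulk uses median-of-ratios against the geometric-mean
pseudo-reference (library-size fallback with a warning when no gene is
expressed everywhere); single-cell uses a pooled estimate — pool
pseudo-bulks normalized by median-of-ratios, cells scaling their pool's
factor by relative library size — as a light-weight stand-in for
deconvolution-based sum factors. Factors are rescaled to geometric mean
one, which is the contract downstream code relies on. Cells as
replicates is assumed throughout the single-cell contrasts.

Expression localization summarizes each (gene, cell type) as the
fraction of expressing cells and the mean of `log(1 + count per 10,000)`
(natural log), the conventional dot-plot quantities.

## Bridging, mining, and the map

Ligand–receptor bridging is set intersection with one asymmetric rule: a
multi-subunit complex joins the DEgene list if *any* subunit is a
DEgene (the published tables list IL6R/IL6ST as the receptor for the
DEgene ligand IL6, which forces the any-subunit reading), but counts as
expressed in the partner organ only if *all* subunits pass the
expression threshold (`min_frac = 0.1` of cells in at least one cell
type) — a functional complex is required for cross-organ signaling.
Matching is exact and case-sensitive after whitespace trimming.

KGML files parse into directed entry-level graphs: nodes are `entry`
tags (a single entry may carry several gene symbols, as KEGG does for
the calmodulins), edges run `entry1 -> entry2` for each `relation`.
Group entries are expanded — each edge touching a group is replicated to
its components — and non-gene entries (compounds) remain traversable
intermediates. Relation subtypes (activation vs. inhibition) are
ignored: the positioning rule is pure directed connectivity with no
path-length cap. Anchoring is per receptor subunit present in the
pathway (hence a two-subunit receptor contributes one row per subunit
found, and a subunit absent from the file contributes none); when no
receptor subunit is present the ligand subunits anchor the search. A
feature that is itself a pair subunit never self-hits (paths must have
length ≥ 1).

Map assembly places the DEgene side of every surviving pair in the
primary organ and the partner side in the partner organ. Downstream
hits draw a `pathway` edge receptor → feature in the receptor's organ;
upstream hits draw feature → ligand in the *ligand's* organ — upstream
evidence describes signaling into the ligand, which lives with the
ligand, and this placement is what closes the published loop (the
calmodulin node sits in the lung between BDKRB1 and IL6). Features with
identical hit profiles collapse into one node. Finally, every feature
node with no outgoing edge gets an `unknown` ("?") edge to each map
ligand in its own organ — the open link of the loop — and never to
arbitrary genes. Nodes carry their top-3 cell types by mean log CP10K
as localization evidence.

## The synthetic data: what it emulates, and what it does not

The generators are first-class, seeded, and emit their planted truth:

* **Disease corpus** (`simulate_disease_corpus`): topics own disjoint
  per-modality gene pools (an overlap parameter exists but defaults to
  0 — disjoint pools make recovery tests sharp); each disease activates
  one or, with probability 0.3, two topics; tokens are drawn from the
  active pools or, with probability `noise_rate`, uniformly. Defaults
  (240 diseases, 6 topics, 300 genes per modality, mean set size 30,
  noise 0.1) are the study conditions for the imputation benchmark and
  were fixed once; they emulate the *structure* of a disease–gene
  association resource, not its scale (thousands of diseases) or its
  heavy-tailed gene-set sizes.
* **Counts** (`simulate_counts`): one NB draw per gene and column, with
  log-normal size factors, planted log2 fold changes (optionally
  cell-type-restricted) and, for cells, planted mitochondrial-fraction
  outliers for QC tests. The bulk default emulates the cohort contrast
  (95 vs 204 subjects). There is no zero inflation beyond the NB, no
  batch structure, no gene–gene correlation, and no ambient RNA — so
  passing tests demonstrate the *statistics* behave as specified, not
  that the pipeline is robust to every artifact of real sequencing.
* **Tables and pathways** (`build_table_fixtures`): the
  ligand–receptor table contains every published lung pair plus 20
  decoys whose members never occur in the DEgene list; the KGML files
  are synthetic topologies (labelled as such) that realize exactly the
  published receptor→feature positions, plus a decoy pathway and a
  group-entry dialect demo; gene lists carry the 21 real symbols that
  matter and clearly-synthetic filler (`IPFDEG###`, `LATF###`) up to
  the published scales of 112 DEgenes and 83 latent features.

The corpus world (synthetic vocabularies) and the expression world (real
gene symbols) are deliberately separate vocabularies; the fixture latent
features play the role of the imputed features in the downstream stages.

## Problem sizes and runtime

The shipped configuration is desk-scale by design: the imputation
benchmark fits 240-disease corpora (three seeds) in seconds thanks to
the C++ sampler; the end-to-end pipeline (800-gene, 299-sample bulk
matrix; five single-cell matrices of 150–420 cells; seven pathway
files) runs in about ten seconds and is byte-identical across runs at a
fixed seed. The full test suite runs in under two minutes.

## Known limitations

* The topic model's structure (shared `theta`, independent `phi_m`) is
  one defensible reading of "multi-modal generative topic modeling";
  alternatives with per-modality topic weights are not implemented.
* The score threshold separating "generated" from "latent" features is
  a free parameter; no attempt is made to reproduce a particular
  feature count from real resources.
* Reachability-based positioning ignores edge signs, so an inhibitory
  chain counts as a connection; sign-aware mining would need a
  different hit definition.
* Whether ligand–receptor and pathway steps act within one cell type or
  in trans across cell types within an organ is not asserted: the map
  stores cell-type evidence per node and deliberately makes no
  same-cell claim.
* Cells are treated as replicates in single-cell contrasts;
  patient-level pseudo-replication is not modeled.
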