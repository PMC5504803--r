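---
title: "Methods and design of the specdep pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the specdep pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specdep)
```

# Scope

`specdep` implements a comparative proteomic analysis for a paired
malignant / non-malignant epithelial cell-line model quantified by spectral
counting, together with the downstream questions such a comparison raises:
which protein classes are overrepresented among the differentially
expressed proteins (DEPs), which gene sets associate with each phenotype,
which signed signaling pathways are coherently perturbed, and whether the
same genes separate patient tumors by race once race-specific non-malignant
baselines are removed. A synthetic-data module generates every input the
pipeline consumes, so all of it is exercisable and testable offline.

# Ingestion and count processing

Spectral counts are semi-quantitative: the number of peptide-spectrum
matches assigned to a protein. Raw tables may contain fractional values
(from shared-peptide apportioning upstream) and several isoform rows per
gene.

Processing applies two rules:

* **Isoform consolidation.** Rows sharing a gene symbol are summed
  column-wise into one row per gene; rows without a symbol pass through.
  A symbol mapping to two distinct gene identifiers is an error rather
  than a silent merge. Consolidation conserves each sample's total count
  exactly.
* **Integerization.** Every count is replaced by its ceiling ("rounded up
  to the nearest whole integer"), so integer counts and zeros are fixed
  points and the operation is idempotent.

The default order is consolidate-then-ceiling. The order matters because
the ceiling of a sum is not the sum of ceilings; the alternative order is
one flag away (`process_spectral_counts(x, integerize_first = TRUE)`) for
sensitivity analysis.

# Differential expression

Each gene is tested with the unpaired two-sided Wilcoxon rank-sum test
with continuity correction, treating all nine runs per line (3 biological
x 3 technical replicates) as samples. This unit-of-replication choice is
deliberate: the smallest attainable two-sided exact p-value for 3-vs-3 is
0.1, so per-protein p-values in the 10^-4 range are only reachable when
technical replicates enter the test. The conservative alternative —
averaging technical into biological replicates — is available via
`collapse_technical = TRUE`. The test uses the exact null for small untied
samples and the tie-corrected normal approximation otherwise (spectral
counts tie frequently); a sample in which every value is identical carries
no rank information and is assigned p = 1.

P-values are adjusted by Benjamini-Hochberg; DEPs are genes with
q < `alpha`, default 0.1 (90% confidence). Fold changes are
`log2(mean_T / mean_N)`; when either mean is zero, one is added to both
means before the ratio, so fold changes stay finite and the rule fires
only where needed. DEPs whose counts are entirely absent from one line are
labelled `malignant_only` / `non_malignant_only`; other DEPs are
`upregulated` / `downregulated` by fold-change sign. Detection ("total
count > 0 in a line") also drives the shared / one-line-only partition
reported alongside the records, and MA-plot and fold-change scatter tables
are emitted as data artifacts.

# Overrepresentation analysis

Categories (protein classes, ontology terms, pathway memberships) are flat
gene sets with a declared background size N. The test is the one-sided
hypergeometric upper tail P(X >= k) for k observed members among n listed
genes with class size K — equivalently Fisher's exact test with
alternative "greater" — followed by Benjamini-Hochberg across categories.
For projected databases the declared K wins over the membership count.

The **resampling validation** repeats the entire ORA on random gene
subsets of the same size as the DEP list, drawn uniformly without
replacement from a reference pool (the non-DEPs, or all identified
proteins), and counts per category how often it is significant at a
per-subset BH threshold (default q < 0.05, exposed as `alpha`; the
original analysis did not state its threshold). The complement of that
frequency, `empirical_confidence()`, is the percent confidence that the
real list's enrichment is not a size artifact: 2 significant subsets in
1000 gives 99.8%. One RNG stream per validation run; results are
bit-reproducible from the seed.

# Gene set enrichment

The enrichment engine is written from first principles:

* **Ranking.** Genes are scored by signal-to-noise
  `(mu_T - mu_N) / (sd_T + sd_N)` with the conventional floor
  `sd >= 0.2 |mu|` (and 0.2 when the mean is zero), or by difference of
  means for tiny samples. Ties break lexicographically by gene so results
  are deterministic.
* **Running sum.** Walking the ranked list, set members add
  `|score|^p / sum |score|^p` (default weight exponent p = 1) and
  non-members subtract `1/(L - G)`. The enrichment score (ES) is the
  signed extremum of the walk; on an exact tie between the positive and
  negative extremes the positive one is taken. The leading edge is the
  members at or before (positive ES) or at and after (negative ES) the
  extremum.
* **Null, NES, FDR.** The default null permutes gene sets (random
  equal-size sets), because with three biological replicates per class
  phenotype permutation has too few distinct relabelings; phenotype
  permutation remains available. NES divides ES by the mean same-signed
  null ES; nominal p is the same-signed null tail with a +1 correction so
  p stays in (0, 1]; FDR uses the pooled same-sign null-NES ratio
  estimator, capped at 1. Sets are size-filtered on their overlap with
  the data (default 5-500 inclusive).

Positive scores mean association with the malignant phenotype.

# Pathway impact analysis

Pathways are signed directed graphs: `beta[i, j]` is the influence of gene
j on gene i (+1 activation/expression, -1 inhibition/repression, 0
binding/association by default; the type-to-weight map is overridable).
Three probabilities are combined:

* **Overrepresentation** `p_nde`: hypergeometric upper tail of the number
  of DE genes on the pathway, conditioned on measured genes (the
  background is the number of identifier-mapped genes in the data, not
  the genome).
* **Perturbation** `p_pert`: perturbation factors solve
  `PF = dE + B PF` with `B[i, j] = beta[i, j] / N_ds(j)` where `N_ds` is
  the downstream-target count; the net accumulation is
  `t_a = sum(PF - dE)`. Because `t_a` is linear in `dE`
  (`t_a = (colSums((I - B)^-1) - 1) . dE`), the bootstrap — reassigning
  the observed changes to random pathway positions — is a cheap dot
  product. The null is median-centred and the p-value is the doubled
  one-sided tail in the observed direction with a `(count+1)/(n_boot+1)`
  correction: an observation at the null median gives p near 1, and p is
  never 0. A singular system matrix is damped (`beta` scaled by 0.99,
  iterated and logged) before giving up.
* **Combination** `p_g = c - c ln c`, `c = p_nde * p_pert`: the
  probability that a product of two independent uniforms is at most `c`.

`p_g` is BH-adjusted across analyzed pathways; direction is called from
the sign of `t_a` (negative = inhibited). Pathways containing no DE gene
are skipped: they contribute no perturbation evidence.

# Cohort comparison

Clinical filtering keeps Gleason <= 7 tumors (inclusive). Cross-race pairs
are formed greedily — within each Gleason stratum, nearest-age first, each
specimen used once, subject to an age tolerance — which is this package's
own operationalization of "age- and stage-matched"; the original cohort's
pairing rule is not recoverable, and "stage" is operationalized as the
Gleason group. Per-gene race comparisons use the Welch t-test (the default
of the standard `t.test`), with a pooled-variance option; no multiple
testing correction is applied across the handful of genes tested by
default (`bh = TRUE` adds it).

The race-specific normalization subtracts, per gene, the mean expression
of same-race non-malignant specimens from each tumor specimen. It is exact
arithmetic (location-invariant within race), and a negative normalized
value reads "below the race-matched normal mean". This is what lets a
tumor-specific shift emerge when a race main effect masks it in the direct
tumor-vs-tumor comparison.

# Synthetic data

The generators define the study conditions the tests run under:

* **Counts** (`simulate_spectral_counts`): negative binomial
  (dispersion 0.15) around log-normal gene baselines (median ~6 counts,
  matching shallow spectral counting), 3 biological x 3 technical
  replicates per line, with a shared log-normal biological-replicate
  effect (sd 0.15) creating the nested correlation the 9-vs-9 testing
  decision must tolerate. Defaults: 833 genes, 7.6% planted DEPs at
  |log2 fc| = 2, 73% up, 32% of planted genes zeroed in their low line —
  the proportions of the cell-line dataset this pipeline was built
  around.
* **Annotations** (`simulate_annotation_db`): random categories with the
  declared class sizes of a 20,814-gene reference proteome
  (`default_class_sizes`), non-disjoint, with optional planted overlap.
* **Topologies** (`simulate_pathway_topology`): random signed digraphs
  with a guaranteed activating cascade.
* **Cohorts** (`simulate_cohort`): Gaussian expression with additive
  race, disease and race-by-disease terms; default sizes 12 tumors per
  race and 4 + 30 non-malignant specimens, mirroring a Gleason-filtered
  tumor/normal extract. The reversal demonstration plants a race main
  effect of -2 cancelled by a +2 interaction on a unit-noise scale,
  chosen so the direct comparison is near-null while the post-subtraction
  comparison has high power at these group sizes.

What the generators do **not** emulate: peptide-level structure, shared
peptides, abundance-dependent dropout (dropout is planted per line, not
stochastic), correlated annotation categories, real pathway topologies,
and non-Gaussian cohort expression. Passing tests therefore demonstrate
the pipeline's statistical behaviour under its stated assumptions, not
performance on any particular real dataset.

# Numerical conventions and test scale

Degenerate inputs are decided, not left to chance: all-tied rank-sum
samples give p = 1; flat cohort groups with equal means give p = 1; a
zero mean triggers the +1 fold-change rule only then; ES ties go
positive; `combine_global(1, 1) = 1` by continuity. All randomized
components (resampling, permutation, bootstrap, generators) are pure
functions of their parameters and a seed.

The test suite verifies the statistical kernels against independent
oracles (exhaustive rank-assignment enumeration, hand step-up BH, subset
enumeration for the hypergeometric tail, a brute-force running-sum walk,
and the closed-form Welch statistic) and calibrates error rates by
simulation at deliberately modest problem sizes — 200-gene null matrices
across 200 replicates for FDR control, 500 pathway simulations for the
uniformity of the global probability, 150 random sets for permutation-p
calibration — sizes at which Monte-Carlo error bands are tight enough to
be meaningful while the whole suite stays fast.

# Known limitations

* The overrepresentation test conditions on a declared background; it
  does not reproduce any specific annotation service's internal
  projection, so printed p-values from such services are not comparable
  number-for-number.
* Gene-set permutation tends to anti-conservatism relative to phenotype
  permutation when genes are strongly correlated; with three biological
  replicates per class there is no better-calibrated alternative at this
  design size.
* The count model is not moderated: no information sharing across genes,
  by design — the pipeline reproduces a rank-test-based analysis, not a
  negative-binomial regression framework.
* Greedy age matching is not guaranteed optimal for arbitrary age
  distributions (it is optimal in the small strata exercised in the
  tests).
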