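---
title: "Cluster-aware diagnostics for methylation batch correction"
author: "methylvr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster-aware diagnostics for methylation batch correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylvr)
```

# The model and its assumptions

Infinium-style methylation arrays report, per CpG probe and sample, a
methylated fraction β ∈ [0, 1] (or the underlying methylated/unmethylated
signals). Slides of 8–12 arrays are processed together and behave as
batches; same-day runs of several slides form superbatches. Batch
correctors remove per-batch structure from the data while preserving
*declared* sample-level covariates. The failure mode this package
diagnoses is feature-level biology — multi-modal β caused by a genotype at
the probed CpG (allele-specific methylation, ASM), gender, or cell
composition — which cannot be declared per sample and per probe, and which
a corrector will erase whenever the clusters are unbalanced across
batches.

Three assumptions underpin the workflow:

* **Correction belongs on the M scale.** β is bounded; corrected β is not
  guaranteed to stay in [0, 1]. All correction is done on
  M = log2(β/(1−β)) and inverted afterwards, so extreme corrected values
  saturate smoothly towards 0/1.
* **Clusters are found before correction.** The diagnostic must detect
  *destroyed* clustering, so cluster assignments are frozen from the
  pre-correction data and reused when scoring the corrected data.
  Re-clustering the corrected data would hide exactly the damage we are
  looking for.
* **Cluster-aware variance separates the two phenomena.** With
  assignments fixed, the pooled within-cluster variance
  s² = Σ_c Σ_{i∈c} (x_i − x̄_c)²/(n−1) falls when technical spread inside
  clusters is removed (intended correction) and rises when cluster
  centres are dragged together unevenly (erroneous correction), even
  though the *ordinary* SD falls in both cases. The log-variance ratio
  LVR = log2(s²_post/s²_pre) is therefore signed: ≤ −log2(1.5) with a
  mean |Δβ| ≥ 0.01 flags batch-effect susceptibility, ≥ log2(1.5) with
  the same shift gate flags erroneous correction.

The LVR orientation deserves a note: the convention adopted here is
post-over-pre, which is the only orientation under which "LVR > 0 means
variance was inflated by correction" and the ±log2(1.5) cut-off semantics
are coherent; the statistic is antisymmetric under swapping pre and post.

# Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `eps` (`shiftBetas`) | 1e-4 | β | boundary substitution for exact 0/1; small against the 0.01 shift gate yet keeps \|M\| < 14 |
| `noise_sd` (`shiftBetas`) | 1e-8 | β | noise injected into zero-variance probes only, so the EB corrector's standardization is defined; far below any biological signal |
| `offset` (`signalsToBeta`) | 0 | signal | the plain ratio; set 100 for parity with pipelines that damp low-intensity probes |
| `kmax` | 4 | clusters | larger optima are recoded to 4 |
| `min_cluster_size` | 5 | samples | a modal component below this is indistinguishable from outliers |
| `min_centroid_sep` | 0.1 | β | 10% methylation between adjacent centroids |
| `lvr_cut` | log2(1.5) ≈ 0.585 | — | a 50% variance change |
| `shift_cut` | 0.01 | β | screens out large ratios caused by near-zero pre-variance (fully (un)methylated probes) |
| `alpha` (attribution) | 0.001 | FDR-adjusted p | stringent cut for factor attribution |
| EB `conv`, `max_iter` | 1e-4, 100 | — | relative change of posterior γ*, δ²* between iterations |
| BIC `var_floor` | 1e-6 | β² | keeps degenerate tight clusters scorable |

# Cluster-number selection

For each probe, `ckmeans1d()` computes the globally optimal k-means
partition for k = 1..4 by dynamic programming over the sorted values
(optimal univariate clusters are contiguous intervals of the sorted
data). Candidates are scored by a Gaussian-mixture BIC (cluster-wise
means, ML variances floored at `var_floor`, mixing proportions; 3k − 1
parameters; larger is better). The two best candidates are checked
against the size and separation rules; the largest qualifying k wins,
k = 1 qualifying always. BIC ties break towards smaller k. Two
consequences are worth knowing:

* When the top two candidates are, say, {3, 4} and both fail the rules,
  selection falls back to k = 1 rather than silently trying k = 2 — the
  protocol only re-examines the two best-scoring candidates.
* The ≥ 5-sample rule places a hard floor on detectable minor clusters.
  For an ASM probe at minor allele frequency q in n samples, the minor
  homozygote cluster is Binomial(n, q²): with n = 96 and q = 0.3 about 6%
  of such probes draw fewer than 5 minor homozygotes and are structurally
  unrecoverable at k = 3. Recovery rates on the default synthetic study
  sit at this ceiling (~94% in expectation), which is a property of the
  acceptance rules at desk-scale n, not of the optimiser.

The two-stage protocol (`clusterProbes(..., excluded_slides = )`) selects
k with the most batch-affected slides set aside — technical shifts can
otherwise manufacture clusters — and then re-clusters all samples at the
fixed k. The exclusion list is caller-supplied, typically after PCA
review (`pcaOverview()`, which drops chrX/Y probes when annotation is
available and centres probes without scaling).

# The correctors

`fitCorrection()`/`applyCorrection()` implement a parametric
empirical-Bayes location/scale corrector: per-probe standardization by
the covariate fit (intercept + declared covariates; categorical as
factors, continuous linear — with an optional documented dichotomization,
e.g. `dichotomize = c(cell_fraction = 0.06)`) and the pooled residual SD;
per-batch location/scale estimates shrunk toward method-of-moments
normal / inverse-gamma priors; posterior estimates iterated to `conv`.
The reference distribution is the covariate-adjusted grand mean — there
is no reference batch, and the nonparametric prior variant is out of
scope. `mean_center` subtracts per-batch means of covariate-fit residuals
and is exact (batch residual means are zero to machine precision, and the
operation is idempotent). A single-batch fit applies as the identity.
Confounded designs (batch nested in a covariate) and zero-variance probes
are rejected with explicit diagnostics. Sequential correction over
several batch variables (e.g. superbatch then slide) is available via
`correctBatch(batch_var = c("superbatch", "slide"))` but single-variable
slide correction is the default workflow.

# Attribution tests

Modal probes are tested per factor: Fisher exact for gender/slide/
superbatch on the cluster × factor table, switching to a seeded
Monte-Carlo χ² (p = (1 + #{χ²* ≥ χ²})/(B + 1), B = 10,000 by default)
when the table exceeds 30 cells; one-way ANOVA for the continuous cell
fraction; and a Levene–Haldane exact Hardy–Weinberg test on the cluster
sizes of autosomal probes with 2–3 clusters. Cluster sizes in ascending
centroid order stand in for genotype counts; with two clusters, the
larger maps to the common homozygote and the smaller to the heterozygote,
the minor homozygote count set to 0 — under which a rare-allele-like
pattern such as 81/18 is (correctly) HWE-consistent. p values are
BH-adjusted within factor across probes; HWE *consistency* is
non-rejection at the adjusted 0.001 level, so probes may carry several
factor flags, and unflagged probes are reported as unknown.

# What the generator emulates — and what it does not

`simulateStudy()` builds studies on the M scale: per-probe base level +
archetype effect + per-slide shift (susceptible probes, SD
`batch_sd_m` = 0.5 M) + a centred per-row position trend
(`position_slope_m` = 0.02 M/row, echoing the reduced intensity of early
slide rows) + Gaussian noise (`noise_sd_m` = 0.15 M), then inverts to β.
The default desk-scale study is 8 slides × 12 arrays (96 samples), two
superbatches, and 2,000 probes: 1,400 clean, 200 batch-susceptible, 150
ASM-trimodal (HWE genotypes at maf 0.3 mapped to β centroids
0.1/0.5/0.9, mimicking a C→T SNP), 100 gender-bimodal (males at β 0.7,
females 0.3), 100 cell-gradient and 50 constant near-boundary probes
(exercising the zero-variance path). The cell fraction is a low/high
mixture (80% near 0.03, 20% near 0.30) reflecting saliva-like immune
admixture; the high component is kept tight (SD 0.02) so the archetype is
genuinely bimodal. In unbalanced mode (the default) minor-allele carriers
are concentrated into the leading slides — the configuration under which
undeclared ASM clustering is erroneously corrected — while gender is only
mildly skewed so that the correction design remains full rank.

Deliberately *not* emulated: probe-type (Infinium I/II) intensity
chemistry, dye bias and background, detection p-values, spatial
within-array artefacts, correlated neighbouring CpGs, and population
structure beyond the single-SNP HWE model. Passing recovery tests on this
generator therefore demonstrates that the statistics respond to the
structures they target, not that any particular real cohort is free of
further complications.

# Numerical choices and degenerate inputs

* `mToBeta()` uses the stable logistic CDF, so |M| up to ±1000 maps into
  [0, 1] without overflow or NaN.
* Boundary-constant probes can have exactly zero pre-correction
  cluster-aware variance even after noise injection is clipped; their LVR
  is reported as missing and they are never classified or dropped
  silently.
* The moderate adjustment group is the closed interval [0.01, 0.10] β of
  the maximal probe-wise β difference, with low strictly below and high
  strictly above; classification comparisons at the LVR/shift cut-offs
  are non-strict.
* The mean β shift uses |Δβ| (a signed mean would cancel opposing batch
  moves and defeat the gate); `signed = TRUE` is available for
  sensitivity analysis.
* Noise injection for zero-variance probes happens on the β scale after
  the missing/boundary substitutions; the exported matrices round LVR and
  shift to 4 decimal places, while summaries keep full precision.

# Scope of the interfaces

The exported functions, this vignette and `scripts/acceptance.R` are the
package's interface; the workflow surfaces (simulate / cluster / correct
/ diagnose / attribute / consensus) are plain R calls designed to be
scripted, and no shell wrapper is shipped.

# Problem sizes used by the test-suite

The suite validates the exact algorithms against enumeration oracles
(contiguous-partition search for n ≤ 12, k ≤ 4; all Hardy–Weinberg tables
with n ≤ 50; 100 random 2×2 Fisher tables), calibrates the null tests on
1,000 replicates, and runs the full pipeline on the default 2,000 × 96
study — sizes chosen so the whole suite completes in a few minutes on one
core while keeping every recovery estimate's Monte-Carlo error well below
the margins being asserted.

# Known limitations

* Real-world exclusion lists for clustering stage 1 must come from the
  analyst (e.g. PCA review); the package does not choose them.
* The Hardy–Weinberg test is applied to cluster sizes, not re-thresholded
  genotype calls; heavily overlapping clusters blur the mapping.
* Continuous covariates enter the correction design linearly; strongly
  non-linear cell-composition effects are only partially preserved.
* The consensus machinery assumes a shared probe universe; probes missing
  from any dataset are dropped from the intersection.
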