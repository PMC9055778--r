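# methylvr

Probe-wise, cluster-aware diagnostics for batch-effect correction of
Infinium-style DNA methylation arrays (450K/EPIC-like probe × sample β
matrices).

## The problem

Batch correctors (ComBat-style empirical-Bayes adjustment, per-batch mean
centering) operate per *sample*: biological variance can be declared to
them only as sample-level covariates. Methylation data, however, carry
*feature-level* biological structure — allele-specific methylation (ASM)
driven by a SNP at the probed CpG, gender-linked bimodality, metastable
epialleles — which shows up as multi-modal β distributions across
individuals. When such clustering is unbalanced across slides, a corrector
mistakes it for technical variance and converges the batch means,
destroying the biology. Conversely, genuinely batch-prone probes need
substantial correction. Both sets should be known to an EWAS analyst
before trusting corrected data.

`methylvr` implements a post hoc audit that distinguishes the two:

1. **Modal clustering.** Each probe's β values are partitioned by exact
   optimal univariate k-means (dynamic programming over the sorted data),
   with k ∈ {1..4} selected by BIC subject to the acceptance rules: every
   cluster ≥ 5 samples, adjacent centroids ≥ 0.1 β apart. A two-stage
   protocol first selects k with the worst slides set aside, then
   re-clusters all samples at that k.
2. **Correction on the M scale.** β is mapped to M = log2(β/(1−β)),
   corrected by a parametric empirical-Bayes location/scale model (batch
   locations γ and scales δ² shrunk toward normal / inverse-gamma priors)
   or by plain mean centering, with declared covariates (gender, cell
   fraction) preserved, then mapped back.
3. **Cluster-aware variance and the LVR.** With pre-correction
   assignments fixed, the cluster-aware variance is
   s² = Σ_clusters Σ_members (x − x̄_cluster)² / (n − 1),
   and the log-variance ratio is **LVR = log2(s²_post / s²_pre)**.
   Combined with the mean β shift (mean |β_post − β_pre|):
   * LVR ≥ log2(1.5) ≈ 0.585 and shift ≥ 0.01 → **erroneously corrected**;
   * LVR ≤ −log2(1.5) and shift ≥ 0.01 → **batch-effect susceptible**.
4. **Attribution.** Modal probes are tested against gender, slide,
   superbatch (Fisher exact / Monte-Carlo χ²), cell composition (one-way
   ANOVA) and Hardy–Weinberg equilibrium of the cluster sizes
   (Levene–Haldane exact test), each BH-FDR-moderated at p < 0.001.

A synthetic Infinium-like study generator (`simulateStudy()`) emits all of
these structures with ground truth, so the whole workflow is testable end
to end.

## Worked example

```r
library(methylvr)

se  <- simulateStudy(studyConfig(seed = 1))   # 2,000 probes x 96 samples
res <- runPipeline(se = se, seed = 1)

table(res$diagnostics$classification)
#> erroneously_corrected     batch_susceptible          unclassified
#>                   143                   200                  1657

res$clusters
#> ProbeClusters: 2000 probes x 96 samples
#> k
#>    1    2    3    4
#> 1542  295  162    1

head(subset(res$diagnostics, classification == "erroneously_corrected",
            c(probe_id, k, lvr, mean_beta_shift, sd_pre, sd_post)), 3)
#>      probe_id k  lvr mean_beta_shift sd_pre sd_post
#> 1601 cg001601 3 3.55           0.209  0.265  0.0643
#> 1602 cg001602 3 3.15           0.210  0.265  0.0659
#> 1603 cg001603 3 2.69           0.199  0.241  0.0704
```

The three example probes are simulated ASM probes (trimodal at β ≈
0.1/0.5/0.9) whose genotypes were concentrated into a few slides: the
corrector collapsed the clusters, so the overall SD *fell* (0.27 → 0.06)
while the cluster-aware variance — hence the LVR — rose far above the
log2(1.5) cut-off, with a mean β shift of ~0.2. Truly batch-prone probes
show the mirror image (LVR ≈ −1, SD reduced, shift above 0.01), and the
clean majority sits at LVR ≈ 0, unclassified. `res$attribution` carries
the per-factor attribution of every modal probe
(`attr(res$attribution, "intersections")` gives the upset-style tally),
and `runPipeline(..., outdir = )` exports the 4-dp reference matrix,
attribution table and summary JSON.

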