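---
title: "Methods: from resting-state amplitude maps to gene expression associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from resting-state amplitude maps to gene expression associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurotx)
```

# The analysis chain

`neurotx` implements an imaging-transcriptomics pipeline of the kind used
to relate case–control brain differences to spatial gene expression:

1. **ALFF** — per subject, the amplitude of low-frequency fluctuations is
   computed voxel-wise from 4D resting-state data and standardized.
2. **Group GLM** — a mass-univariate two-sample model with nuisance
   covariates (age, sex, education, BMI) yields a t-map per modality:
   ALFF for function, gray-matter volume (GMV) for structure.
3. **Cluster-level inference** — Gaussian-random-field (GRF) theory for
   the ALFF branch, Monte-Carlo cluster-extent simulation for the GMV
   branch; both are available for either input.
4. **Expression preprocessing** — donor-tagged probe-level samples are
   refined into a genes × features matrix in nine steps (reannotation,
   intensity filtering, probe selection, sample matching, missing data,
   sample and gene normalization, aggregation, stability filtering).
5. **Spatial association** — each gene's expression profile is Pearson-
   correlated with the t-values extracted at the matched features; genes
   pass if the Bonferroni-corrected p-value beats `alpha = 0.01` *and*
   `|r| > 0.2` (the dual criterion). Lists from the two modalities are
   intersected into "crossover" genes.
6. **Enrichment** — hypergeometric over-representation of the crossover
   list against user-supplied gene-set collections (GMT), with
   Benjamini–Hochberg control per category.
7. **Clinical statistics** — Mann–Whitney and Fisher tests for group
   comparisons; Spearman correlations (with FDR) between per-subject
   cluster summaries and clinical measures.

Because the cohort data and donor atlas such analyses run on are not
redistributable, every stage is exercised end to end on synthetic data
with known ground truth (see below), and the package is tested against
that truth.

# ALFF

For a voxel series \(x_t\) (length \(N\), repetition time `tr`), the
pipeline applies, in order: discarding initial volumes (config option,
default 0 here; clinical pipelines typically drop 10), least-squares
linear detrending, nuisance regression (ordinary least squares against
motion, tissue and optionally global-mean regressors), and an ideal
band-pass filter that zeroes DFT coefficients whose bin-centre frequency
lies outside \([0.01, 0.08]\) Hz (inclusive on both edges; membership is
decided by bin centre). The one-sided amplitude spectrum is
\(a_k = 2|X_k|/N\), and

\[\mathrm{ALFF} = \frac{1}{|B|}\sum_{k \in B} a_k,\qquad
  B = \{k : 0.01 \le k/(N\,\mathrm{tr}) \le 0.08\}.\]

Averaging (rather than summing) over in-band bins makes ALFF invariant
to series length for a fixed band. For a pure sinusoid of amplitude
\(A\) on an exact in-band bin, ALFF is exactly \(A/|B|\) — the closed
form the test suite checks to machine precision.

Two conventions are deliberate choices where the field varies:

* **Standardization** is mALFF: division by the in-mask mean, so the
  standardized map has in-mask mean 1. A z-score variant exists in the
  literature; mean-division is the dominant convention and is recorded
  in the map's metadata.
* **Global-signal regression** is exposed as a flag on
  [nuisance_set()], default on; whether to include the global mean is
  genuinely contested and pipelines differ.

Band-passing before the FFT and then averaging only in-band bins is
redundant but harmless; the stated processing order (filter, then
spectrum) is honored.

Smoothing uses a separable Gaussian (\(\sigma =
\mathrm{FWHM}/2\sqrt{2\ln 2}\) per axis, in mm) with mask-aware
renormalization: the smoothed value is the kernel-weighted average over
in-mask voxels only, so constants are preserved up to the mask edge and
a delta integrates to 1.

# Group inference

The design matrix is intercept + group (case = 1, so positive t means
case > control) + covariates; the voxel-wise statistic is
\(t = c^\top\hat\beta / \sqrt{\hat\sigma^2\, c^\top (X^\top X)^{-1} c}\)
with `dof = n - rank(X)`. With no covariates this reduces exactly to the
pooled-variance two-sample t.

An optional **one-sample masking** step first restricts analysis to
voxels where either group's standardized ALFF differs from 1 (two-sided
uncorrected `alpha = 0.05` by default — the threshold is not a settled
convention, so it is a config option).

**Smoothness** is estimated from the model residuals: each voxel's
residual vector is normalized to unit norm, and per axis

\[\mathrm{FWHM}_\mathrm{axis} = v_\mathrm{axis}
  \sqrt{4\ln 2 / r_\mathrm{axis}},\qquad
  r_\mathrm{axis} = \frac{\mathrm{var(first\ differences)}}
                         {\mathrm{var(residuals)}}.\]

For spatially independent noise this gives \(v\sqrt{2\ln 2}\) (≈ 1.18
voxels), the estimator's analytic floor. The formula uses the small-lag
expansion of a Gaussian autocorrelation, which overestimates mildly at
low smoothness (a 6 mm kernel on 3 mm voxels reads ≈ 6.5 mm); the
recovery tests use the band 5.1–6.9 mm.

**GRF cluster correction** thresholds each tail at `voxel_p / 2` and
tests each tail's clusters at `cluster_p / 2` (so the family-wise error
over increases and decreases together is `cluster_p`; this per-tail
split matches the convention of the widely used resting-state
toolboxes). The expected cluster count is the four-term expected Euler
characteristic over lattice resel counts (voxel/edge/face/cube counting
of the mask at the estimated per-axis FWHM), and cluster extent follows
the standard approximation \(P(n \ge k) = \exp(-\beta k^{2/3})\) with
\(\beta = (\Gamma(5/2)/E[n])^{2/3}\). Corrected
\(p = 1 - \exp(-E[m]\,P(n \ge k))\). Null simulations at the default
conditions measure a family-wise error of about 0.03–0.05 at nominal
0.05.

**Monte-Carlo extent thresholding** simulates Gaussian noise on the
mask, smooths to the estimated FWHM, standardizes, thresholds two-tailed
at `voxel_p`, and records the maximum cluster extent per iteration. The
significance threshold is the smallest integer \(k\) with
\(\Pr(\max\ \mathrm{extent} \ge k) \le\) `cluster_p` in the simulated
distribution — the classic AlphaSim rule, which (unlike a plain quantile
of an integer sample) guarantees the nominal level on the simulated
distribution. Cluster connectivity is 26-neighborhood by default
(configurable to 6/18); labeling is deterministic, ordered by smallest
linear index.

# Expression preprocessing

The nine steps run in fixed order, each logging retained counts:

1. *Reannotation*: probe symbols are replaced from a current map; probes
   absent from it are dropped.
2. *Intensity filter*: keep probes above their background in ≥ 50% of
   samples.
3. *Probe selection*: one probe per gene by **differential stability** —
   the mean over donor pairs of the correlation of donor-wise,
   structure-aggregated expression profiles. Donors contribute samples
   at disjoint coordinates, so cross-donor correlation needs a shared
   support; coarse structure labels provide it (in the synthetic data, a
   block partition of the mask). Single-donor data fall back to highest
   mean intensity; exact ties break to the smaller probe id.
4. *Sample matching*: nearest in-mask voxel centre within 2 mm;
   a left-hemisphere filter (world x < 0) is available and off by
   default.
5. *Missing data*: genes over 50% missing are dropped; the rest imputed
   by the gene's donor-wise median.
6. & 7. *Normalization*: a scaled robust sigmoid
   \(x' = (1 + \exp(-(x - \mathrm{med})/(\mathrm{IQR}/1.349)))^{-1}\)
   followed by min–max rescaling to [0, 1] — first per sample across
   genes, then per gene across each donor's samples. The transform is
   invariant to per-donor affine intensity distortions, which is exactly
   what the synthetic generator plants. Constant genes map to 0.5.
8. *Aggregation*: samples sharing a voxel are averaged into one feature.
9. *Stability filter*: genes with differential stability below 0.2 are
   dropped. The threshold is not standardized in the field; 0.2 on mean
   inter-donor correlation is a conservative middle ground and is
   configurable.

# Spatial association and enrichment

Gene profiles are correlated with the t-values extracted at the feature
voxels; p-values come from the t-distribution with \(n - 2\) dof
(two-sided — both positively and negatively correlated genes are
reported). The Bonferroni denominator is the number of genes actually
tested after preprocessing, not the pre-filter count. Selection requires
both `p < alpha / n_tests` and `|r| > r_min`; since the conjunction is
commutative it is implemented as a single AND. Constant genes are
excluded and logged.

Enrichment uses the hypergeometric upper tail \(P(X \ge k)\) with the
universe defaulting to the genes that survived preprocessing (the screen
actually performed), BH adjustment within each category (mirroring
per-ontology reporting; a global flag exists), and a minimum overlap of
3 to suppress singleton artifacts.

# Clinical statistics

`mann_whitney` uses midranks; for small samples (both groups ≤ 8) the
two-sided p is an exact enumeration over all group assignments, which
remains exact under ties; larger samples use the normal approximation
with tie and continuity corrections. `fisher_exact` sums the conditional
hypergeometric probabilities of tables at most as probable as the
observed one and reports the sample odds ratio. Imaging–clinical
correlations are midrank Spearman with t-approximation p-values and BH
across the full (cluster × measure) family; the per-subject imaging
value is the mean standardized map value within each significant cluster
(peak-voxel summary available). By default the correlations are computed
within cases only, the usual design for symptom–imaging associations.

# The synthetic ground truth

The generator provides every input at a desk scale chosen once: a
24 × 28 × 24 grid at 3 mm (an ellipsoidal "brain" of ~5,600 voxels),
31 subjects per arm, 200 time points at TR 2 s, 2,000 genes (50 true,
target coupling r = 0.5), 300 samples, 3 donors, 2 probes per gene.

* **fMRI**: per subject, a smooth baseline plus band-limited
  (0.01–0.08 Hz) noise whose amplitude is multiplied by
  `1 + amplitude_effect` for cases inside positive clusters (divided for
  negative ones), plus white noise. The group difference therefore lives
  purely in the band-limited amplitude — i.e., in ALFF, not in the mean
  signal. A smooth amplitude-heterogeneity field (±30%) gives the
  standardized ALFF map a regional topography, as in real data; without
  it the one-sample masking step would retain almost nothing.
* **GMV**: smooth template + additive signed cluster effects for cases +
  subject noise smoothed at 8 mm.
* **Expression**: samples at distinct in-mask voxel centres (sub-voxel
  jitter), round-robin donors, shared structure tags. Every gene owns a
  fixed spatial pattern — a smooth structure-scale component plus
  sample-level white variation. True genes are
  \(r\,z(\mathrm{effect}) + \sqrt{1 - r^2}\,\eta\) with their intrinsic
  \(\eta\) drawn from a longer-range basis (18 mm FWHM, smooth fraction
  0.75); null genes use 8 mm / 0.5. The asymmetry is deliberate:
  differential stability can only retain genes with donor-reproducible
  structure-scale patterns, so the planted disease genes are drawn from
  that reproducible stratum (as real stable genes are), while weakly
  patterned null genes are largely removed by the stability filter —
  and the survivors' modest autocorrelation keeps the plain-Bonferroni
  null honest against the smooth t-maps. Per-probe offsets, per-donor
  affine distortions, planted below-background probes (10%), stale
  annotations (10%) and unmappable probes (2%) exercise steps 1–3.
* **Gene sets**: a planted set carrying 80% of the true genes plus
  random sets, for the enrichment stage.
* **Clinical table**: severity-like and cognition-like measures with
  group separation; one measure is coupled to a supplied imaging score.

All generators are pure functions of (parameters, seed); the pipeline
derives per-stage child seeds from one master seed and records them.

What the generator does **not** emulate: hemodynamic response shape,
head motion and scanner artifacts, anatomical parcellations, realistic
gene–gene correlation structure beyond a shared low-rank spatial basis,
and donor-specific anatomy. Passing tests therefore demonstrate the
statistical machinery is correct and calibrated under the stated model,
not that any particular clinical finding replicates.

# Numerical choices and degenerate inputs

* Ideal (boxcar) frequency filtering; band edges inclusive.
* Zero-variance voxels are excluded from one-sample masking (counted),
  and GLM voxels with zero residual variance are flagged undefined and
  removed from the statistic mask.
* Constant genes normalize to 0.5 and are excluded from correlation
  testing.
* The closed-form ALFF check runs with detrending disabled: the fitted
  line of a finite sinusoid is small but its spectral leakage exceeds a
  1e-6 closed-form tolerance (for 200 points it changes the series by
  several percent of the amplitude).
* Cluster records sort by |peak t|; ranking ties in gene lists break
  lexicographically.
* Seeds are kept below 2^31; child seeds are `seed * 100 + stage`.

# Problem sizes used by the tests

The test-suite and acceptance script sizes were chosen as the smallest
that keep the Monte-Carlo estimates stable: 500 null analyses for the
family-wise error, 200 maps for smoothness recovery, 20 seeds for the
gene screen (2,000 genes × 300 samples each), 1e5 iterations for the
brute-force extent-threshold oracle on a 10³ mask, and replicated
pipeline runs at reduced cohort/time-point counts where a property does
not depend on the full scale. The full default pipeline run completes in
well under a minute per seed on one core.

# Known limitations

* The Gaussian Monte-Carlo surrogate slightly understates cluster sizes
  of t-fields at low degrees of freedom (FWE ≈ 0.06 at dof ≈ 18 in our
  measurements); at study-scale dof the effect vanishes.
* GRF theory is approximate below ~2 voxels FWHM smoothness; the
  package warns when the estimate falls under that bound.
* The parametric correlation null ignores spatial autocorrelation of
  expression maps; autocorrelation-preserving nulls (spin tests,
  generative surrogates) are out of scope here, matching the plain
  Bonferroni screen it reimplements. The generator keeps null-gene
  autocorrelation realistic but moderate, and the screen's calibration
  under stronger autocorrelation should not be assumed.
* The exact Mann–Whitney path enumerates all assignments and is limited
  to small groups (≤ 8 per arm by default).
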