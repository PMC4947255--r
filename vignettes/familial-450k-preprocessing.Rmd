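---
title: "Pre-processing familial methylation array data: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pre-processing familial methylation array data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Infinium 450k-style methylation arrays report, per CpG probe, a methylated
(M) and unmethylated (U) fluorescence intensity, summarised as the
proportion methylated, the beta value $\beta = M/(M+U+100)$; the offset of
100 regularises scores when both signals are near zero. Beta values are
heteroskedastic near 0 and 1, so statistics in this package operate on the
base-2 logit, the M value $m = \log_2(\beta/(1-\beta))$, and transform back
for interpretation.

Most pre-processing recipes for these arrays assume two contrasting groups
(case/control, tumour/normal) and exploit the contrast during
normalisation. Family studies have no such reference group: every sample is
"normal", the signal of interest is inter-individual variation that tracks
kinship, and the dominant nuisance is the batch (processing-date) effect.
famnorm implements the pieces needed to pick a pre-processing strategy in
that setting: QC filters, eight normalisation algorithms plus
empirical-Bayes batch correction, an evaluation battery whose metrics are
all reference-free, and a simulator that generates familial datasets with
known ground truth.

## The processing chain

1. **QC.** Probes are dropped when their detection p value (computed
   against the negative-control background) exceeds 0.05 in *more than one*
   sample — a single failing sample is tolerated, following a literal
   reading of the rule — and when fewer than 3 beads underlie the
   measurement in at least 5% of samples (boundary inclusive). Probes on
   chrX/chrY (either `chrX` or bare `X` naming) are removed and never
   re-introduced, since X-inactivation makes them incomparable between
   sexes. Samples are only ever *flagged* (mean detection p above
   threshold), never silently dropped: the sample-level criterion is a
   stand-in, because exclusion decisions belong to the analyst.

2. **Normalisation.** Seven methods are compared (an eighth family member,
   the negative-control-factor regression approach RUV, requires contrast
   groups and is out of scope here):

   * `norm_qn` — global quantile normalisation of the M and U intensity
     matrices separately. Ties receive the mean of their rank-range
     reference values (average ranks interpolated into the reference), so
     within-column order is preserved.
   * `norm_stratified_qn` — quantile normalisation within genomic strata
     (island / shore-shelf / open sea): type II probes are normalised
     across samples per stratum and type I probes are mapped onto the
     stratum's type II reference quantile function by monotone
     interpolation. No background correction is applied. Strata with fewer
     than two type II probes fall back to the global reference with a
     warning.
   * `norm_swan` — subset-quantile within-array normalisation: per sample,
     equal-sized random subsets of type I and II probes are drawn per
     CpG-body-count class (1, 2, 3+; subset size is the smaller class size
     across types), a mean quantile distribution is built over the pooled
     subsets, and all probes are adjusted by monotone interpolation between
     flanking subset values.
   * `norm_bmiq` — beta-mixture quantile dilation: per sample, three-state
     (unmethylated / hemi / methylated) beta mixtures are fitted to each
     probe type by EM; type II probes in the U and M states are
     quantile-mapped onto the corresponding type I state distribution
     (right-tail orientation for M), and the H state is rescaled by the
     affine dilation that makes its range abut the transformed neighbours.
     Type I values are never changed.
   * `norm_noob` — normal-exponential background correction using
     out-of-band signals: type I probes read in their opposite colour
     channel measure pure non-specific fluorescence; a truncated-normal
     background is fitted per sample and allele channel, the exponential
     signal mean is estimated by moments, and each intensity is replaced by
     its posterior expected signal plus an offset of 15.
   * `norm_dasen` — per-sample alignment of the type I background level
     (kernel-density mode of the low intensities) to the type II level,
     then quantile normalisation across samples within each probe type.
   * `norm_funnorm` — functional normalisation: per-sample control-probe
     summaries (mean/sd per control type and channel) are reduced to
     principal components and each intensity quantile anchor is regressed
     on them across samples; the fitted technical deviations are removed
     while the across-sample mean quantile is kept.

3. **Batch correction.** `combat()` implements the empirical-Bayes
   location/scale model on M values: probes are standardised with the
   batch-size-weighted grand mean and pooled scale; per-batch, per-probe
   location ($\gamma$) and scale ($\delta^2$) estimates are shrunk with a
   normal and an inverse-gamma prior (hyperparameters by method of
   moments, jointly iterated to tolerance $10^{-4}$) and removed. Only the
   parametric variant with known batches is implemented; a batch of one
   sample is rejected because its scale is undefined, and a single batch
   passes through with a warning. The exact weighted grand mean is
   preserved only up to the (small) shrinkage residual, since the shrunken
   $\gamma^*$ differ from the raw batch means.

4. **Evaluation.** Eight reference-free metrics, each a number (plots are
   optional views of the same quantities):
   per-sample beta densities plus the Kolmogorov–Smirnov distance between
   pooled type I and type II betas; classical MDS of the 1000 most
   variable M values; a one-way ANOVA of batch (or family) on the first
   principal component of the 1000 most variable beta values; the median
   absolute M-value difference per technical replicate pair; the
   imprinted-region standard error DMRSE — iDMR probes are expected
   hemi-methylated at $\beta \approx 0.5$, so each probe row is centred by
   its cross-sample mean, per-sample mean deviations are taken, and DMRSE
   is their standard deviation divided by $\sqrt{\#\text{probes}}$;
   complete-linkage hierarchical clustering on all probes with the
   adjusted Rand index against batch labels; a two-stage kinship-adjusted
   meQTL association; and the age-EWAS inflation lambda, the median
   observed $-\log_{10} p$ over the median expected under uniformity
   (order statistics $(i-0.5)/n$).

   The meQTL stage fits $y \sim N(\mu \mathbf{1},\,
   \sigma_g^2\, 2K + \sigma_e^2 I)$ by maximum likelihood, profiling the
   single variance ratio on the eigenbasis of $2K$ (1-D optimisation,
   tolerance $10^{-8}$), then regresses the environmental residuals
   (phenotype minus mean and BLUP) on each SNP dosage with a two-sided
   t test and Bonferroni adjustment over the window. When the profile
   likelihood is flat (e.g. $2K \propto I$, where the two variance
   components are unidentifiable) the no-genetic-variance boundary is
   preferred, so the residuals reduce to centred phenotypes. Kinship can
   come from a pedigree (Kinman–Emik recursion) or from genotypes
   (identity-by-state sharing).

`run_pipeline()` executes QC once, runs every normalisation branch
independently from the QC'd data, optionally follows each with ComBat,
computes all metrics per branch and ranks branches per metric in the
stated direction (batch-ANOVA p: larger better; replicate MAD, DMRSE and
batch-ARI: smaller better; meQTL preservation and lambda are reported, not
ranked), with average ranks for ties.

## What the simulator emulates

`simulate_dataset()` reproduces the design features the metrics assume: 45
unique blood-derived individuals from 4 families on 3 batches; 5 extra
replicate arrays arranged in groups of (3,2,2,2) arrays per individual so
that 6 pairwise replicate pairs each span two batches; 227 iDMR probes
forced hemi-methylated with mean beta 0.5; a 72% type II probe fraction
with type II betas compressed toward 0.5 by a factor 0.8; a planted
cis-meQTL and age-associated drift.

Generation proceeds on the M scale: per-probe baseline states
(unmeth/hemi/meth beta centres drawn from Beta(2,10)/Beta(10,10)/Beta(10,2),
state proportions 0.4/0.2/0.4); a family-structured biological effect with
covariance $2K\sigma_{bio}^2$ ($\sigma_{bio} = 0.3$ M-units, exchangeable
within-family kinship 0.25 by default, or pedigree-derived); the meQTL
effect (0.8 M-units per allele at one hemi-methylated probe, 50 SNPs at
MAF 0.4 with AR(1) latent LD 0.7 in a 2-Mb window, genotypes in HWE); age
slopes on 2000 of 10000 probes with sd 0.02 M-units/year, ages uniform on
23–89. The fraction of age-affected probes matters for the lambda metric:
because lambda is a ratio of *medians*, a 5% affected fraction cannot push
it past $\approx 1.08$ even with infinitely strong effects; the 20%
default, in line with the breadth of blood aging signatures, yields
corrected-data lambdas around 1.3–1.5. Batch artefacts are applied as the
location/scale model the batch-correction step assumes: per-probe,
per-batch shifts $\gamma \sim N(0, 1)$ and a mild lognormal batch scale on
the technical noise ($\sigma_{tech} = 0.2$).

Intensities follow a normal + exponential convolution so that the
out-of-band background model is correctly specified: each probe owns a
total signal affinity $T_p \sim$ Gamma(shape 2, scale 3000) (the sum of
two exponential channel signals), split between channels by the
(compressed) beta; per-array lognormal factors apply an overall scale
(sdlog 0.15), a background level (mean 500, sd 100, sdlog 0.2), a
meth-channel dye-like imbalance (sdlog 0.08) and per-probe wobble (sdlog
0.1). Probe-specific affinities are deliberately stable across arrays, as
on real chips — were they redrawn per array, the attenuation
$T/(T+2\mu_{bg}+100)$ would act as huge multiplicative noise. Negative
controls are drawn from the background; strong normalisation controls
(level 2000 a.u. times the array scale) additionally expose the array
scale to the control-based normalisation. Detection p values are
upper-tail probabilities of the total intensity under a normal fit to the
negative controls; a 0.2% random signal dropout and a 0.05% low-bead-count
rate feed the QC filters. Technical replicates re-draw only these
technical layers.

What the simulator does *not* contain — and hence what passing tests do
not certify on real data: cross-hybridising probes, SNPs under probe
bodies, cell-composition heterogeneity, realistic genome coordinates or
chained LD beyond the AR(1) window, genotype inheritance within pedigrees
(genotypes are drawn independently per individual; kinship enters through
the methylation covariance), and batch effects that are *not* of
location/scale form. The last point matters most: the batch artefact is
generated by the same family of models ComBat assumes, so batch-removal
results here are a best case.

## Numerical choices and degenerate inputs

* Beta offset 100; logit base 2; clip at $\epsilon = 10^{-6}$ before the
  logit (the clip bound corresponds to $|m| \le 19.9$; callers needing a
  wider invertible range pass a smaller epsilon).
* "Most variable" means cross-sample variance with lexical probe-id tie
  break, computed on betas for the PC ANOVA and on M values for MDS.
* Quantile-normalisation ties: dense average ranks interpolated into the
  reference (matches the behaviour of the standard microarray
  implementation with tie handling enabled).
* The beta-mixture EM uses hard threshold initialisation (1/3, 2/3),
  responsibility-weighted moment updates, relative log-likelihood
  tolerance $10^{-4}$, at most 100 iterations, components re-ordered by
  mean after fitting; a degenerate component triggers one
  re-initialisation before the fit is flagged. Mixtures are fitted on a
  subsample of at most 5000 probes per type; the transform is applied to
  all probes. The U/M state maps use the empirical state quantile
  functions (the fitted mixture supplies the state assignments); the H
  dilation anchors at the 0.5%/99.5% quantiles of the transformed
  neighbours so single outliers cannot squeeze the hemi-methylated mass.
* The background mode for `norm_dasen` is the kernel-density mode of the
  values below the median.
* MDS axes are signed so the first nonzero loading is positive; PC-ANOVA
  returns p = 1 when PC1 is constant.
* DMRSE centres at the probe mean, not at 0.5: the metric quantifies
  between-sample dispersion; deviation-from-0.5 is a property of the
  array's calibration, not of a normalisation step.
* Randomised steps (SWAN subsets, BMIQ fitting subsample, the simulator)
  take explicit seeds; the simulator derives per-stage sub-streams from
  its seed so probe-level settings do not perturb sample-level draws.

## Problem sizes used by the test suite

The packaged checks run the generator at the full study scale (10000
probes, 45+5 arrays) for the acceptance battery — 20 seeds for the
batch-removal and error-ordering properties, 50 seeds each for meQTL power
and size, 20 for the lambda calibration, 10 full pipeline runs for the
ranking property — and at reduced scale (600–4000 probes, 12–24 samples)
for the per-module tests, where the properties under test do not depend on
the probe count.

## Known limitations

* The three-state architecture of BMIQ caps how far it can align probe
  types when the states overlap heavily: with the generator's 20%
  hemi-methylated fraction and background attenuation, the fitted state
  *proportions* differ between types, and residual type I/II CDF gaps of a
  few percent persist at the state boundaries. Likewise SWAN aligns the
  marginal intensity distributions, which cannot fully undo a compression
  applied in beta space (the M/U dependence structure still differs), so
  both methods settle near — rather than comfortably past — a 50%
  reduction of the type I/II KS distance here.
* After correction, near-tied branches (global/stratified/type-wise
  quantile variants followed by ComBat) differ by less than the
  between-seed noise on the replicate-MAD and DMRSE metrics, so per-metric
  ranks among them are close to exchangeable; the ranking table is most
  informative about the separation between branch *groups* (uncorrected vs
  corrected, background-only vs between-array methods).
* The meQTL power analysis shares a single target probe per dataset; with
  per-probe batch shifts of 1 M-unit, the raw-data power at effect 0.8 is
  limited by the batch draw at that probe, not by the association method.
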