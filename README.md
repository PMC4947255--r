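# famnorm

Pre-processing and evaluation of Infinium 450k-style DNA methylation array
data for **family studies** — designs with no matched control or "normal"
reference group, where the signal of interest is inter-individual variation
that tracks kinship and the dominant nuisance is the processing batch.

Most published pre-processing recipes assume two contrasting sample groups
and are ineffective (or harmful) on pedigree data. famnorm packages the
components needed to choose a strategy empirically on such data:

* **Quality control** — detection p-value filter (probe dropped when
  p > 0.05 in more than one sample), bead-count filter (< 3 beads in ≥ 5%
  of samples), sex-chromosome removal, and flag-only sample QC.
* **Eight normalisation algorithms** — global quantile normalisation,
  stratified (by genomic region) quantile normalisation, SWAN-style subset
  quantile normalisation, beta-mixture quantile dilation (BMIQ), noob
  normal-exponential out-of-band background correction, dasen-style
  type-wise normalisation, control-probe functional normalisation — plus
  **ComBat-style empirical-Bayes location/scale batch correction** on
  M values.
* **An eight-metric evaluation battery**, all reference-free: beta density
  summaries and the type I/II probe KS distance; classical MDS; ANOVA of
  batch (or family) on the first principal component of the 1000 most
  variable beta values; median absolute M-value differences between
  technical replicate pairs; the imprinted-region standard error (DMRSE);
  hierarchical-cluster agreement with batch (adjusted Rand index); a
  kinship-adjusted meQTL association; and the age-EWAS inflation lambda.
* **A synthetic-data generator** reproducing the familial design the
  metrics assume (45 individuals, 4 families, 3 batches, 6 cross-batch
  replicate pairs, 227 hemi-methylated imprinted-region probes, two probe
  chemistries, a planted cis-meQTL and age drift) with full ground truth.

The core scales: `beta = M / (M + U + 100)` is the proportion methylated;
statistics run on the base-2 logit (`M value`), which removes the severe
heteroskedasticity of betas near 0 and 1. The meQTL check is two-stage:
`y ~ N(mu, sigma_g^2 * 2K + sigma_e^2 * I)` fitted by ML on the kinship
eigenbasis, then OLS of the environmental residuals on SNP dosage with
Bonferroni correction over a 2-Mb window.

## Worked example

```r
library(famnorm)

sim <- simulate_dataset(simulate_config(), seed = 1)
qc  <- run_qc(sim$dataset)
ds  <- qc$dataset                       # 9622 probes x 50 arrays

corrected <- apply_combat(norm_stratified_qn(ds))

pc_anova(ds$beta, ds$samples$batch)         # 4.6e-62  batch dominates raw data
pc_anova(corrected$beta, ds$samples$batch)  # 0.9993   gone after correction

mean(replicate_mad(get_mvals(ds), ds$samples$replicate_group)$mad)
# 0.456  raw replicate disagreement (M-value units)
mean(replicate_mad(get_mvals(corrected), ds$samples$replicate_group)$mad)
# 0.144  after stratified QN + ComBat

dmrse(ds$beta, ds$annotation$is_idmr)          # 0.00135 raw
dmrse(corrected$beta, ds$annotation$is_idmr)   # 0.00017 corrected

# biology is preserved: the planted meQTL and age signal strengthen
ids <- colnames(sim$truth$genotypes)
meqtl_association(get_mvals(corrected)[sim$truth$meqtl$probe, ids],
                  sim$truth$genotypes, sim$truth$kinship)$min_p_adjusted
# 1.1e-10
age_ewas_lambda(get_mvals(corrected), ds$samples$age)$lambda
# 1.448 (raw: 1.144)
```

Interpretation: before correction the leading axis of variation is the
batch (ANOVA p ~ 1e-62, cluster ARI vs batch = 1); after stratified
quantile normalisation plus batch correction the batch signal is gone
(p ≈ 1, ARI ≈ 0), technical replicates agree three times better, the
imprinted-region error drops an order of magnitude, and the planted
genetic and age associations come through more strongly — removing
technical variance without removing biology.

`run_pipeline(pipeline_config(seed = 1))` runs QC once, evaluates raw plus
all seven methods with and without batch correction (15 branches), and
ranks them per metric; `rank_methods()` summarises by mean rank. A thin
command-line wrapper is installed at `inst/cli/famnorm.R`
(`simulate`, `qc`, `normalize`, `pipeline` subcommands).

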