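## Shared fixtures: everything is generated in code at test time.

## A small but fully featured simulated dataset.
small_sim <- function(seed = 1, ...) {
  args <- list(n_probes = 800, n_samples = 12, n_families = 3,
               n_idmr = 40, n_age_probes = 160, n_replicate_pairs = 2,
               n_snps = 20)
  dots <- list(...)
  args[names(dots)] <- dots
  simulate_dataset(do.call(simulate_config, args), seed = seed)
}

## A tiny hand-built dataset for contract tests.
toy_dataset <- function(n_probes = 6, n_samples = 4) {
  probe_id <- sprintf("cg%02d", seq_len(n_probes))
  sample_id <- sprintf("S%d", seq_len(n_samples))
  set.seed(99)
  meth <- matrix(runif(n_probes * n_samples, 1000, 5000), n_probes, n_samples,
                 dimnames = list(probe_id, sample_id))
  unmeth <- matrix(runif(n_probes * n_samples, 1000, 5000), n_probes,
                   n_samples, dimnames = list(probe_id, sample_id))
  ann <- tibble::tibble(
    probe_id = probe_id,
    design_type = rep(c("I", "II"), length.out = n_probes),
    channel = ifelse(rep(c(TRUE, FALSE), length.out = n_probes),
                     "red", "both"),
    chromosome = rep("chr1", n_probes),
    position = seq_len(n_probes) * 1000L,
    region_stratum = rep(c("island", "open_sea"), length.out = n_probes),
    is_idmr = rep(FALSE, n_probes),
    cpg_body_count = rep(1L, n_probes))
  smp <- tibble::tibble(
    sample_id = sample_id,
    batch = rep(c("B1", "B2"), length.out = n_samples),
    family_id = rep("F1", n_samples),
    replicate_group = NA_character_,
    age = seq(30, 60, length.out = n_samples),
    sex = rep(c("F", "M"), length.out = n_samples))
  methyl_dataset(meth = meth, unmeth = unmeth, annotation = ann,
                 samples = smp)
}
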