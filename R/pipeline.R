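#' Configuration for the end-to-end comparison pipeline
#'
#' @param sim_config A [simulate_config()] used when `input_dir` is `NULL`.
#' @param input_dir Optional directory readable by [load_dataset()]; when
#'   given, simulation is skipped and the meQTL/kinship inputs must be
#'   supplied through `genotypes`/`kinship`/`target_probe`.
#' @param seed Integer seed controlling every random stage.
#' @param methods Normalisation methods to compare, a subset of
#'   `c("qn", "stratified_qn", "swan", "bmiq", "noob", "dasen", "funnorm")`.
#' @param with_combat Also evaluate every method followed by batch
#'   correction.
#' @param qc Named list of [run_qc()] threshold overrides.
#' @param genotypes,kinship,target_probe meQTL inputs for loaded datasets
#'   (filled from the simulation truth otherwise).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim_config = simulate_config(),
                            input_dir = NULL, seed = 1,
                            methods = c("qn", "stratified_qn", "swan",
                                        "bmiq", "noob", "dasen", "funnorm"),
                            with_combat = TRUE, qc = list(),
                            genotypes = NULL, kinship = NULL,
                            target_probe = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (!length(methods)) stop("at least one method is required")
  structure(list(sim_config = sim_config, input_dir = input_dir,
                 seed = as.integer(seed), methods = methods,
                 with_combat = with_combat, qc = qc,
                 genotypes = genotypes, kinship = kinship,
                 target_probe = target_probe),
            class = "pipeline_config")
}

apply_method <- function(ds, method, seed) {
  switch(method,
         raw = ds,
         qn = norm_qn(ds),
         stratified_qn = norm_stratified_qn(ds),
         swan = norm_swan(ds, seed = seed),
         bmiq = norm_bmiq(ds, seed = seed),
         noob = norm_noob(ds),
         dasen = norm_dasen(ds),
         funnorm = norm_funnorm(ds),
         stop("unknown method '", method, "'"))
}

#' Compute the full metric battery for one processing state
#'
#' @param ds A [methyl_dataset()].
#' @param label Branch label recorded in the report.
#' @param genotypes,kinship,target_probe Optional meQTL inputs; the meQTL
#'   metric is `NA` when absent (or when the target probe was filtered).
#' @param k Number of most-variable probes for the MDS/PC-ANOVA metrics.
#' @return A `metric_report` (list); see [tidy.metric_report()] for the
#'   tabular form.
#' @export
compute_metrics <- function(ds, label = "state", genotypes = NULL,
                            kinship = NULL, target_probe = NULL, k = 1000) {
  mvals <- get_mvals(ds)
  dens <- density_summary(ds$beta, ds$annotation)
  mds <- mds_coordinates(mvals, k = k)
  p_batch <- pc_anova(ds$beta, ds$samples$batch, k = k)
  p_family <- pc_anova(ds$beta, ds$samples$family_id, k = k)
  mad_tbl <- replicate_mad(mvals, ds$samples$replicate_group)
  dm <- if (any(ds$annotation$is_idmr)) {
    dmrse(ds$beta, ds$annotation$is_idmr)
  } else NA_real_
  cl <- cluster_batch_agreement(mvals, ds$samples$batch)
  meqtl <- NULL
  if (!is.null(genotypes) && !is.null(kinship) && !is.null(target_probe) &&
      target_probe %in% rownames(mvals)) {
    ids <- intersect(colnames(genotypes), colnames(mvals))
    y <- mvals[target_probe, ids]
    meqtl <- meqtl_association(y, genotypes[, ids, drop = FALSE],
                               kinship[ids, ids])
  }
  ewas <- age_ewas_lambda(mvals, ds$samples$age)
  structure(list(
    label = label,
    density = dens, mds = mds,
    pc1_batch_p = p_batch, pc1_family_p = p_family,
    replicate_mad = mad_tbl,
    dmrse = dm, cluster = cl,
    meqtl = meqtl, ewas = ewas), class = "metric_report")
}

#' Run the end-to-end method-comparison pipeline
#'
#' Simulates (or loads) a dataset, applies QC once, runs every requested
#' normalisation branch independently from the QC'd data (optionally
#' followed by batch correction), computes the metric battery per branch
#' and ranks the branches. Branch failures are recorded without affecting
#' the other branches; the run is deterministic given the seed.
#'
#' @param config A [pipeline_config()].
#' @return A `comparison_report`: list with `report` (tibble, one row per
#'   branch), `ranking` (from [rank_methods()]), `qc`, `metrics` (the full
#'   `metric_report` objects), `truth` (when simulated) and `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- config
  truth <- NULL
  if (is.null(cfg$input_dir)) {
    sim <- simulate_dataset(cfg$sim_config, seed = cfg$seed)
    ds0 <- sim$dataset
    truth <- sim$truth
    genotypes <- truth$genotypes
    kinship <- truth$kinship
    target_probe <- truth$meqtl$probe
  } else {
    ds0 <- load_dataset(cfg$input_dir)
    genotypes <- cfg$genotypes
    kinship <- cfg$kinship
    target_probe <- cfg$target_probe
  }
  qc <- do.call(run_qc, c(list(ds0), cfg$qc))
  base <- qc$dataset

  branches <- c("raw", cfg$methods)
  metrics <- list()
  failed <- character()
  for (method in branches) {
    norm_ds <- tryCatch(
      suppressWarnings(apply_method(base, method, seed = cfg$seed)),
      error = function(e) e)
    if (inherits(norm_ds, "error")) {
      failed <- c(failed, method)
      metrics[[method]] <- NULL
      next
    }
    metrics[[method]] <- compute_metrics(
      norm_ds, label = method, genotypes = genotypes,
      kinship = kinship, target_probe = target_probe)
    if (cfg$with_combat && method != "raw") {
      lab <- paste0(method, "+combat")
      cds <- tryCatch(suppressWarnings(apply_combat(norm_ds)),
                      error = function(e) e)
      if (inherits(cds, "error")) {
        failed <- c(failed, lab)
        next
      }
      metrics[[lab]] <- compute_metrics(
        cds, label = lab, genotypes = genotypes,
        kinship = kinship, target_probe = target_probe)
    }
  }
  report <- do.call(rbind, lapply(metrics, tidy_metric_report))
  ranking <- rank_methods(report)
  structure(list(report = report, ranking = ranking, qc = qc$report,
                 metrics = metrics, failed = failed,
                 truth = truth, config = cfg),
            class = "comparison_report")
}

## One-row tabular summary of a metric_report.
tidy_metric_report <- function(m) {
  tibble::tibble(
    branch = m$label,
    ks_type = m$density$ks_type,
    pc1_batch_p = m$pc1_batch_p,
    pc1_family_p = m$pc1_family_p,
    replicate_mad_mean = if (nrow(m$replicate_mad)) mean(m$replicate_mad$mad)
    else NA_real_,
    dmrse = m$dmrse,
    cluster_ari_batch = m$cluster$ari,
    meqtl_min_p_adjusted = if (!is.null(m$meqtl)) m$meqtl$min_p_adjusted
    else NA_real_,
    age_lambda = m$ewas$lambda)
}

#' Rank pipeline branches across the headline metrics
#'
#' Ranks every branch per metric in its stated direction — PC1-batch ANOVA
#' p (larger better), replicate MAD, DMRSE and batch-cluster ARI (smaller
#' better) — with average ranks for ties, and summarises by mean rank.
#' meQTL preservation (Bonferroni-adjusted p < 0.05) and the age lambda are
#' reported as information, not ranked.
#'
#' @param report Branch-level tibble as produced by [run_pipeline()].
#' @return Tibble: `branch`, one `rank_*` column per headline metric,
#'   `mean_rank`, `meqtl_preserved`, `age_lambda`, ordered by `mean_rank`.
#' @export
rank_methods <- function(report) {
  if (nrow(report) < 2) stop("ranking needs at least 2 branches")
  rk <- tibble::tibble(
    branch = report$branch,
    rank_pc1_batch_p = rank(-report$pc1_batch_p, ties.method = "average"),
    rank_replicate_mad = rank(report$replicate_mad_mean,
                              ties.method = "average"),
    rank_dmrse = rank(report$dmrse, ties.method = "average"),
    rank_cluster_ari = rank(report$cluster_ari_batch,
                            ties.method = "average"))
  rk$mean_rank <- rowMeans(rk[, -1])
  rk$meqtl_preserved <- !is.na(report$meqtl_min_p_adjusted) &
    report$meqtl_min_p_adjusted < 0.05
  rk$age_lambda <- report$age_lambda
  rk[order(rk$mean_rank, rk$branch), ]
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %d branches (%d failed)\n",
              nrow(x$report), length(x$failed)))
  print(x$report, n = nrow(x$report))
  invisible(x)
}

#' Write a comparison report to disk
#'
#' `report.json` holds the branch-level metrics and config snapshot;
#' `ranking.tsv` the ranking table.
#'
#' @param x A `comparison_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_comparison_report <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  payload <- list(
    report = x$report,
    failed = x$failed,
    seed = x$config$seed,
    methods = x$config$methods)
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  data.table::fwrite(x$ranking, file.path(dir, "ranking.tsv"), sep = "\t")
  invisible(dir)
}
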