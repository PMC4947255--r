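#' Remove probes failing the detection p-value threshold
#'
#' A probe is removed when its detection p value exceeds `p_threshold` in
#' more than `max_failed_samples` samples (so a single failing sample is
#' tolerated under the defaults).
#'
#' @param ds A [methyl_dataset()] with `detection_p` present.
#' @param p_threshold Detection p-value threshold (default 0.05).
#' @param max_failed_samples Maximum tolerated number of failing samples
#'   (strictly more fails the probe).
#' @return List with `dataset` (filtered) and `n_removed`.
#' @export
detection_filter <- function(ds, p_threshold = 0.05, max_failed_samples = 1) {
  if (is.null(ds$detection_p)) stop("detection p values are not available")
  failed <- rowSums(ds$detection_p > p_threshold)
  drop <- failed > max_failed_samples
  out <- subset_probes(ds, !drop)
  out <- add_provenance(out, sprintf("detection_filter[p>%g in >%d]",
                                     p_threshold, max_failed_samples))
  list(dataset = out, n_removed = sum(drop))
}

#' Remove probes failing the bead-count threshold
#'
#' A probe is removed when the fraction of samples with a bead count below
#' `min_beads` is at least `max_fail_fraction` (boundary inclusive).
#'
#' @param ds A [methyl_dataset()] with `bead_count` present.
#' @param min_beads Minimum acceptable bead count (default 3).
#' @param max_fail_fraction Failing-sample fraction at which the probe is
#'   removed (default 0.05).
#' @return List with `dataset` and `n_removed`.
#' @export
beadcount_filter <- function(ds, min_beads = 3, max_fail_fraction = 0.05) {
  if (is.null(ds$bead_count)) stop("bead counts are not available")
  frac <- rowMeans(ds$bead_count < min_beads)
  drop <- frac >= max_fail_fraction
  out <- subset_probes(ds, !drop)
  out <- add_provenance(out, sprintf("beadcount_filter[<%d in >=%g]",
                                     min_beads, max_fail_fraction))
  list(dataset = out, n_removed = sum(drop))
}

#' Remove sex-chromosome probes
#'
#' Drops every probe whose chromosome is in `{chrX, chrY, X, Y}`
#' (case-insensitive). Sex-linked dosage compensation makes these probes
#' incomparable between sexes, so they are removed before normalisation and
#' not re-introduced.
#'
#' @param ds A [methyl_dataset()].
#' @return List with `dataset` and `n_removed`.
#' @export
remove_sex_chromosomes <- function(ds) {
  sex_names <- c("chrx", "chry", "x", "y")
  drop <- tolower(ds$annotation$chromosome) %in% sex_names
  out <- subset_probes(ds, !drop)
  out <- add_provenance(out, "remove_sex_chromosomes")
  list(dataset = out, n_removed = sum(drop))
}

#' Flag samples with poor overall detection
#'
#' Flags (does not remove) samples whose mean detection p value exceeds the
#' threshold; the caller decides whether to drop them.
#'
#' @param ds A [methyl_dataset()] with `detection_p` present.
#' @param mean_detp_threshold Mean detection p-value threshold.
#' @return Character vector of flagged sample ids.
#' @export
sample_qc <- function(ds, mean_detp_threshold = 0.05) {
  if (is.null(ds$detection_p)) stop("detection p values are not available")
  mu <- colMeans(ds$detection_p)
  names(mu)[mu > mean_detp_threshold]
}

#' Run the full probe/sample QC stage
#'
#' Applies the detection, bead-count and sex-chromosome filters in that
#' (disjoint, ordered) sequence and flags poor samples.
#'
#' @param ds A [methyl_dataset()].
#' @inheritParams detection_filter
#' @inheritParams beadcount_filter
#' @inheritParams sample_qc
#' @return List with `dataset` (filtered) and `report`, a `qc_report` tibble
#'   row with removal counts, flagged samples and the thresholds used.
#' @export
run_qc <- function(ds, p_threshold = 0.05, max_failed_samples = 1,
                   min_beads = 3, max_fail_fraction = 0.05,
                   mean_detp_threshold = 0.05) {
  flagged <- if (!is.null(ds$detection_p)) {
    sample_qc(ds, mean_detp_threshold)
  } else character()
  s1 <- if (!is.null(ds$detection_p)) {
    detection_filter(ds, p_threshold, max_failed_samples)
  } else list(dataset = ds, n_removed = NA_integer_)
  s2 <- if (!is.null(s1$dataset$bead_count)) {
    beadcount_filter(s1$dataset, min_beads, max_fail_fraction)
  } else list(dataset = s1$dataset, n_removed = NA_integer_)
  s3 <- remove_sex_chromosomes(s2$dataset)
  report <- tibble::tibble(
    n_probes_removed_detection = s1$n_removed,
    n_probes_removed_beadcount = s2$n_removed,
    n_probes_removed_sex = s3$n_removed,
    n_probes_remaining = nrow(s3$dataset$annotation),
    samples_flagged = list(flagged),
    p_threshold = p_threshold, max_failed_samples = max_failed_samples,
    min_beads = min_beads, max_fail_fraction = max_fail_fraction,
    mean_detp_threshold = mean_detp_threshold)
  class(report) <- c("qc_report", class(report))
  list(dataset = s3$dataset, report = report)
}

#' Write a QC report as JSON and a human-readable log
#' @param report A `qc_report` from [run_qc()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_qc_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rep_list <- as.list(report)
  rep_list$samples_flagged <- report$samples_flagged[[1]]
  jsonlite::write_json(rep_list, file.path(dir, "qc_report.json"),
                       auto_unbox = TRUE, digits = NA)
  lines <- c(
    sprintf("probes removed by detection p filter: %s",
            report$n_probes_removed_detection),
    sprintf("probes removed by bead count filter:  %s",
            report$n_probes_removed_beadcount),
    sprintf("probes removed on sex chromosomes:    %s",
            report$n_probes_removed_sex),
    sprintf("probes remaining:                     %s",
            report$n_probes_remaining),
    sprintf("samples flagged: %s",
            if (length(report$samples_flagged[[1]]))
              paste(report$samples_flagged[[1]], collapse = ", ") else "none"))
  writeLines(lines, file.path(dir, "qc_report.txt"))
  invisible(dir)
}
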