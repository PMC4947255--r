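#' Bundle of methylation array matrices, annotation and sample metadata
#'
#' The central container of the package. Holds probe x sample matrices
#' (intensities, beta values, detection p values, bead counts), the per-probe
#' annotation, the sample sheet and an append-only provenance trail of
#' processing steps. All components are index-aligned: matrix rownames equal
#' `annotation$probe_id` and colnames equal `samples$sample_id`, in order.
#'
#' @param meth,unmeth Optional non-negative intensity matrices (probes x
#'   samples). Dropped by beta-only normalisation steps.
#' @param beta Beta-value matrix in `[0, 1]`; computed from the intensities
#'   when omitted.
#' @param annotation Data frame with columns `probe_id`, `design_type`
#'   (`"I"`/`"II"`), `channel` (`"red"`/`"green"`/`"both"`), `chromosome`,
#'   `position`, `region_stratum` (`"island"`/`"shore_shelf"`/`"open_sea"`),
#'   `is_idmr` (logical), `cpg_body_count` (>= 1).
#' @param samples Data frame with columns `sample_id`, `batch`, `family_id`,
#'   `replicate_group` (may be `NA`), `age`, `sex`.
#' @param detection_p Optional matrix of detection p values in `[0, 1]`.
#' @param bead_count Optional matrix of non-negative integer bead counts.
#' @param oob_meth,oob_unmeth Optional out-of-band intensity matrices for
#'   type I probes (rownames a subset of type I probe ids).
#' @param controls Optional control-probe table: columns `control_id`,
#'   `control_type`, `channel`, then one column per sample.
#' @param provenance Character vector of processing-step labels.
#' @return An object of class `methyl_dataset`.
#' @export
methyl_dataset <- function(meth = NULL, unmeth = NULL, beta = NULL,
                           annotation, samples,
                           detection_p = NULL, bead_count = NULL,
                           oob_meth = NULL, oob_unmeth = NULL,
                           controls = NULL, provenance = character()) {
  annotation <- tibble::as_tibble(annotation)
  samples <- tibble::as_tibble(samples)
  if (is.null(beta)) {
    if (is.null(meth) || is.null(unmeth)) {
      stop("either `beta` or both `meth` and `unmeth` must be supplied")
    }
    beta <- beta_from_intensities(list(meth = meth, unmeth = unmeth))
  }
  ds <- structure(list(
    meth = meth, unmeth = unmeth, beta = beta,
    annotation = annotation, samples = samples,
    detection_p = detection_p, bead_count = bead_count,
    oob_meth = oob_meth, oob_unmeth = oob_unmeth,
    controls = controls, fits = list(),
    provenance = as.character(provenance)
  ), class = "methyl_dataset")
  validate_methyl_dataset(ds)
  ds
}

#' Validate the alignment invariants of a methyl_dataset
#'
#' Checks unique ids, matrix/annotation/sample-sheet index alignment and
#' value ranges; errors list the first 10 offending ids.
#'
#' @param ds A [methyl_dataset()].
#' @return `ds`, invisibly, if valid.
#' @export
validate_methyl_dataset <- function(ds) {
  ann <- ds$annotation
  smp <- ds$samples
  need_ann <- c("probe_id", "design_type", "channel", "chromosome", "position",
                "region_stratum", "is_idmr", "cpg_body_count")
  miss <- setdiff(need_ann, names(ann))
  if (length(miss)) stop("annotation is missing columns: ",
                         paste(miss, collapse = ", "))
  need_smp <- c("sample_id", "batch", "family_id", "replicate_group",
                "age", "sex")
  miss <- setdiff(need_smp, names(smp))
  if (length(miss)) stop("sample sheet is missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(ann$probe_id)) {
    dup <- unique(ann$probe_id[duplicated(ann$probe_id)])
    stop("duplicate probe_id in annotation: ",
         paste(utils::head(dup, 10), collapse = ", "))
  }
  if (anyDuplicated(smp$sample_id)) {
    dup <- unique(smp$sample_id[duplicated(smp$sample_id)])
    stop("duplicate sample_id in sample sheet: ",
         paste(utils::head(dup, 10), collapse = ", "))
  }
  if (any(ann$cpg_body_count < 1)) stop("cpg_body_count must be >= 1")
  bad <- ann$design_type == "II" & ann$channel != "both"
  if (any(bad)) stop("type II probes must have channel 'both': ",
                     paste(utils::head(ann$probe_id[bad], 10), collapse = ", "))
  check_mat <- function(x, nm, range01 = FALSE) {
    if (is.null(x)) return(invisible())
    if (!identical(rownames(x), ann$probe_id)) {
      off <- utils::head(setdiff(union(rownames(x), ann$probe_id),
                                 intersect(rownames(x), ann$probe_id)), 10)
      stop(sprintf("probe ids of `%s` do not match the annotation; offenders: %s",
                   nm, paste(off, collapse = ", ")))
    }
    if (!identical(colnames(x), smp$sample_id)) {
      off <- utils::head(setdiff(union(colnames(x), smp$sample_id),
                                 intersect(colnames(x), smp$sample_id)), 10)
      stop(sprintf("sample ids of `%s` do not match the sample sheet; offenders: %s",
                   nm, paste(off, collapse = ", ")))
    }
    if (range01 && length(x) && (min(x, na.rm = TRUE) < 0 ||
                                 max(x, na.rm = TRUE) > 1)) {
      stop(sprintf("`%s` must lie in [0, 1]", nm))
    }
    invisible()
  }
  check_mat(ds$meth, "meth")
  check_mat(ds$unmeth, "unmeth")
  check_mat(ds$beta, "beta", range01 = TRUE)
  check_mat(ds$detection_p, "detection_p", range01 = TRUE)
  check_mat(ds$bead_count, "bead_count")
  for (nm in c("oob_meth", "oob_unmeth")) {
    x <- ds[[nm]]
    if (is.null(x)) next
    if (!all(rownames(x) %in% ann$probe_id)) {
      off <- utils::head(setdiff(rownames(x), ann$probe_id), 10)
      stop(sprintf("`%s` has probes absent from the annotation: %s",
                   nm, paste(off, collapse = ", ")))
    }
    if (!identical(colnames(x), smp$sample_id)) {
      stop(sprintf("sample ids of `%s` do not match the sample sheet", nm))
    }
  }
  invisible(ds)
}

#' @export
print.methyl_dataset <- function(x, ...) {
  cat(sprintf("<methyl_dataset> %d probes x %d samples\n",
              nrow(x$annotation), nrow(x$samples)))
  cat(sprintf("  type II probes: %d | iDMR probes: %d\n",
              sum(x$annotation$design_type == "II"),
              sum(x$annotation$is_idmr)))
  cat(sprintf("  intensities: %s | detection p: %s | bead counts: %s\n",
              ifelse(is.null(x$meth), "absent", "present"),
              ifelse(is.null(x$detection_p), "absent", "present"),
              ifelse(is.null(x$bead_count), "absent", "present")))
  cat("  provenance:", if (length(x$provenance))
    paste(x$provenance, collapse = " -> ") else "(raw)", "\n")
  invisible(x)
}

#' M values of a dataset
#'
#' @param ds A [methyl_dataset()].
#' @param epsilon Clipping bound passed to [m_from_beta()].
#' @return Matrix of M values, probes x samples.
#' @export
get_mvals <- function(ds, epsilon = 1e-6) m_from_beta(ds$beta, epsilon)

## Append a processing label to the provenance trail.
add_provenance <- function(ds, label) {
  ds$provenance <- c(ds$provenance, label)
  ds
}

## Keep only the given probes (logical or character index), preserving order.
subset_probes <- function(ds, keep) {
  if (is.logical(keep)) keep <- ds$annotation$probe_id[keep]
  idx <- match(keep, ds$annotation$probe_id)
  if (anyNA(idx)) stop("unknown probe ids in subset")
  for (nm in c("meth", "unmeth", "beta", "detection_p", "bead_count")) {
    if (!is.null(ds[[nm]])) ds[[nm]] <- ds[[nm]][keep, , drop = FALSE]
  }
  for (nm in c("oob_meth", "oob_unmeth")) {
    if (!is.null(ds[[nm]])) {
      ds[[nm]] <- ds[[nm]][intersect(keep, rownames(ds[[nm]])), , drop = FALSE]
    }
  }
  ds$annotation <- ds$annotation[idx, , drop = FALSE]
  ds
}

## Replace intensity matrices and recompute beta (offset 100 convention).
set_intensities <- function(ds, meth, unmeth, offset = 100) {
  ds$meth <- meth
  ds$unmeth <- unmeth
  ds$beta <- beta_from_intensities(list(meth = meth, unmeth = unmeth),
                                   offset = offset)
  ds
}
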