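## broom-style tidiers for the fitted objects and reports.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a batch-correction fit
#'
#' One row per probe x batch with the raw and shrunken location/scale
#' estimates.
#'
#' @param x A `combat_fit` from [combat()].
#' @param ... Unused.
#' @return Tibble: `probe_id`, `batch`, `gamma_hat`, `delta_hat`,
#'   `gamma_star`, `delta_star`.
#' @method tidy combat_fit
#' @export
tidy.combat_fit <- function(x, ...) {
  if (isTRUE(x$identity)) {
    return(tibble::tibble(probe_id = character(), batch = character(),
                          gamma_hat = numeric(), delta_hat = numeric(),
                          gamma_star = numeric(), delta_star = numeric()))
  }
  probes <- names(x$grand_mean)
  if (is.null(probes)) probes <- as.character(seq_along(x$grand_mean))
  do.call(rbind, lapply(seq_along(x$batches), function(bi) {
    tibble::tibble(probe_id = probes, batch = x$batches[bi],
                   gamma_hat = x$gamma_hat[, bi],
                   delta_hat = x$delta_hat[, bi],
                   gamma_star = x$gamma_star[, bi],
                   delta_star = x$delta_star[, bi])
  }))
}

#' One-row summary of a batch-correction fit
#' @param x A `combat_fit`.
#' @param ... Unused.
#' @return Tibble with batch count, prior hyperparameter summaries and the
#'   spread of the shrunken batch effects.
#' @method glance combat_fit
#' @export
glance.combat_fit <- function(x, ...) {
  if (isTRUE(x$identity)) {
    return(tibble::tibble(n_batches = 1L, gamma_star_sd = 0,
                          mean_delta_star = 1))
  }
  tibble::tibble(
    n_batches = length(x$batches),
    gamma_star_sd = stats::sd(as.vector(x$gamma_star)),
    mean_delta_star = mean(as.vector(x$delta_star)))
}

#' Tidy a meQTL scan
#' @param x A `meqtl_result` from [meqtl_association()].
#' @param ... Unused.
#' @return The per-SNP association tibble.
#' @method tidy meqtl_result
#' @export
tidy.meqtl_result <- function(x, ...) x$table

#' One-row summary of a meQTL scan
#' @param x A `meqtl_result`.
#' @param ... Unused.
#' @return Tibble: `min_p_adjusted`, `top_snp`, `heritability_ratio`.
#' @method glance meqtl_result
#' @export
glance.meqtl_result <- function(x, ...) {
  tibble::tibble(
    min_p_adjusted = x$min_p_adjusted,
    top_snp = x$table$snp_id[which.min(x$table$p_adjusted)],
    heritability_ratio = x$lmm$ratio)
}

#' Tidy a metric report into its one-row tabular form
#' @param x A `metric_report` from [compute_metrics()].
#' @param ... Unused.
#' @return One-row tibble of the headline metrics.
#' @method tidy metric_report
#' @export
tidy.metric_report <- function(x, ...) tidy_metric_report(x)
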