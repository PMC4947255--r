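## ggplot2 views of the metric battery. Each returns a ggplot object.

#' Beta density plot, one line per sample
#'
#' @param ds A [methyl_dataset()].
#' @param colour_by Sample-sheet column used for line colour.
#' @return A ggplot object.
#' @export
plot_beta_density <- function(ds, colour_by = "batch") {
  dens <- density_summary(ds$beta, ds$annotation)
  df <- do.call(rbind, lapply(seq_len(ncol(dens$density)), function(j) {
    tibble::tibble(beta = dens$grid,
                   density = dens$density[, j],
                   sample_id = colnames(dens$density)[j])
  }))
  df$group <- ds$samples[[colour_by]][match(df$sample_id,
                                            ds$samples$sample_id)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta, y = .data$density,
                                   group = .data$sample_id,
                                   colour = .data$group)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = expression(beta), y = "density", colour = colour_by) +
    ggplot2::theme_minimal()
}

#' MDS plot of samples on the most variable M values
#'
#' @param ds A [methyl_dataset()].
#' @param colour_by Sample-sheet column used for point colour.
#' @param k Number of most-variable probes.
#' @return A ggplot object.
#' @export
plot_mds <- function(ds, colour_by = "batch", k = 1000) {
  mds <- mds_coordinates(get_mvals(ds), k = k)
  df <- tibble::tibble(
    dim1 = mds$coords[, 1], dim2 = mds$coords[, 2],
    group = ds$samples[[colour_by]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                   colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("MDS 1 (%.0f%%)", 100 * mds$variance_share[1]),
      y = sprintf("MDS 2 (%.0f%%)", 100 * mds$variance_share[2]),
      colour = colour_by) +
    ggplot2::theme_minimal()
}

#' QQ plot of age-EWAS p values
#'
#' @param p Per-probe p values (e.g. from [age_ewas_lambda()]).
#' @return A ggplot object annotated with the inflation lambda.
#' @export
plot_ewas_qq <- function(p) {
  n <- length(p)
  obs <- sort(-log10(pmax(p, 1e-300)))
  expd <- sort(-log10((seq_len(n) - 0.5) / n))
  lambda <- stats::median(obs) / stats::median(expd)
  df <- tibble::tibble(expected = expd, observed = obs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::annotate("text", x = min(expd), y = max(obs), hjust = 0,
                      label = sprintf("lambda == %.3f", lambda),
                      parse = TRUE) +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
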