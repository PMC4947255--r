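#' Empirical-Bayes location/scale batch correction (ComBat-style)
#'
#' Standardises each probe with the batch-size-weighted grand mean and
#' pooled scale, estimates per-batch, per-probe location (`gamma`) and scale
#' (`delta^2`) effects, shrinks them with parametric empirical-Bayes priors
#' (normal on `gamma`, inverse-gamma on `delta^2`, hyperparameters by method
#' of moments, jointly iterated to convergence), and removes the shrunken
#' effects. Operates on M values, the variance-stabilised scale used for all
#' statistics in the package.
#'
#' @param mvals Numeric matrix of M values (probes x samples).
#' @param batch Batch labels, one per sample; at least 2 batches with at
#'   least 2 samples each (a single batch returns the input with a warning).
#' @param parametric Only the parametric EB variant is implemented; must be
#'   `TRUE`.
#' @param conv Convergence tolerance of the EB iteration.
#' @return List with `m` (adjusted M-value matrix) and `fit`, a
#'   `combat_fit` object holding the grand mean, pooled variance, batch
#'   design, shrunken `gamma_star`/`delta_star` and the prior
#'   hyperparameters.
#' @export
combat <- function(mvals, batch, parametric = TRUE, conv = 1e-4) {
  stopifnot(is.matrix(mvals), all(is.finite(mvals)))
  if (!parametric) stop("only the parametric EB variant is implemented")
  batch <- as.factor(batch)
  if (length(batch) != ncol(mvals)) {
    stop("`batch` must have one label per sample")
  }
  if (nlevels(batch) == 1) {
    warning("single batch: batch correction is the identity")
    fit <- structure(list(batches = levels(batch), identity = TRUE),
                     class = "combat_fit")
    return(list(m = mvals, fit = fit))
  }
  n_b <- table(batch)
  if (any(n_b < 2)) {
    stop("every batch needs at least 2 samples (scale undefined otherwise)")
  }
  n <- ncol(mvals)
  levs <- levels(batch)
  B <- length(levs)

  batch_means <- vapply(levs, function(b) {
    rowMeans(mvals[, batch == b, drop = FALSE])
  }, numeric(nrow(mvals)))
  grand_mean <- as.vector(batch_means %*% (as.numeric(n_b) / n))
  names(grand_mean) <- rownames(mvals)
  resid <- mvals - batch_means[, as.integer(batch)]
  var_pooled <- rowSums(resid^2) / n
  var_pooled[var_pooled < 1e-12] <- 1e-12

  z <- (mvals - grand_mean) / sqrt(var_pooled)
  gamma_hat <- vapply(levs, function(b) {
    rowMeans(z[, batch == b, drop = FALSE])
  }, numeric(nrow(z)))
  delta_hat <- vapply(levs, function(b) {
    row_vars(z[, batch == b, drop = FALSE])
  }, numeric(nrow(z)))

  gamma_bar <- colMeans(gamma_hat)
  tau2 <- apply(gamma_hat, 2, stats::var)
  a_prior <- apply(delta_hat, 2, function(d) {
    m <- mean(d); s2 <- stats::var(d); (2 * s2 + m^2) / s2
  })
  b_prior <- apply(delta_hat, 2, function(d) {
    m <- mean(d); s2 <- stats::var(d); (m * s2 + m^3) / s2
  })

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (bi in seq_len(B)) {
    nb <- as.numeric(n_b[bi])
    zb <- z[, batch == levs[bi], drop = FALSE]
    g_old <- gamma_hat[, bi]
    d_old <- delta_hat[, bi]
    repeat {
      g_new <- (nb * tau2[bi] * gamma_hat[, bi] + d_old * gamma_bar[bi]) /
        (nb * tau2[bi] + d_old)
      sum2 <- rowSums((zb - g_new)^2)
      d_new <- (0.5 * sum2 + b_prior[bi]) / (nb / 2 + a_prior[bi] - 1)
      change <- max(abs(g_new - g_old) / (abs(g_old) + 1e-12),
                    abs(d_new - d_old) / (abs(d_old) + 1e-12))
      g_old <- g_new
      d_old <- d_new
      if (change < conv) break
    }
    gamma_star[, bi] <- g_old
    delta_star[, bi] <- d_old
  }

  adj <- z
  for (bi in seq_len(B)) {
    cols <- batch == levs[bi]
    adj[, cols] <- (z[, cols, drop = FALSE] - gamma_star[, bi]) /
      sqrt(delta_star[, bi])
  }
  out <- adj * sqrt(var_pooled) + grand_mean
  dimnames(out) <- dimnames(mvals)
  fit <- structure(list(
    batches = levs, n_per_batch = as.integer(n_b),
    grand_mean = grand_mean, var_pooled = var_pooled,
    gamma_hat = gamma_hat, delta_hat = delta_hat,
    gamma_star = gamma_star, delta_star = delta_star,
    gamma_bar = gamma_bar, tau2 = tau2,
    a_prior = a_prior, b_prior = b_prior, identity = FALSE),
    class = "combat_fit")
  list(m = out, fit = fit)
}

#' Apply batch correction to a dataset's beta values via M values
#'
#' Convenience wrapper: transforms beta to M, runs [combat()] with the
#' sample sheet's batch labels, and transforms back.
#'
#' @param ds A [methyl_dataset()].
#' @param ... Passed to [combat()].
#' @return The corrected dataset (provenance label `"combat"`); the fit is
#'   stored in `ds$fits$combat`.
#' @export
apply_combat <- function(ds, ...) {
  res <- combat(get_mvals(ds), ds$samples$batch, ...)
  ds$beta <- beta_from_m(res$m)
  ds$meth <- NULL
  ds$unmeth <- NULL
  ds$fits$combat <- res$fit
  add_provenance(ds, "combat")
}
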