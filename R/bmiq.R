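#' Fit a three-state beta mixture to beta values
#'
#' EM fit of a three-component beta mixture (unmethylated / hemi-methylated /
#' methylated states). Components are initialised from hard assignments at
#' beta thresholds 1/3 and 2/3 with method-of-moments parameters; the M step
#' uses responsibility-weighted moments. Components are kept ordered by mean
#' (U < H < M). A degenerate component (vanishing variance) triggers one
#' re-initialisation, after which the fit is flagged.
#'
#' @param x Numeric vector of beta values in `[0, 1]`.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @return List of class `beta_mixture_fit`: `a`, `b` (shape vectors),
#'   `pi` (weights), `state` (hard assignments 1..3 for `x`), `loglik`,
#'   `iterations`, `converged`, `flagged`.
#' @export
fit_beta_mixture <- function(x, tol = 1e-4, max_iter = 100) {
  eps <- 1e-6
  x <- pmin(pmax(x, eps), 1 - eps)
  n <- length(x)
  if (n < 30) stop("too few beta values to fit a three-state mixture")

  mom <- function(mu, v) {
    v <- min(v, 0.999 * mu * (1 - mu))
    v <- max(v, 1e-8)
    k <- mu * (1 - mu) / v - 1
    c(a = max(mu * k, 1e-3), b = max((1 - mu) * k, 1e-3))
  }
  init_from_thresholds <- function(lo, hi) {
    grp <- findInterval(x, c(lo, hi)) + 1L
    for (k in 1:3) if (sum(grp == k) < 3) {
      grp[order(abs(x - c(0.1, 0.5, 0.9)[k]))[1:3]] <- k
    }
    a <- b <- pi_k <- numeric(3)
    for (k in 1:3) {
      xk <- x[grp == k]
      ab <- mom(mean(xk), max(stats::var(xk), 1e-6))
      a[k] <- ab["a"]; b[k] <- ab["b"]
      pi_k[k] <- mean(grp == k)
    }
    list(a = a, b = b, pi = pi_k)
  }

  run_em <- function(par) {
    ll_old <- -Inf
    converged <- FALSE
    degenerate <- FALSE
    iter <- 0
    resp <- NULL
    for (iter in seq_len(max_iter)) {
      dens <- vapply(1:3, function(k) {
        par$pi[k] * stats::dbeta(x, par$a[k], par$b[k])
      }, numeric(n))
      tot <- rowSums(dens)
      tot[tot < 1e-300] <- 1e-300
      resp <- dens / tot
      ll <- sum(log(tot))
      if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 1)) {
        converged <- TRUE
        ll_old <- ll
        break
      }
      ll_old <- ll
      for (k in 1:3) {
        w <- resp[, k]
        sw <- sum(w)
        if (sw < 1e-8) { degenerate <- TRUE; break }
        mu <- sum(w * x) / sw
        v <- sum(w * (x - mu)^2) / sw
        if (v < 1e-10) { degenerate <- TRUE; break }
        ab <- mom(mu, v)
        par$a[k] <- ab["a"]; par$b[k] <- ab["b"]
        par$pi[k] <- sw / n
      }
      if (degenerate) break
    }
    list(par = par, loglik = ll_old, iterations = iter,
         converged = converged, degenerate = degenerate, resp = resp)
  }

  fit <- run_em(init_from_thresholds(1 / 3, 2 / 3))
  flagged <- FALSE
  if (fit$degenerate) {
    fit <- run_em(init_from_thresholds(0.25, 0.75))
    flagged <- TRUE
  }
  if (!fit$converged) flagged <- TRUE
  par <- fit$par
  ord <- order(par$a / (par$a + par$b))       # means ascending: U < H < M
  par$a <- par$a[ord]; par$b <- par$b[ord]; par$pi <- par$pi[ord]
  resp <- fit$resp[, ord, drop = FALSE]
  structure(list(a = par$a, b = par$b, pi = par$pi,
                 state = max.col(resp), loglik = fit$loglik,
                 iterations = fit$iterations, converged = fit$converged,
                 flagged = flagged),
            class = "beta_mixture_fit")
}

#' Beta-mixture quantile dilation normalisation (BMIQ-style)
#'
#' Per sample, three-state beta mixtures are fitted to the type I and type II
#' beta values. Type II probes assigned to the unmethylated state are
#' remapped by quantile mapping onto the type I unmethylated component
#' (`q = F^II_U(beta)`, `beta' = (F^I_U)^{-1}(q)`); the methylated state is
#' mapped analogously with right-tail orientation; the hemi-methylated state
#' is rescaled by the affine dilation that makes its range abut the
#' transformed U and M ranges. Type I betas are unchanged and all outputs
#' stay in `[0, 1]`.
#'
#' @param ds A [methyl_dataset()] with both probe types present.
#' @param em_tol,em_max_iter EM controls passed to [fit_beta_mixture()].
#' @param fit_sample_size Maximum number of probes per type used to fit the
#'   mixtures (the transform is applied to all probes).
#' @param seed Seed for the fitting subsample.
#' @return The normalised dataset (provenance label `"bmiq"`); per-sample
#'   fits are stored in `ds$fits$bmiq`.
#' @export
norm_bmiq <- function(ds, em_tol = 1e-4, em_max_iter = 100,
                      fit_sample_size = 5000, seed = 1) {
  type2 <- ds$annotation$design_type == "II"
  if (!any(type2) || all(type2)) {
    stop("both probe types are required for beta-mixture normalisation")
  }
  eps <- 1e-6
  beta <- ds$beta
  set.seed(as.integer(seed))
  fits <- vector("list", ncol(beta))
  names(fits) <- colnames(beta)
  for (j in seq_len(ncol(beta))) {
    b1 <- beta[!type2, j]
    b2 <- beta[type2, j]
    sub <- function(v) if (length(v) > fit_sample_size)
      v[sample.int(length(v), fit_sample_size)] else v
    f1 <- fit_beta_mixture(sub(b1), tol = em_tol, max_iter = em_max_iter)
    f2 <- fit_beta_mixture(sub(b2), tol = em_tol, max_iter = em_max_iter)
    ## hard state assignments for every probe under each type's mixture
    classify <- function(b, f) {
      bc <- pmin(pmax(b, eps), 1 - eps)
      dens <- vapply(1:3, function(k) {
        f$pi[k] * stats::dbeta(bc, f$a[k], f$b[k])
      }, numeric(length(bc)))
      max.col(dens)
    }
    s1 <- classify(b1, f1)
    state <- classify(b2, f2)
    out <- b2
    iU <- state == 1
    iH <- state == 2
    iM <- state == 3
    ## quantile-map the U and M states onto the matching type I state
    ## distributions (q = F^II_state(beta), beta' = (F^I_state)^{-1}(q),
    ## realised through the empirical quantile functions; the M state's
    ## right-tail orientation is implicit in the monotone map)
    if (any(iU) && sum(s1 == 1) >= 2) {
      out[iU] <- map_to_reference(b2[iU], sort(b1[s1 == 1]))
    }
    if (any(iM) && sum(s1 == 3) >= 2) {
      out[iM] <- map_to_reference(b2[iM], sort(b1[s1 == 3]))
    }
    if (any(iH)) {
      ## robust range anchors: a stray extreme probe must not squeeze the
      ## whole hemi-methylated mass
      left <- if (any(iU)) stats::quantile(out[iU], 0.995, names = FALSE) else
        stats::qbeta(0.995, f1$a[1], f1$b[1])
      right <- if (any(iM)) stats::quantile(out[iM], 0.005, names = FALSE) else
        stats::qbeta(0.005, f1$a[3], f1$b[3])
      h <- b2[iH]
      lo <- stats::quantile(h, 0.005, names = FALSE)
      hi <- stats::quantile(h, 0.995, names = FALSE)
      if (right > left && hi > lo) {
        out[iH] <- left + (h - lo) / (hi - lo) * (right - left)
      }
    }
    beta[type2, j] <- pmin(pmax(out, 0), 1)
    fits[[j]] <- list(type1 = f1, type2 = f2)
  }
  ds$beta <- beta
  ds$meth <- NULL
  ds$unmeth <- NULL
  ds$fits$bmiq <- fits
  add_provenance(ds, "bmiq")
}
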