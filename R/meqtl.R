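## Biology-preservation metrics: identity-by-state kinship, the
## kinship-adjusted meQTL association, and the age-EWAS inflation lambda.

#' Identity-by-state kinship matrix from genotype dosages
#'
#' `K_ij` is the mean over non-missing SNPs of `(2 - |g_i - g_j|) / 2`,
#' i.e. the average fraction of alleles shared by state.
#'
#' @param genotypes SNPs x samples matrix of 0/1/2 dosages (`NA` allowed);
#'   at least 10 SNPs.
#' @return Symmetric samples x samples matrix with entries in `[0, 1]`.
#' @export
ibs_kinship <- function(genotypes) {
  g <- as.matrix(genotypes)
  if (nrow(g) < 10) stop("at least 10 SNPs are required")
  n <- ncol(g)
  K <- matrix(1, n, n, dimnames = list(colnames(g), colnames(g)))
  for (i in seq_len(n)) {
    for (j in seq_len(i)) {
      ok <- !is.na(g[, i]) & !is.na(g[, j])
      if (!any(ok)) {
        stop(sprintf("samples %d and %d share no non-missing SNPs", i, j))
      }
      K[i, j] <- K[j, i] <- mean((2 - abs(g[ok, i] - g[ok, j])) / 2)
    }
  }
  K
}

## One-variance-ratio LMM y ~ N(mu, sg2 * 2K + se2 * I), fitted by ML with
## the heritability ratio profiled on the eigenbasis of 2K. Returns the
## environmental residuals r = y - mu - BLUP.
lmm_kinship_residuals <- function(y, K, tol = 1e-8) {
  n <- length(y)
  stopifnot(nrow(K) == n, ncol(K) == n)
  eg <- tryCatch(eigen(2 * K, symmetric = TRUE), error = function(e) NULL)
  if (is.null(eg) || min(eg$values) < -1e-6) {
    warning("kinship eigendecomposition unstable; adding ridge 1e-8")
    eg <- eigen(2 * K + diag(1e-8, n), symmetric = TRUE)
  }
  lambda <- pmax(eg$values, 0)
  U <- eg$vectors
  yt <- drop(crossprod(U, y))
  xt <- drop(crossprod(U, rep(1, n)))
  ## profile log-likelihood in the ratio r = sg2 / se2
  prof <- function(log_r) {
    r <- exp(log_r)
    w <- r * lambda + 1
    mu <- sum(xt * yt / w) / sum(xt^2 / w)
    se2 <- sum((yt - mu * xt)^2 / w) / n
    -0.5 * (n * log(2 * pi * se2) + sum(log(w)) + n)
  }
  opt <- stats::optimize(prof, c(-12, 12), maximum = TRUE, tol = tol)
  ## prefer the r = 0 boundary (no genetic variance) when the profile is
  ## flat or the interior gain is within numerical noise — this also covers
  ## the unidentifiable 2K = I case, where residuals must reduce to y - mean
  r <- if (prof(-30) >= opt$objective - 1e-6) 0 else exp(opt$maximum)
  w <- r * lambda + 1
  mu <- sum(xt * yt / w) / sum(xt^2 / w)
  resid_rot <- (yt - mu * xt) / w      # environmental part in eigenbasis
  r_env <- drop(U %*% resid_rot)
  se2 <- sum((yt - mu * xt)^2 / w) / n
  list(residuals = r_env, mu = mu, ratio = r,
       sigma_g2 = r * se2, sigma_e2 = se2)
}

#' Kinship-adjusted meQTL association scan
#'
#' Two-stage analysis of a candidate methylation probe against SNPs in a
#' cis window. Stage 1 fits the linear mixed model
#' `y ~ N(mu, sigma_g^2 * 2K + sigma_e^2 * I)` by maximum likelihood
#' (profiling the single variance ratio on the kinship eigenbasis) and
#' extracts the environmental residuals (phenotype minus mean and BLUP).
#' Stage 2 regresses those residuals on each SNP's additive dosage by OLS
#' with a two-sided t test; Bonferroni adjustment multiplies by the number
#' of SNPs. Monomorphic SNPs are recorded with p = 1.
#'
#' @param y Named numeric vector: methylation (M value or beta) of the
#'   target probe per sample.
#' @param genotypes SNPs x samples dosage matrix; sample columns must cover
#'   the names of `y`.
#' @param kinship Symmetric kinship matrix over the same samples.
#' @return List of class `meqtl_result`: `table` (tibble: `snp_id`, `beta`,
#'   `se`, `t`, `p`, `p_adjusted`), `min_p_adjusted`, `lmm` (stage-1 fit
#'   summary).
#' @export
meqtl_association <- function(y, genotypes, kinship) {
  ids <- names(y)
  if (is.null(ids)) stop("`y` must be named by sample id")
  if (length(ids) < 10) stop("at least 10 samples are required")
  g <- as.matrix(genotypes)[, ids, drop = FALSE]
  K <- as.matrix(kinship)[ids, ids]
  lmm <- lmm_kinship_residuals(as.numeric(y), K)
  r <- lmm$residuals
  n <- length(r)
  n_snps <- nrow(g)
  out <- tibble::tibble(
    snp_id = rownames(g),
    beta = NA_real_, se = NA_real_, t = NA_real_, p = 1)
  for (s in seq_len(n_snps)) {
    x <- g[s, ]
    if (stats::sd(x) < 1e-12) next               # monomorphic: p = 1
    fit <- stats::lm(r ~ x)
    cf <- summary(fit)$coefficients
    out$beta[s] <- cf["x", "Estimate"]
    out$se[s] <- cf["x", "Std. Error"]
    out$t[s] <- cf["x", "t value"]
    out$p[s] <- cf["x", "Pr(>|t|)"]
  }
  out$p_adjusted <- pmin(1, out$p * n_snps)
  structure(list(table = out,
                 min_p_adjusted = min(out$p_adjusted),
                 lmm = lmm[c("mu", "ratio", "sigma_g2", "sigma_e2")]),
            class = "meqtl_result")
}

#' Epigenome-wide association with age and inflation lambda
#'
#' Per probe, a simple linear regression of methylation on age with a
#' two-sided t test of the slope. The inflation lambda is the median of the
#' observed `-log10 p` values divided by the median of the expected values
#' under uniformity (order statistics `(i - 0.5) / n`). Lambda near 1 means
#' no systematic signal; above ~1.2 the scan carries genuine (or residual
#' technical) association.
#'
#' @param mat Matrix (probes x samples) of M values (or betas).
#' @param ages Numeric ages, one per sample, non-constant.
#' @return List with `p` (per-probe p values), `lambda`.
#' @export
age_ewas_lambda <- function(mat, ages) {
  stopifnot(length(ages) == ncol(mat))
  if (stats::sd(ages) < 1e-12) stop("ages must not be constant")
  n <- ncol(mat)
  x <- ages - mean(ages)
  sxx <- sum(x^2)
  yc <- mat - rowMeans(mat)
  b <- drop(yc %*% x) / sxx
  rss <- rowSums(yc^2) - b^2 * sxx
  rss[rss < 0] <- 0
  sigma2 <- rss / (n - 2)
  se <- sqrt(sigma2 / sxx)
  tstat <- ifelse(se > 0, b / se, 0)
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[se == 0] <- 1                                 # constant probes
  np <- length(p)
  expected <- -log10((seq_len(np) - 0.5) / np)
  lambda <- stats::median(-log10(pmax(p, 1e-300))) / stats::median(expected)
  list(p = p, lambda = lambda)
}
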