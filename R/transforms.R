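#' Convert methylated/unmethylated intensities to beta values
#'
#' The proportion-methylated scale used throughout the Infinium platform:
#' \eqn{\beta = M / (M + U + a)} where `M` and `U` are the methylated and
#' unmethylated fluorescence intensities and `a` is a small regularising
#' offset that keeps scores stable when both signals are close to zero.
#'
#' @param intensities A [methyl_dataset()] or a list with numeric matrices
#'   `meth` and `unmeth` (probes x samples, identical dimnames).
#' @param offset Non-negative regularising constant added to the denominator.
#'   The platform convention is 100.
#' @return A numeric matrix of beta values in `[0, 1)` (in `[0, 1]` when
#'   `offset = 0`), carrying the input dimnames.
#' @examples
#' x <- list(meth = matrix(c(100, 900), 2, 1), unmeth = matrix(c(100, 0), 2, 1))
#' beta_from_intensities(x)          # 1/3 and 0.9
#' @export
beta_from_intensities <- function(intensities, offset = 100) {
  stopifnot(is.numeric(offset), length(offset) == 1, offset >= 0)
  meth <- intensities$meth
  unmeth <- intensities$unmeth
  if (is.null(meth) || is.null(unmeth)) {
    stop("`intensities` must contain `meth` and `unmeth` matrices")
  }
  if (!identical(dim(meth), dim(unmeth))) {
    stop("`meth` and `unmeth` must have identical dimensions")
  }
  bad <- which(!is.finite(meth) | !is.finite(unmeth) | meth < 0 | unmeth < 0,
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    pr <- rownames(meth)[bad[1, 1]]
    sm <- colnames(meth)[bad[1, 2]]
    stop(sprintf(
      "negative or non-finite intensity at probe '%s', sample '%s' (%d offending entries)",
      if (is.null(pr)) bad[1, 1] else pr,
      if (is.null(sm)) bad[1, 2] else sm, nrow(bad)))
  }
  denom <- meth + unmeth + offset
  beta <- meth / denom
  beta[denom == 0] <- 0
  dimnames(beta) <- dimnames(meth)
  beta
}

#' Beta to M-value (base-2 logit) transform
#'
#' M values, \eqn{m = \log_2(\beta / (1 - \beta))}, stabilise the severe
#' heteroskedasticity that beta values show near 0 and 1 and are the scale on
#' which the package's statistics operate. Betas are clipped to
#' `[epsilon, 1 - epsilon]` first so the transform is total.
#'
#' @param beta Numeric matrix (or vector) of beta values in `[0, 1]`.
#' @param epsilon Clipping bound, `0 < epsilon < 0.5`.
#' @return Matrix (or vector) of finite M values.
#' @examples
#' m_from_beta(c(0.2, 0.5, 0.8))   # -2, 0, 2
#' @export
m_from_beta <- function(beta, epsilon = 1e-6) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1,
            epsilon > 0, epsilon < 0.5)
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  m <- log2(b / (1 - b))
  if (is.matrix(beta)) dimnames(m) <- dimnames(beta)
  m
}

#' M-value to beta transform
#'
#' Inverse of [m_from_beta()] away from the clipping region:
#' \eqn{\beta = 2^m / (1 + 2^m)}.
#'
#' @param m Numeric matrix (or vector) of finite M values.
#' @return Matrix (or vector) of beta values in `(0, 1)`.
#' @export
beta_from_m <- function(m) {
  stopifnot(all(is.finite(m)))
  beta <- stats::plogis(m * log(2))
  if (is.matrix(m)) dimnames(beta) <- dimnames(m)
  beta
}

#' Most variable probes of a matrix
#'
#' Ranks probes (rows) by decreasing cross-sample variance, breaking ties by
#' lexical probe id, and returns the top `k` probe ids. Used by the MDS and
#' PC-ANOVA metrics, which operate on the 1000 most variable sites.
#'
#' @param x Numeric matrix, probes x samples, with rownames.
#' @param k Number of probes to return (`0 < k <=` `nrow(x)`).
#' @return Character vector of `k` probe ids, most variable first.
#' @export
top_variable_probes <- function(x, k = 1000) {
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  if (!is.numeric(k) || length(k) != 1 || k <= 0) {
    stop("`k` must be a positive integer")
  }
  if (k > nrow(x)) stop("`k` exceeds the number of probes")
  v <- row_vars(x)
  ids <- rownames(x)
  ord <- order(-v, ids)
  ids[ord][seq_len(k)]
}

## Row variances without a matrixStats dependency.
row_vars <- function(x) {
  n <- ncol(x)
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1)
}
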