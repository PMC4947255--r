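#' Quantile normalisation kernel
#'
#' Forces every column's distribution to the cross-column mean of sorted
#' values (the common reference distribution). Ties receive the mean of
#' their rank-range reference values (average ranks, linearly interpolated
#' into the reference), so column-wise rank order is preserved.
#'
#' @param x Numeric matrix with at least 2 columns and no missing values.
#' @return Matrix of the same shape; every column's sorted values equal the
#'   reference distribution.
#' @export
quantile_normalize <- function(x) {
  stopifnot(is.matrix(x), !anyNA(x))
  if (ncol(x) < 2) {
    warning("quantile normalisation of a single column is the identity")
    return(x)
  }
  n <- nrow(x)
  ref <- rowMeans(apply(x, 2, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    rk <- rank(x[, j], ties.method = "average")
    out[, j] <- stats::approx(seq_len(n), ref, xout = rk)$y
  }
  dimnames(out) <- dimnames(x)
  out
}

## Map values onto a sorted reference distribution by their (average) ranks,
## interpolating the reference quantile function.
map_to_reference <- function(x, ref) {
  n_ref <- length(ref)
  p <- (rank(x, ties.method = "average") - 0.5) / length(x)
  stats::approx((seq_len(n_ref) - 0.5) / n_ref, ref, xout = p, rule = 2)$y
}

#' Global quantile normalisation of intensities
#'
#' Quantile-normalises the methylated and unmethylated intensity matrices
#' separately across samples, then recomputes beta values.
#'
#' @param ds A [methyl_dataset()] with intensities present.
#' @return The normalised dataset (provenance label `"qn"`).
#' @export
norm_qn <- function(ds) {
  if (is.null(ds$meth)) stop("intensities are required for quantile normalisation")
  ds <- set_intensities(ds, quantile_normalize(ds$meth),
                        quantile_normalize(ds$unmeth))
  add_provenance(ds, "qn")
}

#' Stratified quantile normalisation
#'
#' Within each genomic region stratum (island / shore-shelf / open sea), the
#' type II intensities are quantile-normalised across samples and each
#' sample's type I intensities are then mapped by monotone interpolation onto
#' the stratum's type II reference quantile function. No background
#' correction is applied; betas are recomputed with the standard offset.
#' Strata with fewer than 2 type II probes fall back to the global type II
#' reference with a warning.
#'
#' @param ds A [methyl_dataset()] with intensities and annotation present.
#' @return The normalised dataset (provenance label `"stratified_qn"`).
#' @export
norm_stratified_qn <- function(ds) {
  if (is.null(ds$meth)) stop("intensities are required")
  ann <- ds$annotation
  type2 <- ann$design_type == "II"
  meth <- ds$meth
  unmeth <- ds$unmeth
  for (stratum in unique(ann$region_stratum)) {
    in_str <- ann$region_stratum == stratum
    i2 <- which(in_str & type2)
    i1 <- which(in_str & !type2)
    use_global <- length(i2) < 2
    if (use_global) {
      warning(sprintf(
        "stratum '%s' has fewer than 2 type II probes; using the global type II reference",
        stratum))
    }
    for (ch in c("meth", "unmeth")) {
      x <- if (ch == "meth") meth else unmeth
      ref_idx <- if (use_global) which(type2) else i2
      ref <- rowMeans(apply(x[ref_idx, , drop = FALSE], 2, sort))
      if (length(i2) >= 2) {
        x[i2, ] <- quantile_normalize(x[i2, , drop = FALSE])
      }
      if (length(i1)) {
        for (j in seq_len(ncol(x))) {
          x[i1, j] <- map_to_reference(x[i1, j], ref)
        }
      }
      if (ch == "meth") meth <- x else unmeth <- x
    }
  }
  ds <- set_intensities(ds, meth, unmeth)
  add_provenance(ds, "stratified_qn")
}

#' Subset-quantile within-array normalisation (SWAN-style)
#'
#' For each sample and channel, draws per CpG-body-count class (1, 2, 3+)
#' equal-sized random subsets from the type I and type II probes, builds the
#' mean quantile distribution over the pooled subsets, and adjusts each
#' probe type's intensities to it by monotone interpolation between flanking
#' subset values. Empty count classes in either type are dropped with a
#' warning.
#'
#' @param ds A [methyl_dataset()] with intensities and `cpg_body_count`.
#' @param seed Integer seed controlling the random subsets.
#' @return The normalised dataset (provenance label `"swan"`).
#' @export
norm_swan <- function(ds, seed = 1) {
  if (is.null(ds$meth)) stop("intensities are required")
  ann <- ds$annotation
  cls <- pmin(ann$cpg_body_count, 3L)           # classes 1, 2, 3+
  type2 <- ann$design_type == "II"
  set.seed(as.integer(seed))
  meth <- ds$meth
  unmeth <- ds$unmeth
  n_s <- ncol(meth)
  for (j in seq_len(n_s)) {
    sub1 <- integer(0)
    sub2 <- integer(0)
    for (k in 1:3) {
      c1 <- which(!type2 & cls == k)
      c2 <- which(type2 & cls == k)
      if (!length(c1) || !length(c2)) {
        warning(sprintf("CpG count class %d empty in one probe type; dropped", k))
        next
      }
      sz <- min(length(c1), length(c2))
      sub1 <- c(sub1, if (length(c1) == sz) c1 else sample(c1, sz))
      sub2 <- c(sub2, if (length(c2) == sz) c2 else sample(c2, sz))
    }
    if (length(sub1) < 2) stop("too few subset probes for SWAN")
    for (ch in c("meth", "unmeth")) {
      x <- if (ch == "meth") meth[, j] else unmeth[, j]
      s1 <- sort(x[sub1])
      s2 <- sort(x[sub2])
      ref <- (s1 + s2) / 2
      x1 <- stats::approx(s1, ref, xout = x[!type2], rule = 2,
                          ties = mean)$y
      x2 <- stats::approx(s2, ref, xout = x[type2], rule = 2,
                          ties = mean)$y
      x[!type2] <- x1
      x[type2] <- x2
      if (ch == "meth") meth[, j] <- x else unmeth[, j] <- x
    }
  }
  ds <- set_intensities(ds, meth, unmeth)
  add_provenance(ds, "swan")
}

## Mode of a kernel density fitted to the low-intensity half of x.
density_mode_low <- function(x) {
  lo <- x[x <= stats::quantile(x, 0.5)]
  d <- stats::density(lo, n = 512)
  d$x[which.max(d$y)]
}

#' Dasen-style normalisation
#'
#' Per sample, the type I background level (kernel-density mode of the low
#' intensities) is shifted to match the type II background; methylated and
#' unmethylated intensities are then quantile-normalised across samples
#' within each probe type separately.
#'
#' @param ds A [methyl_dataset()] with intensities and `design_type`.
#' @return The normalised dataset (provenance label `"dasen"`).
#' @export
norm_dasen <- function(ds) {
  if (is.null(ds$meth)) stop("intensities are required")
  type2 <- ds$annotation$design_type == "II"
  meth <- ds$meth
  unmeth <- ds$unmeth
  one_type <- !any(type2) || all(type2)
  if (!one_type) {
    for (ch in c("meth", "unmeth")) {
      x <- if (ch == "meth") meth else unmeth
      for (j in seq_len(ncol(x))) {
        shift <- density_mode_low(x[type2, j]) - density_mode_low(x[!type2, j])
        x[!type2, j] <- pmax(x[!type2, j] + shift, 0)
      }
      if (ch == "meth") meth <- x else unmeth <- x
    }
  }
  for (idx in list(which(!type2), which(type2))) {
    if (length(idx) < 2) next
    meth[idx, ] <- quantile_normalize(meth[idx, , drop = FALSE])
    unmeth[idx, ] <- quantile_normalize(unmeth[idx, , drop = FALSE])
  }
  ds <- set_intensities(ds, meth, unmeth)
  add_provenance(ds, "dasen")
}
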