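## The evaluation battery: density/probe-type alignment, MDS, PC1 ANOVA,
## replicate MAD, DMRSE, batch-cluster agreement.

## Two-sample Kolmogorov-Smirnov distance (no p value, tie-safe).
ks_distance <- function(x, y) {
  x <- sort(x); y <- sort(y)
  all_v <- sort(unique(c(x, y)))
  fx <- findInterval(all_v, x) / length(x)
  fy <- findInterval(all_v, y) / length(y)
  max(abs(fx - fy))
}

#' Per-sample beta density summaries and probe-type alignment
#'
#' Evaluates each sample's Gaussian-kernel beta density (Silverman
#' bandwidth) on a fixed grid over `[0, 1]` (step 0.005) and the
#' Kolmogorov-Smirnov distance between the pooled type I and type II beta
#' values — the quantitative form of the "probe types aligned" density
#' plot.
#'
#' @param beta Beta-value matrix (probes x samples).
#' @param annotation Probe annotation with `design_type`.
#' @return List with `grid`, `density` (samples x grid tibble-friendly
#'   matrix) and `ks_type` (scalar KS distance).
#' @export
density_summary <- function(beta, annotation) {
  grid <- seq(0, 1, by = 0.005)
  dens <- vapply(seq_len(ncol(beta)), function(j) {
    stats::density(beta[, j], bw = "nrd0", from = 0, to = 1,
                   n = length(grid))$y
  }, numeric(length(grid)))
  colnames(dens) <- colnames(beta)
  type2 <- annotation$design_type == "II"
  ks <- ks_distance(as.vector(beta[!type2, , drop = FALSE]),
                    as.vector(beta[type2, , drop = FALSE]))
  list(grid = grid, density = dens, ks_type = ks)
}

#' Classical MDS coordinates of samples
#'
#' Classical multidimensional scaling (principal coordinates) of Euclidean
#' distances between samples on the `k` most variable M-value rows; the top
#' two axes are returned scaled by the square root of their eigenvalues,
#' with each axis signed so its first nonzero loading is positive.
#'
#' @param mvals M-value matrix (probes x samples), at least 3 samples.
#' @param k Number of most-variable probes to use (capped at `nrow`).
#' @return List with `coords` (samples x 2 matrix) and `variance_share`
#'   (length-2 numeric).
#' @export
mds_coordinates <- function(mvals, k = 1000) {
  if (ncol(mvals) < 3) stop("at least 3 samples are required")
  k <- min(k, nrow(mvals))
  top <- top_variable_probes(mvals, k)
  d <- stats::dist(t(mvals[top, , drop = FALSE]))
  fit <- stats::cmdscale(d, k = 2, eig = TRUE)
  coords <- fit$points
  for (j in seq_len(ncol(coords))) {
    nz <- which(abs(coords[, j]) > 1e-12)
    if (length(nz) && coords[nz[1], j] < 0) coords[, j] <- -coords[, j]
  }
  pos <- pmax(fit$eig, 0)
  list(coords = coords,
       variance_share = pos[1:2] / sum(pos))
}

#' ANOVA p value of a grouping on the first principal component
#'
#' PCA on the `k` most variable beta rows (samples as observations,
#' centred), then a one-way ANOVA F test of PC1 against the labels. A small
#' p value means the leading axis of variation is explained by the grouping
#' (batch before correction, ideally not after).
#'
#' @param beta Beta-value matrix (probes x samples).
#' @param labels Factor-like grouping, >= 2 levels with >= 2 samples each.
#' @param k Number of most-variable probes (capped at `nrow`).
#' @return The ANOVA p value.
#' @export
pc_anova <- function(beta, labels, k = 1000) {
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("at least 2 label levels are required")
  if (any(table(labels) < 2)) stop("every level needs at least 2 samples")
  k <- min(k, nrow(beta))
  top <- top_variable_probes(beta, k)
  pc <- stats::prcomp(t(beta[top, , drop = FALSE]), center = TRUE,
                      scale. = FALSE)
  pc1 <- pc$x[, 1]
  if (stats::sd(pc1) < 1e-12) return(1)
  fit <- stats::aov(pc1 ~ labels)
  p <- summary(fit)[[1]][["Pr(>F)"]][1]
  if (!is.finite(p)) p <- 1
  p
}

#' Median absolute M-value differences between technical replicates
#'
#' For each replicate pair, the median over probes of the absolute M-value
#' difference; groups with more than two members are evaluated pairwise.
#' Lower is better: replicates are biologically identical, so any
#' difference is technical.
#'
#' @param mvals M-value matrix (probes x samples).
#' @param replicate_group Per-sample group labels (`NA` for unreplicated
#'   samples), aligned with `colnames(mvals)`.
#' @return Tibble with columns `group`, `sample_1`, `sample_2`, `mad`.
#' @export
replicate_mad <- function(mvals, replicate_group) {
  stopifnot(length(replicate_group) == ncol(mvals))
  groups <- unique(replicate_group[!is.na(replicate_group) &
                                     replicate_group != ""])
  rows <- list()
  for (g in groups) {
    members <- which(!is.na(replicate_group) & replicate_group == g)
    if (length(members) < 2) {
      warning(sprintf("replicate group '%s' has a missing member; skipped", g))
      next
    }
    prs <- utils::combn(members, 2)
    for (p in seq_len(ncol(prs))) {
      i <- prs[1, p]; j <- prs[2, p]
      rows[[length(rows) + 1]] <- tibble::tibble(
        group = g,
        sample_1 = colnames(mvals)[i],
        sample_2 = colnames(mvals)[j],
        mad = stats::median(abs(mvals[, i] - mvals[, j])))
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(group = character(), sample_1 = character(),
                          sample_2 = character(), mad = numeric()))
  }
  do.call(rbind, rows)
}

#' Imprinted-region standard error (DMRSE)
#'
#' Imprinted differentially methylated regions are hemi-methylated (beta
#' near 0.5) in all individuals, so between-sample dispersion there is
#' technical. Each iDMR probe row is centred by its cross-sample mean, each
#' sample's mean deviation is taken, and DMRSE is the standard deviation
#' (n-1) of those per-sample means divided by the square root of the number
#' of iDMR probes.
#'
#' @param beta Beta-value matrix (probes x samples), >= 2 samples.
#' @param is_idmr Logical per-probe iDMR flag aligned with the rows.
#' @return Scalar DMRSE (>= 0).
#' @export
dmrse <- function(beta, is_idmr) {
  stopifnot(length(is_idmr) == nrow(beta))
  if (!any(is_idmr)) stop("no iDMR probes present")
  if (ncol(beta) < 2) stop("at least 2 samples are required")
  b <- beta[is_idmr, , drop = FALSE]
  centred <- b - rowMeans(b)
  sample_means <- colMeans(centred)
  stats::sd(sample_means) / sqrt(nrow(b))
}

#' Hierarchical-cluster agreement with a grouping
#'
#' Agglomerative clustering (Euclidean distance on all probes, complete
#' linkage) cut at the number of label levels; agreement is the adjusted
#' Rand index between the cut and the labels. Against batch labels, 1 means
#' samples cluster purely by batch (bad after correction) and values near 0
#' mean the batch structure is gone.
#'
#' @param mvals M-value matrix (probes x samples), >= 3 samples.
#' @param labels Grouping labels, one per sample.
#' @return List with `dendrogram` (an `hclust`) and `ari`.
#' @export
cluster_batch_agreement <- function(mvals, labels) {
  if (ncol(mvals) < 3) stop("at least 3 samples are required")
  labels <- as.factor(labels)
  hc <- stats::hclust(stats::dist(t(mvals)), method = "complete")
  cut <- stats::cutree(hc, k = nlevels(labels))
  list(dendrogram = hc,
       ari = mclust::adjustedRandIndex(cut, labels))
}
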