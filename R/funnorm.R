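## Control-probe functional normalisation: regress each quantile anchor of
## the intensity distributions on principal components of control-probe
## summaries and subtract the fitted technical deviations.

## Per-sample control summaries: mean and sd per (control_type, channel).
control_summaries <- function(controls, sample_ids) {
  key <- interaction(controls$control_type, controls$channel, drop = TRUE)
  feats <- lapply(levels(key), function(k) {
    rows <- key == k
    m <- vapply(sample_ids, function(s) mean(controls[[s]][rows]), numeric(1))
    s <- vapply(sample_ids, function(s) stats::sd(controls[[s]][rows]), numeric(1))
    cbind(m, s)
  })
  out <- do.call(cbind, feats)
  colnames(out) <- unlist(lapply(levels(key), function(k)
    paste(k, c("mean", "sd"), sep = ".")))
  rownames(out) <- sample_ids
  out
}

#' Functional normalisation from control probes (funnorm-style)
#'
#' Summarises the control probes per sample (mean and sd per control type
#' and channel), takes the first `n_pcs` principal components of the
#' standardised summaries, and, for each stratum (methylated/unmethylated
#' intensities crossed with probe type I/II), regresses each empirical
#' quantile anchor across samples on the components. The fitted technical
#' deviations are subtracted (keeping the across-sample mean quantile), the
#' adjusted quantile functions are made non-decreasing, and probe
#' intensities are mapped through them by monotone interpolation.
#'
#' @param ds A [methyl_dataset()] with intensities and a control table.
#' @param n_pcs Number of control principal components to remove
#'   (`0` leaves the data untouched).
#' @param n_quantile_anchors Number of quantile anchors per stratum.
#' @return The normalised dataset (provenance label `"funnorm"`).
#' @export
norm_funnorm <- function(ds, n_pcs = 2, n_quantile_anchors = 500) {
  if (is.null(ds$meth)) stop("intensities are required")
  if (is.null(ds$controls)) stop("control probes are required")
  if (n_pcs == 0) return(add_provenance(ds, "funnorm"))
  sample_ids <- ds$samples$sample_id
  if (length(sample_ids) < n_pcs + 2) {
    stop("need at least n_pcs + 2 samples")
  }
  feats <- control_summaries(ds$controls, sample_ids)
  keep <- apply(feats, 2, stats::sd) > 1e-12
  if (!any(keep)) stop("control summaries are constant; nothing to model")
  pcs <- stats::prcomp(scale(feats[, keep, drop = FALSE]),
                       center = FALSE, scale. = FALSE)$x
  n_pcs <- min(n_pcs, ncol(pcs))
  Z <- scale(pcs[, seq_len(n_pcs), drop = FALSE], center = TRUE, scale = FALSE)

  probs <- seq(0, 1, length.out = n_quantile_anchors)
  type2 <- ds$annotation$design_type == "II"
  meth <- ds$meth
  unmeth <- ds$unmeth
  for (ch in c("meth", "unmeth")) {
    x <- if (ch == "meth") meth else unmeth
    for (idx in list(which(!type2), which(type2))) {
      if (length(idx) < 2) next
      Q <- t(apply(x[idx, , drop = FALSE], 2, stats::quantile, probs = probs,
                   names = FALSE))                   # samples x anchors
      B <- qr.solve(Z, Q)                            # least squares per anchor
      Qadj <- Q - Z %*% B
      for (j in seq_along(sample_ids)) {
        qa <- cummax(Qadj[j, ])                      # enforce monotone
        x[idx, j] <- stats::approx(Q[j, ], qa, xout = x[idx, j],
                                   rule = 2, ties = mean)$y
      }
    }
    if (ch == "meth") meth <- x else unmeth <- x
  }
  ds <- set_intensities(ds, pmax(meth, 0), pmax(unmeth, 0))
  add_provenance(ds, "funnorm")
}
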