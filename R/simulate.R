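#' Configuration for the synthetic 450k-style data generator
#'
#' The defaults emulate the familial blood study the evaluation battery
#' assumes: 45 unique individuals from 4 families on 3 batches, 5 extra
#' replicate arrays forming 6 cross-batch replicate pairs, 227
#' hemi-methylated imprinted-region (iDMR) probes, a 72% type II probe mix
#' with type II betas compressed toward 0.5, per-probe batch location shifts
#' of 1 M-unit and mild batch scale effects, a planted cis-meQTL, and
#' age-associated drift in 20% of probes. Intensity generation follows a
#' normal (background) + exponential-sum (signal) convolution so that
#' out-of-band background correction is correctly specified.
#'
#' @param n_probes Number of probes.
#' @param frac_type2 Fraction of type II probes.
#' @param strata_props Named proportions for `island`, `shore_shelf`,
#'   `open_sea` region strata.
#' @param frac_sex Fraction of probes placed on sex chromosomes.
#' @param n_idmr Number of imprinted-region probes (forced hemi-methylated,
#'   mean beta 0.5).
#' @param n_samples Number of unique individuals.
#' @param n_replicate_pairs Number of cross-batch technical replicate pairs;
#'   the default 6 is realised as replicate array groups of sizes (3,2,2,2),
#'   i.e. 5 extra arrays.
#' @param n_batches,n_families Numbers of processing batches and families.
#' @param batch_shift_sd Per-probe, per-batch location shift sd on the
#'   M-value scale (gamma).
#' @param batch_scale_sdlog Lognormal sdlog of the per-batch residual scale
#'   factor (delta; mean approximately 1).
#' @param type2_compression Factor `c` in (0, 1] compressing type II betas
#'   toward 0.5 before intensity generation.
#' @param bg_mean,bg_sd Background fluorescence mean and sd (a.u.).
#' @param signal_mean Exponential mean of each allele channel's specific
#'   signal (a.u.); total probe signal is the sum of the two channels.
#' @param sample_scale_sdlog,sample_bg_sdlog,dye_sdlog Lognormal sdlogs of
#'   per-array overall intensity scale, background level and meth-channel
#'   (dye-like) imbalance.
#' @param probe_wobble_sdlog Lognormal sdlog of per-probe-per-array signal
#'   wobble around the probe's affinity.
#' @param bio_sd Biological inter-individual sd on the M scale; individuals
#'   are correlated through twice the kinship matrix.
#' @param tech_sd Technical (per-array) M-value noise sd, scaled by the
#'   batch delta.
#' @param meqtl_effect Planted meQTL additive effect per allele, M-value
#'   units, on one hemi-methylated target probe.
#' @param n_snps Number of SNPs in the 2-Mb window around the target probe.
#' @param snp_maf Minor allele frequency of the window SNPs.
#' @param ld_rho AR(1) latent correlation between adjacent SNPs.
#' @param window_bp Width of the SNP window (bp).
#' @param n_age_probes Number of probes given age slopes.
#' @param age_slope_sd sd of the age slopes (M-units per year).
#' @param kinship_model `"exchangeable"` (within-family kinship
#'   `fam_kinship`) or `"pedigree"` (founder-couple pedigrees per family).
#' @param fam_kinship Within-family kinship coefficient for the exchangeable
#'   model (0.25 = full sibs).
#' @param detection_fail_rate Per-entry probability of signal dropout
#'   (drives high detection p values).
#' @param beadcount_low_rate Per-entry probability of a sporadic bead count
#'   below 3 (too thinly spread to trip the probe filter).
#' @param beadcount_bad_probe_frac Fraction of probes with a bead-level
#'   defect: each such probe draws a bead count below 3 in a Binomial(n,
#'   0.3) subset of samples, the clustered failure mode the bead filter is
#'   designed to catch.
#' @param n_controls Negative-control probes per colour channel.
#' @param state_props Proportions of unmethylated / hemi / methylated
#'   baseline probe states.
#' @return A `simulate_config` list.
#' @export
simulate_config <- function(
    n_probes = 10000, frac_type2 = 0.72,
    strata_props = c(island = 0.31, shore_shelf = 0.33, open_sea = 0.36),
    frac_sex = 0.02,
    n_idmr = 227, n_samples = 45, n_replicate_pairs = 6,
    n_batches = 3, n_families = 4,
    batch_shift_sd = 1.0, batch_scale_sdlog = 0.1,
    type2_compression = 0.8,
    bg_mean = 500, bg_sd = 100, signal_mean = 3000,
    sample_scale_sdlog = 0.15, sample_bg_sdlog = 0.2, dye_sdlog = 0.08,
    probe_wobble_sdlog = 0.1,
    bio_sd = 0.3, tech_sd = 0.2,
    meqtl_effect = 0.8, n_snps = 50, snp_maf = 0.4, ld_rho = 0.7,
    window_bp = 2e6,
    n_age_probes = 2000, age_slope_sd = 0.02,
    kinship_model = c("exchangeable", "pedigree"), fam_kinship = 0.25,
    detection_fail_rate = 0.002, beadcount_low_rate = 5e-4,
    beadcount_bad_probe_frac = 0.001,
    n_controls = 300,
    state_props = c(unmeth = 0.4, hemi = 0.2, meth = 0.4)) {
  kinship_model <- match.arg(kinship_model)
  cfg <- as.list(environment())
  stopifnot(n_probes > 0, frac_type2 >= 0, frac_type2 <= 1,
            abs(sum(strata_props) - 1) < 1e-8,
            n_idmr >= 0, n_idmr <= n_probes,
            n_samples > 0, n_batches >= 1, n_families >= 1,
            type2_compression > 0, type2_compression <= 1,
            snp_maf > 0, snp_maf < 1, n_age_probes <= n_probes)
  if (n_replicate_pairs > 0 && n_samples < max(4, n_replicate_pairs)) {
    stop("more replicate pairs than the sample size supports")
  }
  structure(cfg, class = "simulate_config")
}

## Deterministic per-stage sub-streams: reseeding per stage keeps sample-level
## draws stable when probe-level settings change.
stage_seed <- function(seed, stage) {
  set.seed((as.integer(seed) %% 100000000L) + 1000003L * stage)
}

## Replicate-group array counts realising `p` pairwise pairs.
replicate_group_sizes <- function(p) {
  if (p <= 0) return(integer())
  if (p >= 4) c(3L, rep(2L, p - 3L)) else rep(2L, p)
}

logit2 <- function(b) log2(b / (1 - b))

ar1_normal <- function(n, rho) {
  z <- numeric(n)
  z[1] <- stats::rnorm(1)
  if (n > 1) for (k in 2:n) {
    z[k] <- rho * z[k - 1] + sqrt(1 - rho^2) * stats::rnorm(1)
  }
  z
}

#' Simulate a familial 450k-style dataset with ground truth
#'
#' Generates a [methyl_dataset()] (intensities, out-of-band signals,
#' negative controls, detection p values, bead counts) together with a
#' `sim_truth` list recording every planted effect, for parameter-recovery
#' and power studies. Fully deterministic given `(config, seed)`.
#'
#' The recipe: baseline probe states (unmeth/hemi/meth beta centres; iDMR
#' probes hemi with mean 0.5); a family-structured biological effect on the M
#' scale with covariance `2 K bio_sd^2`; a planted cis-meQTL on one
#' hemi-methylated probe with HWE genotypes in an LD window; age slopes on a
#' subset of probes (ages uniform on 23-89); per-probe-per-batch location
#' shifts and per-batch scale inflation of the technical noise (the
#' location/scale model empirical-Bayes batch correction assumes);
#' conversion to intensities through per-probe affinities, per-array scale /
#' background / dye factors and additive normal background (type II betas
#' compressed toward 0.5 first); technical replicates re-draw only the
#' technical layers and sit on different batches; detection p values are
#' upper-tail probabilities of the total intensity under the
#' negative-control background fit.
#'
#' @param config A [simulate_config()].
#' @param seed Integer seed; all randomness derives from it.
#' @return List with elements `dataset` ([methyl_dataset()]) and `truth`
#'   (list: `true_beta`, `gamma`, `delta`, `meqtl`, `age`, `kinship`,
#'   `genotypes`, `snp_positions`, `replicate_map`, `array_params`,
#'   `pedigree`).
#' @export
simulate_dataset <- function(config = simulate_config(), seed = 1) {
  cfg <- config
  P <- cfg$n_probes
  n <- cfg$n_samples

  ## ---- stage 1: individuals, families, batches, replicate layout ----
  stage_seed(seed, 1)
  fam <- sort(rep_len(seq_len(cfg$n_families), n))
  individual <- sprintf("S%02d", seq_len(n))
  ages <- stats::runif(n, 23, 89)
  sex <- sample(c("F", "M"), n, replace = TRUE)

  sizes <- replicate_group_sizes(cfg$n_replicate_pairs)
  rep_ind <- integer(0)
  if (length(sizes)) {
    ## one replicated individual per family, cycling if needed
    first_of_fam <- match(unique(fam), fam)
    rep_ind <- rep_len(first_of_fam, length(sizes))
  }
  n_extra <- sum(pmax(sizes - 1L, 0L))
  ind_of_array <- c(seq_len(n),
                    unlist(mapply(function(i, s) rep(i, s - 1L),
                                  rep_ind, sizes, SIMPLIFY = FALSE)))
  array_id <- individual[ind_of_array]
  is_extra <- c(rep(FALSE, n), rep(TRUE, n_extra))
  if (n_extra > 0) {
    cnt <- stats::ave(seq_along(array_id), array_id, FUN = seq_along)
    array_id[is_extra] <- sprintf("%s.r%d", array_id[is_extra], cnt[is_extra])
  }
  A <- length(array_id)

  ## primary arrays round-robin over family-ordered individuals; replicate
  ## extras step through the following batches so every within-group pair
  ## spans two batches
  batch <- integer(A)
  batch[seq_len(n)] <- rep_len(seq_len(cfg$n_batches), n)
  occ <- stats::ave(seq_along(ind_of_array), ind_of_array, FUN = seq_along)
  if (n_extra > 0) {
    for (j in which(is_extra)) {
      prim <- batch[ind_of_array[j]]
      batch[j] <- ((prim - 1L + occ[j] - 1L) %% cfg$n_batches) + 1L
    }
  }
  rep_group <- rep(NA_character_, A)
  if (length(sizes)) {
    for (g in seq_along(rep_ind)) {
      members <- which(ind_of_array == rep_ind[g])
      rep_group[members] <- sprintf("rep%d", g)
    }
  }
  samples <- tibble::tibble(
    sample_id = array_id,
    batch = sprintf("B%d", batch),
    family_id = sprintf("F%d", fam[ind_of_array]),
    replicate_group = rep_group,
    age = ages[ind_of_array],
    sex = sex[ind_of_array])

  ## genotypes: two latent-AR(1) haplotypes per individual
  g <- matrix(0L, cfg$n_snps, n)
  thr <- stats::qnorm(1 - cfg$snp_maf)
  for (i in seq_len(n)) {
    h1 <- ar1_normal(cfg$n_snps, cfg$ld_rho) > thr
    h2 <- ar1_normal(cfg$n_snps, cfg$ld_rho) > thr
    g[, i] <- as.integer(h1) + as.integer(h2)
  }
  colnames(g) <- individual
  rownames(g) <- sprintf("snp%03d", seq_len(cfg$n_snps))

  pedigree <- NULL
  if (cfg$kinship_model == "pedigree") {
    pedigree <- do.call(rbind, lapply(unique(fam), function(f) {
      ids <- individual[fam == f]
      nf <- length(ids)
      tibble::tibble(
        id = ids,
        father = c(NA, NA, rep(ids[1], max(nf - 2, 0)))[seq_len(nf)],
        mother = c(NA, NA, rep(ids[2], max(nf - 2, 0)))[seq_len(nf)],
        family = sprintf("F%d", f))
    }))
    K <- kinship_from_pedigree(pedigree)
  } else {
    K <- matrix(0, n, n, dimnames = list(individual, individual))
    for (f in unique(fam)) {
      idx <- which(fam == f)
      K[idx, idx] <- cfg$fam_kinship
    }
    diag(K) <- 0.5
  }

  ## ---- stage 2: probe annotation and baseline states ----
  stage_seed(seed, 2)
  probe_id <- sprintf("cg%06d", seq_len(P))
  design_type <- ifelse(stats::runif(P) < cfg$frac_type2, "II", "I")
  channel <- ifelse(design_type == "II", "both",
                    sample(c("red", "green"), P, replace = TRUE))
  n_sex <- round(cfg$frac_sex * P)
  chromosome <- sample(paste0("chr", 1:22), P, replace = TRUE)
  if (n_sex > 0) {
    sex_idx <- sample.int(P, n_sex)
    chromosome[sex_idx] <- sample(c("chrX", "chrY"), n_sex,
                                  replace = TRUE, prob = c(0.8, 0.2))
  }
  position <- sample.int(1e8, P, replace = TRUE)
  region_stratum <- sample(names(cfg$strata_props), P, replace = TRUE,
                           prob = cfg$strata_props)
  cpg_body_count <- sample(1:6, P, replace = TRUE,
                           prob = c(0.35, 0.25, 0.2, 0.1, 0.06, 0.04))
  autosomal <- !(chromosome %in% c("chrX", "chrY"))
  is_idmr <- rep(FALSE, P)
  if (cfg$n_idmr > 0) {
    is_idmr[sample(which(autosomal), cfg$n_idmr)] <- TRUE
  }
  state <- sample(names(cfg$state_props), P, replace = TRUE,
                  prob = cfg$state_props)
  state[is_idmr] <- "hemi"
  centre <- numeric(P)
  centre[state == "unmeth"] <- stats::rbeta(sum(state == "unmeth"), 2, 10)
  centre[state == "hemi"] <- stats::rbeta(sum(state == "hemi"), 10, 10)
  centre[state == "meth"] <- stats::rbeta(sum(state == "meth"), 10, 2)
  centre <- pmin(pmax(centre, 0.01), 0.99)

  age_idx <- sample(which(!is_idmr), min(cfg$n_age_probes, sum(!is_idmr)))
  age_slope <- stats::rnorm(length(age_idx), 0, cfg$age_slope_sd)
  eligible <- which(state == "hemi" & !is_idmr & autosomal &
                      !(seq_len(P) %in% age_idx))
  target_idx <- if (length(eligible)) sample(eligible, 1) else
    which(state == "hemi")[1]
  snp_pos <- round(position[target_idx] - cfg$window_bp / 2 +
                     seq_len(cfg$n_snps) * cfg$window_bp / (cfg$n_snps + 1))
  causal_snp <- ceiling(cfg$n_snps / 2)

  annotation <- tibble::tibble(
    probe_id = probe_id, design_type = design_type, channel = channel,
    chromosome = chromosome, position = position,
    region_stratum = region_stratum, is_idmr = is_idmr,
    cpg_body_count = cpg_body_count)

  ## ---- stage 3: biological M values per individual ----
  stage_seed(seed, 3)
  m0 <- logit2(centre)
  R <- chol(2 * K)                       # row-covariance factor: Z R has cov 2K
  E <- matrix(stats::rnorm(P * n), P, n) %*% R * cfg$bio_sd
  M_bio <- m0 + E
  age_c <- ages - mean(ages)
  M_bio[age_idx, ] <- M_bio[age_idx, ] + outer(age_slope, age_c)
  M_bio[target_idx, ] <- M_bio[target_idx, ] +
    cfg$meqtl_effect * g[causal_snp, ]
  dimnames(M_bio) <- list(probe_id, individual)

  ## ---- stage 4: batch artefact parameters ----
  stage_seed(seed, 4)
  gamma <- matrix(stats::rnorm(P * cfg$n_batches, 0, cfg$batch_shift_sd),
                  P, cfg$n_batches,
                  dimnames = list(probe_id, sprintf("B%d", seq_len(cfg$n_batches))))
  delta <- exp(stats::rnorm(cfg$n_batches, 0, cfg$batch_scale_sdlog))
  names(delta) <- sprintf("B%d", seq_len(cfg$n_batches))

  ## ---- stage 5: per-array technical layers and intensities ----
  stage_seed(seed, 5)
  affinity <- stats::rgamma(P, shape = 2, scale = cfg$signal_mean)
  f_scale <- exp(stats::rnorm(A, 0, cfg$sample_scale_sdlog))
  bg_level <- cfg$bg_mean * exp(stats::rnorm(A, 0, cfg$sample_bg_sdlog))
  dye <- exp(stats::rnorm(A, 0, cfg$dye_sdlog))

  type2 <- design_type == "II"
  type1_ids <- probe_id[!type2]
  meth <- unmeth <- detp <- matrix(0, P, A,
                                   dimnames = list(probe_id, array_id))
  bead <- matrix(0L, P, A, dimnames = list(probe_id, array_id))
  oob_m <- oob_u <- matrix(0, length(type1_ids), A,
                           dimnames = list(type1_ids, array_id))
  nc <- cfg$n_controls
  nn <- 50L                               # strong normalisation controls
  ctrl_n <- 2L * nc + 2L * nn
  controls <- tibble::as_tibble(c(
    list(control_id = c(sprintf("neg%03d", seq_len(2 * nc)),
                        sprintf("norm%02d", seq_len(2 * nn))),
         control_type = c(rep("negative", 2 * nc), rep("norm", 2 * nn)),
         channel = c(rep(c("red", "green"), each = nc),
                     rep(c("red", "green"), each = nn))),
    stats::setNames(rep(list(numeric(ctrl_n)), A), array_id)))
  true_beta <- matrix(0, P, A, dimnames = list(probe_id, array_id))

  for (a in seq_len(A)) {
    i <- ind_of_array[a]
    b <- batch[a]
    m_arr <- M_bio[, i] + gamma[, b] +
      delta[b] * stats::rnorm(P, 0, cfg$tech_sd)
    beta_t <- stats::plogis(m_arr * log(2))
    beta_c <- beta_t
    beta_c[type2] <- 0.5 + cfg$type2_compression * (beta_t[type2] - 0.5)
    s_tot <- affinity * f_scale[a] *
      exp(stats::rnorm(P, 0, cfg$probe_wobble_sdlog))
    drop <- stats::runif(P) < cfg$detection_fail_rate
    s_tot[drop] <- s_tot[drop] * 0.02
    mm <- dye[a] * beta_c * s_tot +
      stats::rnorm(P, bg_level[a] * dye[a], cfg$bg_sd)
    uu <- (1 - beta_c) * s_tot + stats::rnorm(P, bg_level[a], cfg$bg_sd)
    meth[, a] <- pmax(mm, 0)
    unmeth[, a] <- pmax(uu, 0)
    oob_m[, a] <- pmax(stats::rnorm(length(type1_ids),
                                    bg_level[a] * dye[a], cfg$bg_sd), 0)
    oob_u[, a] <- pmax(stats::rnorm(length(type1_ids), bg_level[a],
                                    cfg$bg_sd), 0)
    ctrl_red <- stats::rnorm(nc, bg_level[a], cfg$bg_sd)
    ctrl_green <- stats::rnorm(nc, bg_level[a] * dye[a], cfg$bg_sd)
    norm_red <- stats::rnorm(nn, bg_level[a] + 2000 * f_scale[a], cfg$bg_sd)
    norm_green <- stats::rnorm(nn, (bg_level[a] + 2000 * f_scale[a]) * dye[a],
                               cfg$bg_sd)
    controls[[array_id[a]]] <- c(ctrl_red, ctrl_green, norm_red, norm_green)
    ctrl_all <- c(ctrl_red, ctrl_green)
    detp[, a] <- stats::pnorm(meth[, a] + unmeth[, a],
                              mean = 2 * mean(ctrl_all),
                              sd = sqrt(2) * stats::sd(ctrl_all),
                              lower.tail = FALSE)
    bc <- 3L + stats::rpois(P, 12)
    low <- stats::runif(P) < cfg$beadcount_low_rate
    bc[low] <- sample(0:2, sum(low), replace = TRUE)
    bead[, a] <- bc
    true_beta[, a] <- stats::plogis(M_bio[, i] * log(2))
  }

  ## ---- stage 6: probe-level bead defects (clustered low bead counts) ----
  stage_seed(seed, 6)
  n_bad <- round(cfg$beadcount_bad_probe_frac * P)
  if (n_bad > 0) {
    bad <- sample.int(P, n_bad)
    for (p in bad) {
      hit <- stats::runif(A) < 0.3
      if (!any(hit)) hit[sample.int(A, 1)] <- TRUE
      bead[p, hit] <- sample(0:2, sum(hit), replace = TRUE)
    }
  }

  ds <- methyl_dataset(
    meth = meth, unmeth = unmeth,
    annotation = annotation, samples = samples,
    detection_p = detp, bead_count = bead,
    oob_meth = oob_m, oob_unmeth = oob_u,
    controls = controls, provenance = "simulated")

  geno <- g
  colnames(geno) <- individual        # primary array ids equal individual ids
  truth <- list(
    true_beta = true_beta,
    gamma = gamma, delta = delta,
    meqtl = list(probe = probe_id[target_idx], effect = cfg$meqtl_effect,
                 causal_snp = rownames(g)[causal_snp],
                 window_bp = cfg$window_bp),
    age = tibble::tibble(probe_id = probe_id[age_idx], slope = age_slope),
    kinship = K,
    genotypes = geno,
    snp_positions = tibble::tibble(
      snp_id = rownames(g),
      chromosome = chromosome[target_idx],
      position = snp_pos),
    replicate_map = tibble::tibble(
      array = array_id, individual = individual[ind_of_array],
      batch = sprintf("B%d", batch)),
    array_params = tibble::tibble(
      array = array_id, scale = f_scale, bg_mean = bg_level, dye = dye),
    pedigree = pedigree,
    config = cfg, seed = seed)
  list(dataset = ds, truth = truth)
}

#' Kinship matrix from a pedigree (Kinman-Emik recursion)
#'
#' Founders are taken as unrelated and non-inbred (`phi_ii = 0.5`); for an
#' individual `i` with parents `f` and `m`,
#' `phi_ij = (phi_fj + phi_mj) / 2` for `j != i` and
#' `phi_ii = (1 + phi_fm) / 2`. A missing parent contributes 0.
#'
#' @param pedigree Data frame with columns `id`, `father`, `mother`
#'   (`NA` for founders).
#' @return Symmetric kinship matrix over the pedigree ids.
#' @export
kinship_from_pedigree <- function(pedigree) {
  ped <- as.data.frame(pedigree)
  ids <- as.character(ped$id)
  if (anyDuplicated(ids)) stop("duplicate ids in pedigree")
  father <- as.character(ped$father)
  mother <- as.character(ped$mother)
  for (p in c(father, mother)) {
    if (!is.na(p) && !(p %in% ids)) {
      stop("parent '", p, "' is not a pedigree member")
    }
  }
  n <- length(ids)
  ## topological order: parents before children
  depth <- rep(NA_integer_, n)
  names(depth) <- ids
  get_depth <- function(i, seen = character()) {
    id <- ids[i]
    if (id %in% seen) stop("pedigree contains a cycle involving '", id, "'")
    if (!is.na(depth[id])) return(depth[id])
    f <- father[i]; m <- mother[i]
    d <- 0L
    if (!is.na(f)) d <- max(d, get_depth(match(f, ids), c(seen, id)) + 1L)
    if (!is.na(m)) d <- max(d, get_depth(match(m, ids), c(seen, id)) + 1L)
    depth[id] <<- d
    d
  }
  for (i in seq_len(n)) get_depth(i)
  ord <- order(depth, seq_len(n))
  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  done <- character()
  for (i in ord) {
    id <- ids[i]; f <- father[i]; m <- mother[i]
    for (j_id in done) {
      v <- 0
      if (!is.na(f)) v <- v + 0.5 * phi[f, j_id]
      if (!is.na(m)) v <- v + 0.5 * phi[m, j_id]
      phi[id, j_id] <- phi[j_id, id] <- v
    }
    phi_fm <- if (!is.na(f) && !is.na(m)) phi[f, m] else 0
    phi[id, id] <- 0.5 * (1 + phi_fm)
    done <- c(done, id)
  }
  phi
}
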