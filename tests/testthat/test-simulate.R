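test_that("simulation is bitwise deterministic given the seed", {
  a <- small_sim(17)
  b <- small_sim(17)
  expect_identical(a$dataset$meth, b$dataset$meth)
  expect_identical(a$dataset$beta, b$dataset$beta)
  expect_identical(a$truth$gamma, b$truth$gamma)
  c <- small_sim(18)
  expect_false(identical(a$dataset$meth, c$dataset$meth))
})

test_that("simulated design matches the familial study layout", {
  sim <- simulate_dataset(simulate_config(n_probes = 500, n_age_probes = 50),
                          seed = 2)
  smp <- sim$dataset$samples
  expect_equal(nrow(smp), 50)                      # 45 unique + 5 replicates
  expect_equal(length(unique(smp$family_id)), 4)
  expect_equal(length(unique(smp$batch)), 3)
  expect_equal(sum(sim$dataset$annotation$is_idmr), 227)
  ## six pairwise replicate pairs, each spanning two batches
  mt <- replicate_mad(get_mvals(sim$dataset), smp$replicate_group)
  expect_equal(nrow(mt), 6)
  for (i in seq_len(nrow(mt))) {
    b1 <- smp$batch[smp$sample_id == mt$sample_1[i]]
    b2 <- smp$batch[smp$sample_id == mt$sample_2[i]]
    expect_false(b1 == b2)
  }
})

test_that("iDMR probes are hemi-methylated around 0.5 in truth", {
  ## full 227-probe iDMR panel so the Beta(10,10) centre noise averages out
  sim <- small_sim(5, n_probes = 2000, n_idmr = 227)
  idmr <- sim$dataset$annotation$is_idmr
  mu <- mean(sim$truth$true_beta[idmr, ])
  expect_lt(abs(mu - 0.5), 0.02)
})

test_that("type II compression produces a KS gap that closes as c -> 1", {
  ks_at <- function(cc) {
    sim <- small_sim(8, type2_compression = cc, batch_shift_sd = 0,
                     n_probes = 1500)
    ds <- sim$dataset
    type2 <- ds$annotation$design_type == "II"
    ks <- suppressWarnings(stats::ks.test(
      as.vector(ds$beta[!type2, ]), as.vector(ds$beta[type2, ])))$statistic
    unname(ks)
  }
  k06 <- ks_at(0.6)
  k08 <- ks_at(0.8)
  k10 <- ks_at(1.0)
  expect_gt(k06, k08)
  expect_gt(k08, k10)
  expect_gt(k08, 0)
})

test_that("replicate pairs have the smallest expected MAD without batch shifts", {
  ## per-array dye/background artefacts hit replicate and non-replicate
  ## pairs alike, so the replicate advantage is in expectation: their mean
  ## MAD stays below the mean over all other pairs in (almost) every seed
  hits <- 0
  n_seeds <- 10
  for (s in seq_len(n_seeds)) {
    ## full six-pair replicate layout so per-array dye draws average out
    sim <- small_sim(100 + s, batch_shift_sd = 0, n_probes = 600,
                     n_samples = 45, n_families = 4, n_replicate_pairs = 6)
    m <- get_mvals(sim$dataset)
    rg <- sim$dataset$samples$replicate_group
    rep_pairs <- replicate_mad(m, rg)
    pairs <- utils::combn(ncol(m), 2)
    all_mads <- apply(pairs, 2, function(pr) {
      stats::median(abs(m[, pr[1]] - m[, pr[2]]))
    })
    is_rep <- apply(pairs, 2, function(pr) {
      g1 <- rg[pr[1]]; g2 <- rg[pr[2]]
      !is.na(g1) && !is.na(g2) && g1 == g2
    })
    if (mean(all_mads[is_rep]) < mean(all_mads[!is_rep])) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("null simulation gives uniform PC1-batch ANOVA p values", {
  ## noise only: no batch shift/scale, no compression, no family
  ## correlation, no sample-level artefacts -- samples are exchangeable, so
  ## the PC1 ANOVA p value must be uniform over seeds
  ps <- vapply(1:50, function(s) {
    sim <- simulate_dataset(
      simulate_config(n_probes = 200, n_samples = 12, n_families = 3,
                      n_idmr = 20, n_age_probes = 0, n_replicate_pairs = 0,
                      n_snps = 12, batch_shift_sd = 0, batch_scale_sdlog = 0,
                      type2_compression = 1, meqtl_effect = 0,
                      fam_kinship = 0, sample_bg_sdlog = 0, dye_sdlog = 0),
      seed = 400 + s)
    pc_anova(sim$dataset$beta, sim$dataset$samples$batch, k = 200)
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("pedigree kinship recursion reproduces textbook coefficients", {
  founders <- tibble::tibble(id = c("a", "b"), father = NA_character_,
                             mother = NA_character_)
  k <- kinship_from_pedigree(founders)
  expect_equal(unname(diag(k)), c(0.5, 0.5))
  expect_equal(k["a", "b"], 0)

  sibs <- tibble::tibble(
    id = c("f", "m", "c1", "c2"),
    father = c(NA, NA, "f", "f"),
    mother = c(NA, NA, "m", "m"))
  k <- kinship_from_pedigree(sibs)
  expect_equal(k["c1", "c2"], 0.25)        # full sibs
  expect_equal(k["f", "c1"], 0.25)         # parent-offspring
  expect_equal(k["c1", "c1"], 0.5)         # non-inbred

  ## three generations: grandparent-grandchild = 0.125, checked against a
  ## gene-dropping Monte Carlo oracle
  ped <- tibble::tibble(
    id = c("gf", "gm", "p", "sp", "gc"),
    father = c(NA, NA, "gf", NA, "p"),
    mother = c(NA, NA, "gm", NA, "sp"))
  k <- kinship_from_pedigree(ped)
  expect_equal(k["gf", "gc"], 0.125)

  set.seed(42)
  n_drop <- 1e5
  gf <- cbind(1, 2); gm <- cbind(3, 4); sp <- cbind(5, 6)
  pick <- function(h) h[cbind(seq_len(n_drop),
                              sample(1:2, n_drop, replace = TRUE))]
  gf_m <- matrix(rep(c(1, 2), each = n_drop), ncol = 2)
  gm_m <- matrix(rep(c(3, 4), each = n_drop), ncol = 2)
  sp_m <- matrix(rep(c(5, 6), each = n_drop), ncol = 2)
  p_m <- cbind(pick(gf_m), pick(gm_m))
  gc_m <- cbind(pick(p_m), pick(sp_m))
  ## kinship = P(random allele of gf IBD to random allele of gc)
  a_gf <- pick(gf_m)
  a_gc <- gc_m[cbind(seq_len(n_drop), sample(1:2, n_drop, replace = TRUE))]
  expect_lt(abs(mean(a_gf == a_gc) - 0.125), 0.01)

  cyc <- tibble::tibble(id = c("x", "y"), father = c("y", "x"),
                        mother = c(NA, NA))
  expect_error(kinship_from_pedigree(cyc), "cycle")
})

test_that("family random effects carry the 2K sigma^2 covariance structure", {
  ## parent-offspring kinship 0.25 under the pedigree model implies an
  ## M-scale covariance of 2 * 0.25 * bio_sd^2; check empirically over probes
  sim <- small_sim(21, kinship_model = "pedigree", n_probes = 4000,
                   batch_shift_sd = 0, tech_sd = 0, n_age_probes = 0,
                   meqtl_effect = 0)
  K <- sim$truth$kinship
  ped <- sim$truth$pedigree
  child <- ped$id[!is.na(ped$father)][1]
  parent <- ped$father[ped$id == child]
  expect_equal(K[parent, child], 0.25)
  m <- get_mvals(sim$dataset)
  cfg <- sim$truth$config
  ## empirical covariance between parent and child bio deviations
  mb <- log2(sim$truth$true_beta / (1 - sim$truth$true_beta))
  ## pair differences cancel the per-probe baseline:
  ## var(E_i - E_j) = (2K_ii + 2K_jj - 2 * 2K_ij) * bio_sd^2
  fam <- sim$dataset$samples$family_id[
    match(colnames(mb), sim$dataset$samples$sample_id)]
  other <- colnames(mb)[fam != fam[match(parent, colnames(mb))]][1]
  v_pc <- stats::var(mb[, parent] - mb[, child])    # expect 1 * bio_sd^2
  v_un <- stats::var(mb[, parent] - mb[, other])    # expect 2 * bio_sd^2
  expect_equal(v_pc, cfg$bio_sd^2, tolerance = 0.15)
  expect_equal(v_un, 2 * cfg$bio_sd^2, tolerance = 0.15)
  expect_equal(v_pc / v_un, 0.5, tolerance = 0.15)
})
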