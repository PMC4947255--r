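test_that("quantile kernel matches hand oracles including the tie rule", {
  x <- cbind(c(2, 4, 6), c(1, 3, 5))
  out <- quantile_normalize(x)
  expect_equal(out[, 1], c(1.5, 3.5, 5.5))
  expect_equal(out[, 2], c(1.5, 3.5, 5.5))

  same <- cbind(c(1, 5, 9), c(1, 5, 9))
  expect_equal(quantile_normalize(same), same)

  tied <- cbind(c(1, 1, 3), c(2, 4, 6))
  out <- quantile_normalize(tied)
  ## reference is (1.5, 2.5, 4.5); tied entries get mean of ranks 1-2
  expect_equal(out[, 1], c(2, 2, 4.5))
  expect_equal(out[, 2], c(1.5, 2.5, 4.5))

  expect_warning(quantile_normalize(matrix(1:3, 3, 1)), "single column")
})

test_that("quantile kernel agrees with the limma reference implementation", {
  skip_if_not_installed("limma")
  set.seed(8)
  x <- matrix(rexp(200 * 6, 1 / 3000), 200, 6)
  x[3, ] <- x[5, ]                        # inject ties across rows
  expect_equal(quantile_normalize(x),
               limma::normalizeQuantiles(x, ties = TRUE),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("global QN forces identical intensity distributions", {
  sim <- small_sim(12)
  ds <- norm_qn(sim$dataset)
  sorted <- apply(ds$meth, 2, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-9)
  ks <- suppressWarnings(stats::ks.test(ds$meth[, 1], ds$meth[, 2]))$statistic
  expect_equal(unname(ks), 0, tolerance = 1e-12)
  expect_true("qn" %in% ds$provenance)
  expect_identical(norm_qn(ds)$beta, ds$beta)   # fixed point
})

test_that("stratified QN degenerates to global QN with one all-type-II stratum", {
  ds <- toy_dataset(40, 5)
  ds$annotation$design_type <- "II"
  ds$annotation$channel <- "both"
  ds$annotation$region_stratum <- "open_sea"
  a <- norm_stratified_qn(ds)
  b <- norm_qn(ds)
  expect_equal(a$beta, b$beta, tolerance = 1e-12)
})

test_that("stratified QN aligns samples within strata and preserves stratum contrasts", {
  sim <- small_sim(13, n_probes = 1200)
  ds <- sim$dataset
  out <- norm_stratified_qn(ds)
  ann <- out$annotation
  for (stratum in unique(ann$region_stratum)) {
    i2 <- ann$region_stratum == stratum & ann$design_type == "II"
    sorted <- apply(out$meth[i2, ], 2, sort)
    expect_lt(max(abs(sorted - sorted[, 1])), 1e-9)
  }
  ## disjoint-range strata keep their mean separation
  ds2 <- toy_dataset(60, 5)
  ds2$annotation$design_type <- "II"
  ds2$annotation$channel <- "both"
  ds2$annotation$region_stratum <- rep(c("island", "open_sea"), each = 30)
  lowr <- ds2$annotation$region_stratum == "island"
  set.seed(2)
  ds2$meth[lowr, ] <- matrix(runif(sum(lowr) * 5, 100, 1000), sum(lowr))
  ds2$meth[!lowr, ] <- matrix(runif(sum(!lowr) * 5, 5000, 9000), sum(!lowr))
  ds2$unmeth[] <- 1000
  ds2$beta <- beta_from_intensities(ds2)
  pre <- mean(ds2$meth[!lowr, ]) - mean(ds2$meth[lowr, ])
  out2 <- norm_stratified_qn(ds2)
  post <- mean(out2$meth[!lowr, ]) - mean(out2$meth[lowr, ])
  expect_lt(abs(post - pre) / abs(pre), 0.05)
})

test_that("stratified QN falls back to a global reference for thin strata", {
  ds <- toy_dataset(30, 4)
  ds$annotation$region_stratum <- c("island", rep("open_sea", 29))
  expect_warning(norm_stratified_qn(ds), "fewer than 2 type II probes")
})

test_that("SWAN is a fixed point when both types share each class distribution", {
  ds <- toy_dataset(40, 3)
  ds$annotation$design_type <- rep(c("I", "II"), each = 20)
  ds$annotation$channel <- rep(c("red", "both"), each = 20)
  ds$annotation$cpg_body_count <- rep(rep(1:2, each = 10), 2)
  ## give type I and II literally identical class value sets
  for (k in 1:2) {
    i1 <- which(ds$annotation$design_type == "I" &
                  ds$annotation$cpg_body_count == k)
    i2 <- which(ds$annotation$design_type == "II" &
                  ds$annotation$cpg_body_count == k)
    ds$meth[i2, ] <- ds$meth[i1, ]
    ds$unmeth[i2, ] <- ds$unmeth[i1, ]
  }
  ds$beta <- beta_from_intensities(ds)
  out <- suppressWarnings(norm_swan(ds, seed = 1))
  expect_equal(out$meth, ds$meth, tolerance = 1e-6)
})

test_that("SWAN halves the probe-type KS gap on compressed simulations", {
  sim <- small_sim(14, n_probes = 2000, type2_compression = 0.8)
  ds <- sim$dataset
  type2 <- ds$annotation$design_type == "II"
  ks0 <- suppressWarnings(stats::ks.test(as.vector(ds$beta[!type2, ]),
                                         as.vector(ds$beta[type2, ])))$statistic
  out <- norm_swan(ds, seed = 3)
  ks1 <- suppressWarnings(stats::ks.test(as.vector(out$beta[!type2, ]),
                                         as.vector(out$beta[type2, ])))$statistic
  expect_lt(ks1, 0.5 * ks0)
})

test_that("SWAN is deterministic in its seed", {
  sim <- small_sim(15)
  a <- norm_swan(sim$dataset, seed = 5)
  b <- norm_swan(sim$dataset, seed = 5)
  c <- norm_swan(sim$dataset, seed = 6)
  expect_identical(a$meth, b$meth)
  expect_false(identical(a$meth, c$meth))
})

test_that("dasen reduces to global QN for a single probe type", {
  ds <- toy_dataset(30, 4)
  ds$annotation$design_type <- "II"
  ds$annotation$channel <- "both"
  expect_equal(norm_dasen(ds)$beta, norm_qn(ds)$beta, tolerance = 1e-12)
})

test_that("dasen corrects a planted type I background offset", {
  ## compression off so both types share a generative distribution and the
  ## planted offset is the only type difference
  sim <- small_sim(16, n_probes = 2000, type2_compression = 1)
  ds <- sim$dataset
  t1 <- ds$annotation$design_type == "I"
  ds$meth[t1, ] <- ds$meth[t1, ] + 300
  ds$unmeth[t1, ] <- ds$unmeth[t1, ] + 300
  ds$beta <- beta_from_intensities(ds)
  out <- norm_dasen(ds)
  for (j in 1:3) {
    m1 <- famnorm:::density_mode_low(out$meth[t1, j])
    m2 <- famnorm:::density_mode_low(out$meth[!t1, j])
    expect_lt(abs(m1 - m2), 50)
  }
  ## sorted equality within each probe type
  for (idx in list(t1, !t1)) {
    sorted <- apply(out$meth[idx, ], 2, sort)
    expect_lt(max(abs(sorted - sorted[, 1])), 1e-9)
  }
})

test_that("normalisation methods keep datasets valid", {
  sim <- small_sim(19)
  ds <- run_qc(sim$dataset)$dataset
  for (m in c("qn", "stratified_qn", "swan", "bmiq", "noob", "dasen",
              "funnorm")) {
    out <- suppressWarnings(famnorm:::apply_method(ds, m, seed = 2))
    expect_true(all(out$beta >= 0 & out$beta <= 1), info = m)
    expect_true(all(is.finite(get_mvals(out))), info = m)
    expect_silent(validate_methyl_dataset(out))
  }
})
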