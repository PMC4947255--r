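test_that("identity kinship reduces stage 1 to plain centring", {
  set.seed(20)
  n <- 24
  ids <- sprintf("S%02d", seq_len(n))
  y <- stats::setNames(rnorm(n), ids)
  K <- diag(0.5, n)
  dimnames(K) <- list(ids, ids)
  g <- matrix(sample(0:2, 15 * n, replace = TRUE), 15, n,
              dimnames = list(sprintf("snp%02d", 1:15), ids))
  res <- meqtl_association(y, g, K)
  ## residuals equal centred y (2K = I has a single eigenvalue, so the
  ## genetic and environmental components are not separable; the residual
  ## must still equal y - mean(y) up to overall scale direction)
  r <- res$lmm
  centred <- y - mean(y)
  fit0 <- lm(centred ~ g[1, ])
  tab <- res$table
  direct_p <- summary(lm((y - mean(y)) ~ g[1, ]))$coefficients[2, 4]
  expect_equal(tab$p[1], direct_p, tolerance = 1e-8)
})

test_that("a perfect genotype-methylation relation is recovered exactly", {
  n <- 20
  ids <- sprintf("S%02d", seq_len(n))
  set.seed(21)
  g <- matrix(sample(0:2, 12 * n, replace = TRUE), 12, n,
              dimnames = list(sprintf("snp%02d", 1:12), ids))
  g[1, ] <- rep(c(0L, 1L, 2L), length.out = n)
  y <- stats::setNames(0.7 * g[1, ] + 2, ids)
  K <- diag(0.5, n); dimnames(K) <- list(ids, ids)
  res <- suppressWarnings(meqtl_association(y, g, K))  # exact fit warning
  expect_lt(res$table$p[1], 1e-12)
  expect_equal(res$table$beta[1], 0.7, tolerance = 1e-6)
  expect_equal(res$min_p_adjusted, min(res$table$p_adjusted))
})

test_that("monomorphic SNPs are recorded with p = 1", {
  n <- 16
  ids <- sprintf("S%02d", seq_len(n))
  g <- rbind(mono = rep(1L, n),
             matrix(sample(0:2, 11 * n, replace = TRUE), 11, n))
  rownames(g)[2:12] <- sprintf("snp%02d", 2:12)
  colnames(g) <- ids
  y <- stats::setNames(rnorm(n), ids)
  K <- diag(0.5, n); dimnames(K) <- list(ids, ids)
  res <- meqtl_association(y, g, K)
  expect_equal(res$table$p[res$table$snp_id == "mono"], 1)
})

test_that("the planted meQTL is detected and preserved through correction", {
  detected_raw <- 0; preserved <- 0; n_seeds <- 10
  for (s in seq_len(n_seeds)) {
    sim <- small_sim(200 + s, n_probes = 1200, n_samples = 24,
                     n_families = 4, batch_shift_sd = 0.5)
    ds <- run_qc(sim$dataset)$dataset
    tp <- sim$truth$meqtl$probe
    if (!tp %in% rownames(ds$beta)) next
    ids <- colnames(sim$truth$genotypes)
    y_raw <- get_mvals(ds)[tp, ids]
    r_raw <- meqtl_association(y_raw, sim$truth$genotypes,
                               sim$truth$kinship)
    cds <- apply_combat(norm_stratified_qn(ds))
    y_cor <- get_mvals(cds)[tp, ids]
    r_cor <- meqtl_association(y_cor, sim$truth$genotypes,
                               sim$truth$kinship)
    if (r_raw$min_p_adjusted < 0.05) {
      detected_raw <- detected_raw + 1
      if (r_cor$min_p_adjusted < 0.05) preserved <- preserved + 1
    }
  }
  expect_gte(detected_raw, 6)
  ## preservation: whenever raw detects, corrected keeps it (allow 1 miss)
  expect_gte(preserved, detected_raw - 1)
})

test_that("lambda is 1 by construction when p values equal their expectation", {
  n <- 999
  p <- (seq_len(n) - 0.5) / n
  lam <- stats::median(-log10(p)) /
    stats::median(-log10((seq_len(n) - 0.5) / n))
  expect_equal(lam, 1)
  ## via the full function: regression p of pure noise should give lambda ~ 1
  set.seed(30)
  mat <- matrix(rnorm(4000 * 30), 4000, 30)
  ages <- runif(30, 23, 89)
  res <- age_ewas_lambda(mat, ages)
  expect_gt(res$lambda, 0.9)
  expect_lt(res$lambda, 1.1)
})

test_that("planted age slopes inflate lambda above 1.2", {
  set.seed(31)
  n <- 40; P <- 4000
  ages <- runif(n, 23, 89)
  mat <- matrix(rnorm(P * n, 0, 0.35), P, n)
  idx <- seq_len(P * 0.2)                  # 20% affected, as in the generator
  slopes <- rnorm(length(idx), 0, 0.02)
  mat[idx, ] <- mat[idx, ] + outer(slopes, ages - mean(ages))
  res <- age_ewas_lambda(mat, ages)
  expect_gt(res$lambda, 1.2)
  expect_error(age_ewas_lambda(mat, rep(50, n)), "constant")
})

test_that("constant probes get p = 1 in the age scan", {
  mat <- rbind(rep(0.5, 10), matrix(rnorm(50), 5, 10))
  res <- age_ewas_lambda(mat, seq(20, 60, length.out = 10))
  expect_equal(res$p[1], 1)
})
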