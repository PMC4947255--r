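test_that("density summaries integrate to 1 and detect no gap for equal types", {
  ds <- toy_dataset(200, 4)
  set.seed(6)
  ds$beta <- matrix(rbeta(200 * 4, 5, 5), 200, 4,
                    dimnames = dimnames(ds$meth))
  dens <- density_summary(ds$beta, ds$annotation)
  for (j in 1:4) {
    area <- sum(dens$density[, j]) * 0.005
    expect_lt(abs(area - 1), 0.01)
  }
  ## identical type I and II value sets -> KS distance 0
  ds$beta[ds$annotation$design_type == "II", ] <-
    ds$beta[ds$annotation$design_type == "I", ]
  dens2 <- density_summary(ds$beta, ds$annotation)
  expect_equal(dens2$ks_type, 0)
  ## concentrated betas put the density mass at 0.5
  ds$beta[] <- 0.5
  dens3 <- density_summary(ds$beta, ds$annotation)
  expect_equal(dens3$grid[which.max(dens3$density[, 1])], 0.5,
               tolerance = 0.01)
})

test_that("classical MDS reproduces a 3-4-5 triangle", {
  ## three samples whose M-value profiles sit at mutual distances 3, 4, 5
  m <- rbind(c(0, 3, 0), c(0, 0, 4))
  m <- rbind(m, matrix(0, 48, 3))
  dimnames(m) <- list(sprintf("cg%02d", 1:50), c("A", "B", "C"))
  d0 <- as.matrix(dist(t(m)))
  expect_equal(sort(d0[upper.tri(d0)]), c(3, 4, 5))
  res <- mds_coordinates(m, k = 50)
  d1 <- as.matrix(dist(res$coords))
  expect_equal(sort(d1[upper.tri(d1)]), c(3, 4, 5), tolerance = 1e-6)

  ## duplicated sample lands on identical coordinates
  m2 <- cbind(m, D = m[, "C"])
  res2 <- mds_coordinates(m2, k = 50)
  expect_equal(res2$coords["C", ], res2$coords["D", ], tolerance = 1e-8)

  ## permutation of samples leaves coordinates invariant up to sign
  perm <- c("B", "C", "A")
  res3 <- mds_coordinates(m[, perm], k = 50)
  for (j in 1:2) {
    expect_equal(abs(res3$coords[perm, j]), abs(res$coords[perm, j]),
                 tolerance = 1e-8)
  }
})

test_that("PC1 ANOVA separates planted shifts and is calibrated under the null", {
  set.seed(9)
  n <- 20
  labels <- rep(c("a", "b"), each = n / 2)
  base <- matrix(rnorm(300 * n, 0, 0.05), 300, n,
                 dimnames = list(sprintf("cg%03d", 1:300),
                                 sprintf("S%02d", 1:n)))
  shift <- base + 0.4 * outer(rep(1, 300), as.numeric(labels == "b"))
  shift <- pmin(pmax(shift + 0.5, 0), 1)
  expect_lt(pc_anova(shift, labels, k = 300), 1e-6)

  null_mat <- pmin(pmax(base + 0.5, 0), 1)
  ps <- vapply(1:200, function(i) {
    pc_anova(null_mat, sample(labels), k = 300)
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)

  ## degenerate: identical PC1 values in both groups
  flat <- matrix(0.5, 10, 4, dimnames = list(sprintf("cg%02d", 1:10),
                                             sprintf("S%d", 1:4)))
  expect_equal(pc_anova(flat, c("a", "a", "b", "b"), k = 10), 1)
  expect_error(pc_anova(shift, rep("a", n)), "2 label levels")
})

test_that("replicate MAD matches hand and brute-force oracles", {
  m <- rbind(c(1, 1.5), c(2, 2), c(3, 2.5))
  dimnames(m) <- list(sprintf("cg%d", 1:3), c("r1", "r2"))
  tb <- replicate_mad(m, c("g", "g"))
  expect_equal(tb$mad, 0.5)

  mm <- cbind(a = rnorm(101), b = rnorm(101))
  rownames(mm) <- sprintf("cg%03d", 1:101)
  tb2 <- replicate_mad(mm, c("g", "g"))
  d <- sort(abs(mm[, 1] - mm[, 2]))
  expect_equal(tb2$mad, unname(d[51]))     # sorted-middle oracle

  expect_equal(replicate_mad(cbind(mm, c = mm[, 1]),
                             c("g", "g", NA))$mad, tb2$mad)
  same <- replicate_mad(cbind(mm[, 1], mm[, 1]), c("g", "g"))
  expect_equal(same$mad, 0)
  ## a three-member group yields all three pairwise rows
  tb3 <- replicate_mad(cbind(mm, c = mm[, 2] + 0.1), c("g", "g", "g"))
  expect_equal(nrow(tb3), 3)
})

test_that("DMRSE follows its closed form", {
  b <- matrix(0.5, 5, 4, dimnames = list(sprintf("cg%d", 1:5),
                                         sprintf("S%d", 1:4)))
  expect_equal(dmrse(b, rep(TRUE, 5)), 0)

  one <- matrix(c(0.4, 0.6), 1, 2, dimnames = list("cg1", c("S1", "S2")))
  expect_equal(dmrse(one, TRUE), sd(c(-0.1, 0.1)), tolerance = 1e-12)
  expect_equal(dmrse(one, TRUE), 0.1414, tolerance = 1e-3)

  two <- matrix(c(0.3, 0.7), 1, 2, dimnames = list("cg1", c("S1", "S2")))
  expect_equal(dmrse(two, TRUE), 2 * dmrse(one, TRUE))   # linearity

  expect_error(dmrse(b, rep(FALSE, 5)), "no iDMR")
})

test_that("cluster agreement is 1 for separated batches and ~0 under permutation", {
  set.seed(12)
  n <- 12
  batch <- rep(c("A", "B"), each = n / 2)
  m <- matrix(rnorm(200 * n, 0, 0.3), 200, n,
              dimnames = list(sprintf("cg%03d", 1:200), sprintf("S%02d", 1:n)))
  m[, batch == "B"] <- m[, batch == "B"] + 5
  res <- cluster_batch_agreement(m, batch)
  expect_equal(res$ari, 1)
  expect_s3_class(res$dendrogram, "hclust")

  aris <- vapply(1:100, function(i) {
    cluster_batch_agreement(m, sample(batch))$ari
  }, numeric(1))
  expect_lt(abs(mean(aris)), 0.05)
})

test_that("replicates merge low in the dendrogram after correction", {
  sim <- small_sim(44, n_probes = 1000, n_samples = 16, n_replicate_pairs = 2)
  ds <- run_qc(sim$dataset)$dataset
  cds <- apply_combat(norm_stratified_qn(ds))
  m <- get_mvals(cds)
  dd <- as.matrix(dist(t(m)))
  rg <- cds$samples$replicate_group
  rep_d <- c()
  for (g in unique(rg[!is.na(rg)])) {
    mem <- which(!is.na(rg) & rg == g)
    prs <- utils::combn(mem, 2)
    rep_d <- c(rep_d, dd[t(prs)])
  }
  all_d <- dd[upper.tri(dd)]
  expect_lt(max(rep_d), stats::quantile(all_d, 0.1))
})

test_that("IBS kinship matches its per-SNP average definition", {
  g <- cbind(a = c(0L, 1L, 2L, 0L), b = c(0L, 1L, 2L, 0L))
  g <- rbind(g, g, g)                     # 12 SNPs
  K <- ibs_kinship(g)
  expect_equal(K["a", "b"], 1)

  g2 <- cbind(a = rep(0L, 12), b = rep(2L, 12))
  expect_equal(ibs_kinship(g2)["a", "b"], 0)

  set.seed(13)
  g3 <- matrix(sample(0:2, 1000 * 3, replace = TRUE), 1000, 3,
               dimnames = list(NULL, c("x", "y", "z")))
  K3 <- ibs_kinship(g3)
  for (pr in list(c("x", "y"), c("x", "z"), c("y", "z"))) {
    oracle <- mean((2 - abs(g3[, pr[1]] - g3[, pr[2]])) / 2)
    expect_equal(K3[pr[1], pr[2]], oracle)
  }
  expect_equal(K3, t(K3))
  expect_error(ibs_kinship(g3[1:5, ]), "at least 10 SNPs")
})
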