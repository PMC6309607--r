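test_that("pearson map matches cor.test voxel by voxel on a toy stack", {
  set.seed(5)
  n <- 12
  level <- rnorm(n)
  vals <- matrix(rnorm(n * 5), n, 5)
  vals[, 1] <- level                     # exact copy -> r = 1
  vals[, 2] <- -2 * level + 1            # anti-linear -> r = -1
  stack <- tinyStack(vals, dm = c(5, 1, 1))
  pm <- pearsonMap(level, stack)
  for (v in 1:5) {
    ct <- cor.test(level, vals[, v])
    expect_equal(pm$rMap[v], unname(ct$estimate), tolerance = 1e-10)
    if (abs(ct$estimate) < 1)
      expect_equal(pm$pMap[v], ct$p.value, tolerance = 1e-10)
  }
  expect_equal(pm$rMap[1], 1)
  expect_equal(pm$rMap[2], -1)
  expect_equal(pm$pMap[1], 0)
  st3 <- tinyStack(matrix(c(6, 4, 2, 1, 5, 9), 3, 2), dm = c(2, 1, 1))
  expect_error(pearsonMap(c(1, 2, 3), st3), "4 subjects")
  expect_error(pearsonMap(rep(1, n), stack), "constant")
})

test_that("zero-variance voxels get undefined r and p = 1", {
  set.seed(6)
  vals <- matrix(rnorm(40), 10, 4)
  vals[, 3] <- 7
  stack <- tinyStack(vals, dm = c(4, 1, 1))
  pm <- pearsonMap(rnorm(10), stack)
  expect_true(is.na(pm$rMap[3]))
  expect_equal(pm$pMap[3], 1)
})

test_that("null p-values are uniform (Kolmogorov-Smirnov at alpha 0.01)", {
  set.seed(11)
  n <- 20
  nvox <- 10000
  stack <- tinyStack(matrix(rnorm(n * nvox), n, nvox), dm = c(nvox, 1, 1))
  pm <- pearsonMap(rnorm(n), stack)
  ks <- suppressWarnings(ks.test(as.vector(pm$pMap), "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("BH threshold reproduces the step-up definition and p.adjust", {
  # largest i with p_(i) <= (i/m) q is 4 -> all four rejected
  p4 <- array(c(0.01, 0.02, 0.03, 0.04), c(4, 1, 1))
  fd <- fdrThreshold(p4, q = 0.05)
  expect_equal(fd$qThreshold, 0.04)
  expect_true(all(fd$sigMask))
  # all p = 1 -> nothing; single p = 0.04 at q = 0.05 -> rejected
  expect_equal(sum(fdrThreshold(array(1, c(3, 1, 1)), q = 0.05)$sigMask), 0)
  expect_true(fdrThreshold(array(0.04, c(1, 1, 1)), q = 0.05)$sigMask[1])
  # agreement with p.adjust on random p-values
  set.seed(2)
  p <- array(runif(500)^2, c(500, 1, 1))
  fd <- fdrThreshold(p, q = 0.05)
  expect_identical(as.vector(fd$sigMask),
                   p.adjust(as.vector(p), "BH") <= 0.05)
  expect_error(fdrThreshold(array(0.5, c(1, 1, 1)), q = 1.5), "q must")
  expect_error(fdrThreshold(p4, mask = array(FALSE, c(4, 1, 1))), "empty")
})

test_that("connected-component labels match an independent oracle", {
  set.seed(9)
  for (conn in c(6, 18, 26)) {
    for (rep in 1:3) {
      mask <- array(runif(6 * 5 * 4) < 0.35, c(6, 5, 4))
      got <- labelComponents(mask, conn)
      want <- oracleLabelComponents(mask, conn)
      expect_identical(got, want)
    }
  }
  # two voxels sharing only a corner: separate under 6, joined under 26
  m <- array(FALSE, c(3, 3, 3))
  m[1, 1, 1] <- m[2, 2, 2] <- TRUE
  expect_equal(max(labelComponents(m, 6)), 2)
  expect_equal(max(labelComponents(m, 26)), 1)
})

test_that("cluster filter keeps 100-voxel clusters and drops 99-voxel ones", {
  m <- array(FALSE, c(20, 20, 20))
  m[1:4, 1:5, 1:5] <- TRUE               # 100 voxels: retained
  m[10:20, 10:12, 10:12] <- TRUE         # 99 voxels: removed
  expect_equal(sum(m), 199)
  cf <- clusterFilter(m, minClusterVoxels = 100, connectivity = 6)
  expect_equal(nrow(cf$clusters), 1)
  expect_equal(cf$clusters$size, 100)
  expect_equal(sum(cf$sigMaskFinal), 100)
  # idempotent; monotone in the threshold
  cf2 <- clusterFilter(cf$sigMaskFinal, 100, 6)
  expect_identical(cf2$sigMaskFinal, cf$sigMaskFinal)
  cf3 <- clusterFilter(m, 150, 6)
  expect_true(all(which(cf3$sigMaskFinal) %in% which(cf$sigMaskFinal)))
  # mm^3 interface: 100 mm^3 at 2 mm voxels is 13 voxels after rounding up
  cf4 <- clusterFilter(m, connectivity = 6, minClusterMm3 = 100,
                       voxelSize = 2)
  expect_equal(nrow(cf4$clusters), 2)
})

test_that("mapAllModules separates a coupled from a null module", {
  roi <- roiCuboid(c(8, 8, 8), c(6, 6, 6), c(20, 20, 20))
  cfg <- simConfig(nSubjects = 150, nFeatures = 20, gridShape = c(20, 20, 20),
                   moduleSpec = data.frame(module_id = 1:2, n_features = 10,
                                           within_correlation = 0.9),
                   couplingSpec = list(list(module = 1, roi = roi,
                                            beta = 1.5)),
                   maskType = "box", seed = 31)
  om <- generateOmics(cfg)
  stack <- generateR2Stack(cfg, om$latents)
  lv <- ModuleLevels(om$latents)
  mp <- mapAllModules(lv, stack, q = 0.05, minClusterVoxels = 100)
  final1 <- sigMask(mp$results[["1"]])
  expect_gt(sum(final1[roi]), 0.8 * length(roi))
  expect_equal(sum(sigMask(mp$results[["2"]])), 0)
  # uncorrected p < .01 counts dominate FDR counts (solid vs hollow bars)
  expect_true(all(mp$summary$n_sig_uncorrected >= mp$summary$n_sig_fdr))
  # q = 1 is rejected as out of range, q near 1 floods the prefilter
  expect_error(mapAllModules(lv, stack, q = 1), "q must")
})

test_that("vanishing SNR yields empty final masks", {
  roi <- roiCuboid(c(5, 5, 5), c(5, 5, 5), c(16, 16, 16))
  cfg <- simConfig(nSubjects = 60, nFeatures = 10, gridShape = c(16, 16, 16),
                   moduleSpec = data.frame(module_id = 1, n_features = 10,
                                           within_correlation = 0.9),
                   couplingSpec = list(list(module = 1, roi = roi,
                                            beta = 0.5)),
                   noise = list(smoothSigma = 2, sd = 500),
                   maskType = "box", seed = 32)
  om <- generateOmics(cfg)
  stack <- generateR2Stack(cfg, om$latents)
  mp <- mapAllModules(ModuleLevels(om$latents), stack, q = 0.05,
                      minClusterVoxels = 100)
  expect_true(all(mp$summary$n_sig_final == 0))
})

test_that("pooled and per-module BH families agree on a single module", {
  set.seed(12)
  vals <- matrix(rnorm(30 * 64), 30, 64)
  stack <- tinyStack(vals, dm = c(4, 4, 4))
  lv <- ModuleLevels(matrix(rnorm(30), 1, 30,
                            dimnames = list("1", subjectIds(stack))))
  a <- mapAllModules(lv, stack, family = "per_module")
  b <- mapAllModules(lv, stack, family = "pooled")
  expect_identical(sigMask(a$results[["1"]], final = FALSE),
                   sigMask(b$results[["1"]], final = FALSE))
})
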