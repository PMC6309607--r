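test_that("planted module correlation follows the single-factor model", {
  # degenerate: within_correlation 1 makes all members copies of the latent
  cfg1 <- simConfig(nSubjects = 30, nFeatures = 10,
                    moduleSpec = data.frame(module_id = 1, n_features = 10,
                                            within_correlation = 1),
                    seed = 11)
  om1 <- generateOmics(cfg1)
  cc <- cor(t(assay(om1$omics, "omics")))
  expect_equal(max(abs(cc - 1)), 0, tolerance = 1e-12)

  # two 50-feature modules at 0.6: mean within-module sample r within 0.05
  cfg <- simConfig(nSubjects = 200, nFeatures = 100,
                   moduleSpec = data.frame(module_id = 1:2, n_features = 50,
                                           within_correlation = 0.6),
                   seed = 5)
  om <- generateOmics(cfg)
  cc <- cor(t(assay(om$omics, "omics")))
  for (rows in list(1:50, 51:100)) {
    w <- cc[rows, rows]
    expect_lt(abs(mean(w[upper.tri(w)]) - 0.6), 0.05)
  }
})

test_that("planted within-module correlation converges to its target", {
  cfg <- simConfig(nSubjects = 2000, nFeatures = 60,
                   moduleSpec = data.frame(module_id = 1, n_features = 60,
                                           within_correlation = 0.6),
                   seed = 42)
  om <- generateOmics(cfg)
  cc <- cor(t(assay(om$omics, "omics")))
  expect_lt(abs(mean(cc[upper.tri(cc)]) - 0.6), 0.02)
})

test_that("omics generation is seed-deterministic and validates its config", {
  cfg <- simConfig(nSubjects = 20, nFeatures = 30, seed = 3,
                   moduleSpec = data.frame(module_id = 1, n_features = 10,
                                           within_correlation = 0.5))
  a <- generateOmics(cfg)
  b <- generateOmics(cfg)
  expect_identical(assay(a$omics, "omics"), assay(b$omics, "omics"))
  expect_identical(a$latents, b$latents)

  expect_error(simConfig(nFeatures = 10,
                         moduleSpec = data.frame(module_id = 1,
                                                 n_features = 50,
                                                 within_correlation = 0.5)),
               "exceed")
  expect_error(simConfig(moduleSpec = data.frame(module_id = 1,
                                                 n_features = 10,
                                                 within_correlation = 1.2),
                         nFeatures = 20), "within_correlation")
})

test_that("R2 stack composes baseline, couplings and pathology as planted", {
  roi <- roiCuboid(c(3, 3, 3), c(5, 5, 5), c(12, 12, 12))
  # zero effects, zero noise: every in-mask voxel equals the baseline
  cfg0 <- simConfig(nSubjects = 10, nFeatures = 5, gridShape = c(12, 12, 12),
                    moduleSpec = data.frame(module_id = 1, n_features = 5,
                                            within_correlation = 0.9),
                    noise = list(smoothSigma = 2, sd = 0), baseline = 20,
                    seed = 2)
  om <- generateOmics(cfg0)
  st0 <- generateR2Stack(cfg0, om$latents)
  inm <- which(as.vector(brainMask(st0)))
  expect_true(all(voxelValues(st0)[, inm] == 20))

  # beta = 1, zero noise: in-ROI voxels correlate perfectly with the latent
  cfgb <- simConfig(nSubjects = 10, nFeatures = 5, gridShape = c(12, 12, 12),
                    moduleSpec = data.frame(module_id = 1, n_features = 5,
                                            within_correlation = 0.9),
                    couplingSpec = list(list(module = 1, roi = roi, beta = 1)),
                    noise = list(smoothSigma = 2, sd = 0), seed = 2)
  stb <- generateR2Stack(cfgb, om$latents)
  roiIn <- intersect(roi, inm)
  r <- cor(om$latents[1, ], voxelValues(stb)[, roiIn[1]])
  expect_equal(r, 1, tolerance = 1e-12)
  # and ground truth records exactly that ROI
  omb <- generateOmics(cfgb)
  expect_identical(unlist(omb$truth$trueCoupledVoxels[["1"]]), roi)
})

test_that("smoothed noise fields are spatially autocorrelated", {
  cfg <- simConfig(nSubjects = 6, nFeatures = 5, gridShape = c(20, 20, 20),
                   moduleSpec = data.frame(module_id = 1, n_features = 5,
                                           within_correlation = 0.9),
                   noise = list(smoothSigma = 2, sd = 1), maskType = "box",
                   baseline = 0, seed = 9)
  st <- generateR2Stack(cfg)
  d <- gridDim(st)
  x <- xl <- NULL
  for (s in seq_len(nrow(voxelValues(st)))) {
    v <- array(voxelValues(st)[s, ], d)
    x <- c(x, as.vector(v[2:(d[1] - 2), 2:(d[2] - 1), 2:(d[3] - 1)]))
    xl <- c(xl, as.vector(v[3:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)]))
  }
  expect_gt(cor(x, xl), 0.3)
  # marginal SD near the configured noise SD (kernel l2 norm divided out)
  expect_equal(sd(x), 1, tolerance = 0.15)
})

test_that("streamline endpoint pairs follow the stated distribution", {
  cfg <- simConfig(nSubjects = 10, nFeatures = 5,
                   moduleSpec = data.frame(module_id = 1, n_features = 5,
                                           within_correlation = 0.9),
                   seed = 21)
  pp <- data.frame(region_a = c("A", "A", "B"), region_b = c("B", "C", "C"),
                   prob = c(0.5, 0.3, 0.2))
  st <- generateStreamlines(cfg, 10000, c("A", "B", "C"), pp)
  rec <- streamlineRecords(st)
  expect_true(all(lengths(rec$traversed) > 0))
  freq <- table(paste(rec$region_a, rec$region_b)) / nrow(rec)
  expect_lt(abs(freq[["A B"]] - 0.5), 0.02)
  expect_lt(abs(freq[["A C"]] - 0.3), 0.02)
  expect_lt(abs(freq[["B C"]] - 0.2), 0.02)
  # determinism and degenerate single-pair case
  st2 <- generateStreamlines(cfg, 10000, c("A", "B", "C"), pp)
  expect_identical(streamlineRecords(st), streamlineRecords(st2))
  one <- generateStreamlines(cfg, 50, c("A", "B"),
                             data.frame(region_a = "A", region_b = "B",
                                        prob = 1))
  expect_true(all(streamlineRecords(one)$region_a == "A"))
  expect_error(generateStreamlines(cfg, 0, c("A", "B")), "nStreamlines")
})

test_that("trait generator plants the requested variance decomposition", {
  # module-only R^2 = 0.17 at n = 200: empirical value within sampling error
  cfg <- simConfig(seed = 4, traitSpec = list(r2_module = 0.17))
  m <- rnorm(200)
  tr <- generateTraits(cfg, m)
  r2 <- summary(lm(tr$cognitive_decline ~ m))$r.squared
  expect_lt(abs(r2 - 0.17), 0.08)

  # all weights zero: R^2 near zero
  cfg0 <- simConfig(seed = 4, traitSpec = list(r2_module = 0))
  tr0 <- generateTraits(cfg0, m)
  expect_lt(summary(lm(tr0$cognitive_decline ~ m))$r.squared, 0.05)

  # noise-free single predictor: R^2 = 1
  cfg1 <- simConfig(seed = 4, traitSpec = list(r2_module = 1))
  tr1 <- generateTraits(cfg1, m)
  expect_equal(summary(lm(tr1$cognitive_decline ~ m))$r.squared, 1,
               tolerance = 1e-12)

  # over-committed variance budget is rejected
  expect_error(simConfig(traitSpec = list(r2_module = 0.8,
                                          pathology_weight = 0.7)),
               "exceed")
})

test_that("ground truth round-trips through JSON serialization", {
  cfg <- simConfig(nSubjects = 15, nFeatures = 20, seed = 8,
                   moduleSpec = data.frame(module_id = 1:2, n_features = 8,
                                           within_correlation = c(0.5, 0.7)),
                   couplingSpec = list(list(module = 1,
                                            roi = roiCuboid(c(2, 2, 2),
                                                            c(3, 3, 3),
                                                            c(24, 24, 24)),
                                            beta = 1.5)))
  truth <- generateOmics(cfg)$truth
  f <- tempfile(fileext = ".json")
  writeGroundTruth(truth, f)
  back <- readGroundTruth(f)
  expect_identical(unlist(back$truePartition), unlist(truth$truePartition))
  expect_identical(unlist(back$trueCoupledVoxels[["1"]]),
                   unlist(truth$trueCoupledVoxels[["1"]]))
  expect_equal(back$trueEffects$trait$r2_module,
               truth$trueEffects$trait$r2_module)
})
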