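test_that("correlation matrix matches hand-evaluated Pearson values", {
  # duplicated feature -> off-diagonal 1; anti-linear pair -> -1;
  # (1,2,3,4) vs (1,3,2,4) -> 0.8 by direct evaluation of the formula
  m <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8),
             c = c(4, 3, 2, 1), d = c(1, 3, 2, 4))
  colnames(m) <- paste0("s", 1:4)
  cc <- correlationMatrix(OmicsMatrix(m, "expression"))
  expect_equal(cc["a", "b"], 1)
  expect_equal(cc["a", "c"], -1)
  expect_equal(cc["a", "d"], 0.8)
  expect_equal(cc, t(cc))
  expect_true(all(diag(cc) == 1))
})

test_that("correlation matrix rejects degenerate inputs by name", {
  m <- rbind(a = c(1, 2, 3, 4), flat = c(2, 2, 2, 2))
  colnames(m) <- paste0("s", 1:4)
  expect_error(correlationMatrix(OmicsMatrix(m, "expression")), "flat")
  two <- OmicsMatrix(matrix(1:4, 2, 2,
                            dimnames = list(c("a", "b"), c("s1", "s2"))),
                     "expression")
  expect_error(correlationMatrix(two), "3 subjects")
})

test_that("variance filter drops constant features with a message", {
  m <- rbind(a = c(1, 2, 3, 4), flat = c(2, 2, 2, 2), b = c(0, 1, 0, 2))
  colnames(m) <- paste0("s", 1:4)
  expect_message(f <- filterFeatures(OmicsMatrix(m, "expression")),
                 "1 zero-variance")
  expect_identical(rownames(f), c("a", "b"))
})

test_that("consensus clustering recovers perfectly separable blocks", {
  p <- 10
  cc <- matrix(0, 2 * p, 2 * p)
  cc[1:p, 1:p] <- 1
  cc[(p + 1):(2 * p), (p + 1):(2 * p)] <- 1
  diag(cc) <- 1
  rownames(cc) <- colnames(cc) <- sprintf("f%02d", 1:(2 * p))
  part <- consensusCluster(cc, minModuleSize = 5, seed = 1)
  a <- moduleAssignment(part)
  truth <- rep(1:2, each = p)
  expect_equal(mclust::adjustedRandIndex(a, truth), 1)
  expect_identical(unname(sort(moduleSizes(part))), c(10L, 10L))
})

test_that("identity and empty correlation matrices are handled", {
  id <- diag(20)
  rownames(id) <- colnames(id) <- sprintf("f%02d", 1:20)
  part <- consensusCluster(id, minModuleSize = 3, seed = 1)
  expect_length(moduleSizes(part), 0)
  expect_true(all(moduleAssignment(part) == 0L))
  expect_error(consensusCluster(matrix(numeric(0), 0, 0)), "empty")
})

test_that("clustering is deterministic under a seed and order-invariant on
           separable data", {
  cfg <- simConfig(nSubjects = 120, nFeatures = 60, seed = 13,
                   moduleSpec = data.frame(module_id = 1:2, n_features = 25,
                                           within_correlation = 0.8))
  om <- generateOmics(cfg)
  cc <- correlationMatrix(om$omics)
  p1 <- consensusCluster(cc, minModuleSize = 10, seed = 7)
  p2 <- consensusCluster(cc, minModuleSize = 10, seed = 7)
  expect_identical(moduleAssignment(p1), moduleAssignment(p2))

  perm <- sample(nrow(cc))
  p3 <- consensusCluster(cc[perm, perm], minModuleSize = 10, seed = 7)
  a3 <- moduleAssignment(p3)[names(moduleAssignment(p1))]
  expect_equal(mclust::adjustedRandIndex(a3, moduleAssignment(p1)), 1)
})

test_that("recovery is monotone in the planted within-module correlation", {
  ari <- vapply(c(0.3, 0.5, 0.7, 0.9), function(r) {
    mean(vapply(1:3, function(s) {
      cfg <- simConfig(nSubjects = 200, nFeatures = 150, seed = 100 * s,
                       moduleSpec = data.frame(module_id = 1:2,
                                               n_features = 40,
                                               within_correlation = r))
      om <- generateOmics(cfg)
      part <- consensusCluster(correlationMatrix(om$omics), seed = s)
      mclust::adjustedRandIndex(moduleAssignment(part),
                                unlist(om$truth$truePartition))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(ari) >= -0.02))
  expect_gt(ari[4], 0.95)
})

test_that("module averages equal the mean of z-scored member features", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(5, 1, 2, 9))
  colnames(m) <- paste0("s", 1:4)
  om <- OmicsMatrix(m, "expression")
  part <- new("ModulePartition",
              assignment = c(a = 1L, b = 1L, c = 2L),
              moduleSizes = c(`1` = 2L, `2` = 1L),
              consensusSummary = c(`1` = 1, `2` = 1), parameters = list())
  lv <- assay(moduleAverages(om, part), "levels")
  z <- t(scale(t(m)))                   # independent z-score path
  expect_equal(unname(lv["1", ]), unname(colMeans(z[c("a", "b"), ])))
  # singleton module: its row is that feature's z-scores
  expect_equal(unname(lv["2", ]), unname(z["c", ]))
  # two identical-profile features: the shared z-profile
  expect_equal(unname(lv["1", ]), unname(z["a", ]))
})

test_that("module level rows are centered with SD at most 1", {
  cfg <- simConfig(nSubjects = 80, nFeatures = 60, seed = 17,
                   moduleSpec = data.frame(module_id = 1:2, n_features = 25,
                                           within_correlation = c(0.6, 1)))
  om <- generateOmics(cfg)
  part <- consensusCluster(correlationMatrix(om$omics), minModuleSize = 10,
                           seed = 2)
  lv <- assay(moduleAverages(om$omics, part), "levels")
  expect_equal(max(abs(rowMeans(lv))), 0, tolerance = 1e-12)
  expect_true(all(apply(lv, 1, sd) <= 1 + 1e-12))
  # perfectly correlated module attains SD 1 exactly
  expect_equal(max(apply(lv, 1, sd)), 1, tolerance = 1e-12)
})

test_that("module averaging rejects unknown features and empty partitions", {
  om <- tinyOmics()
  bad <- new("ModulePartition", assignment = c(zz = 1L),
             moduleSizes = c(`1` = 1L), consensusSummary = c(`1` = 1),
             parameters = list())
  expect_error(moduleAverages(om, bad), "absent")
  none <- new("ModulePartition",
              assignment = setNames(integer(3), rownames(om)),
              moduleSizes = setNames(integer(0), character(0)),
              consensusSummary = setNames(numeric(0), character(0)),
              parameters = list())
  expect_error(moduleAverages(om, none), "no named modules")
})
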