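## Synthetic cohort generator: plants coexpression/comethylation modules,
## voxel-module couplings, pathology confounding and trait effects with known
## ground truth, emulating the statistical structure of a ~200-subject
## postmortem imaging + DLPFC omics cohort.

#' SimConfig: configuration of the synthetic imaging-omics cohort
#'
#' @slot nSubjects number of subjects.
#' @slot nFeatures total omics features (planted module members + background).
#' @slot moduleSpec data.frame with columns `module_id` (integer),
#'   `n_features`, `within_correlation` (target pairwise Pearson correlation
#'   among module members, in (0, 1]).
#' @slot gridShape integer(3) voxel grid.
#' @slot voxelSize isotropic voxel edge (mm).
#' @slot maskType `"ellipsoid"` (brain-like) or `"box"` (all but a 1-voxel
#'   border).
#' @slot baseline mean in-mask R2 value (1/s).
#' @slot couplingSpec list of `list(module=, roi=, beta=)`: module level is
#'   added to R2 in the ROI (1-based linear voxel indices) with slope beta.
#' @slot pathologySpec list with optional elements `r2` (list of
#'   `list(pathology=, roi=, gamma=)`; `roi = NULL` means the whole mask) and
#'   `modules` (named numeric: correlation of each module's latent factor with
#'   the z-scored named pathology, names are module ids).
#' @slot noise list: `smoothSigma` (Gaussian kernel SD, voxels) and `sd`
#'   (marginal SD of the smoothed residual field).
#' @slot traitSpec list: `r2_module` (population R-squared of cognitive
#'   decline on the module level), `r2_increment` (R-squared gained by the
#'   module over the mean-R2 base predictor), `pathology_weight`
#'   (standardized linear weight of global AD pathology).
#' @slot seed integer root seed; all stages draw from named substreams of it.
#' @export
setClass("SimConfig",
  slots = c(nSubjects = "integer", nFeatures = "integer",
            moduleSpec = "data.frame", gridShape = "integer",
            voxelSize = "numeric", maskType = "character",
            baseline = "numeric", couplingSpec = "list",
            pathologySpec = "list", noise = "list", traitSpec = "list",
            seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nSubjects < 2L) msg <- c(msg, "nSubjects must be >= 2")
  if (object@nFeatures < 1L) msg <- c(msg, "nFeatures must be positive")
  ms <- object@moduleSpec
  if (nrow(ms)) {
    if (any(ms$n_features < 1)) msg <- c(msg, "module n_features must be positive")
    if (any(ms$within_correlation <= 0 | ms$within_correlation > 1))
      msg <- c(msg, "within_correlation must lie in (0, 1]")
    if (sum(ms$n_features) > object@nFeatures)
      msg <- c(msg, "module feature counts exceed nFeatures")
    if (anyDuplicated(ms$module_id)) msg <- c(msg, "duplicate module ids")
  }
  if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
    msg <- c(msg, "gridShape must be 3 positive integers")
  nvox <- prod(object@gridShape)
  for (cs in object@couplingSpec)
    if (any(cs$roi < 1L) || any(cs$roi > nvox))
      msg <- c(msg, "coupling ROI indices must lie inside the grid")
  if (!object@maskType %in% c("ellipsoid", "box"))
    msg <- c(msg, "maskType must be 'ellipsoid' or 'box'")
  if (object@noise$smoothSigma < 0 || object@noise$sd < 0)
    msg <- c(msg, "noise parameters must be nonnegative")
  ts <- object@traitSpec
  tot <- ts$r2_module + ts$r2_increment + ts$pathology_weight^2
  if (tot > 1) msg <- c(msg, "requested trait variance components exceed 1")
  if (length(msg)) msg else TRUE
})

#' Build a simulation configuration
#'
#' Defaults emulate the study conditions the package is designed around: a
#' cohort of 200 subjects, four planted 50-feature modules at within-module
#' correlation 0.6 among 400 features, a 24x24x24 grid of 1 mm voxels with a
#' brain-like ellipsoid mask, spatially smooth residual R2 noise (Gaussian
#' kernel SD 2 voxels, unit marginal SD), and a cognitive-decline slope with
#' population module R-squared 0.17.
#'
#' @param nSubjects,nFeatures,moduleSpec,gridShape,voxelSize,maskType,baseline,couplingSpec,pathologySpec,noise,traitSpec,seed
#'   see [SimConfig-class].
#' @return A validated [SimConfig-class] object.
#' @export
simConfig <- function(nSubjects = 200, nFeatures = 400,
                      moduleSpec = data.frame(module_id = 1:4, n_features = 50,
                                              within_correlation = 0.6),
                      gridShape = c(24, 24, 24), voxelSize = 1,
                      maskType = "ellipsoid", baseline = 20,
                      couplingSpec = list(), pathologySpec = list(),
                      noise = list(smoothSigma = 2, sd = 1),
                      traitSpec = list(r2_module = 0.17, r2_increment = 0,
                                       pathology_weight = 0),
                      seed = 1) {
  ts <- list(r2_module = 0.17, r2_increment = 0, pathology_weight = 0)
  ts[names(traitSpec)] <- traitSpec
  ns <- list(smoothSigma = 2, sd = 1)
  ns[names(noise)] <- noise
  new("SimConfig", nSubjects = as.integer(nSubjects),
      nFeatures = as.integer(nFeatures), moduleSpec = moduleSpec,
      gridShape = as.integer(gridShape), voxelSize = as.numeric(voxelSize),
      maskType = maskType, baseline = as.numeric(baseline),
      couplingSpec = couplingSpec, pathologySpec = pathologySpec,
      noise = ns, traitSpec = ts, seed = as.integer(seed))
}

## Deterministic named substreams of the root seed: stages are independently
## reproducible and adding a stage never perturbs another stage's draws.
.substreams <- c(pathology = 1L, omics = 2L, volumes = 3L,
                 streamlines = 4L, traits = 5L, clustering = 6L)

substreamSeed <- function(seed, stream) {
  off <- .substreams[[stream]]
  as.integer((as.numeric(seed) %% 2^31 + off * 1000003) %% 2147483629)
}

#' Brain mask for a synthetic grid
#'
#' @param gridShape integer(3).
#' @param type `"ellipsoid"`: voxels inside the inscribed ellipsoid;
#'   `"box"`: all voxels except a 1-voxel border.
#' @return logical 3D array.
#' @export
makeBrainMask <- function(gridShape, type = c("ellipsoid", "box")) {
  type <- match.arg(type)
  d <- as.integer(gridShape)
  if (type == "box") {
    m <- array(TRUE, d)
    m[c(1, d[1]), , ] <- FALSE
    m[, c(1, d[2]), ] <- FALSE
    m[, , c(1, d[3])] <- FALSE
    return(m)
  }
  ctr <- (d + 1) / 2
  ax <- (d - 1) / 2
  g <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
  inside <- ((g$i - ctr[1]) / ax[1])^2 + ((g$j - ctr[2]) / ax[2])^2 +
    ((g$k - ctr[3]) / ax[3])^2 <= 1
  array(inside, d)
}

#' Cuboid region of interest as linear voxel indices
#'
#' @param corner integer(3) lower corner (1-based).
#' @param size integer(3) extent along each axis.
#' @param gridShape integer(3).
#' @return integer vector of 1-based linear indices into the grid.
#' @export
roiCuboid <- function(corner, size, gridShape) {
  d <- as.integer(gridShape)
  hi <- corner + size - 1L
  if (any(corner < 1L) || any(hi > d)) stop("ROI extends outside the grid")
  ii <- corner[1]:hi[1]; jj <- corner[2]:hi[2]; kk <- corner[3]:hi[3]
  idx <- as.vector(outer(outer(ii, (jj - 1L) * d[1], "+"),
                         (kk - 1L) * d[1] * d[2], "+"))
  sort(idx)
}

#' Simulate neuropathology indicators
#'
#' Gamma-distributed severity scores and Bernoulli presence indicators with
#' moments matching an aged, community-based autopsy cohort (global AD
#' pathology mean 0.75, SD 0.62; amyloid 4.82/4.52; tangles 6.89/8.18; gross
#' infarcts 32.4%, microinfarcts 25.7%, Lewy bodies 20.3%).
#'
#' @param cfg a [SimConfig-class].
#' @return data.frame with subject_id, continuous scores and binary
#'   indicators.
#' @export
generatePathology <- function(cfg) {
  set.seed(substreamSeed(cfg@seed, "pathology"))
  n <- cfg@nSubjects
  rgam <- function(m, s) stats::rgamma(n, shape = (m / s)^2, scale = s^2 / m)
  data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    global_ad_pathology = rgam(0.75, 0.62),
    amyloid = rgam(4.82, 4.52),
    tangles = rgam(6.89, 8.18),
    gross_infarcts = rbinom(n, 1, 0.324),
    microinfarcts = rbinom(n, 1, 0.257),
    lewy_bodies = rbinom(n, 1, 0.203))
}

#' Simulate the omics matrix with planted modules
#'
#' Each planted module has one latent subject factor f ~ N(0,1); member
#' features are sqrt(r)*f + sqrt(1-r)*noise so the expected pairwise
#' within-module Pearson correlation equals the configured
#' `within_correlation` r (single-factor model, r = b^2/(b^2+sigma^2) with
#' b = sqrt(r)). Background features are independent N(0,1). If
#' `pathologySpec$modules` names a module, its latent factor is built as
#' delta * z(pathology) + sqrt(1-delta^2) * innovation, planting a
#' pathology-module correlation of delta.
#'
#' @param cfg a [SimConfig-class].
#' @param pathology optional data.frame from [generatePathology()]; required
#'   when `pathologySpec$modules` is nonempty.
#' @return list with `omics` ([OmicsMatrix-class]), `latents` (modules x
#'   subjects matrix of the latent factors) and `truth` (ground-truth list:
#'   `truePartition`, `trueEffects`).
#' @export
generateOmics <- function(cfg, pathology = NULL) {
  validObject(cfg)
  set.seed(substreamSeed(cfg@seed, "omics"))
  n <- cfg@nSubjects
  p <- cfg@nFeatures
  ms <- cfg@moduleSpec
  subjects <- sprintf("S%04d", seq_len(n))
  features <- sprintf("f%05d", seq_len(p))
  vals <- matrix(NA_real_, p, n, dimnames = list(features, subjects))
  part <- setNames(integer(p), features)
  pmod <- cfg@pathologySpec$modules
  if (length(pmod) && is.null(pathology))
    stop("pathologySpec$modules requires a pathology table")
  latents <- matrix(0, nrow(ms), n,
                    dimnames = list(as.character(ms$module_id), subjects))
  at <- 1L
  for (j in seq_len(nrow(ms))) {
    k <- ms$n_features[j]; r <- ms$within_correlation[j]
    mid <- as.character(ms$module_id[j])
    f <- rnorm(n)
    if (!is.null(pmod) && mid %in% names(pmod)) {
      delta <- pmod[[mid]]
      pz <- as.vector(scale(pathology$global_ad_pathology))
      f <- delta * pz + sqrt(1 - delta^2) * f
    }
    latents[mid, ] <- f
    rows <- at:(at + k - 1L)
    eps <- matrix(rnorm(k * n), k, n)
    vals[rows, ] <- sqrt(r) * matrix(f, k, n, byrow = TRUE) + sqrt(1 - r) * eps
    part[rows] <- as.integer(ms$module_id[j])
    at <- at + k
  }
  nbg <- p - sum(ms$n_features)
  if (nbg > 0)
    vals[at:(at + nbg - 1L), ] <- matrix(rnorm(nbg * n), nbg, n)
  coupled <- lapply(cfg@couplingSpec, function(cs) as.list(cs$roi))
  names(coupled) <- vapply(cfg@couplingSpec,
                           function(cs) as.character(cs$module), character(1))
  truth <- list(truePartition = as.list(part),
                trueCoupledVoxels = coupled,
                trueEffects = list(
                  within_correlation = setNames(as.list(ms$within_correlation),
                                                as.character(ms$module_id)),
                  coupling_beta = setNames(
                    lapply(cfg@couplingSpec, function(cs) cs$beta),
                    vapply(cfg@couplingSpec,
                           function(cs) as.character(cs$module), character(1))),
                  pathology_module = as.list(pmod %||% list()),
                  trait = cfg@traitSpec))
  list(omics = OmicsMatrix(vals, "expression"), latents = latents,
       truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

gaussKernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

## Separable 3D Gaussian convolution of many volumes at once.
## E: nvox x nsub matrix (volumes in column-major grid order).
## The result is rescaled so white noise keeps unit marginal variance in the
## grid interior (the composite kernel's l2 norm is divided out).
smoothVolumes <- function(E, gridShape, sigma) {
  if (sigma <= 0) return(E)
  d <- as.integer(gridShape)
  ns <- ncol(E)
  k <- gaussKernel1d(sigma)
  r <- (length(k) - 1L) / 2L
  band <- function(n) {
    K <- matrix(0, n, n)
    for (o in -r:r) {
      idx <- seq_len(n - abs(o))
      if (o >= 0) K[cbind(idx, idx + o)] <- k[o + r + 1L]
      else K[cbind(idx - o, idx)] <- k[o + r + 1L]
    }
    K
  }
  A <- array(E, c(d, ns))
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:3, ax), 4L)
    Ap <- aperm(A, perm)
    dp <- dim(Ap)
    M <- band(dp[1]) %*% matrix(Ap, dp[1])
    A <- aperm(array(M, dp), order(perm))
  }
  matrix(A, prod(d), ns) / sqrt(sum(k^2))^3
}

#' Simulate the R2 volume stack
#'
#' Per subject, in-mask voxel value = baseline + sum of planted module
#' couplings (beta * module latent over each coupled ROI) + pathology effects
#' (gamma * z-scored pathology over its ROI or the whole mask) + spatially
#' smoothed Gaussian noise with marginal SD `noise$sd`.
#'
#' @param cfg a [SimConfig-class].
#' @param latents modules x subjects latent matrix from [generateOmics()]
#'   (module ids as rownames); may be NULL when `couplingSpec` is empty.
#' @param pathology optional pathology table aligned to the same subjects.
#' @return An [R2Stack-class].
#' @export
generateR2Stack <- function(cfg, latents = NULL, pathology = NULL) {
  validObject(cfg)
  set.seed(substreamSeed(cfg@seed, "volumes"))
  n <- cfg@nSubjects
  d <- cfg@gridShape
  nvox <- prod(d)
  subjects <- sprintf("S%04d", seq_len(n))
  if (!is.null(latents) && ncol(latents) != n)
    stop("subject mismatch between latents and configuration")
  if (!is.null(pathology) && nrow(pathology) != n)
    stop("subject mismatch between pathology table and configuration")
  vals <- matrix(cfg@baseline, n, nvox, dimnames = list(subjects, NULL))
  for (cs in cfg@couplingSpec) {
    if (is.null(latents) || !as.character(cs$module) %in% rownames(latents))
      stop("couplingSpec references module absent from latents: ", cs$module)
    vals[, cs$roi] <- vals[, cs$roi] +
      cs$beta * latents[as.character(cs$module), ]
  }
  for (ps in cfg@pathologySpec$r2 %||% list()) {
    if (is.null(pathology)) stop("pathologySpec$r2 requires a pathology table")
    pz <- as.vector(scale(pathology[[ps$pathology]]))
    roi <- ps$roi %||% seq_len(nvox)
    vals[, roi] <- vals[, roi] + ps$gamma * pz
  }
  if (cfg@noise$sd > 0) {
    E <- matrix(rnorm(nvox * n), nvox, n)
    E <- smoothVolumes(E, d, cfg@noise$smoothSigma)
    vals <- vals + cfg@noise$sd * t(E)
  }
  mask <- makeBrainMask(d, cfg@maskType)
  R2Stack(vals, mask, cfg@voxelSize)
}

#' Simulate a streamline-connectivity table
#'
#' Endpoint region pairs are drawn from a categorical distribution over
#' region pairs; each streamline's traversed voxel set is an axis-aligned
#' segment from a random in-grid start (length 3 + Poisson(5), clipped at the
#' grid boundary).
#'
#' @param cfg a [SimConfig-class].
#' @param nStreamlines number of records (>= 1).
#' @param regionLabels character vector of >= 2 gray-region labels.
#' @param pairProbs optional data.frame (region_a, region_b, prob); defaults
#'   to uniform over all unordered distinct pairs.
#' @return A [StreamlineTable-class].
#' @export
generateStreamlines <- function(cfg, nStreamlines, regionLabels,
                                pairProbs = NULL) {
  if (nStreamlines < 1) stop("nStreamlines must be >= 1")
  if (length(regionLabels) < 2) stop("need at least 2 gray-region labels")
  set.seed(substreamSeed(cfg@seed, "streamlines"))
  if (is.null(pairProbs)) {
    cmb <- utils::combn(sort(regionLabels), 2)
    pairProbs <- data.frame(region_a = cmb[1, ], region_b = cmb[2, ],
                            prob = 1 / ncol(cmb))
  }
  if (abs(sum(pairProbs$prob) - 1) > 1e-8)
    stop("pair probabilities must sum to 1")
  d <- cfg@gridShape
  pick <- sample.int(nrow(pairProbs), nStreamlines, replace = TRUE,
                     prob = pairProbs$prob)
  start <- cbind(sample.int(d[1], nStreamlines, TRUE),
                 sample.int(d[2], nStreamlines, TRUE),
                 sample.int(d[3], nStreamlines, TRUE))
  axis <- sample.int(3, nStreamlines, TRUE)
  len <- 3L + rpois(nStreamlines, 5)
  traversed <- lapply(seq_len(nStreamlines), function(i) {
    pos <- start[i, ]
    steps <- pos[axis[i]]:min(d[axis[i]], pos[axis[i]] + len[i] - 1L)
    coords <- matrix(pos, length(steps), 3, byrow = TRUE)
    coords[, axis[i]] <- steps
    as.integer(coords[, 1] + (coords[, 2] - 1L) * d[1] +
                 (coords[, 3] - 1L) * d[1] * d[2])
  })
  rec <- data.frame(streamline_id = seq_len(nStreamlines),
                    region_a = pairProbs$region_a[pick],
                    region_b = pairProbs$region_b[pick])
  rec$traversed <- traversed
  new("StreamlineTable", records = rec,
      regionLabels = sort(unique(regionLabels)), gridDim = d)
}

#' Simulate the trait table with a planted variance decomposition
#'
#' The cognitive-decline slope is built so that the population R-squared of a
#' regression on the module level equals `traitSpec$r2_module`, and — when
#' `traitSpec$r2_increment > 0` and an `r2Summary` predictor is supplied —
#' adding the module to a regression already containing `r2Summary` raises
#' R-squared by exactly `traitSpec$r2_increment`. Writing the slope as
#' y = alpha*m + beta*b + sigma*eps with m, b the standardized module level
#' and R2 base and rho their sample correlation, the increment is
#' alpha^2 (1 - rho^2) and the marginal module R-squared is
#' (alpha + beta*rho)^2, which the generator solves for alpha and beta. The
#' residual is drawn orthogonal (in sample) to the planted predictors, so the
#' requested decomposition holds exactly for the simulated cohort and not
#' just in expectation.
#' Global AD pathology enters with standardized weight
#' `traitSpec$pathology_weight`. Also emits covariates (age at death, sex,
#' years of education), a correlated global-cognition score, and a binary AD
#' diagnosis.
#'
#' @param cfg a [SimConfig-class].
#' @param moduleLevel numeric per-subject module level (the mapped module).
#' @param r2Summary optional per-subject mean R2 over a reference mask,
#'   required when `traitSpec$r2_increment > 0`.
#' @param pathology optional pathology table; required when
#'   `traitSpec$pathology_weight != 0`.
#' @return data.frame of traits and covariates, one row per subject.
#' @export
generateTraits <- function(cfg, moduleLevel, r2Summary = NULL,
                           pathology = NULL) {
  validObject(cfg)
  set.seed(substreamSeed(cfg@seed, "traits"))
  n <- cfg@nSubjects
  if (length(moduleLevel) != n) stop("moduleLevel/config subject mismatch")
  ts <- cfg@traitSpec
  m <- as.vector(scale(moduleLevel))
  lp <- numeric(n)
  varExplained <- 0
  if (ts$r2_increment > 0) {
    if (is.null(r2Summary)) stop("r2_increment > 0 requires r2Summary")
    b <- as.vector(scale(r2Summary))
    rho <- cor(m, b)
    if (abs(rho) < 0.05)
      stop("module level and r2Summary are nearly uncorrelated; ",
           "the requested marginal/incremental split is not identifiable")
    alpha <- sqrt(ts$r2_increment / (1 - rho^2))
    beta <- (sqrt(ts$r2_module) - alpha) / rho
    varExplained <- alpha^2 + beta^2 + 2 * alpha * beta * rho
    if (varExplained >= 1)
      stop("requested trait variance components exceed 1")
    lp <- alpha * m + beta * b
  } else if (ts$r2_module > 0) {
    lp <- sqrt(ts$r2_module) * m
    varExplained <- ts$r2_module
  }
  if (ts$pathology_weight != 0) {
    if (is.null(pathology)) stop("pathology_weight != 0 requires a pathology table")
    pz <- as.vector(scale(pathology$global_ad_pathology))
    lp <- lp + ts$pathology_weight * pz
    varExplained <- varExplained + ts$pathology_weight^2
    if (varExplained >= 1) stop("requested trait variance components exceed 1")
  }
  sigma <- sqrt(1 - varExplained)
  ## draw the residual orthogonal to the planted predictors in sample, so the
  ## requested variance decomposition holds exactly for the simulated cohort
  ## rather than only in expectation
  eps <- rnorm(n)
  X0 <- cbind(1, m)
  if (ts$r2_increment > 0) X0 <- cbind(X0, b)
  if (ts$pathology_weight != 0)
    X0 <- cbind(X0, as.vector(scale(pathology$global_ad_pathology)))
  eps <- qr.resid(qr(X0), eps)
  eps <- eps / sd(eps)
  decline <- lp + sigma * eps
  gcog <- 0.7 * as.vector(scale(decline)) + sqrt(1 - 0.49) * rnorm(n)
  if (!is.null(pathology)) {
    pz <- as.vector(scale(pathology$global_ad_pathology))
    pAD <- stats::plogis(stats::qlogis(0.477) + 0.8 * pz)
  } else pAD <- rep(0.477, n)
  out <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    cognitive_decline = decline,
    global_cognition = gcog,
    age_at_death = rnorm(n, 89.75, 5.96),
    sex = rbinom(n, 1, 0.689),
    education = pmax(6, round(rnorm(n, 15.77, 3.59))),
    ad_diagnosis = rbinom(n, 1, pAD))
  if (!is.null(pathology))
    out <- cbind(out, pathology[, setdiff(names(pathology), "subject_id")])
  out
}

#' Write / read ground truth as JSON
#'
#' @param truth ground-truth list (e.g. `generateOmics(cfg)$truth`).
#' @param path file path.
#' @return `readGroundTruth` returns the list.
#' @export
writeGroundTruth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
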