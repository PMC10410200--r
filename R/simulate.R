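## Seeded generator of complete synthetic studies: correlated smooth
## template fields, disjoint tissue masks, and BOLD-like runs whose voxel
## series are template-weighted mixtures of per-system time series with
## planted cell effects and (optionally AR(1)) Gaussian noise. The planted
## structure is returned as ground truth so every analysis stage can be
## validated without any download.

#' Planted effect specification
#'
#' Describes one planted effect: which molecular system it loads on, its
#' type, the compact cluster it occupies, its amplitude in FC units and the
#' 2 x 4 matrix of cell offsets (rows audio/rest, columns
#' awake/light/deep/recovery). A state main effect is constant across
#' conditions, a condition main effect constant across states, an
#' interaction profile has zero row and column margins, and a null effect
#' has amplitude 0.
#'
#' @slot targetSystem System label.
#' @slot effectType One of "interaction", "state_main", "condition_main",
#'   "null".
#' @slot clusterMask \code{VolumeMask} of the planted region.
#' @slot amplitude Effect amplitude in FC units.
#' @slot cellProfile Numeric 2 x 4 matrix of cell offsets.
#' @export
setClass("EffectSpec",
         representation(targetSystem = "character", effectType = "character",
                        clusterMask = "VolumeMask", amplitude = "numeric",
                        cellProfile = "matrix"))

setValidity("EffectSpec", function(object) {
  if (!object@effectType %in% c("interaction", "state_main",
                                "condition_main", "null"))
    return("unknown effect type")
  p <- object@cellProfile
  if (!all(dim(p) == c(2L, 4L)))
    return("cellProfile must be 2 x 4 (condition x state)")
  tol <- 1e-10
  if (object@effectType == "state_main" && max(abs(p[1L, ] - p[2L, ])) > tol)
    return("a state main effect must be constant across conditions")
  if (object@effectType == "condition_main" &&
      (max(abs(p[1L, ] - p[1L, 1L])) > tol ||
       max(abs(p[2L, ] - p[2L, 1L])) > tol))
    return("a condition main effect must be constant across states")
  if (object@effectType == "interaction") {
    pc <- p - rowMeans(p) ; pc <- sweep(pc, 2L, colMeans(pc))
    if (max(abs(rowMeans(pc))) > tol || max(abs(colMeans(pc))) > tol ||
        max(abs(pc - p)) > tol)
      return("an interaction profile must have zero row and column margins")
  }
  if (object@effectType == "null" && object@amplitude != 0)
    return("a null effect must have amplitude 0")
  TRUE
})

.canonicalProfile <- function(effectType) {
  switch(effectType,
         condition_main = rbind(audio = rep(-0.5, 4), rest = rep(0.5, 4)),
         state_main = rbind(audio = c(-0.7, 0.4, 1.0, -0.7),
                            rest = c(-0.7, 0.4, 1.0, -0.7)),
         interaction = rbind(audio = c(0.5, -0.5, -0.5, 0.5),
                             rest = c(-0.5, 0.5, 0.5, -0.5)),
         null = matrix(0, 2, 4))
}

#' Construct an EffectSpec
#'
#' @param targetSystem System label the effect loads on.
#' @param effectType "interaction", "state_main", "condition_main" or
#'   "null".
#' @param clusterMask \code{VolumeMask} of the planted region.
#' @param amplitude Amplitude in FC units (forced to 0 for "null").
#' @param cellProfile Optional 2 x 4 offset matrix; defaults to a canonical
#'   profile for the type (sedation-increasing for state, rest > audio for
#'   condition, audio-vs-rest sign-flipped sedation pattern for the
#'   interaction).
#' @return An \code{EffectSpec}.
#' @export
effectSpec <- function(targetSystem, effectType, clusterMask, amplitude = 1,
                       cellProfile = NULL) {
  if (is.null(cellProfile)) cellProfile <- .canonicalProfile(effectType)
  if (effectType == "null") amplitude <- 0
  new("EffectSpec", targetSystem = targetSystem, effectType = effectType,
      clusterMask = clusterMask, amplitude = as.numeric(amplitude),
      cellProfile = cellProfile)
}

setMethod("show", "EffectSpec", function(object) {
  cat("EffectSpec [", object@effectType, "] on ", object@targetSystem,
      ", amplitude ", object@amplitude, ", cluster of ",
      maskCount(object@clusterMask), " voxels\n", sep = "")
})

#' Audio-only sedation effect pair
#'
#' The qualitative pattern of the propofol findings for a demo: state
#' differences present during the audio condition and absent at rest. That
#' pattern is the sum of a pure (doubly centred) interaction and a state
#' main effect; this helper returns the pair sharing one cluster, system
#' and amplitude.
#'
#' @param targetSystem System label.
#' @param clusterMask \code{VolumeMask} of the planted region.
#' @param amplitude Amplitude in FC units.
#' @return List of two \code{EffectSpec}s (interaction, state_main).
#' @export
audioOnlyEffectPair <- function(targetSystem, clusterMask, amplitude = 1) {
  half <- rbind(audio = c(0.5, -0.5, -0.5, 0.5),
                rest = c(0.5, -0.5, -0.5, 0.5))
  list(effectSpec(targetSystem, "interaction", clusterMask, amplitude),
       effectSpec(targetSystem, "state_main", clusterMask, amplitude,
                  cellProfile = half))
}

## Default inter-system correlation target: weak background collinearity
## with one moderately correlated pair, echoing the low-moderate
## collinearity of empirical transporter/receptor maps.
.defaultTargetCorr <- function(k) {
  C <- matrix(0.2, k, k)
  diag(C) <- 1
  if (k >= 4) C[3L, 4L] <- C[4L, 3L] <- 0.5
  C
}

#' Simulate a conditioned molecular template set
#'
#' Smooth Gaussian random fields are standardised and mixed by the Cholesky
#' factor of a target correlation matrix, then min-max rescaled to [0, 1],
#' giving a conditioned template set whose empirical pairwise correlations
#' approach the target as the grid grows.
#'
#' @param k Number of systems, default 5.
#' @param dim Grid dimensions, default c(20, 20, 20).
#' @param names System labels, default NAT/DAT/SERT/VAChT/GABAA.
#' @param targetCorr Symmetric positive-definite K x K matrix with unit
#'   diagonal; default has 0.2 background and one 0.5 pair.
#' @param smoothFwhmVox Field smoothness (FWHM in voxels), default 2.
#' @param affine Voxel-to-world matrix, default 3 mm isotropic.
#' @param seed Integer seed.
#' @return A conditioned \code{TemplateSet}.
#' @export
simulateTemplates <- function(k = 5, dim = c(20, 20, 20), names = NULL,
                              targetCorr = NULL, smoothFwhmVox = 2,
                              affine = diag(c(3, 3, 3, 1)), seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (is.null(names))
    names <- c("NAT", "DAT", "SERT", "VAChT", "GABAA")[seq_len(k)]
  if (is.null(targetCorr)) targetCorr <- .defaultTargetCorr(k)
  if (!isSymmetric(unname(targetCorr)) ||
      max(abs(diag(targetCorr) - 1)) > 1e-8)
    stop("invalid parameter: targetCorr must be symmetric with unit diagonal",
         call. = FALSE)
  U <- tryCatch(chol(targetCorr), error = function(e)
    stop("invalid parameter: targetCorr is not positive definite",
         call. = FALSE))
  set.seed(seed)
  v <- prod(dim)
  sigma <- rep(smoothFwhmVox / (2 * sqrt(2 * log(2))), 3L)
  Z <- matrix(0, nrow = v, ncol = k)
  for (j in seq_len(k)) {
    field <- array(stats::rnorm(v), dim = dim)
    if (smoothFwhmVox > 0) field <- .smoothVolume(field, sigma)
    Z[, j] <- (field - mean(field)) / stats::sd(field)
  }
  X <- Z %*% U
  out <- array(0, dim = c(dim, k))
  for (j in seq_len(k)) {
    x <- X[, j]
    out[, , , j] <- array((x - min(x)) / (max(x) - min(x)), dim = dim)
  }
  new("TemplateSet", data = out, names = names, affine = affine,
      conditioned = TRUE)
}

#' Simulate disjoint tissue masks
#'
#' Voxels are ranked by distance from the grid centre and assigned, from
#' the inside out, to white matter, grey matter and CSF compartments so
#' that compartment sizes match the requested fractions of the grid to
#' within a voxel. The reference region is the innermost requested fraction
#' of grey matter.
#'
#' @param dim Grid dimensions.
#' @param affine Voxel-to-world matrix, default 3 mm isotropic.
#' @param wmFrac,gmFrac,csfFrac Fractions of the grid assigned to each
#'   compartment (defaults 0.15, 0.40, 0.10).
#' @param refFrac Fraction of grey matter used as reference region,
#'   default 0.05.
#' @return Named list of \code{VolumeMask}s: gm, wm, csf, ref.
#' @export
simulateMasks <- function(dim, affine = diag(c(3, 3, 3, 1)),
                          wmFrac = 0.15, gmFrac = 0.40, csfFrac = 0.10,
                          refFrac = 0.05) {
  if (wmFrac + gmFrac + csfFrac > 1)
    stop("compartment fractions exceed the grid", call. = FALSE)
  v <- prod(dim)
  centre <- (dim + 1) / 2
  coords <- arrayInd(seq_len(v), dim)
  dist <- sqrt(colSums((t(coords) - centre)^2))
  ord <- order(dist)
  nWm <- round(wmFrac * v); nGm <- round(gmFrac * v)
  nCsf <- round(csfFrac * v)
  asMask <- function(idx) {
    a <- array(FALSE, dim = dim)
    a[idx] <- TRUE
    VolumeMask(a, affine)
  }
  wmIdx <- ord[seq_len(nWm)]
  gmIdx <- ord[nWm + seq_len(nGm)]
  csfIdx <- ord[nWm + nGm + seq_len(nCsf)]
  refIdx <- gmIdx[seq_len(round(refFrac * nGm))]
  list(gm = asMask(gmIdx), wm = asMask(wmIdx), csf = asMask(csfIdx),
       ref = asMask(refIdx))
}

## Unit-variance (population) time series matrix, K x T.
.unitSeries <- function(k, nT) {
  s <- matrix(stats::rnorm(k * nT), k, nT)
  s <- s - rowMeans(s)
  s / sqrt(rowMeans(s^2))
}

## T x V Gaussian noise, optionally AR(1) with marginal SD noiseSd.
.noiseMatrix <- function(nT, v, noiseSd, rho) {
  if (noiseSd == 0) return(matrix(0, nT, v))
  if (rho == 0) return(matrix(stats::rnorm(nT * v, sd = noiseSd), nT, v))
  burn <- 50L
  innov <- matrix(stats::rnorm((nT + burn) * v,
                               sd = noiseSd * sqrt(1 - rho^2)),
                  nT + burn, v)
  out <- stats::filter(innov, rho, method = "recursive")
  matrix(out[burn + seq_len(nT), ], nT, v)
}

#' Simulate a complete synthetic study
#'
#' Generates one run per design cell. Each voxel's series is the
#' template-weighted mixture of K unit-SD per-system time series, plus
#' planted cell offsets (amplitude x profile x template value inside the
#' effect cluster, on the target system's loading) and Gaussian noise.
#' Because loadings are proportional to the conditioned template values,
#' the stage-2 enrichment maps are the generative truth: with zero noise
#' and no effects the betas equal the loadings exactly. With all amplitudes
#' zero the study is an exact null for all three effects.
#'
#' @param templates A conditioned \code{TemplateSet}.
#' @param masks Mask list from \code{\link{simulateMasks}}.
#' @param design A \code{StudyDesign}, default 17 subjects.
#' @param tAudio,tRest Volumes per audio / rest run (defaults 155 and 256).
#' @param tr Repetition time in seconds, default 2.
#' @param effects List of \code{EffectSpec}s.
#' @param noiseSd Marginal noise SD, default 1.
#' @param rho AR(1) coefficient of the noise, default 0 (white).
#' @param seed Integer seed; the dataset is fully determined by
#'   (parameters, seed).
#' @param dir Optional output directory; when given, runs are written as
#'   NIfTI with a design TSV, masks, templates and a JSON truth sidecar,
#'   and file paths are returned instead of in-memory scans.
#' @return List with elements \code{runs} (list of \code{Scan4D}, or of
#'   file paths when \code{dir} is given), \code{design}, and \code{truth}
#'   (parameters, effect specs and planted cluster voxels).
#' @export
simulateStudy <- function(templates, masks, design = StudyDesign(17),
                          tAudio = 155, tRest = 256, tr = 2,
                          effects = list(), noiseSd = 1, rho = 0, seed,
                          dir = NULL) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  stopifnot(is(templates, "TemplateSet"), is(design, "StudyDesign"))
  k <- nSystems(templates)
  if (min(tAudio, tRest) <= k)
    stop("invalid parameter: runs must have more volumes than systems",
         call. = FALSE)
  for (e in effects) {
    stopifnot(is(e, "EffectSpec"))
    if (!e@targetSystem %in% systemNames(templates))
      stop("effect targets unknown system ", e@targetSystem, call. = FALSE)
    if (any(!is.finite(e@amplitude)))
      stop("effect amplitude must be finite", call. = FALSE)
    .stopIfGridMismatch(templates, e@clusterMask,
                        "templates and effect cluster")
  }
  d <- gridDim(templates)
  v <- prod(d)
  L0 <- matrix(templates@data, nrow = v)          # V x K loadings
  runs <- designTable(design)
  set.seed(seed)
  scans <- vector("list", nrow(runs))
  series <- vector("list", nrow(runs))
  files <- character(nrow(runs))
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (r in seq_len(nrow(runs))) {
    cond <- runs$condition[r]; state <- runs$state[r]
    ci <- match(cond, design@conditions)
    si <- match(state, design@states)
    nT <- if (cond == "audio") tAudio else tRest
    L <- L0
    for (e in effects) {
      if (e@amplitude == 0) next
      j <- match(e@targetSystem, systemNames(templates))
      offset <- e@amplitude * e@cellProfile[ci, si]
      if (offset != 0) {
        cl <- as.vector(e@clusterMask@data)
        L[cl, j] <- L[cl, j] + offset * L0[cl, j]
      }
    }
    S <- .unitSeries(k, nT)                       # K x T
    rownames(S) <- systemNames(templates)
    series[[r]] <- S
    Y <- L %*% S + t(.noiseMatrix(nT, v, noiseSd, rho))
    scan <- Scan4D(array(Y, dim = c(d, nT)), tr = tr,
                   affine = templates@affine, subject = runs$subject[r],
                   condition = cond, state = state)
    if (is.null(dir)) {
      scans[[r]] <- scan
    } else {
      f <- file.path(dir, sprintf("%s_cond-%s_state-%s_bold.nii.gz",
                                  runs$subject[r], cond, state))
      writeScan(scan, f)
      files[r] <- basename(f)
    }
  }
  truth <- list(
    seed = seed, noiseSd = noiseSd, rho = rho, tr = tr,
    tAudio = tAudio, tRest = tRest,
    systems = systemNames(templates),
    series = series,
    effects = lapply(effects, function(e) list(
      targetSystem = e@targetSystem, effectType = e@effectType,
      amplitude = e@amplitude, cellProfile = e@cellProfile,
      clusterVoxels = which(e@clusterMask@data))))
  class(truth) <- "SimTruth"
  if (!is.null(dir)) {
    runs$file <- files
    runs$tr <- tr
    writeTable(runs, file.path(dir, "design.tsv"))
    writeVolume(templates@data, templates@affine,
                file.path(dir, "templates.nii.gz"))
    writeLines(systemNames(templates), file.path(dir, "systems.txt"))
    for (nm in names(masks))
      writeMask(masks[[nm]], file.path(dir, sprintf("mask_%s.nii.gz", nm)))
    tr2json <- truth
    class(tr2json) <- NULL
    tr2json$series <- NULL        # sidecar records parameters, not draws
    tr2json$effects <- lapply(tr2json$effects, function(e) {
      e$cellProfile <- as.data.frame(e$cellProfile)
      e
    })
    jsonlite::write_json(tr2json, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    list(runs = file.path(dir, files), design = design, truth = truth,
         dir = dir)
  } else {
    list(runs = scans, design = design, truth = truth)
  }
}

#' A compact cubic cluster mask for planting effects
#'
#' @param dim Grid dimensions.
#' @param centre Voxel centre of the cube (defaults to the grid centre).
#' @param halfWidth Half-width in voxels (1 gives a 3 x 3 x 3 = 27-voxel
#'   cube).
#' @param affine Voxel-to-world matrix.
#' @return A \code{VolumeMask}.
#' @export
cubicClusterMask <- function(dim, centre = NULL, halfWidth = 1,
                             affine = diag(c(3, 3, 3, 1))) {
  if (is.null(centre)) centre <- round((dim + 1) / 2)
  a <- array(FALSE, dim = dim)
  rng <- function(c0, n) max(1, c0 - halfWidth):min(n, c0 + halfWidth)
  a[rng(centre[1], dim[1]), rng(centre[2], dim[2]),
    rng(centre[3], dim[3])] <- TRUE
  VolumeMask(a, affine)
}
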