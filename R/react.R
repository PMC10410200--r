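## Signal conditioning (WM/CSF nuisance regression, discrete-cosine
## high-pass, Gaussian smoothing) and the two-stage dual regression that
## produces molecular-enriched FC maps.

## Voxels-by-time matrix of a 4-D array, optionally restricted to a mask.
.voxelMatrix <- function(data4d, maskVec = NULL) {
  d <- dim(data4d)
  m <- matrix(data4d, nrow = prod(d[1:3]), ncol = d[4L])
  if (is.null(maskVec)) m else m[maskVec, , drop = FALSE]
}

## Residualise rows of Y (voxels x time) against the time-domain design X
## (time x p) via an orthonormal basis; numerically stable for any rank.
.residualiseRows <- function(Y, X) {
  q <- qr.Q(qr(X))
  Y - (Y %*% q) %*% t(q)
}

#' Regress mean WM and CSF signals out of a run
#'
#' Per voxel, the residual time series after a least-squares fit of
#' intercept, mean white-matter series and mean CSF series. The output is
#' orthogonal to both nuisance series (and temporally demeaned, since the
#' intercept is in the model). A constant nuisance series carries no signal
#' and is dropped with a warning.
#'
#' @param scan A \code{Scan4D}.
#' @param wmMask,csfMask Non-empty \code{VolumeMask}s on the scan grid.
#' @return A \code{Scan4D} of residuals.
#' @export
regressNuisance <- function(scan, wmMask, csfMask) {
  stopifnot(is(scan, "Scan4D"), is(wmMask, "VolumeMask"),
            is(csfMask, "VolumeMask"))
  .stopIfGridMismatch(scan, wmMask, "scan and WM mask")
  .stopIfGridMismatch(scan, csfMask, "scan and CSF mask")
  if (maskCount(wmMask) < 1L || maskCount(csfMask) < 1L)
    stop("invalid mask: empty nuisance mask", call. = FALSE)
  Y <- .voxelMatrix(scan@data)
  nuis <- list(wm = colMeans(Y[as.vector(wmMask@data), , drop = FALSE]),
               csf = colMeans(Y[as.vector(csfMask@data), , drop = FALSE]))
  keep <- vapply(nuis, function(x) stats::sd(x) > 0, logical(1))
  if (!all(keep))
    warning("constant nuisance series dropped: ",
            paste(names(nuis)[!keep], collapse = ", "), call. = FALSE)
  X <- cbind(1, do.call(cbind, nuis[keep]))
  R <- .residualiseRows(Y, X)
  new("Scan4D", data = array(R, dim = dim(scan@data)), affine = scan@affine,
      tr = scan@tr, subject = scan@subject, condition = scan@condition,
      state = scan@state)
}

## Discrete-cosine drift basis: columns cos(pi*(2t-1)*k/(2T)), t = 1..T,
## for all k whose frequency k/(2*T*TR) lies strictly below cutoffHz.
.dctBasis <- function(nTime, tr, cutoffHz) {
  kMax <- ceiling(2 * nTime * tr * cutoffHz) - 1L
  if (kMax < 1L)
    stop("invalid parameter: run too short for any drift term below ",
         cutoffHz, " Hz", call. = FALSE)
  if (kMax >= nTime - 1L)
    stop("invalid parameter: drift basis would span the data", call. = FALSE)
  t <- seq_len(nTime)
  vapply(seq_len(kMax),
         function(k) cos(pi * (2 * t - 1) * k / (2 * nTime)),
         numeric(nTime))
}

#' High-pass filter a run with a discrete-cosine drift basis
#'
#' Per voxel, the residual after regressing out an intercept plus the
#' discrete-cosine functions with frequency below \code{cutoffHz}. Because
#' the basis is orthogonal, power at retained frequencies is preserved.
#'
#' @param scan A \code{Scan4D}.
#' @param cutoffHz High-pass cut-off in Hz, default 0.005.
#' @return A filtered \code{Scan4D}.
#' @export
highpassDCT <- function(scan, cutoffHz = 0.005) {
  stopifnot(is(scan, "Scan4D"))
  if (!is.finite(cutoffHz) || cutoffHz <= 0)
    stop("invalid parameter: cutoffHz must be positive", call. = FALSE)
  nT <- nVolumes(scan)
  X <- cbind(1, .dctBasis(nT, scan@tr, cutoffHz))
  Y <- .voxelMatrix(scan@data)
  R <- .residualiseRows(Y, X)
  new("Scan4D", data = array(R, dim = dim(scan@data)), affine = scan@affine,
      tr = scan@tr, subject = scan@subject, condition = scan@condition,
      state = scan@state)
}

.gaussKernel <- function(sigmaVox) {
  r <- max(1L, ceiling(4 * sigmaVox))
  x <- seq(-r, r)
  k <- exp(-x^2 / (2 * sigmaVox^2))
  k / sum(k)
}

## n x n convolution operator for a symmetric kernel, rows renormalised at
## the boundaries so constants are preserved exactly.
.convOperator <- function(n, kern) {
  r <- (length(kern) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (j in seq(-r, r)) {
    i <- seq_len(n)
    ok <- i + j >= 1L & i + j <= n
    K[cbind(i[ok], i[ok] + j)] <- kern[j + r + 1L]
  }
  K / rowSums(K)
}

## Convolve the first dimension of an n x m matrix with a normalised kernel.
.convolveCols <- function(m, kern) {
  .convOperator(nrow(m), kern) %*% m
}

## Separable Gaussian smoothing of the three spatial axes of a 3-D or 4-D
## array (a 4-D array is smoothed volume by volume in one filtering pass
## per axis); sigma per axis in voxels.
.smoothVolume <- function(vol, sigmaVox) {
  d <- dim(vol)
  nd <- length(d)
  for (ax in 1:3) {
    if (sigmaVox[ax] <= 0) next
    kern <- .gaussKernel(sigmaVox[ax])
    perm <- c(ax, setdiff(seq_len(nd), ax))
    v <- aperm(vol, perm)
    pd <- dim(v)
    v <- array(.convolveCols(matrix(v, nrow = pd[1L]), kern), dim = pd)
    vol <- aperm(v, order(perm))
  }
  vol
}

#' Spatially smooth a run with a Gaussian kernel
#'
#' Per volume, separable 3-D Gaussian convolution with
#' sigma = FWHM / (2 * sqrt(2 * log(2))) per axis in mm, converted to voxels
#' using the voxel sizes from the affine (anisotropic grids are handled per
#' axis). Boundaries are renormalised so the kernel integrates to one over
#' the grid and constant volumes are preserved. \code{fwhmMm = 0} returns
#' the input unchanged.
#'
#' @param scan A \code{Scan4D}.
#' @param fwhmMm Full width at half maximum in mm, default 6.
#' @return A smoothed \code{Scan4D}.
#' @export
smoothGaussian <- function(scan, fwhmMm = 6) {
  stopifnot(is(scan, "Scan4D"))
  if (!is.finite(fwhmMm) || fwhmMm < 0)
    stop("invalid parameter: fwhmMm must be >= 0", call. = FALSE)
  if (fwhmMm == 0) return(scan)
  voxMm <- sqrt(colSums(scan@affine[1:3, 1:3]^2))
  sigmaVox <- (fwhmMm / (2 * sqrt(2 * log(2)))) / voxMm
  out <- .smoothVolume(scan@data, sigmaVox)
  new("Scan4D", data = out, affine = scan@affine, tr = scan@tr,
      subject = scan@subject, condition = scan@condition, state = scan@state)
}

## Spatially demeaned within-mask template matrix with a rank check that
## names the offending columns.
.stage1Design <- function(templates, mask) {
  M <- .templateMatrix(templates, mask)
  M <- sweep(M, 2L, colMeans(M))
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    bad <- colnames(M)[qrM$pivot[(qrM$rank + 1L):ncol(M)]]
    stop("singular design: template(s) ", paste(bad, collapse = ", "),
         " are linearly dependent on the others over the mask",
         call. = FALSE)
  }
  M
}

#' Stage 1: extract per-system BOLD time series by spatial regression
#'
#' At every time point, the spatially demeaned within-mask volume is
#' regressed by ordinary least squares on the spatially demeaned template
#' matrix; the coefficients over time form the K dominant BOLD fluctuations,
#' one per molecular system. Both the data and the design are demeaned
#' across mask voxels, so adding a spatial constant to any volume leaves the
#' result unchanged.
#'
#' @param scan A \code{Scan4D} (already pre-processed as desired).
#' @param templates A conditioned \code{TemplateSet}.
#' @param mask The analysis \code{VolumeMask} from
#'   \code{\link{buildAnalysisMask}}.
#' @return A \code{SystemTimeSeries} (K x T).
#' @export
reactStage1 <- function(scan, templates, mask) {
  stopifnot(is(scan, "Scan4D"), is(templates, "TemplateSet"),
            is(mask, "VolumeMask"))
  if (!templates@conditioned)
    stop("templates must be conditioned first", call. = FALSE)
  .stopIfGridMismatch(scan, templates, "scan and templates")
  .stopIfGridMismatch(scan, mask, "scan and mask")
  k <- nSystems(templates)
  if (nVolumes(scan) < k + 1L)
    stop("run too short: need T >= K + 1", call. = FALSE)
  M <- .stage1Design(templates, mask)
  D <- .voxelMatrix(scan@data, as.vector(mask@data))      # V x T
  D <- sweep(D, 2L, colMeans(D))                          # spatial demean
  S <- solve(crossprod(M), crossprod(M, D))               # K x T
  rownames(S) <- templates@names
  SystemTimeSeries(S, tr = scan@tr, subject = scan@subject,
                   condition = scan@condition, state = scan@state)
}

#' Stage 2: molecular-enriched FC maps by temporal regression
#'
#' The stage-1 time series are temporally demeaned and scaled to unit
#' standard deviation (population, 1/T denominator); each within-mask
#' voxel's series is temporally demeaned; the voxelwise multiple-regression
#' betas against the K unit-SD regressors are the molecular-enriched FC
#' maps, in BOLD-signal units per unit-SD fluctuation. Betas are 0 outside
#' the mask and for zero-variance voxels.
#'
#' @param scan The same run used in stage 1.
#' @param ts The \code{SystemTimeSeries} from \code{\link{reactStage1}}.
#' @param mask \code{VolumeMask} for stage 2 (a participant-level GM mask;
#'   defaults in the pipeline to the stage-1 analysis mask).
#' @return An \code{EnrichedFCMaps}.
#' @export
reactStage2 <- function(scan, ts, mask) {
  stopifnot(is(scan, "Scan4D"), is(ts, "SystemTimeSeries"),
            is(mask, "VolumeMask"))
  .stopIfGridMismatch(scan, mask, "scan and mask")
  sameRun <- function(a, b) is.na(a) || is.na(b) || a == b
  if (!(sameRun(scan@subject, ts@subject) &&
        sameRun(scan@condition, ts@condition) &&
        sameRun(scan@state, ts@state)))
    stop("scan and time series come from different runs", call. = FALSE)
  S <- t(ts@values)                                       # T x K
  k <- ncol(S)
  nT <- nVolumes(scan)
  if (nrow(S) != nT)
    stop("time series length does not match the scan", call. = FALSE)
  if (nT < k + 1L)
    stop("run too short: need T >= K + 1", call. = FALSE)
  S <- sweep(S, 2L, colMeans(S))
  sdPop <- sqrt(colMeans(S^2))
  if (any(sdPop == 0))
    stop("singular design: zero-variance time series for ",
         paste(rownames(ts@values)[sdPop == 0], collapse = ", "),
         call. = FALSE)
  S <- sweep(S, 2L, sdPop, "/")
  xtx <- crossprod(S)
  if (qr(xtx)$rank < k)
    stop("singular design: collinear stage-1 time series", call. = FALSE)
  Y <- .voxelMatrix(scan@data, as.vector(mask@data))      # V x T
  Y <- Y - rowMeans(Y)                                    # temporal demean
  B <- Y %*% S %*% solve(xtx)                             # V x K
  d <- gridDim(scan)
  betas <- array(0, dim = c(d, k))
  mv <- mask@data
  for (j in seq_len(k)) {
    vol <- array(0, dim = d)
    vol[mv] <- B[, j]
    betas[, , , j] <- vol
  }
  EnrichedFCMaps(betas, names = rownames(ts@values), mask = mask,
                 affine = scan@affine, subject = scan@subject,
                 condition = scan@condition, state = scan@state)
}
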