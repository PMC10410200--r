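## Conditioning of molecular density templates into the stage-1 spatial
## design: reference-region fill, min-max rescaling over grey matter, the
## template-support analysis mask, and collinearity screening (pairwise r,
## VIF).

#' Fill a tracer reference region with the grey-matter minimum
#'
#' Regions used as kinetic-model reference (e.g. occipital cortex or
#' cerebellum, depending on tracer) carry no valid density signal. Their
#' voxels are replaced by the minimum density over all grey-matter voxels so
#' that they contribute minimally without being excluded. All voxels outside
#' the reference region are returned unchanged.
#'
#' @param template Numeric 3-D array (raw density volume).
#' @param refMask \code{VolumeMask} of the reference region (may be empty).
#' @param gmMask Non-empty grey-matter \code{VolumeMask}.
#' @return Numeric 3-D array.
#' @export
applyReferenceFill <- function(template, refMask, gmMask) {
  stopifnot(is(refMask, "VolumeMask"), is(gmMask, "VolumeMask"))
  if (length(dim(template)) != 3L)
    stop("template must be a 3-D array", call. = FALSE)
  if (!all(dim(template) == gridDim(refMask)) ||
      !all(dim(template) == gridDim(gmMask)))
    stop("grid mismatch: template and masks differ in shape", call. = FALSE)
  .stopIfGridMismatch(refMask, gmMask, "reference and GM masks")
  if (maskCount(gmMask) < 1L)
    stop("invalid mask: grey-matter mask is empty", call. = FALSE)
  out <- template
  if (maskCount(refMask) > 0L)
    out[refMask@data] <- min(template[gmMask@data])
  out
}

#' Min-max rescale a template within a mask
#'
#' Affine map of within-mask values onto [0, 1] (shape-preserving: the
#' intensity distribution is only shifted and scaled, so rank order is
#' unchanged). Voxels outside the mask are set to 0.
#'
#' @param template Numeric 3-D array.
#' @param mask \code{VolumeMask} over which to rescale.
#' @return Numeric 3-D array in [0, 1] within the mask, 0 outside.
#' @export
rescaleMinMax <- function(template, mask) {
  stopifnot(is(mask, "VolumeMask"))
  if (!all(dim(template) == gridDim(mask)))
    stop("grid mismatch: template and mask differ in shape", call. = FALSE)
  v <- template[mask@data]
  lo <- min(v); hi <- max(v)
  if (hi <= lo)
    stop("degenerate template: constant within the mask", call. = FALSE)
  out <- array(0, dim = dim(template))
  out[mask@data] <- (v - lo) / (hi - lo)
  out
}

#' Condition a raw template set
#'
#' Applies, per template, the reference-region fill (when a reference mask is
#' supplied for that system) followed by min-max rescaling over the
#' grey-matter mask, in that order.
#'
#' @param templates A raw \code{TemplateSet}.
#' @param gmMask Grey-matter \code{VolumeMask}.
#' @param refMasks Optional named list of reference-region
#'   \code{VolumeMask}s, names matching system labels; systems without an
#'   entry are not reference-filled.
#' @return A conditioned \code{TemplateSet}.
#' @export
conditionTemplates <- function(templates, gmMask, refMasks = list()) {
  stopifnot(is(templates, "TemplateSet"), is(gmMask, "VolumeMask"))
  .stopIfGridMismatch(templates, gmMask, "templates and GM mask")
  out <- templates@data
  for (k in seq_len(nSystems(templates))) {
    vol <- out[, , , k]
    nm <- templates@names[k]
    if (!is.null(refMasks[[nm]]))
      vol <- applyReferenceFill(vol, refMasks[[nm]], gmMask)
    out[, , , k] <- rescaleMinMax(vol, gmMask)
  }
  new("TemplateSet", data = out, names = templates@names,
      affine = templates@affine, conditioned = TRUE)
}

#' Build the template-support analysis mask
#'
#' Grey-matter voxels at which every conditioned template is strictly
#' positive, i.e. where density information is available from all systems.
#' Both regression stages are restricted to a mask of this kind.
#'
#' @param templates A conditioned \code{TemplateSet}.
#' @param gmMask Grey-matter \code{VolumeMask}.
#' @return A \code{VolumeMask}.
#' @export
buildAnalysisMask <- function(templates, gmMask) {
  stopifnot(is(templates, "TemplateSet"), is(gmMask, "VolumeMask"))
  if (!templates@conditioned)
    stop("templates must be conditioned first", call. = FALSE)
  .stopIfGridMismatch(templates, gmMask, "templates and GM mask")
  keep <- gmMask@data
  for (k in seq_len(nSystems(templates)))
    keep <- keep & (templates@data[, , , k] > 0)
  if (!any(keep))
    stop("invalid mask: no GM voxel has support from every template",
         call. = FALSE)
  VolumeMask(keep, gmMask@affine)
}

## Within-mask template matrix (V x K), columns named.
.templateMatrix <- function(templates, mask) {
  .stopIfGridMismatch(templates, mask, "templates and mask")
  k <- nSystems(templates)
  v <- maskCount(mask)
  X <- matrix(0, nrow = v, ncol = k,
              dimnames = list(NULL, templates@names))
  for (j in seq_len(k))
    X[, j] <- templates@data[, , , j][mask@data]
  X
}

#' Pairwise template correlations over mask voxels
#'
#' @param templates A \code{TemplateSet} (conditioned by convention; raw
#'   sets are accepted since Pearson r is affine-invariant).
#' @param mask Analysis \code{VolumeMask} with at least 3 voxels.
#' @return A \code{CollinearityReport} holding the K x K correlation matrix
#'   (VIF slot empty).
#' @export
pairwiseTemplateCorrelation <- function(templates, mask) {
  stopifnot(is(templates, "TemplateSet"), is(mask, "VolumeMask"))
  if (maskCount(mask) < 3L)
    stop("mask must contain at least 3 voxels", call. = FALSE)
  X <- .templateMatrix(templates, mask)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0))
    stop("undefined correlation: template(s) ",
         paste(colnames(X)[sds == 0], collapse = ", "),
         " have zero variance within the mask", call. = FALSE)
  r <- stats::cor(X)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  new("CollinearityReport", correlations = r, vif = numeric(0),
      vifThreshold = NA_real_, flagged = logical(0))
}

#' Variance inflation factors of a template set
#'
#' For each system k, template k is regressed (with intercept) on the other
#' K-1 templates over mask voxels; VIF_k = 1 / (1 - R^2_k). A template that
#' is an exact linear combination of the others yields an infinite VIF with
#' a flag rather than an error. VIFs are invariant to affine rescaling of
#' any template, so conditioned and raw sets give identical values.
#'
#' @param templates A \code{TemplateSet} with K >= 2 systems.
#' @param mask Analysis \code{VolumeMask} with more voxels than systems.
#' @param vifThreshold Flagging threshold, default 5.
#' @return A \code{CollinearityReport} with correlations, VIFs and flags.
#' @export
computeVIF <- function(templates, mask, vifThreshold = 5) {
  stopifnot(is(templates, "TemplateSet"), is(mask, "VolumeMask"))
  k <- nSystems(templates)
  if (k < 2L) stop("VIF needs at least two templates", call. = FALSE)
  if (maskCount(mask) <= k)
    stop("mask must contain more voxels than templates", call. = FALSE)
  report <- pairwiseTemplateCorrelation(templates, mask)
  X <- .templateMatrix(templates, mask)
  vif <- numeric(k)
  names(vif) <- colnames(X)
  for (j in seq_len(k)) {
    y <- X[, j]
    Z <- cbind(1, X[, -j, drop = FALSE])
    fit <- stats::lm.fit(Z, y)
    tss <- sum((y - mean(y))^2)
    rss <- sum(fit$residuals^2)
    r2 <- 1 - rss / tss
    vif[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  flagged <- vif > vifThreshold
  if (any(is.infinite(vif)))
    warning("exact collinearity: infinite VIF for ",
            paste(names(vif)[is.infinite(vif)], collapse = ", "),
            call. = FALSE)
  new("CollinearityReport", correlations = report@correlations,
      vif = vif, vifThreshold = as.numeric(vifThreshold), flagged = flagged)
}
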