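## Central S4 containers for the molecular-enriched FC pipeline.
## All volumetric objects carry a 4x4 voxel-to-world affine; grids are
## compared on both dimensions and affine (to a small tolerance) before any
## voxelwise operation.

.affineTol <- 1e-6

.checkAffine <- function(affine) {
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)) ||
      !is.numeric(affine))
    return("affine must be a numeric 4x4 matrix")
  if (any(!is.finite(affine)))
    return("affine contains non-finite values")
  NULL
}

.sameGrid <- function(dimA, affA, dimB, affB) {
  all(dimA == dimB) && max(abs(affA - affB)) <= .affineTol
}

#' Stop unless two objects share a spatial grid
#' @param a,b Objects with \code{gridDim} and \code{affineMat} methods.
#' @param what Label used in the error message.
#' @return Invisibly \code{TRUE}.
#' @keywords internal
.stopIfGridMismatch <- function(a, b, what = "inputs") {
  if (!.sameGrid(gridDim(a), affineMat(a), gridDim(b), affineMat(b)))
    stop("grid mismatch: ", what, " do not share dimensions and affine",
         call. = FALSE)
  invisible(TRUE)
}

## ---------------------------------------------------------------------------
## VolumeMask
## ---------------------------------------------------------------------------

#' Binary 3-D volume mask
#'
#' A binary mask on a 3-D grid with its voxel-to-world affine. Used for the
#' grey-matter analysis mask, white-matter/CSF nuisance masks, reference
#' regions and planted-effect clusters.
#'
#' @slot data Logical 3-D array.
#' @slot affine Numeric 4x4 voxel-to-world matrix.
#' @export
setClass("VolumeMask",
         representation(data = "array", affine = "matrix"))

setValidity("VolumeMask", function(object) {
  if (length(dim(object@data)) != 3L)
    return("mask data must be a 3-D array")
  if (!is.logical(object@data))
    return("mask data must be logical")
  if (any(is.na(object@data)))
    return("mask data contains NA")
  msg <- .checkAffine(object@affine)
  if (!is.null(msg)) return(msg)
  TRUE
})

#' Construct a VolumeMask
#'
#' @param data A 3-D array; numeric input is binarised as \code{data != 0}.
#' @param affine Numeric 4x4 voxel-to-world matrix (defaults to identity
#'   spacing of 1 mm).
#' @return A \code{VolumeMask}.
#' @examples
#' m <- VolumeMask(array(c(TRUE, FALSE), dim = c(2, 2, 2)))
#' maskCount(m)
#' @export
VolumeMask <- function(data, affine = diag(4)) {
  if (is.numeric(data)) {
    storage <- array(data != 0, dim = dim(data))
    data <- storage
  }
  new("VolumeMask", data = data, affine = affine)
}

#' Extract the logical array of a mask
#' @param x A \code{VolumeMask}.
#' @return Logical 3-D array.
#' @export
maskArray <- function(x) {
  stopifnot(is(x, "VolumeMask"))
  x@data
}

#' @describeIn VolumeMask-class Number of true voxels.
#' @param x A \code{VolumeMask}.
#' @export
setMethod("maskCount", "VolumeMask", function(x) sum(x@data))

setMethod("gridDim", "VolumeMask", function(x) dim(x@data))
setMethod("affineMat", "VolumeMask", function(x) x@affine)

setMethod("show", "VolumeMask", function(object) {
  d <- dim(object@data)
  cat("VolumeMask ", paste(d, collapse = " x "),
      " (", sum(object@data), " of ", prod(d), " voxels)\n", sep = "")
})

## ---------------------------------------------------------------------------
## TemplateSet
## ---------------------------------------------------------------------------

#' Set of molecular density templates
#'
#' K molecular density volumes (e.g. NAT, DAT, SERT, VAChT, GABAA transporter
#' and receptor maps) sharing one grid. Raw templates are in arbitrary
#' density units; after conditioning (reference-region fill and min-max
#' rescaling over the grey-matter mask) every within-mask value lies in
#' [0, 1]. The conditioned set is the stage-1 spatial design matrix.
#'
#' @slot data Numeric 4-D array (x, y, z, system).
#' @slot names Character vector of K unique system labels.
#' @slot affine Numeric 4x4 voxel-to-world matrix.
#' @slot conditioned Logical: has the set been reference-filled and rescaled?
#' @export
setClass("TemplateSet",
         representation(data = "array", names = "character",
                        affine = "matrix", conditioned = "logical"))

setValidity("TemplateSet", function(object) {
  if (length(dim(object@data)) != 4L)
    return("template data must be a 4-D array (x, y, z, system)")
  k <- dim(object@data)[4L]
  if (k < 1L) return("at least one template is required")
  if (length(object@names) != k)
    return("names length must equal the number of templates")
  if (anyDuplicated(object@names))
    return("system names must be unique")
  if (any(!is.finite(object@data)))
    return("template data contains non-finite values")
  msg <- .checkAffine(object@affine)
  if (!is.null(msg)) return(msg)
  if (length(object@conditioned) != 1L)
    return("conditioned must be a logical scalar")
  TRUE
})

#' Construct a TemplateSet
#'
#' @param volumes A 4-D array (x, y, z, system) or list of 3-D arrays.
#' @param names Character vector of system labels.
#' @param affine Numeric 4x4 voxel-to-world matrix.
#' @param conditioned Logical; \code{TRUE} once reference-filled and
#'   min-max rescaled.
#' @return A \code{TemplateSet}.
#' @export
TemplateSet <- function(volumes, names, affine = diag(4),
                        conditioned = FALSE) {
  if (is.list(volumes)) {
    d <- dim(volumes[[1L]])
    volumes <- array(unlist(volumes, use.names = FALSE),
                     dim = c(d, length(volumes)))
  }
  new("TemplateSet", data = volumes, names = as.character(names),
      affine = affine, conditioned = conditioned)
}

setMethod("systemNames", "TemplateSet", function(x) x@names)
setMethod("nSystems", "TemplateSet", function(x) dim(x@data)[4L])
setMethod("gridDim", "TemplateSet", function(x) dim(x@data)[1:3])
setMethod("affineMat", "TemplateSet", function(x) x@affine)

#' Extract one template volume
#' @param x A \code{TemplateSet}.
#' @param which System label or index.
#' @return Numeric 3-D array.
#' @export
templateVolume <- function(x, which) {
  stopifnot(is(x, "TemplateSet"))
  if (is.character(which)) which <- match(which, x@names)
  if (is.na(which) || which < 1L || which > nSystems(x))
    stop("unknown template", call. = FALSE)
  x@data[, , , which, drop = TRUE]
}

setMethod("show", "TemplateSet", function(object) {
  cat("TemplateSet with", nSystems(object), "systems on grid",
      paste(gridDim(object), collapse = " x "), "\n")
  cat("  systems:", paste(object@names, collapse = ", "), "\n")
  cat("  conditioned:", object@conditioned, "\n")
})

## ---------------------------------------------------------------------------
## Scan4D
## ---------------------------------------------------------------------------

#' A 4-D BOLD run
#'
#' One subject-run 4-D volume with repetition time and design labels
#' (subject, condition in audio/rest, state in awake/light/deep/recovery).
#'
#' @slot data Numeric 4-D array (x, y, z, t).
#' @slot affine Numeric 4x4 voxel-to-world matrix.
#' @slot tr Repetition time in seconds.
#' @slot subject,condition,state Run labels (character scalars, possibly NA).
#' @export
setClass("Scan4D",
         representation(data = "array", affine = "matrix", tr = "numeric",
                        subject = "character", condition = "character",
                        state = "character"))

setValidity("Scan4D", function(object) {
  if (length(dim(object@data)) != 4L)
    return("scan data must be a 4-D array (x, y, z, t)")
  if (dim(object@data)[4L] < 2L)
    return("a run needs at least two time points")
  if (length(object@tr) != 1L || !is.finite(object@tr) || object@tr <= 0)
    return("tr must be a positive scalar (seconds)")
  msg <- .checkAffine(object@affine)
  if (!is.null(msg)) return(msg)
  TRUE
})

#' Construct a Scan4D
#'
#' @param data Numeric 4-D array (x, y, z, t).
#' @param tr Repetition time in seconds.
#' @param affine Numeric 4x4 voxel-to-world matrix.
#' @param subject,condition,state Optional run labels.
#' @return A \code{Scan4D}.
#' @export
Scan4D <- function(data, tr, affine = diag(4), subject = NA_character_,
                   condition = NA_character_, state = NA_character_) {
  new("Scan4D", data = data, affine = affine, tr = as.numeric(tr),
      subject = as.character(subject), condition = as.character(condition),
      state = as.character(state))
}

setMethod("gridDim", "Scan4D", function(x) dim(x@data)[1:3])
setMethod("affineMat", "Scan4D", function(x) x@affine)

#' Number of volumes in a run
#' @param x A \code{Scan4D}.
#' @return Integer scalar.
#' @export
nVolumes <- function(x) {
  stopifnot(is(x, "Scan4D"))
  dim(x@data)[4L]
}

#' Repetition time in seconds
#' @param x A \code{Scan4D} or \code{SystemTimeSeries}.
#' @return Numeric scalar.
#' @export
trSeconds <- function(x) x@tr

#' Raw 4-D data array of a run
#' @param x A \code{Scan4D}.
#' @return Numeric 4-D array.
#' @export
scanArray <- function(x) {
  stopifnot(is(x, "Scan4D"))
  x@data
}

#' Run labels of a scan or derived object
#' @param x A \code{Scan4D}, \code{SystemTimeSeries} or \code{EnrichedFCMaps}.
#' @return Named character vector (subject, condition, state).
#' @export
runLabels <- function(x) {
  c(subject = x@subject, condition = x@condition, state = x@state)
}

setMethod("show", "Scan4D", function(object) {
  d <- dim(object@data)
  cat("Scan4D ", paste(d[1:3], collapse = " x "), ", T=", d[4L],
      ", TR=", object@tr, "s", sep = "")
  cat(" [", object@subject, "/", object@condition, "/", object@state, "]\n",
      sep = "")
})

## ---------------------------------------------------------------------------
## SystemTimeSeries
## ---------------------------------------------------------------------------

#' Per-system BOLD time series (stage-1 output)
#'
#' The K x T matrix of dominant BOLD fluctuations per molecular system for
#' one run, obtained by spatially regressing each volume on the conditioned
#' templates.
#'
#' @slot values Numeric K x T matrix (rows named by system).
#' @slot tr Repetition time in seconds.
#' @slot subject,condition,state Run labels.
#' @export
setClass("SystemTimeSeries",
         representation(values = "matrix", tr = "numeric",
                        subject = "character", condition = "character",
                        state = "character"))

setValidity("SystemTimeSeries", function(object) {
  if (!is.numeric(object@values))
    return("values must be numeric")
  if (any(!is.finite(object@values)))
    return("values contain non-finite entries")
  if (is.null(rownames(object@values)))
    return("rows must be named by system")
  TRUE
})

#' Construct a SystemTimeSeries
#' @param values Numeric K x T matrix with rownames = system labels.
#' @param tr Repetition time in seconds.
#' @param subject,condition,state Optional run labels.
#' @return A \code{SystemTimeSeries}.
#' @export
SystemTimeSeries <- function(values, tr = NA_real_, subject = NA_character_,
                             condition = NA_character_, state = NA_character_) {
  if (is.null(rownames(values)))
    rownames(values) <- paste0("sys", seq_len(nrow(values)))
  new("SystemTimeSeries", values = values, tr = as.numeric(tr),
      subject = as.character(subject), condition = as.character(condition),
      state = as.character(state))
}

setMethod("systemNames", "SystemTimeSeries", function(x) rownames(x@values))
setMethod("nSystems", "SystemTimeSeries", function(x) nrow(x@values))

#' The K x T matrix of a SystemTimeSeries
#' @param x A \code{SystemTimeSeries}.
#' @return Numeric matrix.
#' @export
timeSeriesMatrix <- function(x) {
  stopifnot(is(x, "SystemTimeSeries"))
  x@values
}

setMethod("show", "SystemTimeSeries", function(object) {
  cat("SystemTimeSeries: ", nrow(object@values), " systems x ",
      ncol(object@values), " time points", sep = "")
  cat(" [", object@subject, "/", object@condition, "/", object@state, "]\n",
      sep = "")
})

## ---------------------------------------------------------------------------
## EnrichedFCMaps
## ---------------------------------------------------------------------------

#' Molecular-enriched FC maps (stage-2 output)
#'
#' K voxelwise beta volumes for one run: the coupling of each voxel's BOLD
#' series to the unit-SD fluctuation of each molecular system. Betas are 0
#' outside the analysis mask.
#'
#' @slot data Numeric 4-D array (x, y, z, system).
#' @slot names Character vector of system labels.
#' @slot affine Numeric 4x4 voxel-to-world matrix.
#' @slot mask \code{VolumeMask} the stage-2 fit was restricted to.
#' @slot subject,condition,state Run labels.
#' @export
setClass("EnrichedFCMaps",
         representation(data = "array", names = "character",
                        affine = "matrix", mask = "VolumeMask",
                        subject = "character", condition = "character",
                        state = "character"))

setValidity("EnrichedFCMaps", function(object) {
  if (length(dim(object@data)) != 4L)
    return("beta data must be a 4-D array (x, y, z, system)")
  if (length(object@names) != dim(object@data)[4L])
    return("names length must equal the number of beta volumes")
  if (!all(dim(object@data)[1:3] == dim(object@mask@data)))
    return("beta volumes and mask grids differ")
  inMask <- object@mask@data
  for (k in seq_len(dim(object@data)[4L])) {
    v <- object@data[, , , k]
    if (any(!is.finite(v[inMask])))
      return("non-finite betas inside the mask")
    if (any(v[!inMask] != 0))
      return("betas outside the mask must be 0")
  }
  TRUE
})

#' Construct an EnrichedFCMaps object
#' @param data Numeric 4-D array (x, y, z, system).
#' @param names System labels.
#' @param mask \code{VolumeMask} of the stage-2 fit.
#' @param affine Numeric 4x4 voxel-to-world matrix.
#' @param subject,condition,state Optional run labels.
#' @return An \code{EnrichedFCMaps}.
#' @export
EnrichedFCMaps <- function(data, names, mask, affine = diag(4),
                           subject = NA_character_, condition = NA_character_,
                           state = NA_character_) {
  new("EnrichedFCMaps", data = data, names = as.character(names),
      affine = affine, mask = mask, subject = as.character(subject),
      condition = as.character(condition), state = as.character(state))
}

setMethod("systemNames", "EnrichedFCMaps", function(x) x@names)
setMethod("nSystems", "EnrichedFCMaps", function(x) dim(x@data)[4L])
setMethod("gridDim", "EnrichedFCMaps", function(x) dim(x@data)[1:3])
setMethod("affineMat", "EnrichedFCMaps", function(x) x@affine)

#' Extract one beta volume
#' @param x An \code{EnrichedFCMaps}.
#' @param which System label or index.
#' @return Numeric 3-D array.
#' @export
betaVolume <- function(x, which) {
  stopifnot(is(x, "EnrichedFCMaps"))
  if (is.character(which)) which <- match(which, x@names)
  if (is.na(which) || which < 1L || which > nSystems(x))
    stop("unknown system", call. = FALSE)
  x@data[, , , which, drop = TRUE]
}

setMethod("show", "EnrichedFCMaps", function(object) {
  cat("EnrichedFCMaps:", nSystems(object), "systems on grid",
      paste(gridDim(object), collapse = " x "), "\n")
  cat("  [", object@subject, "/", object@condition, "/", object@state, "]\n",
      sep = "")
})

## ---------------------------------------------------------------------------
## CollinearityReport
## ---------------------------------------------------------------------------

#' Collinearity screen of a template set
#'
#' Pairwise Pearson correlations over analysis-mask voxels and variance
#' inflation factors VIF_k = 1 / (1 - R^2_k) from regressing each template on
#' the K-1 others (with intercept). VIF above the threshold (default 5)
#' flags strong collinearity; an exactly collinear template is reported as
#' infinite VIF rather than an error so screening can proceed.
#'
#' @slot correlations Numeric K x K symmetric matrix.
#' @slot vif Numeric vector of VIFs (length 0 until computed).
#' @slot vifThreshold Numeric scalar.
#' @slot flagged Logical vector, VIF > threshold.
#' @export
setClass("CollinearityReport",
         representation(correlations = "matrix", vif = "numeric",
                        vifThreshold = "numeric", flagged = "logical"))

setValidity("CollinearityReport", function(object) {
  r <- object@correlations
  if (nrow(r) != ncol(r)) return("correlation matrix must be square")
  if (max(abs(r - t(r))) > 1e-10) return("correlation matrix not symmetric")
  if (max(abs(diag(r) - 1)) > 1e-10) return("correlation diagonal must be 1")
  if (max(abs(r)) > 1 + 1e-10) return("|r| must be <= 1")
  if (length(object@vif) > 0L) {
    if (any(object@vif < 1 - 1e-10, na.rm = TRUE))
      return("every VIF must be >= 1")
  }
  TRUE
})

setMethod("show", "CollinearityReport", function(object) {
  cat("CollinearityReport for", nrow(object@correlations), "templates\n")
  if (length(object@vif)) {
    cat("  VIF:", paste(sprintf("%s=%.3g", names(object@vif), object@vif),
                        collapse = ", "), "\n")
    if (any(object@flagged))
      cat("  flagged (VIF >", object@vifThreshold, "):",
          paste(names(object@vif)[object@flagged], collapse = ", "), "\n")
  } else {
    cat("  correlations only (VIF not computed)\n")
  }
})

#' Pairwise template correlations from a report
#' @param x A \code{CollinearityReport}.
#' @return Numeric K x K matrix.
#' @export
templateCorrelations <- function(x) {
  stopifnot(is(x, "CollinearityReport"))
  x@correlations
}

#' Variance inflation factors from a report
#' @param x A \code{CollinearityReport}.
#' @return Named numeric vector.
#' @export
vifValues <- function(x) {
  stopifnot(is(x, "CollinearityReport"))
  x@vif
}

## ---------------------------------------------------------------------------
## StudyDesign
## ---------------------------------------------------------------------------

#' Crossed 2 x 4 within-subject study design
#'
#' N subjects, each scanned in both conditions (audio, rest) at all four
#' states (awake, light, deep, recovery): a complete 2 x 4 repeated-measures
#' design with 8 N runs.
#'
#' @slot subjects Character vector of N subject IDs.
#' @slot conditions Character vector, fixed to c("audio", "rest").
#' @slot states Character vector, fixed to
#'   c("awake", "light", "deep", "recovery").
#' @export
setClass("StudyDesign",
         representation(subjects = "character", conditions = "character",
                        states = "character"))

setValidity("StudyDesign", function(object) {
  if (length(object@subjects) < 2L)
    return("at least two subjects are required")
  if (anyDuplicated(object@subjects))
    return("subject IDs must be unique")
  if (length(object@conditions) != 2L)
    return("exactly two conditions are required")
  if (length(object@states) != 4L)
    return("exactly four states are required")
  TRUE
})

#' Construct a StudyDesign
#' @param subjects Subject IDs (character) or a subject count.
#' @param conditions,states Factor levels; defaults match the propofol
#'   listening design.
#' @return A \code{StudyDesign}.
#' @examples
#' d <- StudyDesign(17)
#' nrow(designTable(d))  # 136 runs
#' @export
StudyDesign <- function(subjects,
                        conditions = c("audio", "rest"),
                        states = c("awake", "light", "deep", "recovery")) {
  if (is.numeric(subjects) && length(subjects) == 1L)
    subjects <- sprintf("sub-%02d", seq_len(subjects))
  new("StudyDesign", subjects = as.character(subjects),
      conditions = conditions, states = states)
}

#' Number of subjects in a design
#' @param x A \code{StudyDesign}.
#' @return Integer scalar.
#' @export
nSubjects <- function(x) {
  stopifnot(is(x, "StudyDesign"))
  length(x@subjects)
}

#' Long-format run table of a design
#'
#' @param x A \code{StudyDesign}.
#' @return A data.frame with one row per run (subject, condition, state),
#'   subjects varying slowest.
#' @export
designTable <- function(x) {
  stopifnot(is(x, "StudyDesign"))
  expand.grid(state = x@states, condition = x@conditions,
              subject = x@subjects, stringsAsFactors = FALSE,
              KEEP.OUT.ATTRS = FALSE)[, c("subject", "condition", "state")]
}

setMethod("show", "StudyDesign", function(object) {
  cat("StudyDesign:", length(object@subjects), "subjects x",
      length(object@conditions), "conditions x",
      length(object@states), "states\n")
})

## ---------------------------------------------------------------------------
## FStatMap
## ---------------------------------------------------------------------------

#' Voxelwise F-statistic map for one within-subject effect
#'
#' @slot effect One of "condition", "state", "interaction".
#' @slot f Numeric 3-D array of F values (0 outside the mask).
#' @slot df1,df2 Numerator and denominator degrees of freedom.
#' @slot affine Numeric 4x4 voxel-to-world matrix.
#' @export
setClass("FStatMap",
         representation(effect = "character", f = "array",
                        df1 = "integer", df2 = "integer", affine = "matrix"))

setValidity("FStatMap", function(object) {
  if (!object@effect %in% c("condition", "state", "interaction"))
    return("effect must be condition, state or interaction")
  if (length(dim(object@f)) != 3L)
    return("f must be a 3-D array")
  if (any(object@f < 0, na.rm = TRUE))
    return("F values must be non-negative")
  if (object@df1 < 1L || object@df2 < 1L)
    return("degrees of freedom must be positive")
  TRUE
})

setMethod("gridDim", "FStatMap", function(x) dim(x@f))
setMethod("affineMat", "FStatMap", function(x) x@affine)

#' F array of an FStatMap
#' @param x An \code{FStatMap}.
#' @return Numeric 3-D array.
#' @export
fArray <- function(x) {
  stopifnot(is(x, "FStatMap"))
  x@f
}

#' Degrees of freedom of an FStatMap
#' @param x An \code{FStatMap}.
#' @return Integer vector c(df1, df2).
#' @export
fDegrees <- function(x) {
  stopifnot(is(x, "FStatMap"))
  c(df1 = x@df1, df2 = x@df2)
}

setMethod("show", "FStatMap", function(object) {
  cat("FStatMap [", object@effect, "] F(", object@df1, ", ", object@df2,
      "), max F = ", signif(max(object@f), 4), "\n", sep = "")
})

## ---------------------------------------------------------------------------
## PermutationScheme
## ---------------------------------------------------------------------------

#' Permutation scheme for cluster-extent FWE inference
#'
#' Subjects are exchangeability blocks: relabellings act only within
#' subjects. Effect-specific rules: the condition effect swaps the two
#' condition labels within a random subset of subjects; the state effect
#' permutes the four state labels within each subject (identically in both
#' conditions by default); the interaction permutes within-subject residual
#' cells after removing both main-effect profiles. When the relabelling
#' group is no larger than \code{nPerm} it is enumerated exhaustively.
#'
#' @slot nPerm Number of random relabellings (identity handled by the
#'   add-one p-value estimator).
#' @slot seed Integer seed driving all permutation draws.
#' @slot stateScheme "shared" (same state permutation in both conditions)
#'   or "independent".
#' @export
setClass("PermutationScheme",
         representation(nPerm = "integer", seed = "integer",
                        stateScheme = "character"))

setValidity("PermutationScheme", function(object) {
  if (object@nPerm < 1L) return("nPerm must be >= 1")
  if (!object@stateScheme %in% c("shared", "independent"))
    return("stateScheme must be 'shared' or 'independent'")
  TRUE
})

#' Construct a PermutationScheme
#' @param nPerm Number of permutations (default 5000).
#' @param seed Integer seed (required).
#' @param stateScheme "shared" or "independent" state relabelling across
#'   conditions.
#' @return A \code{PermutationScheme}.
#' @export
PermutationScheme <- function(nPerm = 5000L, seed, stateScheme = "shared") {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  new("PermutationScheme", nPerm = as.integer(nPerm),
      seed = as.integer(seed), stateScheme = stateScheme)
}

setMethod("show", "PermutationScheme", function(object) {
  cat("PermutationScheme:", object@nPerm, "permutations, seed",
      object@seed, ", state scheme", object@stateScheme, "\n")
})
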