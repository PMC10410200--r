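## NIfTI-1 and table I/O. Volumes go through RNifti; the affine written is
## the sform (code 2, "aligned"), which is also what readVolume trusts.

#' Read a 3-D or 4-D NIfTI volume
#'
#' @param path Path to a .nii or .nii.gz file.
#' @return List with elements \code{data} (numeric array) and \code{affine}
#'   (4x4 matrix).
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  attributes(aff) <- list(dim = dim(aff))
  list(data = array(as.numeric(img), dim = dim(img)), affine = aff)
}

#' Write an array as NIfTI-1
#'
#' @param data Numeric 3-D or 4-D array.
#' @param affine 4x4 voxel-to-world matrix.
#' @param path Output path (.nii or .nii.gz).
#' @param datatype RNifti datatype string, default "float" (32-bit).
#' @return The path, invisibly.
#' @export
writeVolume <- function(data, affine, path, datatype = "float") {
  img <- RNifti::asNifti(data)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a binary mask from NIfTI
#' @param path Path to a NIfTI file.
#' @return A \code{VolumeMask}.
#' @export
readMask <- function(path) {
  v <- readVolume(path)
  VolumeMask(v$data != 0, v$affine)
}

#' Write a VolumeMask as NIfTI
#' @param mask A \code{VolumeMask}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "VolumeMask"))
  writeVolume(array(as.numeric(mask@data), dim = dim(mask@data)),
              mask@affine, path, datatype = "uint8")
}

#' Read a Scan4D from NIfTI
#' @param path Path to a 4-D NIfTI file.
#' @param tr Repetition time in seconds.
#' @param subject,condition,state Optional run labels.
#' @return A \code{Scan4D}.
#' @export
readScan <- function(path, tr, subject = NA_character_,
                     condition = NA_character_, state = NA_character_) {
  v <- readVolume(path)
  Scan4D(v$data, tr = tr, affine = v$affine, subject = subject,
         condition = condition, state = state)
}

#' Write a Scan4D as NIfTI
#' @param scan A \code{Scan4D}.
#' @param path Output path.
#' @param datatype RNifti datatype string.
#' @return The path, invisibly.
#' @export
writeScan <- function(scan, path, datatype = "float") {
  stopifnot(is(scan, "Scan4D"))
  writeVolume(scan@data, scan@affine, path, datatype = datatype)
}

#' Write a SystemTimeSeries as TSV
#'
#' T rows x K named columns, mirroring the text output of dual-regression
#' tools.
#'
#' @param ts A \code{SystemTimeSeries}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeTimeSeries <- function(ts, path) {
  stopifnot(is(ts, "SystemTimeSeries"))
  df <- as.data.frame(t(ts@values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SystemTimeSeries from TSV
#' @param path Path to a TSV written by \code{writeTimeSeries}.
#' @param tr Repetition time in seconds.
#' @return A \code{SystemTimeSeries}.
#' @export
readTimeSeries <- function(path, tr = NA_real_) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  SystemTimeSeries(t(as.matrix(df)), tr = tr)
}

#' Write a data frame as TSV
#' @param df A data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeTable <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialise a collinearity report
#'
#' Writes the pairwise correlation matrix as TSV and the VIFs, threshold and
#' flags as JSON.
#'
#' @param report A \code{CollinearityReport}.
#' @param tsvPath Path for the correlation matrix TSV.
#' @param jsonPath Path for the VIF JSON.
#' @return Invisibly, the two paths.
#' @export
writeCollinearityReport <- function(report, tsvPath, jsonPath) {
  stopifnot(is(report, "CollinearityReport"))
  r <- as.data.frame(report@correlations)
  utils::write.table(cbind(system = rownames(report@correlations), r),
                     tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(vif = as.list(report@vif),
         vif_threshold = report@vifThreshold,
         flagged = as.list(report@flagged)),
    jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(c(tsvPath, jsonPath))
}
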