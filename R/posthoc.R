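## Post-hoc decomposition of significant ANOVA effects: cluster-mean
## extraction, Sidak-corrected paired contrasts, simple main effects, and
## atlas-overlap contextualisation of mean network maps.

#' Extract mean enriched FC over a cluster for every run
#'
#' @param maps List of per-run \code{EnrichedFCMaps}.
#' @param clusterMask Non-empty \code{VolumeMask} of the cluster.
#' @param system System label (or index) whose betas are averaged.
#' @param cluster Optional cluster identifier recorded in the table.
#' @return A data.frame with one row per run: subject, condition, state,
#'   system, cluster, value (arithmetic mean beta over cluster voxels).
#' @export
extractClusterMeans <- function(maps, clusterMask, system, cluster = 1L) {
  stopifnot(is(clusterMask, "VolumeMask"))
  if (maskCount(clusterMask) < 1L)
    stop("invalid mask: empty cluster", call. = FALSE)
  rows <- lapply(maps, function(m) {
    .stopIfGridMismatch(m, clusterMask, "beta maps and cluster mask")
    data.frame(subject = m@subject, condition = m@condition,
               state = m@state,
               system = if (is.character(system)) system
               else systemNames(m)[system],
               cluster = cluster,
               value = mean(betaVolume(m, system)[clusterMask@data]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sidak multiple-comparison adjustment
#'
#' p_adj = 1 - (1 - p)^m for a family of m comparisons; monotone in p,
#' never below p, and equal to p when m = 1.
#'
#' @param p Unadjusted p-value(s).
#' @param m Number of comparisons in the family.
#' @return Adjusted p-value(s) in [0, 1].
#' @examples
#' sidakAdjust(0.05, 3)   # 0.142625
#' @export
sidakAdjust <- function(p, m) {
  if (m < 1) stop("invalid m: need at least one comparison", call. = FALSE)
  pmin(pmax(1 - (1 - p)^m, 0), 1)
}

## Paired t contrast of two within-subject mean vectors (matched by
## subject), with Sidak adjustment over a family of m comparisons.
.pairedSidak <- function(a, b, m, alpha, adjustCI, nSub) {
  d <- a - b
  md <- mean(d)
  sdd <- stats::sd(d)
  df <- nSub - 1L
  degenerate <- sdd == 0
  alphaAdj <- if (adjustCI) 1 - (1 - alpha)^(1 / m) else alpha
  if (degenerate) {
    tval <- NA_real_; p <- NA_real_; pAdj <- NA_real_
    se <- 0; ciLow <- md; ciHigh <- md
  } else {
    se <- sdd / sqrt(nSub)
    tval <- md / se
    p <- 2 * stats::pt(-abs(tval), df)
    pAdj <- sidakAdjust(p, m)
    q <- stats::qt(1 - alphaAdj / 2, df)
    ciLow <- md - q * se
    ciHigh <- md + q * se
  }
  data.frame(meanDifference = md, se = se, tValue = tval, df = df,
             pUnadjusted = p, pAdjusted = pAdj,
             ciLow = ciLow, ciHigh = ciHigh, m = m,
             degenerate = degenerate)
}

## Within-subject marginal means of a cluster-means table for one factor.
.marginalMeans <- function(table, factor) {
  agg <- stats::aggregate(value ~ subject + table[[factor]], data = table,
                          FUN = mean)
  names(agg)[2L] <- factor
  agg
}

#' Sidak-corrected pairwise contrasts on cluster means
#'
#' Marginal pairwise comparisons of one within-subject factor: cell values
#' are averaged over the other factor within subject, pairs are compared by
#' paired t-tests (df N-1), and p-values are Sidak-adjusted,
#' p_adj = 1 - (1 - p)^m, over the m comparisons in the family (6 for the
#' four states, 1 for the two conditions). Confidence intervals are
#' two-sided at the Sidak-adjusted level 1 - (1 - alpha)^(1/m) by default.
#'
#' @param table Cluster-means data.frame from
#'   \code{\link{extractClusterMeans}}.
#' @param factor "condition" or "state".
#' @param m Number of comparisons in the family; defaults to the number of
#'   level pairs.
#' @param alpha Family alpha for the CIs, default 0.05.
#' @param adjustCI Use the Sidak-adjusted CI level (default) or the raw
#'   level.
#' @param levels Optional level order; defaults to the design order.
#' @return A data.frame with one row per pair: levels, mean difference
#'   (A - B), SE, t, df, unadjusted and adjusted p, CI bounds.
#' @export
pairedContrastsSidak <- function(table, factor = c("state", "condition"),
                                 m = NULL, alpha = 0.05, adjustCI = TRUE,
                                 levels = NULL) {
  factor <- match.arg(factor)
  if (is.null(levels))
    levels <- if (factor == "condition") c("audio", "rest")
  else c("awake", "light", "deep", "recovery")
  levels <- intersect(levels, unique(table[[factor]]))
  pairs <- utils::combn(levels, 2L)
  if (is.null(m)) m <- ncol(pairs)
  if (m < 1) stop("invalid m: need at least one comparison", call. = FALSE)
  agg <- .marginalMeans(table, factor)
  subjects <- sort(unique(agg$subject))
  nSub <- length(subjects)
  wide <- sapply(levels, function(l) {
    sub <- agg[agg[[factor]] == l, ]
    sub$value[match(subjects, sub$subject)]
  })
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    res <- .pairedSidak(wide[, pairs[1L, j]], wide[, pairs[2L, j]],
                        m, alpha, adjustCI, nSub)
    cbind(data.frame(factor = factor, levelA = pairs[1L, j],
                     levelB = pairs[2L, j]), res)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Simple main effects of state within each condition
#'
#' Decomposes a significant condition-by-state interaction: within each
#' condition separately, all six pairwise state contrasts are tested by
#' paired t with Sidak adjustment over m = 6, mirroring the reporting
#' convention of decomposing an interaction into per-condition state
#' differences.
#'
#' @param table Cluster-means data.frame from
#'   \code{\link{extractClusterMeans}}.
#' @param alpha Family alpha for the CIs, default 0.05.
#' @param adjustCI Use Sidak-adjusted CI levels (default).
#' @return A data.frame of 12 contrasts (2 conditions x 6 state pairs) with
#'   a \code{condition} column.
#' @export
simpleMainEffects <- function(table, alpha = 0.05, adjustCI = TRUE) {
  conditions <- intersect(c("audio", "rest"), unique(table$condition))
  out <- lapply(conditions, function(cc) {
    sub <- table[table$condition == cc, , drop = FALSE]
    res <- pairedContrastsSidak(sub, factor = "state", m = 6L,
                                alpha = alpha, adjustCI = adjustCI)
    cbind(data.frame(condition = cc), res)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Atlas overlap of a thresholded mean network map
#'
#' Binarises a mean enriched-FC map at a threshold (3 by convention, purely
#' for contextualisation, never for inference) and reports, per labelled
#' atlas region, the fraction of network voxels falling in the region and
#' the fraction of the region covered by the network.
#'
#' @param meanMap Numeric 3-D array (mean enriched FC map).
#' @param atlas Integer-labelled 3-D array on the same grid (0 =
#'   background).
#' @param threshold Binarisation threshold, default 3.
#' @return A data.frame with columns region, regionSize, networkVoxels,
#'   networkFraction, regionCoverage. Empty when no voxel exceeds the
#'   threshold.
#' @export
atlasOverlapReport <- function(meanMap, atlas, threshold = 3) {
  if (!all(dim(meanMap) == dim(atlas)))
    stop("grid mismatch: map and atlas differ in shape", call. = FALSE)
  if (!is.finite(threshold))
    stop("threshold must be finite", call. = FALSE)
  net <- meanMap >= threshold
  nNet <- sum(net)
  regions <- sort(unique(atlas[atlas > 0]))
  if (nNet == 0L || length(regions) == 0L)
    return(data.frame(region = integer(0), regionSize = integer(0),
                      networkVoxels = integer(0),
                      networkFraction = numeric(0),
                      regionCoverage = numeric(0)))
  rows <- lapply(regions, function(r) {
    inRegion <- atlas == r
    both <- sum(net & inRegion)
    data.frame(region = r, regionSize = sum(inRegion),
               networkVoxels = both,
               networkFraction = both / nNet,
               regionCoverage = both / sum(inRegion))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
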