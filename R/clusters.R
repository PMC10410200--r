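## Cluster formation under 6/18/26-connectivity and permutation-based
## cluster-extent FWE inference with subjects as exchangeability blocks.

.connOffsets <- function(connectivity) {
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  off <- switch(as.character(connectivity),
                "6" = off[rowSums(abs(off)) == 1L, , drop = FALSE],
                "18" = off[rowSums(abs(off)) <= 2L, , drop = FALSE],
                "26" = off,
                stop("connectivity must be 6, 18 or 26", call. = FALSE))
  ## forward half only: each unordered pair appears once
  off[off[, 3L] > 0 | (off[, 3L] == 0 & off[, 2L] > 0) |
        (off[, 3L] == 0 & off[, 2L] == 0 & off[, 1L] > 0), , drop = FALSE]
}

## Edge list (2-col matrix of mask-local indices) connecting neighbouring
## mask voxels. Computed once per mask and reused across permutations.
.maskEdges <- function(maskArr, connectivity = 26) {
  d <- dim(maskArr)
  idx <- which(maskArr)
  pos <- array(0L, dim = d)
  pos[idx] <- seq_along(idx)
  coords <- arrayInd(idx, d)
  off <- .connOffsets(connectivity)
  edges <- vector("list", nrow(off))
  for (r in seq_len(nrow(off))) {
    nb <- coords + matrix(off[r, ], nrow(coords), 3L, byrow = TRUE)
    ok <- nb[, 1L] >= 1L & nb[, 1L] <= d[1L] &
      nb[, 2L] >= 1L & nb[, 2L] <= d[2L] &
      nb[, 3L] >= 1L & nb[, 3L] <= d[3L]
    a <- pos[idx[ok]]
    b <- pos[nb[ok, 1L] + (nb[ok, 2L] - 1L) * d[1L] +
               (nb[ok, 3L] - 1L) * d[1L] * d[2L]]
    keep <- b > 0L
    edges[[r]] <- cbind(a[keep], b[keep])
  }
  do.call(rbind, edges)
}

## Connected-component membership for nodes 1..n given an edge list
## (union-find with path halving). Returns integer labels 1..ncomp.
.componentsFromEdges <- function(n, edges) {
  parent <- seq_len(n)
  findRoot <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (!is.null(edges) && nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      ra <- findRoot(edges[e, 1L])
      rb <- findRoot(edges[e, 2L])
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_len(n), findRoot, integer(1))
  match(roots, unique(roots))
}

## Size of the largest suprathreshold component, given the precomputed
## mask edge list. supra is logical over mask-local voxels.
.maxClusterSize <- function(supra, edges) {
  n <- sum(supra)
  if (n <= 1L) return(n)
  sel <- supra[edges[, 1L]] & supra[edges[, 2L]]
  if (!any(sel)) return(1L)
  nodes <- which(supra)
  remap <- integer(length(supra))
  remap[nodes] <- seq_len(n)
  sub <- cbind(remap[edges[sel, 1L]], remap[edges[sel, 2L]])
  memb <- .componentsFromEdges(n, sub)
  max(tabulate(memb))
}

#' Critical F value for a cluster-forming threshold
#'
#' @param df1,df2 Degrees of freedom.
#' @param formingP Voxelwise cluster-forming p, default 0.001.
#' @return Numeric scalar, \code{qf(1 - formingP, df1, df2)}.
#' @export
clusterFormingF <- function(df1, df2, formingP = 0.001) {
  stats::qf(1 - formingP, df1, df2)
}

## Shared cluster-table builder. fVec over mask-local voxels.
.clusterTable <- function(fVec, crit, maskArr, edges, affine) {
  supra <- fVec > crit
  n <- sum(supra)
  empty <- data.frame(label = integer(0), size = integer(0),
                      peakF = numeric(0), peakI = integer(0),
                      peakJ = integer(0), peakK = integer(0),
                      peakXmm = numeric(0), peakYmm = numeric(0),
                      peakZmm = numeric(0))
  if (n == 0L) return(empty)
  nodes <- which(supra)
  remap <- integer(length(supra))
  remap[nodes] <- seq_len(n)
  sel <- supra[edges[, 1L]] & supra[edges[, 2L]]
  sub <- if (any(sel)) cbind(remap[edges[sel, 1L]], remap[edges[sel, 2L]])
  else NULL
  memb <- .componentsFromEdges(n, sub)
  maskIdx <- which(maskArr)
  coords <- arrayInd(maskIdx[nodes], dim(maskArr))
  ncl <- max(memb)
  out <- empty[rep(1L, 0L), ]
  rows <- lapply(seq_len(ncl), function(cl) {
    members <- which(memb == cl)
    peak <- members[which.max(fVec[nodes[members]])]
    ijk <- coords[peak, ]
    mm <- affine %*% c(ijk - 1L, 1)
    data.frame(label = cl, size = length(members),
               peakF = fVec[nodes[peak]],
               peakI = ijk[1L], peakJ = ijk[2L], peakK = ijk[3L],
               peakXmm = mm[1L], peakYmm = mm[2L], peakZmm = mm[3L])
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$size), , drop = FALSE]
  out$label <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Form suprathreshold clusters from an F map
#'
#' Binarises the map at the critical F for the cluster-forming threshold and
#' labels connected components (26-connectivity by default).
#'
#' @param fmap An \code{FStatMap}.
#' @param mask Analysis \code{VolumeMask}.
#' @param formingP Cluster-forming p, default 0.001.
#' @param connectivity 6, 18 or 26 (default).
#' @return A data.frame with one row per cluster: label, size, peak F, peak
#'   voxel (1-based i/j/k) and peak mm coordinates. Empty when nothing
#'   survives the threshold.
#' @export
formClusters <- function(fmap, mask, formingP = 0.001, connectivity = 26) {
  stopifnot(is(fmap, "FStatMap"), is(mask, "VolumeMask"))
  .stopIfGridMismatch(fmap, mask, "F map and mask")
  crit <- clusterFormingF(fmap@df1, fmap@df2, formingP)
  edges <- .maskEdges(mask@data, connectivity)
  fVec <- fmap@f[mask@data]
  .clusterTable(fVec, crit, mask@data, edges, fmap@affine)
}

## --------------------------------------------------------------------------
## Relabelling generation. All draws flow from one seeded generator per
## effect; subjects are exchangeability blocks.
## --------------------------------------------------------------------------

.perms4 <- function() {
  ## all 24 permutations of 1:4, deterministic order
  out <- matrix(0L, 24L, 4L)
  r <- 1L
  for (a in 1:4) for (b in setdiff(1:4, a)) for (cc in setdiff(1:4, c(a, b))) {
    out[r, ] <- c(a, b, cc, setdiff(1:4, c(a, b, cc)))
    r <- r + 1L
  }
  out
}

## Source-index vector for a condition-label swap within the flipped subjects.
.permCondition <- function(pc, flip) {
  p <- seq_len(pc$m)
  for (i in which(flip)) {
    a <- pc$lookup[i, 1L, ]
    b <- pc$lookup[i, 2L, ]
    p[a] <- b
    p[b] <- a
  }
  p
}

## Source-index vector for per-subject state relabellings. sigma is an
## N x 4 matrix (shared across conditions) or an N x 2 x 4 array
## (independent per condition).
.permState <- function(pc, sigma) {
  p <- integer(pc$m)
  shared <- length(dim(sigma)) == 2L
  for (m in seq_len(pc$m)) {
    i <- pc$subj[m]; cc <- pc$cond[m]; s <- pc$state[m]
    srcState <- if (shared) sigma[i, s] else sigma[i, cc, s]
    p[m] <- pc$lookup[i, cc, srcState]
  }
  p
}

## Source-index vector permuting the 8 cells within each subject.
.permCells <- function(pc, pi8) {
  p <- integer(pc$m)
  for (i in seq_len(max(pc$subj))) {
    rows <- pc$lookup[i, , ]          # 2 x 4, cell order c + 2*(s-1)? use vec
    rows <- as.vector(pc$lookup[i, , ])
    p[rows] <- rows[pi8[i, ]]
  }
  p
}

## Within-subject residuals after removing both main-effect profiles
## (per subject, across its 8 cells): r = y - m_cond - m_state + m_subject.
.interactionResiduals <- function(Yt, pc) {
  n <- pc$n
  mCI <- .groupMeans(Yt, pc$ci, 4L)
  mSI <- .groupMeans(Yt, pc$si, 2L)
  mI <- .groupMeans(Yt, pc$subj, 8L)
  rowsCI <- (pc$cond - 1L) * n + pc$subj
  rowsSI <- (pc$state - 1L) * n + pc$subj
  Yt - mCI[rowsCI, , drop = FALSE] - mSI[rowsSI, , drop = FALSE] +
    mI[pc$subj, , drop = FALSE]
}

## Effect-specific seed derivation, kept inside 32-bit integer range.
.effectSeed <- function(seed, effect) {
  k <- c(condition = 1L, state = 2L, interaction = 3L)[effect]
  as.integer((as.numeric(seed) + as.numeric(k) * 1000003) %% 2147483647)
}

## Core permutation null of the maximum cluster extent for one effect.
## Returns list(table, nullMax, exhaustive, nPermUsed).
.permEffect <- function(Yt, pc, effect, scheme, crit, maskArr, edges,
                        affine) {
  n <- pc$n
  engineF <- function(Ym) .rmEngine(Ym, pc, effects = effect)[[effect]]$f
  obsF <- engineF(Yt)
  obsTab <- .clusterTable(obsF, crit, maskArr, edges, affine)
  maxSizeOf <- function(fv) .maxClusterSize(fv > crit, edges)
  nPerm <- scheme@nPerm
  set.seed(.effectSeed(scheme@seed, effect))

  if (effect == "interaction") {
    R <- .interactionResiduals(Yt, pc)
    nullMax <- integer(nPerm)
    for (b in seq_len(nPerm)) {
      pi8 <- t(vapply(seq_len(n), function(i) sample.int(8L),
                      integer(8L)))
      nullMax[b] <- maxSizeOf(engineF(R[.permCells(pc, pi8), ,
                                        drop = FALSE]))
    }
    exhaustive <- FALSE
  } else if (effect == "condition") {
    total <- 2^n
    if (total <= nPerm) {
      nullMax <- integer(total)
      for (b in seq_len(total)) {
        flip <- as.logical(bitwAnd(b - 1L, bitwShiftL(1L, 0:(n - 1L))) > 0L)
        nullMax[b] <- maxSizeOf(engineF(Yt[.permCondition(pc, flip), ,
                                           drop = FALSE]))
      }
      exhaustive <- TRUE
      message("condition effect: enumerated all ", total,
              " sign relabellings exactly")
    } else {
      nullMax <- integer(nPerm)
      for (b in seq_len(nPerm)) {
        flip <- sample(c(TRUE, FALSE), n, replace = TRUE)
        nullMax[b] <- maxSizeOf(engineF(Yt[.permCondition(pc, flip), ,
                                           drop = FALSE]))
      }
      exhaustive <- FALSE
    }
  } else {                              # state
    shared <- scheme@stateScheme == "shared"
    p4 <- .perms4()
    total <- if (shared) 24^n else 24^(2 * n)
    if (total <= nPerm) {
      ## enumerate shared per-subject state permutations by mixed radix
      stopifnot(shared)
      nullMax <- integer(total)
      for (b in seq_len(total)) {
        code <- b - 1L
        sigma <- matrix(0L, n, 4L)
        for (i in seq_len(n)) {
          sigma[i, ] <- p4[(code %% 24L) + 1L, ]
          code <- code %/% 24L
        }
        nullMax[b] <- maxSizeOf(engineF(Yt[.permState(pc, sigma), ,
                                           drop = FALSE]))
      }
      exhaustive <- TRUE
      message("state effect: enumerated all ", total,
              " relabellings exactly")
    } else {
      nullMax <- integer(nPerm)
      for (b in seq_len(nPerm)) {
        sigma <- if (shared) {
          t(vapply(seq_len(n), function(i) p4[sample.int(24L, 1L), ],
                   integer(4L)))
        } else {
          arr <- array(0L, dim = c(n, 2L, 4L))
          for (i in seq_len(n)) for (cc in 1:2)
            arr[i, cc, ] <- p4[sample.int(24L, 1L), ]
          arr
        }
        nullMax[b] <- maxSizeOf(engineF(Yt[.permState(pc, sigma), ,
                                           drop = FALSE]))
      }
      exhaustive <- FALSE
    }
  }

  if (nrow(obsTab)) {
    obsTab$fweP <- if (exhaustive) {
      vapply(obsTab$size, function(sz) mean(nullMax >= sz), numeric(1))
    } else {
      vapply(obsTab$size,
             function(sz) (1 + sum(nullMax >= sz)) / (nPerm + 1),
             numeric(1))
    }
  } else {
    obsTab$fweP <- numeric(0)
  }
  list(table = obsTab, nullMax = nullMax, exhaustive = exhaustive,
       observedF = obsF)
}

#' Permutation cluster-extent FWE inference for one system
#'
#' For each requested effect, builds the permutation null of the maximum
#' suprathreshold cluster size under within-subject relabellings (condition:
#' condition-label swaps within a random subset of subjects; state:
#' permutation of the four state labels within each subject; interaction:
#' permutation of within-subject residual cells after removing both
#' main-effect profiles) and assigns each observed cluster the add-one FWE
#' p-value (1 + #\{null max >= observed size\}) / (nPerm + 1). When the
#' relabelling group is small enough it is enumerated exhaustively and the
#' p-value is exact.
#'
#' @param maps List of per-run \code{EnrichedFCMaps}.
#' @param system System label (or index) to analyse.
#' @param design A \code{StudyDesign}.
#' @param mask Analysis \code{VolumeMask}.
#' @param scheme A \code{PermutationScheme}.
#' @param effects Effects to test (default all three).
#' @param formingP Cluster-forming p, default 0.001.
#' @param connectivity 6, 18 or 26 (default).
#' @return Named list per effect with elements \code{table} (cluster table
#'   with \code{fweP}), \code{fmap} (the observed \code{FStatMap}),
#'   \code{nullMax} (null maximum cluster sizes) and \code{exhaustive}.
#' @export
permutationClusterFWE <- function(maps, system, design, mask, scheme,
                                  effects = c("condition", "state",
                                              "interaction"),
                                  formingP = 0.001, connectivity = 26) {
  stopifnot(is(scheme, "PermutationScheme"))
  st <- .stackSystem(maps, system, design, mask)
  pc <- .rmPrecompute(st$codes$subj, st$codes$cond, st$codes$state)
  edges <- .maskEdges(mask@data, connectivity)
  d <- gridDim(mask)
  dfs <- .rmEngine(st$Yt[, 1L, drop = FALSE], pc)
  out <- lapply(stats::setNames(nm = effects), function(eff) {
    crit <- clusterFormingF(dfs[[eff]]$df1, dfs[[eff]]$df2, formingP)
    res <- .permEffect(st$Yt, pc, eff, scheme, crit, mask@data, edges,
                       mask@affine)
    vol <- array(0, dim = d)
    vol[mask@data] <- res$observedF
    res$fmap <- new("FStatMap", effect = eff, f = vol, df1 = dfs[[eff]]$df1,
                    df2 = dfs[[eff]]$df2, affine = mask@affine)
    res$observedF <- NULL
    res
  })
  out
}

#' Bonferroni adjustment across molecular systems
#'
#' Marks clusters whose FWE p-value survives division of alpha by the
#' number of systems tested (p < 0.05 / 5 = 0.01 for the five-system
#' analysis).
#'
#' @param table A cluster table with an \code{fweP} column (or a list of
#'   them, one per system).
#' @param nSystems Number of systems in the family, default 5.
#' @param alpha Family-wise alpha, default 0.05.
#' @return The input with a \code{survivesBonferroni} logical column added.
#' @export
bonferroniAcrossSystems <- function(table, nSystems = 5, alpha = 0.05) {
  if (nSystems < 1) stop("nSystems must be >= 1", call. = FALSE)
  adjust <- function(tab) {
    tab$survivesBonferroni <- tab$fweP < alpha / nSystems
    tab
  }
  if (is.data.frame(table)) adjust(table) else lapply(table, adjust)
}
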