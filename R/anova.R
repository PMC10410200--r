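## Voxelwise 2 x 4 within-subject ANOVA. The engine works on a runs-by-
## voxels matrix so that permutation relabellings are plain row indexing;
## all sums of squares come from group means computed with rowsum (C speed).

## Validate labels and precompute grouping structure for the engine.
## subj/cond/state are integer codes (1..N, 1..2, 1..4), one per run.
.rmPrecompute <- function(subj, cond, state) {
  n <- max(subj)
  m <- length(subj)
  if (m != 8L * n ||
      !all(table(factor(subj, 1:n), factor(cond, 1:2),
                 factor(state, 1:4)) == 1L)) {
    have <- paste(subj, cond, state)
    want <- with(expand.grid(i = 1:n, c = 1:2, s = 1:4), paste(i, c, s))
    stop("incomplete design: missing cell(s) ",
         paste(utils::head(setdiff(want, have), 5L), collapse = "; "),
         call. = FALSE)
  }
  cs <- (cond - 1L) * 4L + state
  ci <- (cond - 1L) * n + subj
  si <- (state - 1L) * n + subj
  lookup <- array(0L, dim = c(n, 2L, 4L))
  lookup[cbind(subj, cond, state)] <- seq_len(m)
  list(n = n, m = m, subj = subj, cond = cond, state = state,
       cs = cs, ci = ci, si = si,
       cOfCs = rep(1:2, each = 4L), sOfCs = rep(1:4, times = 2L),
       cOfCi = rep(1:2, each = n), iOfCi = rep(seq_len(n), times = 2L),
       sOfSi = rep(1:4, each = n), iOfSi = rep(seq_len(n), times = 4L),
       lookup = lookup)
}

.groupMeans <- function(Yt, grp, sizePer) {
  rowsum(Yt, grp, reorder = TRUE) / sizePer
}

## Classical two-way within-subject decomposition per voxel.
## Yt is runs x voxels. Returns F vectors (0 where the error SS vanishes)
## and degrees of freedom.
.rmEngine <- function(Yt, pc,
                      effects = c("condition", "state", "interaction")) {
  n <- pc$n
  gv <- colMeans(Yt)
  mC <- .groupMeans(Yt, pc$cond, 4L * n)
  mS <- .groupMeans(Yt, pc$state, 2L * n)
  mI <- .groupMeans(Yt, pc$subj, 8L)
  devSq <- function(x) colSums(x^2)
  sweepG <- function(x) sweep(x, 2L, gv)
  ssTot <- devSq(sweepG(Yt))
  ssC <- 4 * n * devSq(sweepG(mC))
  ssS <- 2 * n * devSq(sweepG(mS))
  ssI <- 8 * devSq(sweepG(mI))
  mCI <- .groupMeans(Yt, pc$ci, 4L)
  mSI <- .groupMeans(Yt, pc$si, 2L)
  mCS <- .groupMeans(Yt, pc$cs, n)
  ssCsub <- 4 * devSq(sweep(mCI - mC[pc$cOfCi, , drop = FALSE] -
                              mI[pc$iOfCi, , drop = FALSE], 2L, gv, "+"))
  ssSsub <- 2 * devSq(sweep(mSI - mS[pc$sOfSi, , drop = FALSE] -
                              mI[pc$iOfSi, , drop = FALSE], 2L, gv, "+"))
  ssCS <- n * devSq(sweep(mCS - mC[pc$cOfCs, , drop = FALSE] -
                            mS[pc$sOfCs, , drop = FALSE], 2L, gv, "+"))
  ssCSsub <- pmax(ssTot - ssC - ssS - ssI - ssCS - ssCsub - ssSsub, 0)
  safeF <- function(num, dfn, den, dfd) {
    f <- ifelse(den > 0, (num / dfn) / (den / dfd), 0)
    pmax(f, 0)
  }
  out <- list()
  if ("condition" %in% effects)
    out$condition <- list(f = safeF(ssC, 1L, ssCsub, n - 1L),
                          df1 = 1L, df2 = n - 1L)
  if ("state" %in% effects)
    out$state <- list(f = safeF(ssS, 3L, ssSsub, 3L * (n - 1L)),
                      df1 = 3L, df2 = 3L * (n - 1L))
  if ("interaction" %in% effects)
    out$interaction <- list(f = safeF(ssCS, 3L, ssCSsub, 3L * (n - 1L)),
                            df1 = 3L, df2 = 3L * (n - 1L))
  out
}

## Integer-code the labels of a run table against a StudyDesign.
.codeRuns <- function(runs, design) {
  subj <- match(runs$subject, design@subjects)
  cond <- match(runs$condition, design@conditions)
  state <- match(runs$state, design@states)
  if (any(is.na(subj)) || any(is.na(cond)) || any(is.na(state)))
    stop("run labels not found in the design", call. = FALSE)
  list(subj = subj, cond = cond, state = state)
}

#' Within-subject 2 x 4 ANOVA F statistics
#'
#' Classical repeated-measures decomposition for a complete crossed design
#' with factors condition (2 levels) and state (4 levels): each effect is
#' tested against its interaction with subjects
#' (F_condition = MS_C / MS_CxSubj with df (1, N-1); F_state and
#' F_interaction against their subject interactions with df (3, 3(N-1))).
#' Degrees of freedom are not sphericity-corrected; validity at the map
#' level comes from permutation. Voxels with zero error variance get F = 0.
#'
#' @param values Numeric matrix (units x runs) or vector (one unit).
#' @param subject,condition,state Run labels (character or integer codes),
#'   one per column of \code{values}.
#' @param design Optional \code{StudyDesign} fixing the level order; by
#'   default levels are taken in audio/rest, awake/light/deep/recovery
#'   order for character labels.
#' @return A list with one element per effect (condition, state,
#'   interaction), each holding \code{f} (numeric vector), \code{df1} and
#'   \code{df2}.
#' @examples
#' d <- StudyDesign(5)
#' runs <- designTable(d)
#' y <- matrix(rnorm(2 * nrow(runs)), nrow = 2)
#' str(rmAnovaF(y, runs$subject, runs$condition, runs$state))
#' @export
rmAnovaF <- function(values, subject, condition, state, design = NULL) {
  if (is.vector(values)) values <- matrix(values, nrow = 1L)
  if (is.character(subject) || !is.null(design)) {
    if (is.null(design)) design <- StudyDesign(unique(subject))
    codes <- .codeRuns(data.frame(subject = subject, condition = condition,
                                  state = state), design)
  } else {
    codes <- list(subj = as.integer(subject), cond = as.integer(condition),
                  state = as.integer(state))
  }
  pc <- .rmPrecompute(codes$subj, codes$cond, codes$state)
  .rmEngine(t(values), pc)
}

## Stack the betas of one system from a list of per-run EnrichedFCMaps into
## a runs x voxels matrix, with integer-coded labels.
.stackSystem <- function(maps, system, design, mask) {
  stopifnot(is(design, "StudyDesign"), is(mask, "VolumeMask"))
  runs <- data.frame(
    subject = vapply(maps, function(m) m@subject, character(1)),
    condition = vapply(maps, function(m) m@condition, character(1)),
    state = vapply(maps, function(m) m@state, character(1)))
  codes <- .codeRuns(runs, design)
  mv <- as.vector(mask@data)
  Yt <- t(vapply(maps, function(m) {
    .stopIfGridMismatch(m, mask, "beta maps and mask")
    as.vector(betaVolume(m, system))[mv]
  }, numeric(sum(mv))))
  list(Yt = Yt, codes = codes)
}

#' Voxelwise repeated-measures F maps for one molecular system
#'
#' @param maps List of per-run \code{EnrichedFCMaps} (one per subject x
#'   condition x state cell).
#' @param system System label (or index) whose beta maps are analysed.
#' @param design A \code{StudyDesign}.
#' @param mask Analysis \code{VolumeMask}.
#' @return Named list of three \code{FStatMap}s (condition, state,
#'   interaction).
#' @export
rmAnovaFMaps <- function(maps, system, design, mask) {
  st <- .stackSystem(maps, system, design, mask)
  pc <- .rmPrecompute(st$codes$subj, st$codes$cond, st$codes$state)
  res <- .rmEngine(st$Yt, pc)
  d <- gridDim(mask)
  lapply(stats::setNames(nm = names(res)), function(eff) {
    vol <- array(0, dim = d)
    vol[mask@data] <- res[[eff]]$f
    new("FStatMap", effect = eff, f = vol, df1 = res[[eff]]$df1,
        df2 = res[[eff]]$df2, affine = mask@affine)
  })
}
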