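# Small deterministic fixtures shared across tests. Everything is built in
# code; nothing is read from disk except files the tests themselves write.

fixtureAffine <- function(spacing = 3) diag(c(rep(spacing, 3), 1))

# A mask covering the whole grid.
fullMask <- function(dim, affine = fixtureAffine()) {
  VolumeMask(array(TRUE, dim = dim), affine)
}

# Mask from a logical vector/array.
maskFrom <- function(sel, dim, affine = fixtureAffine()) {
  VolumeMask(array(sel, dim = dim), affine)
}

# Template set with exactly controlled within-mask values; values are laid
# out in voxel order over the whole grid.
templatesFrom <- function(columns, dim, names = NULL, affine = fixtureAffine(),
                          conditioned = TRUE) {
  k <- ncol(columns)
  if (is.null(names)) names <- paste0("sys", seq_len(k))
  TemplateSet(array(columns, dim = c(dim, k)), names, affine = affine,
              conditioned = conditioned)
}

# Two standardised orthogonal template columns over n voxels (exact zero
# covariance by construction).
orthogonalPair <- function(n) {
  stopifnot(n %% 2 == 0)
  a <- rep(c(1, -1), n / 2)
  b <- rep(c(1, 1, -1, -1), length.out = n)
  b <- b - mean(b)
  cbind(a - mean(a), b)
}

# A pair with exact sample correlation r, built from an orthogonal pair.
correlatedPair <- function(n, r) {
  z <- orthogonalPair(n)
  z <- scale(z)[, ]                       # unit sample SD
  cbind(z[, 1], r * z[, 1] + sqrt(1 - r^2) * z[, 2])
}

# In-memory fixture study on an 8^3 grid.
tinyStudy <- function(nSubjects = 2, k = 3, dim = c(8, 8, 8), tAudio = 12,
                      tRest = 14, noiseSd = 0.5, effects = list(), seed = 42) {
  tpl <- simulateTemplates(k = k, dim = dim, seed = seed)
  msk <- simulateMasks(dim)
  am <- buildAnalysisMask(tpl, msk$gm)
  design <- StudyDesign(nSubjects)
  sim <- simulateStudy(tpl, msk, design, tAudio = tAudio, tRest = tRest,
                       effects = effects, noiseSd = noiseSd,
                       seed = seed + 1)
  list(templates = tpl, masks = msk, analysisMask = am, design = design,
       runs = sim$runs, truth = sim$truth)
}

# A compact cluster inside a mask: the box neighbourhood (half-width 1) of
# the first mask voxel whose box overlaps the mask in at least minSize
# voxels (requireFull demands the whole 27-voxel box).
compactCluster <- function(mask, minSize = 9, requireFull = FALSE) {
  d <- gridDim(mask)
  arr <- maskArray(mask)
  for (idx in which(arr)) {
    co <- arrayInd(idx, d)
    if (any(co == 1) || any(co == d)) next
    box <- array(FALSE, d)
    box[(co[1] - 1):(co[1] + 1), (co[2] - 1):(co[2] + 1),
        (co[3] - 1):(co[3] + 1)] <- TRUE
    hit <- box & arr
    if (requireFull && sum(hit) == 27) return(VolumeMask(box, mask@affine))
    if (!requireFull && sum(hit) >= minSize)
      return(VolumeMask(hit, mask@affine))
  }
  stop("no compact cluster fits inside the mask")
}

# Per-run enriched maps for an in-memory study.
reactAll <- function(study, smoothFwhm = 0) {
  lapply(study$runs, function(s) {
    if (smoothFwhm > 0) s <- smoothGaussian(s, smoothFwhm)
    reactStage2(s, reactStage1(s, study$templates, study$analysisMask),
                study$analysisMask)
  })
}
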