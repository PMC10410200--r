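# Synthetic-study generator: determinism, marginals, planted structure.

test_that("template generation is deterministic and hits the target correlation", {
  tplA <- simulateTemplates(k = 3, dim = c(12, 12, 12), seed = 61)
  tplB <- simulateTemplates(k = 3, dim = c(12, 12, 12), seed = 61)
  expect_identical(tplA@data, tplB@data)
  tplC <- simulateTemplates(k = 3, dim = c(12, 12, 12), seed = 62)
  expect_false(identical(tplA@data, tplC@data))
  expect_true(tplA@conditioned)
  # conditioned range attained
  for (j in 1:3) {
    v <- templateVolume(tplA, j)
    expect_equal(range(v), c(0, 1))
  }

  # identity target: near-orthogonal fields, VIF close to 1
  full <- fullMask(c(30, 30, 30))
  tplI <- simulateTemplates(k = 5, dim = c(30, 30, 30),
                            targetCorr = diag(5), seed = 63)
  r <- templateCorrelations(pairwiseTemplateCorrelation(tplI, full))
  expect_lt(max(abs(r[upper.tri(r)])), 0.1)
  expect_lt(max(vifValues(computeVIF(tplI, full))), 1.2)

  # planted r = 0.6 pair recovered within 0.05 on a 30^3 grid
  C <- diag(5); C[1, 2] <- C[2, 1] <- 0.6
  tplR <- simulateTemplates(k = 5, dim = c(30, 30, 30), targetCorr = C,
                            seed = 64)
  r2 <- templateCorrelations(pairwiseTemplateCorrelation(tplR, full))
  expect_lt(abs(r2[1, 2] - 0.6), 0.05)

  bad <- matrix(0.99, 3, 3) + diag(0.01, 3)
  bad[1, 2] <- bad[2, 1] <- -0.99
  expect_error(simulateTemplates(k = 3, dim = c(8, 8, 8), targetCorr = bad,
                                 seed = 1), "positive definite")
})

test_that("masks are disjoint, nested and sized to the requested fractions", {
  d3 <- c(14, 14, 14)
  msk <- simulateMasks(d3, wmFrac = 0.2, gmFrac = 0.35, csfFrac = 0.1,
                       refFrac = 0.08)
  v <- prod(d3)
  expect_equal(sum(maskArray(msk$gm) & maskArray(msk$wm)), 0L)
  expect_equal(sum(maskArray(msk$gm) & maskArray(msk$csf)), 0L)
  expect_equal(sum(maskArray(msk$wm) & maskArray(msk$csf)), 0L)
  expect_true(all(which(maskArray(msk$ref)) %in% which(maskArray(msk$gm))))
  expect_lte(abs(maskCount(msk$wm) - 0.2 * v), 1)
  expect_lte(abs(maskCount(msk$gm) - 0.35 * v), 1)
  expect_lte(abs(maskCount(msk$csf) - 0.1 * v), 1)
  expect_lte(abs(maskCount(msk$ref) - 0.08 * maskCount(msk$gm)), 1)
})

test_that("study generation is deterministic and noise marginals match", {
  study1 <- tinyStudy(seed = 65)
  study2 <- tinyStudy(seed = 65)
  expect_identical(scanArray(study1$runs[[3]]), scanArray(study2$runs[[3]]))

  # empirical noise SD within 2% at >= 1e4 samples (zero-signal voxels do
  # not exist, so check the AR(1) noise generator directly)
  set.seed(66)
  w <- reactfc:::.noiseMatrix(100, 200, noiseSd = 1.5, rho = 0)
  expect_lt(abs(sd(w) - 1.5) / 1.5, 0.02)
  a <- reactfc:::.noiseMatrix(100, 200, noiseSd = 2, rho = 0.4)
  expect_lt(abs(sd(a) - 2) / 2, 0.02)
  ac <- mean(apply(a[, 1:50], 2, function(x)
    cor(x[-1], x[-length(x)])))
  expect_lt(abs(ac - 0.4), 0.05)
})

test_that("noiseless studies are recovered exactly by the two stages", {
  study <- tinyStudy(nSubjects = 2, noiseSd = 0, seed = 67)
  L <- matrix(study$templates@data, nrow = prod(gridDim(study$templates)))
  sel <- maskArray(study$analysisMask)
  for (r in c(1, 8)) {
    fc <- reactStage2(study$runs[[r]],
                      reactStage1(study$runs[[r]], study$templates,
                                  study$analysisMask),
                      study$analysisMask)
    B <- sapply(seq_len(nSystems(fc)), function(j) betaVolume(fc, j)[sel])
    expect_lt(max(abs(B - L[sel, ])), 1e-6)
  }
})

test_that("null studies give F statistics with the nominal F distribution", {
  study <- tinyStudy(nSubjects = 10, k = 3, tAudio = 20, tRest = 20,
                     noiseSd = 1, seed = 68)
  maps <- reactAll(study)
  fmaps <- rmAnovaFMaps(maps, "DAT", study$design, study$analysisMask)
  fv <- fArray(fmaps$state)[maskArray(study$analysisMask)]
  ks <- suppressWarnings(ks.test(fv, "pf", 3, 27))
  expect_gt(ks$p.value, 0.01)
  fvI <- fArray(fmaps$interaction)[maskArray(study$analysisMask)]
  ksI <- suppressWarnings(ks.test(fvI, "pf", 3, 27))
  expect_gt(ksI$p.value, 0.01)
})

test_that("effect specifications enforce their structural invariants", {
  cl <- cubicClusterMask(c(8, 8, 8))
  expect_equal(maskCount(cl), 27L)
  # interaction with non-zero margins is rejected
  badProfile <- rbind(c(1, 0, 0, 0), c(0, 0, 0, 0))
  expect_error(effectSpec("DAT", "interaction", cl,
                          cellProfile = badProfile), "margins")
  # canonical profiles satisfy the invariants
  for (ty in c("interaction", "state_main", "condition_main", "null")) {
    e <- effectSpec("DAT", ty, cl)
    expect_s4_class(e, "EffectSpec")
  }
  expect_equal(effectSpec("DAT", "null", cl, amplitude = 3)@amplitude, 0)
  pair <- audioOnlyEffectPair("DAT", cl, amplitude = 2)
  total <- pair[[1]]@cellProfile + pair[[2]]@cellProfile
  expect_equal(unname(total[1, ]), c(1, -1, -1, 1))   # audio states differ
  expect_equal(unname(total[2, ]), rep(0, 4))         # rest flat
})

test_that("planted interaction shifts cell means by amplitude x template", {
  d3 <- c(8, 8, 8)
  cl <- compactCluster(simulateMasks(d3)$gm)
  study <- tinyStudy(nSubjects = 2, k = 3, dim = d3, noiseSd = 0,
                     effects = list(effectSpec("DAT", "interaction", cl,
                                               amplitude = 2)),
                     seed = 69)
  sel <- maskArray(study$analysisMask) & maskArray(cl)
  tplDat <- templateVolume(study$templates, "DAT")
  beta <- function(r) {
    fc <- reactStage2(study$runs[[r]],
                      reactStage1(study$runs[[r]], study$templates,
                                  study$analysisMask),
                      study$analysisMask)
    betaVolume(fc, "DAT")[sel]
  }
  # audio awake (+0.5) minus audio light (-0.5): planted difference is
  # amplitude x (0.5 - (-0.5)) x template = 2 x template; stage-1 series
  # are estimated from the perturbed run, so recovery is approximate at
  # the level of the loading perturbation (a few percent), not exact
  diffGot <- beta(1) - beta(2)
  diffWant <- 2 * tplDat[sel]
  expect_equal(diffGot, diffWant, tolerance = 0.1)
  expect_gt(cor(diffGot, diffWant), 0.95)
})
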