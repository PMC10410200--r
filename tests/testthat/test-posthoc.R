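# Cluster means, Sidak contrasts, simple main effects, atlas overlap.

clusterTable <- function(n, fill) {
  d <- StudyDesign(n)
  runs <- designTable(d)
  runs$system <- "A"
  runs$cluster <- 1L
  runs$value <- fill(runs)
  runs
}

test_that("cluster means equal constants, singletons and the voxel-loop oracle", {
  study <- tinyStudy(nSubjects = 2, seed = 51)
  maps <- reactAll(study)
  d3 <- gridDim(study$analysisMask)

  clSel <- which(maskArray(study$analysisMask))[1:4]
  clMask <- maskFrom(seq_len(prod(d3)) %in% clSel, d3)
  tab <- extractClusterMeans(maps, clMask, "DAT")
  expect_equal(nrow(tab), 16L)                  # 2 x 2 x 4 runs
  # voxel-loop oracle
  for (r in c(1, 9, 16)) {
    acc <- 0
    vol <- betaVolume(maps[[r]], "DAT")
    for (i in clSel) acc <- acc + vol[i]
    expect_equal(tab$value[r], acc / 4, tolerance = 1e-10)
  }
  # singleton cluster gives that voxel's beta
  single <- maskFrom(seq_len(prod(d3)) == clSel[1], d3)
  tab1 <- extractClusterMeans(maps, single, "DAT")
  expect_equal(tab1$value[3], betaVolume(maps[[3]], "DAT")[clSel[1]])
  expect_error(extractClusterMeans(maps, maskFrom(rep(FALSE, prod(d3)), d3),
                                   "DAT"), "invalid mask")
})

test_that("Sidak adjustment: closed form, monotonicity, m = 1 identity", {
  set.seed(52)
  tab <- clusterTable(8, function(r) rnorm(nrow(r)))
  res <- pairedContrastsSidak(tab, "state")
  expect_equal(nrow(res), 6L)
  expect_equal(res$m, rep(6L, 6))
  # p_adj = 1 - (1 - p)^m and never below p
  expect_equal(res$pAdjusted, 1 - (1 - res$pUnadjusted)^6, tolerance = 1e-12)
  expect_true(all(res$pAdjusted >= res$pUnadjusted))
  expect_true(all(res$ciLow <= res$meanDifference &
                    res$meanDifference <= res$ciHigh))

  # m = 1 reduces to the plain paired t with a standard CI
  resC <- pairedContrastsSidak(tab, "condition", m = 1)
  expect_equal(resC$pAdjusted, resC$pUnadjusted, tolerance = 1e-12)
  agg <- aggregate(value ~ subject + condition, tab, mean)
  wide <- reshape(agg, idvar = "subject", timevar = "condition",
                  direction = "wide")
  orc <- oraclePairedT(wide$value.audio, wide$value.rest)
  expect_equal(resC$meanDifference, orc$md, tolerance = 1e-8)
  expect_equal(resC$se, orc$se, tolerance = 1e-8)
  expect_equal(resC$pUnadjusted, orc$p, tolerance = 1e-8)
  expect_equal(c(resC$ciLow, resC$ciHigh), c(orc$lo, orc$hi),
               tolerance = 1e-8)
})

test_that("Sidak state contrasts match a first-principles paired-t oracle", {
  set.seed(53)
  tab <- clusterTable(11, function(r)
    rnorm(nrow(r)) + ifelse(r$state == "deep", 0.8, 0))
  res <- pairedContrastsSidak(tab, "state")
  agg <- aggregate(value ~ subject + state, tab, mean)
  sidakLevel <- 1 - (1 - (1 - 0.05)^(1 / 6))
  for (i in seq_len(nrow(res))) {
    a <- agg$value[agg$state == res$levelA[i]]
    b <- agg$value[agg$state == res$levelB[i]]
    orc <- oraclePairedT(a, b, level = sidakLevel)
    expect_equal(res$meanDifference[i], orc$md, tolerance = 1e-8)
    expect_equal(res$tValue[i], orc$t, tolerance = 1e-8)
    expect_equal(res$pAdjusted[i], 1 - (1 - orc$p)^6, tolerance = 1e-8)
    expect_equal(c(res$ciLow[i], res$ciHigh[i]), c(orc$lo, orc$hi),
                 tolerance = 1e-8)
  }
})

test_that("marginal contrasts commute with averaging (linearity)", {
  set.seed(54)
  tab <- clusterTable(7, function(r) rnorm(nrow(r)))
  res <- pairedContrastsSidak(tab, "state")
  # difference of cell means averaged over conditions, per subject
  for (i in seq_len(nrow(res))) {
    byCell <- with(tab, tapply(value, list(subject, condition, state), mean))
    dAvg <- rowMeans(byCell[, , res$levelA[i]]) -
      rowMeans(byCell[, , res$levelB[i]])
    expect_equal(res$meanDifference[i], mean(dAvg), tolerance = 1e-10)
  }
})

test_that("simple main effects mirror the audio-only planted pattern", {
  set.seed(55)
  # audio: awake/recovery high, sedation low; rest: exactly flat profile
  tab <- clusterTable(12, function(r) {
    off <- ifelse(r$condition == "audio" & r$state %in% c("awake", "recovery"),
                  1.5, 0)
    rnorm(nrow(r), sd = 0.3) + off
  })
  res <- simpleMainEffects(tab)
  expect_equal(nrow(res), 12L)
  expect_equal(unname(table(res$condition)), c(6L, 6L), ignore_attr = TRUE)
  audioAL <- res[res$condition == "audio" & res$levelA == "awake" &
                   res$levelB == "light", ]
  expect_gt(audioAL$meanDifference, 0)
  expect_lt(audioAL$pAdjusted, 0.05)
  # planted offset 1.5 recovered within the CI
  expect_true(audioAL$ciLow <= 1.5 && 1.5 <= audioAL$ciHigh)
  restP <- res$pAdjusted[res$condition == "rest"]
  expect_gt(min(restP), 0.05)

  # degenerate: states identical within rest
  tab2 <- clusterTable(5, function(r) ifelse(r$condition == "rest", 1,
                                             rnorm(nrow(r))))
  res2 <- simpleMainEffects(tab2)
  restRows <- res2[res2$condition == "rest", ]
  expect_true(all(restRows$meanDifference == 0))
  expect_true(all(restRows$degenerate))
})

test_that("atlas overlap matches containment, emptiness and counting oracles", {
  d3 <- c(6, 6, 6)
  atlas <- array(0L, d3)
  atlas[1:3, , ] <- 1L; atlas[4:5, , ] <- 2L; atlas[6, , ] <- 3L
  mp <- array(0, d3); mp[2, 2:4, 2] <- 5
  rep1 <- atlasOverlapReport(mp, atlas, threshold = 3)
  expect_equal(rep1$networkFraction[rep1$region == 1], 1)
  expect_equal(rep1$networkFraction[rep1$region == 2], 0)
  expect_equal(rep1$regionCoverage[rep1$region == 1], 3 / sum(atlas == 1))

  expect_equal(nrow(atlasOverlapReport(mp, atlas, threshold = 10)), 0L)

  set.seed(56)
  mp2 <- array(rnorm(prod(d3)), d3)
  rep2 <- atlasOverlapReport(mp2, atlas, threshold = 0.5)
  net <- mp2 >= 0.5
  for (r in 1:3) {
    expect_equal(rep2$networkVoxels[rep2$region == r],
                 sum(net & atlas == r))
    expect_equal(rep2$networkFraction[rep2$region == r],
                 sum(net & atlas == r) / sum(net))
  }
  expect_error(atlasOverlapReport(mp2, array(0L, c(2, 2, 2))), "shape")
})
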