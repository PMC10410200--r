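# Cluster formation and permutation cluster-extent FWE inference.

fmapFrom <- function(f, df1 = 3L, df2 = 48L, affine = fixtureAffine()) {
  new("FStatMap", effect = "state", f = f, df1 = df1, df2 = df2,
      affine = affine)
}

# Enriched maps for one system built directly from a voxels-vector per run.
fcMapsFrom <- function(values, runs, mask, system = "A") {
  d <- gridDim(mask)
  lapply(seq_len(nrow(runs)), function(r) {
    vol <- array(0, dim = d)
    vol[maskArray(mask)] <- values[, r]
    EnrichedFCMaps(array(vol, dim = c(d, 1)), system, mask,
                   affine = mask@affine, subject = runs$subject[r],
                   condition = runs$condition[r], state = runs$state[r])
  })
}

test_that("cluster formation: singletons, blocks, connectivity rules", {
  d3 <- c(7, 7, 7)
  mask <- fullMask(d3)
  crit <- clusterFormingF(3, 48, 0.001)
  expect_equal(crit, qf(0.999, 3, 48))

  f <- array(0, d3); f[2, 2, 2] <- crit + 1
  tab <- formClusters(fmapFrom(f), mask)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$size, 1L)
  expect_equal(c(tab$peakI, tab$peakJ, tab$peakK), c(2, 2, 2))
  expect_equal(tab$peakXmm, 3)                      # (2-1) * 3 mm spacing

  f2 <- array(0, d3); f2[3:5, 3:5, 3:5] <- crit + 1
  tab2 <- formClusters(fmapFrom(f2), mask)
  expect_equal(tab2$size, 27L)

  # corner contact: one cluster under 26-connectivity, two under 6
  f3 <- array(0, d3); f3[1, 1, 1] <- crit + 1; f3[2, 2, 2] <- crit + 2
  expect_equal(formClusters(fmapFrom(f3), mask, connectivity = 26)$size, 2L)
  expect_equal(sort(formClusters(fmapFrom(f3), mask,
                                 connectivity = 6)$size), c(1L, 1L))
  # matches the flood-fill oracle on both connectivities
  expect_equal(sort(formClusters(fmapFrom(f3), mask)$size),
               sort(oracleClusterSizes(f3 > crit, 26)))
  expect_equal(sort(oracleClusterSizes(f3 > crit, 6)), c(1L, 1L))

  # empty suprathreshold set is a valid empty table
  expect_equal(nrow(formClusters(fmapFrom(array(0, d3)), mask)), 0L)
})

test_that("random maps: component sizes agree with the flood-fill oracle", {
  set.seed(41)
  d3 <- c(9, 9, 9)
  mask <- fullMask(d3)
  for (rep in 1:5) {
    f <- array(rexp(prod(d3)) * 4, d3)
    tab <- formClusters(fmapFrom(f), mask)
    orc <- oracleClusterSizes(f > clusterFormingF(3, 48, 0.001), 26)
    expect_equal(sort(tab$size), sort(orc))
  }
})

test_that("FWE p attains its lower bound for a dominant cluster", {
  set.seed(42)
  d <- StudyDesign(10)
  runs <- designTable(d)
  mask <- fullMask(c(5, 5, 5))
  v <- maskCount(mask)
  # strong condition effect in a 3x3x3 block, faint noise elsewhere
  blockSel <- as.vector(maskArray(cubicClusterMask(c(5, 5, 5),
                                                   halfWidth = 1)))
  values <- matrix(rnorm(v * nrow(runs), sd = 0.05), v, nrow(runs))
  condEff <- ifelse(runs$condition == "audio", 2, -2)
  values[blockSel, ] <- values[blockSel, ] +
    matrix(rep(condEff, each = sum(blockSel)), sum(blockSel))
  maps <- fcMapsFrom(values, runs, mask)
  sch <- PermutationScheme(nPerm = 199, seed = 9)
  res <- permutationClusterFWE(maps, "A", d, mask, sch,
                               effects = "condition", formingP = 0.01)
  tab <- res$condition$table
  expect_false(res$condition$exhaustive)           # 2^10 > 199
  expect_gte(tab$size[1], 27)
  expect_equal(tab$fweP[1], 1 / 200)
  # p never below the add-one bound
  expect_true(all(tab$fweP >= 1 / 200))
})

test_that("two-subject toy design is enumerated exactly and matches the oracle", {
  set.seed(43)
  d <- StudyDesign(2)
  runs <- designTable(d)
  d3 <- c(4, 4, 4)
  mask <- fullMask(d3)
  v <- maskCount(mask)
  condEff <- ifelse(runs$condition == "audio", 1, -1)
  sel <- rep(FALSE, v); sel[c(1, 2, 5)] <- TRUE
  values <- matrix(rnorm(v * 16, sd = 1e-3), v, 16)
  values[sel, ] <- values[sel, ] + matrix(rep(condEff, each = 3), 3)
  maps <- fcMapsFrom(values, runs, mask)
  sch <- PermutationScheme(nPerm = 1000, seed = 11)
  expect_message(
    res <- permutationClusterFWE(maps, "A", d, mask, sch,
                                 effects = "condition", formingP = 0.05),
    "enumerated")
  expect_true(res$condition$exhaustive)
  tab <- res$condition$table

  # independent oracle: enumerate the 4 relabellings from first principles
  subj <- match(runs$subject, d@subjects)
  cond <- match(runs$condition, c("audio", "rest"))
  state <- match(runs$state, c("awake", "light", "deep", "recovery"))
  crit <- qf(1 - 0.05, 1, 1)
  nullMax <- sapply(0:3, function(b) {
    flip <- c(bitwAnd(b, 1L) > 0, bitwAnd(b, 2L) > 0)
    condPerm <- ifelse(flip[subj], 3L - cond, cond)
    fv <- apply(values, 1, function(y)
      oracleRmAnova(y, subj, condPerm, state)$condition)
    supra <- array(fv > crit, d3)
    sizes <- oracleClusterSizes(supra, 26)
    if (length(sizes)) max(sizes) else 0L
  })
  for (i in seq_len(nrow(tab)))
    expect_equal(tab$fweP[i], mean(nullMax >= tab$size[i]))
})

test_that("Bonferroni flags follow alpha / nSystems exactly", {
  tab <- data.frame(label = 1:3, size = c(40, 20, 10),
                    fweP = c(0.009, 0.011, 0.5))
  out <- bonferroniAcrossSystems(tab, nSystems = 5, alpha = 0.05)
  expect_equal(out$survivesBonferroni, c(TRUE, FALSE, FALSE))
  out1 <- bonferroniAcrossSystems(tab, nSystems = 1, alpha = 0.05)
  expect_equal(out1$survivesBonferroni, tab$fweP < 0.05)
  expect_error(bonferroniAcrossSystems(tab, nSystems = 0), "nSystems")
})

test_that("state relabelling preserves the null and p-values are reproducible", {
  set.seed(44)
  d <- StudyDesign(5)
  runs <- designTable(d)
  mask <- fullMask(c(4, 4, 4))
  values <- matrix(rnorm(64 * nrow(runs)), 64, nrow(runs))
  maps <- fcMapsFrom(values, runs, mask)
  sch <- PermutationScheme(nPerm = 60, seed = 7)
  r1 <- permutationClusterFWE(maps, "A", d, mask, sch, effects = "state",
                              formingP = 0.05)
  r2 <- permutationClusterFWE(maps, "A", d, mask, sch, effects = "state",
                              formingP = 0.05)
  expect_identical(r1$state$nullMax, r2$state$nullMax)   # seeded draws
  expect_identical(r1$state$table, r2$state$table)
})
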