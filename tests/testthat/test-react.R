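# Signal conditioning and the two regression stages.

dim3 <- c(5, 5, 5)
nvox <- prod(dim3)

makeScan <- function(Y, tr = 2, affine = fixtureAffine()) {
  # Y is voxels x time
  Scan4D(array(Y, dim = c(dim3, ncol(Y))), tr = tr, affine = affine)
}

.voxMat <- function(scan) {
  d <- dim(scanArray(scan))
  matrix(scanArray(scan), nrow = prod(d[1:3]))
}

test_that("nuisance regression removes WM/CSF signal exactly where it should", {
  set.seed(21)
  nT <- 20
  wmSel <- rep(FALSE, nvox); wmSel[1:10] <- TRUE
  csfSel <- rep(FALSE, nvox); csfSel[11:18] <- TRUE
  wm <- maskFrom(wmSel, dim3); csf <- maskFrom(csfSel, dim3)

  # every voxel equals the WM mean series -> residual identically 0
  base <- rnorm(nT)
  Y <- matrix(rep(base, each = nvox), nvox, nT)
  out <- regressNuisance(makeScan(Y), wm, csf)
  expect_lt(max(abs(scanArray(out))), 1e-10)

  # random scan vs per-voxel normal-equations oracle
  Y2 <- matrix(rnorm(nvox * nT), nvox, nT)
  out2 <- regressNuisance(makeScan(Y2), wm, csf)
  wmSeries <- colMeans(Y2[wmSel, ])
  csfSeries <- colMeans(Y2[csfSel, ])
  R2 <- .voxMat(out2)
  for (i in sample(nvox, 12)) {
    fit <- lm(Y2[i, ] ~ wmSeries + csfSeries)
    expect_equal(unname(R2[i, ]), unname(residuals(fit)), tolerance = 1e-8)
  }
  # residuals orthogonal to both nuisance series
  expect_lt(max(abs(R2 %*% cbind(wmSeries - mean(wmSeries),
                                 csfSeries - mean(csfSeries)))), 1e-8)

  # constant nuisance dropped with a warning; remaining regression intact
  Y3 <- Y2; Y3[csfSel, ] <- 1
  expect_warning(out3 <- regressNuisance(makeScan(Y3), wm, csf), "csf")
  R3 <- .voxMat(out3)
  i <- which(!wmSel & !csfSel)[1]
  fit <- lm(Y3[i, ] ~ colMeans(Y3[wmSel, ]))
  expect_equal(unname(R3[i, ]), unname(residuals(fit)), tolerance = 1e-8)
})

test_that("DCT high-pass removes drift and preserves the passband", {
  nT <- 256; tr <- 2
  t <- seq_len(nT)
  lowFreq <- cos(2 * pi * 0.002 * (t - 1) * tr)       # below 0.005 Hz
  highFreq <- cos(2 * pi * 0.05 * (t - 1) * tr)       # well above
  Y <- rbind(matrix(rep(lowFreq, each = 2), 2, nT),
             matrix(rep(highFreq, each = 2), 2, nT),
             matrix(5, 1, nT),
             matrix(rnorm((nvox - 5) * nT), nvox - 5, nT))
  out <- highpassDCT(makeScan(Y, tr = tr), cutoffHz = 0.005)
  R <- .voxMat(out)
  expect_lt(sd(R[1, ]), 0.01 * sd(lowFreq))           # drift removed
  expect_gt(cor(R[3, ], highFreq), 0.999)             # passband preserved
  expect_lt(max(abs(R[5, ])), 1e-10)                  # constant -> 0

  # residual equals projection oracle for a random voxel
  kMax <- ceiling(2 * nT * tr * 0.005) - 1
  C <- sapply(seq_len(kMax), function(k) cos(pi * (2 * t - 1) * k / (2 * nT)))
  i <- 10
  fit <- lm(Y[i, ] ~ C)
  expect_equal(unname(R[i, ]), unname(residuals(fit)), tolerance = 1e-8)

  expect_error(highpassDCT(makeScan(Y[, 1:4], tr = tr), cutoffHz = 0.4),
               "invalid parameter")
  expect_error(highpassDCT(makeScan(Y, tr = tr), cutoffHz = 1e-6),
               "invalid parameter")
})

test_that("Gaussian smoothing: identity at 0, mean preservation, impulse peak", {
  set.seed(22)
  Y <- matrix(rnorm(nvox * 3), nvox, 3)
  scan <- makeScan(Y)
  expect_identical(scanArray(smoothGaussian(scan, 0)), scanArray(scan))

  const <- makeScan(matrix(7.5, nvox, 2))
  expect_equal(scanArray(smoothGaussian(const, 6)), scanArray(const),
               tolerance = 1e-12)

  # impulse at an interior voxel (kernel radius 4 fits inside 11^3):
  # peak equals the product of the three 1-D kernel centre weights
  imp <- array(0, c(11, 11, 11, 2)); imp[6, 6, 6, 1:2] <- 1
  sm <- smoothGaussian(Scan4D(imp, tr = 2, affine = fixtureAffine(3)), 6)
  sigma <- 6 / (2 * sqrt(2 * log(2))) / 3
  x <- seq(-ceiling(4 * sigma), ceiling(4 * sigma))
  k1 <- exp(-x^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
  expect_equal(scanArray(sm)[6, 6, 6, 1], max(k1)^3, tolerance = 1e-6)

  # anisotropic voxels: coarser spacing means a smaller sigma in voxels,
  # so less leakage to the neighbour along that axis
  aff <- diag(c(2, 4, 2, 1))
  sm2 <- smoothGaussian(Scan4D(imp, tr = 2, affine = aff), 6)
  expect_gt(scanArray(sm2)[7, 6, 6, 1], scanArray(sm2)[6, 7, 6, 1])
})

test_that("stage 1 recovers planted series and matches a per-volume oracle", {
  set.seed(23)
  k <- 3; nT <- 15
  mask <- fullMask(dim3)
  M <- matrix(runif(nvox * k, 0.2, 1), nvox, k)
  tpl <- templatesFrom(M, dim3)
  S0 <- matrix(rnorm(k * nT), k, nT)
  S0 <- S0 - rowMeans(S0)
  Y <- M %*% S0                              # noiseless mixture
  ts <- reactStage1(makeScan(Y), tpl, mask)
  expect_equal(timeSeriesMatrix(ts), S0, tolerance = 1e-8,
               ignore_attr = TRUE)

  # spatial-constant invariance: add a constant to one volume
  Y2 <- Y; Y2[, 4] <- Y2[, 4] + 17
  ts2 <- reactStage1(makeScan(Y2), tpl, mask)
  expect_equal(timeSeriesMatrix(ts2), timeSeriesMatrix(ts),
               tolerance = 1e-10)

  # random scan vs per-timepoint least-squares oracle
  Y3 <- matrix(rnorm(nvox * nT), nvox, nT)
  ts3 <- reactStage1(makeScan(Y3), tpl, mask)
  Md <- sweep(M, 2, colMeans(M))
  for (tt in c(1, 7, nT)) {
    d <- Y3[, tt] - mean(Y3[, tt])
    fit <- lm(d ~ 0 + Md)
    expect_equal(unname(timeSeriesMatrix(ts3)[, tt]), unname(coef(fit)),
                 tolerance = 1e-8)
  }

  # rank-deficient design names the offending template
  Mbad <- cbind(M[, 1], M[, 1] * 2, M[, 3])
  expect_error(reactStage1(makeScan(Y3), templatesFrom(Mbad, dim3), mask),
               "singular design")
})

test_that("stage 2 betas match exact and brute-force cases", {
  set.seed(24)
  k <- 3; nT <- 20
  mask <- fullMask(dim3)
  S <- matrix(rnorm(k * nT), k, nT)
  ts <- SystemTimeSeries(S, tr = 2)
  # unit-SD version of the design, as stage 2 defines it
  Sd <- S - rowMeans(S)
  Su <- Sd / sqrt(rowMeans(Sd^2))

  # voxel equal to 3 x unit-SD series 2, orthogonalised design not needed:
  # build an orthogonal design so the fit is exactly univariate
  Sor <- matrix(0, 3, 20)
  Sor[1, ] <- rep(c(1, -1), 10)
  Sor[2, ] <- rep(c(1, 1, -1, -1), 5)
  Sor[3, ] <- Sor[1, ] * Sor[2, ]            # Walsh product: orthogonal
  tsOr <- SystemTimeSeries(Sor, tr = 2)
  Y <- matrix(0, nvox, nT)
  Y[1, ] <- 3 * Sor[2, ]                     # already unit pop SD
  Y[2, ] <- rep(c(1, -1, -1, 1), 5) * 0      # zero voxel
  fc <- reactStage2(makeScan(Y), tsOr, mask)
  b1 <- sapply(1:3, function(j) betaVolume(fc, j)[1])
  expect_equal(b1, c(0, 3, 0), tolerance = 1e-10)
  expect_equal(sapply(1:3, function(j) betaVolume(fc, j)[2]), rep(0, 3))

  # random run vs per-voxel regression oracle
  Y2 <- matrix(rnorm(nvox * nT), nvox, nT)
  fc2 <- reactStage2(makeScan(Y2), ts, mask)
  B <- sapply(1:k, function(j) as.vector(betaVolume(fc2, j)))
  for (i in sample(nvox, 10)) {
    fit <- lm(I(Y2[i, ] - mean(Y2[i, ])) ~ 0 + t(Su))
    expect_equal(unname(B[i, ]), unname(coef(fit)), tolerance = 1e-8)
  }

  # temporal-constant invariance per voxel
  Y3 <- Y2; Y3[5, ] <- Y3[5, ] + 100
  fc3 <- reactStage2(makeScan(Y3), ts, mask)
  expect_equal(sapply(1:k, function(j) betaVolume(fc3, j)[5]),
               B[5, ], tolerance = 1e-8)

  # zero-variance time series is a singular design
  Sbad <- S; Sbad[2, ] <- 4
  expect_error(reactStage2(makeScan(Y2), SystemTimeSeries(Sbad, tr = 2),
                           mask), "singular design")
})

test_that("permuting template order permutes stage-1 rows and stage-2 maps", {
  set.seed(25)
  k <- 3; nT <- 12
  mask <- fullMask(dim3)
  M <- matrix(runif(nvox * k, 0.2, 1), nvox, k)
  tpl <- templatesFrom(M, dim3, names = c("A", "B", "C"))
  tplPerm <- templatesFrom(M[, c(3, 1, 2)], dim3, names = c("C", "A", "B"))
  Y <- matrix(rnorm(nvox * nT), nvox, nT)
  scan <- makeScan(Y)
  ts1 <- reactStage1(scan, tpl, mask)
  ts2 <- reactStage1(scan, tplPerm, mask)
  expect_equal(timeSeriesMatrix(ts2), timeSeriesMatrix(ts1)[c(3, 1, 2), ],
               tolerance = 1e-10)
  fc1 <- reactStage2(scan, ts1, mask)
  fc2 <- reactStage2(scan, ts2, mask)
  expect_equal(betaVolume(fc2, "B"), betaVolume(fc1, "B"),
               tolerance = 1e-10)
})
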