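# Region-mean extraction, confound regression, band-pass filtering.

test_that("region means average the labelled voxels", {
  dims <- c(4, 4, 4)
  labels <- array(0L, dims)
  labels[1, 1, 1] <- 1L; labels[2, 1, 1] <- 1L     # region A: 2 voxels
  labels[3:4, 2, 2] <- 2L                           # region B
  nT <- 6
  bold <- array(0, c(dims, nT))
  bold[1, 1, 1, ] <- 1; bold[2, 1, 1, ] <- 3
  set.seed(4); bold[3, 2, 2, ] <- rnorm(nT); bold[4, 2, 2, ] <- rnorm(nT)
  lm2 <- data.frame(id = c(1, 2), name = c("A", "B"))

  ts <- extractRegionMeans(bold, labels, lm2, tr = 2.16, subjectId = "s1")
  expect_equal(unname(tsMatrix(ts)[, "A"]), rep(2, nT))
  expect_equal(tsMatrix(ts)[, "B"],
               (bold[3, 2, 2, ] + bold[4, 2, 2, ]) / 2,
               ignore_attr = TRUE)

  # permutation of voxel values within a region leaves the mean unchanged
  bold2 <- bold
  bold2[1, 1, 1, ] <- bold[2, 1, 1, ]; bold2[2, 1, 1, ] <- bold[1, 1, 1, ]
  expect_equal(tsMatrix(extractRegionMeans(bold2, labels, lm2, tr = 2.16)),
               tsMatrix(ts))

  # errors: empty region, shape mismatch
  expect_error(extractRegionMeans(bold, labels,
                                  data.frame(id = 9, name = "ghost"),
                                  tr = 2.16), "ghost")
  expect_error(extractRegionMeans(bold, labels[1:3, , ], lm2, tr = 2.16),
               "dimensions")
})

test_that("extraction commutes with temporal subsetting", {
  dims <- c(3, 3, 3); nT <- 8
  set.seed(9)
  labels <- array(sample(0:2, prod(dims), replace = TRUE), dims)
  labels[1:2] <- 1:2  # both regions present
  bold <- array(rnorm(prod(dims) * nT), c(dims, nT))
  lm2 <- data.frame(id = 1:2, name = c("A", "B"))
  full <- extractRegionMeans(bold, labels, lm2, tr = 2)
  part <- extractRegionMeans(bold[, , , 1:5], labels, lm2, tr = 2)
  expect_equal(tsMatrix(full)[1:5, ], tsMatrix(part))
})

test_that("a 102-label volume yields a 102-region timeseries", {
  dims <- c(6, 6, 6)
  labels <- array(rep_len(1:102, prod(dims)), dims)
  nT <- 4
  set.seed(2)
  bold <- array(rnorm(prod(dims) * nT), c(dims, nT))
  lmap <- data.frame(id = 1:102, name = modifiedParcellation())
  ts <- extractRegionMeans(bold, labels, lmap, tr = 2.16)
  expect_equal(nRegions(ts), 102L)
  expect_equal(regionLabels(ts), modifiedParcellation())
})

test_that("NIfTI volumes round-trip through extraction", {
  dims <- c(4, 4, 4); nT <- 5
  set.seed(11)
  bold <- array(rnorm(prod(dims) * nT), c(dims, nT))
  labels <- array(rep_len(0:2, prod(dims)), dims)
  fb <- withr::local_tempfile(fileext = ".nii.gz")
  fl <- withr::local_tempfile(fileext = ".nii.gz")
  img <- RNifti::asNifti(bold)
  RNifti::pixdim(img) <- c(3, 3, 3, 2.16)
  RNifti::writeNifti(img, fb)
  RNifti::writeNifti(RNifti::asNifti(labels), fl)
  lm2 <- data.frame(id = 1:2, name = c("A", "B"))
  tsFile <- extractRegionMeans(fb, fl, lm2)
  tsMem <- extractRegionMeans(bold, labels, lm2, tr = 2.16)
  expect_equal(tsMatrix(tsFile), tsMatrix(tsMem), tolerance = 1e-6)
  expect_equal(repetitionTime(tsFile), 2.16, tolerance = 1e-6)
})

test_that("confound regression matches the normal-equations oracle", {
  set.seed(3)
  nT <- 30
  ts <- makeTimeseries(nT = nT, R = 4, seed = 3)
  C <- matrix(rnorm(nT * 3), nT, 3,
              dimnames = list(NULL, c("c1", "c2", "c3")))
  out <- regressConfounds(ts, C)

  X <- cbind(1, C)
  betaOracle <- solve(t(X) %*% X, t(X) %*% tsMatrix(ts))
  residOracle <- tsMatrix(ts) - X %*% betaOracle
  expect_equal(tsMatrix(out), residOracle, tolerance = 1e-8,
               ignore_attr = TRUE)

  # residuals orthogonal to every confound column
  expect_lt(max(abs(crossprod(C, tsMatrix(out)))), 1e-8)

  # idempotence
  out2 <- regressConfounds(out, C)
  expect_equal(tsMatrix(out2), tsMatrix(out), tolerance = 1e-10)
})

test_that("confound regression handles degenerate designs", {
  ts <- makeTimeseries(nT = 25, R = 3, seed = 5)
  C <- matrix(rnorm(50), 25, 2)
  # series exactly in the confound span -> zero residuals
  Y <- cbind(a = 2 * C[, 1] - C[, 2] + 3, b = C[, 2], c = C[, 1] + 1)
  tsLin <- regionTimeseries(Y, tr = 2)
  expect_lt(max(abs(tsMatrix(regressConfounds(tsLin, C)))),
            1e-8 * max(abs(Y)))
  # empty confounds -> demeaning
  dem <- regressConfounds(ts, NULL)
  expect_equal(tsMatrix(dem),
               scale(tsMatrix(ts), scale = FALSE), ignore_attr = TRUE)
  # duplicated column -> dropped with warning, result as with one copy
  expect_warning(outDup <- regressConfounds(ts, cbind(C, C[, 1])),
                 "dependent")
  expect_equal(tsMatrix(outDup), tsMatrix(regressConfounds(ts, C)),
               tolerance = 1e-10)
})

test_that("band-pass filter passes mid-band and rejects out-of-band", {
  tr <- 2.16; nT <- 295
  t <- (0:(nT - 1)) * tr
  amp <- function(y, x) sqrt(sum(y^2) / sum(x^2))
  for (m in c("butterworth", "fft")) {
    mid <- sin(2 * pi * 0.055 * t)
    hi <- sin(2 * pi * 0.20 * t)
    ts <- regionTimeseries(cbind(mid = mid, hi = hi, dc = rep(1, nT)), tr)
    out <- tsMatrix(bandpass(ts, 0.04, 0.07, method = m))
    expect_gte(amp(out[, "mid"], mid), 0.90)
    expect_lte(amp(out[, "hi"], hi), 0.10)
    expect_lt(max(abs(out[, "dc"])), 1e-6)
  }
})

test_that("band-pass filtering is linear and rejects invalid bands", {
  ts <- makeTimeseries(nT = 60, R = 2, tr = 2.16, seed = 7)
  x <- tsMatrix(ts)[, 1]; y <- tsMatrix(ts)[, 2]
  mix <- regionTimeseries(cbind(m = 3 * x - 2 * y, x = x, y = y), 2.16)
  out <- tsMatrix(bandpass(mix))
  expect_equal(out[, "m"], 3 * out[, "x"] - 2 * out[, "y"],
               tolerance = 1e-10)
  expect_equal(nrow(out), 60)
  expect_error(bandpass(ts, 0.04, 0.30), "Nyquist")
  expect_error(bandpass(ts, -0.01, 0.07), "Nyquist")
  expect_error(bandpass(ts, 0.07, 0.04), "Nyquist")
})

test_that("butterworth and fft filters agree on mid-band content", {
  tr <- 2.16; nT <- 295
  t <- (0:(nT - 1)) * tr
  x <- sin(2 * pi * 0.055 * t)
  ts <- regionTimeseries(cbind(a = x, b = x), tr)
  yb <- tsMatrix(bandpass(ts, method = "butterworth"))[, 1]
  yf <- tsMatrix(bandpass(ts, method = "fft"))[, 1]
  # both are near-identity mid-band; differences are edge/rolloff effects
  expect_lt(sqrt(sum((yb - yf)^2) / sum(yf^2)), 0.15)
})

test_that("timeseries round-trip through TSV + sidecar", {
  ts <- makeTimeseries(nT = 12, R = 3, tr = 2.16, seed = 13)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeRegionTimeseries(ts, f)
  back <- readRegionTimeseries(f)
  expect_equal(tsMatrix(back), tsMatrix(ts), tolerance = 1e-9)
  expect_equal(repetitionTime(back), 2.16)
  expect_equal(subjectId(back), "sub-test")
})
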