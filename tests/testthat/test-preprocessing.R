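test_that("absorbance transform follows log10(1/R) with informative errors", {
  expect_equal(toAbsorbance(1), 0)
  expect_equal(toAbsorbance(0.01), 2)
  expect_equal(toAbsorbance(c(1, 0.1, 0.01)), c(0, 1, 2))
  expect_error(toAbsorbance(c(0.5, -1)), "position 2")
  expect_error(toAbsorbance(c(a = 0.5, b = 0)), "\\bb\\b")
})

test_that("replicate averaging is the pointwise mean and validates grids", {
  s <- c(0.2, 0.4, 0.6)
  expect_equal(averageReplicates(list(s, s, s)), s)
  expect_equal(averageReplicates(list(c(0, 0), c(2, 2))), c(1, 1))
  expect_equal(averageReplicates(list(s)), s)
  expect_error(averageReplicates(list(c(1, 2), c(1, 2, 3))), "mismatched grids")

  d <- makeDataset(n = 3, seed = 1, replicates = 3)
  avg <- averageReplicates(d)
  expect_equal(ncol(avg), 3L)
  ids <- SummarizedExperiment::colData(d)$sample_id
  expect_equal(reflectance(avg)[, 1],
               rowMeans(reflectance(d)[, ids == sampleIds(d)[1]]))
})

test_that("normalization methods match their closed forms", {
  expect_equal(normalizeSpectrum(c(3, 4), "vector"), c(0.6, 0.8))
  expect_equal(normalizeSpectrum(c(2, 4, 6), "minmax"), c(0, 0.5, 1))
  expect_equal(normalizeSpectrum(c(5, 7, 6), "zero"), c(0, 2, 1))
  expect_error(normalizeSpectrum(c(0, 0), "vector"), "all-zero")
  expect_error(normalizeSpectrum(c(2, 2), "minmax"), "constant")
  # per-row on matrices; vector rows land on the unit sphere
  M <- matrix(rnorm(50), 5, 10)
  V <- normalizeSpectrum(M, "vector")
  expect_equal(sqrt(rowSums(V^2)), rep(1, 5), tolerance = 1e-12)
})

test_that("Savitzky-Golay second derivative is exact on polynomials", {
  expect_equal(as.numeric(savgolDerivative(rep(3, 20))), rep(0, 18))
  lin <- 2 * (1:20) + 5
  expect_equal(max(abs(savgolDerivative(lin))), 0)
  quad <- (1:15)^2
  out <- savgolDerivative(quad, window = 3, polyorder = 2, deriv = 2)
  expect_equal(as.numeric(out), rep(2, 13))
  expect_equal(attr(out, "margin"), 1L)
  expect_error(savgolDerivative(1:10, window = 4), "odd")
  expect_error(savgolDerivative(1:10, window = 3, polyorder = 3), "polyorder")
  expect_error(savgolDerivative(1:10, window = 3, polyorder = 2, deriv = 3),
               "deriv")
})

test_that("savgol(3,2,2) equals the central second difference everywhere", {
  set.seed(1)
  y <- cumsum(rnorm(60))
  got <- as.numeric(savgolDerivative(y, 3, 2, 2))
  oracle <- y[1:58] - 2 * y[2:59] + y[3:60]
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("Norris gap-segment derivative annihilates affine and is exact on i^2", {
  expect_equal(max(abs(norrisDerivative(rep(1.5, 30)))), 0)
  expect_equal(max(abs(norrisDerivative(3 * (1:30) - 7))), 0)
  for (cfg in list(c(5, 2), c(3, 1), c(7, 3), c(1, 2))) {
    out <- norrisDerivative((1:40)^2, segment = cfg[1], gap = cfg[2])
    expect_equal(as.numeric(out), rep(2, 40 - 2 * (cfg[2] + (cfg[1] - 1) / 2)),
                 tolerance = 1e-10)
    expect_equal(attr(out, "margin"), as.integer(cfg[2] + (cfg[1] - 1) %/% 2))
  }
  expect_error(norrisDerivative(1:5, segment = 5, gap = 2), "too short")
  expect_error(norrisDerivative(1:30, segment = 4), "odd")
})

test_that("preprocessing trims the wavelength axis consistently", {
  d <- makeDataset(n = 6, seed = 2)
  sg <- preprocessSpectra(d, preprocessConfig(normalization = "none",
                                              derivative = "savgol"))
  expect_equal(length(sg$wavelengths), 139L)
  expect_equal(ncol(sg$X), 139L)
  expect_equal(range(sg$wavelengths), c(955, 1645))
  no <- preprocessSpectra(d, preprocessConfig(normalization = "none",
                                              derivative = "norris",
                                              norrisSegment = 5, norrisGap = 2))
  expect_equal(length(no$wavelengths), 141L - 2L * 4L)
  expect_equal(nrow(no$X), 6L)
})

test_that("preprocessing is per-spectrum: permuting samples permutes outputs", {
  set.seed(4)
  M <- matrix(runif(8 * 141, 0.2, 0.9), 8, 141)
  wl <- spectralGrid()$axis
  cfg <- preprocessConfig(normalization = "vector", derivative = "norris")
  out <- preprocessSpectra(toAbsorbance(M), cfg, wavelengths = wl)
  perm <- c(5, 3, 8, 1, 2, 7, 6, 4)
  outP <- preprocessSpectra(toAbsorbance(M[perm, ]), cfg, wavelengths = wl)
  expect_equal(outP$X, out$X[perm, ], tolerance = 1e-14)
})
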