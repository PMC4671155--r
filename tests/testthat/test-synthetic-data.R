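test_that("composition sampling respects ranges, correlation sign and determinism", {
  comp <- sampleCompositions(500, seed = 7)
  for (cc in c("CP", "ADF", "NDF")) {
    p <- populationParams(cc)
    expect_true(all(comp[[cc]] >= p$min & comp[[cc]] <= p$max))
  }
  # correlation structure survives truncation, at least in sign
  expect_lt(cor(comp$CP, comp$ADF), -0.1)
  expect_gt(cor(comp$ADF, comp$NDF), 0.3)
  expect_identical(sampleCompositions(50, seed = 3),
                   sampleCompositions(50, seed = 3))
  expect_false(isTRUE(all.equal(sampleCompositions(50, seed = 3)$CP,
                                sampleCompositions(50, seed = 4)$CP)))
})

test_that("composition sampling edge cases and input validation", {
  empty <- sampleCompositions(0, seed = 1)
  expect_equal(nrow(empty), 0L)
  expect_named(empty, c("sample_id", "CP", "ADF", "NDF"))

  degenerate <- list(CP = populationParams("CP", min = 0, max = 20,
                                           mean = 10, sd = 1e-12))
  x <- sampleCompositions(25, params = degenerate, seed = 1,
                          correlation = matrix(1, 1, 1, dimnames = list("CP", "CP")))
  expect_true(all(abs(x$CP - 10) < 1e-9))

  expect_error(populationParams("CP", sd = 0), "sd must be positive")
  expect_error(populationParams("CP", min = 15, max = 10), "min must be <")
})

test_that("generator ensemble statistics match the configured populations", {
  nseed <- 50
  draws <- lapply(seq_len(nseed), function(s)
    sampleCompositions(203, seed = s)[, c("CP", "ADF", "NDF")])
  all <- do.call(rbind, draws)
  # analytic mean/SD of a normal truncated to [min, max] (univariate oracle;
  # the joint rejection perturbs margins only slightly)
  truncStats <- function(p) {
    a <- (p$min - p$mean) / p$sd; b <- (p$max - p$mean) / p$sd
    Z <- pnorm(b) - pnorm(a)
    m <- p$mean + p$sd * (dnorm(a) - dnorm(b)) / Z
    v <- p$sd^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z -
                     ((dnorm(a) - dnorm(b)) / Z)^2)
    c(mean = m, sd = sqrt(v))
  }
  for (cc in c("CP", "ADF", "NDF")) {
    p <- populationParams(cc)
    seedMeans <- vapply(draws, function(d) mean(d[[cc]]), numeric(1))
    mcse <- sd(seedMeans) / sqrt(nseed)
    expect_lt(abs(mean(all[[cc]]) - truncStats(p)[["mean"]]), 2 * mcse)
    # realized SD tracks the truncated-normal SD (strong shrinkage for ADF);
    # the joint rejection under the copula perturbs margins a little, so the
    # band is 10%
    expect_lt(abs(sd(all[[cc]]) / truncStats(p)[["sd"]] - 1), 0.10)
  }
  # truncation barely moves the CP and NDF means from the nominal ones
  expect_lt(abs(mean(all$CP) - 10.54), 0.1)
  expect_lt(abs(mean(all$NDF) - 60.89), 0.2)
})

test_that("pure component spectra have the expected band structure", {
  grid <- spectralGrid()
  E <- pureComponentSpectra(grid)
  expect_equal(dim(E), c(141L, 4L))
  expect_true(all(E >= 0))
  wl <- grid$axis
  expect_lt(abs(wl[which.max(E[, "CP"])] - 1100), 25)
  expect_lt(abs(wl[which.max(E[, "background"])] - 1450), 25)
  # non-negativity holds on an arbitrary grid too
  g2 <- spectralGrid(1000, 1600, 10)
  expect_true(all(pureComponentSpectra(g2) >= 0))
})

test_that("noiseless spectra are an exact invertible linear mixture", {
  d <- noiselessDataset(n = 12, seed = 5)
  grid <- spectralGrid()
  E <- pureComponentSpectra(grid)
  A <- toAbsorbance(t(reflectance(averageReplicates(d))))  # samples x wl
  # absorbance/reflectance round trip at machine precision
  expect_equal(10^(-A), t(reflectance(averageReplicates(d))), tolerance = 1e-12)
  # least squares on the known mixing matrix recovers all concentrations
  truth <- cbind(as.matrix(chemistry(d)[, c("CP", "ADF", "NDF")]),
                 background = S4Vectors::metadata(d)$mixing$background)
  chat <- t(qr.solve(E, t(A)))
  expect_lt(max(abs(chat - truth[, colnames(E)])), 1e-6)
})

test_that("baseline groups split per the configured fraction", {
  d <- makeDataset(n = 400, seed = 11,
                   noise = noiseParams(group2Fraction = 0.5))
  grp <- S4Vectors::metadata(d)$mixing$group
  expect_true(abs(mean(grp == 2) - 0.5) < 0.1)
  d1 <- makeDataset(n = 100, seed = 2, noise = noiseParams(group2Fraction = 0))
  expect_true(all(S4Vectors::metadata(d1)$mixing$group == 1))
})

test_that("full dataset generation is dimensioned, valid and reproducible", {
  d <- makeDataset(n = 203, seed = 1)
  expect_s4_class(d, "NIRSpectra")
  expect_equal(dim(reflectance(d)), c(141L, 609L))
  expect_equal(length(sampleIds(d)), 203L)
  R <- reflectance(d)
  expect_true(all(R > 0 & R <= 1))

  d2 <- makeDataset(n = 203, seed = 1)
  expect_identical(reflectance(d), reflectance(d2))
  expect_identical(chemistry(d), chemistry(d2))

  small <- makeDataset(n = 5, seed = 9, replicates = 2)
  expect_equal(dim(reflectance(small)), c(141L, 10L))
  expect_true(validObject(small))
})

test_that("synthesis rejects inconsistent inputs", {
  comp <- sampleCompositions(4, seed = 1)
  E <- pureComponentSpectra(spectralGrid())
  comp$CP[1] <- -1
  expect_error(synthesizeReflectance(comp, E, seed = 1), "non-negative")
  expect_error(noiseParams(additiveSd = -1), ">= 0")
  expect_error(noiseParams(group2Fraction = 1.5), "\\[0, 1\\]")
  comp2 <- sampleCompositions(4, seed = 1)
  expect_error(synthesizeReflectance(comp2, E[1:50, ], seed = 1), "grid")
})

test_that("smooth-artifact term adds seeded structured variation when enabled", {
  comp <- sampleCompositions(6, seed = 2)
  E <- pureComponentSpectra(spectralGrid())
  on <- synthesizeReflectance(comp, E, seed = 3,
                              noise = noiseParams(0, 0, 0, 0, smoothSd = 1e-3))
  off <- synthesizeReflectance(comp, E, seed = 3,
                               noise = noiseParams(0, 0, 0, 0, smoothSd = 0))
  expect_false(isTRUE(all.equal(reflectance(on), reflectance(off))))
  on2 <- synthesizeReflectance(comp, E, seed = 3,
                               noise = noiseParams(0, 0, 0, 0, smoothSd = 1e-3))
  expect_identical(reflectance(on), reflectance(on2))
})
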