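test_that("random split yields the documented sizes deterministically", {
  s <- splitCalVal(203, fraction = 0.749, seed = 1)
  expect_equal(length(s$calibration), 152L)
  expect_equal(length(s$validation), 51L)
  s75 <- splitCalVal(203, seed = 2)
  expect_equal(length(s75$calibration), 152L)
  expect_equal(sort(c(s75$calibration, s75$validation)), 1:203)
  expect_length(intersect(s75$calibration, s75$validation), 0)

  tiny <- splitCalVal(4, seed = 1)
  expect_equal(lengths(tiny[c("calibration", "validation")]),
               c(calibration = 3L, validation = 1L))
  expect_identical(splitCalVal(50, seed = 9), splitCalVal(50, seed = 9))
  expect_false(identical(splitCalVal(50, seed = 9)$calibration,
                         splitCalVal(50, seed = 10)$calibration))
  expect_error(splitCalVal(3), "at least 4")
  expect_error(splitCalVal(10, fraction = 1), "fraction")
})

test_that("RMSE matches its closed forms", {
  expect_equal(rmse(c(5, 5), c(5, 5)), 0)
  expect_equal(rmse(c(0, 0), c(1, -1)), 1)
  expect_equal(rmse(c(1, 2, 3), c(2, 1, 3)), sqrt(2 / 3))
  expect_error(rmse(numeric(0), numeric(0)), "empty")
  expect_equal(attr(rmse(1:3, 1:3, which = "RMSEP"), "label"), "RMSEP")
})

test_that("r-squared conventions agree where they must", {
  y <- c(1, 3, 2, 5, 4)
  expect_equal(rSquared(y, y), 1)
  expect_equal(rSquared(y, 2 * y + 3), 1)  # correlation is affine-invariant
  # for an in-sample least-squares fit, cor^2 equals 1 - SSE/SST
  set.seed(6)
  x <- rnorm(30); yy <- 2 * x + rnorm(30)
  fit <- lm(yy ~ x)
  expect_equal(rSquared(yy, fitted(fit)),
               rSquared(yy, fitted(fit), "decomposition"), tolerance = 1e-12)
  expect_error(rSquared(rep(1, 4), 1:4), "constant")
})

test_that("RPD bands follow the forage-NIRS thresholds with closed boundaries", {
  expect_equal(rpd(3.2, 1)$band, "good")
  expect_equal(rpd(1.5, 1)$band, "acceptable")
  expect_equal(rpd(0.9, 1)$band, "unreliable")
  expect_equal(rpd(2, 1)$band, "good")          # boundary -> good
  expect_equal(rpd(1.4, 1)$band, "acceptable")  # boundary -> acceptable
  expect_equal(rpd(1.25, 0.39)$value, 1.25 / 0.39)
  expect_error(rpd(0, 1), "positive")
  expect_error(rpd(1, 0), "positive")
})

test_that("leave-one-out matches the intercept-model closed form", {
  set.seed(14)
  y <- rnorm(12)
  X <- matrix(rnorm(12 * 4), 12, 4)
  cv <- looCrossValidate(X, y, "intercept")
  n <- length(y)
  closed <- n / (n - 1) * (y - mean(y))       # held-out residuals
  expect_equal(cv$predictions$y - cv$predictions$yhat, closed,
               tolerance = 1e-12)
  expect_identical(looCrossValidate(X, y, "intercept"), cv)  # deterministic

  cv3 <- looCrossValidate(X[1:3, ], y[1:3], "mlr", config = list(indices = 1L))
  expect_equal(nrow(cv3$predictions), 3L)
})

test_that("benchmark produces the 9+9-row grid with consistent metrics", {
  d <- makeDataset(n = 60, seed = 3)
  b <- runBenchmark(d, config = benchmarkConfig("fixed"), seed = 3)
  expect_s4_class(b, "BenchmarkReport")
  expect_equal(nrow(calibrationTable(b)), 9L)
  expect_equal(nrow(validationTable(b)), 9L)
  expect_setequal(unique(validationTable(b)$method), c("PLS", "PCR", "MLR"))
  v <- validationTable(b)
  expect_true(all(v$RMSEP > 0))
  expect_true(all(v$RPD > 0))
  expect_true(all(v$band %in% c("good", "acceptable", "unreliable")))
  # band labels consistent with the RPD values
  expect_identical(v$band, vapply(v$RPD, function(z) rpd(z, 1)$band, ""))
  # the split is shared across constituents and methods
  expect_equal(length(b@split$calibration), 45L)
  expect_equal(unique(v$n_val), 15L)
})

test_that("unbiased predictions tie RPD to r2 via 1/sqrt(1-r2)", {
  d <- makeDataset(n = 203, seed = 12)
  b <- runBenchmark(d, config = benchmarkConfig("fixed"), seed = 12)
  v <- validationTable(b)
  pls <- v[v$method == "PLS", ]
  expect_true(all(abs(pls$RPD * sqrt(1 - pls$r2) - 1) < 0.1))
})

test_that("calibration RMSE of latent-variable models never rises with k", {
  d <- makeDataset(n = 50, seed = 8)
  pp <- preprocessSpectra(d, preprocessConfig(normalization = "none"))
  y <- chemistry(d)$CP
  err <- vapply(1:10, function(k)
    rmse(y, predict(fitPLS(pp$X, y, k), pp$X)), numeric(1))
  expect_true(all(diff(err) <= 1e-10))
})
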