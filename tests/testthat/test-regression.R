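test_that("correlation spectrum follows the Pearson conventions", {
  set.seed(2)
  X <- matrix(rnorm(60), 20, 3)
  X[, 3] <- 1                      # zero-variance column
  y <- X[, 1]
  r <- correlationSpectrum(X, y)
  expect_equal(r[1], 1)
  expect_equal(r[3], 0)
  expect_equal(correlationSpectrum(X, -y), -r)
  expect_error(correlationSpectrum(X[1:2, ], y[1:2]), "at least 3")
})

test_that("greedy wavelength selection matches exhaustive pair search", {
  set.seed(12)
  n <- 30; p <- 20
  X <- matrix(rnorm(n * p), n, p)
  X <- X + 0.5 * rowMeans(X)       # induce mild collinearity
  y <- 2 * X[, 5] - X[, 12] + rnorm(n, 0, 0.05)
  greedy <- selectMlrWavelengths(X, y, 2)
  best <- selectMlrWavelengths(X, y, 2, exhaustive = TRUE)
  expect_setequal(greedy, best)
  expect_equal(greedy[1], 5L)
  expect_equal(selectMlrWavelengths(X, y, 1), 5L)
  expect_error(selectMlrWavelengths(X[1:3, ], y[1:3], 2), "too few samples")
})

test_that("MLR recovers an exact linear truth and detects collinearity", {
  set.seed(5)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- 2 * X[, 2] - X[, 4] + 1
  m <- fitMLR(X, y, c(2L, 4L))
  expect_equal(m@coefficients[c(2, 4)], c(2, -1), tolerance = 1e-10)
  yhat <- predict(m, X)
  expect_equal(yhat, y, tolerance = 1e-10)
  expect_error(fitMLR(X, y, c(2L, 2L)), "duplicates")
  Xd <- cbind(X, X[, 2])
  expect_error(fitMLR(Xd, y, c(2L, 7L)), "collinear")
  # residuals orthogonal to selected columns (normal equations)
  y2 <- y + rnorm(40)
  m2 <- fitMLR(X, y2, c(1L, 3L, 5L))
  res <- y2 - predict(m2, X)
  expect_lt(max(abs(crossprod(X[, c(1, 3, 5)], res) -
                      colSums(X[, c(1, 3, 5)]) * mean(res))), 1e-8)
  expect_lt(abs(sum(res)), 1e-8)
})

test_that("PCR at full rank reproduces least squares; components span coefficients", {
  inst <- randomInstance(12, 8, seed = 31, noiseSd = 0.3)
  m <- fitPCR(inst$X, inst$y, 8)
  expect_equal(predict(m, inst$X), olsOracle(inst$X, inst$y),
               tolerance = 1e-8)
  # rank-1 X with y in its column space: one component suffices
  set.seed(7)
  t1 <- rnorm(15); v <- rnorm(10)
  X1 <- outer(t1, v)
  y1 <- 3 * t1
  m1 <- fitPCR(X1, y1, 1)
  expect_equal(predict(m1, X1), y1, tolerance = 1e-8)
  # coefficients lie in the span of the retained loadings
  m3 <- fitPCR(inst$X, inst$y, 3)
  Rk <- m3@details$rotation
  proj <- Rk %*% crossprod(Rk, m3@coefficients)
  expect_equal(as.numeric(proj), m3@coefficients, tolerance = 1e-10)
  expect_error(fitPCR(inst$X, inst$y, 12), "nComponents")
})

test_that("NIPALS PLS matches least squares at full rank and keeps scores orthogonal", {
  inst <- randomInstance(12, 8, seed = 13, noiseSd = 0.3)
  m <- fitPLS(inst$X, inst$y, 8)
  expect_equal(predict(m, inst$X), olsOracle(inst$X, inst$y),
               tolerance = 1e-8)
  # all columns proportional to y: one component gives a perfect fit
  set.seed(19)
  y1 <- rnorm(20)
  X1 <- outer(y1, runif(30, 0.5, 2))
  m1 <- fitPLS(X1, y1, 1)
  expect_lt(max(abs(predict(m1, X1) - y1)), 1e-10)
  # score orthogonality on a 20 x 50 random matrix
  inst2 <- randomInstance(20, 50, seed = 23, noiseSd = 1)
  m2 <- fitPLS(inst2$X, inst2$y, 8)
  G <- crossprod(m2@details$scores)
  offdiag <- G - diag(diag(G))
  expect_lt(max(abs(offdiag)) / max(diag(G)), 1e-8)
  expect_error(fitPLS(inst$X, rep(1, 12), 2), "zero variance")
})

test_that("PLS calibration error is monotone in k and never worse than PCR", {
  for (s in 1:5) {
    inst <- randomInstance(25, 40, seed = 200 + s, noiseSd = 0.5)
    rms <- function(m) rmse(inst$y, predict(m, inst$X))
    plsErr <- vapply(1:6, function(k) rms(fitPLS(inst$X, inst$y, k)), numeric(1))
    pcrErr <- vapply(1:6, function(k) rms(fitPCR(inst$X, inst$y, k)), numeric(1))
    expect_true(all(diff(plsErr) <= 1e-10))
    expect_true(all(plsErr <= pcrErr + 1e-10))
  }
})

test_that("LOO component selection recovers a planted 3-factor structure", {
  set.seed(41)
  n <- 40; p <- 30
  Tm <- matrix(rnorm(n * 3), n, 3)
  X <- Tm %*% matrix(rnorm(3 * p), 3, p) + matrix(rnorm(n * p, 0, 1e-4), n, p)
  y <- Tm %*% c(1, -2, 0.5) + rnorm(n, 0, 1e-4)
  expect_equal(as.integer(selectNComponents(X, y, "pls", maxPc = 10)), 3L)
  expect_equal(as.integer(selectNComponents(X, y, "pcr", maxPc = 10)), 3L)
  expect_equal(as.integer(selectNComponents(X, y, "pls", maxPc = 1)), 1L)
})

test_that("pure-noise responses select one component in most seeds", {
  picks <- vapply(1:10, function(s) {
    set.seed(300 + s)
    X <- matrix(rnorm(30 * 25), 30, 25)
    y <- rnorm(30)
    as.integer(selectNComponents(X, y, "pls", maxPc = 8))
  }, integer(1))
  expect_gte(sum(picks == 1L), 7L)
})

test_that("fits are invariant to sample order", {
  inst <- randomInstance(20, 15, seed = 77, noiseSd = 0.4)
  perm <- sample(20)
  for (fit in list(function(X, y) fitPLS(X, y, 4),
                   function(X, y) fitPCR(X, y, 4),
                   function(X, y) fitMLR(X, y, c(3L, 9L)))) {
    m1 <- fit(inst$X, inst$y)
    m2 <- fit(inst$X[perm, ], inst$y[perm])
    expect_equal(m2@coefficients, m1@coefficients, tolerance = 1e-8)
    expect_equal(m2@yCenter, m1@yCenter, tolerance = 1e-12)
  }
})

test_that("prediction is linear in the spectrum and survives JSON round trips", {
  inst <- randomInstance(18, 10, seed = 55, noiseSd = 0.2)
  m <- fitPLS(inst$X, inst$y, 4)
  base <- predict(m, inst$X)
  shifted <- inst$X
  shifted[3, 7] <- shifted[3, 7] + 0.25
  expect_equal(predict(m, shifted)[3] - base[3],
               m@coefficients[7] * 0.25, tolerance = 1e-10)
  expect_equal(predict(m, shifted)[-3], base[-3])

  path <- tempfile(fileext = ".json")
  writeModelJSON(m, path)
  m2 <- readModelJSON(path)
  expect_identical(predict(m2, inst$X), base)  # bit-identical
  expect_error(predict(m, inst$X[, 1:5]), "grid mismatch")
})
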