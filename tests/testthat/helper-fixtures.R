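# Shared fixture builders. Everything is generated in code at test time;
# no binary fixtures are stored.

# Small noiseless dataset: exact linear mixture, no baseline.
noiselessDataset <- function(n = 10, seed = 42) {
  makeDataset(n = n, seed = seed,
              noise = noiseParams(0, 0, 0, 0, 0, group2Fraction = 0.5),
              baseline = FALSE)
}

# Random regression instance with controllable rank.
randomInstance <- function(n, p, rank = min(n, p), seed = 1, noiseSd = 0) {
  set.seed(seed)
  X <- matrix(rnorm(n * rank), n, rank) %*% matrix(rnorm(rank * p), rank, p)
  beta <- rnorm(p)
  y <- as.numeric(X %*% beta) + rnorm(n, 0, noiseSd)
  list(X = X, y = y, beta = beta)
}

# Minimum-norm least-squares predictions (independent oracle via SVD
# pseudoinverse on the centered problem).
olsOracle <- function(X, y, Xnew = X) {
  xc <- colMeans(X)
  Xc <- sweep(X, 2, xc)
  s <- svd(Xc)
  keep <- s$d > 1e-10 * s$d[1]
  b <- s$v[, keep, drop = FALSE] %*%
    ((crossprod(s$u[, keep, drop = FALSE], y - mean(y))) / s$d[keep])
  as.numeric(mean(y) + sweep(Xnew, 2, xc) %*% b)
}

# Tiny JCAMP-DX file covering the default grid, written to a temp path.
writeJcampFixture <- function(path, wl = seq(950, 1650, by = 5),
                              y = NULL, perLine = 6) {
  if (is.null(y)) y <- round(0.5 + 0.3 * sin(wl / 100), 6)
  con <- file(path, "w")
  writeLines(c("##TITLE=synthetic hay scan",
               "##JCAMP-DX=4.24",
               "##DATA TYPE=INFRARED SPECTRUM",
               "##XUNITS=NANOMETERS",
               "##YUNITS=REFLECTANCE",
               "##XFACTOR=1", "##YFACTOR=1",
               paste0("##FIRSTX=", wl[1]), paste0("##LASTX=", wl[length(wl)]),
               paste0("##NPOINTS=", length(wl)),
               "##XYDATA=(X++(Y..Y))"), con)
  i <- 1
  while (i <= length(wl)) {
    j <- min(i + perLine - 1, length(wl))
    writeLines(paste(c(wl[i], y[i:j]), collapse = " "), con)
    i <- j + 1
  }
  writeLines("##END=", con)
  close(con)
  invisible(y)
}
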