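## The three calibration engines. MLR works on a handful of selected
## wavelengths found through the correlation spectrum; PCR and PLS are
## full-spectrum latent-variable regressions. PLS is PLS1 by the classical
## NIPALS algorithm, written out here because it is the core of the
## package; PCR leans on stats::prcomp. X columns and y are mean-centered,
## never autoscaled (standard NIR practice).

#' Correlation spectrum
#'
#' Pearson correlation of every wavelength column of `X` with the
#' response. Zero-variance columns map to 0 by convention.
#'
#' @param X samples x wavelengths matrix.
#' @param y response vector.
#' @return numeric vector, one correlation per wavelength.
#' @export
correlationSpectrum <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) < 3) stop("need at least 3 samples")
  r <- suppressWarnings(as.numeric(cor(X, y)))
  r[!is.finite(r)] <- 0
  r
}

#' Select MLR wavelengths from the correlation spectrum
#'
#' The first wavelength maximizes the absolute correlation with `y`;
#' subsequent wavelengths are added greedily, each maximizing the
#' calibration R^2 of the joint ordinary-least-squares fit. Ties break
#' toward the shorter wavelength. An exhaustive search over all pairs is
#' available as a verification mode when `nWavelengths = 2`.
#'
#' @param X samples x wavelengths matrix.
#' @param y response vector.
#' @param nWavelengths how many wavelengths to select (default 2).
#' @param exhaustive if TRUE (and `nWavelengths == 2`), evaluate every pair
#'   instead of the greedy path.
#' @return integer column indices into `X`, in selection order.
#' @export
selectMlrWavelengths <- function(X, y, nWavelengths = 2, exhaustive = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (nWavelengths < 1) stop("nWavelengths must be >= 1")
  if (n <= nWavelengths + 1)
    stop("too few samples (", n, ") for ", nWavelengths, " wavelengths")
  if (exhaustive && nWavelengths == 2) return(.bestPairExhaustive(X, y))
  r <- correlationSpectrum(X, y)
  sel <- which.max(abs(r))  # ties resolve to the lowest index
  while (length(sel) < nWavelengths) {
    gain <- .partialR2(X, y, sel)
    gain[sel] <- -Inf
    if (all(!is.finite(gain))) stop("no informative wavelength left to add")
    sel <- c(sel, which.max(gain))
  }
  as.integer(sel)
}

## Squared partial correlation of each column with y given the columns in
## `sel` (plus intercept): the R^2 gain direction, vectorized over columns.
.partialR2 <- function(X, y, sel) {
  Q <- qr(cbind(1, X[, sel, drop = FALSE]))
  yr <- qr.resid(Q, y)
  Xr <- qr.resid(Q, X)
  num <- as.numeric(crossprod(Xr, yr))
  den <- sqrt(colSums(Xr^2) * sum(yr^2))
  out <- ifelse(den > 1e-12 * max(1, sum(yr^2)), (num / den)^2, -Inf)
  out
}

.bestPairExhaustive <- function(X, y) {
  p <- ncol(X)
  best <- c(NA_integer_, NA_integer_); bestR2 <- -Inf
  sst <- sum((y - mean(y))^2)
  for (i in seq_len(p - 1)) {
    Q <- qr(cbind(1, X[, i]))
    yr <- qr.resid(Q, y)
    Xr <- qr.resid(Q, X[, (i + 1):p, drop = FALSE])
    num <- as.numeric(crossprod(Xr, yr))
    den <- colSums(Xr^2)
    sse1 <- sum(yr^2)
    sse2 <- ifelse(den > 1e-12, sse1 - num^2 / den, sse1)
    r2 <- 1 - sse2 / sst
    j <- which.max(r2)
    if (r2[j] > bestR2 + 1e-12) {
      bestR2 <- r2[j]; best <- c(i, i + j)
    }
  }
  as.integer(best)
}

.modelAxis <- function(X, wavelengths) {
  if (!is.null(wavelengths)) return(as.numeric(wavelengths))
  wl <- suppressWarnings(as.numeric(colnames(X)))
  if (length(wl) == ncol(X) && !anyNA(wl)) wl else seq_len(ncol(X))
}

#' Fit a multiple linear regression on selected wavelengths
#'
#' Ordinary least squares of `y` on the selected spectral columns plus an
#' intercept, stored in centered form so prediction shares one code path
#' with the latent-variable models.
#'
#' @param X samples x wavelengths (preprocessed) matrix.
#' @param y response vector.
#' @param indices integer columns selected (e.g. from
#'   [selectMlrWavelengths()]); must be duplicate-free and linearly
#'   independent.
#' @param wavelengths wavelength axis of `X` (defaults to numeric column
#'   names).
#' @param config the [PreprocessConfig-class] snapshot to store.
#' @param constituent label to store.
#' @return A [CalibrationModel-class].
#' @export
fitMLR <- function(X, y, indices, wavelengths = NULL,
                   config = preprocessConfig(), constituent = "") {
  X <- as.matrix(X)
  indices <- as.integer(indices)
  if (anyDuplicated(indices)) stop("selected wavelengths contain duplicates")
  if (nrow(X) < length(indices) + 1)
    stop("too few samples for ", length(indices), " wavelengths")
  Xs <- X[, indices, drop = FALSE]
  if (qr(cbind(1, Xs))$rank < ncol(Xs) + 1L)
    stop("selected wavelength columns are collinear")
  xc <- colMeans(X)
  yc <- mean(y)
  Xsc <- sweep(Xs, 2, xc[indices])
  b_sel <- qr.solve(Xsc, y - yc)
  b <- numeric(ncol(X)); b[indices] <- b_sel
  new("CalibrationModel", method = "MLR", constituent = constituent,
      preprocess = config, wavelengths = .modelAxis(X, wavelengths),
      xCenter = xc, yCenter = yc, coefficients = b, ncomp = 0L,
      selected = indices, details = list())
}

#' Fit a principal component regression
#'
#' Regresses the centered response on the top `nComponents` principal-
#' component scores of the centered spectra and folds the result back to a
#' coefficient vector on the wavelength axis.
#'
#' @inheritParams fitMLR
#' @param nComponents number of components, `1 <= k <= min(n - 1, p)`.
#' @return A [CalibrationModel-class]; `details` holds the loadings, the
#'   per-component response weights and the cumulative coefficient path
#'   `Bmat` (column k = coefficients of the k-component model).
#' @export
fitPCR <- function(X, y, nComponents, wavelengths = NULL,
                   config = preprocessConfig(), constituent = "") {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  k <- as.integer(nComponents)
  if (k < 1 || k > min(n - 1, p))
    stop("nComponents must lie in [1, min(n-1, p)] = [1, ", min(n - 1, p), "]")
  pr <- prcomp(X, center = TRUE, scale. = FALSE, rank. = k)
  Tm <- pr$x[, seq_len(k), drop = FALSE]
  yc <- y - mean(y)
  ss <- colSums(Tm^2)
  keep <- ss > 1e-12 * max(ss)
  gamma <- as.numeric(crossprod(Tm, yc)) / ifelse(keep, ss, Inf)
  Bmat <- apply(sweep(pr$rotation[, seq_len(k), drop = FALSE], 2, gamma, `*`),
                1, cumsum)
  Bmat <- if (k == 1L) matrix(Bmat, ncol = 1L) else t(Bmat)
  new("CalibrationModel", method = "PCR", constituent = constituent,
      preprocess = config, wavelengths = .modelAxis(X, wavelengths),
      xCenter = colMeans(X), yCenter = mean(y),
      coefficients = Bmat[, k], ncomp = k, selected = integer(0),
      details = list(rotation = pr$rotation[, seq_len(k), drop = FALSE],
                     gamma = gamma, scoreSS = ss, Bmat = Bmat))
}

## NIPALS PLS1 core. Returns weights W, loadings P, response weights q,
## scores T, and the cumulative coefficient path Bmat (p x k). If the data
## rank is exhausted before k components, stops with an error when
## strict = TRUE, otherwise pads the path with the last valid column.
.nipals <- function(X, y, k, tol = 1e-10, maxIter = 500, strict = TRUE) {
  n <- nrow(X); p <- ncol(X)
  if (sd(y) == 0) stop("response has zero variance")
  Xd <- sweep(X, 2, colMeans(X))
  yd <- y - mean(y)
  W <- P <- matrix(0, p, k); Tm <- matrix(0, n, k); q <- numeric(k)
  R <- matrix(0, p, k); Bmat <- matrix(0, p, k)
  baseNw <- NA_real_  # ||X'y|| at the first component sets the scale
  a <- 0L
  for (comp in seq_len(k)) {
    u <- yd
    w <- numeric(p); converged <- FALSE; collapsed <- FALSE
    for (it in seq_len(maxIter)) {
      wn <- as.numeric(crossprod(Xd, u))
      nw <- sqrt(sum(wn^2))
      if (is.na(baseNw)) baseNw <- nw + .Machine$double.xmin
      if (nw < 1e-12 * baseNw) { collapsed <- TRUE; break }
      wn <- wn / nw
      if (it > 1L && sqrt(sum((wn - w)^2)) < tol) {
        w <- wn; converged <- TRUE; break
      }
      w <- wn
      u <- yd  # PLS1: the single-column response block never changes
    }
    if (collapsed) {
      if (strict) stop("NIPALS component ", comp,
                       " collapsed: requested components exceed the rank ",
                       "of X (or y is already fully fitted)")
      break
    }
    if (!converged) {
      if (strict) stop("NIPALS component ", comp, " did not converge in ",
                       maxIter, " iterations")
      break
    }
    tt <- as.numeric(Xd %*% w)
    tsq <- sum(tt^2)
    if (tsq == 0) {
      if (strict) stop("NIPALS component ", comp,
                       " collapsed: zero score vector")
      break
    }
    pv <- as.numeric(crossprod(Xd, tt)) / tsq
    qv <- sum(yd * tt) / tsq
    Xd <- Xd - tcrossprod(tt, pv)
    yd <- yd - qv * tt
    a <- comp
    W[, a] <- w; P[, a] <- pv; q[a] <- qv; Tm[, a] <- tt
    r <- w
    if (a > 1L)
      r <- r - R[, seq_len(a - 1L), drop = FALSE] %*%
        crossprod(P[, seq_len(a - 1L), drop = FALSE], w)
    R[, a] <- r
    Bmat[, a] <- (if (a > 1L) Bmat[, a - 1L] else 0) + r * qv
  }
  if (a == 0L) stop("no PLS component could be extracted")
  if (a < k) for (j in (a + 1L):k) Bmat[, j] <- Bmat[, a]
  list(W = W[, seq_len(a), drop = FALSE], P = P[, seq_len(a), drop = FALSE],
       q = q[seq_len(a)], scores = Tm[, seq_len(a), drop = FALSE],
       Bmat = Bmat, ncomp = a)
}

#' Fit a partial least squares regression (NIPALS PLS1)
#'
#' Classical NIPALS: per component, the weight vector is proportional to
#' \eqn{X^\top y} (iterated to convergence), scores are \eqn{t = Xw},
#' loadings \eqn{p = X^\top t / t^\top t} and response weight
#' \eqn{q = y^\top t / t^\top t}; X and y are then deflated and the next
#' component extracted. Score vectors are mutually orthogonal. The
#' regression vector is assembled as \eqn{b = W (P^\top W)^{-1} q}.
#'
#' @inheritParams fitPCR
#' @param tol relative weight-change convergence tolerance (default 1e-10).
#' @param maxIter iteration cap per component (default 500); exceeding it
#'   is an error.
#' @return A [CalibrationModel-class]; `details` holds `W`, `P`, `q`, the
#'   score matrix and the cumulative coefficient path `Bmat`.
#' @export
fitPLS <- function(X, y, nComponents, wavelengths = NULL,
                   config = preprocessConfig(), constituent = "",
                   tol = 1e-10, maxIter = 500) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  k <- as.integer(nComponents)
  if (k < 1 || k > min(n - 1, p))
    stop("nComponents must lie in [1, min(n-1, p)] = [1, ", min(n - 1, p), "]")
  fit <- .nipals(X, y, k, tol = tol, maxIter = maxIter, strict = TRUE)
  new("CalibrationModel", method = "PLS", constituent = constituent,
      preprocess = config, wavelengths = .modelAxis(X, wavelengths),
      xCenter = colMeans(X), yCenter = mean(y),
      coefficients = fit$Bmat[, k], ncomp = k, selected = integer(0),
      details = fit[c("W", "P", "q", "scores", "Bmat")])
}

setMethod("show", "CalibrationModel", function(object) {
  cat("CalibrationModel [", object@method, "]",
      if (nzchar(object@constituent)) paste0(" for ", object@constituent),
      ": ", length(object@wavelengths), " wavelengths", sep = "")
  if (object@method == "MLR")
    cat("; selected ", paste(round(object@wavelengths[object@selected]),
                             collapse = ", "), " nm", sep = "")
  else cat("; ", object@ncomp, " components", sep = "")
  cat("\n  preprocessing: ", object@preprocess@normalization, " + ",
      object@preprocess@derivative, " 2nd derivative\n", sep = "")
})

#' Predict new spectra with a calibration model
#'
#' A pure function of the stored model fields:
#' \eqn{\hat y = \bar y + (x - \bar x)^\top b} on the model's trimmed,
#' preprocessed wavelength axis. An [NIRSpectra-class] input is passed
#' through the model's own preprocessing first; a matrix input must
#' already be preprocessed onto the model's axis.
#'
#' @param object a [CalibrationModel-class].
#' @param newdata an [NIRSpectra-class] of raw reflectance scans, or a
#'   preprocessed samples x wavelengths matrix on the model's trimmed axis.
#' @param ... ignored.
#' @return numeric vector of predictions, one per sample.
#' @export
setMethod("predict", "CalibrationModel", function(object, newdata, ...) {
  if (is(newdata, "NIRSpectra")) {
    pp <- preprocessSpectra(newdata, object@preprocess)
    if (length(pp$wavelengths) != length(object@wavelengths) ||
        max(abs(pp$wavelengths - object@wavelengths)) > 1e-8)
      stop("spectral grid mismatch: new spectra preprocess onto a ",
           "different wavelength axis than the model's")
    X <- pp$X
  } else {
    X <- as.matrix(newdata)
    if (ncol(X) == 1L && length(object@wavelengths) > 1L &&
        nrow(X) == length(object@wavelengths)) X <- t(X)
    if (ncol(X) != length(object@wavelengths))
      stop("grid mismatch: model expects ", length(object@wavelengths),
           " preprocessed columns, got ", ncol(X))
  }
  as.numeric(object@yCenter +
               (X %*% object@coefficients) -
               sum(object@xCenter * object@coefficients))
})

#' Choose the component count by leave-one-out cross-validation
#'
#' Fits 1..`maxPc` components, computes the leave-one-out RMSE for each
#' count, and returns the count minimizing it; ties break toward fewer
#' components. Each fold refits the full path once, so the cost is n model
#' fits, not n x maxPc.
#'
#' @param X samples x wavelengths matrix.
#' @param y response vector.
#' @param method `"pls"` or `"pcr"`.
#' @param maxPc largest count considered (default 15), capped at
#'   `min(n - 2, p)`.
#' @return integer component count, with attribute `rmsecv`: the LOO RMSE
#'   for each count 1..maxPc.
#' @export
selectNComponents <- function(X, y, method = c("pls", "pcr"), maxPc = 15) {
  method <- match.arg(method)
  X <- as.matrix(X)
  n <- nrow(X)
  maxPc <- min(as.integer(maxPc), n - 2L, ncol(X))
  if (maxPc < 1) stop("too few samples/wavelengths for component selection")
  res <- matrix(NA_real_, n, maxPc)
  for (i in seq_len(n)) {
    Xt <- X[-i, , drop = FALSE]; yt <- y[-i]
    Bmat <- if (method == "pls")
      .nipals(Xt, yt, maxPc, strict = FALSE)$Bmat
    else .pcrPath(Xt, yt, maxPc)
    xc <- X[i, ] - colMeans(Xt)
    res[i, ] <- (mean(yt) + as.numeric(xc %*% Bmat)) - y[i]
  }
  rmsecv <- sqrt(colMeans(res^2))
  k <- which.min(rmsecv)  # first minimum = fewest components on ties
  structure(as.integer(k), rmsecv = rmsecv)
}

.pcrPath <- function(X, y, k) {
  pr <- prcomp(X, center = TRUE, scale. = FALSE, rank. = k)
  Tm <- pr$x[, seq_len(k), drop = FALSE]
  ss <- colSums(Tm^2)
  keep <- ss > 1e-12 * max(ss)
  gamma <- as.numeric(crossprod(Tm, y - mean(y))) / ifelse(keep, ss, Inf)
  B <- sweep(pr$rotation[, seq_len(k), drop = FALSE], 2, gamma, `*`)
  Bm <- apply(B, 1, cumsum)
  if (k == 1L) matrix(Bm, ncol = 1L) else t(Bm)
}
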