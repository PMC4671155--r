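## Splitting, the error metrics and leave-one-out cross-validation.
## Conventions: calibration R^2 and validation r^2 are both squared Pearson
## correlations between reference and predicted values (identical to
## 1 - SSE/SST for in-sample least-squares fits); RPD is the validation-set
## reference SD divided by RMSEP.

#' Random calibration/validation split
#'
#' Uniform random partition without replacement; the calibration set gets
#' `round(fraction * n)` samples. Deterministic given the seed. Defaults
#' reproduce the conventional 75/25 split (203 samples -> 152/51).
#'
#' @param n total number of samples (>= 4).
#' @param fraction calibration fraction in (0, 1); default 0.75.
#' @param seed integer seed.
#' @return list with integer index vectors `calibration` and `validation`
#'   (disjoint, exhaustive, both sorted), plus `fraction` and `seed`.
#' @examples
#' s <- splitCalVal(203, seed = 1)
#' c(length(s$calibration), length(s$validation))  # 152 51
#' @export
splitCalVal <- function(n, fraction = 0.75, seed = NULL) {
  if (n < 4) stop("need at least 4 samples to split")
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  nc <- round(fraction * n)
  if (nc < 1 || nc > n - 1)
    stop("degenerate split: calibration size ", nc, " of ", n)
  if (!is.null(seed)) set.seed(seed)
  cal <- sort(sample.int(n, nc))
  list(calibration = cal, validation = setdiff(seq_len(n), cal),
       fraction = fraction, seed = seed)
}

#' Root mean squared error
#'
#' \eqn{\mathrm{RMSE} = \sqrt{\frac{1}{n}\sum_i (\hat y_i - y_i)^2}};
#' called RMSEC when the pairs come from the calibration set and RMSEP
#' when they come from the validation (prediction) set.
#'
#' @param y reference values.
#' @param yhat predicted values, same length.
#' @param which optional label, `"RMSEC"` or `"RMSEP"` (attached as the
#'   `label` attribute).
#' @return non-negative scalar.
#' @examples
#' rmse(c(0, 0), c(1, -1))  # 1
#' @export
rmse <- function(y, yhat, which = NULL) {
  if (length(y) == 0) stop("empty input")
  if (length(y) != length(yhat)) stop("y and yhat lengths differ")
  out <- sqrt(mean((yhat - y)^2))
  if (!is.null(which)) attr(out, "label") <- match.arg(which, c("RMSEC", "RMSEP"))
  out
}

#' Coefficient of determination
#'
#' By default the squared Pearson correlation between reference and
#' predicted values -- the convention matching measured-vs-predicted
#' scatter plots, and identical to `1 - SSE/SST` for in-sample
#' least-squares fits. `method = "decomposition"` gives `1 - SSE/SST`
#' directly (which can be negative out of sample).
#'
#' @param y reference values (non-constant).
#' @param yhat predicted values.
#' @param method `"correlation"` (default) or `"decomposition"`.
#' @return scalar.
#' @export
rSquared <- function(y, yhat, method = c("correlation", "decomposition")) {
  method <- match.arg(method)
  if (length(y) != length(yhat)) stop("y and yhat lengths differ")
  if (sd(y) == 0) stop("reference values are constant")
  if (method == "correlation") {
    if (sd(yhat) == 0) stop("predictions are constant")
    cor(y, yhat)^2
  } else {
    1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  }
}

#' RPD and its quality band
#'
#' RPD is the ratio of the validation set's reference-value standard
#' deviation to RMSEP. Banding follows forage-NIRS convention: good for
#' RPD >= 2, acceptable for 1.4 <= RPD < 2, unreliable below 1.4 (the
#' boundaries are assigned to the better band).
#'
#' @param sdValidation SD of the validation reference values (> 0).
#' @param rmsep root mean squared error of prediction (> 0).
#' @return list with `value` and `band`.
#' @examples
#' rpd(1.25, 0.39)$band  # "good"
#' @export
rpd <- function(sdValidation, rmsep) {
  if (!is.finite(sdValidation) || sdValidation <= 0)
    stop("sdValidation must be positive")
  if (!is.finite(rmsep) || rmsep <= 0) stop("rmsep must be positive")
  v <- sdValidation / rmsep
  band <- if (v >= 2) "good" else if (v >= 1.4) "acceptable" else "unreliable"
  list(value = v, band = band)
}

#' Leave-one-out cross-validation of a calibration method
#'
#' Refits the model n times, each time predicting the held-out sample, and
#' aggregates the held-out residuals into a single cross-validated RMSE.
#'
#' @param X samples x wavelengths matrix.
#' @param y response vector.
#' @param method `"pls"`, `"pcr"`, `"mlr"` or `"intercept"` (the null
#'   model predicting the training mean).
#' @param config list of method settings: `ncomp` for pls/pcr, `indices`
#'   (fixed wavelength columns) for mlr.
#' @return list with `predictions` (data.frame fold/y/yhat) and `rmsecv`.
#' @export
looCrossValidate <- function(X, y, method = c("pls", "pcr", "mlr", "intercept"),
                             config = list()) {
  method <- match.arg(method)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 samples for leave-one-out")
  yhat <- numeric(n)
  for (i in seq_len(n)) {
    Xt <- X[-i, , drop = FALSE]; yt <- y[-i]
    yhat[i] <- tryCatch({
      switch(method,
        intercept = mean(yt),
        pls = predict(fitPLS(Xt, yt, config$ncomp), X[i, , drop = FALSE]),
        pcr = predict(fitPCR(Xt, yt, config$ncomp), X[i, , drop = FALSE]),
        mlr = predict(fitMLR(Xt, yt, config$indices), X[i, , drop = FALSE]))
    }, error = function(e)
      stop("leave-one-out fold ", i, " failed: ", conditionMessage(e),
           call. = FALSE))
  }
  list(predictions = data.frame(fold = seq_len(n), y = y, yhat = yhat),
       rmsecv = rmse(y, yhat))
}

#' Assemble calibration and validation metrics for one model
#'
#' @param model a [CalibrationModel-class].
#' @param Xcal,ycal preprocessed calibration matrix and reference values.
#' @param Xval,yval preprocessed validation matrix and reference values.
#' @return A [MetricsReport-class].
#' @export
metricsReport <- function(model, Xcal, ycal, Xval, yval) {
  yhat_c <- predict(model, Xcal)
  yhat_v <- predict(model, Xval)
  sdv <- sd(yval)
  rmsep <- rmse(yval, yhat_v)
  band <- rpd(sdv, rmsep)
  new("MetricsReport",
      method = model@method, constituent = model@constituent,
      nC = as.integer(length(ycal)), nP = as.integer(length(yval)),
      rmsec = rmse(ycal, yhat_c), rmsep = rmsep,
      r2Cal = rSquared(ycal, yhat_c),
      r2Val = rSquared(yval, yhat_v),
      r2ValDecomp = rSquared(yval, yhat_v, "decomposition"),
      sdVal = sdv, rpd = band$value, band = band$band,
      calPairs = data.frame(y = ycal, yhat = yhat_c),
      valPairs = data.frame(y = yval, yhat = yhat_v))
}

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf(
    "MetricsReport [%s%s]: nC=%d R2=%.3f RMSEC=%.3f | nP=%d r2=%.3f RMSEP=%.3f RPD=%.2f (%s)\n",
    object@method,
    if (nzchar(object@constituent)) paste0(", ", object@constituent) else "",
    object@nC, object@r2Cal, object@rmsec,
    object@nP, object@r2Val, object@rmsep, object@rpd, object@band))
})
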