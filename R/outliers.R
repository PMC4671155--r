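## Mahalanobis outlier screening in principal-component score space.
## Calibration outliers are flagged where the Mahalanobis distance of a
## sample's PC scores exceeds the mean distance by 3 SD (of the distance
## distribution); flagging uses spectra only, never the chemistry.

#' Principal-component scores of a spectra matrix
#'
#' Column-mean-centers `X` and projects onto its top `k` principal
#' directions (maximum-variance orthogonal directions), scores ordered by
#' decreasing variance.
#'
#' @param X numeric matrix, samples x wavelengths (preprocessed).
#' @param k number of score dimensions, `1 <= k <= min(n - 1, p)`.
#' @return n x k score matrix.
#' @examples
#' pcaScores(matrix(rnorm(40), 10, 4), k = 2)
#' @export
pcaScores <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 2) stop("need at least 2 samples")
  if (k < 1 || k > min(n - 1, p))
    stop("k must lie in [1, min(n-1, p)] = [1, ", min(n - 1, p), "]")
  pr <- prcomp(X, center = TRUE, scale. = FALSE)
  pr$x[, seq_len(k), drop = FALSE]
}

#' Flag outliers by Mahalanobis distance in score space
#'
#' Computes each sample's Mahalanobis distance from the score centroid
#' (using the score covariance) and flags samples whose distance is at
#' least `criterionSd` standard deviations above the mean distance --
#' the "3 SD or more" screening rule of NIR calibration practice.
#'
#' @param scores n x k score matrix (from [pcaScores()]).
#' @param criterionSd SD multiplier; default 3. `Inf` flags nothing.
#' @param constituent optional context label stored in the report.
#' @return An [OutlierReport-class].
#' @export
mahalanobisOutliers <- function(scores, criterionSd = 3, constituent = "") {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (n < 3) stop("need at least 3 samples to estimate the score covariance")
  S <- cov(scores)
  if (rcond(S) < 1e-12)
    stop("score covariance is singular; use fewer score dimensions")
  d <- as.numeric(sqrt(mahalanobis(scores, colMeans(scores), S)))
  thr <- mean(d) + criterionSd * sd(d)
  new("OutlierReport",
      distances = d, threshold = thr,
      flags = d >= thr, criterionSd = as.numeric(criterionSd),
      nScoreDims = ncol(scores), constituent = constituent)
}

#' @describeIn hayNIRS-generics logical outlier flags of an
#'   [OutlierReport-class].
#' @export
setMethod("outlierFlags", "OutlierReport", function(x, ...) x@flags)

#' @describeIn hayNIRS-generics Mahalanobis distances of an
#'   [OutlierReport-class].
#' @export
setMethod("distances", "OutlierReport", function(x, ...) x@distances)

setMethod("show", "OutlierReport", function(object) {
  cat("OutlierReport",
      if (nzchar(object@constituent)) paste0("[", object@constituent, "]"),
      ": ", sum(object@flags), "/", length(object@flags),
      " flagged (distance >= ", signif(object@threshold, 4),
      ", ", object@nScoreDims, " score dims, criterion ",
      object@criterionSd, " SD)\n", sep = "")
})

#' Convert an outlier report to a data.frame
#'
#' @param x an [OutlierReport-class].
#' @param sampleIds optional ids for the rows.
#' @param ... ignored.
#' @return data.frame with `sample_id`, `distance`, `flagged`.
#' @export
#' @method as.data.frame OutlierReport
as.data.frame.OutlierReport <- function(x, sampleIds = NULL, ...) {
  data.frame(
    sample_id = if (is.null(sampleIds)) seq_along(x@distances) else sampleIds,
    distance = x@distances, flagged = x@flags)
}

#' Remove calibration outliers for one constituent
#'
#' Preprocesses the calibration spectra with the constituent's recipe,
#' computes PC scores (as many dimensions as the constituent's model will
#' use, capped so the score covariance stays well-conditioned) and drops
#' the samples flagged by [mahalanobisOutliers()]. Screening is performed
#' independently per constituent; validation samples are never screened.
#'
#' @param x an [NIRSpectra-class] (calibration subset) or a preprocessed
#'   samples x wavelengths matrix.
#' @param constituent label ("CP", "ADF" or "NDF") recorded in the report.
#' @param config list with `ncomp` (score dimensions), `criterionSd`
#'   (default 3) and -- for NIRSpectra input -- `preprocess`, a
#'   [PreprocessConfig-class].
#' @return list with `clean` (same type as `x`, flagged samples removed)
#'   and `report` (an [OutlierReport-class]).
#' @export
removeOutliers <- function(x, constituent = "", config = list()) {
  ncomp <- if (is.null(config$ncomp)) 10L else as.integer(config$ncomp)
  crit <- if (is.null(config$criterionSd)) 3 else config$criterionSd
  if (is(x, "NIRSpectra")) {
    pp <- if (is.null(config$preprocess)) preprocessConfig() else config$preprocess
    X <- preprocessSpectra(x, pp)$X
  } else {
    X <- as.matrix(x)
  }
  k <- min(ncomp, nrow(X) - 2L, ncol(X))
  rep <- mahalanobisOutliers(pcaScores(X, k), criterionSd = crit,
                             constituent = constituent)
  if (is(x, "NIRSpectra")) {
    bad_ids <- sampleIds(x)[rep@flags]
    clean <- x[, !colData(x)$sample_id %in% bad_ids]
  } else {
    clean <- X[!rep@flags, , drop = FALSE]
  }
  list(clean = clean, report = rep)
}
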