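#' Spectral preprocessing configuration
#'
#' Holds the preprocessing recipe applied to raw reflectance spectra before
#' calibration: normalization of the absorbance spectrum, then a numerical
#' second derivative computed either by Savitzky-Golay polynomial filtering
#' or by the Norris gap-segment method. Derivatives are taken with respect
#' to the data-point index (the conventional way filter parameters are
#' quoted in NIR software); multiply by \code{step_nm^2} to convert a second
#' derivative to per-nm^2 units.
#'
#' @slot normalization character; one of \code{"none"}, \code{"vector"}
#'   (unit Euclidean norm), \code{"minmax"} (affine map onto \[0, 1\]) or
#'   \code{"zero"} (subtract the minimum).
#' @slot derivative character; \code{"none"}, \code{"savgol"} or
#'   \code{"norris"}.
#' @slot savgolWindow odd integer window length (data points), >= 3.
#' @slot savgolOrder polynomial order, < window.
#' @slot norrisSegment odd integer segment (moving-mean) length, >= 1.
#' @slot norrisGap integer gap between segment centers, >= 1.
#' @slot derivOrder derivative order; fixed at 2 in this package.
#'
#' @seealso [preprocessSpectra()], [savgolDerivative()], [norrisDerivative()]
#' @export
setClass("PreprocessConfig",
  representation(
    normalization = "character",
    derivative    = "character",
    savgolWindow  = "integer",
    savgolOrder   = "integer",
    norrisSegment = "integer",
    norrisGap     = "integer",
    derivOrder    = "integer"
  ),
  prototype(
    normalization = "vector",
    derivative    = "savgol",
    savgolWindow  = 3L,
    savgolOrder   = 2L,
    norrisSegment = 5L,
    norrisGap     = 2L,
    derivOrder    = 2L
  )
)

setValidity("PreprocessConfig", function(object) {
  msg <- character()
  if (!object@normalization %in% c("none", "vector", "minmax", "zero"))
    msg <- c(msg, "normalization must be one of none/vector/minmax/zero")
  if (!object@derivative %in% c("none", "savgol", "norris"))
    msg <- c(msg, "derivative must be one of none/savgol/norris")
  if (object@savgolWindow < 3L || object@savgolWindow %% 2L == 0L)
    msg <- c(msg, "savgolWindow must be odd and >= 3")
  if (object@savgolOrder >= object@savgolWindow)
    msg <- c(msg, "savgolOrder must be < savgolWindow")
  if (object@norrisSegment < 1L || object@norrisSegment %% 2L == 0L)
    msg <- c(msg, "norrisSegment must be odd and >= 1")
  if (object@norrisGap < 1L)
    msg <- c(msg, "norrisGap must be >= 1")
  if (object@derivOrder != 2L)
    msg <- c(msg, "derivOrder is fixed at 2")
  if (object@derivative == "savgol" && object@derivOrder > object@savgolOrder)
    msg <- c(msg, "derivOrder must be <= savgolOrder")
  if (length(msg)) msg else TRUE
})

#' Construct a PreprocessConfig
#'
#' @param normalization normalization method; default \code{"vector"}.
#' @param derivative derivative filter; default \code{"savgol"}.
#' @param savgolWindow,savgolOrder Savitzky-Golay window (odd, data points)
#'   and polynomial order. The default \code{3, 2} is the exact central
#'   second-difference stencil.
#' @param norrisSegment,norrisGap Norris gap-segment parameters (data
#'   points): segment (moving-mean) length and gap.
#' @return A [PreprocessConfig-class] object.
#' @examples
#' preprocessConfig(derivative = "norris", norrisSegment = 5, norrisGap = 2)
#' @export
preprocessConfig <- function(normalization = "vector", derivative = "savgol",
                             savgolWindow = 3, savgolOrder = 2,
                             norrisSegment = 5, norrisGap = 2) {
  new("PreprocessConfig",
      normalization = as.character(normalization),
      derivative    = as.character(derivative),
      savgolWindow  = as.integer(savgolWindow),
      savgolOrder   = as.integer(savgolOrder),
      norrisSegment = as.integer(norrisSegment),
      norrisGap     = as.integer(norrisGap),
      derivOrder    = 2L)
}

#' Container for NIR reflectance scans
#'
#' `NIRSpectra` extends [SummarizedExperiment::SummarizedExperiment]: the
#' assay matrix holds one spectrum per column (rows are wavelengths), the
#' row data carry the wavelength axis in nm, and the column data carry the
#' sample id, the replicate-scan number and, when known, the reference
#' chemistry (CP/ADF/NDF, percent dry matter). Replicate scans of a sample
#' are adjacent columns sharing a `sample_id`.
#'
#' The assay is named either `"reflectance"` (values in (0, 1\]) or
#' `"absorbance"` (log10(1/R)).
#'
#' @seealso [makeDataset()], [averageReplicates()], [preprocessSpectra()]
#' @export
setClass("NIRSpectra", contains = "SummarizedExperiment")

setValidity("NIRSpectra", function(object) {
  msg <- character()
  if (length(assayNames(object)) < 1L ||
      !assayNames(object)[1] %in% c("reflectance", "absorbance"))
    msg <- c(msg, "first assay must be named 'reflectance' or 'absorbance'")
  if (!"wavelength_nm" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData must contain 'wavelength_nm'")
  else {
    wl <- rowData(object)$wavelength_nm
    if (any(diff(wl) <= 0)) msg <- c(msg, "wavelengths must be strictly increasing")
  }
  if (!"sample_id" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain 'sample_id'")
  if (length(assayNames(object)) >= 1L &&
      assayNames(object)[1] == "reflectance" && ncol(object) > 0) {
    R <- assay(object, 1L)
    if (any(!is.finite(R)) || any(R <= 0) || any(R > 1))
      msg <- c(msg, "reflectance values must lie in (0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an NIRSpectra object
#'
#' @param spectra numeric matrix of spectra, one column per scan, rows in
#'   wavelength order (a samples-in-rows matrix is accepted and transposed
#'   when its column count equals `length(wavelengths)` and its row count
#'   does not).
#' @param wavelengths numeric vector of wavelengths in nm, strictly
#'   increasing, one per spectral point.
#' @param sampleId character/integer vector, one per scan; replicate scans
#'   share an id.
#' @param replicate integer replicate index per scan; defaults to the
#'   running count within each `sampleId`.
#' @param chemistry optional data.frame with columns `sample_id` and any of
#'   `CP`, `ADF`, `NDF`; joined onto the scans.
#' @param assayName `"reflectance"` (default) or `"absorbance"`.
#' @param metadata list of provenance fields stored in [S4Vectors::metadata()].
#' @return An [NIRSpectra-class] object.
#' @export
NIRSpectra <- function(spectra, wavelengths, sampleId,
                       replicate = NULL, chemistry = NULL,
                       assayName = "reflectance", metadata = list()) {
  spectra <- as.matrix(spectra)
  p <- length(wavelengths)
  if (nrow(spectra) != p && ncol(spectra) == p) spectra <- t(spectra)
  if (nrow(spectra) != p)
    stop("spectra matrix does not match the wavelength axis (", p, " points)")
  sampleId <- as.character(sampleId)
  if (length(sampleId) != ncol(spectra))
    stop("need one sample_id per scan")
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_along(sampleId), sampleId, FUN = seq_along)
  }
  cd <- S4Vectors::DataFrame(sample_id = sampleId,
                             replicate = as.integer(replicate))
  if (!is.null(chemistry)) {
    chemistry <- as.data.frame(chemistry)
    if (!"sample_id" %in% names(chemistry))
      stop("chemistry table must have a 'sample_id' column")
    chemistry$sample_id <- as.character(chemistry$sample_id)
    idx <- match(sampleId, chemistry$sample_id)
    if (anyNA(idx))
      stop("sample ids missing from chemistry table: ",
           paste(unique(sampleId[is.na(idx)]), collapse = ", "))
    for (col in setdiff(names(chemistry), "sample_id"))
      cd[[col]] <- chemistry[[col]][idx]
  }
  al <- list(spectra)
  names(al) <- assayName
  se <- SummarizedExperiment(
    assays = al,
    rowData = S4Vectors::DataFrame(wavelength_nm = as.numeric(wavelengths)),
    colData = cd)
  S4Vectors::metadata(se) <- metadata
  new("NIRSpectra", se)
}

#' A fitted NIR calibration model
#'
#' Stores everything needed to predict new spectra: the method tag, the
#' preprocessing recipe, the trimmed wavelength axis the model operates on,
#' the column and response centering terms, and a regression coefficient
#' vector on that axis. For MLR the coefficient vector is zero outside the
#' selected wavelengths; for PLS/PCR the component count and loadings are
#' kept in `details`.
#'
#' Predictions are \eqn{\hat y = \bar y + (x - \bar x)^\top b} where `x` is
#' the preprocessed spectrum on the model's trimmed axis.
#'
#' @slot method \code{"MLR"}, \code{"PCR"} or \code{"PLS"}.
#' @slot constituent constituent label ("CP", "ADF", "NDF" or "").
#' @slot preprocess the [PreprocessConfig-class] snapshot.
#' @slot wavelengths trimmed wavelength axis (nm) of the model matrix.
#' @slot xCenter column means of the calibration model matrix.
#' @slot yCenter calibration mean of the response.
#' @slot coefficients regression vector on the trimmed axis.
#' @slot ncomp retained component count (PLS/PCR; 0 for MLR).
#' @slot selected integer indices (into `wavelengths`) of MLR-selected
#'   wavelengths; empty for PLS/PCR.
#' @slot details list of method metadata (weights/loadings/scores, per-count
#'   coefficient paths).
#' @export
setClass("CalibrationModel",
  representation(
    method       = "character",
    constituent  = "character",
    preprocess   = "PreprocessConfig",
    wavelengths  = "numeric",
    xCenter      = "numeric",
    yCenter      = "numeric",
    coefficients = "numeric",
    ncomp        = "integer",
    selected     = "integer",
    details      = "list"
  ))

setValidity("CalibrationModel", function(object) {
  msg <- character()
  if (!object@method %in% c("MLR", "PCR", "PLS"))
    msg <- c(msg, "method must be MLR, PCR or PLS")
  p <- length(object@wavelengths)
  if (length(object@coefficients) != p || length(object@xCenter) != p)
    msg <- c(msg, "coefficients and xCenter must match the wavelength axis")
  if (object@method %in% c("PCR", "PLS") && object@ncomp < 1L)
    msg <- c(msg, "PLS/PCR models need ncomp >= 1")
  if (object@method == "MLR") {
    if (length(object@selected) < 1L)
      msg <- c(msg, "MLR models need a non-empty wavelength selection")
    if (anyDuplicated(object@selected))
      msg <- c(msg, "MLR wavelength selection must be duplicate-free")
  }
  if (length(msg)) msg else TRUE
})

#' Mahalanobis outlier screening report
#'
#' @slot distances per-sample Mahalanobis distance in PC-score space.
#' @slot threshold the distance cut-off used (mean + criterion * SD).
#' @slot flags logical; TRUE where distance >= threshold.
#' @slot criterionSd the SD multiplier (3 by convention).
#' @slot nScoreDims number of principal-component score dimensions used.
#' @slot constituent constituent context, or "" when generic.
#' @seealso [mahalanobisOutliers()]
#' @export
setClass("OutlierReport",
  representation(
    distances   = "numeric",
    threshold   = "numeric",
    flags       = "logical",
    criterionSd = "numeric",
    nScoreDims  = "integer",
    constituent = "character"
  ))

setValidity("OutlierReport", function(object) {
  msg <- character()
  if (length(object@flags) != length(object@distances))
    msg <- c(msg, "flags and distances must have equal length")
  if (any(object@distances < 0))
    msg <- c(msg, "distances must be non-negative")
  if (!identical(object@flags, object@distances >= object@threshold))
    msg <- c(msg, "flags must equal (distance >= threshold)")
  if (length(msg)) msg else TRUE
})

#' Calibration/validation metrics for one fitted model
#'
#' @slot method,constituent model identity.
#' @slot nC,nP calibration and validation sample counts.
#' @slot rmsec,rmsep root mean squared error of calibration / prediction.
#' @slot r2Cal in-sample coefficient of determination (calibration R^2).
#' @slot r2Val squared Pearson correlation on the validation set (r^2).
#' @slot r2ValDecomp validation 1 - SSE/SST, reported alongside r2Val.
#' @slot sdVal standard deviation of the validation reference values.
#' @slot rpd sdVal / rmsep.
#' @slot band RPD quality band: good (>= 2), acceptable (>= 1.4), else
#'   unreliable.
#' @slot calPairs,valPairs data.frames of (y, yhat) pairs.
#' @export
setClass("MetricsReport",
  representation(
    method      = "character",
    constituent = "character",
    nC = "integer", nP = "integer",
    rmsec = "numeric", rmsep = "numeric",
    r2Cal = "numeric", r2Val = "numeric", r2ValDecomp = "numeric",
    sdVal = "numeric", rpd = "numeric", band = "character",
    calPairs = "data.frame", valPairs = "data.frame"
  ))

#' Three-method benchmark report
#'
#' Result of [runBenchmark()]: per constituent x method, calibration
#' accuracy (R^2, RMSEC) and validation accuracy (r^2, RMSEP, RPD with its
#' quality band), plus the measured-vs-predicted scatter pairs and the
#' fitted models.
#'
#' @slot calibration data.frame of calibration rows.
#' @slot validation data.frame of validation rows.
#' @slot scatter named list of validation (y, yhat) data.frames.
#' @slot models named list of [CalibrationModel-class] objects.
#' @slot outliers named list of [OutlierReport-class] per constituent.
#' @slot split the calibration/validation split used.
#' @slot config the benchmark configuration list.
#' @export
setClass("BenchmarkReport",
  representation(
    calibration = "data.frame",
    validation  = "data.frame",
    scatter     = "list",
    models      = "list",
    outliers    = "list",
    split       = "list",
    config      = "list"
  ))
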