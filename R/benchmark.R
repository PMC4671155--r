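## End-to-end three-method benchmark: split -> per-constituent outlier
## screening on the calibration set -> preprocessing -> fit -> metrics.
## One split is shared by all constituents and methods so comparisons are
## paired.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default benchmark configuration
#'
#' Preprocessing per constituent follows the reference instrument recipe:
#' CP uses the Savitzky-Golay (window 3, order 2) second derivative, ADF
#' and NDF the Norris gap-segment (segment 5, gap 2) second derivative,
#' taken directly on the absorbance spectrum (no prior normalization: the
#' second derivative itself removes additive offsets and linear baselines,
#' and renormalizing first would let baseline variation rescale the
#' chemistry signal). Component
#' counts are selected by leave-one-out cross-validation up to `maxPc`
#' (`componentPolicy = "loo"`); setting `componentPolicy = "fixed"` uses
#' the `fixedComponents` (CP 8, ADF 7, NDF 10).
#'
#' @param componentPolicy `"loo"` or `"fixed"`.
#' @param maxPc leave-one-out search cap (default 15).
#' @param splitFraction calibration fraction (default 0.75).
#' @param splitSeed seed of the random split; `NULL` means use the
#'   benchmark seed.
#' @param outlierCriterionSd Mahalanobis screening criterion (default 3).
#' @param mlrWavelengths number of MLR wavelengths (default 2).
#' @return configuration list for [runBenchmark()].
#' @export
benchmarkConfig <- function(componentPolicy = c("loo", "fixed"),
                            maxPc = 15, splitFraction = 0.75,
                            splitSeed = NULL, outlierCriterionSd = 3,
                            mlrWavelengths = 2) {
  componentPolicy <- match.arg(componentPolicy)
  list(
    constituents = CONSTITUENTS,
    methods = c("PLS", "PCR", "MLR"),
    preprocess = list(
      CP  = preprocessConfig(normalization = "none", derivative = "savgol",
                             savgolWindow = 3, savgolOrder = 2),
      ADF = preprocessConfig(normalization = "none", derivative = "norris",
                             norrisSegment = 5, norrisGap = 2),
      NDF = preprocessConfig(normalization = "none", derivative = "norris",
                             norrisSegment = 5, norrisGap = 2)),
    componentPolicy = componentPolicy,
    fixedComponents = c(CP = 8L, ADF = 7L, NDF = 10L),
    maxPc = maxPc,
    splitFraction = splitFraction,
    splitSeed = splitSeed,
    outlierCriterionSd = outlierCriterionSd,
    mlrWavelengths = mlrWavelengths)
}

#' Run the three-method calibration benchmark
#'
#' For every constituent x method pair: preprocess the spectra with the
#' constituent's recipe, split calibration/validation (one shared random
#' split), screen calibration outliers by Mahalanobis distance in PC-score
#' space (independently per constituent; validation samples are never
#' screened), fit the model, and score it with RMSEC/R^2 on the
#' calibration set and r^2/RMSEP/RPD on the validation set.
#'
#' @param dataset an [NIRSpectra-class] with chemistry for all requested
#'   constituents (e.g. from [makeDataset()]).
#' @param config a [benchmarkConfig()] list.
#' @param seed seed for the random split (used when `config$splitSeed` is
#'   `NULL`).
#' @return A [BenchmarkReport-class].
#' @examples
#' \donttest{
#' rep <- runBenchmark(makeDataset(n = 60, seed = 1),
#'                     config = benchmarkConfig("fixed"), seed = 1)
#' rep
#' }
#' @export
runBenchmark <- function(dataset, config = benchmarkConfig(), seed = 1) {
  chem <- chemistry(dataset)
  miss <- setdiff(config$constituents, names(chem))
  if (length(miss))
    stop("dataset chemistry lacks constituent(s): ", paste(miss, collapse = ", "))
  n <- nrow(chem)
  if (n < 40) stop("benchmark needs at least ~40 samples, got ", n)
  split <- splitCalVal(n, fraction = config$splitFraction,
                       seed = config$splitSeed %||% seed)
  calRows <- valRows <- list()
  scatter <- models <- outliers <- list()

  for (cons in config$constituents) {
    ppc <- config$preprocess[[cons]]
    pp <- preprocessSpectra(dataset, ppc)
    X <- pp$X; wl <- pp$wavelengths
    y <- chem[[cons]]
    Xcal0 <- X[split$calibration, , drop = FALSE]
    ycal0 <- y[split$calibration]
    Xval <- X[split$validation, , drop = FALSE]
    yval <- y[split$validation]

    kScreen <- min(config$fixedComponents[[cons]], nrow(Xcal0) - 2L, ncol(Xcal0))
    out <- removeOutliers(Xcal0, constituent = cons,
                          config = list(ncomp = kScreen,
                                        criterionSd = config$outlierCriterionSd))
    keep <- !outlierFlags(out$report)
    Xcal <- Xcal0[keep, , drop = FALSE]
    ycal <- ycal0[keep]
    outliers[[cons]] <- out$report

    ncomp <- c(PLS = NA_integer_, PCR = NA_integer_)
    if ("PLS" %in% config$methods)
      ncomp["PLS"] <- if (config$componentPolicy == "loo")
        as.integer(selectNComponents(Xcal, ycal, "pls", config$maxPc))
      else config$fixedComponents[[cons]]
    if ("PCR" %in% config$methods)
      ncomp["PCR"] <- if (config$componentPolicy == "loo")
        as.integer(selectNComponents(Xcal, ycal, "pcr", config$maxPc))
      else config$fixedComponents[[cons]]

    for (m in config$methods) {
      model <- switch(m,
        PLS = fitPLS(Xcal, ycal, ncomp[["PLS"]], wavelengths = wl,
                     config = ppc, constituent = cons),
        PCR = fitPCR(Xcal, ycal, ncomp[["PCR"]], wavelengths = wl,
                     config = ppc, constituent = cons),
        MLR = {
          sel <- selectMlrWavelengths(Xcal, ycal, config$mlrWavelengths)
          fitMLR(Xcal, ycal, sel, wavelengths = wl,
                 config = ppc, constituent = cons)
        })
      met <- metricsReport(model, Xcal, ycal, Xval, yval)
      key <- paste(cons, m, sep = ".")
      models[[key]] <- model
      scatter[[key]] <- met@valPairs
      calRows[[key]] <- data.frame(
        constituent = cons, method = m, n_cal = met@nC,
        n_removed = sum(outlierFlags(out$report)),
        ncomp = if (m == "MLR") NA_integer_ else model@ncomp,
        R2 = met@r2Cal, RMSEC = met@rmsec)
      valRows[[key]] <- data.frame(
        constituent = cons, method = m, n_val = met@nP,
        r2 = met@r2Val, r2_decomp = met@r2ValDecomp,
        RMSEP = met@rmsep, SD = met@sdVal, RPD = met@rpd, band = met@band)
    }
  }
  new("BenchmarkReport",
      calibration = do.call(rbind, c(calRows, make.row.names = FALSE)),
      validation = do.call(rbind, c(valRows, make.row.names = FALSE)),
      scatter = scatter, models = models, outliers = outliers,
      split = split, config = config)
}

#' @describeIn runBenchmark calibration table of a report.
#' @param x a [BenchmarkReport-class].
#' @export
calibrationTable <- function(x) x@calibration

#' @describeIn runBenchmark validation table of a report.
#' @export
validationTable <- function(x) x@validation

setMethod("show", "BenchmarkReport", function(object) {
  cat("BenchmarkReport:", length(unique(object@calibration$constituent)),
      "constituents x", length(unique(object@calibration$method)),
      "methods;", length(object@split$calibration), "calibration /",
      length(object@split$validation), "validation samples\n\n")
  cat("Calibration (R2, RMSEC):\n")
  print(format(object@calibration, digits = 3), row.names = FALSE)
  cat("\nValidation (r2, RMSEP, RPD):\n")
  v <- object@validation[, c("constituent", "method", "n_val", "r2",
                             "RMSEP", "RPD", "band")]
  print(format(v, digits = 3), row.names = FALSE)
})
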