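## On-disk formats. One run lives in a directory holding a spectra matrix
## CSV (row = sample-replicate scan, header = wavelengths in nm), a
## chemistry CSV (sample_id, CP, ADF, NDF) and a JSON provenance sidecar.
## JCAMP-DX is supported read-only as the spectroscopy interchange format.

#' Write/read a spectra matrix CSV
#'
#' The matrix layout is one row per scan: columns `sample_id`, `replicate`,
#' then one column per wavelength with the nm value as header. Numeric
#' round-tripping is lossless (values are written with full precision).
#'
#' @param x an [NIRSpectra-class].
#' @param path CSV file path.
#' @return `writeSpectraCSV()`: the path, invisibly. `readSpectraCSV()`:
#'   an [NIRSpectra-class] (no chemistry attached).
#' @export
writeSpectraCSV <- function(x, path) {
  M <- t(assay(x, 1L))
  df <- data.frame(sample_id = colData(x)$sample_id,
                   replicate = colData(x)$replicate,
                   format(M, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  names(df)[-(1:2)] <- wavelengths(x)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSpectraCSV
#' @export
readSpectraCSV <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, check.names = FALSE, fill = FALSE)
  if (!all(c("sample_id", "replicate") %in% names(df)))
    stop(path, ": expected 'sample_id' and 'replicate' columns")
  wlNames <- setdiff(names(df), c("sample_id", "replicate"))
  wl <- suppressWarnings(as.numeric(wlNames))
  if (anyNA(wl))
    stop(path, ": non-numeric wavelength headers: ",
         paste(head(wlNames[is.na(wl)], 3), collapse = ", "))
  M <- as.matrix(df[, wlNames, drop = FALSE])
  if (!is.numeric(M)) {
    bad <- which(!vapply(df[, wlNames, drop = FALSE], is.numeric,
                         logical(1)))[1]
    stop(path, ": non-numeric cell(s) in wavelength column ", wl[bad])
  }
  NIRSpectra(t(M), wl, df$sample_id, replicate = df$replicate)
}

#' Write/read a chemistry table CSV
#'
#' Columns: `sample_id` plus any of `CP`, `ADF`, `NDF` (percent dry
#' matter).
#'
#' @param chem data.frame of reference values.
#' @param path CSV file path.
#' @return `readChemistryCSV()`: validated data.frame.
#' @export
writeChemistryCSV <- function(chem, path) {
  write.csv(chem, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeChemistryCSV
#' @export
readChemistryCSV <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, check.names = FALSE)
  if (!"sample_id" %in% names(df))
    stop(path, ": missing 'sample_id' column")
  cons <- intersect(CONSTITUENTS, names(df))
  if (!length(cons))
    stop(path, ": no constituent column (CP/ADF/NDF) found")
  for (col in cons) {
    if (!is.numeric(df[[col]]))
      stop(path, ": column ", col, " is not numeric")
    if (any(df[[col]] < 0, na.rm = TRUE))
      stop(path, ": negative value in column ", col)
  }
  df$sample_id <- as.character(df$sample_id)
  df
}

#' Read spectra and chemistry together
#'
#' Joins the chemistry onto the scans by `sample_id`; ids present in one
#' table but not the other are an error listing the offenders.
#'
#' @param spectraPath spectra matrix CSV.
#' @param chemistryPath chemistry CSV.
#' @return An [NIRSpectra-class] with chemistry attached.
#' @export
readDataset <- function(spectraPath, chemistryPath) {
  sp <- readSpectraCSV(spectraPath)
  chem <- readChemistryCSV(chemistryPath)
  only_chem <- setdiff(chem$sample_id, sampleIds(sp))
  if (length(only_chem))
    stop("ids present in chemistry but absent in spectra: ",
         paste(head(only_chem, 10), collapse = ", "))
  NIRSpectra(assay(sp, 1L), wavelengths(sp), colData(sp)$sample_id,
             replicate = colData(sp)$replicate, chemistry = chem)
}

#' Write a synthetic dataset to a run directory
#'
#' Emits `spectra.csv`, `chemistry.csv` and `provenance.json` (the
#' generator parameters and seed, sufficient to regenerate the dataset).
#'
#' @param x an [NIRSpectra-class] from [makeDataset()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeDataset <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeSpectraCSV(x, file.path(dir, "spectra.csv"))
  writeChemistryCSV(chemistry(x), file.path(dir, "chemistry.csv"))
  prov <- S4Vectors::metadata(x)$provenance
  if (!is.null(prov))
    jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a JCAMP-DX spectrum
#'
#' Minimal reader for single-spectrum JCAMP-DX files with tabular
#' `(X++(Y..Y))` data: honors `XFACTOR`/`YFACTOR`, `FIRSTX`/`LASTX` and
#' `NPOINTS`, and requires wavelength units (`XUNITS=NANOMETERS`). The
#' spectrum is linearly interpolated onto the declared grid when its axis
#' is within one grid step of alignment, and rejected otherwise.
#'
#' @param path JCAMP-DX file.
#' @param grid target [spectralGrid()].
#' @return numeric vector of length `grid$nPoints` (the resampled
#'   spectrum), with the sample title as the `title` attribute.
#' @export
readJCAMP <- function(path, grid = spectralGrid()) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- function(key) {
    i <- grep(paste0("^##", key, "\\s*="), lines, ignore.case = TRUE)
    if (!length(i)) return(NA_character_)
    trimws(sub("^##[^=]*=", "", lines[i[1]]))
  }
  xunits <- toupper(hdr("XUNITS") %||% "")
  if (!is.na(xunits) && !grepl("NANOMET", xunits))
    stop(path, ": XUNITS must be nanometers, got '", xunits, "'")
  xf <- as.numeric(hdr("XFACTOR")); if (is.na(xf)) xf <- 1
  yf <- as.numeric(hdr("YFACTOR")); if (is.na(yf)) yf <- 1
  np <- as.numeric(hdr("NPOINTS"))
  i0 <- grep("^##XYDATA\\s*=", lines, ignore.case = TRUE)
  if (!length(i0)) stop(path, ": no ##XYDATA block")
  iEnd <- grep("^##END", lines, ignore.case = TRUE)
  iEnd <- iEnd[iEnd > i0[1]][1]
  if (is.na(iEnd)) iEnd <- length(lines) + 1L
  body <- lines[(i0[1] + 1L):(iEnd - 1L)]
  xs <- c(); ys <- c()
  for (ln in body) {
    tok <- as.numeric(strsplit(trimws(ln), "[ \t,]+")[[1]])
    tok <- tok[!is.na(tok)]
    if (length(tok) < 2) next
    x0 <- tok[1] * xf
    yv <- tok[-1] * yf
    xs <- c(xs, x0); ys <- c(ys, list(yv))
  }
  if (!length(xs)) stop(path, ": empty XYDATA block")
  ## reconstruct per-line x increments from consecutive line starts
  x_all <- c(); y_all <- c()
  for (i in seq_along(xs)) {
    yv <- ys[[i]]
    dx <- if (i < length(xs)) (xs[i + 1] - xs[i]) / length(yv)
          else if (length(xs) > 1) (xs[i] - xs[i - 1]) / length(ys[[i - 1]])
          else grid$step
    x_all <- c(x_all, xs[i] + dx * (seq_along(yv) - 1))
    y_all <- c(y_all, yv)
  }
  if (!is.na(np) && length(y_all) != np)
    stop(path, ": NPOINTS=", np, " but ", length(y_all), " values read")
  lo <- min(x_all); hi <- max(x_all)
  if (lo > grid$start + grid$step || hi < grid$end - grid$step)
    stop(path, ": spectrum covers ", lo, "-", hi, " nm but the grid needs ",
         grid$start, "-", grid$end, " nm (off by more than one step)")
  out <- approx(x_all, y_all, xout = grid$axis, rule = 2)$y
  attr(out, "title") <- hdr("TITLE")
  out
}

#' Serialize / restore a calibration model as JSON
#'
#' Versioned JSON holding everything prediction needs (method,
#' preprocessing, trimmed axis, centering terms, coefficients, metadata).
#' Numbers are written at full precision, so a round-tripped model gives
#' bit-identical predictions.
#'
#' @param model a [CalibrationModel-class].
#' @param path JSON file path.
#' @return `readModelJSON()`: the restored [CalibrationModel-class].
#' @export
writeModelJSON <- function(model, path) {
  pp <- model@preprocess
  obj <- list(
    format = "hayNIRS-model", version = 1L,
    method = model@method, constituent = model@constituent,
    preprocess = list(
      normalization = pp@normalization, derivative = pp@derivative,
      savgolWindow = pp@savgolWindow, savgolOrder = pp@savgolOrder,
      norrisSegment = pp@norrisSegment, norrisGap = pp@norrisGap,
      derivOrder = pp@derivOrder),
    wavelengths = model@wavelengths,
    xCenter = model@xCenter, yCenter = model@yCenter,
    coefficients = model@coefficients,
    ncomp = model@ncomp, selected = model@selected)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname writeModelJSON
#' @export
readModelJSON <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "hayNIRS-model"))
    stop(path, " is not a hayNIRS model file")
  pp <- obj$preprocess
  new("CalibrationModel",
      method = obj$method, constituent = obj$constituent %||% "",
      preprocess = preprocessConfig(pp$normalization, pp$derivative,
                                    pp$savgolWindow, pp$savgolOrder,
                                    pp$norrisSegment, pp$norrisGap),
      wavelengths = as.numeric(obj$wavelengths),
      xCenter = as.numeric(obj$xCenter), yCenter = as.numeric(obj$yCenter),
      coefficients = as.numeric(obj$coefficients),
      ncomp = as.integer(obj$ncomp),
      selected = as.integer(obj$selected), details = list())
}

#' Read a structured run configuration (YAML)
#'
#' Recognized keys (all optional; defaults in parentheses): `seed` (1),
#' `n_samples` (203; a bare `n` would be parsed as a YAML boolean),
#' `replicates` (3), `grid: {start, end, step}`,
#' `population: {CP: {min, max, mean, sd}, ...}`,
#' `noise: {additive_sd, scatter_sd, replicate_sd, baseline_slope_sd,
#' group2_fraction}`, `split: {fraction, seed}`,
#' `outlier: {criterion_sd}`, `component_policy` ("loo" or "fixed"),
#' `fixed_components: {CP, ADF, NDF}`, `max_pc`,
#' `preprocess: {CP: {normalization, derivative, window, polyorder,
#' segment, gap}, ...}`, `methods`.
#'
#' @param path YAML file.
#' @return validated configuration list with a `benchmark` element ready
#'   for [runBenchmark()] and a `generator` element for [makeDataset()].
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- yaml::read_yaml(path)
  bad <- setdiff(names(cfg$population), CONSTITUENTS)
  if (length(bad))
    stop(path, ": unknown constituent(s) in population: ",
         paste(bad, collapse = ", "))
  bad <- setdiff(names(cfg$preprocess), CONSTITUENTS)
  if (length(bad))
    stop(path, ": unknown constituent(s) in preprocess: ",
         paste(bad, collapse = ", "))
  gridCfg <- cfg$grid %||% list()
  grid <- spectralGrid(gridCfg$start %||% 950, gridCfg$end %||% 1650,
                       gridCfg$step %||% 5)
  params <- defaultPopulationParams()
  for (cons in names(cfg$population)) {
    p <- cfg$population[[cons]]
    params[[cons]] <- populationParams(cons, p$min, p$max, p$mean, p$sd)
  }
  nz <- cfg$noise %||% list()
  noise <- noiseParams(
    additiveSd = nz$additive_sd %||% formals(noiseParams)$additiveSd,
    scatterSd = nz$scatter_sd %||% formals(noiseParams)$scatterSd,
    replicateSd = nz$replicate_sd %||% formals(noiseParams)$replicateSd,
    baselineSlopeSd = nz$baseline_slope_sd %||% formals(noiseParams)$baselineSlopeSd,
    group2Fraction = nz$group2_fraction %||% formals(noiseParams)$group2Fraction)
  bench <- benchmarkConfig(
    componentPolicy = cfg$component_policy %||% "loo",
    maxPc = cfg$max_pc %||% 15,
    splitFraction = (cfg$split %||% list())$fraction %||% 0.75,
    splitSeed = (cfg$split %||% list())$seed,
    outlierCriterionSd = (cfg$outlier %||% list())$criterion_sd %||% 3,
    mlrWavelengths = cfg$mlr_wavelengths %||% 2)
  if (!is.null(cfg$fixed_components))
    bench$fixedComponents[names(cfg$fixed_components)] <-
      as.integer(unlist(cfg$fixed_components))
  if (!is.null(cfg$methods)) {
    m <- toupper(unlist(cfg$methods))
    bad <- setdiff(m, c("PLS", "PCR", "MLR"))
    if (length(bad)) stop(path, ": unknown method(s): ", paste(bad, collapse = ", "))
    bench$methods <- m
  }
  for (cons in names(cfg$preprocess)) {
    p <- cfg$preprocess[[cons]]
    bench$preprocess[[cons]] <- preprocessConfig(
      normalization = p$normalization %||% "vector",
      derivative = p$derivative %||% "savgol",
      savgolWindow = p$window %||% 3, savgolOrder = p$polyorder %||% 2,
      norrisSegment = p$segment %||% 5, norrisGap = p$gap %||% 2)
  }
  list(seed = cfg$seed %||% 1, n = cfg$n_samples %||% 203,
       replicates = cfg$replicates %||% 3, grid = grid,
       params = params, noise = noise, benchmark = bench)
}

#' Write benchmark report CSVs
#'
#' Writes `calibration.csv` and `validation.csv` (column order mirrors the
#' conventional accuracy tables: R2, RMSEC | r2, RMSEP, RPD) plus one
#' measured-vs-predicted scatter CSV per constituent and method.
#'
#' @param report a [BenchmarkReport-class].
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
writeBenchmarkCSV <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report@calibration, file.path(dir, "calibration.csv"),
            row.names = FALSE)
  write.csv(report@validation, file.path(dir, "validation.csv"),
            row.names = FALSE)
  for (key in names(report@scatter))
    write.csv(report@scatter[[key]],
              file.path(dir, paste0("scatter_", key, ".csv")),
              row.names = FALSE)
  invisible(dir)
}
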