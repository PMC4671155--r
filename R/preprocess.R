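## Spectral preprocessing: replicate averaging, absorbance transform,
## normalization, and the two second-derivative filters used in NIR work.
## All derivative filters operate in data-point index units and drop the
## edge points where the stencil does not fit; callers receive the trimmed
## wavelength axis so calibration and prediction use identical columns.

#' @describeIn hayNIRS-generics wavelength axis of an [NIRSpectra-class].
#' @export
setMethod("wavelengths", "NIRSpectra", function(x, ...)
  rowData(x)$wavelength_nm)

#' @describeIn hayNIRS-generics reflectance (or first-assay) matrix,
#'   wavelengths x scans.
#' @export
setMethod("reflectance", "NIRSpectra", function(x, ...) assay(x, 1L))

#' @describeIn hayNIRS-generics unique sample ids in column order.
#' @export
setMethod("sampleIds", "NIRSpectra", function(x, ...)
  unique(colData(x)$sample_id))

#' @describeIn hayNIRS-generics per-sample reference chemistry (one row per
#'   sample; only the constituent columns present in the object).
#' @export
setMethod("chemistry", "NIRSpectra", function(x, ...) {
  cd <- as.data.frame(colData(x))
  keep <- c("sample_id", intersect(CONSTITUENTS, names(cd)))
  first <- !duplicated(cd$sample_id)
  out <- cd[first, keep, drop = FALSE]
  rownames(out) <- NULL
  out
})

setMethod("show", "NIRSpectra", function(object) {
  wl <- wavelengths(object)
  cat("NIRSpectra:", ncol(object), "scans of", length(sampleIds(object)),
      "samples;", length(wl), "points",
      sprintf("(%g-%g nm)\n", min(wl), max(wl)))
  cat("  assay:", assayNames(object)[1],
      "| chemistry:", paste(intersect(CONSTITUENTS,
                                      colnames(colData(object))),
                            collapse = ", "), "\n")
})

#' Reflectance to absorbance
#'
#' Computes absorbance as the log of the reciprocal reflectance,
#' \eqn{A(\lambda) = \log_{10}(1/R(\lambda))}, elementwise.
#'
#' @param R numeric vector or matrix of reflectance values in (0, 1].
#' @return Object of the same shape holding absorbance.
#' @examples
#' toAbsorbance(c(1, 0.1, 0.01))  # 0 1 2
#' @export
toAbsorbance <- function(R) {
  bad <- which(!is.finite(R) | R <= 0)
  if (length(bad)) {
    lbl <- if (!is.null(names(R))) names(R)[bad[1]]
           else if (is.matrix(R)) paste0("row ", row(R)[bad[1]])
           else paste0("position ", bad[1])
    stop("reflectance must be positive to take log10(1/R); first offending ",
         "value at ", lbl)
  }
  log10(1 / R)
}

#' @describeIn hayNIRS-generics average replicate scans of an
#'   [NIRSpectra-class] into one spectrum per sample (pointwise mean of the
#'   reflectance), keeping sample order and chemistry.
#' @export
setMethod("averageReplicates", "NIRSpectra", function(x, ...) {
  ids <- colData(x)$sample_id
  uid <- unique(ids)
  M <- assay(x, 1L)
  avg <- vapply(uid, function(s) rowMeans(M[, ids == s, drop = FALSE]),
                numeric(nrow(M)))
  chem <- chemistry(x)
  chem <- if (ncol(chem) > 1) chem else NULL
  NIRSpectra(avg, wavelengths(x), uid, replicate = rep(1L, length(uid)),
             chemistry = chem, assayName = assayNames(x)[1],
             metadata = S4Vectors::metadata(x))
})

#' @describeIn hayNIRS-generics average a list of spectra (equal-length
#'   numeric vectors) pointwise.
#' @export
setMethod("averageReplicates", "list", function(x, ...) {
  if (!length(x)) stop("need at least one scan")
  len <- lengths(x)
  if (length(unique(len)) != 1L)
    stop("replicate scans are on mismatched grids (lengths ",
         paste(unique(len), collapse = ", "), ")")
  Reduce(`+`, x) / length(x)
})

#' @describeIn hayNIRS-generics average the columns of a wavelengths x scans
#'   matrix pointwise.
#' @export
setMethod("averageReplicates", "matrix", function(x, ...) rowMeans(x))

#' Normalize a spectrum
#'
#' @param x numeric vector, or matrix with one spectrum per row.
#' @param method `"vector"` (unit Euclidean norm), `"minmax"` (affine onto
#'   \[0, 1\]), `"zero"` (subtract the minimum) or `"none"`.
#' @return Normalized object of the same shape.
#' @examples
#' normalizeSpectrum(c(3, 4), "vector")   # 0.6 0.8
#' normalizeSpectrum(c(2, 4, 6), "minmax")  # 0 0.5 1
#' @export
normalizeSpectrum <- function(x, method = c("vector", "minmax", "zero", "none")) {
  method <- match.arg(method)
  f <- function(v) {
    if (!length(v)) stop("cannot normalize an empty spectrum")
    switch(method,
      none = v,
      vector = {
        nrm <- sqrt(sum(v^2))
        if (nrm == 0) stop("vector normalization undefined for an all-zero spectrum")
        v / nrm
      },
      minmax = {
        rng <- range(v)
        if (diff(rng) == 0) stop("min/max normalization undefined for a constant spectrum")
        (v - rng[1]) / diff(rng)
      },
      zero = v - min(v))
  }
  if (is.matrix(x)) t(apply(x, 1, f)) else f(x)
}

## Apply a symmetric convolution stencil along spectra (rows of a matrix or
## a single vector), dropping `h` points at each edge.
.convTrim <- function(x, coef) {
  h <- (length(coef) - 1L) %/% 2L
  vec <- !is.matrix(x)
  X <- if (vec) matrix(x, nrow = 1) else x
  p <- ncol(X)
  if (p < length(coef))
    stop("spectrum too short (", p, " points) for a ", length(coef),
         "-point stencil")
  idx <- (h + 1L):(p - h)
  out <- matrix(0, nrow(X), length(idx))
  for (o in -h:h)
    out <- out + coef[o + h + 1L] * X[, idx + o, drop = FALSE]
  attr(out, "margin") <- h
  if (vec) {
    v <- drop(out)
    attr(v, "margin") <- h
    v
  } else out
}

#' Savitzky-Golay derivative filter
#'
#' Local least-squares polynomial smoothing-derivative. The stencil is
#' taken from [signal::sgolay()]; with the default window 3 and order 2
#' the second derivative is the exact central second difference
#' (1, -2, 1). Derivatives are with respect to the data-point index;
#' multiply by `step_nm^(-deriv)`... more precisely divide by
#' `step_nm^deriv` to express per nm.
#'
#' Edge points where the stencil does not fit are dropped; the returned
#' object carries an attribute `margin` giving the number of points
#' trimmed from each end.
#'
#' @param x numeric vector, or matrix with one spectrum per row.
#' @param window odd filter length in data points (>= 3).
#' @param polyorder polynomial order (< window).
#' @param deriv derivative order (<= polyorder); default 2.
#' @return Trimmed derivative spectrum (length reduced by `window - 1`).
#' @examples
#' savgolDerivative((1:10)^2)  # all 2
#' @export
savgolDerivative <- function(x, window = 3, polyorder = 2, deriv = 2) {
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  if (window < 3L || window %% 2L == 0L) stop("window must be odd and >= 3")
  if (polyorder >= window) stop("polyorder must be < window")
  if (deriv > polyorder) stop("deriv must be <= polyorder")
  Fm <- signal::sgolay(p = polyorder, n = window, m = deriv, ts = 1)
  coef <- Fm[(window + 1L) %/% 2L, ]  # central (interior) stencil
  .convTrim(x, coef)
}

#' Norris gap-segment derivative
#'
#' The chemometrics gap-segment second derivative: with \eqn{m_i} the
#' moving mean of width `segment` centered at point \eqn{i},
#' \deqn{d_i = (m_{i-g} - 2 m_i + m_{i+g}) / g^2} for gap \eqn{g}. The
#' segment mean supplies the smoothing; the gap sets the differencing
#' scale. Exact on quadratics: the segment mean of \eqn{i^2} is
#' \eqn{i^2 + (s^2-1)/12} and the added constant cancels in the second
#' difference, so `y = i^2` maps to 2 everywhere in the interior.
#'
#' Edges are trimmed by `gap + (segment-1)/2` points per end (attribute
#' `margin`).
#'
#' @param x numeric vector, or matrix with one spectrum per row.
#' @param segment odd moving-mean length in data points (>= 1).
#' @param gap gap between segment centers in data points (>= 1).
#' @param deriv derivative order; only 2 is supported.
#' @return Trimmed derivative spectrum.
#' @examples
#' norrisDerivative((1:20)^2, segment = 5, gap = 2)  # all 2
#' @export
norrisDerivative <- function(x, segment = 5, gap = 2, deriv = 2) {
  segment <- as.integer(segment); gap <- as.integer(gap)
  if (segment < 1L || segment %% 2L == 0L) stop("segment must be odd and >= 1")
  if (gap < 1L) stop("gap must be >= 1")
  if (deriv != 2) stop("only the second derivative is supported")
  h <- (segment - 1L) %/% 2L
  seg <- rep(1 / segment, segment)
  ## combined stencil: second gap-difference of segment means
  width <- 2L * (gap + h) + 1L
  coef <- numeric(width)
  ctr <- gap + h + 1L
  for (shift in c(-gap, 0L, gap)) {
    wgt <- if (shift == 0L) -2 else 1
    coef[(ctr + shift - h):(ctr + shift + h)] <-
      coef[(ctr + shift - h):(ctr + shift + h)] + wgt * seg
  }
  .convTrim(x, coef / gap^2)
}

.applyDerivative <- function(X, config) {
  switch(config@derivative,
    none = { attr(X, "margin") <- 0L; X },
    savgol = savgolDerivative(X, config@savgolWindow, config@savgolOrder,
                              config@derivOrder),
    norris = norrisDerivative(X, config@norrisSegment, config@norrisGap,
                              config@derivOrder))
}

#' @describeIn hayNIRS-generics run the full preprocessing pipeline on an
#'   [NIRSpectra-class]: average replicates, transform to absorbance,
#'   normalize, differentiate. Returns a list with the model matrix `X`
#'   (samples x trimmed wavelengths), the trimmed `wavelengths`,
#'   `sampleIds` and the `config`.
#' @export
setMethod("preprocessSpectra", signature("NIRSpectra", "PreprocessConfig"),
  function(x, config, ...) {
    validObject(config)
    avg <- averageReplicates(x)
    M <- t(assay(avg, 1L))  # samples x wavelengths
    if (assayNames(avg)[1] == "reflectance") M <- toAbsorbance(M)
    out <- preprocessSpectra(M, config, wavelengths = wavelengths(x),
                             normalizeOnly = FALSE)
    out$sampleIds <- sampleIds(x)
    out
  })

#' @describeIn hayNIRS-generics preprocess an absorbance matrix (samples x
#'   wavelengths) directly; `wavelengths` must be supplied via the
#'   like-named argument.
#' @param wavelengths wavelength axis for the matrix method.
#' @param normalizeOnly internal; skip nothing by default.
#' @export
setMethod("preprocessSpectra", signature("matrix", "PreprocessConfig"),
  function(x, config, wavelengths = NULL, normalizeOnly = FALSE, ...) {
    validObject(config)
    if (is.null(wavelengths)) wavelengths <- as.numeric(colnames(x))
    if (length(wavelengths) != ncol(x) || anyNA(wavelengths))
      stop("supply a numeric wavelength axis matching ncol(x)")
    X <- normalizeSpectrum(x, config@normalization)
    X <- .applyDerivative(X, config)
    m <- attr(X, "margin")
    attr(X, "margin") <- NULL
    wl <- if (m > 0) wavelengths[(m + 1L):(length(wavelengths) - m)]
          else wavelengths
    colnames(X) <- wl
    list(X = as.matrix(X), wavelengths = wl, config = config, margin = m)
  })
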