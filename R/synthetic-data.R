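## Seeded generator of hay-like NIR datasets: compositions drawn from
## truncated, correlated normals; reflectance built from a Beer-Lambert
## style linear mixture of fixed Gaussian-band pure-component spectra plus
## an affine baseline and instrument noise.

#' Population parameters for one constituent
#'
#' Range, mean and SD (percent dry matter) of a constituent's population.
#' Defaults reproduce the summary statistics of a 203-sample sheepgrass hay
#' survey: CP 6.20-14.33 (mean 10.54, SD 1.24), ADF 35.13-42.34 (mean
#' 38.74, SD 2.33), NDF 50.71-71.08 (mean 60.89, SD 2.67).
#'
#' @param constituent one of "CP", "ADF", "NDF".
#' @param min,max,mean,sd population parameters; `NULL` means the default
#'   for that constituent.
#' @return A list with class `"PopulationParams"`.
#' @examples
#' populationParams("CP")
#' @export
populationParams <- function(constituent = c("CP", "ADF", "NDF"),
                             min = NULL, max = NULL, mean = NULL, sd = NULL) {
  constituent <- match.arg(constituent)
  def <- .POPULATION_DEFAULTS[[constituent]]
  p <- list(constituent = constituent,
            min  = if (is.null(min))  def$min  else as.numeric(min),
            max  = if (is.null(max))  def$max  else as.numeric(max),
            mean = if (is.null(mean)) def$mean else as.numeric(mean),
            sd   = if (is.null(sd))   def$sd   else as.numeric(sd))
  if (p$sd <= 0) stop("sd must be positive for ", constituent)
  if (p$min >= p$max) stop("min must be < max for ", constituent)
  if (p$mean <= p$min || p$mean >= p$max)
    stop("mean must lie strictly inside [min, max] for ", constituent)
  class(p) <- "PopulationParams"
  p
}

.POPULATION_DEFAULTS <- list(
  CP  = list(min =  6.20, max = 14.33, mean = 10.54, sd = 1.24),
  ADF = list(min = 35.13, max = 42.34, mean = 38.74, sd = 2.33),
  NDF = list(min = 50.71, max = 71.08, mean = 60.89, sd = 2.67)
)

#' @rdname populationParams
#' @return `defaultPopulationParams()`: named list of the three default
#'   parameter sets.
#' @export
defaultPopulationParams <- function() {
  out <- lapply(CONSTITUENTS, populationParams)
  names(out) <- CONSTITUENTS
  out
}

#' The wavelength grid of the instrument
#'
#' @param start,end,step grid limits and spacing in nm; defaults 950, 1650,
#'   5 give the instrument's 141-point axis.
#' @return List with `start`, `end`, `step`, `nPoints` and the `axis` itself.
#' @examples
#' spectralGrid()$nPoints  # 141
#' @export
spectralGrid <- function(start = 950, end = 1650, step = 5) {
  if (step <= 0 || end <= start) stop("need end > start and step > 0")
  n <- (end - start) / step + 1
  if (abs(n - round(n)) > 1e-9) stop("step must divide the range exactly")
  n <- as.integer(round(n))
  list(start = start, end = end, step = step, nPoints = n,
       axis = seq(start, end, by = step))
}

#' Default between-constituent correlation of the generator
#'
#' Protein trades off against both fiber fractions (rho = -0.4) while the
#' two fiber fractions rise together (rho = +0.6), so downstream models
#' face realistic collinearity.
#'
#' @return 3x3 correlation matrix over CP, ADF, NDF.
#' @export
defaultCompositionCorrelation <- function() {
  r <- matrix(c(1, -0.4, -0.4,
                -0.4, 1, 0.6,
                -0.4, 0.6, 1), 3, 3,
              dimnames = list(CONSTITUENTS, CONSTITUENTS))
  r
}

#' Draw correlated, range-truncated constituent compositions
#'
#' Draws per-sample (CP, ADF, NDF) vectors from a Gaussian copula with the
#' given correlation, maps each margin to normal(mean, sd), and rejects and
#' redraws any sample falling outside its \[min, max\] range (resampling,
#' not clipping, so no probability mass piles up at the bounds).
#'
#' Note that truncation shrinks the realized SD below the nominal `sd` when
#' the range is tight relative to it (markedly so for ADF, whose range
#' spans only about +/-1.55 SD); the realized mean is essentially
#' unaffected for near-symmetric ranges.
#'
#' @param n number of samples (>= 0).
#' @param params named list of [populationParams()] per constituent.
#' @param seed integer seed; the draw is deterministic given it.
#' @param correlation constituent correlation matrix;
#'   [defaultCompositionCorrelation()] by default.
#' @return data.frame with columns `sample_id`, `CP`, `ADF`, `NDF`.
#' @examples
#' head(sampleCompositions(5, seed = 1))
#' @export
sampleCompositions <- function(n, params = defaultPopulationParams(),
                               seed = NULL,
                               correlation = defaultCompositionCorrelation()) {
  stopifnot(n >= 0)
  cons <- names(params)
  for (p in params) {
    if (p$sd <= 0) stop("sd must be positive")
    if (p$min >= p$max) stop("min must be < max")
  }
  if (!is.null(seed)) set.seed(seed)
  empty <- as.data.frame(c(list(sample_id = character(0)),
                           stats::setNames(rep(list(numeric(0)), length(cons)), cons)))
  if (n == 0) return(empty)
  L <- chol(correlation[cons, cons, drop = FALSE])
  mu <- vapply(params, `[[`, numeric(1), "mean")
  sig <- vapply(params, `[[`, numeric(1), "sd")
  lo <- vapply(params, `[[`, numeric(1), "min")
  hi <- vapply(params, `[[`, numeric(1), "max")
  out <- matrix(NA_real_, n, length(cons), dimnames = list(NULL, cons))
  need <- seq_len(n)
  guard <- 0L
  while (length(need)) {
    z <- matrix(rnorm(length(need) * length(cons)), ncol = length(cons)) %*% L
    x <- sweep(sweep(z, 2, sig, `*`), 2, mu, `+`)
    ok <- rowSums(x < rep(lo, each = nrow(x)) | x > rep(hi, each = nrow(x))) == 0
    out[need[ok], ] <- x[ok, , drop = FALSE]
    need <- need[!ok]
    guard <- guard + 1L
    if (guard > 10000L) stop("rejection sampling failed to converge; ",
                             "check that [min, max] has usable mass")
  }
  data.frame(sample_id = sprintf("S%03d", seq_len(n)), out,
             stringsAsFactors = FALSE)
}

## Fixed Gaussian band tables of the pure-component spectra (centers and
## widths in nm, amplitudes in absorbance units per % DM). Constants are
## frozen so tests are stable. The protein component carries the dominant
## ~1100 nm band; the background/moisture component the ~1450 nm band.
.PURE_BANDS <- list(
  CP = data.frame(center = c(1100, 1190, 1510),
                  width  = c(  40,   60,   50),
                  amp    = c(0.0200, 0.0060, 0.0080)),
  ADF = data.frame(center = c(1210, 1365, 1480),
                   width  = c(  50,   45,   60),
                   amp    = c(0.0040, 0.0025, 0.0015)),
  NDF = data.frame(center = c(1160, 1420, 1540),
                   width  = c(  55,   50,   60),
                   amp    = c(0.0030, 0.0020, 0.0018)),
  background = data.frame(center = c(1450, 1140, 960),
                          width  = c(  45,   50,  80),
                          amp    = c(0.0600, 0.0200, 0.0200))
)

## Baseline model constants: per-sample affine offset in absorbance,
## intercept ~ N(0.12, 0.04) truncated at 0.03, slope rising from 950 nm,
## with a steeper-slope second group emulating the two spectral families
## seen in raw hay spectra.
.BASELINE <- list(interceptMean = 0.12, interceptSd = 0.04, interceptMin = 0.03,
                  slopeMeanGroup1 = 0.06, slopeMeanGroup2 = 0.25)

## Background/moisture concentration distribution (arbitrary units).
.BACKGROUND_CONC <- list(mean = 3, sd = 1.5, min = 0.2)

#' Pure-component absorptivity spectra
#'
#' One spectrum per constituent (CP, ADF, NDF) plus a background/moisture
#' component, each a fixed sum of Gaussian bands on the given grid. The
#' protein spectrum peaks near 1100 nm and the background component near
#' 1450 nm, mimicking the dominant overtone bands of N-H/C-H and O-H
#' groups in hay.
#'
#' @param grid a [spectralGrid()].
#' @return numeric matrix (grid points x 4), columns `CP`, `ADF`, `NDF`,
#'   `background`; units are absorbance per percent DM (per concentration
#'   unit for the background).
#' @examples
#' E <- pureComponentSpectra(spectralGrid())
#' dim(E)  # 141 x 4
#' @export
pureComponentSpectra <- function(grid = spectralGrid()) {
  wl <- grid$axis
  E <- vapply(.PURE_BANDS, function(tab) {
    rowSums(vapply(seq_len(nrow(tab)), function(i)
      tab$amp[i] * exp(-0.5 * ((wl - tab$center[i]) / tab$width[i])^2),
      numeric(length(wl))))
  }, numeric(length(wl)))
  rownames(E) <- wl
  E
}

#' Noise and artefact parameters of the scan model
#'
#' @param additiveSd SD of per-wavelength additive absorbance noise applied
#'   at the sample level (shared by that sample's replicate scans).
#' @param scatterSd SD of the per-replicate multiplicative scatter factor
#'   applied to reflectance.
#' @param replicateSd SD of per-wavelength additive reflectance noise per
#'   replicate scan.
#' @param baselineSlopeSd SD of the per-sample baseline slope around its
#'   group mean (absorbance over the full axis).
#' @param smoothSd SD of the coefficients of the smooth sample-presentation
#'   artifact (a per-sample random combination of broad Gaussian bumps,
#'   emulating packing/particle-size structure that derivative filters
#'   cannot fully remove).
#' @param group2Fraction fraction of samples in the steeper-baseline group.
#' @return list with class `"NoiseParams"`.
#' @export
noiseParams <- function(additiveSd = 0.00016, scatterSd = 0.01,
                        replicateSd = 0.0002, baselineSlopeSd = 0.03,
                        smoothSd = 0, group2Fraction = 0.5) {
  if (any(c(additiveSd, scatterSd, replicateSd, baselineSlopeSd, smoothSd) < 0))
    stop("noise SDs must be >= 0")
  if (group2Fraction < 0 || group2Fraction > 1)
    stop("group2Fraction must lie in [0, 1]")
  structure(list(additiveSd = additiveSd, scatterSd = scatterSd,
                 replicateSd = replicateSd, baselineSlopeSd = baselineSlopeSd,
                 smoothSd = smoothSd, group2Fraction = group2Fraction),
            class = "NoiseParams")
}

## Fixed smooth-artifact basis: broad Gaussian bumps every 30 nm, width
## 40 nm. Per-sample random coefficients on this basis emulate smooth
## sample-presentation structure (packing, particle size) that survives
## derivative filtering.
.smoothBasis <- function(grid) {
  centers <- seq(grid$start, grid$end, by = 30)
  vapply(centers, function(cc) exp(-0.5 * ((grid$axis - cc) / 40)^2),
         numeric(grid$nPoints))
}

#' Synthesize replicate reflectance scans from known chemistry
#'
#' Per sample, the true absorbance is the linear mixture
#' \eqn{A(\lambda) = \sum_k c_k e_k(\lambda)} over the pure-component
#' spectra (the three constituents plus a random background/moisture
#' concentration), optionally plus a per-sample affine baseline whose slope
#' class splits the population into the two spectral groups. Each
#' replicate scan is \eqn{R = 10^{-A}} perturbed by a multiplicative
#' scatter factor and additive noise, clipped to (0, 1].
#'
#' @param compositions data.frame from [sampleCompositions()].
#' @param pure matrix from [pureComponentSpectra()] on the same grid.
#' @param noise a [noiseParams()] object.
#' @param seed integer seed; deterministic given it.
#' @param grid the [spectralGrid()] matching `pure`.
#' @param replicates scans per sample (>= 1); default 3.
#' @param baseline logical; include the affine baseline term (default TRUE).
#' @return An [NIRSpectra-class] object; `S4Vectors::metadata()` carries the
#'   true mixing record (`background`, `baselineIntercept`, `baselineSlope`,
#'   `group` per sample) and the generator parameters.
#' @export
synthesizeReflectance <- function(compositions, pure, noise = noiseParams(),
                                  seed = NULL, grid = spectralGrid(),
                                  replicates = 3, baseline = TRUE) {
  cons <- intersect(colnames(pure), names(compositions))
  if (!all(setdiff(colnames(pure), "background") %in% cons))
    stop("compositions and pure spectra must cover the same constituents")
  C <- as.matrix(compositions[, cons, drop = FALSE])
  if (any(C < 0)) stop("compositions must be non-negative")
  n <- nrow(C)
  if (replicates < 1) stop("need at least one replicate scan")
  if (!is.null(seed)) set.seed(seed)
  wl <- grid$axis
  if (nrow(pure) != length(wl)) stop("pure spectra do not match the grid")

  bg <- .truncnormDraw(n, .BACKGROUND_CONC$mean, .BACKGROUND_CONC$sd,
                       .BACKGROUND_CONC$min)
  conc <- cbind(C, background = bg)
  A_true <- conc %*% t(pure[, colnames(conc), drop = FALSE])  # n x p

  group <- 1L + (runif(n) < noise$group2Fraction)
  if (baseline) {
    b0 <- .truncnormDraw(n, .BASELINE$interceptMean, .BASELINE$interceptSd,
                         .BASELINE$interceptMin)
    slopeMean <- ifelse(group == 2L, .BASELINE$slopeMeanGroup2,
                        .BASELINE$slopeMeanGroup1)
    b1 <- pmax(0, rnorm(n, slopeMean, noise$baselineSlopeSd))
    ramp <- (wl - grid$start) / (grid$end - grid$start)
    A_true <- A_true + outer(b0, rep(1, length(wl))) + outer(b1, ramp)
  } else {
    b0 <- b1 <- rep(0, n)
  }
  if (!is.null(noise$smoothSd) && noise$smoothSd > 0) {
    B <- .smoothBasis(grid)
    A_true <- A_true + matrix(rnorm(n * ncol(B), 0, noise$smoothSd),
                              n, ncol(B)) %*% t(B)
  }
  if (noise$additiveSd > 0)
    A_true <- A_true + matrix(rnorm(n * length(wl), 0, noise$additiveSd),
                              n, length(wl))

  R_true <- 10^(-A_true)
  scans <- matrix(0, length(wl), n * replicates)
  ids <- character(n * replicates)
  rep_no <- integer(n * replicates)
  k <- 0L
  for (i in seq_len(n)) {
    for (r in seq_len(replicates)) {
      k <- k + 1L
      s <- if (noise$scatterSd > 0) 1 + rnorm(1, 0, noise$scatterSd) else 1
      eps <- if (noise$replicateSd > 0)
        rnorm(length(wl), 0, noise$replicateSd) else 0
      Rr <- R_true[i, ] * s + eps
      scans[, k] <- pmin(pmax(Rr, .Machine$double.eps), 1)
      ids[k] <- compositions$sample_id[i]
      rep_no[k] <- r
    }
  }
  chem <- data.frame(sample_id = compositions$sample_id, C,
                     stringsAsFactors = FALSE)
  obj <- NIRSpectra(scans, wl, ids, replicate = rep_no, chemistry = chem,
                    metadata = list(
                      seed = seed, noise = unclass(noise),
                      replicates = replicates, baseline = baseline,
                      mixing = data.frame(
                        sample_id = compositions$sample_id,
                        background = bg, baselineIntercept = b0,
                        baselineSlope = b1, group = group,
                        stringsAsFactors = FALSE)))
  obj
}

## normal(mean, sd) truncated below at `lower` by rejection (sd = 0 allowed:
## degenerates to the mean).
.truncnormDraw <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower)
  guard <- 0L
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower]
    guard <- guard + 1L
    if (guard > 10000L) { x[bad] <- lower; break }
  }
  x
}

#' Generate a complete synthetic hay dataset
#'
#' Composes [sampleCompositions()], [pureComponentSpectra()] and
#' [synthesizeReflectance()] under a single seed. Defaults emulate the
#' survey the package's benchmarks are modelled on: 203 samples, three
#' replicate scans each, 141-point grid from 950 to 1650 nm.
#'
#' @param n number of samples; default 203.
#' @param seed integer seed; the dataset is bit-identical given
#'   (seed, parameters).
#' @param replicates replicate scans per sample; default 3.
#' @param grid a [spectralGrid()].
#' @param params constituent [populationParams()] list.
#' @param noise a [noiseParams()] object.
#' @param correlation constituent correlation matrix.
#' @param baseline include the affine baseline (default TRUE).
#' @return An [NIRSpectra-class]; `S4Vectors::metadata()$provenance` records
#'   every generator parameter.
#' @examples
#' d <- makeDataset(n = 5, seed = 1)
#' dim(reflectance(d))  # 141 x 15
#' @export
makeDataset <- function(n = 203, seed = 1, replicates = 3,
                        grid = spectralGrid(),
                        params = defaultPopulationParams(),
                        noise = noiseParams(),
                        correlation = defaultCompositionCorrelation(),
                        baseline = TRUE) {
  set.seed(seed)
  comp <- sampleCompositions(n, params = params, correlation = correlation)
  pure <- pureComponentSpectra(grid)
  obj <- synthesizeReflectance(comp, pure, noise = noise, grid = grid,
                               replicates = replicates, baseline = baseline)
  md <- S4Vectors::metadata(obj)
  md$seed <- seed
  md$provenance <- list(
    n = n, seed = seed, replicates = replicates,
    grid = grid[c("start", "end", "step")],
    params = lapply(params, unclass),
    noise = unclass(noise),
    correlation = correlation, baseline = baseline,
    package = "hayNIRS",
    version = as.character(utils::packageVersion("hayNIRS")))
  S4Vectors::metadata(obj) <- md
  obj
}
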