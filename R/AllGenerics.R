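#' @name hayNIRS-generics
#' @title Accessor generics for hayNIRS classes
#' @description Small accessor generics following Bioconductor conventions:
#'   slot access goes through these, never through `@`.
#' @param x,object an object from this package.
#' @param ... passed to methods.
NULL

#' @rdname hayNIRS-generics
#' @return `wavelengths()`: the wavelength axis in nm.
#' @export
setGeneric("wavelengths", function(x, ...) standardGeneric("wavelengths"))

#' @rdname hayNIRS-generics
#' @return `reflectance()`: the reflectance matrix (wavelengths x scans).
#' @export
setGeneric("reflectance", function(x, ...) standardGeneric("reflectance"))

#' @rdname hayNIRS-generics
#' @return `sampleIds()`: unique sample ids in column order.
#' @export
setGeneric("sampleIds", function(x, ...) standardGeneric("sampleIds"))

#' @rdname hayNIRS-generics
#' @return `chemistry()`: one-row-per-sample data.frame of reference values.
#' @export
setGeneric("chemistry", function(x, ...) standardGeneric("chemistry"))

#' @rdname hayNIRS-generics
#' @return `averageReplicates()`: an object with one spectrum per sample.
#' @export
setGeneric("averageReplicates", function(x, ...) standardGeneric("averageReplicates"))

#' @rdname hayNIRS-generics
#' @return `preprocessSpectra()`: list with the model matrix and trimmed axis.
#' @param config a [PreprocessConfig-class].
#' @export
setGeneric("preprocessSpectra", function(x, config, ...) standardGeneric("preprocessSpectra"))

#' @rdname hayNIRS-generics
#' @return `outlierFlags()`: logical flag vector of an [OutlierReport-class].
#' @export
setGeneric("outlierFlags", function(x, ...) standardGeneric("outlierFlags"))

#' @rdname hayNIRS-generics
#' @return `distances()`: Mahalanobis distances of an [OutlierReport-class].
#' @export
setGeneric("distances", function(x, ...) standardGeneric("distances"))
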