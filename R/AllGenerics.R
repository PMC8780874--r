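#' @import methods
NULL

#' Wavelength grid of a spectral object
#'
#' @param x a \linkS4class{SpectraSet}, \linkS4class{PCAModel} or
#'   \linkS4class{PLSModel}.
#' @return Numeric vector of wavelengths in nm, strictly increasing and
#'   evenly spaced.
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' Absorbance matrix of a SpectraSet
#'
#' @param x a \linkS4class{SpectraSet}.
#' @return Numeric matrix with one row per spectrum and one column per
#'   wavelength (columns named by nm value).
#' @export
setGeneric("absorbance", function(x) standardGeneric("absorbance"))

#' Per-spectrum sample metadata
#'
#' @param x a \linkS4class{SpectraSet}.
#' @return A \link[S4Vectors]{DataFrame} with columns \code{sample_id},
#'   \code{variety}, \code{robusta_fraction}, \code{form},
#'   \code{replicate}, \code{refill}, \code{scan}.
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' Number of spectra in an object
#' @param x a \linkS4class{SpectraSet}.
#' @return Integer count of spectra (rows of the absorbance matrix).
#' @export
setGeneric("nSpectra", function(x) standardGeneric("nSpectra"))

#' Project spectra onto a fitted low-dimensional model
#'
#' @param model a fitted \linkS4class{PCAModel}.
#' @param x a \linkS4class{SpectraSet} on the model's wavelength grid.
#' @return Numeric score matrix, one row per spectrum.
#' @export
setGeneric("projectScores", function(model, x) standardGeneric("projectScores"))
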