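#' SpectraSet: NIR absorbance spectra with hierarchical sample metadata
#'
#' A \code{SpectraSet} holds a block of absorbance spectra acquired on a
#' common, evenly spaced wavelength grid, together with per-spectrum sample
#' metadata describing the acquisition hierarchy (sample type, replicate,
#' refill, consecutive scan) and, for blend studies, the adulterant mass
#' fraction in \% w/w.
#'
#' The class extends \link[SummarizedExperiment]{SummarizedExperiment}:
#' wavelengths are features (rows of the assay), spectra are samples
#' (columns).  User-facing accessors present the chemometric orientation,
#' i.e. \code{absorbance(x)} is an N spectra x P wavelengths matrix.
#'
#' @slot ... see \link[SummarizedExperiment]{SummarizedExperiment}; the
#'   single assay is named \code{"absorbance"} and
#'   \code{rowData(x)$wavelength_nm} stores the grid.
#'
#' @section Validity:
#' \itemize{
#'   \item at least one spectrum; no missing absorbance values;
#'   \item wavelengths strictly increasing and evenly spaced (the grid step
#'     is constant to within a relative tolerance of 1e-6);
#'   \item metadata columns \code{sample_id}, \code{variety},
#'     \code{robusta_fraction}, \code{form}, \code{replicate},
#'     \code{refill}, \code{scan} present;
#'   \item \code{robusta_fraction} within [0, 100].
#' }
#'
#' @seealso \code{\link{readSpectra}}, \code{\link{generateMixtureDataset}}
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @export
setClass("SpectraSet", contains = "SummarizedExperiment")

.META_COLS <- c("sample_id", "variety", "robusta_fraction", "form",
                "replicate", "refill", "scan")

.check_grid <- function(w) {
  if (length(w) < 1L || anyNA(w))
    return("wavelength grid must be non-empty and free of NAs")
  if (length(w) >= 2L) {
    d <- diff(w)
    if (any(d <= 0))
      return("wavelengths must be strictly increasing")
    step <- d[1L]
    if (any(abs(d - step) > 1e-6 * step))
      return(sprintf(
        "wavelengths must be evenly spaced (grid error): steps range %g-%g nm",
        min(d), max(d)))
  }
  NULL
}

setValidity("SpectraSet", function(object) {
  msgs <- character()
  if (ncol(object) < 1L)
    msgs <- c(msgs, "a SpectraSet must contain at least one spectrum")
  if (!"absorbance" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'absorbance' is missing")
  else if (anyNA(SummarizedExperiment::assay(object, "absorbance")))
    msgs <- c(msgs, "absorbance values must not be missing")
  rd <- SummarizedExperiment::rowData(object)
  if (!"wavelength_nm" %in% colnames(rd)) {
    msgs <- c(msgs, "rowData column 'wavelength_nm' is missing")
  } else {
    g <- .check_grid(rd$wavelength_nm)
    if (!is.null(g)) msgs <- c(msgs, g)
  }
  cd <- SummarizedExperiment::colData(object)
  missing_cols <- setdiff(.META_COLS, colnames(cd))
  if (length(missing_cols))
    msgs <- c(msgs, paste0("metadata column(s) missing: ",
                           paste(missing_cols, collapse = ", ")))
  if ("robusta_fraction" %in% colnames(cd)) {
    f <- cd$robusta_fraction
    if (anyNA(f) || any(f < 0 | f > 100))
      msgs <- c(msgs, "robusta_fraction must lie within [0, 100]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a SpectraSet
#'
#' @param absorbance numeric matrix, N spectra (rows) x P wavelengths
#'   (columns).  A single spectrum may be given as a vector.
#' @param wavelength numeric vector of P wavelengths in nm, strictly
#'   increasing and evenly spaced.
#' @param meta optional data.frame (or DataFrame) of N rows with columns
#'   \code{sample_id}, \code{variety}, \code{robusta_fraction},
#'   \code{form}, \code{replicate}, \code{refill}, \code{scan}.  Missing
#'   columns are filled with neutral defaults so that small ad-hoc blocks
#'   are easy to build.
#' @return a \linkS4class{SpectraSet}.
#' @examples
#' s <- SpectraSet(matrix(runif(20), 4, 5), wavelength = seq(1300, 1308, 2))
#' nSpectra(s)
#' @importFrom S4Vectors DataFrame
#' @export
SpectraSet <- function(absorbance, wavelength, meta = NULL) {
  if (is.vector(absorbance)) absorbance <- matrix(absorbance, nrow = 1L)
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  dimnames(absorbance) <- NULL
  n <- nrow(absorbance)
  if (ncol(absorbance) != length(wavelength))
    stop("ncol(absorbance) [", ncol(absorbance),
         "] must equal length(wavelength) [", length(wavelength), "]")
  if (is.null(meta)) meta <- S4Vectors::DataFrame(row.names = seq_len(n))
  meta <- S4Vectors::DataFrame(meta)
  if (nrow(meta) != n)
    stop("meta must have one row per spectrum")
  defaults <- list(sample_id = paste0("S", seq_len(n)), variety = "UNKNOWN",
                   robusta_fraction = 0, form = "liquid",
                   replicate = 1L, refill = 1L, scan = seq_len(n))
  for (col in .META_COLS)
    if (!col %in% colnames(meta)) meta[[col]] <- rep(defaults[[col]],
                                                     length.out = n)
  meta <- meta[, .META_COLS, drop = FALSE]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(absorbance = t(absorbance)),
    rowData = S4Vectors::DataFrame(wavelength_nm = as.numeric(wavelength)),
    colData = meta)
  colnames(se) <- make.unique(as.character(meta$sample_id))
  rownames(se) <- format(wavelength, trim = TRUE, scientific = FALSE)
  new("SpectraSet", se)
}

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "SpectraSet", function(x)
  as.numeric(SummarizedExperiment::rowData(x)$wavelength_nm))

#' @rdname absorbance
#' @export
setMethod("absorbance", "SpectraSet", function(x) {
  m <- t(SummarizedExperiment::assay(x, "absorbance"))
  dimnames(m) <- list(colnames(x), rownames(x))
  m
})

#' @rdname sampleData
#' @export
setMethod("sampleData", "SpectraSet", function(x)
  SummarizedExperiment::colData(x)[, .META_COLS, drop = FALSE])

#' @rdname nSpectra
#' @export
setMethod("nSpectra", "SpectraSet", function(x) ncol(x))

#' Grid spacing of a SpectraSet in nm
#' @param x a \linkS4class{SpectraSet}.
#' @return the (constant) wavelength step in nm; \code{NA} for a
#'   single-wavelength grid.
#' @export
gridStep <- function(x) {
  w <- wavelengths(x)
  if (length(w) < 2L) NA_real_ else w[2L] - w[1L]
}

#' Subset the spectra of a SpectraSet
#'
#' @param x a \linkS4class{SpectraSet}
#' @param i logical/integer index over spectra (rows of
#'   \code{absorbance(x)})
#' @return a \linkS4class{SpectraSet} with the selected spectra.
#' @export
selectSpectra <- function(x, i) {
  stopifnot(is(x, "SpectraSet"))
  x[, i]
}

#' Replace the absorbance matrix, keeping metadata
#'
#' Internal helper used by all row-wise preprocessing transforms.
#' @noRd
.with_absorbance <- function(x, m, wavelength = wavelengths(x)) {
  out <- SpectraSet(m, wavelength, meta = sampleData(x))
  S4Vectors::metadata(out) <- S4Vectors::metadata(x)
  out
}

setMethod("show", "SpectraSet", function(object) {
  w <- wavelengths(object)
  cat("SpectraSet with", ncol(object), "spectra x", nrow(object),
      "wavelengths\n")
  cat(sprintf("  grid: %g-%g nm, step %g nm\n", min(w), max(w),
              if (length(w) > 1) w[2] - w[1] else NA))
  v <- table(sampleData(object)$variety)
  cat("  sample types:", paste0(names(v), " (", v, ")", collapse = ", "),
      "\n")
  steps <- S4Vectors::metadata(object)$preprocessing
  if (length(steps))
    cat("  preprocessing:", paste(vapply(steps, `[[`, "", "name"),
                                  collapse = " | "), "\n")
  invisible(object)
})
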