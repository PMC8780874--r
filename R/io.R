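#' Read a wide-format spectra CSV
#'
#' The expected layout is one header row naming the seven metadata
#' columns (\code{sample_id}, \code{variety}, \code{robusta_fraction},
#' \code{form}, \code{replicate}, \code{refill}, \code{scan}) followed by
#' one numeric column per wavelength, named by its nm value in increasing
#' order.  The wavelength grid is inferred from the headers and must be
#' evenly spaced.
#'
#' @param path path to a CSV file.
#' @return a \linkS4class{SpectraSet}; row order is preserved.
#' @seealso \code{\link{writeSpectra}}
#' @export
readSpectra <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  missing_cols <- setdiff(.META_COLS, colnames(df))
  if (length(missing_cols))
    stop("format error: missing metadata column(s): ",
         paste(missing_cols, collapse = ", "))
  wcols <- setdiff(colnames(df), .META_COLS)
  w <- suppressWarnings(as.numeric(wcols))
  if (anyNA(w))
    stop("format error: non-numeric wavelength column(s): ",
         paste(wcols[is.na(w)], collapse = ", "))
  g <- .check_grid(w)
  if (!is.null(g)) stop("grid error: ", g)
  A <- as.matrix(df[, wcols, drop = FALSE])
  storage.mode(A) <- "double"
  SpectraSet(A, w, meta = df[, .META_COLS, drop = FALSE])
}

#' Write a SpectraSet as a wide-format CSV
#'
#' Metadata columns come first, then one column per wavelength named by
#' its nm value.  Absorbances are written with full double precision
#' (15 significant digits) so that a write/read round trip is lossless
#' for practical purposes.
#'
#' @param x a \linkS4class{SpectraSet}.
#' @param path destination path.
#' @return \code{path}, invisibly.
#' @export
writeSpectra <- function(x, path) {
  stopifnot(is(x, "SpectraSet"))
  meta <- as.data.frame(sampleData(x))
  A <- absorbance(x)
  colnames(A) <- format(wavelengths(x), trim = TRUE, scientific = FALSE)
  out <- cbind(meta, as.data.frame(A, optional = TRUE))
  rownames(out) <- NULL
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("I/O error writing ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}
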