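#' Water matrix coordinate (WAMAC) wavelengths
#'
#' The characteristic wavelengths at which specific water molecular
#' conformations absorb: 11 coordinates in the second OH overtone
#' (890-1060 nm) and 12 in the first overtone (1342-1512 nm).
#'
#' @param overtone "first" or "second".
#' @return numeric vector of wavelengths in nm.
#' @export
defaultWamacs <- function(overtone = c("second", "first")) {
  overtone <- match.arg(overtone)
  switch(overtone,
    second = c(890, 908, 924, 946, 954, 975, 1001, 1019, 1036, 1044,
               1060),
    first = c(1342, 1364, 1374, 1384, 1412, 1426, 1440, 1452, 1462,
              1476, 1488, 1512))
}

.OVERTONE_RANGE <- list(first = c(1300, 1600), second = c(800, 1100))

#' AquagramSpec: configuration of an aquagram computation
#'
#' @slot overtone "first" (1300-1600 nm) or "second" (800-1100 nm).
#' @slot wamacs WAMAC wavelengths, all within the overtone range.
#' @slot preprocessing the \linkS4class{PreprocessSpec} applied before
#'   standardization.
#' @export
setClass("AquagramSpec",
  representation(overtone = "character", wamacs = "numeric",
                 preprocessing = "PreprocessSpec"))

setValidity("AquagramSpec", function(object) {
  if (!object@overtone %in% names(.OVERTONE_RANGE))
    return("overtone must be 'first' or 'second'")
  rng <- .OVERTONE_RANGE[[object@overtone]]
  if (any(object@wamacs < rng[1L] | object@wamacs > rng[2L]))
    return(sprintf("all WAMACs must lie within the %s overtone range %g-%g nm",
                   object@overtone, rng[1L], rng[2L]))
  TRUE
})

#' @rdname AquagramSpec-class
#' @param overtone "first" or "second".
#' @param wamacs WAMAC wavelengths (defaults to
#'   \code{\link{defaultWamacs}}).
#' @param preprocessing chain applied before standardization; the
#'   default truncates to the overtone range, smooths with
#'   Savitzky-Golay (window 19, order 2) and applies MSC against the
#'   mean spectrum.
#' @return an \linkS4class{AquagramSpec}.
#' @export
aquagramSpec <- function(overtone = c("second", "first"),
                         wamacs = defaultWamacs(overtone),
                         preprocessing = NULL) {
  overtone <- match.arg(overtone)
  if (is.null(preprocessing)) {
    rng <- .OVERTONE_RANGE[[overtone]]
    preprocessing <- preprocessSpec(
      list(name = "truncate", lo = rng[1L], hi = rng[2L]),
      list(name = "savgol", window = 19, polyorder = 2, deriv = 0),
      list(name = "msc", reference = "mean"))
  }
  if (is.character(preprocessing)) preprocessing <- parseChain(preprocessing)
  new("AquagramSpec", overtone = overtone, wamacs = wamacs,
      preprocessing = preprocessing)
}

#' Compute a classical aquagram (water absorption spectral pattern)
#'
#' After the configured preprocessing chain, every wavelength is z-scored
#' across ALL rows passed in — \code{z = (A - mu_lambda)/sigma_lambda}
#' with the sample s.d. — and each group's mean z at each WAMAC (nearest
#' grid point) is reported.  The standardization population is exactly
#' the rows passed in, so changing the displayed sample set changes the
#' pattern, as it does when different figure subsets are plotted.
#'
#' @param x a \linkS4class{SpectraSet} covering the overtone range, with
#'   >= 2 spectra.
#' @param groupKey metadata column(s) defining the displayed groups
#'   (default "variety").
#' @param spec an \linkS4class{AquagramSpec}; default second overtone.
#' @return an \linkS4class{AquagramResult}.
#' @export
computeAquagram <- function(x, groupKey = "variety",
                            spec = aquagramSpec("second")) {
  stopifnot(is(x, "SpectraSet"))
  validObject(spec)
  if (nSpectra(x) < 2L)
    stop("an aquagram needs at least 2 spectra")
  pre <- applyChain(x, spec@preprocessing)
  w <- wavelengths(pre)
  idx <- vapply(spec@wamacs, function(wm) {
    if (wm < min(w) - gridStep(pre) / 2 || wm > max(w) + gridStep(pre) / 2)
      stop("coverage error: WAMAC ", wm,
           " nm lies outside the processed grid (", min(w), "-", max(w),
           " nm)")
    which.min(abs(w - wm))
  }, integer(1L))
  A <- absorbance(pre)
  sdv <- apply(A, 2L, stats::sd)
  Z <- sweep(A, 2L, colMeans(A))
  nz <- sdv > 0
  Z[, nz] <- sweep(Z[, nz, drop = FALSE], 2L, sdv[nz], "/")
  Z[, !nz] <- 0  # no variation at this wavelength: pattern value 0
  meta <- as.data.frame(sampleData(pre))
  grp <- interaction(meta[groupKey], drop = TRUE, lex.order = TRUE)
  grp <- factor(grp, levels = unique(grp))
  vals <- rowsum(Z[, idx, drop = FALSE], grp, reorder = FALSE) /
    as.integer(table(grp)[levels(grp)])
  dimnames(vals) <- list(levels(grp), format(spec@wamacs, trim = TRUE))
  new("AquagramResult", groups = levels(grp), wamacs = spec@wamacs,
      gridWamacs = w[idx], values = as.matrix(vals),
      nPerGroup = as.integer(table(grp)[levels(grp)]))
}

#' Export an aquagram as tidy CSV
#'
#' One row per (group, WAMAC): columns \code{group},
#' \code{wavelength_nm}, \code{value}, \code{n}.
#'
#' @param result an \linkS4class{AquagramResult}.
#' @param path destination CSV path.
#' @return \code{path}, invisibly.
#' @export
exportAquagram <- function(result, path) {
  stopifnot(is(result, "AquagramResult"))
  if (!length(result@groups)) stop("empty aquagram result")
  df <- data.frame(
    group = rep(result@groups, times = length(result@wamacs)),
    wavelength_nm = rep(result@wamacs, each = length(result@groups)),
    value = as.vector(result@values),
    n = rep(result@nPerGroup, times = length(result@wamacs)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
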