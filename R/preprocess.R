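#' @importFrom S4Vectors metadata metadata<-
NULL

.add_prov <- function(x, name, params = list()) {
  prov <- S4Vectors::metadata(x)$preprocessing
  S4Vectors::metadata(x)$preprocessing <- c(prov,
                                            list(c(list(name = name), params)))
  x
}

#' Truncate a SpectraSet to a wavelength range
#'
#' Keeps the columns with \code{lo <= lambda <= hi} (inclusive); sample
#' metadata is unchanged.  Typical ranges: 800-1670 nm (noise
#' reduction), 1300-1600 nm (first OH overtone), 800-1100 nm (second OH
#' overtone).
#'
#' @param x a \linkS4class{SpectraSet}.
#' @param lo,hi range bounds in nm.
#' @return the truncated \linkS4class{SpectraSet}.
#' @export
truncateSpectra <- function(x, lo, hi) {
  stopifnot(is(x, "SpectraSet"), lo <= hi)
  keep <- which(wavelengths(x) >= lo & wavelengths(x) <= hi)
  if (!length(keep))
    stop("range error: no wavelengths within [", lo, ", ", hi, "] nm")
  out <- .with_absorbance(x, absorbance(x)[, keep, drop = FALSE],
                          wavelengths(x)[keep])
  .add_prov(out, "truncate", list(lo = lo, hi = hi))
}

#' Savitzky-Golay smoothing and derivatives
#'
#' Fits a local polynomial of degree \code{polyorder} in a centered
#' window of \code{window} points and evaluates its value
#' (\code{deriv = 0}) or derivative at the window center.  Derivatives
#' are returned in per-nm units (the per-index derivative is divided by
#' \code{step^deriv}), so regression vectors stay comparable across
#' grids.  The \code{(window - 1)/2} edge columns on each side have no
#' centered window and are dropped; the grid shrinks accordingly.
#'
#' @param x a \linkS4class{SpectraSet}.
#' @param window odd window width in points (the study screened 11, 17
#'   and 19).
#' @param polyorder polynomial degree, < window (default 2).
#' @param deriv derivative order 0, 1 or 2; must be <= polyorder.
#' @return the filtered \linkS4class{SpectraSet} on the shortened grid.
#' @export
savgolFilter <- function(x, window, polyorder = 2, deriv = 0) {
  stopifnot(is(x, "SpectraSet"))
  if (window %% 2 != 1 || window < polyorder + 1)
    stop("parameter error: window must be odd and >= polyorder + 1")
  if (deriv > polyorder)
    stop("parameter error: deriv must be <= polyorder")
  p <- length(wavelengths(x))
  if (window > p)
    stop("parameter error: window (", window, ") exceeds grid length (",
         p, ")")
  k <- (window - 1L) / 2L
  co <- signal::sgolay(p = polyorder, n = window, m = deriv)[k + 1L, ]
  A <- absorbance(x)
  keep <- (k + 1L):(p - k)
  out <- matrix(0, nrow(A), length(keep))
  for (j in seq_along(keep))
    out[, j] <- A[, (keep[j] - k):(keep[j] + k), drop = FALSE] %*% co
  if (deriv > 0) out <- out / gridStep(x)^deriv
  res <- .with_absorbance(x, out, wavelengths(x)[keep])
  .add_prov(res, "savgol",
            list(window = window, polyorder = polyorder, deriv = deriv))
}

.msc_core <- function(A, ref) {
  refc <- ref - mean(ref)
  vr <- sum(refc^2)
  rowm <- rowMeans(A)
  b <- as.numeric((A - rowm) %*% refc) / vr
  bad <- which(abs(b) < 1e-8)
  if (length(bad))
    stop("degenerate-row error: slope on reference ~ 0 for row(s) ",
         paste(bad, collapse = ", "))
  a <- rowm - b * mean(ref)
  (A - a) / b
}

#' Multiplicative scatter correction
#'
#' Each spectrum is regressed on a reference spectrum by ordinary least
#' squares, \code{A_i ~ a_i + b_i * ref}, and corrected as \code{(A_i -
#' a_i)/b_i}, removing per-spectrum additive and multiplicative scatter.
#' With \code{reference = "mean"} the reference is the mean spectrum of
#' the block being corrected; the fitted reference is stored in the
#' result (see \code{\link{mscReference}}) so that validation data can be
#' corrected against the calibration reference rather than its own mean.
#'
#' @param x a \linkS4class{SpectraSet} (>= 2 spectra when
#'   \code{reference = "mean"}).
#' @param reference \code{"mean"} or a numeric vector of length
#'   \code{ncol(absorbance(x))}.
#' @return the corrected \linkS4class{SpectraSet}, with the reference
#'   used stored in its metadata.
#' @export
mscCorrect <- function(x, reference = "mean") {
  stopifnot(is(x, "SpectraSet"))
  A <- absorbance(x)
  if (identical(reference, "mean")) {
    if (nrow(A) < 2L)
      stop("msc with reference='mean' needs at least 2 spectra")
    ref <- colMeans(A)
  } else {
    ref <- as.numeric(reference)
    if (length(ref) != ncol(A))
      stop("reference length (", length(ref),
           ") must equal the number of wavelengths (", ncol(A), ")")
  }
  out <- .with_absorbance(x, .msc_core(A, ref))
  S4Vectors::metadata(out)$mscReference <- ref
  .add_prov(out, "msc", list(reference = if (identical(reference, "mean"))
    "mean" else "fixed"))
}

#' Reference spectrum used by the last MSC step
#' @param x a \linkS4class{SpectraSet} returned by
#'   \code{\link{mscCorrect}} (or a chain containing an msc step).
#' @return numeric reference spectrum, or NULL if none stored.
#' @export
mscReference <- function(x) S4Vectors::metadata(x)$mscReference

#' Standard normal variate
#'
#' Row-wise standardization: each spectrum is centered to mean 0 and
#' scaled to sample standard deviation 1 (denominator n - 1).
#'
#' @param x a \linkS4class{SpectraSet}; every row must have nonzero
#'   variance.
#' @return the transformed \linkS4class{SpectraSet}.
#' @export
snvScale <- function(x) {
  stopifnot(is(x, "SpectraSet"))
  A <- absorbance(x)
  s <- apply(A, 1L, stats::sd)
  bad <- which(s < .Machine$double.eps * 100)
  if (length(bad))
    stop("degenerate-row error: constant spectrum in row(s) ",
         paste(bad, collapse = ", "))
  .add_prov(.with_absorbance(x, (A - rowMeans(A)) / s), "snv")
}

#' Detrend: per-spectrum polynomial baseline removal
#'
#' Subtracts from each spectrum its least-squares polynomial of the
#' given degree in wavelength.  Degree 2 is the classical NIR detrend.
#'
#' @param x a \linkS4class{SpectraSet}.
#' @param degree polynomial degree >= 1 (default 2); must be < number of
#'   wavelengths.
#' @return the detrended \linkS4class{SpectraSet}.
#' @export
detrendSpectra <- function(x, degree = 2) {
  stopifnot(is(x, "SpectraSet"), degree >= 1)
  w <- wavelengths(x)
  if (degree >= length(w))
    stop("parameter error: degree must be < number of wavelengths")
  A <- absorbance(x)
  B <- cbind(1 / sqrt(length(w)), stats::poly(w, degree))  # orthonormal
  out <- A - (A %*% B) %*% t(B)
  .add_prov(.with_absorbance(x, out), "detrend", list(degree = degree))
}

#' Average spectra over the acquisition hierarchy
#'
#' Collapses the lowest level(s) of the (replicate, refill, scan)
#' hierarchy by arithmetic mean within each sample type:
#' \code{level = "scan"} averages the consecutive scans of each refill,
#' \code{"refill"} additionally averages over refills, and
#' \code{"replicate"} collapses everything to one spectrum per sample
#' type.  \code{variety} and \code{robusta_fraction} are preserved;
#' collapsed indices are reset to 1.
#'
#' @param x a \linkS4class{SpectraSet}.
#' @param level "scan", "refill" or "replicate".
#' @return the averaged \linkS4class{SpectraSet}.
#' @export
averageSpectra <- function(x, level = c("scan", "refill", "replicate")) {
  level <- match.arg(level)
  meta <- as.data.frame(sampleData(x))
  keys <- switch(level,
    scan = c("variety", "robusta_fraction", "form", "replicate", "refill"),
    refill = c("variety", "robusta_fraction", "form", "replicate"),
    replicate = c("variety", "robusta_fraction", "form"))
  grp <- interaction(meta[keys], drop = TRUE, lex.order = TRUE)
  grp <- factor(grp, levels = unique(grp))  # keep first-appearance order
  A <- absorbance(x)
  sums <- rowsum(A, grp, reorder = FALSE)
  counts <- as.integer(table(grp)[levels(grp)])
  M <- sums / counts
  first <- match(levels(grp), grp)
  newmeta <- meta[first, , drop = FALSE]
  if (level %in% c("scan", "refill", "replicate")) newmeta$scan <- 1L
  if (level %in% c("refill", "replicate")) newmeta$refill <- 1L
  if (level == "replicate") newmeta$replicate <- 1L
  newmeta$sample_id <- sprintf("%s_r%d_f%d_s%d", newmeta$variety,
                               newmeta$replicate, newmeta$refill,
                               newmeta$scan)
  out <- SpectraSet(M, wavelengths(x), meta = newmeta)
  S4Vectors::metadata(out) <- S4Vectors::metadata(x)
  .add_prov(out, "average", list(level = level))
}

#' PreprocessSpec: an ordered preprocessing chain
#'
#' @slot steps list of steps, each a list with a \code{name} in
#'   \{truncate, savgol, msc, snv, detrend, average\} plus that step's
#'   parameters.
#' @export
setClass("PreprocessSpec", representation(steps = "list"),
         prototype(steps = list()))

.STEP_NAMES <- c("truncate", "savgol", "msc", "snv", "detrend", "average")

setValidity("PreprocessSpec", function(object) {
  for (s in object@steps) {
    if (!is.list(s) || is.null(s$name) || !s$name %in% .STEP_NAMES)
      return(paste("unknown preprocessing step:",
                   if (is.list(s)) s$name else "<malformed>"))
    if (s$name == "savgol" &&
        (s$window %% 2 != 1 || s$window < s$polyorder + 1))
      return("savgol window must be odd and >= polyorder + 1")
    if (s$name == "average" &&
        !s$level %in% c("scan", "refill", "replicate"))
      return("average level must be scan, refill or replicate")
  }
  TRUE
})

#' @rdname PreprocessSpec-class
#' @param ... steps, each a list such as
#'   \code{list(name = "savgol", window = 19, polyorder = 2, deriv = 1)}.
#' @return a \linkS4class{PreprocessSpec}.
#' @export
preprocessSpec <- function(...) new("PreprocessSpec", steps = list(...))

#' Parse a compact chain string into a PreprocessSpec
#'
#' Steps are separated by \code{"|"}; parameters follow the step name
#' after \code{":"}, comma-separated, e.g.
#' \code{"truncate:1300,1600|savgol:19,2,1|snv"}.
#'
#' @param chain a chain string.
#' @return a \linkS4class{PreprocessSpec}.
#' @export
parseChain <- function(chain) {
  parts <- strsplit(chain, "|", fixed = TRUE)[[1L]]
  steps <- lapply(parts, function(p) {
    bits <- strsplit(p, ":", fixed = TRUE)[[1L]]
    name <- trimws(bits[1L])
    args <- if (length(bits) > 1L)
      strsplit(bits[2L], ",", fixed = TRUE)[[1L]] else character()
    switch(name,
      truncate = list(name = name, lo = as.numeric(args[1L]),
                      hi = as.numeric(args[2L])),
      savgol = list(name = name, window = as.numeric(args[1L]),
                    polyorder = if (length(args) > 1L)
                      as.numeric(args[2L]) else 2,
                    deriv = if (length(args) > 2L)
                      as.numeric(args[3L]) else 0),
      msc = list(name = name, reference = "mean"),
      snv = list(name = name),
      detrend = list(name = name, degree = if (length(args))
        as.numeric(args[1L]) else 2),
      average = list(name = name, level = args[1L]),
      stop("unknown preprocessing step: ", name))
  })
  do.call(preprocessSpec, steps)
}

# Apply one step; `artifact` carries fold-fitted state (msc reference).
# Returns list(block, artifact).
.apply_step <- function(x, s, artifact = NULL) {
  switch(s$name,
    truncate = list(block = truncateSpectra(x, s$lo, s$hi),
                    artifact = NULL),
    savgol = list(block = savgolFilter(x, s$window, s$polyorder, s$deriv),
                  artifact = NULL),
    msc = {
      ref <- if (!is.null(artifact)) artifact
      else if (!identical(s$reference, "mean")) s$reference
      out <- if (is.null(ref)) mscCorrect(x, "mean")
      else mscCorrect(x, ref)
      list(block = out, artifact = mscReference(out))
    },
    snv = list(block = snvScale(x), artifact = NULL),
    detrend = list(block = detrendSpectra(x, s$degree), artifact = NULL),
    average = list(block = averageSpectra(x, s$level), artifact = NULL))
}

# Fit-and-apply a chain; returns list(block, artifacts) where artifacts
# can be replayed on new data via .chain_apply (prevents leakage of
# learned references into validation folds).
.chain_fit <- function(x, spec) {
  validObject(spec)
  artifacts <- vector("list", length(spec@steps))
  for (i in seq_along(spec@steps)) {
    r <- .apply_step(x, spec@steps[[i]])
    x <- r$block
    artifacts[[i]] <- r$artifact
  }
  list(block = x, artifacts = artifacts)
}

.chain_apply <- function(x, spec, artifacts) {
  for (i in seq_along(spec@steps))
    x <- .apply_step(x, spec@steps[[i]], artifacts[[i]])$block
  x
}

#' Apply an ordered preprocessing chain
#'
#' Steps are applied in the listed order; the chain is recorded in the
#' result's provenance metadata, and any fitted MSC reference is stored
#' so validation data can be corrected consistently (see
#' \code{\link{mscReference}}).
#'
#' @param x a \linkS4class{SpectraSet}.
#' @param spec a \linkS4class{PreprocessSpec} or chain string accepted by
#'   \code{\link{parseChain}}.
#' @return the preprocessed \linkS4class{SpectraSet}.
#' @examples
#' d <- generateMixtureDataset(noise = noisePreset("low", seed = 1))
#' p <- applyChain(d, "truncate:1300,1600|savgol:19,2,1")
#' @export
applyChain <- function(x, spec) {
  if (is.character(spec)) spec <- parseChain(spec)
  .chain_fit(x, spec)$block
}
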