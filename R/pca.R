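#' Fit principal components to a spectra block
#'
#' Mean-centers the N x P absorbance matrix (no column scaling: spectra
#' share units) and takes its singular value decomposition; the loadings
#' are the leading right singular vectors.  The sign of each loading is
#' fixed so that its largest-magnitude element is positive, making
#' fitted models reproducible across platforms.
#'
#' @param x a \linkS4class{SpectraSet}.
#' @param nComponents number of components K, \code{<= min(N - 1, P)}.
#' @return a \linkS4class{PCAModel}.
#' @export
fitPCA <- function(x, nComponents) {
  stopifnot(is(x, "SpectraSet"))
  A <- absorbance(x)
  n <- nrow(A); p <- ncol(A)
  kmax <- min(n - 1L, p)
  if (nComponents < 1L || nComponents > kmax)
    stop("parameter error: nComponents must lie in [1, ", kmax, "]")
  ctr <- colMeans(A)
  Xc <- sweep(A, 2L, ctr)
  sv <- svd(Xc, nu = 0, nv = nComponents)
  L <- sv$v
  for (k in seq_len(ncol(L))) {
    i <- which.max(abs(L[, k]))
    if (L[i, k] < 0) L[, k] <- -L[, k]
  }
  tot <- sum(sv$d^2)
  evr <- if (tot > 0) sv$d[seq_len(nComponents)]^2 / tot
         else rep(0, nComponents)
  rownames(L) <- format(wavelengths(x), trim = TRUE, scientific = FALSE)
  new("PCAModel", center = ctr, loadings = L,
      explainedVarianceRatio = evr,
      nComponents = as.integer(nComponents), wavelength = wavelengths(x))
}

#' @describeIn fitPCA project spectra onto a fitted model:
#'   \code{scores = (A - center) loadings}.  The block's grid must match
#'   the fitting grid.
#' @param model a \linkS4class{PCAModel}.
#' @export
setMethod("projectScores", signature("PCAModel", "SpectraSet"),
  function(model, x) {
    w <- wavelengths(x)
    if (length(w) != length(model@wavelength) ||
        max(abs(w - model@wavelength)) > 1e-9)
      stop("dimension error: wavelength grid does not match the model's")
    sweep(absorbance(x), 2L, model@center) %*% model@loadings
  })

#' Reconstruct spectra from PCA scores
#'
#' @param model a \linkS4class{PCAModel}.
#' @param scores N x K score matrix.
#' @return N x P absorbance matrix \code{scores \%*\% t(loadings) +
#'   center}.
#' @export
reconstructSpectra <- function(model, scores) {
  sweep(scores %*% t(model@loadings), 2L, model@center, `+`)
}
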