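#' Coefficient of determination
#'
#' \code{1 - sum((y - yhat)^2) / sum((y - mean(y))^2)}.
#'
#' @param y observed values; must vary.
#' @param yhat predictions, same length.
#' @return scalar R-squared.
#' @export
rSquared <- function(y, yhat) {
  stopifnot(length(y) == length(yhat))
  tss <- sum((y - mean(y))^2)
  if (tss <= 0) stop("degenerate error: y is constant")
  1 - sum((y - yhat)^2) / tss
}

#' Root mean square error
#'
#' @param y observed values (here \% w/w Robusta).
#' @param yhat predictions, same length.
#' @return scalar RMSE in the units of \code{y}.
#' @export
rmse <- function(y, yhat) {
  stopifnot(length(y) == length(yhat))
  if (!length(y)) stop("rmse of empty vectors is undefined")
  sqrt(mean((y - yhat)^2))
}

# NIPALS core on plain matrices; X uncentered, y uncentered.
.nipals <- function(X, y, K) {
  n <- nrow(X); p <- ncol(X)
  if (K < 1L || K > min(n - 1L, p))
    stop("parameter error: nComponents must lie in [1, ", min(n - 1L, p),
         "]")
  xm <- colMeans(X); ym <- mean(y)
  if (stats::sd(y) == 0) stop("degenerate-response error: y is constant")
  E <- sweep(X, 2L, xm); f <- y - ym
  W <- matrix(0, p, K); P <- matrix(0, p, K); q <- numeric(K)
  Tm <- matrix(0, n, K)
  for (k in seq_len(K)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300) {  # residual X carries no covariance with y
      W <- W[, seq_len(k - 1L), drop = FALSE]
      P <- P[, seq_len(k - 1L), drop = FALSE]
      q <- q[seq_len(k - 1L)]; Tm <- Tm[, seq_len(k - 1L), drop = FALSE]
      break
    }
    w <- w / nw
    t_ <- as.numeric(E %*% w)
    tt <- sum(t_^2)
    p_ <- as.numeric(crossprod(E, t_)) / tt
    q_ <- sum(f * t_) / tt
    E <- E - tcrossprod(t_, p_)
    f <- f - q_ * t_
    W[, k] <- w; P[, k] <- p_; q[k] <- q_; Tm[, k] <- t_
  }
  list(W = W, P = P, q = q, T = Tm, xMean = xm, yMean = ym,
      K = length(q))
}

# Regression vector using the first k latent variables.
.plsr_beta <- function(fit, k) {
  W <- fit$W[, seq_len(k), drop = FALSE]
  P <- fit$P[, seq_len(k), drop = FALSE]
  q <- fit$q[seq_len(k)]
  b <- W %*% solve(crossprod(P, W), q)
  as.numeric(b)
}

#' Fit a NIPALS partial least squares regression
#'
#' Univariate-response NIPALS: X and y are mean-centered (no scaling);
#' each latent variable maximizes covariance of an X score with the y
#' residual, and X and y are deflated in turn.  The regression vector b
#' and intercept reproduce the latent-variable predictions exactly.
#'
#' @param x a \linkS4class{SpectraSet}.
#' @param y numeric response, here the Robusta fraction in \% w/w.
#' @param nComponents number of latent variables K,
#'   \code{<= min(N - 1, P)}.
#' @return a \linkS4class{PLSModel} with calibration metrics R2C and
#'   RMSEC.
#' @export
fitPLSR <- function(x, y, nComponents) {
  stopifnot(is(x, "SpectraSet"))
  A <- absorbance(x)
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(A))
  fit <- .nipals(A, y, nComponents)
  b <- .plsr_beta(fit, fit$K)
  icpt <- fit$yMean - sum(fit$xMean * b)
  yhat <- icpt + as.numeric(A %*% b)
  new("PLSModel", nComponents = as.integer(fit$K), xMean = fit$xMean,
      yMean = fit$yMean, weights = fit$W, xLoadings = fit$P,
      yLoadings = fit$q, scores = fit$T, regressionVector = b,
      intercept = icpt, wavelength = wavelengths(x),
      metrics = list(R2C = rSquared(y, yhat), RMSEC = rmse(y, yhat)))
}

#' Predict the blend fraction from spectra
#'
#' @param object a \linkS4class{PLSModel}.
#' @param newdata a \linkS4class{SpectraSet} on the training grid.
#' @param method "regvec" (default; \code{intercept + A b}) or "latent"
#'   (sequential score computation with deflation).  Both paths agree to
#'   numerical precision; the latent path exists as an internal
#'   cross-check.
#' @param ... ignored.
#' @return numeric predictions in \% w/w.
#' @export
setMethod("predict", "PLSModel",
  function(object, newdata, method = c("regvec", "latent"), ...) {
    method <- match.arg(method)
    w <- wavelengths(newdata)
    if (length(w) != length(object@wavelength) ||
        max(abs(w - object@wavelength)) > 1e-9)
      stop("dimension error: wavelength grid does not match the model's")
    A <- absorbance(newdata)
    if (method == "regvec")
      return(object@intercept + as.numeric(A %*% object@regressionVector))
    E <- sweep(A, 2L, object@xMean)
    yhat <- rep(object@yMean, nrow(A))
    for (k in seq_len(object@nComponents)) {
      t_ <- as.numeric(E %*% object@weights[, k])
      E <- E - tcrossprod(t_, object@xLoadings[, k])
      yhat <- yhat + object@yLoadings[k] * t_
    }
    yhat
  })

#' Cross-validate PLSR over the number of latent variables
#'
#' For each K up to \code{maxComponents}, out-of-fold predictions are
#' pooled into a single PRESS, giving \code{R2CV = 1 - PRESS/TSS} (TSS
#' about the global response mean) and \code{RMSECV = sqrt(PRESS/N)}.
#' All learned artifacts — the preprocessing chain's MSC reference (if
#' any) and the PLSR centering — are refit on each fold's calibration
#' rows only.  The selected K is the global RMSECV minimum, ties going
#' to the smaller K.
#'
#' @param x a \linkS4class{SpectraSet} of raw (or row-wise preprocessed)
#'   spectra.
#' @param y numeric response in \% w/w, one value per spectrum.
#' @param scheme a \linkS4class{CVScheme}.
#' @param maxComponents largest K to evaluate (capped by the smallest
#'   calibration fold).
#' @param chain optional \linkS4class{PreprocessSpec} (or chain string)
#'   refit within each fold.
#' @return a list with \code{table} (per-K data.frame of R2C, RMSEC,
#'   R2CV, RMSECV), \code{selectedK}, \code{model} (full-data refit at
#'   the selected K, with CV metrics attached), and
#'   \code{cvPredictions} (pooled out-of-fold predictions at the
#'   selected K).
#' @export
crossValidatePLSR <- function(x, y, scheme, maxComponents, chain = NULL) {
  stopifnot(is(x, "SpectraSet"))
  y <- as.numeric(y)
  n <- nSpectra(x)
  stopifnot(length(y) == n)
  if (is.character(chain)) chain <- parseChain(chain)
  folds <- makeFolds(x, scheme)
  nf <- max(folds)
  kmax <- min(maxComponents, min(n - tabulate(folds, nf)) - 1L)
  if (kmax < 1L) stop("parameter error: calibration folds too small")
  preds <- matrix(NA_real_, n, kmax)
  for (fd in seq_len(nf)) {
    tr <- which(folds != fd); te <- which(folds == fd)
    xtr <- x[, tr]; xte <- x[, te]
    if (!is.null(chain)) {
      cf <- .chain_fit(xtr, chain)
      xtr <- cf$block
      xte <- .chain_apply(xte, chain, cf$artifacts)
    }
    ytr <- y[tr]
    if (stats::sd(ytr) == 0)
      stop("degenerate-fold error: constant response in training fold ",
           fd)
    fit <- .nipals(absorbance(xtr), ytr,
                   min(kmax, length(tr) - 1L, ncol(absorbance(xtr))))
    Ate <- absorbance(xte)
    for (k in seq_len(fit$K)) {
      b <- .plsr_beta(fit, k)
      preds[te, k] <- (fit$yMean - sum(fit$xMean * b)) +
        as.numeric(Ate %*% b)
    }
    if (fit$K < kmax)  # deflation exhausted: reuse the deepest model
      for (k in (fit$K + 1L):kmax) preds[te, k] <- preds[te, fit$K]
  }
  tss <- sum((y - mean(y))^2)
  press <- colSums((preds - y)^2)
  r2cv <- 1 - press / tss
  rmsecv <- sqrt(press / n)
  # calibration metrics from a full-data fit (same chain, fit once)
  xall <- if (is.null(chain)) x else .chain_fit(x, chain)$block
  fit_all <- .nipals(absorbance(xall), y,
                     min(kmax, ncol(absorbance(xall))))
  r2c <- rmsec <- rep(NA_real_, kmax)
  Aall <- absorbance(xall)
  for (k in seq_len(fit_all$K)) {
    b <- .plsr_beta(fit_all, k)
    yh <- (fit_all$yMean - sum(fit_all$xMean * b)) + as.numeric(Aall %*% b)
    r2c[k] <- rSquared(y, yh); rmsec[k] <- rmse(y, yh)
  }
  selectedK <- which.min(rmsecv)
  model <- fitPLSR(xall, y, selectedK)
  model@metrics <- c(model@metrics,
                     list(R2CV = r2cv[selectedK],
                          RMSECV = rmsecv[selectedK]))
  list(table = data.frame(ncomp = seq_len(kmax), R2C = r2c, RMSEC = rmsec,
                          R2CV = r2cv, RMSECV = rmsecv),
       selectedK = selectedK, model = model,
       cvPredictions = preds[, selectedK])
}
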