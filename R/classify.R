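#' Fit a hybrid PCA-LDA classifier
#'
#' Spectra are first reduced to \code{nrpcs} principal-component scores;
#' linear discriminant analysis with equal class priors is then fitted
#' in score space.  The pooled within-class covariance receives a small
#' ridge (default \code{1e-8 * trace/nrpcs}) so its inversion is stable,
#' and a spectrum is classified to the class whose centroid is nearest
#' in Mahalanobis distance — with equal priors this is exactly the
#' maximum-linear-discriminant-score rule.
#'
#' @param x a \linkS4class{SpectraSet}.
#' @param labels class label per spectrum (>= 2 classes, each with >= 2
#'   rows).
#' @param nrpcs number of principal components (NrPCs).
#' @param ridge diagonal regularizer; \code{NULL} for the default.
#' @return a \linkS4class{PCALDAModel}.
#' @export
fitPCALDA <- function(x, labels, nrpcs, ridge = NULL) {
  stopifnot(is(x, "SpectraSet"))
  labels <- as.character(labels)
  stopifnot(length(labels) == nSpectra(x))
  cls <- unique(labels)
  if (length(cls) < 2L)
    stop("degenerate-labels error: need at least 2 classes")
  if (any(table(labels) < 2L))
    stop("every class needs at least 2 spectra")
  pca <- fitPCA(x, nrpcs)
  S <- projectScores(pca, x)
  K <- ncol(S)
  mu <- matrix(0, length(cls), K, dimnames = list(cls, NULL))
  W <- matrix(0, K, K)
  for (cl in cls) {
    rows <- which(labels == cl)
    mu[cl, ] <- colMeans(S[rows, , drop = FALSE])
    d <- sweep(S[rows, , drop = FALSE], 2L, mu[cl, ])
    W <- W + crossprod(d)
  }
  W <- W / (nrow(S) - length(cls))
  # absolute floor keeps noiseless (zero within-class scatter) data usable
  if (is.null(ridge)) ridge <- max(1e-8 * sum(diag(W)) / K, 1e-12)
  W <- W + diag(ridge, K)
  # canonical discriminant directions: eigenvectors of W^-1 B
  gm <- colMeans(S)
  B <- crossprod(sweep(mu, 2L, gm) *
                   sqrt(as.numeric(table(labels)[cls])))
  D <- min(K, length(cls) - 1L)
  ev <- eigen(solve(W, B))
  disc <- Re(ev$vectors[, seq_len(D), drop = FALSE])
  new("PCALDAModel", pca = pca, classLabels = cls, classMeans = mu,
      pooledCov = W, discriminants = disc, ridge = ridge)
}

#' Classify spectra with a fitted PCA-LDA model
#'
#' @param object a \linkS4class{PCALDAModel}.
#' @param newdata a \linkS4class{SpectraSet} on the training grid.
#' @param ... ignored.
#' @return character vector of assigned class labels.
#' @export
setMethod("predict", "PCALDAModel", function(object, newdata, ...) {
  S <- projectScores(object@pca, newdata)
  Winv <- solve(object@pooledCov)
  d2 <- vapply(seq_along(object@classLabels), function(i) {
    d <- sweep(S, 2L, object@classMeans[i, ])
    rowSums((d %*% Winv) * d)
  }, numeric(nrow(S)))
  d2 <- matrix(d2, nrow = nrow(S))
  object@classLabels[apply(d2, 1L, which.min)]
})

#' Grouped, stratified cross-validation of a PCA-LDA classifier
#'
#' Folds are group-aware (all scans/refills of one replicate travel
#' together) and stratified by sample type; see \code{\link{makeFolds}}.
#' The PCA and LDA are refit on each fold's calibration rows only.
#' Recognition accuracy is the mean calibration-set accuracy over
#' folds; prediction accuracy is the pooled validation-set accuracy,
#' and the confusion matrix pools validation assignments over all
#' folds.
#'
#' @param x a \linkS4class{SpectraSet}.
#' @param labels class label per spectrum.
#' @param scheme a \linkS4class{CVScheme} (typically
#'   \code{groupedKFold(3, "replicate", seed)}).
#' @param nrpcs number of principal components.
#' @param chain optional preprocessing chain refit within each fold.
#' @return a \linkS4class{ConfusionResult}.
#' @export
crossvalidatePCALDA <- function(x, labels, scheme, nrpcs, chain = NULL) {
  stopifnot(is(x, "SpectraSet"))
  labels <- as.character(labels)
  if (is.character(chain)) chain <- parseChain(chain)
  folds <- makeFolds(x, scheme)
  cls <- unique(labels)
  counts <- matrix(0L, length(cls), length(cls),
                   dimnames = list(cls, cls))
  recog <- numeric(max(folds))
  for (fd in seq_len(max(folds))) {
    tr <- which(folds != fd); te <- which(folds == fd)
    if (!all(cls %in% labels[tr]))
      stop("stratification error: class absent from training fold ", fd)
    xtr <- x[, tr]; xte <- x[, te]
    if (!is.null(chain)) {
      cf <- .chain_fit(xtr, chain)
      xtr <- cf$block
      xte <- .chain_apply(xte, chain, cf$artifacts)
    }
    fit <- fitPCALDA(xtr, labels[tr],
                     min(nrpcs, length(tr) - 1L,
                         length(wavelengths(xtr))))
    recog[fd] <- 100 * mean(predict(fit, xtr) == labels[tr])
    pr <- predict(fit, xte)
    for (i in seq_along(te))
      counts[labels[te[i]], pr[i]] <- counts[labels[te[i]], pr[i]] + 1L
  }
  rs <- rowSums(counts)
  pct <- 100 * counts / ifelse(rs > 0, rs, 1)
  new("ConfusionResult", labels = cls, counts = counts, percent = pct,
      recognition = mean(recog),
      prediction = 100 * sum(diag(counts)) / sum(counts))
}

#' Apply the NrPC-selection rule to a candidate accuracy table
#'
#' Among candidates whose validation accuracy is within \code{tol}
#' percentage points of the best, pick the one minimizing the
#' (training - validation) accuracy gap; remaining ties go to the
#' smallest NrPCs.
#'
#' @param table data.frame with columns \code{nrpc}, \code{train},
#'   \code{val} (accuracies in \%).
#' @param tol validation-accuracy tolerance in percentage points
#'   (default 1).
#' @return the chosen NrPCs.
#' @export
chooseNrPC <- function(table, tol = 1) {
  stopifnot(all(c("nrpc", "train", "val") %in% colnames(table)))
  if (!nrow(table)) stop("parameter error: empty candidate table")
  near <- table[table$val >= max(table$val) - tol, , drop = FALSE]
  gap <- near$train - near$val
  near <- near[gap == min(gap), , drop = FALSE]
  min(near$nrpc)
}

#' Select the number of principal components for PCA-LDA
#'
#' Runs \code{\link{crossvalidatePCALDA}} for every candidate NrPCs and
#' applies \code{\link{chooseNrPC}}: best validation accuracy (within a
#' 1-point tolerance) combined with the smallest training-validation
#' gap, ties to fewer components.
#'
#' @inheritParams crossvalidatePCALDA
#' @param candidates integer vector of NrPCs values to try.
#' @param tol validation-accuracy tolerance in percentage points.
#' @return the selected NrPCs (integer).
#' @export
selectNrPCs <- function(x, labels, scheme, candidates, chain = NULL,
                        tol = 1) {
  if (!length(candidates))
    stop("parameter error: empty candidate range")
  acc <- lapply(candidates, function(k) {
    cv <- crossvalidatePCALDA(x, labels, scheme, k, chain = chain)
    c(train = cv@recognition, val = cv@prediction)
  })
  tab <- data.frame(nrpc = candidates,
                    train = vapply(acc, `[[`, 0, "train"),
                    val = vapply(acc, `[[`, 0, "val"))
  chooseNrPC(tab, tol = tol)
}
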