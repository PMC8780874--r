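#' MixtureDesign: the two-endmember blending and acquisition design
#'
#' Describes which Robusta mass fractions are prepared and how many
#' spectra are acquired per sample type: \code{nReplicates} independently
#' prepared replicates, each measured over \code{nRefills} cuvette refills
#' with \code{nScans} consecutive scans per refill.
#'
#' @slot levels numeric, blend levels in \% w/w Robusta, each in (0, 100).
#' @slot controls numeric, pure-sample fractions (typically 0 and 100).
#' @slot blends data.frame with columns \code{label}, \code{fraction}:
#'   externally sourced test blends.
#' @slot nReplicates,nRefills,nScans positive integers.
#' @export
setClass("MixtureDesign",
  representation(levels = "numeric", controls = "numeric",
                 blends = "data.frame", nReplicates = "integer",
                 nRefills = "integer", nScans = "integer"),
  prototype(levels = numeric(), controls = c(0, 100),
            blends = data.frame(label = character(), fraction = numeric()),
            nReplicates = 3L, nRefills = 3L, nScans = 3L))

setValidity("MixtureDesign", function(object) {
  msgs <- character()
  if (length(object@levels) && any(object@levels <= 0 | object@levels >= 100))
    msgs <- c(msgs, "blend levels must lie strictly within (0, 100)")
  if (any(object@controls < 0 | object@controls > 100))
    msgs <- c(msgs, "control fractions must lie within [0, 100]")
  if (nrow(object@blends) &&
      !all(c("label", "fraction") %in% colnames(object@blends)))
    msgs <- c(msgs, "blends needs columns 'label' and 'fraction'")
  for (s in c("nReplicates", "nRefills", "nScans"))
    if (slot(object, s) < 1L)
      msgs <- c(msgs, paste(s, "must be a positive integer"))
  if (length(msgs)) msgs else TRUE
})

#' @rdname MixtureDesign-class
#' @param levels,controls,blends,nReplicates,nRefills,nScans see slots.
#' @return a \linkS4class{MixtureDesign}.
#' @export
mixtureDesign <- function(levels = numeric(), controls = c(0, 100),
                          blends = data.frame(label = character(),
                                              fraction = numeric()),
                          nReplicates = 3, nRefills = 3, nScans = 3) {
  new("MixtureDesign", levels = as.numeric(levels),
      controls = as.numeric(controls), blends = blends,
      nReplicates = as.integer(nReplicates),
      nRefills = as.integer(nRefills), nScans = as.integer(nScans))
}

#' Total number of spectra a design generates
#' @param design a \linkS4class{MixtureDesign}.
#' @return integer: (number of sample types) x replicates x refills x scans.
#' @export
totalSpectra <- function(design) {
  stopifnot(is(design, "MixtureDesign"))
  (length(design@levels) + length(design@controls) + nrow(design@blends)) *
    design@nReplicates * design@nRefills * design@nScans
}

setMethod("show", "MixtureDesign", function(object) {
  cat("MixtureDesign:", length(object@levels), "blend levels,",
      length(object@controls), "controls,", nrow(object@blends),
      "external blends\n")
  cat(sprintf("  hierarchy %d replicates x %d refills x %d scans -> %d spectra\n",
              object@nReplicates, object@nRefills, object@nScans,
              totalSpectra(object)))
  invisible(object)
})

#' EndmemberSpec: a pure-variety absorbance spectrum as Gaussian peaks
#'
#' A pure endmember is modelled as a constant baseline plus a sum of
#' Gaussian absorption bands, A(lambda) = baseline +
#' sum_j h_j exp(-(lambda - c_j)^2 / (2 w_j^2)).
#'
#' @slot peaks data.frame with columns \code{center} (nm), \code{width}
#'   (nm, Gaussian sigma), \code{height} (absorbance units).
#' @slot baseline numeric scalar absorbance offset.
#' @export
setClass("EndmemberSpec",
  representation(peaks = "data.frame", baseline = "numeric"),
  prototype(peaks = data.frame(center = numeric(), width = numeric(),
                               height = numeric()),
            baseline = 0))

setValidity("EndmemberSpec", function(object) {
  p <- object@peaks
  msgs <- character()
  if (!all(c("center", "width", "height") %in% colnames(p)))
    msgs <- c(msgs, "peaks needs columns center, width, height")
  else {
    if (any(p$width <= 0)) msgs <- c(msgs, "peak widths must be positive")
    if (any(p$height < 0)) msgs <- c(msgs, "peak heights must be >= 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' @rdname EndmemberSpec-class
#' @param peaks,baseline see slots.
#' @return an \linkS4class{EndmemberSpec}.
#' @export
endmemberSpec <- function(peaks = data.frame(center = numeric(),
                                             width = numeric(),
                                             height = numeric()),
                          baseline = 0) {
  new("EndmemberSpec", peaks = peaks, baseline = baseline)
}

#' NoiseModel: instrument and presentation artifacts for simulation
#'
#' One multiplicative gain, additive offset and linear baseline tilt are
#' drawn per cuvette refill (consecutive scans of a refill share the
#' physical presentation); independent Gaussian noise is drawn per
#' wavelength per scan.
#'
#' @slot multSD s.d. of the multiplicative gain around 1.
#' @slot addOffsetSD s.d. of the additive absorbance offset.
#' @slot tiltSD s.d. of the linear baseline slope, absorbance per nm.
#' @slot noiseSD s.d. of i.i.d. per-wavelength noise.
#' @slot seed integer RNG seed.
#' @export
setClass("NoiseModel",
  representation(multSD = "numeric", addOffsetSD = "numeric",
                 tiltSD = "numeric", noiseSD = "numeric", seed = "integer"),
  prototype(multSD = 0, addOffsetSD = 0, tiltSD = 0, noiseSD = 0, seed = 1L))

setValidity("NoiseModel", function(object) {
  if (any(c(object@multSD, object@addOffsetSD, object@tiltSD,
            object@noiseSD) < 0))
    "all noise standard deviations must be >= 0" else TRUE
})

#' @rdname NoiseModel-class
#' @param multSD,addOffsetSD,tiltSD,noiseSD,seed see slots.
#' @return a \linkS4class{NoiseModel}.
#' @export
noiseModel <- function(multSD = 0, addOffsetSD = 0, tiltSD = 0,
                       noiseSD = 0, seed = 1) {
  new("NoiseModel", multSD = multSD, addOffsetSD = addOffsetSD,
      tiltSD = tiltSD, noiseSD = noiseSD, seed = as.integer(seed))
}

#' PCAModel: principal components of a spectra block
#'
#' Fitted by mean-centering the N x P absorbance matrix and taking its
#' singular value decomposition; loadings are the right singular vectors.
#'
#' @slot center numeric P-vector, the training mean spectrum.
#' @slot loadings P x K matrix with orthonormal columns; the sign of each
#'   column is fixed so its largest-magnitude element is positive.
#' @slot explainedVarianceRatio K fractions of total centered variance,
#'   non-increasing.
#' @slot nComponents integer K.
#' @slot wavelength the fitting grid (used to check projection inputs).
#' @export
setClass("PCAModel",
  representation(center = "numeric", loadings = "matrix",
                 explainedVarianceRatio = "numeric", nComponents = "integer",
                 wavelength = "numeric"))

setValidity("PCAModel", function(object) {
  msgs <- character()
  L <- object@loadings
  if (ncol(L) != object@nComponents)
    msgs <- c(msgs, "loadings must have nComponents columns")
  g <- crossprod(L)
  if (max(abs(g - diag(ncol(L)))) > 1e-8)
    msgs <- c(msgs, "loadings columns must be orthonormal (tol 1e-8)")
  evr <- object@explainedVarianceRatio
  if (any(evr < -1e-12 | evr > 1 + 1e-12) || any(diff(evr) > 1e-12) ||
      sum(evr) > 1 + 1e-8)
    msgs <- c(msgs, "explainedVarianceRatio must be non-increasing fractions summing to <= 1")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "PCAModel", function(object) {
  cat("PCAModel:", object@nComponents, "components on",
      length(object@center), "wavelengths\n")
  cat("  explained variance ratio:",
      paste(sprintf("%.3f", object@explainedVarianceRatio), collapse = " "),
      "\n")
  invisible(object)
})

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "PCAModel", function(x) x@wavelength)

#' PLSModel: NIPALS partial least squares regression, univariate response
#'
#' @slot nComponents integer K.
#' @slot xMean,yMean centering constants.
#' @slot weights,xLoadings P x K matrices (NIPALS W and P).
#' @slot yLoadings K-vector (NIPALS q).
#' @slot scores N x K training score matrix T.
#' @slot regressionVector P-vector b with \code{yhat = intercept + A b}.
#' @slot intercept scalar.
#' @slot wavelength training grid.
#' @slot metrics named list (R2C, RMSEC and, after cross-validation,
#'   R2CV, RMSECV).
#' @export
setClass("PLSModel",
  representation(nComponents = "integer", xMean = "numeric",
                 yMean = "numeric", weights = "matrix",
                 xLoadings = "matrix", yLoadings = "numeric",
                 scores = "matrix", regressionVector = "numeric",
                 intercept = "numeric", wavelength = "numeric",
                 metrics = "list"),
  prototype(metrics = list()))

setMethod("show", "PLSModel", function(object) {
  cat("PLSModel:", object@nComponents, "latent variables on",
      length(object@xMean), "wavelengths\n")
  m <- object@metrics
  if (length(m))
    cat(" ", paste(names(m), sprintf("%.4g", unlist(m)), sep = " = ",
                   collapse = ", "), "\n")
  invisible(object)
})

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "PLSModel", function(x) x@wavelength)

#' PCALDAModel: linear discriminant classifier in PC-score space
#'
#' PCA reduces the spectra to \code{NrPCs} scores; LDA with equal class
#' priors and a pooled within-class covariance (plus a small ridge for
#' numerical stability) classifies a spectrum to the class whose score-
#' space centroid is nearest in Mahalanobis distance.
#'
#' @slot pca the underlying \linkS4class{PCAModel} with NrPCs components.
#' @slot classLabels ordered class labels.
#' @slot classMeans C x NrPCs matrix of score-space centroids.
#' @slot pooledCov NrPCs x NrPCs pooled within-class covariance
#'   (ridge already added).
#' @slot discriminants NrPCs x D matrix of canonical discriminant
#'   directions, D <= min(NrPCs, C - 1).
#' @slot ridge the ridge actually added to the diagonal.
#' @export
setClass("PCALDAModel",
  representation(pca = "PCAModel", classLabels = "character",
                 classMeans = "matrix", pooledCov = "matrix",
                 discriminants = "matrix", ridge = "numeric"))

setMethod("show", "PCALDAModel", function(object) {
  cat("PCALDAModel:", length(object@classLabels), "classes, NrPCs =",
      object@pca@nComponents, "\n")
  cat("  classes:", paste(object@classLabels, collapse = ", "), "\n")
  invisible(object)
})

#' ConfusionResult: cross-validated classification summary
#'
#' @slot labels ordered class labels.
#' @slot counts raw confusion counts (rows = true, columns = assigned),
#'   pooled over validation folds.
#' @slot percent row-normalized percentages (each row sums to 100).
#' @slot recognition mean calibration-set accuracy over folds, \%.
#' @slot prediction pooled validation-set accuracy, \%.
#' @export
setClass("ConfusionResult",
  representation(labels = "character", counts = "matrix",
                 percent = "matrix", recognition = "numeric",
                 prediction = "numeric"))

setValidity("ConfusionResult", function(object) {
  msgs <- character()
  rs <- rowSums(object@percent)
  if (any(abs(rs[rowSums(object@counts) > 0] - 100) > 0.1))
    msgs <- c(msgs, "confusion-matrix rows must each sum to 100%")
  for (a in c(object@recognition, object@prediction))
    if (a < 0 || a > 100) msgs <- c(msgs, "accuracies must lie in [0, 100]")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ConfusionResult", function(object) {
  cat(sprintf("ConfusionResult: recognition %.2f%%, prediction %.2f%%\n",
              object@recognition, object@prediction))
  print(round(object@percent, 1))
  invisible(object)
})

#' CVScheme: grouped cross-validation layout
#'
#' Folds never split an acquisition group: all rows sharing the grouping
#' key (within one sample type) travel together.  Two kinds are
#' supported: \code{kfold_grouped} assigns groups to k folds, stratified
#' by sample type, under a deterministic seeded shuffle; and
#' \code{leave_group_out} makes one fold per group (e.g. the three
#' consecutive scans of one replicate).
#'
#' @slot kind "kfold_grouped" or "leave_group_out".
#' @slot groupKey metadata column names defining a group within a sample
#'   type (e.g. \code{"replicate"}, or \code{c("replicate", "refill")} for
#'   scan triplets of refilled liquid samples).
#' @slot k number of folds (kfold only), >= 2.
#' @slot seed integer seed for the fold-assignment shuffle.
#' @export
setClass("CVScheme",
  representation(kind = "character", groupKey = "character", k = "integer",
                 seed = "integer"),
  prototype(kind = "kfold_grouped", groupKey = "replicate", k = 3L,
            seed = 1L))

setValidity("CVScheme", function(object) {
  msgs <- character()
  if (!object@kind %in% c("kfold_grouped", "leave_group_out"))
    msgs <- c(msgs, "kind must be 'kfold_grouped' or 'leave_group_out'")
  if (object@kind == "kfold_grouped" && object@k < 2L)
    msgs <- c(msgs, "k must be >= 2")
  ok <- object@groupKey %in% c("replicate", "refill", "scan")
  if (!all(ok))
    msgs <- c(msgs, "groupKey entries must be metadata hierarchy columns")
  if (length(msgs)) msgs else TRUE
})

#' @rdname CVScheme-class
#' @param k number of folds.
#' @param groupKey metadata columns defining the grouping unit.
#' @param seed RNG seed for fold assignment.
#' @return a \linkS4class{CVScheme}.
#' @export
groupedKFold <- function(k = 3, groupKey = "replicate", seed = 1) {
  new("CVScheme", kind = "kfold_grouped", groupKey = groupKey,
      k = as.integer(k), seed = as.integer(seed))
}

#' @rdname CVScheme-class
#' @export
leaveGroupOut <- function(groupKey = c("replicate", "refill"), seed = 1) {
  new("CVScheme", kind = "leave_group_out", groupKey = groupKey, k = 0L,
      seed = as.integer(seed))
}

#' AquagramResult: standardized absorbances at WAMAC wavelengths
#'
#' @slot groups ordered group labels.
#' @slot wamacs WAMAC wavelengths used (nm, as requested).
#' @slot gridWamacs the nearest grid wavelengths actually read.
#' @slot values groups x WAMACs matrix of group-mean z-scored absorbances.
#' @slot nPerGroup spectra per group.
#' @export
setClass("AquagramResult",
  representation(groups = "character", wamacs = "numeric",
                 gridWamacs = "numeric", values = "matrix",
                 nPerGroup = "integer"))

setValidity("AquagramResult", function(object) {
  wm <- colSums(object@values * object@nPerGroup) / sum(object@nPerGroup)
  if (max(abs(wm)) > 1e-8)
    "count-weighted mean of group values must be 0 at every WAMAC"
  else TRUE
})

setMethod("show", "AquagramResult", function(object) {
  cat("AquagramResult:", length(object@groups), "groups x",
      length(object@wamacs), "WAMACs\n")
  print(round(object@values, 3))
  invisible(object)
})
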