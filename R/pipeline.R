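#' Run the full blend-authentication experiment suite on synthetic data
#'
#' Generates a synthetic mixture dataset and reproduces the study
#' sequence end-to-end: (1) pure-variety PCA and PCA-LDA
#' discrimination; (2) multi-class PCA-LDA of all mixture levels with a
#' pooled confusion matrix; (3) PLSR prediction of the Robusta fraction
#' under both grouped 3-fold and leave-scan-triplet-out
#' cross-validation, first with the marketed blends held out as an
#' external test set and then with them included; (4) aquagrams of the
#' mixture series and of the series extended with the marketed blends.
#' All outputs (a metrics JSON plus confusion/aquagram/regression CSVs)
#' are written under \code{outDir} and are a deterministic function of
#' \code{seed}.
#'
#' @param outDir output directory (created if needed).
#' @param seed integer master seed; every random stream (data
#'   generation, fold shuffles) derives from it.
#' @param form "liquid" or "ground".
#' @param noise noise preset name ("none", "low", "realistic") or a
#'   \linkS4class{NoiseModel}.
#' @param classifyChain preprocessing chain for the classification
#'   experiments.
#' @param regressChain preprocessing chain for the PLSR experiments.
#' @param maxComponents largest PLSR latent-variable count screened.
#' @param nrpcCandidates NrPCs candidates for
#'   \code{\link{selectNrPCs}}.
#' @param quiet suppress progress messages.
#' @return (invisibly) the report list that is also written to
#'   \code{report.json}.
#' @export
runExperimentSuite <- function(outDir, seed = 42, form = "liquid",
                               noise = "realistic",
                               classifyChain = "truncate:1300,1600|savgol:19,2,0",
                               regressChain = "truncate:1300,1600|savgol:19,2,1",
                               maxComponents = 10,
                               nrpcCandidates = c(2, 4, 6, 8, 10),
                               quiet = FALSE) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  t0 <- Sys.time()
  if (is.character(noise)) noise <- noisePreset(noise, seed = seed)
  design <- defaultDesign(form)
  say("generating ", totalSpectra(design), " synthetic ", form,
      " spectra (seed ", seed, ")")
  d <- generateMixtureDataset(design = design, noise = noise, form = form)
  meta <- as.data.frame(sampleData(d))
  is_blend <- meta$variety %in% design@blends$label
  is_pure <- meta$robusta_fraction %in% c(0, 100) & !is_blend

  # ---- (1) pure-variety discrimination -------------------------------
  say("experiment 1: pure-variety PCA-LDA")
  pure <- d[, is_pure]
  pure_lab <- sampleData(pure)$variety
  pca2 <- fitPCA(applyChain(pure, classifyChain), 2)
  scheme1 <- groupedKFold(3, "replicate", seed = seed)
  nrpc1 <- selectNrPCs(pure, pure_lab, scheme1,
                       candidates = nrpcCandidates[nrpcCandidates <=
                                                     nSpectra(pure) / 2],
                       chain = classifyChain)
  cv1 <- crossvalidatePCALDA(pure, pure_lab, scheme1, nrpc1,
                             chain = classifyChain)

  # ---- (2) mixture-level classification ------------------------------
  say("experiment 2: mixture PCA-LDA")
  mix <- d[, !is_blend]
  mix_lab <- paste0(sampleData(mix)$robusta_fraction, "%")
  scheme2 <- groupedKFold(3, "replicate", seed = seed + 1L)
  nrpc2 <- selectNrPCs(mix, mix_lab, scheme2, candidates = nrpcCandidates,
                       chain = classifyChain)
  cv2 <- crossvalidatePCALDA(mix, mix_lab, scheme2, nrpc2,
                             chain = classifyChain)
  ord <- order(as.numeric(sub("%", "", cv2@labels)))
  conf <- cv2@percent[ord, ord]
  confusion_path <- file.path(outDir, "confusion_mixtures.csv")
  utils::write.csv(round(conf, 2), confusion_path)

  # ---- (3) PLSR of the Robusta fraction ------------------------------
  say("experiment 3: PLSR")
  y_mix <- sampleData(mix)$robusta_fraction
  lgo <- leaveGroupOut(c("replicate", "refill"))
  k3 <- groupedKFold(3, "replicate", seed = seed + 2L)
  cv_lgo <- crossValidatePLSR(mix, y_mix, lgo, maxComponents,
                              chain = regressChain)
  cv_k3 <- crossValidatePLSR(mix, y_mix, k3, maxComponents,
                             chain = regressChain)
  # blends as an external test set
  cfmix <- .chain_fit(mix, parseChain(regressChain))
  blends <- d[, is_blend]
  blend_pred <- data.frame()
  if (nSpectra(blends) > 0) {
    bl_pre <- .chain_apply(blends, parseChain(regressChain),
                           cfmix$artifacts)
    bp <- predict(cv_lgo$model, bl_pre)
    blend_pred <- data.frame(label = sampleData(blends)$variety,
                             true = sampleData(blends)$robusta_fraction,
                             predicted = bp)
    utils::write.csv(blend_pred, file.path(outDir, "blend_predictions.csv"),
                     row.names = FALSE)
  }
  # blends included in calibration
  y_all <- meta$robusta_fraction
  cv_incl <- crossValidatePLSR(d, y_all, lgo, maxComponents,
                               chain = regressChain)
  utils::write.csv(cv_lgo$table, file.path(outDir, "plsr_percomp.csv"),
                   row.names = FALSE)
  regvec <- data.frame(wavelength_nm = wavelengths(cv_lgo$model),
                       coefficient = cv_lgo$model@regressionVector)
  utils::write.csv(regvec, file.path(outDir, "plsr_regvec.csv"),
                   row.names = FALSE)

  # ---- (4) aquagrams -------------------------------------------------
  say("experiment 4: aquagrams")
  spec2 <- aquagramSpec("second")
  aq_mix <- computeAquagram(d[, !is_blend & meta$robusta_fraction < 100],
                            "variety", spec2)
  aq_all <- computeAquagram(d[, meta$robusta_fraction %in%
                                c(0, 1, 35, 100) | is_blend],
                            "variety", spec2)
  aq_paths <- c(mixtures = file.path(outDir, "aquagram_mixtures.csv"),
                with_blends = file.path(outDir, "aquagram_with_blends.csv"))
  exportAquagram(aq_mix, aq_paths[["mixtures"]])
  exportAquagram(aq_all, aq_paths[["with_blends"]])

  report <- list(
    config = list(seed = seed, form = form,
                  noise = list(multSD = noise@multSD,
                               addOffsetSD = noise@addOffsetSD,
                               tiltSD = noise@tiltSD,
                               noiseSD = noise@noiseSD),
                  classifyChain = classifyChain,
                  regressChain = regressChain),
    pure_discrimination = list(
      nrpcs = nrpc1,
      pc12_variance = sum(pca2@explainedVarianceRatio),
      recognition = cv1@recognition, prediction = cv1@prediction),
    classification = list(
      nrpcs = nrpc2, recognition = cv2@recognition,
      prediction = cv2@prediction, confusion_path = confusion_path),
    regression = list(
      leave_scan_triplet_out = list(
        selectedK = cv_lgo$selectedK,
        R2C = cv_lgo$model@metrics$R2C,
        RMSEC = cv_lgo$model@metrics$RMSEC,
        R2CV = cv_lgo$model@metrics$R2CV,
        RMSECV = cv_lgo$model@metrics$RMSECV),
      grouped_3fold = list(
        selectedK = cv_k3$selectedK,
        R2CV = cv_k3$model@metrics$R2CV,
        RMSECV = cv_k3$model@metrics$RMSECV),
      blends_included = list(
        selectedK = cv_incl$selectedK,
        R2CV = cv_incl$model@metrics$R2CV,
        RMSECV = cv_incl$model@metrics$RMSECV),
      blend_external_rmse = if (nrow(blend_pred))
        rmse(blend_pred$true, blend_pred$predicted) else NULL),
    aquagram = list(csv_paths = as.list(aq_paths)))
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say(sprintf("done in %.1f s", as.numeric(Sys.time() - t0, units = "secs")))
  invisible(report)
}
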