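# two well-separated spectral classes with grouped structure
separable_block <- function(n_per = 9, gap = 1, noise_sd = 0.01,
                            seed = 21) {
  set.seed(seed)
  w <- seq(800, 898, 2)
  base <- sin(w / 30)
  A <- rbind(
    matrix(rep(base, n_per), n_per, byrow = TRUE),
    matrix(rep(base + gap, n_per), n_per, byrow = TRUE)) +
    rnorm(2 * n_per * length(w), 0, noise_sd)
  meta <- data.frame(
    variety = rep(c("A", "B"), each = n_per),
    robusta_fraction = rep(c(0, 100), each = n_per),
    replicate = rep(rep(1:3, each = n_per / 3), 2),
    refill = 1L, scan = rep(seq_len(n_per / 3), 2 * 3))
  SpectraSet(A, w, meta = meta)
}

test_that("separable classes are learned perfectly in training", {
  x <- separable_block()
  lab <- sampleData(x)$variety
  m <- fitPCALDA(x, lab, 3)
  expect_equal(predict(m, x), lab)
  # class means are the projected class centroids
  S <- projectScores(m@pca, x)
  expect_equal(m@classMeans["A", ], colMeans(S[lab == "A", ]),
               ignore_attr = TRUE)
  expect_error(fitPCALDA(x, rep("A", nSpectra(x)), 2),
               "degenerate-labels")
})

test_that("classification equals a Mahalanobis-to-centroid oracle", {
  set.seed(22)
  w <- seq(800, 830, 2)
  centers <- matrix(c(0, 0, 3, 0.5, 1.5, 2), 3, 2, byrow = TRUE)
  A <- NULL; lab <- NULL
  dir1 <- c(rep(1, 8), rep(0, 8)); dir2 <- c(rep(0, 8), rep(1, 8))
  for (cl in 1:3) {
    s <- cbind(rnorm(10, centers[cl, 1], .7), rnorm(10, centers[cl, 2], .4))
    A <- rbind(A, outer(s[, 1], dir1) + outer(s[, 2], dir2))
    lab <- c(lab, rep(letters[cl], 10))
  }
  x <- SpectraSet(A, w)
  m <- fitPCALDA(x, lab, 2)
  S <- projectScores(m@pca, x)
  Winv <- solve(m@pooledCov)
  oracle <- apply(S, 1, function(row) {
    d2 <- apply(m@classMeans, 1, function(mu)
      t(row - mu) %*% Winv %*% (row - mu))
    names(d2)[which.min(d2)]
  })
  expect_equal(predict(m, x), unname(oracle))
})

test_that("score-space LDA agrees with an independent LDA implementation", {
  skip_if_not_installed("MASS")
  set.seed(23)
  x <- separable_block(n_per = 12, gap = 0.05, noise_sd = 0.02)
  lab <- sampleData(x)$variety
  m <- fitPCALDA(x, lab, 4)
  S <- projectScores(m@pca, x)
  ref <- MASS::lda(S, grouping = lab, prior = c(.5, .5))
  expect_equal(predict(m, x),
               as.character(stats::predict(ref, S)$class))
})

test_that("the NrPC selection rule is applied exactly", {
  same <- data.frame(nrpc = c(3, 6, 9), train = 100, val = 95)
  expect_equal(chooseNrPC(same), 3)
  spec_case <- data.frame(nrpc = c(2, 5, 12),
                          train = c(100, 100, 100),
                          val = c(90, 98, 98))
  expect_equal(chooseNrPC(spec_case), 5)
  gap_case <- data.frame(nrpc = c(4, 7), train = c(100, 99),
                         val = c(99, 99))
  expect_equal(chooseNrPC(gap_case), 7)  # gap 0 beats gap 1
  expect_error(chooseNrPC(data.frame(nrpc = numeric(),
                                     train = numeric(),
                                     val = numeric())), "empty")
  expect_error(selectNrPCs(separable_block(), rep(c("A", "B"), each = 9),
                           groupedKFold(3), integer()), "empty")
})

test_that("grouped CV of separated classes is perfect and well-formed", {
  x <- separable_block(noise_sd = 0.001)
  lab <- sampleData(x)$variety
  cv <- crossvalidatePCALDA(x, lab, groupedKFold(3, "replicate", 1), 2)
  expect_equal(cv@recognition, 100)
  expect_equal(cv@prediction, 100)
  expect_equal(unname(rowSums(cv@percent)), rep(100, 2))
  # groups are never split across folds
  folds <- makeFolds(x, groupedKFold(3, "replicate", 1))
  m <- as.data.frame(sampleData(x))
  expect_true(all(tapply(folds, interaction(m$variety, m$replicate),
                         function(v) length(unique(v))) == 1))
})

test_that("shuffled labels drop prediction accuracy to chance", {
  d <- generateMixtureDataset(
    design = mixtureDesign(levels = c(0.5, 1, 2, 3, 5, 10, 20, 35),
                           controls = c(0, 100), nReplicates = 6,
                           nRefills = 1, nScans = 1),
    noise = noisePreset("realistic", seed = 24),
    wavelength = seq(800, 1100, 2))
  lab <- sampleData(d)$variety
  set.seed(25)
  accs <- replicate(50, {
    tryCatch(
      crossvalidatePCALDA(d, sample(lab), groupedKFold(3, "replicate", 1),
                          3)@prediction,
      error = function(e) NA_real_)  # a shuffle may empty a training class
  })
  expect_gt(mean(!is.na(accs)), 0.5)
  expect_lt(abs(mean(accs, na.rm = TRUE) - 10), 5)
})

test_that("calibration artifacts ignore validation rows (leakage canary)", {
  set.seed(26)
  x <- separable_block(n_per = 9, gap = 0, noise_sd = 0.05)  # no signal
  lab <- sampleData(x)$variety
  scheme <- groupedKFold(3, "replicate", 2)
  folds <- makeFolds(x, scheme)
  val <- which(folds == 1); cal <- which(folds != 1)
  # corrupt validation rows with a label-separating artifact
  A2 <- absorbance(x)
  A2[val, ] <- A2[val, ] + 5 * (sampleData(x)$variety[val] == "B")
  x2 <- SpectraSet(A2, wavelengths(x), meta = sampleData(x))
  chain <- "msc|snv"
  p1 <- applyChain(x[, cal], chain)
  p2 <- applyChain(x2[, cal], chain)
  expect_identical(absorbance(p1), absorbance(p2))
  expect_identical(mscReference(p1), mscReference(p2))
  m1 <- fitPCALDA(p1, lab[cal], 3)
  m2 <- fitPCALDA(p2, lab[cal], 3)
  expect_identical(predict(m1, p1), predict(m2, p2))
})

test_that("prediction does not beat recognition on average under noise", {
  gaps <- sapply(1:20, function(seed) {
    d <- generateMixtureDataset(
      design = mixtureDesign(levels = c(1, 3), controls = c(0, 100),
                             nReplicates = 3, nRefills = 1, nScans = 3),
      noise = noiseModel(multSD = .01, addOffsetSD = .005, tiltSD = 5e-6,
                         noiseSD = 6e-3, seed = seed),
      wavelength = seq(800, 1100, 2))
    cv <- crossvalidatePCALDA(d, sampleData(d)$variety,
                              groupedKFold(3, "replicate", seed), 5)
    cv@recognition - cv@prediction
  })
  expect_gte(mean(gaps), 0)
})

test_that("a class missing from a training fold raises a stratification error", {
  x <- separable_block()
  lab <- sampleData(x)$variety
  lab[sampleData(x)$variety == "B"] <- "A"
  lab[1] <- "C"  # class C lives in a single replicate group
  lab[2] <- "C"
  expect_error(
    crossvalidatePCALDA(x, lab, groupedKFold(3, "replicate", 1), 2),
    "stratification error")
})
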