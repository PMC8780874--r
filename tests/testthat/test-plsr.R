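test_that("R-squared and RMSE match hand computations", {
  expect_equal(rSquared(c(0, 10), c(0, 10)), 1.0)
  y <- c(1, 2, 3, 4)
  expect_equal(rSquared(y, rep(mean(y), 4)), 0.0)
  expect_equal(rSquared(c(0, 10), c(1, 9)), 0.96)  # RSS 2, TSS 50
  expect_equal(rmse(c(0, 10), c(0, 10)), 0.0)
  expect_equal(rmse(c(0, 10), c(1, 9)), 1.0)
  a <- runif(6); b <- runif(6)
  expect_equal(rmse(3 * a, 3 * b), 3 * rmse(a, b))
  expect_error(rSquared(c(2, 2), c(1, 2)), "degenerate")
  expect_error(rmse(numeric(), numeric()), "empty")
})

test_that("a single latent variable fits a rank-1 signal exactly", {
  set.seed(14)
  w <- seq(1300, 1398, 2)
  dir <- exp(-(w - 1350)^2 / 200)
  f <- runif(10, 0, 100)
  x <- SpectraSet(0.3 + outer(f / 100, dir), w)
  m <- fitPLSR(x, f, 1)
  expect_lt(m@metrics$RMSEC, 1e-8)
  expect_equal(m@metrics$R2C, 1.0, tolerance = 1e-10)
})

test_that("the first weight vector is the normalized X'y covariance", {
  x <- toy_block(12, 20, seed = 15)
  set.seed(16); y <- rnorm(12)
  m <- fitPLSR(x, y, 3)
  A <- absorbance(x)
  w1 <- crossprod(sweep(A, 2, colMeans(A)), y - mean(y))
  w1 <- as.numeric(w1 / sqrt(sum(w1^2)))
  expect_equal(m@weights[, 1], w1, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("full-rank PLSR reproduces OLS and scores stay orthogonal", {
  x <- toy_block(9, 4, seed = 17)
  set.seed(18); y <- rnorm(9)
  m <- fitPLSR(x, y, 4)
  A <- absorbance(x)
  ols <- lm(y ~ A)
  expect_equal(predict(m, x), unname(fitted(ols)), tolerance = 1e-8)
  G <- crossprod(m@scores); diag(G) <- 0
  expect_lt(max(abs(G)), 1e-8)
})

test_that("prediction paths agree and behave linearly", {
  x <- toy_block(10, 15, seed = 19)
  set.seed(20); y <- rnorm(10)
  m <- fitPLSR(x, y, 4)
  expect_equal(predict(m, x), predict(m, x, method = "latent"),
               tolerance = 1e-10)
  mean_block <- SpectraSet(matrix(colMeans(absorbance(x)), 1),
                           wavelengths(x))
  expect_equal(predict(m, mean_block), m@yMean, tolerance = 1e-10)
  # adding a direction orthogonal to the regression vector changes nothing
  b <- m@regressionVector
  v <- rnorm(15); v <- v - b * sum(v * b) / sum(b^2)
  shifted <- SpectraSet(sweep(absorbance(x), 2, -v), wavelengths(x))
  expect_equal(predict(m, shifted), predict(m, x), tolerance = 1e-8)
  expect_error(predict(m, toy_block(2, 14)), "dimension error")
})

test_that("cross-validation pools PRESS and selects by minimum RMSECV", {
  d <- generateMixtureDataset(design = ground_design(),
                              noise = noisePreset("none"), form = "ground")
  y <- sampleData(d)$robusta_fraction
  cv <- crossValidatePLSR(d, y, leaveGroupOut(c("replicate", "refill")),
                          4)
  expect_equal(cv$model@metrics$R2CV, 1.0, tolerance = 1e-8)
  expect_lt(cv$model@metrics$RMSECV, 1e-6)
  # one fold per (sample type x replicate) scan triplet: 9 x 3 = 27
  folds <- makeFolds(d, leaveGroupOut(c("replicate", "refill")))
  expect_equal(max(folds), 27L)
  expect_true(all(table(folds) == 3L))
  expect_lte(cv$table$RMSECV[cv$selectedK], cv$table$RMSECV[1])
})

test_that("degenerate responses are rejected", {
  x <- toy_block(6, 10)
  expect_error(fitPLSR(x, rep(2, 6), 2), "degenerate-response")
})

test_that("cross-validated predictions are unbiased at every level", {
  errs <- list()
  for (seed in 1:20) {
    d <- ground_data(seed = seed, preset = "low",
                     levels = c(2, 5, 10, 20, 35))
    y <- sampleData(d)$robusta_fraction
    cv <- crossValidatePLSR(d, y, leaveGroupOut(c("replicate", "refill")),
                            5, chain = "truncate:1300,1600|savgol:19,2,1")
    errs[[seed]] <- tapply(cv$cvPredictions - y, y, mean)
  }
  E <- do.call(rbind, errs)
  # seven simultaneous level checks: use a 3-s.e. (Bonferroni-style)
  # band so the family-wise false-alarm rate stays below ~2%
  for (lv in colnames(E)) {
    se <- sd(E[, lv]) / sqrt(nrow(E))
    expect_lt(abs(mean(E[, lv])), 3 * se + 1e-8)
  }
})

test_that("RMSECV degrades monotonically with the noise level", {
  out <- sapply(c("none", "low", "realistic"), function(p) {
    v <- sapply(1:3, function(s) {
      d <- ground_data(seed = s, preset = p, levels = c(2, 5, 10, 20, 35))
      y <- sampleData(d)$robusta_fraction
      crossValidatePLSR(d, y, leaveGroupOut(c("replicate", "refill")), 5,
                        chain = "truncate:1300,1600|savgol:19,2,1"
                        )$model@metrics$RMSECV
    })
    mean(v)
  })
  expect_true(all(diff(out) > 0))
})

test_that("regression-vector peaks co-locate with endmember-difference peaks", {
  d <- generateMixtureDataset(design = ground_design(),
                              noise = noisePreset("none"), form = "ground")
  pre <- truncateSpectra(d, 1300, 1600)
  y <- sampleData(pre)$robusta_fraction
  m <- fitPLSR(pre, y, 1)  # noiseless: b is proportional to the difference
  w <- wavelengths(pre)
  diffspec <- endmember_difference(w)
  b <- m@regressionVector
  expect_gt(cor(b, diffspec), 0.999)
  for (i in local_maxima(diffspec)) {
    j <- local_maxima(b)
    expect_lte(min(abs(w[j] - w[i])), gridStep(pre))
  }
})
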