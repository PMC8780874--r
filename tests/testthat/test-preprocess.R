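test_that("truncation keeps the inclusive wavelength range", {
  d <- toy_block(2, 481, wavelength = seq(740, 1700, by = 2))
  expect_equal(length(wavelengths(truncateSpectra(d, 800, 1670))), 436L)
  expect_equal(absorbance(truncateSpectra(d, 740, 1700)), absorbance(d))
  expect_error(truncateSpectra(d, 100, 200), "range error")
})

test_that("Savitzky-Golay reproduces low-degree polynomials and drops edges", {
  w <- seq(800, 1100, by = 2)
  lam <- (w - 950) / 100           # modest scale, keeps arithmetic exact
  quad <- 0.4 + 0.3 * lam + 0.2 * lam^2
  x <- SpectraSet(rbind(rep(0.7, length(w)), quad), w)
  for (win in c(11, 17, 19)) {
    sm <- savgolFilter(x, win, 2, 0)
    k <- (win - 1) / 2
    expect_equal(length(wavelengths(sm)), length(w) - 2 * k)
    expect_equal(absorbance(sm)[1, ], rep(0.7, length(w) - 2 * k),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(absorbance(sm)[2, ], quad[(k + 1):(length(w) - k)],
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("Savitzky-Golay derivatives are in per-nm units", {
  w <- seq(800, 1100, by = 2)
  lin <- SpectraSet(matrix(0.01 * w, 1), w)
  d1 <- savgolFilter(lin, 11, 2, 1)
  expect_equal(absorbance(d1)[1, ], rep(0.01, length(wavelengths(d1))),
               tolerance = 1e-10, ignore_attr = TRUE)
  quad <- SpectraSet(matrix(1e-5 * w^2, 1), w)
  d2 <- savgolFilter(quad, 11, 2, 2)
  expect_equal(absorbance(d2)[1, ], rep(2e-5, length(wavelengths(d2))),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("Savitzky-Golay is linear and validates its parameters", {
  x <- toy_block(3, 60, seed = 2)
  y <- toy_block(3, 60, seed = 3)
  comb <- .5 * absorbance(x) + 2 * absorbance(y)
  sm <- function(b) absorbance(savgolFilter(b, 11, 2, 1))
  expect_equal(sm(SpectraSet(comb, wavelengths(x))),
               .5 * sm(x) + 2 * sm(y), tolerance = 1e-12)
  expect_error(savgolFilter(x, 10, 2, 0), "odd")
  expect_error(savgolFilter(x, 11, 2, 3), "deriv")
})

test_that("MSC inverts affine scatter and is idempotent", {
  x <- toy_block(5, 40, seed = 4)
  ref <- colMeans(absorbance(x))
  scattered <- SpectraSet(rbind(ref, 0.5 + 2 * ref), wavelengths(x))
  out <- mscCorrect(scattered, ref)
  expect_equal(absorbance(out)[1, ], ref, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(absorbance(out)[2, ], ref, tolerance = 1e-12,
               ignore_attr = TRUE)
  # self-consistency: corrected rows regress on ref with slope 1, icpt 0
  corr <- mscCorrect(x, ref)
  for (i in 1:5) {
    co <- coef(lm(absorbance(corr)[i, ] ~ ref))
    expect_equal(unname(co), c(0, 1), tolerance = 1e-10)
  }
  twice <- mscCorrect(corr, ref)
  expect_equal(absorbance(twice), absorbance(corr), tolerance = 1e-10)
  expect_equal(mscReference(corr), unname(ref))
  flat <- SpectraSet(rbind(ref, rep(1, 40)), wavelengths(x))
  expect_error(mscCorrect(flat, ref), "degenerate-row.*2")
})

test_that("SNV standardizes every row to mean 0 and sample s.d. 1", {
  expect_equal(absorbance(snvScale(SpectraSet(matrix(1:3, 1), c(1, 2, 3) + 799))),
               matrix(c(-1, 0, 1), 1), ignore_attr = TRUE)
  x <- toy_block(20, 15, seed = 5)
  out <- absorbance(snvScale(x))
  expect_equal(unname(rowMeans(out)), rep(0, 20), tolerance = 1e-12)
  expect_equal(unname(apply(out, 1, sd)), rep(1, 20), tolerance = 1e-12)
  expect_error(snvScale(SpectraSet(matrix(2, 1, 5), seq(800, 808, 2))),
               "degenerate-row")
})

test_that("detrend annihilates polynomials and matches a refit oracle", {
  w <- seq(1300, 1478, by = 2)
  quad <- 2 - 0.01 * w + 1e-5 * w^2
  x <- SpectraSet(rbind(quad, rep(3, length(w))), w)
  expect_equal(absorbance(detrendSpectra(x, 2))[1, ],
               rep(0, length(w)), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(absorbance(detrendSpectra(x, 1))[2, ],
               rep(0, length(w)), tolerance = 1e-12, ignore_attr = TRUE)
  peak <- quad + 0.5 * exp(-(w - 1400)^2 / (2 * 15^2))
  got <- absorbance(detrendSpectra(SpectraSet(matrix(peak, 1), w), 2))[1, ]
  oracle <- residuals(lm(peak ~ poly(w, 2)))
  expect_equal(got, oracle, tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(detrendSpectra(toy_block(1, 3), 3), "degree")
})

test_that("hierarchical averaging collapses the right levels", {
  one <- toy_block(1, 5)
  rep3 <- SpectraSet(absorbance(one)[c(1, 1, 1), ], wavelengths(one),
                     meta = data.frame(variety = "A", replicate = 1,
                                       refill = 1, scan = 1:3))
  expect_equal(absorbance(averageSpectra(rep3, "scan"))[1, ],
               absorbance(one)[1, ], ignore_attr = TRUE)
  d <- generateMixtureDataset(noise = noisePreset("low", seed = 6))
  expect_equal(nSpectra(averageSpectra(d, "scan")), 108L)
  expect_equal(nSpectra(averageSpectra(d, "refill")), 36L)
  expect_equal(nSpectra(averageSpectra(d, "replicate")), 12L)
  av <- averageSpectra(d, "replicate")
  expect_setequal(sampleData(av)$robusta_fraction,
                  unique(sampleData(d)$robusta_fraction))
})

test_that("chains compose in order and are deterministic", {
  d <- generateMixtureDataset(design = ground_design(c(5, 20)),
                              noise = noisePreset("low", seed = 7),
                              form = "ground")
  manual <- mscCorrect(savgolFilter(truncateSpectra(d, 1300, 1600),
                                    19, 2, 0), "mean")
  chained <- applyChain(d, "truncate:1300,1600|savgol:19,2,0|msc")
  expect_equal(absorbance(chained), absorbance(manual))
  expect_equal(mscReference(chained), mscReference(manual))
  expect_equal(absorbance(applyChain(d, preprocessSpec())), absorbance(d))
  d2 <- generateMixtureDataset(design = ground_design(c(5, 20)),
                               noise = noisePreset("low", seed = 7),
                               form = "ground")
  expect_identical(absorbance(applyChain(d2, "snv|detrend:2")),
                   absorbance(applyChain(d, "snv|detrend:2")))
})

test_that("MSC removes pure multiplicative/additive scatter exactly", {
  noise <- noiseModel(multSD = 0.05, addOffsetSD = 0.05, seed = 8)
  des <- mixtureDesign(levels = c(10, 50), controls = c(0, 100),
                       nReplicates = 2, nRefills = 3, nScans = 1)
  d <- generateMixtureDataset(design = des, noise = noise)
  corr <- mscCorrect(d, "mean")
  m <- as.data.frame(sampleData(corr))
  A <- absorbance(corr)
  # refills of one replicate differ only by (g, o): identical after MSC
  for (f in unique(m$robusta_fraction)) {
    rows <- which(m$robusta_fraction == f & m$replicate == 1)
    expect_lt(max(abs(sweep(A[rows, ], 2, A[rows[1], ]))), 1e-10)
  }
})

test_that("degree-1 detrend removes a linear baseline tilt exactly", {
  tilt <- noiseModel(tiltSD = 1e-3, seed = 9)
  des <- mixtureDesign(levels = 50, controls = numeric(),
                       nReplicates = 2, nRefills = 2, nScans = 1)
  clean <- generateMixtureDataset(design = des,
                                  noise = noisePreset("none"))
  tilted <- generateMixtureDataset(design = des, noise = tilt)
  expect_equal(absorbance(detrendSpectra(tilted, 1)),
               absorbance(detrendSpectra(clean, 1)), tolerance = 1e-10)
})

test_that("averaging does not commute with row-wise transforms on noisy data", {
  d <- generateMixtureDataset(design = ground_design(c(5, 20)),
                              noise = noisePreset("realistic", seed = 10),
                              form = "ground")
  a_then_s <- absorbance(snvScale(averageSpectra(d, "scan")))
  s_then_a <- absorbance(averageSpectra(snvScale(d), "scan"))
  expect_gt(max(abs(a_then_s - s_then_a)), 1e-6)
})
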