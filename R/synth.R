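#' Default wavelength grid: 740-1700 nm in 2 nm steps
#'
#' The 2 nm step is an assumption of this package: the characteristic
#' wavelengths used throughout the NIR coffee literature (908, 954, 1060,
#' 1126, 1464 nm, ...) are all even, and a 2 nm grid places 481 points
#' across 740-1700 nm.
#'
#' @return numeric vector of 481 wavelengths.
#' @export
defaultGrid <- function() seq(740, 1700, by = 2)

#' Evaluate a Gaussian-peak endmember on a wavelength grid
#'
#' A(lambda) = baseline + sum_j height_j exp(-(lambda - center_j)^2 /
#' (2 width_j^2)).  Deterministic.
#'
#' @param spec an \linkS4class{EndmemberSpec}.
#' @param wavelength numeric grid in nm.
#' @return numeric absorbance vector, one value per grid point.
#' @export
endmemberSpectrum <- function(spec, wavelength) {
  stopifnot(is(spec, "EndmemberSpec"))
  validObject(spec)
  a <- rep(spec@baseline, length(wavelength))
  p <- spec@peaks
  for (j in seq_len(nrow(p)))
    a <- a + p$height[j] *
      exp(-(wavelength - p$center[j])^2 / (2 * p$width[j]^2))
  a
}

#' Default Arabica-like and Robusta-like endmember spectra
#'
#' Both endmembers share the broad water/organic absorption bands of an
#' aqueous coffee extract (second-overtone OH around 970 nm, the
#' combination band near 1190 nm, first-overtone OH around 1450 nm).
#' They differ at the bands that the aquaphotomics literature associates
#' with the two varieties: the Robusta-like endmember carries extra
#' absorbance at 908 and 954 nm (water shells / solvated free water) and
#' at 1342, 1374 and 1440 nm in the first overtone, while the
#' Arabica-like endmember absorbs more at 1018, 1036, 1044 and 1060 nm
#' (strongly hydrogen-bonded water structures) and at 1412, 1462 and
#' 1488 nm.  Peak heights are chosen so the largest between-class
#' absorbance difference is about 0.1 AU, a realistic contrast for
#' varietal NIR work.
#'
#' @return list with elements \code{arabica} and \code{robusta}, each an
#'   \linkS4class{EndmemberSpec}.
#' @export
defaultEndmembers <- function() {
  common <- data.frame(
    center = c(970, 1190, 1450),
    width  = c(45,  40,   55),
    height = c(0.55, 0.25, 0.90))
  ara <- data.frame(
    center = c(1018, 1036, 1044, 1060, 1412, 1462, 1488),
    width  = c(12,   12,   12,   14,   15,   15,   14),
    height = c(0.10, 0.08, 0.08, 0.12, 0.10, 0.08, 0.06))
  rob <- data.frame(
    center = c(908, 954, 1342, 1374, 1440),
    width  = c(14,  14,  14,   15,   15),
    height = c(0.12, 0.14, 0.08, 0.10, 0.08))
  list(arabica = endmemberSpec(rbind(common, ara), baseline = 0.35),
       robusta = endmemberSpec(rbind(common, rob), baseline = 0.38))
}

#' Noise presets for the mixture simulator
#'
#' \code{"none"} disables all artifacts (useful for algebraic tests).
#' \code{"low"} keeps the per-point noise s.d. (5e-4 AU) below 1\% of the
#' roughly 0.1 AU endmember-difference amplitude of
#' \code{\link{defaultEndmembers}}, with mild refill-level scatter;
#' this emulates a well-behaved powder measurement.  \code{"realistic"}
#' has 4x the noise and stronger multiplicative/additive scatter and
#' baseline tilt, emulating transflectance spectra of liquid extracts
#' where scatter correction is actually needed.
#'
#' @param name one of "none", "low", "realistic".
#' @param seed integer RNG seed stored in the model.
#' @return a \linkS4class{NoiseModel}.
#' @export
noisePreset <- function(name = c("none", "low", "realistic"), seed = 1) {
  name <- match.arg(name)
  switch(name,
    "none" = noiseModel(0, 0, 0, 0, seed = seed),
    "low" = noiseModel(multSD = 0.002, addOffsetSD = 0.001,
                       tiltSD = 2e-6, noiseSD = 5e-4, seed = seed),
    "realistic" = noiseModel(multSD = 0.01, addOffsetSD = 0.005,
                              tiltSD = 5e-6, noiseSD = 2e-3, seed = seed))
}

#' The study's blending and acquisition design
#'
#' Blend levels 0.5, 1, 2, 3, 5, 10, 20 and 35 \% w/w Robusta plus pure
#' controls (0 and 100\%) and two marketed test blends at 10 and 30\%.
#' Liquid extracts are measured as 3 replicates x 3 cuvette refills x 3
#' consecutive scans (12 sample types x 27 = 324 spectra); ground coffee
#' has no refill step (3 replicates x 3 scans, 108 spectra).
#'
#' @param form "liquid" or "ground".
#' @return a \linkS4class{MixtureDesign}.
#' @export
defaultDesign <- function(form = c("liquid", "ground")) {
  form <- match.arg(form)
  mixtureDesign(
    levels = c(0.5, 1, 2, 3, 5, 10, 20, 35),
    controls = c(0, 100),
    blends = data.frame(label = c("B10", "B30"), fraction = c(10, 30)),
    nReplicates = 3, nRefills = if (form == "liquid") 3 else 1,
    nScans = 3)
}

.design_sample_types <- function(design) {
  ctrl <- sort(design@controls)
  ctrl_lab <- ifelse(ctrl == 0, "ARA", ifelse(ctrl == 100, "ROB",
                     paste0("CTRL", ctrl)))
  lev <- sort(design@levels)
  lev_lab <- if (length(lev)) paste0("MIX", as.character(lev))
             else character()
  types <- data.frame(
    variety = c(ctrl_lab, lev_lab, as.character(design@blends$label)),
    fraction = c(ctrl, lev, design@blends$fraction),
    stringsAsFactors = FALSE)
  types
}

#' Generate a synthetic two-endmember NIR mixture dataset
#'
#' Clean spectra follow Beer-Lambert linear mixing,
#' \code{A_f = (1 - f/100) A_ara + (f/100) A_rob}, at each fraction f of
#' the design.  Each emitted scan is \code{g * A_f + o + t * (lambda -
#' lambda_mid) + eps}, where the gain g ~ N(1, multSD), offset o ~ N(0,
#' addOffsetSD) and tilt t ~ N(0, tiltSD) are drawn once per (sample
#' type, replicate, refill) — consecutive scans of one refill share the
#' physical presentation — and eps is i.i.d. N(0, noiseSD) per point per
#' scan.  The draw order is fixed, so the dataset is a deterministic
#' function of \code{noise@seed}.
#'
#' @param arabica,robusta \linkS4class{EndmemberSpec} endmembers.
#' @param design a \linkS4class{MixtureDesign}.
#' @param noise a \linkS4class{NoiseModel}.
#' @param wavelength grid in nm (default \code{\link{defaultGrid}()}).
#' @param form "liquid" or "ground" metadata tag.
#' @return a \linkS4class{SpectraSet} with \code{totalSpectra(design)}
#'   rows and fully populated metadata.
#' @examples
#' d <- generateMixtureDataset(noise = noisePreset("low", seed = 42))
#' nSpectra(d)  # 324
#' @export
generateMixtureDataset <- function(arabica = defaultEndmembers()$arabica,
                                   robusta = defaultEndmembers()$robusta,
                                   design = defaultDesign("liquid"),
                                   noise = noisePreset("none"),
                                   wavelength = defaultGrid(),
                                   form = c("liquid", "ground")) {
  form <- match.arg(form)
  validObject(design); validObject(noise)
  types <- .design_sample_types(design)
  if (any(types$fraction < 0 | types$fraction > 100))
    stop("domain error: fractions must lie within [0, 100]")
  a_ara <- endmemberSpectrum(arabica, wavelength)
  a_rob <- endmemberSpectrum(robusta, wavelength)
  lam_mid <- (min(wavelength) + max(wavelength)) / 2
  p <- length(wavelength)
  n <- totalSpectra(design)
  A <- matrix(NA_real_, n, p)
  meta <- data.frame(sample_id = character(n), variety = character(n),
                     robusta_fraction = numeric(n), form = form,
                     replicate = integer(n), refill = integer(n),
                     scan = integer(n), stringsAsFactors = FALSE)
  set.seed(noise@seed)
  row <- 0L
  for (i in seq_len(nrow(types))) {
    f <- types$fraction[i] / 100
    clean <- (1 - f) * a_ara + f * a_rob
    for (rep_ in seq_len(design@nReplicates)) {
      for (ref in seq_len(design@nRefills)) {
        g <- 1 + stats::rnorm(1L, 0, noise@multSD)
        o <- stats::rnorm(1L, 0, noise@addOffsetSD)
        tl <- stats::rnorm(1L, 0, noise@tiltSD)
        base <- g * clean + o + tl * (wavelength - lam_mid)
        for (sc in seq_len(design@nScans)) {
          row <- row + 1L
          A[row, ] <- base + stats::rnorm(p, 0, noise@noiseSD)
          meta$variety[row] <- types$variety[i]
          meta$robusta_fraction[row] <- types$fraction[i]
          meta$replicate[row] <- rep_
          meta$refill[row] <- ref
          meta$scan[row] <- sc
          meta$sample_id[row] <- sprintf("%s_r%d_f%d_s%d",
                                         types$variety[i], rep_, ref, sc)
        }
      }
    }
  }
  SpectraSet(A, wavelength, meta = meta)
}
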