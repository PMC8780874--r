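# Small in-code fixtures shared across test files.

# random block with default metadata on an even grid
toy_block <- function(n = 4, p = 6, seed = 1,
                      wavelength = seq(1300, by = 2, length.out = p)) {
  set.seed(seed)
  SpectraSet(matrix(rnorm(n * p), n, p), wavelength)
}

# ground-coffee style design: no refill step
ground_design <- function(levels = c(1, 2, 3, 5, 10, 20, 35)) {
  mixtureDesign(levels = levels, controls = c(0, 100),
                nReplicates = 3, nRefills = 1, nScans = 3)
}

# two pure classes only, full liquid hierarchy (27 spectra per class)
pure_design <- function() {
  mixtureDesign(levels = numeric(), controls = c(0, 100),
                nReplicates = 3, nRefills = 3, nScans = 3)
}

# deterministic ground dataset for regression tests
ground_data <- function(seed = 42, preset = "low",
                        levels = c(1, 2, 3, 5, 10, 20, 35)) {
  generateMixtureDataset(design = ground_design(levels),
                         noise = noisePreset(preset, seed = seed),
                         form = "ground")
}

# difference spectrum of the default endmembers on a grid
endmember_difference <- function(wavelength = defaultGrid()) {
  em <- defaultEndmembers()
  endmemberSpectrum(em$robusta, wavelength) -
    endmemberSpectrum(em$arabica, wavelength)
}

# positions (in index units) of interior local maxima of a vector
local_maxima <- function(v) {
  which(diff(sign(diff(v))) == -2) + 1L
}
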