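# Shared fixtures and independent oracles, built in code at test time.

gauss <- function(x, center, height, fwhm) {
  height * exp(-(x - center)^2 / (2 * (fwhm / 2.3548200450309493)^2))
}

# dense-grid argmax oracle: apex positions of an analytic mixture evaluated
# on a 0.01 cm^-1 grid, independent of the package's detection path
dense_argmax <- function(f, lo, hi) {
  x <- seq(lo, hi, by = 0.01)
  y <- f(x)
  idx <- which(diff(sign(diff(y))) < 0) + 1L
  x[idx]
}

# dense-grid second-derivative-minimum oracle (numeric differentiation)
dense_d2_minima <- function(f, lo, hi) {
  x <- seq(lo, hi, by = 0.01)
  y <- f(x)
  d2 <- diff(y, differences = 2) / 0.01^2
  idx <- which(diff(sign(diff(d2))) > 0) + 1L
  idx <- idx[d2[idx] < 0]
  x[idx + 1L]
}

# a small uniform grid over the carrageenan diagnostic region
carr_grid <- function() canonical_grid(800, 1240)

# noise-free single-component spectrum on the canonical full grid
pure_spectrum <- function(component, seed = 1L) {
  simulate_spectrum(stats::setNames(list(1), component), seed = seed)
}

# detection + matching against the carrageenan library on the diagnostic
# window (noise-free convenience path used by many tests)
carr_report <- function(spectrum) {
  s <- baseline_correct(crop(spectrum, "carrageenan"))
  match_bands(detect_peaks(s), band_library("carrageenan"))
}
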