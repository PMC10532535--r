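test_that("pseudo-Voigt has unit-height apex and the stated half width", {
  x <- seq(-50, 50, by = 0.01)
  for (eta in c(0, 0.3, 1)) {
    y <- pseudo_voigt(x, 0, 1, 10, eta)
    expect_equal(max(y), 1, tolerance = 1e-6)
    half <- range(x[y >= 0.5])
    expect_equal(diff(half), 10, tolerance = 0.05)
  }
})

test_that("component band sets carry the published standard positions", {
  iota <- component_bandset("iota")
  expect_equal(iota$center,
               c(1218.05, 1066.37, 967.89, 923.74, 901.51, 870.45, 844.7, 802.5))
  expect_equal(nrow(iota), 8L)
  kappa <- component_bandset("kappa")
  expect_equal(kappa$center,
               c(1224.62, 1063.61, 970, 921.27, 874.26, 843.27))
  fuc <- component_bandset("fucoidan")
  expect_equal(fuc$center, c(1220, 1020, 820))
  alg <- component_bandset("alginate")
  expect_equal(alg$center, c(1600, 1410, 1081, 1026, 797))
  expect_error(component_bandset("agarose"), "unknown")
})

test_that("degenerate compositions are rejected or contribute nothing", {
  g <- canonical_grid(800, 900)
  expect_error(composition_profile(c(iota = 0)), "positive")
  expect_error(composition_profile(c(agar = 1)), "components")
  # a zero-weight component contributes no bands
  sp <- simulate_spectrum(c(iota = 1, nu = 0), grid = g, seed = 5)
  truth <- attr(sp, "ground_truth")
  expect_false("nu" %in% truth$component)
  # far from every iota band the noise-free, drift-free trace is ~0
  far <- simulate_spectrum(c(fucoidan = 1), grid = canonical_grid(3000, 3100),
                           seed = 5)
  expect_lt(max(far$absorbance), 1e-4)
})

test_that("seeding is exact: same seed identical, different seed different", {
  a <- simulate_spectrum(c(iota = 1), noise_sd = 0.01, seed = 42)
  b <- simulate_spectrum(c(iota = 1), noise_sd = 0.01, seed = 42)
  c <- simulate_spectrum(c(iota = 1), noise_sd = 0.01, seed = 43)
  expect_identical(a$absorbance, b$absorbance)
  expect_false(identical(a$absorbance, c$absorbance))
})

test_that("noise-free planted bands are recovered within half a wavenumber", {
  lib_windows <- list(iota = "carrageenan", kappa = "carrageenan")
  for (comp in c("iota", "kappa", "fucoidan", "alginate")) {
    sp <- simulate_spectrum(stats::setNames(list(1), comp), seed = 1)
    win <- if (comp %in% c("iota", "kappa")) c(790, 1250) else c(500, 1700)
    s <- baseline_correct(crop(sp, win))
    pk <- detect_peaks(s)
    truth <- attr(sp, "ground_truth")
    for (ctr in truth$center) {
      expect_lt(min(abs(pk$position - ctr)), 0.5,
                label = sprintf("%s band at %.2f recovered", comp, ctr))
    }
  }
})

test_that("raising the nu weight raises the matched 867 band height", {
  g <- carr_grid()
  heights <- vapply(c(0, 0.1, 0.2, 0.3, 0.4, 0.5), function(w) {
    prof <- if (w == 0) c(iota = 1) else c(iota = 1, nu = w)
    sp <- simulate_spectrum(prof, grid = g, seed = 3)
    rep <- match_bands(detect_peaks(baseline_correct(sp)),
                       band_library("carrageenan"))
    rep$height[rep$code == "G/D6S*"]
  }, 0)
  expect_true(all(is.finite(heights)))
  expect_true(all(diff(heights) > 0))
})

test_that("seasonal datasets have the designed shape and determinism", {
  simA <- simulate_seasonal_dataset(shipped_design("solieria_2014"))
  expect_equal(length(simA$set), 36L)
  months <- vapply(simA$set$spectra, function(s) s$meta$month, 0L)
  expect_equal(sort(unique(months)), 1:12)
  expect_equal(unname(table(months)), rep(3L, 12L), ignore_attr = TRUE)
  simB <- simulate_seasonal_dataset(shipped_design("solieria_2014"))
  for (i in seq_len(length(simA$set)))
    expect_identical(simA$set[[i]]$absorbance, simB$set[[i]]$absorbance)
  expect_identical(simA$ground_truth, simB$ground_truth)

  simC <- simulate_seasonal_dataset(shipped_design("sargassum_2015"))
  expect_equal(length(simC$set), 12L)
  expect_equal(sort(unique(vapply(simC$set$spectra,
                                  function(s) s$meta$month, 0L))),
               c(2L, 4L, 6L, 10L))
})

test_that("per-month seeds are stable when months are added", {
  base <- shipped_design("solieria_2014")
  # a design holding only March must reproduce the full design's March draws
  march <- seasonal_design(data.frame(month = 3, year = 2014),
                           base$profiles["2014-3"],
                           n_replicates = base$n_replicates,
                           position_jitter_sd = base$position_jitter_sd,
                           height_cv = base$height_cv,
                           noise_sd = base$noise_sd,
                           baseline_drift_amplitude = base$baseline_drift_amplitude,
                           seed = base$seed, species = base$species)
  g <- canonical_grid(800, 900)
  full <- simulate_seasonal_dataset(base, grid = g)
  solo <- simulate_seasonal_dataset(march, grid = g)
  ids_full <- set_sample_ids(full$set)
  for (i in seq_len(length(solo$set))) {
    j <- match(set_sample_ids(solo$set)[i], ids_full)
    expect_identical(solo$set[[i]]$absorbance, full$set[[j]]$absorbance)
  }
})

test_that("single replicates with zero dispersion are reproducible", {
  d <- seasonal_design(data.frame(month = 6, year = 2020),
                       list("2020-6" = composition_profile(c(iota = 1))),
                       n_replicates = 1L, position_jitter_sd = 0,
                       height_cv = 0, noise_sd = 0,
                       baseline_drift_amplitude = 0, seed = 9L)
  g <- canonical_grid(800, 900)
  a <- simulate_seasonal_dataset(d, grid = g)
  b <- simulate_seasonal_dataset(d, grid = g)
  expect_identical(a$set[[1]]$absorbance, b$set[[1]]$absorbance)
})
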