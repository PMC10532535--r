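# PCA property tests use raw conditioning (no baseline, no normalization) so
# the planted low-rank structure is preserved exactly.
pp_raw <- preprocess_config(window = "carrageenan", baseline_method = "none",
                            normalization = "none")

rank1_set <- function(n = 5) {
  g <- canonical_grid(800, 1240)
  base <- gauss(g, 968, 1, 12) + gauss(g, 845, 0.8, 12)
  d <- gauss(g, 805, 1, 12)
  spectrum_set(lapply(seq_len(n), function(i)
    ftir_spectrum(g, base + (i / n) * d,
                  sample_meta(sample_id = sprintf("s%02d", i)))),
    common_grid = g)
}

test_that("rank-1 variation puts all variance on PC-1", {
  m <- pca_fit(rank1_set(), window = "carrageenan", preprocess = pp_raw)
  expect_equal(m$explained_pct[1], 100, tolerance = 1e-6)
  expect_lt(sum(m$explained_pct[-1]), 1e-6)
})

test_that("explained variances are non-increasing, bounded, and loadings orthonormal", {
  set.seed(11)
  g <- canonical_grid(800, 1240)
  set <- spectrum_set(lapply(1:8, function(i)
    ftir_spectrum(g, gauss(g, 968, 1 + 0.1 * rnorm(1), 12) +
                       gauss(g, 845, 0.8 + 0.1 * rnorm(1), 12) +
                       0.01 * rnorm(length(g)),
                  sample_meta(sample_id = sprintf("s%02d", i)))))
  m <- pca_fit(set, window = "carrageenan", preprocess = pp_raw)
  expect_true(all(diff(m$explained_pct) <= 1e-9))
  expect_lte(sum(m$explained_pct), 100 + 1e-6)
  gram <- m$loadings %*% t(m$loadings)
  expect_equal(gram, diag(nrow(m$loadings)), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("all components reconstruct the centered data to 1e-8", {
  set.seed(12)
  g <- canonical_grid(800, 1240)
  set <- spectrum_set(lapply(1:6, function(i)
    ftir_spectrum(g, gauss(g, 930, 1 + 0.2 * rnorm(1), 14) +
                       gauss(g, 1066, 0.5 + 0.2 * rnorm(1), 14),
                  sample_meta(sample_id = sprintf("s%02d", i)))))
  m <- pca_fit(set, window = "carrageenan", preprocess = pp_raw)
  X <- t(vapply(set$spectra, function(s)
    crop(s, "carrageenan")$absorbance, numeric(length(m$grid))))
  recon <- m$scores %*% m$loadings + matrix(m$mean_trace, nrow(X),
                                            ncol(X), byrow = TRUE)
  expect_lt(max(abs(recon - X)), 1e-8)
})

test_that("two classes differing in one band separate fully on PC-1", {
  g <- canonical_grid(800, 1240)
  base <- gauss(g, 968, 1, 12) + gauss(g, 845, 0.8, 12)
  amp <- c(0, 0, 0, 0.4, 0.4, 0.4)
  set <- spectrum_set(lapply(seq_along(amp), function(i)
    ftir_spectrum(g, base + amp[i] * gauss(g, 805, 1, 12),
                  sample_meta(sample_id = sprintf("s%02d", i)))))
  m <- pca_fit(set, window = "carrageenan", preprocess = pp_raw)
  expect_equal(m$explained_pct[1], 100, tolerance = 1e-6)
  expect_lt(m$explained_pct[2], 1e-6)
  cls <- rep(c("lo", "hi"), each = 3)
  expect_gt(min(abs(tapply(m$scores[, 1], cls, mean))), 0)
  expect_true(max(m$scores[cls == "lo", 1]) < min(m$scores[cls == "hi", 1]) ||
              min(m$scores[cls == "lo", 1]) > max(m$scores[cls == "hi", 1]))
})

test_that("results are invariant to sample order and uniform scaling", {
  set <- rank1_set(6)
  m1 <- pca_fit(set, window = "carrageenan", preprocess = pp_raw)
  perm <- c(4, 2, 6, 1, 5, 3)
  setp <- spectrum_set(set$spectra[perm])
  m2 <- pca_fit(setp, window = "carrageenan", preprocess = pp_raw)
  expect_equal(m1$explained_pct, m2$explained_pct, tolerance = 1e-9)
  expect_equal(m1$scores[m2$sample_ids, ], m2$scores, tolerance = 1e-8)
  sets <- spectrum_set(lapply(set$spectra, function(s)
    ftir_spectrum(s$wavenumbers, 4.2 * s$absorbance, s$meta)))
  m3 <- pca_fit(sets, window = "carrageenan", preprocess = pp_raw)
  expect_equal(m1$explained_pct, m3$explained_pct, tolerance = 1e-9)
})

test_that("k planted modes give an explained-variance elbow at k", {
  set.seed(13)
  g <- canonical_grid(800, 1240)
  base <- gauss(g, 968, 1, 12)
  d1 <- gauss(g, 805, 1, 12)
  d2 <- gauss(g, 1218, 1, 12)
  set <- spectrum_set(lapply(1:10, function(i)
    ftir_spectrum(g, base + rnorm(1, 0, 0.3) * d1 + rnorm(1, 0, 0.3) * d2 +
                       rnorm(length(g), 0, 0.01),
                  sample_meta(sample_id = sprintf("s%02d", i)))))
  m <- pca_fit(set, window = "carrageenan", preprocess = pp_raw)
  expect_gt(sum(m$explained_pct[1:2]), 95)
  expect_true(all(m$explained_pct[3:length(m$explained_pct)] < 1))
})

test_that("fewer than 3 spectra are rejected", {
  expect_error(pca_fit(spectrum_set(rank1_set(5)$spectra[1:2]),
                       window = "carrageenan", preprocess = pp_raw),
               "at least 3")
})

test_that("projection of the training set reproduces the scores", {
  set <- rank1_set(5)
  m <- pca_fit(set, window = "carrageenan", preprocess = pp_raw)
  proj <- predict(m, set)
  expect_equal(unname(proj), unname(m$scores), tolerance = 1e-8)
})

test_that("ideal point-clusters give silhouette 1 and singletons are flagged", {
  g <- canonical_grid(800, 1240)
  base <- gauss(g, 968, 1, 12)
  d <- gauss(g, 805, 1, 12)
  amp <- c(0, 0, 1, 1, 3)
  set <- spectrum_set(lapply(seq_along(amp), function(i)
    ftir_spectrum(g, base + amp[i] * d,
                  sample_meta(sample_id = sprintf("s%02d", i)))))
  m <- pca_fit(set, window = "carrageenan", preprocess = pp_raw)
  gs <- season_separation(m, c("a", "a", "b", "b", "c"), 2)
  expect_equal(gs$per_group_silhouette[["a"]], 1, tolerance = 1e-9)
  expect_equal(gs$per_group_silhouette[["b"]], 1, tolerance = 1e-9)
  expect_equal(gs$per_group_silhouette[["c"]], 0)
  expect_equal(gs$singletons, "c")
})

test_that("shuffled labels on separated groups score near zero", {
  sim <- simulate_seasonal_dataset(shipped_design("solieria_2014"))
  m <- pca_fit(sim$set, window = "pca_red", n_components = 2)
  months <- vapply(sim$set$spectra, function(s) s$meta$month, 0L)
  block <- ifelse(months >= 9, "mature", "transition")
  real <- season_separation(m, block, 2)$mean_silhouette
  expect_gt(real, 0.5)
  set.seed(21)
  shuffled <- vapply(1:20, function(k)
    season_separation(m, sample(block), 2)$mean_silhouette, 0)
  expect_lt(abs(mean(shuffled)), 0.15)
})
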