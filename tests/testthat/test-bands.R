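test_that("band libraries load with valid windows and unique codes", {
  for (nm in c("carrageenan", "fucoidan", "alginate")) {
    lib <- band_library(nm)
    expect_s3_class(lib, "band_library")
    expect_false(anyDuplicated(lib$code) > 0)
    expect_true(all(lib$center >= lib$window_lo & lib$center <= lib$window_hi))
    expect_equal(attr(lib, "version"), "1.0")
  }
  expect_true(band_library("carrageenan")$shoulder_expected[
    band_library("carrageenan")$code == "DA2S*"])
})

test_that("band matching follows the window / nearest-center contract", {
  lib <- band_library("carrageenan")
  # a single peak inside the sulfate-ester window is matched to it
  rep1 <- match_bands(peak_list(1218.05, 1), lib)
  expect_equal(rep1$status[rep1$code == "S=O"], "matched")
  expect_equal(rep1$position[rep1$code == "S=O"], 1218.05)

  # an out-of-library peak contributes nothing
  rep2 <- match_bands(peak_list(c(700, 1218.05), c(1, 1),
                                source_window = c(650, 1240)), lib)
  expect_identical(rep2$status, rep1$status)

  # the kappa-standard peak set leaves every iota/nu-specific band absent
  kap <- peak_list(c(1224.62, 1063.61, 970, 921.27, 874.26, 843.27),
                   c(1, 0.25, 1, 0.5, 0.25, 1))
  rep3 <- match_bands(kap, lib)
  absent <- c("DA2S", "DA2S*", "G/D2S", "G/D6S")
  expect_true(all(rep3$status[rep3$code %in% absent] == "absent"))
  expect_equal(rep3$position[rep3$code == "S=O"], 1224.62)
})

test_that("matching is invariant to peak order and stays in-window", {
  lib <- band_library("carrageenan")
  pos <- c(1218.05, 1066.37, 967.89, 923.74, 901.51, 870.45, 844.7, 802.5)
  hei <- c(1, 0.25, 1, 0.5, 0.25, 0.25, 1, 0.5)
  a <- match_bands(peak_list(pos, hei), lib)
  set.seed(7)
  for (k in 1:5) {
    o <- sample(length(pos))
    b <- match_bands(peak_list(pos[o], hei[o]), lib)
    expect_identical(a, b)
  }
  ok <- a$status == "matched"
  expect_true(all(a$position[ok] >= lib$window_lo[ok] &
                  a$position[ok] <= lib$window_hi[ok]))
})

test_that("low peaks are demoted to present_low against the tallest match", {
  lib <- band_library("carrageenan")
  rep <- match_bands(peak_list(c(1218, 967.9, 805), c(1, 0.9, 0.05)), lib)
  expect_equal(rep$status[rep$code == "DA2S"], "present_low")
  expect_equal(rep$status[rep$code == "S=O"], "matched")
})

test_that("growing a 867 band walks absent -> present_low -> matched", {
  g <- carr_grid()
  base <- function(x) gauss(x, 1218, 1, 12) + gauss(x, 968, 1, 12) +
    gauss(x, 845, 1, 12)
  lib <- band_library("carrageenan")
  rank <- c(absent = 0, present_low = 1, matched = 2)
  last <- -1
  heights <- c(0, 0.04, 0.3, 0.6)
  for (h in heights) {
    s <- ftir_spectrum(g, base(g) + gauss(g, 867, h, 16))
    st <- match_bands(detect_peaks(s), lib)
    st <- st$status[st$code == "G/D6S*"]
    expect_gte(rank[[st]], last)
    last <- rank[[st]]
  }
  expect_equal(last, 2) # ends fully matched
})

test_that("carrageenan standards classify to their own type", {
  iot <- carr_report(pure_spectrum("iota"))
  tp <- classify_carrageenan(iot)
  expect_equal(tp$dominant, "iota")
  expect_equal(tp$colloid_family, "carrageenan")
  expect_gt(tp$scores[["iota"]], tp$scores[["nu"]])

  kap <- carr_report(pure_spectrum("kappa"))
  tpk <- classify_carrageenan(kap)
  expect_equal(tpk$dominant, "kappa")
  expect_equal(tpk$colloid_family, "carrageenan")
})

test_that("joint iota and nu evidence yields a mixture call", {
  lib <- band_library("carrageenan")
  rep <- match_bands(peak_list(c(805, 905, 867), c(0.5, 0.4, 0.4),
                               is_shoulder = c(FALSE, FALSE, TRUE)), lib)
  expect_equal(rep$status[rep$code %in% c("DA2S", "DA2S*", "G/D6S*")],
               rep("matched", 3))
  expect_equal(classify_carrageenan(rep)$dominant, "mixture")
})

test_that("no specific evidence gives undetermined", {
  lib <- band_library("carrageenan")
  rep <- match_bands(peak_list(c(1218, 968, 845), c(1, 1, 1)), lib)
  tp <- classify_carrageenan(rep)
  expect_equal(tp$dominant, "undetermined")
  expect_equal(tp$colloid_family, "carrageenan") # S=O plus backbone present
  # empty report: no evidence at all
  rep0 <- match_bands(peak_list(numeric(0), numeric(0),
                                source_window = c(800, 1240)), lib)
  expect_equal(classify_carrageenan(rep0)$dominant, "undetermined")
})

test_that("iota-only synthetic spectra are never called kappa or nu", {
  for (i in 1:25) {
    sp <- simulate_spectrum(c(iota = 1), position_jitter_sd = 0.3,
                            height_cv = 0.05, seed = 100 + i)
    tp <- classify_carrageenan(carr_report(sp))
    expect_false(tp$dominant %in% c("kappa", "nu"))
  }
})

test_that("marker fractions decide the colloid family", {
  libs <- list(band_library("carrageenan"), band_library("fucoidan"),
               band_library("alginate"))
  fuc <- classify_colloid_family(peak_list(c(1220, 1020, 820), c(1, 0.8, 0.6)),
                                 libs)
  expect_equal(fuc$colloid_family, "fucoidan")
  expect_equal(fuc$fractions[["fucoidan"]], 1)

  alg <- classify_colloid_family(
    peak_list(c(1600, 1410, 1081, 1026, 797), c(1, 0.8, 0.6, 0.9, 0.5)), libs)
  expect_equal(alg$colloid_family, "alginate")
  expect_equal(alg$fractions[["alginate"]], 1)

  none <- classify_colloid_family(peak_list(numeric(0), numeric(0),
                                            source_window = c(400, 4000)), libs)
  expect_equal(none$colloid_family, "undetermined")
  expect_error(classify_colloid_family(peak_list(1220, 1), list()), "non-empty")
})

test_that("assignment tables render matched/low/absent cells like Table rows", {
  lib <- band_library("carrageenan")
  iota_rep <- match_bands(peak_list(
    c(1218.05, 1066.37, 967.89, 923.74, 901.51, 870.45, 844.7, 802.5),
    c(1, 0.25, 1, 0.5, 0.25, 0.25, 1, 0.5)), lib,
    meta = sample_meta(sample_id = "IOTA Stand."))
  tab <- report_to_table(list(iota_rep))
  expect_equal(tab$sample, "IOTA Stand.")
  expect_equal(tab[["S=O"]], "1218.05")
  expect_equal(tab[["DA2S"]], "802.50")
  expect_equal(tab[["G/D2S"]], "-")
  expect_equal(tab[["G/D6S"]], "-")

  # low-intensity cell renders "+"
  low_rep <- match_bands(peak_list(c(1218, 968, 805), c(1, 0.9, 0.05)), lib)
  tab2 <- report_to_table(list(low_rep))
  expect_equal(tab2[["DA2S"]], "+")

  # empty list gives a header-only table
  expect_equal(nrow(report_to_table(list())), 0L)

  # mixed libraries are rejected
  fuc_rep <- match_bands(peak_list(1220, 1), band_library("fucoidan"))
  expect_error(report_to_table(list(iota_rep, fuc_rep)), "same library")
})

test_that("shoulder-expected bands prefer shoulder matches", {
  lib <- band_library("carrageenan")
  pk <- peak_list(c(903, 906), c(0.4, 0.3), is_shoulder = c(FALSE, TRUE))
  rep <- match_bands(pk, lib)
  row <- rep[rep$code == "DA2S*", ]
  expect_equal(row$status, "matched")
  expect_true(row$is_shoulder)
  expect_equal(row$position, 906)
})
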