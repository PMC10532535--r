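# Diagnostic band libraries, peak/shoulder detection, band matching,
# assignment tables and colloid classification.

#' Load a diagnostic band library
#'
#' Libraries ship as versioned plain-text CSV files under `extdata`
#' (columns: code, center, window_lo, window_hi, types, shoulder_expected,
#' specificity). The `carrageenan` library covers the structural-unit bands
#' of the 800-1240 cm^-1 diagnostic region (sulfate ester S=O,
#' 3,6-anhydrogalactose DA/DA2S, galactose backbone G/D with its sulfated
#' variants, G4S); `fucoidan` and `alginate` hold the family marker bands.
#'
#' @param name `"carrageenan"`, `"fucoidan"`, `"alginate"`, or a path to a
#'   library CSV of the same layout.
#' @return A data frame of class `band_library` with attributes `name` and
#'   `version`.
#' @export
band_library <- function(name = c("carrageenan", "fucoidan", "alginate")) {
  if (length(name) == 1 && file.exists(name)) {
    path <- name
    libname <- tools::file_path_sans_ext(basename(name))
  } else {
    name <- match.arg(name)
    path <- system.file("extdata", paste0("band_library_", name, ".csv"),
                        package = "phycospec", mustWork = TRUE)
    libname <- name
  }
  header <- readLines(path, n = 1)
  version <- sub(".*version\\s+([0-9.]+).*", "\\1", header)
  if (identical(version, header)) version <- "unversioned"
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("code", "center", "window_lo", "window_hi", "types",
            "shoulder_expected", "specificity")
  if (!all(need %in% names(d)))
    stop("band library is missing columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  if (anyDuplicated(d$code))
    stop("band codes must be unique within a library")
  key <- paste(d$window_lo, d$window_hi)
  if (anyDuplicated(key))
    stop("identical windows under different codes are not allowed")
  if (any(d$center < d$window_lo | d$center > d$window_hi))
    stop("every band center must lie inside its window")
  d$shoulder_expected <- as.logical(d$shoulder_expected)
  structure(d, class = c("band_library", "data.frame"),
            name = libname, version = version)
}

#' @export
print.band_library <- function(x, ...) {
  cat(sprintf("Band library '%s' (version %s): %d bands\n",
              attr(x, "name"), attr(x, "version"), nrow(x)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Construct a peak list by hand
#'
#' Mostly useful for testing band matching against known peak positions;
#' [detect_peaks()] builds peak lists from spectra.
#'
#' @param position apex/shoulder wavenumbers (cm^-1).
#' @param height heights above the corrected baseline (AU).
#' @param prominence topological prominences (AU); 0 for shoulders.
#' @param is_shoulder logical flags.
#' @param source_window the analysis window the peaks came from.
#' @return A `peak_list` data frame sorted by position.
#' @export
peak_list <- function(position, height, prominence = height,
                      is_shoulder = FALSE,
                      source_window = range(position)) {
  out <- data.frame(position = position, height = height,
                    prominence = prominence,
                    is_shoulder = rep_len(is_shoulder, length(position)))
  if (any(out$height < 0)) stop("peak heights must be non-negative")
  if (any(!out$is_shoulder & out$prominence > out$height + 1e-12))
    stop("prominence cannot exceed height for apex peaks")
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("peak_list", "data.frame"),
            source_window = as.numeric(source_window))
}

# Topological prominence of local maximum i: height above the higher of the
# two valley minima separating it from the nearest taller point (or edge).
peak_prominence <- function(y, i) {
  n <- length(y)
  lmin <- y[i]; j <- i
  while (j > 1 && y[j - 1] <= y[i]) { j <- j - 1; lmin <- min(lmin, y[j]) }
  if (j == 1) lmin <- min(y[1:i])
  rmin <- y[i]; j <- i
  while (j < n && y[j + 1] <= y[i]) { j <- j + 1; rmin <- min(rmin, y[j]) }
  if (j == n) rmin <- min(y[i:n])
  y[i] - max(lmin, rmin)
}

# 3-point parabolic apex refinement around index i
parabolic_refine <- function(x, y, i) {
  if (i <= 1 || i >= length(y)) return(list(pos = x[i], val = y[i]))
  d1 <- (y[i + 1] - y[i - 1]) / 2
  d2 <- y[i + 1] - 2 * y[i] + y[i - 1]
  if (d2 == 0) return(list(pos = x[i], val = y[i]))
  delta <- -d1 / d2
  delta <- max(min(delta, 1), -1)
  h <- x[i + 1] - x[i]
  list(pos = x[i] + delta * h, val = y[i] + 0.5 * d1 * delta)
}

#' Detect absorption peaks and shoulders
#'
#' Apex peaks are local maxima whose topological prominence reaches
#' `min_prominence_frac` of the window's absorbance range; apex positions are
#' refined by 3-point parabolic interpolation. Shoulders -- partially
#' resolved bands riding on the flank of a stronger one -- are found as
#' additional local minima of the Savitzky-Golay second derivative whose
#' magnitude reaches `shoulder_threshold` of the window's largest
#' second-derivative magnitude and which lie outside the derivative
#' filter's half-support of any apex (second-derivative structure closer to
#' an apex than the filter can resolve belongs to the apex, not to a
#' separate band).
#'
#' @param spectrum a baseline-corrected `ftir_spectrum` on a uniform grid,
#'   cropped to the analysis window.
#' @param min_prominence_frac apex prominence threshold as a fraction of the
#'   window's absorbance range (default 0.02).
#' @param shoulder_threshold second-derivative magnitude threshold as a
#'   fraction of the window maximum (default 0.10).
#' @param noise_sd estimated noise standard deviation of the input trace
#'   (absorbance units). When positive, apexes must also clear a prominence
#'   of `5 * noise_sd` and shoulders an absorbance of `5 * noise_sd`, which
#'   suppresses spurious detections on noisy spectra; the default 0 applies
#'   the fractional thresholds alone.
#' @param sg_window_points,sg_polyorder Savitzky-Golay settings for the
#'   second derivative.
#' @return A data frame of class `peak_list` (columns `position`, `height`,
#'   `prominence`, `is_shoulder`), sorted by position, with attribute
#'   `source_window`.
#' @export
detect_peaks <- function(spectrum, min_prominence_frac = 0.02,
                         shoulder_threshold = 0.10, noise_sd = 0,
                         sg_window_points = 21L, sg_polyorder = 3L) {
  stopifnot(inherits(spectrum, "ftir_spectrum"))
  grid_step(spectrum) # precondition: uniform grid
  x <- spectrum$wavenumbers
  y <- spectrum$absorbance
  n <- length(y)
  if (n < sg_window_points)
    stop("window too short for the Savitzky-Golay filter")
  rng <- max(y) - min(y)
  if (rng == 0) {
    out <- data.frame(position = numeric(), height = numeric(),
                      prominence = numeric(), is_shoulder = logical())
    return(structure(out, class = c("peak_list", "data.frame"),
                     source_window = range(x)))
  }
  # apex candidates: strict local maxima (plateaus take their first point)
  prom_floor <- max(min_prominence_frac * rng, 5 * noise_sd)
  is_max <- which(diff(sign(diff(y))) < 0) + 1L
  apex <- list()
  for (i in is_max) {
    p <- peak_prominence(y, i)
    if (p >= prom_floor) {
      r <- parabolic_refine(x, y, i)
      apex[[length(apex) + 1]] <- c(pos = r$pos, height = r$val,
                                    prom = p, idx = i)
    }
  }
  apex_idx <- vapply(apex, function(a) a[["idx"]], 0)
  # shoulders: local minima of the second derivative away from apexes
  d2 <- signal::sgolayfilt(y, p = sg_polyorder, n = sg_window_points, m = 2,
                           ts = x[2] - x[1])
  d2min <- which(diff(sign(diff(d2))) > 0) + 1L
  maxd2 <- max(abs(d2))
  shoulders <- list()
  for (i in d2min) {
    if (d2[i] >= 0) next
    if (abs(d2[i]) < shoulder_threshold * maxd2) next
    if (noise_sd > 0 && y[i] < 5 * noise_sd) next
    if (length(apex_idx) &&
        min(abs(i - apex_idx)) <= (sg_window_points - 1) / 2) next
    r <- parabolic_refine(x, -d2, i) # refine on the second-derivative dip
    shoulders[[length(shoulders) + 1]] <- c(pos = r$pos, height = y[i],
                                            prom = 0, idx = i)
  }
  rows <- c(apex, shoulders)
  out <- data.frame(
    position = vapply(rows, function(a) a[["pos"]], 0),
    height = vapply(rows, function(a) a[["height"]], 0),
    prominence = vapply(rows, function(a) a[["prom"]], 0),
    is_shoulder = rep(c(FALSE, TRUE), c(length(apex), length(shoulders)))
  )
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("peak_list", "data.frame"),
            source_window = range(x))
}

#' @export
print.peak_list <- function(x, ...) {
  w <- attr(x, "source_window")
  cat(sprintf("Peak list: %d apexes, %d shoulders in [%.1f, %.1f] cm^-1\n",
              sum(!x$is_shoulder), sum(x$is_shoulder), w[1], w[2]))
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Match detected peaks to a diagnostic band library
#'
#' Each library band is assigned at most one detected peak (apex or
#' shoulder) from inside its window, and each peak satisfies at most one
#' band. Bands marked shoulder-expected prefer shoulder matches over apexes
#' when both are available; otherwise the peak nearest the band center wins,
#' with ties broken toward the lower wavenumber. After matching, a matched
#' peak whose height falls below `low_intensity_frac` of the tallest matched
#' height is demoted to `present_low` (the "+" convention of assignment
#' tables); bands with no in-window peak are `absent`.
#'
#' @param peaks a `peak_list` from [detect_peaks()].
#' @param library a [band_library()].
#' @param low_intensity_frac the low-intensity demotion fraction
#'   (default 0.08).
#' @param meta optional [sample_meta()] carried into the report.
#' @return A data frame of class `band_assignment` with one row per library
#'   code: `code`, `status` (`matched`/`present_low`/`absent`), `position`,
#'   `height`, `is_shoulder`.
#' @export
match_bands <- function(peaks, library, low_intensity_frac = 0.08,
                        meta = NULL) {
  stopifnot(inherits(peaks, "peak_list"), inherits(library, "band_library"))
  nb <- nrow(library); np <- nrow(peaks)
  status <- rep("absent", nb)
  pos <- rep(NA_real_, nb); hei <- rep(NA_real_, nb)
  shl <- rep(NA, nb)
  if (np > 0) {
    # candidate (band, peak) pairs, ranked: shoulder preference first for
    # shoulder-expected bands, then distance to center, then lower wavenumber
    cand <- NULL
    for (b in seq_len(nb)) {
      inw <- which(peaks$position >= library$window_lo[b] &
                   peaks$position <= library$window_hi[b])
      if (!length(inw)) next
      pref <- if (library$shoulder_expected[b] && any(peaks$is_shoulder[inw]))
        ifelse(peaks$is_shoulder[inw], 0L, 1L) else rep(0L, length(inw))
      cand <- rbind(cand, data.frame(
        band = b, peak = inw, pref = pref,
        dist = abs(peaks$position[inw] - library$center[b]),
        wn = peaks$position[inw]))
    }
    if (!is.null(cand)) {
      cand <- cand[order(cand$pref, cand$dist, cand$wn), , drop = FALSE]
      band_done <- rep(FALSE, nb); peak_done <- rep(FALSE, np)
      for (k in seq_len(nrow(cand))) {
        b <- cand$band[k]; p <- cand$peak[k]
        if (band_done[b] || peak_done[p]) next
        band_done[b] <- TRUE; peak_done[p] <- TRUE
        status[b] <- "matched"
        pos[b] <- peaks$position[p]
        hei[b] <- peaks$height[p]
        shl[b] <- peaks$is_shoulder[p]
      }
    }
    matched <- status == "matched"
    if (any(matched)) {
      tallest <- max(hei[matched])
      low <- matched & hei < low_intensity_frac * tallest
      status[low] <- "present_low"
    }
  }
  out <- data.frame(code = library$code, status = status, position = pos,
                    height = hei, is_shoulder = shl,
                    stringsAsFactors = FALSE)
  structure(out, class = c("band_assignment", "data.frame"),
            library_name = attr(library, "name"),
            library_version = attr(library, "version"),
            library = library,
            meta = if (is.null(meta)) sample_meta() else as_sample_meta(meta))
}

#' @export
print.band_assignment <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("Band assignment (%s library, version %s)%s\n",
              attr(x, "library_name"), attr(x, "library_version"),
              if (!is.na(meta$sample_id)) paste0(" - ", meta$sample_id) else ""))
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Render assignment reports as an assignment table
#'
#' One row per sample, one column per band code. Matched bands print their
#' apex wavenumber to two decimals, low-intensity presences print `"+"`,
#' absences print `"-"` (the conventions of published peak-identification
#' tables).
#'
#' @param reports a list of `band_assignment` objects against one library.
#' @return A character data frame (first column `sample`) ready for CSV
#'   export.
#' @export
report_to_table <- function(reports) {
  if (!is.list(reports) || (length(reports) &&
      !all(vapply(reports, inherits, TRUE, "band_assignment"))))
    stop("reports must be a list of band_assignment objects")
  if (!length(reports)) {
    return(data.frame(sample = character()))
  }
  libs <- vapply(reports, function(r) attr(r, "library_name"), "")
  if (length(unique(libs)) != 1)
    stop("all reports must come from the same library")
  codes <- reports[[1]]$code
  rows <- lapply(reports, function(r) {
    if (!identical(r$code, codes)) stop("reports disagree on band codes")
    cell <- ifelse(r$status == "matched", sprintf("%.2f", r$position),
                   ifelse(r$status == "present_low", "+", "-"))
    cell
  })
  ids <- vapply(reports, function(r) {
    id <- attr(r, "meta")$sample_id
    if (is.na(id)) "" else id
  }, "")
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- codes
  cbind(data.frame(sample = ids, stringsAsFactors = FALSE), out)
}

# weight of one assignment row toward classification scores
assignment_weight <- function(status) {
  ifelse(status == "matched", 1, ifelse(status == "present_low", 0.5, 0))
}

#' Classify carrageenan type from a band assignment
#'
#' Decision rule (documented in the methods vignette): the iota-unique
#' 2-sulfated anhydrogalactose bands (DA2S at 805 cm^-1, DA2S* at 905 cm^-1)
#' define iota evidence; the anhydro bands (DA at 930, DA* at 1070) are
#' shared between iota and kappa and count toward kappa only when no
#' iota-unique band is present (anhydro plus 2-sulfate is iota, anhydro
#' alone is kappa); the nu precursor is evidenced by G/D2S, G/D6S and the
#' 867 cm^-1 G/D6S* shoulder, the latter at full weight only when matched
#' within 2 cm^-1 of 867 (matches out at 871-874 cm^-1 are ambiguous sulfate
#' signatures and count half). Matched bands weigh 1, low-intensity
#' presences 0.5. The dominant type is the strictly largest score; a mixture
#' is declared when at least two types score >= 1; undetermined when no
#' evidence at all is present.
#'
#' @param report a `band_assignment` produced against the carrageenan
#'   library.
#' @return A list of class `type_profile` with `evidence` (per-type specific
#'   and shared counts), `scores`, `dominant` and `colloid_family`.
#' @export
classify_carrageenan <- function(report) {
  stopifnot(inherits(report, "band_assignment"))
  if (!identical(attr(report, "library_name"), "carrageenan"))
    stop("report was not produced against the carrageenan library")
  lib <- attr(report, "library")
  w <- assignment_weight(report$status)
  names(w) <- report$code
  gv <- function(code) if (code %in% names(w)) w[[code]] else 0
  uniq_iota <- gv("DA2S") + gv("DA2S*")
  anhydro <- gv("DA") + gv("DA*")
  # G/D6S* ambiguity: full nu weight only near the nominal 867 cm^-1 center
  g6s_star <- gv("G/D6S*")
  if (g6s_star > 0) {
    p <- report$position[report$code == "G/D6S*"]
    if (!is.na(p) && abs(p - 867) > 2) g6s_star <- g6s_star * 0.5
  }
  nu <- gv("G/D2S") + gv("G/D6S") + g6s_star
  iota <- if (uniq_iota > 0) uniq_iota + anhydro else 0
  kappa <- if (uniq_iota == 0) anhydro else 0
  scores <- c(iota = iota, kappa = kappa, nu = nu)
  shared_codes <- lib$code[lib$specificity == "shared"]
  shared_n <- vapply(c("iota", "kappa", "nu"), function(tp) {
    codes <- lib$code[grepl(tp, lib$types) & lib$specificity == "shared"]
    sum(report$status[report$code %in% codes] != "absent")
  }, 0)
  evidence <- lapply(c(iota = "iota", kappa = "kappa", nu = "nu"), function(tp) {
    spec_codes <- lib$code[grepl(tp, lib$types) & lib$specificity == "specific"]
    c(n_specific_bands_matched =
        sum(report$status[report$code %in% spec_codes] != "absent"),
      n_shared_bands_matched = unname(shared_n[tp]))
  })
  dominant <- if (all(scores == 0)) {
    "undetermined"
  } else if (sum(scores >= 1) >= 2) {
    "mixture"
  } else if (sum(scores == max(scores)) > 1) {
    "mixture" # tied evidence below the mixture threshold: call it mixed
  } else {
    names(scores)[which.max(scores)]
  }
  family <- if (gv("S=O") > 0 && (gv("G/D") > 0 || gv("G4S") > 0))
    "carrageenan" else "undetermined"
  structure(list(evidence = evidence, scores = scores, dominant = dominant,
                 colloid_family = family),
            class = "type_profile")
}

#' @export
print.type_profile <- function(x, ...) {
  cat("Type profile\n")
  cat("  dominant type:", x$dominant, "\n")
  cat("  colloid family:", x$colloid_family, "\n")
  if (!is.null(x$scores))
    cat("  scores:", paste(sprintf("%s=%.2f", names(x$scores), x$scores),
                           collapse = "  "), "\n")
  invisible(x)
}

#' Classify colloid family from detected peaks
#'
#' Scores each candidate library by the fraction of its marker bands matched
#' by the detected peaks (via [match_bands()]); the family of the library
#' with the strictly highest fraction wins. Ties and all-zero fractions give
#' `undetermined`.
#'
#' @param peaks a `peak_list` from a full-window detection.
#' @param libraries a non-empty list of [band_library()] objects.
#' @param low_intensity_frac passed to [match_bands()]; low-intensity
#'   presences count half toward the fraction.
#' @return A list of class `type_profile` with `colloid_family`,
#'   `fractions`, and `dominant = colloid_family` for convenience.
#' @export
classify_colloid_family <- function(peaks, libraries = list(
                                      band_library("carrageenan"),
                                      band_library("fucoidan"),
                                      band_library("alginate")),
                                    low_intensity_frac = 0.08) {
  if (!is.list(libraries) || !length(libraries) ||
      !all(vapply(libraries, inherits, TRUE, "band_library")))
    stop("libraries must be a non-empty list of band_library objects")
  fam_of <- c(carrageenan = "carrageenan", fucoidan = "fucoidan",
              alginate = "alginate")
  fractions <- vapply(libraries, function(lib) {
    rep <- match_bands(peaks, lib, low_intensity_frac)
    sum(assignment_weight(rep$status)) / nrow(lib)
  }, 0)
  names(fractions) <- vapply(libraries, function(l) attr(l, "name"), "")
  best <- max(fractions)
  family <- if (best == 0 || sum(fractions == best) > 1) "undetermined"
            else {
              nm <- names(fractions)[which.max(fractions)]
              if (nm %in% names(fam_of)) unname(fam_of[nm]) else nm
            }
  structure(list(evidence = as.list(fractions), scores = fractions,
                 fractions = fractions,
                 dominant = family, colloid_family = family),
            class = "type_profile")
}

#' One-call classification of a raw spectrum
#'
#' Convenience wrapper: conditions the spectrum over \[500, 1700\] cm^-1
#' (baseline correction, Savitzky-Golay smoothing), detects peaks, decides
#' the colloid family, and -- when the family is carrageenan -- matches the
#' carrageenan library over the 800-1240 cm^-1 diagnostic window and
#' classifies the carrageenan type.
#'
#' @param spectrum a raw `ftir_spectrum` covering at least 500-1700 cm^-1.
#' @param min_prominence_frac,shoulder_threshold,low_intensity_frac detection
#'   and matching thresholds (see [detect_peaks()] and [match_bands()]).
#' @param config a [preprocess_config()]; its window is ignored (the family
#'   and carrageenan windows are fixed here), the baseline and Savitzky-Golay
#'   settings are used.
#' @return A list with `family_profile` (`type_profile`), and for
#'   carrageenans also `report` (`band_assignment`) and `type_profile`.
#' @export
classify_spectrum <- function(spectrum,
                              min_prominence_frac = 0.02,
                              shoulder_threshold = 0.10,
                              low_intensity_frac = 0.08,
                              config = preprocess_config()) {
  s <- crop(spectrum, c(500, 1700))
  s <- baseline_correct(s, config$baseline_method, config$als_lambda,
                        config$als_p, config$als_maxit)
  raw <- s$absorbance
  s <- savgol_derivative(s, 0L, config$sg_window_points, config$sg_polyorder)
  # residual noise floor of the smoothed trace: raw noise estimated robustly
  # from the smoothing residual, scaled by the filter's variance reduction
  sd_raw <- stats::mad(raw - s$absorbance)
  gain <- sqrt(sum(signal::sgolay(p = config$sg_polyorder,
                                  n = config$sg_window_points)[
                     (config$sg_window_points + 1) / 2, ]^2))
  noise_sd <- sd_raw * gain
  pk <- detect_peaks(s, min_prominence_frac, shoulder_threshold, noise_sd,
                     config$sg_window_points, config$sg_polyorder)
  fam <- classify_colloid_family(pk, low_intensity_frac = low_intensity_frac)
  out <- list(family_profile = fam)
  if (identical(fam$colloid_family, "carrageenan")) {
    # pad the diagnostic window so edge bands keep their full prominence
    carr <- window_preset("carrageenan")
    sc <- crop(s, carr + c(-10, 10))
    pk2 <- detect_peaks(sc, min_prominence_frac, shoulder_threshold, noise_sd,
                        config$sg_window_points, config$sg_polyorder)
    rep <- match_bands(pk2, band_library("carrageenan"), low_intensity_frac,
                       meta = spectrum$meta)
    out$report <- rep
    out$type_profile <- classify_carrageenan(rep)
  }
  out
}
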