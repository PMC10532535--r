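# Seeded synthetic ATR-FTIR spectra: pseudo-Voigt bands at the published
# standard positions, composition mixing, baseline drift and noise, plus
# shipped seasonal study designs with known ground truth.

#' Pseudo-Voigt band profile
#'
#' Weighted sum of a Lorentzian (fraction `eta`) and a Gaussian
#' (fraction `1 - eta`), both with the same full width at half maximum and
#' unit apex height scaled by `height`.
#'
#' @param x wavenumbers (cm^-1).
#' @param center band center (cm^-1).
#' @param height apex height (absorbance units).
#' @param fwhm full width at half maximum (cm^-1).
#' @param eta Lorentzian fraction in \[0, 1\].
#' @return numeric vector of absorbance contributions.
#' @export
pseudo_voigt <- function(x, center, height, fwhm, eta = 0.3) {
  if (fwhm <= 0) stop("fwhm must be positive")
  if (height < 0) stop("height must be non-negative")
  if (eta < 0 || eta > 1) stop("eta must be in [0, 1]")
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  gamma <- fwhm / 2
  eta * height * gamma^2 / ((x - center)^2 + gamma^2) +
    (1 - eta) * height * exp(-(x - center)^2 / (2 * sigma^2))
}

# Canonical band sets per component. Carrageenan standards use the apex
# positions reported for the commercial iota and kappa standards; the nu
# precursor uses the nominal diagnostic centers of its sulfate bands.
# Height tiers: 1.0 strong, 0.5 medium, 0.25 weak/shouldered. Shouldered
# bands get a wider profile (16 cm^-1) so they ride the flank of their
# neighbor; other bands use 12 cm^-1. The amide/backbone background carries
# the protein amide-II band and the broad 1022 cm^-1 sugar-ring envelope.
standard_band_table <- function() {
  rbind(
    data.frame(component = "iota",
               code   = c("S=O", "DA*", "G/D", "DA", "DA2S*", "G/D6S*", "G4S", "DA2S"),
               center = c(1218.05, 1066.37, 967.89, 923.74, 901.51, 870.45, 844.7, 802.5),
               height = c(1, 0.25, 1, 0.5, 0.25, 0.25, 1, 0.5),
               fwhm   = c(12, 16, 12, 12, 16, 16, 12, 12)),
    data.frame(component = "kappa",
               code   = c("S=O", "DA*", "G/D", "DA", "G/D6S*", "G4S"),
               center = c(1224.62, 1063.61, 970, 921.27, 874.26, 843.27),
               height = c(1, 0.25, 1, 0.5, 0.25, 1),
               fwhm   = c(12, 16, 12, 12, 16, 12)),
    data.frame(component = "nu",
               code   = c("S=O", "G/D", "G/D6S*", "G4S", "G/D2S", "G/D6S"),
               center = c(1232, 971, 867, 845, 827.5, 817.5),
               height = c(1, 1, 0.25, 1, 0.5, 0.5),
               fwhm   = c(12, 12, 16, 12, 12, 12)),
    data.frame(component = "fucoidan",
               code   = c("S=O", "O=S=O", "C-O-S"),
               center = c(1220, 1020, 820),
               height = c(1, 0.8, 0.6),
               fwhm   = c(12, 12, 12)),
    data.frame(component = "alginate",
               code   = c("C-C/C=O", "C-OH", "GulA-1081", "O=S=O", "GulA-797"),
               center = c(1600, 1410, 1081, 1026, 797),
               height = c(1, 0.8, 0.6, 0.9, 0.5),
               fwhm   = c(12, 12, 12, 12, 12)),
    data.frame(component = "amide_background",
               code   = c("amide-II", "ring-envelope"),
               center = c(1548, 1022),
               height = c(0.3, 0.8),
               fwhm   = c(18, 18))
  )
}

#' Canonical band set of one colloid component
#'
#' Returns the pseudo-Voigt band parameters used to synthesize the named
#' component: centers at the published standard apex positions (iota/kappa
#' carrageenan standards, fucoidan and alginate marker bands, nu-precursor
#' diagnostic centers) with canonical relative heights (strong 1.0 /
#' medium 0.5 / weak-shouldered 0.25).
#'
#' @param component one of `"iota"`, `"kappa"`, `"nu"`, `"fucoidan"`,
#'   `"alginate"`, `"amide_background"`.
#' @param eta Lorentzian fraction applied to every band.
#' @return A data frame with columns `code`, `center`, `height`, `fwhm`,
#'   `eta`.
#' @export
component_bandset <- function(component, eta = 0.3) {
  tab <- standard_band_table()
  if (!component %in% unique(tab$component))
    stop("unknown component: ", component)
  out <- tab[tab$component == component,
             c("code", "center", "height", "fwhm")]
  out$eta <- eta
  rownames(out) <- NULL
  out
}

# deterministic 32-bit hash for per-spectrum seed derivation
stable_hash <- function(...) {
  s <- paste(..., sep = "|")
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}

#' Composition profile
#'
#' Non-negative mixing weights over the simulator components.
#'
#' @param weights named numeric vector or list; names among `iota`, `kappa`,
#'   `nu`, `fucoidan`, `alginate`, `amide_background`.
#' @param name profile label.
#' @return A list of class `composition_profile`.
#' @export
composition_profile <- function(weights, name = "profile") {
  weights <- unlist(weights)
  known <- c("iota", "kappa", "nu", "fucoidan", "alginate", "amide_background")
  if (is.null(names(weights)) || !all(names(weights) %in% known))
    stop("weights must be named with components among: ",
         paste(known, collapse = ", "))
  if (any(weights < 0)) stop("weights must be non-negative")
  if (!any(weights > 0)) stop("at least one weight must be positive")
  structure(list(weights = weights, name = name),
            class = "composition_profile")
}

#' Canonical single-colloid composition profiles
#'
#' The four reference compositions used for classifier validation: pure
#' iota-carrageenan, pure kappa-carrageenan, pure fucoidan and pure
#' alginate, each at unit weight.
#'
#' @return Named list of [composition_profile()] objects.
#' @export
shipped_profiles <- function() {
  list(iota = composition_profile(c(iota = 1), "iota"),
       kappa = composition_profile(c(kappa = 1), "kappa"),
       fucoidan = composition_profile(c(fucoidan = 1), "fucoidan"),
       alginate = composition_profile(c(alginate = 1), "alginate"))
}

#' Simulate one ATR-FTIR spectrum
#'
#' The absorbance is the weighted sum of each component's pseudo-Voigt
#' bands, with per-band center jitter and multiplicative height variation,
#' plus a smooth low-order polynomial baseline drift and additive Gaussian
#' noise. Fully reproducible from `seed`. The realized (post-jitter) band
#' list is attached as attribute `"ground_truth"`.
#'
#' @param profile a [composition_profile()] (or a named weight vector).
#' @param grid strictly increasing wavenumber grid; default the canonical
#'   0.482 cm^-1 instrument grid over \[400, 4000\].
#' @param position_jitter_sd SD of the per-band center jitter (cm^-1).
#' @param height_cv coefficient of variation of per-band heights.
#' @param noise_sd SD of the additive Gaussian noise (absorbance units).
#' @param baseline_drift_amplitude amplitude of the smooth drift (AU).
#' @param seed integer random seed.
#' @param meta optional [sample_meta()].
#' @return An `ftir_spectrum` with attribute `"ground_truth"` (data frame of
#'   planted bands: component, code, center, height, fwhm, eta).
#' @export
simulate_spectrum <- function(profile, grid = canonical_grid(),
                              position_jitter_sd = 0, height_cv = 0,
                              noise_sd = 0, baseline_drift_amplitude = 0,
                              seed = 1L, meta = sample_meta()) {
  if (!inherits(profile, "composition_profile"))
    profile <- composition_profile(profile)
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed %% 2147483647))
  y <- numeric(length(grid))
  truth <- NULL
  for (comp in names(profile$weights)) {
    wt <- profile$weights[[comp]]
    if (wt == 0) next
    bands <- component_bandset(comp)
    for (i in seq_len(nrow(bands))) {
      center <- bands$center[i] +
        if (position_jitter_sd > 0) stats::rnorm(1, 0, position_jitter_sd) else 0
      height <- wt * bands$height[i] *
        (if (height_cv > 0) max(0, 1 + height_cv * stats::rnorm(1)) else 1)
      y <- y + pseudo_voigt(grid, center, height, bands$fwhm[i], bands$eta[i])
      truth <- rbind(truth, data.frame(
        component = comp, code = bands$code[i], center = center,
        height = height, fwhm = bands$fwhm[i], eta = bands$eta[i]))
    }
  }
  if (is.null(truth) || max(y) == 0) {
    if (noise_sd == 0 && baseline_drift_amplitude == 0)
      warning("all weights zero with no noise: returning a flat zero trace")
  }
  if (baseline_drift_amplitude > 0) {
    # smooth cubic drift with random coefficients, scaled to the amplitude
    u <- (grid - grid[1]) / (grid[length(grid)] - grid[1])
    cf <- stats::rnorm(4)
    drift <- cf[1] + cf[2] * u + cf[3] * u^2 + cf[4] * u^3
    drift <- drift - min(drift)
    if (max(drift) > 0) drift <- drift / max(drift) * baseline_drift_amplitude
    y <- y + drift
  }
  if (noise_sd > 0) y <- y + stats::rnorm(length(grid), 0, noise_sd)
  out <- ftir_spectrum(grid, y, meta)
  attr(out, "ground_truth") <- truth
  out
}

#' Seasonal simulation design
#'
#' Describes a monthly sampling campaign: which months are sampled, the
#' composition profile of each month, the replicate count, and the
#' within-month dispersion parameters. Per-spectrum seeds are derived from
#' the master seed by a stable hash of (month, year, replicate), so adding a
#' month never perturbs the draws of the others.
#'
#' @param months data frame with columns `month`, `year`.
#' @param profiles named list mapping `"<year>-<month>"` (or just
#'   `"<month>"`) to [composition_profile()] objects.
#' @param n_replicates replicates per month (default 3, the usual triplicate
#'   acquisition).
#' @param position_jitter_sd,height_cv,noise_sd,baseline_drift_amplitude
#'   within-month dispersion parameters (see [simulate_spectrum()]).
#' @param seed master seed.
#' @param species species label stamped into the metadata.
#' @param name design label.
#' @return A list of class `seasonal_design`.
#' @export
seasonal_design <- function(months, profiles, n_replicates = 3L,
                            position_jitter_sd = 0.5, height_cv = 0.07,
                            noise_sd = 0.01, baseline_drift_amplitude = 0.02,
                            seed = 1L, species = NA_character_,
                            name = "design") {
  stopifnot(is.data.frame(months), all(c("month", "year") %in% names(months)))
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  if (position_jitter_sd < 0 || height_cv < 0 || noise_sd < 0 ||
      baseline_drift_amplitude < 0)
    stop("dispersion parameters must be non-negative")
  keys <- paste0(months$year, "-", months$month)
  miss <- !(keys %in% names(profiles) | as.character(months$month) %in% names(profiles))
  if (any(miss))
    stop("no profile for month(s): ", paste(keys[miss], collapse = ", "))
  structure(list(months = months, profiles = profiles,
                 n_replicates = n_replicates,
                 position_jitter_sd = position_jitter_sd,
                 height_cv = height_cv, noise_sd = noise_sd,
                 baseline_drift_amplitude = baseline_drift_amplitude,
                 seed = as.integer(seed), species = species, name = name),
            class = "seasonal_design")
}

#' Shipped seasonal designs
#'
#' Two ready-made study designs mirroring the published sampling campaigns:
#'
#' * `"solieria_2014"`: twelve months of 2014 in triplicate. September to
#'   December carry a pure iota-carrageenan profile (the mature stage);
#'   January to August add a nu-precursor trace (weight 0.35) and an
#'   amide/backbone background (weight 0.3), giving the two-block seasonal
#'   structure resolved by PCA.
#' * `"sargassum_2015"`: February, April, June and October 2015 in
#'   triplicate; alginate-dominated profiles whose alginate/fucoidan balance
#'   shifts with the season, giving four PCA groups.
#'
#' @param name design name.
#' @param seed master seed (default 20140101 for solieria, 20150101 for
#'   sargassum).
#' @return A [seasonal_design()].
#' @export
shipped_design <- function(name = c("solieria_2014", "sargassum_2015"),
                           seed = NULL) {
  name <- match.arg(name)
  if (name == "solieria_2014") {
    months <- data.frame(month = 1:12, year = 2014)
    mature <- composition_profile(c(iota = 1), "mature_iota")
    transition <- composition_profile(
      c(iota = 1, nu = 0.35, amide_background = 0.3), "transition_mix")
    profiles <- stats::setNames(
      lapply(1:12, function(m) if (m >= 9) mature else transition),
      paste0("2014-", 1:12))
    seasonal_design(months, profiles, n_replicates = 3L,
                    position_jitter_sd = 0.5, height_cv = 0.07,
                    noise_sd = 0.01, baseline_drift_amplitude = 0.02,
                    seed = if (is.null(seed)) 20140101L else seed,
                    species = "S.chordalis", name = name)
  } else {
    months <- data.frame(month = c(2, 4, 6, 10), year = 2015)
    profiles <- list(
      "2015-2"  = composition_profile(c(alginate = 1.0, fucoidan = 0.15), "winter"),
      "2015-4"  = composition_profile(c(alginate = 1.0, fucoidan = 0.55), "spring"),
      "2015-6"  = composition_profile(c(alginate = 0.7, fucoidan = 0.90), "summer"),
      "2015-10" = composition_profile(c(alginate = 1.2, fucoidan = 0.35), "autumn"))
    seasonal_design(months, profiles, n_replicates = 3L,
                    position_jitter_sd = 0.5, height_cv = 0.07,
                    noise_sd = 0.01, baseline_drift_amplitude = 0.02,
                    seed = if (is.null(seed)) 20150101L else seed,
                    species = "S.muticum", name = name)
  }
}

#' Simulate a seasonal dataset
#'
#' Generates `n_replicates` spectra per design month on the canonical grid
#' and records the ground truth (composition weights and realized band
#' parameters per spectrum).
#'
#' @param design a [seasonal_design()] (or a [shipped_design()] name).
#' @param grid wavenumber grid; default the canonical instrument grid.
#' @return A list with `set` (an `ftir_spectrum_set`) and `ground_truth`
#'   (data frame: sample_id, month, year, replicate, profile, component,
#'   code, center, height).
#' @export
simulate_seasonal_dataset <- function(design, grid = canonical_grid()) {
  if (is.character(design)) design <- shipped_design(design)
  stopifnot(inherits(design, "seasonal_design"))
  spectra <- list(); gt <- NULL
  for (i in seq_len(nrow(design$months))) {
    m <- design$months$month[i]; yr <- design$months$year[i]
    key <- paste0(yr, "-", m)
    prof <- design$profiles[[key]]
    if (is.null(prof)) prof <- design$profiles[[as.character(m)]]
    for (r in seq_len(design$n_replicates)) {
      id <- sprintf("%s_%04d-%02d_rep%d",
                    if (is.na(design$species)) "sample" else design$species,
                    yr, m, r)
      seed_i <- (design$seed + stable_hash(m, yr, r)) %% 2147483647
      meta <- sample_meta(sample_id = id, species = design$species,
                          month = m, year = yr, replicate = r)
      sp <- simulate_spectrum(prof, grid,
                              position_jitter_sd = design$position_jitter_sd,
                              height_cv = design$height_cv,
                              noise_sd = design$noise_sd,
                              baseline_drift_amplitude = design$baseline_drift_amplitude,
                              seed = seed_i, meta = meta)
      spectra[[length(spectra) + 1]] <- sp
      tr <- attr(sp, "ground_truth")
      tr <- cbind(data.frame(sample_id = id, month = m, year = yr,
                             replicate = r, profile = prof$name), tr)
      gt <- rbind(gt, tr)
    }
  }
  list(set = spectrum_set(spectra, common_grid = as.numeric(grid)),
       ground_truth = gt)
}
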