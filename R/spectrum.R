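#' Construct an FTIR spectrum object
#'
#' A spectrum is an absorbance trace on a strictly increasing wavenumber grid
#' together with sample metadata. Wavenumbers are always stored ascending;
#' inputs supplied in descending instrument order are reversed (with the
#' absorbance co-reversed) on construction.
#'
#' @param wavenumbers numeric vector of wavenumbers (cm^-1), strictly
#'   monotone, length >= 2, all within \[100, 8000\].
#' @param absorbance numeric vector of absorbance values (dimensionless,
#'   absorbance units), same length as `wavenumbers`, no missing values.
#' @param meta a [sample_meta()] list (or a plain list with its fields).
#' @return An object of class `ftir_spectrum`: a list with elements
#'   `wavenumbers`, `absorbance`, `meta`.
#' @examples
#' s <- ftir_spectrum(c(400, 400.482, 400.964), c(0, 0.1, 0))
#' s
#' @export
ftir_spectrum <- function(wavenumbers, absorbance, meta = sample_meta()) {
  wavenumbers <- as.numeric(wavenumbers)
  absorbance <- as.numeric(absorbance)
  if (length(wavenumbers) != length(absorbance))
    stop("wavenumbers and absorbance must have equal length")
  if (length(wavenumbers) < 2)
    stop("a spectrum needs at least 2 points")
  if (anyNA(wavenumbers) || anyNA(absorbance))
    stop("missing values are not allowed in a spectrum")
  d <- diff(wavenumbers)
  if (all(d < 0)) { # descending source order: reverse to canonical ascending
    wavenumbers <- rev(wavenumbers)
    absorbance <- rev(absorbance)
    d <- -rev(d)
  }
  if (any(d <= 0))
    stop("wavenumbers must be strictly monotone (duplicated or unordered values found)")
  if (any(wavenumbers < 100) || any(wavenumbers > 8000))
    stop("wavenumbers outside the sanity range [100, 8000] cm^-1")
  structure(
    list(wavenumbers = wavenumbers, absorbance = absorbance,
         meta = as_sample_meta(meta)),
    class = "ftir_spectrum"
  )
}

#' Sample metadata
#'
#' Metadata attached to a spectrum: sample identifier, species, sampling month
#' and year, replicate number, and role (`"sample"` or `"standard"`).
#'
#' @param sample_id character scalar identifier.
#' @param species character scalar or `NA`.
#' @param month integer 1-12 or `NA`.
#' @param year integer or `NA`.
#' @param replicate integer >= 1.
#' @param role `"sample"` or `"standard"`.
#' @return A list of class `sample_meta`.
#' @export
sample_meta <- function(sample_id = NA_character_, species = NA_character_,
                        month = NA_integer_, year = NA_integer_,
                        replicate = 1L, role = c("sample", "standard")) {
  role <- match.arg(role)
  month <- as.integer(month)
  if (!is.na(month) && (month < 1L || month > 12L))
    stop("month must be in 1..12")
  replicate <- as.integer(replicate)
  if (is.na(replicate) || replicate < 1L)
    stop("replicate must be an integer >= 1")
  structure(
    list(sample_id = as.character(sample_id), species = as.character(species),
         month = month, year = as.integer(year),
         replicate = replicate, role = role),
    class = "sample_meta"
  )
}

as_sample_meta <- function(x) {
  if (inherits(x, "sample_meta")) return(x)
  if (is.null(x)) return(sample_meta())
  do.call(sample_meta, x[intersect(names(x),
    c("sample_id", "species", "month", "year", "replicate", "role"))])
}

#' @export
print.ftir_spectrum <- function(x, ...) {
  rng <- range(x$wavenumbers)
  cat(sprintf("FTIR spectrum: %d points, %.1f-%.1f cm^-1\n",
              length(x$wavenumbers), rng[1], rng[2]))
  if (!is.na(x$meta$sample_id))
    cat("  sample_id:", x$meta$sample_id, "\n")
  if (!is.na(x$meta$species) || !is.na(x$meta$month)) {
    cat(sprintf("  species: %s  month: %s  year: %s  replicate: %d  role: %s\n",
                x$meta$species, x$meta$month, x$meta$year,
                x$meta$replicate, x$meta$role))
  }
  cat(sprintf("  absorbance range: [%.4g, %.4g]\n",
              min(x$absorbance), max(x$absorbance)))
  invisible(x)
}

#' @export
as.data.frame.ftir_spectrum <- function(x, ...) {
  data.frame(wavenumber = x$wavenumbers, absorbance = x$absorbance)
}

#' Plot a spectrum
#'
#' Renders with the wavenumber axis descending left to right, the usual
#' spectroscopy convention; the stored data remain ascending.
#'
#' @param x an `ftir_spectrum`.
#' @param ... passed to [graphics::plot.default()].
#' @export
plot.ftir_spectrum <- function(x, ...) {
  graphics::plot(x$wavenumbers, x$absorbance, type = "l",
                 xlim = rev(range(x$wavenumbers)),
                 xlab = expression(Wavenumber ~ (cm^-1)),
                 ylab = "Absorbance", ...)
  invisible(x)
}

#' Construct a collection of spectra
#'
#' @param spectra list of `ftir_spectrum` objects.
#' @param common_grid optional numeric grid; if given, every member must be
#'   sampled exactly on it.
#' @return An object of class `ftir_spectrum_set`.
#' @export
spectrum_set <- function(spectra, common_grid = NULL) {
  if (!is.list(spectra) || !all(vapply(spectra, inherits, TRUE, "ftir_spectrum")))
    stop("spectra must be a list of ftir_spectrum objects")
  if (!is.null(common_grid)) {
    common_grid <- as.numeric(common_grid)
    ok <- vapply(spectra, function(s)
      length(s$wavenumbers) == length(common_grid) &&
        max(abs(s$wavenumbers - common_grid)) < 1e-9, TRUE)
    if (!all(ok))
      stop("all member spectra must be sampled exactly on common_grid")
  }
  structure(list(spectra = spectra, common_grid = common_grid),
            class = "ftir_spectrum_set")
}

#' @export
length.ftir_spectrum_set <- function(x) length(x$spectra)

#' @export
`[[.ftir_spectrum_set` <- function(x, i) x$spectra[[i]]

#' @export
print.ftir_spectrum_set <- function(x, ...) {
  cat(sprintf("FTIR spectrum set: %d spectra%s\n", length(x$spectra),
              if (!is.null(x$common_grid))
                sprintf(" on a common %d-point grid", length(x$common_grid))
              else ""))
  ids <- vapply(x$spectra, function(s) s$meta$sample_id, "")
  if (any(!is.na(ids))) cat("  ids:", paste(utils::head(ids, 8), collapse = ", "),
                            if (length(ids) > 8) "..." else "", "\n")
  invisible(x)
}

#' Sample identifiers of a spectrum set
#' @param set an `ftir_spectrum_set`.
#' @return character vector of sample ids.
#' @export
set_sample_ids <- function(set) {
  vapply(set$spectra, function(s) s$meta$sample_id, "")
}

#' The canonical instrument grid
#'
#' The acquisition grid used throughout: 0.482 cm^-1 spacing over
#' \[400, 4000\] cm^-1 (16-scan ATR acquisition at nominal resolution 4).
#'
#' @param lo,hi window bounds in cm^-1.
#' @return numeric vector of wavenumbers.
#' @export
canonical_grid <- function(lo = 400, hi = 4000) {
  seq(lo, hi, by = 0.482)
}

#' Resample a spectrum onto a new wavenumber grid
#'
#' Linear interpolation; no extrapolation is performed, so the target grid
#' must lie within the spectrum's span. Values at nodes shared with the
#' original grid are unchanged.
#'
#' @param spectrum an `ftir_spectrum`.
#' @param grid strictly increasing numeric vector of target wavenumbers.
#' @return An `ftir_spectrum` on `grid`, metadata preserved.
#' @export
resample_to_grid <- function(spectrum, grid) {
  stopifnot(inherits(spectrum, "ftir_spectrum"))
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0)) stop("target grid must be strictly increasing")
  w <- spectrum$wavenumbers
  if (grid[1] < w[1] - 1e-9 || grid[length(grid)] > w[length(w)] + 1e-9)
    stop(sprintf("target grid [%.3f, %.3f] exceeds spectrum span [%.3f, %.3f]",
                 grid[1], grid[length(grid)], w[1], w[length(w)]))
  a <- stats::approx(w, spectrum$absorbance, xout = grid, rule = 1)$y
  ftir_spectrum(grid, a, spectrum$meta)
}

grid_step <- function(spectrum) {
  d <- diff(spectrum$wavenumbers)
  if (max(d) - min(d) > 1e-6 * mean(d))
    stop("spectrum grid is not uniform; resample_to_grid() first")
  mean(d)
}
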