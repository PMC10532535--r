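# Spectral conditioning: cropping, baseline correction, normalization,
# Savitzky-Golay smoothing and derivatives.

#' Named analysis windows
#'
#' Shipped wavenumber windows (cm^-1): `full` = \[400, 4000\],
#' `mid_ir` = \[500, 4000\], `carrageenan` = \[800, 1240\] (the diagnostic
#' carrageenan region), `pca_red` = \[580, 1350\] (red-alga PCA window),
#' `pca_brown` = \[500, 1600\] (brown-alga comparison window).
#'
#' @param name one of the preset names.
#' @return numeric length-2 vector `c(lo, hi)`.
#' @export
window_preset <- function(name = c("full", "mid_ir", "carrageenan",
                                   "pca_red", "pca_brown")) {
  name <- match.arg(name)
  switch(name,
    full        = c(400, 4000),
    mid_ir      = c(500, 4000),
    carrageenan = c(800, 1240),
    pca_red     = c(580, 1350),
    pca_brown   = c(500, 1600)
  )
}

#' Preprocessing configuration
#'
#' Bundles the conditioning choices applied before peak detection,
#' similarity scoring and PCA.
#'
#' @param window length-2 numeric window (cm^-1) or a [window_preset()] name.
#' @param baseline_method `"als"` (asymmetric least squares) or `"none"`.
#' @param als_lambda smoothness penalty of the ALS baseline (default 1e6 on
#'   the canonical 0.482 cm^-1 grid).
#' @param als_p asymmetry parameter in (0, 1).
#' @param als_maxit number of reweighting iterations.
#' @param normalization `"snv"`, `"max_in_window"` or `"none"`.
#' @param sg_window_points odd Savitzky-Golay window length (points).
#' @param sg_polyorder Savitzky-Golay polynomial order, < `sg_window_points`.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(window = "carrageenan",
                              baseline_method = c("als", "none"),
                              als_lambda = 1e6, als_p = 0.01, als_maxit = 10L,
                              normalization = c("snv", "max_in_window", "none"),
                              sg_window_points = 21L, sg_polyorder = 3L) {
  if (is.character(window)) window <- window_preset(window)
  window <- as.numeric(window)
  if (length(window) != 2 || window[1] >= window[2])
    stop("window must be c(lo, hi) with lo < hi")
  baseline_method <- match.arg(baseline_method)
  normalization <- match.arg(normalization)
  sg_window_points <- as.integer(sg_window_points)
  sg_polyorder <- as.integer(sg_polyorder)
  if (sg_window_points < 5L || sg_window_points %% 2L == 0L)
    stop("sg_window_points must be an odd integer >= 5")
  if (sg_polyorder < 2L || sg_polyorder >= sg_window_points)
    stop("sg_polyorder must be >= 2 and < sg_window_points")
  if (als_lambda <= 0) stop("als_lambda must be positive")
  if (als_p <= 0 || als_p >= 1) stop("als_p must be in (0, 1)")
  structure(list(window = window, baseline_method = baseline_method,
                 als_lambda = als_lambda, als_p = als_p,
                 als_maxit = as.integer(als_maxit),
                 normalization = normalization,
                 sg_window_points = sg_window_points,
                 sg_polyorder = sg_polyorder),
            class = "preprocess_config")
}

#' @export
print.preprocess_config <- function(x, ...) {
  cat(sprintf(
    "Preprocess config: window [%g, %g] cm^-1, baseline %s (lambda=%g, p=%g), %s, SG %d/%d\n",
    x$window[1], x$window[2], x$baseline_method, x$als_lambda, x$als_p,
    x$normalization, x$sg_window_points, x$sg_polyorder))
  invisible(x)
}

#' Crop a spectrum to a wavenumber window
#'
#' Retains exactly the points with `lo <= wavenumber <= hi` (closed
#' interval).
#'
#' @param spectrum an `ftir_spectrum`.
#' @param window length-2 numeric `c(lo, hi)` or a [window_preset()] name.
#' @return The cropped `ftir_spectrum`.
#' @export
crop <- function(spectrum, window) {
  stopifnot(inherits(spectrum, "ftir_spectrum"))
  if (is.character(window)) window <- window_preset(window)
  keep <- spectrum$wavenumbers >= window[1] & spectrum$wavenumbers <= window[2]
  if (sum(keep) < 2)
    stop(sprintf("window [%g, %g] retains fewer than 2 points", window[1], window[2]))
  ftir_spectrum(spectrum$wavenumbers[keep], spectrum$absorbance[keep],
                spectrum$meta)
}

# Eilers asymmetric least squares baseline: penalized least squares with
# asymmetric weights (p above the baseline, 1-p below), second-difference
# smoothness penalty lambda, solved with sparse banded systems.
als_baseline <- function(y, lambda = 1e6, p = 0.01, maxit = 10L) {
  n <- length(y)
  D <- Matrix::bandSparse(n - 2, n, k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  P <- lambda * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  for (it in seq_len(maxit)) {
    z <- as.numeric(Matrix::solve(Matrix::Diagonal(n, w) + P, w * y))
    if (any(!is.finite(z)))
      stop("ALS baseline solve diverged at iteration ", it)
    w_new <- ifelse(y > z, p, 1 - p)
    if (identical(w_new, w)) break
    w <- w_new
  }
  z
}

#' Baseline-correct a spectrum
#'
#' Subtracts an estimated slowly varying baseline. The default estimator is
#' Eilers' asymmetric least squares (ALS): a smoothness-penalized fit with
#' asymmetric residual weights so the curve hugs the valleys under the
#' absorption bands.
#'
#' @param spectrum an `ftir_spectrum`.
#' @param method `"als"` or `"none"`.
#' @param lambda,p,maxit ALS parameters (see [preprocess_config()]).
#' @return The corrected `ftir_spectrum`; the estimated baseline is attached
#'   as attribute `"baseline"`.
#' @export
baseline_correct <- function(spectrum, method = c("als", "none"),
                             lambda = 1e6, p = 0.01, maxit = 10L) {
  stopifnot(inherits(spectrum, "ftir_spectrum"))
  method <- match.arg(method)
  if (method == "none") return(spectrum)
  b <- als_baseline(spectrum$absorbance, lambda, p, maxit)
  out <- ftir_spectrum(spectrum$wavenumbers, spectrum$absorbance - b,
                       spectrum$meta)
  attr(out, "baseline") <- b
  out
}

#' Normalize a spectrum
#'
#' `"snv"` (standard normal variate) centers the trace to mean 0 and scales
#' to unit standard deviation over the window, removing the
#' pathlength/contact variation of ATR sampling. `"max_in_window"` scales so
#' the maximum within the window equals 1.
#'
#' @param spectrum an `ftir_spectrum`.
#' @param method `"snv"`, `"max_in_window"` or `"none"`.
#' @param window window used for the statistics; defaults to the full span.
#' @return The normalized `ftir_spectrum` (same grid).
#' @export
normalize <- function(spectrum, method = c("snv", "max_in_window", "none"),
                      window = NULL) {
  stopifnot(inherits(spectrum, "ftir_spectrum"))
  method <- match.arg(method)
  if (method == "none") return(spectrum)
  a <- spectrum$absorbance
  idx <- if (is.null(window)) seq_along(a) else {
    if (is.character(window)) window <- window_preset(window)
    which(spectrum$wavenumbers >= window[1] & spectrum$wavenumbers <= window[2])
  }
  if (length(idx) < 2) stop("normalization window retains fewer than 2 points")
  if (method == "snv") {
    s <- stats::sd(a[idx])
    if (s == 0) stop("constant spectrum: SNV normalization is undefined")
    out <- (a - mean(a[idx])) / s
  } else {
    mx <- max(a[idx])
    if (mx == 0) stop("maximum in window is zero: cannot scale to 1")
    out <- a / mx
  }
  ftir_spectrum(spectrum$wavenumbers, out, spectrum$meta)
}

#' Savitzky-Golay smoothing and derivatives
#'
#' Order 0 is plain smoothing; orders 1 and 2 return the first and second
#' derivative per unit wavenumber (cm^-1) and per cm^-2 respectively.
#' Requires a uniform grid.
#'
#' @param spectrum an `ftir_spectrum` on a uniform grid.
#' @param order derivative order 0, 1 or 2.
#' @param window_points odd filter length in points.
#' @param polyorder polynomial order (> `order`, < `window_points`).
#' @return An `ftir_spectrum` holding the filtered trace (same grid).
#' @export
savgol_derivative <- function(spectrum, order = 0L, window_points = 21L,
                              polyorder = 3L) {
  stopifnot(inherits(spectrum, "ftir_spectrum"))
  order <- as.integer(order)
  if (!order %in% 0:2) stop("order must be 0, 1 or 2")
  h <- grid_step(spectrum) # errors on non-uniform grid
  if (polyorder <= order) stop("polyorder must exceed the derivative order")
  y <- signal::sgolayfilt(spectrum$absorbance, p = polyorder,
                          n = window_points, m = order, ts = h)
  ftir_spectrum(spectrum$wavenumbers, y, spectrum$meta)
}

#' Apply a full preprocessing configuration
#'
#' Crop, then baseline-correct, then normalize, in that order.
#'
#' @param spectrum an `ftir_spectrum`.
#' @param config a [preprocess_config()].
#' @return The conditioned `ftir_spectrum`.
#' @export
apply_preprocess <- function(spectrum, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  s <- crop(spectrum, config$window)
  s <- baseline_correct(s, config$baseline_method, config$als_lambda,
                        config$als_p, config$als_maxit)
  normalize(s, config$normalization, config$window)
}
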