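# Similarity scoring of a sample spectrum against a standard.

#' Similarity percentage between a sample and a standard spectrum
#'
#' Both spectra are brought onto a common grid inside `window`, conditioned
#' identically (baseline correction and SNV normalization per `preprocess`),
#' and compared by Pearson correlation: the score is
#' `100 * max(0, r)`. This is an open analog of the proprietary "match"
#' metrics of instrument library-search software, not a replica of any of
#' them; SNV makes it invariant to positive scaling and offsets of the raw
#' absorbance.
#'
#' @param sample,standard `ftir_spectrum` objects covering `window`.
#' @param window length-2 numeric window or [window_preset()] name
#'   (default `"full"`, \[400, 4000\]).
#' @param preprocess a [preprocess_config()]; its `window` field is replaced
#'   by `window`.
#' @return A list of class `similarity_result`: `percent`, `window`,
#'   `n_points`, `sample_id`, `standard_id`.
#' @export
similarity_percent <- function(sample, standard, window = "full",
                               preprocess = preprocess_config()) {
  stopifnot(inherits(sample, "ftir_spectrum"),
            inherits(standard, "ftir_spectrum"))
  if (is.character(window)) window <- window_preset(window)
  lo <- max(window[1], sample$wavenumbers[1], standard$wavenumbers[1])
  hi <- min(window[2], max(sample$wavenumbers), max(standard$wavenumbers))
  if (lo >= hi)
    stop("window does not overlap the common span of the two spectra")
  grid <- sample$wavenumbers[sample$wavenumbers >= lo & sample$wavenumbers <= hi]
  if (length(grid) < 3) stop("fewer than 3 common points in the window")
  cond <- function(sp) {
    sp <- resample_to_grid(sp, grid)
    sp <- baseline_correct(sp, preprocess$baseline_method,
                           preprocess$als_lambda, preprocess$als_p,
                           preprocess$als_maxit)
    a <- sp$absorbance
    s <- stats::sd(a)
    if (s == 0) stop("spectrum is constant after preprocessing: similarity undefined")
    (a - mean(a)) / s
  }
  r <- stats::cor(cond(sample), cond(standard))
  structure(list(percent = 100 * max(0, r), window = c(lo, hi),
                 n_points = length(grid),
                 sample_id = sample$meta$sample_id,
                 standard_id = standard$meta$sample_id),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("Similarity: %.2f%% over [%g, %g] cm^-1 (%d points)\n",
              x$percent, x$window[1], x$window[2], x$n_points))
  invisible(x)
}

#' Similarity of every member of a collection against one standard
#'
#' @param samples an `ftir_spectrum_set`.
#' @param standard an `ftir_spectrum`.
#' @param window,preprocess as in [similarity_percent()].
#' @return A data frame (one row per sample, ordered by `sample_id`):
#'   `sample_id`, `month`, `percent`, `window_lo`, `window_hi`, `n_points`.
#'   Per-sample failures are re-signalled with the sample id attached.
#' @export
similarity_batch <- function(samples, standard, window = "full",
                             preprocess = preprocess_config()) {
  stopifnot(inherits(samples, "ftir_spectrum_set"))
  if (!length(samples$spectra)) {
    return(data.frame(sample_id = character(), month = integer(),
                      percent = numeric(), window_lo = numeric(),
                      window_hi = numeric(), n_points = integer()))
  }
  rows <- lapply(samples$spectra, function(sp) {
    res <- tryCatch(similarity_percent(sp, standard, window, preprocess),
                    error = function(e)
                      stop(sprintf("sample '%s': %s", sp$meta$sample_id,
                                   conditionMessage(e)), call. = FALSE))
    data.frame(sample_id = sp$meta$sample_id,
               month = sp$meta$month,
               percent = res$percent,
               window_lo = res$window[1], window_hi = res$window[2],
               n_points = res$n_points)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
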