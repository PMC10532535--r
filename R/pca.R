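# PCA of spectrum collections and seasonal group separation.

#' Principal component analysis of a spectrum collection
#'
#' Each spectrum is cropped to `window`, conditioned per `preprocess`
#' (baseline correction and normalization), and stacked into a
#' samples-by-wavenumbers matrix; mean-centered PCA is computed on it (no
#' unit-variance scaling of the wavenumber variables, the usual choice for
#' spectra). Component signs are canonicalized so each loading's
#' largest-magnitude element is positive, making results deterministic and
#' invariant to sample order.
#'
#' @param set an `ftir_spectrum_set`; members must share or cover `window`.
#' @param window length-2 numeric window or [window_preset()] name.
#' @param n_components number of components to retain (default all).
#' @param preprocess a [preprocess_config()].
#' @return An object of class `ftir_pca`: `mean_trace`, `loadings`
#'   (components x wavenumbers), `scores` (samples x components),
#'   `explained_pct`, `grid`, `window`, `sample_ids`, `total_variance`.
#' @export
pca_fit <- function(set, window = "pca_red", n_components = NULL,
                    preprocess = preprocess_config(window = "pca_red")) {
  stopifnot(inherits(set, "ftir_spectrum_set"))
  if (length(set$spectra) < 3)
    stop("PCA needs at least 3 spectra")
  if (is.character(window)) window <- window_preset(window)
  base <- crop(set$spectra[[1]], window)
  grid <- base$wavenumbers
  cond <- function(sp) {
    sp <- crop(sp, window)
    if (length(sp$wavenumbers) != length(grid) ||
        max(abs(sp$wavenumbers - grid)) > 1e-9)
      sp <- resample_to_grid(sp, grid)
    sp <- baseline_correct(sp, preprocess$baseline_method,
                           preprocess$als_lambda, preprocess$als_p,
                           preprocess$als_maxit)
    sp <- normalize(sp, preprocess$normalization)
    sp$absorbance
  }
  X <- t(vapply(set$spectra, cond, numeric(length(grid))))
  ids <- set_sample_ids(set)
  max_k <- min(nrow(X) - 1L, ncol(X))
  if (is.null(n_components)) n_components <- max_k
  n_components <- min(as.integer(n_components), max_k)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  total_var <- sum(Xc^2) / (nrow(X) - 1)
  k <- n_components
  load <- t(pc$rotation[, seq_len(k), drop = FALSE])
  scores <- pc$x[, seq_len(k), drop = FALSE]
  # sign canonicalization: largest-|value| loading element positive
  for (j in seq_len(k)) {
    i <- which.max(abs(load[j, ]))
    if (load[j, i] < 0) {
      load[j, ] <- -load[j, ]
      scores[, j] <- -scores[, j]
    }
  }
  explained <- 100 * pc$sdev[seq_len(k)]^2 / total_var
  rownames(scores) <- ids
  structure(list(mean_trace = mu, loadings = load, scores = scores,
                 explained_pct = explained, grid = grid,
                 window = as.numeric(window), sample_ids = ids,
                 total_variance = total_var, preprocess = preprocess),
            class = "ftir_pca")
}

#' @export
print.ftir_pca <- function(x, ...) {
  cat(sprintf("Spectral PCA: %d samples, %d wavenumbers in [%g, %g] cm^-1, %d components\n",
              length(x$sample_ids), length(x$grid), x$window[1], x$window[2],
              nrow(x$loadings)))
  cat("  explained variance (%):",
      paste(sprintf("%.1f", utils::head(x$explained_pct, 6)), collapse = ", "),
      if (length(x$explained_pct) > 6) "..." else "", "\n")
  invisible(x)
}

#' @export
summary.ftir_pca <- function(object, ...) {
  d <- data.frame(component = seq_along(object$explained_pct),
                  explained_pct = object$explained_pct,
                  cumulative_pct = cumsum(object$explained_pct))
  cat("Spectral PCA summary\n")
  print(d, row.names = FALSE, digits = 4)
  invisible(d)
}

#' Project new spectra onto a fitted spectral PCA
#'
#' @param object an `ftir_pca`.
#' @param newdata an `ftir_spectrum_set` (or single `ftir_spectrum`).
#' @param ... unused.
#' @return A scores matrix (samples x components).
#' @export
predict.ftir_pca <- function(object, newdata, ...) {
  if (inherits(newdata, "ftir_spectrum"))
    newdata <- spectrum_set(list(newdata))
  stopifnot(inherits(newdata, "ftir_spectrum_set"))
  pp <- object$preprocess
  cond <- function(sp) {
    sp <- crop(sp, object$window)
    if (length(sp$wavenumbers) != length(object$grid) ||
        max(abs(sp$wavenumbers - object$grid)) > 1e-9)
      sp <- resample_to_grid(sp, object$grid)
    sp <- baseline_correct(sp, pp$baseline_method, pp$als_lambda, pp$als_p,
                           pp$als_maxit)
    sp <- normalize(sp, pp$normalization)
    sp$absorbance
  }
  X <- t(vapply(newdata$spectra, cond, numeric(length(object$grid))))
  sweep(X, 2, object$mean_trace) %*% t(object$loadings)
}

#' Score plot of a spectral PCA
#'
#' PC-1 versus PC-2, optionally colored by a grouping label.
#'
#' @param x an `ftir_pca` with at least 2 components.
#' @param labels optional per-sample group labels.
#' @param ... passed to [graphics::plot.default()].
#' @export
plot.ftir_pca <- function(x, labels = NULL, ...) {
  if (nrow(x$loadings) < 2) stop("need at least 2 components to plot scores")
  col <- if (is.null(labels)) 1L else as.integer(factor(labels))
  graphics::plot(x$scores[, 1], x$scores[, 2], col = col, pch = 19,
                 xlab = sprintf("PC-1 (%.1f%%)", x$explained_pct[1]),
                 ylab = sprintf("PC-2 (%.1f%%)", x$explained_pct[2]), ...)
  if (!is.null(labels))
    graphics::legend("topright", legend = levels(factor(labels)),
                     col = seq_along(levels(factor(labels))), pch = 19)
  invisible(x)
}

#' Quantify group separation in PCA score space
#'
#' Computes silhouette widths on Euclidean distances between scores
#' restricted to the first `n_components_used` components. A sample in a
#' singleton group gets silhouette 0 and is flagged.
#'
#' @param model an `ftir_pca`.
#' @param labels per-sample group labels aligned with `model$sample_ids`.
#' @param n_components_used number of leading components (default 2).
#' @return A list of class `group_separation`: `labels`, `mean_silhouette`,
#'   `per_group_silhouette`, `silhouette_widths`, `singletons`.
#' @export
season_separation <- function(model, labels, n_components_used = 2L) {
  stopifnot(inherits(model, "ftir_pca"))
  if (length(labels) != length(model$sample_ids))
    stop("labels must align with the model's sample_ids")
  k <- as.integer(n_components_used)
  if (k < 1L || k > nrow(model$loadings))
    stop("n_components_used exceeds the fitted components")
  f <- factor(labels)
  sc <- model$scores[, seq_len(k), drop = FALSE]
  singles <- names(table(f))[table(f) == 1]
  if (nlevels(f) < 2)
    stop("need at least two groups to measure separation")
  sil <- cluster::silhouette(as.integer(f), stats::dist(sc))
  widths <- if (is.matrix(sil)) sil[, "sil_width"] else rep(0, length(f))
  # cluster::silhouette already defines singleton clusters as width 0
  per_group <- tapply(widths, f, mean)
  structure(list(labels = as.character(labels),
                 mean_silhouette = mean(widths),
                 per_group_silhouette = as.list(per_group),
                 silhouette_widths = as.numeric(widths),
                 singletons = singles),
            class = "group_separation")
}

#' @export
print.group_separation <- function(x, ...) {
  cat(sprintf("Group separation: mean silhouette %.3f over %d samples\n",
              x$mean_silhouette, length(x$labels)))
  for (g in names(x$per_group_silhouette))
    cat(sprintf("  %s: %.3f\n", g, x$per_group_silhouette[[g]]))
  if (length(x$singletons))
    cat("  singleton groups (silhouette fixed at 0):",
        paste(x$singletons, collapse = ", "), "\n")
  invisible(x)
}
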