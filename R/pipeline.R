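# End-to-end orchestration: ingest or simulate -> preprocess -> band
# assignment and classification -> similarity -> PCA -> reports, driven by a
# YAML config, plus a small command-line front end.

config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 131 + v) %% 2^31
  sprintf("%08x", h)
}

month_season <- function(m) {
  c("winter", "winter", "spring", "spring", "spring", "summer",
    "summer", "summer", "autumn", "autumn", "autumn", "winter")[m]
}

#' Build a pipeline configuration
#'
#' Exactly one of `input` (a wide-matrix CSV path or a vector of per-sample
#' spectrum files) and `simulation` (a shipped design name or a
#' [seasonal_design()]) must be given.
#'
#' @param input input path(s), or `NULL`.
#' @param simulation design name / object, or `NULL`.
#' @param preprocess a [preprocess_config()].
#' @param library band library name for carrageenan-type assignment.
#' @param standard optional path to a standard spectrum (CSV), or a
#'   component name (`"iota"`, `"fucoidan"`, ...) to synthesize a noise-free
#'   standard.
#' @param pca_window,pca_components PCA window and component count.
#' @param out_dir output directory (created if missing).
#' @param seed integer seed for any simulation.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, simulation = NULL,
                            preprocess = preprocess_config(),
                            library = "carrageenan", standard = NULL,
                            pca_window = "pca_red", pca_components = 2L,
                            out_dir = tempfile("phycospec_run_"),
                            seed = 1L) {
  if (is.null(input) == is.null(simulation))
    stop("exactly one of 'input' and 'simulation' must be given")
  structure(list(input = input, simulation = simulation,
                 preprocess = preprocess, library = library,
                 standard = standard, pca_window = pca_window,
                 pca_components = as.integer(pca_components),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized keys: `input` (path or list of paths), `simulation` (shipped
#' design name), `preprocess` (subkeys of [preprocess_config()]), `library`,
#' `standard`, `pca_window`, `pca_components`, `out_dir`, `seed`.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pp <- do.call(preprocess_config, if (is.null(y$preprocess)) list() else y$preprocess)
  pipeline_config(
    input = y$input, simulation = y$simulation, preprocess = pp,
    library = if (is.null(y$library)) "carrageenan" else y$library,
    standard = y$standard,
    pca_window = if (is.null(y$pca_window)) "pca_red" else y$pca_window,
    pca_components = if (is.null(y$pca_components)) 2L else y$pca_components,
    out_dir = if (is.null(y$out_dir)) tempfile("phycospec_run_") else y$out_dir,
    seed = if (is.null(y$seed)) 1L else y$seed)
}

load_input_set <- function(input) {
  if (length(input) == 1 && grepl("\\.csv$", input) &&
      ncol(utils::read.csv(input, nrows = 1)) > 2) {
    read_spectrum_set(input)
  } else {
    spectra <- lapply(input, function(p)
      read_spectrum(p, if (grepl("\\.(jdx|dx)$", p, ignore.case = TRUE))
        "jcampdx" else "csv2col"))
    spectrum_set(spectra)
  }
}

resolve_standard <- function(standard, grid = canonical_grid()) {
  if (is.null(standard)) return(NULL)
  if (file.exists(standard)) {
    read_spectrum(standard,
                  if (grepl("\\.(jdx|dx)$", standard, ignore.case = TRUE))
                    "jcampdx" else "csv2col")
  } else {
    sp <- simulate_spectrum(stats::setNames(list(1), standard), grid,
                            seed = 1L,
                            meta = sample_meta(sample_id = paste0(standard, "_standard"),
                                               role = "standard"))
    sp
  }
}

#' Run the full analysis pipeline
#'
#' Ingests (or simulates) a spectrum collection, classifies every sample
#' (colloid family, and carrageenan type where applicable), scores
#' similarity against the standard when one is configured, fits a PCA over
#' the configured window and measures seasonal group separation, and writes
#' all stage outputs (assignment, similarity, PCA score/loading/variance
#' CSVs and a score plot) under `config$out_dir`. Reruns with the same
#' config produce byte-identical CSV outputs.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `run_report`: `set`, `classifications`,
#'   `assignment_table`, `similarity`, `pca`, `separation`, `files`,
#'   `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  if (!is.null(config$simulation)) {
    design <- config$simulation
    if (is.character(design)) design <- shipped_design(design, seed = config$seed)
    sim <- simulate_seasonal_dataset(design)
    set <- sim$set
    gt_path <- file.path(config$out_dir, "ground_truth.csv")
    utils::write.csv(sim$ground_truth, gt_path, row.names = FALSE)
    files <- c(files, ground_truth = gt_path)
  } else {
    set <- load_input_set(config$input)
  }

  # per-sample classification
  classifications <- lapply(set$spectra, classify_spectrum,
                            config = config$preprocess)
  names(classifications) <- set_sample_ids(set)
  reports <- Filter(Negate(is.null),
                    lapply(classifications, function(cl) cl$report))
  assignment_table <- report_to_table(unname(reports))
  fam <- vapply(classifications, function(cl) cl$family_profile$colloid_family, "")
  typ <- vapply(classifications, function(cl)
    if (is.null(cl$type_profile)) NA_character_ else cl$type_profile$dominant, "")
  cls_path <- file.path(config$out_dir, "classification.csv")
  utils::write.csv(data.frame(sample_id = names(classifications),
                              colloid_family = fam, carrageenan_type = typ),
                   cls_path, row.names = FALSE)
  files <- c(files, classification = cls_path)
  if (nrow(assignment_table)) {
    at_path <- file.path(config$out_dir, "assignment.csv")
    utils::write.csv(assignment_table, at_path, row.names = FALSE)
    files <- c(files, assignment = at_path)
  }

  # similarity against the standard
  similarity <- NULL
  std <- resolve_standard(config$standard)
  if (!is.null(std)) {
    similarity <- similarity_batch(set, std, window = "full",
                                   preprocess = config$preprocess)
    sim_path <- file.path(config$out_dir, "similarity.csv")
    utils::write.csv(similarity, sim_path, row.names = FALSE)
    files <- c(files, similarity = sim_path)
  }

  # PCA and seasonal separation
  pca <- NULL; separation <- NULL
  if (length(set$spectra) >= 3) {
    pca <- pca_fit(set, window = config$pca_window,
                   n_components = max(2L, config$pca_components),
                   preprocess = config$preprocess)
    utils::write.csv(data.frame(sample_id = pca$sample_ids, pca$scores),
                     file.path(config$out_dir, "pca_scores.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(wavenumber = pca$grid, t(pca$loadings)),
                     file.path(config$out_dir, "pca_loadings.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(component = seq_along(pca$explained_pct),
                                explained_pct = pca$explained_pct),
                     file.path(config$out_dir, "pca_explained.csv"),
                     row.names = FALSE)
    files <- c(files, pca_scores = file.path(config$out_dir, "pca_scores.csv"),
               pca_loadings = file.path(config$out_dir, "pca_loadings.csv"),
               pca_explained = file.path(config$out_dir, "pca_explained.csv"))
    months <- vapply(set$spectra, function(s) s$meta$month, 0L)
    if (!anyNA(months)) {
      labels <- month_season(months)
      if (length(unique(labels)) >= 2) {
        separation <- season_separation(pca, labels,
                                        min(2L, nrow(pca$loadings)))
      }
      plot_path <- file.path(config$out_dir, "pca_scores.png")
      ok <- tryCatch({
        grDevices::png(plot_path, width = 800, height = 600)
        plot(pca, labels = labels)
        grDevices::dev.off()
        TRUE
      }, error = function(e) FALSE)
      if (ok) files <- c(files, score_plot = plot_path)
    }
  }

  structure(list(set = set, classifications = classifications,
                 assignment_table = assignment_table,
                 similarity = similarity, pca = pca,
                 separation = separation, files = files,
                 provenance = list(
                   config_hash = config_hash(unclass(config)),
                   library = config$library,
                   library_version = attr(band_library("carrageenan"), "version"),
                   seed = config$seed,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("phycospec run report\n")
  cat(sprintf("  samples: %d\n", length(x$set$spectra)))
  fam <- table(vapply(x$classifications,
                      function(cl) cl$family_profile$colloid_family, ""))
  cat("  families:", paste(names(fam), fam, sep = "=", collapse = "  "), "\n")
  if (!is.null(x$separation))
    cat(sprintf("  seasonal mean silhouette: %.3f\n",
                x$separation$mean_silhouette))
  cat("  outputs:", paste(basename(x$files), collapse = ", "), "\n")
  cat("  provenance: config", x$provenance$config_hash,
      "library version", x$provenance$library_version, "\n")
  invisible(x)
}

cli_usage <- function() {
  paste(
    "usage: phycospec <subcommand> [options]",
    "subcommands:",
    "  simulate   --design <name> --out <dir> [--seed <int>]",
    "  classify   --in <spectrum.csv> [--library carrageenan]",
    "  similarity --in <spectrum.csv> --standard <spectrum.csv|component> [--window <preset>]",
    "  pca        --in <wide.csv> [--window <preset>] [--out <dir>]",
    "  run        --config <config.yaml> [--seed <int>]",
    sep = "\n")
}

cli_args <- function(argv) {
  out <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (startsWith(a, "--")) {
      out[[substring(a, 3)]] <- if (i < length(argv)) argv[i + 1L] else ""
      i <- i + 2L
    } else i <- i + 1L
  }
  out
}

#' Command-line entry point
#'
#' Thin argument-parsing front end over the package functions; see
#' `inst/cli/phycospec.R` for the installed launcher script. Returns (does
#' not call `quit()` with) the exit code: 0 on success, 2 on usage/config
#' errors, 1 on runtime errors.
#'
#' @param argv character vector of command-line arguments.
#' @return Integer exit code, invisibly.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (!length(argv)) { message(cli_usage()); return(invisible(2L)) }
  sub <- argv[1]
  opts <- cli_args(argv[-1])
  code <- tryCatch({
    switch(sub,
      simulate = {
        if (is.null(opts$design) || is.null(opts$out)) { message(cli_usage()); return(invisible(2L)) }
        seed <- if (is.null(opts$seed)) NULL else as.integer(opts$seed)
        sim <- simulate_seasonal_dataset(shipped_design(opts$design, seed = seed))
        dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
        write_spectrum_set(sim$set, file.path(opts$out, "spectra.csv"))
        utils::write.csv(sim$ground_truth,
                         file.path(opts$out, "ground_truth.csv"),
                         row.names = FALSE)
        message("wrote ", file.path(opts$out, "spectra.csv"))
        0L
      },
      classify = {
        if (is.null(opts$`in`)) { message(cli_usage()); return(invisible(2L)) }
        sp <- read_spectrum(opts$`in`)
        cl <- classify_spectrum(sp)
        print(cl$family_profile)
        if (!is.null(cl$report)) {
          print(report_to_table(list(cl$report)))
          print(cl$type_profile)
        }
        0L
      },
      similarity = {
        if (is.null(opts$`in`) || is.null(opts$standard)) { message(cli_usage()); return(invisible(2L)) }
        sp <- read_spectrum(opts$`in`)
        std <- resolve_standard(opts$standard)
        win <- if (is.null(opts$window)) "full" else opts$window
        print(similarity_percent(sp, std, window = win))
        0L
      },
      pca = {
        if (is.null(opts$`in`)) { message(cli_usage()); return(invisible(2L)) }
        set <- read_spectrum_set(opts$`in`)
        win <- if (is.null(opts$window)) "pca_red" else opts$window
        m <- pca_fit(set, window = win)
        print(m); summary(m)
        0L
      },
      run = {
        if (is.null(opts$config)) { message(cli_usage()); return(invisible(2L)) }
        cfg <- read_pipeline_config(opts$config)
        if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
        rep <- run_pipeline(cfg)
        print(rep)
        0L
      },
      { message(cli_usage()); 2L }
    )
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("config|usage|exactly one", conditionMessage(e))) 2L else 1L
  })
  invisible(as.integer(code))
}
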