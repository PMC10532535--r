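# Readers and writers for two-column CSV, wide-matrix CSV and minimal
# JCAMP-DX (AFFN-encoded XYDATA / XYPOINTS only; compressed SQZ/DIF forms
# are out of scope).

#' Read a spectrum from disk
#'
#' @param path path to the file.
#' @param format `"csv2col"` (two numeric columns wavenumber, absorbance,
#'   optional single header row auto-detected) or `"jcampdx"` (AFFN
#'   XYDATA/XYPOINTS).
#' @return An `ftir_spectrum`. Metadata are populated from the filename when
#'   it follows the `<species>_<YYYY>-<MM>_rep<k>` pattern, and from JCAMP
#'   `##TITLE` when present.
#' @export
read_spectrum <- function(path, format = c("csv2col", "jcampdx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- parse_sample_filename(basename(path))
  xy <- switch(format,
    csv2col = read_csv2col(path),
    jcampdx = read_jcampdx(path)
  )
  ftir_spectrum(xy$x, xy$y, meta)
}

read_csv2col <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("CSV has fewer than 2 data rows: ", path)
  first <- strsplit(lines[1], ",")[[1]]
  skip <- if (suppressWarnings(anyNA(as.numeric(first[1:2])))) 1L else 0L
  d <- utils::read.csv(text = lines, header = FALSE, skip = skip,
                       stringsAsFactors = FALSE)
  if (ncol(d) < 2) stop("CSV must have two columns (wavenumber, absorbance): ", path)
  x <- suppressWarnings(as.numeric(d[[1]]))
  y <- suppressWarnings(as.numeric(d[[2]]))
  bad <- which(is.na(x) | is.na(y))
  if (length(bad))
    stop(sprintf("non-numeric value in %s at data row %d", path, bad[1]))
  list(x = x, y = y)
}

read_jcampdx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  title <- sub("^##TITLE=\\s*", "", grep("^##TITLE=", lines, value = TRUE)[1])
  start <- grep("^##(XYDATA|XYPOINTS)=", lines)
  if (!length(start))
    stop("no ##XYDATA or ##XYPOINTS record found in ", path)
  start <- start[1]
  end <- grep("^##END", lines)
  end <- if (length(end)) min(end[end > start]) - 1L else length(lines)
  body <- lines[(start + 1L):end]
  body <- body[nzchar(trimws(body))]
  is_xydata <- grepl("^##XYDATA=", lines[start])
  if (is_xydata) {
    # (X++(Y..Y)): each line starts with an X value followed by Y values
    xf <- num_field(lines, "FIRSTX"); xl <- num_field(lines, "LASTX")
    yfac <- num_field(lines, "YFACTOR", default = 1)
    xfac <- num_field(lines, "XFACTOR", default = 1)
    xs <- NULL; ys <- NULL
    for (i in seq_along(body)) {
      vals <- suppressWarnings(as.numeric(strsplit(trimws(body[i]), "[ \t]+")[[1]]))
      if (anyNA(vals) || length(vals) < 2)
        stop(sprintf("unparseable XYDATA line %d in %s", i, path))
      xs <- c(xs, vals[1]); ys <- c(ys, list(vals[-1]))
    }
    npts <- sum(lengths(ys))
    if (is.na(xf) || is.na(xl)) stop("XYDATA without FIRSTX/LASTX in ", path)
    step <- (xl - xf) / (npts - 1)
    x <- xf + step * (seq_len(npts) - 1)
    list(x = x * xfac, y = unlist(ys) * yfac)
  } else {
    # XYPOINTS=(XY..XY): "x, y" pairs
    pr <- strsplit(trimws(body), "[,;][ \t]*")
    x <- suppressWarnings(as.numeric(vapply(pr, `[`, "", 1)))
    y <- suppressWarnings(as.numeric(vapply(pr, `[`, "", 2)))
    bad <- which(is.na(x) | is.na(y))
    if (length(bad))
      stop(sprintf("unparseable XYPOINTS record %d in %s", bad[1], path))
    list(x = x, y = y)
  }
}

num_field <- function(lines, field, default = NA_real_) {
  hit <- grep(paste0("^##", field, "="), lines, value = TRUE)
  if (!length(hit)) return(default)
  as.numeric(sub(paste0("^##", field, "=\\s*"), "", hit[1]))
}

#' Write a spectrum to disk
#'
#' @param spectrum an `ftir_spectrum`.
#' @param path output path.
#' @param format `"csv2col"` or `"jcampdx"`.
#' @return `path`, invisibly. Round trip through [read_spectrum()] preserves
#'   values to within 1e-9.
#' @export
write_spectrum <- function(spectrum, path, format = c("csv2col", "jcampdx")) {
  format <- match.arg(format)
  stopifnot(inherits(spectrum, "ftir_spectrum"))
  w <- spectrum$wavenumbers; a <- spectrum$absorbance
  if (format == "csv2col") {
    lines <- c("wavenumber,absorbance",
               sprintf("%.10g,%.10g", w, a))
    writeLines(lines, path)
  } else {
    id <- spectrum$meta$sample_id
    lines <- c(
      paste0("##TITLE=", if (is.na(id)) "spectrum" else id),
      "##JCAMP-DX=4.24",
      "##DATA TYPE=INFRARED SPECTRUM",
      "##XUNITS=1/CM",
      "##YUNITS=ABSORBANCE",
      sprintf("##FIRSTX=%.10g", w[1]),
      sprintf("##LASTX=%.10g", w[length(w)]),
      sprintf("##NPOINTS=%d", length(w)),
      "##XYPOINTS=(XY..XY)",
      sprintf("%.10g, %.10g", w, a),
      "##END="
    )
    writeLines(lines, path)
  }
  invisible(path)
}

#' Parse sample metadata from a filename
#'
#' Recognizes the `<species>_<YYYY>-<MM>_rep<k>` pattern (any extension);
#' unrecognized names yield empty metadata with `sample_id` set to the file
#' stem.
#'
#' @param filename a file name (directory part ignored).
#' @return A [sample_meta()] object.
#' @export
parse_sample_filename <- function(filename) {
  stem <- tools::file_path_sans_ext(basename(filename))
  m <- regmatches(stem, regexec("^([A-Za-z.]+)_([0-9]{4})-([0-9]{2})_rep([0-9]+)$", stem))[[1]]
  if (length(m) == 5) {
    sample_meta(sample_id = stem, species = m[2],
                month = as.integer(m[4]), year = as.integer(m[3]),
                replicate = as.integer(m[5]))
  } else {
    sample_meta(sample_id = stem)
  }
}

#' Read a spectrum collection from a wide-matrix CSV
#'
#' First column is the wavenumber; each further column is one sample, with
#' the header row carrying the sample ids.
#'
#' @param path path to the CSV.
#' @return An `ftir_spectrum_set` on the file's (common) grid.
#' @export
read_spectrum_set <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (ncol(d) < 2) stop("wide-matrix CSV needs a wavenumber column plus samples")
  w <- as.numeric(d[[1]])
  spectra <- lapply(seq(2, ncol(d)), function(j) {
    meta <- parse_sample_filename(names(d)[j])
    ftir_spectrum(w, as.numeric(d[[j]]), meta)
  })
  grid <- spectra[[1]]$wavenumbers # constructor may have reversed a descending file
  spectrum_set(spectra, common_grid = grid)
}

#' Write a spectrum collection as a wide-matrix CSV
#'
#' @param set an `ftir_spectrum_set` on a common grid.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_set <- function(set, path) {
  stopifnot(inherits(set, "ftir_spectrum_set"))
  grid <- set$common_grid
  if (is.null(grid)) {
    grid <- set$spectra[[1]]$wavenumbers
    ok <- vapply(set$spectra, function(s)
      length(s$wavenumbers) == length(grid) &&
        max(abs(s$wavenumbers - grid)) < 1e-9, TRUE)
    if (!all(ok)) stop("set members are not on a common grid")
  }
  m <- vapply(set$spectra, function(s) s$absorbance, numeric(length(grid)))
  ids <- set_sample_ids(set)
  ids[is.na(ids) | ids == "NA"] <- paste0("s", seq_along(set$spectra))[is.na(ids) | ids == "NA"]
  d <- data.frame(wavenumber = grid, m, check.names = FALSE)
  names(d) <- c("wavenumber", ids)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
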