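#' Read a 1D spectrum from disk
#'
#' Supports two plain-text formats: JCAMP-DX with an `XYDATA=(X++(Y..Y))`
#' block in AFFN (free-form numeric) representation, and a headerless
#' two-column table (ppm, intensity) separated by whitespace or tabs.
#' On ingestion the spectrum is clipped to the 0--12 ppm analysis window and
#' the grid normalized to descending ppm.
#'
#' @param path File to read.
#' @param format `"jcamp-dx"` or `"tsv"`; `"auto"` guesses from the file
#'   extension (`.jdx`/`.dx` vs anything else).
#' @param sample_id Sample id; defaults to the JCAMP TITLE or the file name.
#' @param group Optional group label.
#' @return An [nmr_spectrum].
#' @seealso [write_spectrum()]
#' @export
read_spectrum <- function(path, format = c("auto", "jcamp-dx", "tsv"),
                          sample_id = NULL, group = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.(jdx|dx)$", path, ignore.case = TRUE)) "jcamp-dx" else "tsv"
  out <- switch(format,
    "jcamp-dx" = read_jcamp(path),
    "tsv"      = read_tsv_spectrum(path))
  if (is.null(sample_id))
    sample_id <- if (!is.null(out$title)) out$title else
      sub("\\.[^.]*$", "", basename(path))
  keep <- out$ppm >= 0 & out$ppm <= 12
  if (sum(keep) < 2L) stop("no spectral points inside 0..12 ppm in ", path)
  nmr_spectrum(out$ppm[keep], out$intensity[keep], sample_id, group)
}

read_tsv_spectrum <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty spectrum file: ", path)
  ppm <- numeric(length(lines)); y <- numeric(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "[\t ]+")[[1L]]
    if (length(f) < 2L)
      stop("malformed row at ", path, ":", i, " (need two columns)")
    v <- suppressWarnings(as.numeric(f[1:2]))
    if (any(is.na(v) & !grepl("^(nan|inf|-inf)$", tolower(f[1:2]))))
      stop("non-numeric value at ", path, ":", i)
    ppm[i] <- v[1L]; y[i] <- v[2L]
  }
  if (any(!is.finite(y)))
    stop("non-finite intensity at ", path, ":",
         which(!is.finite(y))[1L])
  list(ppm = ppm, intensity = y, title = NULL)
}

read_jcamp <- function(path) {
  lines <- readLines(path)
  lab <- function(name) {
    i <- grep(paste0("^##", name, "="), lines)
    if (!length(i)) return(NULL)
    sub(paste0("^##", name, "="), "", lines[i[1L]])
  }
  title <- lab("TITLE")
  xy <- grep("^##XYDATA=", lines)
  if (!length(xy)) stop("no ##XYDATA block in ", path)
  np <- as.integer(lab("NPOINTS"))
  firstx <- as.numeric(lab("FIRSTX")); lastx <- as.numeric(lab("LASTX"))
  xf <- as.numeric(lab("XFACTOR")); yf <- as.numeric(lab("YFACTOR"))
  if (!length(xf) || is.na(xf)) xf <- 1
  if (!length(yf) || is.na(yf)) yf <- 1
  if (!length(np) || !length(firstx) || !length(lastx) ||
      any(is.na(c(np, firstx, lastx))))
    stop("missing NPOINTS/FIRSTX/LASTX header in ", path)
  endi <- grep("^##END", lines)
  endi <- if (length(endi)) endi[1L] else length(lines) + 1L
  y <- numeric(0)
  for (i in seq.int(xy[1L] + 1L, endi - 1L)) {
    f <- strsplit(trimws(lines[i]), "[\t ]+")[[1L]]
    v <- suppressWarnings(as.numeric(f))
    if (any(is.na(v))) stop("malformed AFFN data at ", path, ":", i)
    y <- c(y, v[-1L] * yf)  # first token on each line is the X value
  }
  if (length(y) != np)
    stop("NPOINTS=", np, " but ", length(y), " Y values read from ", path)
  ppm <- seq(firstx, lastx, length.out = np) * xf
  if (any(!is.finite(y))) stop("non-finite intensity in ", path)
  list(ppm = ppm, intensity = y, title = title)
}

#' Write a 1D spectrum to disk
#'
#' @param spectrum An [nmr_spectrum] (real intensities).
#' @param path Output file.
#' @param format `"jcamp-dx"` or `"tsv"` (see [read_spectrum()]).
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path, format = c("jcamp-dx", "tsv")) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  format <- match.arg(format)
  if (is.complex(spectrum$intensity))
    stop("phase the spectrum before writing (complex intensities)")
  ppm <- spectrum$ppm; y <- spectrum$intensity
  if (format == "tsv") {
    writeLines(sprintf("%.15g\t%.15g", ppm, y), path)
    return(invisible(path))
  }
  n <- length(ppm)
  hdr <- c(
    paste0("##TITLE=", spectrum$sample_id),
    "##JCAMP-DX=4.24",
    "##DATA TYPE=NMR SPECTRUM",
    "##XUNITS=PPM",
    "##YUNITS=ARBITRARY UNITS",
    "##XFACTOR=1", "##YFACTOR=1",
    sprintf("##FIRSTX=%.15g", ppm[1L]),
    sprintf("##LASTX=%.15g", ppm[n]),
    sprintf("##NPOINTS=%d", n),
    "##XYDATA=(X++(Y..Y))")
  # 4 Y values per AFFN line, each prefixed by its X
  idx <- split(seq_len(n), ceiling(seq_len(n) / 4))
  body <- vapply(idx, function(ii)
    paste(c(sprintf("%.15g", ppm[ii[1L]]), sprintf("%.15g", y[ii])),
          collapse = " "), character(1))
  writeLines(c(hdr, body, "##END="), path)
  invisible(path)
}

#' Read / write a sample metadata table
#'
#' Plain CSV with header `sample_id,group`.
#'
#' @param path CSV file.
#' @return A data.frame with character columns `sample_id` and `group`.
#' @export
read_metadata <- function(path) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(md)))
    stop("metadata must have columns sample_id,group: ", path)
  md$sample_id <- as.character(md$sample_id)
  md$group <- as.character(md$group)
  if (anyDuplicated(md$sample_id)) stop("duplicate sample ids in ", path)
  md
}

#' @rdname read_metadata
#' @param metadata Data.frame with `sample_id` and `group` columns.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.csv(metadata[, c("sample_id", "group")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resample spectra onto one common ppm grid
#'
#' Linear interpolation onto a shared grid so that cross-sample features can
#' be formed per chemical-shift point.  Values at grid points already present
#' in a spectrum are preserved exactly.
#'
#' @param spectra List of [nmr_spectrum] objects whose ranges cover the grid.
#' @param grid Target ppm grid (numeric vector, either direction), or `NULL`
#'   to reuse the first spectrum's grid.
#' @return An [nmr_spectrum_set] on the (descending) target grid.
#' @export
resample_to_common_grid <- function(spectra, grid = NULL) {
  if (inherits(spectra, "nmr_spectrum")) spectra <- list(spectra)
  if (is.null(grid)) grid <- spectra[[1L]]$ppm
  grid <- sort(as.numeric(grid), decreasing = TRUE)
  if (anyDuplicated(grid)) stop("target grid has duplicated points")
  out <- lapply(spectra, function(s) {
    if (min(grid) < min(s$ppm) || max(grid) > max(s$ppm))
      stop("grid extends beyond the range of sample '", s$sample_id, "'")
    if (isTRUE(all.equal(s$ppm, grid, tolerance = 0)) ||
        identical(s$ppm, grid))
      return(nmr_spectrum(grid, s$intensity, s$sample_id, s$group))
    y <- rev(stats::approx(rev(s$ppm), rev(s$intensity), xout = rev(grid),
                           method = "linear", ties = "ordered")$y)
    nmr_spectrum(grid, y, s$sample_id, s$group)
  })
  nmr_spectrum_set(out)
}
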