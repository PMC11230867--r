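#' Construct a 1D NMR spectrum
#'
#' A spectrum is a pair of equal-length vectors: a strictly monotone chemical
#' shift axis in ppm and the corresponding intensities.  Internally the ppm
#' axis is always stored in descending order (the NMR display convention,
#' highest shift on the left); input in either direction is reordered.
#'
#' @param ppm Numeric vector of chemical shifts (ppm), strictly monotone.
#' @param intensity Numeric (or complex, prior to phasing) vector of the same
#'   length.  Non-finite values are rejected.
#' @param sample_id Character scalar identifying the sample.
#' @param group Character scalar group label (may be `NA`).
#' @return An object of class `nmr_spectrum`: a list with elements `ppm`
#'   (descending), `intensity`, `sample_id` and `group`.
#' @examples
#' s <- nmr_spectrum(seq(0, 12, length.out = 5), c(0, 1, 0, 2, 0), "s1")
#' s$ppm[1]  # 12: stored high-to-low
#' @export
nmr_spectrum <- function(ppm, intensity, sample_id = "sample", group = NA_character_) {
  ppm <- as.numeric(ppm)
  if (length(ppm) != length(intensity))
    stop("ppm and intensity must have the same length")
  if (length(ppm) < 2L) stop("a spectrum needs at least 2 points")
  if (any(!is.finite(ppm))) stop("non-finite ppm values are not allowed")
  d <- diff(ppm)
  if (all(d > 0)) {
    ord <- rev(seq_along(ppm))
    ppm <- ppm[ord]; intensity <- intensity[ord]
  } else if (!all(d < 0)) {
    stop("ppm grid must be strictly monotone")
  }
  if (!is.complex(intensity)) intensity <- as.numeric(intensity)
  if (any(!is.finite(intensity)))
    stop("non-finite intensity values are not allowed")
  structure(list(ppm = ppm, intensity = intensity,
                 sample_id = as.character(sample_id),
                 group = as.character(group)),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum> %s (group: %s), %d points, %.3f..%.3f ppm\n",
              x$sample_id, x$group, length(x$ppm),
              min(x$ppm), max(x$ppm)))
  invisible(x)
}

#' Bundle spectra sharing one ppm grid into a set
#'
#' All member spectra must sit on bit-identical ppm grids (use
#' [resample_to_common_grid()] first if they do not) and carry unique sample
#' ids.  The set stores intensities as a samples-by-points matrix.
#'
#' @param spectra List of [nmr_spectrum] objects on one identical grid.
#' @return An object of class `nmr_spectrum_set` with elements `ppm`,
#'   `intensity` (matrix, one row per sample), `sample_id`, `group`.
#' @export
nmr_spectrum_set <- function(spectra) {
  if (length(spectra) == 0L) stop("empty spectrum list")
  stopifnot(all(vapply(spectra, inherits, logical(1), "nmr_spectrum")))
  ppm <- spectra[[1L]]$ppm
  for (s in spectra)
    if (!identical(s$ppm, ppm))
      stop("spectrum '", s$sample_id, "' is not on the common ppm grid")
  ids <- vapply(spectra, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) stop("sample ids are not unique")
  mat <- do.call(rbind, lapply(spectra, `[[`, "intensity"))
  rownames(mat) <- ids
  structure(list(ppm = ppm, intensity = mat, sample_id = ids,
                 group = vapply(spectra, `[[`, character(1), "group")),
            class = "nmr_spectrum_set")
}

#' @export
print.nmr_spectrum_set <- function(x, ...) {
  cat(sprintf("<nmr_spectrum_set> %d spectra x %d points, %.3f..%.3f ppm\n",
              nrow(x$intensity), ncol(x$intensity), min(x$ppm), max(x$ppm)))
  tg <- table(x$group)
  cat("  groups:", paste(sprintf("%s (n=%d)", names(tg), tg), collapse = ", "), "\n")
  invisible(x)
}

#' Extract one member spectrum from a set
#' @param set An `nmr_spectrum_set`.
#' @param i Row index or sample id.
#' @return An [nmr_spectrum].
#' @export
set_spectrum <- function(set, i) {
  stopifnot(inherits(set, "nmr_spectrum_set"))
  if (is.character(i)) i <- match(i, set$sample_id)
  nmr_spectrum(set$ppm, set$intensity[i, ], set$sample_id[i], set$group[i])
}

n_samples <- function(set) nrow(set$intensity)
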