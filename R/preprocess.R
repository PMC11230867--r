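#' Default spectral exclusion windows
#'
#' Chemical-shift windows removed before analysis: residual water
#' (4.70--5.10 ppm), methanol (3.32--3.35 ppm), the fumarate reference peak
#' (6.45--6.58 ppm) and the propylene glycol windows (anaesthetic vehicle:
#' 1.10--1.15, 3.40--4.43, 3.436--3.442, 3.509--3.521, 3.53--3.54,
#' 3.841--3.884 ppm).
#'
#' The broad 3.40--4.43 ppm propylene-glycol window swallows a full ppm of
#' spectrum and is very likely a typographic variant of 3.40--3.43 (it
#' envelops the separately listed sub-windows); both behaviours are
#' available.  The default keeps the window as printed.
#'
#' @param narrow_pg_window If `TRUE`, replace 3.40--4.43 by 3.40--3.43.
#' @return Data.frame with columns `lo`, `hi`, `label`.
#' @export
default_exclusion_windows <- function(narrow_pg_window = FALSE) {
  pg_hi <- if (narrow_pg_window) 3.43 else 4.43
  w <- data.frame(
    lo = c(4.70, 3.32, 6.45, 1.10, 3.40, 3.436, 3.509, 3.53, 3.841),
    hi = c(5.10, 3.35, 6.58, 1.15, pg_hi, 3.442, 3.521, 3.54, 3.884),
    label = c("residual water", "methanol", "fumarate reference",
              rep("propylene glycol", 6)))
  w
}

#' Automatic phase correction
#'
#' For complex input, chooses zeroth- and first-order phase angles that
#' minimize the sum of squared negative excursions of the real part (an
#' absorptive spectrum is non-negative up to noise), then returns the real
#' part.  Real input is already phased and passes through unchanged.
#'
#' @param spectrum An [nmr_spectrum]; intensity may be complex.
#' @param first_order Also fit a first-order (frequency-proportional) phase
#'   term.  With sparse spectra the zeroth- and first-order terms trade off
#'   against each other; disable for a pure zeroth-order correction.
#' @return A real-valued [nmr_spectrum] with attribute `phase` = applied
#'   `c(phi0, phi1)` in radians.
#' @export
phase_correct <- function(spectrum, first_order = TRUE) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  z <- spectrum$intensity
  if (!is.complex(z)) return(spectrum)
  n <- length(z)
  frac <- seq(0, 1, length.out = n)
  obj <- function(par) {
    re <- Re(z * exp(-1i * (par[1] + par[2] * frac)))
    sum(pmin(re, 0)^2)
  }
  # coarse scan over phi0 (the objective has 2*pi-periodic local minima)
  grid0 <- seq(0, 2 * pi, length.out = 73)[-73]
  vals <- vapply(grid0, function(p0) obj(c(p0, 0)), numeric(1))
  p00 <- grid0[which.min(vals)]
  if (first_order) {
    best <- stats::optim(c(p00, 0), obj, method = "Nelder-Mead",
                         control = list(reltol = 1e-12, maxit = 2000))
    phi <- best$par
  } else {
    best <- stats::optimize(function(p0) obj(c(p0, 0)),
                            interval = p00 + c(-0.2, 0.2), tol = 1e-10)
    phi <- c(best$minimum, 0)
  }
  out <- nmr_spectrum(spectrum$ppm,
                      Re(z * exp(-1i * (phi[1] + phi[2] * frac))),
                      spectrum$sample_id, spectrum$group)
  attr(out, "phase") <- phi
  out
}

#' Align a spectrum to the internal reference peak
#'
#' Finds the tallest local maximum within `target +/- search_halfwidth`
#' (fumarate by default), then shifts the whole spectrum, re-interpolating
#' onto the original grid, so that this maximum sits on the grid point
#' nearest `target`.
#'
#' @param spectrum A real-valued [nmr_spectrum].
#' @param target Reference position, ppm (6.5 for fumarate).
#' @param search_halfwidth Half-width of the search window, ppm.
#' @return Shifted [nmr_spectrum] with attribute `shift` (ppm applied).
#' @export
align_to_reference <- function(spectrum, target = 6.5, search_halfwidth = 0.15) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  ppm <- spectrum$ppm; y <- spectrum$intensity
  inwin <- which(ppm >= target - search_halfwidth &
                 ppm <= target + search_halfwidth)
  if (length(inwin) < 3L) stop("reference peak not found (window too small)")
  # local maxima within the window (neighbours taken from the full grid)
  cand <- inwin[inwin > 1L & inwin < length(ppm)]
  ismax <- y[cand] > y[cand - 1L] & y[cand] > y[cand + 1L]
  if (!any(ismax)) stop("reference peak not found in [",
                        target - search_halfwidth, ", ",
                        target + search_halfwidth, "] ppm")
  peaks <- cand[ismax]
  p_star <- ppm[peaks[which.max(y[peaks])]]
  g_star <- ppm[which.min(abs(ppm - target))]
  shift <- p_star - g_star
  if (shift == 0) {
    out <- spectrum
  } else {
    ynew <- rev(stats::approx(rev(ppm), rev(y), xout = rev(ppm + shift),
                              method = "linear", rule = 2,
                              ties = "ordered")$y)
    out <- nmr_spectrum(ppm, ynew, spectrum$sample_id, spectrum$group)
  }
  attr(out, "shift") <- shift
  out
}

#' Remove excluded chemical-shift regions
#'
#' Drops every grid point falling inside any window (`lo <= ppm <= hi`).
#' The remaining grid keeps its order; downstream operations work on the
#' gapped grid.
#'
#' @param set An [nmr_spectrum_set].
#' @param windows Data.frame `lo`/`hi`/`label`; see
#'   [default_exclusion_windows()].
#' @return The reduced [nmr_spectrum_set].
#' @export
exclude_regions <- function(set, windows = default_exclusion_windows()) {
  stopifnot(inherits(set, "nmr_spectrum_set"))
  if (!nrow(windows)) return(set)
  if (any(windows$lo >= windows$hi)) stop("invalid window: lo must be < hi")
  drop <- rep(FALSE, length(set$ppm))
  for (i in seq_len(nrow(windows)))
    drop <- drop | (set$ppm >= windows$lo[i] & set$ppm <= windows$hi[i])
  if (all(drop)) stop("exclusion windows remove every spectral point")
  structure(list(ppm = set$ppm[!drop],
                 intensity = set$intensity[, !drop, drop = FALSE],
                 sample_id = set$sample_id, group = set$group),
            class = "nmr_spectrum_set")
}

#' Normalize each spectrum to unit total area
#'
#' Divides each sample's retained intensities by their sum, so retained
#' points sum to 1.  Run after region exclusion ("retained data points were
#' normalized"), not before.
#'
#' @param set An [nmr_spectrum_set].
#' @return Normalized [nmr_spectrum_set].
#' @export
normalize_total_area <- function(set) {
  stopifnot(inherits(set, "nmr_spectrum_set"))
  tot <- rowSums(set$intensity)
  bad <- which(tot <= 0)
  if (length(bad))
    stop("non-positive total intensity for sample '",
         set$sample_id[bad[1L]], "'")
  set$intensity <- set$intensity / tot
  set
}

#' Estimate per-sample noise from the signal-free region
#'
#' The noise level of each spectrum is the standard deviation of its
#' intensities between 0 and 0.2 ppm (a signal-free region of serum
#' spectra); the working threshold is 5x that level.
#'
#' @param set An [nmr_spectrum_set].
#' @param window Noise window in ppm, default `c(0, 0.2)`.
#' @param fold Threshold multiplier (5).
#' @return A `noise_model`: data.frame `sample_id`, `sigma`, `threshold`
#'   with attributes `window` and `fold`.
#' @export
estimate_noise <- function(set, window = c(0, 0.2), fold = 5) {
  stopifnot(inherits(set, "nmr_spectrum_set"))
  mask <- set$ppm >= window[1] & set$ppm <= window[2]
  if (sum(mask) < 2L)
    stop("noise window [", window[1], ", ", window[2],
         "] ppm is empty on the current grid")
  sigma <- apply(set$intensity[, mask, drop = FALSE], 1, stats::sd)
  out <- data.frame(sample_id = set$sample_id, sigma = sigma,
                    threshold = fold * sigma)
  attr(out, "window") <- window
  attr(out, "fold") <- fold
  class(out) <- c("noise_model", "data.frame")
  out
}

#' Discard chemical shifts dominated by noise
#'
#' A chemical-shift column is discarded if and only if strictly more than
#' 50% of samples have intensity below their own 5-sigma threshold.
#' Retained values are left untouched.
#'
#' @param set An [nmr_spectrum_set] (normalized).
#' @param noise A `noise_model` from [estimate_noise()]; computed from
#'   `set` when `NULL`.
#' @return The filtered [nmr_spectrum_set].
#' @export
threshold_filter <- function(set, noise = NULL) {
  stopifnot(inherits(set, "nmr_spectrum_set"))
  if (is.null(noise)) noise <- estimate_noise(set)
  stopifnot(nrow(noise) == n_samples(set))
  below <- sweep(set$intensity, 1, noise$threshold, `<`)
  frac_below <- colMeans(below)
  keep <- frac_below <= 0.5  # discard iff strictly more than half below
  if (!any(keep)) stop("all chemical shifts fall below the noise threshold")
  structure(list(ppm = set$ppm[keep],
                 intensity = set$intensity[, keep, drop = FALSE],
                 sample_id = set$sample_id, group = set$group),
            class = "nmr_spectrum_set")
}

# strict local maxima of a vector stored in descending-ppm order;
# plateaus (runs of equal values above both flanks) contribute their
# lowest-ppm point, i.e. the last index of the run.  Endpoints excluded.
local_maxima_idx <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  inner <- 2:(k - 1L)
  ismax <- r$values[inner] > r$values[inner - 1L] &
           r$values[inner] > r$values[inner + 1L]
  ends[inner][ismax]
}

#' Pick peaks as local maxima of the mean spectrum
#'
#' Detects strict local maxima of the across-sample mean spectrum; these
#' grid points become the shared feature set, and each sample contributes
#' its amplitude at those points ("peak amplitudes reflect metabolite
#' concentrations").  Plateaus resolve to their lowest-ppm point.
#'
#' @param set A thresholded, normalized [nmr_spectrum_set].
#' @return An `nmr_features` object: list with `values` (samples x
#'   features), `feature_ppm`, `sample_id`, `group`, `zscored = FALSE`.
#' @export
pick_peaks <- function(set) {
  stopifnot(inherits(set, "nmr_spectrum_set"))
  m <- colMeans(set$intensity)
  idx <- local_maxima_idx(m)
  if (!length(idx)) stop("no peaks found (no interior local maxima)")
  values <- set$intensity[, idx, drop = FALSE]
  colnames(values) <- sprintf("%.4f", set$ppm[idx])
  structure(list(values = values, feature_ppm = set$ppm[idx],
                 sample_id = set$sample_id, group = set$group,
                 zscored = FALSE),
            class = "nmr_features")
}

#' @export
print.nmr_features <- function(x, ...) {
  cat(sprintf("<nmr_features> %d samples x %d features%s\n",
              nrow(x$values), ncol(x$values),
              if (x$zscored) " (z-scored)" else ""))
  invisible(x)
}

#' Z-score features over a sample subset
#'
#' Per feature over the chosen samples: subtract the mean, divide by the
#' sample SD (n-1 denominator).  Zero-variance features are dropped with a
#' warning.  Z-scoring is done within each pairwise comparison's samples.
#'
#' @param features An `nmr_features` object.
#' @param samples Sample ids or indices to keep; `NULL` keeps all.
#' @return A z-scored `nmr_features` restricted to `samples`.
#' @export
zscore_features <- function(features, samples = NULL) {
  stopifnot(inherits(features, "nmr_features"))
  v <- features$values
  ids <- features$sample_id
  grp <- features$group
  if (!is.null(samples)) {
    i <- if (is.character(samples)) match(samples, ids) else samples
    if (anyNA(i)) stop("unknown sample id in subset")
    v <- v[i, , drop = FALSE]; ids <- ids[i]; grp <- grp[i]
  }
  if (nrow(v) < 3L) stop("z-scoring needs at least 3 samples")
  mu <- colMeans(v)
  sdv <- apply(v, 2, stats::sd)
  zero <- sdv == 0
  if (any(zero)) {
    warning(sum(zero), " constant feature(s) dropped before z-scoring")
    v <- v[, !zero, drop = FALSE]
    mu <- mu[!zero]; sdv <- sdv[!zero]
  }
  if (!ncol(v)) stop("no features left after dropping constant columns")
  z <- sweep(sweep(v, 2, mu), 2, sdv, `/`)
  structure(list(values = z, feature_ppm = features$feature_ppm[
                   if (any(zero)) !zero else seq_along(features$feature_ppm)],
                 sample_id = ids, group = grp, zscored = TRUE),
            class = "nmr_features")
}

#' Annotate features against a metabolite shift table
#'
#' Maps each feature to the nearest resonance line of the reference library;
#' features farther than `tolerance` from every line are "unassigned".  A
#' feature whose two nearest lines belong to different metabolites and are
#' both within tolerance is flagged ambiguous (overlapping peaks are later
#' excluded from pathway analysis).
#'
#' @param features An `nmr_features` object.
#' @param library List of [metabolite_spec]s.
#' @param tolerance Assignment tolerance, ppm.
#' @param spectrometer_mhz Frequency for the J-coupling conversion.
#' @return Data.frame `feature_ppm`, `metabolite`, `distance`, `ambiguous`.
#' @export
annotate_features <- function(features, library = build_reference_library(),
                              tolerance = 0.01, spectrometer_mhz = 600) {
  stopifnot(inherits(features, "nmr_features"))
  if (!length(library)) stop("empty metabolite library")
  lines <- library_lines(library, spectrometer_mhz)
  ann <- lapply(features$feature_ppm, function(fp) {
    d <- abs(lines$ppm - fp)
    o <- order(d)
    nearest <- o[1L]
    hit <- d[nearest] <= tolerance
    other <- o[lines$metabolite[o] != lines$metabolite[nearest]]
    amb <- hit && length(other) && d[other[1L]] <= tolerance
    data.frame(feature_ppm = fp,
               metabolite = if (hit) lines$metabolite[nearest] else "unassigned",
               distance = d[nearest], ambiguous = amb)
  })
  out <- do.call(rbind, ann)
  rownames(out) <- NULL
  out
}

#' Full spectral preprocessing pipeline
#'
#' Applies, in order: phase correction (identity on real data), alignment of
#' the reference peak to 6.5 ppm, exclusion windows, total-area
#' normalization of the retained points, the 5x-noise threshold with the
#' strict greater-than-50% discard rule, and local-maxima peak picking.
#' Z-scoring is deliberately left to the per-comparison stage.
#'
#' @param set An [nmr_spectrum_set] on a common grid.
#' @param windows Exclusion windows (data.frame `lo`/`hi`/`label`).
#' @param align Align each spectrum to the reference peak first?
#' @param target,search_halfwidth Passed to [align_to_reference()].
#' @return List with `features` (`nmr_features`), `set` (the processed
#'   spectrum set) and `noise` (the fitted `noise_model`).
#' @export
preprocess_spectra <- function(set, windows = default_exclusion_windows(),
                               align = TRUE, target = 6.5,
                               search_halfwidth = 0.15) {
  stopifnot(inherits(set, "nmr_spectrum_set"))
  if (align) {
    spectra <- lapply(seq_len(n_samples(set)), function(i)
      align_to_reference(phase_correct(set_spectrum(set, i)),
                         target, search_halfwidth))
    set <- nmr_spectrum_set(spectra)
  }
  set <- exclude_regions(set, windows)
  set <- normalize_total_area(set)
  noise <- estimate_noise(set)
  set <- threshold_filter(set, noise)
  features <- pick_peaks(set)
  list(features = features, set = set, noise = noise)
}
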