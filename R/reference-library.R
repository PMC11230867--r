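#' Define a metabolite for the spectral forward model
#'
#' Each metabolite is a set of first-order multiplets.  A multiplet has a
#' center (ppm), a number of lines, a scalar coupling J (Hz) and the fraction
#' of the metabolite's total signal it carries; line intensities within a
#' multiplet follow the binomial (Pascal) ratios of first-order coupling.
#'
#' @param name Canonical metabolite name.
#' @param multiplets Data.frame with columns `center` (ppm), `n_lines`
#'   (>= 1), `j_hz`, `relative_area` (fractions summing to 1).
#' @param halfwidth Lorentzian half-width at half-maximum, ppm (> 0).
#' @param base_concentration Baseline concentration, arbitrary units.
#' @param is_reference `TRUE` for the internal chemical-shift standard.
#' @return An object of class `metabolite_spec`.
#' @export
metabolite_spec <- function(name, multiplets, halfwidth = 0.0025,
                            base_concentration = 1,
                            is_reference = FALSE) {
  stopifnot(is.data.frame(multiplets),
            all(c("center", "n_lines", "j_hz", "relative_area") %in%
                  names(multiplets)))
  if (abs(sum(multiplets$relative_area) - 1) > 1e-9)
    stop("relative areas of '", name, "' must sum to 1")
  if (halfwidth <= 0) stop("halfwidth must be > 0")
  if (any(multiplets$n_lines < 1)) stop("n_lines must be >= 1")
  structure(list(name = name, multiplets = multiplets,
                 halfwidth = halfwidth,
                 base_concentration = base_concentration,
                 is_reference = isTRUE(is_reference)),
            class = "metabolite_spec")
}

mk_mult <- function(...) {
  m <- matrix(c(...), ncol = 4, byrow = TRUE)
  data.frame(center = m[, 1], n_lines = as.integer(m[, 2]),
             j_hz = m[, 3], relative_area = m[, 4])
}

#' Bundled serum metabolite reference library
#'
#' A built-in table of serum metabolites commonly resolved in 600 MHz
#' 1H spectra of mouse serum, with approximate literature chemical shifts,
#' first-order multiplicities and couplings.  It includes the fumarate
#' internal-standard singlet (near 6.5 ppm) used for chemical-shift
#' referencing, the branched-chain amino acids, common organic acids and
#' sugars, and the less abundant species (kynurenate, uridine monophosphate,
#' gluconate, N6-acetyllysine, N,N-dimethylglycine, 2-oxocaproate,
#' isovalerate, succinate, proline) relevant to stroke-recovery profiling.
#'
#' Shifts are nominal values for the simulator and for peak annotation, not
#' a substitute for curated assignment databases.
#'
#' @return List of [metabolite_spec] objects (>= 18 metabolites).
#' @export
build_reference_library <- function() {
  lib <- list(
    metabolite_spec("fumarate", mk_mult(6.50, 1, 0, 1),
                    base_concentration = 1.2, is_reference = TRUE),
    metabolite_spec("lactate", mk_mult(1.33, 2, 6.9, 0.75,
                                       4.11, 4, 6.9, 0.25),
                    base_concentration = 3.0),
    metabolite_spec("glucose", mk_mult(5.23, 2, 3.8, 0.2,
                                       3.47, 3, 9.1, 0.4,
                                       3.89, 2, 3.5, 0.4),
                    base_concentration = 2.5),
    metabolite_spec("taurine", mk_mult(3.26, 3, 6.6, 0.5,
                                       3.42, 3, 6.6, 0.5),
                    base_concentration = 1.5),
    metabolite_spec("myo-inositol", mk_mult(3.27, 3, 9.5, 0.35,
                                            3.61, 3, 9.9, 0.40,
                                            4.05, 3, 2.9, 0.25),
                    base_concentration = 1.2),
    metabolite_spec("glutamate", mk_mult(2.08, 3, 7.0, 0.4,
                                         2.34, 3, 7.5, 0.6),
                    base_concentration = 1.5),
    metabolite_spec("leucine", mk_mult(0.96, 2, 6.3, 0.6,
                                       1.70, 3, 7.0, 0.4),
                    base_concentration = 1.8),
    metabolite_spec("isoleucine", mk_mult(0.93, 3, 7.4, 0.5,
                                          1.01, 2, 7.0, 0.5),
                    base_concentration = 1.2),
    metabolite_spec("valine", mk_mult(0.99, 2, 7.0, 0.5,
                                      1.04, 2, 7.0, 0.5),
                    base_concentration = 1.4),
    metabolite_spec("glycerol", mk_mult(3.56, 2, 5.9, 0.5,
                                        3.65, 2, 4.4, 0.3,
                                        3.78, 3, 4.7, 0.2),
                    base_concentration = 2.0),
    metabolite_spec("isovalerate", mk_mult(0.905, 2, 6.6, 0.7,
                                           2.05, 2, 7.0, 0.3),
                    base_concentration = 1.0),
    metabolite_spec("kynurenate", mk_mult(6.70, 1, 0, 0.25,
                                          7.65, 3, 7.8, 0.35,
                                          8.03, 2, 8.4, 0.40),
                    base_concentration = 0.8),
    metabolite_spec("UMP", mk_mult(5.97, 2, 4.6, 0.5,
                                   8.08, 2, 8.1, 0.5),
                    base_concentration = 0.7),
    metabolite_spec("gluconate", mk_mult(4.60, 2, 4.0, 0.6,
                                         3.76, 2, 5.0, 0.4),
                    base_concentration = 0.9),
    metabolite_spec("N6-acetyllysine", mk_mult(1.98, 1, 0, 0.4,
                                               3.01, 3, 7.0, 0.3,
                                               1.43, 3, 7.3, 0.3),
                    base_concentration = 0.9),
    metabolite_spec("N,N-dimethylglycine", mk_mult(2.93, 1, 0, 0.75,
                                                   3.71, 1, 0, 0.25),
                    base_concentration = 0.8),
    metabolite_spec("succinate", mk_mult(2.41, 1, 0, 1),
                    base_concentration = 1.0),
    metabolite_spec("proline", mk_mult(2.01, 3, 7.0, 0.35,
                                       2.35, 3, 7.2, 0.30,
                                       4.14, 3, 8.0, 0.35),
                    base_concentration = 1.1),
    metabolite_spec("2-oxocaproate", mk_mult(0.885, 3, 7.4, 0.4,
                                             1.58, 3, 7.4, 0.3,
                                             2.73, 3, 7.3, 0.3),
                    base_concentration = 0.6),
    metabolite_spec("alanine", mk_mult(1.48, 2, 7.2, 1),
                    base_concentration = 1.3),
    metabolite_spec("citrate", mk_mult(2.54, 2, 15.1, 0.5,
                                       2.66, 2, 15.1, 0.5),
                    base_concentration = 1.0),
    metabolite_spec("creatine", mk_mult(3.03, 1, 0, 0.6,
                                        3.93, 1, 0, 0.4),
                    base_concentration = 1.0),
    metabolite_spec("glycine", mk_mult(3.55, 1, 0, 1),
                    base_concentration = 1.0),
    metabolite_spec("formate", mk_mult(8.46, 1, 0, 1),
                    base_concentration = 0.3),
    metabolite_spec("acetate", mk_mult(1.92, 1, 0, 1),
                    base_concentration = 0.8)
  )
  names(lib) <- vapply(lib, `[[`, character(1), "name")
  lib
}

#' Flatten a metabolite library into one line table
#'
#' Expands every multiplet of every metabolite into its individual resonance
#' lines (first-order pattern: lines spaced by J, binomial intensities).
#'
#' @param library List of [metabolite_spec]s.
#' @param spectrometer_mhz Spectrometer frequency used for the Hz-to-ppm
#'   conversion of couplings.
#' @return Data.frame with columns `metabolite`, `ppm`, `height_fraction`
#'   (line amplitude per unit concentration), `halfwidth`.
#' @export
library_lines <- function(library, spectrometer_mhz = 600) {
  if (!length(library)) stop("empty metabolite library")
  rows <- lapply(library, function(sp) {
    do.call(rbind, lapply(seq_len(nrow(sp$multiplets)), function(i) {
      m <- sp$multiplets[i, ]
      n <- m$n_lines
      pas <- choose(n - 1, 0:(n - 1))
      pas <- pas / sum(pas)
      jppm <- m$j_hz / spectrometer_mhz
      pos <- m$center + (seq_len(n) - (n + 1) / 2) * jppm
      data.frame(metabolite = sp$name, ppm = pos,
                 height_fraction = m$relative_area * pas,
                 halfwidth = sp$halfwidth)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
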