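#' Configuration for the synthetic serum-spectrum generator
#'
#' The defaults emulate the cohort design this package targets: four groups
#' of mice (non-diabetic / type-2-diabetic, sham / stroke surgery) with
#' sizes 5, 4, 9 and 9; 600 MHz spectra on a 0--12 ppm grid; a fumarate
#' internal standard whose position jitters per sample; contaminant signal
#' from residual water, methanol and propylene glycol placed inside the
#' standard exclusion windows; additive Gaussian noise; and log-normal
#' biological variation of metabolite concentrations.
#'
#' @param n_per_group Named integer vector: samples per group label.
#' @param grid `c(min_ppm, max_ppm, n_points)`.
#' @param spectrometer_mhz Spectrometer frequency (MHz) for J conversion.
#' @param noise_sd SD of additive Gaussian noise, intensity units.
#' @param shift_jitter_sd SD (ppm) of the per-sample global chemical-shift
#'   offset that fumarate referencing must correct.
#' @param effects Group-dependent concentration changes: data.frame with
#'   columns `group`, `metabolite`, `log2fc`.  Empty means no group effect.
#' @param seed Integer seed; cohort generation is reproducible given it.
#' @param contaminants_on Include water/methanol/propylene-glycol signal.
#' @param biological_sdlog SD (log scale) of per-sample log-normal
#'   concentration variation.
#' @param per_metabolite_jitter_sd Optional extra per-metabolite shift
#'   jitter (ppm); 0 disables it (default).
#' @param phase_error_deg If non-zero, spectra are emitted as complex pairs
#'   (absorption + i dispersion) rotated by a random zeroth-order phase with
#'   this SD in degrees, for exercising phase correction.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_per_group = c("ND-sham" = 5L, "T2D-sham" = 4L,
                                              "ND-stroke" = 9L, "T2D-stroke" = 9L),
                              grid = c(0, 12, 16384),
                              spectrometer_mhz = 600,
                              noise_sd = 0.004,
                              shift_jitter_sd = 0.02,
                              effects = NULL,
                              seed = 1L,
                              contaminants_on = TRUE,
                              biological_sdlog = 0.25,
                              per_metabolite_jitter_sd = 0,
                              phase_error_deg = 0) {
  if (length(grid) != 3L || grid[3] < 2) stop("grid must be c(min, max, n>=2)")
  if (grid[1] >= grid[2]) stop("grid min must be below max")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(effects))
    effects <- data.frame(group = character(), metabolite = character(),
                          log2fc = numeric())
  stopifnot(all(c("group", "metabolite", "log2fc") %in% names(effects)))
  structure(list(n_per_group = n_per_group, grid = as.numeric(grid),
                 spectrometer_mhz = spectrometer_mhz, noise_sd = noise_sd,
                 shift_jitter_sd = shift_jitter_sd, effects = effects,
                 seed = seed, contaminants_on = isTRUE(contaminants_on),
                 biological_sdlog = biological_sdlog,
                 per_metabolite_jitter_sd = per_metabolite_jitter_sd,
                 phase_error_deg = phase_error_deg),
            class = "sim_config")
}

sim_grid <- function(config) {
  seq(config$grid[2], config$grid[1], length.out = config$grid[3])
}

# Contaminant lines: every center sits strictly inside one of the default
# exclusion windows (residual water, methanol, propylene glycol) so that
# exclusion behaviour has known targets.
contaminant_lines <- function() {
  data.frame(
    metabolite = c("water", "methanol",
                   "propylene glycol", "propylene glycol",
                   "propylene glycol", "propylene glycol",
                   "propylene glycol", "propylene glycol"),
    ppm       = c(4.90, 3.335, 1.125, 1.135, 3.438, 3.515, 3.535, 3.862),
    height    = c(5.0, 0.8, 0.30, 0.30, 0.20, 0.25, 0.20, 0.25),
    halfwidth = c(0.030, 0.0025, 0.0025, 0.0025, 0.0025, 0.0025, 0.0025,
                  0.0025))
}

#' Simulate one 1D spectrum from the Lorentzian forward model
#'
#' Intensity at shift delta is the sum over metabolite lines of
#' `conc * height_fraction * g^2 / ((delta - d0 - jitter)^2 + g^2)` (pure
#' absorptive Lorentzian of half-width-at-half-maximum `g`, unit amplitude
#' per unit concentration at the line center), plus contaminant signal and
#' additive Gaussian noise.  Draws from the current RNG stream.
#'
#' @param specs List of [metabolite_spec]s.
#' @param concentrations Named vector of concentrations (>= 0); metabolites
#'   absent from the map use their `base_concentration`.
#' @param config A [simulation_config()].
#' @param jitter Global ppm offset applied to every line of this sample.
#' @param sample_id,group Labels for the emitted spectrum.
#' @return An [nmr_spectrum]; complex-valued when `phase_error_deg != 0`.
#' @export
simulate_spectrum <- function(specs, concentrations = NULL,
                              config = simulation_config(),
                              jitter = 0, sample_id = "sim", group = NA) {
  if (!length(specs)) stop("empty metabolite spec list")
  nm <- vapply(specs, `[[`, character(1), "name")
  conc <- vapply(specs, `[[`, numeric(1), "base_concentration")
  names(conc) <- nm
  if (!is.null(concentrations)) {
    unknown <- setdiff(names(concentrations), nm)
    if (length(unknown))
      stop("unknown metabolite in concentrations: ",
           paste(unknown, collapse = ", "))
    conc[names(concentrations)] <- concentrations
  }
  if (any(conc < 0)) stop("concentrations must be >= 0")
  ppm <- sim_grid(config)
  lines <- library_lines(specs, config$spectrometer_mhz)
  if (config$per_metabolite_jitter_sd > 0) {
    mj <- stats::rnorm(length(nm), 0, config$per_metabolite_jitter_sd)
    names(mj) <- nm
    lines$ppm <- lines$ppm + mj[lines$metabolite]
  }
  amp <- conc[lines$metabolite] * lines$height_fraction
  absorb <- numeric(length(ppm))
  disp <- if (config$phase_error_deg != 0) numeric(length(ppm)) else NULL
  add_line <- function(a, d0, g) {
    dd <- ppm - d0 - jitter
    absorb <<- absorb + a * g^2 / (dd^2 + g^2)
    if (!is.null(disp)) disp <<- disp + a * g * dd / (dd^2 + g^2)
  }
  for (i in seq_len(nrow(lines)))
    add_line(amp[i], lines$ppm[i], lines$halfwidth[i])
  if (config$contaminants_on) {
    cl <- contaminant_lines()
    for (i in seq_len(nrow(cl)))
      add_line(cl$height[i], cl$ppm[i], cl$halfwidth[i])
  }
  if (config$noise_sd > 0)
    absorb <- absorb + stats::rnorm(length(ppm), 0, config$noise_sd)
  intensity <- absorb
  if (!is.null(disp)) {
    phi <- stats::rnorm(1, 0, config$phase_error_deg) * pi / 180
    intensity <- complex(real = absorb, imaginary = disp) * exp(1i * phi)
    attr(phi, "applied_phase_rad") <- phi
  }
  s <- nmr_spectrum(ppm, intensity, sample_id, group)
  if (!is.null(disp)) s$applied_phase_rad <- phi
  s
}

#' Simulate a cohort of serum spectra with known ground truth
#'
#' Draws per-sample metabolite concentrations (base level times the group's
#' 2^log2fc effect times log-normal biological variation), a per-sample
#' global chemical-shift jitter, and forwards each sample through
#' [simulate_spectrum()].  Fully reproducible given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @param library Metabolite library; defaults to
#'   [build_reference_library()].
#' @return List with elements `set` (an [nmr_spectrum_set]) and `truth`
#'   (list: `concentrations` samples-x-metabolites matrix, `jitter`,
#'   `effects`, `groups`, `sample_id`, `config`).
#' @export
simulate_cohort <- function(config = simulation_config(),
                            library = build_reference_library()) {
  nm <- vapply(library, `[[`, character(1), "name")
  if (nrow(config$effects)) {
    unknown <- setdiff(config$effects$metabolite, nm)
    if (length(unknown))
      stop("unknown metabolite in effects: ", paste(unknown, collapse = ", "))
    if (anyDuplicated(config$effects[c("group", "metabolite")]))
      stop("duplicate (group, metabolite) entry in effects")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  groups <- rep(names(config$n_per_group), config$n_per_group)
  n <- length(groups)
  ids <- paste0(groups, "_", unlist(lapply(config$n_per_group, seq_len)))
  base <- vapply(library, `[[`, numeric(1), "base_concentration")
  lfc <- matrix(0, n, length(nm), dimnames = list(ids, nm))
  for (i in seq_len(nrow(config$effects))) {
    e <- config$effects[i, ]
    lfc[groups == e$group, e$metabolite] <- e$log2fc
  }
  biol <- matrix(stats::rlnorm(n * length(nm), 0, config$biological_sdlog),
                 n, length(nm))
  conc <- sweep(2^lfc * biol, 2, base, `*`)
  dimnames(conc) <- list(ids, nm)
  jit <- stats::rnorm(n, 0, config$shift_jitter_sd)
  spectra <- lapply(seq_len(n), function(i)
    simulate_spectrum(library, conc[i, ], config, jitter = jit[i],
                      sample_id = ids[i], group = groups[i]))
  truth <- list(concentrations = conc, jitter = jit,
                effects = config$effects, groups = groups,
                sample_id = ids, config = config)
  list(set = nmr_spectrum_set(spectra), truth = truth)
}

#' Write a simulated cohort to plain-text files
#'
#' Spectra as JCAMP-DX or two-column TSV, sample metadata as CSV
#' (`sample_id,group`) and the ground truth as JSON.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @param format Spectrum format, `"tsv"` or `"jcamp-dx"`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("tsv", "jcamp-dx")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set <- cohort$set
  ext <- if (format == "tsv") ".tsv" else ".jdx"
  for (i in seq_len(n_samples(set)))
    write_spectrum(set_spectrum(set, i),
                   file.path(dir, paste0(set$sample_id[i], ext)), format)
  write_metadata(data.frame(sample_id = set$sample_id, group = set$group),
                 file.path(dir, "metadata.csv"))
  tr <- cohort$truth
  jsonlite::write_json(
    list(concentrations = as.data.frame(tr$concentrations),
         sample_id = tr$sample_id, jitter = tr$jitter,
         effects = tr$effects, groups = tr$groups),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
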