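#' Default pairwise comparisons of the four-group cohort
#'
#' The four comparisons of the stroke-recovery design: the diet effect
#' after stroke (ND-stroke vs T2D-stroke), the stroke effect within each
#' diet (ND-sham vs ND-stroke; T2D-sham vs T2D-stroke), and the diet effect
#' without stroke (ND-sham vs T2D-sham).  `group_a` is the reference;
#' effect signs are comparison minus reference.
#'
#' @return Data.frame `name`, `group_a`, `group_b`, `type` (`"stroke"` for
#'   stroke-vs-sham, `"diet"` for HFD-vs-SD contrasts).
#' @export
default_comparisons <- function() {
  data.frame(
    name = c("ND-stroke vs T2D-stroke", "ND-sham vs ND-stroke",
             "T2D-sham vs T2D-stroke", "ND-sham vs T2D-sham"),
    group_a = c("ND-stroke", "ND-sham", "T2D-sham", "ND-sham"),
    group_b = c("T2D-stroke", "ND-stroke", "T2D-stroke", "T2D-sham"),
    type = c("diet", "stroke", "stroke", "diet"))
}

#' Run the full fingerprinting pipeline on a spectrum set
#'
#' Preprocesses the cohort once (alignment, exclusion windows, total-area
#' normalization, 5x-noise threshold with the strict majority discard rule,
#' peak picking), then for every pairwise comparison: z-scores the features
#' within the comparison's samples, fits an OPLS model (with permutation
#' validation), assembles the VIP table and volcano statistics, collapses
#' VIP > 1 features to metabolites and runs the pathway
#' over-representation/impact analysis.
#'
#' @param set An [nmr_spectrum_set] with group labels.
#' @param comparisons Data.frame as from [default_comparisons()].
#' @param library Metabolite reference library for annotation.
#' @param pathway_library A `pathway_library` for the enrichment stage.
#' @param windows Exclusion windows.
#' @param n_orth Orthogonal components (`"auto"` or integer, recycled over
#'   comparisons).
#' @param n_perm Permutations for model validation (100).
#' @param vip_threshold VIP cut-off for the metabolite collapse (1).
#' @param alpha FDR threshold for pathway selection (0.05).
#' @param seed Integer seed controlling the permutation draws.
#' @param outdir Optional directory: writes per-comparison tables (scores,
#'   VIP, volcano, pathway results), model summaries and a manifest.
#' @return A list of class `nmr_report`: `features`, `annotations`,
#'   `noise`, and `comparisons` (per comparison: `model`, `permutation`,
#'   `vip_table`, `volcano`, `metabolites`, `pathways`).
#' @export
run_pipeline <- function(set, comparisons = default_comparisons(),
                         library = build_reference_library(),
                         pathway_library = read_pathway_library(),
                         windows = default_exclusion_windows(),
                         n_orth = "auto", n_perm = 100, vip_threshold = 1,
                         alpha = 0.05, seed = 1L, outdir = NULL) {
  stopifnot(inherits(set, "nmr_spectrum_set"))
  # fail fast on configuration errors, before any computation
  missing <- setdiff(unique(c(comparisons$group_a, comparisons$group_b)),
                     unique(set$group))
  if (length(missing)) {
    bad <- comparisons$name[comparisons$group_a %in% missing |
                            comparisons$group_b %in% missing]
    stop("group(s) ", paste(missing, collapse = ", "),
         " absent from metadata (comparison: ",
         paste(bad, collapse = "; "), ")")
  }
  if (any(comparisons$group_a == comparisons$group_b))
    stop("a comparison has identical groups")
  pp <- preprocess_spectra(set, windows = windows)
  ann <- annotate_features(pp$features, library)
  n_orth <- rep(n_orth, length.out = nrow(comparisons))
  res <- vector("list", nrow(comparisons))
  names(res) <- comparisons$name
  for (i in seq_len(nrow(comparisons))) {
    ga <- comparisons$group_a[i]; gb <- comparisons$group_b[i]
    samples <- pp$features$sample_id[pp$features$group %in% c(ga, gb)]
    z <- suppressWarnings(zscore_features(pp$features, samples))
    zann <- ann[match(z$feature_ppm, ann$feature_ppm), ]
    set.seed(seed + i)
    model <- opls(z, factor(z$group, levels = c(ga, gb)),
                  n_orth = n_orth[[i]])
    perm <- permutation_test(model, n_perm = n_perm, seed = seed + i)
    volcano <- ttest_features(z, ga, gb, annotations = zann)
    mets <- collapse_to_metabolites(model$vip, zann,
                                    threshold = vip_threshold,
                                    delta_z = volcano$delta_z)
    pw <- pathway_analysis(mets, pathway_library, alpha = alpha)
    vip_table <- data.frame(ppm = z$feature_ppm,
                            metabolite = zann$metabolite,
                            vip = unname(model$vip),
                            delta_z = volcano$delta_z)
    vip_table <- vip_table[order(-vip_table$vip), ]
    res[[i]] <- list(name = comparisons$name[i], group_a = ga, group_b = gb,
                     model = model, permutation = perm,
                     vip_table = vip_table, volcano = volcano,
                     metabolites = mets, pathways = pw)
  }
  report <- structure(list(features = pp$features, annotations = ann,
                           noise = pp$noise, comparisons = res,
                           comparison_table = comparisons, seed = seed),
                      class = "nmr_report")
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' @export
print.nmr_report <- function(x, ...) {
  cat(sprintf("<nmr_report> %d features, %d comparisons\n",
              ncol(x$features$values), length(x$comparisons)))
  for (cm in x$comparisons)
    cat(sprintf("  %-26s R2Y=%.3f Q2=%.3f VIP>1: %d  pathways selected: %d\n",
                cm$name, cm$model$r2y_cum, cm$model$q2_cum,
                sum(cm$model$vip > 1), sum(cm$pathways$selected)))
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits, per comparison, the scores/VIP/volcano/pathway tables plus a JSON
#' model summary, and a `manifest.json` listing every artifact so the
#' bundle is self-contained.
#'
#' @param report An `nmr_report`.
#' @param outdir Output directory (created if needed).
#' @return Manifest (character vector of paths), invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  emit <- function(obj, file, writer) {
    path <- file.path(outdir, file)
    writer(obj, path)
    manifest <<- c(manifest, file)
  }
  fm <- as.data.frame(report$features$values)
  fm <- cbind(sample_id = report$features$sample_id,
              group = report$features$group, fm)
  emit(fm, "feature_matrix.tsv", function(o, p)
    utils::write.table(o, p, sep = "\t", row.names = FALSE, quote = FALSE))
  emit(report$annotations, "annotations.csv", function(o, p)
    utils::write.csv(o, p, row.names = FALSE, quote = FALSE))
  for (cm in report$comparisons) {
    slug <- gsub("[^A-Za-z0-9]+", "_", cm$name)
    scores <- data.frame(sample_id = rownames(cm$model$x),
                         t_pred = cm$model$t_pred)
    if (cm$model$n_orth > 0) scores$t_orth1 <- cm$model$T_orth[, 1]
    emit(scores, paste0(slug, "_scores.tsv"), function(o, p)
      utils::write.table(o, p, sep = "\t", row.names = FALSE, quote = FALSE))
    emit(cm$vip_table, paste0(slug, "_vip.tsv"), function(o, p)
      utils::write.table(o, p, sep = "\t", row.names = FALSE, quote = FALSE))
    emit(cm$volcano, paste0(slug, "_volcano.csv"), function(o, p)
      write_volcano(o, p))
    emit(cm$pathways, paste0(slug, "_pathways.csv"), function(o, p)
      utils::write.csv(o, p, row.names = FALSE, quote = FALSE))
    emit(cm, paste0(slug, "_model.json"), function(o, p)
      opls_summary_json(o$model, o$permutation, p))
  }
  jsonlite::write_json(list(files = manifest, seed = report$seed),
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Set difference of altered metabolites or pathways across comparisons
#'
#' Members of each target set (for example metabolites with VIP > 1 in a
#' stroke-vs-sham comparison) that appear in none of the background sets
#' (the diet comparisons).  Direction of change is carried through when the
#' sets are data.frames with a `delta_z` column.
#'
#' @param target_sets Named list of character vectors or data.frames with a
#'   `metabolite` (or `pathway`) first identifier column.
#' @param background_sets List of sets to subtract.
#' @return Named list, one element per target set, of the unique members
#'   (same type as the input sets).
#' @export
unique_changes <- function(target_sets, background_sets) {
  members <- function(s) {
    if (is.data.frame(s)) {
      key <- intersect(c("metabolite", "pathway"), names(s))[1]
      if (is.na(key)) stop("set data.frame needs a metabolite/pathway column")
      as.character(s[[key]])
    } else as.character(s)
  }
  bg <- unique(unlist(lapply(background_sets, members)))
  lapply(target_sets, function(s) {
    m <- members(s)
    keep <- !(m %in% bg)
    if (is.data.frame(s)) s[keep, , drop = FALSE] else m[keep]
  })
}

#' Unique stroke-associated alterations from a pipeline report
#'
#' Convenience wrapper applying [unique_changes()] to a fitted
#' [run_pipeline()] report: metabolites (VIP > 1, after annotation
#' collapse) and selected pathways of the stroke-vs-sham comparisons that
#' do not appear in either diet comparison.
#'
#' @param report An `nmr_report`.
#' @return List with `metabolites` and `pathways`, each a named list per
#'   stroke comparison.
#' @export
unique_stroke_changes <- function(report) {
  ct <- report$comparison_table
  stroke <- ct$name[ct$type == "stroke"]
  diet <- ct$name[ct$type == "diet"]
  mets <- lapply(report$comparisons, `[[`, "metabolites")
  pws <- lapply(report$comparisons, function(cm)
    select_pathways(cm$pathways))
  list(metabolites = unique_changes(mets[stroke], mets[diet]),
       pathways = unique_changes(pws[stroke], pws[diet]))
}
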