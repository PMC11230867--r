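#' Canonicalize metabolite names
#'
#' Lower-cases, trims and resolves common synonyms so that peak annotations
#' match the pathway library's compound names by exact (case-insensitive)
#' comparison; there is no fuzzy matching.
#'
#' @param x Character vector of metabolite names.
#' @return Canonical lower-case names.
#' @export
canonical_name <- function(x) {
  syn <- c("uridine monophosphate" = "ump",
           "uridine 5'-monophosphate" = "ump",
           "myoinositol" = "myo-inositol",
           "inositol" = "myo-inositol",
           "kynurenic acid" = "kynurenate",
           "succinic acid" = "succinate",
           "2-oxohexanoate" = "2-oxocaproate",
           "dimethylglycine" = "n,n-dimethylglycine",
           "n6-acetyl-l-lysine" = "n6-acetyllysine",
           "gluconic acid" = "gluconate",
           "isovaleric acid" = "isovalerate",
           "fumaric acid" = "fumarate",
           "lactic acid" = "lactate",
           "citric acid" = "citrate",
           "acetic acid" = "acetate",
           "formic acid" = "formate")
  x <- tolower(trimws(x))
  hit <- x %in% names(syn)
  x[hit] <- syn[x[hit]]
  x
}

#' Read a pathway library from JSON
#'
#' Expected schema: `pathways` is an array of objects with `name`,
#' `compounds` (array of names) and `edges` (array of 2-element arrays over
#' those compounds).  The compound universe is the union of all pathway
#' compound sets.
#'
#' @param path JSON file; defaults to the bundled miniature library (a
#'   synthetic, reduced stand-in with a KEGG-like schema).
#' @return A `pathway_library`: list with `pathways` and `universe`.
#' @export
read_pathway_library <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "pathway_library.json",
                        package = "oplsnmr", mustWork = TRUE)
  raw <- jsonlite::read_json(path)
  if (is.null(raw$pathways)) stop("no 'pathways' array in ", path)
  pws <- lapply(raw$pathways, function(p) {
    comp <- canonical_name(unlist(p$compounds))
    edges <- if (length(p$edges))
      do.call(rbind, lapply(p$edges, function(e) canonical_name(unlist(e))))
    else matrix(character(0), 0, 2)
    if (length(edges) && !all(edges %in% comp))
      stop("edge endpoint outside compound set in pathway '", p$name, "'")
    list(name = p$name, compounds = comp, edges = edges)
  })
  names(pws) <- vapply(pws, `[[`, character(1), "name")
  structure(list(pathways = pws,
                 universe = sort(unique(unlist(lapply(pws, `[[`, "compounds"))))),
            class = "pathway_library")
}

#' @export
print.pathway_library <- function(x, ...) {
  cat(sprintf("<pathway_library> %d pathways, %d compounds in universe\n",
              length(x$pathways), length(x$universe)))
  invisible(x)
}

#' Collapse VIP-selected features to metabolites
#'
#' Keeps metabolites whose best annotated feature exceeds the VIP
#' threshold; when a metabolite has several spectral points, the one with
#' the highest VIP represents it (ties break to the lower chemical shift).
#' Features flagged ambiguous (overlapping peaks) or unassigned are
#' excluded from pathway analysis.
#'
#' @param vip Per-feature VIP scores, aligned with `annotations` rows.
#' @param annotations Annotation table from [annotate_features()].
#' @param threshold VIP cut-off (features must exceed it strictly).
#' @param delta_z Optional per-feature effect (e.g. mean z-score
#'   difference) carried through for the representative feature.
#' @return Data.frame `metabolite` (canonical name), `feature_ppm`, `vip`,
#'   and `delta_z` when supplied.
#' @export
collapse_to_metabolites <- function(vip, annotations, threshold = 1,
                                    delta_z = NULL) {
  if (length(vip) != nrow(annotations))
    stop("vip and annotations must align per feature")
  keep <- annotations$metabolite != "unassigned" & !annotations$ambiguous
  df <- data.frame(metabolite = canonical_name(annotations$metabolite[keep]),
                   feature_ppm = annotations$feature_ppm[keep],
                   vip = vip[keep])
  if (!is.null(delta_z)) df$delta_z <- delta_z[keep]
  if (!nrow(df))
    return(df[0, , drop = FALSE])
  # highest VIP per metabolite; ties to lower ppm
  df <- df[order(df$metabolite, -df$vip, df$feature_ppm), ]
  df <- df[!duplicated(df$metabolite), ]
  df <- df[df$vip > threshold, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Over-representation p-value (hypergeometric upper tail)
#'
#' Probability of observing at least `hits` pathway members in a random
#' draw of `selected` compounds from a universe of `universe` compounds of
#' which `pathway_size` belong to the pathway.
#'
#' @param hits Matched compounds in the pathway.
#' @param selected Total selected (significant) compounds in the universe.
#' @param pathway_size Compounds in the pathway.
#' @param universe Compounds in the reference universe.
#' @return P(X >= hits) for X ~ Hypergeometric.
#' @export
ora_pvalue <- function(hits, selected, pathway_size, universe) {
  if (any(c(hits, selected, pathway_size, universe) < 0))
    stop("counts must be >= 0")
  if (pathway_size > universe) stop("pathway_size exceeds universe")
  if (selected > universe) stop("selected exceeds universe")
  if (hits > min(selected, pathway_size))
    stop("hits exceeds min(selected, pathway_size)")
  stats::phyper(hits - 1, pathway_size, universe - pathway_size, selected,
                lower.tail = FALSE)
}

#' Topology-based pathway impact score
#'
#' Impact is the summed relative betweenness centrality of the matched
#' compounds divided by the summed centrality of all compounds in the
#' pathway graph (undirected shortest-path betweenness).  If every node has
#' zero centrality (for example a 2-node pathway), impact is defined as 0.
#'
#' @param pathway One element of a [read_pathway_library()] `pathways`
#'   list: `name`, `compounds`, `edges`.
#' @param matched Character vector of matched compound names (canonical).
#' @return Impact in [0, 1].
#' @export
topology_impact <- function(pathway, matched) {
  matched <- canonical_name(matched)
  compounds <- canonical_name(pathway$compounds)
  if (length(matched) && !all(matched %in% compounds))
    stop("matched compound not in pathway '", pathway$name, "'")
  if (!length(matched)) return(0)
  edges <- pathway$edges
  g <- if (length(edges)) {
    edf <- data.frame(from = canonical_name(edges[, 1]),
                      to = canonical_name(edges[, 2]))
    igraph::graph_from_data_frame(edf, directed = FALSE,
                                  vertices = data.frame(name = compounds))
  } else {
    igraph::make_empty_graph(n = length(compounds), directed = FALSE)
  }
  # unnormalized shortest-path betweenness; the normalization constant
  # cancels in the matched-to-total ratio
  cent <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  names(cent) <- compounds
  tot <- sum(cent)
  if (tot == 0) return(0)
  sum(cent[matched]) / tot
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement, capped at 1.
#'
#' @param pvalues Numeric vector in [0, 1].
#' @return Adjusted p-values, same order as input.
#' @export
adjust_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE) || any(is.na(pvalues)))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Pathway over-representation analysis with topology impact
#'
#' For each library pathway: count hits among the selected metabolites,
#' compute the hypergeometric over-representation p-value against the
#' library universe, the topology impact of the matched compounds, adjust
#' p-values across pathways by Benjamini-Hochberg, and flag pathways
#' passing the dual rule adjusted p < 0.05 AND impact > 0 (strict).
#' Pathways with impact 0 remain in the table, unselected.
#'
#' @param metabolites Character vector of selected metabolite names (or the
#'   data.frame from [collapse_to_metabolites()]).
#' @param library A `pathway_library`.
#' @param universe_size Override for the universe size (defaults to the
#'   number of compounds in the library universe).
#' @param alpha Significance level for the selection rule.
#' @return Data.frame of class `pathway_result`: `pathway`, `hits`
#'   (semicolon-joined), `n_hits`, `pathway_size`, `p`, `p_adjusted`,
#'   `impact`, `selected`, ordered by adjusted p then raw p.
#' @export
pathway_analysis <- function(metabolites, library = read_pathway_library(),
                             universe_size = NULL, alpha = 0.05) {
  if (is.data.frame(metabolites)) metabolites <- metabolites$metabolite
  met <- unique(canonical_name(metabolites))
  in_universe <- met[met %in% library$universe]
  n_univ <- if (is.null(universe_size)) length(library$universe)
            else universe_size
  n_sel <- length(in_universe)
  rows <- lapply(library$pathways, function(pw) {
    hit <- intersect(in_universe, pw$compounds)
    data.frame(pathway = pw$name,
               hits = paste(hit, collapse = ";"),
               n_hits = length(hit),
               pathway_size = length(pw$compounds),
               p = ora_pvalue(length(hit), n_sel, length(pw$compounds),
                              n_univ),
               impact = topology_impact(pw, hit))
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- adjust_fdr(out$p)
  out$selected <- out$p_adjusted < alpha & out$impact > 0
  out <- out[order(out$p_adjusted, out$p, -out$impact), ]
  out <- out[, c("pathway", "hits", "n_hits", "pathway_size", "p",
                 "p_adjusted", "impact", "selected")]
  rownames(out) <- NULL
  class(out) <- c("pathway_result", "data.frame")
  out
}

#' Select pathways of interest
#'
#' Applies the dual rule: FDR-adjusted p strictly below `alpha` and impact
#' strictly above 0.  Pathways failing only the impact criterion stay
#' reported in the full table but are not selected.
#'
#' @param results A `pathway_result` table.
#' @param alpha Adjusted-p threshold.
#' @return The selected subset of `results`.
#' @export
select_pathways <- function(results, alpha = 0.05) {
  stopifnot(is.data.frame(results),
            all(c("p_adjusted", "impact") %in% names(results)))
  results[results$p_adjusted < alpha & results$impact > 0, , drop = FALSE]
}
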