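#' Per-feature two-sample t-tests (volcano table)
#'
#' Classical equal-variance Student's t-test per feature on z-scores,
#' two-sided p from the t distribution with n1 + n2 - 2 degrees of freedom,
#' with no multiplicity adjustment (the volcano display reports unadjusted
#' p-values; FDR control is applied at the pathway stage only).  The effect
#' column `delta_z` is the mean z-score of `group2` minus `group1`
#' (comparison minus reference).
#'
#' @param features An `nmr_features` object (z-scored over the two groups).
#' @param group1 Reference group label.
#' @param group2 Comparison group label.
#' @param welch Use the Welch (unequal variance) statistic instead.
#' @param annotations Optional annotation table from [annotate_features()]
#'   used to fill the `metabolite` column.
#' @return A data.frame of class `volcano_table`: `ppm`, `metabolite`,
#'   `delta_z`, `t`, `p`, with attribute `significance_line = 0.05`.
#' @export
ttest_features <- function(features, group1, group2, welch = FALSE,
                           annotations = NULL) {
  stopifnot(inherits(features, "nmr_features"))
  i1 <- which(features$group == group1)
  i2 <- which(features$group == group2)
  if (length(i1) < 2L || length(i2) < 2L)
    stop("each group needs at least 2 samples")
  x1 <- features$values[i1, , drop = FALSE]
  x2 <- features$values[i2, , drop = FALSE]
  n1 <- length(i1); n2 <- length(i2)
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- apply(x1, 2, stats::var); v2 <- apply(x2, 2, stats::var)
  if (welch) {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- se^4 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  }
  d <- m2 - m1
  t <- ifelse(se == 0, ifelse(d == 0, 0, sign(d) * Inf), d / se)
  p <- 2 * stats::pt(-abs(t), df)
  p <- pmax(pmin(p, 1), .Machine$double.xmin)
  ann <- if (!is.null(annotations))
    annotations$metabolite[match(features$feature_ppm,
                                 annotations$feature_ppm)]
  else rep(NA_character_, length(d))
  out <- data.frame(ppm = features$feature_ppm, metabolite = ann,
                    delta_z = d, t = t, p = p, row.names = NULL)
  attr(out, "significance_line") <- 0.05
  attr(out, "groups") <- c(reference = group1, comparison = group2)
  class(out) <- c("volcano_table", "data.frame")
  out
}

#' Write a volcano table to CSV
#'
#' Emits the per-feature table plus the dashed significance line value
#' (p = 0.05) as a comment-free extra column-less header line is avoided:
#' the line value is stored in the column `significance_line` of every row
#' for machine readability.
#'
#' @param volcano A `volcano_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_volcano <- function(volcano, path) {
  out <- as.data.frame(volcano)
  out$significance_line <- attr(volcano, "significance_line")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
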