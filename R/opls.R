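#' Orthogonal projections to latent structures (OPLS) regression
#'
#' Fits a single-response OPLS model by NIPALS-style deflation: variation in
#' `x` that is orthogonal to the response is stripped into `n_orth`
#' orthogonal components before a final predictive PLS component is
#' computed.  The response is a binary group membership (encoded 0/1 and
#' mean-centered internally) or any numeric vector; predictors are expected
#' to be z-scored (see [zscore_features()]).
#'
#' For each orthogonal component the algorithm computes `w` proportional to
#' `X'y` (unit norm), scores `t = Xw`, loadings `p = X't/(t't)`, the
#' orthogonal weight `w_o` proportional to `p - (w'p)w` (unit norm, so
#' `w_o` is orthogonal to `w`), orthogonal scores `t_o = X w_o` and loadings
#' `p_o = X't_o/(t_o't_o)`, and deflates `X <- X - t_o p_o'`.  After the
#' last deflation the predictive component is computed on the deflated
#' matrix.  Model quality is summarized by cumulative R2Y (fraction of
#' response variation modelled) and cumulative Q2 (fraction predicted under
#' stratified k-fold cross-validation; negative for models worse than the
#' mean).
#'
#' @param x Numeric matrix (samples x features) or an `nmr_features`
#'   object (z-scored).
#' @param y Binary group labels (factor/character with 2 levels, or 0/1),
#'   or a numeric response.
#' @param n_orth Number of orthogonal components, or `"auto"` to add
#'   components greedily while cross-validated Q2 improves by more than
#'   `auto_tol` (see [select_n_orthogonal()]).
#' @param max_orth Cap on orthogonal components for `"auto"`.
#' @param cv_folds Folds for the cross-validated Q2 (default 7,
#'   stratified round-robin; capped at n).
#' @param auto_tol Minimum Q2 improvement for `"auto"` selection.
#' @return An object of class `opls`: list with predictive weight `w`
#'   (unit norm), scores `t_pred`, loadings `p_pred`, y-loading `c`,
#'   orthogonal `W_orth`/`T_orth`/`P_orth`, `n_orth`, `r2y_cum`, `q2_cum`,
#'   `vip` (see [vip()]), the encoded response and group levels, and the
#'   training matrix.
#' @seealso [predict.opls()], [vip()], [permutation_test()],
#'   [hotelling_ellipse()]
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(14 * 10), 14, 10)
#' y <- rep(c("a", "b"), each = 7)
#' x[, 1] <- ifelse(y == "b", 1, -1) + rnorm(14, 0, 0.1)
#' x <- scale(x)
#' m <- opls(x, y, n_orth = 0)
#' which.max(m$vip)  # feature 1 carries the class signal
#' @export
opls <- function(x, y, n_orth = "auto", max_orth = 5, cv_folds = 7,
                 auto_tol = 0.01) {
  xy <- opls_xy(x, y)
  X <- xy$X; yc <- xy$yc
  if (nrow(X) < 4L) stop("OPLS needs at least 4 samples")
  if (identical(n_orth, "auto"))
    n_orth <- select_n_orthogonal(X, xy$y_num, max_k = max_orth,
                                  folds = cv_folds, improvement = auto_tol)
  n_orth <- as.integer(n_orth)
  fit <- opls_core(X, yc, n_orth)
  q2 <- cross_validate(X, xy$y_num, n_orth, folds = cv_folds)
  vip <- vip_from_fit(fit)
  names(vip) <- colnames(X)
  structure(c(fit,
              list(q2_cum = q2, vip = vip, x = X, y = xy$y_num,
                   y_mean = xy$y_mean, levels = xy$levels,
                   cv_folds = cv_folds, call = match.call())),
            class = "opls")
}

# normalize inputs: feature matrix + numeric response, 0/1 for two groups
opls_xy <- function(x, y) {
  if (inherits(x, "nmr_features")) {
    if (!x$zscored)
      warning("feature matrix is not z-scored; OPLS expects z-scores")
    x <- x$values
  }
  x <- as.matrix(x)
  levels <- NULL
  if (is.character(y) || is.factor(y)) {
    y <- factor(y)
    if (nlevels(y) != 2L) stop("y must have exactly 2 groups")
    levels <- levels(y)
    y <- as.numeric(y) - 1
  }
  y <- as.numeric(y)
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  ym <- mean(y)
  list(X = x, yc = y - ym, y_num = y, y_mean = ym, levels = levels)
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("y orthogonal to X (zero covariance weight)")
  v / n
}

# NIPALS O-PLS core on a centered response.  Returns predictive component,
# orthogonal components and cumulative R2Y.
opls_core <- function(X, yc, n_orth) {
  p <- ncol(X)
  rnk <- qr(X)$rank
  if (n_orth < 0) stop("n_orth must be >= 0")
  if (n_orth >= rnk)
    stop("n_orth (", n_orth, ") must be below the rank of X (", rnk, ")")
  Xd <- X
  W_o <- P_o <- matrix(0, p, 0)
  T_o <- matrix(0, nrow(X), 0)
  w <- unit(drop(crossprod(Xd, yc)))
  for (j in seq_len(n_orth)) {
    t <- drop(Xd %*% w)
    pl <- drop(crossprod(Xd, t)) / sum(t^2)
    wo <- pl - sum(w * pl) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-10)
      stop("no orthogonal variation left after ", j - 1L, " component(s)")
    wo <- wo / nwo
    to <- drop(Xd %*% wo)
    po <- drop(crossprod(Xd, to)) / sum(to^2)
    Xd <- Xd - tcrossprod(to, po)
    W_o <- cbind(W_o, wo); T_o <- cbind(T_o, to); P_o <- cbind(P_o, po)
    w <- unit(drop(crossprod(Xd, yc)))
  }
  t <- drop(Xd %*% w)
  pl <- drop(crossprod(Xd, t)) / sum(t^2)
  cc <- sum(yc * t) / sum(t^2)
  r2 <- 1 - sum((yc - cc * t)^2) / sum(yc^2)
  list(w = w, t_pred = t, p_pred = pl, c = cc,
       W_orth = W_o, T_orth = T_o, P_orth = P_o,
       n_orth = n_orth, r2y_cum = r2, yc = yc)
}

# remove orthogonal variation from new observations, then score
opls_filter <- function(fit, xnew) {
  xnew <- as.matrix(xnew)
  for (j in seq_len(fit$n_orth)) {
    to <- drop(xnew %*% fit$W_orth[, j])
    xnew <- xnew - tcrossprod(to, fit$P_orth[, j])
  }
  xnew
}

#' Cross-validated Q2 of an OPLS fit
#'
#' Stratified k-fold cross-validation with a deterministic round-robin fold
#' assignment (samples sorted within each class, dealt to folds in order).
#' Q2 = 1 - PRESS / SSY, where PRESS accumulates squared prediction errors
#' of held-out samples under models refit on the remaining folds, and SSY
#' is the total centered sum of squares of the response.  Negative values
#' indicate a model predicting worse than the mean.
#'
#' @param x Feature matrix (z-scored) or `nmr_features`.
#' @param y Response (binary labels or numeric).
#' @param n_orth Number of orthogonal components for each refit.
#' @param folds Number of folds (default 7; `folds = n` gives
#'   leave-one-out).
#' @return Q2, a scalar (at most 1, possibly negative).
#' @export
cross_validate <- function(x, y, n_orth = 0, folds = 7) {
  xy <- opls_xy(x, y)
  X <- xy$X; yn <- xy$y_num
  n <- nrow(X)
  folds <- min(folds, n)
  if (folds < 2L) stop("need at least 2 folds")
  # deterministic stratified round-robin: samples sorted within class,
  # classes concatenated, dealt cyclically to folds (folds = n gives LOO)
  fold_of <- integer(n)
  pos <- 0L
  for (g in sort(unique(yn))) {
    idx <- sort(which(yn == g))
    fold_of[idx] <- ((pos + seq_along(idx) - 1L) %% folds) + 1L
    pos <- pos + length(idx)
  }
  press <- 0
  for (f in seq_len(folds)) {
    test <- which(fold_of == f)
    if (!length(test)) next
    train <- setdiff(seq_len(n), test)
    ytr <- yn[train]
    if (length(unique(ytr)) < 2L && length(unique(yn)) == 2L)
      stop("fold ", f, " leaves a training set with a single class")
    fit <- opls_core(X[train, , drop = FALSE], ytr - mean(ytr), n_orth)
    Xf <- opls_filter(fit, X[test, , drop = FALSE])
    yhat <- drop(Xf %*% fit$w) * fit$c + mean(ytr)
    press <- press + sum((yn[test] - yhat)^2)
  }
  1 - press / sum((yn - mean(yn))^2)
}

#' Choose the number of orthogonal components automatically
#'
#' Greedy rule approximating the behaviour of automated chemometrics
#' software: starting from zero, an orthogonal component is added while it
#' improves the cross-validated Q2 by more than `improvement` (default
#' 0.01).  The result is always user-overridable in [opls()].
#'
#' @inheritParams cross_validate
#' @param max_k Maximum number of orthogonal components to consider.
#' @param improvement Minimum Q2 gain to accept one more component.
#' @return Integer number of orthogonal components (0..max_k).
#' @export
select_n_orthogonal <- function(x, y, max_k = 5, folds = 7,
                                improvement = 0.01) {
  xy <- opls_xy(x, y)
  rnk <- qr(xy$X)$rank
  best_k <- 0L
  best_q2 <- cross_validate(xy$X, xy$y_num, 0, folds)
  for (k in seq_len(max_k)) {
    if (k >= rnk) break
    q2 <- tryCatch(cross_validate(xy$X, xy$y_num, k, folds),
                   error = function(e) -Inf)
    if (q2 > best_q2 + improvement) {
      best_k <- k; best_q2 <- q2
    } else break
  }
  best_k
}

vip_from_fit <- function(fit) {
  # VIP_j = sqrt(p * sum_a SSY_a (w_aj / ||w_a||)^2 / sum_a SSY_a) over the
  # predictive and orthogonal components; components orthogonal to y have
  # SSY ~ 0 and contribute only residually.
  p <- length(fit$w)
  W <- cbind(fit$w, fit$W_orth)
  Tm <- cbind(fit$t_pred, fit$T_orth)
  ssy <- vapply(seq_len(ncol(Tm)), function(a) {
    ta <- Tm[, a]
    sum(fit$yc * ta)^2 / sum(ta^2)
  }, numeric(1))
  wn <- sweep(W, 2, sqrt(colSums(W^2)), `/`)
  sqrt(p * drop(wn^2 %*% ssy) / sum(ssy))
}

#' Variable importance in projection (VIP) scores
#'
#' Per-feature influence scores of an OPLS model, normalized so that the
#' mean squared VIP equals 1; features with VIP > 1 are conventionally
#' considered important.  The default sums Y-variance-weighted squared
#' weights over the predictive plus orthogonal components; the
#' `"predictive"` variant restricts to the predictive component.
#'
#' @param model A fitted [opls] model.
#' @param type `"total"` or `"predictive"`.
#' @return Named numeric vector of VIP scores (mean(VIP^2) = 1).
#' @export
vip <- function(model, type = c("total", "predictive")) {
  stopifnot(inherits(model, "opls"))
  type <- match.arg(type)
  if (type == "total") return(model$vip)
  p <- length(model$w)
  v <- sqrt(p) * abs(model$w)
  names(v) <- names(model$vip)
  v
}

#' Permutation validation of an OPLS model
#'
#' Refits the model under `n_perm` random permutations of the response,
#' records for each the absolute correlation between permuted and original
#' response together with the refitted R2Y and Q2, and reports the
#' y-intercepts of least-squares lines of R2 and Q2 against |correlation|
#' (the unpermuted model is included as the point at correlation 1).  A
#' valid model shows intercepts well below its own R2/Q2; in particular the
#' Q2 intercept is typically negative.
#'
#' @param model A fitted [opls] model.
#' @param n_perm Number of permutations (default 100).
#' @param seed Optional integer seed for the permutation draws.
#' @param n_orth `"inherit"` to reuse the model's number of orthogonal
#'   components for every refit, `"auto"` to rerun the selection rule per
#'   permutation, or an integer.
#' @return An object of class `opls_permutation`: list with `records`
#'   (data.frame `correlation`, `r2`, `q2`; first row is the unpermuted
#'   model), `r2_intercept`, `q2_intercept`, `n_perm`.
#' @export
permutation_test <- function(model, n_perm = 100, seed = NULL,
                             n_orth = "inherit") {
  stopifnot(inherits(model, "opls"))
  if (!is.null(seed)) set.seed(seed)
  X <- model$x; yn <- model$y
  fit_one <- function(yp) {
    k <- if (identical(n_orth, "inherit")) model$n_orth
         else if (identical(n_orth, "auto"))
           select_n_orthogonal(X, yp, folds = model$cv_folds)
         else as.integer(n_orth)
    fit <- opls_core(X, yp - mean(yp), k)
    c(r2 = fit$r2y_cum,
      q2 = cross_validate(X, yp, k, folds = model$cv_folds))
  }
  rec <- matrix(NA_real_, n_perm + 1L, 3L,
                dimnames = list(NULL, c("correlation", "r2", "q2")))
  rec[1L, ] <- c(1, model$r2y_cum, model$q2_cum)
  for (i in seq_len(n_perm)) {
    yp <- sample(yn)
    rec[i + 1L, ] <- c(abs(stats::cor(yp, yn)), fit_one(yp))
  }
  rec <- as.data.frame(rec)
  ic <- perm_intercepts(rec)
  structure(list(records = rec, r2_intercept = ic$r2_intercept,
                 q2_intercept = ic$q2_intercept, n_perm = n_perm),
            class = "opls_permutation")
}

# y-intercepts of the least-squares lines of R2 and Q2 against |corr|,
# including the unpermuted corr = 1 point.  A degenerate design (all
# correlations equal) falls back to the mean value.
perm_intercepts <- function(rec) {
  fit1 <- function(v) {
    if (diff(range(rec$correlation)) < 1e-12) return(mean(v))
    unname(stats::coef(stats::lm(v ~ rec$correlation))[1L])
  }
  list(r2_intercept = fit1(rec$r2), q2_intercept = fit1(rec$q2))
}

#' @export
print.opls_permutation <- function(x, ...) {
  cat(sprintf("OPLS permutation validation (%d permutations)\n", x$n_perm))
  cat(sprintf("  R2 y-intercept: %7.3f\n  Q2 y-intercept: %7.3f\n",
              x$r2_intercept, x$q2_intercept))
  invisible(x)
}

#' Hotelling's T2 confidence ellipse in score space
#'
#' Semi-axes on the two score axes are `s_i * sqrt(2 (n^2 - 1) /
#' (n (n - 2)) * F_level(2, n - 2))` with `s_i` the per-axis score SD, the
#' classical two-dimensional Hotelling region drawn on score plots to flag
#' outliers.
#'
#' @param t1,t2 Score vectors (e.g. predictive and first orthogonal).
#' @param level Confidence level in (0, 1), default 0.95.
#' @return A `score_ellipse`: list `center`, `semi_axes`, `level`, `n`.
#' @export
hotelling_ellipse <- function(t1, t2, level = 0.95) {
  n <- length(t1)
  if (length(t2) != n) stop("score vectors must have equal length")
  if (n < 3L) stop("Hotelling ellipse needs at least 3 samples")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  fac <- sqrt(2 * (n^2 - 1) / (n * (n - 2)) * stats::qf(level, 2, n - 2))
  structure(list(center = c(mean(t1), mean(t2)),
                 semi_axes = c(stats::sd(t1), stats::sd(t2)) * fac,
                 level = level, n = n),
            class = "score_ellipse")
}

# ---- standard model methods -------------------------------------------

#' @export
print.opls <- function(x, ...) {
  cat(sprintf("OPLS model: 1 predictive + %d orthogonal component(s)\n",
              x$n_orth))
  cat(sprintf("  n = %d samples, p = %d features\n",
              nrow(x$x), ncol(x$x)))
  cat(sprintf("  R2Y(cum) = %.3f   Q2(cum) = %.3f\n", x$r2y_cum, x$q2_cum))
  cat(sprintf("  features with VIP > 1: %d\n", sum(x$vip > 1)))
  invisible(x)
}

#' @export
summary.opls <- function(object, ...) {
  out <- list(n = nrow(object$x), p = ncol(object$x),
              n_orth = object$n_orth, r2y_cum = object$r2y_cum,
              q2_cum = object$q2_cum, n_vip_gt_1 = sum(object$vip > 1),
              levels = object$levels,
              vip_top = sort(object$vip, decreasing = TRUE)[
                seq_len(min(10, length(object$vip)))])
  class(out) <- "summary.opls"
  out
}

#' @export
print.summary.opls <- function(x, ...) {
  cat(sprintf("OPLS regression summary\n  samples: %d  features: %d\n", x$n, x$p))
  if (!is.null(x$levels))
    cat(sprintf("  groups: %s (0) vs %s (1)\n", x$levels[1], x$levels[2]))
  cat(sprintf("  orthogonal components: %d\n", x$n_orth))
  cat(sprintf("  R2Y(cum) = %.3f   Q2(cum) = %.3f\n", x$r2y_cum, x$q2_cum))
  cat(sprintf("  features with VIP > 1: %d\n", x$n_vip_gt_1))
  cat("  top VIP scores:\n")
  print(round(x$vip_top, 3))
  invisible(x)
}

#' Regression coefficients of an OPLS model
#'
#' The combined linear map from (orthogonal-filtered) predictors to the
#' response: prediction is `x B + mean(y)` with
#' `B = prod_j (I - w_oj p_oj') w c` applied in deflation order.
#'
#' @param object A fitted [opls] model.
#' @param ... Unused.
#' @return Named numeric vector of per-feature coefficients.
#' @export
coef.opls <- function(object, ...) {
  p <- length(object$w)
  B <- diag(p)
  for (j in seq_len(object$n_orth))
    B <- B %*% (diag(p) - tcrossprod(object$W_orth[, j], object$P_orth[, j]))
  b <- drop(B %*% object$w) * object$c
  names(b) <- colnames(object$x)
  b
}

#' Predict from an OPLS model
#'
#' New observations are filtered through the orthogonal components and
#' scored on the predictive component.  With `type = "class"` (binary
#' models) predictions are thresholded at the midpoint of the two encoded
#' group means.
#'
#' @param object A fitted [opls] model.
#' @param newdata Matrix (or `nmr_features`) on the same feature space,
#'   scaled like the training data.  Defaults to the training matrix.
#' @param type `"response"` (numeric) or `"class"` (group labels).
#' @param ... Unused.
#' @return Numeric predictions or a factor of group labels.
#' @export
predict.opls <- function(object, newdata = NULL,
                         type = c("response", "class"), ...) {
  type <- match.arg(type)
  x <- if (is.null(newdata)) object$x
       else if (inherits(newdata, "nmr_features")) newdata$values
       else as.matrix(newdata)
  if (ncol(x) != length(object$w))
    stop("newdata must have ", length(object$w), " features")
  xf <- opls_filter(object, x)
  yhat <- drop(xf %*% object$w) * object$c + object$y_mean
  if (type == "response") return(yhat)
  if (is.null(object$levels))
    stop("class predictions need a model fitted on group labels")
  factor(object$levels[(yhat > 0.5) + 1L], levels = object$levels)
}

#' @export
fitted.opls <- function(object, ...) predict.opls(object)

#' @export
residuals.opls <- function(object, ...) object$y - fitted.opls(object)

#' Score plot of an OPLS model
#'
#' Predictive score against the first orthogonal score (or sample index for
#' models without orthogonal components), with the Hotelling's T2 ellipse
#' at the requested level.
#'
#' @param x A fitted [opls] model.
#' @param level Hotelling confidence level.
#' @param ... Passed to [graphics::plot()].
#' @return The `score_ellipse`, invisibly.
#' @export
plot.opls <- function(x, level = 0.95, ...) {
  t1 <- x$t_pred
  t2 <- if (x$n_orth > 0) x$T_orth[, 1] else seq_along(t1)
  ell <- if (x$n_orth > 0) hotelling_ellipse(t1, t2, level) else NULL
  grp <- if (!is.null(x$levels)) x$levels[x$y + 1L] else rep("sample", length(t1))
  cols <- as.integer(factor(grp)) + 1L
  xlim <- range(t1); ylim <- range(t2)
  if (!is.null(ell)) {
    xlim <- range(xlim, ell$center[1] + c(-1, 1) * ell$semi_axes[1])
    ylim <- range(ylim, ell$center[2] + c(-1, 1) * ell$semi_axes[2])
  }
  graphics::plot(t1, t2, col = cols, pch = 19, xlim = xlim, ylim = ylim,
                 xlab = "t[1] (predictive)",
                 ylab = if (x$n_orth > 0) "t[o1] (orthogonal)" else "sample",
                 ...)
  if (!is.null(ell)) {
    th <- seq(0, 2 * pi, length.out = 200)
    graphics::lines(ell$center[1] + ell$semi_axes[1] * cos(th),
                    ell$center[2] + ell$semi_axes[2] * sin(th), lty = 2)
  }
  if (!is.null(x$levels))
    graphics::legend("topright", legend = x$levels, col = 2:3, pch = 19,
                     bty = "n")
  invisible(ell)
}

#' Machine-readable OPLS model summary
#'
#' @param model A fitted [opls] model.
#' @param permutation Optional [permutation_test()] result to embed.
#' @param path Optional path to write JSON to.
#' @return A list (written as JSON when `path` is given).
#' @export
opls_summary_json <- function(model, permutation = NULL, path = NULL) {
  out <- list(r2y_cum = model$r2y_cum, q2_cum = model$q2_cum,
              n_orth = model$n_orth,
              n_features_vip_gt_1 = sum(model$vip > 1))
  if (!is.null(permutation))
    out$permutation <- list(r2_intercept = permutation$r2_intercept,
                            q2_intercept = permutation$q2_intercept)
  if (model$n_orth > 0) {
    ell <- hotelling_ellipse(model$t_pred, model$T_orth[, 1])
    out$hotelling <- list(center = ell$center, semi_axes = ell$semi_axes,
                          level = ell$level)
  }
  if (!is.null(path))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  out
}
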