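test_that("with no orthogonal components the scores match minimal PLS1", {
  d <- rand_xy(1)
  m <- opls(d$X, d$y, n_orth = 0)
  expect_equal(m$t_pred, pls1_oracle_scores(d$X, d$y), tolerance = 1e-10)
})

test_that("a single feature equal to the centered response is fit perfectly", {
  y <- rep(c(0, 1), each = 4)
  X <- matrix(y - mean(y), ncol = 1)
  m <- opls(X, y, n_orth = 0, cv_folds = 4)
  expect_equal(m$r2y_cum, 1, tolerance = 1e-12)
  expect_equal(unname(m$vip), 1, tolerance = 1e-12)
})

test_that("orthogonal components strip y-orthogonal structure and lift Q2", {
  set.seed(33)
  n <- 20; p <- 30
  y <- rep(0:1, each = n / 2)
  conf <- rnorm(n)                    # structured factor orthogonal to y
  conf <- conf - mean(conf)
  conf <- conf - (y - mean(y)) * sum(conf * (y - mean(y))) / sum((y - mean(y))^2)
  X <- outer(y - mean(y), c(rep(1, 5), rep(0, p - 5))) +
       outer(conf, c(rep(0, p - 10), rep(2, 10))) +
       matrix(rnorm(n * p, 0, 0.3), n, p)
  X <- scale(X)
  q0 <- cross_validate(X, y, 0)
  q1 <- cross_validate(X, y, 1)
  expect_gte(q1, q0)
  m <- opls(X, y, n_orth = 1)
  # orthogonality invariants
  expect_equal(sum(m$w^2), 1, tolerance = 1e-9)
  expect_lt(abs(sum(m$w * m$W_orth[, 1])), 1e-8)
  expect_lt(abs(sum(m$t_pred * m$T_orth[, 1])) /
              (sqrt(sum(m$t_pred^2)) * sqrt(sum(m$T_orth[, 1]^2))), 1e-6)
})

test_that("cross-validation behaves like Q2 should", {
  # noiseless perfectly informative features at n = 14: near-perfect Q2
  y <- rep(0:1, each = 7)
  X <- scale(cbind(y, 2 * y))
  expect_gt(cross_validate(X, y, 0), 0.9)
  # useless models predict worse than the mean: median Q2 < 0
  q2s <- vapply(1:100, function(s) {
    set.seed(s)
    Xn <- scale(matrix(rnorm(12 * 6), 12, 6))
    cross_validate(Xn, sample(rep(0:1, 6)), 0)
  }, numeric(1))
  expect_lt(stats::median(q2s), 0)
})

test_that("7-fold on n = 7 equals brute-force leave-one-out PRESS", {
  set.seed(9)
  n <- 7
  y <- c(0, 1, 0, 1, 0, 1, 0)
  X <- scale(cbind(y + rnorm(n, 0, 0.5), matrix(rnorm(n * 3), n, 3)))
  q2 <- cross_validate(X, y, 0, folds = 7)
  press <- 0
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    ytr <- y[tr]
    w <- drop(crossprod(X[tr, ], ytr - mean(ytr)))
    w <- w / sqrt(sum(w^2))
    t <- drop(X[tr, ] %*% w)
    cc <- sum((ytr - mean(ytr)) * t) / sum(t^2)
    press <- press + (y[i] - (sum(X[i, ] * w) * cc + mean(ytr)))^2
  }
  expect_equal(q2, 1 - press / sum((y - mean(y))^2), tolerance = 1e-12)
})

test_that("VIP is normalized and symmetric, with the sqrt(p) limit", {
  # two exchangeable informative features get equal VIPs
  y <- rep(c(0, 1), each = 5)
  X <- cbind(y - mean(y), y - mean(y), matrix(0.5, 10, 2) * rep(c(-1, 1), 5))
  X <- scale(X)
  m <- opls(X, y, n_orth = 0)
  expect_equal(m$vip[[1]], m$vip[[2]], tolerance = 1e-9)
  expect_equal(mean(m$vip^2), 1, tolerance = 1e-9)
  # all signal in one feature, the rest exactly orthogonal to y: the
  # closed-form limit VIP -> sqrt(p) for the informative feature
  p <- 12
  yc <- y - mean(y)
  set.seed(14)
  noise <- matrix(rnorm(10 * (p - 1)), 10, p - 1)
  noise <- apply(noise, 2, function(v) {
    v <- v - mean(v)
    v <- v - yc * sum(v * yc) / sum(yc^2)
    v / sd(v)
  })
  m2 <- opls(cbind(yc / sd(yc), noise), y, n_orth = 0)
  expect_equal(max(m2$vip), sqrt(p), tolerance = 1e-9)
  expect_identical(which.max(m2$vip), 1L)
  # predictive-only variant agrees up to the near-zero orthogonal SSY
  d <- rand_xy(5, n = 16, p = 10)
  m3 <- opls(d$X, d$y, n_orth = 1)
  expect_equal(mean(vip(m3)^2), 1, tolerance = 1e-9)
  expect_equal(mean(vip(m3, "predictive")^2), 1, tolerance = 1e-9)
})

test_that("R2Y is non-decreasing in the number of orthogonal components", {
  for (s in 1:5) {
    d <- rand_xy(s, n = 14, p = 10, signal = 0.8)
    r2 <- vapply(0:3, function(k) opls(d$X, d$y, n_orth = k)$r2y_cum,
                 numeric(1))
    expect_true(all(diff(r2) >= -1e-10))
  }
})

test_that("automatic selection returns 0 for pure noise and caps at max_k", {
  ks <- vapply(1:20, function(s) {
    set.seed(s)
    X <- scale(matrix(rnorm(14 * 10), 14, 10))
    select_n_orthogonal(X, rep(0:1, 7))
  }, numeric(1))
  expect_gte(mean(ks == 0), 0.8)  # no structured variation to strip
  d <- rand_xy(2)
  expect_identical(select_n_orthogonal(d$X, d$y, max_k = 0), 0L)
})

test_that("automatic selection recovers one injected orthogonal factor", {
  hits <- vapply(1:50, function(s) {
    set.seed(s)
    n <- 18; p <- 24
    y <- rep(0:1, each = n / 2)
    yc <- y - mean(y)
    conf <- rnorm(n)                          # strong factor, exactly
    conf <- conf - mean(conf)                 # orthogonal to the response
    conf <- conf - yc * sum(conf * yc) / sum(yc^2)
    X <- outer(yc, c(rep(3, 6), rep(0, p - 6))) +
         outer(conf * 4, c(rep(0, 6), rep(1, p - 6))) +
         matrix(rnorm(n * p, 0, 0.05), n, p)
    select_n_orthogonal(scale(X), y, max_k = 3)
  }, numeric(1))
  expect_gte(mean(hits == 1), 0.9)
})

test_that("permutation report includes the unpermuted model and sane intercepts", {
  d <- rand_xy(3, n = 16, p = 12, signal = 2)
  m <- opls(d$X, d$y, n_orth = 0)
  pr <- permutation_test(m, n_perm = 30, seed = 1)
  expect_identical(nrow(pr$records), 31L)
  expect_equal(pr$records$correlation[1], 1)
  expect_equal(pr$records$r2[1], m$r2y_cum)
  expect_equal(pr$records$q2[1], m$q2_cum)
  # structured data: intercept below the model Q2
  expect_lt(pr$q2_intercept, m$q2_cum)
})

test_that("a flat R2 cloud yields an intercept equal to that value", {
  rec <- data.frame(correlation = c(1, 0.2, 0.5, 0.1, 0.7),
                    r2 = rep(0.83, 5),
                    q2 = c(0.5, -0.2, 0.1, -0.4, 0.3))
  ic <- oplsnmr:::perm_intercepts(rec)
  expect_equal(ic$r2_intercept, 0.83, tolerance = 1e-12)
  # and against an independent least-squares computation for q2
  b <- cov(rec$correlation, rec$q2) / var(rec$correlation)
  expect_equal(ic$q2_intercept, mean(rec$q2) - b * mean(rec$correlation),
               tolerance = 1e-10)
})

test_that("degenerate responses are rejected", {
  X <- scale(matrix(rnorm(20), 10, 2))
  expect_error(opls(X, rep(0, 10)), "orthogonal to X|2 groups")
  expect_error(opls(X[1:3, ], rep(0:1, length.out = 3)), "4 samples")
  d <- rand_xy(1, n = 8, p = 3)
  expect_error(opls(d$X, d$y, n_orth = 3), "rank")
})

test_that("Hotelling ellipse matches its closed form and scales correctly", {
  set.seed(10)
  t1 <- rnorm(10); t2 <- rnorm(10)
  e <- hotelling_ellipse(t1, t2, 0.95)
  # F_{0.95}(2, 8) = 4.45897 from standard tables
  fac <- sqrt(2 * (100 - 1) / (10 * 8) * 4.45897)
  expect_equal(e$semi_axes, c(sd(t1), sd(t2)) * fac, tolerance = 1e-4)
  # homogeneity: doubling the scores doubles the semi-axes
  e2 <- hotelling_ellipse(2 * t1, 2 * t2, 0.95)
  expect_equal(e2$semi_axes, 2 * e$semi_axes, tolerance = 1e-12)
  # equal variances give a circle
  e3 <- hotelling_ellipse(t1, rev(t1), 0.95)
  expect_equal(e3$semi_axes[1], e3$semi_axes[2], tolerance = 1e-12)
  expect_error(hotelling_ellipse(1:2, 1:2), "at least 3")
})

test_that("model methods are mutually consistent", {
  d <- rand_xy(6, n = 16, p = 10, signal = 1.5)
  m <- opls(d$X, factor(ifelse(d$y == 1, "case", "ctrl"),
                        levels = c("ctrl", "case")), n_orth = 1)
  # coef reproduces predict on the training data
  yhat <- drop(d$X %*% coef(m)) + m$y_mean
  expect_equal(yhat, unname(predict(m)), tolerance = 1e-10)
  expect_equal(unname(residuals(m)), unname(m$y - fitted(m)), tolerance = 1e-12)
  cls <- predict(m, type = "class")
  expect_s3_class(cls, "factor")
  expect_identical(levels(cls), c("ctrl", "case"))
  expect_gt(mean(cls == c("ctrl", "case")[d$y + 1]), 0.8)
  s <- summary(m)
  expect_identical(s$n_orth, 1L)
  expect_output(print(s), "R2Y")
  # plotting runs headless and returns the ellipse
  pdf(NULL)
  on.exit(dev.off())
  ell <- plot(m)
  expect_s3_class(ell, "score_ellipse")
})
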