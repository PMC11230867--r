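make_singlet_set <- function(centers, heights, n = 1, ppm_n = 4096,
                             noise = 0, seed = 1, groups = NULL) {
  grid <- seq(12, 0, length.out = ppm_n)
  set.seed(seed)
  mats <- t(vapply(seq_len(n), function(i) {
    y <- numeric(ppm_n)
    for (k in seq_along(centers))
      y <- y + heights[k] * 0.0025^2 / ((grid - centers[k])^2 + 0.0025^2)
    y + if (noise > 0) rnorm(ppm_n, 0, noise) else 0
  }, numeric(ppm_n)))
  set_from_matrix(grid, mats, groups)
}

test_that("phase correction is the identity on real spectra", {
  s <- set_spectrum(make_singlet_set(c(3, 7), c(1, 2)), 1)
  expect_identical(phase_correct(s)$intensity, s$intensity)
})

test_that("phase correction recovers a known zeroth-order error", {
  cfg <- simulation_config(grid = c(0, 12, 8192), noise_sd = 0.002,
                           contaminants_on = FALSE, phase_error_deg = 1)
  set.seed(42)
  s <- simulate_spectrum(toy_library(), NULL, cfg)
  # overwrite the random phase with a controlled 30 degree rotation
  z0 <- s$intensity * exp(-1i * s$applied_phase_rad)
  s$intensity <- z0 * exp(1i * 30 * pi / 180)
  out <- phase_correct(s, first_order = FALSE)
  rec <- attr(out, "phase")[1] %% (2 * pi)
  err <- min(abs(rec - 30 * pi / 180), abs(rec - 30 * pi / 180 - 2 * pi))
  expect_lt(err * 180 / pi, 2)
  expect_false(is.complex(out$intensity))
})

test_that("phase objective is nearly flat on pure complex noise", {
  set.seed(7)
  n <- 1500000
  z <- complex(real = rnorm(n), imaginary = rnorm(n))
  obj <- vapply(seq(0, 2 * pi, length.out = 37), function(phi)
    sum(pmin(Re(z * exp(-1i * phi)), 0)^2), numeric(1))
  expect_lt((max(obj) - min(obj)) / mean(obj), 0.01)
  # and the optimizer tolerates it without error
  s <- nmr_spectrum(seq(12, 0, length.out = 2048), z[1:2048], "noise")
  expect_s3_class(phase_correct(s), "nmr_spectrum")
})

test_that("reference alignment shifts the tallest window maximum onto 6.5", {
  grid <- seq(12, 0, length.out = 4096)
  target_pt <- grid[which.min(abs(grid - 6.5))]
  # already aligned: zero shift
  s0 <- set_spectrum(make_singlet_set(target_pt, 1), 1)
  expect_identical(attr(align_to_reference(s0), "shift"), 0)
  # off by +0.03
  s1 <- set_spectrum(make_singlet_set(6.53, 1), 1)
  a1 <- align_to_reference(s1)
  expect_equal(a1$ppm[which.max(a1$intensity)], target_pt)
  # no local maximum in the window
  flat <- nmr_spectrum(grid, seq_along(grid) * 1e-4, "flat")
  expect_error(align_to_reference(flat), "reference peak not found")
})

test_that("alignment corrects jitter to within one grid step (Monte Carlo)", {
  grid <- seq(12, 0, length.out = 4096)
  step <- 12 / 4095
  target_pt <- grid[which.min(abs(grid - 6.5))]
  set.seed(99)
  jit <- rnorm(50, 0, 0.02)
  for (j in jit) {
    s <- set_spectrum(make_singlet_set(6.5 + j, 1, noise = 0.002,
                                       seed = sample.int(1e6, 1)), 1)
    a <- align_to_reference(s)
    peak <- a$ppm[which.max(a$intensity)]
    expect_lte(abs(peak - 6.5), step + 1e-12)
  }
})

test_that("exclusion windows drop exactly the covered grid points", {
  grid <- seq(12, 0, by = -0.01)
  set <- set_from_matrix(grid, matrix(1, 2, length(grid)))
  w <- data.frame(lo = 4.70, hi = 5.10, label = "water")
  out <- exclude_regions(set, w)
  expect_identical(length(set$ppm) - length(out$ppm), 41L)
  # empty window list is the identity
  expect_identical(exclude_regions(set, w[0, ]), set)
  # overlapping windows match the brute-force per-point membership oracle
  w2 <- data.frame(lo = c(2, 2.5, 8), hi = c(3, 3.2, 8.05),
                   label = c("a", "b", "c"))
  out2 <- exclude_regions(set, w2)
  oracle <- vapply(grid, function(p)
    !any(p >= w2$lo & p <= w2$hi), logical(1))
  expect_identical(out2$ppm, grid[oracle])
  expect_error(exclude_regions(set, data.frame(lo = 0, hi = 12, label = "all")),
               "every spectral point")
})

test_that("total-area normalization sums to one and is scale invariant", {
  grid <- c(3, 2, 1)
  set <- set_from_matrix(grid, rbind(c(2, 3, 5), c(4, 6, 10)))
  out <- normalize_total_area(set)
  expect_equal(unname(out$intensity[1, ]), c(0.2, 0.3, 0.5))
  # doubling raw intensities changes nothing; renormalizing is idempotent
  expect_equal(out$intensity[1, ], out$intensity[2, ])
  expect_equal(normalize_total_area(out)$intensity, out$intensity)
  bad <- set_from_matrix(grid, rbind(c(0, 0, 0), c(1, 1, 1)))
  expect_error(normalize_total_area(bad), "s1")
})

test_that("noise threshold discards on a strict majority below 5 sigma", {
  # grid with a noise region (0..0.2) and two signal columns
  grid <- c(seq(12, 0.21, length.out = 30), seq(0.2, 0, length.out = 50))
  n <- 10
  set.seed(12)
  mat <- matrix(0, n, length(grid))
  mat[, 31:80] <- rnorm(n * 50, 0, 0.01)       # noise window
  noise <- estimate_noise(set_from_matrix(grid, mat))
  expect_equal(noise$threshold, 5 * noise$sigma)
  # column 1: 6 of 10 samples below their threshold -> discarded
  mat[, 1] <- ifelse(seq_len(n) <= 6, 0, 1)
  # column 2: 5 of 10 below -> retained
  mat[, 2] <- ifelse(seq_len(n) <= 5, 0, 1)
  mat[, 3:30] <- 1                              # comfortably above
  set <- set_from_matrix(grid, mat)
  out <- threshold_filter(set)
  expect_false(grid[1] %in% out$ppm)
  expect_true(grid[2] %in% out$ppm)
  # retained values are unmodified
  expect_equal(unname(out$intensity[, match(grid[2], out$ppm)]), mat[, 2])
})

test_that("zero noise level discards nothing (boundary case)", {
  grid <- c(seq(12, 0.21, length.out = 10), seq(0.2, 0, length.out = 10))
  mat <- matrix(0, 4, 20)
  mat[, 1:10] <- rep(c(0, 0.5), each = 2)  # half the samples at exactly 0
  out <- threshold_filter(set_from_matrix(grid, mat))
  expect_identical(out$ppm, grid)  # nothing is strictly below 0
})

test_that("threshold filtering matches a brute-force recount on a cohort", {
  co <- simulate_cohort(tiny_config(seed = 21))
  set <- normalize_total_area(exclude_regions(co$set))
  noise <- estimate_noise(set)
  out <- threshold_filter(set, noise)
  below <- sweep(set$intensity, 1, noise$threshold, `<`)
  keep_oracle <- vapply(seq_along(set$ppm), function(j)
    sum(below[, j]) <= nrow(below) / 2, logical(1))
  expect_identical(out$ppm, set$ppm[keep_oracle])
  expect_true(all(out$ppm %in% set$ppm))
  expect_lte(length(out$ppm), length(set$ppm))
})

test_that("peak picking finds isolated Lorentzians and fails on ramps", {
  one <- make_singlet_set(5.005, 2, ppm_n = 2048)
  f1 <- pick_peaks(one)
  expect_identical(ncol(f1$values), 1L)
  grid <- one$ppm
  expect_equal(f1$feature_ppm, grid[which.min(abs(grid - 5.005))])
  two <- make_singlet_set(c(3, 8), c(1, 1), ppm_n = 2048)
  expect_identical(ncol(pick_peaks(two)$values), 2L)
  ramp <- set_from_matrix(grid, matrix(seq_along(grid), 1, byrow = TRUE))
  expect_error(pick_peaks(ramp), "no peaks")
})

test_that("plateaus resolve to their lowest-ppm point", {
  grid <- seq(10, 1, by = -1)
  y <- c(0, 1, 2, 2, 2, 1, 0, 3, 1, 0)
  f <- pick_peaks(set_from_matrix(grid, matrix(y, 1, byrow = TRUE)))
  # plateau 2,2,2 at ppm 8,7,6 -> lowest ppm 6; singleton max 3 at ppm 3
  expect_equal(sort(f$feature_ppm), c(3, 6))
})

test_that("z-scoring matches the n-1 convention and is idempotent", {
  fm <- structure(list(values = cbind(a = c(1, 2, 3), b = c(5, 5, 5)),
                       feature_ppm = c(1.0, 2.0),
                       sample_id = c("s1", "s2", "s3"),
                       group = rep("g", 3), zscored = FALSE),
                  class = "nmr_features")
  expect_warning(z <- zscore_features(fm), "constant")
  expect_equal(unname(z$values[, 1]), c(-1, 0, 1))
  expect_identical(ncol(z$values), 1L)          # constant column dropped
  expect_equal(zscore_features(z)$values, z$values)  # idempotent
  expect_error(zscore_features(fm, c("s1", "s2")), "3 samples")
})

test_that("annotation maps features to nearby library lines", {
  lib <- toy_library()
  fm <- structure(list(values = matrix(0, 3, 3),
                       feature_ppm = c(2.0, 7.55, 9.0),
                       sample_id = paste0("s", 1:3),
                       group = rep("g", 3), zscored = FALSE),
                  class = "nmr_features")
  ann <- annotate_features(fm, lib, tolerance = 0.01)
  expect_identical(ann$metabolite, c("alpha", "unassigned", "gamma"))
  expect_identical(ann$distance[1], 0)
  expect_equal(ann$distance[2], 0.05)
})

test_that("most features of a simulated cohort annotate correctly", {
  co <- simulate_cohort(simulation_config(seed = 31))
  pp <- preprocess_spectra(co$set)
  ann <- annotate_features(pp$features)
  # restrict to features near well-separated singlets of the library
  clean <- c(succinate = 2.41, "N,N-dimethylglycine" = 2.93,
             formate = 8.46, acetate = 1.92, creatine = 3.03)
  hits <- vapply(names(clean), function(m) {
    i <- which(abs(ann$feature_ppm - clean[[m]]) < 0.005)
    length(i) > 0 && any(ann$metabolite[i] == m)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # and globally, the assigned fraction among strong features is sensible
  expect_gt(sum(ann$metabolite != "unassigned"), 20)
})

test_that("normalization happens after exclusion, not before", {
  co <- simulate_cohort(tiny_config(seed = 41))
  aligned <- nmr_spectrum_set(lapply(seq_len(27), function(i)
    align_to_reference(set_spectrum(co$set, i))))
  pp <- preprocess_spectra(co$set)
  right <- normalize_total_area(exclude_regions(aligned))
  wrong <- exclude_regions(normalize_total_area(aligned))
  # retained intensities in the pipeline output equal the exclude-first
  # values at the surviving columns, and differ from normalize-first
  idx_r <- match(pp$set$ppm, right$ppm)
  expect_equal(pp$set$intensity, right$intensity[, idx_r],
               tolerance = 1e-12)
  expect_gt(max(abs(right$intensity - wrong$intensity)), 1e-6)
  expect_equal(unname(rowSums(right$intensity)), rep(1, 27), tolerance = 1e-9)
})
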