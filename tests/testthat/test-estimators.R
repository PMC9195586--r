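test_that("normalization recovers the simulator's unit-amplitude intensities", {
  cfg <- cfg_bimodal()
  grid <- default_grid(cfg, n = 301)
  sp <- simulate_spectrum(cfg, 0.17, grid = grid, amplitude = 5.3)
  ns <- normalize_spectrum(sp, cfg)
  expect_equal(ns$amplitude, 5.3, tolerance = 1e-9)
  x <- grid - cfg$lambda0
  expect_equal(ns$y, (1 - cos(cfg$k * x + 0.17)) * exp(-ns$u^2),
               tolerance = 1e-6)
  expect_error(normalize_spectrum(spectrum(1:5, rep(0, 5)), cfg), "zero")
})

test_that("source profile passes through as the envelope weight", {
  cfg <- cfg_coupling(0.07)
  grid <- protocol_grid(cfg)
  env <- .source_envelope(protocol_source_shape(cfg), cfg, grid)
  src <- spectrum(grid, 2.5 * env)
  sp <- simulate_spectrum(cfg, 0.1, grid = grid, envelope = env)
  ns <- normalize_spectrum(sp, cfg, source = src)
  expect_equal(ns$w, env, tolerance = 1e-9)
})

test_that("method A: symmetric spectra give zero shift, response slope
           matches a finite-difference oracle", {
  cfg <- cfg_bimodal()
  grid <- default_grid(cfg, n = 801)
  sp0 <- simulate_spectrum(cfg, 0, grid = grid)
  expect_equal(method_a(sp0, cfg)$statistic, 0, tolerance = 1e-10)
  # two equal delta-like peaks
  twin <- spectrum(c(838, 839, 840, 841, 842), c(0, 5, 0, 5, 0))
  expect_equal(method_a(twin, cfg, reference_centroid = 840)$statistic, 0)
  # linear response at small delta vs central finite difference
  h <- 1e-4
  cent <- function(d) method_a(simulate_spectrum(cfg, d, grid = grid),
                               cfg)$statistic
  slope_fd <- (cent(h) - cent(-h)) / (2 * h)
  d <- 5e-3
  expect_equal(cent(d) / d, slope_fd, tolerance = 1e-3)
  expect_error(method_a(spectrum(1:3, c(0, 0, 0)), cfg), "zero")
})

test_that("method B equals the brute-force weighted sums and limits", {
  cfg <- cfg_coupling(0.3)
  grid <- default_grid(cfg, n = 501)
  sp <- simulate_spectrum(cfg, 0.05, grid = grid)
  stat <- method_b(sp, cfg)$statistic
  u <- (grid - cfg$lambda0) / cfg$sigma_lambda
  w <- exp(-u^2)
  expect_equal(stat, sum(w * u * sp$intensities) / sum(w * sp$intensities),
               tolerance = 1e-12)
  # dark-fringe symmetric spectrum: odd integrand sums to zero
  sp0 <- simulate_spectrum(cfg, 0, grid = default_grid(cfg, n = 501))
  expect_equal(method_b(sp0, cfg)$statistic, 0, tolerance = 1e-10)
  # flat-weight limit reduces to the unweighted centroid in u units
  cfg_wide <- optical_config(cfg$alpha, cfg$beta, k = cfg$k,
                             lambda0 = cfg$lambda0,
                             sigma_lambda = 1e6)
  stat_wide <- method_b(sp, cfg_wide)$statistic
  centroid_u <- (method_a(sp, cfg)$statistic) / cfg_wide$sigma_lambda
  expect_equal(stat_wide, centroid_u, tolerance = 1e-9)
})

test_that("skew-Gaussian fit: symmetry, parameter recovery, degeneracy", {
  cfg <- cfg_bimodal()
  grid <- default_grid(cfg, n = 801)
  x <- grid - 840
  sym <- spectrum(grid, 3 * exp(-x^2 / SIGMA40^2))
  fit <- fit_skew_gaussian(sym)
  expect_true(fit$converged)
  expect_equal(fit$sigma_left, fit$sigma_right, tolerance = 1e-6)
  expect_equal(fit$sigma_left, SIGMA40, tolerance = 1e-3)
  expect_equal(fit$center, 840, tolerance = 1e-6)

  s1 <- 0.8 * SIGMA40; s2 <- 1.1 * SIGMA40
  skw <- spectrum(grid, exp(-x^2 / ifelse(x < 0, s1, s2)^2))
  fit2 <- fit_skew_gaussian(skw)
  expect_true(fit2$converged)
  expect_equal(fit2$sigma_left, s1, tolerance = 0.01)
  expect_equal(fit2$sigma_right, s2, tolerance = 0.01)

  tiny <- fit_skew_gaussian(spectrum(1:3, c(1, 2, 1)))
  expect_false(tiny$converged)
})

test_that("method C reduces to B for a symmetric fit and matches direct sums", {
  cfg <- cfg_coupling(0.3)
  grid <- default_grid(cfg, n = 501)
  x <- grid - cfg$lambda0
  sym_fit <- fit_skew_gaussian(spectrum(grid, exp(-x^2 / SIGMA40^2)))
  sp <- simulate_spectrum(cfg, 0.08, grid = grid)
  expect_equal(method_c(sp, cfg, sym_fit)$statistic,
               method_b(sp, cfg)$statistic, tolerance = 1e-6)
  # skewed weights against a direct summation oracle
  shape <- protocol_source_shape(cfg)
  env <- .source_envelope(shape, cfg, grid)
  spk <- simulate_spectrum(cfg, 0, grid = grid, envelope = env)
  fit <- fit_skew_gaussian(spectrum(grid, env))
  st <- method_c(spk, cfg, fit)$statistic
  xs <- grid - fit$center
  s <- ifelse(xs < 0, fit$sigma_left, fit$sigma_right)
  w <- exp(-xs^2 / s^2)
  u <- x / cfg$sigma_lambda
  expect_equal(st, sum(w * u * spk$intensities) / sum(w * spk$intensities),
               tolerance = 1e-12)
  bad <- fit; bad$converged <- FALSE
  expect_error(method_c(sp, cfg, bad), "converge")
})

test_that("method D: ideal Gaussian source equals B, flat source equals A,
           noisy source matches the direct sum", {
  cfg <- cfg_coupling(0.3)
  grid <- default_grid(cfg, n = 501)
  x <- grid - cfg$lambda0
  sp <- simulate_spectrum(cfg, 0.12, grid = grid)
  gauss_src <- spectrum(grid, 4 * exp(-x^2 / cfg$sigma_lambda^2))
  expect_equal(method_d(sp, cfg, gauss_src)$statistic,
               method_b(sp, cfg)$statistic, tolerance = 1e-9)
  flat_src <- spectrum(grid, rep(2, length(grid)))
  expect_equal(method_d(sp, cfg, flat_src)$statistic,
               method_a(sp, cfg)$statistic / cfg$sigma_lambda,
               tolerance = 1e-9)
  set.seed(3)
  noisy <- spectrum(grid, pmax(exp(-x^2 / SIGMA40^2) +
                                 rnorm(length(grid), 0, 0.01), 0))
  w <- noisy$intensities / max(noisy$intensities)
  u <- x / cfg$sigma_lambda
  expect_equal(method_d(sp, cfg, noisy)$statistic,
               sum(w * u * sp$intensities) / sum(w * sp$intensities),
               tolerance = 1e-12)
  other <- spectrum(grid + 1, gauss_src$intensities)
  expect_error(method_d(sp, cfg, other), "grid")
})

test_that("ML estimate is exact on noiseless model spectra", {
  for (ks in c(pi, 0.5, 0.07)) {
    cfg <- cfg_coupling(ks)
    for (d in c(-0.8, -0.1, 0.05, 0.3, 1.2)) {
      est <- ml_estimate(nspec_at(cfg, d), cfg, bracket = c(-1.45, 1.45))
      expect_equal(est$delta_hat, d, tolerance = 1e-8)
    }
  }
})

test_that("ML root coincides with the dense-grid argmin on noisy spectra", {
  cfg <- cfg_bimodal()
  grid <- default_grid(cfg, n = 257)
  set.seed(11)
  for (i in 1:20) {
    d <- runif(1, -1, 1)
    sp <- simulate_spectrum(cfg, d, grid = grid)
    noisy <- spectrum(grid, pmax(sp$intensities +
                                   rnorm(length(grid), 0, 5e-3), 0))
    ns <- normalize_spectrum(noisy, cfg)
    est <- ml_estimate(ns, cfg, bracket = c(-1.4, 1.4))
    ora <- oracle_grid_argmin(ns, cfg, c(-1.4, 1.4), n_grid = 4001)
    expect_lt(abs(est$delta_hat - ora), 2 * 2.8 / 4000)
    # the root is a descent-to-ascent stationary point of the objective
    h <- 1e-5
    expect_lt(ls_objective(ns, cfg, est$delta_hat)[1],
              min(ls_objective(ns, cfg, est$delta_hat + c(-h, h))))
  }
})

test_that("ML errors when the bracket excludes every objective minimum", {
  cfg <- cfg_coupling(0.5)
  ns <- nspec_at(cfg, 0.05)
  expect_error(ml_estimate(ns, cfg, bracket = c(0.7, 1.2)),
               class = "wmchar_no_root")
  expect_error(ml_estimate(ns, cfg, bracket = c(-4, 4)), "bracket")
})

test_that("classical estimate inverts the intensity ratio", {
  u <- seq(-3, 3, length.out = 301)
  for (d in c(0.2, 0.9, 2.5)) {
    ns <- normalized_spectrum(u, (1 - cos(d)) * exp(-u^2))
    expect_equal(classical_estimate(ns)$delta_hat, d, tolerance = 1e-12)
  }
  dark <- normalized_spectrum(u, rep(0, length(u)))
  expect_equal(classical_estimate(dark)$delta_hat, 0)
  hot <- normalized_spectrum(u, 3 * exp(-u^2))
  expect_error(classical_estimate(hot), class = "wmchar_out_of_model")
})

test_that("classical estimate recovers a large phase at weak coupling", {
  cfg <- cfg_coupling(0.01)
  est <- classical_estimate(nspec_at(cfg, 1.0))
  expect_equal(est$delta_hat, 1.0, tolerance = 1e-3)
})

test_that("transition equation: zero at dark fringe, round trip in its
           premise regime, classical limit", {
  cfg0 <- cfg_coupling(0.002)
  u <- seq(-3, 3, length.out = 301)
  ns0 <- normalized_spectrum(u, rep(0, length(u)),
                             sigma_lambda = cfg0$sigma_lambda)
  expect_equal(method_e(ns0, cfg0)$delta_hat, 0)
  # round trip where the coupling phase is small across the band
  for (d in c(0.01, 0.05, 0.1, 0.3, -0.05, -0.3)) {
    est <- method_e(nspec_at(cfg0, d), cfg0)
    expect_equal(est$delta_hat, d, tolerance = 0.01)
    expect_equal(sign(est$delta_hat), sign(d))
  }
  # convergence to the classical inversion as coupling vanishes
  gap <- vapply(c(0.1, 0.01, 0.001), function(ks) {
    cfg <- cfg_coupling(ks)
    ns <- nspec_at(cfg, 0.4)
    abs(method_e(ns, cfg)$delta_hat - classical_estimate(ns)$delta_hat)
  }, numeric(1))
  expect_true(all(diff(gap) < 0))
  expect_lt(gap[3], 1e-3)
})

test_that("transition equation reports its root set when none is admissible", {
  cfg <- cfg_coupling(0.1)
  u <- seq(-3, 3, length.out = 201)
  ns <- normalized_spectrum(u, 1.5 * exp(-u^2),
                            sigma_lambda = cfg$sigma_lambda)
  err <- tryCatch(method_e(ns, cfg), error = function(e) e)
  expect_s3_class(err, "wmchar_no_root")
  expect_length(err$diagnostics$roots, 4)
})

test_that("all estimators are invariant to overall intensity rescaling", {
  cfg <- cfg_coupling(0.07)
  grid <- protocol_grid(cfg)
  shape <- protocol_source_shape(cfg)
  env <- .source_envelope(shape, cfg, grid)
  src <- spectrum(grid, env)
  fit <- fit_skew_gaussian(src)
  sp1 <- simulate_spectrum(cfg, 0.15, grid = grid, envelope = env)
  sp2 <- spectrum(grid, 37.1 * sp1$intensities)
  aux <- list(source = src, fit = fit)
  for (m in c("A", "B", "C", "D", "E", "classical", "ml")) {
    s1 <- estimate_phase(sp1, m, cfg, aux)$statistic
    s2 <- estimate_phase(sp2, m, cfg, aux)$statistic
    expect_equal(s1, s2, tolerance = 1e-8)
  }
})
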