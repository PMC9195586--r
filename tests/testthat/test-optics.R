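test_that("optical_config validates and maps FWHM to the envelope scale", {
  cfg <- optical_config(0.3, 0.2, k = 0.1, fwhm = 40)
  expect_equal(cfg$sigma_lambda, 40 / (2 * sqrt(log(2))))
  expect_equal(cfg$fwhm, 2 * sqrt(log(2)) * cfg$sigma_lambda)
  lit <- optical_config(0.3, 0.2, k = 0.1, fwhm = 40,
                        sigma_convention = "literal")
  expect_equal(lit$sigma_lambda, 40)
  expect_error(optical_config(0.3, 0.2, k = -1), "positive")
  expect_error(optical_config(0.3, 0.2, k = 0.1, fwhm = 0), "positive")
})

test_that("weak value matches the closed form and the inner-product oracle", {
  cfg <- optical_config(0.6, 0.5, k = 0.1)
  wv <- weak_value(cfg, 0)
  expect_equal(Re(wv), sin(1.1) / sin(0.1), tolerance = 1e-12)
  expect_equal(Im(wv), 0, tolerance = 1e-14)

  # matched angles, quarter-pi phase: compare against brute force
  cfg2 <- optical_config(0.4, 0.4, k = 0.1)
  wv2 <- weak_value(cfg2, pi / 4)
  expect_true(is.finite(Re(wv2)) && is.finite(Im(wv2)))
  expect_equal(wv2, oracle_weak_moment(0.4, 0.4, pi / 4, 1),
               tolerance = 1e-12)

  set.seed(42)
  for (i in 1:500) {
    a <- runif(1, -1.2, 1.2); b <- runif(1, -1.2, 1.2)
    d <- runif(1, -3, 3)
    denom <- sin(a + b)^2 * sin(d)^2 + sin(a - b)^2 * cos(d)^2
    if (denom < 1e-4) next
    cfg_i <- optical_config(a, b, k = 0.1)
    expect_equal(weak_value(cfg_i, d), oracle_weak_moment(a, b, d, 1),
                 tolerance = 1e-10)
  }
})

test_that("near-orthogonal selection amplifies; orthogonal selection errors", {
  cfg <- optical_config(0.3, 0.3 + 1e-9, k = 0.1)
  expect_gt(Mod(weak_value(cfg, 1e-9)), 1e6)
  cfg_orth <- optical_config(0.3, 0.3, k = 0.1)
  expect_error(weak_value(cfg_orth, 0), "degenerate")
  expect_error(weak_moment(cfg_orth, 0, 2), "degenerate")
})

test_that("weak moments alternate: 1 for even n, the weak value for odd n", {
  set.seed(7)
  for (i in 1:50) {
    a <- runif(1, 0.1, 1); b <- runif(1, 0.1, 1); d <- runif(1, -2, 2)
    denom <- sin(a + b)^2 * sin(d)^2 + sin(a - b)^2 * cos(d)^2
    if (denom < 1e-4) next
    cfg <- optical_config(a, b, k = 0.1)
    expect_identical(weak_moment(cfg, d, 2), 1 + 0i)
    expect_identical(weak_moment(cfg, d, 4), 1 + 0i)
    expect_identical(weak_moment(cfg, d, 1), weak_value(cfg, d))
    expect_identical(weak_moment(cfg, d, 3), weak_value(cfg, d))
    # and against the direct matrix-power oracle
    expect_equal(weak_moment(cfg, d, 6), oracle_weak_moment(a, b, d, 6),
                 tolerance = 1e-10)
    expect_equal(weak_moment(cfg, d, 5), oracle_weak_moment(a, b, d, 5),
                 tolerance = 1e-10)
  }
})

test_that("simulated dark-fringe spectrum vanishes at center and is even", {
  cfg <- cfg_bimodal()
  grid <- default_grid(cfg, n = 401)
  sp <- simulate_spectrum(cfg, 0, grid = grid)
  expect_equal(sp$intensities[201], 0, tolerance = 1e-14)  # lambda0 point
  expect_equal(sp$intensities, rev(sp$intensities), tolerance = 1e-12)
  expect_true(all(sp$intensities >= 0))
  expect_error(simulate_spectrum(cfg, 0, grid = numeric(0)), "empty")
})

test_that("bimodal peak positions match a dense-grid argmax search", {
  cfg <- cfg_bimodal()
  sp <- simulate_spectrum(cfg, 0, grid = default_grid(cfg, n = 2001))
  pk <- spectrum_peaks(sp)
  expect_equal(nrow(pk), 2)
  # brute-force maximization on a 20x denser grid, each half separately
  dense <- default_grid(cfg, n = 40001)
  x <- dense - cfg$lambda0
  y <- (1 - cos(cfg$k * x)) * exp(-x^2 / cfg$sigma_lambda^2)
  left <- dense[dense < cfg$lambda0]
  right <- dense[dense > cfg$lambda0]
  xl <- left[which.max(y[dense < cfg$lambda0])]
  xr <- right[which.max(y[dense > cfg$lambda0])]
  res <- diff(sp$wavelengths[1:2])
  expect_lt(abs(pk$wavelength[1] - xl), res)
  expect_lt(abs(pk$wavelength[2] - xr), res)
  # symmetric about the center
  expect_equal(pk$wavelength[1] - cfg$lambda0, cfg$lambda0 - pk$wavelength[2],
               tolerance = 1e-6)
})

test_that("peak finding: single peak for monotone-flank input, zero for dark", {
  half <- spectrum(1:10, c(10, 9, 7.5, 6, 4.5, 3, 2, 1.2, 0.5, 0.1))
  expect_equal(nrow(spectrum_peaks(half)), 1)
  dark <- spectrum(1:10, rep(0, 10))
  expect_equal(nrow(spectrum_peaks(dark)), 0)
})

test_that("peak height ordering flips between +delta and -delta", {
  cfg <- cfg_bimodal()
  grid <- default_grid(cfg, n = 2001)
  pk_pos <- spectrum_peaks(simulate_spectrum(cfg, 0.2, grid = grid))
  pk_neg <- spectrum_peaks(simulate_spectrum(cfg, -0.2, grid = grid))
  expect_equal(nrow(pk_pos), 2)
  expect_equal(nrow(pk_neg), 2)
  expect_true(xor(pk_pos$height[1] > pk_pos$height[2],
                  pk_neg$height[1] > pk_neg$height[2]))
  # oracle: evaluate the model at the two peak wavelengths directly
  x <- pk_pos$wavelength - cfg$lambda0
  env <- exp(-x^2 / cfg$sigma_lambda^2)
  expect_equal(order((1 - cos(cfg$k * x + 0.2)) * env),
               order(pk_pos$height))
})

test_that("physical amplitude produces the single-peak pedestal regime", {
  # mismatched selection at slow fringe: pedestal with a weak modulation
  cfg <- optical_config(pi / 4, pi / 4 - 0.4, k = 0.3 / SIGMA40)
  sp <- simulate_spectrum(cfg, 0.05, grid = default_grid(cfg, n = 1001),
                          physical_amplitude = TRUE)
  expect_equal(nrow(spectrum_peaks(sp)), 1)
})

test_that("centroid shift stays bounded even where |Im A_w| diverges", {
  cfg <- cfg_bimodal()
  grid <- default_grid(cfg, n = 501)
  span <- diff(range(grid))
  shifts <- vapply(seq(-pi, pi, length.out = 101), function(d) {
    sp <- simulate_spectrum(cfg, d, grid = grid)
    if (sum(sp$intensities) == 0) return(0)
    method_a(sp, cfg)$statistic
  }, numeric(1))
  expect_true(all(abs(shifts) <= span))
})

test_that("centroid shift is proportional to Im A_w near a slightly
           mismatched working point", {
  # second-order Taylor regime: alpha close to (not equal to) beta, so the
  # weak value stays finite and Im A_w is linear in the small phase
  cfg <- optical_config(pi / 4, pi / 4 - 0.05, k = pi / SIGMA40)
  grid <- default_grid(cfg, n = 1001)
  deltas <- seq(-0.01, 0.01, length.out = 21)
  shift <- vapply(deltas, function(d)
    method_a(simulate_spectrum(cfg, d, grid = grid,
                               physical_amplitude = TRUE), cfg)$statistic,
    numeric(1))
  im_aw <- vapply(deltas, function(d) Im(weak_value(cfg, d)), numeric(1))
  r2 <- summary(stats::lm(shift ~ im_aw))$r.squared
  expect_gt(r2, 0.999)
})

test_that("coupling strength is recovered from the bimodal lobe spacing", {
  cfg <- cfg_bimodal()
  sp <- simulate_spectrum(cfg, 0, grid = default_grid(cfg, n = 4001))
  expect_equal(estimate_coupling(sp, cfg), cfg$k, tolerance = 5e-3)
})
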