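# Shared fixtures and independent oracles.

SIGMA40 <- 40 / (2 * sqrt(log(2)))  # envelope scale of a 40 nm FWHM source

# bimodal working configuration: fringe period comparable to the band
cfg_bimodal <- function(alpha = pi / 4, beta = pi / 4)
  optical_config(alpha, beta, k = pi / SIGMA40)

# configuration with coupling phase k*sigma_lambda = ks (dimensionless)
cfg_coupling <- function(ks, alpha = pi / 4, beta = pi / 4)
  optical_config(alpha, beta, k = ks / SIGMA40)

# study conditions of the stepped-ramp evaluation protocol
protocol_config <- function() cfg_coupling(0.07)
protocol_grid <- function(cfg = protocol_config(), n = 501)
  default_grid(cfg, n = n, span = 2)
protocol_source_shape <- function(cfg = protocol_config())
  list(type = "skew_gaussian", sigma1 = 0.80 * cfg$sigma_lambda,
       sigma2 = 0.95 * cfg$sigma_lambda)

# --- independent oracles -------------------------------------------------

# weak moment by direct two-component linear algebra (bra convention: the
# bra row is the post-selected ket's components, unconjugated, matching the
# closed form implemented by weak_value)
oracle_weak_moment <- function(alpha, beta, delta, n) {
  psi_i <- c(sin(alpha), cos(alpha))
  psi_f <- c(exp(-1i * delta) * cos(beta), -exp(1i * delta) * sin(beta))
  A <- diag(c(1, -1))
  An <- diag(2)
  for (j in seq_len(n)) An <- An %*% A
  sum(psi_f * (An %*% psi_i)) / sum(psi_f * psi_i)
}

# least-squares objective whose stationary points the ML estimating
# equation must reproduce
ls_objective <- function(nspec, config, delta) {
  kx <- config$k * nspec$x
  vapply(delta, function(d)
    sum((nspec$y - (1 - cos(kx + d)) * nspec$w)^2), numeric(1))
}

# dense-grid argmin of the least-squares objective
oracle_grid_argmin <- function(nspec, config, bracket, n_grid = 1e4) {
  dg <- seq(bracket[1], bracket[2], length.out = n_grid)
  dg[which.min(ls_objective(nspec, config, dg))]
}

# exhaustive linear-window scan (independent re-implementation)
oracle_linear_window <- function(deltas, stats_, tolerance) {
  n <- length(deltas)
  centre <- which.min(abs(deltas - mean(range(deltas))))
  best <- NULL
  for (i in 1:centre) for (j in centre:n) {
    if (j - i < 2) next
    d <- deltas[i:j]; s <- stats_[i:j]
    co <- stats::coef(stats::lm(s ~ d))
    resid <- s - (co[1] + co[2] * d)
    if (max(abs(resid)) <= tolerance * diff(range(s))) {
      if (is.null(best) || diff(range(d)) > diff(best)) best <- range(d)
    }
  }
  best
}

# simulated noiseless spectrum -> normalized form in one call
nspec_at <- function(config, delta, n = 501, span = 3, amplitude = 1) {
  sp <- simulate_spectrum(config, delta,
                          grid = default_grid(config, n = n, span = span),
                          amplitude = amplitude)
  normalize_spectrum(sp, config)
}
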