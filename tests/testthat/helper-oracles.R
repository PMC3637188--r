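# Independent oracles: deliberately coded from first principles (complex
# arithmetic, brute-force search, direct summation) rather than through the
# package's closed-form helpers.

# magnitude response via explicit complex arithmetic
oracle_mag <- function(beta, theta_deg, f, d = 0.01, c = 340, tau = 0) {
  phase <- 2 * pi * f * (d * cos(theta_deg * pi / 180) / c + tau)
  Mod(1 - beta * exp(-1i * phase))
}

# brute-force minimiser of the band-edge response over beta
oracle_turning_weight <- function(d = 0.01, c = 340, tau = 0, f_max = 6000,
                                  step = 1e-4) {
  betas <- seq(0, 1, by = step)
  vals <- oracle_mag(betas, 0, f_max, d, c, tau)
  betas[which.min(vals)]
}

# piecewise-linear response built directly from the printed-style recipe
oracle_linearized <- function(beta, f, beta_turn, d = 0.01, c = 340, tau = 0,
                              f_max = 6000) {
  H2 <- oracle_mag(beta_turn, 0, f_max, d, c, tau)
  H3 <- oracle_mag(1, 0, f_max, d, c, tau)
  endpoint <- if (beta <= beta_turn) {
    1 - (beta / beta_turn) * (1 - H2)
  } else {
    H2 + (beta - beta_turn) / (1 - beta_turn) * (H3 - H2)
  }
  (1 - beta) + (endpoint - (1 - beta)) * f / f_max
}

# energy ratio by direct summation (the raw squared form)
oracle_energy_ratio <- function(beta, n, beta_turn, d = 0.01, c = 340,
                                tau = 0, f_max = 6000) {
  f <- (0:n) / n * f_max
  sum(oracle_mag(beta, 0, f, d, c, tau)^2) /
    sum(oracle_linearized(beta, f, beta_turn, d, c, tau, f_max)^2)
}

# rms of the central part of a waveform (transient-insensitive)
trimmed_rms <- function(wave, trim = 0.1) {
  sqrt(mean(trim_waveform(wave, trim)$value^2))
}

default_model <- function() linearized_model()
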