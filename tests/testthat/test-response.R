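test_that("closed-form magnitude matches the complex-arithmetic oracle on a dense grid", {
  cfg <- array_config()
  betas <- seq(0, 4, length.out = 20)
  taus <- c(0, 0.342, 1) * cfg$d / cfg$c
  thetas <- seq(-180, 180, by = 10)
  freqs <- seq(0, 6000, length.out = 25)
  for (beta in betas) {
    for (tau in taus) {
      p <- beam_params("custom", beta = beta, tau = tau)
      got <- outer(thetas, freqs, function(th, f) system_response(th, f, p, cfg))
      want <- outer(thetas, freqs, function(th, f) oracle_mag(beta, th, f, tau = tau))
      expect_equal(got, want, tolerance = 1e-12)
      expect_true(all(got >= response_lower_bound(beta) - 1e-12))
    }
  }
})

test_that("limiting values of the response match the closed-form levels", {
  # 0 Hz level is |1 - beta| regardless of angle and delay
  expect_equal(system_response(37, 0, beam_params(beta = 0.2)), 0.8)
  expect_equal(system_response(-120, 0, beam_params(beta = 4, tau = 0,
                                                    pattern = "custom")), 3)
  # beta = 0: no second-microphone contribution
  expect_equal(system_response(45, 3000, beam_params(beta = 0)), 1)
  # frozen from the complex oracle: 2*sin(pi*6000*0.01/340)
  expect_equal(system_response(0, 6000), 1.0528643, tolerance = 1e-7)
  expect_error(system_response(0, -5), "nonnegative")
})

test_that("small-frequency approximation is linear in f and tracks the exact response", {
  p <- beam_params() # dipolar, beta = 1
  expect_equal(small_f_approximation(0, 0, p), 0)
  expect_equal(small_f_approximation(90, 1234, p), 0, tolerance = 1e-12)
  # frozen from 2*pi*100*0.01/340
  expect_equal(small_f_approximation(0, 100, p), 0.018479956, tolerance = 1e-7)
  # within 0.1% of the exact response for f <= 200 Hz on-axis
  f <- seq(10, 200, by = 10)
  expect_equal(small_f_approximation(0, f, p), system_response(0, f, p),
               tolerance = 1e-3)
  expect_error(small_f_approximation(0, 100, beam_params(beta = 0.5)), "beta")
})

test_that("reciprocal weights give proportional responses", {
  eq <- reciprocal_equivalent(0.5)
  expect_equal(eq$equivalent_beta, 2)
  expect_equal(eq$scale, 0.5)
  expect_error(reciprocal_equivalent(0), "degenerate")
  expect_error(reciprocal_equivalent(1.2), "strictly")
  # |H(beta)| = beta * |H(1/beta)| pointwise on a 10 x 10 grid
  thetas <- seq(-180, 180, length.out = 10)
  freqs <- seq(0, 6000, length.out = 10)
  for (beta in c(0.2, 0.5, 0.9)) {
    lhs <- outer(thetas, freqs,
                 function(th, f) system_response(th, f, beam_params(beta = beta)))
    rhs <- outer(thetas, freqs,
                 function(th, f) system_response(th, f, beam_params(beta = 1 / beta)))
    expect_equal(lhs, beta * rhs, tolerance = 1e-12)
  }
})

test_that("on-axis dipolar response is strictly increasing up to the band edge", {
  f <- seq(0, 6000, by = 50)
  h <- system_response(0, f, beam_params())
  expect_true(all(diff(h) > 0))
})

test_that("far-field rule gives two wavelengths", {
  expect_equal(round(far_field_min_distance(274), 2), 2.48)
  expect_equal(round(far_field_min_distance(6276), 2), 0.11)
  # a 1.5 m source distance is far-field down to about 453 Hz
  expect_equal(2 * 340 / 1.5, 453, tolerance = 1e-3)
  expect_error(far_field_min_distance(0), "positive")
})
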