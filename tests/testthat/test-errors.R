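test_that("error metrics vanish identically when the weight is zero", {
  m <- default_model()
  f <- seq(0, 6000, by = 500)
  expect_equal(relative_error(m, 0, f), rep(0, length(f)))
  expect_equal(normalization_coefficient(m, 0), 1)
  expect_equal(normalization_coefficient(m, 0, variant = "energy"), 1)
  expect_equal(normalized_error(m, 0, f), rep(0, length(f)))
  expect_equal(average_error(m, 0), 0)
})

test_that("relative error agrees with direct evaluation of the two responses", {
  m <- default_model()
  # both branches nearly meet at the band edge for beta = 1
  e_edge <- relative_error(m, 1, 6000)
  expect_lt(abs(e_edge), 0.2) # small positive/negative residual in percent
  expect_equal(e_edge,
               100 * (linearized_response(m, 1, 6000) - oracle_mag(1, 0, 6000)) /
                 oracle_mag(1, 0, 6000),
               tolerance = 1e-12)
  # undefined where the exact response vanishes
  expect_warning(e0 <- relative_error(m, 1, 0), "undefined")
  expect_true(is.na(e0))
})

test_that("normalisation coefficient matches the direct-summation oracle and converges", {
  m <- default_model()
  # raw energy-ratio form, frozen from the closed-form integral:
  # (2 f_max - sin(2 a f_max)/a) / (H3^2 f_max / 3) with a = pi d / c = 1.0429
  expect_equal(normalization_coefficient(m, 1, 1000, variant = "energy"),
               1.042793, tolerance = 1e-5)
  expect_equal(normalization_coefficient(m, 1, 1000, variant = "energy"),
               oracle_energy_ratio(1, 1000, m$beta_turn), tolerance = 1e-12)
  # default amplitude form is its square root
  expect_equal(normalization_coefficient(m, 1, 1000),
               sqrt(oracle_energy_ratio(1, 1000, m$beta_turn)), tolerance = 1e-12)
  # stabilises quickly in N for all weights
  for (beta in seq(0, 1, by = 0.1)) {
    expect_lt(abs(normalization_coefficient(m, beta, 500) -
                  normalization_coefficient(m, beta, 5000)), 1e-3)
  }
})

test_that("normalised error balances the energy and reduces the low-frequency bias", {
  m <- default_model()
  # frozen from the oracle: G * H_eva(1, 50) / H(1, 50) - 1 in percent
  expect_equal(normalized_error(m, 1, 50), -3.0322, tolerance = 1e-3)
  # after scaling, the linearised response has the energy of the exact one
  f <- (0:2000) / 2000 * m$f_max
  G <- normalization_coefficient(m, 1)
  expect_equal(sum((G * linearized_response(m, 1, f))^2),
               sum(exact_response(m, 1, f)^2), tolerance = 1e-9)
  # and the normalised low-frequency error is smaller than the raw one
  expect_lt(abs(normalized_error(m, 1, 50)), abs(relative_error(m, 1, 50)))
})

test_that("average error recomputes from its definition and is nonnegative", {
  m <- default_model()
  for (beta in c(0.3, 0.86, 1)) {
    G <- sqrt(oracle_energy_ratio(beta, 2000, m$beta_turn))
    f <- (1:50) / 50 * 6000
    direct <- mean(abs(100 * (G * oracle_linearized(beta, f, m$beta_turn) -
                              oracle_mag(beta, 0, f)) / oracle_mag(beta, 0, f)))
    expect_equal(average_error(m, beta), direct, tolerance = 1e-10)
    expect_gte(average_error(m, beta), 0)
  }
})

test_that("error report summarises the grid and its tidiers round-trip", {
  m <- default_model()
  rep <- error_report(m, beta_grid = c(0, 0.5, 1))
  expect_s3_class(tidy(rep), "tbl_df")
  expect_equal(nrow(tidy(rep)), 3 * 120)
  g <- glance(rep)
  expect_true(g$relative_max > 0 && g$relative_min < 0)
  expect_equal(rep$by_beta$G[rep$by_beta$beta == 0], 1)
  expect_equal(rep$by_beta$average_error[1], 0)
  expect_s3_class(autoplot(rep), "ggplot")
})
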