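test_that("plane-wave simulation reproduces the inter-microphone delay", {
  fs <- 48000
  src <- make_source("white_noise", fs = fs, duration = 0.2, seed = 2)
  # broadside: zero delay, mic2 identical to mic1 within interpolation error
  p90 <- simulate_plane_wave(src, 90)
  mid <- 2000:7000
  err <- p90$mic2[mid] - p90$mic1[mid]
  expect_lt(10 * log10(mean(err^2) / mean(p90$mic1[mid]^2)), -60)
  # endfire: cross-correlation delay d/c = 29.4 us within half a sample
  p0 <- simulate_plane_wave(src, 0)
  expect_equal(estimate_pair_delay(p0), 0.01 / 340, tolerance = 0.5 / fs / (0.01 / 340))
  # rear incidence: microphone 2 leads by the same amount
  p180 <- simulate_plane_wave(src, 180)
  expect_equal(estimate_pair_delay(p180), -0.01 / 340,
               tolerance = 0.5 / fs / (0.01 / 340))
})

test_that("additive noise hits the requested per-microphone SNR exactly and is seeded", {
  src <- make_source("speech_like", fs = 16000, duration = 0.5, seed = 4)
  pair <- simulate_plane_wave(src, 45)
  for (snr in c(15, 10, 5, 0)) {
    noisy <- add_noise(pair, snr, "white", seed = 9)
    measured <- 10 * log10(mean(pair$mic1^2) /
                           mean((noisy$mic1 - pair$mic1)^2))
    expect_equal(measured, snr, tolerance = 0.1)
  }
  # coloured noise concentrates its energy below the cutoff
  noisy <- add_noise(pair, 0, "lowpass_colored", seed = 9)
  nz <- waveform(noisy$mic1 - pair$mic1, 16000)
  ps <- welch_psd(nz)
  low <- sum(ps$psd[ps$frequency <= 500])
  expect_gt(low / sum(ps$psd), 0.9)
  # determinism and the no-noise identity
  expect_identical(add_noise(pair, 5, "white", seed = 1)$mic1,
                   add_noise(pair, 5, "white", seed = 1)$mic1)
  expect_identical(add_noise(pair, Inf, "white")$mic1, pair$mic1)
})

test_that("the time-domain beamformer degenerates correctly and kills low frequencies", {
  fs <- 16000
  src <- make_source("white_noise", fs = fs, duration = 0.5, seed = 6)
  pair <- simulate_plane_wave(src, 0)
  # beta = 0 passes microphone 1 through untouched
  expect_equal(time_domain_beamform(pair, beam_params(beta = 0))$value, pair$mic1)
  # first-order differential output strongly attenuates the low band
  y <- time_domain_beamform(pair, beam_params("dipolar"))
  ps_in <- welch_psd(trim_waveform(waveform(pair$mic1, fs), 0.05))
  ps_out <- welch_psd(trim_waveform(y, 0.05))
  low <- ps_in$frequency > 0 & ps_in$frequency < 300
  high <- ps_in$frequency > 3000 & ps_in$frequency < 6000
  atten_low <- mean(10 * log10(ps_out$psd[low] / ps_in$psd[low]))
  atten_high <- mean(10 * log10(ps_out$psd[high] / ps_in$psd[high]))
  expect_lt(atten_low, -15)
  expect_gt(atten_high - atten_low, 15)
})

test_that("probe tones reproduce the closed-form response across angles and frequencies", {
  res <- empirical_beam_response(beam_params("supercardioid", beta = 0.5))
  expect_equal(res$measured, res$predicted, tolerance = 0.02)
  # cardioid rear null: > 40 dB attenuation at 180 degrees
  src <- make_source("white_noise", fs = 32000, duration = 0.5, seed = 7)
  out <- time_domain_beamform(simulate_plane_wave(src, 180), beam_params("cardioid"))
  att_db <- 20 * log10(trimmed_rms(src) / trimmed_rms(out))
  expect_gt(att_db, 40)
})

test_that("sources have the advertised spectra and are deterministic under a seed", {
  fs <- 16000
  ts <- make_source("tone_set", fs = fs, duration = 1)
  ps <- welch_psd(ts)
  ls <- line_spectrum(ps)
  expect_true(all(10 * log10(ls$psd / stats::median(ps$psd[ps$psd > 0])) > 20))
  sp1 <- make_source("speech_like", fs = fs, duration = 0.3, seed = 8)
  sp2 <- make_source("speech_like", fs = fs, duration = 0.3, seed = 8)
  expect_identical(sp1$value, sp2$value)
  # speech-like energy concentrates at low frequencies
  pss <- welch_psd(sp1)
  expect_gt(sum(pss$psd[pss$frequency <= 1500]) / sum(pss$psd), 0.7)
  expect_error(make_source("tone_set", duration = 0), "positive")
})
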