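make_bands <- function(x, fs = 16000) {
  apply_filter_bank(waveform(x, fs), build_filter_bank(fs = fs))
}

test_that("steady tones give near-constant envelopes at the rectified mean level", {
  fs <- 16000
  t <- (0:(2 * fs - 1)) / fs
  env <- extract_envelopes(make_bands(sin(2 * pi * 274 * t)))
  mid <- env$ch1[(fs / 2):(3 * fs / 2)]
  # settles within 10% around the full-wave rectified mean 2/pi
  expect_lt((max(mid) - min(mid)) / mean(mid), 0.1)
  expect_equal(mean(mid), 2 / pi, tolerance = 0.05)
  expect_true(all(env$ch1 >= 0))
  # zero signal -> zero envelope
  env0 <- extract_envelopes(make_bands(rep(0, fs)))
  expect_equal(max(abs(env0$ch4)), 0)
})

test_that("an amplitude-modulated carrier yields an envelope tracking the modulator", {
  fs <- 16000
  t <- (0:(2 * fs - 1)) / fs
  modu <- 1 + sin(2 * pi * 10 * t)
  env <- extract_envelopes(make_bands(modu * sin(2 * pi * 1005 * t)))
  mid <- (fs / 4):(7 * fs / 4)
  expect_gt(cor(env$ch4[mid], modu[mid]), 0.95)
})

test_that("gain application scales envelopes per channel and validates input", {
  fs <- 16000
  t <- (0:(fs / 2 - 1)) / fs
  env <- extract_envelopes(make_bands(sin(2 * pi * 1005 * t) + sin(2 * pi * 274 * t)))
  m <- default_model()
  ones <- suppressWarnings(channel_gains(m, 0, mode = "ideal")) # all-unit gains
  expect_equal(apply_channel_gains(env, ones)$ch4, env$ch4)
  g <- suppressWarnings(channel_gains(m, 1, mode = "ideal"))
  scaled <- apply_channel_gains(env, g)
  expect_equal(scaled$ch1, env$ch1 * g$gain[g$channel == 1])
  bad <- g
  bad$gain[1] <- 0
  expect_error(apply_channel_gains(env, bad), "positive")
})

test_that("CIS resynthesis puts lines exactly at the channel centre frequencies", {
  fs <- 16000
  spec <- filter_bank_spec()
  t <- (0:(fs - 1)) / fs
  # single active channel with constant envelope -> a pure tone at its centre
  env <- structure(
    tibble::tibble(time = t, !!!stats::setNames(
      lapply(1:8, function(i) if (i == 4) rep(0.5, fs) else rep(0, fs)),
      paste0("ch", 1:8)
    )),
    fs = fs, spec = spec,
    class = c("channel_envelopes", class(tibble::tibble()))
  )
  y <- cis_modulate(env)
  expect_equal(y$value, 0.5 * sin(2 * pi * 1005 * t), tolerance = 1e-12)

  # a full tone-set scene has PSD maxima only at the eight centres
  src <- make_source("tone_set", fs = fs, duration = 1)
  cis <- cis_modulate(extract_envelopes(apply_filter_bank(src, build_filter_bank(fs = fs))))
  ps <- welch_psd(trim_waveform(cis, 0.1))
  ls <- line_spectrum(ps, spec)
  # every line must be a local maximum of the PSD
  for (i in seq_len(8)) {
    k <- which(ps$frequency == ls$bin_frequency[i])
    expect_gt(ps$psd[k], ps$psd[k - 2])
    expect_gt(ps$psd[k], ps$psd[k + 2])
  }
  # and the lines dominate: each at least 20 dB above the median PSD level
  expect_true(all(10 * log10(ls$psd / stats::median(ps$psd[ps$psd > 0])) > 20))
})

test_that("CIS resynthesis is linear: doubling one envelope adds 6 dB to its line only", {
  fs <- 16000
  src <- make_source("tone_set", fs = fs, duration = 1)
  env <- extract_envelopes(apply_filter_bank(src, build_filter_bank(fs = fs)))
  env2 <- env
  env2$ch3 <- 2 * env2$ch3
  ls1 <- line_spectrum(welch_psd(trim_waveform(cis_modulate(env), 0.1)))
  ls2 <- line_spectrum(welch_psd(trim_waveform(cis_modulate(env2), 0.1)))
  diff_db <- ls2$level_db - ls1$level_db
  expect_equal(diff_db[3], 20 * log10(2), tolerance = 0.25)
  expect_true(all(abs(diff_db[-3]) < 0.5))
})
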