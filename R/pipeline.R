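# High-level reproducible runs tying the model, the compensation and the
# simulated CIS chain together. These are the workhorses behind the
# command-line front-end in inst/cli/.

#' Compute and optionally export beam patterns
#'
#' Evaluates the beam pattern for the given parameters (raw, and optionally
#' normalised at 0 Hz) and writes CSV/JSON files when `out_dir` is given.
#'
#' @param params A [beam_params()].
#' @param cfg An [array_config()].
#' @param frequencies Frequencies in Hz.
#' @param angle_step Angular step in degrees.
#' @param normalize Also produce the 0 Hz-normalised pattern (requires
#'   `beta != 1`).
#' @param out_dir Optional output directory for `beam_pattern_raw.csv` (and
#'   `beam_pattern_normalized.csv`).
#' @return A named list of `beam_pattern` tibbles (`raw`, and `normalized` if
#'   requested), invisibly when writing files.
#' @export
run_beampattern <- function(params = beam_params(), cfg = array_config(),
                            frequencies = filter_bank_spec()$center,
                            angle_step = 1, normalize = FALSE, out_dir = NULL) {
  pat <- beam_pattern(params, cfg, frequencies, angle_step)
  out <- list(raw = pat)
  if (normalize) out$normalized <- normalize_at_dc(pat)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_beam_pattern(pat, file.path(out_dir, "beam_pattern_raw.csv"))
    if (normalize) {
      write_beam_pattern(out$normalized,
                         file.path(out_dir, "beam_pattern_normalized.csv"))
    }
    return(invisible(out))
  }
  out
}

#' Compute and optionally export the linearisation error report
#'
#' Builds the [linearized_model()] for the given geometry and delay, computes
#' the [error_report()] over the standard grid, and writes the surface, the
#' per-weight summary and the fitted slope coefficients when `out_dir` is
#' given.
#'
#' @param cfg An [array_config()].
#' @param tau Algorithm delay, seconds.
#' @param f_max Band limit, Hz.
#' @param beta_grid,f_grid,n_points Grid controls, see [error_report()].
#' @param out_dir Optional output directory.
#' @return The `error_report` object (invisibly when writing files).
#' @export
run_error_report <- function(cfg = array_config(), tau = 0, f_max = 6000,
                             beta_grid = seq(0, 1, by = 0.02), f_grid = NULL,
                             n_points = 50, out_dir = NULL) {
  model <- linearized_model(cfg, tau = tau, f_max = f_max)
  rep <- error_report(model, beta_grid = beta_grid, f_grid = f_grid,
                      n_points = n_points)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(rep$surface, file.path(out_dir, "error_surface.csv"),
              row.names = FALSE)
    write.csv(rep$by_beta, file.path(out_dir, "error_by_beta.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(coefficients = tidy(model), model = glance(model),
           summary = glance(rep)),
      file.path(out_dir, "linearization.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
    return(invisible(rep))
  }
  rep
}

#' Simulated end-to-end CIS compensation experiment
#'
#' Reproduces the full evaluation chain on a synthetic scene: a source is
#' recorded by the simulated microphone pair at incidence `theta` (optionally
#' with additive noise), beamformed, split by the CI filter bank, envelope
#' extracted, compensated with no / linearised / ideal channel gains, CIS
#' resynthesised, and compared channel-by-channel (Welch PSD line levels, dB)
#' with the same chain applied to the unbeamformed source.
#'
#' @param params A [beam_params()].
#' @param cfg An [array_config()].
#' @param bank_spec Band plan tibble.
#' @param source_kind Source type for [make_source()].
#' @param theta Source incidence angle, degrees.
#' @param snr_db Per-microphone SNR in dB (`Inf` = noiseless).
#' @param noise_kind Noise colour for [add_noise()].
#' @param fs Sample rate, Hz.
#' @param duration Scene duration, seconds.
#' @param seed RNG seed (stochastic sources and noise).
#' @param reference_channel Reference channel for the gains.
#' @param trim Edge trim before PSD measurement, seconds.
#' @param modes Gain modes to evaluate.
#' @param out_dir Optional output directory for `channel_errors.csv` and a
#'   JSON provenance block.
#' @return A tibble with columns `mode`, `channel`, `center`, `error_db`.
#' @examples
#' \donttest{
#' run_end_to_end(duration = 0.5, seed = 1)
#' }
#' @export
run_end_to_end <- function(params = beam_params(), cfg = array_config(),
                           bank_spec = filter_bank_spec(),
                           source_kind = "tone_set", theta = 0, snr_db = Inf,
                           noise_kind = "lowpass_colored", fs = 16000,
                           duration = 1, seed = 1, reference_channel = 4,
                           trim = 0.1,
                           modes = c("uncompensated", "linearized", "ideal"),
                           out_dir = NULL) {
  bank <- build_filter_bank(bank_spec, fs = fs)
  model <- linearized_model(cfg, tau = params$tau)
  src <- make_source(source_kind, fs = fs, duration = duration, seed = seed,
                     centers = bank_spec$center)

  chain <- function(wave, gains = NULL) {
    env <- extract_envelopes(apply_filter_bank(wave, bank))
    if (!is.null(gains)) env <- apply_channel_gains(env, gains)
    cis <- trim_waveform(cis_modulate(env, bank_spec), trim)
    line_spectrum(welch_psd(cis), bank_spec)
  }

  reference <- chain(src)
  scene <- simulate_plane_wave(src, theta, cfg)
  scene <- add_noise(scene, snr_db, noise_kind, seed = seed + 1L)
  beamformed <- time_domain_beamform(scene, params, cfg)

  gain_for <- function(mode) {
    switch(mode,
      uncompensated = NULL,
      linearized = channel_gains(model, params$beta, bank_spec,
                                 reference_channel, mode = "linearized"),
      ideal = channel_gains(model, params$beta, bank_spec,
                            reference_channel, mode = "ideal")
    )
  }
  out <- purrr::map_dfr(modes, function(m) {
    errs <- psd_channel_errors(chain(beamformed, gain_for(m)), reference)
    dplyr::mutate(errs, mode = m, .before = 1)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(out, file.path(out_dir, "channel_errors.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(beta = params$beta, tau = params$tau, pattern = params$pattern,
           d = cfg$d, c = cfg$c, source = source_kind, theta = theta,
           snr_db = if (is.infinite(snr_db)) "none" else snr_db,
           noise_kind = noise_kind, fs = fs, duration = duration, seed = seed,
           reference_channel = reference_channel,
           version = as.character(utils::packageVersion("beamcomp"))),
      file.path(out_dir, "run_config.json"), auto_unbox = TRUE, digits = NA
    )
  }
  out
}
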