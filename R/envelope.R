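# CIS-style envelope extraction, per-channel gain application, and
# sinusoidal resynthesis at the channel centre frequencies.

#' Extract channel envelopes
#'
#' Full-wave rectification followed by a zero-phase Butterworth low-pass on
#' each channel signal — the envelope path of a CIS speech strategy. Small
#' negative excursions from the low-pass are clamped to zero.
#'
#' @param bands A `channel_signals` tibble from [apply_filter_bank()].
#' @param cutoff Envelope low-pass cutoff in Hz.
#' @param order Low-pass order (the default 4 keeps rectifier ripple on the
#'   lowest channel within a few percent).
#' @return A tibble of class `channel_envelopes` (same shape as `bands`, all
#'   values nonnegative).
#' @export
extract_envelopes <- function(bands, cutoff = 400, order = 4) {
  stopifnot(inherits(bands, "channel_signals"))
  fs <- attr(bands, "fs")
  if (nrow(bands) == 0L) abort("Empty signal.")
  lp <- signal::butter(order, cutoff / (fs / 2), type = "low")
  cols <- channel_columns(bands)
  out <- dplyr::mutate(as_tibble(bands), dplyr::across(
    dplyr::all_of(cols),
    function(x) pmax(signal::filtfilt(lp, abs(x)), 0)
  ))
  structure(out, fs = fs, spec = attr(bands, "spec"),
            class = c("channel_envelopes", class(tibble())))
}

#' Apply per-channel compensation gains to envelopes
#'
#' Scales each channel envelope by its [channel_gains()] gain — equivalent to
#' gain adjustment in the filter bank, since the factors are scalar per
#' channel.
#'
#' @param envelopes A `channel_envelopes` tibble.
#' @param gains A [channel_gains()] tibble (same channels).
#' @return A `channel_envelopes` tibble with scaled envelopes.
#' @export
apply_channel_gains <- function(envelopes, gains) {
  stopifnot(inherits(envelopes, "channel_envelopes"))
  cols <- channel_columns(envelopes)
  want <- paste0("ch", gains$channel)
  if (!setequal(cols, want)) {
    abort("Channel mismatch between envelopes and gains.")
  }
  if (any(gains$gain <= 0) || any(!is.finite(gains$gain))) {
    abort("Gains must be positive and finite.")
  }
  out <- as_tibble(envelopes)
  for (i in seq_len(nrow(gains))) {
    col <- paste0("ch", gains$channel[i])
    out[[col]] <- out[[col]] * gains$gain[i]
  }
  structure(out, fs = attr(envelopes, "fs"), spec = attr(envelopes, "spec"),
            class = class(envelopes))
}

#' CIS sinusoidal resynthesis
#'
#' Modulates one sinusoid per channel, at the channel centre frequency, by the
#' channel envelope, and sums: the acoustic emulation of CIS stimulation. The
#' spectrum of the result is a line spectrum at the centre frequencies.
#'
#' @param envelopes A `channel_envelopes` tibble.
#' @param spec Band plan (defaults to the one attached to `envelopes`).
#' @return A [waveform()].
#' @export
cis_modulate <- function(envelopes, spec = NULL) {
  stopifnot(inherits(envelopes, "channel_envelopes"))
  spec <- spec %||% attr(envelopes, "spec")
  cols <- channel_columns(envelopes)
  if (length(cols) != nrow(spec)) {
    abort("Channel counts of envelopes and band plan differ.")
  }
  fs <- attr(envelopes, "fs")
  t <- envelopes$time
  y <- numeric(length(t))
  for (i in seq_len(nrow(spec))) {
    y <- y + envelopes[[paste0("ch", spec$channel[i])]] *
      sin(2 * pi * spec$center[i] * t)
  }
  waveform(y, fs)
}
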