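# Welch power spectral density and line-spectrum utilities for the CIS
# evaluation chain.

#' Welch power spectral density estimate
#'
#' Averages modified periodograms of Hann-windowed, overlapping segments — the
#' standard Welch estimator. One-sided density scaled so that the integral
#' over frequency equals the signal power.
#'
#' @param wave A [waveform()] (or numeric vector with `fs` supplied).
#' @param fs Sample rate; inferred from `wave` when possible.
#' @param n Segment length (power of two recommended).
#' @param overlap Fractional overlap between segments in \[0, 1).
#' @param window Window type; `"hann"` or `"rectangular"`.
#' @return A tibble of class `welch_psd` with columns `frequency` (Hz) and
#'   `psd` (power per Hz); attributes `fs`, `n`.
#' @examples
#' w <- make_source("tone_set", duration = 0.5)
#' welch_psd(w)
#' @export
welch_psd <- function(wave, fs = NULL, n = 1024, overlap = 0.5,
                      window = c("hann", "rectangular")) {
  window <- match.arg(window)
  x <- wave_values(wave)
  fs <- fs %||% wave_fs(wave)
  if (length(x) < n) abort("Signal shorter than one Welch segment.")
  if (overlap < 0 || overlap >= 1) abort("`overlap` must lie in [0, 1).")
  w <- if (window == "hann") 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n) else rep(1, n)
  step <- max(1L, round(n * (1 - overlap)))
  starts <- seq(1L, length(x) - n + 1L, by = step)
  acc <- numeric(n %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + n - 1)] * w
    spec <- Mod(fft(seg))^2
    acc <- acc + spec[1:(n %/% 2 + 1)]
  }
  scale <- fs * sum(w^2) * length(starts)
  psd <- acc / scale
  # one-sided: double everything except DC and Nyquist
  psd[2:(n %/% 2)] <- 2 * psd[2:(n %/% 2)]
  structure(
    tibble(frequency = (0:(n %/% 2)) * fs / n, psd = psd),
    fs = fs, n = n,
    class = c("welch_psd", class(tibble()))
  )
}

#' Read a CIS line spectrum off a PSD
#'
#' After CIS resynthesis the spectrum is a set of lines at the channel centre
#' frequencies; this reads the PSD value at the bin nearest each centre.
#'
#' @param psd A [welch_psd()] tibble.
#' @param spec Band plan, see [filter_bank_spec()].
#' @return A tibble of class `cis_line_spectrum` with columns `channel`,
#'   `center`, `bin_frequency`, `psd`, `level_db` (10 log10 of `psd`).
#' @export
line_spectrum <- function(psd, spec = filter_bank_spec()) {
  stopifnot(inherits(psd, "welch_psd"))
  validate_bank_spec(spec)
  idx <- vapply(spec$center, function(fc) which.min(abs(psd$frequency - fc)),
                integer(1))
  vals <- psd$psd[idx]
  tibble(
    channel = spec$channel, center = spec$center,
    bin_frequency = psd$frequency[idx], psd = vals,
    level_db = 10 * log10(vals)
  ) |>
    structure(class = c("cis_line_spectrum", class(tibble())))
}

#' Per-channel dB errors between two CIS line spectra
#'
#' Both spectra are first put at equal total line power (energy
#' normalisation); the per-channel error is then `10 log10(test / reference)`
#' in dB — relative enhancement (positive) or attenuation (negative) of each
#' channel.
#'
#' @param test,reference `cis_line_spectrum` tibbles over the same channels.
#' @return A tibble with columns `channel`, `center`, `error_db`.
#' @export
psd_channel_errors <- function(test, reference) {
  stopifnot(inherits(test, "cis_line_spectrum"),
            inherits(reference, "cis_line_spectrum"))
  if (!identical(test$channel, reference$channel)) {
    abort("Line spectra cover different channels.")
  }
  if (any(reference$psd <= 0)) abort("Reference line power must be positive.")
  if (any(test$psd <= 0)) abort("Test line power must be positive.")
  scale <- sum(reference$psd) / sum(test$psd)
  tibble(channel = test$channel, center = test$center,
         error_db = 10 * log10(test$psd * scale / reference$psd))
}

#' Line-spectrum bar plot
#'
#' @param object A `cis_line_spectrum`.
#' @param ... Unused.
#' @return A ggplot bar chart of line levels in dB.
#' @method autoplot cis_line_spectrum
#' @export
autoplot.cis_line_spectrum <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(factor(.data$channel), .data$level_db)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "channel", y = "line level (dB)") +
    ggplot2::theme_minimal()
}
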