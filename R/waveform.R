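#' Waveform and microphone-pair containers
#'
#' Audio is carried in tibbles: a `waveform` has columns `time` (seconds) and
#' `value`; a `mic_pair` has `time`, `mic1`, `mic2`. The sample rate is stored
#' in the `fs` attribute and retrieved with [wave_fs()].
#'
#' @param samples Numeric sample vector.
#' @param fs Sample rate in Hz.
#' @return `waveform()` returns a tibble of class `waveform`.
#' @examples
#' w <- waveform(sin(2 * pi * 440 * (0:999) / 8000), fs = 8000)
#' wave_fs(w)
#' @export
waveform <- function(samples, fs) {
  if (!is.numeric(samples) || length(samples) == 0L || any(!is.finite(samples))) {
    abort("`samples` must be a nonempty finite numeric vector.")
  }
  n <- length(samples)
  structure(tibble(time = (seq_len(n) - 1) / fs, value = as.numeric(samples)),
            fs = fs, class = c("waveform", class(tibble())))
}

#' @rdname waveform
#' @param mic1,mic2 Equal-length sample vectors for the two microphones.
#' @return `mic_pair()` returns a tibble of class `mic_pair`.
#' @export
mic_pair <- function(mic1, mic2, fs) {
  if (length(mic1) != length(mic2)) abort("`mic1` and `mic2` must have equal length.")
  if (any(!is.finite(mic1)) || any(!is.finite(mic2))) {
    abort("Microphone samples must be finite.")
  }
  n <- length(mic1)
  structure(tibble(time = (seq_len(n) - 1) / fs,
                   mic1 = as.numeric(mic1), mic2 = as.numeric(mic2)),
            fs = fs, class = c("mic_pair", class(tibble())))
}

#' @rdname waveform
#' @param wave A `waveform` or `mic_pair` tibble.
#' @return `wave_fs()` returns the sample rate in Hz.
#' @export
wave_fs <- function(wave) {
  fs <- attr(wave, "fs")
  if (is.null(fs)) {
    if (!"time" %in% names(wave) || nrow(wave) < 2) {
      abort("Cannot infer the sample rate: no `fs` attribute or `time` column.")
    }
    fs <- 1 / stats::median(diff(wave$time))
  }
  fs
}

# internal: numeric samples of a mono waveform
wave_values <- function(wave) {
  if (is.numeric(wave)) return(as.numeric(wave))
  if (!"value" %in% names(wave)) abort("Expected a waveform with a `value` column.")
  wave$value
}

#' Trim the edges of a waveform
#'
#' Removes `seconds` from each end — used to discard filter and interpolation
#' transients before measuring amplitudes or spectra.
#'
#' @param wave A [waveform()].
#' @param seconds Duration to drop from each end.
#' @return A shorter `waveform` (time restarted at 0).
#' @export
trim_waveform <- function(wave, seconds) {
  fs <- wave_fs(wave)
  n_drop <- round(seconds * fs)
  x <- wave_values(wave)
  if (2 * n_drop >= length(x)) abort("Trimming would remove the whole waveform.")
  waveform(x[(n_drop + 1):(length(x) - n_drop)], fs)
}
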