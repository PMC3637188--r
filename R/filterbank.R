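#' The 8-channel cochlear-implant filter-bank band plan
#'
#' Band edges and centre frequencies of the default 8-channel CI analysis
#' filter bank. Edges are contiguous from 156 Hz to 7769 Hz; centre
#' frequencies are stored as conventionally printed (e.g. 274 Hz for channel
#' 1), which can differ by a hertz or two from the arithmetic midpoints.
#'
#' @return A tibble with columns `channel`, `low`, `high`, `center` (Hz).
#' @examples
#' filter_bank_spec()
#' @export
filter_bank_spec <- function() {
  tibble(
    channel = 1:8,
    low     = c(156, 396, 639, 883, 1127, 1797, 2955, 4783),
    high    = c(396, 639, 883, 1127, 1797, 2955, 4783, 7769),
    center  = c(274, 517.5, 761, 1005, 1462, 2376, 3869, 6276)
  )
}

validate_bank_spec <- function(spec) {
  stopifnot(is.data.frame(spec),
            all(c("channel", "low", "high", "center") %in% names(spec)))
  if (any(spec$high <= spec$low)) abort("Band edges must satisfy low < high.")
  if (is.unsorted(spec$low, strictly = TRUE)) abort("Bands must be ordered by frequency.")
  invisible(spec)
}

#' Build the band-pass analysis filter bank
#'
#' One Butterworth band-pass filter per channel, with the -3 dB points at the
#' band edges (a property of the Butterworth band-pass design).
#'
#' @param spec Band plan tibble, see [filter_bank_spec()].
#' @param fs Sample rate in Hz; the Nyquist frequency must exceed the highest
#'   band edge (so `fs >= 16000` for the default plan).
#' @param order Band-pass filter order (even; default 4, i.e. second-order
#'   sections on each skirt).
#'
#' @return An object of class `filter_bank`: list with the band `spec`, `fs`,
#'   `order` and per-channel `signal::butter` coefficients.
#' @examples
#' bank <- build_filter_bank(fs = 16000)
#' @export
build_filter_bank <- function(spec = filter_bank_spec(), fs = 16000, order = 4) {
  validate_bank_spec(spec)
  if (fs / 2 <= max(spec$high)) {
    abort(sprintf("Nyquist frequency %g Hz must exceed the top band edge %g Hz.",
                  fs / 2, max(spec$high)))
  }
  if (order %% 2 != 0 || order < 2) abort("`order` must be an even integer >= 2.")
  filters <- purrr::map2(spec$low, spec$high, function(lo, hi) {
    signal::butter(order / 2, c(lo, hi) / (fs / 2), type = "pass")
  })
  structure(list(spec = as_tibble(spec), fs = fs, order = order,
                 filters = filters),
            class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf("<filter_bank> %d channels, order-%d Butterworth, fs = %g Hz\n",
              nrow(x$spec), x$order, x$fs))
  print(x$spec)
  invisible(x)
}

#' Frequency response of the filter bank
#'
#' Evaluates each channel filter's magnitude response (single-pass; the
#' zero-phase analysis application squares these magnitudes).
#'
#' @param bank A [build_filter_bank()] object.
#' @param f Frequencies in Hz.
#' @return A tibble with columns `channel`, `frequency`, `magnitude`.
#' @export
filter_bank_response <- function(bank, f) {
  stopifnot(inherits(bank, "filter_bank"))
  w <- 2 * pi * f / bank$fs
  z <- exp(-1i * w)
  purrr::imap_dfr(bank$filters, function(flt, i) {
    num <- outer(z, seq_along(flt$b) - 1, `^`) %*% flt$b
    den <- outer(z, seq_along(flt$a) - 1, `^`) %*% flt$a
    tibble(channel = bank$spec$channel[i], frequency = f,
           magnitude = as.numeric(Mod(num / den)))
  })
}

#' Split a waveform into filter-bank channel signals
#'
#' Applies each channel band-pass filter forward and backward (zero phase),
#' producing one band-limited signal per channel.
#'
#' @param wave A [waveform()] tibble (columns `time`, `value`).
#' @param bank A [build_filter_bank()] object whose `fs` matches the waveform.
#' @param zero_phase Apply each filter forward and backward (default; squares
#'   the magnitude response) or single-pass causal filtering.
#' @return A tibble of class `channel_signals`: column `time` plus one `ch<i>`
#'   column per channel; attributes `fs` and `spec`.
#' @export
apply_filter_bank <- function(wave, bank, zero_phase = TRUE) {
  stopifnot(inherits(bank, "filter_bank"))
  x <- wave_values(wave)
  fs <- wave_fs(wave)
  if (abs(fs - bank$fs) > 1e-6 * bank$fs) {
    abort(sprintf("Waveform fs (%g) does not match filter bank fs (%g).", fs, bank$fs))
  }
  bands <- purrr::map(bank$filters, function(flt) {
    if (zero_phase) signal::filtfilt(flt, x)
    else as.numeric(signal::filter(flt, x))
  })
  names(bands) <- paste0("ch", bank$spec$channel)
  out <- tibble(time = wave$time, !!!bands)
  new_channel_signals(out, fs = fs, spec = bank$spec)
}

new_channel_signals <- function(x, fs, spec) {
  structure(as_tibble(x), fs = fs, spec = as_tibble(spec),
            class = c("channel_signals", class(tibble())))
}

channel_columns <- function(x) {
  grep("^ch[0-9]+$", names(x), value = TRUE)
}
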