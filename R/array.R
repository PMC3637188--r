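#' Physical configuration of the two-microphone array
#'
#' The delay-and-subtract front-end is characterised by the inter-microphone
#' spacing `d` and the speed of sound `c`. Defaults are the cochlear-implant
#' values used throughout the package: a 1 cm microphone pair in air.
#'
#' @param d Inter-microphone distance in metres (> 0).
#' @param c Speed of sound in m/s (> 0).
#'
#' @return An object of class `array_config`: a list with elements `d` and `c`.
#' @examples
#' array_config()
#' array_config(d = 0.012)
#' @export
array_config <- function(d = 0.01, c = 340) {
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d <= 0) {
    abort("`d` must be a single positive number (metres).")
  }
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c <= 0) {
    abort("`c` must be a single positive number (m/s).")
  }
  structure(list(d = d, c = c), class = "array_config")
}

#' @export
print.array_config <- function(x, ...) {
  cat(sprintf("<array_config> d = %g m, c = %g m/s (d/c = %.4g s)\n",
              x$d, x$c, x$d / x$c))
  invisible(x)
}

#' Beamformer parameters (delay and weight)
#'
#' A first-order delay-and-subtract beamformer is parameterised by the
#' algorithm delay `tau` (seconds) and the subtraction weight `beta`.
#' The canonical patterns fix the delay relative to the acoustic transit
#' time `d/c`: dipolar `tau = 0`, supercardioid `tau = 0.342 d/c`,
#' cardioid `tau = d/c`.
#'
#' @param pattern One of `"dipolar"`, `"supercardioid"`, `"cardioid"`,
#'   `"custom"`. Named patterns derive `tau` from `cfg`; `"custom"` requires
#'   an explicit `tau`.
#' @param beta Dimensionless weight, `beta >= 0`. Default 1 (equal weighting).
#' @param tau Algorithm delay in seconds (`tau >= 0`). For a named pattern a
#'   supplied `tau` is validated against the pattern's value (relative
#'   tolerance 1e-9).
#' @param cfg An [array_config()].
#'
#' @return An object of class `beam_params`: list with `beta`, `tau`,
#'   `pattern`.
#' @examples
#' beam_params("supercardioid")
#' beam_params("custom", beta = 0.5, tau = 2e-5)
#' @export
beam_params <- function(pattern = c("dipolar", "supercardioid", "cardioid", "custom"),
                        beta = 1, tau = NULL, cfg = array_config()) {
  pattern <- match.arg(pattern)
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta < 0) {
    abort("`beta` must be a single nonnegative number.")
  }
  dc <- cfg$d / cfg$c
  named_tau <- switch(pattern,
    dipolar = 0,
    supercardioid = 0.342 * dc,
    cardioid = dc,
    custom = NULL
  )
  if (pattern == "custom") {
    if (is.null(tau)) abort("`pattern = \"custom\"` requires an explicit `tau`.")
  } else if (is.null(tau)) {
    tau <- named_tau
  } else {
    ref <- max(named_tau, dc)
    if (abs(tau - named_tau) > 1e-9 * ref) {
      abort(sprintf(
        "`tau` = %g is inconsistent with pattern \"%s\" (expected %g).",
        tau, pattern, named_tau
      ))
    }
  }
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau < 0) {
    abort("`tau` must be a single nonnegative number (seconds).")
  }
  structure(list(beta = beta, tau = tau, pattern = pattern),
            class = "beam_params")
}

#' @export
print.beam_params <- function(x, ...) {
  cat(sprintf("<beam_params> pattern = %s, beta = %g, tau = %.4g s\n",
              x$pattern, x$beta, x$tau))
  invisible(x)
}

#' Minimum source distance for the far-field (plane-wave) assumption
#'
#' Plane-wave propagation from a monopole source is commonly assumed valid
#' beyond two wavelengths, so the minimum loudspeaker-to-array distance for a
#' tone at frequency `f` is `2 c / f`. At 340 m/s a 1.5 m distance is
#' far-field for frequencies above about 453 Hz.
#'
#' @param f Frequency in Hz (> 0); vectorised.
#' @param c Speed of sound in m/s.
#'
#' @return Distance(s) in metres, `2 * c / f` (unrounded).
#' @examples
#' round(far_field_min_distance(c(274, 6276)), 2)
#' @export
far_field_min_distance <- function(f, c = 340) {
  if (!is.numeric(f) || any(!is.finite(f)) || any(f <= 0)) {
    abort("`f` must be positive and finite (Hz).")
  }
  2 * c / f
}
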