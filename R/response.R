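# Closed-form narrowband response of the delay-and-subtract pair.
# The magnitude |1 - beta * exp(-j * 2*pi*f * (d*cos(theta)/c + tau))| reduces
# to sqrt(1 + beta^2 - 2*beta*cos(2*pi*f*(d*cos(theta)/c + tau))).

# internal: magnitude from weight and phase (radians); vectorised
h_mag <- function(beta, phase) {
  sqrt(pmax(1 + beta^2 - 2 * beta * cos(phase), 0))
}

#' Narrowband magnitude response of the two-microphone beamformer
#'
#' Evaluates the closed-form magnitude response of the delay-and-subtract
#' beamformer for a plane wave of frequency `f` arriving from incidence angle
#' `theta` (degrees, measured from the endfire axis through the microphones).
#'
#' @param theta Incidence angle(s) in degrees, conventionally in
#'   \[-180, 180\].
#' @param f Frequency in Hz (`f >= 0`); `f = 0` is evaluated literally and
#'   gives the theta-independent value `|1 - beta|`.
#' @param params A [beam_params()] (weight `beta`, delay `tau`).
#' @param cfg An [array_config()].
#'
#' @return Nonnegative magnitude(s), vectorised over `theta` and `f`.
#' @examples
#' system_response(0, 1000)                               # dipolar, beta = 1
#' system_response(90, 500, beam_params(beta = 0.2))      # low-f level -> 0.8
#' @export
system_response <- function(theta, f, params = beam_params(), cfg = array_config()) {
  if (any(!is.finite(f)) || any(f < 0)) {
    abort("`f` must be nonnegative and finite (Hz).")
  }
  delay <- cfg$d * cos(theta * pi / 180) / cfg$c + params$tau
  h_mag(params$beta, 2 * pi * f * delay)
}

#' Small-frequency approximation of the equally-weighted response
#'
#' For `beta = 1` the exact magnitude is `2 |sin(pi f (d cos(theta)/c + tau))|`,
#' which for small `f` is approximately proportional to frequency:
#' `2 pi f |d cos(theta)/c + tau|`. This linear-in-`f` behaviour is the
#' low-frequency roll-off of first-order differential arrays
#' (about 6 dB/octave).
#'
#' @inheritParams system_response
#'
#' @return Approximate magnitude(s). Errors unless `params$beta == 1`.
#' @examples
#' small_f_approximation(0, 100)
#' @export
small_f_approximation <- function(theta, f, params = beam_params(), cfg = array_config()) {
  if (params$beta != 1) {
    abort("The small-frequency approximation is stated for `beta = 1` only.")
  }
  if (any(!is.finite(f)) || any(f < 0)) {
    abort("`f` must be nonnegative and finite (Hz).")
  }
  delay <- cfg$d * cos(theta * pi / 180) / cfg$c + params$tau
  2 * pi * f * abs(delay)
}

#' Lower bound of the beamformer magnitude response
#'
#' Over all angles, frequencies and delays the magnitude response is bounded
#' below by `|1 - beta|` (attained where the phase term vanishes, e.g. at
#' `f = 0`). For `beta = 1` the bound is zero: the equally-weighted system
#' fully cancels at 0 Hz.
#'
#' @param beta Nonnegative weight(s).
#' @return `|1 - beta|`, vectorised.
#' @examples
#' response_lower_bound(c(0.3, 1, 4))
#' @export
response_lower_bound <- function(beta) {
  if (any(!is.finite(beta)) || any(beta < 0)) {
    abort("`beta` must be nonnegative and finite.")
  }
  abs(1 - beta)
}

#' Reciprocal weight equivalence
#'
#' A weight `beta < 1` is equivalent to the reciprocal weight `1/beta > 1`
#' up to a constant gain: `|H(beta, theta, f)| = beta * |H(1/beta, theta, f)|`
#' pointwise. Normalised beam patterns for `beta` and `1/beta` therefore
#' coincide, so analysis can be restricted to `beta <= 1`.
#'
#' @param beta A single weight in (0, 1).
#' @return A list with `equivalent_beta = 1/beta` and `scale = beta`.
#' @examples
#' reciprocal_equivalent(0.5)
#' @export
reciprocal_equivalent <- function(beta) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta)) {
    abort("`beta` must be a single finite number.")
  }
  if (beta == 0) abort("`beta` = 0 has no reciprocal equivalent (degenerate).")
  if (beta <= 0 || beta >= 1) abort("`beta` must lie strictly in (0, 1).")
  list(equivalent_beta = 1 / beta, scale = beta)
}
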