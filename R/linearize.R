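# Piecewise-linear approximation of the on-axis frequency response.
#
# All frequency-response linearisation is done at theta = 0 (on-axis target):
# with the default geometry this is the only incidence angle for which the
# endpoint-minimising weight equals the conventional turning value 0.45.

#' Weight at which the band-edge response is minimal (the turning weight)
#'
#' At `theta = 0` the exact magnitude at the band-limit frequency `f_max` is
#' `sqrt(1 + beta^2 - 2 beta cos(phi))` with
#' `phi = 2 pi f_max (d/c + tau)`; as a function of `beta` it is minimised at
#' `beta = cos(phi)`, clamped to \[0, 1\]. With the default CI geometry
#' (`d` = 0.01 m, `c` = 340 m/s, `tau` = 0, `f_max` = 6000 Hz) this evaluates
#' to 0.45 (two decimals).
#'
#' @param cfg An [array_config()].
#' @param tau Algorithm delay in seconds.
#' @param f_max Band-limit frequency in Hz (> 0).
#' @return The turning weight in \[0, 1\] (unrounded).
#' @examples
#' round(find_turning_weight(), 2)
#' @export
find_turning_weight <- function(cfg = array_config(), tau = 0, f_max = 6000) {
  if (f_max <= 0) abort("`f_max` must be positive.")
  phi <- 2 * pi * f_max * (cfg$d / cfg$c + tau)
  min(max(cos(phi), 0), 1)
}

#' Piecewise-linear model of the on-axis frequency response
#'
#' Constructs the low-complexity compensation model: for each weight `beta`
#' the exact on-axis response over \[0, `f_max`\] is approximated by the
#' straight line through its endpoints `(0, |1 - beta|)` and
#' `(f_max, endpoint)`, where the endpoint itself is linearised in `beta`
#' piecewise about the turning weight. With the default geometry the model's
#' frequency slope reproduces the conventional numeric coefficients
#' 1.279e-4 * beta (low branch) and 2.145e-4 * beta - 3.896e-5 (high branch)
#' to better than 0.5%.
#'
#' @param cfg An [array_config()].
#' @param tau Algorithm delay in seconds (on-axis analysis).
#' @param f_max Band-limit frequency in Hz.
#' @param beta_turn Turning weight; default `NULL` computes it exactly via
#'   [find_turning_weight()]. Pass `0.45` to reproduce the conventional
#'   rounded value.
#'
#' @return An object of class `linearized_model`, a list with the geometry,
#'   `beta_turn`, the endpoint magnitudes `H1` (=1 at `beta` 0), `H2` (at the
#'   turning weight) and `H3` (at `beta` 1), and the slope coefficients.
#' @examples
#' m <- linearized_model()
#' tidy(m)
#' @export
linearized_model <- function(cfg = array_config(), tau = 0, f_max = 6000,
                             beta_turn = NULL) {
  if (f_max <= 0) abort("`f_max` must be positive.")
  if (tau < 0) abort("`tau` must be nonnegative.")
  bt <- beta_turn %||% find_turning_weight(cfg, tau, f_max)
  if (bt < 0 || bt > 1) abort("`beta_turn` must lie in [0, 1].")
  delay <- cfg$d / cfg$c + tau
  h_at <- function(beta, f) h_mag(beta, 2 * pi * f * delay)
  H2 <- h_at(bt, f_max)
  H3 <- h_at(1, f_max)
  # frequency slope written as slope(beta) = a * beta - b per branch
  if (bt > 0) {
    a_low <- (1 - (1 - H2) / bt) / f_max
  } else {
    a_low <- NA_real_ # degenerate low branch (turning weight at 0)
  }
  a_high <- (1 + (H3 - H2) / (1 - bt)) / f_max
  b_high <- (1 - H2 + bt * (H3 - H2) / (1 - bt)) / f_max
  structure(
    list(d = cfg$d, c = cfg$c, tau = tau, f_max = f_max,
         beta_turn = bt, H1 = 1, H2 = H2, H3 = H3,
         coef_low = a_low, coef_high_beta = a_high, coef_high_const = b_high,
         exact = h_at),
    class = "linearized_model"
  )
}

#' @export
print.linearized_model <- function(x, ...) {
  cat("<linearized_model> piecewise-linear on-axis response\n")
  cat(sprintf("  geometry: d = %g m, c = %g m/s, tau = %.4g s, f_max = %g Hz\n",
              x$d, x$c, x$tau, x$f_max))
  cat(sprintf("  turning weight = %.4f;  H2 = %.4f, H3 = %.4f\n",
              x$beta_turn, x$H2, x$H3))
  if (is.finite(x$coef_low %||% NA_real_)) {
    cat(sprintf("  H_eva = (1-b) + %.4g*b*f              (b <= %.4f)\n",
                x$coef_low, x$beta_turn))
  }
  cat(sprintf("  H_eva = (1-b) + (%.4g*b - %.4g)*f  (b >  %.4f)\n",
              x$coef_high_beta, x$coef_high_const, x$beta_turn))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the linearised-model coefficients
#'
#' @param x A [linearized_model()].
#' @param ... Unused.
#' @return A tibble with one row per coefficient of the frequency slope
#'   (`term`, `estimate`): the `beta * f` coefficient on the low-weight
#'   branch and the `beta * f` and constant-`f` coefficients on the
#'   high-weight branch.
#' @method tidy linearized_model
#' @export
tidy.linearized_model <- function(x, ...) {
  tibble(
    term = c("low_branch_beta_f", "high_branch_beta_f", "high_branch_const_f"),
    estimate = c(x$coef_low, x$coef_high_beta, x$coef_high_const)
  )
}

#' One-row summary of a linearised model
#'
#' @param x A [linearized_model()].
#' @param ... Unused.
#' @return A one-row tibble with the geometry, turning weight and endpoint
#'   magnitudes.
#' @method glance linearized_model
#' @export
glance.linearized_model <- function(x, ...) {
  tibble(d = x$d, c = x$c, tau = x$tau, f_max = x$f_max,
         beta_turn = x$beta_turn, H1 = x$H1, H2 = x$H2, H3 = x$H3)
}

check_beta01 <- function(beta) {
  if (any(!is.finite(beta)) || any(beta < 0) || any(beta > 1)) {
    abort(paste0("`beta` must lie in [0, 1]; reduce larger weights with ",
                 "reciprocal_equivalent() first."))
  }
  invisible(beta)
}

#' Linearised response endpoint at the band-limit frequency
#'
#' The `f_max` endpoint of the linearised response, interpolated linearly in
#' `beta` between the anchors `H1 = 1` (at `beta` 0), `H2` (at the turning
#' weight, where `H2` and `H3` are exact on-axis magnitudes) and `H3` (at
#' `beta` 1).
#'
#' @param model A [linearized_model()].
#' @param beta Weight(s) in \[0, 1\].
#' @return Endpoint magnitude(s) at `f_max`.
#' @examples
#' m <- linearized_model()
#' endpoint_response(m, c(0, m$beta_turn, 1))
#' @export
endpoint_response <- function(model, beta) {
  stopifnot(inherits(model, "linearized_model"))
  check_beta01(beta)
  bt <- model$beta_turn
  if (bt > 0) {
    ifelse(beta <= bt,
           1 - (beta / bt) * (1 - model$H2),
           model$H2 + (beta - bt) / (1 - bt) * (model$H3 - model$H2))
  } else {
    1 + beta * (model$H3 - 1)
  }
}

#' Linearised on-axis frequency response
#'
#' The straight line through `(0, |1 - beta|)` and
#' `(f_max, endpoint_response(model, beta))` — the response the compensation
#' algorithm uses in place of the exact one.
#'
#' @param model A [linearized_model()].
#' @param beta Weight(s) in \[0, 1\].
#' @param f Frequencies in Hz, normally within \[0, `f_max`\]; values above
#'   `f_max` are extrapolated with a warning.
#' @return Approximate magnitude(s).
#' @examples
#' linearized_response(linearized_model(), 0.2, 3000)
#' @export
linearized_response <- function(model, beta, f) {
  stopifnot(inherits(model, "linearized_model"))
  check_beta01(beta)
  if (any(!is.finite(f)) || any(f < 0)) abort("`f` must be nonnegative (Hz).")
  if (any(f > model$f_max)) {
    warn(sprintf("Extrapolating the linearised response beyond f_max = %g Hz.",
                 model$f_max))
  }
  (1 - beta) + (endpoint_response(model, beta) - (1 - beta)) * f / model$f_max
}

#' Exact on-axis response used by the compensation model
#'
#' Convenience accessor for the exact closed-form magnitude at `theta = 0`
#' with the model's geometry (equivalent to [system_response()] at
#' `theta = 0`).
#'
#' @inheritParams linearized_response
#' @return Exact magnitude(s).
#' @export
exact_response <- function(model, beta, f) {
  stopifnot(inherits(model, "linearized_model"))
  model$exact(beta, f)
}
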