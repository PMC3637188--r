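#' Per-channel compensation gains for the CI filter bank
#'
#' The compensation multiplies each filter-bank channel by the ratio of the
#' on-axis response at a reference centre frequency to the response at that
#' channel's centre frequency, so that after beamforming all channels sit at
#' the reference level. `mode = "linearized"` uses the piecewise-linear
#' response (the low-complexity algorithm); `mode = "ideal"` uses the exact
#' closed form.
#'
#' The reference channel defaults to channel 4 (1005 Hz), the band nearest the
#' 1 kHz region where speech energy concentrates.
#'
#' Weights above 1 are reduced to their reciprocal equivalent: gains are
#' response ratios, and the constant factor relating `beta` and `1/beta`
#' responses cancels.
#'
#' @param model A [linearized_model()] (geometry and delay of the beamformer).
#' @param beta Beamformer weight (>= 0).
#' @param bank Band plan tibble, see [filter_bank_spec()].
#' @param reference_channel Index of the reference channel.
#' @param mode `"linearized"` or `"ideal"`.
#'
#' @return A tibble of class `channel_gains` with columns `channel`, `center`,
#'   `response` (at the channel centre) and `gain`; attributes
#'   `reference_channel`, `mode`, `beta`. The gain at the reference channel
#'   is 1.
#' @examples
#' channel_gains(linearized_model(), beta = 1, mode = "ideal")
#' @export
channel_gains <- function(model, beta, bank = filter_bank_spec(),
                          reference_channel = 4,
                          mode = c("linearized", "ideal")) {
  stopifnot(inherits(model, "linearized_model"))
  mode <- match.arg(mode)
  validate_bank_spec(bank)
  if (!reference_channel %in% bank$channel) {
    abort("`reference_channel` must be one of the band-plan channels.")
  }
  if (!is.finite(beta) || beta < 0) abort("`beta` must be nonnegative.")
  beta_eff <- if (beta > 1) 1 / beta else beta
  resp <- switch(mode,
    linearized = linearized_response(model, beta_eff, bank$center),
    ideal      = exact_response(model, beta_eff, bank$center)
  )
  ref <- resp[match(reference_channel, bank$channel)]
  if (any(resp == 0)) {
    abort("A channel centre frequency has zero response; gains are undefined.")
  }
  out <- tibble(channel = bank$channel, center = bank$center,
                response = resp, gain = ref / resp)
  structure(out, reference_channel = reference_channel, mode = mode,
            beta = beta,
            class = c("channel_gains", class(tibble())))
}
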