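#' Multi-frequency beam pattern of the delay-and-subtract array
#'
#' Evaluates [system_response()] on a full angular grid for a set of
#' frequencies. By default the frequencies are the eight centre frequencies of
#' the CI filter bank (see [filter_bank_spec()]), so that the pattern shows
#' how the beam grows with frequency — the broadband low-frequency roll-off.
#'
#' @param params A [beam_params()].
#' @param cfg An [array_config()].
#' @param frequencies Frequencies in Hz (nonempty).
#' @param angle_step Angular grid step in degrees; must divide 360.
#'
#' @return A tibble of class `beam_pattern` with columns `theta_deg`,
#'   `frequency`, `magnitude`, covering theta in \[-180, 180\]. Attributes:
#'   `beta`, `tau`, `normalized` (FALSE for raw magnitudes).
#' @examples
#' beam_pattern(beam_params("dipolar"), frequencies = c(274, 1005))
#' @export
beam_pattern <- function(params = beam_params(), cfg = array_config(),
                         frequencies = filter_bank_spec()$center,
                         angle_step = 1) {
  if (length(frequencies) == 0L) abort("`frequencies` must be nonempty.")
  if (!is.numeric(angle_step) || angle_step <= 0 ||
      abs(360 / angle_step - round(360 / angle_step)) > 1e-9) {
    abort("`angle_step` must be a positive divisor of 360.")
  }
  grid <- tidyr::expand_grid(
    theta_deg = seq(-180, 180, by = angle_step),
    frequency = frequencies
  )
  out <- dplyr::mutate(
    grid,
    magnitude = system_response(.data$theta_deg, .data$frequency, params, cfg)
  )
  new_beam_pattern(out, beta = params$beta, tau = params$tau, normalized = FALSE)
}

new_beam_pattern <- function(x, beta, tau, normalized) {
  structure(
    as_tibble(x),
    beta = beta, tau = tau, normalized = normalized,
    class = c("beam_pattern", class(tibble()))
  )
}

#' Normalise a beam pattern at 0 Hz
#'
#' Divides all magnitudes by the 0 Hz response `|1 - beta|`, which is
#' independent of incidence angle (so its circular average equals it). After
#' normalisation the 0 Hz level is 1 for every angle, which puts patterns with
#' different weights on a common scale: reciprocal weights `beta` and `1/beta`
#' then yield identical surfaces.
#'
#' @param pattern A [beam_pattern()].
#' @return A `beam_pattern` tibble with rescaled magnitudes
#'   (`normalized = TRUE`).
#' @examples
#' p <- beam_pattern(beam_params(beta = 0.5), frequencies = 1005)
#' normalize_at_dc(p)
#' @export
normalize_at_dc <- function(pattern) {
  stopifnot(inherits(pattern, "beam_pattern"))
  beta <- attr(pattern, "beta")
  dc <- abs(1 - beta)
  if (dc == 0) {
    abort("Normalisation is degenerate for `beta` = 1: the 0 Hz response is zero.")
  }
  out <- dplyr::mutate(as_tibble(pattern), magnitude = .data$magnitude / dc)
  new_beam_pattern(out, beta = beta, tau = attr(pattern, "tau"), normalized = TRUE)
}

#' Polar plot of a beam pattern
#'
#' @param object A [beam_pattern()].
#' @param ... Unused.
#' @return A ggplot object: one polar trace per frequency.
#' @method autoplot beam_pattern
#' @export
autoplot.beam_pattern <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(.data$theta_deg, .data$magnitude,
                 colour = factor(.data$frequency))
  ) +
    ggplot2::geom_line() +
    ggplot2::coord_polar(start = pi) +
    ggplot2::scale_x_continuous(limits = c(-180, 180),
                                breaks = seq(-180, 135, by = 45)) +
    ggplot2::labs(
      x = "incidence angle (deg)", y = "|H|", colour = "f (Hz)",
      title = sprintf("beta = %g, tau = %.3g s%s", attr(object, "beta"),
                      attr(object, "tau"),
                      if (isTRUE(attr(object, "normalized"))) ", normalised at 0 Hz" else "")
    ) +
    ggplot2::theme_minimal()
}

#' Write a beam pattern to CSV (wide) or JSON
#'
#' The CSV layout is one row per angle: a `theta_deg` column followed by one
#' column per frequency (named `f<Hz>`).
#'
#' @param pattern A [beam_pattern()].
#' @param path Output file path; format chosen by extension (`.csv`/`.json`).
#' @return `path`, invisibly.
#' @export
write_beam_pattern <- function(pattern, path) {
  stopifnot(inherits(pattern, "beam_pattern"))
  wide <- tidyr::pivot_wider(
    as_tibble(pattern),
    names_from = "frequency", values_from = "magnitude",
    names_prefix = "f"
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    payload <- list(
      beta = attr(pattern, "beta"), tau = attr(pattern, "tau"),
      normalized = isTRUE(attr(pattern, "normalized")), pattern = wide
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  } else {
    write.csv(wide, path, row.names = FALSE)
  }
  invisible(path)
}
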