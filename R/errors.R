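# Error metrics quantifying the accuracy of the piecewise-linear response.

#' Relative error of the linearised response
#'
#' Percent deviation of the linearised response from the exact on-axis
#' response: `100 * (H_eva - H) / H`. Undefined where the exact response is
#' zero (only `beta = 1`, `f` with vanishing phase, e.g. `f = 0`); such points
#' yield `NA` with a warning unless dropped by the caller.
#'
#' @param model A [linearized_model()].
#' @param beta Weight(s) in \[0, 1\].
#' @param f Frequencies in Hz.
#' @return Relative error(s) in percent.
#' @examples
#' relative_error(linearized_model(), 1, 6000)
#' @export
relative_error <- function(model, beta, f) {
  h <- exact_response(model, beta, f)
  heva <- linearized_response(model, beta, f)
  out <- ifelse(h > 0, 100 * (heva - h) / h, NA_real_)
  if (anyNA(out)) {
    warn("Relative error is undefined where the exact response is zero; returning NA.")
  }
  out
}

#' Energy-balancing normalisation coefficient
#'
#' The linearised response systematically over- or under-weights parts of the
#' band, so before comparing shapes the two responses are put at equal energy
#' over \[0, `f_max`\]. On the uniform grid `f_i = (i/N) f_max`, `i = 0..N`,
#' the energy ratio is `sum(H^2) / sum(H_eva^2)`; the amplitude coefficient
#' that equalises the energies when applied to the linearised response is its
#' square root (default). `variant = "energy"` returns the raw squared-ratio
#' form.
#'
#' @param model A [linearized_model()].
#' @param beta A single weight in \[0, 1\].
#' @param n_points Number of grid intervals `N` (>= 2); the coefficient
#'   stabilises rapidly with `N`.
#' @param variant `"amplitude"` (default, square root) or `"energy"`.
#' @return A positive scalar; 1 when `beta = 0` (the responses coincide).
#' @examples
#' normalization_coefficient(linearized_model(), 1)
#' @export
normalization_coefficient <- function(model, beta, n_points = 2000,
                                      variant = c("amplitude", "energy")) {
  stopifnot(inherits(model, "linearized_model"))
  variant <- match.arg(variant)
  check_beta01(beta)
  if (length(beta) != 1L) abort("`beta` must be a single weight.")
  if (n_points < 2) abort("`n_points` must be at least 2.")
  f <- (0:n_points) / n_points * model$f_max
  h <- exact_response(model, beta, f)
  heva <- linearized_response(model, beta, f)
  if (all(heva == 0)) abort("Degenerate: the linearised response is identically zero.")
  ratio <- sum(h^2) / sum(heva^2)
  if (variant == "amplitude") sqrt(ratio) else ratio
}

#' Normalised error of the energy-balanced linearised response
#'
#' Percent deviation after scaling the linearised response to the energy of
#' the exact one: `100 * (G * H_eva - H) / H`, with `G` the amplitude
#' coefficient from [normalization_coefficient()]. This isolates the shape
#' (spectral-tilt) error of the compensation from its overall gain.
#'
#' @inheritParams relative_error
#' @param G Normalisation coefficient; defaults to the amplitude coefficient
#'   for `beta` (requires scalar `beta` in that case).
#' @return Normalised error(s) in percent.
#' @examples
#' normalized_error(linearized_model(), 1, 50)
#' @export
normalized_error <- function(model, beta, f, G = NULL) {
  G <- G %||% normalization_coefficient(model, beta)
  h <- exact_response(model, beta, f)
  heva <- linearized_response(model, beta, f)
  out <- ifelse(h > 0, 100 * (G * heva - h) / h, NA_real_)
  if (anyNA(out)) {
    warn("Normalised error is undefined where the exact response is zero; returning NA.")
  }
  out
}

#' Average absolute normalised error over the band
#'
#' Mean of `|normalized_error|` over the uniform frequency grid
#' `f_i = (i/N) f_max`, `i = 1..N` (the `f = 0` point is excluded, where the
#' error is undefined for `beta = 1`).
#'
#' @inheritParams normalization_coefficient
#' @param n_points Number of frequency points `N`; 50 by convention.
#' @return A nonnegative percent scalar.
#' @examples
#' average_error(linearized_model(), 1)
#' @export
average_error <- function(model, beta, n_points = 50) {
  stopifnot(inherits(model, "linearized_model"))
  if (n_points < 1) abort("`n_points` must be at least 1.")
  f <- (1:n_points) / n_points * model$f_max
  G <- normalization_coefficient(model, beta)
  mean(abs(normalized_error(model, beta, f, G = G)))
}

#' Full error report over a weight-by-frequency grid
#'
#' Evaluates the exact and linearised responses, the relative and normalised
#' errors on a `beta` x `f` grid, and the per-weight normalisation
#' coefficient and average error.
#'
#' @param model A [linearized_model()].
#' @param beta_grid Weights (default `0, 0.02, ..., 1`).
#' @param f_grid Frequencies in Hz (default `50, 100, ..., f_max`; excludes 0
#'   where the relative error can be undefined).
#' @param n_points `N` for the average error.
#'
#' @return An object of class `error_report`: list with
#'   * `surface`: tibble `beta`, `frequency`, `exact`, `linearized`,
#'     `relative_error`, `normalized_error`;
#'   * `by_beta`: tibble `beta`, `G`, `average_error`;
#'   * `tau`, `model`.
#' @examples
#' rep <- error_report(linearized_model(), beta_grid = c(0, 0.5, 1))
#' glance(rep)
#' @export
error_report <- function(model, beta_grid = seq(0, 1, by = 0.02),
                         f_grid = NULL, n_points = 50) {
  stopifnot(inherits(model, "linearized_model"))
  check_beta01(beta_grid)
  f_grid <- f_grid %||% seq(50, model$f_max, by = 50)
  rows <- purrr::map_dfr(beta_grid, function(b) {
    G <- normalization_coefficient(model, b)
    h <- exact_response(model, b, f_grid)
    heva <- linearized_response(model, b, f_grid)
    tibble(
      beta = b, frequency = f_grid, exact = h, linearized = heva,
      relative_error = ifelse(h > 0, 100 * (heva - h) / h, NA_real_),
      normalized_error = ifelse(h > 0, 100 * (G * heva - h) / h, NA_real_)
    )
  })
  by_beta <- purrr::map_dfr(beta_grid, function(b) {
    tibble(beta = b,
           G = normalization_coefficient(model, b),
           average_error = average_error(model, b, n_points = n_points))
  })
  structure(list(surface = rows, by_beta = by_beta, tau = model$tau,
                 model = model),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("<error_report> tau = %.4g s, %d weights x %d frequencies\n",
              x$tau, nrow(x$by_beta),
              length(unique(x$surface$frequency))))
  print(glance(x))
  invisible(x)
}

#' @rdname error_report
#' @param x An `error_report`.
#' @param ... Unused.
#' @return `tidy()` returns the error surface as a long tibble.
#' @method tidy error_report
#' @export
tidy.error_report <- function(x, ...) x$surface

#' @rdname error_report
#' @return `glance()` returns a one-row tibble with the error-surface extremes
#'   and the maximum average error.
#' @method glance error_report
#' @export
glance.error_report <- function(x, ...) {
  tibble(
    relative_min = min(x$surface$relative_error, na.rm = TRUE),
    relative_max = max(x$surface$relative_error, na.rm = TRUE),
    normalized_min = min(x$surface$normalized_error, na.rm = TRUE),
    normalized_max = max(x$surface$normalized_error, na.rm = TRUE),
    average_max = max(x$by_beta$average_error),
    tau = x$tau
  )
}

#' Heatmap of an error surface
#'
#' @param object An [error_report()].
#' @param metric `"relative_error"` or `"normalized_error"`.
#' @param ... Unused.
#' @return A ggplot tile plot of the chosen error over (frequency, beta).
#' @method autoplot error_report
#' @export
autoplot.error_report <- function(object,
                                  metric = c("relative_error", "normalized_error"),
                                  ...) {
  metric <- match.arg(metric)
  ggplot2::ggplot(object$surface,
                  ggplot2::aes(.data$frequency, .data$beta,
                               fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::labs(x = "frequency (Hz)", y = "weight beta",
                  fill = paste0(metric, " (%)")) +
    ggplot2::theme_minimal()
}
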