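#' Plot a balance-theory sweep
#'
#' Normalized (or raw) population rates against the optogenetic drive, with
#' vertical marks at the breakpoints where the active set changes.
#'
#' @param object a `balance_sweep` from [sweep_opto()].
#' @param normalized plot rates normalized to baseline (default) or raw Hz.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot balance_sweep
#' @export
autoplot.balance_sweep <- function(object, normalized = TRUE, ...) {
  y <- if (normalized) "norm_rate" else "rate"
  bps <- attr(object, "breakpoints")
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$I_opto, y = .data[[y]],
                                    color = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(I[opto] ~ "(nA/cm"^2 * ")"),
                  y = if (normalized) "rate / baseline" else "rate (Hz)",
                  color = "population") +
    ggplot2::theme_minimal()
  if (nrow(bps) > 0) {
    p <- p + ggplot2::geom_vline(data = bps,
                                 ggplot2::aes(xintercept = .data$I_opto),
                                 linetype = "dashed", color = "grey50")
  }
  p
}

#' Plot a simulated intensity sweep
#'
#' Thick lines: population-averaged normalized rates. Thin lines: a random
#' subset of single neurons, illustrating the heterogeneity of responses in
#' the balanced regime.
#'
#' @param object a `sim_sweep` from [intensity_sweep_sim()].
#' @param n_examples single neurons per population to overlay.
#' @param seed subsampling seed.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot sim_sweep
#' @export
autoplot.sim_sweep <- function(object, n_examples = 10, seed = 1, ...) {
  set.seed(seed)
  ex <- object$neurons |>
    dplyr::distinct(.data$population, .data$neuron) |>
    group_by(.data$population) |>
    dplyr::slice_sample(n = n_examples) |>
    ungroup()
  thin <- dplyr::semi_join(object$neurons, ex, by = c("population", "neuron"))
  ggplot2::ggplot(object$population,
                  ggplot2::aes(x = .data$Gamma, y = .data$norm_rate,
                               color = .data$population)) +
    ggplot2::geom_line(data = thin,
                       ggplot2::aes(group = .data$neuron), alpha = 0.25,
                       linewidth = 0.3) +
    ggplot2::geom_line(linewidth = 1.2) +
    ggplot2::labs(x = expression(Gamma[opto] ~ "(mW/mm"^2 * ")"),
                  y = "rate / baseline", color = "population") +
    ggplot2::theme_minimal()
}

#' Plot a normalized response table
#'
#' Population normalized spike rate against laser intensity per unit class,
#' with bootstrap SEM ribbons when available.
#'
#' @param object a `response_table` from [normalize_responses()].
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot response_table
#' @export
autoplot.response_table <- function(object, ...) {
  pop <- object$population
  p <- ggplot2::ggplot(pop, ggplot2::aes(x = .data$intensity,
                                         y = .data$norm_rate,
                                         color = .data$class)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = expression("laser intensity (mW/mm"^2 * ")"),
                  y = "normalized spike rate", color = "class") +
    ggplot2::theme_minimal()
  if ("sem" %in% names(pop)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$norm_rate - .data$sem,
                   ymax = .data$norm_rate + .data$sem),
      width = 0
    )
  }
  p
}

#' Plot response-category fractions
#'
#' Stacked bars of the increase / decrease / no-change / silenced fractions
#' per class and intensity.
#'
#' @param fractions output of [response_fractions()].
#' @return A ggplot.
#' @export
plot_fractions <- function(fractions) {
  ggplot2::ggplot(fractions,
                  ggplot2::aes(x = factor(.data$intensity),
                               y = .data$fraction, fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~class) +
    ggplot2::labs(x = expression("laser intensity (mW/mm"^2 * ")"),
                  y = "fraction of units", fill = NULL) +
    ggplot2::theme_minimal()
}
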