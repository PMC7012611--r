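#' Tidy a balanced-state solution
#'
#' @param x a `balance_state` from [solve_balance()].
#' @param ... unused.
#' @return A tibble with one row per population: `population`, `rate` (Hz),
#'   `active`, `net_input` (nA/cm^2, 0 for active populations).
#' @method tidy balance_state
#' @export
tidy.balance_state <- function(x, ...) x$rates

#' @rdname tidy.balance_state
#' @method glance balance_state
#' @export
glance.balance_state <- function(x, ...) {
  tibble(n_active = length(x$active), consistent = x$consistent,
         residual = x$residual)
}

#' Tidy a paradoxical-effect audit
#'
#' @param x a `paradox_audit`.
#' @param ... unused.
#' @return The criteria tibble (`criterion`, `holds`, `margin`).
#' @method tidy paradox_audit
#' @export
tidy.paradox_audit <- function(x, ...) x$criteria

#' @rdname tidy.paradox_audit
#' @method glance paradox_audit
#' @export
glance.paradox_audit <- function(x, ...) {
  tibble(topology = x$topology, paradoxical = x$paradoxical,
         chi_II = x$chi_II, agreement = x$agreement,
         jee_star = x$jee_star)
}

#' Tidy a slope estimate
#'
#' @param x a `slope_estimate` from [response_slope()].
#' @param ... unused.
#' @return The per-class slope tibble with bootstrap SEMs.
#' @method tidy slope_estimate
#' @export
tidy.slope_estimate <- function(x, ...) x$slopes

#' @rdname tidy.slope_estimate
#' @method glance slope_estimate
#' @export
glance.slope_estimate <- function(x, ...) {
  if (is.null(x$ratio)) {
    return(tibble(ratio = NA_real_, ratio_sem = NA_real_))
  }
  tibble(ratio = x$ratio$estimate, ratio_sem = x$ratio$sem,
         ratio_ci_low = x$ratio$ci[1], ratio_ci_high = x$ratio$ci[2])
}

#' Tidy an activity summary
#'
#' @param x an `activity_summary` from [summarize_activity()].
#' @param ... unused.
#' @return The per-population tibble.
#' @method tidy activity_summary
#' @export
tidy.activity_summary <- function(x, ...) x$population

#' Tidy a response table
#'
#' @param x a `response_table` from [normalize_responses()].
#' @param ... unused.
#' @return The population-level tibble.
#' @method tidy response_table
#' @export
tidy.response_table <- function(x, ...) x$population
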