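#' Balance equations in the large-N,K limit
#'
#' When synapses scale as `1/sqrt(K)`, the net input into every active
#' population must remain comparable to the rheobase as `K` grows, which
#' forces the linear *balance equations*
#' `2 * J0 * r0 + I_opto + sum_b polarity[b] * J[, b] * r[b] = 0`.
#' `balance_problem()` assembles the signed matrix `A` (see
#' [effective_matrix()]) and the input vector `c` (nA/cm^2) for a given
#' optogenetic drive.
#'
#' @param spec a [circuit_spec()].
#' @param I_opto optogenetic current (nA/cm^2) injected into the target
#'   populations; alternative to `Gamma`.
#' @param Gamma laser intensity (mW/mm^2), converted through
#'   [opto_current()]; overrides `I_opto` when supplied.
#' @return A list of class `balance_problem` with `A`, `c`, `populations`.
#' @export
balance_problem <- function(spec, I_opto = 0, Gamma = NULL) {
  if (!is.null(Gamma)) I_opto <- opto_current(Gamma, spec$opto)
  pops <- spec$populations
  drive <- setNames(rep(0, length(pops)), pops)
  drive[intersect(spec$opto$targets, pops)] <- I_opto
  structure(
    list(A = effective_matrix(spec), c = 2 * spec$J0 * spec$r0 + drive,
         populations = pops, spec = spec),
    class = "balance_problem"
  )
}

#' Solve the balance equations on a given active set
#'
#' Solves `A[act, act] %*% r[act] = -c[act]` for the populations assumed
#' active, pins silent populations at zero rate, and evaluates the net input
#' into each silent population. The solution is *consistent* when all active
#' rates are nonnegative (within `tol`) and every silent population receives
#' hyperpolarizing (negative) net input, so that its silence is
#' self-consistent.
#'
#' @param problem a [balance_problem()].
#' @param active character vector of active populations (default: all).
#' @param tol nonnegativity tolerance on rates; silent-input strictness.
#' @return A list of class `balance_state` with a tidy `rates` tibble
#'   (`population`, `rate` in Hz, `active`, `net_input` in nA/cm^2),
#'   the `active` set, `consistent` flag, and the residual of the active
#'   block.
#' @examples
#' pr <- balance_problem(load_architecture("two_pop"))
#' solve_balance(pr)$rates$rate  # c(28.33, 33.06)
#' @export
solve_balance <- function(problem, active = problem$populations,
                          tol = 1e-12) {
  pops <- problem$populations
  stopifnot(all(active %in% pops))
  active <- pops[pops %in% active]  # canonical order
  silent <- setdiff(pops, active)
  r <- setNames(rep(0, length(pops)), pops)
  residual <- 0
  if (length(active) > 0) {
    Aact <- problem$A[active, active, drop = FALSE]
    d <- det(Aact)
    if (!is.finite(d) || abs(d) < 1e-10 * max(1, max(abs(Aact)))^length(active)) {
      abort(paste0(
        "degenerate determinant for active set {",
        paste(active, collapse = ","),
        "}: the balance equations are fine-tuned and have no unique solution"
      ))
    }
    r[active] <- solve(Aact, -problem$c[active])
    residual <- max(abs(problem$c[active] +
                          Aact %*% r[active]))
  }
  net <- problem$c + drop(problem$A %*% r)
  consistent <- all(r[active] >= -tol) &&
    (length(silent) == 0 || all(net[silent] < tol))
  r[abs(r) <= tol] <- 0
  is_active <- pops %in% active
  structure(
    list(
      rates = tibble(population = pops, rate = unname(r),
                     active = is_active,
                     net_input = ifelse(is_active, 0, unname(net))),
      active = active, consistent = consistent, residual = residual,
      populations = pops
    ),
    class = "balance_state"
  )
}

#' Enumerate all self-consistent balanced states
#'
#' Brute-force enumeration of every active subset (including the all-silent
#' state): each nonempty subset is solved with [solve_balance()] and kept if
#' consistent; the all-silent state is consistent only if every population
#' receives hyperpolarizing input at rest. States are returned ordered by
#' active-set size, largest first. Multiple consistent (partially balanced)
#' states can coexist; the attribute `multiplicity` records how many were
#' found.
#'
#' @param problem a [balance_problem()].
#' @param tol consistency tolerance, as in [solve_balance()].
#' @return A list of `balance_state` objects with attribute `multiplicity`.
#' @export
consistent_states <- function(problem, tol = 1e-12) {
  pops <- problem$populations
  n <- length(pops)
  states <- list()
  for (k in seq(n, 0)) {
    if (k == 0) {
      subsets <- list(character(0))
    } else {
      subsets <- utils::combn(pops, k, simplify = FALSE)
    }
    for (act in subsets) {
      st <- tryCatch(solve_balance(problem, active = act, tol = tol),
                     error = function(e) NULL)
      if (!is.null(st) && st$consistent) states[[length(states) + 1]] <- st
    }
  }
  attr(states, "multiplicity") <- length(states)
  states
}

#' Sweep the optogenetic drive and track the balanced state
#'
#' Solves the balance equations along a grid of optogenetic currents (or
#' laser intensities). At each grid point the consistent state is selected:
#' the state whose active set matches the previous grid point is preferred
#' (continuity), falling back to the largest consistent active set;
#' multiplicity is recorded. Between grid points where the active set
#' changes, the breakpoint -- the drive at which a population's rate reaches
#' zero and the system switches to a reduced (partially balanced) set of
#' equations -- is located by bisection. Rates are piecewise linear in the
#' drive between breakpoints.
#'
#' @param spec a [circuit_spec()].
#' @param I_opto grid of optogenetic currents (nA/cm^2); must include 0 so
#'   rates can be normalized to baseline.
#' @param Gamma alternatively, a grid of laser intensities (mW/mm^2).
#' @param tol consistency tolerance.
#' @param bisect_tol breakpoint localization tolerance on `I_opto`.
#' @return A tibble of class `balance_sweep` in long format with columns
#'   `I_opto`, `Gamma` (NA when the sweep is specified in current),
#'   `population`, `rate`, `norm_rate`, `active`, `active_set`,
#'   `multiplicity`; breakpoints are stored in `attr(, "breakpoints")`.
#' @export
sweep_opto <- function(spec, I_opto = NULL, Gamma = NULL,
                       tol = 1e-12, bisect_tol = 1e-8) {
  if (is.null(I_opto) && is.null(Gamma)) {
    abort("supply a grid of I_opto or Gamma values")
  }
  if (!is.null(Gamma)) {
    Gamma <- sort(Gamma)
    I_grid <- opto_current(Gamma, spec$opto)
  } else {
    I_grid <- sort(I_opto)
    Gamma <- rep(NA_real_, length(I_grid))
  }
  if (min(I_grid) > 0) abort("the sweep grid must include the baseline (0)")

  base_state <- solve_balance(balance_problem(spec, I_opto = 0), tol = tol)
  if (!base_state$consistent) {
    abort("the all-active baseline state is not consistent for this circuit")
  }
  pops <- spec$populations
  base_rates <- setNames(base_state$rates$rate, pops)

  pick_state <- function(I, prev_active) {
    sts <- consistent_states(balance_problem(spec, I_opto = I), tol = tol)
    if (length(sts) == 0) {
      abort(paste0("no consistent balanced state at I_opto = ", I))
    }
    if (!is.null(prev_active)) {
      same <- purrr::detect(sts, function(s) setequal(s$active, prev_active))
      if (!is.null(same)) {
        attr(same, "multiplicity") <- attr(sts, "multiplicity")
        return(same)
      }
    }
    st <- sts[[1]]
    attr(st, "multiplicity") <- attr(sts, "multiplicity")
    st
  }

  rows <- vector("list", length(I_grid))
  prev_active <- NULL
  actives <- vector("list", length(I_grid))
  for (i in seq_along(I_grid)) {
    st <- pick_state(I_grid[i], prev_active)
    actives[[i]] <- st$active
    prev_active <- st$active
    rows[[i]] <- mutate(st$rates,
      I_opto = I_grid[i], Gamma = Gamma[i],
      norm_rate = unname(ifelse(base_rates[.data$population] > 0,
                                .data$rate / base_rates[.data$population],
                                NA_real_)),
      active_set = paste(st$active, collapse = "+"),
      multiplicity = attr(st, "multiplicity")
    )
  }

  # bisection on active-set changes
  bps <- list()
  for (i in seq_len(length(I_grid) - 1)) {
    if (!setequal(actives[[i]], actives[[i + 1]])) {
      lo <- I_grid[i]; hi <- I_grid[i + 1]
      act_lo <- actives[[i]]
      while (hi - lo > bisect_tol) {
        mid <- (lo + hi) / 2
        st <- pick_state(mid, act_lo)
        if (setequal(st$active, act_lo)) lo <- mid else hi <- mid
      }
      bps[[length(bps) + 1]] <- tibble(
        I_opto = (lo + hi) / 2,
        from = paste(actives[[i]], collapse = "+"),
        to = paste(actives[[i + 1]], collapse = "+")
      )
    }
  }

  out <- bind_rows(rows)
  out <- select(out, "I_opto", "Gamma", "population", "rate", "norm_rate",
                "active", "active_set", "multiplicity")
  attr(out, "breakpoints") <- if (length(bps)) bind_rows(bps) else
    tibble(I_opto = numeric(), from = character(), to = character())
  attr(out, "spec_name") <- spec$name
  class(out) <- c("balance_sweep", class(out))
  out
}

#' Susceptibility matrix of the balanced state
#'
#' The susceptibility `chi[a, b]` is the derivative of population `a`'s
#' steady-state rate with respect to a small extra input into population
#' `b` (Hz per nA/cm^2). On an active set it equals `-solve(A[act, act])`,
#' embedded with zero rows and columns for silent populations (whose rates
#' are pinned at zero under small perturbations).
#'
#' @param spec a [circuit_spec()].
#' @param active active populations (default: all).
#' @return A matrix of class `susceptibility` with population dimnames.
#' @export
susceptibility <- function(spec, active = spec$populations) {
  pops <- spec$populations
  A <- effective_matrix(spec)
  active <- pops[pops %in% active]
  chi <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  Aact <- A[active, active, drop = FALSE]
  if (abs(det(Aact)) < 1e-10 * max(1, max(abs(Aact)))^length(active)) {
    abort("singular active block: susceptibility undefined")
  }
  chi[active, active] <- -solve(Aact)
  structure(chi, class = c("susceptibility", "matrix"))
}

#' Audit the paradoxical-effect criteria of a circuit
#'
#' For the supported topologies, evaluates the closed-form conditions that
#' determine whether photostimulation of the PV population *decreases* its
#' own rate (the paradoxical effect, `chi_II < 0`):
#'
#' * two-population circuit: paradoxical iff `J_EE > 0` (with `det(A) > 0`);
#' * V1-like four-population circuit (PC/PV/SOM/VIP): paradoxical iff
#'   `J_EE < J_EE* = J_VE * J_ES / J_VS` -- the recurrent excitation against
#'   the gain of the disinhibitory loop through the VIP and SOM populations;
#' * PC/PV/SOM/X circuit: paradoxical iff `J_EX * J_XS > J_XX * J_ES`
#'   (independently of `J_EE`), with the companion requirement
#'   `J_IX * J_XS > J_XX * J_IS` for the PC rate to increase with its
#'   feedforward input.
#'
#' Every boolean is cross-checked against the sign of `chi_II` from
#' [susceptibility()]. Unrecognized topologies fall back to the generic
#' `sign(chi_II)` result with a warning.
#'
#' @param spec a [circuit_spec()].
#' @return A list of class `paradox_audit` with `topology`, `paradoxical`,
#'   `chi_II`, `agreement` (criterion vs. `sign(chi_II)`), a `criteria`
#'   tibble with margins, and `jee_star` where applicable.
#' @examples
#' paradox_audit(load_architecture("model1_paradox"))$paradoxical  # TRUE
#' @export
paradox_audit <- function(spec) {
  topo <- circuit_topology(spec)
  J <- spec$J
  chi <- susceptibility(spec)
  # self-susceptibility of the stimulated population ("I" in the fixtures)
  tgt <- intersect(spec$opto$targets, spec$populations)[1]
  if (is.na(tgt)) tgt <- spec$populations[2]
  chi_II <- chi[tgt, tgt]
  crit <- NULL
  jee_star <- NA_real_
  if (topo %in% c("two_pop")) {
    detA <- det(effective_matrix(spec))
    paradoxical <- J["E", "E"] > 0 && detA > 0
    crit <- tibble(
      criterion = c("J_EE > 0", "det(A) > 0"),
      holds = c(J["E", "E"] > 0, detA > 0),
      margin = c(J["E", "E"], detA)
    )
  } else if (topo == "model1") {
    jee_star <- J["V", "E"] * J["E", "S"] / J["V", "S"]
    paradoxical <- J["E", "E"] < jee_star
    crit <- tibble(
      criterion = "J_EE < J_EE* (= J_VE * J_ES / J_VS)",
      holds = paradoxical,
      margin = jee_star - J["E", "E"]
    )
  } else if (topo == "model2") {
    loop_par <- J["E", "X"] * J["X", "S"] > J["X", "X"] * J["E", "S"]
    loop_ff <- J["I", "X"] * J["X", "S"] > J["X", "X"] * J["I", "S"]
    paradoxical <- loop_par
    crit <- tibble(
      criterion = c("J_EX * J_XS > J_XX * J_ES",
                    "J_IX * J_XS > J_XX * J_IS"),
      holds = c(loop_par, loop_ff),
      margin = c(J["E", "X"] * J["X", "S"] - J["X", "X"] * J["E", "S"],
                 J["I", "X"] * J["X", "S"] - J["X", "X"] * J["I", "S"])
    )
  } else {
    warn(paste0("unsupported topology '", topo,
                "': reporting generic sign(chi_II) only"))
    paradoxical <- chi_II < 0
    crit <- tibble(criterion = "sign(chi_II) < 0", holds = paradoxical,
                   margin = -chi_II)
  }
  structure(
    list(topology = topo, paradoxical = paradoxical, chi_II = chi_II,
         agreement = identical(unname(paradoxical), unname(chi_II < 0)),
         criteria = crit, jee_star = jee_star),
    class = "paradox_audit"
  )
}

#' Necessary stability condition of the balanced state
#'
#' A necessary condition for stability of the fully balanced state against
#' rate divergence is that all eigenvalues of the signed interaction matrix
#' `A` have negative real part, which requires `det(-A) > 0`, i.e.
#' `det(A) > 0` for the even-dimensional (two- and four-population)
#' circuits. This is necessary only: the full dynamical stability also
#' depends on the synaptic time constants and is not evaluated here.
#'
#' @param spec a [circuit_spec()].
#' @return A list with `det` (determinant of `A`) and `necessary_ok`
#'   (`(-1)^n * det(A) > 0`).
#' @export
stability_check <- function(spec) {
  d <- det(effective_matrix(spec))
  n <- length(spec$populations)
  list(det = d, necessary_ok = (-1)^n * d > 0)
}

#' Predicted proportional population pair
#'
#' The balance of excitation and inhibition onto the SOM population ties two
#' other populations together: in the V1-like circuit SOM receives only PC
#' and VIP input, so `r_V / r_E = J_SE / J_SV` whenever SOM is active; in
#' the PC/PV/SOM/X circuit SOM receives only PC and PV input, so
#' `r_I / r_E = J_SE / J_SI`. The predicted ratio is verified against the
#' baseline balanced rates.
#'
#' @param spec a [circuit_spec()] with a recognized topology.
#' @return A list with `pair` (character 2-vector, numerator first),
#'   `ratio`, `applicable` (FALSE when SOM is silent at baseline), and
#'   `observed` (ratio from the baseline solve, NA when not applicable).
#' @export
proportionality_ratio <- function(spec) {
  topo <- circuit_topology(spec)
  J <- spec$J
  pair_ratio <- switch(topo,
    model1 = list(pair = c("V", "E"), ratio = J["S", "E"] / J["S", "V"]),
    model2 = ,
    three_pop = list(pair = c("I", "E"), ratio = J["S", "E"] / J["S", "I"]),
    abort("proportionality prediction requires a SOM-bearing topology")
  )
  st <- solve_balance(balance_problem(spec))
  som_active <- st$consistent && st$rates$rate[st$rates$population == "S"] > 0
  obs <- if (som_active) {
    r <- setNames(st$rates$rate, st$rates$population)
    unname(r[pair_ratio$pair[1]] / r[pair_ratio$pair[2]])
  } else {
    NA_real_
  }
  list(pair = pair_ratio$pair, ratio = unname(pair_ratio$ratio),
       applicable = som_active, observed = obs)
}

#' @export
print.balance_state <- function(x, ...) {
  cat("<balance_state> active: {", paste(x$active, collapse = ","),
      "} consistent:", x$consistent, "\n")
  print(x$rates)
  invisible(x)
}

#' @export
print.paradox_audit <- function(x, ...) {
  cat("<paradox_audit> topology:", x$topology,
      "| paradoxical:", x$paradoxical,
      "| chi_II:", signif(x$chi_II, 4),
      "| criterion/chi agreement:", x$agreement, "\n")
  print(x$criteria)
  invisible(x)
}
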