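#' Run a theory / simulation comparison experiment
#'
#' Orchestrates the standard protocol for one architecture: a
#' balance-theory sweep over the laser-intensity grid, optionally a
#' finite-size simulation sweep on the same grid, the paradoxical-effect
#' audit, per-neuron heterogeneity summaries (response-category fractions
#' of the simulated PC and PV neurons at each intensity), and discrepancy
#' metrics between the normalized theory and simulation curves. Results can
#' be written to disk as CSV/JSON and read back with [read_experiment()].
#'
#' @param spec a [circuit_spec()] or architecture name.
#' @param Gamma laser-intensity grid including 0 (mW/mm^2).
#' @param mode `"theory"`, `"simulation"`, or `"both"`.
#' @param sizes optional [network_sizes()] override for the simulation.
#' @param config a [sim_config()] for the simulation runs.
#' @param outdir optional output directory.
#' @param rate_threshold category threshold (Hz) for the heterogeneity
#'   summary.
#' @return A list of class `comparison_report` with `theory` (long sweep
#'   tibble or NULL), `sim` (population sweep tibble or NULL),
#'   `sim_neurons`, `fractions`, `audit`, `discrepancy`, and the grid.
#' @export
run_experiment <- function(spec, Gamma,
                           mode = c("theory", "simulation", "both"),
                           sizes = NULL, config = sim_config(),
                           outdir = NULL, rate_threshold = 0.1) {
  mode <- match.arg(mode)
  if (is.character(spec)) spec <- load_architecture(spec)
  if (!0 %in% Gamma) abort("the intensity grid must include 0")
  audit <- paradox_audit(spec)
  theory <- NULL
  sim_pop <- NULL
  sim_neurons <- NULL
  fractions <- NULL
  if (mode %in% c("theory", "both")) {
    theory <- sweep_opto(spec, Gamma = Gamma)
  }
  if (mode %in% c("simulation", "both")) {
    sw <- intensity_sweep_sim(spec, Gamma = Gamma, config = config,
                              sizes = sizes)
    sim_pop <- sw$population
    sim_neurons <- sw$neurons
    base <- sim_neurons |>
      filter(.data$Gamma == 0) |>
      select("neuron", base_rate = "rate")
    fractions <- sim_neurons |>
      filter(.data$Gamma > 0) |>
      left_join(base, by = "neuron") |>
      mutate(category = dplyr::case_when(
        .data$rate < rate_threshold ~ "silenced",
        .data$rate - .data$base_rate > rate_threshold ~ "increase",
        .data$rate - .data$base_rate < -rate_threshold ~ "decrease",
        TRUE ~ "no_change"
      )) |>
      group_by(.data$population, .data$Gamma, .data$category) |>
      summarise(n = n(), .groups = "drop_last") |>
      mutate(fraction = .data$n / sum(.data$n)) |>
      ungroup()
  }
  discrepancy <- NULL
  if (!is.null(theory) && !is.null(sim_pop)) {
    discrepancy <- theory |>
      select("Gamma", "population", theory_norm = "norm_rate") |>
      left_join(select(sim_pop, "Gamma", "population", sim_norm = "norm_rate"),
                by = c("Gamma", "population")) |>
      group_by(.data$population) |>
      summarise(mean_abs_norm_diff =
                  mean(abs(.data$theory_norm - .data$sim_norm), na.rm = TRUE),
                .groups = "drop")
  }
  report <- structure(
    list(spec_name = spec$name, Gamma = sort(Gamma), mode = mode,
         theory = theory, sim = sim_pop, sim_neurons = sim_neurons,
         fractions = fractions, audit = audit, discrepancy = discrepancy),
    class = "comparison_report"
  )
  if (!is.null(outdir)) write_experiment(report, outdir)
  report
}

#' @rdname run_experiment
#' @param report a `comparison_report`.
#' @export
write_experiment <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(spec_name = report$spec_name, Gamma = report$Gamma,
               mode = report$mode,
               audit = list(topology = report$audit$topology,
                            paradoxical = report$audit$paradoxical,
                            chi_II = report$audit$chi_II,
                            agreement = report$audit$agreement,
                            jee_star = report$audit$jee_star,
                            criteria = report$audit$criteria))
  jsonlite::write_json(meta, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  save_csv <- function(df, name) {
    if (!is.null(df)) utils::write.csv(df, file.path(outdir, name),
                                       row.names = FALSE)
  }
  save_csv(report$theory, "sweep_theory.csv")
  save_csv(report$sim, "sweep_sim.csv")
  save_csv(report$sim_neurons, "sim_neurons.csv")
  save_csv(report$fractions, "fractions.csv")
  save_csv(report$discrepancy, "discrepancy.csv")
  invisible(outdir)
}

#' @rdname run_experiment
#' @export
read_experiment <- function(outdir) {
  meta <- jsonlite::read_json(file.path(outdir, "report.json"),
                              simplifyVector = TRUE)
  load_csv <- function(name) {
    p <- file.path(outdir, name)
    if (file.exists(p)) as_tibble(utils::read.csv(p)) else NULL
  }
  structure(
    list(spec_name = meta$spec_name, Gamma = meta$Gamma, mode = meta$mode,
         theory = load_csv("sweep_theory.csv"), sim = load_csv("sweep_sim.csv"),
         sim_neurons = load_csv("sim_neurons.csv"),
         fractions = load_csv("fractions.csv"),
         audit = meta$audit, discrepancy = load_csv("discrepancy.csv")),
    class = "comparison_report"
  )
}

#' Robustness of the audit outcome to interaction jitter
#'
#' Redraws every nonzero recurrent interaction strength independently and
#' uniformly within `+/- jitter` of its reference value, re-runs
#' [paradox_audit()] on each draw (and optionally a reduced simulation),
#' and reports the fraction of draws preserving the reference qualitative
#' outcome (the paradoxical flag and every individual criterion).
#'
#' @param spec a [circuit_spec()] or architecture name.
#' @param n_nets number of jittered parameter draws.
#' @param jitter relative half-width of the uniform jitter band.
#' @param seed RNG seed.
#' @param include_feedforward also jitter the feedforward strengths
#'   (they do not enter the criteria).
#' @return A list with `fraction_preserved`, `fraction_criteria_preserved`,
#'   and the per-draw tibble `draws`.
#' @export
jitter_robustness <- function(spec, n_nets = 100, jitter = 0.1, seed = 1,
                              include_feedforward = FALSE) {
  if (is.character(spec)) spec <- load_architecture(spec)
  ref <- paradox_audit(spec)
  set.seed(seed)
  draws <- purrr::map(seq_len(n_nets), function(k) {
    sp <- spec
    nz <- sp$J > 0
    sp$J[nz] <- sp$J[nz] * runif(sum(nz), 1 - jitter, 1 + jitter)
    if (include_feedforward) {
      nz0 <- sp$J0 > 0
      sp$J0[nz0] <- sp$J0[nz0] * runif(sum(nz0), 1 - jitter, 1 + jitter)
    }
    aud <- paradox_audit(sp)
    tibble(draw = k,
           paradoxical = aud$paradoxical,
           criteria_match = identical(aud$criteria$holds, ref$criteria$holds),
           chi_II = aud$chi_II,
           agreement = aud$agreement)
  }) |> bind_rows()
  list(
    reference = ref,
    fraction_preserved = mean(draws$paradoxical == ref$paradoxical),
    fraction_criteria_preserved = mean(draws$criteria_match),
    draws = draws
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report '", x$spec_name, "'> mode: ", x$mode, "\n", sep = "")
  cat("  paradoxical:", x$audit$paradoxical, "\n")
  if (!is.null(x$discrepancy)) {
    cat("  theory vs simulation (mean |norm diff|):\n")
    print(x$discrepancy)
  }
  invisible(x)
}
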