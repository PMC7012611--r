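#' Simulation configuration
#'
#' @param dt integration time step (ms). The membrane potential is advanced
#'   with a second-order Runge-Kutta step; synaptic variables decay exactly
#'   between spikes; spikes are recorded at end-of-step times without
#'   interpolation.
#' @param duration total simulated time (ms), including the warmup.
#' @param warmup initial transient discarded from all statistics (ms).
#' @param seed integer seed controlling the initial membrane potentials
#'   (uniform between reset and threshold) and, through
#'   [build_connectivity()], the adjacency draw.
#' @param record_spikes keep individual spike times (otherwise only counts).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(dt = 0.01, duration = 20000, warmup = 1000,
                       seed = 1, record_spikes = TRUE) {
  stopifnot(dt > 0, warmup < duration, warmup >= 0)
  structure(list(dt = dt, duration = duration, warmup = warmup,
                 seed = as.integer(seed), record_spikes = record_spikes),
            class = "sim_config")
}

#' Population counts for a finite-size network
#'
#' Derives per-population neuron counts from the spec's convention: 75%
#' excitatory, the remainder split equally among the inhibitory populations
#' (two-population circuit: 3N/4 and N/4). Passing `N` rescales the spec's
#' counts proportionally; `K` overrides the mean in-degree.
#'
#' @param spec a [circuit_spec()].
#' @param N total neuron count (default: the spec's).
#' @param K mean in-degree per presynaptic population (default: the spec's).
#' @return A list with `N` (named integer counts) and `K`.
#' @export
network_sizes <- function(spec, N = NULL, K = NULL) {
  counts <- spec$sizes$N
  if (!is.null(N)) counts <- round(counts / sum(counts) * N)
  K <- K %||% spec$sizes$K
  if (any(K > counts)) abort("in-degree K exceeds a population size")
  list(N = setNames(as.integer(counts), names(counts)), K = K)
}

#' Draw a sparse random connectivity realization
#'
#' Every ordered (postsynaptic, presynaptic) neuron pair is connected
#' independently with probability `K / N_pre_pop`, so each neuron receives on
#' average `K` inputs from every presynaptic population. Self-connections are
#' excluded; pairs are single-contact (Bernoulli). The draw is deterministic
#' given `seed`.
#'
#' @param sizes a list with `N` (named counts) and `K`, e.g. from
#'   [network_sizes()].
#' @param seed integer seed for the adjacency draw.
#' @param exclude_self exclude autapses (default TRUE).
#' @return A list of class `connectivity` with CSR adjacency by presynaptic
#'   neuron (`ptr`, `targets`, 0-based), the population index per neuron,
#'   and the draw parameters.
#' @export
build_connectivity <- function(sizes, seed = 1, exclude_self = TRUE) {
  counts <- sizes$N
  K <- sizes$K
  if (any(K > counts)) abort("in-degree K exceeds a population size")
  adj <- build_connectivity_cpp(as.integer(counts), K, as.integer(seed),
                                exclude_self)
  pop_offsets <- c(0L, cumsum(as.integer(counts)))
  structure(
    list(ptr = adj$ptr, targets = adj$targets,
         pop = rep(seq_along(counts) - 1L, counts),
         pop_offsets = pop_offsets, populations = names(counts),
         N = counts, K = K, seed = as.integer(seed)),
    class = "connectivity"
  )
}

#' Realized in-degree statistics per connection block
#'
#' @param conn a [build_connectivity()] realization.
#' @return A tibble with `post`, `pre`, `mean_in_degree`, `sd_in_degree`,
#'   and the binomial expectation `K`.
#' @export
in_degree_stats <- function(conn) {
  pops <- conn$populations
  pre_pop <- rep(conn$pop, diff(conn$ptr))
  post <- conn$targets
  Ntot <- sum(conn$N)
  out <- list()
  for (b in seq_along(pops)) {
    deg <- tabulate(post[pre_pop == (b - 1L)] + 1L, nbins = Ntot)
    for (a in seq_along(pops)) {
      idx <- (conn$pop_offsets[a] + 1L):conn$pop_offsets[a + 1L]
      out[[length(out) + 1]] <- tibble(
        post = pops[a], pre = pops[b],
        mean_in_degree = mean(deg[idx]), sd_in_degree = sd(deg[idx]),
        K = conn$K
      )
    }
  }
  bind_rows(out)
}

#' Simulate a finite-size spiking network
#'
#' Integrates the leaky integrate-and-fire dynamics
#' `C_M dV/dt = -g_leak (V - V_R) + I_rec + Lambda_ext + Lambda_opto` with
#' threshold `V_th` and reset to `V_R`. Recurrent input is the sum of
#' exponentially filtered presynaptic spike trains weighted by the
#' finite-size couplings `J / sqrt(K)`; the feedforward drive is the
#' constant current `2 K j0 r0` and the optogenetic drive
#' `sqrt(K) * I_opto(Gamma)` enters the target populations
#' (see [scale_to_finite_K()]).
#'
#' @param spec a [circuit_spec()].
#' @param Gamma laser intensity (mW/mm^2) for this run.
#' @param config a [sim_config()].
#' @param sizes optional [network_sizes()] override.
#' @param connectivity optional shared [build_connectivity()] realization
#'   (built from `sizes` and `config$seed` when omitted).
#' @param lambda_override optional named per-population constant drive
#'   (uA/cm^2) replacing the feedforward + optogenetic currents (used for
#'   controlled single-neuron and probe experiments).
#' @return A list of class `spike_data` with `spikes`
#'   (tibble: `neuron`, `population`, `time_ms`; post-warmup only),
#'   `counts` (tibble: per-neuron post-warmup spike count and rate in Hz),
#'   and the run metadata.
#' @export
simulate_network <- function(spec, Gamma = 0, config = sim_config(),
                             sizes = NULL, connectivity = NULL,
                             lambda_override = NULL) {
  sizes <- sizes %||% network_sizes(spec)
  if (is.null(connectivity)) {
    connectivity <- build_connectivity(sizes, seed = config$seed)
  }
  pops <- spec$populations
  stopifnot(identical(connectivity$populations, pops))
  sc <- scale_to_finite_K(spec, sizes$K)
  lambda <- if (is.null(lambda_override)) {
    sc$lambda_ext + sc$lambda_opto(Gamma)
  } else {
    as_pop_vector(lambda_override, pops, fill = 0)
  }
  tau <- spec$tau
  tau[is.na(tau)] <- 0
  res <- simulate_lif_cpp(
    pop = connectivity$pop, pop_offsets = as.integer(connectivity$pop_offsets),
    ptr = connectivity$ptr, targets = connectivity$targets,
    js = sc$j_signed, tau = tau,
    lambda = unname(lambda[pops]), g_leak = unname(spec$neuron$g_leak[pops]),
    C_M = spec$neuron$C_M, V_th = spec$neuron$V_th, V_R = spec$neuron$V_R,
    dt = config$dt, duration = config$duration, warmup = config$warmup,
    seed = config$seed + 1L, record_spikes = config$record_spikes,
    randomize_V = TRUE, V_init = spec$neuron$V_R
  )
  T_ana <- (config$duration - config$warmup) / 1000  # s
  pop_per_neuron <- pops[connectivity$pop + 1L]
  structure(
    list(
      spikes = tibble(neuron = res$spike_id,
                      population = pop_per_neuron[res$spike_id],
                      time_ms = res$spike_time),
      counts = tibble(neuron = seq_along(res$counts),
                      population = pop_per_neuron,
                      n = res$counts, rate = res$counts / T_ana),
      Gamma = Gamma, config = config, sizes = sizes,
      window = c(config$warmup, config$duration)
    ),
    class = "spike_data"
  )
}

#' Single leaky integrate-and-fire neuron under constant current
#'
#' Deterministic run of the same integrator used for networks, for one
#' isolated neuron starting from reset. With suprathreshold current `I`
#' (above the rheobase `g_leak * (V_th - V_R)`), the closed-form interspike
#' interval is `(C_M / g_leak) * log(I / (I - g_leak * (V_th - V_R)))`.
#'
#' @param I constant input current (uA/cm^2).
#' @param g_leak leak conductance (mS/cm^2).
#' @param C_M membrane capacitance (uF/cm^2).
#' @param V_th,V_R threshold and reset potentials (mV).
#' @param dt time step (ms).
#' @param duration simulated time (ms).
#' @return A numeric vector of spike times (ms).
#' @export
lif_single_neuron <- function(I, g_leak = 0.05, C_M = 1,
                              V_th = -50, V_R = -70,
                              dt = 0.01, duration = 1000) {
  res <- simulate_lif_cpp(
    pop = 0L, pop_offsets = c(0L, 1L),
    ptr = c(0L, 0L), targets = integer(0),
    js = matrix(0, 1, 1), tau = matrix(0, 1, 1),
    lambda = I, g_leak = g_leak, C_M = C_M, V_th = V_th, V_R = V_R,
    dt = dt, duration = duration, warmup = 0,
    seed = 1L, record_spikes = TRUE, randomize_V = FALSE, V_init = V_R
  )
  res$spike_time
}

#' Exponential synaptic kernel
#'
#' `f(t) = exp(-t / tau) / tau` for `t >= 0`, zero before; unit integral.
#'
#' @param t time since the presynaptic spike (ms).
#' @param tau synaptic time constant (ms).
#' @return Kernel values (ms^-1).
#' @export
synaptic_kernel <- function(t, tau) {
  ifelse(t >= 0, exp(-t / tau) / tau, 0)
}

#' Summarize spiking activity
#'
#' Computes per-neuron and population firing statistics over a time window:
#' rates (spike count over window length), the coefficient of variation of
#' interspike intervals per neuron (restricted to neurons with at least 10
#' ISIs, then averaged within population), and the across-neuron rate
#' heterogeneity.
#'
#' @param x a `spike_data` object from [simulate_network()], or a data frame
#'   with columns `neuron`, `population`, `time_ms`.
#' @param window `c(t0, t1)` in ms (default: the post-warmup span for
#'   `spike_data`, the data range for a plain data frame).
#' @param min_isi minimal number of ISIs for a neuron to enter the CV
#'   average.
#' @return A list of class `activity_summary` with `$population`
#'   (per-population mean rate, across-neuron rate SD and CV, mean ISI CV)
#'   and `$neurons` (per-neuron rate and ISI CV).
#' @export
summarize_activity <- function(x, window = NULL, min_isi = 10) {
  if (inherits(x, "spike_data")) {
    spikes <- x$spikes
    window <- window %||% x$window
    universe <- x$counts[, c("neuron", "population")]
  } else {
    spikes <- as_tibble(x)
    window <- window %||% range(spikes$time_ms)
    universe <- dplyr::distinct(spikes, .data$neuron, .data$population)
  }
  if (window[2] <= window[1]) abort("empty analysis window")
  T_s <- (window[2] - window[1]) / 1000
  sp <- filter(spikes, .data$time_ms >= window[1], .data$time_ms <= window[2])
  per_neuron <- sp |>
    group_by(.data$neuron, .data$population) |>
    summarise(
      n = n(),
      cv_isi = if (n() >= min_isi + 1) {
        isi <- diff(sort(.data$time_ms))
        sd(isi) / mean(isi)
      } else {
        NA_real_
      },
      .groups = "drop"
    )
  neurons <- universe |>
    left_join(per_neuron, by = c("neuron", "population")) |>
    mutate(n = dplyr::coalesce(.data$n, 0L), rate = .data$n / T_s)
  population <- neurons |>
    group_by(.data$population) |>
    summarise(
      n_neurons = n(),
      rate_sd = sd(.data$rate),
      rate = mean(.data$rate),
      rate_cv = .data$rate_sd / .data$rate,
      cv_isi = mean(.data$cv_isi, na.rm = TRUE),
      .groups = "drop"
    )
  structure(list(population = population, neurons = neurons,
                 window = window),
            class = "activity_summary")
}

#' Simulated intensity sweep
#'
#' Runs one simulation per laser intensity on a shared connectivity
#' realization and normalizes population and single-neuron rates to the
#' baseline (`Gamma = 0`) run. Populations (or neurons) silent at baseline
#' get `NA` normalized rates.
#'
#' @param spec a [circuit_spec()].
#' @param Gamma intensity grid (mW/mm^2), must include 0.
#' @param config a [sim_config()]; run `i` uses seed `config$seed + i` for
#'   its initial conditions while the connectivity uses `config$seed`.
#' @param sizes optional [network_sizes()] override.
#' @param keep_spikes retain the per-run `spike_data` objects under `$runs`.
#' @return A list of class `sim_sweep` with `$population`
#'   (`Gamma`, `population`, `rate`, `norm_rate`), `$neurons` (per-neuron
#'   rates and normalized rates), and optionally `$runs`.
#' @export
intensity_sweep_sim <- function(spec, Gamma, config = sim_config(),
                                sizes = NULL, keep_spikes = FALSE) {
  Gamma <- sort(unique(Gamma))
  if (Gamma[1] != 0) abort("the intensity grid must include the baseline 0")
  sizes <- sizes %||% network_sizes(spec)
  conn <- build_connectivity(sizes, seed = config$seed)
  runs <- vector("list", length(Gamma))
  for (i in seq_along(Gamma)) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i
    cfg_i$record_spikes <- config$record_spikes || keep_spikes
    runs[[i]] <- simulate_network(spec, Gamma = Gamma[i], config = cfg_i,
                                  sizes = sizes, connectivity = conn)
  }
  neurons <- purrr::map2(runs, Gamma, function(r, g) {
    mutate(r$counts, Gamma = g)
  }) |> bind_rows()
  base_n <- filter(neurons, .data$Gamma == 0) |>
    select("neuron", base_rate = "rate")
  neurons <- neurons |>
    left_join(base_n, by = "neuron") |>
    mutate(norm_rate = ifelse(.data$base_rate > 0,
                              .data$rate / .data$base_rate, NA_real_)) |>
    select("Gamma", "neuron", "population", "rate", "norm_rate")
  population <- purrr::map2(runs, Gamma, function(r, g) {
    r$counts |>
      group_by(.data$population) |>
      summarise(rate = mean(.data$rate), .groups = "drop") |>
      mutate(Gamma = g)
  }) |> bind_rows()
  base_p <- filter(population, .data$Gamma == 0) |>
    select("population", base_rate = "rate")
  population <- population |>
    left_join(base_p, by = "population") |>
    mutate(norm_rate = ifelse(.data$base_rate > 0,
                              .data$rate / .data$base_rate, NA_real_)) |>
    select("Gamma", "population", "rate", "norm_rate")
  structure(
    list(population = population, neurons = neurons,
         runs = if (keep_spikes) runs, Gamma = Gamma,
         sizes = sizes, config = config, spec_name = spec$name),
    class = "sim_sweep"
  )
}
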