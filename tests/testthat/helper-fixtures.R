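# Shared fixtures and independent oracles for the test suite.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Reduced-scale simulation sweep used by several tests. The suite runs the
# spiking models at N = 4800 neurons, K = 150, dt = 0.02 ms, 10 s of
# analyzed activity -- large enough for the balanced-regime phenomenology
# (qualitative response signs, irregular spiking, heterogeneity) at a cost
# compatible with routine testing.
reduced_sweep <- function(name, keep_spikes = FALSE) {
  cached(paste0("sweep_", name, "_", keep_spikes), {
    spec <- load_architecture(name)
    sizes <- network_sizes(spec, N = 4800, K = 150)
    cfg <- sim_config(dt = 0.02, duration = 11000, warmup = 1000, seed = 11,
                      record_spikes = keep_spikes)
    intensity_sweep_sim(spec, Gamma = c(0, 1, 10), config = cfg,
                        sizes = sizes, keep_spikes = keep_spikes)
  })
}

# Independent brute-force oracle for the piecewise balance solutions: plain
# subset enumeration with dense linear algebra, written without reference to
# the package internals.
oracle_states <- function(A, cvec, tol = 1e-9) {
  n <- nrow(A)
  out <- list()
  idx_sets <- c(list(integer(0)),
                unlist(lapply(seq_len(n), function(k) {
                  utils::combn(seq_len(n), k, simplify = FALSE)
                }), recursive = FALSE))
  for (act in idx_sets) {
    r <- rep(0, n)
    ok <- TRUE
    if (length(act) > 0) {
      Aa <- A[act, act, drop = FALSE]
      if (abs(det(Aa)) < 1e-9) next
      r[act] <- solve(Aa, -cvec[act])
      ok <- all(r[act] >= -tol)
    }
    if (ok) {
      sil <- setdiff(seq_len(n), act)
      if (length(sil) > 0) {
        net <- cvec[sil] + (A %*% r)[sil]
        ok <- all(net < tol)
      }
    }
    if (ok) out[[length(out) + 1]] <- list(active = act, rates = r)
  }
  out
}

# Random strongly-coupled specs with an excitatory population and n_inh
# inhibitory populations; used for property tests on the linear algebra.
random_spec <- function(n_inh = 3, seed = 1) {
  set.seed(seed)
  pops <- c("E", paste0("I", seq_len(n_inh)))
  n <- length(pops)
  repeat {
    J <- matrix(runif(n * n, 5, 40), n, n, dimnames = list(pops, pops))
    tau <- matrix(2, n, n, dimnames = list(pops, pops))
    pol <- setNames(c(1, rep(-1, n_inh)), pops)
    A <- sweep(J, 2, pol, `*`)
    if (abs(det(A)) > 1) break
  }
  circuit_spec(
    populations = pops, polarity = pol, J = J,
    J0 = setNames(runif(n, 5, 30), pops), tau = tau,
    neuron = list(C_M = 1, g_leak = setNames(rep(0.05, n), pops),
                  V_th = -50, V_R = -70),
    r0 = 5,
    opto = list(targets = pops[2], I0 = 8, Gamma0 = 0.5)
  )
}

# Deterministic toy recording: one unit per row of `counts`, one trial per
# intensity, exact spike counts in the two analysis windows.
toy_recording <- function(counts) {
  # counts: tibble(unit_id, width, intensity, n_stim, n_base)
  trials <- tibble::tibble(intensity = sort(unique(counts$intensity)))
  trials$trial_id <- seq_len(nrow(trials))
  spikes <- list()
  for (i in seq_len(nrow(counts))) {
    tr <- trials$trial_id[trials$intensity == counts$intensity[i]]
    n_s <- counts$n_stim[i]
    n_b <- counts$n_base[i]
    spikes[[i]] <- tibble::tibble(
      unit_id = counts$unit_id[i], trial_id = tr,
      time_ms = c(seq_len(n_s) * 999 / max(1, n_s),
                  -seq_len(n_b) * 499 / max(1, n_b))[c(rep(TRUE, n_s),
                                                       rep(TRUE, n_b))]
    )
  }
  units <- unique(counts[, c("unit_id", "width")])
  recording(units, trials[, c("trial_id", "intensity")],
            dplyr::bind_rows(spikes))
}
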