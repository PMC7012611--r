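#' Configuration for synthetic optogenetic recordings
#'
#' Describes a population of extracellular units with the statistical
#' structure the spike-train analysis assumes: per-class unit counts and
#' spike-width bands, lognormal baseline rates, and a per-unit response
#' model in which each unit's normalized-rate curve is the class template
#' scaled by a unit gain, `nu_u(Gamma) = max(0, 1 + g_u * (T(Gamma) - 1))`,
#' with `g_u ~ Normal(1, sigma_gain)` and an optional sign-mixing fraction
#' that flips gains to create units incongruous with the population
#' response. Spiking is homogeneous Poisson within each analysis window
#' (the downstream analysis uses only window counts). Trials follow the
#' experimental protocol: 1.3 s stimulation epochs (analyzed over the first
#' 1 s) delivered at ~7 s intervals, with laser powers drawn from an
#' area-specific grid.
#'
#' @param area preset for unit counts and intensity grid: `"S1"` (52 PC /
#'   8 FS; 0.5-12 mW/mm^2), `"ALM_L23"` (26/9), or `"ALM_L5"` (62/12; both
#'   ALM presets use the 0.3-15 mW/mm^2 grid).
#' @param n_pc,n_fs unit counts (defaults from `area`).
#' @param intensities laser grid, mW/mm^2; 0 (control) is added if absent.
#' @param trials_per_intensity trials at each intensity (default 20).
#' @param baseline_median,sigma_log lognormal baseline-rate parameters
#'   (median in Hz; log-scale SD).
#' @param width_pc,width_fs uniform spike-width bands per class (ms).
#' @param template_pc,template_fs class response templates: functions of
#'   intensity returning the population normalized rate. Defaults emulate a
#'   proportional paradoxical suppression of both classes with a
#'   fast-spiking recovery at high intensity.
#' @param sigma_gain SD of the unit gains around 1.
#' @param p_incongruous probability that a unit's gain is sign-flipped.
#' @param stim_duration_ms,analysis_window_ms,baseline_window_ms,
#'   inter_trial_ms trial timing (ms).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(area = c("S1", "ALM_L23", "ALM_L5"),
                             n_pc = NULL, n_fs = NULL, intensities = NULL,
                             trials_per_intensity = 20,
                             baseline_median = 5, sigma_log = 1,
                             width_pc = c(0.45, 0.65),
                             width_fs = c(0.15, 0.35),
                             template_pc = NULL, template_fs = NULL,
                             sigma_gain = 0.3, p_incongruous = 0,
                             stim_duration_ms = 1300,
                             analysis_window_ms = 1000,
                             baseline_window_ms = 500,
                             inter_trial_ms = 7000) {
  area <- match.arg(area)
  preset <- switch(area,
    S1 = list(n_pc = 52, n_fs = 8,
              intensities = c(0.5, 1.2, 2.2, 5, 12)),
    ALM_L23 = list(n_pc = 26, n_fs = 9,
                   intensities = c(0.3, 0.5, 1, 1.5, 2, 3.3, 5, 8, 15)),
    ALM_L5 = list(n_pc = 62, n_fs = 12,
                  intensities = c(0.3, 0.5, 1, 1.5, 2, 3.3, 5, 8, 15))
  )
  n_pc <- n_pc %||% preset$n_pc
  n_fs <- n_fs %||% preset$n_fs
  intensities <- sort(unique(c(0, intensities %||% preset$intensities)))
  template_pc <- template_pc %||% function(G) pmax(0, 1 - 2 * G)
  template_fs <- template_fs %||%
    function(G) pmax(0, 1 - 2 * G) + 0.2 * pmax(0, G - 0.5)
  stopifnot(sigma_log >= 0, sigma_gain >= 0,
            p_incongruous >= 0, p_incongruous <= 1,
            trials_per_intensity >= 1,
            analysis_window_ms <= stim_duration_ms)
  structure(
    list(area = area, n_pc = n_pc, n_fs = n_fs, intensities = intensities,
         trials_per_intensity = trials_per_intensity,
         baseline_median = baseline_median, sigma_log = sigma_log,
         width_pc = width_pc, width_fs = width_fs,
         template_pc = template_pc, template_fs = template_fs,
         sigma_gain = sigma_gain, p_incongruous = p_incongruous,
         stim_duration_ms = stim_duration_ms,
         analysis_window_ms = analysis_window_ms,
         baseline_window_ms = baseline_window_ms,
         inter_trial_ms = inter_trial_ms),
    class = "synthetic_config"
  )
}

#' Generate a synthetic recording with known ground truth
#'
#' Draws units (widths, lognormal baselines, gains), then for every trial
#' emits homogeneous-Poisson spikes at the baseline rate in the pre-stimulus
#' window and at `baseline * nu_u(Gamma)` during the stimulation epoch.
#' Rates are clipped at zero before sampling, so the Poisson sampler is
#' never asked for a negative intensity. Deterministic given `seed`.
#'
#' @param config a [synthetic_config()].
#' @param seed RNG seed.
#' @return A [recording()] with attribute `"ground_truth"` (also retrievable
#'   with [ground_truth()]); the hidden per-unit parameters are stored in
#'   `attr(, "unit_params")`.
#' @export
generate_recording <- function(config, seed = 1) {
  set.seed(seed)
  n <- config$n_pc + config$n_fs
  cls <- c(rep("PC", config$n_pc), rep("FS", config$n_fs))
  width <- ifelse(cls == "PC",
                  runif(n, config$width_pc[1], config$width_pc[2]),
                  runif(n, config$width_fs[1], config$width_fs[2]))
  baseline <- rlnorm(n, meanlog = log(config$baseline_median),
                     sdlog = config$sigma_log)
  gain <- rnorm(n, 1, config$sigma_gain)
  flip <- runif(n) < config$p_incongruous
  gain[flip] <- -gain[flip]
  units <- tibble(unit_id = sprintf("u%03d", seq_len(n)), width = width,
                  class = cls)
  trials <- tibble(
    trial_id = seq_len(length(config$intensities) * config$trials_per_intensity),
    intensity = rep(config$intensities, each = config$trials_per_intensity)
  )
  base_len <- config$baseline_window_ms
  stim_len <- config$stim_duration_ms
  template <- function(class, G) {
    if (class == "PC") config$template_pc(G) else config$template_fs(G)
  }
  spikes <- vector("list", n)
  for (u in seq_len(n)) {
    nu <- pmax(0, 1 + gain[u] * (template(cls[u], trials$intensity) - 1))
    stim_rate <- baseline[u] * nu                       # Hz
    n_base <- rpois(nrow(trials), baseline[u] * base_len / 1000)
    n_stim <- rpois(nrow(trials), stim_rate * stim_len / 1000)
    t_base <- runif(sum(n_base), -base_len, 0)
    t_stim <- runif(sum(n_stim), 0, stim_len)
    spikes[[u]] <- tibble(
      unit_id = units$unit_id[u],
      trial_id = c(rep(trials$trial_id, n_base), rep(trials$trial_id, n_stim)),
      time_ms = c(t_base, t_stim)
    )
  }
  rec <- recording(units, trials, bind_rows(spikes))
  attr(rec, "unit_params") <- tibble(unit_id = units$unit_id, class = cls,
                                     baseline = baseline, gain = gain,
                                     incongruous = flip)
  attr(rec, "ground_truth") <- ground_truth(config)
  rec
}

#' Ground truth implied by a synthetic configuration
#'
#' Closed-form population quantities implied by the templates: the
#' population normalized-rate curve is `1 + E[gain] * (T(Gamma) - 1)` with
#' `E[gain] = 1 - 2 * p_incongruous` (gains are independent of baselines;
#' rate clipping is neglected, which is accurate as long as the templates
#' and gain spread keep `nu_u` away from 0). Slopes are exact OLS fits to
#' the curve over the grid at or below `max_intensity`.
#'
#' @param config a [synthetic_config()].
#' @param max_intensity largest intensity entering the programmed slope.
#' @return A list of class `ground_truth` with `$curves` (tibble: `class`,
#'   `intensity`, `norm_rate`), `$slopes`, `$slope_ratio` (FS/PC), and
#'   `$incongruous_fraction`.
#' @export
ground_truth <- function(config, max_intensity = Inf) {
  e_gain <- 1 - 2 * config$p_incongruous
  grid <- config$intensities
  curves <- bind_rows(
    tibble(class = "PC", intensity = grid,
           norm_rate = 1 + e_gain * (config$template_pc(grid) - 1)),
    tibble(class = "FS", intensity = grid,
           norm_rate = 1 + e_gain * (config$template_fs(grid) - 1))
  )
  fit <- curves |>
    filter(.data$intensity <= max_intensity) |>
    group_by(.data$class) |>
    summarise(slope = {
      xc <- .data$intensity - mean(.data$intensity)
      sum(xc * (.data$norm_rate - mean(.data$norm_rate))) / sum(xc^2)
    }, .groups = "drop")
  ratio <- fit$slope[fit$class == "FS"] / fit$slope[fit$class == "PC"]
  structure(
    list(curves = curves, slopes = fit, slope_ratio = ratio,
         incongruous_fraction = config$p_incongruous),
    class = "ground_truth"
  )
}

#' Convert simulator output to the recording format
#'
#' Slices the spike trains of a simulated intensity sweep into
#' pseudo-trials so the electrophysiology pipeline can be run end to end on
#' model output. For each intensity, trial `k`'s stimulation window is a 1 s
#' slice of that intensity's run; its baseline window is a 500 ms slice of
#' the laser-off run (offset past the slices used as the laser-off
#' stimulation windows, so no data are reused). Excitatory neurons are
#' labeled `PC` and the PV population `FS`, with synthetic spike widths
#' drawn inside the corresponding class band.
#'
#' @param sweep a [intensity_sweep_sim()] result with `keep_spikes = TRUE`.
#' @param n_trials pseudo-trials per intensity.
#' @param probe populations to include and their class labels.
#' @param max_units_per_class optional subsampling cap.
#' @param seed seed for widths and unit subsampling.
#' @return A [recording()].
#' @export
from_simulation <- function(sweep, n_trials = 20,
                            probe = c(E = "PC", I = "FS"),
                            max_units_per_class = NULL, seed = 1) {
  if (is.null(sweep$runs)) {
    abort("run intensity_sweep_sim() with keep_spikes = TRUE")
  }
  gammas <- sweep$Gamma
  if (gammas[1] != 0) abort("the sweep must include the baseline intensity 0")
  run0 <- sweep$runs[[1]]
  span <- run0$window
  stim_len <- 1000
  base_len <- 500
  need <- n_trials * stim_len + n_trials * base_len
  if (diff(span) < need) {
    abort(paste0("simulation too short for ", n_trials,
                 " pseudo-trials: need ", need, " ms after warmup"))
  }
  base_offset <- span[1] + n_trials * stim_len
  set.seed(seed)
  keep_pops <- names(probe)
  unit_tbl <- run0$counts |>
    filter(.data$population %in% keep_pops) |>
    mutate(class = unname(probe[.data$population]))
  if (!is.null(max_units_per_class)) {
    unit_tbl <- unit_tbl |>
      group_by(.data$class) |>
      dplyr::slice_sample(n = max_units_per_class) |>
      ungroup()
  }
  width_band <- list(PC = c(0.48, 0.62), FS = c(0.18, 0.33))
  units <- unit_tbl |>
    mutate(unit_id = paste0("sim", .data$neuron),
           width = ifelse(.data$class == "PC",
                          runif(n(), width_band$PC[1], width_band$PC[2]),
                          runif(n(), width_band$FS[1], width_band$FS[2]))) |>
    select("unit_id", "width", "class")
  neuron_ids <- unit_tbl$neuron
  id_map <- setNames(paste0("sim", neuron_ids), neuron_ids)

  trials <- tidyr::expand_grid(intensity = gammas, k = seq_len(n_trials)) |>
    mutate(trial_id = dplyr::row_number())
  spike_rows <- vector("list", length(gammas))
  base_spikes <- filter(run0$spikes, .data$neuron %in% neuron_ids)
  for (gi in seq_along(gammas)) {
    run <- sweep$runs[[gi]]
    sp <- filter(run$spikes, .data$neuron %in% neuron_ids)
    tr <- filter(trials, .data$intensity == gammas[gi])
    per_trial <- vector("list", n_trials)
    for (k in seq_len(n_trials)) {
      s0 <- span[1] + (k - 1) * stim_len
      stim <- filter(sp, .data$time_ms >= s0, .data$time_ms < s0 + stim_len)
      b0 <- base_offset + (k - 1) * base_len
      base <- filter(base_spikes, .data$time_ms >= b0,
                     .data$time_ms < b0 + base_len)
      per_trial[[k]] <- bind_rows(
        tibble(unit_id = id_map[as.character(stim$neuron)],
               trial_id = tr$trial_id[k], time_ms = stim$time_ms - s0),
        tibble(unit_id = id_map[as.character(base$neuron)],
               trial_id = tr$trial_id[k],
               time_ms = base$time_ms - b0 - base_len)
      )
    }
    spike_rows[[gi]] <- bind_rows(per_trial)
  }
  recording(units, select(trials, "trial_id", "intensity"),
            bind_rows(spike_rows))
}
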