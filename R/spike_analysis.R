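#' Assemble a recording object
#'
#' A `recording` holds extracellular units and their trial-aligned spike
#' times. Spike times are in ms relative to photostimulus onset; the
#' analysis uses a 1 s stimulation window `[0, 1000)` and a 500 ms baseline
#' window `[-500, 0)` before onset.
#'
#' @param units tibble with `unit_id` and `width` (trough-to-peak spike
#'   width, ms); a `class` column is added via [classify_unit()] if absent.
#' @param trials tibble with `trial_id` and `intensity` (mW/mm^2; 0 for
#'   control trials).
#' @param spikes tibble with `unit_id`, `trial_id`, `time_ms`.
#' @return A list of class `recording`.
#' @export
recording <- function(units, trials, spikes) {
  units <- as_tibble(units)
  if (!"class" %in% names(units)) {
    units$class <- classify_unit(units$width)
  }
  structure(list(units = units, trials = as_tibble(trials),
                 spikes = as_tibble(spikes)),
            class = "recording")
}

#' Classify units by spike width
#'
#' Units with trough-to-peak spike width below 0.35 ms are fast-spiking
#' (`"FS"`, putatively PV-positive); above 0.45 ms, putative pyramidal
#' (`"PC"`); intermediate widths (including the boundary values) are
#' `"excluded"` from analysis.
#'
#' @param width spike width(s) in ms; must be positive.
#' @return Character vector in `c("FS", "PC", "excluded")`.
#' @examples
#' classify_unit(c(0.30, 0.50, 0.40))
#' @export
classify_unit <- function(width) {
  if (any(width <= 0)) abort("spike width must be positive")
  dplyr::case_when(width < 0.35 ~ "FS",
                   width > 0.45 ~ "PC",
                   TRUE ~ "excluded")
}

#' Trial-window spike rates per unit and intensity
#'
#' Counts spikes in the stimulation window `[0, 1000)` ms and the baseline
#' window `[-500, 0)` ms of every trial, converts to rates, and averages
#' across the trials of each laser intensity. The unit's overall baseline
#' rate (pooled over all trials, since every trial contributes a pre-stimulus
#' window) is attached as `base_rate_all`.
#'
#' @param rec a [recording()].
#' @param stim_window,base_window analysis windows in ms relative to onset.
#' @return A tibble with `unit_id`, `class`, `intensity`, `stim_rate`,
#'   `base_rate` (per-intensity), `base_rate_all`, `n_trials`.
#' @export
windowed_rates <- function(rec, stim_window = c(0, 1000),
                           base_window = c(-500, 0)) {
  if (nrow(rec$trials) == 0) abort("recording has no trials")
  stim_len <- diff(stim_window) / 1000
  base_len <- diff(base_window) / 1000
  counts <- rec$spikes |>
    group_by(.data$unit_id, .data$trial_id) |>
    summarise(
      n_stim = sum(.data$time_ms >= stim_window[1] &
                     .data$time_ms < stim_window[2]),
      n_base = sum(.data$time_ms >= base_window[1] &
                     .data$time_ms < base_window[2]),
      .groups = "drop"
    )
  grid <- tidyr::expand_grid(unit_id = rec$units$unit_id,
                             trial_id = rec$trials$trial_id)
  per_trial <- grid |>
    left_join(counts, by = c("unit_id", "trial_id")) |>
    mutate(n_stim = dplyr::coalesce(.data$n_stim, 0L),
           n_base = dplyr::coalesce(.data$n_base, 0L)) |>
    left_join(rec$trials, by = "trial_id")
  base_all <- per_trial |>
    group_by(.data$unit_id) |>
    summarise(base_rate_all = mean(.data$n_base) / base_len, .groups = "drop")
  per_trial |>
    group_by(.data$unit_id, .data$intensity) |>
    summarise(stim_rate = mean(.data$n_stim) / stim_len,
              base_rate = mean(.data$n_base) / base_len,
              n_trials = n(), .groups = "drop") |>
    left_join(base_all, by = "unit_id") |>
    left_join(select(rec$units, "unit_id", "class"), by = "unit_id") |>
    select("unit_id", "class", "intensity", "stim_rate", "base_rate",
           "base_rate_all", "n_trials")
}

#' Normalized spike-rate response table
#'
#' Normalized spike rate is the rate during photostimulation divided by the
#' pre-stimulus baseline rate. Two modes follow two distinct orders of
#' operations: per-unit normalization divides each unit's stimulation rate
#' by its own baseline (units with zero baseline are flagged and excluded
#' from per-unit statistics); population normalization *first* averages
#' stimulation rates across the units of a class, *then* divides by the
#' averaged baseline rate -- the two orders differ whenever rates are
#' heterogeneous. The laser-off point is the baseline itself, so the
#' population normalized rate at intensity 0 is exactly 1.
#'
#' @param rec a [recording()], or a precomputed [windowed_rates()] tibble.
#' @param classes unit classes to include (default `c("PC", "FS")`).
#' @param se add a bootstrap standard error (resampling units with
#'   replacement within each class) to the population table.
#' @param reps,seed bootstrap settings (see [bootstrap_sem()]).
#' @return A list of class `response_table` with `$units` (per-unit
#'   `norm_rate` by intensity, `flagged_zero_baseline`) and `$population`
#'   (per class and intensity: `mean_stim`, `mean_base`, `norm_rate`,
#'   optionally `sem`, and `n_units`).
#' @examples
#' # average-then-normalize: units (stim, base) = (2,4) and (6,2)
#' # give (2+6)/(4+2) = 4/3, not the mean of per-unit ratios 1.75
#' @export
normalize_responses <- function(rec, classes = c("PC", "FS"), se = FALSE,
                                reps = 10000, seed = 1) {
  rates <- if (inherits(rec, "recording")) windowed_rates(rec) else as_tibble(rec)
  rates <- filter(rates, .data$class %in% classes)
  units <- rates |>
    mutate(flagged_zero_baseline = .data$base_rate_all == 0,
           norm_rate = ifelse(.data$base_rate_all > 0,
                              ifelse(.data$intensity == 0, 1,
                                     .data$stim_rate / .data$base_rate_all),
                              NA_real_))
  pop_cell <- function(df) {
    # average across units first, then normalize
    tibble(mean_stim = mean(df$stim_rate), mean_base = mean(df$base_rate_all),
           n_units = nrow(df))
  }
  population <- units |>
    group_by(.data$class, .data$intensity) |>
    summarise(pop_cell(dplyr::pick(dplyr::everything())), .groups = "drop") |>
    mutate(norm_rate = ifelse(.data$intensity == 0, 1,
                              .data$mean_stim / .data$mean_base))
  if (se) {
    set.seed(seed)
    sems <- population |>
      group_by(.data$class, .data$intensity) |>
      summarise(.groups = "drop", sem = {
        df <- filter(units, .data$class == dplyr::cur_group()$class,
                     .data$intensity == dplyr::cur_group()$intensity)
        if (dplyr::cur_group()$intensity == 0 || nrow(df) < 2) 0 else {
          ids <- seq_len(nrow(df))
          reps_vals <- vapply(seq_len(reps), function(k) {
            take <- sample(ids, replace = TRUE)
            mean(df$stim_rate[take]) / mean(df$base_rate_all[take])
          }, numeric(1))
          sd(reps_vals)
        }
      })
    population <- left_join(population, sems, by = c("class", "intensity"))
  }
  structure(list(units = units, population = population),
            class = "response_table")
}

#' Bootstrap standard error of the mean over neurons
#'
#' Resamples whole neurons with replacement (each neuron's values across
#' intensities move together when a matrix is supplied), recomputes the mean
#' on every resample, and reports the standard deviation of the resampled
#' means as the SEM, plus a percentile confidence interval.
#'
#' @param values numeric vector (one statistic per neuron) or a matrix with
#'   one row per neuron.
#' @param reps number of bootstrap resamples (>= 100).
#' @param seed RNG seed.
#' @param conf percentile CI level.
#' @return A list with `sem`, `ci` (and per-column results for matrices).
#' @examples
#' bootstrap_sem(c(0, 1), reps = 10000)$sem  # -> sqrt(0.125) as reps grows
#' @export
bootstrap_sem <- function(values, reps = 10000, seed = 1, conf = 0.95) {
  if (length(values) == 0) abort("empty input")
  if (reps < 100) abort("use at least 100 bootstrap replicates")
  m <- if (is.matrix(values)) values else matrix(values, ncol = 1)
  n <- nrow(m)
  set.seed(seed)
  boots <- matrix(NA_real_, reps, ncol(m))
  for (k in seq_len(reps)) {
    boots[k, ] <- colMeans(m[sample.int(n, replace = TRUE), , drop = FALSE])
  }
  alpha <- (1 - conf) / 2
  sem <- apply(boots, 2, sd)
  ci <- apply(boots, 2, stats::quantile, probs = c(alpha, 1 - alpha))
  if (!is.matrix(values)) {
    list(sem = sem[1], ci = unname(ci[, 1]))
  } else {
    list(sem = sem, ci = ci)
  }
}

#' Response slopes and the PV/PC slope ratio
#'
#' Fits an ordinary least-squares line to the population normalized rate
#' against laser intensity, using intensities at or below `max_intensity`
#' (chosen below the intensity at which the PV rate starts to rise, so the
#' fit captures the initial response) and including the laser-off point at
#' normalized rate 1. Per-unit slopes use each unit's own normalized curve.
#' Uncertainty comes from bootstrapping units within each class
#' independently; the ratio SEM is the standard deviation of the resampled
#' FS/PC slope ratios.
#'
#' @param table a `response_table` from [normalize_responses()].
#' @param max_intensity largest intensity entering the fit (mW/mm^2).
#' @param reps,seed bootstrap settings.
#' @return A list of class `slope_estimate` with `$slopes` (per class:
#'   `slope`, `sem`, `n_units`), `$ratio` (FS/PC `estimate`, `sem`, `ci`),
#'   and `$unit_slopes`.
#' @export
response_slope <- function(table, max_intensity = Inf, reps = 10000,
                           seed = 1) {
  units <- filter(table$units, .data$intensity <= max_intensity,
                  !.data$flagged_zero_baseline)
  if (length(unique(units$intensity)) < 2) {
    abort("need at least two intensity points at or below max_intensity")
  }
  ols_slope <- function(x, y) {
    xc <- x - mean(x)
    sum(xc * (y - mean(y))) / sum(xc^2)
  }
  classes <- sort(unique(units$class))
  # per class: units x intensities matrix of stimulation rates plus the
  # per-unit pooled baselines; the average-then-normalized slope of any
  # unit resample is then a couple of column sums
  class_mats <- purrr::map(classes, function(cl) {
    df <- filter(units, .data$class == cl)
    wide <- tidyr::pivot_wider(df[, c("unit_id", "intensity", "stim_rate")],
                               names_from = "intensity",
                               values_from = "stim_rate")
    ints <- as.numeric(names(wide)[-1])
    ord <- order(ints)
    S <- as.matrix(wide[, -1, drop = FALSE])[, ord, drop = FALSE]
    b <- df$base_rate_all[match(wide$unit_id, df$unit_id)]
    ints <- ints[ord]
    # the laser-off point (normalized rate 1) always enters the fit
    x <- if (0 %in% ints) ints else c(0, ints)
    xc <- x - mean(x)
    list(S = S, b = b, ints = ints, x = x, xc = xc, n = nrow(S))
  })
  names(class_mats) <- classes
  slope_of <- function(m, idx) {
    norm <- colSums(m$S[idx, , drop = FALSE]) / sum(m$b[idx])
    if (0 %in% m$ints) norm[m$ints == 0] <- 1 else norm <- c(1, norm)
    sum(m$xc * norm) / sum(m$xc^2)
  }
  slopes <- purrr::map(classes, function(cl) {
    m <- class_mats[[cl]]
    tibble(class = cl, slope = slope_of(m, seq_len(m$n)), n_units = m$n)
  }) |> bind_rows()
  unit_slopes <- units |>
    group_by(.data$unit_id, .data$class) |>
    summarise(slope = ols_slope(.data$intensity, .data$norm_rate),
              .groups = "drop")
  # independent bootstrap over units within each class
  set.seed(seed)
  boots <- purrr::map(classes, function(cl) {
    m <- class_mats[[cl]]
    vapply(seq_len(reps), function(k) {
      slope_of(m, sample.int(m$n, replace = TRUE))
    }, numeric(1))
  })
  names(boots) <- classes
  slopes$sem <- vapply(classes, function(cl) sd(boots[[cl]]), numeric(1))
  ratio <- NULL
  if (all(c("FS", "PC") %in% classes)) {
    pc <- slopes$slope[slopes$class == "PC"]
    if (pc == 0) {
      warn("PC slope is zero: slope ratio undefined")
      ratio <- list(estimate = NA_real_, sem = NA_real_,
                    ci = c(NA_real_, NA_real_))
    } else {
      rboot <- boots[["FS"]] / boots[["PC"]]
      rboot <- rboot[is.finite(rboot)]
      ratio <- list(
        estimate = slopes$slope[slopes$class == "FS"] / pc,
        sem = sd(rboot),
        ci = unname(stats::quantile(rboot, c(0.025, 0.975)))
      )
    }
  }
  structure(list(slopes = slopes, ratio = ratio, unit_slopes = unit_slopes,
                 max_intensity = max_intensity),
            class = "slope_estimate")
}

#' Response-category fractions
#'
#' Classifies every unit at every laser intensity: `silenced` when the
#' stimulation-window rate falls below `rate_threshold` (evaluated on the
#' stimulation rate regardless of baseline, and taking precedence);
#' otherwise `increase` / `decrease` when the rate change from baseline
#' exceeds `rate_threshold` in magnitude, `no_change` otherwise. Fractions
#' sum to 1 within every class-intensity cell.
#'
#' @param table a `response_table` or [windowed_rates()] tibble.
#' @param rate_threshold rate criterion in Hz (default 0.1).
#' @return A tibble with `class`, `intensity`, `category`, `n`, `fraction`.
#' @export
response_fractions <- function(table, rate_threshold = 0.1) {
  units <- if (inherits(table, "response_table")) table$units else
    as_tibble(table)
  units |>
    filter(.data$intensity > 0) |>
    mutate(category = dplyr::case_when(
      .data$stim_rate < rate_threshold ~ "silenced",
      .data$stim_rate - .data$base_rate_all > rate_threshold ~ "increase",
      .data$stim_rate - .data$base_rate_all < -rate_threshold ~ "decrease",
      TRUE ~ "no_change"
    )) |>
    group_by(.data$class, .data$intensity, .data$category) |>
    summarise(n = n(), .groups = "drop_last") |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    ungroup() |>
    tidyr::complete(.data$class, .data$intensity,
                    category = c("increase", "decrease", "no_change",
                                 "silenced"),
                    fill = list(n = 0L, fraction = 0)) |>
    rename(class = 1, intensity = 2)
}

#' @export
print.recording <- function(x, ...) {
  cat("<recording>", nrow(x$units), "units,", nrow(x$trials), "trials,",
      nrow(x$spikes), "spikes\n")
  print(dplyr::count(x$units, .data$class))
  invisible(x)
}

#' @export
print.response_table <- function(x, ...) {
  cat("<response_table>\n")
  print(x$population, n = 20)
  invisible(x)
}
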