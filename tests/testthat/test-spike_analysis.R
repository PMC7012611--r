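test_that("spike-width classification uses the standard width thresholds", {
  expect_equal(classify_unit(c(0.30, 0.50, 0.40)), c("FS", "PC", "excluded"))
  # boundary widths are excluded (strict inequalities)
  expect_equal(classify_unit(c(0.35, 0.45)), c("excluded", "excluded"))
  expect_error(classify_unit(0), "positive")
})

test_that("windowed rates convert counts with the documented windows", {
  # two trials at one intensity, built by hand
  trials <- tibble::tibble(trial_id = 1:2, intensity = 0.5)
  spikes <- dplyr::bind_rows(
    tibble::tibble(unit_id = "u1", trial_id = 1,
                   time_ms = c(seq(1, 999, length.out = 3), -c(100, 200))),
    tibble::tibble(unit_id = "u1", trial_id = 2,
                   time_ms = c(seq(1, 999, length.out = 5), -c(100, 200)))
  )
  rec <- recording(tibble::tibble(unit_id = "u1", width = 0.5),
                   trials, spikes)
  wr <- windowed_rates(rec)
  # 8 spikes over two 1 s windows -> 4 Hz; 2 spikes in each 500 ms window -> 4 Hz
  expect_equal(wr$stim_rate, 4)
  expect_equal(wr$base_rate, 4)
  expect_equal(wr$n_trials, 2L)
})

test_that("population normalization averages before dividing", {
  # units (stim, base) = (2, 4) and (6, 2) Hz, both PC
  counts <- tibble::tibble(
    unit_id = c("a", "a", "b", "b"), width = 0.5,
    intensity = c(0, 1, 0, 1),
    n_stim = c(4L, 2L, 2L, 6L),  # at intensity 0 the stim window sees baseline
    n_base = c(2L, 2L, 1L, 1L)   # 500 ms window: 2 spikes -> 4 Hz, 1 -> 2 Hz
  )
  rec <- toy_recording(counts)
  rt <- normalize_responses(rec)
  pop1 <- rt$population[rt$population$intensity == 1, ]
  expect_equal(pop1$norm_rate, (2 + 6) / (4 + 2))
  # whereas per-unit normalization would give mean(0.5, 3) = 1.75
  u1 <- rt$units[rt$units$intensity == 1, ]
  expect_equal(sort(u1$norm_rate), c(0.5, 3))
  expect_equal(mean(u1$norm_rate), 1.75)
  # laser-off rows are exactly 1
  expect_equal(rt$population$norm_rate[rt$population$intensity == 0], 1)

  # all units at baseline -> 1 everywhere
  flat <- tibble::tibble(unit_id = c("a", "a"), width = 0.5,
                         intensity = c(0, 1), n_stim = c(4L, 4L),
                         n_base = c(2L, 2L))
  rtf <- normalize_responses(toy_recording(flat))
  expect_equal(rtf$population$norm_rate, c(1, 1))
})

test_that("population normalization is invariant to unit and trial relabeling", {
  cfg <- synthetic_config(area = "S1", intensities = c(0.2, 0.5),
                          trials_per_intensity = 5)
  rec <- generate_recording(cfg, seed = 8)
  rt <- normalize_responses(rec)
  # shuffle unit ids and trial order
  perm <- sample(nrow(rec$units))
  relabel <- setNames(paste0("z", seq_len(nrow(rec$units))),
                      rec$units$unit_id[perm])
  rec2 <- rec
  rec2$units <- rec$units[perm, ]
  rec2$units$unit_id <- unname(relabel[rec2$units$unit_id])
  rec2$spikes$unit_id <- unname(relabel[rec$spikes$unit_id])
  rec2$spikes <- rec2$spikes[sample(nrow(rec2$spikes)), ]
  rec2$trials <- rec2$trials[sample(nrow(rec2$trials)), ]
  rt2 <- normalize_responses(rec2)
  expect_equal(rt$population$norm_rate, rt2$population$norm_rate)
})

test_that("the neuron bootstrap reproduces exact small-sample results", {
  # all values equal -> SEM 0; single neuron -> SEM 0
  expect_equal(bootstrap_sem(rep(2.5, 6), reps = 500)$sem, 0)
  expect_equal(bootstrap_sem(3.14, reps = 500)$sem, 0)
  # {0, 1}: the 4 equiprobable resamples give SD sqrt(0.125)
  expect_equal(bootstrap_sem(c(0, 1), reps = 10000, seed = 2)$sem,
               sqrt(0.125), tolerance = 0.02 / sqrt(0.125))
  expect_error(bootstrap_sem(numeric(0)), "empty")
  expect_error(bootstrap_sem(1:5, reps = 10), "at least 100")
})

test_that("bootstrap SEM scales as one over the square root of n", {
  set.seed(31)
  ns <- c(10, 40, 160, 640)
  sems <- vapply(ns, function(n) {
    bootstrap_sem(rnorm(n), reps = 2000, seed = n)$sem
  }, numeric(1))
  slope <- coef(lm(log(sems) ~ log(ns)))[2]
  expect_equal(unname(slope), -0.5, tolerance = 0.1)
})

test_that("slopes are exact on linear responses and the ratio is 1 for twins", {
  # PC unit tracing exactly 1 - 2 * Gamma, FS unit identical
  counts <- dplyr::bind_rows(lapply(list(c("p", 0.5), c("f", 0.3)),
    function(u) {
      tibble::tibble(unit_id = u[1], width = as.numeric(u[2]),
                     intensity = c(0, 0.1, 0.2, 0.3),
                     n_stim = c(10L, 8L, 6L, 4L), n_base = c(5L, 5L, 5L, 5L))
    }))
  rec <- toy_recording(counts)
  rt <- normalize_responses(rec)
  sl <- response_slope(rt, max_intensity = 0.3, reps = 200)
  expect_equal(sl$slopes$slope, c(-2, -2))
  expect_equal(sl$ratio$estimate, 1)
  expect_equal(sl$unit_slopes$slope, c(-2, -2))
  expect_error(response_slope(rt, max_intensity = 0.05), "two intensity")
})

test_that("response categories follow the threshold rules and sum to one", {
  counts <- tibble::tibble(
    unit_id = c("a", "a", "b", "b", "c", "c", "d", "d"), width = 0.5,
    intensity = rep(c(0, 1), 4),
    # pooled baselines 5, 5, 1, 5 Hz; stim rates 6 (increase), 0 (silenced),
    # 1 (no change), 3 (decrease)
    n_stim = c(5L, 6L, 5L, 0L, 1L, 1L, 5L, 3L),
    n_base = c(2L, 3L, 2L, 3L, 0L, 1L, 2L, 3L)
  )
  rec <- toy_recording(counts)
  rt <- normalize_responses(rec)
  fr <- response_fractions(rt)
  got <- setNames(fr$fraction, fr$category)
  expect_equal(unname(got[c("increase", "silenced", "no_change", "decrease")]),
               rep(0.25, 4))
  sums <- tapply(fr$fraction, list(fr$class, fr$intensity), sum)
  expect_true(all(abs(sums - 1) < 1e-12))

  # silenced takes precedence over decrease even with high baseline
  one <- toy_recording(tibble::tibble(
    unit_id = "s", width = 0.5, intensity = c(0, 1),
    n_stim = c(5L, 0L), n_base = c(3L, 3L)
  ))
  fr1 <- response_fractions(normalize_responses(one))
  expect_equal(fr1$fraction[fr1$category == "silenced"], 1)
})

test_that("zero-baseline units are excluded from per-unit but kept in population", {
  counts <- tibble::tibble(
    unit_id = c("a", "a", "z", "z"), width = 0.5,
    intensity = c(0, 1, 0, 1),
    n_stim = c(4L, 2L, 0L, 3L),
    n_base = c(2L, 2L, 0L, 0L)
  )
  rt <- normalize_responses(toy_recording(counts))
  z <- rt$units[rt$units$unit_id == "z", ]
  expect_true(all(z$flagged_zero_baseline))
  expect_true(all(is.na(z$norm_rate)))
  # population mean still includes the unit's stimulation rate
  pop1 <- rt$population[rt$population$intensity == 1, ]
  expect_equal(pop1$mean_stim, (2 + 3) / 2)
  expect_equal(pop1$n_units, 2L)
})
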