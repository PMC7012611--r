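test_that("balanced rates match independent linear solves", {
  # two-population circuit: 170 + 29 rE - 30 rI = 0, 170 + 36 rE - 36 rI = 0
  oracle2 <- solve(matrix(c(29, 36, -30, -36), 2), -c(170, 170))
  st <- solve_balance(balance_problem(load_architecture("two_pop")))
  expect_true(st$consistent)
  expect_equal(st$rates$rate, unname(oracle2), tolerance = 1e-12)
  expect_equal(st$rates$rate, c(28.3333, 33.0556), tolerance = 1e-4)

  # PC/PV/SOM/X circuit at rest
  A4 <- rbind(c(20, -30, -32, -36), c(40, -28, -16, -32),
              c(26, -12, 0, 0), c(24, 0, -36, -22))
  oracle4 <- solve(A4, -c(480, 290, 0, 240))
  st2 <- solve_balance(balance_problem(load_architecture("model2")))
  expect_true(st2$consistent)
  expect_equal(st2$rates$rate, unname(oracle4), tolerance = 1e-12)
  expect_equal(st2$rates$rate, c(3.0362, 6.5783, 6.2653, 3.9690),
               tolerance = 1e-4)

  # scalar balance: a single self-inhibiting population
  one <- circuit_spec(
    populations = "I", polarity = c(I = -1),
    J = matrix(10, 1, 1, dimnames = list("I", "I")), J0 = c(I = 1),
    tau = matrix(2, 1, 1, dimnames = list("I", "I")),
    neuron = list(C_M = 1, g_leak = c(I = 0.1), V_th = -50, V_R = -70),
    opto = list(targets = "I")
  )
  st1 <- solve_balance(balance_problem(one))
  expect_equal(st1$rates$rate, 2 * 1 * 5 / 10)
})

test_that("solved states satisfy the balance residual bound", {
  for (s in 1:25) {
    spec <- random_spec(n_inh = sample(1:3, 1), seed = s)
    pr <- balance_problem(spec, I_opto = runif(1, 0, 30))
    for (st in consistent_states(pr)) {
      act <- st$active
      if (length(act) == 0) next
      r <- setNames(st$rates$rate, st$rates$population)
      res <- max(abs(pr$c[act] + drop(pr$A %*% r)[act]))
      expect_lt(res, 1e-9)
    }
  }
})

test_that("consistent-state enumeration agrees with the brute-force oracle", {
  # documented examples first
  tp <- load_architecture("two_pop")
  sts0 <- consistent_states(balance_problem(tp, I_opto = 0))
  expect_length(sts0, 1)
  expect_equal(sts0[[1]]$active, c("E", "I"))

  sts50 <- consistent_states(balance_problem(tp, I_opto = 50))
  expect_length(sts50, 1)
  expect_equal(sts50[[1]]$active, "I")
  expect_equal(sts50[[1]]$rates$rate[2], (170 + 50) / 36)

  # random problems, exhaustive oracle
  for (s in 1:30) {
    spec <- random_spec(n_inh = sample(1:3, 1), seed = 100 + s)
    pr <- balance_problem(spec, I_opto = runif(1, 0, 60))
    got <- consistent_states(pr)
    want <- oracle_states(pr$A, pr$c)
    expect_length(got, length(want))
    got_sets <- sort(vapply(got, function(x) paste(sort(x$active),
                                                   collapse = ","), ""))
    want_sets <- sort(vapply(want, function(x) {
      paste(sort(spec$populations[x$active]), collapse = ",")
    }, ""))
    expect_equal(got_sets, want_sets)
  }
})

test_that("degenerate active blocks are reported explicitly", {
  spec <- random_spec(n_inh = 1, seed = 7)
  spec$J["E", ] <- spec$J["I1", ]  # proportional rows: singular A
  expect_error(solve_balance(balance_problem(spec)), "degenerate determinant")
})

test_that("the two-population sweep is piecewise linear with the exact breakpoint", {
  tp <- load_architecture("two_pop")
  sw <- sweep_opto(tp, I_opto = seq(0, 60, by = 2))
  bps <- attr(sw, "breakpoints")
  expect_equal(nrow(bps), 1)
  # E silences exactly at I_opto = 34 (rE = (34 - I)/1.2)
  expect_equal(bps$I_opto, 34, tolerance = 1e-6)

  rI <- sw[sw$population == "I", ]
  before <- rI[rI$I_opto <= 34, ]
  after <- rI[rI$I_opto >= 36, ]
  # closed-form branch slopes: -29/36 while E is active, +1/36 after
  fit_b <- lm(rate ~ I_opto, data = before)
  fit_a <- lm(rate ~ I_opto, data = after)
  expect_equal(unname(coef(fit_b)[2]), -29 / 36, tolerance = 1e-9)
  expect_equal(unname(coef(fit_a)[2]), 1 / 36, tolerance = 1e-9)
  expect_lt(max(abs(residuals(fit_b))), 1e-9)
  expect_lt(max(abs(residuals(fit_a))), 1e-9)
  # the PV minimum sits at the breakpoint where E reaches zero
  expect_equal(rI$I_opto[which.min(rI$rate)], 34)
  # normalized rates are 1 at baseline
  expect_equal(sw$norm_rate[sw$I_opto == 0], c(1, 1))
})

test_that("susceptibility matches finite differences and the documented signs", {
  chi_tp <- susceptibility(load_architecture("two_pop"))
  expect_equal(unname(chi_tp), -solve(matrix(c(29, 36, -30, -36), 2)))

  expect_equal(susceptibility(load_architecture("two_pop_noEE"))["I", "I"], 0)

  chi_np <- susceptibility(load_architecture("model1_nonparadox"))
  expect_gt(chi_np["I", "I"], 0)
  expect_gt(chi_np["E", "I"] * chi_np["I", "E"], 0)
  expect_lt(susceptibility(load_architecture("model1_paradox"))["I", "I"], 0)

  # derivative property against central differences of the solver
  eps <- 1e-6
  for (s in 1:20) {
    spec <- random_spec(n_inh = sample(1:3, 1), seed = 200 + s)
    chi <- susceptibility(spec)
    pr <- balance_problem(spec)
    pops <- spec$populations
    b <- sample(pops, 1)
    pr_hi <- pr; pr_hi$c[b] <- pr_hi$c[b] + eps
    pr_lo <- pr; pr_lo$c[b] <- pr_lo$c[b] - eps
    fd <- (solve_balance(pr_hi)$rates$rate -
             solve_balance(pr_lo)$rates$rate) / (2 * eps)
    expect_equal(fd, unname(chi[, b]), tolerance = 1e-6)
  }
})

test_that("paradox criteria agree with the susceptibility sign on all fixtures", {
  aud_np <- paradox_audit(load_architecture("model1_nonparadox"))
  expect_equal(aud_np$jee_star, 12 * 41 / 35)
  expect_false(aud_np$paradoxical)

  aud_p <- paradox_audit(load_architecture("model1_paradox"))
  expect_equal(aud_p$jee_star, 31.2 * 32.8 / 14.6)
  expect_true(aud_p$paradoxical)

  aud_m2 <- paradox_audit(load_architecture("model2"))
  expect_equal(aud_m2$criteria$margin, c(36 * 36 - 22 * 32, 32 * 36 - 22 * 16))
  expect_true(all(aud_m2$criteria$holds))

  for (nm in builtin_architectures()) {
    aud <- paradox_audit(load_architecture(nm))
    expect_true(aud$agreement, info = nm)
  }

  # unsupported topology falls back to the generic susceptibility sign
  expect_warning(aud_g <- paradox_audit(random_spec(n_inh = 2, seed = 3)),
                 "unsupported topology")
  expect_equal(aud_g$paradoxical, aud_g$chi_II < 0)
})

test_that("the determinant stability condition behaves as documented", {
  expect_equal(stability_check(load_architecture("two_pop"))$det, 36)
  expect_true(stability_check(load_architecture("two_pop"))$necessary_ok)
  expect_equal(stability_check(load_architecture("model1_nonparadox"))$det,
               208382.72, tolerance = 1e-6)
  tp <- load_architecture("two_pop")
  tp$J["E", "I"] <- 0
  tp$tau["E", "I"] <- NA
  sc <- stability_check(tp)
  expect_equal(sc$det, -1044)
  expect_false(sc$necessary_ok)
})

test_that("SOM balance ties population pairs in fixed proportion along sweeps", {
  m1 <- load_architecture("model1_nonparadox")
  pr1 <- proportionality_ratio(m1)
  expect_equal(pr1$pair, c("V", "E"))
  expect_equal(pr1$ratio, 24 / 14)
  expect_equal(pr1$observed, pr1$ratio, tolerance = 1e-9)

  m2 <- load_architecture("model2")
  pr2 <- proportionality_ratio(m2)
  expect_equal(pr2$ratio, 26 / 12)
  expect_equal(pr2$observed, pr2$ratio, tolerance = 1e-9)

  # normalized E and V trajectories coincide while all populations are active
  sw1 <- sweep_opto(m1, I_opto = seq(0, 10, by = 0.5))
  all_active <- sw1$active_set == "E+I+S+V"
  wide <- tidyr::pivot_wider(sw1[all_active, c("I_opto", "population",
                                               "norm_rate")],
                             names_from = "population",
                             values_from = "norm_rate")
  expect_lt(max(abs(wide$E - wide$V)), 1e-9)

  # E and I stay proportional wherever SOM is active
  sw2 <- sweep_opto(m2, I_opto = seq(0, 40, by = 2))
  with_som <- dplyr::filter(
    tidyr::pivot_wider(sw2[, c("I_opto", "population", "rate")],
                       names_from = "population", values_from = "rate"),
    S > 0
  )
  expect_lt(max(abs(with_som$I / with_som$E - 26 / 12)), 1e-9)
})

test_that("rates are piecewise linear between breakpoints on all fixtures", {
  for (nm in c("two_pop", "model1_paradox", "model2")) {
    spec <- load_architecture(nm)
    sw <- sweep_opto(spec, I_opto = seq(0, 80, by = 2.5))
    bps <- attr(sw, "breakpoints")$I_opto
    edges <- c(-Inf, bps, Inf)
    for (seg in seq_len(length(edges) - 1)) {
      part <- sw[sw$I_opto > edges[seg] + 1e-6 &
                   sw$I_opto < edges[seg + 1] - 1e-6, ]
      for (p in unique(part$population)) {
        d <- part[part$population == p, ]
        if (nrow(d) < 3) next
        fit <- lm(rate ~ I_opto, data = d)
        expect_lt(max(abs(residuals(fit))), 1e-9)
      }
    }
  }
})

test_that("a PC/PV/SOM circuit without the X loop cannot be paradoxical", {
  # random three-population draws with SOM receiving only PC and PV input:
  # whenever the balanced state exists (positive rates, stability necessary
  # condition), the PV self-susceptibility is nonnegative
  set.seed(99)
  n_checked <- 0
  for (k in 1:1000) {
    pops <- c("E", "I", "S")
    J <- matrix(runif(9, 5, 40), 3, 3, dimnames = list(pops, pops))
    J["S", "S"] <- 0
    pol <- c(E = 1, I = -1, S = -1)
    A <- sweep(J, 2, pol, `*`)
    if (-det(A) <= 0) next  # divergence-stability necessary condition, n = 3
    J0 <- c(E = runif(1, 5, 40), I = runif(1, 5, 40), S = 0)
    r <- solve(A, -2 * J0 * 5)
    if (any(r <= 0)) next
    chi_II <- -solve(A)[2, 2]
    expect_gte(chi_II, 0)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 100)
})
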