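test_that("pure decay matches the analytic exponential", {
  k <- 0.0046
  tr <- integrate_scenario(decay_scenario(n0 = 1000, k = k))
  exact <- 1000 * exp(-k * tr$times)
  expect_lt(max(abs(tr$n - exact) / pmax(exact, 1e-12)), 1e-4)
  # half of the population is gone after ln(2)/k minutes
  t_half <- log(2) / k            # about 150.7 min
  i <- which.min(abs(tr$times - t_half))
  expect_equal(tr$n[i], 500, tolerance = 1e-2)
})

test_that("zero dynamics leave the state constant", {
  sc <- scenario(release = release_params(0, 0, 0, 0),
                 kinetics = ctc_kinetics(k_dead = 0, k_deadc = 0,
                                         k_met = 0, k_metc = 0),
                 duration = 1440, h = 1, n0 = 42, c0 = 7, m0 = 3)
  tr <- integrate_scenario(sc)
  expect_true(all(tr$n == 42))
  expect_true(all(tr$c == 7))
  expect_true(all(tr$m == 3))
})

test_that("constant release plateaus at the equilibrium count", {
  tr <- integrate_scenario(plateau_scenario())
  n_eq <- 25 / (0.0046 + 1e-8)
  expect_equal(tail(tr$n, 1), n_eq, tolerance = 1e-4)
})

test_that("trajectories have a uniform grid and non-decreasing burden", {
  reg <- scenario_registry()
  for (id in c("fig2", "fig3", "figA8", "figA9")) {
    tr <- integrate_scenario(reg[[id]])
    len <- length(tr$times)
    expect_identical(len, length(tr$n))
    expect_identical(len, length(tr$m))
    expect_identical(len, length(tr$r))
    expect_equal(diff(tr$times), rep(tr$h, len - 1))
    expect_true(all(diff(tr$m) >= 0))
    expect_true(all(tr$n >= 0) && all(tr$c >= 0))
  }
})

test_that("the delayed burden reads the constant history before the delay", {
  sc <- feedback_scenario()          # m0 = 5, M = 0.01, delay = 720 min
  tr <- integrate_scenario(sc)
  pre <- tr$times < 720
  # while t < delay the release feedback factor is exactly 1 + M * m0,
  # and with a 24 h implanted device the attenuation (1 - eff_dev) applies
  expected_r <- sc$release$r_const * ((1 - 0.9) + 0.01 * 5)
  expect_equal(tr$r[pre], rep(expected_r, sum(pre)))
  # after the delay the lookup switches to the growing stored history
  expect_gt(tail(tr$r, 1), expected_r)
})

test_that("recorded release series agrees with the release law", {
  sc <- circadian_scenario()
  tr <- integrate_scenario(sc)
  idx <- c(1, 101, 181, 3600, length(tr$times))
  for (i in idx) {
    rr <- release_rates(tr$times[i], 0, sc$release, sc$device)
    expect_equal(tr$r[i], rr$r)
    expect_equal(tr$p[i], rr$p)
  }
})

test_that("steps are aligned to switch times or rejected", {
  sc <- circadian_scenario()
  expect_identical(adjust_step(sc, 0.5), 0.5)
  expect_identical(adjust_step(sc, 0.75), 0.75)
  # 32 min does not divide the 3 h window; halving finds 4 min
  expect_warning(h <- adjust_step(sc, 32), "reduced")
  expect_identical(h, 4)
  # 0.7 min can never align with the 1440 min day
  expect_error(suppressWarnings(adjust_step(sc, 0.7)), "align")
  expect_error(integrate_scenario(sc, h = -1), "h must")
})

test_that("a divergent configuration aborts with a diagnostic", {
  stiff <- scenario(release = release_params(0, 0, 0, 0),
                    kinetics = ctc_kinetics(k_dead = 10, k_met = 0,
                                            k_metc = 0),
                    duration = 2880, h = 0.5, n0 = 1000)
  expect_error(integrate_scenario(stiff), "non-finite")
})

test_that("the observed convergence order is two on smooth problems", {
  ord <- convergence_order(decay_scenario(duration = 720, h = 2),
                           c(4, 2, 1, 0.25))
  expect_false(ord$exact)
  expect_gt(ord$order, 1.8)
  expect_lt(ord$order, 2.2)
})

test_that("a constant problem converges exactly", {
  sc <- scenario(release = release_params(0, 0, 0, 0),
                 kinetics = ctc_kinetics(k_dead = 0, k_deadc = 0,
                                         k_met = 0, k_metc = 0),
                 duration = 1440, h = 2, n0 = 10)
  ord <- convergence_order(sc, c(2, 1, 0.5))
  expect_true(ord$exact)
  expect_true(is.na(ord$order))
  expect_error(convergence_order(sc, c(2, 1)), "three")
})

test_that("halving the step leaves scenario metrics essentially unchanged", {
  reg <- scenario_registry()
  for (id in c("fig3", "figA8")) {
    red_h <- run_with_control(reg[[id]], h = 0.5)$reduction_pct
    red_h2 <- run_with_control(reg[[id]], h = 0.25)$reduction_pct
    expect_lt(abs(red_h - red_h2), 0.2)
  }
})

test_that("the midpoint path agrees with a fine-step explicit-Euler oracle", {
  sc <- feedback_scenario()
  ctl <- sc; ctl$device$placement <- "none"
  tr <- integrate_scenario(sc)
  tc <- integrate_scenario(ctl)
  ref_dev <- euler_oracle(sc, h = 0.005)
  ref_ctl <- euler_oracle(ctl, h = 0.005)
  expect_equal(tail(tr$n, 1), ref_dev$n, tolerance = 1e-4)
  expect_equal(tail(tr$m, 1), ref_dev$m, tolerance = 1e-4)
  red_pkg <- 100 * (tail(tc$m, 1) - tail(tr$m, 1)) / tail(tc$m, 1)
  red_ora <- 100 * (ref_ctl$m - ref_dev$m) / ref_ctl$m
  expect_lt(abs(red_pkg - red_ora), 0.5)
})
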