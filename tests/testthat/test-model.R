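test_that("circadian release peaks at baseline plus amplitude", {
  rel <- suppressWarnings(release_params(5, 40, 10, 60))
  dev <- device_params("extracorporeal", T_dev = 180, R_vol = 0.1)
  t_peak <- release_peak_time(dev)
  expect_equal(t_peak, 90)
  at_peak <- release_rates(t_peak, 0, rel, dev)
  expect_equal(at_peak$r, 45)
  expect_equal(at_peak$p, 70)
  at_trough <- release_rates(t_peak + 720, 0, rel, dev)
  expect_equal(at_trough$r, 5)
  expect_equal(at_trough$p, 10)
})

test_that("zero amplitude gives a constant release at any time", {
  rel <- release_params(25, 0, 30, 0)
  dev <- device_params("none")
  for (t in c(0, 17.3, 900, 5000)) {
    rr <- release_rates(t, 0, rel, dev)
    expect_equal(rr$r, 25)
    expect_equal(rr$p, 30)
  }
})

test_that("implanted attenuation and metastatic bypass combine additively", {
  # a perfect implanted device nulls the primary release entirely
  rel <- release_params(10, 0, 10, 0)
  perfect <- device_params("implanted", T_dev = 1440, R_vol = 0.02,
                           eff_dev = 1, eff_devc = 1)
  expect_equal(release_rates(300, 0, rel, perfect)$r, 0)
  # with feedback, the metastasis-derived release passes the device:
  # r = 10 * ((1 - 0.9) + 0.01 * 100) = 11
  rel_fb <- release_params(10, 0, 10, 0, M = 0.01)
  dev <- device_params("implanted", T_dev = 1440, R_vol = 0.02,
                       eff_dev = 0.9, eff_devc = 0.99)
  expect_equal(release_rates(300, 100, rel_fb, dev)$r,
               10 * (0.1 + 1.0))
  # while the device is off, the primary release is not attenuated
  off_dev <- device_params("implanted", T_dev = 180, R_vol = 0.02,
                           eff_dev = 0.9, eff_devc = 0.99)
  expect_equal(release_rates(1000, 0, rel, off_dev)$r, 10)
})

test_that("release rejects invalid time and delayed burden", {
  rel <- release_params()
  dev <- device_params("none")
  expect_error(release_rates(-1, 0, rel, dev), "non-negative")
  expect_error(release_rates(0, NaN, rel, dev), "m_delayed")
  expect_error(device_on(-5, dev), "non-negative")
})

test_that("daily device window repeats and respects placement", {
  dev <- device_params("extracorporeal", T_dev = 180, R_vol = 0.1)
  expect_true(device_on(90, dev))
  expect_false(device_on(200, dev))
  expect_true(device_on(1440 + 90, dev))
  expect_false(device_on(1440 - 1, dev))
  always <- device_params("extracorporeal", T_dev = 1440, R_vol = 0.1)
  expect_true(all(device_on(seq(0, 5000, by = 13), always)))
  expect_false(any(device_on(seq(0, 5000, by = 13),
                             device_params("none"))))
  onoff <- device_params("implanted", T_dev = 0, R_vol = 0.1)
  expect_false(any(device_on(c(0, 100), onoff)))
})

test_that("one-off windows override the daily schedule", {
  dev <- device_params("implanted", T_dev = 1440, R_vol = 0.02,
                       eff_dev = 0.9, eff_devc = 0.99,
                       window_start = 1440, window_end = 2160)
  expect_false(device_on(100, dev))
  expect_true(device_on(1440, dev))
  expect_true(device_on(2159, dev))
  expect_false(device_on(2160, dev))
})

test_that("intrinsic dynamics match the rate balance", {
  kin <- ctc_kinetics(k_dead = 0.0046, k_met = 1e-8)
  dyn <- intrinsic_dynamics(1000, 0, kin)
  expect_equal(dyn$f_dyn, -1000 * (0.0046 + 1e-8))
  expect_equal(intrinsic_dynamics(0, 0, kin),
               list(f_dyn = 0, g_dyn = 0))
  # disrupted clusters seed singles when N_c > 0
  kin2 <- ctc_kinetics(k_dead = 0, k_deadc = 0.023, k_met = 0, k_metc = 0,
                       N_c = 1)
  dyn2 <- intrinsic_dynamics(0, 100, kin2)
  expect_equal(dyn2$f_dyn, 2.3)
  expect_equal(dyn2$g_dyn, -2.3)
  expect_error(intrinsic_dynamics(-1, 0, kin), "non-negative")
})

test_that("device clearance terms match the flow balance", {
  dev <- device_params("extracorporeal", T_dev = 180, R_vol = 0.1,
                       eff_dev = 0.9, eff_devc = 0.99)
  expect_equal(device_clearance(1000, 0, dev, on = TRUE)$f_dev, -90)
  expect_equal(device_clearance(1000, 500, dev, on = FALSE),
               list(f_dev = 0, g_dev = 0))
  surv <- device_params("extracorporeal", T_dev = 180, R_vol = 0.02,
                        eff_dev = 0.5, eff_devc = 0.99, N_cdev = 15)
  cl <- device_clearance(0, 200, surv, on = TRUE)
  expect_equal(cl$f_dev, 0.02 * 200 * 0.99 * 15)
  expect_equal(cl$g_dev, -0.02 * 200 * 0.99)
})

test_that("metastasis inflow adds extravasation and lymphatic seeding", {
  kin <- ctc_kinetics()  # k_met = 1e-8, k_metc = 5e-7
  ly0 <- lymph_params()
  expect_equal(metastasis_inflow(1e6, 1e4, 0, 0, kin, ly0), 0.015)
  expect_equal(metastasis_inflow(0, 0, 0, 0, kin, ly0), 0)
  ly <- lymph_params(p_lymph = 0.3, l_pass = 0.0095, l_dead = 0.99)
  expect_equal(metastasis_inflow(0, 0, 100, 0, kin, ly),
               100 * 0.3 * 0.0005)
})

test_that("the assembled derivative matches its parts", {
  # lymph channel inert: dn/dt is exactly release + dynamics + clearance
  sc <- circadian_scenario()
  st <- c(n = 500, c = 200, m = 1)
  d <- ctc_rhs(100, st, 0, sc)
  on <- device_on(100, sc$device)
  rel <- release_rates(100, 0, sc$release, sc$device, on)
  dyn <- intrinsic_dynamics(500, 200, sc$kinetics)
  dev <- device_clearance(500, 200, sc$device, on)
  expect_identical(unname(d["dn"]), rel$r + dyn$f_dyn + dev$f_dev)
  expect_identical(unname(d["dc"]), rel$p + dyn$g_dyn + dev$g_dev)
  # closed-form equilibrium of the constant-release linear system
  sc_eq <- plateau_scenario()
  n_eq <- 25 / (0.0046 + 1e-8)
  d_eq <- ctc_rhs(0, c(n_eq, 0, 0), 0, sc_eq)
  expect_equal(unname(d_eq["dn"]), 0, tolerance = 1e-12)
  # full lymphatic diversion with no return removes the release term
  sc_ly <- scenario(release = release_params(25, 0, 30, 0),
                    lymph = lymph_params(p_lymph = 1, l_pass = 0,
                                         l_dead = 0.99))
  d_ly <- ctc_rhs(0, c(100, 0, 0), 0, sc_ly)
  dyn_ly <- intrinsic_dynamics(100, 0, sc_ly$kinetics)
  expect_identical(unname(d_ly["dn"]), dyn_ly$f_dyn)
})

test_that("released cells split exactly into blood, lymph death and seeding", {
  set.seed(11)
  for (i in 1:25) {
    l_dead <- runif(1); l_pass <- runif(1, 0, 1 - l_dead)
    ly <- lymph_params(p_lymph = runif(1), p_lymphc = runif(1),
                       l_dead = l_dead, l_pass = l_pass)
    r <- runif(1, 0, 100)
    blood <- r * ((1 - ly$p_lymph) + ly$p_lymph * ly$l_pass)
    died <- r * ly$p_lymph * ly$l_dead
    seeded <- r * ly$p_lymph * ly$l_meta
    expect_equal(blood + died + seeded, r, tolerance = 1e-12)
  }
})

test_that("an absent device, zero efficiency and zero flow are equivalent", {
  base <- circadian_scenario()
  variants <- list(
    none = within_device(base, placement = "none"),
    eff0 = within_device(base, eff_dev = 0, eff_devc = 0),
    flow0 = within_device(base, R_vol = 0))
  st <- c(n = 1234, c = 56, m = 7)
  for (t in c(0, 90, 200, 3000)) {
    outs <- lapply(variants, function(s) ctc_rhs(t, st, 0, s))
    expect_identical(outs$none, outs$eff0)
    expect_identical(outs$none, outs$flow0)
  }
})

test_that("stronger clearance never increases the net inflow of singles", {
  base <- circadian_scenario()
  st <- c(n = 1000, c = 100, m = 0)
  effs <- seq(0, 1, by = 0.1)
  dns <- vapply(effs, function(e) {
    s <- within_device(base, eff_dev = e)
    unname(ctc_rhs(90, st, 0, s)["dn"])
  }, numeric(1))
  expect_true(all(diff(dns) <= 0))
  rvols <- seq(0, 1, by = 0.1)
  dns_r <- vapply(rvols, function(rv) {
    s <- within_device(base, R_vol = rv)
    unname(ctc_rhs(90, st, 0, s)["dn"])
  }, numeric(1))
  expect_true(all(diff(dns_r) <= 0))
})

test_that("surgery spikes multiply the base release only inside the window", {
  rel <- apply_surgery_spike(release_params(25, 0, 30, 0),
                             start = 1440, duration = 60, factor = 100)
  dev <- device_params("none")
  expect_equal(release_rates(1470, 0, rel, dev)$r, 2500)
  expect_equal(release_rates(1510, 0, rel, dev)$r, 25)
  expect_equal(release_rates(1439.5, 0, rel, dev)$r, 25)
  silenced <- apply_surgery_spike(release_params(25, 0, 30, 0),
                                  start = 0, duration = 10, factor = 0)
  expect_equal(release_rates(5, 0, silenced, dev)$r, 0)
  unchanged <- apply_surgery_spike(release_params(25, 0, 30, 0),
                                   start = 0, duration = 10, factor = 1)
  expect_equal(release_rates(5, 0, unchanged, dev)$r, 25)
  expect_error(apply_surgery_spike(rel, 100, 10, 2), "overlapping")
})
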