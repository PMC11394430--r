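# Small scenario builders shared across test files.

# modify single device fields of a scenario in place
within_device <- function(sc, ...) {
  mods <- list(...)
  sc$device[names(mods)] <- mods
  sc
}

# release switched off entirely; n decays exponentially at rate k
decay_scenario <- function(n0 = 1000, k = 0.0046, duration = 720, h = 0.5) {
  scenario(release = release_params(0, 0, 0, 0),
           kinetics = ctc_kinetics(k_dead = k, k_met = 0, k_metc = 0),
           duration = duration, h = h, n0 = n0)
}

# constant release against first-order loss; n plateaus at r / (k_dead + k_met)
plateau_scenario <- function(r = 25, duration = 5 * 1440, h = 0.5) {
  scenario(release = release_params(r, 0, 0, 0),
           kinetics = ctc_kinetics(k_dead = 0.0046, k_met = 1e-8),
           duration = duration, h = h)
}

# circadian release with a 3 h extracorporeal window on the peak
circadian_scenario <- function(duration = 5 * 1440, h = 0.5, ...) {
  scenario(release = suppressWarnings(
             release_params(5, 40, 10, 60, ...)),
           kinetics = ctc_kinetics(k_dead = 0.0046, k_deadc = 0.023),
           device = device_params("extracorporeal", T_dev = 180,
                                  R_vol = 0.1, eff_dev = 0.9,
                                  eff_devc = 0.99),
           duration = duration, h = h)
}

# short horizon with active metastasis feedback and a pre-existing burden,
# exercising the delayed lookup without a 50-day run
feedback_scenario <- function(duration = 2 * 1440, h = 0.5) {
  scenario(release = release_params(25, 0, 30, 0, M = 0.01, delay = 720),
           kinetics = ctc_kinetics(k_dead = 0.0115, k_deadc = 0.069),
           device = device_params("implanted", T_dev = 1440, R_vol = 0.02,
                                  eff_dev = 0.9, eff_devc = 0.99),
           duration = duration, h = h, m0 = 5)
}
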