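# Brute-force explicit-Euler reference integrator, written directly from the
# model definition with no calls into the package's solver or term
# functions.  Deliberately simple and slow: it exists to cross-check the
# compiled midpoint path at a much finer step.
euler_oracle <- function(sc, h) {
  rel <- sc$release; kin <- sc$kinetics; dev <- sc$device; ly <- sc$lymph
  steps <- as.integer(round(sc$duration / h))
  t_peak <- (dev$T_dev / 2 - dev$dT_dev) %% rel$T_day
  implanted <- dev$placement == "implanted"
  active <- dev$placement != "none" && dev$T_dev > 0
  d <- if (rel$M > 0 && rel$delay > 0) as.integer(round(rel$delay / h)) else 0L
  m_hist <- rep(sc$m0, d + steps + 1L)
  n <- sc$n0; c <- sc$c0; m <- sc$m0
  w <- 2 * pi / rel$T_day
  blood_r <- (1 - ly$p_lymph) + ly$p_lymph * ly$l_pass
  blood_p <- (1 - ly$p_lymphc) + ly$p_lymphc * ly$l_passc
  for (k in seq_len(steps)) {
    t <- (k - 1L) * h
    on <- if (!active) FALSE else if (!is.null(dev$window_start))
      t >= dev$window_start && t < dev$window_end
    else (t %% rel$T_day) < dev$T_dev
    ph <- 1 + cos(w * (t - t_peak))
    br <- rel$r_const + rel$r_dyn / 2 * ph
    bp <- rel$p_const + rel$p_dyn / 2 * ph
    if (rel$spike_factor != 1 && t >= rel$spike_start &&
        t < rel$spike_start + rel$spike_duration) {
      br <- br * rel$spike_factor
      bp <- bp * rel$spike_factor
    }
    md <- if (d == 0L) m else m_hist[k]
    fb <- rel$M * md
    if (implanted) {
      r <- br * ((1 - dev$eff_dev * on) + fb)
      p <- bp * ((1 - dev$eff_devc * on) + fb)
    } else {
      r <- br * (1 + fb)
      p <- bp * (1 + fb)
    }
    dn <- r * blood_r - n * (kin$k_met + kin$k_dead) +
      c * kin$k_deadc * kin$N_c
    dc <- p * blood_p - c * (kin$k_metc + kin$k_deadc)
    dm <- kin$k_met * n + kin$k_metc * c +
      r * ly$p_lymph * ly$l_meta + p * ly$p_lymphc * ly$l_metac
    if (on) {
      dn <- dn + dev$R_vol * (-n * dev$eff_dev +
                                c * dev$eff_devc * dev$N_cdev)
      dc <- dc - dev$R_vol * c * dev$eff_devc
    }
    n <- max(n + h * dn, 0)
    c <- max(c + h * dc, 0)
    m <- max(m + h * dm, 0)
    m_hist[d + k + 1L] <- m
  }
  list(n = n, c = c, m = m)
}

# percent burden reduction computed entirely through the oracle
oracle_reduction <- function(sc, h) {
  ctl <- sc
  ctl$device$placement <- "none"
  m_dev <- euler_oracle(sc, h)$m
  m_ctl <- euler_oracle(ctl, h)$m
  100 * (m_ctl - m_dev) / m_ctl
}
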