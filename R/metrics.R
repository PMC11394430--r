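#' Convert a circulation half-life to a first-order rate
#'
#' `k = ln(2) / t_half` for exponential elimination.  A measured CTC
#' half-life of 150 min gives `k_dead` of about 0.0046 min^-1; a cluster
#' half-life of 30 min gives about 0.023 min^-1.
#'
#' @param half_life half-life in minutes (> 0, vectorized).
#' @return rate in min^-1.
#' @examples
#' halflife_to_rate(c(150, 30))
#' @export
halflife_to_rate <- function(half_life) {
  stop_unless(is.numeric(half_life) && all(is.finite(half_life)) &&
                all(half_life > 0),
              "half_life must be finite and > 0")
  log(2) / half_life
}

#' Baseline release implied by an observed CTC concentration
#'
#' At equilibrium between constant release and first-order death,
#' `r_const = [CTC] * V_tot * k_dead`: the measured steady concentration
#' times the blood volume gives the circulating count, and multiplying by
#' the turnover rate gives the release needed to sustain it.
#'
#' @param ctc_conc observed CTC concentration in cells per mL.
#' @param V_tot total blood volume in mL.
#' @param k_dead single-CTC death rate in min^-1.
#' @return release rate in min^-1.
#' @examples
#' equilibrium_release(1.087, 5000, 0.0046)  # about 25 CTCs per minute
#' @export
equilibrium_release <- function(ctc_conc, V_tot = 5000, k_dead = 0.0046) {
  for (v in list(ctc_conc, V_tot, k_dead))
    stop_unless(is.numeric(v) && all(is.finite(v)) && all(v >= 0),
                "all arguments must be finite and non-negative")
  ctc_conc * V_tot * k_dead
}

# The untreated control: identical scenario with the device absent.  Only
# the placement changes: the window fields stay, so the circadian peak
# (anchored to the device window) is the same in both runs.
.control_scenario <- function(sc) {
  sc$device$placement <- "none"
  sc$scenario_id <- if (is.null(sc$scenario_id)) "control"
                    else paste0(sc$scenario_id, "_control")
  sc
}

#' Simulate a scenario against its untreated control
#'
#' Integrates the scenario twice on the same grid -- once as configured and
#' once with the device removed -- and reports the percent reduction in
#' final metastatic burden, `100 * (m_control - m_device) / m_control`.
#' Only this ratio (and crossing times) is meaningful: the burden itself is
#' in arbitrary units because the metastasis-formation rates are known only
#' up to a common factor.
#'
#' @param scenario a [scenario()] object.
#' @param h integration step in minutes; defaults to the scenario's.
#' @return an object of class `"ctc_result"`: a list with `scenario_id`,
#'   final burdens `m_device` and `m_control` (au), `reduction_pct`, and the
#'   two `"ctc_trajectory"` records in `trajectories`.
#' @examples
#' res <- run_with_control(scenario_registry()[["fig2"]])
#' res$reduction_pct
#' @export
run_with_control <- function(scenario, h = scenario$h) {
  stop_unless(inherits(scenario, "ctc_scenario"),
              "scenario must be a ctc_scenario object")
  tr_dev <- integrate_scenario(scenario, h = h)
  tr_ctl <- integrate_scenario(.control_scenario(scenario), h = h)
  k <- length(tr_dev$times)
  m_dev <- tr_dev$m[k]
  m_ctl <- tr_ctl$m[k]
  reduction <- if (m_ctl > 0) 100 * (m_ctl - m_dev) / m_ctl else 0
  structure(list(scenario_id = scenario$scenario_id,
                 m_device = m_dev, m_control = m_ctl,
                 reduction_pct = reduction,
                 trajectories = list(device = tr_dev, control = tr_ctl)),
            class = "ctc_result")
}

#' @export
print.ctc_result <- function(x, ...) {
  cat(sprintf("Scenario%s: burden %.6g au with device vs %.6g au control\n",
              if (!is.null(x$scenario_id)) paste0(" '", x$scenario_id, "'")
              else "", x$m_device, x$m_control))
  cat(sprintf("  reduction in metastatic burden: %.1f%%\n", x$reduction_pct))
  invisible(x)
}

#' Days-to-equal-burden delay of a device
#'
#' Long-horizon metric for scenarios with metastasis feedback (`M > 0`),
#' where the burden eventually grows regardless of the device and the
#' device's benefit is best expressed as time gained.  Both the device run
#' and its untreated control are integrated to `reference_horizon`; the
#' metric asks how much longer the device trajectory needs to accumulate
#' the burden it shows at the horizon than the control did: with the device
#' it takes the full horizon to reach `m_device(horizon)`, the control
#' already reached that burden at some earlier time `t*`, and the delay is
#' `(horizon - t*)` in days, with `t*` linearly interpolated between grid
#' points.  Identical device and control trajectories give a delay of zero;
#' an effective device gives a positive delay.
#'
#' @param scenario a [scenario()] object with `M > 0` (or otherwise
#'   monotonically growing burden).
#' @param reference_horizon horizon in minutes; defaults to the scenario
#'   duration.
#' @param h integration step in minutes; defaults to the scenario's.
#' @return an object of class `"ctc_burden_delay"`: a list with
#'   `reference_horizon` (minutes), `delay_days`, the reference burden
#'   `m_reference` (the device trajectory at the horizon, au), the control
#'   crossing time `crossing_min`, and both trajectories.  `delay_days` is
#'   `NA` with a warning if the control never reaches the device's final
#'   burden (a device that increases the burden).
#' @examples
#' \donttest{
#' reg <- scenario_registry()
#' days_to_equal_burden(reg[["fig7b"]])
#' }
#' @export
days_to_equal_burden <- function(scenario,
                                 reference_horizon = scenario$duration,
                                 h = scenario$h) {
  stop_unless(inherits(scenario, "ctc_scenario"),
              "scenario must be a ctc_scenario object")
  stop_unless(is_pos_scalar(reference_horizon),
              "reference_horizon must be a single value > 0")
  scenario$duration <- reference_horizon
  tr_dev <- integrate_scenario(scenario, h = h)
  tr_ctl <- integrate_scenario(.control_scenario(scenario), h = h)
  k <- length(tr_dev$times)
  m_ref <- tr_dev$m[k]
  idx <- which(tr_ctl$m >= m_ref)
  if (length(idx) == 0) {
    warning("the control never reaches the device trajectory's final ",
            "burden; the device does not delay the burden", call. = FALSE)
    t_cross <- NA_real_
    delay <- NA_real_
  } else {
    i <- idx[1]
    if (i == 1) {
      t_cross <- tr_ctl$times[1]
    } else {
      # linear interpolation between the bracketing grid points
      frac <- (m_ref - tr_ctl$m[i - 1]) / (tr_ctl$m[i] - tr_ctl$m[i - 1])
      t_cross <- tr_ctl$times[i - 1] + frac * tr_ctl$h
    }
    delay <- (reference_horizon - t_cross) / 1440
  }
  structure(list(scenario_id = scenario$scenario_id,
                 reference_horizon = reference_horizon,
                 delay_days = delay, m_reference = m_ref,
                 crossing_min = t_cross,
                 trajectories = list(device = tr_dev, control = tr_ctl)),
            class = "ctc_burden_delay")
}

#' @export
print.ctc_burden_delay <- function(x, ...) {
  cat(sprintf("Days-to-equal-burden%s over a %.0f-day horizon:\n",
              if (!is.null(x$scenario_id)) paste0(" '", x$scenario_id, "'")
              else "", x$reference_horizon / 1440))
  if (is.na(x$delay_days))
    cat("  no crossing: the device does not delay the burden\n")
  else
    cat(sprintf("  the device delays the burden %.6g au by %.0f days\n",
                x$m_reference, x$delay_days))
  invisible(x)
}
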