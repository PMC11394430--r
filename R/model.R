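#' Circadian release peak time
#'
#' The daily device window is `[0, T_dev)` in simulation time, so the
#' circadian release maximum is placed at `T_dev/2 - dT_dev` (modulo the day
#' length): with `dT_dev = 0` the window is centered on the release peak,
#' and a positive `dT_dev` makes the window lag the peak by that many
#' minutes.  All phase logic is concentrated here so the convention can be
#' swapped in one place.
#'
#' @param device a [device_params()] object.
#' @param T_day day length in minutes.
#' @return peak time in minutes within `[0, T_day)`.
#' @export
release_peak_time <- function(device, T_day = 1440) {
  (device$T_dev / 2 - device$dT_dev) %% T_day
}

#' Daily device activity indicator
#'
#' The device is active while `t mod T_day < T_dev`; a device with
#' `placement = "none"` or `T_dev = 0` is never active, and `T_dev = T_day`
#' means permanent operation.  If the device defines a one-off absolute
#' window it overrides the daily schedule.
#'
#' @param t time in minutes (vectorized); negative times are rejected.
#' @param device a [device_params()] object.
#' @param T_day day length in minutes.
#' @return logical vector, `TRUE` where the device is active.
#' @examples
#' dev <- device_params("extracorporeal", T_dev = 180, R_vol = 0.1)
#' device_on(c(90, 200, 1530), dev)
#' @export
device_on <- function(t, device, T_day = 1440) {
  stop_unless(is.numeric(t) && all(is.finite(t)), "t must be finite numeric")
  stop_unless(all(t >= 0), "t must be non-negative")
  if (device$placement == "none" || device$T_dev <= 0)
    return(rep(FALSE, length(t)))
  if (!is.null(device$window_start))
    return(t >= device$window_start & t < device$window_end)
  (t %% T_day) < device$T_dev
}

#' Instantaneous release rates of single CTCs and clusters
#'
#' Evaluates the release law: a raised cosine over the day with its maximum
#' at [release_peak_time()], multiplied by the surgery spike factor inside
#' the spike window, and scaled by the metastasis feedback term
#' `M * m(t - delay)`.  For an implanted device the primary-tumor release
#' must pass the device and is attenuated by `1 - eff` while the device is
#' active; the metastasis-derived contribution bypasses the implanted device
#' (secondary lesions do not drain through the tumor vessel).
#'
#' @param t time in minutes (vectorized); negative times are rejected.
#' @param m_delayed delayed metastatic burden `m(t - delay)` in arbitrary
#'   units.
#' @param release a [release_params()] object.
#' @param device a [device_params()] object.
#' @param on logical, whether the device is active at `t`; defaults to
#'   `device_on(t, device, release$T_day)`.
#' @return list with numeric components `r` (singles, min^-1) and `p`
#'   (clusters, min^-1), both non-negative.
#' @examples
#' rel <- release_params(r_const = 5, r_dyn = 40, p_const = 10, p_dyn = 60)
#' dev <- device_params("extracorporeal", T_dev = 180, R_vol = 0.1)
#' release_rates(release_peak_time(dev), 0, rel, dev)  # r at the peak
#' @export
release_rates <- function(t, m_delayed, release, device,
                          on = device_on(t, device, release$T_day)) {
  stop_unless(is.numeric(t) && all(is.finite(t)), "t must be finite numeric")
  stop_unless(all(t >= 0), "t must be non-negative")
  stop_unless(is.numeric(m_delayed) && all(is.finite(m_delayed)) &&
                all(m_delayed >= 0),
              "m_delayed must be finite and non-negative")
  t_peak <- release_peak_time(device, release$T_day)
  phase <- 1 + cos(2 * pi * (t - t_peak) / release$T_day)
  base_r <- release$r_const + release$r_dyn / 2 * phase
  base_p <- release$p_const + release$p_dyn / 2 * phase
  if (release$spike_factor != 1) {
    in_spike <- t >= release$spike_start &
      t < release$spike_start + release$spike_duration
    base_r <- ifelse(in_spike, base_r * release$spike_factor, base_r)
    base_p <- ifelse(in_spike, base_p * release$spike_factor, base_p)
  }
  fb <- release$M * m_delayed
  if (device$placement == "implanted") {
    r <- base_r * ((1 - device$eff_dev * as.numeric(on)) + fb)
    p <- base_p * ((1 - device$eff_devc * as.numeric(on)) + fb)
  } else {
    r <- base_r * (1 + fb)
    p <- base_p * (1 + fb)
  }
  list(r = r, p = p)
}

#' Intrinsic dynamics of circulating events
#'
#' Loss of singles to natural death and metastasis formation, loss of
#' clusters to shear disruption and metastasis formation, and the gain of
#' singles from physiologically disrupted clusters (`N_c` survivors per
#' cluster).
#'
#' @param n,c current single-CTC and cluster counts (>= 0, vectorized).
#' @param kinetics a [ctc_kinetics()] object.
#' @return list with components `f_dyn` (dn/dt contribution) and `g_dyn`
#'   (dc/dt contribution, always <= 0).
#' @examples
#' intrinsic_dynamics(1000, 0, ctc_kinetics())
#' @export
intrinsic_dynamics <- function(n, c, kinetics) {
  stop_unless(is.numeric(n) && all(is.finite(n)) && all(n >= 0),
              "n must be finite and non-negative")
  stop_unless(is.numeric(c) && all(is.finite(c)) && all(c >= 0),
              "c must be finite and non-negative")
  list(f_dyn = -n * (kinetics$k_met + kinetics$k_dead) +
         c * kinetics$k_deadc * kinetics$N_c,
       g_dyn = -c * (kinetics$k_metc + kinetics$k_deadc))
}

#' Device clearance terms
#'
#' While active, the device removes a fraction `R_vol * eff_dev` of singles
#' and `R_vol * eff_devc` of clusters per minute from the compartment, and
#' each destroyed cluster releases `N_cdev` surviving singles back into
#' circulation.  The clearance acts on circulating blood for both
#' placements; the implanted device additionally attenuates the primary
#' release (handled in [release_rates()]).
#'
#' @param n,c current single-CTC and cluster counts (>= 0, vectorized).
#' @param device a [device_params()] object.
#' @param on logical, whether the device is active.
#' @return list with components `f_dev` and `g_dev`; both are zero when the
#'   device is off, and `g_dev <= 0` always.
#' @examples
#' dev <- device_params("extracorporeal", R_vol = 0.1, eff_dev = 0.9,
#'                      eff_devc = 0.99, T_dev = 180)
#' device_clearance(1000, 0, dev, on = TRUE)
#' @export
device_clearance <- function(n, c, device, on) {
  stop_unless(is.numeric(n) && all(is.finite(n)) && all(n >= 0),
              "n must be finite and non-negative")
  stop_unless(is.numeric(c) && all(is.finite(c)) && all(c >= 0),
              "c must be finite and non-negative")
  on_num <- as.numeric(on)
  list(f_dev = on_num * device$R_vol *
         (-n * device$eff_dev + c * device$eff_devc * device$N_cdev),
       g_dev = -on_num * device$R_vol * c * device$eff_devc)
}

#' Metastasis formation rate
#'
#' The burden grows by extravasation of circulating singles and clusters
#' (`k_met * n + k_metc * c`) plus lymphatic seeding by the fraction of the
#' release routed through the lymphatic system.  All terms are non-negative,
#' so the burden is non-decreasing along any trajectory.
#'
#' @param n,c current single-CTC and cluster counts (>= 0).
#' @param r,p instantaneous release rates of singles and clusters (min^-1).
#' @param kinetics a [ctc_kinetics()] object.
#' @param lymph a [lymph_params()] object.
#' @return dm/dt in arbitrary units per minute (>= 0).
#' @examples
#' metastasis_inflow(1e6, 1e4, 0, 0, ctc_kinetics(), lymph_params())
#' @export
metastasis_inflow <- function(n, c, r, p, kinetics, lymph) {
  for (v in list(n, c, r, p))
    stop_unless(is.numeric(v) && all(is.finite(v)) && all(v >= 0),
                "n, c, r and p must be finite and non-negative")
  kinetics$k_met * n + kinetics$k_metc * c +
    r * lymph$p_lymph * lymph$l_meta +
    p * lymph$p_lymphc * lymph$l_metac
}

#' Right-hand side of the CTC system
#'
#' Composes the release, intrinsic-dynamics, device-clearance and
#' metastasis-formation terms into the derivative of the state
#' `(n, c, m)`.  Of each released single CTC, a fraction
#' `(1 - p_lymph) + p_lymph * l_pass` reaches the blood compartment
#' (directly or after transiting the lymphatic system), `p_lymph * l_dead`
#' dies in the lymphatic system, and `p_lymph * l_meta` seeds a lymphatic
#' metastasis; clusters are routed analogously.
#'
#' @param t time in minutes.
#' @param state numeric vector `c(n, c, m)` (all >= 0).
#' @param m_delayed delayed burden `m(t - delay)` in arbitrary units.
#' @param scenario a [scenario()] object.
#' @return named numeric vector `c(dn, dc, dm)`.
#' @examples
#' sc <- scenario(duration = 1440)
#' ctc_rhs(0, c(n = 0, c = 0, m = 0), 0, sc)
#' @export
ctc_rhs <- function(t, state, m_delayed, scenario) {
  stop_unless(inherits(scenario, "ctc_scenario"),
              "scenario must be a ctc_scenario object")
  stop_unless(is.numeric(state) && length(state) == 3 &&
                all(is.finite(state)) && all(state >= 0),
              "state must be three finite non-negative values (n, c, m)")
  n <- state[[1]]; c <- state[[2]]
  on <- device_on(t, scenario$device, scenario$release$T_day)
  rel <- release_rates(t, m_delayed, scenario$release, scenario$device, on)
  dyn <- intrinsic_dynamics(n, c, scenario$kinetics)
  dev <- device_clearance(n, c, scenario$device, on)
  ly <- scenario$lymph
  c(dn = rel$r * ((1 - ly$p_lymph) + ly$p_lymph * ly$l_pass) +
      dyn$f_dyn + dev$f_dev,
    dc = rel$p * ((1 - ly$p_lymphc) + ly$p_lymphc * ly$l_passc) +
      dyn$g_dyn + dev$g_dev,
    dm = metastasis_inflow(n, c, rel$r, rel$p, scenario$kinetics, ly))
}
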