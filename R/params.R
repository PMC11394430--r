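#' Primary-tumor release parameters
#'
#' The release of single CTCs and CTC clusters from the primary tumor is a
#' raised cosine with period `T_day`: the single-CTC release oscillates
#' between `r_const` (trough) and `r_const + r_dyn` (peak), and analogously
#' for clusters with `p_const`/`p_dyn`.  Established metastases add a
#' delayed, burden-proportional contribution `M * m(t - delay)` that
#' multiplies the circadian base rate.  An optional one-off spike (e.g. the
#' transient shedding burst after tumor-removal surgery) multiplies the base
#' rates by `spike_factor` on `[spike_start, spike_start + spike_duration)`.
#'
#' All rates are per minute; all times are minutes.
#'
#' @param r_const baseline single-CTC release rate (min^-1).
#' @param r_dyn peak-to-peak circadian amplitude of single-CTC release
#'   (min^-1).
#' @param p_const baseline cluster release rate (min^-1).
#' @param p_dyn peak-to-peak circadian amplitude of cluster release (min^-1).
#' @param T_day day length in minutes.
#' @param M dimensionless weight of metastasis-derived release per arbitrary
#'   unit of metastatic burden; `M = 0` disables the feedback loop.
#' @param delay minutes before a newly formed metastasis starts emitting
#'   CTCs (includes dormancy).
#' @param spike_start,spike_duration,spike_factor optional multiplicative
#'   release spike window (minutes, minutes, dimensionless).  The default
#'   `spike_factor = 1` leaves the release law untouched.
#' @return an object of class `"release_params"`.
#' @seealso [release_rates()], [apply_surgery_spike()]
#' @examples
#' release_params(r_const = 5, r_dyn = 40, p_const = 10, p_dyn = 60)
#' @export
release_params <- function(r_const = 25, r_dyn = 0, p_const = 30, p_dyn = 0,
                           T_day = 1440, M = 0, delay = 0,
                           spike_start = 0, spike_duration = 0,
                           spike_factor = 1) {
  stop_unless(is_nonneg_scalar(r_const), "r_const must be a single value >= 0")
  stop_unless(is_nonneg_scalar(r_dyn), "r_dyn must be a single value >= 0")
  stop_unless(is_nonneg_scalar(p_const), "p_const must be a single value >= 0")
  stop_unless(is_nonneg_scalar(p_dyn), "p_dyn must be a single value >= 0")
  stop_unless(is_pos_scalar(T_day), "T_day must be a single value > 0")
  stop_unless(is_nonneg_scalar(M), "M must be a single value >= 0")
  stop_unless(is_nonneg_scalar(delay), "delay must be a single value >= 0")
  stop_unless(is_nonneg_scalar(spike_start), "spike_start must be >= 0")
  stop_unless(is_nonneg_scalar(spike_duration), "spike_duration must be >= 0")
  stop_unless(is_nonneg_scalar(spike_factor), "spike_factor must be >= 0")
  if (r_dyn > r_const || p_dyn > p_const)
    warning("circadian amplitude exceeds the baseline rate; the 1 + cos ",
            "form keeps the release non-negative, but the trough equals ",
            "the baseline rather than baseline - amplitude", call. = FALSE)
  structure(list(r_const = r_const, r_dyn = r_dyn, p_const = p_const,
                 p_dyn = p_dyn, T_day = T_day, M = M, delay = delay,
                 spike_start = spike_start, spike_duration = spike_duration,
                 spike_factor = spike_factor),
            class = "release_params")
}

#' Intrinsic CTC kinetics
#'
#' First-order rate constants for the fate of circulating events: natural
#' death of singles (`k_dead`) and physiological disruption of clusters
#' (`k_deadc`, dominated by hemodynamic shear), and metastasis formation by
#' singles (`k_met`) and clusters (`k_metc`).  A physiologically disrupted
#' cluster releases on average `N_c` surviving single CTCs, so cluster decay
#' can be a source of singles.
#'
#' The default `k_metc = 50 * k_met` encodes the roughly fifty-fold higher
#' metastatic potential of clusters.  Because the burden equation is a dead
#' end in the system, rescaling `k_met` and `k_metc` by a common factor only
#' rescales the burden; ratio metrics are unaffected.
#'
#' @param k_dead single-CTC death rate (min^-1); `halflife_to_rate()`
#'   converts a circulation half-life.
#' @param k_deadc cluster death/disruption rate (min^-1).
#' @param k_met single-CTC metastasis-formation rate (min^-1).
#' @param k_metc cluster metastasis-formation rate (min^-1).
#' @param N_c mean surviving single CTCs released per physiologically
#'   disrupted cluster (dimensionless, >= 0).
#' @return an object of class `"ctc_kinetics"`.
#' @examples
#' ctc_kinetics(k_dead = halflife_to_rate(150), k_deadc = halflife_to_rate(30))
#' @export
ctc_kinetics <- function(k_dead = 0.0046, k_deadc = 0.023,
                         k_met = 1e-8, k_metc = 50 * k_met, N_c = 0) {
  for (nm in c("k_dead", "k_deadc", "k_met", "k_metc", "N_c"))
    stop_unless(is_nonneg_scalar(get(nm)),
                sprintf("%s must be a single value >= 0", nm))
  structure(list(k_dead = k_dead, k_deadc = k_deadc, k_met = k_met,
                 k_metc = k_metc, N_c = N_c),
            class = "ctc_kinetics")
}

#' Blood-clearing device parameters
#'
#' Describes either an extracorporeal device (a dialysis-like machine acting
#' on a peripheral side stream of circulating blood) or a device implanted in
#' the tumor-draining vessel (which additionally intercepts the primary
#' release before it reaches the compartment).  The device is active for
#' `T_dev` minutes per day starting at midnight of simulation time; `dT_dev`
#' shifts the circadian release peak relative to the window (see
#' [release_rates()]).  A one-off absolute window (`window_start`,
#' `window_end`) overrides the daily schedule, which is how a
#' "12 h after surgery" device is expressed.
#'
#' @param placement one of `"none"`, `"extracorporeal"`, `"implanted"`.
#' @param T_dev daily active duration in minutes, between 0 and the day
#'   length.
#' @param dT_dev offset in minutes between device activation and the
#'   circadian release maximum; 0 centers the daily window on the peak.
#' @param R_vol fraction of the heart minute volume passing the device per
#'   minute (0-1).  0.1 corresponds to a 500 mL/min arteriovenous shunt at a
#'   5 L/min cardiac output.
#' @param eff_dev per-pass kill ratio for single CTCs (0-1).
#' @param eff_devc per-pass destruction ratio for clusters (0-1).
#' @param N_cdev mean surviving single CTCs released per device-destroyed
#'   cluster (>= 0).
#' @param window_start,window_end optional one-off absolute active window in
#'   minutes; `NULL` for the daily schedule.
#' @return an object of class `"device_params"`.
#' @examples
#' device_params("extracorporeal", T_dev = 180, R_vol = 0.1)
#' device_params("implanted", T_dev = 1440, R_vol = 0.02)
#' @export
device_params <- function(placement = c("none", "extracorporeal", "implanted"),
                          T_dev = 0, dT_dev = 0, R_vol = 0,
                          eff_dev = 0, eff_devc = 0, N_cdev = 0,
                          window_start = NULL, window_end = NULL) {
  placement <- match.arg(placement)
  stop_unless(is_nonneg_scalar(T_dev), "T_dev must be a single value >= 0")
  stop_unless(is.numeric(dT_dev) && length(dT_dev) == 1 && is.finite(dT_dev),
              "dT_dev must be a single finite value")
  stop_unless(is_fraction(R_vol), "R_vol must be in [0,1]")
  stop_unless(is_fraction(eff_dev), "eff_dev must be in [0,1]")
  stop_unless(is_fraction(eff_devc), "eff_devc must be in [0,1]")
  stop_unless(is_nonneg_scalar(N_cdev), "N_cdev must be a single value >= 0")
  if (is.null(window_start) != is.null(window_end))
    stop("window_start and window_end must be given together")
  if (!is.null(window_start)) {
    stop_unless(is_nonneg_scalar(window_start), "window_start must be >= 0")
    stop_unless(is_pos_scalar(window_end - window_start),
                "window_end must exceed window_start")
  }
  structure(list(placement = placement, T_dev = T_dev, dT_dev = dT_dev,
                 R_vol = R_vol, eff_dev = eff_dev, eff_devc = eff_devc,
                 N_cdev = N_cdev,
                 window_start = window_start, window_end = window_end),
            class = "device_params")
}

#' Lymphatic bypass parameters
#'
#' A fraction `p_lymph` of released single CTCs (and `p_lymphc` of clusters)
#' enters the lymphatic system instead of the blood compartment, out of reach
#' of any clearing device.  There each cell is destroyed with probability
#' `l_dead`, returns to blood with probability `l_pass`, or seeds a lymphatic
#' metastasis with the complementary probability
#' `l_meta = 1 - (l_pass + l_dead)` (and analogously for clusters).  The
#' three outcomes are exhaustive and exclusive, so the probabilities sum to
#' one exactly; parameter sets for which `l_pass + l_dead > 1` are rejected.
#'
#' @param p_lymph,p_lymphc fraction of released singles/clusters entering the
#'   lymphatic system (0-1).
#' @param l_dead,l_deadc probability of destruction in the lymphatic system.
#' @param l_pass,l_passc probability of returning to the blood compartment.
#' @return an object of class `"lymph_params"` with derived fields `l_meta`
#'   and `l_metac`.
#' @examples
#' lymph_params(p_lymph = 0.3, p_lymphc = 0.3,
#'              l_dead = 0.99, l_deadc = 0.9999,
#'              l_pass = 0.0095, l_passc = 0)
#' @export
lymph_params <- function(p_lymph = 0, p_lymphc = 0,
                         l_dead = 0.99, l_deadc = 0.9999,
                         l_pass = 0.0095, l_passc = 0) {
  for (nm in c("p_lymph", "p_lymphc", "l_dead", "l_deadc", "l_pass", "l_passc"))
    stop_unless(is_fraction(get(nm)), sprintf("%s must be in [0,1]", nm))
  l_meta <- 1 - (l_pass + l_dead)
  l_metac <- 1 - (l_passc + l_deadc)
  if (l_meta < 0 || l_metac < 0)
    stop("destruction and return probabilities exceed 1; no probability ",
         "mass is left for lymphatic metastasis formation", call. = FALSE)
  structure(list(p_lymph = p_lymph, p_lymphc = p_lymphc,
                 l_dead = l_dead, l_deadc = l_deadc,
                 l_pass = l_pass, l_passc = l_passc,
                 l_meta = l_meta, l_metac = l_metac),
            class = "lymph_params")
}

#' Assemble a simulation scenario
#'
#' Bundles the release law, intrinsic kinetics, device, lymphatic bypass,
#' initial conditions and integration settings into a single validated
#' object that [integrate_scenario()] and the metric functions consume.
#'
#' @param release a [release_params()] object.
#' @param kinetics a [ctc_kinetics()] object.
#' @param device a [device_params()] object.
#' @param lymph a [lymph_params()] object.
#' @param duration total simulated time in minutes.
#' @param h requested integration step in minutes; it is adjusted downward if
#'   needed so that the day length, the metastasis delay and all device
#'   switch times fall on the grid (see [integrate_scenario()]).
#' @param n0,c0,m0 initial single-CTC count, cluster count and metastatic
#'   burden (burden in arbitrary units).  The delayed burden history is
#'   constant at `m0` for times before the start.
#' @param V_tot total blood volume in mL; used only by estimation helpers
#'   such as [equilibrium_release()].
#' @param scenario_id optional label carried through to results and reports.
#' @return an object of class `"ctc_scenario"`.
#' @examples
#' sc <- scenario(release_params(25, 0, 30, 0),
#'                ctc_kinetics(),
#'                device_params("extracorporeal", T_dev = 180, R_vol = 0.1,
#'                              eff_dev = 0.9, eff_devc = 0.99),
#'                duration = 5 * 1440)
#' sc
#' @export
scenario <- function(release = release_params(),
                     kinetics = ctc_kinetics(),
                     device = device_params(),
                     lymph = lymph_params(),
                     duration = 5 * 1440, h = 0.5,
                     n0 = 0, c0 = 0, m0 = 0,
                     V_tot = 5000, scenario_id = NULL) {
  stop_unless(inherits(release, "release_params"),
              "release must be a release_params object")
  stop_unless(inherits(kinetics, "ctc_kinetics"),
              "kinetics must be a ctc_kinetics object")
  stop_unless(inherits(device, "device_params"),
              "device must be a device_params object")
  stop_unless(inherits(lymph, "lymph_params"),
              "lymph must be a lymph_params object")
  stop_unless(is_pos_scalar(duration), "duration must be a single value > 0")
  stop_unless(is_pos_scalar(h), "h must be a single value > 0")
  stop_unless(h <= duration, "h must not exceed duration")
  for (nm in c("n0", "c0", "m0"))
    stop_unless(is_nonneg_scalar(get(nm)),
                sprintf("%s must be a single value >= 0", nm))
  stop_unless(is_pos_scalar(V_tot), "V_tot must be a single value > 0")
  if (device$T_dev > release$T_day)
    stop("T_dev must not exceed the day length T_day", call. = FALSE)
  structure(list(release = release, kinetics = kinetics, device = device,
                 lymph = lymph, duration = duration, h = h,
                 n0 = n0, c0 = c0, m0 = m0, V_tot = V_tot,
                 scenario_id = scenario_id),
            class = "ctc_scenario")
}

#' @export
print.ctc_scenario <- function(x, ...) {
  cat("CTC simulation scenario",
      if (!is.null(x$scenario_id)) paste0("'", x$scenario_id, "'"), "\n")
  cat(sprintf("  release : r = %g + %g/2*(1+cos), p = %g + %g/2*(1+cos) min^-1",
              x$release$r_const, x$release$r_dyn,
              x$release$p_const, x$release$p_dyn), "\n")
  if (x$release$M > 0)
    cat(sprintf("  feedback: M = %g, delay = %g d\n",
                x$release$M, x$release$delay / 1440))
  if (x$release$spike_factor != 1)
    cat(sprintf("  spike   : x%g on [%g, %g) min\n", x$release$spike_factor,
                x$release$spike_start,
                x$release$spike_start + x$release$spike_duration))
  cat(sprintf("  kinetics: k_dead = %g, k_deadc = %g, N_c = %g\n",
              x$kinetics$k_dead, x$kinetics$k_deadc, x$kinetics$N_c))
  cat(sprintf("  device  : %s", x$device$placement))
  if (x$device$placement != "none")
    cat(sprintf(", T_dev = %g h, R_vol = %g, eff = %g/%g",
                x$device$T_dev / 60, x$device$R_vol,
                x$device$eff_dev, x$device$eff_devc))
  cat("\n")
  if (x$lymph$p_lymph > 0 || x$lymph$p_lymphc > 0)
    cat(sprintf("  lymph   : p_lymph = %g, p_lymphc = %g\n",
                x$lymph$p_lymph, x$lymph$p_lymphc))
  cat(sprintf("  run     : %g days at h = %g min, y0 = (%g, %g, %g)\n",
              x$duration / 1440, x$h, x$n0, x$c0, x$m0))
  invisible(x)
}

# --- internal validation helpers -------------------------------------------

stop_unless <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

is_nonneg_scalar <- function(x)
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0

is_pos_scalar <- function(x)
  is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0

is_fraction <- function(x)
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x <= 1
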