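# Configuration files are flat YAML key-value sets, one scenario per file.
# Times cross the boundary in the units practitioners use (hours for device
# windows, days for durations and delays); everything is minutes internally.

.config_keys <- c(
  "scenario_id", "placement",
  "r_const", "r_dyn", "p_const", "p_dyn", "M", "delay_days",
  "spike_start_h", "spike_duration_h", "spike_factor",
  "k_dead", "k_deadc", "k_met", "k_metc", "N_c", "N_cdev",
  "T_dev_h", "dT_dev_h", "R_vol", "eff_dev", "eff_devc",
  "window_start_h", "window_end_h",
  "p_lymph", "p_lymphc", "l_dead", "l_deadc", "l_pass", "l_passc",
  "duration_days", "h_min", "n0", "c0", "m0", "V_tot")

#' Read a scenario configuration file
#'
#' Parses a flat YAML key-value file into a validated [scenario()].  Keys
#' mirror the parameter symbols; device windows are given in hours
#' (`T_dev_h`, `dT_dev_h`, `window_start_h`, `window_end_h`), durations and
#' the metastasis delay in days (`duration_days`, `delay_days`), the step in
#' minutes (`h_min`).  Unknown keys are rejected, and every value passes the
#' same validation as the constructors.
#'
#' @param path path to a YAML configuration file.
#' @return a `"ctc_scenario"` object.
#' @seealso [write_scenario_config()] for the inverse.
#' @examples
#' path <- tempfile(fileext = ".yaml")
#' write_scenario_config(scenario_registry()[["fig2"]], path)
#' read_scenario_config(path)
#' @export
read_scenario_config <- function(path) {
  stop_unless(file.exists(path), sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg) || !is.list(cfg)) stop("config is empty or not a mapping",
                                          call. = FALSE)
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  g <- function(key, default) if (!is.null(cfg[[key]])) cfg[[key]] else default

  release <- release_params(
    r_const = g("r_const", 25), r_dyn = g("r_dyn", 0),
    p_const = g("p_const", 30), p_dyn = g("p_dyn", 0),
    M = g("M", 0), delay = g("delay_days", 0) * 1440,
    spike_start = g("spike_start_h", 0) * 60,
    spike_duration = g("spike_duration_h", 0) * 60,
    spike_factor = g("spike_factor", 1))
  k_met <- g("k_met", 1e-8)
  kinetics <- ctc_kinetics(
    k_dead = g("k_dead", 0.0046), k_deadc = g("k_deadc", 0.023),
    k_met = k_met, k_metc = g("k_metc", 50 * k_met), N_c = g("N_c", 0))
  device <- device_params(
    placement = g("placement", "none"),
    T_dev = g("T_dev_h", 0) * 60, dT_dev = g("dT_dev_h", 0) * 60,
    R_vol = g("R_vol", 0),
    eff_dev = g("eff_dev", 0), eff_devc = g("eff_devc", 0),
    N_cdev = g("N_cdev", 0),
    window_start = if (!is.null(cfg$window_start_h)) cfg$window_start_h * 60,
    window_end = if (!is.null(cfg$window_end_h)) cfg$window_end_h * 60)
  lymph <- lymph_params(
    p_lymph = g("p_lymph", 0), p_lymphc = g("p_lymphc", 0),
    l_dead = g("l_dead", 0.99), l_deadc = g("l_deadc", 0.9999),
    l_pass = g("l_pass", 0.0095), l_passc = g("l_passc", 0))
  scenario(release = release, kinetics = kinetics, device = device,
           lymph = lymph,
           duration = g("duration_days", 5) * 1440, h = g("h_min", 0.5),
           n0 = g("n0", 0), c0 = g("c0", 0), m0 = g("m0", 0),
           V_tot = g("V_tot", 5000),
           scenario_id = g("scenario_id", NULL))
}

#' Write a scenario configuration file
#'
#' Serializes a scenario to the flat YAML schema of
#' [read_scenario_config()]; reading the file back yields an identical
#' resolved parameter set.
#'
#' @param scenario a `"ctc_scenario"` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(scenario, path) {
  stop_unless(inherits(scenario, "ctc_scenario"),
              "scenario must be a ctc_scenario object")
  rel <- scenario$release; kin <- scenario$kinetics
  dev <- scenario$device; ly <- scenario$lymph
  cfg <- list(
    scenario_id = scenario$scenario_id,
    placement = dev$placement,
    r_const = rel$r_const, r_dyn = rel$r_dyn,
    p_const = rel$p_const, p_dyn = rel$p_dyn,
    M = rel$M, delay_days = rel$delay / 1440,
    k_dead = kin$k_dead, k_deadc = kin$k_deadc,
    k_met = kin$k_met, k_metc = kin$k_metc, N_c = kin$N_c,
    N_cdev = dev$N_cdev,
    T_dev_h = dev$T_dev / 60, dT_dev_h = dev$dT_dev / 60,
    R_vol = dev$R_vol, eff_dev = dev$eff_dev, eff_devc = dev$eff_devc,
    p_lymph = ly$p_lymph, p_lymphc = ly$p_lymphc,
    l_dead = ly$l_dead, l_deadc = ly$l_deadc,
    l_pass = ly$l_pass, l_passc = ly$l_passc,
    duration_days = scenario$duration / 1440, h_min = scenario$h,
    n0 = scenario$n0, c0 = scenario$c0, m0 = scenario$m0,
    V_tot = scenario$V_tot)
  if (rel$spike_factor != 1)
    cfg <- c(cfg, list(spike_start_h = rel$spike_start / 60,
                       spike_duration_h = rel$spike_duration / 60,
                       spike_factor = rel$spike_factor))
  if (!is.null(dev$window_start))
    cfg <- c(cfg, list(window_start_h = dev$window_start / 60,
                       window_end_h = dev$window_end / 60))
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Run manifest
#'
#' Captures everything needed to reproduce a run bit-identically: the fully
#' resolved parameter set in minutes, the step actually used, the package
#' version and a timestamp.  The pipeline is deterministic, so re-running
#' from a manifest reproduces the outputs exactly.
#'
#' @param scenario a `"ctc_scenario"` object.
#' @param h_used the integration step actually used (after
#'   [adjust_step()]).
#' @return a list suitable for [jsonlite::write_json()].
#' @export
run_manifest <- function(scenario, h_used) {
  rel <- scenario$release; dev <- scenario$device
  list(
    scenario_id = scenario$scenario_id,
    parameters = list(
      release = unclass(rel),
      kinetics = unclass(scenario$kinetics),
      device = dev[!vapply(dev, is.null, logical(1))],
      lymph = unclass(scenario$lymph),
      duration = scenario$duration,
      n0 = scenario$n0, c0 = scenario$c0, m0 = scenario$m0,
      V_tot = scenario$V_tot),
    h_requested = scenario$h,
    h_used = h_used,
    package_version = as.character(utils::packageVersion("ctcsim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}
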