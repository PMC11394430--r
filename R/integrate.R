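#' @useDynLib ctcsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Flatten a scenario into the fixed numeric layout the C++ core expects.
# Order must match enum Par in src/midpoint.cpp.
.flatten_params <- function(sc) {
  rel <- sc$release; kin <- sc$kinetics; dev <- sc$device; ly <- sc$lymph
  placement <- match(dev$placement, c("none", "extracorporeal", "implanted")) - 1
  c(rel$r_const, rel$r_dyn, rel$p_const, rel$p_dyn, rel$T_day, rel$M,
    rel$delay,
    if (rel$spike_factor != 1) rel$spike_start else -1,
    rel$spike_duration, rel$spike_factor,
    kin$k_dead, kin$k_deadc, kin$k_met, kin$k_metc, kin$N_c,
    placement, dev$T_dev, dev$R_vol, dev$eff_dev, dev$eff_devc, dev$N_cdev,
    if (is.null(dev$window_start)) -1 else dev$window_start,
    if (is.null(dev$window_end)) -1 else dev$window_end,
    ly$p_lymph, ly$p_lymphc, ly$l_pass, ly$l_passc, ly$l_meta, ly$l_metac,
    release_peak_time(dev, rel$T_day))
}

# Times at which the right-hand side is discontinuous or the delayed lookup
# must be grid-aligned; h is shrunk (by halving) until every one of them is
# an integer number of steps.
.step_constraints <- function(sc) {
  v <- c(sc$release$T_day, sc$duration)
  dev <- sc$device
  if (dev$placement != "none" && dev$T_dev > 0 && dev$T_dev < sc$release$T_day)
    v <- c(v, dev$T_dev)
  if (!is.null(dev$window_start))
    v <- c(v, dev$window_start, dev$window_end)
  if (sc$release$M > 0 && sc$release$delay > 0)
    v <- c(v, sc$release$delay)
  if (sc$release$spike_factor != 1)
    v <- c(v, sc$release$spike_start,
           sc$release$spike_start + sc$release$spike_duration)
  v[v > 0]
}

#' Align the integration step with model discontinuities
#'
#' Returns the largest step of the form `h / 2^k` such that the day length,
#' the simulation duration, the metastasis delay and every device switch or
#' spike edge is an integer number of steps.  Grid alignment keeps the
#' midpoint method at its nominal second order: an on/off switch inside a
#' step would otherwise degrade the local error to first order.
#'
#' @param scenario a [scenario()] object.
#' @param h requested step in minutes; defaults to the scenario's.
#' @return the adjusted step (<= `h`), with a warning when it differs.
#' @export
adjust_step <- function(scenario, h = scenario$h) {
  stop_unless(is_pos_scalar(h), "h must be a single value > 0")
  targets <- .step_constraints(scenario)
  aligned <- function(hh) all(abs(targets / hh - round(targets / hh)) < 1e-6)
  hh <- h
  for (i in 0:40) {
    if (aligned(hh)) {
      if (hh < h)
        warning(sprintf("step reduced from %g to %g min to align the grid %s",
                        h, hh,
                        "with device switches and the delay"), call. = FALSE)
      return(hh)
    }
    hh <- hh / 2
  }
  stop("unable to align the step with the scenario's switch times; ",
       "choose h so that T_day, T_dev, the delay and the duration are ",
       "integer multiples of it", call. = FALSE)
}

#' Integrate a scenario
#'
#' Solves the delayed three-variable system with the fixed-step midpoint
#' (improved Euler) scheme: a half step with the slope at `t_k` followed by
#' a full step with the slope at `t_k + h/2`, giving local error O(h^3) and
#' global second order on smooth segments.  The delayed burden
#' `m(t - delay)` is read from the stored grid history (the delay is an
#' integer number of steps after [adjust_step()]); the half-step lookup is
#' linearly interpolated between adjacent grid values, and the history is
#' constant at `m0` before the start.  States are clipped at zero after each
#' step; with valid parameters and an adequate step this never triggers, and
#' any clip is reported as a warning because it indicates the step is too
#' large for the rates involved.
#'
#' @param scenario a [scenario()] object.
#' @param h integration step in minutes, adjusted via [adjust_step()];
#'   defaults to the scenario's step.
#' @return an object of class `"ctc_trajectory"`: a list with the time grid
#'   `times` (minutes), the state series `n`, `c`, `m`, the instantaneous
#'   release series `r`, `p`, the step `h` actually used and the scenario
#'   label.  Convert with `as.data.frame()`.
#' @examples
#' tr <- integrate_scenario(scenario(duration = 1440, h = 1))
#' tail(as.data.frame(tr), 3)
#' @export
integrate_scenario <- function(scenario, h = scenario$h) {
  stop_unless(inherits(scenario, "ctc_scenario"),
              "scenario must be a ctc_scenario object")
  h <- adjust_step(scenario, h)
  n_steps <- as.integer(round(scenario$duration / h))
  rel <- scenario$release
  d <- if (rel$M > 0 && rel$delay > 0) as.integer(round(rel$delay / h)) else 0L
  out <- .midpoint_core(c(scenario$n0, scenario$c0, scenario$m0),
                        0, n_steps, h,
                        rep(scenario$m0, d + 1L),
                        .flatten_params(scenario))
  if (out$clipped > 0)
    warning(sprintf("state clipped to zero %d time(s); ", out$clipped),
            "the step may be too large for the rates involved (stiffness)",
            call. = FALSE)
  structure(list(times = seq(0, by = h, length.out = n_steps + 1L),
                 n = out$n, c = out$c, m = out$m, r = out$r, p = out$p,
                 h = h, clipped = out$clipped,
                 scenario_id = scenario$scenario_id),
            class = "ctc_trajectory")
}

#' @export
print.ctc_trajectory <- function(x, ...) {
  k <- length(x$times)
  cat(sprintf("CTC trajectory%s: %d points, t = 0..%g min (h = %g)\n",
              if (!is.null(x$scenario_id)) paste0(" '", x$scenario_id, "'")
              else "", k, x$times[k], x$h))
  cat(sprintf("  final state: n = %.4g, c = %.4g, m = %.6g au\n",
              x$n[k], x$c[k], x$m[k]))
  invisible(x)
}

#' @export
as.data.frame.ctc_trajectory <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  data.frame(t_min = x$times, n = x$n, c = x$c, m = x$m,
             r = x$r, p = x$p)
}

#' Write a trajectory to CSV
#'
#' Columns `t_min, n, c, m, r, p`, one row per grid point (or per `thin`-th
#' grid point); numbers are written in the C locale with a decimal point.
#'
#' @param trajectory a `"ctc_trajectory"` object.
#' @param path output file path.
#' @param thin keep every `thin`-th grid point (the final point is always
#'   kept).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path, thin = 1L) {
  stop_unless(inherits(trajectory, "ctc_trajectory"),
              "trajectory must be a ctc_trajectory object")
  stop_unless(is_pos_scalar(thin), "thin must be a single value >= 1")
  df <- as.data.frame(trajectory)
  if (thin > 1) {
    keep <- unique(c(seq(1L, nrow(df), by = as.integer(thin)), nrow(df)))
    df <- df[keep, ]
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Empirical convergence order of the integrator
#'
#' Integrates the scenario at each step in `h_values`, measures the error of
#' the final state against the run at the finest step, and estimates the
#' order as the slope of log(error) versus log(h).  On smooth scenarios the
#' midpoint method is second order; on/off switches that are not aligned
#' with every grid reduce the observed order toward one, which is why
#' [adjust_step()] aligns them.
#'
#' @param scenario a [scenario()] object.
#' @param h_values at least three steps, ideally in geometric progression;
#'   each must satisfy the alignment constraints of [adjust_step()].
#' @return an object of class `"ctc_convergence"`: a list with the steps
#'   `h`, the final-state errors `error`, the estimated `order` (`NA` when
#'   all errors vanish) and the flag `exact`.
#' @examples
#' sc <- scenario(release_params(0, 0, 0, 0),
#'                ctc_kinetics(k_dead = 0.0046),
#'                duration = 720, h = 2, n0 = 1000)
#' convergence_order(sc, c(2, 1, 0.5))
#' @export
convergence_order <- function(scenario, h_values) {
  stop_unless(is.numeric(h_values) && length(h_values) >= 3 &&
                all(h_values > 0),
              "h_values must contain at least three positive steps")
  h_values <- sort(unique(h_values), decreasing = TRUE)
  final_state <- function(h) {
    tr <- integrate_scenario(scenario, h = h)
    k <- length(tr$times)
    c(tr$n[k], tr$c[k], tr$m[k])
  }
  h_ref <- h_values[length(h_values)]
  ref <- final_state(h_ref)
  hs <- h_values[-length(h_values)]
  errs <- vapply(hs, function(h) max(abs(final_state(h) - ref)), numeric(1))
  scale <- max(abs(ref), 1)
  exact <- all(errs <= 1e-12 * scale)
  order <- if (exact) NA_real_ else
    unname(stats::coef(stats::lm(log(errs) ~ log(hs)))[2])
  structure(list(h = hs, error = errs, order = order, exact = exact,
                 h_reference = h_ref),
            class = "ctc_convergence")
}

#' @export
print.ctc_convergence <- function(x, ...) {
  if (x$exact)
    cat("Convergence check: exact (all errors numerically zero)\n")
  else
    cat(sprintf("Convergence check: estimated order %.2f over h = %s\n",
                x$order, paste(signif(x$h, 3), collapse = ", ")))
  invisible(x)
}
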