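# Non-compartmental and analytic exposure metrics: AUC, Cmax, Tmax, terminal
# half-life. For all four parameter sets here Ka < ke (flip-flop kinetics),
# so the terminal slope reflects absorption and T1/2 converges to ln(2)/Ka.

#' Trapezoidal AUC over a time window
#'
#' Linear trapezoidal rule by default; the log-linear rule (log trapezoid on
#' strictly decreasing positive segments, linear elsewhere) is available via
#' `method = "log-linear"`. Window endpoints not on the grid are obtained by
#' linear interpolation.
#'
#' @param profile A [conc_profile].
#' @param t_start,t_end Window bounds (h); must lie within the profile range.
#'   Default to the full profile.
#' @param method `"linear"` (default) or `"log-linear"`.
#' @return AUC in ng/mL·h.
#' @export
auc_trapezoid <- function(profile, t_start = NULL, t_end = NULL,
                          method = c("linear", "log-linear")) {
  stopifnot(is_conc_profile(profile))
  method <- match.arg(method)
  t_start <- t_start %||% profile$time[1]
  t_end <- t_end %||% profile$time[nrow(profile)]
  if (t_start < profile$time[1] || t_end > profile$time[nrow(profile)] ||
      t_start > t_end) {
    stop("auc_trapezoid: [t_start, t_end] must lie within the profile range",
         call. = FALSE)
  }
  inside <- profile$time > t_start & profile$time < t_end
  tt <- c(t_start, profile$time[inside], t_end)
  cc <- stats::approx(profile$time, profile$conc, xout = tt)$y
  dt <- diff(tt)
  c1 <- cc[-length(cc)]
  c2 <- cc[-1]
  if (method == "linear") {
    return(sum(dt * (c1 + c2) / 2))
  }
  # log-linear on strictly decreasing positive segments
  seg <- dt * (c1 + c2) / 2
  lg <- c1 > 0 & c2 > 0 & c2 < c1
  seg[lg] <- dt[lg] * (c1[lg] - c2[lg]) / log(c1[lg] / c2[lg])
  sum(seg)
}

#' Analytic AUC to infinity
#'
#' For a linear model the total exposure is dose/CL independent of absorption:
#' AUC\eqn{_\infty} = D/CL, converted to ng/mL·h.
#'
#' @param params A [pk_params] object.
#' @param total_dose Total administered dose (mg); 0 allowed.
#' @return AUC in ng/mL·h.
#' @export
auc_infinity <- function(params, total_dose) {
  stopifnot(is_pk_params(params))
  if (total_dose < 0) stop("auc_infinity: dose must be non-negative", call. = FALSE)
  total_dose / params$CL * 1000
}

#' Observed Cmax and Tmax of a profile
#'
#' Maximum concentration on the grid and the grid time at which it occurs;
#' ties are broken toward the earliest time.
#'
#' @param profile A [conc_profile].
#' @return Named numeric vector `c(cmax = , tmax = )`.
#' @export
cmax_tmax <- function(profile) {
  stopifnot(is_conc_profile(profile), nrow(profile) >= 1)
  i <- which.max(profile$conc)  # which.max returns the first maximum
  c(cmax = profile$conc[i], tmax = profile$time[i])
}

#' Analytic time of peak concentration
#'
#' Closed-form peak time of the lagged one-compartment oral model,
#' Tlag + ln(Ka/ke)/(Ka − ke); the Ka = ke limit is Tlag + 1/Ka.
#'
#' @param params A [pk_params] object.
#' @return Peak time (h).
#' @export
analytic_tmax <- function(params) {
  stopifnot(is_pk_params(params))
  ke <- elimination_rate(params)
  Ka <- params$Ka
  if (abs(Ka - ke) < .KA_KE_TOL * max(Ka, ke)) {
    return(params$Tlag + 1 / Ka)
  }
  params$Tlag + log(Ka / ke) / (Ka - ke)
}

#' Terminal half-life by log-linear regression on the profile tail
#'
#' Fits a least-squares line to log-concentration versus time over the last
#' `n_tail_points` positive-concentration points and returns ln(2) divided by
#' the negative slope. By default the tail is the last 25% of the
#' positive-concentration grid, which sits safely inside the terminal phase
#' for the metoprolol parameter sets. Under flip-flop kinetics (Ka < ke) this
#' converges to ln(2)/Ka, not ln(2)/ke.
#'
#' @param profile A [conc_profile].
#' @param n_tail_points Number of tail points to regress on (>= 3); default
#'   the last 25% of positive-concentration points.
#' @return Terminal half-life (h).
#' @export
terminal_half_life <- function(profile, n_tail_points = NULL) {
  stopifnot(is_conc_profile(profile))
  pos <- which(profile$conc > 0)
  if (is.null(n_tail_points)) n_tail_points <- max(3L, ceiling(length(pos) / 4))
  if (length(pos) < n_tail_points || n_tail_points < 3) {
    stop("terminal_half_life: need at least 3 positive-concentration tail points",
         call. = FALSE)
  }
  tail_idx <- pos[(length(pos) - n_tail_points + 1L):length(pos)]
  fit <- stats::lm(log(profile$conc[tail_idx]) ~ profile$time[tail_idx])
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) {
    stop("terminal_half_life: tail is not log-linearly decreasing", call. = FALSE)
  }
  -log(2) / slope
}

#' Exposure summary for a parameter set and regimen
#'
#' Simulates a profile with [simulate_profile] and bundles the standard
#' exposure metrics: AUC over the simulated window (linear trapezoid),
#' analytic AUC to infinity (total dose / CL), Cmax, Tmax, and the terminal
#' half-life from tail regression.
#'
#' @inheritParams simulate_profile
#' @return An `exposure_summary`: a list with elements `auc_0_t`, `auc_inf`,
#'   `cmax`, `tmax`, `t_half`, `horizon`.
#'
#' @examples
#' male <- pk_params(V = 55.3, CL = 253, Ka = 0.241, Tlag = 0.67)
#' exposure_summary(male, dosing_regimen(100, 0))
#' @export
exposure_summary <- function(params, regimen, n_points = 1000, horizon = 24) {
  prof <- simulate_profile(params, regimen, n_points, horizon)
  ct <- cmax_tmax(prof)
  structure(list(
    auc_0_t = auc_trapezoid(prof),
    auc_inf = auc_infinity(params, sum(regimen$amt)),
    cmax = unname(ct["cmax"]),
    tmax = unname(ct["tmax"]),
    t_half = terminal_half_life(prof),
    horizon = horizon
  ), class = "exposure_summary")
}

#' @export
print.exposure_summary <- function(x, ...) {
  cat(sprintf("Exposure summary (0-%g h grid):\n", x$horizon))
  cat(sprintf("  AUC(0-%g h) %8.4g ng/mL.h\n  AUC(inf)    %8.4g ng/mL.h\n",
              x$horizon, x$auc_0_t, x$auc_inf))
  cat(sprintf("  Cmax        %8.4g ng/mL\n  Tmax        %8.4g h\n  T1/2        %8.4g h\n",
              x$cmax, x$tmax, x$t_half))
  invisible(x)
}
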