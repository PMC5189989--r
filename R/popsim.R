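# Monte-Carlo population simulation: lognormal inter-individual variability
# around typical parameter values, profile evaluation at a sampling design,
# and a proportional residual-error model. All randomness comes from R's
# global RNG stream, so set.seed() before a call makes it fully reproducible.

#' Convert a coefficient of variation to a log-scale variance
#'
#' Two conventions are in use for lognormal inter-individual variability.
#' The exact convention inverts the lognormal CV, \eqn{\omega^2 =
#' \ln(1 + CV^2)}; the approximate convention takes \eqn{\omega^2 = CV^2}
#' (equivalently CV = \eqn{\sqrt{\omega^2}}), which is how population-PK
#' estimate tables usually print their CV column. Simulation defaults to the
#' exact convention; reporting uses the approximate one.
#'
#' @param cv Coefficient of variation as a fraction (>= 0); vectorized.
#' @param convention `"exact"` or `"approx"`.
#' @return Log-scale variance(s) \eqn{\omega^2}.
#'
#' @examples
#' cv_to_variance(0.59, "exact")   # ln(1 + 0.59^2)
#' cv_to_variance(0.55, "approx")  # 0.55^2 ~ 0.30
#' @export
cv_to_variance <- function(cv, convention = c("exact", "approx")) {
  convention <- match.arg(convention)
  if (any(cv < 0)) stop("cv_to_variance: cv must be non-negative", call. = FALSE)
  if (convention == "exact") log(1 + cv^2) else cv^2
}

#' Proportional residual error model
#'
#' Observation model y = f (1 + b e), e ~ N(0, 1): the observation noise SD
#' is the fraction `b` of the predicted concentration.
#'
#' @param b Proportional error magnitude as a fraction (>= 0).
#' @return A `residual_error_model` object.
#' @export
residual_error_model <- function(b) {
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b < 0) {
    stop("residual_error_model: b must be a single non-negative number",
         call. = FALSE)
  }
  structure(list(kind = "proportional", b = b), class = "residual_error_model")
}

#' Population pharmacokinetic model
#'
#' Typical parameter values, per-parameter inter-individual coefficients of
#' variation (lognormal), and a residual error model. Parameters with CV 0
#' are fixed across subjects.
#'
#' @param typical A [pk_params] object of typical values.
#' @param iiv_cv Named numeric vector of CVs (fractions) for any of
#'   `CL`, `V`, `Ka`, `Tlag`; omitted names default to 0.
#' @param residual A [residual_error_model]; default b = 0.
#' @param cv_convention Convention used to translate CVs to log-variances,
#'   see [cv_to_variance]; default `"exact"`.
#' @return A `population_model` object.
#'
#' @examples
#' pm <- population_model(
#'   typical = pk_params(V = 34.9, CL = 101, Ka = 0.161, Tlag = 0.38),
#'   iiv_cv = c(CL = 0.49, V = 0.34, Ka = 0.40),
#'   residual = residual_error_model(0.0281)
#' )
#' @export
population_model <- function(typical, iiv_cv = c(CL = 0, V = 0, Ka = 0, Tlag = 0),
                             residual = residual_error_model(0),
                             cv_convention = c("exact", "approx")) {
  stopifnot(is_pk_params(typical), inherits(residual, "residual_error_model"))
  cv_convention <- match.arg(cv_convention)
  cv <- c(V = 0, CL = 0, Ka = 0, Tlag = 0)
  if (length(iiv_cv)) {
    bad <- setdiff(names(iiv_cv), names(cv))
    if (length(bad)) stop("population_model: unknown iiv_cv names: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    cv[names(iiv_cv)] <- iiv_cv
  }
  if (any(cv < 0)) stop("population_model: CVs must be non-negative", call. = FALSE)
  structure(list(typical = typical, iiv_cv = cv,
                 omega2 = cv_to_variance(cv, cv_convention),
                 residual = residual, cv_convention = cv_convention),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat("Population PK model (lognormal IIV, proportional error)\n")
  cat("Typical values:\n")
  print(x$typical)
  cat(sprintf("IIV CV (%s convention): %s\n", x$cv_convention,
              paste(sprintf("%s=%.0f%%", names(x$iiv_cv), 100 * x$iiv_cv),
                    collapse = ", ")))
  cat(sprintf("Proportional residual error b = %.4g\n", x$residual$b))
  invisible(x)
}

#' Sampling design for a simulated trial
#'
#' @param times Observation times (h), non-negative and sorted.
#' @param n_per_group Subjects per group (>= 1).
#' @param groups Character vector of group labels (e.g. sexes).
#' @param regimen Dose events per subject, a [dosing_regimen].
#' @return A `sampling_design` object.
#' @export
sampling_design <- function(times, n_per_group, groups, regimen) {
  stopifnot(is_dosing_regimen(regimen))
  if (any(times < 0) || is.unsorted(times)) {
    stop("sampling_design: times must be non-negative and sorted", call. = FALSE)
  }
  if (n_per_group < 1) stop("sampling_design: n_per_group must be >= 1", call. = FALSE)
  structure(list(times = times, n_per_group = as.integer(n_per_group),
                 groups = as.character(groups), regimen = regimen),
            class = "sampling_design")
}

#' @export
print.sampling_design <- function(x, ...) {
  cat(sprintf("Sampling design: %d group(s) x %d subjects x %d times = %d observations\n",
              length(x$groups), x$n_per_group, length(x$times),
              length(x$groups) * x$n_per_group * length(x$times)))
  invisible(x)
}

# Draw n individual parameter vectors; returns an n x 4 matrix (V, CL, Ka,
# Tlag). theta_i = theta_typ * exp(eta), eta ~ N(0, omega2) per parameter.
draw_population_matrix <- function(pop, n) {
  stopifnot(inherits(pop, "population_model"))
  typ <- unlist(pop$typical)[c("V", "CL", "Ka", "Tlag")]
  om <- pop$omega2[c("V", "CL", "Ka", "Tlag")]
  eta <- matrix(stats::rnorm(n * 4L), n, 4L)
  eta <- sweep(eta, 2L, sqrt(om), `*`)
  theta <- sweep(exp(eta), 2L, typ, `*`)
  colnames(theta) <- c("V", "CL", "Ka", "Tlag")
  theta
}

#' Draw one individual's parameters from a population model
#'
#' Each varying parameter is drawn lognormally,
#' \eqn{\theta_i = \theta_{typ} e^{\eta}}, \eqn{\eta \sim N(0, \omega^2)};
#' parameters with CV 0 are copied from the typical values.
#'
#' @param pop A [population_model].
#' @return A [pk_params] object.
#' @export
draw_individual <- function(pop) {
  th <- draw_population_matrix(pop, 1L)
  pk_params(V = th[1, "V"], CL = th[1, "CL"], Ka = th[1, "Ka"],
            Tlag = th[1, "Tlag"])
}

#' Apply proportional residual error to true concentrations
#'
#' y = f (1 + b e), e ~ N(0,1), floored at 0. A true concentration of 0
#' stays 0 under the proportional model.
#'
#' @param true_conc Non-negative true concentration(s) (ng/mL).
#' @param model A [residual_error_model].
#' @return Observed concentration(s), >= 0.
#' @export
apply_residual_error <- function(true_conc, model) {
  stopifnot(inherits(model, "residual_error_model"))
  if (any(true_conc < 0)) {
    stop("apply_residual_error: true_conc must be non-negative", call. = FALSE)
  }
  if (model$b == 0) return(true_conc)
  pmax(true_conc * (1 + model$b * stats::rnorm(length(true_conc))), 0)
}

#' Simulate a clinical trial
#'
#' For each subject of each design group: draw individual parameters from
#' that group's population model, evaluate the concentration model at the
#' design times, and apply residual error. Returns a NONMEM-style dataset
#' with one dose row per dose event and one observation row per sampling
#' time per subject; subject IDs are dense from 1 across groups.
#'
#' @param pop_by_group Named list mapping each group label in the design to a
#'   [population_model].
#' @param design A [sampling_design].
#' @return A `pk_dataset` data.frame with columns `ID`, `TIME`, `AMT`, `DV`,
#'   `EVID`, `SEX`.
#'
#' @examples
#' set.seed(42)
#' trial <- simulate_trial(
#'   list(male = cts_population_model("male"),
#'        female = cts_population_model("female")),
#'   cts_design()
#' )
#' nrow(trial[trial$EVID == 0, ])  # 1700 observations
#' @export
simulate_trial <- function(pop_by_group, design) {
  stopifnot(inherits(design, "sampling_design"))
  missing <- setdiff(design$groups, names(pop_by_group))
  if (length(missing)) {
    stop("simulate_trial: no population model for group(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- vector("list", length(design$groups))
  id0 <- 0L
  for (g in seq_along(design$groups)) {
    grp <- design$groups[g]
    pop <- pop_by_group[[grp]]
    n <- design$n_per_group
    theta <- draw_population_matrix(pop, n)
    true_conc <- conc_matrix(theta, design$regimen, design$times)
    obs <- apply_residual_error(as.vector(t(true_conc)), pop$residual)
    ids <- id0 + seq_len(n)
    dose_rows <- data.frame(
      ID = rep(ids, each = nrow(design$regimen)),
      TIME = rep(design$regimen$time, times = n),
      AMT = rep(design$regimen$amt, times = n),
      DV = NA_real_, EVID = 1L, SEX = grp
    )
    obs_rows <- data.frame(
      ID = rep(ids, each = length(design$times)),
      TIME = rep(design$times, times = n),
      AMT = 0, DV = obs, EVID = 0L, SEX = grp
    )
    out[[g]] <- rbind(dose_rows, obs_rows)
    id0 <- id0 + n
  }
  ds <- do.call(rbind, out)
  ds <- ds[order(ds$ID, ds$TIME, -ds$EVID), ]
  rownames(ds) <- NULL
  structure(ds, class = c("pk_dataset", "data.frame"))
}

#' Pointwise percentile bands of simulated individual profiles
#'
#' Simulates `n_subjects` noise-free individual concentration curves from
#' the population model and returns pointwise percentiles at `probs`
#' together with the typical-value curve. Percentiles use the
#' linear-interpolation quantile definition (R type 7).
#'
#' @param pop A [population_model].
#' @param regimen A [dosing_regimen].
#' @param grid Evaluation times (h).
#' @param n_subjects Number of simulated subjects (>= 2).
#' @param probs Percentile levels, default c(0.1, 0.5, 0.9).
#' @return A data.frame with columns `time`, `typical`, and one `p<level>`
#'   column per probability.
#' @export
percentile_bands <- function(pop, regimen, grid, n_subjects = 3000,
                             probs = c(0.1, 0.5, 0.9)) {
  stopifnot(inherits(pop, "population_model"), n_subjects >= 2)
  theta <- draw_population_matrix(pop, n_subjects)
  cm <- conc_matrix(theta, regimen, grid)
  qs <- apply(cm, 2L, stats::quantile, probs = probs, names = FALSE, type = 7)
  if (length(probs) == 1L) qs <- matrix(qs, nrow = 1L)
  out <- data.frame(time = grid,
                    typical = conc_regimen(pop$typical, regimen, grid))
  for (j in seq_along(probs)) {
    out[[sprintf("p%g", 100 * probs[j])]] <- qs[j, ]
  }
  out
}
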