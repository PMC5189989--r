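# Packaged reference values: sex-by-enantiomer one-compartment parameter
# sets for metoprolol, the population CV%s used by the clinical trial
# simulation, and the reference population-estimate table kept for
# report-format comparisons. Shipped as versioned CSVs under inst/extdata.

.fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "metopop")
  if (!nzchar(p)) stop("fixture file not found: ", file, call. = FALSE)
  p
}

.read_fixture <- function(file) {
  utils::read.csv(.fixture_path(file), stringsAsFactors = FALSE)
}

#' Reference one-compartment parameters by sex and enantiomer
#'
#' Returns the packaged apparent one-compartment parameter set (V, CL, Ka,
#' Tlag) for one of the four sex-by-enantiomer metoprolol populations. The
#' S-enantiomer is the pharmacologically active one and drives the dosing
#' analysis; R-enantiomer sets are included for completeness.
#'
#' @param sex `"male"` or `"female"`.
#' @param enantiomer `"S"` (default) or `"R"`.
#' @return A [pk_params] object.
#'
#' @examples
#' reference_parameters("female", "S")
#' @export
reference_parameters <- function(sex = c("male", "female"), enantiomer = c("S", "R")) {
  sex <- match.arg(sex)
  enantiomer <- match.arg(enantiomer)
  tab <- .read_fixture("reference_parameters.csv")
  row <- tab[tab$sex == sex & tab$enantiomer == enantiomer, ]
  stopifnot(nrow(row) == 1L)
  pk_params(V = row$V, CL = row$CL, Ka = row$Ka, Tlag = row$Tlag)
}

#' Reference population-estimate table
#'
#' The sex-stratified population PK estimate table (typical values, standard
#' errors, RSE%, CV%, interindividual variances and the proportional error
#' parameter) kept as a packaged fixture so that estimate reports can be laid
#' out and compared against it.
#'
#' @return A data.frame with columns `parameter`, `group`, `value`, `se`,
#'   `rse_pct`, `cv_pct`.
#' @export
reference_estimates <- function() {
  .read_fixture("reference_estimates.csv")
}

#' Population CV values used by the clinical trial simulation
#'
#' Inter-individual coefficients of variation (as fractions) for CL and V by
#' sex and enantiomer, plus the assumed 40% CV for the absorption rate
#' constant. Tlag carries no inter-individual variability in simulation.
#'
#' @inheritParams reference_parameters
#' @return Named numeric vector `c(CL = , V = , Ka = , Tlag = 0)`.
#' @export
cts_iiv_cv <- function(sex = c("male", "female"), enantiomer = c("S", "R")) {
  sex <- match.arg(sex)
  enantiomer <- match.arg(enantiomer)
  tab <- .read_fixture("cts_iiv_cv.csv")
  row <- tab[tab$sex == sex & tab$enantiomer == enantiomer, ]
  stopifnot(nrow(row) == 1L)
  c(CL = row$cv_CL, V = row$cv_V, Ka = row$cv_Ka, Tlag = 0)
}

#' Population model for one clinical-trial-simulation arm
#'
#' Convenience constructor combining the reference typical values
#' ([reference_parameters]), the per-sex CV set ([cts_iiv_cv]) and the
#' proportional residual error parameter b = 0.0281 into a
#' [population_model].
#'
#' @inheritParams reference_parameters
#' @param residual_b Proportional residual error fraction.
#' @return A [population_model].
#' @export
cts_population_model <- function(sex = c("male", "female"), enantiomer = c("S", "R"),
                                 residual_b = 0.0281) {
  sex <- match.arg(sex)
  enantiomer <- match.arg(enantiomer)
  population_model(
    typical = reference_parameters(sex, enantiomer),
    iiv_cv = cts_iiv_cv(sex, enantiomer),
    residual = residual_error_model(residual_b)
  )
}

#' Clinical trial simulation sampling design
#'
#' The default trial design: 50 subjects per sex, a single oral 100 mg dose
#' at time 0, and 17 sampling times (0, 0.1, 0.2, 0.3, 0.4, 0.6, 0.8, 1, 2,
#' 4, 6, 8, 12, 14, 16, 18, 24 h). The pre-dose t = 0 sample is included as
#' an observation record, so the design yields 2 x 50 x 17 = 1700
#' observations.
#'
#' @return A [sampling_design].
#' @export
cts_design <- function() {
  sampling_design(
    times = c(0, 0.1, 0.2, 0.3, 0.4, 0.6, 0.8, 1, 2, 4, 6, 8, 12, 14, 16, 18, 24),
    n_per_group = 50,
    groups = c("male", "female"),
    regimen = dosing_regimen(100, 0)
  )
}

#' Generate a digitized-style mean concentration profile dataset
#'
#' Emulates the mean concentration-time input that the original model fit
#' consumed: a single mean "subject" given nine 100 mg oral doses every 12 h,
#' sampled densely across the ninth dosing interval and a 24 h washout, with
#' optional multiplicative (proportional) observation noise. The exact
#' sampling schedule of the source study is unknown; the default schedule is
#' a documented stand-in that covers absorption, peak and terminal phases.
#'
#' @inheritParams reference_parameters
#' @param noise_cv Proportional noise magnitude as a fraction (>= 0).
#' @param times Optional observation times (h); defaults to a schedule dense
#'   after the ninth dose (96 h) through 120 h.
#' @return A NONMEM-style dataset (see [read_dataset]) with one subject,
#'   nine dose rows and one observation row per sampling time.
#'
#' @examples
#' set.seed(1)
#' d <- generate_digitized_profile("female", "S", noise_cv = 0.0281)
#' head(d)
#' @export
generate_digitized_profile <- function(sex = c("male", "female"),
                                       enantiomer = c("S", "R"),
                                       noise_cv = 0, times = NULL) {
  sex <- match.arg(sex)
  enantiomer <- match.arg(enantiomer)
  if (noise_cv < 0) stop("noise_cv must be non-negative", call. = FALSE)
  params <- reference_parameters(sex, enantiomer)
  regimen <- dosing_regimen(100, seq(0, 96, by = 12))
  if (is.null(times)) {
    times <- c(seq(2, 94, by = 4),
               96 + c(0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 5, 6, 8, 10, 12,
                      14, 16, 18, 20, 22, 24))
  }
  conc <- conc_regimen(params, regimen, times)
  if (noise_cv > 0) {
    conc <- pmax(conc * (1 + noise_cv * stats::rnorm(length(conc))), 0)
  }
  dose_rows <- data.frame(ID = 1L, TIME = regimen$time, AMT = regimen$amt,
                          DV = NA_real_, EVID = 1L, SEX = sex)
  obs_rows <- data.frame(ID = 1L, TIME = times, AMT = 0, DV = conc,
                         EVID = 0L, SEX = sex)
  ds <- rbind(dose_rows, obs_rows)
  ds <- ds[order(ds$TIME, -ds$EVID), ]
  rownames(ds) <- NULL
  structure(ds, class = c("pk_dataset", "data.frame"))
}
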