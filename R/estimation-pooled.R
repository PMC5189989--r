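# Naive pooled nonlinear least squares: all observations are treated as if
# they came from one subject with common parameters. Used to fit mean
# (digitized-style) profiles and to initialize the mixed-effects fit.

# Split a pk_dataset into per-subject pieces: regimen + observation table.
# Subjects are taken in sorted-ID order and records in time order, so the
# result is independent of the row order of the input.
split_subjects <- function(dataset) {
  stopifnot(inherits(dataset, "data.frame"))
  ids <- sort(unique(dataset$ID))
  lapply(ids, function(id) {
    d <- dataset[dataset$ID == id, ]
    d <- d[order(d$TIME, -d$EVID), ]
    doses <- d[d$EVID == 1L, ]
    obs <- d[d$EVID == 0L, ]
    if (nrow(doses) == 0L) {
      stop("subject ", id, " has no dose events", call. = FALSE)
    }
    list(id = id, group = if ("SEX" %in% names(d)) d$SEX[1] else NA_character_,
         regimen = dosing_regimen(doses$AMT, doses$TIME),
         times = obs$TIME, dv = obs$DV)
  })
}

#' Naive pooled least-squares fit of the one-compartment oral model
#'
#' Minimizes the summed squared log-scale (proportional) residuals
#' \eqn{\sum_j (\ln y_j - \ln f_j)^2} over log-parameters with a
#' Levenberg-Marquardt optimizer ([minpack.lm::nls.lm]), pooling all
#' observation records. The log-scale residual equals the proportional
#' residual \eqn{(y-f)/f} to first order but stays bounded when individual
#' curves span orders of magnitude, and it rules out the degenerate
#' zero-prediction plateau (a lag time past an observation would cost an
#' infinite residual). Observations with non-positive values (pre-dose
#' zeros) are excluded from the objective. Each subject's own dose events
#' are honoured, so the fitter applies equally to a single mean profile and
#' to pooled multi-subject data.
#'
#' @param dataset A NONMEM-style dataset (see [read_dataset]).
#' @param init A [pk_params] object of starting values.
#' @return A [pk_params] object of fitted values, with attributes
#'   `objective` (final sum of squares), `niter` and `message`.
#'
#' @examples
#' d <- generate_digitized_profile("female", "S", noise_cv = 0)
#' start <- pk_params(V = 50, CL = 150, Ka = 0.2, Tlag = 0.3)
#' naive_pooled_fit(d, start)
#' @export
naive_pooled_fit <- function(dataset, init) {
  stopifnot(is_pk_params(init))
  subjects <- split_subjects(dataset)
  obs_all <- do.call(rbind, lapply(subjects, function(s) {
    data.frame(sid = s$id, time = s$times, dv = s$dv)
  }))
  obs_all <- obs_all[is.finite(obs_all$dv) & obs_all$dv > 0, ]
  if (length(unique(obs_all$time)) < 4L) {
    stop("naive_pooled_fit: need >= 4 observations at distinct times ",
         "to identify 4 parameters", call. = FALSE)
  }
  resid_fn <- function(logpar) {
    p <- pk_params(V = exp(logpar[1]), CL = exp(logpar[2]),
                   Ka = exp(logpar[3]), Tlag = exp(logpar[4]))
    pred <- numeric(nrow(obs_all))
    for (s in subjects) {
      sel <- obs_all$sid == s$id
      if (any(sel)) pred[sel] <- conc_regimen(p, s$regimen, obs_all$time[sel])
    }
    log(obs_all$dv) - log(pmax(pred, 1e-300))
  }
  # box constraints keep the search away from degenerate plateaus: once
  # Tlag exceeds the earliest positive observation every prediction is 0
  # and the objective goes flat, so Tlag is capped just below that time
  tlag_cap <- 0.999 * min(obs_all$time)
  lower <- log(c(1e-3, 1e-3, 1e-4, 1e-4))
  upper <- log(c(1e5, 1e5, 1e3, tlag_cap))
  start <- pmin(pmax(log(c(init$V, init$CL, init$Ka, max(init$Tlag, 1e-3))),
                     lower), upper)
  fit <- minpack.lm::nls.lm(
    par = start,
    fn = resid_fn, lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                         ptol = 1e-12)
  )
  if (fit$info == 0 || fit$info == 9) {
    stop("naive_pooled_fit: optimizer failed to converge: ", fit$message,
         call. = FALSE)
  }
  est <- exp(fit$par)
  out <- pk_params(V = est[1], CL = est[2], Ka = est[3], Tlag = est[4])
  attr(out, "objective") <- fit$deviance
  attr(out, "niter") <- fit$niter
  attr(out, "message") <- fit$message
  out
}
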