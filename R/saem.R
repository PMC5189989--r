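# Stochastic approximation EM (SAEM) for the nonlinear mixed-effects
# one-compartment model. Individual log-parameters phi_i = log theta_i are
# sampled by MCMC (an independence kernel from the current population prior
# plus component-wise random-walk kernels with adaptive steps), and the
# population parameters are updated from stochastically approximated
# sufficient statistics. Variances are annealed during burn-in to avoid
# premature collapse; standard errors come from a stochastic approximation
# of the Fisher information (Louis' principle) accumulated during the
# smoothing phase.
#
# Model: phi_i ~ N(mu, Omega) with diagonal Omega; y_ij = f_ij (1 + b e_ij).
# The observation SD used in the likelihood is sqrt(a^2 + (b f)^2) with a
# tiny fixed additive floor a = 1e-8 ng/mL so that pre-dose records (true
# and predicted concentration both 0) contribute a finite constant instead
# of a 0/0 degeneracy.

.SD_FLOOR <- 1e-8   # additive floor on the observation SD (ng/mL)
.F_MIN <- 1e-6      # predictions below this are excluded from the b update
.FIX_OMEGA <- 1e-4  # terminal sampling variance for fixed-effect-only params

#' SAEM algorithm settings
#'
#' @param n_burn Burn-in (annealing/exploration) iterations.
#' @param n_smooth Smoothing iterations (step size 1/k).
#' @param n_chains Independent MCMC chains per subject.
#' @param target_accept Target acceptance rate for the adaptive random-walk
#'   kernels.
#' @param omega_floor Lower bound on estimated log-scale variances.
#' @param anneal Per-iteration shrink factor bounding how fast variance
#'   estimates may decrease during burn-in.
#' @param ll_tol Relative change in the log-likelihood trace over the final
#'   smoothing stretch below which the fit is declared stabilized.
#' @return A list of class `saem_control`.
#' @export
saem_control <- function(n_burn = 300, n_smooth = 100, n_chains = 3,
                         target_accept = 0.4, omega_floor = 1e-6,
                         anneal = 0.95, ll_tol = 1e-3) {
  stopifnot(n_burn >= 1, n_smooth >= 10, n_chains >= 1)
  structure(list(n_burn = n_burn, n_smooth = n_smooth, n_chains = n_chains,
                 target_accept = target_accept, omega_floor = omega_floor,
                 anneal = anneal, ll_tol = ll_tol),
            class = "saem_control")
}

# Build the per-subject observation structures and, when every subject
# shares the same observation times and regimen, a fast matrix evaluator.
.build_objective <- function(subjects) {
  times1 <- subjects[[1]]$times
  reg1 <- subjects[[1]]$regimen
  shared <- all(vapply(subjects, function(s) {
    identical(s$times, times1) && isTRUE(all.equal(as.data.frame(s$regimen),
                                                   as.data.frame(reg1)))
  }, logical(1)))
  n <- length(subjects)
  if (shared) {
    Y <- do.call(rbind, lapply(subjects, function(s) s$dv))
    predict_all <- function(phi) conc_matrix(exp(phi), reg1, times1)
    loglik <- function(phi, b) {
      f <- predict_all(phi)
      sd <- sqrt(.SD_FLOOR^2 + (b * f)^2)
      rowSums(stats::dnorm(Y, f, sd, log = TRUE))
    }
    resid_stat <- function(phi, b) {
      f <- predict_all(phi)
      use <- f > .F_MIN
      c(sum(((Y[use] - f[use]) / f[use])^2), sum(use))
    }
  } else {
    loglik <- function(phi, b) {
      vapply(seq_len(n), function(i) {
        s <- subjects[[i]]
        p <- exp(phi[i, ])
        f <- conc_regimen(pk_params(p[1], p[2], p[3], p[4]), s$regimen, s$times)
        sd <- sqrt(.SD_FLOOR^2 + (b * f)^2)
        sum(stats::dnorm(s$dv, f, sd, log = TRUE))
      }, numeric(1))
    }
    resid_stat <- function(phi, b) {
      acc <- c(0, 0)
      for (i in seq_len(n)) {
        s <- subjects[[i]]
        p <- exp(phi[i, ])
        f <- conc_regimen(pk_params(p[1], p[2], p[3], p[4]), s$regimen, s$times)
        use <- f > .F_MIN
        acc <- acc + c(sum(((s$dv[use] - f[use]) / f[use])^2), sum(use))
      }
      acc
    }
    predict_all <- NULL
  }
  list(loglik = loglik, resid_stat = resid_stat, shared = shared)
}

#' Fit a population model by SAEM
#'
#' Maximum-likelihood estimation of the population typical values, the
#' diagonal log-scale interindividual variances for CL, V and Ka, and the
#' proportional residual error fraction b. Tlag is estimated as a fixed
#' effect: its individual variability is excluded from the model and its
#' sampling variance is annealed to a floor during estimation.
#'
#' Randomness comes from R's global RNG; `set.seed()` before the call makes
#' the fit fully reproducible.
#'
#' @param dataset A NONMEM-style dataset (one stratum; fit strata
#'   separately).
#' @param init A [population_model] of starting values, or `NULL` to
#'   initialize from [naive_pooled_fit] with omega^2 = 0.1 and b = 0.05.
#' @param settings A [saem_control] list.
#' @param iiv_params Parameters carrying interindividual variability;
#'   default `c("CL", "V", "Ka")`.
#' @return A `population_estimate`: typical values, omega^2 estimates,
#'   residual b, standard errors / RSE%, the log-likelihood trace, subject-
#'   level mean sampled parameters, and convergence diagnostics.
#'
#' @examples
#' \donttest{
#' set.seed(7)
#' trial <- simulate_trial(list(female = cts_population_model("female")),
#'                         sampling_design(cts_design()$times, 25, "female",
#'                                         dosing_regimen(100, 0)))
#' fit <- saem_fit(trial, settings = saem_control(n_burn = 150, n_smooth = 50))
#' fit
#' }
#' @export
saem_fit <- function(dataset, init = NULL, settings = saem_control(),
                     iiv_params = c("CL", "V", "Ka")) {
  stopifnot(inherits(settings, "saem_control"))
  subjects <- split_subjects(dataset)
  n <- length(subjects)
  if (n < 2 && length(iiv_params) > 0) {
    stop("saem_fit: need >= 2 subjects to estimate interindividual variances",
         call. = FALSE)
  }
  pnames <- c("V", "CL", "Ka", "Tlag")
  iiv_idx <- match(iiv_params, pnames)
  if (anyNA(iiv_idx)) stop("saem_fit: unknown iiv_params", call. = FALSE)
  fix_idx <- setdiff(seq_len(4L), iiv_idx)

  if (is.null(init)) {
    pooled <- naive_pooled_fit(dataset, pk_params(V = 50, CL = 150, Ka = 0.2,
                                                  Tlag = 0.3))
    init <- population_model(
      typical = pooled,
      iiv_cv = stats::setNames(sqrt(exp(rep(0.1, length(iiv_params))) - 1),
                               iiv_params),
      residual = residual_error_model(0.05)
    )
  }
  stopifnot(inherits(init, "population_model"))

  obj <- .build_objective(subjects)
  K1 <- settings$n_burn
  K2 <- settings$n_smooth
  nc <- settings$n_chains

  mu <- log(unlist(init$typical)[pnames])
  omega2 <- pmax(init$omega2[pnames], settings$omega_floor)
  # fixed-effect-only parameters start with a moderate sampling variance
  # that is annealed geometrically over the burn-in down to .FIX_OMEGA;
  # keeping it there (rather than at the estimation floor) lets the fixed
  # effect continue to track during smoothing instead of freezing early
  omega2[fix_idx] <- 0.1
  fix_rho <- (.FIX_OMEGA / 0.1)^(1 / K1)
  b <- max(init$residual$b, 1e-4)

  # chains: list of n x 4 phi matrices with cached log-likelihoods; all
  # chains start at mu, dispersion comes from the independence kernel
  phi <- lapply(seq_len(nc), function(c) matrix(mu, n, 4L, byrow = TRUE))
  ll <- lapply(phi, function(ph) obj$loglik(ph, b))

  rw_step <- rep(0.4, 4L)
  s1 <- colSums(phi[[1]]) * 0      # running sufficient statistics
  s2 <- s1
  s3 <- 0; s3n <- 0
  have_stats <- FALSE

  # Louis FIM accumulators over psi = (mu[4], omega2[iiv], b)
  npsi <- 4L + length(iiv_idx) + 1L
  D_acc <- numeric(npsi)
  G_acc <- matrix(0, npsi, npsi)

  trace <- matrix(NA_real_, K1 + K2, 2L + 4L + length(iiv_idx) + 1L)
  colnames(trace) <- c("iter", "loglik", paste0("mu_", pnames),
                       paste0("omega2_", pnames[iiv_idx]), "b")

  prior_ll <- function(ph) {
    -0.5 * sweep(sweep(ph, 2L, mu)^2, 2L, omega2, "/")
  }

  for (k in seq_len(K1 + K2)) {
    gamma <- if (k <= K1) 1 else 1 / (k - K1)

    for (c in seq_len(nc)) {
      ph <- phi[[c]]; llc <- ll[[c]]
      # kernel 1: independence proposal from the current population prior
      prop <- matrix(mu, n, 4L, byrow = TRUE) +
        sweep(matrix(stats::rnorm(n * 4L), n, 4L), 2L, sqrt(omega2), `*`)
      llp <- obj$loglik(prop, b)
      acc <- log(stats::runif(n)) < (llp - llc)
      ph[acc, ] <- prop[acc, , drop = FALSE]
      llc[acc] <- llp[acc]
      # kernel 2: component-wise random walks
      for (p in seq_len(4L)) {
        prop <- ph
        prop[, p] <- ph[, p] + rw_step[p] * sqrt(omega2[p]) * stats::rnorm(n)
        llp <- obj$loglik(prop, b)
        dprior <- -((prop[, p] - mu[p])^2 - (ph[, p] - mu[p])^2) / (2 * omega2[p])
        acc <- log(stats::runif(n)) < (llp - llc + dprior)
        ph[acc, p] <- prop[acc, p]
        llc[acc] <- llp[acc]
        if (k <= K1 && c == 1L) {
          rate <- mean(acc)
          rw_step[p] <- rw_step[p] *
            exp(min(0.5, 2 / sqrt(k)) * (rate - settings$target_accept))
          rw_step[p] <- min(max(rw_step[p], 0.01), 20)
        }
      }
      phi[[c]] <- ph; ll[[c]] <- llc
    }

    # sufficient statistics averaged over chains
    S1 <- Reduce(`+`, lapply(phi, colSums)) / nc
    S2 <- Reduce(`+`, lapply(phi, function(ph) colSums(ph^2))) / nc
    rs <- Reduce(`+`, lapply(phi, function(ph) obj$resid_stat(ph, b))) / nc
    if (!have_stats) {
      s1 <- S1; s2 <- S2; s3 <- rs[1]; s3n <- rs[2]; have_stats <- TRUE
    } else {
      s1 <- s1 + gamma * (S1 - s1)
      s2 <- s2 + gamma * (S2 - s2)
      s3 <- s3 + gamma * (rs[1] - s3)
      s3n <- s3n + gamma * (rs[2] - s3n)
    }

    # M-step
    mu <- s1 / n
    om_new <- pmax(s2 / n - mu^2, settings$omega_floor)
    if (k <= K1) {  # bound the shrink rate during annealing
      om_new <- pmax(om_new, settings$anneal * omega2)
    }
    omega2[iiv_idx] <- om_new[iiv_idx]
    omega2[fix_idx] <- pmax(0.1 * fix_rho^min(k, K1), .FIX_OMEGA)
    b_new <- sqrt(max(s3 / max(s3n, 1), 1e-10))
    b <- if (k <= K1) max(b_new, settings$anneal * b) else b_new

    cur_ll <- mean(vapply(ll, sum, numeric(1)))
    trace[k, ] <- c(k, cur_ll, mu, omega2[iiv_idx], b)

    # Fisher information accumulation during smoothing
    if (k > K1) {
      gH <- .louis_terms(phi, mu, omega2, b, iiv_idx, obj, n)
      D_acc <- D_acc + gamma * (gH$g - D_acc)
      G_acc <- G_acc + gamma * (gH$G - G_acc)
    }
  }

  FIM <- G_acc - tcrossprod(D_acc)
  se_psi <- rep(NA_real_, npsi)
  fim_ok <- FALSE
  ev <- try(solve(FIM), silent = TRUE)
  if (!inherits(ev, "try-error") && all(diag(ev) > 0)) {
    se_psi <- sqrt(diag(ev))
    fim_ok <- TRUE
  }

  theta <- exp(mu)
  names(theta) <- pnames
  se_theta <- theta * se_psi[1:4]
  se_omega2 <- stats::setNames(se_psi[4L + seq_along(iiv_idx)], pnames[iiv_idx])
  se_b <- se_psi[npsi]

  n_obs_total <- sum(vapply(subjects, function(s) length(s$dv), numeric(1)))
  # stabilization check: the per-iteration log-likelihood at the current
  # MCMC draws carries sampling noise, so look for a residual linear drift
  # over the final smoothing stretch rather than the raw range; scale by
  # the larger of |mean ll| and the observation count so the criterion
  # reads as a relative change even when the total ll sits near zero
  win <- min(K2, 50)
  ll_tail <- trace[(K1 + K2 - win + 1):(K1 + K2), "loglik"]
  slope <- stats::cov(seq_len(win), ll_tail) / stats::var(seq_len(win))
  ll_drift <- abs(slope) * win / max(abs(mean(ll_tail)), n_obs_total)
  converged <- is.finite(ll_drift) && ll_drift < settings$ll_tol * 10
  if (!converged) {
    warning("saem_fit: log-likelihood trace has not stabilized ",
            sprintf("(relative drift %.3g over the final smoothing stretch)",
                    ll_drift), call. = FALSE)
  }
  floor_hit <- pnames[iiv_idx][omega2[iiv_idx] <= settings$omega_floor * 1.01]
  if (length(floor_hit)) {
    message("saem_fit: omega^2 at the variance floor for: ",
            paste(floor_hit, collapse = ", "))
  }

  phi_mean <- Reduce(`+`, phi) / nc
  est_omega2 <- omega2[iiv_idx]
  structure(list(
    typical = pk_params(theta["V"], theta["CL"], theta["Ka"], theta["Tlag"]),
    mu = stats::setNames(mu, pnames),
    omega2 = stats::setNames(est_omega2, pnames[iiv_idx]),
    b = b,
    se = list(theta = stats::setNames(se_theta, pnames), omega2 = se_omega2,
              b = se_b),
    rse_pct = list(
      theta = stats::setNames(100 * se_theta / theta, pnames),
      omega2 = 100 * se_omega2 / est_omega2,
      b = 100 * se_b / b
    ),
    cv_pct_report = 100 * sqrt(est_omega2),  # CV = sqrt(omega^2) convention
    trace = as.data.frame(trace),
    converged = converged,
    fim_ok = fim_ok,
    iiv_params = pnames[iiv_idx],
    phi_mean = phi_mean,
    subject_ids = vapply(subjects, function(s) s$id, numeric(1)),
    n_subjects = n,
    n_obs = n_obs_total,
    settings = settings
  ), class = "population_estimate")
}

# Louis-principle terms: complete-data score g and (-hessian + g g^T)
# contribution G for psi = (mu[1:4], omega2[iiv], b), averaged over chains.
.louis_terms <- function(phi, mu, omega2, b, iiv_idx, obj, n) {
  npsi <- 4L + length(iiv_idx) + 1L
  g_sum <- numeric(npsi)
  G_sum <- matrix(0, npsi, npsi)
  nc <- length(phi)
  for (c in seq_len(nc)) {
    ph <- phi[[c]]
    dev <- sweep(ph, 2L, mu)
    g <- numeric(npsi)
    H <- matrix(0, npsi, npsi)  # negative hessian
    g[1:4] <- colSums(dev) / omega2
    for (p in 1:4) H[p, p] <- n / omega2[p]
    for (j in seq_along(iiv_idx)) {
      p <- iiv_idx[j]
      col <- 4L + j
      g[col] <- sum(-1 / (2 * omega2[p]) + dev[, p]^2 / (2 * omega2[p]^2))
      H[col, col] <- -n / (2 * omega2[p]^2) + sum(dev[, p]^2) / omega2[p]^3
      H[p, col] <- H[col, p] <- sum(dev[, p]) / omega2[p]^2
    }
    rs <- obj$resid_stat(ph, b)
    g[npsi] <- -rs[2] / b + rs[1] / b^3
    H[npsi, npsi] <- -rs[2] / b^2 + 3 * rs[1] / b^4
    g_sum <- g_sum + g
    G_sum <- G_sum + H + tcrossprod(g)
  }
  list(g = g_sum / nc, G = G_sum / nc)
}

#' @export
print.population_estimate <- function(x, ...) {
  cat(sprintf("Population PK estimate (SAEM, %d subjects, %d observations)\n",
              x$n_subjects, x$n_obs))
  tab <- estimate_table(x)
  print(tab, row.names = FALSE, digits = 4)
  cat(sprintf("Converged: %s; FIM invertible: %s\n",
              x$converged, x$fim_ok))
  invisible(x)
}

#' Estimate table in the standard report layout
#'
#' One row per parameter with columns estimate, SE, RSE% and, for parameters
#' carrying interindividual variability, the CV% under the CV =
#' sqrt(omega^2) reporting convention.
#'
#' @param fit A `population_estimate` from [saem_fit].
#' @return A data.frame.
#' @export
estimate_table <- function(fit) {
  stopifnot(inherits(fit, "population_estimate"))
  th <- unlist(fit$typical)
  pnames <- names(th)
  cvs <- stats::setNames(rep(NA_real_, 4L), pnames)
  cvs[fit$iiv_params] <- fit$cv_pct_report
  top <- data.frame(
    parameter = pnames,
    estimate = unname(th),
    se = unname(fit$se$theta[pnames]),
    rse_pct = unname(fit$rse_pct$theta[pnames]),
    cv_pct = unname(cvs)
  )
  om <- data.frame(
    parameter = paste0("omega2_", fit$iiv_params),
    estimate = unname(fit$omega2),
    se = unname(fit$se$omega2),
    rse_pct = unname(fit$rse_pct$omega2),
    cv_pct = NA_real_
  )
  res <- data.frame(parameter = "prop_error_b", estimate = fit$b,
                    se = fit$se$b, rse_pct = fit$rse_pct$b, cv_pct = NA_real_)
  rbind(top, om, res)
}

#' Convert a population estimate to a simulatable population model
#'
#' Inverts the exact lognormal CV relation (CV = sqrt(exp(omega^2) - 1)) so
#' that simulating from the returned model reproduces the estimated
#' log-scale variances exactly.
#'
#' @param fit A `population_estimate`.
#' @return A [population_model].
#' @export
as_population_model <- function(fit) {
  stopifnot(inherits(fit, "population_estimate"))
  cv <- sqrt(exp(fit$omega2) - 1)
  population_model(
    typical = fit$typical,
    iiv_cv = stats::setNames(cv, fit$iiv_params),
    residual = residual_error_model(fit$b),
    cv_convention = "exact"
  )
}

#' Empirical Bayes individual parameter estimates
#'
#' Per-subject posterior modes of the log-parameters given the population
#' estimates (MAP / empirical Bayes), together with individual and
#' population predicted concentrations at the observation times.
#'
#' @param fit A `population_estimate` from [saem_fit].
#' @param dataset The dataset the fit was computed from.
#' @return A list with `parameters` (data.frame ID, V, CL, Ka, Tlag) and
#'   `predictions` (data.frame ID, TIME, DV, PRED, IPRED).
#' @export
individual_estimates <- function(fit, dataset) {
  stopifnot(inherits(fit, "population_estimate"))
  subjects <- split_subjects(dataset)
  mu <- fit$mu
  omega2 <- stats::setNames(rep(.FIX_OMEGA, 4L), names(mu))
  omega2[fit$iiv_params] <- fit$omega2
  b <- fit$b
  par_rows <- vector("list", length(subjects))
  pred_rows <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    neg_post <- function(phi) {
      p <- exp(phi)
      f <- conc_regimen(pk_params(p[1], p[2], p[3], p[4]), s$regimen, s$times)
      sd <- sqrt(.SD_FLOOR^2 + (b * f)^2)
      -(sum(stats::dnorm(s$dv, f, sd, log = TRUE)) -
          sum((phi - mu)^2 / (2 * omega2)))
    }
    start <- if (!is.null(fit$phi_mean) && i <= nrow(fit$phi_mean)) {
      fit$phi_mean[i, ]
    } else mu
    op <- stats::optim(start, neg_post, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-10))
    ph <- op$par
    theta_i <- exp(ph)
    par_rows[[i]] <- data.frame(ID = s$id, V = theta_i[1], CL = theta_i[2],
                                Ka = theta_i[3], Tlag = theta_i[4])
    p_i <- pk_params(theta_i[1], theta_i[2], theta_i[3], theta_i[4])
    pred_rows[[i]] <- data.frame(
      ID = s$id, TIME = s$times, DV = s$dv,
      PRED = conc_regimen(fit$typical, s$regimen, s$times),
      IPRED = conc_regimen(p_i, s$regimen, s$times)
    )
  }
  list(parameters = do.call(rbind, par_rows),
       predictions = do.call(rbind, pred_rows))
}

#' Goodness-of-fit tables
#'
#' Paired (observed, population-predicted) and (observed,
#' individual-predicted) tables for identity-line diagnostic plots, plus
#' proportional residuals (DV - IPRED)/IPRED against the individual
#' predictions for predictions above the reporting floor. Individual-level
#' residuals are used for the misfit checks because under lognormal
#' interindividual variability the residuals against the typical prediction
#' are right-skewed even when the model is correct.
#'
#' @inheritParams individual_estimates
#' @param indiv Optional precomputed [individual_estimates] result, to avoid
#'   recomputing the per-subject optimizations.
#' @return A list with `population`, `individual` and `residuals`
#'   data.frames.
#' @export
goodness_of_fit <- function(fit, dataset, indiv = NULL) {
  if (is.null(indiv)) indiv <- individual_estimates(fit, dataset)
  pr <- indiv$predictions
  ok <- pr$IPRED > .F_MIN
  list(
    population = data.frame(ID = pr$ID, TIME = pr$TIME, observed = pr$DV,
                            predicted = pr$PRED),
    individual = data.frame(ID = pr$ID, TIME = pr$TIME, observed = pr$DV,
                            predicted = pr$IPRED),
    residuals = data.frame(ID = pr$ID[ok], TIME = pr$TIME[ok],
                           prop_residual = (pr$DV[ok] - pr$IPRED[ok]) / pr$IPRED[ok])
  )
}
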