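#' One-compartment oral pharmacokinetic parameters
#'
#' Constructs a validated set of apparent one-compartment parameters for a
#' single subject or a population typical value. Because metoprolol data are
#' oral, bioavailability F is not identifiable and all parameters are
#' apparent (V/F, CL/F) with F fixed at 1.
#'
#' @param V Apparent volume of distribution (L).
#' @param CL Apparent clearance (L/h).
#' @param Ka First-order absorption rate constant (1/h).
#' @param Tlag Absorption lag time (h). May be 0.
#'
#' @return An object of class `pk_params`: a named list with elements
#'   `V`, `CL`, `Ka`, `Tlag`.
#'
#' @examples
#' p <- pk_params(V = 34.9, CL = 101, Ka = 0.161, Tlag = 0.38)
#' elimination_rate(p)
#' @export
pk_params <- function(V, CL, Ka, Tlag = 0) {
  for (nm in c("V", "CL", "Ka", "Tlag")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop("pk_params: '", nm, "' must be a single finite number", call. = FALSE)
    }
  }
  if (V <= 0) stop("pk_params: V must be strictly positive", call. = FALSE)
  if (CL <= 0) stop("pk_params: CL must be strictly positive", call. = FALSE)
  if (Ka <= 0) stop("pk_params: Ka must be strictly positive", call. = FALSE)
  if (Tlag < 0) stop("pk_params: Tlag must be non-negative", call. = FALSE)
  structure(list(V = unname(V), CL = unname(CL), Ka = unname(Ka),
                 Tlag = unname(Tlag)), class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat("One-compartment oral PK parameters (apparent, F = 1)\n")
  cat(sprintf("  V    %8.3g L\n  CL   %8.3g L/h\n  Ka   %8.3g 1/h\n  Tlag %8.3g h\n",
              x$V, x$CL, x$Ka, x$Tlag))
  cat(sprintf("  ke = CL/V = %.4g 1/h%s\n", elimination_rate(x),
              if (x$Ka < elimination_rate(x)) "  (flip-flop: Ka < ke)" else ""))
  invisible(x)
}

#' @export
as.list.pk_params <- function(x, ...) unclass(x)

is_pk_params <- function(x) inherits(x, "pk_params")

#' Elimination rate constant
#'
#' @param params A [pk_params] object.
#' @return ke = CL/V in 1/h.
#' @export
elimination_rate <- function(params) {
  stopifnot(is_pk_params(params))
  params$CL / params$V
}

#' Oral dosing regimen
#'
#' A sequence of oral dose events (amount, time). Dose amounts are in mg and
#' times in h; times must be non-decreasing.
#'
#' @param amt Numeric vector of dose amounts (mg), all positive.
#' @param time Numeric vector of dose times (h), non-negative, non-decreasing.
#'   Recycled against `amt` if length 1.
#'
#' @return A `dosing_regimen`: a data.frame with columns `amt` and `time`.
#'
#' @examples
#' dosing_regimen(100, 0)                       # single 100 mg dose
#' dosing_regimen(100, seq(0, 96, by = 12))     # nine 100 mg doses q12h
#' @export
dosing_regimen <- function(amt, time) {
  n <- max(length(amt), length(time))
  amt <- rep_len(as.numeric(amt), n)
  time <- rep_len(as.numeric(time), n)
  if (any(!is.finite(amt)) || any(amt <= 0)) {
    stop("dosing_regimen: dose amounts must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(time)) || any(time < 0)) {
    stop("dosing_regimen: dose times must be non-negative and finite", call. = FALSE)
  }
  if (is.unsorted(time)) {
    stop("dosing_regimen: dose times must be non-decreasing", call. = FALSE)
  }
  structure(data.frame(amt = amt, time = time),
            class = c("dosing_regimen", "data.frame"))
}

is_dosing_regimen <- function(x) inherits(x, "dosing_regimen")

#' @export
print.dosing_regimen <- function(x, ...) {
  cat(sprintf("Oral dosing regimen: %d dose(s), total %g mg\n", nrow(x), sum(x$amt)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
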