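# Enzyme characterisation math used to rank mutants: Michaelis-Menten
# kinetics by nonlinear least squares, first-order thermal inactivation and
# half-life, activity-profile normalisation, fold/percent comparisons, and
# fibrin-plate calibration against a urokinase standard curve.

#' Fit Michaelis-Menten kinetics
#'
#' Nonlinear least-squares fit of `v = Vmax * S / (Km + S)` (Levenberg-
#' Marquardt via [minpack.lm::nlsLM()]). When the enzyme concentration is
#' supplied, `kcat = Vmax / enzyme_conc` and the catalytic efficiency
#' `kcat / Km` are reported as well.
#'
#' @param substrate Substrate concentrations (same unit as the reported Km,
#'   e.g. umol/L); at least 4 distinct levels.
#' @param rate Initial rates (>= 0), one per substrate level.
#' @param enzyme_conc Optional enzyme concentration used to convert Vmax to
#'   kcat (rate unit / concentration unit -> 1/s when the units agree).
#' @return Object of class `kinetics_result`: list with `Km`, `Vmax`,
#'   `kcat`, `efficiency`, `se` (named standard errors) and the `fit`.
#' @export
fit_michaelis_menten <- function(substrate, rate, enzyme_conc = NULL) {
  stopifnot(length(substrate) == length(rate))
  if (length(unique(substrate)) < 4L) {
    stop_msc("need >= 4 distinct substrate levels", class = "msc_value_error")
  }
  if (any(rate < 0) || any(substrate <= 0)) {
    stop_msc("substrate must be > 0 and rates >= 0", class = "msc_value_error")
  }
  vmax0 <- max(rate)
  km0 <- substrate[which.min(abs(rate - vmax0 / 2))]
  if (km0 <= 0) km0 <- stats::median(substrate)
  dat <- data.frame(S = substrate, v = rate)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ Vmax * S / (Km + S), data = dat,
                      start = list(Vmax = vmax0, Km = km0),
                      lower = c(Vmax = 1e-12, Km = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop_msc("Michaelis-Menten fit failed (%s); initial guesses Vmax=%g, Km=%g",
               conditionMessage(e), vmax0, km0, class = "msc_fit_error")
    }
  )
  co <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(Vmax = NA_real_, Km = NA_real_))
  kcat <- if (!is.null(enzyme_conc)) unname(co["Vmax"]) / enzyme_conc else NA_real_
  structure(
    list(Km = unname(co["Km"]), Vmax = unname(co["Vmax"]),
         kcat = kcat,
         efficiency = if (is.na(kcat)) NA_real_ else kcat / unname(co["Km"]),
         se = c(Vmax = unname(se["Vmax"]), Km = unname(se["Km"])),
         fit = fit),
    class = "kinetics_result"
  )
}

#' Fit first-order thermal inactivation
#'
#' Fits `A(t) = A0 * exp(-k t)` to residual-activity measurements and
#' reports the decay constant and the half-life `ln(2) / k`.
#'
#' @param times Incubation times, min (>= 3 points).
#' @param activity Residual activities, % of the untreated enzyme, in
#'   `(0, 100]` (small overshoots above 100 from noise are tolerated).
#' @return Object of class `inactivation_fit`: list with `k_inact` (1/min),
#'   `half_life` (min), `A0` (%), `se` and the `fit`.
#' @export
fit_first_order_decay <- function(times, activity) {
  stopifnot(length(times) == length(activity))
  if (length(times) < 3L) {
    stop_msc("need >= 3 time points", class = "msc_value_error")
  }
  if (any(activity <= 0)) {
    stop_msc("activities must be > 0 (%% of untreated)", class = "msc_value_error")
  }
  # log-linear start values; also the quickest no-decay check
  lmfit <- stats::lm(log(activity) ~ times)
  k0 <- -unname(stats::coef(lmfit)[2])
  if (k0 <= 0) {
    stop_msc("activities do not decay with time (estimated k = %g <= 0)", k0,
             class = "msc_no_decay_error")
  }
  dat <- data.frame(t = times, A = activity)
  fit <- tryCatch(
    minpack.lm::nlsLM(A ~ A0 * exp(-k * t), data = dat,
                      start = list(A0 = exp(unname(stats::coef(lmfit)[1])), k = k0),
                      lower = c(A0 = 1e-12, k = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop_msc("decay fit failed (%s)", conditionMessage(e), class = "msc_fit_error")
    }
  )
  co <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(A0 = NA_real_, k = NA_real_))
  structure(
    list(k_inact = unname(co["k"]),
         half_life = log(2) / unname(co["k"]),
         A0 = unname(co["A0"]),
         se = c(A0 = unname(se["A0"]), k = unname(se["k"])),
         fit = fit),
    class = "inactivation_fit"
  )
}

#' Fold change and percent change of a mutant value over a reference
#'
#' `fold = mutant / reference`; `percent = 100 (mutant - reference) /
#' reference`. Reported values are conventionally rounded to one decimal
#' (see `print`); the returned numbers are exact.
#'
#' @param reference Reference (wild-type) value, > 0.
#' @param mutant Mutant value.
#' @return List with `fold` and `percent_change` (class `fold_change`).
#' @export
fold_and_percent <- function(reference, mutant) {
  if (!is.numeric(reference) || any(reference <= 0)) {
    stop_msc("reference must be > 0", class = "msc_value_error")
  }
  structure(list(fold = mutant / reference,
                 percent_change = 100 * (mutant - reference) / reference),
            class = "fold_change")
}

#' @export
print.fold_change <- function(x, ...) {
  cat(sprintf("%.1f-fold (%+.1f%%)\n", x$fold, x$percent_change))
  invisible(x)
}

#' Normalise an activity profile to percent of maximum
#'
#' The highest activity is defined as 100%.
#'
#' @param labels Condition labels (temperature, pH, ...).
#' @param activities Measured activities (max must be > 0).
#' @return Data frame with `label`, `activity`, `percent`.
#' @export
normalize_profile <- function(labels, activities) {
  stopifnot(length(labels) == length(activities))
  m <- max(activities)
  if (!is.finite(m) || m <= 0) {
    stop_msc("profile maximum must be > 0", class = "msc_value_error")
  }
  data.frame(label = labels, activity = activities,
             percent = 100 * activities / m)
}

#' Calibrate a fibrin-plate assay against activity standards
#'
#' Radial-diffusion convention: `log10(activity)` is linear in the
#' clear-zone area. Fitted by ordinary least squares over the standards.
#'
#' @param activity Standard activities (U/ml), > 0.
#' @param area Clear-zone areas (mm^2); at least 2 distinct values.
#' @return Object of class `plate_calibration`: list with `intercept`,
#'   `slope`, `standards` and the `fit`.
#' @export
calibrate_plate <- function(activity, area) {
  stopifnot(length(activity) == length(area))
  if (length(unique(area)) < 2L) {
    stop_msc("need >= 2 standards with distinct zone areas (rank-deficient line)",
             class = "msc_rank_deficiency_error")
  }
  if (any(activity <= 0)) {
    stop_msc("standard activities must be > 0", class = "msc_value_error")
  }
  fit <- stats::lm(log10(activity) ~ area,
                   data = data.frame(activity = activity, area = area))
  co <- stats::coef(fit)
  structure(
    list(intercept = unname(co[1]), slope = unname(co[2]),
         standards = data.frame(activity = activity, area = area),
         fit = fit),
    class = "plate_calibration"
  )
}

#' Convert a clear-zone area to an activity via a plate calibration
#'
#' @param calibration `plate_calibration`.
#' @param area Zone area(s), mm^2.
#' @return Activity in U/ml.
#' @export
zone_to_activity <- function(calibration, area) {
  stopifnot(inherits(calibration, "plate_calibration"))
  10^(calibration$intercept + calibration$slope * area)
}

#' Published characterisation parameters of rAprY and its position-216 mutants
#'
#' Reference parameter sets for the wild-type nattokinase rAprY and the
#' A216E/A216K/A216R mutants: Michaelis constant Km (umol/L), turnover
#' number kcat (1/s) and thermal-inactivation half-life at 55 degrees C
#' (min). Used as ground truth by the synthetic kinetics generator and for
#' fold/percent comparisons.
#'
#' @return Data frame with columns `variant`, `Km`, `kcat`, `half_life`.
#' @export
kinetics_presets <- function() {
  data.frame(
    variant   = c("rAprY", "A216E", "A216K", "A216R"),
    Km        = c(1.52, 2.44, 1.29, 2.27),
    kcat      = c(7.10, 9.21, 5.53, 20.38),
    half_life = c(9.80, 54.30, 55.93, 35.36),
    stringsAsFactors = FALSE
  )
}

#' @export
print.kinetics_result <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit: Km = %.4g (SE %.2g), Vmax = %.4g (SE %.2g)\n",
              x$Km, x$se["Km"], x$Vmax, x$se["Vmax"]))
  if (!is.na(x$kcat)) {
    cat(sprintf("  kcat = %.4g 1/s, kcat/Km = %.4g\n", x$kcat, x$efficiency))
  }
  invisible(x)
}

#' @export
print.inactivation_fit <- function(x, ...) {
  cat(sprintf("First-order inactivation: k = %.4g 1/min, half-life = %.4g min (A0 = %.1f%%)\n",
              x$k_inact, x$half_life, x$A0))
  invisible(x)
}
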