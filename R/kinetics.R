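#' Initial velocity from a progress curve
#'
#' The fluorogenic phosphatase assay follows product accumulation over
#' minutes; the initial velocity at one substrate concentration is the
#' least-squares slope of signal versus time inside a window chosen to skip
#' mixing artefacts (default 2-10 min). If the curve is in raw fluorescence
#' units, a linear `calibration` factor (concentration units per signal
#' unit) converts the slope to uM/min; without it the velocity is returned
#' in signal units per minute and tagged uncalibrated.
#'
#' @param time_min numeric vector, minutes, strictly increasing.
#' @param signal numeric vector, fluorescence or product concentration.
#' @param window length-2 numeric, inclusive time window in minutes.
#' @param calibration optional linear factor (uM per signal unit).
#' @return list: `v0` (slope, uM/min if calibrated), `n_points`,
#'   `calibrated`, `intercept`.
#' @export
initial_velocity <- function(time_min, signal, window = c(2, 10),
                             calibration = NULL) {
  if (length(time_min) != length(signal)) stop("time and signal lengths differ")
  if (any(diff(time_min) <= 0)) stop("time points must be strictly increasing")
  if (any(!is.finite(signal))) stop("signal must be finite")
  keep <- time_min >= window[1L] & time_min <= window[2L]
  if (sum(keep) < 2L)
    stop("fewer than 2 points inside the window [", window[1L], ", ", window[2L], "] min")
  fit <- stats::lm(signal[keep] ~ time_min[keep])
  slope <- unname(stats::coef(fit)[2L])
  calibrated <- !is.null(calibration)
  if (calibrated) slope <- slope * calibration
  list(v0 = slope, n_points = sum(keep), calibrated = calibrated,
       intercept = unname(stats::coef(fit)[1L]))
}

#' Initial velocities for a tidy progress-curve table
#'
#' @param curves data frame with columns `time_min`, `signal`,
#'   `substrate_uM`, and optionally `replicate`.
#' @inheritParams initial_velocity
#' @return data frame: `substrate_uM`, `replicate`, `v0`.
#' @export
initial_velocities <- function(curves, window = c(2, 10), calibration = NULL) {
  req <- c("time_min", "signal", "substrate_uM")
  if (!all(req %in% names(curves)))
    stop("curve table needs columns: ", paste(req, collapse = ", "))
  if (!"replicate" %in% names(curves)) curves$replicate <- 1L
  groups <- unique(curves[, c("substrate_uM", "replicate")])
  groups$v0 <- vapply(seq_len(nrow(groups)), function(i) {
    g <- curves[curves$substrate_uM == groups$substrate_uM[i] &
                  curves$replicate == groups$replicate[i], , drop = FALSE]
    g <- g[order(g$time_min), ]
    initial_velocity(g$time_min, g$signal, window = window,
                     calibration = calibration)$v0
  }, numeric(1))
  rownames(groups) <- NULL
  groups
}

#' Michaelis-Menten fit of initial velocities
#'
#' Fits v = Vmax * S / (KM + S) to (substrate, velocity) points. The
#' reaction scheme is hyperbolic saturation (equivalently a Hill equation
#' with coefficient fixed at 1). Two estimators are provided: `"nonlinear"`
#' least squares (Levenberg-Marquardt; start values Vmax0 = max v, KM0 = S
#' at half-max by interpolation) and the classical `"lineweaver-burk"`
#' double-reciprocal line (unweighted 1/v vs 1/S; slope = KM/Vmax,
#' intercept = 1/Vmax). kcat is derived from Vmax and the enzyme
#' concentration with explicit unit conversion: Vmax [uM/min] / [E] [uM]
#' / 60 gives kcat in 1/s; KM is reported in mM, so kcat/KM is in
#' 1/(s mM).
#'
#' @param substrate_uM substrate concentrations, uM.
#' @param v0 initial velocities, uM/min (or signal/min if uncalibrated).
#' @param enzyme_nM total enzyme concentration, nM.
#' @param method `"nonlinear"` or `"lineweaver-burk"`.
#' @param calibrated whether `v0` is in concentration units; if FALSE the
#'   kcat fields are tagged uncalibrated.
#' @return object of class `mm_fit`: `vmax` (uM/min), `km_mM`, `kcat_s`
#'   (1/s), `kcat_over_km` (1/(s mM)), `se` (named numeric, Vmax/KM
#'   standard errors), `method`, `rss`, `fitted`, `calibrated`.
#' @export
fit_mm <- function(substrate_uM, v0, enzyme_nM, method = c("nonlinear", "lineweaver-burk"),
                   calibrated = TRUE) {
  method <- match.arg(method)
  if (is.data.frame(substrate_uM)) {
    v0 <- substrate_uM$v0; substrate_uM <- substrate_uM$substrate_uM
  }
  S <- as.numeric(substrate_uM)
  if (length(unique(S)) < 3L) stop("need at least 3 distinct substrate concentrations")
  if (length(S) != length(v0)) stop("substrate and velocity lengths differ")
  dat <- data.frame(S = S, v = as.numeric(v0))
  if (method == "nonlinear") {
    vmax0 <- max(dat$v)
    half <- vmax0 / 2
    ord <- order(dat$S)
    km0 <- tryCatch(stats::approx(dat$v[ord], dat$S[ord], xout = half,
                                  ties = mean)$y, error = function(e) NA_real_)
    if (!is.finite(km0) || km0 <= 0) km0 <- stats::median(dat$S)
    fit <- minpack.lm::nlsLM(v ~ Vmax * S / (Km + S), data = dat,
                             start = list(Vmax = vmax0, Km = km0),
                             control = minpack.lm::nls.lm.control(
                               ftol = 1e-12, ptol = 1e-12, maxiter = 200))
    cf <- stats::coef(fit)
    vmax <- unname(cf["Vmax"]); km_uM <- unname(cf["Km"])
    se <- summary(fit)$coefficients[, "Std. Error"]
    se <- c(vmax = unname(se["Vmax"]), km_uM = unname(se["Km"]))
    fitted_v <- stats::fitted(fit)
  } else {
    if (any(dat$v <= 0)) stop("double-reciprocal fit requires positive velocities")
    lb <- stats::lm(I(1 / v) ~ I(1 / S), data = dat)
    cf <- stats::coef(lb)
    vmax <- 1 / unname(cf[1L])
    km_uM <- unname(cf[2L]) * vmax
    ## summary() warns on numerically exact data; the SEs are still valid
    sm <- suppressWarnings(summary(lb))$coefficients[, "Std. Error"]
    ## delta-method propagation from (intercept, slope)
    se <- c(vmax = vmax^2 * unname(sm[1L]),
            km_uM = sqrt((vmax * unname(sm[2L]))^2 +
                           (unname(cf[2L]) * vmax^2 * unname(sm[1L]))^2))
    fitted_v <- vmax * dat$S / (km_uM + dat$S)
  }
  if (km_uM <= 0) stop("fitted KM is non-positive; data do not support a saturation fit")
  enzyme_uM <- enzyme_nM / 1000
  kcat_s <- vmax / enzyme_uM / 60
  km_mM <- km_uM / 1000
  out <- list(vmax = vmax, km_mM = km_mM, kcat_s = kcat_s,
              kcat_over_km = kcat_s / km_mM,
              se = c(vmax = unname(se["vmax"]), km_mM = unname(se["km_uM"]) / 1000),
              method = method, rss = sum((dat$v - fitted_v)^2),
              n = nrow(dat), enzyme_nM = enzyme_nM, calibrated = calibrated,
              data = dat, fitted = fitted_v)
  class(out) <- "mm_fit"
  out
}

#' @export
print.mm_fit <- function(x, ...) {
  unit <- if (x$calibrated) "" else " (uncalibrated signal units)"
  cat(sprintf("<mm_fit:%s> Vmax = %.4g uM/min%s, KM = %.4g mM, kcat = %.4g 1/s, kcat/KM = %.4g 1/(s mM)\n",
              x$method, x$vmax, unit, x$km_mM, x$kcat_s, x$kcat_over_km))
  invisible(x)
}

#' Catalytic-efficiency ratio of two fits
#'
#' @param fit_a,fit_b `mm_fit` objects (or lists with `kcat_over_km`).
#' @return (kcat/KM)_a / (kcat/KM)_b, dimensionless.
#' @export
efficiency_ratio <- function(fit_a, fit_b) {
  if (!is.finite(fit_b$kcat_over_km) || fit_b$kcat_over_km == 0)
    stop("denominator efficiency is zero or non-finite")
  fit_a$kcat_over_km / fit_b$kcat_over_km
}

#' Diagnostic Hill fit with free coefficient
#'
#' Companion to [fit_mm()]: fits v = Vmax * S^h / (K^h + S^h) with the Hill
#' coefficient free, as a check that the saturation data carry no
#' cooperativity (h should come back near 1 for a single-site phosphatase).
#'
#' @inheritParams fit_mm
#' @return list: `vmax`, `k_uM`, `hill`, `rss`.
#' @export
fit_hill <- function(substrate_uM, v0, enzyme_nM = NA) {
  dat <- data.frame(S = as.numeric(substrate_uM), v = as.numeric(v0))
  vmax0 <- max(dat$v); km0 <- stats::median(dat$S)
  fit <- minpack.lm::nlsLM(v ~ Vmax * S^h / (K^h + S^h), data = dat,
                           start = list(Vmax = vmax0, K = km0, h = 1),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  list(vmax = unname(cf["Vmax"]), k_uM = unname(cf["K"]), hill = unname(cf["h"]),
       rss = sum(stats::residuals(fit)^2))
}
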