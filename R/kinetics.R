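#' Initial rate from a coupled-assay absorbance trace
#'
#' The NADH-coupled assay reports ADP production as A340 decay. The most
#' linear contiguous window (highest R^2 of a straight-line fit, default
#' 60% of the points) is selected, and its slope is converted to a
#' substrate turnover rate via Beer-Lambert:
#' `rate [uM/s] = |slope| / (epsilon * path) * 1e6`.
#'
#' @param time seconds
#' @param a340 absorbance at 340 nm
#' @param epsilon NADH molar extinction coefficient, 1/(M cm); 6220 is the
#'   standard 340 nm value
#' @param path cuvette path length, cm
#' @param window_fraction fraction of points in the fitted window
#' @param reference optional blank trace (same grid), subtracted pointwise
#'   before windowing
#' @return list: `rate` (uM/s), `slope` (absorbance/s), `r_squared`,
#'   `window` (index range), `low_confidence` (TRUE when R^2 < 0.9)
#' @export
rate_from_trace <- function(time, a340, epsilon = 6220, path = 1,
                            window_fraction = 0.6, reference = NULL) {
  if (length(time) < 10) stop("need at least 10 trace points")
  if (any(!is.finite(a340))) stop("non-finite absorbance values")
  if (!is.null(reference)) {
    if (length(reference) != length(a340))
      stop("reference trace length differs")
    a340 <- a340 - reference
  }
  n <- length(time)
  w <- max(2L, ceiling(window_fraction * n))
  best <- list(r2 = -Inf)
  for (s in 1:(n - w + 1)) {
    idx <- s:(s + w - 1)
    ft <- stats::lm.fit(cbind(1, time[idx]), a340[idx])
    ss_res <- sum(ft$residuals^2)
    ss_tot <- sum((a340[idx] - mean(a340[idx]))^2)
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1  # flat trace: perfect line
    if (r2 > best$r2)
      best <- list(r2 = r2, slope = ft$coefficients[2], window = c(s, s + w - 1))
  }
  list(rate = abs(unname(best$slope)) / (epsilon * path) * 1e6,
       slope = unname(best$slope), r_squared = best$r2,
       window = best$window, low_confidence = best$r2 < 0.9)
}

#' Michaelis-Menten fit
#'
#' Nonlinear least squares of `v = Vmax [S] / (Km + [S])`, initialised
#' from a Hanes-Woolf linearisation and refined with Levenberg-Marquardt
#' (`minpack.lm::nlsLM`). `kcat = Vmax / enzyme_conc`.
#'
#' @param substrate substrate concentrations, uM (>= 5 levels recommended)
#' @param rate initial velocities, uM/s
#' @param enzyme_conc enzyme concentration, uM
#' @param weights optional per-point weights for the residuals (e.g.
#'   `1/rate^2`); default unweighted
#' @return `mm_fit` object: `Km` (uM), `Vmax` (uM/s), `kcat` (1/s),
#'   `efficiency` (kcat/Km, 1/(uM s)), `se` (standard errors for Km and
#'   Vmax), `fit` (the nls object)
#' @export
mm_fit <- function(substrate, rate, enzyme_conc = 1, weights = NULL) {
  if (length(substrate) < 5)
    warning("fewer than 5 substrate levels: parameters may be ill-determined")
  if (any(substrate <= 0)) stop("substrate concentrations must be positive")
  if (any(rate < 0)) stop("rates must be non-negative")
  hw <- stats::lm(I(substrate / pmax(rate, max(rate) * 1e-6)) ~ substrate)
  v0 <- max(1 / stats::coef(hw)[2], max(rate))
  k0 <- max(stats::coef(hw)[1] * v0, min(substrate) / 10)
  d <- data.frame(S = substrate, v = rate)
  args <- list(v ~ Vmax * S / (Km + S), data = d,
               start = list(Vmax = unname(v0), Km = unname(k0)),
               lower = c(Vmax = 0, Km = 0),
               control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!is.null(weights)) args$weights <- weights
  fit <- do.call(minpack.lm::nlsLM, args)
  cf <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  if (max(substrate) < 2 * cf[["Km"]])
    warning("data do not span Km: confidence intervals will be wide")
  structure(list(Km = cf[["Km"]], Vmax = cf[["Vmax"]],
                 kcat = cf[["Vmax"]] / enzyme_conc,
                 efficiency = cf[["Vmax"]] / enzyme_conc / cf[["Km"]],
                 enzyme_conc = enzyme_conc,
                 se = c(Km = unname(se["Km"]), Vmax = unname(se["Vmax"])),
                 fit = fit), class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit: Km %.3g uM, Vmax %.3g uM/s, kcat %.3g 1/s, kcat/Km %.3g>\n",
              x$Km, x$Vmax, x$kcat, x$efficiency))
  invisible(x)
}

#' Percent reduction in catalytic efficiency
#'
#' `100 (1 - (kcat/Km)_complexed / (kcat/Km)_free)`; the statistic used to
#' express competitive inhibition of an enzyme by a bound partner.
#'
#' @param free,complexed `mm_fit` objects, or bare kcat/Km efficiencies
#' @return percent reduction (0 = unchanged, 100 = complete loss)
#' @export
efficiency_reduction <- function(free, complexed) {
  eff <- function(x) if (inherits(x, "mm_fit")) x$efficiency else as.numeric(x)
  ef <- eff(free); ec <- eff(complexed)
  if (ef == 0) stop("free-enzyme efficiency is zero: reduction undefined")
  100 * (1 - ec / ef)
}

#' Single-site binding fit
#'
#' Least squares of `signal = s [P] / (Kd + [P])`; the amplitude `s` is a
#' free scale factor unless frozen (as done when one titration calibrates
#' the scale for a series).
#'
#' @param protein_conc protein concentrations, uM
#' @param signal bound-fraction signal (non-negative)
#' @param s_fixed freeze the scale factor at this value instead of fitting
#' @return `binding_fit` object: `Kd` (uM), `s`, `se`
#' @export
binding_fit <- function(protein_conc, signal, s_fixed = NULL) {
  if (length(protein_conc) < 5)
    warning("fewer than 5 concentrations: Kd may be ill-determined")
  if (any(signal < 0)) stop("signal must be non-negative")
  d <- data.frame(P = protein_conc, y = signal)
  half <- max(signal) / 2
  k0 <- d$P[which.min(abs(signal - half))]
  if (is.null(s_fixed)) {
    fit <- minpack.lm::nlsLM(y ~ s * P / (Kd + P), data = d,
                             start = list(s = max(signal), Kd = unname(k0)),
                             lower = c(s = 0, Kd = 0))
  } else {
    fit <- minpack.lm::nlsLM(y ~ s_fixed * P / (Kd + P), data = d,
                             start = list(Kd = unname(k0)), lower = c(Kd = 0))
  }
  cf <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  structure(list(Kd = cf[["Kd"]],
                 s = if (is.null(s_fixed)) cf[["s"]] else s_fixed,
                 se = se, fit = fit), class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit: Kd %.3g uM, scale %.3g>\n", x$Kd, x$s))
  invisible(x)
}
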