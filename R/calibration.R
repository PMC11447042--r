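#' Fit a linear calibration of signal on concentration
#'
#' Ordinary least squares of the method signal against analyte
#' concentration, the central fitted object of the package.  The residual
#' standard deviation `sigma` (n - 2 degrees of freedom) and the slope feed
#' the detection limits `LOD = 3.3 sigma / S` and `LOQ = 10 sigma / S`;
#' inverse prediction converts signals of unknowns to concentrations.
#'
#' @param concentration Numeric vector of concentrations in ug/mL (at least
#'   3 points, at least 2 distinct values).
#' @param signal Numeric vector of method signals, same length.
#' @param method_config Optional [method_config()] recorded with the fit
#'   for reporting and audit.
#' @param sigma_method `"residual"` (default): `sigma` is the residual SD of
#'   the calibration line; `"intercept"`: `sigma` is the standard error of
#'   the intercept (the ICH Q2 alternative).
#'
#' @return An object of class `calibration_fit` with components `slope`,
#'   `intercept`, `sigma`, `r_squared`, `n`, `conc_range`, `residuals`,
#'   `fitted`, `data`, `sigma_method`, `method_config`.
#' @examples
#' fit <- fit_calibration(1:5, 2 * (1:5) + 1)
#' coef(fit); lod(fit); loq(fit)
#' predict(fit, signal = 5)
#' @seealso [lod()], [loq()], [predict.calibration_fit()]
#' @export
fit_calibration <- function(concentration, signal, method_config = NULL,
                            sigma_method = c("residual", "intercept")) {
  sigma_method <- match.arg(sigma_method)
  concentration <- as.numeric(concentration)
  signal <- as.numeric(signal)
  if (length(concentration) != length(signal))
    rs_stop("concentration and signal must have the same length",
            "ratiospec_domain_error")
  if (length(concentration) < 3L)
    rs_stop("calibration needs at least 3 points", "ratiospec_domain_error")
  if (length(unique(concentration)) < 2L)
    rs_stop("calibration needs at least 2 distinct concentrations",
            "ratiospec_rank_error")
  fit <- stats::lm(signal ~ concentration)
  # summary.lm warns on an exactly collinear (noise-free) fit; that case is
  # legitimate here, so muffle it
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  sigma <- if (sigma_method == "residual") sm$sigma
           else sm$coefficients[1, 2]
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    sigma = sigma,
    r_squared = sm$r.squared,
    n = length(concentration),
    conc_range = range(concentration),
    residuals = unname(stats::residuals(fit)),
    fitted = unname(stats::fitted(fit)),
    data = data.frame(concentration = concentration, signal = signal),
    sigma_method = sigma_method,
    method_config = method_config
  ), class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, digits = 4, ...) {
  cat("Linear calibration: signal = slope * concentration + intercept\n")
  if (!is.null(x$method_config))
    print(x$method_config)
  cat(sprintf("  slope     %s  (signal per ug/mL)\n",
              format(x$slope, digits = digits)))
  cat(sprintf("  intercept %s\n", format(x$intercept, digits = digits)))
  cat(sprintf("  r^2       %s   sigma (%s) %s   n = %d, range %g-%g ug/mL\n",
              format(x$r_squared, digits = 6), x$sigma_method,
              format(x$sigma, digits = digits), x$n,
              x$conc_range[1], x$conc_range[2]))
  invisible(x)
}

#' @export
coef.calibration_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
residuals.calibration_fit <- function(object, ...) object$residuals

#' @export
summary.calibration_fit <- function(object, ...) {
  out <- list(fit = object, lod = lod(object), loq = loq(object))
  class(out) <- "summary.calibration_fit"
  out
}

#' @export
print.summary.calibration_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  LOD %.4f ug/mL   LOQ %.4f ug/mL\n", x$lod, x$loq))
  invisible(x)
}

#' @export
plot.calibration_fit <- function(x, ..., xlab = "Concentration (ug/mL)",
                                 ylab = "Signal") {
  graphics::plot(x$data$concentration, x$data$signal, xlab = xlab,
                 ylab = ylab, ...)
  graphics::abline(x$intercept, x$slope)
  invisible(x)
}

#' Predict concentrations (inverse) or signals (forward)
#'
#' With `signal` supplied, inverts the calibration line,
#' `(signal - intercept) / slope`, the routine use in quantification; a
#' warning flags signals mapping outside the calibrated concentration
#' range (the value is still returned).  With `concentration` supplied the
#' forward line is evaluated.  With neither, fitted values are returned.
#'
#' @param object A [fit_calibration()] fit.
#' @param signal Numeric vector of signals to invert.
#' @param concentration Numeric vector of concentrations for forward
#'   prediction.
#' @param ... Unused.
#' @return Numeric vector of concentrations (ug/mL) or signals.
#' @export
predict.calibration_fit <- function(object, signal = NULL,
                                    concentration = NULL, ...) {
  if (!is.null(concentration))
    return(object$intercept + object$slope * concentration)
  if (is.null(signal))
    return(object$fitted)
  if (slope_degenerate(object))
    rs_stop("zero slope: calibration is not invertible",
            "ratiospec_inversion_error")
  conc <- (signal - object$intercept) / object$slope
  out_of_range <- conc < object$conc_range[1] - 1e-9 |
                  conc > object$conc_range[2] + 1e-9
  if (any(out_of_range))
    warning(sprintf("%d prediction(s) outside the calibrated range %g-%g ug/mL",
                    sum(out_of_range), object$conc_range[1],
                    object$conc_range[2]), call. = FALSE)
  conc
}

#' @export
simulate.calibration_fit <- function(object, nsim = 1, seed = NULL, ...) {
  n <- object$n
  sims <- function() object$fitted + stats::rnorm(n, 0, object$sigma)
  gen <- function() as.data.frame(replicate(nsim, sims()))
  out <- if (is.null(seed)) gen() else with_local_seed(seed, gen())
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Limits of detection and quantitation
#'
#' `lod()` returns `3.3 * sigma / |S|` and `loq()` returns
#' `10 * sigma / |S|`, where `sigma` is the calibration fit's residual
#' standard deviation (or intercept SE, depending on how the model was
#' fitted) and `S` its slope.  `loq(m) == (10 / 3.3) * lod(m)` identically.
#'
#' @param model A [fit_calibration()] fit.
#' @return Concentration in ug/mL.
#' @export
lod <- function(model) {
  stopifnot(inherits(model, "calibration_fit"))
  if (slope_degenerate(model))
    rs_stop("zero slope: LOD undefined", "ratiospec_inversion_error")
  3.3 * model$sigma / abs(model$slope)
}

# a slope is unusable when it is zero relative to the spread of the data
# (an exactly-zero OLS slope lands at ~1e-17 in floating point)
slope_degenerate <- function(model) {
  sy <- stats::sd(model$data$signal)
  sx <- stats::sd(model$data$concentration)
  abs(model$slope) <= 1e-10 * (if (sy > 0) sy / sx else 1)
}

#' @rdname lod
#' @export
loq <- function(model) {
  stopifnot(inherits(model, "calibration_fit"))
  if (slope_degenerate(model))
    rs_stop("zero slope: LOQ undefined", "ratiospec_inversion_error")
  10 * model$sigma / abs(model$slope)
}

#' Tabulate regression and sensitivity parameters for a set of fits
#'
#' One row per method: analysis wavelengths, linearity range, slope,
#' intercept, r^2, LOD and LOQ, mirroring the regression-parameter table of
#' a validation report.
#'
#' @param fits Named list of [fit_calibration()] fits.
#' @param path Optional CSV destination.
#' @return A data frame (invisibly written to `path` if given).
#' @export
calibration_report <- function(fits, path = NULL) {
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    cfg <- f$method_config
    data.frame(
      method = nm,
      analyte = if (!is.null(cfg)) cfg$analyte else NA_character_,
      wavelengths = if (!is.null(cfg))
        paste(cfg$wavelengths, collapse = "/") else NA_character_,
      range_low = f$conc_range[1], range_high = f$conc_range[2],
      slope = f$slope, intercept = f$intercept,
      r_squared = f$r_squared, lod = lod(f), loq = loq(f),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
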