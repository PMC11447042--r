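#' Ratio spectrum of a sample against a divisor standard
#'
#' Divides a sample spectrum pointwise by the spectrum of a standard of the
#' interfering analyte (the divisor).  Under Beer-Lambert additivity the
#' interferent's contribution to the ratio spectrum is a constant, which the
#' three manipulation methods (ratio difference, first derivative, mean
#' centering) then annihilate.  Wavelengths where the divisor magnitude
#' falls below the division guard `epsilon` are masked rather than emitted
#' as huge or infinite ratios.
#'
#' @param sample A [uv_spectrum()] of the mixture or pure analyte.
#' @param divisor A [uv_spectrum()] of the divisor standard.  If its grid
#'   differs from the sample's it is linearly resampled onto the sample
#'   grid over their common range.
#' @param epsilon Division guard in AU (default 0.01): samples with
#'   `|A_divisor| < epsilon` are masked.
#'
#' @return An object of class `ratio_spectrum`: list with `wavelength`,
#'   `amplitude` (dimensionless, `NA` where masked), `mask` (logical,
#'   `TRUE` = valid), `divisor_label`, `transform` ("ratio").
#' @examples
#' p <- default_profiles()
#' mix <- simulate_mixture(list(p$bpl, p$tst), c(4, 32))
#' r <- ratio_spectrum(mix, component_spectrum(p$tst, 16))
#' ratio_difference(r, 210, 224)
#' @export
ratio_spectrum <- function(sample, divisor, epsilon = 0.01) {
  stopifnot(inherits(sample, "uv_spectrum"), inherits(divisor, "uv_spectrum"))
  if (epsilon <= 0)
    rs_stop("epsilon must be > 0", "ratiospec_domain_error")
  same_grid <- length(sample$wavelength) == length(divisor$wavelength) &&
    all(abs(sample$wavelength - divisor$wavelength) <= 1e-9)
  if (!same_grid) {
    lo <- max(min(sample$wavelength), min(divisor$wavelength))
    hi <- min(max(sample$wavelength), max(divisor$wavelength))
    keep <- sample$wavelength >= lo - 1e-9 & sample$wavelength <= hi + 1e-9
    if (sum(keep) < 3L)
      rs_stop("sample and divisor grids share fewer than 3 wavelengths",
              "ratiospec_grid_error")
    sample <- uv_spectrum(sample$wavelength[keep], sample$absorbance[keep],
                          sample$metadata)
    divisor <- resample_spectrum(divisor, sample$wavelength)
  }
  mask <- abs(divisor$absorbance) >= epsilon
  if (sum(mask) < 3L)
    rs_stop("fewer than 3 unmasked samples after applying the division guard",
            "ratiospec_degenerate_ratio_error")
  amp <- rep(NA_real_, length(mask))
  amp[mask] <- sample$absorbance[mask] / divisor$absorbance[mask]
  new_ratio_spectrum(sample$wavelength, amp, mask,
                     divisor_label = spectrum_label(divisor),
                     transform = "ratio")
}

new_ratio_spectrum <- function(wavelength, amplitude, mask, divisor_label,
                               transform) {
  structure(list(wavelength = wavelength, amplitude = amplitude,
                 mask = mask, divisor_label = divisor_label,
                 transform = transform),
            class = "ratio_spectrum")
}

spectrum_label <- function(s) {
  m <- s$metadata
  a <- if (!is.null(m$analyte)) m$analyte else "unknown"
  if (!is.null(m$concentration))
    sprintf("%s %g ug/mL", a, as.numeric(m$concentration)) else a
}

#' @export
print.ratio_spectrum <- function(x, ...) {
  cat(sprintf("Ratio spectrum (%s): %d points, %d unmasked, divisor %s\n",
              x$transform, length(x$wavelength), sum(x$mask),
              x$divisor_label))
  invisible(x)
}

#' @export
plot.ratio_spectrum <- function(x, ..., xlab = "Wavelength (nm)",
                                ylab = "Ratio amplitude", type = "l") {
  graphics::plot(x$wavelength, x$amplitude, type = type,
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

ratio_step <- function(r) mean(diff(r$wavelength))

ratio_index <- function(r, lambda, what = "wavelength") {
  i <- which(abs(r$wavelength - lambda) <= 1e-6)
  if (!length(i))
    rs_stop(sprintf("%s %g nm is not on the grid", what, lambda),
            "ratiospec_grid_error")
  i[1]
}

#' Amplitude of a ratio spectrum at a wavelength
#'
#' Returns the stored amplitude at an on-grid wavelength.  Derived signals
#' are never silently interpolated: an off-grid wavelength is an error, and
#' reading a masked wavelength raises a masked-signal error.
#'
#' @param r A `ratio_spectrum` (possibly transformed).
#' @param lambda Wavelength in nm, on the grid.
#' @return The amplitude (dimensionless scalar).
#' @export
amplitude_at <- function(r, lambda) {
  stopifnot(inherits(r, "ratio_spectrum"))
  i <- ratio_index(r, lambda)
  if (!r$mask[i])
    rs_stop(sprintf("wavelength %g nm is masked", lambda),
            "ratiospec_masked_error")
  r$amplitude[i]
}

#' Ratio-difference signal
#'
#' The difference of ratio-spectrum amplitudes at two wavelengths,
#' `P(lambda1) - P(lambda2)`, signed.  The interferent contributes the same
#' constant at both wavelengths and cancels, leaving a signal proportional
#' to the target analyte's concentration.
#'
#' @param r A `ratio_spectrum`.
#' @param lambda1,lambda2 Distinct on-grid, unmasked wavelengths in nm.
#' @return The amplitude difference (dimensionless scalar).
#' @export
ratio_difference <- function(r, lambda1, lambda2) {
  if (isTRUE(all.equal(lambda1, lambda2)))
    rs_stop("ratio difference needs two distinct wavelengths",
            "ratiospec_domain_error")
  amplitude_at(r, lambda1) - amplitude_at(r, lambda2)
}

#' First derivative of a ratio spectrum
#'
#' The default operator is the symmetric difference over +/- `delta_lambda`,
#' `D(lambda) = k * (P(lambda + dl) - P(lambda - dl)) / (2 dl)`, which is
#' exact for locally quadratic signals; a Savitzky-Golay first-derivative
#' filter is available as an option.  Wavelengths within `delta_lambda` of
#' either end of the grid (or whose stencil touches a masked point) are
#' masked in the output.  Differentiation annihilates the interferent's
#' constant in the ratio spectrum.
#'
#' @param r A `ratio_spectrum`.
#' @param delta_lambda Half-width of the difference stencil in nm; must be a
#'   positive multiple of the grid spacing.  Default 4 nm.
#' @param scaling_factor Dimensionless multiplier applied to the derivative
#'   (cosmetic: it cancels in calibration, but keeps amplitudes comparable
#'   with instrument-software output).  Default 10.
#' @param method `"central"` (default) or `"savgol"`.
#' @param sg_window,sg_order Savitzky-Golay window length (odd) and
#'   polynomial order, used only when `method = "savgol"`.
#' @return A `ratio_spectrum` with `transform = "dd1"`; amplitudes have
#'   units 1/nm times `scaling_factor`.
#' @export
first_derivative <- function(r, delta_lambda = 4, scaling_factor = 10,
                             method = c("central", "savgol"),
                             sg_window = 9, sg_order = 2) {
  stopifnot(inherits(r, "ratio_spectrum"))
  method <- match.arg(method)
  if (delta_lambda <= 0 || scaling_factor <= 0)
    rs_stop("delta_lambda and scaling_factor must be positive",
            "ratiospec_domain_error")
  h <- ratio_step(r)
  k <- delta_lambda / h
  if (abs(k - round(k)) > 1e-6)
    rs_stop(sprintf("delta_lambda %g nm is not a multiple of the grid step %g nm",
                    delta_lambda, h), "ratiospec_grid_error")
  k <- as.integer(round(k))
  n <- length(r$wavelength)
  if (n < 2L * k + 1L)
    rs_stop("spectrum span is too short for this delta_lambda",
            "ratiospec_grid_error")
  amp <- rep(NA_real_, n)
  mask <- rep(FALSE, n)
  if (method == "central") {
    i <- (k + 1L):(n - k)
    ok <- r$mask[i - k] & r$mask[i + k]
    amp[i[ok]] <- scaling_factor *
      (r$amplitude[i[ok] + k] - r$amplitude[i[ok] - k]) / (2 * delta_lambda)
    mask[i[ok]] <- TRUE
  } else {
    if (sg_window %% 2 != 1 || sg_window <= sg_order)
      rs_stop("sg_window must be odd and greater than sg_order",
              "ratiospec_domain_error")
    half <- (sg_window - 1L) / 2L
    # filter each maximal unmasked run long enough for the window
    runs <- rle(r$mask)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (j in seq_along(runs$values)) {
      if (!runs$values[j] || runs$lengths[j] < sg_window) next
      idx <- starts[j]:ends[j]
      d <- signal::sgolayfilt(r$amplitude[idx], p = sg_order, n = sg_window,
                              m = 1, ts = h)
      inner <- idx[(half + 1L):(length(idx) - half)]
      amp[inner] <- scaling_factor * d[(half + 1L):(length(idx) - half)]
      mask[inner] <- TRUE
    }
    if (sum(mask) < 1L)
      rs_stop("no unmasked run is long enough for the Savitzky-Golay window",
              "ratiospec_degenerate_ratio_error")
  }
  new_ratio_spectrum(r$wavelength, amp, mask, r$divisor_label, "dd1")
}

#' Mean centering of a ratio spectrum
#'
#' Subtracts the mean amplitude over the unmasked samples of a wavelength
#' window from the ratio spectrum, restricted to that window.  The
#' interferent's constant contribution is removed exactly; the centered
#' output sums to zero over its unmasked support.
#'
#' @param r A `ratio_spectrum`.
#' @param lo,hi Window bounds in nm (inclusive), `lo < hi`; the window must
#'   contain at least 3 unmasked samples.
#' @return A `ratio_spectrum` on the window with `transform = "mc"`.
#' @export
mean_center <- function(r, lo, hi) {
  stopifnot(inherits(r, "ratio_spectrum"))
  if (lo >= hi)
    rs_stop("mean-centering window must have lo < hi",
            "ratiospec_domain_error")
  keep <- r$wavelength >= lo - 1e-9 & r$wavelength <= hi + 1e-9
  wl <- r$wavelength[keep]
  amp <- r$amplitude[keep]
  mask <- r$mask[keep]
  if (sum(mask) < 3L)
    rs_stop("fewer than 3 unmasked samples in the mean-centering window",
            "ratiospec_degenerate_ratio_error")
  amp[mask] <- amp[mask] - mean(amp[mask])
  new_ratio_spectrum(wl, amp, mask, r$divisor_label, "mc")
}

#' Per-method, per-analyte configuration
#'
#' Bundles the parameters that define one quantification method for one
#' analyte: the transform, the divisor standard (analyte and concentration),
#' the analysis wavelength(s), and the transform parameters.
#'
#' @param method One of `"RD"` (ratio difference), `"DD1"` (first
#'   derivative of ratio spectra), `"MC"` (mean centering of ratio spectra).
#' @param analyte Label of the target analyte.
#' @param divisor_analyte,divisor_conc Label and concentration (ug/mL) of
#'   the divisor standard (the other analyte).
#' @param wavelengths For RD a pair `(lambda1, lambda2)` nm; for DD1 and MC
#'   a single wavelength nm.
#' @param delta_lambda,scaling_factor DD1 parameters (defaults 4 nm, 10).
#' @param mc_range MC working window `(lo, hi)` nm (default `c(200, 305)`).
#' @param epsilon Division guard in AU (default 0.01).
#' @return An object of class `method_config`.
#' @export
method_config <- function(method, analyte, divisor_analyte, divisor_conc,
                          wavelengths, delta_lambda = 4, scaling_factor = 10,
                          mc_range = c(200, 305), epsilon = 0.01) {
  method <- match.arg(method, c("RD", "DD1", "MC"))
  wavelengths <- as.numeric(wavelengths)
  if (method == "RD") {
    if (length(wavelengths) != 2 || wavelengths[1] == wavelengths[2])
      rs_stop("RD needs two distinct wavelengths", "ratiospec_domain_error")
  } else if (length(wavelengths) != 1) {
    rs_stop(sprintf("%s needs a single analysis wavelength", method),
            "ratiospec_domain_error")
  }
  if (method == "DD1" && (delta_lambda <= 0 || scaling_factor <= 0))
    rs_stop("DD1 needs delta_lambda > 0 and scaling_factor > 0",
            "ratiospec_domain_error")
  if (method == "MC" && mc_range[1] >= mc_range[2])
    rs_stop("MC range must have lo < hi", "ratiospec_domain_error")
  structure(list(method = method, analyte = analyte,
                 divisor_analyte = divisor_analyte,
                 divisor_conc = as.numeric(divisor_conc),
                 wavelengths = wavelengths,
                 delta_lambda = delta_lambda,
                 scaling_factor = scaling_factor,
                 mc_range = as.numeric(mc_range),
                 epsilon = epsilon),
            class = "method_config")
}

#' @export
print.method_config <- function(x, ...) {
  wl <- paste(x$wavelengths, collapse = "/")
  extra <- switch(x$method,
    RD  = "",
    DD1 = sprintf(", delta_lambda %g nm, scaling %g", x$delta_lambda,
                  x$scaling_factor),
    MC  = sprintf(", window %g-%g nm", x$mc_range[1], x$mc_range[2]))
  cat(sprintf("%s method for %s at %s nm (divisor %s %g ug/mL%s)\n",
              x$method, x$analyte, wl, x$divisor_analyte, x$divisor_conc,
              extra))
  invisible(x)
}

#' The six bundled method configurations
#'
#' The canonical configurations for the bisoprolol (BPL) / telmisartan
#' (TST) assay: RD at 210/224 nm (BPL) and 255/265 nm (TST); DD1 at 232 nm
#' (BPL) and 243 nm (TST) with `delta_lambda = 4` nm and scaling factor 10;
#' MC at 223 nm (BPL) and 245 nm (TST) over 200-305 nm.  Divisors are
#' TST 16 ug/mL (for BPL) and BPL 10 ug/mL (for TST).
#'
#' @return Named list of six [method_config()] objects:
#'   `BPL_RD`, `BPL_DD1`, `BPL_MC`, `TST_RD`, `TST_DD1`, `TST_MC`.
#' @export
default_method_configs <- function() {
  list(
    BPL_RD  = method_config("RD",  "BPL", "TST", 16, c(210, 224)),
    BPL_DD1 = method_config("DD1", "BPL", "TST", 16, 232),
    BPL_MC  = method_config("MC",  "BPL", "TST", 16, 223),
    TST_RD  = method_config("RD",  "TST", "BPL", 10, c(255, 265)),
    TST_DD1 = method_config("DD1", "TST", "BPL", 10, 243),
    TST_MC  = method_config("MC",  "TST", "BPL", 10, 245)
  )
}

#' Write / read method configurations as YAML
#'
#' @param configs Named list of [method_config()] objects.
#' @param path File path.
#' @return `write_method_configs` returns `path` invisibly;
#'   `read_method_configs` returns a named list of [method_config()].
#' @export
write_method_configs <- function(configs, path) {
  stopifnot(all(vapply(configs, inherits, logical(1), "method_config")))
  yaml::write_yaml(lapply(configs, unclass), path)
  invisible(path)
}

#' @rdname write_method_configs
#' @export
read_method_configs <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(x)
    method_config(x$method, x$analyte, x$divisor_analyte, x$divisor_conc,
                  unlist(x$wavelengths), x$delta_lambda, x$scaling_factor,
                  unlist(x$mc_range), x$epsilon))
}

#' Scalar method signal for a mixture spectrum
#'
#' Runs the full signal chain for one method configuration: divide the
#' mixture spectrum by the divisor standard, apply the configured transform
#' (none for RD, first derivative for DD1, mean centering for MC), and read
#' the analysis wavelength(s).  All three transforms are linear in the
#' sample spectrum and reject a pure-divisor-analyte sample exactly.
#'
#' @param mixture A [uv_spectrum()] of the sample.
#' @param config A [method_config()].
#' @param divisor A [uv_spectrum()] of the divisor standard.
#' @return The scalar signal (dimensionless; signed).
#' @export
method_signal <- function(mixture, config, divisor) {
  stopifnot(inherits(config, "method_config"))
  r <- ratio_spectrum(mixture, divisor, epsilon = config$epsilon)
  switch(config$method,
    RD = ratio_difference(r, config$wavelengths[1], config$wavelengths[2]),
    DD1 = amplitude_at(first_derivative(r, config$delta_lambda,
                                        config$scaling_factor),
                       config$wavelengths[1]),
    MC = amplitude_at(mean_center(r, config$mc_range[1], config$mc_range[2]),
                      config$wavelengths[1]))
}
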