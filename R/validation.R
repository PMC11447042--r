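#' Percent recovery
#'
#' `100 * found / taken`, the accuracy metric of the validation layer.
#'
#' @param found Found concentration(s) in ug/mL.
#' @param taken Nominal concentration(s) in ug/mL, > 0.
#' @return Percent recovery (vectorized).
#' @export
percent_recovery <- function(found, taken) {
  if (any(taken <= 0))
    rs_stop("taken concentration must be > 0", "ratiospec_domain_error")
  100 * found / taken
}

#' Standard-addition recovery
#'
#' Recovery of the added amount: `100 * (spiked_found - base_found) /
#' added`.  Computed on the added amount so matrix contributions present in
#' both the base and the spiked determinations cancel.
#'
#' @param base_found Found concentration of the unspiked sample (ug/mL).
#' @param spiked_found Found concentration of the spiked sample (ug/mL).
#' @param added Spiked amount (ug/mL), > 0.
#' @return Percent recovery of the added amount (vectorized).
#' @export
standard_addition_recovery <- function(base_found, spiked_found, added) {
  if (any(added <= 0))
    rs_stop("added amount must be > 0", "ratiospec_domain_error")
  100 * (spiked_found - base_found) / added
}

#' Summarize a set of recoveries
#'
#' Mean, sample standard deviation (n - 1 degrees of freedom) and relative
#' standard deviation `RSD = 100 * SD / mean` of a vector of percent
#' recoveries.
#'
#' @param recoveries Numeric vector of percent recoveries, length >= 2.
#' @return An object of class `recovery_summary`: list with `recoveries`,
#'   `mean_recovery`, `sd`, `rsd`, `n`.
#' @export
summarize_recoveries <- function(recoveries) {
  recoveries <- as.numeric(recoveries)
  if (length(recoveries) < 2L)
    rs_stop("need at least 2 recoveries to summarize",
            "ratiospec_domain_error")
  m <- mean(recoveries)
  s <- stats::sd(recoveries)
  structure(list(recoveries = recoveries, mean_recovery = m, sd = s,
                 rsd = 100 * s / m, n = length(recoveries)),
            class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf("Recovery summary (n = %d): mean %%R %.2f, SD %.3f, RSD %.3f%%\n",
              x$n, x$mean_recovery, x$sd, x$rsd))
  invisible(x)
}

#' Pooled-variance two-sample t comparison
#'
#' The method-comparison t statistic computed from summary statistics
#' (means, SDs, group sizes), using the pooled-variance formula with
#' `df = n_a + n_b - 2`; `|t|` is reported together with the two-tailed
#' critical value at `alpha`.  If both SDs are zero the statistic is 0 for
#' equal means and flagged infinite otherwise.
#'
#' @param mean_a,sd_a,n_a Summary statistics of group A.
#' @param mean_b,sd_b,n_b Summary statistics of group B.
#' @param alpha Significance level (default 0.05, two-tailed).
#' @return An object of class `comparison_result` with `t_stat`, `df_t`,
#'   `t_critical`, `significant`, `infinite` flag.
#' @export
two_sample_t <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                         alpha = 0.05) {
  if (n_a < 2 || n_b < 2)
    rs_stop("both groups need n >= 2", "ratiospec_domain_error")
  if (sd_a < 0 || sd_b < 0)
    rs_stop("standard deviations must be >= 0", "ratiospec_domain_error")
  df <- n_a + n_b - 2
  pooled_var <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
  infinite <- FALSE
  if (pooled_var == 0) {
    if (mean_a == mean_b) t_stat <- 0
    else { t_stat <- Inf; infinite <- TRUE }
  } else {
    t_stat <- abs(mean_a - mean_b) / sqrt(pooled_var * (1 / n_a + 1 / n_b))
  }
  t_crit <- stats::qt(1 - alpha / 2, df)
  structure(list(t_stat = t_stat, df_t = df, t_critical = t_crit,
                 significant = is.finite(t_stat) && t_stat > t_crit,
                 infinite = infinite, alpha = alpha),
            class = "comparison_result")
}

#' Variance-ratio F comparison
#'
#' The larger-over-smaller variance ratio (so `F >= 1` always), with
#' degrees of freedom ordered accordingly and the critical value at
#' `alpha` (one-tailed on the ordered ratio, the convention of validation
#' reports; `F(0.05; 4, 4) = 6.388` for two groups of five).
#'
#' @param var_a,var_b Group variances, > 0.
#' @param n_a,n_b Group sizes (default 5 each).
#' @param alpha Significance level (default 0.05).
#' @return An object of class `comparison_result` with `f_stat`, `df_f`,
#'   `f_critical`, `significant`.
#' @export
f_ratio <- function(var_a, var_b, n_a = 5, n_b = 5, alpha = 0.05) {
  if (var_a <= 0 || var_b <= 0)
    rs_stop("variances must be > 0", "ratiospec_domain_error")
  if (var_a >= var_b) {
    f_stat <- var_a / var_b; df <- c(n_a - 1, n_b - 1)
  } else {
    f_stat <- var_b / var_a; df <- c(n_b - 1, n_a - 1)
  }
  f_crit <- stats::qf(1 - alpha, df[1], df[2])
  structure(list(f_stat = f_stat, df_f = df, f_critical = f_crit,
                 significant = f_stat > f_crit, alpha = alpha),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  if (!is.null(x$t_stat))
    cat(sprintf("t = %.3f (df = %d, critical %.3f at alpha %.2f)%s\n",
                x$t_stat, x$df_t, x$t_critical, x$alpha,
                if (isTRUE(x$significant)) " *" else ""))
  if (!is.null(x$f_stat))
    cat(sprintf("F = %.3f (df = %d, %d, critical %.3f at alpha %.2f)%s\n",
                x$f_stat, x$df_f[1], x$df_f[2], x$f_critical, x$alpha,
                if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}

# vectorized simple-OLS summaries of Y (n x m) on x: slope, intercept, r2
ols_columns <- function(x, Y) {
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  Ym <- colMeans(Y)
  Yc <- sweep(Y, 2, Ym)
  sxy <- as.numeric(crossprod(xc, Yc))
  syy <- colSums(Yc^2)
  slope <- sxy / sxx
  r2 <- ifelse(syy > 0, sxy^2 / (sxx * syy), 0)
  list(slope = slope, intercept = Ym - slope * mean(x), r_squared = r2)
}

transform_for_method <- function(r, method, delta_lambda = 4,
                                 scaling_factor = 10, mc_range = NULL) {
  switch(method,
    RD = r,
    DD1 = first_derivative(r, delta_lambda, scaling_factor),
    MC = mean_center(r, if (is.null(mc_range)) min(r$wavelength) else mc_range[1],
                     if (is.null(mc_range)) max(r$wavelength) else mc_range[2]))
}

#' Select analysis wavelengths by linearity and interferent rejection
#'
#' Scores every candidate wavelength (DD1, MC) or wavelength pair (RD)
#' over a target analyte's ratio-spectrum calibration set: the r^2 of the
#' signal-versus-concentration line, the absolute slope (sensitivity), and
#' the interferent rejection, i.e. the largest absolute signal the
#' interfering analyte's own ratio spectra produce at that candidate.
#' The selected candidate maximizes r^2 among those whose interferent
#' leakage stays below `rejection_frac` of the target's mid-range signal,
#' ties broken by larger `|slope|`.  The full score table is returned for
#' audit.
#'
#' @param target List with `spectra` (list of [ratio_spectrum()] of the
#'   target analyte at increasing concentrations, all against the same
#'   divisor) and `concentrations` (ug/mL, length >= 3).
#' @param interferent List with `spectra`: ratio spectra of the pure
#'   interfering analyte (same divisor, any levels).
#' @param method `"RD"`, `"DD1"` or `"MC"`.
#' @param candidates Candidate wavelengths (nm) on the grid; for RD all
#'   unordered pairs are scored.
#' @param rejection_frac Leakage threshold as a fraction of the target
#'   mid-range signal (default 0.01).
#' @param delta_lambda,scaling_factor,mc_range Transform parameters for
#'   DD1 / MC (defaults 4 nm, 10, full range).
#' @return An object of class `wavelength_selection`: list with
#'   `wavelengths` (chosen lambda or pair), `score` (its table row), and
#'   `table` (all candidates, ranked).
#' @export
select_signal_wavelengths <- function(target, interferent,
                                      method = c("RD", "DD1", "MC"),
                                      candidates, rejection_frac = 0.01,
                                      delta_lambda = 4, scaling_factor = 10,
                                      mc_range = NULL) {
  method <- match.arg(method)
  conc <- as.numeric(target$concentrations)
  if (length(conc) < 3L)
    rs_stop("need at least 3 target concentrations",
            "ratiospec_domain_error")
  tspec <- lapply(target$spectra, transform_for_method, method,
                  delta_lambda, scaling_factor, mc_range)
  ispec <- lapply(interferent$spectra, transform_for_method, method,
                  delta_lambda, scaling_factor, mc_range)
  # keep candidates that are on-grid and unmasked in every spectrum
  ok <- vapply(candidates, function(wl) {
    all(vapply(c(tspec, ispec), function(r) {
      i <- which(abs(r$wavelength - wl) <= 1e-6)
      length(i) == 1L && r$mask[i]
    }, logical(1)))
  }, logical(1))
  usable <- candidates[ok]
  if (length(usable) < ifelse(method == "RD", 2L, 1L))
    rs_stop("no usable candidate wavelengths (off-grid or masked)",
            "ratiospec_selection_error")
  amp_at <- function(specs, wls) {
    m <- vapply(specs, function(r)
      r$amplitude[vapply(wls, function(w)
        which(abs(r$wavelength - w) <= 1e-6)[1], integer(1))],
      numeric(length(wls)))
    # vapply lays candidates out along rows; we need spectra x candidates
    if (length(wls) == 1L) matrix(m, ncol = 1L) else t(m)
  }
  Tamp <- amp_at(tspec, usable)          # n_conc x n_wl
  Iamp <- amp_at(ispec, usable)
  if (method == "RD") {
    pairs <- utils::combn(seq_along(usable), 2)
    S <- Tamp[, pairs[1, ], drop = FALSE] - Tamp[, pairs[2, ], drop = FALSE]
    leak_tab <- abs(Iamp[, pairs[1, ], drop = FALSE] -
                    Iamp[, pairs[2, ], drop = FALSE])
    lab1 <- usable[pairs[1, ]]; lab2 <- usable[pairs[2, ]]
  } else {
    S <- Tamp
    leak_tab <- abs(Iamp)
    lab1 <- usable; lab2 <- rep(NA_real_, length(usable))
  }
  fit <- ols_columns(conc, S)
  leakage <- apply(leak_tab, 2, max)
  mid <- mean(range(conc))
  mid_signal <- abs(fit$intercept + fit$slope * mid)
  threshold <- rejection_frac * mid_signal
  pass <- leakage <= threshold
  tab <- data.frame(lambda1 = lab1, lambda2 = lab2,
                    slope = fit$slope, r_squared = fit$r_squared,
                    interferent_max = leakage,
                    rejection_threshold = threshold, pass = pass)
  tab <- tab[order(-tab$pass, -tab$r_squared, -abs(tab$slope)), ]
  rownames(tab) <- NULL
  if (!any(pass)) {
    best <- utils::head(tab, 5)
    rs_stop(paste0("no candidate passes the interferent-rejection threshold; ",
                   "best failures (lambda1/lambda2, leakage): ",
                   paste(sprintf("%g/%g: %.3g", best$lambda1, best$lambda2,
                                 best$interferent_max), collapse = "; ")),
            "ratiospec_selection_error")
  }
  chosen <- tab[1, ]
  wl <- if (method == "RD") c(chosen$lambda1, chosen$lambda2) else chosen$lambda1
  structure(list(wavelengths = wl, score = chosen, table = tab,
                 method = method),
            class = "wavelength_selection")
}

#' @export
print.wavelength_selection <- function(x, ...) {
  cat(sprintf("Selected %s wavelength(s): %s nm (r^2 %.6f, |slope| %.4g, leakage %.3g)\n",
              x$method, paste(x$wavelengths, collapse = "/"),
              x$score$r_squared, abs(x$score$slope), x$score$interferent_max))
  invisible(x)
}

#' Rank candidate divisor standards
#'
#' For each candidate divisor spectrum, fits the target analyte's
#' calibration through the configured method and computes a noise
#' amplification index, the mean of `1 / |A_divisor|` over the method's
#' working window (unmasked points).  Divisors are ranked by calibration
#' r^2, ties broken by lower noise amplification; divisors that leave a
#' degenerate ratio spectrum are excluded with a diagnostic.
#'
#' @param divisors List of candidate divisor [uv_spectrum()] objects.
#' @param target_spectra List of [uv_spectrum()] of the target analyte at
#'   the calibration concentrations.
#' @param concentrations Calibration concentrations (ug/mL).
#' @param config A [method_config()] for the target analyte (its
#'   `divisor_conc` is ignored; the candidates stand in).
#' @return An object of class `divisor_scan`: a ranked data frame with
#'   columns `divisor`, `rank`, `r_squared`, `noise_amplification`,
#'   `excluded`, `diagnostic`.
#' @export
divisor_scan <- function(divisors, target_spectra, concentrations, config) {
  stopifnot(inherits(config, "method_config"))
  if (length(divisors) < 1L)
    rs_stop("need at least one candidate divisor", "ratiospec_domain_error")
  window <- switch(config$method,
    RD = range(config$wavelengths),
    DD1 = config$wavelengths + c(-1, 1) * config$delta_lambda,
    MC = config$mc_range)
  rows <- lapply(divisors, function(d) {
    label <- spectrum_label(d)
    res <- tryCatch({
      sig <- vapply(target_spectra, method_signal, numeric(1),
                    config = config, divisor = d)
      fit <- fit_calibration(concentrations, sig)
      inwin <- d$wavelength >= window[1] - 1e-9 &
               d$wavelength <= window[2] + 1e-9 &
               abs(d$absorbance) >= config$epsilon
      amp <- mean(1 / abs(d$absorbance[inwin]))
      data.frame(divisor = label, r_squared = fit$r_squared,
                 noise_amplification = amp, excluded = FALSE,
                 diagnostic = "", stringsAsFactors = FALSE)
    }, ratiospec_error = function(e)
      data.frame(divisor = label, r_squared = NA_real_,
                 noise_amplification = NA_real_, excluded = TRUE,
                 diagnostic = conditionMessage(e), stringsAsFactors = FALSE))
    res
  })
  tab <- do.call(rbind, rows)
  keep <- !tab$excluded
  # rank: r2 (rounded so ties from noise-free data resolve on noise amp)
  ord <- order(tab$excluded, -round(tab$r_squared, 9),
               tab$noise_amplification)
  tab <- tab[ord, ]
  tab$rank <- ifelse(tab$excluded, NA_integer_, seq_len(nrow(tab)))
  rownames(tab) <- NULL
  structure(tab, class = c("divisor_scan", "data.frame"))
}

#' @export
print.divisor_scan <- function(x, ...) {
  cat("Divisor scan (ranked by r^2, then noise amplification):\n")
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}
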