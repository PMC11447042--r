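#' Load a spectra directory and its manifest
#'
#' Reads `manifest.csv` (columns `file`, `role`, `conc_BPL`, `conc_TST`,
#' `replicate`, `day`, `added`) and every referenced spectrum file.
#'
#' @param dir Directory written by [generate_validation_study()] or laid
#'   out the same way.
#' @return A list with `manifest` (data frame), `spectra` (named list of
#'   [uv_spectrum()] keyed by file name) and `divisors` (named by analyte).
#' @export
load_study <- function(dir) {
  mf_path <- file.path(dir, "manifest.csv")
  if (!file.exists(mf_path))
    rs_stop(sprintf("no manifest.csv in '%s'", dir), "ratiospec_io_error")
  manifest <- utils::read.csv(mf_path, stringsAsFactors = FALSE)
  spectra <- lapply(manifest$file, function(f) read_spectrum(file.path(dir, f)))
  names(spectra) <- manifest$file
  div_rows <- which(manifest$role == "divisor")
  divisors <- list()
  for (i in div_rows) {
    s <- spectra[[i]]
    a <- s$metadata$analyte
    if (is.null(a))
      a <- if (manifest$conc_BPL[i] > 0) "BPL" else "TST"
    divisors[[a]] <- s
  }
  list(manifest = manifest, spectra = spectra, divisors = divisors)
}

#' Fit the calibration models of a study
#'
#' For every method configuration, computes the method signal of each
#' calibration spectrum of the configured analyte (using the study's
#' divisor standard of the other analyte) and fits the signal-concentration
#' line.
#'
#' @param study A [load_study()] result.
#' @param configs Named list of [method_config()]
#'   (default [default_method_configs()]).
#' @return Named list of [fit_calibration()] fits.
#' @export
fit_study_calibrations <- function(study, configs = default_method_configs()) {
  lapply(configs, function(cfg) {
    div <- study$divisors[[cfg$divisor_analyte]]
    if (is.null(div))
      rs_stop(sprintf("study has no divisor spectrum for %s",
                      cfg$divisor_analyte), "ratiospec_io_error")
    conc_col <- paste0("conc_", cfg$analyte)
    rows <- which(study$manifest$role == "calibration" &
                    study$manifest[[conc_col]] > 0)
    if (length(rows) < 3L)
      rs_stop(sprintf("fewer than 3 calibration spectra for %s", cfg$analyte),
              "ratiospec_rank_error")
    sig <- vapply(rows, function(i)
      method_signal(study$spectra[[i]], cfg, div), numeric(1))
    fit_calibration(study$manifest[[conc_col]][rows], sig,
                    method_config = cfg)
  })
}

#' Quantify the non-calibration samples of a study
#'
#' Applies every fitted method to every mixture, tablet and spiked
#' spectrum and inverts the calibration to found concentrations.
#'
#' @param study A [load_study()] result.
#' @param fits Fits from [fit_study_calibrations()].
#' @param roles Manifest roles to quantify.
#' @return Long-format data frame: file, role, replicate, day, added,
#'   method, analyte, taken, found, recovery_pct.
#' @export
quantify_study <- function(study, fits,
                           roles = c("mixture", "tablet", "spiked")) {
  rows <- which(study$manifest$role %in% roles)
  out <- list()
  for (nm in names(fits)) {
    fit <- fits[[nm]]
    cfg <- fit$method_config
    div <- study$divisors[[cfg$divisor_analyte]]
    taken <- study$manifest[[paste0("conc_", cfg$analyte)]][rows]
    found <- vapply(rows, function(i) {
      sig <- method_signal(study$spectra[[i]], cfg, div)
      suppressWarnings(predict(fit, signal = sig))
    }, numeric(1))
    out[[nm]] <- data.frame(
      file = study$manifest$file[rows], role = study$manifest$role[rows],
      replicate = study$manifest$replicate[rows],
      day = study$manifest$day[rows], added = study$manifest$added[rows],
      method = nm, analyte = cfg$analyte, taken = taken, found = found,
      recovery_pct = ifelse(taken > 0, 100 * found / taken, NA_real_),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

summarize_panel <- function(q) {
  split_q <- split(q, q$method)
  rows <- lapply(names(split_q), function(nm) {
    s <- summarize_recoveries(split_q[[nm]]$recovery_pct)
    data.frame(method = nm, n = s$n, mean_recovery = s$mean_recovery,
               sd = s$sd, rsd = s$rsd, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full validation computation on a study directory
#'
#' Calibrates all six methods, quantifies the mixture panel, and produces
#' the standard validation tables: regression parameters with LOD/LOQ,
#' intra-day accuracy/repeatability (day 1), intermediate precision
#' (across days), and the standard-addition block computed on the added
#' amounts over the tablet base.
#'
#' @param dir Study directory (see [generate_validation_study()]).
#' @param configs Method configurations.
#' @return A list of data frames: `regression`, `accuracy`,
#'   `intermediate_precision`, `standard_addition`, plus `quantified`
#'   (the raw long table) and `fits`.
#' @export
validate_study <- function(dir, configs = default_method_configs()) {
  study <- load_study(dir)
  fits <- fit_study_calibrations(study, configs)
  q <- quantify_study(study, fits)
  mixtures <- q[q$role == "mixture", ]
  intra <- summarize_panel(mixtures[mixtures$day == 1, ])
  inter <- summarize_panel(mixtures)
  # standard addition: recovery of the added amount over the tablet base
  sa_rows <- list()
  for (nm in names(fits)) {
    qa <- q[q$method == nm, ]
    base_found <- qa$found[qa$role == "tablet"][1]
    sp <- qa[qa$role == "spiked", ]
    if (!nrow(sp) || is.na(base_found)) next
    level_means <- tapply(sp$found, sp$added, mean)
    added <- as.numeric(names(level_means))
    rec <- standard_addition_recovery(base_found, as.numeric(level_means),
                                      added)
    s <- summarize_recoveries(rec)
    sa_rows[[nm]] <- data.frame(method = nm,
                                added = paste(added, collapse = "/"),
                                mean_recovery = s$mean_recovery,
                                sd = s$sd, rsd = s$rsd,
                                stringsAsFactors = FALSE)
  }
  list(regression = calibration_report(fits),
       accuracy = intra,
       intermediate_precision = inter,
       standard_addition = do.call(rbind, c(sa_rows,
                                            list(make.row.names = FALSE))),
       quantified = q, fits = fits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a pipeline command
#'
#' The programmatic core behind the command-line interface.  Commands:
#' \describe{
#'   \item{simulate}{Generate a synthetic validation study into
#'     `config$out` (requires `config$seed`).}
#'   \item{calibrate}{Fit the six calibrations on `config$spectra_dir` and
#'     write a regression report.}
#'   \item{quantify}{Write found concentrations for every mixture, tablet
#'     and spiked spectrum.}
#'   \item{validate}{Write the full validation tables.}
#'   \item{select}{Write wavelength-selection and divisor-scan tables for
#'     both analytes.}
#' }
#' Every run writes `run.log` in the output directory with the package
#' version, the command, the seed and an echo of the configuration and of
#' the exact method configurations used.
#'
#' @param command One of `"simulate"`, `"calibrate"`, `"quantify"`,
#'   `"validate"`, `"select"`.
#' @param config Named list: `out` (output directory), `spectra_dir`
#'   (input study, read commands), `seed` (integer, required by
#'   `simulate`), `noise_sd` (AU, default 0.002), `baseline` (AU, default
#'   0), `configs` (optional list of [method_config()]).
#' @return Invisibly, the command's main result (manifest, tables, ...).
#' @export
run_pipeline <- function(command = c("simulate", "calibrate", "quantify",
                                     "validate", "select"),
                         config = list()) {
  command <- match.arg(command)
  out <- config$out %||% "."
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  configs <- config$configs %||% default_method_configs()
  if (command == "simulate" && is.null(config$seed))
    rs_stop("simulate requires an explicit seed", "ratiospec_usage_error")
  if (command != "simulate") {
    if (is.null(config$spectra_dir))
      rs_stop(sprintf("%s requires spectra_dir", command),
              "ratiospec_usage_error")
    if (!dir.exists(config$spectra_dir))
      rs_stop(sprintf("spectra_dir '%s' does not exist", config$spectra_dir),
              "ratiospec_io_error")
  }
  write_tables <- function(tabs) {
    for (nm in names(tabs))
      if (is.data.frame(tabs[[nm]]))
        utils::write.csv(format(tabs[[nm]], digits = 15),
                         file.path(out, paste0(nm, ".csv")),
                         row.names = FALSE, quote = FALSE)
  }
  result <- switch(command,
    simulate = {
      nm <- noise_model(config$noise_sd %||% 0.002,
                        config$baseline %||% 0, config$seed)
      generate_validation_study(out, nm)
    },
    calibrate = {
      study <- load_study(config$spectra_dir)
      fits <- fit_study_calibrations(study, configs)
      tab <- calibration_report(fits)
      write_tables(list(regression = tab))
      tab
    },
    quantify = {
      study <- load_study(config$spectra_dir)
      fits <- fit_study_calibrations(study, configs)
      q <- quantify_study(study, fits)
      write_tables(list(quantified = q))
      q
    },
    validate = {
      v <- validate_study(config$spectra_dir, configs)
      write_tables(v[c("regression", "accuracy", "intermediate_precision",
                       "standard_addition", "quantified")])
      v
    },
    select = {
      study <- load_study(config$spectra_dir)
      tabs <- list()
      for (analyte in c("BPL", "TST")) {
        other <- setdiff(c("BPL", "TST"), analyte)
        div <- study$divisors[[other]]
        conc_col <- paste0("conc_", analyte)
        cal <- which(study$manifest$role == "calibration" &
                       study$manifest[[conc_col]] > 0)
        icol <- paste0("conc_", other)
        ical <- which(study$manifest$role == "calibration" &
                        study$manifest[[icol]] > 0)
        target <- list(
          spectra = lapply(study$spectra[cal], ratio_spectrum, divisor = div),
          concentrations = study$manifest[[conc_col]][cal])
        interferent <- list(
          spectra = lapply(study$spectra[ical], ratio_spectrum, divisor = div))
        cand <- seq(205, 300, by = 5)
        for (m in c("RD", "DD1", "MC")) {
          sel <- tryCatch(
            select_signal_wavelengths(target, interferent, m, cand,
                                      mc_range = c(200, 305)),
            ratiospec_selection_error = function(e) NULL)
          if (!is.null(sel))
            tabs[[paste0("select_", analyte, "_", m)]] <- sel$table
        }
      }
      write_tables(tabs)
      tabs
    })
  log_lines <- c(
    sprintf("ratiospec %s", as.character(utils::packageVersion("ratiospec"))),
    sprintf("command: %s", command),
    sprintf("time: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("seed: %s", config$seed %||% "none"),
    "config:",
    paste0("  ", strsplit(yaml::as.yaml(
      config[setdiff(names(config), "configs")]), "\n")[[1]]),
    "method configs:",
    paste0("  ", strsplit(yaml::as.yaml(lapply(configs, unclass)),
                          "\n")[[1]]))
  writeLines(log_lines, file.path(out, "run.log"))
  invisible(result)
}
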