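#' Gaussian-band absorber profile
#'
#' A synthetic molar-absorptivity-like curve: the unit-concentration
#' absorbance is a sum of Gaussian bands on a wavelength grid.  Together
#' with Beer-Lambert additivity this generates mixture spectra that are
#' exactly linear in concentration, the regime the ratio-spectra methods
#' assume.
#'
#' @param label Analyte label.
#' @param bands Data frame with columns `center` (nm), `width` (nm, Gaussian
#'   SD, > 0), `height` (AU per ug/mL, >= 0); one row per band.
#' @param grid Wavelength grid in nm (default 1 nm over 200-400 nm).
#' @return An object of class `component_profile`.
#' @export
component_profile <- function(label, bands,
                              grid = seq(200, 400, by = 1)) {
  bands <- as.data.frame(bands)
  stopifnot(all(c("center", "width", "height") %in% names(bands)))
  if (any(bands$width <= 0) || any(bands$height < 0))
    rs_stop("band widths must be > 0 and heights >= 0",
            "ratiospec_domain_error")
  structure(list(label = label, bands = bands, grid = as.numeric(grid)),
            class = "component_profile")
}

#' @export
print.component_profile <- function(x, ...) {
  cat(sprintf("Component profile '%s': %d Gaussian band(s), grid %g-%g nm\n",
              x$label, nrow(x$bands), min(x$grid), max(x$grid)))
  print(x$bands, row.names = FALSE)
  invisible(x)
}

unit_absorbance <- function(profile) {
  a <- numeric(length(profile$grid))
  for (i in seq_len(nrow(profile$bands))) {
    b <- profile$bands[i, ]
    a <- a + b$height * exp(-(profile$grid - b$center)^2 / (2 * b$width^2))
  }
  a
}

#' Pure-component spectrum at a given concentration
#'
#' Evaluates the Beer-Lambert forward model: absorbance is the profile's
#' unit-concentration curve scaled by the concentration, exactly linear.
#'
#' @param profile A [component_profile()].
#' @param concentration Concentration in ug/mL, >= 0.
#' @return A [uv_spectrum()] with `analyte` and `concentration` metadata.
#' @export
component_spectrum <- function(profile, concentration) {
  stopifnot(inherits(profile, "component_profile"))
  if (concentration < 0)
    rs_stop("concentration must be >= 0", "ratiospec_domain_error")
  uv_spectrum(profile$grid, concentration * unit_absorbance(profile),
              list(analyte = profile$label, concentration = concentration))
}

#' Instrument noise model
#'
#' Additive white Gaussian noise on absorbance plus an optional constant
#' baseline offset per spectrum.  Every stochastic operation takes its seed
#' from here; there is no hidden global generator state (the calling R
#' session's RNG state is saved and restored around each draw).
#'
#' @param additive_sd Noise SD in AU (default 0.002, a typical benchtop
#'   photometric noise level).
#' @param baseline_drift Constant absorbance offset in AU added to each
#'   spectrum (default 0).
#' @param seed Integer seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(additive_sd = 0.002, baseline_drift = 0, seed = 1L) {
  if (additive_sd < 0)
    rs_stop("additive_sd must be >= 0", "ratiospec_domain_error")
  structure(list(additive_sd = additive_sd,
                 baseline_drift = baseline_drift,
                 seed = as.integer(seed)),
            class = "noise_model")
}

# run code under a temporary seed, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Simulate a mixture spectrum
#'
#' Sums the Beer-Lambert component spectra, adds the noise model's baseline
#' offset and seeded additive white noise.  With `noise = NULL` the exact
#' noise-free mixture is returned.  Metadata records the true
#' concentrations (as `conc_<label>`) and the seed used.
#'
#' @param profiles List of [component_profile()] on a shared grid.
#' @param concentrations Numeric vector of concentrations (ug/mL), one per
#'   profile.
#' @param noise A [noise_model()] or `NULL` for noise-free.
#' @return A [uv_spectrum()].
#' @export
simulate_mixture <- function(profiles, concentrations, noise = NULL) {
  stopifnot(all(vapply(profiles, inherits, logical(1), "component_profile")))
  if (length(profiles) != length(concentrations))
    rs_stop("one concentration per profile is required",
            "ratiospec_domain_error")
  grid <- profiles[[1]]$grid
  for (p in profiles)
    if (length(p$grid) != length(grid) || any(abs(p$grid - grid) > 1e-9))
      rs_stop("component profiles must share a wavelength grid",
              "ratiospec_grid_error")
  ab <- numeric(length(grid))
  meta <- list()
  for (i in seq_along(profiles)) {
    if (concentrations[i] < 0)
      rs_stop("concentration must be >= 0", "ratiospec_domain_error")
    ab <- ab + concentrations[i] * unit_absorbance(profiles[[i]])
    meta[[paste0("conc_", profiles[[i]]$label)]] <- concentrations[i]
  }
  if (!is.null(noise)) {
    stopifnot(inherits(noise, "noise_model"))
    ab <- ab + noise$baseline_drift +
      with_local_seed(noise$seed,
                      stats::rnorm(length(grid), 0, noise$additive_sd))
    meta$seed <- noise$seed
  }
  uv_spectrum(grid, ab, meta)
}

#' Default overlapping absorber pair
#'
#' The bundled synthetic stand-ins for the bisoprolol-like (BPL) and
#' telmisartan-like (TST) absorptivity curves (the true curves are not
#' published numerically).  They reproduce the selectivity geometry of the
#' assay: BPL is a weak absorber peaking near 223 nm with negligible
#' absorbance above ~290 nm; TST is a strong broad absorber spanning
#' ~210-330 nm that dominates where BPL's ratio-difference pair
#' (210/224 nm) lies; the two zero-order spectra overlap heavily below
#' 290 nm.
#'
#' @return List with elements `bpl` and `tst`, both [component_profile()].
#' @export
default_profiles <- function() {
  list(
    bpl = component_profile("BPL", data.frame(
      center = c(223, 271), width = c(8, 15), height = c(0.065, 0.006))),
    tst = component_profile("TST", data.frame(
      center = c(212, 235, 296), width = c(11, 16, 15),
      height = c(0.020, 0.026, 0.030)))
  )
}

#' Default validation study design
#'
#' The study geometry of the assay: eight-level calibrations over
#' 2-20 ug/mL (BPL) and 4-32 ug/mL (TST), five mixture ratios at the 1:8
#' dose ratio, three replicates on each of three days, and a tablet matrix
#' (2 + 16 ug/mL) with spikes of 4, 8 and 12 ug/mL of both analytes.
#'
#' @return A list understood by [generate_validation_study()].
#' @export
default_study_design <- function() {
  list(
    calibration = list(BPL = c(2, 4, 6, 8, 10, 12, 16, 20),
                       TST = c(4, 8, 12, 16, 20, 24, 28, 32)),
    mixtures = data.frame(BPL = c(4, 3.5, 3, 2.5, 2),
                          TST = c(32, 28, 24, 20, 16)),
    replicates = 3L,
    days = 3L,
    tablet = c(BPL = 2, TST = 16),
    spikes = c(4, 8, 12),
    divisors = c(TST = 16, BPL = 10)
  )
}

#' Generate a complete synthetic validation study on disk
#'
#' Writes a directory of spectrum CSV files plus a `manifest.csv` with the
#' full study geometry: per-analyte calibration series, noise-free divisor
#' standards, mixture replicates across days, and a tablet base with
#' spiked samples for standard addition.  Per-file seeds are derived
#' deterministically from the noise model's seed, so identical calls
#' produce byte-identical output.
#'
#' @param dir Output directory (created if needed).
#' @param noise A [noise_model()]; its `additive_sd` may be 0 for a
#'   noise-free study.
#' @param design Study design list, see [default_study_design()].
#' @param profiles Absorber pair, see [default_profiles()].
#' @return Invisibly, the manifest data frame.
#' @export
generate_validation_study <- function(dir, noise = noise_model(),
                                      design = default_study_design(),
                                      profiles = default_profiles()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labels <- vapply(profiles, function(p) p$label, character(1))
  names(profiles) <- labels
  manifest <- list()
  counter <- 0L
  emit <- function(file, role, conc, replicate = NA, day = NA,
                   added = NA, spectrum) {
    write_spectrum(spectrum, file.path(dir, file))
    manifest[[length(manifest) + 1L]] <<- data.frame(
      file = file, role = role,
      conc_BPL = conc[["BPL"]], conc_TST = conc[["TST"]],
      replicate = replicate, day = day, added = added,
      stringsAsFactors = FALSE)
  }
  mix <- function(conc, seed_offset) {
    counter <<- counter + 1L
    nm <- noise_model(noise$additive_sd, noise$baseline_drift,
                      noise$seed + counter)
    simulate_mixture(unname(profiles[c("BPL", "TST")]),
                     c(conc[["BPL"]], conc[["TST"]]), nm)
  }
  # divisor standards: noise-free reference spectra
  for (a in names(design$divisors)) {
    s <- component_spectrum(profiles[[a]], design$divisors[[a]])
    conc <- c(BPL = 0, TST = 0); conc[a] <- design$divisors[[a]]
    emit(sprintf("divisor_%s_%g.csv", a, design$divisors[[a]]),
         "divisor", conc, spectrum = s)
  }
  # calibration series (one noisy spectrum per level)
  for (a in names(design$calibration)) {
    for (c0 in design$calibration[[a]]) {
      conc <- c(BPL = 0, TST = 0); conc[a] <- c0
      emit(sprintf("cal_%s_%g.csv", a, c0), "calibration", conc,
           spectrum = mix(conc))
    }
  }
  # mixture panel: ratios x replicates x days
  for (i in seq_len(nrow(design$mixtures)))
    for (d in seq_len(design$days))
      for (r in seq_len(design$replicates)) {
        conc <- c(BPL = design$mixtures$BPL[i], TST = design$mixtures$TST[i])
        emit(sprintf("mix_%d_day%d_rep%d.csv", i, d, r), "mixture", conc,
             replicate = r, day = d, spectrum = mix(conc))
      }
  # tablet base + standard-addition spikes (non-absorbing excipients)
  base <- design$tablet
  emit("tablet_base.csv", "tablet", c(BPL = base[["BPL"]], TST = base[["TST"]]),
       spectrum = mix(base))
  for (sp in design$spikes)
    for (r in seq_len(design$replicates)) {
      conc <- c(BPL = base[["BPL"]] + sp, TST = base[["TST"]] + sp)
      emit(sprintf("spiked_%g_rep%d.csv", sp, r), "spiked", conc,
           replicate = r, added = sp, spectrum = mix(conc))
    }
  manifest <- do.call(rbind, manifest)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
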