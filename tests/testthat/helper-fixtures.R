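# shared fixture builders: everything is generated in code at test time

fixture_profiles <- function() default_profiles()

fixture_divisors <- function(p = fixture_profiles()) {
  list(TST = component_spectrum(p$tst, 16),
       BPL = component_spectrum(p$bpl, 10))
}

cal_levels <- function(analyte) {
  if (analyte == "BPL") c(2, 4, 6, 8, 10, 12, 16, 20)
  else c(4, 8, 12, 16, 20, 24, 28, 32)
}

# noise-free calibration fits for all six bundled methods
fixture_fits <- function(p = fixture_profiles(),
                         configs = default_method_configs()) {
  divs <- fixture_divisors(p)
  lapply(configs, function(cfg) {
    prof <- if (cfg$analyte == "BPL") p$bpl else p$tst
    concs <- cal_levels(cfg$analyte)
    sig <- vapply(concs, function(c0)
      method_signal(component_spectrum(prof, c0), cfg,
                    divs[[cfg$divisor_analyte]]), numeric(1))
    fit_calibration(concs, sig, method_config = cfg)
  })
}

# a small synthetic ratio spectrum with a prescribed amplitude function
fixture_ratio <- function(f, grid = seq(200, 300, by = 1),
                          mask = rep(TRUE, length(grid))) {
  amp <- ifelse(mask, f(grid), NA_real_)
  ratiospec:::new_ratio_spectrum(grid, amp, mask, "synthetic", "ratio")
}
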