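test_that("recovery arithmetic", {
  expect_equal(percent_recovery(4, 4), 100)
  expect_equal(percent_recovery(4.01, 4.00), 100.25)
  expect_error(percent_recovery(1, 0), class = "ratiospec_domain_error")

  expect_equal(standard_addition_recovery(2, 2 + 4, 4), 100)
  expect_equal(standard_addition_recovery(2.00, 5.982, 4), 99.55)
  expect_error(standard_addition_recovery(2, 5, -1),
               class = "ratiospec_domain_error")
})

test_that("recovery summaries reproduce the published per-level arithmetic", {
  # tablet panel, BPL by ratio difference
  s <- summarize_recoveries(c(100.18, 99.62, 100.01, 100.22, 100.52))
  expect_equal(s$mean_recovery, 100.11, tolerance = 0.01)
  # standard addition, TST by mean centering
  s2 <- summarize_recoveries(c(98.76, 99.27, 99.87))
  expect_equal(s2$mean_recovery, 99.30, tolerance = 0.01)
  expect_equal(s2$rsd, 0.560, tolerance = 0.005)
  expect_equal(s2$rsd, 100 * s2$sd / s2$mean_recovery)

  s3 <- summarize_recoveries(rep(100.2, 4))
  expect_equal(s3$sd, 0)
  expect_equal(s3$rsd, 0)
  expect_error(summarize_recoveries(100), class = "ratiospec_domain_error")
})

test_that("pooled t matches direct formula evaluation to 1e-12", {
  direct_t <- function(ma, sa, na, mb, sb, nb) {
    sp2 <- ((na - 1) * sa^2 + (nb - 1) * sb^2) / (na + nb - 2)
    abs(ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  }
  cases <- list(c(1, 1, 5, 2, 1, 5), c(100.04, 0.469, 5, 100.51, 0.774, 5),
                c(10, 2, 8, 11, 0.5, 3), c(0, 1.3, 4, -2, 2.6, 9))
  for (cs in cases) {
    r <- two_sample_t(cs[1], cs[2], cs[3], cs[4], cs[5], cs[6])
    expect_equal(r$t_stat, do.call(direct_t, as.list(cs)), tolerance = 1e-12)
    expect_equal(r$df_t, cs[3] + cs[6] - 2)
  }
  # the benchmark comparison: critical value 2.306 at df = 8
  r <- two_sample_t(100.04, 0.469, 5, 100.51, 0.774, 5)
  expect_equal(r$t_stat, 1.16, tolerance = 0.005)
  expect_equal(r$t_critical, 2.306, tolerance = 5e-4)
  expect_false(r$significant)
})

test_that("t edge cases: identical groups and zero-variance groups", {
  expect_equal(two_sample_t(5, 1, 5, 5, 1, 5)$t_stat, 0)
  expect_equal(two_sample_t(5, 0, 5, 5, 0, 5)$t_stat, 0)
  z <- two_sample_t(5, 0, 5, 6, 0, 5)
  expect_true(z$infinite)
  expect_equal(z$t_stat, Inf)
  expect_error(two_sample_t(1, 1, 1, 2, 1, 5),
               class = "ratiospec_domain_error")
})

test_that("F ratio is larger/smaller, order-invariant, matches qf critical", {
  expect_equal(f_ratio(2, 2)$f_stat, 1)
  r <- f_ratio(0.294, 0.436)
  expect_equal(r$f_stat, 0.436 / 0.294, tolerance = 1e-12)
  expect_equal(r$f_stat, 1.483, tolerance = 0.001)
  expect_equal(r$f_critical, 6.388, tolerance = 5e-4)
  expect_equal(f_ratio(0.436, 0.294)$f_stat, r$f_stat)
  expect_gte(f_ratio(1e-3, 5)$f_stat, 1)
  expect_equal(f_ratio(0.2, 0.1, n_a = 7, n_b = 4)$df_f, c(6, 3))
  expect_error(f_ratio(0, 1), class = "ratiospec_domain_error")
})

test_that("type-I error of the t comparison is 5% under the null", {
  n_sim <- 10000
  rejections <- with(new.env(), {
    set.seed(20240901)
    mean(vapply(seq_len(n_sim), function(i) {
      a <- rnorm(5, 100, 0.5)
      b <- rnorm(5, 100, 0.5)
      two_sample_t(mean(a), sd(a), 5, mean(b), sd(b), 5)$significant
    }, logical(1)))
  })
  expect_lt(abs(rejections - 0.05), 0.01)
})

test_that("wavelength selection equals the exhaustive lm-based oracle", {
  p <- fixture_profiles()
  div <- fixture_divisors(p)$TST
  concs <- c(2, 6, 10, 14, 18)
  noise <- lapply(seq_along(concs), function(i) noise_model(5e-4, seed = 40 + i))
  target <- list(
    spectra = lapply(seq_along(concs), function(i)
      ratio_spectrum(simulate_mixture(list(p$bpl), concs[i], noise[[i]]), div)),
    concentrations = concs)
  interferent <- list(
    spectra = lapply(c(8, 16, 24), function(c0)
      ratio_spectrum(simulate_mixture(list(p$tst), c0,
                                      noise_model(5e-4, seed = 90 + c0)), div)))
  cand <- seq(205, 285, by = 5)
  sel <- select_signal_wavelengths(target, interferent, "RD", cand)

  # independent exhaustive search: loop over all pairs with lm()
  amp <- function(r, wl) r$amplitude[which(abs(r$wavelength - wl) <= 1e-6)]
  best <- NULL
  for (i in seq_along(cand)) for (j in seq_along(cand)) {
    if (j <= i) next
    sig <- vapply(target$spectra, function(r)
      amp(r, cand[i]) - amp(r, cand[j]), numeric(1))
    leak <- max(vapply(interferent$spectra, function(r)
      abs(amp(r, cand[i]) - amp(r, cand[j])), numeric(1)))
    f <- lm(sig ~ concs)
    mid_sig <- abs(sum(coef(f) * c(1, mean(range(concs)))))
    if (leak > 0.01 * mid_sig) next
    r2 <- summary(f)$r.squared
    key <- c(r2, abs(coef(f)[2]))
    if (is.null(best) || key[1] > best$key[1] ||
        (key[1] == best$key[1] && key[2] > best$key[2]))
      best <- list(key = key, pair = c(cand[i], cand[j]))
  }
  expect_equal(sort(sel$wavelengths), sort(best$pair))
  expect_equal(sel$score$r_squared, unname(best$key[1]), tolerance = 1e-9)

  # noise-free: interferent leakage at the chosen pair is numerically zero
  target0 <- list(
    spectra = lapply(concs, function(c0)
      ratio_spectrum(component_spectrum(p$bpl, c0), div)),
    concentrations = concs)
  interferent0 <- list(
    spectra = lapply(c(8, 16, 24), function(c0)
      ratio_spectrum(component_spectrum(p$tst, c0), div)))
  sel0 <- select_signal_wavelengths(target0, interferent0, "RD", cand)
  expect_lt(sel0$score$interferent_max, 1e-9)
})

test_that("wavelength selection handles single candidates and masked grids", {
  p <- fixture_profiles()
  div <- fixture_divisors(p)$TST
  concs <- c(4, 10, 16)
  target <- list(
    spectra = lapply(concs, function(c0)
      ratio_spectrum(component_spectrum(p$bpl, c0), div)),
    concentrations = concs)
  interferent <- list(
    spectra = list(ratio_spectrum(component_spectrum(p$tst, 16), div)))
  one <- select_signal_wavelengths(target, interferent, "MC", 223,
                                   mc_range = c(200, 305))
  expect_equal(one$wavelengths, 223)
  expect_equal(nrow(one$table), 1)

  # candidates in a masked region (divisor below the guard past 340 nm)
  expect_error(
    select_signal_wavelengths(target, interferent, "DD1", c(350, 360)),
    class = "ratiospec_selection_error")
})

test_that("divisor scan ranks by r^2 then noise amplification", {
  p <- fixture_profiles()
  cfg <- default_method_configs()$BPL_RD
  concs <- c(2, 6, 10, 14, 18)
  targets <- lapply(concs, function(c0) component_spectrum(p$bpl, c0))
  divisors <- lapply(c(12, 16, 20), function(c0)
    component_spectrum(p$tst, c0))
  scan <- divisor_scan(divisors, targets, concs, cfg)
  expect_s3_class(scan, "divisor_scan")
  # noise-free: all r^2 = 1, ranking falls to noise amplification, which
  # decreases with divisor concentration
  expect_true(all(abs(scan$r_squared - 1) < 1e-9))
  expect_equal(scan$divisor[1], "TST 20 ug/mL")
  expect_equal(scan$divisor[3], "TST 12 ug/mL")
  expect_true(all(diff(scan$noise_amplification) > 0))

  single <- divisor_scan(divisors[2], targets, concs, cfg)
  expect_equal(single$rank[1], 1L)

  # a divisor that is zero over the working range is excluded
  dead <- uv_spectrum(p$tst$grid, rep(0, length(p$tst$grid)),
                      list(analyte = "blank", concentration = 0))
  scan2 <- divisor_scan(list(divisors[[2]], dead), targets, concs, cfg)
  expect_true(scan2$excluded[scan2$divisor == "blank 0 ug/mL"])
  expect_match(scan2$diagnostic[scan2$excluded], "unmasked")
})
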