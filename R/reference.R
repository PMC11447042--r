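#' Published validation benchmarks for the BPL/TST assay
#'
#' The printed regression, recovery and method-comparison tables of the
#' published bisoprolol fumarate (BPL) / telmisartan (TST) ratio-spectra
#' assay, as machine-readable data frames.  They serve as arithmetic
#' benchmarks: the package's summary statistics (means, RSDs, LOD/LOQ
#' consistency, t and F) can be recomputed from these printed inputs and
#' compared with the printed summaries.  Absolute slopes and limits depend
#' on the physical absorptivity curves of the two drugs and are not
#' reproducible from synthetic profiles; the table arithmetic is.
#'
#' Components:
#' \describe{
#'   \item{regression}{Per method/analyte: wavelengths, linearity range,
#'     slope, intercept, r^2, LOD, LOQ (ug/mL).}
#'   \item{accuracy}{Intra-day recovery panel: five mixture levels
#'     (BPL + TST, ug/mL) with per-level %R for the six methods, plus the
#'     printed mean and RSD rows.}
#'   \item{precision}{Inter-day (intermediate precision) panel, same
#'     layout.}
#'   \item{tablets}{Laboratory-prepared tablet panel, same layout.}
#'   \item{standard_addition}{Standard-addition recoveries: base 2 + 16
#'     ug/mL, added 4/8/12 ug/mL per analyte and method, with printed mean
#'     and RSD.}
#'   \item{comparison}{Method-comparison block: mean, n, SD, variance per
#'     method and for the reported reference method, printed t (critical
#'     2.306) and F (critical 6.388).}
#' }
#'
#' @return A named list of data frames (see Details).
#' @export
reference_tables <- function() {
  methods6 <- c("BPL_RD", "BPL_DD1", "BPL_MC", "TST_RD", "TST_DD1", "TST_MC")

  regression <- data.frame(
    method = methods6,
    analyte = rep(c("BPL", "TST"), each = 3),
    wavelengths = c("224-210", "232", "223", "265-255", "243", "245"),
    range_low = c(2, 2, 2, 4, 4, 4),
    range_high = c(20, 20, 20, 32, 32, 32),
    slope = c(0.0110, 0.0315, 0.0243, 0.5845, 2.2634, 2.2829),
    intercept = c(0.0206, 0.0617, 0.0363, 0.2964, 1.8242, 1.7896),
    r_squared = c(0.9999, 0.9999, 0.9999, 0.9997, 0.9998, 0.9995),
    lod = c(0.2433, 0.3128, 0.4056, 0.5965, 0.9141, 0.7066),
    loq = c(0.7372, 0.9478, 1.2291, 1.8076, 2.7700, 2.1411),
    stringsAsFactors = FALSE)

  panel <- function(bpl, tst, rec, mean_row, rsd_row) {
    out <- data.frame(conc_BPL = bpl, conc_TST = tst)
    out <- cbind(out, as.data.frame(rec))
    names(out)[-(1:2)] <- methods6
    attr(out, "printed_mean") <- stats::setNames(mean_row, methods6)
    attr(out, "printed_rsd") <- stats::setNames(rsd_row, methods6)
    out
  }

  accuracy <- panel(
    bpl = c(4, 3.5, 3, 2.5, 2), tst = c(32, 28, 24, 20, 16),
    rec = cbind(
      c(100.24,  99.80,  99.94, 100.39, 100.51),
      c(100.19, 100.15,  99.87, 100.79, 100.59),
      c( 99.98,  99.65,  99.94, 100.72, 100.78),
      c( 99.24,  98.92, 100.65, 100.13,  99.68),
      c( 99.47,  99.93, 100.31, 100.05, 100.31),
      c( 99.33,  99.33,  99.75,  99.47,  99.69)),
    mean_row = c(100.17, 100.32, 100.21, 99.72, 100.01, 99.51),
    rsd_row = c(0.298, 0.366, 0.505, 0.692, 0.346, 0.198))

  precision <- panel(
    bpl = c(4, 3.5, 3, 2.5, 2), tst = c(32, 28, 24, 20, 16),
    rec = cbind(
      c(100.22,  99.65, 100.56,  99.96, 101.08),
      c(100.04, 101.18, 101.28, 100.89, 100.54),
      c(100.44,  99.54, 101.03, 100.24, 101.33),
      c(100.63,  99.03, 101.10, 100.80, 100.77),
      c(100.30, 101.31, 100.88,  99.60, 101.45),
      c( 99.24, 100.69, 100.27,  98.94, 100.81)),
    mean_row = c(100.29, 100.79, 100.51, 100.46, 100.71, 99.99),
    rsd_row = c(0.549, 0.503, 0.697, 0.818, 0.759, 0.852))

  tablets <- panel(
    bpl = c(4, 3.5, 3, 2.5, 2), tst = c(32, 28, 24, 20, 16),
    rec = cbind(
      c(100.18,  99.62, 100.01, 100.22, 100.52),
      c(100.12, 100.56, 100.45, 100.94, 100.71),
      c(100.01, 100.01, 100.09, 100.62, 100.71),
      c( 99.95,  99.78, 100.48, 101.19,  99.96),
      c( 99.84, 100.52, 100.35,  99.87, 100.61),
      c( 99.24,  99.91,  99.76,  99.25,  99.98)),
    mean_row = c(100.11, 100.56, 100.29, 100.27, 100.24, 99.63),
    rsd_row = c(0.330, 0.305, 0.346, 0.573, 0.359, 0.359))

  standard_addition <- data.frame(
    taken_BPL = 2, taken_TST = 16,
    added = c(4, 8, 12),
    BPL_RD = c(99.56, 100.53, 100.40),
    BPL_DD1 = c(99.46, 99.65, 99.71),
    BPL_MC = c(99.32, 100.47, 100.16),
    TST_RD = c(99.37, 98.49, 98.74),
    TST_DD1 = c(100.59, 99.47, 100.69),
    TST_MC = c(98.76, 99.27, 99.87))
  attr(standard_addition, "printed_mean") <- stats::setNames(
    c(100.16, 99.61, 99.99, 98.87, 100.25, 99.30), methods6)
  attr(standard_addition, "printed_rsd") <- stats::setNames(
    c(0.525, 0.134, 0.593, 0.459, 0.676, 0.560), methods6)

  comparison <- data.frame(
    method = c(methods6[1:3], "BPL_reported", methods6[4:6], "TST_reported"),
    analyte = rep(c("BPL", "TST"), each = 4),
    mean = c(100.04, 100.66, 100.22, 100.51, 100.31, 100.45, 99.74, 100.05),
    n = rep(5L, 8),
    sd = c(0.469, 0.505, 0.398, 0.774, 0.543, 0.542, 0.650, 0.660),
    rsd = c(0.469, 0.502, 0.397, 0.770, 0.541, 0.540, 0.651, 0.660),
    variance = c(0.220, 0.255, 0.158, 0.599, 0.294, 0.294, 0.422, 0.436),
    t_stat = c(1.160, 0.106, 0.752, NA, 0.665, 1.053, 0.757, NA),
    f_stat = c(2.719, 2.347, 3.789, NA, 1.482, 1.484, 1.034, NA),
    stringsAsFactors = FALSE)
  attr(comparison, "t_critical") <- 2.306
  attr(comparison, "f_critical") <- 6.388

  list(regression = regression, accuracy = accuracy, precision = precision,
       tablets = tablets, standard_addition = standard_addition,
       comparison = comparison)
}
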