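#' Absorbance spectrum on a regular wavelength grid
#'
#' Constructs a `uv_spectrum`, the basic I/O currency of the package: a
#' sampled absorbance curve on a strictly ascending, regularly spaced
#' wavelength grid.  All downstream transforms (ratio spectra, derivative,
#' mean centering) assume this representation.
#'
#' @param wavelength Numeric vector of wavelengths in nm, strictly
#'   ascending with constant spacing (to within 1e-9 nm).
#' @param absorbance Numeric vector of absorbances in AU, same length.
#' @param metadata Named list of free-form labels (e.g. `analyte`,
#'   `concentration` in ug/mL, `replicate`).
#'
#' @return An object of class `uv_spectrum`: a list with elements
#'   `wavelength`, `absorbance`, `metadata`.
#' @examples
#' s <- uv_spectrum(200:210, runif(11), list(analyte = "BPL"))
#' print(s)
#' @export
uv_spectrum <- function(wavelength, absorbance, metadata = list()) {
  wavelength <- as.numeric(wavelength)
  absorbance <- as.numeric(absorbance)
  if (length(wavelength) != length(absorbance))
    rs_stop("wavelength and absorbance must have the same length",
            "ratiospec_grid_error")
  if (length(wavelength) < 3L)
    rs_stop("a spectrum needs at least 3 samples", "ratiospec_grid_error")
  if (anyNA(wavelength) || anyNA(absorbance))
    rs_stop("NA values are not allowed in a spectrum", "ratiospec_parse_error")
  d <- diff(wavelength)
  if (any(d <= 0)) {
    if (any(d == 0))
      rs_stop("duplicate wavelength in grid", "ratiospec_grid_error")
    rs_stop("wavelengths must be strictly increasing", "ratiospec_grid_error")
  }
  if (max(d) - min(d) > 1e-9)
    rs_stop(sprintf("irregular grid spacing (spread %.3g nm exceeds 1e-9)",
                    max(d) - min(d)), "ratiospec_grid_error")
  structure(list(wavelength = wavelength, absorbance = absorbance,
                 metadata = as.list(metadata)),
            class = "uv_spectrum")
}

#' @export
print.uv_spectrum <- function(x, ...) {
  cat(sprintf("UV spectrum: %d points, %.7g-%.7g nm (step %.7g nm)\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              grid_step(x)))
  if (length(x$metadata)) {
    meta <- paste(names(x$metadata), unlist(lapply(x$metadata, format)),
                  sep = "=", collapse = ", ")
    cat("  metadata:", meta, "\n")
  }
  cat(sprintf("  absorbance range: %.5g to %.5g AU\n",
              min(x$absorbance), max(x$absorbance)))
  invisible(x)
}

#' @export
as.data.frame.uv_spectrum <- function(x, ...) {
  data.frame(wavelength = x$wavelength, absorbance = x$absorbance)
}

#' @export
plot.uv_spectrum <- function(x, ..., xlab = "Wavelength (nm)",
                             ylab = "Absorbance (AU)", type = "l") {
  graphics::plot(x$wavelength, x$absorbance, type = type,
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

grid_step <- function(s) mean(diff(s$wavelength))

#' Read a spectrum from a two-column text table
#'
#' Parses the lowest-common-denominator instrument export: two numeric
#' columns (wavelength nm, absorbance AU), comma-, tab- or
#' whitespace-separated, with optional header line and optional
#' `# key=value` comment lines carrying metadata.  Rows are sorted
#' ascending by wavelength before the grid invariants are enforced.
#'
#' @param path Path to the text file.
#' @return A [uv_spectrum()].
#' @seealso [write_spectrum()]
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path))
    rs_stop(sprintf("cannot read spectrum file '%s'", path),
            "ratiospec_io_error")
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  is_comment <- startsWith(trimws(lines), "#")
  for (ln in lines[is_comment]) {
    body <- trimws(sub("^\\s*#", "", ln))
    if (grepl("=", body, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", body))
      val <- trimws(sub("^[^=]*=", "", body))
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (!is.na(num)) num else val
    }
  }
  data_lines <- lines[!is_comment & nzchar(trimws(lines))]
  if (!length(data_lines))
    rs_stop(sprintf("no data rows in '%s'", path), "ratiospec_parse_error")
  parse_row <- function(ln) strsplit(trimws(ln), "[,\t ]+")[[1]]
  first <- suppressWarnings(as.numeric(parse_row(data_lines[1])))
  if (anyNA(first)) data_lines <- data_lines[-1]  # header line
  wl <- ab <- numeric(length(data_lines))
  for (i in seq_along(data_lines)) {
    cells <- suppressWarnings(as.numeric(parse_row(data_lines[i])))
    if (length(cells) < 2 || anyNA(cells[1:2]))
      rs_stop(sprintf("non-numeric cell in data row %d of '%s'", i, path),
              "ratiospec_parse_error")
    wl[i] <- cells[1]; ab[i] <- cells[2]
  }
  ord <- order(wl)
  uv_spectrum(wl[ord], ab[ord], meta)
}

#' Write a spectrum to a two-column text table
#'
#' Metadata is serialized as `# key=value` comment lines; values are
#' written at full double precision so that
#' `read_spectrum(write_spectrum(s))` reproduces `s` exactly.
#'
#' @param s A [uv_spectrum()].
#' @param path Destination file path.
#' @return Invisibly, `path`.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "uv_spectrum"))
  lines <- character(0)
  if (length(s$metadata))
    lines <- sprintf("# %s=%s", names(s$metadata),
                     vapply(s$metadata, function(v)
                       if (is.numeric(v)) format(v, digits = 17) else as.character(v),
                       character(1)))
  lines <- c(lines, "wavelength,absorbance",
             paste(format(s$wavelength, digits = 17, trim = TRUE),
                   format(s$absorbance, digits = 17, trim = TRUE), sep = ","))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok)
    rs_stop(sprintf("cannot write spectrum to '%s'", path),
            "ratiospec_io_error")
  invisible(path)
}

#' Resample a spectrum onto a target grid
#'
#' Linear interpolation at each target wavelength; no extrapolation is
#' performed.  Exact on piecewise-linear spectra and the identity on the
#' native grid.
#'
#' @param s A [uv_spectrum()].
#' @param grid Target wavelengths (nm), regular ascending, inside the
#'   wavelength range of `s`.
#' @return A [uv_spectrum()] on `grid` (metadata preserved).
#' @export
resample_spectrum <- function(s, grid) {
  stopifnot(inherits(s, "uv_spectrum"))
  grid <- as.numeric(grid)
  if (min(grid) < min(s$wavelength) - 1e-9 ||
      max(grid) > max(s$wavelength) + 1e-9)
    rs_stop("target grid extends outside the source wavelength range",
            "ratiospec_range_error")
  ab <- stats::approx(s$wavelength, s$absorbance, xout = grid,
                      method = "linear", rule = 1)$y
  uv_spectrum(grid, ab, s$metadata)
}

#' Crop a spectrum to a wavelength window
#'
#' Retains samples with `lo <= wavelength <= hi`; both endpoints are
#' inclusive, matching how working ranges such as 200-305 nm are quoted.
#'
#' @param s A [uv_spectrum()].
#' @param lo,hi Window bounds in nm, `lo < hi`.
#' @return A [uv_spectrum()] restricted to the window.
#' @export
crop_spectrum <- function(s, lo, hi) {
  stopifnot(inherits(s, "uv_spectrum"))
  if (lo >= hi)
    rs_stop("crop window must have lo < hi", "ratiospec_range_error")
  keep <- s$wavelength >= lo - 1e-9 & s$wavelength <= hi + 1e-9
  if (sum(keep) < 3L)
    rs_stop(sprintf("crop window [%g, %g] leaves fewer than 3 samples",
                    lo, hi), "ratiospec_range_error")
  uv_spectrum(s$wavelength[keep], s$absorbance[keep], s$metadata)
}

# classed condition helper so callers can test error categories
rs_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "ratiospec_error")))
}
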