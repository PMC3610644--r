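#' Acquisition metadata for a CW-ESR spectrum
#'
#' Holds the instrument settings that travel with a spectrum. The defaults are
#' typical X-band settings for nitroxide work (1.0 G field modulation at
#' 100 kHz over a 160 G sweep).
#'
#' @param modulation_amplitude_G Field-modulation amplitude in Gauss.
#' @param modulation_frequency_kHz Modulation frequency in kHz.
#' @param field_range_G Recorded field range in Gauss (stored as given).
#' @param label Free-text description (probe, lipid, condition).
#'
#' @return An object of class `acquisition_meta`.
#' @export
acquisition_meta <- function(modulation_amplitude_G = 1.0,
                             modulation_frequency_kHz = 100,
                             field_range_G = 160,
                             label = "") {
  for (v in c(modulation_amplitude_G, modulation_frequency_kHz,
              field_range_G)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("acquisition settings must be positive finite numbers")
    }
  }
  structure(list(modulation_amplitude_G = modulation_amplitude_G,
                 modulation_frequency_kHz = modulation_frequency_kHz,
                 field_range_G = field_range_G,
                 label = as.character(label)[1L]),
            class = "acquisition_meta")
}

#' First-derivative CW-ESR spectrum
#'
#' The basic data container of the package: a magnetic-field axis in Gauss
#' paired with first-derivative absorption intensities (arbitrary units),
#' plus acquisition metadata. The field axis must be strictly increasing and
#' hold at least 64 points; the sign convention is the standard CW display in
#' which the low-field lobe of each resonance line is positive.
#'
#' @param field_G Strictly increasing numeric vector of field values (Gauss).
#' @param intensity Numeric vector of first-derivative intensities, same
#'   length as `field_G`.
#' @param meta An [acquisition_meta()] object.
#'
#' @return An object of class `esr_spectrum` with elements `field_G`,
#'   `intensity` and `meta`.
#' @export
esr_spectrum <- function(field_G, intensity, meta = acquisition_meta()) {
  field_G <- as.numeric(field_G)
  intensity <- as.numeric(intensity)
  if (length(field_G) != length(intensity)) {
    stop("field_G and intensity must have the same length")
  }
  if (length(field_G) < 64L) {
    stop("a spectrum needs at least 64 points, got ", length(field_G))
  }
  if (anyNA(field_G) || anyNA(intensity) ||
      !all(is.finite(field_G)) || !all(is.finite(intensity))) {
    stop("non-finite values in spectrum data")
  }
  if (any(diff(field_G) <= 0)) {
    stop("non-monotone field axis: field_G must be strictly increasing")
  }
  if (!inherits(meta, "acquisition_meta")) {
    stop("meta must be an acquisition_meta object")
  }
  structure(list(field_G = field_G, intensity = intensity, meta = meta),
            class = "esr_spectrum")
}

#' @export
print.esr_spectrum <- function(x, ...) {
  n <- length(x$field_G)
  cat(sprintf("<esr_spectrum> %d points, %.2f-%.2f G (step %.4g G)\n",
              n, x$field_G[1L], x$field_G[n], .mean_step(x$field_G)))
  if (nzchar(x$meta$label)) cat("  label:", x$meta$label, "\n")
  cat(sprintf("  modulation %.3g G @ %.4g kHz, field range %.4g G\n",
              x$meta$modulation_amplitude_G, x$meta$modulation_frequency_kHz,
              x$meta$field_range_G))
  invisible(x)
}

#' @export
plot.esr_spectrum <- function(x, ..., xlab = "Magnetic field (G)",
                              ylab = "dA/dB (arb. units)", type = "l") {
  main <- if (nzchar(x$meta$label)) x$meta$label else ""
  graphics::plot(x$field_G, x$intensity, type = type, xlab = xlab,
                 ylab = ylab, main = main, ...)
  graphics::abline(h = 0, col = "grey70", lty = 3)
  invisible(x)
}

.detect_dialect <- function(lines) {
  probe <- lines[1L]
  if (grepl(",", probe, fixed = TRUE)) return("csv")
  if (grepl("\t", probe, fixed = TRUE)) return("tsv")
  "whitespace"
}

#' Read a spectrum from a plain-text two-column file
#'
#' Reads field (column 1, Gauss) and intensity (column 2) from a CSV, TSV or
#' whitespace-separated file. Lines starting with `#` are treated as header
#' lines; `# key=value` entries matching acquisition-metadata fields
#' (`modulation_amplitude_G`, `modulation_frequency_kHz`, `field_range_G`,
#' `label`) are parsed into the spectrum's metadata. Extra data columns are
#' ignored.
#'
#' @param path File path.
#' @param dialect One of `"auto"`, `"csv"`, `"tsv"`, `"whitespace"`.
#'
#' @return An [esr_spectrum()].
#' @export
read_spectrum <- function(path, dialect = c("auto", "csv", "tsv",
                                            "whitespace")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  is_header <- startsWith(trimws(lines), "#")
  header <- sub("^\\s*#\\s*", "", lines[is_header])
  data_lines <- lines[!is_header]
  if (length(data_lines) < 64L) {
    stop("too few data rows (", length(data_lines), "); need at least 64")
  }
  if (dialect == "auto") {
    dialect <- .detect_dialect(data_lines)
  }
  sep <- switch(dialect, csv = ",", tsv = "\t", whitespace = "")
  tab <- utils::read.table(text = data_lines, sep = sep,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) {
    stop("need at least 2 numeric columns (field_G, intensity)")
  }
  field <- suppressWarnings(as.numeric(tab[[1L]]))
  inten <- suppressWarnings(as.numeric(tab[[2L]]))
  if (anyNA(field) || anyNA(inten)) {
    stop("non-numeric rows in spectrum file")
  }
  if (any(diff(field) <= 0)) {
    stop("non-monotone field axis")
  }

  meta <- acquisition_meta()
  kv <- header[grepl("=", header, fixed = TRUE)]
  if (length(kv)) {
    keys <- trimws(sub("=.*$", "", kv))
    vals <- trimws(sub("^[^=]*=", "", kv))
    for (j in seq_along(keys)) {
      if (keys[j] %in% c("modulation_amplitude_G", "modulation_frequency_kHz",
                         "field_range_G")) {
        meta[[keys[j]]] <- as.numeric(vals[j])
      } else if (keys[j] == "label") {
        meta$label <- vals[j]
      }
    }
  }
  esr_spectrum(field, inten, meta)
}

#' Write a spectrum to a plain-text two-column file
#'
#' The inverse of [read_spectrum()]: metadata as `# key=value` header lines,
#' then one `(field_G, intensity)` pair per row. Values are written with 15
#' significant digits so a write/read round trip reproduces the data to well
#' below 1e-9.
#'
#' @param s An [esr_spectrum()].
#' @param path Output file path.
#' @param dialect One of `"whitespace"`, `"csv"`, `"tsv"`.
#'
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path, dialect = c("whitespace", "csv", "tsv")) {
  stopifnot(inherits(s, "esr_spectrum"))
  dialect <- match.arg(dialect)
  sep <- switch(dialect, csv = ",", tsv = "\t", whitespace = " ")
  header <- c(
    sprintf("# modulation_amplitude_G=%.15g", s$meta$modulation_amplitude_G),
    sprintf("# modulation_frequency_kHz=%.15g",
            s$meta$modulation_frequency_kHz),
    sprintf("# field_range_G=%.15g", s$meta$field_range_G),
    if (nzchar(s$meta$label)) sprintf("# label=%s", s$meta$label)
  )
  body <- sprintf("%.15g%s%.15g", s$field_G, sep, s$intensity)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Double integral of a first-derivative spectrum
#'
#' Integrates the first-derivative signal once (cumulative trapezoid) to
#' recover the absorption lineshape, then integrates the absorption
#' (trapezoid) over the sweep. The result is proportional to the number of
#' spins in the sample and is the quantity used for "equal areas"
#' normalization.
#'
#' @param s An [esr_spectrum()].
#' @return A single number (arbitrary units times Gauss squared).
#' @export
double_integral <- function(s) {
  stopifnot(inherits(s, "esr_spectrum"))
  absorption <- pracma::cumtrapz(s$field_G, s$intensity)
  pracma::trapz(s$field_G, as.vector(absorption))
}

#' Normalize a spectrum to unit spin count
#'
#' Scales the intensity so the double integral over the recorded sweep equals
#' exactly 1. Spectra normalized this way have equal areas, i.e. represent
#' the same number of spins, which makes amplitudes comparable across
#' conditions and makes unmixing amplitudes interpretable as spin-count
#' fractions. The input should be baseline-corrected first.
#'
#' @param s An [esr_spectrum()].
#' @return The rescaled [esr_spectrum()].
#' @export
normalize_to_unit_spins <- function(s) {
  di <- double_integral(s)
  if (!is.finite(di) || di <= 0) {
    stop("non-positive double integral: inverted, empty or uncorrected ",
         "baseline signal")
  }
  s$intensity <- s$intensity / di
  s
}

#' Polynomial baseline correction
#'
#' Fits a polynomial of the given order to the outer 5% of points at each end
#' of the sweep (where a first-derivative nitroxide spectrum has returned to
#' baseline) and subtracts it across the whole sweep.
#'
#' @param s An [esr_spectrum()].
#' @param order Polynomial order, an integer from 0 to 3.
#' @param edge_frac Fraction of points at each edge used for the fit.
#'
#' @return The corrected [esr_spectrum()].
#' @export
baseline_correct <- function(s, order = 1L, edge_frac = 0.05) {
  stopifnot(inherits(s, "esr_spectrum"))
  if (!is.numeric(order) || length(order) != 1L || order != round(order) ||
      order < 0 || order > 3) {
    stop("order must be an integer between 0 and 3")
  }
  order <- as.integer(order)
  n <- length(s$field_G)
  k <- max(order + 2L, floor(edge_frac * n))
  idx <- c(seq_len(k), (n - k + 1L):n)
  # scale the field to [-1, 1] to keep the Vandermonde well conditioned
  mid <- (s$field_G[1L] + s$field_G[n]) / 2
  half <- (s$field_G[n] - s$field_G[1L]) / 2
  x <- (s$field_G - mid) / half
  X <- outer(x, 0:order, `^`)
  fit <- stats::lm.fit(X[idx, , drop = FALSE], s$intensity[idx])
  s$intensity <- s$intensity - as.vector(X %*% fit$coefficients)
  s
}

#' Resample two spectra onto a common grid and align them in field
#'
#' Interpolates both spectra onto one uniform field grid covering their
#' overlap, then estimates the field offset of `b` relative to `a` by
#' maximizing the cross-correlation over integer grid steps with parabolic
#' refinement, and shifts `b` to match `a`. Free-versus-bound nitroxide
#' centre shifts are sub-Gauss, so a required shift larger than
#' `max_shift_G` is treated as a data problem.
#'
#' @param a,b [esr_spectrum()] objects with field ranges overlapping over at
#'   least `min_overlap` of each sweep.
#' @param max_shift_G Largest allowed alignment shift in Gauss.
#' @param step_G Grid step for the common axis; defaults to the finer of the
#'   two mean steps.
#' @param min_overlap Minimum required overlap as a fraction of each sweep.
#'
#' @return A list with elements `a`, `b` (aligned spectra on the shared
#'   grid) and `shift_G`, the field shift applied to `b` (negative when
#'   `b`'s features sat at higher field than `a`'s).
#' @export
resample_align <- function(a, b, max_shift_G = 5, step_G = NULL,
                           min_overlap = 0.8) {
  stopifnot(inherits(a, "esr_spectrum"), inherits(b, "esr_spectrum"))
  lo <- max(a$field_G[1L], b$field_G[1L])
  hi <- min(a$field_G[length(a$field_G)], b$field_G[length(b$field_G)])
  span_a <- diff(range(a$field_G))
  span_b <- diff(range(b$field_G))
  if (hi <= lo || (hi - lo) < min_overlap * max(span_a, span_b)) {
    stop("insufficient overlap between field ranges")
  }
  if (is.null(step_G)) {
    step_G <- min(.mean_step(a$field_G), .mean_step(b$field_G))
  }
  grid <- seq(lo, hi, by = step_G)
  if (length(grid) < 64L) {
    stop("common grid too short; decrease step_G")
  }
  ya <- stats::approx(a$field_G, a$intensity, xout = grid, rule = 2)$y
  yb <- stats::approx(b$field_G, b$intensity, xout = grid, rule = 2)$y

  L <- max(1L, round(max_shift_G / step_G))
  n <- length(grid)
  if (n <= 2L * L + 16L) {
    stop("overlap too short for the requested alignment window")
  }
  w <- (L + 1L):(n - L)
  lags <- -L:L
  cc <- vapply(lags, function(k) sum(ya[w] * yb[w + k]), numeric(1L))
  kbest <- which.max(cc)
  if (kbest == 1L || kbest == length(lags)) {
    stop("required shift exceeds max_shift_G = ", max_shift_G, " G")
  }
  # parabolic refinement of the correlation peak
  y1 <- cc[kbest - 1L]; y2 <- cc[kbest]; y3 <- cc[kbest + 1L]
  denom <- y1 - 2 * y2 + y3
  delta <- if (denom != 0) 0.5 * (y1 - y3) / denom else 0
  shift_G <- -(lags[kbest] + delta) * step_G
  if (abs(shift_G) > max_shift_G) {
    stop("required shift exceeds max_shift_G = ", max_shift_G, " G")
  }
  yb_aligned <- stats::approx(grid, yb, xout = grid - shift_G, rule = 2)$y

  list(a = esr_spectrum(grid, ya, a$meta),
       b = esr_spectrum(grid, yb_aligned, b$meta),
       shift_G = shift_G)
}
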