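# Fluorescence spectra: ingestion, long-pass filtering, band integration,
# and the distance-series optimum location.

#' Fluorescence spectrum container
#'
#' A wavelength/intensity series with acquisition metadata: the probe-sample
#' distance at which it was recorded and the excitation wavelength.
#'
#' @param wavelengths Wavelengths in nm, strictly increasing, length >= 2.
#' @param intensities Intensities in counts, `>= 0`, same length.
#' @param probe_distance Probe-sample distance in micrometres (`NA` if
#'   unknown).
#' @param excitation Excitation wavelength in nm (default 450).
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(wavelengths, intensities, probe_distance = NA_real_,
                     excitation = 450) {
  if (length(wavelengths) != length(intensities)) {
    stop_invariant("'wavelengths' and 'intensities' must have the same length")
  }
  if (length(wavelengths) < 2L) {
    stop_invariant("a spectrum needs at least 2 samples")
  }
  if (any(!is.finite(wavelengths)) || any(diff(wavelengths) <= 0)) {
    stop_invariant("'wavelengths' must be finite and strictly increasing")
  }
  if (any(!is.finite(intensities)) || any(intensities < 0)) {
    stop_invariant("'intensities' must be finite and non-negative")
  }
  structure(
    list(wavelengths = as.numeric(wavelengths),
         intensities = as.numeric(intensities),
         probe_distance = as.numeric(probe_distance),
         excitation = as.numeric(excitation)),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, %g-%g nm", length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  if (!is.na(x$probe_distance)) cat(sprintf(", probe distance %g um", x$probe_distance))
  cat(sprintf(", excitation %g nm\n", x$excitation))
  invisible(x)
}

#' Read a two-column spectrum file
#'
#' Parses delimited text with two numeric columns (wavelength nm, intensity
#' counts).  Lines starting with `#` are comments; the header keys
#' `# distance_um: <x>` and `# excitation_nm: <x>` populate the metadata.
#' Rows are sorted by wavelength; duplicate wavelengths are rejected.
#'
#' @param path Path to the file.
#' @return A [spectrum()].
#' @seealso [write_spectrum()]
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path, warn = FALSE)
  distance <- NA_real_
  excitation <- 450
  wl <- numeric(0)
  it <- numeric(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    if (startsWith(ln, "#")) {
      m <- regmatches(ln, regexec("^#\\s*(distance_um|excitation_nm)\\s*:\\s*([-0-9.eE+]+)", ln))[[1]]
      if (length(m) == 3L) {
        if (m[2] == "distance_um") distance <- as.numeric(m[3])
        else excitation <- as.numeric(m[3])
      }
      next
    }
    fields <- strsplit(ln, "[,;\t ]+")[[1]]
    fields <- fields[fields != ""]
    if (length(fields) < 2L) {
      stop_invariant(sprintf("parse error at line %d of '%s': expected 2 columns", i, path))
    }
    vals <- suppressWarnings(as.numeric(fields[1:2]))
    if (any(is.na(vals))) {
      stop_invariant(sprintf("parse error at line %d of '%s': non-numeric value", i, path))
    }
    wl <- c(wl, vals[1])
    it <- c(it, vals[2])
  }
  if (length(wl) < 2L) {
    stop_invariant(sprintf("'%s' contains fewer than 2 spectral samples", path))
  }
  if (anyDuplicated(wl)) {
    dup <- wl[duplicated(wl)][1]
    stop_invariant(sprintf("duplicate wavelength %g nm in '%s'", dup, path))
  }
  o <- order(wl)
  spectrum(wl[o], it[o], probe_distance = distance, excitation = excitation)
}

#' Write a spectrum to two-column text
#'
#' Inverse of [read_spectrum()]: metadata as `#` header keys, then one
#' `wavelength intensity` pair per line at full double precision, so the
#' round trip is the identity on values.
#'
#' @param s A [spectrum()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "spectrum"))
  hdr <- character(0)
  if (!is.na(s$probe_distance)) {
    hdr <- c(hdr, sprintf("# distance_um: %.17g", s$probe_distance))
  }
  hdr <- c(hdr, sprintf("# excitation_nm: %.17g", s$excitation))
  body <- sprintf("%.17g %.17g", s$wavelengths, s$intensities)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Apply an ideal long-pass edge filter
#'
#' Zeroes the intensity at every wavelength below the cutoff (the detection
#' arm of a fluorescence setup blocks the excitation line this way; 470 nm
#' is the usual cutoff for 450 nm excitation).  Wavelengths are unchanged.
#'
#' @param s A [spectrum()].
#' @param cutoff Cutoff wavelength in nm (default 470).
#' @return The filtered [spectrum()].
#' @export
apply_longpass <- function(s, cutoff = 470) {
  stopifnot(inherits(s, "spectrum"))
  s$intensities[s$wavelengths < cutoff] <- 0
  s
}

#' Integrated band fluorescence
#'
#' Trapezoidal integral of the intensity over `[band_min, band_max]` nm,
#' with linear interpolation at the band edges.  The defaults cover the
#' broad skin autofluorescence band (475-700 nm under 450 nm excitation).
#'
#' @param s A [spectrum()].
#' @param band_min,band_max Band limits in nm, `band_min < band_max`; the
#'   band must intersect the spectrum's wavelength range.
#' @return Integrated intensity in counts*nm.
#' @export
total_fluorescence <- function(s, band_min = 475, band_max = 700) {
  stopifnot(inherits(s, "spectrum"))
  if (!(band_min < band_max)) stop_invariant("require band_min < band_max")
  lo <- max(band_min, min(s$wavelengths))
  hi <- min(band_max, max(s$wavelengths))
  if (lo >= hi) {
    stop_domain(sprintf("band [%g, %g] nm does not intersect the spectrum range [%g, %g] nm",
                        band_min, band_max, min(s$wavelengths), max(s$wavelengths)))
  }
  inside <- s$wavelengths > lo & s$wavelengths < hi
  wl <- c(lo, s$wavelengths[inside], hi)
  it <- stats::approx(s$wavelengths, s$intensities, xout = wl)$y
  pracma::trapz(wl, it)
}

#' Distance series of integrated fluorescence
#'
#' Ordered (probe distance, total band fluorescence) pairs, the quantity an
#' experimenter scans to find the optimal probe distance.
#'
#' @param distances Probe distances in micrometres, strictly increasing.
#' @param total_fluorescence Integrated band fluorescence per distance,
#'   counts*nm, `>= 0`.
#' @param model_optimum Optional: the generating model's true optimal
#'   distance (recorded by [generate_distance_series()] for recovery
#'   tests); `NA` for measured data.
#' @return An object of class `distance_series`.
#' @export
distance_series <- function(distances, total_fluorescence,
                            model_optimum = NA_real_) {
  if (length(distances) != length(total_fluorescence)) {
    stop_invariant("'distances' and 'total_fluorescence' must have the same length")
  }
  if (any(diff(distances) <= 0)) {
    stop_invariant("'distances' must be strictly increasing")
  }
  if (any(total_fluorescence < 0)) {
    stop_invariant("'total_fluorescence' must be non-negative")
  }
  structure(
    list(distances = as.numeric(distances),
         total_fluorescence = as.numeric(total_fluorescence),
         model_optimum = model_optimum),
    class = "distance_series"
  )
}

#' @export
print.distance_series <- function(x, ...) {
  cat(sprintf("<distance_series> %d distances over [%g, %g] um\n",
              length(x$distances), min(x$distances), max(x$distances)))
  invisible(x)
}

#' @export
as.data.frame.distance_series <- function(x, ...) {
  data.frame(distance_um = x$distances,
             total_fluorescence = x$total_fluorescence)
}

#' Locate the optimum of a fluorescence distance series
#'
#' Finds the grid maximum of the series.  If it is interior, the estimate is
#' refined by parabolic interpolation through the maximum and its two
#' neighbours (exact for a locally quadratic peak); if it falls on a series
#' boundary the boundary distance is returned and a monotone-series warning
#' is raised, since the true optimum may lie outside the scanned range.
#'
#' @param series A [distance_series()] with at least 3 entries.
#' @return The optimum distance in micrometres, with attributes `method`
#'   (`"parabolic"` or `"grid_max"`) and `boundary` (logical).
#' @export
distance_series_optimum <- function(series) {
  stopifnot(inherits(series, "distance_series"))
  d <- series$distances
  v <- series$total_fluorescence
  if (length(d) < 3L) {
    stop_invariant("need at least 3 distances to locate an optimum")
  }
  i <- which.max(v)
  if (i == 1L || i == length(d)) {
    warning("series maximum lies on the scan boundary (monotone series?); the optimum may be outside the scanned range",
            call. = FALSE)
    return(structure(d[i], method = "grid_max", boundary = TRUE))
  }
  x <- d[(i - 1):(i + 1)]
  y <- v[(i - 1):(i + 1)]
  denom <- (x[1] - x[2]) * (y[1] - y[3]) - (x[1] - x[3]) * (y[1] - y[2])
  if (abs(denom) < .Machine$double.eps * max(abs(y), 1)) {
    return(structure(d[i], method = "grid_max", boundary = FALSE))  # flat triple
  }
  vertex <- ((x[1]^2 - x[2]^2) * (y[1] - y[3]) - (x[1]^2 - x[3]^2) * (y[1] - y[2])) /
    (2 * denom)
  vertex <- min(max(vertex, x[1]), x[3])   # keep inside the bracketing pair
  structure(vertex, method = "parabolic", boundary = FALSE)
}
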