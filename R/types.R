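# Domain types: fiber geometry, probe arrangement, tissue optical constants.
#
# All lengths are micrometres and all angles are degrees at every exported
# interface; trigonometry is done in radians internally.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Error taxonomy: invariant errors are malformed inputs (usage errors at the
# CLI, exit 2); domain errors are valid objects pushed outside the model's
# domain of validity (exit 1).
stop_invariant <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("fiberprobe_invariant_error", "error")))
}

stop_domain <- function(msg) {
  stop(errorCondition(msg, class = c("fiberprobe_domain_error", "error")))
}

#' Optical geometry of a single fiber
#'
#' Bundles the parameters of one fiber that enter the collection-efficiency
#' model: the core size, the numerical aperture and the refractive index of
#' the medium between the fiber tip and the sample (air by default).  The
#' acceptance half-angle follows as `theta = arcsin(NA / n0)`.
#'
#' @param core_size Core size in micrometres.  Whether this number is
#'   interpreted as the core radius `r` or as a diameter (`r = core_size/2`)
#'   is decided by the `size_convention` field of [probe_config()]; the
#'   default convention feeds it straight into the formulas as `r`.
#' @param numerical_aperture Numerical aperture (NA) of the fiber,
#'   dimensionless, `0 < NA < medium_index`.
#' @param medium_index Refractive index `n0` of the external medium
#'   (default 1, air).
#'
#' @return An object of class `fiber_spec`.
#' @seealso [acceptance_angle()], [probe_config()]
#' @examples
#' f <- fiber_spec(core_size = 200, numerical_aperture = 0.22)
#' acceptance_angle(f)
#' @export
fiber_spec <- function(core_size, numerical_aperture, medium_index = 1.0) {
  if (!is.numeric(core_size) || length(core_size) != 1L || !is.finite(core_size) ||
      core_size <= 0) {
    stop_invariant("'core_size' must be a single positive number (micrometres)")
  }
  if (!is.numeric(numerical_aperture) || length(numerical_aperture) != 1L ||
      !is.finite(numerical_aperture) || numerical_aperture <= 0) {
    stop_invariant("'numerical_aperture' must be a single positive number")
  }
  if (!is.numeric(medium_index) || length(medium_index) != 1L ||
      !is.finite(medium_index) || medium_index <= 0) {
    stop_invariant("'medium_index' must be a single positive number")
  }
  if (numerical_aperture >= medium_index) {
    stop_invariant(
      "'numerical_aperture' must be smaller than 'medium_index' (NA >= n0 has no acceptance cone)")
  }
  structure(
    list(
      core_size = as.numeric(core_size),
      numerical_aperture = as.numeric(numerical_aperture),
      medium_index = as.numeric(medium_index)
    ),
    class = "fiber_spec"
  )
}

#' @export
print.fiber_spec <- function(x, ...) {
  cat("<fiber_spec>\n")
  cat(sprintf("  core size          : %g um\n", x$core_size))
  cat(sprintf("  numerical aperture : %g\n", x$numerical_aperture))
  cat(sprintf("  medium index (n0)  : %g\n", x$medium_index))
  cat(sprintf("  acceptance angle   : %.2f deg\n", acceptance_angle(x)))
  invisible(x)
}

#' Probe arrangement and model conventions
#'
#' Describes how one or more fibers are deployed over the sample: single
#' bare fiber or an illumination/collection pair, the probe-sample distance,
#' the tilt of the probe axis from the surface normal, and (multi mode) the
#' edge-to-edge spacing between illumination and collection fibers.
#'
#' Two model dialects are first-class configuration.  `"as_printed"`
#' evaluates the published closed forms literally: the spread factor
#' `(r + d' tan(theta))^2 / r^2` multiplies the solid-angle fraction with the
#' escape ratio held constant, and the two-circle overlap fraction carries a
#' leading coefficient of 4 (clamped to 1, since it reaches 2 at full
#' overlap).  `"energy_conserving"` substitutes the surface-intensity
#' relation so the spread factor cancels (leaving `cos(beta) * Omega`), and
#' uses the exact equal-circle lens-area fraction (leading coefficient 2)
#' for the overlap.  The dialects agree on the location of all qualitative
#' features (contact optimum for single fibers, overlap onset and interior
#' optimum for fiber pairs) but differ in the curve shapes; `"as_printed"`
#' is the default because it reproduces the published distance checkpoints.
#'
#' @param mode `"single"` (one fiber both illuminates and collects) or
#'   `"multi"` (separate illumination and collection fibers).
#' @param distance Probe-sample distance `d` in micrometres, `>= 0`.
#' @param tilt Tilt angle `beta` of the probe axis in degrees,
#'   `0 <= beta < 90`.  The model additionally requires
#'   `beta < 90 - theta`; that bound depends on the fiber and is enforced
#'   when the geometry is evaluated.
#' @param fiber_spacing Multi mode only: spacing `r_c` between the
#'   illumination and the collection fiber, micrometres (default 10).
#' @param dialect `"as_printed"` or `"energy_conserving"`; see Details.
#' @param size_convention `"as_radius"` (default) feeds
#'   `fiber_spec$core_size` directly into the formulas as the radius `r`;
#'   `"as_diameter"` uses `r = core_size / 2`.
#' @param n_collection Integer number of collection fibers in the ring
#'   around the illumination fiber (default 1).  Scales absolute, never
#'   normalized, output.
#'
#' @return An object of class `probe_config`.
#' @examples
#' probe_config("multi", distance = 700, fiber_spacing = 10)
#' @export
probe_config <- function(mode = c("single", "multi"),
                         distance = 0,
                         tilt = 0,
                         fiber_spacing = 10,
                         dialect = c("as_printed", "energy_conserving"),
                         size_convention = c("as_radius", "as_diameter"),
                         n_collection = 1L) {
  mode <- match.arg(mode)
  dialect <- match.arg(dialect)
  size_convention <- match.arg(size_convention)
  if (!is.numeric(distance) || length(distance) != 1L || !is.finite(distance) ||
      distance < 0) {
    stop_invariant("'distance' must be a single non-negative number (micrometres)")
  }
  if (!is.numeric(tilt) || length(tilt) != 1L || !is.finite(tilt) ||
      tilt < 0 || tilt >= 90) {
    stop_invariant("'tilt' must be a single angle in [0, 90) degrees")
  }
  if (!is.numeric(fiber_spacing) || length(fiber_spacing) != 1L ||
      !is.finite(fiber_spacing) || fiber_spacing < 0) {
    stop_invariant("'fiber_spacing' must be a single non-negative number (micrometres)")
  }
  if (!is.numeric(n_collection) || length(n_collection) != 1L ||
      n_collection < 1 || n_collection != round(n_collection)) {
    stop_invariant("'n_collection' must be a positive integer")
  }
  structure(
    list(
      mode = mode,
      distance = as.numeric(distance),
      tilt = as.numeric(tilt),
      fiber_spacing = as.numeric(fiber_spacing),
      dialect = dialect,
      size_convention = size_convention,
      n_collection = as.integer(n_collection)
    ),
    class = "probe_config"
  )
}

#' @export
print.probe_config <- function(x, ...) {
  cat("<probe_config>\n")
  cat(sprintf("  mode            : %s\n", x$mode))
  cat(sprintf("  distance        : %g um\n", x$distance))
  cat(sprintf("  tilt            : %g deg\n", x$tilt))
  if (x$mode == "multi") {
    cat(sprintf("  fiber spacing   : %g um\n", x$fiber_spacing))
    cat(sprintf("  collection fibers: %d\n", x$n_collection))
  }
  cat(sprintf("  dialect         : %s\n", x$dialect))
  cat(sprintf("  size convention : %s\n", x$size_convention))
  invisible(x)
}

#' Tissue optical constants entering the collection bookkeeping
#'
#' The escaping intensity splits into a specular part (`R_sp`, carrying no
#' subsurface information) and a diffuse part (`R_diffuse`).  Neither is
#' predicted by the geometric model; they are supplied constants.  The
#' escape ratio `I_esc / I_out` is likewise treated as a distance-independent
#' constant in the `"as_printed"` dialect, so efficiencies are relative.
#'
#' @param specular_reflectance `R_sp` in `[0, 1]`; default 0 (the fluorescence
#'   and multi-fiber analysis assumes no collected specular light).
#' @param diffuse_reflectance `R_diffuse` in `[0, 1]`; default 1, a pure
#'   normalizing constant.
#' @param escape_ratio `I_esc / I_out`, dimensionless; default 1.
#'
#' @return An object of class `tissue_optics`.
#' @export
tissue_optics <- function(specular_reflectance = 0,
                          diffuse_reflectance = 1.0,
                          escape_ratio = 1.0) {
  chk01 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
      stop_invariant(sprintf("'%s' must be a single number in [0, 1]", nm))
    }
  }
  chk01(specular_reflectance, "specular_reflectance")
  chk01(diffuse_reflectance, "diffuse_reflectance")
  if (!is.numeric(escape_ratio) || length(escape_ratio) != 1L ||
      !is.finite(escape_ratio) || escape_ratio < 0) {
    stop_invariant("'escape_ratio' must be a single non-negative number")
  }
  structure(
    list(
      specular_reflectance = as.numeric(specular_reflectance),
      diffuse_reflectance = as.numeric(diffuse_reflectance),
      escape_ratio = as.numeric(escape_ratio)
    ),
    class = "tissue_optics"
  )
}

#' @export
print.tissue_optics <- function(x, ...) {
  cat("<tissue_optics>\n")
  cat(sprintf("  R_sp      : %g\n", x$specular_reflectance))
  cat(sprintf("  R_diffuse : %g\n", x$diffuse_reflectance))
  cat(sprintf("  I_esc/I_out (escape ratio): %g\n", x$escape_ratio))
  invisible(x)
}

# Effective core radius under the probe's size convention.
core_radius <- function(fiber, size_convention = "as_radius") {
  stopifnot(inherits(fiber, "fiber_spec"))
  if (identical(size_convention, "as_diameter")) fiber$core_size / 2 else fiber$core_size
}
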