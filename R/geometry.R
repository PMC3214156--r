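# Closed-form geometry of illumination and collection for bare-fiber probes.
#
# The model treats the sample surface as a plane at distance d from the fiber
# tip.  Light leaves the fiber in a cone of half-angle theta = arcsin(NA/n0),
# illuminating a spot of radius r + d*tan(theta); diffusely re-emitted light
# re-enters the core within the solid angle subtended by the core disk.  Tilt
# is folded into an effective distance d'.

#' Acceptance half-angle of a fiber
#'
#' `theta = arcsin(NA / n0)`, the half-angle of the cone of rays a fiber
#' guides, in degrees.  For the common NA = 0.22 fiber in air this is 12.7
#' degrees.
#'
#' @param fiber A [fiber_spec()].
#' @return Acceptance angle in degrees.
#' @examples
#' acceptance_angle(fiber_spec(100, 0.22))  # 12.71
#' @export
acceptance_angle <- function(fiber) {
  stopifnot(inherits(fiber, "fiber_spec"))
  rad2deg(asin(fiber$numerical_aperture / fiber$medium_index))
}

# tan(theta) for a fiber; used pervasively.
tan_theta <- function(fiber) {
  tan(asin(fiber$numerical_aperture / fiber$medium_index))
}

# Shared tilt-domain check: the geometry degenerates as beta -> 90 - theta,
# where the tilted cone edge runs parallel to the surface.
check_tilt_domain <- function(fiber, tilt) {
  theta <- acceptance_angle(fiber)
  if (tilt < 0 || tilt >= 90 - theta) {
    stop_domain(sprintf(
      "tilt angle %.3f deg outside model domain [0, %.3f) deg (90 - acceptance angle)",
      tilt, 90 - theta))
  }
  invisible(TRUE)
}

#' Tilt-corrected effective probe distance
#'
#' For a probe tilted by `beta` from the surface normal, the distance that
#' enters the solid-angle and spot-size formulas is
#' `d' = d + (r + d tan(theta)) sin(beta) tan(beta) tan(theta) /
#' (cos(beta)^2 - sin(beta)^2 tan(theta)^2)`.
#' At normal incidence (`beta = 0`) this reduces to `d' = d`, and `d' >= d`
#' for any admissible tilt.  The formula is valid for
#' `beta < 90 - theta` degrees, where the denominator is positive.
#'
#' @param d Probe-sample distance in micrometres, `>= 0`.
#' @param fiber A [fiber_spec()].
#' @param tilt Tilt angle `beta` in degrees.
#' @param size_convention See [probe_config()].
#' @return Effective distance `d'` in micrometres.
#' @examples
#' f <- fiber_spec(100, 0.22)
#' effective_distance(500, f, tilt = 0)   # 500
#' effective_distance(100, f, tilt = 15)  # ~102.1
#' @export
effective_distance <- function(d, fiber, tilt = 0, size_convention = "as_radius") {
  stopifnot(inherits(fiber, "fiber_spec"))
  if (any(!is.finite(d)) || any(d < 0)) {
    stop_invariant("'d' must be non-negative and finite")
  }
  check_tilt_domain(fiber, tilt)
  if (tilt == 0) return(d)
  r <- core_radius(fiber, size_convention)
  tt <- tan_theta(fiber)
  b <- deg2rad(tilt)
  denom <- cos(b)^2 - sin(b)^2 * tt^2
  d + (r + d * tt) * sin(b) * tan(b) * tt / denom
}

#' Illuminated spot radius
#'
#' Radius of the illuminated (equivalently, collection-acceptance) spot on
#' the sample surface: `r + d_eff * tan(theta)`.  Equals the core radius at
#' contact.
#'
#' @param d_eff Effective probe distance `d'` in micrometres, `>= 0`.
#' @inheritParams effective_distance
#' @return Spot radius in micrometres.
#' @export
spot_radius <- function(d_eff, fiber, size_convention = "as_radius") {
  stopifnot(inherits(fiber, "fiber_spec"))
  if (any(!is.finite(d_eff)) || any(d_eff < 0)) {
    stop_invariant("'d_eff' must be non-negative and finite")
  }
  core_radius(fiber, size_convention) + d_eff * tan_theta(fiber)
}

#' Surface intensity relative to the fiber-output intensity
#'
#' Energy conservation over the expanding illumination cone gives
#' `I_0 / I_out = r^2 cos(beta) / (r + d tan(theta))^2`:
#' the fiber's output power is spread over the (tilt-foreshortened)
#' illuminated spot.  Maximal (=1) at contact with normal incidence.
#'
#' @inheritParams effective_distance
#' @return Dimensionless ratio in `(0, 1]`.
#' @export
surface_intensity_ratio <- function(d, fiber, tilt = 0, size_convention = "as_radius") {
  stopifnot(inherits(fiber, "fiber_spec"))
  if (any(!is.finite(d)) || any(d < 0)) {
    stop_invariant("'d' must be non-negative and finite")
  }
  check_tilt_domain(fiber, tilt)
  r <- core_radius(fiber, size_convention)
  r^2 * cos(deg2rad(tilt)) / (r + d * tan_theta(fiber))^2
}

#' Solid-angle fraction subtended by the fiber core
#'
#' First-order fraction of the hemisphere into which an on-axis surface
#' point re-emits that is intercepted by the core disk of radius `r` at
#' height `d'`:
#' `Omega = 1 - d' / sqrt(d'^2 + r^2)`.
#' Equals 1 at contact and decreases monotonically to 0.
#'
#' @inheritParams spot_radius
#' @return Fraction in `[0, 1]`.  Vectorized over `d_eff`.
#' @seealso [mc_solid_angle_fraction()] for the ray-sampling validation.
#' @export
solid_angle_fraction <- function(d_eff, fiber, size_convention = "as_radius") {
  stopifnot(inherits(fiber, "fiber_spec"))
  if (any(!is.finite(d_eff)) || any(d_eff < 0)) {
    stop_invariant("'d_eff' must be non-negative and finite")
  }
  r <- core_radius(fiber, size_convention)
  1 - d_eff / sqrt(d_eff^2 + r^2)
}

#' Overlap fraction between illumination and collection spots
#'
#' In a two-fiber probe the illumination spot and the collection fiber's
#' acceptance spot are two circles of equal radius `R = r + d' tan(theta)`
#' whose centers sit `2c` apart with `c = r + r_c` (`r_c` = inter-fiber
#' spacing).  They begin to intersect once `R > c` ("overlap onset").
#'
#' Dialect `"as_printed"` evaluates the published expression
#' `[4 R^2 acos(c/R) - 2 c sqrt(R^2 - c^2)] / (pi R^2)`, which tends to 2
#' at full overlap; by default it is clamped to `[0, 1]`.  Dialect
#' `"energy_conserving"` evaluates the exact equal-circle lens-area
#' fraction `[2 R^2 acos(c/R) - 2 c sqrt(R^2 - c^2)] / (pi R^2)`, which
#' lies in `[0, 1]` without clamping and tends to 1 as `c/R -> 0`.
#'
#' @inheritParams spot_radius
#' @param spacing Inter-fiber spacing `r_c` in micrometres, `>= 0`.
#' @param dialect `"as_printed"` or `"energy_conserving"`.
#' @param clamp Clamp the `"as_printed"` value into `[0, 1]` (default TRUE).
#'   Setting `clamp = FALSE` exposes the raw formula, which exceeds 1 in the
#'   far field.
#' @return Overlap fraction, vectorized over `d_eff`.
#' @seealso [mc_overlap_fraction()] for the point-sampling validation,
#'   [overlap_onset()].
#' @export
overlap_fraction <- function(d_eff, fiber, spacing,
                             dialect = c("as_printed", "energy_conserving"),
                             size_convention = "as_radius",
                             clamp = TRUE) {
  stopifnot(inherits(fiber, "fiber_spec"))
  dialect <- match.arg(dialect)
  if (any(!is.finite(d_eff)) || any(d_eff < 0)) {
    stop_invariant("'d_eff' must be non-negative and finite")
  }
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing < 0) {
    stop_invariant("'spacing' must be a single non-negative number")
  }
  r <- core_radius(fiber, size_convention)
  R <- r + d_eff * tan_theta(fiber)
  cc <- r + spacing
  out <- numeric(length(R))
  open <- R > cc
  if (any(open)) {
    Ro <- R[open]
    u <- cc / Ro                      # in (0, 1) past onset
    second <- 2 * cc * sqrt(Ro^2 - cc^2) / (pi * Ro^2)
    lead <- if (dialect == "as_printed") 4 else 2
    val <- lead * acos(u) / pi - second
    if (dialect == "as_printed" && clamp) val <- pmin(pmax(val, 0), 1)
    out[open] <- val
  }
  out
}

#' Overlap-onset distance
#'
#' Smallest probe-sample distance at which the illumination and collection
#' spots of a two-fiber probe begin to intersect.  At normal incidence this
#' is `r_c / tan(theta)`, independent of the core radius.
#'
#' @param fiber A [fiber_spec()].
#' @param spacing Inter-fiber spacing `r_c` in micrometres.
#' @return Onset distance in micrometres.
#' @export
overlap_onset <- function(fiber, spacing) {
  stopifnot(inherits(fiber, "fiber_spec"))
  spacing / tan_theta(fiber)
}

# Assemble an efficiency result object.
efficiency_result <- function(efficiency, efficiency_normalized, d_eff, spot,
                              omega, overlap, intensity_ratio, mode, dialect) {
  structure(
    list(
      efficiency = efficiency,
      efficiency_normalized = efficiency_normalized,
      effective_distance = d_eff,
      spot_radius = spot,
      solid_angle_fraction = omega,
      overlap_fraction = overlap,
      intensity_ratio = intensity_ratio,
      mode = mode,
      dialect = dialect
    ),
    class = "efficiency_result"
  )
}

#' @export
print.efficiency_result <- function(x, ...) {
  cat(sprintf("<efficiency_result> (%s mode, %s dialect)\n", x$mode, x$dialect))
  cat(sprintf("  efficiency (relative)    : %.6g\n", x$efficiency))
  if (!is.na(x$efficiency_normalized)) {
    cat(sprintf("  normalized to contact    : %.6g\n", x$efficiency_normalized))
  }
  cat(sprintf("  effective distance d'    : %.6g um\n", x$effective_distance))
  cat(sprintf("  spot radius              : %.6g um\n", x$spot_radius))
  cat(sprintf("  solid-angle fraction     : %.6g\n", x$solid_angle_fraction))
  cat(sprintf("  overlap fraction         : %.6g\n", x$overlap_fraction))
  cat(sprintf("  surface intensity ratio  : %.6g\n", x$intensity_ratio))
  invisible(x)
}

# Dialect kernel common to single and multi mode: everything except the
# overlap fraction and the collection-fiber multiplier.
efficiency_kernel <- function(d, fiber, tilt, tissue, dialect, size_convention) {
  d_eff <- effective_distance(d, fiber, tilt, size_convention)
  r <- core_radius(fiber, size_convention)
  spot <- spot_radius(d_eff, fiber, size_convention)
  omega <- solid_angle_fraction(d_eff, fiber, size_convention)
  kern <- if (dialect == "as_printed") {
    (spot / r)^2 * omega * tissue$escape_ratio
  } else {
    cos(deg2rad(tilt)) * omega * tissue$diffuse_reflectance
  }
  list(kernel = kern, d_eff = d_eff, spot = spot, omega = omega)
}

#' Collection efficiency of a single bare-fiber probe
#'
#' Relative signal collected by one fiber that both illuminates and collects,
#' at the probe distance and tilt recorded in `probe`.  In the
#' `"as_printed"` dialect the efficiency is the spread factor
#' `(r + d' tan(theta))^2 / r^2` times the solid-angle fraction times the
#' (constant) escape ratio; in the `"energy_conserving"` dialect the spread
#' factor cancels against the diluted surface intensity, leaving
#' `cos(beta) * Omega(d') * R_diffuse`.  Both dialects are maximal at
#' contact and decrease with distance; `efficiency_normalized` reports the
#' value relative to contact (`d = 0`) at the same tilt.
#'
#' @param probe A [probe_config()] with `mode = "single"`.
#' @param fiber A [fiber_spec()].
#' @param tissue A [tissue_optics()] (defaults: `R_sp = 0`,
#'   `R_diffuse = 1`, escape ratio 1).
#' @return An `efficiency_result` with the factor decomposition
#'   (effective distance, spot radius, solid-angle fraction, surface
#'   intensity ratio; overlap fraction is 1 by convention in single mode).
#' @examples
#' f <- fiber_spec(50, 0.22)
#' p <- probe_config("single", distance = 100)
#' single_fiber_efficiency(p, f)$efficiency_normalized  # ~0.22
#' @export
single_fiber_efficiency <- function(probe, fiber, tissue = tissue_optics()) {
  stopifnot(inherits(probe, "probe_config"), inherits(fiber, "fiber_spec"),
            inherits(tissue, "tissue_optics"))
  if (probe$mode != "single") {
    stop_invariant("'probe' must have mode = \"single\"")
  }
  k <- efficiency_kernel(probe$distance, fiber, probe$tilt, tissue,
                         probe$dialect, probe$size_convention)
  k0 <- efficiency_kernel(0, fiber, probe$tilt, tissue,
                          probe$dialect, probe$size_convention)
  efficiency_result(
    efficiency = k$kernel,
    efficiency_normalized = if (k0$kernel > 0) k$kernel / k0$kernel else NA_real_,
    d_eff = k$d_eff, spot = k$spot, omega = k$omega,
    overlap = 1.0,
    intensity_ratio = surface_intensity_ratio(probe$distance, fiber, probe$tilt,
                                              probe$size_convention),
    mode = "single", dialect = probe$dialect
  )
}

#' Collection efficiency of a multi-fiber probe
#'
#' Relative signal collected by a collection fiber spaced `r_c` from the
#' illumination fiber.  The single-fiber dialect kernel is multiplied by the
#' overlap fraction between the illumination and collection spots (see
#' [overlap_fraction()]); in the `"as_printed"` dialect a `1/cos(beta)`
#' factor enters exactly as published.  Below the overlap-onset distance
#' `r_c / tan(theta)` (normal incidence) the efficiency is exactly 0, so
#' unlike the single-fiber case the maximum lies at a strictly positive
#' probe distance.
#'
#' @param probe A [probe_config()] with `mode = "multi"`.
#' @inheritParams single_fiber_efficiency
#' @return An `efficiency_result`.  `efficiency_normalized` is `NA` in
#'   multi mode: the contact value is 0, so profiles are normalized to
#'   their maximum instead (see [efficiency_profile()]).
#' @examples
#' f <- fiber_spec(1000, 0.22)
#' p <- probe_config("multi", distance = 700, fiber_spacing = 10)
#' multi_fiber_efficiency(p, f)
#' @export
multi_fiber_efficiency <- function(probe, fiber, tissue = tissue_optics()) {
  stopifnot(inherits(probe, "probe_config"), inherits(fiber, "fiber_spec"),
            inherits(tissue, "tissue_optics"))
  if (probe$mode != "multi") {
    stop_invariant("'probe' must have mode = \"multi\"")
  }
  k <- efficiency_kernel(probe$distance, fiber, probe$tilt, tissue,
                         probe$dialect, probe$size_convention)
  ov <- overlap_fraction(k$d_eff, fiber, probe$fiber_spacing,
                         dialect = probe$dialect,
                         size_convention = probe$size_convention)
  tilt_factor <- if (probe$dialect == "as_printed") 1 / cos(deg2rad(probe$tilt)) else 1
  eff <- k$kernel * tilt_factor * ov * probe$n_collection
  efficiency_result(
    efficiency = eff,
    efficiency_normalized = NA_real_,
    d_eff = k$d_eff, spot = k$spot, omega = k$omega,
    overlap = ov,
    intensity_ratio = surface_intensity_ratio(probe$distance, fiber, probe$tilt,
                                              probe$size_convention),
    mode = "multi", dialect = probe$dialect
  )
}

#' Evaluate the efficiency model configured in a probe
#'
#' Dispatches to [single_fiber_efficiency()] or [multi_fiber_efficiency()]
#' according to `probe$mode`, optionally overriding the probe distance.
#'
#' @inheritParams single_fiber_efficiency
#' @param distance Optional probe-sample distance (micrometres) overriding
#'   `probe$distance`.
#' @return An `efficiency_result`.
#' @export
probe_efficiency <- function(probe, fiber, tissue = tissue_optics(),
                             distance = NULL) {
  stopifnot(inherits(probe, "probe_config"))
  if (!is.null(distance)) {
    probe$distance <- distance
    probe <- do.call(probe_config, unclass(probe))
  }
  if (probe$mode == "single") {
    single_fiber_efficiency(probe, fiber, tissue)
  } else {
    multi_fiber_efficiency(probe, fiber, tissue)
  }
}

#' Collection fraction from an efficiency result
#'
#' The collection fraction `f = R_collect / R_diffuse`: collected diffuse
#' signal over the total diffuse signal escaping the surface (specular
#' reflection excluded, `R_sp = 0` convention).
#'
#' @param result An `efficiency_result`.
#' @param tissue A [tissue_optics()] with `diffuse_reflectance > 0`.
#' @return The fraction `f`.
#' @export
collection_fraction <- function(result, tissue = tissue_optics()) {
  stopifnot(inherits(result, "efficiency_result"), inherits(tissue, "tissue_optics"))
  if (tissue$diffuse_reflectance == 0) {
    stop_domain("collection fraction undefined: diffuse_reflectance is 0")
  }
  result$efficiency / tissue$diffuse_reflectance
}
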