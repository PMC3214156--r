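# Seeded Monte-Carlo geometric oracles.
#
# These estimators re-derive the two nontrivial closed forms of the model
# (on-axis disk solid-angle fraction, equal-circle overlap fraction) by
# direct geometric sampling, so the closed forms can be audited for any
# configuration.  They ship in the package, not only in its tests.

oracle_estimate <- function(estimate, standard_error, n_samples, seed,
                            analytic = NA_real_, quantity = "") {
  stopifnot(estimate >= 0, estimate <= 1, standard_error >= 0, n_samples > 0)
  structure(
    list(estimate = estimate, standard_error = standard_error,
         n_samples = as.integer(n_samples), seed = as.integer(seed),
         analytic = analytic, quantity = quantity),
    class = "oracle_estimate"
  )
}

#' @export
print.oracle_estimate <- function(x, ...) {
  cat(sprintf("<oracle_estimate> %s\n", x$quantity))
  cat(sprintf("  estimate : %.6g +/- %.3g (n = %d, seed = %d)\n",
              x$estimate, x$standard_error, x$n_samples, x$seed))
  if (is.finite(x$analytic)) {
    z <- if (x$standard_error > 0) (x$estimate - x$analytic) / x$standard_error else 0
    cat(sprintf("  closed form: %.6g   (z = %.2f)\n", x$analytic, z))
  }
  invisible(x)
}

#' Ray-sampling estimate of the disk solid-angle fraction
#'
#' Samples `n` directions uniformly in solid angle over the hemisphere above
#' an on-axis surface point and counts the rays that intersect the fiber
#' core disk of radius `r` at height `d`.  The expectation is exactly the
#' closed form `1 - d / sqrt(d^2 + r^2)` of [solid_angle_fraction()].
#' Uniform (not Lambertian) emission is used: the closed form is the plain
#' solid-angle fraction and no angular emission model is assumed for the
#' tissue.
#'
#' @param d Disk height (probe distance) in micrometres, `>= 0`.
#' @param r Disk (core) radius in micrometres, `> 0`.
#' @param n Number of rays, `>= 1000` (default `1e5`).
#' @param seed Integer RNG seed; estimates are reproducible bit-for-bit
#'   given `(n, seed)`.
#' @return An `oracle_estimate` with fields `estimate`, `standard_error`
#'   (binomial), `n_samples`, `seed` and the closed-form value in
#'   `analytic`.
#' @examples
#' mc_solid_angle_fraction(d = 100, r = 50, n = 1e4, seed = 1)
#' @export
mc_solid_angle_fraction <- function(d, r, n = 1e5, seed = 1L) {
  stopifnot(d >= 0, r > 0)
  if (n < 1000) stop_invariant("'n' must be at least 1000")
  n <- as.integer(n)
  hits <- withr::with_seed(seed, {
    # Uniform over the hemisphere: direction cosine u = cos(polar) ~ U(0,1).
    u <- stats::runif(n)
    if (d == 0) {
      rep(TRUE, n)                 # every upward ray meets the coincident disk
    } else {
      # Radial distance where the ray pierces the plane z = d.
      rho <- d * sqrt(1 - u^2) / u
      rho <= r
    }
  })
  p <- mean(hits)
  oracle_estimate(
    estimate = p,
    standard_error = sqrt(p * (1 - p) / n),
    n_samples = n, seed = seed,
    analytic = 1 - d / sqrt(d^2 + r^2),
    quantity = sprintf("solid-angle fraction (d = %g, r = %g)", d, r)
  )
}

#' Point-sampling estimate of the equal-circle overlap fraction
#'
#' Samples `n` points uniformly in a disk of radius `R` (the illumination
#' spot) and counts those also inside a second disk of radius `R` whose
#' center is `2c` away (the collection spot, `c = r + r_c` in probe terms).
#' The expectation is the exact lens-area fraction, i.e. the
#' `"energy_conserving"` dialect of [overlap_fraction()]; comparing against
#' the `"as_printed"` dialect quantifies that formula's inflation.
#'
#' @param R Spot radius in micrometres, `> 0`.
#' @param c_half Half the center separation, micrometres, `>= 0`.
#' @param n Number of points, `>= 1000` (default `1e5`).
#' @param seed Integer RNG seed.
#' @return An `oracle_estimate`; `analytic` holds the closed-form lens
#'   fraction.
#' @examples
#' mc_overlap_fraction(R = 1157.8, c_half = 1010, n = 1e4, seed = 1)
#' @export
mc_overlap_fraction <- function(R, c_half, n = 1e5, seed = 1L) {
  stopifnot(R > 0, c_half >= 0)
  if (n < 1000) stop_invariant("'n' must be at least 1000")
  n <- as.integer(n)
  inside <- withr::with_seed(seed, {
    rad <- R * sqrt(stats::runif(n))
    phi <- 2 * pi * stats::runif(n)
    x <- rad * cos(phi)
    y <- rad * sin(phi)
    (x - 2 * c_half)^2 + y^2 <= R^2
  })
  p <- mean(inside)
  analytic <- if (c_half >= R) 0 else {
    (2 * R^2 * acos(c_half / R) - 2 * c_half * sqrt(R^2 - c_half^2)) / (pi * R^2)
  }
  oracle_estimate(
    estimate = p,
    standard_error = sqrt(p * (1 - p) / n),
    n_samples = n, seed = seed,
    analytic = analytic,
    quantity = sprintf("overlap fraction (R = %g, c = %g)", R, c_half)
  )
}
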