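# Distance and tilt scans over the geometric efficiency model, and the
# optimal-distance search for multi-fiber probes.

# Vectorized evaluation of the configured model over a distance vector.
# Returns the factor decomposition for table export.
eval_efficiency <- function(d, probe, fiber, tissue) {
  k <- efficiency_kernel(d, fiber, probe$tilt, tissue,
                         probe$dialect, probe$size_convention)
  if (probe$mode == "single") {
    ov <- rep(1.0, length(d))
    eff <- k$kernel
  } else {
    ov <- overlap_fraction(k$d_eff, fiber, probe$fiber_spacing,
                           dialect = probe$dialect,
                           size_convention = probe$size_convention)
    tilt_factor <- if (probe$dialect == "as_printed") 1 / cos(deg2rad(probe$tilt)) else 1
    eff <- k$kernel * tilt_factor * ov * probe$n_collection
  }
  list(distance = d, efficiency = eff, d_eff = k$d_eff, spot = k$spot,
       omega = k$omega, overlap = ov)
}

#' Collection-efficiency profile over a distance grid
#'
#' Evaluates the efficiency model configured in `probe` on the inclusive
#' grid `seq(d_min, d_max, by = step)` (the endpoint is appended if the
#' step does not land on it).  Deterministic.
#'
#' @inheritParams single_fiber_efficiency
#' @param d_min,d_max Grid bounds in micrometres, `0 <= d_min < d_max`.
#' @param step Grid step in micrometres, `> 0`.
#' @return An object of class `efficiency_profile`: the grid, the
#'   efficiency values and their factor decomposition, the profile argmax,
#'   and a snapshot of the probe configuration.  `as.data.frame()` yields
#'   the export table (columns `distance_um`, `d_eff_um`, `spot_radius_um`,
#'   `omega`, `overlap_fraction`, `efficiency`, `efficiency_normalized`,
#'   `dialect`), with `efficiency_normalized` relative to the profile
#'   maximum.
#' @examples
#' f <- fiber_spec(1000, 0.22)
#' p <- probe_config("multi", fiber_spacing = 10)
#' prof <- efficiency_profile(p, f, d_min = 0, d_max = 2000, step = 10)
#' prof$argmax_distance
#' @export
efficiency_profile <- function(probe, fiber, tissue = tissue_optics(),
                               d_min = 0, d_max = 5 * fiber$core_size,
                               step = (d_max - d_min) / 400) {
  stopifnot(inherits(probe, "probe_config"), inherits(fiber, "fiber_spec"))
  if (!(d_min >= 0 && d_min < d_max)) {
    stop_invariant("require 0 <= d_min < d_max")
  }
  if (step <= 0) stop_invariant("'step' must be positive")
  grid <- seq(d_min, d_max, by = step)
  if (utils::tail(grid, 1) < d_max) grid <- c(grid, d_max)
  ev <- eval_efficiency(grid, probe, fiber, tissue)
  i <- which.max(ev$efficiency)
  structure(
    list(
      probe = probe, fiber = fiber,
      distances = grid,
      efficiency = ev$efficiency,
      d_eff = ev$d_eff, spot_radius = ev$spot, omega = ev$omega,
      overlap_fraction = ev$overlap,
      argmax_distance = grid[i],
      argmax_value = ev$efficiency[i]
    ),
    class = "efficiency_profile"
  )
}

#' @export
as.data.frame.efficiency_profile <- function(x, ...) {
  mx <- max(x$efficiency)
  data.frame(
    distance_um = x$distances,
    d_eff_um = x$d_eff,
    spot_radius_um = x$spot_radius,
    omega = x$omega,
    overlap_fraction = x$overlap_fraction,
    efficiency = x$efficiency,
    efficiency_normalized = if (mx > 0) x$efficiency / mx else x$efficiency,
    dialect = x$probe$dialect
  )
}

#' @export
print.efficiency_profile <- function(x, ...) {
  cat(sprintf("<efficiency_profile> %s mode, %s dialect, %d points over [%g, %g] um\n",
              x$probe$mode, x$probe$dialect, length(x$distances),
              min(x$distances), max(x$distances)))
  cat(sprintf("  argmax: d = %g um, efficiency = %.6g\n",
              x$argmax_distance, x$argmax_value))
  invisible(x)
}

#' Optimal probe-sample distance
#'
#' For a single-fiber probe the efficiency is maximal at contact and 0 is
#' returned immediately.  For a multi-fiber probe the profile is 0 up to
#' the overlap onset and unimodal but flat near its peak, so the search is
#' a deterministic coarse grid scan (step `d_max / 2000`) followed by
#' golden-section/parabolic refinement ([stats::optimize()]) on the
#' bracketing interval.  Ties resolve to the smallest distance.
#'
#' @inheritParams single_fiber_efficiency
#' @param d_max Scan ceiling in micrometres (default `5 * core_size`,
#'   which covers all regimes of practical fiber sizes).
#' @param tol Absolute refinement tolerance on the distance (default
#'   `1e-4 * d_max`).
#' @return Optimal distance in micrometres.
#' @examples
#' f <- fiber_spec(1000, 0.22)
#' p <- probe_config("multi", fiber_spacing = 10)
#' optimal_distance(p, f, d_max = 2000)  # ~700 (flat peak)
#' @export
optimal_distance <- function(probe, fiber, tissue = tissue_optics(),
                             d_max = 5 * fiber$core_size,
                             tol = 1e-4 * d_max) {
  stopifnot(inherits(probe, "probe_config"), inherits(fiber, "fiber_spec"))
  if (d_max <= 0) stop_invariant("'d_max' must be positive")
  if (probe$mode == "single") return(0)
  grid <- seq(0, d_max, length.out = 2001L)
  vals <- eval_efficiency(grid, probe, fiber, tissue)$efficiency
  if (all(vals == 0)) {
    stop_domain("efficiency is 0 over the whole scan range (no spot overlap anywhere); increase d_max")
  }
  i <- which.max(vals)            # first index on exact ties -> smallest d
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  f <- function(d) eval_efficiency(d, probe, fiber, tissue)$efficiency
  opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = tol)
  # Prefer the refined point only if it genuinely improves; on a numerical
  # tie keep the smaller distance for reproducibility on flat plateaus.
  cand_d <- c(grid[i], opt$maximum)
  cand_v <- c(vals[i], opt$objective)
  best_v <- max(cand_v)
  eps <- 1e-12 * max(best_v, 1)
  min(cand_d[cand_v >= best_v - eps])
}

#' Enhancement over a reference probe distance
#'
#' Ratio of the efficiency at the optimal probe distance to the efficiency
#' at a reference distance (contact, by default).  In multi mode the model
#' efficiency at true contact is exactly 0, so the contact-referenced ratio
#' is unbounded; in that case an explicit marker is returned together with
#' a secondary finite ratio taken just past the overlap-onset distance.
#'
#' @inheritParams optimal_distance
#' @param reference_distance Reference distance in micrometres, `>= 0`.
#' @return A list of class `enhancement_ratio`: `ratio` (possibly `Inf`),
#'   `unbounded` flag, `optimal_distance`, `optimal_value`,
#'   `reference_distance`, `reference_value`, and when unbounded the
#'   `secondary_ratio` with its `secondary_reference` distance.
#' @export
enhancement_ratio <- function(probe, fiber, tissue = tissue_optics(),
                              reference_distance = 0,
                              d_max = 5 * fiber$core_size) {
  stopifnot(reference_distance >= 0)
  d_opt <- optimal_distance(probe, fiber, tissue, d_max = d_max)
  e_opt <- eval_efficiency(d_opt, probe, fiber, tissue)$efficiency
  e_ref <- eval_efficiency(reference_distance, probe, fiber, tissue)$efficiency
  out <- list(
    optimal_distance = d_opt,
    optimal_value = e_opt,
    reference_distance = reference_distance,
    reference_value = e_ref,
    unbounded = e_ref == 0 && e_opt > 0,
    ratio = if (e_ref > 0) e_opt / e_ref else if (e_opt > 0) Inf else NaN
  )
  if (out$unbounded) {
    # Just past the overlap onset the efficiency becomes positive; report a
    # finite ratio there so "unbounded" is never the whole answer.
    onset <- overlap_onset(fiber, probe$fiber_spacing)
    d2 <- onset
    e2 <- eval_efficiency(d2, probe, fiber, tissue)$efficiency
    if (e2 == 0) {                 # exactly at onset the overlap is still 0
      d2 <- onset + max(1e-3 * d_opt, 1e-6)
      e2 <- eval_efficiency(d2, probe, fiber, tissue)$efficiency
    }
    out$secondary_reference <- d2
    out$secondary_ratio <- if (e2 > 0) e_opt / e2 else NaN
  }
  structure(out, class = "enhancement_ratio")
}

#' @export
print.enhancement_ratio <- function(x, ...) {
  cat("<enhancement_ratio>\n")
  cat(sprintf("  optimal distance : %.6g um (efficiency %.6g)\n",
              x$optimal_distance, x$optimal_value))
  if (x$unbounded) {
    cat(sprintf("  vs reference %g um: unbounded (reference efficiency is 0)\n",
                x$reference_distance))
    cat(sprintf("  secondary ratio  : %.6g at reference %.6g um (just past overlap onset)\n",
                x$secondary_ratio, x$secondary_reference))
  } else {
    cat(sprintf("  vs reference %g um: %.6g\n", x$reference_distance, x$ratio))
  }
  invisible(x)
}

#' Efficiency surface over tilt and distance
#'
#' Evaluates the configured model on the outer grid of tilt angles and
#' probe distances.  Tilt angles outside the model domain
#' (`beta >= 90 - theta`) are rejected per entry: their rows are `NA` and
#' are listed in the `rejected_tilts` attribute rather than aborting the
#' scan.
#'
#' @inheritParams single_fiber_efficiency
#' @param beta_grid Tilt angles in degrees.
#' @param d_grid Probe distances in micrometres.
#' @return A numeric matrix (rows = tilt angles, columns = distances) with
#'   dimnames, and attribute `rejected_tilts`.
#' @export
tilt_scan <- function(probe, fiber, tissue = tissue_optics(),
                      beta_grid, d_grid) {
  stopifnot(inherits(probe, "probe_config"), inherits(fiber, "fiber_spec"))
  m <- matrix(NA_real_, nrow = length(beta_grid), ncol = length(d_grid),
              dimnames = list(beta = format(beta_grid, trim = TRUE),
                              distance_um = format(d_grid, trim = TRUE)))
  rejected <- numeric(0)
  for (j in seq_along(beta_grid)) {
    p <- probe
    p$tilt <- beta_grid[j]
    val <- tryCatch(
      eval_efficiency(d_grid, p, fiber, tissue)$efficiency,
      fiberprobe_domain_error = function(e) NULL
    )
    if (is.null(val)) rejected <- c(rejected, beta_grid[j]) else m[j, ] <- val
  }
  attr(m, "rejected_tilts") <- rejected
  m
}
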