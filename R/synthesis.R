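# Synthetic skin-autofluorescence generator driven by the efficiency model.
#
# Skin excited at 450 nm emits a broad featureless band between roughly 475
# and 700 nm (keratin / collagen / elastin).  The generator emulates that
# envelope with two overlapping Gaussian components and scales its amplitude
# with the probe's geometric collection efficiency at the requested
# distance, so a simulated distance scan reproduces the model's distance
# dependence.  Absolute counts are arbitrary: only ratios and argmax
# locations are meaningful.

# Emission envelope on a wavelength grid (nm).  Two fixed Gaussians whose
# sum spans 475-700 nm: a shorter-wavelength component near the
# keratin/collagen region and a broader long-wavelength shoulder.
skin_emission_envelope <- function(wavelengths) {
  0.85 * exp(-(wavelengths - 520)^2 / (2 * 32^2)) +
    0.60 * exp(-(wavelengths - 600)^2 / (2 * 55^2))
}

#' Generate a synthetic skin fluorescence spectrum
#'
#' Emits the two-Gaussian skin autofluorescence envelope sampled at 1 nm,
#' with amplitude proportional to the probe's collection efficiency at
#' `distance` (via [probe_efficiency()], so a multi-fiber probe gives zero
#' signal below the overlap onset), multiplied by i.i.d. multiplicative
#' Gaussian noise of relative standard deviation `noise_sd` and clipped at
#' zero.  Deterministic per seed.
#'
#' @param distance Probe-sample distance in micrometres.
#' @inheritParams single_fiber_efficiency
#' @param noise_sd Relative standard deviation of the multiplicative noise,
#'   `>= 0` (0 = noiseless).
#' @param seed Integer RNG seed (`NULL` leaves the RNG stream alone).
#' @param wavelengths Sampling grid in nm (default 455-750 at 1 nm).
#' @param peak_counts Envelope peak amplitude at unit efficiency, counts
#'   (default 1e4; arbitrary scale).
#' @return A [spectrum()] with `probe_distance = distance`.
#' @export
generate_skin_spectrum <- function(distance, probe, fiber,
                                   tissue = tissue_optics(),
                                   noise_sd = 0, seed = NULL,
                                   wavelengths = seq(455, 750, by = 1),
                                   peak_counts = 1e4) {
  if (noise_sd < 0) stop_invariant("'noise_sd' must be non-negative")
  eff <- probe_efficiency(probe, fiber, tissue, distance = distance)$efficiency
  base <- peak_counts * eff * skin_emission_envelope(wavelengths)
  noisy <- if (noise_sd > 0) {
    factors <- if (is.null(seed)) {
      1 + stats::rnorm(length(base), sd = noise_sd)
    } else {
      withr::with_seed(seed, 1 + stats::rnorm(length(base), sd = noise_sd))
    }
    base * factors
  } else {
    base
  }
  spectrum(wavelengths, pmax(noisy, 0), probe_distance = distance,
           excitation = 450)
}

#' Generate a synthetic fluorescence distance series
#'
#' Simulates the distance-scan experiment: one synthetic spectrum per grid
#' distance ([generate_skin_spectrum()]), integrated over the fluorescence
#' band ([total_fluorescence()]).  The generating model's true optimal
#' distance is recorded in the result so recovery can be tested.
#'
#' @param d_grid Probe distances in micrometres, strictly increasing,
#'   length >= 3.
#' @inheritParams generate_skin_spectrum
#' @param band Integration band in nm (default `c(475, 700)`).
#' @return A [distance_series()]; its `model_optimum` field holds the
#'   model's [optimal_distance()] (0 for single-fiber probes).
#' @export
generate_distance_series <- function(d_grid, probe, fiber,
                                     tissue = tissue_optics(),
                                     noise_sd = 0, seed = NULL,
                                     band = c(475, 700)) {
  if (length(d_grid) < 3L) stop_invariant("'d_grid' needs at least 3 distances")
  tf <- vapply(seq_along(d_grid), function(i) {
    s <- generate_skin_spectrum(d_grid[i], probe, fiber, tissue,
                                noise_sd = noise_sd,
                                seed = if (is.null(seed)) NULL else seed + i)
    total_fluorescence(s, band[1], band[2])
  }, numeric(1))
  model_opt <- optimal_distance(probe, fiber, tissue,
                                d_max = max(d_grid))
  distance_series(d_grid, tf, model_optimum = model_opt)
}
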