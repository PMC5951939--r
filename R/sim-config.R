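#' Simulation configuration for a synthetic spheroid well
#'
#' Describes the physical geometry of a culture well, the spheroid population
#' grown in it, and the way the well is imaged as a grid of partly overlapping
#' 16-bit brightfield tiles. Defaults emulate a day-6 low-attachment culture:
#' a log-normal diameter distribution with median 250 um truncated to
#' 50--600 um, dark spheroids on a brighter well bottom, and a tile grid with
#' 25% overlap (microscope acquisition software typically overlaps tiles by
#' 15--35%).
#'
#' @param well_width_um,well_height_um physical field size in micrometres.
#' @param um_per_px pixel calibration, micrometres per pixel (> 0).
#' @param n_spheroids number of spheroids seeded in the well.
#' @param diameter_median_um median of the log-normal diameter distribution.
#' @param diameter_sdlog sigma of the log-diameter.
#' @param diameter_range_um length-2 truncation interval for diameters (um);
#'   must extend above 50 um so that at least part of the population passes
#'   the size-inclusion filter.
#' @param fused_fraction fraction of spheroids placed as touching/overlapping
#'   pairs, in \[0, 1\].
#' @param debris_count number of sub-threshold objects (single cells and
#'   debris, diameter < 50 um) scattered in the well.
#' @param roughness amplitude of the radial boundary perturbation applied when
#'   rendering, as a fraction of the radius, in \[0, 0.2\]. Annotations always
#'   record the nominal circle.
#' @param dark_core logical; render a darker core disk at half radius
#'   (crypt-like morphology).
#' @param dark_core_level intensity of the core disk as a fraction of the
#'   16-bit dynamic range.
#' @param tile_rows,tile_cols tile grid layout.
#' @param overlap_frac nominal fractional overlap between adjacent tiles.
#'   Values outside \[0.15, 0.35\] are allowed but trigger a warning.
#' @param jitter_px maximum absolute integer jitter (pixels) applied to tile
#'   offsets, so that registration is exercised; tile (1,1) is never jittered.
#' @param noise_sd additive Gaussian intensity noise, in 16-bit counts.
#' @param background_level,spheroid_level background and spheroid intensities
#'   as fractions of the 16-bit dynamic range (spheroids are darker than the
#'   well bottom in brightfield).
#' @param seed integer seed for the single RNG stream of the well.
#'
#' @return an object of class `sim_config` (a validated list).
#' @seealso [generate_ground_truth()], [render_tiles()]
#' @export
sim_config <- function(well_width_um = 6000, well_height_um = 6000,
                       um_per_px = 2.5, n_spheroids = 150,
                       diameter_median_um = 250, diameter_sdlog = 0.35,
                       diameter_range_um = c(50, 600),
                       fused_fraction = 0, debris_count = 0,
                       roughness = 0, dark_core = FALSE,
                       dark_core_level = 0.15,
                       tile_rows = 3, tile_cols = 3, overlap_frac = 0.25,
                       jitter_px = 2, noise_sd = 300,
                       background_level = 0.60, spheroid_level = 0.25,
                       seed = 1L) {
  stopifnot(well_width_um > 0, well_height_um > 0,
            is.finite(um_per_px), um_per_px > 0,
            n_spheroids >= 0, diameter_median_um > 0, diameter_sdlog > 0,
            length(diameter_range_um) == 2,
            diameter_range_um[1] > 0,
            diameter_range_um[2] > diameter_range_um[1],
            fused_fraction >= 0, fused_fraction <= 1,
            debris_count >= 0,
            roughness >= 0, roughness <= 0.2,
            tile_rows >= 1, tile_cols >= 1,
            overlap_frac > 0, overlap_frac < 1,
            jitter_px >= 0, noise_sd >= 0,
            background_level > 0, background_level <= 1,
            spheroid_level > 0, spheroid_level < background_level)
  if (diameter_range_um[2] <= 50)
    stop("diameter distribution must admit support above 50 um; ",
         "upper truncation is ", diameter_range_um[2], " um")
  if (overlap_frac < 0.15 || overlap_frac > 0.35)
    warning("overlap_frac ", overlap_frac,
            " is outside the usual acquisition range [0.15, 0.35]")
  cfg <- list(well_width_um = well_width_um, well_height_um = well_height_um,
              um_per_px = um_per_px, n_spheroids = as.integer(n_spheroids),
              diameter_median_um = diameter_median_um,
              diameter_sdlog = diameter_sdlog,
              diameter_range_um = diameter_range_um,
              fused_fraction = fused_fraction,
              debris_count = as.integer(debris_count),
              roughness = roughness, dark_core = isTRUE(dark_core),
              dark_core_level = dark_core_level,
              tile_rows = as.integer(tile_rows),
              tile_cols = as.integer(tile_cols),
              overlap_frac = overlap_frac,
              jitter_px = as.integer(jitter_px), noise_sd = noise_sd,
              background_level = background_level,
              spheroid_level = spheroid_level,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Treatment effect applied to a simulated well
#'
#' A multiplicative volume effect plus a spheroid-loss effect, matching the
#' two ways a cytotoxic treatment manifests in whole-well imaging: surviving
#' spheroids shrink (volume scaled by `volume_fold`, i.e. radii scaled by
#' `volume_fold^(1/3)`), and a fraction of spheroids is destroyed outright
#' (`kill_fraction`), rendered as scattered sub-threshold fragments.
#'
#' @param arm treatment-arm label (e.g. "CTR", "Z5", "Vd2", "Vd2+Z5").
#' @param volume_fold multiplicative factor on per-spheroid volume (> 0).
#' @param kill_fraction fraction of spheroids destroyed, in \[0, 1\].
#' @return an object of class `treatment_effect`.
#' @export
treatment_effect <- function(arm = "CTR", volume_fold = 1, kill_fraction = 0) {
  stopifnot(is.character(arm), length(arm) == 1L,
            is.finite(volume_fold), volume_fold > 0,
            kill_fraction >= 0, kill_fraction <= 1)
  structure(list(arm = arm, volume_fold = volume_fold,
                 kill_fraction = kill_fraction),
            class = "treatment_effect")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %g x %g um well @ %g um/px, %d spheroids\n",
              x$well_width_um, x$well_height_um, x$um_per_px, x$n_spheroids))
  cat(sprintf("  diameters ~ lognormal(median %g um, sdlog %g) in [%g, %g]\n",
              x$diameter_median_um, x$diameter_sdlog,
              x$diameter_range_um[1], x$diameter_range_um[2]))
  cat(sprintf("  tiles %dx%d, overlap %.0f%%, jitter <= %d px, noise sd %g\n",
              x$tile_rows, x$tile_cols, 100 * x$overlap_frac,
              x$jitter_px, x$noise_sd))
  invisible(x)
}
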