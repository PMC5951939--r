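# Per-spheroid morphometry: circle/sphere formulas on the fitted ROI radius.

#' Sphere volume from radius
#' @param radius_um radius in micrometres.
#' @return volume in cubic micrometres.
#' @export
sphere_volume <- function(radius_um) 4 / 3 * pi * radius_um^3

#' Single-cell geometry model
#'
#' The cell-number estimate treats a spheroid as a dense packing whose volume
#' is the sum of the volumes of its (spherical) cells, so the only parameter
#' is the measured diameter of a single cell. There is no default: the value
#' must come from a measurement of the cell line at hand.
#'
#' @param cell_diameter_um diameter of a single cell, micrometres (> 0).
#' @return an object of class `cell_model` with `cell_diameter_um` and the
#'   derived `cell_volume_um3`.
#' @export
cell_model <- function(cell_diameter_um) {
  stopifnot(is.numeric(cell_diameter_um), length(cell_diameter_um) == 1,
            is.finite(cell_diameter_um), cell_diameter_um > 0)
  structure(list(cell_diameter_um = cell_diameter_um,
                 cell_volume_um3 = sphere_volume(cell_diameter_um / 2)),
            class = "cell_model")
}

#' Measure detected ROIs: perimeter, area, volume, cell count, size filter
#'
#' Applies the closed-form circle/sphere formulas to each fitted ROI radius:
#' perimeter `pi*d`, projected area `pi*(d/2)^2`, volume `(4/3)*pi*(d/2)^3`
#' (the sphere on the maximal fitted radius), and optionally the cell-number
#' estimate `volume / cell volume`. `passes_filter` records the strict
#' minimum-diameter inclusion rule (`diameter > min_diameter_um`).
#'
#' @param rois a `spheroid_rois` table ([detect_spheroids()],
#'   [truth_to_rois()]), or any data.frame with `roi_id` and `radius_um`.
#' @param cells optional [cell_model()]; when supplied, `cell_count` (real)
#'   and `cell_count_rounded` (half-up) columns are added.
#' @param min_diameter_um inclusion threshold for `passes_filter`.
#' @return a `spheroid_measurements` data.frame with one row per ROI.
#' @export
measure_rois <- function(rois, cells = NULL, min_diameter_um = 50) {
  stopifnot(is.data.frame(rois), "radius_um" %in% names(rois),
            min_diameter_um >= 0)
  r <- rois$radius_um
  if (any(!is.finite(r) | r <= 0))
    stop("all ROI radii must be finite and positive")
  out <- data.frame(roi_id = rois$roi_id,
                    diameter_um = 2 * r,
                    perimeter_um = 2 * pi * r,
                    area_um2 = pi * r^2,
                    volume_um3 = sphere_volume(r),
                    stringsAsFactors = FALSE)
  for (col in c("well_id", "arm", "source"))
    if (col %in% names(rois)) out[[col]] <- rois[[col]]
  if (!is.null(cells)) {
    stopifnot(inherits(cells, "cell_model"))
    out$cell_count <- estimate_cell_number(out$volume_um3, cells)
    out$cell_count_rounded <- floor(out$cell_count + 0.5)
  }
  out$passes_filter <- out$diameter_um > min_diameter_um
  class(out) <- c("spheroid_measurements", "data.frame")
  out
}

#' Apply the strict minimum-diameter inclusion filter
#'
#' Retains exactly the measurements with `diameter_um` strictly greater than
#' the threshold (a spheroid of exactly the threshold diameter is excluded),
#' preserving order. This avoids counting single cells and small cell/debris
#' aggregates as spheroids.
#'
#' @param measurements a `spheroid_measurements` data.frame (or any
#'   data.frame with `diameter_um`).
#' @param min_diameter_um threshold in micrometres (>= 0).
#' @return the filtered data.frame.
#' @export
filter_by_diameter <- function(measurements, min_diameter_um = 50) {
  stopifnot(is.data.frame(measurements),
            "diameter_um" %in% names(measurements))
  if (min_diameter_um < 0) stop("min_diameter_um must be non-negative")
  measurements[measurements$diameter_um > min_diameter_um, , drop = FALSE]
}

#' Estimate the number of cells in a spheroid from its volume
#'
#' Volumes-add model: the spheroid volume is the sum of the volumes of its
#' cells, so the count is `volume_um3 / cell_volume_um3` (real-valued; round
#' for reporting).
#'
#' @param volume_um3 spheroid volume(s), cubic micrometres (>= 0).
#' @param cells a [cell_model()].
#' @return real-valued cell count(s).
#' @export
estimate_cell_number <- function(volume_um3, cells) {
  stopifnot(inherits(cells, "cell_model"))
  if (cells$cell_volume_um3 <= 0) stop("cell volume must be positive")
  if (any(volume_um3 < 0)) stop("volumes must be non-negative")
  volume_um3 / cells$cell_volume_um3
}

#' Cell number from an ATP-luminescence reading
#'
#' Inverts a cell-number-mode standard curve: `(rlu - blank) / slope`,
#' floored at zero (with a warning) for readings below blank.
#'
#' @param rlu relative-light-unit reading(s).
#' @param curve an [fit_atp_curve()] result in `vs_cellnumber` mode.
#' @return estimated cell number(s).
#' @export
cells_from_atp <- function(rlu, curve) {
  stopifnot(inherits(curve, "atp_curve"))
  if (curve$mode != "vs_cellnumber")
    stop("curve must be calibrated against known cell numbers ",
         "(mode 'vs_cellnumber')")
  n <- (rlu - curve$intercept) / curve$slope
  if (any(n < 0)) {
    warning("RLU below the fitted blank; reporting 0 cells")
    n <- pmax(n, 0)
  }
  n
}
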