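# File interfaces: 16-bit TIFF tiles/mosaics, JSON layout and ground truth,
# CSV tables for ROIs, measurements and plate-reader readouts.

.write_raster16 <- function(raster, path) {
  tiff::writeTIFF(raster / 65535, path, bits.per.sample = 16,
                  compression = "none")
}

.read_raster16 <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Write a tile set as 16-bit TIFF files plus a layout JSON
#'
#' One file per tile, named `tile_rRR_cCC.tif`, and `layout.json` carrying
#' the grid metadata (nominal offsets, overlap fraction, calibration; true
#' offsets are simulator ground truth and are not written).
#'
#' @param tiles a `tile_set`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_tiles <- function(tiles, dir) {
  stopifnot(inherits(tiles, "tile_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(schema = "spheromet-tiles/1",
               overlap_frac = tiles$overlap_frac,
               um_per_px = tiles$um_per_px,
               tile_w = tiles$tile_w, tile_h = tiles$tile_h,
               mosaic_w = tiles$mosaic_w, mosaic_h = tiles$mosaic_h,
               tiles = lapply(tiles$tiles, function(t) list(
                 tile_id = t$tile_id, row = t$row, col = t$col,
                 file = sprintf("tile_r%02d_c%02d.tif", t$row, t$col),
                 nominal_offset_px = unname(t$nominal_offset_px))))
  for (t in tiles$tiles)
    .write_raster16(t$raster,
                    file.path(dir, sprintf("tile_r%02d_c%02d.tif", t$row, t$col)))
  jsonlite::write_json(meta, file.path(dir, "layout.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a tile set written by [write_tiles()]
#' @param dir directory containing the TIFF tiles and `layout.json`.
#' @return a `tile_set`.
#' @export
read_tiles <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "layout.json"),
                              simplifyVector = TRUE, simplifyDataFrame = FALSE)
  tiles <- lapply(meta$tiles, function(t) list(
    tile_id = t$tile_id, row = as.integer(t$row), col = as.integer(t$col),
    raster = .read_raster16(file.path(dir, t$file)),
    nominal_offset_px = c(x = t$nominal_offset_px[1],
                          y = t$nominal_offset_px[2]),
    true_offset_px = c(x = NA_real_, y = NA_real_)))
  structure(list(tiles = tiles, overlap_frac = meta$overlap_frac,
                 um_per_px = meta$um_per_px,
                 tile_w = meta$tile_w, tile_h = meta$tile_h,
                 mosaic_w = meta$mosaic_w, mosaic_h = meta$mosaic_h),
            class = "tile_set")
}

#' Write / read a stitched mosaic (16-bit TIFF + provenance JSON)
#' @param mosaic a `well_mosaic`.
#' @param path TIFF path; provenance and calibration go to `<path>.json`.
#' @return invisibly, `path`.
#' @export
write_mosaic <- function(mosaic, path) {
  stopifnot(inherits(mosaic, "well_mosaic"))
  .write_raster16(mosaic$raster, path)
  jsonlite::write_json(list(schema = "spheromet-mosaic/1",
                            um_per_px = mosaic$calibration$um_per_px,
                            provenance = mosaic$provenance),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mosaic
#' @export
read_mosaic <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(raster = .read_raster16(path),
                 calibration = calibration_profile(meta$um_per_px),
                 provenance = as.data.frame(meta$provenance)),
            class = "well_mosaic")
}

#' Write ground truth as a schema-versioned JSON
#' @param truth a `ground_truth`.
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(list(schema = "spheromet-truth/1",
                            config = unclass(truth$config),
                            effect = unclass(truth$effect),
                            objects = truth$objects),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read tabular outputs as CSV
#'
#' ROI tables (`well_id, roi_id, center_x_um, center_y_um, radius_um,
#' source`), measurement tables and plate-reader readout tables
#' (`well_id, arm, readout_type, value`) round-trip through plain CSV.
#'
#' @param x the table.
#' @param path CSV path.
#' @return invisibly `path`; readers return the table.
#' @export
write_rois <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(x) <- c("spheroid_rois", "data.frame")
  x
}

#' @rdname write_rois
#' @export
write_readouts <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rois
#' @export
read_readouts <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(x) <- c("assay_readouts", "data.frame")
  x
}
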