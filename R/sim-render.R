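# Rendering of synthetic wells. Raster convention throughout the package:
# an integer matrix [row = y, col = x] with 16-bit values in 0..65535; the
# centre of pixel [r, c] (1-based) sits at ((c - 0.5) * um_per_px,
# (r - 0.5) * um_per_px) in well coordinates (origin top-left, y downward).

MAX16 <- 65535

# paint a (possibly rough-edged) disk into `raster` at intensity `level`;
# rough boundary: r(theta) = r * (1 + amp * sum of low-order sinusoids)
.paint_disk <- function(raster, cx_um, cy_um, r_um, s, level,
                        rough_amp = 0, phases = c(0, 0, 0)) {
  r_max <- r_um * (1 + rough_amp)
  H <- nrow(raster); W <- ncol(raster)
  c0 <- max(1L, floor((cx_um - r_max) / s)); c1 <- min(W, ceiling((cx_um + r_max) / s) + 1L)
  r0 <- max(1L, floor((cy_um - r_max) / s)); r1 <- min(H, ceiling((cy_um + r_max) / s) + 1L)
  if (c0 > c1 || r0 > r1) return(raster)
  px <- (c0:c1 - 0.5) * s; py <- (r0:r1 - 0.5) * s
  dx <- matrix(px - cx_um, nrow = length(py), ncol = length(px), byrow = TRUE)
  dy <- matrix(py - cy_um, nrow = length(py), ncol = length(px))
  dist <- sqrt(dx^2 + dy^2)
  if (rough_amp > 0) {
    th <- atan2(dy, dx)
    pert <- (sin(3 * th + phases[1]) + 0.5 * sin(5 * th + phases[2]) +
             0.33 * sin(7 * th + phases[3])) / 1.83
    rb <- r_um * (1 + rough_amp * pert)
  } else rb <- r_um
  inside <- dist <= rb
  block <- raster[r0:r1, c0:c1, drop = FALSE]
  block[inside] <- level
  raster[r0:r1, c0:c1] <- block
  raster
}

# deterministic body of the well render; assumes the RNG has been seeded
.render_well_impl <- function(truth) {
  cfg <- truth$config
  s <- cfg$um_per_px
  W <- round(cfg$well_width_um / s); H <- round(cfg$well_height_um / s)
  bg <- as.integer(round(cfg$background_level * MAX16))
  fg <- as.integer(round(cfg$spheroid_level * MAX16))
  core <- as.integer(round(cfg$dark_core_level * MAX16))
  raster <- matrix(bg, nrow = H, ncol = W)
  obj <- truth$objects
  for (i in seq_len(nrow(obj))) {
    o <- obj[i, ]
    if (o$class == "spheroid" && !o$alive) {
      # destroyed spheroid: scattered sub-threshold fragments
      nf <- 8L
      fr <- stats::runif(nf, 4, 12)
      fd <- stats::runif(nf, 0, 0.8 * o$radius_um)
      fth <- stats::runif(nf, 0, 2 * pi)
      for (k in seq_len(nf))
        raster <- .paint_disk(raster, o$center_x_um + fd[k] * cos(fth[k]),
                              o$center_y_um + fd[k] * sin(fth[k]),
                              fr[k], s, fg)
      next
    }
    phases <- if (cfg$roughness > 0 && o$class == "spheroid")
      stats::runif(3, 0, 2 * pi) else c(0, 0, 0)
    amp <- if (o$class == "spheroid") cfg$roughness else 0
    raster <- .paint_disk(raster, o$center_x_um, o$center_y_um, o$radius_um,
                          s, fg, amp, phases)
    if (cfg$dark_core && o$class == "spheroid")
      raster <- .paint_disk(raster, o$center_x_um, o$center_y_um,
                            o$radius_um / 2, s, core)
  }
  raster
}

#' Render the whole well as a single noiseless 16-bit raster
#'
#' Mainly a testing aid: the same image that [render_tiles()] cuts into
#' tiles, before per-tile noise is added. Live spheroids are rendered as
#' disks darker than the well bottom (optionally with a rough boundary and a
#' darker half-radius core); destroyed spheroids appear as scattered
#' sub-threshold fragments; debris and single cells as small dark disks.
#'
#' @param truth a [generate_ground_truth()] result.
#' @return integer matrix \[y, x\] with values in 0..65535.
#' @export
render_well <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(truth$config$seed + 1L)
  .render_well_impl(truth)
}

#' Render a synthetic well as a grid of overlapping 16-bit tiles
#'
#' Cuts the rendered well into a row-major grid of tiles with the configured
#' fractional overlap, applies an integer offset jitter of at most
#' `jitter_px` pixels per tile (tile 1,1 is the anchor and never jittered),
#' and adds independent Gaussian intensity noise per tile. Nominal grid
#' offsets are emitted as metadata; the true (jittered) offsets are also
#' recorded so registration can be validated against them.
#'
#' @param truth a [generate_ground_truth()] result.
#' @param config simulation config; defaults to the one stored in `truth`.
#' @return an object of class `tile_set`: list with `tiles` (each a list with
#'   `tile_id`, `row`, `col`, `raster`, `nominal_offset_px`,
#'   `true_offset_px`, both offsets as (x, y), 0-based pixels), `overlap_frac`,
#'   `um_per_px`, `tile_w`, `tile_h`, `mosaic_w`, `mosaic_h`.
#' @export
render_tiles <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  well <- .render_well_impl(truth)
  H <- nrow(well); W <- ncol(well)
  nr <- config$tile_rows; nc <- config$tile_cols
  ov <- config$overlap_frac
  tile_w <- if (nc == 1) W else ceiling(W / (nc - (nc - 1) * ov))
  tile_h <- if (nr == 1) H else ceiling(H / (nr - (nr - 1) * ov))
  if (tile_w > W || tile_h > H)
    stop("tile grid does not cover the field: tile larger than well")
  off_x <- if (nc == 1) 0 else round((seq_len(nc) - 1) * (W - tile_w) / (nc - 1))
  off_y <- if (nr == 1) 0 else round((seq_len(nr) - 1) * (H - tile_h) / (nr - 1))
  tiles <- vector("list", nr * nc)
  k <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    k <- k + 1L
    jx <- 0L; jy <- 0L
    if (!(r == 1L && c == 1L) && config$jitter_px > 0) {
      jx <- sample.int(2L * config$jitter_px + 1L, 1L) - config$jitter_px - 1L
      jy <- sample.int(2L * config$jitter_px + 1L, 1L) - config$jitter_px - 1L
    }
    tx <- min(max(off_x[c] + jx, 0L), W - tile_w)
    ty <- min(max(off_y[r] + jy, 0L), H - tile_h)
    sub <- well[(ty + 1):(ty + tile_h), (tx + 1):(tx + tile_w), drop = FALSE]
    if (config$noise_sd > 0) {
      sub <- sub + stats::rnorm(length(sub), 0, config$noise_sd)
      sub <- matrix(as.integer(pmin(pmax(round(sub), 0), MAX16)),
                    nrow = tile_h, ncol = tile_w)
    }
    tiles[[k]] <- list(tile_id = sprintf("r%02d_c%02d", r, c),
                       row = r, col = c, raster = sub,
                       nominal_offset_px = c(x = off_x[c], y = off_y[r]),
                       true_offset_px = c(x = tx, y = ty))
  }
  structure(list(tiles = tiles, overlap_frac = ov,
                 um_per_px = config$um_per_px,
                 tile_w = tile_w, tile_h = tile_h,
                 mosaic_w = W, mosaic_h = H),
            class = "tile_set")
}

#' @export
print.tile_set <- function(x, ...) {
  cat(sprintf("tile_set: %d tiles of %d x %d px, overlap %.0f%%, %g um/px\n",
              length(x$tiles), x$tile_w, x$tile_h, 100 * x$overlap_frac,
              x$um_per_px))
  invisible(x)
}
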