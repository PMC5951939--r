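# shared fixtures: everything is generated in code at test time

# a small, quick well: 2000 um square, 2x2 tiles
small_config <- function(...) {
  args <- list(well_width_um = 2000, well_height_um = 2000,
               n_spheroids = 20, tile_rows = 2, tile_cols = 2, seed = 42L)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# analytic binary mask of a union of disks, [y, x], pixel-centre rule
make_disk_mask <- function(cx, cy, r, W, H) {
  xs <- matrix(rep(seq_len(W) - 0.5, each = H), H)
  ys <- matrix(rep(seq_len(H) - 0.5, W), H)
  m <- matrix(0L, H, W)
  for (k in seq_along(cx)) m[(xs - cx[k])^2 + (ys - cy[k])^2 <= r[k]^2] <- 1L
  m
}

# mosaic with given disks painted dark on a bright background
make_disk_mosaic <- function(cx, cy, r, W, H, um_per_px = 1,
                             bg = 39321L, fg = 16384L) {
  raster <- matrix(bg, H, W)
  raster[make_disk_mask(cx / um_per_px, cy / um_per_px, r / um_per_px,
                        W, H) > 0] <- fg
  as_well_mosaic(raster, um_per_px)
}
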