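# synthetic well generator: placement, treatment effects, rendering, readouts

test_that("empty configuration yields an empty object list", {
  truth <- generate_ground_truth(small_config(n_spheroids = 0, debris_count = 0))
  expect_identical(nrow(truth$objects), 0L)
})

test_that("identity effect reproduces the untreated draw for the same seed", {
  t1 <- generate_ground_truth(small_config(),
                              treatment_effect(volume_fold = 1, kill_fraction = 0))
  t2 <- generate_ground_truth(small_config())
  expect_identical(t1$objects$radius_um, t2$objects$radius_um)
  expect_true(all(t1$objects$alive))
})

test_that("volume fold scales mean true volume exactly on paired draws", {
  cfg <- sim_config(seed = 7)
  v1 <- sphere_volume(generate_ground_truth(cfg, treatment_effect())$objects$radius_um)
  v3 <- sphere_volume(generate_ground_truth(
    cfg, treatment_effect("T", volume_fold = 1 / 3))$objects$radius_um)
  expect_equal(length(v1), length(v3))  # object count conserved
  expect_equal(mean(v3) / mean(v1), 1 / 3, tolerance = 0.01)
})

test_that("object classes partition at the 50 um diameter boundary", {
  truth <- generate_ground_truth(small_config(debris_count = 15, seed = 9))
  obj <- truth$objects
  expect_true(all(obj$radius_um[obj$class == "spheroid"] >= 25))
  expect_true(all(obj$radius_um[obj$class != "spheroid"] < 25))
})

test_that("non-fused spheroids never overlap", {
  truth <- generate_ground_truth(small_config(n_spheroids = 25, seed = 3))
  obj <- truth$objects[truth$objects$class == "spheroid", ]
  n <- nrow(obj)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt((obj$center_x_um[i] - obj$center_x_um[j])^2 +
              (obj$center_y_um[i] - obj$center_y_um[j])^2)
    expect_gte(d, obj$radius_um[i] + obj$radius_um[j])
  }
})

test_that("fused pairs overlap by 10-40% of the smaller radius", {
  truth <- generate_ground_truth(small_config(n_spheroids = 20,
                                              fused_fraction = 0.4, seed = 5))
  obj <- truth$objects
  pairs <- obj[!is.na(obj$fused_with) & obj$object_id < obj$fused_with, ]
  expect_gt(nrow(pairs), 0)
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    q <- obj[obj$object_id == p$fused_with, ]
    d <- sqrt((p$center_x_um - q$center_x_um)^2 +
              (p$center_y_um - q$center_y_um)^2)
    ov <- (p$radius_um + q$radius_um - d) / min(p$radius_um, q$radius_um)
    expect_gte(ov, 0.10); expect_lte(ov, 0.40)
  }
})

test_that("an overcrowded field fails with an error naming the density limit", {
  cfg <- small_config(well_width_um = 600, well_height_um = 600,
                      n_spheroids = 40, seed = 1)
  expect_error(generate_ground_truth(cfg), "density|packing|crowded")
})

test_that("noiseless render of one spheroid is exactly bimodal", {
  cfg <- small_config(n_spheroids = 1, noise_sd = 0, jitter_px = 0,
                      tile_rows = 1, tile_cols = 1)
  truth <- generate_ground_truth(cfg)
  well <- render_well(truth)
  lv <- sort(unique(as.vector(well)))
  expect_identical(lv, as.integer(c(round(0.25 * 65535), round(0.60 * 65535))))
  expect_equal(sum(well == lv[1]) / (pi * (truth$objects$radius_um / 2.5)^2),
               1, tolerance = 0.02)
})

test_that("rendered disk centroid matches the annotated centre within 0.5 px", {
  for (sd in c(8, 9, 10)) {
    cfg <- small_config(n_spheroids = 1, noise_sd = 0, roughness = 0, seed = sd)
    truth <- generate_ground_truth(cfg)
    well <- render_well(truth)
    idx <- which(well < 30000, arr.ind = TRUE)
    cx <- (mean(idx[, 2]) - 0.5) * cfg$um_per_px
    cy <- (mean(idx[, 1]) - 0.5) * cfg$um_per_px
    o <- truth$objects
    expect_lt(abs(cx - o$center_x_um), 0.5 * cfg$um_per_px)
    expect_lt(abs(cy - o$center_y_um), 0.5 * cfg$um_per_px)
  }
})

test_that("adjacent tiles duplicate the configured overlap strip", {
  cfg <- small_config(n_spheroids = 10, noise_sd = 0, jitter_px = 0,
                      overlap_frac = 0.25, tile_rows = 2, tile_cols = 2)
  tiles <- render_tiles(generate_ground_truth(cfg))
  t11 <- tiles$tiles[[1]]; t12 <- tiles$tiles[[2]]
  shift <- unname(t12$nominal_offset_px["x"] - t11$nominal_offset_px["x"])
  ov_w <- tiles$tile_w - shift
  # integer tile grid quantizes the overlap slightly
  expect_equal(ov_w / tiles$tile_w, 0.25, tolerance = 0.02)
  expect_identical(t11$raster[, (shift + 1):tiles$tile_w],
                   t12$raster[, 1:ov_w])
})

test_that("tile rendering is deterministic for a fixed seed", {
  cfg <- small_config(n_spheroids = 8, seed = 21)
  truth <- generate_ground_truth(cfg)
  a <- render_tiles(truth); b <- render_tiles(truth)
  for (k in seq_along(a$tiles))
    expect_identical(a$tiles[[k]]$raster, b$tiles[[k]]$raster)
})

test_that("assay readouts are linear in viable cell number", {
  cm <- cell_model(15)
  cfg <- small_config(n_spheroids = 10, seed = 4)
  truth <- generate_ground_truth(cfg)
  ro <- generate_assay_readouts(truth, cm, noise_cv = 0,
                                rlu_blank = 0, od_blank = 0)
  n <- true_viable_cells(truth, cm)
  # doubling the population doubles both signals (blank-free, noiseless)
  cfg2 <- small_config(n_spheroids = 20, seed = 4)
  truth2 <- generate_ground_truth(cfg2)
  ro2 <- generate_assay_readouts(truth2, cm, noise_cv = 0,
                                 rlu_blank = 0, od_blank = 0)
  n2 <- true_viable_cells(truth2, cm)
  expect_equal(ro2$value[ro2$readout_type == "RLU"] /
                 ro$value[ro$readout_type == "RLU"], n2 / n, tolerance = 1e-12)
  expect_equal(ro2$value[ro2$readout_type == "OD595"] /
                 ro$value[ro$readout_type == "OD595"], n2 / n, tolerance = 1e-12)
})

test_that("empty well reads back the blank baselines", {
  truth <- generate_ground_truth(small_config(n_spheroids = 0))
  ro <- generate_assay_readouts(truth, cell_model(15), noise_cv = 0,
                                rlu_blank = 150, od_blank = 0.05)
  expect_equal(ro$value[ro$readout_type == "RLU"], 150)
  expect_equal(ro$value[ro$readout_type == "OD595"], 0.05)
})

test_that("kill_fraction reduces OD by the killed share of true volume", {
  cm <- cell_model(15)
  cfg <- sim_config(seed = 13, n_spheroids = 60)
  t0 <- generate_ground_truth(cfg, treatment_effect(kill_fraction = 0))
  t5 <- generate_ground_truth(cfg, treatment_effect("K", kill_fraction = 0.5))
  expect_identical(t0$objects$radius_um, t5$objects$radius_um)
  ro0 <- generate_assay_readouts(t0, cm, noise_cv = 0, od_blank = 0)
  ro5 <- generate_assay_readouts(t5, cm, noise_cv = 0, od_blank = 0)
  expected <- sum(sphere_volume(t5$objects$radius_um[t5$objects$alive])) /
    sum(sphere_volume(t0$objects$radius_um))
  got <- ro5$value[ro5$readout_type == "OD595"] /
    ro0$value[ro0$readout_type == "OD595"]
  expect_equal(got, expected, tolerance = 1e-10)
})
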