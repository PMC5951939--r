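# circular-ROI detection: circle fitting, splitting, full-well recovery

test_that("three-point circle fit returns the exact circumcircle", {
  fit <- fit_circle(rbind(c(0, 0), c(2, 0), c(1, 1)))
  expect_equal(unname(fit$center), c(1, 0))
  expect_equal(fit$radius, 1)  # equidistant from all three points
  expect_equal(fit$rms, 0)
  # a second, scalene case checked against the analytic circumradius
  p <- rbind(c(0, 0), c(4, 0), c(1, 3))
  fit2 <- fit_circle(p)
  ab <- dist(p)
  R <- prod(ab) / (4 * abs((p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
                           (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2])) / 2)
  expect_equal(fit2$radius, R, tolerance = 1e-12)
})

test_that("collinear points are rejected as degenerate", {
  expect_error(fit_circle(rbind(c(0, 0), c(1, 1), c(2, 2))), "collinear")
  expect_error(fit_circle(cbind(0:9, 0:9)), "collinear")
})

test_that("least-squares fit recovers a noiseless circle to 1e-6", {
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  pts <- cbind(300 + 125 * cos(th), 200 + 125 * sin(th))
  fit <- fit_circle(pts)
  expect_equal(fit$radius, 125, tolerance = 1e-6 / 125)
  expect_equal(unname(fit$center), c(300, 200), tolerance = 1e-6)
  expect_lt(fit$rms, 1e-9)
})

test_that("least-squares fit is unbiased under isotropic point noise", {
  # Monte-Carlo: 100 points on r = 125 um, sd 2 um, 100 replicates
  radii <- vapply(1:100, function(s) {
    set.seed(s)
    th <- stats::runif(100, 0, 2 * pi)
    r <- 125 + stats::rnorm(100, 0, 2)
    fit_circle(cbind(r * cos(th), r * sin(th)))$radius
  }, numeric(1))
  expect_lt(abs(mean(radii) - 125), 1)
})

test_that("a perfect disk is returned unsplit as a single circle", {
  m <- make_disk_mask(100, 100, 60, 200, 200)
  sp <- split_fused(m, detection_params(), um_per_px = 1)
  expect_identical(nrow(sp), 1L)
  expect_equal(sp$center_x_px, 100, tolerance = 0.5)
  expect_equal(sp$center_y_px, 100, tolerance = 0.5)
  expect_equal(sp$radius_px, 60, tolerance = 0.05 * 60)
})

test_that("two fused disks split into two circles with radii within 5%", {
  m <- make_disk_mask(c(90, 210), c(150, 150), c(75, 75), 300, 300)
  sp <- split_fused(m, detection_params(), um_per_px = 1)
  expect_identical(nrow(sp), 2L)
  expect_true(all(abs(sp$radius_px - 75) / 75 < 0.05))
  expect_equal(sort(sp$center_x_px), c(90, 210), tolerance = 3)
})

test_that("a three-disk chain splits into three circles near truth", {
  m <- make_disk_mask(c(90, 210, 330), c(150, 150, 150), c(75, 75, 75),
                      420, 300)
  sp <- split_fused(m, detection_params(), um_per_px = 1)
  expect_identical(nrow(sp), 3L)
  cent_err <- abs(sort(sp$center_x_px) - c(90, 210, 330))
  expect_true(all(cent_err < 10))
  expect_true(all(abs(sp$center_y_px - 150) < 10))
})

test_that("blank mosaics give no detections", {
  blank <- as_well_mosaic(matrix(39321L, 400, 400), 2)
  expect_identical(nrow(detect_spheroids(blank)), 0L)
  set.seed(1)
  noisy <- matrix(as.integer(39321 + round(rnorm(400 * 400, 0, 300))), 400, 400)
  expect_warning(out <- detect_spheroids(as_well_mosaic(noisy, 2)),
                 "bimodality")
  expect_identical(nrow(out), 0L)
})

test_that("the strict diameter gate excludes sub-threshold circles", {
  # disks of diameter 40, 44, 60 um at 1 um/px: only the last passes
  mos <- make_disk_mosaic(c(100, 300, 500), c(200, 200, 200),
                          c(20, 22, 30), 700, 400)
  rois <- detect_spheroids(mos)
  expect_identical(nrow(rois), 1L)
  expect_equal(rois$radius_um, 30, tolerance = 0.02 * 30)
})

test_that("detection on a default synthetic well recovers ground truth", {
  cfg <- sim_config(seed = 101)
  truth <- generate_ground_truth(cfg)
  mos <- stitch(render_tiles(truth))
  rois <- detect_spheroids(mos)
  sc <- match_rois(rois, truth)
  expect_gte(sc$precision, 0.99)
  expect_gte(sc$recall, 0.99)
  expect_lt(max(sc$matches$center_err_um), 3)
  expect_lt(max(abs(sc$matches$radius_rel_err)), 0.03)
})

test_that("detection is deterministic and sorted by descending radius", {
  cfg <- small_config(n_spheroids = 15, seed = 77)
  mos <- stitch(render_tiles(generate_ground_truth(cfg)))
  r1 <- detect_spheroids(mos); r2 <- detect_spheroids(mos)
  expect_identical(r1, r2)
  expect_true(all(diff(r1$radius_um) <= 0))
  expect_identical(r1$roi_id, sprintf("roi_%03d", seq_len(nrow(r1))))
})

test_that("fused pairs yield overlapping ROIs covering the pair's true area", {
  cfg <- sim_config(seed = 55, n_spheroids = 40, fused_fraction = 0.2)
  truth <- generate_ground_truth(cfg)
  mos <- stitch(render_tiles(truth))
  rois <- detect_spheroids(mos)
  obj <- truth$objects
  pairs <- obj[!is.na(obj$fused_with) & obj$object_id < obj$fused_with, ]
  expect_gt(nrow(pairs), 0)
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]; q <- obj[obj$object_id == p$fused_with, ]
    # ROIs whose centre lies inside either true circle
    inside <- sqrt((rois$center_x_um - p$center_x_um)^2 +
                   (rois$center_y_um - p$center_y_um)^2) < p$radius_um |
              sqrt((rois$center_x_um - q$center_x_um)^2 +
                   (rois$center_y_um - q$center_y_um)^2) < q$radius_um
    expect_gte(sum(inside), 2)
    # union coverage of the true pair area on a 1 um grid
    x0 <- min(p$center_x_um, q$center_x_um) - max(p$radius_um, q$radius_um)
    x1 <- max(p$center_x_um, q$center_x_um) + max(p$radius_um, q$radius_um)
    y0 <- min(p$center_y_um, q$center_y_um) - max(p$radius_um, q$radius_um)
    y1 <- max(p$center_y_um, q$center_y_um) + max(p$radius_um, q$radius_um)
    gx <- seq(x0, x1, by = 1); gy <- seq(y0, y1, by = 1)
    XX <- matrix(rep(gx, each = length(gy)), length(gy))
    YY <- matrix(rep(gy, length(gx)), length(gy))
    truth_mask <- (XX - p$center_x_um)^2 + (YY - p$center_y_um)^2 <= p$radius_um^2 |
                  (XX - q$center_x_um)^2 + (YY - q$center_y_um)^2 <= q$radius_um^2
    det_mask <- matrix(FALSE, length(gy), length(gx))
    for (k in which(inside))
      det_mask <- det_mask |
        (XX - rois$center_x_um[k])^2 + (YY - rois$center_y_um[k])^2 <=
          rois$radius_um[k]^2
    expect_gte(sum(truth_mask & det_mask) / sum(truth_mask), 0.90)
  }
})

test_that("edge-clipped components are kept only when an arc fit is reliable", {
  # a disk clipped by the left border, visible arc supports the fit
  mos <- make_disk_mosaic(30, 200, 60, 500, 400)
  rois <- detect_spheroids(mos)
  expect_identical(nrow(rois), 1L)
  expect_equal(rois$radius_um, 60, tolerance = 0.05 * 60)
  expect_equal(rois$center_x_um, 30, tolerance = 3)
})
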