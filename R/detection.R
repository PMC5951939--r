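# Automated circular-ROI detection: threshold -> connected components ->
# circularity gate -> (single-circle fit | distance-transform splitting).

#' Detection parameters
#'
#' @param min_diameter_um inclusion threshold: ROIs with diameter less than
#'   or equal to this are discarded (strictly-greater-than rule, default
#'   50 um, the conventional cutoff separating spheroids from single cells
#'   and debris).
#' @param max_diameter_um search cap; larger circles are discarded.
#' @param intensity_threshold_method global threshold method; only
#'   `"otsu"` is implemented (dark objects on a bright well bottom give a
#'   bimodal histogram by construction).
#' @param min_circularity floor on 4*pi*A/P^2 for a component to be accepted
#'   as a single circle; components below it are split into overlapping
#'   circles.
#' @param nms_iou circle-overlap (intersection-over-union) threshold above
#'   which the smaller of two duplicate circles is suppressed.
#' @return an object of class `detection_params`.
#' @export
detection_params <- function(min_diameter_um = 50, max_diameter_um = 700,
                             intensity_threshold_method = "otsu",
                             min_circularity = 0.8, nms_iou = 0.6) {
  stopifnot(min_diameter_um > 0, max_diameter_um > min_diameter_um,
            min_circularity > 0, min_circularity <= 1,
            nms_iou > 0, nms_iou <= 1)
  intensity_threshold_method <- match.arg(intensity_threshold_method, "otsu")
  structure(list(min_diameter_um = min_diameter_um,
                 max_diameter_um = max_diameter_um,
                 intensity_threshold_method = intensity_threshold_method,
                 min_circularity = min_circularity, nms_iou = nms_iou),
            class = "detection_params")
}

# Vossepoel-Smeulders corner-corrected perimeter of an 8-connected closed
# chain (0-based contour coordinates as returned by EBImage::ocontour)
.chain_perimeter <- function(pts) {
  if (nrow(pts) < 3) return(nrow(pts))
  d <- rbind(diff(pts), pts[1, ] - pts[nrow(pts), ])
  step <- abs(d[, 1]) + abs(d[, 2])
  ne <- sum(step == 1)
  no <- sum(step == 2 & abs(d[, 1]) == 1)
  dirs <- atan2(d[, 2], d[, 1])
  nc <- sum(abs(diff(c(dirs, dirs[1]))) > 1e-9)
  0.980 * ne + 1.406 * no - 0.091 * nc
}

# area of intersection of two circles
.circle_lens <- function(d, r1, r2) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  a1 <- acos((d^2 + r1^2 - r2^2) / (2 * d * r1))
  a2 <- acos((d^2 + r2^2 - r1^2) / (2 * d * r2))
  r1^2 * (a1 - sin(2 * a1) / 2) + r2^2 * (a2 - sin(2 * a2) / 2)
}

.circle_iou <- function(x1, y1, r1, x2, y2, r2) {
  inter <- .circle_lens(sqrt((x1 - x2)^2 + (y1 - y2)^2), r1, r2)
  inter / (pi * r1^2 + pi * r2^2 - inter)
}

#' Fit a circle to boundary points
#'
#' With exactly three (non-collinear) points the circumscribed circle is
#' returned exactly — the classic three-point circle tool. With more points
#' an algebraic (Kasa) least-squares circle is fitted and the RMS radial
#' residual reported.
#'
#' @param boundary_points numeric matrix or data.frame with two columns
#'   (x, y), any consistent length unit.
#' @return list with `center` (x, y), `radius`, and `rms` (0 for the exact
#'   three-point case).
#' @export
fit_circle <- function(boundary_points) {
  p <- as.matrix(boundary_points)
  stopifnot(ncol(p) == 2, nrow(p) >= 3)
  x <- p[, 1]; y <- p[, 2]
  if (nrow(p) == 3) {
    det2 <- (x[2] - x[1]) * (y[3] - y[1]) - (x[3] - x[1]) * (y[2] - y[1])
    scale <- max(dist(p))
    if (abs(det2) < 1e-10 * scale^2)
      stop("degenerate input: the three points are collinear")
    b1 <- (x[2]^2 - x[1]^2 + y[2]^2 - y[1]^2) / 2
    b2 <- (x[3]^2 - x[1]^2 + y[3]^2 - y[1]^2) / 2
    cx <- (b1 * (y[3] - y[1]) - b2 * (y[2] - y[1])) / det2
    cy <- (b2 * (x[2] - x[1]) - b1 * (x[3] - x[1])) / det2
    r <- sqrt((x[1] - cx)^2 + (y[1] - cy)^2)
    return(list(center = c(x = cx, y = cy), radius = r, rms = 0))
  }
  A <- cbind(x, y, 1)
  qrA <- qr(A)
  if (qrA$rank < 3)
    stop("degenerate input: boundary points are collinear")
  sol <- qr.coef(qrA, x^2 + y^2)
  cx <- sol[1] / 2; cy <- sol[2] / 2
  r <- sqrt(sol[3] + cx^2 + cy^2)
  res <- sqrt((x - cx)^2 + (y - cy)^2) - r
  list(center = c(x = unname(cx), y = unname(cy)), radius = unname(r),
       rms = sqrt(mean(res^2)))
}

#' Split a fused component into overlapping circles
#'
#' Clusters of touching spheroids fail the circularity gate; this routine
#' recovers the individual bodies as overlapping circles, mirroring how
#' fused spheroids are annotated as partly overlapping circular ROIs. Seeds
#' are the local maxima of the interior Euclidean distance transform (minimum
#' separation half the minimum spheroid diameter); each seed gets one circle
#' with radius equal to the distance-transform value, refined by a
#' least-squares circle fit to the boundary arc nearest that seed. Always
#' returns at least one circle.
#'
#' @param component_mask binary matrix \[y, x\] of one connected component.
#' @param params a [detection_params()].
#' @param um_per_px pixel calibration of the mask.
#' @return data.frame with `center_x_px`, `center_y_px`, `radius_px`, `rms`
#'   (pixel units, 0-based continuous coordinates of the mask).
#' @export
split_fused <- function(component_mask, params = detection_params(),
                        um_per_px = 1) {
  m <- (component_mask > 0) * 1L
  stopifnot(is.matrix(m), any(m > 0))
  img <- EBImage::Image(t(m))
  dm <- t(EBImage::imageData(EBImage::distmap(img)))   # [y, x]
  min_sep_px <- (params$min_diameter_um / 2) / um_per_px

  # local maxima of the distance transform within the separation radius
  sz <- 2L * max(1L, floor(min_sep_px)) + 1L
  dil <- t(EBImage::imageData(
    EBImage::dilate(EBImage::Image(t(dm)),
                    EBImage::makeBrush(sz, shape = "disc"))))
  cand <- which(dm >= dil - 1e-9 & dm >= max(2, 0.25 * min_sep_px))
  seeds <- NULL
  if (length(cand) > 0) {
    cy <- (cand - 1) %% nrow(dm) + 1; cx <- (cand - 1) %/% nrow(dm) + 1
    ord <- order(dm[cand], decreasing = TRUE)
    keep <- integer(0)
    for (k in ord) {
      if (length(keep) == 0 ||
          all(sqrt((cx[keep] - cx[k])^2 + (cy[keep] - cy[k])^2) >= min_sep_px))
        keep <- c(keep, k)
    }
    seeds <- cbind(x = cx[keep] - 0.5, y = cy[keep] - 0.5,
                   r = dm[cand][keep])
  }
  if (is.null(seeds) || nrow(seeds) == 0) {
    idx <- which(m > 0)
    ys <- (idx - 1) %% nrow(m) + 1; xs <- (idx - 1) %/% nrow(m) + 1
    return(data.frame(center_x_px = mean(xs) - 0.5,
                      center_y_px = mean(ys) - 0.5,
                      radius_px = sqrt(length(idx) / pi), rms = NA_real_))
  }

  oc <- EBImage::ocontour(EBImage::bwlabel(img))
  cont <- oc[[which.max(vapply(oc, nrow, integer(1)))]] + 0.5  # pixel centres
  # assign each boundary point to its nearest seed
  d2 <- outer(cont[, 1], seeds[, "x"], "-")^2 +
        outer(cont[, 2], seeds[, "y"], "-")^2
  assign <- max.col(-d2)
  out <- vector("list", nrow(seeds))
  for (k in seq_len(nrow(seeds))) {
    arc <- cont[assign == k, , drop = FALSE]
    fit <- NULL
    if (nrow(arc) >= 8)
      fit <- tryCatch(fit_circle(arc), error = function(e) NULL)
    ok <- !is.null(fit) && is.finite(fit$radius) &&
      fit$radius > 0.5 * seeds[k, "r"] && fit$radius < 2.0 * seeds[k, "r"] &&
      fit$rms < 0.15 * fit$radius
    if (ok) {
      out[[k]] <- data.frame(center_x_px = fit$center[1],
                             center_y_px = fit$center[2],
                             radius_px = fit$radius, rms = fit$rms)
    } else {
      out[[k]] <- data.frame(center_x_px = seeds[k, "x"],
                             center_y_px = seeds[k, "y"],
                             radius_px = seeds[k, "r"] + 0.5, rms = NA_real_)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Detect spheroids in a calibrated mosaic as circular ROIs
#'
#' Pipeline: (1) global Otsu threshold separates dark objects from the well
#' bottom; (2) connected-component labelling; (3) components passing the
#' circularity floor are measured as single circles (centroid +
#' area-equivalent radius); (4) components failing it are split into
#' overlapping circles with [split_fused()]; (5) circles with diameter at or
#' below `min_diameter_um` (or above `max_diameter_um`) are discarded;
#' (6) duplicate circles are suppressed by circle IoU, keeping the larger.
#' Components clipped by the image border are kept only if a least-squares
#' circle fit to their non-border boundary has RMS residual below 5% of the
#' radius. The result is deterministic for a given mosaic and parameters;
#' ROIs are sorted by descending radius and ids assigned in that order.
#'
#' @param mosaic a `well_mosaic` (see [stitch()], [as_well_mosaic()]).
#' @param params a [detection_params()].
#' @param well_id well identifier carried into the output table.
#' @return a `spheroid_rois` data.frame: `well_id`, `roi_id`, `center_x_um`,
#'   `center_y_um`, `radius_um`, `source` (single / split-from-fused). A
#'   blank mosaic gives an empty table.
#' @export
detect_spheroids <- function(mosaic, params = detection_params(),
                             well_id = "well1") {
  stopifnot(inherits(mosaic, "well_mosaic"), inherits(params, "detection_params"))
  s <- mosaic$calibration$um_per_px
  empty <- data.frame(well_id = character(0), roi_id = character(0),
                      center_x_um = numeric(0), center_y_um = numeric(0),
                      radius_um = numeric(0), source = character(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("spheroid_rois", "data.frame")

  I <- mosaic$raster / 65535
  if (diff(range(I)) == 0) return(empty)       # blank constant image
  img <- EBImage::Image(t(I))
  thr <- EBImage::otsu(img, range = c(0, 1))
  fgmask <- img < thr                           # dark objects
  if (mean(fgmask) > 0.4) {
    warning("no foreground/background bimodality in the mosaic histogram; ",
            "returning no detections")
    return(empty)
  }
  lab <- EBImage::bwlabel(fgmask)
  nobj <- max(lab)
  if (nobj == 0) return(empty)

  labmat <- EBImage::imageData(lab)             # [x, y]
  nx <- nrow(labmat); ny <- ncol(labmat)
  idx <- which(labmat > 0)
  lb <- labmat[idx]
  x0 <- (idx - 1) %% nx                          # 0-based
  y0 <- (idx - 1) %/% nx
  area <- tabulate(lb, nobj)
  sums <- rowsum(cbind(x0, y0), lb)
  oc <- EBImage::ocontour(lab)

  circles <- list()
  for (i in seq_len(nobj)) {
    if (area[i] < 5) next
    cont <- oc[[i]]
    on_border <- cont[, 1] == 0 | cont[, 1] == nx - 1 |
                 cont[, 2] == 0 | cont[, 2] == ny - 1
    if (any(on_border)) {
      inner <- cont[!on_border, , drop = FALSE] + 0.5
      if (nrow(inner) < 8) next
      fit <- tryCatch(fit_circle(inner), error = function(e) NULL)
      if (is.null(fit) || fit$rms >= 0.05 * fit$radius) next
      circles[[length(circles) + 1L]] <- data.frame(
        cx = fit$center[1], cy = fit$center[2], r = fit$radius,
        source = "single")
      next
    }
    P <- .chain_perimeter(cont)
    circ <- 4 * pi * area[i] / P^2
    if (circ >= params$min_circularity) {
      circles[[length(circles) + 1L]] <- data.frame(
        cx = sums[i, 1] / area[i] + 0.5, cy = sums[i, 2] / area[i] + 0.5,
        r = sqrt(area[i] / pi), source = "single")
    } else {
      sel <- idx[lb == i]
      rx <- range((sel - 1) %% nx); ry <- range((sel - 1) %/% nx)
      sub <- matrix(0L, ry[2] - ry[1] + 1, rx[2] - rx[1] + 1)  # [y, x]
      sub[cbind((sel - 1) %/% nx - ry[1] + 1,
                (sel - 1) %% nx - rx[1] + 1)] <- 1L
      sp <- split_fused(sub, params, s)
      circles[[length(circles) + 1L]] <- data.frame(
        cx = sp$center_x_px + rx[1], cy = sp$center_y_px + ry[1],
        r = sp$radius_px, source = "split-from-fused")
    }
  }
  if (length(circles) == 0) return(empty)
  cc <- do.call(rbind, circles)

  # size gate (strict >), expressed in um
  d_um <- 2 * cc$r * s
  cc <- cc[d_um > params$min_diameter_um & d_um <= params$max_diameter_um, ,
           drop = FALSE]
  if (nrow(cc) == 0) return(empty)

  # duplicate suppression: keep the larger of any highly overlapping pair
  ord <- order(cc$r, decreasing = TRUE)
  cc <- cc[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(cc))
  for (i in seq_len(nrow(cc))) {
    if (!keep[i]) next
    if (i < nrow(cc)) for (j in (i + 1):nrow(cc)) {
      if (keep[j] && .circle_iou(cc$cx[i], cc$cy[i], cc$r[i],
                                 cc$cx[j], cc$cy[j], cc$r[j]) > params$nms_iou)
        keep[j] <- FALSE
    }
  }
  cc <- cc[keep, , drop = FALSE]

  out <- data.frame(well_id = well_id,
                    roi_id = sprintf("roi_%03d", seq_len(nrow(cc))),
                    center_x_um = cc$cx * s, center_y_um = cc$cy * s,
                    radius_um = cc$r * s, source = cc$source,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("spheroid_rois", "data.frame")
  out
}
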