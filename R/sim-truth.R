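#' Generate ground-truth annotations for a synthetic well
#'
#' Draws a spheroid population from the configured diameter distribution,
#' applies the treatment effect (volume fold as a `fold^(1/3)` radius scaling;
#' `kill_fraction` of spheroids flagged dead), and places all objects in the
#' well by rejection sampling so that non-fused spheroids never overlap. Fused
#' pairs are placed so their boundaries overlap by 10--40% of the smaller
#' radius. Sub-threshold debris/single cells (diameter < 50 um) are added
#' last, also without touching other objects.
#'
#' The same `(config, effect)` with the same seed always reproduces the same
#' truth. Radii are drawn before placement, so two runs with identical seed
#' but different `volume_fold` contain the same base draw scaled object by
#' object.
#'
#' @param config a [sim_config()].
#' @param effect a [treatment_effect()].
#' @param max_tries placement attempts per object before the well is declared
#'   too crowded.
#' @return an object of class `ground_truth`: a list with `objects` (a
#'   data.frame with columns `object_id`, `class` (spheroid / debris /
#'   single_cell), `center_x_um`, `center_y_um`, `radius_um`, `arm`, `alive`,
#'   `fused_with`) and `config`.
#' @export
generate_ground_truth <- function(config, effect = treatment_effect(),
                                  max_tries = 2000L) {
  stopifnot(inherits(config, "sim_config"), inherits(effect, "treatment_effect"))
  set.seed(config$seed)
  n <- config$n_spheroids

  # base diameters: truncated log-normal (resampled into range), then the
  # treatment's volume fold applied as a radius scaling
  draw_d <- function(k) {
    d <- numeric(0)
    while (length(d) < k) {
      x <- stats::rlnorm(k, meanlog = log(config$diameter_median_um),
                         sdlog = config$diameter_sdlog)
      d <- c(d, x[x >= config$diameter_range_um[1] &
                  x <= config$diameter_range_um[2]])
    }
    d[seq_len(k)]
  }
  radius <- if (n > 0) draw_d(n) / 2 * effect$volume_fold^(1 / 3) else numeric(0)

  n_fused <- 2L * (round(config$fused_fraction * n) %/% 2L)
  fused_idx <- if (n_fused > 0) seq_len(n_fused) else integer(0)

  placed_x <- numeric(0); placed_y <- numeric(0); placed_r <- numeric(0)
  gap_um <- 8  # clearance so rendered components stay disjoint
  W <- config$well_width_um; H <- config$well_height_um

  place_one <- function(r, margin = gap_um) {
    for (i in seq_len(max_tries)) {
      x <- stats::runif(1, r + margin, W - r - margin)
      y <- stats::runif(1, r + margin, H - r - margin)
      if (length(placed_x) == 0 ||
          all(sqrt((placed_x - x)^2 + (placed_y - y)^2) >=
              placed_r + r + margin))
        return(c(x, y))
    }
    stop("could not place an object of radius ", round(r, 1),
         " um after ", max_tries, " tries: the configured density (",
         n, " spheroids in ", W, " x ", H,
         " um) exceeds the packing limit of rejection sampling")
  }

  xs <- numeric(n); ys <- numeric(n); fused_with <- rep(NA_integer_, n)
  # placement order: fused pairs first (they need the most room), then
  # singles largest-first so rejection sampling does not jam on late
  # large objects
  singles <- setdiff(seq_len(n), fused_idx)
  order_seq <- c(fused_idx[fused_idx %% 2L == 1L],
                 singles[order(radius[singles], decreasing = TRUE)])
  for (i in order_seq) {
    if (i %in% fused_idx) {
      # fused pair: place the first member, then its partner at a distance
      # giving 10-40% boundary overlap of the smaller radius
      r1 <- radius[i]; r2 <- radius[i + 1L]
      p1 <- place_one(max(r1, r2) + r2 + gap_um)  # room for the partner
      ok <- FALSE
      for (k in seq_len(max_tries)) {
        u <- stats::runif(1, 0.10, 0.40)
        d <- r1 + r2 - u * min(r1, r2)
        th <- stats::runif(1, 0, 2 * pi)
        x2 <- p1[1] + d * cos(th); y2 <- p1[2] + d * sin(th)
        inside <- x2 > r2 + gap_um && x2 < W - r2 - gap_um &&
                  y2 > r2 + gap_um && y2 < H - r2 - gap_um
        clear <- length(placed_x) == 0 ||
          all(sqrt((placed_x - x2)^2 + (placed_y - y2)^2) >=
              placed_r + r2 + gap_um)
        if (inside && clear) { ok <- TRUE; break }
      }
      if (!ok) stop("could not place a fused pair; well too crowded")
      xs[i] <- p1[1]; ys[i] <- p1[2]
      xs[i + 1L] <- x2; ys[i + 1L] <- y2
      fused_with[i] <- i + 1L; fused_with[i + 1L] <- i
      placed_x <- c(placed_x, p1[1], x2); placed_y <- c(placed_y, p1[2], y2)
      placed_r <- c(placed_r, r1, r2)
    } else {
      p <- place_one(radius[i])
      xs[i] <- p[1]; ys[i] <- p[2]
      placed_x <- c(placed_x, p[1]); placed_y <- c(placed_y, p[2])
      placed_r <- c(placed_r, radius[i])
    }
  }

  alive <- rep(TRUE, n)
  n_kill <- round(effect$kill_fraction * n)
  if (n_kill > 0) alive[sample.int(n, n_kill)] <- FALSE

  objects <- data.frame(
    object_id = if (n > 0) sprintf("sph_%03d", seq_len(n)) else character(0),
    class = rep("spheroid", n),
    center_x_um = xs, center_y_um = ys, radius_um = radius,
    arm = rep(effect$arm, n), alive = alive,
    fused_with = if (n > 0) ifelse(is.na(fused_with), NA_character_,
                                   sprintf("sph_%03d", fused_with))
                 else character(0),
    stringsAsFactors = FALSE)

  nd <- config$debris_count
  if (nd > 0) {
    dr <- stats::runif(nd, 5, 20)          # radius < 25 um by construction
    dcls <- ifelse(dr < 8, "single_cell", "debris")
    dx <- numeric(nd); dy <- numeric(nd)
    for (j in seq_len(nd)) {
      p <- place_one(dr[j])
      dx[j] <- p[1]; dy[j] <- p[2]
      placed_x <- c(placed_x, p[1]); placed_y <- c(placed_y, p[2])
      placed_r <- c(placed_r, dr[j])
    }
    objects <- rbind(objects, data.frame(
      object_id = sprintf("deb_%03d", seq_len(nd)),
      class = dcls, center_x_um = dx, center_y_um = dy, radius_um = dr,
      arm = effect$arm, alive = TRUE, fused_with = NA_character_,
      stringsAsFactors = FALSE))
  }

  structure(list(objects = objects, config = config, effect = effect),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  tab <- table(x$objects$class)
  cat("ground_truth:", paste(names(tab), tab, collapse = ", "),
      sprintf("(arm %s, %d alive)\n", x$effect$arm, sum(x$objects$alive)))
  invisible(x)
}

#' Convert ground-truth spheroids to a detection-style ROI table
#'
#' Gives the ROI table that a perfect detector would produce on this well:
#' one circular ROI per live annotated spheroid. Useful as an oracle and for
#' running the morphometry/statistics layers directly on simulated truth
#' without rendering images.
#'
#' @param truth a [generate_ground_truth()] result.
#' @param well_id well identifier carried into the table.
#' @param alive_only keep only live spheroids (default).
#' @return a `spheroid_rois` data.frame (see [detect_spheroids()]).
#' @export
truth_to_rois <- function(truth, well_id = "well1", alive_only = TRUE) {
  stopifnot(inherits(truth, "ground_truth"))
  obj <- truth$objects
  obj <- obj[obj$class == "spheroid" & (!alive_only | obj$alive), ,
             drop = FALSE]
  rois <- data.frame(
    well_id = rep(well_id, nrow(obj)),
    roi_id = obj$object_id,
    center_x_um = obj$center_x_um, center_y_um = obj$center_y_um,
    radius_um = obj$radius_um,
    source = ifelse(is.na(obj$fused_with), "single", "split-from-fused"),
    stringsAsFactors = FALSE)
  class(rois) <- c("spheroid_rois", "data.frame")
  rois
}
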