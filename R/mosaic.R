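# Tile registration and mosaic assembly.

#' Pixel calibration of a mosaic
#'
#' Fixes the convention used throughout: pixel (0,0) at the top-left, x
#' rightward, y downward, 0-based indices, object centres continuous-valued;
#' a length of `n` pixels corresponds to `n * um_per_px` micrometres.
#'
#' @param um_per_px micrometres per pixel (> 0, finite).
#' @return an object of class `calibration_profile`.
#' @export
calibration_profile <- function(um_per_px) {
  if (!is.numeric(um_per_px) || length(um_per_px) != 1 ||
      !is.finite(um_per_px) || um_per_px <= 0)
    stop("um_per_px must be a single positive finite number")
  structure(list(um_per_px = um_per_px), class = "calibration_profile")
}

#' Convert pixel lengths/coordinates to micrometres (and back)
#'
#' @param value_px,value_um numeric lengths or coordinates.
#' @param cal a [calibration_profile()].
#' @return the converted numeric vector.
#' @export
px_to_um <- function(value_px, cal) {
  stopifnot(inherits(cal, "calibration_profile"))
  value_px * cal$um_per_px
}

#' @rdname px_to_um
#' @export
um_to_px <- function(value_um, cal) {
  stopifnot(inherits(cal, "calibration_profile"))
  value_um / cal$um_per_px
}

# normalized cross-correlation of two equal-size matrices (NA if flat)
.ncc <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(NA_real_)
  sum(a * b) / den
}

# best integer shift (dx, dy) aligning tile B to tile A on their nominal
# overlap region; returns c(dx, dy, corr) or NULL if the overlap is unusable
.pair_shift <- function(rastA, rastB, offA, offB, search_px) {
  # canvas extent of the nominal overlap
  x0 <- max(offA[1], offB[1]); x1 <- min(offA[1] + ncol(rastA), offB[1] + ncol(rastB))
  y0 <- max(offA[2], offB[2]); y1 <- min(offA[2] + nrow(rastA), offB[2] + nrow(rastB))
  # shrink so shifted windows of B stay in-bounds
  x0 <- x0 + search_px; x1 <- x1 - search_px
  y0 <- y0 + search_px; y1 <- y1 - search_px
  if (x1 - x0 < 8 || y1 - y0 < 8) return(NULL)
  aw <- rastA[(y0 - offA[2] + 1):(y1 - offA[2]),
              (x0 - offA[1] + 1):(x1 - offA[1]), drop = FALSE]
  best <- c(0, 0, -Inf)
  for (dy in -search_px:search_px) for (dx in -search_px:search_px) {
    bw <- rastB[(y0 - offB[2] + 1 + dy):(y1 - offB[2] + dy),
                (x0 - offB[1] + 1 + dx):(x1 - offB[1] + dx), drop = FALSE]
    cc <- .ncc(aw, bw)
    if (!is.na(cc) && cc > best[3]) best <- c(dx, dy, cc)
  }
  if (!is.finite(best[3])) return(NULL)
  # a shift of B's content by (dx,dy) means B's true offset is offB - (dx,dy)
  c(dx = -best[1], dy = -best[2], corr = best[3])
}

#' Assemble overlapping tiles into a calibrated whole-well mosaic
#'
#' With `refine = FALSE` tiles are composited at their nominal grid offsets.
#' With `refine = TRUE` the translation between each pair of grid neighbours
#' is estimated by normalized cross-correlation on the shared overlap strip
#' (integer-pixel search within `search_px` of nominal), the pairwise
#' estimates are reconciled by least squares over the tile-offset graph
#' (anchored at the first tile), and tiles are composited at the fitted
#' offsets. Pairs whose correlation peak falls below `corr_floor` (e.g. a
#' featureless strip) fall back to the nominal offset with a warning.
#' Overlapping pixels are blended by linear feathering: each tile is weighted
#' by the product of its ramp distances to the tile borders, so seams fade
#' across the overlap strip.
#'
#' @param tiles a `tile_set` (from [render_tiles()] or [read_tiles()]).
#' @param refine estimate tile offsets from the image content (default TRUE).
#' @param search_px half-width of the integer shift search around nominal.
#' @param corr_floor confidence floor on the correlation peak.
#' @return an object of class `well_mosaic`: list with `raster` (16-bit
#'   integer matrix \[y, x\]), `calibration` (a [calibration_profile()]) and
#'   `provenance` (data.frame of tile ids with nominal and fitted offsets).
#' @export
stitch <- function(tiles, refine = TRUE, search_px = 5L, corr_floor = 0.3) {
  stopifnot(inherits(tiles, "tile_set"), length(tiles$tiles) >= 1)
  tl <- tiles$tiles
  dims <- vapply(tl, function(t) dim(t$raster), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent tile raster sizes")
  n <- length(tl)
  nom <- t(vapply(tl, function(t) as.numeric(t$nominal_offset_px), numeric(2)))
  fitted <- nom

  if (refine && n > 1) {
    rows <- vapply(tl, `[[`, integer(1), "row")
    cols <- vapply(tl, `[[`, integer(1), "col")
    pairs <- list(); meas <- list()
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (j <= i) next
      if (!((rows[i] == rows[j] && abs(cols[i] - cols[j]) == 1) ||
            (cols[i] == cols[j] && abs(rows[i] - rows[j]) == 1))) next
      sh <- .pair_shift(tl[[i]]$raster, tl[[j]]$raster,
                        nom[i, ], nom[j, ], as.integer(search_px))
      if (is.null(sh) || sh[3] < corr_floor) {
        warning("low-confidence registration for pair ", tl[[i]]$tile_id,
                " / ", tl[[j]]$tile_id, "; falling back to nominal offset")
        next
      }
      pairs[[length(pairs) + 1L]] <- c(i, j)
      # measured offset difference: (offB + (dx,dy)) - offA
      meas[[length(meas) + 1L]] <- (nom[j, ] + sh[1:2]) - nom[i, ]
    }
    if (length(pairs) > 0) {
      # least squares over t_j - t_i = m_ij per axis; the gauge is fixed by
      # anchoring the first tile at its nominal offset, and a tiny ridge pulls
      # any tile left unconstrained (disconnected component) back to nominal
      A <- matrix(0, length(pairs), n)
      for (k in seq_along(pairs)) {
        A[k, pairs[[k]][1]] <- -1; A[k, pairs[[k]][2]] <- 1
      }
      M <- do.call(rbind, meas)
      free <- 2:n  # tile 1 is the anchor (delta = 0)
      Af <- A[, free, drop = FALSE]
      AtA <- crossprod(Af) + diag(1e-9, length(free))
      for (ax in 1:2) {
        rhs <- crossprod(Af, M[, ax] - as.vector(A %*% nom[, ax]))
        delta <- numeric(n)
        delta[free] <- as.vector(solve(AtA, rhs))
        fitted[, ax] <- nom[, ax] + delta
      }
      fitted <- round(fitted)
    }
  }

  th <- nrow(tl[[1]]$raster); tw <- ncol(tl[[1]]$raster)
  W <- max(fitted[, 1]) + tw; H <- max(fitted[, 2]) + th
  num <- matrix(0, H, W); den <- matrix(0, H, W)
  wgt <- outer(pmin(seq_len(th), th + 1 - seq_len(th)),
               pmin(seq_len(tw), tw + 1 - seq_len(tw)))
  for (i in seq_len(n)) {
    rs <- (fitted[i, 2] + 1):(fitted[i, 2] + th)
    cs <- (fitted[i, 1] + 1):(fitted[i, 1] + tw)
    num[rs, cs] <- num[rs, cs] + wgt * tl[[i]]$raster
    den[rs, cs] <- den[rs, cs] + wgt
  }
  uncovered <- den == 0
  if (mean(uncovered) > 0.005)
    stop("tile grid does not cover the mosaic canvas (",
         round(100 * mean(uncovered), 1), "% uncovered)")
  raster <- matrix(0L, H, W)
  raster[!uncovered] <- as.integer(round(num[!uncovered] / den[!uncovered]))
  if (any(uncovered))  # px-wide border slivers left by offset jitter
    raster[uncovered] <- as.integer(stats::median(raster[!uncovered]))

  prov <- data.frame(
    tile_id = vapply(tl, `[[`, character(1), "tile_id"),
    row = vapply(tl, `[[`, integer(1), "row"),
    col = vapply(tl, `[[`, integer(1), "col"),
    nominal_x = nom[, 1], nominal_y = nom[, 2],
    fitted_x = fitted[, 1], fitted_y = fitted[, 2],
    stringsAsFactors = FALSE)
  structure(list(raster = raster,
                 calibration = calibration_profile(tiles$um_per_px),
                 provenance = prov),
            class = "well_mosaic")
}

#' @export
print.well_mosaic <- function(x, ...) {
  cat(sprintf("well_mosaic: %d x %d px @ %g um/px (%d tiles)\n",
              ncol(x$raster), nrow(x$raster), x$calibration$um_per_px,
              nrow(x$provenance)))
  invisible(x)
}

#' Wrap a bare raster as a calibrated mosaic
#'
#' @param raster 16-bit integer matrix \[y, x\].
#' @param um_per_px pixel calibration.
#' @return a `well_mosaic`.
#' @export
as_well_mosaic <- function(raster, um_per_px) {
  stopifnot(is.matrix(raster))
  structure(list(raster = raster,
                 calibration = calibration_profile(um_per_px),
                 provenance = data.frame()),
            class = "well_mosaic")
}
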