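# End-to-end convenience wrappers and detection-vs-truth scoring.

#' Run the full analysis pipeline on one synthetic well
#'
#' Ground truth -> tiles -> stitched mosaic -> circular-ROI detection ->
#' morphometry with the size-inclusion filter. When `out_dir` is given, the
#' ROI and measurement tables are written as CSV (deterministic content for a
#' fixed config/effect).
#'
#' @param config a [sim_config()].
#' @param effect a [treatment_effect()].
#' @param cells optional [cell_model()] for cell-count estimates.
#' @param params a [detection_params()].
#' @param refine refine tile offsets during stitching.
#' @param well_id well identifier.
#' @param out_dir optional directory for CSV outputs.
#' @return list with `truth`, `tiles`, `mosaic`, `rois`, `measurements`
#'   (filtered to `passes_filter`).
#' @export
analyze_well <- function(config, effect = treatment_effect(), cells = NULL,
                         params = detection_params(), refine = TRUE,
                         well_id = "well1", out_dir = NULL) {
  truth <- generate_ground_truth(config, effect)
  tiles <- render_tiles(truth)
  mosaic <- stitch(tiles, refine = refine)
  rois <- detect_spheroids(mosaic, params, well_id = well_id)
  meas <- if (nrow(rois) > 0) {
    m <- measure_rois(rois, cells = cells,
                      min_diameter_um = params$min_diameter_um)
    m$arm <- effect$arm
    filter_by_diameter(m, params$min_diameter_um)
  } else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_rois(rois, file.path(out_dir, sprintf("%s_rois.csv", well_id)))
    if (!is.null(meas))
      write_rois(meas, file.path(out_dir, sprintf("%s_measurements.csv",
                                                  well_id)))
  }
  list(truth = truth, tiles = tiles, mosaic = mosaic, rois = rois,
       measurements = meas)
}

#' Score detected ROIs against simulator ground truth
#'
#' Greedy nearest-centre matching between detections and live annotated
#' spheroids: pairs are accepted closest-first while the centre distance is
#' below `max_dist_um`. Reports precision, recall, and centre/radius errors
#' over the matched pairs.
#'
#' @param rois a `spheroid_rois` table.
#' @param truth a `ground_truth`.
#' @param max_dist_um maximum centre distance for a match.
#' @return list with `matches` (data.frame of pairs with centre and radius
#'   errors), `precision`, `recall`, `n_detected`, `n_truth`.
#' @export
match_rois <- function(rois, truth, max_dist_um = 25) {
  stopifnot(inherits(truth, "ground_truth"))
  gt <- truth$objects
  gt <- gt[gt$class == "spheroid" & gt$alive, , drop = FALSE]
  n_det <- nrow(rois); n_gt <- nrow(gt)
  if (n_det == 0 || n_gt == 0)
    return(list(matches = data.frame(), precision = ifelse(n_det == 0, NA, 0),
                recall = ifelse(n_gt == 0, NA, 0),
                n_detected = n_det, n_truth = n_gt))
  D <- outer(rois$center_x_um, gt$center_x_um, "-")^2 +
       outer(rois$center_y_um, gt$center_y_um, "-")^2
  D <- sqrt(D)
  pairs <- list()
  used_d <- logical(n_det); used_g <- logical(n_gt)
  ord <- order(D)
  for (k in ord) {
    if (D[k] > max_dist_um) break
    i <- (k - 1) %% n_det + 1; j <- (k - 1) %/% n_det + 1
    if (used_d[i] || used_g[j]) next
    used_d[i] <- TRUE; used_g[j] <- TRUE
    pairs[[length(pairs) + 1L]] <- data.frame(
      roi_id = rois$roi_id[i], object_id = gt$object_id[j],
      center_err_um = D[k],
      radius_err_um = rois$radius_um[i] - gt$radius_um[j],
      radius_rel_err = (rois$radius_um[i] - gt$radius_um[j]) / gt$radius_um[j],
      stringsAsFactors = FALSE)
  }
  m <- if (length(pairs)) do.call(rbind, pairs) else data.frame()
  list(matches = m,
       precision = nrow(m) / n_det,
       recall = nrow(m) / n_gt,
       n_detected = n_det, n_truth = n_gt)
}

#' Simulate a multi-arm treatment experiment at ground-truth level
#'
#' Generates one well per treatment arm from the same configuration (and
#' seed), so every arm applies its effect to the same base spheroid draw —
#' the paired design of the simulator, in which a treatment transforms the
#' population a control well would have had. Returns the pooled, filtered
#' measurement table ready for [summarize_spheroids()] / [compare_arms()].
#'
#' @param config a [sim_config()] shared by all arms.
#' @param effects list of [treatment_effect()]s (unique arm labels).
#' @param cells optional [cell_model()].
#' @param min_diameter_um size-inclusion threshold.
#' @return a `spheroid_measurements` data.frame with an `arm` column.
#' @export
simulate_treatment_arms <- function(config, effects, cells = NULL,
                                    min_diameter_um = 50) {
  stopifnot(inherits(config, "sim_config"), length(effects) >= 1)
  arms <- vapply(effects, `[[`, character(1), "arm")
  if (anyDuplicated(arms)) stop("arm labels must be unique")
  out <- lapply(effects, function(e) {
    tr <- generate_ground_truth(config, e)
    m <- measure_rois(truth_to_rois(tr, well_id = paste0("well_", e$arm)),
                      cells = cells, min_diameter_um = min_diameter_um)
    m$arm <- e$arm
    filter_by_diameter(m, min_diameter_um)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("spheroid_measurements", "data.frame")
  res
}
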