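# Simulated plate-reader readouts matched to a ground-truth well.

#' True viable cell number of a simulated well
#'
#' The oracle for the cell-number layer: sums `volume / cell volume` over
#' live annotated spheroids (the same volumes-add model the morphometry layer
#' uses; debris and single cells are below the inclusion threshold and do not
#' contribute).
#'
#' @param truth a [generate_ground_truth()] result.
#' @param cells a [cell_model()].
#' @return total viable cell number (real-valued).
#' @export
true_viable_cells <- function(truth, cells) {
  stopifnot(inherits(truth, "ground_truth"), inherits(cells, "cell_model"))
  obj <- truth$objects
  obj <- obj[obj$class == "spheroid" & obj$alive, , drop = FALSE]
  sum(sphere_volume(obj$radius_um)) / cells$cell_volume_um3
}

#' Simulate ATP-luminescence and crystal-violet readouts for a well
#'
#' ATP content and crystal-violet uptake are both proportional to the number
#' of living cells; the simulator computes that number from the true spheroid
#' volumes and emits one RLU (relative light units) and one OD595 value per
#' well, each with multiplicative log-normal-free noise of coefficient of
#' variation `noise_cv` on the signal above blank.
#'
#' RLU is modelled through ATP concentration: total ATP (amol) = cells x
#' `atp_per_cell_amol`, converted to uM in `well_volume_ul`, then
#' RLU = blank + `rlu_per_um_atp` x concentration. Optionally
#' `effector_cells` co-cultured effector lymphocytes add their own ATP (they
#' luminesce like any living cell) but, being non-adherent, contribute
#' nothing to the crystal-violet OD — the classic caveat of ATP-based
#' viability in co-cultures.
#'
#' @param truth a [generate_ground_truth()] result.
#' @param cells a [cell_model()] giving the single-cell volume.
#' @param atp_per_cell_amol ATP content per cell, attomoles (> 0).
#' @param rlu_per_um_atp luminometer response, RLU per uM ATP (> 0).
#' @param od_per_cell crystal-violet OD595 per living cell (> 0).
#' @param noise_cv multiplicative noise coefficient of variation (>= 0).
#' @param well_volume_ul culture volume used to convert amol to uM.
#' @param rlu_blank,od_blank instrument blanks added to every value.
#' @param effector_cells number of live effector cells co-cultured in the
#'   well (adds ATP, not OD).
#' @param well_id,seed identifiers; `seed` defaults to `config seed + 2`.
#' @return an `assay_readouts` data.frame: `well_id`, `arm`, `readout_type`
#'   (RLU or OD595), `value`.
#' @export
generate_assay_readouts <- function(truth, cells,
                                    atp_per_cell_amol = 2000,
                                    rlu_per_um_atp = 1e5,
                                    od_per_cell = 2e-6,
                                    noise_cv = 0.05,
                                    well_volume_ul = 200,
                                    rlu_blank = 150, od_blank = 0.05,
                                    effector_cells = 0,
                                    well_id = "well1",
                                    seed = truth$config$seed + 2L) {
  stopifnot(inherits(truth, "ground_truth"),
            atp_per_cell_amol > 0, rlu_per_um_atp > 0, od_per_cell > 0,
            noise_cv >= 0, well_volume_ul > 0, effector_cells >= 0)
  set.seed(seed)
  n_cells <- true_viable_cells(truth, cells)
  # amol -> mol (1e-18), / litres, -> uM (1e6)
  atp_um <- (n_cells + effector_cells) * atp_per_cell_amol * 1e-18 /
    (well_volume_ul * 1e-6) * 1e6
  rlu_sig <- rlu_per_um_atp * atp_um
  od_sig <- od_per_cell * n_cells
  if (noise_cv > 0) {
    rlu_sig <- rlu_sig * (1 + stats::rnorm(1, 0, noise_cv))
    od_sig <- od_sig * (1 + stats::rnorm(1, 0, noise_cv))
  }
  out <- data.frame(well_id = well_id, arm = truth$effect$arm,
                    readout_type = c("RLU", "OD595"),
                    value = pmax(c(rlu_blank + rlu_sig, od_blank + od_sig), 0),
                    stringsAsFactors = FALSE)
  class(out) <- c("assay_readouts", "data.frame")
  out
}

#' Simulate an ATP standard curve
#'
#' Known ATP concentrations (or known cell numbers) read with a linear
#' luminometer response plus multiplicative noise, for exercising
#' [fit_atp_curve()].
#'
#' @param levels known standard levels (uM ATP, or cells).
#' @param slope true instrument slope (RLU per unit level).
#' @param intercept true blank RLU.
#' @param noise_cv coefficient of variation of multiplicative noise on the
#'   signal above blank.
#' @param seed RNG seed.
#' @return data.frame with columns `level`, `rlu`.
#' @export
simulate_atp_standards <- function(levels, slope = 1000, intercept = 50,
                                   noise_cv = 0, seed = 1L) {
  stopifnot(slope > 0, noise_cv >= 0)
  set.seed(seed)
  sig <- slope * levels
  if (noise_cv > 0) sig <- sig * (1 + stats::rnorm(length(levels), 0, noise_cv))
  data.frame(level = levels, rlu = intercept + sig)
}
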