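# Plate-reader calibration (ATP standard curve) and crystal-violet summaries.

#' Fit an ATP standard curve
#'
#' Ordinary least-squares line through the standards, either RLU against
#' known ATP concentration (uM) or RLU against known cell number. The fitted
#' intercept is the blank; a free intercept is fitted rather than forcing the
#' line through the origin.
#'
#' @param standards data.frame with columns `level` (known concentration or
#'   cell number) and `rlu`; at least two distinct levels.
#' @param mode `"vs_concentration"` (level = uM ATP) or `"vs_cellnumber"`
#'   (level = cells).
#' @return an object of class `atp_curve`: `slope`, `intercept`,
#'   `r_squared`, `mode`, `n`.
#' @export
fit_atp_curve <- function(standards,
                          mode = c("vs_concentration", "vs_cellnumber")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(standards),
            all(c("level", "rlu") %in% names(standards)))
  if (length(unique(standards$level)) < 2)
    stop("at least two distinct standard levels are required")
  fit <- stats::lm(rlu ~ level, data = standards)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    stop("calibration failure: fitted slope is not positive (",
         format(slope), " RLU per unit level)")
  sst <- sum((standards$rlu - mean(standards$rlu))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else NA_real_
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, mode = mode, n = nrow(standards)),
            class = "atp_curve")
}

#' @export
print.atp_curve <- function(x, ...) {
  cat(sprintf("atp_curve (%s): RLU = %.4g + %.4g * level, R^2 = %.4f (n = %d)\n",
              x$mode, x$intercept, x$slope,
              ifelse(is.na(x$r_squared), NaN, x$r_squared), x$n))
  invisible(x)
}

#' Convert RLU to uM ATP on a fitted standard curve (and back)
#'
#' `rlu_to_atp` computes `(rlu - intercept) / slope`, floored at zero;
#' `atp_to_rlu` is its inverse on the fitted line.
#'
#' @param rlu,atp_um readings / concentrations.
#' @param curve an [fit_atp_curve()] result in `vs_concentration` mode.
#' @return converted values.
#' @export
rlu_to_atp <- function(rlu, curve) {
  stopifnot(inherits(curve, "atp_curve"))
  if (curve$mode != "vs_concentration")
    stop("curve must be in 'vs_concentration' mode to convert RLU to uM ATP")
  pmax((rlu - curve$intercept) / curve$slope, 0)
}

#' @rdname rlu_to_atp
#' @export
atp_to_rlu <- function(atp_um, curve) {
  stopifnot(inherits(curve, "atp_curve"))
  if (curve$mode != "vs_concentration")
    stop("curve must be in 'vs_concentration' mode")
  curve$intercept + curve$slope * atp_um
}

#' Crystal-violet viability summary for a two-arm comparison
#'
#' Crystal violet stains the nuclei of adherent living cells, so the OD at
#' 595 nm is proportional to the number of living cells in the well.
#' Summarises replicate OD readings per arm (mean, SD), compares the two arms
#' with the two-tailed unpaired t test, and reports fractional viability
#' `mean(treated) / mean(control)` — scale-invariant, so instrument gain
#' cancels.
#'
#' @param readouts an `assay_readouts`-style data.frame (`arm`,
#'   `readout_type`, `value`); only `OD595` rows are used.
#' @param arms length-2 character vector `c(control, treated)`; both must be
#'   present with at least 2 replicates each.
#' @return an object of class `cv_summary`: per-arm `summary` data.frame,
#'   `comparison` (a `group_comparison`), and `viability`.
#' @export
crystal_violet_summary <- function(readouts, arms) {
  stopifnot(is.data.frame(readouts), length(arms) == 2)
  od <- readouts[readouts$readout_type == "OD595", , drop = FALSE]
  vals <- lapply(arms, function(a) od$value[od$arm == a])
  names(vals) <- arms
  for (a in arms)
    if (length(vals[[a]]) < 2)
      stop("arm '", a, "' needs at least 2 replicate OD595 values (has ",
           length(vals[[a]]), ")")
  summ <- data.frame(arm = arms,
                     n = vapply(vals, length, integer(1)),
                     mean = vapply(vals, mean, numeric(1)),
                     sd = vapply(vals, stats::sd, numeric(1)),
                     stringsAsFactors = FALSE)
  cmp <- compare_groups(vals[[1]], vals[[2]], arm_a = arms[1], arm_b = arms[2])
  structure(list(summary = summ, comparison = cmp,
                 viability = summ$mean[2] / summ$mean[1]),
            class = "cv_summary")
}

#' @export
print.cv_summary <- function(x, ...) {
  print(x$summary)
  cat(sprintf("fractional viability (%s / %s): %.3f, p = %.3g\n",
              x$summary$arm[2], x$summary$arm[1], x$viability,
              x$comparison$p_two_sided))
  invisible(x)
}
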