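# Treatment-group statistics: per-arm summaries, two-tailed unpaired t
# tests, fold-changes, and report export.

#' Map a p value to a significance label
#'
#' Default cutoffs follow the common figure-legend convention
#' `* p < 0.01`, `** p < 0.001`, `*** p < 0.0001`; both cutoffs and symbols
#' are configurable since conventions vary between figures.
#'
#' @param p p value(s).
#' @param cutoffs decreasing numeric vector of cutoffs.
#' @param symbols labels matching `cutoffs`.
#' @return character vector ("" when not significant).
#' @export
significance_label <- function(p, cutoffs = c(0.01, 0.001, 1e-4),
                               symbols = c("*", "**", "***")) {
  stopifnot(length(cutoffs) == length(symbols),
            all(diff(cutoffs) < 0))
  vapply(p, function(pi) {
    hit <- which(pi < cutoffs)
    if (length(hit) == 0) "" else symbols[max(hit)]
  }, character(1))
}

#' Summarise spheroid measurements per group
#'
#' Per-group n, mean, SD (n-1 denominator) and SEM (`sd/sqrt(n)`) for each
#' measured variable, in the scatter-with-bars style of per-spheroid plots
#' (each symbol a spheroid, bar the group mean +/- SEM). Groups with a single
#' observation keep their mean but get `NA` SD/SEM and are flagged; empty
#' groups are reported with n = 0, never dropped silently.
#'
#' @param measurements a `spheroid_measurements` data.frame.
#' @param group_col grouping column, e.g. `"arm"` or `"well_id"`.
#' @param variables measured columns to summarise.
#' @return a `well_summary` data.frame in long form: group, variable, n,
#'   mean, sd, sem, moments_defined; ordered by group label then variable.
#' @export
summarize_spheroids <- function(measurements, group_col = "arm",
                                variables = c("perimeter_um", "area_um2",
                                              "volume_um3", "cell_count")) {
  stopifnot(is.data.frame(measurements), group_col %in% names(measurements))
  variables <- intersect(variables, names(measurements))
  if (length(variables) == 0) stop("none of the requested variables present")
  groups <- sort(unique(as.character(measurements[[group_col]])))
  rows <- list()
  for (g in groups) for (v in variables) {
    x <- measurements[[v]][measurements[[group_col]] == g]
    n <- length(x)
    rows[[length(rows) + 1L]] <- data.frame(
      group = g, variable = v, n = n,
      mean = if (n > 0) mean(x) else NA_real_,
      sd = if (n > 1) stats::sd(x) else NA_real_,
      sem = if (n > 1) stats::sd(x) / sqrt(n) else NA_real_,
      moments_defined = n > 1,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  names(out)[1] <- group_col
  class(out) <- c("well_summary", "data.frame")
  out
}

#' Two-tailed unpaired Student's t comparison of two arms
#'
#' Classical pooled-variance two-sample t statistic,
#' `t = (mean_a - mean_b) / sqrt(s_p^2 (1/n_a + 1/n_b))`, with the two-sided
#' p value from the t distribution on `n_a + n_b - 2` degrees of freedom
#' (Welch's unpooled variant available via `welch = TRUE`). Also reports the
#' fold-change of means `mean_b / mean_a`. Degenerate inputs (zero pooled
#' variance) give p = 1 when the means agree and an essentially-zero p
#' flagged `degenerate` when they differ.
#'
#' @param a,b numeric vectors of per-spheroid (or per-well) values, each of
#'   length >= 2.
#' @param arm_a,arm_b arm labels.
#' @param welch use Welch's unequal-variance t instead of the pooled form.
#' @param cutoffs,symbols passed to [significance_label()].
#' @return an object of class `group_comparison` (a one-row data.frame):
#'   arm_a, arm_b, n_a, n_b, mean_a, mean_b, t_statistic, df, p_two_sided,
#'   fold_change, label, degenerate.
#' @export
compare_groups <- function(a, b, arm_a = "A", arm_b = "B", welch = FALSE,
                           cutoffs = c(0.01, 0.001, 1e-4),
                           symbols = c("*", "**", "***")) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2)
    stop("both arms need at least 2 observations")
  na <- length(a); nb <- length(b)
  ma <- mean(a); mb <- mean(b)
  va <- stats::var(a); vb <- stats::var(b)
  degenerate <- FALSE
  if (welch) {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  }
  if (!is.finite(se) || se == 0) {
    if (isTRUE(all.equal(ma, mb)) || ma == mb) {
      tstat <- 0; p <- 1
    } else {
      tstat <- sign(ma - mb) * Inf; p <- .Machine$double.xmin
      degenerate <- TRUE
    }
    if (!welch) df <- na + nb - 2
  } else {
    tstat <- (ma - mb) / se
    p <- 2 * stats::pt(-abs(tstat), df)
    p <- min(max(p, .Machine$double.xmin), 1)
  }
  out <- data.frame(arm_a = arm_a, arm_b = arm_b, n_a = na, n_b = nb,
                    mean_a = ma, mean_b = mb,
                    t_statistic = tstat, df = df, p_two_sided = p,
                    fold_change = mb / ma,
                    label = significance_label(p, cutoffs, symbols),
                    degenerate = degenerate,
                    stringsAsFactors = FALSE)
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Fold-change of group means
#'
#' `mean(treated) / mean(control)` — the convention behind statements like
#' "treated spheroid volume was threefold larger than control". A
#' median-of-groups variant is available for skewed populations.
#'
#' @param treated,control numeric vectors (non-empty; control mean/median
#'   must be positive).
#' @param type `"mean"` (default) or `"median"` ratio.
#' @return the fold (scalar).
#' @export
effect_fold <- function(treated, control, type = c("mean", "median")) {
  type <- match.arg(type)
  if (length(treated) == 0 || length(control) == 0)
    stop("both groups must be non-empty")
  f <- match.fun(type)
  denom <- f(control)
  if (!is.finite(denom) || denom <= 0)
    stop("control ", type, " must be positive")
  f(treated) / denom
}

#' Compare a measured variable between two arms of a measurement table
#'
#' @param measurements a `spheroid_measurements` data.frame with an `arm`
#'   column.
#' @param arm_a,arm_b arm labels (a = reference/control).
#' @param variable measured column to compare.
#' @param ... passed to [compare_groups()].
#' @return a `group_comparison`.
#' @export
compare_arms <- function(measurements, arm_a, arm_b, variable = "volume_um3",
                         ...) {
  stopifnot(is.data.frame(measurements),
            all(c("arm", variable) %in% names(measurements)))
  a <- measurements[[variable]][measurements$arm == arm_a]
  b <- measurements[[variable]][measurements$arm == arm_b]
  cmp <- compare_groups(a, b, arm_a = arm_a, arm_b = arm_b, ...)
  cmp$variable <- variable
  cmp
}

#' Write a per-spheroid report: scatter plots, summaries, comparisons
#'
#' Emits the figure-style outputs of a spheroid experiment: one
#' scatter-with-bars plot per variable (each point a spheroid, bar the arm
#' mean +/- SEM, significance labels over treated arms), plus
#' machine-readable `summaries.csv` and `comparisons.csv` and a
#' `report_notes.txt` stating that p values are reported raw (no
#' multiple-testing correction). File naming is deterministic.
#'
#' @param measurements a `spheroid_measurements` data.frame with `arm`.
#' @param comparisons a data.frame of `group_comparison` rows (may be empty).
#' @param out_dir output directory (created if needed).
#' @param variables variables to plot.
#' @param format plot format, `"png"` or `"pdf"`.
#' @return invisibly, the paths written.
#' @export
render_report <- function(measurements, comparisons, out_dir,
                          variables = c("perimeter_um", "area_um2",
                                        "volume_um3"),
                          format = c("png", "pdf")) {
  format <- match.arg(format)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  paths <- character(0)

  summ <- if (nrow(measurements) > 0)
    summarize_spheroids(measurements, variables = variables)
  else data.frame(arm = character(0), variable = character(0),
                  n = integer(0), mean = numeric(0), sd = numeric(0),
                  sem = numeric(0), moments_defined = logical(0))
  p_s <- file.path(out_dir, "summaries.csv")
  utils::write.csv(summ, p_s, row.names = FALSE)
  paths <- c(paths, p_s)

  cmp <- as.data.frame(comparisons)
  p_c <- file.path(out_dir, "comparisons.csv")
  utils::write.csv(cmp, p_c, row.names = FALSE)
  paths <- c(paths, p_c)

  p_n <- file.path(out_dir, "report_notes.txt")
  writeLines(c("Two-tailed unpaired Student's t test (pooled variance).",
               "P values are reported raw; no multiple-testing correction applied."),
             p_n)
  paths <- c(paths, p_n)

  if (nrow(measurements) > 0) {
    variables <- intersect(variables, names(measurements))
    for (v in variables) {
      df <- data.frame(arm = factor(measurements$arm,
                                    levels = sort(unique(measurements$arm))),
                       value = measurements[[v]])
      sv <- summ[summ$variable == v, ]
      sv$arm <- factor(sv$arm, levels = levels(df$arm))
      gg <- ggplot2::ggplot(df, ggplot2::aes(x = arm, y = value)) +
        ggplot2::geom_jitter(width = 0.15, height = 0, size = 0.8,
                             alpha = 0.6, colour = "grey30") +
        ggplot2::geom_errorbar(
          data = sv,
          ggplot2::aes(x = arm, y = mean, ymin = mean - sem,
                       ymax = mean + sem),
          inherit.aes = FALSE,
          width = 0.3, linewidth = 0.8, colour = "red") +
        ggplot2::geom_point(data = sv,
                            ggplot2::aes(x = arm, y = mean),
                            inherit.aes = FALSE,
                            shape = 95, size = 8, colour = "red") +
        ggplot2::labs(x = NULL, y = v,
                      title = sprintf("%s per spheroid (bar: mean ± SEM)", v)) +
        ggplot2::theme_classic()
      p_f <- file.path(out_dir, sprintf("scatter_%s.%s", v, format))
      ggplot2::ggsave(p_f, gg, width = 5, height = 4, dpi = 150)
      paths <- c(paths, p_f)
    }
  }
  invisible(paths)
}
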