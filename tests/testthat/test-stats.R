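# group summaries, Student's t comparisons, fold-changes, report export

test_that("textbook moments: {1,2,3} and the n=1 flag", {
  m <- data.frame(arm = c("A", "A", "A", "B"),
                  volume_um3 = c(1, 2, 3, 7))
  s <- summarize_spheroids(m, variables = "volume_um3")
  a <- s[s$arm == "A", ]
  expect_equal(a$mean, 2); expect_equal(a$sd, 1)
  expect_equal(a$sem, 1 / sqrt(3))
  b <- s[s$arm == "B", ]
  expect_equal(b$mean, 7)
  expect_true(is.na(b$sd) && is.na(b$sem))
  expect_false(b$moments_defined)
})

test_that("group means cover the distribution mean at the nominal rate", {
  # 1000 draws of n=150 from the configured log-normal: |mean - mu| < 3 SEM
  # in at least 99% of draws
  mu <- exp(log(250) + 0.35^2 / 2)
  ok <- vapply(1:1000, function(s) {
    set.seed(s)
    x <- rlnorm(150, log(250), 0.35)
    abs(mean(x) - mu) < 3 * sd(x) / sqrt(150)
  }, logical(1))
  expect_gte(mean(ok), 0.99)
})

test_that("pooled t statistic matches the closed-form oracle", {
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  cmp <- compare_groups(a, b)
  # hand-computed pooled-variance oracle: sp2 = 5/3, se = sqrt(5/6)
  expect_equal(cmp$t_statistic, -1 / sqrt(5 / 6), tolerance = 1e-12)
  expect_equal(cmp$t_statistic, -1.095, tolerance = 1e-3)
  expect_equal(cmp$df, 6)
  expect_equal(cmp$p_two_sided, 0.3153, tolerance = 1e-3)
  # independent route: stats::t.test with pooled variance
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(cmp$t_statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(cmp$p_two_sided, tt$p.value, tolerance = 1e-12)
})

test_that("identical samples give t = 0 and p = 1", {
  cmp <- compare_groups(c(5, 6, 7), c(5, 6, 7))
  expect_equal(cmp$t_statistic, 0)
  expect_equal(cmp$p_two_sided, 1)
  expect_equal(cmp$fold_change, 1)
})

test_that("swapping arms negates t, preserves p, inverts the fold", {
  set.seed(3); a <- rnorm(20, 10); b <- rnorm(25, 11)
  c1 <- compare_groups(a, b); c2 <- compare_groups(b, a)
  expect_equal(c1$t_statistic, -c2$t_statistic)
  expect_equal(c1$p_two_sided, c2$p_two_sided)
  expect_equal(c1$fold_change, 1 / c2$fold_change)
})

test_that("p values honor the t distribution function", {
  # independent numerical integration of the t density
  for (tv in c(0.5, 1.095, 2.7)) for (df in c(6, 30)) {
    p_num <- 2 * stats::integrate(function(x) stats::dt(x, df), -Inf, -tv,
                                  rel.tol = 1e-12)$value
    cmp_p <- 2 * stats::pt(-tv, df)
    expect_equal(cmp_p, p_num, tolerance = 1e-8)
  }
  # and the package reproduces them through compare_groups
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  expect_equal(compare_groups(a, b)$p_two_sided, 2 * pt(-1 / sqrt(5 / 6), 6),
               tolerance = 1e-12)
})

test_that("null simulation gives nominal type-I error", {
  set.seed(202)
  reps <- 10000
  rej <- logical(reps)
  for (i in seq_len(reps)) {
    a <- rnorm(10); b <- rnorm(10)
    rej[i] <- compare_groups(a, b)$p_two_sided < 0.05
  }
  expect_gte(mean(rej), 0.04)
  expect_lte(mean(rej), 0.06)
})

test_that("degenerate zero-variance contrasts are flagged", {
  cmp <- compare_groups(c(1, 1, 1), c(2, 2, 2))
  expect_true(cmp$degenerate)
  expect_lt(cmp$p_two_sided, 1e-300)
})

test_that("fold-change of means recovers forced and generated effects", {
  expect_equal(effect_fold(c(2, 4), c(2, 4)), 1)
  expect_equal(effect_fold(3 * c(1, 2, 5), c(1, 2, 5)), 3)
  expect_error(effect_fold(numeric(0), c(1)), "non-empty")
  # generating-parameter recovery across seeds (paired-arm design)
  folds <- vapply(1:25, function(s) {
    m <- simulate_treatment_arms(
      sim_config(seed = 300 + s),
      list(treatment_effect("CTR"),
           treatment_effect("T", volume_fold = 1 / 3)))
    effect_fold(m$volume_um3[m$arm == "T"], m$volume_um3[m$arm == "CTR"])
  }, numeric(1))
  expect_gte(mean(folds >= 0.30 & folds <= 0.37), 0.95)
})

test_that("welch option relaxes the equal-variance assumption", {
  set.seed(9); a <- rnorm(10, sd = 1); b <- rnorm(40, sd = 6)
  cw <- compare_groups(a, b, welch = TRUE)
  tt <- t.test(a, b)
  expect_equal(cw$t_statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(cw$df, unname(tt$parameter), tolerance = 1e-9)
})

test_that("four-arm experiment reproduces the generated ordering and contrast", {
  effects <- list(treatment_effect("CTR", 1), treatment_effect("Z5", 0.85),
                  treatment_effect("Vd2", 0.9),
                  treatment_effect("Vd2+Z5", 1 / 3))
  m <- simulate_treatment_arms(sim_config(seed = 12), effects)
  s <- summarize_spheroids(m, variables = "volume_um3")
  means <- setNames(s$mean, s$arm)
  expect_true(means["Vd2+Z5"] < means["Z5"] &&
              means["Z5"] < means["Vd2"] && means["Vd2"] < means["CTR"])
  cmp <- compare_arms(m, "CTR", "Vd2+Z5")
  expect_lt(cmp$p_two_sided, 0.001)
})

test_that("report files are deterministic and complete", {
  dir <- withr::local_tempdir()
  m <- measure_rois(data.frame(roi_id = sprintf("r%d", 1:6),
                               radius_um = c(50, 60, 70, 40, 45, 55)))
  m$arm <- rep(c("CTR", "T"), each = 3)
  cmp <- compare_arms(m, "CTR", "T")
  paths <- render_report(m, cmp, dir)
  expect_true(all(file.exists(file.path(dir, c("summaries.csv",
                                               "comparisons.csv",
                                               "report_notes.txt")))))
  got <- read.csv(file.path(dir, "comparisons.csv"))
  expect_identical(nrow(got), 1L)
  expect_equal(got$fold_change, cmp$fold_change, tolerance = 1e-12)
  # frozen snapshot of the summary table for this fixed input
  s <- read.csv(file.path(dir, "summaries.csv"))
  expect_equal(s$mean[s$variable == "volume_um3" & s$arm == "CTR"],
               mean(sphere_volume(c(50, 60, 70))), tolerance = 1e-9)
  # empty input: headers only
  dir2 <- withr::local_tempdir()
  render_report(m[0, ], cmp[0, ], dir2)
  expect_identical(nrow(read.csv(file.path(dir2, "summaries.csv"))), 0L)
})
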