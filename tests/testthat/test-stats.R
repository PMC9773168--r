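test_that("Student's t matches the hand-pooled textbook formula", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  res <- students_t(a, b, boot_reps = 0)
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(res$statistic, t_hand)
  expect_equal(res$df, 4)
  expect_equal(res$p, 2 * pt(abs(t_hand), 4, lower.tail = FALSE))
  # swapping samples negates t, preserves p
  rev <- students_t(b, a, boot_reps = 0)
  expect_equal(rev$statistic, -res$statistic)
  expect_equal(rev$p, res$p)
})

test_that("degenerate zero-variance t-tests are flagged, not fatal", {
  same <- students_t(rep(2, 5), rep(2, 5), boot_reps = 0)
  expect_equal(same$statistic, 0); expect_equal(same$p, 1)
  diff <- students_t(rep(2, 5), rep(3, 5), boot_reps = 0)
  expect_true(is.infinite(diff$statistic)); expect_equal(diff$p, 0)
  expect_true(diff$degenerate)
  ident <- students_t(c(1, 2, 3), c(1, 2, 3), boot_reps = 0)
  expect_equal(ident$statistic, 0); expect_equal(ident$p, 1)
})

test_that("two-group ANOVA F equals the pooled t squared", {
  set.seed(7)
  x <- rnorm(20, 5, 2); y <- rnorm(25, 6, 2)
  fit <- oneway_anova(c(x, y), rep(c("a", "b"), c(20, 25)))
  tt <- students_t(x, y, boot_reps = 0)
  expect_equal(fit$F, tt$statistic^2)
  expect_equal(fit$p, tt$p)
  # cross-check the omnibus F against the base-R route
  ref <- stats::oneway.test(v ~ g, data.frame(v = c(x, y),
                                              g = rep(c("a", "b"), c(20, 25))),
                            var.equal = TRUE)
  expect_equal(fit$F, unname(ref$statistic))
  expect_equal(fit$p, ref$p.value)
})

test_that("ANOVA rejects degenerate layouts and has ~5% null size", {
  expect_error(oneway_anova(1:5, rep("a", 5)), "at least 2")
  expect_error(oneway_anova(c(1, 2), c("a", "b")), "size 1")
  set.seed(101)
  rej <- mean(replicate(2000, {
    v <- rnorm(36)
    oneway_anova(v, rep(letters[1:4], each = 9))$p <= 0.05
  }))
  expect_gt(rej, 0.035); expect_lt(rej, 0.065)
})

test_that("a two-cell planned contrast reproduces the pooled two-sample t", {
  set.seed(12)
  x <- rnorm(15, 10, 3); y <- rnorm(18, 12, 3)
  fit <- oneway_anova(c(x, y), rep(c("g1", "g2"), c(15, 18)))
  w <- c(g1 = 1, g2 = -1)
  pc <- planned_contrast(fit, w, boot_reps = 0)
  tt <- students_t(x, y, boot_reps = 0)
  expect_equal(pc$statistic, tt$statistic)
  expect_equal(pc$p, tt$p)
  expect_equal(pc$estimate, mean(x) - mean(y))
})

test_that("contrast validation: zero-sum weights, empty cells, identical groups", {
  set.seed(3)
  vals <- rnorm(30); grp <- rep(c("a", "b", "c"), 10)
  fit <- oneway_anova(vals, grp)
  expect_error(planned_contrast(fit, c(a = 1, b = -0.5)), "sum to zero")
  expect_error(planned_contrast(fit, c(a = 1, d = -1)), "empty cells")
  two <- rep(c(1, 2, 3), 4)
  fit2 <- oneway_anova(c(two, two), rep(c("g1", "g2"), each = 12))
  pc <- planned_contrast(fit2, c(g1 = 1, g2 = -1), boot_reps = 0)
  expect_equal(pc$estimate, 0)
  expect_equal(pc$p, 1)
})

test_that("the 17 planned contrasts are well-formed", {
  specs <- contrast_specs()
  expect_length(specs, 17)
  cells <- all_groups()$cell
  for (w in specs) {
    expect_equal(sum(w), 0)
    expect_setequal(names(w), cells)
    expect_true(any(w > 0) && any(w < 0))
  }
  # lumped contrasts use 1/3 per constituent cell
  w <- specs[["All MH vs All FH"]]
  expect_equal(unname(w["M.healthy.45-54"]), 1 / 3)
  expect_equal(unname(w["F.healthy.65-74"]), -1 / 3)
  expect_equal(sum(w != 0), 6)
})

test_that("Bonferroni threshold rounds the familywise quotient", {
  expect_equal(bonferroni_alpha(17, 0.05, 3), 0.003)
  expect_equal(bonferroni_alpha(1, 0.05, 3), 0.05)
  expect_equal(bonferroni_alpha(5, 0.05, 3), 0.01)
  expect_equal(bonferroni_alpha(17, 0.05, NULL), 0.05 / 17)
  expect_error(bonferroni_alpha(0), "at least 1")
})

test_that("bootstrap CI: reproducible, degenerate on constants, ~95% coverage", {
  x <- rnorm(50)
  ci1 <- bootstrap_ci(x, mean, reps = 500, seed = 5)
  ci2 <- bootstrap_ci(x, mean, reps = 500, seed = 5)
  expect_identical(ci1, ci2)
  expect_equal(bootstrap_ci(rep(3, 10), mean, reps = 200, seed = 1), c(3, 3))
  expect_error(bootstrap_ci(x, mean, reps = 50), "at least 100")
  set.seed(61)
  cover <- mean(replicate(150, {
    d <- rnorm(100)
    ci <- bootstrap_ci(d, mean, reps = 1000, seed = sample(1e6, 1))
    ci[1] <= 0 && 0 <= ci[2]
  }))
  expect_gt(cover, 0.88); expect_lt(cover, 0.99)
})

test_that("bootstrap CIs shrink at roughly 1/sqrt(n)", {
  set.seed(8)
  widths <- sapply(c(50, 200, 800), function(n) {
    ci <- bootstrap_ci(rnorm(n), mean, reps = 800, seed = 3)
    diff(ci)
  })
  expect_true(all(diff(widths) < 0))
  expect_equal(widths[1] / widths[3], 4, tolerance = 0.4)
})

test_that("Pearson correlation: exact limits, null behaviour, degeneracy", {
  x <- 1:20
  expect_equal(pearson_cor(x, 2 * x, boot_reps = 0)$r, 1)
  expect_equal(pearson_cor(x, -x, boot_reps = 0)$r, -1)
  expect_error(pearson_cor(rep(1, 10), rnorm(10)), "zero-variance")
  expect_error(pearson_cor(1:2, 2:3), "at least 3")
  set.seed(17)
  res <- pearson_cor(rnorm(1000), rnorm(1000), boot_reps = 200, seed = 2)
  expect_lt(abs(res$r), 0.1)
  ps <- replicate(500, pearson_cor(rnorm(30), rnorm(30), boot_reps = 0)$p)
  expect_gt(mean(ps <= 0.05), 0.02); expect_lt(mean(ps <= 0.05), 0.09)
})

test_that("run_battery produces the documented structure on a measured cohort", {
  cfg <- cohort_config(default_n = 8L, n_frames = 12L, n_points = 24L)
  meas <- measure_cohort(generate_cohort(cfg, master_seed = 31))
  bat <- run_battery(meas, boot_reps = 100, seed = 9)
  expect_s3_class(bat, "strain_battery")
  expect_equal(nrow(bat$t_tests), 18)          # 9 variables x 2 lumpings
  expect_equal(nrow(bat$anova), 9)
  expect_lte(nrow(bat$contrasts), 153)         # 9 x 17 upper bound
  expect_equal(nrow(bat$correlations), 4 * 8 * 2)
  expect_equal(bat$threshold, 0.003)
  expect_true(all(bat$contrasts$p >= 0 & bat$contrasts$p <= 1, na.rm = TRUE))
  expect_true(all(bat$t_tests$p >= 0 & bat$t_tests$p <= 1, na.rm = TRUE))
  # contrasts appear only for ANOVA-gated variables
  gated <- bat$anova$variable[bat$anova$gated_in]
  expect_setequal(unique(bat$contrasts$variable), gated)
})

test_that("a planted male/female BCS offset is detected by the lumped contrast", {
  # two simulated cohorts with a 1-pooled-SD sex offset in BCS
  set.seed(55)
  cells <- all_groups()
  detected <- replicate(5, {
    n <- 60
    tab <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      mu <- if (cells$sex[i] == "M") -28 else -32   # 1 SD apart, SD = 4
      data.frame(cell = cells$cell[i], sex = cells$sex[i],
                 health = cells$health[i], age = 60,
                 BCS = rnorm(n, mu, 4))
    }))
    fit <- oneway_anova(tab$BCS, tab$cell)
    pc <- planned_contrast(fit, contrast_specs()[["All MH vs All FH"]],
                           threshold = 0.003, boot_reps = 0)
    pc$significant
  })
  expect_true(all(detected))
})
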