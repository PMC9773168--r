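test_that("subject sampling is reproducible and respects inclusion ranges", {
  g <- all_groups()[3, ]
  s1 <- sample_subject(g, seed = 9)
  s2 <- sample_subject(g, seed = 9)
  expect_identical(s1, s2)
  s3 <- sample_subject(g, seed = 10)
  expect_false(isTRUE(all.equal(s1$edv_true, s3$edv_true)))
  set.seed(5)
  for (i in 1:25) {
    g <- all_groups()[sample(12, 1), ]
    s <- sample_subject(g, seed = sample(1e6, 1))
    lim <- switch(g$age_band, "45-54" = c(45, 55), "55-64" = c(55, 65),
                  "65-74" = c(65, 75))
    expect_true(s$age >= lim[1] && s$age < lim[2])
    expect_true(s$bmi_true >= 18.5 && s$bmi_true <= 30)
    # BMI consistent with the derived height/weight to 0.1
    expect_equal(s$weight / (s$height / 100)^2, s$bmi_true, tolerance = 1e-6)
    expect_true(all(c(s$c_base, s$c_mid, s$c_apex) > 0 &
                      c(s$c_base, s$c_mid, s$c_apex) < 1))
  }
})

test_that("regional deficit modifier scales the affected region's contraction", {
  g <- all_groups()[all_groups()$health == "unhealthy", ][1, ]
  s0 <- sample_subject(g, seed = 33, deficit = 0)
  s5 <- sample_subject(g, seed = 33, deficit = 0.5, deficit_region = "mid")
  expect_equal(s5$c_mid, 0.5 * s0$c_mid)
  expect_equal(s5$c_base, s0$c_base)
  expect_error(sample_subject(g, seed = 1, deficit = 1), "0, 1")
  bad <- list(sex = "F", age_band = "45-54", health = "nope")
  expect_error(sample_subject(bad, seed = 1), "configuration error")
})

test_that("jitter-free phantom reproduces contraction and EDV exactly", {
  for (n_sl in c(6, 8, 10)) {
    subj <- fixture_subject(cell_row = n_sl - 4, seed = n_sl)
    st <- synthesize_cine(subj, acquisition_params(n_sl), seed = 1,
                          jitter_sd = 0)
    fit <- strain_analysis(st)
    expect_equal(unname(fit$strains["BCS"]), -100 * subj$c_base)
    expect_equal(unname(fit$strains["MCS"]), -100 * subj$c_mid)
    expect_equal(unname(fit$strains["ACS"]), -100 * subj$c_apex)
    # frame 1 (end diastole) has zero strain on every slice
    expect_true(all(vapply(fit$curves, function(cv) cv$strain[1],
                           numeric(1)) == 0))
    v <- volume_indices(st)
    expect_equal(v$EDV, subj$edv_true, tolerance = 1e-10)
  }
})

test_that("phantom ED stack volume matches the analytic truncated ellipsoid", {
  subj <- fixture_subject(seed = 4)
  st <- synthesize_cine(subj, acquisition_params(8), seed = 1, jitter_sd = 0)
  # reconstruct r0 from the most basal slice and compare with the closed form
  spacing <- 10; n <- 8; L <- n * spacing
  z1 <- 0.5 * spacing
  r1 <- mean(sqrt(rowSums(as.matrix(st$contours[[1]][[1]])^2)))
  r0 <- r1 / sqrt(1 - (z1 / L)^2)
  v_analytic <- (2 / 3) * pi * r0^2 * L / 1000
  expect_equal(volume_indices(st)$EDV, v_analytic, tolerance = 0.02)
})

test_that("dilatation raises measured EDV; weaker contraction lowers LVEF", {
  subj <- fixture_subject(seed = 8)
  acq <- acquisition_params(8)
  edvs <- sapply(c(1, 1.1, 1.25), function(f) {
    s <- subj; s$dilatation <- f
    volume_indices(synthesize_cine(s, acq, seed = 2, jitter_sd = 0))$EDV
  })
  expect_true(all(diff(edvs) > 0))
  efs <- sapply(c(1, 0.7, 0.4), function(scale) {
    s <- subj
    s$c_base <- s$c_base * scale; s$c_mid <- s$c_mid * scale
    s$c_apex <- s$c_apex * scale
    volume_indices(synthesize_cine(s, acq, seed = 2, jitter_sd = 0))$LVEF
  })
  expect_true(all(diff(efs) < 0))
  s <- subj; s$c_mid <- 1.2
  expect_error(synthesize_cine(s, acq), "degenerate")
})

test_that("cohort generation is deterministic and sized per config", {
  cfg <- cohort_config(default_n = 2L, n_frames = 11L, n_points = 24L)
  co1 <- generate_cohort(cfg, master_seed = 77)
  co2 <- generate_cohort(cfg, master_seed = 77)
  expect_equal(nrow(co1$subjects), 24)
  expect_identical(co1$subjects, co2$subjects)
  expect_identical(co1$stacks[[5]]$contours, co2$stacks[[5]]$contours)
  co3 <- generate_cohort(cfg, master_seed = 78)
  expect_false(identical(co1$subjects$edv_true, co3$subjects$edv_true))
  expect_error(cohort_config(default_n = 0L), "positive")
  expect_error(generate_cohort(cohort_config(group_sizes = c(bogus = 5L))),
               "unknown cells")
})

test_that("cohort means of configured variables are recovered at n = 200", {
  # healthy 55-64 cell, n = 200, jitter on: measured means of MCS and EDV
  # should sit within 3 SE of the configured distribution means
  cfg <- cohort_config(default_n = 100L, n_frames = 20L)
  co <- generate_cohort(cfg, master_seed = 202,
                        cells = c("F.healthy.55-64", "M.healthy.55-64"))
  meas <- measure_cohort(co)
  cell <- meas[meas$age_band == "55-64" & meas$health == "healthy", ]
  expect_equal(nrow(cell), 200)
  d <- default_distributions()$healthy[["55-64"]]
  expect_lt(abs(mean(cell$MCS) - d$mcs[1]), 3 * d$mcs[2] / sqrt(200) + 0.5)
  expect_lt(abs(mean(cell$EDV) - d$edv[1]), 3 * d$edv[2] / sqrt(200))
})
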