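test_that("inclusion filters tag each exclusion with its failing rule", {
  rec <- make_records(6)
  rec$bmi[2] <- 31          # out of range
  rec$age[3] <- 44          # too young
  rec$diabetes[4] <- TRUE
  rec$ethnicity[5] <- "other"
  rec$bmi[6] <- NA          # missing
  out <- apply_inclusion_filters(rec)
  expect_equal(out$kept$id, "R001")
  expect_equal(out$excluded$reason[out$excluded$id == "R002"], "bmi")
  expect_equal(out$excluded$reason[out$excluded$id == "R003"], "age")
  expect_equal(out$excluded$reason[out$excluded$id == "R004"], "diabetes")
  expect_equal(out$excluded$reason[out$excluded$id == "R005"], "ethnicity")
  expect_equal(out$excluded$reason[out$excluded$id == "R006"], "missing-data")
  # idempotent on the kept set
  again <- apply_inclusion_filters(out$kept)
  expect_equal(again$kept, out$kept)
  expect_equal(nrow(again$excluded), 0)
})

test_that("age band edges: 45 and 74.9 in, 44 and 75 out", {
  rec <- make_records(4)
  rec$age <- c(45, 74.9, 44.5, 75)
  out <- apply_inclusion_filters(rec)
  expect_setequal(out$kept$id, c("R001", "R002"))
  expect_true(all(out$excluded$reason == "age"))
})

test_that("stratification is a partition into the 12 cells with flag-driven health", {
  rec <- make_records(8)
  rec$sex <- rep(c("F", "M"), 4)
  rec$age <- c(50, 65, 58, 50, 70, 60, 47, 68)
  rec$stemi <- c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE)
  rec$nstemi <- c(FALSE, TRUE, rep(FALSE, 6))
  rec$hf <- c(rep(FALSE, 7), TRUE)
  st <- stratify(rec)
  expect_equal(st$cell[1], "F.healthy.45-54")
  expect_equal(st$cell[2], "M.unhealthy.65-74")
  expect_equal(st$cell[6], "M.unhealthy.55-64")
  expect_equal(st$cell[8], "M.unhealthy.65-74")
  expect_true(all(st$cell %in% all_groups()$cell))
  # the cell split is a partition: sizes sum to n and ids never repeat
  parts <- attr(st, "cells")
  expect_equal(sum(vapply(parts, nrow, integer(1))), nrow(rec))
  expect_false(anyDuplicated(unlist(lapply(parts, `[[`, "id"))) > 0)
})

test_that("random cell selection is reproducible, and small cells pass whole", {
  rec <- make_records(828)
  s1 <- select_random(rec, 100, seed = 13)
  s2 <- select_random(rec, 100, seed = 13)
  expect_equal(nrow(s1), 100)
  expect_identical(s1, s2)
  s3 <- select_random(rec, 100, seed = 14)
  expect_false(identical(s1$id, s3$id))
  small <- make_records(6)
  expect_warning(keep <- select_random(small, 100, seed = 1), "keeping all")
  expect_equal(nrow(keep), 6)
})

test_that("healthy cells are truncated to n, unhealthy cells pass untouched", {
  healthy <- make_records(150); healthy$age <- 50
  sick <- make_records(6, health = "unhealthy")
  sick$id <- paste0("U", seq_len(6)); sick$age <- 50
  st <- stratify(rbind(healthy, sick))
  suppressWarnings(sel <- select_study_cohort(st, n_healthy = 100, seed = 2))
  expect_equal(sum(sel$health == "healthy"), 100)
  expect_equal(sum(sel$health == "unhealthy"), 6)
})

test_that("the k-SD outlier rule removes exactly the planted individual", {
  set.seed(99)
  n <- 100
  tab <- data.frame(id = sprintf("P%03d", 1:n), cell = "F.healthy.45-54",
                    EDV = rnorm(n, 150, 15), MCS = rnorm(n, -29, 4))
  mu <- mean(tab$MCS); sdv <- sd(tab$MCS)
  tab$MCS[37] <- mu + 5 * sdv
  out <- remove_outliers(tab, c("EDV", "MCS"), k = 2.7)
  expect_true("P037" %in% out$removed_ids)
  expect_equal(out$removed$reason[out$removed$id == "P037"], "outlier:MCS")
  # single pass: nobody new is removed by re-running on the kept set
  expect_lte(nrow(remove_outliers(out$kept, c("EDV", "MCS"), 2.7)$removed),
             nrow(out$removed))
})

test_that("outlier rule edge cases: constant data, huge k, tiny groups, unphysical volumes", {
  tab <- data.frame(id = as.character(1:10), cell = "c1", EDV = rep(150, 10))
  expect_equal(nrow(remove_outliers(tab, "EDV")$removed), 0)
  set.seed(1)
  tab2 <- data.frame(id = as.character(1:50), cell = "c1",
                     EDV = rnorm(50, 150, 20))
  expect_equal(nrow(remove_outliers(tab2, "EDV", k = 1e6)$removed), 0)
  tiny <- data.frame(id = c("a", "b"), cell = "c1", EDV = c(100, 400))
  expect_warning(out <- remove_outliers(tiny, "EDV"), "fewer than 3")
  expect_equal(nrow(out$removed), 0)
  # data-entry errors 8-10x the expected magnitude precede the SD rule
  tab3 <- data.frame(id = as.character(1:40), cell = "c1",
                     EDV = c(rnorm(39, 150, 10), 150 * 9))
  out3 <- remove_outliers(tab3, "EDV")
  expect_equal(out3$removed$reason, "unphysical:EDV")
})

test_that("group summaries: location, zero-width CI, and CI coverage", {
  tab <- data.frame(cell = "g", x = c(1, 2, 3))
  s <- summarize_groups(tab, "x")
  expect_equal(s$mean, 2); expect_equal(s$median, 2); expect_equal(s$n, 3)
  const <- data.frame(cell = "g", x = rep(5, 8))
  sc <- summarize_groups(const, "x")
  expect_equal(sc$ci_lo, sc$ci_hi)
  # ~95% coverage of the true mean over simulation reps
  set.seed(42)
  hits <- mean(replicate(400, {
    d <- data.frame(cell = "g", x = rnorm(40, 10, 2))
    s <- summarize_groups(d, "x")
    s$ci_lo <= 10 && 10 <= s$ci_hi
  }))
  expect_gt(hits, 0.90); expect_lt(hits, 0.99)
  # missing entries reduce per-variable n, never crash
  tab_na <- data.frame(cell = "g", x = c(1, NA, 3, NA))
  expect_equal(summarize_groups(tab_na, "x")$n, 2)
})
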