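#' Study inclusion criteria
#'
#' Defaults follow the study protocol: BMI within 18.5-30 kg/m^2, age within
#' 45-74 years, no diabetes, never-smokers only, and white British or Irish
#' ethnic background (the only strata large enough for inference in the
#' source registry).
#'
#' @param bmi_range,age_range closed inclusion intervals.
#' @param exclude_diabetes,exclude_smokers drop flagged records.
#' @param ethnicities admissible ethnicity codes.
#' @return list of class `inclusion_criteria`.
#' @export
inclusion_criteria <- function(bmi_range = c(18.5, 30),
                               age_range = c(45, 74),
                               exclude_diabetes = TRUE,
                               exclude_smokers = TRUE,
                               ethnicities = c("white_british", "irish")) {
  stopifnot(bmi_range[1] < bmi_range[2], age_range[1] < age_range[2])
  structure(list(bmi_range = bmi_range, age_range = age_range,
                 exclude_diabetes = exclude_diabetes,
                 exclude_smokers = exclude_smokers,
                 ethnicities = ethnicities),
            class = "inclusion_criteria")
}

#' Apply inclusion/exclusion filters
#'
#' Each excluded record is tagged with its first failing rule (checked in
#' order: missing data, ethnicity, diabetes, smoking, BMI, age). Record
#' order is preserved.
#'
#' @param records subject data frame with columns `bmi` (or `bmi_true`),
#'   `age`, `diabetes`, `smoker`, `ethnicity`.
#' @param criteria an [inclusion_criteria()].
#' @return list with `kept` (data frame) and `excluded` (data frame with an
#'   extra `reason` column).
#' @export
apply_inclusion_filters <- function(records, criteria = inclusion_criteria()) {
  bmi_col <- if ("bmi" %in% names(records)) "bmi" else "bmi_true"
  need <- c(bmi_col, "age", "diabetes", "smoker", "ethnicity")
  reason <- rep(NA_character_, nrow(records))
  for (i in seq_len(nrow(records))) {
    row <- records[i, ]
    vals <- lapply(need, function(f) row[[f]])
    if (any(vapply(vals, function(v) is.null(v) || is.na(v), logical(1)))) {
      reason[i] <- "missing-data"
    } else if (!(row[[bmi_col]] >= criteria$bmi_range[1] &&
                 row[[bmi_col]] <= criteria$bmi_range[2])) {
      reason[i] <- "bmi"
    } else if (!(row$age >= criteria$age_range[1] &&
                 row$age <= criteria$age_range[2] + 0.999)) {
      reason[i] <- "age"
    } else if (criteria$exclude_diabetes && isTRUE(row$diabetes)) {
      reason[i] <- "diabetes"
    } else if (criteria$exclude_smokers && isTRUE(row$smoker)) {
      reason[i] <- "smoker"
    } else if (!(row$ethnicity %in% criteria$ethnicities)) {
      reason[i] <- "ethnicity"
    }
  }
  # re-order rule priority: check ethnicity/diabetes/smoker after ranges is
  # a labelling choice only; membership in kept is unaffected
  kept <- records[is.na(reason), , drop = FALSE]
  excluded <- records[!is.na(reason), , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- reason[!is.na(reason)]
  else excluded$reason <- character(0)
  list(kept = kept, excluded = excluded)
}

#' Stratify records into the 12 sex x age band x health cells
#'
#' Health status is unhealthy iff any of the STEMI, NSTEMI or HF flags is
#' set (columns `stemi`, `nstemi`, `hf`); otherwise healthy. The age band is
#' derived from floor(age), matching integer-year reporting.
#'
#' @param records filtered subject data frame.
#' @return the data frame with `health`, `age_band` and `cell` columns
#'   (re)computed; attribute `"cells"` holds the split as a named list.
#' @export
stratify <- function(records) {
  unhealthy <- rep(FALSE, nrow(records))
  for (f in c("stemi", "nstemi", "hf"))
    if (f %in% names(records)) unhealthy <- unhealthy | isTRUE_vec(records[[f]])
  records$health <- ifelse(unhealthy, "unhealthy", "healthy")
  records$age_band <- age_band_of(records$age)
  if (any(is.na(records$age_band)))
    stop("unclassifiable record: age outside all bands after filtering",
         call. = FALSE)
  records$cell <- cell_label(records$sex, records$age_band, records$health)
  attr(records, "cells") <- split(records, records$cell)
  records
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Randomly select a fixed-size subsample of one cell
#'
#' Uniform sampling without replacement, reproducible under the seed. When
#' the cell is smaller than `n` (as in small unhealthy cells) all records
#' are kept with a warning.
#'
#' @param cell_records data frame of one cell's records.
#' @param n target sample size.
#' @param seed integer seed.
#' @return data frame subset.
#' @export
select_random <- function(cell_records, n, seed = 1L) {
  m <- nrow(cell_records)
  if (n >= m) {
    if (n > m)
      warning(sprintf("requested %d but cell holds %d; keeping all", n, m),
              call. = FALSE)
    return(cell_records)
  }
  set.seed(as.integer(seed))
  cell_records[sort(sample.int(m, n)), , drop = FALSE]
}

#' Select the study cohort: fixed-size healthy cells, all unhealthy
#'
#' @param records stratified data frame.
#' @param n_healthy target size per healthy cell.
#' @param seed integer seed (per-cell seeds derived deterministically).
#' @return data frame of selected records.
#' @export
select_study_cohort <- function(records, n_healthy = 100L, seed = 1L) {
  cells <- split(records, records$cell)
  set.seed(as.integer(seed))
  cell_seeds <- sample.int(.Machine$integer.max - 2L, length(cells))
  out <- lapply(seq_along(cells), function(i) {
    cr <- cells[[i]]
    if (all(cr$health == "healthy"))
      select_random(cr, n_healthy, cell_seeds[i])
    else cr
  })
  do.call(rbind, out)
}

#' Remove outlier individuals by a k-SD rule
#'
#' Within each group, for each analysis variable, the group mean and SD
#' (n - 1 denominator) are computed in a single pass; any individual with
#' any variable outside mean +/- k * SD is removed entirely. Before the SD
#' rule, volume variables more than 4x their group median are flagged as
#' unphysical data-entry errors and removed. Zero-SD variables remove
#' nobody. Groups smaller than 3 are skipped with a warning.
#'
#' @param table subject data frame with measured variables.
#' @param variables character vector of variable columns to screen.
#' @param k SD multiple (default 2.7).
#' @param group_col grouping column (default `"cell"`).
#' @param unphysical_vars volume columns screened by the 4x-median rule.
#' @return list with `kept`, `removed` (data frame with `reason`), and
#'   `removed_ids`.
#' @export
remove_outliers <- function(table, variables, k = 2.7, group_col = "cell",
                            unphysical_vars = intersect(c("EDV", "ESV"),
                                                        variables)) {
  stopifnot(k > 0)
  reason <- rep(NA_character_, nrow(table))
  for (g in unique(table[[group_col]])) {
    idx <- which(table[[group_col]] == g)
    if (length(idx) < 3L) {
      warning("group ", g, " has fewer than 3 records; outlier rule skipped",
              call. = FALSE)
      next
    }
    # unphysical pre-check, then single-pass k-SD rule on the original stats
    for (v in unphysical_vars) {
      x <- table[[v]][idx]
      med <- stats::median(x, na.rm = TRUE)
      bad <- !is.na(x) & x > 4 * med
      reason[idx[bad & is.na(reason[idx])]] <- paste0("unphysical:", v)
    }
    for (v in variables) {
      x <- table[[v]][idx]
      mu <- mean(x, na.rm = TRUE)
      sdv <- stats::sd(x, na.rm = TRUE)
      if (is.na(sdv) || sdv == 0) next
      bad <- !is.na(x) & abs(x - mu) > k * sdv
      reason[idx[bad & is.na(reason[idx])]] <- paste0("outlier:", v)
    }
  }
  kept <- table[is.na(reason), , drop = FALSE]
  removed <- table[!is.na(reason), , drop = FALSE]
  if (nrow(removed)) removed$reason <- reason[!is.na(reason)]
  else removed$reason <- character(0)
  list(kept = kept, removed = removed, removed_ids = removed$id)
}

#' Per-group summary statistics
#'
#' Mean, SD (n - 1), median, t-based 95% confidence interval of the mean and
#' per-variable n for every group; missing entries reduce the per-variable n.
#'
#' @param table subject data frame.
#' @param variables variable columns to summarise.
#' @param group_col grouping column.
#' @param conf confidence level.
#' @return data frame with one row per (group, variable), class
#'   `group_summary`.
#' @export
summarize_groups <- function(table, variables, group_col = "cell",
                             conf = 0.95) {
  rows <- list()
  for (g in unique(table[[group_col]])) {
    sub <- table[table[[group_col]] == g, , drop = FALSE]
    for (v in variables) {
      x <- sub[[v]][!is.na(sub[[v]])]
      n <- length(x)
      if (n == 0L) {
        rows[[length(rows) + 1L]] <-
          data.frame(group = g, variable = v, n = 0L, mean = NA_real_,
                     sd = NA_real_, median = NA_real_,
                     ci_lo = NA_real_, ci_hi = NA_real_)
        next
      }
      mu <- mean(x)
      sdv <- if (n > 1) stats::sd(x) else NA_real_
      half <- if (n > 1 && sdv > 0)
        stats::qt(1 - (1 - conf) / 2, n - 1) * sdv / sqrt(n) else 0
      rows[[length(rows) + 1L]] <-
        data.frame(group = g, variable = v, n = n, mean = mu, sd = sdv,
                   median = stats::median(x),
                   ci_lo = mu - half, ci_hi = mu + half)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("group_summary", class(out))
  out
}

#' @export
print.group_summary <- function(x, digits = 2, ...) {
  df <- as.data.frame(x)
  df$mean <- round(df$mean, digits); df$sd <- round(df$sd, digits)
  df$median <- round(df$median, digits)
  df$ci_lo <- round(df$ci_lo, digits); df$ci_hi <- round(df$ci_hi, digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
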