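#' Pooled-variance Student's t-test with bootstrap CI
#'
#' Classical two-sample Student's t-test (pooled variance, two-sided).
#' A percentile bootstrap confidence interval of the mean difference
#' (case resampling within each sample) is attached when `boot_reps > 0`.
#' Degenerate zero-variance inputs do not error: equal means give t = 0,
#' p = 1; unequal means give infinite t, p = 0, with `degenerate = TRUE`.
#'
#' @param a,b numeric samples (each n >= 2).
#' @param alpha significance level for the `significant` flag.
#' @param boot_reps bootstrap resamples (0 disables).
#' @param seed bootstrap seed.
#' @return one-row data frame: `statistic`, `df`, `p`, `estimate`
#'   (mean(a) - mean(b)), `ci_lo`, `ci_hi`, `significant`, `degenerate`.
#' @export
students_t <- function(a, b, alpha = 0.05, boot_reps = 1000L, seed = 1L) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("both samples need at least 2 observations", call. = FALSE)
  est <- mean(a) - mean(b)
  pooled <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  degenerate <- pooled == 0
  if (degenerate) {
    tt <- if (est == 0) 0 else sign(est) * Inf
    p <- if (est == 0) 1 else 0
    df <- length(a) + length(b) - 2
  } else {
    ht <- stats::t.test(a, b, var.equal = TRUE)
    tt <- unname(ht$statistic); df <- unname(ht$parameter); p <- ht$p.value
  }
  ci <- c(NA_real_, NA_real_)
  if (boot_reps > 0) {
    set.seed(as.integer(seed))
    diffs <- boot_means(a, boot_reps) - boot_means(b, boot_reps)
    ci <- unname(stats::quantile(diffs, c(0.025, 0.975)))
  }
  data.frame(statistic = tt, df = df, p = p, estimate = est,
             ci_lo = ci[1], ci_hi = ci[2],
             significant = p <= alpha, degenerate = degenerate)
}

# reps resampled means of x (case resampling)
boot_means <- function(x, reps) {
  n <- length(x)
  colMeans(matrix(sample(x, n * reps, replace = TRUE), nrow = n))
}

#' One-way ANOVA across groups
#'
#' Standard between/within decomposition with a common error variance
#' (the classical fixed-effects one-way layout, as used to gate planned
#' contrasts). The fit carries the pooled mean-square error used by
#' [planned_contrast()].
#'
#' @param values numeric response vector.
#' @param groups group labels, same length.
#' @return list of class `oneway_fit`: `F`, `df1`, `df2`, `p`, `mse`
#'   (pooled within-group mean square), `means`, `ns` (named per group),
#'   and `data` (values split by group).
#' @export
oneway_anova <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups)[keep]
  split_x <- split(values, groups)
  split_x <- split_x[lengths(split_x) > 0L]
  k <- length(split_x)
  if (k < 2L) stop("need at least 2 non-empty groups", call. = FALSE)
  ns <- lengths(split_x)
  if (all(ns == 1L)) stop("ANOVA undefined: all groups of size 1",
                          call. = FALSE)
  means <- vapply(split_x, mean, numeric(1))
  n_tot <- sum(ns)
  grand <- sum(ns * means) / n_tot
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum(vapply(split_x, function(x) sum((x - mean(x))^2),
                          numeric(1)))
  df1 <- k - 1L
  df2 <- n_tot - k
  mse <- ss_within / df2
  f <- (ss_between / df1) / mse
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  structure(list(F = f, df1 = df1, df2 = df2, p = p, mse = mse,
                 means = means, ns = ns, data = split_x),
            class = "oneway_fit")
}

#' @export
print.oneway_fit <- function(x, ...) {
  cat(sprintf("<oneway_fit> F(%d, %d) = %.3f, p = %.4g (%d groups)\n",
              x$df1, x$df2, x$F, x$p, length(x$ns)))
  invisible(x)
}

#' The study's 17 planned contrasts
#'
#' Weight vectors over the 12 sex x age band x health cells: nine pairwise
#' comparisons among healthy cells (within-sex age comparisons and
#' between-sex age-matched comparisons), three age/sex-matched
#' healthy-unhealthy comparisons, one within-unhealthy age comparison, and
#' four lumped comparisons using equal weights of 1/3 per constituent cell.
#' All weight vectors sum to zero.
#'
#' @return named list of 17 numeric weight vectors, each named by the 12
#'   cell labels of [all_groups()].
#' @export
contrast_specs <- function() {
  cells <- all_groups()$cell
  w0 <- stats::setNames(numeric(length(cells)), cells)
  pair <- function(a, b) { w <- w0; w[a] <- 1; w[b] <- -1; w }
  lump <- function(a, b) {
    w <- w0; w[a] <- 1 / length(a); w[b] <- -1 / length(b); w
  }
  FH <- paste("F.healthy", c("45-54", "55-64", "65-74"), sep = ".")
  MH <- paste("M.healthy", c("45-54", "55-64", "65-74"), sep = ".")
  FU <- paste("F.unhealthy", c("45-54", "55-64", "65-74"), sep = ".")
  MU <- paste("M.unhealthy", c("45-54", "55-64", "65-74"), sep = ".")
  list(
    "FH45-54 vs FH55-64" = pair(FH[1], FH[2]),
    "FH45-54 vs FH65-74" = pair(FH[1], FH[3]),
    "FH55-64 vs FH65-74" = pair(FH[2], FH[3]),
    "FH45-54 vs MH45-54" = pair(FH[1], MH[1]),
    "FH55-64 vs MH55-64" = pair(FH[2], MH[2]),
    "FH65-74 vs MH65-74" = pair(FH[3], MH[3]),
    "MH45-54 vs MH55-64" = pair(MH[1], MH[2]),
    "MH45-54 vs MH65-74" = pair(MH[1], MH[3]),
    "MH55-64 vs MH65-74" = pair(MH[2], MH[3]),
    "MH65-74 vs MU65-74" = pair(MH[3], MU[3]),
    "FH65-74 vs FU65-74" = pair(FH[3], FU[3]),
    "MH55-64 vs MU55-64" = pair(MH[2], MU[2]),
    "MU55-64 vs MU65-74" = pair(MU[2], MU[3]),
    "All MH vs All FH" = lump(MH, FH),
    "All FH vs All FU" = lump(FH, FU),
    "All MH vs All MU" = lump(MH, MU),
    "All FU vs All MU" = lump(FU, MU)
  )
}

#' Planned contrast within a one-way ANOVA
#'
#' Tests the weighted comparison sum(w_i * mean_i) using the omnibus pooled
#' mean-square error: SE = sqrt(MSE * sum(w_i^2 / n_i)), t with the
#' within-group degrees of freedom, two-sided p. When `boot_reps > 0` a
#' percentile bootstrap CI of the contrast estimate is computed by case
#' resampling within each involved cell.
#'
#' @param fit an `oneway_fit` over the cells the weights refer to.
#' @param weights named zero-sum weight vector (names = cell labels).
#' @param threshold significance threshold (e.g. the Bonferroni-corrected
#'   level).
#' @param boot_reps,seed bootstrap settings.
#' @return one-row data frame: `estimate`, `se`, `statistic`, `df`, `p`,
#'   `ci_lo`, `ci_hi`, `significant`.
#' @export
planned_contrast <- function(fit, weights, threshold = 0.05,
                             boot_reps = 1000L, seed = 1L) {
  stopifnot(inherits(fit, "oneway_fit"))
  if (abs(sum(weights)) > 1e-8)
    stop("contrast weights must sum to zero", call. = FALSE)
  active <- names(weights)[weights != 0]
  missing_cells <- setdiff(active, names(fit$means))
  if (length(missing_cells))
    stop("contrast touches empty cells: ",
         paste(missing_cells, collapse = ", "), call. = FALSE)
  w <- weights[active]
  est <- sum(w * fit$means[active])
  se <- sqrt(fit$mse * sum(w^2 / fit$ns[active]))
  tt <- est / se
  p <- 2 * stats::pt(abs(tt), fit$df2, lower.tail = FALSE)
  ci <- c(NA_real_, NA_real_)
  if (boot_reps > 0) {
    set.seed(as.integer(seed))
    bm <- vapply(active, function(g) boot_means(fit$data[[g]], boot_reps),
                 numeric(boot_reps))
    ci <- unname(stats::quantile(bm %*% w, c(0.025, 0.975)))
  }
  data.frame(estimate = est, se = se, statistic = tt, df = fit$df2, p = p,
             ci_lo = ci[1], ci_hi = ci[2], significant = p <= threshold)
}

#' Bonferroni-corrected decision threshold
#'
#' Familywise level divided by the number of planned comparisons, rounded
#' to the stated number of decimals (the study's operational rule: 0.05/17
#' rounded to 3 decimals gives 0.003).
#'
#' @param m number of comparisons (>= 1).
#' @param alpha familywise level.
#' @param decimals rounding (NULL for the unrounded quotient).
#' @return the decision threshold.
#' @export
bonferroni_alpha <- function(m, alpha = 0.05, decimals = 3) {
  if (m < 1) stop("number of comparisons must be at least 1", call. = FALSE)
  thr <- alpha / m
  if (!is.null(decimals)) thr <- round(thr, decimals)
  thr
}

#' Percentile bootstrap confidence interval
#'
#' Seeded case-resampling percentile interval of an arbitrary statistic.
#' Constant data yield the degenerate zero-width interval.
#'
#' @param data numeric vector (n >= 2).
#' @param statistic function of a numeric vector returning a scalar.
#' @param reps resamples (>= 100).
#' @param seed integer seed.
#' @param conf confidence level.
#' @return numeric `c(lo, hi)`.
#' @export
bootstrap_ci <- function(data, statistic = mean, reps = 1000L, seed = 1L,
                         conf = 0.95) {
  data <- data[!is.na(data)]
  if (length(data) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (reps < 100L) stop("use at least 100 bootstrap resamples", call. = FALSE)
  set.seed(as.integer(seed))
  n <- length(data)
  stat <- vapply(seq_len(reps),
                 function(i) statistic(sample(data, n, replace = TRUE)),
                 numeric(1))
  a <- (1 - conf) / 2
  unname(stats::quantile(stat, c(a, 1 - a)))
}

#' Pearson correlation with bootstrap CI
#'
#' Sample Pearson r with the two-sided t-transform p-value, plus a seeded
#' percentile bootstrap CI (pair resampling). A `ci_disagrees` flag marks
#' the case where the parametric decision at `alpha` and the bootstrap CI
#' (containing zero or not) point in opposite directions.
#'
#' @param x,y numeric vectors (n >= 3, both with positive variance).
#' @param alpha significance level.
#' @param boot_reps,seed bootstrap settings (0 reps disables).
#' @return one-row data frame: `r`, `n`, `statistic`, `df`, `p`, `ci_lo`,
#'   `ci_hi`, `significant`, `ci_disagrees`.
#' @export
pearson_cor <- function(x, y, alpha = 0.05, boot_reps = 1000L, seed = 1L) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for zero-variance input", call. = FALSE)
  ht <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ht$estimate)
  ci <- c(NA_real_, NA_real_)
  if (boot_reps > 0) {
    set.seed(as.integer(seed))
    n <- length(x)
    rb <- vapply(seq_len(boot_reps), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      if (stats::sd(x[idx]) == 0 || stats::sd(y[idx]) == 0) return(NA_real_)
      stats::cor(x[idx], y[idx])
    }, numeric(1))
    ci <- unname(stats::quantile(rb, c(0.025, 0.975), na.rm = TRUE))
  }
  sig <- ht$p.value <= alpha
  disag <- if (anyNA(ci)) NA else sig != (ci[1] > 0 || ci[2] < 0)
  data.frame(r = r, n = length(x), statistic = unname(ht$statistic),
             df = unname(ht$parameter), p = ht$p.value,
             ci_lo = ci[1], ci_hi = ci[2], significant = sig,
             ci_disagrees = disag)
}

#' Run the full inferential battery on a measured cohort table
#'
#' Reproduces the study's workflow on any post-outlier subject table:
#' \enumerate{
#'   \item initial pooled-variance t-tests of all healthy vs all unhealthy
#'     and all male vs all female, for every variable (alpha 0.05);
#'   \item per-variable one-way ANOVA over the 12 cells, gating the
#'     contrasts at p <= 0.05;
#'   \item the 17 planned contrasts per gated variable, judged against the
#'     rounded Bonferroni threshold (0.003 for 17 contrasts at 0.05);
#'   \item Pearson correlations of each variable with age and BSA within
#'     the four lumped groups (healthy/unhealthy x F/M).
#' }
#' Individual test failures are recorded per row and never abort the batch.
#'
#' @param table measured subject data frame (needs `cell`, `sex`, `health`,
#'   `age` and the variable columns).
#' @param variables analysis variables (default the study's nine).
#' @param corr_variables variables correlated with age and BSA.
#' @param alpha familywise/initial level.
#' @param boot_reps,seed bootstrap settings.
#' @return list of class `strain_battery`: data frames `t_tests`, `anova`,
#'   `contrasts`, `correlations`, `significant` (the Table-3-style listing
#'   of contrasts significant at the corrected threshold) and the
#'   `threshold` used.
#' @export
run_battery <- function(table,
                        variables = c("ESV", "EDV", "LVEF", "ESVi", "BSA",
                                      "ACS", "MCS", "BCS", "GCS"),
                        corr_variables = c("EDV", "ESV", "ESVi", "LVEF",
                                           "ACS", "MCS", "BCS", "GCS"),
                        alpha = 0.05, boot_reps = 1000L, seed = 1L) {
  specs <- contrast_specs()
  threshold <- bonferroni_alpha(length(specs), alpha, 3)
  set.seed(as.integer(seed))
  seed_pool <- sample.int(.Machine$integer.max - 2L, 100000L)
  s_i <- 0L
  next_seed <- function() { s_i <<- s_i + 1L; seed_pool[s_i] }

  t_rows <- list(); a_rows <- list(); c_rows <- list(); r_rows <- list()
  for (v in variables) {
    for (cmp in c("healthy vs unhealthy", "male vs female")) {
      res <- tryCatch({
        if (cmp == "healthy vs unhealthy") {
          a <- table[[v]][table$health == "healthy"]
          b <- table[[v]][table$health == "unhealthy"]
        } else {
          a <- table[[v]][table$sex == "M"]
          b <- table[[v]][table$sex == "F"]
        }
        cbind(variable = v, comparison = cmp,
              students_t(a, b, alpha, boot_reps, next_seed()),
              error = NA_character_)
      }, error = function(e)
        data.frame(variable = v, comparison = cmp, statistic = NA_real_,
                   df = NA_real_, p = NA_real_, estimate = NA_real_,
                   ci_lo = NA_real_, ci_hi = NA_real_, significant = NA,
                   degenerate = NA, error = conditionMessage(e)))
      t_rows[[length(t_rows) + 1L]] <- res
    }

    fit <- tryCatch(oneway_anova(table[[v]], table$cell),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      a_rows[[length(a_rows) + 1L]] <-
        data.frame(variable = v, F = NA_real_, df1 = NA_integer_,
                   df2 = NA_integer_, p = NA_real_, gated_in = FALSE,
                   error = conditionMessage(fit))
      next
    }
    gated <- fit$p <= alpha
    a_rows[[length(a_rows) + 1L]] <-
      data.frame(variable = v, F = fit$F, df1 = fit$df1, df2 = fit$df2,
                 p = fit$p, gated_in = gated, error = NA_character_)
    if (gated) {
      for (nm in names(specs)) {
        res <- tryCatch(
          cbind(variable = v, contrast = nm,
                planned_contrast(fit, specs[[nm]], threshold, boot_reps,
                                 next_seed()),
                error = NA_character_),
          error = function(e)
            data.frame(variable = v, contrast = nm, estimate = NA_real_,
                       se = NA_real_, statistic = NA_real_, df = NA_real_,
                       p = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                       significant = NA, error = conditionMessage(e)))
        c_rows[[length(c_rows) + 1L]] <- res
      }
    }
  }

  lumped <- list("healthy F" = table$health == "healthy" & table$sex == "F",
                 "healthy M" = table$health == "healthy" & table$sex == "M",
                 "unhealthy F" = table$health == "unhealthy" & table$sex == "F",
                 "unhealthy M" = table$health == "unhealthy" & table$sex == "M")
  for (gname in names(lumped)) {
    sub <- table[lumped[[gname]], , drop = FALSE]
    for (v in corr_variables) {
      for (against in c("age", "BSA")) {
        res <- tryCatch(
          cbind(group = gname, variable = v, against = against,
                pearson_cor(sub[[v]], sub[[against]], alpha, boot_reps,
                            next_seed()),
                error = NA_character_),
          error = function(e)
            data.frame(group = gname, variable = v, against = against,
                       r = NA_real_, n = NA_integer_, statistic = NA_real_,
                       df = NA_real_, p = NA_real_, ci_lo = NA_real_,
                       ci_hi = NA_real_, significant = NA,
                       ci_disagrees = NA, error = conditionMessage(e)))
        r_rows[[length(r_rows) + 1L]] <- res
      }
    }
  }

  contrasts_df <- if (length(c_rows)) do.call(rbind, c_rows) else
    data.frame(variable = character(0), contrast = character(0),
               estimate = numeric(0), se = numeric(0), statistic = numeric(0),
               df = numeric(0), p = numeric(0), ci_lo = numeric(0),
               ci_hi = numeric(0), significant = logical(0),
               error = character(0))
  sig <- contrasts_df[!is.na(contrasts_df$significant) &
                        contrasts_df$significant,
                      c("contrast", "variable", "p"), drop = FALSE]
  sig <- sig[order(sig$contrast, sig$variable), , drop = FALSE]
  structure(list(t_tests = do.call(rbind, t_rows),
                 anova = do.call(rbind, a_rows),
                 contrasts = contrasts_df,
                 correlations = do.call(rbind, r_rows),
                 significant = sig, threshold = threshold,
                 alpha = alpha, seed = as.integer(seed),
                 boot_reps = as.integer(boot_reps)),
            class = "strain_battery")
}

#' @export
print.strain_battery <- function(x, ...) {
  cat(sprintf("<strain_battery> %d t-tests, %d ANOVAs (%d gated in), %d contrast rows\n",
              nrow(x$t_tests), nrow(x$anova), sum(x$anova$gated_in),
              nrow(x$contrasts)))
  cat(sprintf("Bonferroni threshold %.3f; %d contrasts significant:\n",
              x$threshold, nrow(x$significant)))
  if (nrow(x$significant))
    print.data.frame(x$significant, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
summary.strain_battery <- function(object, ...) {
  cat("Initial t-tests (alpha", object$alpha, "):\n")
  print.data.frame(object$t_tests[, c("variable", "comparison", "statistic",
                                      "p", "significant")],
                   row.names = FALSE, digits = 3)
  cat("\nOne-way ANOVA gate:\n")
  print.data.frame(object$anova[, c("variable", "F", "p", "gated_in")],
                   row.names = FALSE, digits = 3)
  cat("\nSignificant planned contrasts (p <=", object$threshold, "):\n")
  print.data.frame(object$significant, row.names = FALSE, digits = 3)
  invisible(object)
}
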