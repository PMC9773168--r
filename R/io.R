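#' Write a contour stack to a JSON-lines file
#'
#' Line 1 is a header object (subject id, acquisition parameters, ground
#' truth when present); every following line is one (slice, frame) contour
#' with full-precision mm coordinates. The format round-trips losslessly.
#'
#' @param stack a `contour_stack`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_contour_stack <- function(stack, path) {
  stopifnot(inherits(stack, "contour_stack"))
  header <- list(type = "contour_stack_header",
                 subject_id = stack$subject_id,
                 acquisition = unclass(stack$acquisition),
                 ground_truth = stack$ground_truth)
  lines <- c(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA))
  for (s in seq_along(stack$contours)) {
    for (f in seq_along(stack$contours[[s]])) {
      pts <- stack$contours[[s]][[f]]
      rec <- list(slice = s, frame = f,
                  x = as.numeric(pts[, 1]), y = as.numeric(pts[, 2]))
      lines <- c(lines, jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a contour stack from a JSON-lines file
#'
#' @param path file written by [write_contour_stack()].
#' @return a `contour_stack`.
#' @export
read_contour_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L)
    stop("parse error in ", path, ": truncated file", call. = FALSE)
  header <- tryCatch(jsonlite::fromJSON(lines[1]), error = function(e)
    stop("parse error in ", path, " line 1: ", conditionMessage(e),
         call. = FALSE))
  if (!identical(header$type, "contour_stack_header"))
    stop("parse error in ", path, " line 1: missing header", call. = FALSE)
  acq <- do.call(acquisition_params, header$acquisition)
  contours <- rep(list(vector("list", acq$n_frames)), acq$n_slices)
  for (i in seq_along(lines)[-1]) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e)
      stop("parse error in ", path, " line ", i, ": ",
           conditionMessage(e), call. = FALSE))
    for (fld in c("slice", "frame", "x", "y"))
      if (is.null(rec[[fld]]))
        stop("parse error in ", path, " line ", i, ": missing field '",
             fld, "'", call. = FALSE)
    if (rec$slice < 1 || rec$slice > acq$n_slices ||
        rec$frame < 1 || rec$frame > acq$n_frames)
      stop("parse error in ", path, " line ", i,
           ": slice/frame out of range", call. = FALSE)
    contours[[rec$slice]][[rec$frame]] <- contour_points(cbind(rec$x, rec$y))
  }
  if (any(vapply(contours, function(sl) any(vapply(sl, is.null, logical(1))),
                 logical(1))))
    stop("parse error in ", path, ": incomplete stack", call. = FALSE)
  gt <- header$ground_truth
  structure(list(subject_id = header$subject_id, acquisition = acq,
                 contours = contours,
                 ground_truth = if (length(gt)) gt else NULL),
            class = "contour_stack")
}

#' Write/read a subject table as CSV
#'
#' @param table subject data frame.
#' @param path CSV path.
#' @return `path` invisibly / the data frame.
#' @export
write_subject_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_subject_table
#' @export
read_subject_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Contour-audit bookkeeping
#'
#' Segmentation-audit style rate: the percentage of contours needing manual
#' correction among all contours processed, rounded to two decimals (e.g.
#' 636 corrected of 29,826 processed is 2.13).
#'
#' @param corrected number of corrected contours.
#' @param total number of contours processed (> 0).
#' @param decimals rounding of the percentage.
#' @return percentage.
#' @export
audit_rate <- function(corrected, total, decimals = 2) {
  if (total <= 0) stop("total must be positive", call. = FALSE)
  if (corrected < 0 || corrected > total)
    stop("corrected must lie in [0, total]", call. = FALSE)
  round(100 * corrected / total, decimals)
}

#' Append a structured audit record to a JSON-lines log
#'
#' @param path log file path.
#' @param stage stage name.
#' @param ... named fields (counts, seeds, versions).
#' @return invisibly, the record.
#' @export
audit_log <- function(path, stage, ...) {
  rec <- c(list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                stage = stage), list(...))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
      file = path, append = TRUE, sep = "")
  invisible(rec)
}

#' Load a run configuration from YAML or JSON
#'
#' Recognised top-level keys: `master_seed`, `group_sizes` (named map),
#' `default_n`, `n_slices_range`, `n_frames`, `n_points`, `jitter_sd`,
#' `systole_fraction`, `axis_ratio`, `bsa_method`, `n_healthy`,
#' `outlier_k`, `bootstrap_reps`, `out_dir`. Unset keys fall back to the
#' package defaults, so a run is reproducible from config + seed alone.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
}

resolve_config <- function(cfg) {
  gs <- cfg$group_sizes
  if (!is.null(gs)) gs <- unlist(gs)
  cc <- cohort_config(
    group_sizes = gs,
    default_n = cfg$default_n %||% 10L,
    n_slices_range = cfg$n_slices_range %||% c(6L, 10L),
    n_frames = cfg$n_frames %||% 25L,
    n_points = cfg$n_points %||% 50L,
    jitter_sd = cfg$jitter_sd %||% 0.2,
    systole_fraction = cfg$systole_fraction %||% 0.4,
    axis_ratio = cfg$axis_ratio %||% 1,
    bsa_method = cfg$bsa_method %||% "du_bois")
  list(cohort = cc,
       master_seed = as.integer(cfg$master_seed %||% 1L),
       n_healthy = as.integer(cfg$n_healthy %||% 100L),
       outlier_k = cfg$outlier_k %||% 2.7,
       bootstrap_reps = as.integer(cfg$bootstrap_reps %||% 1000L),
       out_dir = cfg$out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the complete pipeline: generate, measure, select, test
#'
#' Chains the phantom generator, the strain/volume measurement, cohort
#' selection with outlier removal, group summaries and the statistical
#' battery. All randomness derives from the master seed.
#'
#' @param config a list as returned by [read_run_config()] (or an empty
#'   list for all defaults).
#' @param master_seed overrides the config's master seed when non-NULL.
#' @param out_dir output directory (created if needed); when neither this
#'   argument nor the config's `out_dir` is set, nothing is written.
#' @return list of class `lv_pipeline`: `cohort`, `measured`, `selected`,
#'   `outliers`, `summary`, `battery`.
#' @export
run_pipeline <- function(config = list(), master_seed = NULL,
                         out_dir = NULL) {
  rc <- resolve_config(config)
  if (!is.null(master_seed)) rc$master_seed <- as.integer(master_seed)
  if (!is.null(out_dir)) rc$out_dir <- out_dir
  variables <- c("ESV", "EDV", "LVEF", "ESVi", "BSA",
                 "ACS", "MCS", "BCS", "GCS")
  set.seed(rc$master_seed)
  stage_seeds <- sample.int(.Machine$integer.max - 2L, 3L)

  cohort <- generate_cohort(rc$cohort, stage_seeds[1])
  measured <- measure_cohort(cohort)
  measured$bmi <- measured$BMI
  flt <- apply_inclusion_filters(measured)
  strat <- stratify(flt$kept)
  selected <- select_study_cohort(strat, rc$n_healthy, stage_seeds[2])
  out <- remove_outliers(selected, variables, k = rc$outlier_k)
  summ <- summarize_groups(out$kept, variables)
  battery <- run_battery(out$kept, variables,
                         boot_reps = rc$bootstrap_reps,
                         seed = stage_seeds[3])

  res <- structure(list(cohort = cohort, measured = measured,
                        selected = selected, outliers = out,
                        summary = summ, battery = battery,
                        config = rc),
                   class = "lv_pipeline")
  if (!is.null(rc$out_dir) && nzchar(rc$out_dir)) {
    dir.create(rc$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_subject_table(out$kept, file.path(rc$out_dir, "subjects.csv"))
    utils::write.csv(as.data.frame(summ),
                     file.path(rc$out_dir, "group_summary.csv"),
                     row.names = FALSE)
    write_battery(battery, rc$out_dir)
    logp <- file.path(rc$out_dir, "audit.jsonl")
    n_contours <- sum(vapply(cohort$stacks, function(s)
      s$acquisition$n_slices * s$acquisition$n_frames, numeric(1)))
    audit_log(logp, "pipeline", master_seed = rc$master_seed,
              subjects_generated = nrow(measured),
              subjects_selected = nrow(selected),
              outliers_removed = nrow(out$removed),
              contours_processed = n_contours, contours_corrected = 0,
              correction_rate_pct = audit_rate(0, n_contours))
  }
  res
}

#' @export
print.lv_pipeline <- function(x, ...) {
  cat(sprintf("<lv_pipeline> %d generated, %d selected, %d outliers removed\n",
              nrow(x$measured), nrow(x$selected), nrow(x$outliers$removed)))
  print(x$battery)
  invisible(x)
}

#' Write a battery result bundle to disk
#'
#' One CSV per test family plus a JSON bundle and a Table-3-style listing
#' of contrasts significant at the corrected threshold.
#'
#' @param battery a `strain_battery`.
#' @param out_dir output directory.
#' @return `out_dir` invisibly.
#' @export
write_battery <- function(battery, out_dir) {
  stopifnot(inherits(battery, "strain_battery"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(battery$t_tests, file.path(out_dir, "t_tests.csv"),
                   row.names = FALSE)
  utils::write.csv(battery$anova, file.path(out_dir, "anova.csv"),
                   row.names = FALSE)
  utils::write.csv(battery$contrasts, file.path(out_dir, "contrasts.csv"),
                   row.names = FALSE)
  utils::write.csv(battery$correlations,
                   file.path(out_dir, "correlations.csv"), row.names = FALSE)
  utils::write.csv(battery$significant,
                   file.path(out_dir, "significant_contrasts.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(threshold = battery$threshold, alpha = battery$alpha,
         seed = battery$seed, boot_reps = battery$boot_reps,
         significant = battery$significant),
    file.path(out_dir, "battery.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(out_dir)
}

#' Command-line entry point
#'
#' Thin dispatcher over the pipeline stages. Subcommands: `cohortgen`
#' (generate + measure + write subject table and contour stacks), `stats`
#' (battery on an existing subject table), `report` (group summaries), and
#' `all` (full pipeline). Flags: `--seed`, `--config`, `--out`, `--in`,
#' `--bootstrap-reps`, `--outlier-k`, `--n-healthy`, `--write-contours`.
#'
#' @param args character vector of arguments (as from
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return integer exit status (0 = success, 2 = usage error).
#' @export
lvs_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: lvstrain <cohortgen|stats|report|all> [--seed N] [--config FILE]",
    "                [--out DIR] [--in FILE] [--bootstrap-reps N]",
    "                [--outlier-k K] [--n-healthy N] [--write-contours]",
    sep = "\n")
  if (length(args) < 1L) { message(usage); return(2L) }
  cmd <- args[1]
  if (!cmd %in% c("cohortgen", "stats", "report", "all")) {
    message("unknown subcommand: ", cmd, "\n", usage)
    return(2L)
  }
  opts <- list(seed = 1L, config = NULL, out = "lvstrain_out", input = NULL,
               bootstrap_reps = NULL, outlier_k = NULL, n_healthy = NULL,
               write_contours = FALSE)
  i <- 2L
  while (i <= length(args)) {
    a <- args[i]
    take <- function() { i <<- i + 1L
      if (i > length(args)) stop("missing value for ", a, call. = FALSE)
      args[i] }
    res <- tryCatch({
      switch(a,
             "--seed" = opts$seed <- as.integer(take()),
             "--config" = opts$config <- take(),
             "--out" = opts$out <- take(),
             "--in" = opts$input <- take(),
             "--bootstrap-reps" = opts$bootstrap_reps <- as.integer(take()),
             "--outlier-k" = opts$outlier_k <- as.numeric(take()),
             "--n-healthy" = opts$n_healthy <- as.integer(take()),
             "--write-contours" = opts$write_contours <- TRUE,
             stop("unknown flag: ", a, call. = FALSE))
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) { message(res, "\n", usage); return(2L) }
    i <- i + 1L
  }
  cfg <- if (!is.null(opts$config)) {
    tryCatch(read_run_config(opts$config), error = function(e) e)
  } else list()
  if (inherits(cfg, "error")) { message(conditionMessage(cfg)); return(1L) }
  if (!is.null(opts$bootstrap_reps)) cfg$bootstrap_reps <- opts$bootstrap_reps
  if (!is.null(opts$outlier_k)) cfg$outlier_k <- opts$outlier_k
  if (!is.null(opts$n_healthy)) cfg$n_healthy <- opts$n_healthy

  status <- tryCatch({
    dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
    if (cmd %in% c("cohortgen", "all")) {
      pipe <- run_pipeline(cfg, master_seed = opts$seed, out_dir = opts$out)
      write_subject_table(pipe$measured,
                          file.path(opts$out, "measured_cohort.csv"))
      if (opts$write_contours) {
        cdir <- file.path(opts$out, "contours")
        dir.create(cdir, showWarnings = FALSE)
        for (st in pipe$cohort$stacks)
          write_contour_stack(st, file.path(cdir,
                                            paste0(st$subject_id, ".jsonl")))
      }
      message(sprintf("wrote %s (%d subjects kept)", opts$out,
                      nrow(pipe$outliers$kept)))
    } else {
      if (is.null(opts$input))
        stop("subcommand '", cmd, "' needs --in SUBJECT_TABLE.csv",
             call. = FALSE)
      tab <- read_subject_table(opts$input)
      variables <- intersect(c("ESV", "EDV", "LVEF", "ESVi", "BSA",
                               "ACS", "MCS", "BCS", "GCS"), names(tab))
      if (cmd == "stats") {
        bat <- run_battery(tab, variables,
                           boot_reps = cfg$bootstrap_reps %||% 1000L,
                           seed = opts$seed)
        write_battery(bat, opts$out)
        message(sprintf("wrote battery results to %s (%d significant contrasts)",
                        opts$out, nrow(bat$significant)))
      } else {
        summ <- summarize_groups(tab, variables)
        utils::write.csv(as.data.frame(summ),
                         file.path(opts$out, "group_summary.csv"),
                         row.names = FALSE)
        message("wrote ", file.path(opts$out, "group_summary.csv"))
      }
    }
    0L
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
  status
}
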