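#' Acquisition geometry for a synthetic short-axis cine stack
#'
#' Defaults mirror a routine 1.5 T short-axis cine protocol: 8 mm slice
#' thickness, 2 mm gap (10 mm effective spacing) and 31.56 ms temporal
#' resolution. Admissible stacks have 6 to 10 slices. 25 frames cover about
#' one cycle at roughly 60 bpm.
#'
#' @param n_slices number of short-axis slices, integer in \[6, 10\].
#' @param n_frames frames per cardiac cycle (>= 3); frame 1 is end diastole.
#' @param slice_thickness,slice_gap,temporal_resolution protocol constants
#'   (mm, mm, ms).
#' @return list of class `acquisition_params`.
#' @export
acquisition_params <- function(n_slices = 8L, n_frames = 25L,
                               slice_thickness = 8, slice_gap = 2,
                               temporal_resolution = 31.56) {
  n_slices <- as.integer(n_slices)
  if (n_slices < 6L || n_slices > 10L)
    stop("n_slices must be between 6 and 10", call. = FALSE)
  if (n_frames < 3L) stop("n_frames must be at least 3", call. = FALSE)
  structure(list(n_slices = n_slices, n_frames = as.integer(n_frames),
                 slice_thickness = slice_thickness, slice_gap = slice_gap,
                 temporal_resolution = temporal_resolution),
            class = "acquisition_params")
}

#' The 12 stratification cells
#'
#' Sex (F/M) x age band (45-54, 55-64, 65-74) x health (healthy/unhealthy).
#'
#' @return data frame with columns `sex`, `age_band`, `health` and `cell`
#'   (the canonical label, e.g. `"F.healthy.45-54"`), 12 rows.
#' @export
all_groups <- function() {
  g <- expand.grid(sex = c("F", "M"),
                   age_band = c("45-54", "55-64", "65-74"),
                   health = c("healthy", "unhealthy"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$cell <- cell_label(g$sex, g$age_band, g$health)
  g
}

cell_label <- function(sex, age_band, health) {
  paste(sex, health, age_band, sep = ".")
}

age_band_of <- function(age) {
  a <- floor(age)
  ifelse(a >= 45 & a <= 54, "45-54",
         ifelse(a >= 55 & a <= 64, "55-64",
                ifelse(a >= 65 & a <= 74, "65-74", NA_character_)))
}

#' Default group-level distribution parameters
#'
#' Normal mean/SD per variable for each health status x age band cell of the
#' reference population table: age (years), heart rate (bpm), BMI (kg/m^2),
#' weight (kg), EDV (ml) and the three regional peak circumferential strains
#' (%, negative). Strain SDs are between-subject; the phantom contracts each
#' region at exactly the subject's drawn fraction.
#'
#' @return nested list: `dists[[health]][[age_band]]` is a named list of
#'   `c(mean, sd)` pairs for `age`, `hr`, `bmi`, `weight`, `edv`, `acs`,
#'   `mcs`, `bcs`.
#' @export
default_distributions <- function() {
  v <- function(age, hr, bmi, weight, edv, acs, mcs, bcs)
    list(age = age, hr = hr, bmi = bmi, weight = weight, edv = edv,
         acs = acs, mcs = mcs, bcs = bcs)
  list(
    healthy = list(
      "45-54" = v(c(52, 2), c(59.9, 8.0), c(25.4, 2.6), c(74.9, 12.1),
                  c(151.6, 31.1), c(-41.7, 7.4), c(-28.5, 3.6), c(-31.6, 5.0)),
      "55-64" = v(c(60, 3), c(61.1, 9.4), c(24.8, 2.7), c(72.4, 11.9),
                  c(141.2, 30.9), c(-41.9, 8.0), c(-29.6, 4.3), c(-31.5, 3.9)),
      "65-74" = v(c(69, 3), c(62.7, 9.6), c(25.1, 2.6), c(72.1, 10.7),
                  c(136.3, 30.9), c(-41.6, 8.1), c(-30.0, 4.4), c(-31.8, 4.8))
    ),
    unhealthy = list(
      "45-54" = v(c(53, 1), c(53.6, 11.2), c(27.3, 2.1), c(76.7, 6.2),
                  c(170.6, 22.8), c(-36.7, 10.3), c(-29.0, 5.2), c(-30.5, 3.9)),
      "55-64" = v(c(61, 3), c(57.0, 10.4), c(25.0, 2.5), c(75.9, 8.9),
                  c(169.8, 25.6), c(-40.2, 14.6), c(-28.3, 8.4), c(-29.2, 5.8)),
      "65-74" = v(c(69, 3), c(57.0, 9.2), c(25.6, 2.3), c(75.9, 10.5),
                  c(158.8, 41.6), c(-37.8, 13.8), c(-26.8, 6.8), c(-29.3, 8.0))
    )
  )
}

# Truncated-normal draw by rejection; bounds guard physiological ranges.
rtnorm1 <- function(mean, sd, lower = -Inf, upper = Inf) {
  for (i in 1:10000) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lower && x <= upper) return(x)
  }
  min(max(mean, lower), upper)
}

band_limits <- function(age_band) {
  switch(age_band,
         "45-54" = c(45, 54.999), "55-64" = c(55, 64.999),
         "65-74" = c(65, 74.999),
         stop("unknown age band: ", age_band, call. = FALSE))
}

#' Draw one synthetic subject
#'
#' Attributes are drawn from the group's configured normal distributions,
#' truncated to the study's inclusion ranges (BMI 18.5-30 kg/m^2, age within
#' its band). Height is derived from the weight and BMI draws. The
#' ground-truth per-region peak perimeter contraction fractions are set so
#' that the perimeter-based peak regional strains equal the (negated) strain
#' draws exactly: c_region = -strain/100.
#'
#' Disease modifiers: `dilatation` multiplies all end-diastolic radii;
#' `deficit` multiplies the contraction fraction of `deficit_region` by
#' (1 - deficit). Both default to no effect, since unhealthy cells carry
#' their own distribution parameters.
#'
#' @param group one row of [all_groups()] (or a list with `sex`, `age_band`,
#'   `health`).
#' @param dists distribution set, see [default_distributions()].
#' @param seed integer RNG seed (draws are reproducible given the seed).
#' @param dilatation end-diastolic radial scale factor (> 0).
#' @param deficit regional contraction deficit fraction in \[0, 1).
#' @param deficit_region `"base"`, `"mid"` or `"apex"`.
#' @param id subject identifier.
#' @return one-row data frame (a subject record).
#' @export
sample_subject <- function(group, dists = default_distributions(), seed = 1L,
                           dilatation = 1, deficit = 0,
                           deficit_region = "mid", id = "S0001") {
  d <- dists[[group$health]][[group$age_band]]
  if (is.null(d))
    stop("configuration error: no distributions for group ",
         cell_label(group$sex, group$age_band, group$health), call. = FALSE)
  if (deficit < 0 || deficit >= 1)
    stop("deficit must lie in [0, 1)", call. = FALSE)
  set.seed(as.integer(seed))
  lim <- band_limits(group$age_band)
  age <- rtnorm1(d$age[1], d$age[2], lim[1], lim[2])
  bmi_v <- rtnorm1(d$bmi[1], d$bmi[2], 18.5, 30)
  weight <- rtnorm1(d$weight[1], d$weight[2], 40, 140)
  height <- 100 * sqrt(weight / bmi_v)
  hr <- rtnorm1(d$hr[1], d$hr[2], 35, 120)
  edv <- rtnorm1(d$edv[1], d$edv[2], 50, 400)
  # contraction fractions: -strain%/100, kept strictly inside (0, 1)
  cfrac <- function(p) -rtnorm1(p[1], p[2], -95, -2) / 100
  c_base <- cfrac(d$bcs); c_mid <- cfrac(d$mcs); c_apex <- cfrac(d$acs)
  reg <- match.arg(deficit_region, c("base", "mid", "apex"))
  if (deficit > 0) {
    if (reg == "base") c_base <- c_base * (1 - deficit)
    if (reg == "mid") c_mid <- c_mid * (1 - deficit)
    if (reg == "apex") c_apex <- c_apex * (1 - deficit)
  }
  data.frame(id = id, sex = group$sex, age_band = group$age_band,
             health = group$health,
             cell = cell_label(group$sex, group$age_band, group$health),
             age = age, height = height, weight = weight,
             bmi_true = bmi_v, hr = hr,
             diabetes = FALSE, smoker = FALSE, ethnicity = "white_british",
             stemi = FALSE, nstemi = group$health == "unhealthy", hf = FALSE,
             edv_true = edv, dilatation = dilatation,
             c_base = c_base, c_mid = c_mid, c_apex = c_apex,
             stringsAsFactors = FALSE)
}

# Raised-cosine activation: 0 at frame 1, 1 at the end-systolic frame,
# back to 0 at the last frame.
activation_curve <- function(n_frames, systole_fraction = 0.4) {
  t_es <- round(systole_fraction * (n_frames - 1))
  t_es <- max(1L, min(n_frames - 2L, as.integer(t_es)))
  t <- seq_len(n_frames) - 1L
  w <- numeric(n_frames)
  up <- t <= t_es
  w[up] <- 0.5 * (1 - cos(pi * t[up] / t_es))
  w[!up] <- 0.5 * (1 + cos(pi * (t[!up] - t_es) / (n_frames - 1 - t_es)))
  w
}

#' Synthesize a beating-LV contour stack for one subject
#'
#' The cavity is a truncated prolate half-ellipsoid sampled at slice
#' mid-planes from base to apex. End-diastolic slice radii are sized so that
#' the slice-summation volume of the polygonal contours equals the subject's
#' drawn EDV. Each slice contracts as
#' R_s(t) = R_s(ED) * (1 - c_s * w(t)) with w a raised-cosine activation
#' peaking at end systole (default 40% of the cycle), c_s the contraction
#' fraction of the slice's region. Since perimeters scale linearly with
#' radius, the jitter-free measured peak strain per slice is exactly -c_s.
#' Optional zero-mean Gaussian jitter (SD in mm) perturbs every contour
#' point, emulating segmentation noise. Through-plane motion is not
#' modelled: slices are material rings.
#'
#' @param subject a subject record from [sample_subject()].
#' @param acq an [acquisition_params()] object.
#' @param seed integer RNG seed for the jitter stream.
#' @param n_points contour vertices per slice.
#' @param jitter_sd point jitter SD in mm (0 disables).
#' @param systole_fraction position of end systole within the cycle.
#' @param axis_ratio in-plane minor/major axis ratio (1 = circular
#'   cross-sections).
#' @return object of class `contour_stack`: list with `subject_id`,
#'   `acquisition`, `contours` (list\[slice\]\[frame\] of `lv_contour`,
#'   slices ordered base to apex) and `ground_truth`.
#' @export
synthesize_cine <- function(subject, acq = acquisition_params(), seed = 1L,
                            n_points = 50L, jitter_sd = 0.2,
                            systole_fraction = 0.4, axis_ratio = 1) {
  stopifnot(inherits(acq, "acquisition_params"))
  cb <- subject$c_base; cm <- subject$c_mid; ca <- subject$c_apex
  if (any(c(cb, cm, ca) >= 1))
    stop("degenerate geometry: contraction fraction >= 1", call. = FALSE)
  n_sl <- acq$n_slices
  n_fr <- acq$n_frames
  spacing <- acq$slice_thickness + acq$slice_gap
  # prolate profile: slice mid-planes z_i, apex of the ellipsoid at z = L
  z <- (seq_len(n_sl) - 0.5) * spacing
  L <- n_sl * spacing
  prof <- 1 - (z / L)^2
  # size ED polygon areas so slice-summation volume == drawn EDV
  v_mm3 <- subject$edv_true * 1000
  areas <- v_mm3 * prof / (spacing * sum(prof))
  poly_factor <- 0.5 * n_points * sin(2 * pi / n_points) * axis_ratio
  r_ed <- sqrt(areas / poly_factor) * subject$dilatation
  alloc <- allocate_regions(n_sl)
  c_slice <- numeric(n_sl)
  c_slice[alloc$base] <- cb
  c_slice[alloc$mid] <- cm
  c_slice[alloc$apex] <- ca
  w <- activation_curve(n_fr, systole_fraction)
  th <- 2 * pi * seq(0L, n_points - 1L) / n_points
  ux <- cos(th) * axis_ratio
  uy <- sin(th)
  set.seed(as.integer(seed))
  contours <- lapply(seq_len(n_sl), function(s) {
    lapply(seq_len(n_fr), function(f) {
      r <- r_ed[s] * (1 - c_slice[s] * w[f])
      xy <- cbind(r * ux, r * uy)
      if (jitter_sd > 0)
        xy <- xy + matrix(stats::rnorm(2L * n_points, 0, jitter_sd),
                          ncol = 2L)
      contour_points(xy)
    })
  })
  structure(list(subject_id = subject$id, acquisition = acq,
                 contours = contours,
                 ground_truth = list(edv = subject$edv_true,
                                     c_base = cb, c_mid = cm, c_apex = ca)),
            class = "contour_stack")
}

#' @export
print.contour_stack <- function(x, ...) {
  cat(sprintf("<contour_stack> subject %s: %d slices x %d frames\n",
              as.character(x$subject_id), x$acquisition$n_slices,
              x$acquisition$n_frames))
  invisible(x)
}

#' Cohort generation configuration
#'
#' @param group_sizes named integer vector of subjects per cell (names are
#'   cell labels as in [all_groups()]; cells absent from the vector get
#'   `default_n`).
#' @param default_n subjects per cell when not listed in `group_sizes`.
#' @param dists distribution set ([default_distributions()] by default).
#' @param n_slices_range inclusive range subjects' slice counts are drawn
#'   from (uniform).
#' @param n_frames frames per cycle.
#' @param n_points,jitter_sd,systole_fraction,axis_ratio phantom settings,
#'   see [synthesize_cine()].
#' @param bsa_method `"du_bois"` or `"mosteller"`.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(group_sizes = NULL, default_n = 10L,
                          dists = default_distributions(),
                          n_slices_range = c(6L, 10L), n_frames = 25L,
                          n_points = 50L, jitter_sd = 0.2,
                          systole_fraction = 0.4, axis_ratio = 1,
                          bsa_method = "du_bois") {
  if (default_n <= 0 || (!is.null(group_sizes) && any(group_sizes <= 0)))
    stop("configuration error: group sizes must be positive", call. = FALSE)
  structure(list(group_sizes = group_sizes, default_n = as.integer(default_n),
                 dists = dists, n_slices_range = as.integer(n_slices_range),
                 n_frames = as.integer(n_frames),
                 n_points = as.integer(n_points), jitter_sd = jitter_sd,
                 systole_fraction = systole_fraction, axis_ratio = axis_ratio,
                 bsa_method = bsa_method),
            class = "cohort_config")
}

#' Generate a synthetic cohort of subjects and contour stacks
#'
#' Per-subject seeds are derived deterministically from the master seed, so
#' the same configuration and seed reproduce the cohort exactly.
#'
#' @param config a [cohort_config()].
#' @param master_seed integer master seed.
#' @param cells which stratification cells to generate: a subset of
#'   [all_groups()] or a character vector of cell labels (all 12 by
#'   default).
#' @return list of class `lv_cohort` with `subjects` (data frame, one row
#'   per subject) and `stacks` (list of `contour_stack`, same order).
#' @export
generate_cohort <- function(config = cohort_config(), master_seed = 1L,
                            cells = all_groups()) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.character(cells)) {
    cells <- all_groups()[match(cells, all_groups()$cell), , drop = FALSE]
    if (anyNA(cells$cell))
      stop("configuration error: unknown cell labels", call. = FALSE)
  }
  n_per <- rep(config$default_n, nrow(cells))
  names(n_per) <- cells$cell
  if (!is.null(config$group_sizes)) {
    bad <- setdiff(names(config$group_sizes), cells$cell)
    if (length(bad))
      stop("configuration error: unknown cells ", paste(bad, collapse = ", "),
           call. = FALSE)
    n_per[names(config$group_sizes)] <- config$group_sizes
  }
  total <- sum(n_per)
  set.seed(as.integer(master_seed))
  seeds <- matrix(sample.int(.Machine$integer.max - 2L, 3L * total),
                  nrow = 3L)
  n_slice_draw <- sample(seq(config$n_slices_range[1],
                             config$n_slices_range[2]),
                         total, replace = TRUE)
  subjects <- vector("list", total)
  stacks <- vector("list", total)
  i <- 0L
  for (g in seq_len(nrow(cells))) {
    for (k in seq_len(n_per[cells$cell[g]])) {
      i <- i + 1L
      subj <- sample_subject(cells[g, ], config$dists, seed = seeds[1, i],
                             id = sprintf("S%05d", i))
      acq <- acquisition_params(n_slices = n_slice_draw[i],
                                n_frames = config$n_frames)
      stacks[[i]] <- synthesize_cine(subj, acq, seed = seeds[2, i],
                                     n_points = config$n_points,
                                     jitter_sd = config$jitter_sd,
                                     systole_fraction = config$systole_fraction,
                                     axis_ratio = config$axis_ratio)
      subjects[[i]] <- subj
    }
  }
  structure(list(subjects = do.call(rbind, subjects), stacks = stacks,
                 config = config, master_seed = as.integer(master_seed)),
            class = "lv_cohort")
}

#' @export
print.lv_cohort <- function(x, ...) {
  cat(sprintf("<lv_cohort> %d subjects across %d cells (master seed %d)\n",
              nrow(x$subjects), length(unique(x$subjects$cell)),
              x$master_seed))
  invisible(x)
}

#' Measure strains and volumes for every subject of a cohort
#'
#' Runs the contour-to-strain and contour-to-volume pipelines on each
#' subject's stack and appends the measured indices (EDV, ESV, LVEF, ESVi,
#' BSA, BMI, ACS, MCS, BCS, GCS) to the subject table.
#'
#' @param cohort an `lv_cohort` from [generate_cohort()].
#' @return the subject data frame with measured-index columns added.
#' @export
measure_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "lv_cohort"))
  subj <- cohort$subjects
  meth <- cohort$config$bsa_method
  rows <- lapply(seq_len(nrow(subj)), function(i) {
    st <- strain_analysis(cohort$stacks[[i]])$strains
    vol <- volume_indices(cohort$stacks[[i]], height_cm = subj$height[i],
                          weight_kg = subj$weight[i], bsa_method = meth)
    data.frame(EDV = vol$EDV, ESV = vol$ESV, LVEF = vol$LVEF,
               ESVi = vol$ESVi, BSA = vol$BSA, BMI = vol$BMI,
               ACS = st[["ACS"]], MCS = st[["MCS"]], BCS = st[["BCS"]],
               GCS = st[["GCS"]])
  })
  cbind(subj, do.call(rbind, rows))
}
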