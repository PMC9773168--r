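#' Circumferential strain curve from per-frame perimeters
#'
#' Endocardial circumferential strain at frame n is the fractional change of
#' the slice perimeter relative to its end-diastolic reference length:
#' eps_n = (L_n - L0) / L0, with L0 the perimeter at frame 0 (end diastole).
#' Strain is dimensionless and negative during systole.
#'
#' @param perimeters numeric vector of per-frame perimeter lengths in mm,
#'   frame 1 being end diastole; all strictly positive, length >= 2.
#' @param slice optional slice index carried on the result.
#' @return an object of class `strain_curve`: list with `strain` (numeric
#'   per-frame strain, first element exactly 0), `L0` (reference perimeter,
#'   mm) and `slice`.
#' @export
strain_curve <- function(perimeters, slice = NA_integer_) {
  p <- as.numeric(perimeters)
  if (length(p) < 2L)
    stop("need at least 2 frames to compute strain", call. = FALSE)
  if (any(!is.finite(p)) || any(p <= 0))
    stop("invalid measurement: perimeters must be finite and positive",
         call. = FALSE)
  eps <- (p - p[1]) / p[1]
  eps[1] <- 0
  structure(list(strain = eps, L0 = p[1], slice = slice),
            class = "strain_curve")
}

#' @export
print.strain_curve <- function(x, ...) {
  cat(sprintf("<strain_curve> slice %s, %d frames, L0 = %.2f mm, peak = %.3f\n",
              as.character(x$slice), length(x$strain), x$L0, min(x$strain)))
  invisible(x)
}

#' Allocate short-axis slices to apex, mid-ventricle and base
#'
#' Divides `n_slices` consecutive short-axis slices (ordered base to apex)
#' into three vertical regions. Each region gets floor(n/3) slices; remainder
#' slices are assigned base first, then mid. For protocol-admissible totals
#' (6 to 10 slices) every region holds between 2 and 4 slices.
#'
#' @param n_slices total slice count, integer in \[6, 10\].
#' @return list with integer counts `n_base`, `n_mid`, `n_apex` and integer
#'   index vectors `base`, `mid`, `apex` (1 = most basal slice).
#' @examples
#' allocate_regions(7)  # 3 base, 2 mid, 2 apex
#' @export
allocate_regions <- function(n_slices) {
  n <- as.integer(n_slices)
  if (is.na(n) || n < 6L || n > 10L)
    stop("out of protocol: total slice count must be between 6 and 10",
         call. = FALSE)
  k <- n %/% 3L
  r <- n %% 3L
  n_base <- k + as.integer(r >= 1L)
  n_mid <- k + as.integer(r >= 2L)
  n_apex <- k
  list(n_base = n_base, n_mid = n_mid, n_apex = n_apex,
       base = seq_len(n_base),
       mid = n_base + seq_len(n_mid),
       apex = n_base + n_mid + seq_len(n_apex))
}

# Stack per-slice strain curves into a frames x slices matrix, checking a
# common frame grid.
strain_matrix <- function(curves) {
  if (length(curves) == 0L) stop("no strain curves supplied", call. = FALSE)
  if (inherits(curves, "strain_curve")) curves <- list(curves)
  lens <- vapply(curves, function(cv) length(cv$strain), integer(1))
  if (length(unique(lens)) != 1L)
    stop("alignment error: strain curves have differing frame counts",
         call. = FALSE)
  vapply(curves, function(cv) cv$strain, numeric(lens[1]))
}

#' Regional peak circumferential strains (ACS, MCS, BCS)
#'
#' For each region the per-slice strain curves are averaged frame-wise and
#' the peak (most negative) value of the region-mean curve is reported, in
#' percent. With synchronous contraction this equals the mean of the
#' per-slice peaks; with dyssynchronous slices it is attenuated towards zero
#' relative to that mean.
#'
#' @param curves list of `strain_curve` objects ordered base to apex,
#'   covering all slices in `alloc`.
#' @param alloc a region allocation from [allocate_regions()].
#' @return named numeric vector `c(BCS, MCS, ACS)` in percent.
#' @export
regional_strain <- function(curves, alloc) {
  m <- strain_matrix(curves)
  if (ncol(m) != alloc$n_base + alloc$n_mid + alloc$n_apex)
    stop("curves do not cover the allocated slices", call. = FALSE)
  peak <- function(idx) 100 * min(rowMeans(m[, idx, drop = FALSE]))
  c(BCS = peak(alloc$base), MCS = peak(alloc$mid), ACS = peak(alloc$apex))
}

#' Global circumferential strain (GCS)
#'
#' Frame-wise mean of the strain curves across all slices, then the peak
#' (most negative) value of the mean curve, in percent.
#'
#' @param curves list of `strain_curve` objects, one per slice.
#' @return GCS in percent (scalar).
#' @export
global_strain <- function(curves) {
  m <- strain_matrix(curves)
  100 * min(rowMeans(m))
}

#' Strain analysis of one contour stack
#'
#' Runs the full per-subject strain pipeline: per-slice perimeter extraction,
#' strain curves, base/mid/apex allocation and the regional and global peak
#' strain summaries.
#'
#' @param stack a `contour_stack` (see [synthesize_cine()]).
#' @return object of class `strain_fit`: list with `curves` (per-slice
#'   `strain_curve`s), `alloc`, and `strains` — named vector
#'   `c(BCS, MCS, ACS, GCS)` in percent.
#' @export
strain_analysis <- function(stack) {
  stopifnot(inherits(stack, "contour_stack"))
  per <- stack_perimeters(stack)
  curves <- lapply(seq_len(ncol(per)), function(s) strain_curve(per[, s], s))
  alloc <- allocate_regions(ncol(per))
  st <- c(regional_strain(curves, alloc), GCS = global_strain(curves))
  structure(list(subject_id = stack$subject_id, curves = curves,
                 alloc = alloc, strains = st),
            class = "strain_fit")
}

#' @export
print.strain_fit <- function(x, ...) {
  cat(sprintf("<strain_fit> subject %s: BCS %.1f%%, MCS %.1f%%, ACS %.1f%%, GCS %.1f%%\n",
              as.character(x$subject_id), x$strains["BCS"], x$strains["MCS"],
              x$strains["ACS"], x$strains["GCS"]))
  invisible(x)
}

# Per-frame perimeters of every slice: frames x slices matrix.
stack_perimeters <- function(stack) {
  vapply(stack$contours,
         function(sl) vapply(sl, contour_perimeter, numeric(1)),
         numeric(stack$acquisition$n_frames))
}

# Per-frame enclosed areas of every slice: frames x slices matrix.
stack_areas <- function(stack) {
  vapply(stack$contours,
         function(sl) vapply(sl, contour_area, numeric(1)),
         numeric(stack$acquisition$n_frames))
}
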