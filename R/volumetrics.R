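#' Slice-summation volume of a short-axis stack
#'
#' Simpson-style slice summation: each slice's enclosed area is extruded over
#' the full inter-slice spacing (slice thickness plus gap) and the products
#' are summed, converting mm^3 to ml.
#'
#' @param areas numeric vector of per-slice enclosed areas in mm^2 (>= 0).
#' @param spacing inter-slice spacing in mm (> 0); default 10 (8 mm
#'   thickness + 2 mm gap).
#' @return volume in ml.
#' @examples
#' slice_stack_volume(rep(500, 8), 10)  # 40 ml
#' @export
slice_stack_volume <- function(areas, spacing = 10) {
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("spacing must be a positive scalar (mm)", call. = FALSE)
  a <- as.numeric(areas)
  if (length(a) == 0L) return(0)
  if (any(!is.finite(a)) || any(a < 0))
    stop("invalid input: slice areas must be finite and non-negative",
         call. = FALSE)
  sum(a) * spacing / 1000
}

#' Left-ventricular ejection fraction
#'
#' @param edv end-diastolic volume, ml (> 0).
#' @param esv end-systolic volume, ml (0 <= esv <= edv).
#' @return LVEF in percent: 100 * (EDV - ESV) / EDV.
#' @export
lvef <- function(edv, esv) {
  if (any(edv <= 0)) stop("EDV must be positive", call. = FALSE)
  if (any(esv < 0) || any(esv > edv))
    stop("invalid cycle: ESV must lie in [0, EDV]", call. = FALSE)
  100 * (edv - esv) / edv
}

#' Body surface area
#'
#' Du Bois: 0.007184 * W^0.425 * H^0.725; Mosteller: sqrt(H * W / 3600).
#' Du Bois is the default, being the dominant convention for indexing
#' cardiac volumes.
#'
#' @param height_cm height in cm (> 0).
#' @param weight_kg weight in kg (> 0).
#' @param method `"du_bois"` (default) or `"mosteller"`.
#' @return BSA in m^2.
#' @examples
#' bsa(180, 80, "mosteller")  # 2.0
#' @export
bsa <- function(height_cm, weight_kg, method = c("du_bois", "mosteller")) {
  method <- match.arg(method)
  if (any(height_cm <= 0) || any(weight_kg <= 0))
    stop("height and weight must be positive", call. = FALSE)
  switch(method,
         du_bois = 0.007184 * weight_kg^0.425 * height_cm^0.725,
         mosteller = sqrt(height_cm * weight_kg / 3600))
}

#' End-systolic volume index
#'
#' @param esv end-systolic volume, ml (>= 0).
#' @param bsa_m2 body surface area, m^2 (> 0).
#' @return ESVi in ml/m^2.
#' @export
esvi <- function(esv, bsa_m2) {
  if (any(bsa_m2 <= 0)) stop("BSA must be positive", call. = FALSE)
  if (any(esv < 0)) stop("ESV must be non-negative", call. = FALSE)
  esv / bsa_m2
}

#' Body mass index
#'
#' @param weight_kg weight in kg (> 0).
#' @param height_m height in metres (> 0).
#' @return BMI in kg/m^2.
#' @export
bmi <- function(weight_kg, height_m) {
  if (any(weight_kg <= 0) || any(height_m <= 0))
    stop("weight and height must be positive", call. = FALSE)
  weight_kg / height_m^2
}

#' Volumetric indices of one contour stack
#'
#' EDV from the frame-1 (end-diastolic) areas, ESV from the frame with the
#' smallest stack volume, LVEF and — when height and weight are supplied —
#' BSA, BMI and ESVi.
#'
#' @param stack a `contour_stack`.
#' @param height_cm,weight_kg optional anthropometrics for indexing.
#' @param bsa_method passed to [bsa()].
#' @return named list with `EDV`, `ESV`, `LVEF` and optionally `BSA`, `BMI`,
#'   `ESVi` (units: ml, ml, %, m^2, kg/m^2, ml/m^2).
#' @export
volume_indices <- function(stack, height_cm = NULL, weight_kg = NULL,
                           bsa_method = "du_bois") {
  ar <- stack_areas(stack)
  spacing <- stack$acquisition$slice_thickness + stack$acquisition$slice_gap
  vols <- apply(ar, 1, slice_stack_volume, spacing = spacing)
  edv <- vols[1]
  esv <- min(vols)
  out <- list(EDV = edv, ESV = esv, LVEF = lvef(edv, esv))
  if (!is.null(height_cm) && !is.null(weight_kg)) {
    out$BSA <- bsa(height_cm, weight_kg, bsa_method)
    out$BMI <- bmi(weight_kg, height_cm / 100)
    out$ESVi <- esvi(esv, out$BSA)
  }
  out
}
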