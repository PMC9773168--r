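# Shared fixtures: small synthetic subjects/stacks built in code.

unit_square <- function() contour_points(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))

fixture_subject <- function(cell_row = 5, seed = 42) {
  sample_subject(all_groups()[cell_row, ], seed = seed)
}

fixture_stack <- function(n_slices = 8, jitter_sd = 0, seed = 7,
                          subject = fixture_subject()) {
  synthesize_cine(subject, acquisition_params(n_slices), seed = seed,
                  jitter_sd = jitter_sd)
}

# Hand-built subject records for the cohort-builder tests.
make_records <- function(n, sex = "F", age = 50, bmi = 25, health = "healthy",
                         diabetes = FALSE, smoker = FALSE,
                         ethnicity = "white_british") {
  data.frame(id = sprintf("R%03d", seq_len(n)), sex = sex, age = age,
             bmi = bmi, diabetes = diabetes, smoker = smoker,
             ethnicity = ethnicity,
             stemi = health == "unhealthy", nstemi = FALSE, hf = FALSE,
             stringsAsFactors = FALSE)
}

# Rotate + translate a contour (rigid motion) for invariance checks.
rigid_move <- function(pts, angle, shift) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2)
  contour_points(sweep(as.matrix(pts) %*% t(R), 2, -shift))
}
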