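# Shared in-code fixtures for the test suite.

# Minimal two-sex, two-knot LMS table (L = 1 rows make the transform linear,
# so expected z-scores are hand-computable).
tiny_lms <- function() {
  lms_reference(data.frame(
    sex = c("male", "male", "female", "female"),
    age = c(4, 12, 4, 12),
    L = c(1, 1, 1, 1),
    M = c(15, 17, 15, 17),
    S = c(0.1, 0.1, 0.1, 0.1)
  ))
}

# Smooth fixture reference used wherever realistic curvature matters.
fixture_ref <- function() generate_lms_fixture()

# A handful of valid child records spanning both cohorts.
small_records <- function() {
  data.frame(
    id = sprintf("c%02d", 1:8),
    sex = rep(c("male", "female"), 4),
    age = c(4.5, 5.2, 10.3, 11.1, 4.8, 5.5, 10.9, 11.6),
    ethnicity = c("White", "White", "SouthAsian", "Black", "White", "Black",
                  "SouthAsian", "White"),
    subgroup = c(NA, NA, "Pakistani", "BlackAfrican", NA, "BlackCaribbean",
                 "Indian", NA),
    la_code = c("LA01", "LA01", "LA02", "LA02", "LA01", "LA02", "LA01", "LA02"),
    height = c(105, 108, 140, 145, 104, 112, 142, 150),
    weight = c(17, 18.5, 35, 42, 16.5, 21, 38, 45),
    stringsAsFactors = FALSE
  )
}

# small_records() with bmi and cohort columns filled in, as apply_exclusions
# would leave them.
prepared_records <- function() {
  apply_exclusions(small_records())$kept
}
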