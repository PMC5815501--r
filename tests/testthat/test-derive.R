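# Derivation of adjustments from calibration data by regression
# standardisation.

noiseless_cfg <- function(offsets, groups = c("White", names(offsets)),
                          seed = 10, n = 30) {
  calibration_config(
    seed = seed, n_per_cell = n, groups = groups,
    white_law = list(intercept = 10, fmi_slope = 2,
                     band_effects = c(0, 0.8, 1.8), sigma = 0),
    offsets = offsets)
}

test_that("a constant offset is recovered as additive_constant to machine precision", {
  calib <- generate_calibration(noiseless_cfg(
    list(SouthAsian = list(type = "constant", male = -1.1, female = -1.1))))
  fit <- derive_adjustments(calib)
  for (s in c("male", "female")) {
    rule <- fit$model$rules[[s]]$SouthAsian
    expect_equal(rule$type, "additive_constant")
    expect_equal(rule$delta, 1.1, tolerance = 1e-9)
  }
})

test_that("identical generating laws yield the identity rule", {
  # noiseless null: the fitted group difference is ~0, collapsing to identity
  calib0 <- generate_calibration(noiseless_cfg(
    list(SouthAsian = list(type = "none")), seed = 11))
  fit0 <- derive_adjustments(calib0)
  expect_equal(fit0$model$rules$male$SouthAsian$type, "identity")
  expect_equal(fit0$model$rules$female$SouthAsian$type, "identity")
  # noisy null: entry is gated at the 5% level, so identity must come back
  # in all but a type-I-rate share of seeded replicates
  types <- character()
  for (seed in 1:10) {
    cfg <- calibration_config(seed = 200 + seed, n_per_cell = 30,
                              groups = c("White", "SouthAsian"),
                              offsets = list(SouthAsian = list(type = "none")))
    fit <- derive_adjustments(generate_calibration(cfg))
    types <- c(types, fit$model$rules$male$SouthAsian$type,
               fit$model$rules$female$SouthAsian$type)
  }
  expect_gte(mean(types == "identity"), 0.8)
})

test_that("band- and fatness-dependent offsets come back as banded_linear rules
           whose application matches the generating law", {
  offsets <- list(Black = list(type = "banded_fmi", base = 0.3,
                               band_step = 0.25, fmi_slope = 0.15))
  calib <- generate_calibration(noiseless_cfg(offsets, seed = 12))
  fit <- derive_adjustments(calib)
  for (s in c("male", "female")) {
    rule <- fit$model$rules[[s]]$Black
    expect_equal(rule$type, "banded_linear")
    # negative adjustments, larger in magnitude in older bands at equal bmi
    adj_at <- function(age, bmi) {
      apply_adjustment(fit$model, data.frame(sex = s, age = age,
                                             ethnicity = "Black", bmi = bmi)) - bmi
    }
    expect_lt(adj_at(5, 18), 0)
    expect_lt(adj_at(11, 18), adj_at(5, 18))
    # application equals bmi - (true offset at the implied fmi): for band b,
    # white law gives fmi = (bmi - 10 - band_effect) / 2
    for (band_idx in 1:3) {
      age <- c(5, 8, 11)[band_idx]
      band_eff <- c(0, 0.8, 1.8)[band_idx]
      bmi <- 19
      fmi_implied <- (bmi - 10 - band_eff) / 2
      true_offset <- 0.3 + 0.25 * (band_idx - 1) + 0.15 * fmi_implied
      expect_equal(adj_at(age, bmi), -true_offset, tolerance = 1e-6)
    }
  }
})

test_that("derivation is self-consistent on data simulated under its own model", {
  offsets <- list(SouthAsian = list(type = "constant", male = -0.9,
                                    female = -0.8))
  cfg <- calibration_config(seed = 20, n_per_cell = 150,
                            groups = c("White", "SouthAsian"),
                            offsets = offsets)
  fit <- derive_adjustments(generate_calibration(cfg))
  expect_equal(fit$model$rules$male$SouthAsian$delta, 0.9, tolerance = 0.15)
  expect_equal(fit$model$rules$female$SouthAsian$delta, 0.8, tolerance = 0.15)
  # report carries the estimate, its SE and a CI containing the estimate
  rep_m <- fit$report$male$groups$SouthAsian
  expect_true(rep_m$ci[1] <= rep_m$delta_hat && rep_m$delta_hat <= rep_m$ci[2])
  expect_gt(rep_m$se, 0)
  expect_true(all(c("fmi", "ethnicity", "age_band") %in%
                  rownames(fit$report$male$coefficients) |
                  nrow(fit$report$male$coefficients) >= 5))
})

test_that("derivation rejects unusable calibration data", {
  calib <- generate_calibration(noiseless_cfg(
    list(SouthAsian = list(type = "constant", male = -1, female = -1))))
  expect_error(derive_adjustments(calib[calib$ethnicity != "White", ]),
               "White reference")
  drop_cell <- !(calib$ethnicity == "SouthAsian" & calib$sex == "male" &
                 calib$age_band == "7.0-9.9")
  expect_error(derive_adjustments(calib[drop_cell, ]),
               "empty calibration cell.*male.*SouthAsian.*7.0-9.9")
  bad <- calib; bad$fat_mass[1] <- -2
  expect_error(derive_adjustments(bad), "positive")
  expect_error(validate_calibration(transform(calib, fmi = fmi * 1.5)),
               "disagrees")
})

test_that("stepwise selection enters only significant interaction terms", {
  # constant offset, moderate noise: interactions should mostly stay out
  calib <- generate_calibration(calibration_config(
    seed = 30, n_per_cell = 100, groups = c("White", "SouthAsian"),
    offsets = list(SouthAsian = list(type = "constant", male = -1.12,
                                     female = -1.07))))
  fit <- derive_adjustments(calib)
  steps <- fit$report$male$steps
  expect_true(all(steps$p_value[steps$entered] < 0.05, na.rm = TRUE))
  # a strong fmi-by-group interaction is detected
  calib2 <- generate_calibration(noiseless_cfg(
    list(Black = list(type = "banded_fmi", base = 0, band_step = 0,
                      fmi_slope = 0.5)), seed = 31))
  cfg2 <- attr(calib2, "config"); cfg2$white_law$sigma <- 0.3
  calib2 <- generate_calibration(cfg2)
  fit2 <- derive_adjustments(calib2)
  expect_true("fmi:ethnicity" %in% fit2$report$male$terms_entered)
})
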