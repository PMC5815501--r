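# Group summaries, Mann-Whitney U, two-proportion z and before/after tables.

test_that("stratum summaries use type-7 quantiles and Wilson intervals", {
  s <- summarize_group(c(15, 16, 17), c(50, 60, 70))
  expect_equal(s$n, 3L)
  expect_equal(s$median_bmi, 16)
  expect_equal(s$lq, 15.5)
  expect_equal(s$uq, 16.5)
  expect_equal(s$prev_healthy, 100)
  expect_equal(s$prev_obese, 0)
  expect_equal(s$prev_overweight_obese,
               s$prev_overweight + s$prev_obese)
  expect_error(summarize_group(numeric(), numeric()), "empty stratum")

  # Wilson interval contains the point estimate for random small strata
  set.seed(5)
  for (i in 1:50) {
    n <- sample(3:40, 1); k <- sample(0:n, 1)
    ci <- wilson_ci(k, n)
    expect_true(ci$lower <= ci$estimate && ci$estimate <= ci$upper)
    expect_true(ci$lower >= 0 && ci$upper <= 1)
  }
  # cross-check against the closed-form Wilson expression at a known point
  ci <- wilson_ci(30, 100)
  z <- qnorm(0.975)
  expect_equal(ci$lower, (0.3 + z^2 / 200 - z * sqrt(0.3 * 0.7 / 100 +
               z^2 / 40000)) / (1 + z^2 / 100))
})

test_that("Mann-Whitney U handles separation, ties and degenerate samples", {
  # complete separation: U = 0, exact two-sided p = 2/20
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$statistic, 0)
  expect_equal(mw$p_value, 0.1)
  expect_equal(mw$method, "exact enumeration")
  # identical samples are degenerate with p = 1
  mw2 <- mann_whitney(rep(2, 5), rep(2, 7))
  expect_true(mw2$degenerate)
  expect_equal(mw2$p_value, 1)
  # a ~ b with overlap: p near 1
  expect_gt(mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))$p_value, 0.9)
  expect_error(mann_whitney(numeric(), 1:3), "nonempty")
})

test_that("Mann-Whitney agrees with stats::wilcox.test on both routes", {
  set.seed(8)
  # untied data: exact p equals wilcox.test's exact distribution
  a <- runif(6); b <- runif(7) + 0.2
  ours <- mann_whitney(a, b, exact = TRUE)
  ref <- wilcox.test(a, b, exact = TRUE)
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$p_value, ref$p.value)
  # tied data, large-sample route: matches the tie-corrected,
  # continuity-corrected normal approximation
  x <- sample(1:8, 30, replace = TRUE)
  y <- sample(2:9, 35, replace = TRUE)
  ours2 <- mann_whitney(x, y, exact = FALSE)
  ref2 <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  expect_equal(ours2$statistic, unname(ref2$statistic))
  expect_equal(ours2$p_value, ref2$p.value, tolerance = 1e-12)
})

test_that("approximate and exact Mann-Whitney p agree for untied samples of 3+", {
  # exhaustive over rank configurations: for untied data the exact p depends
  # only on (n1, n2, U), so every achievable U is checked
  for (n1 in 3:8) for (n2 in 3:8) {
    a_ranks <- utils::combn(n1 + n2, n1)
    for (u_col in c(1, ncol(a_ranks) %/% 2, ncol(a_ranks))) {
      a <- a_ranks[, u_col]; b <- setdiff(seq_len(n1 + n2), a)
      p_exact <- mann_whitney(a, b, exact = TRUE)$p_value
      p_approx <- mann_whitney(a, b, exact = FALSE)$p_value
      expect_lt(abs(p_exact - p_approx), 0.05)
    }
  }
})

test_that("two-proportion z-test matches the pooled formula", {
  eq <- two_proportion_ztest(20, 100, 10, 50)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  # hand-evaluated pooled formula
  z <- (0.3 - 0.2) / sqrt(0.25 * 0.75 * (1 / 100 + 1 / 100))
  tt <- two_proportion_ztest(30, 100, 20, 100)
  expect_equal(tt$statistic, z)
  expect_equal(tt$p_value, 2 * pnorm(-abs(z)))
  # antisymmetry
  rev <- two_proportion_ztest(20, 100, 30, 100)
  expect_equal(rev$statistic, -tt$statistic)
  expect_equal(rev$p_value, tt$p_value)
  # degenerate pooled proportion
  expect_true(two_proportion_ztest(0, 10, 0, 20)$degenerate)
  # z^2 equals the uncorrected chi-square statistic
  pt <- prop.test(c(30, 20), c(100, 100), correct = FALSE)
  expect_equal(tt$statistic^2, unname(pt$statistic))
})

test_that("before/after tables: identity model is a no-op, constants shift medians", {
  ref <- fixture_ref()
  cfg <- population_config(
    seed = 21,
    cohort_n = list("4-5y" = c(male = 400, female = 400),
                    "10-11y" = c(male = 400, female = 400)),
    z_shift = c(White = 0, Black = 0, SouthAsian = 0, OtherAsian = 0,
                Other = 0, Unknown = 0),
    z_scale = c(White = 1, Black = 1, SouthAsian = 1, OtherAsian = 1,
                Other = 1, Unknown = 1))
  pop <- generate_population(cfg, ref)
  # identity adjustments: before and after rows are bit-identical
  out <- compare_before_after(pop, ref, adjustment_model(list()))
  before <- out$summaries[out$summaries$phase == "before", ]
  after <- out$summaries[out$summaries$phase == "after", ]
  before$phase <- NULL; after$phase <- NULL
  rownames(before) <- rownames(after) <- NULL
  expect_identical(before, after)

  # constants move the South Asian median by exactly the constant
  out2 <- compare_before_after(pop, ref, default_adjustment_model())
  sm <- out2$summaries
  for (s in c("male", "female")) {
    delta <- if (s == "male") 1.12 else 1.07
    med <- sm[sm$stratum == "SouthAsian" & sm$sex == s & sm$cohort == "4-5y", ]
    expect_equal(med$median_bmi[med$phase == "after"],
                 med$median_bmi[med$phase == "before"] + delta)
  }
  # adjustment never changes stratum sizes
  expect_identical(sm$n[sm$phase == "after"], sm$n[sm$phase == "before"])
  # White rows identical across phases under the default model
  wh <- sm[sm$stratum == "White", ]
  wb <- wh[wh$phase == "before", ]; wa <- wh[wh$phase == "after", ]
  wb$phase <- NULL; wa$phase <- NULL
  rownames(wb) <- rownames(wa) <- NULL
  expect_identical(wb, wa)
  # tests table: minority strata against White, p in [0, 1]
  expect_true(all(out2$tests$p_value >= 0 & out2$tests$p_value <= 1))
  expect_false("White" %in% out2$tests$stratum)
})

test_that("overall prevalence change equals the mixture-weighted group change", {
  ref <- fixture_ref()
  pop <- generate_population(population_config(seed = 22), ref)
  out <- compare_before_after(pop, ref, default_adjustment_model())
  sm <- out$summaries
  for (co in unique(sm$cohort)) for (s in unique(sm$sex)) {
    slice <- sm[sm$cohort == co & sm$sex == s, ]
    broad <- slice[!slice$stratum %in% c("Overall") &
                   !grepl("^(Black(African|Caribbean|Other)|Indian|Pakistani|Bangladeshi)$",
                          slice$stratum), ]
    overall <- slice[slice$stratum == "Overall", ]
    for (phase in c("before", "after")) {
      g <- broad[broad$phase == phase, ]
      o <- overall[overall$phase == phase, ]
      expect_equal(sum(g$n * g$prev_overweight_obese) / sum(g$n),
                   o$prev_overweight_obese, tolerance = 1e-9)
    }
  }
})

test_that("adding a constant to a stratum shifts its median by that constant", {
  set.seed(13)
  bmi <- rlnorm(101, log(17), 0.15)
  cent <- runif(101, 1, 99)
  base <- summarize_group(bmi, cent)
  shifted <- summarize_group(bmi + 1.07, cent)
  expect_equal(shifted$median_bmi, base$median_bmi + 1.07)
  expect_equal(shifted$lq, base$lq + 1.07)
})
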