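# LMS growth-reference engine: parsing, interpolation, transforms.

test_that("reference tables parse, validate and round-trip through disk", {
  ref <- tiny_lms()
  expect_s3_class(ref, "lms_reference")
  expect_equal(nrow(ref), 4L)
  expect_equal(unname(table(ref$sex)["male"]), 2L)

  # duplicated age within one sex violates strict monotonicity
  bad <- data.frame(sex = c("male", "male", "female", "female"),
                    age = c(4, 4, 4, 12), L = 1, M = 15, S = 0.1)
  expect_error(lms_reference(bad), "strictly increasing")
  expect_error(lms_reference(data.frame(sex = "male", age = 4, L = 1, S = 0.1)),
               "missing column")
  expect_error(lms_reference(transform(as.data.frame(tiny_lms()), S = -0.1)),
               "positive")

  # write -> read round-trip is the identity, including a dialect remap
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lms_reference(fixture_ref(), path)
  expect_equal(as.data.frame(load_lms_reference(path)),
               as.data.frame(fixture_ref()))

  renamed <- withr::local_tempfile(fileext = ".csv")
  tab <- as.data.frame(fixture_ref())
  names(tab) <- c("sexcode", "age", "lambda", "mu", "sigma")
  tab$sexcode <- ifelse(tab$sexcode == "male", "1", "2")
  write.csv(tab, renamed, row.names = FALSE)
  expect_equal(as.data.frame(load_lms_reference(
    renamed, dialect = list(sex = "sexcode", L = "lambda", M = "mu", S = "sigma"))),
    as.data.frame(fixture_ref()))
})

test_that("interpolation is exact at knots, linear between, and never extrapolates", {
  ref <- tiny_lms()
  at_knot <- interpolate_lms(ref, "male", 4)
  expect_equal(unlist(at_knot), c(L = 1, M = 15, S = 0.1))
  # midway between M = 15 and 17 -> 16
  expect_equal(interpolate_lms(ref, "male", 8)$M, 16)
  expect_error(interpolate_lms(ref, "male", 3.9), "range error")
  expect_error(interpolate_lms(ref, "female", 12.1), "range error")

  # bracketing: interior ages stay within the bracketing knot values
  ref2 <- fixture_ref()
  ages <- runif(200, 4, 13)
  vals <- interpolate_lms(ref2, "female", ages)
  rows <- ref2[ref2$sex == "female", ]
  for (col in c("L", "M", "S")) {
    lo <- approx(rows$age, rows[[col]], xout = ages, method = "constant")$y
    hi <- approx(rows$age, rows[[col]], xout = ages, method = "constant",
                 f = 1)$y
    expect_true(all(vals[[col]] >= pmin(lo, hi) - 1e-12 &
                    vals[[col]] <= pmax(lo, hi) + 1e-12))
  }
})

test_that("bmi_to_zscore matches the Box-Cox transform and its log limit", {
  expect_equal(bmi_to_zscore(16, L = 1, M = 16, S = 0.1), 0)
  expect_equal(bmi_to_zscore(17.6, L = 1, M = 16, S = 0.1), 1.0)
  # independent formula evaluation, frozen
  oracle <- ((20 / 16.5)^(-1.5) - 1) / (-1.5 * 0.09)
  expect_equal(bmi_to_zscore(20, L = -1.5, M = 16.5, S = 0.09), oracle)
  expect_equal(oracle, 1.8567151, tolerance = 1e-7)
  # continuity across L -> 0
  expect_equal(bmi_to_zscore(17, L = 1e-12, M = 16, S = 0.1),
               bmi_to_zscore(17, L = 0, M = 16, S = 0.1), tolerance = 1e-9)
  expect_equal(bmi_to_zscore(17, L = 0, M = 16, S = 0.1), log(17 / 16) / 0.1)
  expect_error(bmi_to_zscore(-1, 1, 16, 0.1), "domain error")
})

test_that("z-scores map to centiles through the normal CDF", {
  expect_equal(zscore_to_centile(0), 50)
  z <- c(-2.7, -0.3, 0.8, 1.9)
  expect_equal(zscore_to_centile(z) + zscore_to_centile(-z), rep(100, 4))
  expect_equal(zscore_to_centile(1.6449), 95, tolerance = 1e-3)
  expect_error(zscore_to_centile(Inf), "domain error")
  # clamped extremes stay strictly inside (0, 100)
  expect_true(zscore_to_centile(50) < 100 && zscore_to_centile(-50) > 0)
})

test_that("centile_to_bmi inverts the centile map and is monotone", {
  ref <- fixture_ref()
  expect_equal(centile_to_bmi(ref, "male", 7, 50),
               interpolate_lms(ref, "male", 7)$M)
  expect_error(centile_to_bmi(ref, "male", 7, 0), "domain error")
  expect_error(centile_to_bmi(ref, "male", 7, 100), "domain error")

  set.seed(42)
  cent <- runif(500, 0.2, 99.8)
  age <- runif(500, 4, 13)
  sex <- sample(c("male", "female"), 500, replace = TRUE)
  bmi <- centile_to_bmi(ref, sex, age, cent)
  expect_lt(max(abs(bmi_centile(ref, sex, age, bmi) - cent)), 1e-9)

  grid <- centile_to_bmi(ref, "female", 10.5, seq(1, 99, by = 1))
  expect_true(all(diff(grid) > 0))
})

test_that("z is strictly increasing in BMI for random LMS parameters", {
  set.seed(99)
  for (i in 1:200) {
    L <- runif(1, -3, 3)
    if (i %% 20 == 0) L <- 0   # exercise the log branch too
    M <- runif(1, 10, 25); S <- runif(1, 0.05, 0.2)
    bmi <- sort(runif(20, 9, 45))
    expect_true(all(diff(bmi_to_zscore(bmi, L, M, S)) > 0))
  }
})

test_that("uniform centiles land above the 85th centile with nominal frequency", {
  ref <- fixture_ref()
  set.seed(7)
  n <- 20000
  cent <- runif(n, 0, 100)
  cent <- cent[cent > 0 & cent < 100]
  bmi <- centile_to_bmi(ref, "male", 5, cent)
  frac <- mean(bmi_centile(ref, rep("male", length(bmi)), 5, bmi) >= 85)
  se <- sqrt(0.15 * 0.85 / length(bmi))
  expect_lt(abs(frac - 0.15), 3 * se)
})
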