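# LMS growth-reference engine: parse reference tables and convert
# BMI <-> z-score <-> centile for a given sex and decimal age.

# |L| below this switches the Box-Cox transform to its log-form limit.
LMS_L_EPS <- 1e-7
# z is clamped here before the normal CDF so centiles stay strictly in (0, 100)
# in double precision.
LMS_Z_CLAMP <- 8

.sex_levels <- c("male", "female")

#' Normalise sex codes
#'
#' Maps common codings ("M"/"F", "1"/"2", "boy"/"girl", case-insensitive) to
#' the canonical `"male"`/`"female"`.
#'
#' @param x character or numeric vector of sex codes.
#' @param codes optional named character vector of extra mappings,
#'   e.g. `c("h" = "male")`; names are matched case-insensitively.
#' @return character vector with values `"male"`/`"female"`.
#' @export
normalise_sex <- function(x, codes = NULL) {
  map <- c(
    m = "male", male = "male", boy = "male", boys = "male", "1" = "male",
    f = "female", female = "female", girl = "female", girls = "female",
    "2" = "female"
  )
  if (!is.null(codes)) {
    names(codes) <- tolower(names(codes))
    map[names(codes)] <- codes
  }
  key <- tolower(trimws(as.character(x)))
  out <- unname(map[key])
  if (anyNA(out[!is.na(key)])) {
    bad <- unique(key[is.na(out) & !is.na(key)])
    stop("unrecognised sex code(s): ", paste(bad, collapse = ", "))
  }
  out
}

#' Construct an LMS reference table
#'
#' An LMS reference represents an age-varying BMI distribution per sex by the
#' Box-Cox power (L), median (M, kg m^-2) and coefficient of variation (S).
#' Rows are validated and sorted by (sex, age).
#'
#' @param data data.frame with columns `sex`, `age`, `L`, `M`, `S`.
#' @return object of class `lms_reference` (a validated data.frame).
#' @export
lms_reference <- function(data) {
  required <- c("sex", "age", "L", "M", "S")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("LMS reference format error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  data <- as.data.frame(data)[required]
  data$sex <- normalise_sex(data$sex)
  for (col in c("age", "L", "M", "S")) {
    data[[col]] <- as.numeric(data[[col]])
    if (anyNA(data[[col]])) {
      stop("LMS reference format error: non-numeric values in column ", col)
    }
  }
  if (any(data$M <= 0) || any(data$S <= 0)) {
    stop("LMS reference validation error: M and S must be positive")
  }
  data <- data[order(match(data$sex, .sex_levels), data$age), , drop = FALSE]
  rownames(data) <- NULL
  for (s in unique(data$sex)) {
    ages <- data$age[data$sex == s]
    if (length(ages) < 2) {
      stop("LMS reference validation error: fewer than 2 rows for sex ", s)
    }
    dup <- which(diff(ages) <= 0)
    if (length(dup) > 0) {
      stop("LMS reference validation error: ages not strictly increasing for sex ",
           s, " at age(s) ", paste(unique(ages[dup + 1L]), collapse = ", "))
    }
  }
  class(data) <- c("lms_reference", "data.frame")
  data
}

#' @export
print.lms_reference <- function(x, ...) {
  cat("LMS reference:", nrow(x), "rows;")
  for (s in unique(x$sex)) {
    ages <- x$age[x$sex == s]
    cat(sprintf(" %s ages [%g, %g] (%d rows)", s, min(ages), max(ages),
                length(ages)))
  }
  cat("\n")
  invisible(x)
}

.sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else ""
}

#' Read an LMS reference table from delimited text
#'
#' @param path path to a delimited file (tab, comma or whitespace separated)
#'   with header columns for sex, age, L, M and S.
#' @param dialect optional named list mapping canonical column names to the
#'   file's column names, e.g. `list(L = "lambda", M = "mu", S = "sigma")`,
#'   and optionally `sex_codes`, a named vector of extra sex codings.
#' @return an [lms_reference()].
#' @export
load_lms_reference <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("LMS reference file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = .sniff_sep(path),
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  colmap <- list(sex = "sex", age = "age", L = "L", M = "M", S = "S")
  sex_codes <- NULL
  if (!is.null(dialect)) {
    sex_codes <- dialect$sex_codes
    dialect$sex_codes <- NULL
    colmap[names(dialect)] <- dialect
  }
  for (canon in names(colmap)) {
    if (!colmap[[canon]] %in% names(raw)) {
      stop("LMS reference format error: missing column ", colmap[[canon]])
    }
  }
  data <- data.frame(
    sex = normalise_sex(raw[[colmap$sex]], codes = sex_codes),
    age = as.numeric(raw[[colmap$age]]),
    L = as.numeric(raw[[colmap$L]]),
    M = as.numeric(raw[[colmap$M]]),
    S = as.numeric(raw[[colmap$S]])
  )
  lms_reference(data)
}

#' Write an LMS reference table as tab-delimited text
#'
#' @param ref an [lms_reference()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lms_reference <- function(ref, path) {
  stopifnot(inherits(ref, "lms_reference"))
  utils::write.table(as.data.frame(ref), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Interpolate L, M, S at given sex and decimal age
#'
#' L, M and S are interpolated piecewise-linearly in age, separately per
#' parameter, within each sex's reference span. Ages outside the span are a
#' hard error: extrapolated centiles are silently wrong, so none are offered.
#'
#' @param ref an [lms_reference()].
#' @param sex vector of sex codes (recycled against `age`).
#' @param age vector of decimal ages in years.
#' @return data.frame with columns `L`, `M`, `S`, one row per input.
#' @export
interpolate_lms <- function(ref, sex, age) {
  stopifnot(inherits(ref, "lms_reference"))
  n <- max(length(sex), length(age))
  sex <- rep_len(normalise_sex(sex), n)
  age <- rep_len(as.numeric(age), n)
  out <- data.frame(L = numeric(n), M = numeric(n), S = numeric(n))
  for (s in unique(sex)) {
    rows <- ref[ref$sex == s, , drop = FALSE]
    if (nrow(rows) == 0) stop("no reference rows for sex ", s)
    idx <- which(sex == s)
    a <- age[idx]
    lo <- min(rows$age); hi <- max(rows$age)
    if (any(is.na(a)) || any(a < lo | a > hi)) {
      stop(sprintf(
        "age range error: age outside the %s reference span [%g, %g]", s, lo, hi))
    }
    for (col in c("L", "M", "S")) {
      out[[col]][idx] <- stats::approx(rows$age, rows[[col]], xout = a,
                                       method = "linear", ties = "ordered")$y
    }
  }
  out
}

#' Convert BMI to an LMS z-score
#'
#' Applies the Box-Cox LMS transform `z = ((bmi/M)^L - 1) / (L * S)` for
#' `L != 0`, with the continuous limit `z = log(bmi/M) / S` used when
#' `|L| < 1e-7`.
#'
#' @param bmi positive BMI value(s), kg m^-2.
#' @param L,M,S LMS parameters (M, S positive); recycled against `bmi`.
#' @return numeric vector of z-scores.
#' @export
bmi_to_zscore <- function(bmi, L, M, S) {
  n <- max(length(bmi), length(L), length(M), length(S))
  bmi <- rep_len(as.numeric(bmi), n); L <- rep_len(as.numeric(L), n)
  M <- rep_len(as.numeric(M), n); S <- rep_len(as.numeric(S), n)
  if (anyNA(bmi) || any(bmi <= 0)) stop("domain error: bmi must be positive")
  if (any(M <= 0) || any(S <= 0)) stop("domain error: M and S must be positive")
  log_form <- abs(L) < LMS_L_EPS
  z <- numeric(n)
  z[log_form] <- log(bmi[log_form] / M[log_form]) / S[log_form]
  z[!log_form] <- ((bmi[!log_form] / M[!log_form])^L[!log_form] - 1) /
    (L[!log_form] * S[!log_form])
  z
}

#' Convert a z-score to a centile
#'
#' Standard-normal CDF scaled to percent. z is clamped to +/- 8 so the result
#' is strictly inside (0, 100) in double precision.
#'
#' @param z finite z-score(s).
#' @return centiles in (0, 100).
#' @export
zscore_to_centile <- function(z) {
  z <- as.numeric(z)
  if (anyNA(z) || any(!is.finite(z))) stop("domain error: z must be finite")
  100 * stats::pnorm(pmin(pmax(z, -LMS_Z_CLAMP), LMS_Z_CLAMP))
}

#' Convert a centile to BMI at a given sex and age
#'
#' Inverse of the LMS transform: `bmi = M * (1 + L*S*z)^(1/L)` (or
#' `M * exp(S*z)` for `L` near 0) with `z` the normal quantile of the centile.
#'
#' @param ref an [lms_reference()].
#' @param sex,age sex codes and decimal ages (recycled).
#' @param centile centile(s) strictly inside (0, 100).
#' @return BMI values, kg m^-2.
#' @export
centile_to_bmi <- function(ref, sex, age, centile) {
  centile <- as.numeric(centile)
  if (anyNA(centile) || any(centile <= 0 | centile >= 100)) {
    stop("domain error: centile must lie strictly within (0, 100)")
  }
  p <- interpolate_lms(ref, sex, age)
  z <- stats::qnorm(centile / 100)
  log_form <- abs(p$L) < LMS_L_EPS
  bmi <- numeric(length(z))
  bmi[log_form] <- p$M[log_form] * exp(p$S[log_form] * z[log_form])
  base <- 1 + p$L[!log_form] * p$S[!log_form] * z[!log_form]
  if (any(base <= 0)) {
    stop("domain error: centile outside the representable BMI range for L, S")
  }
  bmi[!log_form] <- p$M[!log_form] * base^(1 / p$L[!log_form])
  bmi
}

#' BMI centile for child records
#'
#' Convenience wrapper: interpolates the reference at each (sex, age) and maps
#' BMI through z to a centile.
#'
#' @param ref an [lms_reference()].
#' @param sex,age,bmi vectors (recycled to a common length).
#' @return centiles in (0, 100).
#' @export
bmi_centile <- function(ref, sex, age, bmi) {
  p <- interpolate_lms(ref, sex, age)
  zscore_to_centile(bmi_to_zscore(bmi, p$L, p$M, p$S))
}
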