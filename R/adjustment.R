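# Ethnic-specific BMI adjustment models: representation, validation,
# serialisation and application.

BROAD_ETHNIC_GROUPS <- c("White", "Black", "SouthAsian", "OtherAsian",
                         "Other", "Unknown")

# Canonical 3-year derivation age bands (half-open in years).
AGE_BANDS <- data.frame(
  label = c("4.0-6.9", "7.0-9.9", "10.0-12.9"),
  lo = c(4, 7, 10), hi = c(7, 10, 13),
  stringsAsFactors = FALSE
)

#' Adjustment rules
#'
#' Three rule types map (age, unadjusted BMI) to adjusted BMI within a
#' sex-by-ethnic-group cell:
#' * `identity_rule()`: BMI unchanged (White and Unknown groups always).
#' * `additive_rule(delta)`: BMI + delta, independent of age and BMI.
#' * `banded_linear_rule(bands)`: per half-open age band `[lo, hi)`,
#'   `adjusted = intercept + (1 + slope) * bmi`; slopes must exceed -1 so the
#'   rule is order-preserving in BMI.
#'
#' @param delta additive constant, kg m^-2.
#' @param bands data.frame with columns `lo`, `hi`, `intercept`, `slope`.
#' @return a rule list with a `type` element.
#' @name adjustment_rules
NULL

#' @rdname adjustment_rules
#' @export
identity_rule <- function() list(type = "identity")

#' @rdname adjustment_rules
#' @export
additive_rule <- function(delta) {
  stopifnot(is.numeric(delta), length(delta) == 1, is.finite(delta))
  list(type = "additive_constant", delta = delta)
}

#' @rdname adjustment_rules
#' @export
banded_linear_rule <- function(bands) {
  bands <- as.data.frame(bands)
  required <- c("lo", "hi", "intercept", "slope")
  if (!all(required %in% names(bands))) {
    stop("banded_linear rule needs columns ", paste(required, collapse = ", "))
  }
  bands <- bands[order(bands$lo), required, drop = FALSE]
  if (any(bands$hi <= bands$lo)) stop("banded_linear rule: bands must have lo < hi")
  if (nrow(bands) > 1 && any(bands$lo[-1] < bands$hi[-nrow(bands)])) {
    stop("banded_linear rule: bands must not overlap")
  }
  if (any(bands$slope <= -1)) {
    stop("banded_linear rule: slopes must be > -1 (order preservation)")
  }
  rownames(bands) <- NULL
  list(type = "banded_linear", bands = bands)
}

#' Construct an ethnic BMI adjustment model
#'
#' A model holds one rule per sex and broad ethnic group. Groups without a
#' rule, and always the White and Unknown groups, are identity. Sub-ethnic
#' groups (e.g. Black African, Indian) inherit their broad group's rule.
#'
#' @param rules nested named list `rules[[sex]][[group]]` of
#'   [adjustment_rules].
#' @param cohort_ranges optional list of numeric `[lo, hi)` age ranges that
#'   every banded rule must cover (coverage validation).
#' @return object of class `adjustment_model`.
#' @export
adjustment_model <- function(rules = list(), cohort_ranges = NULL) {
  stopifnot(is.list(rules))
  for (sex in names(rules)) {
    if (!sex %in% .sex_levels) stop("adjustment model: unknown sex ", sex)
    for (group in names(rules[[sex]])) {
      if (!group %in% BROAD_ETHNIC_GROUPS) {
        stop("adjustment model: unknown ethnic group ", group)
      }
      rule <- rules[[sex]][[group]]
      if (!is.list(rule) || is.null(rule$type) ||
          !rule$type %in% c("identity", "additive_constant", "banded_linear")) {
        stop("adjustment model: invalid rule for ", sex, "/", group)
      }
      if (group %in% c("White", "Unknown") && rule$type != "identity") {
        stop("adjustment model: ", group, " must map to the identity rule")
      }
      if (rule$type == "additive_constant") {
        rules[[sex]][[group]] <- additive_rule(rule$delta)
      }
      if (rule$type == "banded_linear") {
        rule <- banded_linear_rule(rule$bands)
        if (!is.null(cohort_ranges)) {
          for (rng in cohort_ranges) {
            covered <- any(rule$bands$lo <= rng[1] & rule$bands$hi >= rng[2]) ||
              .bands_cover(rule$bands, rng)
            if (!covered) {
              stop(sprintf(
                "adjustment model: %s/%s bands do not cover ages [%g, %g)",
                sex, group, rng[1], rng[2]))
            }
          }
        }
        rules[[sex]][[group]] <- rule
      }
    }
  }
  structure(list(rules = rules), class = "adjustment_model")
}

# TRUE if contiguous bands jointly cover [lo, hi)
.bands_cover <- function(bands, rng) {
  b <- bands[bands$hi > rng[1] & bands$lo < rng[2], , drop = FALSE]
  if (nrow(b) == 0) return(FALSE)
  if (b$lo[1] > rng[1] || b$hi[nrow(b)] < rng[2]) return(FALSE)
  nrow(b) == 1 || all(b$lo[-1] == b$hi[-nrow(b)])
}

#' @export
print.adjustment_model <- function(x, ...) {
  cat("adjustment model:\n")
  for (sex in names(x$rules)) {
    for (group in names(x$rules[[sex]])) {
      rule <- x$rules[[sex]][[group]]
      desc <- switch(rule$type,
        identity = "identity",
        additive_constant = sprintf("bmi %+.3f", rule$delta),
        banded_linear = paste(sprintf("[%g,%g): %+.3f %+.4f*bmi", rule$bands$lo,
                                      rule$bands$hi, rule$bands$intercept,
                                      rule$bands$slope), collapse = "; "))
      cat(sprintf("  %s / %s: %s\n", sex, group, desc))
    }
  }
  invisible(x)
}

#' Default adjustment model
#'
#' Encodes the published sex-specific South Asian constants (+1.12 kg m^-2 for
#' boys, +1.07 kg m^-2 for girls) and an example negative Black rule that is
#' larger in magnitude at higher BMI and older ages; the published Black
#' coefficients are not reproduced here, so the banded values are an
#' illustrative configuration with the documented structure.
#'
#' @return an [adjustment_model()].
#' @export
default_adjustment_model <- function() {
  black_bands <- data.frame(lo = AGE_BANDS$lo, hi = AGE_BANDS$hi,
                            intercept = c(-0.30, -0.40, -0.50),
                            slope = c(-0.040, -0.050, -0.060))
  adjustment_model(list(
    male = list(SouthAsian = additive_rule(1.12),
                Black = banded_linear_rule(black_bands)),
    female = list(SouthAsian = additive_rule(1.07),
                  Black = banded_linear_rule(black_bands))
  ))
}

#' Read / write adjustment models as JSON
#'
#' The serialised form is `{sex: {group: {type, ...parameters}}}`; banded
#' rules carry a `bands` array of `{lo, hi, intercept, slope}` objects.
#'
#' @param path JSON file path.
#' @param model an [adjustment_model()].
#' @return `read_adjustment_model()` returns the validated model;
#'   `write_adjustment_model()` returns `path` invisibly.
#' @export
read_adjustment_model <- function(path) {
  if (!file.exists(path)) stop("adjustment model file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  rules <- lapply(raw, function(by_group) {
    lapply(by_group, function(rule) {
      if (is.null(rule$type)) stop("adjustment model schema error: rule without type")
      switch(rule$type,
        identity = identity_rule(),
        additive_constant = additive_rule(as.numeric(rule$delta)),
        banded_linear = banded_linear_rule(
          do.call(rbind, lapply(rule$bands, function(b) {
            data.frame(lo = as.numeric(b$lo), hi = as.numeric(b$hi),
                       intercept = as.numeric(b$intercept),
                       slope = as.numeric(b$slope))
          }))),
        stop("adjustment model schema error: unknown rule type ", rule$type))
    })
  })
  adjustment_model(rules)
}

#' @rdname read_adjustment_model
#' @export
write_adjustment_model <- function(model, path) {
  stopifnot(inherits(model, "adjustment_model"))
  out <- lapply(model$rules, function(by_group) {
    lapply(by_group, function(rule) {
      if (rule$type == "banded_linear") {
        rule$bands <- lapply(seq_len(nrow(rule$bands)), function(i) {
          as.list(rule$bands[i, c("lo", "hi", "intercept", "slope")])
        })
      }
      rule
    })
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Apply an ethnic BMI adjustment model to child records
#'
#' Identity groups (and any group without a rule) return BMI unchanged;
#' additive rules return `bmi + delta`; banded-linear rules return
#' `intercept + (1 + slope) * bmi` for the record's age band. Sub-ethnic
#' groups use their broad group's rule.
#'
#' @param model an [adjustment_model()].
#' @param records data.frame with `sex`, `age`, `ethnicity` and `bmi` columns
#'   (`ethnicity` holds broad group labels).
#' @return numeric vector of adjusted BMI values, kg m^-2.
#' @export
apply_adjustment <- function(model, records) {
  stopifnot(inherits(model, "adjustment_model"), is.data.frame(records))
  for (col in c("sex", "age", "ethnicity", "bmi")) {
    if (!col %in% names(records)) stop("records lack required column ", col)
  }
  sex <- normalise_sex(records$sex)
  eth <- as.character(records$ethnicity)
  bad <- !eth %in% BROAD_ETHNIC_GROUPS
  if (any(bad)) {
    stop("unknown broad ethnic group(s): ", paste(unique(eth[bad]), collapse = ", "))
  }
  out <- as.numeric(records$bmi)
  for (s in unique(sex)) {
    for (g in unique(eth[sex == s])) {
      rule <- model$rules[[s]][[g]]
      if (is.null(rule) || rule$type == "identity") next
      idx <- which(sex == s & eth == g)
      if (rule$type == "additive_constant") {
        out[idx] <- out[idx] + rule$delta
      } else {
        band <- findInterval(records$age[idx], rule$bands$lo)
        in_band <- band >= 1 & records$age[idx] < rule$bands$hi[pmax(band, 1L)]
        if (any(!in_band)) {
          stop(sprintf(
            "configuration error: age(s) not covered by any %s/%s band", s, g))
        }
        out[idx] <- rule$bands$intercept[band] +
          (1 + rule$bands$slope[band]) * out[idx]
      }
    }
  }
  out
}

#' Fat mass index (FMI)
#'
#' Height-independent fatness measure: fat mass divided by height to the fifth
#' power.
#'
#' @param fat_mass fat mass in kg.
#' @param height height in cm.
#' @return FMI in kg m^-5.
#' @export
compute_fmi <- function(fat_mass, height) {
  fat_mass <- as.numeric(fat_mass); height <- as.numeric(height)
  if (anyNA(fat_mass) || anyNA(height) || any(fat_mass <= 0) || any(height <= 0)) {
    stop("domain error: fat_mass and height must be positive")
  }
  fat_mass / (height / 100)^5
}
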