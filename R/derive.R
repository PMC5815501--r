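# Derivation of ethnic BMI adjustments from body-composition calibration
# data by regression standardisation: sex-stratified linear models of BMI on
# FMI, ethnic group and 3-year age band, with stepwise-forward entry of
# two-way interactions at the 5% level (three-way only if all two-ways
# entered), then negation of the fitted group-vs-White BMI difference at
# equal FMI.

#' Validate and complete a calibration dataset
#'
#' @param calib data.frame with columns `sex`, `age_band` (labels matching
#'   `"4.0-6.9"`, `"7.0-9.9"`, `"10.0-12.9"`), `ethnicity` (broad groups),
#'   `height` (cm), `fat_mass` (kg) and `bmi`; `fmi` is recomputed as
#'   fat mass / height(m)^5 and, if present, validated against the stored
#'   column.
#' @return the validated data.frame with an `fmi` column.
#' @export
validate_calibration <- function(calib) {
  stopifnot(is.data.frame(calib))
  required <- c("sex", "age_band", "ethnicity", "height", "fat_mass", "bmi")
  missing_cols <- setdiff(required, names(calib))
  if (length(missing_cols) > 0) {
    stop("calibration data missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  calib <- as.data.frame(calib)
  calib$sex <- normalise_sex(calib$sex)
  calib$age_band <- as.character(calib$age_band)
  bad_band <- !calib$age_band %in% AGE_BANDS$label
  if (any(bad_band)) {
    stop("calibration data: unknown age band(s) ",
         paste(unique(calib$age_band[bad_band]), collapse = ", "))
  }
  bad_eth <- !calib$ethnicity %in% BROAD_ETHNIC_GROUPS
  if (any(bad_eth)) {
    stop("calibration data: unknown ethnic group(s) ",
         paste(unique(calib$ethnicity[bad_eth]), collapse = ", "))
  }
  if (any(calib$height <= 0) || any(calib$fat_mass <= 0) || any(calib$bmi <= 0)) {
    stop("calibration data: height, fat_mass and bmi must be positive")
  }
  fmi <- compute_fmi(calib$fat_mass, calib$height)
  if ("fmi" %in% names(calib) &&
      any(abs(calib$fmi - fmi) > 1e-6 * pmax(1, fmi))) {
    stop("calibration data: stored fmi disagrees with fat_mass / height^5")
  }
  calib$fmi <- fmi
  calib
}

# Partial-F p-value for adding one term to a fitted lm.
.partial_f_p <- function(fit0, fit1) {
  tab <- stats::anova(fit0, fit1)
  p <- tab[["Pr(>F)"]][2]
  if (is.null(p) || is.na(p)) NA_real_ else p
}

# Stepwise-forward selection among the three two-way interactions at level
# alpha; ties in p broken by the fixed order of `candidates`. The three-way
# term is considered only when all two-ways entered.
.stepwise_fit <- function(data, alpha) {
  base_terms <- c("fmi", "ethnicity", "age_band")
  candidates <- c("fmi:ethnicity", "fmi:age_band", "ethnicity:age_band")
  entered <- character()
  steps <- list()
  refit <- function(terms) {
    stats::lm(stats::reformulate(terms, response = "bmi"), data = data)
  }
  fit <- refit(base_terms)
  repeat {
    remaining <- setdiff(candidates, entered)
    if (length(remaining) == 0) break
    pvals <- vapply(remaining, function(term) {
      .partial_f_p(fit, refit(c(base_terms, entered, term)))
    }, numeric(1))
    ok <- which(!is.na(pvals) & pvals < alpha)
    if (length(ok) == 0) {
      for (term in remaining) {
        steps[[length(steps) + 1L]] <- data.frame(
          term = term, p_value = pvals[[term]], entered = FALSE)
      }
      break
    }
    best <- ok[which.min(pvals[ok])]   # ties: first in fixed candidate order
    term <- remaining[best]
    entered <- c(entered, term)
    steps[[length(steps) + 1L]] <- data.frame(
      term = term, p_value = pvals[[term]], entered = TRUE)
    fit <- refit(c(base_terms, entered))
  }
  if (length(entered) == length(candidates)) {
    term <- "fmi:ethnicity:age_band"
    fit3 <- refit(c(base_terms, entered, term))
    p <- .partial_f_p(fit, fit3)
    enter3 <- !is.na(p) && p < alpha
    steps[[length(steps) + 1L]] <- data.frame(
      term = term, p_value = p, entered = enter3)
    if (enter3) {
      entered <- c(entered, term)
      fit <- fit3
    }
  }
  list(fit = fit, entered = entered,
       steps = do.call(rbind, steps))
}

# Predicted BMI from the fitted model at explicit cells.
.predict_cell <- function(fit, data, ethnicity, age_band, fmi) {
  nd <- data.frame(
    fmi = fmi,
    ethnicity = factor(ethnicity, levels = levels(data$ethnicity)),
    age_band = factor(age_band, levels = levels(data$age_band)))
  as.numeric(stats::predict(fit, newdata = nd))
}

# Group-vs-White contrast averaged over observed bands at mean FMI, with SE
# from the coefficient covariance.
.avg_contrast <- function(fit, data, group) {
  bands <- levels(data$age_band)
  fmi_ref <- mean(data$fmi)
  nd <- function(eth) data.frame(
    fmi = fmi_ref,
    ethnicity = factor(eth, levels = levels(data$ethnicity)),
    age_band = factor(bands, levels = bands))
  tt <- stats::delete.response(stats::terms(fit))
  Xg <- stats::model.matrix(tt, nd(group))
  Xw <- stats::model.matrix(tt, nd("White"))
  cvec <- colMeans(Xg - Xw)
  est <- as.numeric(cvec %*% stats::coef(fit))
  # vcov.lm warns on zero residual variance (noiseless calibration); the SE
  # is legitimately ~0 there
  se <- sqrt(as.numeric(cvec %*% suppressWarnings(stats::vcov(fit)) %*% cvec))
  c(est = est, se = se)
}

#' Derive ethnic BMI adjustments from calibration data
#'
#' Per sex, fits BMI on FMI, ethnic group and age band with stepwise-forward
#' entry of the three two-way interactions at the given significance level
#' (partial F-tests on nested fits; three-way only if all two-ways entered).
#' The adjustment for group g is the negation of the fitted expected BMI
#' difference between g and White at equal FMI and age band:
#' `adjusted_bmi = bmi - (E[BMI | fmi, g, band] - E[BMI | fmi, White, band])`.
#' When the fitted difference is FMI- and band-independent (to within
#' `collapse_tol` kg m^-2 across the observed range) the emitted rule is an
#' `additive_constant`; an FMI-dependent difference is re-expressed in
#' unadjusted BMI through the White fitted BMI-FMI relation and emitted as a
#' `banded_linear` rule; a negligible difference collapses to identity.
#'
#' @param calib calibration data, see [validate_calibration()].
#' @param alpha significance level for stepwise entry (default 0.05).
#' @param collapse_tol rule-collapse tolerance in kg m^-2 (default 0.01).
#' @return list with `model` (an [adjustment_model()]) and `report` (per sex:
#'   stepwise steps, coefficient table, and per-group offset estimate with
#'   standard error and 95% CI).
#' @export
derive_adjustments <- function(calib, alpha = 0.05, collapse_tol = 0.01) {
  calib <- validate_calibration(calib)
  groups_all <- unique(calib$ethnicity)
  if (!"White" %in% groups_all) {
    stop("derivation error: calibration data lack a White reference group")
  }
  if (length(groups_all) < 2) {
    stop("derivation error: calibration data must contain at least two ethnic groups")
  }
  cells <- expand.grid(sex = unique(calib$sex), ethnicity = groups_all,
                       age_band = unique(calib$age_band),
                       stringsAsFactors = FALSE)
  counts <- as.data.frame(table(sex = calib$sex, ethnicity = calib$ethnicity,
                                age_band = calib$age_band))
  for (i in seq_len(nrow(cells))) {
    n_cell <- counts$Freq[counts$sex == cells$sex[i] &
                          counts$ethnicity == cells$ethnicity[i] &
                          counts$age_band == cells$age_band[i]]
    if (length(n_cell) == 0 || n_cell == 0) {
      stop(sprintf("derivation error: empty calibration cell %s / %s / %s",
                   cells$sex[i], cells$ethnicity[i], cells$age_band[i]))
    }
  }

  rules <- list()
  report <- list()
  for (s in unique(calib$sex)) {
    dat <- calib[calib$sex == s, , drop = FALSE]
    dat$ethnicity <- factor(dat$ethnicity,
                            levels = c("White", setdiff(sort(unique(dat$ethnicity)),
                                                        "White")))
    dat$age_band <- factor(dat$age_band,
                           levels = AGE_BANDS$label[AGE_BANDS$label %in%
                                                    unique(dat$age_band)])
    sel <- .stepwise_fit(dat, alpha)
    fit <- sel$fit
    # joint significance of the ethnic-group effect: if dropping every term
    # involving ethnicity loses nothing at level alpha, all groups are
    # identity (null case)
    terms_no_eth <- setdiff(c("fmi", "ethnicity", "age_band", sel$entered),
                            grep("ethnicity", c("ethnicity", sel$entered),
                                 value = TRUE))
    fit_no_eth <- stats::lm(stats::reformulate(terms_no_eth, response = "bmi"),
                            data = dat)
    p_eth <- .partial_f_p(fit_no_eth, fit)
    eth_significant <- !is.na(p_eth) && p_eth < alpha
    bands <- levels(dat$age_band)
    band_rows <- AGE_BANDS[match(bands, AGE_BANDS$label), , drop = FALSE]
    fmi_range <- range(dat$fmi)

    # White fitted BMI-FMI relation per band: bmi = a_b + b_b * fmi
    a_b <- .predict_cell(fit, dat, "White", bands, 0)
    b_b <- .predict_cell(fit, dat, "White", bands, 1) - a_b

    sex_rules <- list()
    group_report <- list()
    for (g in setdiff(levels(dat$ethnicity), "White")) {
      # fitted difference per band as a linear function of fmi: d0_b + d1_b*fmi
      d0 <- .predict_cell(fit, dat, g, bands, 0) -
        .predict_cell(fit, dat, "White", bands, 0)
      d1 <- (.predict_cell(fit, dat, g, bands, 1) -
             .predict_cell(fit, dat, "White", bands, 1)) - d0
      corners <- outer(d1, fmi_range) + d0   # bands x fmi extremes
      spread <- max(corners) - min(corners)
      avg <- .avg_contrast(fit, dat, g)
      delta_hat <- -avg[["est"]]
      ci <- delta_hat + c(-1, 1) * stats::qnorm(0.975) * avg[["se"]]

      if (!eth_significant ||
          (spread < collapse_tol && max(abs(corners)) < collapse_tol)) {
        rule <- identity_rule()
      } else if (spread < collapse_tol) {
        rule <- additive_rule(delta_hat)
      } else {
        if (any(b_b <= 0)) {
          stop("derivation error: non-positive White BMI-FMI slope; cannot ",
               "re-express the FMI dependence in unadjusted BMI")
        }
        slope <- -d1 / b_b
        intercept <- -d0 + d1 * a_b / b_b
        rule <- banded_linear_rule(data.frame(
          lo = band_rows$lo, hi = band_rows$hi,
          intercept = intercept, slope = slope))
      }
      sex_rules[[g]] <- rule
      group_report[[g]] <- list(
        rule_type = rule$type, delta_hat = delta_hat, se = avg[["se"]],
        ci = ci, diff_intercepts = stats::setNames(d0, bands),
        diff_fmi_slopes = stats::setNames(d1, bands))
    }
    rules[[s]] <- sex_rules
    coef_tab <- as.data.frame(suppressWarnings(summary(fit))$coefficients)
    names(coef_tab) <- c("estimate", "se", "t", "p_value")
    report[[s]] <- list(steps = sel$steps, terms_entered = sel$entered,
                        p_ethnicity = p_eth, coefficients = coef_tab,
                        groups = group_report, n = nrow(dat))
  }
  list(model = adjustment_model(rules), report = report)
}
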