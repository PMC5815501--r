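# Group-level summaries and hypothesis tests: medians with quartiles,
# category prevalences with Wilson 95% CIs, Mann-Whitney U comparisons and
# pooled two-proportion z-tests.

#' Wilson score confidence interval for a proportion
#'
#' @param k successes, `n` trials (vectors recycled).
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @return data.frame with columns `estimate`, `lower`, `upper` (proportions).
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  stopifnot(all(n > 0), all(k >= 0), all(k <= n))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  # clamp: at k = 0 (or k = n) centre - half equals p only up to floating
  # error, and the interval must always contain the point estimate
  data.frame(estimate = p,
             lower = pmin(pmax(0, centre - half), p),
             upper = pmax(pmin(1, centre + half), p))
}

#' Summarise one stratum of child records
#'
#' Median and quartiles of BMI (linear interpolation between order statistics,
#' `stats::quantile` type 7) plus the prevalence of each weight-status
#' category, and of combined overweight-obesity, with Wilson 95% CIs.
#'
#' @param bmi numeric BMI values for the stratum.
#' @param centile matching BMI centiles.
#' @param scheme a [threshold_scheme()].
#' @param conf confidence level for the prevalence intervals.
#' @return one-row data.frame: `n`, `median_bmi`, `lq`, `uq`, then for each of
#'   underweight/healthy/overweight/obese/overweight_obese a prevalence in
#'   percent (`prev_*`) with `*_lo`/`*_hi` bounds.
#' @export
summarize_group <- function(bmi, centile, scheme = threshold_scheme("population"),
                            conf = 0.95) {
  stopifnot(length(bmi) == length(centile))
  if (length(bmi) == 0) stop("empty stratum")
  cats <- classify_centile(centile, scheme)
  n <- length(bmi)
  qs <- stats::quantile(bmi, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  out <- data.frame(n = n, median_bmi = qs[2], lq = qs[1], uq = qs[3])
  counts <- c(table(cats))
  counts <- c(counts,
              overweight_obese = sum(counts[c("overweight", "obese")]))
  for (cat in names(counts)) {
    ci <- wilson_ci(counts[[cat]], n, conf)
    out[[paste0("prev_", cat)]] <- 100 * ci$estimate
    out[[paste0("prev_", cat, "_lo")]] <- 100 * ci$lower
    out[[paste0("prev_", cat, "_hi")]] <- 100 * ci$upper
  }
  rownames(out) <- NULL
  out
}

# Midrank U statistic for sample a against b (number of (a, b) pairs with
# a > b, counting ties as half).
.u_statistic <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Mann-Whitney U test
#'
#' Two-sided comparison of two samples via the Mann-Whitney U statistic with
#' midrank tie handling. By default the p-value comes from the normal
#' approximation with tie-corrected variance and continuity correction; when
#' both samples have at most 8 observations the exact permutation distribution
#' is fully enumerated instead (p = proportion of arrangements at least as far
#' from the null mean as observed, which handles ties exactly).
#'
#' @param a,b numeric samples (nonempty).
#' @param exact force (`TRUE`) or suppress (`FALSE`) exact enumeration;
#'   `NULL` (default) enumerates when `length(a) <= 8 && length(b) <= 8`.
#' @return list of class `bmi_test`: `test`, `statistic` (U for `a` over `b`),
#'   `p_value`, `method`, `n`, `degenerate`.
#' @export
mann_whitney <- function(a, b, exact = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) stop("both samples must be nonempty")
  if (anyNA(a) || anyNA(b)) stop("samples must not contain NA")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  u <- .u_statistic(a, b)
  mu <- n1 * n2 / 2
  if (length(unique(c(a, b))) == 1) {
    return(structure(list(test = "mann_whitney", statistic = u, p_value = 1,
                          method = "degenerate", n = c(n1, n2),
                          degenerate = TRUE), class = "bmi_test"))
  }
  use_exact <- if (is.null(exact)) n1 <= 8 && n2 <= 8 else isTRUE(exact)
  if (use_exact) {
    r <- rank(c(a, b))
    combos <- utils::combn(N, n1)
    u_all <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(c(a, b))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    cc <- 0.5 * sign(u - mu)
    z <- (u - mu - cc) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation, tie-corrected, continuity-corrected"
  }
  structure(list(test = "mann_whitney", statistic = u, p_value = p,
                 method = method, n = c(n1, n2), degenerate = FALSE),
            class = "bmi_test")
}

#' Two-proportion z-test (pooled variance)
#'
#' `z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))` with p the pooled proportion;
#' two-sided p-value. A pooled proportion of exactly 0 or 1 is degenerate and
#' returns p = 1 with a flag.
#'
#' @param k1,n1 successes and trials in group 1.
#' @param k2,n2 successes and trials in group 2.
#' @return list of class `bmi_test`: `test`, `statistic` (z), `p_value`, `n`,
#'   `degenerate`.
#' @export
two_proportion_ztest <- function(k1, n1, k2, n2) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2)
  pooled <- (k1 + k2) / (n1 + n2)
  if (pooled == 0 || pooled == 1) {
    return(structure(list(test = "two_proportion_z", statistic = 0, p_value = 1,
                          n = c(n1, n2), degenerate = TRUE), class = "bmi_test"))
  }
  z <- (k1 / n1 - k2 / n2) /
    sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  structure(list(test = "two_proportion_z", statistic = z,
                 p_value = min(1, 2 * stats::pnorm(-abs(z))), n = c(n1, n2),
                 degenerate = FALSE), class = "bmi_test")
}

#' @export
print.bmi_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s)%s\n", x$test,
              x$statistic, x$p_value, paste(x$n, collapse = ", "),
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

# Strata to summarise within one cohort x sex slice: each broad group, each
# named sub-ethnic group, and the overall slice.
.strata_of <- function(slice) {
  strata <- lapply(unique(slice$ethnicity), function(g) {
    list(label = g, idx = which(slice$ethnicity == g), broad = g)
  })
  if ("subgroup" %in% names(slice)) {
    subs <- unique(slice$subgroup[!is.na(slice$subgroup) & slice$subgroup != ""])
    strata <- c(strata, lapply(subs, function(sg) {
      idx <- which(!is.na(slice$subgroup) & slice$subgroup == sg)
      list(label = sg, idx = idx, broad = slice$ethnicity[idx[1]])
    }))
  }
  c(strata, list(list(label = "Overall", idx = seq_len(nrow(slice)),
                      broad = NA_character_)))
}

#' Before/after adjustment comparison tables
#'
#' For each cohort x sex slice, emits unadjusted ("before") and adjusted
#' ("after") stratum summaries for every broad ethnic group, sub-ethnic group
#' and the overall slice, plus Mann-Whitney comparisons of the (adjusted) BMI
#' distribution and pooled two-proportion z-tests of overweight-obesity of
#' each minority stratum against the White reference.
#'
#' @param records excluded/validated child records with columns `sex`, `age`,
#'   `ethnicity`, `bmi`, `cohort` and optionally `subgroup`.
#' @param ref an [lms_reference()].
#' @param model an [adjustment_model()].
#' @param scheme a [threshold_scheme()].
#' @return list with `summaries` (data.frame: cohort, sex, stratum, phase and
#'   the [summarize_group()] columns) and `tests` (data.frame: one row per
#'   stratum x phase x test against White).
#' @export
compare_before_after <- function(records, ref, model = default_adjustment_model(),
                                 scheme = threshold_scheme("population")) {
  stopifnot(is.data.frame(records))
  if (!"cohort" %in% names(records)) {
    records$cohort <- assign_cohort(records$age)
  }
  if (anyNA(records$cohort)) stop("records contain ages outside every cohort window")
  records$sex <- normalise_sex(records$sex)
  bmi_before <- as.numeric(records$bmi)
  cent_before <- bmi_centile(ref, records$sex, records$age, bmi_before)
  bmi_after <- apply_adjustment(model, records)
  cent_after <- bmi_centile(ref, records$sex, records$age, bmi_after)

  summaries <- list(); tests <- list()
  for (co in unique(records$cohort)) {
    for (s in unique(records$sex)) {
      sel <- which(records$cohort == co & records$sex == s)
      if (length(sel) == 0) next
      slice <- records[sel, , drop = FALSE]
      strata <- .strata_of(slice)
      white_idx <- which(slice$ethnicity == "White")
      if (length(white_idx) == 0) {
        stop(sprintf("reference error: no White stratum in %s %s", co, s))
      }
      for (phase in c("before", "after")) {
        bmi_ph <- if (phase == "before") bmi_before[sel] else bmi_after[sel]
        cent_ph <- if (phase == "before") cent_before[sel] else cent_after[sel]
        ow_white <- sum(is_overweight_obese(cent_ph[white_idx], scheme))
        for (st in strata) {
          if (length(st$idx) == 0) next
          row <- summarize_group(bmi_ph[st$idx], cent_ph[st$idx], scheme)
          summaries[[length(summaries) + 1L]] <- cbind(
            data.frame(cohort = co, sex = s, stratum = st$label, phase = phase),
            row)
          if (!is.na(st$broad) && st$broad != "White") {
            mw <- mann_whitney(bmi_ph[st$idx], bmi_ph[white_idx], exact = FALSE)
            zt <- two_proportion_ztest(
              sum(is_overweight_obese(cent_ph[st$idx], scheme)),
              length(st$idx), ow_white, length(white_idx))
            tests[[length(tests) + 1L]] <- data.frame(
              cohort = co, sex = s, stratum = st$label, phase = phase,
              test = c(mw$test, zt$test),
              statistic = c(mw$statistic, zt$statistic),
              p_value = c(mw$p_value, zt$p_value),
              n_group = length(st$idx), n_white = length(white_idx),
              degenerate = c(mw$degenerate, zt$degenerate))
          }
        }
      }
    }
  }
  list(summaries = do.call(rbind, summaries),
       tests = do.call(rbind, tests))
}
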