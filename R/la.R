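# Local-authority analysis: per-LA overweight-obesity prevalence before and
# after adjustment, rankings, rank correlation and ethnic-composition classes.

#' Per-LA overweight-obesity prevalence and rankings
#'
#' Computes, for each cohort x sex and each local authority with at least
#' `min_n` included participants (counted across all cohorts and sexes, as the
#' per-LA participation rule is defined on the LA's total), the
#' overweight-obesity prevalence before and after BMI adjustment and dense
#' rankings by descending prevalence (rank 1 = highest), with ties broken
#' deterministically by LA code. Each LA is classed by its ethnic composition
#' from the within-LA South Asian and Black proportions (computed on the same
#' included records, across the whole LA).
#'
#' @param records excluded/validated child records with `sex`, `age`,
#'   `ethnicity`, `bmi`, `la_code` and `cohort` columns.
#' @param ref an [lms_reference()].
#' @param model an [adjustment_model()].
#' @param scheme a [threshold_scheme()].
#' @param min_n minimum total LA participants (default 1000).
#' @param composition_threshold proportion defining a "high" minority
#'   presence (default 0.20).
#' @return data.frame with columns `cohort`, `sex`, `la_code`, `n`,
#'   `prev_before`, `prev_after`, `rank_before`, `rank_after`, `sa_prop`,
#'   `black_prop`, `composition_class`; empty (with a warning) if no LA
#'   qualifies.
#' @export
la_prevalence_table <- function(records, ref, model = default_adjustment_model(),
                                scheme = threshold_scheme("population"),
                                min_n = 1000, composition_threshold = 0.20) {
  stopifnot(is.data.frame(records), "la_code" %in% names(records))
  if (!"cohort" %in% names(records)) records$cohort <- assign_cohort(records$age)
  records$sex <- normalise_sex(records$sex)
  records$la_code <- as.character(records$la_code)

  la_n <- table(records$la_code)
  included <- names(la_n)[la_n >= min_n]
  if (length(included) == 0) {
    warning("no local authority meets the minimum participant count")
    return(data.frame(cohort = character(), sex = character(),
                      la_code = character(), n = integer(),
                      prev_before = numeric(), prev_after = numeric(),
                      rank_before = integer(), rank_after = integer(),
                      sa_prop = numeric(), black_prop = numeric(),
                      composition_class = character()))
  }
  records <- records[records$la_code %in% included, , drop = FALSE]

  cent_before <- bmi_centile(ref, records$sex, records$age, records$bmi)
  cent_after <- bmi_centile(ref, records$sex, records$age,
                            apply_adjustment(model, records))
  ow_before <- is_overweight_obese(cent_before, scheme)
  ow_after <- is_overweight_obese(cent_after, scheme)

  comp <- do.call(rbind, lapply(included, function(la) {
    eth <- records$ethnicity[records$la_code == la]
    data.frame(la_code = la, sa_prop = mean(eth == "SouthAsian"),
               black_prop = mean(eth == "Black"))
  }))
  high_sa <- comp$sa_prop >= composition_threshold
  high_black <- comp$black_prop >= composition_threshold
  comp$composition_class <- ifelse(high_sa & high_black, "both>=20%",
                            ifelse(high_sa, "SA>=20%",
                            ifelse(high_black, "Black>=20%", "both<20%")))

  out <- list()
  for (co in unique(records$cohort)) {
    for (s in unique(records$sex)) {
      sel <- which(records$cohort == co & records$sex == s)
      if (length(sel) == 0) next
      tab <- do.call(rbind, lapply(included, function(la) {
        idx <- sel[records$la_code[sel] == la]
        data.frame(cohort = co, sex = s, la_code = la, n = length(idx),
                   prev_before = 100 * mean(ow_before[idx]),
                   prev_after = 100 * mean(ow_after[idx]))
      }))
      tab$rank_before <- .rank_desc(tab$prev_before, tab$la_code)
      tab$rank_after <- .rank_desc(tab$prev_after, tab$la_code)
      out[[length(out) + 1L]] <- merge(tab, comp, by = "la_code", sort = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$cohort, res$sex, res$rank_before),
      c("cohort", "sex", "la_code", "n", "prev_before", "prev_after",
        "rank_before", "rank_after", "sa_prop", "black_prop",
        "composition_class")]
}

# Rank 1 = largest value; ties broken by id for determinism.
.rank_desc <- function(values, ids) {
  ord <- order(-values, ids)
  rk <- integer(length(values))
  rk[ord] <- seq_along(values)
  rk
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks. Zero variance in either input is
#' undefined: the function returns `NA` with a warning.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return rho in `[-1, 1]`, or `NA` if undefined.
#' @export
spearman_rank_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    warning("Spearman correlation undefined: zero variance input")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Top-k ranking overlap
#'
#' Given before/after rankings of the same units, counts how many units sit in
#' both top-k sets and how many entered or left (the two directions are equal
#' in size since both sets have k members).
#'
#' @param rank_before,rank_after integer rank vectors (1 = top) over the same
#'   units, in the same order.
#' @param k top-set size, `k <= length(rank_before)`.
#' @return list with `overlap` and `changed` counts.
#' @export
top_k_overlap <- function(rank_before, rank_after, k) {
  stopifnot(length(rank_before) == length(rank_after),
            k >= 1, k <= length(rank_before))
  top_before <- which(rank_before <= k)
  top_after <- which(rank_after <= k)
  overlap <- length(intersect(top_before, top_after))
  list(overlap = overlap, changed = k - overlap)
}

#' Scatter plot of LA prevalence before vs after adjustment
#'
#' One panel per cohort x sex; points colour-coded by ethnic-composition
#' class, with the identity line for reference.
#'
#' @param la_table output of [la_prevalence_table()].
#' @param path output PDF path.
#' @return `path`, invisibly.
#' @export
la_scatter_plot <- function(la_table, path) {
  classes <- c("both<20%", "SA>=20%", "Black>=20%", "both>=20%")
  cols <- stats::setNames(c("grey40", "forestgreen", "red3", "blue3"), classes)
  pch <- stats::setNames(c(1, 18, 17, 15), classes)
  panels <- unique(la_table[c("cohort", "sex")])
  grDevices::pdf(path, width = 9, height = 9)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(ceiling(nrow(panels) / 2), 2), mar = c(4, 4, 2, 1))
  for (i in seq_len(nrow(panels))) {
    tab <- la_table[la_table$cohort == panels$cohort[i] &
                    la_table$sex == panels$sex[i], , drop = FALSE]
    lim <- range(tab$prev_before, tab$prev_after)
    graphics::plot(tab$prev_before, tab$prev_after, xlim = lim, ylim = lim,
                   col = cols[tab$composition_class],
                   pch = pch[tab$composition_class],
                   xlab = "overweight-obesity prevalence before adjustment (%)",
                   ylab = "after adjustment (%)",
                   main = paste(panels$cohort[i], panels$sex[i]))
    graphics::abline(0, 1, lty = 2, col = "grey70")
  }
  graphics::legend("bottomright", legend = classes, col = cols, pch = pch,
                   bty = "n", cex = 0.9)
  invisible(path)
}
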