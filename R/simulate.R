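# Synthetic-data generators: an LMS reference fixture, NCMP-like child
# populations with configurable ethnic structure and LA clustering, and
# deuterium-style body-composition calibration datasets.

# Default broad + sub-ethnic mixture (national marginal). Proportions follow
# the programme's published composition: ~65% White, ~5% Black, ~8% South
# Asian, small Other-Asian/Other shares and ~14% unknown ethnicity.
.default_ethnic_mix <- function() {
  data.frame(
    broad = c("White", "Black", "Black", "Black",
              "SouthAsian", "SouthAsian", "SouthAsian",
              "OtherAsian", "Other", "Unknown"),
    subgroup = c(NA, "BlackAfrican", "BlackCaribbean", "BlackOther",
                 "Indian", "Pakistani", "Bangladeshi", NA, NA, NA),
    prop = c(0.650, 0.030, 0.010, 0.009, 0.025, 0.039, 0.014,
             0.020, 0.060, 0.143),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic LMS reference fixture
#'
#' Smooth deterministic per-sex curves: median BMI (M) rising with age,
#' Box-Cox power (L) slightly negative (so the implied BMI distribution is
#' positively skewed, as observed in child BMI data) and coefficient of
#' variation (S) in the 0.08-0.13 range. This is a synthetic stand-in, not
#' the official UK90 coefficients.
#'
#' @param ages strictly increasing age grid in years (default 4-13 by 0.5).
#' @param sexes sexes to tabulate.
#' @return an [lms_reference()].
#' @export
generate_lms_fixture <- function(ages = seq(4, 13, by = 0.5),
                                 sexes = c("male", "female")) {
  ages <- as.numeric(ages)
  if (length(ages) < 2 || any(diff(ages) <= 0)) {
    stop("age grid must be strictly increasing with at least two points")
  }
  sexes <- normalise_sex(sexes)
  rows <- lapply(sexes, function(s) {
    t <- ages - 4
    if (s == "male") {
      M <- 15.5 + 0.05 * t + 0.020 * t^2
      L <- -1.3 - 0.060 * t
    } else {
      M <- 15.3 + 0.04 * t + 0.024 * t^2
      L <- -1.5 - 0.050 * t
    }
    data.frame(sex = s, age = ages, L = L, M = M, S = 0.085 + 0.004 * t)
  })
  lms_reference(do.call(rbind, rows))
}

#' Population generator configuration
#'
#' The default ("NCMP-like") preset emulates the national survey's structure
#' at 1/100 scale: two school cohorts with the published cohort sizes scaled
#' down 100x, the published ethnic mixture, z-scale BMI shifts giving Black
#' children a higher unadjusted BMI distribution and South Asian children a
#' slightly shifted, wider one, cohort-specific height models, and LA
#' clustering with designated high-South-Asian, high-Black and one
#' high-both LAs (baseline LAs absorb the residual mixture so the national
#' marginal matches the configured proportions).
#'
#' @param seed integer RNG seed.
#' @param cohort_n named list (per cohort) of named vectors (per sex) of
#'   record counts.
#' @param age_windows named list of half-open cohort age windows.
#' @param ethnic_mix data.frame with columns `broad`, `subgroup`, `prop`
#'   summing to 1.
#' @param z_shift,z_scale named numeric vectors per broad group: mean shift
#'   and scale of the reference-scale BMI z-score.
#' @param n_la number of local authorities.
#' @param n_high_sa,n_high_black,n_high_both counts of LAs with elevated
#'   minority shares.
#' @param high_sa_prop,high_black_prop minority share inside the designated
#'   high LAs.
#' @param height_model named list (per cohort) of named lists (per sex) of
#'   `c(mean, sd)` height parameters in cm.
#' @param z_clip clamp for sampled z-scores (keeps generated BMI within
#'   plausible bounds).
#' @return object of class `population_config`.
#' @export
population_config <- function(
    seed = 1,
    cohort_n = list("4-5y" = c(male = 2979, female = 2850),
                    "10-11y" = c(male = 2488, female = 2366)),
    age_windows = list("4-5y" = c(4, 6), "10-11y" = c(10, 12)),
    ethnic_mix = .default_ethnic_mix(),
    z_shift = c(White = 0, Black = 0.25, SouthAsian = 0.10, OtherAsian = 0.05,
                Other = 0.05, Unknown = 0),
    z_scale = c(White = 1, Black = 1, SouthAsian = 1.15, OtherAsian = 1,
                Other = 1, Unknown = 1),
    n_la = 30, n_high_sa = 4, n_high_black = 3, n_high_both = 1,
    high_sa_prop = 0.35, high_black_prop = 0.30,
    height_model = list(
      "4-5y" = list(male = c(110.0, 5.1), female = c(109.0, 5.1)),
      "10-11y" = list(male = c(144.7, 7.0), female = c(145.4, 7.5))),
    z_clip = 4) {
  stopifnot(is.numeric(seed), length(seed) == 1,
            all(names(cohort_n) %in% names(age_windows)),
            abs(sum(ethnic_mix$prop) - 1) < 1e-8, all(ethnic_mix$prop >= 0),
            all(unlist(cohort_n) > 0), all(z_scale > 0), z_clip > 0,
            n_la >= n_high_sa + n_high_black + n_high_both)
  missing_groups <- setdiff(unique(ethnic_mix$broad), names(z_shift))
  if (length(missing_groups) > 0) {
    stop("z_shift missing group(s): ", paste(missing_groups, collapse = ", "))
  }
  structure(list(seed = as.integer(seed), cohort_n = cohort_n,
                 age_windows = age_windows, ethnic_mix = ethnic_mix,
                 z_shift = z_shift, z_scale = z_scale, n_la = n_la,
                 n_high_sa = n_high_sa, n_high_black = n_high_black,
                 n_high_both = n_high_both, high_sa_prop = high_sa_prop,
                 high_black_prop = high_black_prop,
                 height_model = height_model, z_clip = z_clip),
            class = "population_config")
}

# Rescale a mixture so the broad South Asian / Black totals hit the targets,
# keeping within-group subgroup shares and relative shares of other groups.
.mix_with_targets <- function(mix, sa_target, black_target) {
  out <- mix
  base_sa <- sum(mix$prop[mix$broad == "SouthAsian"])
  base_black <- sum(mix$prop[mix$broad == "Black"])
  base_rest <- 1 - base_sa - base_black
  rest_scale <- (1 - sa_target - black_target) / base_rest
  if (rest_scale < 0) stop("LA mixture targets exceed 1")
  sel_sa <- mix$broad == "SouthAsian"
  sel_black <- mix$broad == "Black"
  out$prop[sel_sa] <- mix$prop[sel_sa] * sa_target / base_sa
  out$prop[sel_black] <- mix$prop[sel_black] * black_target / base_black
  out$prop[!sel_sa & !sel_black] <- mix$prop[!sel_sa & !sel_black] * rest_scale
  out
}

# Build the per-LA mixtures implied by a population_config: designated
# high-minority LAs get fixed elevated shares; the remaining baseline LAs
# share the residual so that the equal-weight average over LAs equals the
# configured national mixture.
.la_structure <- function(cfg) {
  n_special <- cfg$n_high_sa + cfg$n_high_black + cfg$n_high_both
  n_base <- cfg$n_la - n_special
  if (n_base < 1) stop("config must leave at least one baseline LA")
  la_codes <- sprintf("LA%02d", seq_len(cfg$n_la))
  types <- c(rep("high_sa", cfg$n_high_sa), rep("high_black", cfg$n_high_black),
             rep("high_both", cfg$n_high_both), rep("baseline", n_base))
  mix <- cfg$ethnic_mix
  mixes <- list(
    high_sa = .mix_with_targets(mix, cfg$high_sa_prop, 0.03),
    high_black = .mix_with_targets(mix, 0.05, cfg$high_black_prop),
    high_both = .mix_with_targets(mix, 0.25, 0.25)
  )
  # residual baseline mixture so the national marginal is preserved
  special_sum <- rep(0, nrow(mix))
  for (ty in c("high_sa", "high_black", "high_both")) {
    w <- sum(types == ty) / cfg$n_la
    special_sum <- special_sum + w * mixes[[ty]]$prop
  }
  base_prop <- (mix$prop - special_sum) / (n_base / cfg$n_la)
  if (any(base_prop < 0)) {
    stop("infeasible LA composition: baseline mixture would be negative; ",
         "reduce the number or share of high-minority LAs")
  }
  mixes$baseline <- transform(mix, prop = base_prop / sum(base_prop))
  list(la_codes = la_codes, types = types, mixes = mixes)
}

#' Generate an NCMP-like synthetic child population
#'
#' For each child: the LA is drawn uniformly, the (sub)ethnic group from the
#' LA's mixture, a BMI z-score on the reference scale from
#' `Normal(z_shift[group], z_scale[group])` (clamped to `z_clip`), which is
#' converted through the reference to a BMI at the child's age; height comes
#' from the cohort x sex height model and weight is set so that recomputed
#' BMI equals the sampled BMI exactly. Fully reproducible from the seed.
#'
#' @param cfg a [population_config()].
#' @param ref an [lms_reference()] covering the cohort age windows.
#' @return data.frame of child records (`id`, `sex`, `age`, `ethnicity`,
#'   `subgroup`, `la_code`, `height`, `weight`, `bmi`, `cohort`) with
#'   attributes `la_info` (LA codes and types) and `config`.
#' @export
generate_population <- function(cfg = population_config(),
                                ref = generate_lms_fixture()) {
  stopifnot(inherits(cfg, "population_config"), inherits(ref, "lms_reference"))
  set.seed(cfg$seed)
  las <- .la_structure(cfg)
  out <- list()
  for (co in names(cfg$cohort_n)) {
    w <- cfg$age_windows[[co]]
    for (s in names(cfg$cohort_n[[co]])) {
      n <- cfg$cohort_n[[co]][[s]]
      age <- stats::runif(n, w[1], w[2])
      la_idx <- sample.int(cfg$n_la, n, replace = TRUE)
      eth_row <- integer(n)
      for (ty in unique(las$types)) {
        sel <- which(las$types[la_idx] == ty)
        if (length(sel) == 0) next
        eth_row[sel] <- sample.int(nrow(cfg$ethnic_mix), length(sel),
                                   replace = TRUE, prob = las$mixes[[ty]]$prop)
      }
      broad <- cfg$ethnic_mix$broad[eth_row]
      z <- stats::rnorm(n, mean = cfg$z_shift[broad],
                        sd = cfg$z_scale[broad])
      z <- pmin(pmax(z, -cfg$z_clip), cfg$z_clip)
      bmi <- centile_to_bmi(ref, s, age, zscore_to_centile(z))
      hm <- cfg$height_model[[co]][[s]]
      height <- pmin(pmax(stats::rnorm(n, hm[1], hm[2]), 85), 195)
      weight <- bmi * (height / 100)^2
      out[[length(out) + 1L]] <- data.frame(
        id = sprintf("%s_%s_%06d", co, s, seq_len(n)), sex = s, age = age,
        ethnicity = broad, subgroup = cfg$ethnic_mix$subgroup[eth_row],
        la_code = las$la_codes[la_idx], height = height, weight = weight,
        bmi = bmi, cohort = co, stringsAsFactors = FALSE)
    }
  }
  pop <- do.call(rbind, out)
  rownames(pop) <- NULL
  attr(pop, "la_info") <- data.frame(la_code = las$la_codes, type = las$types)
  attr(pop, "config") <- cfg
  pop
}

#' Calibration generator configuration
#'
#' Emulates a pooled deuterium-dilution body-composition dataset: per
#' sex x ethnic group x 3-year age band cell, FMI is drawn log-normally,
#' height normally, fat mass follows from FMI, and BMI follows the White
#' generating law `a + b*fmi + band effect + Normal(0, sigma)` plus a
#' group-specific offset at equal FMI (the quantity the derivation must
#' recover, stored alongside the data).
#'
#' @param seed integer RNG seed.
#' @param n_per_cell records per sex x group x band cell.
#' @param groups broad ethnic groups to simulate (must include White).
#' @param sexes sexes to simulate.
#' @param bands age-band labels (subset of the canonical three).
#' @param white_law list: `intercept`, `fmi_slope` (> 0), `band_effects`
#'   (one per band), `sigma` (>= 0).
#' @param offsets named list per non-White group; each either
#'   `list(type = "constant", male =, female =)` (kg m^-2 at equal FMI) or
#'   `list(type = "banded_fmi", base =, band_step =, fmi_slope =)` giving
#'   `base + band_step*(band-1) + fmi_slope*fmi`, or `list(type = "none")`.
#' @param fmi_meanlog,fmi_sdlog log-normal FMI parameters, one `meanlog` per
#'   band.
#' @param height_mean,height_sd per-band height model (cm).
#' @return object of class `calibration_config`.
#' @export
calibration_config <- function(
    seed = 1, n_per_cell = 60,
    groups = c("White", "SouthAsian", "Black"),
    sexes = c("male", "female"),
    bands = AGE_BANDS$label,
    white_law = list(intercept = 12, fmi_slope = 1.4,
                     band_effects = c(0, 0.8, 1.8), sigma = 0.8),
    offsets = list(
      SouthAsian = list(type = "constant", male = -1.12, female = -1.07),
      Black = list(type = "banded_fmi", base = 0.3, band_step = 0.25,
                   fmi_slope = 0.15)),
    fmi_meanlog = log(c(2.5, 3.0, 3.5)), fmi_sdlog = 0.3,
    height_mean = c(115, 133, 148), height_sd = 6) {
  stopifnot("White" %in% groups, all(bands %in% AGE_BANDS$label),
            n_per_cell >= 2, white_law$fmi_slope > 0,
            length(white_law$band_effects) >= length(bands),
            length(fmi_meanlog) >= length(bands),
            length(height_mean) >= length(bands))
  if (white_law$sigma < 0) stop("validation error: sigma must be >= 0")
  for (g in names(offsets)) {
    if (!g %in% groups) stop("offset specified for group not simulated: ", g)
    if (!offsets[[g]]$type %in% c("none", "constant", "banded_fmi")) {
      stop("unknown offset type for group ", g)
    }
  }
  structure(list(seed = as.integer(seed), n_per_cell = n_per_cell,
                 groups = groups, sexes = normalise_sex(sexes), bands = bands,
                 white_law = white_law, offsets = offsets,
                 fmi_meanlog = fmi_meanlog, fmi_sdlog = fmi_sdlog,
                 height_mean = height_mean, height_sd = height_sd),
            class = "calibration_config")
}

# Offset of `group` relative to White at equal FMI, per record.
.offset_value <- function(spec, sex, band_idx, fmi) {
  if (is.null(spec) || spec$type == "none") return(rep(0, length(fmi)))
  if (spec$type == "constant") return(rep(spec[[sex]], length(fmi)))
  spec$base + spec$band_step * (band_idx - 1) + spec$fmi_slope * fmi
}

#' Generate a synthetic body-composition calibration dataset
#'
#' @param cfg a [calibration_config()].
#' @return data.frame of calibration records (`sex`, `age_band`, `ethnicity`,
#'   `height`, `fat_mass`, `bmi`, `fmi`) with attribute `true_offsets`, the
#'   per-group offset specification the data were generated under.
#' @export
generate_calibration <- function(cfg = calibration_config()) {
  stopifnot(inherits(cfg, "calibration_config"))
  set.seed(cfg$seed)
  out <- list()
  for (s in cfg$sexes) {
    for (g in cfg$groups) {
      for (bi in seq_along(cfg$bands)) {
        n <- cfg$n_per_cell
        fmi <- stats::rlnorm(n, cfg$fmi_meanlog[bi], cfg$fmi_sdlog)
        height <- stats::rnorm(n, cfg$height_mean[bi], cfg$height_sd)
        fat_mass <- fmi * (height / 100)^5
        bmi <- cfg$white_law$intercept + cfg$white_law$fmi_slope * fmi +
          cfg$white_law$band_effects[bi] +
          .offset_value(cfg$offsets[[g]], s, bi, fmi) +
          stats::rnorm(n, 0, cfg$white_law$sigma)
        out[[length(out) + 1L]] <- data.frame(
          sex = s, age_band = cfg$bands[bi], ethnicity = g, height = height,
          fat_mass = fat_mass, bmi = bmi, fmi = fmi, stringsAsFactors = FALSE)
      }
    }
  }
  calib <- do.call(rbind, out)
  rownames(calib) <- NULL
  attr(calib, "true_offsets") <- cfg$offsets
  attr(calib, "config") <- cfg
  calib
}
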