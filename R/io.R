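# Delimited-text I/O for child records.

#' Read child records from delimited text
#'
#' Expects one row per child with header columns `id`, `sex`, `age`,
#' `ethnicity`, `la_code`, `height` (cm), `weight` (kg) and optionally
#' `subgroup` and `bmi`. BMI is always recomputed from height and weight; a
#' stored `bmi` column is validated against the recomputed value (a warning
#' is raised when any stored value deviates by more than 0.1 kg m^-2), never
#' trusted.
#'
#' @param path path to a tab- or comma-delimited file.
#' @param dialect optional named list mapping canonical column names to the
#'   file's names.
#' @return data.frame of child records.
#' @export
load_child_records <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("child records file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = .sniff_sep(path),
                           stringsAsFactors = FALSE, check.names = FALSE)
  colmap <- list(id = "id", sex = "sex", age = "age", ethnicity = "ethnicity",
                 subgroup = "subgroup", la_code = "la_code", height = "height",
                 weight = "weight", bmi = "bmi")
  if (!is.null(dialect)) colmap[names(dialect)] <- dialect
  required <- c("id", "sex", "age", "ethnicity", "la_code", "height", "weight")
  for (canon in required) {
    if (!colmap[[canon]] %in% names(raw)) {
      stop("child records format error: missing column ", colmap[[canon]])
    }
  }
  out <- data.frame(
    id = as.character(raw[[colmap$id]]),
    sex = raw[[colmap$sex]],
    age = as.numeric(raw[[colmap$age]]),
    ethnicity = as.character(raw[[colmap$ethnicity]]),
    la_code = as.character(raw[[colmap$la_code]]),
    height = as.numeric(raw[[colmap$height]]),
    weight = as.numeric(raw[[colmap$weight]]),
    stringsAsFactors = FALSE
  )
  out$subgroup <- if (colmap$subgroup %in% names(raw)) {
    as.character(raw[[colmap$subgroup]])
  } else NA_character_
  bmi <- out$weight / (out$height / 100)^2
  if (colmap$bmi %in% names(raw)) {
    stored <- as.numeric(raw[[colmap$bmi]])
    off <- which(!is.na(stored) & abs(stored - bmi) > 0.1)
    if (length(off) > 0) {
      warning(length(off), " stored BMI value(s) disagree with weight/height^2; ",
              "recomputed values used")
    }
  }
  out$bmi <- bmi
  out
}

#' Write child records as tab-delimited text
#'
#' @param records child-record data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_child_records <- function(records, path) {
  utils::write.table(records, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a calibration dataset as tab-delimited text
#'
#' @param calib calibration data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(calib, path) {
  utils::write.table(calib, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a calibration dataset from delimited text
#'
#' @param path path to a delimited file with columns `sex`, `age_band`,
#'   `ethnicity`, `height`, `fat_mass`, `bmi`.
#' @return validated calibration data.frame (see [validate_calibration()]).
#' @export
load_calibration <- function(path) {
  if (!file.exists(path)) stop("calibration file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = .sniff_sep(path),
                           stringsAsFactors = FALSE)
  validate_calibration(raw)
}
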