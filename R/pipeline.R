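# End-to-end pipeline: load -> exclude -> centile -> classify (before) ->
# adjust -> re-centile -> classify (after) -> summaries -> tests -> LA
# analysis -> sensitivity reruns, with a run manifest.

#' Pipeline configuration
#'
#' Inputs may be given as file paths (delimited text / JSON, loaded through
#' the package readers) or as in-memory objects.
#'
#' @param records child records: path or data.frame.
#' @param lms LMS reference: path or [lms_reference()].
#' @param model adjustment model: path or [adjustment_model()].
#' @param out_dir output directory (created if needed).
#' @param scheme threshold scheme name or [threshold_scheme()].
#' @param exclusions an [exclusion_config()].
#' @param min_la_n minimum LA participant count for the LA analysis.
#' @param top_k top-set size for the ranking-overlap summary.
#' @param clinical_rerun also rerun summaries under the clinical scheme.
#' @param severe_obesity_cutoffs optional cut-off table (path or data.frame)
#'   enabling the severe-obesity-exclusion sensitivity rerun.
#' @param make_plots write the LA before/after scatter (PDF).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(records, lms, model = default_adjustment_model(),
                            out_dir, scheme = "population",
                            exclusions = exclusion_config(), min_la_n = 1000,
                            top_k = 20, clinical_rerun = FALSE,
                            severe_obesity_cutoffs = NULL, make_plots = FALSE) {
  if (is.character(scheme)) scheme <- threshold_scheme(scheme)
  stopifnot(inherits(exclusions, "exclusion_config"),
            inherits(scheme, "threshold_scheme"))
  structure(list(records = records, lms = lms, model = model,
                 out_dir = out_dir, scheme = scheme, exclusions = exclusions,
                 min_la_n = min_la_n, top_k = top_k,
                 clinical_rerun = clinical_rerun,
                 severe_obesity_cutoffs = severe_obesity_cutoffs,
                 make_plots = make_plots),
            class = "pipeline_config")
}

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

# Summaries + tests + LA tables for one (records, scheme) pass; writes files
# tagged with `tag` and returns the results plus written paths.
.analysis_pass <- function(records, ref, model, scheme, min_la_n, top_k,
                           out_dir, tag, make_plots) {
  written <- character()
  cmp <- compare_before_after(records, ref, model, scheme)
  for (co in unique(cmp$summaries$cohort)) {
    for (s in unique(cmp$summaries$sex)) {
      sub <- cmp$summaries[cmp$summaries$cohort == co & cmp$summaries$sex == s, ]
      if (nrow(sub) == 0) next
      written <- c(written, .write_csv(sub, file.path(
        out_dir, sprintf("summary_%s_%s_%s.csv", tag, co, s))))
    }
  }
  written <- c(written, .write_csv(cmp$tests,
                                   file.path(out_dir, sprintf("tests_%s.csv", tag))))
  la <- la_prevalence_table(records, ref, model, scheme, min_n = min_la_n)
  la_summary <- NULL
  if (nrow(la) > 0) {
    for (co in unique(la$cohort)) {
      for (s in unique(la$sex)) {
        sub <- la[la$cohort == co & la$sex == s, ]
        if (nrow(sub) == 0) next
        written <- c(written, .write_csv(sub, file.path(
          out_dir, sprintf("la_%s_%s_%s.csv", tag, co, s))))
      }
    }
    la_summary <- do.call(rbind, lapply(unique(la$cohort), function(co) {
      do.call(rbind, lapply(unique(la$sex), function(s) {
        sub <- la[la$cohort == co & la$sex == s, ]
        if (nrow(sub) < 2) return(NULL)
        k <- min(top_k, nrow(sub))
        ov <- top_k_overlap(sub$rank_before, sub$rank_after, k)
        data.frame(cohort = co, sex = s, n_la = nrow(sub),
                   spearman_rho = spearman_rank_correlation(sub$prev_before,
                                                            sub$prev_after),
                   top_k = k, top_k_overlap = ov$overlap,
                   top_k_changed = ov$changed)
      }))
    }))
    if (!is.null(la_summary)) {
      written <- c(written, .write_csv(la_summary, file.path(
        out_dir, sprintf("la_ranking_summary_%s.csv", tag))))
    }
    if (make_plots) {
      written <- c(written,
                   la_scatter_plot(la, file.path(out_dir,
                                                 sprintf("la_scatter_%s.pdf", tag))))
    }
  }
  list(summaries = cmp$summaries, tests = cmp$tests, la = la,
       la_summary = la_summary, written = written)
}

#' Run the full before/after adjustment pipeline
#'
#' Executes load, exclusion filtering, centile assignment, classification
#' before and after ethnic BMI adjustment, group summaries and tests, the LA
#' prevalence/ranking analysis, and (optionally) clinical-threshold and
#' severe-obesity-exclusion sensitivity reruns. All outputs are delimited
#' text under `out_dir` plus a JSON run manifest recording row counts at
#' every stage; on any stage failure the partial outputs are removed.
#'
#' @param cfg a [pipeline_config()].
#' @return invisible list with `main` (summaries, tests, LA tables),
#'   `sensitivity` (any reruns), `exclusion_log` and `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  on_fail_clean <- function(expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop(e)
    })
  }
  on_fail_clean({
    records <- .stage("load", {
      if (is.character(cfg$records)) load_child_records(cfg$records)
      else as.data.frame(cfg$records)
    })
    ref <- .stage("load", {
      if (is.character(cfg$lms)) load_lms_reference(cfg$lms) else cfg$lms
    })
    model <- .stage("load", {
      if (is.character(cfg$model)) read_adjustment_model(cfg$model) else cfg$model
    })
    n_in <- nrow(records)

    excl <- .stage("exclude", apply_exclusions(records, cfg$exclusions))
    written <- c(written, .write_csv(excl$log,
                                     file.path(cfg$out_dir, "exclusion_log.csv")))
    kept <- excl$kept
    if (nrow(kept) == 0) stop("pipeline stage 'exclude' failed: no records kept")

    main <- .stage("analysis", .analysis_pass(
      kept, ref, model, cfg$scheme, cfg$min_la_n, cfg$top_k, cfg$out_dir,
      "population", cfg$make_plots))
    written <- c(written, main$written)

    sensitivity <- list()
    if (isTRUE(cfg$clinical_rerun)) {
      sensitivity$clinical <- .stage("clinical_rerun", .analysis_pass(
        kept, ref, model, threshold_scheme("clinical"), cfg$min_la_n,
        cfg$top_k, cfg$out_dir, "clinical", FALSE))
      written <- c(written, sensitivity$clinical$written)
    }
    n_severe <- NA_integer_
    if (!is.null(cfg$severe_obesity_cutoffs)) {
      cut_tab <- .stage("severe_obesity", {
        if (is.character(cfg$severe_obesity_cutoffs)) {
          load_severe_obesity_cutoffs(cfg$severe_obesity_cutoffs)
        } else cfg$severe_obesity_cutoffs
      })
      severe <- .stage("severe_obesity", flag_severe_obesity(kept, cut_tab))
      n_severe <- sum(severe)
      sensitivity$severe_obesity_excluded <- .stage("severe_obesity",
        .analysis_pass(kept[!severe, , drop = FALSE], ref, model, cfg$scheme,
                       cfg$min_la_n, cfg$top_k, cfg$out_dir,
                       "no_severe_obesity", FALSE))
      written <- c(written, sensitivity$severe_obesity_excluded$written)
    }

    manifest <- list(
      package = "bmiadjust",
      version = as.character(utils::packageVersion("bmiadjust")),
      scheme = cfg$scheme$name,
      min_la_n = cfg$min_la_n,
      rows = list(input = n_in, kept = nrow(kept),
                  excluded = n_in - nrow(kept),
                  exclusions_by_reason = stats::setNames(as.list(excl$log$n),
                                                         excl$log$reason),
                  severe_obesity_flagged = n_severe,
                  la_included = length(unique(main$la$la_code))),
      outputs = basename(written))
    cfg_path <- file.path(cfg$out_dir, "config.json")
    jsonlite::write_json(.config_as_json(cfg), cfg_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    manifest$config_md5 <- unname(tools::md5sum(cfg_path))
    manifest_path <- file.path(cfg$out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    written <- c(written, cfg_path, manifest_path)

    invisible(list(main = main, sensitivity = sensitivity,
                   exclusion_log = excl$log, manifest = manifest,
                   written = written))
  })
}

# JSON-serialisable echo of a pipeline config (in-memory inputs are described,
# not dumped).
.config_as_json <- function(cfg) {
  describe <- function(x) {
    if (is.character(x)) x else paste0("<in-memory ", class(x)[1], ">")
  }
  # out_dir is run metadata, not analysis configuration: leaving it out keeps
  # the config echo (and its hash) identical across reruns into different
  # directories
  list(records = describe(cfg$records), lms = describe(cfg$lms),
       model = describe(cfg$model),
       scheme = cfg$scheme$name,
       exclusions = unclass(cfg$exclusions), min_la_n = cfg$min_la_n,
       top_k = cfg$top_k, clinical_rerun = cfg$clinical_rerun,
       severe_obesity = !is.null(cfg$severe_obesity_cutoffs),
       make_plots = cfg$make_plots)
}
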