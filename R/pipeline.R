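# End-to-end orchestration: non-targeted screen -> targeted quantitation
# cleanup -> three-set concordance selection -> cumulative panel models,
# from a single validated configuration, with a machine-readable report.

#' Pipeline configuration
#'
#' Centralizes every constant the workflow applies: matching tolerances
#' (10 ppm, 0.1 min), screening and panel AUC thresholds (0.75 for the
#' three-set filter), exclusion options, the 7:3 split and its seed, the
#' classifier, covariate handling (CA19-9, log10), and the operating cutoffs
#' (probability 0.5; CA19-9 37 U/mL). All values are echoed into the report.
#' Unknown arguments are rejected (the constructor has no `...`).
#'
#' @param seed master seed; every stage derives its randomness from it.
#' @param run_screen run the non-targeted cross-species screen stage.
#' @param ppm_tol,rt_tol_min cross-species matching tolerances.
#' @param screen_auc_min named vector `c(human = , mouse = )` of screening
#'   AUC thresholds.
#' @param panel_threshold simultaneous-pass AUC threshold.
#' @param lipid_missing_frac_max,require_ca199 exclusion options (see
#'   [apply_exclusions()]).
#' @param train_fraction training fraction of the class-stratified split.
#' @param classifier `"LR"`, `"RF"` or `"SVM_RBF"`.
#' @param log_lipids,log_ca199 log10-transform predictors before modeling.
#' @param prob_cutoff probability cutoff for confusion summaries.
#' @param ca199_cutoff clinical covariate cutoff in U/mL.
#' @param plateau_first_step first cumulative step in the plateau mean.
#' @param synth [synth_config()] used when no input files are given.
#' @param panel_a_file,panel_b_file,lipid_meta_file optional CSV inputs
#'   replacing the synthetic cohorts.
#' @param out_dir optional directory for the JSON report and CSV artifacts.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            run_screen = TRUE,
                            ppm_tol = 10, rt_tol_min = 0.1,
                            screen_auc_min = c(human = 0.60, mouse = 0.75),
                            panel_threshold = 0.75,
                            lipid_missing_frac_max = 0,
                            require_ca199 = TRUE,
                            train_fraction = 0.7,
                            classifier = c("LR", "RF", "SVM_RBF"),
                            log_lipids = TRUE, log_ca199 = TRUE,
                            prob_cutoff = 0.5,
                            ca199_cutoff = 37,
                            plateau_first_step = 11,
                            synth = synth_config(),
                            panel_a_file = NULL, panel_b_file = NULL,
                            lipid_meta_file = NULL,
                            out_dir = NULL) {
  classifier <- match.arg(classifier)
  check01 <- function(x, nm, lo = 0, hi = 1) {
    if (!is.numeric(x) || any(x < lo) || any(x > hi)) {
      stop(nm, " must lie in [", lo, ", ", hi, "]", call. = FALSE)
    }
  }
  check01(panel_threshold, "panel_threshold")
  check01(screen_auc_min, "screen_auc_min")
  check01(lipid_missing_frac_max, "lipid_missing_frac_max")
  check01(prob_cutoff, "prob_cutoff")
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  if (ppm_tol <= 0 || rt_tol_min <= 0) {
    stop("matching tolerances must be positive", call. = FALSE)
  }
  if (!is.finite(ca199_cutoff) || ca199_cutoff <= 0) {
    stop("ca199_cutoff must be positive", call. = FALSE)
  }
  files <- c(panel_a_file, panel_b_file, lipid_meta_file)
  if (length(files) > 0 && length(files) != 3) {
    stop("panel_a_file, panel_b_file and lipid_meta_file must be given together",
         call. = FALSE)
  }
  structure(list(seed = as.integer(seed), run_screen = run_screen,
                 ppm_tol = ppm_tol, rt_tol_min = rt_tol_min,
                 screen_auc_min = screen_auc_min,
                 panel_threshold = panel_threshold,
                 lipid_missing_frac_max = lipid_missing_frac_max,
                 require_ca199 = require_ca199,
                 train_fraction = train_fraction, classifier = classifier,
                 log_lipids = log_lipids, log_ca199 = log_ca199,
                 prob_cutoff = prob_cutoff, ca199_cutoff = ca199_cutoff,
                 plateau_first_step = plateau_first_step,
                 synth = synth, panel_a_file = panel_a_file,
                 panel_b_file = panel_b_file,
                 lipid_meta_file = lipid_meta_file, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full biomarker-discovery workflow
#'
#' Stages, in order: (1) optional non-targeted cross-species screen on
#' synthetic feature tables; (2) build or load the two targeted cohorts and
#' apply the exclusion rules; (3) three-set AUC concordance selection with
#' batch flagging and majority-platform restriction; (4) class-stratified
#' split of the pooled set and cumulative marker-addition curves without and
#' with the CA19-9 covariate; (5) plateau means, covariate cutoff
#' sensitivity, and lipid-covariate correlations. Any stage failure
#' surfaces as an error naming the stage. Reruns with the same config and
#' seed produce identical reports apart from the timestamp.
#'
#' @param config a [pipeline_config()].
#' @return object of class `pipeline_report`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  report <- list(config = config[setdiff(names(config), "synth")],
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  if (config$run_screen) {
    report$screen <- stage("screen", {
      feats <- generate_nontargeted(seed = config$seed + 11L)
      matches <- match_features(feats$human, feats$mouse,
                                ppm_tol = config$ppm_tol,
                                rt_tol_min = config$rt_tol_min,
                                human_auc_min = config$screen_auc_min[["human"]],
                                mouse_auc_min = config$screen_auc_min[["mouse"]])
      list(n_matches = nrow(matches), matches = matches)
    })
  }

  panels <- stage("quant", {
    if (!is.null(config$panel_a_file)) {
      list(panel_a = read_lipid_panel(config$panel_a_file, config$lipid_meta_file),
           panel_b = read_lipid_panel(config$panel_b_file, config$lipid_meta_file))
    } else {
      sim <- generate_panel(config$synth, seed = config$seed)
      report$ground_truth <- sim$ground_truth
      list(panel_a = sim$panel_a, panel_b = sim$panel_b)
    }
  })
  excl <- stage("exclusions", {
    list(A = apply_exclusions(panels$panel_a,
                              config$lipid_missing_frac_max,
                              config$require_ca199),
         B = apply_exclusions(panels$panel_b,
                              config$lipid_missing_frac_max,
                              config$require_ca199))
  })
  report$exclusions <- list(A = excl$A$report, B = excl$B$report)
  panel_a <- excl$A$panel
  panel_b <- excl$B$panel

  selection <- stage("selection", {
    auc_by_set(panel_a, panel_b, threshold = config$panel_threshold)
  })
  report$selection <- selection

  report$model <- stage("model", {
    pooled <- pool_panels(panel_a, panel_b)
    split <- stratified_split(pooled$samples$group,
                              train_fraction = config$train_fraction,
                              seed = config$seed + 29L)
    train <- panel_subset(pooled, samples = split$train)
    validation <- panel_subset(pooled, samples = split$validation)
    curve_without <- cumulative_curve(train, validation,
                                      selection$selected_panel,
                                      with_covariate = FALSE,
                                      classifier = config$classifier,
                                      cutoff = config$prob_cutoff,
                                      log_lipids = config$log_lipids,
                                      log_covariate = config$log_ca199)
    curve_with <- cumulative_curve(train, validation,
                                   selection$selected_panel,
                                   with_covariate = TRUE,
                                   classifier = config$classifier,
                                   cutoff = config$prob_cutoff,
                                   log_lipids = config$log_lipids,
                                   log_covariate = config$log_ca199)
    fs <- min(config$plateau_first_step, max(curve_without$steps$step))
    list(split = split,
         validation_stage_I_PC = sum(validation$samples$group == "PC" &
                                       validation$samples$stage %in% "I"),
         curve_without = curve_without, curve_with = curve_with,
         plateau_first_step = fs,
         plateau_without = plateau_mean(curve_without, fs),
         plateau_with = plateau_mean(curve_with, fs))
  })

  report$covariate <- stage("covariate", {
    pooled <- pool_panels(panel_a, panel_b)
    sens <- covariate_cutoff_sensitivity(pooled$samples$ca199,
                                         pooled$samples$group,
                                         pooled$samples$stage,
                                         cutoff = config$ca199_cutoff)
    corr <- marker_covariate_correlation(pooled)
    list(cutoff_sensitivity = sens,
         max_abs_correlation = max(abs(corr), na.rm = TRUE),
         correlations = corr)
  })

  report <- structure(report, class = "pipeline_report")
  if (!is.null(config$out_dir)) write_pipeline_report(report, config$out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report (seed ", x$config$seed, ")\n", sep = "")
  if (!is.null(x$screen)) {
    cat(sprintf("  screen: %d cross-species matches\n", x$screen$n_matches))
  }
  cat(sprintf("  set A: %d samples x %d lipids; set B: %d x %d after exclusions\n",
              x$exclusions$A$retained_samples, x$exclusions$A$retained_lipids,
              x$exclusions$B$retained_samples, x$exclusions$B$retained_lipids))
  cat(sprintf("  selection: %d pass all three sets; panel of %d %ss; %d batch-flagged\n",
              length(x$selection$passing), length(x$selection$selected_panel),
              x$selection$selected_platform, length(x$selection$batch_flagged)))
  cat(sprintf("  split: train %d NM + %d PC, validation %d NM + %d PC\n",
              x$model$split$counts["train_NM"], x$model$split$counts["train_PC"],
              x$model$split$counts["validation_NM"],
              x$model$split$counts["validation_PC"]))
  cat(sprintf("  plateau mean AUC (steps >= %d): %.4f without, %.4f with CA19-9\n",
              x$model$plateau_first_step, x$model$plateau_without,
              x$model$plateau_with))
  cat(sprintf("  CA19-9 at %g U/mL: sensitivity %.2f%% (stage I %.2f%%, II-IV %.2f%%)\n",
              x$covariate$cutoff_sensitivity$cutoff,
              100 * x$covariate$cutoff_sensitivity$sensitivity,
              100 * x$covariate$cutoff_sensitivity$sensitivity_stage_I,
              100 * x$covariate$cutoff_sensitivity$sensitivity_stage_II_IV))
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits `report.json` (the full machine-readable report), the per-lipid
#' selection records CSV, the per-step curve CSVs, and the cross-species
#' match CSV when the screen stage ran.
#'
#' @param report a `pipeline_report`.
#' @param out_dir output directory (created if needed).
#' @export
write_pipeline_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  json <- list(
    config = report$config,
    timestamp = report$timestamp,
    screen = if (!is.null(report$screen)) list(n_matches = report$screen$n_matches),
    exclusions = lapply(report$exclusions, function(r) {
      list(input_samples = r$input_samples, retained_samples = r$retained_samples,
           input_lipids = r$input_lipids, retained_lipids = r$retained_lipids,
           retained_by_group = as.list(r$retained_by_group),
           retained_by_platform = as.list(r$retained_by_platform),
           dropped_samples = r$dropped_samples, dropped_lipids = r$dropped_lipids)
    }),
    selection = list(threshold = report$selection$threshold,
                     venn_counts = as.list(report$selection$venn_counts),
                     batch_flagged = report$selection$batch_flagged,
                     selected_panel = report$selection$selected_panel,
                     covariate = report$selection$covariate_record),
    model = list(split = report$model$split[c("counts", "train_fraction", "seed")],
                 plateau_first_step = report$model$plateau_first_step,
                 plateau_without = report$model$plateau_without,
                 plateau_with = report$model$plateau_with,
                 steps_without = report$model$curve_without$steps,
                 steps_with = report$model$curve_with$steps),
    covariate = list(
      cutoff = report$covariate$cutoff_sensitivity$cutoff,
      sensitivity = report$covariate$cutoff_sensitivity$sensitivity,
      sensitivity_stage_I = report$covariate$cutoff_sensitivity$sensitivity_stage_I,
      sensitivity_stage_II_IV = report$covariate$cutoff_sensitivity$sensitivity_stage_II_IV,
      max_abs_correlation = report$covariate$max_abs_correlation))
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  utils::write.csv(report$selection$records,
                   file.path(out_dir, "selection_records.csv"),
                   row.names = FALSE)
  utils::write.csv(report$model$curve_without$steps,
                   file.path(out_dir, "curve_without_ca199.csv"),
                   row.names = FALSE)
  utils::write.csv(report$model$curve_with$steps,
                   file.path(out_dir, "curve_with_ca199.csv"),
                   row.names = FALSE)
  if (!is.null(report$screen)) {
    write_matches(report$screen$matches,
                  file.path(out_dir, "cross_species_matches.csv"))
  }
  invisible(out_dir)
}

#' Validate a panel file against the expected schema
#'
#' Checks delimiter/header conformance, group and cohort enums, numeric
#' lipid columns, and reports row/column counts with per-row diagnostics.
#'
#' @param path panel CSV/TSV.
#' @return list with `valid`, `n_samples`, `n_lipids`, and a `problems`
#'   data.frame (row number, message).
#' @export
validate_panel_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !nzchar(first)) {
    stop("empty input file: ", path, call. = FALSE)
  }
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  head_cols <- c("sample_id", "group", "cohort", "stage", "ca199_u_per_ml")
  problems <- data.frame(row = integer(), message = character(),
                         stringsAsFactors = FALSE)
  add <- function(row, msg) {
    problems <<- rbind(problems, data.frame(row = row, message = msg,
                                            stringsAsFactors = FALSE))
  }
  missing_cols <- setdiff(head_cols, names(df))
  if (length(missing_cols) > 0L) {
    add(0L, paste("missing columns:", paste(missing_cols, collapse = ", ")))
  } else {
    bad_group <- which(!df$group %in% c("NM", "PC"))
    for (r in bad_group) add(r, sprintf("group '%s' not in {NM, PC}", df$group[r]))
    bad_cohort <- which(!df$cohort %in% c("A", "B"))
    for (r in bad_cohort) add(r, sprintf("cohort '%s' not in {A, B}", df$cohort[r]))
    bad_stage <- which(!(is.na(df$stage) | df$stage %in% c("I", "II", "III", "IV", "NA", "")))
    for (r in bad_stage) add(r, sprintf("stage '%s' not in {I, II, III, IV, NA}", df$stage[r]))
    lipid_cols <- setdiff(names(df), head_cols)
    for (lc in lipid_cols) {
      if (!is.numeric(df[[lc]]) && !all(is.na(df[[lc]]))) {
        add(0L, sprintf("lipid column '%s' is not numeric", lc))
      }
    }
  }
  list(valid = nrow(problems) == 0L,
       n_samples = nrow(df),
       n_lipids = length(setdiff(names(df), head_cols)),
       problems = problems)
}
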