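# Three-set concordance filter for discriminative lipids: per-lipid AUCs in
# cohort A, cohort B, and the pooled set C; simultaneous-pass filter at a
# configurable threshold (default 0.75); Venn accounting; batch-effect
# flagging (passes within each cohort, fails pooled); and restriction of the
# final panel to the modal platform.

#' Classify pass-flag triplets into Venn regions
#'
#' @param pass_a,pass_b,pass_c logical vectors (or `pass_a` may be a
#'   data.frame carrying columns `pass_a`, `pass_b`, `pass_c`).
#' @return named integer vector over the 7 Venn regions plus `none`;
#'   the regions partition the lipid set (counts sum to its size).
#' @export
venn_regions <- function(pass_a, pass_b = NULL, pass_c = NULL) {
  if (is.data.frame(pass_a)) {
    df <- pass_a
    pass_a <- df$pass_a; pass_b <- df$pass_b; pass_c <- df$pass_c
  }
  stopifnot(length(pass_a) == length(pass_b), length(pass_b) == length(pass_c))
  key <- paste0(as.integer(pass_a), as.integer(pass_b), as.integer(pass_c))
  region <- c("000" = "none", "100" = "a_only", "010" = "b_only",
              "001" = "c_only", "110" = "ab", "101" = "ac",
              "011" = "bc", "111" = "abc")[key]
  counts <- table(factor(region, levels = c("a_only", "b_only", "c_only",
                                            "ab", "ac", "bc", "abc", "none")))
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Restrict passing lipids to the modal platform and order the panel
#'
#' Most of a concordant lipid set typically comes from a single targeted
#' platform; the modeling panel keeps only lipids of that modal platform,
#' ordered by descending pooled-set AUC (lexicographic tie-break on the
#' name). An exact tie for the modal platform is an error demanding an
#' explicit choice rather than a silent one.
#'
#' @param records data.frame with columns `name`, `platform`, `auc_c`
#'   (typically the triple-passers from [auc_by_set()]).
#' @return the restricted records, ordered; the panel is `$name`.
#' @export
restrict_to_majority_platform <- function(records) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L) stop("no passing lipids to restrict", call. = FALSE)
  counts <- sort(table(records$platform), decreasing = TRUE)
  if (length(counts) > 1L && counts[1] == counts[2]) {
    stop("tie for the modal platform (",
         paste(names(counts)[counts == counts[1]], collapse = " vs "),
         "); restrict explicitly", call. = FALSE)
  }
  out <- records[records$platform == names(counts)[1], , drop = FALSE]
  out[order(-out$auc_c, out$name), , drop = FALSE]
}

#' Apply the simultaneous-pass filter to a table of per-analyte AUC triplets
#'
#' Shared by the data-driven path ([auc_by_set()]) and by replaying a
#' published AUC table through the same filter. Covariate rows (e.g. CA19-9)
#' are filtered out of the lipid accounting and reported separately.
#'
#' @param records data.frame with columns `name`, `platform`, `auc_a`,
#'   `auc_b`, `auc_c` and optionally `covariate` (logical).
#' @param threshold pass threshold on each set's AUC (default 0.75).
#' @return object of class `panel_selection`; see [auc_by_set()].
#' @export
select_from_auc_records <- function(records, threshold = 0.75) {
  records <- as.data.frame(records)
  is_cov <- if (!is.null(records$covariate)) as.logical(records$covariate) else
    rep(FALSE, nrow(records))
  cov <- records[is_cov, , drop = FALSE]
  records <- records[!is_cov, , drop = FALSE]
  records$pass_a <- records$auc_a >= threshold
  records$pass_b <- records$auc_b >= threshold
  records$pass_c <- records$auc_c >= threshold
  if (nrow(cov) > 0L) {
    cov$pass_a <- cov$auc_a >= threshold
    cov$pass_b <- cov$auc_b >= threshold
    cov$pass_c <- cov$auc_c >= threshold
  }
  passing <- records[records$pass_a & records$pass_b & records$pass_c, ,
                     drop = FALSE]
  selected <- if (nrow(passing) > 0L) restrict_to_majority_platform(passing)
              else passing
  structure(list(
    records = records,
    threshold = threshold,
    venn_counts = venn_regions(records),
    batch_flagged = records$name[records$pass_a & records$pass_b & !records$pass_c],
    passing = passing$name[order(-passing$auc_c, passing$name)],
    selected_panel = selected$name,
    selected_platform = if (nrow(selected) > 0L) selected$platform[1] else NA_character_,
    covariate_record = cov),
    class = "panel_selection")
}

#' Per-lipid AUC concordance across two cohorts and their pooled set
#'
#' Computes, for every lipid shared by the two cohort panels, the AUC
#' (direction auto) in cohort A, cohort B, and the pooled set C (simple
#' concatenation of samples — deliberately unadjusted, so cohort-specific
#' concentration-range shifts dilute the pooled AUC and get flagged as batch
#' effects). Lipids passing the threshold in all three sets form the
#' candidate panel, which is then restricted to the modal platform. CA19-9
#' (sample metadata) is evaluated the same way but kept as a covariate
#' record, never as a panel member.
#'
#' @param panel_a,panel_b post-exclusion [lipid_panel()] objects.
#' @param threshold simultaneous AUC threshold (default 0.75).
#' @return object of class `panel_selection` with `records` (per-lipid AUC
#'   triplets, directions, pass flags), `venn_counts`, `batch_flagged`
#'   (pass A and B, fail C), `passing`, `selected_panel` (ordered by
#'   descending set-C AUC), and `covariate_record`.
#' @export
auc_by_set <- function(panel_a, panel_b, threshold = 0.75) {
  stopifnot(inherits(panel_a, "lipid_panel"), inherits(panel_b, "lipid_panel"))
  pooled <- pool_panels(panel_a, panel_b)
  shared <- pooled$lipids$name
  ga <- panel_a$samples$group
  gb <- panel_b$samples$group
  gc_ <- pooled$samples$group
  rows <- lapply(shared, function(nm) {
    a <- .auc_auto(panel_a$concentrations[, nm], ga)
    b <- .auc_auto(panel_b$concentrations[, nm], gb)
    cc <- .auc_auto(pooled$concentrations[, nm], gc_)
    data.frame(name = nm,
               platform = pooled$lipids$platform[pooled$lipids$name == nm],
               auc_a = a$auc, auc_b = b$auc, auc_c = cc$auc,
               direction = cc$direction,
               direction_consistent = (a$direction == b$direction &&
                                       b$direction == cc$direction),
               stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, rows)
  sel <- select_from_auc_records(records, threshold = threshold)
  # CA19-9 covariate evaluated on samples with non-missing values
  cov <- data.frame(name = "CA19-9", platform = NA_character_,
                    auc_a = marker_auc(panel_a$samples$ca199, ga),
                    auc_b = marker_auc(panel_b$samples$ca199, gb),
                    auc_c = marker_auc(pooled$samples$ca199, gc_),
                    direction = .auc_auto(pooled$samples$ca199, gc_)$direction,
                    stringsAsFactors = FALSE)
  cov$pass_a <- cov$auc_a >= threshold
  cov$pass_b <- cov$auc_b >= threshold
  cov$pass_c <- cov$auc_c >= threshold
  sel$covariate_record <- cov
  sel
}

#' @export
print.panel_selection <- function(x, ...) {
  cat(sprintf("panel_selection: %d lipids at threshold %.2f\n",
              nrow(x$records), x$threshold))
  cat(sprintf("  pass A %d, pass B %d, pass C %d; all three %d\n",
              sum(x$records$pass_a), sum(x$records$pass_b),
              sum(x$records$pass_c), length(x$passing)))
  cat(sprintf("  batch-flagged (A+B pass, C fail): %s\n",
              if (length(x$batch_flagged)) paste(x$batch_flagged, collapse = ", ")
              else "none"))
  cat(sprintf("  selected panel (%s): %d lipids\n",
              x$selected_platform %||% NA, length(x$selected_panel)))
  invisible(x)
}

#' Correlation of each lipid with a covariate such as CA19-9
#'
#' Pearson (default) or Spearman correlation between each lipid's
#' concentration column and the covariate, missing pairs dropped pairwise;
#' fewer than 3 complete pairs or zero variance yields `NA`.
#'
#' @param panel a [lipid_panel()].
#' @param covariate numeric vector, one value per sample; defaults to the
#'   panel's CA19-9 metadata.
#' @param method `"pearson"` (untransformed concentrations) or
#'   `"spearman"`.
#' @return named numeric vector of per-lipid correlation coefficients.
#' @export
marker_covariate_correlation <- function(panel, covariate = panel$samples$ca199,
                                         method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(panel, "lipid_panel"),
            length(covariate) == nrow(panel$samples))
  out <- vapply(seq_len(nrow(panel$lipids)), function(j) {
    x <- panel$concentrations[, j]
    ok <- !is.na(x) & !is.na(covariate)
    if (sum(ok) < 3L) return(NA_real_)
    if (stats::sd(x[ok]) == 0 || stats::sd(covariate[ok]) == 0) return(NA_real_)
    stats::cor(x[ok], covariate[ok], method = method)
  }, numeric(1))
  names(out) <- panel$lipids$name
  out
}

#' Write a selection report to CSV and JSON
#'
#' @param selection a `panel_selection`.
#' @param csv_path per-lipid records CSV.
#' @param json_path summary JSON (Venn counts, batch flags, ordered panel).
#' @export
write_selection_report <- function(selection, csv_path, json_path = NULL) {
  utils::write.csv(selection$records, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(threshold = selection$threshold,
                              venn_counts = as.list(selection$venn_counts),
                              batch_flagged = selection$batch_flagged,
                              selected_panel = selection$selected_panel,
                              covariate = selection$covariate_record),
                         json_path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(csv_path)
}
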