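# Targeted lipid panel handling: the samples x lipids concentration matrix
# with platform annotations, internal-standard normalization, and the
# ordered missingness-exclusion rules that produce the analysis-ready
# cohorts.

PLATFORMS <- c("acylcarnitine", "fatty_acid_amide", "sphingolipid", "phospholipid")

#' Construct a targeted lipid panel table
#'
#' @param concentrations numeric matrix, samples x lipids, of IS-normalized
#'   concentrations. Missing measurements are `NA` — never silently zero.
#' @param lipids data.frame with one row per lipid: `name`, `platform` (one
#'   of acylcarnitine, fatty_acid_amide, sphingolipid, phospholipid), and
#'   optionally `q1`, `q3`, `rt_min`, `quant_type` (absolute/relative).
#' @param samples data.frame with one row per sample: `sample_id`, `group`
#'   (NM/PC), `cohort` (A/B), `stage` (I/II/III/IV or NA), `ca199` (U/mL,
#'   may be NA).
#' @return object of class `lipid_panel`.
#' @export
lipid_panel <- function(concentrations, lipids, samples) {
  concentrations <- as.matrix(concentrations)
  lipids <- as.data.frame(lipids)
  samples <- as.data.frame(samples)
  stopifnot(all(c("name", "platform") %in% names(lipids)),
            all(c("sample_id", "group", "cohort") %in% names(samples)))
  if (!all(lipids$platform %in% PLATFORMS)) {
    stop("unknown lipid platform: ",
         paste(setdiff(unique(lipids$platform), PLATFORMS), collapse = ", "),
         call. = FALSE)
  }
  as_group(samples$group)  # validates labels
  if (ncol(concentrations) != nrow(lipids)) {
    stop("concentration column count must equal lipid count", call. = FALSE)
  }
  if (nrow(concentrations) != nrow(samples)) {
    stop("concentration row count must equal sample count", call. = FALSE)
  }
  if (is.null(samples$stage)) samples$stage <- NA_character_
  if (is.null(samples$ca199)) samples$ca199 <- NA_real_
  rownames(concentrations) <- samples$sample_id
  colnames(concentrations) <- lipids$name
  structure(list(concentrations = concentrations, lipids = lipids,
                 samples = samples),
            class = "lipid_panel")
}

#' @export
print.lipid_panel <- function(x, ...) {
  cen <- platform_census(x)
  cat(sprintf("lipid_panel: %d samples (%d NM, %d PC; cohort %s) x %d lipids\n",
              nrow(x$samples), sum(x$samples$group == "NM"),
              sum(x$samples$group == "PC"),
              paste(unique(x$samples$cohort), collapse = "/"),
              nrow(x$lipids)))
  cat("  platforms:", paste(sprintf("%s=%d", names(cen), cen), collapse = ", "), "\n")
  invisible(x)
}

# row/column subset preserving metadata alignment
panel_subset <- function(panel, samples = NULL, lipids = NULL) {
  i <- samples %||% seq_len(nrow(panel$samples))
  j <- lipids %||% seq_len(nrow(panel$lipids))
  lipid_panel(panel$concentrations[i, j, drop = FALSE],
              panel$lipids[j, , drop = FALSE],
              panel$samples[i, , drop = FALSE])
}

#' Normalize an EIC area to its internal standard
#'
#' Each lipid is quantified as the ratio of its extracted-ion-chromatogram
#' area to the area of the spiked internal standard (IS) for its platform.
#' Vectorized; a non-positive IS area is an error naming the offending
#' lipid/sample when given.
#'
#' @param eic_area analyte EIC area(s), >= 0.
#' @param is_area internal-standard area(s), > 0.
#' @param lipid,sample optional identifiers used in error messages.
#' @return `eic_area / is_area`.
#' @export
normalize_to_is <- function(eic_area, is_area, lipid = NULL, sample = NULL) {
  bad <- which(!is.finite(is_area) | is_area <= 0)
  if (length(bad) > 0L) {
    stop(sprintf("internal-standard area must be positive (lipid %s, sample %s)",
                 (lipid %||% "?")[min(bad[1], length(lipid %||% "?"))],
                 (sample %||% "?")[min(bad[1], length(sample %||% "?"))]),
         call. = FALSE)
  }
  if (any(eic_area < 0, na.rm = TRUE)) {
    stop("EIC areas must be non-negative", call. = FALSE)
  }
  eic_area / is_area
}

#' Count lipids per targeted platform
#'
#' @param x a `lipid_panel` or a lipid-metadata data.frame with a `platform`
#'   column.
#' @return named integer vector over the four platforms (fixed order:
#'   acylcarnitine, fatty_acid_amide, sphingolipid, phospholipid).
#' @export
platform_census <- function(x) {
  lipids <- if (inherits(x, "lipid_panel")) x$lipids else as.data.frame(x)
  counts <- table(factor(lipids$platform, levels = PLATFORMS))
  out <- as.integer(counts)
  names(out) <- PLATFORMS
  out
}

#' Apply the cohort's missingness exclusion rules
#'
#' Ordered rule application, mirroring how targeted cohorts are cleaned
#' before analysis:
#' \enumerate{
#'   \item drop any sample whose measurements are missing for an entire
#'     platform (a platform-level assay failure);
#'   \item when `require_ca199`, drop samples with missing CA19-9 — CA19-9 is
#'     sample metadata, so this rule only applies when the downstream
#'     analysis uses it (both reference cohorts do);
#'   \item drop any lipid still missing in more than `lipid_missing_frac_max`
#'     of the \emph{remaining} samples (default 0: any sporadic missingness
#'     drops the lipid — values are excluded, never imputed).
#' }
#' The order matters: a platform-failure sample must not drag its whole
#' platform's lipids out of the panel.
#'
#' @param panel a [lipid_panel()].
#' @param lipid_missing_frac_max maximum tolerated missing fraction per lipid
#'   among retained samples (default 0).
#' @param require_ca199 drop samples with missing CA19-9 (default TRUE).
#' @return list with `panel` (the reduced [lipid_panel()]) and `report`
#'   (class `exclusion_report`): dropped samples/lipids with reasons and
#'   retained counts per group and platform. Row/column accounting always
#'   reconciles: retained + dropped = input on both axes.
#' @export
apply_exclusions <- function(panel, lipid_missing_frac_max = 0,
                             require_ca199 = TRUE) {
  stopifnot(inherits(panel, "lipid_panel"))
  if (nrow(panel$samples) == 0L || nrow(panel$lipids) == 0L) {
    stop("panel is empty", call. = FALSE)
  }
  conc <- panel$concentrations
  platform <- panel$lipids$platform

  # rule 1: whole-platform missingness drops the sample
  plat_fail <- vapply(seq_len(nrow(conc)), function(i) {
    for (p in unique(platform)) {
      idx <- platform == p
      if (all(is.na(conc[i, idx]))) return(p)
    }
    NA_character_
  }, character(1))
  drop1 <- !is.na(plat_fail)

  # rule 2: missing CA19-9 drops the sample (metadata requirement)
  drop2 <- if (require_ca199) is.na(panel$samples$ca199) & !drop1 else
    rep(FALSE, nrow(conc))

  keep_s <- !(drop1 | drop2)
  if (!any(keep_s)) stop("exclusion rules dropped every sample", call. = FALSE)

  # rule 3: lipid missingness among remaining samples
  miss_frac <- colMeans(is.na(conc[keep_s, , drop = FALSE]))
  drop_l <- miss_frac > lipid_missing_frac_max
  if (all(drop_l)) stop("exclusion rules dropped every lipid", call. = FALSE)

  dropped_samples <- rbind(
    data.frame(sample_id = panel$samples$sample_id[drop1],
               group = panel$samples$group[drop1],
               reason = sprintf("platform failure: %s", plat_fail[drop1]),
               stringsAsFactors = FALSE),
    data.frame(sample_id = panel$samples$sample_id[drop2],
               group = panel$samples$group[drop2],
               reason = rep("missing CA19-9", sum(drop2)),
               stringsAsFactors = FALSE))
  dropped_lipids <- data.frame(
    name = panel$lipids$name[drop_l],
    platform = panel$lipids$platform[drop_l],
    missing_frac = unname(miss_frac[drop_l]),
    reason = rep("missing in some retained samples", sum(drop_l)),
    stringsAsFactors = FALSE)

  reduced <- panel_subset(panel, samples = which(keep_s), lipids = which(!drop_l))
  report <- structure(list(
    dropped_samples = dropped_samples,
    dropped_lipids = dropped_lipids,
    input_samples = nrow(panel$samples),
    input_lipids = nrow(panel$lipids),
    retained_samples = nrow(reduced$samples),
    retained_lipids = nrow(reduced$lipids),
    retained_by_group = c(NM = sum(reduced$samples$group == "NM"),
                          PC = sum(reduced$samples$group == "PC")),
    retained_by_platform = platform_census(reduced)),
    class = "exclusion_report")
  list(panel = reduced, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("exclusions: %d -> %d samples (NM %d, PC %d); %d -> %d lipids\n",
              x$input_samples, x$retained_samples,
              x$retained_by_group["NM"], x$retained_by_group["PC"],
              x$input_lipids, x$retained_lipids))
  if (nrow(x$dropped_samples) > 0L) {
    cat("  dropped samples:\n")
    for (i in seq_len(nrow(x$dropped_samples))) {
      cat(sprintf("    %s (%s): %s\n", x$dropped_samples$sample_id[i],
                  x$dropped_samples$group[i], x$dropped_samples$reason[i]))
    }
  }
  if (nrow(x$dropped_lipids) > 0L) {
    cat("  dropped lipids:", paste(x$dropped_lipids$name, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Pool two cohorts into a combined set over their shared lipids
#'
#' Concatenates the samples of both panels, restricted to lipids present in
#' both. No re-scaling or batch correction is applied before pooling — the
#' concordance filter relies on the pooled set being sensitive to
#' between-cohort concentration-range (batch) shifts.
#'
#' @param panel_a,panel_b [lipid_panel()] objects sharing a lipid namespace.
#' @return a [lipid_panel()] for the pooled set.
#' @export
pool_panels <- function(panel_a, panel_b) {
  shared <- intersect(panel_a$lipids$name, panel_b$lipids$name)
  if (length(shared) == 0L) stop("panels share no lipids", call. = FALSE)
  ia <- match(shared, panel_a$lipids$name)
  ib <- match(shared, panel_b$lipids$name)
  meta_cols <- c("sample_id", "group", "cohort", "stage", "ca199")
  lipid_panel(rbind(panel_a$concentrations[, ia, drop = FALSE],
                    panel_b$concentrations[, ib, drop = FALSE]),
              panel_a$lipids[ia, , drop = FALSE],
              rbind(panel_a$samples[meta_cols], panel_b$samples[meta_cols]))
}

#' Read a lipid panel from delimited text
#'
#' Panel layout: one row per sample with columns `sample_id`,
#' `group` (NM/PC), `cohort` (A/B), `stage`, `ca199_u_per_ml` (may be empty),
#' then one column per lipid. The companion metadata file has columns
#' `name`, `platform`, `q1`, `q3`, `rt_min`, `quant_type`.
#'
#' @param panel_path sample x lipid CSV/TSV.
#' @param lipid_meta_path lipid metadata CSV/TSV.
#' @return a [lipid_panel()].
#' @export
read_lipid_panel <- function(panel_path, lipid_meta_path) {
  sep <- if (grepl("\t", readLines(panel_path, n = 1L))) "\t" else ","
  df <- utils::read.table(panel_path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  sep2 <- if (grepl("\t", readLines(lipid_meta_path, n = 1L))) "\t" else ","
  meta <- utils::read.table(lipid_meta_path, header = TRUE, sep = sep2,
                            check.names = FALSE, stringsAsFactors = FALSE)
  head_cols <- c("sample_id", "group", "cohort", "stage", "ca199_u_per_ml")
  if (!all(head_cols %in% names(df))) {
    stop("panel file must have columns: ", paste(head_cols, collapse = ", "),
         call. = FALSE)
  }
  lipid_cols <- setdiff(names(df), head_cols)
  missing_meta <- setdiff(lipid_cols, meta$name)
  if (length(missing_meta) > 0L) {
    stop("lipids missing from metadata: ",
         paste(utils::head(missing_meta, 5), collapse = ", "), call. = FALSE)
  }
  lipid_panel(as.matrix(df[lipid_cols]),
              meta[match(lipid_cols, meta$name), , drop = FALSE],
              data.frame(sample_id = df$sample_id, group = df$group,
                         cohort = df$cohort, stage = df$stage,
                         ca199 = df$ca199_u_per_ml, stringsAsFactors = FALSE))
}

#' Write a lipid panel (and its lipid metadata) to CSV
#'
#' @param panel a [lipid_panel()].
#' @param panel_path output CSV for the sample x lipid table.
#' @param lipid_meta_path optional output CSV for the lipid metadata.
#' @export
write_lipid_panel <- function(panel, panel_path, lipid_meta_path = NULL) {
  df <- cbind(data.frame(sample_id = panel$samples$sample_id,
                         group = panel$samples$group,
                         cohort = panel$samples$cohort,
                         stage = panel$samples$stage,
                         ca199_u_per_ml = panel$samples$ca199,
                         stringsAsFactors = FALSE),
              as.data.frame(panel$concentrations, check.names = FALSE))
  utils::write.csv(df, panel_path, row.names = FALSE)
  if (!is.null(lipid_meta_path)) {
    utils::write.csv(panel$lipids, lipid_meta_path, row.names = FALSE)
  }
  invisible(panel_path)
}
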