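# Non-targeted metabolomic feature tables and cross-species matching.
# Features carry accurate mass (m/z), retention time (min) and ionization
# mode; discriminative features shared between human and mouse plasma are
# identified by accurate-mass (ppm) + retention-time agreement.

#' Convert positive peak areas to common logarithms
#'
#' Non-targeted peak-area tables are analyzed on the log10 scale. Any
#' non-positive or missing area is an error naming the offending
#' feature/sample cell, because zeros must be handled upstream, not silently
#' log-transformed.
#'
#' @param areas numeric matrix of raw peak areas, features x samples.
#' @return matrix of the same shape with `log10(areas)`.
#' @export
log10_peak_areas <- function(areas) {
  areas <- as.matrix(areas)
  bad <- which(!is.finite(areas) | areas <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    rn <- rownames(areas) %||% as.character(seq_len(nrow(areas)))
    cn <- colnames(areas) %||% as.character(seq_len(ncol(areas)))
    stop(sprintf("non-positive or missing peak area for feature '%s', sample '%s'",
                 rn[bad[1, 1]], cn[bad[1, 2]]), call. = FALSE)
  }
  log10(areas)
}

#' Construct a non-targeted feature table
#'
#' @param features data.frame with columns `feature_id`, `mz` (> 0), `rt_min`
#'   (>= 0), `mode` (`"positive"`/`"negative"`); one row per feature.
#' @param log_areas numeric matrix of log10 normalized peak areas,
#'   features x samples.
#' @param samples data.frame of per-sample metadata with at least `sample_id`
#'   and `group` (NM/PC).
#' @return object of class `feature_table`.
#' @export
feature_table <- function(features, log_areas, samples) {
  features <- as.data.frame(features)
  samples <- as.data.frame(samples)
  log_areas <- as.matrix(log_areas)
  stopifnot(all(c("feature_id", "mz", "rt_min", "mode") %in% names(features)),
            all(c("sample_id", "group") %in% names(samples)))
  if (any(features$mz <= 0)) stop("feature m/z must be positive", call. = FALSE)
  if (any(features$rt_min < 0)) stop("retention time must be >= 0", call. = FALSE)
  if (!all(features$mode %in% c("positive", "negative"))) {
    stop("ionization mode must be 'positive' or 'negative'", call. = FALSE)
  }
  if (nrow(log_areas) != nrow(features) || ncol(log_areas) != nrow(samples)) {
    stop("log_areas must be features x samples", call. = FALSE)
  }
  rownames(log_areas) <- features$feature_id
  colnames(log_areas) <- samples$sample_id
  structure(list(features = features, log_areas = log_areas, samples = samples),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d features x %d samples (%d NM, %d PC)\n",
              nrow(x$features), nrow(x$samples),
              sum(x$samples$group == "NM"), sum(x$samples$group == "PC")))
  invisible(x)
}

#' Per-feature discriminative AUC screen
#'
#' Computes one AUC per feature (direction `"auto"`: the orientation with
#' AUC >= 0.5 is reported together with the resolved direction) from the
#' log10 abundances and the NM/PC sample labels.
#'
#' @param table a [feature_table()].
#' @return data.frame: `feature_id`, `mz`, `rt_min`, `mode`, `auc`,
#'   `direction`.
#' @export
feature_auc_screen <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  g <- table$samples$group
  res <- lapply(seq_len(nrow(table$features)), function(i) {
    a <- .auc_auto(table$log_areas[i, ], g)
    data.frame(auc = a$auc, direction = a$direction)
  })
  cbind(table$features[, c("feature_id", "mz", "rt_min", "mode")],
        do.call(rbind, res))
}

#' Parts-per-million mass error
#'
#' `|mz_a - mz_b| / mz_a * 1e6`; the first argument is the reference mass
#' (by convention the human feature), a fixed choice that keeps matching
#' deterministic — at a 10 ppm tolerance the asymmetry is negligible.
#'
#' @param mz_a,mz_b positive mass-to-charge ratios; vectorized.
#' @return ppm error(s).
#' @export
ppm_error <- function(mz_a, mz_b) {
  if (any(mz_a <= 0) || any(mz_b <= 0)) stop("m/z must be positive", call. = FALSE)
  abs(mz_a - mz_b) / mz_a * 1e6
}

#' Match candidate features across species by mass and retention time
#'
#' Core matcher over pre-screened candidate data.frames (columns
#' `feature_id`, `mz`, `rt_min`, `mode`, `auc`). All cross pairs with equal
#' ionization mode, ppm error within `ppm_tol` (human mass as reference) and
#' retention-time difference within `rt_tol_min` are candidates; a greedy
#' one-to-one assignment by ascending ppm error (ties broken by smaller rt
#' difference, then feature ids) pairs each human feature with at most one
#' mouse feature. Result is independent of input row order.
#'
#' @param human,mouse candidate data.frames as above.
#' @param ppm_tol mass tolerance in ppm (default 10).
#' @param rt_tol_min retention-time tolerance in minutes (default 0.1).
#' @return data.frame of matches: ids, masses, rts, mode, `ppm_error`,
#'   `rt_delta`, `human_auc`, `mouse_auc`. Zero rows is a valid result.
#' @export
match_candidates <- function(human, mouse, ppm_tol = 10, rt_tol_min = 0.1) {
  empty <- data.frame(human_id = character(), mouse_id = character(),
                      mode = character(),
                      human_mz = numeric(), mouse_mz = numeric(),
                      human_rt = numeric(), mouse_rt = numeric(),
                      ppm_error = numeric(), rt_delta = numeric(),
                      human_auc = numeric(), mouse_auc = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(human) == 0L || nrow(mouse) == 0L) return(empty)
  cand <- expand.grid(h = seq_len(nrow(human)), m = seq_len(nrow(mouse)))
  cand <- cand[human$mode[cand$h] == mouse$mode[cand$m], , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  ppm <- ppm_error(human$mz[cand$h], mouse$mz[cand$m])
  drt <- abs(human$rt_min[cand$h] - mouse$rt_min[cand$m])
  ok <- ppm <= ppm_tol & drt <= rt_tol_min
  cand <- cand[ok, , drop = FALSE]
  ppm <- ppm[ok]
  drt <- drt[ok]
  if (nrow(cand) == 0L) return(empty)
  ord <- order(ppm, drt,
               as.character(human$feature_id[cand$h]),
               as.character(mouse$feature_id[cand$m]))
  cand <- cand[ord, , drop = FALSE]
  ppm <- ppm[ord]
  drt <- drt[ord]
  used_h <- logical(nrow(human))
  used_m <- logical(nrow(mouse))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    h <- cand$h[i]
    m <- cand$m[i]
    if (!used_h[h] && !used_m[m]) {
      keep[i] <- TRUE
      used_h[h] <- TRUE
      used_m[m] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  out <- data.frame(human_id = as.character(human$feature_id[cand$h]),
                    mouse_id = as.character(mouse$feature_id[cand$m]),
                    mode = as.character(human$mode[cand$h]),
                    human_mz = human$mz[cand$h],
                    mouse_mz = mouse$mz[cand$m],
                    human_rt = human$rt_min[cand$h],
                    mouse_rt = mouse$rt_min[cand$m],
                    ppm_error = ppm[keep],
                    rt_delta = drt[keep],
                    human_auc = human$auc[cand$h],
                    mouse_auc = mouse$auc[cand$m],
                    stringsAsFactors = FALSE)
  out[order(out$ppm_error, out$rt_delta, out$human_id), , drop = FALSE]
}

#' Identify standard discriminative features shared by human and mouse plasma
#'
#' Screens each species' feature table for discriminative features (AUC at or
#' above the species threshold, direction auto) and matches the survivors
#' across species by accurate mass and retention time via
#' [match_candidates()]. An empty result is valid — e.g. negative-mode data
#' may yield no shared discriminative feature.
#'
#' @param human,mouse [feature_table()] objects.
#' @param ppm_tol mass tolerance in ppm (default 10).
#' @param rt_tol_min retention-time tolerance in minutes (default 0.1).
#' @param human_auc_min,mouse_auc_min screening AUC thresholds
#'   (defaults 0.60 and 0.75).
#' @return data.frame of cross-species matches (see [match_candidates()]).
#' @export
match_features <- function(human, mouse, ppm_tol = 10, rt_tol_min = 0.1,
                           human_auc_min = 0.60, mouse_auc_min = 0.75) {
  stopifnot(inherits(human, "feature_table"), inherits(mouse, "feature_table"))
  if (!any(human$features$mode %in% mouse$features$mode)) {
    stop("feature tables share no ionization mode", call. = FALSE)
  }
  h <- feature_auc_screen(human)
  m <- feature_auc_screen(mouse)
  match_candidates(h[h$auc >= human_auc_min, , drop = FALSE],
                   m[m$auc >= mouse_auc_min, , drop = FALSE],
                   ppm_tol = ppm_tol, rt_tol_min = rt_tol_min)
}

#' Read a non-targeted feature table from delimited text
#'
#' Expected layout: header columns `feature_id`, `mz`, `rt_min`, `mode`
#' followed by one column of log10 abundances per sample. Sample groups are
#' taken from `sample_groups` (named by sample id) or, failing that, from the
#' sample-name prefix before the first underscore (`NM_01` -> `NM`).
#'
#' @param path CSV/TSV file (delimiter sniffed from the header line).
#' @param sample_groups optional named character vector of NM/PC labels.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, sample_groups = NULL) {
  sep <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- c("feature_id", "mz", "rt_min", "mode")
  if (!all(meta_cols %in% names(df))) {
    stop("feature table must have columns: ", paste(meta_cols, collapse = ", "),
         call. = FALSE)
  }
  sample_ids <- setdiff(names(df), meta_cols)
  groups <- if (!is.null(sample_groups)) {
    unname(sample_groups[sample_ids])
  } else {
    sub("_.*$", "", sample_ids)
  }
  feature_table(df[meta_cols],
                as.matrix(df[sample_ids]),
                data.frame(sample_id = sample_ids, group = groups,
                           stringsAsFactors = FALSE))
}

#' Write cross-species matches to CSV
#' @param matches data.frame from [match_features()].
#' @param path output file.
#' @export
write_matches <- function(matches, path) {
  utils::write.csv(matches, path, row.names = FALSE)
  invisible(path)
}
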