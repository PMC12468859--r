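# Rank-based ROC/AUC and threshold confusion metrics. Every downstream stage
# (non-targeted screen, targeted lipid filter, model evaluation) funnels
# through marker_auc(), so it is implemented from scratch and checked against
# a brute-force pairwise oracle in the test suite.

# Core Mann-Whitney statistic: P(score_PC > score_NM) + 0.5 * P(tie),
# computed via midranks. `g` must be the NM/PC factor with both classes
# present and no NAs.
.auc_high <- function(scores, g) {
  n_pos <- sum(g == "PC")
  n_neg <- sum(g == "NM")
  r <- rank(scores)  # midranks handle ties with the 1/2 convention
  (sum(r[g == "PC"]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

.check_scores <- function(scores, labels) {
  g <- as_group(labels)
  if (length(scores) != length(g)) {
    stop("scores and labels must have the same length", call. = FALSE)
  }
  keep <- !is.na(scores) & !is.na(g)
  scores <- scores[keep]
  g <- g[keep]
  if (sum(g == "PC") == 0L) {
    stop("no PC (positive-class) samples with non-missing scores", call. = FALSE)
  }
  if (sum(g == "NM") == 0L) {
    stop("no NM (negative-class) samples with non-missing scores", call. = FALSE)
  }
  list(scores = scores, g = g)
}

#' Area under the ROC curve for a single marker
#'
#' AUC equals the normalized Mann-Whitney U statistic: the probability that a
#' randomly chosen PC sample outranks a randomly chosen NM sample, with ties
#' contributing 1/2. The marker may discriminate in either direction;
#' `direction = "auto"` (the screening default) reports the orientation giving
#' AUC >= 0.5, `"higher_in_PC"` / `"lower_in_PC"` fix it.
#'
#' @param scores numeric marker values (concentration, U/mL, or a model
#'   probability), one per sample. Pairs with missing score or label are
#'   dropped.
#' @param labels group labels, values in \{"NM", "PC"\}.
#' @param direction one of `"auto"`, `"higher_in_PC"`, `"lower_in_PC"`.
#' @return a single AUC in \[0, 1\] (in \[0.5, 1\] under `"auto"`).
#' @examples
#' marker_auc(c(1, 2, 3, 4, 5, 6), rep(c("NM", "PC"), each = 3),
#'            direction = "higher_in_PC")  # 1: perfect separation
#' @export
marker_auc <- function(scores, labels,
                       direction = c("auto", "higher_in_PC", "lower_in_PC")) {
  direction <- match.arg(direction)
  d <- .check_scores(scores, labels)
  a <- .auc_high(d$scores, d$g)
  switch(direction,
         higher_in_PC = a,
         lower_in_PC  = 1 - a,
         auto         = max(a, 1 - a))
}

# Resolve the orientation of a marker: which direction gives AUC >= 0.5.
# Returns both the oriented AUC and the resolved direction; ties (AUC exactly
# 0.5) resolve to "higher_in_PC".
.auc_auto <- function(scores, labels) {
  d <- .check_scores(scores, labels)
  a <- .auc_high(d$scores, d$g)
  if (a >= 0.5) {
    list(auc = a, direction = "higher_in_PC")
  } else {
    list(auc = 1 - a, direction = "lower_in_PC")
  }
}

#' Empirical ROC curve
#'
#' Sweeps every distinct score value as a cutoff (after orienting scores so
#' that larger means more PC-like under the resolved direction) and records
#' sensitivity and specificity. The curve starts at (0, 0) and ends at (1, 1)
#' in (1 - specificity, sensitivity) space; its trapezoidal area equals
#' [marker_auc()] exactly, including the tie-credit of 1/2.
#'
#' @inheritParams marker_auc
#' @return object of class `roc_curve`: list with `thresholds` (leading `Inf`
#'   gives the (0, 0) corner), `sensitivity`, `specificity`, `auc`, and
#'   `resolved_direction`.
#' @export
roc_curve <- function(scores, labels,
                      direction = c("auto", "higher_in_PC", "lower_in_PC")) {
  direction <- match.arg(direction)
  d <- .check_scores(scores, labels)
  a_high <- .auc_high(d$scores, d$g)
  resolved <- switch(direction,
                     higher_in_PC = "higher_in_PC",
                     lower_in_PC  = "lower_in_PC",
                     auto         = if (a_high >= 0.5) "higher_in_PC" else "lower_in_PC")
  s <- if (resolved == "higher_in_PC") d$scores else -d$scores
  pos <- s[d$g == "PC"]
  neg <- s[d$g == "NM"]
  cuts <- sort(unique(s), decreasing = TRUE)
  sens <- vapply(cuts, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(cuts, function(t) mean(neg < t), numeric(1))
  thresholds <- c(Inf, cuts)
  sens <- c(0, sens)
  spec <- c(1, spec)
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
  structure(list(thresholds = if (resolved == "higher_in_PC") thresholds else -thresholds,
                 sensitivity = sens,
                 specificity = spec,
                 auc = auc,
                 resolved_direction = resolved),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d thresholds, AUC = %.4f (direction: %s)\n",
              length(x$thresholds), x$auc, x$resolved_direction))
  invisible(x)
}

#' Confusion matrix and derived metrics at a fixed cutoff
#'
#' Dichotomizes a marker at `cutoff` and tabulates it against the NM/PC
#' labels. Used both for CA19-9 at its 37 U/mL clinical cutoff and for model
#' probabilities at 0.5. Undefined ratios (0/0 in PPV/NPV, or sensitivity
#' with no positives) are reported as `NA`, never silently as 0.
#'
#' @inheritParams marker_auc
#' @param cutoff finite score cutoff, in the units of `scores`.
#' @param positive_if `"ge"` calls a sample PC when `score >= cutoff`,
#'   `"le"` when `score <= cutoff`.
#' @return object of class `confusion_summary`: cutoff, tp/fp/tn/fn counts,
#'   sensitivity, specificity, ppv, npv.
#' @export
confusion_at_cutoff <- function(scores, labels, cutoff,
                                positive_if = c("ge", "le")) {
  positive_if <- match.arg(positive_if)
  if (!is.finite(cutoff)) stop("cutoff must be finite", call. = FALSE)
  g <- as_group(labels)
  keep <- !is.na(scores) & !is.na(g)
  scores <- scores[keep]
  g <- g[keep]
  pred_pc <- if (positive_if == "ge") scores >= cutoff else scores <= cutoff
  tp <- sum(pred_pc & g == "PC")
  fp <- sum(pred_pc & g == "NM")
  fn <- sum(!pred_pc & g == "PC")
  tn <- sum(!pred_pc & g == "NM")
  structure(list(cutoff = cutoff,
                 positive_if = positive_if,
                 tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = safe_ratio(tp, tp + fn),
                 specificity = safe_ratio(tn, tn + fp),
                 ppv = safe_ratio(tp, tp + fp),
                 npv = safe_ratio(tn, tn + fn)),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("cutoff %.4g (%s): tp %d fp %d tn %d fn %d | sens %.3f spec %.3f ppv %.3f npv %.3f\n",
              x$cutoff, x$positive_if, x$tp, x$fp, x$tn, x$fn,
              x$sensitivity, x$specificity, x$ppv, x$npv))
  invisible(x)
}

# serialize for the pipeline JSON report
.confusion_as_list <- function(x) {
  x[c("cutoff", "positive_if", "tp", "fp", "tn", "fn",
      "sensitivity", "specificity", "ppv", "npv")]
}
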