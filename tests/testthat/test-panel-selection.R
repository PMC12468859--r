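# Three-set concordance filter: the packaged reference AUC table replayed
# through the threshold filter, Venn accounting, batch flagging, platform
# restriction and covariate correlations.

test_that("the reference AUC table yields 20 passing lipids, 18 of them
           phospholipids, with CA19-9 kept as covariate", {
  ref <- reference_panel_aucs()
  expect_identical(nrow(ref), 21L)
  sel <- select_from_auc_records(ref, threshold = 0.75)
  expect_identical(length(sel$passing), 20L)
  expect_identical(as.integer(table(sel$records$platform[
    sel$records$pass_a & sel$records$pass_b & sel$records$pass_c])[
      c("acylcarnitine", "sphingolipid", "phospholipid")]),
    c(1L, 1L, 18L))
  expect_identical(length(sel$selected_panel), 18L)
  expect_identical(sel$selected_platform, "phospholipid")
  # ordering: descending pooled AUC, top and bottom fixed
  expect_identical(sel$selected_panel[1], "PE(20:4/20:4)")
  expect_identical(sel$selected_panel[18], "LysoPC(20:3)")
  # CA19-9 passes only in cohort A and never joins the panel
  cov <- sel$covariate_record
  expect_true(cov$pass_a)
  expect_false(cov$pass_b)
  expect_false(cov$pass_c)
  expect_false("CA19-9" %in% sel$selected_panel)
  # known row: the decanoyl carnitine passes everywhere
  c10 <- sel$records[sel$records$name == "C10-carnitine", ]
  expect_equal(unlist(c10[c("auc_a", "auc_b", "auc_c")], use.names = FALSE),
               c(0.8264, 0.8564, 0.8462))
})

test_that("Venn regions partition the lipid set and match brute force", {
  set.seed(14)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    pa <- sample(c(TRUE, FALSE), n, replace = TRUE)
    pb <- sample(c(TRUE, FALSE), n, replace = TRUE)
    pc <- sample(c(TRUE, FALSE), n, replace = TRUE)
    vr <- venn_regions(pa, pb, pc)
    expect_identical(sum(vr), n)
    # brute-force region assignment per lipid
    expect_identical(vr[["abc"]], sum(pa & pb & pc))
    expect_identical(vr[["a_only"]], sum(pa & !pb & !pc))
    expect_identical(vr[["bc"]], sum(!pa & pb & pc))
    expect_identical(vr[["none"]], sum(!pa & !pb & !pc))
  }
  expect_identical(venn_regions(rep(TRUE, 4), rep(TRUE, 4), rep(TRUE, 4))[["abc"]],
                   4L)
  expect_identical(venn_regions(rep(FALSE, 3), rep(FALSE, 3),
                                rep(FALSE, 3))[["none"]], 3L)
})

test_that("a lipid passing both cohorts but failing the pooled set is
           batch-flagged", {
  recs <- data.frame(name = c("x", "y"), platform = "phospholipid",
                     auc_a = c(0.80, 0.80), auc_b = c(0.80, 0.80),
                     auc_c = c(0.74, 0.80))
  sel <- select_from_auc_records(recs)
  expect_identical(sel$batch_flagged, "x")
  expect_identical(sel$selected_panel, "y")
})

test_that("raising the threshold never increases pass counts", {
  ref <- reference_panel_aucs()
  thresholds <- c(0.70, 0.75, 0.80, 0.85, 0.90)
  passing <- vapply(thresholds, function(t) {
    length(select_from_auc_records(ref, threshold = t)$passing)
  }, integer(1))
  expect_true(all(diff(passing) <= 0))
  triple <- vapply(thresholds, function(t) {
    select_from_auc_records(ref, threshold = t)$venn_counts[["abc"]]
  }, integer(1))
  expect_true(all(diff(triple) <= 0))
})

test_that("platform restriction keeps the modal platform in sorted order", {
  recs <- data.frame(name = c("b", "a", "c", "z"),
                     platform = c("phospholipid", "phospholipid",
                                  "phospholipid", "sphingolipid"),
                     auc_c = c(0.80, 0.90, 0.80, 0.99))
  out <- restrict_to_majority_platform(recs)
  expect_identical(out$name, c("a", "b", "c"))  # desc AUC, name tie-break
  tie <- data.frame(name = c("a", "b"),
                    platform = c("phospholipid", "sphingolipid"),
                    auc_c = c(0.8, 0.9))
  expect_error(restrict_to_majority_platform(tie), "tie")
  expect_error(restrict_to_majority_platform(recs[0, ]), "no passing")
})

test_that("data-driven selection recovers AUC triplets for shared lipids", {
  set.seed(77)
  group_a <- rep(c("NM", "PC"), each = 60)
  group_b <- rep(c("NM", "PC"), each = 60)
  mk <- function(group, d) {
    conc <- exp(cbind(rnorm(120) + d * (group == "PC"),
                      rnorm(120),
                      rnorm(120) - 2 * (group == "PC")))
    colnames(conc) <- c("strong_down_wait", "null", "strong")
    conc
  }
  pa <- make_panel(mk(group_a, -2), group_a, cohort = "A",
                   ca199 = exp(rnorm(120) + (group_a == "PC")))
  pb <- make_panel(mk(group_b, -2), group_b, cohort = "B",
                   ca199 = exp(rnorm(120) + (group_b == "PC")))
  sel <- auc_by_set(pa, pb, threshold = 0.75)
  recs <- sel$records
  expect_identical(nrow(recs), 3L)
  expect_true(all(recs$name[recs$pass_a & recs$pass_b & recs$pass_c] %in%
                    c("strong", "strong_down_wait")))
  expect_false(recs$pass_c[recs$name == "null"])
  expect_identical(recs$direction[recs$name == "strong"], "lower_in_PC")
  # pooled AUC sits between the per-cohort AUCs for a shift-free lipid
  strong <- recs[recs$name == "strong", ]
  expect_gte(strong$auc_c, min(strong$auc_a, strong$auc_b) - 0.02)
  expect_lte(strong$auc_c, max(strong$auc_a, strong$auc_b) + 0.02)
})

test_that("covariate correlations hit the exact poles and a null bound", {
  group <- rep(c("NM", "PC"), each = 5)
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  panel <- make_panel(cbind(anti = 11 - x, self = x, flat = rep(1, 10)),
                      group, ca199 = x)
  r <- marker_covariate_correlation(panel)
  expect_equal(unname(r["anti"]), -1)
  expect_equal(unname(r["self"]), 1)
  expect_true(is.na(r["flat"]))
  # independent lipid and covariate, n = 340: weak correlation w.h.p.
  set.seed(15)
  g2 <- rep(c("NM", "PC"), each = 170)
  p2 <- make_panel(matrix(exp(rnorm(340)), ncol = 1), g2,
                   ca199 = exp(rnorm(340)))
  expect_lt(abs(marker_covariate_correlation(p2)[1]), 0.15)
  # rank-based option is invariant to monotone distortion
  p3 <- make_panel(cbind(a = exp(x)), group, ca199 = x)
  expect_equal(unname(marker_covariate_correlation(p3, method = "spearman")["a"]),
               1)
})
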