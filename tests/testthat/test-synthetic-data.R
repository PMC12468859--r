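# The generator: shapes, determinism, analytic AUC calibration, coupling
# structure, stage plan and the packaged reference fixtures.

test_that("default configuration emits the documented cohort shapes", {
  sim <- generate_panel(seed = 1)
  expect_identical(dim(sim$panel_a$concentrations), c(173L, 102L))
  expect_identical(dim(sim$panel_b$concentrations), c(180L, 102L))
  expect_identical(as.integer(table(sim$panel_a$samples$group)[c("NM", "PC")]),
                   c(70L, 103L))
  expect_identical(as.integer(table(sim$panel_b$samples$group)[c("NM", "PC")]),
                   c(100L, 80L))
  expect_identical(unname(platform_census(sim$panel_a)), c(13L, 13L, 12L, 64L))
  # ground truth is aligned with the roster and self-consistent
  gt <- sim$ground_truth
  expect_identical(gt$name, sim$panel_a$lipids$name)
  expect_equal(gt$auc_a_analytic, pnorm(abs(gt$d_a) / sqrt(2)))
  expect_identical(sum(gt$batch), 4L)
  expect_identical(sum(gt$coupled), 20L)
  # planted panel lipids are all lower in PC
  expect_true(all(gt$d_a[gt$coupled] < 0))
})

test_that("same seed reproduces byte-identical panels, different seeds only
           reshuffle values", {
  s1 <- generate_panel(seed = 9)
  s2 <- generate_panel(seed = 9)
  expect_identical(s1$panel_a$concentrations, s2$panel_a$concentrations)
  expect_identical(s1$panel_b$samples, s2$panel_b$samples)
  s3 <- generate_panel(seed = 10)
  expect_false(identical(s1$panel_a$concentrations, s3$panel_a$concentrations))
  expect_identical(dim(s1$panel_a$concentrations),
                   dim(s3$panel_a$concentrations))
  # generation does not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(generate_panel(seed = 11)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("planted shifts reproduce the analytic normal-shift AUC", {
  cfg <- synth_config(n_nm = c(A = 200, B = 10), n_pc = c(A = 200, B = 10))
  sim <- generate_panel(cfg, seed = 21)
  panel <- sim$panel_a
  g <- panel$samples$group
  # a strongly planted lipid: the top reference phospholipid (analytic 0.90)
  top <- "PE(20:4/20:4)"
  expect_equal(marker_auc(panel$concentrations[, top], g),
               0.90, tolerance = 0.03)
  # null lipids stay near 0.5 at default n
  nulls <- sim$ground_truth$name[sim$ground_truth$d_a == 0][1:10]
  aucs <- vapply(nulls, function(nm) {
    marker_auc(panel$concentrations[, nm], g)
  }, numeric(1))
  expect_true(all(aucs >= 0.40 & aucs <= 0.65))
})

test_that("a planted d = -2 lipid hits pnorm(sqrt(2)) at n = 200/200", {
  cfg <- synth_config(n_nm = c(A = 200, B = 10), n_pc = c(A = 200, B = 10))
  cfg$effects["LysoPE(16:0)", c("d_a", "d_b")] <- -2
  sim <- generate_panel(cfg, seed = 22)
  a <- marker_auc(sim$panel_a$concentrations[, "LysoPE(16:0)"],
                  sim$panel_a$samples$group)
  expect_equal(a, pnorm(2 / sqrt(2)), tolerance = 0.03)
})

test_that("coupled lipids correlate weakly and negatively with CA19-9", {
  cfg <- synth_config(n_nm = c(A = 2000, B = 10), n_pc = c(A = 2000, B = 10))
  sim <- generate_panel(cfg, seed = 23)
  panel <- sim$panel_a
  coupled <- sim$ground_truth$name[sim$ground_truth$coupled]
  r <- marker_covariate_correlation(panel)[coupled]
  expect_true(all(r < 0))
  expect_lt(max(abs(r)), 0.2)
  expect_gt(max(abs(r)), 0)
})

test_that("PC stage labels are stage-I dominated and match the planted plan
           after exclusion", {
  sim <- generate_panel(seed = 24)
  ea <- apply_exclusions(sim$panel_a)$panel
  eb <- apply_exclusions(sim$panel_b)$panel
  stage_a <- table(ea$samples$stage[ea$samples$group == "PC"])
  expect_identical(as.integer(stage_a[c("I", "II", "III", "IV")]),
                   c(84L, 6L, 6L, 6L))
  stage_b <- table(eb$samples$stage[eb$samples$group == "PC"])
  expect_identical(as.integer(stage_b[c("I", "II", "III", "IV")]),
                   c(54L, 9L, 10L, 5L))
  expect_true(all(is.na(ea$samples$stage[ea$samples$group == "NM"])))
})

test_that("CA19-9 is higher in PC with ~0.75 discrimination and ~50%
           sensitivity at 37 U/mL", {
  cfg <- synth_config(n_nm = c(A = 2000, B = 10), n_pc = c(A = 2000, B = 10))
  sim <- generate_panel(cfg, seed = 25)
  s <- sim$panel_a$samples
  expect_equal(marker_auc(s$ca199, s$group, "higher_in_PC"), 0.75,
               tolerance = 0.03)
  sens <- mean(s$ca199[s$group == "PC"] >= 37)
  expect_equal(sens, 0.5, tolerance = 0.04)
})

test_that("non-targeted generator plants matchable features among distant
           decoys", {
  sim <- generate_nontargeted(n_decoys = 100, seed = 26)
  expect_identical(nrow(sim$human$features), 108L)
  expect_identical(nrow(sim$mouse$features), 108L)
  expect_identical(nrow(sim$human$samples), 202L)
  expect_identical(nrow(sim$mouse$samples), 29L)
  # decoys are at least 50 ppm from every planted mass
  planted_mz <- sim$ground_truth$human_mz
  decoy_mz <- sim$human$features$mz[grepl("decoy", sim$human$features$feature_id)]
  min_ppm <- vapply(decoy_mz, function(m) {
    min(abs(m - planted_mz) / planted_mz * 1e6)
  }, numeric(1))
  expect_gt(min(min_ppm), 50)
  # zero planted, zero decoys: empty but valid
  empty <- generate_nontargeted(planted = cross_species_reference()[0, ],
                                n_decoys = 0, seed = 27)
  expect_identical(nrow(empty$human$features), 0L)
  # determinism
  again <- generate_nontargeted(n_decoys = 100, seed = 26)
  expect_identical(again$human$log_areas, sim$human$log_areas)
})

test_that("the packaged fixtures carry the documented structure", {
  ref <- reference_panel_aucs()
  expect_identical(nrow(ref), 21L)
  expect_identical(sum(ref$covariate), 1L)
  expect_identical(sum(ref$platform == "phospholipid", na.rm = TRUE), 18L)
  expect_identical(sum(ref$quant_type == "relative", na.rm = TRUE), 6L)
  c10 <- ref[ref$name == "C10-carnitine", ]
  expect_equal(c(c10$auc_a, c10$auc_b, c10$auc_c), c(0.8264, 0.8564, 0.8462))
  expect_equal(c(c10$q1, c10$q3, c10$rt_min), c(316.4, 84.9, 4.16))
  ca <- ref[ref$covariate, ]
  expect_equal(c(ca$auc_a, ca$auc_b, ca$auc_c), c(0.7571, 0.7356, 0.7489))
})
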