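# Synthetic plasma-lipidome generator. Emits targeted lipid panel tables for
# two human cohorts (A and B) and non-targeted feature tables for human and
# mouse plasma with the statistical structure the analysis pipeline assumes:
# log-normal concentrations with planted standardized group shifts (so each
# marker's analytic AUC is pnorm(|d| / sqrt(2))), a cohort-level
# concentration-range (batch) shift in one platform, a latent CA19-9 with
# weak negative coupling to the discriminative lipids, planned missingness,
# and stage labels dominated by stage I. Ground truth is returned beside
# every dataset so recovery tests can compare against what was planted.

#' The default 102-analyte targeted lipid roster
#'
#' 13 acylcarnitines, 13 fatty acid amides, 12 sphingolipids and 64
#' phospholipids (6 of them relatively quantified). Analyte names follow the
#' usual shorthand of targeted lipidomics (acyl chain composition; `P-` for
#' plasmalogens); MRM transitions and retention times for analytes without a
#' published reference are formula-generated placeholders — illustrative, not
#' instrument values.
#'
#' @return data.frame: `name`, `platform`, `q1`, `q3`, `rt_min`,
#'   `quant_type`.
#' @export
default_lipid_roster <- function() {
  acyl <- c("Acetylcarnitine", "C3-carnitine", "C4-carnitine", "C5-carnitine",
            "C6-carnitine", "C8-carnitine", "C10-carnitine", "C12-carnitine",
            "C14-carnitine", "Palmitoylcarnitine", "C18-carnitine",
            "C18:1-carnitine", "C18:2-carnitine")
  faa <- c("Linoleamide", "Oleamide", "Palmitamide", "Mystamide",
           "Stearamide", "Erucamide", "Myristoyl EA", "Arachidonoyl EA",
           "EPA EA", "Palmitoyl EA", "Oleoyl EA", "Linoleoyl EA",
           "Stearoyl EA")
  sphingo <- c("C14 Ceramide", "C16 Ceramide", "C17 Ceramide", "C18 Ceramide",
               "C18:1 Ceramide", "C20 Ceramide", "C22 Ceramide",
               "C24 Ceramide", "C24:1 Ceramide", "Sphingosine", "Sphinganine",
               "SM(d18:1/16:0)")
  ref <- reference_panel_aucs()
  ref_pl <- ref$name[!ref$covariate & ref$platform == "phospholipid"]
  extra_pl <- c("PC(12:0/12:0)", "PE(14:0/14:0)", "PE(18:2/18:2)",
                "PE(22:6/22:6)", "PC(16:0/16:0)", "PC(P-18:0/20:4)",
                "LysoPC(14:0)", "LysoPC(16:0)", "LysoPC(16:1)",
                "LysoPC(17:0)", "LysoPC(18:0)", "LysoPC(18:1)",
                "LysoPC(20:0)", "LysoPC(20:1)", "LysoPC(20:4)",
                "LysoPC(22:4)", "PC(14:0/16:0)", "PC(15:0/18:1)",
                "PC(16:0/16:1)", "PC(16:0/18:1)", "PC(16:0/20:4)",
                "PC(16:0/20:5)", "PC(16:0/22:5)", "PC(18:0/18:1)",
                "PC(18:0/18:2)", "PC(18:0/20:4)", "PC(18:1/18:2)",
                "PC(18:2/18:2)", "PC(P-16:0/18:1)", "PC(P-16:0/20:4)",
                "PC(P-18:0/18:1)", "PE(16:0/18:1)", "PE(16:0/18:2)",
                "PE(16:0/20:4)", "PE(16:0/22:6)", "PE(18:0/18:1)",
                "PE(18:0/18:2)", "PE(18:0/20:4)", "PE(18:0/22:6)",
                "PE(18:1/18:1)", "PE(P-16:0/18:1)", "PE(P-16:0/22:6)",
                "PE(P-18:0/18:1)", "LysoPE(16:0)", "LysoPE(18:0)",
                "LysoPE(18:2)")
  name <- c(acyl, faa, sphingo, ref_pl, extra_pl)
  platform <- c(rep("acylcarnitine", length(acyl)),
                rep("fatty_acid_amide", length(faa)),
                rep("sphingolipid", length(sphingo)),
                rep("phospholipid", length(ref_pl) + length(extra_pl)))
  roster <- data.frame(name = name, platform = platform,
                       q1 = NA_real_, q3 = NA_real_, rt_min = NA_real_,
                       quant_type = "absolute", stringsAsFactors = FALSE)
  # published transitions where available, placeholders elsewhere
  i <- match(ref$name, roster$name)
  ok <- !is.na(i)
  roster$q1[i[ok]] <- ref$q1[ok]
  roster$q3[i[ok]] <- ref$q3[ok]
  roster$rt_min[i[ok]] <- ref$rt_min[ok]
  roster$quant_type[i[ok]] <- ref$quant_type[ok]
  filler <- is.na(roster$q1)
  k <- seq_len(sum(filler))
  roster$q1[filler] <- round(250 + 6.1 * k, 1)
  roster$q3[filler] <- round(120 + 2.3 * k, 1)
  roster$rt_min[filler] <- round(0.5 + (k %% 23) * 0.45, 2)
  rownames(roster) <- NULL
  roster
}

# fixture-ordered names of the 18 reference phospholipids (descending pooled
# AUC) — used to anchor the default planted panel
.reference_phospholipids <- function() {
  ref <- reference_panel_aucs()
  ref <- ref[!ref$covariate & ref$platform == "phospholipid", ]
  ref$name[order(-ref$auc_c)]
}

#' Generator configuration for the synthetic targeted cohorts
#'
#' The defaults define the study conditions emulated by the generator:
#' cohort A with 70 NM + 103 PC and cohort B with 100 NM + 80 PC samples over
#' the 102-analyte roster; 18 phospholipids planted with standardized log-scale
#' shifts spanning analytic AUCs 0.90 down to 0.76 (all lower in PC), one
#' acylcarnitine and one ceramide planted at 0.85; four acylcarnitines
#' discriminative within each cohort but carrying the platform batch shift;
#' three fatty acid amides discriminative only in cohort A (higher in PC) and
#' six analytes discriminative only in cohort B; CA19-9 log-normal, higher in
#' PC, with analytic AUC ~0.75 and ~50% sensitivity at 37 U/mL; weak negative
#' lipid-CA19-9 coupling (0.10 on the latent log scale) for the planted panel
#' analytes; within-platform equicorrelation 0.3; and the planned missingness
#' that the exclusion rules consume (one whole-platform PC failure in A,
#' missing CA19-9 for 2 NM in A and 4 NM + 2 PC in B, sporadic missingness in
#' 4 analytes in A and 6 in B). PC stage labels reproduce the reference stage
#' tables exactly among the samples that survive exclusion.
#'
#' @param n_nm,n_pc named vectors `c(A = , B = )` of group sizes per cohort.
#' @param roster lipid metadata (default [default_lipid_roster()]).
#' @param panel_auc_range analytic AUC span of the planted phospholipid
#'   panel, descending (default `c(0.90, 0.76)`).
#' @param batch_shift log-scale location shift applied to cohort B's
#'   acylcarnitines (default -3: B measured in a lower concentration range).
#' @param batch_exempt acylcarnitines exempt from the shift (default
#'   C10-carnitine).
#' @param coupling latent coupling of planted panel analytes to CA19-9
#'   (default 0.10; enters negatively).
#' @param equicorrelation within-platform equicorrelation of the latent log
#'   concentrations (default 0.3).
#' @param ca199 list of log-normal CA19-9 parameters per group.
#' @param seed default seed used when [generate_panel()] is not given one.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_nm = c(A = 70, B = 100),
                         n_pc = c(A = 103, B = 80),
                         roster = default_lipid_roster(),
                         panel_auc_range = c(0.90, 0.76),
                         batch_shift = -3,
                         batch_exempt = "C10-carnitine",
                         coupling = 0.10,
                         equicorrelation = 0.3,
                         ca199 = list(meanlog_nm = 2.45, sdlog_nm = 1.0,
                                      meanlog_pc = log(37), sdlog_pc = 1.4),
                         seed = 20201L) {
  if (any(c(n_nm, n_pc) < 2)) stop("group sizes must be >= 2", call. = FALSE)
  if (abs(coupling) >= 1) stop("|coupling| must be < 1", call. = FALSE)
  if (equicorrelation < 0 || equicorrelation >= 1) {
    stop("equicorrelation must be in [0, 1)", call. = FALSE)
  }

  L <- nrow(roster)
  effects <- data.frame(name = roster$name, platform = roster$platform,
                        d_a = 0, d_b = 0, coupled = FALSE, batch = FALSE,
                        stringsAsFactors = FALSE)
  rownames(effects) <- effects$name
  d_of <- function(auc) -stats::qnorm(auc) * sqrt(2)  # negative: lower in PC

  panel_pl <- .reference_phospholipids()
  theta <- seq(panel_auc_range[1], panel_auc_range[2], length.out = length(panel_pl))
  effects[panel_pl, "d_a"] <- d_of(theta)
  effects[panel_pl, "d_b"] <- d_of(theta)
  effects[c("C10-carnitine", "C24 Ceramide"), c("d_a", "d_b")] <- d_of(0.85)
  effects[c("C10-carnitine", "C24 Ceramide", panel_pl), "coupled"] <- TRUE

  batch_lipids <- c("C3-carnitine", "C4-carnitine", "C8-carnitine",
                    "C12-carnitine")
  effects[batch_lipids, c("d_a", "d_b")] <- d_of(0.82)
  effects[batch_lipids, "batch"] <- TRUE

  a_only <- c("Linoleamide", "Oleamide", "Palmitamide")  # higher in PC
  effects[a_only, "d_a"] <- -d_of(0.88)
  effects[a_only, "d_b"] <- -d_of(0.62)
  b_only <- c("PC(16:0/18:1)", "PC(18:0/18:2)", "PE(16:0/20:4)",
              "PE(18:0/22:6)", "SM(d18:1/16:0)", "C16 Ceramide")
  effects[b_only, "d_a"] <- d_of(0.62)
  effects[b_only, "d_b"] <- d_of(0.82)

  # deterministic per-lipid baseline (location is AUC-irrelevant)
  baseline <- 1 + (seq_len(L) - 1) %% 7 * 0.5

  structure(list(
    n_nm = n_nm, n_pc = n_pc, roster = roster, effects = effects,
    baseline = baseline,
    batch_shift = batch_shift, batch_platform = "acylcarnitine",
    batch_exempt = batch_exempt,
    coupling = coupling, equicorrelation = equicorrelation,
    ca199 = ca199,
    # PC stage counts INCLUDING the samples destined for exclusion (which are
    # assigned stage I), so post-exclusion stage tables match the reference;
    # rescaled by largest-remainder-to-stage-I when group sizes change
    stage_counts = list(
      A = .scale_stage_counts(c(I = 85, II = 6, III = 6, IV = 6), n_pc[["A"]]),
      B = .scale_stage_counts(c(I = 56, II = 9, III = 10, IV = 5), n_pc[["B"]])),
    ca199_missing = list(A = c(NM = 2, PC = 0), B = c(NM = 4, PC = 2)),
    platform_failure = list(A = list(platform = "phospholipid", group = "PC",
                                     n = 1),
                            B = NULL),
    sporadic_missing = list(
      A = c("Myristoyl EA", "PC(12:0/12:0)", "PE(14:0/14:0)", "PE(18:2/18:2)"),
      B = c("Myristoyl EA", "Arachidonoyl EA", "EPA EA", "PC(12:0/12:0)",
            "PE(18:2/18:2)", "PE(22:6/22:6)")),
    n_sporadic_samples = 3L,
    seed = as.integer(seed)),
    class = "synth_config")
}

# rescale planted stage counts to a different PC group size, keeping the
# stage-I-dominated profile and exact total
.scale_stage_counts <- function(base, n) {
  if (n == sum(base)) return(base)
  out <- floor(base / sum(base) * n)
  out["I"] <- out["I"] + (n - sum(out))
  out
}

# one cohort's panel; assumes the RNG is already seeded by the caller
.generate_cohort <- function(cohort, config) {
  n_nm <- config$n_nm[[cohort]]
  n_pc <- config$n_pc[[cohort]]
  n <- n_nm + n_pc
  roster <- config$roster
  L <- nrow(roster)
  eff <- config$effects
  d <- if (cohort == "A") eff$d_a else eff$d_b

  group <- c(rep("NM", n_nm), rep("PC", n_pc))
  sample_id <- sprintf("%s_%s_%03d", cohort, group,
                       c(seq_len(n_nm), seq_len(n_pc)))

  # stage labels: NM always NA; PC stages drawn without replacement from the
  # planted counts
  stage <- rep(NA_character_, n)
  sc <- config$stage_counts[[cohort]]
  if (sum(sc) != n_pc) stop("stage counts must sum to the PC group size",
                            call. = FALSE)
  stage[group == "PC"] <- sample(rep(names(sc), sc))

  # latent CA19-9 z-score per sample, realized per-group log-normal
  z_ca <- stats::rnorm(n)
  ca <- config$ca199
  ca199 <- exp(ifelse(group == "PC",
                      ca$meanlog_pc + ca$sdlog_pc * z_ca,
                      ca$meanlog_nm + ca$sdlog_nm * z_ca))

  # latent structure: per-platform common factor + CA19-9 coupling +
  # idiosyncratic noise, weighted to keep unit marginal variance
  rho <- config$equicorrelation
  cvec <- ifelse(eff$coupled, config$coupling, 0)
  w_ca <- -cvec
  w_plat <- sqrt((1 - cvec^2) * rho)
  w_eps <- sqrt((1 - cvec^2) * (1 - rho))
  plats <- unique(roster$platform)
  z_plat <- matrix(stats::rnorm(n * length(plats)), n,
                   dimnames = list(NULL, plats))
  eps <- matrix(stats::rnorm(n * L), n, L)

  shift <- numeric(L)
  if (cohort == "B") {
    shift[roster$platform == config$batch_platform &
          !(roster$name %in% config$batch_exempt)] <- config$batch_shift
  }

  loglip <- matrix(config$baseline, n, L, byrow = TRUE) +
    outer(as.numeric(group == "PC"), d) +
    matrix(shift, n, L, byrow = TRUE) +
    outer(z_ca, w_ca) +
    sweep(z_plat[, roster$platform, drop = FALSE], 2, w_plat, "*") +
    sweep(eps, 2, w_eps, "*")
  conc <- exp(loglip)

  # planned missingness ---------------------------------------------------
  pf <- config$platform_failure[[cohort]]
  plat_fail_idx <- integer(0)
  if (!is.null(pf)) {
    eligible <- which(group == pf$group & stage %in% "I")
    plat_fail_idx <- sample(eligible, pf$n)
    conc[plat_fail_idx, roster$platform == pf$platform] <- NA_real_
  }
  cm <- config$ca199_missing[[cohort]]
  ca_missing_idx <- integer(0)
  for (grp in names(cm)) {
    if (cm[[grp]] > 0) {
      eligible <- setdiff(which(group == grp), plat_fail_idx)
      if (grp == "PC") eligible <- eligible[stage[eligible] %in% "I"]
      ca_missing_idx <- c(ca_missing_idx, sample(eligible, cm[[grp]]))
    }
  }
  ca199[ca_missing_idx] <- NA_real_
  # sporadic missingness lands only on samples that survive the sample-level
  # exclusion rules, so the lipid-level rule always sees it
  survivors <- setdiff(seq_len(n), c(plat_fail_idx, ca_missing_idx))
  if (length(survivors) < config$n_sporadic_samples ||
      !any(group[survivors] == "NM") || !any(group[survivors] == "PC")) {
    stop("missingness plan would remove a whole class", call. = FALSE)
  }
  for (lip in config$sporadic_missing[[cohort]]) {
    j <- match(lip, roster$name)
    if (is.na(j)) stop("sporadic-missing lipid not in roster: ", lip,
                       call. = FALSE)
    conc[sample(survivors, config$n_sporadic_samples), j] <- NA_real_
  }

  lipid_panel(conc, roster,
              data.frame(sample_id = sample_id, group = group,
                         cohort = cohort, stage = stage, ca199 = ca199,
                         stringsAsFactors = FALSE))
}

#' Generate the two synthetic targeted cohorts plus ground truth
#'
#' Fully reproducible from `seed` (same seed, byte-identical panels); the
#' caller's RNG state is untouched.
#'
#' @param config a [synth_config()].
#' @param seed integer seed (default: the config's).
#' @return list of class `synthetic_panels`: `panel_a`, `panel_b`
#'   ([lipid_panel()] objects), `ground_truth` (per-lipid planted shifts,
#'   analytic AUCs `pnorm(|d|/sqrt(2))`, batch/coupling flags), and `config`.
#' @export
generate_panel <- function(config = synth_config(), seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  out <- with_seed(seed, {
    list(panel_a = .generate_cohort("A", config),
         panel_b = .generate_cohort("B", config))
  })
  eff <- config$effects
  gt <- data.frame(name = eff$name, platform = eff$platform,
                   d_a = eff$d_a, d_b = eff$d_b,
                   auc_a_analytic = stats::pnorm(abs(eff$d_a) / sqrt(2)),
                   auc_b_analytic = stats::pnorm(abs(eff$d_b) / sqrt(2)),
                   coupled = eff$coupled, batch = eff$batch,
                   stringsAsFactors = FALSE)
  rownames(gt) <- NULL
  structure(list(panel_a = out$panel_a, panel_b = out$panel_b,
                 ground_truth = gt, config = config, seed = seed),
            class = "synthetic_panels")
}

#' @export
print.synthetic_panels <- function(x, ...) {
  cat("synthetic targeted cohorts (seed ", x$seed, ")\n", sep = "")
  print(x$panel_a)
  print(x$panel_b)
  invisible(x)
}

#' Generate paired human/mouse non-targeted feature tables
#'
#' Plants shared discriminative features (by default the packaged
#' cross-species reference set: same identity, species-specific accurate
#' masses and retention times agreeing within the matching tolerances) among
#' mass-distant decoys, with group shifts sized so each planted feature's
#' analytic AUC matches its reference value (capped at 0.995). Decoy masses
#' are redrawn deterministically until at least `decoy_min_ppm` from every
#' planted mass.
#'
#' @param planted data.frame like [cross_species_reference()]; may have zero
#'   rows.
#' @param n_decoys decoy features per species (default 500).
#' @param n_human,n_mouse named group sizes.
#' @param decoy_min_ppm minimum ppm distance of decoys from planted masses
#'   (default 50).
#' @param seed integer seed.
#' @return list of class `synthetic_features`: `human`, `mouse`
#'   ([feature_table()]s of log10 areas), `ground_truth`.
#' @export
generate_nontargeted <- function(planted = cross_species_reference(),
                                 n_decoys = 500,
                                 n_human = c(NM = 99, PC = 103),
                                 n_mouse = c(NM = 7, PC = 22),
                                 decoy_min_ppm = 50,
                                 seed = 20201L) {
  d_of <- function(auc, pattern) {
    a <- pmin(auc, 0.995)
    stats::qnorm(a) * sqrt(2) * ifelse(pattern == "up", 1, -1)
  }
  make_species <- function(prefix, mz, rt, d, n_by_group) {
    n_feat <- length(mz) + n_decoys
    # decoy masses >= decoy_min_ppm from every planted mass
    draw_decoys <- function(k) stats::runif(k, 150, 900)
    dmz <- draw_decoys(n_decoys)
    if (length(mz) > 0 && n_decoys > 0) {
      repeat {
        too_close <- vapply(dmz, function(m) {
          any(abs(m - mz) / mz * 1e6 < decoy_min_ppm)
        }, logical(1))
        if (!any(too_close)) break
        dmz[too_close] <- draw_decoys(sum(too_close))
      }
    }
    features <- data.frame(
      feature_id = c(sprintf("%s_planted_%02d", prefix, seq_along(mz)),
                     sprintf("%s_decoy_%04d", prefix, seq_len(n_decoys))),
      mz = c(mz, dmz),
      rt_min = c(rt, stats::runif(n_decoys, 0.5, 12)),
      mode = c(rep("positive", length(mz)),
               rep(c("positive", "negative"), length.out = n_decoys)),
      stringsAsFactors = FALSE)
    group <- rep(names(n_by_group), n_by_group)
    n <- length(group)
    shifts <- c(d, rep(0, n_decoys))
    log_areas <- matrix(5 + stats::rnorm(n_feat * n), n_feat, n) +
      outer(shifts, as.numeric(group == "PC"))
    feature_table(features, log_areas,
                  data.frame(sample_id = sprintf("%s_%s_%03d", prefix, group,
                                                 seq_len(n)),
                             group = group, stringsAsFactors = FALSE))
  }
  out <- with_seed(seed, {
    list(human = make_species("hs", planted$human_mz, planted$human_rt,
                              d_of(planted$human_auc, planted$pattern),
                              n_human),
         mouse = make_species("mm", planted$mouse_mz, planted$mouse_rt,
                              d_of(planted$mouse_auc, planted$pattern),
                              n_mouse))
  })
  gt <- planted
  if (nrow(gt) > 0) {
    gt$human_id <- sprintf("hs_planted_%02d", seq_len(nrow(gt)))
    gt$mouse_id <- sprintf("mm_planted_%02d", seq_len(nrow(gt)))
  }
  structure(list(human = out$human, mouse = out$mouse, ground_truth = gt,
                 seed = seed),
            class = "synthetic_features")
}

#' Packaged reference AUC table for the concordance filter
#'
#' The published panel of 20 concordant lipids plus the CA19-9 covariate,
#' with MRM transitions, retention times, quantitation type and the AUCs in
#' cohorts A, B and the pooled set C. Used to replay the simultaneous-pass
#' filter and as the anchor for the generator's planted panel.
#'
#' @return data.frame of 21 rows; `covariate` marks the CA19-9 row.
#' @export
reference_panel_aucs <- function() {
  path <- system.file("extdata", "reference_panel_aucs.csv",
                      package = "lipidscreen", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Packaged cross-species reference features
#'
#' Eight positive-mode metabolomic features discriminative in both human and
#' mouse plasma, with species-specific accurate masses, retention times,
#' per-species AUCs and the direction of change in disease (`up`/`down`
#' versus control).
#'
#' @return data.frame of 8 rows.
#' @export
cross_species_reference <- function() {
  path <- system.file("extdata", "cross_species_features.csv",
                      package = "lipidscreen", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
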