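# Independent oracles and small fixture builders used across the suite.

# Brute-force pairwise AUC: enumerate every (PC, NM) pair, count PC > NM as 1
# and ties as 1/2. Deliberately O(n^2) and rank-free, so it shares nothing
# with the implementation under test.
auc_pair_oracle <- function(pc_scores, nm_scores) {
  total <- 0
  for (p in pc_scores) {
    for (q in nm_scores) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pc_scores) * length(nm_scores))
}

# Reference ridge-penalized logistic regression: BFGS on the penalized
# negative log-likelihood over the same standardized parametrization as
# fit_logistic (intercept unpenalized). Independent of the IRLS path.
logit_reference_std <- function(x, y01, ridge_penalty = 1e-6) {
  x <- as.matrix(x)
  cen <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2, cen), 2, scl, "/")
  X <- cbind(1, xs)
  p <- ncol(xs)
  obj <- function(b) {
    eta <- drop(X %*% b)
    -sum(y01 * eta - log1p(exp(eta))) + ridge_penalty / 2 * sum(b[-1]^2)
  }
  grad <- function(b) {
    mu <- plogis(drop(X %*% b))
    drop(-crossprod(X, y01 - mu)) + ridge_penalty * c(0, b[-1])
  }
  fit <- optim(rep(0, p + 1), obj, grad, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-15))
  fit$par
}

# Minimal lipid panel: concentrations matrix (samples x lipids) with simple
# metadata; platform defaults to phospholipid for every lipid.
make_panel <- function(conc, group, cohort = "A",
                       platform = rep("phospholipid", ncol(conc)),
                       ca199 = rep(10, nrow(conc)),
                       stage = ifelse(group == "PC", "I", NA_character_)) {
  conc <- as.matrix(conc)
  if (is.null(colnames(conc))) {
    colnames(conc) <- sprintf("L%02d", seq_len(ncol(conc)))
  }
  lipid_panel(conc,
              data.frame(name = colnames(conc), platform = platform,
                         stringsAsFactors = FALSE),
              data.frame(sample_id = sprintf("%s_%03d", cohort,
                                             seq_len(nrow(conc))),
                         group = group, cohort = cohort, stage = stage,
                         ca199 = ca199, stringsAsFactors = FALSE))
}

# Small feature table with given per-feature metadata and log10 areas.
make_feature_table <- function(mz, rt, mode, log_areas, group) {
  feature_table(data.frame(feature_id = sprintf("f%03d", seq_along(mz)),
                           mz = mz, rt_min = rt, mode = mode,
                           stringsAsFactors = FALSE),
                log_areas,
                data.frame(sample_id = sprintf("s%03d", seq_along(group)),
                           group = group, stringsAsFactors = FALSE))
}
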