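# Panel modeling: class-stratified 7:3 split, natively implemented
# ridge-penalized logistic regression (IRLS on standardized predictors),
# optional random-forest / RBF-SVM adapters, cumulative marker addition in
# descending pooled-set AUC order with and without the CA19-9 covariate, and
# the plateau-mean summary of the cumulative curve.

#' Class-stratified train/validation split
#'
#' Within each class the training count is round-to-nearest of
#' `train_fraction` times the class size (half-up), so e.g. 164 NM + 180 PC
#' at 0.7 gives 115 + 126 training and 49 + 54 validation samples.
#' Membership is randomized by `seed`; the same seed always reproduces the
#' same split and the caller's RNG state is untouched.
#'
#' @param labels NM/PC labels, one per sample.
#' @param train_fraction fraction assigned to training (default 0.7).
#' @param seed integer seed controlling the assignment.
#' @return list with sorted integer index vectors `train` and `validation`
#'   (disjoint, exhaustive) and a `counts` table.
#' @export
stratified_split <- function(labels, train_fraction = 0.7, seed = 1) {
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  g <- as_group(labels)
  if (any(is.na(g))) stop("labels must be complete", call. = FALSE)
  train <- integer(0)
  with_seed(seed, {
    for (cls in levels(g)) {
      idx <- which(g == cls)
      if (length(idx) < 2L) {
        stop("class ", cls, " has fewer than 2 samples", call. = FALSE)
      }
      n_train <- round_half_up(train_fraction * length(idx))
      n_train <- max(1L, min(length(idx) - 1L, n_train))
      train <- c(train, sample(idx, n_train))
    }
  })
  train <- sort(train)
  validation <- setdiff(seq_along(g), train)
  counts <- c(train_NM = sum(g[train] == "NM"), train_PC = sum(g[train] == "PC"),
              validation_NM = sum(g[validation] == "NM"),
              validation_PC = sum(g[validation] == "PC"))
  list(train = train, validation = validation, counts = counts,
       train_fraction = train_fraction, seed = seed)
}

#' Ridge-penalized logistic regression via IRLS
#'
#' Maximizes the Bernoulli log-likelihood minus `ridge_penalty / 2` times the
#' squared norm of the slope coefficients (intercept unpenalized), on
#' predictors standardized with training-set means and standard deviations.
#' Fitting is iteratively reweighted least squares; convergence when the
#' largest coefficient change drops below `tol` (default 1e-8) or after
#' `max_iter` iterations (warning, best iterate kept and flagged).
#' The tiny default ridge keeps separable problems finite without materially
#' biasing coefficients.
#'
#' @param x numeric predictor matrix (samples x predictors), no missing
#'   values.
#' @param y NM/PC labels (PC is the positive class) or a 0/1 vector.
#' @param ridge_penalty ridge strength on standardized slopes (default 1e-6).
#' @param max_iter,tol IRLS iteration cap and convergence tolerance.
#' @return object of class `panel_logit` with `coefficients` (original
#'   predictor scale), `coefficients_std` (standardized scale), `se`
#'   (delta-method standard errors on the original scale), `center`/`scale`
#'   captured from training data, and a `convergence` record.
#' @export
fit_logistic <- function(x, y, ridge_penalty = 1e-6, max_iter = 100,
                         tol = 1e-8) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("predictors must not contain missing values", call. = FALSE)
  y01 <- if (is.numeric(y) && all(y %in% c(0, 1))) as.numeric(y) else {
    g <- as_group(y)
    if (anyNA(g)) stop("labels must be complete", call. = FALSE)
    as.numeric(g == "PC")
  }
  if (length(y01) != nrow(x)) stop("x and y lengths differ", call. = FALSE)
  if (sum(y01 == 1) < 2L || sum(y01 == 0) < 2L) {
    stop("need at least 2 samples per class", call. = FALSE)
  }
  p <- ncol(x)
  cen <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1  # constant column: standardized to 0, ridge zeroes it
  xs <- sweep(sweep(x, 2, cen), 2, scl, "/")
  X <- cbind(`(Intercept)` = 1, xs)
  pen <- diag(c(0, rep(ridge_penalty, p)), p + 1)
  beta <- rep(0, p + 1)
  converged <- FALSE
  delta <- Inf
  iter <- 0L
  A <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y01 - mu) / w
    A <- crossprod(X, w * X) + pen
    beta_new <- drop(solve(A, crossprod(X, w * z)))
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("IRLS did not converge in ", max_iter,
            " iterations (max coefficient change ", signif(delta, 3), ")",
            call. = FALSE)
  }
  # back-transform to the original predictor scale
  b0 <- beta[1]
  bs <- beta[-1]
  coef_orig <- c(`(Intercept)` = unname(b0 - sum(bs * cen / scl)), bs / scl)
  names(coef_orig)[-1] <- colnames(x) %||% paste0("x", seq_len(p))
  # delta method: coef_orig = T %*% beta_std
  Tm <- diag(c(1, 1 / scl), p + 1)
  Tm[1, -1] <- -cen / scl
  vcov_std <- solve(A)
  vcov_orig <- Tm %*% vcov_std %*% t(Tm)
  se <- sqrt(diag(vcov_orig))
  names(se) <- names(coef_orig)
  structure(list(coefficients = coef_orig,
                 coefficients_std = beta,
                 se = se,
                 center = cen, scale = scl,
                 ridge_penalty = ridge_penalty,
                 convergence = list(converged = converged, iterations = iter,
                                    max_delta = delta)),
            class = "panel_logit")
}

#' @export
print.panel_logit <- function(x, ...) {
  cat(sprintf("panel_logit: %d predictors, ridge %g, %s in %d iterations\n",
              length(x$coefficients) - 1L, x$ridge_penalty,
              if (x$convergence$converged) "converged" else "NOT converged",
              x$convergence$iterations))
  print(x$coefficients)
  invisible(x)
}

#' @export
coef.panel_logit <- function(object, ...) object$coefficients

#' Predict PC probabilities from a fitted panel logit
#'
#' New data are standardized with the training-set center/scale captured at
#' fit time, so probabilities are invariant to affine rescaling of the raw
#' predictors.
#'
#' @param object a `panel_logit`.
#' @param newdata matrix with the same predictor columns as the fit.
#' @param type `"response"` (probability of PC) or `"link"`.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.panel_logit <- function(object, newdata, type = c("response", "link"),
                                ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  eta <- drop(object$coefficients_std[1] + xs %*% object$coefficients_std[-1])
  if (type == "link") eta else stats::plogis(eta)
}

# ---- classifier adapters -------------------------------------------------

# Fit `classifier` on (x, g) and return a function newx -> P(PC).
# LR is native; RF and SVM-RBF are thin adapters behind the same interface
# and require their packages to be installed.
.fit_classifier <- function(x, g, classifier, ridge_penalty = 1e-6) {
  switch(classifier,
    LR = {
      fit <- suppressWarnings(fit_logistic(x, g, ridge_penalty = ridge_penalty))
      function(newx) predict(fit, newx)
    },
    RF = {
      if (!requireNamespace("randomForest", quietly = TRUE)) {
        stop("classifier 'RF' requires the randomForest package", call. = FALSE)
      }
      fit <- randomForest::randomForest(x = x, y = factor(g, c("NM", "PC")))
      function(newx) unname(stats::predict(fit, newx, type = "prob")[, "PC"])
    },
    SVM_RBF = {
      if (!requireNamespace("e1071", quietly = TRUE)) {
        stop("classifier 'SVM_RBF' requires the e1071 package", call. = FALSE)
      }
      fit <- e1071::svm(x = x, y = factor(g, c("NM", "PC")), kernel = "radial",
                        probability = TRUE)
      function(newx) {
        pr <- stats::predict(fit, newx, probability = TRUE)
        unname(attr(pr, "probabilities")[, "PC"])
      }
    },
    stop("unknown classifier: ", classifier, call. = FALSE))
}

# assemble the predictor matrix for a step: top-k panel lipids
# (log10-transformed by default) plus optionally log10 CA19-9
.step_predictors <- function(panel, markers, with_covariate, log_lipids,
                             log_covariate) {
  x <- panel$concentrations[, markers, drop = FALSE]
  if (anyNA(x)) stop("model lipids must be complete after exclusions", call. = FALSE)
  if (log_lipids) {
    if (any(x <= 0)) stop("cannot log-transform non-positive concentrations",
                          call. = FALSE)
    x <- log10(x)
  }
  if (with_covariate) {
    ca <- panel$samples$ca199
    if (anyNA(ca)) stop("CA19-9 must be complete for covariate models",
                        call. = FALSE)
    x <- cbind(x, `CA19-9` = if (log_covariate) log10(ca) else ca)
  }
  x
}

#' Cumulative marker-addition curve
#'
#' Starting from the two top-ranked panel markers, fits the chosen classifier
#' on the training samples, scores the validation samples, and records the
#' validation AUC (direction fixed: higher probability means PC) and a
#' confusion summary at the probability `cutoff`; then adds the next-ranked
#' marker and repeats until the panel is exhausted. When `with_covariate`,
#' CA19-9 (log10 by default) is appended as an extra predictor at every step.
#' Marker subsets are nested by construction: step k uses exactly the k
#' top-ranked markers.
#'
#' @param train,validation disjoint [lipid_panel()] slices over the same
#'   lipids.
#' @param ordered_panel character vector of marker names, descending
#'   pooled-set AUC.
#' @param with_covariate append CA19-9 as a predictor (default FALSE).
#' @param classifier `"LR"` (native), `"RF"` or `"SVM_RBF"` (adapters).
#' @param cutoff probability cutoff for the confusion summary (default 0.5).
#' @param log_lipids,log_covariate log10-transform lipid concentrations /
#'   CA19-9 before fitting (both default TRUE; concentrations span orders of
#'   magnitude).
#' @param ridge_penalty passed to [fit_logistic()] for the LR classifier.
#' @return object of class `cumulative_curve`: `steps` data.frame
#'   (`step` = number of panel markers, `n_predictors`, `auc`, confusion
#'   metrics), plus the marker order and settings.
#' @export
cumulative_curve <- function(train, validation, ordered_panel,
                             with_covariate = FALSE,
                             classifier = c("LR", "RF", "SVM_RBF"),
                             cutoff = 0.5, log_lipids = TRUE,
                             log_covariate = TRUE, ridge_penalty = 1e-6) {
  classifier <- match.arg(classifier)
  stopifnot(inherits(train, "lipid_panel"), inherits(validation, "lipid_panel"))
  if (length(ordered_panel) < 2L) {
    stop("ordered_panel must contain at least 2 markers", call. = FALSE)
  }
  if (length(intersect(train$samples$sample_id,
                       validation$samples$sample_id)) > 0L) {
    stop("training and validation samples overlap", call. = FALSE)
  }
  g_train <- train$samples$group
  g_val <- validation$samples$group
  steps <- lapply(2:length(ordered_panel), function(k) {
    markers <- ordered_panel[1:k]
    x_tr <- .step_predictors(train, markers, with_covariate, log_lipids,
                             log_covariate)
    x_va <- .step_predictors(validation, markers, with_covariate, log_lipids,
                             log_covariate)
    predict_fun <- .fit_classifier(x_tr, g_train, classifier, ridge_penalty)
    prob <- predict_fun(x_va)
    conf <- confusion_at_cutoff(prob, g_val, cutoff, positive_if = "ge")
    data.frame(step = k, n_predictors = ncol(x_tr),
               auc = marker_auc(prob, g_val, direction = "higher_in_PC"),
               sensitivity = conf$sensitivity, specificity = conf$specificity,
               ppv = conf$ppv, npv = conf$npv,
               stringsAsFactors = FALSE)
  })
  structure(list(steps = do.call(rbind, steps),
                 markers = ordered_panel,
                 with_covariate = with_covariate,
                 classifier = classifier,
                 cutoff = cutoff),
            class = "cumulative_curve")
}

#' @export
print.cumulative_curve <- function(x, ...) {
  cat(sprintf("cumulative_curve (%s%s): steps 2..%d\n", x$classifier,
              if (x$with_covariate) " + CA19-9" else "",
              max(x$steps$step)))
  print(x$steps[, c("step", "auc", "sensitivity", "specificity")],
        row.names = FALSE)
  invisible(x)
}

#' Plateau mean of a cumulative curve
#'
#' Arithmetic mean of the validation AUCs over the steps with `first_step`
#' or more markers — for an 18-marker panel and the default `first_step` of
#' 11, the last eight steps, where the curve has typically flattened.
#'
#' @param curve a [cumulative_curve()].
#' @param first_step first step included in the average (default 11).
#' @return mean validation AUC over steps `first_step..max`.
#' @export
plateau_mean <- function(curve, first_step = 11) {
  stopifnot(inherits(curve, "cumulative_curve"))
  if (max(curve$steps$step) < first_step) {
    stop("curve reaches step ", max(curve$steps$step),
         " but plateau starts at ", first_step, call. = FALSE)
  }
  mean(curve$steps$auc[curve$steps$step >= first_step])
}

#' Sensitivity of a covariate at a clinical cutoff, overall and by stage
#'
#' Dichotomizes the covariate at `cutoff` (positive if `>=`) and reports
#' sensitivity overall, within stage-I PC samples, and within stage II-IV PC
#' samples. An empty stratum yields `NA`; input without any PC sample is an
#' error.
#'
#' @param covariate numeric values (e.g. CA19-9 in U/mL).
#' @param labels NM/PC labels.
#' @param stages per-sample stage labels (`"I"`, `"II"`, `"III"`, `"IV"`,
#'   `NA` for NM).
#' @param cutoff positivity cutoff (default 37, the CA19-9 clinical cutoff
#'   in U/mL).
#' @return list with `overall` (a `confusion_summary`), `sensitivity`,
#'   `sensitivity_stage_I`, `sensitivity_stage_II_IV`, and `cutoff`.
#' @export
covariate_cutoff_sensitivity <- function(covariate, labels, stages,
                                         cutoff = 37) {
  g <- as_group(labels)
  if (sum(g == "PC", na.rm = TRUE) == 0L) {
    stop("no PC samples: sensitivity is undefined", call. = FALSE)
  }
  conf <- confusion_at_cutoff(covariate, g, cutoff, positive_if = "ge")
  pc <- which(g == "PC" & !is.na(covariate))
  stage <- as.character(stages)
  sens_in <- function(idx) {
    if (length(idx) == 0L) NA_real_ else mean(covariate[idx] >= cutoff)
  }
  list(overall = conf,
       sensitivity = conf$sensitivity,
       sensitivity_stage_I = sens_in(pc[stage[pc] %in% "I"]),
       sensitivity_stage_II_IV = sens_in(pc[stage[pc] %in% c("II", "III", "IV")]),
       cutoff = cutoff)
}
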