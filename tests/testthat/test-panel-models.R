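# Split arithmetic, the native IRLS logistic regression against its BFGS
# reference, cumulative curves, plateau means and the covariate cutoff.

test_that("stratified split reproduces the 7:3 class counts exactly", {
  labels <- rep(c("NM", "PC"), c(164, 180))
  sp <- stratified_split(labels, 0.7, seed = 4)
  expect_identical(unname(sp$counts),
                   c(115L, 126L, 49L, 54L))
  expect_identical(sort(c(sp$train, sp$validation)), seq_along(labels))
  expect_length(intersect(sp$train, sp$validation), 0)
  # determinism: same seed identical, different seed same counts
  expect_identical(stratified_split(labels, 0.7, seed = 4)$train, sp$train)
  sp2 <- stratified_split(labels, 0.7, seed = 5)
  expect_false(identical(sp2$train, sp$train))
  expect_identical(sp2$counts, sp$counts)
  expect_identical(unname(stratified_split(rep(c("NM", "PC"), each = 10),
                                           0.5, seed = 1)$counts),
                   c(5L, 5L, 5L, 5L))
  expect_error(stratified_split(c("NM", "PC", "PC"), 0.7, 1), "fewer than 2")
  expect_error(stratified_split(labels, 1.2, 1), "train_fraction")
})

test_that("native logistic regression matches the BFGS reference", {
  set.seed(33)
  for (i in 1:8) {
    n <- sample(60:120, 1)
    p <- sample(1:4, 1)
    x <- matrix(rnorm(n * p), n, p)
    beta <- rnorm(p + 1)
    y <- rbinom(n, 1, plogis(beta[1] + x %*% beta[-1]))
    if (sum(y) < 2 || sum(1 - y) < 2) next
    fit <- fit_logistic(x, y, ridge_penalty = 1e-6)
    ref <- logit_reference_std(x, y, ridge_penalty = 1e-6)
    expect_lt(max(abs(fit$coefficients_std - ref)), 1e-4)
  }
})

test_that("separable data give a positive finite slope and training AUC 1", {
  x <- matrix(c(-3, -2, -1, 1, 2, 3), ncol = 1)
  y <- c("NM", "NM", "NM", "PC", "PC", "PC")
  fit <- suppressWarnings(fit_logistic(x, y))
  expect_gt(fit$coefficients[2], 0)
  expect_true(is.finite(fit$coefficients[2]))
  prob <- predict(fit, x)
  expect_true(all(prob > 0 & prob < 1))
  expect_equal(marker_auc(prob, y, "higher_in_PC"), 1)
})

test_that("duplicated predictors under ridge get equal finite coefficients", {
  set.seed(12)
  x1 <- rnorm(80)
  y <- rbinom(80, 1, plogis(1.5 * x1))
  fit <- fit_logistic(cbind(a = x1, b = x1), y, ridge_penalty = 1e-4)
  expect_equal(fit$coefficients[["a"]], fit$coefficients[["b"]],
               tolerance = 1e-8)
  expect_true(all(is.finite(fit$coefficients)))
})

test_that("predictions are invariant to affine rescaling of raw predictors", {
  set.seed(13)
  x <- matrix(rnorm(200), 100, 2)
  y <- rbinom(100, 1, plogis(x[, 1] - x[, 2]))
  fit1 <- fit_logistic(x, y)
  x2 <- sweep(sweep(x, 2, c(10, -3), "*"), 2, c(100, 7), "+")
  fit2 <- fit_logistic(x2, y)
  expect_lt(max(abs(predict(fit1, x) - predict(fit2, x2))), 1e-10)
})

test_that("coefficients recover the generating model within 3 SE", {
  set.seed(41)
  n <- 5000
  x <- matrix(rnorm(2 * n), n, 2)
  truth <- c(-0.5, 1.2, -0.8)
  y <- rbinom(n, 1, plogis(truth[1] + x %*% truth[-1]))
  fit <- fit_logistic(x, y)
  expect_true(all(abs(fit$coefficients - truth) < 3 * fit$se))
})

test_that("missing predictors and single-class labels are rejected", {
  x <- matrix(c(1, NA, 3, 4), 2, 2)
  expect_error(fit_logistic(x, c(0, 1)), "missing")
  expect_error(fit_logistic(matrix(rnorm(8), 4, 2), c(1, 1, 1, 1)),
               "2 samples per class")
})

test_that("cumulative curve is nested, sized k (+1 with covariate) and exact
           on noiseless data", {
  set.seed(55)
  n <- 60
  group <- rep(c("NM", "PC"), each = n / 2)
  # one perfectly separating lipid plus three decoys
  conc <- exp(cbind(sep = 3 - 2 * (group == "PC") + 0 * rnorm(n),
                    d1 = rnorm(n), d2 = rnorm(n), d3 = rnorm(n)))
  panel <- make_panel(conc, group, ca199 = exp(rnorm(n)))
  sp <- stratified_split(group, 0.7, seed = 2)
  train <- lipidscreen:::panel_subset(panel, samples = sp$train)
  val <- lipidscreen:::panel_subset(panel, samples = sp$validation)
  curve <- cumulative_curve(train, val, c("sep", "d1", "d2", "d3"))
  expect_identical(curve$steps$step, 2:4)
  expect_identical(curve$steps$n_predictors, 2:4)
  expect_true(all(curve$steps$auc == 1))
  with_cov <- cumulative_curve(train, val, c("sep", "d1", "d2", "d3"),
                               with_covariate = TRUE)
  expect_identical(with_cov$steps$n_predictors, 3:5)
  expect_error(cumulative_curve(train, train, c("sep", "d1")), "overlap")
  expect_error(cumulative_curve(train, val, "sep"), "at least 2")
})

test_that("RF and SVM adapters run behind the same interface", {
  skip_if_not_installed("randomForest")
  skip_if_not_installed("e1071")
  set.seed(66)
  n <- 80
  group <- rep(c("NM", "PC"), each = n / 2)
  conc <- exp(cbind(a = rnorm(n) - 2 * (group == "PC"),
                    b = rnorm(n) - 1.5 * (group == "PC"),
                    c = rnorm(n)))
  panel <- make_panel(conc, group)
  sp <- stratified_split(group, 0.7, seed = 3)
  train <- lipidscreen:::panel_subset(panel, samples = sp$train)
  val <- lipidscreen:::panel_subset(panel, samples = sp$validation)
  for (clf in c("RF", "SVM_RBF")) {
    curve <- cumulative_curve(train, val, c("a", "b", "c"), classifier = clf)
    expect_identical(nrow(curve$steps), 2L)
    expect_gt(curve$steps$auc[2], 0.7)
  }
})

test_that("plateau mean averages exactly the steps at and after the start", {
  fake <- structure(list(steps = data.frame(
    step = 2:18,
    auc = c(rep(0.8, 9), c(0.90, 0.91, 0.92, 0.92, 0.93, 0.92, 0.93, 0.93)))),
    class = "cumulative_curve")
  expect_equal(plateau_mean(fake, first_step = 11),
               mean(c(0.90, 0.91, 0.92, 0.92, 0.93, 0.92, 0.93, 0.93)))
  expect_length(fake$steps$auc[fake$steps$step >= 11], 8)
  const <- structure(list(steps = data.frame(step = 2:12, auc = 0.9)),
                     class = "cumulative_curve")
  expect_equal(plateau_mean(const), 0.9)
  short <- structure(list(steps = data.frame(step = 2:5, auc = 0.9)),
                     class = "cumulative_curve")
  expect_error(plateau_mean(short), "plateau starts at")
})

test_that("covariate cutoff sensitivity stratifies by stage correctly", {
  # 9-sample table, hand-enumerated: PC stage I {40, 30}, PC II {50, 10, 39},
  # PC III {5}, NM {20, 8, 45}
  ca <- c(40, 30, 50, 10, 39, 5, 20, 8, 45)
  labels <- c(rep("PC", 6), rep("NM", 3))
  stages <- c("I", "I", "II", "II", "II", "III", NA, NA, NA)
  out <- covariate_cutoff_sensitivity(ca, labels, stages, cutoff = 37)
  expect_equal(out$sensitivity, 3 / 6)        # 40, 50, 39 over the cutoff
  expect_equal(out$sensitivity_stage_I, 1 / 2)
  expect_equal(out$sensitivity_stage_II_IV, 2 / 4)
  expect_equal(out$overall$specificity, 2 / 3)  # NM 45 is a false positive
  # all PC above the cutoff
  all_up <- covariate_cutoff_sensitivity(c(50, 60, 10), c("PC", "PC", "NM"),
                                         c("I", "II", NA))
  expect_equal(all_up$sensitivity, 1)
  expect_equal(all_up$sensitivity_stage_I, 1)
  # empty stratum is NA, NM-only input errors
  no_late <- covariate_cutoff_sensitivity(c(50, 10), c("PC", "NM"), c("I", NA))
  expect_true(is.na(no_late$sensitivity_stage_II_IV))
  expect_error(covariate_cutoff_sensitivity(c(1, 2), c("NM", "NM"),
                                            c(NA, NA)), "no PC")
})
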