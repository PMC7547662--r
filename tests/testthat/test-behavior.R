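test_that("roc_auc equals exhaustive pair counting and handles ties", {
  scores <- c(0.1, 0.4, 0.4, 0.7, 0.2, 0.9, 0.4, 0.05)
  labels <- c("weaker", "stronger", "weaker", "stronger",
              "weaker", "stronger", "stronger", "weaker")
  expect_identical(roc_auc(scores, labels), brute_auc(scores, labels))
  # perfect separation
  expect_identical(roc_auc(c(1, 2, 3, 10, 11), c(rep("weaker", 3), rep("stronger", 2))), 1)
  # complement symmetry is exact
  expect_identical(roc_auc(scores, labels) + roc_auc(-scores, labels), 1)
  # chance level for independent labels
  set.seed(3)
  s <- rnorm(10000)
  l <- sample(c("stronger", "weaker"), 10000, replace = TRUE)
  expect_lt(abs(roc_auc(s, l) - 0.5), 0.02)
  expect_error(roc_auc(1:5, rep("stronger", 5)), "both label classes")
})

test_that("SDT labels cross category with choice", {
  tr <- toy_trials(matrix(0.5, 4, 10),
                   category = c("stronger", "stronger", "weaker", "weaker"),
                   choice = c("stronger", "weaker", "stronger", "weaker"))
  expect_identical(as.character(categorize_sdt(tr)),
                   c("hit", "miss", "false_alarm", "correct_reject"))
  tr$choice[2] <- NA
  lab <- categorize_sdt(tr)
  expect_true(is.na(lab[2]))
  expect_identical(attr(lab, "n_excluded"), 1L)
})

test_that("psychophysical kernel matches the explicit-ROC oracle exactly", {
  tr <- null_trials(200, seed = 8)
  k <- psychophysical_kernel(tr)
  expect_equal(k$auc, brute_kernel(tr), tolerance = 1e-12)
})

test_that("kernel is invariant under increasing transforms and null at chance", {
  tr <- null_trials(400, seed = 9)
  k1 <- psychophysical_kernel(tr)$auc
  tr2 <- tr
  tr2[, sprintf("s%02d", 1:10)] <- exp(3 * contrast_matrix(tr))
  expect_identical(psychophysical_kernel(tr2)$auc, k1)
  big <- null_trials(10000, seed = 10)
  expect_true(all(abs(psychophysical_kernel(big)$auc - 0.5) < 0.02))
})

test_that("single-sample observer concentrates the kernel on that sample", {
  obs <- observer_params(weights = c(1, rep(0, 9)), internal_noise_sd = 0.01,
                         lapse_rate = 0)
  tr <- simulate_subject(1, 1500, seed = 13, observer = obs)
  k <- psychophysical_kernel(tr)$auc
  expect_gt(k[1], 0.9)
  expect_true(all(abs(k[2:10] - 0.5) < 0.06))
})

test_that("kernel slope is the OLS slope over positions", {
  expect_equal(kernel_slope(rep(0.6, 10)), 0)
  series <- 0.6 - 0.01 * (0:9)
  expect_equal(kernel_slope(series), -0.01, tolerance = 1e-12)
  expect_error(kernel_slope(c(NA, NA, 0.5)), "non-missing")
})

test_that("primacy weights produce negative group-mean kernel slopes", {
  coh <- simulate_cohort(n_subjects = 8, n_trials = 400, seed = 17)
  km <- cohort_kernels(coh)
  slopes <- apply(km, 1, kernel_slope)
  expect_lt(mean(slopes), 0)
  # parameter recovery: kernel deviations track the generating weights
  w <- observer_params()$weights
  r <- cor(colMeans(km) - 0.5, w, method = "spearman")
  expect_gt(r, 0.6)
})

test_that("choice logistic regression recovers generating coefficients", {
  set.seed(101)
  n <- 20000
  C <- matrix(runif(n * 10, 0.2, 0.8), n, 10)
  beta <- seq(8, 3, length.out = 10)
  eta <- C %*% beta - mean(C %*% beta)
  y <- ifelse(runif(n) < plogis(eta), "stronger", "weaker")
  tr <- toy_trials(C, ifelse(rowMeans(C) > 0.5, "stronger", "weaker"), y)
  fit <- fit_choice_logreg(tr, seed = 3)
  expect_lt(sqrt(sum((fit$coefficients[2:11] - beta)^2) / sum(beta^2)), 0.05)
  expect_gt(fit$cv_accuracy, 0.5)
})

test_that("degenerate designs behave as documented", {
  # identical contrasts on every trial: accuracy ~ majority class
  C <- matrix(0.5, 400, 10)
  set.seed(5)
  y <- ifelse(runif(400) < 0.6, "stronger", "weaker")
  tr <- toy_trials(C, sample(c("stronger", "weaker"), 400, TRUE), y)
  fit <- fit_choice_logreg(tr, seed = 1)
  expect_lt(abs(fit$cv_accuracy - max(mean(y == "stronger"),
                                      mean(y == "weaker"))), 0.06)
  # noiseless ideal observer: near-perfect prediction (ridged separation)
  obs <- observer_params(weights = rep(1, 10), internal_noise_sd = 1e-9,
                         lapse_rate = 0)
  tr2 <- simulate_subject(1, 400, seed = 19, observer = obs)
  fit2 <- fit_choice_logreg(tr2, seed = 2)
  expect_gt(fit2$cv_accuracy, 0.95)
  expect_true(fit2$ridged)
})

test_that("confidence regression separates informative from coin confidence", {
  tr <- simulate_subject(1, 1200, seed = 23)
  fits <- fit_confidence_logreg(tr, seed = 4)
  expect_gt(fits$stronger$cv_accuracy, 0.55)
  expect_gt(fits$weaker$cv_accuracy, 0.55)
  trc <- tr
  trc$confidence <- with_seed(7, sample(c("high", "low"), nrow(tr), TRUE))
  fitc <- fit_confidence_logreg(trc, seed = 4)
  expect_lt(abs(fitc$stronger$cv_accuracy - 0.5), 0.07)
  # stratification: fold class proportions within one trial of parity
  y <- tr$choice
  folds <- choicekernels:::stratified_folds(y, 5, seed = 6)
  for (f in 1:5) {
    expect_lt(abs(sum(y[folds == f] == "stronger") -
                    sum(y == "stronger") / 5), 1 + 1e-9)
  }
})

test_that("fast-RT exclusion is strict and matches the generated RT mass", {
  tr <- toy_trials(matrix(0.5, 3, 10), rep("stronger", 3), rep("stronger", 3))
  tr$rt <- c(1.0, 1.225, 1.3)
  out <- exclude_fast_rts(tr)
  expect_identical(nrow(out), 2L)
  expect_identical(attr(out, "n_excluded"), 1L)
  expect_true(all(out$rt >= 1.225))
  big <- simulate_subject(1, 10000, seed = 29)
  kept <- exclude_fast_rts(big)
  expect_lt(abs(nrow(kept) / nrow(big) - 0.95), 0.01)
  expect_identical(contamination_free_boundary(), 1.1)
})

test_that("FDR-corrected kernel test controls false rejections under the null", {
  n_sims <- 300
  any_rej <- vapply(1:n_sims, function(i) {
    km <- t(vapply(1:8, function(s)
      psychophysical_kernel(null_trials(80, seed = i * 100 + s))$auc,
      numeric(10)))
    p <- apply(km, 2, function(col) t.test(col, mu = 0.5)$p.value)
    any(fdr_correct(p))
  }, logical(1))
  rate <- mean(any_rej)
  mc_se <- sqrt(0.05 * 0.95 / n_sims)
  expect_lte(rate, 0.05 + 3 * mc_se)
})
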