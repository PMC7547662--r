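test_that("residualization matches hand OLS and is idempotent", {
  pw <- matrix(c(2, 4, 5, 7, 8, 10), 6, 10)
  ct <- matrix(c(0.3, 0.4, 0.45, 0.55, 0.6, 0.7), 6, 10)
  res <- residualize_on_contrast(pw, ct)
  b <- cov(pw[, 1], ct[, 1]) / var(ct[, 1])
  a <- mean(pw[, 1]) - b * mean(ct[, 1])
  expect_equal(res[, 1], pw[, 1] - (a + b * ct[, 1]), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_lt(max(abs(residualize_on_contrast(res, ct) - res)), 1e-12)
})

test_that("residual kernels null stimulus-driven channels and keep endogenous ones", {
  n <- 2000
  tr <- simulate_subject(1, n, seed = 51)
  C <- contrast_matrix(tr)
  set.seed(52)
  # purely stimulus-driven channel: power = affine(contrast) + noise
  p_stim <- 1 + 3 * C + matrix(rnorm(n * 10, sd = 0.15), n, 10)
  k_over <- neural_kernel(p_stim, tr, "overall")
  k_res <- neural_kernel(p_stim, tr, "residual")
  expect_gt(mean(k_over$auc[1:5]), 0.54)
  expect_lt(max(abs(k_res$auc - 0.5)), 0.045)
  # purely endogenous channel: power = f(choice), independent of contrast
  sgn <- ifelse(tr$choice == "stronger", 1, -1)
  p_endo <- matrix(sgn, n, 10) + matrix(rnorm(n * 10, sd = 1.5), n, 10)
  e_over <- neural_kernel(p_endo, tr, "overall")
  e_res <- neural_kernel(p_endo, tr, "residual")
  expect_gt(mean(e_over$auc), 0.55)
  expect_lt(max(abs(e_res$auc - e_over$auc)), 0.03)
})

test_that("kernel correlation behaves as a Pearson correlation", {
  a <- seq(0.62, 0.48, length.out = 10)  # strictly monotone, affine
  expect_equal(correlate_kernels(a, a), 1)
  expect_equal(correlate_kernels(a, rev(a)), -1, tolerance = 1e-12)
  expect_true(is.na(correlate_kernels(a, rep(0.5, 10))))
  expect_error(correlate_kernels(a[1:2], a[1:2]), "at least 3")
})

test_that("gamma kernels correlate with psychophysical kernels on generated data", {
  np <- neural_gen_params(frequency_grid = c(10, 50, 55, 60, 65))
  rs <- vapply(1:5, function(s) {
    tr <- simulate_subject(s, 500, seed = 60 + s)
    tens <- generate_power_tensor(tr, np, "V1", seed = 70 + s)
    havg <- hemi_average(baseline_normalize(tens))
    g <- sample_band_power(havg, band_definition("gamma"), roi = "V1")
    correlate_kernels(neural_kernel(g, tr)$auc, psychophysical_kernel(tr)$auc)
  }, numeric(1))
  expect_gt(mean(rs), 0.2)
})

test_that("interaction model recovers its own generating coefficients", {
  set.seed(71)
  n <- 20000
  a1 <- rnorm(n); a2 <- rnorm(n); g1 <- rnorm(n); g2 <- rnorm(n)
  beta <- c(a1 = 0.5, a2 = 0.8, g1 = 0.6, g2 = 0.45, i1 = 0.4, i2 = -0.5)
  eta <- beta[1] * a1 + beta[2] * a2 + beta[3] * g1 + beta[4] * g2 +
    beta[5] * a1 * g1 + beta[6] * a2 * g2
  y <- ifelse(runif(n) < plogis(eta), "stronger", "weaker")
  tr <- toy_trials(matrix(0.5, n, 10),
                   sample(c("stronger", "weaker"), n, TRUE), y)
  ap <- cbind(matrix(a1, n, 5), matrix(a2, n, 5))
  gp <- cbind(matrix(g1, n, 5), matrix(g2, n, 5))
  fit <- interaction_logreg(tr, ap, gp)
  est <- fit$coefficients[2:7]
  expect_lt(max(abs(est - beta) / abs(beta)), 0.10)
  expect_equal(unname(fit$asymmetry["inter"]),
               unname(est["inter2"] - est["inter1"]))
  # no interaction in the generator: interaction terms near zero
  eta0 <- a1 + g1
  y0 <- ifelse(runif(n) < plogis(eta0), "stronger", "weaker")
  tr0 <- toy_trials(matrix(0.5, n, 10),
                    sample(c("stronger", "weaker"), n, TRUE), y0)
  fit0 <- interaction_logreg(tr0, ap, gp)
  expect_lt(max(abs(fit0$coefficients[c("inter1", "inter2")])), 0.05)
})

test_that("time-resolved kernels are flat under the null and track injected signals", {
  n <- 400
  tr <- null_trials(n, seed = 81)
  times <- seq(-0.2, 1.0, by = 0.05)
  pow <- array(rnorm(n * 1 * 1 * length(times)), c(n, 1, 1, length(times)))
  tens <- structure(list(power = pow, trial_ids = tr$trial, rois = "V1",
                         hemis = NULL, freqs = 10, times = times,
                         units = "pct_change"), class = "power_tensor")
  k0 <- highres_kernel(tens, tr, band_definition("low_frequency"))
  expect_lt(max(abs(k0$auc - 0.5)), 0.1)
  # inject a late choice signal from 0.5 s on
  sgn <- ifelse(tr$choice == "stronger", 1, -1)
  late <- times >= 0.5
  pow[, 1, 1, late] <- pow[, 1, 1, late] + 2 * sgn
  tens$power <- pow
  k1 <- highres_kernel(tens, tr, band_definition("low_frequency"))
  expect_lt(mean(abs(k1$auc[times < 0.45] - 0.5)), 0.05)
  expect_gt(mean(k1$auc[late]), 0.85)
})

test_that("cross-correlation recovers exact shifts and the leakage reference", {
  times <- seq(0, 1.0, by = 1 / 60)
  set.seed(91)
  base <- cumsum(rnorm(length(times)))
  m1 <- data.frame(time = times, auc = base)
  vk_same <- structure(list(axis = times, auc = base, variant = "highres"),
                       class = "kernel_series")
  cc <- crosscorr_choice_feedback(m1, vk_same)
  expect_equal(cc$r[cc$lag == 0], 1)
  expect_identical(cc$lag[which.max(cc$r)], 0)
  # shift by k bins: peak lag = k * dt exactly
  for (k in c(3, 9)) {
    shifted <- structure(list(axis = times + k / 60, auc = base,
                              variant = "highres"), class = "kernel_series")
    cck <- crosscorr_choice_feedback(m1, shifted)
    expect_equal(cck$lag[which.max(cck$r)], k / 60, tolerance = 1e-9)
  }
  # lag grid is symmetric and confined to [-0.215, 0.215]
  expect_true(all(abs(cc$lag) <= 0.215))
  expect_equal(cc$lag, -rev(cc$lag))
  # leakage reference: independent series correlate near zero
  set.seed(92)
  ref <- leakage_reference(
    data.frame(time = times, auc = rnorm(length(times))),
    structure(list(axis = times, auc = rnorm(length(times))),
              class = "kernel_series"))
  expect_lt(abs(ref), 0.3)
})

test_that("sample-resolved and time-resolved kernels agree on noise-free fixtures", {
  n <- 200
  tr <- simulate_subject(1, n, seed = 95)
  np <- neural_gen_params(frequency_grid = c(10, 60), noise_sdlog = 0)
  tens <- generate_power_tensor(tr, np, "V1", seed = 96)
  havg <- hemi_average(baseline_normalize(tens))
  lo_sp <- sample_band_power(havg, band_definition("low_frequency"), roi = "V1")
  k_sample <- neural_kernel(lo_sp, tr)$auc
  onsets <- seq(0, 0.9, by = 0.1)
  k_time <- highres_kernel(havg, tr, band_definition("low_frequency"),
                           times = onsets + 0.19)$auc
  expect_equal(k_sample, k_time, tolerance = 1e-12)
})
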