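test_that("multitaper power matches a direct tapered-DFT evaluation", {
  sfreq <- 400
  tt <- seq(0, 0.5 - 1 / sfreq, by = 1 / sfreq)
  set.seed(1)
  x <- matrix(rnorm(length(tt)), 1)
  f0 <- 60
  out <- multitaper_tfr(x, sfreq, tt, freqs = f0, window_s = 0.1,
                        half_bw_hz = 10, t_centers = 0.25)
  # independent oracle: explicit taper * complex exponential sums
  L <- round(0.1 * sfreq)
  nw <- 0.1 * 10
  K <- max(1, round(2 * nw - 1))
  tap <- dpss_tapers(L, nw, K)
  start_t <- 0.25 - 0.05
  i0 <- which.min(abs(tt - start_t))
  seg <- x[1, i0:(i0 + L - 1)]
  p <- 0
  for (k in seq_len(K)) {
    re <- sum(seg * tap[, k] * cos(-2 * pi * f0 * (0:(L - 1)) / sfreq))
    im <- sum(seg * tap[, k] * sin(-2 * pi * f0 * (0:(L - 1)) / sfreq))
    p <- p + (re^2 + im^2)
  }
  expect_equal(out[1, 1, 1], p / K, tolerance = 1e-10)
})

test_that("sinusoid power peaks at its frequency and scales quadratically", {
  sfreq <- 400
  tt <- seq(0, 1 - 1 / sfreq, by = 1 / sfreq)
  x1 <- matrix(sin(2 * pi * 60 * tt), 1)
  x2 <- 2 * x1
  freqs <- seq(10, 150, by = 5)
  p1 <- multitaper_tfr(x1, sfreq, tt, freqs, t_centers = 0.5)
  p2 <- multitaper_tfr(x2, sfreq, tt, freqs, t_centers = 0.5)
  expect_identical(freqs[which.max(p1[1, , 1])], 60)
  expect_equal(p2[1, , 1], 4 * p1[1, , 1], tolerance = 1e-9)
  # additivity for orthogonal sinusoids within taper-leakage tolerance
  x3 <- matrix(sin(2 * pi * 60 * tt) + sin(2 * pi * 100 * tt), 1)
  p3 <- multitaper_tfr(x3, sfreq, tt, freqs, t_centers = 0.5)
  i60 <- which(freqs == 60); i100 <- which(freqs == 100)
  expect_lt(abs(p3[1, i60, 1] + p3[1, i100, 1] -
                  (p1[1, i60, 1] + multitaper_tfr(
                    matrix(sin(2 * pi * 100 * tt), 1), sfreq, tt, freqs,
                    t_centers = 0.5)[1, i100, 1])) /
              (p3[1, i60, 1] + p3[1, i100, 1]), 0.05)
  # edge bins whose window leaves the epoch are NA
  pe <- multitaper_tfr(x1, sfreq, tt, 60, t_centers = c(0.01, 0.5))
  expect_true(is.na(pe[1, 1, 1]) && !is.na(pe[1, 1, 2]))
})

make_tensor <- function(pow, freqs, times, rois = "V1",
                        hemis = c("left", "right"), units = "raw") {
  structure(list(power = pow, trial_ids = seq_len(dim(pow)[1]), rois = rois,
                 hemis = if (length(dim(pow)) == 5) hemis else NULL,
                 freqs = freqs, times = times, units = units),
            class = "power_tensor")
}

test_that("baseline normalization matches hand arithmetic", {
  times <- c(-0.2, -0.1, 0.1, 0.2)
  pow <- array(0, c(2, 1, 1, 1, 4))
  pow[1, 1, 1, 1, ] <- c(8, 12, 20, 30)
  pow[2, 1, 1, 1, ] <- c(9, 11, 10, 40)
  tens <- make_tensor(pow, freqs = 10, times = times)
  out <- baseline_normalize(tens)
  b <- mean(c(8, 12, 9, 11))
  expect_equal(out$power[1, 1, 1, 1, ], 100 * (c(8, 12, 20, 30) - b) / b)
  expect_identical(out$units, "pct_change")
  expect_true(all(out$power >= -100))
  # power equal to baseline -> 0; power = 2x baseline -> +100
  pow2 <- array(5, c(1, 1, 1, 1, 4))
  pow2[1, 1, 1, 1, 3:4] <- 10
  out2 <- baseline_normalize(make_tensor(pow2, 10, times))
  expect_equal(as.numeric(out2$power[1, 1, 1, 1, ]), c(0, 0, 100, 100))
  expect_error(baseline_normalize(out2), "raw")
})

test_that("lateralization is antisymmetric and follows the hand convention", {
  times <- c(0, 0.1)
  pow <- array(1, c(2, 1, 2, 1, 2))
  pow[, 1, 1, 1, ] <- 3   # left hemisphere excess
  tens <- make_tensor(pow, 10, times, units = "pct_change")
  # right hand reports stronger: contra = left, so excess is positive
  lat <- lateralize(tens, "right")
  expect_true(all(lat$power == 2))
  latL <- lateralize(tens, "left")
  expect_true(all(latL$power == -2))
  expect_identical(lat$power, -latL$power)
  # identical hemispheres: zero
  pow[, 1, 1, 1, ] <- 1
  expect_true(all(lateralize(make_tensor(pow, 10, times,
                                         units = "pct_change"),
                             "right")$power == 0))
})

test_that("band power averages the configured centers at the nearest bin", {
  freqs <- c(10, 50, 55, 60, 65, 70)
  times <- seq(0, 0.5, by = 0.1)
  pow <- array(0, c(1, 1, 6, 6))
  pow[1, 1, , 4] <- c(1, 2, 4, 6, 8, 100)
  tens <- make_tensor(pow, freqs, times, units = "pct_change")
  g <- band_power(tens, band_definition("gamma"), at_time = 0.3)
  expect_equal(unname(g[1, 1]), mean(c(2, 4, 6, 8)))  # 70 Hz not a gamma center
  single <- band_power(tens, list(name = "x", centers = 10), at_time = 0.3)
  expect_equal(unname(single[1, 1]), 1)
  # nearest-bin rule resolves ties toward the earlier bin
  expect_identical(choicekernels:::nearest_time_bin(times, 0.35), 4L)
  expect_error(band_power(tens, band_definition("gamma"), at_time = 2), "epoch")
})

test_that("condition contrasts factor out the other factor (balanced rule)", {
  n <- 400
  set.seed(12)
  category <- rep(c("stronger", "weaker"), each = n / 2)
  # choices correlated with category (accuracy 70%) to create imbalance
  choice <- ifelse(runif(n) < 0.7, category,
                   ifelse(category == "stronger", "weaker", "stronger"))
  times <- c(0, 0.1)
  # additive category effect only: +2 for stronger stimuli, no choice effect
  base <- rnorm(n, sd = 0.1) + ifelse(category == "stronger", 2, 0)
  pow <- array(rep(base, 2), c(n, 1, 1, 2))
  tens <- make_tensor(pow, 10, times, units = "pct_change")
  tr <- toy_trials(matrix(0.5, n, 10), category, choice)
  stim <- condition_tfr_contrast(tens, tr, "stimulus_specific")
  cho <- condition_tfr_contrast(tens, tr, "choice_specific")
  expect_lt(abs(stim[1, 1, 1] - 2), 0.05)
  expect_lt(abs(cho[1, 1, 1]), 0.05)
  # naive unbalanced choice difference is confounded by the category effect
  naive <- mean(base[choice == "stronger"]) - mean(base[choice == "weaker"])
  expect_gt(abs(naive), 0.5)
  # empty cell propagates missingness
  tr_bad <- tr
  tr_bad$choice[tr_bad$stimulus_category == "stronger"] <- "stronger"
  out <- condition_tfr_contrast(tens, tr_bad, "choice_specific")
  expect_true(all(is.na(out)))
})
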