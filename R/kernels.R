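# Neural-activity kernels: choice-predictive information in band power,
# computed with the same two-cell SDT-balanced AUC rule as psychophysical
# kernels.

#' Neural-activity kernel over sample positions
#'
#' Substitutes band power at each sample's extraction latency for sample
#' contrast in the psychophysical-kernel computation: per sample position,
#' AUC(hit vs miss) and AUC(false alarm vs correct reject) averaged. The
#' "residual" variant first regresses power on the same sample's contrast
#' (per sample position, OLS) and computes the kernel from the residuals,
#' isolating choice-predictive activity not driven by the external
#' stimulus fluctuations.
#'
#' @param sample_power trials x 10 matrix of hemisphere-averaged band
#'   power extracted at sample onset + latency
#'   (\code{\link{sample_band_power}}).
#' @param trials matching trial table.
#' @param variant "overall" or "residual".
#' @return a "kernel_series" (axis = sample positions 1..10).
#' @export
neural_kernel <- function(sample_power, trials,
                          variant = c("overall", "residual")) {
  variant <- match.arg(variant)
  stopifnot(nrow(sample_power) == nrow(trials), ncol(sample_power) == 10)
  vals <- sample_power
  if (variant == "residual") {
    vals <- residualize_on_contrast(sample_power, contrast_matrix(trials))
  }
  auc <- kernel_auc(vals, trials)
  structure(list(axis = 1:10, auc = auc, variant = variant,
                 band = attr(sample_power, "band"), roi = NULL),
            class = "kernel_series")
}

#' Regress sample contrast out of per-sample power
#'
#' Per sample position, OLS of power on the same sample's contrast (with
#' intercept); returns the residuals. Idempotent: residualizing residuals
#' changes nothing.
#'
#' @param sample_power trials x positions matrix.
#' @param contrasts trials x positions matrix.
#' @return residual matrix, same shape.
#' @export
residualize_on_contrast <- function(sample_power, contrasts) {
  stopifnot(all(dim(sample_power) == dim(contrasts)))
  out <- sample_power
  for (i in seq_len(ncol(sample_power))) {
    c_i <- contrasts[, i]
    if (stats::sd(c_i) == 0) {
      out[, i] <- sample_power[, i] - mean(sample_power[, i])
    } else {
      out[, i] <- stats::residuals(stats::lm(sample_power[, i] ~ c_i))
    }
  }
  out
}

#' Frequency-resolved kernel summaries
#'
#' Per frequency bin: the time-collapsed kernel (mean of AUC - 0.5 across
#' sample positions) and the OLS slope of AUC over positions. Positive
#' collapsed values flag choice-predictive bands; the slope separates
#' early (stimulus-driven, decaying) from late (endogenous, building)
#' choice information.
#'
#' @param tensor hemisphere-averaged "power_tensor" (trial x roi x
#'   frequency x time).
#' @param trials matching trial table.
#' @param roi ROI name.
#' @param latency extraction latency after sample onset, seconds.
#' @return data.frame with columns freq, collapsed (mean AUC - 0.5) and
#'   slope.
#' @export
frequency_resolved_kernels <- function(tensor, trials, roi = NULL,
                                       latency = 0.190) {
  stopifnot(inherits(tensor, "power_tensor"), length(dim(tensor$power)) == 4)
  if (is.null(roi)) roi <- tensor$rois[1]
  ridx <- match(roi, tensor$rois)
  onsets <- seq(0, 0.9, by = 0.1)
  tidx <- vapply(onsets + latency, function(t)
    nearest_time_bin(tensor$times, t), 1L)
  out <- data.frame(freq = tensor$freqs, collapsed = NA_real_,
                    slope = NA_real_)
  for (fi in seq_along(tensor$freqs)) {
    vals <- tensor$power[, ridx, fi, tidx]
    auc <- kernel_auc(vals, trials)
    if (all(is.na(auc))) next
    out$collapsed[fi] <- mean(auc - 0.5, na.rm = TRUE)
    out$slope[fi] <- kernel_slope(auc)
  }
  out
}

#' Pearson correlation between two kernels
#'
#' @param a,b "kernel_series" objects (or numeric vectors) on a common
#'   axis with at least 3 shared non-missing positions.
#' @return Pearson r; NA if either series is constant.
#' @export
correlate_kernels <- function(a, b) {
  va <- if (inherits(a, "kernel_series")) a$auc else a
  vb <- if (inherits(b, "kernel_series")) b$auc else b
  ok <- !is.na(va) & !is.na(vb)
  if (sum(ok) < 3) stop("need at least 3 common kernel positions")
  if (stats::sd(va[ok]) == 0 || stats::sd(vb[ok]) == 0) return(NA_real_)
  stats::cor(va[ok], vb[ok])
}

#' Choice model with low-frequency x gamma interaction
#'
#' Logistic regression of choice on z-scored low-frequency and gamma-band
#' power averaged over the first (samples 1-5) and second (samples 6-10)
#' half of the test interval, plus their within-half products:
#' choice ~ a1 + a2 + g1 + g2 + a1*g1 + a2*g2. The interaction terms
#' measure how low-frequency power modulates the gamma-choice coupling;
#' temporal asymmetry per term is the second-half minus first-half
#' coefficient.
#'
#' @param trials trial table.
#' @param alpha_power,gamma_power trials x 10 matrices of band power at
#'   the sample extraction latency.
#' @return list with coefficients (b0, alpha1, alpha2, gamma1, gamma2,
#'   inter1, inter2), asymmetry (per term), and a ridged flag.
#' @export
interaction_logreg <- function(trials, alpha_power, gamma_power) {
  zs <- function(x) (x - mean(x)) / stats::sd(x)
  a1 <- zs(rowMeans(alpha_power[, 1:5])); a2 <- zs(rowMeans(alpha_power[, 6:10]))
  g1 <- zs(rowMeans(gamma_power[, 1:5])); g2 <- zs(rowMeans(gamma_power[, 6:10]))
  X <- cbind(alpha1 = a1, alpha2 = a2, gamma1 = g1, gamma2 = g2,
             inter1 = a1 * g1, inter2 = a2 * g2)
  y <- as.integer(trials$choice == "stronger")
  if (length(unique(y)) < 2) stop("both choices must be present")
  fit <- safe_logreg(X, y)
  co <- stats::setNames(fit$coef, c("b0", colnames(X)))
  list(coefficients = co,
       asymmetry = c(alpha = unname(co["alpha2"] - co["alpha1"]),
                     gamma = unname(co["gamma2"] - co["gamma1"]),
                     inter = unname(co["inter2"] - co["inter1"])),
       ridged = fit$ridged)
}

#' Time-resolved neural-activity kernel
#'
#' Same two-cell AUC rule as \code{\link{neural_kernel}} but indexed by
#' time bin instead of sample position, for comparison with decoding time
#' courses.
#'
#' @param tensor hemisphere-averaged "power_tensor".
#' @param trials matching trial table.
#' @param band a \code{\link{band_definition}}.
#' @param roi ROI name.
#' @param times time bins (default: all).
#' @return a "kernel_series" with axis = time bins (seconds).
#' @export
highres_kernel <- function(tensor, trials, band, roi = NULL, times = NULL) {
  stopifnot(inherits(tensor, "power_tensor"), length(dim(tensor$power)) == 4)
  if (is.null(roi)) roi <- tensor$rois[1]
  ridx <- match(roi, tensor$rois)
  fidx <- which(tensor$freqs %in% band$centers)
  if (length(fidx) == 0) stop("band centers not in frequency grid")
  if (is.null(times)) times <- tensor$times
  tidx <- vapply(times, function(t) nearest_time_bin(tensor$times, t), 1L)
  bp <- apply(tensor$power[, ridx, fidx, tidx, drop = FALSE], c(1, 4), mean)
  auc <- kernel_auc(bp, trials)
  structure(list(axis = tensor$times[tidx], auc = auc, variant = "highres",
                 band = band$name, roi = roi),
            class = "kernel_series")
}

#' Lagged correlation between motor choice decoding and a visual kernel
#'
#' Per lag l, the Pearson correlation between the motor (M1-hand) choice
#' decoding AUC time course on [0, 0.8] s and the visual low-frequency
#' kernel on [l, 0.8 + l] s. Positive lags mean the motor signal leads.
#' Lags whose shifted window exceeds the kernel support are NA (the
#' overlap is truncated, never padded).
#'
#' @param m1_auc data.frame(time, auc): choice decoding time course.
#' @param visual_kernel "kernel_series" with a time axis (from
#'   \code{\link{highres_kernel}}).
#' @param lags lag grid, seconds (subset of [-0.215, 0.215] by default).
#' @param window correlation window on the motor time course, seconds.
#' @return data.frame with columns lag and r.
#' @export
crosscorr_choice_feedback <- function(m1_auc, visual_kernel,
                                      lags = seq(-12, 12) / 60,
                                      window = c(0, 0.8)) {
  kt <- visual_kernel$axis
  kv <- visual_kernel$auc
  mmask <- m1_auc$time >= window[1] - 1e-9 & m1_auc$time <= window[2] + 1e-9
  mt <- m1_auc$time[mmask]
  mv <- m1_auc$auc[mmask]
  dt <- stats::median(diff(kt))
  r <- vapply(lags, function(l) {
    tv <- mt + l
    idx <- vapply(tv, function(t) {
      j <- which.min(abs(kt - t))
      if (abs(kt[j] - t) > dt / 2 + 1e-9) NA_integer_ else j
    }, 1L)
    ok <- !is.na(idx) & is.finite(mv)
    if (sum(ok) < 3) return(NA_real_)
    a <- mv[ok]; b <- kv[idx[ok]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  data.frame(lag = lags, r = r)
}

#' Group peak lag of the lagged coupling
#'
#' Averages per-subject cross-correlation functions across subjects and
#' returns the lag maximizing the group mean (the group-level summary; not
#' the mean of per-subject argmax lags).
#'
#' @param cc_list list of per-subject data.frames from
#'   \code{\link{crosscorr_choice_feedback}} on a common lag grid.
#' @return list with lag grid, group-mean r, and peak_lag.
#' @export
group_peak_lag <- function(cc_list) {
  lags <- cc_list[[1]]$lag
  R <- vapply(cc_list, function(d) d$r, numeric(length(lags)))
  m <- rowMeans(R, na.rm = TRUE)
  list(lags = lags, mean_r = m, peak_lag = lags[which.max(m)])
}

#' Leakage reference correlation
#'
#' Zero-lag correlation between the motor choice decoding time course and
#' the low-frequency kernel taken from the same motor ROI. Because the two
#' statistics come from the same region, the value bounds from above any
#' correlation attributable to source leakage, and serves as the
#' conservative reference against which visual-ROI cross-correlations are
#' compared (paired t-tests per lag).
#'
#' @param m1_auc data.frame(time, auc).
#' @param m1_lowfreq_kernel "kernel_series" on a time axis from the same
#'   ROI.
#' @param window correlation window, seconds.
#' @return Pearson r at lag 0.
#' @export
leakage_reference <- function(m1_auc, m1_lowfreq_kernel, window = c(0, 0.8)) {
  cc <- crosscorr_choice_feedback(m1_auc, m1_lowfreq_kernel, lags = 0,
                                  window = window)
  cc$r[1]
}
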