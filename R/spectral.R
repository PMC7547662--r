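#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed from the standard symmetric tridiagonal eigenproblem; the
#' first k eigenvectors maximize spectral concentration in [-W, W].
#'
#' @param n taper length in samples.
#' @param nw time-bandwidth product N*W (W in cycles per sample).
#' @param k number of tapers.
#' @return n x k matrix of unit-norm tapers (leading taper positive-sum).
#' @export
dpss_tapers <- function(n, nw, k) {
  stopifnot(n >= 2, k >= 1, nw > 0)
  W <- nw / n
  t_idx <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * t_idx) / 2)^2 * cos(2 * pi * W)
  off <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A <- diag(diag_main)
  A[cbind(1:(n - 1), 2:n)] <- off
  A[cbind(2:n, 1:(n - 1))] <- off
  e <- eigen(A, symmetric = TRUE)
  tapers <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    tapers[, j] <- tapers[, j] / sqrt(sum(tapers[, j]^2))
    if (sum(tapers[, j]) < 0) tapers[, j] <- -tapers[, j]
  }
  tapers
}

#' Multitaper time-frequency power
#'
#' Sliding-window DPSS multitaper estimate at arbitrary center
#' frequencies. Window length and frequency smoothing follow the grid
#' convention: 0.25 s windows with +/-4 Hz smoothing for 1-9 Hz, 0.1 s
#' windows with +/-10 Hz smoothing for 10-150 Hz; the taper count is
#' round(2*T*W - 1) (at least one) from the window x half-bandwidth
#' product. Time bins whose window falls outside the epoch are NA.
#'
#' @param x trials x samples matrix of a (narrow-band) time series.
#' @param sfreq sampling rate, Hz (>= 2x the largest requested frequency).
#' @param sample_times times of the columns of x, seconds.
#' @param freqs center frequencies, Hz.
#' @param window_s window length per frequency (recycled), seconds.
#' @param half_bw_hz half-bandwidth per frequency (recycled), Hz.
#' @param t_centers output time bins; default the sample times.
#' @return array trials x frequency x time of power (>= 0).
#' @export
multitaper_tfr <- function(x, sfreq, sample_times, freqs,
                           window_s = ifelse(freqs < 10, 0.25, 0.1),
                           half_bw_hz = ifelse(freqs < 10, 4, 10),
                           t_centers = sample_times) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  stopifnot(ncol(x) == length(sample_times), sfreq >= 2 * max(freqs))
  window_s <- rep_len(window_s, length(freqs))
  half_bw_hz <- rep_len(half_bw_hz, length(freqs))
  out <- array(NA_real_, dim = c(nrow(x), length(freqs), length(t_centers)))
  for (fi in seq_along(freqs)) {
    L <- round(window_s[fi] * sfreq)
    nw <- window_s[fi] * half_bw_hz[fi]
    K <- max(1, round(2 * nw - 1))
    tap <- dpss_tapers(L, nw, K)
    tseg <- (seq_len(L) - 1) / sfreq
    e <- exp(-2i * pi * freqs[fi] * tseg)
    for (ti in seq_along(t_centers)) {
      start_t <- t_centers[ti] - window_s[fi] / 2
      i0 <- which.min(abs(sample_times - start_t))
      if (sample_times[i0] > start_t + 0.5 / sfreq) i0 <- i0 - 1
      if (i0 < 1 || i0 + L - 1 > ncol(x)) next
      seg <- x[, i0:(i0 + L - 1), drop = FALSE]
      p <- 0
      for (k in seq_len(K)) {
        z <- (seg * matrix(tap[, k], nrow(seg), L, byrow = TRUE)) %*% e
        p <- p + Mod(z)^2
      }
      out[, fi, ti] <- p / K
    }
  }
  out
}

# Internal: nearest time bin with ties resolved toward the earlier bin.
nearest_time_bin <- function(times, t) {
  d <- abs(times - t)
  which(d == min(d))[1]
}

#' Baseline-normalize a power tensor to percent change
#'
#' Per frequency (and ROI/hemisphere), the baseline is the mean raw power
#' over all trials and the time bins in \code{window}; the output is
#' 100 * (power - baseline) / baseline. The baseline is condition
#' independent by construction.
#'
#' @param tensor a "power_tensor" in raw units.
#' @param window baseline time interval, seconds (half-open: [from, to)).
#' @return the tensor with units "pct_change".
#' @export
baseline_normalize <- function(tensor, window = c(-0.25, 0)) {
  stopifnot(inherits(tensor, "power_tensor"))
  if (tensor$units != "raw") stop("baseline_normalize expects raw power")
  bmask <- tensor$times >= window[1] & tensor$times < window[2]
  if (!any(bmask)) stop("baseline window outside epoch")
  p <- tensor$power
  nd <- length(dim(p))
  if (nd == 5) {
    for (ri in seq_len(dim(p)[2])) for (hi in seq_len(dim(p)[3])) {
      for (fi in seq_len(dim(p)[4])) {
        b <- mean(p[, ri, hi, fi, bmask])
        if (!is.finite(b) || b <= 0) stop("non-positive baseline")
        p[, ri, hi, fi, ] <- 100 * (p[, ri, hi, fi, ] - b) / b
      }
    }
  } else if (nd == 4) {
    for (ri in seq_len(dim(p)[2])) for (fi in seq_len(dim(p)[3])) {
      b <- mean(p[, ri, fi, bmask])
      if (!is.finite(b) || b <= 0) stop("non-positive baseline")
      p[, ri, fi, ] <- 100 * (p[, ri, fi, ] - b) / b
    }
  } else stop("unsupported tensor layout")
  tensor$power <- p
  tensor$units <- "pct_change"
  tensor
}

#' Hemispheric lateralization (contra minus ipsi)
#'
#' Signed difference of the two hemispheres' values relative to the hand
#' used to report "stronger" choices: the hemisphere contralateral to that
#' hand minus the ipsilateral one. Swapping the hand mapping flips the
#' sign exactly.
#'
#' @param tensor a "power_tensor" with both hemispheres.
#' @param hand_for_stronger "left"/"right", scalar or per-trial vector.
#' @return a "power_tensor" with the hemisphere axis collapsed
#'   (power: trial x roi x frequency x time).
#' @export
lateralize <- function(tensor, hand_for_stronger) {
  stopifnot(inherits(tensor, "power_tensor"))
  p <- tensor$power
  if (length(dim(p)) != 5) stop("both hemispheres required")
  hand <- rep_len(hand_for_stronger, dim(p)[1])
  li <- which(tensor$hemis == "left")
  ri <- which(tensor$hemis == "right")
  # contra to the right hand is the left hemisphere
  sgn <- ifelse(hand == "right", 1, -1)
  out <- (p[, , li, , , drop = FALSE] - p[, , ri, , , drop = FALSE])
  out <- array(out, dim = dim(p)[-3], dimnames = dimnames(p)[-3])
  out <- out * array(sgn, dim = dim(out))
  tensor$power <- out
  tensor$hemis <- NULL
  tensor
}

#' Average power across hemispheres
#'
#' @param tensor a "power_tensor" with both hemispheres.
#' @return a "power_tensor" with power trial x roi x frequency x time.
#' @export
hemi_average <- function(tensor) {
  stopifnot(inherits(tensor, "power_tensor"), length(dim(tensor$power)) == 5)
  p <- tensor$power
  out <- (p[, , 1, , , drop = FALSE] + p[, , 2, , , drop = FALSE]) / 2
  tensor$power <- array(out, dim = dim(p)[-3], dimnames = dimnames(p)[-3])
  tensor$hemis <- NULL
  tensor
}

#' Band power at one time point
#'
#' Mean over the band's center-frequency bins at the nearest time bin
#' (ties resolved toward the earlier bin).
#'
#' @param tensor a hemisphere-collapsed "power_tensor" (trial x roi x
#'   frequency x time).
#' @param band a \code{\link{band_definition}}.
#' @param at_time extraction time, seconds (must lie inside the epoch).
#' @return trials x roi matrix.
#' @export
band_power <- function(tensor, band, at_time) {
  stopifnot(inherits(tensor, "power_tensor"), length(dim(tensor$power)) == 4)
  if (at_time < min(tensor$times) || at_time > max(tensor$times)) {
    stop("extraction time outside epoch")
  }
  fidx <- which(tensor$freqs %in% band$centers)
  if (length(fidx) == 0) stop("band centers not in frequency grid")
  ti <- nearest_time_bin(tensor$times, at_time)
  m <- tensor$power[, , fidx, ti, drop = FALSE]
  out <- apply(m, c(1, 2), mean)
  dimnames(out) <- list(NULL, tensor$rois)
  out
}

#' Band power at each sample's extraction latency
#'
#' Extracts band power at sample onset + latency for all ten samples
#' (sample onsets at 0, 0.1, ..., 0.9 s).
#'
#' @param tensor hemisphere-collapsed "power_tensor".
#' @param band a \code{\link{band_definition}}.
#' @param latency extraction latency after sample onset, seconds.
#' @param roi which ROI to extract.
#' @return trials x 10 matrix.
#' @export
sample_band_power <- function(tensor, band, latency = 0.190, roi = NULL) {
  if (is.null(roi)) roi <- tensor$rois[1]
  ridx <- match(roi, tensor$rois)
  if (is.na(ridx)) stop("unknown ROI: ", roi)
  onsets <- seq(0, 0.9, by = 0.1)
  out <- vapply(onsets, function(t0) {
    band_power(tensor, band, t0 + latency)[, ridx]
  }, numeric(dim(tensor$power)[1]))
  colnames(out) <- sprintf("s%02d", 1:10)
  out
}

#' Condition-contrast TFR map
#'
#' choice_specific: the difference between stronger and weaker choices
#' computed separately within each physical stimulus category (hits minus
#' misses; false alarms minus correct rejects) and then averaged, so that
#' stimulus-driven differences are factored out. stimulus_specific: the
#' category difference computed separately within each choice and then
#' averaged, factoring choice out. Choice-specific maps are meant to be
#' computed on lateralized input, stimulus-specific maps on
#' hemisphere-averaged input.
#'
#' @param tensor hemisphere-collapsed "power_tensor" (trial x roi x
#'   frequency x time).
#' @param trials matching trial table.
#' @param mode "choice_specific" or "stimulus_specific".
#' @return array roi x frequency x time; all-NA with a warning attribute
#'   if any required cell is empty.
#' @export
condition_tfr_contrast <- function(tensor, trials,
                                   mode = c("choice_specific",
                                            "stimulus_specific")) {
  mode <- match.arg(mode)
  stopifnot(inherits(tensor, "power_tensor"), length(dim(tensor$power)) == 4)
  p <- tensor$power
  stopifnot(dim(p)[1] == nrow(trials))
  sdt <- categorize_sdt(trials)
  cells <- table(sdt)
  if (any(cells == 0)) {
    out <- array(NA_real_, dim = dim(p)[-1], dimnames = dimnames(p)[-1])
    attr(out, "missing") <- TRUE
    return(out)
  }
  cell_mean <- function(mask) {
    m <- apply(p[mask, , , , drop = FALSE], c(2, 3, 4), mean)
    m
  }
  if (mode == "choice_specific") {
    d1 <- cell_mean(sdt == "hit") - cell_mean(sdt == "miss")
    d2 <- cell_mean(sdt == "false_alarm") - cell_mean(sdt == "correct_reject")
  } else {
    strong_cho <- trials$choice == "stronger"
    d1 <- cell_mean(sdt == "hit") - cell_mean(sdt == "false_alarm")
    d2 <- cell_mean(sdt == "miss") - cell_mean(sdt == "correct_reject")
  }
  out <- (d1 + d2) / 2
  dimnames(out) <- dimnames(p)[-1]
  out
}
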