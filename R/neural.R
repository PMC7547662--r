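#' Default time-frequency grids
#'
#' Low frequencies 1-9 Hz in steps of 1 Hz (0.25 s windows, +/-4 Hz
#' smoothing); high frequencies 10-150 Hz in steps of 5 Hz (0.1 s windows,
#' +/-10 Hz smoothing). The decoding feature set uses 1-145 Hz.
#'
#' @return list with components low, high, full, decoding, and per-bin
#'   window lengths / half-bandwidths (window_s, half_bw_hz).
#' @export
default_frequency_grid <- function() {
  low <- 1:9
  high <- seq(10, 150, by = 5)
  full <- c(low, high)
  list(low = low, high = high, full = full,
       decoding = full[full >= 1 & full <= 145],
       window_s = c(rep(0.25, length(low)), rep(0.1, length(high))),
       half_bw_hz = c(rep(4, length(low)), rep(10, length(high))))
}

#' Frequency-band definitions
#'
#' gamma: center frequencies 50-65 Hz (effective bandwidth 40-75 Hz given
#' the +/-10 Hz spectral smoothing); low_frequency: center 10 Hz
#' (effective 0-20 Hz).
#'
#' @param name "gamma" or "low_frequency".
#' @return list with name, centers (Hz), effective range (Hz).
#' @export
band_definition <- function(name = c("gamma", "low_frequency")) {
  name <- match.arg(name)
  if (name == "gamma") {
    list(name = name, centers = seq(50, 65, by = 5), effective = c(40, 75))
  } else {
    list(name = name, centers = 10, effective = c(0, 20))
  }
}

#' Parameters of the synthetic ROI power generator
#'
#' The generator emits trial x ROI x hemisphere x frequency x time power
#' with the structure the analyses assume: visual-cortex gamma power is an
#' affine function of the current sample contrast (attenuated by an
#' adaptation factor that grows with the within-trial contrast SD),
#' convolved with an impulse response peaking \code{response_latency} after
#' sample onset; visual low-frequency power additionally carries an
#' endogenous choice signal: the trial's (unit-variance) decision variable
#' times a normalized build-up ramp delayed by \code{feedback_lag}; motor
#' ROIs carry the same decision-variable build-up, hemisphere-lateralized
#' with sign set by the response hand. Noise is multiplicative
#' lognormal; the pre-stimulus interval contains baseline plus noise only.
#'
#' @param gamma_gain,gamma_offset visual gamma modulation per unit contrast
#'   and contrast-independent stimulus response (fractions of baseline).
#' @param adaptation_rate_per_sd named vector mapping sd_level to the
#'   exponential decay constant per sample position.
#' @param response_latency seconds from sample onset to response peak.
#' @param response_shape gamma shape of the impulse response (higher =
#'   more temporally focal).
#' @param alpha_feedback_gain amplitude of the endogenous low-frequency
#'   choice signal (fraction of baseline).
#' @param feedback_lag delay of the visual choice signal behind the motor
#'   build-up, seconds.
#' @param motor_buildup_gain lateralized motor build-up per unit
#'   (normalized) decision variable (fraction of baseline).
#' @param noise_sdlog sdlog of the multiplicative lognormal noise.
#' @param baseline_level function(freq_hz) -> baseline power (arbitrary
#'   units, > 0); default falls off as 1/f.
#' @param time_step epoch sampling step, seconds.
#' @param frequency_grid center frequencies to emit, Hz.
#' @param epoch time range relative to test onset, seconds.
#' @return object of class "neural_gen_params".
#' @export
neural_gen_params <- function(gamma_gain = 0.8,
                              gamma_offset = 0.3,
                              adaptation_rate_per_sd =
                                c("0.05" = 0.05, "0.1" = 0.1, "0.15" = 0.15),
                              response_latency = 0.190,
                              response_shape = 20,
                              alpha_feedback_gain = 0.1,
                              feedback_lag = 0.150,
                              motor_buildup_gain = 0.12,
                              noise_sdlog = 0.15,
                              baseline_level = function(f) 50 / (f + 5),
                              time_step = 1 / 60,
                              frequency_grid = default_frequency_grid()$full,
                              epoch = c(-0.25, 1.35)) {
  stopifnot(response_latency >= 0, feedback_lag >= 0, noise_sdlog >= 0,
            time_step > 0, epoch[1] < 0, epoch[2] > 1)
  structure(list(gamma_gain = gamma_gain, gamma_offset = gamma_offset,
                 adaptation_rate_per_sd = adaptation_rate_per_sd,
                 response_latency = response_latency,
                 response_shape = response_shape,
                 alpha_feedback_gain = alpha_feedback_gain,
                 feedback_lag = feedback_lag,
                 motor_buildup_gain = motor_buildup_gain,
                 noise_sdlog = noise_sdlog,
                 baseline_level = baseline_level,
                 time_step = time_step,
                 frequency_grid = frequency_grid,
                 epoch = epoch),
            class = "neural_gen_params")
}

#' ROI type lookup
#'
#' @param roi character vector of ROI names.
#' @return "visual" or "motor" per ROI; motor for M1, IPS/PostCeS and
#'   aIPS, visual otherwise (retinotopic field maps).
#' @export
roi_type <- function(roi) {
  ifelse(roi %in% c("M1", "IPS/PostCeS", "aIPS"), "motor", "visual")
}

# Impulse response: gamma-shaped, normalized to peak 1 at `latency`
# seconds after onset. The shape parameter controls temporal focality
# (FWHM ~ 130 ms at the default shape 20), keeping each sample's response
# concentrated near its own extraction latency.
response_kernel <- function(u, latency, shape = 20) {
  ifelse(u > 0, (u / latency)^(shape - 1) * exp((shape - 1) * (1 - u / latency)), 0)
}

# Normalized decision build-up: piecewise linear, 0 before 0.4 s, a
# steep rise to 0.8 at 0.6 s, then a shallow approach to 1 at 1.15 s
# (saturating evidence accumulation), flat after.
buildup_ramp <- function(t, t0 = 0.4, t_knee = 0.6, b_knee = 0.8, t1 = 1.15) {
  ifelse(t <= t0, 0,
  ifelse(t <= t_knee, b_knee * (t - t0) / (t_knee - t0),
  ifelse(t <= t1, b_knee + (1 - b_knee) * (t - t_knee) / (t1 - t_knee), 1)))
}

#' Generate a synthetic ROI power tensor
#'
#' @param trials trial table from \code{\link{simulate_subject}} (one
#'   subject). The realized decision variable column dv drives the motor
#'   build-up; if absent, the signed choice is used.
#' @param params a \code{\link{neural_gen_params}}.
#' @param roi_set character vector of ROI names (typed via
#'   \code{\link{roi_type}}).
#' @param seed integer seed (required).
#' @return object of class "power_tensor": list with power (array trial x
#'   roi x hemisphere x frequency x time), trial_ids, rois, hemis, freqs,
#'   times, units = "raw".
#' @export
generate_power_tensor <- function(trials, params, roi_set, seed) {
  stopifnot(inherits(params, "neural_gen_params"))
  if (length(roi_set) == 0) stop("roi_set must not be empty")
  n <- nrow(trials)
  times <- seq(params$epoch[1], params$epoch[2], by = params$time_step)
  if (params$epoch[2] < params$response_latency + 0.9) {
    stop("epoch ends before the last sample's response latency")
  }
  freqs <- params$frequency_grid
  onsets <- seq(0, 0.9, by = 0.1)
  # per-sample impulse-response basis (10 x time)
  B <- t(vapply(onsets, function(t0)
    response_kernel(times - t0, params$response_latency,
                    params$response_shape), numeric(length(times))))
  # adapted contrast drive per trial (n x time)
  C <- contrast_matrix(trials)
  arate <- params$adaptation_rate_per_sd[as.character(trials$sd_level)]
  arate[is.na(arate)] <- 0
  adapt <- exp(-outer(arate, 0:9))      # n x 10
  G <- (C * adapt) %*% B                # n x time
  stim_ind <- as.numeric(times >= 0 & times <= 1.15)
  stim_drive <- matrix(stim_ind, n, length(times), byrow = TRUE)
  chsign <- ifelse(trials$choice == "stronger", 1, -1)
  dv <- if ("dv" %in% names(trials)) trials$dv else chsign
  # graded choice signal: unit-variance decision variable, so both the
  # motor build-up and the delayed visual feedback carry the same
  # per-trial signal and differ only by the configured lag
  dvn <- if (stats::sd(dv) > 0) dv / stats::sd(dv) else dv
  Fb <- outer(dvn, buildup_ramp(times - params$feedback_lag))
  Mb <- outer(dvn, buildup_ramp(times))
  contra_left <- trials$hand_for_stronger == "right"  # left hemi contra to right hand
  latsign_left <- ifelse(contra_left, 0.5, -0.5)

  hemis <- c("left", "right")
  pow <- array(NA_real_,
               dim = c(n, length(roi_set), 2, length(freqs), length(times)),
               dimnames = list(NULL, roi_set, hemis, freqs, NULL))
  bl <- params$baseline_level(freqs)
  stopifnot(all(bl > 0))
  is_gamma <- freqs >= 40 & freqs <= 75
  is_low <- freqs <= 20
  with_seed(seed, {
    for (ri in seq_along(roi_set)) {
      type <- roi_type(roi_set[ri])
      for (hi in 1:2) {
        for (fi in seq_along(freqs)) {
          mod <- matrix(0, n, length(times))
          if (type == "visual") {
            if (is_gamma[fi]) {
              mod <- params$gamma_offset * stim_drive + params$gamma_gain * G
            }
            if (is_low[fi]) {
              mod <- mod + params$alpha_feedback_gain * Fb
            }
          } else {
            if (is_low[fi]) {
              ls <- if (hi == 1) latsign_left else -latsign_left
              mod <- params$motor_buildup_gain * (ls * Mb)
            }
          }
          mod[, times < 0] <- 0
          mod <- pmax(mod, -0.95)
          noise <- if (params$noise_sdlog > 0) {
            exp(matrix(stats::rnorm(n * length(times),
                                    -params$noise_sdlog^2 / 2,
                                    params$noise_sdlog),
                       n, length(times)))
          } else 1
          pow[, ri, hi, fi, ] <- bl[fi] * (1 + mod) * noise
        }
      }
    }
  })
  structure(list(power = pow, trial_ids = trials$trial,
                 rois = roi_set, hemis = hemis,
                 freqs = freqs, times = times, units = "raw"),
            class = "power_tensor")
}
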