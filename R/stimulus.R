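#' Stimulus specification for the drifting circular grating
#'
#' The test and reference stimuli are expanding or contracting circular
#' gratings. Pixel intensity is a sinusoidal function of eccentricity d:
#' a blending value a = 1/2 + 1/2 sin(pi (d - s) / (2 r)) mixes two gray
#' levels 0.5 -/+ c/2, where c is the Michelson contrast of the grating and
#' r sets the spatial period (4 r degrees per cycle). Varying the phase
#' parameter s over frames drifts the rings radially. An inner annulus is
#' uniform mid-gray, and the grating is truncated at the screen border.
#'
#' @param spatial_param_r spatial-frequency parameter r in degrees
#'   (period of the grating is 4 r).
#' @param drift_speed radial drift speed in degrees per second.
#' @param annulus_radius radius of the uniform gray inner annulus, degrees.
#' @param truncation_radius outer truncation radius, degrees.
#' @param frame_rate display frame rate, Hz.
#' @param direction "expand" or "contract".
#' @param pixels_per_degree rendering resolution.
#' @return object of class "stimulus_spec".
#' @export
stimulus_spec <- function(spatial_param_r = 0.75,
                          drift_speed = 4 / 3,
                          annulus_radius = 1.5,
                          truncation_radius = 11.3,
                          frame_rate = 60,
                          direction = c("expand", "contract"),
                          pixels_per_degree = 24) {
  direction <- match.arg(direction)
  stopifnot(spatial_param_r > 0, annulus_radius > 0, truncation_radius > 0,
            annulus_radius < truncation_radius, frame_rate > 0,
            drift_speed > 0, pixels_per_degree > 0)
  structure(list(spatial_param_r = spatial_param_r,
                 drift_speed = drift_speed,
                 annulus_radius = annulus_radius,
                 truncation_radius = truncation_radius,
                 frame_rate = frame_rate,
                 direction = direction,
                 pixels_per_degree = pixels_per_degree),
            class = "stimulus_spec")
}

# Blending value at eccentricity d (degrees) for phase s.
blend_value <- function(d, s, r) {
  0.5 + 0.5 * sin(pi * (d - s) / (2 * r))
}

#' Render one stimulus frame
#'
#' Returns a square intensity field in [0, 1]. Pixels inside the inner
#' annulus are exactly 0.5; pixels outside are the two gray levels
#' 0.5 - c/2 and 0.5 + c/2 blended by the sinusoidal value, so the
#' Michelson contrast of the grating region equals \code{contrast}.
#' Pixels beyond the truncation radius are set to 0.5 (screen border).
#'
#' @param spec a \code{\link{stimulus_spec}}.
#' @param contrast Michelson contrast in [0, 1].
#' @param phase_s phase parameter s in degrees.
#' @param n_px optional grid side length in pixels; defaults to covering
#'   the truncation radius at \code{spec$pixels_per_degree}.
#' @return matrix of intensities with attribute "eccentricity" (matrix of
#'   pixel eccentricities in degrees).
#' @export
render_frame <- function(spec, contrast, phase_s, n_px = NULL) {
  stopifnot(inherits(spec, "stimulus_spec"))
  if (!is.finite(phase_s)) stop("phase_s must be finite")
  if (!is.finite(contrast) || contrast < 0 || contrast > 1) {
    stop("contrast must lie in [0, 1]")
  }
  if (is.null(n_px)) {
    n_px <- 2L * ceiling(spec$truncation_radius * spec$pixels_per_degree) + 1L
  }
  half <- spec$truncation_radius
  ax <- seq(-half, half, length.out = n_px)
  d <- sqrt(outer(ax^2, ax^2, `+`))
  a <- blend_value(d, phase_s, spec$spatial_param_r)
  l <- a * (0.5 - contrast / 2) + (1 - a) * (0.5 + contrast / 2)
  l[d < spec$annulus_radius] <- 0.5
  l[d > spec$truncation_radius] <- 0.5
  attr(l, "eccentricity") <- d
  l
}

#' Advance the grating phase by a number of frames
#'
#' The phase increment is direction_sign * drift_speed * n_frames /
#' frame_rate; iso-intensity contours (fixed d - s) drift radially at
#' \code{drift_speed} degrees per second, outward for "expand".
#'
#' @param spec a \code{\link{stimulus_spec}}.
#' @param phase_s current phase in degrees.
#' @param n_frames number of frames to advance (>= 0).
#' @return new phase in degrees.
#' @export
advance_phase <- function(spec, phase_s, n_frames) {
  stopifnot(inherits(spec, "stimulus_spec"), n_frames >= 0)
  sgn <- if (spec$direction == "expand") 1 else -1
  phase_s + sgn * spec$drift_speed * n_frames / spec$frame_rate
}

#' Michelson contrast of a rendered frame region
#'
#' (max - min) / (max + min) of intensities over pixels with eccentricity
#' between the annulus and truncation radii.
#'
#' @param frame output of \code{\link{render_frame}}.
#' @param spec the spec used to render it.
#' @return scalar Michelson contrast.
#' @export
frame_michelson <- function(frame, spec) {
  d <- attr(frame, "eccentricity")
  if (is.null(d)) stop("frame lacks eccentricity metadata; use render_frame()")
  v <- frame[d >= spec$annulus_radius & d <= spec$truncation_radius]
  (max(v) - min(v)) / (max(v) + min(v))
}
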