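#' QUEST adaptive staircase
#'
#' Bayesian adaptive placement of the test-stimulus contrast offset,
#' targeting a fixed proportion correct (default 75%). The staircase keeps
#' a posterior over the log10 contrast-offset threshold of an assumed
#' Weibull psychometric function
#'   P(correct | x, T) = g + (1 - g - l) * (1 - exp(-10^(b (x - T)))),
#' updates it by Bayes rule after each trial, and proposes the next test
#' intensity from the posterior mean of T (QUEST mean rule) shifted so the
#' assumed function predicts the target accuracy at the proposed level.
#'
#' @param grid log10 contrast-offset grid for the threshold posterior.
#' @param prior_mean,prior_sd Gaussian prior on the log10 threshold.
#' @param assumed_slope Weibull slope b.
#' @param guess_rate lower asymptote g (0.5 for a two-choice task).
#' @param lapse_rate lapse probability l.
#' @param target_accuracy proportion correct the staircase converges to;
#'   must lie in (guess_rate, 1 - lapse_rate).
#' @return object of class "quest_state".
#' @export
quest_state <- function(grid = seq(-3, -0.3, length.out = 121),
                        prior_mean = -1, prior_sd = 1,
                        assumed_slope = 3.5,
                        guess_rate = 0.5,
                        lapse_rate = 0.02,
                        target_accuracy = 0.75) {
  stopifnot(all(diff(grid) > 0),
            target_accuracy > guess_rate,
            target_accuracy < 1 - lapse_rate)
  posterior <- stats::dnorm(grid, prior_mean, prior_sd)
  posterior <- posterior / sum(posterior)
  structure(list(grid = grid, posterior = posterior,
                 assumed_slope = assumed_slope,
                 guess_rate = guess_rate, lapse_rate = lapse_rate,
                 target_accuracy = target_accuracy,
                 degenerate = FALSE),
            class = "quest_state")
}

#' Assumed Weibull psychometric function (QUEST form)
#'
#' @param x log10 test intensity.
#' @param threshold log10 threshold T.
#' @param slope,guess,lapse psychometric parameters.
#' @return probability of a correct response.
#' @export
quest_weibull <- function(x, threshold, slope = 3.5, guess = 0.5, lapse = 0.02) {
  guess + (1 - guess - lapse) * (1 - exp(-10^(slope * (x - threshold))))
}

# Offset from threshold at which the assumed function hits target accuracy.
quest_epsilon <- function(state) {
  p <- (state$target_accuracy - state$guess_rate) /
    (1 - state$guess_rate - state$lapse_rate)
  log10(-log(1 - p)) / state$assumed_slope
}

#' Propose the next test intensity
#'
#' Posterior-mean threshold plus the fixed offset that maps threshold to
#' the target-accuracy point of the assumed psychometric function.
#'
#' @param state a \code{\link{quest_state}}.
#' @return log10 contrast offset to show next.
#' @export
quest_propose <- function(state) {
  stopifnot(inherits(state, "quest_state"))
  sum(state$grid * state$posterior) + quest_epsilon(state)
}

#' Update the staircase posterior after one trial
#'
#' @param state a \code{\link{quest_state}}.
#' @param shown_offset log10 contrast offset actually shown.
#' @param correct logical outcome.
#' @return updated \code{quest_state}; the \code{degenerate} flag is set if
#'   essentially all posterior mass sits on one grid edge.
#' @export
quest_update <- function(state, shown_offset, correct) {
  stopifnot(inherits(state, "quest_state"), is.logical(correct))
  p <- quest_weibull(shown_offset, state$grid, state$assumed_slope,
                     state$guess_rate, state$lapse_rate)
  lik <- if (correct) p else 1 - p
  post <- state$posterior * lik
  s <- sum(post)
  if (s <= 0) stop("degenerate likelihood: posterior mass vanished")
  state$posterior <- post / s
  edge <- state$posterior[1] > 0.999 ||
    state$posterior[length(state$posterior)] > 0.999
  if (edge) {
    state$degenerate <- TRUE
    warning("QUEST posterior collapsed onto a grid edge")
  }
  state
}

#' Run the staircase against a simulated Weibull observer
#'
#' Utility for convergence checks: the observer responds correctly with
#' probability given by \code{\link{quest_weibull}} at its true threshold.
#'
#' @param n_trials number of trials.
#' @param true_threshold observer log10 threshold.
#' @param seed integer seed (required).
#' @param state initial \code{\link{quest_state}}.
#' @param observer_slope,observer_guess,observer_lapse observer parameters
#'   (defaults mirror the staircase's assumed function).
#' @return data.frame with columns trial, shown_offset, correct.
#' @export
quest_simulate <- function(n_trials, true_threshold, seed,
                           state = quest_state(),
                           observer_slope = state$assumed_slope,
                           observer_guess = state$guess_rate,
                           observer_lapse = state$lapse_rate) {
  with_seed(seed, {
    shown <- numeric(n_trials)
    correct <- logical(n_trials)
    for (i in seq_len(n_trials)) {
      x <- quest_propose(state)
      x <- min(max(x, state$grid[1]), state$grid[length(state$grid)])
      p <- quest_weibull(x, true_threshold, observer_slope,
                         observer_guess, observer_lapse)
      ok <- stats::runif(1) < p
      state <- quest_update(state, x, ok)
      shown[i] <- x
      correct[i] <- ok
    }
    data.frame(trial = seq_len(n_trials), shown_offset = shown,
               correct = correct)
  })
}
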