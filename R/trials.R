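#' Observer parameters for the weighted-accumulator model
#'
#' The synthetic observer forms a decision variable
#'   DV = sum_i w_i (c_i - 0.5) + Normal(0, internal_noise_sd),
#' chooses "stronger" iff DV > 0 (flipped with probability
#' \code{lapse_rate}), reports high confidence iff |DV| exceeds
#' \code{confidence_criterion}, and draws its reaction time from a shifted
#' lognormal independent of the decision. The default weights decay
#' exponentially over sample position (primacy), the empirical signature of
#' early samples carrying more weight on choice.
#'
#' @param weights ten evidence weights.
#' @param internal_noise_sd SD of additive decision noise (DV units).
#' @param confidence_criterion |DV| criterion separating high from low
#'   confidence.
#' @param lapse_rate probability of a random response flip, in [0, 0.1].
#' @param rt_shift,rt_meanlog,rt_sdlog shifted-lognormal RT parameters
#'   (seconds from test offset). Defaults put ~5% of mass below 1.225 s so
#'   the fast-RT exclusion rule has work to do.
#' @return object of class "observer_params".
#' @export
observer_params <- function(weights = exp(-0.15 * (0:9)),
                            internal_noise_sd = 0.25,
                            confidence_criterion = 0.3,
                            lapse_rate = 0.02,
                            rt_shift = 0.8,
                            rt_meanlog = -0.28,
                            rt_sdlog = 0.35) {
  stopifnot(length(weights) == 10, all(is.finite(weights)),
            internal_noise_sd >= 0,
            lapse_rate >= 0, lapse_rate <= 0.1)
  structure(list(weights = weights,
                 internal_noise_sd = internal_noise_sd,
                 confidence_criterion = confidence_criterion,
                 lapse_rate = lapse_rate,
                 rt_shift = rt_shift, rt_meanlog = rt_meanlog,
                 rt_sdlog = rt_sdlog),
            class = "observer_params")
}

#' Draw the ten contrast samples of one trial
#'
#' Samples are i.i.d. Normal(0.5 +/- mean_offset, sd_level), the sign set
#' by the stimulus category, with per-sample rejection resampling until
#' each value lies in [0, 1] (resampling preserves the nominal mean better
#' than clipping would).
#'
#' @param mean_offset contrast offset of the trial mean from the 0.5
#'   reference (Michelson units, >= 0).
#' @param sd_level within-trial sample SD; one of the configured noise
#'   levels (0 is allowed for degenerate test cases).
#' @param category "stronger" or "weaker".
#' @param seed integer seed (required).
#' @return numeric vector of 10 contrasts in [0, 1].
#' @export
sample_trial_contrasts <- function(mean_offset, sd_level, category, seed) {
  category <- match.arg(category, c("stronger", "weaker"))
  mu <- 0.5 + if (category == "stronger") mean_offset else -mean_offset
  stopifnot(mu > 0, mu < 1, sd_level >= 0)
  with_seed(seed, draw_contrasts(mu, sd_level))
}

# Vectorized rejection sampler used internally (assumes RNG already seeded).
draw_contrasts <- function(mu, sd_level, n = 10) {
  if (sd_level == 0) return(rep(mu, n))
  x <- stats::rnorm(n, mu, sd_level)
  bad <- which(x < 0 | x > 1)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mu, sd_level)
    bad <- bad[x[bad] < 0 | x[bad] > 1]
  }
  x
}

#' Simulate one observer response
#'
#' @param contrasts ten sample contrasts in [0, 1].
#' @param params an \code{\link{observer_params}}.
#' @param seed integer seed (required).
#' @return list with choice ("stronger"/"weaker"), confidence
#'   ("high"/"low"), rt (seconds from test offset) and dv (realized
#'   decision variable, before any lapse flip).
#' @export
simulate_observer <- function(contrasts, params, seed) {
  stopifnot(inherits(params, "observer_params"),
            length(contrasts) == 10,
            all(contrasts >= 0 & contrasts <= 1))
  with_seed(seed, observer_response(contrasts, params))
}

observer_response <- function(contrasts, params) {
  dv <- sum(params$weights * (contrasts - 0.5)) +
    stats::rnorm(1, 0, params$internal_noise_sd)
  choice <- if (dv > 0) "stronger" else "weaker"
  if (stats::runif(1) < params$lapse_rate) {
    choice <- if (choice == "stronger") "weaker" else "stronger"
  }
  confidence <- if (abs(dv) >= params$confidence_criterion) "high" else "low"
  rt <- params$rt_shift + stats::rlnorm(1, params$rt_meanlog, params$rt_sdlog)
  list(choice = choice, confidence = confidence, rt = rt, dv = dv)
}

#' Simulate one subject's session with the staircase in the loop
#'
#' Runs the QUEST staircase continuously: each trial's contrast offset is
#' the current staircase proposal, the stimulus category is a fair coin,
#' sample contrasts are drawn at a per-trial noise level chosen uniformly
#' from \code{sd_levels}, and the observer's correctness feeds the next
#' staircase update.
#'
#' @param subject subject identifier.
#' @param n_trials number of trials.
#' @param seed integer seed (required).
#' @param observer an \code{\link{observer_params}}.
#' @param sd_levels the within-trial noise levels to sample from.
#' @param hand_for_stronger which hand reports "stronger" for this subject
#'   ("left" or "right"; counterbalanced across subjects by the cohort
#'   wrapper).
#' @param staircase initial \code{\link{quest_state}}.
#' @return a trial table: data.frame with one row per trial and columns
#'   subject, trial, s01..s10, sd_level, trial_mean, stimulus_category,
#'   choice, confidence, rt, correct, response_hand, dv.
#' @export
simulate_subject <- function(subject, n_trials, seed,
                             observer = observer_params(),
                             sd_levels = c(0.05, 0.1, 0.15),
                             hand_for_stronger = "right",
                             staircase = quest_state()) {
  hand_for_stronger <- match.arg(hand_for_stronger, c("left", "right"))
  with_seed(seed, {
    smat <- matrix(NA_real_, n_trials, 10)
    sd_level <- sample(sd_levels, n_trials, replace = TRUE)
    category <- ifelse(stats::runif(n_trials) < 0.5, "stronger", "weaker")
    choice <- character(n_trials)
    confidence <- character(n_trials)
    rt <- numeric(n_trials)
    dv <- numeric(n_trials)
    st <- staircase
    for (i in seq_len(n_trials)) {
      x <- quest_propose(st)
      x <- min(max(x, st$grid[1]), st$grid[length(st$grid)])
      offset <- 10^x
      mu <- 0.5 + if (category[i] == "stronger") offset else -offset
      mu <- min(max(mu, 1e-3), 1 - 1e-3)
      smat[i, ] <- draw_contrasts(mu, sd_level[i])
      resp <- observer_response(smat[i, ], observer)
      choice[i] <- resp$choice
      confidence[i] <- resp$confidence
      rt[i] <- resp$rt
      dv[i] <- resp$dv
      st <- quest_update(st, x, resp$choice == category[i])
    }
    trial_mean <- rowMeans(smat)
    correct <- choice == category
    other_hand <- if (hand_for_stronger == "right") "left" else "right"
    response_hand <- ifelse(choice == "stronger", hand_for_stronger, other_hand)
    out <- data.frame(subject = subject, trial = seq_len(n_trials))
    colnames(smat) <- sprintf("s%02d", 1:10)
    out <- cbind(out, smat)
    out$sd_level <- sd_level
    out$trial_mean <- trial_mean
    out$stimulus_category <- category
    out$choice <- choice
    out$confidence <- confidence
    out$rt <- rt
    out$correct <- correct
    out$response_hand <- response_hand
    out$hand_for_stronger <- hand_for_stronger
    out$dv <- dv
    out
  })
}

#' Simulate a cohort of subjects
#'
#' @param n_subjects number of subjects (default 15).
#' @param n_trials trials per subject.
#' @param seed master seed; per-subject seeds are derived substreams.
#' @param observer shared \code{\link{observer_params}}.
#' @param sd_levels within-trial noise levels.
#' @return single trial table with all subjects stacked; the
#'   stronger-choice hand alternates across subjects (counterbalancing).
#' @export
simulate_cohort <- function(n_subjects = 15, n_trials = 500, seed,
                            observer = observer_params(),
                            sd_levels = c(0.05, 0.1, 0.15)) {
  tabs <- lapply(seq_len(n_subjects), function(s) {
    simulate_subject(subject = s, n_trials = n_trials,
                     seed = derive_seed(seed, paste0("trials:", s)),
                     observer = observer, sd_levels = sd_levels,
                     hand_for_stronger = if (s %% 2 == 1) "right" else "left")
  })
  do.call(rbind, tabs)
}

#' Extract the 10-column sample-contrast matrix from a trial table
#'
#' @param trials a trial table.
#' @return n_trials x 10 numeric matrix.
#' @export
contrast_matrix <- function(trials) {
  as.matrix(trials[, sprintf("s%02d", 1:10)])
}
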