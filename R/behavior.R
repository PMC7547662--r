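#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with ties counted 0.5 per pair.
#' Orientation: AUC > 0.5 means larger scores associate with the positive
#' class (default "stronger").
#'
#' @param scores numeric scores.
#' @param labels vector with exactly two classes.
#' @param positive the class treated as positive.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels, positive = "stronger") {
  stopifnot(length(scores) == length(labels))
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both label classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Signal-detection labels for each trial
#'
#' Hits and misses are stronger and weaker choices on trials whose test
#' mean was stronger than the reference; false alarms and correct rejects
#' are stronger and weaker choices on weaker-category trials. Crossing
#' stimulus category with choice in this way lets all later choice
#' contrasts factor the physical stimulus category out.
#'
#' @param trials a trial table with stimulus_category and choice columns.
#' @return factor with levels hit, miss, false_alarm, correct_reject;
#'   trials with a missing choice get NA (their count is reported via the
#'   "n_excluded" attribute).
#' @export
categorize_sdt <- function(trials) {
  cat_s <- trials$stimulus_category == "stronger"
  cho_s <- trials$choice == "stronger"
  lab <- ifelse(cat_s & cho_s, "hit",
         ifelse(cat_s & !cho_s, "miss",
         ifelse(!cat_s & cho_s, "false_alarm", "correct_reject")))
  lab[is.na(trials$choice)] <- NA
  out <- factor(lab, levels = c("hit", "miss", "false_alarm", "correct_reject"))
  attr(out, "n_excluded") <- sum(is.na(trials$choice))
  out
}

# Two-cell AUC averaging rule shared by psychophysical and neural kernels:
# AUC(hit vs miss) and AUC(false alarm vs correct reject) computed
# separately, then averaged. `values` is an n_trials x K matrix (sample
# positions or time bins).
kernel_auc <- function(values, trials) {
  sdt <- categorize_sdt(trials)
  strong_cat <- sdt %in% c("hit", "miss")
  weak_cat <- sdt %in% c("false_alarm", "correct_reject")
  K <- ncol(values)
  out <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    a1 <- tryCatch(
      roc_auc(values[strong_cat, k], trials$choice[strong_cat]),
      error = function(e) NA_real_)
    a2 <- tryCatch(
      roc_auc(values[weak_cat, k], trials$choice[weak_cat]),
      error = function(e) NA_real_)
    out[k] <- mean(c(a1, a2))
  }
  out
}

#' Psychophysical kernel
#'
#' Time course (over the ten sample positions) of the ROC-AUC relating
#' within-category contrast fluctuations to the subsequent choice: per
#' position, AUC(hit vs miss) and AUC(false alarm vs correct reject) are
#' computed separately and averaged. 0.5 means contrast fluctuations carry
#' no choice information; > 0.5 means larger contrasts precede "stronger"
#' choices. An empty SDT cell yields NA at every position (not imputed).
#'
#' @param trials one subject's trial table.
#' @return object of class "kernel_series": list with positions 1..10,
#'   auc values, and variant = "overall".
#' @export
psychophysical_kernel <- function(trials) {
  auc <- kernel_auc(contrast_matrix(trials), trials)
  structure(list(axis = 1:10, auc = auc, variant = "overall",
                 band = NULL, roi = NULL),
            class = "kernel_series")
}

#' Per-subject kernels for a cohort trial table
#'
#' @param trials stacked trial table with a subject column.
#' @param kernel_fn function(trials) -> kernel_series.
#' @return matrix subjects x positions of AUC values.
#' @export
cohort_kernels <- function(trials, kernel_fn = psychophysical_kernel) {
  subs <- sort(unique(trials$subject))
  out <- t(vapply(subs, function(s) {
    kernel_fn(trials[trials$subject == s, ])$auc
  }, numeric(length(kernel_fn(trials[trials$subject == subs[1], ])$auc))))
  rownames(out) <- subs
  out
}

#' OLS slope of a kernel over sample position
#'
#' Negative slopes indicate primacy (early samples weigh more on choice).
#'
#' @param series a "kernel_series" or numeric vector of AUC values.
#' @return slope in AUC units per sample position.
#' @export
kernel_slope <- function(series) {
  auc <- if (inherits(series, "kernel_series")) series$auc else series
  pos <- if (inherits(series, "kernel_series")) series$axis else seq_along(auc)
  ok <- !is.na(auc)
  if (sum(ok) < 2) stop("need at least 2 non-missing kernel positions")
  unname(stats::coef(stats::lm(auc[ok] ~ pos[ok]))[2])
}

# Stratified fold assignment: preserves class proportions per fold.
stratified_folds <- function(labels, n_folds, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    fold
  })
}

# Logistic fit with fallback to a tiny L2 ridge (1e-6 on z-scored
# predictors) if the ML fit separates or fails to converge.
safe_logreg <- function(X, y01) {
  fit <- suppressWarnings(stats::glm.fit(cbind(1, X), y01,
                                         family = stats::binomial()))
  sep <- !fit$converged || any(fit$fitted.values > 1 - 1e-10) ||
    any(fit$fitted.values < 1e-10)
  if (!sep) {
    co <- fit$coefficients
    co[is.na(co)] <- 0  # aliased/constant predictors carry no information
    return(list(coef = co, ridged = FALSE))
  }
  g <- glmnet::glmnet(X, y01, family = "binomial", alpha = 0,
                      lambda = 1e-6, standardize = TRUE)
  list(coef = c(as.numeric(g$a0), as.numeric(g$beta)), ridged = TRUE)
}

#' Logistic regression of choice on the ten sample contrasts
#'
#' Fits choice ~ logistic(b0 + sum_i b_i c_i) per subject with stratified
#' 5-fold cross-validation (stratified on choice); reports coefficients
#' from the full-data fit and the cross-validated prediction accuracy
#' averaged across folds. Because the staircase titrates accuracy to 75%,
#' the cross-validated accuracy of this model is itself bounded near 75%.
#'
#' @param trials one subject's trial table (>= 50 trials, both choices).
#' @param n_folds number of CV folds.
#' @param seed integer seed for fold assignment.
#' @return list with coefficients (b0, b1..b10), cv_accuracy, fold
#'   assignments, and a ridged flag (TRUE if a separation fallback was
#'   used).
#' @export
fit_choice_logreg <- function(trials, n_folds = 5, seed = 1) {
  X <- contrast_matrix(trials)
  y <- as.integer(trials$choice == "stronger")
  stopifnot(nrow(X) >= 50, length(unique(y)) == 2)
  fold <- stratified_folds(y, n_folds, seed)
  acc <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    m <- safe_logreg(X[tr, , drop = FALSE], y[tr])
    eta <- cbind(1, X[!tr, , drop = FALSE]) %*% m$coef
    acc[f] <- mean((eta > 0) == (y[!tr] == 1))
  }
  full <- safe_logreg(X, y)
  list(coefficients = stats::setNames(full$coef, c("b0", paste0("b", 1:10))),
       cv_accuracy = mean(acc), folds = fold, ridged = full$ridged)
}

#' Logistic regression of confidence on sample contrasts, per choice
#'
#' Same model and cross-validation as \code{\link{fit_choice_logreg}} but
#' predicting high vs low confidence, fitted separately within each choice.
#'
#' @param trials one subject's trial table.
#' @param n_folds number of CV folds.
#' @param seed integer seed.
#' @return named list with one fit per choice ("stronger", "weaker").
#' @export
fit_confidence_logreg <- function(trials, n_folds = 5, seed = 1) {
  out <- list()
  for (ch in c("stronger", "weaker")) {
    sub <- trials[trials$choice == ch, ]
    X <- contrast_matrix(sub)
    y <- as.integer(sub$confidence == "high")
    if (nrow(X) < 50 || length(unique(y)) < 2) {
      out[[ch]] <- NULL
      next
    }
    fold <- stratified_folds(y, n_folds, derive_seed(seed, ch))
    acc <- numeric(n_folds)
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      m <- safe_logreg(X[tr, , drop = FALSE], y[tr])
      eta <- cbind(1, X[!tr, , drop = FALSE]) %*% m$coef
      acc[f] <- mean((eta > 0) == (y[!tr] == 1))
    }
    full <- safe_logreg(X, y)
    out[[ch]] <- list(
      coefficients = stats::setNames(full$coef, c("b0", paste0("b", 1:10))),
      cv_accuracy = mean(acc), folds = fold, ridged = full$ridged)
  }
  out
}

#' Exclude fast reaction times
#'
#' Removes trials with rt strictly below the threshold ("faster than" read
#' strictly: a boundary RT is kept). The number removed is attached as the
#' "n_excluded" attribute.
#'
#' @param trials a trial table with an rt column (seconds from test
#'   offset).
#' @param threshold seconds; default 1.225.
#' @return filtered trial table.
#' @export
exclude_fast_rts <- function(trials, threshold = 1.225) {
  stopifnot("rt" %in% names(trials))
  keep <- trials$rt >= threshold
  out <- trials[keep, , drop = FALSE]
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Movement-contamination-free decoding boundary
#'
#' With reaction times below \code{rt_threshold} excluded and a spectral
#' estimation window of \code{window} seconds, decoding up to
#' rt_threshold - window/2 after stimulus onset cannot be contaminated by
#' movement execution: 1.225 - 0.25/2 = 1.1 s with the defaults.
#'
#' @param rt_threshold fast-RT exclusion threshold, seconds.
#' @param window maximum spectral-estimation window length, seconds.
#' @return boundary time in seconds.
#' @export
contamination_free_boundary <- function(rt_threshold = 1.225, window = 0.25) {
  rt_threshold - window / 2
}
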