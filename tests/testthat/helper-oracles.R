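# Independent oracles used across the suite. These deliberately use
# different algorithms from the package implementations.

# AUC by exhaustive pair counting (ties = 0.5 per pair).
brute_auc <- function(scores, labels, positive = "stronger") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  s <- 0
  for (a in pos) for (b in neg) {
    s <- s + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  s / (length(pos) * length(neg))
}

# AUC via the explicit ROC curve and trapezoidal integration.
trapezoid_auc <- function(scores, labels, positive = "stronger") {
  ths <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  pos <- labels == positive
  tpr <- vapply(ths, function(h) mean(scores[pos] >= h), numeric(1))
  fpr <- vapply(ths, function(h) mean(scores[!pos] >= h), numeric(1))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Psychophysical kernel via the explicit-ROC oracle.
brute_kernel <- function(trials) {
  C <- as.matrix(trials[, sprintf("s%02d", 1:10)])
  strong <- trials$stimulus_category == "stronger"
  vapply(1:10, function(i) {
    a1 <- trapezoid_auc(C[strong, i], trials$choice[strong])
    a2 <- trapezoid_auc(C[!strong, i], trials$choice[!strong])
    (a1 + a2) / 2
  }, numeric(1))
}

# TFCE by an explicit threshold loop with its own component labelling
# (scan-line union on vectors; row/column merge on matrices).
brute_tfce <- function(stat, H = 2, E = 0.5, dh = NULL) {
  x <- as.numeric(stat)
  dims <- if (is.matrix(stat)) dim(stat) else length(x)
  mx <- max(abs(x))
  if (mx == 0) return(stat * 0)
  if (is.null(dh)) dh <- mx / 100
  comp_sizes <- function(mask) {
    if (length(dims) == 1) {
      lab <- cumsum(c(mask[1], diff(mask) == 1)) * mask
    } else {
      m <- matrix(mask, dims[1], dims[2])
      lab <- matrix(0L, dims[1], dims[2])
      nxt <- 0L
      for (j in seq_len(dims[2])) for (i in seq_len(dims[1])) {
        if (!m[i, j]) next
        up <- if (i > 1) lab[i - 1, j] else 0L
        left <- if (j > 1) lab[i, j - 1] else 0L
        if (up == 0L && left == 0L) {
          nxt <- nxt + 1L; lab[i, j] <- nxt
        } else if (up != 0L && (left == 0L || left == up)) {
          lab[i, j] <- up
        } else if (up == 0L) {
          lab[i, j] <- left
        } else {
          lab[i, j] <- up
          lab[lab == left] <- up
        }
      }
      lab <- as.integer(lab)
    }
    list(lab = lab, size = as.numeric(table(factor(lab[lab > 0]))),
         ids = sort(unique(lab[lab > 0])))
  }
  enh <- numeric(length(x))
  for (sgn in c(1, -1)) {
    v <- sgn * x
    if (max(v) <= 0) next
    for (h in seq(dh, max(v), by = dh)) {
      cs <- comp_sizes(v >= h)
      for (k in seq_along(cs$ids)) {
        idx <- which(cs$lab == cs$ids[k])
        enh[idx] <- enh[idx] + sgn * length(idx)^E * h^H * dh
      }
    }
  }
  if (is.matrix(stat)) matrix(enh, dims[1], dims[2]) else enh
}

# Minimal trial table with given contrasts/categories/choices.
toy_trials <- function(contrasts, category, choice, subject = 1) {
  n <- nrow(contrasts)
  colnames(contrasts) <- sprintf("s%02d", 1:10)
  df <- data.frame(subject = subject, trial = seq_len(n))
  df <- cbind(df, as.data.frame(contrasts))
  df$sd_level <- 0.1
  df$trial_mean <- rowMeans(contrasts)
  df$stimulus_category <- category
  df$choice <- choice
  df$confidence <- "high"
  df$rt <- 1.5
  df$correct <- category == choice
  df$response_hand <- ifelse(choice == "stronger", "right", "left")
  df$hand_for_stronger <- "right"
  df
}

# Random trial table with choices independent of contrasts (null world).
null_trials <- function(n, seed, subject = 1) {
  set.seed(seed)
  contrasts <- matrix(runif(n * 10, 0.3, 0.7), n, 10)
  category <- ifelse(runif(n) < 0.5, "stronger", "weaker")
  choice <- ifelse(runif(n) < 0.5, "stronger", "weaker")
  toy_trials(contrasts, category, choice, subject)
}
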