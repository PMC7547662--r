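# Multivariate decoding of choice and contrast from ROI spectral patterns.

# z-score columns using training statistics only; zero-variance columns are
# centered and left unscaled.
ztrain <- function(Xtr, Xte) {
  mu <- colMeans(Xtr)
  sd <- apply(Xtr, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(tr = sweep(sweep(Xtr, 2, mu), 2, sd, "/"),
       te = sweep(sweep(Xte, 2, mu), 2, sd, "/"))
}

# Upsample the minority class by random repetition until the classes are
# balanced (training data only).
upsample_minority <- function(idx, labels, seed) {
  tab <- table(labels[idx])
  if (length(tab) < 2 || tab[1] == tab[2]) return(idx)
  minority <- names(tab)[which.min(tab)]
  need <- abs(diff(as.integer(tab)))
  pool <- idx[labels[idx] == minority]
  extra <- with_seed(seed, sample(pool, need, replace = TRUE))
  c(idx, extra)
}

# Linear SVM AUC on one train/test split; decision-value orientation is
# read off the decision-value column name.
svm_fold_auc <- function(Xtr, ytr, Xte, yte, cost = 1) {
  fit <- e1071::svm(Xtr, factor(ytr), kernel = "linear", cost = cost,
                    scale = FALSE)
  dv <- attr(stats::predict(fit, Xte, decision.values = TRUE),
             "decision.values")
  pos <- strsplit(colnames(dv), "/")[[1]][1]
  roc_auc(as.numeric(dv), yte, positive = pos)
}

#' Decode choice from the regional spectral power pattern
#'
#' For each time bin (and, by default, separately per stimulus category so
#' decoders separate correct choices from errors within category):
#' features are the percent-change power values at the decoding
#' frequencies from both hemispheres; features are z-scored on training
#' folds only; the minority choice is upsampled in the training set by
#' random repetition; a linear SVM (C = 1) is trained and ROC-AUC computed
#' from its decision values on the held-out fold; AUCs are averaged over
#' folds, then over categories. Folds are stratified on choice. A fold in
#' which one class is absent is skipped.
#'
#' @param tensor a "power_tensor" with both hemispheres (percent-change
#'   units recommended).
#' @param trials matching trial table.
#' @param roi ROI to decode from.
#' @param seed integer seed (folds, upsampling).
#' @param times time bins to decode (default: all epoch bins).
#' @param per_category decode separately per stimulus category.
#' @param n_folds cross-validation folds (default 10).
#' @param freq_range feature frequency range, Hz (default 1-145).
#' @param cost SVM regularization C.
#' @return data.frame with columns time and auc.
#' @export
decode_choice_spectral <- function(tensor, trials, roi, seed,
                                   times = NULL, per_category = TRUE,
                                   n_folds = 10, freq_range = c(1, 145),
                                   cost = 1) {
  stopifnot(inherits(tensor, "power_tensor"), length(dim(tensor$power)) == 5)
  ridx <- match(roi, tensor$rois)
  if (is.na(ridx)) stop("unknown ROI: ", roi)
  fmask <- tensor$freqs >= freq_range[1] & tensor$freqs <= freq_range[2]
  if (is.null(times)) times <- tensor$times
  tidx <- vapply(times, function(t) nearest_time_bin(tensor$times, t), 1L)
  groups <- if (per_category) c("stronger", "weaker") else "all"
  auc_t <- numeric(length(tidx))
  for (k in seq_along(tidx)) {
    ti <- tidx[k]
    X_all <- cbind(tensor$power[, ridx, 1, fmask, ti],
                   tensor$power[, ridx, 2, fmask, ti])
    aucs <- c()
    for (g in groups) {
      rows <- if (g == "all") seq_len(nrow(trials)) else
        which(trials$stimulus_category == g)
      y <- trials$choice[rows]
      if (length(unique(y)) < 2 || min(table(y)) < n_folds) next
      fold <- stratified_folds(y, n_folds, derive_seed(seed, paste0(g, ":fold")))
      fa <- c()
      for (f in seq_len(n_folds)) {
        tr <- which(fold != f); te <- which(fold == f)
        if (length(unique(y[tr])) < 2 || length(unique(y[te])) < 2) next
        tr_up <- upsample_minority(tr, y, derive_seed(seed, paste0(g, ":up", f, ":t", k)))
        z <- ztrain(X_all[rows[tr_up], , drop = FALSE],
                    X_all[rows[te], , drop = FALSE])
        fa <- c(fa, svm_fold_auc(z$tr, y[tr_up], z$te, y[te], cost))
      }
      if (length(fa) > 0) aucs <- c(aucs, mean(fa))
    }
    auc_t[k] <- if (length(aucs) > 0) mean(aucs) else NA_real_
  }
  data.frame(time = tensor$times[tidx], auc = auc_t)
}

#' Fine-grained choice decoding with dimensionality reduction
#'
#' Decoding pipeline for high-dimensional (vertex-level) features, fitted
#' per fold on training data only: z-score, PCA retaining components up to
#' 95% cumulative variance, sparse feature selection by an L1-penalized
#' linear classifier (penalty scale C = 10 / n_features) pruning weights
#' with |w| < 1e-5, and a final linear SVM (C = 1/2) on the surviving
#' components. One decoder is trained across both stimulus categories.
#'
#' @param X trials x features matrix.
#' @param labels choice labels.
#' @param seed integer seed.
#' @param n_folds folds (default 10).
#' @param var_keep cumulative variance retained by PCA.
#' @param prune_tol weight pruning threshold.
#' @return list with auc (fold-averaged), n_kept (selected features per
#'   fold) and fallback (folds where pruning removed everything and all
#'   PCA components were used instead).
#' @export
decode_choice_finegrained <- function(X, labels, seed, n_folds = 10,
                                      var_keep = 0.95, prune_tol = 1e-5) {
  y <- labels
  fold <- stratified_folds(y, n_folds, derive_seed(seed, "fg:fold"))
  aucs <- c(); kept <- c(); fallback <- 0L
  for (f in seq_len(n_folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    if (length(unique(y[tr])) < 2 || length(unique(y[te])) < 2) next
    tr_up <- upsample_minority(tr, y, derive_seed(seed, paste0("fg:up", f)))
    z <- ztrain(X[tr_up, , drop = FALSE], X[te, , drop = FALSE])
    pc <- stats::prcomp(z$tr, center = FALSE, scale. = FALSE)
    cumvar <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    ncomp <- max(1, which(cumvar >= var_keep)[1])
    Ptr <- pc$x[, seq_len(ncomp), drop = FALSE]
    Pte <- z$te %*% pc$rotation[, seq_len(ncomp), drop = FALSE]
    # sparse selection: L1-penalized linear classifier at the C = 10/p scale
    lam <- ncol(X) / (10 * nrow(Ptr))
    g <- glmnet::glmnet(Ptr, factor(y[tr_up]), family = "binomial",
                        alpha = 1, lambda = lam, standardize = FALSE)
    w <- as.numeric(g$beta)
    sel <- which(abs(w) >= prune_tol)
    if (length(sel) == 0) {
      sel <- seq_len(ncomp)
      fallback <- fallback + 1L
    }
    aucs <- c(aucs, svm_fold_auc(Ptr[, sel, drop = FALSE], y[tr_up],
                                 Pte[, sel, drop = FALSE], y[te],
                                 cost = 0.5))
    kept <- c(kept, length(sel))
  }
  list(auc = mean(aucs), n_kept = kept, fallback = fallback)
}

#' Remove linear leakage of one region from another
#'
#' Per frequency, predicts the target region's power from the source
#' region's power by OLS (with intercept) and returns the residuals; the
#' residuals are exactly orthogonal to the source on the fitting set. A
#' constant source yields the centered target.
#'
#' @param target,source trials x frequency matrices (or trials x frequency
#'   x time arrays) with matched trials.
#' @return residual target, same shape.
#' @export
remove_region_leakage <- function(target, source) {
  if (length(dim(target)) == 3) {
    out <- target
    for (ti in seq_len(dim(target)[3])) {
      out[, , ti] <- remove_region_leakage(target[, , ti], source[, , ti])
    }
    return(out)
  }
  target <- as.matrix(target); source <- as.matrix(source)
  stopifnot(nrow(target) == nrow(source), ncol(target) == ncol(source))
  out <- target
  for (fi in seq_len(ncol(target))) {
    s <- source[, fi]
    if (stats::sd(s) == 0) {
      out[, fi] <- target[, fi] - mean(target[, fi])
    } else {
      out[, fi] <- stats::residuals(stats::lm(target[, fi] ~ s))
    }
  }
  out
}

# Closed-form ridge on centered variables: penalty alpha * ||beta||^2.
ridge_solve <- function(X, y, alpha) {
  p <- ncol(X)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  beta <- solve(crossprod(Xc) + diag(alpha, p), crossprod(Xc, y - ym))
  list(beta = beta, intercept = ym - sum(xm * beta))
}

#' Ridge decoding of a continuous target
#'
#' Predicts a continuous target (e.g. the contrast of sample i, or the
#' running mean of contrasts up to sample i) from a feature matrix with
#' 10-fold cross-validation. Features are z-scored on training data only;
#' the ridge penalty is selected from \code{lambda_grid} by nested inner
#' cross-validation (maximizing inner-fold Pearson correlation). The score
#' is the Pearson correlation between held-out predictions and true
#' targets, averaged over outer folds.
#'
#' @param X trials x features matrix.
#' @param y continuous target (non-constant).
#' @param seed integer seed.
#' @param n_folds outer folds.
#' @param lambda_grid candidate penalties.
#' @param inner_folds inner folds for penalty selection.
#' @return list with r (fold-averaged Pearson correlation), per_fold, and
#'   chosen lambdas.
#' @export
decode_contrast <- function(X, y, seed, n_folds = 10,
                            lambda_grid = c(0.1, 1, 10), inner_folds = 3) {
  if (stats::sd(y) == 0) stop("constant target: correlation undefined")
  n <- nrow(X)
  fold <- with_seed(derive_seed(seed, "ridge:fold"),
                    sample(rep_len(seq_len(n_folds), n)))
  rs <- c(); lams <- c()
  for (f in seq_len(n_folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    z <- ztrain(X[tr, , drop = FALSE], X[te, , drop = FALSE])
    lam <- if (length(lambda_grid) == 1) lambda_grid else {
      ifold <- with_seed(derive_seed(seed, paste0("ridge:in", f)),
                         sample(rep_len(seq_len(inner_folds), length(tr))))
      score <- vapply(lambda_grid, function(a) {
        ir <- c()
        for (g in seq_len(inner_folds)) {
          itr <- ifold != g; ite <- ifold == g
          if (stats::sd(y[tr][ite]) == 0) next
          m <- ridge_solve(z$tr[itr, , drop = FALSE], y[tr][itr], a)
          pred <- z$tr[ite, , drop = FALSE] %*% m$beta + m$intercept
          ir <- c(ir, stats::cor(pred, y[tr][ite]))
        }
        mean(ir)
      }, numeric(1))
      lambda_grid[which.max(score)]
    }
    m <- ridge_solve(z$tr, y[tr], lam)
    pred <- z$te %*% m$beta + m$intercept
    if (stats::sd(y[te]) > 0 && stats::sd(pred) > 0) {
      rs <- c(rs, stats::cor(as.numeric(pred), y[te]))
    }
    lams <- c(lams, lam)
  }
  list(r = mean(rs), per_fold = rs, lambda = lams)
}

#' Ridge decoding time course for one target
#'
#' Runs \code{\link{decode_contrast}} at each requested time bin using the
#' decoding-range spectral features of one ROI.
#'
#' @param tensor hemisphere-collapsed "power_tensor" (hemisphere-averaged
#'   for visual ROIs or lateralized for motor ROIs).
#' @param trials matching trial table.
#' @param roi ROI name.
#' @param target "sample" (contrast of sample i) or "accumulated" (running
#'   mean of contrasts up to sample i).
#' @param sample_i sample position (1..10).
#' @param seed integer seed.
#' @param times time bins to decode.
#' @param freq_range feature frequencies, Hz.
#' @param ... passed to \code{\link{decode_contrast}}.
#' @return data.frame with columns time and r.
#' @export
decode_contrast_timecourse <- function(tensor, trials, roi,
                                       target = c("sample", "accumulated"),
                                       sample_i, seed, times = NULL,
                                       freq_range = c(1, 145), ...) {
  target <- match.arg(target)
  stopifnot(inherits(tensor, "power_tensor"), length(dim(tensor$power)) == 4)
  ridx <- match(roi, tensor$rois)
  if (is.na(ridx)) stop("unknown ROI: ", roi)
  C <- contrast_matrix(trials)
  y <- if (target == "sample") C[, sample_i] else
    rowMeans(C[, seq_len(sample_i), drop = FALSE])
  fmask <- tensor$freqs >= freq_range[1] & tensor$freqs <= freq_range[2]
  if (is.null(times)) times <- tensor$times
  tidx <- vapply(times, function(t) nearest_time_bin(tensor$times, t), 1L)
  r <- vapply(seq_along(tidx), function(k) {
    X <- tensor$power[, ridx, fmask, tidx[k]]
    decode_contrast(X, y, derive_seed(seed, paste0("t", k)), ...)$r
  }, numeric(1))
  data.frame(time = tensor$times[tidx], r = r)
}

#' Upper envelope of per-sample decoding curves
#'
#' Pointwise maximum across sample-specific decoding time courses on a
#' common time grid; the summary curve traces peak decoding precision over
#' the trial.
#'
#' @param curves matrix (curves x time bins).
#' @return numeric vector, one value per time bin.
#' @export
envelope <- function(curves) {
  curves <- as.matrix(curves)
  if (nrow(curves) < 2) stop("need at least 2 curves")
  apply(curves, 2, max)
}

#' Contrast-encoding regression across frequencies
#'
#' For each frequency and sample position, the OLS slope of z-scored power
#' at the sample's extraction latency on the z-scored sample contrast;
#' with both variables standardized the slope equals the Pearson
#' correlation. Zero-variance power bins yield NA.
#'
#' @param sample_power trials x frequency x sample array of power at
#'   onset + latency.
#' @param contrasts trials x 10 contrast matrix.
#' @return list with beta1 (frequency x sample matrix of standardized
#'   slopes) and beta0 (always 0 for standardized inputs).
#' @export
encoding_regression <- function(sample_power, contrasts) {
  stopifnot(length(dim(sample_power)) == 3,
            dim(sample_power)[3] == ncol(contrasts))
  nf <- dim(sample_power)[2]; ns <- dim(sample_power)[3]
  beta1 <- matrix(NA_real_, nf, ns)
  for (fi in seq_len(nf)) for (si in seq_len(ns)) {
    p <- sample_power[, fi, si]
    if (stats::sd(p) == 0 || stats::sd(contrasts[, si]) == 0) next
    beta1[fi, si] <- stats::cor(p, contrasts[, si])
  }
  list(beta1 = beta1, beta0 = 0)
}
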