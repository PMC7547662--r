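# Group-level inference: hierarchical Bayesian AUC model, TFCE
# permutation tests, FDR correction, and thin t-test/ANOVA utilities.

#' Hierarchical Bayesian group model for AUC time courses
#'
#' Models each subject's AUC at time bin t as a draw from a Student-t
#' distribution, auc[s,t] ~ StudentT(mu_t, sigma_t, gamma), with priors
#' mu_t ~ Normal(0.5, 1), sigma_t ~ Uniform(0, 5) and
#' gamma ~ Exponential(mean 29) + 1 (gamma shared across time bins).
#' Sampled by MCMC (JAGS) with 2 chains x 3000 iterations; convergence is
#' gated on split-Rhat < 1.05 for every parameter.
#'
#' @param auc subjects x time matrix of AUC values (>= 3 subjects).
#' @param seed integer seed.
#' @param n_iter sampling iterations per chain.
#' @param n_adapt,n_burn adaptation and burn-in iterations.
#' @return list with summary (data.frame: time index, posterior mean of
#'   mu, 95% HDI bounds, sd), gamma_mean, rhat (named vector),
#'   rhat_ok flag, and draws (mcmc.list).
#' @export
group_auc_posterior <- function(auc, seed = 1, n_iter = 3000,
                                n_adapt = 500, n_burn = 500) {
  auc <- as.matrix(auc)
  stopifnot(nrow(auc) >= 3)
  model_str <- "
  model {
    for (s in 1:S) {
      for (t in 1:T) {
        auc[s, t] ~ dt(mu[t], tau[t], gamma)
      }
    }
    for (t in 1:T) {
      mu[t] ~ dnorm(0.5, 1)
      sigma[t] ~ dunif(0, 5)
      tau[t] <- pow(sigma[t], -2)
    }
    g0 ~ dexp(0.03448276)
    gamma <- g0 + 1
  }"
  dat <- list(auc = auc, S = nrow(auc), T = ncol(auc))
  inits <- lapply(1:2, function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = derive_seed(seed, paste0("chain", ch)),
         mu = rep(0.5, ncol(auc)), sigma = rep(0.1, ncol(auc)), g0 = 10)
  })
  jm <- rjags::jags.model(textConnection(model_str), data = dat,
                          inits = inits, n.chains = 2, n.adapt = n_adapt,
                          quiet = TRUE)
  stats::update(jm, n_burn, progress.bar = "none")
  draws <- rjags::coda.samples(jm, c("mu", "sigma", "gamma"), n_iter,
                               progress.bar = "none")
  gd <- coda::gelman.diag(draws, multivariate = FALSE, autoburnin = FALSE)
  rhat <- gd$psrf[, 1]
  rhat_ok <- all(is.finite(rhat) & rhat < 1.05)
  if (!rhat_ok) warning("split-Rhat >= 1.05 for some parameters")
  mat <- as.matrix(draws)
  mu_cols <- grep("^mu", colnames(mat))
  hdi <- coda::HPDinterval(coda::as.mcmc(mat[, mu_cols, drop = FALSE]),
                           prob = 0.95)
  summary <- data.frame(
    time = seq_len(ncol(auc)),
    mu_mean = colMeans(mat[, mu_cols, drop = FALSE]),
    mu_sd = apply(mat[, mu_cols, drop = FALSE], 2, stats::sd),
    hdi_lower = hdi[, 1], hdi_upper = hdi[, 2])
  list(summary = summary, gamma_mean = mean(mat[, "gamma"]),
       rhat = rhat, rhat_ok = rhat_ok, draws = draws)
}

# Connected components on a lattice: 1-D uses a 2-neighborhood (runs),
# 2-D a 4-neighborhood. `mask` is logical; returns integer labels (0 =
# background) and a vector of component sizes.
label_components <- function(mask, map_dim) {
  if (length(map_dim) == 1) {
    lab <- integer(length(mask))
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    cl <- 0L
    for (i in seq_along(r$values)) {
      if (r$values[i]) {
        cl <- cl + 1L
        lab[starts[i]:ends[i]] <- cl
      }
    }
    return(list(labels = lab, sizes = tabulate(lab, cl)))
  }
  m <- matrix(mask, map_dim[1], map_dim[2])
  lab <- matrix(0L, map_dim[1], map_dim[2])
  cl <- 0L
  for (j in seq_len(map_dim[2])) for (i in seq_len(map_dim[1])) {
    if (!m[i, j] || lab[i, j] != 0L) next
    cl <- cl + 1L
    queue <- matrix(c(i, j), 1)
    lab[i, j] <- cl
    while (nrow(queue) > 0) {
      cur <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ni <- cur[1] + d[1]; nj <- cur[2] + d[2]
        if (ni >= 1 && ni <= map_dim[1] && nj >= 1 && nj <= map_dim[2] &&
            m[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- cl
          queue <- rbind(queue, c(ni, nj))
        }
      }
    }
  }
  list(labels = as.integer(lab), sizes = tabulate(as.integer(lab), cl))
}

#' Threshold-free cluster enhancement
#'
#' TFCE(v) = sum over thresholds h (step dh, up to |stat(v)|) of
#' extent(v, h)^E * h^H * dh, where extent is the size of the
#' suprathreshold cluster containing v. Applied separately to the positive
#' and negative tails; the enhanced map carries the sign of the input.
#'
#' @param stat_map numeric vector or matrix (1-D: 2-neighborhood; 2-D:
#'   4-neighborhood).
#' @param H height exponent (default 2).
#' @param E extent exponent (default 0.5).
#' @param dh integration step; default max|stat|/100.
#' @return enhanced map, same shape as the input.
#' @export
tfce <- function(stat_map, H = 2, E = 0.5, dh = NULL) {
  if (!all(is.finite(stat_map))) stop("stat map must be finite")
  map_dim <- if (is.matrix(stat_map)) dim(stat_map) else length(stat_map)
  x <- as.numeric(stat_map)
  mx <- max(abs(x))
  if (mx == 0) return(stat_map * 0)
  if (is.null(dh)) dh <- mx / 100
  enh <- numeric(length(x))
  for (sgn in c(1, -1)) {
    v <- sgn * x
    top <- max(v)
    if (top <= 0) next
    hs <- seq(dh, top, by = dh)
    if (length(map_dim) == 1) {
      # fast path: run lengths give cluster extents directly
      for (h in hs) {
        r <- rle(v >= h)
        contrib <- rep.int(ifelse(r$values, r$lengths^E, 0), r$lengths)
        enh <- enh + sgn * h^H * dh * contrib
      }
    } else {
      for (h in hs) {
        comp <- label_components(v >= h, map_dim)
        inside <- comp$labels > 0L
        enh[inside] <- enh[inside] +
          sgn * comp$sizes[comp$labels[inside]]^E * h^H * dh
      }
    }
  }
  if (is.matrix(stat_map)) matrix(enh, map_dim[1], map_dim[2]) else enh
}

#' TFCE permutation test against zero
#'
#' One-sample, two-sided cluster test: the observed map of one-sample t
#' values across subjects is TFCE-enhanced; the null distribution of the
#' map-wise maximum |enhanced| statistic is built by randomly sign-flipping
#' each subject's map (valid under symmetric exchangeability about zero).
#' Corrected p per element is the rank of its |enhanced| value in the null
#' maximum distribution.
#'
#' @param data subjects x elements matrix (an element is a time bin, or a
#'   time x frequency cell if \code{map_dim} has length 2).
#' @param n_perm number of permutations (>= 500 recommended).
#' @param seed integer seed.
#' @param map_dim lattice shape of an element map; default 1-D.
#' @param H,E,dh TFCE parameters (dh defaults per map to max|t|/100).
#' @param alpha significance level for the mask.
#' @return list with t_map, enhanced, p (corrected, two-sided), mask
#'   (p < alpha) and the null max distribution.
#' @export
cluster_permutation_test <- function(data, n_perm = 1000, seed = 1,
                                     map_dim = NULL, H = 2, E = 0.5,
                                     dh = NULL, alpha = 0.05) {
  data <- as.matrix(data)
  n <- nrow(data)
  if (n_perm < 1 / alpha) stop("n_perm too small for requested alpha")
  if (is.null(map_dim)) map_dim <- ncol(data)
  tmap_of <- function(d) {
    m <- colMeans(d)
    s <- sqrt(pmax(colSums(d * d) - n * m^2, 0) / (n - 1))
    s[s == 0] <- Inf
    m / (s / sqrt(n))
  }
  shape <- function(v) if (length(map_dim) == 2)
    matrix(v, map_dim[1], map_dim[2]) else v
  tobs <- tmap_of(data)
  eobs <- as.numeric(tfce(shape(tobs), H, E, dh))
  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      flips <- sample(c(-1, 1), n, replace = TRUE)
      tp <- tmap_of(data * flips)
      max(abs(as.numeric(tfce(shape(tp), H, E, dh))))
    }, numeric(1))
  })
  p <- vapply(abs(eobs), function(e) (1 + sum(null_max >= e)) / (n_perm + 1),
              numeric(1))
  list(t_map = tobs, enhanced = eobs, p = p, mask = p < alpha,
       null_max = null_max)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up procedure controlling the false discovery rate at level q.
#'
#' @param p_values vector of p-values in [0, 1].
#' @param q FDR level.
#' @return logical rejection mask.
#' @export
fdr_correct <- function(p_values, q = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  stats::p.adjust(p_values, method = "BH") <= q
}

#' One-sample / paired t statistics (utility)
#'
#' @param x numeric sample (or differences).
#' @param y optional second sample for a paired test.
#' @param mu null value.
#' @return htest object from \code{stats::t.test}.
#' @export
t_test_util <- function(x, y = NULL, mu = 0) {
  if (length(x) < 2) stop("need n >= 2")
  if (!is.null(y)) {
    d <- x - y
    if (stats::sd(d) == 0 && mean(d) == mu) {
      # degenerate paired case: no deviation, no evidence
      return(structure(list(statistic = c(t = 0), p.value = 1,
                            estimate = mean(d), method = "Paired t-test"),
                       class = "htest"))
    }
    return(stats::t.test(x, y, paired = TRUE, mu = mu))
  }
  stats::t.test(x, mu = mu)
}

#' One-way ANOVA F (utility)
#'
#' Used for e.g. testing whether gamma-adaptation slopes differ across the
#' three within-trial noise levels.
#'
#' @param values numeric vector.
#' @param groups factor of group labels.
#' @return list with F, df1, df2, p.
#' @export
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  if (length(values) < 2 || nlevels(groups) < 2) stop("need >= 2 groups")
  fit <- stats::aov(values ~ groups)
  s <- summary(fit)[[1]]
  list(F = s$`F value`[1], df1 = s$Df[1], df2 = s$Df[2],
       p = s$`Pr(>F)`[1])
}
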