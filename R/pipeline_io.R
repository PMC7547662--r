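# Configuration, file formats and end-to-end orchestration.

TENSOR_SCHEMA_VERSION <- "1"

#' Write / read a trial table as TSV
#'
#' One row per trial; the ten sample contrasts occupy columns s01..s10.
#' Floats survive the round trip to better than 1e-12 (17 significant
#' digits).
#'
#' @param trials trial table.
#' @param path output file.
#' @return path, invisibly.
#' @export
write_trials <- function(trials, path) {
  df <- trials
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("subject", "trial", sprintf("s%02d", 1:10), "stimulus_category",
            "choice")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("trial table missing columns: ",
                             paste(miss, collapse = ", "))
  df
}

#' Write / read a power tensor
#'
#' Plain-text hierarchical container: a directory with meta.json (schema
#' version, dimensions, units flag, frequency/time grids, ROI and trial
#' identifiers) and power.txt (flat column-major values, one per line).
#'
#' @param tensor a "power_tensor".
#' @param dir output directory (created).
#' @return dir, invisibly.
#' @export
write_tensor <- function(tensor, dir) {
  stopifnot(inherits(tensor, "power_tensor"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(schema_version = TENSOR_SCHEMA_VERSION,
               dims = dim(tensor$power),
               units = tensor$units,
               rois = tensor$rois, hemis = tensor$hemis,
               freqs = tensor$freqs, times = tensor$times,
               trial_ids = tensor$trial_ids)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(sprintf("%.17g", as.numeric(tensor$power)),
             file.path(dir, "power.txt"))
  invisible(dir)
}

#' @rdname write_tensor
#' @export
read_tensor <- function(dir) {
  mpath <- file.path(dir, "meta.json")
  if (!file.exists(mpath)) stop("not a tensor container: missing meta.json")
  meta <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  if (is.null(meta$schema_version) ||
      meta$schema_version != TENSOR_SCHEMA_VERSION) {
    stop("tensor schema version mismatch: found ",
         meta$schema_version %||% "<none>", ", expected ",
         TENSOR_SCHEMA_VERSION)
  }
  if (is.null(meta$freqs)) stop("tensor schema error: missing freqs")
  vals <- as.numeric(readLines(file.path(dir, "power.txt")))
  if (length(vals) != prod(meta$dims)) {
    stop("truncated tensor payload: expected ", prod(meta$dims),
         " values, found ", length(vals))
  }
  structure(list(power = array(vals, dim = meta$dims),
                 trial_ids = meta$trial_ids, rois = meta$rois,
                 hemis = meta$hemis, freqs = meta$freqs,
                 times = meta$times, units = meta$units),
            class = "power_tensor")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write analysis results as JSON
#'
#' @param results named list.
#' @param path output file.
#' @return path, invisibly.
#' @export
write_results <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Bundles every stage's parameters with their standard defaults: 75%
#' staircase target, within-trial noise levels {0.05, 0.1, 0.15}, 190 ms
#' extraction latency, 150 ms feedback lag, 1.225 s fast-RT threshold,
#' lag grid within [-0.215, 0.215] s, SVM C = 1, ridge grid {0.1, 1, 10},
#' TFCE H = 2 / E = 0.5, and the Student-t model priors.
#'
#' @param seed master seed.
#' @param n_subjects cohort size.
#' @param n_trials trials per subject.
#' @param rois ROI set for the synthetic tensors.
#' @param observer an \code{\link{observer_params}}.
#' @param neural a \code{\link{neural_gen_params}}.
#' @param rt_threshold fast-RT exclusion threshold, seconds.
#' @param latency kernel/encoding extraction latency, seconds.
#' @param n_perm permutations for cluster tests.
#' @param bayes_iter MCMC iterations for the group AUC model (0 disables
#'   the Bayesian stage).
#' @param decode_times time bins for decoding time courses (default: the
#'   full epoch grid).
#' @return object of class "run_config".
#' @export
run_config <- function(seed = 1, n_subjects = 15, n_trials = 500,
                       rois = c("V1", "M1"),
                       observer = observer_params(),
                       neural = neural_gen_params(),
                       rt_threshold = 1.225, latency = 0.190,
                       n_perm = 1000, bayes_iter = 3000,
                       decode_times = NULL) {
  stopifnot(n_subjects >= 1, n_trials >= 50)
  structure(list(seed = seed, n_subjects = n_subjects, n_trials = n_trials,
                 rois = rois, observer = observer, neural = neural,
                 rt_threshold = rt_threshold, latency = latency,
                 n_perm = n_perm, bayes_iter = bayes_iter,
                 decode_times = decode_times),
            class = "run_config")
}

#' Run the full pipeline on synthetic data
#'
#' generation -> behavior -> decoding -> kernels -> coupling -> group
#' statistics, deterministic given the config seed. Results are returned
#' as a named list and, if \code{out_dir} is given, written as TSV/JSON
#' with a manifest. Any stage failure halts the run with the stage name;
#' tables computed so far are still written.
#'
#' @param config a \code{\link{run_config}}.
#' @param out_dir optional output directory.
#' @return named list of stage outputs.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  res <- list()
  persist <- function() {
    if (is.null(out_dir)) return(invisible())
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(res$trials)) write_trials(res$trials,
                                           file.path(out_dir, "trials.tsv"))
    keep <- setdiff(names(res), "trials")
    if (length(keep) > 0) write_results(res[keep],
                                        file.path(out_dir, "results.json"))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      persist()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  cohort <- stage("generate", simulate_cohort(
    n_subjects = config$n_subjects, n_trials = config$n_trials,
    seed = derive_seed(config$seed, "trials"), observer = config$observer))
  res$trials <- cohort

  filtered <- stage("behavior", exclude_fast_rts(cohort, config$rt_threshold))
  res$n_rt_excluded <- attr(filtered, "n_excluded")
  kmat <- stage("behavior", cohort_kernels(filtered))
  res$psychophysical_kernels <- kmat
  res$kernel_slopes <- apply(kmat, 1, kernel_slope)
  subs <- sort(unique(filtered$subject))
  res$choice_fit_accuracy <- mean(vapply(subs, function(s) {
    fit_choice_logreg(filtered[filtered$subject == s, ],
                      seed = derive_seed(config$seed, paste0("cv", s)))$cv_accuracy
  }, numeric(1)))
  tstat <- stats::t.test(kmat[, 1] - 0.5)
  res$kernel_pos1_t <- unname(tstat$statistic)

  bands <- list(gamma = band_definition("gamma"),
                low = band_definition("low_frequency"))
  neural <- config$neural
  times <- seq(neural$epoch[1], neural$epoch[2], by = neural$time_step)
  dec_times <- config$decode_times %||% times[times >= 0 & times <= 0.8]
  visual_roi <- config$rois[roi_type(config$rois) == "visual"][1]
  motor_roi <- config$rois[roi_type(config$rois) == "motor"][1]

  per_subj <- stage("neural+decode+kernels", lapply(subs, function(s) {
    tr <- filtered[filtered$subject == s, ]
    tens <- generate_power_tensor(tr, neural, config$rois,
                                  seed = derive_seed(config$seed,
                                                     paste0("neural", s)))
    pct <- baseline_normalize(tens)
    havg <- hemi_average(pct)
    gamma_sp <- sample_band_power(havg, bands$gamma, config$latency,
                                  roi = visual_roi)
    low_sp <- sample_band_power(havg, bands$low, config$latency,
                                roi = visual_roi)
    k_overall <- neural_kernel(gamma_sp, tr, "overall")
    k_resid <- neural_kernel(gamma_sp, tr, "residual")
    k_low <- neural_kernel(low_sp, tr, "overall")
    enc <- encoding_regression(
      sample_power_array(havg, visual_roi, config$latency),
      contrast_matrix(tr))
    out <- list(gamma_overall = k_overall$auc, gamma_residual = k_resid$auc,
                low_overall = k_low$auc, encoding_beta = enc$beta1,
                psycho = psychophysical_kernel(tr)$auc)
    if (!is.na(motor_roi)) {
      m1_auc <- decode_choice_spectral(
        pct, tr, motor_roi, seed = derive_seed(config$seed, paste0("dec", s)),
        times = dec_times, freq_range = c(1, 20))
      vk <- highres_kernel(havg, tr, bands$low, roi = visual_roi,
                           times = times[times >= -0.2 & times <= 1.05])
      mk <- highres_kernel(havg, tr, bands$low, roi = motor_roi,
                           times = times[times >= -0.2 & times <= 1.05])
      out$m1_auc <- m1_auc
      out$crosscorr <- crosscorr_choice_feedback(m1_auc, vk)
      out$leak_ref <- leakage_reference(m1_auc, mk)
    }
    out
  }))

  res$gamma_kernel_overall <- t(vapply(per_subj, `[[`, numeric(10),
                                       "gamma_overall"))
  res$gamma_kernel_residual <- t(vapply(per_subj, `[[`, numeric(10),
                                        "gamma_residual"))
  res$low_kernel_overall <- t(vapply(per_subj, `[[`, numeric(10),
                                     "low_overall"))
  res$kernel_correlation <- mean(vapply(per_subj, function(x)
    correlate_kernels(x$gamma_overall, x$psycho), numeric(1)), na.rm = TRUE)

  if (!is.na(motor_roi)) {
    cc <- stage("coupling", group_peak_lag(lapply(per_subj, `[[`, "crosscorr")))
    res$crosscorr_mean_r <- cc$mean_r
    res$crosscorr_lags <- cc$lags
    res$peak_lag <- cc$peak_lag
    res$leakage_reference <- mean(vapply(per_subj, `[[`, numeric(1),
                                         "leak_ref"))
    m1_mat <- t(vapply(per_subj, function(x) x$m1_auc$auc,
                       numeric(nrow(per_subj[[1]]$m1_auc))))
    res$m1_auc_mean <- colMeans(m1_mat)
    res$m1_auc_times <- per_subj[[1]]$m1_auc$time
    if (config$bayes_iter > 0) {
      post <- stage("stats", group_auc_posterior(
        m1_mat[, seq(1, ncol(m1_mat), length.out = min(10, ncol(m1_mat)))],
        seed = derive_seed(config$seed, "bayes"),
        n_iter = config$bayes_iter))
      res$group_posterior <- post$summary
      res$group_posterior_rhat_ok <- post$rhat_ok
    }
  }

  perm <- stage("stats", cluster_permutation_test(
    kmat - 0.5, n_perm = config$n_perm,
    seed = derive_seed(config$seed, "perm")))
  res$kernel_tfce_p <- perm$p
  res$kernel_tfce_mask <- perm$mask
  pvals <- apply(kmat, 2, function(col) stats::t.test(col, mu = 0.5)$p.value)
  res$kernel_fdr_mask <- fdr_correct(pvals)

  res$manifest <- list(seed = config$seed, n_subjects = config$n_subjects,
                       n_trials = config$n_trials, rois = config$rois,
                       r_version = as.character(getRversion()))
  persist()
  res
}

# trials x frequency x sample array of power at onset + latency (one ROI).
sample_power_array <- function(tensor, roi, latency = 0.190) {
  ridx <- match(roi, tensor$rois)
  onsets <- seq(0, 0.9, by = 0.1)
  tidx <- vapply(onsets + latency, function(t)
    nearest_time_bin(tensor$times, t), 1L)
  out <- tensor$power[, ridx, , tidx, drop = FALSE]
  array(out, dim = c(dim(tensor$power)[1], length(tensor$freqs),
                     length(onsets)))
}
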