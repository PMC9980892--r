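## Recovery metrics (two-class AUC, relative energy, normalized MSE) and
## bootstrap group inference.  Every metric is computed at each time point
## on the recovered signal and then averaged across time.

## mid-rank Mann-Whitney AUC for scores of one class vs the rest; ties
## count one half
.auc2 <- function(scores, is_active) {
  na <- sum(is_active)
  ni <- sum(!is_active)
  r <- rank(scores, ties.method = "average")
  (sum(r[is_active]) - na * (na + 1) / 2) / (na * ni)
}

#' Two-class AUC separating active from inactive ROIs
#'
#' At each time point, per-ROI scores are the absolute recovered
#' coefficients (so sign inversions of real activity are not penalized);
#' the two-class AUC of Hand and Till — the Mann-Whitney pair statistic
#' with ties counted one half — compares the active set against the
#' inactive set, and the per-time values are averaged.  1 means perfect
#' separation at every threshold, 0.5 chance-level.
#'
#' @param truth_active character vector of truly active ROI labels, or a
#'   logical/integer index into the rows of `beta`.
#' @param beta ROIs x samples matrix of recovered activity (rownames used
#'   to resolve labels).
#' @return scalar AUC.
#' @export
auc_active_vs_inactive <- function(truth_active, beta) {
  beta <- as.matrix(beta)
  act <- .resolve_active(truth_active, beta)
  if (sum(act) < 1 || sum(act) >= nrow(beta)) {
    stopf("need at least one active and one inactive ROI")
  }
  vals <- apply(abs(beta), 2, .auc2, is_active = act)
  mean(vals)
}

.resolve_active <- function(truth_active, beta) {
  if (is.character(truth_active)) {
    if (is.null(rownames(beta))) stopf("beta needs rownames to match labels")
    miss <- setdiff(truth_active, rownames(beta))
    if (length(miss)) stopf("active labels not in beta: %s",
                            paste(miss, collapse = ", "))
    rownames(beta) %in% truth_active
  } else if (is.logical(truth_active)) {
    truth_active
  } else {
    seq_len(nrow(beta)) %in% truth_active
  }
}

#' Relative energy recovered in the active ROIs
#'
#' Per time point, the recovered energy (squared coefficients, normalized
#' across ROIs) inside the true active set divided by the total; averaged
#' across time.  1 means no leakage; time points with all-zero estimates
#' are skipped with a warning.
#'
#' @inheritParams auc_active_vs_inactive
#' @return scalar in `[0, 1]`.
#' @export
relative_energy <- function(truth_active, beta) {
  beta <- as.matrix(beta)
  act <- .resolve_active(truth_active, beta)
  e <- beta^2
  tot <- colSums(e)
  keep <- tot > 0
  if (!all(keep)) {
    warning(sprintf("%d all-zero time point(s) skipped", sum(!keep)),
            call. = FALSE)
  }
  if (!any(keep)) {
    return(NaN)
  }
  mean(colSums(e[act, keep, drop = FALSE]) / tot[keep])
}

#' Normalized mean squared error between true and recovered activity
#'
#' Per time point, both the true and the recovered ROI vectors are scaled
#' to unit Euclidean norm across ROIs (all-zero vectors map to zero), and
#' the mean squared difference across ROIs is taken; per-time values are
#' averaged.  Invariant to positive rescaling of either argument; 0 for a
#' perfect (up to positive scale) recovery.
#'
#' @param truth ROIs x samples matrix of true source activity.
#' @param beta ROIs x samples matrix of recovered activity.
#' @return scalar >= 0.
#' @export
normalized_mse <- function(truth, beta) {
  truth <- as.matrix(truth)
  beta <- as.matrix(beta)
  if (!identical(dim(truth), dim(beta))) {
    stopf("truth and beta must have the same shape")
  }
  unit <- function(M) {
    n <- sqrt(colSums(M^2))
    sweep(M, 2, ifelse(n > 0, n, 1), `/`)
  }
  mean(colMeans((unit(truth) - unit(beta))^2))
}

#' Evaluate a fit against simulation ground truth
#'
#' Convenience wrapper computing the three recovery metrics, with
#' per-time breakdowns.
#'
#' @param fit an `eeg_fit` (or a ROIs x samples matrix).
#' @param truth ROIs x samples matrix of true activity.
#' @param active optional explicit active set; defaults to the rows of
#'   `truth` with any nonzero activity.
#' @return list of class `metrics_report` with `auc`, `relative_energy`,
#'   `nmse` and `per_time` breakdowns.
#'
#' @details The summary metrics average the per-time values over the time
#'   points at which at least one true source is active: during a silent
#'   baseline the active/inactive distinction carries no signal (any
#'   recovered activity is noise), so those samples are excluded from the
#'   classification-style summaries.  The `per_time` breakdowns still
#'   cover every sample.
#' @export
evaluate_fit <- function(fit, truth, active = NULL) {
  beta <- if (inherits(fit, "eeg_fit")) fit$beta else as.matrix(fit)
  truth <- as.matrix(truth)
  active <- active %||% rownames(truth)[rowSums(abs(truth)) > 0]
  act <- .resolve_active(active, beta)
  per_auc <- apply(abs(beta), 2, .auc2, is_active = act)
  e <- beta^2
  tot <- colSums(e)
  per_re <- ifelse(tot > 0, colSums(e[act, , drop = FALSE]) / tot, NA_real_)
  unit <- function(M) {
    n <- sqrt(colSums(M^2))
    sweep(M, 2, ifelse(n > 0, n, 1), `/`)
  }
  per_mse <- colMeans((unit(truth) - unit(beta))^2)
  on <- colSums(abs(truth)) > 0 # time points with any true activity
  if (!any(on)) on <- rep(TRUE, ncol(truth))
  structure(
    list(auc = mean(per_auc[on]),
         relative_energy = mean(per_re[on], na.rm = TRUE),
         nmse = mean(per_mse[on]),
         per_time = list(auc = per_auc, relative_energy = per_re,
                         nmse = per_mse, scored = on),
         active = rownames(beta)[act]),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> AUC %.3f | relative energy %.3f | normalized MSE %.3f (active: %s)\n",
    x$auc, x$relative_energy, x$nmse, paste(x$active, collapse = ", ")
  ))
  invisible(x)
}

#' Bootstrap significance of ROI activity at the group level
#'
#' Resamples participants with replacement `n_boot` times; each replicate
#' averages the resampled participants' scalp data and refits the
#' templates.  Per ROI and time point, the percentile `1 - alpha`
#' confidence interval of the bootstrap distribution of the coefficients
#' is computed, and the ROI is flagged active wherever the interval
#' excludes zero.  No multiple-comparison correction is applied by
#' default; `bonferroni = TRUE` divides alpha by the number of (ROI, time)
#' cells.
#'
#' @param per_participant_data list of electrodes x samples matrices, one
#'   per participant (>= 2).
#' @param templates an `eeg_templates`.
#' @param n_boot bootstrap replicates (default 500; < 100 warns).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed.
#' @param selector regularization selector passed to [fit_templates()].
#' @param bonferroni apply Bonferroni correction across cells.
#' @return list of class `bootstrap_result` with `mean_course`, `ci_low`,
#'   `ci_high`, `active_flags`, `n_boot`, `alpha`.
#' @export
bootstrap_significance <- function(per_participant_data, templates,
                                   n_boot = 500, alpha = 0.05, seed = 1,
                                   selector = "lcurve", bonferroni = FALSE) {
  np <- length(per_participant_data)
  if (np < 2) stopf("need at least 2 participants")
  if (n_boot < 100) {
    warning("n_boot < 100 gives unstable percentile intervals", call. = FALSE)
  }
  a <- if (bonferroni) {
    alpha / (nrow(templates$matrix) * ncol(per_participant_data[[1]]))
  } else {
    alpha
  }
  with_seed(seed, {
    draws <- NULL
    for (b in seq_len(n_boot)) {
      idx <- sample.int(np, np, replace = TRUE)
      avg <- Reduce(`+`, per_participant_data[idx]) / np
      fit <- fit_templates(templates, avg, selector = selector)
      if (is.null(draws)) {
        draws <- array(NA_real_, c(dim(fit$beta), n_boot),
                       dimnames = list(rownames(fit$beta), NULL, NULL))
      }
      draws[, , b] <- fit$beta
    }
  })
  mean_course <- apply(draws, c(1, 2), mean)
  ci_low <- apply(draws, c(1, 2), stats::quantile, probs = a / 2)
  ci_high <- apply(draws, c(1, 2), stats::quantile, probs = 1 - a / 2)
  structure(
    list(mean_course = mean_course, ci_low = ci_low, ci_high = ci_high,
         active_flags = ci_low > 0 | ci_high < 0,
         n_boot = n_boot, alpha = alpha),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_result> %d replicates, alpha %.3g; %d of %d (ROI, time) cells active\n",
    x$n_boot, x$alpha, sum(x$active_flags), length(x$active_flags)
  ))
  invisible(x)
}

#' Permutation test between two conditions
#'
#' For paired condition data (one matrix per participant per condition),
#' tests the ROI-level difference in recovered activity by randomly
#' swapping the condition labels within participants.  Reports per-ROI
#' p-values for the maximum absolute time-course difference, a statistic
#' whose null distribution the permutations estimate.
#'
#' @param data_a,data_b lists of electrodes x samples matrices (same
#'   participants, two conditions).
#' @param templates an `eeg_templates`.
#' @param n_perm permutations (default 500).
#' @param seed integer seed.
#' @param selector regularization selector.
#' @return list with `observed` (ROIs x samples difference), `p_values`
#'   (per ROI) and `n_perm`.
#' @export
permutation_test_conditions <- function(data_a, data_b, templates,
                                        n_perm = 500, seed = 1,
                                        selector = "lcurve") {
  np <- length(data_a)
  if (np != length(data_b) || np < 2) {
    stopf("need the same >= 2 participants in both conditions")
  }
  fit_diff <- function(la, lb) {
    avg_a <- Reduce(`+`, la) / np
    avg_b <- Reduce(`+`, lb) / np
    fit_templates(templates, avg_a, selector = selector)$beta -
      fit_templates(templates, avg_b, selector = selector)$beta
  }
  obs <- fit_diff(data_a, data_b)
  stat <- apply(abs(obs), 1, max)
  with_seed(seed, {
    exceed <- matrix(0, nrow(obs), 1)
    for (k in seq_len(n_perm)) {
      flip <- stats::runif(np) < 0.5
      la <- data_a; lb <- data_b
      la[flip] <- data_b[flip]
      lb[flip] <- data_a[flip]
      d <- fit_diff(la, lb)
      exceed <- exceed + (apply(abs(d), 1, max) >= stat)
    }
  })
  p <- (exceed + 1) / (n_perm + 1)
  list(observed = obs, p_values = stats::setNames(as.vector(p), rownames(obs)),
       n_perm = n_perm)
}
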