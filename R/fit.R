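## High-level source-localization fits: the template method (regularized
## regression of group-averaged scalp data on the ROI templates) and the
## three individual-model comparison methods.

#' Fit ROI templates to group-averaged scalp data
#'
#' The template method: the group-averaged EEG (electrodes x samples) is
#' regressed on the template matrix with Tikhonov regularization, one
#' shared regularization weight across all samples, selected by the
#' L-curve corner by default.  Regularization is applied once, to the
#' group average; this is deliberately not the same as averaging
#' per-participant regularized fits, and the two pipelines genuinely
#' disagree when participants have heterogeneous noise.
#'
#' @param templates an `eeg_templates`.
#' @param group_avg electrodes x samples matrix.  If it has rownames they
#'   must match the template montage labels in order.  Complex-valued data
#'   (e.g. frequency-domain harmonics) is accepted and handled by stacking
#'   real and imaginary parts as extra samples.
#' @param selector `"lcurve"` (default), `"gcv"`, `"optimal"` (requires
#'   `truth`) or `"fixed"` (requires `lambda`).
#' @param lambda fixed regularization weight for `selector = "fixed"`.
#' @param truth true coefficients for `selector = "optimal"`.
#' @param lambdas optional explicit grid.
#' @return object of class `eeg_fit`: `beta` (ROIs x samples), `lambda`,
#'   `selector`, `method = "template"` and `diagnostics` (the
#'   [ridge_path()]).
#' @export
fit_templates <- function(templates, group_avg,
                          selector = c("lcurve", "gcv", "optimal", "fixed"),
                          lambda = NULL, truth = NULL, lambdas = NULL) {
  stopifnot(inherits(templates, "eeg_templates"))
  selector <- match.arg(selector)
  Y <- group_avg
  if (is.complex(Y)) Y <- cbind(Re(Y), Im(Y))
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(templates$matrix)) {
    stopf(paste("data has %d electrodes but templates have %d;",
                "use customize_templates() to match the montages"),
          nrow(Y), nrow(templates$matrix))
  }
  if (!is.null(rownames(Y)) &&
      !identical(rownames(Y), templates$montage$labels)) {
    stopf(paste("data channel labels do not match the template montage;",
                "use customize_templates() to align them"))
  }
  Y <- apply_reference(Y, templates$montage$reference,
                       labels = templates$montage$labels)
  path <- ridge_path(templates$matrix, Y, lambdas = lambdas)
  if (all(Y == 0)) { # degenerate null data: the zero fit, maximally smoothed
    beta <- matrix(0, ncol(templates$matrix), ncol(Y),
                   dimnames = list(templates$roi_names, NULL))
    return(structure(
      list(beta = beta, lambda = path$lambdas[1], selector = selector,
           method = "template", diagnostics = path),
      class = "eeg_fit"
    ))
  }
  lam <- switch(selector,
    lcurve = lcurve_select(path),
    gcv = gcv_select(path),
    optimal = {
      if (is.null(truth)) stopf("selector 'optimal' requires `truth`")
      optimal_select(path, truth)
    },
    fixed = {
      if (is.null(lambda)) stopf("selector 'fixed' requires `lambda`")
      lambda
    }
  )
  beta <- ridge_coef(path, lam)
  rownames(beta) <- templates$roi_names
  structure(
    list(beta = beta, lambda = lam, selector = selector,
         method = "template", diagnostics = path),
    class = "eeg_fit"
  )
}

#' @export
print.eeg_fit <- function(x, ...) {
  cat(sprintf(
    "<eeg_fit> method %s (%s selector, lambda %.4g): %d ROIs x %d samples\n",
    x$method, x$selector, x$lambda, nrow(x$beta), ncol(x$beta)
  ))
  invisible(x)
}

#' Individual-model source localization with ROI pooling
#'
#' The three comparison methods built on one participant's own forward
#' model:
#' \describe{
#'   \item{`whole_brain`}{design = the full lead field; per-source
#'     coefficients are estimated and then pooled within each ROI
#'     (sources outside the ROIs are ignored).}
#'   \item{`roi_only`}{design restricted to the columns of the ROI sources
#'     before solving; pooled the same way.}
#'   \item{`oracle_rois`}{design = the participant's own 18 ROI
#'     topographies (one column per ROI), the upper bound when the true
#'     source regions are known exactly.}
#' }
#' GCV selection is the default for the individual-based methods.
#' Group-level results are obtained by averaging per-participant `beta`
#' across participants (see [average_fits()]).
#'
#' @param fm a `forward_model`.
#' @param participant_data electrodes x samples matrix in the participant's
#'   montage (average reference applied if not already).
#' @param selector as in [fit_templates()] (default `"gcv"`).
#' @param subset `"whole_brain"`, `"roi_only"` or `"oracle_rois"`.
#' @param roi_names ROIs pooled/reported (default [visual_rois()]).
#' @param pool `"sum"` (default; consistent with forward pooling of unit
#'   dipoles) or `"mean"` of per-source coefficients within an ROI.
#' @param lambda,lambdas,truth as in [fit_templates()].
#' @return an `eeg_fit` with `beta` = ROIs x samples and the method tag
#'   `"individual"`, `"individual_subset"` or `"individual_oracle"`.
#' @export
fit_individual <- function(fm, participant_data,
                           selector = c("gcv", "lcurve", "optimal", "fixed"),
                           subset = c("whole_brain", "roi_only", "oracle_rois"),
                           roi_names = visual_rois(),
                           pool = c("sum", "mean"),
                           lambda = NULL, lambdas = NULL, truth = NULL) {
  stopifnot(inherits(fm, "forward_model"))
  selector <- match.arg(selector)
  subset <- match.arg(subset)
  pool <- match.arg(pool)
  Y <- participant_data
  if (is.complex(Y)) Y <- cbind(Re(Y), Im(Y))
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(fm$leadfield)) {
    stopf("data has %d electrodes, forward model %d",
          nrow(Y), nrow(fm$leadfield))
  }
  Y <- apply_reference(Y, "average")
  roi_idx <- lapply(roi_names, function(r) roi_sources(fm, r))
  if (subset != "whole_brain" && sum(lengths(roi_idx)) == 0) {
    stopf("no sources in any requested ROI")
  }
  design <- switch(subset,
    whole_brain = fm$leadfield,
    roi_only = fm$leadfield[, unlist(roi_idx), drop = FALSE],
    oracle_rois = vapply(roi_names, function(r) roi_topography(fm, r),
                         numeric(nrow(fm$leadfield)))
  )
  path <- ridge_path(design, Y, lambdas = lambdas)
  lam <- switch(selector,
    lcurve = lcurve_select(path),
    gcv = gcv_select(path),
    optimal = {
      if (is.null(truth)) stopf("selector 'optimal' requires `truth`")
      optimal_select(path, truth)
    },
    fixed = {
      if (is.null(lambda)) stopf("selector 'fixed' requires `lambda`")
      lambda
    }
  )
  Bsrc <- ridge_coef(path, lam)
  beta <- switch(subset,
    whole_brain = .pool_rois(Bsrc, roi_idx, roi_names, pool),
    roi_only = {
      # rows of Bsrc follow the concatenated ROI column order
      counts <- lengths(roi_idx)
      grp <- rep(seq_along(roi_names), counts)
      .pool_rois(Bsrc, split(seq_len(nrow(Bsrc)), factor(grp, seq_along(roi_names))),
                 roi_names, pool)
    },
    oracle_rois = {
      rownames(Bsrc) <- roi_names
      Bsrc
    }
  )
  method <- switch(subset, whole_brain = "individual",
                   roi_only = "individual_subset",
                   oracle_rois = "individual_oracle")
  structure(
    list(beta = beta, lambda = lam, selector = selector,
         method = method, diagnostics = path),
    class = "eeg_fit"
  )
}

.pool_rois <- function(Bsrc, idx_list, roi_names, pool) {
  out <- matrix(0, length(roi_names), ncol(Bsrc),
                dimnames = list(roi_names, NULL))
  for (r in seq_along(roi_names)) {
    idx <- idx_list[[r]]
    if (length(idx) == 0) next
    rows <- Bsrc[idx, , drop = FALSE]
    out[r, ] <- if (pool == "sum") colSums(rows) else colMeans(rows)
  }
  out
}

#' Average per-participant fits into a group-level result
#'
#' The individual-based pipelines regularize each participant separately
#' and then average the recovered ROI activity across participants; this
#' helper performs that average.
#'
#' @param fits list of `eeg_fit` objects with identical `beta` shapes.
#' @return an `eeg_fit` whose `beta` is the element-wise mean; `lambda`
#'   holds the per-participant values.
#' @export
average_fits <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "eeg_fit")))
  beta <- Reduce(`+`, lapply(fits, `[[`, "beta")) / length(fits)
  structure(
    list(beta = beta, lambda = vapply(fits, `[[`, 1, "lambda"),
         selector = fits[[1]]$selector,
         method = fits[[1]]$method, diagnostics = NULL),
    class = "eeg_fit"
  )
}

#' Display normalization of recovered activity
#'
#' For reports and plots only: divides the coefficient matrix by the
#' maximum absolute recovered activity across time and ROIs, so the
#' largest excursion is 1.  Never applied before computing metrics.
#'
#' @param beta ROIs x samples matrix (or an `eeg_fit`).
#' @return matrix of the same shape.
#' @export
normalize_display <- function(beta) {
  if (inherits(beta, "eeg_fit")) beta <- beta$beta
  m <- max(abs(beta))
  if (m == 0) beta else beta / m
}
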