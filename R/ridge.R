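## Tikhonov (ridge) regularization path via the SVD of the design, with
## multi-sample pooling, GCV and L-curve selection of the regularization
## weight, and the truth-informed optimal selector.
##
## Convention: the objective is ||Y - X B||^2 + lambda^2 ||B||^2, so the
## SVD filter factors are d_i^2 / (d_i^2 + lambda^2) and lambda has the
## units of a singular value of the design.  (Some texts put the penalty
## weight unsquared; with this convention their weight equals our
## lambda^2.)

#' Default logarithmic regularization grid for a design matrix
#'
#' 200 logarithmically spaced values spanning `[1e-6, 10]` times the
#' largest singular value of the design, descending.  This brackets both
#' limits of the filter factors (all ~1 at the bottom of the grid, all ~0
#' at the top).
#'
#' @param design the design matrix (or its precomputed singular values).
#' @param n grid length.
#' @return descending numeric vector.
#' @export
lambda_grid <- function(design, n = 200) {
  d <- if (is.matrix(design)) svd(design, nu = 0, nv = 0)$d else design
  smax <- max(d)
  exp(seq(log(10 * smax), log(1e-6 * smax), length.out = n))
}

#' Compute a Tikhonov regularization path
#'
#' Solves `min ||Y - X B||_F^2 + lambda^2 ||B||_F^2` for every lambda on
#' the grid via one SVD of the design; a single lambda is shared across
#' all sample columns of `Y`, with residual and solution norms pooled as
#' root-sum-of-squares over samples.  Returns the path diagnostics used by
#' the selectors: pooled residual and solution norms, GCV values, and the
#' analytic signed curvature of the log-log L-curve.
#'
#' @param design n_electrodes x p matrix.
#' @param Y n_electrodes x n_samples matrix (a vector is treated as one
#'   sample).
#' @param lambdas positive descending grid; defaults to
#'   [lambda_grid()] of the design.
#' @return object of class `ridge_path`.
#' @export
ridge_path <- function(design, Y, lambdas = NULL) {
  design <- as.matrix(design)
  Y <- as.matrix(Y)
  check_finite(design, "design")
  check_finite(Y, "Y")
  if (nrow(design) != nrow(Y)) {
    stopf("design has %d rows but Y has %d", nrow(design), nrow(Y))
  }
  sv <- svd(design)
  d <- sv$d
  lambdas <- lambdas %||% lambda_grid(d)
  if (is.unsorted(rev(lambdas))) lambdas <- sort(lambdas, decreasing = TRUE)
  if (any(lambdas < 0)) stopf("lambdas must be positive")
  if (any(lambdas == 0) && min(d) < 1e-12 * max(d)) {
    stopf("lambda = 0 requires a full-column-rank design")
  }
  UtY <- crossprod(sv$u, Y) # r x s
  c2 <- rowSums(UtY^2) # pooled squared svd-space data coefficients
  resid0 <- sum(Y^2) - sum(c2) # out-of-column-space residual, pooled
  resid0 <- max(resid0, 0)
  l <- lambdas
  D2 <- outer(d^2, l^2, `+`) # r x nl: d_i^2 + lambda_j^2
  Fi <- d^2 / D2 # filter factors
  # pooled squared norms per lambda (forms safe for d_i = 0)
  rho <- colSums((1 - Fi)^2 * c2) + resid0 # residual
  eta <- colSums(c2 * d^2 / D2^2) # solution
  edf <- colSums(Fi) # effective dof
  gcv <- rho / (nrow(Y) - edf)^2
  # analytic derivatives of rho(lambda), eta(lambda):
  #   rho'  =  4 l^3 S3,  eta'  = -4 l S3,        S3 = sum c2 d^2 / D2^3
  #   rho'' = 12 l^2 sum c2 d^2 (d^2 - l^2)/D2^4
  #   eta'' = -4 sum c2 d^2 (d^2 - 5 l^2)/D2^4
  A3 <- (d^2 * c2) / D2^3
  A4 <- (d^2 * c2) / D2^4
  S3 <- colSums(A3)
  drho <- 4 * l^3 * S3
  deta <- -4 * l * S3
  d2rho <- 12 * l^2 * colSums(A4 * outer(d^2, l^2, `-`))
  d2eta <- -4 * colSums(A4 * outer(d^2, 5 * l^2, `-`))
  # curvature of (x, y) = (log sqrt(rho), log sqrt(eta))
  xp <- drho / (2 * rho)
  yp <- deta / (2 * eta)
  xpp <- (d2rho * rho - drho^2) / (2 * rho^2)
  ypp <- (d2eta * eta - deta^2) / (2 * eta^2)
  curv <- (xp * ypp - yp * xpp) / (xp^2 + yp^2)^1.5
  structure(
    list(lambdas = lambdas,
         residual_norm = sqrt(rho), solution_norm = sqrt(eta),
         gcv = gcv, curvature = curv, edf = edf,
         svd = sv, UtY = UtY, resid0 = resid0,
         n_electrodes = nrow(Y), n_samples = ncol(Y),
         design_colnames = colnames(design)),
    class = "ridge_path"
  )
}

#' @export
print.ridge_path <- function(x, ...) {
  cat(sprintf(
    "<ridge_path> %d lambdas in [%.3g, %.3g]; %d electrodes, %d samples\n",
    length(x$lambdas), min(x$lambdas), max(x$lambdas),
    x$n_electrodes, x$n_samples
  ))
  invisible(x)
}

#' Coefficients of a ridge path at a given lambda
#'
#' @param path a [ridge_path()].
#' @param lambda a value from the path grid (values off the grid are
#'   allowed and computed exactly; the grid is only used by the
#'   selectors).
#' @return p x n_samples coefficient matrix.
#' @export
ridge_coef <- function(path, lambda) {
  stopifnot(inherits(path, "ridge_path"))
  d <- path$svd$d
  f <- ifelse(d > 0, d / (d^2 + lambda^2), 0)
  B <- path$svd$v %*% (f * path$UtY)
  rownames(B) <- path$design_colnames
  B
}

#' Select lambda by generalized cross-validation
#'
#' Minimizes `GCV(lambda) = RSS(lambda) / (n_electrodes - edf(lambda))^2`
#' with the residual sum of squares pooled over all samples and the
#' effective degrees of freedom given by the filter-factor trace.
#' Restricted to the path grid.  If all GCV values are (numerically) equal
#' the tie breaks toward the largest lambda, i.e. more regularization, with
#' a warning.
#'
#' @param path a [ridge_path()].
#' @return the selected lambda (scalar).
#' @export
gcv_select <- function(path) {
  stopifnot(inherits(path, "ridge_path"))
  g <- path$gcv
  rng <- range(g)
  if (rng[2] - rng[1] <= 1e-14 * max(rng[2], 1e-300)) {
    warning("GCV is flat across the grid; choosing the largest lambda",
            call. = FALSE)
    return(path$lambdas[1])
  }
  # ties toward larger lambda: grid is descending, take the first minimum
  path$lambdas[which.min(g)]
}

#' Select lambda at the L-curve corner
#'
#' Returns the grid lambda maximizing the signed curvature of the
#' parametric curve `(log residual_norm, log solution_norm)`, computed
#' analytically from the SVD quantities (no finite differences).  The sign
#' convention makes the convex corner of the "L" positive.  If the
#' curvature has no positive maximum (degenerate monotone path) the
#' maximum-curvature endpoint is returned with a warning.
#'
#' @param path a [ridge_path()] with at least 5 grid points.
#' @return the selected lambda (scalar).
#' @export
lcurve_select <- function(path) {
  stopifnot(inherits(path, "ridge_path"))
  if (length(path$lambdas) < 5) stopf("L-curve needs at least 5 grid points")
  k <- path$curvature
  if (all(!is.finite(k))) stopf("curvature is undefined along the path")
  kmax <- max(k[is.finite(k)])
  if (kmax <= 0) {
    warning("L-curve has no convex corner; using maximum-curvature endpoint",
            call. = FALSE)
  }
  # ties toward larger lambda (descending grid: first index)
  path$lambdas[which.max(replace(k, !is.finite(k), -Inf))]
}

#' Select the truth-optimal lambda
#'
#' Scans the grid for the lambda minimizing the mean squared error between
#' the ridge coefficients and the known true coefficients.  Only available
#' in simulations, where the truth is known; it bounds what any data-driven
#' selector could achieve on the same grid.
#'
#' @param path a [ridge_path()].
#' @param truth p x n_samples matrix of true coefficients.
#' @return the selected lambda (scalar).
#' @export
optimal_select <- function(path, truth) {
  stopifnot(inherits(path, "ridge_path"))
  truth <- as.matrix(truth)
  d <- path$svd$d
  Vt_truth <- crossprod(path$svd$v, truth)
  if (nrow(truth) != nrow(path$svd$v) || ncol(truth) != path$n_samples) {
    stopf("truth must be %d x %d", nrow(path$svd$v), path$n_samples)
  }
  mse <- vapply(path$lambdas, function(l) {
    f <- ifelse(d > 0, d / (d^2 + l^2), 0)
    # ||B(l) - truth||^2 = ||V'B - V'truth||^2 + ||(I-VV')truth||^2;
    # the second term is lambda-free, so compare in V-space
    mean((f * path$UtY - Vt_truth)^2)
  }, numeric(1))
  path$lambdas[which.min(mse)]
}
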