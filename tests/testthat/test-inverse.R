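test_that("the ridge path equals the normal-equations solution", {
  set.seed(100)
  for (rep in 1:100) {
    n <- sample(5:20, 1)
    p <- sample(2:(n - 1), 1)
    s <- sample(1:4, 1)
    X <- matrix(rnorm(n * p), n)
    Y <- matrix(rnorm(n * s), n)
    l <- 10^runif(1, -2, 1)
    path <- ridge_path(X, Y, lambdas = c(10, l, 0.001))
    B1 <- ridge_coef(path, l)
    B2 <- solve(crossprod(X) + l^2 * diag(p), crossprod(X, Y))
    expect_lt(max(abs(B1 - B2)), 1e-10 * max(1, max(abs(B2))))
    # filter-factor monotonicity in lambda, asserted on every path
    full <- ridge_path(X, Y)
    expect_true(all(diff(full$residual_norm) <= 1e-10)) # descending grid
    expect_true(all(diff(full$solution_norm) >= -1e-10))
  }
})

test_that("ridge limits: least squares at small lambda, zero at huge lambda", {
  set.seed(101)
  X <- matrix(rnorm(40), 10, 4)
  y <- rnorm(10)
  path <- ridge_path(X, y)
  bls <- qr.coef(qr(X), y)
  expect_lt(max(abs(ridge_coef(path, 1e-9 * max(svd(X)$d)) - bls)), 1e-8)
  bhuge <- ridge_coef(path, 1e6 * max(svd(X)$d))
  expect_lt(sqrt(sum(bhuge^2)), 1e-9 * sqrt(sum(bls^2)))
  # 5 x 3, two samples, lambda = 1: brute force oracle
  X2 <- matrix(rnorm(15), 5, 3)
  Y2 <- matrix(rnorm(10), 5, 2)
  p2 <- ridge_path(X2, Y2, lambdas = c(2, 1, 0.5))
  expect_lt(max(abs(ridge_coef(p2, 1) -
                      solve(crossprod(X2) + diag(3), crossprod(X2, Y2)))),
            1e-10)
})

test_that("GCV matches the classical single-sample formula", {
  set.seed(102)
  X <- matrix(rnorm(60), 15, 4)
  y <- rnorm(15)
  path <- ridge_path(X, y)
  sv <- svd(X)
  uy <- crossprod(sv$u, y)
  direct <- vapply(path$lambdas, function(l) {
    f <- sv$d^2 / (sv$d^2 + l^2)
    rss <- sum(((1 - f) * uy)^2) + sum(y^2) - sum(uy^2)
    rss / (15 - sum(f))^2
  }, numeric(1))
  expect_equal(path$gcv, direct, tolerance = 1e-10)
})

test_that("GCV over-smooths pure noise and pools duplicated samples", {
  set.seed(103)
  X <- matrix(rnorm(160), 20, 8)
  grid <- lambda_grid(X, 60)
  med <- stats::median(grid)
  hits <- 0
  for (s in 1:100) {
    set.seed(5000 + s)
    Y <- matrix(rnorm(80), 20, 4)
    if (gcv_select(ridge_path(X, Y, grid)) >= med) hits <- hits + 1
  }
  expect_gte(hits, 90)
  # duplicating sample columns leaves the selection unchanged
  set.seed(104)
  Y <- matrix(rnorm(60), 20, 3)
  l1 <- gcv_select(ridge_path(X, Y, grid))
  l2 <- gcv_select(ridge_path(X, cbind(Y, Y), grid))
  expect_identical(l1, l2)
})

test_that("the L-curve corner tracks the error-optimal lambda", {
  for (seed in c(1, 2, 3, 4, 5)) {
    fx <- planted_illposed(seed)
    grid <- lambda_grid(fx$X, 25)
    path <- ridge_path(fx$X, fx$y, lambdas = grid)
    lam <- lcurve_select(path)
    err <- vapply(grid, function(l) sum((ridge_coef(path, l) - fx$xtrue)^2),
                  numeric(1))
    expect_lte(abs(which(grid == lam) - which.min(err)), 1)
  }
})

test_that("the L-curve corner is invariant to rescaling the data", {
  # rho and eta both scale by the same factor, so the log-log curve only
  # translates and its curvature profile over lambda is unchanged
  fx <- planted_illposed(6)
  grid <- lambda_grid(fx$X, 40)
  p1 <- ridge_path(fx$X, fx$y, lambdas = grid)
  p10 <- ridge_path(fx$X, 10 * fx$y, lambdas = grid)
  expect_equal(p1$curvature, p10$curvature, tolerance = 1e-8)
  expect_identical(lcurve_select(p1), lcurve_select(p10))
})

test_that("noiseless well-conditioned data drives the corner to the grid floor", {
  set.seed(105)
  X <- matrix(rnorm(200), 20, 10)
  y <- X %*% rnorm(10)
  path <- ridge_path(X, y, lambda_grid(X, 50))
  lam <- suppressWarnings(lcurve_select(path))
  expect_lte(which(rev(path$lambdas) == lam), 2) # within two steps of min
})

test_that("optimal selection dominates and matches a brute-force scan", {
  fx <- planted_illposed(9)
  grid <- lambda_grid(fx$X, 40)
  path <- ridge_path(fx$X, fx$y, lambdas = grid)
  # constructed truth at a grid point is recovered exactly
  l0 <- grid[17]
  expect_identical(optimal_select(path, ridge_coef(path, l0)), l0)
  # brute-force scan agreement
  mse <- vapply(grid, function(l) mean((ridge_coef(path, l) - fx$xtrue)^2),
                numeric(1))
  lopt <- optimal_select(path, fx$xtrue)
  expect_identical(lopt, grid[which.min(mse)])
  # argmin dominance over the data-driven selector
  llc <- lcurve_select(path)
  expect_lte(mean((ridge_coef(path, lopt) - fx$xtrue)^2),
             mean((ridge_coef(path, llc) - fx$xtrue)^2))
})

test_that("template fits recover noiseless coefficients and null data", {
  set.seed(106)
  # well-separated synthetic templates: near-orthogonal zero-sum columns
  E <- 24
  raw <- qr.Q(qr(cbind(1, matrix(rnorm(E * 6), E))))[, 2:7]
  mon <- toy_montage(E)
  ts <- template_set(raw, paste0("R", 1:6), mon)
  beta0 <- matrix(c(2, -1, 0.5, 0, 0, 3), 6, 4) * runif(24, 0.5, 1.5)
  Y <- raw %*% beta0
  fit <- suppressWarnings(fit_templates(ts, Y, selector = "lcurve"))
  expect_lt(max(abs(fit$beta - beta0)), 0.02 * max(abs(beta0)))
  expect_identical(fit$method, "template")
  # null data gives the zero fit
  fit0 <- fit_templates(ts, Y * 0)
  expect_equal(unname(fit0$beta), matrix(0, 6, 4))
})

test_that("template fits are invariant to common-mode offsets", {
  ts <- test_templates()
  set.seed(107)
  Y <- matrix(rnorm(32 * 10), 32)
  f1 <- fit_templates(ts, Y)
  f2 <- fit_templates(ts, Y + matrix(5, 32, 1)[, rep(1, 10)])
  expect_equal(f1$beta, f2$beta, tolerance = 1e-9)
  expect_identical(f1$lambda, f2$lambda)
})

test_that("complex data is fitted by stacking real and imaginary parts", {
  ts <- test_templates()
  set.seed(108)
  Yc <- matrix(complex(real = rnorm(32 * 3), imaginary = rnorm(32 * 3)), 32)
  fc <- fit_templates(ts, Yc)
  fr <- fit_templates(ts, cbind(Re(Yc), Im(Yc)))
  expect_equal(fc$beta, fr$beta)
})

test_that("the simulated source is the dominant recovered ROI", {
  pop <- test_population()
  ts <- test_templates()
  hits <- 0
  for (s in 1:30) {
    ds <- simulate_group(pop, sim_config("MT-L", snr = 10,
                                         n_participants = 12,
                                         seed = child_seed(606, s)))
    fit <- fit_templates(ts, ds$group_avg)
    on <- colSums(abs(ds$truth)) > 0
    score <- rowMeans(abs(fit$beta[, on, drop = FALSE]))
    if (names(which.max(score)) == "MT-L") hits <- hits + 1
  }
  expect_gte(hits, 27) # >= 90% of seeded runs
})

test_that("individual-model methods recover and pool per-source activity", {
  fm <- test_population()[[1]]
  # oracle design on self-generated data: near-exact recovery at tiny lambda
  topo <- vapply(visual_rois(), function(r) roi_topography(fm, r),
                 numeric(32))
  beta0 <- matrix(0, 18, 3, dimnames = list(visual_rois(), NULL))
  beta0["V3A-L", ] <- c(1, 2, 3)
  beta0["MT-R", ] <- c(-1, 0, 1)
  Y <- topo %*% beta0
  smax <- max(svd(topo)$d)
  fit <- fit_individual(fm, Y, selector = "fixed", lambda = 1e-7 * smax,
                        subset = "oracle_rois")
  expect_lt(max(abs(fit$beta - beta0)), 1e-6 * max(abs(beta0)))
  expect_identical(fit$method, "individual_oracle")

  # whole-brain pooling equals the hand-summed per-source estimates
  set.seed(109)
  Y2 <- matrix(rnorm(32 * 4), 32)
  lam <- 0.5 * smax
  fit2 <- fit_individual(fm, Y2, selector = "fixed", lambda = lam,
                         subset = "whole_brain")
  path <- ridge_path(fm$leadfield, apply_reference(Y2))
  Bsrc <- ridge_coef(path, lam)
  manual <- t(vapply(visual_rois(), function(r) {
    colSums(Bsrc[roi_sources(fm, r), , drop = FALSE])
  }, numeric(4)))
  expect_equal(fit2$beta, manual, tolerance = 1e-10, ignore_attr = TRUE)
  expect_identical(fit2$method, "individual")

  # roi_only restricts the design before solving
  fit3 <- fit_individual(fm, Y2, selector = "fixed", lambda = lam,
                         subset = "roi_only")
  expect_identical(fit3$method, "individual_subset")
  expect_identical(dim(fit3$beta), c(18L, 4L))
})

test_that("regularizing the average differs from averaging regularized fits", {
  # heterogeneous noise across participants: the nonlinear selector makes
  # the two pipelines genuinely disagree
  ts <- test_templates()
  pop <- test_population()
  set.seed(110)
  beta0 <- matrix(0, 18, 5, dimnames = list(visual_rois(), NULL))
  beta0["V1-L", ] <- seq(1, 3, length.out = 5)
  clean <- ts$matrix %*% beta0
  noise_sd <- c(0.02, 0.02, 2, 2) * max(abs(clean))
  per <- lapply(noise_sd, function(s) clean + matrix(rnorm(32 * 5, 0, s), 32))
  avg_then_reg <- fit_templates(ts, Reduce(`+`, per) / 4, selector = "gcv")
  reg_then_avg <- average_fits(
    lapply(per, function(Y) fit_templates(ts, Y, selector = "gcv"))
  )
  rel_gap <- max(abs(avg_then_reg$beta - reg_then_avg$beta)) /
    max(abs(avg_then_reg$beta))
  expect_gt(rel_gap, 0.05)
})

test_that("display normalization scales the peak to one", {
  set.seed(111)
  B <- matrix(rnorm(12), 3)
  N <- normalize_display(B)
  expect_equal(max(abs(N)), 1)
  expect_equal(N * max(abs(B)), B)
  expect_equal(normalize_display(B * 0), B * 0)
})
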