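test_that("ERP waveforms respect the window and amplitude contract", {
  cfg <- erp_config()
  t_ms <- erp_times(cfg)
  expect_identical(length(t_ms), 91L) # 1 kHz over -45..45 ms
  for (s in 1:20) {
    w <- make_erp(cfg, seed = s)
    expect_true(all(w[t_ms <= 0] == 0))
    expect_gte(max(w), 1)
    expect_lte(max(w), 10)
    expect_true(all(w >= 0))
  }
  expect_identical(make_erp(cfg, seed = 42), make_erp(cfg, seed = 42))
  diffs <- vapply(1:100, function(s) {
    max(abs(make_erp(cfg, seed = s) - make_erp(cfg, seed = s + 1000)))
  }, numeric(1))
  expect_true(all(diffs > 0))
  expect_error(erp_config(baseline_window = c(0, 50),
                          active_window = c(0, 45)), "precede")
})

test_that("the SNR definition matches its Pythagorean construction", {
  # orthogonal signal and noise with RMS ratio r: SNR = r^2 exactly
  s <- matrix(0, 4, 4)
  s[1, 1] <- 2
  n <- matrix(0, 4, 4)
  n[2, 2] <- 1
  expect_equal(snr_of(s + n, n), (2 / 1)^2, tolerance = 1e-12)
  expect_identical(snr_of(s, matrix(0, 4, 4)), Inf)
  # no signal: mean SNR over replicates is ~0
  set.seed(200)
  snrs <- vapply(1:1000, function(i) {
    noise <- matrix(rnorm(64), 8)
    snr_of(noise, noise)
  }, numeric(1))
  expect_identical(mean(snrs), 0) # signal==0 means data == noise exactly
  # independent equal-power draws for data and noise: the small positive
  # bias is E[1/chi^2] inflation, 2/(k-2) for k = 64 cells
  snrs2 <- vapply(1:1000, function(i) {
    snr_of(matrix(rnorm(64), 8), matrix(rnorm(64), 8))
  }, numeric(1))
  se <- sd(snrs2) / sqrt(length(snrs2))
  expect_lt(abs(mean(snrs2) - 2 / 62), 3 * se)
})

test_that("noise injection is calibrated to the target SNR", {
  set.seed(201)
  clean <- matrix(rnorm(128 * 91), 128)
  res <- add_noise(clean, 10, "white", seed = 7)
  expect_lt(abs(res$achieved_snr - 10) / 10, 0.05)
  expect_identical(add_noise(clean, Inf)$noisy, clean)
  # unbiased in expectation at targets 1, 10, 200
  for (target in c(1, 10, 200)) {
    ach <- vapply(1:500, function(s) {
      add_noise(clean[1:16, 1:20], target, "white", seed = s)$achieved_snr
    }, numeric(1))
    expect_lt(abs(mean(ach) - target) / target, 0.02)
  }
})

test_that("correlated noise has structured spatial covariance", {
  fm <- test_population()[[1]]
  clean <- matrix(0, nrow(fm$leadfield), 600)
  clean[1, 1] <- 1 # nonzero so scaling is defined
  w <- add_noise(clean, 1, "white", seed = 3)$noise
  c_ <- add_noise(clean, 1, "correlated", fm = fm, seed = 3)$noise
  offdiag <- function(M) {
    C <- stats::cor(t(M))
    mean(abs(C[upper.tri(C)]))
  }
  expect_gt(offdiag(c_), 5 * offdiag(w))
  expect_error(add_noise(clean, 1, "correlated"), "forward model")
})

test_that("group simulation is an exact linear projection when noiseless", {
  pop <- test_population()
  cfg <- sim_config("V1-L", snr = Inf, n_participants = 1, seed = 5)
  ds <- simulate_group(pop, cfg)
  fm <- pop[[ds$participant_idx[1]]]
  expect_equal(ds$group_avg,
               outer(roi_topography(fm, "V1-L"), ds$waveform),
               tolerance = 1e-12, ignore_attr = TRUE)
  # additivity of two sources
  cfg2 <- sim_config("MT-R", snr = Inf, n_participants = 1, seed = 5)
  cfg12 <- sim_config(c("V1-L", "MT-R"), snr = Inf, n_participants = 1,
                      seed = 5)
  expect_equal(simulate_group(pop, cfg12)$group_avg,
               ds$group_avg + simulate_group(pop, cfg2)$group_avg,
               tolerance = 1e-12)
})

test_that("group averages, truth masks and resampling behave as defined", {
  pop <- test_population()
  cfg <- sim_config(c("V1-L", "V1-R"), snr = 10, n_participants = 8, seed = 9)
  ds <- simulate_group(pop, cfg)
  expect_equal(Reduce(`+`, ds$per_participant) / 8, ds$group_avg,
               tolerance = 1e-12)
  expect_true(all(ds$truth[setdiff(visual_rois(), c("V1-L", "V1-R")), ] == 0))
  expect_true(all(ds$truth[, attr(ds$waveform, "times_ms") <= 0] == 0))
  # with-replacement draws are reproducible under the seed
  ds2 <- simulate_group(pop, cfg)
  expect_identical(ds$participant_idx, ds2$participant_idx)
  expect_equal(ds$group_avg, ds2$group_avg, tolerance = 1e-15)
  expect_error(sim_config("V9-L"), "unknown")
})

test_that("the interferer is half the visual peak with its own waveform", {
  pop <- test_population()
  base <- sim_config(c("V1-L", "V1-R"), snr = Inf, n_participants = 3,
                     seed = 77)
  with_int <- sim_config(c("V1-L", "V1-R"), snr = Inf, n_participants = 3,
                         interferer = list(label = "frontal-L",
                                           relative_strength = 0.5),
                         seed = 77)
  d0 <- simulate_group(pop, base)
  d1 <- simulate_group(pop, with_int)
  extra <- d1$group_avg - d0$group_avg
  # the added scalp signal is rank one: topography x interferer waveform
  sv <- svd(extra)
  expect_lt(sv$d[2], 1e-9 * sv$d[1])
  # recover the interferer waveform by projecting onto the mean topography
  tbar <- rowMeans(vapply(seq_len(3), function(p) {
    roi_topography(pop[[d1$participant_idx[p]]], "frontal-L")
  }, numeric(nrow(extra))))
  iw <- as.vector(crossprod(tbar, extra)) / sum(tbar^2)
  # its peak is half the visual peak; the shape itself differs
  expect_equal(max(abs(iw)), 0.5 * max(abs(d0$waveform)), tolerance = 1e-9)
  expect_gt(max(abs(iw / max(abs(iw)) -
                      as.vector(d0$waveform) / max(abs(d0$waveform)))), 0.01)
  expect_error(sim_config("V1-L", interferer = list(label = "nope")),
               "unknown interferer")
})

test_that("an orthonormal noiseless system has identity crosstalk", {
  # hand-built population: 18 single-source ROIs whose scalp columns are
  # orthonormal within the zero-sum subspace
  E <- 24
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(E * 18), E))))[, 2:19]
  mon <- toy_montage(E)
  fm <- structure(list(
    participant_id = "ortho",
    geometry = head_geometry(),
    source_space = list(positions = matrix(0, 18, 3),
                        orientations = diag(3)[rep(1, 18), ],
                        roi_of = visual_rois(), parent_roi = NULL),
    leadfield = Q, montage = mon
  ), class = "forward_model")
  X <- suppressWarnings(
    crosstalk_matrix(list(fm), "template", snr = Inf, n_sim = 1,
                     n_participants = 1, seed = 4)
  )
  expect_lt(max(abs(X - diag(18))), 1e-8)
  expect_equal(unname(apply(X, 1, max)), rep(1, 18))
})

test_that("crosstalk concentrates within hemispheres on synthetic populations", {
  pop <- test_population()
  ts <- test_templates()
  X <- crosstalk_matrix(pop, "template", snr = 10, n_sim = 3,
                        n_participants = 12, seed = 21, templates = ts)
  expect_equal(unname(apply(X, 1, max)), rep(1, 18))
  rois <- visual_rois()
  hemi <- ifelse(grepl("-L$", rois), "L", "R")
  off <- !diag(18)
  same <- outer(hemi, hemi, `==`) & off
  expect_gt(mean(X[same]), mean(X[!same & off]))
})
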