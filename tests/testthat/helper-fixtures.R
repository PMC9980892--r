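# Shared fixtures.  Populations are expensive, so they are built once per
# test run and cached in a session-local environment.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# small desk-scale population: 12 participants, 300 sources, 32 electrodes
test_population <- function() {
  cached("pop_small", function() {
    mon <- montage_subsets(master_montage(), 32)[[1]]
    cfg <- population_config(n_sources = 300, montage = mon,
                             n_harmonics = 80L)
    make_population(12, cfg, seed = 424242)
  })
}

test_templates <- function() {
  cached("templates_small", function() build_templates(test_population()))
}

# study-scale population for the acceptance-criterion checks: 50
# participants, 1000 sources, 128 electrodes
acceptance_population <- function() {
  cached("pop_full", function() {
    mon <- montage_subsets(master_montage(), 128)[[1]]
    cfg <- population_config(n_sources = 1000, montage = mon)
    make_population(50, cfg, seed = 20260901)
  })
}

acceptance_templates <- function() {
  cached("templates_full", function() build_templates(acceptance_population()))
}

# independently derived closed-form potential for a dipole in a homogeneous
# conducting sphere (generating-function sums of the Legendre series), used
# as an analytic oracle for the shell model's homogeneous limit
homogeneous_sphere_potential <- function(radius, sigma, dip_pos, dip_mom,
                                         elec_pos) {
  R <- radius
  b <- sqrt(sum(dip_pos^2))
  rq <- dip_pos / b
  x <- b / R
  E <- if (is.matrix(elec_pos)) elec_pos else matrix(elec_pos, 1)
  eh <- E / sqrt(rowSums(E^2))
  cg <- as.vector(eh %*% rq)
  tv <- eh - outer(cg, rq)
  mr <- sum(dip_mom * rq)
  mt <- as.vector(tv %*% dip_mom)
  Ft <- sqrt(1 - 2 * x * cg + x^2)
  K <- 1 / (4 * pi * sigma * (R / 1000)^2)
  termA <- mr * (2 * (cg - x) / Ft^3 + (1 / x) * (1 / Ft - 1))
  termB <- mt * (2 / Ft^3 + (Ft + 1) / (Ft * (1 - x * cg + Ft)))
  K * (termA + termB)
}

# classic planted-truth ill-posed fixture: exponentially decaying singular
# values with the true solution confined to the leading singular directions,
# plus 1% noise -- the Picard coefficients drop sharply below the noise
# floor, giving the L-curve a well-defined corner
planted_illposed <- function(seed, n = 40, p = 30, decay = 0.8, k_sig = 8,
                             noise_level = 0.01) {
  set.seed(seed)
  U <- qr.Q(qr(matrix(rnorm(n * n), n)))[, 1:p]
  V <- qr.Q(qr(matrix(rnorm(p * p), p)))
  d <- exp(-decay * (1:p))
  X <- U %*% (d * t(V))
  coefs <- numeric(p)
  coefs[1:k_sig] <- 1
  xtrue <- V %*% coefs
  y0 <- X %*% xtrue
  noise <- rnorm(n)
  noise <- noise / sqrt(sum(noise^2)) * noise_level * sqrt(sum(y0^2))
  list(X = X, y = y0 + noise, xtrue = xtrue)
}

# naive O(n^2) pair-counting AUC oracle (ties one half)
naive_auc <- function(scores, is_active) {
  a <- scores[is_active]
  i <- scores[!is_active]
  tot <- 0
  for (av in a) tot <- tot + sum(av > i) + 0.5 * sum(av == i)
  tot / (length(a) * length(i))
}

# a tiny hand-made montage on a sphere
toy_montage <- function(n = 10, radius = 92, reference = "average") {
  set.seed(7)
  u <- matrix(rnorm(3 * n), n)
  u <- u / sqrt(rowSums(u^2))
  u[, 3] <- abs(u[, 3]) # upper hemisphere
  u <- u / sqrt(rowSums(u^2))
  montage(paste0("E", seq_len(n)), u * radius, reference = reference)
}
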