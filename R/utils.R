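#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

#' Derive a child seed from a parent seed
#'
#' All stochastic operations in the package flow from a single integer seed.
#' Sub-computations (participants of a population, simulation replicates,
#' bootstrap draws) use child seeds derived deterministically from the parent
#' seed and an index, so that populations are reproducible element-wise and
#' independent streams do not collide.  The mixing is a fixed affine map
#' modulo the Mersenne prime 2^31 - 1, keeping every seed a valid 32-bit
#' integer.
#'
#' @param seed integer parent seed.
#' @param index non-negative integer stream index.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, index) {
  m <- 2147483647 # 2^31 - 1
  s <- (as.numeric(seed) %% m) * 48271 %% m
  s <- (s + (as.numeric(index) + 1) * 69621) %% m
  s <- (s * 16807) %% m
  as.integer(if (s == 0) 1 else s)
}

## Evaluate `expr` under a given seed without disturbing the caller's RNG
## state.  A NULL seed leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stopf("%s contains non-finite values", what)
  invisible(x)
}

## row-wise unit normalization of a matrix of 3-vectors
unit_rows <- function(x) {
  n <- sqrt(rowSums(x^2))
  if (any(n < 1e-12)) stopf("cannot normalize zero-length vector")
  x / n
}

## Draw n unit vectors from a von Mises-Fisher distribution on S^2 centred on
## `mu` with concentration `kappa` (Wood 1994 inversion for the colatitude).
rvmf <- function(n, mu, kappa) {
  mu <- mu / sqrt(sum(mu^2))
  if (kappa <= 0) {
    w <- stats::runif(n, -1, 1)
  } else {
    u <- stats::runif(n)
    w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  }
  phi <- stats::runif(n, 0, 2 * pi)
  st <- sqrt(pmax(0, 1 - w^2))
  local <- cbind(st * cos(phi), st * sin(phi), w)
  # rotate local z-axis onto mu (Rodrigues, axis = z x mu)
  v <- c(-mu[2], mu[1], 0)
  c_ <- mu[3]
  if (abs(c_ - 1) < 1e-12) {
    return(local)
  }
  if (abs(c_ + 1) < 1e-12) {
    return(cbind(local[, 1], -local[, 2], -local[, 3]))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  rot <- diag(3) + vx + vx %*% vx / (1 + c_)
  local %*% t(rot)
}

## angular distance (radians) between unit row-vectors in `x` and a unit
## vector `mu`
angle_to <- function(x, mu) {
  acos(pmin(1, pmax(-1, as.vector(x %*% mu))))
}
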