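## Analytic forward physics: dipole potentials in a three-concentric-sphere
## head model (brain, skull, scalp), via the classical Legendre series.
##
## For each harmonic order n the radial part of the potential in shell j is
## a_j s^n + b_j s^-(n+1) with s = r / r_scalp.  The dipole's primary
## potential fixes the singular coefficient in the brain shell; continuity
## of potential and of radial current at the two interfaces plus the no-flux
## condition at the scalp determine the rest.  The scalp-surface gain g_n
## per unit source coefficient is precomputed per geometry and reused for
## all dipoles and electrodes.

#' Construct a three-shell head geometry
#'
#' Concentric spheres for brain, skull and scalp.  The default
#' conductivities are 0.33, 0.025 and 0.33 S/m for brain, skull and scalp,
#' the values commonly used for boundary-element EEG head models; default
#' radii are 80, 86 and 92 mm.
#'
#' @param radii strictly increasing numeric 3-vector (brain, outer skull,
#'   scalp) in millimetres.
#' @param conductivities positive numeric 3-vector (brain, skull, scalp) in
#'   S/m.
#' @return an object of class `head_geometry`.
#' @export
head_geometry <- function(radii = c(80, 86, 92),
                          conductivities = c(0.33, 0.025, 0.33)) {
  radii <- as.numeric(radii)
  conductivities <- as.numeric(conductivities)
  if (length(radii) != 3 || any(diff(radii) <= 0) || radii[1] <= 0) {
    stopf("radii must be 3 strictly increasing positive values")
  }
  if (length(conductivities) != 3 || any(conductivities <= 0)) {
    stopf("conductivities must be 3 positive values")
  }
  structure(list(radii = radii, conductivities = conductivities),
            class = "head_geometry")
}

#' @export
print.head_geometry <- function(x, ...) {
  cat(sprintf(
    "<head_geometry> radii %s mm; conductivities %s S/m\n",
    paste(signif(x$radii, 4), collapse = "/"),
    paste(signif(x$conductivities, 4), collapse = "/")
  ))
  invisible(x)
}

## Scalp-surface gain per harmonic order for a three-shell geometry.
## Returns g[1:n_max]; in the homogeneous limit g_n = (2n + 1) / n.
## Gains depend on the geometry only through the radius ratios and the
## conductivities, so results are memoized on those (a whole population
## whose radii jitter by a common factor shares one gain table).
.gain_cache <- new.env(parent = emptyenv())

shell_gains <- function(geometry, n_max) {
  s1 <- geometry$radii[1] / geometry$radii[3]
  s2 <- geometry$radii[2] / geometry$radii[3]
  cond <- geometry$conductivities
  key <- paste(signif(c(s1, s2, cond), 12), n_max, collapse = "|")
  hit <- .gain_cache[[key]]
  if (!is.null(hit)) {
    return(hit)
  }
  g <- numeric(n_max)
  for (n in seq_len(n_max)) {
    p1 <- s1^n; q1 <- s1^-(n + 1)
    p2 <- s2^n; q2 <- s2^-(n + 1)
    dp1 <- n * s1^(n - 1); dq1 <- -(n + 1) * s1^-(n + 2)
    dp2 <- n * s2^(n - 1); dq2 <- -(n + 1) * s2^-(n + 2)
    # unknowns a1, a2, b2, a3, b3; the source contributes s^-(n+1) with unit
    # coefficient in the brain shell
    A <- rbind(
      c(p1, -p1, -q1, 0, 0),
      c(cond[1] * dp1, -cond[2] * dp1, -cond[2] * dq1, 0, 0),
      c(0, p2, q2, -p2, -q2),
      c(0, cond[2] * dp2, cond[2] * dq2, -cond[3] * dp2, -cond[3] * dq2),
      c(0, 0, 0, n, -(n + 1))
    )
    rhs <- c(-q1, -cond[1] * dq1, 0, 0, 0)
    # equilibrate rows and columns: the two bases span a huge dynamic range
    # at large n, which is pure scaling, not intrinsic ill-conditioning
    dr <- 1 / apply(abs(A) + abs(rhs), 1, max)
    A <- A * dr
    rhs <- rhs * dr
    dc <- 1 / apply(abs(A), 2, max)
    x <- solve(sweep(A, 2, dc, `*`), rhs) * dc
    g[n] <- x[4] + x[5]
  }
  .gain_cache[[key]] <- g
  g
}

#' Scalp potential of a current dipole in a three-shell sphere
#'
#' Evaluates the Legendre-series solution for the electric potential at
#' scalp electrodes generated by a current dipole inside the brain sphere.
#' The series is truncated at `n_harmonics` terms; with the default 120
#' terms the truncation error for sources at up to ~0.9 of the brain radius
#' is far below 1e-8 of the peak potential (the geometric decay factor is
#' `(b / r_scalp)^n`).  The potential is exactly linear in the dipole
#' moment.
#'
#' @param geometry a [head_geometry()].
#' @param dipole_position 3-vector, mm; must lie strictly inside the brain
#'   sphere.
#' @param dipole_moment 3-vector, ampere-metres (A m).
#' @param electrode_position 3-vector or n x 3 matrix of scalp positions
#'   (mm); radial distance should equal the scalp radius (positions are
#'   projected onto the scalp sphere direction-wise).
#' @param n_harmonics series truncation order.
#' @return numeric vector of potentials in volts, one per electrode.
#' @export
dipole_potential <- function(geometry, dipole_position, dipole_moment,
                             electrode_position, n_harmonics = 120L) {
  stopifnot(inherits(geometry, "head_geometry"))
  b <- sqrt(sum(dipole_position^2))
  if (b >= geometry$radii[1]) {
    stopf("dipole at radius %.3g mm lies outside the brain sphere (%.3g mm)",
          b, geometry$radii[1])
  }
  E <- if (is.matrix(electrode_position)) electrode_position else
    matrix(electrode_position, 1)
  g <- shell_gains(geometry, n_harmonics)
  as.vector(leadfield_block(
    geometry, g,
    matrix(dipole_position, 1), matrix(dipole_moment, 1), E, n_harmonics
  ))
}

## Vectorized series evaluation: potentials (n_electrodes x n_dipoles) for
## dipoles with positions `pos` (d x 3), moments `mom` (d x 3), electrodes
## `elec` (e x 3), given precomputed gains g.  All dipoles may sit at
## different radii.
leadfield_block <- function(geometry, g, pos, mom, elec, n_harmonics) {
  r3 <- geometry$radii[3]
  sigma1 <- geometry$conductivities[1]
  d <- nrow(pos)
  b <- sqrt(rowSums(pos^2))
  rq <- pos / ifelse(b > 1e-12, b, 1) # unit dipole directions
  x <- b / r3
  eh <- unit_rows(elec)
  C <- eh %*% t(rq) # e x d, cos(gamma)
  mr <- rowSums(mom * rq) # radial moment per dipole
  # tangential term m . t with t = e_hat - cos(gamma) * rq, per (e, d):
  # m . e_hat  -  C * (m . rq)
  MT <- eh %*% t(mom) - C * matrix(mr, nrow(C), d, byrow = TRUE)
  K <- 1 / (4 * pi * sigma1 * (r3 / 1000)^2) # mm -> m in the 1/R^2 factor
  e <- nrow(C)
  Pm <- matrix(1, e, d) # P_0
  Pn <- C # P_1
  dPm <- matrix(0, e, d) # P_0'
  dPn <- matrix(1, e, d) # P_1'
  V <- matrix(0, e, d)
  xp <- rep(1, d) # x^(n-1)
  MRn <- matrix(mr, e, d, byrow = TRUE)
  for (n in seq_len(n_harmonics)) {
    w <- g[n] * xp
    V <- V + sweep(n * MRn * Pn + MT * dPn, 2, w, `*`)
    if (n < n_harmonics) {
      Pnx <- ((2 * n + 1) * C * Pn - n * Pm) / (n + 1)
      dPnx <- dPm + (2 * n + 1) * Pn
      Pm <- Pn; Pn <- Pnx
      dPm <- dPn; dPn <- dPnx
      xp <- xp * x
    }
  }
  K * V
}

#' Lead field of a set of dipoles at a set of electrodes
#'
#' Computes the electrodes x sources lead-field matrix (volts per unit
#' dipole moment) for unit-moment dipoles with the given positions and
#' orientations, then applies the average reference so that every column
#' sums to zero.
#'
#' @param geometry a [head_geometry()].
#' @param positions n_sources x 3 matrix of dipole positions (mm, inside
#'   the brain sphere).
#' @param orientations n_sources x 3 matrix of unit orientation vectors.
#' @param electrodes n_electrodes x 3 matrix of scalp positions (mm).
#' @param n_harmonics series truncation order.
#' @param reference `"average"` (default) or `"none"`.
#' @return n_electrodes x n_sources matrix.
#' @export
leadfield_matrix <- function(geometry, positions, orientations, electrodes,
                             n_harmonics = 120L, reference = "average") {
  positions <- as.matrix(positions)
  orientations <- as.matrix(orientations)
  if (any(sqrt(rowSums(positions^2)) >= geometry$radii[1])) {
    stopf("all dipoles must lie strictly inside the brain sphere")
  }
  g <- shell_gains(geometry, n_harmonics)
  L <- leadfield_block(geometry, g, positions, orientations,
                       as.matrix(electrodes), n_harmonics)
  if (identical(reference, "average")) {
    L <- sweep(L, 2, colMeans(L), `-`)
  }
  L
}
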