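## The master montage: a dense, idealized 10-05-style electrode layout on a
## sphere.  It is generated geometrically (not digitized from a head), which
## keeps it exactly consistent with the spherical head model used by the
## synthetic population: rows of electrodes are arcs from a midline point to
## the equatorial rim, at 5% steps of the nasion-inion distance, with
## 10-20/10-10 labels where they exist (Fz, C3, T7, ...) and systematic
## extension labels elsewhere (e.g. FFC5, PO3h).  All 19 classic anchors of
## [alignment_anchors()] are present at their conventional locations.

## row name by anterior fraction (0.10 steps are 10-10 rows, 0.05 the 10-05
## intermediates)
.row_names <- c(
  "0.1" = "Fp", "0.15" = "AFp", "0.2" = "AF", "0.25" = "AFF",
  "0.3" = "F", "0.35" = "FFC", "0.4" = "FC", "0.45" = "FCC",
  "0.5" = "C", "0.55" = "CCP", "0.6" = "CP", "0.65" = "CPP",
  "0.7" = "P", "0.75" = "PPO", "0.8" = "PO", "0.85" = "POO",
  "0.9" = "O", "0.95" = "OI"
)

.col_label <- function(k, side) {
  # k = 1..8 lateral steps from midline; even k are the standard numbered
  # columns (1, 3, 5, 7 left / 2, 4, 6, 8 right), odd k the 10-05 "h"
  # intermediates
  num <- if (side == "L") c("1h", "1", "3h", "3", "5h", "5", "7h", "7") else
    c("2h", "2", "4h", "4", "6h", "6", "8h", "8")
  num[k]
}

#' Generate the master montage
#'
#' A dense idealized 10-05-style montage of 307 electrodes on a sphere of
#' the given radius: 18 electrode rows from Fp to OI at 5% steps, each with
#' a midline electrode and 8 lateral positions per side at equal angular
#' steps down to the equatorial rim, plus Iz.  Temporal-row electrodes use
#' the conventional T7/T8 names.  Positions are millimetres (+x right, +y
#' anterior, +z superior), head-centred; the reference is average.
#'
#' @param radius scalp sphere radius in mm.
#' @return an `eeg_montage`.
#' @export
master_montage <- function(radius = 92) {
  labels <- character(0)
  pos <- NULL
  for (a in as.numeric(names(.row_names))) {
    row <- .row_names[[as.character(a)]]
    # midline point at anterior fraction a (vertex at a = 0.5)
    th <- pi * (0.5 - a) # signed polar angle toward the front
    mid <- c(0, sin(th), cos(th))
    for (k in -8:8) {
      if (k == 0) {
        lab <- paste0(row, "z")
        p <- mid
      } else {
        side <- if (k < 0) "L" else "R"
        lab <- paste0(row, .col_label(abs(k), side))
        if (row == "C" && abs(k) >= 7) {
          # temporal naming on the central row
          lab <- paste0("T", .col_label(abs(k), side))
        }
        # rotate the midline point about the nasion-inion (y) axis; negative
        # k rotates toward the left (-x)
        beta <- (k / 8) * (pi / 2)
        p <- c(sin(beta) * mid[3], mid[2], cos(beta) * mid[3])
        p <- p / sqrt(sum(p^2))
      }
      labels <- c(labels, lab)
      pos <- rbind(pos, p)
    }
  }
  labels <- c(labels, "Iz")
  pos <- rbind(pos, c(0, -1, 0))
  montage(labels, pos * radius, reference = "average")
}

#' Nested electrode subsets of a montage
#'
#' Deterministic farthest-point thinning of a montage: starting from the
#' electrode closest to the vertex, electrodes are added one at a time by
#' always taking the one farthest (great-circle) from the set selected so
#' far, ties broken by montage order.  The first `n` selected electrodes
#' therefore form spatially near-uniform montages that are nested across
#' sizes (the 32-subset is contained in the 64-subset, and so on).
#'
#' @param m an `eeg_montage` (typically [master_montage()]).
#' @param sizes integer vector of subset sizes.
#' @return a named list of `eeg_montage` objects, one per size, electrodes
#'   in master order.
#' @export
montage_subsets <- function(m, sizes = c(32, 64, 128, 256)) {
  stopifnot(inherits(m, "eeg_montage"))
  if (max(sizes) > n_electrodes(m)) {
    stopf("requested subset of %d from a %d-electrode montage",
          max(sizes), n_electrodes(m))
  }
  u <- unit_rows(m$positions)
  n <- nrow(u)
  # start nearest the vertex (0,0,1)
  sel <- integer(0)
  d2vert <- u[, 3]
  first <- which.max(d2vert)
  sel <- first
  mind <- as.vector(u %*% u[first, ]) # cosine similarity to selected set
  for (i in seq_len(max(sizes) - 1)) {
    cand <- which.min(ifelse(seq_len(n) %in% sel, Inf, mind))
    sel <- c(sel, cand)
    mind <- pmax(mind, as.vector(u %*% u[cand, ]))
  }
  out <- lapply(sizes, function(s) {
    keep <- sort(sel[seq_len(s)])
    montage(m$labels[keep], m$positions[keep, , drop = FALSE],
            reference = m$reference)
  })
  names(out) <- as.character(sizes)
  out
}
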