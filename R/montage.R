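## Electrode montages: construction, SFP file I/O, affine alignment to the
## master montage, and referencing.
##
## Coordinates are millimetres in head-centred Cartesian axes: +x right,
## +y anterior, +z superior.  All file I/O in the package uses this
## convention.

#' Construct an electrode montage
#'
#' A montage is an ordered, labelled set of 3D electrode positions together
#' with a reference specification.  The reference is either `"average"`
#' (common average reference) or the label of one of the electrodes.
#'
#' @param labels character vector of unique, non-empty electrode labels.
#' @param positions numeric matrix with one row per electrode and columns
#'   x, y, z in millimetres (+x right, +y anterior, +z superior).
#' @param reference `"average"` or an electrode label present in `labels`.
#' @return an object of class `eeg_montage` with fields `labels`,
#'   `positions` (rownames set to the labels) and `reference`.
#' @export
montage <- function(labels, positions, reference = "average") {
  labels <- as.character(labels)
  positions <- as.matrix(positions)
  if (length(labels) < 2) stopf("a montage needs at least 2 electrodes")
  if (any(!nzchar(labels))) stopf("electrode labels must be non-empty")
  if (anyDuplicated(labels)) {
    stopf("duplicate electrode labels: %s",
          paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  if (nrow(positions) != length(labels) || ncol(positions) != 3) {
    stopf("positions must be a %d x 3 matrix", length(labels))
  }
  check_finite(positions, "electrode positions")
  if (!identical(reference, "average") && !(reference %in% labels)) {
    stopf("reference label '%s' not in montage", reference)
  }
  dimnames(positions) <- list(labels, c("x", "y", "z"))
  structure(
    list(labels = labels, positions = positions, reference = reference),
    class = "eeg_montage"
  )
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %d electrodes, reference: %s\n",
              length(x$labels), x$reference))
  cat("  ", paste(utils::head(x$labels, 8), collapse = " "),
      if (length(x$labels) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
format.eeg_montage <- function(x, ...) {
  sprintf("<eeg_montage> %d electrodes", length(x$labels))
}

#' Number of electrodes in a montage
#' @param m an `eeg_montage`.
#' @return integer electrode count.
#' @export
n_electrodes <- function(m) length(m$labels)

#' Read an electrode montage from an SFP-style file
#'
#' The SFP dialect is whitespace-separated `label x y z`, one electrode per
#' line; lines starting with `#` are comments.  Coordinates are millimetres
#' (+x right, +y anterior, +z superior).  The reference defaults to the
#' average reference; pass `reference` to override (e.g. from a JSON sidecar
#' or a CLI flag).
#'
#' @param path path to the electrode file.
#' @param reference `"average"` or an electrode label.
#' @return an `eeg_montage` preserving file order.
#' @export
load_montage <- function(path, reference = "average") {
  if (!file.exists(path)) stopf("montage file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stopf("montage file '%s' is empty", path)
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- which(vapply(parts, length, 1L) != 4)
  if (length(bad)) {
    stopf("montage file '%s': line %d does not have 4 fields", path, bad[1])
  }
  labels <- vapply(parts, `[`, "", 1)
  coords <- suppressWarnings(
    t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  )
  if (any(is.na(coords))) {
    i <- which(rowSums(is.na(coords)) > 0)[1]
    stopf("montage file '%s': non-numeric coordinate for electrode '%s'",
          path, labels[i])
  }
  montage(labels, coords, reference = reference)
}

#' Write a montage to an SFP-style file
#'
#' @param m an `eeg_montage`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_montage <- function(m, path) {
  stopifnot(inherits(m, "eeg_montage"))
  txt <- sprintf("%s\t%.15g\t%.15g\t%.15g", m$labels,
                 m$positions[, 1], m$positions[, 2], m$positions[, 3])
  writeLines(c("# label x y z (mm; +x right, +y anterior, +z superior)", txt),
             path)
  invisible(path)
}

#' Standard 19-electrode anchor set for montage alignment
#'
#' The default anchor labels used by [affine_align()]: the classic 10-20
#' electrodes Fp1, Fp2, Fz, F7, F3, C3, T7, P3, P7, Pz, O1, Oz, O2, P4, P8,
#' T8, C4, F4, F8.
#'
#' @return character vector of 19 labels.
#' @export
alignment_anchors <- function() {
  c("Fp1", "Fp2", "Fz", "F7", "F3", "C3", "T7", "P3", "P7", "Pz",
    "O1", "Oz", "O2", "P4", "P8", "T8", "C4", "F4", "F8")
}

#' Least-squares affine alignment of one montage onto another
#'
#' Estimates the general 12-parameter affine transform mapping the measured
#' anchor positions onto the standard montage's anchor positions in the
#' least-squares sense.  Anchors are electrodes common to both montages; the
#' default set is the 19 classic 10-20 electrodes of
#' [alignment_anchors()].
#'
#' @param measured the montage to be aligned (`eeg_montage`).
#' @param standard the target montage (`eeg_montage`).
#' @param anchors character vector of anchor labels present in both
#'   montages; at least 4 non-coplanar anchors are required.
#' @return an object of class `eeg_alignment`: list with `affine` (3 x 4
#'   matrix, linear part in columns 1:3 and translation in column 4,
#'   millimetres), `rms_residual` (mm, over anchors) and `anchor_labels`.
#' @export
affine_align <- function(measured, standard, anchors = alignment_anchors()) {
  stopifnot(inherits(measured, "eeg_montage"), inherits(standard, "eeg_montage"))
  miss_m <- setdiff(anchors, measured$labels)
  miss_s <- setdiff(anchors, standard$labels)
  if (length(miss_m) || length(miss_s)) {
    stopf("anchor labels missing: %s",
          paste(unique(c(miss_m, miss_s)), collapse = ", "))
  }
  if (length(anchors) < 4) stopf("need at least 4 anchors, got %d", length(anchors))
  X <- measured$positions[anchors, , drop = FALSE]
  Y <- standard$positions[anchors, , drop = FALSE]
  Xh <- cbind(X, 1)
  q <- qr(Xh)
  if (q$rank < 4) {
    stopf("anchor set is coplanar or degenerate (rank %d < 4)", q$rank)
  }
  # solve Xh %*% t(affine) = Y
  coefs <- qr.coef(q, Y) # 4 x 3
  affine <- t(coefs)[, c(1, 2, 3, 4), drop = FALSE]
  fitted <- Xh %*% coefs
  rms <- sqrt(mean(rowSums((fitted - Y)^2)))
  if (abs(det(affine[, 1:3])) < 1e-12) {
    stopf("estimated affine linear part is singular")
  }
  structure(
    list(affine = affine, rms_residual = rms, anchor_labels = anchors),
    class = "eeg_alignment"
  )
}

#' @export
print.eeg_alignment <- function(x, ...) {
  cat(sprintf("<eeg_alignment> %d anchors, rms residual %.4g mm\n",
              length(x$anchor_labels), x$rms_residual))
  invisible(x)
}

#' Apply an affine transform to 3D positions
#'
#' @param affine a 3 x 4 affine matrix (linear part + translation) or an
#'   `eeg_alignment` object.
#' @param positions n x 3 matrix of positions (mm).
#' @return n x 3 matrix of transformed positions.
#' @export
affine_apply <- function(affine, positions) {
  if (inherits(affine, "eeg_alignment")) affine <- affine$affine
  stopifnot(is.matrix(affine), nrow(affine) == 3, ncol(affine) == 4)
  positions <- as.matrix(positions)
  out <- cbind(positions, 1) %*% t(affine)
  colnames(out) <- c("x", "y", "z")
  out
}

#' Re-reference a matrix of scalp data
#'
#' Under the average reference the mean over electrodes is subtracted at
#' each sample, so every column of the output sums to zero; under a label
#' reference that electrode's row is subtracted from all rows (and becomes
#' identically zero).  Both operations are idempotent linear projectors.
#'
#' @param data electrodes x samples numeric matrix.  For a label reference
#'   the rows must be named (or `labels` supplied).
#' @param reference `"average"` or an electrode label.
#' @param labels optional character vector of row labels overriding
#'   `rownames(data)`.
#' @return the re-referenced matrix (same shape).
#' @export
apply_reference <- function(data, reference = "average", labels = NULL) {
  data <- as.matrix(data)
  check_finite(data, "data")
  if (identical(reference, "average")) {
    return(sweep(data, 2, colMeans(data), `-`))
  }
  labels <- labels %||% rownames(data)
  if (is.null(labels)) stopf("label reference needs row labels on the data")
  i <- match(reference, labels)
  if (is.na(i)) stopf("reference label '%s' not found in data rows", reference)
  sweep(data, 2, data[i, ], `-`)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reference projector matrix
#'
#' The matrix `P` such that `apply_reference(data, ref) == P %*% data`.
#' Useful for reasoning about referencing as a linear operator (`P` is
#' idempotent and its rows sum to zero for the average reference).
#'
#' @param n number of electrodes.
#' @param reference `"average"` or a label present in `labels`.
#' @param labels electrode labels (needed for a label reference).
#' @return n x n projector matrix.
#' @export
reference_projector <- function(n, reference = "average", labels = NULL) {
  if (identical(reference, "average")) {
    return(diag(n) - matrix(1 / n, n, n))
  }
  i <- match(reference, labels)
  if (is.na(i)) stopf("reference label '%s' not found", reference)
  P <- diag(n)
  P[, i] <- P[, i] - 1
  P
}
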