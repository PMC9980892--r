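## ROI scalp topographies and EEG templates: per-participant projection of
## unit ROI activation to the scalp, cross-participant averaging, template
## file I/O, montage customization and sampling-variability analysis.

#' Scalp topography of one ROI for one participant
#'
#' Sum of the lead-field columns of all sources assigned to the ROI, i.e.
#' the scalp pattern generated when every source in the ROI is active with
#' unit dipole moment.  An empty ROI yields a zero vector with a warning.
#'
#' @param fm a `forward_model`.
#' @param roi an ROI label.
#' @return numeric vector of length `n_electrodes`, volts per unit ROI
#'   activation.
#' @export
roi_topography <- function(fm, roi) {
  idx <- roi_sources(fm, roi)
  if (length(idx) == 0) {
    warning(sprintf("ROI '%s' is empty for participant %s; zero topography",
                    roi, fm$participant_id), call. = FALSE)
    return(stats::setNames(numeric(nrow(fm$leadfield)),
                           rownames(fm$leadfield)))
  }
  rowSums(fm$leadfield[, idx, drop = FALSE])
}

#' Construct a template set
#'
#' Low-level constructor; most users will call [build_templates()].
#'
#' @param matrix electrodes x ROIs numeric matrix (volts per unit ROI
#'   activation).
#' @param roi_names character vector naming the columns.
#' @param montage the `eeg_montage` the rows refer to.
#' @param n_participants number of participants averaged.
#' @param provenance free-form metadata list.
#' @return an object of class `eeg_templates`.
#' @export
template_set <- function(matrix, roi_names, montage, n_participants = NA_integer_,
                         provenance = list()) {
  matrix <- as.matrix(matrix)
  check_finite(matrix, "template matrix")
  if (anyDuplicated(roi_names)) stopf("ROI names must be unique")
  if (ncol(matrix) != length(roi_names)) {
    stopf("template matrix has %d columns for %d ROI names",
          ncol(matrix), length(roi_names))
  }
  if (nrow(matrix) != n_electrodes(montage)) {
    stopf("template matrix has %d rows for a %d-electrode montage",
          nrow(matrix), n_electrodes(montage))
  }
  dimnames(matrix) <- list(montage$labels, roi_names)
  structure(
    list(matrix = matrix, roi_names = as.character(roi_names),
         montage = montage, n_participants = n_participants,
         provenance = provenance),
    class = "eeg_templates"
  )
}

#' @export
print.eeg_templates <- function(x, ...) {
  cat(sprintf(
    "<eeg_templates> %d electrodes x %d ROIs (averaged over %s participants, reference: %s)\n",
    nrow(x$matrix), ncol(x$matrix),
    ifelse(is.na(x$n_participants), "?", x$n_participants),
    x$montage$reference
  ))
  invisible(x)
}

#' Build EEG templates from a population of forward models
#'
#' Column `r` of the template matrix is the across-participant mean of
#' [roi_topography()] for ROI `r`.  Templates are deliberately not
#' normalized per ROI: a large ROI (e.g. V1) produces a stronger scalp
#' pattern than a small one, and the templates keep that physical scale.
#' Pass `normalize = TRUE` to rescale every column to unit Euclidean norm
#' instead.
#'
#' @param population list of `forward_model`s sharing one montage.
#' @param roi_names ROIs to include (default the 18 visual ROIs).
#' @param normalize rescale each column to unit norm (default `FALSE`).
#' @return an `eeg_templates` object.
#' @export
build_templates <- function(population, roi_names = visual_rois(),
                            normalize = FALSE) {
  stopifnot(length(population) >= 1)
  mon <- population[[1]]$montage
  for (fm in population) {
    if (!identical(fm$montage$labels, mon$labels)) {
      stopf("participants do not share a montage (labels differ)")
    }
  }
  acc <- matrix(0, n_electrodes(mon), length(roi_names))
  for (fm in population) {
    for (r in seq_along(roi_names)) {
      acc[, r] <- acc[, r] + roi_topography(fm, roi_names[r])
    }
  }
  M <- acc / length(population)
  if (normalize) {
    nrm <- sqrt(colSums(M^2))
    M <- sweep(M, 2, ifelse(nrm > 0, nrm, 1), `/`)
  }
  template_set(M, roi_names, mon, n_participants = length(population),
               provenance = list(normalized = normalize))
}

#' Fit templates to an arbitrary target montage
#'
#' Subsets (and reorders) a template set to the electrodes of a target
#' montage, then re-references the rows to the target's reference.
#' Matching is `by_label` (labels must be present in the template montage)
#' or `nearest_position` (after affine alignment of the target onto the
#' template montage using the shared anchor electrodes, each target
#' electrode takes the nearest template electrode within
#' `distance_threshold`; ties break to the smallest template index).
#' Re-referencing happens after subsetting because the average-reference
#' projector depends on the electrode set: the projector is always applied
#' in the target space.
#'
#' @param templates an `eeg_templates`.
#' @param target an `eeg_montage`.
#' @param match_mode `"by_label"` or `"nearest_position"`.
#' @param distance_threshold maximum electrode match distance in mm for
#'   `nearest_position` (default 10); beyond it matching fails.
#' @param anchors anchor labels used to align the target for
#'   `nearest_position` matching.
#' @return an `eeg_templates` on the target montage, with provenance
#'   recording the match mode and matched labels.
#' @export
customize_templates <- function(templates, target,
                                match_mode = c("by_label", "nearest_position"),
                                distance_threshold = 10,
                                anchors = alignment_anchors()) {
  stopifnot(inherits(templates, "eeg_templates"), inherits(target, "eeg_montage"))
  match_mode <- match.arg(match_mode)
  src <- templates$montage
  if (match_mode == "by_label") {
    idx <- match(target$labels, src$labels)
    if (anyNA(idx)) {
      stopf("electrodes not present in template montage: %s",
            paste(target$labels[is.na(idx)], collapse = ", "))
    }
  } else {
    common <- intersect(anchors, intersect(target$labels, src$labels))
    # with enough shared anchors, bring the target into the template frame
    # first; otherwise the two montages are assumed co-registered already
    tpos <- if (length(common) >= 4) {
      affine_apply(affine_align(target, src, anchors = common),
                   target$positions)
    } else {
      target$positions
    }
    idx <- integer(length(target$labels))
    dist <- numeric(length(idx))
    for (i in seq_along(idx)) {
      d <- sqrt(rowSums(sweep(src$positions, 2, tpos[i, ], `-`)^2))
      idx[i] <- which.min(d) # ties: smallest template index
      dist[i] <- d[idx[i]]
    }
    if (any(dist > distance_threshold)) {
      bad <- target$labels[dist > distance_threshold]
      stopf("electrodes with no template electrode within %g mm: %s",
            distance_threshold, paste(bad, collapse = ", "))
    }
  }
  M <- templates$matrix[idx, , drop = FALSE]
  M <- apply_reference(M, target$reference, labels = target$labels)
  rownames(M) <- target$labels
  out_mon <- montage(target$labels, target$positions, target$reference)
  template_set(
    M, templates$roi_names, out_mon, templates$n_participants,
    provenance = c(templates$provenance, list(
      match_mode = match_mode,
      matched_from = src$labels[idx],
      dropped = setdiff(src$labels, src$labels[idx])
    ))
  )
}

#' Save templates to a CSV file with a JSON sidecar
#'
#' The CSV has channel labels in the first column and one header-named
#' column per ROI, cells in volts.  The sidecar `<path>.json` records the
#' reference, the number of participants, the electrode positions and any
#' provenance metadata, making the round trip lossless.
#'
#' @param ts an `eeg_templates`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
save_templates <- function(ts, path) {
  stopifnot(inherits(ts, "eeg_templates"))
  df <- data.frame(channel = ts$montage$labels,
                   ts$matrix, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(
    reference = ts$montage$reference,
    n_participants = ts$n_participants,
    roi_names = ts$roi_names,
    positions_mm = unname(ts$montage$positions),
    provenance = ts$provenance
  )
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_templates
#' @export
load_templates <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!("channel" %in% names(df))) {
    stopf("template file '%s' lacks a 'channel' column", path)
  }
  labels <- as.character(df$channel)
  M <- as.matrix(df[, setdiff(names(df), "channel"), drop = FALSE])
  if (any(is.na(M))) stopf("template file '%s': non-numeric or missing cells", path)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!identical(sort(unname(unlist(side$roi_names))), sort(colnames(M)))) {
      stopf("template file and sidecar disagree on ROI names")
    }
    pos <- matrix(unlist(side$positions_mm), ncol = 3, byrow = FALSE)
    if (is.matrix(side$positions_mm)) pos <- side$positions_mm
    mon <- montage(labels, pos, reference = side$reference)
    np <- side$n_participants
    prov <- side$provenance
  } else {
    # no sidecar: positions unknown; place electrodes on a unit sphere
    # placeholder so the montage object is still valid
    ang <- seq(0, 2 * pi, length.out = length(labels) + 1)[-1]
    mon <- montage(labels, cbind(cos(ang), sin(ang), 1), reference = "average")
    np <- NA_integer_
    prov <- list()
  }
  template_set(M, colnames(M), mon, n_participants = np,
               provenance = as.list(prov))
}

#' Sampling variability of averaged templates versus sample size
#'
#' For each sample size `N`, draws `n_boot` independent `N`-participant
#' samples from the generator, averages each sample, and records the mean
#' (over matrix cells) squared deviation of the `N`-average from the grand
#' mean of a large reference sample.  For independent participants this
#' variance decays as 1/N, i.e. the magnitude of the log-log slope is 1.
#'
#' @param population_generator function `f(n)` returning the stacked
#'   per-participant quantities for `n` fresh participants as a matrix with
#'   one column per participant (any number of rows: electrodes, or
#'   electrode x ROI cells).  It is called under seeded RNG, so it should
#'   consume the current RNG stream and need not seed itself.
#' @param n_values strictly increasing sample sizes (at least 2 values).
#' @param n_boot bootstrap samples per `N` (>= 50).
#' @param seed integer seed.
#' @param reference_n size of the reference sample used to estimate the
#'   grand mean (default 2000).
#' @return list of class `variability_curve` with `n_values`, `variance`,
#'   `fitted_exponent` (magnitude of the least-squares log-log slope) and
#'   `grand_mean`.
#' @export
template_variability <- function(population_generator, n_values,
                                 n_boot = 200, seed = 1,
                                 reference_n = 2000) {
  n_values <- sort(unique(as.integer(n_values)))
  if (length(n_values) < 2) {
    stopf("need at least 2 sample sizes to fit a decay slope")
  }
  if (n_boot < 50) stopf("n_boot must be >= 50")
  with_seed(seed, {
    ref <- population_generator(reference_n)
    grand <- rowMeans(ref)
    variance <- vapply(n_values, function(N) {
      dev2 <- vapply(seq_len(n_boot), function(b) {
        avg <- rowMeans(population_generator(N))
        mean((avg - grand)^2)
      }, numeric(1))
      mean(dev2)
    }, numeric(1))
  })
  fit <- stats::lm(log(variance) ~ log(n_values))
  structure(
    list(n_values = n_values, variance = variance,
         fitted_exponent = abs(unname(stats::coef(fit)[2])),
         grand_mean = grand),
    class = "variability_curve"
  )
}

#' @export
print.variability_curve <- function(x, ...) {
  cat(sprintf("<variability_curve> N = %s; fitted decay exponent %.3f\n",
              paste(x$n_values, collapse = ", "), x$fitted_exponent))
  invisible(x)
}

#' Lightweight per-participant ROI topography sampler
#'
#' Returns a generator `f(n)` producing an electrodes x n matrix of
#' single-ROI scalp topographies for `n` fresh synthetic participants.
#' Only the sources of the requested ROI cap are generated, which makes
#' sampling thousands of surrogate participants cheap; the per-participant
#' variability model (centroid, orientation and radii jitter) is the same
#' as in [make_participant()].
#'
#' @param roi one of [visual_rois()].
#' @param config a [population_config()]; `n_sources` only sets the
#'   expected number of sources falling in the cap.
#' @return function `f(n)` consuming the current RNG stream.
#' @export
roi_topography_sampler <- function(roi, config = population_config()) {
  dirs_all <- .roi_directions()
  if (!(roi %in% rownames(dirs_all))) stopf("unknown ROI '%s'", roi)
  mu0 <- dirs_all[roi, ]
  cap <- config$roi_cap_deg * pi / 180
  # expected cap occupancy under uniform source placement
  frac <- (1 - cos(cap)) / 2
  lambda <- config$n_sources * frac
  elec_dir <- unit_rows(config$montage$positions)
  g0 <- config$geometry
  force(config)
  # The radii jitter is a common factor on all three shells, so the radius
  # ratios, the series gains and x = b/r_scalp are identical across
  # participants; the dipole potential then scales as 1/r_scalp^2.  All
  # participants of one draw can therefore share a single batched series
  # evaluation at the base geometry, with per-participant 1/jitter^2
  # column scaling.
  function(n) {
    scale2 <- exp(-2 * stats::rnorm(n, 0, config$radii_sd))
    pos_all <- NULL
    ori_all <- NULL
    owner <- integer(0)
    for (j in seq_len(n)) {
      mu <- as.vector(rvmf(1, mu0, config$centroid_kappa))
      k <- max(1L, stats::rpois(1, lambda))
      # uniform directions within the cap around mu
      w <- 1 - stats::runif(k) * (1 - cos(cap))
      phi <- stats::runif(k, 0, 2 * pi)
      st <- sqrt(pmax(0, 1 - w^2))
      local <- cbind(st * cos(phi), st * sin(phi), w)
      v <- c(-mu[2], mu[1], 0)
      if (abs(mu[3] - 1) < 1e-12) {
        sd_ <- local
      } else if (abs(mu[3] + 1) < 1e-12) {
        sd_ <- cbind(local[, 1], -local[, 2], -local[, 3])
      } else {
        vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
        rot <- diag(3) + vx + vx %*% vx / (1 + mu[3])
        sd_ <- local %*% t(rot)
      }
      ori <- sd_
      for (i in seq_len(k)) {
        ori[i, ] <- rvmf(1, sd_[i, ], config$orientation_kappa)
      }
      pos_all <- rbind(pos_all, sd_ * (config$source_radius_frac * g0$radii[1]))
      ori_all <- rbind(ori_all, ori)
      owner <- c(owner, rep(j, k))
    }
    g <- shell_gains(g0, config$n_harmonics)
    L <- leadfield_block(g0, g, pos_all, ori_all, elec_dir * g0$radii[3],
                         config$n_harmonics)
    L <- sweep(L, 2, colMeans(L), `-`) # average reference
    out <- matrix(0, nrow(elec_dir), n)
    for (j in seq_len(n)) {
      out[, j] <- rowSums(L[, owner == j, drop = FALSE]) * scale2[j]
    }
    out
  }
}
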