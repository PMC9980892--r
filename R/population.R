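## Synthetic head-model population: per-participant lead fields with ROI
## assignments, emulating the statistical structure of a multi-participant
## set of MRI-derived forward models.  Sources live on a cortical sphere
## inside the brain shell; ROIs are spherical caps around canonical
## directions near the occipital pole, mirrored across the sagittal plane;
## between-participant variability enters through von Mises-Fisher jitter of
## the cap centroids, jitter of the source orientations around the surface
## normal, and jitter of the shell radii.

#' Names of the 18 visual ROIs
#'
#' The functionally defined visual areas for which templates are built:
#' V1, V2v, V2d, V3v, V3d, V4, V3A, LOC and MT, each for the left (-L) and
#' right (-R) hemisphere.
#'
#' @return character vector of 18 labels.
#' @export
visual_rois <- function() {
  base <- c("V1", "V2v", "V2d", "V3v", "V3d", "V4", "V3A", "LOC", "MT")
  as.vector(t(outer(base, c("L", "R"), paste, sep = "-")))
}

#' Names of the non-visual anatomical cap labels
#'
#' Eight bilateral caps at frontal/temporal directions used as interfering
#' (non-recovered) sources in the simulation battery.
#'
#' @return character vector of 8 labels.
#' @export
anatomical_labels <- function() {
  base <- c("frontal", "orbitofrontal", "temporal", "parahippocampal")
  as.vector(t(outer(base, c("L", "R"), paste, sep = "-")))
}

## canonical (pre-jitter) cap centroid directions, unit vectors.
## Left-hemisphere entries; right is the mirror x -> -x.
## The ventral cluster V2v/V3v/V4 is deliberately placed at small angular
## separation so that their templates are mutually similar.
.roi_directions <- function() {
  ## directions parameterized by (azimuth from the occipital pole toward
  ## -x, elevation): the ventral trio V2v/V3v/V4 sits 11-15 degrees apart
  ## (mutually similar templates), V1 near the pole, dorsal areas above,
  ## LOC/MT lateral and anterior
  L <- rbind(
    "V1"  = c(-0.1736, -0.9848,  0.0000),
    "V2v" = c(-0.2314, -0.9279, -0.2924),
    "V2d" = c(-0.2301, -0.9228,  0.3090),
    "V3v" = c(-0.3918, -0.8403, -0.3746),
    "V3d" = c(-0.3861, -0.8280,  0.4067),
    "V4"  = c(-0.2649, -0.8152, -0.5150),
    "V3A" = c(-0.2767, -0.7602,  0.5878),
    "LOC" = c(-0.5584, -0.8279, -0.0523),
    "MT"  = c(-0.7319, -0.6590,  0.1736)
  )
  A <- rbind(
    "frontal"         = c(-0.40, 0.85,  0.33),
    "orbitofrontal"   = c(-0.30, 0.90, -0.31),
    "temporal"        = c(-0.95, 0.10, -0.10),
    "parahippocampal" = c(-0.30, 0.05, -0.95)
  )
  dirs <- rbind(L, A)
  out <- NULL
  nm <- character(0)
  for (i in seq_len(nrow(dirs))) {
    d <- dirs[i, ] / sqrt(sum(dirs[i, ]^2))
    out <- rbind(out, d, d * c(-1, 1, 1))
    nm <- c(nm, paste0(rownames(dirs)[i], "-L"), paste0(rownames(dirs)[i], "-R"))
  }
  rownames(out) <- nm
  out
}

#' Configuration of the synthetic population generator
#'
#' @param n_sources number of cortical sources per participant.
#' @param montage `eeg_montage` whose electrode directions are projected
#'   onto each participant's scalp sphere (default: [master_montage()]).
#' @param roi_cap_deg angular radius (degrees) of the 18 visual ROI caps.
#'   The default 12 degrees makes the 18 caps cover roughly a fifth of the
#'   cortical sphere.
#' @param anat_cap_deg angular radius (degrees) of the 8 non-visual caps.
#' @param centroid_kappa von Mises-Fisher concentration of the
#'   between-participant jitter of cap centroid directions (larger = less
#'   anatomical variability; 200 corresponds to an angular sd of about 4
#'   degrees).
#' @param orientation_kappa concentration of the per-source orientation
#'   jitter around the outward surface normal.
#' @param radii_sd relative (lognormal) sd of the per-participant shell
#'   radii jitter.
#' @param source_radius_frac radius of the cortical source sphere as a
#'   fraction of the brain radius.
#' @param n_harmonics series truncation order of the forward model.
#' @param geometry base [head_geometry()].
#' @return a list of class `population_config`.
#' @export
population_config <- function(n_sources = 1000,
                              montage = master_montage(),
                              roi_cap_deg = 12,
                              anat_cap_deg = 15,
                              centroid_kappa = 200,
                              orientation_kappa = 50,
                              radii_sd = 0.02,
                              source_radius_frac = 0.85,
                              n_harmonics = 120L,
                              geometry = head_geometry()) {
  stopifnot(inherits(montage, "eeg_montage"), inherits(geometry, "head_geometry"))
  if (n_sources < 50) stopf("n_sources must be at least 50")
  cfg <- list(
    n_sources = as.integer(n_sources), montage = montage,
    roi_cap_deg = roi_cap_deg, anat_cap_deg = anat_cap_deg,
    centroid_kappa = centroid_kappa, orientation_kappa = orientation_kappa,
    radii_sd = radii_sd, source_radius_frac = source_radius_frac,
    n_harmonics = as.integer(n_harmonics), geometry = geometry
  )
  class(cfg) <- "population_config"
  cfg
}

## jittered cap centroids for one participant (current RNG state)
.jitter_directions <- function(dirs, kappa) {
  out <- dirs
  for (i in seq_len(nrow(dirs))) {
    out[i, ] <- rvmf(1, dirs[i, ], kappa)
  }
  out
}

## assign each source direction to a cap: nearest centroid among those whose
## cap radius covers it (visual caps first, then anatomical), else unlabeled.
## Ties (exactly equal angles) resolve to the smaller row index.
.assign_rois <- function(src_dirs, centroids, roi_cap_deg, anat_cap_deg) {
  nv <- length(visual_rois())
  radius <- c(rep(roi_cap_deg, nv),
              rep(anat_cap_deg, nrow(centroids) - nv)) * pi / 180
  cosang <- src_dirs %*% t(centroids) # n x caps
  ang <- acos(pmin(pmax(cosang, -1), 1))
  dim(ang) <- dim(cosang)
  inside <- sweep(ang, 2, radius, `<=`)
  ang[!inside] <- Inf
  best <- apply(ang, 1, which.min)
  lab <- rownames(centroids)[best]
  lab[!is.finite(ang[cbind(seq_len(nrow(ang)), best)])] <- "unlabeled"
  lab
}

#' Generate one synthetic participant forward model
#'
#' @param participant_id character id.
#' @param config a [population_config()].
#' @param seed integer seed for this participant.
#' @return an object of class `forward_model`: list with `participant_id`,
#'   `geometry`, `source_space` (positions, orientations, roi_of,
#'   parent_roi), `leadfield` (average-referenced electrodes x sources
#'   matrix) and `montage`.
#' @export
make_participant <- function(participant_id, config = population_config(),
                             seed = 1) {
  with_seed(seed, {
    g0 <- config$geometry
    radii <- g0$radii * exp(stats::rnorm(1, 0, config$radii_sd))
    geometry <- head_geometry(radii, g0$conductivities)
    centroids <- .jitter_directions(.roi_directions(), config$centroid_kappa)
    ns <- config$n_sources
    dirs <- unit_rows(matrix(stats::rnorm(3 * ns), ns))
    roi_of <- .assign_rois(dirs, centroids,
                           config$roi_cap_deg, config$anat_cap_deg)
    # guarantee every visual ROI is populated: drop a source at the
    # (jittered) centroid of any empty cap
    for (roi in c(visual_rois(), anatomical_labels())) {
      if (!any(roi_of == roi)) {
        dirs <- rbind(dirs, centroids[roi, ])
        roi_of <- c(roi_of, roi)
      }
    }
    r_src <- config$source_radius_frac * radii[1]
    positions <- dirs * r_src
    # orientation: outward surface normal (radial) with vMF jitter
    orientations <- dirs
    for (i in seq_len(nrow(dirs))) {
      orientations[i, ] <- rvmf(1, dirs[i, ], config$orientation_kappa)
    }
    elec <- unit_rows(config$montage$positions) * radii[3]
    L <- leadfield_matrix(geometry, positions, orientations, elec,
                          n_harmonics = config$n_harmonics)
    rownames(L) <- config$montage$labels
    fm <- list(
      participant_id = as.character(participant_id),
      geometry = geometry,
      source_space = list(positions = positions,
                          orientations = orientations,
                          roi_of = roi_of,
                          parent_roi = NULL),
      leadfield = L,
      montage = montage(config$montage$labels, elec, reference = "average")
    )
    class(fm) <- "forward_model"
    fm
  })
}

#' @export
print.forward_model <- function(x, ...) {
  cat(sprintf(
    "<forward_model> participant %s: %d electrodes x %d sources\n",
    x$participant_id, nrow(x$leadfield), ncol(x$leadfield)
  ))
  invisible(x)
}

#' Generate a population of synthetic forward models
#'
#' Deterministic given `seed`: participant `i` is generated under
#' `child_seed(seed, i)`, so regenerating the same population (or any
#' prefix of it) reproduces lead fields bitwise.
#'
#' @param n_participants number of participants (>= 1).
#' @param config a [population_config()].
#' @param seed integer master seed.
#' @return list of [make_participant()] forward models, with the config
#'   attached as attribute `config`.
#' @export
make_population <- function(n_participants, config = population_config(),
                            seed = 1) {
  if (n_participants < 1) stopf("n_participants must be >= 1")
  pop <- lapply(seq_len(n_participants), function(i) {
    make_participant(sprintf("P%03d", i), config, child_seed(seed, i))
  })
  attr(pop, "config") <- config
  attr(pop, "seed") <- seed
  pop
}

#' Indices of the sources belonging to an ROI
#'
#' @param fm a `forward_model`.
#' @param roi one of the known labels ([visual_rois()],
#'   [anatomical_labels()], a V1 subdivision label, or `"unlabeled"`).
#' @return integer vector of source indices (possibly empty).
#' @export
roi_sources <- function(fm, roi) {
  stopifnot(inherits(fm, "forward_model"))
  known <- unique(c(visual_rois(), anatomical_labels(), "unlabeled",
                    fm$source_space$roi_of))
  if (!(roi %in% known)) stopf("unknown ROI label '%s'", roi)
  lab <- fm$source_space$roi_of
  # a parent ROI resolves to its subdivisions (V1-L covers V1v-L + V1d-L)
  which(lab == roi | parent_roi(lab) == roi)
}

#' Subdivide V1 into ventral and dorsal halves
#'
#' Splits the V1-L and V1-R sources into ventral/dorsal halves at the
#' median z-coordinate of each cap (ties to ventral), relabelling them
#' V1v-L / V1d-L / V1v-R / V1d-R.  The parent mapping is retained in
#' `source_space$parent_roi`, so that recovery of a V1v/V1d simulation can
#' be scored at the parent V1 level.
#'
#' @param fm a `forward_model` with non-empty V1-L and V1-R.
#' @return a modified `forward_model`.
#' @export
subdivide_v1 <- function(fm) {
  stopifnot(inherits(fm, "forward_model"))
  roi_of <- fm$source_space$roi_of
  parent <- roi_of
  for (hemi in c("L", "R")) {
    v1 <- paste0("V1-", hemi)
    idx <- which(roi_of == v1)
    if (length(idx) < 2) {
      stopf("cannot subdivide %s: needs at least 2 sources, has %d",
            v1, length(idx))
    }
    z <- fm$source_space$positions[idx, 3]
    zc <- stats::median(z)
    ventral <- idx[z <= zc]
    dorsal <- setdiff(idx, ventral)
    if (length(dorsal) == 0) { # all z equal: split by order
      dorsal <- ventral[seq_len(floor(length(ventral) / 2))]
      ventral <- setdiff(idx, dorsal)
    }
    roi_of[ventral] <- paste0("V1v-", hemi)
    roi_of[dorsal] <- paste0("V1d-", hemi)
  }
  fm$source_space$roi_of <- roi_of
  fm$source_space$parent_roi <- parent
  fm
}

#' Map a (possibly subdivided) ROI label to its scoring parent
#'
#' V1v-L and V1d-L map to V1-L (likewise on the right); every other label
#' maps to itself.
#'
#' @param roi character vector of labels.
#' @return character vector of parent labels.
#' @export
parent_roi <- function(roi) {
  sub("^V1[vd]-", "V1-", roi)
}

#' Save / load a population as a plain-text directory
#'
#' One tab-separated lead-field matrix per participant plus a JSON manifest
#' recording the geometry, seeds, ROI label table and montage.
#'
#' @param population result of [make_population()].
#' @param dir directory to create.
#' @return `dir`, invisibly.
#' @export
save_population <- function(population, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- attr(population, "config")
  save_montage(population[[1]]$montage, file.path(dir, "montage.sfp"))
  manifest <- list(
    n_participants = length(population),
    seed = attr(population, "seed"),
    montage_file = "montage.sfp",
    participants = lapply(population, function(fm) {
      list(
        participant_id = fm$participant_id,
        radii = fm$geometry$radii,
        conductivities = fm$geometry$conductivities,
        roi_of = fm$source_space$roi_of
      )
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (fm in population) {
    base <- file.path(dir, fm$participant_id)
    utils::write.table(fm$leadfield, paste0(base, "_leadfield.tsv"),
                       sep = "\t", col.names = FALSE)
    utils::write.table(
      cbind(fm$source_space$positions, fm$source_space$orientations),
      paste0(base, "_sources.tsv"),
      sep = "\t", col.names = FALSE, row.names = FALSE
    )
  }
  invisible(dir)
}

#' @rdname save_population
#' @param dir directory written by [save_population()].
#' @export
load_population <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  mon <- load_montage(file.path(dir, manifest$montage_file))
  pop <- lapply(seq_len(manifest$n_participants), function(i) {
    meta <- if (is.data.frame(manifest$participants)) {
      lapply(manifest$participants, function(col) col[[i]])
    } else {
      manifest$participants[[i]]
    }
    base <- file.path(dir, meta$participant_id)
    L <- as.matrix(utils::read.table(paste0(base, "_leadfield.tsv"),
                                     sep = "\t", row.names = 1))
    colnames(L) <- NULL
    so <- as.matrix(utils::read.table(paste0(base, "_sources.tsv"), sep = "\t"))
    dimnames(so) <- NULL
    fm <- list(
      participant_id = meta$participant_id,
      geometry = head_geometry(unlist(meta$radii), unlist(meta$conductivities)),
      source_space = list(positions = so[, 1:3], orientations = so[, 4:6],
                          roi_of = unlist(meta$roi_of), parent_roi = NULL),
      leadfield = L,
      montage = mon
    )
    class(fm) <- "forward_model"
    fm
  })
  attr(pop, "seed") <- manifest$seed
  pop
}
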