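## Figure-level experiment drivers: factor grids over SNR, number of
## participants, montage size, active-ROI count and method, wiring
## simulate -> inverse -> evaluate into tidy long-format results tables.

#' Define an experiment grid
#'
#' Factors default to the full study grids: SNR in {0.1, 1, 10, 200,
#' 10000}, participants in {2, 8, 20, 50}, montage sizes {32, 64, 128,
#' 256}, 1 to 8 active bilateral pairs, and the five recovery methods.
#' Only the factors you pass vary; the rest stay at single default levels
#' (SNR 10, N 50, the population's montage, the given active set,
#' template method).
#'
#' @param snr numeric vector of SNR levels.
#' @param n_participants integer vector.
#' @param montage_size integer vector (`NA` = the population montage).
#' @param n_active_bilateral integer vector of active bilateral-pair
#'   counts (`NA` = use `active_rois` as given).
#' @param method character vector of method names.
#' @param active_rois baseline active set (default bilateral V1 + MT).
#' @param n_sim simulations per cell (default 30).
#' @param seed integer seed.
#' @return list of class `experiment_grid`.
#' @export
experiment_grid <- function(snr = 10, n_participants = 50,
                            montage_size = NA,
                            n_active_bilateral = NA,
                            method = "template",
                            active_rois = c("V1-L", "V1-R", "MT-L", "MT-R"),
                            n_sim = 30, seed = 1) {
  allowed_methods <- c("template", "template_optimal", "individual",
                       "individual_subset", "individual_oracle")
  if (!all(method %in% allowed_methods)) {
    stopf("unknown method(s): %s",
          paste(setdiff(method, allowed_methods), collapse = ", "))
  }
  structure(list(snr = snr, n_participants = n_participants,
                 montage_size = montage_size,
                 n_active_bilateral = n_active_bilateral,
                 method = method, active_rois = active_rois,
                 n_sim = n_sim, seed = seed),
            class = "experiment_grid")
}

.bilateral_pairs <- function() {
  c("V1", "V2v", "V2d", "V3v", "V3d", "V4", "V3A", "LOC", "MT")
}

## restrict every participant's forward model to an electrode subset
.subset_population <- function(population, labels) {
  lapply(population, function(fm) {
    keep <- match(labels, fm$montage$labels)
    if (anyNA(keep)) stopf("montage subset labels missing from population")
    L <- fm$leadfield[keep, , drop = FALSE]
    L <- sweep(L, 2, colMeans(L), `-`) # re-reference in the subset space
    fm$leadfield <- L
    fm$montage <- montage(labels,
                          fm$montage$positions[keep, , drop = FALSE],
                          reference = "average")
    fm
  })
}

#' Run an experiment grid
#'
#' Crosses all factor levels; each cell runs `n_sim` seeded simulations,
#' fits with the cell's method and scores AUC, relative energy and
#' normalized MSE.  Deterministic given the grid seed.  Infeasible cells
#' (e.g. a montage size larger than the population montage) are recorded
#' as missing with a reason, and the run continues.
#'
#' @param grid an [experiment_grid()].
#' @param population list of `forward_model`s.
#' @return long-format `data.frame`: one row per cell x simulation x
#'   metric, with columns `snr`, `n_participants`, `montage_size`,
#'   `n_active_bilateral`, `method`, `sim`, `metric`, `value`, `note`.
#' @export
run_grid <- function(grid, population) {
  stopifnot(inherits(grid, "experiment_grid"))
  cells <- expand.grid(
    snr = grid$snr, n_participants = grid$n_participants,
    montage_size = grid$montage_size,
    n_active_bilateral = grid$n_active_bilateral,
    method = grid$method,
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  )
  full_mon <- population[[1]]$montage
  # montage subsets and their populations/templates, computed once per size
  pop_cache <- list()
  get_pop <- function(size) {
    key <- if (is.na(size)) "full" else as.character(size)
    if (is.null(pop_cache[[key]])) {
      if (is.na(size)) {
        pop <- population
      } else {
        if (size > n_electrodes(full_mon)) {
          return(NULL)
        }
        sub <- montage_subsets(full_mon, size)[[1]]
        pop <- .subset_population(population, sub$labels)
      }
      pop_cache[[key]] <<- list(pop = pop,
                                templates = build_templates(pop))
    }
    pop_cache[[key]]
  }
  rows <- list()
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    rownames(cell) <- NULL
    entry <- get_pop(cell$montage_size)
    if (is.null(entry)) {
      rows[[length(rows) + 1]] <- data.frame(
        cell, sim = NA_integer_, metric = NA_character_, value = NA_real_,
        note = "infeasible: montage size exceeds population montage"
      )
      next
    }
    if (is.na(cell$montage_size)) {
      cell$montage_size <- n_electrodes(full_mon)
    }
    for (s in seq_len(grid$n_sim)) {
      sim_seed <- child_seed(grid$seed, ci * 1000 + s)
      active <- grid$active_rois
      if (!is.na(cell$n_active_bilateral)) {
        pairs <- with_seed(child_seed(sim_seed, 7),
                           sample(.bilateral_pairs(),
                                  cell$n_active_bilateral))
        active <- as.vector(outer(pairs, c("L", "R"), paste, sep = "-"))
      }
      cfg <- sim_config(active, snr = cell$snr,
                        n_participants = cell$n_participants,
                        seed = sim_seed)
      ds <- simulate_group(entry$pop, cfg)
      fit <- fit_dataset(ds, cell$method, entry$pop, entry$templates)
      rep <- evaluate_fit(fit, ds$truth, active = active)
      cell$n_active_bilateral <- length(active) / 2
      rows[[length(rows) + 1]] <- cbind(
        cell[rep(1, 3), , drop = FALSE],
        data.frame(sim = s,
                   metric = c("auc", "relative_energy", "nmse"),
                   value = c(rep$auc, rep$relative_energy, rep$nmse),
                   note = ""),
        row.names = NULL
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize a grid results table
#'
#' Mean and standard deviation of each metric per cell (over simulations).
#'
#' @param results output of [run_grid()].
#' @return `data.frame` with one row per cell x metric.
#' @export
summarize_grid <- function(results) {
  ok <- !is.na(results$value)
  agg <- stats::aggregate(
    value ~ snr + n_participants + montage_size + n_active_bilateral +
      method + metric,
    data = results[ok, ], na.action = stats::na.pass,
    FUN = function(v) c(mean = mean(v), sd = stats::sd(v))
  )
  out <- cbind(agg[setdiff(names(agg), "value")],
               mean = agg$value[, "mean"], sd = agg$value[, "sd"])
  out
}

#' Interference experiment: effect of a non-visual source
#'
#' Paired runs, identical except for the presence of an interfering
#' anatomical source at 50% relative strength, for each requested method
#' and SNR; reports per-simulation AUC with and without interference and
#' the AUC delta.
#'
#' @param population list of `forward_model`s.
#' @param methods methods to compare.
#' @param snr SNR levels.
#' @param n_sim simulations per condition.
#' @param n_participants group size.
#' @param relative_strength interferer peak strength relative to the
#'   visual sources (default 0.5).
#' @param seed integer seed.
#' @return `data.frame` with columns `method`, `snr`, `sim`,
#'   `interferer`, `auc`, plus attribute `deltas` (mean AUC delta per
#'   method x snr).
#' @export
interference_experiment <- function(population,
                                    methods = c("template", "individual",
                                                "individual_subset"),
                                    snr = c(10, 200), n_sim = 30,
                                    n_participants = 50,
                                    relative_strength = 0.5, seed = 1) {
  templates <- build_templates(population)
  active <- c("V1-L", "V1-R", "MT-L", "MT-R")
  rows <- list()
  k <- 0
  for (m in methods) for (sv in snr) for (s in seq_len(n_sim)) {
    k <- k + 1
    sim_seed <- child_seed(seed, k)
    interferer <- with_seed(
      child_seed(sim_seed, 3),
      list(label = sample(anatomical_labels(), 1),
           relative_strength = relative_strength)
    )
    for (with_int in c(FALSE, TRUE)) {
      cfg <- sim_config(active, snr = sv, n_participants = n_participants,
                        interferer = if (with_int) interferer,
                        seed = sim_seed) # same seed: paired designs
      ds <- simulate_group(population, cfg)
      fit <- fit_dataset(ds, m, population, templates)
      rows[[length(rows) + 1]] <- data.frame(
        method = m, snr = sv, sim = s, interferer = with_int,
        auc = auc_active_vs_inactive(active, fit$beta)
      )
    }
  }
  out <- do.call(rbind, rows)
  wide <- merge(out[!out$interferer, c("method", "snr", "sim", "auc")],
                out[out$interferer, c("method", "snr", "sim", "auc")],
                by = c("method", "snr", "sim"),
                suffixes = c("_without", "_with"))
  deltas <- stats::aggregate(cbind(delta = auc_with - auc_without) ~ method + snr,
                             data = wide, FUN = mean)
  attr(out, "deltas") <- deltas
  out
}

#' Partial-V1 experiment: recovery when only V1v or V1d is active
#'
#' Simulates a unilateral ERP in one V1 subdivision (V1v-L, V1d-L, V1v-R
#' or V1d-R) and scores whether the template method recovers the parent
#' V1 of the correct hemisphere (subdivision hits count for the parent).
#'
#' @param population population whose participants have been passed
#'   through [subdivide_v1()].
#' @param n_sim simulations per subdivision.
#' @param snr SNR level.
#' @param n_participants group size.
#' @param seed integer seed.
#' @return `data.frame` with columns `sub_roi`, `sim`, `argmax_roi`,
#'   `hit` (argmax is the parent V1 of the simulated hemisphere) and
#'   `hit_hemi` (argmax V1 is in the simulated hemisphere).
#' @export
partial_v1_experiment <- function(population, n_sim = 30, snr = 10,
                                  n_participants = 50, seed = 1) {
  has_sub <- all(c("V1v-L", "V1d-L") %in% population[[1]]$source_space$roi_of)
  if (!has_sub) stopf("apply subdivide_v1() to every participant first")
  templates <- build_templates(population) # parent-level templates:
  rows <- list()
  k <- 0
  for (sub in c("V1v-L", "V1d-L", "V1v-R", "V1d-R")) {
    for (s in seq_len(n_sim)) {
      k <- k + 1
      cfg <- sim_config(sub, snr = snr, n_participants = n_participants,
                        seed = child_seed(seed, k))
      ds <- simulate_group(population, cfg)
      fit <- fit_templates(templates, ds$group_avg, selector = "lcurve")
      score <- rowMeans(abs(fit$beta))
      argmax <- names(score)[which.max(score)]
      parent <- parent_roi(sub)
      opposite <- if (endsWith(parent, "-L")) "V1-R" else "V1-L"
      rows[[length(rows) + 1]] <- data.frame(
        sub_roi = sub, sim = s, argmax_roi = argmax,
        hit = argmax == parent,
        hit_opposite = argmax == opposite
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
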