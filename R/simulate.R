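## ERP-style multi-participant simulation battery: seeded ERP waveforms,
## the SNR definition, calibrated white/correlated noise, group simulation
## with participants drawn with replacement, and crosstalk matrices.

#' ERP waveform configuration
#'
#' @param sample_rate sampling rate in Hz (default 1000, giving 91 samples
#'   over -45..45 ms).
#' @param baseline_window baseline interval in ms (activity exactly zero).
#' @param active_window response interval in ms.
#' @param amplitude_range peak amplitude drawn uniformly from this range
#'   (arbitrary source units).
#' @return list of class `erp_config`.
#' @export
erp_config <- function(sample_rate = 1000,
                       baseline_window = c(-45, 0),
                       active_window = c(0, 45),
                       amplitude_range = c(1, 10)) {
  if (baseline_window[2] > active_window[1]) {
    stopf("baseline window must precede the active window")
  }
  if (any(amplitude_range <= 0) || diff(amplitude_range) < 0) {
    stopf("amplitude_range must be positive and increasing")
  }
  structure(list(sample_rate = sample_rate,
                 baseline_window = baseline_window,
                 active_window = active_window,
                 amplitude_range = amplitude_range),
            class = "erp_config")
}

#' Sample times (ms) of an ERP configuration
#' @param cfg an [erp_config()].
#' @return numeric vector of sample times in ms.
#' @export
erp_times <- function(cfg) {
  step <- 1000 / cfg$sample_rate
  seq(cfg$baseline_window[1], cfg$active_window[2], by = step)
}

#' Generate a seeded ERP-like waveform
#'
#' Zero during the baseline window, then a smooth unimodal bump over the
#' active window: a raised-cosine lobe with a seeded asymmetry (power-law
#' time warp), scaled so the peak equals an amplitude drawn uniformly from
#' `amplitude_range`.  The same seed reproduces the waveform exactly;
#' different seeds give different shapes and amplitudes.
#'
#' @param cfg an [erp_config()].
#' @param seed integer seed.
#' @return numeric vector over [erp_times()] with attribute `times_ms`.
#' @export
make_erp <- function(cfg = erp_config(), seed = 1) {
  t_ms <- erp_times(cfg)
  with_seed(seed, {
    amp <- stats::runif(1, cfg$amplitude_range[1], cfg$amplitude_range[2])
    warp <- exp(stats::runif(1, log(0.5), log(2))) # asymmetry exponent
    w <- numeric(length(t_ms))
    a0 <- cfg$active_window[1]
    a1 <- cfg$active_window[2]
    act <- t_ms > a0 & t_ms < a1
    u <- ((t_ms[act] - a0) / (a1 - a0))^warp
    w[act] <- sin(pi * u)^2
    w <- w / max(w) * amp
    attr(w, "times_ms") <- t_ms
    w
  })
}

#' Signal-to-noise ratio of a noisy recording
#'
#' `SNR = (RMS(signal + noise) / RMS(noise))^2 - 1`, with the RMS taken
#' over all electrodes and samples.  For independent zero-mean noise this
#' estimates the signal-to-noise power ratio; it can be slightly negative
#' by sampling fluctuation when the signal is absent.
#'
#' @param signal_plus_noise electrodes x samples matrix.
#' @param noise matrix of the same shape, not identically zero.
#' @return scalar SNR (`Inf` if `noise` is all zeros).
#' @export
snr_of <- function(signal_plus_noise, noise) {
  signal_plus_noise <- as.matrix(signal_plus_noise)
  noise <- as.matrix(noise)
  if (!identical(dim(signal_plus_noise), dim(noise))) {
    stopf("shape mismatch between data and noise")
  }
  pn <- mean(noise^2)
  if (pn == 0) {
    return(Inf)
  }
  mean(signal_plus_noise^2) / pn - 1
}

#' Add calibrated noise to a clean scalp recording
#'
#' White noise is i.i.d. Gaussian on every electrode and sample;
#' correlated noise is Gaussian source-space noise projected through the
#' participant's lead field, giving the spatially structured covariance of
#' brain noise.  Either kind is scaled so the SNR definition of
#' [snr_of()] hits `target_snr` in expectation.
#'
#' @param clean electrodes x samples matrix.
#' @param target_snr positive scalar, or `Inf` for no noise.
#' @param kind `"white"` or `"correlated"`.
#' @param fm `forward_model` (required for correlated noise).
#' @param seed integer seed (`NULL` = use current RNG stream).
#' @return list with `noisy`, `noise` and `achieved_snr`.
#' @export
add_noise <- function(clean, target_snr, kind = c("white", "correlated"),
                      fm = NULL, seed = NULL) {
  kind <- match.arg(kind)
  clean <- as.matrix(clean)
  if (target_snr <= 0) stopf("target_snr must be positive")
  if (is.infinite(target_snr)) {
    return(list(noisy = clean, noise = clean * 0, achieved_snr = Inf))
  }
  with_seed(seed, {
    if (kind == "white") {
      noise <- matrix(stats::rnorm(length(clean)), nrow(clean))
    } else {
      if (is.null(fm)) stopf("correlated noise needs a forward model")
      z <- matrix(stats::rnorm(ncol(fm$leadfield) * ncol(clean)),
                  ncol(fm$leadfield))
      noise <- fm$leadfield %*% z
    }
    # scale so that E[snr_of] = target: signal power / noise power = target
    scale <- sqrt(mean(clean^2) / (target_snr * mean(noise^2)))
    noise <- noise * scale
    list(noisy = clean + noise, noise = noise,
         achieved_snr = snr_of(clean + noise, noise))
  })
}

#' Simulation configuration
#'
#' @param active_rois character vector of active ROI labels.
#' @param snr target SNR (default 10, a realistic ERP level); `Inf` for
#'   noiseless.
#' @param n_participants participants drawn (with replacement) from the
#'   population per simulation.
#' @param noise_kind `"white"` or `"correlated"`.
#' @param interferer optional `list(label =, relative_strength =)` naming a
#'   non-visual anatomical cap simultaneously active with the given peak
#'   strength relative to the visual sources (0.5 = strong interference).
#' @param erp an [erp_config()].
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(active_rois, snr = 10, n_participants = 50,
                       noise_kind = c("white", "correlated"),
                       interferer = NULL, erp = erp_config(), seed = 1) {
  noise_kind <- match.arg(noise_kind)
  known <- c(visual_rois(), "V1v-L", "V1v-R", "V1d-L", "V1d-R")
  if (!all(active_rois %in% known)) {
    stopf("unknown active ROI(s): %s",
          paste(setdiff(active_rois, known), collapse = ", "))
  }
  if (snr <= 0) stopf("snr must be positive")
  if (!is.null(interferer)) {
    if (!(interferer$label %in% anatomical_labels())) {
      stopf("unknown interferer label '%s'", interferer$label)
    }
    interferer$relative_strength <- interferer$relative_strength %||% 0.5
  }
  structure(list(active_rois = active_rois, snr = snr,
                 n_participants = n_participants, noise_kind = noise_kind,
                 interferer = interferer, erp = erp, seed = seed),
            class = "sim_config")
}

#' Simulate a multi-participant scalp EEG dataset
#'
#' Draws `n_participants` forward models from the population with
#' replacement, projects a common ERP waveform from the active ROIs
#' through each participant's own ROI topographies, optionally adds an
#' interfering non-visual source with its own waveform (peak amplitude a
#' fixed fraction of the visual peak, so the instantaneous strength ratio
#' varies over time), adds per-participant noise at the target SNR, and
#' averages.
#'
#' @param population list of `forward_model`s.
#' @param cfg a [sim_config()].
#' @return list of class `simulated_dataset`: `truth` (ROIs x samples,
#'   nonzero only in active ROIs), `per_participant` (list of noisy
#'   electrodes x samples matrices), `group_avg`, `participant_idx`,
#'   `waveform`, `config`.
#' @export
simulate_group <- function(population, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  roi_names <- visual_rois()
  with_seed(cfg$seed, {
    idx <- sample.int(length(population), cfg$n_participants, replace = TRUE)
    wave <- make_erp(cfg$erp, seed = child_seed(cfg$seed, 1))
    t_ms <- attr(wave, "times_ms")
    nt <- length(wave)
    truth <- matrix(0, length(roi_names), nt,
                    dimnames = list(roi_names, NULL))
    for (r in cfg$active_rois) {
      truth[parent_roi(r), ] <- wave # subdivided ROIs score at parent V1
    }
    interferer_wave <- NULL
    if (!is.null(cfg$interferer)) {
      iw <- make_erp(cfg$erp, seed = child_seed(cfg$seed, 2))
      interferer_wave <- iw / max(abs(iw)) *
        max(abs(wave)) * cfg$interferer$relative_strength
    }
    per <- vector("list", cfg$n_participants)
    for (p in seq_len(cfg$n_participants)) {
      fm <- population[[idx[p]]]
      clean <- matrix(0, nrow(fm$leadfield), nt)
      for (r in cfg$active_rois) {
        if (grepl("^V1[vd]-", r) && !(r %in% fm$source_space$roi_of)) {
          stopf("population lacks the V1 subdivision needed for '%s'; %s",
                r, "apply subdivide_v1() to each participant first")
        }
        clean <- clean + outer(roi_topography(fm, r), wave)
      }
      if (!is.null(interferer_wave)) {
        clean <- clean +
          outer(roi_topography(fm, cfg$interferer$label), interferer_wave)
      }
      res <- add_noise(clean, cfg$snr, cfg$noise_kind, fm = fm, seed = NULL)
      per[[p]] <- res$noisy
    }
    group_avg <- Reduce(`+`, per) / length(per)
    structure(
      list(truth = truth, per_participant = per, group_avg = group_avg,
           participant_idx = idx, waveform = wave, times_ms = t_ms,
           config = cfg),
      class = "simulated_dataset"
    )
  })
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf(
    "<simulated_dataset> %d participants, %d electrodes x %d samples; active: %s; SNR %s\n",
    length(x$per_participant), nrow(x$group_avg), ncol(x$group_avg),
    paste(x$config$active_rois, collapse = ", "), format(x$config$snr)
  ))
  invisible(x)
}

#' Crosstalk (leakage) matrix between ROIs
#'
#' Activates one ROI at a time (ERP waveform, default SNR 10), recovers
#' all ROIs with the requested method, and reports the mean absolute
#' recovered activity per ROI over simulations and time, normalized by the
#' maximum of each row.  The diagonal is self-recovery; off-diagonal mass
#' is leakage.  For an orthonormal noiseless system the matrix would be
#' the identity.
#'
#' @param population list of `forward_model`s.
#' @param fit_method `"template"`, `"template_optimal"`, `"individual"`,
#'   `"individual_subset"` or `"individual_oracle"`.
#' @param snr target SNR per participant (default 10).
#' @param n_sim simulations per ROI (default 30).
#' @param n_participants participants per simulation (default 50, drawn
#'   with replacement).
#' @param seed integer seed.
#' @param templates optional precomputed `eeg_templates` (otherwise built
#'   from the population).
#' @return ROIs x ROIs row-normalized matrix (rows = simulated ROI,
#'   columns = recovered ROI).
#' @export
crosstalk_matrix <- function(population, fit_method = "template", snr = 10,
                             n_sim = 30, n_participants = 50, seed = 1,
                             templates = NULL) {
  roi_names <- visual_rois()
  if (fit_method %in% c("template", "template_optimal") && is.null(templates)) {
    templates <- build_templates(population, roi_names)
  }
  M <- matrix(0, length(roi_names), length(roi_names),
              dimnames = list(roi_names, roi_names))
  for (r in seq_along(roi_names)) {
    for (s in seq_len(n_sim)) {
      cfg <- sim_config(roi_names[r], snr = snr,
                        n_participants = n_participants,
                        seed = child_seed(seed, (r - 1) * n_sim + s))
      ds <- simulate_group(population, cfg)
      beta <- fit_dataset(ds, fit_method, population, templates)$beta
      on <- colSums(abs(ds$truth)) > 0 # score where the source is active
      M[r, ] <- M[r, ] + rowMeans(abs(beta[, on, drop = FALSE])) / n_sim
    }
  }
  sweep(M, 1, apply(M, 1, max), `/`)
}

#' Recover sources from a simulated dataset with a named method
#'
#' Dispatch helper used by the crosstalk and experiment drivers: applies
#' the template method (L-curve), the truth-informed template-optimal
#' variant, or one of the individual-based methods (GCV, per participant,
#' averaged across participants).
#'
#' @param ds a `simulated_dataset`.
#' @param method one of `"template"`, `"template_optimal"`,
#'   `"individual"`, `"individual_subset"`, `"individual_oracle"`.
#' @param population the population the dataset was simulated from.
#' @param templates `eeg_templates` (required for the template methods).
#' @return an `eeg_fit`.
#' @export
fit_dataset <- function(ds, method, population, templates = NULL) {
  stopifnot(inherits(ds, "simulated_dataset"))
  method <- match.arg(method, c("template", "template_optimal", "individual",
                                "individual_subset", "individual_oracle"))
  if (method %in% c("template", "template_optimal")) {
    if (is.null(templates)) stopf("template methods need `templates`")
    if (method == "template") {
      return(fit_templates(templates, ds$group_avg, selector = "lcurve"))
    }
    return(fit_templates(templates, ds$group_avg, selector = "optimal",
                         truth = ds$truth))
  }
  subset <- switch(method, individual = "whole_brain",
                   individual_subset = "roi_only",
                   individual_oracle = "oracle_rois")
  fits <- lapply(seq_along(ds$per_participant), function(p) {
    fm <- population[[ds$participant_idx[p]]]
    fit_individual(fm, ds$per_participant[[p]], selector = "gcv",
                   subset = subset)
  })
  out <- average_fits(fits)
  out
}
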