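#' Synthetic cohorts with planted gradients, arousal dynamics and receptors
#'
#' The generator emulates the statistical structure of an awake resting-state
#' fMRI study paired with a retrograde-tracing connectome and a receptor
#' gene-expression atlas: smooth orthonormal spatial maps play the role of
#' the planted connectivity gradients; region time series are drawn from a
#' zero-mean Gaussian whose correlation matrix mixes a static structural
#' similarity with an arousal-modulated neuromodulatory similarity; a latent
#' arousal process is observed through a noisy, blink-interrupted pupil
#' trace; and a directed log-normal tracing matrix plus a receptor-by-region
#' expression matrix carry the planted structure into the two predictor
#' similarity matrices.
#'
#' @name synthetic
NULL

#' Generate smooth orthonormal spatial maps on random 2-D coordinates
#'
#' Region coordinates are drawn uniformly in the unit square; each map is a
#' Gaussian random field with exponential covariance \code{exp(-d/smoothness)}
#' over pairwise distances \code{d}, and the maps are then Gram-Schmidt
#' orthonormalized (unit norm, mutually orthogonal).
#'
#' @param n_regions number of regions N.
#' @param n_maps number of maps K (must be < N).
#' @param smoothness correlation length of the field, in coordinate units
#'   (> 0); the limit towards 0 gives spatially white maps.
#' @param seed integer seed; identical seeds reproduce the maps bit-exactly.
#' @param coords optional N x 2 coordinate matrix to reuse.
#' @return list with `maps` (N x K orthonormal matrix) and `coords` (N x 2).
#' @export
make_spatial_maps <- function(n_regions, n_maps, smoothness = 0.25,
                              seed = NULL, coords = NULL) {
  if (n_maps >= n_regions) {
    stop("rank error: n_maps must be smaller than n_regions")
  }
  if (smoothness <= 0) stop("smoothness must be > 0")
  local_seed(seed, {
    if (is.null(coords)) {
      coords <- cbind(runif(n_regions), runif(n_regions))
    }
    D <- coord_dist(coords)
    K_cov <- exp(-D / smoothness)
    # jitter keeps the Cholesky stable when regions nearly coincide
    L <- chol(K_cov + diag(1e-8, n_regions))
    maps <- crossprod(L, matrix(rnorm(n_regions * n_maps), n_regions, n_maps))
    # Gram-Schmidt
    for (k in seq_len(n_maps)) {
      v <- maps[, k]
      if (k > 1) {
        prev <- maps[, seq_len(k - 1), drop = FALSE]
        v <- v - prev %*% crossprod(prev, v)
      }
      maps[, k] <- v / sqrt(sum(v^2))
    }
    rownames(coords) <- rownames(maps) <- region_labels(n_regions)
    list(maps = maps, coords = coords)
  })
}

region_labels <- function(n) sprintf("R%03d", seq_len(n))

#' Generate a latent arousal process
#'
#' A stationary AR(1) process (unit marginal variance) squashed to \[0, 1\]
#' by the logistic function. High persistence at a 2-s frame interval mimics
#' the slow drift between drowsy and alert states seen in awake recordings.
#'
#' @param n_frames number of frames.
#' @param persistence AR(1) coefficient in \[0, 1).
#' @param seed integer seed.
#' @return numeric vector in \[0, 1\] of length `n_frames`.
#' @export
make_arousal_process <- function(n_frames, persistence = 0.95, seed = NULL) {
  if (persistence < 0 || persistence >= 1) {
    stop("persistence must be in [0, 1)")
  }
  local_seed(seed, {
    innov_sd <- sqrt(1 - persistence^2)
    z <- numeric(n_frames)
    z[1] <- rnorm(1)
    if (n_frames > 1) {
      e <- rnorm(n_frames - 1, sd = innov_sd)
      for (t in 2:n_frames) z[t] <- persistence * z[t - 1] + e[t - 1]
    }
    stats::plogis(1.5 * z)
  })
}

# Arousal-dependent weight of the neuromodulatory similarity in the
# generative correlation mixture: w_mod(a) = b2 * 4 * (a - 1/2)^2, a U shape
# peaking at the drowsy and alert extremes (b2 < 0 plants the inverted U).
modulation_weight <- function(a, b2) b2 * 4 * (a - 0.5)^2

#' Assemble the ground truth for a synthetic cohort
#'
#' Builds the generative model in four steps. (1) Smooth latent fields and
#' region coordinates are drawn, and the directed tracing matrix is
#' generated with per-target connection profiles that vary smoothly along
#' the latent fields (a Gaussian-process construction, so that profile
#' correlations decay with distance in field space) plus physical distance
#' decay. (2) The structural similarity is derived from the tracing matrix
#' exactly as the analysis pipeline derives it, and provisional gradients of
#' the structure-driven correlation define the axes the receptor loadings
#' refer to; the expression matrix and neuromodulatory similarity follow.
#' (3) The population correlation matrix — the arousal-weighted mixture
#' `b0*I + b1*SC + w_mod(a)*NS` (normalized to unit diagonal) averaged over
#' the stationary arousal distribution, plus the arousal-amplitude template
#' component and observation noise — is assembled; the arousal distribution
#' and the amplitude variance are calibrated by a long seeded simulation of
#' the arousal process. (4) The planted gradient maps are defined as the
#' orthonormalized leading diffusion gradients of that population matrix:
#' they are exactly what the pipeline estimates at infinite data, so
#' finite-sample recovery measures estimation error, not model mismatch.
#'
#' @param n_regions,n_targets region count and tracing-target count
#'   (targets are the first `n_targets` regions).
#' @param n_maps number of planted gradient maps K.
#' @param weights named vector `c(b0=, b1=, b2=)`: idiosyncratic, structural
#'   and (peak) neuromodulatory mixture weights. `b2` scales the U-shaped
#'   arousal modulation; negative `b2` plants an inverted U.
#' @param amp amplitude of the global arousal-coupled signal added along the
#'   arousal template map (recoverable as the fMRI arousal index).
#' @param sigma_obs default observation noise SD (part of the population
#'   correlation the planted maps are defined on).
#' @param smoothness field correlation length for the latent maps.
#' @param field_bandwidth squared-distance bandwidth (in latent field space)
#'   of the tracing-profile Gaussian process.
#' @param n_receptors,n_null total receptors and how many are pure-noise
#'   nulls.
#' @param expr_noise_sd receptor map observation noise (map values are
#'   approximately unit variance).
#' @param null_smoothness correlation length of the null receptors' smooth
#'   (map-independent) fields.
#' @param tracing_decay exponential distance decay of tracing log-weights.
#' @param tracing_noise_sd log-normal scatter of tracing weights.
#' @param persistence arousal AR(1) persistence used for the population
#'   calibration (should match the cohort's).
#' @param density,n_levels embedding density and arousal quantization used
#'   throughout.
#' @param seed integer seed.
#' @return object of class `gradflow_truth`; fields include
#'   `gradient_maps` (N x K orthonormal), `population_fc`, `pop_gradients`
#'   (reference `gradient_set`), `sc_sim`, `ns_sim`, `template`, `tracing`,
#'   `expression`, `receptor_loadings`, `receptor_groups`, `coords`.
#' @export
make_ground_truth <- function(n_regions = 116, n_targets = 55, n_maps = 2,
                              weights = c(b0 = 0.30, b1 = 0.55, b2 = 0.80),
                              amp = 1.4, sigma_obs = 0.2, smoothness = 0.25,
                              field_bandwidth = 4,
                              n_receptors = 12, n_null = 4,
                              expr_noise_sd = 0.30,
                              null_smoothness = 0.10,
                              tracing_decay = 0.3,
                              tracing_noise_sd = 0.30,
                              persistence = 0.95,
                              density = 0.10, n_levels = 21,
                              seed = NULL) {
  b0 <- weights[["b0"]]; b1 <- weights[["b1"]]; b2 <- weights[["b2"]]
  local_seed(seed, {
    sm <- make_spatial_maps(n_regions, n_maps + 1L, smoothness)
    fields <- sm$maps[, seq_len(n_maps), drop = FALSE] * sqrt(n_regions)
    template <- sm$maps[, n_maps + 1L] * sqrt(n_regions)  # ~unit variance
    field_cov <- exp(-coord_dist(fields)^2 / field_bandwidth)
    tracing <- make_tracing(n_regions, n_targets, sm$coords,
                            decay = tracing_decay,
                            field_cov = field_cov,
                            noise_sd = tracing_noise_sd)
    sc_sim <- tracing_similarity(tracing)
    # population calibration of the arousal-level distribution and of the
    # variance of the HRF-convolved arousal deviation (long seeded run)
    cal <- local_seed(20240101, {
      a <- make_arousal_process(20000, persistence)
      list(p = tabulate(quantize_arousal(a, n_levels), n_levels) / 20000,
           vdev = var(hrf_convolve(a - mean(a), 2)))
    })
    a_mid <- (seq_len(n_levels) - 0.5) / n_levels
    population_sigma <- function(ns) {
      S <- Reduce(`+`, lapply(seq_len(n_levels), function(l) {
        wm <- modulation_weight(a_mid[l], b2)
        cal$p[l] * (b0 * diag(n_regions) + b1 * sc_sim + wm * ns) /
          (b0 + b1 + wm)
      }))
      S + amp^2 * cal$vdev * tcrossprod(template) +
        diag(sigma_obs^2, n_regions)
    }
    # fixed-point for the planted axes: receptor loadings are expressed on
    # the current maps, the neuromodulatory similarity and population matrix
    # rebuilt, and the new leading gradients matched back by Procrustes. The
    # final maps are then both the population gradients and (to ~0.98) the
    # frame the receptor loadings live on.
    C0 <- (b0 * diag(n_regions) + b1 * sc_sim) / (b0 + b1)
    maps <- qr.Q(qr(connectivity_gradients(C0, n_maps,
                                           density)$components))
    expr_noise <- matrix(rnorm(n_receptors * n_regions, sd = expr_noise_sd),
                         n_receptors, n_regions)
    n_load <- n_receptors - n_null
    if (n_null > 0) {
      # null receptors are smooth (but map-independent) fields at unit
      # variance: real expression maps are spatially autocorrelated, and the
      # variogram-matched surrogate test assumes that of every receptor
      null_maps <- make_spatial_maps(n_regions, n_null,
                                     smoothness = null_smoothness,
                                     coords = sm$coords)$maps
      expr_noise[(n_load + 1L):n_receptors, ] <-
        t(scale(null_maps) * sqrt((n_regions - 1) / n_regions))
    }
    loaded <- seq_len(n_receptors - n_null)
    for (it in seq_len(4L)) {
      expr <- make_expression_internal(maps, n_receptors, n_null,
                                       expr_noise_sd, noise = expr_noise)
      # the generative neuromodulatory similarity uses the loaded receptors
      # only: the null receptors are observation-side negatives and must
      # have no causal role in the dynamics
      ns_sim <- expression_similarity(expr$values[loaded, , drop = FALSE])
      Sigma <- population_sigma(ns_sim)
      pop_gradients <- connectivity_gradients(stats::cov2cor(Sigma),
                                              min(n_maps + 2L,
                                                  n_regions - 1L),
                                              density)
      pop2 <- qr.Q(qr(pop_gradients$components[, seq_len(n_maps),
                                               drop = FALSE]))
      maps <- qr.Q(qr(procrustes_align(pop2, maps)))
    }
    population_fc <- stats::cov2cor(Sigma)
    dimnames(maps) <- list(region_labels(n_regions),
                           paste0("G", seq_len(n_maps)))
    truth <- list(
      gradient_maps = maps,
      coords = sm$coords,
      template = template,
      weights = weights,
      amp = amp,
      sigma_obs = sigma_obs,
      n_levels = n_levels,
      tracing = tracing,
      expression = expr$values,
      receptor_loadings = expr$loadings,
      receptor_groups = expr$groups,
      sc_sim = sc_sim,
      ns_sim = ns_sim,
      population_fc = population_fc,
      pop_gradients = pop_gradients
    )
    class(truth) <- "gradflow_truth"
    truth
  })
}

quantize_arousal <- function(a, n_levels) {
  pmin(n_levels, pmax(1L, as.integer(ceiling(a * n_levels))))
}

#' Generate a directed tracing weight matrix
#'
#' Log-weights decay with inter-region distance and receive log-normal
#' scatter; all weights are strictly positive and the matrix is generally
#' asymmetric. Optionally, each target's connection profile additionally
#' varies as a smooth Gaussian-process field over the source regions
#' (covariance `field_cov`), which is how the cohort generator plants
#' gradient structure: profiles of regions that are close in latent field
#' space are then correlated. Targets are the first `n_target` regions,
#' mirroring a tracing atlas where the injected areas are a subset of the
#' labelled source areas.
#'
#' @param n_source,n_target matrix dimensions, `n_target <= n_source`.
#' @param coords N x 2 coordinates for the source regions.
#' @param decay distance-decay rate of the mean log-weight (0 = none).
#' @param seed integer seed.
#' @param field_cov optional N x N covariance of the per-target smooth
#'   field over source regions.
#' @param noise_sd independent log-normal scatter.
#' @return `n_source` x `n_target` positive weight matrix.
#' @export
make_tracing <- function(n_source, n_target, coords, decay = 0.5,
                         seed = NULL, field_cov = NULL, noise_sd = 0.25) {
  if (n_target > n_source) stop("n_target must be <= n_source")
  local_seed(seed, {
    D <- coord_dist(coords)[seq_len(n_source), seq_len(n_target), drop = FALSE]
    logw <- -decay * D
    if (!is.null(field_cov)) {
      L <- chol(field_cov[seq_len(n_source), seq_len(n_source)] +
                  diag(1e-8, n_source))
      logw <- logw + crossprod(L, matrix(rnorm(n_source * n_target),
                                         n_source, n_target))
    }
    logw <- logw + matrix(rnorm(n_source * n_target, sd = noise_sd),
                          n_source, n_target)
    w <- exp(logw)
    rownames(w) <- region_labels(n_source)
    colnames(w) <- region_labels(n_source)[seq_len(n_target)]
    w
  })
}

# Receptor loadings cycle through a balanced block of eight patterns —
# +/- gradient 1, +/- gradient 2, and the four +/- diagonal directions —
# followed by n_null all-zero rows. The design is balanced (loadings sum to
# zero) so the across-receptor centering inside the Pearson similarity does
# not rotate the effective axes, and isotropic (the summed loading kernel
# is proportional to the identity in map space) so the receptor set does
# not tilt the population gradients away from the loading frame. Groups:
# 1 = gradient 1 only, 2 = gradient 2 only, 3 = both, 4 = null.
default_loadings <- function(n_receptors, n_null, n_maps) {
  n_load <- n_receptors - n_null
  L <- matrix(0, n_receptors, n_maps)
  groups <- integer(n_receptors)
  s2 <- 1 / sqrt(2)
  block <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                c(s2, s2), c(-s2, -s2), c(s2, -s2), c(-s2, s2))
  block_grp <- c(1L, 1L, 2L, 2L, 3L, 3L, 3L, 3L)
  for (g in seq_len(n_load)) {
    i <- (g - 1L) %% 8L + 1L
    L[g, seq_len(min(n_maps, 2L))] <- block[[i]][seq_len(min(n_maps, 2L))]
    groups[g] <- block_grp[i]
  }
  if (n_null > 0) groups[(n_load + 1L):n_receptors] <- 4L
  list(loadings = L, groups = groups)
}

make_expression_internal <- function(maps, n_receptors, n_null, noise_sd,
                                     loadings = NULL, noise = NULL) {
  n_regions <- nrow(maps)
  n_maps <- ncol(maps)
  if (is.null(loadings)) {
    dl <- default_loadings(n_receptors, n_null, n_maps)
    loadings <- dl$loadings
    groups <- dl$groups
  } else {
    groups <- ifelse(rowSums(abs(loadings)) > 0, 0L, 4L)
  }
  null_rows <- which(rowSums(abs(loadings)) == 0)
  if (is.null(noise)) {
    noise <- matrix(rnorm(n_receptors * n_regions, sd = noise_sd),
                    n_receptors, n_regions)
    # null receptors are pure unit-variance noise so all receptors share
    # the scale of the loaded (map + noise) rows
    if (length(null_rows)) {
      noise[null_rows, ] <- matrix(rnorm(length(null_rows) * n_regions),
                                   length(null_rows), n_regions)
    }
  }
  mz <- maps * sqrt(n_regions)
  E <- loadings %*% t(mz) + noise
  E <- E - apply(E, 1, min)  # nonnegative; Pearson similarity is shift-free
  fams <- c("dopaminergic", "noradrenergic", "serotonergic", "cholinergic")
  rownames(E) <- sprintf("REC%02d_%s", seq_len(n_receptors),
                         ifelse(groups == 4L, "other",
                                fams[(seq_len(n_receptors) - 1L) %% 4L + 1L]))
  colnames(E) <- region_labels(n_regions)
  list(values = E, loadings = loadings, groups = groups)
}

#' Generate a receptor-by-region expression matrix with planted loadings
#'
#' Each non-null receptor map is its loading row times the planted gradient
#' maps plus Gaussian noise; null receptors are pure map-independent noise
#' (smooth fields when `null_smoothness > 0`), the negative controls for the
#' receptor-significance test.
#'
#' @param truth a `gradflow_truth` object (provides the maps and
#'   coordinates).
#' @param n_receptors,n_null receptor counts.
#' @param noise_sd observation noise.
#' @param seed integer seed.
#' @param loadings optional explicit loading matrix (receptors x maps).
#' @param null_smoothness correlation length of the null receptors' fields
#'   (0 = white noise).
#' @return nonnegative receptor x region matrix with attributes `loadings`
#'   and `groups` (1 = gradient 1, 2 = gradient 2, 3 = both, 4 = null).
#' @export
make_expression <- function(truth, n_receptors, n_null, noise_sd = 0.3,
                            seed = NULL, loadings = NULL,
                            null_smoothness = 0.10) {
  if (n_null > n_receptors) stop("n_null must be <= n_receptors")
  n_regions <- nrow(truth$gradient_maps)
  local_seed(seed, {
    noise <- matrix(rnorm(n_receptors * n_regions, sd = noise_sd),
                    n_receptors, n_regions)
    n_load <- n_receptors - n_null
    if (n_null > 0) {
      nm <- if (null_smoothness > 0) {
        t(scale(make_spatial_maps(n_regions, n_null,
                                  smoothness = null_smoothness,
                                  coords = truth$coords)$maps)) *
          sqrt((n_regions - 1) / n_regions)
      } else {
        matrix(rnorm(n_null * n_regions), n_null, n_regions)
      }
      noise[(n_load + 1L):n_receptors, ] <- nm
    }
    out <- make_expression_internal(truth$gradient_maps, n_receptors, n_null,
                                    noise_sd, loadings, noise = noise)
    structure(out$values, loadings = out$loadings, groups = out$groups)
  })
}

#' Generate one scan of region time series from the planted model
#'
#' Frame t is drawn from a zero-mean Gaussian whose correlation matrix is the
#' normalized mixture `b0*I + b1*SC_sim + w_mod(a_t)*NS_sim`, with
#' `w_mod(a) = b2 * 4 * (a - 1/2)^2` (U-shaped in arousal), projected to the
#' nearest valid correlation matrix. A global-amplitude term proportional to
#' the HRF-convolved, mean-centred arousal scales the fixed template map so
#' that the fMRI arousal index is recoverable. Arousal levels are quantized
#' to `n_levels` to bound the number of Cholesky factorizations.
#'
#' @param truth a `gradflow_truth` object.
#' @param arousal per-frame arousal in \[0, 1\] (length = n_frames).
#' @param tr repetition time in seconds.
#' @param sigma_obs observation noise SD added independently per region.
#' @param seed integer seed.
#' @param n_levels arousal quantization levels for the correlation mixture.
#' @return T x N matrix of class `gradflow_ts` with attributes `tr` and
#'   `arousal`.
#' @export
make_timeseries <- function(truth, arousal, tr = 2, sigma_obs = NULL,
                            seed = NULL, n_levels = NULL) {
  n_frames <- length(arousal)
  n <- nrow(truth$gradient_maps)
  w <- truth$weights
  if (is.null(sigma_obs)) sigma_obs <- truth$sigma_obs %||% 0.2
  if (is.null(n_levels)) n_levels <- truth$n_levels %||% 21
  local_seed(seed, {
    lev <- quantize_arousal(arousal, n_levels)
    a_mid <- (seq_len(n_levels) - 0.5) / n_levels
    X <- matrix(0, n_frames, n)
    for (l in sort(unique(lev))) {
      wm <- modulation_weight(a_mid[l], w[["b2"]])
      raw <- w[["b0"]] * diag(n) + w[["b1"]] * truth$sc_sim + wm * truth$ns_sim
      C <- nearest_correlation(raw / (w[["b0"]] + w[["b1"]] + wm))
      R <- chol(C)
      idx <- which(lev == l)
      X[idx, ] <- matrix(rnorm(length(idx) * n), length(idx), n) %*% R
    }
    # arousal-coupled global amplitude along the template map
    a_dev <- hrf_convolve(arousal - mean(arousal), tr)
    X <- X + truth$amp * tcrossprod(a_dev, truth$template)
    if (sigma_obs > 0) {
      X <- X + matrix(rnorm(n_frames * n, sd = sigma_obs), n_frames, n)
    }
    colnames(X) <- region_labels(n)
    structure(X, tr = tr, arousal = arousal, class = c("gradflow_ts", "matrix"))
  })
}

#' Generate a noisy pupil trace observing a latent arousal signal
#'
#' The arousal signal is step-upsampled to `fps * tr` samples per frame,
#' Gaussian noise is added, and blink gaps (runs of missing samples shorter
#' than 0.5 s) are inserted at a Poisson rate.
#'
#' @param arousal_signal per-frame arousal.
#' @param tr frame interval in seconds.
#' @param fps pupil sampling rate (samples per second); `fps * tr` must be
#'   an integer.
#' @param noise_sd additive Gaussian noise SD.
#' @param blink_rate expected blinks per second.
#' @param seed integer seed.
#' @return numeric vector of length `frames * fps * tr` with `NA` during
#'   blinks.
#' @export
make_pupil <- function(arousal_signal, tr = 2, fps = 6, noise_sd = 0.05,
                       blink_rate = 0.1, seed = NULL) {
  spf <- fps * tr
  if (abs(spf - round(spf)) > 1e-9) stop("fps * tr must be an integer")
  spf <- as.integer(round(spf))
  local_seed(seed, {
    trace <- rep(arousal_signal, each = spf)
    if (noise_sd > 0) trace <- trace + rnorm(length(trace), sd = noise_sd)
    if (blink_rate > 0) {
      dur_s <- length(trace) / fps
      n_blinks <- stats::rpois(1, blink_rate * dur_s)
      if (n_blinks > 0) {
        starts <- sample.int(length(trace), n_blinks, replace = TRUE)
        max_gap <- max(1L, as.integer(floor(0.5 * fps)))
        for (s in starts) {
          len <- sample.int(max_gap, 1)
          trace[s:min(length(trace), s + len - 1L)] <- NA
        }
      }
    }
    trace
  })
}

#' Generate a complete synthetic cohort
#'
#' Bundles the ground truth with `n_scans` scans, matching pupil traces, the
#' tracing matrix and the expression matrix. Defaults mirror the study
#' conditions the pipeline is meant for: 116 regions with 55 tracing
#' targets, 512 frames at TR = 2 s per scan, pupil video at 6 fps.
#'
#' @param n_scans number of scans.
#' @param n_frames frames per scan.
#' @param tr,fps frame interval (s) and pupil sampling rate (Hz).
#' @param persistence arousal AR(1) persistence.
#' @param sigma_obs observation noise SD on the BOLD series.
#' @param pupil_noise_sd,blink_rate pupil observation model.
#' @param seed integer seed; all per-scan seeds derive from it.
#' @param ... passed to [make_ground_truth()].
#' @return object of class `gradflow_cohort`: list with `truth`, `scans`,
#'   `pupil`, `arousal` (per-scan latent signals), `tracing`, `expression`,
#'   `tr`, `fps`.
#' @export
make_cohort <- function(n_scans = 4, n_frames = 512, tr = 2, fps = 6,
                        persistence = 0.95, sigma_obs = 0.2,
                        pupil_noise_sd = 0.05, blink_rate = 0.1,
                        seed = NULL, ...) {
  truth <- make_ground_truth(seed = child_seed(seed, "truth"),
                             sigma_obs = sigma_obs,
                             persistence = persistence, ...)
  scans <- vector("list", n_scans)
  pupil <- vector("list", n_scans)
  arousal <- vector("list", n_scans)
  for (s in seq_len(n_scans)) {
    a <- make_arousal_process(n_frames, persistence,
                              seed = child_seed(seed, paste0("arousal", s)))
    arousal[[s]] <- a
    scans[[s]] <- make_timeseries(truth, a, tr = tr, sigma_obs = sigma_obs,
                                  seed = child_seed(seed, paste0("scan", s)))
    pupil[[s]] <- make_pupil(a, tr = tr, fps = fps,
                             noise_sd = pupil_noise_sd,
                             blink_rate = blink_rate,
                             seed = child_seed(seed, paste0("pupil", s)))
  }
  structure(list(truth = truth, scans = scans, pupil = pupil,
                 arousal = arousal, tracing = truth$tracing,
                 expression = truth$expression, tr = tr, fps = fps),
            class = "gradflow_cohort")
}

#' Write a synthetic cohort to disk as plain-text tables
#'
#' Scans are written as frames x regions TSV with region-label header, pupil
#' traces as single-column TSV, tracing/expression/coords as labelled TSV,
#' plus a YAML manifest recording TR, fps and file names.
#'
#' @param cohort a `gradflow_cohort`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scan_files <- sprintf("scan%02d.tsv", seq_along(cohort$scans))
  pupil_files <- sprintf("pupil%02d.tsv", seq_along(cohort$pupil))
  for (i in seq_along(cohort$scans)) {
    write_tsv(as.data.frame(unclass(cohort$scans[[i]])),
              file.path(dir, scan_files[i]))
    write_tsv(data.frame(pupil = cohort$pupil[[i]]),
              file.path(dir, pupil_files[i]))
  }
  write_tsv(as.data.frame(cohort$tracing), file.path(dir, "tracing.tsv"),
            row_names = TRUE)
  write_tsv(as.data.frame(cohort$expression),
            file.path(dir, "expression.tsv"), row_names = TRUE)
  write_tsv(as.data.frame(cohort$truth$coords), file.path(dir, "coords.tsv"),
            row_names = TRUE)
  manifest <- list(tr = cohort$tr, fps = cohort$fps, scans = scan_files,
                   pupil = pupil_files, tracing = "tracing.tsv",
                   expression = "expression.tsv", coords = "coords.tsv")
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}
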