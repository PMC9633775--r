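#' Arousal-binned gradient dynamics
#'
#' Frame-wise dynamic connectivity is binned by arousal level (equal-sized
#' bins), averaged per bin, and embedded into per-bin gradient sets aligned
#' to a reference. Gradient trajectories across bins ("gradient flow"), a
#' scan-shuffled null for the flow, the entropy of connectivity, and
#' quadratic (U / inverted-U) trend fits quantify the dynamics.
#'
#' @name dynamics
NULL

#' Per-bin mean of dynamic connectivity frames
#'
#' Element-wise mean of the frame correlation matrices within each arousal
#' bin, re-projected to the nearest correlation matrix when the mean is not
#' one (a guard; means of correlation matrices already are).
#'
#' @param dfc N x N x T array of frame correlation matrices (e.g.
#'   `dcc_fit()$dfc`) or list of matrices.
#' @param assignment integer bin label per frame (`NA` = dropped frame),
#'   from [bin_by_arousal()].
#' @return list of per-bin correlation matrices, ascending arousal.
#' @export
binned_mean_dfc <- function(dfc, assignment) {
  if (is.list(dfc)) dfc <- simplify2array(dfc)
  n_bins <- max(assignment, na.rm = TRUE)
  if (any(!(seq_len(n_bins) %in% assignment))) stop("empty arousal bin")
  means <- bin_mean_slices(dfc, as.integer(assignment), as.integer(n_bins))
  lapply(seq_len(n_bins), function(b) {
    M <- means[, , b]
    dimnames(M) <- dimnames(dfc)[1:2]
    nearest_correlation(M)
  })
}

#' Per-bin dynamic gradients aligned to a reference
#'
#' Runs threshold / normalized-angle / diffusion embedding on each bin-mean
#' connectivity matrix and Procrustes-aligns each gradient set to the
#' reference, so components keep a common orientation across bins.
#'
#' @param bin_matrices list of per-bin connectivity matrices.
#' @param reference reference `gradient_set` (typically from the static FC).
#' @param n_components,density,alpha embedding parameters.
#' @return list of aligned `gradient_set`s (one per bin).
#' @export
dynamic_gradients <- function(bin_matrices, reference, n_components = 4,
                              density = 0.10, alpha = 0.5) {
  lapply(bin_matrices, connectivity_gradients, n_components = n_components,
         density = density, alpha = alpha, reference = reference)
}

#' Gradient flow: per-network trajectories across arousal bins
#'
#' For every network, the centroid (mean gradient-1, mean gradient-2 value
#' of its member regions) is tracked across ordered bins; the displacement
#' is the least-squares linear drift of the centroid per bin step, and its
#' magnitude the Euclidean norm of that drift.
#'
#' @param bin_gradients list of aligned `gradient_set`s across bins.
#' @param network_labels factor/character vector assigning each region to a
#'   network.
#' @return list with `trajectories` (bins x 2 x networks array),
#'   `displacement` (networks x 2 drift per bin step) and `magnitude`
#'   (named vector).
#' @export
gradient_flow <- function(bin_gradients, network_labels) {
  networks <- sort(unique(as.character(network_labels)))
  n_bins <- length(bin_gradients)
  traj <- array(NA_real_, c(n_bins, 2, length(networks)),
                dimnames = list(NULL, c("g1", "g2"), networks))
  for (b in seq_len(n_bins)) {
    comps <- as_component_matrix(bin_gradients[[b]])
    for (k in seq_along(networks)) {
      rows <- which(as.character(network_labels) == networks[k])
      traj[b, , k] <- colMeans(comps[rows, 1:2, drop = FALSE])
    }
  }
  bin_idx <- seq_len(n_bins)
  disp <- t(vapply(seq_along(networks), function(k) {
    c(coef(lm(traj[, 1, k] ~ bin_idx))[2],
      coef(lm(traj[, 2, k] ~ bin_idx))[2])
  }, numeric(2)))
  dimnames(disp) <- list(networks, c("g1", "g2"))
  magnitude <- sqrt(rowSums(disp^2))
  list(trajectories = traj, displacement = disp, magnitude = magnitude)
}

# Pool per-scan dynamic connectivity and arousal, bin, and compute flow.
pooled_flow <- function(dfc_list, arousal_values, network_labels, reference,
                        n_bins, n_components = 4, density = 0.10) {
  dfc <- do.call(abind3, dfc_list)
  assignment <- bin_by_arousal(arousal_values, n_bins)
  bins <- binned_mean_dfc(dfc, assignment)
  grads <- dynamic_gradients(bins, reference, n_components, density)
  gradient_flow(grads, network_labels)
}

abind3 <- function(...) {
  mats <- list(...)
  n <- dim(mats[[1]])[1]
  array(unlist(mats), c(n, n, sum(vapply(mats, function(m) dim(m)[3], 1L))))
}

#' Scan-shuffled null distribution for gradient-flow displacement
#'
#' The per-scan arousal traces are randomly reassigned across scans (scan
#' labels permuted), the binning and flow analysis recomputed, and a
#' right-tailed permutation p-value reported per network with the +1
#' correction.
#'
#' @param dfc_list list of per-scan N x N x T arrays.
#' @param arousal_list list of per-scan arousal index vectors (equal
#'   lengths).
#' @param network_labels per-region network assignment.
#' @param reference reference `gradient_set`.
#' @param n_bins number of arousal bins.
#' @param n_perm number of scan-label permutations (>= 1; < 100 warns).
#' @param seed integer seed.
#' @param n_components,density embedding parameters.
#' @return list with `observed` (flow list), `null_magnitude`
#'   (n_perm x networks), `p` (named vector).
#' @export
flow_null <- function(dfc_list, arousal_list, network_labels, reference,
                      n_bins = 10, n_perm = 1000, seed = NULL,
                      n_components = 4, density = 0.10) {
  if (length(dfc_list) < 2) stop("need at least 2 scans")
  if (n_perm < 1) stop("n_perm must be positive")
  if (n_perm < 100) warning("n_perm < 100 gives a coarse null")
  lens <- vapply(arousal_list, length, 1L)
  if (length(unique(lens)) != 1) stop("scans must have equal frame counts")
  observed <- pooled_flow(dfc_list, unlist(arousal_list), network_labels,
                          reference, n_bins, n_components, density)
  local_seed(seed, {
    null_mag <- matrix(NA_real_, n_perm, length(observed$magnitude),
                       dimnames = list(NULL, names(observed$magnitude)))
    for (p in seq_len(n_perm)) {
      perm <- sample(length(arousal_list))
      fl <- pooled_flow(dfc_list, unlist(arousal_list[perm]), network_labels,
                        reference, n_bins, n_components, density)
      null_mag[p, ] <- fl$magnitude
    }
    pval <- vapply(seq_along(observed$magnitude), function(k) {
      (1 + sum(null_mag[, k] >= observed$magnitude[k])) / (1 + n_perm)
    }, numeric(1))
    names(pval) <- names(observed$magnitude)
    list(observed = observed, null_magnitude = null_mag, p = pval)
  })
}

#' Shannon entropy of a connectivity matrix
#'
#' Entropy (base 2) of the histogram of upper-triangle connectivity values
#' over fixed equal-width bins spanning \[-1, 1\]. Higher entropy means a
#' more heterogeneous connectivity distribution.
#'
#' @param C symmetric connectivity matrix.
#' @param n_hist_bins number of histogram bins.
#' @return entropy in bits.
#' @export
fc_entropy <- function(C, n_hist_bins = 64) {
  if (nrow(C) < 2) stop("need at least 2 regions")
  v <- vectorize_pairs(C)
  breaks <- seq(-1, 1, length.out = n_hist_bins + 1)
  v <- pmin(pmax(v, -1), 1)
  counts <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE),
                     nbins = n_hist_bins)
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Second-order polynomial trend fit
#'
#' OLS fit of `y = c2 x^2 + c1 x + c0` with 95% coefficient confidence
#' intervals. The shape is `inverted_u` iff `c2 < 0` with its CI excluding
#' 0, `u` iff `c2 > 0` likewise; otherwise `monotone` when the linear CI
#' excludes 0, else `flat`.
#'
#' @param x,y numeric vectors (>= 4 points).
#' @return list of class `trend_fit`: `coefficients` (c0, c1, c2),
#'   `conf_int`, `shape`, `r_squared`.
#' @export
quadratic_trend <- function(x, y) {
  if (length(x) < 4 || length(y) != length(x)) {
    stop("need at least 4 matched points")
  }
  fit <- lm(y ~ x + I(x^2))
  cf <- coef(fit)
  ci <- suppressWarnings(confint(fit, level = 0.95))
  c2 <- cf[3]; c2_ci <- ci[3, ]
  c1_ci <- ci[2, ]
  shape <- if (is.finite(c2_ci[1]) && (c2_ci[1] > 0 || c2_ci[2] < 0)) {
    if (c2 < 0) "inverted_u" else "u"
  } else if (is.finite(c1_ci[1]) && (c1_ci[1] > 0 || c1_ci[2] < 0)) {
    "monotone"
  } else {
    "flat"
  }
  structure(list(coefficients = c(c0 = unname(cf[1]), c1 = unname(cf[2]),
                                  c2 = unname(cf[3])),
                 conf_int = ci, shape = shape,
                 r_squared = suppressWarnings(summary(fit)$r.squared)),
            class = "trend_fit")
}
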