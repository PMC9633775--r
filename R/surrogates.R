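#' Spatial-autocorrelation preserving surrogate maps and significance tests
#'
#' Brain maps are spatially autocorrelated, so naive parametric tests of
#' map-to-map correlations are anti-conservative. These routines build
#' surrogate maps that randomize the topography while matching the
#' empirical variogram, and derive permutation-style p-values from them.
#'
#' @name surrogates
NULL

# Equal-count distance-lag bins defined by D alone (shared across maps).
variogram_bins <- function(D, n_lag_bins) {
  iu <- which(upper.tri(D))
  d <- D[iu]
  qs <- quantile(d, probs = seq(0, 1, length.out = n_lag_bins + 1))
  bin <- findInterval(d, qs, rightmost.closed = TRUE, all.inside = TRUE)
  list(pair_idx = iu, bin = bin, d = d)
}

#' Empirical variogram of a region map
#'
#' Semivariance `gamma(h) = mean of 0.5 * (x_i - x_j)^2` over region pairs
#' falling in equal-count distance-lag bins.
#'
#' @param map numeric vector over regions.
#' @param D N x N distance matrix.
#' @param n_lag_bins number of lag bins (>= 3).
#' @return list with `centers` (mean pair distance per bin) and `gamma`.
#' @export
variogram <- function(map, D, n_lag_bins = 10) {
  if (n_lag_bins < 3) stop("n_lag_bins must be >= 3")
  vb <- variogram_bins(D, n_lag_bins)
  ii <- row(D)[vb$pair_idx]; jj <- col(D)[vb$pair_idx]
  sq <- 0.5 * (map[ii] - map[jj])^2
  gamma <- as.numeric(rowsum(sq, vb$bin) / tabulate(vb$bin, n_lag_bins))
  centers <- as.numeric(rowsum(vb$d, vb$bin) / tabulate(vb$bin, n_lag_bins))
  list(centers = centers, gamma = gamma)
}

#' Variogram-matched surrogate maps
#'
#' Each surrogate permutes the map values (destroying the topography),
#' smooths the permuted map by distance-kernel averaging over k nearest
#' neighbors for a grid of k, and affinely rescales (adding white noise as
#' the nugget) so the surrogate variogram best matches the target variogram;
#' the k minimizing the squared variogram mismatch is kept.
#'
#' @param map numeric vector over regions (non-constant).
#' @param D N x N distance matrix.
#' @param M number of surrogates.
#' @param seed integer seed (same seed, identical ensemble).
#' @param k_grid candidate neighborhood sizes.
#' @param n_lag_bins variogram lag bins.
#' @return list of class `surrogate_ensemble`: `maps` (M x N), `target`
#'   (target variogram), `fit_error` (per surrogate), `k` (chosen per
#'   surrogate), `seed`.
#' @export
make_surrogates <- function(map, D, M = 1000, seed = NULL,
                            k_grid = c(3, 5, 8, 13, 21, 34, 55, 89),
                            n_lag_bins = 10) {
  n <- length(map)
  if (sd(map) == 0) stop("map is constant; surrogates undefined")
  k_grid <- k_grid[k_grid < n]
  vb <- variogram_bins(D, n_lag_bins)
  ii <- row(D)[vb$pair_idx]; jj <- col(D)[vb$pair_idx]
  counts <- tabulate(vb$bin, n_lag_bins)
  gamma_of <- function(x) {
    as.numeric(rowsum(0.5 * (x[ii] - x[jj])^2, vb$bin) / counts)
  }
  target <- gamma_of(map)
  # precompute neighbor weights per k: exponential kernel truncated at the
  # k nearest neighbors (self included)
  ord <- apply(D, 1, order)              # n x n, columns = regions
  Wk <- lapply(k_grid, function(k) {
    Wm <- matrix(0, n, n)
    for (i in seq_len(n)) {
      nb <- ord[seq_len(k), i]
      dk <- D[i, nb[k]]
      w <- exp(-D[i, nb] / max(dk, .Machine$double.eps))
      Wm[i, nb] <- w / sum(w)
    }
    Wm
  })
  local_seed(seed, {
    maps <- matrix(NA_real_, M, n)
    fit_error <- numeric(M)
    k_sel <- integer(M)
    w <- 1 / target^2                     # relative-error weighting
    for (s in seq_len(M)) {
      x <- map[sample(n)]
      noise <- rnorm(n)
      gno <- gamma_of(noise)
      best <- NULL
      for (g in seq_along(k_grid)) {
        sm <- as.numeric(Wk[[g]] %*% x)
        sm <- (sm - mean(sm)) / sd(sm)
        gsm <- gamma_of(sm)
        # independent-component variogram algebra with realized variograms:
        # gamma(sqrt(b)*sm + sqrt(a)*noise) ~ b*gamma_sm + a*gamma_noise;
        # closed-form weighted (relative-error) least squares
        a11 <- sum(w * gsm^2); a12 <- sum(w * gsm * gno)
        a22 <- sum(w * gno^2)
        b1 <- sum(w * gsm * target); b2 <- sum(w * gno * target)
        det <- a11 * a22 - a12^2
        cf <- if (det > 1e-12) {
          c(a22 * b1 - a12 * b2, a11 * b2 - a12 * b1) / det
        } else c(1, 0)
        b_ <- max(cf[1], 0)
        a_ <- max(cf[2], 0)
        cand <- sqrt(b_) * sm + sqrt(a_) * noise
        # final scalar calibration against the realized candidate variogram
        # (absorbs the finite-sample cross-variogram of the two components);
        # scaling the map by c scales its variogram by c^2 exactly
        gc <- gamma_of(cand)
        c2 <- max(sum(w * gc * target) / sum(w * gc^2), 0)
        cand <- cand * sqrt(c2)
        err <- max(abs(c2 * gc - target) / target)
        if (is.null(best) || err < best$err) {
          best <- list(err = err, cand = cand, k = k_grid[g])
        }
      }
      maps[s, ] <- best$cand
      fit_error[s] <- best$err
      k_sel[s] <- best$k
    }
    structure(list(maps = maps, target = target, fit_error = fit_error,
                   k = k_sel, seed = seed),
              class = "surrogate_ensemble")
  })
}

#' Permutation-style p-value against a surrogate null
#'
#' `p = (1 + #(null >= obs)) / (1 + M)` for the right tail, mirrored for
#' the left, and twice the smaller tail (capped at 1) for two-sided.
#'
#' @param observed_stat scalar observed statistic.
#' @param surrogate_stats null statistics (>= 100 recommended).
#' @param tail `"right"`, `"left"` or `"two_sided"`.
#' @return p-value.
#' @export
sa_pvalue <- function(observed_stat, surrogate_stats,
                      tail = c("right", "left", "two_sided")) {
  tail <- match.arg(tail)
  M <- length(surrogate_stats)
  pr <- (1 + sum(surrogate_stats >= observed_stat)) / (1 + M)
  pl <- (1 + sum(surrogate_stats <= observed_stat)) / (1 + M)
  switch(tail, right = pr, left = pl, two_sided = min(1, 2 * min(pr, pl)))
}

#' Right-tailed receptor-specificity test
#'
#' Correlates, across surrogates, the similarity of each surrogate map to
#' the empirical receptor map with the contribution retained under that
#' surrogate. A significantly positive correlation means larger map
#' disruption causes larger contribution loss, i.e. the empirical map
#' specifically drives the contribution.
#'
#' @param surrogate_similarities Pearson similarity of each surrogate to the
#'   empirical map (length M).
#' @param contributions per-surrogate contribution statistic (length M).
#' @return list with `r`, `t`, `p` (right-tailed Student t).
#' @export
receptor_significance <- function(surrogate_similarities, contributions) {
  if (length(surrogate_similarities) != length(contributions)) {
    stop("length mismatch between similarities and contributions")
  }
  n <- length(contributions)
  r <- cor(surrogate_similarities, contributions)
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, t = t, p = pt(t, df = n - 2, lower.tail = FALSE))
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' @param pvals p-values in \[0, 1\].
#' @param q FDR level.
#' @return list with `rejected` (logical), `p_adjusted`.
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  adj <- p.adjust(pvals, method = "BH")
  list(rejected = adj <= q, p_adjusted = adj)
}

#' Pearson correlation with Student-t significance
#'
#' `t = r * sqrt((n - 2) / (1 - r^2))` with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors (length >= 3, non-constant).
#' @param tails `"two_sided"`, `"right"` or `"left"`.
#' @return list with `r`, `t`, `p`, `df`.
#' @export
correlation_test <- function(x, y, tails = c("two_sided", "right", "left")) {
  tails <- match.arg(tails)
  if (length(x) < 3 || length(x) != length(y)) stop("need >= 3 paired values")
  if (sd(x) == 0 || sd(y) == 0) stop("zero-variance input")
  n <- length(x)
  r <- cor(x, y)
  t <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- switch(tails,
              two_sided = 2 * pt(abs(t), n - 2, lower.tail = FALSE),
              right = pt(t, n - 2, lower.tail = FALSE),
              left = pt(t, n - 2))
  list(r = r, t = t, p = min(p, 1), df = n - 2)
}
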