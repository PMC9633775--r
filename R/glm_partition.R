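#' Variance partitioning of functional connectivity
#'
#' Linear model of connectivity over region pairs,
#' `FC = b0 + b1 * SC + b2 * NS`, fitted by least squares with a small ridge
#' penalty on the slopes ("Euclidean norm constraint"; the default penalty
#' is negligible so OLS is recovered on well-conditioned data). Contribution
#' of each predictor is bracketed by the single-variable model (upper bound)
#' and the shuffle-based reduced model (lower bound, `deltaR2`), both
#' evaluated with leave-one-scan-out cross-validation.
#'
#' @name glm_partition
NULL

as_pair_vector <- function(x) {
  if (is.matrix(x) && nrow(x) == ncol(x)) vectorize_pairs(x) else as.numeric(x)
}

design_matrix <- function(predictors) {
  cols <- lapply(predictors, as_pair_vector)
  X <- cbind(intercept = 1, do.call(cbind, cols))
  colnames(X) <- c("intercept", names(predictors))
  X
}

ridge_solve <- function(X, y, ridge) {
  p <- ncol(X) - 1L
  pen <- diag(c(0, rep(1, p)), ncol(X))
  lambda <- ridge * sum(X[, -1, drop = FALSE]^2) / max(p, 1)
  XtX <- crossprod(X) + lambda * pen
  ok <- tryCatch({solve(XtX, crossprod(X, y))}, error = function(e) NULL)
  if (is.null(ok)) {
    stop("design is exactly collinear; refit with ridge > 0")
  }
  list(beta = drop(ok), lambda = lambda)
}

#' Fit the pairwise connectivity model
#'
#' @param fc_vec connectivity over region pairs (vector from
#'   [vectorize_pairs()], or a symmetric matrix).
#' @param predictors named list of predictor similarity matrices or pair
#'   vectors (conventionally `SC` and `NS`).
#' @param ridge ridge weight on the slope coefficients, scaled by the mean
#'   squared predictor magnitude; default 1e-6 (effectively OLS).
#' @return list of class `glm_fit`: `coefficients` (b0 and one slope per
#'   predictor), `fitted`, `r_squared`, `lambda`.
#' @export
fit_glm <- function(fc_vec, predictors, ridge = 1e-6) {
  y <- as_pair_vector(fc_vec)
  X <- design_matrix(predictors)
  if (length(y) < 3 || nrow(X) != length(y)) {
    stop("need >= 3 pairs with matching predictor length")
  }
  sol <- ridge_solve(X, y, ridge)
  fitted <- drop(X %*% sol$beta)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 0 else 1 - sum((y - fitted)^2) / sst
  structure(list(coefficients = setNames(sol$beta, colnames(X)),
                 fitted = fitted, r_squared = r2, lambda = sol$lambda),
            class = "glm_fit")
}

#' Leave-one-scan-out cross-validated explained variance
#'
#' For each held-out scan the model is fitted to the mean connectivity of
#' the remaining scans and scored on the held-out scan as
#' `cvR2 = 1 - SSE/SST`; the squared Pearson correlation between predicted
#' and held-out connectivity is reported alongside.
#'
#' @param fc_vecs list of per-scan pair vectors (or symmetric matrices).
#' @param predictors named list of predictors (shared across scans).
#' @param ridge ridge weight.
#' @return list with `cv_r2` (per scan), `mean`, `sem`, `pearson_r2`.
#' @export
loo_cv <- function(fc_vecs, predictors, ridge = 1e-6) {
  if (length(fc_vecs) < 2) stop("leave-one-out needs at least 2 scans")
  Y <- vapply(fc_vecs, as_pair_vector,
              numeric(length(as_pair_vector(fc_vecs[[1]]))))
  X <- design_matrix(predictors)
  n <- ncol(Y)
  cv <- pr <- numeric(n)
  for (i in seq_len(n)) {
    y_train <- rowMeans(Y[, -i, drop = FALSE])
    beta <- ridge_solve(X, y_train, ridge)$beta
    pred <- drop(X %*% beta)
    y_test <- Y[, i]
    cv[i] <- 1 - sum((y_test - pred)^2) / sum((y_test - mean(y_test))^2)
    pr[i] <- cor(pred, y_test)^2
  }
  list(cv_r2 = cv, mean = mean(cv), sem = sd(cv) / sqrt(n), pearson_r2 = pr)
}

#' Single-variable model cvR2 (upper bound of a predictor's contribution)
#'
#' @inheritParams loo_cv
#' @param predictor one predictor matrix or pair vector.
#' @param name predictor name.
#' @return as [loo_cv()].
#' @export
single_variable <- function(fc_vecs, predictor, name = "X", ridge = 1e-6) {
  loo_cv(fc_vecs, setNames(list(predictor), name), ridge)
}

# Shuffle a predictor: joint row/column permutation of the similarity
# matrix (keeps it a valid similarity matrix), or independent permutation of
# the pair entries.
shuffle_predictor <- function(x, mode = c("regions", "pairs")) {
  mode <- match.arg(mode)
  if (mode == "regions" && is.matrix(x) && nrow(x) == ncol(x)) {
    perm <- sample(nrow(x))
    x[perm, perm]
  } else {
    v <- as_pair_vector(x)
    v[sample(length(v))]
  }
}

#' Reduced-model unique contribution (deltaR2)
#'
#' The target predictor is randomly shuffled `n_shuffles` times (by default
#' a joint row/column permutation of its similarity matrix, keeping the
#' model's degrees of freedom), the model refitted, and
#' `deltaR2 = cvR2_full - mean(shuffled cvR2)`: a lower bound on the
#' predictor's unique contribution.
#'
#' @inheritParams loo_cv
#' @param target_var name of the predictor to shuffle.
#' @param n_shuffles number of shuffles (>= 2).
#' @param seed integer seed.
#' @param shuffle `"regions"` (joint row/column permutation) or `"pairs"`.
#' @return list with `delta_r2`, `cv_r2_full`, `shuffled_cv_r2`
#'   (distribution), `n_shuffles`, `seed`.
#' @export
reduced_delta <- function(fc_vecs, predictors, target_var, n_shuffles = 1000,
                          seed = NULL, ridge = 1e-6,
                          shuffle = c("regions", "pairs")) {
  shuffle <- match.arg(shuffle)
  if (n_shuffles < 2) stop("n_shuffles must be >= 2")
  if (!(target_var %in% names(predictors))) stop("unknown target_var")
  full <- loo_cv(fc_vecs, predictors, ridge)
  local_seed(seed, {
    shuf <- vapply(seq_len(n_shuffles), function(s) {
      preds <- predictors
      preds[[target_var]] <- shuffle_predictor(predictors[[target_var]],
                                               shuffle)
      loo_cv(fc_vecs, preds, ridge)$mean
    }, numeric(1))
    list(delta_r2 = full$mean - mean(shuf), cv_r2_full = full$mean,
         shuffled_cv_r2 = shuf, n_shuffles = n_shuffles, seed = seed)
  })
}

#' Full variance partition: full model, single-variable and reduced models
#'
#' @inheritParams reduced_delta
#' @return list of class `variance_partition`: `full` (from [loo_cv()]),
#'   `single` (per predictor), `delta` (per predictor, from
#'   [reduced_delta()]).
#' @export
partition_variance <- function(fc_vecs, predictors, n_shuffles = 1000,
                               seed = NULL, ridge = 1e-6) {
  full <- loo_cv(fc_vecs, predictors, ridge)
  single <- lapply(names(predictors), function(nm) {
    single_variable(fc_vecs, predictors[[nm]], nm, ridge)
  })
  names(single) <- names(predictors)
  delta <- lapply(names(predictors), function(nm) {
    reduced_delta(fc_vecs, predictors, nm, n_shuffles,
                  seed = child_seed(seed, nm), ridge = ridge)
  })
  names(delta) <- names(predictors)
  structure(list(full = full, single = single, delta = delta),
            class = "variance_partition")
}

#' Frame-by-frame connectivity model
#'
#' Fits the pairwise model independently to every frame of a dynamic
#' connectivity array (shared design, per-frame coefficients) and assembles
#' the predicted frames. Zero-variance frames are flagged and get zero
#' slopes with the frame mean as intercept.
#'
#' @param dfc N x N x T array (or T x P matrix of pair vectors).
#' @param predictors named list of predictors.
#' @param ridge ridge weight.
#' @return list with `coefficients` (T x (1 + p)), `predicted` (same form
#'   as input), `r_squared` (per frame), `flagged`.
#' @export
framewise_glm <- function(dfc, predictors, ridge = 1e-6) {
  as_array <- !is.matrix(dfc)
  if (as_array) {
    T_ <- dim(dfc)[3]
    Y <- vapply(seq_len(T_), function(t) vectorize_pairs(dfc[, , t]),
                numeric(dim(dfc)[1] * (dim(dfc)[1] - 1) / 2))
  } else {
    Y <- t(dfc)
  }
  X <- design_matrix(predictors)
  p <- ncol(X) - 1L
  pen <- diag(c(0, rep(1, p)), ncol(X))
  lambda <- ridge * sum(X[, -1, drop = FALSE]^2) / max(p, 1)
  B <- solve(crossprod(X) + lambda * pen, crossprod(X, Y))
  sds <- apply(Y, 2, sd)
  flagged <- sds == 0
  if (any(flagged)) {
    B[, flagged] <- 0
    B[1, flagged] <- colMeans(Y[, flagged, drop = FALSE])
  }
  P <- X %*% B
  ss_res <- colSums((Y - P)^2)
  ss_tot <- colSums(sweep(Y, 2, colMeans(Y))^2)
  r2 <- ifelse(ss_tot == 0, 0, 1 - ss_res / ss_tot)
  predicted <- if (as_array) {
    out <- array(0, dim(dfc))
    for (t in seq_len(ncol(P))) out[, , t] <- unvectorize_pairs(P[, t])
    out
  } else {
    t(P)
  }
  list(coefficients = t(B), predicted = predicted, r_squared = r2,
       flagged = flagged)
}

#' Unique contribution of one receptor to gradient dynamics
#'
#' The receptor's expression map is replaced by spatial-autocorrelation
#' preserving surrogate maps. Two quantities are derived from the ensemble.
#' (1) Significance per gradient: the right-tailed SA-corrected p-value of
#' the receptor map's absolute spatial correlation with the reference
#' gradient, against the surrogate-map null — the statistic class the
#' variogram-matched ensemble is calibrated for. (2) Contribution magnitude
#' per gradient (`delta`): for each surrogate the neuromodulatory
#' similarity is rebuilt, the per-bin connectivity model refitted, and the
#' reconstruction score of the binned dynamic connectivity along the
#' gradient axis computed (minus the squared error between predicted and
#' empirical connectivity projected on the unit pair-space direction of
#' `ref_k ref_k'`, summed over bins); `delta` is the observed score minus
#' the surrogate mean — positive when the empirical map is needed to
#' reconstruct that gradient's connectivity. Fit-based scores are reported
#' as magnitudes but not used for the p-values: surrogate ensembles share a
#' construction family, and quadratic fit statistics inherit a cohort-level
#' family bias that spatial-correlation statistics do not.
#'
#' @param dfc_binned list of per-bin connectivity matrices (ascending
#'   arousal), e.g. from [binned_mean_dfc()].
#' @param expression receptors x regions expression matrix.
#' @param receptor receptor name (must match a row of `expression`).
#' @param sc structural similarity matrix (second predictor).
#' @param distance_matrix N x N region distance matrix for the surrogates.
#' @param n_shuffles number of surrogate maps M.
#' @param seed integer seed.
#' @param reference reference `gradient_set` whose leading components define
#'   the gradients being attributed.
#' @param n_gradients number of reference gradients to track.
#' @param ridge ridge weight of the pairwise model.
#' @param surrogate_method `"sa"` (variogram-matched) or `"permute"`.
#' @param compute_delta if `FALSE`, skip the (much costlier) reduced-model
#'   score ensemble and return alignment significance only.
#' @return list of class `receptor_contribution`: `alignment` (per-gradient
#'   absolute spatial correlation with the reference gradients), `p`
#'   (per-gradient SA-corrected right-tailed p), and — when `compute_delta`
#'   — `observed` (per-gradient observed score), `surrogate`
#'   (M x gradients surrogate scores), `surrogate_similarity` (M), `delta`
#'   (per-gradient unique contribution); plus `receptor`, `seed`.
#' @export
receptor_contribution <- function(dfc_binned, expression, receptor, sc,
                                  distance_matrix, n_shuffles = 1000,
                                  seed = NULL, reference, n_gradients = 2,
                                  ridge = 1e-6,
                                  surrogate_method = c("sa", "permute"),
                                  compute_delta = TRUE) {
  surrogate_method <- match.arg(surrogate_method)
  if (!(receptor %in% rownames(expression))) {
    stop("receptor absent: ", receptor)
  }
  ref <- as_component_matrix(reference)[, seq_len(n_gradients), drop = FALSE]
  ref <- apply(ref, 2, function(v) v / sqrt(sum(v^2)))
  map <- expression[receptor, ]

  local_seed(seed, {
    surr <- if (surrogate_method == "sa") {
      make_surrogates(map, distance_matrix, M = n_shuffles)$maps
    } else {
      t(vapply(seq_len(n_shuffles), function(s) map[sample(length(map))],
               numeric(length(map))))
    }
    alignment <- abs(as.numeric(cor(map, ref)))
    null_align <- abs(cor(t(surr), ref))        # M x K
    p <- vapply(seq_len(n_gradients), function(k) {
      sa_pvalue(alignment[k], null_align[, k], tail = "right")
    }, numeric(1))
    out <- list(alignment = alignment, p = p, receptor = receptor,
                seed = seed)

    if (compute_delta) {
      n_bins <- length(dfc_binned)
      fc_list <- lapply(dfc_binned, vectorize_pairs)
      sc_vec <- vectorize_pairs(sc)
      uk <- vapply(seq_len(n_gradients), function(k) {
        u <- vectorize_pairs(tcrossprod(ref[, k]))
        u / sqrt(sum(u^2))
      }, numeric(length(sc_vec)))
      c_emp <- vapply(fc_list, function(y) drop(crossprod(uk, y)),
                      numeric(n_gradients))
      score <- function(E) {
        ns_vec <- vectorize_pairs(expression_similarity(E))
        X <- cbind(1, sc_vec, ns_vec)
        lambda <- ridge * sum(X[, -1]^2) / 2
        XtX <- crossprod(X) + lambda * diag(c(0, 1, 1))
        err <- matrix(0, n_gradients, n_bins)
        for (b in seq_len(n_bins)) {
          beta <- solve(XtX, crossprod(X, fc_list[[b]]))
          err[, b] <- (drop(crossprod(uk, drop(X %*% beta))) - c_emp[, b])^2
        }
        -rowSums(err)
      }
      observed <- score(expression)
      surrogate <- matrix(NA_real_, n_shuffles, n_gradients)
      sim <- numeric(n_shuffles)
      E_s <- expression
      for (s in seq_len(n_shuffles)) {
        E_s[receptor, ] <- surr[s, ]
        surrogate[s, ] <- score(E_s)
        sim[s] <- cor(surr[s, ], map)
      }
      out$observed <- observed
      out$surrogate <- surrogate
      out$surrogate_similarity <- sim
      out$delta <- observed - colMeans(surrogate)
    }
    structure(out, class = "receptor_contribution")
  })
}

#' Screen all receptors for significant contributions to gradient dynamics
#'
#' Runs [receptor_contribution()] for every receptor, applies BH-FDR across
#' receptors per gradient to the SA-corrected alignment p-values, and
#' assigns the four groups: 1 = gradient 1 only, 2 = gradient 2 only,
#' 3 = both, 4 = neither.
#'
#' @inheritParams receptor_contribution
#' @param q FDR level.
#' @return data.frame with per-receptor alignment and p-value per gradient,
#'   FDR-adjusted p, significance flags, `group`, and (when
#'   `compute_delta`) the per-gradient unique contribution `delta.k`.
#' @export
receptor_screen <- function(dfc_binned, expression, sc, distance_matrix,
                            n_shuffles = 1000, seed = NULL, reference,
                            n_gradients = 2, ridge = 1e-6, q = 0.05,
                            surrogate_method = c("sa", "permute"),
                            compute_delta = TRUE) {
  surrogate_method <- match.arg(surrogate_method)
  receptors <- rownames(expression)
  res <- lapply(seq_along(receptors), function(i) {
    rc <- receptor_contribution(dfc_binned, expression, receptors[i], sc,
                                distance_matrix, n_shuffles,
                                seed = child_seed(seed, receptors[i]),
                                reference = reference,
                                n_gradients = n_gradients, ridge = ridge,
                                surrogate_method = surrogate_method,
                                compute_delta = compute_delta)
    c(rc$alignment, rc$p, if (compute_delta) rc$delta)
  })
  res <- do.call(rbind, res)
  k <- seq_len(n_gradients)
  named <- function(M, stem) {
    colnames(M) <- paste0(stem, ".", k)
    as.data.frame(M)
  }
  out <- cbind(data.frame(receptor = receptors),
               named(res[, k, drop = FALSE], "alignment"),
               named(res[, n_gradients + k, drop = FALSE], "p"))
  if (compute_delta) {
    out <- cbind(out, named(res[, 2 * n_gradients + k, drop = FALSE],
                            "delta"))
  }
  padj <- apply(res[, n_gradients + k, drop = FALSE], 2,
                function(p) fdr_bh(p, q)$p_adjusted)
  sig <- matrix(padj <= q, ncol = n_gradients)
  out <- cbind(out, named(padj, "p_adj"), named(sig, "significant"))
  g1 <- sig[, 1]; g2 <- if (n_gradients >= 2) sig[, 2] else FALSE
  out$group <- ifelse(g1 & g2, 3L, ifelse(g1, 1L, ifelse(g2, 2L, 4L)))
  out
}
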