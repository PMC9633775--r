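#' Connectivity gradients by diffusion-map embedding
#'
#' A connectivity matrix is row-thresholded to its strongest connections,
#' converted to a normalized-angle affinity, and embedded with diffusion
#' maps. The resulting components ("gradients") are ordered by explained
#' variance, and gradient sets can be Procrustes-aligned and compared by
#' fingerprinting.
#'
#' @name gradients
NULL

#' Pearson functional connectivity of one scan
#'
#' @param ts T x N region time-series matrix (frames in rows).
#' @return symmetric N x N correlation matrix with unit diagonal.
#' @export
compute_fc <- function(ts) {
  ts <- unclass(ts)
  if (nrow(ts) < 3) stop("need at least 3 frames")
  sds <- apply(ts, 2, sd)
  if (any(sds == 0)) {
    bad <- colnames(ts)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("degenerate (constant) time series for region(s): ",
         paste(bad, collapse = ", "))
  }
  C <- cor(ts)
  diag(C) <- 1
  C
}

#' Row-wise thresholding of a connectivity matrix
#'
#' Per row (diagonal excluded) the `ceiling(density * (N - 1))` largest
#' entries are retained and the rest set to zero; ties are broken
#' deterministically in favour of the lower column index. The result is
#' generally asymmetric.
#'
#' @param C symmetric connectivity matrix.
#' @param density fraction of connections retained per row (0, 1].
#' @return N x N sparse (dense-stored) matrix of retained weights, zero
#'   diagonal.
#' @export
threshold_rows <- function(C, density = 0.10) {
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  n <- nrow(C)
  keep <- as.integer(ceiling(density * (n - 1)))
  out <- matrix(0, n, n, dimnames = dimnames(C))
  for (i in seq_len(n)) {
    row <- C[i, ]
    row[i] <- -Inf
    # order(): decreasing value, ties resolved by lower column index
    idx <- order(row, decreasing = TRUE)[seq_len(keep)]
    out[i, idx] <- C[i, idx]
  }
  out
}

#' Normalized-angle affinity between thresholded connectivity profiles
#'
#' `A[i, j] = 1 - acos(cosine(row_i, row_j)) / pi`, with the cosine clipped
#' to \[-1, 1\]. Identical profiles map to 1, orthogonal to 0.5,
#' antiparallel to 0.
#'
#' @param M thresholded (possibly asymmetric) matrix whose rows are
#'   connectivity profiles.
#' @return symmetric N x N affinity matrix in \[0, 1\].
#' @export
normalized_angle <- function(M) {
  norms <- sqrt(rowSums(M^2))
  if (any(norms == 0)) {
    stop("isolated node: all-zero profile for row(s) ",
         paste(which(norms == 0), collapse = ", "))
  }
  cosine <- tcrossprod(M / norms)
  cosine[cosine > 1] <- 1
  cosine[cosine < -1] <- -1
  A <- 1 - acos(cosine) / pi
  (A + t(A)) / 2
}

#' Diffusion-map embedding of an affinity matrix
#'
#' Applies the anisotropic normalization `W = D^-alpha A D^-alpha`, forms the
#' Markov transition matrix `P = Dw^-1 W`, and decomposes it through the
#' conjugate symmetric matrix. Components are the non-trivial eigenvectors,
#' scaled by `lambda / (1 - lambda)` when `diffusion_time = 0` (the
#' multi-scale convention) or `lambda^diffusion_time` otherwise. Explained
#' variance of component k is `lambda_k^2 / sum(lambda^2)` over the
#' non-trivial spectrum.
#'
#' @param A symmetric nonnegative affinity matrix.
#' @param n_components number of gradients to return (K <= N - 1).
#' @param alpha anisotropic diffusion exponent (0.5 = Fokker-Planck).
#' @param diffusion_time diffusion time t; 0 selects multi-scale scaling.
#' @return object of class `gradient_set`: list with `components` (N x K),
#'   `eigenvalues`, `explained_variance`, `reference_aligned = FALSE`.
#' @export
diffusion_embed <- function(A, n_components = 4, alpha = 0.5,
                            diffusion_time = 0) {
  n <- nrow(A)
  if (n_components > n - 1) stop("n_components must be <= N - 1")
  if (max(abs(A - t(A))) > 1e-10) stop("affinity must be symmetric")
  if (min(A) < 0) stop("affinity must be nonnegative")
  if (!affinity_connected(A)) {
    stop("affinity graph is disconnected; embedding undefined across components")
  }
  d <- rowSums(A)
  W <- A / outer(d^alpha, d^alpha)
  dw <- rowSums(W)
  # P = Dw^-1 W shares eigenvalues with S = Dw^-1/2 W Dw^-1/2 (symmetric)
  S <- W / outer(sqrt(dw), sqrt(dw))
  es <- eigen(S, symmetric = TRUE)
  lam <- es$values
  psi <- es$vectors / sqrt(dw)          # right eigenvectors of P
  # drop the trivial stationary component (lambda = 1, constant eigenvector),
  # then order by explained variance (lambda^2): indefinite affinities can
  # have negative eigenvalues, so ordering by lambda alone is not the
  # explained-variance order
  trivial <- which.max(lam)
  lam_nt <- lam[-trivial]
  psi_nt <- psi[, -trivial, drop = FALSE]
  ord <- order(lam_nt^2, decreasing = TRUE)
  lam_nt <- lam_nt[ord]
  psi_nt <- psi_nt[, ord, drop = FALSE]
  # normalize sign-free scale: psi columns such that psi_0 = 1
  psi_nt <- psi_nt / psi[1, trivial]
  scale_fac <- if (diffusion_time == 0) lam_nt / (1 - lam_nt)
               else lam_nt^diffusion_time
  comps <- sweep(psi_nt[, seq_len(n_components), drop = FALSE], 2,
                 scale_fac[seq_len(n_components)], `*`)
  ev <- lam_nt^2 / sum(lam_nt^2)
  rownames(comps) <- rownames(A)
  structure(list(components = comps,
                 eigenvalues = lam_nt[seq_len(n_components)],
                 explained_variance = ev[seq_len(n_components)],
                 reference_aligned = FALSE),
            class = "gradient_set")
}

# breadth-first connectivity check on the nonzero pattern
affinity_connected <- function(A) {
  n <- nrow(A)
  seen <- logical(n)
  stack <- 1L
  seen[1L] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    nb <- which(A[v, ] > 0 & !seen)
    seen[nb] <- TRUE
    stack <- c(stack, nb)
  }
  all(seen)
}

#' Convenience chain: connectivity matrix to gradient set
#'
#' Threshold, normalized-angle affinity, diffusion embedding in one call.
#'
#' @inheritParams threshold_rows
#' @inheritParams diffusion_embed
#' @param reference optional gradient set or matrix; if given, the result is
#'   Procrustes-aligned to it.
#' @return a `gradient_set`.
#' @export
connectivity_gradients <- function(C, n_components = 4, density = 0.10,
                                   alpha = 0.5, diffusion_time = 0,
                                   reference = NULL) {
  G <- diffusion_embed(normalized_angle(threshold_rows(C, density)),
                       n_components, alpha, diffusion_time)
  if (!is.null(reference)) G <- procrustes_align(G, reference)
  G
}

as_component_matrix <- function(x) {
  if (inherits(x, "gradient_set")) x$components else as.matrix(x)
}

#' Procrustes alignment of a gradient set to a reference
#'
#' Finds the orthogonal rotation/reflection (no scaling) minimizing the
#' Frobenius distance to the reference and applies it to the components.
#' Explained variance is carried over unchanged.
#'
#' @param G a `gradient_set` (or plain component matrix).
#' @param ref reference `gradient_set` or matrix with matching dimensions.
#' @return aligned `gradient_set` with `reference_aligned = TRUE` and the
#'   rotation stored as attribute `rotation`.
#' @export
procrustes_align <- function(G, ref) {
  X <- as_component_matrix(G)
  R <- as_component_matrix(ref)
  K <- min(ncol(X), ncol(R))
  X <- X[, seq_len(K), drop = FALSE]
  R <- R[, seq_len(K), drop = FALSE]
  if (!all(dim(X) == dim(R))) stop("shape mismatch between G and reference")
  sv <- svd(crossprod(X, R))
  Q <- sv$u %*% t(sv$v)
  aligned <- X %*% Q
  if (inherits(G, "gradient_set")) {
    out <- G
    out$components <- aligned
    out$eigenvalues <- G$eigenvalues[seq_len(K)]
    out$explained_variance <- G$explained_variance[seq_len(K)]
    out$reference_aligned <- TRUE
    attr(out, "rotation") <- Q
    out
  } else {
    structure(aligned, rotation = Q)
  }
}

#' Fingerprint similarity between two gradient sets
#'
#' Entry (i, j) is the absolute Pearson correlation between component i of
#' `Ga` and component j of `Gb`. The order-match score is the mean diagonal
#' minus the mean off-diagonal: near 1 when the two sets express the same
#' gradients in the same order, negative when the ordering is permuted.
#'
#' @param Ga,Gb gradient sets (or component matrices) on the same regions.
#' @param k number of leading components to compare.
#' @return list with `matrix` (k x k absolute correlations) and `score`.
#' @export
fingerprint_similarity <- function(Ga, Gb, k = 2) {
  A <- as_component_matrix(Ga)[, seq_len(k), drop = FALSE]
  B <- as_component_matrix(Gb)[, seq_len(k), drop = FALSE]
  M <- abs(cor(A, B))
  off <- M; diag(off) <- NA
  score <- mean(diag(M)) - mean(off, na.rm = TRUE)
  list(matrix = M, score = score)
}

#' Mean absolute gradient strength
#'
#' Mean over regions of the absolute value of component `k`; used as a
#' scalar summary of how strongly a gradient separates the cortex.
#'
#' @param G gradient set or component matrix.
#' @param k component index.
#' @return scalar.
#' @export
mean_absolute_strength <- function(G, k = 1) {
  X <- as_component_matrix(G)
  if (k > ncol(X)) stop("k exceeds the number of components")
  mean(abs(X[, k]))
}
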