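#' Predictor similarity matrices and receptor principal components
#'
#' The two predictors of the connectivity model: structural-connectivity
#' similarity (Pearson correlation of log-transformed directed tracing
#' profiles) and neuromodulatory similarity (Pearson correlation of receptor
#' expression profiles between regions), plus a PCA of receptor maps.
#'
#' @name similarity
NULL

#' Structural-connectivity similarity from a directed tracing matrix
#'
#' Weights are log-transformed (`log(w + epsilon)`) and the similarity
#' between two source regions is the Pearson correlation of their target
#' profiles (matrix rows). The directed sources x targets matrix therefore
#' yields a symmetric sources x sources similarity with unit diagonal.
#'
#' @param M sources x targets positive weight matrix.
#' @param epsilon offset added before the log (handles zero weights).
#' @return symmetric similarity matrix (role: SC), attribute `low_confidence`
#'   flags sources whose profile is entirely at the offset floor.
#' @export
tracing_similarity <- function(M, epsilon = 1) {
  M <- as.matrix(M)
  if (nrow(M) < 3 || ncol(M) < 3) stop("need >= 3 sources and >= 3 targets")
  L <- log(M + epsilon)
  flat <- apply(L, 1, function(x) max(x) - min(x) == 0)
  if (any(flat)) {
    warning("all-floor tracing profile for ", sum(flat),
            " source region(s); similarity flagged low-confidence")
    L[flat, ] <- L[flat, ] + rnorm(sum(flat) * ncol(L), sd = 1e-12)
  }
  S <- cor(t(L))
  diag(S) <- 1
  attr(S, "low_confidence") <- which(flat)
  S
}

#' Neuromodulatory similarity from a receptor expression matrix
#'
#' Similarity between regions i and j is the Pearson correlation of their
#' expression profiles over the selected receptors. One receptor's map can
#' be substituted by a surrogate (the reduced-model shuffle for a single
#' receptor).
#'
#' @param E receptors x regions expression matrix.
#' @param receptor_subset receptor names/indices to use (default all).
#' @param replace named list mapping one or more receptor names to
#'   replacement maps of length N.
#' @return symmetric N x N similarity matrix (role: NS).
#' @export
expression_similarity <- function(E, receptor_subset = NULL, replace = NULL) {
  E <- as.matrix(E)
  if (!is.null(receptor_subset)) E <- E[receptor_subset, , drop = FALSE]
  if (!is.null(replace)) {
    for (nm in names(replace)) {
      if (!(nm %in% rownames(E))) stop("receptor absent: ", nm)
      E[nm, ] <- replace[[nm]]
    }
  }
  if (nrow(E) < 3) stop("need at least 3 receptors")
  const <- apply(E, 1, function(x) sd(x) == 0)
  if (any(const)) {
    warning("excluding constant receptor row(s): ",
            paste(rownames(E)[const], collapse = ", "))
    E <- E[!const, , drop = FALSE]
  }
  S <- cor(E)
  diag(S) <- 1
  S
}

#' Principal components of receptor expression maps
#'
#' Receptor maps are z-scored across regions and PCA is applied with
#' receptors as observations and regions as variables; PC maps live on
#' regions and each receptor gets a signed coefficient per component. The
#' decomposition is uncentered (the maps are already standardized), so a
#' shared map replicated across receptors loads entirely on the first
#' component.
#'
#' @param E receptors x regions expression matrix.
#' @param n_pc number of components.
#' @return list with `maps` (regions x n_pc), `coefficients`
#'   (receptors x n_pc) and `variance_explained` (fractions).
#' @export
receptor_pca <- function(E, n_pc = 3) {
  E <- as.matrix(E)
  if (nrow(E) < n_pc) stop("need at least n_pc receptors")
  Z <- t(scale(t(E)))                    # z-score each receptor map
  p <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  ve <- p$sdev^2 / sum(p$sdev^2)
  k <- seq_len(min(n_pc, ncol(p$rotation)))
  list(maps = p$rotation[, k, drop = FALSE],
       coefficients = p$x[, k, drop = FALSE],
       variance_explained = ve[k])
}
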