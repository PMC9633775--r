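#' @useDynLib gradflow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor median quantile rnorm runif sd var lm coef confint
#'   pt p.adjust dist optim arima.sim setNames complete.cases approx
#' @importFrom utils head tail write.table read.table modifyList
NULL

# Evaluate `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. All stochastic operations in the package go
# through this so that a seed argument is reproducible without clobbering the
# user's global seed.
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Derive a per-stage child seed from a global seed; keeps values < 2^31.
child_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

#' Flatten the upper triangle of a symmetric matrix
#'
#' Region-pair quantities (functional connectivity, structural and
#' neuromodulatory similarity) enter the regression model as vectors over
#' unordered region pairs. The upper triangle (i < j) is flattened in
#' row-major order, i.e. (1,2), (1,3), ..., (1,N), (2,3), ...
#'
#' @param S symmetric numeric matrix.
#' @return numeric vector of length N(N-1)/2.
#' @seealso [unvectorize_pairs()] for the inverse.
#' @export
vectorize_pairs <- function(S) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S) || max(abs(S - t(S))) > 1e-8) {
    stop("vectorize_pairs() requires a symmetric matrix")
  }
  t(S)[lower.tri(S)]  # row-major upper triangle
}

#' Restore a symmetric matrix from its flattened upper triangle
#'
#' @param v vector produced by [vectorize_pairs()].
#' @param diag value to place on the diagonal (default 1).
#' @return symmetric N x N matrix.
#' @export
unvectorize_pairs <- function(v, diag = 1) {
  n <- (1 + sqrt(1 + 8 * length(v))) / 2
  if (abs(n - round(n)) > 1e-8) stop("length is not N(N-1)/2 for integer N")
  n <- round(n)
  S <- matrix(0, n, n)
  S[lower.tri(S)] <- v
  S <- S + t(S)
  diag(S) <- diag
  S
}

# Project a symmetric matrix to the nearest correlation matrix (Higham
# alternating projections via Matrix::nearPD). Cheap no-op when the input is
# already a valid correlation matrix.
nearest_correlation <- function(S, tol = 1e-8) {
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) >= -tol && max(abs(diag(S) - 1)) < tol) {
    diag(S) <- 1
    return(S)
  }
  out <- Matrix::nearPD(S, corr = TRUE, conv.tol = tol, maxit = 200)
  as.matrix(out$mat)
}

# Euclidean distance matrix from N x d coordinates.
coord_dist <- function(coords) {
  as.matrix(dist(coords))
}

write_tsv <- function(x, path, row_names = FALSE) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = row_names,
              col.names = if (row_names) NA else TRUE)
}

read_tsv <- function(path, row_names = FALSE) {
  if (row_names) {
    read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
               row.names = 1)
  } else {
    read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  }
}
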