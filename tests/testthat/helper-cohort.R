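# Shared small synthetic cohort, built once per test run. 40 regions keeps
# the embedding and DCC fast while leaving room for spatial structure.
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_cohort(n_scans = 2, n_frames = 512, seed = 424242,
                            n_regions = 40, n_targets = 25,
                            n_receptors = 10, n_null = 2)
    }
    cache
  }
})

# random symmetric connected affinity matrix in [0, 1]
random_affinity <- function(n) {
  A <- matrix(runif(n * n, 0.05, 1), n, n)
  A <- (A + t(A)) / 2
  diag(A) <- 1
  A
}

# random orthogonal matrix via QR
random_orthogonal <- function(k) {
  qr.Q(qr(matrix(rnorm(k * k), k, k)))
}

expect_symmetric_unit_diag <- function(S, tol = 1e-10) {
  expect_lt(max(abs(S - t(S))), tol)
  expect_lt(max(abs(diag(S) - 1)), tol)
}
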