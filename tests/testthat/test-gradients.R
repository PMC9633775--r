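test_that("functional connectivity is a valid Pearson matrix", {
  ts <- matrix(rnorm(200), 50, 4)
  C <- compute_fc(ts)
  expect_symmetric_unit_diag(C)

  x <- 1:20
  expect_equal(compute_fc(cbind(a = x, b = x, c = rnorm(20)))["a", "b"], 1)
  expect_equal(compute_fc(cbind(a = x, b = -x, c = rnorm(20)))["a", "b"], -1)

  # hand-evaluated Pearson formula
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(compute_fc(cbind(x = x, y = y))["x", "y"], r_oracle)

  bad <- cbind(R1 = rnorm(10), R2 = rep(1, 10))
  expect_error(compute_fc(bad), "R2")
})

test_that("row thresholding keeps the stated number of connections", {
  C <- random_affinity(11)
  Th <- threshold_rows(C, 0.10)
  expect_true(all(rowSums(Th != 0) == 1))  # ceiling(0.1 * 10) = 1
  expect_true(all(diag(Th) == 0))

  Th1 <- threshold_rows(C, 1)
  off <- C; diag(off) <- 0
  expect_equal(Th1, off)

  # deterministic tie-break: lower column index wins
  C4 <- rbind(c(1, 0.9, 0.5, 0.5),
              c(0.9, 1, 0.5, 0.1),
              c(0.5, 0.5, 1, 0.9),
              c(0.5, 0.1, 0.9, 1))
  Th2 <- threshold_rows(C4, 2 / 3)       # budget ceiling(2/3*3) = 2 per row
  expect_equal(which(Th2[1, ] != 0), c(2L, 3L))
})

test_that("normalized angle maps cosine to [0, 1] affinities", {
  M <- rbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0))
  A <- normalized_angle(M)
  expect_equal(A[1, 2], 1)
  expect_equal(A[1, 3], 0.5)
  expect_equal(A[1, 4], 0)
  expect_error(normalized_angle(rbind(c(1, 1), c(0, 0))), "isolated")
})

test_that("diffusion embedding matches a dense eigendecomposition oracle", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      n <- sample(6:16, 1)
      A <- random_affinity(n)
      G <- diffusion_embed(A, n_components = n - 1, alpha = 0.5)

      # independent oracle: build P explicitly, nonsymmetric eigen,
      # drop the stationary eigenvalue, order by explained variance
      d <- rowSums(A)
      W <- A / outer(d^0.5, d^0.5)
      P <- W / rowSums(W)
      e <- eigen(P)
      lam_all <- Re(e$values)
      vec_all <- Re(e$vectors)
      trivial <- which.max(lam_all)
      lam <- lam_all[-trivial]
      vec <- vec_all[, -trivial, drop = FALSE]
      ord <- order(lam^2, decreasing = TRUE)
      lam <- lam[ord]
      vec <- vec[, ord, drop = FALSE]
      expect_equal(G$eigenvalues, lam, tolerance = 1e-8)
      for (k in seq_len(n - 1)) {
        g <- G$components[, k] / sqrt(sum(G$components[, k]^2))
        o <- vec[, k] / sqrt(sum(vec[, k]^2))
        expect_lt(min(max(abs(g - o)), max(abs(g + o))), 1e-8)
      }
    }
  })
})

test_that("two-block affinity yields a block-separating first gradient", {
  A <- matrix(0.02, 12, 12)
  A[1:6, 1:6] <- 1
  A[7:12, 7:12] <- 1
  g1 <- diffusion_embed(A, 2)$components[, 1]
  expect_true(all(sign(g1[1:6]) == sign(g1[1])))
  expect_true(all(sign(g1[7:12]) == -sign(g1[1])))
})

test_that("explained variance behaves like a probability vector", {
  withr::with_seed(22, {
    A <- random_affinity(15)
    G <- diffusion_embed(A, 14)
    expect_true(all(diff(G$explained_variance) <= 1e-12))
    expect_lte(sum(G$explained_variance), 1 + 1e-12)
    expect_true(all(G$explained_variance >= 0))
  })
})

test_that("disconnected affinity graphs are rejected", {
  A <- diag(4)
  A[1, 2] <- A[2, 1] <- 1
  A[3, 4] <- A[4, 3] <- 1
  expect_error(diffusion_embed(A, 2), "disconnected")
})

test_that("Procrustes alignment recovers rotations and reflections", {
  withr::with_seed(23, {
    ref <- matrix(rnorm(80), 40, 2)
    same <- procrustes_align(ref, ref)
    expect_lt(max(abs(same - ref)), 1e-10)

    flipped <- ref %*% diag(c(1, -1))
    back <- procrustes_align(flipped, ref)
    expect_lt(max(abs(back - ref)), 1e-10)

    Q <- random_orthogonal(2)
    rot <- procrustes_align(ref %*% Q, ref)
    expect_lt(max(abs(rot - ref)), 1e-8)

    # independent cross-check against vegan's Procrustes (no scaling);
    # vegan always translates, so compare on column-centred configurations
    refc <- scale(ref, scale = FALSE)
    G <- refc %*% Q + 0.01 * scale(matrix(rnorm(80), 40, 2), scale = FALSE)
    ours <- procrustes_align(G, refc)
    vg <- vegan::procrustes(refc, G, scale = FALSE)
    expect_lt(max(abs(ours - vg$Yrot)), 1e-6)
  })
})

test_that("fingerprinting scores gradient order correspondence", {
  withr::with_seed(24, {
    G <- matrix(rnorm(400), 200, 2)
    self <- fingerprint_similarity(G, G, 2)
    expect_equal(diag(self$matrix), c(1, 1))
    expect_equal(self$score, 1 - mean(self$matrix[row(self$matrix) !=
                                                    col(self$matrix)]))

    swapped <- fingerprint_similarity(G, G[, 2:1], 2)
    expect_lt(swapped$score, 0)

    # sign-flip invariance
    flip <- fingerprint_similarity(G, G %*% diag(c(-1, 1)), 2)
    expect_equal(flip$score, self$score)

    # independent noise: score near zero
    scores <- replicate(20, {
      fingerprint_similarity(matrix(rnorm(400), 200, 2),
                             matrix(rnorm(400), 200, 2), 2)$score
    })
    expect_lt(abs(mean(scores)), 0.05)
  })
})

test_that("mean absolute strength summarizes one component", {
  G <- cbind(rep(0.3, 10), rep(c(-1, 1), 5))
  expect_equal(mean_absolute_strength(G, 1), 0.3)
  expect_equal(mean_absolute_strength(G, 2), 1)
  v <- rnorm(10)
  expect_equal(mean_absolute_strength(cbind(v), 1), mean(abs(v)))
  expect_error(mean_absolute_strength(G, 3), "exceeds")
})
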