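test_that("bin means average member frames exactly", {
  withr::with_seed(51, {
    M1 <- cov2cor(crossprod(matrix(rnorm(100), 20, 5)) + diag(5))
    M2 <- cov2cor(crossprod(matrix(rnorm(100), 20, 5)) + diag(5))

    dfc <- array(M1, c(5, 5, 6))
    out <- binned_mean_dfc(dfc, rep(1:2, each = 3))
    expect_equal(out[[1]], M1, ignore_attr = TRUE)
    expect_equal(out[[2]], M1, ignore_attr = TRUE)

    dfc2 <- array(0, c(5, 5, 6))
    assign <- rep(1:2, 3)
    for (t in 1:6) dfc2[, , t] <- if (assign[t] == 1) M1 else M2
    out2 <- binned_mean_dfc(dfc2, assign)
    expect_equal(out2[[1]], M1, ignore_attr = TRUE)
    expect_equal(out2[[2]], M2, ignore_attr = TRUE)

    # brute-force average with dropped frames
    dfc3 <- array(rnorm(5 * 5 * 8), c(5, 5, 8))
    for (t in 1:8) {
      dfc3[, , t] <- cov2cor(crossprod(matrix(rnorm(150), 30, 5)))
    }
    assign3 <- c(1, 2, 1, 2, NA, 1, 2, NA)
    out3 <- binned_mean_dfc(dfc3, assign3)
    oracle <- (dfc3[, , 1] + dfc3[, , 3] + dfc3[, , 6]) / 3
    expect_equal(out3[[1]], oracle, tolerance = 1e-8, ignore_attr = TRUE)
    expect_error(binned_mean_dfc(dfc3, c(1, 1, 3, 3, 3, NA, 1, 3)), "empty")
  })
})

test_that("dynamic gradients align consistently to a reference", {
  withr::with_seed(52, {
    C <- compute_fc(matrix(rnorm(400 * 20), 400, 20))
    ref <- connectivity_gradients(C, 3)
    dyn <- dynamic_gradients(list(C, C, C), ref, n_components = 3)
    for (g in dyn) {
      expect_lt(max(abs(g$components - ref$components)), 1e-8)
      expect_equal(g$explained_variance, ref$explained_variance)
    }
  })
})

test_that("gradient flow measures linear centroid drift", {
  labels <- rep(c("A", "B"), each = 5)
  base <- cbind(rnorm(10), rnorm(10))
  # translate network A by (0.2, 0) per bin step
  bins <- lapply(0:3, function(b) {
    g <- base
    g[1:5, 1] <- g[1:5, 1] + 0.2 * b
    g
  })
  fl <- gradient_flow(bins, labels)
  expect_equal(unname(fl$displacement["A", ]), c(0.2, 0), tolerance = 1e-10)
  expect_equal(unname(fl$magnitude["A"]), 0.2, tolerance = 1e-10)
  expect_equal(unname(fl$magnitude["B"]), 0, tolerance = 1e-10)

  fl0 <- gradient_flow(list(base, base, base), labels)
  expect_true(all(fl0$magnitude < 1e-12))
})

test_that("scan-shuffled flow null is calibrated and guards its inputs", {
  withr::with_seed(53, {
    n <- 16
    mk_dfc <- function() {
      arr <- array(0, c(n, n, 60))
      for (t in 1:60) {
        arr[, , t] <- cov2cor(crossprod(matrix(rnorm(3 * n * n), 3 * n, n)) +
                                diag(n))
      }
      arr
    }
    dfc <- list(mk_dfc(), mk_dfc(), mk_dfc())
    ar <- lapply(1:3, function(i) runif(60))
    labels <- rep(c("X", "Y"), each = n / 2)
    ref <- connectivity_gradients(apply(dfc[[1]], c(1, 2), mean), 2)

    expect_error(flow_null(dfc, ar, labels, ref, n_bins = 4, n_perm = 0),
                 "positive")
    expect_warning(
      fn <- flow_null(dfc, ar, labels, ref, n_bins = 4, n_perm = 19,
                      seed = 5),
      "coarse")
    expect_true(all(fn$p > 0 & fn$p <= 1))

    # arousal unrelated to the frames: p should not concentrate near 0
    ps <- replicate(15, {
      arp <- lapply(1:3, function(i) runif(60))
      suppressWarnings(flow_null(dfc, arp, labels, ref, n_bins = 4,
                                 n_perm = 19, seed = NULL)$p[1])
    })
    expect_gt(mean(ps > 0.05), 0.7)
    expect_gt(mean(ps), 0.3)
  })
})

test_that("connectivity entropy matches a direct histogram computation", {
  C1 <- matrix(0.42, 10, 10); diag(C1) <- 1
  expect_equal(fc_entropy(C1), 0)

  # 129 regions give 8256 = 64 * 129 pairs: fill bins uniformly
  n <- 129
  vals <- rep(seq(-1 + 1 / 64, 1 - 1 / 64, length.out = 64), 129)
  Cu <- unvectorize_pairs(vals)
  expect_equal(fc_entropy(Cu, 64), 6)

  withr::with_seed(54, {
    C <- cov2cor(crossprod(matrix(rnorm(900), 30, 30)))
    v <- C[upper.tri(C)]
    counts <- table(cut(v, seq(-1, 1, length.out = 65), include.lowest = TRUE))
    p <- counts[counts > 0] / sum(counts)
    expect_equal(fc_entropy(C, 64), -sum(p * log2(p)))
  })
})

test_that("quadratic trend fits classify U and inverted-U shapes", {
  x <- seq(0, 1, length.out = 10)
  down <- quadratic_trend(x, -(x - 0.5)^2)
  expect_equal(unname(down$coefficients["c2"]), -1, tolerance = 1e-8)
  expect_equal(down$shape, "inverted_u")

  up <- quadratic_trend(x, (x - 0.5)^2)
  expect_equal(unname(up$coefficients["c2"]), 1, tolerance = 1e-8)
  expect_equal(up$shape, "u")

  withr::with_seed(55, {
    lin <- quadratic_trend(x, 2 * x + rnorm(10, sd = 0.01))
    expect_equal(lin$shape, "monotone")
    flat <- quadratic_trend(x, rnorm(10, sd = 0.01))
    expect_true(flat$shape %in% c("flat", "monotone"))
  })
  expect_error(quadratic_trend(1:3, 1:3), "4")
})
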