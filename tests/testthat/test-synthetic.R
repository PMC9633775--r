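test_that("spatial maps are orthonormal and seeded deterministically", {
  sm <- make_spatial_maps(50, 2, smoothness = 0.3, seed = 1)
  G <- crossprod(sm$maps)
  expect_lt(max(abs(G - diag(2))), 1e-10)
  sm2 <- make_spatial_maps(50, 2, smoothness = 0.3, seed = 1)
  expect_identical(sm$maps, sm2$maps)
  expect_error(make_spatial_maps(10, 10, 0.3), "rank")
})

test_that("map smoothness controls spatial autocorrelation", {
  # near-zero smoothness: value at a region is unrelated to its neighbour
  sm0 <- make_spatial_maps(300, 1, smoothness = 1e-3, seed = 7)
  D <- as.matrix(dist(sm0$coords)); diag(D) <- Inf
  nn <- apply(D, 1, which.min)
  expect_lt(abs(cor(sm0$maps[, 1], sm0$maps[nn, 1])), 0.2)

  # smooth map: brute-force variogram increases with distance
  sm <- make_spatial_maps(200, 1, smoothness = 0.3, seed = 8)
  m <- sm$maps[, 1]
  D <- as.matrix(dist(sm$coords))
  iu <- which(upper.tri(D))
  sq <- 0.5 * (m[row(D)[iu]] - m[col(D)[iu]])^2      # brute-force semivariance
  qs <- quantile(D[iu], seq(0, 1, length.out = 7))
  bin <- findInterval(D[iu], qs, rightmost.closed = TRUE, all.inside = TRUE)
  gamma <- tapply(sq, bin, mean)
  expect_true(all(diff(gamma[1:4]) > 0))  # rising limb of the variogram
  expect_gt(gamma[6], gamma[1])
})

test_that("arousal process respects persistence and range", {
  a0 <- make_arousal_process(4000, persistence = 0, seed = 3)
  expect_lt(abs(cor(a0[-1], a0[-4000])), 0.05)
  expect_true(all(a0 >= 0 & a0 <= 1))

  # Monte-Carlo oracle for the lag-1 autocorrelation of the transformed AR(1)
  oracle <- withr::with_seed(99, {
    mean(replicate(12, {
      z <- as.numeric(arima.sim(list(ar = 0.95), 5000, sd = sqrt(1 - 0.95^2)))
      a <- plogis(1.5 * z)
      cor(a[-1], a[-5000])
    }))
  })
  a <- make_arousal_process(5000, persistence = 0.95, seed = 11)
  expect_lt(abs(cor(a[-1], a[-5000]) - oracle), 0.05)
})

test_that("time series reproduce the static correlation at large n", {
  truth <- make_ground_truth(n_regions = 30, n_targets = 20,
                             weights = c(b0 = 0.3, b1 = 0.55, b2 = 0),
                             n_receptors = 10, n_null = 2, seed = 5)
  ts <- make_timeseries(truth, arousal = rep(0.5, 20000), sigma_obs = 0,
                        seed = 6)
  target <- (0.3 * diag(30) + 0.55 * truth$sc_sim) / 0.85
  err <- norm(cor(ts) - target, "F") / norm(target, "F")
  expect_lt(err, 0.05)
  # constant arousal: amplitude term vanishes, columns centred
  expect_lt(max(abs(colMeans(ts))), 0.05)
})

test_that("time series are bit-reproducible under a seed", {
  truth <- small_cohort()$truth
  a <- make_arousal_process(50, seed = 1)
  x1 <- make_timeseries(truth, a, seed = 2)
  x2 <- make_timeseries(truth, a, seed = 2)
  x3 <- make_timeseries(truth, a, seed = 3)
  expect_identical(unclass(x1), unclass(x2))
  expect_false(identical(unclass(x1), unclass(x3)))
})

test_that("generated correlation structure is positive semidefinite", {
  truth <- small_cohort()$truth
  expect_gte(min(eigen(truth$population_fc, symmetric = TRUE,
                       only.values = TRUE)$values), -1e-10)
  for (a in c(0.05, 0.5, 0.95)) {
    wm <- 4 * truth$weights[["b2"]] * (a - 0.5)^2
    C <- (truth$weights[["b0"]] * diag(nrow(truth$sc_sim)) +
            truth$weights[["b1"]] * truth$sc_sim + wm * truth$ns_sim) /
      (truth$weights[["b0"]] + truth$weights[["b1"]] + wm)
    expect_gte(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
})

test_that("pupil trace summarizes arousal per frame bin", {
  a <- c(0.2, 0.4, 0.6, 0.8)
  p <- make_pupil(a, tr = 2, fps = 6, noise_sd = 0, blink_rate = 0, seed = 1)
  expect_equal(length(p), 4 * 12)
  med <- apply(matrix(p, nrow = 12), 2, median)
  expect_equal(med, a)

  p7 <- make_pupil(rep(0.7, 50), tr = 2, fps = 6, noise_sd = 0.02,
                   blink_rate = 0, seed = 2)
  med7 <- apply(matrix(p7, nrow = 12), 2, median)
  expect_lt(max(abs(med7 - 0.7)), 0.1)
})

test_that("blink gaps appear at roughly the requested rate", {
  a <- make_arousal_process(500, seed = 4)
  p <- make_pupil(a, tr = 2, fps = 6, noise_sd = 0, blink_rate = 0.2,
                  seed = 5)
  dur <- length(p) / 6
  mean_gap <- mean(1:3)                  # uniform on 1..floor(0.5*fps)
  expected <- 0.2 * dur * mean_gap / length(p)
  observed <- mean(is.na(p))             # counting oracle
  expect_lt(abs(observed - expected) / expected, 0.5)
  expect_gt(observed, 0)
})

test_that("tracing matrix is positive, asymmetric and distance-decaying", {
  sm <- make_spatial_maps(60, 2, seed = 9)
  W <- make_tracing(60, 40, sm$coords, decay = 1, seed = 10)
  expect_equal(dim(W), c(60, 40))
  expect_true(all(W > 0))
  expect_false(isTRUE(all.equal(W[1:40, 1:40], t(W[1:40, 1:40]))))

  D <- as.matrix(dist(sm$coords))[, 1:40]
  cors <- withr::with_seed(11, {
    vapply(c(0, 0.5, 2), function(dec) {
      mean(replicate(25, {
        Wd <- make_tracing(60, 40, sm$coords, decay = dec)
        cor(as.numeric(log(Wd)), as.numeric(D))
      }))
    }, numeric(1))
  })
  expect_lt(abs(cors[1]), 0.05)          # no decay, no distance structure
  expect_true(all(diff(cors) < 0))       # stronger decay, more negative
})

test_that("expression matrix carries the planted loadings", {
  truth <- small_cohort()$truth
  L <- rbind(c(1, 0), c(0, 1), c(1, 1) / sqrt(2))
  E0 <- make_expression(truth, 3, 0, noise_sd = 1e-12, seed = 12,
                        loadings = L)
  expect_gt(cor(E0[1, ], truth$gradient_maps[, 1]), 0.999999)
  r <- abs(cor(E0[3, ], truth$gradient_maps))
  expect_lt(abs(r[1] - r[2]), 1e-6)      # symmetric loading, equal correlation

  # null receptors: map-independent in the overwhelming majority of draws
  truth200 <- make_ground_truth(n_regions = 200, n_targets = 50,
                                n_receptors = 8, n_null = 2, seed = 13)
  E <- make_expression(truth200, 50, 50, seed = 14)
  rn <- abs(cor(t(E), truth200$gradient_maps))
  expect_gte(mean(rn < 0.2), 0.95)
})

test_that("cohorts are internally consistent and writable", {
  ch <- small_cohort()
  expect_length(ch$scans, 2)
  expect_true(all(vapply(ch$scans, nrow, 1L) == 512))
  expect_true(all(vapply(ch$pupil, length, 1L) == 512 * 12))
  expect_equal(attr(ch$scans[[1]], "tr"), 2)

  dir <- withr::local_tempdir()
  write_cohort(ch, dir)
  back <- read_cohort(dir)
  expect_equal(back$tr, ch$tr)
  expect_equal(dim(back$scans[[1]]), dim(unclass(ch$scans[[1]])))
  expect_equal(back$tracing, ch$tracing, tolerance = 1e-6,
               ignore_attr = TRUE)
})
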