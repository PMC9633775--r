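test_that("pair vectorization round-trips and counts pairs", {
  S <- matrix(c(1, .2, .3, .2, 1, .4, .3, .4, 1), 3)
  v <- vectorize_pairs(S)
  expect_equal(v, c(.2, .3, .4))         # row-major upper triangle
  expect_identical(unvectorize_pairs(v), S)
  expect_length(vectorize_pairs(diag(116)), 6670)
  expect_error(vectorize_pairs(matrix(1:9, 3)), "symmetric")
})

test_that("the pairwise model matches a normal-equations oracle", {
  withr::with_seed(71, {
    n <- 20
    sc <- cov2cor(crossprod(matrix(rnorm(n * n), n, n)) + diag(n))
    ns0 <- cov2cor(crossprod(matrix(rnorm(n * n), n, n)) + diag(n))
    # orthogonalize NS pair-values against SC pair-values
    vsc <- vectorize_pairs(sc)
    vns <- residuals(lm(vectorize_pairs(ns0) ~ vsc))

    fit <- fit_glm(2 * vsc, list(SC = vsc, NS = vns))
    expect_equal(unname(fit$coefficients), c(0, 2, 0), tolerance = 1e-6)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)

    cfit <- fit_glm(rep(3.2, length(vsc)), list(SC = vsc, NS = vns))
    expect_equal(unname(cfit$coefficients[1]), 3.2, tolerance = 1e-8)
    expect_lt(max(abs(cfit$coefficients[2:3])), 1e-8)

    # random instance vs explicit ridge normal equations
    y <- rnorm(length(vsc))
    ridge <- 1e-4
    fit2 <- fit_glm(y, list(SC = vsc, NS = vns), ridge = ridge)
    X <- cbind(1, vsc, vns)
    lambda <- ridge * sum(X[, -1]^2) / 2
    beta_oracle <- solve(crossprod(X) + lambda * diag(c(0, 1, 1)),
                         crossprod(X, y))
    expect_equal(unname(fit2$coefficients), unname(drop(beta_oracle)),
                 tolerance = 1e-8)

    expect_error(fit_glm(y, list(SC = vsc, NS = vsc), ridge = 0),
                 "collinear")
  })
})

test_that("leave-one-scan-out cvR2 behaves at the extremes", {
  withr::with_seed(72, {
    n <- 20
    sc <- cov2cor(crossprod(matrix(rnorm(n * n), n, n)) + diag(n))
    vsc <- vectorize_pairs(sc)
    fcs <- replicate(4, 1 + 2 * vsc, simplify = FALSE)
    cv <- loo_cv(fcs, list(SC = sc))
    expect_equal(cv$cv_r2, rep(1, 4), tolerance = 1e-9)

    # connectivity unrelated to the predictor
    fcs0 <- replicate(4, rnorm(length(vsc)), simplify = FALSE)
    cv0 <- loo_cv(fcs0, list(SC = sc))
    expect_lt(cv0$mean, 0.05)

    expect_error(loo_cv(fcs[1], list(SC = sc)), "2 scans")
  })
})

test_that("single-variable models bound the shared contribution", {
  withr::with_seed(73, {
    n_pairs <- 300
    shared <- rnorm(n_pairs)
    sc <- shared + 0.4 * rnorm(n_pairs)
    ns <- shared + 0.4 * rnorm(n_pairs)
    fcs <- replicate(4, shared + 0.3 * rnorm(n_pairs), simplify = FALSE)
    full <- loo_cv(fcs, list(SC = sc, NS = ns))$mean
    s_sc <- single_variable(fcs, sc, "SC")$mean
    s_ns <- single_variable(fcs, ns, "NS")$mean
    # heavily overlapping predictors: single-variable sum exceeds the full
    expect_gt(s_sc + s_ns, full)
    expect_gt(single_variable(fcs, fcs[[1]], "self")$mean, 0.8)
  })
})

test_that("reduced-model deltaR2 isolates unique contributions", {
  withr::with_seed(74, {
    n <- 24
    sc <- cov2cor(crossprod(matrix(rnorm(n * n), n, n)) + diag(n))
    ns <- cov2cor(crossprod(matrix(rnorm(n * n), n, n)) + diag(n))
    vsc <- vectorize_pairs(sc)
    fcs <- replicate(4, 2 * vsc + 0.2 * rnorm(length(vsc)),
                     simplify = FALSE)

    d_ns <- reduced_delta(fcs, list(SC = sc, NS = ns), "NS",
                          n_shuffles = 100, seed = 1)
    d_sc <- reduced_delta(fcs, list(SC = sc, NS = ns), "SC",
                          n_shuffles = 100, seed = 2)
    expect_lt(abs(d_ns$delta_r2), 0.01)  # NS is truly null
    expect_gt(d_sc$delta_r2, 0.3)

    # perfect overlap: both unique contributions vanish
    d_same <- reduced_delta(fcs, list(SC = sc, NS = sc), "SC",
                            n_shuffles = 50, seed = 3)
    expect_lt(abs(d_same$delta_r2), 0.05)

    # lower bound does not exceed the single-variable upper bound
    s_sc <- single_variable(fcs, sc, "SC")$mean
    expect_lte(d_sc$delta_r2, s_sc + 0.02)
    expect_error(reduced_delta(fcs, list(SC = sc), "NS", 100), "target_var")
    expect_error(reduced_delta(fcs, list(SC = sc), "SC", 1), "n_shuffles")
  })
})

test_that("frame-wise fits recover per-frame coefficients", {
  withr::with_seed(75, {
    n <- 15
    sc <- cov2cor(crossprod(matrix(rnorm(n * n), n, n)) + diag(n))
    ns <- cov2cor(crossprod(matrix(rnorm(n * n), n, n)) + diag(n))
    vsc <- vectorize_pairs(sc); vns <- vectorize_pairs(ns)
    T_ <- 80
    w <- (seq_len(T_) / T_ - 0.5)^2 * 4  # planted U-shaped NS weight
    Y <- t(sapply(seq_len(T_), function(t) {
      0.1 + 2 * vsc + w[t] * vns + 0.05 * rnorm(length(vsc))
    }))
    fw <- framewise_glm(Y, list(SC = sc, NS = ns))
    expect_equal(dim(fw$coefficients), c(T_, 3))
    expect_lt(max(abs(fw$coefficients[, "SC"] - 2)), 0.2)
    expect_gt(cor(fw$coefficients[, "NS"], w), 0.8)

    # constant frames are flagged with zero slopes
    Y2 <- rbind(Y, rep(0.7, ncol(Y)))
    fw2 <- framewise_glm(Y2, list(SC = sc, NS = ns))
    expect_true(fw2$flagged[T_ + 1])
    expect_equal(unname(fw2$coefficients[T_ + 1, ]), c(0.7, 0, 0))

    # every frame equal to 2*SC: constant recovered coefficients
    Y3 <- matrix(rep(2 * vsc, 10), 10, byrow = TRUE)
    fw3 <- framewise_glm(Y3, list(SC = sc, NS = ns))
    expect_lt(max(abs(fw3$coefficients[, "SC"] - 2)), 1e-5)
  })
})

test_that("variance partition brackets contributions on a cohort", {
  ch <- small_cohort()
  sc <- tracing_similarity(ch$tracing)
  ns <- expression_similarity(ch$expression)
  fcs <- lapply(ch$scans, function(s) vectorize_pairs(compute_fc(s)))
  vp <- partition_variance(fcs, list(SC = sc, NS = ns), n_shuffles = 60,
                           seed = 7)
  expect_gt(vp$full$mean, 0.3)
  for (nm in c("SC", "NS")) {
    expect_lte(vp$delta[[nm]]$delta_r2, vp$single[[nm]]$mean + 0.02)
    expect_gte(vp$delta[[nm]]$delta_r2, -0.02)
  }
  expect_gt(vp$single$SC$mean, vp$delta$SC$delta_r2)
})

test_that("receptor contribution and screen recover planted groups", {
  ch <- small_cohort()
  sc <- tracing_similarity(ch$tracing)
  fc_mean <- Reduce(`+`, lapply(ch$scans, compute_fc)) / 2
  ref <- procrustes_align(connectivity_gradients(fc_mean, 4),
                          ch$truth$gradient_maps)
  D <- coord_dist(ch$truth$coords)
  beh <- lapply(ch$pupil, behavioral_index, fps = ch$fps, tr = ch$tr)
  tmpl <- arousal_template(ch$scans, beh, tr = ch$tr)
  idx <- unlist(lapply(ch$scans, function(s)
    fmri_arousal_index(s, tmpl)$index))
  dfc <- lapply(ch$scans, function(s) dcc_fit(s)$dfc)
  dfc <- array(c(dfc[[1]], dfc[[2]]), c(40, 40, 1024))
  bins <- binned_mean_dfc(dfc, bin_by_arousal(idx, 4))

  scr <- receptor_screen(bins, ch$expression, sc, D, n_shuffles = 150,
                         seed = 9, reference = ref)
  expect_gte(mean(scr$group == ch$truth$receptor_groups), 0.8)
  # null receptors are not declared significant
  nulls <- ch$truth$receptor_groups == 4
  expect_true(all(scr$group[nulls] == 4))
  # loaded receptors retain positive unique contributions on their axes
  g1 <- ch$truth$receptor_groups == 1
  expect_gt(mean(scr$delta.1[g1]), 0)

  rc <- receptor_contribution(bins, ch$expression,
                              rownames(ch$expression)[1], sc, D,
                              n_shuffles = 100, seed = 10, reference = ref)
  expect_length(rc$p, 2)
  expect_equal(dim(rc$surrogate), c(100, 2))
  expect_error(receptor_contribution(bins, ch$expression, "nope", sc, D,
                                     100, reference = ref), "absent")
})
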