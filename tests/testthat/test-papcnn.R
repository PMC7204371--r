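test_that("adaptive parameter formulas reproduce hand arithmetic", {
  # sigma = 0.25, S_max = 1, Otsu threshold 0.5
  st <- shearfuse:::.adaptive_from_stats(0.25, 1, 0.5)
  expect_equal(st$alpha_f, log(4), tolerance = 1e-12)
  expect_equal(st$lambda, 1 / 6, tolerance = 1e-12)
  expect_equal(st$V_E, 0.25 + 1 + 1, tolerance = 1e-12)
  denom <- 0.5 * (1 - exp(-3 * log(4))) / (1 - exp(-log(4))) + 1 / 4
  expect_equal(st$alpha_e, log(2.25 / denom), tolerance = 1e-12)
})

test_that("adaptive parameters are finite and positive on any band", {
  set.seed(21)
  for (i in 1:100) {
    n <- sample(8:24, 1)
    band <- matrix(runif(n * n, min = 1e-3), n, n)
    p <- compute_adaptive_params(band)
    vals <- c(p$alpha_f, p$alpha_e, p$V_E, p$lambda_link)
    expect_true(all(is.finite(vals)))
    expect_true(all(vals[1:3] > 0))
    expect_gte(p$lambda_link, 0)
    expect_gt(p$V_E, 1)
  }
  # constant band: sigma clipped, no exception
  p <- compute_adaptive_params(matrix(0.4, 16, 16))
  expect_true(is.finite(p$alpha_f))
})

test_that("firing dynamics behave as the model dictates", {
  set.seed(22)
  band <- matrix(runif(16 * 16, 0.05, 1), 16, 16)
  p <- compute_adaptive_params(band)
  Tm <- papcnn_iterate(band, p)
  # zero-initialised threshold: every positive neuron fires at n = 1
  expect_true(all(Tm >= 1))
  expect_true(all(Tm <= p$N))
  expect_true(all(Tm == round(Tm)))
  # identical neurons fire identically
  pc <- papcnn_params(alpha_f = 0.7, alpha_e = 0.4, V_E = 2, beta = 0.2, N = 50)
  Tc <- papcnn_iterate(matrix(0.6, 12, 12), pc)
  expect_length(unique(as.vector(Tc)), 1)
  # stronger stimulus accumulates at least as many firings on average
  half <- cbind(matrix(0.9, 8, 4), matrix(0.1, 8, 4))
  Th <- papcnn_iterate(half, papcnn_params(alpha_f = 0.7, alpha_e = 0.4,
                                           V_E = 2, beta = 0.2, N = 110))
  expect_gte(mean(Th[, 1:4]), mean(Th[, 5:8]))
})

test_that("vectorized dynamics equal the literal scalar transcription", {
  set.seed(23)
  for (i in 1:4) {
    band <- matrix(runif(8 * 8, 0.01, 1), 8, 8)
    p <- compute_adaptive_params(band, iterations = 110)
    expect_identical(unclass(papcnn_iterate(band, p))[, ],
                     papcnn_oracle(band, p))
  }
  # also under a non-trivial fixed link strength
  band <- matrix(runif(8 * 8, 0.01, 1), 8, 8)
  p <- papcnn_params(alpha_f = 0.9, alpha_e = 0.3, V_E = 1.8, beta = 0.75,
                     N = 110)
  expect_identical(unclass(papcnn_iterate(band, p))[, ],
                   papcnn_oracle(band, p))
})

test_that("link-strength search matches exhaustive grid minimization", {
  set.seed(24)
  p <- papcnn_params(alpha_f = 1.1, alpha_e = 0.5, V_E = 2.2, beta = 0.3,
                     N = 110)
  for (i in 1:6) {
    ctx <- random_beta_context(6)
    for (db in c(0.5, 0.1, 0.01)) {
      cfg <- beta_search_config(delta_beta = db)
      b_impl <- optimize_beta(ctx$I, ctx$state, cfg, p)
      b_orac <- beta_grid_oracle(ctx$I, ctx$state, cfg, p)
      expect_equal(b_impl, b_orac)
      expect_gte(b_impl, 0); expect_lte(b_impl, 1)
    }
  }
})

test_that("degenerate search contexts fall back to the adaptive beta", {
  p <- papcnn_params(alpha_f = 1, alpha_e = 0.5, V_E = 2, beta = 0.37, N = 10)
  n <- 4
  state <- list(U = matrix(0, n, n), Y = matrix(0, n, n),
                E = matrix(1, n, n), L = matrix(0, n, n))  # X empty
  b <- optimize_beta(matrix(0.5, n, n), state, beta_search_config(), p)
  expect_equal(b, 0.37)
  b2 <- optimize_beta(matrix(0.5, n, n), state,
                      beta_search_config(fallback_beta = 0.9), p)
  expect_equal(b2, 0.9)
})

test_that("high-band fusion selects per pixel by firing count, ties to A", {
  HA <- matrix(c(1, -2, 3, -4), 2, 2)
  HB <- matrix(c(-5, 6, -7, 8), 2, 2)
  TA <- matrix(c(5, 3, 4, 4), 2, 2)
  TB <- matrix(c(3, 5, 4, 9), 2, 2)
  out <- fuse_high(HA, HB, TA, TB)
  expect_equal(out, matrix(c(1, 6, 3, 8), 2, 2))
  # selection property: each output pixel equals one of the two sources
  set.seed(25)
  HA <- matrix(rnorm(64), 8, 8); HB <- matrix(rnorm(64), 8, 8)
  TA <- matrix(sample(0:5, 64, TRUE), 8, 8)
  TB <- matrix(sample(0:5, 64, TRUE), 8, 8)
  out <- fuse_high(HA, HB, TA, TB)
  expect_true(all(out == HA | out == HB))
  expect_equal(fuse_high(HA, HA, TA, TB), HA)
  expect_error(fuse_high(HA, HB[1:4, 1:4], TA, TB), "shape")
})

test_that("iterate-time link-strength refinement stays in range", {
  set.seed(26)
  band <- matrix(runif(24 * 24, 0.01, 1), 24, 24)
  p <- compute_adaptive_params(band)
  Tm <- papcnn_iterate(band, p, beta_search = beta_search_config())
  b <- attr(Tm, "beta")
  expect_gte(b, 0); expect_lte(b, 1)
  expect_true(all(Tm >= 0 & Tm <= p$N))
  # negative stimulus is rejected (callers must pass |H|)
  expect_error(papcnn_iterate(band - 2, p), "non-negative")
})
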