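test_that("dictionary constructor enforces the unit-norm constraint", {
  f <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
  expect_error(conv_dictionary(f), "unit-norm")
  d <- conv_dictionary(f, normalize = TRUE)
  norms <- apply(d$filters, 3, function(m) sqrt(sum(m^2)))
  expect_true(all(abs(norms - 1) < 1e-12))
  expect_error(conv_dictionary(array(0, c(4, 5, 2))), "square")
})

test_that("coding a zero signal gives exactly zero maps", {
  set.seed(31)
  d <- ortho_dictionary(6, 4)
  co <- csr_encode(matrix(0, 24, 24), d, 0.01)
  expect_true(all(co$maps == 0))
  expect_true(co$converged)
})

test_that("the encode objective never exceeds the zero-solution objective", {
  set.seed(32)
  d <- ortho_dictionary(8, 6)
  for (i in 1:10) {
    s <- matrix(rnorm(32 * 32), 32, 32); s <- s - mean(s)
    co <- suppressWarnings(csr_encode(s, d, 0.05))
    expect_lte(co$final_objective, 0.5 * sum(s^2))
    # recorded trace starts at the zero-initialisation objective and the
    # best iterate is its running minimum
    expect_equal(co$objective[1], 0.5 * sum(s^2))
    expect_lte(co$final_objective, min(co$objective))
  }
})

test_that("a planted dictionary atom is recovered sparsely", {
  set.seed(33)
  d <- ortho_dictionary(8, 6)
  s <- matrix(0, 32, 32)
  s[11:18, 13:20] <- d$filters[, , 1]
  co <- suppressWarnings(
    csr_encode(s, d, 1e-5, admm_options(max_iter = 400, lambda = 1e-5)))
  rec <- csr_reconstruct(co, d)
  expect_lt(sqrt(sum((rec - s)^2) / sum(s^2)), 1e-2)
  # with a sparsity-enforcing weight, the response at the planted location
  # concentrates on the true atom's map
  co2 <- suppressWarnings(
    csr_encode(s, d, 0.02, admm_options(max_iter = 300, lambda = 0.02)))
  at_loc <- abs(co2$maps[11, 13, ])
  expect_equal(which.max(at_loc), 1L)
  expect_equal(which.max(abs(co2$maps[, , 1])),
               which(row(s) == 11 & col(s) == 13))
})

test_that("the first ADMM iteration matches an independent transcription", {
  set.seed(34)
  d <- ortho_dictionary(6, 4)
  s <- matrix(rnorm(20 * 20), 20, 20); s <- s - mean(s)
  lambda <- 0.01; rho <- 10 * lambda + 0.1
  res <- shearfuse:::.csr_encode_cpp(s, d$filters, lambda, rho, 1L,
                                     1e-12, 1e-12, NULL)
  oracle <- admm_first_step_oracle(s, d, lambda, rho)
  # both are the soft-thresholded split variable after one step from zero
  expect_lt(max(abs(res$maps - oracle)), 1e-10)
})

test_that("dictionary learning keeps unit norms and decreases the objective", {
  set.seed(35)
  train <- matrix(rnorm(32 * 32), 32, 32)
  train <- shearfuse:::.gauss_smooth(train, 1.5)
  d <- csr_learn_dictionary(train, M = 4, filter_size = 6, lambda_csr = 0.02,
                            opts = admm_options(max_iter = 60, lambda = 0.02),
                            alternations = 5, seed = 9)
  norms <- apply(d$filters, 3, function(m) sqrt(sum(m^2)))
  expect_true(all(abs(norms - 1) < 1e-8))
  obj <- attr(d, "objective")
  expect_true(all(diff(obj) <= 1e-6))
  # penalty-dominated limit: huge lambda drives the maps to zero
  dbig <- ortho_dictionary(6, 4)
  co <- csr_encode(train, dbig, 1e4, admm_options(max_iter = 50, lambda = 1e4))
  expect_true(all(co$maps == 0))
  expect_equal(co$final_objective, 0.5 * sum(train^2))
})

test_that("learning rejects invalid configurations", {
  expect_error(csr_learn_dictionary(list(), M = 4), "non-empty")
  expect_error(csr_learn_dictionary(matrix(0.5, 6, 6), M = 4,
                                    filter_size = 8), "larger than")
  expect_error(csr_learn_dictionary(matrix(0.5, 32, 32), M = 0), "M must be")
})

test_that("low-band fusion selects whole coefficient vectors per pixel", {
  set.seed(36)
  d <- ortho_dictionary(8, 6)
  p <- make_gray_pair(seed = 3, size = 64)
  cfg <- nsst_config(2, c(4, 4))
  LA <- nsst_decompose(p$modality_a, cfg)$low
  LB <- nsst_decompose(p$modality_b, cfg)$low
  opts <- admm_options(max_iter = 120, lambda = 0.01)
  fused <- fuse_low(LA, LB, d, 0.01, opts)
  expect_identical(dim(fused), dim(LA))
  sel <- attr(fused, "selection")
  expect_true(is.logical(sel))

  # replicate the rule independently: encode both, box-smooth the l1
  # activity, choose-max (ties to A), synthesise plus mean DC
  ca <- suppressWarnings(csr_encode(LA - mean(LA), d, 0.01, opts))
  cb <- suppressWarnings(csr_encode(LB - mean(LB), d, 0.01, opts))
  aa <- shearfuse:::.box3(apply(abs(ca$maps), c(1, 2), sum))
  ab <- shearfuse:::.box3(apply(abs(cb$maps), c(1, 2), sum))
  take_a <- aa >= ab
  maps <- cb$maps
  for (m in 1:6) {
    sl <- maps[, , m]; sl[take_a] <- ca$maps[, , m][take_a]
    maps[, , m] <- sl
  }
  ref <- (mean(LA) + mean(LB)) / 2 + csr_reconstruct(maps, d)
  expect_equal(unclass(fused)[, ], ref, tolerance = 1e-12)
  # per-pixel coefficient vectors come from exactly one source
  expect_true(all(take_a == sel))
  expect_error(fuse_low(LA, LB[1:10, 1:10], d), "shape")
})

test_that("fusing a band with a flat partner preserves the detailed band", {
  set.seed(37)
  d <- ortho_dictionary(8, 8)
  p <- make_gray_pair(seed = 4, size = 64)
  LA <- nsst_decompose(p$modality_a, nsst_config(2, c(4, 4)))$low
  LBflat <- matrix(0.5, 64, 64)
  fused <- fuse_low(LA, LBflat, d, 0.01,
                    admm_options(max_iter = 150, lambda = 0.01))
  # the flat band codes to (near-)zero maps, so A's detail wins everywhere
  detail_corr <- stats::cor(as.vector(fused - mean(fused)),
                            as.vector(LA - mean(LA)))
  expect_gt(detail_corr, 0.95)
  # merged DC plus the (small) mean of the synthesised detail
  expect_lt(abs(mean(fused) - (mean(LA) + 0.5) / 2), 0.01)
})

test_that("dictionary text serialization round-trips", {
  set.seed(38)
  d <- ortho_dictionary(5, 3)
  f <- tempfile(fileext = ".txt")
  write_dictionary(d, f, meta = list(seed = 42))
  d2 <- read_dictionary(f)
  expect_equal(d2$filters, d$filters, tolerance = 1e-15)
  expect_equal(d2$M, 3)
  expect_equal(d2$filter_size, 5)
})

test_that("the shipped dictionary loads and satisfies its constraints", {
  d <- default_dictionary()
  expect_s3_class(d, "conv_dictionary")
  expect_equal(d$M, 32)
  expect_equal(d$filter_size, 8)
  norms <- apply(d$filters, 3, function(m) sqrt(sum(m^2)))
  expect_true(all(abs(norms - 1) < 1e-8))
})
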