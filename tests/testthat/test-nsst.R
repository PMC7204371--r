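test_that("band bookkeeping and shapes match the configuration", {
  set.seed(11)
  img <- matrix(runif(64 * 64), 64, 64)
  co <- nsst_decompose(img, nsst_config(2, c(4, 4)))
  expect_length(co$high, 2)
  expect_length(co$high[[1]], 4)
  expect_length(co$high[[2]], 4)
  for (l in 1:2) for (k in 1:4)
    expect_identical(dim(co$high[[l]][[k]]), dim(img))
  expect_identical(dim(co$low), dim(img))
})

test_that("a constant image has all its energy in the low band", {
  co <- nsst_decompose(matrix(0.7, 64, 64), nsst_config(2, c(4, 4)))
  expect_lt(max(abs(co$low - 0.7)), 1e-8)
  for (l in 1:2) for (k in 1:4) {
    expect_lt(max(abs(co$high[[l]][[k]])), 1e-8)
    expect_lt(abs(mean(co$high[[l]][[k]])), 1e-8)
  }
})

test_that("decompose/reconstruct is a perfect-reconstruction pair", {
  set.seed(12)
  # unit impulse
  z <- matrix(0, 64, 64); z[33, 33] <- 1
  expect_lt(max(abs(nsst_reconstruct(nsst_decompose(z)) - z)), 1e-6)
  # random images, default and non-default configs, non-square sizes
  cfgs <- list(nsst_config(), nsst_config(2, c(4, 4)),
               nsst_config(3, c(8, 4, 2)))
  for (cfg in cfgs) {
    x <- matrix(rnorm(64 * 96), 64, 96)
    err <- max(abs(nsst_reconstruct(nsst_decompose(x, cfg)) - x))
    expect_lt(err, 1e-6)
  }
})

test_that("the transform pair is linear", {
  set.seed(13)
  cfg <- nsst_config(2, c(4, 4))
  x1 <- matrix(rnorm(32 * 32), 32, 32)
  x2 <- matrix(rnorm(32 * 32), 32, 32)
  c1 <- nsst_decompose(x1, cfg); c2 <- nsst_decompose(x2, cfg)
  c12 <- nsst_decompose(2 * x1 - 3 * x2, cfg)
  expect_lt(max(abs(c12$low - (2 * c1$low - 3 * c2$low))), 1e-10)
  expect_lt(max(abs(c12$high[[1]][[3]] -
                      (2 * c1$high[[1]][[3]] - 3 * c2$high[[1]][[3]]))), 1e-10)
  # linearity of reconstruction via coefficient mixing
  mix <- c1
  mix$low <- 0.5 * c1$low + 2 * c2$low
  for (l in 1:2) for (k in 1:4)
    mix$high[[l]][[k]] <- 0.5 * c1$high[[l]][[k]] + 2 * c2$high[[l]][[k]]
  expect_lt(max(abs(nsst_reconstruct(mix) -
                      (0.5 * x1 + 2 * x2))), 1e-10)
  # all-zero coefficients reconstruct to zero
  zero <- nsst_decompose(matrix(0, 32, 32), cfg)
  expect_equal(nsst_reconstruct(zero), matrix(0, 32, 32))
})

test_that("circularly shifting the input shifts every band", {
  set.seed(14)
  x <- matrix(runif(64 * 64), 64, 64)
  cfg <- nsst_config(2, c(4, 4))
  c0 <- nsst_decompose(x, cfg)
  c1 <- nsst_decompose(shift_mat(x, 5, -3), cfg)
  expect_lt(max(abs(c1$low - shift_mat(c0$low, 5, -3))), 1e-6)
  for (l in 1:2) for (k in 1:4)
    expect_lt(max(abs(c1$high[[l]][[k]] -
                        shift_mat(c0$high[[l]][[k]], 5, -3))), 1e-6)
})

test_that("invalid inputs are rejected with informative errors", {
  expect_error(nsst_config(levels = 0), "positive")
  expect_error(nsst_config(2, c(4, 3)), "power of two")
  expect_error(nsst_config(2, c(4)), "one entry per level")
  x <- matrix(runif(32 * 32), 32, 32)
  # 32 < 2^(4+2): the sizing error must name the minimum dimension
  expect_error(nsst_decompose(x, nsst_config()), "64")
  x[3, 3] <- NaN
  expect_error(nsst_decompose(x, nsst_config(2, c(4, 4))), "non-finite")
  co <- nsst_decompose(matrix(runif(64 * 64), 64, 64), nsst_config(2, c(4, 4)))
  co$high[[1]][[2]] <- matrix(0, 10, 10)
  expect_error(nsst_reconstruct(co), "shape")
})
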