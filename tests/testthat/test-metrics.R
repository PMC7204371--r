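test_that("a constant image carries no information, variation or edges", {
  Fc <- matrix(0.5, 32, 32)
  m <- compute_metrics(Fc, Fc, Fc)
  expect_equal(m$EN, 0)
  expect_equal(m$SD, 0)
  expect_equal(m$SF, 0)
  expect_equal(m$AG, 0)
})

test_that("two-level half/half image: closed-form entropy and mutual information", {
  x <- cbind(matrix(0, 16, 8), matrix(1, 16, 8))
  m <- compute_metrics(x, x, x)
  expect_equal(m$EN, 1, tolerance = 1e-12)          # 1 bit
  expect_equal(m$MI, 2, tolerance = 1e-12)          # I(F;A) + I(F;B) = 2 bits
  # MI(F;A) equals EN(A) whenever F = A
  set.seed(41)
  a <- matrix(runif(16 * 16), 16, 16) * 255
  expect_equal(metric_mi(a, a), metric_en(a), tolerance = 1e-12)
})

test_that("entropy is maximal for a uniform 256-level histogram", {
  ramp <- matrix(rep(0:255, each = 16), 16, 256) / 255
  m <- compute_metrics(ramp, ramp, ramp)
  expect_equal(m$EN, 8, tolerance = 1e-12)
})

test_that("perfect edge transfer scores exactly one", {
  set.seed(42)
  a <- matrix(runif(24 * 24), 24, 24)
  m <- compute_metrics(a, a, a)
  expect_equal(m$Q_ABF, 1, tolerance = 1e-6)
  expect_equal(qabf_oracle(a * 255, a * 255, a * 255), 1, tolerance = 1e-6)
})

test_that("metrics agree with brute-force oracles on random images", {
  set.seed(43)
  for (i in 1:5) {
    f <- matrix(runif(16 * 16), 16, 16) * 255
    a <- matrix(runif(16 * 16), 16, 16) * 255
    expect_equal(metric_en(f), en_oracle(f), tolerance = 1e-10)
    expect_equal(metric_mi(f, a), mi_oracle(f, a), tolerance = 1e-10)
    expect_equal(metric_sd(f), sd_oracle(f), tolerance = 1e-10)
    expect_equal(metric_sf(f), sf_oracle(f), tolerance = 1e-10)
    expect_equal(metric_ag(f), ag_oracle(f), tolerance = 1e-10)
    expect_equal(metric_qabf(f, a, f), qabf_oracle(f, a, f), tolerance = 1e-10)
  }
})

test_that("edge retention is bounded and symmetric in its construction", {
  set.seed(44)
  f <- matrix(runif(16 * 16), 16, 16) * 255
  a <- matrix(runif(16 * 16), 16, 16) * 255
  b <- matrix(runif(16 * 16), 16, 16) * 255
  q <- metric_qabf(f, a, b)
  expect_gte(q, 0); expect_lte(q, 1)
  expect_equal(metric_qabf(f, a, b), metric_qabf(f, b, a), tolerance = 1e-12)
})

test_that("variation metrics are invariant to a pre-clipping intensity shift", {
  set.seed(45)
  x <- matrix(runif(16 * 16, 50, 150), 16, 16)
  for (shift in c(-20, 35)) {
    expect_equal(metric_sd(x + shift), metric_sd(x), tolerance = 1e-10)
    expect_equal(metric_sf(x + shift), metric_sf(x), tolerance = 1e-10)
    expect_equal(metric_ag(x + shift), metric_ag(x), tolerance = 1e-10)
  }
})

test_that("metric report behaves as a table and validates shapes", {
  set.seed(46)
  a <- matrix(runif(16 * 16), 16, 16)
  m <- compute_metrics(a, a, a)
  df <- as.data.frame(m)
  expect_named(df, c("EN", "Q_ABF", "MI", "AG", "SF", "SD"))
  expect_true(all(vapply(df, is.finite, logical(1))))
  expect_error(compute_metrics(a, a[1:8, 1:8], a), "shape")
  # colour input is scored on luminance
  rgb <- array(0, c(16, 16, 3)); for (ch in 1:3) rgb[, , ch] <- a
  m2 <- compute_metrics(rgb, a, a)
  expect_equal(m2$EN, m$EN, tolerance = 1e-12)
})
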