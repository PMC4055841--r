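# Per-pixel Weber primitives: closed-form pixel values, quantization rule,
# histogram assembly, and the randomized invariance properties.

test_that("differential excitation matches hand-computed closed forms", {
  # all 8 neighbors 10% brighter: f_ratio = 8 * 10/100
  expect_equal(
    as.numeric(differential_excitation(ring_image(100, 110))),
    atan(0.8), tolerance = 1e-12
  )
  # sign-symmetric case: neighbors darker
  expect_equal(
    as.numeric(differential_excitation(ring_image(100, 90))),
    atan(-0.8), tolerance = 1e-12
  )
  # constant image: zero excitation
  expect_equal(as.numeric(differential_excitation(ring_image(100, 100))), 0)
})

test_that("zero-intensity centers use denominator one instead of dividing by zero", {
  e <- differential_excitation(ring_image(0, 8))
  expect_equal(as.numeric(e), atan(64))  # sum of differences 64, denominator 1
})

test_that("excitation rejects images smaller than the neighborhood", {
  expect_error(differential_excitation(matrix(1, 2, 5)), "too small")
  expect_error(differential_excitation(matrix(1, 6, 6), wld_scale(24, 3)),
               "too small")
})

test_that("excitation is bounded in [-pi/2, pi/2] on random images at all scales", {
  set.seed(101)
  for (i in 1:50) {
    img <- random_test_image(sample(9:16, 1), sample(9:16, 1),
                             max_val = sample(c(3, 255, 65535), 1))
    for (sc in list(wld_scale(8, 1), wld_scale(16, 2), wld_scale(24, 3))) {
      e <- differential_excitation(img, sc)
      expect_true(all(e >= -pi / 2 & e <= pi / 2))
    }
  }
})

test_that("gradient orientation follows the cross differences and atan2 shift", {
  # horizontal gradient only: left 30, right 10 -> I73 = 20, I51 = 0
  img <- matrix(20, 3, 3)
  img[2, 1] <- 30
  img[2, 3] <- 10
  expect_equal(gradient_orientation(img)[1, 1], 3 * pi / 2, tolerance = 1e-12)
  # vertical gradient only: below 40, above 20 -> I51 = 20, I73 = 0
  img <- matrix(20, 3, 3)
  img[3, 2] <- 40
  img[1, 2] <- 20
  expect_equal(gradient_orientation(img)[1, 1], pi, tolerance = 1e-12)
  # flat cross maps to pi
  expect_equal(gradient_orientation(matrix(7, 3, 3))[1, 1], pi)
})

test_that("orientation quantization reproduces the rounding rule and wraps", {
  expect_identical(as.integer(quantize_orientation(matrix(0), 8)), 0L)
  expect_identical(as.integer(quantize_orientation(matrix(3 * pi / 2), 8)), 6L)
  expect_identical(as.integer(quantize_orientation(matrix(2 * pi), 8)), 0L)
  # T = 8: anything within pi/8 of phi_t maps to t
  set.seed(7)
  t_true <- sample(0:7, 40, replace = TRUE)
  jitter <- runif(40, -pi / 8 + 1e-9, pi / 8 - 1e-9)
  theta <- (t_true * pi / 4 + jitter) %% (2 * pi)
  expect_identical(as.integer(quantize_orientation(matrix(theta), 8)), t_true)
  expect_error(quantize_orientation(matrix(7), 8), "out of range")
})

test_that("constant images put all histogram mass in a single known bin", {
  params <- wld_params(4, 4, 5)
  h <- wld_descriptor(matrix(42, 9, 9), params)
  expect_length(h, 80)
  expect_equal(sum(h), 1, tolerance = 1e-9)
  # eps = 0 -> interval M*S/2 = 10 -> m = 2, s = 0; theta' = pi -> t = 2
  bin <- 2 * (4 * 5) + 2 * 5 + 0 + 1
  expect_equal(h[bin], 1)
  expect_equal(sum(h > 0), 1)
})

test_that("histogram length is T*M*S and the L1 norm holds for random shapes", {
  set.seed(55)
  for (i in 1:20) {
    tt <- sample(c(2, 4, 6, 8, 12), 1)
    mm <- sample(1:8, 1)
    ss <- sample(1:20, 1)
    img <- random_test_image(11)
    h <- wld_descriptor(img, wld_params(tt, mm, ss))
    expect_length(h, tt * mm * ss)
    expect_equal(sum(h), 1, tolerance = 1e-9)
    expect_true(all(h >= 0))
  }
})

test_that("vectorized histogram equals the per-pixel scalar oracle", {
  set.seed(202)
  scales <- list(wld_scale(8, 1), wld_scale(16, 2), wld_scale(24, 3))
  for (i in 1:25) {
    img <- random_test_image(sample(9:16, 1), sample(9:16, 1))
    sc <- scales[[sample(3, 1)]]
    got <- wld_descriptor(img, wld_params(4, 4, 5), sc)
    want <- oracle_wld_hist(img, 4, 4, 5, sc$r)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("descriptor maps are invariant to multiplicative illumination change", {
  set.seed(303)
  for (i in 1:25) {
    img <- matrix(runif(144, 1, 255), 12, 12)  # strictly positive
    k <- exp(runif(1, -3, 3))
    for (sc in list(wld_scale(8, 1), wld_scale(24, 3))) {
      expect_equal(differential_excitation(img * k, sc),
                   differential_excitation(img, sc), tolerance = 1e-9)
    }
    expect_equal(gradient_orientation(img * k), gradient_orientation(img),
                 tolerance = 1e-9)
  }
})

test_that("intensity inversion shifts orientation bins by T/2", {
  set.seed(404)
  for (i in 1:25) {
    img <- matrix(runif(121, 10, 100), 11, 11)
    c0 <- 120
    inv <- 2 * c0 - img   # stays positive
    for (tt in c(4, 8)) {
      t1 <- quantize_orientation(gradient_orientation(img), tt)
      t2 <- quantize_orientation(gradient_orientation(inv), tt)
      expect_identical(as.integer((t1 + tt / 2) %% tt), as.integer(t2))
    }
  }
})
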