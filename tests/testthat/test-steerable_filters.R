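test_that("kernels have the required normalization and parities", {
  k0 <- gaussian_derivative_kernel(0, 0, 1)
  expect_equal(sum(k0), 1, tolerance = 1e-12)
  kx <- gaussian_derivative_kernel(1, 0, 1)
  expect_equal(sum(kx), 0, tolerance = 1e-12)
  expect_equal(kx, -kx[, ncol(kx):1], tolerance = 1e-14)  # odd in x
  expect_equal(kx, kx[nrow(kx):1, ], tolerance = 1e-14)   # even in y
  # every derivative kernel sums to zero, including pure even ones
  for (i in 0:3) for (j in 0:(3 - i)) {
    if (i + j == 0) next
    expect_lt(abs(sum(gaussian_derivative_kernel(i, j, 0.5))), 1e-12)
  }
  expect_error(gaussian_derivative_kernel(2, 2, 1), "unsupported")
})

test_that("sampled first derivative agrees with finite differences of the Gaussian", {
  sigma <- 1
  r <- kernel_radius(sigma)
  kx <- gaussian_derivative_kernel(1, 0, sigma)
  # central finite difference of the Gaussian surface, same normalization
  t <- seq(-r, r)
  h <- 1e-3
  gauss <- function(u) exp(-u^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
  s0 <- sum(gauss(t))
  fd <- outer(gauss(t) / s0, (gauss(t + h) - gauss(t - h)) / (2 * h) / s0)
  expect_lt(max(abs(kx - fd)), 1e-3)
})

test_that("minimal basis counts are order + 1", {
  expect_identical(min_basis_count(1), 2L)
  expect_identical(min_basis_count(2), 3L)
  expect_identical(min_basis_count(3), 4L)
  expect_error(min_basis_count(4), "unsupported")
  # order-3 harmonic count: FFT of the angular profile of the directional
  # derivative cos(phi)^3 has exactly 4 nonzero coefficients
  phi <- seq(0, 2 * pi, length.out = 256L + 1L)[-257L]
  co <- fft(cos(phi)^3)
  expect_identical(sum(Mod(co) > 1e-8 * max(Mod(co))), 4L)
})

test_that("steering coefficients match the directional-derivative expansion", {
  expect_equal(steering_coefficients(1, 0), c(1, 0))
  expect_equal(steering_coefficients(1, 90), c(0, 1))
  expect_equal(steering_coefficients(2, 45), c(0.5, 1, 0.5))
  expect_equal(steering_coefficients(3, 0), c(1, 0, 0, 0))
  th <- 37
  expect_equal(steering_coefficients(3, th),
               c(cospi(th / 180)^3,
                 3 * cospi(th / 180)^2 * sinpi(th / 180),
                 3 * cospi(th / 180) * sinpi(th / 180)^2,
                 sinpi(th / 180)^3))
})

test_that("basis responses equal dense convolution with the basis kernels", {
  img <- random_image(64, seed = 41)
  cfg <- filter_bank_config(orders = 1:3, scales = 1, n_directions = 4)
  b <- build_basis_responses(img, cfg)
  for (ord in 1:3) {
    pl <- b$planes[[as.character(ord)]][[sprintf("%.6g", 1)]]
    for (i in 0:ord) {
      ref <- naive_conv2(img, gaussian_derivative_kernel(ord - i, i, 1))
      expect_lt(max(abs(pl[[i + 1L]] - ref)), 1e-10)
    }
  }
})

test_that("derivative responses vanish on constants and track ramps", {
  cfg <- filter_bank_config(orders = 1:2, scales = 1, n_directions = 4)
  b <- build_basis_responses(matrix(0.7, 32, 32), cfg)
  for (ord in c("1", "2")) {
    for (pl in b$planes[[ord]][[sprintf("%.6g", 1)]]) {
      expect_lt(max(abs(pl)), 1e-12)
    }
  }
  # ramp I(x, y) = x: unit G_x response, null G_y response in the interior
  ramp <- matrix(rep(1:40, each = 40), 40) * 1.0  # value = column index
  br <- build_basis_responses(ramp, cfg)
  gx <- interior_values(steer_response(br, 1, 1, 0), 8)
  gy <- interior_values(steer_response(br, 1, 1, 90), 8)
  expect_equal(mean(gx), 1, tolerance = 1e-3)
  expect_lt(max(abs(gy)), 1e-10)
})

test_that("steering responses equals steering kernels, with trig parities", {
  img <- random_image(48, seed = 17)
  cfg <- filter_bank_config(orders = 1:3, scales = 1, n_directions = 8)
  b <- build_basis_responses(img, cfg)
  sk1 <- sprintf("%.6g", 1)
  # theta = 0 / 90 are exact basis planes
  expect_identical(steer_response(b, 1, 1, 0), b$planes[["1"]][[sk1]][[1L]])
  expect_equal(steer_response(b, 1, 1, 90), b$planes[["1"]][[sk1]][[2L]],
               tolerance = 1e-15)
  # odd order flips at 180 degrees, even order repeats
  expect_equal(steer_response(b, 1, 1, 180), -steer_response(b, 1, 1, 0),
               tolerance = 1e-12)
  expect_equal(steer_response(b, 2, 1, 197), steer_response(b, 2, 1, 17),
               tolerance = 1e-12)
  # response-space steering == kernel-space steering at arbitrary angles
  for (ord in 1:3) {
    for (th in c(17, 63, 151)) {
      ref <- naive_conv2(img, steered_kernel(ord, 1, th))
      expect_lt(max(abs(steer_response(b, ord, 1, th) - ref)), 1e-12)
    }
  }
  # cos/sin law for order 1
  r37 <- steer_response(b, 1, 1, 37)
  expect_equal(r37,
               cospi(37 / 180) * steer_response(b, 1, 1, 0) +
                 sinpi(37 / 180) * steer_response(b, 1, 1, 90),
               tolerance = 1e-12)
  expect_error(steer_response(b, 1, 3, 0), "no basis")
})

test_that("steered responses match convolution with a bicubic-rotated kernel", {
  img <- random_image(64, seed = 3)
  for (sigma in c(0.5, 1, 2)) {
    radius <- kernel_radius(sigma)
    cfg <- filter_bank_config(orders = 1:3, scales = sigma, n_directions = 4)
    b <- build_basis_responses(img, cfg)
    for (ord in 1:3) {
      for (th in c(17, 63, 151)) {
        sr <- steer_response(b, ord, sigma, th)
        ref <- naive_conv2(img, rotated_kernel_oracle(ord, sigma, th, radius))
        d <- abs(sr - ref)[(radius + 1L):(64L - radius),
                           (radius + 1L):(64L - radius)]
        expect_lt(max(d), 1e-2 * max(abs(sr)))
      }
    }
  }
})

test_that("rotating the image commutes with shifting the steering angle", {
  img <- random_image(48, seed = 23)
  cfg <- filter_bank_config(orders = 1, scales = 1, n_directions = 4)
  # rotate image by 90 degrees: (x, y) -> (-y, x)
  img_rot <- t(img)[, nrow(img):1]
  b <- build_basis_responses(img, cfg)
  b_rot <- build_basis_responses(img_rot, cfg)
  th <- 25
  a <- steer_response(b_rot, 1, 1, th)
  e <- steer_response(b, 1, 1, th - 90)
  e_rot <- t(e)[, nrow(e):1]
  m <- 6L
  expect_equal(a[(m + 1):(48 - m), (m + 1):(48 - m)],
               e_rot[(m + 1):(48 - m), (m + 1):(48 - m)],
               tolerance = 1e-10)
})

test_that("configuration and size validation", {
  expect_error(filter_bank_config(orders = 4), "subset")
  expect_error(filter_bank_config(scales = -1), "positive")
  expect_error(build_basis_responses(matrix(1, 4, 4),
                                     filter_bank_config(scales = 2)),
               "too small")
  expect_identical(kernel_radius(0.3), 2L)
  expect_identical(kernel_radius(2), 8L)
  dflt <- filter_bank_config()
  expect_equal(dflt$scales, c(0.5, sqrt(2) / 2, 1, sqrt(2), 2))
  expect_identical(dflt$n_directions, 180L)
})
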