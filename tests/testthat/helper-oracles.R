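# Independent reference implementations used as test oracles. These are
# deliberately naive (dense loops, generic optimizers, numerical quadrature)
# and share no code with the package paths they check.

# Dense 2D convolution with reflect padding (edge repeated), double loop.
naive_conv2 <- function(img, kernel) {
  radius <- (nrow(kernel) - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  ri <- c(radius:1, 1:nr, nr:(nr - radius + 1L))
  ci <- c(radius:1, 1:nc, nc:(nc - radius + 1L))
  p <- img[ri, ci]
  kf <- kernel[nrow(kernel):1, ncol(kernel):1]  # flip: convolution proper
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      out[r, c] <- sum(p[r:(r + 2L * radius), c:(c + 2L * radius)] * kf)
    }
  }
  out
}

# Keys bicubic interpolation weight (a = -0.5).
cubic_w <- function(s) {
  s <- abs(s)
  ifelse(s <= 1, 1.5 * s^3 - 2.5 * s^2 + 1,
         ifelse(s < 2, -0.5 * s^3 + 2.5 * s^2 - 4 * s + 2, 0))
}

# Analytic 1D Gaussian-derivative profiles (continuum, unnormalized).
gd_profile <- function(d, t, sigma) {
  g <- exp(-t^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
  switch(as.character(d),
    "0" = g,
    "1" = -t / sigma^2 * g,
    "2" = (t^2 / sigma^4 - 1 / sigma^2) * g,
    "3" = (-t^3 / sigma^6 + 3 * t / sigma^4) * g)
}

# Numerically rotated derivative kernel: the x-aligned order-k kernel is
# rasterized at `os`-fold oversampling from the analytic profiles, rotated by
# bicubic interpolation, and given the package's normalization convention
# (1/s0 per 1D factor) and, for order 2, the same isotropic DC correction.
# Independent of the steering-coefficient path under test.
rotated_kernel_oracle <- function(order, sigma, theta_deg, radius, os = 8L) {
  pad <- ceiling(radius * 0.5) + 3
  tt <- seq(-(radius + pad), radius + pad, by = 1 / os)
  s0 <- sum(gd_profile(0, seq(-radius, radius), sigma))
  rast <- outer(gd_profile(0, tt, sigma), gd_profile(order, tt, sigma)) / s0^2
  th <- theta_deg * pi / 180
  coords <- seq(-radius, radius)
  out <- matrix(0, 2L * radius + 1L, 2L * radius + 1L)
  for (r in seq_along(coords)) {
    for (c in seq_along(coords)) {
      y <- coords[r]; x <- coords[c]
      xr <- cos(th) * x + sin(th) * y
      yr <- -sin(th) * x + cos(th) * y
      fy <- (yr + radius + pad) * os + 1
      fx <- (xr + radius + pad) * os + 1
      iy <- floor(fy); ix <- floor(fx)
      acc <- 0
      for (my in -1:2) {
        for (mx in -1:2) {
          acc <- acc + cubic_w(fy - (iy + my)) * cubic_w(fx - (ix + mx)) *
            rast[iy + my, ix + mx]
        }
      }
      out[r, c] <- acc
    }
  }
  if (order == 2L) {
    g0 <- gd_profile(0, coords, sigma)
    g0 <- g0 / sum(g0)
    out <- out - sum(out) * outer(g0, g0)
  }
  out
}

# Pivoted classical Gram-Schmidt on explicit feature vectors (columns of a
# symmetric square root of K), max-residual-norm pivoting; returns the pivot
# order and the trace of the residual Gram matrix after each step.
gram_schmidt_pivot_oracle <- function(k, gamma) {
  e <- eigen(k, symmetric = TRUE)
  v <- sqrt(pmax(e$values, 0))
  phi <- diag(v) %*% t(e$vectors)       # columns phi[, i] satisfy t(phi)%*%phi = K
  n <- ncol(phi)
  pivots <- integer(gamma)
  rtrace <- numeric(gamma)
  res <- phi
  active <- rep(TRUE, n)
  for (t in seq_len(gamma)) {
    norms <- colSums(res^2)
    norms[!active] <- -Inf
    i <- which.max(norms)
    pivots[t] <- i
    active[i] <- FALSE
    q <- res[, i] / sqrt(sum(res[, i]^2))
    proj <- drop(crossprod(q, res))
    res <- res - q %o% proj
    res[, i] <- 0
    rtrace[t] <- sum(res[, active]^2)
  }
  list(pivots = pivots, residual_trace = rtrace)
}

# Primal minimizer of the weighted LS-SVM objective for the explicit feature
# map phi(x) = (1, x / sqrt(c)) of the kernel K(u, v) = 1 + u.v/c:
# min_w,b 0.5 ||w||^2 + (r/2) sum_t c_t (y_t - w.phi(x_t) - b)^2.
# A ridge-type quadratic solved exactly by its normal equations.
primal_lssvm_oracle <- function(x, y, r, ct, poly_offset = 1) {
  phi <- cbind(1, x / sqrt(poly_offset))
  p <- ncol(phi)
  # stack b as an unpenalized extra coordinate: params = (w, b)
  a_mat <- cbind(phi, 1)
  w_pen <- diag(c(rep(1, p), 0))
  h <- w_pen + r * t(a_mat) %*% (ct * a_mat)
  g <- r * t(a_mat) %*% (ct * y)
  sol <- solve(h, g)
  list(w = sol[seq_len(p)], b = sol[p + 1L],
       decision = drop(a_mat %*% sol))
}

# Quadrature CDF of the integral-form WD density.
wd_cdf_quadrature <- function(q, lambda, beta) {
  vapply(q, function(z) {
    stats::integrate(function(t) wd_pdf(t, wd_params(lambda, beta)),
                     lower = -Inf, upper = z,
                     rel.tol = 1e-10)$value
  }, numeric(1))
}

# Sinusoidal stripe image whose intensity gradient points along `angle_deg`.
stripe_image <- function(angle_deg, n = 96L, period = 8) {
  th <- angle_deg * pi / 180
  xy <- expand.grid(y = seq_len(n), x = seq_len(n))
  matrix(0.5 + 0.4 * sin(2 * pi * (cos(th) * xy$x + sin(th) * xy$y) / period),
         n, n)
}
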