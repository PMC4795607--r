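#' Steerable Gaussian-derivative filter bank
#'
#' Gaussian derivatives up to order 3 are steerable: the response to the
#' directional derivative operator
#' \eqn{(\cos\theta\,\partial_x + \sin\theta\,\partial_y)^\kappa G_\sigma}
#' at any angle is an exact linear combination of \eqn{\kappa + 1} separable
#' basis responses. The bank therefore convolves once per basis kernel and
#' obtains all N orientations as cheap weighted sums.
#'
#' Image convention: matrices are indexed `[row, col]` with x along columns
#' and y along rows; angles are measured in degrees from the +x axis toward
#' +y (i.e. clockwise on screen for row-down displays).
#'
#' @name steerable_filters
NULL

## 1D sampled Gaussian-derivative factors on -R..R. Every factor is divided
## by the discrete sum of the sampled Gaussian (not just the 0-order one):
## a uniform per-factor scale keeps the smoothing kernel at unit DC gain
## while leaving all basis kernels exact scalar multiples of continuum
## samples, so steering a basis equals rotating a kernel to interpolation
## accuracy even at sigma = 0.5. Odd orders are exactly zero-sum by
## antisymmetry; the sampled second derivative keeps its small DC leakage
## here -- it is removed at the 2D level with an isotropic Gaussian term
## (see gdf_dc_correction), which also preserves the steering identity.
gauss_deriv_1d <- function(d, sigma, radius) {
  t <- seq(-radius, radius)
  g <- exp(-t^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
  k <- switch(as.character(d),
    "0" = g,
    "1" = -t / sigma^2 * g,
    "2" = (t^2 / sigma^4 - 1 / sigma^2) * g,
    "3" = (-t^3 / sigma^6 + 3 * t / sigma^4) * g,
    stop("unsupported derivative order (0..3)"))
  k / sum(g)
}

## DC leakage of the sampled pure second derivative: the discrete sum of the
## 1D g'' samples (zero in the continuum, nonzero under integer sampling,
## noticeably so at sigma = 0.5). Pure even kernels (G_xx, G_yy) are
## corrected by subtracting this times the unit-sum Gaussian, an isotropic
## term, so steering a corrected basis still equals rotating a corrected
## kernel.
gdf_dc_correction <- function(sigma, radius) {
  sum(gauss_deriv_1d(2L, sigma, radius))
}

#' Truncation radius of a Gaussian kernel
#'
#' Kernels are truncated at 4 standard deviations with a floor of 2 pixels.
#'
#' @param sigma Gaussian scale in pixels.
#' @return Integer radius; the kernel support is `(2R+1) x (2R+1)`.
#' @export
kernel_radius <- function(sigma) {
  max(2L, as.integer(ceiling(4 * sigma)))
}

#' Sampled 2-D Gaussian-derivative kernel
#'
#' \eqn{G_{x^i y^j}} with total order \eqn{i + j \le 3}, sampled on the
#' integer grid. The pure smoothing kernel (i = j = 0) sums to one;
#' derivative kernels sum to zero.
#'
#' @param x_order,y_order derivative orders i, j along x and y (>= 0,
#'   i + j <= 3).
#' @param sigma Gaussian scale in pixels.
#' @param radius truncation radius; default [kernel_radius()].
#' @return `(2R+1) x (2R+1)` matrix `K[row, col]` = \eqn{g^{(j)}(y) g^{(i)}(x)};
#'   the pure second derivatives carry an isotropic DC correction so every
#'   derivative kernel sums to zero exactly.
#' @export
gaussian_derivative_kernel <- function(x_order, y_order, sigma,
                                       radius = kernel_radius(sigma)) {
  if (x_order < 0 || y_order < 0 || x_order + y_order > 3L)
    stop("unsupported order: need x_order, y_order >= 0 and total order <= 3")
  if (!is.finite(sigma) || sigma <= 0) stop("'sigma' must be positive")
  kx <- gauss_deriv_1d(x_order, sigma, radius)
  ky <- gauss_deriv_1d(y_order, sigma, radius)
  k <- outer(ky, kx)
  if (x_order %% 2L == 0L && y_order %% 2L == 0L && x_order + y_order > 0L) {
    g0 <- gauss_deriv_1d(0L, sigma, radius)
    k <- k - sum(k) * outer(g0, g0)
  }
  k
}

#' Minimal steerable basis size
#'
#' A Gaussian derivative of order \eqn{\kappa} has \eqn{\kappa + 1} nonzero
#' angular harmonics, so \eqn{\kappa + 1} basis orientations suffice to
#' steer it exactly.
#'
#' @param order derivative order in 1..3.
#' @return Integer basis count M.
#' @export
min_basis_count <- function(order) {
  if (!order %in% 1:3) stop("unsupported order: must be 1, 2 or 3")
  as.integer(order) + 1L
}

#' Steering weights for a direction
#'
#' Expansion of the directional derivative
#' \eqn{(\cos\theta\,\partial_x + \sin\theta\,\partial_y)^\kappa}:
#' order 1 gives \eqn{[\cos\theta, \sin\theta]}, order 2
#' \eqn{[\cos^2\theta, 2\sin\theta\cos\theta, \sin^2\theta]}, order 3 the
#' binomial pattern
#' \eqn{[\cos^3, 3\cos^2\sin, 3\cos\sin^2, \sin^3]}.
#' Weights apply to basis planes ordered by descending x-derivative degree
#' \eqn{(G_{x^\kappa}, G_{x^{\kappa-1}y}, \ldots, G_{y^\kappa})}.
#'
#' @param order derivative order in 1..3.
#' @param theta_deg orientation in degrees.
#' @return Numeric weight vector of length `order + 1`.
#' @export
steering_coefficients <- function(order, theta_deg) {
  if (!order %in% 1:3) stop("unsupported order: must be 1, 2 or 3")
  th <- theta_deg * pi / 180
  i <- 0:order
  choose(order, i) * cos(th)^(order - i) * sin(th)^i
}

## Reflect-pad a matrix by R rows/cols on each side (edge pixel repeated,
## scipy 'reflect' convention).
pad_reflect <- function(m, radius) {
  nr <- nrow(m); nc <- ncol(m)
  if (radius > nr || radius > nc)
    stop("image too small for kernel support")
  ri <- c(radius:1, 1:nr, nr:(nr - radius + 1L))
  ci <- c(radius:1, 1:nc, nc:(nc - radius + 1L))
  m[ri, ci, drop = FALSE]
}

## Band matrix performing 1D convolution (kernel flipped) on a padded axis:
## out = A %*% f_pad with A[i, i + 2R + 1 - j] = k[j].
conv_band_matrix <- function(k, n_out) {
  radius <- (length(k) - 1L) %/% 2L
  a <- matrix(0, n_out, n_out + 2L * radius)
  for (j in seq_along(k)) {
    idx <- cbind(seq_len(n_out), seq_len(n_out) + 2L * radius + 1L - j)
    a[idx] <- k[j]
  }
  a
}

## Separable 2D convolution with reflect boundary; kx acts along columns (x),
## ky along rows (y). Exact convolution (not correlation).
conv2_separable <- function(img, kx, ky) {
  radius <- (length(kx) - 1L) %/% 2L
  stopifnot(length(ky) == length(kx))
  p <- pad_reflect(img, radius)
  ay <- conv_band_matrix(ky, nrow(img))
  ax <- conv_band_matrix(kx, ncol(img))
  ay %*% p %*% t(ax)
}

#' Filter-bank configuration
#'
#' @param orders derivative orders used, subset of 1:3.
#' @param scales Gaussian scales in pixels; default
#'   `c(0.5, sqrt(2)/2, 1, sqrt(2), 2)`.
#' @param n_directions number of orientations N; directions are
#'   \eqn{\theta_i = i \cdot 360/N} degrees, \eqn{i = 0..N-1}. Default 180.
#' @param boundary boundary mode (only "reflect" is implemented).
#' @return A `filter_bank_config` list.
#' @export
filter_bank_config <- function(orders = 1:3,
                               scales = c(0.5, sqrt(2) / 2, 1, sqrt(2), 2),
                               n_directions = 180L,
                               boundary = "reflect") {
  orders <- sort(unique(as.integer(orders)))
  if (!all(orders %in% 1:3)) stop("orders must be a subset of 1:3")
  if (any(!is.finite(scales)) || any(scales <= 0))
    stop("scales must be positive")
  if (n_directions < 1L) stop("need at least one direction")
  boundary <- match.arg(boundary, "reflect")
  structure(list(orders = orders, scales = sort(scales),
                 n_directions = as.integer(n_directions),
                 boundary = boundary),
            class = "filter_bank_config")
}

scale_key <- function(sigma) sprintf("%.6g", sigma)

#' Convolve an image with every basis kernel of a filter bank
#'
#' One separable convolution per basis kernel per scale; steering to any
#' orientation then costs only a weighted sum of planes
#' (see [steer_response()]).
#'
#' @param image numeric matrix (finite values).
#' @param config a [filter_bank_config()].
#' @return Object of class `basis_responses`: nested list
#'   `planes[[order]][[scale]]` of `order + 1` response matrices (x-degree
#'   descending), plus the config and per-scale truncation radii.
#' @export
build_basis_responses <- function(image, config = filter_bank_config()) {
  if (!is.matrix(image) || !is.numeric(image) || any(!is.finite(image)))
    stop("'image' must be a finite numeric matrix")
  max_r <- kernel_radius(max(config$scales))
  if (min(dim(image)) < 2L * max_r + 1L)
    stop("image too small for the largest kernel support")
  planes <- list()
  radii <- numeric(0)
  for (sigma in config$scales) {
    radius <- kernel_radius(sigma)
    radii[scale_key(sigma)] <- radius
    f1d <- lapply(0:3, gauss_deriv_1d, sigma = sigma, radius = radius)
    dc <- gdf_dc_correction(sigma, radius)
    smooth <- if (2L %in% config$orders)
      conv2_separable(image, f1d[[1L]], f1d[[1L]]) else NULL
    for (ord in config$orders) {
      key <- as.character(ord)
      if (is.null(planes[[key]])) planes[[key]] <- list()
      planes[[key]][[scale_key(sigma)]] <- lapply(0:ord, function(i) {
        ## basis kernel G_{x^{ord-i} y^i}
        r <- conv2_separable(image, f1d[[ord - i + 1L]], f1d[[i + 1L]])
        ## DC correction of the pure second derivatives (G_xx, G_yy)
        if (ord == 2L && i %in% c(0L, 2L)) r <- r - dc * smooth
        r
      })
    }
  }
  structure(list(planes = planes, config = config, radii = radii,
                 dim = dim(image), img_scale = max(abs(image))),
            class = "basis_responses")
}

#' Steer basis responses to an arbitrary orientation
#'
#' By linearity of convolution, the weighted sum of basis response planes
#' equals convolving the image with the explicitly steered kernel.
#'
#' @param basis a [build_basis_responses()] result.
#' @param order derivative order (present in the basis).
#' @param sigma scale (present in the basis).
#' @param theta_deg orientation in degrees.
#' @return Response matrix of the same shape as the input image.
#' @export
steer_response <- function(basis, order, sigma, theta_deg) {
  key <- as.character(order)
  sk <- scale_key(sigma)
  pl <- basis$planes[[key]][[sk]]
  if (is.null(pl))
    stop(sprintf("no basis responses for order %s at scale %s", key, sk))
  w <- steering_coefficients(order, theta_deg)
  out <- w[1L] * pl[[1L]]
  for (i in seq_along(w)[-1L]) out <- out + w[i] * pl[[i]]
  out
}

#' Explicitly steered kernel (reference path)
#'
#' The same linear combination as [steer_response()], applied to the basis
#' kernels instead of the responses. Used mainly for inspection and testing.
#'
#' @inheritParams steer_response
#' @param radius truncation radius; default [kernel_radius()].
#' @return Steered kernel matrix.
#' @export
steered_kernel <- function(order, sigma, theta_deg,
                           radius = kernel_radius(sigma)) {
  w <- steering_coefficients(order, theta_deg)
  k <- 0
  for (i in 0:order) {
    k <- k + w[i + 1L] *
      gaussian_derivative_kernel(order - i, i, sigma, radius)
  }
  k
}

#' Interior of a response plane
#'
#' Drops a margin (by default the kernel truncation radius) on every side so
#' that reflect-padding artifacts do not enter downstream tail statistics.
#'
#' @param plane response matrix.
#' @param margin margin width in pixels.
#' @return Numeric vector of interior values.
#' @export
interior_values <- function(plane, margin) {
  nr <- nrow(plane); nc <- ncol(plane)
  if (2L * margin >= nr || 2L * margin >= nc)
    stop("margin too large for plane")
  as.vector(plane[(margin + 1L):(nr - margin), (margin + 1L):(nc - margin)])
}
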