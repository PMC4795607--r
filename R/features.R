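#' Omnidirectional WD-parameter features
#'
#' For each orientation of the steered derivative response, the interior
#' pixels are fitted with the integral-form Weibull model; the fitted
#' (beta, lambda) pairs over all N directions form the per-scale feature
#' block `[beta_1..beta_N, lambda_1..lambda_N]`, and blocks are concatenated
#' over derivative orders (ascending) then scales (ascending) into the full
#' image descriptor.
#'
#' @name features
NULL

#' Per-scale omnidirectional WD features
#'
#' @param image numeric matrix; ignored if `basis` is supplied.
#' @param order derivative order in 1..3.
#' @param sigma Gaussian scale in pixels.
#' @param n_directions number of orientations N.
#' @param basis optional precomputed [build_basis_responses()] (must contain
#'   the requested order and scale); avoids re-convolution.
#' @return Object of class `scale_feature`: `betas`, `lambdas` (length N),
#'   `theta_deg`, `order`, `sigma`, `converged` (logical per direction).
#' @details A direction whose fit does not converge keeps the last iterate
#'   and raises a warning (feature length stays fixed); an all-zero response
#'   (e.g. a constant image) is an error.
#' @export
extract_scale_features <- function(image = NULL, order, sigma,
                                   n_directions = 180L, basis = NULL) {
  if (is.null(basis)) {
    basis <- build_basis_responses(
      image, filter_bank_config(orders = order, scales = sigma,
                                n_directions = n_directions))
  }
  margin <- basis$radii[[scale_key(sigma)]]
  ## blank/constant image: every basis plane is at roundoff level relative
  ## to the image intensities -- no contrast structure to model
  ref <- max(vapply(basis$planes[[as.character(order)]][[scale_key(sigma)]],
                    function(p) max(abs(p)), numeric(1)))
  if (basis$img_scale == 0 || ref < 1e-12 * basis$img_scale)
    stop("degenerate response: the image has no contrast structure at this ",
         "order and scale")
  theta <- (seq_len(n_directions) - 1L) * 360 / n_directions
  betas <- numeric(n_directions)
  lambdas <- numeric(n_directions)
  conv <- logical(n_directions)
  for (i in seq_len(n_directions)) {
    vals <- interior_values(steer_response(basis, order, sigma, theta[i]),
                            margin)
    if (all(vals == 0))
      stop("degenerate response: steered interior is identically zero")
    fit <- wd_fit(vals)
    if (!fit$converged)
      warning(sprintf(
        "WD fit did not converge at order %d, sigma %.3g, theta %.1f",
        order, sigma, theta[i]))
    betas[i] <- fit$params$beta
    lambdas[i] <- fit$params$lambda
    conv[i] <- fit$converged
  }
  structure(list(order = order, sigma = sigma, theta_deg = theta,
                 betas = betas, lambdas = lambdas, converged = conv),
            class = "scale_feature")
}

#' Flatten a per-scale feature block
#'
#' @param sf a `scale_feature`.
#' @return Named numeric vector `[beta_1..beta_N, lambda_1..lambda_N]`.
#' @export
scale_feature_vector <- function(sf) {
  n <- length(sf$theta_deg)
  v <- c(sf$betas, sf$lambdas)
  names(v) <- c(
    sprintf("order%d_s%s_beta_%d", sf$order, scale_key(sf$sigma), seq_len(n)),
    sprintf("order%d_s%s_lambda_%d", sf$order, scale_key(sf$sigma), seq_len(n)))
  v
}

#' Multiscale omnidirectional feature vector of an image
#'
#' @param image numeric matrix.
#' @param config a [filter_bank_config()].
#' @param standardize_intensity optionally standardize image intensities
#'   (zero mean, unit variance) before filtering, to cancel illumination
#'   differences between acquisitions; off by default.
#' @return Named numeric vector of length
#'   `length(orders) * length(scales) * 2 * n_directions`, ordered by
#'   ascending order, then ascending scale, each block
#'   `[betas, lambdas]` over directions.
#' @export
extract_features <- function(image, config = filter_bank_config(),
                             standardize_intensity = FALSE) {
  if (standardize_intensity) {
    s <- stats::sd(image)
    if (s == 0) stop("constant image cannot be standardized")
    image <- (image - mean(image)) / s
  }
  basis <- build_basis_responses(image, config)
  out <- lapply(config$orders, function(ord) {
    blocks <- lapply(config$scales, function(sg) {
      scale_feature_vector(extract_scale_features(
        order = ord, sigma = sg, n_directions = config$n_directions,
        basis = basis))
    })
    do.call(c, blocks)
  })
  do.call(c, out)
}

#' Dominant direction of a WD-parameter polar profile
#'
#' The circular argmax of the chosen parameter over orientation. Because the
#' WD fit is symmetric in response sign, profiles have period 180 degrees for
#' every derivative order; the returned angle lies in [0, 180).
#'
#' @param sf a `scale_feature`.
#' @param which `"beta"` (contrast anisotropy) or `"lambda"`
#'   (grain-size anisotropy).
#' @param flat_tol relative range below which the profile is declared
#'   isotropic, default 0.1 (direction-to-direction sampling scatter on a
#'   truly isotropic image is a few percent).
#' @return List with `angle_deg` (NA if isotropic) and `isotropic` flag.
#' @export
dominant_direction <- function(sf, which = c("beta", "lambda"),
                               flat_tol = 0.1) {
  which <- match.arg(which)
  prof <- if (which == "beta") sf$betas else sf$lambdas
  rng <- (max(prof) - min(prof)) / max(abs(prof))
  if (rng < flat_tol)
    return(list(angle_deg = NA_real_, isotropic = TRUE))
  th <- sf$theta_deg %% 180
  ## fold the profile to [0, 180) and average duplicates before the argmax
  agg <- tapply(prof, th, mean)
  ang <- as.numeric(names(agg))
  list(angle_deg = ang[which.max(agg)], isotropic = FALSE)
}
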