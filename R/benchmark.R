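#' Synthetic two-class grain classification benchmark
#'
#' A desk-scale analog of conveyor-line grain quality grading: two
#' dead-leaves grain classes that differ in mean particle radius and in
#' contrast spread are generated, multiscale omnidirectional WD features are
#' extracted, the RBF width of the sparse multikernel LS-SVM is tuned by PSO
#' against cross-validated classification error, and held-out accuracy is
#' reported, both for the full order-1..3 feature set and for order 3 alone.
#'
#' @param seed master seed for scene generation, fold assignment and the
#'   swarm.
#' @param n_train,n_test images per class for training and testing.
#' @param image_size image side length in pixels.
#' @param n_directions orientations per scale.
#' @param scales filter scales.
#' @param pso a [pso_config()] for the RBF-width search.
#' @param sigma_bounds search interval for the RBF width.
#' @return List with `accuracy_g123`, `accuracy_g3` (held-out accuracy, %),
#'   `ce_g123`, `ce_g3`, `rbf_sigma` (tuned width), `n_test` (total held-out
#'   images).
#' @export
grain_benchmark <- function(seed = 1L, n_train = 100L, n_test = 50L,
                            image_size = 80L, n_directions = 36L,
                            scales = c(0.5, 1, 2),
                            pso = pso_config(swarm_size = 10L,
                                             iterations = 15L,
                                             seed = seed),
                            sigma_bounds = c(0.5, 100)) {
  class_a <- grain_scene_config(height = image_size, width = image_size,
                                density = 40, mean_radius = 3,
                                radius_dispersion = 1, elongation = 1.5,
                                contrast_mean = 0.55, contrast_sd = 0.12,
                                background = 0.2, noise_sd = 0.02)
  class_b <- grain_scene_config(height = image_size, width = image_size,
                                density = 40, mean_radius = 6,
                                radius_dispersion = 1, elongation = 1.5,
                                contrast_mean = 0.55, contrast_sd = 0.22,
                                background = 0.2, noise_sd = 0.02)
  n_per <- n_train + n_test
  ds <- generate_labeled_dataset(class_a, class_b, n_per, n_per, seed = seed)
  config <- filter_bank_config(orders = 1:3, scales = scales,
                               n_directions = n_directions)
  feats <- t(vapply(ds$images, extract_features,
                    numeric(length(config$orders) * length(config$scales) *
                              2L * n_directions),
                    config = config))
  ## train/test split: first n_train of each class train, the rest test
  idx_a <- seq_len(n_per)
  idx_b <- n_per + seq_len(n_per)
  tr <- c(idx_a[seq_len(n_train)], idx_b[seq_len(n_train)])
  te <- setdiff(c(idx_a, idx_b), tr)

  fit_eval <- function(cols) {
    x_tr <- feats[tr, cols, drop = FALSE]
    y_tr <- ds$labels[tr]
    obj <- cv_objective(x_tr, y_tr, tunable = "rbf_sigma",
                        kc = kernel_config(), tc = train_config(),
                        folds = 5L, seed = seed)
    best <- pso_optimize(obj, sigma_bounds[1L], sigma_bounds[2L], pso)
    kc <- kernel_config(rbf_sigma = best$par)
    model <- smk_train(x_tr, y_tr, kc, train_config())
    ce <- evaluate_error(model, feats[te, cols, drop = FALSE], ds$labels[te])
    list(ce = ce, sigma = best$par)
  }
  all_cols <- seq_len(ncol(feats))
  g3_cols <- grep("^order3_", colnames(feats))
  r_all <- fit_eval(all_cols)
  r_g3 <- fit_eval(g3_cols)
  list(accuracy_g123 = 100 - r_all$ce, accuracy_g3 = 100 - r_g3$ce,
       ce_g123 = r_all$ce, ce_g3 = r_g3$ce,
       rbf_sigma = r_all$sigma, n_test = length(te))
}
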