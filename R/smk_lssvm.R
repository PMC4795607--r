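#' Sparse multikernel least-squares SVM
#'
#' Binary LS-SVM classifier with class-weighted penalties, a combined
#' polynomial + RBF kernel, and a pivoted Gram-Schmidt (Nystrom-style)
#' sparsification of the kernel matrix. Labels follow the convention
#' -1 = "high quality", +1 = "other quality".
#'
#' @name smk_lssvm
NULL

#' Multikernel configuration
#'
#' @param eta weight of the polynomial kernel in [0, 1]; default 0.4.
#' @param poly_offset polynomial kernel offset c > 0; default 1.
#' @param poly_exponent polynomial exponent d; default 0.25.
#' @param rbf_sigma RBF width sigma > 0; default 1.
#' @return A `kernel_config` list.
#' @export
kernel_config <- function(eta = 0.4, poly_offset = 1, poly_exponent = 0.25,
                          rbf_sigma = 1) {
  if (!is.finite(eta) || eta < 0 || eta > 1) stop("'eta' must be in [0, 1]")
  if (!is.finite(poly_offset) || poly_offset <= 0)
    stop("'poly_offset' must be > 0")
  if (!is.finite(rbf_sigma) || rbf_sigma <= 0)
    stop("'rbf_sigma' must be > 0")
  structure(list(eta = eta, poly_offset = poly_offset,
                 poly_exponent = poly_exponent, rbf_sigma = rbf_sigma),
            class = "kernel_config")
}

#' Combined polynomial + RBF kernel
#'
#' \deqn{K(u, v) = \eta (1 + u^\top v / c)^d +
#'   (1 - \eta) \exp(-\|u - v\|^2 / 2\sigma^2).}
#' With a non-integer exponent d the polynomial part is undefined for a
#' negative base; such bases are clamped at zero with a warning (the
#' combined kernel is then no longer guaranteed to satisfy Mercer's
#' condition -- the solver reports conditioning problems if they arise).
#'
#' @param u,v numeric vectors of equal length.
#' @param kc a [kernel_config()].
#' @return Scalar kernel value.
#' @export
multikernel <- function(u, v, kc = kernel_config()) {
  if (length(u) != length(v)) stop("dimension mismatch")
  drop(multikernel_gram(matrix(u, 1L), matrix(v, 1L), kc))
}

#' Multikernel Gram matrix
#'
#' @param x,y numeric matrices with observations in rows (same number of
#'   columns); `y` defaults to `x`.
#' @param kc a [kernel_config()].
#' @return `nrow(x) x nrow(y)` kernel matrix.
#' @export
multikernel_gram <- function(x, y = x, kc = kernel_config()) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (ncol(x) != ncol(y)) stop("dimension mismatch")
  out <- 0
  if (kc$eta > 0) {
    base <- 1 + tcrossprod(x, y) / kc$poly_offset
    if (kc$poly_exponent %% 1 != 0 && any(base < 0)) {
      warning("negative polynomial-kernel base with non-integer exponent; ",
              "clamped at 0")
      base[base < 0] <- 0
    }
    out <- kc$eta * base^kc$poly_exponent
  }
  if (kc$eta < 1) {
    d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
    d2[d2 < 0] <- 0
    out <- out + (1 - kc$eta) * exp(-d2 / (2 * kc$rbf_sigma^2))
  }
  out + matrix(0, nrow(x), nrow(y))
}

#' Per-sample penalty weights
#'
#' Samples of the positive class get weight `s_plus`, negative class
#' `s_minus`; the effective penalty on sample t is `r * c_t`. The defaults
#' `n / (2 n_plus)` and `n / (2 n_minus)` balance the classes (mean weight 1).
#'
#' @param y labels in {-1, +1}.
#' @param s_plus,s_minus class weights > 0; `NULL` selects the class-balanced
#'   default.
#' @return Numeric weight vector c_t.
#' @export
class_penalties <- function(y, s_plus = NULL, s_minus = NULL) {
  if (!all(y %in% c(-1, 1))) stop("labels must be -1 or +1")
  n <- length(y)
  np <- sum(y == 1); nm <- sum(y == -1)
  if (is.null(s_plus)) s_plus <- n / (2 * np)
  if (is.null(s_minus)) s_minus <- n / (2 * nm)
  if (s_plus <= 0 || s_minus <= 0) stop("class weights must be positive")
  ifelse(y == 1, s_plus, s_minus)
}

#' Solve the LS-SVM bordered linear system
#'
#' The KKT conditions of the weighted LS-SVM reduce to
#' \deqn{\begin{bmatrix} 0 & \mathbf{1}^\top \\ \mathbf{1} &
#'   K + \mathrm{diag}(1/(r c_t)) \end{bmatrix}
#'   \begin{bmatrix} b \\ a \end{bmatrix} =
#'   \begin{bmatrix} 0 \\ y \end{bmatrix},}
#' whose solution satisfies the equality constraint \eqn{\sum_t a_t = 0}.
#'
#' @param gram symmetric kernel matrix K.
#' @param y labels in {-1, +1}.
#' @param r regularization factor > 0; default 8.4.
#' @param penalties per-sample weights c_t (default all ones, the uniform
#'   LS-SVM).
#' @return List with `a` (support coefficients), `b` (bias), `residual`
#'   (infinity norm of the linear-system residual).
#' @export
solve_lssvm <- function(gram, y, r = 8.4, penalties = rep(1, length(y))) {
  n <- length(y)
  if (!all(y %in% c(-1, 1))) stop("labels must be -1 or +1")
  if (!is.matrix(gram) || nrow(gram) != n || ncol(gram) != n)
    stop("'gram' must be an n x n matrix")
  if (r <= 0 || any(penalties <= 0)) stop("'r' and penalties must be > 0")
  h <- gram + diag(1 / (r * penalties), n)
  m <- rbind(c(0, rep(1, n)), cbind(rep(1, n), h))
  rhs <- c(0, y)
  sol <- tryCatch(solve(m, rhs), error = function(e)
    stop("singular LS-SVM system (condition estimate ",
         format(kappa(m)), "): ", conditionMessage(e)))
  list(a = sol[-1L], b = sol[1L],
       residual = max(abs(m %*% sol - rhs)))
}

#' Pivoted Gram-Schmidt sparsification of a kernel matrix
#'
#' Greedy rank-gamma factorization of a PSD Gram matrix: at each step the
#' column with the largest residual diagonal is selected as a pivot and the
#' remaining columns are orthogonalized against it (equivalently, a pivoted
#' incomplete Cholesky of K). The rank-gamma reconstruction
#' `K_hat = L L'` is exact on the pivot block and exact everywhere at
#' gamma = n.
#'
#' @param gram symmetric PSD matrix.
#' @param gamma_rank target rank, 1 <= gamma <= n.
#' @param tol tolerance below which a negative residual diagonal is treated
#'   as a PSD violation, default 1e-8 relative to the largest
#'   diagonal entry.
#' @param on_indefinite what to do when a residual diagonal entry falls
#'   below `-tol`: `"error"` (default) raises a numerical-PSD error;
#'   `"truncate"` excludes the offending indices from further pivoting with
#'   a warning (used by [smk_train()], whose clamped fractional polynomial
#'   kernel is not guaranteed Mercer).
#' @return Object of class `sparse_gram`: `pivots` (selection order),
#'   `L` (n x gamma factor, `K_hat = L %*% t(L)`), `residual_trace`
#'   (trace of `K - K_hat` after each step), `gamma`.
#' @export
schmidt_sparsify <- function(gram, gamma_rank, tol = 1e-8,
                             on_indefinite = c("error", "truncate")) {
  on_indefinite <- match.arg(on_indefinite)
  n <- nrow(gram)
  if (gamma_rank < 1L || gamma_rank > n) stop("'gamma_rank' must be in [1, n]")
  if (max(abs(gram - t(gram))) > 1e-8 * max(abs(gram)))
    stop("'gram' must be symmetric")
  d <- diag(gram)
  scale0 <- max(abs(d), .Machine$double.eps)
  l <- matrix(0, n, gamma_rank)
  pivots <- integer(gamma_rank)
  rtrace <- numeric(gamma_rank)
  warned <- FALSE
  for (t in seq_len(gamma_rank)) {
    if (min(d) < -tol * scale0) {
      if (on_indefinite == "error")
        stop("kernel matrix is not positive semidefinite (residual diagonal ",
             format(min(d)), ")")
      if (!warned) {
        warning("indefinite kernel matrix: ", sum(d < -tol * scale0),
                " direction(s) with negative residual excluded from pivoting")
        warned <- TRUE
      }
      d[d < -tol * scale0] <- 0
    }
    i <- which.max(d)
    if (d[i] <= 1e-14 * scale0) {
      ## residual numerically zero everywhere: the factorization is exact
      ## at rank t - 1 and further pivots would divide by ~0
      pivots <- pivots[seq_len(t - 1L)]
      l <- l[, seq_len(t - 1L), drop = FALSE]
      rtrace <- rtrace[seq_len(t - 1L)]
      break
    }
    pivots[t] <- i
    col <- gram[, i]
    if (t > 1L)
      col <- col - l[, seq_len(t - 1L), drop = FALSE] %*%
        l[i, seq_len(t - 1L)]
    l[, t] <- col / sqrt(d[i])
    d <- d - l[, t]^2
    d[pivots[seq_len(t)]] <- 0
    rtrace[t] <- sum(pmax(d, 0))
  }
  structure(list(pivots = pivots, L = l, residual_trace = rtrace,
                 gamma = length(pivots)),
            class = "sparse_gram")
}

#' Training configuration
#'
#' @param r regularization factor > 0; default 8.4.
#' @param s_plus,s_minus class penalty weights (NULL = class-balanced, see
#'   [class_penalties()]).
#' @param gamma_rank number of support points retained by sparsification;
#'   `NULL` selects `ceiling(0.2 n)`.
#' @param standardize standardize feature columns (training mean/sd) before
#'   kernel evaluation; default TRUE.
#' @return A `train_config` list.
#' @export
train_config <- function(r = 8.4, s_plus = NULL, s_minus = NULL,
                         gamma_rank = NULL, standardize = TRUE) {
  if (!is.finite(r) || r <= 0) stop("'r' must be > 0")
  structure(list(r = r, s_plus = s_plus, s_minus = s_minus,
                 gamma_rank = gamma_rank, standardize = standardize),
            class = "train_config")
}

#' Train the sparse multikernel LS-SVM
#'
#' Builds the multikernel Gram matrix on (optionally standardized) features,
#' selects `gamma_rank` pivots by [schmidt_sparsify()], and solves the
#' weighted LS-SVM bordered system restricted to the pivot set; the decision
#' function uses only the pivot rows, so prediction cost scales with gamma,
#' not n. At `gamma_rank = n` this reduces exactly to the dense weighted
#' LS-SVM.
#'
#' @param x n x p feature matrix.
#' @param y labels in {-1, +1}; both classes must be present.
#' @param kc a [kernel_config()].
#' @param tc a [train_config()].
#' @return Object of class `smk_lssvm`: support indices/rows, coefficients
#'   `a`, bias `b`, kernel config, standardization stats.
#' @export
smk_train <- function(x, y, kc = kernel_config(), tc = train_config()) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (length(y) != n) stop("length(y) must match nrow(x)")
  if (!all(y %in% c(-1, 1)) || length(unique(y)) < 2L)
    stop("need labels in {-1, +1} with both classes present")
  if (any(!is.finite(x))) stop("non-finite feature values")
  if (tc$standardize) {
    mu <- colMeans(x)
    sdv <- apply(x, 2L, stats::sd)
    sdv[sdv == 0] <- 1
  } else {
    mu <- rep(0, ncol(x)); sdv <- rep(1, ncol(x))
  }
  xs <- sweep(sweep(x, 2L, mu), 2L, sdv, "/")
  gamma_rank <- if (is.null(tc$gamma_rank)) ceiling(0.2 * n)
                else min(tc$gamma_rank, n)
  ct <- class_penalties(y, tc$s_plus, tc$s_minus)
  gram <- multikernel_gram(xs, xs, kc)
  sg <- schmidt_sparsify(gram, gamma_rank, on_indefinite = "truncate")
  piv <- sg$pivots
  sol <- solve_lssvm(gram[piv, piv, drop = FALSE], y[piv], tc$r, ct[piv])
  structure(
    list(support_index = piv, support_x = xs[piv, , drop = FALSE],
         a = sol$a, b = sol$b, kernel = kc, r = tc$r,
         penalties = ct, gamma = sg$gamma,
         center = mu, scale = sdv, n_train = n,
         residual = sol$residual),
    class = "smk_lssvm")
}

#' @export
print.smk_lssvm <- function(x, ...) {
  cat(sprintf(
    "SMK-LSSVM: %d support points of %d training samples (eta = %.2f, d = %.2f, sigma = %.3g, r = %.3g)\n",
    x$gamma, x$n_train, x$kernel$eta, x$kernel$poly_exponent,
    x$kernel$rbf_sigma, x$r))
  invisible(x)
}

#' Decision values and labels for new samples
#'
#' \eqn{f(x) = \mathrm{sgn}\left(\sum_{t \in \mathrm{support}} a_t
#' K(x, x_t) + b\right)}; a decision value of exactly 0 maps to +1.
#'
#' @param object a fitted `smk_lssvm` model.
#' @param x matrix (rows = samples) or single feature vector.
#' @param ... unused.
#' @return `data.frame` with columns `decision` and `label`.
#' @export
predict.smk_lssvm <- function(object, x, ...) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != length(object$center)) stop("dimension mismatch")
  xs <- sweep(sweep(x, 2L, object$center), 2L, object$scale, "/")
  k <- multikernel_gram(xs, object$support_x, object$kernel)
  dec <- drop(k %*% object$a) + object$b
  data.frame(decision = dec, label = ifelse(dec >= 0, 1, -1))
}

#' Classification error (CE) in percent
#'
#' \eqn{CE = \frac{1}{N_T}\sum_t \frac{|\hat y_t - y_t|}{2} \times 100\%}.
#'
#' @param model a fitted `smk_lssvm` (or anything with a compatible
#'   `predict` method returning a `label` column).
#' @param x test features.
#' @param y test labels in {-1, +1}.
#' @return Scalar percentage of misclassified samples.
#' @export
evaluate_error <- function(model, x, y) {
  if (length(y) == 0L) stop("empty test set")
  pred <- predict(model, x)$label
  mean(abs(pred - y) / 2) * 100
}
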