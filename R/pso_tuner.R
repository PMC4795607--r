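#' Particle swarm optimization of classifier hyperparameters
#'
#' Constant-inertia PSO: per component,
#' \deqn{v \leftarrow d\,v + c_1 r_1 (P_i - x) + c_2 r_2 (P_g - x), \qquad
#'       x \leftarrow x + v,}
#' with fresh uniform draws r1, r2 in [0, 1] per component per step,
#' positions clipped to the search box and velocities clamped to a fraction
#' of the box width.
#'
#' @name pso_tuner
NULL

#' PSO configuration
#'
#' @param swarm_size number of particles; default 30.
#' @param iterations number of update sweeps; default 100.
#' @param inertia constant inertia weight d in [0, 1]; default 0.7.
#' @param c1,c2 cognitive and social learning rates; default 2.0 each.
#' @param v_clamp velocity bound as a fraction of the per-dimension box
#'   width; default 0.2.
#' @param seed integer seed; all swarm randomness is derived from it.
#' @return A `pso_config` list.
#' @export
pso_config <- function(swarm_size = 30L, iterations = 100L, inertia = 0.7,
                       c1 = 2, c2 = 2, v_clamp = 0.2, seed = 1L) {
  if (inertia < 0 || inertia > 1) stop("'inertia' must be in [0, 1]")
  if (c1 <= 0 || c2 <= 0) stop("learning rates must be > 0")
  structure(list(swarm_size = as.integer(swarm_size),
                 iterations = as.integer(iterations), inertia = inertia,
                 c1 = c1, c2 = c2, v_clamp = v_clamp, seed = seed),
            class = "pso_config")
}

#' Minimize an objective with particle swarm optimization
#'
#' @param objective function mapping a parameter vector to a scalar;
#'   non-finite values are rejected (the candidate never becomes a personal
#'   or global best) with a warning.
#' @param lower,upper numeric vectors of per-dimension box bounds
#'   (finite, lower < upper).
#' @param cfg a [pso_config()].
#' @return List with `par` (best position), `value` (best objective),
#'   `trace` (global best after each iteration, non-increasing).
#' @export
pso_optimize <- function(objective, lower, upper, cfg = pso_config()) {
  p <- length(lower)
  if (length(upper) != p || any(!is.finite(c(lower, upper))) ||
      any(lower >= upper))
    stop("bounds must be finite with lower < upper per dimension")
  width <- upper - lower
  vmax <- cfg$v_clamp * width
  eval_obj <- function(x) {
    v <- objective(x)
    if (!is.finite(v)) {
      warning("non-finite objective value; candidate rejected")
      v <- Inf
    }
    v
  }
  with_seed(cfg$seed, {
    pos <- matrix(stats::runif(cfg$swarm_size * p), cfg$swarm_size, p)
    pos <- sweep(sweep(pos, 2L, width, "*"), 2L, lower, "+")
    vel <- matrix(0, cfg$swarm_size, p)
    pval <- apply(pos, 1L, eval_obj)
    pbest <- pos
    g <- which.min(pval)
    gbest <- pos[g, ]
    gval <- pval[g]
    trace <- numeric(cfg$iterations)
    for (it in seq_len(cfg$iterations)) {
      r1 <- matrix(stats::runif(cfg$swarm_size * p), cfg$swarm_size, p)
      r2 <- matrix(stats::runif(cfg$swarm_size * p), cfg$swarm_size, p)
      vel <- cfg$inertia * vel +
        cfg$c1 * r1 * (pbest - pos) +
        cfg$c2 * r2 * sweep(-pos, 2L, gbest, "+")
      vel <- pmin(pmax(vel, matrix(-vmax, cfg$swarm_size, p, byrow = TRUE)),
                  matrix(vmax, cfg$swarm_size, p, byrow = TRUE))
      pos <- pos + vel
      pos <- pmin(pmax(pos, matrix(lower, cfg$swarm_size, p, byrow = TRUE)),
                  matrix(upper, cfg$swarm_size, p, byrow = TRUE))
      val <- apply(pos, 1L, eval_obj)
      better <- val < pval
      pbest[better, ] <- pos[better, , drop = FALSE]
      pval[better] <- val[better]
      g <- which.min(pval)
      if (pval[g] < gval) {
        gval <- pval[g]
        gbest <- pbest[g, ]
      }
      trace[it] <- gval
    }
    list(par = gbest, value = gval, trace = trace)
  })
}

#' Cross-validated classification-error objective
#'
#' Builds the function a swarm minimizes when tuning classifier
#' hyperparameters: a stratified k-fold split is frozen from `seed`, and the
#' returned closure maps a vector of tunable hyperparameters to the mean
#' held-out classification error (percent) over folds.
#'
#' @param x,y labeled training data (labels in {-1, +1}).
#' @param tunable character vector naming the tuned dimensions, a subset of
#'   `c("s_plus", "s_minus", "rbf_sigma", "poly_exponent")`; the parameter
#'   vector passed to the closure is interpreted in this order.
#' @param kc,tc base kernel and training configurations; tuned fields are
#'   overridden per evaluation.
#' @param folds number of folds, >= 2; every fold must contain both classes.
#' @param seed integer seed freezing the fold assignment.
#' @return Function `par -> mean CE%`.
#' @export
cv_objective <- function(x, y, tunable = "rbf_sigma",
                         kc = kernel_config(), tc = train_config(),
                         folds = 5L, seed = 1L) {
  allowed <- c("s_plus", "s_minus", "rbf_sigma", "poly_exponent")
  if (!all(tunable %in% allowed))
    stop("'tunable' must be a subset of ", paste(allowed, collapse = ", "))
  if (folds < 2L) stop("need at least 2 folds")
  x <- as.matrix(x)
  fold_id <- integer(length(y))
  with_seed(seed, {
    for (cls in c(-1, 1)) {
      idx <- which(y == cls)
      if (length(idx) < folds)
        stop("stratification infeasible: a class has fewer samples than folds")
      idx <- idx[sample.int(length(idx))]
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  force(kc); force(tc)
  function(par) {
    if (length(par) != length(tunable)) stop("hyperparameter length mismatch")
    kci <- kc; tci <- tc
    for (i in seq_along(tunable)) {
      f <- tunable[i]
      if (f %in% c("rbf_sigma", "poly_exponent")) kci[[f]] <- par[i]
      else tci[[f]] <- par[i]
    }
    if (kci$rbf_sigma <= 0) return(Inf)
    ce <- vapply(seq_len(folds), function(k) {
      tr <- fold_id != k
      m <- smk_train(x[tr, , drop = FALSE], y[tr], kci, tci)
      evaluate_error(m, x[!tr, , drop = FALSE], y[!tr])
    }, numeric(1))
    mean(ce)
  }
}
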