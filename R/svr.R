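#' Vectorize a percent-change stack into a predictor matrix
#'
#' Reshapes the depth x width x time percent-change array into a
#' time x pixels matrix restricted to the analysis mask, together with a
#' pixel-index map (column-major grid indices) that makes the reshaping
#' exactly invertible.
#'
#' @param pct a `pct_stack`
#' @param window integer frame indices forming the rows; default all
#'   post-baseline (experiment-period) frames
#' @return list with `X` (time x pixels), `pixel_index` (grid index of
#'   each column), `dim` (grid dimensions), `window`
#' @export
vectorize <- function(pct, window = NULL) {
  stopifnot(inherits(pct, "pct_stack"))
  d <- dim(pct$data)
  if (is.null(window)) window <- seq(pct$baseline_frames + 1, d[3])
  if (length(window) == 0) stop("empty frame window")
  idx <- which(pct$analysis_mask)
  if (length(idx) == 0) stop("empty analysis mask")
  flat <- matrix(pct$data, nrow = d[1] * d[2])
  list(X = t(flat[idx, window, drop = FALSE]),
       pixel_index = idx, dim = d[1:2], window = window)
}

#' Random 80/20 time-point partition
#'
#' Uniform partition without replacement; the test set holds
#' `floor(fraction_test * n)` frames (1254 frames give the printed
#' 1004/250 split).  Deterministic per seed.
#'
#' @param n_frames number of experiment frames (>= 5)
#' @param seed integer seed
#' @param fraction_test held-out fraction (default 0.2)
#' @return object of class `split_index`: list with sorted disjoint
#'   `train_times`, `test_times` (1-based frame indices), `seed`,
#'   `fraction_test`
#' @export
split_80_20 <- function(n_frames, seed = 1L, fraction_test = 0.2) {
  if (n_frames < 5) stop("need at least 5 frames")
  n_test <- floor(fraction_test * n_frames)
  test <- withr_seed(seed, sort(sample.int(n_frames, n_test)))
  structure(list(train_times = setdiff(seq_len(n_frames), test),
                 test_times = test, seed = as.integer(seed),
                 fraction_test = fraction_test),
            class = "split_index")
}

#' Train a linear epsilon-insensitive SVR in the dual
#'
#' Fits \eqn{F(x) = x'\beta + b} by maximizing the Lagrange dual of the
#' epsilon-insensitive loss with ridge penalty
#' \eqn{J(\beta) = \tfrac12 \beta'\beta + C\sum_n(\xi_n + \xi_n^*)},
#' subject to the box constraints \eqn{0 \le a_n, a_n^* \le C} and the
#' equality \eqn{\sum_n (a_n - a_n^*) = 0}.  The solver performs
#' SMO-style pairwise coordinate updates on \eqn{\theta_n = a_n -
#' a_n^*} (a dual stochastic gradient scheme): at each step a
#' KKT-violating coordinate is drawn at random (seeded), paired with
#' the maximally violating partner, and the pair is moved to the exact
#' constrained optimum of the piecewise-quadratic 1D restriction, so
#' the equality constraint holds exactly throughout.  The weight
#' vector is assembled as \eqn{\beta = \sum_n \theta_n x_n} and the
#' bias recovered from the KKT equalities of free support vectors
#' (averaged), or from the midpoint of the feasible bias interval if
#' no multiplier is strictly inside the box.
#'
#' @param X_train numeric matrix (observations x pixels), finite
#' @param y_train numeric response (normalized pressure)
#' @param epsilon half-width of the insensitivity tube; default
#'   `0.1 * sd(y_train)`
#' @param C box constraint (default 1)
#' @param tol KKT violation tolerance (default 1e-6)
#' @param max_passes maximum number of pairwise updates (default
#'   `10 * nrow(X_train)`)
#' @param seed seed for the randomized working-set selection
#' @return object of class `svm_model` with elements `beta`, `bias`,
#'   `alphas`, `alphas_star`, `theta`, `epsilon`, `C`, `xi`, `xi_star`,
#'   `training_objective` (primal J), `dual_objective` (the minimized
#'   dual L; equals -J at the optimum), `kkt_violation`, `converged`,
#'   `n_train`, `seed`
#' @export
train_svr <- function(X_train, y_train, epsilon = NULL, C = 1,
                      tol = 1e-6, max_passes = NULL, seed = 1L) {
  X_train <- as.matrix(X_train)
  if (!all(is.finite(X_train)) || !all(is.finite(y_train))) {
    stop("non-finite entries in training data")
  }
  n <- nrow(X_train)
  stopifnot(length(y_train) == n, n >= 2)
  if (C <= 0) stop("C must be > 0")
  if (is.null(epsilon)) epsilon <- 0.1 * stats::sd(y_train)
  if (epsilon < 0) stop("epsilon must be >= 0")
  if (is.null(max_passes)) max_passes <- 10L * n

  K <- tcrossprod(X_train)          # linear kernel Gram matrix
  fit <- withr_seed(seed, smo_solve(K, y_train, epsilon, C, tol,
                                    as.integer(max_passes)))
  theta <- fit$theta
  Ktheta <- fit$Ktheta
  if (fit$violation > tol) {
    warning("SMO update cap reached before the KKT tolerance (violation ",
            signif(fit$violation, 3), "); model returned unconverged")
  }

  beta <- drop(crossprod(X_train, theta))
  bias <- svr_bias(theta, y_train, Ktheta, epsilon, C)
  f <- Ktheta + bias
  resid <- y_train - f
  xi <- pmax(0, resid - epsilon)
  xi_star <- pmax(0, -resid - epsilon)
  primal <- 0.5 * sum(beta^2) + C * sum(xi + xi_star)
  # Minimized dual form: L = 0.5 th'K th + eps sum|th| - y'th; at the
  # optimum L = -J.
  dual <- 0.5 * sum(theta * Ktheta) + epsilon * sum(abs(theta)) -
    sum(y_train * theta)
  structure(list(beta = beta, bias = bias,
                 alphas = pmax(theta, 0), alphas_star = pmax(-theta, 0),
                 theta = theta, epsilon = epsilon, C = C,
                 xi = xi, xi_star = xi_star,
                 training_objective = primal, dual_objective = dual,
                 kkt_violation = fit$violation, converged = fit$violation <= tol,
                 n_iter = fit$iter, n_train = n, seed = as.integer(seed)),
            class = "svm_model")
}

# bias from KKT equalities: for 0 < theta_i < C, y_i - f_i = eps;
# for -C < theta_i < 0, y_i - f_i = -eps.  f_i = Ktheta_i + b.
svr_bias <- function(theta, y, Ktheta, eps, C) {
  inner <- 1e-8 * max(C, 1)
  free_pos <- theta > inner & theta < C - inner
  free_neg <- theta < -inner & theta > -C + inner
  b_vals <- c(y[free_pos] - Ktheta[free_pos] - eps,
              y[free_neg] - Ktheta[free_neg] + eps)
  if (length(b_vals) > 0) return(mean(b_vals))
  # fall back to the feasible interval from the KKT inequalities
  g <- y - Ktheta
  lo <- suppressWarnings(max(c(g[theta < C - inner] - eps,
                               g[theta < -inner] + eps)))
  hi <- suppressWarnings(min(c(g[theta > -C + inner] + eps,
                               g[theta > inner] - eps)))
  if (!is.finite(lo) && !is.finite(hi)) return(mean(g))
  if (!is.finite(lo)) return(hi)
  if (!is.finite(hi)) return(lo)
  (lo + hi) / 2
}

#' Predict with a trained SVR model
#'
#' Computes \eqn{F(x) = x'\beta + b}.  Setting `form = "dual"` instead
#' evaluates the support-vector expansion
#' \eqn{\sum_n (a_n - a_n^*) x_n' x + b}, which must agree with the
#' primal form to numerical precision.
#'
#' @param object an `svm_model`
#' @param X matrix of observations (columns match training pixels)
#' @param form `"primal"` (default) or `"dual"`
#' @param X_train training matrix, required for `form = "dual"`
#' @param ... unused
#' @return numeric predictions
#' @export
predict.svm_model <- function(object, X, form = c("primal", "dual"),
                              X_train = NULL, ...) {
  form <- match.arg(form)
  X <- as.matrix(X)
  if (ncol(X) != length(object$beta)) {
    stop("column count does not match training (", length(object$beta), ")")
  }
  if (form == "primal") {
    drop(X %*% object$beta) + object$bias
  } else {
    if (is.null(X_train)) stop("X_train required for dual-form prediction")
    drop(X %*% crossprod(X_train, object$theta)) + object$bias
  }
}

#' Reconstruct held-out pressure and score by MSE
#'
#' Predicts the test frames, orders everything by the stored time
#' instants so the predicted and actual curves overlay the experiment
#' timeline, and reports the mean squared error on the normalized
#' scale.
#'
#' @param model an `svm_model`
#' @param X_test test predictor matrix (rows in `test_times` order)
#' @param y_test actual normalized pressure at the test frames
#' @param test_times frame indices of the test rows
#' @return object of class `reconstruction_result`: list with
#'   `test_times`, `y_true`, `y_pred` (time-ordered) and `mse`
#' @export
reconstruct_and_score <- function(model, X_test, y_test, test_times) {
  if (length(test_times) == 0) stop("empty test set")
  stopifnot(nrow(X_test) == length(y_test),
            length(y_test) == length(test_times))
  ord <- order(test_times)
  y_pred <- predict(model, X_test)
  structure(list(test_times = test_times[ord],
                 y_true = y_test[ord], y_pred = y_pred[ord],
                 mse = mean((y_test - y_pred)^2)),
            class = "reconstruction_result")
}

#' @export
print.reconstruction_result <- function(x, ...) {
  cat(sprintf("reconstruction_result: %d test frames, MSE = %.5f\n",
              length(x$test_times), x$mse))
  invisible(x)
}

#' @export
print.svm_model <- function(x, ...) {
  cat(sprintf(
    "svm_model: %d train obs, %d pixels, eps=%.4g, C=%g, %s (KKT viol %.2g, %d updates)\n",
    x$n_train, length(x$beta), x$epsilon, x$C,
    if (x$converged) "converged" else "NOT converged",
    x$kkt_violation, x$n_iter))
  invisible(x)
}

#' Project the SVR weights back to image space
#'
#' @param model an `svm_model`
#' @param pixel_index grid indices of the predictor columns (from
#'   [vectorize()])
#' @param dim grid dimensions (depth, width)
#' @return matrix with masked-out pixels 0; `beta_map(...)[pixel_index]`
#'   recovers the flat weight vector exactly
#' @export
beta_map <- function(model, pixel_index, dim) {
  if (length(pixel_index) != length(model$beta)) {
    stop("pixel index map does not match the weight vector")
  }
  g <- matrix(0, dim[1], dim[2])
  g[pixel_index] <- model$beta
  g
}

#' Signed sums of all and of the top-fraction beta weights
#'
#' @param model an `svm_model`
#' @param fraction top fraction by |beta| (default 0.05)
#' @return list with `sum_total`, `sum_top_fraction`, `top_mask`
#'   (logical over predictor columns)
#' @export
beta_summary <- function(model, fraction = 0.05) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  beta <- model$beta
  n_top <- ceiling(fraction * length(beta))
  top_idx <- order(abs(beta), decreasing = TRUE)[seq_len(n_top)]
  top_mask <- logical(length(beta))
  top_mask[top_idx] <- TRUE
  list(sum_total = sum(beta),
       sum_top_fraction = sum(beta[top_mask]),
       top_mask = top_mask)
}
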