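#' Smallest penalty shrinking every Lasso weight to zero
#'
#' Under the objective `(1/2N) * RSS + lam * ||beta||_1`, all weights are zero
#' exactly when `lam >= max_j |sum_i x_ij (y_i - mean(y))| / N` (features
#' centered).
#'
#' @param X Feature matrix (rows = observations).
#' @param y Numeric targets.
#' @return The critical penalty `lambda_max`.
#' @export
lasso_lambda_max <- function(X, y) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  Xc <- sweep(X, 2, colMeans(X))
  max(abs(crossprod(Xc, y - mean(y)))) / nrow(X)
}

#' Fit an L1-regularized linear (Lasso) angle model
#'
#' Minimizes \deqn{\frac{1}{2N}\sum_i (\beta' x_i + \beta'_0 - y_i)^2 +
#' \lambda \sum_j |\beta_j|} by cyclic coordinate descent with
#' soft-thresholding, warm-started active-set iteration, and an unpenalized
#' intercept. This is the squared-error (Gaussian-deviance) generalized
#' linear model with identity link; the L1 term performs the region/feature
#' selection.
#'
#' @param X Feature matrix, one observation per row (region features `S` or
#'   augmented features).
#' @param y Scalar targets (wrist angle of one DoF, degrees).
#' @param lam Penalty weight, >= 0.
#' @param tol Convergence tolerance: the fit stops when the largest
#'   standardized coefficient change in a sweep, `|d_j| * sd(x_j) / sd(y)`,
#'   falls below `tol` (scale-free in both features and targets).
#' @param maxit Sweep cap.
#' @param dof_label Optional DoF name carried on the model.
#' @return Object of class `lasso_model`: `beta`, `beta0`, `lam`,
#'   `dof_label`, `n_sweeps`.
#' @examples
#' X <- matrix(rnorm(60), 20, 3); y <- X %*% c(1, 0, -2) + rnorm(20, sd = .1)
#' m <- fit_lasso(X, y, lam = 0.05)
#' predict(m, X)[1:3]
#' @export
fit_lasso <- function(X, y, lam, tol = 1e-4, maxit = 1e5, dof_label = NA_character_) {
  stopifnot(is.matrix(X), nrow(X) >= 2, nrow(X) == length(y), lam >= 0)
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    stop("data error: non-finite values in features or targets", call. = FALSE)
  }
  # small penalties are reached pathwise (warm starts from lambda_max):
  # same convex optimum, far fewer sweeps than a cold start
  lpath <- lam
  if (lam > 0) {
    lmax <- lasso_lambda_max(X, y)
    if (lam < lmax) {
      nstep <- max(2, ceiling(log(lmax / lam) / log(10) * 5))
      lpath <- exp(seq(log(lmax), log(lam), length.out = nstep))
    }
  }
  fit <- .lasso_cd_path(X, as.numeric(y), lambda = lpath, tol = tol,
                        maxit = as.integer(maxit), trace = FALSE)
  k <- length(lpath)
  structure(list(beta = fit$beta[, k], beta0 = fit$beta0[k], lam = lam,
                 dof_label = dof_label, n_sweeps = sum(fit$sweeps)),
            class = "lasso_model")
}

#' Lasso solution path over a decreasing penalty grid
#'
#' Fits the whole regularization path with warm starts. When `lambda` is not
#' supplied, a log-spaced grid of `nlambda` values over
#' `[lambda_min_ratio, 1] * lambda_max` is used.
#'
#' @inheritParams fit_lasso
#' @param lambda Optional decreasing penalty grid.
#' @param nlambda,lambda_min_ratio Grid construction parameters.
#' @return Object of class `lasso_path`: `lambda`, `beta` (p x nlambda),
#'   `beta0`.
#' @export
lasso_path <- function(X, y, lambda = NULL, nlambda = 50, lambda_min_ratio = 1e-4,
                       tol = 1e-4, maxit = 1e5) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (is.null(lambda)) {
    lmax <- lasso_lambda_max(X, y)
    if (lmax <= 0) lmax <- 1e-12
    lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
  }
  lambda <- sort(lambda, decreasing = TRUE)
  fit <- .lasso_cd_path(X, as.numeric(y), lambda = lambda, tol = tol,
                        maxit = as.integer(maxit), trace = FALSE)
  structure(list(lambda = lambda, beta = fit$beta, beta0 = fit$beta0),
            class = "lasso_path")
}

#' Predict wrist angles from a Lasso model
#'
#' Affine prediction `beta' x + beta0`.
#'
#' @param object A `lasso_model`.
#' @param X Feature matrix with the training feature dimension.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.lasso_model <- function(object, X, ...) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (ncol(X) != length(object$beta)) {
    stop("prediction error: feature dimension mismatch", call. = FALSE)
  }
  as.vector(X %*% object$beta) + object$beta0
}

#' @rdname predict.lasso_model
#' @param m A `lasso_model`.
#' @export
predict_lasso <- function(m, X) predict.lasso_model(m, X)

#' Fit an epsilon-insensitive RBF support vector regressor
#'
#' Solves the usual SVR dual quadratic program (box constraints `[0, C]` on
#' each dual pair, equality constraint `sum(alpha - alpha*) = 0`) with the
#' radial basis kernel `exp(-gamma * ||u - v||^2)`. Residuals smaller than
#' `eps` are not penalized; `C` prices the excess. Fitting is delegated to
#' the libsvm SMO solver; the fitted model is stored in dual form and
#' predictions are evaluated directly from the kernel expansion.
#'
#' @param X Feature matrix.
#' @param y Scalar targets.
#' @param C Error-cost constant (> 0).
#' @param eps Tube half-width (>= 0).
#' @param gamma RBF width (> 0). The kernel-width symbol is named `gamma`
#'   here to avoid any collision with the conductivity sigma.
#' @param tol SMO termination tolerance.
#' @param dof_label Optional DoF name.
#' @return Object of class `svr_model`: `alpha`, `alpha_star` (full-length,
#'   complementary), `coefs` (= alpha - alpha*), `b`, `support_inputs`,
#'   `support_index`, and the hyperparameters.
#' @export
fit_svr <- function(X, y, C = 1, eps = 0.1, gamma = 1, tol = 1e-6,
                    dof_label = NA_character_) {
  stopifnot(is.matrix(X), nrow(X) == length(y), C > 0, eps >= 0, gamma > 0)
  sv <- e1071::svm(x = X, y = as.numeric(y), type = "eps-regression",
                   kernel = "radial", cost = C, epsilon = eps, gamma = gamma,
                   scale = FALSE, tolerance = tol, fitted = FALSE)
  n <- nrow(X)
  coefs <- numeric(n)
  coefs[sv$index] <- as.vector(sv$coefs)
  structure(list(alpha = pmax(coefs, 0), alpha_star = pmax(-coefs, 0),
                 coefs = coefs, b = -sv$rho,
                 support_index = sv$index,
                 support_inputs = X[sv$index, , drop = FALSE],
                 C = C, eps = eps, gamma = gamma, dof_label = dof_label),
            class = "svr_model")
}

# RBF kernel block between row sets
.rbf_kernel <- function(A, B, gamma) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

#' Predict wrist angles from an SVR model
#'
#' Evaluates the kernel expansion
#' `sum_i (alpha_i - alpha_i*) kappa(x_i, x) + b` over the support vectors.
#'
#' @param object An `svr_model`.
#' @param X Feature matrix.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.svr_model <- function(object, X, ...) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (ncol(X) != ncol(object$support_inputs)) {
    stop("prediction error: feature dimension mismatch", call. = FALSE)
  }
  if (nrow(object$support_inputs) == 0) return(rep(object$b, nrow(X)))
  K <- .rbf_kernel(X, object$support_inputs, object$gamma)
  as.vector(K %*% object$coefs[object$support_index]) + object$b
}

#' @rdname predict.svr_model
#' @param m An `svr_model`.
#' @export
predict_svr <- function(m, X) predict.svr_model(m, X)

#' Fit one scalar model per wrist degree of freedom
#'
#' Trains three independent scalar regressors (F/E, RD/UD, P/S) of the same
#' kind on a shared feature matrix; hyperparameters may differ per DoF.
#'
#' @param X Feature matrix (region features or augmented features).
#' @param Y n x 3 matrix of angles, columns in DoF order F/E, RD/UD, P/S.
#' @param kind `"lasso"` or `"svr"`.
#' @param hyper Hyperparameters: a single named list applied to every DoF
#'   (e.g. `list(lam = 0.01)` or `list(C = 1, eps = 0.1, gamma = 0.5)`), or a
#'   list of three such lists.
#' @param feature_mode `"normal"` (region means) or `"augmented"`.
#' @return Object of class `multidof_model`: `models` (list of 3), `kind`,
#'   `feature_mode`.
#' @export
fit_multidof <- function(X, Y, kind = c("lasso", "svr"), hyper,
                         feature_mode = c("normal", "augmented")) {
  kind <- match.arg(kind)
  feature_mode <- match.arg(feature_mode)
  stopifnot(is.matrix(Y), ncol(Y) == 3, nrow(Y) == nrow(X))
  per_dof <- if (!is.null(names(hyper))) rep(list(hyper), 3) else hyper
  stopifnot(length(per_dof) == 3)
  models <- lapply(1:3, function(k) {
    h <- per_dof[[k]]
    if (kind == "lasso") {
      fit_lasso(X, Y[, k], lam = h$lam, dof_label = .dof_names[k])
    } else {
      fit_svr(X, Y[, k], C = h$C, eps = h$eps, gamma = h$gamma,
              dof_label = .dof_names[k])
    }
  })
  names(models) <- .dof_names
  structure(list(models = models, kind = kind, feature_mode = feature_mode),
            class = "multidof_model")
}

#' Predict all three DoF angles
#'
#' @param object A `multidof_model`.
#' @param X Feature matrix.
#' @param ... Unused.
#' @return n x 3 matrix of predicted angles (F/E, RD/UD, P/S).
#' @export
predict.multidof_model <- function(object, X, ...) {
  out <- vapply(object$models, function(m) predict(m, X), numeric(nrow(X)))
  colnames(out) <- .dof_names
  out
}

#' @export
print.lasso_model <- function(x, ...) {
  cat(sprintf("Lasso model (%s): %d/%d non-zero weights, lam = %.4g\n",
              x$dof_label, sum(x$beta != 0), length(x$beta), x$lam))
  invisible(x)
}

#' @export
print.svr_model <- function(x, ...) {
  cat(sprintf("RBF SVR model (%s): %d support vectors, C = %g, eps = %g, gamma = %g\n",
              x$dof_label, length(x$support_index), x$C, x$eps, x$gamma))
  invisible(x)
}

#' @export
print.multidof_model <- function(x, ...) {
  cat(sprintf("Multi-DoF %s model on %s features\n", x$kind, x$feature_mode))
  for (m in x$models) print(m)
  invisible(x)
}
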