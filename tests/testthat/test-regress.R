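test_that("lasso at lam = 0 reproduces the normal-equations solution", {
  set.seed(1)
  X <- matrix(rnorm(80), 40, 2)
  y <- 2 + X %*% c(1.5, -0.7) + rnorm(40, sd = 0.3)
  m <- fit_lasso(X, y, lam = 0, tol = 1e-9)
  ols <- solve(crossprod(cbind(1, X)), crossprod(cbind(1, X), y))
  expect_lt(max(abs(c(m$beta0, m$beta) - ols)), 1e-6)
  expect_equal(predict(m, X), as.vector(cbind(1, X) %*% ols), tolerance = 1e-6)
})

test_that("single standardized feature obeys the soft-threshold closed form", {
  set.seed(2)
  n <- 50
  x <- rnorm(n); x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))  # sum(x^2) = n
  y <- x + rnorm(n, sd = 1e-12)          # OLS slope 1.0
  m <- fit_lasso(matrix(x), y, lam = 0.4, tol = 1e-10)
  expect_equal(m$beta, 0.6, tolerance = 1e-6)
  m2 <- fit_lasso(matrix(x), y, lam = 1.2)   # beyond lambda_max = 1.0
  expect_equal(m2$beta, 0)
  expect_equal(m2$beta0, mean(y))
})

test_that("penalties at or above lambda_max give the all-zero model", {
  set.seed(3)
  X <- matrix(rnorm(200), 50, 4)
  y <- X %*% c(1, 2, 0, -1) + rnorm(50)
  lmax <- lasso_lambda_max(X, y)
  m <- fit_lasso(X, y, lam = lmax * (1 + 1e-12))
  expect_true(all(m$beta == 0))
  expect_equal(m$beta0, mean(y))
  m2 <- fit_lasso(X, y, lam = lmax * 0.9, tol = 1e-8)
  expect_gt(sum(m2$beta != 0), 0)
})

test_that("coordinate-descent objective is non-increasing across sweeps", {
  set.seed(4)
  X <- matrix(rnorm(600), 30, 20)
  X <- X + X[, c(20, 1:19)]               # induce correlation
  y <- X %*% rnorm(20) + rnorm(30)
  fit <- eitwrist:::.lasso_cd_path(X, as.numeric(y), lambda = 0.05,
                                   tol = 1e-10, maxit = 1000L, trace = TRUE)
  obj <- fit$objective
  expect_gt(length(obj), 2)
  expect_true(all(diff(obj) <= 1e-10))
})

test_that("lasso path agrees with glmnet across the grid", {
  skip_if_not_installed("glmnet")
  set.seed(5)
  X <- matrix(rnorm(1500), 50, 30)
  y <- X %*% c(rep(2, 3), rep(0, 27)) + rnorm(50, sd = 0.5)
  lam <- c(0.5, 0.1, 0.02)
  p <- lasso_path(X, y, lambda = lam, tol = 1e-8)
  g <- glmnet::glmnet(X, y, lambda = lam, standardize = FALSE, thresh = 1e-14)
  expect_lt(max(abs(p$beta - as.matrix(g$beta))), 1e-5)
  expect_lt(max(abs(p$beta0 - g$a0)), 1e-5)
})

test_that("SVR on a constant target fits inside the tube with zero duals", {
  X <- matrix(seq(0, 1, length.out = 10))
  m <- fit_svr(X, rep(3, 10), C = 10, eps = 0.1, gamma = 1)
  expect_equal(sum(abs(m$coefs)), 0)
  expect_equal(predict(m, X), rep(3, 10), tolerance = 1e-8)
})

test_that("RBF kernel is 1 at zero distance", {
  A <- matrix(rnorm(6), 2, 3)
  K <- eitwrist:::.rbf_kernel(A, A, gamma = 0.7)
  expect_equal(diag(K), c(1, 1))
  expect_true(all(K <= 1 + 1e-12))
})

test_that("SVR matches the dense dual-QP oracle on a 3-point toy", {
  X <- matrix(c(0, 1, 2))
  y <- c(0, 1, 2)
  C <- 100; eps <- 0.1; gamma <- 0.5
  m <- fit_svr(X, y, C = C, eps = eps, gamma = gamma, tol = 1e-8)
  # training points inside/at the tube
  expect_lt(max(abs(predict(m, X) - y)), eps + 1e-3)
  oracle <- svr_dual_oracle(X, y, C, eps, gamma)
  xs <- matrix(seq(-0.5, 2.5, by = 0.25))
  expect_lt(max(abs(predict(m, xs) - oracle$predict(xs))), 1e-4)
})

test_that("SVR duals satisfy box, complementarity and equality constraints", {
  set.seed(6)
  X <- matrix(rnorm(40), 20, 2)
  y <- sin(X[, 1]) + rnorm(20, sd = 0.05)
  m <- fit_svr(X, y, C = 5, eps = 0.05, gamma = 1, tol = 1e-8)
  expect_true(all(m$alpha >= -1e-8 & m$alpha <= 5 + 1e-8))
  expect_true(all(m$alpha_star >= -1e-8 & m$alpha_star <= 5 + 1e-8))
  expect_true(all(m$alpha * m$alpha_star == 0))
  expect_lt(abs(sum(m$alpha - m$alpha_star)), 1e-8)
  # prediction at a free support vector sits on the tube boundary
  free <- which(abs(m$coefs) > 1e-6 & abs(m$coefs) < 5 * (1 - 1e-6))
  if (length(free)) {
    resid <- abs(predict(m, X[free, , drop = FALSE]) - y[free])
    expect_lt(max(abs(resid - m$eps)), 1e-3)
  }
})

test_that("multi-DoF fitting is independent per column", {
  set.seed(7)
  X <- matrix(rnorm(300), 50, 6)
  y1 <- X %*% c(1, -1, 0, 0, 0, 0) + rnorm(50, sd = 0.1)
  Y <- cbind(y1, y1, y1)
  m <- fit_multidof(X, Y, kind = "lasso", hyper = list(lam = 0.05),
                    feature_mode = "normal")
  expect_equal(m$models$fe$beta, m$models$rdud$beta)
  expect_equal(m$models$fe$beta, m$models$ps$beta)

  y2 <- X %*% c(0, 0, 2, 0, 0, 0) + rnorm(50, sd = 0.1)
  Yp <- cbind(y1, y2, y1)
  mp <- fit_multidof(X, Yp, kind = "lasso", hyper = list(lam = 0.05),
                     feature_mode = "normal")
  mrev <- fit_multidof(X, Yp[, c(2, 1, 3)], kind = "lasso",
                       hyper = list(lam = 0.05), feature_mode = "normal")
  expect_equal(mp$models$fe$beta, mrev$models$rdud$beta)
  expect_equal(dim(predict(mp, X)), c(50L, 3L))
})
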