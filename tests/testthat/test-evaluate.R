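# tiny deterministic "sessions" with a planted linear feature-angle map
.make_linear_sessions <- function(n_per_seg = 30, noise = 0.01, seed = 10) {
  set.seed(seed)
  make_one <- function() {
    seg <- rep(c("fe", "rdud", "ps"), each = n_per_seg)
    Y <- matrix(0, 3 * n_per_seg, 3)
    for (d in 1:3) {
      idx <- (d - 1) * n_per_seg + seq_len(n_per_seg)
      Y[idx, d] <- 40 * sin(seq(0, 4 * pi, length.out = n_per_seg))
      Y[idx, -d] <- rnorm(2 * n_per_seg, sd = 0.5)
    }
    # features 1..3 track the three angles; feature 4 is a mixture
    X <- cbind(Y, Y %*% c(0.5, -0.2, 0.1)) + rnorm(4 * 3 * n_per_seg, sd = noise)
    session_data(X, Y, seg)
  }
  list(make_one(), make_one())
}

test_that("metric formulas match hand-computed values", {
  y <- c(0, 1, 2); yhat <- c(0, 1, 4)
  expect_equal(rmse(y, yhat), sqrt(4 / 3))
  expect_equal(nrmse(y, yhat), sqrt(4 / 3) / 2)
  expect_equal(r2(y, yhat), -1)

  expect_equal(rmse(y, y), 0)
  expect_equal(nrmse(y, y), 0)
  expect_equal(r2(y, y), 1)
  expect_equal(r2(y, rep(mean(y), 3)), 0)
})

test_that("nrmse is invariant under joint affine rescaling", {
  set.seed(12)
  y <- rnorm(40); yhat <- y + rnorm(40, sd = 0.3)
  for (a in c(0.5, 3)) {
    expect_equal(nrmse(a * y + 7, a * yhat + 7), nrmse(y, yhat))
  }
})

test_that("degenerate constant references raise errors, not NaN", {
  expect_error(nrmse(rep(1, 5), rnorm(5)), "constant")
  expect_error(r2(rep(1, 5), rnorm(5)), "constant")
})

test_that("hyperparameter selection returns the CV-MSE minimizer with documented tie-breaks", {
  set.seed(13)
  X <- matrix(rnorm(300), 100, 3)
  y <- X %*% c(2, -1, 0) + rnorm(100, sd = 0.05)

  one <- select_hyperparams(X, y, data.frame(lam = 0.02), k = 3)
  expect_equal(one$best$lam, 0.02)

  # planted sparse linear truth: small penalties achieve near-zero CV MSE
  sel <- select_hyperparams(X, y, data.frame(lam = c(2, 0.2, 0.002)), k = 3)
  expect_equal(sel$best$lam, 0.002)
  expect_lt(min(sel$cv$mse), 0.01)

  # exact tie -> larger lam preferred (zero features: every lam fits the mean)
  ytie <- rep(c(-1, 1), 50)
  Xz <- matrix(0, 100, 2)
  tie <- select_hyperparams(Xz, ytie, data.frame(lam = c(0.1, 0.9, 0.5)), k = 2)
  expect_equal(tie$best$lam, 0.9)

  expect_error(select_hyperparams(X, y, data.frame(), k = 3), "config error")
})

test_that("segment-stratified folds keep every segment in every training fold", {
  seg <- rep(c("fe", "rdud", "ps"), each = 30)
  set.seed(14)
  X <- matrix(rnorm(90 * 2), 90, 2)
  y <- X[, 1] * ifelse(seg == "fe", 5, 1) + rnorm(90, sd = 0.1)
  sel <- select_hyperparams(X, y, data.frame(lam = c(1e-3, 1e-2)), k = 3,
                            segment = seg)
  expect_true(sel$best$lam %in% c(1e-3, 1e-2))
})

test_that("session CV averages fold metrics and reports per DoF", {
  sessions <- .make_linear_sessions()
  rep1 <- session_cv(sessions, kind = "lasso", feature_mode = "normal",
                     hyper = list(lam = 1e-4), cross_table = TRUE)
  expect_equal(rep1$per_dof$dof, c("fe", "rdud", "ps"))
  expect_true(all(rep1$per_dof$r2 > 0.98))

  # averaged metrics equal the arithmetic mean of the fold metrics
  manual <- (rep1$folds[[1]] + rep1$folds[[2]]) / 2
  expect_equal(as.matrix(rep1$per_dof[, c("rmse", "nrmse", "r2")]),
               manual, ignore_attr = TRUE)

  # identical sessions -> averaged metrics equal single-split metrics
  twin <- list(sessions[[1]], sessions[[1]])
  rep2 <- session_cv(twin, kind = "lasso", feature_mode = "normal",
                     hyper = list(lam = 1e-4), cross_table = FALSE)
  expect_equal(rep2$folds[[1]], rep2$folds[[2]])
  expect_equal(as.matrix(rep2$per_dof[, c("rmse", "nrmse", "r2")]),
               rep2$folds[[1]], ignore_attr = TRUE)
})

test_that("cross table separates principal from transfer DoFs on planted data", {
  sessions <- .make_linear_sessions()
  rep1 <- session_cv(sessions, kind = "lasso", feature_mode = "normal",
                     hyper = list(lam = 1e-4), cross_table = TRUE)
  ct <- rep1$cross_table$nrmse
  expect_equal(dim(ct), c(3L, 3L))
  expect_lt(mean(diag(ct)), mean(ct[row(ct) != col(ct)]))
})

test_that("selection summary counts non-zeros, diagonal terms and region endpoints", {
  M <- 6
  p_aug <- M * (M + 1) / 2
  # minimal fake grid and multidof model with planted sparsity
  grid <- structure(list(M = M, regions = as.list(1:M), K = rep(1, M),
                         element_region = 1:M, n_elements = M,
                         cell_size = 1, origin = c(0, 0)),
                    class = "eit_region_grid")
  mk <- function(nz_idx, vals) {
    beta <- numeric(p_aug); beta[nz_idx] <- vals
    structure(list(beta = beta, beta0 = 0, lam = 0.1, dof_label = "fe"),
              class = "lasso_model")
  }
  # flat index of (i, j): row-major upper triangle
  flat <- function(i, j) (i - 1) * (2 * M - i + 2) / 2 + (j - i + 1)
  m <- structure(list(models = list(fe = mk(flat(3, 3), 1),
                                    rdud = mk(flat(1, 2), 2),
                                    ps = mk(integer(0), numeric(0))),
                      kind = "lasso", feature_mode = "augmented"),
                 class = "multidof_model")
  ss <- selection_summary(m, grid)
  expect_equal(ss$per_dof$n_nonzero, c(1L, 1L, 0L))
  expect_equal(ss$per_dof$n_diag, c(1L, 0L, 0L))
  expect_equal(unname(ss$region_heat[3, "fe"]), 2L)           # (3,3): both endpoints
  expect_equal(unname(ss$region_heat[1, "rdud"]), 1L)
  expect_equal(unname(ss$region_heat[2, "rdud"]), 1L)
  expect_equal(sum(ss$region_heat[, "ps"]), 0L)

  bad <- m; bad$kind <- "svr"
  expect_error(selection_summary(bad, grid), "contract error")
})
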