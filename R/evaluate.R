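#' Estimation-error metrics
#'
#' `rmse()` is the root-mean-square error in degrees; `nrmse()` divides it by
#' the range `max(y) - min(y)` of the reference angles; `r2()` is the
#' coefficient of determination `1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`.
#' `nrmse()` and `r2()` are undefined for a constant reference signal and
#' raise an error rather than returning NaN.
#'
#' @param y Reference angles (degrees).
#' @param yhat Estimated angles, same length.
#' @return A single number.
#' @examples
#' rmse(c(0, 1, 2), c(0, 1, 4))   # sqrt(4/3)
#' r2(c(0, 1, 2), c(0, 1, 4))     # -1
#' @export
rmse <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2)
  sqrt(mean((yhat - y)^2))
}

#' @rdname rmse
#' @export
nrmse <- function(y, yhat) {
  rng <- max(y) - min(y)
  if (rng == 0) {
    stop("undefined metric: reference signal is constant (zero range)", call. = FALSE)
  }
  rmse(y, yhat) / rng
}

#' @rdname rmse
#' @export
r2 <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2)
  ss <- sum((y - mean(y))^2)
  if (ss == 0) {
    stop("undefined metric: reference signal is constant (zero variance)", call. = FALSE)
  }
  1 - sum((y - yhat)^2) / ss
}

.metric_row <- function(y, yhat) {
  c(rmse = rmse(y, yhat), nrmse = nrmse(y, yhat), r2 = r2(y, yhat))
}

#' Bundle one session's data for cross-validation
#'
#' @param features Feature matrix, one row per frame.
#' @param angles n x 3 matrix of reference angles (F/E, RD/UD, P/S).
#' @param segment Factor/character of length n: which DoF was being exercised
#'   (`"fe"`, `"rdud"`, `"ps"`), used for the single-DoF cross table.
#' @return Object of class `eit_session_data`.
#' @export
session_data <- function(features, angles, segment) {
  stopifnot(is.matrix(features), is.matrix(angles), ncol(angles) == 3,
            nrow(features) == nrow(angles), length(segment) == nrow(features))
  segment <- factor(as.character(segment), levels = .segment_levels)
  if (anyNA(segment)) stop("segment labels must be rest/fe/rdud/ps", call. = FALSE)
  structure(list(features = features, angles = angles, segment = segment),
            class = "eit_session_data")
}

#' Hyperparameter selection by k-fold cross-validation on training data
#'
#' Evaluates every grid row by k-fold CV mean squared error on the training
#' set and returns the minimizer. Folds are contiguous blocks in time (no
#' shuffling), which respects the serial correlation of motion data; when the
#' recording is segmented by DoF, pass `segment` so each segment is split
#' into k contiguous blocks and block f of every segment forms fold f --
#' otherwise plain thirds of a three-segment session would each delete one
#' DoF's entire signal from the training folds. Ties break toward stronger
#' regularization: larger `lam` for Lasso, smaller `C` (then larger `eps`)
#' for SVR.
#'
#' @param X Training feature matrix.
#' @param y Training targets for one DoF.
#' @param grid Data frame of candidate hyperparameters: a `lam` column
#'   (Lasso) or `C`, `eps`, `gamma` columns (SVR).
#' @param k Number of folds (default 3).
#' @param segment Optional per-sample segment labels for stratified
#'   contiguous folds.
#' @return List: `best` (named list of chosen hyperparameters), `cv` (the
#'   grid with a `mse` column).
#' @export
select_hyperparams <- function(X, y, grid, k = 3, segment = NULL) {
  stopifnot(is.matrix(X), nrow(X) == length(y), k >= 2)
  if (!is.data.frame(grid) || nrow(grid) == 0) {
    stop("config error: hyperparameter grid is empty", call. = FALSE)
  }
  n <- nrow(X)
  if (is.null(segment)) {
    fold <- cut(seq_len(n), breaks = k, labels = FALSE)
  } else {
    stopifnot(length(segment) == n)
    fold <- integer(n)
    for (lev in unique(segment)) {
      idx <- which(segment == lev)
      fold[idx] <- cut(seq_along(idx), breaks = k, labels = FALSE)
    }
  }
  is_lasso <- "lam" %in% names(grid)
  mse <- matrix(NA_real_, nrow(grid), k)
  for (f in seq_len(k)) {
    tr <- fold != f
    if (is_lasso) {
      path <- lasso_path(X[tr, , drop = FALSE], y[tr],
                         lambda = sort(grid$lam, decreasing = TRUE))
      ord <- match(path$lambda, grid$lam)
      pred <- X[!tr, , drop = FALSE] %*% path$beta
      pred <- sweep(pred, 2, path$beta0, "+")
      mse[ord, f] <- colMeans((pred - y[!tr])^2)
    } else {
      for (g in seq_len(nrow(grid))) {
        m <- fit_svr(X[tr, , drop = FALSE], y[tr], C = grid$C[g],
                     eps = grid$eps[g], gamma = grid$gamma[g])
        mse[g, f] <- mean((predict(m, X[!tr, , drop = FALSE]) - y[!tr])^2)
      }
    }
  }
  cv <- cbind(grid, mse = rowMeans(mse))
  cand <- which(cv$mse == min(cv$mse))
  if (length(cand) > 1) {
    if (is_lasso) {
      cand <- cand[which.max(grid$lam[cand])]
    } else {
      o <- order(grid$C[cand], -grid$eps[cand])
      cand <- cand[o[1]]
    }
  }
  best <- as.list(grid[cand, , drop = FALSE])
  list(best = best, cv = cv)
}

#' Default hyperparameter grids
#'
#' Lasso: 50 log-spaced penalties over `[1e-4, 1] * lambda_max`. SVR:
#' `C in {0.1, 1, 10, 100}` crossed with `eps in {0.01, 0.1} * sd(y)` and
#' `gamma in {0.01, 0.1, 1} / median squared inter-sample distance`.
#'
#' @param X Training features.
#' @param y Training targets.
#' @param kind `"lasso"` or `"svr"`.
#' @param nlambda Grid size for Lasso.
#' @return Data frame grid for [select_hyperparams()].
#' @export
default_grid <- function(X, y, kind = c("lasso", "svr"), nlambda = 50) {
  kind <- match.arg(kind)
  if (kind == "lasso") {
    lmax <- lasso_lambda_max(X, y)
    if (lmax <= 0) lmax <- 1e-12
    data.frame(lam = exp(seq(log(lmax), log(lmax * 1e-4), length.out = nlambda)))
  } else {
    ns <- min(nrow(X), 200L)
    sub <- X[seq.int(1L, nrow(X), length.out = ns), , drop = FALSE]
    d2 <- stats::median(stats::dist(sub)^2)
    if (!is.finite(d2) || d2 <= 0) d2 <- 1
    expand.grid(C = c(0.1, 1, 10, 100),
                eps = c(0.01, 0.1) * stats::sd(y),
                gamma = c(0.01, 0.1, 1) / d2)
  }
}

.fit_with_selection <- function(X, y, kind, hyper, grid, cv_folds, dof_label,
                                segment = NULL) {
  if (is.null(hyper)) {
    g <- if (is.null(grid)) default_grid(X, y, kind) else grid
    hyper <- select_hyperparams(X, y, g, k = cv_folds, segment = segment)$best
  }
  if (kind == "lasso") {
    fit_lasso(X, y, lam = hyper$lam, dof_label = dof_label)
  } else {
    fit_svr(X, y, C = hyper$C, eps = hyper$eps, gamma = hyper$gamma,
            dof_label = dof_label)
  }
}

#' Session-wise cross-validation of a wrist-angle model
#'
#' Trains on one session and tests on the other, swaps, and averages the two
#' folds' per-DoF metrics (fold metrics are averaged, not pooled). When
#' `hyper` is NULL, hyperparameters are re-selected on each training session
#' by [select_hyperparams()]. Also fills the 3 x 3 single-DoF cross table:
#' entry (d, c) evaluates the model trained only on the training session's
#' DoF-d segment (target: DoF-d angle) against the DoF-d angle observed
#' during the test session's DoF-c segment — the diagonal is the principal
#' DoF, off-diagonal entries probe cross-DoF generalization.
#'
#' @param sessions List of >= 2 [session_data()] objects (2 in the standard
#'   protocol).
#' @param kind `"lasso"` or `"svr"`.
#' @param feature_mode Label recorded on fitted models (`"normal"` or
#'   `"augmented"`); features themselves come in via `sessions`.
#' @param hyper Fixed hyperparameters (named list, or list of 3 per DoF);
#'   NULL to select by CV.
#' @param grid Optional selection grid (default [default_grid()]).
#' @param cv_folds Folds for hyperparameter selection (default 3).
#' @param cross_table Compute the single-DoF cross table (default TRUE).
#' @return Object of class `eit_metrics_report`: `per_dof` (data frame of
#'   averaged rmse/nrmse/r2 per DoF), `mean` (DoF-averaged metrics),
#'   `cross_table` (list of 3 x 3 matrices `rmse`, `nrmse`, `r2`), `folds`
#'   (per-fold detail), `hyper` (chosen hyperparameters per fold).
#' @export
session_cv <- function(sessions, kind = c("lasso", "svr"),
                       feature_mode = c("normal", "augmented"),
                       hyper = NULL, grid = NULL, cv_folds = 3,
                       cross_table = TRUE) {
  kind <- match.arg(kind)
  feature_mode <- match.arg(feature_mode)
  stopifnot(is.list(sessions), length(sessions) >= 2)
  lapply(sessions, function(s) stopifnot(inherits(s, "eit_session_data")))
  ns <- length(sessions)
  fold_metrics <- vector("list", ns)
  fold_cross <- vector("list", ns)
  fold_hyper <- vector("list", ns)

  for (f in seq_len(ns)) {
    train <- sessions[[f]]
    tests <- sessions[-f]
    if (cross_table && any(table(train$segment)[.dof_names] == 0)) {
      stop("protocol error: training session is missing a DoF segment", call. = FALSE)
    }
    per_dof_hyper <- vector("list", 3)
    models <- vector("list", 3)
    for (k in 1:3) {
      h <- if (is.null(hyper)) NULL else if (!is.null(names(hyper))) hyper else hyper[[k]]
      models[[k]] <- .fit_with_selection(train$features, train$angles[, k],
                                         kind, h, grid, cv_folds, .dof_names[k],
                                         segment = train$segment)
      per_dof_hyper[[k]] <- if (kind == "lasso") list(lam = models[[k]]$lam) else
        list(C = models[[k]]$C, eps = models[[k]]$eps, gamma = models[[k]]$gamma)
    }
    fold_hyper[[f]] <- per_dof_hyper
    mm <- t(vapply(1:3, function(k) {
      pk <- unlist(lapply(tests, function(s) predict(models[[k]], s$features)))
      yk <- unlist(lapply(tests, function(s) s$angles[, k]))
      .metric_row(yk, pk)
    }, numeric(3)))
    rownames(mm) <- .dof_names
    fold_metrics[[f]] <- mm

    if (cross_table) {
      ct <- list(rmse = matrix(NA_real_, 3, 3, dimnames = list(.dof_names, .dof_names)),
                 nrmse = matrix(NA_real_, 3, 3, dimnames = list(.dof_names, .dof_names)),
                 r2 = matrix(NA_real_, 3, 3, dimnames = list(.dof_names, .dof_names)))
      for (d in 1:3) {
        seg_idx <- train$segment == .dof_names[d]
        # single-DoF models reuse the hyperparameters already selected on the
        # full training session for that DoF
        md <- .fit_with_selection(train$features[seg_idx, , drop = FALSE],
                                  train$angles[seg_idx, d], kind,
                                  per_dof_hyper[[d]], grid,
                                  cv_folds, .dof_names[d])
        for (cseg in 1:3) {
          y <- unlist(lapply(tests, function(s) s$angles[s$segment == .dof_names[cseg], d]))
          p <- unlist(lapply(tests, function(s) {
            predict(md, s$features[s$segment == .dof_names[cseg], , drop = FALSE])
          }))
          ct$rmse[d, cseg] <- rmse(y, p)
          ct$nrmse[d, cseg] <- nrmse(y, p)
          ct$r2[d, cseg] <- r2(y, p)
        }
      }
      fold_cross[[f]] <- ct
    }
  }

  avg <- Reduce(`+`, fold_metrics) / ns
  per_dof <- data.frame(dof = .dof_names, avg, row.names = NULL)
  ct_avg <- if (cross_table) {
    lapply(c(rmse = "rmse", nrmse = "nrmse", r2 = "r2"), function(m) {
      Reduce(`+`, lapply(fold_cross, `[[`, m)) / ns
    })
  } else NULL
  structure(list(per_dof = per_dof,
                 mean = colMeans(avg),
                 cross_table = ct_avg,
                 folds = fold_metrics,
                 hyper = fold_hyper,
                 kind = kind, feature_mode = feature_mode),
            class = "eit_metrics_report")
}

#' @export
print.eit_metrics_report <- function(x, ...) {
  cat(sprintf("Session-wise CV report (%s, %s features)\n", x$kind, x$feature_mode))
  print(x$per_dof, digits = 4)
  cat(sprintf("DoF-averaged: RMSE %.3f deg, NRMSE %.4f, R2 %.4f\n",
              x$mean["rmse"], x$mean["nrmse"], x$mean["r2"]))
  if (!is.null(x$cross_table)) {
    cat("Cross-table NRMSE (train DoF x test segment):\n")
    print(round(x$cross_table$nrmse, 4))
  }
  invisible(x)
}

#' Summarize which augmented features a Lasso model selected
#'
#' For a Lasso model on augmented features, counts the non-zero weights per
#' DoF, how many of them sit on the diagonal of the outer-product matrix
#' (pure single-region squares), and accumulates the selected feature
#' endpoints onto regions: every selected flat index (i, j) adds 1 to region
#' i and 1 to region j (the same region twice when i = j), yielding the
#' region-selection heat map.
#'
#' @param m A `multidof_model` with `kind = "lasso"` and
#'   `feature_mode = "augmented"`.
#' @param grid The `eit_region_grid` the features were built on.
#' @return Object of class `eit_selection_summary`: `per_dof` (data frame
#'   with `n_nonzero`, `n_diag`), `region_heat` (M x 3 integer matrix), `M`.
#' @export
selection_summary <- function(m, grid) {
  if (!inherits(m, "multidof_model") || m$kind != "lasso" ||
      m$feature_mode != "augmented") {
    stop("contract error: selection_summary needs a Lasso model on augmented features",
         call. = FALSE)
  }
  stopifnot(inherits(grid, "eit_region_grid"))
  M <- grid$M
  stopifnot(length(m$models[[1]]$beta) == M * (M + 1) / 2)
  heat <- matrix(0L, M, 3, dimnames = list(NULL, .dof_names))
  per <- data.frame(dof = .dof_names, n_nonzero = 0L, n_diag = 0L)
  for (k in 1:3) {
    nz <- which(m$models[[k]]$beta != 0)
    per$n_nonzero[k] <- length(nz)
    if (length(nz)) {
      ij <- unmap_index(nz, M)
      per$n_diag[k] <- sum(ij[, 1] == ij[, 2])
      tab <- tabulate(c(ij[, 1], ij[, 2]), nbins = M)
      heat[, k] <- tab
    }
  }
  structure(list(per_dof = per, region_heat = heat, M = M),
            class = "eit_selection_summary")
}

#' @export
print.eit_selection_summary <- function(x, ...) {
  cat(sprintf("Lasso selection summary (M = %d regions):\n", x$M))
  print(x$per_dof, row.names = FALSE)
  invisible(x)
}
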