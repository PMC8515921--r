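#' Build a one-step time-difference reconstructor
#'
#' Precomputes the linear Tikhonov-regularized reconstruction operator
#' \deqn{\delta\sigma = (J^T W J + \lambda^2 Q)^{-1} J^T W \, \delta V,}
#' the standard one-step linearized Gauss-Newton solution for time-difference
#' EIT. `W` weights the measurements and `Q` is the regularization prior.
#'
#' By default `lam` is interpreted *relative* to the scale of the problem:
#' the absolute regularization weight is `lam * s_max`, where `s_max` is the
#' largest singular value of `sqrt(W) J`, making the choice mesh- and
#' current-amplitude-free. Pass `lam_absolute = TRUE` to use `lam` directly.
#'
#' @param fm An `eit_forward_model`.
#' @param lam Regularization hyperparameter, >= 0.
#' @param weighting Measurement weighting `W`: `"identity"` or a user SPD
#'   matrix.
#' @param prior Regularization matrix `Q`: `"identity"` (0th-order Tikhonov),
#'   `"noser"` (`diag(J^T W J)`), or a user PSD matrix.
#' @param lam_absolute Interpret `lam` as an absolute weight.
#' @return Object of class `eit_reconstructor` with the precomputed
#'   `solve_matrix` (n_elements x frame_length).
#' @examples
#' mesh <- build_forearm_mesh(disc_boundary(), density = 64)
#' fm <- forward_model(mesh, build_pattern(electrode_layout(16)))
#' rec <- build_reconstructor(fm, lam = 1e-2)
#' @export
build_reconstructor <- function(fm, lam = 1e-2, weighting = "identity",
                                prior = "identity", lam_absolute = FALSE) {
  stopifnot(inherits(fm, "eit_forward_model"), lam >= 0)
  J <- fm$jacobian
  nmeas <- nrow(J); nelem <- ncol(J)

  # weighted Jacobian: Jw = chol(W) J (identity W leaves J untouched)
  Lw <- NULL
  if (is.matrix(weighting)) {
    stopifnot(nrow(weighting) == nmeas, ncol(weighting) == nmeas)
    Lw <- chol(weighting)
    Jw <- Lw %*% J
  } else {
    Jw <- J
  }
  # diagonal priors are handled by rescaling columns: beta = sqrt(q) dsigma
  q <- if (is.matrix(prior)) {
    stopifnot(nrow(prior) == nelem, ncol(prior) == nelem)
    dq <- diag(prior)
    if (max(abs(prior - diag(dq))) > 0) {
      stop("only diagonal regularization matrices Q are supported", call. = FALSE)
    }
    dq
  } else if (identical(prior, "noser")) {
    colSums(Jw^2)
  } else {
    rep(1, nelem)
  }
  if (any(q <= 0)) stop("regularization error: Q must be positive on the diagonal",
                        call. = FALSE)

  # pseudo-inverse via SVD of Jw Q^{-1/2}: numerically stable at any lam,
  # unlike forming the normal equations (EIT Jacobians are severely
  # ill-conditioned, so J'WJ underflows to numerical singularity)
  sv <- svd(sweep(Jw, 2, sqrt(q), "/"))
  d <- sv$d
  lam_abs <- if (lam_absolute) lam else lam * d[1]
  if (lam_abs == 0 && min(d) <= max(d) * max(dim(J)) * .Machine$double.eps) {
    stop("regularization error: J'WJ + lam^2 Q is singular; increase lam",
         call. = FALSE)
  }
  filt <- d / (d^2 + lam_abs^2)
  op <- (sv$v * rep(filt, each = nelem)) %*% t(sv$u)   # beta from weighted dV
  solve_matrix <- op / sqrt(q)
  if (!is.null(Lw)) solve_matrix <- solve_matrix %*% Lw
  structure(list(model = fm, lam = lam, lam_abs = lam_abs,
                 weighting = if (is.matrix(weighting)) "user" else "identity",
                 prior = if (is.matrix(prior)) "user" else prior,
                 singular_values = d,
                 solve_matrix = solve_matrix),
            class = "eit_reconstructor")
}

#' Reconstruct a conductivity-change image from one frame
#'
#' Applies the precomputed linear operator to the voltage difference between a
#' measured frame and the baseline frame (first neutral-posture frames; see
#' [baseline_frame()]). Stateless and linear in `frame - baseline`.
#'
#' @param rec An `eit_reconstructor`.
#' @param frame Numeric measurement vector in pattern order.
#' @param baseline Baseline frame of the same length.
#' @return Numeric vector of per-element conductivity changes.
#' @export
reconstruct_frame <- function(rec, frame, baseline) {
  stopifnot(inherits(rec, "eit_reconstructor"))
  nmeas <- ncol(rec$solve_matrix)
  if (length(frame) != nmeas || length(baseline) != nmeas) {
    stop(sprintf("frame error: expected %d values per frame", nmeas), call. = FALSE)
  }
  as.vector(rec$solve_matrix %*% (frame - baseline))
}

#' Reconstruct a series of frames
#'
#' @param rec An `eit_reconstructor`.
#' @param frames Matrix, one frame per row.
#' @param baseline Baseline frame (default: [baseline_frame()] of `frames`).
#' @return Matrix of images, one row per frame (n_frames x n_elements).
#' @export
reconstruct_series <- function(rec, frames, baseline = baseline_frame(frames)) {
  stopifnot(inherits(rec, "eit_reconstructor"), is.matrix(frames))
  nmeas <- ncol(rec$solve_matrix)
  if (ncol(frames) != nmeas) {
    stop(sprintf("frame error: expected %d values per frame", nmeas), call. = FALSE)
  }
  dv <- sweep(frames, 2, baseline)
  t(rec$solve_matrix %*% t(dv))
}

#' Baseline frame from initial neutral-posture frames
#'
#' The time-difference baseline `V0` is the mean of the first `k` frames,
#' assumed recorded at the neutral posture.
#'
#' @param frames Matrix of frames (rows) in time order.
#' @param k Number of initial frames to average (default 10, capped at the
#'   number available).
#' @return Numeric baseline frame.
#' @export
baseline_frame <- function(frames, k = 10) {
  stopifnot(is.matrix(frames), nrow(frames) >= 1, k >= 1)
  colMeans(frames[seq_len(min(k, nrow(frames))), , drop = FALSE])
}

#' @export
print.eit_reconstructor <- function(x, ...) {
  cat(sprintf(
    "EIT reconstructor: %d elements from %d measurements, lam = %.3g (abs %.3g), prior %s\n",
    nrow(x$solve_matrix), ncol(x$solve_matrix), x$lam, x$lam_abs, x$prior))
  invisible(x)
}
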