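#' FEM forward model for 2D EIT
#'
#' Assembles everything needed to map an internal conductivity distribution to
#' a boundary voltage frame: the linear (P1) triangular finite-element
#' discretization of \eqn{\nabla\cdot\sigma\nabla\phi = 0} with Neumann
#' current boundary conditions, the stimulation/measurement pattern, a
#' baseline conductivity, the baseline frame `v0` and the sensitivity
#' (Jacobian) matrix at the baseline.
#'
#' Electrodes use the gap model: the injected current is split uniformly over
#' the drive electrode's boundary nodes and an electrode potential is the mean
#' over its nodes. The Neumann problem fixes the gauge by zeroing the mean
#' boundary potential; measurements are pair differences, so the gauge choice
#' is immaterial.
#'
#' @param mesh An `eit_mesh` from [build_forearm_mesh()].
#' @param pattern An `eit_pattern`; its electrode count must match the mesh.
#' @param sigma0 Baseline conductivity: scalar or per-element vector
#'   (arbitrary units; only conductivity *changes* are ever imaged).
#' @param current Drive current amplitude in amperes (RMS); default 400 uA.
#'   The model is linear in the current, so this only sets the voltage scale.
#' @return Object of class `eit_forward_model` with fields `mesh`, `pattern`,
#'   `sigma0`, `current`, `jacobian` (frame_length x n_elements) and `v0`.
#' @examples
#' mesh <- build_forearm_mesh(disc_boundary(), density = 64)
#' fm <- forward_model(mesh, build_pattern(electrode_layout(16)))
#' length(fm$v0)
#' @export
forward_model <- function(mesh, pattern, sigma0 = 1, current = 400e-6) {
  stopifnot(inherits(mesh, "eit_mesh"), inherits(pattern, "eit_pattern"))
  n_el <- length(mesh$electrode_nodes)
  if (attr(pattern, "n_electrodes") != n_el) {
    stop("pattern and mesh disagree on electrode count", call. = FALSE)
  }
  nelem <- nrow(mesh$elements)
  nvert <- nrow(mesh$vertices)
  sigma0 <- if (length(sigma0) == 1) rep(sigma0, nelem) else sigma0
  stopifnot(length(sigma0) == nelem, all(sigma0 > 0))

  # per-element P1 stiffness at unit conductivity:
  # grad(lambda_i) = (b_i, c_i); Ke[i,j] = area * (b_i b_j + c_i c_j)
  tri <- mesh$elements
  x <- matrix(mesh$vertices[tri, 1], ncol = 3)
  y <- matrix(mesh$vertices[tri, 2], ncol = 3)
  A <- mesh$areas
  b <- cbind(y[, 2] - y[, 3], y[, 3] - y[, 1], y[, 1] - y[, 2]) / (2 * A)
  cc <- cbind(x[, 3] - x[, 2], x[, 1] - x[, 3], x[, 2] - x[, 1]) / (2 * A)
  # 9 stiffness entries per element, row-major over (i,j)
  ke <- matrix(0, nelem, 9)
  for (i in 1:3) for (j in 1:3) {
    ke[, (i - 1) * 3 + j] <- A * (b[, i] * b[, j] + cc[, i] * cc[, j])
  }
  ii <- as.vector(t(tri[, rep(1:3, each = 3)]))
  jj <- as.vector(t(tri[, rep(1:3, times = 3)]))

  # unit-current injection/extraction patterns for the n adjacent pairs:
  # pair e = (+ on electrode e, - on electrode e+1)
  P <- matrix(0, nvert, n_el)
  for (e in seq_len(n_el)) {
    pos <- mesh$electrode_nodes[[e]]
    neg <- mesh$electrode_nodes[[e %% n_el + 1L]]
    P[pos, e] <- P[pos, e] + 1 / length(pos)
    P[neg, e] <- P[neg, e] - 1 / length(neg)
  }

  fm <- structure(list(mesh = mesh, pattern = pattern, sigma0 = sigma0,
                       current = current,
                       drive_id = .pair_id(pattern$drive_pos),
                       meas_id = .pair_id(pattern$meas_pos),
                       ke = ke, kidx_i = ii, kidx_j = jj,
                       grad_b = b, grad_c = cc,
                       patterns = P, ground = 1L),
                  class = "eit_forward_model")
  fm$v0 <- solve_forward(fm, sigma0)
  fm$jacobian <- compute_jacobian(fm)
  fm
}

# assemble the global stiffness matrix K(sigma) (sparse, symmetric)
.assemble_stiffness <- function(fm, sigma) {
  nvert <- nrow(fm$mesh$vertices)
  Matrix::sparseMatrix(i = fm$kidx_i, j = fm$kidx_j,
                       x = as.vector(t(fm$ke * sigma)),
                       dims = c(nvert, nvert))
}

# nodal potential fields for all unit-current adjacent-pair injections;
# returns nvert x n_electrodes matrix, mean boundary potential zeroed
.solve_fields <- function(fm, sigma, chol_cache = NULL) {
  g <- fm$ground
  K <- .assemble_stiffness(fm, sigma)
  Kr <- Matrix::forceSymmetric(K[-g, -g, drop = FALSE])
  Pr <- fm$patterns[-g, , drop = FALSE]
  if (is.null(chol_cache)) {
    phi_r <- as.matrix(Matrix::solve(Kr, Pr))
  } else {
    ch <- Matrix::update(chol_cache, Kr)
    phi_r <- as.matrix(Matrix::solve(ch, Pr))
  }
  phi <- matrix(0, nrow(fm$mesh$vertices), ncol(Pr))
  phi[-g, ] <- phi_r
  shift <- colMeans(phi[fm$mesh$boundary_nodes, , drop = FALSE])
  sweep(phi, 2, shift)
}

# symbolic+numeric Cholesky of the reduced baseline system, reusable across
# conductivity updates with the same sparsity pattern
.chol_cache <- function(fm) {
  K <- .assemble_stiffness(fm, fm$sigma0)
  g <- fm$ground
  Matrix::Cholesky(Matrix::forceSymmetric(K[-g, -g, drop = FALSE]), LDL = FALSE)
}

# frame from precomputed unit fields
.frame_from_fields <- function(fm, phi) {
  V <- crossprod(fm$patterns, phi)        # n_el x n_el pair-voltage matrix
  fm$current * V[cbind(fm$meas_id, fm$drive_id)]
}

#' Solve the forward problem for a given conductivity
#'
#' Predicts the full boundary voltage frame (in pattern order) for a strictly
#' positive per-element conductivity.
#'
#' @param fm An `eit_forward_model`.
#' @param sigma Per-element conductivity (scalar recycled), all > 0.
#' @param current Optional drive current override (amperes).
#' @return Numeric vector of length `frame_length(fm$pattern)`.
#' @export
solve_forward <- function(fm, sigma, current = NULL) {
  stopifnot(inherits(fm, "eit_forward_model"))
  nelem <- nrow(fm$mesh$elements)
  if (length(sigma) == 1) sigma <- rep(sigma, nelem)
  if (length(sigma) != nelem || any(!is.finite(sigma))) {
    stop("sigma must be a finite per-element vector", call. = FALSE)
  }
  if (any(sigma <= 0)) stop("domain error: conductivity must be positive", call. = FALSE)
  if (!is.null(current)) fm$current <- current
  if (fm$current == 0) return(numeric(nrow(fm$pattern)))
  phi <- tryCatch(.solve_fields(fm, sigma),
                  error = function(e) stop("solver error: singular FEM system (",
                                           conditionMessage(e), ")", call. = FALSE))
  .frame_from_fields(fm, phi)
}

#' Sensitivity (Jacobian) matrix at the baseline conductivity
#'
#' Computes \eqn{J[k, e] = \partial V_k / \partial \sigma_e} at `sigma0` by
#' the adjoint method: minus the integral over element e of the dot product of
#' the drive-field and measurement-field gradients (times the drive current).
#'
#' @param fm An `eit_forward_model`.
#' @return Dense matrix, `frame_length` rows x n_elements columns.
#' @export
compute_jacobian <- function(fm) {
  stopifnot(inherits(fm, "eit_forward_model"))
  phi <- .solve_fields(fm, fm$sigma0)      # unit-current fields, one per pair
  tri <- fm$mesh$elements
  n_pairs <- ncol(phi)
  nelem <- nrow(tri)
  gx <- matrix(0, nelem, n_pairs)
  gy <- matrix(0, nelem, n_pairs)
  for (i in 1:3) {
    gx <- gx + fm$grad_b[, i] * phi[tri[, i], , drop = FALSE]
    gy <- gy + fm$grad_c[, i] * phi[tri[, i], , drop = FALSE]
  }
  d <- fm$drive_id; m <- fm$meas_id
  S <- (gx[, m, drop = FALSE] * gx[, d, drop = FALSE] +
        gy[, m, drop = FALSE] * gy[, d, drop = FALSE]) * fm$mesh$areas
  J <- -fm$current * t(S)
  dimnames(J) <- NULL
  J
}

#' @export
print.eit_forward_model <- function(x, ...) {
  cat(sprintf(
    "EIT forward model: %d elements, %d-electrode pattern, %d-value frame, current %.3g A\n",
    nrow(x$mesh$elements), attr(x$pattern, "n_electrodes"), nrow(x$pattern), x$current))
  invisible(x)
}
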