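#' Forearm cross-section boundary curve
#'
#' Parameterizes the scan-plane boundary as a star-shaped closed curve: an
#' ellipse with an optional low-order cosine flattening term, which captures
#' the mildly flattened, asymmetric latitudinal outline of a forearm without
#' pretending to subject-specific anatomy. `flatten = 0` with `a == b`
#' degenerates to a circle.
#'
#' @param a,b Ellipse semi-axes (mesh units).
#' @param flatten Amplitude of the `cos(theta - phase)` radial modulation
#'   (fraction of local radius; must keep the radius positive).
#' @param phase Angular location of the flattened side, radians.
#' @return An object of class `eit_boundary`: a list with the parameters and a
#'   vectorized radius function `r(theta)`.
#' @examples
#' b <- forearm_boundary()
#' b$r(c(0, pi / 2, pi))
#' @export
forearm_boundary <- function(a = 1.1, b = 0.85, flatten = 0.1, phase = pi / 2) {
  stopifnot(a > 0, b > 0, is.finite(flatten), abs(flatten) < 1)
  r <- function(theta) {
    re <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
    re * (1 + flatten * cos(theta - phase))
  }
  th <- seq(0, 2 * pi, length.out = 721)
  if (any(r(th) <= 0)) {
    stop("geometry error: boundary radius is not positive everywhere", call. = FALSE)
  }
  structure(list(a = a, b = b, flatten = flatten, phase = phase, r = r),
            class = "eit_boundary")
}

#' Circular boundary (degenerate forearm shape)
#' @param radius Circle radius.
#' @return An `eit_boundary`.
#' @export
disc_boundary <- function(radius = 1) forearm_boundary(radius, radius, 0)

# stitch two concentric closed node rings (given as global vertex indices,
# counter-clockwise, angle-aligned at index 1) into a conforming triangle strip
.stitch_rings <- function(inner, outer) {
  m <- length(inner); M <- length(outer)
  if (m == 1L) {                         # fan around the centre node
    return(cbind(inner, outer, outer[c(seq_len(M)[-1], 1L)]))
  }
  tri <- matrix(0L, nrow = m + M, ncol = 3)
  i <- 0L; o <- 0L; k <- 0L
  while (i < m || o < M) {
    adv_outer <- if (o >= M) FALSE else if (i >= m) TRUE else (o + 1) / M <= (i + 1) / m
    k <- k + 1L
    if (adv_outer) {
      tri[k, ] <- c(inner[i %% m + 1L], outer[o %% M + 1L], outer[(o + 1L) %% M + 1L])
      o <- o + 1L
    } else {
      tri[k, ] <- c(inner[i %% m + 1L], outer[o %% M + 1L], inner[(i + 1L) %% m + 1L])
      i <- i + 1L
    }
  }
  tri[seq_len(k), , drop = FALSE]
}

#' Build a triangular FEM mesh of the forearm cross-section
#'
#' Generates a structured star-shaped triangulation: `k` concentric rings with
#' `n1 * j` nodes on ring `j`, radially mapped onto the boundary curve, giving
#' `n1 * k^2` triangles. `n1` and `k` are chosen so the element count lands
#' within 20% of `density` (usually much closer). Electrodes are placed evenly
#' by arc length along the boundary; each electrode owns a contiguous,
#' disjoint set of boundary nodes covering `electrode_coverage` of its share
#' of the perimeter.
#'
#' @param boundary An `eit_boundary` (default [forearm_boundary()]).
#' @param density Target triangle count.
#' @param n_electrodes Number of electrodes to place (default 16).
#' @param electrode_coverage Fraction (0, 1] of the per-electrode arc covered
#'   by electrode nodes.
#' @return An object of class `eit_mesh`: list with `vertices` (V x 2),
#'   `elements` (T x 3 vertex indices, positive orientation), `boundary_nodes`
#'   (counter-clockwise), `boundary_edges`, `electrode_nodes` (list of
#'   node-index vectors), plus cached `areas` and `centroids`.
#' @examples
#' m <- build_forearm_mesh(disc_boundary(), density = 256)
#' nrow(m$elements)
#' @export
build_forearm_mesh <- function(boundary = forearm_boundary(), density = 800,
                               n_electrodes = 16, electrode_coverage = 0.5) {
  stopifnot(inherits(boundary, "eit_boundary"), density >= 4,
            n_electrodes >= 4, electrode_coverage > 0, electrode_coverage <= 1)
  # pick ring structure: n1*k^2 triangles, boundary nodes n1*k >= n_electrodes
  best <- NULL
  for (n1 in seq(4L, 64L, by = 2L)) {
    k <- max(2L, as.integer(round(sqrt(density / n1))))
    for (kk in unique(c(k - 1L, k, k + 1L))) {
      if (kk < 2L || n1 * kk < n_electrodes) next
      err <- abs(n1 * kk^2 - density)
      if (is.null(best) || err < best$err) best <- list(n1 = n1, k = kk, err = err)
    }
  }
  n1 <- best$n1; k <- best$k
  if (best$err > 0.2 * density) {
    stop("geometry error: cannot mesh to within 20% of requested density", call. = FALSE)
  }

  # vertices: centre + rings
  verts <- list(c(0, 0))
  ring_ids <- vector("list", k + 1L)
  ring_ids[[1]] <- 1L
  nid <- 1L
  for (j in seq_len(k)) {
    nj <- n1 * j
    th <- 2 * pi * (seq_len(nj) - 1) / nj
    rho <- (j / k) * boundary$r(th)
    ids <- nid + seq_len(nj)
    for (q in seq_len(nj)) verts[[ids[q]]] <- c(rho[q] * cos(th[q]), rho[q] * sin(th[q]))
    ring_ids[[j + 1L]] <- ids
    nid <- nid + nj
  }
  vertices <- do.call(rbind, verts)
  elements <- do.call(rbind, lapply(seq_len(k), function(j) {
    .stitch_rings(ring_ids[[j]], ring_ids[[j + 1L]])
  }))
  storage.mode(elements) <- "integer"

  # enforce positive (counter-clockwise) orientation
  p1 <- vertices[elements[, 1], , drop = FALSE]
  p2 <- vertices[elements[, 2], , drop = FALSE]
  p3 <- vertices[elements[, 3], , drop = FALSE]
  a2 <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
        (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])
  flip <- a2 < 0
  if (any(flip)) elements[flip, c(2, 3)] <- elements[flip, c(3, 2)]
  areas <- abs(a2) / 2
  if (any(areas <= 0)) stop("geometry error: degenerate element produced", call. = FALSE)

  boundary_nodes <- ring_ids[[k + 1L]]
  nb <- length(boundary_nodes)
  boundary_edges <- cbind(boundary_nodes, boundary_nodes[c(seq_len(nb)[-1], 1L)])

  # electrode placement, even by arc length starting at angle 0
  bxy <- vertices[boundary_nodes, , drop = FALSE]
  seg <- sqrt(rowSums((bxy[c(seq_len(nb)[-1], 1L), ] - bxy)^2))
  arc <- c(0, cumsum(seg))[seq_len(nb)]      # arc position of each boundary node
  L <- sum(seg)
  centers <- L * (seq_len(n_electrodes) - 1) / n_electrodes
  half <- electrode_coverage * (L / n_electrodes) / 2
  circ_d <- function(x, c) { d <- abs(x - c); pmin(d, L - d) }
  dmat <- vapply(centers, function(cc) circ_d(arc, cc), numeric(nb))
  nearest <- max.col(-dmat)                  # electrode index per boundary node
  electrode_nodes <- vector("list", n_electrodes)
  for (e in seq_len(n_electrodes)) {
    sel <- which(nearest == e & dmat[, e] <= half)
    if (length(sel) == 0) sel <- which.min(dmat[, e])
    electrode_nodes[[e]] <- boundary_nodes[sel[order(arc[sel])]]
  }
  if (anyDuplicated(unlist(electrode_nodes))) {
    stop("geometry error: electrode node sets overlap", call. = FALSE)
  }

  centroids <- (p1 + p2 + p3) / 3
  structure(list(vertices = vertices, elements = elements,
                 boundary_nodes = boundary_nodes, boundary_edges = boundary_edges,
                 electrode_nodes = electrode_nodes,
                 areas = areas, centroids = centroids,
                 boundary = boundary),
            class = "eit_mesh")
}

#' @export
print.eit_mesh <- function(x, ...) {
  cat(sprintf("EIT mesh: %d vertices, %d elements, %d electrodes (%d boundary nodes)\n",
              nrow(x$vertices), nrow(x$elements), length(x$electrode_nodes),
              length(x$boundary_nodes)))
  invisible(x)
}

#' Serialize / read a mesh as delimited text tables
#'
#' Writes three CSV tables under `dir`: `vertices.csv` (id,x,y),
#' `elements.csv` (id,v1,v2,v3) and `electrodes.csv` (electrode,node).
#'
#' @param mesh An `eit_mesh`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mesh <- function(mesh, dir) {
  stopifnot(inherits(mesh, "eit_mesh"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(data.frame(id = seq_len(nrow(mesh$vertices)),
                                x = mesh$vertices[, 1], y = mesh$vertices[, 2]),
                     file.path(dir, "vertices.csv"))
  data.table::fwrite(data.frame(id = seq_len(nrow(mesh$elements)),
                                v1 = mesh$elements[, 1], v2 = mesh$elements[, 2],
                                v3 = mesh$elements[, 3]),
                     file.path(dir, "elements.csv"))
  el <- mesh$electrode_nodes
  data.table::fwrite(data.frame(electrode = rep(seq_along(el), lengths(el)),
                                node = unlist(el)),
                     file.path(dir, "electrodes.csv"))
  invisible(dir)
}
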