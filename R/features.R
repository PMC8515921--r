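#' Partition a mesh into equal-size square regions
#'
#' Overlays an axis-aligned square grid on the mesh bounding box and assigns
#' every element to the cell containing its centroid. Empty cells are
#' dropped; the cell size is bisected so the number of non-empty cells lands
#' within `tol` (default 5%) of `target_M`. Cells are geometrically equal;
#' their element counts K(i) differ, which is why region features are
#' count-normalized means.
#'
#' Regions are ordered deterministically by grid row (ascending y), then
#' column (ascending x).
#'
#' @param mesh An `eit_mesh`.
#' @param target_M Desired region count (382 at the full image scale).
#' @param tol Relative tolerance on the achieved count.
#' @return Object of class `eit_region_grid`: `cell_size`, `origin`, `M`,
#'   `regions` (list of element-index vectors), `element_region` (per-element
#'   region id), `K` (per-region counts), `n_elements`.
#' @export
build_region_grid <- function(mesh, target_M, tol = 0.05) {
  stopifnot(inherits(mesh, "eit_mesh"), target_M >= 1)
  cen <- mesh$centroids
  nelem <- nrow(cen)
  if (target_M > nelem) {
    stop("grid error: target_M exceeds the element count", call. = FALSE)
  }
  origin <- c(min(cen[, 1]), min(cen[, 2]))
  span <- c(max(cen[, 1]), max(cen[, 2])) - origin
  count_for <- function(h) {
    ix <- floor((cen[, 1] - origin[1]) / h)
    iy <- floor((cen[, 2] - origin[2]) / h)
    length(unique(ix + 1e6 * iy))
  }
  hi <- max(span) * 1.01          # one cell
  lo <- hi / (2 * nelem)          # at least one element per cell
  best_h <- hi; best_err <- Inf
  for (it in 1:200) {
    h <- sqrt(lo * hi)
    mcount <- count_for(h)
    err <- abs(mcount - target_M) / target_M
    if (err < best_err) { best_err <- err; best_h <- h }
    if (err <= tol && mcount >= min(target_M, nelem)) break
    if (mcount > target_M) lo <- h else hi <- h
    if (hi / lo < 1 + 1e-12) break
  }
  h <- best_h
  ix <- floor((cen[, 1] - origin[1]) / h)
  iy <- floor((cen[, 2] - origin[2]) / h)
  key <- ix + 1e6 * iy
  cells <- sort(unique(key))
  region_of <- match(key, cells)
  regions <- split(seq_len(nelem), region_of)
  names(regions) <- NULL
  structure(list(cell_size = h, origin = origin, M = length(regions),
                 regions = regions, element_region = region_of,
                 K = lengths(regions), n_elements = nelem),
            class = "eit_region_grid")
}

#' Region-mean features of a conductivity image
#'
#' Feature i is the mean conductivity change over the elements of region i:
#' \eqn{S(i) = K(i)^{-1} \sum_{e \in \Omega(i)} \delta\sigma_e}.
#'
#' @param img Per-element image vector, or a matrix of images with one image
#'   per row (n_frames x n_elements).
#' @param grid An `eit_region_grid` built on the same mesh.
#' @return Length-M feature vector, or an n_frames x M matrix.
#' @export
region_features <- function(img, grid) {
  stopifnot(inherits(grid, "eit_region_grid"))
  if (is.matrix(img)) {
    if (ncol(img) != grid$n_elements) {
      stop("feature error: image does not match the grid's mesh", call. = FALSE)
    }
    S <- t(rowsum(t(img), group = grid$element_region, reorder = TRUE))
    S <- sweep(S, 2, grid$K, "/")
    dimnames(S) <- NULL
    S
  } else {
    if (length(img) != grid$n_elements) {
      stop("feature error: image does not match the grid's mesh", call. = FALSE)
    }
    as.vector(rowsum(img, group = grid$element_region, reorder = TRUE)) / grid$K
  }
}

# cached (i, j) index pair vectors for the row-major upper triangle
.aug_index <- function(M) {
  list(i = rep.int(seq_len(M), M:1),
       j = unlist(lapply(seq_len(M), function(i) i:M), use.names = FALSE))
}

#' Outer-product feature augmentation
#'
#' Maps a length-M feature vector to the vectorized upper triangle (diagonal
#' included) of its outer product: all pairwise products `s_i * s_j`, i <= j,
#' capturing co-activation of region pairs. The flat order is row-major (i
#' outer, j inner); [unmap_index()] inverts it. Length M(M+1)/2 (73,153 for
#' M = 382).
#'
#' @param s Numeric feature vector, or an n x M matrix of feature rows.
#' @return Length M(M+1)/2 vector, or an n x M(M+1)/2 matrix.
#' @export
augment <- function(s) {
  if (is.matrix(s)) {
    idx <- .aug_index(ncol(s))
    s[, idx$i, drop = FALSE] * s[, idx$j, drop = FALSE]
  } else {
    stopifnot(all(is.finite(s)))
    idx <- .aug_index(length(s))
    s[idx$i] * s[idx$j]
  }
}

#' Invert the augmented-feature flat index
#'
#' Returns the region pair (i, j), i <= j, whose product sits at flat
#' position `k` of [augment()]'s output (1-based, row-major upper triangle).
#'
#' @param k Flat index (or vector of indices), in 1..M(M+1)/2.
#' @param M Region count.
#' @return Integer matrix with columns `i`, `j` (one row per `k`).
#' @examples
#' unmap_index(1, 5)       # (1, 1)
#' unmap_index(5, 5)       # (1, 5)
#' @export
unmap_index <- function(k, M) {
  stopifnot(M >= 1)
  kmax <- M * (M + 1) / 2
  if (any(k < 1 | k > kmax | k != round(k))) {
    stop(sprintf("index error: flat index must be in 1..%d", kmax), call. = FALSE)
  }
  # row i starts at offset n_i = (i-1)(2M - i + 2)/2
  i <- floor(M + 1.5 - sqrt((M + 0.5)^2 - 2 * (k - 1)))
  start <- (i - 1) * (2 * M - i + 2) / 2
  # guard against floating-point edge cases
  too_big <- start >= k
  i[too_big] <- i[too_big] - 1
  start <- (i - 1) * (2 * M - i + 2) / 2
  nxt <- i * (2 * M - i + 1) / 2
  too_small <- k > nxt
  i[too_small] <- i[too_small] + 1
  start <- (i - 1) * (2 * M - i + 2) / 2
  j <- i + (k - start) - 1
  cbind(i = as.integer(i), j = as.integer(j))
}

#' @export
print.eit_region_grid <- function(x, ...) {
  cat(sprintf("EIT region grid: M = %d square regions (cell %.4g) over %d elements\n",
              x$M, x$cell_size, x$n_elements))
  invisible(x)
}
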