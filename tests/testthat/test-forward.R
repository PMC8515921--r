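test_that("meshing hits the requested density with valid geometry", {
  m <- build_forearm_mesh(disc_boundary(), density = 800)
  expect_lte(abs(nrow(m$elements) - 800) / 800, 0.2)
  expect_true(all(m$areas > 0))
  expect_length(m$electrode_nodes, 16)
  expect_false(anyDuplicated(unlist(m$electrode_nodes)) > 0)

  me <- build_forearm_mesh(forearm_boundary(a = 1.2, b = 0.9, flatten = 0),
                           density = 300)
  expect_true(all(me$areas > 0))
  # boundary edges form one closed loop
  expect_equal(sort(me$boundary_edges[, 1]), sort(me$boundary_edges[, 2]))
  expect_equal(length(unique(me$boundary_edges[, 1])), nrow(me$boundary_edges))

  # full-image-scale request is approachable within tolerance
  mp <- build_forearm_mesh(forearm_boundary(), density = 5868)
  expect_lte(abs(nrow(mp$elements) - 5868) / 5868, 0.2)
})

test_that("forward solve scales as 1/sigma and vanishes at zero current", {
  fm <- disc_model_64()
  nelem <- nrow(fm$mesh$elements)
  expect_equal(solve_forward(fm, rep(2, nelem)), fm$v0 / 2, tolerance = 1e-10)
  expect_equal(solve_forward(fm, fm$sigma0, current = 0), numeric(208))
  expect_error(solve_forward(fm, rep(-1, nelem)), "domain error")
})

test_that("reciprocity holds on a ~500-element disc", {
  fm <- disc_model_500()
  p <- fm$pattern
  set.seed(2)
  sig <- exp(rnorm(nrow(fm$mesh$elements), sd = 0.2))   # inhomogeneous field
  v <- solve_forward(fm, sig)
  scale <- max(abs(v))
  # swap every (drive, measure) combination present in the pattern
  key <- paste(p$drive_pos, p$meas_pos)
  swapped <- match(paste(p$meas_pos, p$drive_pos), key)
  ok <- !is.na(swapped)
  expect_gt(sum(ok), 100)
  expect_lt(max(abs(v[ok] - v[swapped[ok]])) / scale, 1e-8)
})

test_that("injected current sums to zero over the domain", {
  fm <- disc_model_500()
  expect_lt(max(abs(colSums(fm$patterns))), 1e-12)
})

test_that("Jacobian matches central finite differences on a coarse mesh", {
  fm <- disc_model_64()
  nelem <- nrow(fm$mesh$elements)
  h <- 1e-5
  Jfd <- vapply(seq_len(nelem), function(e) {
    up <- fm$sigma0; up[e] <- up[e] + h
    dn <- fm$sigma0; dn[e] <- dn[e] - h
    (solve_forward(fm, up) - solve_forward(fm, dn)) / (2 * h)
  }, numeric(208))
  expect_lt(max(abs(fm$jacobian - Jfd)) / max(abs(Jfd)), 1e-4)
})

test_that("Jacobian prediction error is second order in the perturbation", {
  fm <- disc_model_64()
  nelem <- nrow(fm$mesh$elements)
  set.seed(5)
  direction <- rnorm(nelem)
  err_at <- function(delta) {
    ds <- delta * direction
    dv_true <- solve_forward(fm, fm$sigma0 + ds) - fm$v0
    max(abs(dv_true - as.vector(fm$jacobian %*% ds)))
  }
  e1 <- err_at(2e-2)
  e2 <- err_at(1e-2)
  expect_gt(e1 / e2, 3.3)   # halving delta ~quarters the error
  expect_lt(e1 / e2, 4.7)
})

test_that("interior elements are less sensitive than near-boundary elements", {
  fm <- disc_model_500()
  r <- sqrt(rowSums(fm$mesh$centroids^2))
  sens <- colSums(abs(fm$jacobian))
  inner <- sens[r < 0.3]
  outer <- sens[r > 0.85]
  expect_lt(max(inner), max(outer))
  expect_true(all(is.finite(fm$jacobian)))
})

test_that("mesh serialization writes consistent tables", {
  dir <- withr::local_tempdir()
  m <- disc_model_64()$mesh
  write_mesh(m, dir)
  v <- read.csv(file.path(dir, "vertices.csv"))
  e <- read.csv(file.path(dir, "elements.csv"))
  el <- read.csv(file.path(dir, "electrodes.csv"))
  expect_equal(nrow(v), nrow(m$vertices))
  expect_equal(nrow(e), nrow(m$elements))
  expect_equal(max(e$v1, e$v2, e$v3), nrow(v))
  expect_equal(sort(unique(el$electrode)), 1:16)
})
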