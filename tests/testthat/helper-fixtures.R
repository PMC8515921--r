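# Shared small fixtures, built once per test run and memoized.
.fix <- local({
  cache <- new.env(parent = emptyenv())
  function(name, build) {
    if (!exists(name, envir = cache)) assign(name, build(), envir = cache)
    get(name, envir = cache)
  }
})

pattern16 <- function() .fix("pattern16", function() build_pattern(electrode_layout(16)))

# 64-element disc: coarse enough for finite-difference Jacobian checks
disc_model_64 <- function() .fix("disc64", function() {
  forward_model(build_forearm_mesh(disc_boundary(), density = 64), pattern16())
})

# ~500-element disc for physics property checks
disc_model_500 <- function() .fix("disc500", function() {
  forward_model(build_forearm_mesh(disc_boundary(), density = 500), pattern16())
})

# small forearm-shaped model shared by phantom/pipeline tests
forearm_model_400 <- function() .fix("forearm400", function() {
  forward_model(build_forearm_mesh(forearm_boundary(), density = 400), pattern16())
})

# brute-force enumeration oracle for the adjacent-adjacent protocol:
# all (drive, measure) combinations of adjacent pairs sharing no electrode
enumerate_adjacent_entries <- function(n) {
  pairs <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  total <- 0L
  for (d in seq_len(n)) {
    for (m in seq_len(n)) {
      if (length(intersect(pairs[d, ], pairs[m, ])) == 0) total <- total + 1L
    }
  }
  total
}

# dense interior-point QP oracle for the SVR dual, in (alpha, alpha*) variables
svr_dual_oracle <- function(X, y, C, eps, gamma) {
  n <- length(y)
  K <- exp(-gamma * as.matrix(dist(X))^2)
  H <- rbind(cbind(K, -K), cbind(-K, K)) + diag(2 * n) * 1e-10
  cc <- c(eps - y, eps + y)
  A <- matrix(c(rep(1, n), rep(-1, n)), nrow = 1)
  sol <- kernlab::ipop(c = cc, H = H, A = A, b = 0, r = 0,
                       l = rep(0, 2 * n), u = rep(C, 2 * n), sigf = 9)
  z <- kernlab::primal(sol)
  beta <- z[1:n] - z[(n + 1):(2 * n)]
  free <- which(abs(beta) > 1e-6 * C & abs(beta) < C * (1 - 1e-6))
  b <- if (length(free)) {
    mean(y[free] - K[free, , drop = FALSE] %*% beta - eps * sign(beta[free]))
  } else 0
  list(beta = beta, b = b,
       predict = function(Xn) {
         d2 <- outer(rowSums(Xn^2), rowSums(X^2), "+") - 2 * tcrossprod(Xn, X)
         as.vector(exp(-gamma * pmax(d2, 0)) %*% beta) + b
       })
}
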