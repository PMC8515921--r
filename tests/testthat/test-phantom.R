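test_that("trajectory structure follows the session protocol", {
  cfg <- phantom_config(cycles_per_dof = 20, cadence = 4, seed = 42, rest_s = 0)
  tr <- generate_trajectory(cfg, session = 1)
  expect_equal(nrow(tr), 2400)                      # 3 DoF x 20 cycles x 4 s x 10 Hz
  expect_equal(max(tr$t), 239.9)
  expect_equal(as.vector(table(tr$segment)), c(0, 800, 800, 800))

  # starts at neutral within jitter
  expect_true(all(abs(tr[1, c("fe", "rdud", "ps")]) <= 4 * cfg$jitter_sd))

  # default config holds a neutral rest window first (the baseline frames)
  cfg_r <- phantom_config(cycles_per_dof = 20, seed = 42)
  tr_r <- generate_trajectory(cfg_r, 1)
  expect_equal(sum(tr_r$segment == "rest"), 20)
  expect_lt(max(abs(as.matrix(tr_r[tr_r$segment == "rest",
                                   c("fe", "rdud", "ps")]))), 4 * cfg_r$jitter_sd)

  # active DoF reaches near its range of motion; idle DoFs stay small
  fe_seg <- tr$segment == "fe"
  expect_gt(max(tr$fe[fe_seg]), 0.8 * cfg$rom["fe"])
  expect_lt(min(tr$fe[fe_seg]), -0.8 * cfg$rom["fe"])
  expect_lt(max(abs(tr$rdud[fe_seg])), 6 * cfg$jitter_sd)

  # determinism and session independence
  expect_identical(tr, generate_trajectory(cfg, session = 1))
  tr2 <- generate_trajectory(cfg, session = 2)
  expect_false(isTRUE(all.equal(tr$fe, tr2$fe)))
})

test_that("angle-conductivity map is zero at neutral, linear in gains, additive over blobs", {
  mesh <- forearm_model_400()$mesh
  blobs <- list(
    list(center = c(0.5, 0), radius = 0.2, gain = c(0.2, 0, 0)),
    list(center = c(-0.5, 0), radius = 0.2, gain = c(0, 0.1, 0.1))
  )
  cfg <- phantom_config(muscle_regions = blobs, seed = 1)
  expect_equal(angles_to_conductivity(c(0, 0, 0), cfg, mesh),
               numeric(nrow(mesh$elements)))

  a <- c(30, -10, 20)
  ds <- angles_to_conductivity(a, cfg, mesh)
  cfg2 <- phantom_config(muscle_regions = lapply(blobs, function(b) {
    b$gain <- 2 * b$gain; b
  }), seed = 1)
  expect_equal(angles_to_conductivity(a, cfg2, mesh), 2 * ds)

  # superposition over (disjointly supported) blobs
  cfg_a <- phantom_config(muscle_regions = blobs[1], seed = 1)
  cfg_b <- phantom_config(muscle_regions = blobs[2], seed = 1)
  expect_equal(angles_to_conductivity(a, cfg_a, mesh) +
                 angles_to_conductivity(a, cfg_b, mesh), ds)
})

test_that("asymmetry parameter controls linearity in the angles", {
  mesh <- forearm_model_400()$mesh
  lin <- phantom_config(asym = 0, seed = 1)
  a <- c(40, 10, -25)
  expect_equal(angles_to_conductivity(2 * a, lin, mesh),
               2 * angles_to_conductivity(a, lin, mesh))
  expect_equal(angles_to_conductivity(-a, lin, mesh),
               -angles_to_conductivity(a, lin, mesh))
  asym <- phantom_config(asym = 0.4, seed = 1)
  expect_false(isTRUE(all.equal(angles_to_conductivity(-a, asym, mesh),
                                -angles_to_conductivity(a, asym, mesh))))
})

test_that("noiseless neutral trajectory reproduces the baseline frame", {
  fm <- forearm_model_400()
  cfg <- phantom_config(cycles_per_dof = 1, cadence = 1, noise_sd = 0,
                        jitter_sd = 0, extent_jitter = 0,
                        rom = c(fe = 1e-9, rdud = 1e-9, ps = 1e-9), seed = 3)
  s <- simulate_session(cfg, fm)
  expect_equal(max(abs(sweep(s$frames, 2, fm$v0))) / max(abs(fm$v0)), 0,
               tolerance = 1e-8)
})

test_that("reconstructed image correlates with the injected conductivity field", {
  fm <- forearm_model_400()
  # small amplitude keeps the chain in its linear regime
  blobs <- lapply(default_muscle_regions(), function(b) { b$gain <- b$gain / 4; b })
  cfg <- phantom_config(muscle_regions = blobs, noise_sd = 0, seed = 8,
                        cycles_per_dof = 1)
  a <- c(45, 0, 0)                                   # mid-flexion posture
  ds_true <- angles_to_conductivity(a, cfg, fm$mesh)
  frame <- solve_forward(fm, fm$sigma0 + ds_true)
  rec <- build_reconstructor(fm, lam = 1e-2)
  ds_hat <- reconstruct_frame(rec, frame, fm$v0)
  expect_gt(cor(ds_hat, ds_true), 0.9)
})

test_that("sessions are seeded: reruns identical, sessions distinct", {
  fm <- forearm_model_400()
  cfg <- phantom_config(cycles_per_dof = 1, seed = 21)
  s1a <- simulate_session(cfg, fm, session = 1)
  s1b <- simulate_session(cfg, fm, session = 1)
  expect_identical(s1a$frames, s1b$frames)
  s2 <- simulate_session(cfg, fm, session = 2)
  expect_false(isTRUE(all.equal(s1a$frames, s2$frames)))
  expect_equal(s1a$t, s2$t)                          # same clock
})

test_that("conductivity clipping warns instead of failing", {
  fm <- forearm_model_400()
  blobs <- list(list(center = c(0.4, 0.3), radius = 0.4, gain = c(-40, 0, 0)))
  cfg <- phantom_config(muscle_regions = blobs, cycles_per_dof = 1,
                        noise_sd = 0, seed = 2)
  expect_warning(s <- simulate_session(cfg, fm), "clipped")
  expect_true(all(is.finite(s$frames)))
})
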