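#' Default synthetic muscle regions
#'
#' Three antagonistic muscle groups standing in for the forearm compartments
#' whose contraction state tracks wrist posture: a group responding mainly to
#' flexion/extension, one to radial/ulnar deviation and one to
#' pronation/supination. Each group is an agonist/antagonist pair of Gaussian
#' conductivity blobs on opposite sides of the cross-section (flexor-side
#' volar vs extensor-side dorsal, and so on): the agonist lobe at `center`
#' activates for positive gain-weighted drive, the antagonist lobe at
#' `antagonist_center` (default: `center` mirrored through the origin) for
#' negative drive. Gains are conductivity change (baseline units) per 90
#' degrees; magnitudes give peak changes of roughly 10-20% of baseline at
#' full range of motion, in line with the tens-of-percent conductivity
#' swings of contracting muscle.
#'
#' @return List of muscle groups, each
#'   `list(center, radius, gain[, antagonist_center])` with `gain` a length-3
#'   vector over (F/E, RD/UD, P/S).
#' @export
default_muscle_regions <- function() {
  list(
    list(center = c(0.45, 0.30), radius = 0.32, gain = c(0.22, 0.05, -0.03)),
    list(center = c(-0.35, 0.42), radius = 0.30, gain = c(-0.08, 0.20, 0.05)),
    list(center = c(0.05, -0.48), radius = 0.35, gain = c(0.03, -0.05, 0.24))
  )
}

#' Configuration of the synthetic recording protocol
#'
#' Describes the emulated experiment: per session, each degree of freedom
#' (F/E, then RD/UD, then P/S) is exercised for `cycles_per_dof` smooth
#' cycles from neutral to both extremes while the other two DoFs idle near
#' zero with small smooth jitter; two sessions are recorded at 10 Hz; frames
#' carry additive Gaussian measurement noise.
#'
#' @param muscle_regions Conductivity blobs, see [default_muscle_regions()].
#' @param noise_sd Voltage noise standard deviation as a fraction of the RMS
#'   of the baseline frame.
#' @param cycles_per_dof Cycles per DoF per session (default 20).
#' @param cadence Cycle period in seconds (default 4).
#' @param rom Range of motion in degrees per DoF, named `fe`, `rdud`, `ps`.
#'   F/E and P/S ranges are physiologically larger than RD/UD.
#' @param jitter_sd Approximate sd (degrees) of the idle-DoF jitter.
#' @param extent_jitter Relative sd of per-cycle peak-extent variation
#'   (emulates self-paced motion).
#' @param rest_s Neutral hold at the start of each session, seconds (default
#'   2): the subject rests at the neutral posture before the first cycle, and
#'   these frames are what the time-difference baseline is estimated from.
#' @param rate Sampling rate, Hz (default 10).
#' @param sessions Number of sessions (default 2).
#' @param seed RNG seed; session s uses stream `seed + 1000 * (s - 1)`.
#' @param asym Directional selectivity of the muscle response, in `[0, 1]`.
#'   Each group's scalar drive is `u = gain . angles / 90`; the agonist lobe
#'   responds with `act(u)` and the antagonist lobe with `act(-u)`, where
#'   `act(v) = (v + asym * |v|) / (1 + asym)`. At `asym = 1` each lobe only
#'   responds when it "contracts" (fully rectified activation, as paired
#'   agonist/antagonist muscles); at `asym = 0` the map is strictly linear
#'   (odd) in the angles. Monotone in the drive for any `asym` in `[0, 1]`.
#' @return Object of class `eit_phantom_config`.
#' @export
phantom_config <- function(muscle_regions = default_muscle_regions(),
                           noise_sd = 1e-3, cycles_per_dof = 20, cadence = 4,
                           rom = c(fe = 60, rdud = 25, ps = 70),
                           jitter_sd = 2, extent_jitter = 0.05, rest_s = 2,
                           rate = 10, sessions = 2, seed = 1, asym = 0.8) {
  stopifnot(noise_sd >= 0, cycles_per_dof >= 1, cadence > 0, rate > 0,
            sessions >= 1, all(rom > 0), length(rom) == 3,
            asym >= 0, asym <= 1, rest_s >= 0)
  for (b in muscle_regions) {
    stopifnot(length(b$center) == 2, b$radius > 0,
              length(b$gain) == 3, all(is.finite(b$gain)))
    if (!is.null(b$antagonist_center)) stopifnot(length(b$antagonist_center) == 2)
  }
  structure(list(muscle_regions = muscle_regions, noise_sd = noise_sd,
                 cycles_per_dof = cycles_per_dof, cadence = cadence,
                 rom = rom, jitter_sd = jitter_sd, extent_jitter = extent_jitter,
                 rest_s = rest_s, rate = rate, sessions = sessions,
                 seed = seed, asym = asym),
            class = "eit_phantom_config")
}

.dof_names <- c("fe", "rdud", "ps")
.segment_levels <- c("rest", "fe", "rdud", "ps")

.session_seed <- function(cfg, session) (cfg$seed + 1000L * (session - 1L)) %% .Machine$integer.max

# smooth near-zero idle-posture jitter: stationary AR(1) (correlation time
# tau) with a short binomial smooth, rescaled to the requested sd — postural
# micro-motion decorrelates over seconds rather than following any fixed
# low-dimensional curve
.smooth_jitter <- function(t, sd, tau = 1.5) {
  n <- length(t)
  if (sd <= 0 || n == 0) return(numeric(n))
  dt <- if (n > 1) stats::median(diff(t)) else 0.1
  rho <- exp(-dt / tau)
  x <- as.vector(stats::filter(stats::rnorm(n), rho, method = "recursive"))
  if (n >= 3) x <- as.vector(stats::filter(x, c(0.25, 0.5, 0.25), sides = 2))
  x[is.na(x)] <- 0
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(numeric(n))
  x * (sd / s)
}

#' Generate a reference wrist-angle trajectory for one session
#'
#' Deterministic given the config seed and session index. The session runs
#' the three DoFs in fixed order (F/E, RD/UD, P/S); the active DoF follows
#' `extent * sin(2*pi*t/cadence)` (neutral -> +max -> neutral -> -max ->
#' neutral per cycle) with per-cycle extent jitter, while idle DoFs carry
#' small smooth jitter.
#'
#' @param cfg An `eit_phantom_config`.
#' @param session Session index (1-based).
#' @return Data frame with columns `t` (s), `fe`, `rdud`, `ps` (degrees) and
#'   `segment` (factor: `"rest"` during the initial neutral hold, then which
#'   DoF is being exercised).
#' @export
generate_trajectory <- function(cfg, session = 1) {
  stopifnot(inherits(cfg, "eit_phantom_config"), session >= 1)
  set.seed(.session_seed(cfg, session))
  seg_dur <- cfg$cycles_per_dof * cfg$cadence
  n_seg <- as.integer(round(seg_dur * cfg$rate))
  n_rest <- as.integer(round(cfg$rest_s * cfg$rate))
  n <- n_rest + 3L * n_seg
  t_all <- (seq_len(n) - 1) / cfg$rate
  ang <- matrix(0, n, 3, dimnames = list(NULL, .dof_names))
  segment <- c(rep("rest", n_rest), rep(.dof_names, each = n_seg))
  if (n_rest > 0) {
    for (o in 1:3) ang[seq_len(n_rest), o] <- .smooth_jitter(t_all[seq_len(n_rest)],
                                                             cfg$jitter_sd)
  }
  for (d in 1:3) {
    idx <- n_rest + (d - 1L) * n_seg + seq_len(n_seg)
    tl <- t_all[idx] - t_all[idx[1]]
    cyc <- pmin(floor(tl / cfg$cadence), cfg$cycles_per_dof - 1) + 1
    extent <- cfg$rom[d] * (1 + cfg$extent_jitter * stats::rnorm(cfg$cycles_per_dof))
    ang[idx, d] <- extent[cyc] * sin(2 * pi * tl / cfg$cadence)
    for (o in setdiff(1:3, d)) {
      ang[idx, o] <- .smooth_jitter(tl, cfg$jitter_sd)
    }
  }
  out <- data.frame(t = t_all, ang,
                    segment = factor(segment, levels = .segment_levels))
  out
}

# spatial supports of agonist/antagonist lobes (nelem x n_groups each) and
# drive gains (n_groups x 3)
.blob_basis <- function(cfg, mesh) {
  cen <- mesh$centroids
  lobe <- function(center, radius) {
    d2 <- (cen[, 1] - center[1])^2 + (cen[, 2] - center[2])^2
    exp(-d2 / radius^2)
  }
  Phi_ago <- vapply(cfg$muscle_regions, function(b) lobe(b$center, b$radius),
                    numeric(nrow(cen)))
  Phi_ant <- vapply(cfg$muscle_regions, function(b) {
    ac <- if (is.null(b$antagonist_center)) -b$center else b$antagonist_center
    lobe(ac, b$radius)
  }, numeric(nrow(cen)))
  G <- t(vapply(cfg$muscle_regions, function(b) b$gain / 90, numeric(3)))
  list(Phi_ago = matrix(Phi_ago, ncol = length(cfg$muscle_regions)),
       Phi_ant = matrix(Phi_ant, ncol = length(cfg$muscle_regions)),
       G = matrix(G, ncol = 3))
}

#' Map wrist angles to a conductivity-change field
#'
#' Each muscle group has a scalar drive `u = gain . angles / 90` and two
#' Gaussian lobes on opposite sides of the cross-section: the agonist lobe
#' contributes `act(u) * exp(-dist^2 / r^2)` and the antagonist lobe
#' `act(-u)` on its own support, with the directionally selective activation
#' `act` of [phantom_config()]. The field is smooth in space, zero at the
#' neutral posture, scales linearly with the gains, and is additive over
#' groups; it is linear in the angles exactly when `asym = 0`.
#'
#' @param angles Length-3 numeric (degrees, order F/E, RD/UD, P/S) or an
#'   n x 3 matrix of samples.
#' @param cfg An `eit_phantom_config`.
#' @param mesh An `eit_mesh`.
#' @return Per-element conductivity change: a vector, or an n_elements x
#'   n_samples matrix for matrix input.
#' @export
angles_to_conductivity <- function(angles, cfg, mesh) {
  stopifnot(inherits(cfg, "eit_phantom_config"), inherits(mesh, "eit_mesh"))
  bb <- .blob_basis(cfg, mesh)
  vec_in <- !is.matrix(angles)
  if (vec_in) {
    stopifnot(length(angles) == 3)
    angles <- rbind(angles)
  }
  stopifnot(ncol(angles) == 3)
  U <- angles %*% t(bb$G)                     # per-sample group drives
  act <- function(v) (v + cfg$asym * abs(v)) / (1 + cfg$asym)
  out <- bb$Phi_ago %*% t(act(U)) + bb$Phi_ant %*% t(act(-U))
  if (vec_in) as.vector(out) else out
}

#' Simulate one recording session of EIT frames and reference angles
#'
#' Generates the session trajectory, maps angles to conductivity fields,
#' solves the FEM forward problem per 100 ms sample and adds i.i.d. Gaussian
#' voltage noise with sd `noise_sd * RMS(V0)`. Elements whose total
#' conductivity would drop to zero or below are clipped at 5% of baseline
#' with a warning. Frames and angles are time-aligned at the config rate.
#'
#' @param cfg An `eit_phantom_config`.
#' @param fm An `eit_forward_model` built on the mesh the blobs live in.
#' @param session Session index (seeds trajectory and noise streams).
#' @return Object of class `eit_session`: list with `t`, `frames` (n x
#'   frame_length), `angles` (n x 3 matrix), `segment`, `v0` (noise-free
#'   neutral frame) and the config.
#' @export
simulate_session <- function(cfg, fm, session = 1) {
  stopifnot(inherits(cfg, "eit_phantom_config"), inherits(fm, "eit_forward_model"))
  traj <- generate_trajectory(cfg, session)
  ang <- as.matrix(traj[, .dof_names])
  dsig <- angles_to_conductivity(ang, cfg, fm$mesh)    # nelem x n
  sig <- fm$sigma0 + dsig
  floor_sig <- 0.05 * fm$sigma0
  n_clip <- sum(sig < floor_sig)
  if (n_clip > 0) {
    warning(sprintf("clipped %d non-positive conductivity values at 5%% of baseline", n_clip))
    sig <- pmax(sig, floor_sig)
  }
  n <- nrow(traj)
  frames <- matrix(0, n, nrow(fm$pattern))
  ch <- .chol_cache(fm)
  for (i in seq_len(n)) {
    phi <- .solve_fields(fm, sig[, i], chol_cache = ch)
    frames[i, ] <- .frame_from_fields(fm, phi)
  }
  if (cfg$noise_sd > 0) {
    # noise stream continues the session RNG stream started by the trajectory
    sdv <- cfg$noise_sd * sqrt(mean(fm$v0^2))
    frames <- frames + matrix(stats::rnorm(length(frames), sd = sdv), nrow = n)
  }
  structure(list(t = traj$t, frames = frames, angles = ang,
                 segment = traj$segment, v0 = fm$v0, session = session,
                 config = cfg),
            class = "eit_session")
}

#' @export
print.eit_session <- function(x, ...) {
  cat(sprintf("EIT phantom session %d: %d frames x %d values, %.0f s at %g Hz\n",
              x$session, nrow(x$frames), ncol(x$frames), max(x$t), x$config$rate))
  invisible(x)
}
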