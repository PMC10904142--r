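# Synthetic task generators. Everything the package claims is testable
# without downloads:
#   (1) labeled tetrahedral stereocenters for R/S chirality recognition;
#   (2) Newtonian many-body trajectories under electrostatic, gravity and
#       Lorentz-like force fields, integrated with velocity Verlet.

#' Generate a labeled chiral-molecule dataset
#'
#' Each molecule is a tetrahedral stereocenter: a central atom at the
#' local origin surrounded by four substituents with distinct priority
#' labels (encoded as atom types `A1`..`A4`, highest priority first) at
#' randomized near-tetrahedral directions and bond lengths. The handedness
#' label is the sign of the signed volume
#' `det[v1 - v4, v2 - v4, v3 - v4]` over the priority-ordered substituent
#' positions: positive volume is labeled `R`, negative `S`. Every base
#' molecule is also emitted as its mirror image (z-negated before the
#' final rigid motion), which necessarily carries the opposite label, so
#' the dataset is balanced to within one sample. Each emitted molecule
#' receives an independent random rotation and translation; the label is
#' rigid-motion invariant by construction.
#'
#' Geometries whose signed volume falls below the degeneracy margin are
#' resampled, and coordinate noise is redrawn whenever it would push the
#' volume across the labeling margin, so labels are never ambiguous.
#'
#' @param n Total number of molecules to emit (mirror images included).
#' @param seed Integer seed; regeneration is bitwise identical per seed.
#' @param noise Standard deviation of isotropic Gaussian coordinate noise
#'   (same length units as the unit-order bond lengths).
#' @return List of `chiral_molecule` objects, each with `positions`
#'   (5 x 3; center first, then substituents in priority order), `types`,
#'   `label` (`"R"` or `"S"`), `node_order`, `pair_id` (shared by a
#'   molecule and its mirror) and `substituent_priorities`.
#' @export
generate_chiral_dataset <- function(n, seed, noise = 0.02) {
  if (n < 1L) stop("generate_chiral_dataset(): n must be >= 1")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  n_base <- ceiling(n / 2)
  out <- vector("list", 2L * n_base)
  idx <- 0L
  for (b in seq_len(n_base)) {
    base <- sample_stereocenter(noise)
    for (mirror in c(FALSE, TRUE)) {
      pos <- base$positions
      if (mirror) pos[, 3L] <- -pos[, 3L]
      lab <- chirality_label(pos)
      Q <- random_rotation()
      gtr <- stats::runif(3L, -3, 3)
      pos <- apply_rigid_motion(pos, Q, gtr)
      idx <- idx + 1L
      out[[idx]] <- structure(
        list(positions = pos,
             types = c("X0", "A1", "A2", "A3", "A4"),
             substituent_priorities = 1:4,
             label = lab, node_order = 1:5, pair_id = b),
        class = "chiral_molecule")
    }
  }
  out[seq_len(n)]
}

# Signed volume of the priority-ordered substituents (rows 2..5, center
# row 1 at the local frame origin is irrelevant to the determinant of
# differences).
signed_volume <- function(positions) {
  v <- positions[2:5, , drop = FALSE]
  det(rbind(v[1L, ] - v[4L, ], v[2L, ] - v[4L, ], v[3L, ] - v[4L, ]))
}

#' Handedness label of a stereocenter geometry
#'
#' @param positions 5 x 3 matrix, center first then substituents in
#'   priority order.
#' @return `"R"` for positive signed volume, `"S"` for negative.
#' @export
chirality_label <- function(positions) {
  vol <- signed_volume(positions)
  if (abs(vol) < 1e-6) stop("chirality_label(): degenerate geometry")
  if (vol > 0) "R" else "S"
}

sample_stereocenter <- function(noise, det_margin = 0.15) {
  repeat {
    dirs <- matrix(stats::rnorm(12L), 4L, 3L)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    lens <- stats::runif(4L, 0.9, 1.2)
    pos <- rbind(c(0, 0, 0), dirs * lens)
    if (abs(signed_volume(pos)) < det_margin) next
    if (noise > 0) {
      base_sign <- sign(signed_volume(pos))
      ok <- FALSE
      for (try in 1:50) {
        noisy <- pos + matrix(stats::rnorm(15L, sd = noise), 5L, 3L)
        vol <- signed_volume(noisy)
        if (abs(vol) > 1e-6 && sign(vol) == base_sign) {
          pos <- noisy
          ok <- TRUE
          break
        }
      }
      if (!ok) next
    }
    return(list(positions = pos))
  }
}

#' Default many-body simulation constants
#'
#' Softening `eps_soft` regularizes close encounters; `g0` is the uniform
#' downward gravity acceleration; `B0` the z-axis magnetic field strength
#' of the Lorentz-like force; `pos_sd` / `vel_sd` the standard deviations
#' of the Gaussian initial positions and velocities. All units are the
#' simulation's natural units (unit masses, unit |charge|).
#'
#' @return Named list of constants.
#' @export
nbody_constants <- function() {
  list(eps_soft = 0.1, g0 = 0.2, B0 = 1.0, pos_sd = 1.0, vel_sd = 0.5)
}

# Pairwise softened Coulomb forces plus optional external fields.
nbody_accel <- function(x, v, q, field_kind, k) {
  d1 <- outer(x[, 1L], x[, 1L], "-")
  d2 <- outer(x[, 2L], x[, 2L], "-")
  d3 <- outer(x[, 3L], x[, 3L], "-")
  r2 <- d1^2 + d2^2 + d3^2 + k$eps_soft^2
  w <- outer(q, q) / (r2 * sqrt(r2))
  diag(w) <- 0
  a <- cbind(rowSums(w * d1), rowSums(w * d2), rowSums(w * d3))
  if (field_kind == "G+ES") {
    a[, 3L] <- a[, 3L] - k$g0
  } else if (field_kind == "L+ES") {
    a <- a + q * cbind(v[, 2L] * k$B0, -v[, 1L] * k$B0, 0)
  }
  a
}

#' Simulate a Newtonian many-body trajectory
#'
#' Unit-mass particles with balanced unit charges interact through a
#' softened Coulomb force
#' \deqn{F_i = \sum_{j \ne i} q_i q_j (x_i - x_j) /
#'       (\|x_i - x_j\|^2 + \epsilon^2)^{3/2},}
#' optionally composed with a uniform gravity field `(0, 0, -g0)`
#' (`"G+ES"`) or a Lorentz-like force `q (v x B)`, `B = (0, 0, B0)`
#' (`"L+ES"`). Integration uses velocity Verlet (with the velocity-
#' dependent Lorentz term evaluated at the half-step velocity), which
#' conserves total momentum of the pure electrostatic system to rounding
#' accuracy and keeps energy drift bounded.
#'
#' @param n_particles Number of particles (>= 2).
#' @param field_kind `"ES"`, `"G+ES"` or `"L+ES"`.
#' @param n_steps Number of integration steps.
#' @param dt Time step.
#' @param seed Integer seed for the Gaussian initial conditions.
#' @param constants Constants list, see [nbody_constants()].
#' @param charges Optional explicit charge vector (defaults to a balanced
#'   shuffled mix of +1 and -1).
#' @param x0,v0 Optional explicit initial positions/velocities (N x 3).
#' @return `nbody_trajectory`: list with `positions` and `velocities`
#'   (`(n_steps + 1) x N x 3` arrays), `charges`, `field_kind`, `dt` and
#'   `meta` (seed and constants).
#' @export
simulate_nbody <- function(n_particles, field_kind = c("ES", "G+ES", "L+ES"),
                           n_steps = 1200L, dt = 1e-2, seed = 0L,
                           constants = nbody_constants(), charges = NULL,
                           x0 = NULL, v0 = NULL) {
  field_kind <- match.arg(field_kind)
  if (n_particles < 2L && is.null(x0)) {
    stop("simulate_nbody(): need at least 2 particles")
  }
  if (dt <= 0) stop("simulate_nbody(): dt must be positive")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  if (is.null(charges)) {
    half <- n_particles %/% 2L
    charges <- sample(c(rep(1, n_particles - half), rep(-1, half)))
  }
  n_particles <- length(charges)
  if (is.null(x0)) {
    x0 <- matrix(stats::rnorm(3L * n_particles, sd = constants$pos_sd),
                 n_particles, 3L)
  }
  if (is.null(v0)) {
    v0 <- matrix(stats::rnorm(3L * n_particles, sd = constants$vel_sd),
                 n_particles, 3L)
  }
  pos <- array(0, dim = c(n_steps + 1L, n_particles, 3L))
  vel <- array(0, dim = c(n_steps + 1L, n_particles, 3L))
  x <- x0
  v <- v0
  pos[1L, , ] <- x
  vel[1L, , ] <- v
  a <- nbody_accel(x, v, charges, field_kind, constants)
  for (step in seq_len(n_steps)) {
    x_new <- x + v * dt + 0.5 * a * dt^2
    v_half <- v + 0.5 * a * dt
    a_new <- nbody_accel(x_new, v_half, charges, field_kind, constants)
    v <- v + 0.5 * (a + a_new) * dt
    x <- x_new
    a <- a_new
    pos[step + 1L, , ] <- x
    vel[step + 1L, , ] <- v
  }
  structure(list(positions = pos, velocities = vel, charges = charges,
                 field_kind = field_kind, dt = dt,
                 meta = list(seed = as.integer(seed), constants = constants,
                             n_steps = as.integer(n_steps))),
            class = "nbody_trajectory")
}

#' Total momentum at every stored frame
#'
#' @param traj An `nbody_trajectory`.
#' @return `(n_steps + 1)` x 3 matrix of summed momenta (unit masses).
#' @export
total_momentum <- function(traj) {
  apply(traj$velocities, c(1L, 3L), sum)
}

#' Total energy of an electrostatic system at every stored frame
#'
#' Kinetic energy plus the softened Coulomb potential
#' `sum_{i<j} q_i q_j / sqrt(|x_i - x_j|^2 + eps^2)` (whose negative
#' gradient is exactly the simulated force). Meaningful for
#' `field_kind = "ES"`; the external-field variants add potentials not
#' included here.
#'
#' @param traj An `nbody_trajectory`.
#' @param eps_soft Softening length used in the simulation.
#' @return Numeric vector of total energies, one per stored frame.
#' @export
nbody_energy <- function(traj, eps_soft = traj$meta$constants$eps_soft) {
  if (is.null(eps_soft)) eps_soft <- nbody_constants()$eps_soft
  nt <- dim(traj$positions)[1L]
  np <- dim(traj$positions)[2L]
  q <- traj$charges
  vapply(seq_len(nt), function(t) {
    x <- matrix(traj$positions[t, , ], np, 3L)
    v <- matrix(traj$velocities[t, , ], np, 3L)
    ke <- 0.5 * sum(v^2)
    pe <- 0
    for (i in seq_len(np - 1L)) {
      for (j in (i + 1L):np) {
        r2 <- sum((x[i, ] - x[j, ])^2)
        pe <- pe + q[i] * q[j] / sqrt(r2 + eps_soft^2)
      }
    }
    ke + pe
  }, numeric(1L))
}

#' Slice a trajectory into a forecasting example
#'
#' @param traj An `nbody_trajectory`.
#' @param t_in Input frame index (0-based step count; 0 is the initial
#'   state).
#' @param horizon Number of steps ahead to forecast.
#' @return List with `cloud` (a [point_cloud()] carrying positions,
#'   velocities and charge-sign types `q+` / `q-`) and `target`
#'   (N x 3 positions after `horizon` steps).
#' @export
make_forecast_dataset <- function(traj, t_in, horizon) {
  n_steps <- dim(traj$positions)[1L] - 1L
  if (t_in < 0L || t_in + horizon > n_steps) {
    stop("make_forecast_dataset(): frame index out of range")
  }
  np <- dim(traj$positions)[2L]
  at <- function(arr, t) matrix(arr[t + 1L, , ], nrow = np, ncol = 3L)
  cloud <- point_cloud(positions = at(traj$positions, t_in),
                       types = ifelse(traj$charges > 0, "q+", "q-"),
                       velocities = at(traj$velocities, t_in),
                       type_vocab = c("q-", "q+"))
  list(cloud = cloud, target = at(traj$positions, t_in + horizon))
}

#' Write a trajectory as a tidy CSV table
#'
#' Schema: `id, t, x, y, z, vx, vy, vz, charge`, one row per particle and
#' stored frame.
#'
#' @param traj An `nbody_trajectory`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_trajectory_csv <- function(traj, path) {
  d <- dim(traj$positions)
  nt <- d[1L]; np <- d[2L]
  df <- data.frame(
    id = rep(seq_len(np), times = nt),
    t = rep(seq_len(nt) - 1L, each = np),
    x = as.vector(aperm(traj$positions, c(2L, 1L, 3L))[, , 1L]),
    y = as.vector(aperm(traj$positions, c(2L, 1L, 3L))[, , 2L]),
    z = as.vector(aperm(traj$positions, c(2L, 1L, 3L))[, , 3L]),
    vx = as.vector(aperm(traj$velocities, c(2L, 1L, 3L))[, , 1L]),
    vy = as.vector(aperm(traj$velocities, c(2L, 1L, 3L))[, , 2L]),
    vz = as.vector(aperm(traj$velocities, c(2L, 1L, 3L))[, , 3L]),
    charge = rep(traj$charges, times = nt))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory_csv()]
#'
#' @param path CSV path.
#' @param field_kind Field label to attach (not stored in the CSV).
#' @param dt Time step to attach.
#' @return An `nbody_trajectory`.
#' @export
read_trajectory_csv <- function(path, field_kind = "ES", dt = 1e-2) {
  df <- utils::read.csv(path)
  ids <- sort(unique(df$id))
  ts <- sort(unique(df$t))
  np <- length(ids); nt <- length(ts)
  pos <- array(0, dim = c(nt, np, 3L))
  vel <- array(0, dim = c(nt, np, 3L))
  df <- df[order(df$t, df$id), ]
  pos[, , 1L] <- matrix(df$x, nt, np, byrow = TRUE)
  pos[, , 2L] <- matrix(df$y, nt, np, byrow = TRUE)
  pos[, , 3L] <- matrix(df$z, nt, np, byrow = TRUE)
  vel[, , 1L] <- matrix(df$vx, nt, np, byrow = TRUE)
  vel[, , 2L] <- matrix(df$vy, nt, np, byrow = TRUE)
  vel[, , 3L] <- matrix(df$vz, nt, np, byrow = TRUE)
  charges <- df$charge[df$t == ts[1L]]
  structure(list(positions = pos, velocities = vel, charges = charges,
                 field_kind = field_kind, dt = dt,
                 meta = list(seed = NA_integer_, constants = NULL,
                             n_steps = nt - 1L)),
            class = "nbody_trajectory")
}

#' Featurize a chiral molecule
#'
#' @param mol A `chiral_molecule`.
#' @param k Neighbors per node (default 4: fully connected for 5 atoms).
#' @param config A [featurize_config()]; `d_max` defaults to 4 length
#'   units, matching bond-scale geometry.
#' @return A `graph_state`.
#' @export
featurize_molecule <- function(mol, k = 4L,
                               config = featurize_config(n_rbf = 16L,
                                                         d_max = 4)) {
  cloud <- point_cloud(mol$positions, mol$types, node_order = mol$node_order,
                       type_vocab = c("X0", "A1", "A2", "A3", "A4"))
  featurize_cloud(cloud, k, config)
}
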