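# Generators: chirality labels and many-body physics.

test_that("chiral dataset is balanced, mirror-paired and label-consistent", {
  mols <- generate_chiral_dataset(100L, seed = 4L)
  labs <- vapply(mols, `[[`, character(1L), "label")
  expect_lte(abs(sum(labs == "R") - sum(labs == "S")), 1L)
  # consecutive mirror pairs share pair_id and carry opposite labels
  pid <- vapply(mols, `[[`, integer(1L), "pair_id")
  for (b in unique(pid)) {
    idx <- which(pid == b)
    if (length(idx) == 2L) {
      expect_false(mols[[idx[1L]]]$label == mols[[idx[2L]]]$label)
    }
  }
  # independent signed-volume oracle: triple product computed by hand
  for (m in mols[1:30]) {
    v <- m$positions[2:5, ]
    u1 <- v[1L, ] - v[4L, ]; u2 <- v[2L, ] - v[4L, ]; u3 <- v[3L, ] - v[4L, ]
    vol <- u1[1L] * (u2[2L] * u3[3L] - u2[3L] * u3[2L]) -
      u1[2L] * (u2[1L] * u3[3L] - u2[3L] * u3[1L]) +
      u1[3L] * (u2[1L] * u3[2L] - u2[2L] * u3[1L])
    expect_equal(m$label, if (vol > 0) "R" else "S")
    expect_gt(abs(vol), 1e-6)
  }
  # bitwise reproducibility per seed
  again <- generate_chiral_dataset(100L, seed = 4L)
  expect_identical(mols, again)
})

test_that("chirality labels are rigid-motion invariant and flip under mirroring", {
  mols <- generate_chiral_dataset(40L, seed = 5L)
  for (i in seq(1L, 39L, by = 4L)) {
    m <- mols[[i]]
    mo <- random_rigid_motion(900L + i)
    moved <- apply_rigid_motion(m$positions, mo$Q, mo$g)
    expect_equal(chirality_label(moved), m$label)
    mir <- m$positions
    mir[, 1L] <- -mir[, 1L]
    expect_false(chirality_label(mir) == m$label)
  }
  expect_error(chirality_label(matrix(0, 5L, 3L)), "degenerate")
})

test_that("opposite charges attract and ES momentum is conserved", {
  x0 <- rbind(c(-1, 0, 0), c(1, 0, 0))
  tr <- simulate_nbody(2L, "ES", n_steps = 50L, dt = 1e-2, seed = 1L,
                       charges = c(1, -1), x0 = x0,
                       v0 = matrix(0, 2L, 3L))
  # the gap shrinks
  gap0 <- tr$positions[1L, 2L, 1L] - tr$positions[1L, 1L, 1L]
  gap1 <- tr$positions[51L, 2L, 1L] - tr$positions[51L, 1L, 1L]
  expect_lt(gap1, gap0)
  mom <- total_momentum(tr)
  expect_lt(max(abs(mom)), 1e-10)

  tr5 <- simulate_nbody(5L, "ES", n_steps = 400L, dt = 1e-2, seed = 2L)
  mom5 <- total_momentum(tr5)
  expect_lt(max(abs(sweep(mom5, 2L, mom5[1L, ], "-"))), 1e-10)
})

test_that("the ES simulator commutes with rotations of the initial state", {
  tr <- simulate_nbody(5L, "ES", n_steps = 150L, dt = 1e-2, seed = 3L)
  mo <- random_rigid_motion(77L)
  x0 <- matrix(tr$positions[1L, , ], 5L, 3L) %*% t(mo$Q)
  v0 <- matrix(tr$velocities[1L, , ], 5L, 3L) %*% t(mo$Q)
  tr_rot <- simulate_nbody(5L, "ES", n_steps = 150L, dt = 1e-2, seed = 3L,
                           charges = tr$charges, x0 = x0, v0 = v0)
  ref <- matrix(tr$positions[151L, , ], 5L, 3L) %*% t(mo$Q)
  expect_lt(max(abs(tr_rot$positions[151L, , ] - ref)), 1e-10)
})

test_that("gravity breaks full SO(3) but keeps z-axis rotations", {
  theta <- 1.1
  Qz <- rbind(c(cos(theta), -sin(theta), 0),
              c(sin(theta), cos(theta), 0),
              c(0, 0, 1))
  tr <- simulate_nbody(4L, "G+ES", n_steps = 100L, dt = 1e-2, seed = 6L)
  x0 <- matrix(tr$positions[1L, , ], 4L, 3L) %*% t(Qz)
  v0 <- matrix(tr$velocities[1L, , ], 4L, 3L) %*% t(Qz)
  tr_rot <- simulate_nbody(4L, "G+ES", n_steps = 100L, dt = 1e-2, seed = 6L,
                           charges = tr$charges, x0 = x0, v0 = v0)
  ref <- matrix(tr$positions[101L, , ], 4L, 3L) %*% t(Qz)
  expect_lt(max(abs(tr_rot$positions[101L, , ] - ref)), 1e-10)
  # a generic (non-z) rotation does not commute with the gravity field
  Qg <- random_rigid_motion(78L)$Q
  x0g <- matrix(tr$positions[1L, , ], 4L, 3L) %*% t(Qg)
  v0g <- matrix(tr$velocities[1L, , ], 4L, 3L) %*% t(Qg)
  tr_g <- simulate_nbody(4L, "G+ES", n_steps = 100L, dt = 1e-2, seed = 6L,
                         charges = tr$charges, x0 = x0g, v0 = v0g)
  refg <- matrix(tr$positions[101L, , ], 4L, 3L) %*% t(Qg)
  expect_gt(max(abs(tr_g$positions[101L, , ] - refg)), 1e-3)
})

test_that("energy drift shrinks as the time step is refined", {
  drifts <- vapply(c(1e-2, 5e-3, 2.5e-3), function(dt) {
    n_steps <- round(4 / dt)
    tr <- simulate_nbody(5L, "ES", n_steps = n_steps, dt = dt, seed = 8L)
    en <- nbody_energy(tr)
    max(abs(en - en[1L]))
  }, numeric(1L))
  expect_true(all(diff(drifts) < 0))
})

test_that("a single charge in the Lorentz field follows the cyclotron orbit", {
  v_perp <- 0.7
  tr <- simulate_nbody(1L, "L+ES", n_steps = 6300L, dt = 1e-3, seed = 9L,
                       charges = 1, x0 = matrix(0, 1L, 3L),
                       v0 = matrix(c(v_perp, 0, 0), 1L, 3L))
  xy <- tr$positions[, 1L, 1:2]
  ctr <- colMeans(xy)
  radii <- sqrt((xy[, 1L] - ctr[1L])^2 + (xy[, 2L] - ctr[2L])^2)
  expected <- v_perp / nbody_constants()$B0
  expect_lt(abs(mean(radii) - expected) / expected, 0.01)
})

test_that("forecast slicing honors horizons and closed-form free flight", {
  tr <- simulate_nbody(4L, "ES", n_steps = 100L, dt = 1e-2, seed = 10L)
  ex0 <- make_forecast_dataset(tr, 20L, 0L)
  expect_equal(ex0$target, ex0$cloud$positions)
  expect_error(make_forecast_dataset(tr, 90L, 20L), "out of range")
  # chargeless particles drift ballistically: target = x + v * h * dt
  trf <- simulate_nbody(4L, "ES", n_steps = 80L, dt = 1e-2, seed = 11L,
                        charges = rep(0, 4L))
  ex <- make_forecast_dataset(trf, 10L, 50L)
  expect_lt(max(abs(ex$target -
                      (ex$cloud$positions + ex$cloud$velocities * 0.5))),
            1e-10)
  # all-static variant: zero charge and zero velocity
  trs <- simulate_nbody(3L, "ES", n_steps = 50L, dt = 1e-2, seed = 12L,
                        charges = rep(0, 3L), v0 = matrix(0, 3L, 3L))
  exs <- make_forecast_dataset(trs, 0L, 50L)
  expect_equal(exs$target, exs$cloud$positions)
})

test_that("trajectory CSV files round-trip", {
  tr <- simulate_nbody(3L, "ES", n_steps = 5L, dt = 1e-2, seed = 13L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  back <- read_trajectory_csv(path)
  expect_equal(back$positions, tr$positions, tolerance = 1e-9)
  expect_equal(back$velocities, tr$velocities, tolerance = 1e-9)
  expect_equal(back$charges, tr$charges)
})
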