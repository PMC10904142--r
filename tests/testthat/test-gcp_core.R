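# Unit and property tests for the geometry-complete perceptron.

make_edge_frames <- function(n_edges, seed = 1L) {
  set.seed(seed)
  Xc <- centralize(matrix(rnorm(3L * (n_edges + 1L)), n_edges + 1L, 3L))$Xc
  edges <- cbind(seq_len(n_edges), seq_len(n_edges) + 1L)
  list(frames = localize(Xc, edges), edges = edges, Xc = Xc)
}

test_that("scalarize recovers unit projections and its parity structure", {
  ef <- make_edge_frames(6L)
  fr <- ef$frames
  # channel 1 = the a axis itself, channels 2-3 zero -> q = (1, 0, ..., 0)
  Vs <- array(0, dim = c(6L, 3L, 3L))
  Vs[, 1L, ] <- fr$a
  q <- scalarize(Vs, fr, ef$edges, "edge")
  expect_equal(q[, 1L], rep(1, 6L), tolerance = 1e-6)
  expect_lt(max(abs(q[, -1L])), 1e-6)

  # invariance under a joint rotation of features and geometry
  set.seed(2)
  Vs <- array(rnorm(6L * 9L), dim = c(6L, 3L, 3L))
  q <- scalarize(Vs, fr, ef$edges, "edge")
  for (i in 1:25) {
    Q <- random_rotation()
    fr_rot <- localize(ef$Xc %*% t(Q), ef$edges)
    q_rot <- scalarize(sv_rotate_V(Vs, Q), fr_rot, ef$edges, "edge")
    expect_lt(max(abs(q_rot - q)), 1e-10)
  }

  # point inversion of the geometry flips the entries against a and c
  # (columns 1, 4, 7 and 3, 6, 9) and fixes those against b (2, 5, 8)
  fr_inv <- localize(-ef$Xc, ef$edges)
  q_inv <- scalarize(Vs, fr_inv, ef$edges, "edge")
  a_c_cols <- c(1L, 3L, 4L, 6L, 7L, 9L)
  b_cols <- c(2L, 5L, 8L)
  expect_lt(max(abs(q_inv[, a_c_cols] + q[, a_c_cols])), 1e-10)
  expect_lt(max(abs(q_inv[, b_cols] - q[, b_cols])), 1e-10)
})

test_that("node-entity scalarize averages over outgoing edges", {
  set.seed(3)
  Xc <- centralize(matrix(rnorm(15L), 5L, 3L))$Xc
  edges <- knn_graph(Xc, 2L)
  fr <- localize(Xc, edges)
  Vs <- array(rnorm(5L * 9L), dim = c(5L, 3L, 3L))
  q <- scalarize(Vs, fr, edges, "node")
  # brute-force oracle: per-edge projections of the source node's
  # channels, averaged per source
  for (i in 1:5) {
    eid <- which(edges[, 1L] == i)
    acc <- matrix(0, length(eid), 9L)
    for (row in seq_along(eid)) {
      e <- eid[row]
      for (ch in 1:3) {
        acc[row, 3L * (ch - 1L) + 1L] <- sum(Vs[i, ch, ] * fr$a[e, ])
        acc[row, 3L * (ch - 1L) + 2L] <- sum(Vs[i, ch, ] * fr$b[e, ])
        acc[row, 3L * (ch - 1L) + 3L] <- sum(Vs[i, ch, ] * fr$c[e, ])
      }
    }
    expect_equal(q[i, ], colMeans(acc), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("gcp channel maps are linear and the 3-4-5 norm feature is exact", {
  # zero vector input propagates to zero downscaled channels
  V <- gcpnet:::vchan_zeros(4L, 6L)
  W <- matrix(rnorm(12L), 6L, 2L)
  expect_equal(gcpnet:::vchan_map(V, W), gcpnet:::vchan_zeros(4L, 2L))
  # identity map with lambda = 1
  set.seed(4)
  V <- array(rnorm(4L * 6L * 3L), dim = c(4L, 6L, 3L))
  expect_equal(gcpnet:::vchan_map(V, diag(6)), V)
  # guarded norms: a (3, 4, 0) channel reports 5 within the eps guard
  V1 <- array(0, dim = c(1L, 1L, 3L))
  V1[1L, 1L, ] <- c(3, 4, 0)
  expect_equal(gcpnet:::vchan_norm(V1)[1L, 1L], 5, tolerance = 1e-8)
  # channel maps commute with rotation
  Q <- random_rotation()
  expect_lt(max(abs(gcpnet:::vchan_map(sv_rotate_V(V, Q), W) -
                      sv_rotate_V(gcpnet:::vchan_map(V, W), Q))), 1e-12)
})

test_that("gcp forward honors zero inputs, open gates and residual identity", {
  ef <- make_edge_frames(5L)
  cfg <- gcp_config(omega = 1L)
  set.seed(7)
  p <- gcp_init(4L, 3L, 4L, 3L, cfg)

  # zero vector input: V' = 0 regardless of the gate
  sv0 <- scalar_vector(matrix(rnorm(20L), 5L, 4L), gcpnet:::vchan_zeros(5L, 3L))
  out0 <- gcp_forward(sv0, ef$frames, ef$edges, "edge", p, cfg)$out
  expect_lt(max(abs(out0$V)), 1e-12)

  # open gate: a huge gate offset makes V' equal the updated channels
  sv_in <- scalar_vector(matrix(rnorm(20L), 5L, 4L),
                         array(rnorm(45L), dim = c(5L, 3L, 3L)))
  p_open <- p
  p_open$w_g <- p$w_g * 0
  p_open$b_g <- rep(50, 3L)
  out_open <- gcp_forward(sv_in, ef$frames, ef$edges, "edge", p_open, cfg)$out
  z <- gcpnet:::vchan_map(sv_in$V, p_open$w_dz)
  Vu <- gcpnet:::vchan_map(z, p_open$w_uz)
  expect_lt(max(abs(out_open$V - Vu)), 1e-10)

  # zero-initialized maps turn the residual wrapper into the identity
  p_zero <- zero_gcp_fields(p)
  res <- resgcp_forward(sv_in, ef$frames, ef$edges, "edge", p_zero, cfg)$out
  expect_equal(res$s, sv_in$s)
  expect_equal(res$V, sv_in$V)

  # the residual wrapper equals plain output plus input
  plain <- gcp_forward(sv_in, ef$frames, ef$edges, "edge", p, cfg)$out
  res2 <- resgcp_forward(sv_in, ef$frames, ef$edges, "edge", p, cfg)$out
  expect_equal(res2$s, plain$s + sv_in$s)
  expect_equal(res2$V, plain$V + sv_in$V)

  expect_error(gcp_init(0L, 0L, 4L, 0L), "zero-width")
  expect_error(gcp_init(4L, 0L, 4L, 2L), "vector channels")
})

test_that("gcp outputs are rotation-invariant scalars and equivariant vectors", {
  ef <- make_edge_frames(8L, seed = 21L)
  cfg <- gcp_config()
  set.seed(8)
  p <- gcp_init(5L, 4L, 6L, 3L, cfg)
  sv_in <- scalar_vector(matrix(rnorm(40L), 8L, 5L),
                         array(rnorm(96L), dim = c(8L, 4L, 3L)))
  base <- gcp_forward(sv_in, ef$frames, ef$edges, "edge", p, cfg)$out
  for (i in 1:30) {
    Q <- random_rotation()
    fr_rot <- localize(ef$Xc %*% t(Q), ef$edges)
    rot_in <- scalar_vector(sv_in$s, sv_rotate_V(sv_in$V, Q))
    out <- gcp_forward(rot_in, fr_rot, ef$edges, "edge", p, cfg)$out
    expect_lt(max(abs(out$s - base$s)), 1e-10)
    expect_lt(max(abs(out$V - sv_rotate_V(base$V, Q))), 1e-10)
  }
})

test_that("frame-aware scalars separate mirror images; frame-free do not", {
  ef <- make_edge_frames(8L, seed = 22L)
  set.seed(9)
  sv_in <- scalar_vector(matrix(rnorm(40L), 8L, 5L),
                         array(rnorm(96L), dim = c(8L, 4L, 3L)))
  M <- diag(c(1, 1, -1))
  fr_mir <- localize(ef$Xc %*% M, ef$edges)
  mir_in <- scalar_vector(sv_in$s, sv_rotate_V(sv_in$V, M))
  for (frames_on in c(TRUE, FALSE)) {
    cfg <- gcp_config(use_frames = frames_on)
    set.seed(10)
    p <- gcp_init(5L, 4L, 6L, 3L, cfg)
    s1 <- gcp_forward(sv_in, ef$frames, ef$edges, "edge", p, cfg)$out$s
    s2 <- gcp_forward(mir_in, fr_mir, ef$edges, "edge", p, cfg)$out$s
    if (frames_on) {
      expect_gt(max(abs(s1 - s2)), 1e-3)
    } else {
      expect_lt(max(abs(s1 - s2)), 1e-10)
    }
  }
})

test_that("hand-written gcp gradients match finite differences", {
  ef <- make_edge_frames(6L, seed = 23L)
  cfg <- gcp_config()
  set.seed(12)
  p <- gcp_init(3L, 2L, 4L, 2L, cfg)
  sv_in <- scalar_vector(matrix(rnorm(18L), 6L, 3L),
                         array(rnorm(36L), dim = c(6L, 2L, 3L)))
  R_s <- matrix(rnorm(24L), 6L, 4L)
  R_V <- array(rnorm(36L), dim = c(6L, 2L, 3L))
  loss <- function(pp) {
    o <- gcp_forward(sv_in, ef$frames, ef$edges, "edge", pp, cfg)$out
    sum(o$s * R_s) + sum(o$V * R_V)
  }
  fw <- gcp_forward(sv_in, ef$frames, ef$edges, "edge", p, cfg,
                    keep_cache = TRUE)
  bw <- gcp_backward(R_s, R_V, fw$cache, p, cfg)
  # directional derivative along the analytic gradient
  ana <- grad_sq_norm(bw$grads)
  eps <- 1e-6
  num <- (loss(perturb_params(p, bw$grads, eps)) -
            loss(perturb_params(p, bw$grads, -eps))) / (2 * eps)
  expect_equal(num, ana, tolerance = 1e-6)
})
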