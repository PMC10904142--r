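# Property audits: executable checks of the symmetry claims. Each audit
# builds random graphs and randomly initialized networks, applies group
# actions to the inputs and measures how far the outputs deviate from the
# transformed references. The audits are exposed programmatically (for
# tests) and through the command-line surface.

#' Build a random featurized graph for audits
#'
#' Gaussian positions, random types from a 4-letter vocabulary, random
#' velocities, a sequence order — every feature family is exercised.
#'
#' @param n_nodes Number of nodes.
#' @param seed Integer seed.
#' @param k Neighbors per node.
#' @return A `graph_state`.
#' @export
random_graph_state <- function(n_nodes = 30L, seed = 0L, k = 8L) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  vocab <- c("A", "B", "C", "D")
  cloud <- point_cloud(
    positions = matrix(stats::rnorm(3L * n_nodes), n_nodes, 3L),
    types = sample(vocab, n_nodes, replace = TRUE),
    velocities = matrix(stats::rnorm(3L * n_nodes, sd = 0.5), n_nodes, 3L),
    node_order = sample.int(n_nodes), type_vocab = vocab)
  featurize_cloud(cloud, k = min(k, n_nodes - 1L),
                  config = featurize_config(n_rbf = 8L, d_max = 6))
}

#' Apply a rigid motion (or improper rotation) to a graph state
#'
#' Rotates the coordinates and every vector feature channel; scalar
#' features, topology and batching are untouched. `Q` may be improper
#' (det = -1) to build mirror images.
#'
#' @param state A `graph_state`.
#' @param Q 3 x 3 orthogonal matrix.
#' @param g Length-3 translation (applied to coordinates only).
#' @return Transformed `graph_state`.
#' @export
transform_graph_state <- function(state, Q, g = c(0, 0, 0)) {
  state$X <- apply_rigid_motion(state$X, Q, g)
  state$node <- scalar_vector(state$node$s, sv_rotate_V(state$node$V, Q))
  state$edge <- scalar_vector(state$edge$s, sv_rotate_V(state$edge$V, Q))
  state
}

#' Mirror a graph state through the xy-plane
#'
#' @param state A `graph_state`.
#' @return The reflected state (an enantiomer of the input geometry).
#' @export
mirror_graph_state <- function(state) {
  transform_graph_state(state, diag(c(1, 1, -1)))
}

audit_net_config <- function(update_positions = TRUE, gcp = gcp_config(),
                             out_node = c(8L, 2L)) {
  if (!gcp$use_vectors) out_node[2L] <- 0L
  gcpnet_config(hidden_node = c(16L, 4L), hidden_edge = c(8L, 2L),
                out_node = out_node, n_layers = 2L, k = 8L,
                update_positions = update_positions, gcp = gcp)
}

#' SE(3) equivariance audit
#'
#' Runs a randomly initialized network on a random graph, then on rigidly
#' moved copies, and reports the largest deviations of (a) the scalar
#' node outputs from the originals, (b) the vector node outputs from
#' their Q-rotated references and (c) the output positions from the
#' Q-rotated, g-translated references.
#'
#' @param seed Integer seed.
#' @param n_nodes Nodes in the audit graph.
#' @param n_motions Number of random rigid motions.
#' @param update_positions Audit the position-update path too.
#' @return List of max absolute deviations: `scalar`, `vector`,
#'   `position`.
#' @export
audit_equivariance <- function(seed = 0L, n_nodes = 30L, n_motions = 100L,
                               update_positions = TRUE) {
  state <- random_graph_state(n_nodes, seed)
  config <- audit_net_config(update_positions)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed) + 1L)
  w <- state_widths(state)
  params <- gcpnet_init(w$node, w$edge, config)
  base <- gcpnet_forward(state, params, config)
  dev_s <- 0; dev_v <- 0; dev_x <- 0
  for (i in seq_len(n_motions)) {
    Q <- random_rotation()
    g <- stats::runif(3L, -5, 5)
    fw <- gcpnet_forward(transform_graph_state(state, Q, g), params, config)
    dev_s <- max(dev_s, max(abs(fw$node$s - base$node$s)))
    if (!is.null(base$node$V)) {
      dev_v <- max(dev_v, max(abs(fw$node$V - sv_rotate_V(base$node$V, Q))))
    }
    ref_x <- apply_rigid_motion(base$X, Q, g)
    dev_x <- max(dev_x, max(abs(fw$X - ref_x)))
  }
  list(scalar = dev_s, vector = dev_v, position = dev_x)
}

#' Geometric self-consistency and chirality audit
#'
#' Checks that rigid-motion copies of a generic graph give identical
#' pooled scalar representations while its mirror image gives a clearly
#' different one when frames are enabled — and an identical one when they
#' are disabled (the E(3) ablation).
#'
#' @param seed Integer seed.
#' @param n_nodes Nodes in the audit graph.
#' @param n_motions Rigid motions tested.
#' @param n_inits Independently initialized networks probed; the audit
#'   reports the worst case over all of them.
#' @return List with `rigid_dev` (max pooled deviation over rigid
#'   motions), `mirror_diff_frames` (largest max-abs pooled difference
#'   against the mirror image over the probed networks) and
#'   `mirror_diff_noframes` (the same for the frame-free ablation).
#' @export
audit_self_consistency <- function(seed = 0L, n_nodes = 30L,
                                   n_motions = 20L, n_inits = 3L) {
  state <- random_graph_state(n_nodes, seed)
  mirrored <- mirror_graph_state(state)
  pooled <- function(config, params, st) {
    fw <- gcpnet_forward(st, params, config)
    pool_graph(fw$node$s, "sum", st$batch)
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  res <- list(rigid_dev = 0, mirror_diff_frames = 0,
              mirror_diff_noframes = 0)
  w <- state_widths(state)
  for (frames_on in c(TRUE, FALSE)) {
    config <- audit_net_config(update_positions = FALSE,
                               gcp = gcp_config(use_frames = frames_on))
    for (init in seq_len(n_inits)) {
      set.seed(as.integer(seed) + init)
      params <- gcpnet_init(w$node, w$edge, config)
      base <- pooled(config, params, state)
      mdiff <- max(abs(pooled(config, params, mirrored) - base))
      if (frames_on) {
        for (i in seq_len(n_motions)) {
          mo <- random_rigid_motion(seed + 100L + i)
          res$rigid_dev <- max(res$rigid_dev, max(abs(
            pooled(config, params,
                   transform_graph_state(state, mo$Q, mo$g)) - base)))
        }
        res$mirror_diff_frames <- max(res$mirror_diff_frames, mdiff)
      } else {
        res$mirror_diff_noframes <- max(res$mirror_diff_noframes, mdiff)
      }
    }
  }
  res
}

#' Frame completeness audit
#'
#' Samples generic Gaussian clouds, builds k-NN edges and frames, and
#' measures orthonormality, right-handedness and the degeneracy rate.
#'
#' @param seed Integer seed.
#' @param n_edges Minimum number of edges audited.
#' @return List with `max_unit_dev` (axis norms vs 1), `max_ortho_dev`
#'   (pairwise dot products), `max_det_dev` (determinant vs +1) and
#'   `degeneracy_rate`.
#' @export
audit_frames <- function(seed = 0L, n_edges = 1000L) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  unit_dev <- 0; ortho_dev <- 0; det_dev <- 0
  n_deg <- 0L; n_tot <- 0L
  while (n_tot < n_edges) {
    n <- 25L
    X <- matrix(stats::rnorm(3L * n), n, 3L)
    Xc <- centralize(X)$Xc
    edges <- knn_graph(Xc, 5L)
    fr <- localize(Xc, edges)
    keep <- !fr$degenerate
    n_deg <- n_deg + sum(fr$degenerate)
    n_tot <- n_tot + nrow(edges)
    a <- fr$a[keep, , drop = FALSE]
    b <- fr$b[keep, , drop = FALSE]
    cc <- fr$c[keep, , drop = FALSE]
    unit_dev <- max(unit_dev, max(abs(sqrt(rowSums(a^2)) - 1)),
                    max(abs(sqrt(rowSums(b^2)) - 1)),
                    max(abs(sqrt(rowSums(cc^2)) - 1)))
    ortho_dev <- max(ortho_dev, max(abs(rowSums(a * b))),
                     max(abs(rowSums(a * cc))), max(abs(rowSums(b * cc))))
    dets <- rowSums(a * row_cross(b, cc))
    det_dev <- max(det_dev, max(abs(dets - 1)))
  }
  list(max_unit_dev = unit_dev, max_ortho_dev = ortho_dev,
       max_det_dev = det_dev, degeneracy_rate = n_deg / n_tot,
       n_edges = n_tot)
}
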