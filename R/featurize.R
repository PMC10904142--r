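# Turning raw point clouds into graph states with invariant scalar and
# equivariant vector feature families:
#   node scalars: one-hot type (+ speed when velocities are present)
#   node vectors: unit displacements to the previous/next node of the
#                 sequence order (+ the velocity vector when present)
#   edge scalars: Gaussian RBF expansion of the edge length (+ a one-hot
#                 of the ordered type pair when requested)
#   edge vectors: unit displacement x_i - x_j
# Scalars are E(3)-invariant; vectors are O(3)-equivariant and
# translation-invariant (displacements and velocities, never absolute
# positions).

#' Gaussian radial basis expansion of a distance
#'
#' Evaluates `exp(-(d - mu_k)^2 / (2 sigma^2))` at `n_basis` centers
#' evenly spaced on `[0, d_max]`, with `sigma` equal to the center
#' spacing. Values lie in (0, 1] and each basis function peaks at its own
#' center.
#'
#' @param d Numeric vector of nonnegative distances.
#' @param n_basis Number of basis functions (>= 2).
#' @param d_max Upper end of the center grid (> 0).
#' @return `length(d)` x `n_basis` matrix.
#' @export
rbf_expand <- function(d, n_basis = 16L, d_max = 10) {
  if (d_max <= 0) stop("rbf_expand(): d_max must be positive")
  n_basis <- as.integer(n_basis)
  if (n_basis < 2L) stop("rbf_expand(): need at least 2 basis functions")
  mu <- seq(0, d_max, length.out = n_basis)
  sigma <- mu[2L] - mu[1L]
  outer(as.numeric(d), mu, function(x, m) exp(-(x - m)^2 / (2 * sigma^2)))
}

#' Construct a raw point cloud
#'
#' @param positions N x 3 coordinate matrix.
#' @param types Character vector of node type labels.
#' @param velocities Optional N x 3 velocity matrix.
#' @param node_order Optional integer permutation defining the sequence
#'   used for orientation vectors (molecular chains); `NULL` for unordered
#'   particle sets.
#' @param type_vocab Declared type vocabulary (defaults to the sorted
#'   unique types).
#' @return A list of class `point_cloud`.
#' @export
point_cloud <- function(positions, types, velocities = NULL,
                        node_order = NULL, type_vocab = NULL) {
  positions <- as_coord_matrix(positions)
  types <- as.character(types)
  stopifnot(length(types) == nrow(positions))
  if (is.null(type_vocab)) type_vocab <- sort(unique(types))
  if (!all(types %in% type_vocab)) {
    stop("point_cloud(): unknown type label(s) ",
         paste(setdiff(types, type_vocab), collapse = ", "),
         "; vocabulary is ", paste(type_vocab, collapse = ", "))
  }
  if (!is.null(velocities)) {
    velocities <- as_coord_matrix(velocities)
    stopifnot(nrow(velocities) == nrow(positions), all(is.finite(velocities)))
  }
  structure(list(positions = positions, types = types,
                 velocities = velocities, node_order = node_order,
                 type_vocab = type_vocab),
            class = "point_cloud")
}

one_hot <- function(labels, vocab) {
  m <- matrix(0, length(labels), length(vocab))
  m[cbind(seq_along(labels), match(labels, vocab))] <- 1
  m
}

#' Featurization settings
#'
#' @param n_rbf Number of Gaussian radial basis functions for edge
#'   lengths.
#' @param d_max Largest RBF center, in the coordinate units of the data.
#' @param edge_type_pairs Append a one-hot of the ordered (type_i, type_j)
#'   pair to the edge scalars (used for typed particle systems).
#' @param eps Norm guard for unit displacement vectors.
#' @return List of class `featurize_config`.
#' @export
featurize_config <- function(n_rbf = 16L, d_max = 10, edge_type_pairs = FALSE,
                             eps = 1e-8) {
  structure(list(n_rbf = as.integer(n_rbf), d_max = d_max,
                 edge_type_pairs = isTRUE(edge_type_pairs), eps = eps),
            class = "featurize_config")
}

#' Featurize a point cloud into a graph state
#'
#' Builds the k-NN topology with [knn_graph()] and assembles the scalar /
#' vector node and edge feature families described above. Coordinates are
#' kept raw: centering happens inside [gcpnet_forward()].
#'
#' @param raw A [point_cloud()].
#' @param k Neighbors per node.
#' @param config A [featurize_config()].
#' @return A `graph_state` list: `node` and `edge`
#'   ([scalar_vector()] tuples), `X`, `edges`, `batch`, `n_graphs`.
#' @export
featurize_cloud <- function(raw, k, config = featurize_config()) {
  stopifnot(inherits(raw, "point_cloud"))
  n <- nrow(raw$positions)
  if (n < 2L) stop("featurize_cloud(): need at least 2 nodes")
  edges <- knn_graph(raw$positions, k)
  node_s <- one_hot(raw$types, raw$type_vocab)
  node_V_parts <- list()
  if (!is.null(raw$node_order)) {
    ord <- raw$node_order
    pos_in_seq <- order(ord)  # node ids in sequence order
    fwd <- matrix(0, n, 3L)
    bwd <- matrix(0, n, 3L)
    for (t in seq_len(n)) {
      i <- pos_in_seq[t]
      if (t < n) {
        d <- raw$positions[pos_in_seq[t + 1L], ] - raw$positions[i, ]
        fwd[i, ] <- d / sqrt(sum(d^2) + config$eps^2)
      }
      if (t > 1L) {
        d <- raw$positions[pos_in_seq[t - 1L], ] - raw$positions[i, ]
        bwd[i, ] <- d / sqrt(sum(d^2) + config$eps^2)
      }
    }
    node_V_parts$fwd <- array(fwd, dim = c(n, 1L, 3L))
    node_V_parts$bwd <- array(bwd, dim = c(n, 1L, 3L))
  }
  if (!is.null(raw$velocities)) {
    node_s <- cbind(node_s, sqrt(rowSums(raw$velocities^2)))
    node_V_parts$vel <- array(raw$velocities, dim = c(n, 1L, 3L))
  }
  node_V <- if (length(node_V_parts) > 0L) {
    do.call(vchan_cat, unname(node_V_parts))
  } else NULL
  disp <- raw$positions[edges[, 1L], , drop = FALSE] -
    raw$positions[edges[, 2L], , drop = FALSE]
  d_len <- sqrt(rowSums(disp^2))
  edge_s <- rbf_expand(d_len, config$n_rbf, config$d_max)
  if (config$edge_type_pairs) {
    pair_vocab <- as.vector(outer(raw$type_vocab, raw$type_vocab, paste,
                                  sep = "|"))
    pair_lab <- paste(raw$types[edges[, 1L]], raw$types[edges[, 2L]],
                      sep = "|")
    edge_s <- cbind(edge_s, one_hot(pair_lab, pair_vocab))
  }
  unit_disp <- disp / sqrt(d_len^2 + config$eps^2)
  edge_V <- array(unit_disp, dim = c(nrow(edges), 1L, 3L))
  structure(list(node = scalar_vector(node_s, node_V),
                 edge = scalar_vector(edge_s, edge_V),
                 X = raw$positions, edges = edges,
                 batch = rep.int(1L, n), n_graphs = 1L),
            class = "graph_state")
}

#' Concatenate graph states into one batched state
#'
#' Standard block-diagonal batching: node rows are stacked, edge indices
#' offset, and the `batch` vector records each node's graph of origin so
#' that centering and pooling remain per-graph operations.
#'
#' @param states List of `graph_state` objects with identical feature
#'   widths.
#' @return One batched `graph_state`.
#' @export
batch_graphs <- function(states) {
  if (length(states) == 1L) return(states[[1L]])
  offs <- 0L
  goff <- 0L
  node_s <- list(); node_V <- list(); edge_s <- list(); edge_V <- list()
  Xs <- list(); edges <- list(); batch <- list()
  for (st in states) {
    n <- nrow(st$X)
    node_s[[length(node_s) + 1L]] <- st$node$s
    node_V[[length(node_V) + 1L]] <- st$node$V
    edge_s[[length(edge_s) + 1L]] <- st$edge$s
    edge_V[[length(edge_V) + 1L]] <- st$edge$V
    Xs[[length(Xs) + 1L]] <- st$X
    edges[[length(edges) + 1L]] <- st$edges + offs
    batch[[length(batch) + 1L]] <- st$batch + goff
    offs <- offs + n
    goff <- goff + st$n_graphs
  }
  cat_V <- function(parts) {
    if (is.null(parts[[1L]])) return(NULL)
    r <- dim(parts[[1L]])[2L]
    rows <- sum(vapply(parts, function(p) dim(p)[1L], integer(1L)))
    out <- array(0, dim = c(rows, r, 3L))
    at <- 0L
    for (p in parts) {
      np <- dim(p)[1L]
      out[at + seq_len(np), , ] <- p
      at <- at + np
    }
    out
  }
  structure(list(node = scalar_vector(do.call(rbind, node_s), cat_V(node_V)),
                 edge = scalar_vector(do.call(rbind, edge_s), cat_V(edge_V)),
                 X = do.call(rbind, Xs), edges = do.call(rbind, edges),
                 batch = unlist(batch), n_graphs = goff),
            class = "graph_state")
}

#' Feature widths of a graph state
#'
#' @param state A `graph_state`.
#' @return List with integer pairs `node` and `edge` of (scalar, vector)
#'   channel widths.
#' @export
state_widths <- function(state) {
  list(node = c(sv_swidth(state$node), sv_vwidth(state$node)),
       edge = c(sv_swidth(state$edge), sv_vwidth(state$edge)))
}
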