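# Geometry-complete graph convolution and the full network forward pass:
#   centralize -> localize -> embed (GCPe) -> L x GCPConv
#   -> (optional) re-localize + decentralize -> final projection (GCPp).
#
# Scalar outputs are SE(3)-invariant; vector outputs and updated positions
# are SE(3)-equivariant. All of it runs on batched graphs (block-diagonal
# concatenation with a `batch` index, centering done per graph).

#' Network architecture configuration
#'
#' @param hidden_node,hidden_edge Integer pairs `c(t, r)`: hidden scalar /
#'   vector channel widths for node and edge states.
#' @param out_node Integer pair `c(t, r)`: widths of the final node
#'   projection (e.g. `c(2, 0)` for two-class logits).
#' @param n_layers Number of graph-convolution layers L (>= 1).
#' @param k Neighbors per node for graph construction (used by
#'   featurization helpers).
#' @param update_positions Enable the equivariant position-update path.
#' @param gcp A [gcp_config()] with the GCP-level hyperparameters and
#'   ablation switches.
#' @return A list of class `gcpnet_config`.
#' @export
gcpnet_config <- function(hidden_node = c(100L, 16L), hidden_edge = c(32L, 4L),
                          out_node = c(1L, 0L), n_layers = 4L, k = 16L,
                          update_positions = FALSE, gcp = gcp_config()) {
  if (n_layers < 1L) stop("gcpnet_config(): need at least one layer")
  if (update_positions && !gcp$use_vectors) {
    stop("gcpnet_config(): position updates require vector channels")
  }
  structure(list(hidden_node = as.integer(hidden_node),
                 hidden_edge = as.integer(hidden_edge),
                 out_node = as.integer(out_node),
                 n_layers = as.integer(n_layers), k = as.integer(k),
                 update_positions = isTRUE(update_positions), gcp = gcp),
            class = "gcpnet_config")
}

#' Initialize all network parameters
#'
#' @param in_node,in_edge Integer pairs `c(t, r)`: widths of the raw
#'   featurized node and edge tuples.
#' @param config A [gcpnet_config()].
#' @return Nested parameter list (draws from the current RNG stream; call
#'   `set.seed()` beforehand for reproducibility).
#' @export
gcpnet_init <- function(in_node, in_edge, config) {
  g <- config$gcp
  tn_in <- if (g$use_scalars) in_node[1L] else 1L
  te_in <- if (g$use_scalars) in_edge[1L] else 1L
  rn_in <- if (g$use_vectors) in_node[2L] else 0L
  re_in <- if (g$use_vectors) in_edge[2L] else 0L
  th <- config$hidden_node[1L]
  rh <- if (g$use_vectors) config$hidden_node[2L] else 0L
  te <- config$hidden_edge[1L]
  re <- if (g$use_vectors) config$hidden_edge[2L] else 0L
  t_out <- config$out_node[1L]
  r_out <- if (g$use_vectors) config$out_node[2L] else 0L
  layers <- vector("list", config$n_layers)
  for (l in seq_len(config$n_layers)) {
    layers[[l]] <- list(
      msg = gcp_stack_init(2L * th + te, 2L * rh + re, th, rh, g),
      upd = gcp_init(2L * th, 2L * rh, th, rh, g),
      pos = if (config$update_positions) gcp_init(th, rh, 1L, 1L, g) else NULL
    )
  }
  list(embed_node = gcp_init(tn_in, rn_in, th, rh, g),
       embed_edge = gcp_init(te_in, re_in, te, re, g),
       layers = layers,
       proj_node = gcp_init(th, rh, t_out, r_out, g),
       proj_edge = gcp_init(te, re, te, re, g),
       widths = list(in_node = c(tn_in, rn_in), in_edge = c(te_in, re_in)))
}

# Ablation-aware input preparation: scalar-free models see a constant
# 1-wide scalar channel; vector-free models see no vector channels.
prepare_inputs <- function(sv, g) {
  s <- if (g$use_scalars) sv$s else matrix(1, nrow(sv$s), 1L)
  V <- if (g$use_vectors) sv$V else NULL
  scalar_vector(s, V)
}

# Per-graph centering of batched coordinates.
centralize_batch <- function(X, batch, n_graphs) {
  counts <- tabulate(batch, nbins = n_graphs)
  centers <- rowsum(X, group = batch, reorder = TRUE) / counts
  dimnames(centers) <- NULL
  list(Xc = X - centers[batch, , drop = FALSE], centers = centers)
}

#' Full network forward pass
#'
#' Runs the complete pipeline on a (possibly batched) graph state:
#' per-graph centering, frame construction, feature embedding, `n_layers`
#' rounds of geometry-complete convolution (each round computes per-edge
#' messages with an omega-deep residual GCP stack on the concatenated
#' source-node, destination-node and edge tuples, mean-aggregates them per
#' receiving node, and residually updates the node state), optional
#' equivariant position updates, and final projections. When
#' `config$update_positions` is `FALSE` the returned coordinates are the
#' input object itself, bitwise unchanged.
#'
#' @param state A graph state from [featurize_cloud()] /
#'   [batch_graphs()].
#' @param params From [gcpnet_init()].
#' @param config A [gcpnet_config()].
#' @param keep_cache Keep every intermediate for [gcpnet_backward()].
#' @return List with `node` and `edge` (output `scalar_vector` tuples),
#'   `X` (output coordinates) and optionally `cache`.
#' @export
gcpnet_forward <- function(state, params, config, keep_cache = FALSE) {
  g <- config$gcp
  edges <- state$edges
  src <- edges[, 1L]
  batch <- state$batch
  n <- nrow(state$X)
  cb <- centralize_batch(state$X, batch, state$n_graphs)
  Xc <- cb$Xc
  frames0 <- localize(Xc, edges, g$eps)
  node_in <- prepare_inputs(state$node, g)
  edge_in <- prepare_inputs(state$edge, g)
  em_n <- gcp_forward(node_in, frames0, edges, "node", params$embed_node, g,
                      keep_cache)
  em_e <- gcp_forward(edge_in, frames0, edges, "edge", params$embed_edge, g,
                      keep_cache)
  node <- em_n$out
  edge0 <- em_e$out
  deg <- tabulate(src, nbins = n)
  layer_caches <- vector("list", config$n_layers)
  for (l in seq_len(config$n_layers)) {
    lp <- params$layers[[l]]
    msg_in <- sv_concat(sv_index(node, src), sv_index(node, edges[, 2L]),
                        edge0)
    ms <- gcp_stack_forward(msg_in, frames0, edges, "edge", lp$msg, g,
                            keep_cache)
    agg_s <- matrix(0, n, ncol(ms$out$s))
    rs <- rowsum(ms$out$s, group = src, reorder = FALSE)
    idx <- as.integer(rownames(rs))
    agg_s[idx, ] <- rs / deg[idx]
    agg_V <- NULL
    if (!is.null(ms$out$V)) {
      agg_V <- vchan_rowsum(ms$out$V, src, n)
      for (k in 1:3) agg_V[, , k] <- agg_V[, , k] / pmax(deg, 1L)
    }
    agg <- scalar_vector(agg_s, agg_V)
    upd_in <- sv_concat(node, agg)
    up <- gcp_forward(upd_in, frames0, edges, "node", lp$upd, g, keep_cache)
    node_new <- sv_add(node, up$out)
    pos_cache <- NULL
    if (config$update_positions) {
      ps <- gcp_forward(node_new, frames0, edges, "node", lp$pos, g,
                        keep_cache)
      chi <- matrix(ps$out$V[, 1L, ], nrow = n, ncol = 3L)
      Xc <- Xc + chi
      pos_cache <- ps$cache
    }
    layer_caches[[l]] <- list(msg = ms$caches, upd = up$cache,
                              pos = pos_cache)
    node <- node_new
  }
  if (config$update_positions) {
    frames_final <- localize(Xc, edges, g$eps)
    X_out <- Xc + cb$centers[batch, , drop = FALSE]
  } else {
    frames_final <- frames0
    X_out <- state$X
  }
  pr_n <- gcp_forward(node, frames_final, edges, "node", params$proj_node, g,
                      keep_cache)
  pr_e <- gcp_forward(edge0, frames_final, edges, "edge", params$proj_edge, g,
                      keep_cache)
  cache <- if (keep_cache) {
    list(embed_node = em_n$cache, embed_edge = em_e$cache,
         layers = layer_caches, proj_node = pr_n$cache,
         proj_edge = pr_e$cache, src = src, dst = edges[, 2L], deg = deg,
         n = n, widths = list(th = sv_swidth(node), rh = sv_vwidth(node),
                              te = sv_swidth(edge0), re = sv_vwidth(edge0)))
  } else NULL
  list(node = pr_n$out, edge = pr_e$out, X = X_out, cache = cache)
}

sv_index <- function(sv, idx) {
  scalar_vector(sv$s[idx, , drop = FALSE],
                if (is.null(sv$V)) NULL else sv$V[idx, , , drop = FALSE])
}

# Zero-filled gradient structure matching one gcp_params bundle.
zero_grads_like <- function(p) {
  g <- list(w_s = matrix(0, nrow(p$w_s), ncol(p$w_s)),
            b_s = numeric(length(p$b_s)))
  if (!is.null(p$w_dz)) {
    g$w_dz <- matrix(0, nrow(p$w_dz), ncol(p$w_dz))
    g$w_ds <- matrix(0, nrow(p$w_ds), ncol(p$w_ds))
  }
  if (!is.null(p$w_uz)) {
    g$w_uz <- matrix(0, nrow(p$w_uz), ncol(p$w_uz))
    g$w_g <- matrix(0, nrow(p$w_g), ncol(p$w_g))
    g$b_g <- numeric(length(p$b_g))
  }
  g
}

#' Reverse-mode gradients of the full network
#'
#' Backpropagates through every layer of a cached [gcpnet_forward()] call.
#' Geometry (frames, centers) is treated as constant: position gradients
#' flow through the additive position-update path only, which is exact for
#' losses on the output positions because frames are computed from input
#' coordinates and only refreshed after the last layer.
#'
#' @param g_node_s Gradient w.r.t. output node scalars (N x t_out) or
#'   `NULL`.
#' @param g_X Gradient w.r.t. output coordinates (N x 3) or `NULL`.
#' @param cache From `gcpnet_forward(..., keep_cache = TRUE)`.
#' @param params,config As in [gcpnet_forward()].
#' @return Nested gradient list mirroring `params`.
#' @export
gcpnet_backward <- function(g_node_s, g_X, cache, params, config) {
  g <- config$gcp
  n <- cache$n
  src <- cache$src
  dst <- cache$dst
  deg <- cache$deg
  th <- cache$widths$th
  rh <- cache$widths$rh
  pn <- gcp_backward(g_node_s, NULL, cache$proj_node, params$proj_node, g)
  g_node_s_acc <- pn$g_s
  g_node_V_acc <- pn$g_V
  if (is.null(g_node_V_acc) && rh > 0L) g_node_V_acc <- vchan_zeros(n, rh)
  g_Xc <- g_X  # output positions = final centered coords + constant centers
  grads_layers <- vector("list", config$n_layers)
  for (l in rev(seq_len(config$n_layers))) {
    lp <- params$layers[[l]]
    lc <- cache$layers[[l]]
    grads_l <- list()
    if (config$update_positions) {
      g_chi <- if (is.null(g_Xc)) vchan_zeros(n, 1L) else
        array(g_Xc, dim = c(n, 1L, 3L))
      pb <- gcp_backward(NULL, g_chi, lc$pos, lp$pos, g)
      grads_l$pos <- pb$grads
      g_node_s_acc <- g_node_s_acc + pb$g_s
      if (!is.null(pb$g_V)) g_node_V_acc <- g_node_V_acc + pb$g_V
    }
    # node_new = node + upd(node || agg); residual passthrough plus branch
    ub <- gcp_backward(g_node_s_acc, g_node_V_acc, lc$upd, lp$upd, g)
    grads_l$upd <- ub$grads
    g_node_s_prev <- g_node_s_acc + ub$g_s[, seq_len(th), drop = FALSE]
    g_agg_s <- ub$g_s[, th + seq_len(th), drop = FALSE]
    g_node_V_prev <- g_node_V_acc
    g_agg_V <- NULL
    if (rh > 0L && !is.null(ub$g_V)) {
      g_node_V_prev <- g_node_V_prev + ub$g_V[, seq_len(rh), , drop = FALSE]
      g_agg_V <- ub$g_V[, rh + seq_len(rh), , drop = FALSE]
    }
    # mean aggregation: distribute per receiving node, divided by degree
    g_msg_s <- g_agg_s[src, , drop = FALSE] / deg[src]
    g_msg_V <- if (!is.null(g_agg_V)) {
      out <- g_agg_V[src, , , drop = FALSE]
      for (k in 1:3) out[, , k] <- vchan_slice(out, k) / deg[src]
      out
    } else NULL
    mb <- gcp_stack_backward(g_msg_s, g_msg_V, lc$msg, lp$msg, g)
    grads_l$msg <- mb$grads
    # split message-input gradients back to (src node, dst node, edge)
    te <- cache$widths$te
    re <- cache$widths$re
    gm_s <- mb$g_s
    g_node_s_prev <- g_node_s_prev +
      scatter_add_s(gm_s[, seq_len(th), drop = FALSE], src, n) +
      scatter_add_s(gm_s[, th + seq_len(th), drop = FALSE], dst, n)
    g_edge0_l <- gm_s[, 2L * th + seq_len(te), drop = FALSE]
    g_edge0_V_l <- NULL
    if (rh > 0L && !is.null(mb$g_V)) {
      g_node_V_prev <- g_node_V_prev +
        vchan_rowsum(mb$g_V[, seq_len(rh), , drop = FALSE], src, n) +
        vchan_rowsum(mb$g_V[, rh + seq_len(rh), , drop = FALSE], dst, n)
      if (re > 0L) {
        g_edge0_V_l <- mb$g_V[, 2L * rh + seq_len(re), , drop = FALSE]
      }
    }
    if (l == config$n_layers) {
      g_edge0_s <- g_edge0_l
      g_edge0_V <- g_edge0_V_l
    } else {
      g_edge0_s <- g_edge0_s + g_edge0_l
      if (!is.null(g_edge0_V_l)) g_edge0_V <- g_edge0_V + g_edge0_V_l
    }
    grads_layers[[l]] <- grads_l
    g_node_s_acc <- g_node_s_prev
    g_node_V_acc <- g_node_V_prev
  }
  en <- gcp_backward(g_node_s_acc, g_node_V_acc, cache$embed_node,
                     params$embed_node, g)
  ee <- gcp_backward(g_edge0_s, g_edge0_V, cache$embed_edge,
                     params$embed_edge, g)
  list(embed_node = en$grads, embed_edge = ee$grads, layers = grads_layers,
       proj_node = pn$grads, proj_edge = zero_grads_like(params$proj_edge))
}

scatter_add_s <- function(vals, idx, n) {
  out <- matrix(0, n, ncol(vals))
  rs <- rowsum(vals, group = idx, reorder = FALSE)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

#' Equivariant node-position update
#'
#' Residually adds a learned single-channel vector feature to the previous
#' positions; SO(3)-equivariant whenever `chi_v` came from an equivariant
#' path.
#'
#' @param x_prev N x 3 positions.
#' @param chi_v N x 1 x 3 vector channel (or N x 3 matrix).
#' @return N x 3 updated positions.
#' @export
update_positions <- function(x_prev, chi_v) {
  if (length(dim(chi_v)) == 3L) {
    chi_v <- matrix(chi_v[, 1L, ], nrow = dim(chi_v)[1L], ncol = 3L)
  }
  x_prev + chi_v
}

#' Pool node scalars to one graph-level row
#'
#' @param node_s N x t matrix of node scalar features.
#' @param mode `"mean"` or `"sum"`.
#' @param batch Optional integer graph index per node (defaults to a
#'   single graph).
#' @return n_graphs x t matrix; permutation-invariant.
#' @export
pool_graph <- function(node_s, mode = c("mean", "sum"), batch = NULL) {
  mode <- match.arg(mode)
  node_s <- as.matrix(node_s)
  if (nrow(node_s) == 0L) stop("pool_graph(): empty graph")
  if (is.null(batch)) batch <- rep.int(1L, nrow(node_s))
  out <- rowsum(node_s, group = batch, reorder = TRUE)
  if (mode == "mean") {
    out <- out / tabulate(batch, nbins = nrow(out))
  }
  out
}
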