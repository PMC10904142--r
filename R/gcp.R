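# The geometry-complete perceptron (GCP): a learnable map on (s, V)
# feature tuples conditioned on per-edge frames.
#
# Forward pipeline for one GCP with input widths (t, r) and output widths
# (t', r'):
#   z   = V w_dz                 channel downscale, rz = max(1, ceil(r/lambda))
#   Vs  = V w_ds                 three vector channels for scalarization
#   q   = <Vs, (a, b, c)>        9 frame inner products; node rows average
#                                over their outgoing edges
#   sv  = [s | q | ||z||] w_s + b_s
#   s'  = silu(sv)
#   Vu  = z w_uz
#   V'  = Vu * sigmoid(silu(sv) w_g + b_g)   (one gate scalar per channel)
# Every map touches the channel dimension only, so rotating the geometry
# rotates V' and leaves s' unchanged; the frame parity (-, +, -) under
# point inversion is what makes s' chirality-sensitive.
#
# Each forward returns a cache from which gcp_backward() reproduces exact
# reverse-mode gradients — the package trains without an autodiff
# framework.

#' GCP hyperparameter bundle
#'
#' @param lambda Positive integer channel downscaling factor; the hidden
#'   vector width inside a GCP is `max(1, ceiling(r / lambda))`.
#' @param omega Number of stacked GCP applications inside each message
#'   function.
#' @param use_frames If `FALSE`, the 9 frame inner products are replaced by
#'   a zero block, which makes every scalar output reflection-invariant
#'   (the E(3) ablation).
#' @param use_scalars,use_vectors Ablation switches for the two feature
#'   tracks (widths are set to zero upstream when disabled).
#' @param use_residual If `FALSE`, residual wrappers become plain GCPs.
#' @param eps Norm guard used in all divisions.
#' @return A list of class `gcp_config`.
#' @export
gcp_config <- function(lambda = 3L, omega = 3L, use_frames = TRUE,
                       use_scalars = TRUE, use_vectors = TRUE,
                       use_residual = TRUE, eps = 1e-8) {
  structure(list(lambda = as.integer(lambda), omega = as.integer(omega),
                 use_frames = isTRUE(use_frames),
                 use_scalars = isTRUE(use_scalars),
                 use_vectors = isTRUE(use_vectors),
                 use_residual = isTRUE(use_residual),
                 eps = eps),
            class = "gcp_config")
}

silu <- function(x) x * stats::plogis(x)
silu_grad <- function(x) {
  s <- stats::plogis(x)
  s * (1 + x * (1 - s))
}

# Fan-in uniform initialization; draws from the current RNG stream.
init_mat <- function(nin, nout) {
  if (nout == 0L || nin == 0L) return(matrix(0, nin, nout))
  matrix(stats::runif(nin * nout, -1, 1) / sqrt(nin), nin, nout)
}

#' Initialize the learnable maps of one GCP
#'
#' @param t_in,r_in Input scalar/vector channel widths.
#' @param t_out,r_out Output scalar/vector channel widths (`r_out > 0`
#'   requires `r_in > 0`).
#' @param config A [gcp_config()].
#' @return A `gcp_params` list of weight matrices and offsets.
#' @export
gcp_init <- function(t_in, r_in, t_out, r_out, config = gcp_config()) {
  t_in <- as.integer(t_in); r_in <- as.integer(r_in)
  t_out <- as.integer(t_out); r_out <- as.integer(r_out)
  if (t_in + r_in == 0L || t_out + r_out == 0L) {
    stop("gcp_init(): all-zero-width configuration")
  }
  if (r_out > 0L && r_in == 0L) {
    stop("gcp_init(): cannot emit vector channels without vector inputs")
  }
  rz <- if (r_in > 0L) max(1L, as.integer(ceiling(r_in / config$lambda))) else 0L
  s_in_width <- t_in + if (r_in > 0L) 9L + rz else 0L
  p <- list(
    t_in = t_in, r_in = r_in, t_out = t_out, r_out = r_out, rz = rz,
    w_dz = if (r_in > 0L) init_mat(r_in, rz) else NULL,
    w_ds = if (r_in > 0L) init_mat(r_in, 3L) else NULL,
    w_s = init_mat(s_in_width, t_out),
    b_s = numeric(t_out),
    w_uz = if (r_out > 0L) init_mat(rz, r_out) else NULL,
    w_g = if (r_out > 0L) init_mat(t_out, r_out) else NULL,
    b_g = if (r_out > 0L) numeric(r_out) else NULL
  )
  structure(p, class = "gcp_params")
}

# rows x 3 slice of vector channel `ch` of a rows x r x 3 stack.
vs_channel <- function(Vs, ch) {
  d <- dim(Vs)
  matrix(Vs[, ch, ], nrow = d[1L], ncol = 3L)
}

#' Project vector channels onto local frames (scalarization)
#'
#' Computes the nine inner products between the three vector channels of
#' `Vs` and the three frame axes (a, b, c), flattened channel-major with
#' axis order (a, b, c): columns are (ch1.a, ch1.b, ch1.c, ch2.a, ...).
#' For `entity_kind = "edge"` the rows of `Vs` align with edges and the
#' projection is direct; for `entity_kind = "node"` the rows align with
#' nodes, each node's projections are computed against the frames of its
#' outgoing edges and averaged over that neighborhood (nodes with no
#' outgoing edge get zeros).
#'
#' The result is invariant under a simultaneous rotation of `Vs` and the
#' coordinates that produced the frames, but *not* under reflection:
#' under point inversion the a and c axes flip sign while b is preserved,
#' so the corresponding six columns change sign — the mechanism behind
#' chirality sensitivity.
#'
#' @param Vs rows x 3 x 3 array of vector channels.
#' @param frames [localize()] output aligned with `edges`.
#' @param edges E x 2 integer edge matrix.
#' @param entity_kind `"node"` or `"edge"`.
#' @return rows x 9 matrix of frame inner products.
#' @export
scalarize <- function(Vs, frames, edges, entity_kind = c("edge", "node")) {
  entity_kind <- match.arg(entity_kind)
  scalarize_forward(Vs, frames, edges, entity_kind)$q
}

scalarize_forward <- function(Vs, frames, edges, entity_kind) {
  axes <- list(frames$a, frames$b, frames$c)
  n_rows <- dim(Vs)[1L]
  if (entity_kind == "edge") {
    Vs_e <- Vs
    src <- NULL
    deg <- NULL
  } else {
    src <- edges[, 1L]
    deg <- tabulate(src, nbins = n_rows)
    Vs_e <- Vs[src, , , drop = FALSE]
  }
  n_e <- dim(Vs_e)[1L]
  q_e <- matrix(0, n_e, 9L)
  for (ch in 1:3) {
    vch <- vs_channel(Vs_e, ch)
    for (ax in 1:3) {
      q_e[, 3L * (ch - 1L) + ax] <- rowSums(vch * axes[[ax]])
    }
  }
  if (entity_kind == "edge") {
    q <- q_e
  } else {
    q <- matrix(0, n_rows, 9L)
    rs <- rowsum(q_e, group = src, reorder = FALSE)
    idx <- as.integer(rownames(rs))
    q[idx, ] <- rs / deg[idx]
  }
  list(q = q,
       cache = list(entity_kind = entity_kind, axes = axes, src = src,
                    deg = deg, n_rows = n_rows))
}

scalarize_backward <- function(g_q, cache) {
  axes <- cache$axes
  if (cache$entity_kind == "edge") {
    g_qe <- g_q
  } else {
    src <- cache$src
    g_qe <- g_q[src, , drop = FALSE] / cache$deg[src]
  }
  n_e <- nrow(g_qe)
  g_Vs_e <- array(0, dim = c(n_e, 3L, 3L))
  for (ch in 1:3) {
    acc <- matrix(0, n_e, 3L)
    for (ax in 1:3) {
      acc <- acc + g_qe[, 3L * (ch - 1L) + ax] * axes[[ax]]
    }
    g_Vs_e[, ch, ] <- acc
  }
  if (cache$entity_kind == "edge") {
    g_Vs_e
  } else {
    vchan_rowsum(g_Vs_e, cache$src, cache$n_rows)
  }
}

#' One GCP forward pass
#'
#' @param sv_in A [scalar_vector()] tuple (rows = nodes or edges).
#' @param frames [localize()] output for the graph's edges.
#' @param edges E x 2 integer edge matrix.
#' @param entity_kind `"node"` or `"edge"` — controls how scalarization
#'   aligns rows with frames.
#' @param params A [gcp_init()] parameter bundle.
#' @param config A [gcp_config()].
#' @param keep_cache Keep intermediate values for [gcp_backward()].
#' @return List with `out` (a `scalar_vector`) and, when requested,
#'   `cache`.
#' @export
gcp_forward <- function(sv_in, frames, edges, entity_kind, params,
                        config = gcp_config(), keep_cache = FALSE) {
  s <- sv_in$s
  V <- sv_in$V
  rows <- nrow(s)
  eps <- config$eps
  if (params$r_in > 0L) {
    z <- vchan_map(V, params$w_dz)
    Vs <- vchan_map(V, params$w_ds)
    if (config$use_frames) {
      sf <- scalarize_forward(Vs, frames, edges, entity_kind)
      q <- sf$q
    } else {
      sf <- NULL
      q <- matrix(0, rows, 9L)
    }
    znorm <- vchan_norm(z, eps)
    s_cat <- cbind(s, q, znorm)
  } else {
    z <- NULL; Vs <- NULL; sf <- NULL; znorm <- NULL
    s_cat <- s
  }
  if (!all(is.finite(s_cat))) {
    stop("gcp_forward(): non-finite values in scalar pathway")
  }
  sv <- s_cat %*% params$w_s
  sv <- sweep(sv, 2L, params$b_s, "+")
  s_out <- silu(sv)
  if (params$r_out > 0L) {
    Vu <- vchan_map(z, params$w_uz)
    u <- s_out  # sigma_plus = sigma_s = SiLU, both applied to sv
    gate_pre <- sweep(u %*% params$w_g, 2L, params$b_g, "+")
    gate <- stats::plogis(gate_pre)
    V_out <- array(0, dim = c(rows, params$r_out, 3L))
    for (k in 1:3) {
      V_out[, , k] <- vchan_slice(Vu, k) * gate
    }
  } else {
    Vu <- NULL; gate <- NULL
    V_out <- NULL
  }
  out <- scalar_vector(s_out, V_out)
  cache <- if (keep_cache) {
    list(V = V, z = z, Vs = Vs, scal = sf, znorm = znorm, s_cat = s_cat,
         sv = sv, Vu = Vu, gate = gate, rows = rows)
  } else NULL
  list(out = out, cache = cache)
}

#' Reverse-mode gradients of one GCP
#'
#' Consumes the cache of a [gcp_forward()] call (with `keep_cache = TRUE`)
#' and the gradients of some loss with respect to the GCP's outputs, and
#' returns gradients with respect to its inputs and parameters. Frames are
#' treated as constants of the geometry: gradients never flow into the
#' frame axes.
#'
#' @param g_s Gradient w.r.t. the scalar output (rows x t'), or `NULL`.
#' @param g_V Gradient w.r.t. the vector output (rows x r' x 3), or
#'   `NULL`.
#' @param cache Cache from [gcp_forward()].
#' @param params,config As in [gcp_forward()].
#' @return List with `g_s` (rows x t), `g_V` (rows x r x 3 or `NULL`) and
#'   `grads` (same shapes as the weight fields of `params`).
#' @export
gcp_backward <- function(g_s, g_V, cache, params, config = gcp_config()) {
  rows <- cache$rows
  grads <- list()
  if (is.null(g_s)) g_s <- matrix(0, rows, params$t_out)
  g_u <- NULL
  g_z <- if (params$r_in > 0L) array(0, dim = dim(cache$z)) else NULL
  if (params$r_out > 0L && !is.null(g_V)) {
    gate <- cache$gate
    Vu <- cache$Vu
    gVu <- array(0, dim = dim(Vu))
    g_gate <- matrix(0, rows, params$r_out)
    for (k in 1:3) {
      gk <- vchan_slice(g_V, k)
      gVu[, , k] <- gk * gate
      g_gate <- g_gate + gk * vchan_slice(Vu, k)
    }
    g_gate_pre <- g_gate * gate * (1 - gate)
    u <- silu(cache$sv)
    grads$w_g <- crossprod(u, g_gate_pre)
    grads$b_g <- colSums(g_gate_pre)
    g_u <- g_gate_pre %*% t(params$w_g)
    grads$w_uz <- matrix(0, params$rz, params$r_out)
    for (k in 1:3) {
      zk <- vchan_slice(cache$z, k)
      gk <- vchan_slice(gVu, k)
      grads$w_uz <- grads$w_uz + crossprod(zk, gk)
      g_z[, , k] <- g_z[, , k] + gk %*% t(params$w_uz)
    }
  } else if (params$r_out > 0L) {
    grads$w_g <- matrix(0, params$t_out, params$r_out)
    grads$b_g <- numeric(params$r_out)
    grads$w_uz <- matrix(0, params$rz, params$r_out)
  }
  g_sv <- g_s * silu_grad(cache$sv)
  if (!is.null(g_u)) g_sv <- g_sv + g_u * silu_grad(cache$sv)
  grads$w_s <- crossprod(cache$s_cat, g_sv)
  grads$b_s <- colSums(g_sv)
  g_s_cat <- g_sv %*% t(params$w_s)
  t_in <- params$t_in
  g_s_in <- g_s_cat[, seq_len(t_in), drop = FALSE]
  g_V_in <- NULL
  if (params$r_in > 0L) {
    g_q <- g_s_cat[, t_in + 1:9, drop = FALSE]
    g_znorm <- g_s_cat[, t_in + 9L + seq_len(params$rz), drop = FALSE]
    for (k in 1:3) {
      g_z[, , k] <- g_z[, , k] + g_znorm * vchan_slice(cache$z, k) / cache$znorm
    }
    if (config$use_frames) {
      g_Vs <- scalarize_backward(g_q, cache$scal$cache)
    } else {
      g_Vs <- array(0, dim = dim(cache$Vs))
    }
    grads$w_dz <- matrix(0, params$r_in, params$rz)
    grads$w_ds <- matrix(0, params$r_in, 3L)
    g_V_in <- array(0, dim = dim(cache$V))
    for (k in 1:3) {
      vk <- vchan_slice(cache$V, k)
      gzk <- vchan_slice(g_z, k)
      gvsk <- vchan_slice(g_Vs, k)
      grads$w_dz <- grads$w_dz + crossprod(vk, gzk)
      grads$w_ds <- grads$w_ds + crossprod(vk, gvsk)
      g_V_in[, , k] <- gzk %*% t(params$w_dz) + gvsk %*% t(params$w_ds)
    }
  }
  list(g_s = g_s_in, g_V = g_V_in, grads = grads)
}

#' Residual GCP forward pass
#'
#' Adds the GCP output elementwise to its input on both channels; input
#' and output widths must match. When `config$use_residual` is `FALSE`
#' this degrades to a plain [gcp_forward()] (the "without ResGCP"
#' ablation).
#'
#' @inheritParams gcp_forward
#' @return As [gcp_forward()].
#' @export
resgcp_forward <- function(sv_in, frames, edges, entity_kind, params,
                           config = gcp_config(), keep_cache = FALSE) {
  if (config$use_residual &&
      (params$t_in != params$t_out || params$r_in != params$r_out)) {
    stop("resgcp_forward(): residual connection requires equal widths")
  }
  fw <- gcp_forward(sv_in, frames, edges, entity_kind, params, config,
                    keep_cache)
  if (config$use_residual) {
    fw$out <- sv_add(fw$out, sv_in)
  }
  fw
}

resgcp_backward <- function(g_s, g_V, cache, params, config = gcp_config()) {
  bw <- gcp_backward(g_s, g_V, cache, params, config)
  if (config$use_residual) {
    if (!is.null(g_s)) bw$g_s <- bw$g_s + g_s
    if (!is.null(g_V) && !is.null(bw$g_V)) bw$g_V <- bw$g_V + g_V
  }
  bw
}

# A stack of omega GCP applications: the first maps the input widths to the
# output widths, the remaining omega - 1 are residual at the output widths.
gcp_stack_init <- function(t_in, r_in, t_out, r_out, config) {
  n <- max(1L, config$omega)
  layers <- vector("list", n)
  layers[[1L]] <- gcp_init(t_in, r_in, t_out, r_out, config)
  if (n > 1L) {
    for (i in 2:n) layers[[i]] <- gcp_init(t_out, r_out, t_out, r_out, config)
  }
  layers
}

gcp_stack_forward <- function(sv_in, frames, edges, entity_kind, layers,
                              config, keep_cache = FALSE) {
  caches <- vector("list", length(layers))
  cur <- sv_in
  for (i in seq_along(layers)) {
    f <- if (i == 1L) gcp_forward else resgcp_forward
    fw <- f(cur, frames, edges, entity_kind, layers[[i]], config, keep_cache)
    caches[[i]] <- fw$cache
    cur <- fw$out
  }
  list(out = cur, caches = caches)
}

gcp_stack_backward <- function(g_s, g_V, caches, layers, config) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    b <- if (i == 1L) gcp_backward else resgcp_backward
    bw <- b(g_s, g_V, caches[[i]], layers[[i]], config)
    grads[[i]] <- bw$grads
    g_s <- bw$g_s
    g_V <- bw$g_V
  }
  list(g_s = g_s, g_V = g_V, grads = grads)
}
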