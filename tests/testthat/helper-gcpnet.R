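# Shared fixtures, all built in code at test time.

# A small generic graph state with every feature family populated.
tiny_state <- function(n_nodes = 10L, seed = 3L, k = 4L) {
  random_graph_state(n_nodes, seed, k)
}

# A small network configuration (kept light so property loops stay fast).
tiny_config <- function(update_positions = FALSE, out_node = c(4L, 0L),
                        gcp = gcp_config(omega = 2L), n_layers = 2L) {
  gcpnet_config(hidden_node = c(8L, 3L), hidden_edge = c(6L, 2L),
                out_node = out_node, n_layers = n_layers, k = 4L,
                update_positions = update_positions, gcp = gcp)
}

init_for <- function(state, config, seed = 11L) {
  set.seed(seed)
  w <- state_widths(state)
  gcpnet_init(w$node, w$edge, config)
}

# Sum of squares over every learnable array in a gradient structure.
grad_sq_norm <- function(g) {
  tot <- 0
  walk <- function(x) {
    if (is.list(x)) {
      lapply(x, walk)
    } else if (is.numeric(x)) {
      tot <<- tot + sum(x^2)
    }
    invisible(NULL)
  }
  walk(g)
  tot
}

# Shift every learnable parameter along a same-shaped direction structure.
perturb_params <- function(params, direction, scale) {
  fields <- c("w_dz", "w_ds", "w_s", "b_s", "w_uz", "w_g", "b_g")
  walk <- function(p, d) {
    if (inherits(p, "gcp_params")) {
      for (nm in fields) {
        if (!is.null(p[[nm]]) && !is.null(d[[nm]])) {
          p[[nm]] <- p[[nm]] + scale * d[[nm]]
        }
      }
      return(p)
    }
    if (is.list(p)) {
      for (i in seq_along(p)) {
        nm <- names(p)[i]
        di <- if (!is.null(nm) && nzchar(nm)) d[[nm]] else d[[i]]
        if (!is.null(di)) p[[i]] <- walk(p[[i]], di)
      }
      return(p)
    }
    p
  }
  walk(params, direction)
}

# Set the named fields of one gcp_params bundle inside `params` to zero.
zero_gcp_fields <- function(p) {
  for (nm in c("w_dz", "w_ds", "w_s", "b_s", "w_uz", "w_g", "b_g")) {
    if (!is.null(p[[nm]])) p[[nm]] <- p[[nm]] * 0
  }
  p
}

# Permute the nodes of a graph state by `perm` (new index = position of
# old index in perm).
permute_state <- function(state, perm) {
  inv <- order(perm)  # inv[old] = new position
  ns <- state$node$s[perm, , drop = FALSE]
  nV <- if (is.null(state$node$V)) NULL else
    state$node$V[perm, , , drop = FALSE]
  edges <- cbind(inv[state$edges[, 1L]], inv[state$edges[, 2L]])
  structure(list(node = scalar_vector(ns, nV), edge = state$edge,
                 X = state$X[perm, , drop = FALSE], edges = edges,
                 batch = state$batch[perm], n_graphs = state$n_graphs),
            class = "graph_state")
}
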