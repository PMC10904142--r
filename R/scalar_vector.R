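# The (s, V) feature tuple: s holds rotation-invariant scalar channels
# (rows x t matrix), V holds rotation-equivariant 3-vector channels
# (rows x r x 3 array, or NULL when the vector track is disabled).
# Channel maps always act on the channel dimension and never mix the three
# Cartesian components — that restriction is what preserves equivariance.

#' Construct a scalar-vector feature tuple
#'
#' @param s rows x t numeric matrix of invariant scalar channels (use a
#'   zero-column matrix for a scalar-free tuple).
#' @param V rows x r x 3 numeric array of equivariant vector channels, or
#'   `NULL` when there are none.
#' @return Object of class `scalar_vector`.
#' @export
scalar_vector <- function(s, V = NULL) {
  s <- as.matrix(s)
  storage.mode(s) <- "double"
  if (!is.null(V)) {
    stopifnot(length(dim(V)) == 3L, dim(V)[3L] == 3L,
              dim(V)[1L] == nrow(s))
    storage.mode(V) <- "double"
  }
  structure(list(s = s, V = V), class = "scalar_vector")
}

#' @export
print.scalar_vector <- function(x, ...) {
  r <- if (is.null(x$V)) 0L else dim(x$V)[2L]
  cat(sprintf("<scalar_vector: %d rows, %d scalar ch., %d vector ch.>\n",
              nrow(x$s), ncol(x$s), r))
  invisible(x)
}

sv_rows <- function(sv) nrow(sv$s)
sv_swidth <- function(sv) ncol(sv$s)
sv_vwidth <- function(sv) if (is.null(sv$V)) 0L else dim(sv$V)[2L]

# Empty vector-channel array with the right shape.
vchan_zeros <- function(rows, r) array(0, dim = c(rows, r, 3L))

# rows x r matrix slice of component k (robust to dimension dropping).
vchan_slice <- function(V, k) {
  d <- dim(V)
  matrix(V[, , k], nrow = d[1L], ncol = d[2L])
}

# Channel-wise linear map on a vector stack: (rows x r x 3) %*% (r x r2),
# applied independently to each Cartesian component.
vchan_map <- function(V, W) {
  rows <- dim(V)[1L]
  out <- array(0, dim = c(rows, ncol(W), 3L))
  for (k in 1:3) {
    out[, , k] <- vchan_slice(V, k) %*% W
  }
  out
}

# Per-channel guarded L2 norms: rows x r matrix of sqrt(|v|^2 + eps^2).
vchan_norm <- function(V, eps = 1e-8) {
  sq <- vchan_slice(V, 1L)^2 + vchan_slice(V, 2L)^2 + vchan_slice(V, 3L)^2
  sqrt(sq + eps^2)
}

# Concatenate vector stacks along the channel dimension.
vchan_cat <- function(...) {
  parts <- Filter(Negate(is.null), list(...))
  if (length(parts) == 0L) return(NULL)
  rows <- dim(parts[[1L]])[1L]
  rtot <- sum(vapply(parts, function(p) dim(p)[2L], integer(1L)))
  out <- array(0, dim = c(rows, rtot, 3L))
  at <- 0L
  for (p in parts) {
    r <- dim(p)[2L]
    out[, at + seq_len(r), ] <- p
    at <- at + r
  }
  out
}

# Gather rows of a vector stack.
vchan_index <- function(V, idx) V[idx, , , drop = FALSE]

# Row-wise scatter-add of an E x r x 3 stack into an N x r x 3 stack,
# grouping by `group` (length E, values in 1..n).
vchan_rowsum <- function(V, group, n) {
  r <- dim(V)[2L]
  out <- array(0, dim = c(n, r, 3L))
  for (k in 1:3) {
    rs <- rowsum(vchan_slice(V, k), group = group, reorder = FALSE)
    out[as.integer(rownames(rs)), , k] <- rs
  }
  out
}

# Concatenate tuples channel-wise (same number of rows).
sv_concat <- function(...) {
  parts <- list(...)
  s <- do.call(cbind, lapply(parts, function(p) p$s))
  Vs <- lapply(parts, function(p) p$V)
  scalar_vector(s, do.call(vchan_cat, Vs))
}

# Elementwise sum of two tuples with identical widths.
sv_add <- function(x, y) {
  out_V <- if (is.null(x$V)) y$V else if (is.null(y$V)) x$V else x$V + y$V
  scalar_vector(x$s + y$s, out_V)
}

# Rotate every vector channel by Q (rows kept, components mixed): V Q^T.
sv_rotate_V <- function(V, Q) {
  if (is.null(V)) return(NULL)
  d <- dim(V)
  flat <- matrix(V, nrow = d[1L] * d[2L], ncol = 3L)
  array(flat %*% t(Q), dim = d)
}
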