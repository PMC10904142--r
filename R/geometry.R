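# Coordinate bookkeeping and local frame construction.
#
# All coordinates are plain N x 3 double matrices. Edge indices are 1-based
# E x 2 integer matrices of directed (i, j) pairs, i being the node that
# collects messages from its neighbor j.

#' Remove the center of mass from node positions
#'
#' Subtracts the arithmetic mean of the rows (unit node masses) so that the
#' returned coordinates have zero column means. Centering makes every
#' downstream frame construction translation-invariant.
#'
#' @param X N x 3 numeric matrix of Cartesian coordinates.
#' @return A list with `Xc` (centered N x 3 matrix) and `center`
#'   (length-3 numeric vector, the original center of mass).
#' @seealso [decentralize()]
#' @export
centralize <- function(X) {
  X <- as_coord_matrix(X)
  if (!all(is.finite(X))) {
    stop("centralize(): coordinates contain non-finite values")
  }
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center, "-")
  list(Xc = Xc, center = center)
}

#' Restore the original center of mass
#'
#' Exact inverse of [centralize()]: adds `center` back to every row.
#'
#' @param Xc N x 3 centered coordinate matrix.
#' @param center Length-3 numeric vector.
#' @return N x 3 coordinate matrix.
#' @export
decentralize <- function(Xc, center) {
  Xc <- as_coord_matrix(Xc)
  center <- as.numeric(center)
  if (length(center) != 3L) {
    stop("decentralize(): `center` must have length 3")
  }
  sweep(Xc, 2L, center, "+")
}

as_coord_matrix <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) != 3L) stop("coordinates must be an N x 3 matrix")
  storage.mode(X) <- "double"
  X
}

#' Directed k-nearest-neighbor graph
#'
#' For every node i, adds directed edges (i, j) to its `min(k, N - 1)`
#' nearest neighbors by Euclidean distance. Ties are broken by the lower
#' node index, and distances are compared in double precision, so the
#' topology is reproducible bit-for-bit. Self-loops are never created;
#' coincident points are valid neighbors at distance zero.
#'
#' @param X N x 3 coordinate matrix with N >= 2.
#' @param k Positive integer number of neighbors per node.
#' @return E x 2 integer matrix of directed (i, j) pairs,
#'   E = N * min(k, N - 1).
#' @export
knn_graph <- function(X, k) {
  X <- as_coord_matrix(X)
  n <- nrow(X)
  if (n < 2L) stop("knn_graph(): need at least 2 nodes")
  k <- as.integer(k)
  if (k < 1L) stop("knn_graph(): k must be >= 1")
  k_eff <- min(k, n - 1L)
  d2 <- as.matrix(stats::dist(X))^2
  src <- integer(0)
  dst <- integer(0)
  for (i in seq_len(n)) {
    cand <- setdiff(seq_len(n), i)
    ord <- cand[order(d2[i, cand], cand)]
    nb <- ord[seq_len(k_eff)]
    src <- c(src, rep.int(i, k_eff))
    dst <- c(dst, nb)
  }
  cbind(src, dst, deparse.level = 0L)
}

#' Per-edge local orthonormal frames
#'
#' Builds, for every directed edge (i, j) over *centered* coordinates, the
#' right-handed orthonormal triple
#' \deqn{a = (x_i - x_j) / \|x_i - x_j\|,\quad
#'       b = (x_i \times x_j) / \|x_i \times x_j\|,\quad
#'       c = a \times b.}
#' The triple is SO(3)-equivariant: rotating the coordinates by Q rotates
#' each axis by Q. It is *not* reflection-equivariant — under point
#' inversion the axes pick up the sign pattern (a, b, c) -> (-a, +b, -c) —
#' which is precisely what lets scalarized features distinguish
#' enantiomers.
#'
#' Norms are guarded as `sqrt(|.|^2 + eps^2)`. When the two centered
#' positions are collinear with the origin (`|x_i x x_j| < eps`) the b and
#' c axes are set to zero rather than to an arbitrary direction; such edges
#' are flagged in the `degenerate` field. Collinear configurations have
#' measure zero in generic point clouds.
#'
#' @param Xc N x 3 *centered* coordinates (see [centralize()]; b depends on
#'   absolute centered positions, so centering is the caller's contract).
#' @param edges E x 2 integer edge matrix.
#' @param eps Norm guard, default 1e-8.
#' @return Object of class `gcp_frames`: list with E x 3 matrices `a`, `b`,
#'   `c` and logical vector `degenerate`.
#' @export
localize <- function(Xc, edges, eps = 1e-8) {
  Xc <- as_coord_matrix(Xc)
  xi <- Xc[edges[, 1L], , drop = FALSE]
  xj <- Xc[edges[, 2L], , drop = FALSE]
  diff <- xi - xj
  a <- diff / sqrt(rowSums(diff^2) + eps^2)
  cr <- row_cross(xi, xj)
  cr_norm <- sqrt(rowSums(cr^2))
  degenerate <- cr_norm < eps
  b <- cr / sqrt(cr_norm^2 + eps^2)
  b[degenerate, ] <- 0
  cvec <- row_cross(a, b)
  cvec[degenerate, ] <- 0
  structure(list(a = a, b = b, c = cvec, degenerate = degenerate),
            class = "gcp_frames")
}

# Row-wise cross product of two E x 3 matrices.
row_cross <- function(u, v) {
  cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
        u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
        u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
}

#' Sample a random rigid motion
#'
#' Draws a uniform random rotation Q (via QR decomposition of a Gaussian
#' matrix with the sign convention fixed so that det Q = +1) and a
#' translation g uniform in \eqn{[-5, 5]^3}. Reproducible per seed.
#'
#' @param seed Integer seed.
#' @return List with `Q` (3 x 3 rotation) and `g` (length-3 translation).
#' @export
random_rigid_motion <- function(seed) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  Q <- random_rotation()
  g <- stats::runif(3L, -5, 5)
  list(Q = Q, g = g)
}

#' Sample a uniform random rotation matrix
#'
#' Uses the current RNG stream (call `set.seed()` first for
#' reproducibility).
#'
#' @return 3 x 3 rotation matrix with `det = +1`.
#' @export
random_rotation <- function() {
  M <- matrix(stats::rnorm(9L), 3L, 3L)
  qr_dec <- qr(M)
  Q <- qr.Q(qr_dec)
  d <- sign(diag(qr.R(qr_dec)))
  d[d == 0] <- 1
  Q <- Q %*% diag(d)
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' Apply a rigid motion to coordinates
#'
#' @param X N x 3 coordinates.
#' @param Q 3 x 3 rotation matrix.
#' @param g Optional length-3 translation (default zero).
#' @return Transformed N x 3 matrix `X Q^T + g`.
#' @export
apply_rigid_motion <- function(X, Q, g = c(0, 0, 0)) {
  sweep(as_coord_matrix(X) %*% t(Q), 2L, as.numeric(g), "+")
}

#' Read an XYZ-format point cloud
#'
#' Standard XYZ layout: atom count, a free-text comment line, then one
#' `element x y z` line per atom.
#'
#' @param path File path.
#' @return List with `types` (character), `positions` (N x 3 matrix) and
#'   `comment` (the second line, preserved verbatim).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1L]))
  comment <- if (length(lines) >= 2L) lines[2L] else ""
  body <- lines[seq(3L, length.out = n)]
  parts <- strsplit(trimws(body), "\\s+")
  types <- vapply(parts, `[[`, character(1L), 1L)
  pos <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3L)))
  list(types = types, positions = pos, comment = comment)
}

#' Write an XYZ-format point cloud
#'
#' @param types Character vector of element/type symbols.
#' @param positions N x 3 coordinate matrix.
#' @param path Output file path.
#' @param comment Comment line (default empty).
#' @return Invisibly, the path.
#' @export
write_xyz <- function(types, positions, path, comment = "") {
  positions <- as_coord_matrix(positions)
  stopifnot(length(types) == nrow(positions))
  body <- sprintf("%s %.10f %.10f %.10f", types,
                  positions[, 1L], positions[, 2L], positions[, 3L])
  writeLines(c(as.character(nrow(positions)), comment, body), path)
  invisible(path)
}

#' Write an edge list with its frames to CSV (debugging aid)
#'
#' @param edges E x 2 edge matrix.
#' @param frames `gcp_frames` object aligned with `edges`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_frames_csv <- function(edges, frames, path) {
  df <- data.frame(src = edges[, 1L], dst = edges[, 2L],
                   ax = frames$a[, 1L], ay = frames$a[, 2L], az = frames$a[, 3L],
                   bx = frames$b[, 1L], by = frames$b[, 2L], bz = frames$b[, 3L],
                   cx = frames$c[, 1L], cy = frames$c[, 2L], cz = frames$c[, 3L],
                   degenerate = frames$degenerate)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
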