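# Internal planar-polygon helpers. Vertices are n x 2 matrices in microns,
# closed implicitly (no repeated first vertex), CCW unless noted.

as_vertex_matrix <- function(v) {
  v <- as.matrix(v)
  if (ncol(v) != 2L) stop("vertices must have two columns (x, y)", call. = FALSE)
  storage.mode(v) <- "double"
  dimnames(v) <- list(NULL, c("x", "y"))
  v
}

#' @noRd
signed_area <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

poly_perimeter <- function(v) {
  d <- v[c(seq_len(nrow(v))[-1L], 1L), , drop = FALSE] - v
  sum(sqrt(rowSums(d^2)))
}

poly_centroid <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-300) return(colMeans(v))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

ensure_ccw <- function(v) if (signed_area(v) < 0) v[rev(seq_len(nrow(v))), , drop = FALSE] else v

is_simple_polygon <- function(v) nrow(cpp_crossing_edge_pairs(as_vertex_matrix(v))) == 0L

# Convex hull vertices in CCW order (grDevices::chull returns clockwise).
hull_vertices <- function(v) {
  idx <- rev(grDevices::chull(v[, 1L], v[, 2L]))
  v[idx, , drop = FALSE]
}

rotate_points <- function(v, theta, center = c(0, 0)) {
  ct <- cos(theta); st <- sin(theta)
  vc <- sweep(v, 2L, center)
  out <- cbind(vc[, 1L] * ct - vc[, 2L] * st, vc[, 1L] * st + vc[, 2L] * ct)
  sweep(out, 2L, center, `+`)
}

# Turn angle at each vertex; positive = left turn (convex on a CCW polygon).
turn_angles <- function(v) {
  n <- nrow(v)
  ip <- c(n, seq_len(n - 1L)); nx <- c(seq_len(n)[-1L], 1L)
  e1 <- v - v[ip, , drop = FALSE]
  e2 <- v[nx, , drop = FALSE] - v
  atan2(e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L], rowSums(e1 * e2))
}
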