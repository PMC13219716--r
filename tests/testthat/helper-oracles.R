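# Independent brute-force oracles, deliberately sharing no code with the
# package internals: gift-wrapping hull, edge-support minimal width,
# ray-casting point-in-polygon, O(n^2) simplicity, dense-grid LEC.

oracle_hull <- function(v) {
  # gift wrapping (Jarvis march), CCW
  n <- nrow(v)
  start <- which.min(v[, 1] + 1e-12 * v[, 2])
  hull <- start
  repeat {
    p <- hull[length(hull)]
    cand <- setdiff(seq_len(n), p)
    q <- cand[1]
    for (r in cand[-1]) {
      cr <- (v[q, 1] - v[p, 1]) * (v[r, 2] - v[p, 2]) -
            (v[q, 2] - v[p, 2]) * (v[r, 1] - v[p, 1])
      d_q <- sum((v[q, ] - v[p, ])^2); d_r <- sum((v[r, ] - v[p, ])^2)
      if (cr < 0 || (abs(cr) < 1e-12 && d_r > d_q)) q <- r
    }
    if (q == start) break
    hull <- c(hull, q)
    if (length(hull) > n) stop("gift wrapping failed")
  }
  v[hull, , drop = FALSE]
}

oracle_perimeter <- function(v) {
  n <- nrow(v)
  sum(sqrt(rowSums((v[c(2:n, 1), , drop = FALSE] - v)^2)))
}

oracle_lobeyness <- function(v) oracle_perimeter(v) / oracle_perimeter(oracle_hull(v))

oracle_min_width <- function(v) {
  # exact minimal width: min over hull edges of the farthest-vertex distance
  h <- oracle_hull(v)
  n <- nrow(h)
  best <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- h[j, ] - h[i, ]
    len <- sqrt(sum(e^2))
    if (len < 1e-14) next
    d <- abs((h[, 1] - h[i, 1]) * (-e[2]) + (h[, 2] - h[i, 2]) * e[1]) / len
    best <- min(best, max(d))
  }
  best
}

oracle_point_in_poly <- function(px, py, v) {
  n <- nrow(v)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((v[i, 2] > py) != (v[j, 2] > py) &&
        px < (v[j, 1] - v[i, 1]) * (py - v[i, 2]) / (v[j, 2] - v[i, 2]) + v[i, 1])
      inside <- !inside
    j <- i
  }
  inside
}

oracle_dist_to_boundary <- function(px, py, v) {
  n <- nrow(v)
  best <- Inf
  j <- n
  for (i in seq_len(n)) {
    e <- v[i, ] - v[j, ]
    l2 <- sum(e^2)
    t <- if (l2 > 0) max(0, min(1, ((px - v[j, 1]) * e[1] + (py - v[j, 2]) * e[2]) / l2)) else 0
    q <- v[j, ] + t * e
    best <- min(best, sqrt((px - q[1])^2 + (py - q[2])^2))
    j <- i
  }
  best
}

oracle_lec_radius <- function(v, h) {
  # dense-grid maximum of distance-to-boundary over interior points
  xs <- seq(min(v[, 1]), max(v[, 1]), by = h)
  ys <- seq(min(v[, 2]), max(v[, 2]), by = h)
  best <- 0
  for (x in xs) for (y in ys) {
    if (oracle_point_in_poly(x, y, v)) {
      d <- oracle_dist_to_boundary(x, y, v)
      if (d > best) best <- d
    }
  }
  best
}

oracle_is_simple <- function(v) {
  n <- nrow(v)
  seg_int <- function(p1, p2, p3, p4) {
    d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
    ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
  }
  for (i in seq_len(n)) {
    i2 <- if (i == n) 1L else i + 1L
    for (j in seq_len(n)) {
      if (j <= i + 1L) next
      if (i == 1L && j == n) next
      j2 <- if (j == n) 1L else j + 1L
      if (seg_int(v[i, ], v[i2, ], v[j, ], v[j2, ])) return(FALSE)
    }
  }
  TRUE
}

# random star polygon r(theta) = R (1 + a cos k theta) with jitter
random_star <- function(seed, n_points = 96) {
  set.seed(seed)
  R <- runif(1, 2, 30)
  a <- runif(1, 0, 0.4)
  k <- sample(3:9, 1)
  th <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  r <- R * (1 + a * cos(k * th + runif(1, 0, 2 * pi)))
  cbind(r * cos(th), r * sin(th))
}

rigid_motion <- function(v, theta, shift) {
  cbind(v[, 1] * cos(theta) - v[, 2] * sin(theta) + shift[1],
        v[, 1] * sin(theta) + v[, 2] * cos(theta) + shift[2])
}
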