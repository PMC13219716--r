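# Fully damped mass-spring model of puzzle-cell emergence. Cells are vertex
# cycles on a shared planar spring network; tissue growth is imposed by
# moving the outer rim outward each step, interior vertices relax to force
# equilibrium, and stiff intracellular "connection" springs (the
# microtubule / cellulose proxy) are placed where the local geometry admits
# them, pinning indentations while unreinforced wall spans keep extending.

#' Simulation configuration
#'
#' Mechanical and rule parameters of the mass-spring model. The constants
#' are implementation defaults chosen to reproduce the qualitative shape
#' orderings (lobed vs elongated, lobe-orientation memory, division
#' effects); see the methods vignette for rationale.
#'
#' @param k_wall Wall-spring stiffness.
#' @param k_conn Connection-spring stiffness (stiff: >= 10 x `k_wall`).
#' @param relax_tolerance Convergence threshold on the largest normalised
#'   per-vertex force.
#' @param max_relax_iters Iteration cap per growth step.
#' @param lec_target Target free span in microns; the connection length cap
#'   is `conn_len_factor * lec_target`. Default: initial cell size,
#'   resolved at run time.
#' @param conn_len_factor Multiple of `lec_target` giving the chord length
#'   cap.
#' @param theta_max Maximum angle (radians) between an admitted chord and
#'   the inward wall normal at each endpoint.
#' @param require_concave Require at least one chord endpoint in a concave
#'   (indentation) region.
#' @param yield_rate Plastic yielding rate: interior wall rest lengths move
#'   toward the current length by this fraction per step.
#' @param pretension Residual wall strain: yielding targets
#'   `length * (1 - pretension)`, so interior walls stay slightly taut and
#'   outlines remain smooth.
#' @param conn_break_strain Connections stretched beyond this strain are
#'   released (the microtubule proxy detaches rather than pinning the
#'   tissue indefinitely).
#' @param subdivide_factor Walls longer than `subdivide_factor` times the
#'   initial edge length are split so boundary resolution tracks growth.
#' @param division Enable cell division.
#' @param f_div Division phase: divisions occur while normalised time
#'   `t <= f_div`.
#' @param area_threshold Division area threshold; default 2 x the initial
#'   mean cell area, resolved at run time.
#' @param rng_seed Seed (template jitter is the only stochastic element).
#' @return A `sim_config` list.
#' @export
sim_config <- function(k_wall = 1, k_conn = 10, relax_tolerance = 1e-5,
                       max_relax_iters = 8000L, lec_target = NULL,
                       conn_len_factor = 1.5, theta_max = pi / 6,
                       require_concave = TRUE, yield_rate = 1,
                       pretension = 0, conn_break_strain = 0.15,
                       subdivide_factor = 1.6, division = FALSE,
                       f_div = 0.2, area_threshold = NULL, rng_seed = 0L) {
  stopifnot(k_wall > 0, k_conn > 0, relax_tolerance > 0,
            f_div >= 0, f_div <= 1, theta_max > 0, yield_rate >= 0,
            yield_rate <= 1, subdivide_factor > 1, pretension >= 0,
            pretension < 1, conn_break_strain > 0)
  structure(list(k_wall = k_wall, k_conn = k_conn,
                 relax_tolerance = relax_tolerance,
                 max_relax_iters = as.integer(max_relax_iters),
                 lec_target = lec_target, conn_len_factor = conn_len_factor,
                 theta_max = theta_max, require_concave = require_concave,
                 yield_rate = yield_rate, pretension = pretension,
                 conn_break_strain = conn_break_strain,
                 subdivide_factor = subdivide_factor,
                 division = division, f_div = f_div,
                 area_threshold = area_threshold,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

edge_lengths <- function(pos, e) {
  d <- pos[e[, 2L], , drop = FALSE] - pos[e[, 1L], , drop = FALSE]
  sqrt(rowSums(d^2))
}

new_cell_mesh <- function(pos, boundary, walls, cells, cell_size, ell0) {
  structure(list(pos = pos, boundary = boundary, walls = walls,
                 conns = matrix(numeric(0), 0L, 4L,
                                dimnames = list(NULL, c("a", "b", "rest", "cell"))),
                 cells = cells, center = colMeans(pos[boundary, , drop = FALSE]),
                 cell_size = cell_size, ell0 = ell0),
            class = "cell_mesh")
}

#' Build an initial tissue template
#'
#' A grid of polygonal cells whose shared walls are subdivided into short
#' springs, with seeded jitter on interior vertices to break symmetry. The
#' outer rim is boundary-flagged and will be driven by the growth schedule.
#'
#' @param kind `"isodiametric_grid"` (near-regular cells) or
#'   `"maize_elongated"` (cells elongated along y, as in a young grass
#'   leaf).
#' @param n_cells Approximate number of cells (arranged on the nearest
#'   divisor grid).
#' @param cell_size Cell width in microns.
#' @param rng_seed Seed for the jitter.
#' @param subdivisions Springs per cell wall side.
#' @param jitter Jitter amplitude as a fraction of the spring length.
#' @param aspect Cell height / width for `"maize_elongated"`.
#' @return A `cell_mesh`.
#' @export
make_template <- function(kind = c("isodiametric_grid", "maize_elongated"),
                          n_cells = 16L, cell_size = 1, rng_seed = 0L,
                          subdivisions = 4L, jitter = 0.3, aspect = 5) {
  kind <- match.arg(kind)
  if (cell_size <= 0) stop_pavecell("parameter", "cell_size must be > 0")
  stopifnot(n_cells >= 1)
  nx <- max(1L, round(sqrt(n_cells)))
  while (n_cells %% nx != 0L) nx <- nx - 1L
  ny <- n_cells %/% nx
  cw <- cell_size
  ch <- if (kind == "maize_elongated") cell_size * aspect else cell_size
  m <- as.integer(subdivisions)
  nu <- nx * m; nv <- ny * m
  # vertex ids on the fine lattice: points exist on cell-boundary lines only
  id <- matrix(NA_integer_, nu + 1L, nv + 1L)
  cnt <- 0L
  for (v in 0:nv) for (u in 0:nu) {
    if (u %% m == 0L || v %% m == 0L) {
      cnt <- cnt + 1L
      id[u + 1L, v + 1L] <- cnt
    }
  }
  pos <- matrix(0, cnt, 2L)
  for (v in 0:nv) for (u in 0:nu) {
    i <- id[u + 1L, v + 1L]
    if (!is.na(i)) pos[i, ] <- c(u * cw / m, v * ch / m)
  }
  boundary <- logical(cnt)
  for (v in 0:nv) for (u in 0:nu) {
    i <- id[u + 1L, v + 1L]
    if (!is.na(i) && (u == 0L || u == nu || v == 0L || v == nv))
      boundary[i] <- TRUE
  }
  # jitter interior vertices (shared corners included) to break symmetry
  sp <- min(cw, ch) / m
  jit <- with_seed(rng_seed, matrix(runif(2L * cnt, -jitter, jitter) * sp, cnt, 2L))
  pos[!boundary, ] <- pos[!boundary, , drop = FALSE] + jit[!boundary, , drop = FALSE]
  # walls along the lattice lines
  wa <- integer(0); wb <- integer(0)
  for (v in seq(0L, nv, by = m)) for (u in 0:(nu - 1L))
    { wa <- c(wa, id[u + 1L, v + 1L]); wb <- c(wb, id[u + 2L, v + 1L]) }
  for (u in seq(0L, nu, by = m)) for (v in 0:(nv - 1L))
    { wa <- c(wa, id[u + 1L, v + 1L]); wb <- c(wb, id[u + 1L, v + 2L]) }
  walls <- cbind(a = wa, b = wb, rest = 0)
  walls[, "rest"] <- edge_lengths(pos, walls)
  # cell cycles (CCW)
  cells <- vector("list", nx * ny)
  ci <- 0L
  for (J in seq_len(ny)) for (I in seq_len(nx)) {
    u0 <- (I - 1L) * m; u1 <- I * m
    v0 <- (J - 1L) * m; v1 <- J * m
    cyc <- c(id[(u0:u1) + 1L, v0 + 1L],            # bottom, left -> right
             id[u1 + 1L, (v0:v1)[-1L] + 1L],       # right, up
             id[rev(u0:u1)[-1L] + 1L, v1 + 1L],    # top, right -> left
             id[u0 + 1L, rev(v0:v1)[-c(1L)] + 1L]) # left, down
    cyc <- cyc[-length(cyc)]                       # drop repeated start
    ci <- ci + 1L
    cells[[ci]] <- as.integer(cyc)
  }
  new_cell_mesh(pos, boundary, walls, cells, cell_size = cell_size,
                ell0 = mean(walls[, "rest"]))
}

#' @export
print.cell_mesh <- function(x, ...) {
  cat(sprintf("<cell_mesh> %d vertices (%d rim), %d walls, %d connections, %d cells\n",
              nrow(x$pos), sum(x$boundary), nrow(x$walls), nrow(x$conns),
              length(x$cells)))
  invisible(x)
}

#' Extract cell outlines as contours
#'
#' @param mesh A `cell_mesh`.
#' @param species,clade Labels attached to the contours.
#' @return A `contour_set` with one contour per cell.
#' @export
cells_to_contours <- function(mesh, species = "sim", clade = "sim") {
  cts <- vector("list", length(mesh$cells))
  for (i in seq_along(mesh$cells)) {
    cts[[i]] <- tryCatch(
      contour(mesh$pos[mesh$cells[[i]], , drop = FALSE], label = i,
              clade = clade, species = species, organ = "tissue",
              sample = sprintf("cell%03d", i)),
      error = function(e) NULL)
  }
  contour_set(Filter(Negate(is.null), cts))
}

#' Impose one step of boundary growth
#'
#' Scales the rim anisotropically about the template centroid by
#' `(1 + gx_step, 1 + gy_step)` and resets rim wall rest lengths to their
#' new lengths (rim growth is imposed, not elastic). Interior vertices are
#' untouched by this call.
#'
#' @param mesh A `cell_mesh`.
#' @param gx_step,gy_step Per-step growth increments (>= 0).
#' @return The grown `cell_mesh`.
#' @export
apply_boundary_growth <- function(mesh, gx_step, gy_step) {
  stopifnot(gx_step >= 0, gy_step >= 0)
  b <- mesh$boundary
  mesh$pos[b, 1L] <- mesh$center[1L] + (mesh$pos[b, 1L] - mesh$center[1L]) * (1 + gx_step)
  mesh$pos[b, 2L] <- mesh$center[2L] + (mesh$pos[b, 2L] - mesh$center[2L]) * (1 + gy_step)
  rim <- b[mesh$walls[, "a"]] & b[mesh$walls[, "b"]]
  if (any(rim))
    mesh$walls[rim, "rest"] <- edge_lengths(mesh$pos, mesh$walls[rim, , drop = FALSE])
  mesh
}

#' Relax interior vertices to force equilibrium
#'
#' Damped (fully overdamped) iteration on the spring network with the rim
#' held fixed, until the largest normalised per-vertex force drops below
#' `cfg$relax_tolerance` or the iteration cap is reached. Non-convergence
#' is flagged via attributes, never silent.
#'
#' @param mesh A `cell_mesh`.
#' @param cfg A [sim_config()].
#' @return The relaxed `cell_mesh`, with attributes `iterations` and
#'   `residual`.
#' @export
relax <- function(mesh, cfg = sim_config()) {
  nw <- nrow(mesh$walls); ncn <- nrow(mesh$conns)
  sa <- c(mesh$walls[, "a"], mesh$conns[, "a"])
  sb <- c(mesh$walls[, "b"], mesh$conns[, "b"])
  rest <- c(mesh$walls[, "rest"], mesh$conns[, "rest"])
  stiff <- c(rep(cfg$k_wall, nw), rep(cfg$k_conn, ncn))
  res <- cpp_relax_springs(mesh$pos, as.integer(sa), as.integer(sb),
                           rest, stiff, mesh$boundary,
                           cfg$relax_tolerance, cfg$max_relax_iters, 0.4)
  mesh$pos <- res$pos
  attr(mesh, "iterations") <- res$iterations
  attr(mesh, "residual") <- res$residual
  mesh
}

yield_walls <- function(mesh, rate, pretension = 0) {
  rim <- mesh$boundary[mesh$walls[, "a"]] & mesh$boundary[mesh$walls[, "b"]]
  len <- edge_lengths(mesh$pos, mesh$walls)
  target <- len * (1 - pretension)
  mesh$walls[!rim, "rest"] <- mesh$walls[!rim, "rest"] +
    rate * (target[!rim] - mesh$walls[!rim, "rest"])
  mesh
}

# Split wall k at a point (default midpoint); updates cell cycles and
# returns the new vertex id.
split_wall <- function(mesh, k, at = NULL) {
  a <- mesh$walls[k, "a"]; b <- mesh$walls[k, "b"]
  p <- if (is.null(at)) (mesh$pos[a, ] + mesh$pos[b, ]) / 2 else at
  mesh$pos <- rbind(mesh$pos, p)
  newv <- nrow(mesh$pos)
  mesh$boundary <- c(mesh$boundary, mesh$boundary[a] && mesh$boundary[b])
  r <- mesh$walls[k, "rest"]
  la <- sqrt(sum((p - mesh$pos[a, ])^2))
  lb <- sqrt(sum((p - mesh$pos[b, ])^2))
  tot <- la + lb
  fr <- if (tot > 0) la / tot else 0.5
  mesh$walls[k, ] <- c(a, newv, r * fr)
  mesh$walls <- rbind(mesh$walls, c(newv, b, r * (1 - fr)))
  for (ci in seq_along(mesh$cells)) {
    cyc <- mesh$cells[[ci]]
    n <- length(cyc)
    nxt <- c(cyc[-1L], cyc[1L])
    hit <- which((cyc == a & nxt == b) | (cyc == b & nxt == a))
    if (length(hit)) {
      mesh$cells[[ci]] <- append(cyc, newv, after = hit[1L])
    }
  }
  list(mesh = mesh, vertex = newv)
}

subdivide_walls <- function(mesh, cfg) {
  repeat {
    len <- edge_lengths(mesh$pos, mesh$walls)
    long <- which(len > cfg$subdivide_factor * mesh$ell0)
    if (!length(long)) return(mesh)
    for (k in long) mesh <- split_wall(mesh, k)$mesh
  }
}

concave_flags <- function(cyc_pos) {
  # concave = right turn on a CCW outline
  turn_angles(cyc_pos) < -1e-9
}

#' Place intracellular connection springs
#'
#' For every cell, chords between outline vertices are admitted when they
#' (i) lie entirely inside the cell, (ii) are no longer than the length cap
#' (`conn_len_factor * lec_target`), (iii) leave each endpoint within
#' `theta_max` of the inward wall normal, and (iv) have at least one
#' endpoint in a concave (indentation) region. Admitted chords become stiff
#' springs at their current length; existing connections that no longer lie
#' inside their cell are removed. Re-evaluated every growth step.
#'
#' @param mesh A `cell_mesh`.
#' @param cfg A [sim_config()].
#' @return The `cell_mesh` with updated connections.
#' @export
place_connections <- function(mesh, cfg = sim_config()) {
  lec_target <- if (is.null(cfg$lec_target)) mesh$cell_size else cfg$lec_target
  max_len <- cfg$conn_len_factor * lec_target
  cos_max <- cos(cfg$theta_max)
  keep_a <- integer(0); keep_b <- integer(0); keep_rest <- numeric(0)
  keep_cell <- integer(0)
  old <- mesh$conns
  for (ci in seq_along(mesh$cells)) {
    cyc <- mesh$cells[[ci]]
    cp <- mesh$pos[cyc, , drop = FALSE]
    conc <- concave_flags(cp)
    adm <- cpp_admissible_chords(cp, conc, max_len, cos_max,
                                 cfg$require_concave)
    if (nrow(adm)) {
      va <- cyc[adm[, 1L]]; vb <- cyc[adm[, 2L]]
      key_new <- paste(pmin(va, vb), pmax(va, vb))
      # retain the original rest length of connections that persist
      if (nrow(old)) {
        oc <- old[old[, "cell"] == ci, , drop = FALSE]
        key_old <- paste(pmin(oc[, "a"], oc[, "b"]), pmax(oc[, "a"], oc[, "b"]))
        m2 <- match(key_new, key_old)
      } else m2 <- rep(NA_integer_, length(key_new))
      d <- sqrt(rowSums((mesh$pos[vb, , drop = FALSE] -
                           mesh$pos[va, , drop = FALSE])^2))
      rest_old <- if (nrow(old)) old[old[, "cell"] == ci, , drop = FALSE][m2, "rest"]
                  else rep(NA_real_, length(d))
      # persisting connections keep their rest length until overstretched
      # (breakage), then re-anchor at the current length
      rest <- ifelse(is.na(rest_old) |
                       d > (1 + cfg$conn_break_strain) * rest_old,
                     d, rest_old)
      keep_a <- c(keep_a, va); keep_b <- c(keep_b, vb)
      keep_rest <- c(keep_rest, rest); keep_cell <- c(keep_cell, rep(ci, length(va)))
    }
  }
  mesh$conns <- cbind(a = keep_a, b = keep_b, rest = keep_rest, cell = keep_cell)
  mesh
}

cell_polygon <- function(mesh, ci) mesh$pos[mesh$cells[[ci]], , drop = FALSE]

# Numerical guard: a relaxation step can push a pinched neck just past
# itself. Uncross by replacing the vertices incident to crossing edges with
# their cycle-neighbourhood average (local, a few passes); cells stay simple
# at every snapshot.
fix_crossings <- function(mesh, max_passes = 5L) {
  for (ci in seq_along(mesh$cells)) {
    cyc <- mesh$cells[[ci]]
    n <- length(cyc)
    if (n < 4L) next
    for (p in seq_len(max_passes)) {
      cp <- mesh$pos[cyc, , drop = FALSE]
      cross <- cpp_crossing_edge_pairs(cp)
      if (!nrow(cross)) break
      edges <- unique(as.vector(cross))
      flagged <- unique(c(edges, edges %% n + 1L))
      flagged <- flagged[!mesh$boundary[cyc[flagged]]]  # rim stays imposed
      if (!length(flagged)) break
      ip <- c(n, seq_len(n - 1L)); nx <- c(seq_len(n)[-1L], 1L)
      sm <- (cp[ip, , drop = FALSE] + cp + cp[nx, , drop = FALSE]) / 3
      mesh$pos[cyc[flagged], ] <- sm[flagged, , drop = FALSE]
    }
  }
  mesh
}

# Shortest straight chord through the centroid (Errera-style division plane).
shortest_centroid_chord <- function(poly, n_dirs = 60L) {
  ctr <- poly_centroid(poly)
  n <- nrow(poly)
  nxt <- c(seq_len(n)[-1L], 1L)
  best <- NULL
  for (th in seq(0, pi, length.out = n_dirs + 1L)[-(n_dirs + 1L)]) {
    d <- c(cos(th), sin(th))
    nrm <- c(-d[2L], d[1L])
    # signed distances of vertices from the line through ctr along d
    s <- (poly[, 1L] - ctr[1L]) * nrm[1L] + (poly[, 2L] - ctr[2L]) * nrm[2L]
    hits_edge <- integer(0); hits_t <- numeric(0)
    for (i in seq_len(n)) {
      j <- nxt[i]
      if ((s[i] > 0) != (s[j] > 0)) {
        f <- s[i] / (s[i] - s[j])
        p <- poly[i, ] + f * (poly[j, ] - poly[i, ])
        hits_edge <- c(hits_edge, i)
        hits_t <- c(hits_t, (p[1L] - ctr[1L]) * d[1L] + (p[2L] - ctr[2L]) * d[2L])
      }
    }
    if (length(hits_t) < 2L) next
    neg <- which(hits_t <= 0); pos_ <- which(hits_t >= 0)
    if (!length(neg) || !length(pos_)) next
    i1 <- neg[which.max(hits_t[neg])]
    i2 <- pos_[which.min(hits_t[pos_])]
    if (i1 == i2) next
    width <- hits_t[i2] - hits_t[i1]
    if (is.null(best) || width < best$width)
      best <- list(width = width, edges = c(hits_edge[i1], hits_edge[i2]),
                   points = rbind(ctr + hits_t[i1] * d, ctr + hits_t[i2] * d))
  }
  best
}

#' Divide oversized cells during the division phase
#'
#' While normalised time `t <= cfg$f_div` (and division is enabled), every
#' cell whose area exceeds the threshold is split by a straight wall through
#' its centroid along the shortest crossing direction. Daughters keep the
#' parent's slot in the cell list (first daughter) plus a new slot appended
#' (second daughter). A division that would not produce two simple polygons
#' is skipped and logged.
#'
#' @param mesh A `cell_mesh`.
#' @param t Normalised time in \[0, 1\].
#' @param cfg A [sim_config()].
#' @return The `cell_mesh`.
#' @export
divide_cells <- function(mesh, t, cfg = sim_config()) {
  if (!cfg$division || t > cfg$f_div) return(mesh)
  a_div <- cfg$area_threshold
  if (is.null(a_div))
    stop_pavecell("parameter", "area_threshold must be resolved before division")
  for (ci in seq_along(mesh$cells)) {
    poly <- cell_polygon(mesh, ci)
    if (abs(signed_area(poly)) <= a_div) next
    mesh <- divide_one_cell(mesh, ci, cfg)
  }
  mesh
}

divide_one_cell <- function(mesh, ci, cfg) {
  cyc <- mesh$cells[[ci]]
  poly <- mesh$pos[cyc, , drop = FALSE]
  chord <- shortest_centroid_chord(poly)
  if (is.null(chord)) {
    message("division skipped for cell ", ci, ": no crossing chord")
    return(mesh)
  }
  # split the two crossed walls at the intersection points
  endv <- integer(2)
  for (k in 1:2) {
    i <- chord$edges[k]
    # re-locate the edge in the (possibly already updated) cycle
    cyc <- mesh$cells[[ci]]
    a <- cyc[i]; b <- cyc[if (i == length(cyc)) 1L else i + 1L]
    p <- chord$points[k, ]
    # snap to an endpoint if the hit is essentially on it
    da <- sqrt(sum((p - mesh$pos[a, ])^2)); db <- sqrt(sum((p - mesh$pos[b, ])^2))
    if (da < 1e-9) { endv[k] <- a; next }
    if (db < 1e-9) { endv[k] <- b; next }
    wk <- which((mesh$walls[, "a"] == a & mesh$walls[, "b"] == b) |
                  (mesh$walls[, "a"] == b & mesh$walls[, "b"] == a))
    if (!length(wk)) { endv[k] <- a; next }
    sp <- split_wall(mesh, wk[1L], at = p)
    mesh <- sp$mesh
    endv[k] <- sp$vertex
    if (k == 1L && chord$edges[2L] >= i) {
      # the first split inserts a vertex, shifting the second edge index
      chord$edges[2L] <- chord$edges[2L] + 1L
    }
  }
  if (endv[1L] == endv[2L]) return(mesh)
  cyc <- mesh$cells[[ci]]
  i1 <- match(endv[1L], cyc); i2 <- match(endv[2L], cyc)
  if (is.na(i1) || is.na(i2)) return(mesh)
  if (i1 > i2) { tmp <- i1; i1 <- i2; i2 <- tmp }
  # new wall chain between the two endpoints, subdivided to ~ell0
  p1 <- mesh$pos[cyc[i1], ]; p2 <- mesh$pos[cyc[i2], ]
  seg_len <- sqrt(sum((p2 - p1)^2))
  nseg <- max(1L, ceiling(seg_len / mesh$ell0))
  chain <- cyc[i1]
  for (s in seq_len(nseg - 1L)) {
    q <- p1 + (p2 - p1) * s / nseg
    mesh$pos <- rbind(mesh$pos, q)
    mesh$boundary <- c(mesh$boundary, FALSE)
    chain <- c(chain, nrow(mesh$pos))
  }
  chain <- c(chain, cyc[i2])
  for (s in seq_len(length(chain) - 1L)) {
    l <- sqrt(sum((mesh$pos[chain[s + 1L], ] - mesh$pos[chain[s], ])^2))
    mesh$walls <- rbind(mesh$walls, c(chain[s], chain[s + 1L], l))
  }
  d1 <- c(cyc[i1:i2], rev(chain[-c(1L, length(chain))]))
  d2 <- c(cyc[i2:length(cyc)], if (i1 > 1L) cyc[1L:i1] else cyc[1L],
          chain[-c(1L, length(chain))])
  d2 <- unique_cycle(d2)
  d1 <- unique_cycle(d1)
  ok1 <- length(d1) >= 3L && is_simple_polygon(mesh$pos[d1, , drop = FALSE]) &&
    abs(signed_area(mesh$pos[d1, , drop = FALSE])) > 1e-12
  ok2 <- length(d2) >= 3L && is_simple_polygon(mesh$pos[d2, , drop = FALSE]) &&
    abs(signed_area(mesh$pos[d2, , drop = FALSE])) > 1e-12
  if (!ok1 || !ok2) {
    message("division skipped for cell ", ci, ": daughters not simple")
    return(mesh)
  }
  if (signed_area(mesh$pos[d1, , drop = FALSE]) < 0) d1 <- rev(d1)
  if (signed_area(mesh$pos[d2, , drop = FALSE]) < 0) d2 <- rev(d2)
  # drop connections owned by the parent; they are re-placed next step
  if (nrow(mesh$conns))
    mesh$conns <- mesh$conns[mesh$conns[, "cell"] != ci, , drop = FALSE]
  mesh$cells[[ci]] <- as.integer(d1)
  mesh$cells[[length(mesh$cells) + 1L]] <- as.integer(d2)
  mesh
}

unique_cycle <- function(cyc) {
  cyc <- cyc[c(TRUE, cyc[-1L] != cyc[-length(cyc)])]
  if (length(cyc) > 1L && cyc[1L] == cyc[length(cyc)]) cyc <- cyc[-length(cyc)]
  cyc
}

#' Run a growth simulation
#'
#' Per step: impose boundary growth, relax the spring network, let interior
#' walls yield plastically, subdivide over-stretched walls, re-evaluate
#' connection placement, and (during the division phase) divide oversized
#' cells. Fully reproducible for a given template, schedule and config.
#'
#' @param template A `cell_mesh` from [make_template()].
#' @param schedule A `growth_schedule`.
#' @param cfg A [sim_config()].
#' @param snapshot_every Record a mesh snapshot every this many steps
#'   (`NULL` = none; the final mesh is always kept).
#' @param compute_metrics Compute the final per-cell metric table
#'   (default `TRUE`).
#' @param connections Master switch for connection placement (default
#'   `TRUE`; disabling gives the unreinforced control).
#' @return A `sim_result`: list with `final` (mesh), `snapshots`,
#'   `metrics` (per-cell table or `NULL`), `convergence` (per-step
#'   iterations and residuals), `schedule`, `cfg`.
#' @export
run_simulation <- function(template, schedule, cfg = sim_config(),
                           snapshot_every = NULL, compute_metrics = TRUE,
                           connections = TRUE) {
  stopifnot(inherits(template, "cell_mesh"),
            inherits(schedule, "growth_schedule"))
  mesh <- template
  if (is.null(cfg$lec_target)) cfg$lec_target <- mesh$cell_size
  if (is.null(cfg$area_threshold)) {
    areas <- vapply(seq_along(mesh$cells), function(i)
      abs(signed_area(cell_polygon(mesh, i))), numeric(1))
    cfg$area_threshold <- 2 * mean(areas)
  }
  n <- schedule$n_steps
  snaps <- list()
  conv_it <- integer(n); conv_res <- numeric(n)
  for (k in seq_len(n)) {
    t <- k / n
    f <- schedule$factors[k, ]
    mesh <- apply_boundary_growth(mesh, f[[1L]] - 1, f[[2L]] - 1)
    mesh <- relax(mesh, cfg)
    conv_it[k] <- attr(mesh, "iterations")
    conv_res[k] <- attr(mesh, "residual")
    mesh <- fix_crossings(mesh)
    mesh <- yield_walls(mesh, cfg$yield_rate, cfg$pretension)
    mesh <- subdivide_walls(mesh, cfg)
    if (connections) mesh <- place_connections(mesh, cfg)
    if (cfg$division) mesh <- divide_cells(mesh, t, cfg)
    if (!is.null(snapshot_every) && k %% snapshot_every == 0L)
      snaps[[as.character(k)]] <- mesh
  }
  failed <- conv_res > 10 * cfg$relax_tolerance
  if (mean(failed) > 0.5)
    stop_pavecell("relaxation",
                  sprintf("relaxation failed to converge in %d/%d steps (median residual %.3g)",
                          sum(failed), n, median(conv_res[failed])))
  if (any(failed))
    warning(sprintf("relaxation hit the iteration cap in %d/%d steps", sum(failed), n))
  metrics <- if (compute_metrics)
    metrics_table(cells_to_contours(mesh), n_angles = 720L)
  else NULL
  structure(list(final = mesh, snapshots = snaps, metrics = metrics,
                 convergence = data.frame(step = seq_len(n),
                                          iterations = conv_it,
                                          residual = conv_res),
                 schedule = schedule, cfg = cfg),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %d steps, %d cells", nrow(x$convergence),
              length(x$final$cells)))
  if (!is.null(x$metrics) && any(x$metrics$ok))
    cat(sprintf(", mean lobeyness %.3f",
                mean(x$metrics$lobeyness[x$metrics$ok])))
  cat("\n")
  invisible(x)
}

#' Plot a cell mesh
#'
#' Draws cell outlines and (optionally) connection springs.
#'
#' @param x A `cell_mesh` or `sim_result`.
#' @param connections Draw connection chords.
#' @param ... Ignored.
#' @export
plot.cell_mesh <- function(x, connections = TRUE, ...) {
  plot.new()
  rng <- apply(x$pos, 2L, range)
  plot.window(rng[, 1L], rng[, 2L], asp = 1)
  for (cyc in x$cells) polygon(x$pos[cyc, 1L], x$pos[cyc, 2L], border = "grey20")
  if (connections && nrow(x$conns))
    segments(x$pos[x$conns[, "a"], 1L], x$pos[x$conns[, "a"], 2L],
             x$pos[x$conns[, "b"], 1L], x$pos[x$conns[, "b"], 2L],
             col = "tomato")
  axis(1); axis(2); box()
  invisible(x)
}

#' @export
plot.sim_result <- function(x, ...) plot.cell_mesh(x$final, ...)

#' Preset growth scenarios
#'
#' Named (template, schedule, config) bundles for the canonical scenarios:
#' \describe{
#'   \item{fig1D}{constant weakly anisotropic growth (rim speed ratio
#'     ~1.6:1), cumulative scale (10, 16).}
#'   \item{fig1E}{isotropic growth for 5/6 of the run, then y-only
#'     anisotropic growth; same cumulative scale.}
#'   \item{fig1F}{fig1E reversed in time.}
#'   \item{fig1G/H/I}{as D/E/F with divisions enabled for the first 20% of
#'     steps.}
#'   \item{fig2P}{elongated-cell template; strong y-anisotropy first, then
#'     transverse-dominant near-isotropic growth.}
#'   \item{fig2Q}{fig2P reversed in time.}
#' }
#'
#' @param n_steps Growth steps (default 300).
#' @param n_cells Cells in the template.
#' @param cell_size Cell width in microns.
#' @param seed Template jitter seed.
#' @param subdivisions,jitter Passed to [make_template()].
#' @return Named list of `list(template, schedule, config)` bundles.
#' @export
preset_scenarios <- function(n_steps = 300L, n_cells = 64L, cell_size = 1,
                             seed = 0L, subdivisions = 4L, jitter = 0.3) {
  iso <- make_template("isodiametric_grid", n_cells = n_cells,
                       cell_size = cell_size, rng_seed = seed,
                       subdivisions = subdivisions, jitter = jitter)
  maize <- make_template("maize_elongated", n_cells = n_cells,
                         cell_size = cell_size, rng_seed = seed,
                         subdivisions = subdivisions, jitter = jitter,
                         aspect = 3)
  s1D <- schedule_from_scales(n_steps, rbind(c(0, 1), c(1, 10)),
                              rbind(c(0, 1), c(1, 16)))
  s1E <- schedule_from_scales(n_steps,
                              rbind(c(0, 1), c(5 / 6, 10), c(1, 10)),
                              rbind(c(0, 1), c(5 / 6, 10), c(1, 16)))
  s1F <- reverse_schedule(s1E)
  s2P <- schedule_from_scales(n_steps,
                              rbind(c(0, 1), c(0.6, 1.2), c(1, 4.8)),
                              rbind(c(0, 1), c(0.6, 3), c(1, 4.5)))
  s2Q <- reverse_schedule(s2P)
  cfg <- sim_config(rng_seed = seed)
  cfg_div <- sim_config(division = TRUE, f_div = 0.2, rng_seed = seed)
  list(fig1D = list(template = iso, schedule = s1D, config = cfg),
       fig1E = list(template = iso, schedule = s1E, config = cfg),
       fig1F = list(template = iso, schedule = s1F, config = cfg),
       fig1G = list(template = iso, schedule = s1D, config = cfg_div),
       fig1H = list(template = iso, schedule = s1E, config = cfg_div),
       fig1I = list(template = iso, schedule = s1F, config = cfg_div),
       fig2P = list(template = maize, schedule = s2P, config = cfg),
       fig2Q = list(template = maize, schedule = s2Q, config = cfg))
}
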