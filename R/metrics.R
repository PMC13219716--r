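#' Polygon area
#'
#' Shoelace area of a simple polygon, independent of starting vertex and
#' orientation. Units: square microns for contours in microns.
#'
#' @param c A [contour()] or a two-column vertex matrix.
#' @return Positive area.
#' @export
polygon_area <- function(c) {
  v <- contour_vertices(c)
  a <- abs(signed_area(v))
  if (a < 1e-12)
    stop_pavecell("degenerate_contour", "polygon has zero area (collinear vertices)")
  a
}

#' Polygon perimeter
#'
#' Sum of Euclidean edge lengths including the implicit closure edge.
#'
#' @inheritParams polygon_area
#' @return Perimeter in microns.
#' @export
polygon_perimeter <- function(c) poly_perimeter(contour_vertices(c))

contour_vertices <- function(c) {
  if (inherits(c, "contour")) c$vertices else as_vertex_matrix(c)
}

#' Lobeyness: perimeter over convex-hull perimeter
#'
#' The inverse measure of convexity used to score pavement-cell lobing:
#' the cell perimeter divided by the perimeter of its convex hull. Exactly 1
#' for convex outlines, larger for lobed ones; scale- and rotation-invariant.
#'
#' @inheritParams polygon_area
#' @return Dimensionless value >= 1.
#' @export
lobeyness <- function(c) {
  v <- contour_vertices(c)
  h <- hull_vertices(v)
  hp <- poly_perimeter(h)
  if (hp < 1e-12) stop_pavecell("degenerate_contour", "degenerate convex hull")
  max(1, poly_perimeter(v) / hp)
}

#' Min-axis: the smallest width that fits the cell
#'
#' Width of the smallest enclosing rectangle, i.e. the minimum over axis
#' orientations of the projection extent of the convex hull. Orientations
#' are densely sampled over half a turn (width is pi-periodic); an exact
#' mode evaluates the per-hull-edge closed form instead and is used for
#' cross-checking.
#'
#' @inheritParams polygon_area
#' @param n_angles Number of sampled orientations (>= 2; default 3600).
#' @param exact If `TRUE`, compute the exact minimal width over hull edge
#'   directions instead of sampling.
#' @return List with `width` (microns) and `direction` (unit 2-vector along
#'   which the extent is minimal).
#' @export
min_axis <- function(c, n_angles = 3600L, exact = FALSE) {
  v <- contour_vertices(c)
  h <- hull_vertices(v)
  if (exact) {
    n <- nrow(h)
    nx <- c(seq_len(n)[-1L], 1L)
    e <- h[nx, , drop = FALSE] - h
    len <- sqrt(rowSums(e^2))
    keep <- len > 1e-14
    best <- Inf; bdir <- c(1, 0)
    for (i in which(keep)) {
      nrm <- c(-e[i, 2L], e[i, 1L]) / len[i]
      pr <- h %*% nrm
      w <- max(pr) - min(pr)
      if (w < best - 1e-15) { best <- w; bdir <- nrm }
    }
    dir <- if (bdir[1L] < 0 || (bdir[1L] == 0 && bdir[2L] < 0)) -bdir else bdir
    return(list(width = best, direction = dir))
  }
  if (n_angles < 2L) stop_pavecell("parameter", "n_angles must be >= 2")
  th <- seq(0, pi, length.out = n_angles + 1L)[-(n_angles + 1L)]
  pr <- h %*% rbind(cos(th), sin(th))
  w <- apply(pr, 2L, max) - apply(pr, 2L, min)
  i <- which.min(w)  # smallest qualifying angle on ties (which.min is first)
  list(width = w[i], direction = c(cos(th[i]), sin(th[i])))
}

#' Largest empty circle (maximum inscribed circle)
#'
#' The largest circle that fits inside the cell outline, a geometric proxy
#' for the maximal unsupported wall span. Found by iterative grid refinement
#' (quadtree-style) over the signed distance to the boundary polyline:
#' candidate cells are subdivided best-first until no cell can beat the
#' incumbent by more than `tolerance`.
#'
#' @inheritParams polygon_area
#' @param tolerance Radius tolerance in microns; default 0.5% of the
#'   min-axis width.
#' @return List with `center` (2-vector) and `radius` (microns).
#' @export
largest_empty_circle <- function(c, tolerance = NULL) {
  v <- contour_vertices(c)
  if (is.null(tolerance))
    tolerance <- 0.005 * min_axis(v, n_angles = 720L)$width
  if (!is.numeric(tolerance) || tolerance <= 0)
    stop_pavecell("parameter", "tolerance must be > 0")
  bb_lo <- apply(v, 2L, min); bb_hi <- apply(v, 2L, max)
  span <- bb_hi - bb_lo
  h <- min(span) / 8
  if (h < tolerance) {
    warning("sliver polygon: LEC radius may be tolerance-limited")
    h <- max(h, tolerance / 4)
  }
  # seed grid
  gx <- seq(bb_lo[1L] + h / 2, bb_hi[1L], by = h)
  gy <- seq(bb_lo[2L] + h / 2, bb_hi[2L], by = h)
  cand <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  size <- rep(h, nrow(cand))
  d <- cpp_signed_dist(cand, v)
  # incumbent: also try the centroid
  ctr <- matrix(poly_centroid(v), 1L)
  dc <- cpp_signed_dist(ctr, v)
  best_r <- dc[1L]; best_c <- ctr[1L, ]
  i <- which.max(d)
  if (d[i] > best_r) { best_r <- d[i]; best_c <- cand[i, ] }
  half_diag <- sqrt(2) / 2
  repeat {
    pot <- d + size * half_diag
    keep <- pot > best_r + tolerance
    if (!any(keep)) break
    cand <- cand[keep, , drop = FALSE]
    size <- size[keep]
    # subdivide every surviving cell into 4
    h2 <- size / 2
    off <- h2 / 2
    nc <- rbind(cbind(cand[, 1L] - off, cand[, 2L] - off),
                cbind(cand[, 1L] + off, cand[, 2L] - off),
                cbind(cand[, 1L] - off, cand[, 2L] + off),
                cbind(cand[, 1L] + off, cand[, 2L] + off))
    size <- rep(h2, 4L)
    cand <- nc
    d <- cpp_signed_dist(cand, v)
    i <- which.max(d)
    if (d[i] > best_r + 1e-15 ||
        (abs(d[i] - best_r) <= 1e-15 &&
         (cand[i, 1L] < best_c[1L] ||
          (cand[i, 1L] == best_c[1L] && cand[i, 2L] < best_c[2L])))) {
      best_r <- d[i]; best_c <- cand[i, ]
    }
  }
  list(center = best_c, radius = best_r)
}

#' Directional lobe bias
#'
#' Ratio of the excess boundary excursion in y over that in x:
#' `B = Ey / Ex` where `Ey` is the total `|dy|` over contour edges minus the
#' total `|dy|` over convex-hull edges, and `Ex` analogously. `B > 1`
#' indicates lobes protruding predominantly vertically; `B < 1`
#' horizontally. Convex outlines have no excess excursion and return
#' `NA` (flagged neutral).
#'
#' @inheritParams polygon_area
#' @return Positive ratio, or `NA_real_` for (numerically) convex input.
#' @export
directional_lobe_bias <- function(c) {
  v <- contour_vertices(c)
  h <- hull_vertices(v)
  edge_abs <- function(m) {
    d <- m[c(seq_len(nrow(m))[-1L], 1L), , drop = FALSE] - m
    c(sum(abs(d[, 1L])), sum(abs(d[, 2L])))
  }
  ec <- edge_abs(v); eh <- edge_abs(h)
  ex <- ec[1L] - eh[1L]; ey <- ec[2L] - eh[2L]
  floor_ <- 1e-9 * poly_perimeter(v)
  if (ex < floor_ && ey < floor_) return(NA_real_)
  ey / ex
}

#' All shape descriptors for one contour
#'
#' @inheritParams polygon_area
#' @param n_angles Orientation samples for [min_axis()].
#' @param lec_tolerance Tolerance for [largest_empty_circle()] (default 0.5%
#'   of min-axis).
#' @return Named list: `area`, `perimeter`, `hull_perimeter`, `lobeyness`,
#'   `min_axis`, `lec_radius`, `lec_center`, `lec_area`, `lec_diameter`,
#'   `lobe_bias`.
#' @export
shape_metrics <- function(c, n_angles = 3600L, lec_tolerance = NULL) {
  v <- contour_vertices(c)
  h <- hull_vertices(v)
  per <- poly_perimeter(v)
  hper <- poly_perimeter(h)
  ma <- min_axis(v, n_angles = n_angles)
  lec <- largest_empty_circle(v, tolerance = lec_tolerance)
  list(area = polygon_area(v), perimeter = per, hull_perimeter = hper,
       lobeyness = max(1, per / hper), min_axis = ma$width,
       min_axis_direction = ma$direction,
       lec_radius = lec$radius, lec_center = lec$center,
       lec_area = pi * lec$radius^2, lec_diameter = 2 * lec$radius,
       lobe_bias = directional_lobe_bias(v))
}

#' Per-cell metric table for a contour set
#'
#' One row per contour with all shape descriptors plus group labels, in
#' deterministic order (by clade, species, organ, sample, then label).
#' Contours whose metrics fail are kept as flagged rows (`ok = FALSE`) with
#' the failure reason; the pipeline never drops cells silently.
#'
#' @param cs A `contour_set`.
#' @param n_angles,lec_tolerance Passed to [shape_metrics()].
#' @param path Optional CSV output path.
#' @return Data frame with columns clade, species, organ, sample, label,
#'   area_um2, perimeter_um, hull_perimeter_um, lobeyness, min_axis_um,
#'   lec_radius_um, lec_x, lec_y, lobe_bias, ok, note.
#' @export
metrics_table <- function(cs, n_angles = 3600L, lec_tolerance = NULL,
                          path = NULL) {
  stopifnot(inherits(cs, "contour_set"))
  empty <- data.frame(clade = character(), species = character(),
                      organ = character(), sample = character(),
                      label = integer(), area_um2 = numeric(),
                      perimeter_um = numeric(), hull_perimeter_um = numeric(),
                      lobeyness = numeric(), min_axis_um = numeric(),
                      lec_radius_um = numeric(), lec_x = numeric(),
                      lec_y = numeric(), lobe_bias = numeric(),
                      ok = logical(), note = character())
  if (!length(cs$contours)) {
    if (!is.null(path)) write.csv(empty, path, row.names = FALSE)
    return(empty)
  }
  rows <- lapply(cs$contours, function(ct) {
    m <- tryCatch(shape_metrics(ct, n_angles = n_angles,
                                lec_tolerance = lec_tolerance),
                  error = function(e) e)
    g <- ct$group
    if (inherits(m, "error"))
      data.frame(clade = g[["clade"]], species = g[["species"]],
                 organ = g[["organ"]], sample = g[["sample"]],
                 label = ct$label, area_um2 = NA_real_,
                 perimeter_um = NA_real_, hull_perimeter_um = NA_real_,
                 lobeyness = NA_real_, min_axis_um = NA_real_,
                 lec_radius_um = NA_real_, lec_x = NA_real_, lec_y = NA_real_,
                 lobe_bias = NA_real_, ok = FALSE,
                 note = conditionMessage(m))
    else
      data.frame(clade = g[["clade"]], species = g[["species"]],
                 organ = g[["organ"]], sample = g[["sample"]],
                 label = ct$label, area_um2 = m$area,
                 perimeter_um = m$perimeter,
                 hull_perimeter_um = m$hull_perimeter,
                 lobeyness = m$lobeyness, min_axis_um = m$min_axis,
                 lec_radius_um = m$lec_radius, lec_x = m$lec_center[1L],
                 lec_y = m$lec_center[2L], lobe_bias = m$lobe_bias,
                 ok = TRUE, note = "")
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$clade, df$species, df$organ, df$sample, df$label), ]
  rownames(df) <- NULL
  if (any(!df$ok))
    message(sum(!df$ok), " contour(s) failed metric computation (flagged rows)")
  if (!is.null(path)) write.csv(df, path, row.names = FALSE)
  df
}
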