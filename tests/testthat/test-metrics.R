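test_that("polygon area matches closed forms and a Monte-Carlo oracle", {
  expect_equal(polygon_area(contour(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))), 1)
  expect_equal(polygon_area(contour(rbind(c(0, 0), c(2, 0), c(0, 2)))), 2)
  expect_error(polygon_area(rbind(c(0, 0), c(1, 1), c(2, 2))),
               class = "pavecell_degenerate_contour")

  # area is independent of starting vertex and orientation
  v <- random_star(11, n_points = 12)
  a0 <- polygon_area(contour(v))
  expect_equal(polygon_area(contour(v[c(5:12, 1:4), ])), a0)
  expect_equal(polygon_area(contour(v[rev(seq_len(12)), ])), a0)

  # Monte-Carlo point-in-polygon oracle on a random simple 12-gon
  set.seed(42)
  bb <- apply(v, 2, range)
  n_mc <- 1e6
  px <- runif(n_mc, bb[1, 1], bb[2, 1]); py <- runif(n_mc, bb[1, 2], bb[2, 2])
  inside <- pavecell:::cpp_point_in_poly(cbind(px, py), v)
  mc <- mean(inside) * diff(bb[, 1]) * diff(bb[, 2])
  expect_equal(a0, mc, tolerance = 0.01)
})

test_that("lobeyness is 1 for convex shapes and matches closed forms", {
  hexagon <- contour(cbind(cos(2 * pi * 0:5 / 6), sin(2 * pi * 0:5 / 6)))
  expect_equal(lobeyness(hexagon), 1)

  plus <- contour(rbind(c(1, 0), c(2, 0), c(2, 1), c(3, 1), c(3, 2), c(2, 2),
                        c(2, 3), c(1, 3), c(1, 2), c(0, 2), c(0, 1), c(1, 1)))
  expect_equal(lobeyness(plus), 12 / (4 + 4 * sqrt(2)), tolerance = 1e-12)

  # star r = 1 + 0.3 cos(6 theta), 720 points, vs the gift-wrapping oracle
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  star <- cbind((1 + 0.3 * cos(6 * th)) * cos(th),
                (1 + 0.3 * cos(6 * th)) * sin(th))
  expect_equal(lobeyness(contour(star)), oracle_lobeyness(star),
               tolerance = 1e-9)
})

test_that("min-axis matches rectangles, circles, and the exact-width oracle", {
  rect <- rbind(c(0, 0), c(5, 0), c(5, 2), c(0, 2))
  ma <- min_axis(contour(rect))
  expect_equal(ma$width, 2, tolerance = 1e-5)
  expect_equal(abs(ma$direction), c(0, 1), tolerance = 1e-3)

  th <- seq(0, 2 * pi, length.out = 257)[-257]
  circle <- contour(cbind(3 * cos(th), 3 * sin(th)))
  expect_equal(min_axis(circle)$width, 6, tolerance = 6e-3)

  rot <- rigid_motion(rect, 30 * pi / 180, c(0, 0))
  expect_equal(min_axis(contour(rot))$width, oracle_min_width(rot),
               tolerance = 1e-5)
  expect_equal(min_axis(contour(rot), exact = TRUE)$width, 2, tolerance = 1e-12)
  expect_error(min_axis(contour(rect), n_angles = 1), class = "pavecell_parameter")
})

test_that("largest empty circle matches inscribed-circle geometry and a grid oracle", {
  sq <- contour(rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2)))
  lec <- largest_empty_circle(sq, tolerance = 1e-3)
  expect_equal(lec$radius, 1, tolerance = 2e-3)
  expect_equal(lec$center, c(1, 1), tolerance = 5e-2, ignore_attr = TRUE)

  # 2x6 rectangle: radius 1, centre anywhere on the medial segment
  rect <- contour(rbind(c(0, 0), c(6, 0), c(6, 2), c(0, 2)))
  lec <- largest_empty_circle(rect, tolerance = 1e-3)
  expect_equal(lec$radius, 1, tolerance = 2e-3)
  expect_equal(lec$center[2], 1, tolerance = 5e-2)
  expect_gte(lec$center[1], 0.9); expect_lte(lec$center[1], 5.1)

  # L-shaped hexomino outline vs a 4x-finer dense grid oracle
  L <- rbind(c(0, 0), c(3, 0), c(3, 1), c(1, 1), c(1, 2), c(0, 2))
  tol <- 0.01
  lec <- largest_empty_circle(contour(L), tolerance = tol)
  expect_equal(lec$radius, oracle_lec_radius(L, tol / 4), tolerance = 2 * tol)

  expect_error(largest_empty_circle(sq, tolerance = -1),
               class = "pavecell_parameter")
})

test_that("directional lobe bias flags convex cells and resolves comb teeth", {
  sq <- contour(rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2)))
  expect_true(is.na(directional_lobe_bias(sq)))

  xs <- c(0, 10, 10, 9, 9, 8, 8, 7, 7, 6, 6, 5, 5, 4, 4, 3, 3, 2, 2, 1, 1, 0)
  ys <- c(0, 0, 3, 3, 1, 1, 3, 3, 1, 1, 3, 3, 1, 1, 3, 3, 1, 1, 3, 3, 1, 1)
  comb <- contour(cbind(xs, ys))
  b <- directional_lobe_bias(comb)
  expect_gt(b, 1)

  rot <- contour(rigid_motion(comb$vertices, pi / 2, c(0, 0)))
  b_rot <- directional_lobe_bias(rot)
  expect_lt(b_rot, 1)
  expect_equal(b_rot, 1 / b, tolerance = 1e-9)
})

test_that("metric tables compose per-contour calls and keep failures visible", {
  mk <- function(lab, shift) contour(rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2)) + shift,
                                     label = lab, species = "sp")
  cs <- contour_set(list(mk(1, 0), mk(2, 5), mk(3, 10)))
  tab <- metrics_table(cs, n_angles = 360L)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$lobeyness, rep(1, 3))
  expect_true(all(tab$ok))

  star <- contour(random_star(2), label = 9, species = "sp")
  cs2 <- contour_set(list(mk(1, 0), star))
  tab2 <- metrics_table(cs2, n_angles = 720L)
  expect_equal(tab2$lobeyness[tab2$label == 9],
               lobeyness(star), tolerance = 1e-12)

  empty <- metrics_table(contour_set(list()))
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("lobeyness", "min_axis_um", "lec_radius_um") %in% names(empty)))
})

test_that("scalar metrics are rigid-motion invariant and scale correctly", {
  for (seed in 1:6) {
    v <- random_star(seed)
    ct <- contour(v)
    m <- shape_metrics(ct, n_angles = 720L, lec_tolerance = 1e-3)
    mv <- shape_metrics(contour(rigid_motion(v, 1.1 * seed, c(7, -3))),
                        n_angles = 720L, lec_tolerance = 1e-3)
    expect_equal(mv$area, m$area, tolerance = 1e-9)
    expect_equal(mv$perimeter, m$perimeter, tolerance = 1e-9)
    expect_equal(mv$lobeyness, m$lobeyness, tolerance = 1e-9)
    # angle-sampled width is invariant to within the sampling resolution;
    # the exact edge-support mode is invariant to rounding error
    expect_equal(mv$min_axis, m$min_axis, tolerance = 2e-3)
    expect_equal(min_axis(rigid_motion(v, 1.1 * seed, c(7, -3)), exact = TRUE)$width,
                 min_axis(v, exact = TRUE)$width, tolerance = 1e-9)
    expect_equal(mv$lec_radius, m$lec_radius, tolerance = 5e-3)

    s <- 3.7
    ms <- shape_metrics(contour(v * s), n_angles = 720L, lec_tolerance = 1e-3)
    expect_equal(ms$area, s^2 * m$area, tolerance = 1e-9)
    expect_equal(ms$perimeter, s * m$perimeter, tolerance = 1e-9)
    expect_equal(ms$min_axis, s * m$min_axis, tolerance = 1e-6)
    expect_equal(ms$lec_radius, s * m$lec_radius, tolerance = 2e-2)

    # bound chain on every generated shape
    expect_lte(2 * m$lec_radius, m$min_axis + 1e-6)
  }
})

test_that("lobeyness is monotone in the lobe amplitude", {
  for (k in c(3L, 6L)) {
    amps <- seq(0, 0.5 - 1e-6, by = 0.05)
    lob <- vapply(amps, function(a)
      lobeyness(make_lobed_contour(10, a, k, n_points = 256)), numeric(1))
    expect_true(all(diff(lob) > -1e-12))
  }
})
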