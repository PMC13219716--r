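make_two_spring_mesh <- function(x_mid, rest1, rest2) {
  # fixed ends at 0 and 3 on the x axis, one free middle vertex
  structure(list(
    pos = rbind(c(0, 0), c(x_mid, 0), c(3, 0)),
    boundary = c(TRUE, FALSE, TRUE),
    walls = cbind(a = 1, b = 2, rest = rest1),
    conns = cbind(a = 2, b = 3, rest = rest2, cell = 1),
    cells = list(), center = c(1.5, 0), cell_size = 1, ell0 = 1),
    class = "cell_mesh")
}

test_that("templates are deterministic grids with balanced cell areas", {
  tm <- make_template("isodiametric_grid", n_cells = 16, cell_size = 1,
                      rng_seed = 3)
  expect_equal(length(tm$cells), 16L)
  areas <- vapply(seq_along(tm$cells), function(i)
    abs(pavecell:::signed_area(tm$pos[tm$cells[[i]], ])), numeric(1))
  expect_lt((max(areas) - min(areas)) / mean(areas), 0.2)
  expect_equal(sum(areas), 16, tolerance = 1e-9)  # cells tile the template

  tm2 <- make_template("isodiametric_grid", n_cells = 16, cell_size = 1,
                       rng_seed = 3)
  expect_identical(tm$pos, tm2$pos)

  one <- make_template("isodiametric_grid", n_cells = 1)
  expect_equal(length(one$cells), 1L)
  expect_true(all(one$boundary))

  mz <- make_template("maize_elongated", n_cells = 4, aspect = 5)
  bb <- apply(mz$pos[mz$cells[[1]], ], 2, function(z) diff(range(z)))
  expect_gt(bb[2] / bb[1], 3)

  expect_error(make_template(cell_size = 0), class = "pavecell_parameter")
})

test_that("boundary growth scales the rim and leaves the interior alone", {
  tm <- make_template("isodiametric_grid", n_cells = 4, rng_seed = 1)
  same <- apply_boundary_growth(tm, 0, 0)
  expect_equal(same$pos, tm$pos)

  g <- apply_boundary_growth(tm, 0.1, 0)
  rim0 <- tm$pos[tm$boundary, ]; rim1 <- g$pos[g$boundary, ]
  expect_equal(diff(range(rim1[, 1])), 1.1 * diff(range(rim0[, 1])))
  expect_equal(diff(range(rim1[, 2])), diff(range(rim0[, 2])))
  expect_equal(g$pos[!g$boundary, ], tm$pos[!tm$boundary, ])

  # compounding per-step factors reaches the cumulative scale exactly
  sc <- schedule_from_scales(300, rbind(c(0, 1), c(1, 10)),
                             rbind(c(0, 1), c(1, 16)))
  m <- tm
  for (k in 1:300)
    m <- apply_boundary_growth(m, sc$factors[k, 1] - 1, sc$factors[k, 2] - 1)
  expect_equal(diff(range(m$pos[m$boundary, 1])),
               10 * diff(range(rim0[, 1])), tolerance = 1e-9)
  expect_equal(diff(range(m$pos[m$boundary, 2])),
               16 * diff(range(rim0[, 2])), tolerance = 1e-9)
})

test_that("relaxation solves spring equilibria", {
  # all springs at rest: zero iterations, unchanged
  tm <- make_template("isodiametric_grid", n_cells = 4, rng_seed = 1)
  r <- relax(tm, sim_config())
  expect_equal(attr(r, "iterations"), 0L)
  expect_equal(r$pos, tm$pos)

  # symmetric two-spring chain: middle vertex at the midpoint
  cfg_eq <- sim_config(k_wall = 1, k_conn = 1, relax_tolerance = 1e-9,
                       max_relax_iters = 20000L)
  m <- relax(make_two_spring_mesh(0.7, 1, 1), cfg_eq)
  expect_equal(m$pos[2, 1], 1.5, tolerance = 1e-6)

  # 2:1 stiffness ratio, rest lengths 1 and 1, ends at 0 and 3:
  # k1 (x - 1) = k2 (3 - x - 1)  =>  x = 4/3
  cfg_21 <- sim_config(k_wall = 2, k_conn = 1, relax_tolerance = 1e-9,
                       max_relax_iters = 20000L)
  m2 <- relax(make_two_spring_mesh(1.1, 1, 1), cfg_21)
  expect_equal(m2$pos[2, 1], 4 / 3, tolerance = 1e-6)
})

test_that("connection placement honours the geometric admissibility rules", {
  # convex cell: nothing concave, so the concavity rule admits no chords
  th <- seq(0, 2 * pi, length.out = 25)[-25]
  cyc_pos <- cbind(cos(th), sin(th))
  mesh <- structure(list(pos = cyc_pos, boundary = rep(FALSE, 24),
                         walls = cbind(a = 1:24, b = c(2:24, 1), rest = 1),
                         conns = matrix(numeric(0), 0, 4,
                                        dimnames = list(NULL, c("a", "b", "rest", "cell"))),
                         cells = list(1:24), center = c(0, 0),
                         cell_size = 2, ell0 = 0.3),
                    class = "cell_mesh")
  m1 <- place_connections(mesh, sim_config(require_concave = TRUE,
                                           conn_len_factor = 1.2))
  expect_equal(nrow(m1$conns), 0L)
  # with the concavity rule waived, near-normal chords are admitted
  m2 <- place_connections(mesh, sim_config(require_concave = FALSE,
                                           conn_len_factor = 1.2))
  expect_gt(nrow(m2$conns), 0L)

  # dumbbell: two lobes joined by a neck; connections concentrate at the neck
  th <- seq(0, 2 * pi, length.out = 81)[-81]
  x <- 2 * cos(th)
  y <- sin(th) * (0.3 + 0.9 * cos(th)^2)
  cyc_pos <- cbind(x, y)
  n <- nrow(cyc_pos)
  mesh2 <- structure(list(pos = cyc_pos, boundary = rep(FALSE, n),
                          walls = cbind(a = 1:n, b = c(2:n, 1), rest = 1),
                          conns = matrix(numeric(0), 0, 4,
                                         dimnames = list(NULL, c("a", "b", "rest", "cell"))),
                          cells = list(1:n), center = c(0, 0),
                          cell_size = 1, ell0 = 0.2),
                     class = "cell_mesh")
  m3 <- place_connections(mesh2, sim_config(conn_len_factor = 0.8))
  expect_gt(nrow(m3$conns), 0L)
  mid <- (mesh2$pos[m3$conns[, "a"], 1] + mesh2$pos[m3$conns[, "b"], 1]) / 2
  in_neck <- mean(abs(mid) < 2 / 3)
  expect_gt(in_neck, 0.5)  # majority of chords span the central indentation
  # every admitted chord stays inside the cell (midpoint interior)
  my <- (mesh2$pos[m3$conns[, "a"], 2] + mesh2$pos[m3$conns[, "b"], 2]) / 2
  expect_true(all(pavecell:::cpp_point_in_poly(cbind(mid, my), cyc_pos)))
})

test_that("cell division follows the shortest centroid chord during the phase", {
  # one 2x1 rectangular cell, subdivided rim
  tm <- make_template("maize_elongated", n_cells = 1, cell_size = 1,
                      aspect = 2, subdivisions = 8L, jitter = 0)
  cfg <- sim_config(division = TRUE, f_div = 0.2, area_threshold = 1.5)
  # past the division phase: unchanged
  same <- divide_cells(tm, t = 0.5, cfg)
  expect_equal(length(same$cells), 1L)
  # below the area threshold: unchanged
  cfg_big <- sim_config(division = TRUE, f_div = 0.2, area_threshold = 10)
  expect_equal(length(divide_cells(tm, 0.1, cfg_big)$cells), 1L)

  d <- divide_cells(tm, t = 0.1, cfg)
  expect_equal(length(d$cells), 2L)
  a <- vapply(seq_along(d$cells), function(i)
    abs(pavecell:::signed_area(d$pos[d$cells[[i]], ])), numeric(1))
  expect_equal(sum(a), 2, tolerance = 1e-9)
  expect_equal(a[1], a[2], tolerance = 0.05)
  # the new wall is perpendicular to the long (y) axis
  for (i in 1:2) {
    bb <- apply(d$pos[d$cells[[i]], ], 2, function(z) diff(range(z)))
    expect_equal(bb[1], 1, tolerance = 1e-6)
    expect_equal(bb[2], 1, tolerance = 0.05)
  }
})

test_that("simulations are reproducible, tile the rim, and stay simple", {
  tm <- make_template("isodiametric_grid", n_cells = 9, rng_seed = 2)
  zero <- growth_schedule(5, function(t) rep(0, length(t)))
  r0 <- run_simulation(tm, zero, compute_metrics = FALSE)
  expect_equal(r0$final$pos[seq_len(nrow(tm$pos)), ], tm$pos)

  sc <- schedule_from_scales(40, rbind(c(0, 1), c(1, 3)))
  ra <- suppressWarnings(run_simulation(tm, sc, sim_config(), compute_metrics = FALSE))
  rb <- suppressWarnings(run_simulation(tm, sc, sim_config(), compute_metrics = FALSE))
  expect_identical(ra$final$pos, rb$final$pos)   # bit-identical trajectories
  expect_identical(ra$final$conns, rb$final$conns)

  # geometry safety: simple cells, total area equals rim area within 1%
  areas <- vapply(seq_along(ra$final$cells), function(i) {
    poly <- ra$final$pos[ra$final$cells[[i]], ]
    expect_true(oracle_is_simple(poly))
    abs(pavecell:::signed_area(poly))
  }, numeric(1))
  rim_area <- 9 * 9  # 3x3 template scaled 3x in each axis
  expect_equal(sum(areas), rim_area, tolerance = 0.01 * rim_area)
})

test_that("connections are the lobe-forming ingredient", {
  tm <- make_template("isodiametric_grid", n_cells = 9, rng_seed = 4)
  sc <- schedule_from_scales(50, rbind(c(0, 1), c(1, 3.5)))
  off <- run_simulation(tm, sc, sim_config(), connections = FALSE)
  expect_lt(mean(off$metrics$lobeyness[off$metrics$ok]), 1.02)
  on <- run_simulation(tm, sc, sim_config())
  expect_gt(mean(on$metrics$lobeyness[on$metrics$ok]),
            mean(off$metrics$lobeyness[off$metrics$ok]))
})
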