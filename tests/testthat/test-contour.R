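test_that("contour files parse, normalise orientation, and round-trip", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 0", "1 0", "1 1", "0 1"), f)
  ct <- read_contour_file(f)
  expect_equal(nrow(ct$vertices), 4L)
  expect_equal(polygon_area(ct), 1)

  # clockwise input is re-oriented CCW (positive signed area)
  writeLines(c("0 0", "0 1", "1 1", "1 0"), f)
  cw <- read_contour_file(f)
  expect_gt(pavecell:::signed_area(cw$vertices), 0)
  expect_equal(abs(pavecell:::signed_area(cw$vertices)), 1)

  # comma separation and comments are accepted
  writeLines(c("# a header", "0, 0", "2, 0", "2, 2", "0, 2"), f)
  expect_equal(polygon_area(read_contour_file(f)), 4)

  # full-precision round-trip
  set.seed(7)
  v <- cbind(rnorm(40, sd = 13.7), rnorm(40, sd = 13.7))
  ct <- contour(v[chull(v)[rev(seq_along(chull(v)))], , drop = FALSE])
  write_contour_file(ct, f)
  expect_identical(read_contour_file(f)$vertices, ct$vertices)
})

test_that("malformed contour files raise named errors", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 0", "1 1"), f)
  expect_error(read_contour_file(f), class = "pavecell_malformed_contour")
  writeLines(c("0 0", "1 0", "x y", "0 1"), f)
  expect_error(read_contour_file(f), regexp = "line 3",
               class = "pavecell_parse")
  writeLines(c("0 0", "1 0", "1 1", "", "5 5", "6 5", "6 6"), f)
  expect_error(read_contour_file(f), class = "pavecell_multipiece")
  expect_error(contour(rbind(c(0, 0), c(1, 1))),
               class = "pavecell_malformed_contour")
})

test_that("labeled trees load with path-derived groups and round-trip", {
  root <- withr::local_tempdir()
  tri <- rbind(c(0, 0), c(4, 0), c(2, 3))
  sq <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2))
  for (p in c("cladeA/sp1/leaf/s1.txt", "cladeA/sp1/leaf/s2.txt",
              "cladeA/sp1/leaf/s3.txt", "cladeB/sp2/leaf/s1.txt")) {
    dir.create(file.path(root, dirname(p)), recursive = TRUE, showWarnings = FALSE)
    writeLines(apply(if (grepl("sp1", p)) tri else sq, 1L, paste, collapse = " "),
               file.path(root, p))
  }
  cs <- load_labeled_tree(root)
  expect_equal(length(cs), 4L)
  expect_length(set_groups(cs, "clade"), 2L)
  expect_length(set_groups(cs, "species"), 2L)
  expect_equal(sort(lengths(set_groups(cs, "species")), decreasing = TRUE),
               c(3L, 1L), ignore_attr = TRUE)

  # files outside the 4-level hierarchy are skipped with a message
  writeLines(c("0 0", "1 0", "0 1"), file.path(root, "stray.txt"))
  expect_message(cs2 <- load_labeled_tree(root), "skipping")
  expect_equal(length(cs2), 4L)

  # save -> load round-trip preserves vertices and groups
  root2 <- withr::local_tempdir()
  save_labeled_tree(cs, file.path(root2, "tree"))
  back <- load_labeled_tree(file.path(root2, "tree"))
  expect_equal(length(back), length(cs))
  key <- function(s) vapply(s$contours, function(ct) paste(ct$group, collapse = "/"),
                            character(1))
  o1 <- order(key(cs)); o2 <- order(key(back))
  for (i in seq_along(o1))
    expect_equal(back$contours[[o2[i]]]$vertices, cs$contours[[o1[i]]]$vertices)
  expect_equal(sort(key(cs)), sort(key(back)))

  # empty tree warns
  expect_warning(load_labeled_tree(withr::local_tempdir()), "empty")

  meta <- contour_metadata(cs)
  expect_named(meta, c("label", "clade", "species", "organ", "sample", "n_vertices"))
  expect_equal(nrow(meta), 4L)
})

test_that("neighbourhood smoothing matches the closed-form cases", {
  sq <- contour(rbind(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1)))
  sm <- smooth_contour(sq)
  expect_true(all(abs(abs(sm$vertices) - 1 / 3) < 1e-12))

  # one pass on a triangle maps all vertices to the centroid
  tri <- contour(rbind(c(0, 0), c(3, 0), c(0, 3)))
  expect_warning(expect_error(smooth_contour(tri),
                              class = "pavecell_degenerate_contour"),
                 "centroid")

  # a regular 64-gon shrinks by the circulant-averaging factor
  # (1 + 2 cos(2*pi/64)) / 3 and stays similar in shape
  th <- seq(0, 2 * pi, length.out = 65)[-65]
  poly <- contour(cbind(5 * cos(th), 5 * sin(th)))
  sm <- smooth_contour(poly)
  rad <- sqrt(rowSums(sm$vertices^2))
  expect_equal(rad, rep(5 * (1 + 2 * cos(2 * pi / 64)) / 3, 64), tolerance = 1e-12)
})

test_that("smoothing commutes with rigid motions", {
  for (seed in 1:5) {
    v <- random_star(seed)
    theta <- 0.3 + seed; shift <- c(seed, -2 * seed)
    a <- smooth_contour(contour(rigid_motion(v, theta, shift)))$vertices
    b <- rigid_motion(smooth_contour(contour(v))$vertices, theta, shift)
    expect_equal(a, b, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("repair recovers simple polygons and leaves simple input alone", {
  bow <- contour(rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2)), check = FALSE)
  fixed <- repair_contour(bow)
  expect_true(oracle_is_simple(fixed$vertices))

  ok <- contour(random_star(3))
  expect_equal(repair_contour(ok)$vertices, ok$vertices)

  # noisy stars with a locally swapped vertex pair are repairable,
  # and the result always passes the brute-force simplicity check
  for (seed in 1:6) {
    v <- random_star(seed, n_points = 60)
    i <- 10 + seed
    v[c(i, i + 1), ] <- v[c(i + 1, i), ]
    if (oracle_is_simple(v)) next
    out <- repair_contour(contour(v, check = FALSE))
    expect_true(oracle_is_simple(out$vertices))
  }
})

test_that("rotation to the min-axis aligns width with x and preserves metrics", {
  rect <- rbind(c(0, 0), c(5, 0), c(5, 2), c(0, 2))
  rot <- contour(rigid_motion(rect, 37 * pi / 180, c(3, -1)))
  aligned <- rotate_to_min_axis(rot)
  bb <- apply(aligned$vertices, 2, function(z) diff(range(z)))
  expect_equal(bb, c(2, 5), tolerance = 1e-4, ignore_attr = TRUE)

  # input with the min-axis already on x is unchanged up to tolerance
  ax <- contour(rbind(c(0, 0), c(2, 0), c(2, 5), c(0, 5)))
  expect_equal(rotate_to_min_axis(ax)$vertices, ax$vertices, tolerance = 1e-4)

  # scalar metrics are rotation-invariant
  for (seed in 1:4) {
    ct <- contour(random_star(seed))
    r <- rotate_to_min_axis(ct)
    expect_equal(polygon_area(r), polygon_area(ct), tolerance = 1e-9)
    expect_equal(polygon_perimeter(r), polygon_perimeter(ct), tolerance = 1e-9)
    expect_equal(lobeyness(r), lobeyness(ct), tolerance = 1e-9)
  }
})
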