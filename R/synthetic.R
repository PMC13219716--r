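# Synthetic contour generators: parametric lobed ("star") cells, species
# populations with a controllable min-axis--lobeyness coupling, an on-disk
# survey fixture, and degenerate contours for the error paths. These emulate
# the statistical structure of a cross-species pavement-cell survey; they do
# not imitate real taxa.

#' Parametric lobed contour
#'
#' Samples the star polygon `r(theta) = R * (1 + a*cos(k*theta))`, scales x
#' by `aspect` and rotates by `angle`. Simple by construction for
#' `0 <= a < 0.5`; `a = 0` gives an ellipse (a circle when `aspect = 1`).
#' Optional Gaussian vertex jitter (`noise_sd`) is seeded for
#' reproducibility.
#'
#' @param R Base radius in microns; the unscaled cell half-width.
#' @param a Lobe amplitude in \[0, 0.5).
#' @param k Lobe count (integer >= 0).
#' @param aspect Anisotropic x stretch (>= 1).
#' @param angle Rigid rotation in radians.
#' @param n_points Number of boundary samples (>= 32).
#' @param noise_sd Radial jitter standard deviation (microns; default 0).
#' @param rng_seed Seed used when `noise_sd > 0`.
#' @param ... Labels passed to [contour()].
#' @return A [contour()].
#' @export
make_lobed_contour <- function(R, a = 0, k = 6L, aspect = 1, angle = 0,
                               n_points = 128L, noise_sd = 0, rng_seed = 0L,
                               ...) {
  if (a < 0 || a >= 0.5) stop_pavecell("parameter", "need 0 <= a < 0.5")
  if (k < 0) stop_pavecell("parameter", "need k >= 0")
  if (n_points < 32L) stop_pavecell("parameter", "need n_points >= 32")
  if (aspect < 1) stop_pavecell("parameter", "need aspect >= 1")
  th <- seq(0, 2 * pi, length.out = n_points + 1L)[-(n_points + 1L)]
  r <- R * (1 + a * cos(k * th))
  if (noise_sd > 0) {
    r <- r + with_seed(rng_seed, rnorm(n_points, sd = noise_sd))
    r <- pmax(r, 0.05 * R)
  }
  v <- cbind(aspect * r * cos(th), r * sin(th))
  contour(rotate_points(v, angle), ...)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Specification of a synthetic species population
#'
#' Defines the statistical structure of one species' cells: width
#' (min-axis) log-uniform over `w_range`, aspect ratio uniform over
#' `aspect_range`, lobe amplitude following the law
#' `a(w) = a0 + s*(w - w0) + N(0, sigma_a)` clipped to `[0, a_max]`, fixed
#' lobe count `k`, and uniform lobe orientation. A positive slope `s` with
#' small `sigma_a` couples cell width to lobing (min-axis vs lobeyness
#' correlation at or above 0.3); `s = 0` with large `sigma_a` decouples
#' them.
#'
#' @param n_cells Number of cells.
#' @param w_range Width (min-axis) range in microns, spanning about 1.5
#'   orders of magnitude by default.
#' @param aspect_range Aspect-ratio range.
#' @param a0 Baseline amplitude at reference width `w0`.
#' @param s Amplitude-vs-width slope (per micron).
#' @param w0 Reference width (default geometric mean of `w_range`).
#' @param sigma_a Amplitude noise SD.
#' @param a_max Amplitude clip (< 0.5).
#' @param k Lobe count.
#' @param n_points Boundary samples per cell.
#' @param rng_seed Seed.
#' @return An object of class `species_spec` (validated list).
#' @export
species_spec <- function(n_cells = 200L, w_range = c(10, 300),
                         aspect_range = c(1, 2), a0 = 0.05, s = 0.001,
                         w0 = NULL, sigma_a = 0.02, a_max = 0.45, k = 6L,
                         n_points = 128L, rng_seed = 0L) {
  stopifnot(n_cells >= 1, all(w_range > 0), a_max < 0.5, a_max >= 0,
            sigma_a >= 0, k >= 0)
  if (is.null(w0)) w0 <- sqrt(prod(w_range))
  structure(list(n_cells = as.integer(n_cells), w_range = w_range,
                 aspect_range = aspect_range, a0 = a0, s = s, w0 = w0,
                 sigma_a = sigma_a, a_max = a_max, k = as.integer(k),
                 n_points = as.integer(n_points),
                 rng_seed = as.integer(rng_seed)),
            class = "species_spec")
}

#' Generate a synthetic species population
#'
#' @param spec A [species_spec()].
#' @param clade,species Group labels attached to every cell.
#' @return List with `contours` (a `contour_set`) and `truth` (data frame of
#'   the generating width, amplitude, aspect and lobe count per cell).
#' @export
make_species <- function(spec, clade = "cladeA", species = "speciesA") {
  stopifnot(inherits(spec, "species_spec"))
  with_seed(spec$rng_seed, {
    n <- spec$n_cells
    w <- exp(runif(n, log(spec$w_range[1L]), log(spec$w_range[2L])))
    aspect <- runif(n, spec$aspect_range[1L], spec$aspect_range[2L])
    a <- spec$a0 + spec$s * (w - spec$w0) + rnorm(n, sd = spec$sigma_a)
    a <- pmin(pmax(a, 0), spec$a_max)
    ang <- runif(n, 0, pi)
    cts <- vector("list", n)
    for (i in seq_len(n)) {
      cts[[i]] <- make_lobed_contour(R = w[i] / 2, a = a[i], k = spec$k,
                                     aspect = aspect[i], angle = ang[i],
                                     n_points = spec$n_points,
                                     label = i, clade = clade,
                                     species = species, organ = "leaf",
                                     sample = sprintf("cell%03d", i))
    }
    list(contours = contour_set(cts),
         truth = data.frame(label = seq_len(n), w = w, a = a,
                            aspect = aspect, k = spec$k))
  })
}

#' Write a synthetic multi-species survey tree to disk
#'
#' Generates `n_species` species, a planted fraction of which have their
#' lobe amplitude coupled to cell width (so their min-axis vs lobeyness
#' correlation is moderate-to-high and their LEC-area-vs-area relation is
#' concave), writes them as a `root/clade/species/organ/sample.txt` tree,
#' and records the planted truth in `manifest.csv` under `root`.
#'
#' @param root Output directory (must be empty unless `force = TRUE`).
#' @param n_species Number of species.
#' @param fraction_coupled Fraction of species generated with width-coupled
#'   lobing.
#' @param n_cells Cells per species.
#' @param rng_seed Seed.
#' @param force Overwrite a non-empty directory.
#' @return Invisibly, the manifest data frame (species, clade, coupled).
#' @export
make_survey <- function(root, n_species = 40L, fraction_coupled = 0.75,
                        n_cells = 150L, rng_seed = 0L, force = FALSE) {
  stopifnot(fraction_coupled >= 0, fraction_coupled <= 1, n_species >= 1)
  if (dir.exists(root) && length(list.files(root)) && !force)
    stop_pavecell("io", sprintf("directory not empty: %s (use force = TRUE)", root))
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  clades <- c("eudicots", "monocots", "ferns", "gymnosperms")
  n_coupled <- round(fraction_coupled * n_species)
  coupled <- rep(c(TRUE, FALSE), c(n_coupled, n_species - n_coupled))
  manifest <- data.frame(
    species = sprintf("species%03d", seq_len(n_species)),
    clade = clades[(seq_len(n_species) - 1L) %% length(clades) + 1L],
    coupled = coupled)
  cs_all <- list()
  for (i in seq_len(n_species)) {
    spec <- if (coupled[i])
      species_spec(n_cells = n_cells, s = 0.0015, sigma_a = 0.02,
                   rng_seed = rng_seed * 10000L + i)
    else
      species_spec(n_cells = n_cells, a0 = 0.15, s = 0, sigma_a = 0.1,
                   rng_seed = rng_seed * 10000L + i)
    sp <- make_species(spec, clade = manifest$clade[i],
                       species = manifest$species[i])
    cs_all <- c(cs_all, sp$contours$contours)
  }
  save_labeled_tree(contour_set(cs_all), root)
  write.csv(manifest, file.path(root, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Degenerate contour fixtures for the error paths
#'
#' Writes raw contour files exercising the cleaning pipeline: a bowtie
#' (self-intersecting, repairable), a duplicate-vertex run, a 2-point file
#' (malformed), and a two-loop file (cell in multiple pieces, rejected).
#'
#' @param dir Output directory.
#' @return Data frame with columns `file` and `expected` (the error or
#'   repair the pipeline must produce).
#' @export
make_degenerate_fixtures <- function(dir = tempfile("fixtures")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(name, lines) {
    writeLines(lines, file.path(dir, name))
    file.path(dir, name)
  }
  bowtie <- w("bowtie.txt", c("0 0", "2 2", "2 0", "0 2"))
  dupes <- w("dupes.txt", c("0 0", "0 0", "1 0", "1 0", "1 1", "0 1", "0 1"))
  twopt <- w("twopoint.txt", c("0 0", "1 1"))
  twoloop <- w("twoloop.txt", c("0 0", "1 0", "1 1", "", "3 3", "4 3", "4 4"))
  data.frame(file = c(bowtie, dupes, twopt, twoloop),
             expected = c("self-intersecting: repair_contour must recover a simple polygon",
                          "duplicate vertices: dropped on load",
                          "malformed-contour error",
                          "multi-piece rejection"))
}
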