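#' Polygonal cell contours
#'
#' A `contour` is a closed simple polygon describing one pavement-cell
#' outline, with coordinates in microns and optional group labels
#' (clade, species, organ, sample). The closing edge is implicit: the last
#' vertex is not repeated. Orientation is normalised counter-clockwise
#' (signed area > 0) on construction.
#'
#' @param vertices Two-column matrix (or coercible) of x, y positions in
#'   microns, at least 3 rows.
#' @param label Integer cell id.
#' @param clade,species,organ,sample Group label strings; may be empty.
#' @param check Validate simplicity and degeneracy (default `TRUE`).
#' @return An object of class `contour`: a list with elements `vertices`,
#'   `label` and `group` (named character vector).
#' @examples
#' sq <- contour(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
#' polygon_area(sq)
#' @export
contour <- function(vertices, label = 1L, clade = "", species = "",
                    organ = "", sample = "", check = TRUE) {
  v <- as_vertex_matrix(vertices)
  # drop consecutive duplicates (cyclically)
  keep <- rowSums((v - v[c(nrow(v), seq_len(nrow(v) - 1L)), , drop = FALSE])^2) > 0
  if (!any(keep)) keep[1L] <- TRUE
  v <- v[keep, , drop = FALSE]
  if (nrow(v) < 3L)
    stop_pavecell("malformed_contour",
                  sprintf("contour needs >= 3 distinct vertices, got %d", nrow(v)))
  v <- ensure_ccw(v)
  if (check && abs(signed_area(v)) < 1e-12)
    stop_pavecell("degenerate_contour", "contour has (near-)zero area")
  structure(list(vertices = v, label = as.integer(label),
                 group = c(clade = clade, species = species,
                           organ = organ, sample = sample)),
            class = "contour")
}

stop_pavecell <- function(class, msg, ...) {
  stop(structure(class = c(paste0("pavecell_", class), "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

#' @export
print.contour <- function(x, ...) {
  g <- x$group[nzchar(x$group)]
  cat(sprintf("<contour> label %d, %d vertices, area %.4g um^2%s\n",
              x$label, nrow(x$vertices), abs(signed_area(x$vertices)),
              if (length(g)) paste0(" [", paste(g, collapse = "/"), "]") else ""))
  invisible(x)
}

#' Read one contour from a text file
#'
#' Contour files hold one 2D position per line (microns), whitespace- or
#' comma-separated; lines starting with `#` are ignored. Blank lines inside
#' the coordinate block would indicate a cell stored in multiple pieces and
#' are rejected. The polygon is closed implicitly and re-oriented CCW.
#'
#' @param path Path to a contour text file.
#' @param label Integer cell id to attach.
#' @param check Validate non-degeneracy (default `FALSE`: raw traced
#'   contours may self-intersect or have zero signed area until repaired
#'   with [repair_contour()]).
#' @param ... Group labels passed to [contour()].
#' @return A [contour()].
#' @export
read_contour_file <- function(path, label = 1L, check = FALSE, ...) {
  if (!file.exists(path))
    stop_pavecell("io", sprintf("no such contour file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  blank <- !nzchar(trimws(lines))
  content <- which(!blank)
  if (length(content) >= 2L && any(blank[seq(min(content), max(content))]))
    stop_pavecell("multipiece",
                  sprintf("%s: blank-separated blocks (cell in multiple pieces)", path))
  lines <- trimws(lines[!blank])
  if (length(lines) < 3L)
    stop_pavecell("malformed_contour",
                  sprintf("%s: fewer than 3 coordinate lines", path))
  toks <- strsplit(lines, "[,[:space:]]+")
  bad <- which(vapply(toks, function(t) {
    t <- t[nzchar(t)]
    length(t) < 2L || anyNA(suppressWarnings(as.numeric(t[1:2]))) ||
      any(!is.finite(suppressWarnings(as.numeric(t[1:2]))))
  }, logical(1)))
  if (length(bad))
    stop_pavecell("parse", sprintf("%s: non-numeric coordinates on line %d",
                                   path, bad[1L]))
  xy <- t(vapply(toks, function(t) as.numeric(t[nzchar(t)][1:2]), numeric(2)))
  contour(xy, label = label, check = check, ...)
}

#' Write one contour to a text file
#'
#' Inverse of [read_contour_file()]: one "x y" pair per line, microns,
#' full double precision (round-trips exactly through `read_contour_file`).
#'
#' @param x A [contour()].
#' @param path Output file path.
#' @export
write_contour_file <- function(x, path) {
  stopifnot(inherits(x, "contour"))
  writeLines(sprintf("%.17g %.17g", x$vertices[, 1L], x$vertices[, 2L]), path)
  invisible(path)
}

#' Load a labeled directory tree of contours
#'
#' Reads every `*.txt` under `root/clade/species/organ/sample.txt`; group
#' labels are taken from the path components. Files at any other depth are
#' skipped with a message. Unreadable or malformed files are skipped and
#' recorded (never silently dropped).
#'
#' @param root Directory containing the 4-level tree.
#' @return A `contour_set`: list with `contours` (list of [contour()]) and
#'   `failures` (data frame of skipped files and reasons), plus grouping
#'   accessors via [set_groups()].
#' @export
load_labeled_tree <- function(root) {
  if (!dir.exists(root)) stop_pavecell("io", sprintf("no such directory: %s", root))
  files <- list.files(root, pattern = "\\.txt$", recursive = TRUE,
                      full.names = FALSE)
  if (!length(files)) {
    warning("empty contour tree: ", root)
    return(contour_set(list()))
  }
  parts <- strsplit(files, "/", fixed = TRUE)
  depth_ok <- lengths(parts) == 4L
  for (f in files[!depth_ok])
    message("skipping (not at clade/species/organ/sample depth): ", f)
  contours <- list(); fail_file <- character(); fail_reason <- character()
  lab <- 0L
  for (i in which(depth_ok)) {
    p <- parts[[i]]
    lab <- lab + 1L
    ct <- tryCatch(
      read_contour_file(file.path(root, files[i]), label = lab,
                        clade = p[1L], species = p[2L], organ = p[3L],
                        sample = sub("\\.txt$", "", p[4L])),
      error = function(e) e)
    if (inherits(ct, "error")) {
      fail_file <- c(fail_file, files[i])
      fail_reason <- c(fail_reason, conditionMessage(ct))
      lab <- lab - 1L
    } else contours[[length(contours) + 1L]] <- ct
  }
  contour_set(contours, failures = data.frame(file = fail_file,
                                              reason = fail_reason))
}

#' Construct a contour set
#'
#' @param contours List of [contour()] objects. Labels must be unique; they
#'   are re-assigned sequentially when duplicated.
#' @param failures Optional data frame of per-file load failures.
#' @return A `contour_set`.
#' @export
contour_set <- function(contours, failures = NULL) {
  labs <- vapply(contours, `[[`, integer(1), "label")
  if (anyDuplicated(labs)) {
    for (i in seq_along(contours)) contours[[i]]$label <- i
  }
  structure(list(contours = contours,
                 failures = if (is.null(failures))
                   data.frame(file = character(), reason = character())
                 else failures),
            class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  sp <- unique(group_keys(x, "species"))
  cat(sprintf("<contour_set> %d contours, %d species, %d load failures\n",
              length(x$contours), length(sp[nzchar(sp)]), nrow(x$failures)))
  invisible(x)
}

#' @export
length.contour_set <- function(x) length(x$contours)

group_keys <- function(cs, by = c("species", "clade", "species-organ")) {
  by <- match.arg(by)
  vapply(cs$contours, function(ct) switch(by,
    clade = ct$group[["clade"]],
    species = paste(ct$group[["clade"]], ct$group[["species"]], sep = "/"),
    `species-organ` = paste(ct$group[["clade"]], ct$group[["species"]],
                            ct$group[["organ"]], sep = "/")), character(1))
}

#' Grouping of a contour set
#'
#' One-to-many groupings from grouping key (clade, species or species-organ)
#' to member contour labels.
#'
#' @param cs A `contour_set`.
#' @param by One of `"species"`, `"clade"`, `"species-organ"`.
#' @return Named list of integer label vectors.
#' @export
set_groups <- function(cs, by = c("species", "clade", "species-organ")) {
  keys <- group_keys(cs, by)
  labs <- vapply(cs$contours, `[[`, integer(1), "label")
  split(labs, keys)
}

#' Save a contour set as a labeled tree
#'
#' Mirror of [load_labeled_tree()]: writes each contour to
#' `root/clade/species/organ/sample.txt` (empty group fields become
#' `"unknown"`; duplicate sample names within one organ are disambiguated by
#' suffixing the label).
#'
#' @param cs A `contour_set`.
#' @param root Output directory.
#' @export
save_labeled_tree <- function(cs, root) {
  seen <- character()
  for (ct in cs$contours) {
    g <- ct$group
    g[!nzchar(g)] <- "unknown"
    d <- file.path(root, g[["clade"]], g[["species"]], g[["organ"]])
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    f <- file.path(d, paste0(g[["sample"]], ".txt"))
    if (f %in% seen)
      f <- file.path(d, sprintf("%s_label%d.txt", g[["sample"]], ct$label))
    seen <- c(seen, f)
    write_contour_file(ct, f)
  }
  invisible(root)
}

#' Export per-contour metadata
#'
#' @param cs A `contour_set`.
#' @param path Optional CSV output path.
#' @return Data frame with label, clade, species, organ, sample, n_vertices.
#' @export
contour_metadata <- function(cs, path = NULL) {
  df <- do.call(rbind, lapply(cs$contours, function(ct)
    data.frame(label = ct$label, clade = ct$group[["clade"]],
               species = ct$group[["species"]], organ = ct$group[["organ"]],
               sample = ct$group[["sample"]], n_vertices = nrow(ct$vertices))))
  if (is.null(df)) df <- data.frame(label = integer(), clade = character(),
                                    species = character(), organ = character(),
                                    sample = character(), n_vertices = integer())
  rownames(df) <- NULL
  if (!is.null(path)) write.csv(df, path, row.names = FALSE)
  df
}

#' Smooth a contour by cyclic neighbourhood averaging
#'
#' Each vertex is replaced by the unweighted mean of its closed
#' 1-neighbourhood (previous, self, next; cyclic). This is the standard
#' noise-reduction pass applied to traced cell outlines; repeated
#' application contracts the polygon toward its vertex centroid.
#'
#' @param c A [contour()].
#' @param passes Number of smoothing passes (positive integer).
#' @return Smoothed [contour()].
#' @export
smooth_contour <- function(c, passes = 1L) {
  stopifnot(inherits(c, "contour"), passes >= 1)
  v <- c$vertices
  n <- nrow(v)
  if (n == 3L)
    warning("smoothing a triangle maps every vertex to the centroid")
  for (p in seq_len(passes)) {
    ip <- c(n, seq_len(n - 1L)); nx <- c(seq_len(n)[-1L], 1L)
    v <- (v[ip, , drop = FALSE] + v + v[nx, , drop = FALSE]) / 3
  }
  if (nrow(unique(round(v, 12L))) < 3L || abs(signed_area(v)) < 1e-12)
    stop_pavecell("degenerate_contour", "smoothing collapsed the contour")
  out <- c
  out$vertices <- as_vertex_matrix(v)
  out
}

#' Repair a self-intersecting contour by targeted smoothing
#'
#' Traced contours occasionally have vertices out of order, producing
#' self-intersecting edges. Vertices incident to a crossing edge are flagged
#' and replaced by their 1-neighbourhood average; the scan repeats until the
#' polygon is simple or `max_rounds` is exhausted. Simple inputs are
#' returned unchanged.
#'
#' @param c A [contour()].
#' @param max_rounds Maximum repair rounds.
#' @return A simple [contour()].
#' @export
repair_contour <- function(c, max_rounds = 50L) {
  stopifnot(inherits(c, "contour"))
  v <- c$vertices
  n <- nrow(v)
  prev_crossings <- Inf
  for (round in seq_len(max_rounds)) {
    cross <- cpp_crossing_edge_pairs(v)
    if (nrow(cross) == 0L) {
      out <- c
      out$vertices <- as_vertex_matrix(ensure_ccw(v))
      return(out)
    }
    if (nrow(cross) >= prev_crossings) {
      # smoothing stalled: put the vertices back in order by reversing the
      # run between the first pair of crossing edges (2-opt uncrossing)
      i <- cross[1L, 1L]; j <- cross[1L, 2L]
      seg <- (i + 1L):j
      v[seg, ] <- v[rev(seg), , drop = FALSE]
      prev_crossings <- Inf
      next
    }
    prev_crossings <- nrow(cross)
    edges <- unique(as.vector(cross))
    flagged <- unique(c(edges, edges %% n + 1L))  # both endpoints of each edge
    ip <- c(n, seq_len(n - 1L)); nx <- c(seq_len(n)[-1L], 1L)
    sm <- (v[ip, , drop = FALSE] + v + v[nx, , drop = FALSE]) / 3
    v[flagged, ] <- sm[flagged, ]
  }
  cross <- cpp_crossing_edge_pairs(v)
  stop_pavecell("unrepairable",
                sprintf("contour %d still self-intersects after %d rounds",
                        c$label, max_rounds),
                flagged_vertices = unique(as.vector(cross)))
}

#' Rotate a contour so its min-axis lies along x
#'
#' Rigid rotation about the centroid putting the direction of minimum width
#' (the min-axis) on the +x axis. Width is pi-periodic, so ties (e.g. a
#' near-circular outline) are broken toward the smallest qualifying angle.
#' All scalar shape metrics are invariant under this rotation.
#'
#' @param c A [contour()].
#' @param n_angles Angular samples used for the width search.
#' @return Rotated [contour()].
#' @export
rotate_to_min_axis <- function(c, n_angles = 3600L) {
  stopifnot(inherits(c, "contour"))
  ma <- min_axis(c, n_angles = n_angles)
  theta <- atan2(ma$direction[2L], ma$direction[1L])
  if (theta < 0) theta <- theta + pi  # direction is axial
  out <- c
  out$vertices <- as_vertex_matrix(
    rotate_points(c$vertices, -theta, center = poly_centroid(c$vertices)))
  out
}
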