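# Growth schedules: per-axis growth-rate functions of normalised time
# t in [0,1], discretised to per-step multiplicative factors. The cumulative
# per-axis scale is the product over steps of the factors.

pwl_eval <- function(px, py) {
  force(px); force(py)
  function(t) {
    t <- pmin(max(px), pmax(min(px), t))
    i <- pmax(1L, pmin(findInterval(t, px, rightmost.closed = TRUE),
                       length(px) - 1L))
    x1 <- px[i]; x2 <- px[i + 1L]; y1 <- py[i]; y2 <- py[i + 1L]
    ifelse(x2 > x1, y1 + (t - x1) / (x2 - x1) * (y2 - y1), y2)
  }
}

as_rate_fun <- function(g, what) {
  if (is.function(g)) return(g)
  g <- as.matrix(g)
  if (ncol(g) != 2L || nrow(g) < 2L)
    stop_pavecell("format", sprintf("%s: need >= 2 (t, rate) control points", what))
  if (is.unsorted(g[, 1L]))
    stop_pavecell("format", sprintf("%s: control-point times must be non-decreasing", what))
  pwl_eval(g[, 1L], g[, 2L])
}

#' Growth schedule from per-axis rate functions
#'
#' `gx` and `gy` give per-axis growth rates as functions of normalised time
#' (or as two-column (t, rate) control-point matrices, interpolated
#' piecewise-linearly and clamped outside \[0, 1\]). The schedule is
#' discretised into `n_steps` multiplicative factors
#' `1 + g(t_mid) / n_steps`; the cumulative per-axis scale is their product.
#'
#' @param n_steps Number of growth steps.
#' @param gx,gy Rate functions or control-point matrices (rates must be
#'   non-negative).
#' @return A `growth_schedule`: list with `n_steps`, `factors`
#'   (`n_steps` x 2 matrix), `gx`, `gy`.
#' @export
growth_schedule <- function(n_steps, gx, gy = gx) {
  stopifnot(n_steps >= 1)
  fx <- as_rate_fun(gx, "gx"); fy <- as_rate_fun(gy, "gy")
  tm <- (seq_len(n_steps) - 0.5) / n_steps
  rx <- fx(tm); ry <- fy(tm)
  if (length(rx) != n_steps || length(ry) != n_steps)
    stop_pavecell("format", "rate functions must be vectorised over time")
  if (any(rx < 0) || any(ry < 0))
    stop_pavecell("format", "growth rates must be non-negative")
  structure(list(n_steps = as.integer(n_steps),
                 factors = cbind(x = 1 + rx / n_steps, y = 1 + ry / n_steps),
                 gx = fx, gy = fy),
            class = "growth_schedule")
}

#' Growth schedule from per-axis scale profiles
#'
#' Instead of rates, give the cumulative scale as a piecewise-linear
#' function of normalised time per axis (two-column (t, scale) matrices
#' starting at scale `S(0) = 1`). Per-step factors are the telescoped scale
#' ratios, so the cumulative product equals the profile endpoint exactly.
#' This matches boundary vertices moving outward at piecewise-constant
#' speed.
#'
#' @param n_steps Number of growth steps.
#' @param sx,sy Two-column (t, scale) control-point matrices.
#' @return A `growth_schedule`.
#' @export
schedule_from_scales <- function(n_steps, sx, sy = sx) {
  stopifnot(n_steps >= 1)
  fx <- as_rate_fun(sx, "sx"); fy <- as_rate_fun(sy, "sy")
  tk <- seq(0, 1, length.out = n_steps + 1L)
  Sx <- fx(tk); Sy <- fy(tk)
  if (any(Sx <= 0) || any(Sy <= 0))
    stop_pavecell("format", "scale profiles must stay positive")
  factors <- cbind(x = Sx[-1L] / Sx[-length(Sx)], y = Sy[-1L] / Sy[-length(Sy)])
  if (any(factors < 1 - 1e-12))
    stop_pavecell("format", "scale profiles must be non-decreasing")
  n <- as.integer(n_steps)
  structure(list(n_steps = n, factors = factors,
                 gx = function(t) n * (fx(pmin(1, t + 1 / (2 * n))) /
                                         fx(pmax(0, t - 1 / (2 * n))) - 1),
                 gy = function(t) n * (fy(pmin(1, t + 1 / (2 * n))) /
                                         fy(pmax(0, t - 1 / (2 * n))) - 1)),
            class = "growth_schedule")
}

#' Reverse a schedule in time
#'
#' Per-step factors are applied in reverse order; cumulative scales are
#' unchanged.
#'
#' @param schedule A `growth_schedule`.
#' @return A `growth_schedule`.
#' @export
reverse_schedule <- function(schedule) {
  stopifnot(inherits(schedule, "growth_schedule"))
  out <- schedule
  out$factors <- schedule$factors[rev(seq_len(schedule$n_steps)), , drop = FALSE]
  dimnames(out$factors) <- dimnames(schedule$factors)
  out
}

#' Cumulative per-axis scales of a schedule
#'
#' @param schedule A `growth_schedule`.
#' @return Named vector `c(x = , y = )` of products of per-step factors.
#' @export
cumulative_scales <- function(schedule) {
  stopifnot(inherits(schedule, "growth_schedule"))
  c(x = prod(schedule$factors[, "x"]), y = prod(schedule$factors[, "y"]))
}

#' @export
print.growth_schedule <- function(x, ...) {
  cs <- cumulative_scales(x)
  cat(sprintf("<growth_schedule> %d steps, cumulative scale %.4g x, %.4g y\n",
              x$n_steps, cs["x"], cs["y"]))
  invisible(x)
}

#' Load a growth-curve (.func) control-point file
#'
#' Reads a funcedit-style curve file: any header lines are skipped and each
#' remaining line holding two numbers is taken as a (t, value) control
#' point. Points are interpolated piecewise-linearly (the upstream tool's
#' spline semantics are deliberately not reproduced) and evaluation outside
#' \[0, 1\] clamps to the endpoints.
#'
#' @param path Path to a `.func` file.
#' @return A function of normalised time.
#' @export
load_func <- function(path) {
  if (!file.exists(path)) stop_pavecell("io", sprintf("no such file: %s", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toks <- strsplit(lines, "[,[:space:]]+")
  pts <- lapply(toks, function(t) suppressWarnings(as.numeric(t[nzchar(t)])))
  pts <- Filter(function(p) length(p) >= 2L && !anyNA(p[1:2]), pts)
  if (length(pts) < 2L)
    stop_pavecell("format", sprintf("%s: need >= 2 numeric control points", path))
  m <- t(vapply(pts, function(p) p[1:2], numeric(2)))
  if (is.unsorted(m[, 1L]))
    stop_pavecell("format", sprintf("%s: control-point times decrease", path))
  pwl_eval(m[, 1L], m[, 2L])
}
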