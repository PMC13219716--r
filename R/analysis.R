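#' Select the percentile cell of each group
#'
#' Nearest-rank percentile selection: within each group the member whose
#' metric is the ceiling(q/100 * n)-th order statistic is returned, so a
#' real cell is always selected (q = 0 returns the minimum). Ties are broken
#' deterministically by label.
#'
#' @param cells Metric table (e.g. from [metrics_table()]).
#' @param group Column name to group by (e.g. `"species"`), or a vector of
#'   group keys of length `nrow(cells)`.
#' @param q Percentile in \[0, 100\] (default 95, the upper-range lobing
#'   statistic used to score a species' capacity to form puzzle cells).
#' @param by Metric column (default `"lobeyness"`).
#' @return One row of `cells` per group, with a `group_key` column.
#' @export
percentile_select <- function(cells, group = "species", q = 95,
                              by = "lobeyness") {
  stopifnot(q >= 0, q <= 100)
  keys <- if (length(group) == 1L && group %in% names(cells))
    cells[[group]] else group
  if (length(keys) != nrow(cells))
    stop_pavecell("parameter", "group must name a column or give one key per row")
  if (!nrow(cells)) stop_pavecell("empty_group", "empty metric table")
  out <- lapply(split(seq_len(nrow(cells)), keys), function(idx) {
    sub <- cells[idx, , drop = FALSE]
    sub <- sub[is.finite(sub[[by]]), , drop = FALSE]
    if (!nrow(sub))
      stop_pavecell("empty_group",
                    sprintf("group '%s' has no finite '%s' values",
                            keys[idx[1L]], by))
    ord <- order(sub[[by]], sub$label)
    rank <- max(1L, ceiling(q / 100 * nrow(sub)))
    sub[ord[rank], , drop = FALSE]
  })
  res <- do.call(rbind, out)
  res$group_key <- names(out)
  rownames(res) <- NULL
  res
}

#' Pearson correlation with explicit degeneracy handling
#'
#' Product-moment correlation between two metric vectors (pairwise-complete).
#' Zero variance in either input yields `NA` with a warning, so degenerate
#' species can be excluded rather than propagating NaN.
#'
#' @param x,y Numeric vectors of equal length (>= 3 finite pairs).
#' @return Correlation in \[-1, 1\], or `NA_real_` if undefined.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L)
    stop_pavecell("parameter", "need >= 3 finite pairs for a correlation")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Classify a species by its min-axis vs lobeyness correlation
#'
#' Correlations at or above the threshold (default 0.3, boundary inclusive)
#' are classified moderate-to-high; below, weak; undefined correlations are
#' excluded.
#'
#' @param r Correlation value(s).
#' @param threshold Classification threshold (default 0.3).
#' @return Character vector: `"moderate-high"`, `"weak"` or `"excluded"`.
#' @export
classify_species <- function(r, threshold = 0.3) {
  ifelse(!is.finite(r), "excluded",
         ifelse(r >= threshold, "moderate-high", "weak"))
}

#' Origin-constrained quadratic fit
#'
#' Least-squares fit of `y = beta*x + alpha*x^2` with no intercept, used for
#' the LEC-vs-size scaling test: a concave-downward relation (`alpha < 0`)
#' means the largest empty circle grows more slowly than cell size.
#'
#' @param x Cell sizes (> 0, at least 2 distinct).
#' @param y LEC measures (same length).
#' @return List with `beta`, `alpha`, and `concave` (`sign(alpha) < 0`).
#' @export
fit_quadratic_origin <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2L || length(unique(x)) < 2L)
    stop_pavecell("fit", "need >= 2 distinct x values")
  fit <- stats::lm(y ~ 0 + x + I(x^2))
  cf <- unname(coef(fit))
  list(beta = cf[1L], alpha = cf[2L], concave = cf[2L] < 0)
}

#' Exact two-sided binomial sign test at null probability 1/2
#'
#' Probability, under Binomial(n, 1/2), of an outcome at least as extreme as
#' the observed count, two-sided by doubling the smaller tail (capped at 1).
#' At p = 1/2 this coincides with the minimum-likelihood definition by
#' symmetry.
#'
#' @param n_negative Observed count (e.g. species with negative alpha).
#' @param n_total Number of trials (>= 1).
#' @return p-value in (0, 1\].
#' @export
binomial_sign_test <- function(n_negative, n_total) {
  stopifnot(n_total >= 1, n_negative >= 0, n_negative <= n_total)
  k <- n_negative
  lower <- pbinom(k, n_total, 0.5)
  upper <- pbinom(k - 1, n_total, 0.5, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

#' Areal strain between two time points
#'
#' Relative area increase `(A2 - A1) / A1` of a tissue patch; positive
#' values indicate expansion. Used for daily growth-rate heatmaps in
#' time-lapse data.
#'
#' @param A1 Initial area (> 0).
#' @param A2 Final area.
#' @return Dimensionless strain.
#' @export
areal_strain <- function(A1, A2) {
  if (any(A1 <= 0)) stop_pavecell("parameter", "A1 must be > 0")
  (A2 - A1) / A1
}

#' Per-species summary statistics
#'
#' For each species in a metric table: cell count, the Pearson correlation
#' between min-axis and lobeyness, its classification, the 95th-percentile
#' lobeyness (nearest rank), and origin-constrained quadratic fits of LEC
#' area vs cell area and LEC diameter vs min-axis.
#'
#' @param cells Metric table from [metrics_table()].
#' @param r_threshold Classification threshold (default 0.3).
#' @param q Lobeyness percentile (default 95).
#' @param species_col Column identifying the species (default `"species"`).
#' @return Data frame, one row per species: species, n_cells, pearson_r,
#'   classification, p95_lobeyness, alpha, beta, alpha_daxis, beta_daxis.
#' @export
species_summaries <- function(cells, r_threshold = 0.3, q = 95,
                              species_col = "species") {
  cells <- cells[if ("ok" %in% names(cells)) cells$ok else TRUE, , drop = FALSE]
  out <- lapply(split(cells, cells[[species_col]]), function(sub) {
    n <- nrow(sub)
    r <- if (n >= 3L)
      tryCatch(suppressWarnings(pearson_r(sub$min_axis_um, sub$lobeyness)),
               error = function(e) NA_real_)
    else NA_real_
    p95 <- if (n >= 1L) {
      ord <- order(sub$lobeyness, sub$label)
      sub$lobeyness[ord[max(1L, ceiling(q / 100 * n))]]
    } else NA_real_
    fa <- if (n >= 2L)
      tryCatch(fit_quadratic_origin(sub$area_um2, pi * sub$lec_radius_um^2),
               error = function(e) NULL)
    else NULL
    fd <- if (n >= 2L)
      tryCatch(fit_quadratic_origin(sub$min_axis_um, 2 * sub$lec_radius_um),
               error = function(e) NULL)
    else NULL
    data.frame(species = sub[[species_col]][1L], n_cells = n,
               pearson_r = r,
               classification = classify_species(r, r_threshold),
               p95_lobeyness = p95,
               alpha = if (is.null(fa)) NA_real_ else fa$alpha,
               beta = if (is.null(fa)) NA_real_ else fa$beta,
               alpha_daxis = if (is.null(fd)) NA_real_ else fd$alpha,
               beta_daxis = if (is.null(fd)) NA_real_ else fd$beta)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cross-species survey aggregation
#'
#' Counts and percentages of species whose min-axis vs lobeyness correlation
#' is at or above the threshold and whose LEC-area-vs-cell-area fit is
#' concave downward (alpha < 0), with an exact two-sided binomial test of
#' whether negative and positive alpha signs are equally frequent. Species
#' with undefined correlations or failed fits are kept in the denominator by
#' default (classified weak / sign unknown) and reported; set
#' `drop_undefined = TRUE` for the excluding convention.
#'
#' @param summaries Data frame from [species_summaries()], or any data frame
#'   with columns `pearson_r` and `alpha`.
#' @param r_threshold Correlation threshold (default 0.3).
#' @param drop_undefined Drop species with undefined r / alpha from the
#'   denominators instead of keeping them (default `FALSE`).
#' @return `survey_result` list: n_species, n_r_ge_threshold,
#'   n_alpha_negative, pct_r_ge_threshold, pct_alpha_negative (exact and
#'   integer-rounded), binomial_p, n_undefined_r, n_undefined_alpha.
#' @export
survey <- function(summaries, r_threshold = 0.3, drop_undefined = FALSE) {
  stopifnot(nrow(summaries) >= 1L)
  r <- summaries$pearson_r
  a <- summaries$alpha
  if (drop_undefined) {
    n_r <- sum(is.finite(r))
    n_a <- sum(is.finite(a))
  } else {
    n_r <- n_a <- nrow(summaries)
  }
  k_r <- sum(r >= r_threshold, na.rm = TRUE)
  k_a <- sum(a < 0, na.rm = TRUE)
  structure(list(
    n_species = nrow(summaries),
    n_r_ge_threshold = k_r,
    n_alpha_negative = k_a,
    pct_r_ge_threshold = 100 * k_r / n_r,
    pct_alpha_negative = 100 * k_a / n_a,
    pct_r_ge_threshold_int = as.integer(round(100 * k_r / n_r)),
    pct_alpha_negative_int = as.integer(round(100 * k_a / n_a)),
    binomial_p = binomial_sign_test(k_a, n_a),
    n_undefined_r = sum(!is.finite(r)),
    n_undefined_alpha = sum(!is.finite(a)),
    r_threshold = r_threshold),
    class = "survey_result")
}

#' @export
print.survey_result <- function(x, ...) {
  cat(sprintf("<survey_result> %d species\n", x$n_species))
  cat(sprintf("  r >= %.2g: %d (%d%%)\n", x$r_threshold, x$n_r_ge_threshold,
              x$pct_r_ge_threshold_int))
  cat(sprintf("  alpha < 0: %d (%d%%), exact binomial p = %.3g\n",
              x$n_alpha_negative, x$pct_alpha_negative_int, x$binomial_p))
  if (x$n_undefined_r || x$n_undefined_alpha)
    cat(sprintf("  undefined: r in %d, alpha in %d species\n",
                x$n_undefined_r, x$n_undefined_alpha))
  invisible(x)
}

#' @export
summary.survey_result <- function(object, ...) {
  print(object)
  invisible(unclass(object))
}
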