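#' Marked point pattern in a circular observation window
#'
#' Cell centroids with binary type marks inside a circular window; the input
#' to the cross-K mixing score. Coordinates share the image convention
#' (x = column, y = row, 0-based) when derived from a cell table.
#'
#' @param x,y point coordinates (pixels).
#' @param marks per-point type, coerced to factor with levels
#'   `positive`/`negative`.
#' @param center `(x, y)` of the window centre.
#' @param radius window radius (pixels).
#' @return An object of class `MarkedPointPattern`.
#' @export
point_pattern <- function(x, y, marks, center, radius) {
  stopifnot(length(x) == length(y), length(x) == length(marks))
  marks <- as.character(marks)
  bad <- setdiff(unique(marks), c("positive", "negative"))
  if (length(bad)) {
    sr_stop("spatroi_parameter_error",
            "marks must be 'positive' or 'negative'; got: %s",
            paste(bad, collapse = ", "))
  }
  d2 <- (x - center[1])^2 + (y - center[2])^2
  if (any(d2 > radius^2 * (1 + 1e-9))) {
    sr_stop("spatroi_parameter_error",
            "%d point(s) lie outside the observation window",
            sum(d2 > radius^2 * (1 + 1e-9)))
  }
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 marks = factor(marks, levels = c("positive", "negative")),
                 window = list(center = as.numeric(center),
                               radius = as.numeric(radius))),
            class = "MarkedPointPattern")
}

#' @export
print.MarkedPointPattern <- function(x, ...) {
  cat(sprintf(
    "MarkedPointPattern: %d positive + %d negative points, window radius %.1f\n",
    sum(x$marks == "positive"), sum(x$marks == "negative"), x$window$radius))
  invisible(x)
}

#' Build a marked point pattern from a classified cell table
#'
#' @param cells a feature table from [extract_features()] with a filled
#'   `class_label` column (see [classify_cutoff()] and friends).
#' @param img the cropped `RoiImage` supplying the circular window, or `NULL`
#'   to pass `center`/`radius` directly.
#' @param center,radius window geometry when `img` is `NULL`.
#' @return A `MarkedPointPattern`.
#' @export
cells_to_pattern <- function(cells, img = NULL, center = NULL, radius = NULL) {
  if (!is.null(img)) {
    stopifnot(inherits(img, "RoiImage"))
    center <- img$center
    radius <- img$radius_px
  }
  if (any(is.na(cells$class_label))) {
    sr_stop("spatroi_parameter_error",
            "cells must be classified before building a point pattern")
  }
  # centroids of boundary-straddling cells can sit marginally outside the
  # fitted circle; clamp the window to cover them
  d <- sqrt((cells$x - center[1])^2 + (cells$y - center[2])^2)
  point_pattern(cells$x, cells$y, cells$class_label, center,
                max(radius, if (nrow(cells)) max(d) else radius))
}

# Translation edge-correction weight for a circular window: |W| / |W ∩ W_h|
# where the overlap of a disc of radius R with itself shifted by distance d is
# the lens area 2 R^2 acos(d / 2R) - (d / 2) sqrt(4 R^2 - d^2).
translation_weight_disc <- function(d, R) {
  area <- pi * R^2
  lens <- 2 * R^2 * acos(pmin(1, d / (2 * R))) -
    (d / 2) * sqrt(pmax(0, 4 * R^2 - d^2))
  area / lens
}

#' Bivariate Ripley cross-K with AUC mixing score
#'
#' Estimates the cross-K function between the positive and negative marks,
#' \eqn{\hat K(r) = \frac{|W|}{n_+ n_-} \sum_{i,j} w_{ij} 1[d_{ij} \le r]},
#' over an increasing radius grid, together with the analytic Poisson
#' reference \eqn{\pi r^2} and the signed AUC mixing score
#' \eqn{\mathrm{AUC} = \int (\hat K(r) - \pi r^2)\,dr / r_{max}^2}
#' (trapezoid rule). Under independence of the two populations the score has
#' expectation 0; attraction (mixing) gives positive scores and segregation
#' negative ones.
#'
#' Edge corrections: `"translation"` (default; weights each pair by
#' `|W| / |W ∩ W_shifted|`, unbiased on the circular window), `"border"`
#' (reduced-sample: only positive points at least `r` from the boundary
#' contribute at radius `r`) and `"none"`.
#'
#' @param pattern a [point_pattern()].
#' @param r_max largest radius evaluated; defaults to a quarter of the window
#'   radius. Must not exceed the window radius.
#' @param n_r number of equally spaced radii.
#' @param edge_correction `"translation"`, `"border"` or `"none"`.
#' @param direction `"pos_to_neg"` (default) or `"symmetric"` (average of both
#'   directions; identical for translation/none weights, which are symmetric
#'   in the pair).
#' @return An object of class `CrossKResult`: `radii`, `k_obs`, `k_ref`,
#'   `auc`, `edge_correction`, `n_positive`, `n_negative`.
#' @export
cross_k <- function(pattern, r_max = NULL, n_r = 100,
                    edge_correction = c("translation", "border", "none"),
                    direction = c("pos_to_neg", "symmetric")) {
  stopifnot(inherits(pattern, "MarkedPointPattern"))
  edge_correction <- match.arg(edge_correction)
  direction <- match.arg(direction)
  R <- pattern$window$radius
  if (is.null(r_max)) r_max <- R / 4
  if (r_max > R) {
    sr_stop("spatroi_parameter_error",
            "r_max (%.1f) exceeds the window radius (%.1f)", r_max, R)
  }
  pos <- pattern$marks == "positive"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  for (m in c("positive", "negative")) {
    if (sum(pattern$marks == m) < 2) {
      sr_stop("spatroi_insufficient_points_error",
              "need >= 2 points of mark '%s' (have %d)",
              m, sum(pattern$marks == m))
    }
  }
  px <- pattern$x[pos]; py <- pattern$y[pos]
  qx <- pattern$x[!pos]; qy <- pattern$y[!pos]
  d <- sqrt(outer(px, qx, "-")^2 + outer(py, qy, "-")^2)  # n_pos x n_neg
  area <- pi * R^2
  radii <- seq(r_max / n_r, r_max, length.out = n_r)

  if (edge_correction == "border") {
    # reduced-sample: at radius r use only reference points with boundary
    # distance >= r; applied from the positive side (and averaged with the
    # negative side when direction = "symmetric")
    k_obs <- border_k(px, py, qx, qy, d, pattern$window, radii, n_neg)
    if (direction == "symmetric") {
      k_obs <- (k_obs +
                  border_k(qx, qy, px, py, t(d), pattern$window, radii,
                           n_pos)) / 2
    }
  } else {
    w <- if (edge_correction == "translation") {
      translation_weight_disc(d, R)
    } else {
      matrix(1, nrow(d), ncol(d))
    }
    # cumulative weight below each radius via a single sort
    ord <- order(d)
    ds <- d[ord]; ws <- cumsum(w[ord])
    pos_at <- findInterval(radii, ds)
    csum <- c(0, ws)[pos_at + 1]
    k_obs <- area * csum / (n_pos * n_neg)
  }
  k_ref <- pi * radii^2
  structure(list(radii = radii, k_obs = k_obs, k_ref = k_ref,
                 auc = trapz(radii, k_obs - k_ref) / r_max^2,
                 edge_correction = edge_correction,
                 n_positive = n_pos, n_negative = n_neg),
            class = "CrossKResult")
}

border_k <- function(px, py, qx, qy, d, window, radii, n_other) {
  bdist <- window$radius -
    sqrt((px - window$center[1])^2 + (py - window$center[2])^2)
  area <- pi * window$radius^2
  lambda_other <- n_other / area
  vapply(radii, function(r) {
    use <- bdist >= r
    if (!any(use)) return(NA_real_)
    mean(rowSums(d[use, , drop = FALSE] <= r)) / lambda_other
  }, numeric(1))
}

#' @export
print.CrossKResult <- function(x, ...) {
  cat(sprintf(
    "CrossKResult: %d radii up to %.1f, edge = %s, AUC mixing score = %.4f\n",
    length(x$radii), max(x$radii), x$edge_correction, x$auc))
  invisible(x)
}

#' Brute-force cross-K oracle
#'
#' Direct double loop over all positive x negative pairs with no edge
#' correction; an independent O(n^2) reference used in tests against
#' [cross_k()].
#'
#' @inheritParams cross_k
#' @return A `CrossKResult` (edge correction `"none"`).
#' @export
brute_force_cross_k <- function(pattern, r_max = NULL, n_r = 100) {
  stopifnot(inherits(pattern, "MarkedPointPattern"))
  R <- pattern$window$radius
  if (is.null(r_max)) r_max <- R / 4
  if (r_max > R) {
    sr_stop("spatroi_parameter_error",
            "r_max (%.1f) exceeds the window radius (%.1f)", r_max, R)
  }
  pos <- which(pattern$marks == "positive")
  neg <- which(pattern$marks == "negative")
  for (m in c("positive", "negative")) {
    if (sum(pattern$marks == m) < 2) {
      sr_stop("spatroi_insufficient_points_error",
              "need >= 2 points of mark '%s' (have %d)",
              m, sum(pattern$marks == m))
    }
  }
  radii <- seq(r_max / n_r, r_max, length.out = n_r)
  counts <- numeric(n_r)
  for (i in pos) {
    for (j in neg) {
      dij <- sqrt((pattern$x[i] - pattern$x[j])^2 +
                  (pattern$y[i] - pattern$y[j])^2)
      counts <- counts + (dij <= radii)
    }
  }
  area <- pi * R^2
  k_obs <- area * counts / (length(pos) * length(neg))
  k_ref <- pi * radii^2
  structure(list(radii = radii, k_obs = k_obs, k_ref = k_ref,
                 auc = trapz(radii, k_obs - k_ref) / r_max^2,
                 edge_correction = "none",
                 n_positive = length(pos), n_negative = length(neg)),
            class = "CrossKResult")
}

#' Group ROIs into Mixture vs Separative by their AUC mixing scores
#'
#' A larger AUC indicates a more mixed tumour-stroma pattern. Grouping
#' requires an explicit rule: either `top_n` (the `n` highest-AUC ROIs are
#' `Mixture`, ties broken by lexicographic `roi_id`) or `threshold`
#' (`auc > threshold` is `Mixture`).
#'
#' @param results data frame with columns `roi_id` and `auc` (or a named list
#'   of `CrossKResult` objects, names taken as `roi_id`).
#' @param rule a list with exactly one of `top_n` or `threshold`.
#' @return The input data frame with an added `group` column
#'   (`"Mixture"`/`"Separative"`), sorted by decreasing `auc`.
#' @export
classify_mixing <- function(results, rule) {
  if (is.list(results) && !is.data.frame(results) &&
      all(vapply(results, inherits, logical(1), "CrossKResult"))) {
    results <- data.frame(roi_id = names(results),
                          auc = vapply(results, `[[`, numeric(1), "auc"),
                          stringsAsFactors = FALSE, row.names = NULL)
  }
  stopifnot(is.data.frame(results),
            all(c("roi_id", "auc") %in% names(results)))
  if (nrow(results) < 1) {
    sr_stop("spatroi_parameter_error", "need at least one cross-K result")
  }
  has_top <- !is.null(rule$top_n); has_thr <- !is.null(rule$threshold)
  if (has_top == has_thr) {
    sr_stop("spatroi_parameter_error",
            "rule must contain exactly one of top_n or threshold")
  }
  ord <- order(-results$auc, results$roi_id)
  results <- results[ord, , drop = FALSE]
  if (has_top) {
    if (rule$top_n > nrow(results)) {
      sr_stop("spatroi_parameter_error",
              "top_n (%d) exceeds the number of ROIs (%d)",
              rule$top_n, nrow(results))
    }
    results$group <- ifelse(seq_len(nrow(results)) <= rule$top_n,
                            "Mixture", "Separative")
  } else {
    results$group <- ifelse(results$auc > rule$threshold,
                            "Mixture", "Separative")
  }
  row.names(results) <- NULL
  results
}

#' Write a cross-K curve and summary to CSV
#'
#' @param result a `CrossKResult`.
#' @param path output CSV path (columns `r`, `k_obs`, `k_ref`).
#' @return `path`, invisibly.
#' @export
write_cross_k <- function(result, path) {
  utils::write.csv(
    data.frame(r = result$radii, k_obs = result$k_obs, k_ref = result$k_ref),
    path, row.names = FALSE)
  invisible(path)
}
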