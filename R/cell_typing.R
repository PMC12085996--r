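# Marker-based cell classification from channel intensity distributions.
# The green (PanCK) channel is bimodal in practice: marker-positive (cancer)
# cells form a bright mode well separated from the dim negative mode, so a
# fixed cutoff, a 2-component GMM and 2-means clustering all recover the same
# dichotomy when the modes are separated.

typing_result <- function(method, positive_channel, threshold_used, labels) {
  labels <- factor(labels, levels = c("positive", "negative"))
  n_total <- length(labels)
  n_positive <- sum(labels == "positive")
  structure(list(method = method, positive_channel = positive_channel,
                 threshold_used = threshold_used, labels = labels,
                 n_total = n_total, n_positive = n_positive,
                 positive_fraction = n_positive / n_total),
            class = "TypingResult")
}

#' @export
print.TypingResult <- function(x, ...) {
  cat(sprintf("TypingResult (%s on %s): %d / %d positive (%s)\n",
              x$method, x$positive_channel, x$n_positive, x$n_total,
              format_positive_pct(x$n_positive, x$n_total)))
  if (is.finite(x$threshold_used)) {
    cat(sprintf("  effective intensity boundary: %.3f\n", x$threshold_used))
  }
  invisible(x)
}

#' Format a positive-cell percentage to two decimals
#'
#' The annotation convention used on snapshots: e.g. 258 positive out of 535
#' cells is reported as `"48.22%"`.
#'
#' @param n_positive,n_total cell counts.
#' @return A string like `"48.22%"`.
#' @export
format_positive_pct <- function(n_positive, n_total) {
  sprintf("%.2f%%", 100 * n_positive / n_total)
}

channel_column <- function(cells, channel) {
  col <- c(R = "mean_r", G = "mean_g", B = "mean_b")[[toupper(channel)]]
  if (is.null(col) || !col %in% names(cells)) {
    sr_stop("spatroi_parameter_error", "no intensity column for channel '%s'",
            channel)
  }
  cells[[col]]
}

#' Classify cells by a fixed intensity cutoff
#'
#' A cell is positive when its mean intensity on `channel` strictly exceeds
#' `cutoff` (ties are negative). The default of 20 follows the documented
#' green-channel dichotomization point for PanCK-stained DSP images; note
#' that a value of 10 has also been reported for the same kind of data, so
#' the cutoff is always an explicit parameter and is never auto-selected.
#'
#' @param cells a feature table from [extract_features()].
#' @param channel intensity channel (default `"G"`).
#' @param cutoff intensity boundary (0-255 scale).
#' @return A `TypingResult`.
#' @export
classify_cutoff <- function(cells, channel = "G", cutoff = 20) {
  if (nrow(cells) == 0) {
    sr_stop("spatroi_empty_input_error", "cannot classify an empty cell table")
  }
  v <- channel_column(cells, channel)
  typing_result("cutoff", toupper(channel), cutoff,
                ifelse(v > cutoff, "positive", "negative"))
}

#' Classify cells with a Gaussian mixture model
#'
#' Fits a `k`-component GMM (default 2) to the selected intensity column(s)
#' and labels the component with the higher mean on `positive_channel` as
#' positive (never by component index, which is fit-dependent). In the 1-D
#' case `threshold_used` is the intensity at which the posterior
#' responsibilities cross 0.5 between the two extreme-mean components; in 2-D
#' it is `NaN`.
#'
#' When the fitted components are not separated (mean difference below half
#' the summed component SDs, or a failed fit) the classification falls back
#' to a cutoff at the midpoint of the component means, with a warning.
#'
#' @param cells a feature table.
#' @param channels intensity channels used for the fit (`"G"`, or
#'   `c("R", "G")` for the red-vs-green plane).
#' @param k number of mixture components.
#' @param positive_channel channel whose higher mean defines the positive
#'   class.
#' @param seed RNG seed for the fit.
#' @return A `TypingResult`.
#' @export
classify_gmm <- function(cells, channels = "G", k = 2,
                         positive_channel = "G", seed = 0) {
  if (nrow(cells) == 0) {
    sr_stop("spatroi_empty_input_error", "cannot classify an empty cell table")
  }
  if (nrow(cells) < 2 * k) {
    sr_stop("spatroi_fit_error",
            "need at least %d cells to fit %d components (have %d)",
            2 * k, k, nrow(cells))
  }
  dat <- sapply(channels, function(ch) channel_column(cells, ch))
  dat <- matrix(dat, nrow = nrow(cells))
  pos_v <- channel_column(cells, positive_channel)
  pos_dim <- match(toupper(positive_channel), toupper(channels))

  # Mclust() resolves helper functions in the caller's scope, which fails
  # when mclust is not attached; a local binding satisfies the lookup.
  mclustBIC <- mclust::mclustBIC
  x <- if (ncol(dat) == 1) dat[, 1] else dat
  fit <- with_seed(seed, tryCatch(
    mclust::Mclust(x, G = k, verbose = FALSE),
    error = function(e) NULL))
  # a k-component fit on single-cluster data is degenerate; detect it by
  # model evidence (BIC prefers fewer components) rather than by eyeballing
  # the fitted variances
  bic_all <- with_seed(seed, tryCatch(
    mclust::mclustBIC(x, G = seq_len(k), verbose = FALSE),
    error = function(e) NULL))
  bic_prefers_fewer <- FALSE
  if (!is.null(bic_all) && k > 1) {
    best <- which(bic_all == max(bic_all, na.rm = TRUE), arr.ind = TRUE)
    bic_prefers_fewer <- as.integer(rownames(bic_all)[best[1, 1]]) < k
  }

  fallback <- function(mu_lo, mu_hi) {
    mid <- (mu_lo + mu_hi) / 2
    sr_warn("spatroi_degenerate_fit_warning",
            "GMM components degenerate; falling back to cutoff at %.3f", mid)
    typing_result("gmm", toupper(positive_channel), mid,
                  ifelse(pos_v > mid, "positive", "negative"))
  }
  if (is.null(fit)) {
    return(fallback(min(pos_v), max(pos_v)))
  }
  mu <- fit$parameters$mean
  comp_mu <- if (is.matrix(mu)) mu[if (is.na(pos_dim)) 1 else pos_dim, ] else mu
  hi <- which.max(comp_mu); lo <- which.min(comp_mu)
  sd_of <- function(g) {
    v <- fit$parameters$variance
    if (!is.null(v$sigmasq)) {
      sqrt(if (length(v$sigmasq) == 1) v$sigmasq else v$sigmasq[g])
    } else {
      s <- if (length(dim(v$sigma)) == 3) v$sigma[, , g] else v$sigma
      d <- if (is.na(pos_dim)) 1 else pos_dim
      sqrt(s[d, d])
    }
  }
  if (hi == lo || bic_prefers_fewer ||
      (comp_mu[hi] - comp_mu[lo]) < 0.5 * (sd_of(hi) + sd_of(lo))) {
    return(fallback(comp_mu[lo], comp_mu[hi]))
  }
  labels <- ifelse(fit$classification == hi, "positive", "negative")
  threshold <- NaN
  if (ncol(dat) == 1) {
    p <- fit$parameters
    post_diff <- function(x) {
      dhi <- p$pro[hi] * stats::dnorm(x, comp_mu[hi], sd_of(hi))
      dlo <- p$pro[lo] * stats::dnorm(x, comp_mu[lo], sd_of(lo))
      dhi - dlo
    }
    threshold <- tryCatch(
      stats::uniroot(post_diff, c(comp_mu[lo], comp_mu[hi]))$root,
      error = function(e) NaN)
  }
  typing_result("gmm", toupper(positive_channel), threshold, labels)
}

#' Classify cells with K-means clustering
#'
#' As [classify_gmm()] but with centroid-based assignment. The cluster with
#' the higher centre on `positive_channel` is positive. With `k = 1` every
#' cell is labelled positive (with a warning). In the 1-D 2-cluster case
#' `threshold_used` is the midpoint of the two centres (the assignment
#' boundary).
#'
#' @inheritParams classify_gmm
#' @return A `TypingResult`.
#' @export
classify_kmeans <- function(cells, channels = "G", k = 2,
                            positive_channel = "G", seed = 0) {
  if (nrow(cells) == 0) {
    sr_stop("spatroi_empty_input_error", "cannot classify an empty cell table")
  }
  if (nrow(cells) < 2 * k) {
    sr_stop("spatroi_fit_error",
            "need at least %d cells to fit %d clusters (have %d)",
            2 * k, k, nrow(cells))
  }
  if (k == 1) {
    sr_warn("spatroi_parameter_warning",
            "k = 1: all cells assigned to the positive class")
    return(typing_result("kmeans", toupper(positive_channel), NaN,
                         rep("positive", nrow(cells))))
  }
  dat <- sapply(channels, function(ch) channel_column(cells, ch))
  dat <- matrix(dat, nrow = nrow(cells))
  pos_dim <- match(toupper(positive_channel), toupper(channels))
  if (is.na(pos_dim)) pos_dim <- 1L
  fit <- with_seed(seed, stats::kmeans(dat, centers = k, nstart = 10))
  hi <- which.max(fit$centers[, pos_dim])
  labels <- ifelse(fit$cluster == hi, "positive", "negative")
  threshold <- NaN
  if (ncol(dat) == 1 && k == 2) {
    threshold <- mean(range(fit$centers[, 1]))
  }
  typing_result("kmeans", toupper(positive_channel), threshold, labels)
}

#' Attach typing labels to a cell table
#'
#' @param cells a feature table.
#' @param typing a `TypingResult` computed on the same table.
#' @return The table with `class_label` filled in.
#' @export
apply_typing <- function(cells, typing) {
  stopifnot(inherits(typing, "TypingResult"),
            typing$n_total == nrow(cells))
  cells$class_label <- as.character(typing$labels)
  cells
}

# Count the modes of a kernel density estimate, ignoring bumps below
# `min_height` of the global maximum.
count_density_modes <- function(v, min_height = 0.1) {
  d <- stats::density(v)
  y <- d$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1
  sum(y[peaks] >= min_height * max(y))
}

#' Per-channel intensity density report
#'
#' Writes kernel-density plots of the mean R/G/B intensities per cell plus
#' the red-vs-green scatter (coloured by `class_label` when present), and
#' reports a bimodality diagnostic for the green channel (the number of KDE
#' modes at least 10 percent of the maximum density).
#'
#' @param cells a feature table.
#' @param out_dir output directory for the PNG files (created if needed).
#' @return A list: `paths` (named character vector of written files) and
#'   `green_modes` (mode count, `NA` for an empty table).
#' @export
intensity_density_report <- function(cells, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (nrow(cells) == 0) {
    sr_warn("spatroi_empty_input_warning",
            "empty cell table: writing no density plots")
    return(list(paths = character(0), green_modes = NA_integer_))
  }
  chans <- c(r = "mean_r", g = "mean_g", b = "mean_b")
  cols <- c(r = "firebrick", g = "forestgreen", b = "royalblue")
  paths <- character(0)
  for (ch in names(chans)) {
    p <- file.path(out_dir, sprintf("density_%s.png", ch))
    grDevices::png(p, width = 600, height = 450)
    plot(stats::density(cells[[chans[[ch]]]]), col = cols[[ch]], lwd = 2,
         main = sprintf("Mean %s intensity per cell", toupper(ch)),
         xlab = "intensity (0-255)")
    grDevices::dev.off()
    paths[[sprintf("density_%s", ch)]] <- p
  }
  p <- file.path(out_dir, "scatter_rg.png")
  grDevices::png(p, width = 600, height = 600)
  col <- if (all(!is.na(cells$class_label))) {
    ifelse(cells$class_label == "positive", "forestgreen", "grey40")
  } else "grey40"
  plot(cells$mean_r, cells$mean_g, col = col, pch = 19, cex = 0.6,
       xlab = "mean red intensity", ylab = "mean green intensity",
       main = "Red vs green per-cell intensities")
  grDevices::dev.off()
  paths[["scatter_rg"]] <- p
  list(paths = paths, green_modes = count_density_modes(cells$mean_g))
}

#' Annotated segmentation snapshot
#'
#' Writes a side-by-side PNG: the original ROI image next to an overlay in
#' which positive cells are outlined in orange and negative cells in cyan,
#' headed by the total cell count, positive count and positive percentage
#' (two decimals). Output pixels are deterministic for fixed input.
#'
#' @param img the cropped `RoiImage`.
#' @param mask the `LabelMask` used for typing.
#' @param typing a `TypingResult` whose `n_total` matches `mask$n_cells`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
annotate_snapshot <- function(img, mask, typing, path) {
  stopifnot(inherits(img, "RoiImage"), inherits(mask, "LabelMask"),
            inherits(typing, "TypingResult"),
            typing$n_total == mask$n_cells)
  rgb_eb <- EBImage::Image(aperm(img$pixels, c(2, 1, 3)) / 255,
                           colormode = "Color")
  pos_ids <- which(typing$labels == "positive")
  pos_mask <- mask$labels; pos_mask[!(pos_mask %in% pos_ids)] <- 0L
  neg_mask <- mask$labels; neg_mask[neg_mask %in% c(0L, pos_ids)] <- 0L
  overlay <- rgb_eb
  if (any(pos_mask > 0)) {
    overlay <- EBImage::paintObjects(as_eb(pos_mask), overlay, col = "#FF8C00")
  }
  if (any(neg_mask > 0)) {
    overlay <- EBImage::paintObjects(as_eb(neg_mask), overlay, col = "#00C5FF")
  }
  h <- nrow(img$pixels); w <- ncol(img$pixels)
  grDevices::png(path, width = 2 * w + 30, height = h + 60)
  graphics::par(mfrow = c(1, 2), mar = c(0.5, 0.5, 3.5, 0.5))
  for (im in list(rgb_eb, overlay)) {
    graphics::plot(c(0, w), c(0, h), type = "n", axes = FALSE, xlab = "",
                   ylab = "", asp = 1)
    graphics::rasterImage(aperm(EBImage::imageData(im), c(2, 1, 3)),
                          0, 0, w, h)
  }
  graphics::mtext(sprintf("Total cells: %d   Positive: %d (%s)",
                          typing$n_total, typing$n_positive,
                          format_positive_pct(typing$n_positive,
                                              typing$n_total)),
                  outer = TRUE, line = -2, cex = 1.2)
  grDevices::dev.off()
  invisible(path)
}
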