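#' Specification for a rendered synthetic ROI image
#'
#' Describes a synthetic multiplex-IF ROI image: a circular tissue region on a
#' white margin containing two cell populations (marker-positive vs negative)
#' whose green-channel intensities are drawn from class-specific normal
#' distributions. Defaults mirror the geometry of DSP exports: a 600 x 600 px
#' image with a radius-150 circular ROI, blue-stained nuclei, and a green
#' marker channel separating the two classes.
#'
#' @param image_size_px side length of the square image.
#' @param roi_radius_px radius of the circular ROI.
#' @param n_positive,n_negative cells per class.
#' @param cell_radius_px `c(mean, sd)` of cell radii in pixels.
#' @param green_positive,green_negative `c(mean, sd)` green intensity per class.
#' @param red_params,blue_params `c(mean, sd)` for the red and blue (nuclear)
#'   channels, shared by both classes.
#' @param overlap_allowed if `FALSE` (default) cells are placed with a gap so
#'   that rendered cells never touch.
#' @param tissue_rgb RGB intensities of the tissue background inside the ROI
#'   (non-white so the ROI is detectable; dim green so the marker channel
#'   stays class-separable).
#' @param separable declare the two classes separable; requires the class
#'   green means to differ by at least one pooled SD.
#' @param seed RNG seed; generation is fully deterministic given the spec.
#' @return An object of class `image_fixture_spec`.
#' @export
image_fixture_spec <- function(image_size_px = 600, roi_radius_px = 150,
                               n_positive = 50, n_negative = 50,
                               cell_radius_px = c(5, 0.8),
                               green_positive = c(60, 8),
                               green_negative = c(8, 2),
                               red_params = c(15, 5),
                               blue_params = c(200, 20),
                               overlap_allowed = FALSE,
                               tissue_rgb = c(12, 2, 14),
                               separable = TRUE,
                               seed = 0) {
  if (separable) {
    pooled_sd <- sqrt((green_positive[2]^2 + green_negative[2]^2) / 2)
    if (abs(green_positive[1] - green_negative[1]) < pooled_sd) {
      sr_stop("spatroi_parameter_error",
              "separable fixture requires class green means >= 1 SD apart")
    }
  }
  structure(as.list(environment()), class = "image_fixture_spec")
}

# Non-overlapping centres in a disc by rejection (random sequential placement).
place_centres <- function(n, cx, cy, placement_radius, min_sep,
                          max_tries = 200000L) {
  xs <- numeric(n); ys <- numeric(n)
  placed <- 0L
  tries <- 0L
  while (placed < n && tries < max_tries) {
    tries <- tries + 1L
    rr <- placement_radius * sqrt(stats::runif(1))
    th <- 2 * pi * stats::runif(1)
    x <- cx + rr * cos(th); y <- cy + rr * sin(th)
    if (placed == 0L ||
        min((xs[seq_len(placed)] - x)^2 + (ys[seq_len(placed)] - y)^2) >=
        min_sep^2) {
      placed <- placed + 1L
      xs[placed] <- x; ys[placed] <- y
    }
  }
  if (placed < n) {
    sr_stop("spatroi_parameter_error",
            "could not place %d non-overlapping cells (placed %d); enlarge the ROI",
            n, placed)
  }
  cbind(x = xs, y = ys)
}

#' Render a synthetic ROI image with ground truth
#'
#' Renders anti-aliased elliptical cells inside a circular ROI on a white
#' background. Each cell receives per-channel intensities drawn from the class
#' distributions in the spec; channels are painted additively over a dark
#' tissue background, blurred with a mild Gaussian (sigma 1 px) to emulate
#' optical blur, and clipped at 255. Output is deterministic for a fixed spec
#' (including its seed).
#'
#' @param spec an [image_fixture_spec()].
#' @param dir optional output directory; when given, the image is written as
#'   `roi_<seed>.tiff` with the ground truth as `roi_<seed>_truth.csv`.
#' @return A list with `image` (an uncropped `RoiImage`), `truth` (data frame
#'   with one row per rendered cell: `label`, `x`, `y`, `radius`, `class`,
#'   `green`, `red`, `blue`) and, when `dir` is given, `tiff_path` /
#'   `truth_path`.
#' @export
make_roi_image <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "image_fixture_spec"))
  with_seed(spec$seed, {
    n <- spec$n_positive + spec$n_negative
    sz <- spec$image_size_px
    c0 <- (sz - 1) / 2  # 0-based centre of the image
    radii <- pmax(2, stats::rnorm(n, spec$cell_radius_px[1],
                                  spec$cell_radius_px[2]))
    max_r <- if (n) max(radii) else 0
    min_sep <- if (spec$overlap_allowed) 0 else 2 * max_r + 4
    centres <- if (n) {
      place_centres(n, c0, c0, spec$roi_radius_px - max_r - 3, min_sep)
    } else {
      cbind(x = numeric(), y = numeric())
    }
    cls <- rep(c("positive", "negative"),
               c(spec$n_positive, spec$n_negative))
    g_mu <- ifelse(cls == "positive", spec$green_positive[1],
                   spec$green_negative[1])
    g_sd <- ifelse(cls == "positive", spec$green_positive[2],
                   spec$green_negative[2])
    green <- pmax(0, stats::rnorm(n, g_mu, g_sd))
    red <- pmax(0, stats::rnorm(n, spec$red_params[1], spec$red_params[2]))
    blue <- pmax(0, stats::rnorm(n, spec$blue_params[1], spec$blue_params[2]))

    # white margin, dark tissue inside the ROI
    tissue <- spec$tissue_rgb
    px <- array(255, c(sz, sz, 3))
    roi <- disc_mask(sz, sz, c0, c0, spec$roi_radius_px)
    for (ch in 1:3) {
      plane <- px[, , ch]
      plane[roi] <- tissue[ch]
      px[, , ch] <- plane
    }

    ecc <- stats::runif(n, 0.85, 1.15)   # ellipse aspect
    ang <- stats::runif(n, 0, pi)
    for (i in seq_len(n)) {
      a <- radii[i] * ecc[i]; b <- radii[i] / ecc[i]
      cxp <- centres[i, 1]; cyp <- centres[i, 2]
      r_lo <- max(1L, floor(cyp - radii[i] - 2) + 1L)
      r_hi <- min(sz, ceiling(cyp + radii[i] + 2) + 1L)
      c_lo <- max(1L, floor(cxp - radii[i] - 2) + 1L)
      c_hi <- min(sz, ceiling(cxp + radii[i] + 2) + 1L)
      rows <- r_lo:r_hi; cols <- c_lo:c_hi
      dy <- outer(rows - 1 - cyp, rep(1, length(cols)))
      dx <- outer(rep(1, length(rows)), cols - 1 - cxp)
      u <- dx * cos(ang[i]) + dy * sin(ang[i])
      v <- -dx * sin(ang[i]) + dy * cos(ang[i])
      rho <- sqrt((u / a)^2 + (v / b)^2)
      alpha <- pmin(1, pmax(0, (1 - rho) * radii[i] + 0.5))  # anti-aliased edge
      add <- list(red[i], green[i], blue[i])
      for (ch in 1:3) {
        plane <- px[rows, cols, ch]
        px[rows, cols, ch] <- plane + alpha * add[[ch]]
      }
    }
    for (ch in 1:3) {
      blurred <- from_eb(EBImage::gblur(as_eb(px[, , ch] / 255), sigma = 1))
      px[, , ch] <- pmin(255, pmax(0, round(blurred * 255)))
    }
    truth <- data.frame(
      label = seq_len(n), x = centres[, 1], y = centres[, 2],
      radius = radii, class = cls, green = green, red = red, blue = blue,
      stringsAsFactors = FALSE
    )
    out <- list(image = roi_image(px), truth = truth)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      out$tiff_path <- file.path(dir, sprintf("roi_%d.tiff", spec$seed))
      out$truth_path <- file.path(dir, sprintf("roi_%d_truth.csv", spec$seed))
      tiff::writeTIFF(px / 255, out$tiff_path, bits.per.sample = 8)
      utils::write.csv(truth, out$truth_path, row.names = FALSE)
    }
    out
  })
}

#' Specification for a synthetic marked point pattern
#'
#' @param window_radius radius of the circular observation window (pixels).
#' @param n_positive,n_negative points per mark.
#' @param regime one of `"csr"` (two independent uniform populations),
#'   `"attraction"` (each negative point placed within `distance` of a random
#'   positive point) or `"segregation"` (marks confined to opposite
#'   half-discs along `axis`).
#' @param distance attraction radius in pixels (attraction regime).
#' @param axis `"x"` or `"y"` split axis (segregation regime).
#' @param seed RNG seed.
#' @return An object of class `pattern_fixture_spec`.
#' @export
pattern_fixture_spec <- function(window_radius = 150, n_positive = 200,
                                 n_negative = 200,
                                 regime = c("csr", "attraction", "segregation"),
                                 distance = 5, axis = c("x", "y"), seed = 0) {
  regime <- match.arg(regime)
  axis <- match.arg(axis)
  if (regime == "attraction" &&
      (distance <= 0 || distance > window_radius)) {
    sr_stop("spatroi_parameter_error",
            "attraction distance must be in (0, window_radius]")
  }
  structure(as.list(environment()), class = "pattern_fixture_spec")
}

runif_disc <- function(n, cx, cy, radius) {
  rr <- radius * sqrt(stats::runif(n))
  th <- 2 * pi * stats::runif(n)
  cbind(x = cx + rr * cos(th), y = cy + rr * sin(th))
}

#' Generate a marked point pattern under a controlled mixing regime
#'
#' `csr` plants two independent homogeneous populations (the null for the
#' cross-K mixing score); `attraction` plants negatives near positives
#' (positive mixing score expected); `segregation` confines the marks to
#' opposite half-discs (negative score expected).
#'
#' @param spec a [pattern_fixture_spec()].
#' @return A `MarkedPointPattern`; see [point_pattern()].
#' @export
make_pattern <- function(spec) {
  stopifnot(inherits(spec, "pattern_fixture_spec"))
  R <- spec$window_radius
  with_seed(spec$seed, {
    if (spec$regime == "csr") {
      p <- runif_disc(spec$n_positive, 0, 0, R)
      q <- runif_disc(spec$n_negative, 0, 0, R)
    } else if (spec$regime == "attraction") {
      p <- runif_disc(spec$n_positive, 0, 0, R)
      q <- matrix(NA_real_, 0, 2)
      while (nrow(q) < spec$n_negative) {
        anchor <- p[sample.int(nrow(p), 1), ]
        cand <- runif_disc(1, anchor[1], anchor[2], spec$distance)
        if (sum(cand^2) <= R^2) q <- rbind(q, cand)
      }
      colnames(q) <- c("x", "y")
    } else {  # segregation: opposite half-discs
      draw_half <- function(n, positive_side) {
        out <- matrix(NA_real_, 0, 2)
        while (nrow(out) < n) {
          cand <- runif_disc(2 * n, 0, 0, R)
          coord <- if (spec$axis == "x") cand[, 1] else cand[, 2]
          keep <- if (positive_side) coord < 0 else coord >= 0
          out <- rbind(out, cand[keep, , drop = FALSE])
        }
        out[seq_len(n), , drop = FALSE]
      }
      p <- draw_half(spec$n_positive, TRUE)
      q <- draw_half(spec$n_negative, FALSE)
    }
    point_pattern(x = c(p[, 1], q[, 1]), y = c(p[, 2], q[, 2]),
                  marks = rep(c("positive", "negative"),
                              c(nrow(p), nrow(q))),
                  center = c(0, 0), radius = R)
  })
}

#' Generate a synthetic probe-level expression fixture with ground truth
#'
#' Builds a probe x segment count matrix emulating DSP RNA output: log-normal
#' gene baselines, per-segment multiplicative scale factors, 2-4 probes per
#' gene with multiplicative probe noise, planted gene-gene correlations
#' through shared latent factors, and constructed detection failures for
#' exercising the segment/gene filters.
#'
#' @param n_genes,n_segments matrix dimensions at the gene level.
#' @param planted_scales per-segment scale factors (length `n_segments`), or
#'   `NULL` for all 1.
#' @param planted_pairs data frame with columns `ligand`, `target`, `true_r`:
#'   gene pairs generated with the given Pearson correlation. Gene names refer
#'   to the generated ids `G1..Gn`.
#' @param n_low_detect_segments number of segments constructed to fall below
#'   a 5 percent detection fraction (they keep only 2 detected genes).
#' @param n_rare_genes number of genes constructed to be detected in exactly
#'   one segment (dropped by a 10 percent gene filter when `n_segments >= 11`).
#' @param cv coefficient of variation of gene expression across segments.
#' @param seed RNG seed.
#' @return A list: `probe_matrix` (probes x segments), `probe_to_gene`
#'   (data frame `probe`, `gene`), `table` (a curated ligand-target table
#'   containing the planted pairs plus decoys), and `truth` (gene-level
#'   matrix before probe noise, the scale factors, ids of the constructed
#'   low-detection segments and rare genes, and the planted pairs).
#' @export
make_expression <- function(n_genes = 80, n_segments = 20,
                            planted_scales = NULL, planted_pairs = NULL,
                            n_low_detect_segments = 0, n_rare_genes = 0,
                            cv = 0.3, seed = 0) {
  stopifnot(n_genes >= 4, n_segments >= 3)
  if (is.null(planted_scales)) planted_scales <- rep(1, n_segments)
  stopifnot(length(planted_scales) == n_segments)
  with_seed(seed, {
    genes <- sprintf("G%d", seq_len(n_genes))
    segments <- sprintf("S%d", seq_len(n_segments))
    mu <- stats::rlnorm(n_genes, meanlog = 4, sdlog = 0.8)

    # latent standard-normal variation per gene x segment
    z <- matrix(stats::rnorm(n_genes * n_segments), n_genes, n_segments)
    if (!is.null(planted_pairs)) {
      for (i in seq_len(nrow(planted_pairs))) {
        li <- match(planted_pairs$ligand[i], genes)
        ti <- match(planted_pairs$target[i], genes)
        r <- planted_pairs$true_r[i]
        stopifnot(!is.na(li), !is.na(ti), abs(r) <= 1)
        f <- stats::rnorm(n_segments)
        z[li, ] <- f
        z[ti, ] <- r * f + sqrt(1 - r^2) * stats::rnorm(n_segments)
      }
    }
    gene_values <- pmax(mu * (1 + cv * z), 0)

    rare_genes <- character(0)
    if (n_rare_genes > 0) {
      planted_gene_ids <- if (is.null(planted_pairs)) character(0) else
        c(planted_pairs$ligand, planted_pairs$target)
      pool <- setdiff(genes, planted_gene_ids)
      rare_genes <- utils::tail(pool, n_rare_genes)
      for (g in rare_genes) {
        gi <- match(g, genes)
        keep <- sample.int(n_segments, 1)
        gene_values[gi, -keep] <- 0
      }
    }
    low_segments <- character(0)
    if (n_low_detect_segments > 0) {
      low_segments <- utils::tail(segments, n_low_detect_segments)
      for (s in low_segments) {
        si <- match(s, segments)
        keep <- sample.int(n_genes, 2)  # 2 detected genes << 5% of the panel
        gene_values[-keep, si] <- 0
      }
    }

    n_probes <- sample(2:4, n_genes, replace = TRUE)
    probe_gene <- rep(genes, n_probes)
    probes <- sprintf("%s_P%d", probe_gene,
                      unlist(lapply(n_probes, seq_len)))
    eff <- stats::rlnorm(length(probes), 0, 0.1)
    probe_matrix <- gene_values[match(probe_gene, genes), , drop = FALSE] *
      eff *
      matrix(stats::rlnorm(length(probes) * n_segments, 0, 0.05),
             length(probes), n_segments)
    probe_matrix <- sweep(probe_matrix, 2, planted_scales, `*`)
    dimnames(probe_matrix) <- list(probes, segments)

    table <- NULL
    if (!is.null(planted_pairs)) {
      decoys <- data.frame(
        ligand = genes[seq_len(min(4, n_genes))],
        target = genes[n_genes - seq_len(min(4, n_genes)) + 1],
        source_kind = "curated", stringsAsFactors = FALSE)
      table <- rbind(
        data.frame(ligand = planted_pairs$ligand,
                   target = planted_pairs$target,
                   source_kind = "curated", stringsAsFactors = FALSE),
        decoys)
      table <- table[!duplicated(table[, c("ligand", "target")]), ]
    }
    list(
      probe_matrix = probe_matrix,
      probe_to_gene = data.frame(probe = probes, gene = probe_gene,
                                 stringsAsFactors = FALSE),
      table = table,
      truth = list(gene_values = `dimnames<-`(gene_values,
                                              list(genes, segments)),
                   scales = planted_scales,
                   low_detect_segments = low_segments,
                   rare_genes = rare_genes,
                   planted_pairs = planted_pairs)
    )
  })
}
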