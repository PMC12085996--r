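#' Segmentation parameters
#'
#' Parameters shared by all segmentation backends. The defaults mirror the
#' pipeline defaults used for DSP ROI images: an expected cell diameter of
#' 23 px and a backend-specific quality threshold of 0.4. Channels are named
#' explicitly (`"R"`, `"G"`, `"B"`) rather than by index: nuclei are stained
#' blue (DNA dye) and the cytoplasm/marker stain (e.g. PanCK) is green.
#'
#' @param diameter_px expected cell diameter in pixels (> 0).
#' @param flow_threshold quality threshold passed through to backends that use
#'   one (the reference backend ignores it).
#' @param nuclear_channel channel carrying the nuclear stain.
#' @param cyto_channel channel carrying the cytoplasm/marker stain.
#' @return An object of class `seg_params`.
#' @export
seg_params <- function(diameter_px = 23, flow_threshold = 0.4,
                       nuclear_channel = "B", cyto_channel = "G") {
  if (diameter_px <= 0) {
    sr_stop("spatroi_parameter_error", "diameter_px must be > 0")
  }
  nuc <- channel_index(nuclear_channel)
  cyto <- channel_index(cyto_channel)
  if (nuc == cyto) {
    sr_stop("spatroi_parameter_error",
            "nuclear_channel and cyto_channel must be distinct")
  }
  structure(list(diameter_px = diameter_px, flow_threshold = flow_threshold,
                 nuclear_channel = toupper(nuclear_channel),
                 cyto_channel = toupper(cyto_channel)),
            class = "seg_params")
}

# Backend registry: name -> function(img, params) returning an integer label
# matrix (0 = background). Registered at load time; plugins may add adapters
# for neural backends conforming to the same contract.
.backends <- new.env(parent = emptyenv())

#' Register a segmentation backend
#'
#' @param name backend name used in [segment_cells()].
#' @param fun `function(img, params)` returning an integer label matrix of the
#'   same spatial shape as `img$pixels` with 0 for background.
#' @return `name`, invisibly.
#' @export
register_segmentation_backend <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1, is.function(fun))
  assign(name, fun, envir = .backends)
  invisible(name)
}

#' List registered segmentation backends
#' @return Character vector of backend names.
#' @export
list_segmentation_backends <- function() {
  sort(ls(.backends))
}

#' Segment cells in a cropped ROI image
#'
#' Dispatches to a registered backend and enforces the label-mask contract:
#' labelled pixels are restricted to the ROI mask, cells whose centroid falls
#' outside the mask are dropped (margin artifacts), and labels are recompacted
#' to a consecutive 1..n_cells range.
#'
#' @param img a cropped `RoiImage`.
#' @param params a [seg_params()] object.
#' @param backend name of a registered backend (default `"reference"`).
#' @return An object of class `LabelMask` with elements `labels` (integer
#'   matrix) and `n_cells`.
#' @export
segment_cells <- function(img, params = seg_params(), backend = "reference") {
  stopifnot(inherits(img, "RoiImage"), inherits(params, "seg_params"))
  if (!isTRUE(img$cropped) || is.null(img$roi_mask)) {
    sr_stop("spatroi_parameter_error",
            "segment_cells() requires a cropped RoiImage; run crop_roi() first")
  }
  if (!any(img$roi_mask)) {
    sr_stop("spatroi_empty_roi_error", "roi_mask is empty")
  }
  if (!exists(backend, envir = .backends)) {
    sr_stop("spatroi_configuration_error",
            "unknown segmentation backend '%s'; registered backends: %s",
            backend, paste(list_segmentation_backends(), collapse = ", "))
  }
  fun <- get(backend, envir = .backends)
  labels <- fun(img, params)
  stopifnot(all(dim(labels) == dim(img$pixels)[1:2]))
  labels <- matrix(as.integer(round(labels)), nrow(labels), ncol(labels))

  labels[!img$roi_mask] <- 0L
  labels <- drop_outside_centroids(labels, img$roi_mask)
  labels <- compact_labels(labels)
  structure(list(labels = labels, n_cells = max(labels)), class = "LabelMask")
}

#' @export
print.LabelMask <- function(x, ...) {
  cat(sprintf("LabelMask: %d x %d px, %d cells\n",
              nrow(x$labels), ncol(x$labels), x$n_cells))
  invisible(x)
}

# Drop labels whose (unweighted) centroid lies outside the ROI mask.
drop_outside_centroids <- function(labels, roi_mask) {
  if (!any(labels > 0)) return(labels)
  idx <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[labels > 0]
  cy <- round(rowsum(idx[, 1], lab) / tabulate(lab)[sort(unique(lab))])
  cx <- round(rowsum(idx[, 2], lab) / tabulate(lab)[sort(unique(lab))])
  ids <- as.integer(rownames(cy))
  inside <- roi_mask[cbind(pmin(pmax(cy, 1), nrow(roi_mask)),
                           pmin(pmax(cx, 1), ncol(roi_mask)))]
  drop <- ids[!inside]
  if (length(drop)) labels[labels %in% drop] <- 0L
  labels
}

# Relabel to consecutive 1..n preserving raster-scan order of first occurrence.
compact_labels <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids)) return(labels)
  map <- integer(max(ids))
  map[ids] <- seq_along(ids)
  out <- labels
  out[out > 0] <- map[out[out > 0]]
  out
}

# Otsu threshold of a value vector on [0, 1] (256-bin histogram). Needed
# because the threshold must be computed over in-mask pixels only, not the
# full rectangular raster.
otsu_threshold <- function(v, n_bins = 256) {
  h <- tabulate(pmin(floor(v * n_bins) + 1, n_bins), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(n_bins) - 0.5))
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  (which.max(sigma_b)) / n_bins
}

#' Classical reference segmentation backend
#'
#' A deterministic, weight-free segmenter used as the default backend: smooth
#' the nuclear channel (Gaussian, sigma = `diameter_px / 8`), threshold it
#' (Otsu over in-mask pixels), locate distance-transform peaks with minimum
#' separation `diameter_px / 2`, grow the peaks through a marker-controlled
#' watershed over the foreground, and remove components smaller than
#' `(diameter_px / 4)^2` pixels. Identical input yields an identical label
#' raster.
#'
#' @param img a cropped `RoiImage`.
#' @param params a [seg_params()] object.
#' @return Integer label matrix (0 = background). Usually called through
#'   [segment_cells()], which applies the mask/centroid/compaction contract.
#' @export
reference_backend <- function(img, params = seg_params()) {
  d <- params$diameter_px
  # erode the ROI mask a few pixels: the fitted circle brushes the bright
  # margin transition, which would otherwise surface as false-positive cells
  # along the ROI boundary
  work_mask <- img$roi_mask &
    from_eb(EBImage::erode(as_eb(img$roi_mask + 0),
                           EBImage::makeBrush(7, "disc"))) > 0
  if (!any(work_mask)) work_mask <- img$roi_mask
  nuc <- img$pixels[, , channel_index(params$nuclear_channel)] / 255
  nuc[!work_mask] <- 0

  sm <- from_eb(EBImage::gblur(as_eb(nuc), sigma = max(d / 8, 0.5)))
  inside <- sm[work_mask]
  if (max(inside) <= min(inside)) {
    return(matrix(0L, nrow(nuc), ncol(nuc)))  # uniform image: nothing to find
  }
  thr <- otsu_threshold(inside)
  binary <- sm > thr & work_mask
  if (!any(binary)) {
    return(matrix(0L, nrow(nuc), ncol(nuc)))
  }

  dist <- from_eb(EBImage::distmap(as_eb(binary)))
  # mild smoothing removes spurious distance-map maxima caused by ragged
  # (anti-aliased) foreground boundaries; peaks are found on the smoothed map
  dist_s <- from_eb(EBImage::gblur(as_eb(dist), sigma = max(d / 8, 0.5)))
  dist_s[!binary] <- 0

  # Distance-transform peaks with minimum separation d/2: local maxima under a
  # disc-shaped maximum filter, deduplicated greedily by decreasing height.
  brush_size <- 2L * max(1L, as.integer(floor(d / 4))) + 1L
  brush <- EBImage::makeBrush(brush_size, shape = "disc")
  dil <- from_eb(EBImage::imageData(
    EBImage::dilate(as_eb(dist_s), brush)))
  peak <- dist_s > 0 & dist_s >= dil

  peak_labels <- from_eb(EBImage::bwlabel(as_eb(peak)))
  n_peaks <- max(peak_labels)
  if (n_peaks == 0) {
    return(matrix(0L, nrow(nuc), ncol(nuc)))
  }
  idx <- which(peak_labels > 0, arr.ind = TRUE)
  lab <- peak_labels[peak_labels > 0]
  cnt <- tabulate(lab, n_peaks)
  pr <- round(rowsum(idx[, 1], lab)[, 1] / cnt)  # plateau centroid, rounded
  pc <- round(rowsum(idx[, 2], lab)[, 1] / cnt)
  ph <- dist_s[cbind(pr, pc)]
  ord <- order(-ph, pr, pc)
  keep <- logical(n_peaks)
  min_sep2 <- (d / 2)^2
  for (i in ord) {
    ok <- TRUE
    for (j in which(keep)) {
      if ((pr[i] - pr[j])^2 + (pc[i] - pc[j])^2 < min_sep2) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  seeds <- matrix(0L, nrow(nuc), ncol(nuc))
  kept <- which(keep)
  seeds[cbind(pr[kept], pc[kept])] <- seq_along(kept)

  # Marker-controlled watershed: geodesic growth of the seeds across the
  # foreground; a large lambda makes spatial distance dominate intensity.
  grown <- from_eb(EBImage::imageData(EBImage::propagate(
    as_eb(dist), as_eb(seeds), mask = as_eb(binary), lambda = 100)))
  grown <- matrix(as.integer(round(grown)), nrow(grown), ncol(grown))

  sizes <- tabulate(grown[grown > 0])
  small <- which(sizes < (d / 4)^2)
  if (length(small)) grown[grown %in% small] <- 0L
  compact_labels(grown)
}
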