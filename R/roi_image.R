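#' RoiImage: a DSP ROI raster with its circular mask
#'
#' An `RoiImage` bundles an RGB pixel array with the circular region-of-interest
#' mask that separates tissue from the exported white margin. Pixel intensities
#' are on the 0-255 scale regardless of the source bit depth. The coordinate
#' convention throughout the package is x = column, y = row, origin at the
#' top-left corner, 0-based.
#'
#' @param pixels numeric array `(rows, cols, 3)` with channels ordered R, G, B
#'   and intensities in `[0, 255]`.
#' @param roi_mask logical matrix of the same spatial shape, `TRUE` inside the
#'   ROI, or `NULL` for an image that has not been cropped yet.
#' @param center numeric `(x, y)` of the ROI centre in 0-based pixel
#'   coordinates, or `NULL` if unknown.
#' @param radius_px ROI radius in pixels, or `NULL` if unknown.
#' @param um_per_px physical scale in micrometres per pixel; `NA` when unknown,
#'   in which case all spatial statistics are reported in pixels.
#' @param cropped logical; `TRUE` once [crop_roi()] has been applied.
#'
#' @return An object of class `RoiImage`.
#' @seealso [read_roi_tiff()], [crop_roi()]
#' @export
roi_image <- function(pixels, roi_mask = NULL, center = NULL, radius_px = NULL,
                      um_per_px = NA_real_, cropped = FALSE) {
  if (!is.array(pixels) || length(dim(pixels)) != 3 || dim(pixels)[3] != 3) {
    sr_stop("spatroi_format_error",
            "pixels must be a (rows, cols, 3) array; got dims [%s]",
            paste(dim(pixels), collapse = ", "))
  }
  if (min(pixels) < 0 || max(pixels) > 255) {
    sr_stop("spatroi_format_error", "pixel intensities must lie in [0, 255]")
  }
  if (!is.null(roi_mask)) {
    stopifnot(is.logical(roi_mask), all(dim(roi_mask) == dim(pixels)[1:2]))
  }
  structure(
    list(pixels = pixels, roi_mask = roi_mask, center = center,
         radius_px = radius_px, um_per_px = um_per_px, cropped = cropped),
    class = "RoiImage"
  )
}

#' @export
print.RoiImage <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("RoiImage: %d x %d px, %s\n", d[1], d[2],
              if (x$cropped) "cropped" else "uncropped"))
  if (!is.null(x$center)) {
    cat(sprintf("  ROI centre (x, y) = (%.1f, %.1f), radius = %.1f px\n",
                x$center[1], x$center[2], x$radius_px))
  }
  if (!is.na(x$um_per_px)) {
    cat(sprintf("  scale: %.4f um/px\n", x$um_per_px))
  }
  invisible(x)
}

#' Read an exported ROI TIFF
#'
#' Loads a TIFF exported from a DSP analysis suite (RGB or RGBA, 8- or 16-bit)
#' as an uncropped [roi_image()]. Extra channels beyond the first three (e.g.
#' alpha) are dropped; 16-bit intensities are rescaled to the 0-255 range.
#'
#' @param path path to a TIFF file.
#' @return An uncropped `RoiImage`.
#' @export
read_roi_tiff <- function(path) {
  if (!file.exists(path)) {
    sr_stop("spatroi_io_error", "cannot read TIFF: file not found: %s", path)
  }
  raw <- tryCatch(tiff::readTIFF(path),
                  error = function(e) {
                    sr_stop("spatroi_io_error", "cannot decode TIFF %s: %s",
                            path, conditionMessage(e))
                  })
  if (length(dim(raw)) != 3 || dim(raw)[3] < 3) {
    nch <- if (length(dim(raw)) == 2) 1L else dim(raw)[3]
    sr_stop("spatroi_format_error",
            "expected an image with >= 3 channels (R, G, B); got %d", nch)
  }
  # readTIFF returns intensities on [0, 1] for both 8- and 16-bit sources,
  # so one rescale covers both bit depths.
  roi_image(raw[, , 1:3, drop = FALSE] * 255)
}

#' Write an RoiImage to TIFF (plus a sidecar JSON for ROI geometry)
#'
#' @param img an `RoiImage`.
#' @param path output TIFF path. When the image carries ROI geometry, a sidecar
#'   `<path>.json` with `center`, `radius_px` and `um_per_px` is written next
#'   to it.
#' @return `path`, invisibly.
#' @export
write_roi_tiff <- function(img, path) {
  stopifnot(inherits(img, "RoiImage"))
  tiff::writeTIFF(img$pixels / 255, path, bits.per.sample = 8)
  if (!is.null(img$center)) {
    jsonlite::write_json(
      list(center = img$center, radius_px = img$radius_px,
           um_per_px = img$um_per_px),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Detect the circular ROI and crop away the white margin
#'
#' Exported ROI images place the circular tissue region on a near-white margin.
#' This routine thresholds the near-white background, takes the largest
#' connected non-background component, fits an area-equivalent circle (centre =
#' centroid of the component, radius = radius of the circle with the same
#' area), crops to the circle's tight bounding square, and sets every pixel
#' outside the circular mask to the white sentinel (255, 255, 255). Masked-out
#' pixels are excluded from all downstream statistics via `roi_mask`.
#'
#' If the non-background region touches all four image borders the image is
#' assumed to be pre-cropped: a warning is raised, the crop is skipped, and
#' only the mask is (re)fitted. Calling `crop_roi()` on an already-cropped
#' `RoiImage` is a no-op.
#'
#' @param img an uncropped `RoiImage`.
#' @param background_tol intensity tolerance for the near-white margin: a pixel
#'   is background when all three channels are `>= 255 - background_tol`.
#' @param shape ROI shape; only `"circle"` is supported.
#' @return A cropped `RoiImage` with `roi_mask`, `center` and `radius_px` set.
#' @export
crop_roi <- function(img, background_tol = 10, shape = c("circle")) {
  stopifnot(inherits(img, "RoiImage"))
  shape <- match.arg(shape)
  if (isTRUE(img$cropped)) {
    return(img)
  }
  px <- img$pixels
  fg <- !(px[, , 1] >= 255 - background_tol &
          px[, , 2] >= 255 - background_tol &
          px[, , 3] >= 255 - background_tol)
  if (!any(fg)) {
    sr_stop("spatroi_empty_roi_error",
            "no non-background region found (background_tol = %g)",
            background_tol)
  }
  labels <- from_eb(EBImage::bwlabel(as_eb(fg)))
  sizes <- tabulate(labels[labels > 0])
  comp <- labels == which.max(sizes)
  idx <- which(comp, arr.ind = TRUE)
  cy <- mean(idx[, 1]) - 1  # 0-based
  cx <- mean(idx[, 2]) - 1
  radius <- sqrt(nrow(idx) / pi)

  touches_all <- any(comp[1, ]) && any(comp[nrow(comp), ]) &&
    any(comp[, 1]) && any(comp[, ncol(comp)])
  if (touches_all) {
    sr_warn("spatroi_precropped_warning",
            "ROI touches all four borders; assuming pre-cropped image, crop skipped")
    r0 <- 1L; c0 <- 1L
    sub <- px
  } else {
    r0 <- max(1L, floor(cy - radius) + 1L)
    r1 <- min(nrow(comp), ceiling(cy + radius) + 1L)
    c0 <- max(1L, floor(cx - radius) + 1L)
    c1 <- min(ncol(comp), ceiling(cx + radius) + 1L)
    sub <- px[r0:r1, c0:c1, , drop = FALSE]
  }
  cx_new <- cx - (c0 - 1L)
  cy_new <- cy - (r0 - 1L)
  mask <- disc_mask(dim(sub)[1], dim(sub)[2], cx_new, cy_new, radius)
  for (ch in 1:3) {
    plane <- sub[, , ch]
    plane[!mask] <- 255
    sub[, , ch] <- plane
  }
  roi_image(sub, roi_mask = mask, center = c(cx_new, cy_new),
            radius_px = radius, um_per_px = img$um_per_px, cropped = TRUE)
}

#' Assert the vendor-default physical ROI size to set the pixel scale
#'
#' The exported images carry no pixel-size metadata. When the user asserts that
#' the ROI was acquired at the platform's default diameter (approximately
#' 300 um), the scale is derived as `diameter_um / (2 * radius_px)`. Otherwise
#' the scale stays unknown and spatial statistics are reported in pixels.
#'
#' @param img a cropped `RoiImage`.
#' @param roi_diameter_um asserted physical ROI diameter in micrometres.
#' @return The `RoiImage` with `um_per_px` set.
#' @export
set_roi_scale <- function(img, roi_diameter_um = 300) {
  stopifnot(inherits(img, "RoiImage"))
  if (is.null(img$radius_px)) {
    sr_stop("spatroi_parameter_error",
            "ROI radius unknown; run crop_roi() first")
  }
  img$um_per_px <- roi_diameter_um / (2 * img$radius_px)
  img
}
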