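# Shared fixture builders. Everything is generated in code at test time;
# no binary fixtures are stored.

# Cell table with green intensities drawn from a planted two-class mixture.
mixture_cells <- function(n_per = 250, mean_pos = 60, sd_pos = 8,
                          mean_neg = 8, sd_neg = 2, seed = 1) {
  set.seed(seed)
  g <- c(rnorm(n_per, mean_neg, sd_neg), rnorm(n_per, mean_pos, sd_pos))
  data.frame(
    label = seq_len(2 * n_per),
    x = runif(2 * n_per, 0, 100), y = runif(2 * n_per, 0, 100),
    mean_r = pmax(rnorm(2 * n_per, 15, 5), 0),
    mean_g = pmax(g, 0),
    mean_b = pmax(rnorm(2 * n_per, 200, 20), 0),
    n_pixels = 50L, area = 50, perimeter = 25, circularity = 1,
    class_label = NA_character_,
    truth = rep(c("negative", "positive"), each = n_per),
    stringsAsFactors = FALSE
  )
}

# Plain filled disc on a white background (no blur): the crop-detection
# oracle, with exactly known centre and radius.
disc_image <- function(size = 600, cx = (size - 1) / 2, cy = (size - 1) / 2,
                       radius = 150, rgb = c(80, 120, 60)) {
  px <- array(255, c(size, size, 3))
  x <- matrix(rep(seq_len(size) - 1, each = size), size)
  y <- matrix(rep(seq_len(size) - 1, times = size), size)
  inside <- (x - cx)^2 + (y - cy)^2 <= radius^2
  for (ch in 1:3) {
    plane <- px[, , ch]
    plane[inside] <- rgb[ch]
    px[, , ch] <- plane
  }
  roi_image(px)
}

# Hand-built cropped RoiImage: dark tissue disc with blue nuclei painted as
# hard discs (no anti-aliasing), for precise segmentation/morphology checks.
nuclei_image <- function(size = 120, roi_radius = 55,
                         centers = cbind(x = 60, y = 60), radius = 8,
                         blue = 200) {
  c0 <- (size - 1) / 2
  px <- array(255, c(size, size, 3))
  x <- matrix(rep(seq_len(size) - 1, each = size), size)
  y <- matrix(rep(seq_len(size) - 1, times = size), size)
  mask <- (x - c0)^2 + (y - c0)^2 <= roi_radius^2
  for (ch in 1:3) {
    plane <- px[, , ch]
    plane[mask] <- c(12, 2, 14)[ch]
    px[, , ch] <- plane
  }
  blue_plane <- px[, , 3]
  radius <- rep(radius, length.out = nrow(centers))
  for (i in seq_len(nrow(centers))) {
    inside <- (x - centers[i, 1])^2 + (y - centers[i, 2])^2 <= radius[i]^2
    blue_plane[inside & mask] <- blue
  }
  px[, , 3] <- blue_plane
  roi_image(px, roi_mask = mask, center = c(c0, c0), radius_px = roi_radius,
            cropped = TRUE)
}

# LabelMask from an explicit integer matrix (for morphology unit tests).
label_mask <- function(labels) {
  structure(list(labels = labels, n_cells = max(labels)),
            class = "LabelMask")
}

# Uniform RoiImage whose mask covers everything except a 2 px border.
flat_image <- function(size = 80, value = c(12, 2, 14)) {
  px <- array(0, c(size, size, 3))
  for (ch in 1:3) px[, , ch] <- value[ch]
  mask <- matrix(TRUE, size, size)
  roi_image(px, roi_mask = mask, center = c((size - 1) / 2, (size - 1) / 2),
            radius_px = size / 2, cropped = TRUE)
}

# Expression matrix with a fully controlled detection pattern.
detection_matrix <- function(detected, base = 10) {
  values <- ifelse(detected, base + seq_along(detected) %% 7, 0)
  dim(values) <- dim(detected)
  if (is.null(dimnames(detected))) {
    dimnames(detected) <- list(sprintf("g%d", seq_len(nrow(detected))),
                               sprintf("s%d", seq_len(ncol(detected))))
  }
  dimnames(values) <- dimnames(detected)
  expression_matrix(values, detected)
}
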