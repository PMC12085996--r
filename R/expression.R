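#' Gene x segment expression matrix with detection metadata
#'
#' Container for DSP-style expression data: a non-negative genes x segments
#' matrix, a parallel logical `detected` matrix (expression above the limit
#' of detection), and per-segment annotations. Detection is taken as input:
#' either an explicit `detected` matrix, or the simple default
#' `values > lod` (LOD 0). The vendor's negative-probe detection machinery
#' is intentionally not reimplemented here.
#'
#' @param values numeric genes x segments matrix with unique row (gene) and
#'   column (segment) names.
#' @param detected logical matrix of the same shape, or `NULL` to derive it
#'   as `values > lod`.
#' @param meta per-segment annotation data frame with a `segment_id` column
#'   (e.g. region type, roi_id, mixing group), or `NULL`.
#' @param lod limit of detection used when `detected` is `NULL`.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, detected = NULL, meta = NULL, lod = 0) {
  stopifnot(is.matrix(values))
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)) ||
      is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    sr_stop("spatroi_format_error",
            "values must have unique gene rownames and segment colnames")
  }
  if (any(values < 0)) {
    sr_stop("spatroi_format_error", "expression values must be >= 0")
  }
  if (is.null(detected)) {
    detected <- values > lod
  }
  stopifnot(is.logical(detected), all(dim(detected) == dim(values)))
  dimnames(detected) <- dimnames(values)
  if (!is.null(meta)) {
    stopifnot(is.data.frame(meta), "segment_id" %in% names(meta))
    meta <- meta[match(colnames(values), meta$segment_id), , drop = FALSE]
  }
  structure(list(values = values, detected = detected, meta = meta),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d segments (%.1f%% detected)\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$detected)))
  invisible(x)
}

#' Aggregate probe-level counts to gene level
#'
#' Each gene's value in a segment is the arithmetic mean of its probes'
#' values in that segment.
#'
#' @param probe_matrix numeric probes x segments matrix with probe rownames.
#' @param probe_to_gene data frame with columns `probe` and `gene` mapping
#'   every probe to exactly one gene.
#' @param lod limit of detection forwarded to [expression_matrix()].
#' @param meta optional per-segment metadata forwarded to
#'   [expression_matrix()].
#' @return An `ExpressionMatrix` with one row per gene.
#' @export
aggregate_probes <- function(probe_matrix, probe_to_gene, lod = 0,
                             meta = NULL) {
  stopifnot(is.matrix(probe_matrix), !is.null(rownames(probe_matrix)),
            is.data.frame(probe_to_gene),
            all(c("probe", "gene") %in% names(probe_to_gene)))
  if (anyDuplicated(probe_to_gene$probe)) {
    sr_stop("spatroi_mapping_error", "probe_to_gene maps some probes twice: %s",
            paste(unique(probe_to_gene$probe[
              duplicated(probe_to_gene$probe)]), collapse = ", "))
  }
  gene_of <- probe_to_gene$gene[match(rownames(probe_matrix),
                                      probe_to_gene$probe)]
  if (anyNA(gene_of)) {
    sr_stop("spatroi_mapping_error", "unmapped probes: %s",
            paste(rownames(probe_matrix)[is.na(gene_of)], collapse = ", "))
  }
  sums <- rowsum(probe_matrix, gene_of)
  counts <- as.vector(table(gene_of)[rownames(sums)])
  values <- sums / counts
  # keep first-appearance order of genes rather than rowsum's sorted order
  first <- unique(gene_of)
  expression_matrix(values[first, , drop = FALSE], lod = lod, meta = meta)
}

#' Drop segments with too few detected genes
#'
#' A segment is dropped when the fraction of detected genes it contains,
#' relative to the total number of genes detected in any segment, is strictly
#' below `min_gene_frac` (default 5 percent). Dropped segment ids are stored
#' in the `dropped_segments` attribute. Re-running the filter on its own
#' output is a no-op.
#'
#' @param m an `ExpressionMatrix`.
#' @param min_gene_frac detection-fraction threshold (strict `<`).
#' @return The filtered `ExpressionMatrix`.
#' @export
filter_segments <- function(m, min_gene_frac = 0.05) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  total_detected <- sum(rowSums(m$detected) > 0)
  frac <- colSums(m$detected) / total_detected
  keep <- frac >= min_gene_frac
  out <- expression_matrix(m$values[, keep, drop = FALSE],
                           m$detected[, keep, drop = FALSE],
                           meta = if (is.null(m$meta)) NULL else
                             m$meta[keep, , drop = FALSE])
  attr(out, "dropped_segments") <- colnames(m$values)[!keep]
  out
}

#' Drop genes detected in too few segments
#'
#' Keeps genes detected in at least `min_roi_frac` (default 10 percent) of
#' the remaining segments (inclusive `>=`). Dropped gene ids are stored in
#' the `dropped_genes` attribute. Idempotent.
#'
#' @param m an `ExpressionMatrix` (segments already filtered).
#' @param min_roi_frac detection-fraction threshold (`>=` keeps).
#' @return The filtered `ExpressionMatrix`.
#' @export
filter_genes <- function(m, min_roi_frac = 0.10) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  frac <- rowSums(m$detected) / ncol(m$detected)
  keep <- frac >= min_roi_frac
  out <- expression_matrix(m$values[keep, , drop = FALSE],
                           m$detected[keep, , drop = FALSE], meta = m$meta)
  attr(out, "dropped_genes") <- rownames(m$values)[!keep]
  out
}

#' Upper-quartile (Q3) normalization
#'
#' Per segment, the normalization factor is that segment's 75th percentile
#' over retained genes divided by the geometric mean of the 75th percentiles
#' across segments; values are divided by the factor. Referencing to the
#' geometric mean keeps the matrix on its original scale, and the quantile is
#' computed with linear interpolation between order statistics
#' (`stats::quantile`, type 7). Within-segment gene ranks are unchanged.
#'
#' @param m an `ExpressionMatrix` (after the detection filters).
#' @return The normalized `ExpressionMatrix`; the per-segment factors are in
#'   the `q3_factors` attribute.
#' @export
q3_normalize <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  q3 <- apply(m$values, 2, stats::quantile, probs = 0.75, names = FALSE,
              type = 7)
  if (any(q3 == 0)) {
    sr_stop("spatroi_normalization_error",
            "Q3 is zero for segment(s): %s",
            paste(colnames(m$values)[q3 == 0], collapse = ", "))
  }
  f <- q3 / exp(mean(log(q3)))
  out <- expression_matrix(sweep(m$values, 2, f, `/`), m$detected,
                           meta = m$meta)
  attr(out, "q3_factors") <- stats::setNames(f, colnames(m$values))
  out
}

#' Full expression preprocessing pipeline
#'
#' Fixed order: probe aggregation, segment detection filter, gene detection
#' filter, Q3 normalization.
#'
#' @inheritParams aggregate_probes
#' @inheritParams filter_segments
#' @inheritParams filter_genes
#' @return A normalized `ExpressionMatrix` carrying the `dropped_segments`,
#'   `dropped_genes` and `q3_factors` attributes of the individual steps.
#' @export
preprocess_expression <- function(probe_matrix, probe_to_gene,
                                  min_gene_frac = 0.05, min_roi_frac = 0.10,
                                  lod = 0, meta = NULL) {
  m <- aggregate_probes(probe_matrix, probe_to_gene, lod = lod, meta = meta)
  m <- filter_segments(m, min_gene_frac)
  dropped_segments <- attr(m, "dropped_segments")
  m <- filter_genes(m, min_roi_frac)
  dropped_genes <- attr(m, "dropped_genes")
  m <- q3_normalize(m)
  attr(m, "dropped_segments") <- dropped_segments
  attr(m, "dropped_genes") <- dropped_genes
  m
}

#' Read a genes-(or probes-)by-segments CSV/TSV matrix
#'
#' Expects feature ids in the first column and segment ids in the header.
#'
#' @param path CSV or TSV file path (separator inferred from the extension).
#' @return A numeric matrix with rownames and colnames.
#' @export
read_matrix_csv <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE)
  as.matrix(df)
}

#' Write an ExpressionMatrix (values) to CSV
#'
#' @param m an `ExpressionMatrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_expression_csv <- function(m, path) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  utils::write.csv(data.frame(gene = rownames(m$values), m$values,
                              check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}
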