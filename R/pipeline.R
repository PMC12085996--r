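#' Read and validate a pipeline run configuration
#'
#' The pipeline is driven by one declarative YAML file; command-line flags of
#' the bundled CLI override file values. Recognized top-level keys:
#'
#' * `images`: directory of ROI TIFFs (optional; imaging stages skipped when
#'   absent).
#' * `out_dir`: output directory (required).
#' * `seed`: integer seed used by the stochastic classifiers (default 0).
#' * `params`: `background_tol`, `diameter_px`, `flow_threshold`, `backend`,
#'   and `classify` (`method` = cutoff/gmm/kmeans, `channel`, `cutoff`, `k`).
#' * `crossk`: `r_max` (null = window radius / 4), `n_r`, `edge_correction`,
#'   and `rule` (`top_n` or `threshold`) for Mixture/Separative grouping.
#' * `expression`: `probe_matrix`, `probe_map` (paths), `min_gene_frac`,
#'   `min_roi_frac`, `lod`.
#' * `rl`: `enabled`, `table` (ligand-target TSV path), `ppi_sources`,
#'   `r_threshold`, optional `groups_csv` (`segment_id`, `group`) overriding
#'   the image-derived grouping.
#'
#' @param path YAML file path.
#' @return A validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    sr_stop("spatroi_config_error", "config file not found: %s", path)
  }
  validate_run_config(yaml::read_yaml(path))
}

default_config <- function() {
  list(
    images = NULL, out_dir = NULL, seed = 0,
    params = list(background_tol = 10, diameter_px = 23,
                  flow_threshold = 0.4, backend = "reference",
                  classify = list(method = "cutoff", channel = "G",
                                  cutoff = 20, k = 2)),
    crossk = list(r_max = NULL, n_r = 100, edge_correction = "translation",
                  rule = list(threshold = 0)),
    expression = list(probe_matrix = NULL, probe_map = NULL,
                      min_gene_frac = 0.05, min_roi_frac = 0.10, lod = 0),
    rl = list(enabled = FALSE, table = NULL, ppi_sources = "ppi_prediction",
              r_threshold = 0.75, groups_csv = NULL)
  )
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    # a grouping rule is exclusive (top_n XOR threshold): replace, never merge
    base[[k]] <- if (k != "rule" && is.list(base[[k]]) &&
                     is.list(override[[k]])) {
      merge_config(base[[k]], override[[k]])
    } else {
      override[[k]]
    }
  }
  base
}

#' @rdname read_run_config
#' @param config a (partial) configuration list; missing entries take the
#'   documented defaults.
#' @export
validate_run_config <- function(config) {
  cfg <- merge_config(default_config(), config)
  if (is.null(cfg$out_dir)) {
    sr_stop("spatroi_config_error", "config lacks required key: out_dir")
  }
  if (!is.null(cfg$images) && !dir.exists(cfg$images)) {
    sr_stop("spatroi_config_error", "images directory not found: %s",
            cfg$images)
  }
  if (!cfg$params$classify$method %in% c("cutoff", "gmm", "kmeans")) {
    sr_stop("spatroi_config_error", "unknown classify method '%s'",
            cfg$params$classify$method)
  }
  has_expr <- !is.null(cfg$expression$probe_matrix)
  if (has_expr && is.null(cfg$expression$probe_map)) {
    sr_stop("spatroi_config_error",
            "expression.probe_matrix given without expression.probe_map")
  }
  for (key in c("probe_matrix", "probe_map")) {
    p <- cfg$expression[[key]]
    if (!is.null(p) && !file.exists(p)) {
      sr_stop("spatroi_config_error", "expression.%s not found: %s", key, p)
    }
  }
  if (isTRUE(cfg$rl$enabled)) {
    if (is.null(cfg$rl$table)) {
      sr_stop("spatroi_config_error",
              "rl.enabled is true but rl.table is missing")
    }
    if (!file.exists(cfg$rl$table)) {
      sr_stop("spatroi_config_error", "rl.table not found: %s", cfg$rl$table)
    }
    if (!has_expr) {
      sr_stop("spatroi_config_error",
              "rl stage requires the expression stage inputs")
    }
  }
  structure(cfg, class = "run_config")
}

classify_stage <- function(cells, cl, seed) {
  switch(cl$method,
         cutoff = classify_cutoff(cells, channel = cl$channel,
                                  cutoff = cl$cutoff),
         gmm = classify_gmm(cells, channels = cl$channel, k = cl$k,
                            positive_channel = cl$channel, seed = seed),
         kmeans = classify_kmeans(cells, channels = cl$channel, k = cl$k,
                                  positive_channel = cl$channel, seed = seed))
}

#' Run the end-to-end pipeline
#'
#' Executes crop, segmentation, feature extraction, classification, cross-K
#' scoring and Mixture/Separative grouping over every TIFF in the configured
#' image directory, then (when inputs are present) expression preprocessing
#' and per-group ligand-target pair prediction. Stages whose inputs are
#' absent are skipped. Outputs are written incrementally under `out_dir`
#' (per-ROI cell tables, cross-K curves and snapshots; `summary.csv`;
#' normalized expression; RL pair tables) together with `manifest.json`
#' echoing the effective configuration and package version. An error in any
#' stage aborts the run naming the failing ROI; already-written outputs are
#' preserved.
#'
#' @param config a `run_config` (from [read_run_config()] or
#'   [validate_run_config()]).
#' @param quiet suppress per-ROI progress messages.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  cfg <- if (inherits(config, "run_config")) config else
    validate_run_config(config)
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list(package = "spatroi",
                   version = as.character(utils::packageVersion("spatroi")),
                   config = unclass(cfg), stages = character(0))

  summary_df <- NULL
  if (!is.null(cfg$images)) {
    files <- sort(list.files(cfg$images, pattern = "\\.tiff?$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) {
      sr_stop("spatroi_config_error", "no TIFF files in %s", cfg$images)
    }
    params <- seg_params(diameter_px = cfg$params$diameter_px,
                         flow_threshold = cfg$params$flow_threshold)
    rows <- list()
    for (f in files) {
      roi_id <- tools::file_path_sans_ext(basename(f))
      res <- tryCatch({
        img <- crop_roi(read_roi_tiff(f),
                        background_tol = cfg$params$background_tol)
        mask <- segment_cells(img, params, backend = cfg$params$backend)
        cells <- extract_features(img, mask, roi_id = roi_id)
        typing <- classify_stage(cells, cfg$params$classify, cfg$seed)
        cells <- apply_typing(cells, typing)
        write_cell_table(cells,
                         file.path(cfg$out_dir,
                                   sprintf("cells_%s.csv", roi_id)))
        annotate_snapshot(img, mask, typing,
                          file.path(cfg$out_dir,
                                    sprintf("snapshot_%s.png", roi_id)))
        auc <- NA_real_
        if (typing$n_positive >= 2 &&
            typing$n_total - typing$n_positive >= 2) {
          ck <- cross_k(cells_to_pattern(cells, img),
                        r_max = cfg$crossk$r_max, n_r = cfg$crossk$n_r,
                        edge_correction = cfg$crossk$edge_correction)
          write_cross_k(ck, file.path(cfg$out_dir,
                                      sprintf("crossk_%s.csv", roi_id)))
          auc <- ck$auc
        }
        data.frame(roi_id = roi_id, n_total = typing$n_total,
                   n_positive = typing$n_positive,
                   positive_fraction = typing$positive_fraction,
                   auc = auc, stringsAsFactors = FALSE)
      }, spatroi_error = function(e) {
        sr_stop("spatroi_pipeline_error", "ROI '%s' failed: %s", roi_id,
                conditionMessage(e))
      })
      say("ROI %s: %d cells, %d positive (%s)", roi_id, res$n_total,
          res$n_positive,
          format_positive_pct(res$n_positive, res$n_total))
      rows[[roi_id]] <- res
    }
    summary_df <- do.call(rbind, rows)
    scored <- summary_df[!is.na(summary_df$auc), , drop = FALSE]
    if (nrow(scored) >= 1) {
      grouped <- classify_mixing(scored[, c("roi_id", "auc")],
                                 rule = cfg$crossk$rule)
      summary_df$group <- grouped$group[match(summary_df$roi_id,
                                              grouped$roi_id)]
    } else {
      summary_df$group <- NA_character_
    }
    row.names(summary_df) <- NULL
    utils::write.csv(summary_df, file.path(cfg$out_dir, "summary.csv"),
                     row.names = FALSE)
    manifest$stages <- c(manifest$stages, "imaging")
    manifest$n_rois <- nrow(summary_df)
  }

  if (!is.null(cfg$expression$probe_matrix)) {
    probe_matrix <- read_matrix_csv(cfg$expression$probe_matrix)
    probe_map <- utils::read.table(cfg$expression$probe_map, header = TRUE,
                                   sep = "\t", stringsAsFactors = FALSE)
    m <- preprocess_expression(probe_matrix, probe_map,
                               min_gene_frac = cfg$expression$min_gene_frac,
                               min_roi_frac = cfg$expression$min_roi_frac,
                               lod = cfg$expression$lod)
    write_expression_csv(m, file.path(cfg$out_dir,
                                      "normalized_expression.csv"))
    manifest$stages <- c(manifest$stages, "expression")
    manifest$n_genes <- nrow(m$values)
    manifest$n_segments <- ncol(m$values)

    if (isTRUE(cfg$rl$enabled)) {
      table <- read_ligand_target_table(cfg$rl$table,
                                        ppi_sources = cfg$rl$ppi_sources)
      groups <- if (!is.null(cfg$rl$groups_csv)) {
        utils::read.csv(cfg$rl$groups_csv, stringsAsFactors = FALSE)
      } else if (!is.null(summary_df)) {
        data.frame(segment_id = summary_df$roi_id, group = summary_df$group,
                   stringsAsFactors = FALSE)
      } else {
        sr_stop("spatroi_config_error",
                "rl stage needs rl.groups_csv or image-derived groups")
      }
      results <- list()
      for (g in sort(unique(stats::na.omit(groups$group)))) {
        seg <- groups$segment_id[groups$group %in% g]
        res <- predict_rl_pairs(m, seg, table,
                                r_threshold = cfg$rl$r_threshold, group = g)
        utils::write.csv(res$pairs,
                         file.path(cfg$out_dir,
                                   sprintf("rl_pairs_%s.csv", g)),
                         row.names = FALSE)
        results[[g]] <- res
        say("RL group %s: %d pair(s)", g, nrow(res$pairs))
      }
      if (length(results) == 2) {
        comp <- compare_groups(results[[1]], results[[2]])
        utils::write.csv(comp$plot_table,
                         file.path(cfg$out_dir, "rl_comparison.csv"),
                         row.names = FALSE)
        manifest$rl_counts <- stats::setNames(c(comp$n_a, comp$n_b),
                                              c(comp$group_a, comp$group_b))
      }
      manifest$stages <- c(manifest$stages, "rl")
    }
  }

  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
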