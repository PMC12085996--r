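rl_fixture <- function(seed = 1, true_r = c(0.95, 0.9), n_segments = 10) {
  pairs <- data.frame(ligand = c("G3", "G7"), target = c("G4", "G8"),
                      true_r = true_r)
  fx <- make_expression(n_genes = 40, n_segments = n_segments,
                        planted_pairs = pairs, seed = seed)
  m <- preprocess_expression(fx$probe_matrix, fx$probe_to_gene)
  list(m = m, table = ligand_target_table(fx$table), pairs = pairs)
}

test_that("planted correlated pairs are retained above the threshold", {
  fx <- rl_fixture(seed = 4)
  res <- predict_rl_pairs(fx$m, colnames(fx$m$values), fx$table,
                          group = "Mixture")
  key <- paste(res$pairs$ligand, res$pairs$target)
  expect_true(all(c("G3 G4", "G7 G8") %in% key))
  expect_true(all(res$pairs$pearson_r > 0.75))
  expect_identical(unique(res$pairs$n_segments), ncol(fx$m$values))
})

test_that("ppi_prediction-sourced pairs are excluded", {
  fx <- rl_fixture(seed = 4)
  tab <- fx$table
  tab$source_kind[tab$ligand == "G3" & tab$target == "G4"] <-
    "ppi_prediction"
  res <- predict_rl_pairs(fx$m, colnames(fx$m$values), tab,
                          group = "Mixture")
  key <- paste(res$pairs$ligand, res$pairs$target)
  expect_false("G3 G4" %in% key)
  expect_true("G7 G8" %in% key)
})

test_that("retained pair count is monotone non-increasing in the threshold", {
  fx <- rl_fixture(seed = 9)
  counts <- vapply(c(0.2, 0.5, 0.75, 0.9, 0.99), function(thr) {
    nrow(predict_rl_pairs(fx$m, colnames(fx$m$values), fx$table,
                          r_threshold = thr)$pairs)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("table-restricted computation equals the all-pairs oracle", {
  fx <- rl_fixture(seed = 6)
  res <- predict_rl_pairs(fx$m, colnames(fx$m$values), fx$table,
                          group = "g")
  # oracle: full gene-gene correlation matrix, then intersect with the table
  cm <- cor(t(fx$m$values))
  tab <- fx$table[fx$table$source_kind != "ppi_prediction", ]
  present <- tab$ligand %in% rownames(cm) & tab$target %in% rownames(cm)
  tab <- tab[present, ]
  r <- cm[cbind(tab$ligand, tab$target)]
  oracle <- tab[r > 0.75, c("ligand", "target")]
  oracle$pearson_r <- r[r > 0.75]
  oracle <- oracle[order(-oracle$pearson_r, oracle$ligand, oracle$target), ]
  expect_equal(res$pairs$pearson_r, oracle$pearson_r, tolerance = 1e-12)
  expect_identical(res$pairs$ligand, oracle$ligand)
  expect_identical(res$pairs$target, oracle$target)
})

test_that("results are invariant to segment and gene order", {
  fx <- rl_fixture(seed = 8)
  m <- fx$m
  seg_perm <- sample(ncol(m$values))
  gene_perm <- sample(nrow(m$values))
  m2 <- expression_matrix(m$values[gene_perm, seg_perm],
                          m$detected[gene_perm, seg_perm])
  a <- predict_rl_pairs(m, colnames(m$values), fx$table)
  b <- predict_rl_pairs(m2, colnames(m$values), fx$table)
  expect_equal(a$pairs, b$pairs, tolerance = 1e-12)
})

test_that("constant-expression genes are skipped with a warning", {
  fx <- rl_fixture(seed = 2)
  m <- fx$m
  m$values["G3", ] <- 5  # constant: correlation undefined
  expect_warning(
    res <- predict_rl_pairs(m, colnames(m$values), fx$table),
    class = "spatroi_zero_variance_warning")
  expect_false("G3" %in% res$pairs$ligand)
  # G3 features in two table rows (planted pair + decoy): both skipped
  expect_identical(res$skipped$zero_variance, 2L)
})

test_that("fewer than three segments is an insufficient-replicates error", {
  fx <- rl_fixture(seed = 3)
  expect_error(
    predict_rl_pairs(fx$m, colnames(fx$m$values)[1:2], fx$table),
    class = "spatroi_insufficient_replicates_error")
})

test_that("group comparisons count shared and unique pairs", {
  mk <- function(group, keys, r = 0.9) {
    pairs <- do.call(rbind, lapply(keys, function(k) {
      data.frame(ligand = k[1], target = k[2], pearson_r = r,
                 n_segments = 5, mean_expr_ligand = 1, mean_expr_target = 1)
    }))
    structure(list(group = group, pairs = pairs, r_threshold = 0.75,
                   skipped = list(missing_gene = 0L, zero_variance = 0L)),
              class = "RLPairResult")
  }
  a <- mk("Mixture", list(c("A", "B"), c("C", "D"), c("E", "F")))
  b <- mk("Separative", list(c("A", "B")))
  comp <- compare_groups(a, b)
  expect_identical(c(comp$n_a, comp$n_b, comp$n_shared,
                     comp$n_unique_a, comp$n_unique_b),
                   c(3L, 1L, 1L, 2L, 0L))
  expect_identical(nrow(comp$plot_table), 4L)

  same <- compare_groups(a, mk("Separative",
                               list(c("A", "B"), c("C", "D"), c("E", "F"))))
  expect_identical(same$n_shared, 3L)
  expect_identical(same$n_unique_a, 0L)
})

test_that("more pairs are predicted where more correlations are planted", {
  # Mixture group: 4 planted table pairs; Separative group: 1
  mix_pairs <- data.frame(ligand = sprintf("G%d", c(3, 7, 11, 15)),
                          target = sprintf("G%d", c(4, 8, 12, 16)),
                          true_r = 0.95)
  sep_pairs <- data.frame(ligand = "G3", target = "G4", true_r = 0.95)
  fm <- make_expression(n_genes = 40, n_segments = 8,
                        planted_pairs = mix_pairs, seed = 21)
  fs <- make_expression(n_genes = 40, n_segments = 8,
                        planted_pairs = sep_pairs, seed = 22)
  table <- ligand_target_table(rbind(fm$table, fs$table))
  mm <- preprocess_expression(fm$probe_matrix, fm$probe_to_gene)
  ms <- preprocess_expression(fs$probe_matrix, fs$probe_to_gene)
  rm_ <- predict_rl_pairs(mm, colnames(mm$values), table, group = "Mixture")
  rs <- predict_rl_pairs(ms, colnames(ms$values), table,
                         group = "Separative")
  comp <- compare_groups(rm_, rs)
  expect_gt(comp$n_a, comp$n_b)
})

test_that("ligand-target tables load, uppercase and deduplicate", {
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "lt.tsv")
  writeLines(c("ligand\ttarget\tsource",
               "tgfb1\tACTA2\tkegg",
               "TGFB1\tacta2\tppi_hub",
               "IL6\tSTAT3\tppi_hub"), p)
  tab <- read_ligand_target_table(p, ppi_sources = "ppi_hub")
  expect_identical(nrow(tab), 2L)
  # duplicate pair documented by both kinds collapses to curated
  row <- tab[tab$ligand == "TGFB1", ]
  expect_identical(row$source_kind, "curated")
  expect_identical(tab$source_kind[tab$ligand == "IL6"], "ppi_prediction")
  expect_error(read_ligand_target_table(p, source_col = "nope"),
               class = "spatroi_format_error")
})
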