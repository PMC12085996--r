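test_that("probe aggregation averages probes per gene", {
  pm <- matrix(c(2, 4,   # gene A probes in segment 1
                 6, 8),  # ... in segment 2
               nrow = 2,
               dimnames = list(c("A_P1", "A_P2"), c("s1", "s2")))
  map <- data.frame(probe = c("A_P1", "A_P2"), gene = "A")
  m <- aggregate_probes(pm, map)
  expect_identical(m$values["A", ], c(s1 = 3, s2 = 7))

  # single-probe genes pass through unchanged
  pm2 <- rbind(pm, B_P1 = c(5, 9))
  map2 <- rbind(map, data.frame(probe = "B_P1", gene = "B"))
  m2 <- aggregate_probes(pm2, map2)
  expect_identical(m2$values["B", ], c(s1 = 5, s2 = 9))
})

test_that("aggregation output has one row per gene, in mapping order", {
  fx <- make_expression(n_genes = 20, n_segments = 5, seed = 1)
  expect_identical(nrow(fx$probe_matrix) > 20, TRUE)
  m <- aggregate_probes(fx$probe_matrix, fx$probe_to_gene)
  expect_identical(rownames(m$values), sprintf("G%d", 1:20))
})

test_that("unmapped or doubly mapped probes are mapping errors", {
  pm <- matrix(1, 2, 2, dimnames = list(c("p1", "p2"), c("s1", "s2")))
  expect_error(aggregate_probes(pm, data.frame(probe = "p1", gene = "A")),
               "p2", class = "spatroi_mapping_error")
  expect_error(
    aggregate_probes(pm, data.frame(probe = c("p1", "p1", "p2"),
                                    gene = c("A", "B", "B"))),
    class = "spatroi_mapping_error")
})

test_that("segment filter drops below 5% detection, strictly", {
  detected <- matrix(TRUE, 100, 4,
                     dimnames = list(sprintf("g%d", 1:100),
                                     sprintf("s%d", 1:4)))
  detected[5:100, 2] <- FALSE  # s2 detects 4 of 100: dropped (4% < 5%)
  detected[6:100, 3] <- FALSE  # s3 detects 5 of 100: kept (boundary)
  m <- detection_matrix(detected)
  f <- filter_segments(m, 0.05)
  expect_identical(attr(f, "dropped_segments"), "s2")
  expect_identical(colnames(f$values), c("s1", "s3", "s4"))

  # all-above-threshold input passes unchanged
  f2 <- filter_segments(f, 0.05)
  expect_identical(f2$values, f$values)
})

test_that("gene filter keeps >= 10% detection, inclusive", {
  detected <- matrix(FALSE, 3, 20,
                     dimnames = list(c("g1", "g2", "g3"),
                                     sprintf("s%d", 1:20)))
  detected[1, 1] <- TRUE        # 1 of 20 = 5%: dropped
  detected[2, 1:2] <- TRUE      # 2 of 20 = 10%: kept (>= rule)
  detected[3, ] <- TRUE
  m <- detection_matrix(detected)
  f <- filter_genes(m, 0.10)
  expect_identical(attr(f, "dropped_genes"), "g1")
  expect_identical(rownames(f$values), c("g2", "g3"))
  # idempotence
  expect_identical(filter_genes(f, 0.10)$values, f$values)
})

test_that("generator-constructed detection failures are dropped exactly", {
  fx <- make_expression(n_genes = 60, n_segments = 20,
                        n_low_detect_segments = 2, n_rare_genes = 4,
                        seed = 12)
  m <- aggregate_probes(fx$probe_matrix, fx$probe_to_gene)
  m <- filter_segments(m, 0.05)
  expect_identical(sort(attr(m, "dropped_segments")),
                   sort(fx$truth$low_detect_segments))
  m <- filter_genes(m, 0.10)
  expect_identical(sort(attr(m, "dropped_genes")),
                   sort(fx$truth$rare_genes))
  expect_identical(nrow(m$values), 60L - 4L)
})

test_that("Q3 normalization is a fixed point on symmetric input", {
  v <- matrix(rep(c(1, 5, 10, 20), 3), 4, 3,
              dimnames = list(sprintf("g%d", 1:4), sprintf("s%d", 1:3)))
  m <- q3_normalize(expression_matrix(v))
  expect_equal(m$values, v)
  expect_equal(unname(attr(m, "q3_factors")), rep(1, 3))
})

test_that("Q3 normalization equalizes upper quartiles across segments", {
  set.seed(2)
  base <- rlnorm(50, 3, 1)
  v <- cbind(s1 = base, s2 = 2 * base, s3 = 0.5 * base)
  rownames(v) <- sprintf("g%d", 1:50)
  m <- q3_normalize(expression_matrix(v))
  q3 <- unname(apply(m$values, 2, quantile, 0.75, names = FALSE))
  expect_equal(q3[1], q3[2], tolerance = 1e-12)
  expect_equal(q3[1], q3[3], tolerance = 1e-12)
  # within-segment rank order is preserved
  expect_identical(order(m$values[, "s1"]), order(v[, "s1"]))
})

test_that("Q3 factors recover planted log-normal scale factors", {
  set.seed(31)
  scales <- exp(rnorm(16, 0, 0.4))
  fx <- make_expression(n_genes = 500, n_segments = 16,
                        planted_scales = scales, seed = 31)
  m <- preprocess_expression(fx$probe_matrix, fx$probe_to_gene)
  f <- attr(m, "q3_factors")
  expect_identical(length(f), 16L)
  expect_gte(cor(f, scales), 0.99)
})

test_that("a zero upper quartile is a normalization error naming the segment", {
  v <- matrix(c(1, 2, 3, 4, 0, 0, 0, 0), 4, 2,
              dimnames = list(sprintf("g%d", 1:4), c("good", "dead")))
  expect_error(q3_normalize(expression_matrix(v)), "dead",
               class = "spatroi_normalization_error")
})

test_that("the full pipeline runs in fixed order and is idempotent", {
  fx <- make_expression(n_genes = 80, n_segments = 20,
                        n_low_detect_segments = 1, n_rare_genes = 2,
                        seed = 77)
  m <- preprocess_expression(fx$probe_matrix, fx$probe_to_gene)
  expect_identical(attr(m, "dropped_segments"),
                   fx$truth$low_detect_segments)
  expect_identical(sort(attr(m, "dropped_genes")),
                   sort(fx$truth$rare_genes))
  # the filters leave already-filtered data untouched
  expect_identical(filter_segments(m)$values, m$values)
  expect_identical(filter_genes(m)$values, m$values)
})

test_that("matrix CSV round-trips through the readers", {
  tmp <- withr::local_tempdir()
  fx <- make_expression(n_genes = 10, n_segments = 4, seed = 3)
  m <- aggregate_probes(fx$probe_matrix, fx$probe_to_gene)
  p <- file.path(tmp, "expr.csv")
  write_expression_csv(m, p)
  back <- read_matrix_csv(p)
  expect_equal(back, m$values)
})
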