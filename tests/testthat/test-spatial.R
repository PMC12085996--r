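test_that("cross_k without correction matches the brute-force oracle", {
  for (s in 1:20) {
    n <- sample(20:100, 2)
    pat <- make_pattern(pattern_fixture_spec(n_positive = n[1],
                                             n_negative = n[2], seed = s))
    fast <- cross_k(pat, edge_correction = "none")
    slow <- brute_force_cross_k(pat)
    expect_lt(max(abs(fast$k_obs - slow$k_obs) / pmax(slow$k_obs, 1e-12)),
              1e-9)
    expect_equal(fast$auc, slow$auc, tolerance = 1e-9)
  }
})

test_that("the estimator has the closed form on a tiny configuration", {
  # 2 positives, 2 negatives; cross distances are known exactly
  pat <- point_pattern(x = c(-50, 50, -50, 50), y = c(0, 0, 10, -10),
                       marks = c("positive", "positive",
                                 "negative", "negative"),
                       center = c(0, 0), radius = 100)
  # cross distances: (p1,n1)=10, (p1,n2)=sqrt(100^2+10^2), (p2,n1)=same, (p2,n2)=10
  res <- brute_force_cross_k(pat, r_max = 25, n_r = 50)
  area <- pi * 100^2
  expected <- area / 4 * 2 * (res$radii >= 10)
  expect_equal(res$k_obs, expected, tolerance = 1e-12)
  expect_equal(res$k_ref, pi * res$radii^2)
})

test_that("radius grids are increasing and the reference is exact", {
  pat <- make_pattern(pattern_fixture_spec(n_positive = 30, n_negative = 30,
                                           seed = 1))
  res <- cross_k(pat, r_max = 30, n_r = 64)
  expect_true(all(diff(res$radii) > 0))
  expect_gt(res$radii[1], 0)
  expect_equal(max(res$radii), 30)
  expect_identical(res$k_ref, pi * res$radii^2)
})

test_that("CSR patterns score near zero with translation correction", {
  aucs <- vapply(1:30, function(s) {
    cross_k(make_pattern(pattern_fixture_spec(seed = s)))$auc
  }, numeric(1))
  se <- stats::sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs)), 2 * se)
})

test_that("attraction scores positive and segregation negative", {
  att <- vapply(1:20, function(s) {
    cross_k(make_pattern(pattern_fixture_spec(regime = "attraction",
                                              seed = s)))$auc
  }, numeric(1))
  seg <- vapply(1:20, function(s) {
    cross_k(make_pattern(pattern_fixture_spec(regime = "segregation",
                                              seed = s)))$auc
  }, numeric(1))
  expect_gte(mean(att > 0), 0.95)
  expect_gte(mean(seg < 0), 0.95)
})

test_that("border correction reduces to the plain estimator away from edges", {
  pat <- make_pattern(pattern_fixture_spec(seed = 5))
  keep <- sqrt(pat$x^2 + pat$y^2) <= pat$window$radius / 2
  inner <- point_pattern(pat$x[keep], pat$y[keep], pat$marks[keep],
                         center = c(0, 0), radius = pat$window$radius)
  rb <- cross_k(inner, r_max = pat$window$radius / 4,
                edge_correction = "border")
  bf <- brute_force_cross_k(inner, r_max = pat$window$radius / 4)
  expect_lt(max(abs(rb$k_obs - bf$k_obs) / pmax(bf$k_obs, 1e-9)), 0.01)
})

test_that("the translation-corrected score is symmetric under mark swap", {
  pat <- make_pattern(pattern_fixture_spec(n_positive = 120, n_negative = 120,
                                           seed = 8))
  swapped <- point_pattern(
    pat$x, pat$y,
    ifelse(pat$marks == "positive", "negative", "positive"),
    pat$window$center, pat$window$radius)
  a <- cross_k(pat)
  b <- cross_k(swapped)
  expect_equal(a$auc, b$auc, tolerance = 1e-12)
  # the symmetric average equals either direction for pairwise weights
  expect_equal(cross_k(pat, direction = "symmetric")$k_obs, a$k_obs,
               tolerance = 1e-12)
})

test_that("the score is invariant to rotation and translation of the pattern", {
  pat <- make_pattern(pattern_fixture_spec(n_positive = 80, n_negative = 80,
                                           seed = 13))
  base <- cross_k(pat)$auc
  th <- 0.7
  rot <- point_pattern(pat$x * cos(th) - pat$y * sin(th),
                       pat$x * sin(th) + pat$y * cos(th),
                       pat$marks, c(0, 0), pat$window$radius)
  expect_equal(cross_k(rot)$auc, base, tolerance = 1e-9)
  shift <- point_pattern(pat$x + 30, pat$y - 12, pat$marks,
                         c(30, -12), pat$window$radius)
  expect_equal(cross_k(shift)$auc, base, tolerance = 1e-9)
})

test_that("insufficient marks and oversized radii raise parameter errors", {
  pat <- point_pattern(c(0, 1, 2), c(0, 0, 0),
                       c("positive", "positive", "negative"),
                       c(0, 0), 10)
  expect_error(cross_k(pat), "negative",
               class = "spatroi_insufficient_points_error")
  expect_error(brute_force_cross_k(pat),
               class = "spatroi_insufficient_points_error")
  ok <- make_pattern(pattern_fixture_spec(n_positive = 10, n_negative = 10,
                                          seed = 1))
  expect_error(cross_k(ok, r_max = 1000), class = "spatroi_parameter_error")
})

test_that("mixing groups follow the explicit rule", {
  df <- data.frame(roi_id = c("a", "b", "c"), auc = c(0.5, 0.1, -0.2))
  top <- classify_mixing(df, rule = list(top_n = 1))
  expect_identical(top$group[top$roi_id == "a"], "Mixture")
  expect_identical(sort(top$roi_id[top$group == "Separative"]), c("b", "c"))

  thr <- classify_mixing(df, rule = list(threshold = 0))
  expect_identical(thr$group[match(c("a", "b", "c"), thr$roi_id)],
                   c("Mixture", "Mixture", "Separative"))

  expect_error(classify_mixing(df, rule = list(top_n = 4)),
               class = "spatroi_parameter_error")
  expect_error(classify_mixing(df, rule = list()),
               class = "spatroi_parameter_error")
  expect_error(classify_mixing(df, rule = list(top_n = 1, threshold = 0)),
               class = "spatroi_parameter_error")
})

test_that("a 7-attraction / 19-segregation cohort is regrouped exactly", {
  results <- list()
  for (i in 1:7) {
    results[[sprintf("mix_%02d", i)]] <-
      cross_k(make_pattern(pattern_fixture_spec(
        n_positive = 100, n_negative = 100, regime = "attraction",
        seed = 100 + i)))
  }
  for (i in 1:19) {
    results[[sprintf("sep_%02d", i)]] <-
      cross_k(make_pattern(pattern_fixture_spec(
        n_positive = 100, n_negative = 100, regime = "segregation",
        seed = 200 + i)))
  }
  grouped <- classify_mixing(results, rule = list(top_n = 7))
  expect_identical(sort(grouped$roi_id[grouped$group == "Mixture"]),
                   sprintf("mix_%02d", 1:7))
  expect_identical(sum(grouped$group == "Separative"), 19L)
})

test_that("classified cell tables convert to patterns", {
  cells <- mixture_cells(n_per = 30, seed = 4)
  expect_error(cells_to_pattern(cells, center = c(50, 50), radius = 80),
               class = "spatroi_parameter_error")  # unclassified
  cells <- apply_typing(cells, classify_cutoff(cells))
  pat <- cells_to_pattern(cells, center = c(50, 50), radius = 80)
  expect_s3_class(pat, "MarkedPointPattern")
  expect_identical(length(pat$x), nrow(cells))
})
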