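test_that("Welch t statistic matches hand and reference computations", {
  r <- welch_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t_stat, -3.674, tolerance = 1e-3)
  expect_equal(r$df, 4)
  expect_equal(r$p_value, 0.0213, tolerance = 1e-2)
  # identical groups
  r0 <- welch_t_test(c(5, 6, 7), c(5, 6, 7))
  expect_equal(r0$t_stat, 0)
  expect_equal(r0$p_value, 1)
  # reference oracle on irregular data
  set.seed(12)
  for (i in 1:5) {
    x <- rlnorm(7); y <- rlnorm(5, 0.5)
    ref <- stats::t.test(x, y)
    got <- welch_t_test(x, y)
    expect_equal(got$t_stat, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("degenerate variances follow the documented convention", {
  r <- welch_t_test(c(2, 2, 2), c(5, 5, 5))
  expect_equal(r$p_value, 0)
  expect_equal(r$df, 1)
  expect_true(is.infinite(r$t_stat))
  expect_error(welch_t_test(3, c(1, 2)), "at least 2")
})

make_ft <- function(mat, samples) {
  tibble(feature_id = rep(rownames(mat), ncol(mat)),
         sample_id = rep(samples, each = nrow(mat)),
         area = as.vector(mat))
}

test_that("the fold-change threshold is a strict inequality", {
  m <- rbind(F1 = c(2, 2, 2, 1, 1, 1),
             F2 = c(2.2, 2.2, 2.2, 1, 1, 1))
  ft <- make_ft(m, sprintf("S%d", 1:6))
  res <- select_differential_features(ft, sprintf("S%d", 1:3),
                                      sprintf("S%d", 4:6))
  expect_false(res$selected[res$feature_id == "F1"])  # ratio exactly 2
  expect_true(res$selected[res$feature_id == "F2"])
  expect_equal(res$fold_change[res$feature_id == "F1"], 2)
})

test_that("selection is invariant under uniform area rescaling", {
  set.seed(13)
  m <- matrix(rlnorm(20 * 12, log(1000), 0.8), 20,
              dimnames = list(sprintf("F%02d", 1:20), NULL))
  m[1:5, 1:4] <- m[1:5, 1:4] * 5
  s <- sprintf("S%d", 1:12)
  ft1 <- make_ft(m, s)
  ft2 <- make_ft(m * 1000, s)
  r1 <- select_differential_features(ft1, s[1:4], s[5:12])
  r2 <- select_differential_features(ft2, s[1:4], s[5:12])
  expect_equal(r1$selected, r2$selected)
  expect_equal(r1$fold_change, r2$fold_change, tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-9)
})

test_that("swapping group labels reciprocates fold changes", {
  set.seed(14)
  m <- matrix(rlnorm(10 * 10, log(500), 0.5), 10,
              dimnames = list(sprintf("F%02d", 1:10), NULL))
  s <- sprintf("S%d", 1:10)
  ft <- make_ft(m, s)
  ab <- select_differential_features(ft, s[1:5], s[6:10])
  ba <- select_differential_features(ft, s[6:10], s[1:5])
  expect_equal(ab$fold_change, 1 / ba$fold_change, tolerance = 1e-12)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
})

test_that("zero group means stay finite through the epsilon rule", {
  m <- rbind(F1 = c(0, 0, 0, 10, 12, 14),
             F2 = c(10, 12, 14, 0, 0, 0))
  ft <- make_ft(m, sprintf("S%d", 1:6))
  res <- select_differential_features(ft, sprintf("S%d", 1:3),
                                      sprintf("S%d", 4:6))
  expect_true(all(is.finite(res$fold_change)))
  expect_true(all(res$fold_change > 0))
  expect_true(res$fold_change[res$feature_id == "F2"] > 2)
})

test_that("volcano coordinates agree with the selection rule", {
  set.seed(15)
  m <- matrix(rlnorm(50 * 10, log(100), 1), 50,
              dimnames = list(sprintf("F%02d", 1:50), NULL))
  s <- sprintf("S%d", 1:10)
  res <- select_differential_features(make_ft(m, s), s[1:5], s[6:10])
  expect_equal(res$selected,
               res$log2_fc > 1 & res$neg_log10_p > -log10(0.05))
  expect_s3_class(plot_volcano(res), "ggplot")
})

test_that("groups must be disjoint and non-empty", {
  ft <- make_ft(rbind(F1 = 1:4), sprintf("S%d", 1:4))
  expect_error(select_differential_features(ft, "S1", character(0)),
               "non-empty")
  expect_error(select_differential_features(ft, c("S1", "S2"), c("S2", "S3")),
               "disjoint")
})

test_that("the accumulated ion chromatogram is the exact sum of member XICs", {
  b <- small_bundle(n = 6, seed = 71)
  run <- b$runs[["QC_positive_RPLC_G5"]]
  feats <- deconvolve_qc_dataset(b)
  aic <- build_aic(run, feats)
  xics <- purrr::map(feats$mz, ~ extract_xic(run, .x)$intensity)
  manual <- Reduce(`+`, xics)
  expect_equal(aic$trace$intensity, manual)
  # singleton case
  one <- build_aic(run, feats[1, ])
  expect_equal(one$trace$intensity, xics[[1]])
  # two disjoint-RT features give two apexes at their own heights
  ord <- order(feats$rt_reference)
  f2 <- feats[c(ord[1], ord[nrow(feats)]), ]
  if (diff(f2$rt_reference) > 1) {
    a2 <- build_aic(run, f2)
    expect_equal(sort(a2$scatter$apex_intensity),
                 sort(purrr::map_dbl(f2$mz,
                                     ~ max(extract_xic(run, .x)$intensity))))
  }
})

test_that("feature-list matching is exact on identity and robust to jitter", {
  set.seed(16)
  fl <- tibble(feature_id = sprintf("F%03d", 1:30),
               mz = sort(runif(30, 100, 900)),
               rt_reference = runif(30, 2, 20))
  self <- match_feature_lists(fl, fl, tol_ppm = 10, rt_tol = 0.1)
  expect_equal(self$overlap, 30)
  jit <- fl %>% mutate(mz = .data$mz * (1 + 5e-6),
                       feature_id = paste0("J", .data$feature_id))
  expect_equal(match_feature_lists(fl, jit, tol_ppm = 10, rt_tol = 0.1)$overlap,
               30)
  far <- fl %>% mutate(mz = .data$mz + 200)
  expect_equal(match_feature_lists(fl, far, tol_ppm = 10, rt_tol = 0.1)$overlap,
               0)
})
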