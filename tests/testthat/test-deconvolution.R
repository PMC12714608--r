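# hand-built peak tables: one row per detected MS1 peak per gradient
grad_ids <- paste0("G", 1:9)

peaks_for <- function(mz, rts, height = 5000, gradients = grad_ids) {
  tibble(gradient_id = gradients[seq_along(rts)], mz = mz, rt_apex = rts,
         height = height, area = height * 3)
}

test_that("a compound present in all nine gradients links to one feature", {
  rts <- seq(5, 13, length.out = 9)
  f <- link_precursors_across_gradients(peaks_for(300.12, rts))
  expect_equal(nrow(f), 1)
  expect_equal(f$support, 9L)
  expect_equal(unname(f$rt_vector[[1]][grad_ids]), rts)
  expect_equal(f$rt_reference, rts[5])
})

test_that("features below the gradient-support threshold are discarded", {
  f <- link_precursors_across_gradients(
    peaks_for(300.12, c(5, 6, 7, 8, 9), gradients = paste0("G", c(1:4, 5))),
    min_gradients = 7)
  expect_equal(nrow(f), 0)
})

test_that("clusters with no reference-gradient detection are rejected with a reason", {
  expect_message(
    f <- link_precursors_across_gradients(
      peaks_for(300.12, seq(5, 12, length.out = 8),
                gradients = setdiff(grad_ids, "G5")),
      min_gradients = 7),
    "rejected")
  expect_equal(nrow(f), 0)
  rej <- attr(f, "rejected")
  expect_equal(nrow(rej), 1)
  expect_match(rej$reason, "G5")
})

test_that("isomer pairs with one crossing gradient keep rank-consistent RT vectors", {
  rts_a <- c(5.0, 5.5, 6.0, 6.5, 7.0, 7.5, 8.0, 8.5, 9.0)
  rts_b <- rts_a + 0.8
  rts_b[3] <- rts_a[3] - 0.3  # elution order crosses in G3 only
  pk <- bind_rows(peaks_for(400.2, rts_a), peaks_for(400.2, rts_b))
  f <- link_precursors_across_gradients(pk, min_gradients = 7)
  expect_equal(nrow(f), 2)
  match_a <- vapply(f$rt_vector,
                    function(v) sum(abs(v[grad_ids] - rts_a) < 1e-9), numeric(1))
  match_b <- vapply(f$rt_vector,
                    function(v) sum(abs(v[grad_ids] - rts_b) < 1e-9), numeric(1))
  expect_equal(max(match_a), 8)  # truth recovered in >= 8 of 9 gradients
  expect_equal(max(match_b), 8)
})

wins <- tibble(window = 1:2, core_low = c(70, 400), core_high = c(400, 1200),
               low = c(70, 399.5), high = c(400.5, 1200))

ms2_peaks_for <- function(mz, rts, window = 1, height = 2000,
                          gradients = grad_ids) {
  tibble(gradient_id = gradients[seq_along(rts)], window = window, mz = mz,
         rt_apex = rts, height = height, area = height * 3)
}

feature_for <- function(mz, rts) {
  tibble(feature_id = "F0001", mz = mz,
         rt_vector = list(setNames(rts, grad_ids)),
         rt_reference = rts[5], support = 9L, ref_height = 5000)
}

test_that("a fragment sharing the precursor's retention behavior is assigned", {
  rts <- seq(5, 13, length.out = 9)
  f <- crb_deconvolve_ms2(feature_for(300.12, rts),
                          ms2_peaks_for(150.05, rts), wins)
  sp <- f$ms2_spectrum[[1]]
  expect_equal(nrow(sp), 1)
  expect_equal(sp$behavior_corr, 1)
  expect_equal(sp$intensity, 2000)
})

test_that("fragments above the precursor m/z are never assigned", {
  rts <- seq(5, 13, length.out = 9)
  f <- crb_deconvolve_ms2(feature_for(300.12, rts),
                          ms2_peaks_for(300.20, rts), wins)
  expect_equal(nrow(f$ms2_spectrum[[1]]), 0)
})

test_that("G5-co-eluting precursors with divergent behavior are not cross-assigned", {
  rts_a <- seq(5, 13, length.out = 9)
  rts_b <- c(8.2, 8.4, 8.6, 8.8, rts_a[5], 9.2, 9.4, 9.6, 9.8)
  expect_lt(abs(rts_a[5] - rts_b[5]), 0.02)        # co-elute under G5
  # elsewhere their apexes separate by far more than the tolerance
  expect_gt(min(abs(rts_a - rts_b)[-5]), 0.5)
  frag_b <- ms2_peaks_for(150.05, rts_b)
  f <- crb_deconvolve_ms2(feature_for(300.12, rts_a), frag_b, wins)
  expect_equal(nrow(f$ms2_spectrum[[1]]), 0)
})

test_that("a degenerate single-gradient series collapses to co-elution grouping", {
  # the same gradient relabeled nine times: the co-eluting foreign fragment
  # can no longer be told apart -- the negative control motivating nine
  # genuinely different gradients
  rt5 <- rep(9, 9)
  frag_foreign <- ms2_peaks_for(150.05, rep(9.01, 9))
  f <- crb_deconvolve_ms2(feature_for(300.12, rt5), frag_foreign, wins)
  expect_equal(nrow(f$ms2_spectrum[[1]]), 1)
})

test_that("candidates with too few shared gradients are skipped", {
  rts <- seq(5, 13, length.out = 9)
  frag <- ms2_peaks_for(150.05, rts[1:3], gradients = grad_ids[1:3])
  f <- crb_deconvolve_ms2(feature_for(300.12, rts), frag, wins,
                          min_shared = 4)
  expect_equal(nrow(f$ms2_spectrum[[1]]), 0)
})

test_that("targeted re-search recovers planted areas and handles absence", {
  cmp <- simulate_compounds(6, seed = 61, coelute_fraction = 0)
  cmp$mode <- "positive"
  des <- study_design(3, 2, 3, 2)
  conc <- simulate_concentrations(cmp, des, seed = 61)
  conc$conc_ppm[conc$compound_id == "C001" & conc$sample_id == "S01"] <- 0
  b <- simulate_dia_acquisition(cmp, des, conc, quiet_config(61),
                                modes = "positive", columns = "RPLC",
                                include_samples = TRUE,
                                samples = c("S01", "S02"))
  feats <- deconvolve_qc_dataset(b)
  feats <- match_features_to_truth(feats, b)
  ft <- targeted_peak_areas(b, feats, samples = c("S01", "S02", "S03"))
  truth <- b$truth$run_signals %>% filter(!grepl("^QC", .data$run_id))
  f1 <- feats$feature_id[feats$compound_id == "C001"]
  # compound zeroed out in S01: area 0
  expect_equal(ft$area[ft$feature_id == f1 & ft$sample_id == "S01"], 0)
  # sample S03 has no run: NA, distinct from 0
  expect_true(all(is.na(ft$area[ft$sample_id == "S03"])))
  # detected cells match planted areas
  truth2 <- truth %>%
    mutate(sample_id = sub("_.*", "", .data$run_id))
  chk <- ft %>%
    filter(.data$sample_id %in% c("S01", "S02"), .data$area > 0) %>%
    inner_join(feats %>% select("feature_id", "compound_id"),
               by = "feature_id") %>%
    inner_join(truth2, by = c("compound_id", "sample_id"))
  expect_gt(nrow(chk), 0)
  expect_equal(chk$area, chk$true_area, tolerance = 0.02)
})

test_that("peaks far outside the retention window yield zero area", {
  cmp <- simulate_compounds(2, seed = 62, coelute_fraction = 0)
  cmp$mode <- "positive"
  des <- study_design(2, 2, 2, 2)
  conc <- simulate_concentrations(cmp, des, seed = 62)
  b <- simulate_dia_acquisition(cmp, des, conc, quiet_config(62),
                                modes = "positive", columns = "RPLC",
                                include_samples = TRUE, samples = "S01")
  feats <- deconvolve_qc_dataset(b)
  shifted <- feats %>% mutate(rt_reference = .data$rt_reference + 2 * 0.2)
  ft <- targeted_peak_areas(b, shifted, samples = "S01", rt_window = 0.2)
  ft_true <- targeted_peak_areas(b, feats, samples = "S01", rt_window = 0.2)
  expect_true(all(ft$area == 0))
  expect_true(all(ft_true$area > 0))
})
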