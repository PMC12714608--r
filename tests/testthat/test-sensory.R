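test_that("a noiseless generator returns the group baselines exactly", {
  des <- study_design(3, 2, 3, 2)
  sc <- simulate_sensory_scores(des, noise_sd = 0, assessor_bias_sd = 0,
                                seed = 1)
  joined <- sc %>% left_join(default_group_baselines(),
                             by = c("group", "metric"))
  expect_equal(joined$score, joined$baseline)
  # and the group radar reproduces the baselines after aggregation
  prof <- sample_sensory_profile(flag_outlier_scores(sc))
  radar <- group_sensory_profile(prof) %>%
    left_join(default_group_baselines(), by = c("group", "metric"))
  expect_equal(radar$score, radar$baseline)
})

test_that("scores respect the metric ranges even under extreme noise", {
  des <- study_design(3, 2, 3, 2)
  sc <- simulate_sensory_scores(des, noise_sd = 40, seed = 2)
  rng <- sensory_metric_ranges()
  joined <- left_join(sc, rng, by = "metric")
  expect_true(all(joined$score >= joined$min & joined$score <= joined$max))
  expect_error(simulate_sensory_scores(des, noise_sd = -1), "non-negative")
})

test_that("a planted 6-point astringency effect is recovered on average", {
  base <- default_group_baselines() %>%
    mutate(baseline = dplyr::case_when(
      .data$metric == "astringency" & .data$group == "N2" ~ 30,
      .data$metric == "astringency" & .data$group == "N1" ~ 36,
      TRUE ~ .data$baseline))
  des <- study_design(3, 4, 4, 2)
  diffs <- vapply(seq_len(200), function(r) {
    sc <- simulate_sensory_scores(des, baselines = base, noise_sd = 1,
                                  assessor_bias_sd = 0, seed = 1000 + r)
    m <- sc %>% filter(.data$metric == "astringency") %>%
      group_by(.data$group) %>% summarise(s = mean(.data$score))
    m$s[m$group == "N1"] - m$s[m$group == "N2"]
  }, numeric(1))
  expect_equal(mean(diffs), 6, tolerance = 0.5 / 6)
})

test_that("default baselines rank N1 above N2&T above N3 on the key metrics", {
  des <- study_design(6, 5, 6, 4)
  sc <- simulate_sensory_scores(des, noise_sd = 1, seed = 3)
  prof <- group_sensory_profile(sample_sensory_profile(flag_outlier_scores(sc)))
  for (m in c("astringency", "nasal_moistening")) {
    v <- prof %>% filter(.data$metric == m)
    get <- function(g) v$score[v$group == g]
    expect_gt(get("N1"), max(get("N2"), get("T")))
    expect_gt(min(get("N2"), get("T")), get("N3"))
  }
})

test_that("the IQR screen flags a lone extreme score (Tukey hinges)", {
  x <- tibble(sample_id = "S1", metric = "astringency",
              assessor_id = paste0("A", 1:6),
              score = c(30, 31, 32, 33, 34, 50))
  # hinges 31 and 34, upper fence 34 + 1.5 * 3 = 38.5
  expect_equal(flag_outlier_scores(x)$outlier,
               c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
})

test_that("tight and degenerate score clusters are never flagged", {
  tight <- tibble(sample_id = "S1", metric = "aroma",
                  assessor_id = paste0("A", 1:6), score = 30:35)
  expect_false(any(flag_outlier_scores(tight)$outlier))
  equal <- tibble(sample_id = "S1", metric = "aroma",
                  assessor_id = paste0("A", 1:6), score = rep(33, 6))
  expect_false(any(flag_outlier_scores(equal)$outlier))
})

test_that("cells with fewer than four scores are exempt from flagging", {
  small <- tibble(sample_id = "S1", metric = "aroma",
                  assessor_id = paste0("A", 1:3), score = c(10, 30, 90))
  expect_message(out <- flag_outlier_scores(small), "screened")
  expect_false(any(out$outlier))
})

test_that("profile aggregation excludes flagged scores", {
  x <- tibble(sample_id = "S1", metric = "astringency",
              assessor_id = paste0("A", 1:6),
              score = c(30, 30, 30, 30, 30, 50))
  prof <- sample_sensory_profile(flag_outlier_scores(x))
  expect_equal(prof$astringency, 30)
  prof_all <- sample_sensory_profile(flag_outlier_scores(x),
                                     exclude_flagged = FALSE)
  expect_equal(prof_all$astringency, mean(c(rep(30, 5), 50)))
})

test_that("one aberrant assessor is flagged at about its planted share", {
  des <- study_design(12, 5, 12, 4)
  sc <- simulate_sensory_scores(des, noise_sd = 1, assessor_bias_sd = 0,
                                seed = 9)
  aberr <- sc$assessor_id == "A6" & sc$metric != "aroma"
  sc$score[aberr] <- pmin(sc$score[aberr] + 12, 50)
  fl <- flag_outlier_scores(sc)
  # flagged fraction approximates the planted aberrant share (1/6 of the
  # four affected metrics = 2/15 of all records), within binomial slack
  planted <- mean(aberr)
  got <- mean(fl$outlier)
  se <- sqrt(planted * (1 - planted) / nrow(sc))
  expect_lt(abs(got - planted), 0.02 + 3 * se)
})
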