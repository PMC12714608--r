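#' Default group baselines of the sensory panel
#'
#' Per-group expected scores for the five metrics, encoding the study-design
#' pattern the generator plants: tobacco extracts (T) show strong aroma and
#' moderate everything else; N2 extracts sit marginally above T; N1 extracts
#' stand out on astringency and nasal moistening; N3 extracts fall clearly
#' below on those two metrics.
#'
#' @return Tibble with `group`, `metric`, `baseline`.
#' @export
default_group_baselines <- function() {
  tribble(
    ~group, ~nasal_sweetness, ~mouthful_sweetness, ~aroma,
    ~nasal_moistening, ~astringency,
    "T",  31.3, 31.3, 84.9, 32.6, 32.3,
    "N2", 32.3, 32.3, 84.0, 33.6, 33.3,
    "N1", 33.0, 33.5, 79.0, 39.0, 39.5,
    "N3", 29.0, 32.0, 78.5, 23.5, 23.8
  ) %>%
    pivot_longer(-"group", names_to = "metric", values_to = "baseline")
}

#' Simulate sensory-panel scores
#'
#' Each score is the group baseline for the metric, plus optional
#' compound-driven terms (`weight * log1p(concentration)` summed over driver
#' compounds), plus a per-assessor bias and Gaussian noise, truncated to the
#' metric's allowed range (0--50, or 0--100 for aroma).
#'
#' @param design Tibble from [study_design()].
#' @param concentrations Optional tibble from [simulate_concentrations()];
#'   required when `driver_weights` is given.
#' @param driver_weights Optional tibble `compound_id` x `metric` x `weight`
#'   linking metabolite levels to perceived scores.
#' @param baselines Group baselines, see [default_group_baselines()].
#' @param assessors Number of panel assessors.
#' @param assessor_bias_sd SD of the per-assessor additive bias, points.
#' @param noise_sd SD of the per-score Gaussian noise, points (must be
#'   non-negative).
#' @param seed Integer seed.
#' @return Long tibble: `sample_id`, `group`, `assessor_id`, `metric`,
#'   `score`.
#' @export
simulate_sensory_scores <- function(design, concentrations = NULL,
                                    driver_weights = NULL,
                                    baselines = default_group_baselines(),
                                    assessors = 6, assessor_bias_sd = 0.5,
                                    noise_sd = 1, seed = 1) {
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  set.seed(seed + 2L)
  ranges <- sensory_metric_ranges()
  bias <- tibble(assessor_id = sprintf("A%d", seq_len(assessors)),
                 bias = rnorm(assessors, 0, assessor_bias_sd))
  grid <- crossing(design, bias, ranges)
  grid <- left_join(grid, baselines, by = c("group", "metric"))
  if (!is.null(driver_weights)) {
    stopifnot(!is.null(concentrations))
    drive <- concentrations %>%
      inner_join(driver_weights, by = "compound_id",
                 relationship = "many-to-many") %>%
      group_by(.data$sample_id, .data$metric) %>%
      summarise(drive = sum(.data$weight * log1p(.data$conc_ppm)),
                .groups = "drop")
    grid <- left_join(grid, drive, by = c("sample_id", "metric")) %>%
      mutate(drive = dplyr::coalesce(.data$drive, 0))
  } else {
    grid$drive <- 0
  }
  grid %>%
    mutate(
      score = .data$baseline + .data$drive + .data$bias +
        rnorm(dplyr::n(), 0, noise_sd),
      score = pmin(pmax(.data$score, .data$min), .data$max)
    ) %>%
    select("sample_id", "group", "assessor_id", "metric", "score")
}

#' Flag outlying panel scores by the interquartile-range rule
#'
#' Within each (sample, metric) cell across assessors, scores outside
#' `[Q1 - k * IQR, Q3 + k * IQR]` are flagged, with Q1/Q3 the Tukey hinges
#' (as in `stats::fivenum()`). Flags are annotations; no score is removed.
#' Cells with fewer than 4 scores are left unflagged (too few values for
#' hinges to mean anything) and counted in a message.
#'
#' @param scores Long score tibble (see [simulate_sensory_scores()]).
#' @param k Fence multiplier, conventionally 1.5.
#' @return `scores` with a logical `outlier` column.
#' @export
#' @examples
#' x <- tibble::tibble(sample_id = "S1", metric = "astringency",
#'   assessor_id = paste0("A", 1:6), score = c(30, 31, 32, 33, 34, 50))
#' flag_outlier_scores(x)$outlier
flag_outlier_scores <- function(scores, k = 1.5) {
  out <- scores %>%
    group_by(.data$sample_id, .data$metric) %>%
    mutate(outlier = {
      if (dplyr::n() < 4) {
        rep(FALSE, dplyr::n())
      } else {
        fn <- fivenum(.data$score)
        iqr <- fn[4] - fn[2]
        .data$score < fn[2] - k * iqr | .data$score > fn[4] + k * iqr
      }
    }) %>%
    ungroup()
  small <- scores %>% count(.data$sample_id, .data$metric) %>%
    filter(.data$n < 4) %>% nrow()
  if (small > 0) {
    inform(sprintf("%d sample-metric cell(s) had < 4 scores; not screened",
                   small))
  }
  out
}

#' Per-sample sensory profiles
#'
#' Arithmetic mean score per sample and metric, optionally excluding flagged
#' outliers. When every score of a cell is flagged the cell is left missing.
#'
#' @param scores Score tibble, with an `outlier` column if
#'   `exclude_flagged = TRUE` (see [flag_outlier_scores()]).
#' @param exclude_flagged Drop flagged scores before averaging.
#' @return Wide tibble: `sample_id`, `group` (if present), one column per
#'   metric.
#' @export
sample_sensory_profile <- function(scores, exclude_flagged = TRUE) {
  if (exclude_flagged) {
    if (!"outlier" %in% names(scores)) {
      abort("scores carry no `outlier` column; run flag_outlier_scores() first")
    }
    scores <- filter(scores, !.data$outlier)
  }
  keys <- intersect(c("sample_id", "group"), names(scores))
  scores %>%
    group_by(dplyr::across(dplyr::all_of(c(keys, "metric")))) %>%
    summarise(score = mean(.data$score), .groups = "drop") %>%
    pivot_wider(names_from = "metric", values_from = "score")
}

#' Group-level radar profile
#'
#' Mean of the per-sample profiles within each group, the quantity shown on
#' sensory radar diagrams.
#'
#' @param profiles Wide profile tibble from [sample_sensory_profile()] with
#'   a `group` column.
#' @return Long tibble `group` x `metric` x `score`.
#' @export
group_sensory_profile <- function(profiles) {
  stopifnot("group" %in% names(profiles))
  profiles %>%
    pivot_longer(-dplyr::any_of(c("sample_id", "group")),
                 names_to = "metric", values_to = "score") %>%
    group_by(.data$group, .data$metric) %>%
    summarise(score = mean(.data$score, na.rm = TRUE), .groups = "drop")
}
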