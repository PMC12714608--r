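#' Welch's two-sample t test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom and a
#' two-sided p value. Conventions for degenerate inputs are explicit: with
#' zero variance in both groups the degrees of freedom are clamped at 1 and
#' the statistic is 0 (p = 1) for equal means or +/-Inf (p = 0) for unequal
#' means.
#'
#' @param x,y Numeric vectors (each of length >= 2).
#' @return Tibble with `t_stat`, `df`, `p_value`.
#' @export
#' @examples
#' welch_t_test(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, df = 4, p ~ 0.0213
welch_t_test <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) {
    abort("each group needs at least 2 finite values")
  }
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  dm <- mean(x) - mean(y)
  if (se2 == 0) {
    t_stat <- if (dm == 0) 0 else sign(dm) * Inf
    return(tibble(t_stat = t_stat, df = 1,
                  p_value = if (dm == 0) 1 else 0))
  }
  t_stat <- dm / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  df <- max(df, 1)
  tibble(t_stat = t_stat, df = df,
         p_value = 2 * pt(-abs(t_stat), df))
}

#' Select differential (abundant) ion features between two groups
#'
#' A feature is selected as enriched in group A iff its mean-area fold
#' change over group B strictly exceeds `fc_min` and the Welch-t p value is
#' below `p_max` (no multiple-testing correction, deliberately mirroring the
#' workflow's liberal raw-p filter). Zero group means are replaced by an
#' epsilon equal to half the smallest positive area in the table so fold
#' changes stay finite without inventing an intensity scale; `NA` areas
#' (missing runs) are excluded from the statistics.
#'
#' @param feature_table Long tibble `feature_id` x `sample_id` x `area`.
#' @param group_a,group_b Disjoint character vectors of sample ids;
#'   enrichment is reported for A over B.
#' @param label_a,label_b Group labels carried into the result.
#' @param fc_min Fold-change threshold (strict `>`).
#' @param p_max p-value threshold (strict `<`).
#' @param log_transform Test on `log(area + epsilon)` instead of raw areas.
#' @return Tibble with one row per feature: `feature_id`, `fold_change`,
#'   `t_stat`, `df`, `p_value`, `selected`, `enriched_in`, `log2_fc`,
#'   `neg_log10_p`.
#' @export
select_differential_features <- function(feature_table, group_a, group_b,
                                         label_a = "A", label_b = "B",
                                         fc_min = 2, p_max = 0.05,
                                         log_transform = FALSE) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    abort("both groups must be non-empty")
  }
  if (length(intersect(group_a, group_b)) > 0) {
    abort("groups must be disjoint")
  }
  pos <- feature_table$area[!is.na(feature_table$area) &
                              feature_table$area > 0]
  eps <- if (length(pos)) min(pos) / 2 else .Machine$double.eps
  ft <- feature_table %>%
    filter(.data$sample_id %in% c(group_a, group_b), !is.na(.data$area)) %>%
    mutate(side = ifelse(.data$sample_id %in% group_a, "a", "b"))
  res <- ft %>%
    group_by(.data$feature_id) %>%
    group_modify(function(d, key) {
      xa <- d$area[d$side == "a"]
      xb <- d$area[d$side == "b"]
      if (log_transform) {
        tt <- welch_t_test(log(xa + eps), log(xb + eps))
      } else {
        tt <- welch_t_test(xa, xb)
      }
      ma <- max(mean(xa), eps)
      mb <- max(mean(xb), eps)
      tibble(fold_change = ma / mb, tt)
    }) %>%
    ungroup() %>%
    mutate(
      selected = .data$fold_change > fc_min & .data$p_value < p_max,
      enriched_in = ifelse(.data$selected, label_a, NA_character_),
      log2_fc = log2(.data$fold_change),
      neg_log10_p = -log10(pmax(.data$p_value, .Machine$double.xmin))
    )
  res
}

#' Accumulated ion chromatogram of selected features
#'
#' Sums the XICs of a feature set over the MS1 scan axis of one run: the
#' AIC value at every time point equals the sum of the member XIC values.
#' Also returns the (m/z, retention time, apex intensity) scatter table used
#' for feature-map plots.
#'
#' @param run An `ms_run` (typically the reference-gradient QC run).
#' @param features Feature tibble with `feature_id` and `mz`.
#' @param tol_ppm XIC tolerance.
#' @return List with `trace` (tibble `scan`, `rt`, `intensity`) and
#'   `scatter` (tibble `feature_id`, `mz`, `rt`, `apex_intensity`).
#' @export
build_aic <- function(run, features, tol_ppm = 10) {
  sc <- run$scans[run$scans$ms_level == 1L, c("scan", "rt")]
  total <- rep(0, nrow(sc))
  scatter <- vector("list", nrow(features))
  for (i in seq_len(nrow(features))) {
    x <- extract_xic(run, features$mz[i], tol_ppm = tol_ppm)
    total <- total + x$intensity
    j <- which.max(x$intensity)
    scatter[[i]] <- tibble(feature_id = features$feature_id[i],
                           mz = features$mz[i],
                           rt = if (length(j)) x$rt[j] else NA_real_,
                           apex_intensity = if (length(j)) x$intensity[j] else 0)
  }
  list(trace = tibble(scan = sc$scan, rt = sc$rt, intensity = total),
       scatter = bind_rows(scatter))
}

#' Match two feature lists
#'
#' Greedy nearest-m/z pairing: all candidate pairs within `tol_ppm` and
#' `rt_tol` are ranked by relative m/z gap and accepted greedily so that
#' each feature is matched at most once. Used to compare feature lists from
#' two deconvolution routes.
#'
#' @param list_a,list_b Feature tibbles with `feature_id`, `mz`,
#'   `rt_reference`.
#' @param tol_ppm m/z tolerance.
#' @param rt_tol Retention tolerance, minutes.
#' @return List with `overlap` (count), `pairs` (tibble `feature_a`,
#'   `feature_b`, `d_ppm`, `d_rt`), `unmatched_a`, `unmatched_b`.
#' @export
match_feature_lists <- function(list_a, list_b, tol_ppm = 10, rt_tol = 0.1) {
  if (nrow(list_a) == 0 || nrow(list_b) == 0) {
    return(list(overlap = 0L, pairs = tibble(),
                unmatched_a = list_a$feature_id,
                unmatched_b = list_b$feature_id))
  }
  cand <- crossing(
    list_a %>% transmute(feature_a = .data$feature_id, mz_a = .data$mz,
                         rt_a = .data$rt_reference),
    list_b %>% transmute(feature_b = .data$feature_id, mz_b = .data$mz,
                         rt_b = .data$rt_reference)
  ) %>%
    mutate(d_ppm = abs(.data$mz_a - .data$mz_b) /
             .data$mz_a * 1e6,
           d_rt = abs(.data$rt_a - .data$rt_b)) %>%
    filter(.data$d_ppm <= tol_ppm, .data$d_rt <= rt_tol) %>%
    arrange(.data$d_ppm, .data$d_rt)
  used_a <- character(); used_b <- character()
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!cand$feature_a[i] %in% used_a && !cand$feature_b[i] %in% used_b) {
      keep[i] <- TRUE
      used_a <- c(used_a, cand$feature_a[i])
      used_b <- c(used_b, cand$feature_b[i])
    }
  }
  pairs <- cand[keep, c("feature_a", "feature_b", "d_ppm", "d_rt")]
  list(overlap = nrow(pairs), pairs = pairs,
       unmatched_a = setdiff(list_a$feature_id, pairs$feature_a),
       unmatched_b = setdiff(list_b$feature_id, pairs$feature_b))
}

#' Volcano plot of differential results
#'
#' @param results Tibble from [select_differential_features()].
#' @param fc_min,p_max Thresholds drawn as guide lines.
#' @return A ggplot.
#' @export
plot_volcano <- function(results, fc_min = 2, p_max = 0.05) {
  ggplot2::ggplot(results, ggplot2::aes(.data$log2_fc, .data$neg_log10_p,
                                        color = .data$selected)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(-log2(fc_min), log2(fc_min)),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(p_max), linetype = "dashed") +
    ggplot2::scale_color_manual(values = c(`TRUE` = "#d7301f",
                                           `FALSE` = "grey60")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p") +
    ggplot2::theme_minimal()
}
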