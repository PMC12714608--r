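#' Link MS1 peaks across the gradient series into ion features
#'
#' Peaks from the nine QC gradients of one (ionization mode, column mode)
#' dataset are clustered by m/z; within each cluster the per-gradient peaks
#' are assembled into a retention-time vector, one entry per gradient. When
#' a gradient offers several isomeric peaks of the same m/z, assignment is by
#' within-gradient elution rank: peak ranks are far more stable across
#' gradient programs than absolute retention times, so the rank-consistent
#' assignment minimizes the squared deviation of gradient-normalized
#' retention across the vector. Clusters without a detection in the
#' reference gradient are rejected (the reference retention time anchors all
#' downstream targeted work); features seen in fewer than `min_gradients`
#' gradients are discarded.
#'
#' @param peaks Tibble of MS1 peaks with columns `gradient_id`, `mz`,
#'   `rt_apex`, `height`, `area` (one row per peak, all gradients pooled).
#' @param tol_ppm m/z clustering tolerance.
#' @param min_gradients Minimum number of gradients a feature must appear in.
#' @param reference Reference gradient id (default `"G5"`).
#' @return Tibble of ion features: `feature_id`, `mz`, `rt_vector`
#'   (list-column of named per-gradient retention times), `rt_reference`,
#'   `support`, `ref_height`. Rejected clusters (no reference detection) are
#'   attached as the `"rejected"` attribute with a reason column.
#' @export
link_precursors_across_gradients <- function(peaks, tol_ppm = 10,
                                             min_gradients = 7,
                                             reference = "G5") {
  if (nrow(peaks) == 0) {
    return(structure(empty_features(), rejected = tibble()))
  }
  peaks$cluster <- mz_clusters(peaks$mz, tol_ppm)
  peaks <- peaks %>%
    group_by(.data$cluster, .data$gradient_id) %>%
    arrange(.data$rt_apex, .by_group = TRUE) %>%
    mutate(rank = dplyr::row_number()) %>%
    ungroup()

  assembled <- peaks %>%
    group_by(.data$cluster, .data$rank) %>%
    summarise(
      mz = weighted.mean(.data$mz, .data$height),
      support = dplyr::n(),
      rt_reference = ifelse(any(.data$gradient_id == reference),
                            .data$rt_apex[.data$gradient_id == reference][1],
                            NA_real_),
      ref_height = ifelse(any(.data$gradient_id == reference),
                          .data$height[.data$gradient_id == reference][1],
                          NA_real_),
      rt_vector = list(setNames(.data$rt_apex, .data$gradient_id)),
      .groups = "drop"
    )

  rejected <- assembled %>%
    filter(is.na(.data$rt_reference)) %>%
    mutate(reason = sprintf("no detection in reference gradient %s", reference)) %>%
    select("mz", "support", "reason")
  if (nrow(rejected) > 0) {
    inform(sprintf("%d feature cluster(s) rejected: no %s detection",
                   nrow(rejected), reference))
  }

  feats <- assembled %>%
    filter(!is.na(.data$rt_reference), .data$support >= min_gradients) %>%
    arrange(.data$mz) %>%
    mutate(feature_id = sprintf("F%04d", dplyr::row_number())) %>%
    select("feature_id", "mz", "rt_vector", "rt_reference", "support",
           "ref_height")
  structure(feats, rejected = rejected)
}

empty_features <- function() {
  tibble(feature_id = character(), mz = numeric(), rt_vector = list(),
         rt_reference = numeric(), support = integer(), ref_height = numeric())
}

# behavior agreement between a fragment and its precursor: RT-vector match
# in every shared gradient plus Pearson correlation of the shared vectors.
# Constant shared vectors (degenerate gradient sets) carry no behavior
# information; they are scored 1 when co-elution holds everywhere.
behavior_agreement <- function(prec_rt, frag_rt, rt_tol, min_shared) {
  shared <- intersect(names(prec_rt), names(frag_rt))
  if (length(shared) < min_shared) {
    return(list(ok = FALSE, reason = "fewer shared gradients than required",
                corr = NA_real_))
  }
  d <- frag_rt[shared] - prec_rt[shared]
  if (any(abs(d) > rt_tol)) {
    return(list(ok = FALSE, reason = "retention mismatch", corr = NA_real_))
  }
  p <- prec_rt[shared]; f <- frag_rt[shared]
  r <- if (sd(p) == 0 || sd(f) == 0) 1 else cor(p, f)
  list(ok = TRUE, reason = NA_character_, corr = r)
}

#' Assign DIA fragments to precursors by retention behavior
#'
#' For each linked precursor feature, fragment candidates are the MS2 peaks
#' detected in the SWATH window containing the feature m/z, clustered by
#' fragment m/z across the gradient series. A candidate is assigned iff (a)
#' in every gradient where both fragment and precursor were detected, their
#' apexes agree within `rt_tol`; and (b) the Pearson correlation between the
#' fragment's and the precursor's retention-time vectors over their shared
#' gradients (at least `min_shared`) reaches `min_behavior_corr`. With nine
#' genuinely different gradients this separates co-eluting precursors whose
#' retention *behaviors* differ; with a degenerate single-gradient series it
#' collapses to plain co-elution grouping. Assigned fragment intensities are
#' read from the reference gradient, and the output spectrum is sorted by
#' m/z. Fragments more than 0.02 Da above the precursor m/z are never
#' assigned.
#'
#' @param features Feature tibble from [link_precursors_across_gradients()].
#' @param ms2_peaks Tibble of MS2 peaks pooled over gradients: `gradient_id`,
#'   `window`, `mz`, `rt_apex`, `height`.
#' @param windows SWATH window tibble from [swath_windows()].
#' @param rt_tol Apex agreement tolerance, minutes.
#' @param min_behavior_corr Minimum retention-behavior correlation.
#' @param min_shared Minimum shared gradients for a candidate to be
#'   assessable; candidates below this are skipped, not rejected.
#' @param tol_ppm Fragment m/z clustering tolerance.
#' @param reference Reference gradient id.
#' @return `features` with list-column `ms2_spectrum` (tibbles `mz`,
#'   `intensity`, sorted by m/z) and `n_fragments`.
#' @export
crb_deconvolve_ms2 <- function(features, ms2_peaks, windows,
                               rt_tol = 0.05, min_behavior_corr = 0.99,
                               min_shared = 4, tol_ppm = 15,
                               reference = "G5") {
  if (nrow(features) == 0) {
    features$ms2_spectrum <- list()
    features$n_fragments <- integer()
    return(features)
  }
  # pre-cluster MS2 peaks per window
  by_window <- ms2_peaks %>%
    group_by(.data$window) %>%
    group_split() %>%
    purrr::map(function(d) {
      d$frag_cluster <- mz_clusters(d$mz, tol_ppm)
      d
    })
  names(by_window) <- purrr::map_chr(by_window, ~ as.character(.x$window[1]))

  features$ms2_spectrum <- purrr::pmap(
    list(features$mz, features$rt_vector),
    function(fmz, prec_rt, ...) {
      w <- window_of(windows, fmz)
      d <- by_window[[as.character(w)]]
      if (is.na(w) || is.null(d)) return(empty_spectrum())
      d <- d[d$mz <= fmz + 0.02, ]
      if (nrow(d) == 0) return(empty_spectrum())
      assigned <- d %>%
        group_by(.data$frag_cluster) %>%
        group_map(function(fd, key) {
          # per gradient keep the candidate apex nearest the precursor
          fd <- fd %>%
            mutate(dprec = abs(.data$rt_apex -
                                 prec_rt[.data$gradient_id])) %>%
            filter(!is.na(.data$dprec)) %>%
            group_by(.data$gradient_id) %>%
            slice_min(.data$dprec, n = 1, with_ties = FALSE) %>%
            ungroup()
          if (nrow(fd) == 0) return(NULL)
          frag_rt <- setNames(fd$rt_apex, fd$gradient_id)
          ba <- behavior_agreement(prec_rt, frag_rt, rt_tol, min_shared)
          if (!ba$ok || ba$corr < min_behavior_corr) return(NULL)
          if (!reference %in% fd$gradient_id) return(NULL)
          tibble(mz = weighted.mean(fd$mz, fd$height),
                 intensity = fd$height[fd$gradient_id == reference][1],
                 behavior_corr = ba$corr)
        }) %>%
        bind_rows()
      if (nrow(assigned) == 0) return(empty_spectrum())
      arrange(assigned, .data$mz)
    }
  )
  features$n_fragments <- purrr::map_int(features$ms2_spectrum, nrow)
  features
}

empty_spectrum <- function() {
  tibble(mz = numeric(), intensity = numeric(), behavior_corr = numeric())
}

#' Deconvolve one QC dataset end to end
#'
#' Convenience wrapper for one (ionization mode, column mode) dataset:
#' detects MS1 and MS2 peaks in each QC gradient run, links precursors
#' across gradients, and assigns fragments by retention behavior.
#'
#' @param bundle Simulation bundle from [simulate_dia_acquisition()] (or any
#'   list with `runs` and `windows` shaped the same way).
#' @param mode,column_mode Dataset selector.
#' @param ms1_min_height,ms2_min_height Peak-height thresholds for precursor
#'   and fragment traces (fragments run lower than their precursors).
#' @param tol_ppm,min_gradients,rt_tol,min_behavior_corr,min_shared,reference
#'   Passed through to the linking and CRB steps.
#' @return Feature tibble with `mode` and `column_mode` columns and
#'   deconvolved `ms2_spectrum`.
#' @export
deconvolve_qc_dataset <- function(bundle, mode = "positive",
                                  column_mode = "RPLC",
                                  ms1_min_height = 1000,
                                  ms2_min_height = 300,
                                  tol_ppm = 10, min_gradients = 7,
                                  rt_tol = 0.05, min_behavior_corr = 0.99,
                                  min_shared = 4, reference = "G5") {
  idx <- run_index(bundle) %>%
    filter(is.na(.data$sample_id), .data$mode == !!mode,
           .data$column_mode == !!column_mode)
  stopifnot(nrow(idx) > 0)
  ms1 <- purrr::map(idx$run_id, function(rid) {
    detect_ms1_peaks(bundle$runs[[rid]], tol_ppm = tol_ppm,
                     min_height = ms1_min_height) %>%
      mutate(gradient_id = bundle$runs[[rid]]$gradient_id)
  }) %>% bind_rows()
  ms2 <- purrr::map(idx$run_id, function(rid) {
    detect_ms2_peaks(bundle$runs[[rid]], tol_ppm = tol_ppm,
                     min_height = ms2_min_height) %>%
      mutate(gradient_id = bundle$runs[[rid]]$gradient_id)
  }) %>% bind_rows()
  feats <- link_precursors_across_gradients(ms1, tol_ppm = tol_ppm,
                                            min_gradients = min_gradients,
                                            reference = reference)
  wins <- bundle$windows[[paste(mode, column_mode, sep = "_")]]
  feats <- crb_deconvolve_ms2(feats, ms2, wins, rt_tol = rt_tol,
                              min_behavior_corr = min_behavior_corr,
                              min_shared = min_shared, tol_ppm = 2 * tol_ppm,
                              reference = reference)
  feats$mode <- mode
  feats$column_mode <- column_mode
  feats
}

#' Targeted peak areas of QC features in single-gradient sample runs
#'
#' Re-searches every linked feature in each individual sample run (acquired
#' under the reference gradient only): the XIC at the feature m/z is
#' extracted, a chromatographic peak is looked for with its apex inside
#' `rt_reference +/- rt_window`, and its area integrated. A feature with no
#' qualifying peak gets area 0 ("not detected"); samples with no run in the
#' dataset get `NA` ("missing run"), which is excluded from downstream
#' statistics rather than treated as zero.
#'
#' @param bundle Simulation bundle (or list with `runs`).
#' @param features Feature tibble with `mz` and `rt_reference`.
#' @param mode,column_mode Dataset selector.
#' @param samples Sample ids expected in the table (default: all samples
#'   present in `bundle$design`).
#' @param tol_ppm XIC tolerance.
#' @param rt_window Apex search half-window around the reference retention
#'   time, minutes.
#' @param min_height,min_width Peak criteria for the targeted search (more
#'   permissive than untargeted detection).
#' @return Long feature table: `feature_id`, `sample_id`, `area`.
#' @export
targeted_peak_areas <- function(bundle, features, mode = "positive",
                                column_mode = "RPLC", samples = NULL,
                                tol_ppm = 10, rt_window = 0.2,
                                min_height = 300, min_width = 4) {
  samples <- samples %||% bundle$design$sample_id
  idx <- run_index(bundle) %>%
    filter(!is.na(.data$sample_id), .data$mode == !!mode,
           .data$column_mode == !!column_mode)
  out <- purrr::map(samples, function(sid) {
    rid <- idx$run_id[idx$sample_id == sid]
    if (length(rid) == 0) {
      return(tibble(feature_id = features$feature_id, sample_id = sid,
                    area = NA_real_))
    }
    run <- bundle$runs[[rid[1]]]
    areas <- targeted_areas_one_run(run, features, tol_ppm, rt_window,
                                    min_height, min_width)
    tibble(feature_id = features$feature_id, sample_id = sid, area = areas)
  })
  bind_rows(out)
}

targeted_areas_one_run <- function(run, features, tol_ppm, rt_window,
                                   min_height, min_width) {
  sc <- run$scans[run$scans$ms_level == 1L, c("scan", "rt")]
  cent <- run$centroids[run$centroids$scan %in% sc$scan, ]
  ord <- order(cent$mz)
  cmz <- cent$mz[ord]
  cscan <- cent$scan[ord]
  cint <- cent$intensity[ord]
  vapply(seq_len(nrow(features)), function(i) {
    mz <- features$mz[i]
    rt0 <- features$rt_reference[i]
    tol <- mz * tol_ppm * 1e-6
    r <- findInterval(c(mz - tol, mz + tol), cmz)
    if (r[2] <= r[1]) return(0)
    sel <- (r[1] + 1):r[2]
    win <- sc$rt >= rt0 - rt_window - 0.4 & sc$rt <= rt0 + rt_window + 0.4
    axis <- sc[win, ]
    agg <- rowsum(cint[sel], cscan[sel])
    trace <- tibble(
      scan = axis$scan, rt = axis$rt,
      intensity = dplyr::coalesce(
        agg[match(as.character(axis$scan), rownames(agg)), 1], 0)
    )
    pk <- detect_chrom_peaks(trace, min_height = min_height,
                             min_width = min_width)
    pk <- pk[abs(pk$rt_apex - rt0) <= rt_window, ]
    if (nrow(pk) == 0) return(0)
    pk$area[which.min(abs(pk$rt_apex - rt0))]
  }, numeric(1))
}

#' Pivot a long feature table to a features x samples matrix
#'
#' @param feature_table Long tibble from [targeted_peak_areas()].
#' @return Numeric matrix, rows = features, columns = samples.
#' @export
feature_table_matrix <- function(feature_table) {
  wide <- feature_table %>%
    pivot_wider(names_from = "sample_id", values_from = "area")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$feature_id
  m
}
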