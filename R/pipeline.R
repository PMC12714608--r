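#' Pipeline configuration
#'
#' One object holding every tunable of the end-to-end study replica, with
#' defaults equal to the workflow's stated operating points where it states
#' them (fold change > 2, p < 0.05, mass error < 10 ppm, dot product > 0.4,
#' level-1 retention window 0.1 min) and to the package's documented
#' defaults elsewhere.
#'
#' @param seed Master seed; every stage derives its randomness from it.
#' @param n_compounds,coelute_fraction,isomer_pairs,n1_enriched_fraction,n2t_enriched_fraction,enrichment_fold,p_standard
#'   Compound-panel parameters, see [simulate_compounds()].
#' @param n_t,n_n1,n_n2,n_n3 Group sizes, see [study_design()].
#' @param modes,columns Datasets to simulate and analyze.
#' @param acquisition List of overrides for [acquisition_config()].
#' @param tol_ppm,min_gradients,rt_tol,min_behavior_corr,min_shared,ms1_min_height,ms2_min_height
#'   Deconvolution parameters.
#' @param rt_window,targeted_min_height Targeted re-search parameters.
#' @param fc_min,p_max Differential filter.
#' @param coverage_fraction,isomer_decoys Library emulation.
#' @param me_max_ppm,dp_min,frag_tol,rt_max,isomer_rt Annotation thresholds.
#' @param noise_sd,assessor_bias_sd,assessors Sensory generator.
#' @param quant_noise_cv Standard-addition area noise.
#' @param write_mzml Also serialize every simulated run to mzML.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            n_compounds = 200, coelute_fraction = 0.05,
                            isomer_pairs = 0,
                            n1_enriched_fraction = 0.25,
                            n2t_enriched_fraction = 0.10,
                            enrichment_fold = 6, p_standard = 0.5,
                            n_t = 24, n_n1 = 5, n_n2 = 24, n_n3 = 4,
                            modes = c("positive", "negative"),
                            columns = "RPLC",
                            acquisition = list(),
                            tol_ppm = 10, min_gradients = 7, rt_tol = 0.05,
                            min_behavior_corr = 0.99, min_shared = 4,
                            ms1_min_height = 1000, ms2_min_height = 300,
                            rt_window = 0.2, targeted_min_height = 300,
                            fc_min = 2, p_max = 0.05,
                            coverage_fraction = 0.7, isomer_decoys = 5,
                            me_max_ppm = 10, dp_min = 0.4, frag_tol = 0.025,
                            rt_max = 0.1, isomer_rt = 0.5,
                            noise_sd = 1, assessor_bias_sd = 0.5,
                            assessors = 6,
                            quant_noise_cv = 0,
                            write_mzml = FALSE) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Match deconvolved features to ground-truth compounds
#'
#' Nearest-match pairing of features against the simulated compounds of the
#' same dataset, on precursor m/z (ppm tolerance) and reference-gradient
#' retention time.
#'
#' @param features Feature tibble (with `mz`, `rt_reference`).
#' @param bundle Simulation bundle.
#' @param mode,column_mode Dataset selector.
#' @param tol_ppm,rt_tol Matching tolerances.
#' @param reference Reference gradient id.
#' @return `features` with a `compound_id` column (`NA` = unmatched).
#' @export
match_features_to_truth <- function(features, bundle, mode = "positive",
                                    column_mode = "RPLC", tol_ppm = 10,
                                    rt_tol = 0.1, reference = "G5") {
  truth <- bundle$compounds %>%
    filter(.data$mode == !!mode) %>%
    add_precursor_mz() %>%
    inner_join(bundle$truth$rt %>%
                 filter(.data$column_mode == !!column_mode,
                        .data$gradient_id == reference),
               by = "compound_id")
  features$compound_id <- purrr::map_chr(
    seq_len(nrow(features)), function(i) {
      dppm <- abs(truth$precursor_mz - features$mz[i]) / features$mz[i] * 1e6
      drt <- abs(truth$rt - features$rt_reference[i])
      ok <- which(dppm <= tol_ppm & drt <= rt_tol)
      if (length(ok) == 0) return(NA_character_)
      truth$compound_id[ok[which.min(drt[ok])]]
    })
  features
}

#' Score fragment assignment against generator truth
#'
#' For every truth-matched feature, the assigned fragments are compared to
#' the compound's fragment template. Expected fragments are template entries
#' whose simulated QC intensity clears the MS2 detection threshold with a
#' safety margin (borderline fragments are excluded from the recall
#' denominator but still count as correct when assigned). Precision =
#' TP / (TP + FP), recall = TP / (TP + FN).
#'
#' @param features Truth-matched feature tibble with `ms2_spectrum`.
#' @param bundle Simulation bundle.
#' @param ms2_min_height MS2 detection threshold used in deconvolution.
#' @param mz_tol Fragment m/z match tolerance, Da.
#' @param margin Detectability safety margin on the threshold.
#' @return List: `precision`, `recall`, `tp`, `fp`, `fn`.
#' @export
score_fragment_assignment <- function(features, bundle, ms2_min_height = 300,
                                      mz_tol = 0.05, margin = 1.5) {
  qc_conc <- bundle$truth$run_signals %>%
    filter(grepl("^QC", .data$run_id)) %>%
    distinct(.data$compound_id, .data$apex)
  frags <- bundle$truth$fragments
  ms2_lo <- bundle$config$ms2_range[1]
  ms2_hi <- bundle$config$ms2_range[2]
  tp <- 0L; fp <- 0L; fn <- 0L
  for (i in seq_len(nrow(features))) {
    cid <- features$compound_id[i]
    if (is.na(cid)) next
    tmpl <- frags %>% filter(.data$compound_id == cid) %>% unpack_fragments()
    apex <- qc_conc$apex[qc_conc$compound_id == cid][1]
    if (is.na(apex) || nrow(tmpl) == 0) next
    tmpl <- tmpl %>%
      filter(.data$mz >= ms2_lo, .data$mz <= ms2_hi) %>%
      mutate(clear = .data$rel_int * apex >= ms2_min_height * margin)
    sp <- features$ms2_spectrum[[i]]
    hit <- purrr::map_lgl(sp$mz, ~ any(abs(tmpl$mz - .x) <= mz_tol))
    tp <- tp + sum(hit)
    fp <- fp + sum(!hit)
    missed <- purrr::map_lgl(tmpl$mz[tmpl$clear],
                             ~ !any(abs(sp$mz - .x) <= mz_tol))
    fn <- fn + sum(missed)
  }
  list(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       tp = tp, fp = fp, fn = fn)
}

#' Score splitting of planted co-eluting pairs
#'
#' For every planted co-eluting pair whose two members were both recovered
#' as features, counts fragments assigned to one member that belong to the
#' *other* member's template only (cross-assignments). Retention-behavior
#' deconvolution across genuinely different gradients should keep this at
#' zero; a degenerate single-gradient series cannot.
#'
#' @param features Truth-matched feature tibble (see
#'   [match_features_to_truth()]) with `ms2_spectrum`.
#' @param bundle Simulation bundle.
#' @param mz_tol Fragment matching tolerance, Da.
#' @return List: `n_pairs` (evaluable pairs), `cross_assigned` (fragment
#'   count), `cross_rate` (cross-assigned / assigned fragments in pair
#'   features).
#' @export
score_coelution_splitting <- function(features, bundle, mz_tol = 0.05) {
  pairs <- bundle$compounds %>%
    filter(!is.na(.data$coelute_pair)) %>%
    select("compound_id", "coelute_pair")
  frags <- bundle$truth$fragments
  feats <- features %>% inner_join(pairs, by = "compound_id")
  cross <- 0L; total <- 0L; n_pairs <- 0L
  for (tag in unique(feats$coelute_pair)) {
    two <- feats %>% filter(.data$coelute_pair == tag)
    if (nrow(two) != 2) next
    n_pairs <- n_pairs + 1L
    for (k in 1:2) {
      own <- frags %>% filter(.data$compound_id == two$compound_id[k])
      other <- frags %>% filter(.data$compound_id == two$compound_id[3 - k])
      sp <- two$ms2_spectrum[[k]]
      total <- total + nrow(sp)
      is_own <- purrr::map_lgl(sp$mz, ~ any(abs(own$mz - .x) <= mz_tol))
      is_other <- purrr::map_lgl(sp$mz, ~ any(abs(other$mz - .x) <= mz_tol))
      cross <- cross + sum(is_other & !is_own)
    }
  }
  list(n_pairs = n_pairs, cross_assigned = cross,
       cross_rate = if (total > 0) cross / total else NA_real_)
}

unpack_fragments <- function(d) {
  if ("fragments" %in% names(d)) unnest(d, "fragments") else d
}

features_to_wide <- function(features, gradient_ids = paste0("G", 1:9)) {
  rtm <- purrr::map(features$rt_vector, function(v) {
    out <- setNames(rep(NA_real_, length(gradient_ids)), gradient_ids)
    out[names(v)] <- v
    as_tibble(as.list(out))
  }) %>% bind_rows()
  bind_cols(
    features %>% select(-dplyr::any_of(c("rt_vector", "ms2_spectrum"))),
    rtm %>% rename_with(~ paste0("rt_", .x))
  )
}

#' Run the full study replica
#'
#' Executes every stage in order on the configured (mode x column) datasets:
#' simulate compounds, concentrations, sensory scores and DIA runs; screen
#' and group the panel scores; deconvolve the QC gradient series; quantify
#' features in the sample runs by targeted re-search; select differential
#' features between the sensory contrasts (N1 vs N2&T, N2&T vs N3); build
#' accumulated ion chromatograms; annotate against the emulated library and
#' confirm with standards; quantify validated compounds by standard
#' addition and compose the three validation formulas. Every stage product
#' is written under `out_dir`; a ground-truth scorecard and a JSON summary
#' close the run. Deterministic for a fixed `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return A list of class `crbdia_report` (also serialized as
#'   `report.json`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("crbdia_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  ## --- simulate study ----------------------------------------------------
  compounds <- simulate_compounds(
    n = config$n_compounds, seed = seed,
    coelute_fraction = config$coelute_fraction,
    isomer_pairs = config$isomer_pairs,
    n1_enriched_fraction = config$n1_enriched_fraction,
    n2t_enriched_fraction = config$n2t_enriched_fraction,
    enrichment_fold = config$enrichment_fold,
    p_standard = config$p_standard)
  design <- study_design(config$n_t, config$n_n1, config$n_n2, config$n_n3)
  conc <- simulate_concentrations(compounds, design, seed = seed)
  acq <- do.call(acquisition_config,
                 utils::modifyList(list(seed = seed), config$acquisition))
  bundle <- simulate_dia_acquisition(
    compounds, design, conc, acq,
    modes = config$modes, columns = config$columns)
  if (config$write_mzml) {
    mz_dir <- file.path(out_dir, "mzml")
    dir.create(mz_dir, showWarnings = FALSE)
    purrr::walk(bundle$runs, function(r) {
      write_run_mzml(r, file.path(mz_dir, paste0(r$run_id, ".mzML")))
    })
  }

  ## --- sensory grouping --------------------------------------------------
  scores <- simulate_sensory_scores(
    design, noise_sd = config$noise_sd,
    assessor_bias_sd = config$assessor_bias_sd,
    assessors = config$assessors, seed = seed)
  scores <- flag_outlier_scores(scores)
  profiles <- sample_sensory_profile(scores)
  grouping <- classify_samples(
    profiles, tobacco_ids = design$sample_id[design$group == "T"],
    seed = seed)
  readr::write_csv(scores, file.path(out_dir, "sensory_scores.csv"))
  readr::write_csv(profiles, file.path(out_dir, "sensory_profiles.csv"))
  readr::write_csv(tidy(grouping), file.path(out_dir, "sample_groups.csv"))
  groups <- grouping$assignments
  g_n1 <- groups$sample_id[groups$group == "N1"]
  g_n2t <- groups$sample_id[groups$group %in% c("N2", "T")]
  g_n3 <- groups$sample_id[groups$group == "N3"]

  ## --- per-dataset deconvolution, quantification, statistics -------------
  datasets <- crossing(mode = config$modes, column_mode = config$columns)
  all_feats <- list(); all_ft <- list(); all_diff <- list()
  for (di in seq_len(nrow(datasets))) {
    mo <- datasets$mode[di]; cl <- datasets$column_mode[di]
    tag <- paste(mo, cl, sep = "_")
    feats <- deconvolve_qc_dataset(
      bundle, mode = mo, column_mode = cl,
      ms1_min_height = config$ms1_min_height,
      ms2_min_height = config$ms2_min_height,
      tol_ppm = config$tol_ppm, min_gradients = config$min_gradients,
      rt_tol = config$rt_tol, min_behavior_corr = config$min_behavior_corr,
      min_shared = config$min_shared)
    feats$feature_id <- paste(tag, feats$feature_id, sep = "_")
    readr::write_csv(features_to_wide(feats),
                     file.path(out_dir, paste0("features_", tag, ".csv")))
    spec_tbl <- feats %>%
      filter(purrr::map_int(.data$ms2_spectrum, nrow) > 0) %>%
      transmute(name = .data$feature_id, precursor_mz = .data$mz,
                mode = mo, class_label = "deconvolved",
                spectrum = .data$ms2_spectrum)
    if (nrow(spec_tbl) > 0) {
      write_msp(spec_tbl, file.path(out_dir, paste0("spectra_", tag, ".msp")))
    }
    ft <- targeted_peak_areas(
      bundle, feats, mode = mo, column_mode = cl,
      tol_ppm = config$tol_ppm, rt_window = config$rt_window,
      min_height = config$targeted_min_height)
    readr::write_csv(ft, file.path(out_dir, paste0("feature_table_", tag, ".csv")))
    d1 <- select_differential_features(ft, g_n1, g_n2t, "N1", "N2&T",
                                       fc_min = config$fc_min,
                                       p_max = config$p_max) %>%
      mutate(contrast = "N1_vs_N2T")
    d2 <- select_differential_features(ft, g_n2t, g_n3, "N2&T", "N3",
                                       fc_min = config$fc_min,
                                       p_max = config$p_max) %>%
      mutate(contrast = "N2T_vs_N3")
    diff <- bind_rows(d1, d2)
    readr::write_csv(diff, file.path(out_dir, paste0("differential_", tag, ".csv")))
    sel_ids <- unique(diff$feature_id[diff$selected])
    qc_g5 <- bundle$runs[[sprintf("QC_%s_%s_G5", mo, cl)]]
    if (length(sel_ids) > 0) {
      aic <- build_aic(qc_g5, filter(feats, .data$feature_id %in% sel_ids),
                       tol_ppm = config$tol_ppm)
      readr::write_csv(aic$trace, file.path(out_dir, paste0("aic_", tag, ".csv")))
      readr::write_csv(aic$scatter,
                       file.path(out_dir, paste0("aif_map_", tag, ".csv")))
    }
    all_feats[[tag]] <- feats
    all_ft[[tag]] <- ft
    all_diff[[tag]] <- diff
  }
  features <- bind_rows(all_feats)
  feature_table <- bind_rows(all_ft)
  differential <- bind_rows(all_diff)

  ## --- annotation --------------------------------------------------------
  lib <- export_library_and_standards(
    compounds, bundle$truth$rt,
    coverage_fraction = config$coverage_fraction,
    isomer_decoys = config$isomer_decoys, seed = seed,
    msp_path = file.path(out_dir, "library.msp"),
    standards_path = file.path(out_dir, "standards.csv"))
  sel_feats <- features %>%
    filter(.data$feature_id %in%
             unique(differential$feature_id[differential$selected]))
  ann2 <- annotate_level2(sel_feats, lib$library,
                          me_max_ppm = config$me_max_ppm,
                          dp_min = config$dp_min,
                          frag_tol = config$frag_tol)
  ann <- confirm_level1(ann2, features, lib$standards,
                        rt_max = config$rt_max, isomer_rt = config$isomer_rt)
  readr::write_csv(ann, file.path(out_dir, "annotations.csv"))

  ## --- quantification and formulas ---------------------------------------
  validated <- ann %>%
    filter(.data$level == 1L, !.data$is_decoy) %>%
    distinct(.data$compound_id, .data$name)
  report_formulas <- NULL
  quant_tbl <- NULL
  if (nrow(validated) > 0) {
    spike <- simulate_standard_addition(
      conc %>% filter(.data$compound_id %in% validated$compound_id),
      response_factor = acq$response_factor,
      noise_cv = config$quant_noise_cv, seed = seed)
    quant <- standard_addition_concentration(spike)
    quant_tbl <- group_concentration_table(quant)
    readr::write_csv(quant_tbl, file.path(out_dir, "concentrations.csv"))
    adv <- quant %>%
      group_by(.data$compound_id) %>%
      summarise(conc_ppm = max(tapply(.data$conc_ppm, .data$group, mean)),
                .groups = "drop") %>%
      inner_join(validated, by = "compound_id") %>%
      mutate(level = 1L)
    majors <- adv %>% slice_max(.data$conc_ppm, n = min(3, nrow(adv))) %>%
      pull(.data$name)
    report_formulas <- list(
      formula1 = compose_formula(adv, "all_validated", name = "formula1"),
      formula2 = compose_formula(adv, "majors", majors, name = "formula2"),
      formula3 = compose_formula(adv, "minors", majors, name = "formula3"))
    recipes <- purrr::imap(report_formulas, function(f, nm) {
      mutate(f$components, formula = nm)
    }) %>% bind_rows()
    readr::write_csv(recipes, file.path(out_dir, "formulas.csv"))
  }

  ## --- ground-truth scorecard ---------------------------------------------
  scored <- purrr::imap(all_feats, function(f, tag) {
    mo <- strsplit(tag, "_")[[1]][1]; cl <- strsplit(tag, "_")[[1]][2]
    match_features_to_truth(f, bundle, mode = mo, column_mode = cl,
                            tol_ppm = config$tol_ppm)
  })
  frag_scores <- purrr::map(scored, score_fragment_assignment,
                            bundle = bundle,
                            ms2_min_height = config$ms2_min_height)
  tp <- sum(purrr::map_dbl(frag_scores, "tp"))
  fp <- sum(purrr::map_dbl(frag_scores, "fp"))
  fn <- sum(purrr::map_dbl(frag_scores, "fn"))
  truth_groups <- design$group[match(grouping$assignments$sample_id,
                                     design$sample_id)]
  natural <- design$group != "T"
  ari <- adjusted_rand_index(
    grouping$assignments$group[natural[match(grouping$assignments$sample_id,
                                             design$sample_id)]],
    design$group[natural])

  ## planted-enrichment recovery in the N1 contrast
  matched_map <- bind_rows(purrr::map(scored, ~ select(.x, "feature_id",
                                                       "compound_id")))
  diff1 <- differential %>% filter(.data$contrast == "N1_vs_N2T") %>%
    left_join(matched_map, by = "feature_id") %>%
    left_join(compounds %>%
                transmute(.data$compound_id, planted_in = .data$enriched_in),
              by = "compound_id") %>%
    filter(!is.na(.data$compound_id))
  sens <- diff1 %>% filter(.data$planted_in == "N1")
  fpr <- diff1 %>% filter(.data$planted_in != "N1")
  scorecard <- list(
    n_features = nrow(features),
    n_matched = sum(!is.na(matched_map$compound_id)),
    fragment_precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    fragment_recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    differential_sensitivity =
      if (nrow(sens) > 0) mean(sens$selected) else NA_real_,
    differential_false_rate =
      if (nrow(fpr) > 0) mean(fpr$selected) else NA_real_,
    grouping_ari = ari,
    level2_annotations = sum(ann$level >= 1),
    level1_confirmed = sum(ann$level == 1 & !ann$is_decoy),
    decoy_level1 = sum(ann$level == 1 & ann$is_decoy)
  )

  counts <- list(
    features_per_dataset = purrr::map_int(all_feats, nrow),
    differential_per_contrast = differential %>%
      filter(.data$selected) %>% count(.data$contrast) %>% tibble::deframe(),
    n_annotated = length(unique(ann$feature_id)),
    n_level1 = length(unique(ann$feature_id[ann$level == 1 & !ann$is_decoy])),
    n_validated_compounds = nrow(validated)
  )
  report <- structure(
    list(config = config, counts = counts, scorecard = scorecard,
         grouping = grouping, differential = differential,
         annotations = ann, features = features,
         feature_table = feature_table, quant_table = quant_tbl,
         formulas = report_formulas, out_dir = out_dir),
    class = "crbdia_report")
  json <- list(counts = counts, scorecard = scorecard)
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}

#' @export
print.crbdia_report <- function(x, ...) {
  cat("<crbdia_report>\n")
  cat("features per dataset:\n")
  print(x$counts$features_per_dataset)
  cat("differential (selected) per contrast:\n")
  print(x$counts$differential_per_contrast)
  cat(sprintf("annotated: %d, level 1: %d, validated compounds: %d\n",
              x$counts$n_annotated, x$counts$n_level1,
              x$counts$n_validated_compounds))
  cat(sprintf("fragment precision/recall: %.3f / %.3f, grouping ARI: %.2f\n",
              x$scorecard$fragment_precision, x$scorecard$fragment_recall,
              x$scorecard$grouping_ari))
  invisible(x)
}

#' Pooled summary counts of contrast-level results
#'
#' Adds up, across contrasts, the differential-feature, annotation and
#' validation counts of a study summary table and derives the validation
#' rate, the consistency arithmetic used to sanity-check reported totals.
#'
#' @param contrast_counts Tibble with one row per contrast and columns
#'   `differential_features`, `level2_annotations`, `validated_compounds`.
#' @return One-row tibble with `total_differential`, `total_annotated`,
#'   `total_validated`, `validation_rate_pct`.
#' @export
#' @examples
#' pool_contrast_counts(example_contrast_counts())
pool_contrast_counts <- function(contrast_counts) {
  tibble(
    total_differential = sum(contrast_counts$differential_features),
    total_annotated = sum(contrast_counts$level2_annotations),
    total_validated = sum(contrast_counts$validated_compounds),
    validation_rate_pct = 100 * sum(contrast_counts$validated_compounds) /
      sum(contrast_counts$level2_annotations)
  )
}

#' Contrast-level counts of the emulated study
#'
#' The per-contrast result counts the package's desk-scale replica is
#' patterned on, shipped as a plain CSV in `inst/extdata`.
#'
#' @return Tibble with one row per sensory contrast.
#' @export
example_contrast_counts <- function() {
  readr::read_csv(system.file("extdata", "study_contrast_counts.csv",
                              package = "crbdia"),
                  show_col_types = FALSE)
}
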