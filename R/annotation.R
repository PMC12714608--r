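#' Spectral dot product (cosine) between two fragment spectra
#'
#' Peaks of the two spectra are paired greedily by ascending m/z gap within
#' the fragment tolerance (each peak used at most once); the score is the
#' cosine of the two paired intensity vectors, with unpaired peaks
#' contributing zeros to the other side. The score is symmetric, lies in
#' \[0, 1\], and is invariant to uniform intensity scaling of either
#' spectrum. Optional intensity weightings: `"sqrt"` (square-root
#' intensities) and `"mz"` (square-root intensities weighted by m/z).
#'
#' @param spec_a,spec_b Tibbles/data frames with `mz` and `intensity`.
#' @param frag_tol Pairing tolerance in Da (default 0.025, the conventional
#'   MS2 centroid tolerance).
#' @param weighting Intensity transform applied before the cosine.
#' @return Numeric scalar in \[0, 1\].
#' @export
#' @examples
#' a <- data.frame(mz = c(100, 150), intensity = c(3, 4))
#' b <- data.frame(mz = c(100, 150), intensity = c(4, 3))
#' spectral_dot_product(a, b)  # 24/25
spectral_dot_product <- function(spec_a, spec_b, frag_tol = 0.025,
                                 weighting = c("none", "sqrt", "mz")) {
  weighting <- match.arg(weighting)
  stopifnot(frag_tol > 0, nrow(spec_a) > 0, nrow(spec_b) > 0)
  wfun <- switch(weighting,
                 none = function(mz, i) i,
                 sqrt = function(mz, i) sqrt(i),
                 mz = function(mz, i) sqrt(i) * mz)
  ia <- wfun(spec_a$mz, spec_a$intensity)
  ib <- wfun(spec_b$mz, spec_b$intensity)
  cand <- crossing(a = seq_len(nrow(spec_a)), b = seq_len(nrow(spec_b))) %>%
    mutate(gap = abs(spec_a$mz[.data$a] - spec_b$mz[.data$b])) %>%
    filter(.data$gap <= frag_tol) %>%
    arrange(.data$gap, .data$a, .data$b)
  used_a <- logical(nrow(spec_a)); used_b <- logical(nrow(spec_b))
  va <- numeric(0); vb <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    ai <- cand$a[i]; bi <- cand$b[i]
    if (!used_a[ai] && !used_b[bi]) {
      used_a[ai] <- TRUE; used_b[bi] <- TRUE
      va <- c(va, ia[ai]); vb <- c(vb, ib[bi])
    }
  }
  va <- c(va, ia[!used_a], rep(0, sum(!used_b)))
  vb <- c(vb, rep(0, sum(!used_a)), ib[!used_b])
  denom <- sqrt(sum(va^2)) * sqrt(sum(vb^2))
  if (denom == 0) return(0)
  min(1, sum(va * vb) / denom)
}

#' Putative (level-2) annotation by library matching
#'
#' Candidates for each feature are library records of the same ionization
#' mode whose precursor mass error is below `me_max_ppm`; candidates are
#' scored by the spectral dot product against the feature's deconvolved MS2
#' spectrum and those exceeding `dp_min` are returned ranked by dot product
#' (ties broken by smaller mass error). Features without a deconvolved
#' spectrum yield no candidates.
#'
#' @param features Feature tibble with `feature_id`, `mz`, `mode`,
#'   `ms2_spectrum` list-column.
#' @param library Library tibble (see [export_library_and_standards()]).
#' @param me_max_ppm Maximum absolute precursor mass error, ppm (strict
#'   `<`).
#' @param dp_min Minimum dot product (strict `>`).
#' @param frag_tol Fragment pairing tolerance, Da.
#' @param best_only Keep only the top-ranked annotation per feature.
#' @return Tibble of annotations: `feature_id`, `name`, `compound_id`,
#'   `class_label`, `is_decoy`, `dot_product`, `mass_error_ppm`, `level`
#'   (2), `rank`.
#' @export
annotate_level2 <- function(features, library, me_max_ppm = 10,
                            dp_min = 0.4, frag_tol = 0.025,
                            best_only = TRUE) {
  no_ms2 <- purrr::map_int(features$ms2_spectrum, nrow) == 0
  if (any(no_ms2)) {
    inform(sprintf("%d feature(s) without deconvolved MS2 skipped",
                   sum(no_ms2)))
  }
  feats <- features[!no_ms2, ]
  out <- purrr::pmap(
    list(feats$feature_id, feats$mz, feats$mode, feats$ms2_spectrum),
    function(fid, fmz, fmode, sp) {
      me <- (fmz - library$precursor_mz) / library$precursor_mz * 1e6
      cand <- library[library$mode == fmode & abs(me) < me_max_ppm, ]
      if (nrow(cand) == 0) return(NULL)
      cand$mass_error_ppm <- me[library$mode == fmode & abs(me) < me_max_ppm]
      cand$dot_product <- purrr::map_dbl(cand$spectrum, spectral_dot_product,
                                         spec_a = sp, frag_tol = frag_tol)
      cand <- cand[cand$dot_product > dp_min, ]
      if (nrow(cand) == 0) return(NULL)
      cand %>%
        arrange(dplyr::desc(.data$dot_product), abs(.data$mass_error_ppm)) %>%
        transmute(feature_id = fid, .data$name, .data$compound_id,
                  .data$class_label, .data$is_decoy, .data$dot_product,
                  .data$mass_error_ppm, level = 2L,
                  rank = dplyr::row_number())
    })
  res <- bind_rows(compact(out))
  if (nrow(res) > 0 && best_only) res <- filter(res, .data$rank == 1L)
  res
}

#' Level-1 confirmation against chemical standards
#'
#' An annotation is promoted to level 1 iff the feature's reference-gradient
#' retention time agrees with the standard's within `rt_max` minutes.
#' Annotations whose retention discrepancy exceeds `isomer_rt` are flagged
#' as isomers (spectrally similar, chromatographically distinct compounds);
#' annotations without a standard retention time stay level 2 and are
#' flagged unverifiable.
#'
#' @param annotations Tibble from [annotate_level2()].
#' @param features Feature tibble with `feature_id`, `rt_reference`,
#'   `column_mode`.
#' @param standards Standards tibble (`name`, `column_mode`, `rt_g5`).
#' @param rt_max Level-1 retention window, minutes (default 0.1).
#' @param isomer_rt Retention discrepancy beyond which the match is called
#'   an isomer, minutes (default 0.5).
#' @return `annotations` with `rt_delta`, updated `level`, `isomer_flag`,
#'   `unverifiable`.
#' @export
confirm_level1 <- function(annotations, features, standards,
                           rt_max = 0.1, isomer_rt = 0.5) {
  ann <- annotations %>%
    left_join(select(features, "feature_id", "rt_reference", "column_mode"),
              by = "feature_id") %>%
    left_join(select(standards, "name", "column_mode", "rt_g5"),
              by = c("name", "column_mode")) %>%
    mutate(
      rt_delta = .data$rt_reference - .data$rt_g5,
      unverifiable = is.na(.data$rt_g5),
      level = ifelse(!.data$unverifiable & abs(.data$rt_delta) <= rt_max,
                     1L, 2L),
      isomer_flag = !.data$unverifiable & abs(.data$rt_delta) > isomer_rt
    ) %>%
    select(-"rt_g5")
  ann
}

#' Chemical-class summary of annotated features
#'
#' Per class: number of annotations, proportion of the total, and the
#' accumulated mean intensity (sum over member features of their mean area
#' across samples).
#'
#' @param annotations Annotation tibble with `class_label`.
#' @param feature_table Long feature table (`feature_id`, `sample_id`,
#'   `area`); optional.
#' @return Tibble `class_label`, `n`, `proportion`, `accumulated_intensity`.
#' @export
summarize_classes <- function(annotations, feature_table = NULL) {
  out <- annotations %>%
    count(.data$class_label) %>%
    mutate(proportion = .data$n / sum(.data$n))
  if (!is.null(feature_table)) {
    mean_int <- feature_table %>%
      group_by(.data$feature_id) %>%
      summarise(mean_area = mean(.data$area, na.rm = TRUE), .groups = "drop")
    acc <- annotations %>%
      left_join(mean_int, by = "feature_id") %>%
      group_by(.data$class_label) %>%
      summarise(accumulated_intensity = sum(.data$mean_area, na.rm = TRUE),
                .groups = "drop")
    out <- left_join(out, acc, by = "class_label")
  }
  out
}
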