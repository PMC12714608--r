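default_classes <- c(
  "acid", "amino acid", "phenol", "flavanone", "nitrogenous compound",
  "ketone", "lipid", "aniline", "amide", "alcohol", "saccharide",
  "alkene", "ester", "aldehyde"
)

#' Simulate a ground-truth compound panel
#'
#' Draws a panel of simulated analytes with neutral mass, ionization mode,
#' linear-solvent-strength retention parameters for both column modes, a
#' fragment template, a chemical class, and a group-enrichment assignment
#' that later drives differential abundance and sensory effects.
#'
#' A configurable fraction of compounds is planted as co-eluting pairs under
#' the reference gradient (G5): pair members share ionization mode, fall in
#' the same precursor m/z neighborhood, and have their retention parameters
#' solved so their G5 retention times agree within `coelute_rt_tol` while
#' their retention *behavior* across the gradient series differs. These pairs
#' are the hard case peak-shape deconvolution cannot separate and
#' retention-behavior deconvolution must.
#'
#' @param n Number of compounds.
#' @param seed Integer seed.
#' @param coelute_fraction Fraction of compounds placed into planted
#'   G5-co-eluting pairs (RPLC).
#' @param isomer_pairs Number of isomer pairs (identical neutral mass,
#'   G5 retention times separated by > 0.5 min).
#' @param n1_enriched_fraction,n2t_enriched_fraction Fractions of compounds
#'   enriched in the N1 group (vs N2&T) and in the N2&T group (vs N3).
#' @param enrichment_fold Concentration fold applied in the advantaged group.
#' @param p_standard Probability a compound has a purchasable chemical
#'   standard.
#' @param classes Chemical class labels to sample from.
#' @param reference_gradient Gradient used to plant co-elutions/isomers
#'   (default G5, RPLC).
#' @param coelute_rt_tol Maximum G5 retention-time gap within a planted
#'   co-eluting pair, minutes.
#'
#' @return A tibble with one row per compound: `compound_id`, `name`,
#'   `neutral_mass`, `mode`, `class_label`, `has_standard`, `enriched_in`
#'   (`"none"`, `"N1"` or `"N2T"`), `coelute_pair`, `isomer_pair`, retention
#'   parameters (`log_k0_rplc`, `s_rplc`, `log_k0_hilic`, `s_hilic`) and a
#'   `fragments` list-column of tibbles (`mz`, `rel_int`, max intensity 1).
#' @export
#' @examples
#' cmp <- simulate_compounds(20, seed = 1)
#' cmp[1:3, c("compound_id", "neutral_mass", "mode", "enriched_in")]
simulate_compounds <- function(n = 200, seed = 1,
                               coelute_fraction = 0.05,
                               isomer_pairs = 0,
                               n1_enriched_fraction = 0.25,
                               n2t_enriched_fraction = 0.10,
                               enrichment_fold = 6,
                               p_standard = 0.5,
                               classes = default_classes,
                               reference_gradient = NULL,
                               coelute_rt_tol = 0.02) {
  stopifnot(n >= 2)
  set.seed(seed)
  g5 <- reference_gradient %||% default_gradients("RPLC")$G5

  cmp <- tibble(
    compound_id = sprintf("C%03d", seq_len(n)),
    name = sprintf("compound_%03d", seq_len(n)),
    neutral_mass = runif(n, 100, 900),
    mode = sample(c("positive", "negative"), n, replace = TRUE),
    class_label = sample(classes, n, replace = TRUE),
    has_standard = runif(n) < p_standard,
    log_k0_rplc = runif(n, 1.0, 2.6),
    s_rplc = runif(n, 2.2, 4.5),
    log_k0_hilic = runif(n, 1.0, 2.6),
    s_hilic = runif(n, 2.2, 4.5),
    coelute_pair = NA_character_,
    isomer_pair = NA_character_
  )

  # group-enrichment plan: disjoint N1- and N2&T-enriched sets
  n_n1 <- round(n1_enriched_fraction * n)
  n_n2t <- round(n2t_enriched_fraction * n)
  idx <- sample(n, n_n1 + n_n2t)
  cmp$enriched_in <- "none"
  cmp$enriched_in[idx[seq_len(n_n1)]] <- "N1"
  cmp$enriched_in[idx[n_n1 + seq_len(n_n2t)]] <- "N2T"
  cmp$enrichment_fold <- ifelse(cmp$enriched_in == "none", 1, enrichment_fold)

  # planted G5 co-elutions: pair (a, b), b's log_k0 solved so G5 RTs agree
  n_pairs <- floor(coelute_fraction * n / 2)
  if (n_pairs > 0) {
    free <- seq_len(n)
    for (p in seq_len(n_pairs)) {
      a <- free[1]; b <- free[2]; free <- free[-(1:2)]
      cmp$mode[b] <- cmp$mode[a]
      cmp$neutral_mass[b] <- cmp$neutral_mass[a] + runif(1, 1.5, 3)
      target <- compute_retention_time(
        tibble(log_k0 = cmp$log_k0_rplc[a], s = cmp$s_rplc[a]), g5)$rt
      cmp$s_rplc[b] <- cmp$s_rplc[a] + sample(c(-1, 1), 1) * runif(1, 0.8, 1.4)
      cmp$log_k0_rplc[b] <- solve_log_k0(target, cmp$s_rplc[b], g5)
      tag <- sprintf("coel%02d", p)
      cmp$coelute_pair[c(a, b)] <- tag
    }
  }

  # planted isomers: same mass, clearly separated G5 RTs
  if (isomer_pairs > 0) {
    cand <- which(is.na(cmp$coelute_pair))
    stopifnot(length(cand) >= 2 * isomer_pairs)
    for (p in seq_len(isomer_pairs)) {
      a <- cand[2 * p - 1]; b <- cand[2 * p]
      cmp$mode[b] <- cmp$mode[a]
      cmp$neutral_mass[b] <- cmp$neutral_mass[a]
      rt_a <- compute_retention_time(
        tibble(log_k0 = cmp$log_k0_rplc[a], s = cmp$s_rplc[a]), g5)$rt
      cmp$s_rplc[b] <- cmp$s_rplc[a] * 0.8
      cmp$log_k0_rplc[b] <- solve_log_k0(rt_a + runif(1, 0.8, 1.5),
                                         cmp$s_rplc[b], g5)
      cmp$isomer_pair[c(a, b)] <- sprintf("iso%02d", p)
    }
  }

  cmp$fragments <- purrr::map(seq_len(n), function(i) {
    prec <- cmp$neutral_mass[i] +
      if (cmp$mode[i] == "positive") proton_mass else -proton_mass
    k <- sample(4:8, 1)
    mz <- sort(runif(k, 55, max(60, prec - 10)))
    ri <- runif(k, 0.15, 0.95)
    ri[sample(k, 1)] <- 1
    tibble(mz = mz, rel_int = ri)
  })
  cmp
}

# solve log_k0 so that a compound with slope `s` elutes at `target_rt`
# under `gradient`; retention time is monotone increasing in log_k0
solve_log_k0 <- function(target_rt, s, gradient, interval = c(-1, 6)) {
  f <- function(lk) {
    r <- compute_retention_time(tibble(log_k0 = lk, s = s), gradient,
                                dt = 2 / 6000)
    (if (r$eluted) r$rt else gradient$run_end + lk) - target_rt
  }
  stats::uniroot(f, interval = interval, tol = 1e-5)$root
}

#' Precursor m/z of a compound panel
#'
#' Singly charged adduct m/z under each compound's ionization mode
#' (protonation/deprotonation).
#'
#' @param compounds Tibble from [simulate_compounds()].
#' @return The tibble with an added `precursor_mz` column.
#' @export
add_precursor_mz <- function(compounds) {
  mutate(compounds, precursor_mz = .data$neutral_mass +
           ifelse(.data$mode == "positive", proton_mass, -proton_mass))
}

#' Study design: samples and sensory groups
#'
#' Builds the sample sheet of the emulated study: tobacco extracts (group T)
#' plus natural extracts pre-assigned to the three sensory subgroups N1, N2
#' and N3. Default sizes are 24 T, 5 N1, 24 N2 and 4 N3 (57 samples).
#'
#' @param n_t,n_n1,n_n2,n_n3 Group sizes.
#' @return Tibble with `sample_id` and `group`.
#' @export
#' @examples
#' table(study_design()$group)
study_design <- function(n_t = 24, n_n1 = 5, n_n2 = 24, n_n3 = 4) {
  stopifnot(n_t >= 2, n_n1 >= 2, n_n2 >= 2, n_n3 >= 2)
  groups <- c(rep("T", n_t), rep("N1", n_n1), rep("N2", n_n2), rep("N3", n_n3))
  tibble(
    sample_id = sprintf("S%02d", seq_along(groups)),
    group = groups
  )
}

#' Simulate per-sample concentrations
#'
#' Concentrations (ppm mass fraction) are log-normal around a compound base
#' level; compounds planted as enriched get their `enrichment_fold` applied in
#' the advantaged group(s): N1-enriched compounds are raised in N1 relative
#' to N2, T and N3; N2&T-enriched compounds are raised in both N2 and T
#' relative to N3 (and N1).
#'
#' @param compounds Tibble from [simulate_compounds()].
#' @param design Tibble from [study_design()].
#' @param seed Integer seed.
#' @param base_meanlog,base_sdlog Log-normal parameters of compound base
#'   concentration (ppm).
#' @param within_group_cv Within-group coefficient of variation of the true
#'   concentration.
#' @return Tibble `compound_id` x `sample_id` with `group` and `conc_ppm`.
#' @export
simulate_concentrations <- function(compounds, design, seed = 1,
                                    base_meanlog = log(5), base_sdlog = 0.5,
                                    within_group_cv = 0.2) {
  set.seed(seed + 1L)
  base <- rlnorm(nrow(compounds), base_meanlog, base_sdlog)
  grid <- crossing(
    compounds %>% select("compound_id", "enriched_in", "enrichment_fold"),
    design
  ) %>%
    left_join(tibble(compound_id = compounds$compound_id, base = base),
              by = "compound_id") %>%
    mutate(
      boost = case_when(
        .data$enriched_in == "N1" & .data$group == "N1" ~ .data$enrichment_fold,
        .data$enriched_in == "N2T" & .data$group %in% c("N2", "T") ~
          .data$enrichment_fold,
        TRUE ~ 1
      ),
      conc_ppm = .data$base * .data$boost *
        rlnorm(dplyr::n(), -within_group_cv^2 / 2, within_group_cv)
    ) %>%
    select("compound_id", "sample_id", "group", "conc_ppm")
  grid
}
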