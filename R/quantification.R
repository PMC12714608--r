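#' Single-point standard-addition concentration
#'
#' For each row, the native analyte concentration is
#' `C_s = C_std * A_sample / (A_spiked - A_sample)`: spiking a known amount
#' into the same matrix cancels matrix effects, and for a linear detector
#' response the relation is exact. The result is invariant to any uniform
#' rescaling of both areas. A sample with zero native area yields 0
#' (analyte absent); a spiked area not exceeding the native area (with
#' native signal present) signals an invalid spike and raises an error.
#'
#' @param data Tibble with columns `c_std` (spiked standard concentration,
#'   ppm), `area_sample` and `area_spiked` (peak areas, intensity-seconds).
#' @return `data` with an added `conc_ppm` column.
#' @export
#' @examples
#' standard_addition_concentration(
#'   tibble::tibble(c_std = 10, area_sample = 1000, area_spiked = 1500))
standard_addition_concentration <- function(data) {
  stopifnot(all(c("c_std", "area_sample", "area_spiked") %in% names(data)))
  if (any(data$c_std <= 0)) abort("c_std must be positive")
  if (any(data$area_sample < 0 | data$area_spiked < 0)) {
    abort("areas must be non-negative")
  }
  bad <- data$area_sample > 0 & data$area_spiked <= data$area_sample
  if (any(bad)) {
    abort(sprintf(
      "invalid spike in %d row(s): spiked area does not exceed sample area",
      sum(bad)))
  }
  mutate(data, conc_ppm = ifelse(
    .data$area_sample == 0, 0,
    .data$c_std * .data$area_sample /
      (.data$area_spiked - .data$area_sample)))
}

#' Simulate spiked/unspiked area pairs for standard addition
#'
#' Emulates the wet-lab spike experiment at the area level: the unspiked
#' area is proportional to the true concentration, the spiked area to
#' concentration plus spike, both subject to multiplicative noise. The
#' spike level is the compound's cross-sample mean concentration rounded to
#' two significant digits ("the same magnitude as the analyte").
#'
#' @param concentrations Tibble from [simulate_concentrations()] restricted
#'   to the compounds to quantify.
#' @param response_factor Area counts per ppm.
#' @param noise_cv Multiplicative area noise (fraction; 0 = exact).
#' @param seed Integer seed.
#' @return Tibble `compound_id`, `sample_id`, `group`, `true_ppm`, `c_std`,
#'   `area_sample`, `area_spiked`.
#' @export
simulate_standard_addition <- function(concentrations, response_factor = 2000,
                                       noise_cv = 0, seed = 1) {
  set.seed(seed + 4L)
  spikes <- concentrations %>%
    group_by(.data$compound_id) %>%
    summarise(c_std = signif(max(mean(.data$conc_ppm), 1e-3), 2),
              .groups = "drop")
  concentrations %>%
    left_join(spikes, by = "compound_id") %>%
    mutate(
      true_ppm = .data$conc_ppm,
      area_sample = .data$conc_ppm * response_factor *
        exp(rnorm(dplyr::n(), -noise_cv^2 / 2, noise_cv)),
      area_spiked = (.data$conc_ppm + .data$c_std) * response_factor *
        exp(rnorm(dplyr::n(), -noise_cv^2 / 2, noise_cv))
    ) %>%
    select("compound_id", "sample_id", "group", "true_ppm", "c_std",
           "area_sample", "area_spiked")
}

#' Group-average concentration table
#'
#' Arithmetic mean of the per-sample standard-addition concentrations within
#' each group, zeros (non-detects) included by default.
#'
#' @param quantified Tibble with `compound_id`, `group`, `conc_ppm`.
#' @param include_zeros Keep zero concentrations in the mean.
#' @return Wide tibble `compound_id` x one column per group.
#' @export
group_concentration_table <- function(quantified, include_zeros = TRUE) {
  q <- if (include_zeros) quantified else filter(quantified, .data$conc_ppm > 0)
  q %>%
    group_by(.data$compound_id, .data$group) %>%
    summarise(conc_ppm = mean(.data$conc_ppm), .groups = "drop") %>%
    pivot_wider(names_from = "group", values_from = "conc_ppm")
}

#' Compose a validation formula from level-1 compounds
#'
#' A formula recipe is a named mixture of validated (level-1) compounds at
#' their quantified concentrations: either all of them, only the listed
#' major components, or the complementary minor components. Majors and
#' minors always partition the validated set.
#'
#' @param validated Tibble with `name`, `level`, `conc_ppm` (level-1
#'   entries only).
#' @param rule One of `"all_validated"`, `"majors"`, `"minors"`.
#' @param majors_list Character vector of major-component names (required
#'   for `"majors"`/`"minors"`).
#' @param name Recipe label.
#' @return List of class `formula_recipe`: `name`, `rule`, `components`
#'   (tibble `name`, `conc_ppm`).
#' @export
compose_formula <- function(validated,
                            rule = c("all_validated", "majors", "minors"),
                            majors_list = NULL, name = NULL) {
  rule <- match.arg(rule)
  stopifnot(nrow(validated) > 0)
  if (!all(validated$level == 1L)) {
    abort("formulas are composed from level-1 validated compounds only")
  }
  if (rule != "all_validated") {
    if (is.null(majors_list)) abort("majors_list required for this rule")
    missing <- setdiff(majors_list, validated$name)
    if (length(missing) > 0) {
      abort(sprintf("majors not among validated compounds: %s",
                    paste(missing, collapse = ", ")))
    }
  }
  comp <- switch(rule,
    all_validated = validated,
    majors = filter(validated, .data$name %in% majors_list),
    minors = filter(validated, !.data$name %in% majors_list)
  )
  structure(
    list(name = name %||% rule, rule = rule,
         components = select(comp, "name", "conc_ppm")),
    class = "formula_recipe"
  )
}

#' @export
print.formula_recipe <- function(x, ...) {
  cat(sprintf("<formula_recipe %s (%s): %d components>\n",
              x$name, x$rule, nrow(x$components)))
  invisible(x)
}
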