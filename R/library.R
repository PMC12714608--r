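#' Export a spectral library and standards table from the compound panel
#'
#' Emulates incomplete library coverage: a seeded random subset of the
#' compounds (`coverage_fraction`) gets an MSP library record built from its
#' fragment template, and `isomer_decoys` additional records are appended
#' that share a true compound's spectrum and precursor m/z but whose
#' "standard" elutes more than 0.5 min away -- the isomer trap that level-1
#' confirmation must catch. The standards table lists the reference-gradient
#' retention time of every compound with a purchasable standard (plus the
#' decoys).
#'
#' @param compounds Tibble from [simulate_compounds()].
#' @param truth_rt Retention truth tibble (`compound_id`, `column_mode`,
#'   `gradient_id`, `rt`) as produced in the simulation bundle.
#' @param coverage_fraction Fraction of compounds present in the library
#'   (0 < c <= 1).
#' @param isomer_decoys Number of decoy records.
#' @param seed Integer seed.
#' @param reference Reference gradient id.
#' @param msp_path,standards_path Optional output paths (MSP / CSV).
#' @return List with `library` (tibble: `name`, `compound_id`,
#'   `precursor_mz`, `mode`, `class_label`, `is_decoy`, `spectrum`
#'   list-column) and `standards` (tibble: `name`, `compound_id`,
#'   `column_mode`, `rt_g5`, `is_decoy`).
#' @export
export_library_and_standards <- function(compounds, truth_rt,
                                         coverage_fraction = 0.7,
                                         isomer_decoys = 0, seed = 1,
                                         reference = "G5",
                                         msp_path = NULL,
                                         standards_path = NULL) {
  if (coverage_fraction <= 0 || coverage_fraction > 1) {
    abort("coverage_fraction must be in (0, 1]")
  }
  if (isomer_decoys > nrow(compounds)) {
    abort("more decoys requested than compounds available")
  }
  set.seed(seed + 3L)
  cmp <- add_precursor_mz(compounds)
  n_lib <- round(coverage_fraction * nrow(cmp))
  in_lib <- sort(sample(nrow(cmp), n_lib))
  lib <- cmp[in_lib, ] %>%
    transmute(
      name = .data$name, compound_id = .data$compound_id,
      precursor_mz = .data$precursor_mz, mode = .data$mode,
      class_label = .data$class_label, is_decoy = FALSE,
      spectrum = purrr::map(.data$fragments,
                            ~ tibble(mz = .x$mz, intensity = .x$rel_int))
    )
  ref_rt <- truth_rt %>% filter(.data$gradient_id == reference)
  decoys <- NULL
  if (isomer_decoys > 0) {
    par_idx <- sample(in_lib, isomer_decoys)
    parents <- cmp[par_idx, ]
    offs <- sample(c(-1, 1), isomer_decoys, replace = TRUE) *
      runif(isomer_decoys, 0.55, 1.2)
    decoys <- parents %>%
      transmute(
        name = paste0(.data$name, "_isomer"),
        compound_id = paste0(.data$compound_id, "_decoy"),
        precursor_mz = .data$precursor_mz, mode = .data$mode,
        class_label = .data$class_label, is_decoy = TRUE,
        spectrum = purrr::map(.data$fragments,
                              ~ tibble(mz = .x$mz, intensity = .x$rel_int)),
        parent_id = parents$compound_id, rt_offset = offs
      )
  }
  library_tbl <- bind_rows(lib, decoys)

  standards <- cmp %>%
    filter(.data$has_standard) %>%
    select("name", "compound_id") %>%
    inner_join(ref_rt, by = "compound_id") %>%
    transmute(.data$name, .data$compound_id, .data$column_mode,
              rt_g5 = .data$rt, is_decoy = FALSE)
  if (!is.null(decoys)) {
    dec_std <- decoys %>%
      select("name", "compound_id", "parent_id", "rt_offset") %>%
      inner_join(ref_rt, by = c(parent_id = "compound_id")) %>%
      transmute(.data$name, .data$compound_id, .data$column_mode,
                rt_g5 = .data$rt + .data$rt_offset, is_decoy = TRUE)
    standards <- bind_rows(standards, dec_std)
  }
  if (!is.null(msp_path)) write_msp(library_tbl, msp_path)
  if (!is.null(standards_path)) readr::write_csv(standards, standards_path)
  list(library = library_tbl, standards = standards)
}

#' Write spectral records to an MSP file
#'
#' @param library_tbl Tibble with `name`, `precursor_mz`, `mode`,
#'   `class_label` and a `spectrum` list-column (`mz`, `intensity`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msp <- function(library_tbl, path) {
  blocks <- purrr::pmap_chr(
    list(library_tbl$name, library_tbl$precursor_mz, library_tbl$mode,
         library_tbl$class_label, library_tbl$spectrum),
    function(name, pmz, mode, cls, sp) {
      paste0(
        "NAME: ", name, "\n",
        "PRECURSORMZ: ", format(pmz, digits = 10), "\n",
        "IONMODE: ", mode, "\n",
        "COMMENT: class=", cls, "\n",
        "Num Peaks: ", nrow(sp), "\n",
        paste(sprintf("%.5f %.4f", sp$mz, sp$intensity), collapse = "\n"),
        "\n"
      )
    })
  writeLines(paste(blocks, collapse = "\n"), path)
  invisible(path)
}

#' Read an MSP spectral library
#'
#' Parses the subset of the MSP format written by [write_msp()] (NAME,
#' PRECURSORMZ, IONMODE, COMMENT, Num Peaks + peak lines).
#'
#' @param path MSP file path.
#' @return Tibble with `name`, `precursor_mz`, `mode`, `class_label`,
#'   `spectrum` list-column.
#' @export
read_msp <- function(path) {
  lines <- readLines(path)
  starts <- grep("^NAME:", lines)
  stopifnot(length(starts) > 0)
  ends <- c(starts[-1] - 1, length(lines))
  purrr::map2(starts, ends, function(s, e) {
    block <- lines[s:e]
    field <- function(key) {
      ln <- grep(paste0("^", key, ":"), block, value = TRUE)
      if (length(ln) == 0) return(NA_character_)
      trimws(sub(paste0("^", key, ":"), "", ln[1]))
    }
    np_line <- grep("^Num Peaks:", block)
    np <- as.integer(trimws(sub("^Num Peaks:", "", block[np_line])))
    pk <- if (np > 0) {
      m <- do.call(rbind, strsplit(trimws(block[(np_line + 1):(np_line + np)]),
                                   "\\s+"))
      tibble(mz = as.numeric(m[, 1]), intensity = as.numeric(m[, 2]))
    } else {
      tibble(mz = numeric(), intensity = numeric())
    }
    cls <- sub("^class=", "", field("COMMENT"))
    tibble(name = field("NAME"),
           precursor_mz = as.numeric(field("PRECURSORMZ")),
           mode = field("IONMODE"), class_label = cls,
           spectrum = list(pk))
  }) %>% bind_rows()
}
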