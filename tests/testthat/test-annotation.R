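test_that("spectral dot product reproduces hand-computed cases", {
  a <- tibble(mz = c(100, 150), intensity = c(3, 4))
  b <- tibble(mz = c(100, 150), intensity = c(4, 3))
  expect_equal(spectral_dot_product(a, b), 24 / 25)
  expect_equal(spectral_dot_product(a, a), 1)
  disjoint <- tibble(mz = c(300, 400), intensity = c(1, 1))
  expect_equal(spectral_dot_product(a, disjoint), 0)
})

test_that("dot product is symmetric, bounded and scale invariant", {
  set.seed(17)
  for (i in 1:10) {
    a <- random_spectrum(sample(3:10, 1))
    b <- random_spectrum(sample(3:10, 1))
    d1 <- spectral_dot_product(a, b)
    expect_equal(d1, spectral_dot_product(b, a), tolerance = 1e-12)
    expect_gte(d1, 0); expect_lte(d1, 1)
    a2 <- a %>% mutate(intensity = .data$intensity * 37)
    expect_equal(spectral_dot_product(a2, b), d1, tolerance = 1e-12)
  }
})

test_that("dot product equals the brute-force pairing oracle", {
  set.seed(18)
  for (i in 1:20) {
    a <- random_spectrum(sample(3:12, 1))
    b <- random_spectrum(sample(3:12, 1))
    # mix in near-coincident peaks so pairing is actually exercised
    b$mz[1] <- a$mz[1] + runif(1, -0.02, 0.02)
    if (nrow(b) > 1) b$mz[2] <- a$mz[min(2, nrow(a))] + runif(1, -0.02, 0.02)
    b <- b %>% arrange(.data$mz)
    expect_equal(spectral_dot_product(a, b), oracle_cosine(a, b),
                 tolerance = 1e-12)
  }
})

test_that("MSP records round-trip through write and read", {
  lib <- tibble(
    name = c("alpha", "beta"), compound_id = c("C1", "C2"),
    precursor_mz = c(301.1234, 455.2), mode = c("positive", "negative"),
    class_label = c("acid", "saccharide"), is_decoy = FALSE,
    spectrum = list(tibble(mz = c(100.1, 150.2), intensity = c(0.5, 1)),
                    tibble(mz = 99.5, intensity = 1)))
  f <- tempfile(fileext = ".msp")
  write_msp(lib, f)
  back <- read_msp(f)
  expect_equal(back$name, lib$name)
  expect_equal(back$precursor_mz, lib$precursor_mz, tolerance = 1e-6)
  expect_equal(back$mode, lib$mode)
  expect_equal(back$class_label, lib$class_label)
  expect_equal(back$spectrum[[1]]$mz, lib$spectrum[[1]]$mz, tolerance = 1e-4)
})

make_truth_rt <- function(cmp) {
  tidyr::crossing(compound_id = cmp$compound_id,
                  column_mode = "RPLC", gradient_id = "G5") %>%
    mutate(rt = 5 + 0.1 * seq_len(dplyr::n()))
}

test_that("full library coverage yields one record per compound", {
  cmp <- simulate_compounds(20, seed = 81)
  lib <- export_library_and_standards(cmp, make_truth_rt(cmp),
                                      coverage_fraction = 1,
                                      isomer_decoys = 0, seed = 81)
  expect_equal(sort(lib$library$compound_id), sort(cmp$compound_id))
  expect_false(any(lib$library$is_decoy))
})

test_that("partial coverage is exact and reproducible under a seed", {
  cmp <- simulate_compounds(100, seed = 82)
  l1 <- export_library_and_standards(cmp, make_truth_rt(cmp), 0.3, 0, seed = 5)
  l2 <- export_library_and_standards(cmp, make_truth_rt(cmp), 0.3, 0, seed = 5)
  expect_equal(nrow(l1$library), 30)
  expect_identical(l1$library$compound_id, l2$library$compound_id)
  expect_error(export_library_and_standards(cmp, make_truth_rt(cmp), 1.2),
               "coverage_fraction")
  expect_error(export_library_and_standards(cmp, make_truth_rt(cmp), 1, 200),
               "decoys")
})

test_that("isomer decoys share spectrum and m/z but sit > 0.5 min away", {
  cmp <- simulate_compounds(30, seed = 83)
  rt <- make_truth_rt(cmp)
  lib <- export_library_and_standards(cmp, rt, 1, isomer_decoys = 6, seed = 83)
  dec <- lib$standards %>% filter(.data$is_decoy)
  expect_equal(nrow(dec), 6)
  parent <- rt$rt[match(sub("_decoy", "", dec$compound_id), rt$compound_id)]
  expect_true(all(abs(dec$rt_g5 - parent) >= 0.5))
})

fake_feature <- function(cmp_row, rt_ref = 8) {
  tibble(feature_id = "F0001",
         mz = cmp_row$neutral_mass +
           ifelse(cmp_row$mode == "positive", 1.007276, -1.007276),
         mode = cmp_row$mode, column_mode = "RPLC",
         rt_reference = rt_ref,
         ms2_spectrum = list(tibble(mz = cmp_row$fragments[[1]]$mz,
                                    intensity = cmp_row$fragments[[1]]$rel_int)))
}

test_that("a library compound annotates itself at rank one with DP ~ 1", {
  cmp <- simulate_compounds(25, seed = 84)
  lib <- export_library_and_standards(cmp, make_truth_rt(cmp), 1, 0, seed = 84)
  ft <- fake_feature(cmp[3, ])
  ann <- annotate_level2(ft, lib$library)
  expect_equal(nrow(ann), 1)
  expect_equal(ann$compound_id, cmp$compound_id[3])
  expect_gte(ann$dot_product, 0.99)
  expect_lt(abs(ann$mass_error_ppm), 1)
})

test_that("mass-error and dot-product gates are enforced", {
  cmp <- simulate_compounds(5, seed = 85)
  lib <- export_library_and_standards(cmp, make_truth_rt(cmp), 1, 0, seed = 85)
  ft <- fake_feature(cmp[1, ])
  # 12 ppm precursor error: excluded
  ft12 <- ft %>% mutate(mz = .data$mz * (1 + 12e-6))
  lib1 <- lib$library %>% filter(.data$compound_id == cmp$compound_id[1])
  expect_equal(nrow(annotate_level2(ft12, lib1)), 0)
  # dissimilar spectrum below the DP floor: excluded
  ft_bad <- ft %>%
    mutate(ms2_spectrum = list(tibble(mz = c(61.3, 72.9), intensity = c(1, 1))))
  expect_equal(nrow(annotate_level2(ft_bad, lib1)), 0)
  # features without MS2 are skipped with a message
  ft_none <- ft %>% mutate(ms2_spectrum = list(tibble(mz = numeric(),
                                                      intensity = numeric())))
  expect_message(out <- annotate_level2(ft_none, lib1), "without")
  expect_equal(nrow(out), 0)
})

test_that("level-1 confirmation applies the retention window and isomer flag", {
  ann <- tibble(feature_id = "F0001", name = "alpha", compound_id = "C1",
                class_label = "acid", is_decoy = FALSE, dot_product = 0.95,
                mass_error_ppm = 1, level = 2L, rank = 1L)
  feat <- tibble(feature_id = "F0001", rt_reference = 8, column_mode = "RPLC")
  std <- function(rt) tibble(name = "alpha", column_mode = "RPLC", rt_g5 = rt)
  expect_equal(confirm_level1(ann, feat, std(8))$level, 1L)       # exact
  expect_equal(confirm_level1(ann, feat, std(8.05))$level, 1L)    # within 0.1
  r <- confirm_level1(ann, feat, std(8.6))                        # isomer
  expect_equal(r$level, 2L)
  expect_true(r$isomer_flag)
  r2 <- confirm_level1(ann, feat, std(8)[0, ])                    # no standard
  expect_equal(r2$level, 2L)
  expect_true(r2$unverifiable)
})

test_that("class summaries count and conserve", {
  ann <- tibble(feature_id = sprintf("F%02d", 1:6),
                class_label = c("acid", "acid", "phenol", "lipid", "lipid",
                                "lipid"))
  s <- summarize_classes(ann)
  expect_equal(sum(s$n), 6)
  expect_equal(sum(s$proportion), 1)
  one <- summarize_classes(ann %>% mutate(class_label = "acid"))
  expect_equal(nrow(one), 1)
  expect_equal(one$proportion, 1)
  many <- summarize_classes(tibble(feature_id = sprintf("F%02d", 1:14),
                                   class_label = crbdia:::default_classes))
  expect_equal(nrow(many), 14)
})
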