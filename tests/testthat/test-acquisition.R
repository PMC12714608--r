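test_that("the duty cycle is the MS1 dwell plus twelve MS2 dwells", {
  expect_equal(cycle_time(acquisition_config()), 0.150 + 12 * 0.050)
  sched <- crbdia:::scan_schedule(2, acquisition_config(),
                                  swath_windows(runif(50, 100, 1100)))
  by_cycle <- split(sched$rt, sched$cycle)
  starts <- vapply(by_cycle, min, numeric(1))
  expect_equal(unname(diff(starts)), rep(0.75 / 60, length(starts) - 1),
               tolerance = 1e-9)
  expect_equal(nrow(sched) / length(by_cycle), 13)
})

test_that("variable SWATH windows cover the MS1 range with bounded overlap", {
  w <- swath_windows(runif(500, 80, 1150), n = 12, range = c(70, 1200))
  expect_equal(nrow(w), 12)
  expect_equal(w$core_low[1], 70)
  expect_equal(w$core_high[12], 1200)
  expect_true(all(w$core_low[-1] == w$core_high[-12]))  # contiguous cores
  overlap <- w$high[-12] - w$low[-1]
  expect_true(all(overlap <= 1 + 1e-9))
})

test_that("a noise-free compound yields a Gaussian XIC at its predicted RT", {
  cmp0 <- simulate_compounds(3, seed = 21, coelute_fraction = 0)
  cmp0$mode <- "positive"
  des <- study_design(3, 2, 3, 2)
  conc <- simulate_concentrations(cmp0, des, seed = 21)
  b <- simulate_dia_acquisition(cmp0, des, conc, quiet_config(21),
                                modes = "positive", columns = "RPLC",
                                include_samples = FALSE)
  cmp <- add_precursor_mz(b$compounds)
  run <- b$runs[["QC_positive_RPLC_G5"]]
  truth <- b$truth$run_signals %>%
    filter(.data$run_id == run$run_id, .data$compound_id == cmp$compound_id[1])
  x <- extract_xic(run, cmp$precursor_mz[1], tol_ppm = 10)
  apex_rt <- x$rt[which.max(x$intensity)]
  expect_equal(apex_rt, truth$rt_apex, tolerance = 0.0125 * 1.5)
  expect_equal(max(x$intensity), truth$apex, tolerance = 1e-2)
  # the trace is a single contiguous signal region
  on_idx <- which(x$intensity > 0)
  expect_true(all(diff(on_idx) == 1))
})

test_that("pooled QC signal equals the mean of per-sample signals", {
  b <- small_bundle(n = 6, seed = 22, include_samples = TRUE)
  qc <- b$truth$run_signals %>% filter(grepl("^QC", .data$run_id))
  smp <- b$truth$run_signals %>% filter(!grepl("^QC", .data$run_id))
  joint <- smp %>%
    group_by(.data$compound_id) %>%
    summarise(mean_area = mean(.data$true_area), n = dplyr::n(),
              .groups = "drop") %>%
    inner_join(qc %>% filter(grepl("G5$", .data$run_id)) %>%
                 select("compound_id", "true_area"),
               by = "compound_id") %>%
    filter(.data$n == nrow(b$design))
  expect_gt(nrow(joint), 0)
  expect_equal(joint$true_area, joint$mean_area, tolerance = 0.01)
})

test_that("precursors outside the window set are recorded as unfragmented", {
  cmp <- simulate_compounds(4, seed = 5)
  cmp$neutral_mass[1] <- 1250  # beyond the 1200 Da upper bound
  cmp$mode[1] <- "positive"
  des <- study_design(2, 2, 2, 2)
  conc <- simulate_concentrations(cmp, des, seed = 5)
  b <- simulate_dia_acquisition(cmp, des, conc, quiet_config(5),
                                modes = "positive", columns = "RPLC",
                                include_samples = FALSE)
  tr <- b$truth$run_signals %>% filter(.data$compound_id == "C001")
  expect_true(nrow(tr) > 0)
  expect_true(all(!tr$fragmented))
})

test_that("equal seeds give bit-identical runs, different seeds differ", {
  b1 <- small_bundle(n = 5, seed = 31,
                     config = acquisition_config(seed = 31))
  b2 <- small_bundle(n = 5, seed = 31,
                     config = acquisition_config(seed = 31))
  b3 <- small_bundle(n = 5, seed = 31,
                     config = acquisition_config(seed = 32))
  r1 <- b1$runs[[1]]$centroids
  expect_identical(r1, b2$runs[[1]]$centroids)
  expect_false(identical(r1, b3$runs[[1]]$centroids))
})

test_that("runs round-trip through mzML with identical scans and peaks", {
  skip_if_not_installed("mzR")
  b <- small_bundle(n = 4, seed = 41,
                    config = acquisition_config(seed = 41))
  run <- b$runs[["QC_positive_RPLC_G1"]]
  f <- tempfile(fileext = ".mzML")
  write_run_mzml(run, f)
  back <- read_run_mzml(f)
  expect_equal(nrow(back$scans), nrow(run$scans))
  expect_equal(back$scans$ms_level, run$scans$ms_level)
  expect_equal(back$scans$rt, run$scans$rt, tolerance = 1e-9)
  expect_equal(back$centroids$mz, run$centroids$mz, tolerance = 1e-9)
  expect_equal(back$centroids$intensity, run$centroids$intensity,
               tolerance = 1e-6)
  unlink(f)
})
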