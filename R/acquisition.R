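#' DIA acquisition settings
#'
#' Instrument-side parameters of the simulated acquisition: MS1 survey scans
#' over 70--1200 Da with a 150 ms dwell, followed by 12 variable SWATH
#' MS/MS windows at 50 ms each, giving a 750 ms duty cycle.
#'
#' @param ms1_range,ms2_range Acquisition m/z ranges (Da).
#' @param n_windows Number of SWATH windows.
#' @param ms1_dwell,ms2_dwell Dwell times in seconds.
#' @param mass_jitter_ppm Per-centroid Gaussian m/z error (ppm, 1 sd).
#' @param rt_jitter Per-run Gaussian retention-time error (minutes, 1 sd).
#' @param intensity_cv Multiplicative per-point intensity noise (fraction).
#' @param noise_floor Centroid intensity threshold; also scales chemical
#'   noise peaks.
#' @param noise_peaks_per_scan Mean number of random noise centroids added
#'   per scan.
#' @param peak_sigma Gaussian chromatographic peak sigma, minutes.
#' @param response_factor Peak apex counts per ppm of analyte (unit response:
#'   area strictly proportional to concentration).
#' @param seed Integer seed for the acquisition-level randomness.
#'
#' @return A list of class `acquisition_config`.
#' @export
acquisition_config <- function(ms1_range = c(70, 1200),
                               ms2_range = c(50, 1200),
                               n_windows = 12,
                               ms1_dwell = 0.150, ms2_dwell = 0.050,
                               mass_jitter_ppm = 2,
                               rt_jitter = 0.005,
                               intensity_cv = 0.02,
                               noise_floor = 50,
                               noise_peaks_per_scan = 2,
                               peak_sigma = 0.05,
                               response_factor = 2000,
                               seed = 1L) {
  stopifnot(ms1_dwell > 0, ms2_dwell > 0, n_windows >= 1,
            rt_jitter >= 0, mass_jitter_ppm >= 0)
  structure(
    list(ms1_range = ms1_range, ms2_range = ms2_range, n_windows = n_windows,
         ms1_dwell = ms1_dwell, ms2_dwell = ms2_dwell,
         mass_jitter_ppm = mass_jitter_ppm, rt_jitter = rt_jitter,
         intensity_cv = intensity_cv, noise_floor = noise_floor,
         noise_peaks_per_scan = noise_peaks_per_scan,
         peak_sigma = peak_sigma, response_factor = response_factor,
         seed = as.integer(seed)),
    class = "acquisition_config"
  )
}

#' Duty-cycle time of an acquisition configuration
#'
#' @param config An [acquisition_config()].
#' @return Cycle time in seconds (MS1 dwell + windows x MS2 dwell).
#' @export
#' @examples
#' cycle_time(acquisition_config())  # 0.75 s
cycle_time <- function(config) {
  config$ms1_dwell + config$n_windows * config$ms2_dwell
}

#' Variable SWATH windows from an ion-density quantile split
#'
#' Window boundaries are quantiles of the expected precursor m/z
#' distribution so that each window carries a comparable ion load
#' ("variable" windows); a fixed margin is added on both sides of each
#' boundary so adjacent windows overlap by up to 1 Da. Degenerate quantiles
#' fall back to even spacing.
#'
#' @param mz Precursor m/z values used to estimate ion density.
#' @param n Number of windows.
#' @param range Total covered m/z range.
#' @param margin Half-overlap added at interior boundaries, Da.
#' @return Tibble with `window`, `low`, `high`, `core_low`, `core_high`.
#' @export
swath_windows <- function(mz, n = 12, range = c(70, 1200), margin = 0.5) {
  mz <- mz[mz >= range[1] & mz <= range[2]]
  breaks <- if (length(mz) >= n + 1) {
    as.numeric(quantile(mz, probs = seq(0, 1, length.out = n + 1)))
  } else {
    seq(range[1], range[2], length.out = n + 1)
  }
  breaks[1] <- range[1]
  breaks[n + 1] <- range[2]
  if (any(diff(breaks) <= 1)) {
    breaks <- seq(range[1], range[2], length.out = n + 1)
  }
  tibble(
    window = seq_len(n),
    core_low = breaks[-(n + 1)],
    core_high = breaks[-1],
    low = pmax(range[1], breaks[-(n + 1)] - margin),
    high = pmin(range[2], breaks[-1] + margin)
  )
}

window_of <- function(windows, mz) {
  idx <- findInterval(mz, c(windows$core_low, windows$core_high[nrow(windows)]),
                      rightmost.closed = TRUE)
  idx[idx < 1 | idx > nrow(windows)] <- NA_integer_
  idx
}

new_ms_run <- function(run_id, sample_id, gradient_id, column_mode, mode,
                       run_end, scans, centroids) {
  structure(
    list(run_id = run_id, sample_id = sample_id, gradient_id = gradient_id,
         column_mode = column_mode, mode = mode, run_end = run_end,
         scans = scans, centroids = centroids),
    class = "ms_run"
  )
}

#' @export
print.ms_run <- function(x, ...) {
  cat(sprintf(
    "<ms_run %s: %s %s %s, %d scans, %d centroids, %.1f min>\n",
    x$run_id, x$sample_id %||% "QC", x$mode, x$column_mode,
    nrow(x$scans), nrow(x$centroids), x$run_end))
  invisible(x)
}

# scan schedule of one run: MS1 at each cycle start, then one MS2 scan per
# SWATH window
scan_schedule <- function(run_end, config, windows) {
  ct_min <- cycle_time(config) / 60
  cycles <- seq(0, run_end, by = ct_min)
  nw <- nrow(windows)
  n_cyc <- length(cycles)
  per_cycle <- nw + 1L
  tibble(
    scan = seq_len(n_cyc * per_cycle),
    cycle = rep(seq_len(n_cyc), each = per_cycle),
    ms_level = rep(c(1L, rep(2L, nw)), n_cyc),
    window = rep(c(NA_integer_, windows$window), n_cyc),
    rt = rep(cycles, each = per_cycle) +
      rep(c(0, config$ms1_dwell + (seq_len(nw) - 1) * config$ms2_dwell) / 60,
          n_cyc)
  ) %>%
    left_join(select(windows, "window", "low", "high"), by = "window")
}

# signal centroids for one run given per-compound apex rt/height
run_signal <- function(schedule, cmp, config) {
  sig <- config$peak_sigma
  out <- vector("list", nrow(cmp) * 2)
  ms1 <- filter(schedule, .data$ms_level == 1L)
  for (i in seq_len(nrow(cmp))) {
    rt0 <- cmp$rt_apex[i]
    if (is.na(rt0)) next
    lo <- rt0 - 4.5 * sig; hi <- rt0 + 4.5 * sig
    s1 <- ms1[ms1$rt >= lo & ms1$rt <= hi, ]
    if (nrow(s1) > 0 &&
        cmp$precursor_mz[i] >= config$ms1_range[1] &&
        cmp$precursor_mz[i] <= config$ms1_range[2]) {
      int1 <- cmp$apex[i] * exp(-(s1$rt - rt0)^2 / (2 * sig^2)) *
        (1 + rnorm(nrow(s1), 0, config$intensity_cv))
      out[[2 * i - 1]] <- tibble(
        scan = s1$scan,
        mz = cmp$precursor_mz[i] *
          (1 + rnorm(nrow(s1), 0, config$mass_jitter_ppm) * 1e-6),
        intensity = int1
      )
    }
    if (!is.na(cmp$window[i])) {
      s2 <- schedule[schedule$ms_level == 2L &
                       schedule$window == cmp$window[i] &
                       schedule$rt >= lo & schedule$rt <= hi, ]
      if (nrow(s2) > 0) {
        fr <- cmp$fragments[[i]]
        fr <- fr[fr$mz >= config$ms2_range[1] & fr$mz <= config$ms2_range[2], ]
        if (nrow(fr) > 0) {
          grid <- crossing(tibble(scan = s2$scan, srt = s2$rt),
                           tibble(fmz = fr$mz, ri = fr$rel_int))
          int2 <- cmp$apex[i] * grid$ri *
            exp(-(grid$srt - rt0)^2 / (2 * sig^2)) *
            (1 + rnorm(nrow(grid), 0, config$intensity_cv))
          out[[2 * i]] <- tibble(
            scan = grid$scan,
            mz = grid$fmz *
              (1 + rnorm(nrow(grid), 0, config$mass_jitter_ppm) * 1e-6),
            intensity = int2
          )
        }
      }
    }
  }
  bind_rows(compact(out))
}

run_noise <- function(schedule, config) {
  if (config$noise_peaks_per_scan <= 0) return(NULL)
  n_tot <- rpois(1, nrow(schedule) * config$noise_peaks_per_scan)
  if (n_tot == 0) return(NULL)
  rows <- sample.int(nrow(schedule), n_tot, replace = TRUE)
  lo <- ifelse(schedule$ms_level[rows] == 1L,
               config$ms1_range[1], config$ms2_range[1])
  hi <- ifelse(schedule$ms_level[rows] == 1L,
               config$ms1_range[2],
               pmin(config$ms2_range[2], schedule$high[rows] + 10,
                    na.rm = TRUE))
  tibble(
    scan = schedule$scan[rows],
    mz = runif(n_tot, lo, hi),
    intensity = config$noise_floor * (1 + rexp(n_tot))
  )
}

build_run <- function(run_id, sample_id, gradient, mode, conc_tbl,
                      compounds, true_rt, config, windows) {
  cmp <- compounds %>%
    filter(.data$mode == !!mode) %>%
    add_precursor_mz() %>%
    left_join(true_rt, by = "compound_id") %>%
    left_join(conc_tbl, by = "compound_id") %>%
    mutate(
      rt_apex = .data$rt + rnorm(dplyr::n(), 0, config$rt_jitter),
      apex = .data$conc_ppm * config$response_factor,
      window = window_of(windows, .data$precursor_mz)
    ) %>%
    filter(!is.na(.data$rt_apex), .data$apex > config$noise_floor)
  schedule <- scan_schedule(gradient$run_end, config, windows)
  cent <- bind_rows(run_signal(schedule, cmp, config),
                    run_noise(schedule, config)) %>%
    filter(.data$intensity >= config$noise_floor) %>%
    arrange(.data$scan, .data$mz)
  truth <- cmp %>%
    transmute(
      run_id = run_id,
      .data$compound_id, mz = .data$precursor_mz,
      rt_apex = .data$rt_apex, apex = .data$apex,
      true_area = .data$apex * config$peak_sigma * sqrt(2 * pi) * 60,
      fragmented = !is.na(.data$window)
    )
  list(
    run = new_ms_run(run_id, sample_id, gradient$id, gradient$column_mode,
                     mode, gradient$run_end,
                     select(schedule, "scan", "rt", "ms_level", "window",
                            "low", "high"),
                     cent),
    truth = truth
  )
}

#' Simulate a multi-gradient DIA study
#'
#' Emulates the acquisition layout of the study design: the pooled QC sample
#' (equal-volume mix, i.e. compound concentration = mean over all samples) is
#' acquired under every gradient of the nine-gradient series, while each
#' individual sample is acquired under the reference gradient (G5) only.
#' Each run consists of centroided MS1 survey scans interleaved with one MS2
#' scan per SWATH window; analytes elute as Gaussian peaks with area
#' proportional to concentration; m/z jitter, retention jitter, intensity
#' noise and random noise centroids are applied. Precursors falling outside
#' every SWATH window are recorded as unfragmented in the ground truth, not
#' dropped.
#'
#' @param compounds Tibble from [simulate_compounds()].
#' @param design Tibble from [study_design()].
#' @param concentrations Tibble from [simulate_concentrations()].
#' @param config An [acquisition_config()].
#' @param gradients Named list of nine [gradient_program()]s (one column
#'   mode); defaults to [default_gradients()] for each requested column.
#' @param modes,columns Ionization modes / column modes to simulate.
#' @param include_qc,include_samples Which run sets to generate.
#' @param sample_gradient Gradient id used for individual samples.
#' @param samples Optional subset of sample ids to simulate.
#'
#' @return A bundle (list) with elements `runs` (named list of `ms_run`),
#'   `windows` (per mode/column tibble of SWATH windows), `truth` (list of
#'   tibbles: `rt` true retention per compound x column x gradient,
#'   `run_signals` per-run apex/area/fragmented ground truth, `fragments`
#'   the fragment templates), `design`, `compounds`, `config`.
#' @export
simulate_dia_acquisition <- function(compounds, design, concentrations,
                                     config = acquisition_config(),
                                     gradients = NULL,
                                     modes = c("positive", "negative"),
                                     columns = c("RPLC", "HILIC"),
                                     include_qc = TRUE,
                                     include_samples = TRUE,
                                     sample_gradient = "G5",
                                     samples = NULL) {
  stopifnot(nrow(compounds) > 0)
  set.seed(config$seed)
  gradients <- gradients %||%
    setNames(lapply(columns, default_gradients), columns)
  cmp <- add_precursor_mz(compounds)

  qc_conc <- concentrations %>%
    group_by(.data$compound_id) %>%
    summarise(conc_ppm = mean(.data$conc_ppm), .groups = "drop")
  sample_ids <- samples %||% design$sample_id

  runs <- list()
  signals <- list()
  rt_truth <- list()
  windows_tbl <- list()

  for (col in columns) {
    gl <- gradients[[col]]
    rt_col <- purrr::map(gl, function(g) {
      compute_retention_time(cmp, g) %>%
        transmute(.data$compound_id, gradient_id = g$id,
                  column_mode = col, rt = .data$rt, eluted = .data$eluted)
    }) %>% bind_rows()
    rt_truth[[col]] <- rt_col
    for (mode in modes) {
      wins <- swath_windows(cmp$precursor_mz[cmp$mode == mode],
                            n = config$n_windows, range = config$ms1_range)
      windows_tbl[[paste(mode, col, sep = "_")]] <- wins
      if (include_qc) {
        for (g in gl) {
          rid <- sprintf("QC_%s_%s_%s", mode, col, g$id)
          tr <- rt_col %>% filter(.data$gradient_id == g$id) %>%
            select("compound_id", "rt")
          b <- build_run(rid, NA_character_, g, mode, qc_conc, compounds,
                         tr, config, wins)
          runs[[rid]] <- b$run
          signals[[rid]] <- b$truth
        }
      }
      if (include_samples) {
        g <- gl[[sample_gradient]]
        tr <- rt_col %>% filter(.data$gradient_id == g$id) %>%
          select("compound_id", "rt")
        for (sid in sample_ids) {
          rid <- sprintf("%s_%s_%s_%s", sid, mode, col, g$id)
          sc <- concentrations %>% filter(.data$sample_id == sid) %>%
            select("compound_id", "conc_ppm")
          b <- build_run(rid, sid, g, mode, sc, compounds, tr, config, wins)
          runs[[rid]] <- b$run
          signals[[rid]] <- b$truth
        }
      }
    }
  }

  list(
    runs = runs,
    windows = windows_tbl,
    truth = list(
      rt = bind_rows(rt_truth),
      run_signals = bind_rows(signals),
      fragments = compounds %>% select("compound_id", "fragments") %>%
        unnest("fragments")
    ),
    design = design,
    compounds = compounds,
    config = config,
    gradients = gradients
  )
}

#' Index table of the runs in a simulation bundle
#'
#' @param bundle Output of [simulate_dia_acquisition()].
#' @return Tibble with one row per run: id, sample, gradient, mode, column.
#' @export
run_index <- function(bundle) {
  purrr::map(bundle$runs, function(r) {
    tibble(run_id = r$run_id, sample_id = r$sample_id,
           gradient_id = r$gradient_id, column_mode = r$column_mode,
           mode = r$mode)
  }) %>% bind_rows()
}
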