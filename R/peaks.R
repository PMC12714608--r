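#' Extract an ion chromatogram
#'
#' Sums, scan by scan, the intensities of all centroids within a ppm window
#' of the target m/z. The trace covers every scan of the selected MS level
#' (and SWATH window for MS2), so its length equals the scan count and scans
#' without matching centroids carry zero.
#'
#' @param run An `ms_run`.
#' @param mz Target m/z, Da.
#' @param tol_ppm Half-window in ppm.
#' @param ms_level 1 for precursor traces, 2 for fragment traces.
#' @param window SWATH window id (required when `ms_level = 2`).
#' @return Tibble with `scan`, `rt`, `intensity`.
#' @export
extract_xic <- function(run, mz, tol_ppm = 10, ms_level = 1L, window = NULL) {
  stopifnot(tol_ppm > 0)
  sc <- run$scans[run$scans$ms_level == ms_level, ]
  if (ms_level == 2L) {
    stopifnot(!is.null(window))
    sc <- sc[!is.na(sc$window) & sc$window == window, ]
  }
  if (nrow(sc) == 0) {
    return(tibble(scan = integer(), rt = numeric(), intensity = numeric()))
  }
  tol <- mz * tol_ppm * 1e-6
  cent <- run$centroids
  hit <- cent[cent$mz >= mz - tol & cent$mz <= mz + tol &
                cent$scan %in% sc$scan, ]
  agg <- hit %>% group_by(.data$scan) %>%
    summarise(intensity = sum(.data$intensity), .groups = "drop")
  sc %>% select("scan", "rt") %>%
    left_join(agg, by = "scan") %>%
    mutate(intensity = dplyr::coalesce(.data$intensity, 0))
}

#' Linear weighted moving-average smoother
#'
#' Triangular-weight moving average of half-width `level` (window
#' `2 * level + 1`), the smoother conventionally applied before
#' chromatographic peak picking.
#'
#' @param x Numeric trace.
#' @param level Smoothing level (half-width); 0 returns `x`.
#' @return Smoothed trace, same length.
#' @export
smooth_lwma <- function(x, level = 3) {
  if (level <= 0 || length(x) < 2 * level + 1) return(x)
  w <- level + 1 - abs(-level:level)
  w <- w / sum(w)
  n <- length(x)
  xp <- c(rep(x[1], level), x, rep(x[n], level))
  as.numeric(stats::filter(xp, w, sides = 2))[(level + 1):(level + n)]
}

#' Detect chromatographic peaks in an intensity trace
#'
#' Peaks are local maxima of the smoothed trace above `min_height`, with
#' bounds extended from the apex to the nearest valley (trace rising again)
#' or to near-baseline, and a minimum bound-to-bound width. The apex is the
#' maximum of the smoothed trace; the reported area is a trapezoidal
#' integral of the *raw* trace between the smoothed-trace bounds, in
#' intensity x seconds.
#'
#' @param xic Tibble from [extract_xic()] (`rt` minutes, `intensity`).
#' @param smoothing_level Half-width of the triangular smoother.
#' @param min_height Minimum smoothed apex intensity.
#' @param min_width Minimum peak width, seconds.
#' @param baseline_frac Bound extension stops when the trace falls below
#'   this fraction of the apex.
#' @return Tibble of peaks: `rt_apex`, `rt_lo`, `rt_hi`, `height`, `area`.
#'   Zero rows when nothing qualifies.
#' @export
detect_chrom_peaks <- function(xic, smoothing_level = 3, min_height = 1000,
                               min_width = 5, baseline_frac = 0.005) {
  n <- nrow(xic)
  if (n < 3) return(empty_peaks())
  y <- smooth_lwma(xic$intensity, smoothing_level)
  rt <- xic$rt
  raw <- xic$intensity
  apexes <- which(y >= min_height &
                    y >= dplyr::lag(y, default = -Inf) &
                    y > dplyr::lead(y, default = -Inf))
  if (length(apexes) == 0) return(empty_peaks())
  out <- vector("list", length(apexes))
  for (k in seq_along(apexes)) {
    a <- apexes[k]
    floor_y <- baseline_frac * y[a]
    lo <- a
    while (lo > 1 && y[lo - 1] <= y[lo] && y[lo] > floor_y) lo <- lo - 1
    hi <- a
    while (hi < n && y[hi + 1] <= y[hi] && y[hi] > floor_y) hi <- hi + 1
    # width is judged on the raw trace: contiguous region around the apex
    # where the signal stays above the baseline fraction of its own maximum
    seg <- lo:hi
    raw_max <- max(raw[seg])
    wlo <- a
    while (wlo > lo && raw[wlo - 1] > baseline_frac * raw_max) wlo <- wlo - 1
    whi <- a
    while (whi < hi && raw[whi + 1] > baseline_frac * raw_max) whi <- whi + 1
    if ((rt[whi] - rt[wlo]) * 60 < min_width) next
    area <- sum(diff(rt[seg]) * (head(raw[seg], -1) + tail(raw[seg], -1)) / 2) * 60
    out[[k]] <- tibble(rt_apex = rt[a], rt_lo = rt[lo], rt_hi = rt[hi],
                       height = y[a], area = area)
  }
  res <- bind_rows(compact(out))
  if (nrow(res) == 0) empty_peaks() else res
}

empty_peaks <- function() {
  tibble(rt_apex = numeric(), rt_lo = numeric(), rt_hi = numeric(),
         height = numeric(), area = numeric())
}

# gap-based m/z clustering ("mass slices"): sorted m/z values are split
# where consecutive values differ by more than tol_ppm
mz_clusters <- function(mz, tol_ppm) {
  ord <- order(mz)
  s <- mz[ord]
  brk <- c(FALSE, diff(s) > s[-length(s)] * tol_ppm * 1e-6)
  cl <- cumsum(brk) + 1L
  out <- integer(length(mz))
  out[ord] <- cl
  out
}

# build XIC traces for a set of centroids on a fixed scan axis and pick peaks
detect_peaks_in_slices <- function(cent, scans, tol_ppm, min_points,
                                   smoothing_level, min_height, min_width) {
  if (nrow(cent) == 0) return(tibble())
  cent$slice <- mz_clusters(cent$mz, 2 * tol_ppm)
  keep <- cent %>% count(.data$slice) %>% filter(.data$n >= min_points)
  cent <- semi_join(cent, keep, by = "slice")
  if (nrow(cent) == 0) return(tibble())
  axis <- scans %>% select("scan", "rt")
  cent %>%
    group_by(.data$slice) %>%
    group_modify(function(d, key) {
      agg <- d %>% group_by(.data$scan) %>%
        summarise(intensity = sum(.data$intensity),
                  w_mz = sum(.data$mz * .data$intensity), .groups = "drop")
      trace <- axis %>% left_join(agg, by = "scan") %>%
        mutate(intensity = dplyr::coalesce(.data$intensity, 0))
      pk <- detect_chrom_peaks(trace, smoothing_level, min_height, min_width)
      if (nrow(pk) == 0) return(pk)
      pk$mz <- sum(agg$w_mz) / sum(agg$intensity)
      pk
    }) %>%
    ungroup() %>%
    select(-"slice")
}

#' Untargeted MS1 peak detection for one run
#'
#' Slices the MS1 centroid cloud into narrow m/z bins (gap clustering at
#' twice `tol_ppm`), builds the XIC of each slice over the full MS1 scan
#' axis, and picks chromatographic peaks.
#'
#' @param run An `ms_run`.
#' @param tol_ppm m/z tolerance for slice formation / trace extraction.
#' @param min_points Minimum centroid count for a slice to be considered.
#' @param smoothing_level,min_height,min_width Passed to
#'   [detect_chrom_peaks()].
#' @return Tibble of peaks with columns `mz`, `rt_apex`, `rt_lo`, `rt_hi`,
#'   `height`, `area`.
#' @export
detect_ms1_peaks <- function(run, tol_ppm = 10, min_points = 5,
                             smoothing_level = 3, min_height = 1000,
                             min_width = 5) {
  sc <- run$scans[run$scans$ms_level == 1L, ]
  cent <- run$centroids[run$centroids$scan %in% sc$scan, ]
  detect_peaks_in_slices(cent, sc, tol_ppm, min_points,
                         smoothing_level, min_height, min_width)
}

#' Untargeted MS2 peak detection per SWATH window
#'
#' Same slice-and-pick procedure as [detect_ms1_peaks()] applied separately
#' to the MS2 scan series of each SWATH window.
#'
#' @inheritParams detect_ms1_peaks
#' @return Tibble of peaks with an additional `window` column.
#' @export
detect_ms2_peaks <- function(run, tol_ppm = 10, min_points = 5,
                             smoothing_level = 3, min_height = 1000,
                             min_width = 5) {
  sc2 <- run$scans[run$scans$ms_level == 2L, ]
  wins <- sort(unique(sc2$window))
  purrr::map(wins, function(w) {
    sc <- sc2[sc2$window == w, ]
    cent <- run$centroids[run$centroids$scan %in% sc$scan, ]
    pk <- detect_peaks_in_slices(cent, sc, tol_ppm, min_points,
                                 smoothing_level, min_height, min_width)
    if (nrow(pk) > 0) pk$window <- w
    pk
  }) %>% bind_rows()
}
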