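#' Write a simulated run to mzML
#'
#' Serializes an `ms_run` to a centroided mzML file through the proteowizard
#' bindings in \pkg{mzR}. MS2 scans carry their SWATH isolation window as
#' target m/z plus lower/upper offsets.
#'
#' @param run An `ms_run` object.
#' @param path Output file path (`.mzML`).
#' @return `path`, invisibly.
#' @export
write_run_mzml <- function(run, path) {
  stopifnot(inherits(run, "ms_run"))
  sc <- run$scans
  cent <- run$centroids
  pk_split <- split(cent[c("mz", "intensity")], factor(cent$scan, levels = sc$scan))
  pks <- purrr::map(pk_split, function(d) {
    cbind(mz = d$mz, intensity = d$intensity)
  })
  n <- nrow(sc)
  counts <- vapply(pks, nrow, integer(1))
  tic <- vapply(pks, function(m) sum(m[, 2]), numeric(1))
  bp_i <- vapply(pks, function(m) if (nrow(m)) max(m[, 2]) else 0, numeric(1))
  bp_mz <- vapply(pks, function(m) if (nrow(m)) m[which.max(m[, 2]), 1] else 0,
                  numeric(1))
  is2 <- sc$ms_level == 2L
  target <- ifelse(is2, (sc$low + sc$high) / 2, NA_real_)
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = sc$ms_level,
    polarity = if (identical(run$mode, "negative")) 0L else 1L,
    peaksCount = counts, totIonCurrent = tic,
    retentionTime = sc$rt * 60,
    basePeakMZ = bp_mz, basePeakIntensity = bp_i,
    collisionEnergy = ifelse(is2, 35, 0), ionisationEnergy = 0,
    lowMZ = vapply(pks, function(m) if (nrow(m)) min(m[, 1]) else 0, numeric(1)),
    highMZ = vapply(pks, function(m) if (nrow(m)) max(m[, 1]) else 0, numeric(1)),
    precursorScanNum = 0L,
    precursorMZ = ifelse(is2, target, 0),
    precursorCharge = ifelse(is2, 1L, 0L), precursorIntensity = 0,
    mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = sprintf("scan=%d", seq_len(n)),
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = target,
    isolationWindowLowerOffset = ifelse(is2, target - sc$low, NA_real_),
    isolationWindowUpperOffset = ifelse(is2, sc$high - target, NA_real_),
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_,
    stringsAsFactors = FALSE
  )
  mzR::writeMSData(unname(pks), path, header = hdr, outformat = "mzml")
  invisible(path)
}

#' Read an mzML file back into an `ms_run`
#'
#' Inverse of [write_run_mzml()]. Run-level metadata not stored in mzML
#' (gradient id, sample id, column mode) can be supplied through arguments.
#'
#' @param path mzML file path.
#' @param run_id,sample_id,gradient_id,column_mode Optional metadata.
#' @return An `ms_run`.
#' @export
read_run_mzml <- function(path, run_id = basename(path), sample_id = NA,
                          gradient_id = NA, column_mode = NA) {
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  hdr <- mzR::header(fh)
  pks <- mzR::peaks(fh)
  if (is.matrix(pks)) pks <- list(pks)
  is2 <- hdr$msLevel == 2L
  low <- ifelse(is2, hdr$isolationWindowTargetMZ - hdr$isolationWindowLowerOffset,
                NA_real_)
  high <- ifelse(is2, hdr$isolationWindowTargetMZ + hdr$isolationWindowUpperOffset,
                 NA_real_)
  windows <- rep(NA_integer_, nrow(hdr))
  if (any(is2)) {
    lv <- sort(unique(round(low[is2], 6)))
    windows[is2] <- match(round(low[is2], 6), lv)
  }
  scans <- tibble(
    scan = seq_len(nrow(hdr)),
    rt = hdr$retentionTime / 60,
    ms_level = as.integer(hdr$msLevel),
    window = windows, low = low, high = high
  )
  counts <- vapply(pks, nrow, integer(1))
  cent <- tibble(
    scan = rep(scans$scan, counts),
    mz = unlist(lapply(pks, function(m) m[, 1]), use.names = FALSE),
    intensity = unlist(lapply(pks, function(m) m[, 2]), use.names = FALSE)
  )
  mode <- if (all(hdr$polarity == 0L)) "negative" else "positive"
  new_ms_run(run_id, sample_id, gradient_id, column_mode, mode,
             max(scans$rt), scans, cent)
}
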