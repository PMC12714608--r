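suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
  library(purrr)
})

# brute-force retention oracle: stepwise migration sum on a fine grid,
# written independently of the package's integrator (no trapezoid, no
# interpolation)
oracle_retention <- function(log_k0, s, gradient, dt = 1 / 60000) {
  t0 <- gradient$dead_time
  phi_at <- function(t) {
    bp <- gradient$breakpoints
    if (nrow(bp) == 1) return(rep(bp$fraction, length(t)))
    stats::approx(bp$time, bp$fraction, xout = t, rule = 2)$y
  }
  tau <- 0
  acc <- 0
  while (acc < t0) {
    phi <- phi_at(tau)
    if (gradient$column_mode == "HILIC") phi <- 1 - phi
    k <- 10^(log_k0 - s * phi)
    acc <- acc + dt / k
    tau <- tau + dt
    if (tau > gradient$run_end) return(NA_real_)
  }
  t0 + tau
}

# brute-force cosine oracle: builds the full gap matrix and repeatedly takes
# the globally smallest gap, then computes the cosine explicitly
oracle_cosine <- function(a, b, tol = 0.025) {
  gap <- abs(outer(a$mz, b$mz, "-"))
  pairs <- list()
  repeat {
    m <- which(gap == min(gap), arr.ind = TRUE)[1, , drop = FALSE]
    if (gap[m] > tol || !is.finite(gap[m])) break
    pairs[[length(pairs) + 1]] <- m
    gap[m[1], ] <- Inf
    gap[, m[2]] <- Inf
  }
  ia <- a$intensity; ib <- b$intensity
  va <- numeric(); vb <- numeric()
  pa <- vapply(pairs, function(p) p[1], numeric(1))
  pb <- vapply(pairs, function(p) p[2], numeric(1))
  for (i in seq_along(pa)) {
    va <- c(va, ia[pa[i]]); vb <- c(vb, ib[pb[i]])
  }
  for (i in setdiff(seq_along(ia), pa)) {
    va <- c(va, ia[i]); vb <- c(vb, 0)
  }
  for (j in setdiff(seq_along(ib), pb)) {
    va <- c(va, 0); vb <- c(vb, ib[j])
  }
  s <- sum(va * vb) / (sqrt(sum(va^2)) * sqrt(sum(vb^2)))
  min(1, s)
}

random_spectrum <- function(n = 8, mz_range = c(60, 600)) {
  tibble(mz = sort(runif(n, mz_range[1], mz_range[2])),
         intensity = runif(n, 0.05, 1))
}

# small noise-free acquisition fixture shared by several files
quiet_config <- function(seed = 11, ...) {
  acquisition_config(mass_jitter_ppm = 0, rt_jitter = 0, intensity_cv = 0,
                     noise_peaks_per_scan = 0, seed = seed, ...)
}

small_bundle <- function(n = 12, seed = 11, config = quiet_config(seed),
                         modes = "positive", columns = "RPLC",
                         include_samples = FALSE, ...) {
  cmp <- simulate_compounds(n, seed = seed, coelute_fraction = 0, ...)
  des <- study_design(3, 2, 3, 2)
  conc <- simulate_concentrations(cmp, des, seed = seed)
  simulate_dia_acquisition(cmp, des, conc, config, modes = modes,
                           columns = columns,
                           include_samples = include_samples)
}

# synthetic Gaussian trace on a uniform scan axis
gaussian_trace <- function(height = 1e4, mean = 10, sigma = 0.05,
                           from = 9, to = 11, dt = 0.0125) {
  rt <- seq(from, to, by = dt)
  tibble(scan = seq_along(rt), rt = rt,
         intensity = height * exp(-(rt - mean)^2 / (2 * sigma^2)))
}
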