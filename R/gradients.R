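#' Define a gradient program
#'
#' A gradient program is the solvent-composition schedule of one LC run:
#' piecewise-linear breakpoints of organic fraction over time, plus the column
#' dead time. After the last breakpoint the composition is held constant until
#' `run_end`.
#'
#' @param id Gradient label, e.g. `"G5"`.
#' @param column_mode `"RPLC"` or `"HILIC"`.
#' @param breakpoints Data frame with columns `time` (minutes, strictly
#'   increasing, starting at 0) and `fraction` (organic solvent fraction in
#'   \[0, 1\]).
#' @param dead_time Column dead time t0 in minutes.
#' @param run_end Total run length in minutes; defaults to the last breakpoint
#'   time plus a 5 min hold.
#'
#' @return An object of class `gradient_program`.
#' @export
#' @examples
#' g <- gradient_program("G5", "RPLC",
#'   breakpoints = data.frame(time = c(0, 20), fraction = c(0.02, 0.98)))
#' solvent_fraction(g, c(0, 10, 20, 25))
gradient_program <- function(id, column_mode = c("RPLC", "HILIC"),
                             breakpoints, dead_time = 1,
                             run_end = NULL) {
  column_mode <- match.arg(column_mode)
  breakpoints <- as_tibble(breakpoints)
  stopifnot(all(c("time", "fraction") %in% names(breakpoints)))
  if (breakpoints$time[1] != 0 || is.unsorted(breakpoints$time, strictly = TRUE)) {
    abort("breakpoint times must be strictly increasing and start at 0")
  }
  if (any(breakpoints$fraction < 0 | breakpoints$fraction > 1)) {
    abort("solvent fractions must lie in [0, 1]")
  }
  if (dead_time <= 0) abort("dead_time must be positive")
  run_end <- run_end %||% (max(breakpoints$time) + 5)
  structure(
    list(id = id, column_mode = column_mode, breakpoints = breakpoints,
         dead_time = dead_time, run_end = run_end),
    class = "gradient_program"
  )
}

#' @export
print.gradient_program <- function(x, ...) {
  cat(sprintf("<gradient_program %s [%s], t0 = %g min, end = %g min>\n",
              x$id, x$column_mode, x$dead_time, x$run_end))
  print(x$breakpoints)
  invisible(x)
}

#' Solvent fraction at given times
#'
#' Piecewise-linear interpolation of the gradient program; constant before the
#' first and after the last breakpoint.
#'
#' @param gradient A [gradient_program()].
#' @param t Times in minutes.
#' @return Numeric vector of organic solvent fractions.
#' @export
solvent_fraction <- function(gradient, t) {
  bp <- gradient$breakpoints
  if (nrow(bp) == 1) return(rep(bp$fraction, length(t)))
  approx(bp$time, bp$fraction, xout = t, rule = 2)$y
}

#' Default nine-gradient family
#'
#' The systematic gradient series used to probe retention behavior: nine
#' linear ramps from a starting organic fraction of 0.02 to 0.98 whose ramp
#' durations span 10--30 minutes in evenly spaced steps, followed by a hold.
#' G5 (20 min ramp) is the reference gradient under which individual samples
#' are acquired. The same programs are reused for both column modes; HILIC
#' retention is driven by the aqueous fraction (see
#' [compute_retention_time()]).
#'
#' @param column_mode `"RPLC"` or `"HILIC"`.
#' @param ramp_durations Ramp lengths in minutes, one per gradient.
#' @param start_fraction,end_fraction Organic fraction at ramp start/end.
#' @param dead_time Dead time in minutes.
#' @param hold Post-ramp hold in minutes.
#' @return Named list of nine [gradient_program()] objects `G1`...`G9`.
#' @export
#' @examples
#' gl <- default_gradients("RPLC")
#' names(gl)
default_gradients <- function(column_mode = c("RPLC", "HILIC"),
                              ramp_durations = seq(10, 30, length.out = 9),
                              start_fraction = 0.02, end_fraction = 0.98,
                              dead_time = 1, hold = 5) {
  column_mode <- match.arg(column_mode)
  stopifnot(length(ramp_durations) == 9)
  gl <- purrr::imap(ramp_durations, function(d, i) {
    gradient_program(
      id = paste0("G", i), column_mode = column_mode,
      breakpoints = tibble(time = c(0, d),
                           fraction = c(start_fraction, end_fraction)),
      dead_time = dead_time, run_end = d + hold
    )
  })
  names(gl) <- paste0("G", seq_len(9))
  gl
}

#' Predict gradient retention times under linear solvent strength
#'
#' Retention is modeled by the linear-solvent-strength (LSS) law
#' `log10 k(phi) = log_k0 - S * phi`, where `phi` is the organic solvent
#' fraction for RPLC and the aqueous fraction `1 - phi` for HILIC. The
#' gradient-elution retention time solves
#' `integral_0^(tR - t0) dt / k(phi(t)) = t0`
#' by forward numerical integration on a fixed time step. Under isocratic
#' conditions this reduces to the familiar `tR = t0 * (1 + k)`.
#'
#' @param compounds Data frame with one row per compound carrying LSS
#'   parameters for the gradient's column mode: columns `log_k0_rplc`,
#'   `s_rplc`, `log_k0_hilic`, `s_hilic` (or plain `log_k0`, `s`, used for
#'   either mode).
#' @param gradient A [gradient_program()].
#' @param dt Integration step in minutes (default 10 ms).
#'
#' @return The input tibble with columns `rt` (apex retention time, minutes;
#'   `NA` when the compound does not elute before `run_end`) and `eluted`
#'   (logical). A compound that never reaches the migration criterion within
#'   the program is flagged, never silently clipped to the run end.
#' @export
#' @examples
#' iso <- gradient_program("iso", "RPLC",
#'   breakpoints = data.frame(time = 0, fraction = 0.5),
#'   dead_time = 1, run_end = 30)
#' # k = 9 at phi = 0.5: log10 k0 = log10(9) + 2 * 0.5
#' cmp <- data.frame(log_k0 = log10(9) + 1, s = 2)
#' compute_retention_time(cmp, iso)$rt  # 10 minutes
compute_retention_time <- function(compounds, gradient, dt = 10 / 60000) {
  stopifnot(inherits(gradient, "gradient_program"))
  compounds <- as_tibble(compounds)
  if (all(c("log_k0", "s") %in% names(compounds))) {
    log_k0 <- compounds$log_k0
    s <- compounds$s
  } else if (gradient$column_mode == "RPLC") {
    log_k0 <- compounds$log_k0_rplc
    s <- compounds$s_rplc
  } else {
    log_k0 <- compounds$log_k0_hilic
    s <- compounds$s_hilic
  }
  if (is.null(log_k0) || is.null(s)) {
    abort(sprintf("retention parameters missing for column mode %s",
                  gradient$column_mode))
  }
  t0 <- gradient$dead_time
  tau_max <- gradient$run_end - t0
  grid <- seq(0, tau_max, by = dt)
  phi <- solvent_fraction(gradient, grid)
  if (gradient$column_mode == "HILIC") phi <- 1 - phi

  rt <- numeric(length(log_k0))
  eluted <- rep(TRUE, length(log_k0))
  for (i in seq_along(log_k0)) {
    if (!is.finite(log_k0[i]) && log_k0[i] < 0) {
      rt[i] <- t0
      next
    }
    inv_k <- 10^(-(log_k0[i] - s[i] * phi))
    # trapezoidal cumulative migration integral over the grid
    mig <- cumsum(c(0, (inv_k[-1] + inv_k[-length(inv_k)]) / 2 * dt))
    hit <- which(mig >= t0)
    if (length(hit) == 0) {
      rt[i] <- NA_real_
      eluted[i] <- FALSE
    } else {
      j <- hit[1]
      # linear interpolation inside the crossing step
      if (j == 1) {
        tau <- 0
      } else {
        frac <- (t0 - mig[j - 1]) / (mig[j] - mig[j - 1])
        tau <- grid[j - 1] + frac * dt
      }
      rt[i] <- t0 + tau
    }
  }
  compounds$rt <- rt
  compounds$eluted <- eluted
  compounds
}
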