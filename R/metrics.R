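#' Locate peaks in a regularly sampled series
#'
#' Local maxima filtered by topographic prominence and a minimum inter-peak
#' distance (higher peaks win ties). Small helper used for slow-wave cycle
#' detection; exported because protocol code and tests reuse it.
#'
#' @param x Numeric series.
#' @param prominence Minimum prominence, same units as `x`.
#' @param min_dist Minimum distance between retained peaks, in samples.
#' @return Integer indices of peaks, in increasing order.
#' @export
find_peaks <- function(x, prominence = 2, min_dist = 1L) {
  n <- length(x)
  if (n < 3) return(integer())
  d <- diff(x)
  # rising-then-falling points; runs of equal samples peak at their start
  cand <- which(d[-1] < 0 & d[-(n - 1)] > 0) + 1L
  if (!length(cand)) return(integer())
  prom <- vapply(cand, function(i) {
    j <- i; lmin <- x[i]
    while (j > 1 && x[j] <= x[i]) { j <- j - 1L; lmin <- min(lmin, x[j]) }
    k <- i; rmin <- x[i]
    while (k < n && x[k] <= x[i]) { k <- k + 1L; rmin <- min(rmin, x[k]) }
    x[i] - max(lmin, rmin)
  }, numeric(1))
  cand <- cand[prom >= prominence]
  if (!length(cand)) return(integer())
  keep <- logical(length(cand))
  for (i in order(x[cand], decreasing = TRUE)) {
    if (!any(keep & abs(cand - cand[i]) < min_dist)) keep[i] <- TRUE
  }
  sort(cand[keep])
}

#' Slow-wave metrics from a simulation trace
#'
#' Cycles are delimited by membrane-potential peaks (2 mV prominence,
#' minimum separation `min_period/2`). The resting potential is the mean
#' per-cycle minimum, the peak potential the mean peak value, the amplitude
#' their difference, and the frequency the peak count per minute. Free Ca2+
#' extrema are taken per cycle and reported in nM.
#'
#' @param trace A `jsmc_trace` from [run_free()].
#' @param window Length-2 interval, ms, over which to measure; defaults to
#'   everything after the trace's burn-in metadata. Must contain at least
#'   two peaks.
#' @param prominence Peak prominence threshold, mV.
#' @param min_period Smallest slow-wave period expected, ms (peaks closer
#'   than half this are merged).
#' @return A list of class `jsmc_metrics`: `resting_potential`,
#'   `peak_potential`, `plateau_potential` (mean potential over the 0.5-2.5 s
#'   window after each peak), `amplitude` (mV), `frequency` (cycles/min),
#'   `time_to_peak` (ms), `ca_min`, `ca_max` (nM), `n_cycles`.
#' @export
analyze_trace <- function(trace, window = NULL, prominence = 2,
                          min_period = 4000) {
  if (is.null(window)) {
    window <- c(attr(trace, "burn_in") %||% 0, max(trace$t))
  }
  sub <- trace[trace$t >= window[1] & trace$t <= window[2], ]
  if (nrow(sub) < 3) stop("analysis window too short", call. = FALSE)
  dt_rec <- sub$t[2] - sub$t[1]
  pk <- find_peaks(sub$V_m, prominence = prominence,
                   min_dist = max(1L, floor(min_period / 2 / dt_rec)))
  if (length(pk) < 2) {
    stop("fewer than two peaks detected: frequency undefined", call. = FALSE)
  }
  np <- length(pk)
  trough_idx <- integer(np - 1)
  ca_min <- ca_max <- ttp <- plat <- numeric(np - 1)
  for (i in seq_len(np - 1)) {
    seg <- pk[i]:pk[i + 1]
    trough_idx[i] <- seg[which.min(sub$V_m[seg])]
    ca_min[i] <- min(sub$Ca_free[seg])
    ca_max[i] <- max(sub$Ca_free[seg])
    ttp[i] <- sub$t[pk[i + 1]] - sub$t[trough_idx[i]]
    ps <- sub$t >= sub$t[pk[i]] + 500 & sub$t <= sub$t[pk[i]] + 2500
    plat[i] <- mean(sub$V_m[ps])
  }
  resting <- mean(sub$V_m[trough_idx])
  peak <- mean(sub$V_m[pk])
  out <- list(
    resting_potential = resting,
    peak_potential = peak,
    plateau_potential = mean(plat),
    amplitude = peak - resting,
    frequency = 60000 * (np - 1) / (sub$t[pk[np]] - sub$t[pk[1]]),
    time_to_peak = mean(ttp),
    ca_min = 1e6 * mean(ca_min),
    ca_max = 1e6 * mean(ca_max),
    n_cycles = np - 1
  )
  class(out) <- "jsmc_metrics"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.jsmc_metrics <- function(x, ...) {
  cat(sprintf(paste0("slow-wave metrics (%d cycles):\n",
                     "  resting potential %.2f mV, peak %.2f mV, amplitude %.2f mV\n",
                     "  frequency %.2f cycles/min, time to peak %.0f ms\n",
                     "  free Ca2+ %.1f-%.1f nM\n"),
              x$n_cycles, x$resting_potential, x$peak_potential, x$amplitude,
              x$frequency, x$time_to_peak, x$ca_min, x$ca_max))
  invisible(x)
}

#' @export
print.jsmc_trace <- function(x, ...) {
  cat(sprintf("jsmc trace: %d samples, %.1f s at dt = %g ms (stride %d), protocol %s\n",
              nrow(x), max(x$t) / 1000, attr(x, "dt"), attr(x, "stride"),
              attr(x, "protocol")))
  invisible(x)
}
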