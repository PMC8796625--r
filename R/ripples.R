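#' Band-pass filter specification for fast-ripple detection
#'
#' Order-2 Butterworth band-pass between 200 and 550 Hz, the band in which
#' fast ripples — brief high-frequency EEG oscillations marking epileptogenic
#' (or, over somatosensory cortex, physiological) activity — are sought.
#'
#' @param low,high band edges, Hz.
#' @param order Butterworth order (default 2).
#' @param zero_phase apply forward-backward (`TRUE`, default; preserves event
#'   timing, doubles effective attenuation) or single-pass (`FALSE`; literal
#'   order-2 response with -3 dB at the band edges).
#' @return list of class `filter_spec`.
#' @export
filter_spec <- function(low = 200, high = 550, order = 2, zero_phase = TRUE) {
  if (!(0 < low && low < high)) stop("need 0 < low < high")
  structure(list(low = low, high = high, order = order,
                 zero_phase = zero_phase), class = "filter_spec")
}

#' Band-pass filter one trace
#'
#' @param x numeric trace (one channel).
#' @param fs sampling rate, Hz.
#' @param band length-2 band edges, Hz; or pass a [filter_spec] via `spec`.
#' @param order Butterworth order.
#' @param zero_phase forward-backward application (see [filter_spec]).
#' @param spec optional `filter_spec` overriding the other arguments.
#' @return filtered trace of the same length.
#' @export
bandpass <- function(x, fs, band = c(200, 550), order = 2,
                     zero_phase = TRUE, spec = NULL) {
  if (!is.null(spec)) {
    band <- c(spec$low, spec$high); order <- spec$order
    zero_phase <- spec$zero_phase
  }
  if (band[2] >= fs / 2) stop("band edge at or above the Nyquist frequency")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  if (zero_phase) signal::filtfilt(bf, x)
  else as.numeric(signal::filter(bf, x))
}

#' Fast-ripple detector specification
#'
#' Detection thresholds: an event needs at least `min_oscillations`
#' consecutive band-legitimate oscillations whose mean amplitude exceeds
#' `amplitude_ratio` times the standard deviation of the surrounding
#' `baseline_ms` of filtered signal (the baseline window excludes the
#' candidate samples). Events separated by less than `merge_gap_ms` merge.
#'
#' @param min_oscillations minimum consecutive oscillations (default 4).
#' @param amplitude_ratio amplitude threshold in baseline SDs (default 3).
#' @param baseline_ms total surrounding-baseline duration, ms (default 250,
#'   i.e. 125 ms each side of the candidate).
#' @param merge_gap_ms events closer than this merge (default 10).
#' @param baseline_sd optional fixed global baseline SD; when supplied the
#'   local surrounding-window estimate is bypassed (useful for margin tests
#'   and for recordings with a known noise floor).
#' @param period_tol tolerated fractional deviation of an oscillation's
#'   period from the filter band's period range (default 0.1).
#' @return list of class `detector_spec`.
#' @export
detector_spec <- function(min_oscillations = 4, amplitude_ratio = 3,
                          baseline_ms = 250, merge_gap_ms = 10,
                          baseline_sd = NULL, period_tol = 0.1) {
  if (min_oscillations < 1) stop("min_oscillations must be >= 1")
  if (amplitude_ratio <= 0) stop("amplitude_ratio must be positive")
  structure(list(min_oscillations = min_oscillations,
                 amplitude_ratio = amplitude_ratio,
                 baseline_ms = baseline_ms, merge_gap_ms = merge_gap_ms,
                 baseline_sd = baseline_sd, period_tol = period_tol),
            class = "detector_spec")
}

#' Detect fast ripples in a band-pass filtered trace
#'
#' Oscillations are full cycles delimited by consecutive rising zero
#' crossings of the filtered trace; a cycle is band-legitimate when its
#' period lies within the filter band's period range (about 1.8-5 ms for
#' 200-550 Hz, with `period_tol` slack), which keeps slow artifacts from
#' being counted. A cycle's amplitude is half its peak-to-peak excursion.
#' Candidate windows of `min_oscillations` consecutive legitimate cycles
#' qualify when their mean amplitude exceeds `amplitude_ratio` times the
#' local baseline SD; qualifying windows are merged into maximal events,
#' and events closer than `merge_gap_ms` are joined. The detection is
#' invariant under rescaling of the trace, since thresholds are
#' baseline-relative.
#'
#' @param x band-pass filtered trace (see [bandpass]).
#' @param fs sampling rate, Hz.
#' @param spec a [detector_spec].
#' @param band the filter band used (sets the legitimate period range).
#' @return data.frame of class `ripple_events`: `start_sample`, `end_sample`
#'   (inclusive), `start_s`, `end_s`, `n_oscillations`, `peak_ratio`
#'   (peak amplitude over baseline SD), `mean_freq_hz`.
#' @export
detect_fast_ripples <- function(x, fs, spec = detector_spec(),
                                band = c(200, 550)) {
  n <- length(x)
  if (is.null(spec$baseline_sd) && n < spec$baseline_ms / 1000 * fs)
    stop("trace shorter than the baseline window")
  empty <- data.frame(start_sample = integer(), end_sample = integer(),
                      start_s = numeric(), end_s = numeric(),
                      n_oscillations = integer(), peak_ratio = numeric(),
                      mean_freq_hz = numeric())
  class(empty) <- c("ripple_events", "data.frame")

  rising <- which(x[-n] < 0 & x[-1] >= 0)
  if (length(rising) < 2L) return(empty)
  a <- rising[-length(rising)] + 1L     # cycle start samples
  b <- rising[-1L]                      # cycle end samples (inclusive)
  nc <- length(a)
  len <- b - a + 1L
  period <- len / fs
  p_min <- 1 / (band[2] * (1 + spec$period_tol))
  p_max <- (1 + spec$period_tol) / band[1]
  legit <- period >= p_min & period <= p_max

  grp <- rep.int(seq_len(nc), len)
  seg <- x[a[1L]:b[nc]]
  cyc_max <- as.numeric(tapply(seg, grp, max))
  cyc_min <- as.numeric(tapply(seg, grp, min))
  amp <- (cyc_max - cyc_min) / 2
  peak <- pmax(abs(cyc_max), abs(cyc_min))

  h <- round(spec$baseline_ms / 2 * fs / 1000)
  s1 <- cumsum(x); s2 <- cumsum(x^2)
  cum <- function(s, l, r) {
    lo <- numeric(length(l))
    pos <- l > 1L
    lo[pos] <- s[l[pos] - 1L]
    s[r] - lo
  }
  # SD of the surrounding baseline_ms of signal, candidate span excluded
  surround_sd <- function(l, r) {
    if (!is.null(spec$baseline_sd))
      return(rep(spec$baseline_sd, length(l)))
    wl <- pmax(1L, l - h); wr <- pmin(n, r + h)
    S1 <- cum(s1, wl, wr) - cum(s1, l, r)
    S2 <- cum(s2, wl, wr) - cum(s2, l, r)
    cnt <- (wr - wl + 1L) - (r - l + 1L)
    v <- (S2 - S1^2 / cnt) / (cnt - 1L)
    sqrt(pmax(v, 0))
  }

  m <- spec$min_oscillations
  if (nc < m) return(empty)
  # sliding windows of m consecutive legitimate cycles; the baseline for a
  # window excludes the window's own samples (the candidate)
  nw <- nc - m + 1L
  j <- seq_len(nw)
  all_legit <- if (m == 1L) legit[j]
               else Reduce(`&`, lapply(0:(m - 1L), function(o) legit[j + o]))
  csum_amp <- cumsum(amp)
  mean_amp <- (csum_amp[j + m - 1L] - c(0, csum_amp)[j]) / m
  wsd <- surround_sd(a[j], b[j + m - 1L])
  pass <- all_legit & wsd > 0 & mean_amp > spec$amplitude_ratio * wsd
  marked <- logical(nc)
  for (jj in which(pass)) marked[jj:(jj + m - 1L)] <- TRUE
  if (!any(marked)) return(empty)

  r <- rle(marked)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  ev <- data.frame(c0 = starts[r$values], c1 = ends[r$values])
  # merge events with inter-event gap below merge_gap_ms
  gap_samp <- spec$merge_gap_ms / 1000 * fs
  if (nrow(ev) > 1L) {
    keep <- ev[1L, , drop = FALSE]
    for (i in 2:nrow(ev)) {
      prev_end <- b[keep$c1[nrow(keep)]]
      if (a[ev$c0[i]] - prev_end <= gap_samp)
        keep$c1[nrow(keep)] <- ev$c1[i]
      else keep <- rbind(keep, ev[i, ])
    }
    ev <- keep
  }
  out <- do.call(rbind, lapply(seq_len(nrow(ev)), function(i) {
    cs <- ev$c0[i]:ev$c1[i]
    e0 <- a[ev$c0[i]]; e1 <- b[ev$c1[i]]
    dur <- (e1 - e0 + 1L) / fs
    ev_sd <- surround_sd(e0, e1)
    data.frame(start_sample = e0, end_sample = e1,
               start_s = (e0 - 1L) / fs, end_s = e1 / fs,
               n_oscillations = length(cs),
               peak_ratio = max(peak[cs]) / ev_sd,
               mean_freq_hz = length(cs) / dur)
  }))
  class(out) <- c("ripple_events", "data.frame")
  out
}

#' Detect fast ripples across the channels of a recording
#'
#' Applies the band-pass of `fspec` to each channel and runs
#' [detect_fast_ripples].
#'
#' @param recording an `eeg_recording` (see [simulate_eeg]).
#' @param fspec a [filter_spec].
#' @param spec a [detector_spec].
#' @return `ripple_events` data.frame with a `channel` column.
#' @export
detect_ripples <- function(recording, fspec = filter_spec(),
                           spec = detector_spec()) {
  stopifnot(inherits(recording, "eeg_recording"))
  out <- lapply(seq_len(nrow(recording$samples)), function(c) {
    f <- bandpass(recording$samples[c, ], recording$fs, spec = fspec)
    ev <- detect_fast_ripples(f, recording$fs, spec = spec,
                              band = c(fspec$low, fspec$high))
    if (nrow(ev)) cbind(channel = recording$channel_names[c], ev)
    else cbind(channel = character(0), ev)
  })
  res <- do.call(rbind, out)
  class(res) <- c("ripple_events", "data.frame")
  res
}

#' Summarize fast-ripple rates per channel and group
#'
#' @param counts numeric vector of event counts, one per channel (or per
#'   channel x animal unit), optionally named.
#' @param minutes recording duration in minutes (scalar or per unit).
#' @param groups group label per unit (e.g. genotype); optional.
#' @return list of class `rate_summary`: `rates` (per-unit events/min) and
#'   `group_summary` (median and linear-interpolation 25th/75th percentiles
#'   per group).
#' @export
summarize_rates <- function(counts, minutes, groups = NULL) {
  if (any(minutes <= 0)) stop("minutes must be positive")
  rates <- counts / minutes
  rates_df <- data.frame(unit = if (!is.null(names(counts))) names(counts)
                                else seq_along(counts),
                         group = if (is.null(groups)) "all" else groups,
                         rate_per_min = rates)
  gs <- do.call(rbind, lapply(split(rates_df$rate_per_min, rates_df$group),
    function(r) data.frame(median = median(r),
                           q25 = unname(quantile(r, 0.25)),
                           q75 = unname(quantile(r, 0.75)),
                           n = length(r))))
  gs <- cbind(group = rownames(gs), gs)
  rownames(gs) <- NULL
  structure(list(rates = rates_df, group_summary = gs),
            class = "rate_summary")
}

#' @export
print.rate_summary <- function(x, ...) {
  cat("fast-ripple rates (events/min):\n")
  print(x$group_summary, row.names = FALSE)
  invisible(x)
}
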