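#' Tapered-cosine (Tukey) window
#'
#' Flat-topped window with cosine tapers over a fraction `alpha` of its
#' length (`alpha = 1` is the Hann window, `alpha = 0` rectangular). Used to
#' shape injected oscillation bursts: the flat top keeps the interior
#' oscillations at the calibrated amplitude while the tapers avoid spectral
#' splatter at the edges.
#'
#' @param n window length in samples.
#' @param alpha total taper fraction in \[0, 1\].
#' @return numeric vector of length `n` in \[0, 1\].
#' @export
tukey_window <- function(n, alpha = 0.5) {
  if (n == 1L) return(1)
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  if (alpha > 0) {
    lo <- t < alpha / 2
    hi <- t > 1 - alpha / 2
    w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
    w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - t[hi]) / alpha - 1)))
  }
  w
}

# 1/f^slope amplitude-shaped Gaussian noise with a flat instrument-noise
# floor above floor_hz, low-passed and scaled to sd.
shaped_noise <- function(n, fs, sd_target, slope, lowpass_hz,
                         floor_hz = 150) {
  x <- rnorm(n)
  if (sd_target == 0) return(numeric(n))
  if (slope > 0) {
    f <- seq(0, fs / 2, length.out = floor(n / 2) + 1L)
    # 1/f^slope between 1 Hz and the noise-floor corner, flat beyond:
    # physiological spectra fall off until the recording chain's white
    # noise floor dominates the high frequencies
    gain <- 1 / pmax(pmin(f, floor_hz), 1)^slope
    X <- fft(x)
    full <- c(gain, rev(gain[2:(n - floor(n / 2))]))
    x <- Re(fft(X * full, inverse = TRUE)) / n
  }
  if (!is.null(lowpass_hz) && lowpass_hz < fs / 2) {
    bf <- signal::butter(4, lowpass_hz / (fs / 2), type = "low")
    x <- signal::filtfilt(bf, x)
  }
  s <- sd(x)
  if (s == 0) return(numeric(n))
  x * (sd_target / s)
}

#' Simulate multichannel EEG with injected oscillation bursts
#'
#' Background is Gaussian noise shaped to a 1/f-like amplitude spectrum and
#' low-passed at the acquisition anti-alias corner, mirroring a 4 kHz
#' epicranial recording chain. Each injected event is a Tukey-windowed
#' sinusoidal burst of `n_cycles`, scaled so that the peak of its band-pass
#' filtered waveform equals `amplitude_ratio` times the standard deviation of
#' the band-pass filtered background of its channel (the detection band of
#' [filter_spec]).
#'
#' @param duration_s trace duration, seconds.
#' @param fs sampling rate, Hz (study default 4000).
#' @param channels number of channels, or a character vector of electrode
#'   labels.
#' @param background list with `sd` (trace standard deviation, microvolts),
#'   `slope` (spectral amplitude exponent; 1 gives a 1/f amplitude spectrum)
#'   and optionally `floor_hz` (corner above which the spectrum is flat,
#'   emulating the recording chain's white noise floor; default 150).
#' @param events data.frame with columns `time_s` (burst onset), `channel`,
#'   `freq_hz`, `n_cycles`, `amplitude_ratio`; `NULL` for none.
#' @param band detection band used for amplitude calibration.
#' @param antialias_lowpass_hz acquisition low-pass corner (metadata and
#'   background shaping), default 2000.
#' @param taper total Tukey taper fraction of each burst.
#' @param seed RNG seed.
#' @return list with `recording` (class `eeg_recording`: `samples` C x N
#'   matrix, `fs`, `channel_names`, `antialias_lowpass`) and `truth`
#'   (data.frame of injected events with sample bounds and calibrated
#'   amplitudes, plus attribute `background_sd_band` per channel).
#' @export
simulate_eeg <- function(duration_s = 60, fs = 4000, channels = 1L,
                         background = list(sd = 20, slope = 1),
                         events = NULL, band = c(200, 550),
                         antialias_lowpass_hz = 2000, taper = 0.5,
                         seed = 1L) {
  if (fs <= 2 * band[2]) stop("sampling rate must exceed twice the band top")
  ch_names <- if (is.character(channels)) channels
              else sprintf("E%02d", seq_len(channels))
  C <- length(ch_names)
  n <- round(duration_s * fs)
  set.seed(check_seed(seed))
  samples <- matrix(0, C, n, dimnames = list(ch_names, NULL))
  floor_hz <- if (is.null(background$floor_hz)) 150 else background$floor_hz
  for (c in seq_len(C))
    samples[c, ] <- shaped_noise(n, fs, background$sd, background$slope,
                                 antialias_lowpass_hz, floor_hz)

  sigma_band <- vapply(seq_len(C), function(c)
    sd(bandpass(samples[c, ], fs, band = band)), numeric(1))
  names(sigma_band) <- ch_names

  truth <- data.frame(channel = character(), time_s = numeric(),
                      freq_hz = numeric(), n_cycles = numeric(),
                      amplitude_ratio = numeric(), start_sample = integer(),
                      end_sample = integer(), amplitude = numeric())
  if (!is.null(events) && nrow(events) > 0) {
    ev <- events
    if (is.numeric(ev$channel)) ev$channel <- ch_names[ev$channel]
    for (i in seq_len(nrow(ev))) {
      f <- ev$freq_hz[i]
      if (f <= 0 || f >= fs / 2) stop("event frequency outside (0, fs/2)")
      len <- round(ev$n_cycles[i] / f * fs)
      s0 <- round(ev$time_s[i] * fs) + 1L
      s1 <- s0 + len - 1L
      if (s1 > n) stop("event extends past trace end")
      tt <- (seq_len(len) - 1) / fs
      burst <- tukey_window(len, taper) * sin(2 * pi * f * tt)
      # calibrate against the filtered background SD of this channel
      pad <- round(0.05 * fs)
      padded <- c(numeric(pad), burst, numeric(pad))
      g <- max(abs(bandpass(padded, fs, band = band)))
      ci <- match(ev$channel[i], ch_names)
      if (is.na(ci)) stop("unknown event channel: ", ev$channel[i])
      sb <- sigma_band[ci]
      amp <- if (sb > 0 && g > 0) ev$amplitude_ratio[i] * sb / g else 1
      prev <- truth[truth$channel == ch_names[ci], , drop = FALSE]
      if (any(pmax(prev$start_sample, s0) <= pmin(prev$end_sample, s1)))
        stop("events overlap on channel ", ch_names[ci])
      samples[ci, s0:s1] <- samples[ci, s0:s1] + amp * burst
      truth <- rbind(truth, data.frame(
        channel = ch_names[ci], time_s = ev$time_s[i], freq_hz = f,
        n_cycles = ev$n_cycles[i], amplitude_ratio = ev$amplitude_ratio[i],
        start_sample = s0, end_sample = s1, amplitude = amp))
    }
  }
  attr(truth, "background_sd_band") <- sigma_band
  recording <- structure(
    list(samples = samples, fs = fs, channel_names = ch_names,
         antialias_lowpass = antialias_lowpass_hz),
    class = "eeg_recording")
  list(recording = recording, truth = truth)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channel(s), %d samples at %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, ncol(x$samples) / x$fs))
  invisible(x)
}
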