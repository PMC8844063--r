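#' Averaged power spectrum of a call (Welch method)
#'
#' Computes the call's power spectrum the way a selection spectrum is built
#' in standard bioacoustic software: the waveform is cut into Hann-windowed
#' segments of `window_len` samples with 50% overlap, each segment's
#' periodogram is taken, and the periodograms are averaged. At 44.1 kHz and
#' the default window the bin width is 44100/512 = 86.13 Hz.
#'
#' @param w a [waveform()].
#' @param window_len analysis window length in samples.
#' @param overlap fractional overlap between successive windows.
#' @return object of class `call_spectrum`: list with `freq` (bin centre
#'   frequencies, Hz, from 0 to Nyquist) and `power` (mean per-bin energy).
#' @export
power_spectrum <- function(w, window_len = 512L, overlap = 0.5) {
  stopifnot(inherits(w, "waveform"))
  x <- w$samples
  n <- length(x)
  if (n < window_len)
    stop("waveform too short: ", n, " samples < window length ", window_len)
  if (all(x == 0)) stop("no energy: waveform is silent")
  hann <- 0.5 - 0.5 * cos(2 * pi * seq_len(window_len) / (window_len + 1))
  hop <- max(1L, as.integer(round(window_len * (1 - overlap))))
  starts <- seq.int(1L, n - window_len + 1L, by = hop)
  nb <- window_len %/% 2L + 1L
  acc <- numeric(nb)
  for (s in starts) {
    seg <- x[s:(s + window_len - 1L)] * hann
    p <- Mod(stats::fft(seg))^2
    acc <- acc + p[seq_len(nb)]
  }
  pw <- acc / length(starts)
  if (sum(pw) <= 0) stop("no energy: spectrum is identically zero")
  structure(list(freq = (seq_len(nb) - 1L) * w$sample_rate / window_len,
                 power = pw,
                 window_len = as.integer(window_len),
                 sample_rate = w$sample_rate),
            class = "call_spectrum")
}

#' Dominant frequency of a spectrum
#'
#' Frequency of the maximum-energy bin, as log10 Hz. Ties are broken toward
#' the lower frequency.
#'
#' @param spectrum a `call_spectrum`.
#' @return dominant frequency, log10 Hz.
#' @export
dominant_frequency <- function(spectrum) {
  stopifnot(inherits(spectrum, "call_spectrum"))
  if (sum(spectrum$power) <= 0) stop("no energy: flat zero spectrum")
  i <- which.max(spectrum$power)  # which.max returns the first (lowest) bin
  f <- spectrum$freq[i]
  if (f <= 0) stop("dominant energy at 0 Hz; not a valid call spectrum")
  log10(f)
}

#' Energy-percentile frequency
#'
#' Smallest bin centre frequency at which the cumulative spectral energy
#' reaches a fraction `q` of the total (right-continuous convention). Used
#' with q = 0.05 and q = 0.95 for the 90% bandwidth endpoints.
#'
#' @param spectrum a `call_spectrum`.
#' @param q energy fraction in (0, 1).
#' @return frequency in log10 Hz.
#' @export
energy_percentile_frequency <- function(spectrum, q) {
  stopifnot(inherits(spectrum, "call_spectrum"))
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1)
    stop("q must be a single fraction in (0, 1)")
  tot <- sum(spectrum$power)
  if (tot <= 0) stop("no energy: flat zero spectrum")
  i <- which(cumsum(spectrum$power) >= q * tot)[1L]
  f <- spectrum$freq[i]
  if (f <= 0) f <- spectrum$freq[2L]  # q met inside the DC bin: report first real bin
  log10(f)
}

#' Smoothed amplitude envelope
#'
#' Rectified waveform smoothed with a centred moving average (default 5 ms).
#' Edge windows shrink symmetrically so the envelope covers the full
#' duration of the input.
#'
#' @param w a [waveform()].
#' @param smooth_ms moving-average width in milliseconds.
#' @return numeric vector, one nonnegative value per input sample.
#' @export
amplitude_envelope <- function(w, smooth_ms = 5) {
  stopifnot(inherits(w, "waveform"))
  x <- abs(w$samples)
  k <- max(1L, as.integer(round(w$sample_rate * smooth_ms / 1000)))
  n <- length(x)
  h <- k %/% 2L
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Duration containing 90% of call energy
#'
#' Time between the instants at which the cumulative energy of the squared
#' envelope passes 5% and 95% of its total.
#'
#' @param envelope nonnegative amplitude envelope (from
#'   [amplitude_envelope()]).
#' @param sample_rate Hz.
#' @return duration in seconds.
#' @export
duration90 <- function(envelope, sample_rate) {
  e <- envelope^2
  tot <- sum(e)
  if (tot <= 0) stop("no energy: envelope is silent")
  cs <- cumsum(e)
  i5 <- which(cs >= 0.05 * tot)[1L]
  i95 <- which(cs >= 0.95 * tot)[1L]
  (i95 - i5) / sample_rate
}

#' Relative position of the amplitude peak within a call
#'
#' @param envelope amplitude envelope.
#' @param bounds integer vector `c(start, end)` of sample indices delimiting
#'   the call within `envelope` (inclusive).
#' @return fraction in \[0, 1\]; ties go to the earliest peak.
#' @export
peak_time_relative <- function(envelope, bounds = c(1L, length(envelope))) {
  start <- bounds[1L]; end <- bounds[2L]
  if (start < 1L || end > length(envelope) || end <= start)
    stop("degenerate call bounds [", start, ", ", end, "]")
  seg <- envelope[start:end]
  (which.max(seg) - 1L) / (end - start)
}

#' Segment a call into notes
#'
#' Notes are the subunits of a call separated by silence: maximal runs of
#' the envelope above a threshold, after merging gaps shorter than
#' `min_gap_s` (brief within-note amplitude dips are not silence).
#'
#' @param envelope amplitude envelope.
#' @param sample_rate Hz.
#' @param silence_threshold absolute envelope threshold; runs above it are
#'   sound, below it silence.
#' @param min_gap_s minimum silence duration (s) that separates two notes.
#' @return data.frame with columns `start`, `end` (sample indices,
#'   inclusive) and `start_s`, `end_s` (seconds); zero rows for silence.
#' @export
segment_notes <- function(envelope, sample_rate, silence_threshold,
                          min_gap_s = 0.010) {
  if (silence_threshold <= 0) stop("silence_threshold must be positive")
  above <- envelope > silence_threshold
  if (!any(above)) {
    return(data.frame(start = integer(), end = integer(),
                      start_s = numeric(), end_s = numeric()))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts, end = ends, on = r$values)
  # merge silent gaps shorter than min_gap_s into the surrounding note
  min_gap <- min_gap_s * sample_rate
  keep_on <- runs$on
  for (i in seq_len(nrow(runs))) {
    if (!runs$on[i] && i > 1L && i < nrow(runs) &&
        runs$end[i] - runs$start[i] + 1L < min_gap) {
      keep_on[i] <- TRUE
    }
  }
  r2 <- rle(keep_on)
  e2 <- cumsum(r2$lengths)
  s2 <- e2 - r2$lengths + 1L
  on2 <- r2$values
  note_start <- runs$start[s2[on2]]
  note_end <- runs$end[e2[on2]]
  # leading/trailing silence merged by accident cannot occur: first/last runs
  # keep their original state unless shorter-than-gap and interior
  data.frame(start = note_start, end = note_end,
             start_s = (note_start - 1L) / sample_rate,
             end_s = note_end / sample_rate)
}

#' Note rate
#'
#' @param notes note table from [segment_notes()] (or an integer count).
#' @param call_duration call duration in seconds.
#' @return notes per second.
#' @export
note_rate <- function(notes, call_duration) {
  if (!is.numeric(call_duration) || call_duration <= 0)
    stop("call_duration must be positive")
  n <- if (is.data.frame(notes)) nrow(notes) else as.integer(notes)
  n / call_duration
}

#' Measure the six call parameters from a single-call waveform
#'
#' Produces the three spectral parameters (5%, 95% and dominant frequency,
#' log10 Hz; Welch spectrum, Hann window of `window_len` samples, 50%
#' overlap) and three temporal parameters (90% energy duration, relative
#' peak time, note rate). Call bounds default to the first-to-last envelope
#' sample above `silence_frac` of the envelope peak; explicit bounds can be
#' supplied for manually isolated calls.
#'
#' All six measurements are ratio- or position-based, so they are invariant
#' to a positive rescaling of the waveform amplitude.
#'
#' @param w a [waveform()].
#' @param species_id identifier attached to the result.
#' @param window_len spectral window length in samples.
#' @param silence_frac note-segmentation threshold as a fraction of the
#'   envelope peak.
#' @param min_gap_ms minimum silent gap (ms) separating notes.
#' @param bounds optional explicit call bounds (sample indices, inclusive).
#' @return a `call_params` object (also a one-row data.frame) with columns
#'   `species_id`, `freq5_log10hz`, `freq95_log10hz`, `domfreq_log10hz`,
#'   `dur90_s`, `peaktime_rel`, `note_rate_hz`.
#' @export
measure_call <- function(w, species_id = NA_character_, window_len = 512L,
                         silence_frac = 0.10, min_gap_ms = 10,
                         bounds = NULL) {
  stopifnot(inherits(w, "waveform"))
  if (all(w$samples == 0)) stop("no energy: waveform is silent")
  env <- amplitude_envelope(w)
  thr <- silence_frac * max(env)
  if (is.null(bounds)) {
    idx <- which(env > thr)
    bounds <- c(idx[1L], idx[length(idx)])
  }
  if (bounds[2L] - bounds[1L] + 1L < window_len)
    stop("isolated call shorter than the spectral window (",
         bounds[2L] - bounds[1L] + 1L, " < ", window_len, " samples)")
  call_w <- waveform(w$samples[bounds[1L]:bounds[2L]], w$sample_rate)
  spec <- power_spectrum(call_w, window_len = window_len)

  freq5 <- energy_percentile_frequency(spec, 0.05)
  freq95 <- energy_percentile_frequency(spec, 0.95)
  dom <- dominant_frequency(spec)
  if (dom < freq5 || dom > freq95) {
    stop(sprintf(paste0("measurement inconsistency for '%s': dominant ",
                        "frequency %.4f outside 90%% band [%.4f, %.4f] ",
                        "(log10 Hz)"), species_id, dom, freq5, freq95))
  }

  call_env <- env[bounds[1L]:bounds[2L]]
  dur90 <- duration90(call_env, w$sample_rate)
  peak <- peak_time_relative(env, bounds)
  notes <- segment_notes(env, w$sample_rate, thr, min_gap_ms / 1000)
  dur_call <- (bounds[2L] - bounds[1L] + 1L) / w$sample_rate
  rate <- note_rate(notes, dur_call)

  out <- data.frame(species_id = species_id,
                    freq5_log10hz = freq5, freq95_log10hz = freq95,
                    domfreq_log10hz = dom, dur90_s = dur90,
                    peaktime_rel = peak, note_rate_hz = rate,
                    stringsAsFactors = FALSE)
  class(out) <- c("call_params", class(out))
  out
}
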