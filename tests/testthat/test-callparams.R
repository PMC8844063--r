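bin_hz <- 44100 / 512  # 86.13 Hz spectral bin at the default window

test_that("power spectrum localises tones and rejects degenerate input", {
  sp <- power_spectrum(tone(1000))
  expect_lt(abs(sp$freq[which.max(sp$power)] - 1000), bin_hz)

  # two-tone: stronger component carries more bin energy, checked against a
  # direct unwindowed DFT at the two component frequencies
  sr <- 44100
  t <- seq_len(sr / 10) / sr
  x <- sin(2 * pi * 1000 * t) + 0.5 * sin(2 * pi * 3000 * t)
  dft_power <- function(f) Mod(sum(x * exp(-2i * pi * f * t)))^2
  expect_gt(dft_power(1000), dft_power(3000))
  sp2 <- power_spectrum(waveform(x, sr))
  b1 <- which.min(abs(sp2$freq - 1000))
  b3 <- which.min(abs(sp2$freq - 3000))
  expect_gt(sp2$power[b1], sp2$power[b3])

  expect_error(power_spectrum(waveform(numeric(44100), 44100)), "no energy")
  expect_error(power_spectrum(waveform(rnorm(100), 44100)), "too short")
})

test_that("dominant frequency picks the max-energy bin, low bin on ties", {
  expect_lt(abs(dominant_frequency(power_spectrum(tone(1000))) - 3),
            log10(1000 + bin_hz) - 3)
  pw <- rep(0.1, 60)
  pw[c(10, 20)] <- 5
  fake <- structure(list(freq = (0:59) * bin_hz, power = pw),
                    class = "call_spectrum")
  expect_equal(dominant_frequency(fake), log10(9 * bin_hz))
})

test_that("energy-percentile frequency follows the cumulative-sum rule and is monotone in q", {
  # uniform energy over bins 1..100 (bin 0 = DC held at zero)
  fake <- structure(list(freq = (0:100) * bin_hz, power = c(0, rep(1, 100))),
                    class = "call_spectrum")
  expect_equal(energy_percentile_frequency(fake, 0.05), log10(5 * bin_hz))
  expect_equal(energy_percentile_frequency(fake, 0.95), log10(95 * bin_hz))

  callspace:::with_seed(7, {
    for (i in 1:50) {
      spec <- structure(list(freq = (0:64) * bin_hz,
                             power = c(0, rexp(64))),
                        class = "call_spectrum")
      qs <- sort(runif(4, 0.01, 0.99))
      vals <- vapply(qs, energy_percentile_frequency, numeric(1),
                     spectrum = spec)
      expect_true(all(diff(vals) >= 0))
    }
  })

  # single tone: the 90% band collapses onto the tone's spectral peak
  # (the Hann main lobe spans a few bins, so allow a 3-bin half-width)
  sp <- power_spectrum(tone(2000))
  f5 <- energy_percentile_frequency(sp, 0.05)
  f95 <- energy_percentile_frequency(sp, 0.95)
  expect_lte(f95 - f5, log10((2000 + 3 * bin_hz) / (2000 - 3 * bin_hz)))
})

test_that("amplitude envelope is flat for tones, zero for silence, monotone for ramps", {
  env <- amplitude_envelope(tone(1000, dur = 0.5))
  core <- env[1000:(length(env) - 1000)]
  expect_lt(stats::sd(core) / mean(core), 0.05)

  expect_true(all(amplitude_envelope(waveform(numeric(1000), 44100)) == 0))

  sr <- 44100
  n <- sr %/% 2
  ramp <- seq(0, 1, length.out = n) * sin(2 * pi * 1000 * seq_len(n) / sr)
  env_r <- amplitude_envelope(waveform(ramp, sr))
  sub <- env_r[seq(500, n - 500, by = 100)]
  expect_gt(stats::cor(sub, seq_along(sub), method = "spearman"), 0.99)
})

test_that("duration90 matches closed forms", {
  sr <- 44100
  expect_equal(duration90(rep(1, sr), sr), 0.9, tolerance = 2 / sr)
  imp <- c(numeric(100), 1, numeric(100))
  expect_lte(duration90(imp, sr), 2 / sr)
  # two 0.1 s bursts at the ends of 1 s: 5% energy instant sits 0.01 s into
  # the first burst, the 95% instant 0.01 s before the end of the second,
  # so the 90% duration spans both bursts: 0.99 - 0.01 = 0.98 s
  two <- c(rep(1, sr / 10), numeric(sr * 8 / 10), rep(1, sr / 10))
  expect_equal(duration90(two, sr), 0.98, tolerance = 0.01)
  expect_error(duration90(numeric(100), sr), "no energy")
})

test_that("peak time is relative, tie-broken earliest, and validates bounds", {
  tri <- c(seq(0, 1, length.out = 501), seq(1, 0, length.out = 501)[-1])
  expect_equal(peak_time_relative(tri), 0.5, tolerance = 1e-3)
  expect_equal(peak_time_relative(seq(1, 0, length.out = 100)), 0)
  env <- c(numeric(750), 1, numeric(249))
  expect_equal(peak_time_relative(env), 0.75, tolerance = 2e-3)
  expect_error(peak_time_relative(tri, c(5, 5)), "degenerate")
})

test_that("note segmentation counts bursts and merges sub-gap dips", {
  sr <- 1000
  burst <- function(len) rep(1, len)
  gap <- function(len) numeric(len)
  env3 <- c(burst(100), gap(50), burst(100), gap(50), burst(100))
  expect_equal(nrow(segment_notes(env3, sr, 0.1)), 3)
  expect_equal(nrow(segment_notes(burst(500), sr, 0.1)), 1)
  # 5 bursts, one inter-burst gap shorter than min_gap -> merged to 4 notes
  env5 <- c(burst(50), gap(30), burst(50), gap(5), burst(50), gap(30),
            burst(50), gap(30), burst(50))
  expect_equal(nrow(segment_notes(env5, sr, 0.1, min_gap_s = 0.010)), 4)
  expect_equal(nrow(segment_notes(gap(200), sr, 0.1)), 0)
})

test_that("note rate divides count by duration", {
  expect_equal(note_rate(5L, 1.0), 5.0)
  expect_equal(note_rate(1L, 2.0), 0.5)
  expect_error(note_rate(3L, 0), "positive")
})

test_that("measure_call recovers generator truth and closed forms", {
  g <- gen_call_audio(synthetic_call_spec(carrier_hz = 2000, n_notes = 5,
                                          note_dur_s = 0.08, gap_s = 0.12))
  cp <- measure_call(g$waveform, "sp")
  expect_lt(abs(10^cp$domfreq_log10hz - 2000), bin_hz)
  expect_lt(abs(cp$note_rate_hz - g$truth$note_rate_hz),
            0.1 * g$truth$note_rate_hz)
  expect_lt(abs(cp$peaktime_rel - g$truth$peaktime_rel), 0.05)

  # pure tone: band collapses to the dominant bin, dur90 ~ 0.9 x duration
  cp2 <- measure_call(tone(1500, dur = 1), "tone")
  expect_lt(cp2$freq95_log10hz - cp2$freq5_log10hz,
            log10((1500 + 3 * bin_hz) / (1500 - 3 * bin_hz)))
  expect_gte(cp2$domfreq_log10hz, cp2$freq5_log10hz)
  expect_lte(cp2$domfreq_log10hz, cp2$freq95_log10hz)
  expect_equal(cp2$dur90_s, 0.9, tolerance = 0.02)

  expect_error(measure_call(waveform(numeric(44100), 44100)), "no energy")
})

test_that("measurement is deterministic and amplitude-scale invariant", {
  g <- callspace:::with_seed(11, gen_call_audio(random_call_spec()))
  a <- measure_call(g$waveform, "x")
  b <- measure_call(g$waveform, "x")
  expect_identical(a, b)
  scaled <- waveform(g$waveform$samples * 3.7, g$waveform$sample_rate)
  d <- measure_call(scaled, "x")
  for (col in c("freq5_log10hz", "freq95_log10hz", "domfreq_log10hz",
                "dur90_s", "peaktime_rel", "note_rate_hz"))
    expect_equal(a[[col]], d[[col]], tolerance = 1e-10)
})
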