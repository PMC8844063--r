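# Fixtures and independent oracles shared across test files.

# deterministic call table with hand-controllable parameters
make_call_table <- function(n = 6, seed = 1) {
  callspace:::with_seed(seed, {
    dom <- rnorm(n, 3.1, 0.3)
    bw <- runif(n, 0.1, 0.3)
    data.frame(
      species_id = sprintf("sp%02d", seq_len(n)),
      freq5_log10hz = dom - bw / 2,
      freq95_log10hz = dom + bw / 2,
      domfreq_log10hz = dom,
      dur90_s = rlnorm(n, log(0.6), 0.5),
      peaktime_rel = rbeta(n, 2, 2),
      note_rate_hz = rlnorm(n, log(8), 0.6),
      stringsAsFactors = FALSE)
  })
}

make_assemblage <- function(id, lat, lon, species, date = "2018-01-15",
                            habitat = "ecoA") {
  list(assemblage_id = id, latitude = lat, longitude = lon,
       date = as.Date(date), habitat = habitat, species = sort(species))
}

# brute-force pairwise-mean oracle: explicit double loop over species pairs
brute_assemblage_similarity <- function(species, table, spaces) {
  rows <- table[match(species, table$species_id), ]
  k <- length(species)
  acc <- c(pca_all = 0, pca_spectral = 0, pca_temporal = 0,
           spectral_overlap = 0, domfreq_distance = 0)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    a <- rows[i, ]; b <- rows[j, ]
    for (m in c("pca_all", "pca_spectral", "pca_temporal")) {
      sc <- spaces[[m]]$scores
      acc[m] <- acc[m] +
        sqrt(sum((sc[a$species_id, ] - sc[b$species_id, ])^2))
    }
    acc["spectral_overlap"] <- acc["spectral_overlap"] +
      brute_overlap(a$freq5_log10hz, a$freq95_log10hz,
                    b$freq5_log10hz, b$freq95_log10hz)
    acc["domfreq_distance"] <- acc["domfreq_distance"] +
      abs(a$domfreq_log10hz - b$domfreq_log10hz)
  }
  acc / choose(k, 2)
}

# interval-intersection oracle for spectral overlap, written independently
brute_overlap <- function(f5a, f95a, f5b, f95b,
                          floor_bw = log10(1 + 86.1328125 / 1000)) {
  lo <- max(f5a, f5b)
  hi <- min(f95a, f95b)
  L <- if (hi > lo) hi - lo else 0
  bwa <- max(f95a - f5a, floor_bw)
  bwb <- max(f95b - f5b, floor_bw)
  min(1, 0.5 * (L / bwa + L / bwb))
}

# tone helper for waveform tests
tone <- function(freq, dur = 1, sr = 44100, amp = 0.8) {
  waveform(amp * sin(2 * pi * freq * seq(0, dur, by = 1 / sr)[-1]), sr)
}
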