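#' Specification of one synthetic call
#'
#' A call is a train of `n_notes` tonal notes (carrier sine, Hann note
#' envelope) at regular spacing, with amplitudes shaped so the note at
#' `peak_note` carries the global amplitude peak. The generating parameters
#' are the measurement ground truth: dominant frequency = carrier, note
#' rate = n_notes / call extent, relative peak time = centre of the peak
#' note.
#'
#' @param carrier_hz carrier (dominant) frequency, Hz; must be below
#'   Nyquist.
#' @param n_notes number of notes (>= 1).
#' @param note_dur_s duration of one note, s.
#' @param gap_s silent gap between consecutive notes, s (must be positive
#'   when n_notes > 1: notes are separated by silence by construction).
#' @param peak_note index (1..n_notes) of the loudest note.
#' @param amplitude peak amplitude in \[0, 1\]; 0 gives a silent waveform.
#' @param fm_hz sinusoidal frequency sweep half-width, Hz (gives the call a
#'   nonzero bandwidth; 0 = pure tone).
#' @return a `call_spec` list.
#' @export
synthetic_call_spec <- function(carrier_hz = 2000, n_notes = 5L,
                                note_dur_s = 0.08, gap_s = 0.12,
                                peak_note = ceiling(n_notes / 2),
                                amplitude = 0.9, fm_hz = 0) {
  if (n_notes > 1L && gap_s <= 0) stop("notes must be separated by silence")
  structure(list(carrier_hz = carrier_hz, n_notes = as.integer(n_notes),
                 note_dur_s = note_dur_s, gap_s = gap_s,
                 peak_note = as.integer(peak_note), amplitude = amplitude,
                 fm_hz = fm_hz),
            class = "call_spec")
}

#' Generate synthetic single-call audio with known ground truth
#'
#' @param spec a [synthetic_call_spec()].
#' @param sample_rate Hz.
#' @return list with `waveform` (a [waveform()]) and `truth` (data.frame:
#'   `domfreq_log10hz`, `note_rate_hz`, `peaktime_rel`, `duration_s`,
#'   `n_notes`).
#' @export
gen_call_audio <- function(spec, sample_rate = 44100L) {
  stopifnot(inherits(spec, "call_spec"))
  if (spec$carrier_hz + spec$fm_hz >= sample_rate / 2 || spec$carrier_hz <= 0)
    stop("carrier (+ sweep) must lie in (0, Nyquist)")
  period <- spec$note_dur_s + spec$gap_s
  extent <- (spec$n_notes - 1L) * period + spec$note_dur_s
  n <- as.integer(round(extent * sample_rate))
  x <- numeric(n)
  nd <- as.integer(round(spec$note_dur_s * sample_rate))
  tt <- (seq_len(nd) - 1L) / sample_rate
  hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nd) - 1L) / (nd - 1L))
  # note amplitudes: unique global maximum at peak_note, floor ~0.6 so the
  # first/last notes stay well above the 10% segmentation threshold
  rel <- abs(seq_len(spec$n_notes) - spec$peak_note)
  amps <- spec$amplitude * (0.6 + 0.4 * (1 - rel / max(1L, spec$n_notes)))
  for (i in seq_len(spec$n_notes)) {
    s0 <- as.integer(round((i - 1L) * period * sample_rate))
    phase <- 2 * pi * spec$carrier_hz * tt
    if (spec$fm_hz > 0) {
      # slow sinusoidal sweep across the note widens the band symmetrically
      phase <- phase + (spec$fm_hz / (pi / spec$note_dur_s)) *
        (1 - cos(pi * tt / spec$note_dur_s))
    }
    note <- amps[i] * hann * sin(phase)
    seg <- s0 + seq_len(nd)
    seg <- seg[seg <= n]
    x[seg] <- x[seg] + note[seq_along(seg)]
  }
  truth <- data.frame(
    domfreq_log10hz = log10(spec$carrier_hz),
    note_rate_hz = spec$n_notes / extent,
    peaktime_rel = ((spec$peak_note - 1L) * period + spec$note_dur_s / 2) /
      extent,
    duration_s = extent,
    n_notes = spec$n_notes)
  list(waveform = waveform(if (spec$amplitude == 0) numeric(n) else x,
                           sample_rate),
       truth = truth)
}

#' Random call specification for recovery experiments
#'
#' Draws a call spec from ranges representative of anuran advertisement
#' calls: carrier 800-6000 Hz, 4-10 notes, note rate 2-12 notes/s, duty
#' cycle 0.25-0.55.
#'
#' @return a [synthetic_call_spec()].
#' @export
random_call_spec <- function() {
  rate <- stats::runif(1, 2, 12)
  duty <- stats::runif(1, 0.25, 0.55)
  n_notes <- sample(4:10, 1)
  synthetic_call_spec(
    carrier_hz = stats::runif(1, 800, 6000),
    n_notes = n_notes,
    note_dur_s = duty / rate,
    gap_s = (1 - duty) / rate,
    peak_note = sample(n_notes, 1),
    amplitude = stats::runif(1, 0.3, 1))
}

#' Scenario configuration for synthetic assemblage datasets
#'
#' Defaults emulate a desk-scale version of a continental citizen-science
#' frog dataset: 30 species whose log10 dominant frequencies are normal
#' with mean 3.1 (≈1.26 kHz) and sd 0.3 (≈500 Hz - 3.2 kHz central range),
#' 500 recording sites in 5 spatial clusters far enough apart that 50 km
#' species pools are cluster-local, and assemblage richness 4 + Poisson(2).
#'
#' @param n_species species in the regional pool.
#' @param n_sites number of assemblages (one per site).
#' @param n_clusters spatial clusters.
#' @param species_per_cluster size of each cluster's local species pool.
#' @param mu_logf,sd_logf mean and sd of log10 dominant frequency.
#' @param bw_mean,bw_sd mean and sd of the log10-scale 90% bandwidth
#'   (truncated below at 0.02).
#' @param richness_lambda Poisson rate of richness above the minimum of 4.
#' @param mode assembly mode: `"random"`, `"repulsion"` or `"attraction"`.
#' @param beta repulsion/attraction strength (>= 0; 0 reduces every mode to
#'   random).
#' @param cluster_radius_deg half-extent of a cluster in degrees (~17 km).
#' @param seed master seed for the generator.
#' @return a `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(n_species = 30L, n_sites = 500L,
                               n_clusters = 5L,
                               species_per_cluster = min(15L, n_species),
                               mu_logf = 3.1, sd_logf = 0.3,
                               bw_mean = 0.20, bw_sd = 0.05,
                               richness_lambda = 2, mode = "random",
                               beta = 0, cluster_radius_deg = 0.15,
                               seed = 1L) {
  mode <- match.arg(mode, c("random", "repulsion", "attraction"))
  if (beta < 0) stop("beta must be >= 0")
  if (species_per_cluster > n_species)
    stop("species_per_cluster cannot exceed n_species")
  structure(as.list(environment()), class = "synthetic_scenario")
}

#' Draw species call-parameter traits
#'
#' log10 dominant frequency ~ Normal(mu_logf, sd_logf); the 90% band is
#' dominant ± half a truncated-normal bandwidth; temporal traits (90%
#' duration, relative peak time, note rate) are drawn independently of the
#' spectral traits, so under a spectral repulsion process the temporal
#' similarity measures act as a built-in negative control.
#'
#' @param scenario a [synthetic_scenario()].
#' @return call-parameter data.frame (schema of [read_call_table()]).
#' @export
gen_species_traits <- function(scenario) {
  n <- scenario$n_species
  dom <- stats::rnorm(n, scenario$mu_logf, scenario$sd_logf)
  bw <- pmax(0.02, stats::rnorm(n, scenario$bw_mean, scenario$bw_sd))
  data.frame(
    species_id = sprintf("sp%03d", seq_len(n)),
    freq5_log10hz = dom - bw / 2,
    freq95_log10hz = dom + bw / 2,
    domfreq_log10hz = dom,
    dur90_s = stats::rlnorm(n, log(0.6), 0.5),
    peaktime_rel = stats::rbeta(n, 2, 2),
    note_rate_hz = stats::rlnorm(n, log(8), 0.6),
    source = "synthetic",
    stringsAsFactors = FALSE)
}

#' Generate clustered site coordinates
#'
#' Cluster centres are placed on a jittered grid over an Australia-like
#' extent (lat -38..-15, lon 116..152) with at least ~500 km separation;
#' sites scatter uniformly within `cluster_radius_deg` of their centre, so
#' every 50 km pool is cluster-local by construction.
#'
#' @param scenario a [synthetic_scenario()].
#' @return data.frame: `site_id`, `latitude`, `longitude`, `cluster`,
#'   `habitat` (one label per cluster).
#' @export
gen_sites <- function(scenario) {
  k <- scenario$n_clusters
  grid <- expand.grid(lat = seq(-36, -17, length.out = ceiling(sqrt(k))),
                      lon = seq(118, 150, length.out = ceiling(sqrt(k))))
  pick <- grid[sample.int(nrow(grid), k), ]
  centres <- data.frame(lat = pick$lat + stats::runif(k, -1, 1),
                        lon = pick$lon + stats::runif(k, -1, 1))
  cl <- rep(seq_len(k), length.out = scenario$n_sites)
  r <- scenario$cluster_radius_deg
  data.frame(
    site_id = sprintf("site%04d", seq_len(scenario$n_sites)),
    latitude = centres$lat[cl] + stats::runif(scenario$n_sites, -r, r),
    longitude = centres$lon[cl] + stats::runif(scenario$n_sites, -r, r),
    cluster = cl,
    habitat = paste0("eco", LETTERS[cl]),
    stringsAsFactors = FALSE)
}

#' Assemble one community from a local pool
#'
#' Sequential construction: the first member is uniform; each subsequent
#' member joins with probability proportional to
#' exp(s * beta * min pairwise dominant-frequency distance to the current
#' members), with s = +1 for repulsion, -1 for attraction and anything at
#' beta = 0 reducing to uniform sampling without replacement — the same law
#' as the null sampler, which guarantees SES calibration at zero under the
#' random mode.
#'
#' @param local_pool character vector of candidate species.
#' @param richness community size (<= pool size).
#' @param mode `"random"`, `"repulsion"` or `"attraction"`.
#' @param beta strength (>= 0).
#' @param domfreq named vector of log10 dominant frequencies covering the
#'   pool (ignored for `mode = "random"`).
#' @return character vector of `richness` species.
#' @export
assemble_community <- function(local_pool, richness, mode = "random",
                               beta = 0, domfreq = NULL) {
  if (richness > length(local_pool))
    stop("richness ", richness, " exceeds pool size ", length(local_pool))
  if (mode == "random" || beta == 0)
    return(sample_null_assemblage(local_pool, richness))
  sgn <- switch(mode, repulsion = 1, attraction = -1,
                stop("unknown mode: ", mode))
  members <- local_pool[sample.int(length(local_pool), 1L)]
  while (length(members) < richness) {
    cand <- setdiff(local_pool, members)
    mind <- vapply(cand, function(s)
      min(abs(domfreq[s] - domfreq[members])), numeric(1))
    lw <- sgn * beta * mind
    w <- exp(lw - max(lw))
    members <- c(members, cand[sample.int(length(cand), 1L, prob = w)])
  }
  members
}

#' Generate a full synthetic assemblage dataset
#'
#' Draws species traits, clustered sites and per-site communities (richness
#' 4 + Poisson, capped at the local pool size) under the scenario's
#' assembly mode, with recording dates uniform over one year. Everything is
#' driven by the scenario seed, so datasets are fully reproducible.
#'
#' @param scenario a [synthetic_scenario()].
#' @return list with `assemblages` (records as read by
#'   [read_assemblages()]), `calls` (call table), `sites`, and `manifest`
#'   (generator configuration and per-assemblage mode/beta).
#' @export
gen_dataset <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  with_seed(scenario$seed, {
    calls <- gen_species_traits(scenario)
    sites <- gen_sites(scenario)
    domfreq <- stats::setNames(calls$domfreq_log10hz, calls$species_id)
    # each cluster hosts a random local pool of species
    pools <- lapply(seq_len(scenario$n_clusters), function(i)
      sort(sample(calls$species_id, scenario$species_per_cluster)))
    dates <- as.Date("2017-11-10") + sample.int(365, scenario$n_sites,
                                                replace = TRUE) - 1L
    assemblages <- vector("list", scenario$n_sites)
    for (i in seq_len(scenario$n_sites)) {
      pool <- pools[[sites$cluster[i]]]
      rich <- min(4L + stats::rpois(1, scenario$richness_lambda),
                  length(pool))
      sp <- assemble_community(pool, rich, scenario$mode, scenario$beta,
                               domfreq)
      assemblages[[i]] <- list(assemblage_id = sites$site_id[i],
                               latitude = sites$latitude[i],
                               longitude = sites$longitude[i],
                               date = dates[i],
                               habitat = sites$habitat[i],
                               species = sort(sp))
    }
    list(assemblages = assemblages, calls = calls, sites = sites,
         manifest = list(scenario = unclass(scenario),
                         n_assemblages = scenario$n_sites,
                         mode = scenario$mode, beta = scenario$beta,
                         seed = scenario$seed))
  })
}
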