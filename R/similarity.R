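#' @title Acoustic similarity between species' calls
#' @name similarity
#' @description
#' Five pairwise measures are supported, each averaged over all unordered
#' species pairs of an assemblage:
#' \itemize{
#'   \item `pca_all`, `pca_spectral`, `pca_temporal`: Euclidean distance in
#'     the first three principal components of a centred-and-scaled PCA on
#'     all six, the three spectral, or the three temporal call parameters;
#'   \item `spectral_overlap`: proportion of overlap between the two
#'     species' 90% log10 frequency bandwidths (a similarity, in \[0, 1\]);
#'   \item `domfreq_distance`: absolute distance between log10 dominant
#'     frequencies.
#' }
NULL

SPECTRAL_PARAMS <- c("freq5_log10hz", "freq95_log10hz", "domfreq_log10hz")
TEMPORAL_PARAMS <- c("dur90_s", "peaktime_rel", "note_rate_hz")
ALL_PARAMS <- c(SPECTRAL_PARAMS, TEMPORAL_PARAMS)

#' The five acoustic-similarity measure names
#' @format character vector of length 5.
#' @export
MEASURES <- c("pca_all", "pca_spectral", "pca_temporal",
              "spectral_overlap", "domfreq_distance")

#' Parameter columns required by a similarity measure
#' @param measure one of `pca_all`, `pca_spectral`, `pca_temporal`,
#'   `spectral_overlap`, `domfreq_distance`.
#' @return character vector of call-table column names.
#' @export
measure_params <- function(measure) {
  switch(match.arg(measure, MEASURES),
         pca_all = ALL_PARAMS,
         pca_spectral = SPECTRAL_PARAMS,
         pca_temporal = TEMPORAL_PARAMS,
         spectral_overlap = c("freq5_log10hz", "freq95_log10hz"),
         domfreq_distance = "domfreq_log10hz")
}

#' Fit a principal-component space over species call parameters
#'
#' Centres and scales the chosen parameter subset over all species with
#' complete values, then fits a PCA and retains the first three components.
#' For the three-parameter subsets this is the full space, so score
#' distances equal standardized-parameter distances. Component signs are
#' fixed by forcing each component's largest-magnitude loading positive, so
#' fits are fully deterministic.
#'
#' @param table call-parameter table (one row per species; see
#'   [read_call_table()]).
#' @param subset `"all"`, `"spectral"` or `"temporal"`.
#' @return a `pc_space`: list with `subset`, `params`, `center`, `scale`,
#'   `loadings` (params x 3), `scores` (species x 3, rownames = species
#'   ids), `explained` (variance fractions for the retained components).
#' @export
fit_pca <- function(table, subset = c("all", "spectral", "temporal")) {
  subset <- match.arg(subset)
  params <- switch(subset, all = ALL_PARAMS, spectral = SPECTRAL_PARAMS,
                   temporal = TEMPORAL_PARAMS)
  ok <- stats::complete.cases(table[, params, drop = FALSE])
  dat <- table[ok, , drop = FALSE]
  if (nrow(dat) < 4L)
    stop("need at least 4 species with complete '", subset,
         "' parameters; have ", nrow(dat))
  x <- as.matrix(dat[, params, drop = FALSE])
  rownames(x) <- dat$species_id
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance parameter(s): ",
         paste(params[sds == 0], collapse = ", "))
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  k <- min(3L, ncol(p$rotation))
  load <- p$rotation[, seq_len(k), drop = FALSE]
  flip <- apply(load, 2L, function(v) sign(v[which.max(abs(v))]))
  load <- sweep(load, 2L, flip, `*`)
  scores <- sweep(p$x[, seq_len(k), drop = FALSE], 2L, flip, `*`)
  structure(list(subset = subset, params = params,
                 center = p$center, scale = p$scale,
                 loadings = load, scores = scores,
                 explained = (p$sdev^2 / sum(p$sdev^2))[seq_len(k)]),
            class = "pc_space")
}

#' Euclidean distance between two species in a PC space
#' @param space a `pc_space` from [fit_pca()].
#' @param a,b species ids scored in `space`.
#' @return nonnegative distance.
#' @export
pc_distance <- function(space, a, b) {
  stopifnot(inherits(space, "pc_space"))
  miss <- setdiff(c(a, b), rownames(space$scores))
  if (length(miss)) stop("species not scored in PC space: ",
                         paste(miss, collapse = ", "))
  sqrt(sum((space$scores[a, ] - space$scores[b, ])^2))
}

#' Spectral overlap between two species' 90% bandwidths
#'
#' Overlap length L = max(0, min(f95) - max(f5)) on the log10 Hz scale;
#' the reported proportion is the mean of the two directed proportions
#' (L / bandwidth_a + L / bandwidth_b) / 2, which is symmetric, lies in
#' \[0, 1\], and equals the intuitive single proportion when the two
#' bandwidths are equal. Bandwidths are floored at `bw_floor` so a
#' degenerate single-bin measurement can never produce a zero denominator.
#'
#' @param f5a,f95a,f5b,f95b bandwidth endpoints, log10 Hz.
#' @param bw_floor minimum bandwidth (log10 Hz); the default is one 86.13 Hz
#'   spectral bin at 1 kHz, log10(1086.13/1000).
#' @return overlap proportion in \[0, 1\].
#' @export
spectral_overlap <- function(f5a, f95a, f5b, f95b,
                             bw_floor = log10(1 + 86.1328125 / 1000)) {
  if (any(is.na(c(f5a, f95a, f5b, f95b))))
    stop("missing bandwidth endpoint")
  bwa <- pmax(f95a - f5a, bw_floor)
  bwb <- pmax(f95b - f5b, bw_floor)
  if (any(bwa <= 0) || any(bwb <= 0))
    stop("non-positive bandwidth after flooring")
  L <- pmax(0, pmin(f95a, f95b) - pmax(f5a, f5b))
  pmin(1, (L / bwa + L / bwb) / 2)
}

#' Dominant-frequency distance between two species
#' @param fa,fb dominant frequencies, log10 Hz.
#' @return absolute distance in log10 Hz.
#' @export
domfreq_distance <- function(fa, fb) {
  if (any(is.na(c(fa, fb)))) stop("missing dominant frequency")
  abs(fa - fb)
}

#' Fit all PC spaces needed for a measure set
#' @param table call-parameter table.
#' @param measures which similarity measures will be computed.
#' @return named list of `pc_space` objects (possibly empty).
#' @export
fit_spaces <- function(table, measures = MEASURES) {
  spaces <- list()
  if ("pca_all" %in% measures) spaces$pca_all <- fit_pca(table, "all")
  if ("pca_spectral" %in% measures)
    spaces$pca_spectral <- fit_pca(table, "spectral")
  if ("pca_temporal" %in% measures)
    spaces$pca_temporal <- fit_pca(table, "temporal")
  spaces
}

#' Precompute pairwise similarity matrices over all species
#'
#' Assemblage-level similarity is a mean over species pairs, so observed and
#' null assemblages alike can be scored from one symmetric species-by-species
#' matrix per measure. This is the workhorse behind the null model: a
#' randomized assemblage costs one submatrix mean instead of a fresh
#' pairwise pass.
#'
#' @param table call-parameter table.
#' @param spaces list from [fit_spaces()].
#' @param measures measures to materialise.
#' @return named list of symmetric matrices with zero diagonals (overlap
#'   diagonal is 1), rownames/colnames = species ids.
#' @export
pairwise_matrices <- function(table, spaces, measures = MEASURES) {
  ids <- table$species_id
  out <- list()
  for (m in intersect(measures, c("pca_all", "pca_spectral", "pca_temporal"))) {
    sc <- spaces[[m]]$scores
    keep <- intersect(ids, rownames(sc))
    out[[m]] <- as.matrix(stats::dist(sc[keep, , drop = FALSE]))
  }
  if ("spectral_overlap" %in% measures) {
    ok <- !is.na(table$freq5_log10hz) & !is.na(table$freq95_log10hz)
    f5 <- table$freq5_log10hz[ok]; f95 <- table$freq95_log10hz[ok]
    n <- sum(ok)
    M <- matrix(spectral_overlap(rep(f5, times = n), rep(f95, times = n),
                                 rep(f5, each = n), rep(f95, each = n)),
                n, n, dimnames = list(ids[ok], ids[ok]))
    out$spectral_overlap <- M
  }
  if ("domfreq_distance" %in% measures) {
    ok <- !is.na(table$domfreq_log10hz)
    d <- table$domfreq_log10hz[ok]
    M <- abs(outer(d, d, `-`))
    dimnames(M) <- list(ids[ok], ids[ok])
    out$domfreq_distance <- M
  }
  out
}

#' Mean pairwise similarity of one assemblage
#'
#' Each measure is the unweighted mean of the pairwise values over all
#' C(n, 2) unordered species pairs.
#'
#' @param species character vector of species ids (n >= 2).
#' @param matrices pairwise matrices from [pairwise_matrices()].
#' @param measures measures to report.
#' @return named numeric vector, one value per measure.
#' @export
assemblage_similarity <- function(species, matrices, measures = names(matrices)) {
  species <- unique(species)
  k <- length(species)
  if (k < 2L) stop("an assemblage needs at least 2 species")
  vapply(measures, function(m) {
    M <- matrices[[m]]
    miss <- setdiff(species, rownames(M))
    if (length(miss))
      stop("species missing '", m, "' parameters: ",
           paste(miss, collapse = ", "))
    sub <- M[species, species]
    # symmetric; diagonal excluded: sum of off-diagonal / (k*(k-1)) is the
    # mean over ordered pairs == mean over unordered pairs
    (sum(sub) - sum(diag(sub))) / (k * (k - 1L))
  }, numeric(1))
}
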