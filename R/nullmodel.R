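#' Great-circle distance between two points
#'
#' Haversine formula on a sphere of radius 6371.0088 km (IUGG mean Earth
#' radius).
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (WGS84 assumed,
#'   longitude east-positive). Vectorised.
#' @return distance in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180))
    stop("invalid coordinates")
  r <- 6371.0088
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

#' Build geographic species pools
#'
#' The species pool of a focal assemblage is the union of the species of
#' every assemblage (including the focal one) whose location lies within
#' `radius_km` (boundary inclusive) of the focal location. `species_filter`
#' restricts the pool to species that can actually be scored by the measure
#' set in use (e.g. species with all six parameters vs dominant frequency
#' only); the focal assemblage is assumed to have already passed that
#' filter.
#'
#' @param assemblages list of assemblage records (see [read_assemblages()]):
#'   each a list with `assemblage_id`, `latitude`, `longitude`, `species`.
#' @param radius_km pool radius (default 50).
#' @param species_filter optional character vector; pooled species are
#'   intersected with it.
#' @return named list (by assemblage id) of lists with `species` (pool) and
#'   `n_extra` (pool size minus focal richness).
#' @export
build_pools <- function(assemblages, radius_km = 50, species_filter = NULL) {
  lat <- vapply(assemblages, `[[`, numeric(1), "latitude")
  lon <- vapply(assemblages, `[[`, numeric(1), "longitude")
  ids <- vapply(assemblages, `[[`, character(1), "assemblage_id")
  sp <- lapply(assemblages, `[[`, "species")
  pools <- vector("list", length(assemblages))
  names(pools) <- ids
  for (i in seq_along(assemblages)) {
    d <- haversine_km(lat[i], lon[i], lat, lon)
    pool <- sort(unique(unlist(sp[d <= radius_km])))
    if (!is.null(species_filter)) {
      pool <- union(intersect(pool, species_filter), sp[[i]])
    }
    pools[[i]] <- list(species = pool,
                       n_extra = length(pool) - length(unique(sp[[i]])))
  }
  pools
}

#' Filter assemblages for a similarity measure set
#'
#' Applies the three dataset filters: minimum richness (default 4 species),
#' full call-parameter coverage for the requested measures, and at least one
#' extra species in the 50 km pool (an assemblage whose pool adds nothing
#' would be identical to its own null). Retention can therefore differ
#' between the dominant-frequency-only analysis and the six-parameter
#' analyses.
#'
#' @param assemblages list of assemblage records.
#' @param table call-parameter table.
#' @param measures similarity measures the retained set must support.
#' @param radius_km pool radius (km).
#' @param min_richness minimum species per assemblage.
#' @return list with `assemblages` (retained records), `pools` (their
#'   pools), and `exclusions` (data.frame `assemblage_id`, `rule`).
#' @export
filter_dataset <- function(assemblages, table, measures = MEASURES,
                           radius_km = 50, min_richness = 4L) {
  params <- unique(unlist(lapply(measures, measure_params)))
  ok_sp <- table$species_id[stats::complete.cases(
    table[, params, drop = FALSE])]

  excl <- list()
  keep1 <- logical(length(assemblages))
  for (i in seq_along(assemblages)) {
    a <- assemblages[[i]]
    if (length(unique(a$species)) < min_richness) {
      excl[[length(excl) + 1L]] <- data.frame(
        assemblage_id = a$assemblage_id, rule = "min_richness")
    } else if (!all(a$species %in% ok_sp)) {
      excl[[length(excl) + 1L]] <- data.frame(
        assemblage_id = a$assemblage_id, rule = "missing_parameters")
    } else keep1[i] <- TRUE
  }
  retained <- assemblages[keep1]

  # pools are built over the parameter-complete retained set so that every
  # null draw can be scored
  pools <- build_pools(retained, radius_km = radius_km,
                       species_filter = ok_sp)
  has_extra <- vapply(pools, function(p) p$n_extra >= 1L, logical(1))
  for (a in retained[!has_extra]) {
    excl[[length(excl) + 1L]] <- data.frame(
      assemblage_id = a$assemblage_id, rule = "no_extra_species_50km")
  }
  list(assemblages = retained[has_extra],
       pools = pools[has_extra],
       exclusions = if (length(excl)) do.call(rbind, excl) else
         data.frame(assemblage_id = character(), rule = character()))
}

#' Draw one random assemblage from a species pool
#'
#' Uniform sampling without replacement of `size` distinct species; with
#' `weighting = "occurrence"` species are weighted by how many assemblages
#' within the pool radius they occur in (weights supplied by the caller).
#'
#' @param pool character vector of pooled species.
#' @param size assemblage richness to match.
#' @param weights optional positive occurrence weights, same length as
#'   `pool` (ignored for uniform sampling).
#' @return character vector of `size` species.
#' @export
sample_null_assemblage <- function(pool, size, weights = NULL) {
  if (size > length(pool))
    stop("pool (", length(pool), ") smaller than assemblage size ", size)
  if (size == length(pool)) return(pool)
  if (is.null(weights)) pool[sample.int(length(pool), size)]
  else pool[sample.int(length(pool), size, prob = weights)]
}

#' Null distribution of assemblage similarity
#'
#' Generates `n_null` random assemblages of the focal richness from the
#' focal pool and scores each with the identical code path used for the
#' observed assemblage.
#'
#' @param focal_species observed species set.
#' @param pool pooled species (superset of `focal_species`).
#' @param matrices pairwise matrices from [pairwise_matrices()].
#' @param measures measures to evaluate.
#' @param n_null number of random assemblages (default 1000).
#' @param weights optional occurrence weights for the pool.
#' @return matrix `n_null` x length(measures) of similarity values.
#' @export
null_distribution <- function(focal_species, pool, matrices,
                              measures = names(matrices), n_null = 1000L,
                              weights = NULL) {
  size <- length(unique(focal_species))
  vals <- matrix(NA_real_, n_null, length(measures),
                 dimnames = list(NULL, measures))
  for (j in seq_len(n_null)) {
    draw <- sample_null_assemblage(pool, size, weights)
    vals[j, ] <- assemblage_similarity(draw, matrices, measures)
  }
  vals
}

#' Standardized effect size with the partitioning sign convention
#'
#' SES = (observed - null mean) / null sd (sample sd, denominator n-1). For
#' `spectral_overlap` the sign is reversed, because overlap is a similarity
#' while the other four measures are distances: after reversal, positive SES
#' always indicates acoustic niche partitioning and negative SES
#' aggregation. A zero null sd yields a degenerate (NA) SES flagged in the
#' output, not an error.
#'
#' @param observed observed similarity value.
#' @param null_values numeric vector of null similarity values.
#' @param measure measure name (controls the sign convention).
#' @return one-row data.frame: `observed`, `null_mean`, `null_sd`, `ses`,
#'   `sign_reversed`, `degenerate`.
#' @export
standardized_effect_size <- function(observed, null_values, measure) {
  m <- mean(null_values)
  s <- stats::sd(null_values)
  rev <- identical(measure, "spectral_overlap")
  ses <- if (s > 0) (if (rev) -1 else 1) * (observed - m) / s else NA_real_
  data.frame(observed = observed, null_mean = m, null_sd = s, ses = ses,
             sign_reversed = rev, degenerate = s <= 0)
}

#' Proportion of assemblages less similar than their null mean
#'
#' Fraction of (non-degenerate) assemblages whose observed value indicates
#' less acoustic similarity than the mean of its null distribution, i.e.
#' observed distance above the null mean, or observed overlap below it —
#' equivalently `mean(ses > 0)`.
#'
#' @param ses_table SES table from [compute_ses()] (or any data.frame with
#'   `measure`, `ses`, `degenerate` columns).
#' @param measure measure to summarise.
#' @return fraction in \[0, 1\].
#' @export
proportion_below_null_mean <- function(ses_table, measure) {
  x <- ses_table[ses_table$measure == measure & !ses_table$degenerate, ]
  if (nrow(x) == 0L) stop("no non-degenerate assemblages for ", measure)
  mean(x$ses > 0)
}

# Deterministic per-assemblage seed: a small polynomial hash of the
# assemblage id folded into the master seed, so SES results are invariant
# to assemblage processing order and reproducible across runs.
child_seed <- function(master_seed, id) {
  h <- 0
  for (b in utf8ToInt(as.character(id))) h <- (h * 131 + b) %% 2147483629
  as.integer((h + as.numeric(master_seed) * 2654435761) %% 2147483629)
}

#' Run the full null-model SES analysis
#'
#' For each measure group (the four measures needing all six parameters,
#' and dominant-frequency distance alone) this filters the dataset, fits
#' the PC spaces over all parameter-complete species, builds 50 km pools,
#' draws `n_null` random assemblages per observed assemblage from its pool
#' (matching richness, uniform without replacement by default), and returns
#' SES per assemblage x measure. Randomness is controlled by one master
#' seed with per-assemblage child streams keyed by assemblage id.
#'
#' @param assemblages list of assemblage records.
#' @param table call-parameter table.
#' @param measures similarity measures to analyse.
#' @param n_null random assemblages per observed assemblage.
#' @param radius_km species-pool radius (km).
#' @param min_richness minimum assemblage richness.
#' @param seed master RNG seed.
#' @param pool_weighting `"uniform"` (default) or `"occurrence"`.
#' @return list with `ses` (data.frame: assemblage_id, measure, observed,
#'   null_mean, null_sd, ses, sign_reversed, degenerate, n_species,
#'   n_extra_50km), `exclusions` (per measure group), and `spaces`.
#' @export
compute_ses <- function(assemblages, table, measures = MEASURES,
                        n_null = 1000L, radius_km = 50, min_richness = 4L,
                        seed = 1L,
                        pool_weighting = c("uniform", "occurrence")) {
  pool_weighting <- match.arg(pool_weighting)
  groups <- list(full = setdiff(measures, "domfreq_distance"),
                 domfreq = intersect(measures, "domfreq_distance"))
  groups <- groups[vapply(groups, length, integer(1)) > 0L]

  spaces <- fit_spaces(table, measures)
  matrices <- pairwise_matrices(table, spaces, measures)

  ses_rows <- list()
  excl <- list()
  for (g in names(groups)) {
    gm <- groups[[g]]
    flt <- filter_dataset(assemblages, table, measures = gm,
                          radius_km = radius_km, min_richness = min_richness)
    if (nrow(flt$exclusions))
      excl[[g]] <- cbind(flt$exclusions, measure_group = g)
    occ <- NULL
    if (pool_weighting == "occurrence") {
      occ <- table(unlist(lapply(flt$assemblages, `[[`, "species")))
    }
    for (i in seq_along(flt$assemblages)) {
      a <- flt$assemblages[[i]]
      pool <- flt$pools[[a$assemblage_id]]
      obs <- assemblage_similarity(a$species, matrices, gm)
      w <- if (is.null(occ)) NULL else as.numeric(occ[pool$species])
      nulls <- with_seed(
        child_seed(seed, paste0(a$assemblage_id, "/", g)),
        null_distribution(a$species, pool$species, matrices, gm,
                          n_null = n_null, weights = w))
      for (m in gm) {
        row <- standardized_effect_size(obs[[m]], nulls[, m], m)
        row <- cbind(assemblage_id = a$assemblage_id, measure = m, row,
                     n_species = length(unique(a$species)),
                     n_extra_50km = pool$n_extra)
        ses_rows[[length(ses_rows) + 1L]] <- row
      }
    }
  }
  if (!length(ses_rows)) stop("no assemblages retained after filtering")
  list(ses = do.call(rbind, c(ses_rows, list(make.row.names = FALSE))),
       exclusions = if (length(excl)) do.call(rbind, c(excl, list(
         make.row.names = FALSE))) else NULL,
       spaces = spaces)
}

# Evaluate expr under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
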