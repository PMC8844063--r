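#' Read an assemblage occurrence table
#'
#' Accepts UTF-8 comma-separated files in either of two dialects,
#' auto-detected from the header:
#' \itemize{
#'   \item long format: one row per assemblage x species, columns
#'     `assemblage_id, latitude, longitude, date, species` (optionally
#'     `habitat`);
#'   \item wide format: one row per assemblage with `species` a
#'     semicolon-separated list.
#' }
#' Duplicate species within an assemblage are deduplicated with a warning;
#' malformed coordinates or dates are reported with their line numbers and
#' collected into one error.
#'
#' @param path CSV path.
#' @return list of assemblage records: each a list with `assemblage_id`,
#'   `latitude`, `longitude`, `date` (Date), `habitat` (or NA), `species`
#'   (character vector).
#' @export
read_assemblages <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  required <- c("assemblage_id", "latitude", "longitude", "date", "species")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  probs <- character()
  lat <- suppressWarnings(as.numeric(df$latitude))
  lon <- suppressWarnings(as.numeric(df$longitude))
  dt <- as.Date(df$date, format = "%Y-%m-%d")
  bad <- which(is.na(lat) | is.na(lon) | abs(lat) > 90 | abs(lon) > 180)
  if (length(bad))
    probs <- c(probs, paste0("line ", bad + 1L, ": unparseable coordinates"))
  badd <- which(is.na(dt))
  if (length(badd))
    probs <- c(probs, paste0("line ", badd + 1L, ": unparseable date"))
  if (length(probs))
    stop("malformed rows in ", path, ":\n  ",
         paste(probs, collapse = "\n  "))

  long <- any(duplicated(df$assemblage_id)) || !any(grepl(";", df$species))
  recs <- lapply(split(seq_len(nrow(df)), df$assemblage_id), function(i) {
    sp <- if (long) df$species[i]
          else strsplit(df$species[i[1L]], ";", fixed = TRUE)[[1L]]
    sp <- trimws(sp)
    if (anyDuplicated(sp)) {
      warning("assemblage ", df$assemblage_id[i[1L]],
              ": duplicate species deduplicated")
      sp <- unique(sp)
    }
    list(assemblage_id = as.character(df$assemblage_id[i[1L]]),
         latitude = lat[i[1L]], longitude = lon[i[1L]],
         date = dt[i[1L]],
         habitat = if ("habitat" %in% names(df)) df$habitat[i[1L]]
                   else NA_character_,
         species = sort(sp))
  })
  unname(recs[order(vapply(recs, `[[`, character(1), "assemblage_id"))])
}

#' Write assemblage records as a long-format CSV
#' @param assemblages list of assemblage records.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_assemblages <- function(assemblages, path) {
  rows <- do.call(rbind, lapply(assemblages, function(a)
    data.frame(assemblage_id = a$assemblage_id, latitude = a$latitude,
               longitude = a$longitude, date = as.character(a$date),
               habitat = if (is.null(a$habitat)) NA_character_ else a$habitat,
               species = a$species, stringsAsFactors = FALSE)))
  utils::write.csv(rows, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a species call-parameter table
#'
#' Requires `species_id` and `domfreq_log10hz`; the other five parameter
#' columns may be absent or NA for dominant-frequency-only species (e.g.
#' literature values). Adds a `complete` flag (all six parameters present)
#' and warns about frequencies outside the plausible 10 Hz - 20 kHz band
#' (log10 1.0-4.3).
#'
#' @param path CSV path.
#' @return data.frame with the parameter columns, `source` (if present) and
#'   `complete`.
#' @export
read_call_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (!"species_id" %in% names(df)) stop("missing required column: species_id")
  if (!"domfreq_log10hz" %in% names(df))
    stop("missing required column: domfreq_log10hz")
  if (anyDuplicated(df$species_id))
    stop("duplicate species_id: ",
         paste(unique(df$species_id[duplicated(df$species_id)]),
               collapse = ", "))
  for (col in ALL_PARAMS) if (!col %in% names(df)) df[[col]] <- NA_real_
  bad <- !is.na(df$freq5_log10hz) & !is.na(df$freq95_log10hz) &
    df$freq5_log10hz >= df$freq95_log10hz
  if (any(bad))
    stop("freq5 >= freq95 for: ", paste(df$species_id[bad], collapse = ", "))
  fr <- c(df$freq5_log10hz, df$freq95_log10hz, df$domfreq_log10hz)
  if (any(!is.na(fr) & (fr < 1.0 | fr > 4.3)))
    warning("frequencies outside the plausible 10 Hz - 20 kHz band; ",
            "check that values are log10 Hz")
  df$complete <- stats::complete.cases(df[, ALL_PARAMS])
  df
}

#' Write a species call-parameter table
#' @param table call-parameter data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_call_table <- function(table, path) {
  cols <- c("species_id", ALL_PARAMS,
            intersect("source", names(table)))
  utils::write.csv(table[, cols], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Pipeline configuration
#'
#' @param calls path to the call-parameter CSV.
#' @param assemblages path to the assemblage CSV.
#' @param out_dir output directory.
#' @param measures similarity measures to analyse.
#' @param radius_km species-pool radius.
#' @param n_null random assemblages per observed assemblage.
#' @param n_boot bootstrap resamples for the mean-SES CI.
#' @param min_richness minimum assemblage richness.
#' @param level CI confidence level.
#' @param seed master seed.
#' @param pool_weighting `"uniform"` or `"occurrence"`.
#' @param lmm `"none"`, `"long"` or `"contrast"`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(calls, assemblages, out_dir,
                            measures = MEASURES, radius_km = 50,
                            n_null = 1000L, n_boot = 10000L,
                            min_richness = 4L, level = 0.95, seed = 1L,
                            pool_weighting = "uniform", lmm = "none") {
  stopifnot(radius_km > 0, n_null >= 1, n_boot >= 1000,
            min_richness >= 2, level > 0, level < 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the end-to-end partitioning analysis
#'
#' filter -> PCA fit -> observed similarity -> null distributions -> SES ->
#' BCa bootstrap summary -> optional mixed model, writing `ses.csv`,
#' `summary.csv`, `exclusions.csv`, optionally `lmm.csv`, and
#' `manifest.json` into the output directory. Fully deterministic under the
#' config seed.
#'
#' @param config a [pipeline_config()].
#' @return list with `ses`, `summary`, `exclusions`, `lmm` (or NULL) and
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  calls <- read_call_table(config$calls)
  assemblages <- read_assemblages(config$assemblages)
  res <- compute_ses(assemblages, calls, measures = config$measures,
                     n_null = config$n_null, radius_km = config$radius_km,
                     min_richness = config$min_richness, seed = config$seed,
                     pool_weighting = config$pool_weighting)
  summ <- summarize_ses(res$ses, n_boot = config$n_boot,
                        level = config$level, seed = config$seed)
  lmm_out <- NULL
  if (config$lmm != "none") {
    lmm_out <- do.call(rbind, lapply(unique(res$ses$measure), function(m) {
      d <- build_lmm_data(res$ses, assemblages, m, form = config$lmm)
      fit <- fit_lmm(d, form = config$lmm)
      cbind(measure = m, fit$coefficients,
            singular = fit$singular)
    }))
  }
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  utils::write.csv(res$ses, file.path(config$out_dir, "ses.csv"),
                   row.names = FALSE)
  utils::write.csv(summ, file.path(config$out_dir, "summary.csv"),
                   row.names = FALSE)
  if (!is.null(res$exclusions))
    utils::write.csv(res$exclusions,
                     file.path(config$out_dir, "exclusions.csv"),
                     row.names = FALSE)
  if (!is.null(lmm_out))
    utils::write.csv(lmm_out, file.path(config$out_dir, "lmm.csv"),
                     row.names = FALSE)
  manifest <- list(
    config = unclass(config),
    version = as.character(utils::packageVersion("callspace")),
    n_assemblages_in = length(assemblages),
    n_ses_rows = nrow(res$ses),
    n_excluded = if (is.null(res$exclusions)) 0L else nrow(res$exclusions),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  list(ses = res$ses, summary = summ, exclusions = res$exclusions,
       lmm = lmm_out, manifest = manifest)
}
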