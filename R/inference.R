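#' Bias-corrected and accelerated (BCa) bootstrap CI of a mean
#'
#' Nonparametric bootstrap of the sample mean with BCa endpoint
#' adjustment. The bias-correction constant is
#' z0 = qnorm(#\{boot means < observed mean\}/B), with bootstrap means
#' exactly equal to the observed mean counted as half (mid-rank). The
#' acceleration constant a comes from the jackknife skewness of the
#' leave-one-out means. The adjusted percentile levels are
#' alpha_k = pnorm(z0 + (z0 + z_k) / (1 - a (z0 + z_k))) for the nominal
#' normal quantiles z_k, and the interval is the corresponding empirical
#' quantiles (type 7) of the bootstrap means.
#'
#' @param values numeric vector (>= 10 finite values).
#' @param n_boot bootstrap resamples (default 10000).
#' @param level confidence level (default 0.95).
#' @param z0,accel optional overrides of the bias-correction and
#'   acceleration constants (used to check that BCa collapses to the plain
#'   percentile interval at z0 = a = 0); `NULL` means estimate them.
#' @return data.frame row: `mean`, `ci_low`, `ci_high`, `n`, `n_boot`,
#'   `level`, `z0`, `accel`, `method`.
#' @export
bca_ci <- function(values, n_boot = 10000L, level = 0.95,
                   z0 = NULL, accel = NULL) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 10L) stop("need at least 10 finite values; have ", n)
  if (n_boot < 1000L) stop("n_boot must be at least 1000")
  obs <- mean(values)
  if (all(values == values[1L])) {
    return(data.frame(mean = obs, ci_low = obs, ci_high = obs, n = n,
                      n_boot = n_boot, level = level, z0 = 0, accel = 0,
                      method = "BCa(degenerate)"))
  }
  idx <- sample.int(n, n * n_boot, replace = TRUE)
  boot_means <- colMeans(matrix(values[idx], nrow = n, ncol = n_boot))

  if (is.null(z0)) {
    p0 <- (sum(boot_means < obs) + 0.5 * sum(boot_means == obs)) / n_boot
    p0 <- min(max(p0, 0.5 / n_boot), 1 - 0.5 / n_boot)
    z0 <- stats::qnorm(p0)
  }
  if (is.null(accel)) {
    loo <- (sum(values) - values) / (n - 1)   # leave-one-out means
    dm <- mean(loo) - loo
    accel <- sum(dm^3) / (6 * sum(dm^2)^1.5)
  }
  zl <- stats::qnorm((1 - level) / 2)
  zu <- -zl
  a1 <- stats::pnorm(z0 + (z0 + zl) / (1 - accel * (z0 + zl)))
  a2 <- stats::pnorm(z0 + (z0 + zu) / (1 - accel * (z0 + zu)))
  ci <- stats::quantile(boot_means, c(a1, a2), names = FALSE, type = 7)
  if (ci[1L] > obs || ci[2L] < obs)
    warning("BCa interval does not contain the sample mean ",
            "(extreme skew); endpoints reported as computed")
  data.frame(mean = obs, ci_low = ci[1L], ci_high = ci[2L], n = n,
             n_boot = n_boot, level = level, z0 = z0, accel = accel,
             method = "BCa")
}

#' Classify a mean-SES confidence interval
#'
#' `partitioned` when the whole interval is above 0 (assemblages less
#' acoustically similar than chance), `aggregated` when below 0,
#' `indistinct` when the interval contains 0.
#'
#' @param ci a row from [bca_ci()] (needs `ci_low`, `ci_high`).
#' @return one of `"partitioned"`, `"aggregated"`, `"indistinct"`.
#' @export
ses_significance <- function(ci) {
  if (ci$ci_low > 0) "partitioned"
  else if (ci$ci_high < 0) "aggregated"
  else "indistinct"
}

#' Summarise SES across assemblages, per measure
#'
#' Mean SES with a BCa bootstrap CI, the proportion of assemblages less
#' similar than their null expectation, and the partitioning verdict.
#'
#' @param ses_table SES table from [compute_ses()].
#' @param n_boot bootstrap resamples.
#' @param level confidence level.
#' @param seed RNG seed for the bootstrap (per-measure child streams).
#' @return data.frame, one row per measure: `measure`, `mean_ses`,
#'   `ci_low`, `ci_high`, `n`, `prop_below_null_mean`, `verdict`.
#' @export
summarize_ses <- function(ses_table, n_boot = 10000L, level = 0.95,
                          seed = 1L) {
  out <- lapply(unique(ses_table$measure), function(m) {
    x <- ses_table[ses_table$measure == m & !ses_table$degenerate, "ses"]
    ci <- with_seed(child_seed(seed, paste0("boot/", m)),
                    bca_ci(x, n_boot = n_boot, level = level))
    data.frame(measure = m, mean_ses = ci$mean, ci_low = ci$ci_low,
               ci_high = ci$ci_high, n = ci$n,
               prop_below_null_mean = proportion_below_null_mean(ses_table, m),
               verdict = ses_significance(ci))
  })
  do.call(rbind, out)
}

#' Assemble data for the observed-vs-null mixed model
#'
#' Two response forms are offered, both per measure:
#' \itemize{
#'   \item `"long"`: one row per assemblage for the observed value and one
#'     for the per-assemblage null mean (a single null summary row avoids
#'     pseudo-replicating the 1,000 draws), with indicator `type` in
#'     \{null, observed\};
#'   \item `"contrast"`: one row per assemblage, response = observed minus
#'     null mean (distances) or null mean minus observed (overlap), so a
#'     positive contrast always means partitioning.
#' }
#'
#' @param ses_table SES table from [compute_ses()].
#' @param assemblages assemblage records (for date/habitat metadata).
#' @param measure measure to model.
#' @param form `"long"` or `"contrast"`.
#' @return data.frame ready for [fit_lmm()].
#' @export
build_lmm_data <- function(ses_table, assemblages, measure,
                           form = c("long", "contrast")) {
  form <- match.arg(form)
  x <- ses_table[ses_table$measure == measure & !ses_table$degenerate, ]
  if (nrow(x) == 0L) stop("no rows for measure ", measure)
  meta <- do.call(rbind, lapply(assemblages, function(a) data.frame(
    assemblage_id = a$assemblage_id,
    date = as.character(a$date),
    month = format(as.Date(a$date), "%Y-%m"),
    habitat = if (is.null(a$habitat) || is.na(a$habitat)) "unknown"
              else a$habitat)))
  x <- merge(x, meta, by = "assemblage_id")
  if (form == "long") {
    long <- rbind(
      data.frame(x[c("assemblage_id", "n_species", "n_extra_50km",
                     "date", "month", "habitat")],
                 type = "null", value = x$null_mean),
      data.frame(x[c("assemblage_id", "n_species", "n_extra_50km",
                     "date", "month", "habitat")],
                 type = "observed", value = x$observed))
    long$type <- factor(long$type, levels = c("null", "observed"))
    long
  } else {
    sgn <- if (identical(measure, "spectral_overlap")) -1 else 1
    data.frame(x[c("assemblage_id", "n_species", "n_extra_50km",
                   "date", "month", "habitat")],
               value = sgn * (x$observed - x$null_mean))
  }
}

#' Fit the covariate linear mixed-effects model
#'
#' Long form: `value ~ type * (n_species + n_extra_50km)` with random
#' intercepts for habitat, month, date and assemblage; the `type` contrast
#' (observed vs null) and its interactions with richness and pool surplus
#' are the quantities of interest. Contrast form: `value ~ n_species +
#' n_extra_50km` with habitat/month/date random intercepts. Fitting is
#' delegated to `lmerTest::lmer` (REML, Satterthwaite p-values); this
#' function contributes the model specification, covariate centring and a
#' structured report.
#'
#' @param data data.frame from [build_lmm_data()].
#' @param form `"long"` or `"contrast"` (must match the data).
#' @return list with `coefficients` (data.frame: term, estimate, se, df,
#'   t, p), `varcor` (random-effect variances), `singular` (logical),
#'   `messages` (convergence messages), `model` (the fitted object).
#' @export
fit_lmm <- function(data, form = c("long", "contrast")) {
  form <- match.arg(form)
  groupings <- if (form == "long")
    c("habitat", "month", "date", "assemblage_id")
  else c("habitat", "month", "date")
  # a grouping with one observation per level carries no estimable variance
  # (it is confounded with the residual): warn and drop it from the model
  degenerate <- vapply(groupings, function(v)
    all(!duplicated(data[[v]])), logical(1))
  if (any(degenerate))
    warning("random-effect grouping(s) with all-singleton groups dropped: ",
            paste(groupings[degenerate], collapse = ", "))
  groupings <- groupings[!degenerate]
  data$n_species_c <- data$n_species - mean(data$n_species)
  data$n_extra_c <- data$n_extra_50km - mean(data$n_extra_50km)
  fixed <- if (form == "long") "value ~ type * (n_species_c + n_extra_c)"
           else "value ~ n_species_c + n_extra_c"
  if (!length(groupings))
    stop("no usable random-effect grouping factors in the data")
  fml <- stats::as.formula(paste(
    fixed, "+", paste(sprintf("(1 | %s)", groupings), collapse = " + ")))
  msgs <- character()
  fit <- withCallingHandlers(
    lmerTest::lmer(fml, data = data, REML = TRUE),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    })
  co <- as.data.frame(stats::coef(summary(fit)))
  coefs <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                      se = co[, "Std. Error"], df = co[, "df"],
                      t = co[, "t value"], p = co[, "Pr(>|t|)"],
                      row.names = NULL)
  vc <- as.data.frame(lme4::VarCorr(fit))
  list(coefficients = coefs,
       varcor = data.frame(group = vc$grp, variance = vc$vcov),
       singular = lme4::isSingular(fit),
       messages = msgs,
       model = fit)
}
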