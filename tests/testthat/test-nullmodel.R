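test_that("haversine distance matches the spherical closed form and geosphere", {
  expect_equal(haversine_km(0, 0, 1, 0), 111.195, tolerance = 1e-4)
  expect_equal(haversine_km(-20, 140, -20, 140), 0)
  callspace:::with_seed(2, {
    p <- matrix(c(runif(20, -60, 60), runif(20, -180, 180)), ncol = 2)
    for (i in 1:10) {
      a <- p[i, ]; b <- p[i + 10, ]
      expect_equal(haversine_km(a[1], a[2], b[1], b[2]),
                   haversine_km(b[1], b[2], a[1], a[2]))
      expect_equal(
        haversine_km(a[1], a[2], b[1], b[2]),
        geosphere::distHaversine(c(a[2], a[1]), c(b[2], b[1]),
                                 r = 6371008.8) / 1000,
        tolerance = 1e-9)
    }
  })
  expect_error(haversine_km(95, 0, 0, 0), "invalid")
})

test_that("pools are radius-inclusive unions over nearby assemblages", {
  a1 <- make_assemblage("a1", -20, 140, c("A", "B", "C", "D"))
  a2 <- make_assemblage("a2", -20, 140, c("C", "D", "E"))
  far <- make_assemblage("far", -30, 150, c("X", "Y", "Z", "W"))
  pools <- build_pools(list(a1, a2, far))
  expect_setequal(pools$a1$species, c("A", "B", "C", "D", "E"))
  expect_equal(pools$a1$n_extra, 1)
  expect_setequal(pools$far$species, c("W", "X", "Y", "Z"))
  expect_equal(pools$far$n_extra, 0)

  # boundary rule: an assemblage at exactly the radius is included
  d <- haversine_km(-20, 140, -20.45, 140)
  a3 <- make_assemblage("a3", -20.45, 140, c("Q", "R"))
  pools2 <- build_pools(list(a1, a3), radius_km = d)
  expect_true(all(c("Q", "R") %in% pools2$a1$species))
})

test_that("dataset filtering applies richness, parameter and pool rules", {
  tab <- make_call_table(8, seed = 1)
  tab[8, c("freq5_log10hz", "freq95_log10hz", "dur90_s", "peaktime_rel",
           "note_rate_hz")] <- NA  # sp08: dominant frequency only
  good <- make_assemblage("good", -20, 140, c("sp01", "sp02", "sp03", "sp04"))
  buddy <- make_assemblage("buddy", -20.1, 140, c("sp03", "sp04", "sp05", "sp06"))
  small <- make_assemblage("small", -20, 140, c("sp01", "sp02", "sp03"))
  domonly <- make_assemblage("domonly", -20.05, 140,
                             c("sp05", "sp06", "sp07", "sp08"))
  lonely <- make_assemblage("lonely", -35, 115, c("sp01", "sp02", "sp05", "sp06"))
  all_a <- list(good, buddy, small, domonly, lonely)

  full <- filter_dataset(all_a, tab, measures = setdiff(MEASURES, "domfreq_distance"))
  ids <- vapply(full$assemblages, `[[`, character(1), "assemblage_id")
  expect_setequal(ids, c("good", "buddy"))
  expect_setequal(full$exclusions$rule[full$exclusions$assemblage_id == "small"],
                  "min_richness")
  expect_setequal(full$exclusions$rule[full$exclusions$assemblage_id == "domonly"],
                  "missing_parameters")
  expect_setequal(full$exclusions$rule[full$exclusions$assemblage_id == "lonely"],
                  "no_extra_species_50km")

  # dominant-frequency-only analysis retains the literature-value assemblage
  dom <- filter_dataset(all_a, tab, measures = "domfreq_distance")
  idsd <- vapply(dom$assemblages, `[[`, character(1), "assemblage_id")
  expect_true("domonly" %in% idsd)
  expect_gt(length(idsd), length(ids))
})

test_that("null sampling is uniform without replacement and seed-stable", {
  pool <- LETTERS[1:5]
  expect_setequal(sample_null_assemblage(pool, 5), pool)
  expect_error(sample_null_assemblage(pool, 6), "smaller")

  draws <- callspace:::with_seed(8, replicate(10000, sample_null_assemblage(pool, 4)))
  freq <- table(draws) / 10000
  expect_true(all(abs(freq - 0.8) < 0.02))  # hypergeometric expectation 4/5

  s1 <- callspace:::with_seed(5, replicate(20, sample_null_assemblage(pool, 3)))
  s2 <- callspace:::with_seed(5, replicate(20, sample_null_assemblage(pool, 3)))
  expect_identical(s1, s2)
})

test_that("standardized effect size follows the sign convention and handles sd = 0", {
  r <- standardized_effect_size(4, c(1, 2, 3), "domfreq_distance")
  expect_equal(r$ses, 2)          # (4 - 2) / sd({1,2,3}) with sd = 1
  expect_false(r$sign_reversed)
  ro <- standardized_effect_size(4, c(1, 2, 3), "spectral_overlap")
  expect_equal(ro$ses, -2)
  expect_true(ro$sign_reversed)
  expect_equal(standardized_effect_size(2, c(1, 2, 3), "pca_all")$ses, 0)
  deg <- standardized_effect_size(1, c(1, 1, 1), "pca_all")
  expect_true(deg$degenerate)
  expect_true(is.na(deg$ses))
})

test_that("proportion below null mean counts positive-SES assemblages", {
  tab <- data.frame(measure = "pca_all", ses = c(1, 2, -1, 0.5),
                    degenerate = FALSE)
  expect_equal(proportion_below_null_mean(tab, "pca_all"), 0.75)
  expect_equal(proportion_below_null_mean(tab, "pca_all"),
               mean(tab$ses > 0))
  expect_error(proportion_below_null_mean(tab, "pca_temporal"), "no non-degenerate")
})

test_that("degenerate pools reproduce the observed value with zero spread", {
  tab <- make_call_table(4, seed = 3)
  spaces <- fit_spaces(tab)
  mats <- pairwise_matrices(tab, spaces)
  focal <- tab$species_id
  nulls <- null_distribution(focal, focal, mats, n_null = 50)
  obs <- assemblage_similarity(focal, mats)
  for (m in colnames(nulls)) {
    expect_true(all(nulls[, m] == obs[[m]]))
    expect_equal(stats::sd(nulls[, m]), 0)
  }
})

test_that("Monte-Carlo null moments converge to exact enumeration on a small pool", {
  tab <- make_call_table(6, seed = 13)
  spaces <- fit_spaces(tab)
  mats <- pairwise_matrices(tab, spaces)
  pool <- tab$species_id
  size <- 4L
  combos <- utils::combn(pool, size, simplify = FALSE)
  exact <- sapply(combos, function(cc) assemblage_similarity(cc, mats))
  n_null <- 2000L
  nulls <- callspace:::with_seed(21,
    null_distribution(pool[1:size], pool, mats, n_null = n_null))
  for (m in rownames(exact)) {
    mu <- mean(exact[m, ])
    s <- sqrt(mean((exact[m, ] - mu)^2))  # population sd over compositions
    se_mean <- s / sqrt(n_null)
    expect_lt(abs(mean(nulls[, m]) - mu), 3 * se_mean + 1e-12)
    se_sd <- s / sqrt(2 * (n_null - 1))   # normal-theory SE of the sd
    expect_lt(abs(stats::sd(nulls[, m]) - s), 4 * se_sd + 1e-12)
  }
})

test_that("compute_ses is reproducible and order-invariant under one master seed", {
  d <- gen_dataset(synthetic_scenario(n_sites = 12, n_clusters = 2,
                                      n_species = 12, species_per_cluster = 8,
                                      seed = 4))
  r1 <- compute_ses(d$assemblages, d$calls, n_null = 50, seed = 99)
  r2 <- compute_ses(d$assemblages, d$calls, n_null = 50, seed = 99)
  expect_identical(r1$ses, r2$ses)
  # reversed processing order must give identical SES per assemblage
  r3 <- compute_ses(rev(d$assemblages), d$calls, n_null = 50, seed = 99)
  k1 <- r1$ses[order(r1$ses$assemblage_id, r1$ses$measure), ]
  k3 <- r3$ses[order(r3$ses$assemblage_id, r3$ses$measure), ]
  rownames(k1) <- rownames(k3) <- NULL
  expect_equal(k1, k3)
})
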