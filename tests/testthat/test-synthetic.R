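test_that("generators are pure functions of the seed", {
  a <- simulate_community(n_sites = 5, plots_per_site = 2, n_otus = 50,
                          depth = 500, seed = 3)
  b <- simulate_community(n_sites = 5, plots_per_site = 2, n_otus = 50,
                          depth = 500, seed = 3)
  expect_identical(a$otu$counts, b$otu$counts)
  expect_identical(a$frame, b$frame)
  c1 <- simulate_geochip(n_sites = 2, plots_per_site = 5, n_probes = 20,
                         seed = 4)
  c2 <- simulate_geochip(n_sites = 2, plots_per_site = 5, n_probes = 20,
                         seed = 4)
  expect_identical(c1$intensities, c2$intensities)
})

test_that("similarity-level decay simulation hits its target exactly without noise", {
  sim <- simulate_pairwise_decay(z_true = 0.2, n_sites = 15, seed = 2)
  expect_equal(fit_distance_decay(sim$geo, sim$similarity)$z, 0.2,
               tolerance = 1e-12)
  flat <- simulate_pairwise_decay(z_true = 0, n_sites = 10, seed = 2)
  off <- flat$similarity[upper.tri(flat$similarity)]
  expect_equal(stats::sd(off), 0)
  expect_error(simulate_pairwise_decay(z_true = 0, c0 = 1.5, n_sites = 6,
                                       seed = 1), "truncated")
  expect_error(simulate_pairwise_decay(z_true = -0.1), ">= 0")
})

test_that("count-level turnover is monotone in the turnover rate", {
  z_at <- function(rate, seed) {
    com <- simulate_community(n_sites = 8, plots_per_site = 2, n_otus = 300,
                              depth = 2000, turnover_rate = rate,
                              phylum_multipliers = c(P = 1), seed = seed)
    fit_distance_decay(haversine_matrix(com$frame),
                       bray_curtis(com$otu))$z
  }
  wins <- sum(vapply(1:20, function(s) z_at(2, s) > z_at(1, s), logical(1)))
  expect_gte(wins, 18)
})

test_that("zero turnover gives near-zero realised decay", {
  com <- simulate_community(n_sites = 8, plots_per_site = 2, n_otus = 300,
                            depth = 2000, turnover_rate = 0,
                            phylum_multipliers = c(P = 1), seed = 5)
  z <- fit_distance_decay(haversine_matrix(com$frame),
                          bray_curtis(com$otu))$z
  expect_lt(abs(z), 0.01)
})

test_that("per-phylum multipliers order the realised per-phylum exponents", {
  z_pair <- function(seed) {
    com <- simulate_community(n_sites = 8, plots_per_site = 2, n_otus = 400,
                              depth = 3000, turnover_rate = 2,
                              phylum_multipliers = c(Fast = 2, Slow = 1),
                              seed = seed)
    geo <- haversine_matrix(com$frame)
    vapply(c("Fast", "Slow"), function(p) {
      fit_distance_decay(geo, bray_curtis(subset_by_phylum(com$otu, p)))$z
    }, numeric(1))
  }
  wins <- sum(vapply(1:20, function(s) {
    z <- z_pair(s); z["Fast"] > z["Slow"]
  }, logical(1)))
  expect_gte(wins, 19)
})

test_that("convergent functional profiles show no site signal; divergent ones do", {
  site_p <- function(site_effect_sd, seed) {
    sig <- simulate_geochip(n_sites = 4, plots_per_site = 10, n_probes = 54,
                            site_effect_sd = site_effect_sd, seed = seed)
    prof <- suppressWarnings(function_profile_pipeline(sig,
                                                       log_transform = TRUE))
    pm <- profile_matrix(prof)
    pm <- pm[, apply(pm, 2, stats::sd) > 0, drop = FALSE]
    resp <- dist_matrix(as.matrix(stats::dist(scale(pm))),
                        "scalar-difference")
    site <- prof$site_id
    ind <- outer(site, site, "!=") * 1
    dimnames(ind) <- list(prof$sample_id, prof$sample_id)
    mrm(resp, list(site = dist_matrix(ind, "scalar-difference")),
        n_permutations = 99, seed = seed)$p_r_squared
  }
  p_conv <- vapply(1:30, function(s) site_p(0, s), numeric(1))
  expect_gte(mean(p_conv > 0.05), 0.9)
  p_div <- vapply(1:30, function(s) site_p(1, s), numeric(1))
  expect_gte(mean(p_div <= 0.05), 0.9)
})

test_that("geochip generator degenerates to identical profiles without noise terms", {
  sig <- simulate_geochip(n_sites = 2, plots_per_site = 3, n_probes = 36,
                          scaling_sd = 0, dropout = 0, noise_sd = 0,
                          site_effect_sd = 0, seed = 6)
  prof <- suppressWarnings(category_sums(sig))
  pm <- profile_matrix(prof)
  expect_lt(max(apply(pm, 2, stats::sd)), 1e-9)
})

test_that("environment factor 1 tracks latitude at low noise", {
  frame <- simulate_design(n_sites = 15, plots_per_site = 2, seed = 11)
  env <- simulate_environment(frame, n_factors = 2, noise_sd = 0.05,
                              seed = 11)
  fac <- attr(env, "factors")
  expect_gt(abs(stats::cor(fac[, 1], env$latitude)), 0.9)
  pca <- ord_pca(env[sprintf("bio%02d", 1:19)], log_transform = TRUE)
  expect_gt(abs(stats::cor(pca$sample_scores[, 1], env$latitude)), 0.9)
})

test_that("the study preset emits a full consistent triple quickly", {
  t0 <- Sys.time()
  st <- simulate_study(seed = 2)
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  expect_lt(elapsed, 60)
  expect_equal(dim(st$otu), c(240L, 2000L))
  expect_equal(nrow(st$frame), 240)
  expect_equal(ncol(st$signals$intensities), 540)
  expect_setequal(sample_ids(st$otu), st$frame$sample_id)
  expect_setequal(sample_ids(st$signals), st$frame$sample_id)
  expect_true(all(c("pH", "bio01", "plant_shannon") %in% names(st$frame)))
  # writes in the formats the readers accept
  dir <- withr::local_tempdir()
  write_study(st, dir)
  back <- read_otu_table(file.path(dir, "otu.tsv"))
  expect_identical(back$counts, st$otu$counts)
  frame_back <- read_sample_frame(file.path(dir, "samples.tsv"))
  expect_equal(nrow(frame_back), 240)
})
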