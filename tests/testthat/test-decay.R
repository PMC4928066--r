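test_that("noiseless power-law similarities are recovered exactly", {
  # closed-form check on three distances, S = d^-0.2
  d <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  d["a", "b"] <- d["b", "a"] <- 10
  d["a", "c"] <- d["c", "a"] <- 100
  d["b", "c"] <- d["c", "b"] <- 1000
  geo <- dist_matrix(d, "geographic-km")
  s <- unclass(geo)
  s[s > 0] <- s[s > 0]^(-0.2)
  fit <- fit_distance_decay(geo, s)
  expect_equal(fit$slope, -0.2, tolerance = 1e-12)
  expect_equal(fit$z, 0.1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_identical(fit$z, -fit$slope / 2)

  s2 <- unclass(geo)
  s2[s2 > 0] <- 0.5 * s2[s2 > 0]^(-0.23)
  expect_equal(fit_distance_decay(geo, s2)$z, 0.115, tolerance = 1e-12)

  flat <- unclass(geo)
  flat[flat > 0] <- 0.4
  expect_equal(fit_distance_decay(geo, flat)$z, 0, tolerance = 1e-12)
})

test_that("Bray-Curtis community matrices are converted to similarity before the fit", {
  sim <- simulate_pairwise_decay(z_true = 0.2, n_sites = 10, seed = 5)
  bc_like <- dist_matrix(1 - sim$similarity - diag(diag(1 - sim$similarity)),
                         "bray-curtis")
  f1 <- fit_distance_decay(sim$geo, sim$similarity)
  f2 <- fit_distance_decay(sim$geo, bc_like)
  expect_equal(f1$z, f2$z, tolerance = 1e-10)
})

test_that("pairs with nonpositive similarity or zero distance are dropped and counted", {
  sim <- simulate_pairwise_decay(z_true = 0.1, n_sites = 8, seed = 2)
  s <- sim$similarity
  s["S01P01", "S02P01"] <- s["S02P01", "S01P01"] <- 0   # unusable pair
  fit <- fit_distance_decay(sim$geo, s)
  expect_equal(fit$n_dropped, 1)
  expect_equal(fit$n_pairs, choose(8, 2) - 1)

  expect_error(fit_distance_decay(sim$geo[1:2, 1:2], s[1:2, 1:2]),
               "fewer than 3")
  eq <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(eq) <- 0
  expect_error(fit_distance_decay(dist_matrix(eq, "geographic-km"),
                                  0.5 * eq), "equal")
})

test_that("slope and z are invariant to rescaling all distances", {
  sim <- simulate_pairwise_decay(z_true = 0.15, noise_sd = 0.1,
                                 n_sites = 12, seed = 8)
  f1 <- fit_distance_decay(sim$geo, sim$similarity)
  scaled <- dist_matrix(unclass(sim$geo) * 7.3, "geographic-km")
  f2 <- fit_distance_decay(scaled, sim$similarity)
  expect_equal(f2$slope, f1$slope, tolerance = 1e-10)
  expect_equal(f2$z, f1$z, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(f2$intercept, f1$intercept)))
})

test_that("bootstrap test flags the degenerate zero-variance case", {
  sim <- simulate_pairwise_decay(z_true = 0.1, n_sites = 6, seed = 3)
  # constant log-log relation: every pair resample gives the same slope
  b <- bootstrap_decay_test(sim$geo, sim$similarity, n_boot = 50, seed = 1)
  expect_true(b$degenerate)
  expect_true(is.infinite(b$t_statistic))
  expect_equal(b$p_value, 1 / 51)
})

test_that("bootstrap test is deterministic given seed and detects strong decay", {
  sim <- simulate_pairwise_decay(z_true = 0.2, noise_sd = 0.15,
                                 n_sites = 15, seed = 4)
  b1 <- bootstrap_decay_test(sim$geo, sim$similarity, n_boot = 199, seed = 7)
  b2 <- bootstrap_decay_test(sim$geo, sim$similarity, n_boot = 199, seed = 7)
  expect_identical(b1$t_statistic, b2$t_statistic)
  expect_false(b1$degenerate)
  expect_lt(b1$p_value, 0.001)
  expect_lt(b1$t_statistic, 0)
})

test_that("reported |t| grows as sqrt(n_boot) while the ratio stays stable", {
  sim <- simulate_pairwise_decay(z_true = 0.2, noise_sd = 0.2,
                                 n_sites = 12, seed = 6)
  b_small <- bootstrap_decay_test(sim$geo, sim$similarity, n_boot = 200,
                                  seed = 5)
  b_large <- bootstrap_decay_test(sim$geo, sim$similarity, n_boot = 800,
                                  seed = 5)
  expect_equal(abs(b_large$t_statistic) / abs(b_small$t_statistic), 2,
               tolerance = 0.3)
  expect_equal(b_large$ratio / b_small$ratio, 1, tolerance = 0.3)
})

test_that("null rejection rate of the scale-free ratio is near nominal", {
  hits <- 0L
  n_rep <- 500
  for (r in seq_len(n_rep)) {
    sim <- simulate_pairwise_decay(z_true = 0, c0 = 0.5, noise_sd = 0.3,
                                   n_sites = 10, seed = 1000 + r)
    # shuffle distances against similarities to enforce the null
    labs <- rownames(sim$geo)
    perm <- withr::with_seed(2000 + r, sample(length(labs)))
    g <- unclass(sim$geo)[perm, perm]
    dimnames(g) <- list(labs, labs)
    b <- bootstrap_decay_test(dist_matrix(g, "geographic-km"),
                              sim$similarity, n_boot = 99, seed = 3000 + r)
    if (!b$degenerate && abs(b$ratio) > 1.96) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.02)
  expect_lte(hits / n_rep, 0.09)
})

test_that("per-taxon decay orders spatially structured phyla above uniform ones", {
  com <- simulate_community(n_sites = 10, plots_per_site = 2, n_otus = 400,
                            depth = 4000, turnover_rate = 2,
                            phylum_multipliers = c(Structured = 2,
                                                   Uniform = 0.3),
                            seed = 31)
  tab <- decay_by_taxon(com$otu, com$frame,
                        phyla = c("Structured", "Uniform"),
                        n_boot = 99, seed = 1)
  expect_identical(tab$taxon, c("all", "Structured", "Uniform"))
  z <- stats::setNames(tab$z, tab$taxon)
  expect_gt(z["Structured"], z["Uniform"])
})

test_that("a single-phylum table reproduces the all-sequence fit, empty list gives one row", {
  com <- simulate_community(n_sites = 8, plots_per_site = 1, n_otus = 100,
                            depth = 2000, turnover_rate = 1,
                            phylum_multipliers = c(Only = 1),
                            seed = 17)
  # force every OTU into one phylum
  tax <- stats::setNames(rep("k__Bacteria; p__Only; c__X",
                             ncol(com$otu$counts)),
                         colnames(com$otu$counts))
  otu <- otu_table(com$otu$counts, tax)
  tab <- decay_by_taxon(otu, com$frame, phyla = "Only", n_boot = 49, seed = 2)
  expect_equal(tab$z[tab$taxon == "Only"], tab$z[tab$taxon == "all"],
               tolerance = 1e-12)
  solo <- decay_by_taxon(otu, com$frame, phyla = character(),
                         n_boot = 49, seed = 2)
  expect_identical(solo$taxon, "all")
})
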