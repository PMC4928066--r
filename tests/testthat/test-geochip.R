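test_that("the category registry has exactly 18 unique families in four cycles", {
  reg <- category_registry()
  expect_equal(nrow(reg), 18)
  expect_false(anyDuplicated(reg$category) > 0)
  expect_equal(unname(table(reg$cycle)[c("carbon_fixation",
                                         "carbon_degradation",
                                         "nitrogen", "phosphorus")]),
               c(3L, 7L, 5L, 3L), ignore_attr = TRUE)
})

test_that("detection filter masks per site below 6/10 and keeps probes detected elsewhere", {
  sig <- geochip_fixture()
  filtered <- detection_filter(sig)
  m <- filtered$intensities
  expect_true(all(is.na(m[1:10, "p01"])))        # 5/10 at site A -> masked
  expect_equal(unname(m[11:20, "p01"]), rep(1, 10))  # 10/10 at site B -> kept
  expect_equal(unname(m[1:10, "p11"]), rep(11, 10))  # 10/10 at A -> kept
  expect_true(all(is.na(m[11:20, "p11"])))       # 2/10 at B -> masked
  expect_equal(unname(m[, "p30"]), rep(30, 20))  # untouched elsewhere
  expect_equal(ncol(m), 30)                      # no probe lost everywhere

  # a probe undetected everywhere after filtering is dropped
  gone <- sig
  gone$intensities[, "p02"] <- NA
  gone$intensities[1:3, "p02"] <- 2
  f2 <- detection_filter(gone)
  expect_false("p02" %in% colnames(f2$intensities))
})

test_that("uneven site sizes rescale the detection threshold with a warning", {
  sig <- geochip_fixture()
  sub <- signal_table(sig$intensities[c(1:5, 11:20), , drop = FALSE],
                      sig$category, sig$site_of)
  # site A now has 5 samples: threshold ceil(6/10*5) = 3
  expect_warning(f <- detection_filter(sub), "siteA.*5 samples")
  # p01 detected in A01..A05 = 5 of 5 >= 3 -> now kept at A
  expect_equal(unname(f$intensities[1:5, "p01"]), rep(1, 5))
})

test_that("mean normalisation equalises totals and matches hand arithmetic", {
  m <- rbind(s1 = c(10, 90), s2 = c(30, 270))
  colnames(m) <- c("pA", "pB")
  sig <- signal_table(m, c(pA = "FTHFS", pB = "ureC"),
                      c(s1 = "x", s2 = "x"))
  norm <- mean_normalize(sig)
  expect_equal(norm$intensities["s1", "pA"], 10 / 100 * 200)  # = 20
  expect_equal(unname(rowSums(norm$intensities)), c(200, 200),
               tolerance = 1e-9)

  same <- signal_table(rbind(s1 = c(5, 5), s2 = c(6, 4),
                             deparse.level = 0) |>
                         `dimnames<-`(list(c("s1", "s2"), c("pA", "pB"))),
                       c(pA = "FTHFS", pB = "ureC"), c(s1 = "x", s2 = "x"))
  expect_equal(mean_normalize(same)$intensities, same$intensities)

  zero <- signal_table(matrix(c(0, NA, 3, 4), 2,
                              dimnames = list(c("s1", "s2"), c("pA", "pB"))),
                       c(pA = "FTHFS", pB = "ureC"), c(s1 = "x", s2 = "x"))
  zero$intensities["s1", "pB"] <- NA
  expect_error(mean_normalize(zero), "zero total.*s1")
})

test_that("category sums partition the per-sample totals and track provenance", {
  sig <- geochip_fixture()
  prof <- suppressWarnings(category_sums(sig))
  pm <- profile_matrix(prof)
  expect_equal(unname(rowSums(pm)),
               unname(rowSums(sig$intensities, na.rm = TRUE)),
               tolerance = 1e-12)
  prov <- attr(prof, "provenance")
  expect_equal(prov$n_probes[prov$category == "FTHFS"], 10L)
  expect_equal(sum(prov$n_probes), 30L)
  # masked spots contribute zero
  filtered <- detection_filter(sig)
  p2 <- suppressWarnings(category_sums(filtered))
  expect_equal(profile_matrix(p2)["A01", "FTHFS"], sum(2:10))
})

test_that("the full pipeline reproduces the hand-worked fixture exactly", {
  # post-filter totals: site A samples 464 (p01 masked), site B 454 (p11
  # masked); mean total 459; category sums are the masked within-category
  # sums rescaled by 459/total.
  prof <- suppressWarnings(
    function_profile_pipeline(geochip_fixture(), log_transform = FALSE))
  pm <- profile_matrix(prof)
  expect_equal(unname(rowSums(pm)), rep(459, 20), tolerance = 1e-9)
  for (a in sprintf("A%02d", 1:10)) {
    expect_equal(pm[a, "FTHFS"], sum(2:10) / 464 * 459, tolerance = 1e-12)
    expect_equal(pm[a, "ureC"], sum(11:20) / 464 * 459, tolerance = 1e-12)
    expect_equal(pm[a, "ppk"], sum(21:30) / 464 * 459, tolerance = 1e-12)
  }
  for (b in sprintf("B%02d", 1:10)) {
    expect_equal(pm[b, "FTHFS"], sum(1:10) / 454 * 459, tolerance = 1e-12)
    expect_equal(pm[b, "ureC"], sum(12:20) / 454 * 459, tolerance = 1e-12)
    expect_equal(pm[b, "ppk"], sum(21:30) / 454 * 459, tolerance = 1e-12)
  }
  # unused registry categories stay as explicit zero columns
  expect_equal(sum(pm[, setdiff(colnames(pm), c("FTHFS", "ureC", "ppk"))]), 0)

  # deterministic: identical re-runs
  again <- suppressWarnings(
    function_profile_pipeline(geochip_fixture(), log_transform = FALSE))
  expect_identical(pm, profile_matrix(again))

  logged <- suppressWarnings(
    function_profile_pipeline(geochip_fixture(), log_transform = TRUE))
  expect_equal(profile_matrix(logged), log1p(pm), tolerance = 1e-12)
})

test_that("pipeline order is fixed: filtering before normalisation differs from the reverse", {
  sig <- geochip_fixture()
  a <- profile_matrix(suppressWarnings(
    function_profile_pipeline(sig, log_transform = FALSE)))
  swapped <- suppressWarnings(
    category_sums(detection_filter(mean_normalize(sig))))
  expect_gt(max(abs(a - profile_matrix(swapped))), 1e-6)
})

test_that("normalisation shrinks the between-sample spread of category sums", {
  sig <- simulate_geochip(n_sites = 3, plots_per_site = 10, n_probes = 54,
                          scaling_sd = 0.5, dropout = 0, noise_sd = 0.05,
                          seed = 77)
  raw <- suppressWarnings(category_sums(detection_filter(sig)))
  norm <- suppressWarnings(category_sums(mean_normalize(detection_filter(sig))))
  cv <- function(x) stats::sd(x) / mean(x)
  cv_raw <- apply(profile_matrix(raw), 2, cv)
  cv_norm <- apply(profile_matrix(norm), 2, cv)
  expect_true(all(cv_norm < cv_raw))
})
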