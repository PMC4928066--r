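#' Registry of the 18 functional gene categories
#'
#' The key biogeochemical-cycling gene families profiled on the array:
#' carbon fixation (FTHFS, FBPase, Rubisco), carbon degradation (cellobiase,
#' endoglucanase, chitinase, mannanase, xylanase, phenol oxidase, amyA),
#' nitrogen cycling (ureC, narG, nirS/K, nosZ, nifH) and phosphorus cycling
#' (phytase, ppx, ppk).
#'
#' @return tibble with columns `category` (18 unique names) and `cycle`.
#' @export
category_registry <- function() {
  tibble::tibble(
    category = c("FTHFS", "FBPase", "Rubisco",
                 "cellobiase", "endoglucanase", "chitinase", "mannanase",
                 "xylanase", "phenol_oxidase", "amyA",
                 "ureC", "narG", "nirS_K", "nosZ", "nifH",
                 "phytase", "ppx", "ppk"),
    cycle = c(rep("carbon_fixation", 3), rep("carbon_degradation", 7),
              rep("nitrogen", 5), rep("phosphorus", 3))
  )
}

#' Within-site detection filter for array probes
#'
#' A probe must be detected (positive, non-missing) in at least
#' `min_detected` of the `group_size` samples of a site to be trusted in
#' that site; below the threshold its entries are masked to missing for
#' that site only. A site with a different number of samples gets the
#' proportionally rescaled threshold `ceiling(min_detected / group_size *
#' n)` with a warning. Probes left with no detection anywhere are dropped.
#'
#' @param signals a [signal_table].
#' @param min_detected minimum detections per site group (default 6).
#' @param group_size nominal samples per site (default 10).
#' @return A filtered [signal_table].
#' @export
detection_filter <- function(signals, min_detected = 6, group_size = 10) {
  stopifnot(inherits(signals, "signal_table"))
  m <- signals$intensities
  site <- signals$site_of
  for (g in unique(site)) {
    rows <- which(site == g)
    thr <- min_detected
    if (length(rows) != group_size) {
      warning(sprintf("site '%s' has %d samples (expected %d); threshold rescaled to %d",
                      g, length(rows), group_size,
                      ceiling(min_detected / group_size * length(rows))))
      thr <- ceiling(min_detected / group_size * length(rows))
    }
    det <- colSums(!is.na(m[rows, , drop = FALSE]) &
                     m[rows, , drop = FALSE] > 0)
    mask <- det < thr
    if (any(mask)) m[rows, mask] <- NA_real_
  }
  keep <- colSums(!is.na(m)) > 0
  if (!all(keep)) m <- m[, keep, drop = FALSE]
  signal_table(m, signals$category, signals$site_of)
}

#' Mean-total normalisation of spot intensities
#'
#' Rescales every detected spot by its sample's total signal so that each
#' sample's total equals the across-sample mean of the original totals:
#' `spot' = spot / total(sample) * mean(totals)`. This removes per-sample
#' hybridisation/labelling intensity artefacts while keeping intensity
#' units. Missing (undetected) spots contribute zero to totals and stay
#' missing.
#'
#' @param signals a [signal_table].
#' @return A normalised [signal_table] whose per-sample totals are all equal.
#' @export
mean_normalize <- function(signals) {
  stopifnot(inherits(signals, "signal_table"))
  m <- signals$intensities
  totals <- rowSums(m, na.rm = TRUE)
  if (any(totals <= 0)) {
    stop("sample with zero total signal: ",
         rownames(m)[which(totals <= 0)[1]], call. = FALSE)
  }
  m <- m / totals * mean(totals)
  signal_table(m, signals$category, signals$site_of)
}

#' Per-sample sums of signal intensity by gene category
#'
#' @param signals a [signal_table] (normally filtered and normalised).
#' @param registry category registry tibble (default [category_registry()]).
#'   Probes annotated to a category outside the registry are reported and
#'   excluded.
#' @return A tibble of class `category_profile`: `sample_id`, `site_id`,
#'   then one nonnegative column per registry category (zero-filled, with a
#'   warning, for categories with no detected probe). Attribute
#'   `provenance` counts the probes contributing per category.
#' @export
category_sums <- function(signals, registry = category_registry()) {
  stopifnot(inherits(signals, "signal_table"))
  cats <- registry$category
  probe_cat <- signals$category
  unmapped <- !(probe_cat %in% cats)
  if (any(unmapped)) {
    message(sum(unmapped), " probe(s) with unregistered category excluded: ",
            paste(utils::head(unique(probe_cat[unmapped]), 3), collapse = ", "))
  }
  m <- signals$intensities[, !unmapped, drop = FALSE]
  pc <- probe_cat[!unmapped]
  sums <- matrix(0, nrow(m), length(cats),
                 dimnames = list(rownames(m), cats))
  prov <- stats::setNames(integer(length(cats)), cats)
  for (cat in cats) {
    cols <- which(pc == cat)
    prov[cat] <- length(cols)
    if (length(cols)) {
      sums[, cat] <- rowSums(m[, cols, drop = FALSE], na.rm = TRUE)
    }
  }
  empty <- cats[colSums(sums) == 0]
  if (length(empty)) {
    warning("category with no detected signal kept as zeros: ",
            paste(empty, collapse = ", "))
  }
  out <- tibble::tibble(sample_id = rownames(m),
                        site_id = unname(signals$site_of[rownames(m)]))
  out <- dplyr::bind_cols(out, tibble::as_tibble(sums))
  attr(out, "provenance") <- tibble::tibble(category = cats,
                                            n_probes = unname(prov))
  class(out) <- c("category_profile", class(out))
  out
}

#' Full functional-gene processing pipeline
#'
#' The fixed three-step composition: (i) within-site detection filter, (ii)
#' mean-total normalisation, (iii) per-category signal sums — optionally
#' followed by `ln(x + 1)` of the sums for downstream ordination. The order
#' is part of the method: filtering after normalisation would let
#' unreliable spots distort the sample totals.
#'
#' @inheritParams detection_filter
#' @param registry category registry (default [category_registry()]).
#' @param log_transform apply `ln(x + 1)` to the category sums.
#' @return A `category_profile` tibble (see [category_sums()]); attribute
#'   `steps` records the pipeline stages applied.
#' @export
function_profile_pipeline <- function(signals, registry = category_registry(),
                                      min_detected = 6, group_size = 10,
                                      log_transform = FALSE) {
  filtered <- detection_filter(signals, min_detected, group_size)
  normalized <- mean_normalize(filtered)
  profile <- category_sums(normalized, registry)
  steps <- c("detection_filter", "mean_normalize", "category_sums")
  if (log_transform) {
    num <- setdiff(names(profile), c("sample_id", "site_id"))
    profile[num] <- lapply(profile[num], log1p)
    steps <- c(steps, "log1p")
  }
  attr(profile, "steps") <- steps
  profile
}

#' Numeric matrix view of a category profile
#' @param profile a `category_profile` tibble.
#' @return samples x categories numeric matrix.
#' @export
profile_matrix <- function(profile) {
  num <- setdiff(names(profile), c("sample_id", "site_id"))
  m <- as.matrix(profile[num])
  rownames(m) <- profile$sample_id
  m
}
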