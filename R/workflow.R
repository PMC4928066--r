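#' End-to-end taxonomic endemism analysis
#'
#' Runs the full community workflow: singleton removal, rarefaction to a
#' common depth, Bray-Curtis dissimilarity, DCA of relative abundances,
#' per-taxon distance-decay fits with bootstrap tests, and regression on
#' distance matrices of community dissimilarity against spatial distance
#' and environmental covariates (single regressions per factor plus one
#' joint multiple regression). Environmental blocks present in the frame
#' (soil chemistry, bioclim climate) are first reduced by PCA of the
#' log-transformed variables and enter as PC-score difference matrices.
#'
#' @param otu an [otu_table] of raw counts.
#' @param frame sample tibble with coordinates and covariates.
#' @param depth rarefaction depth (default 20000).
#' @param phyla phyla for the per-taxon decay table (default the four
#'   dominant phyla of the synthetic generator); `character()` for the
#'   all-sequence row only.
#' @param n_boot bootstrap replicates for the decay test (default 9999).
#' @param n_perm permutations for the matrix regressions (default 9999).
#' @param seed integer seed controlling every resampling step.
#' @param include_ordination run the community DCA (default `TRUE`).
#' @param soil_pcs,climate_pcs how many PCs of each block to use.
#' @return An object of class `endemism_analysis`: `decay` tibble,
#'   `mrm_single` tibble (one row per factor), `mrm_multiple` (an
#'   [mrm()] fit), `dca`, `alpha` diversity tibble, `bray_curtis` matrix,
#'   and a `provenance` list (seed, parameters, step log).
#' @export
run_endemism_analysis <- function(otu, frame, depth = 20000,
                                  phyla = c("Acidobacteria", "Actinobacteria",
                                            "Proteobacteria", "Verrucomicrobia"),
                                  n_boot = 9999, n_perm = 9999, seed = 1,
                                  include_ordination = TRUE,
                                  soil_pcs = 2, climate_pcs = 3) {
  steps <- character()
  log_step <- function(s) steps <<- c(steps, s)

  al <- align_tables(otu, frame)
  log_step(sprintf("align_tables: %d shared samples", nrow(al$frame)))
  otu2 <- remove_singletons(al$otu)
  log_step(sprintf("remove_singletons: %d -> %d OTUs",
                   ncol(al$otu$counts), ncol(otu2$counts)))
  otu3 <- suppressMessages(rarefy_counts(otu2, depth = depth, seed = seed))
  frame2 <- al$frame[al$frame$sample_id %in% sample_ids(otu3), , drop = FALSE]
  log_step(sprintf("rarefy: depth %d, %d samples retained", depth,
                   nrow(otu3$counts)))
  bc <- bray_curtis(otu3)
  log_step("bray_curtis")
  geo <- haversine_matrix(frame2)

  dca <- NULL
  if (include_ordination) {
    rel <- otu3$counts / rowSums(otu3$counts)
    rel <- rel[, colSums(rel) > 0, drop = FALSE]
    dca <- ord_dca(rel)
    log_step("dca: community relative abundances")
  }

  decay <- decay_by_taxon(otu3, frame2, phyla = phyla,
                          n_boot = n_boot, seed = seed)
  log_step(sprintf("decay_by_taxon: %d taxa, B = %d", nrow(decay), n_boot))

  preds <- community_predictors(frame2, geo, soil_pcs, climate_pcs)
  singles <- purrr::imap_dfr(preds, function(p, nm) {
    fit <- single_matrix_regression(bc, p, n_permutations = n_perm,
                                    seed = seed)
    dplyr::mutate(glance(fit), predictor = nm, .before = 1)
  })
  log_step(sprintf("single matrix regressions: %d factors, B = %d",
                   length(preds), n_perm))
  multiple <- mrm(bc, preds, n_permutations = n_perm, seed = seed)
  log_step("multiple matrix regression: all factors jointly")

  structure(list(decay = decay, mrm_single = singles,
                 mrm_multiple = multiple, dca = dca,
                 alpha = alpha_diversity(otu3),
                 bray_curtis = bc,
                 provenance = list(
                   seed = seed, depth = depth, phyla = phyla,
                   n_boot = n_boot, n_perm = n_perm,
                   n_samples = nrow(frame2),
                   input_hash = rlang::hash(list(otu$counts, frame)),
                   steps = steps)),
            class = "endemism_analysis")
}

# spatial distance + PC-difference + scalar-difference predictor matrices
community_predictors <- function(frame, geo, soil_pcs = 2, climate_pcs = 3) {
  soil_vars <- intersect(c("moisture", "pH", "SOC", "TN", "AN", "NN", "AMN",
                           "TP", "RAP"), names(frame))
  climate_vars <- intersect(sprintf("bio%02d", 1:19), names(frame))
  preds <- build_predictor_set(frame, geo,
                               intersect(c("elevation", "plant_shannon"),
                                         names(frame)))
  add_block_pcs <- function(preds, vars, label, k) {
    if (length(vars) < 2) return(preds)
    pca <- ord_pca(frame[vars], log_transform = TRUE, standardize = TRUE)
    for (j in seq_len(min(k, ncol(pca$sample_scores)))) {
      preds[[sprintf("%s_pc%d", label, j)]] <-
        scalar_difference_matrix(pca$sample_scores[, j], frame$sample_id)
    }
    preds
  }
  preds <- add_block_pcs(preds, soil_vars, "soil", soil_pcs)
  add_block_pcs(preds, climate_vars, "climate", climate_pcs)
}

#' @export
print.endemism_analysis <- function(x, ...) {
  cat("<endemism_analysis>\n\nDistance decay by taxon:\n")
  print(as.data.frame(x$decay), row.names = FALSE, digits = 4)
  cat("\nSingle matrix regressions on Bray-Curtis dissimilarity:\n")
  print(as.data.frame(x$mrm_single[c("predictor", "r_squared",
                                     "f_statistic", "p_r_squared")]),
        row.names = FALSE, digits = 4)
  cat(sprintf("\nJoint multiple regression: R2 = %.3f (perm p = %.4g)\n",
              x$mrm_multiple$r_squared, x$mrm_multiple$p_r_squared))
  invisible(x)
}

#' End-to-end functional convergence analysis
#'
#' Runs the functional workflow: the three-step array pipeline
#' (detection filter, mean-total normalisation, category sums), PCA of the
#' ln(x+1) category sums, DCA of the log sums, and single matrix
#' regressions of each retained function PC (entering as a score-difference
#' matrix) on spatial distance, environmental covariates and, when
#' supplied, community dissimilarity.
#'
#' @param signals a [signal_table].
#' @param frame sample tibble with coordinates and covariates.
#' @param community_bc optional Bray-Curtis [dist_matrix] of the community,
#'   added as a predictor.
#' @param n_pcs number of function PCs to regress (default 2).
#' @param n_perm permutations (default 9999).
#' @param seed integer seed.
#' @param include_ordination run the DCA of log category sums.
#' @param min_detected detection-filter threshold per nominal site group
#'   (default 6, the 6-in-10 rule).
#' @param group_size nominal samples per site for the detection filter;
#'   `NULL` (default) infers the modal site size so the 6/10 proportion
#'   carries over to designs with other plot counts.
#' @inheritParams run_endemism_analysis
#' @return An object of class `function_analysis`: `profile`
#'   (category sums), `pca`, `dca`, `regressions` tibble (one row per
#'   function PC x predictor), `provenance`.
#' @export
run_function_analysis <- function(signals, frame, community_bc = NULL,
                                  n_pcs = 2, n_perm = 9999, seed = 1,
                                  include_ordination = TRUE,
                                  soil_pcs = 2, climate_pcs = 3,
                                  min_detected = 6, group_size = NULL) {
  steps <- character()
  log_step <- function(s) steps <<- c(steps, s)

  keep <- intersect(sample_ids(signals), frame$sample_id)
  if (!length(keep)) stop("no samples shared between signals and frame",
                          call. = FALSE)
  signals <- signal_table(signals$intensities[keep, , drop = FALSE],
                          signals$category, signals$site_of)
  frame <- frame[match(keep, frame$sample_id), , drop = FALSE]
  log_step(sprintf("aligned on %d samples", length(keep)))

  if (is.null(group_size)) {
    # modal site size of the data at hand, so the detection threshold
    # rescales only for genuinely uneven sites
    sizes <- as.integer(table(signals$site_of))
    group_size <- as.integer(names(which.max(table(sizes))))
  }
  profile <- function_profile_pipeline(signals, log_transform = TRUE,
                                       min_detected = min_detected *
                                         group_size / 10,
                                       group_size = group_size)
  log_step(paste(attr(profile, "steps"), collapse = " -> "))
  pm <- profile_matrix(profile)
  pm_used <- pm[, apply(pm, 2, stats::sd) > 0, drop = FALSE]
  pca <- ord_pca(pm_used, log_transform = FALSE, standardize = TRUE)
  log_step(sprintf("pca of log category sums: PC1 %.1f%%, PC2 %.1f%%",
                   100 * pca$variance_fraction[1],
                   100 * pca$variance_fraction[2]))
  # ln(x+1) sums are nonnegative, so they feed the CA core directly
  dca <- if (include_ordination) ord_dca(pm) else NULL
  if (include_ordination) log_step("dca: log category sums")

  geo <- haversine_matrix(frame)
  preds <- community_predictors(frame, geo, soil_pcs, climate_pcs)
  if (!is.null(community_bc)) {
    cbc <- unclass(community_bc)[frame$sample_id, frame$sample_id]
    preds$community_dissimilarity <- dist_matrix(cbc, "bray-curtis")
  }
  n_pcs <- min(n_pcs, ncol(pca$sample_scores))
  regressions <- purrr::map_dfr(seq_len(n_pcs), function(j) {
    resp <- scalar_difference_matrix(pca$sample_scores[, j], frame$sample_id)
    purrr::imap_dfr(preds, function(p, nm) {
      fit <- single_matrix_regression(resp, p, n_permutations = n_perm,
                                      seed = seed)
      dplyr::mutate(glance(fit),
                    function_pc = paste0("PC", j), predictor = nm,
                    .before = 1)
    })
  })
  log_step(sprintf("single matrix regressions: %d PCs x %d factors, B = %d",
                   n_pcs, length(preds), n_perm))

  structure(list(profile = profile, pca = pca, dca = dca,
                 regressions = regressions,
                 provenance = list(seed = seed, n_perm = n_perm,
                                   n_samples = nrow(frame),
                                   input_hash = rlang::hash(
                                     list(signals$intensities, frame)),
                                   steps = steps)),
            class = "function_analysis")
}

#' @export
print.function_analysis <- function(x, ...) {
  cat("<function_analysis>\n")
  cat(sprintf("PCA of log category sums: PC1 = %.1f%%, PC2 = %.1f%% (cumulative %.1f%%)\n",
              100 * x$pca$variance_fraction[1],
              100 * x$pca$variance_fraction[2],
              100 * sum(x$pca$variance_fraction[1:2])))
  cat("\nSingle matrix regressions on function PC differences:\n")
  print(as.data.frame(x$regressions[c("function_pc", "predictor",
                                      "r_squared", "f_statistic",
                                      "p_r_squared")]),
        row.names = FALSE, digits = 4)
  invisible(x)
}
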