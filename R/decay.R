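#' Fit the power-law distance-decay of community similarity
#'
#' Community similarity is taken as S = 1 - Bray-Curtis dissimilarity and
#' regressed on geographic distance on log-log axes (natural logarithms):
#' `ln S = intercept + slope * ln d`. The spatial turnover exponent is
#' `z = -slope / 2`. Pairs with nonpositive similarity or zero distance
#' cannot enter a log-log fit; they are excluded and counted rather than
#' offset by a pseudo-value.
#'
#' @param geo a [dist_matrix] of geographic distances (km).
#' @param community a [dist_matrix]; if its kind is `"bray-curtis"` it is
#'   converted to similarity via `1 - d`, otherwise entries are taken as
#'   similarities directly.
#' @return An object of class `decay_fit`: slope, intercept, `z`,
#'   `r_squared`, `n_pairs` used, `n_dropped`, and the pair-level data.
#' @seealso [bootstrap_decay_test()], [decay_by_taxon()]
#' @export
fit_distance_decay <- function(geo, community) {
  community <- check_shared_labels(geo, community)
  d <- lower_vec(geo)
  s <- lower_vec(community)
  if (identical(attr(community, "kind"), "bray-curtis")) s <- 1 - s
  usable <- s > 0 & d > 0
  n_dropped <- sum(!usable)
  x <- log(d[usable])
  y <- log(s[usable])
  if (length(x) < 3) stop("fewer than 3 usable pairs", call. = FALSE)
  if (stats::var(x) == 0) {
    stop("all pairwise distances are equal; slope is undefined", call. = FALSE)
  }
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  ss_res <- sum((y - intercept - slope * x)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(slope = slope, intercept = intercept, z = -slope / 2,
                 r_squared = max(0, min(1, r2)),
                 n_pairs = length(x), n_dropped = n_dropped,
                 data = tibble::tibble(log_distance = x, log_similarity = y)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> z = %.4f (slope %.4f), R2 = %.3f, %d pairs (%d dropped)\n",
              x$z, x$slope, x$r_squared, x$n_pairs, x$n_dropped))
  invisible(x)
}

#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope", "z"),
                 estimate = c(x$intercept, x$slope, x$z))
}

#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(z = x$z, slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, n_pairs = x$n_pairs,
                 n_dropped = x$n_dropped)
}

#' @export
autoplot.decay_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$log_distance,
                               y = .data$log_similarity)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "firebrick") +
    ggplot2::labs(x = "ln geographic distance (km)",
                  y = "ln community similarity (1 - Bray-Curtis)",
                  title = sprintf("Distance decay: z = %.3f, R² = %.2f",
                                  object$z, object$r_squared)) +
    ggplot2::theme_minimal()
}

# slope of y on x for resampled index sets, without lm overhead
.ols_slope <- function(x, y) {
  mx <- mean(x)
  sum((x - mx) * (y - mean(y))) / sum((x - mx)^2)
}

#' Bootstrap significance test of the distance-decay slope
#'
#' Resamples the vectorised pair list with replacement `n_boot` times,
#' refitting the log-log slope each time, and applies a one-sample t test of
#' the bootstrap slope distribution against zero:
#' `t = boot_mean / (boot_sd / sqrt(n_boot))`, with p from the t distribution
#' on `n_boot - 1` degrees of freedom (two-sided). Because the bootstrap
#' standard error in the denominator is divided by `sqrt(n_boot)`, |t| grows
#' as `sqrt(n_boot)` on the same data; the scale-free `ratio`
#' (`boot_mean / boot_sd`) is reported alongside as the replication-invariant
#' effect measure. Pair-level resampling ignores the dependence among pairs
#' sharing a sample; an optional sample-level bootstrap (`unit = "sample"`)
#' resamples rows of the matrices instead.
#'
#' @inheritParams fit_distance_decay
#' @param n_boot bootstrap replicates (default 9999).
#' @param seed integer seed; resampling is deterministic given it.
#' @param unit `"pair"` (default) or `"sample"`.
#' @return An object of class `decay_boot` with `t_statistic`, `p_value`,
#'   `boot_mean`, `boot_sd`, `ratio`, `degenerate` flag, `n_boot`, `seed`.
#' @export
bootstrap_decay_test <- function(geo, community, n_boot = 9999, seed = NULL,
                                 unit = c("pair", "sample")) {
  unit <- match.arg(unit)
  fit <- fit_distance_decay(geo, community)
  x <- fit$data$log_distance
  y <- fit$data$log_similarity
  n <- length(x)
  run <- function() {
    if (unit == "pair") {
      vapply(seq_len(n_boot), function(b) {
        i <- sample.int(n, n, replace = TRUE)
        .ols_slope(x[i], y[i])
      }, numeric(1))
    } else {
      labs <- rownames(geo)
      m <- length(labs)
      g <- as.matrix(geo)
      cm <- as.matrix(community)
      vapply(seq_len(n_boot), function(b) {
        i <- sample.int(m, m, replace = TRUE)
        gb <- g[i, i]; cb <- cm[i, i]
        db <- lower_vec(gb); sb <- lower_vec(cb)
        if (identical(dist_kind(community), "bray-curtis")) sb <- 1 - sb
        ok <- sb > 0 & db > 0
        .ols_slope(log(db[ok]), log(sb[ok]))
      }, numeric(1))
    }
  }
  slopes <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  bm <- mean(slopes)
  bs <- stats::sd(slopes)
  if (!is.finite(bs) || bs <= 1e-12 * max(1, abs(bm))) {
    return(structure(list(n_boot = n_boot, t_statistic = sign(bm) * Inf,
                          p_value = 1 / (n_boot + 1), boot_mean = bm,
                          boot_sd = 0, ratio = sign(bm) * Inf,
                          degenerate = TRUE, seed = seed, unit = unit),
                     class = "decay_boot"))
  }
  t_stat <- bm / (bs / sqrt(n_boot))
  p <- 2 * stats::pt(-abs(t_stat), df = n_boot - 1)
  p <- max(p, .Machine$double.xmin)
  structure(list(n_boot = n_boot, t_statistic = t_stat, p_value = p,
                 boot_mean = bm, boot_sd = bs, ratio = bm / bs,
                 degenerate = FALSE, seed = seed, unit = unit),
            class = "decay_boot")
}

#' @export
print.decay_boot <- function(x, ...) {
  cat(sprintf("<decay_boot> B = %d, t = %.2f, p = %.3g%s\n",
              x$n_boot, x$t_statistic, x$p_value,
              if (x$degenerate) " (degenerate: zero bootstrap variance)" else ""))
  invisible(x)
}

#' @export
glance.decay_boot <- function(x, ...) {
  tibble::tibble(n_boot = x$n_boot, t_statistic = x$t_statistic,
                 p_value = x$p_value, boot_mean = x$boot_mean,
                 boot_sd = x$boot_sd, ratio = x$ratio,
                 degenerate = x$degenerate)
}

#' Distance decay per taxonomic group
#'
#' Runs the full decay analysis (Bray-Curtis on the counts, log-log fit,
#' bootstrap test) for all sequences and for each requested phylum,
#' mirroring a per-taxon turnover table. Phyla with fewer than two non-empty
#' samples are skipped with a warning.
#'
#' @param otu an [otu_table] (normally already singleton-filtered and
#'   rarefied).
#' @param frame sample tibble with coordinates.
#' @param phyla character vector of phylum names; empty for the all-sequence
#'   row only.
#' @param n_boot,seed passed to [bootstrap_decay_test()].
#' @return tibble with one row per taxon: `taxon`, `z`, `slope`,
#'   `r_squared`, `t_statistic`, `p_value`, `n_pairs`, `n_dropped`.
#' @export
decay_by_taxon <- function(otu, frame, phyla = character(),
                           n_boot = 9999, seed = NULL) {
  al <- align_tables(otu, frame)
  geo <- haversine_matrix(al$frame)
  one <- function(tab, taxon) {
    tot <- rowSums(tab$counts)
    if (sum(tot > 0) < 2) {
      warning("phylum '", taxon, "' has fewer than 2 non-empty samples; skipped")
      return(NULL)
    }
    keep <- rownames(tab$counts)[tot > 0]
    bc <- bray_curtis(otu_table(tab$counts[keep, , drop = FALSE], tab$taxonomy))
    g <- dist_matrix(as.matrix(geo)[keep, keep], "geographic-km")
    fit <- fit_distance_decay(g, bc)
    boot <- bootstrap_decay_test(g, bc, n_boot = n_boot, seed = seed)
    tibble::tibble(taxon = taxon, z = fit$z, slope = fit$slope,
                   r_squared = fit$r_squared, t_statistic = boot$t_statistic,
                   p_value = boot$p_value, n_pairs = fit$n_pairs,
                   n_dropped = fit$n_dropped)
  }
  rows <- list(one(al$otu, "all"))
  for (ph in phyla) {
    sub <- suppressWarnings(subset_by_phylum(al$otu, ph))
    if (ncol(sub$counts) == 0) {
      warning("phylum '", ph, "' not present; skipped")
      next
    }
    rows <- c(rows, list(one(sub, ph)))
  }
  dplyr::bind_rows(rows)
}
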