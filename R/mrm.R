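#' Multiple regression on distance matrices (MRM)
#'
#' Ordinary least squares of the response matrix's vectorised lower triangle
#' on the predictors' vectorised lower triangles, with Mantel-style
#' permutation inference: the null distribution is built by jointly
#' permuting rows and columns of the response matrix, re-vectorising, and
#' refitting. R-squared significance is the one-sided exceedance of the
#' permuted R-squared; coefficient p-values are two-sided by absolute-value
#' exceedance (one-sided available via `alternative`). With the identity
#' permutation always counted, the smallest attainable p is
#' `1 / (n_permutations + 1)`.
#'
#' @param response a [dist_matrix] (e.g. Bray-Curtis dissimilarity).
#' @param predictors a named list of [dist_matrix] objects sharing the
#'   response's labels.
#' @param n_permutations number of permutations (default 9999).
#' @param seed integer seed; permutations are deterministic given it.
#' @param alternative `"two.sided"` (default) or `"greater"` for the
#'   coefficient tests.
#' @return An object of class `mrm_fit`: `coefficients` tibble (term,
#'   estimate, p_value), `r_squared`, `p_r_squared`, `f_statistic` and its
#'   permutation context.
#' @seealso [single_matrix_regression()], [build_predictor_set()]
#' @export
mrm <- function(response, predictors, n_permutations = 9999, seed = NULL,
                alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (inherits(predictors, "dist_matrix")) predictors <- list(predictors)
  if (is.null(names(predictors)) || any(!nzchar(names(predictors)))) {
    names(predictors) <- paste0("predictor_", seq_along(predictors))
  }
  n <- nrow(response)
  if (n < 4) stop("need at least 4 samples", call. = FALSE)
  predictors <- lapply(predictors, check_shared_labels, a = response)
  y <- lower_vec(response)
  X <- cbind(`(intercept)` = 1,
             vapply(predictors, lower_vec, numeric(length(y))))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    cc <- stats::cor(X[, -1, drop = FALSE])
    bad <- which(abs(cc) > 1 - 1e-10 & upper.tri(cc), arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf("collinear predictors: '%s' and '%s'",
                   colnames(cc)[bad[1, 1]], colnames(cc)[bad[1, 2]]),
           call. = FALSE)
    }
    stop("predictors are rank-deficient after vectorisation", call. = FALSE)
  }
  fit_stats <- function(yv) {
    b <- qr.coef(qx, yv)
    res <- yv - X %*% b
    ss_tot <- sum((yv - mean(yv))^2)
    r2 <- if (ss_tot == 0) 0 else 1 - sum(res^2) / ss_tot
    list(b = b, r2 = r2)
  }
  obs <- fit_stats(y)
  rmat <- unclass(response)
  run_perms <- function() {
    ge_r2 <- 1L                      # identity permutation counts
    ge_b <- rep(1L, ncol(X))
    for (p in seq_len(n_permutations)) {
      idx <- sample.int(n)
      st <- fit_stats(lower_vec(rmat[idx, idx]))
      ge_r2 <- ge_r2 + (st$r2 >= obs$r2)
      ge_b <- ge_b + if (alternative == "two.sided") {
        as.integer(abs(st$b) >= abs(obs$b))
      } else {
        as.integer(st$b >= obs$b)
      }
    }
    list(ge_r2 = ge_r2, ge_b = ge_b)
  }
  perms <- if (is.null(seed)) run_perms() else withr::with_seed(seed, run_perms())
  npairs <- length(y)
  k <- ncol(X) - 1
  f_stat <- if (obs$r2 < 1) {
    (obs$r2 / k) / ((1 - obs$r2) / (npairs - k - 1))
  } else Inf
  coefs <- tibble::tibble(
    term = colnames(X),
    estimate = as.numeric(obs$b),
    p_value = perms$ge_b / (n_permutations + 1)
  )
  structure(list(coefficients = coefs,
                 r_squared = obs$r2,
                 p_r_squared = perms$ge_r2 / (n_permutations + 1),
                 f_statistic = f_stat,
                 n_pairs = npairs, n_samples = n,
                 n_permutations = n_permutations, seed = seed,
                 alternative = alternative),
            class = "mrm_fit")
}

#' @export
print.mrm_fit <- function(x, ...) {
  cat(sprintf("<mrm_fit> R2 = %.4f (perm p = %.4g), %d samples / %d pairs, B = %d\n",
              x$r_squared, x$p_r_squared, x$n_samples, x$n_pairs,
              x$n_permutations))
  print(as.data.frame(x$coefficients), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.mrm_fit <- function(x, ...) x$coefficients

#' @export
glance.mrm_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, p_r_squared = x$p_r_squared,
                 f_statistic = x$f_statistic, n_pairs = x$n_pairs,
                 n_samples = x$n_samples, n_permutations = x$n_permutations)
}

#' Single regression on distance matrices
#'
#' [mrm()] with one predictor, additionally reporting the single-predictor F
#' statistic `F = (n - 2) * R2 / (1 - R2)` over the n vectorised pairs.
#'
#' @inheritParams mrm
#' @param predictor one [dist_matrix].
#' @return An `mrm_fit` (its `f_statistic` uses the one-predictor form).
#' @export
single_matrix_regression <- function(response, predictor,
                                     n_permutations = 9999, seed = NULL,
                                     alternative = c("two.sided", "greater")) {
  v <- lower_vec(predictor)
  if (stats::var(v) == 0) {
    stop("predictor has zero variance across pairs", call. = FALSE)
  }
  mrm(response, list(predictor = predictor),
      n_permutations = n_permutations, seed = seed,
      alternative = match.arg(alternative))
}

#' Build predictor matrices from sample covariates
#'
#' Passes the geographic matrix through and converts each named scalar
#' column of the sample frame to a pairwise absolute-difference matrix, all
#' aligned to the frame's sample order.
#'
#' @param frame sample tibble.
#' @param geo optional [dist_matrix] of geographic distances (labels must
#'   cover the frame's samples).
#' @param scalars character vector of column names in `frame`.
#' @return named list of [dist_matrix] objects (`spatial_distance` first
#'   when `geo` is given).
#' @export
build_predictor_set <- function(frame, geo = NULL, scalars = character()) {
  out <- list()
  if (!is.null(geo)) {
    g <- unclass(geo)[frame$sample_id, frame$sample_id]
    out$spatial_distance <- dist_matrix(g, "geographic-km")
  }
  for (nm in scalars) {
    if (!nm %in% names(frame)) {
      stop("column '", nm, "' not found in the sample frame", call. = FALSE)
    }
    out[[nm]] <- scalar_difference_matrix(frame[[nm]], frame$sample_id)
  }
  out
}
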