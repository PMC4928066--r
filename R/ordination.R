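#' Principal component analysis of a samples x variables table
#'
#' Centred (and by default unit-variance-scaled, since environmental
#' variables mix units such as pH and millimetres of precipitation) singular
#' value decomposition. The per-axis variance fraction is
#' `lambda_k / sum(lambda)`, so fractions over all axes sum to 1.
#'
#' @param x numeric matrix or data frame, samples in rows. A `sample_id`
#'   column, if present, becomes the row labels.
#' @param log_transform if `TRUE`, apply `ln(x)` when all values are
#'   positive, `ln(x + 1)` when zeros are present; negative values are an
#'   error.
#' @param standardize scale columns to unit variance (default `TRUE`).
#' @param n_axes number of axes to keep in the score matrices (eigenvalues
#'   and fractions are always reported for all axes).
#' @return An object of class `ordination` with `method = "pca"`,
#'   `sample_scores`, `variable_scores` (loadings), `eigenvalues`,
#'   `variance_fraction`, `n_axes`.
#' @export
ord_pca <- function(x, log_transform = FALSE, standardize = TRUE,
                    n_axes = NULL) {
  m <- as_sample_matrix(x)
  if (nrow(m) < 2 || ncol(m) < 2) stop("need >= 2 samples and >= 2 variables",
                                       call. = FALSE)
  if (log_transform) m <- log_shift(m)
  if (standardize) {
    sds <- apply(m, 2, stats::sd)
    if (any(sds == 0)) {
      stop("constant column under standardization: '",
           colnames(m)[which(sds == 0)[1]], "'", call. = FALSE)
    }
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = standardize)
  ev <- pc$sdev^2
  k <- if (is.null(n_axes)) length(ev) else min(n_axes, length(ev))
  new_ordination("pca",
                 sample_scores = pc$x[, seq_len(k), drop = FALSE],
                 variable_scores = pc$rotation[, seq_len(k), drop = FALSE],
                 eigenvalues = ev,
                 variance_fraction = ev / sum(ev),
                 n_axes = k)
}

# ln(x) if strictly positive, ln(x+1) if zeros present; negatives error
log_shift <- function(m) {
  if (any(m < 0)) stop("log transform requires nonnegative values", call. = FALSE)
  if (all(m > 0)) log(m) else log1p(m)
}

as_sample_matrix <- function(x) {
  if (inherits(x, "otu_table")) return(x$counts)
  if (is.data.frame(x)) {
    ids <- NULL
    if ("sample_id" %in% names(x)) {
      ids <- as.character(x$sample_id)
      x <- x[setdiff(names(x), "sample_id")]
    }
    x <- as.matrix(x[vapply(x, is.numeric, logical(1))])
    if (!is.null(ids)) rownames(x) <- ids
  }
  m <- as.matrix(x)
  if (is.null(rownames(m))) rownames(m) <- paste0("s", seq_len(nrow(m)))
  m
}

new_ordination <- function(method, sample_scores, variable_scores,
                           eigenvalues, variance_fraction, n_axes,
                           degenerate = FALSE) {
  structure(list(method = method, sample_scores = sample_scores,
                 variable_scores = variable_scores,
                 eigenvalues = eigenvalues,
                 variance_fraction = variance_fraction,
                 n_axes = n_axes, degenerate = degenerate),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("<ordination: %s> %d samples, %d axes kept%s\n",
              x$method, nrow(x$sample_scores), x$n_axes,
              if (isTRUE(x$degenerate)) " (degenerate axes flagged)" else ""))
  k <- min(4, length(x$eigenvalues))
  cat("  eigenvalues:", paste(signif(x$eigenvalues[1:k], 4), collapse = ", "),
      "\n  variance fractions:",
      paste(sprintf("%.1f%%", 100 * x$variance_fraction[1:k]), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
tidy.ordination <- function(x, ...) {
  tibble::as_tibble(x$sample_scores, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "axis", values_to = "score")
}

#' @export
glance.ordination <- function(x, ...) {
  tibble::tibble(method = x$method,
                 axis = seq_along(x$eigenvalues),
                 eigenvalue = x$eigenvalues,
                 variance_fraction = x$variance_fraction)
}

#' @export
autoplot.ordination <- function(object, colour = NULL, ...) {
  df <- tibble::as_tibble(object$sample_scores[, 1:2, drop = FALSE],
                          rownames = "sample_id")
  names(df)[2:3] <- c("axis1", "axis2")
  if (!is.null(colour)) df$group <- colour
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$axis1, y = .data$axis2)) +
    ggplot2::labs(
      x = sprintf("Axis 1 (%.1f%%)", 100 * object$variance_fraction[1]),
      y = sprintf("Axis 2 (%.1f%%)", 100 * object$variance_fraction[2]),
      title = toupper(object$method)) +
    ggplot2::theme_minimal()
  if (is.null(colour)) p + ggplot2::geom_point()
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
}

#' Correspondence analysis
#'
#' Singular value decomposition of the chi-square standardised residual
#' matrix of a nonnegative table. Eigenvalues are the squared singular
#' values (total = the table's phi-squared); sample scores are row principal
#' coordinates. Invariant to uniform rescaling of the table.
#'
#' @param x nonnegative samples x columns matrix/data frame (or
#'   [otu_table]); no all-zero row or column.
#' @param n_axes axes to keep in the score matrices.
#' @return An `ordination` with `method = "ca"`.
#' @export
ord_ca <- function(x, n_axes = NULL) {
  m <- as_sample_matrix(x)
  if (any(m < 0)) stop("negative entries", call. = FALSE)
  zr <- which(rowSums(m) == 0)
  if (length(zr)) stop("all-zero row: '", rownames(m)[zr[1]], "'", call. = FALSE)
  zc <- which(colSums(m) == 0)
  if (length(zc)) stop("all-zero column: '", colnames(m)[zc[1]], "'", call. = FALSE)
  P <- m / sum(m)
  r <- rowSums(P)
  cm <- colSums(P)
  S <- (P - outer(r, cm)) / sqrt(outer(r, cm))
  sv <- svd(S)
  nax <- max(1, min(nrow(m), ncol(m)) - 1)
  d <- sv$d[seq_len(nax)]
  ev <- d^2
  rows <- sweep(sv$u[, seq_len(nax), drop = FALSE], 1, sqrt(r), "/")
  rows <- sweep(rows, 2, d, "*")
  cols <- sweep(sv$v[, seq_len(nax), drop = FALSE], 1, sqrt(cm), "/")
  cols <- sweep(cols, 2, d, "*")
  dimnames(rows) <- list(rownames(m), paste0("CA", seq_len(nax)))
  dimnames(cols) <- list(colnames(m), paste0("CA", seq_len(nax)))
  k <- if (is.null(n_axes)) nax else min(n_axes, nax)
  new_ordination("ca",
                 sample_scores = rows[, seq_len(k), drop = FALSE],
                 variable_scores = cols[, seq_len(k), drop = FALSE],
                 eigenvalues = ev,
                 variance_fraction = ev / sum(ev),
                 n_axes = k)
}

# subtract segment means of x along the ordering given by `by`
detrend_segments <- function(x, by, n_segments) {
  n <- length(x)
  ord <- order(by)
  seg <- cut(seq_len(n), breaks = min(n_segments, n), labels = FALSE)
  out <- x
  for (s in unique(seg)) {
    i <- ord[seg == s]
    out[i] <- x[i] - mean(x[i])
  }
  out
}

#' Detrended correspondence analysis (detrending by segments)
#'
#' Axis 1 is the first correspondence-analysis axis. Each subsequent axis is
#' re-extracted by reciprocal averaging, detrending the sample scores
#' against every prior axis at each iteration by Hill's method of segments:
#' order the samples by the prior axis, split them into `n_segments`
#' equal-count segments, and subtract the segment mean of the current
#' scores. Iteration stops at score convergence (`tol`, up to `max_iter`
#' passes). Nonlinear rescaling of axis units is deliberately not applied:
#' only the score configuration is used downstream, which rescaling does not
#' change qualitatively.
#'
#' @inheritParams ord_ca
#' @param n_segments number of detrending segments (default 26).
#' @param n_axes number of axes to extract (default 4).
#' @param tol convergence tolerance on the score change (default 1e-10).
#' @param max_iter maximum reciprocal-averaging passes per axis (default 30).
#' @return An `ordination` with `method = "dca"`; `degenerate = TRUE` when
#'   fewer axes exist than requested (e.g. two samples).
#' @export
ord_dca <- function(x, n_segments = 26, n_axes = 4, tol = 1e-10,
                    max_iter = 30) {
  if (n_segments < 2) stop("`n_segments` must be >= 2", call. = FALSE)
  m <- as_sample_matrix(x)
  ca <- ord_ca(m)
  n_avail <- max(1, min(nrow(m), ncol(m)) - 1)
  k <- min(n_axes, n_avail)
  degenerate <- k < n_axes
  w_r <- rowSums(m)
  w_c <- colSums(m)
  tot <- sum(m)
  wnorm <- function(v) {
    v <- v - sum(w_r * v) / tot
    ss <- sum(w_r * v^2) / tot
    if (ss <= 0) return(list(v = v, norm = 0))
    list(v = v / sqrt(ss), norm = sqrt(ss))
  }
  axes <- matrix(0, nrow(m), k, dimnames = list(rownames(m),
                                                paste0("DCA", seq_len(k))))
  eig <- numeric(k)
  axes[, 1] <- ca$sample_scores[, 1]
  eig[1] <- ca$eigenvalues[1]
  if (k > 1) {
    for (a in 2:k) {
      x0 <- wnorm(ca$sample_scores[, a])$v
      if (all(x0 == 0)) x0 <- wnorm(stats::rnorm(nrow(m)))$v
      for (it in seq_len(max_iter)) {
        u <- as.numeric(crossprod(m, x0)) / w_c
        x1 <- as.numeric(m %*% u) / w_r
        for (j in seq_len(a - 1)) {
          x1 <- detrend_segments(x1, axes[, j], n_segments)
        }
        nrm <- wnorm(x1)
        if (nrm$norm == 0) break
        if (max(abs(nrm$v - x0)) < tol || max(abs(nrm$v + x0)) < tol) {
          x0 <- nrm$v
          eig[a] <- nrm$norm
          break
        }
        x0 <- nrm$v
        eig[a] <- nrm$norm
      }
      axes[, a] <- x0 * sqrt(max(eig[a], 0))   # principal-like scaling
    }
  }
  # species scores by weighted averaging of the final sample scores
  vscores <- crossprod(m, axes) / w_c
  new_ordination("dca",
                 sample_scores = axes,
                 variable_scores = vscores,
                 eigenvalues = eig,
                 variance_fraction = eig / sum(ca$eigenvalues),
                 n_axes = k, degenerate = degenerate)
}
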