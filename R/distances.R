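#' Labelled distance matrix
#'
#' A square symmetric nonnegative matrix with zero diagonal and a `kind` tag
#' (`"geographic-km"`, `"bray-curtis"` or `"scalar-difference"`). Bray-Curtis
#' matrices must additionally have entries in `[0, 1]`.
#'
#' @param values square numeric matrix with matching row/column labels.
#' @param kind character tag.
#' @return A matrix of class `dist_matrix` with a `kind` attribute.
#' @export
dist_matrix <- function(values,
                        kind = c("geographic-km", "bray-curtis",
                                 "scalar-difference")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("matrix is not square", call. = FALSE)
  if (is.null(rownames(values))) {
    rownames(values) <- colnames(values) <- paste0("s", seq_len(nrow(values)))
  }
  if (!identical(rownames(values), colnames(values))) {
    stop("row and column labels differ", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) stop("duplicate labels", call. = FALSE)
  if (max(abs(values - t(values))) > 1e-12) {
    stop("matrix is not symmetric (tolerance 1e-12)", call. = FALSE)
  }
  if (any(abs(diag(values)) > 1e-12)) stop("diagonal is not zero", call. = FALSE)
  if (any(values < 0)) stop("negative distances", call. = FALSE)
  if (kind == "bray-curtis" && any(values > 1 + 1e-12)) {
    stop("Bray-Curtis entries must be <= 1", call. = FALSE)
  }
  values <- (values + t(values)) / 2
  diag(values) <- 0
  structure(values, kind = kind, class = c("dist_matrix", "matrix", "array"))
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix: %s> %d x %d\n", attr(x, "kind"), nrow(x), nrow(x)))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  invisible(x)
}

dist_kind <- function(x) attr(x, "kind") %||% "scalar-difference"

#' Bray-Curtis dissimilarity matrix
#'
#' BC(u, v) = sum(|u_i - v_i|) / sum(u_i + v_i), computed between every pair
#' of samples. Intended for rarefied counts so that differing sequencing
#' depth does not masquerade as community turnover.
#'
#' @param x an [otu_table] or a samples x OTUs numeric matrix.
#' @return A [dist_matrix] with kind `"bray-curtis"`.
#' @export
bray_curtis <- function(x) {
  m <- if (inherits(x, "otu_table")) x$counts else as.matrix(x)
  if (nrow(m) < 2) stop("need at least 2 samples", call. = FALSE)
  tot <- rowSums(m)
  if (any(tot <= 0)) {
    stop("sample with zero total count: ",
         rownames(m)[which(tot <= 0)[1]], call. = FALSE)
  }
  d <- as.matrix(vegan::vegdist(m, method = "bray"))
  dist_matrix(d, "bray-curtis")
}

#' Great-circle distance matrix
#'
#' Haversine distances in kilometres between sample coordinates on a sphere
#' of radius 6371.0 km.
#'
#' @param frame sample tibble with `sample_id`, `latitude`, `longitude`.
#' @return A [dist_matrix] with kind `"geographic-km"`.
#' @export
haversine_matrix <- function(frame) {
  miss <- which(is.na(frame$latitude) | is.na(frame$longitude))
  if (length(miss)) {
    stop("missing coordinate for sample '", frame$sample_id[miss[1]], "'",
         call. = FALSE)
  }
  pts <- cbind(frame$longitude, frame$latitude)
  d <- geosphere::distm(pts, fun = function(p1, p2) {
    geosphere::distHaversine(p1, p2, r = 6371000)
  }) / 1000
  dimnames(d) <- list(frame$sample_id, frame$sample_id)
  dist_matrix(d, "geographic-km")
}

#' Pairwise absolute-difference matrix of a scalar covariate
#'
#' Turns one numeric value per sample into the pairwise matrix
#' `|x_i - x_j|`, the form in which a scalar covariate (elevation, a PC
#' score, plant diversity) enters regression on distance matrices.
#'
#' @param values numeric vector, one value per sample; no missing values.
#' @param labels sample labels (defaults to `names(values)`).
#' @return A [dist_matrix] with kind `"scalar-difference"`.
#' @export
scalar_difference_matrix <- function(values, labels = names(values)) {
  if (anyNA(values)) {
    who <- if (!is.null(labels)) labels[which(is.na(values))[1]] else which(is.na(values))[1]
    stop("missing value for sample '", who, "'", call. = FALSE)
  }
  d <- abs(outer(values, values, "-"))
  if (is.null(labels)) labels <- paste0("s", seq_along(values))
  dimnames(d) <- list(labels, labels)
  dist_matrix(d, "scalar-difference")
}

#' Vectorise the lower triangle of a distance matrix
#'
#' Deterministic row-major flattening over pairs i < j, keeping the label
#' pair for each entry; [pairs_to_matrix()] reconstructs the matrix.
#'
#' @param m a [dist_matrix] or square labelled matrix.
#' @return tibble with columns `label_1`, `label_2`, `value`; `n(n-1)/2` rows.
#' @export
dist_pairs <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  idx <- which(upper.tri(m), arr.ind = TRUE)   # row-major over i < j
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  tibble::tibble(label_1 = rownames(m)[idx[, 1]],
                 label_2 = colnames(m)[idx[, 2]],
                 value = m[idx])
}

# fast path: values only, pairs in dist_pairs order
lower_vec <- function(m) {
  m <- as.matrix(m)
  t(m)[lower.tri(m)]
}

#' Rebuild a distance matrix from its vectorised pairs
#' @param pairs tibble as produced by [dist_pairs()].
#' @param kind kind tag for the result.
#' @return A [dist_matrix].
#' @export
pairs_to_matrix <- function(pairs, kind = "scalar-difference") {
  labels <- unique(c(pairs$label_1, pairs$label_2))
  n <- length(labels)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  i <- match(pairs$label_1, labels)
  j <- match(pairs$label_2, labels)
  m[cbind(i, j)] <- pairs$value
  m[cbind(j, i)] <- pairs$value
  dist_matrix(m, kind)
}

#' Read / write distance matrices as labelled TSV
#'
#' Square labelled TSV on write; on read, a lower-triangle dialect (empty or
#' absent upper entries) is mirrored automatically.
#'
#' @param path file path.
#' @param kind kind tag for the result.
#' @return `read_dist_matrix()` a [dist_matrix]; `write_dist_matrix()` the
#'   path, invisibly.
#' @export
read_dist_matrix <- function(path, kind = "scalar-difference") {
  dat <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(dat)
  storage.mode(m) <- "double"
  m[is.na(m)] <- 0
  m <- pmax(m, t(m))      # mirrors a lower-triangle-only file; no-op if full
  diag(m) <- 0
  dist_matrix(m, kind)
}

#' @rdname read_dist_matrix
#' @param m a [dist_matrix]
#' @export
write_dist_matrix <- function(m, path) {
  utils::write.table(as.data.frame(as.matrix(m)), path, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}

# reorder b's rows/cols to a's label order, preserving the kind tag
check_shared_labels <- function(a, b) {
  if (!identical(rownames(a), rownames(b))) {
    if (is.null(rownames(a)) || is.null(rownames(b)) ||
        !setequal(rownames(a), rownames(b))) {
      stop("matrices do not share labels", call. = FALSE)
    }
    kind <- attr(b, "kind")
    b <- unclass(b)[rownames(a), rownames(a)]
    if (!is.null(kind)) b <- dist_matrix(b, kind)
  }
  b
}
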