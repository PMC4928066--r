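#' Remove singleton OTUs
#'
#' Drops OTUs whose summed count across all samples equals exactly 1 (the
#' pooled-table convention: a read seen once in the whole study is most
#' likely a sequencing artefact). All other columns are untouched.
#'
#' @param otu an [otu_table] of raw counts.
#' @return An [otu_table] without singleton OTUs. Warns if nothing is left.
#' @export
remove_singletons <- function(otu) {
  stopifnot(inherits(otu, "otu_table"))
  totals <- colSums(otu$counts)
  keep <- totals != 1
  if (!any(keep)) warning("all OTUs were singletons; table is now empty")
  otu_table(otu$counts[, keep, drop = FALSE], otu$taxonomy[keep])
}

#' Rarefy samples to a common depth
#'
#' Replaces each sample's counts by a single without-replacement subsample of
#' exactly `depth` reads, so that all retained samples are directly
#' comparable. Samples whose total is below `depth` are dropped (and listed
#' in the `dropped` attribute). Deterministic given `seed`.
#'
#' @param otu an [otu_table].
#' @param depth target reads per sample (default 20000).
#' @param seed integer RNG seed; `NULL` uses the current RNG state.
#' @return An [otu_table] whose row sums all equal `depth`, with attribute
#'   `dropped` naming any samples that were too shallow.
#' @export
rarefy_counts <- function(otu, depth = 20000, seed = NULL) {
  stopifnot(inherits(otu, "otu_table"))
  if (depth <= 0) stop("`depth` must be a positive integer", call. = FALSE)
  totals <- rowSums(otu$counts)
  keep <- totals >= depth
  dropped <- rownames(otu$counts)[!keep]
  if (length(dropped)) {
    message(length(dropped), " sample(s) below depth ", depth, " dropped: ",
            paste(utils::head(dropped, 5), collapse = ", "))
  }
  if (!any(keep)) stop("no sample reaches depth ", depth, call. = FALSE)
  m <- otu$counts[keep, , drop = FALSE]
  # rrarefy's "observed counts" heuristic misfires on any table whose
  # smallest nonzero count exceeds 1; the constructor already guarantees
  # nonnegative integers, so muffle that specific warning
  draw <- function() withCallingHandlers(
    vegan::rrarefy(m, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  r <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  out <- otu_table(r, otu$taxonomy)
  attr(out, "dropped") <- dropped
  out
}

#' Shannon diversity of one count vector
#'
#' H = -sum(p_i * ln(p_i)) over OTUs with positive count, in nats.
#'
#' @param counts nonnegative numeric vector with at least one positive entry.
#' @return Shannon index in nats.
#' @examples
#' shannon_index(rep(10, 8))   # ln(8)
#' @export
shannon_index <- function(counts) {
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  if (sum(counts) <= 0) stop("all counts are zero", call. = FALSE)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Per-sample alpha diversity
#'
#' @param otu an [otu_table].
#' @return tibble with `sample_id`, `richness` (observed OTUs) and `shannon`
#'   (nats).
#' @export
alpha_diversity <- function(otu) {
  stopifnot(inherits(otu, "otu_table"))
  m <- otu$counts
  tibble::tibble(sample_id = rownames(m),
                 richness = rowSums(m > 0),
                 shannon = vegan::diversity(m, index = "shannon"))
}

#' Phylum of every OTU in a table
#' @param otu an [otu_table].
#' @return named character vector otu id -> phylum.
#' @export
otu_phyla <- function(otu) {
  stats::setNames(parse_phylum(otu$taxonomy), names(otu$taxonomy))
}

#' Restrict an OTU table to one phylum
#'
#' Keeps the OTUs whose parsed phylum matches `phylum` (case-insensitive);
#' counts are unchanged. Subsetting by every phylum plus `"unclassified"`
#' partitions the original column set.
#'
#' @param otu an [otu_table].
#' @param phylum phylum name.
#' @return An [otu_table]; empty (with a warning) if the phylum is absent.
#' @export
subset_by_phylum <- function(otu, phylum) {
  stopifnot(inherits(otu, "otu_table"), nzchar(phylum))
  keep <- tolower(otu_phyla(otu)) == tolower(phylum)
  if (!any(keep)) warning("no OTUs assigned to phylum '", phylum, "'")
  otu_table(otu$counts[, keep, drop = FALSE], otu$taxonomy[keep])
}
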