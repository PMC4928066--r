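#' OTU count table
#'
#' Construct a validated OTU table: a samples x OTUs matrix of nonnegative
#' integer counts plus a taxonomy string per OTU. Internally samples are
#' always rows; file formats that store OTUs as rows are transposed on read.
#'
#' @param counts numeric matrix, samples in rows, OTUs in columns, with
#'   unique dimnames. Values must be nonnegative integers (coerced).
#' @param taxonomy named character vector mapping every OTU id to a taxonomy
#'   string (rank-prefixed `"k__...; p__...;"` style or plain
#'   semicolon-separated). OTUs without an entry get `"unclassified"`.
#' @return An object of class `otu_table`.
#' @examples
#' counts <- matrix(c(5L, 0L, 2L, 3L), 2, 2,
#'                  dimnames = list(c("s1", "s2"), c("otu1", "otu2")))
#' otu_table(counts, c(otu1 = "k__Bacteria; p__Acidobacteria",
#'                     otu2 = "unclassified"))
#' @export
otu_table <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  # a zero-column table (everything filtered away) is legal; R stores no
  # dimnames for zero-extent dimensions
  if (is.null(rownames(counts)) ||
      (ncol(counts) > 0 && is.null(colnames(counts)))) {
    stop("`counts` must have sample (row) and OTU (column) names", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate sample ids", call. = FALSE)
  if (anyDuplicated(colnames(counts))) stop("duplicate OTU ids", call. = FALSE)
  bad <- which(counts < 0 | is.na(counts), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("negative or missing count at sample '%s', OTU '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]),
         call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  tax <- rep_len("unclassified", ncol(counts))
  names(tax) <- colnames(counts)
  if (!is.null(taxonomy)) {
    taxonomy <- taxonomy[!is.na(taxonomy)]
    keep <- intersect(names(taxonomy), colnames(counts))
    tax[keep] <- taxonomy[keep]
  }
  structure(list(counts = counts, taxonomy = tax), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("<otu_table> %d samples x %d OTUs, total count %s\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(as.numeric(x$counts)), big.mark = ",")))
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Sample and OTU identifiers
#' @param x an [otu_table] or [signal_table]
#' @return character vector of ids.
#' @export
sample_ids <- function(x) UseMethod("sample_ids")
#' @export
sample_ids.otu_table <- function(x) rownames(x$counts)
#' @rdname sample_ids
#' @export
otu_ids <- function(x) colnames(x$counts)

#' @export
as_tibble.otu_table <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$counts), rownames = "sample_id")
}

#' Parse the phylum from taxonomy strings
#'
#' Understands QIIME-style rank prefixes (`p__Acidobacteria`) and falls back
#' to the second semicolon-separated field of a plain lineage string.
#'
#' @param taxonomy character vector of taxonomy strings.
#' @return character vector of phylum names, `"unclassified"` where no
#'   phylum can be extracted.
#' @export
parse_phylum <- function(taxonomy) {
  vapply(taxonomy, function(s) {
    if (is.na(s) || !nzchar(s)) return("unclassified")
    fields <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    pref <- grep("^[pP]__", fields, value = TRUE)
    if (length(pref)) {
      out <- sub("^[pP]__", "", pref[1])
      return(if (nzchar(out)) out else "unclassified")
    }
    if (any(grepl("^[a-z]__", fields))) return("unclassified")
    if (length(fields) >= 2 && nzchar(fields[2])) return(fields[2])
    "unclassified"
  }, character(1), USE.NAMES = FALSE)
}

#' Read an OTU table
#'
#' Reads the classic tab-separated dialect (`#OTU ID` header, OTUs as rows,
#' samples as columns, optional trailing `taxonomy` column) or a BIOM 1.0
#' JSON file. The result always stores samples as rows.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"tsv"` or `"biom"`.
#' @return An [otu_table].
#' @export
read_otu_table <- function(path, format = c("auto", "tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.biom$", path, ignore.case = TRUE)) "biom" else "tsv"
  }
  if (format == "biom") return(read_otu_biom(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty OTU table: ", path, call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2) {
    stop("malformed OTU table header (line 1): expected tab-separated columns",
         call. = FALSE)
  }
  dat <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "",
                           check.names = FALSE, stringsAsFactors = FALSE)
  tax_col <- which(tolower(names(dat)) %in% c("taxonomy", "consensus lineage",
                                              "consensuslineage"))
  otu_id <- as.character(dat[[1]])
  tax <- NULL
  if (length(tax_col)) {
    tax <- stats::setNames(as.character(dat[[tax_col[1]]]), otu_id)
    dat <- dat[-tax_col[1]]
  }
  num <- dat[-1]
  for (j in seq_along(num)) {
    v <- suppressWarnings(as.numeric(num[[j]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      stop(sprintf("non-numeric count at OTU '%s', sample '%s'",
                   otu_id[i], names(num)[j]), call. = FALSE)
    }
    num[[j]] <- v
  }
  m <- t(as.matrix(num))                      # samples now rows
  colnames(m) <- otu_id
  rownames(m) <- names(num)
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative count at sample '%s', OTU '%s'",
                 rownames(m)[neg[1, 1]], colnames(m)[neg[1, 2]]), call. = FALSE)
  }
  otu_table(m, tax)
}

read_otu_biom <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    stop("reading BIOM files requires the 'biomformat' package", call. = FALSE)
  }
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix")   # OTUs x samples
  tax_list <- biomformat::observation_metadata(b)
  tax <- NULL
  if (!is.null(tax_list) && length(tax_list)) {
    tax <- vapply(seq_len(nrow(m)), function(i) {
      entry <- if (is.data.frame(tax_list)) unlist(tax_list[i, ]) else tax_list[[i]]
      paste(unlist(entry), collapse = "; ")
    }, character(1))
    names(tax) <- rownames(m)
  }
  otu_table(t(m), tax)
}

#' Write an OTU table to tab-separated text
#'
#' Emits the `#OTU ID` dialect: OTUs as rows, samples as columns, taxonomy in
#' a trailing column. `read_otu_table()` round-trips it losslessly.
#'
#' @param x an [otu_table]
#' @param path output file path
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(x, path) {
  stopifnot(inherits(x, "otu_table"))
  df <- data.frame(`#OTU ID` = colnames(x$counts), t(x$counts),
                   taxonomy = unname(x$taxonomy),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata sheet
#'
#' Tab- or comma-separated with a header. Required columns: `sample_id`,
#' `site_id`, `latitude`, `longitude`. All other columns are kept; numeric
#' columns are parsed as numeric, and absent optional columns stay absent.
#'
#' @param path file path; delimiter sniffed from the header line.
#' @return A tibble with one row per sample.
#' @export
read_sample_frame <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  delim <- if (grepl("\t", first)) "\t" else ","
  frame <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                             progress = FALSE)
  frame$sample_id <- as.character(frame$sample_id)
  validate_sample_frame(frame)
}

#' Validate a sample metadata frame
#'
#' @param frame a data frame with at least `sample_id`, `site_id`,
#'   `latitude`, `longitude`.
#' @return the validated frame as a tibble.
#' @export
validate_sample_frame <- function(frame) {
  need <- c("sample_id", "site_id", "latitude", "longitude")
  miss <- setdiff(need, names(frame))
  if (length(miss)) {
    stop("sample frame is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  dup <- frame$sample_id[duplicated(frame$sample_id)]
  if (length(dup)) {
    stop("duplicate sample_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad_lat <- which(is.na(frame$latitude) | abs(frame$latitude) > 90)
  if (length(bad_lat)) {
    stop(sprintf("latitude out of [-90, 90] for sample '%s' (row %d)",
                 frame$sample_id[bad_lat[1]], bad_lat[1]), call. = FALSE)
  }
  bad_lon <- which(is.na(frame$longitude) | abs(frame$longitude) > 180)
  if (length(bad_lon)) {
    stop(sprintf("longitude out of [-180, 180] for sample '%s' (row %d)",
                 frame$sample_id[bad_lon[1]], bad_lon[1]), call. = FALSE)
  }
  tibble::as_tibble(frame)
}

#' Write a sample metadata sheet
#' @param frame sample tibble
#' @param path output path (tab-separated)
#' @return `path`, invisibly.
#' @export
write_sample_frame <- function(frame, path) {
  utils::write.table(frame, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Functional gene array signal table
#'
#' Probes x samples intensities with a gene-category annotation per probe and
#' a site (reserve) assignment per sample. Undetected spots are `NA`, never 0:
#' the detection filter counts detections while the normaliser treats missing
#' spots as zero contribution.
#'
#' @param intensities numeric matrix, samples in rows, probes in columns;
#'   nonnegative where detected, `NA` for undetected spots.
#' @param category named character vector probe id -> gene category.
#' @param site_of named character vector sample id -> site id.
#' @return An object of class `signal_table`.
#' @export
signal_table <- function(intensities, category, site_of) {
  intensities <- as.matrix(intensities)
  if (is.null(rownames(intensities)) || is.null(colnames(intensities))) {
    stop("`intensities` must have sample (row) and probe (column) names",
         call. = FALSE)
  }
  if (any(intensities < 0, na.rm = TRUE)) {
    stop("detected intensities must be nonnegative", call. = FALSE)
  }
  miss <- setdiff(colnames(intensities), names(category))
  if (length(miss)) {
    stop("probes without a category annotation: ",
         paste(utils::head(miss, 3), collapse = ", "), call. = FALSE)
  }
  miss_s <- setdiff(rownames(intensities), names(site_of))
  if (length(miss_s)) {
    stop("samples without a site assignment: ",
         paste(utils::head(miss_s, 3), collapse = ", "), call. = FALSE)
  }
  structure(list(intensities = intensities,
                 category = category[colnames(intensities)],
                 site_of = site_of[rownames(intensities)]),
            class = "signal_table")
}

#' @export
print.signal_table <- function(x, ...) {
  cat(sprintf("<signal_table> %d samples x %d probes (%d categories, %d sites), %.1f%% detected\n",
              nrow(x$intensities), ncol(x$intensities),
              length(unique(x$category)), length(unique(x$site_of)),
              100 * mean(!is.na(x$intensities))))
  invisible(x)
}

#' @export
sample_ids.signal_table <- function(x) rownames(x$intensities)

#' @export
as_tibble.signal_table <- function(x, ...) {
  long <- tibble::as_tibble(as.data.frame(x$intensities),
                            rownames = "sample_id")
  long <- tidyr::pivot_longer(long, -"sample_id", names_to = "probe_id",
                              values_to = "intensity")
  long$category <- unname(x$category[long$probe_id])
  long$site_id <- unname(x$site_of[long$sample_id])
  long
}

#' Read a functional gene signal table
#'
#' Tab-separated, probes as rows: first column probe id, a `category`
#' annotation column, remaining columns one per sample. Empty cells or `NA`
#' are undetected spots.
#'
#' @param path file path.
#' @param site_of named character vector sample id -> site id, or a sample
#'   frame with `sample_id` and `site_id` columns.
#' @return A [signal_table].
#' @export
read_signal_table <- function(path, site_of) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dat <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  cat_col <- which(tolower(names(dat)) == "category")
  if (!length(cat_col)) stop("signal table needs a 'category' column", call. = FALSE)
  probe_id <- as.character(dat[[1]])
  category <- stats::setNames(as.character(dat[[cat_col[1]]]), probe_id)
  num <- dat[-c(1, cat_col[1])]
  m <- t(as.matrix(num))
  storage.mode(m) <- "double"
  colnames(m) <- probe_id
  if (is.data.frame(site_of)) {
    site_of <- stats::setNames(as.character(site_of$site_id),
                               site_of$sample_id)
  }
  signal_table(m, category, site_of)
}

#' Write a signal table to tab-separated text
#' @param x a [signal_table]
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_signal_table <- function(x, path) {
  df <- data.frame(probe_id = colnames(x$intensities),
                   category = unname(x$category),
                   t(x$intensities),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align tables on their shared samples
#'
#' Restricts an OTU table, a sample frame, and optionally a signal table to
#' the intersection of their sample ids, in the OTU table's sample order, and
#' reports what was dropped from each. Aligning already-aligned tables is a
#' no-op.
#'
#' @param otu an [otu_table]
#' @param frame a sample tibble (see [read_sample_frame()])
#' @param signals optional [signal_table]
#' @return list with elements `otu`, `frame`, `signals` (or `NULL`) and
#'   `dropped`, a named list of the sample ids removed from each input.
#' @export
align_tables <- function(otu, frame, signals = NULL) {
  ids <- intersect(sample_ids(otu), frame$sample_id)
  if (!is.null(signals)) ids <- intersect(ids, sample_ids(signals))
  if (!length(ids)) stop("no samples shared between the tables", call. = FALSE)
  ids <- sample_ids(otu)[sample_ids(otu) %in% ids]   # keep otu order
  dropped <- list(otu = setdiff(sample_ids(otu), ids),
                  frame = setdiff(frame$sample_id, ids))
  out_otu <- otu_table(otu$counts[ids, , drop = FALSE], otu$taxonomy)
  out_frame <- frame[match(ids, frame$sample_id), , drop = FALSE]
  out_sig <- NULL
  if (!is.null(signals)) {
    dropped$signals <- setdiff(sample_ids(signals), ids)
    out_sig <- signal_table(signals$intensities[ids, , drop = FALSE],
                            signals$category, signals$site_of)
  }
  list(otu = out_otu, frame = out_frame, signals = out_sig, dropped = dropped)
}
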