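#' Read an OTU count table
#'
#' Reads a delimited text file of non-negative integer OTU counts into the
#' tibble layout used throughout microclust: one row per sample, a leading
#' `sample_id` column, and one column per OTU. Many microbiome TSV exports
#' ship transposed (OTUs as rows, the biom-TSV convention); set
#' `orientation = "otus_as_rows"` to transpose on read.
#'
#' @param path Path to a TSV or CSV file with a header row and a leading
#'   identifier column.
#' @param orientation Either `"samples_as_rows"` (default) or
#'   `"otus_as_rows"`.
#' @param delim Field delimiter. Guessed from the file extension when `NULL`
#'   (`.csv` means comma, anything else tab).
#' @return A tibble with a `sample_id` character column and one integer
#'   column per OTU.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("id\tOTU1\tOTU2", "s1\t0\t5", "s2\t2\t0"), tf)
#' read_count_table(tf)
#' @export
read_count_table <- function(path,
                             orientation = c("samples_as_rows", "otus_as_rows"),
                             delim = NULL) {
  orientation <- match.arg(orientation)
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- utils::read.delim(path, sep = delim, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) {
    stop("count table needs an identifier column plus at least one data column",
         call. = FALSE)
  }
  ids <- as.character(raw[[1L]])
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  bad <- which(!is.finite(mat) | mat < 0 | mat != round(mat), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-integer or negative count at row '%s', column '%s'",
                 ids[bad[1L, 1L]], colnames(mat)[bad[1L, 2L]]), call. = FALSE)
  }
  rownames(mat) <- ids
  if (orientation == "otus_as_rows") mat <- t(mat)
  if (anyDuplicated(rownames(mat))) {
    stop("duplicate sample identifiers: ",
         paste(unique(rownames(mat)[duplicated(rownames(mat))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(mat))) {
    stop("duplicate OTU identifiers: ",
         paste(unique(colnames(mat)[duplicated(colnames(mat))]), collapse = ", "),
         call. = FALSE)
  }
  count_tbl(mat)
}

#' Write an OTU count table
#'
#' Inverse of [read_count_table()]; integer tables round-trip exactly.
#'
#' @param table A count tibble (see [read_count_table()]).
#' @param path Output path.
#' @param delim Field delimiter, default tab.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path, delim = "\t") {
  mat <- count_matrix(table)
  df <- data.frame(sample_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# tibble <-> matrix bridge ---------------------------------------------------

#' Convert a count/abundance tibble to a numeric matrix
#'
#' @param table A tibble whose first column is `sample_id` and whose remaining
#'   columns are numeric, or a numeric matrix with row names (returned as is).
#' @return Numeric matrix, samples in rows (named), OTUs in columns.
#' @export
count_matrix <- function(table) {
  if (is.matrix(table)) {
    stopifnot(is.numeric(table))
    return(table)
  }
  stopifnot(is.data.frame(table), ncol(table) >= 2L)
  idcol <- if ("sample_id" %in% names(table)) "sample_id" else names(table)[1L]
  mat <- as.matrix(table[, setdiff(names(table), idcol), drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- as.character(table[[idcol]])
  mat
}

count_tbl <- function(mat) {
  tibble::as_tibble(
    cbind(data.frame(sample_id = rownames(mat), stringsAsFactors = FALSE),
          as.data.frame(mat, check.names = FALSE))
  )
}

validate_counts <- function(mat) {
  if (any(!is.finite(mat)) || any(mat < 0) || any(mat != round(mat))) {
    stop("counts must be finite non-negative integers", call. = FALSE)
  }
  invisible(mat)
}

#' Per-sample read totals
#'
#' @param table Count tibble or matrix.
#' @return Named numeric vector of row sums (library sizes).
#' @export
sample_totals <- function(table) {
  rowSums(count_matrix(table))
}

#' Convert counts to relative abundances
#'
#' Divides each sample row by its total read count. Samples with zero total
#' reads become all-zero rows and are reported in a warning, matching the
#' convention that downstream distances treat such samples as empty rather
#' than undefined.
#'
#' @param table Count tibble or matrix (samples in rows).
#' @return A tibble of the same shape with proportions; rows with positive
#'   totals sum to 1.
#' @export
to_relative_abundance <- function(table) {
  mat <- count_matrix(table)
  tot <- rowSums(mat)
  zero <- tot == 0
  if (any(zero)) {
    warning("samples with zero total reads set to all-zero abundance: ",
            paste(rownames(mat)[zero], collapse = ", "), call. = FALSE)
    tot[zero] <- 1
  }
  count_tbl(mat / tot)
}

#' Filter OTUs by zero proportion
#'
#' Drops every OTU whose fraction of zero entries across samples is strictly
#' greater than `max_zero_fraction` (an OTU sitting exactly at the threshold
#' is kept). A zero count is a zero relative abundance and vice versa, so the
#' filter is computed on counts. Column order of the survivors is preserved.
#'
#' @param table Count tibble or matrix.
#' @param max_zero_fraction Maximum tolerated zero fraction, in \[0, 1\].
#'   Default 0.8: OTUs absent from more than 80% of samples are removed.
#' @return Filtered count tibble, same samples.
#' @export
filter_by_zero_proportion <- function(table, max_zero_fraction = 0.8) {
  stopifnot(length(max_zero_fraction) == 1L,
            max_zero_fraction >= 0, max_zero_fraction <= 1)
  mat <- count_matrix(table)
  zf <- colMeans(mat == 0)
  keep <- zf <= max_zero_fraction
  if (!any(keep)) {
    stop("zero-proportion filter removed every OTU", call. = FALSE)
  }
  count_tbl(mat[, keep, drop = FALSE])
}

# trees, labels, distance matrices -------------------------------------------

#' Read a rooted phylogenetic tree in newick format
#'
#' Thin wrapper over [ape::read.tree()] that checks branch lengths are
#' present and non-negative and, when `otu_ids` is given, that every OTU has
#' exactly one leaf.
#'
#' @param path Newick file.
#' @param otu_ids Optional character vector of OTU identifiers to validate
#'   against the tree's leaves.
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(path, otu_ids = NULL) {
  tree <- ape::read.tree(path)
  check_tree(tree, otu_ids)
  tree
}

check_tree <- function(tree, otu_ids = NULL) {
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("tree has negative branch lengths", call. = FALSE)
  }
  if (!is.null(otu_ids)) {
    missing <- setdiff(otu_ids, tree$tip.label)
    if (length(missing) > 0L) {
      stop("missing leaves for OTUs: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  invisible(tree)
}

#' Read or write a sample label file
#'
#' Labels are stored as a two-column TSV (`sample_id`, `label`) and used only
#' for external validation of a clustering, never during model fitting.
#'
#' @param path File path.
#' @return `read_labels()`: a tibble with `sample_id` (character) and `label`
#'   (integer) columns.
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stopifnot(ncol(df) >= 2L)
  tibble::tibble(sample_id = as.character(df[[1L]]),
                 label = as.integer(df[[2L]]))
}

#' @rdname read_labels
#' @param labels Tibble with `sample_id` and `label` columns.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(labels[, c("sample_id", "label")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a distance matrix
#'
#' Square labelled TSV dialect: first column and header row carry sample
#' identifiers, values written with 12 significant digits so that
#' write-then-read round-trips within 1e-12.
#'
#' @param dm A `micro_dist` object or square numeric matrix.
#' @param path File path.
#' @return `read_distance_matrix()`: a `micro_dist` object.
#' @export
write_distance_matrix <- function(dm, path) {
  mat <- as.matrix(dm)
  df <- data.frame(sample_id = rownames(mat),
                   signif(mat, 12L), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @param metric Metric name to attach on read.
#' @export
read_distance_matrix <- function(path, metric = "unknown") {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- as.character(df[[1L]])
  new_micro_dist(mat, metric)
}
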