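#' Construct a spectral-count matrix object
#'
#' Container for a protein-by-sample table of spectral counts from a paired
#' malignant / non-malignant cell-line experiment, together with protein
#' metadata (accession, gene symbol, gene identifier) and the nested sample
#' design (cell line, biological replicate, technical replicate).
#'
#' @param counts Numeric matrix, proteins in rows and samples in columns.
#'   Raw counts may be fractional; processed counts are integers.
#' @param proteins data.frame with columns `accession`, `gene_symbol`,
#'   `gene_id` (one row per count row). Missing symbols/ids are `NA`.
#' @param samples data.frame with columns `sample_id`, `cell_line`
#'   (`"malignant"` or `"non_malignant"`), `bio_rep`, `tech_rep`.
#' @param integerized Logical; whether counts have been integerized.
#'
#' @return An object of class `"spectral_count_matrix"`.
#' @export
spectral_count_matrix <- function(counts, proteins, samples,
                                  integerized = FALSE) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts))
    stop("counts must be numeric")
  storage.mode(counts) <- "double"
  if (any(!is.finite(counts)))
    stop("counts must be finite")
  if (any(counts < 0))
    stop("negative count at row ", which(rowSums(counts < 0) > 0)[1])
  proteins <- as.data.frame(proteins, stringsAsFactors = FALSE)
  samples  <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (nrow(proteins) != nrow(counts))
    stop("proteins table and count rows differ in length")
  if (nrow(samples) != ncol(counts))
    stop("samples table and count columns differ in length")
  if (anyDuplicated(proteins$accession))
    stop("duplicate accession: ",
         proteins$accession[duplicated(proteins$accession)][1])
  key <- with(samples, paste(cell_line, bio_rep, tech_rep))
  if (anyDuplicated(key))
    stop("duplicate sample label: ", key[duplicated(key)][1])
  if (!all(samples$cell_line %in% c("malignant", "non_malignant")))
    stop("cell_line must be 'malignant' or 'non_malignant'")
  if (!"id_missing" %in% names(proteins))
    proteins$id_missing <- is.na(proteins$gene_id)
  # rows are addressed by gene symbol where that is unambiguous,
  # falling back to the accession for unmapped or duplicated symbols
  rn <- proteins$gene_symbol
  amb <- is.na(rn) | duplicated(rn) | duplicated(rn, fromLast = TRUE)
  rn[amb] <- proteins$accession[amb]
  rownames(counts) <- rn
  colnames(counts) <- samples$sample_id
  structure(list(counts = counts, proteins = proteins, samples = samples,
                 integerized = integerized),
            class = "spectral_count_matrix")
}

#' @export
print.spectral_count_matrix <- function(x, ...) {
  cat("spectral_count_matrix:", nrow(x$counts), "proteins x",
      ncol(x$counts), "samples\n")
  tab <- table(x$samples$cell_line)
  cat("  samples:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  integerized:", x$integerized, "\n")
  invisible(x)
}

#' @export
dim.spectral_count_matrix <- function(x) dim(x$counts)

# Parse sample labels of the form <N|T>_b<i>_t<j>.
parse_sample_labels <- function(labels) {
  m <- regmatches(labels, regexec("^([NT])_b([0-9]+)_t([0-9]+)$", labels))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    stop("malformed sample label in header: ", labels[bad][1])
  data.frame(
    sample_id = labels,
    cell_line = ifelse(vapply(m, `[`, "", 2L) == "T",
                       "malignant", "non_malignant"),
    bio_rep  = as.integer(vapply(m, `[`, "", 3L)),
    tech_rep = as.integer(vapply(m, `[`, "", 4L)),
    stringsAsFactors = FALSE)
}

#' Read a spectral-count TSV
#'
#' Reads a tab-separated count table whose first three columns are
#' `accession`, `gene_symbol` and `gene_id`, followed by one column per
#' sample labelled `<N|T>_b<i>_t<j>` (non-malignant/malignant line,
#' biological replicate i, technical replicate j). Counts may be fractional
#' in the raw file; proteins that cannot be mapped to a gene identifier are
#' retained but flagged (`id_missing`) so that downstream enrichment and
#' pathway stages can exclude them.
#'
#' @param path Path to the count TSV.
#' @param mapping_path Optional two-column TSV (`accession`, `gene_symbol`)
#'   used to fill in missing gene symbols.
#' @return A [spectral_count_matrix()].
#' @export
read_spectral_counts <- function(path, mapping_path = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("accession", "gene_symbol", "gene_id")
  if (ncol(df) < 4L || !identical(names(df)[1:3], need))
    stop("malformed header: expected columns ",
         paste(need, collapse = ", "), " then sample labels")
  samples <- parse_sample_labels(names(df)[-(1:3)])
  counts <- as.matrix(df[, -(1:3), drop = FALSE])
  if (!is.numeric(counts))
    stop("non-numeric count in ", path)
  if (any(counts < 0)) {
    idx <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop("negative count at row ", idx[1], ", column ", idx[2])
  }
  proteins <- df[, 1:3]
  proteins$gene_symbol[proteins$gene_symbol %in% c("", "NA")] <- NA_character_
  proteins$gene_id <- suppressWarnings(as.integer(proteins$gene_id))
  if (!is.null(mapping_path)) {
    map <- utils::read.delim(mapping_path, stringsAsFactors = FALSE)
    hit <- match(proteins$accession, map$accession)
    fill <- is.na(proteins$gene_symbol) & !is.na(hit)
    proteins$gene_symbol[fill] <- map$gene_symbol[hit[fill]]
  }
  proteins$id_missing <- is.na(proteins$gene_id)
  spectral_count_matrix(counts, proteins, samples,
                        integerized = all(counts == floor(counts)))
}

#' Write a spectral-count matrix as TSV
#'
#' Inverse of [read_spectral_counts()]; integer matrices round-trip
#' bit-identically.
#'
#' @param x A [spectral_count_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectral_counts <- function(x, path) {
  df <- cbind(x$proteins[c("accession", "gene_symbol", "gene_id")],
              as.data.frame(x$counts, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Consolidate protein isoforms to one row per gene
#'
#' Rows sharing a gene symbol (isoforms of the same gene) are summed
#' column-wise into a single row, so downstream stages see a 1:1
#' protein-to-gene mapping. Rows without a gene symbol pass through
#' unchanged. Rows sharing a symbol but carrying conflicting non-missing
#' gene identifiers are an error rather than a silent merge.
#'
#' @param x A [spectral_count_matrix()].
#' @return A consolidated [spectral_count_matrix()] with unique gene
#'   symbols; column totals are preserved exactly.
#' @export
consolidate_isoforms <- function(x) {
  stopifnot(inherits(x, "spectral_count_matrix"))
  sym <- x$proteins$gene_symbol
  has_sym <- !is.na(sym)
  # unnamed rows keep their accession as the grouping key (no merging)
  key <- ifelse(has_sym, sym, paste0(".acc:", x$proteins$accession))
  first <- !duplicated(key)
  ord <- key[first]
  for (g in unique(key[duplicated(key)])) {
    ids <- x$proteins$gene_id[key == g]
    ids <- unique(ids[!is.na(ids)])
    if (length(ids) > 1L)
      stop("conflicting gene ids for symbol '", g, "': ",
           paste(ids, collapse = ", "))
  }
  counts <- rowsum(x$counts, group = key, reorder = FALSE)
  counts <- counts[ord, , drop = FALSE]
  pick_id <- function(v) {
    v <- v[!is.na(v)]
    if (length(v)) as.integer(v[1]) else NA_integer_
  }
  proteins <- data.frame(
    accession = unname(vapply(split(x$proteins$accession, key)[ord],
                              function(a) paste(a, collapse = ";"), "")),
    gene_symbol = ifelse(startsWith(ord, ".acc:"), NA_character_, ord),
    gene_id = unname(vapply(split(x$proteins$gene_id, key)[ord], pick_id,
                            integer(1))),
    stringsAsFactors = FALSE)
  spectral_count_matrix(counts, proteins, x$samples,
                        integerized = x$integerized)
}

#' Integerize spectral counts by rounding up
#'
#' Replaces every count by its ceiling, so fractional spectral counts become
#' whole numbers while integer values (including zero) are unchanged. The
#' operation is idempotent.
#'
#' @param x A [spectral_count_matrix()].
#' @return The matrix with `ceiling()` applied to every count.
#' @export
integerize_counts <- function(x) {
  stopifnot(inherits(x, "spectral_count_matrix"))
  if (any(x$counts < 0)) stop("negative count")
  x$counts <- ceiling(x$counts)
  x$integerized <- TRUE
  x
}

#' Standard processing of a raw spectral-count matrix
#'
#' Consolidates isoforms and then integerizes counts (ceiling). The
#' alternative order is available via `integerize_first = TRUE`; the two can
#' differ because the ceiling of a sum is not the sum of ceilings.
#'
#' @param x A raw [spectral_count_matrix()].
#' @param integerize_first Integerize before consolidating isoforms.
#' @return A processed [spectral_count_matrix()].
#' @export
process_spectral_counts <- function(x, integerize_first = FALSE) {
  if (integerize_first) consolidate_isoforms(integerize_counts(x))
  else integerize_counts(consolidate_isoforms(x))
}
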