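#' Two-sided unpaired Wilcoxon rank-sum p-value
#'
#' Thin, validated wrapper around the standard rank-sum test as used for
#' per-protein spectral-count comparisons: two-sided alternative, continuity
#' correction, and the usual behaviour of switching from the exact null
#' distribution (small untied samples) to the tie-corrected normal
#' approximation when ties are present.
#'
#' @param x,y Non-empty numeric count vectors for the two groups.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact null; default
#'   `NULL` uses the exact distribution for untied samples with fewer than
#'   50 values per group.
#' @return Two-sided p-value in (0, 1].
#' @export
wilcoxon_rank_sum <- function(x, y, exact = NULL) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both count vectors must be non-empty")
  # a single tied value everywhere carries no rank information; the
  # tie-corrected variance degenerates to zero there
  if (length(unique(c(x, y))) == 1L) return(1)
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)$p.value)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return q-values in the input order: monotone step-up adjusted p-values,
#'   clipped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Log2 fold change of malignant over non-malignant mean counts
#'
#' When either mean is zero the ratio is undefined or infinite, so one is
#' added to both means before taking the ratio; otherwise means are used
#' as-is. Vectorised over genes.
#'
#' @param mean_t,mean_n Non-negative mean spectral counts in the malignant
#'   and non-malignant samples.
#' @return `log2` fold change(s); negative values mean lower abundance in
#'   the malignant line.
#' @export
log2_fold_change <- function(mean_t, mean_n) {
  if (any(!is.finite(mean_t)) || any(!is.finite(mean_n)) ||
      any(mean_t < 0) || any(mean_n < 0))
    stop("means must be finite and non-negative")
  zero <- mean_t == 0 | mean_n == 0
  t2 <- ifelse(zero, mean_t + 1, mean_t)
  n2 <- ifelse(zero, mean_n + 1, mean_n)
  log2(t2 / n2)
}

# Average technical replicates within each (cell line, biological replicate).
collapse_technical_reps <- function(x) {
  key <- with(x$samples, paste(cell_line, bio_rep, sep = "_b"))
  groups <- split(seq_len(ncol(x$counts)), key)
  counts <- vapply(groups, function(j)
    rowMeans(x$counts[, j, drop = FALSE]), numeric(nrow(x$counts)))
  first <- vapply(groups, `[`, 1L, FUN.VALUE = integer(1))
  samples <- x$samples[first, , drop = FALSE]
  samples$tech_rep <- 1L
  samples$sample_id <- names(groups)
  spectral_count_matrix(counts, x$proteins, samples, integerized = FALSE)
}

#' Per-protein differential expression between cell lines
#'
#' Runs the unpaired two-sided Wilcoxon rank-sum test on every protein
#' (malignant vs non-malignant samples), adjusts p-values by
#' Benjamini-Hochberg, computes zero-safe log2 fold changes of the group
#' means, classifies each protein, and partitions proteins by detection.
#' A protein is "detected" in a line when its total count over that line's
#' samples is positive. Differentially expressed proteins (q below `alpha`)
#' detected in a single line are labelled `malignant_only` /
#' `non_malignant_only`; other significant proteins are `upregulated` or
#' `downregulated` by fold-change sign.
#'
#' @param x A processed [spectral_count_matrix()] containing both lines.
#' @param alpha FDR threshold defining differential expression
#'   (default 0.1, i.e. 90% confidence).
#' @param collapse_technical Average technical replicates into their
#'   biological replicate before testing (conservative alternative to
#'   treating all runs as samples).
#' @return List with elements:
#'   \describe{
#'     \item{records}{data.frame, one row per protein: `gene_symbol`,
#'       `gene_id`, `id_missing`, `mean_t`, `mean_n`, `p_value`, `q_value`,
#'       `log2_fc`, `status`, ordered by p-value.}
#'     \item{partition}{detection partition: `shared`, `t_only`, `n_only`
#'       counts (summing to the number of proteins).}
#'     \item{ma}{MA-plot table: mean abundance vs log2 fold change.}
#'     \item{scatter}{1-D fold-change scatter table (`log2_fc`, `dep`).}
#'     \item{alpha}{the threshold used.}
#'   }
#' @export
run_differential_expression <- function(x, alpha = 0.1,
                                        collapse_technical = FALSE) {
  stopifnot(inherits(x, "spectral_count_matrix"))
  if (length(unique(x$samples$cell_line)) < 2L)
    stop("matrix must contain both cell lines")
  if (collapse_technical) x <- collapse_technical_reps(x)
  t_idx <- x$samples$cell_line == "malignant"
  ct <- x$counts[, t_idx, drop = FALSE]
  cn <- x$counts[, !t_idx, drop = FALSE]
  mean_t <- rowMeans(ct)
  mean_n <- rowMeans(cn)
  p <- vapply(seq_len(nrow(x$counts)), function(i)
    wilcoxon_rank_sum(ct[i, ], cn[i, ]), numeric(1))
  q <- bh_adjust(p)
  lfc <- log2_fold_change(mean_t, mean_n)
  det_t <- rowSums(ct) > 0
  det_n <- rowSums(cn) > 0
  status <- rep("not_significant", nrow(x$counts))
  sig <- q < alpha
  status[sig & det_t & !det_n] <- "malignant_only"
  status[sig & !det_t & det_n] <- "non_malignant_only"
  both <- sig & det_t & det_n
  status[both & lfc > 0] <- "upregulated"
  status[both & lfc < 0] <- "downregulated"
  gene <- ifelse(is.na(x$proteins$gene_symbol), x$proteins$accession,
                 x$proteins$gene_symbol)
  records <- data.frame(
    gene_symbol = gene,
    gene_id = x$proteins$gene_id,
    id_missing = x$proteins$id_missing,
    mean_t = mean_t, mean_n = mean_n,
    p_value = p, q_value = q, log2_fc = lfc,
    status = status,
    stringsAsFactors = FALSE, row.names = NULL)
  records <- records[order(records$p_value, records$gene_symbol), ]
  rownames(records) <- NULL
  partition <- list(shared = sum(det_t & det_n),
                    t_only = sum(det_t & !det_n),
                    n_only = sum(!det_t & det_n))
  ma <- data.frame(gene_symbol = gene,
                   mean_abundance = (mean_t + mean_n) / 2,
                   log2_fc = lfc, dep = sig, stringsAsFactors = FALSE)
  scatter <- data.frame(gene_symbol = gene, log2_fc = lfc, dep = sig,
                        stringsAsFactors = FALSE)
  list(records = records, partition = partition, ma = ma,
       scatter = scatter, alpha = alpha)
}

#' Read a differential-expression table
#'
#' Parses a TSV of per-protein differential-expression records (as printed
#' in a publication table or written by this package): columns
#' `gene_symbol`, `p_value`, `q_value`, `log2_fc`, `status`. Status labels
#' may use either this package's vocabulary or the cell-line phrasing
#' ("Downregulated", "Upregulated", "RC-77 T/E only", "RC-77 N/E only"),
#' which is mapped onto
#' `downregulated` / `upregulated` / `malignant_only` / `non_malignant_only`.
#'
#' @param path TSV path.
#' @return data.frame of records with canonical status labels.
#' @export
read_dep_records <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_symbol", "p_value", "q_value", "log2_fc", "status")
  if (!all(need %in% names(df)))
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  map <- c("downregulated" = "downregulated",
           "upregulated" = "upregulated",
           "rc-77 t/e only" = "malignant_only",
           "rc-77 n/e only" = "non_malignant_only",
           "malignant_only" = "malignant_only",
           "non_malignant_only" = "non_malignant_only",
           "not_significant" = "not_significant")
  st <- map[tolower(trimws(df$status))]
  if (any(is.na(st)))
    stop("unknown status label: ", df$status[is.na(st)][1])
  df$status <- unname(st)
  df
}

#' Summarise a differential-expression table
#'
#' Counts records by fold-change sign and by single-line detection status.
#'
#' @param records data.frame as returned by [read_dep_records()] or the
#'   `records` element of [run_differential_expression()].
#' @param dep_only Restrict to differentially expressed records (status not
#'   `not_significant`).
#' @return Named list: `n`, `n_negative`, `n_positive`, `n_malignant_only`,
#'   `n_non_malignant_only`.
#' @export
summarize_dep_records <- function(records, dep_only = TRUE) {
  r <- records
  if (dep_only) r <- r[r$status != "not_significant", , drop = FALSE]
  list(n = nrow(r),
       n_negative = sum(r$log2_fc < 0),
       n_positive = sum(r$log2_fc > 0),
       n_malignant_only = sum(r$status == "malignant_only"),
       n_non_malignant_only = sum(r$status == "non_malignant_only"))
}
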