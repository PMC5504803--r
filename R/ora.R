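#' Construct an annotation database
#'
#' Maps annotation categories (protein classes, ontology terms, pathways) to
#' member genes, against a declared reference background. For projected
#' databases (where the file lists only genes seen in some experiment while
#' the true class size in the reference genome is larger) a per-category
#' declared size `K` can be supplied; the declared size wins over the
#' membership count in the overrepresentation test.
#'
#' @param categories Named list of character vectors of gene identifiers.
#' @param background_size Total genes in the reference background (N).
#' @param category_sizes Optional named integer vector of declared class
#'   sizes K; defaults to the membership counts.
#' @return An object of class `"annotation_db"`.
#' @export
annotation_db <- function(categories, background_size,
                          category_sizes = NULL) {
  stopifnot(is.list(categories), length(categories) > 0)
  if (is.null(names(categories)) || anyDuplicated(names(categories)))
    stop("categories must have unique names")
  background_size <- as.integer(background_size)
  sizes <- vapply(categories, length, integer(1))
  if (is.null(category_sizes)) {
    category_sizes <- sizes
  } else {
    category_sizes <- category_sizes[names(categories)]
    missing <- is.na(category_sizes)
    category_sizes[missing] <- sizes[missing]
    low <- category_sizes < sizes
    if (any(low)) {
      warning("declared K below membership count for: ",
              paste(names(categories)[low], collapse = ", "),
              "; raising to membership count")
      category_sizes[low] <- sizes[low]
    }
  }
  category_sizes <- as.integer(category_sizes)
  names(category_sizes) <- names(categories)
  if (any(category_sizes > background_size))
    stop("category size exceeds background size")
  structure(list(categories = lapply(categories, as.character),
                 background_size = background_size,
                 category_sizes = category_sizes),
            class = "annotation_db")
}

#' @export
print.annotation_db <- function(x, ...) {
  cat("annotation_db:", length(x$categories), "categories, background N =",
      x$background_size, "\n")
  invisible(x)
}

#' Read an annotation database from long-format TSV
#'
#' Expects columns `category` and `gene_id` (one membership per row). An
#' optional sidecar TSV declares `background_size` (single row, column
#' `background_size`) and per-category sizes (columns `category`, `K`).
#'
#' @param path Long-format membership TSV.
#' @param sidecar_path Optional sidecar TSV with declared sizes.
#' @param background_size Background size used when no sidecar declares one;
#'   defaults to the number of distinct genes in the file.
#' @return An [annotation_db()].
#' @export
read_annotation_db <- function(path, sidecar_path = NULL,
                               background_size = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("category", "gene_id") %in% names(df)))
    stop("annotation TSV needs 'category' and 'gene_id' columns")
  cats <- lapply(split(as.character(df$gene_id), df$category), unique)
  sizes <- NULL
  if (!is.null(sidecar_path)) {
    sc <- utils::read.delim(sidecar_path, stringsAsFactors = FALSE)
    if ("background_size" %in% names(sc))
      background_size <- sc$background_size[!is.na(sc$background_size)][1]
    if (all(c("category", "K") %in% names(sc))) {
      ok <- !is.na(sc$category) & !is.na(sc$K)
      sizes <- stats::setNames(as.integer(sc$K[ok]), sc$category[ok])
    }
  }
  if (is.null(background_size))
    background_size <- length(unique(df$gene_id))
  annotation_db(cats, background_size, sizes)
}

#' Count annotation-category members of a gene list
#'
#' @param genes Character vector of gene identifiers.
#' @param db An [annotation_db()].
#' @return List with `counts` (named integer vector over every category,
#'   zeros included) and `unannotated` (genes belonging to no category).
#' @export
count_category_members <- function(genes, db) {
  stopifnot(inherits(db, "annotation_db"))
  genes <- unique(as.character(genes))
  counts <- vapply(db$categories,
                   function(m) length(intersect(genes, m)), integer(1))
  annotated <- unique(unlist(db$categories, use.names = FALSE))
  list(counts = counts, unannotated = setdiff(genes, annotated))
}

#' Hypergeometric overrepresentation probability
#'
#' Upper-tail probability P(X >= k) that at least `observed_k` of
#' `sample_size_n` genes drawn without replacement from a background of
#' `background_N` genes fall in a class of size `class_size_K`.
#'
#' @param observed_k Observed members in the gene list.
#' @param class_size_K Class size in the background.
#' @param sample_size_n Size of the gene list.
#' @param background_N Background (reference genome) size.
#' @return Upper-tail hypergeometric probability; 1 when `observed_k` is 0.
#' @export
overrepresentation_test <- function(observed_k, class_size_K,
                                    sample_size_n, background_N) {
  k <- as.integer(observed_k); K <- as.integer(class_size_K)
  n <- as.integer(sample_size_n); N <- as.integer(background_N)
  if (K > N || n > N || k > min(n, K) || min(k, K, n, N) < 0)
    stop("inconsistent hypergeometric counts (k=", k, ", K=", K,
         ", n=", n, ", N=", N, ")")
  stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
}

#' Overrepresentation analysis of a gene list
#'
#' Tests every category of the database for overrepresentation among
#' `genes` with the one-sided hypergeometric upper tail, and adjusts across
#' categories by Benjamini-Hochberg.
#'
#' @param genes Character vector of gene identifiers (the DEP list).
#' @param db An [annotation_db()].
#' @param alpha Significance threshold applied to q-values in the
#'   `significant` column (default 0.05).
#' @return data.frame sorted by p-value with columns `category`,
#'   `class_size_K`, `sample_size_n`, `observed_k`, `expected`, `p_value`,
#'   `q_value`, `significant`.
#' @export
run_ora <- function(genes, db, alpha = 0.05) {
  stopifnot(inherits(db, "annotation_db"))
  genes <- unique(as.character(genes))
  n <- length(genes)
  cc <- count_category_members(genes, db)$counts
  K <- db$category_sizes
  # observed overlap can exceed declared K only through inconsistent input
  k <- pmin(cc, K)
  N <- db$background_size
  p <- vapply(seq_along(k), function(i)
    overrepresentation_test(k[i], K[i], n, N), numeric(1))
  res <- data.frame(category = names(k),
                    class_size_K = unname(K),
                    sample_size_n = n,
                    observed_k = unname(k),
                    expected = n * unname(K) / N,
                    p_value = p,
                    q_value = bh_adjust(p),
                    stringsAsFactors = FALSE)
  res$significant <- res$q_value < alpha
  res <- res[order(res$p_value, res$category), ]
  rownames(res) <- NULL
  res
}

#' Resampling validation of overrepresentation calls
#'
#' Draws `n_iter` random gene subsets of the same size as the DEP list from
#' a reference pool (the non-differentially-expressed proteins, or all
#' identified proteins), repeats the full overrepresentation analysis on
#' each subset, and counts, per category, in how many subsets the category
#' is significantly overrepresented after FDR adjustment. A category that
#' is rarely significant among random subsets is unlikely to be enriched in
#' the real DEP list by chance.
#'
#' @param dep_count Size of each random subset (the number of DEPs).
#' @param pool Character vector of gene identifiers to sample from.
#' @param db An [annotation_db()].
#' @param n_iter Number of random subsets (default 1000).
#' @param alpha Per-subset FDR significance threshold (default 0.05).
#' @param seed Integer seed; the run is fully reproducible from it.
#' @return data.frame with columns `category`, `n_significant`, `n_iter`,
#'   `empirical_confidence` (percent of subsets in which the category was
#'   \emph{not} significant).
#' @export
resample_validation <- function(dep_count, pool, db, n_iter = 1000,
                                alpha = 0.05, seed = NULL) {
  stopifnot(inherits(db, "annotation_db"))
  pool <- unique(as.character(pool))
  if (length(pool) < dep_count)
    stop("pool (", length(pool), ") smaller than dep_count (",
         dep_count, ")")
  if (!is.null(seed)) set.seed(seed)
  # indicator matrix: category x pool gene, so each draw is a column sum
  ind <- vapply(db$categories, function(m) pool %in% m,
                logical(length(pool)))
  K <- db$category_sizes
  N <- db$background_size
  n_sig <- integer(length(db$categories))
  for (b in seq_len(n_iter)) {
    draw <- sample.int(length(pool), dep_count)
    k <- pmin(colSums(ind[draw, , drop = FALSE]), K)
    p <- stats::phyper(k - 1L, K, N - K, dep_count, lower.tail = FALSE)
    n_sig <- n_sig + (bh_adjust(p) < alpha)
  }
  data.frame(category = names(db$categories),
             n_significant = n_sig,
             n_iter = n_iter,
             empirical_confidence = empirical_confidence(n_sig, n_iter),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Empirical confidence from a resampling validation
#'
#' Percent of random subsets in which a category was \emph{not} called
#' significantly overrepresented: `100 * (1 - n_significant / n_iter)`.
#' For example, a category significant in 2 of 1000 random subsets has
#' 99.8% empirical confidence that its observed overrepresentation is not a
#' chance property of equally sized random lists.
#'
#' @param n_significant Number of significant subsets (vectorised).
#' @param n_iter Number of subsets drawn.
#' @return Confidence in percent.
#' @export
empirical_confidence <- function(n_significant, n_iter) {
  if (any(n_iter == 0)) stop("n_iter must be positive")
  if (any(n_significant < 0) || any(n_significant > n_iter))
    stop("n_significant must lie in [0, n_iter]")
  100 * (1 - n_significant / n_iter)
}
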