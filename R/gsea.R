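#' Read a GMT gene-set collection
#'
#' Standard tab format: one set per line, `name<TAB>description<TAB>member...`.
#'
#' @param path GMT file path.
#' @param source Provenance tag stored on the collection.
#' @return Object of class `"gene_set_collection"`: a named list of
#'   character vectors with a `source` attribute.
#' @export
read_gmt <- function(path, source = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 3L
  if (any(bad))
    stop("malformed GMT line ", which(bad)[1], ": fewer than 3 fields")
  sets <- lapply(parts, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1L)
  if (anyDuplicated(names(sets)))
    stop("duplicate set name: ", names(sets)[duplicated(names(sets))][1])
  gene_set_collection(sets, source = source)
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @export
gene_set_collection <- function(sets, source = "user") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (any(vapply(sets, length, 1L) == 0L))
    stop("empty gene set: ", names(sets)[vapply(sets, length, 1L) == 0][1])
  structure(lapply(sets, as.character), source = source,
            class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#' @param collection A `gene_set_collection`.
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection), function(nm)
    paste(c(nm, attr(collection, "source"), collection[[nm]]),
          collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Filter gene sets by effective size
#'
#' The effective size of a set is its overlap with the genes actually
#' present in the data; sets outside `[min_size, max_size]` (inclusive) are
#' dropped.
#'
#' @param collection A `gene_set_collection`.
#' @param data_genes Genes present in the expression data.
#' @param min_size,max_size Inclusive effective-size bounds (defaults 5 and
#'   500).
#' @return Filtered `gene_set_collection`.
#' @export
filter_sets <- function(collection, data_genes, min_size = 5,
                        max_size = 500) {
  eff <- vapply(collection, function(s)
    length(intersect(s, data_genes)), integer(1))
  keep <- eff >= min_size & eff <= max_size
  gene_set_collection(collection[keep], source = attr(collection, "source"))
}

# Signal-to-noise with the conventional standard-deviation floor:
# sd is raised to 0.2 * |mean|, and to 0.2 when the mean is 0.
floored_sd <- function(s, m) {
  s <- pmax(s, 0.2 * abs(m))
  s[m == 0] <- pmax(s[m == 0], 0.2)
  s
}

#' Rank genes by association with the malignant phenotype
#'
#' Scores every mapped gene (proteins without a gene identifier are
#' excluded) by its differential association with the malignant versus
#' non-malignant samples and returns the descending ranked list used by the
#' enrichment-score walk. Positive scores mean higher abundance in the
#' malignant line.
#'
#' @param x A processed [spectral_count_matrix()].
#' @param metric `"signal_to_noise"` (difference of group means over the sum
#'   of floored group standard deviations) or `"difference_of_means"`.
#' @return data.frame (`gene`, `score`) in descending score order; ties are
#'   broken lexicographically by gene for determinism.
#' @export
rank_by_association <- function(x, metric = c("signal_to_noise",
                                              "difference_of_means")) {
  stopifnot(inherits(x, "spectral_count_matrix"))
  metric <- match.arg(metric)
  keep <- !x$proteins$id_missing
  counts <- x$counts[keep, , drop = FALSE]
  gene <- ifelse(is.na(x$proteins$gene_symbol[keep]),
                 x$proteins$accession[keep], x$proteins$gene_symbol[keep])
  t_idx <- x$samples$cell_line == "malignant"
  if (metric == "signal_to_noise" &&
      (sum(t_idx) < 2L || sum(!t_idx) < 2L))
    stop("signal_to_noise needs at least 2 samples per class")
  ct <- counts[, t_idx, drop = FALSE]
  cn <- counts[, !t_idx, drop = FALSE]
  mt <- rowMeans(ct); mn <- rowMeans(cn)
  score <- switch(metric,
    signal_to_noise = {
      st <- floored_sd(apply(ct, 1, stats::sd), mt)
      sn <- floored_sd(apply(cn, 1, stats::sd), mn)
      (mt - mn) / (st + sn)
    },
    difference_of_means = mt - mn)
  ord <- order(-score, gene)
  data.frame(gene = gene[ord], score = unname(score[ord]),
             stringsAsFactors = FALSE)
}

# Enrichment score from sorted hit positions. w are the |score|^exponent
# weights for the whole ranked list; idx the (sorted) positions of set
# members. Extrema of the running sum occur at hits (candidates for the
# maximum) or just before hits (candidates for the minimum). Returns the
# signed extremum and the peak hit index (for the leading edge).
es_from_positions <- function(idx, w, L) {
  m <- length(idx)
  wh <- w[idx]
  W <- sum(wh)
  cum_hit <- if (W > 0) cumsum(wh) / W else seq_len(m) / m
  miss_before <- (idx - seq_len(m)) / (L - m)
  top <- cum_hit - miss_before            # running sum right after each hit
  bottom <- c(0, cum_hit[-m]) - miss_before  # just before each hit
  hi <- max(top, 0)
  lo <- min(bottom, 0)
  if (hi >= -lo)
    list(es = hi, peak = if (hi > 0) which.max(top) else 0L, positive = TRUE)
  else
    list(es = lo, peak = which.min(bottom), positive = FALSE)
}

#' Weighted running-sum enrichment score
#'
#' Walks down the ranked list; at each set member the running sum gains that
#' gene's weight `|score|^weight_exponent` (normalised over the set), at
#' each non-member it loses `1 / (L - G)`. The enrichment score is the
#' signed extremum of the walk and the leading edge is the set members up
#' to (positive score) or from (negative score) the extremum.
#'
#' @param ranked data.frame (`gene`, `score`) from [rank_by_association()].
#' @param gene_set Character vector of set members.
#' @param weight_exponent Weighting of ranking scores (0 = classical
#'   unweighted Kolmogorov-Smirnov walk; default 1).
#' @return List with `es` (in \[-1, 1\]) and `leading_edge` (genes in rank
#'   order).
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  L <- nrow(ranked)
  hits <- ranked$gene %in% gene_set
  idx <- which(hits)
  if (length(idx) == 0L)
    stop("gene set has no overlap with the ranked list")
  if (length(idx) == L)
    stop("gene set covers the entire ranked list")
  w <- abs(ranked$score)^weight_exponent
  r <- es_from_positions(idx, w, L)
  le <- if (r$positive) idx[seq_len(r$peak)] else idx[idx >= idx[r$peak]]
  list(es = r$es, leading_edge = ranked$gene[le])
}

#' Gene set enrichment analysis with permutation significance
#'
#' Full enrichment analysis of a phenotype-ranked spectral-count matrix:
#' size-filters the collection, computes each set's weighted running-sum
#' enrichment score and leading edge, builds a signed permutation null
#' (random gene sets of equal size by default, or phenotype label
#' permutation), and derives nominal p-values, normalized enrichment scores
#' (score over the mean same-signed null score) and FDR q-values by the
#' pooled same-sign null-NES ratio estimator.
#'
#' @param x A processed [spectral_count_matrix()].
#' @param collection A `gene_set_collection`.
#' @param n_perm Number of permutations (default 1000; fewer than 100 draws
#'   a warning, 0 is an error).
#' @param permutation_scheme `"gene_set"` (default; appropriate for small
#'   replicate numbers) or `"phenotype"`.
#' @param seed Integer seed for reproducibility.
#' @param metric Ranking metric, see [rank_by_association()].
#' @param weight_exponent See [enrichment_score()].
#' @param min_size,max_size Effective-size filter bounds.
#' @return data.frame with one row per retained set: `set_name`,
#'   `effective_size`, `es`, `nes`, `p_value`, `q_value`, `direction`
#'   (`"malignant"` for positive scores), `leading_edge`
#'   (comma-separated), sorted by p-value.
#' @export
gsea_significance <- function(x, collection, n_perm = 1000,
                              permutation_scheme = c("gene_set",
                                                     "phenotype"),
                              seed = NULL,
                              metric = "signal_to_noise",
                              weight_exponent = 1,
                              min_size = 5, max_size = 500) {
  permutation_scheme <- match.arg(permutation_scheme)
  if (n_perm == 0) stop("n_perm must be positive")
  if (n_perm < 100) warning("fewer than 100 permutations: p-values coarse")
  if (!is.null(seed)) set.seed(seed)
  ranked <- rank_by_association(x, metric = metric)
  collection <- filter_sets(collection, ranked$gene, min_size, max_size)
  if (length(collection) == 0L)
    stop("no gene set passed the size filter")
  L <- nrow(ranked)
  w <- abs(ranked$score)^weight_exponent
  obs <- lapply(collection, function(s) {
    r <- enrichment_score(ranked, s, weight_exponent)
    r$effective_size <- length(intersect(s, ranked$gene))
    r
  })
  es <- vapply(obs, `[[`, numeric(1), "es")
  sizes <- vapply(obs, `[[`, integer(1), "effective_size")

  null_es <- matrix(0, nrow = n_perm, ncol = length(collection))
  if (permutation_scheme == "gene_set") {
    for (b in seq_len(n_perm)) {
      for (j in seq_along(collection)) {
        idx <- sort.int(sample.int(L, sizes[j]))
        null_es[b, j] <- es_from_positions(idx, w, L)$es
      }
    }
  } else {
    lab <- x$samples$cell_line
    for (b in seq_len(n_perm)) {
      xp <- x
      xp$samples$cell_line <- sample(lab)
      rp <- rank_by_association(xp, metric = metric)
      wp <- abs(rp$score)^weight_exponent
      for (j in seq_along(collection)) {
        idx <- which(rp$gene %in% collection[[j]])
        null_es[b, j] <- es_from_positions(idx, wp, L)$es
      }
    }
  }

  norm_one <- function(v, pos_mean, neg_mean)
    ifelse(v >= 0, v / pos_mean, v / neg_mean)
  nes <- numeric(length(es))
  p <- numeric(length(es))
  null_nes <- null_es
  for (j in seq_along(es)) {
    nj <- null_es[, j]
    pos_mean <- mean(nj[nj > 0]); neg_mean <- mean(abs(nj[nj < 0]))
    if (!is.finite(pos_mean)) pos_mean <- 1
    if (!is.finite(neg_mean)) neg_mean <- 1
    null_nes[, j] <- norm_one(nj, pos_mean, neg_mean)
    nes[j] <- norm_one(es[j], pos_mean, neg_mean)
    p[j] <- if (es[j] >= 0)
      (sum(nj >= es[j]) + 1) / (sum(nj >= 0) + 1)
    else
      (sum(nj <= es[j]) + 1) / (sum(nj < 0) + 1)
  }

  pool <- as.vector(null_nes)
  q <- vapply(seq_along(nes), function(j) {
    if (nes[j] >= 0) {
      null_frac <- sum(pool >= nes[j]) / max(sum(pool >= 0), 1)
      obs_frac <- sum(nes >= nes[j]) / max(sum(nes >= 0), 1)
    } else {
      null_frac <- sum(pool <= nes[j]) / max(sum(pool < 0), 1)
      obs_frac <- sum(nes <= nes[j]) / max(sum(nes < 0), 1)
    }
    min(1, null_frac / obs_frac)
  }, numeric(1))

  res <- data.frame(
    set_name = names(collection),
    effective_size = unname(sizes),
    es = unname(es),
    nes = unname(nes),
    p_value = unname(p),
    q_value = unname(q),
    direction = ifelse(es >= 0, "malignant", "non_malignant"),
    leading_edge = vapply(obs, function(r)
      paste(r$leading_edge, collapse = ","), ""),
    stringsAsFactors = FALSE, row.names = NULL)
  res <- res[order(res$p_value, -abs(res$nes), res$set_name), ]
  rownames(res) <- NULL
  res
}
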