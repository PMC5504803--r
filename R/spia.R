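#' Default interaction-type weights for pathway topologies
#'
#' Activating/expression edges propagate with +1, inhibitory/repression
#' edges with -1, and physical binding/association edges carry no signed
#' influence (0). User maps override or extend these.
#' @export
default_type_weights <- c(activation = 1, expression = 1,
                          inhibition = -1, repression = -1,
                          binding = 0, association = 0)

#' Construct a pathway topology
#'
#' @param pathway_id,pathway_name Identifiers of the pathway.
#' @param genes Ordered character vector of pathway genes.
#' @param beta Square signed interaction matrix: `beta[i, j]` is the effect
#'   of gene `j` on gene `i`.
#' @return Object of class `"pathway_topology"` with the per-gene
#'   downstream-target count `n_downstream` (nonzero entries in each
#'   gene's column).
#' @export
pathway_topology <- function(pathway_id, genes, beta,
                             pathway_name = pathway_id) {
  genes <- as.character(genes)
  beta <- as.matrix(beta)
  if (nrow(beta) != length(genes) || ncol(beta) != length(genes))
    stop("beta dimensions must match the gene list")
  dimnames(beta) <- list(genes, genes)
  structure(list(pathway_id = pathway_id, pathway_name = pathway_name,
                 genes = genes, beta = beta,
                 n_downstream = colSums(beta != 0)),
            class = "pathway_topology")
}

#' @export
print.pathway_topology <- function(x, ...) {
  cat("pathway_topology", x$pathway_id, "(", x$pathway_name, "):",
      length(x$genes), "genes,", sum(x$beta != 0), "edges\n")
  invisible(x)
}

#' Load signed pathway topologies from an edge-list TSV
#'
#' Edge rows carry `source`, `target`, `type` and `sign` columns (sign is a
#' +-1 multiplier on the type weight); an optional `pathway_id` column
#' allows several pathways in one file. Duplicate edges have their weights
#' summed (with a warning); self-loops are permitted.
#'
#' @param path Edge-list TSV.
#' @param type_weights Named map from relation type to signed weight;
#'   unknown types are an error.
#' @param pathway_name Optional named map id -> display name.
#' @return A single `pathway_topology` if the file holds one pathway, else
#'   a named list of them.
#' @export
load_topology <- function(path, type_weights = default_type_weights,
                          pathway_name = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("source", "target", "type", "sign")
  if (!all(need %in% names(df)))
    stop("edge list needs columns: ", paste(need, collapse = ", "))
  if (!"pathway_id" %in% names(df))
    df$pathway_id <- "pathway1"
  unknown <- setdiff(unique(df$type), names(type_weights))
  if (length(unknown))
    stop("unknown relation type without a declared weight: ",
         paste(unknown, collapse = ", "))
  build <- function(e, id) {
    genes <- sort(unique(c(e$source, e$target)))
    beta <- matrix(0, length(genes), length(genes),
                   dimnames = list(genes, genes))
    wt <- unname(type_weights[e$type]) * e$sign
    key <- paste(e$target, e$source)
    if (anyDuplicated(key))
      warning("duplicate edges in pathway ", id, ": weights summed")
    for (r in seq_len(nrow(e)))
      beta[e$target[r], e$source[r]] <- beta[e$target[r], e$source[r]] + wt[r]
    nm <- if (!is.null(pathway_name) && id %in% names(pathway_name))
      pathway_name[[id]] else id
    pathway_topology(id, genes, beta, pathway_name = nm)
  }
  out <- lapply(split(df, df$pathway_id), function(e)
    build(e, e$pathway_id[1]))
  if (length(out) == 1L) out[[1]] else out
}

#' Write a pathway topology as an edge-list TSV
#' @param topology A `pathway_topology` or list of them.
#' @param path Output path.
#' @export
write_topology <- function(topology, path) {
  if (inherits(topology, "pathway_topology")) topology <- list(topology)
  rows <- do.call(rbind, lapply(topology, function(tp) {
    nz <- which(tp$beta != 0, arr.ind = TRUE)
    if (nrow(nz) == 0) return(NULL)
    data.frame(pathway_id = tp$pathway_id,
               source = tp$genes[nz[, 2]],
               target = tp$genes[nz[, 1]],
               type = ifelse(tp$beta[nz] > 0, "activation", "inhibition"),
               sign = 1L,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Normalised influence matrix B with B[i, j] = beta[i, j] / n_downstream(j),
# and the system matrix A = I - B (possibly damped when singular).
spia_system_matrix <- function(topology, max_damp = 100) {
  nds <- pmax(topology$n_downstream, 1)
  B <- sweep(topology$beta, 2, nds, "/")
  A <- diag(length(topology$genes)) - B
  damp <- 0L
  while (rcond(A) < 1e-12 && damp < max_damp) {
    B <- B * 0.99
    A <- diag(length(topology$genes)) - B
    damp <- damp + 1L
  }
  if (rcond(A) < 1e-12)
    stop("unresolvably singular system for pathway ", topology$pathway_id)
  if (damp > 0)
    message("pathway ", topology$pathway_id, ": singular system, beta ",
            "damped by 0.99^", damp)
  A
}

#' Perturbation accumulation over a signed pathway topology
#'
#' Solves the linear propagation system
#' `PF(g_i) = dE(g_i) + sum_j beta_ij PF(g_j) / N_ds(g_j)`
#' for the per-gene perturbation factors PF, where dE are the observed log2
#' expression changes of the differentially expressed genes (zero
#' elsewhere) and `N_ds` the number of downstream targets of each gene. The
#' per-gene net accumulation is `Acc = PF - dE` and the pathway's total net
#' perturbation `t_a = sum(Acc)`. A singular system is iteratively damped
#' (beta scaled by 0.99) before giving up.
#'
#' @param topology A `pathway_topology`.
#' @param delta_e Named numeric vector of signed log2 fold changes; genes
#'   absent from the topology are dropped with a warning, topology genes
#'   without an entry get 0.
#' @return List with `pf`, `acc` (named per-gene vectors) and `t_a`.
#' @export
perturbation_accumulation <- function(topology, delta_e) {
  stopifnot(inherits(topology, "pathway_topology"))
  extra <- setdiff(names(delta_e), topology$genes)
  if (length(extra))
    warning("genes not on pathway ", topology$pathway_id, " dropped: ",
            paste(extra, collapse = ", "))
  de <- stats::setNames(numeric(length(topology$genes)), topology$genes)
  keep <- intersect(names(delta_e), topology$genes)
  de[keep] <- delta_e[keep]
  A <- spia_system_matrix(topology)
  pf <- drop(solve(A, de))
  acc <- pf - de
  list(pf = pf, acc = acc, t_a = sum(acc))
}

#' Pathway overrepresentation probability
#'
#' Hypergeometric upper-tail probability that at least `nde_on_pathway` of
#' the `total_de` differentially expressed genes land on a pathway of
#' `pathway_size` genes when drawn from `background` measured genes. Shares
#' the [overrepresentation_test()] kernel.
#'
#' @param nde_on_pathway DE genes observed on the pathway.
#' @param total_de Total DE genes in the experiment.
#' @param pathway_size Measured genes on the pathway.
#' @param background Total measured genes with identifiers.
#' @return Upper-tail probability.
#' @export
p_nde <- function(nde_on_pathway, total_de, pathway_size, background) {
  overrepresentation_test(nde_on_pathway, pathway_size, total_de,
                          background)
}

#' Bootstrap perturbation probability
#'
#' Builds the null distribution of the total net perturbation `t_a` by
#' repeatedly reassigning the observed log2 changes to genes drawn
#' uniformly from the pathway, recomputing `t_a` each round. The null is
#' median-centred and the p-value is the doubled one-sided tail in the
#' observed direction with a `(count + 1) / (n_boot + 1)` correction, so an
#' observation at the null median gives p near 1 and p never reaches 0.
#'
#' @param topology A `pathway_topology`.
#' @param observed_delta_e Named nonzero log2 changes of the DE genes on
#'   the pathway.
#' @param n_boot Bootstrap rounds (default 2000).
#' @param seed Integer seed.
#' @return List with `p_pert`, `t_a` (observed) and `t_a_null`.
#' @export
p_pert_bootstrap <- function(topology, observed_delta_e, n_boot = 2000,
                             seed = NULL) {
  stopifnot(inherits(topology, "pathway_topology"))
  vals <- observed_delta_e[names(observed_delta_e) %in% topology$genes]
  nde <- length(vals)
  if (nde == 0L) stop("no DE gene on pathway ", topology$pathway_id)
  if (!is.null(seed)) set.seed(seed)
  A <- spia_system_matrix(topology)
  # t_a = sum(solve(A, de) - de) is linear in de: t_a = a . de with
  # a = colSums(solve(A)) - 1, so the bootstrap is a cheap dot product.
  a <- colSums(solve(A)) - 1
  idx_obs <- match(names(vals), topology$genes)
  t_obs <- sum(a[idx_obs] * vals)
  ng <- length(topology$genes)
  t_null <- vapply(seq_len(n_boot), function(b)
    sum(a[sample.int(ng, nde)] * vals), numeric(1))
  med <- stats::median(t_null)
  obs_c <- t_obs - med
  null_c <- t_null - med
  count <- if (obs_c >= 0) sum(null_c >= obs_c) else sum(null_c <= obs_c)
  p <- min(1, 2 * (count + 1) / (n_boot + 1))
  list(p_pert = p, t_a = t_obs, t_a_null = t_null)
}

#' Combine overrepresentation and perturbation probabilities
#'
#' Treats the two probabilities as independent uniforms under the null and
#' returns the probability that their product is at most the observed
#' product: `p_g = c - c * ln(c)` with `c = p_nde * p_pert` (and
#' `p_g(1, 1) = 1` by continuity). Symmetric and monotone increasing in
#' each argument.
#'
#' @param p_nde,p_pert Probabilities in (0, 1].
#' @return Combined global probability.
#' @export
combine_global <- function(p_nde, p_pert) {
  if (any(p_nde <= 0 | p_nde > 1) || any(p_pert <= 0 | p_pert > 1))
    stop("probabilities must lie in (0, 1]")
  cc <- p_nde * p_pert
  cc - cc * log(cc)
}

#' Topology-based pathway impact analysis
#'
#' For every pathway with at least one differentially expressed gene,
#' combines (i) the hypergeometric overrepresentation probability of the DE
#' genes on the pathway and (ii) the bootstrap probability of the total net
#' accumulated perturbation obtained by propagating the observed log2
#' changes over the signed topology, into a global probability, adjusted by
#' Benjamini-Hochberg across pathways. A pathway is called `inhibited` when
#' its total net perturbation is negative, `activated` otherwise.
#'
#' @param de_results `records` data.frame from
#'   [run_differential_expression()] (or any data.frame with `gene_symbol`,
#'   `q_value`, `log2_fc` and optionally `id_missing`).
#' @param topologies A `pathway_topology` or list of them.
#' @param de_threshold FDR cut-off defining DE membership (default 0.1).
#' @param n_boot Bootstrap rounds per pathway (default 2000).
#' @param seed Integer seed; per-pathway streams are derived from it.
#' @param background Number of measured genes used in the
#'   overrepresentation probability; defaults to the number of mapped genes
#'   in `de_results`.
#' @return data.frame sorted by adjusted global probability: `pathway_id`,
#'   `name`, `nde`, `p_nde`, `t_a`, `p_pert`, `p_g`, `p_g_fdr`, `status`.
#'   Pathways without DE genes are skipped; all skipped means an empty
#'   result.
#' @export
run_spia <- function(de_results, topologies, de_threshold = 0.1,
                     n_boot = 2000, seed = NULL, background = NULL) {
  if (inherits(topologies, "pathway_topology"))
    topologies <- stats::setNames(list(topologies),
                                  topologies$pathway_id)
  records <- de_results
  if ("id_missing" %in% names(records))
    records <- records[!records$id_missing, , drop = FALSE]
  measured <- unique(records$gene_symbol)
  if (is.null(background)) background <- length(measured)
  de <- records[records$q_value < de_threshold, , drop = FALSE]
  delta_e <- stats::setNames(de$log2_fc, de$gene_symbol)
  total_de <- length(delta_e)
  if (!is.null(seed)) set.seed(seed)
  pathway_seeds <- sample.int(.Machine$integer.max, length(topologies))
  rows <- lapply(seq_along(topologies), function(i) {
    tp <- topologies[[i]]
    on_path <- intersect(tp$genes, measured)
    vals <- delta_e[names(delta_e) %in% tp$genes]
    nde <- length(vals)
    if (nde == 0L) return(NULL)
    pn <- p_nde(nde, total_de, max(length(on_path), nde), background)
    boot <- p_pert_bootstrap(tp, vals, n_boot = n_boot,
                             seed = pathway_seeds[i])
    data.frame(pathway_id = tp$pathway_id, name = tp$pathway_name,
               nde = nde, p_nde = pn, t_a = boot$t_a,
               p_pert = boot$p_pert,
               p_g = combine_global(pn, boot$p_pert),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(data.frame(pathway_id = character(), name = character(),
                      nde = integer(), p_nde = numeric(), t_a = numeric(),
                      p_pert = numeric(), p_g = numeric(),
                      p_g_fdr = numeric(), status = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  res$p_g_fdr <- bh_adjust(res$p_g)
  res$status <- ifelse(res$t_a < 0, "inhibited", "activated")
  res <- res[order(res$p_g_fdr, res$p_g, res$pathway_id), ]
  rownames(res) <- NULL
  res
}
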