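#' Protein-class sizes of a reference annotation
#'
#' Default class sizes for the synthetic annotation database: realistic
#' PANTHER-style protein-class sizes against a reference human
#' genome/proteome of 20,814 genes (e.g. cytoskeletal protein 198,
#' nucleic acid binding 2332).
#' @export
default_class_sizes <- c(
  "cytoskeletal protein" = 198L,
  "storage protein" = 25L,
  "chaperone" = 183L,
  "transmembrane receptor regulatory" = 65L,
  "lyase" = 151L,
  "nucleic acid binding" = 2332L,
  "cell junction protein" = 140L,
  "isomerase" = 162L,
  "cell adhesion molecule" = 458L,
  "extracellular matrix protein" = 363L,
  "transfer/carrier protein" = 364L,
  "protease" = 586L,
  "membrane traffic protein" = 372L,
  "oxidoreductase" = 593L,
  "kinase" = 699L,
  "hydrolase" = 1482L,
  "defense/immunity protein" = 561L,
  "transferase" = 1198L,
  "signaling molecule" = 1083L,
  "transporter" = 920L,
  "enzyme modulator" = 1353L,
  "transcription factor" = 1451L,
  "receptor" = 1813L)

#' Simulate a spectral-count matrix with planted effects
#'
#' Generates overdispersed (negative binomial) protein spectral counts for
#' a paired malignant/non-malignant design with technical replicates nested
#' in biological replicates: every technical triplicate shares a log-normal
#' biological-replicate random effect on its negative-binomial mean. A
#' configurable fraction of genes carries a planted malignant-vs-normal
#' shift of `2^effect_log2`; a fraction of those are additionally zeroed in
#' their low line, creating detected-in-one-line-only proteins.
#'
#' @param n_genes Number of genes (default 833, the size of a processed
#'   cell-line proteome at this acquisition depth).
#' @param n_bio,n_tech Biological replicates per line and technical
#'   replicates per biological replicate (defaults 3 and 3).
#' @param frac_dep Fraction of genes with a planted effect (default 0.076).
#' @param effect_log2 Planted |log2 fold change| (default 2).
#' @param up_frac Fraction of planted genes shifted up in the malignant
#'   line (default 0.73).
#' @param dropout_frac Fraction of planted genes zeroed in their low line
#'   (default 0.32).
#' @param dispersion Negative-binomial dispersion (default 0.15; the NB
#'   size parameter is its reciprocal).
#' @param bio_sd Standard deviation of the log-normal biological-replicate
#'   effect (default 0.15).
#' @param baseline_mean Optional per-gene baseline means (recycled);
#'   default log-normal around a median of ~6 counts.
#' @param seed Integer seed; the matrix is a pure function of the
#'   parameters and the seed.
#' @return List with `matrix` (a [spectral_count_matrix()]) and `truth`
#'   (data.frame `gene_symbol`, `status` in
#'   `{null, up, down, t_only, n_only}`, `true_log2_effect`, and the seed
#'   as an attribute).
#' @export
simulate_spectral_counts <- function(n_genes = 833, n_bio = 3, n_tech = 3,
                                     frac_dep = 0.076, effect_log2 = 2,
                                     up_frac = 0.73, dropout_frac = 0.32,
                                     dispersion = 0.15, bio_sd = 0.15,
                                     baseline_mean = NULL, seed = NULL) {
  if (frac_dep < 0 || frac_dep > 1 || up_frac < 0 || up_frac > 1 ||
      dropout_frac < 0 || dropout_frac > 1)
    stop("fractions must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(baseline_mean))
    baseline_mean <- stats::rlnorm(n_genes, meanlog = log(6), sdlog = 1.1)
  baseline_mean <- rep_len(baseline_mean, n_genes)

  n_dep <- round(frac_dep * n_genes)
  dep_idx <- if (n_dep > 0) sample.int(n_genes, n_dep) else integer(0)
  n_up <- round(up_frac * n_dep)
  up_idx <- dep_idx[seq_len(n_up)]
  down_idx <- setdiff(dep_idx, up_idx)
  effect <- numeric(n_genes)
  effect[up_idx] <- effect_log2
  effect[down_idx] <- -effect_log2
  n_drop <- round(dropout_frac * n_dep)
  drop_idx <- if (n_drop > 0) sample(dep_idx, n_drop) else integer(0)

  lines <- c("malignant", "non_malignant")
  samples <- expand.grid(tech_rep = seq_len(n_tech),
                         bio_rep = seq_len(n_bio),
                         cell_line = lines, stringsAsFactors = FALSE)
  samples$sample_id <- sprintf("%s_b%d_t%d",
                               ifelse(samples$cell_line == "malignant",
                                      "T", "N"),
                               samples$bio_rep, samples$tech_rep)
  samples <- samples[c("sample_id", "cell_line", "bio_rep", "tech_rep")]

  counts <- matrix(0, n_genes, nrow(samples))
  for (li in seq_along(lines)) {
    mu_line <- baseline_mean *
      2^(ifelse(lines[li] == "malignant", 1, 0) * effect)
    for (b in seq_len(n_bio)) {
      bio_eff <- exp(stats::rnorm(n_genes, 0, bio_sd))
      cols <- which(samples$cell_line == lines[li] & samples$bio_rep == b)
      for (j in cols)
        counts[, j] <- stats::rnbinom(n_genes, size = 1 / dispersion,
                                      mu = mu_line * bio_eff)
    }
  }
  # one-line-only genes: zero the low line entirely
  if (length(drop_idx)) {
    t_cols <- samples$cell_line == "malignant"
    for (g in drop_idx) {
      if (effect[g] >= 0) counts[g, !t_cols] <- 0
      else counts[g, t_cols] <- 0
    }
  }
  gene <- sprintf("G%04d", seq_len(n_genes))
  proteins <- data.frame(accession = sprintf("P%04d", seq_len(n_genes)),
                         gene_symbol = gene,
                         gene_id = seq_len(n_genes),
                         stringsAsFactors = FALSE)
  status <- rep("null", n_genes)
  status[up_idx] <- "up"
  status[down_idx] <- "down"
  status[intersect(drop_idx, up_idx)] <- "t_only"
  status[intersect(drop_idx, down_idx)] <- "n_only"
  truth <- data.frame(gene_symbol = gene, status = status,
                      true_log2_effect = effect, stringsAsFactors = FALSE)
  attr(truth, "seed") <- seed
  list(matrix = spectral_count_matrix(counts, proteins, samples,
                                      integerized = TRUE),
       truth = truth)
}

#' Simulate an annotation database with declared class sizes
#'
#' Categories are uniform random subsets of a gene universe with exactly
#' the requested sizes (defaults taken from published protein-class sizes
#' against a 20,814-gene reference). Categories are not disjoint: a gene
#' may carry several classes. An optional planted membership forces chosen
#' genes into chosen categories, so overlap with a designated gene list is
#' exact by construction.
#'
#' @param n_genes Background size N (default 20814).
#' @param class_sizes Named integer vector of category sizes (default
#'   [default_class_sizes]).
#' @param gene_universe Optional character vector of gene identifiers
#'   (default `G00001...`); its length must be `n_genes`.
#' @param planted Optional named list category -> genes to force into the
#'   category (counted within the declared size).
#' @param seed Integer seed.
#' @return An [annotation_db()] with `background_size = n_genes`.
#' @export
simulate_annotation_db <- function(n_genes = 20814,
                                   class_sizes = default_class_sizes,
                                   gene_universe = NULL,
                                   planted = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(gene_universe))
    gene_universe <- sprintf("G%05d", seq_len(n_genes))
  if (length(gene_universe) != n_genes)
    stop("gene_universe must have length n_genes")
  cats <- lapply(names(class_sizes), function(nm) {
    size <- class_sizes[[nm]]
    fixed <- character(0)
    if (!is.null(planted) && nm %in% names(planted)) {
      fixed <- intersect(planted[[nm]], gene_universe)
      if (length(fixed) > size)
        stop("planted members exceed class size for ", nm)
    }
    rest <- setdiff(gene_universe, fixed)
    c(fixed, sample(rest, size - length(fixed)))
  })
  names(cats) <- names(class_sizes)
  annotation_db(cats, background_size = n_genes,
                category_sizes = class_sizes)
}

#' Simulate a random signed pathway topology
#'
#' Random directed graph over `n_genes` pathway genes: off-diagonal edges
#' appear independently with probability `edge_density` and carry sign -1
#' with probability `inhibition_prob`. A coherent activating chain through
#' the first `min(5, n_genes)` genes is always included so that every
#' topology contains a multi-step cascade.
#'
#' @param n_genes Pathway size (default 20).
#' @param edge_density Edge probability (default 0.08); 0 keeps only the
#'   guaranteed cascade unless `cascade = FALSE`.
#' @param inhibition_prob Probability an edge is inhibitory (default 0.3).
#' @param cascade Include the guaranteed activating chain (default TRUE).
#' @param pathway_id Identifier (default `"synthetic1"`).
#' @param seed Integer seed.
#' @return A `pathway_topology` (beta entries in {-1, 0, +1}).
#' @export
simulate_pathway_topology <- function(n_genes = 20, edge_density = 0.08,
                                      inhibition_prob = 0.3,
                                      cascade = TRUE,
                                      pathway_id = "synthetic1",
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genes <- sprintf("%s_g%02d", pathway_id, seq_len(n_genes))
  beta <- matrix(0, n_genes, n_genes)
  edge <- matrix(stats::runif(n_genes^2) < edge_density, n_genes, n_genes)
  diag(edge) <- FALSE
  sign_m <- ifelse(stats::runif(n_genes^2) < inhibition_prob, -1, 1)
  beta[edge] <- sign_m[edge]
  if (cascade && n_genes >= 2) {
    for (i in seq_len(min(5L, n_genes) - 1L))
      beta[i + 1L, i] <- 1
  }
  pathway_topology(pathway_id, genes, beta)
}

#' Simulate a two-race tumor/non-malignant cohort
#'
#' Gaussian expression with additive race, disease and race-by-disease
#' interaction terms per gene:
#' `value = baseline + race_effect * [race = first race]
#'  + disease_effect * [tumor] + interaction_effect * [both] + noise`.
#' Ages and Gleason scores (6 or 7) are drawn so that cross-race matching
#' is feasible. The default group sizes mirror a Gleason-filtered
#' tumor/normal extract: 12 tumors per race and 4 + 30 non-malignant
#' specimens.
#'
#' @param n_tumor_per_race Tumors per race (default 12).
#' @param n_normal_per_race Named or unnamed length-2 vector of
#'   non-malignant specimens per race (default `c(4, 30)` in race order).
#' @param genes Character vector of gene names (default `gene01...gene06`).
#' @param race_effect,disease_effect,interaction_effect Named numeric
#'   vectors of planted effects per gene (missing genes get 0).
#' @param noise_sd Residual standard deviation (default 1).
#' @param baseline Baseline expression (default 8).
#' @param races Two race labels (default `c("AA", "CA")`; effects apply to
#'   the first).
#' @param seed Integer seed.
#' @return List with `cohort` (a [cohort_table()]) and `truth` (data.frame
#'   of planted per-gene effects).
#' @export
simulate_cohort <- function(n_tumor_per_race = 12,
                            n_normal_per_race = c(4, 30),
                            genes = sprintf("gene%02d", 1:6),
                            race_effect = numeric(0),
                            disease_effect = numeric(0),
                            interaction_effect = numeric(0),
                            noise_sd = 1, baseline = 8,
                            races = c("AA", "CA"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_normal_per_race <- rep_len(n_normal_per_race, 2L)
  eff <- function(v) {
    if (length(v) && !all(names(v) %in% genes))
      stop("planted effect for unknown gene: ",
           paste(setdiff(names(v), genes), collapse = ", "))
    out <- stats::setNames(numeric(length(genes)), genes)
    out[names(v)] <- v
    out
  }
  re <- eff(race_effect); de <- eff(disease_effect)
  ie <- eff(interaction_effect)
  rows <- list(); k <- 0L
  for (r in seq_along(races)) {
    for (tissue in c("tumor", "non_malignant")) {
      n <- if (tissue == "tumor") n_tumor_per_race else n_normal_per_race[r]
      if (n == 0) next
      for (i in seq_len(n)) {
        k <- k + 1L
        rows[[k]] <- data.frame(
          specimen_id = sprintf("%s_%s_%02d", races[r],
                                substr(tissue, 1, 1), i),
          race = races[r],
          age = sample(55:75, 1),
          gleason = sample(6:7, 1),
          tissue = tissue, stringsAsFactors = FALSE)
      }
    }
  }
  sp <- do.call(rbind, rows)
  is_first <- as.numeric(sp$race == races[1])
  is_tum <- as.numeric(sp$tissue == "tumor")
  mu <- outer(is_first, re) + outer(is_tum, de) +
    outer(is_first * is_tum, ie) + baseline
  expr <- mu + matrix(stats::rnorm(length(mu), 0, noise_sd), nrow(mu))
  dimnames(expr) <- list(sp$specimen_id, genes)
  truth <- data.frame(gene = genes, race_effect = unname(re),
                      disease_effect = unname(de),
                      interaction_effect = unname(ie),
                      stringsAsFactors = FALSE)
  attr(truth, "seed") <- seed
  list(cohort = cohort_table(sp, expr), truth = truth)
}

#' Write a simulation truth table
#'
#' Serializes the truth sidecar produced by the generators as TSV so a
#' generated dataset and its ground truth travel together.
#'
#' @param truth data.frame truth table (from a `simulate_*` function).
#' @param path Output path.
#' @export
write_simulation_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
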