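test_that("GMT files round-trip and malformed lines are rejected", {
  sets <- list(SET_A = c("g1", "g2", "g3"), SET_B = c("g4", "g5"))
  gs <- gene_set_collection(sets, source = "unit")
  path <- tempfile(fileext = ".gmt")
  write_gmt(gs, path)
  back <- read_gmt(path)
  expect_equal(back$SET_A, sets$SET_A)
  expect_equal(back$SET_B, sets$SET_B)
  writeLines("ONLY_NAME\tdesc", path)
  expect_error(read_gmt(path), "malformed GMT")
})

test_that("sets are filtered by effective size with inclusive bounds", {
  data_genes <- sprintf("g%02d", 1:40)
  gs <- gene_set_collection(list(
    too_small = data_genes[1:4],
    at_min = data_genes[1:5],
    inside = data_genes[1:10],
    at_max = data_genes[1:12],
    too_big = data_genes[1:13],
    # 10 listed members but only 4 in the data: effective size drops it
    projected = c(data_genes[1:4], sprintf("x%02d", 1:6))))
  kept <- filter_sets(gs, data_genes, min_size = 5, max_size = 12)
  expect_setequal(names(kept), c("at_min", "inside", "at_max"))
})

test_that("ranking scores match the hand-computed signal-to-noise", {
  counts <- rbind(
    up = c(10, 12, 11, 12, 10, 11, 12, 10, 2, 3, 2, 3, 2, 3, 2, 2),
    const = rep(5, 16),
    down = c(1, 2, 1, 2, 1, 2, 1, 2, 9, 8, 9, 8, 9, 8, 9, 8))
  # 4 malignant + 4 non-malignant columns
  m <- make_tiny_matrix(counts[, c(1:4, 9:12)], genes = rownames(counts))
  r <- rank_by_association(m, metric = "signal_to_noise")
  hand <- function(x, y) {
    fl <- function(s, mu) { s <- max(s, 0.2 * abs(mu))
      if (mu == 0) s <- max(s, 0.2); s }
    (mean(x) - mean(y)) / (fl(stats::sd(x), mean(x)) +
                           fl(stats::sd(y), mean(y)))
  }
  expect_equal(r$score[r$gene == "up"],
               hand(counts["up", 1:4], counts["up", 9:12]))
  expect_equal(r$score[r$gene == "const"], 0)
  expect_equal(r$gene, c("up", "const", "down"))
  # difference-of-means scores a constant gene zero, ranks up above it
  r2 <- rank_by_association(m, metric = "difference_of_means")
  expect_equal(r2$score[r2$gene == "const"], 0)
  expect_gt(r2$score[r2$gene == "up"], 0)
})

test_that("enrichment score agrees with the brute-force walk everywhere", {
  # maximal clustering with equal weights reaches 1 at the set boundary
  ranked_eq <- data.frame(gene = sprintf("g%02d", 1:10),
                          score = rep(1, 10), stringsAsFactors = FALSE)
  expect_equal(enrichment_score(ranked_eq, sprintf("g%02d", 1:3))$es, 1)
  # unweighted 2-of-6 at the top is +1, at the bottom -1
  ranked6 <- data.frame(gene = letters[1:6], score = 6:1,
                        stringsAsFactors = FALSE)
  expect_equal(enrichment_score(ranked6, c("a", "b"), 0)$es, 1)
  expect_equal(enrichment_score(ranked6, c("e", "f"), 0)$es, -1)
  # random instances against the oracle
  set.seed(55)
  for (i in 1:100) {
    L <- sample(10:50, 1)
    ranked <- data.frame(gene = sprintf("g%02d", 1:L),
                         score = sort(stats::rnorm(L), decreasing = TRUE),
                         stringsAsFactors = FALSE)
    gs <- sample(ranked$gene, sample(2:(L - 2), 1))
    wexp <- sample(c(0, 1), 1)
    es <- enrichment_score(ranked, gs, wexp)$es
    expect_equal(es, oracle_enrichment_score(ranked, gs, wexp))
    expect_gte(es, -1); expect_lte(es, 1)
  }
  expect_error(enrichment_score(ranked6, c("zz")), "no overlap")
})

test_that("leading edge collects the members driving the extremum", {
  ranked <- data.frame(gene = letters[1:8], score = 8:1,
                       stringsAsFactors = FALSE)
  pos <- enrichment_score(ranked, c("a", "b", "h"))
  expect_true(all(c("a", "b") %in% pos$leading_edge))
  expect_false("h" %in% pos$leading_edge)
  neg <- enrichment_score(ranked, c("g", "h", "a"), 0)
  expect_true(all(c("g", "h") %in% neg$leading_edge))
  expect_false("a" %in% neg$leading_edge)
})

test_that("planted coherent sets reach significance with the right sign", {
  sim <- simulate_spectral_counts(n_genes = 400, frac_dep = 0.1,
                                  effect_log2 = 2, dropout_frac = 0,
                                  seed = 14)
  up_genes <- sim$truth$gene_symbol[sim$truth$status == "up"]
  null_genes <- sim$truth$gene_symbol[sim$truth$status == "null"]
  gs <- gene_set_collection(list(
    planted = sample(up_genes, 12),
    random = sample(null_genes, 12)))
  res <- gsea_significance(sim$matrix, gs, n_perm = 500, seed = 15)
  planted <- res[res$set_name == "planted", ]
  expect_gt(planted$nes, 0)
  expect_lt(planted$q_value, 0.25)
  expect_equal(planted$direction, "malignant")
  # nes sign always matches es sign
  expect_true(all(sign(res$nes) == sign(res$es) | res$es == 0))
})

test_that("gsea results are reproducible and label-reversal negates scores", {
  sim <- simulate_spectral_counts(n_genes = 200, frac_dep = 0.1,
                                  baseline_mean = 30, seed = 23)
  gs <- gene_set_collection(list(
    s1 = sample(sim$truth$gene_symbol, 15),
    s2 = sample(sim$truth$gene_symbol, 20)))
  r1 <- gsea_significance(sim$matrix, gs, n_perm = 200, seed = 99)
  r2 <- gsea_significance(sim$matrix, gs, n_perm = 200, seed = 99)
  expect_identical(r1, r2)
  # reversing phenotype labels negates ranking scores and es
  flipped <- sim$matrix
  flipped$samples$cell_line <- ifelse(
    flipped$samples$cell_line == "malignant", "non_malignant", "malignant")
  ra <- rank_by_association(sim$matrix)
  rb <- rank_by_association(flipped)
  expect_equal(sort(rb$score), sort(-ra$score))
  for (s in gs) {
    ea <- enrichment_score(ra, s)$es
    eb <- enrichment_score(rb, s)$es
    expect_equal(eb, -ea, tolerance = 1e-10)
  }
})

test_that("enrichment score kernel matches an external implementation", {
  skip_if_not_installed("fgsea")
  set.seed(77)
  for (i in 1:20) {
    L <- sample(20:60, 1)
    stats_v <- sort(stats::rnorm(L), decreasing = TRUE)
    names(stats_v) <- sprintf("g%02d", 1:L)
    ranked <- data.frame(gene = names(stats_v), score = unname(stats_v),
                         stringsAsFactors = FALSE)
    members <- sample(names(stats_v), sample(3:8, 1))
    es <- enrichment_score(ranked, members, weight_exponent = 1)$es
    ref <- fgsea::calcGseaStat(stats_v,
                               selectedStats = which(names(stats_v) %in%
                                                       members),
                               gseaParam = 1, returnAllExtremes = TRUE)
    # same walk extremes; on an exact positive/negative tie this package
    # takes the positive extremum (fgsea reports 0 there)
    hi <- max(ref$tops, 0); lo <- min(ref$bottoms, 0)
    expect_equal(es, if (hi >= -lo) hi else lo, tolerance = 1e-9)
  }
})
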