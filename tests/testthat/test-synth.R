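test_that("generators are pure functions of parameters and seed", {
  a <- simulate_spectral_counts(n_genes = 50, seed = 1)
  b <- simulate_spectral_counts(n_genes = 50, seed = 1)
  expect_identical(a$matrix$counts, b$matrix$counts)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_spectral_counts(n_genes = 50, seed = 2)
  expect_false(identical(a$matrix$counts, c2$matrix$counts))
  d1 <- simulate_annotation_db(n_genes = 500, class_sizes = c(x = 50),
                               seed = 3)
  d2 <- simulate_annotation_db(n_genes = 500, class_sizes = c(x = 50),
                               seed = 3)
  expect_identical(d1$categories, d2$categories)
  t1 <- simulate_pathway_topology(seed = 4)
  t2 <- simulate_pathway_topology(seed = 4)
  expect_identical(t1$beta, t2$beta)
  co1 <- simulate_cohort(seed = 5)
  co2 <- simulate_cohort(seed = 5)
  expect_identical(co1$cohort$expression, co2$cohort$expression)
})

test_that("count generator plants the requested structure", {
  sim <- simulate_spectral_counts(n_genes = 400, frac_dep = 0.1,
                                  effect_log2 = 2, dropout_frac = 0.3,
                                  seed = 6)
  tr <- sim$truth
  expect_equal(nrow(tr), 400L)
  expect_equal(sum(tr$status != "null"), 40L)
  expect_equal(sum(tr$status %in% c("t_only", "n_only")), 12L)
  # one-line-only genes really are zero in their low line
  m <- sim$matrix
  t_cols <- m$samples$cell_line == "malignant"
  for (g in tr$gene_symbol[tr$status == "t_only"])
    expect_equal(sum(m$counts[g, !t_cols]), 0)
  for (g in tr$gene_symbol[tr$status == "n_only"])
    expect_equal(sum(m$counts[g, t_cols]), 0)
  # design is balanced, 3 bio x 3 tech per line
  expect_equal(sum(t_cols), 9L)
  expect_equal(sum(!t_cols), 9L)
  # truth sidecar serializes
  path <- tempfile(fileext = ".tsv")
  write_simulation_truth(tr, path)
  back <- utils::read.delim(path, stringsAsFactors = FALSE)
  expect_equal(back$status, tr$status)
})

test_that("planted effects are recovered on the fold-change scale", {
  sim <- simulate_spectral_counts(n_genes = 300, frac_dep = 0.1,
                                  effect_log2 = 2, dropout_frac = 0,
                                  baseline_mean = 50, seed = 7)
  de <- run_differential_expression(sim$matrix)
  tr <- sim$truth
  rec <- de$records[match(tr$gene_symbol, de$records$gene_symbol), ]
  planted <- tr$status %in% c("up", "down")
  err <- abs(rec$log2_fc[planted] - tr$true_log2_effect[planted])
  expect_gte(mean(err <= 0.5), 0.9)
})

test_that("null data keeps the realized false discovery proportion low", {
  set.seed(8)
  fdp <- vapply(1:200, function(i) {
    s <- simulate_spectral_counts(n_genes = 200, frac_dep = 0)
    d <- run_differential_expression(s$matrix, alpha = 0.1)
    n_disc <- sum(d$records$q_value < 0.1)
    if (n_disc > 0) 1 else 0  # every discovery is false under the null
  }, numeric(1))
  mc_se <- stats::sd(fdp) / sqrt(length(fdp))
  expect_lte(mean(fdp), 0.1 + 3 * max(mc_se, 1e-6))
})

test_that("annotation generator honours sizes and planted overlap", {
  db <- simulate_annotation_db(seed = 9)
  expect_equal(unname(vapply(db$categories, length, 1L)),
               unname(default_class_sizes))
  expect_equal(db$background_size, 20814L)
  # genes may carry multiple classes (no disjointness)
  all_members <- unlist(db$categories, use.names = FALSE)
  expect_gt(length(all_members), length(unique(all_members)))
  # planted overlap is exact by construction
  deps <- sprintf("G%05d", 1:63)
  db2 <- simulate_annotation_db(
    n_genes = 20814, class_sizes = c("cytoskeletal protein" = 198L),
    planted = list("cytoskeletal protein" = deps[1:10]), seed = 10)
  cc <- count_category_members(deps, db2)
  expect_gte(cc$counts[["cytoskeletal protein"]], 10L)
})

test_that("topology generator guarantees a cascade and signed edges", {
  tp <- simulate_pathway_topology(n_genes = 15, edge_density = 0.1,
                                  inhibition_prob = 0.5, seed = 11)
  expect_true(all(tp$beta %in% c(-1, 0, 1)))
  for (i in 1:4) expect_equal(tp$beta[i + 1, i], 1)
  # density 0 without the cascade: no propagation, t_a collapses to zero
  tp0 <- simulate_pathway_topology(n_genes = 10, edge_density = 0,
                                   cascade = FALSE, seed = 12)
  de <- stats::setNames(c(1.5, -0.5), tp0$genes[1:2])
  r <- perturbation_accumulation(tp0, de)
  expect_equal(r$t_a, 0)
  expect_equal(unname(r$acc), rep(0, 10))
  # a coherent activating cascade amplifies the input
  tpc <- simulate_pathway_topology(n_genes = 10, edge_density = 0,
                                   cascade = TRUE, seed = 13)
  rc <- perturbation_accumulation(tpc, stats::setNames(1, tpc$genes[1]))
  expect_gt(rc$t_a, 0)
  # edge-list serialization round-trips the connected part of the graph
  # (isolated genes have no edge rows to carry them)
  path <- tempfile(fileext = ".tsv")
  write_topology(tp, path)
  back <- load_topology(path)
  expect_equal(back$beta, tp$beta[back$genes, back$genes])
  dropped <- setdiff(tp$genes, back$genes)
  expect_true(all(tp$beta[dropped, ] == 0) && all(tp$beta[, dropped] == 0))
})

test_that("cohort generator calibrates under zero planted effects", {
  set.seed(14)
  p_all <- unlist(lapply(1:40, function(i) {
    sim <- simulate_cohort(n_normal_per_race = c(10, 10), seed = 200 + i)
    cohort_race_comparison(sim$cohort)$p_value
  }))
  # uniform null p-values: fraction below 0.05 within binomial error
  n <- length(p_all)
  expect_lt(abs(mean(p_all < 0.05) - 0.05),
            3 * sqrt(0.05 * 0.95 / n) + 0.01)
  # group sizes follow the requested design
  sim <- simulate_cohort(seed = 15)
  tab <- table(sim$cohort$specimens$race, sim$cohort$specimens$tissue)
  expect_equal(unname(tab["AA", "tumor"]), 12L)
  expect_equal(unname(tab["AA", "non_malignant"]), 4L)
  expect_equal(unname(tab["CA", "non_malignant"]), 30L)
})
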