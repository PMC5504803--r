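test_that("edge lists build signed beta matrices with downstream counts", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("source\ttarget\ttype\tsign",
               "A\tB\tactivation\t1"), path)
  tp <- load_topology(path)
  expect_equal(tp$beta["B", "A"], 1)
  expect_equal(unname(tp$n_downstream["A"]), 1)
  writeLines(c("source\ttarget\ttype\tsign",
               "A\tB\tinhibition\t1"), path)
  expect_equal(load_topology(path)$beta["B", "A"], -1)
  # duplicate edges are summed with a warning
  writeLines(c("source\ttarget\ttype\tsign",
               "A\tB\tactivation\t1",
               "A\tB\tactivation\t1"), path)
  expect_warning(tp2 <- load_topology(path), "duplicate edges")
  expect_equal(tp2$beta["B", "A"], 2)
  writeLines(c("source\ttarget\ttype\tsign",
               "A\tB\tmystery\t1"), path)
  expect_error(load_topology(path), "unknown relation type")
})

test_that("perturbation accumulation solves its defining linear system", {
  # hand-solved two-gene chain: activation propagates +1, inhibition -1
  expect_equal(perturbation_accumulation(chain_topology(1),
                                         c(A = 1))$t_a, 1)
  expect_equal(perturbation_accumulation(chain_topology(-1),
                                         c(A = 1))$t_a, -1)
  r <- perturbation_accumulation(chain_topology(1), c(A = 1))
  expect_equal(unname(r$pf), c(1, 1))
  expect_equal(unname(r$acc), c(0, 1))
  # no DE genes: homogeneous system, everything zero
  r0 <- perturbation_accumulation(chain_topology(1), numeric(0))
  expect_equal(r0$t_a, 0)
  expect_equal(unname(r0$pf), c(0, 0))
  # residual of the defining system on random topologies
  for (s in 1:10) {
    tp <- simulate_pathway_topology(n_genes = 25, edge_density = 0.1,
                                    seed = s)
    de <- stats::setNames(stats::rnorm(5), sample(tp$genes, 5))
    r <- perturbation_accumulation(tp, de)
    de_full <- stats::setNames(numeric(25), tp$genes)
    de_full[names(de)] <- de
    nds <- pmax(tp$n_downstream, 1)
    rhs <- de_full + (sweep(tp$beta, 2, nds, "/") %*% r$pf)[, 1]
    expect_lt(sqrt(sum((r$pf - rhs)^2)) / max(sqrt(sum(r$pf^2)), 1e-12),
              1e-9)
    # linearity: doubling the input doubles the net accumulation
    expect_equal(perturbation_accumulation(tp, 2 * de)$t_a, 2 * r$t_a,
                 tolerance = 1e-9)
  }
  expect_warning(perturbation_accumulation(chain_topology(1),
                                           c(A = 1, ZZ = 2)),
                 "dropped")
})

test_that("bootstrap perturbation probability behaves as designed", {
  tp <- simulate_pathway_topology(n_genes = 20, edge_density = 0.1,
                                  seed = 3)
  de <- stats::setNames(c(2, -1, 1.5), sample(tp$genes, 3))
  b1 <- p_pert_bootstrap(tp, de, n_boot = 500, seed = 11)
  b2 <- p_pert_bootstrap(tp, de, n_boot = 500, seed = 11)
  expect_identical(b1, b2)
  expect_gt(b1$p_pert, 0)
  expect_lte(b1$p_pert, 1)
  # a hub source placement perturbs more than a leaf placement
  n <- 20
  beta <- matrix(0, n, n)
  beta[2:6, 1] <- 1          # hub feeding a cascade
  for (i in 2:5) beta[i + 5, i] <- 1
  hub <- pathway_topology("hub", sprintf("g%02d", 1:n), beta)
  p_hub <- p_pert_bootstrap(hub, c(g01 = 5), n_boot = 1000, seed = 12)
  p_leaf <- p_pert_bootstrap(hub, c(g20 = 5), n_boot = 1000, seed = 12)
  expect_lt(p_hub$p_pert, p_leaf$p_pert)
  expect_error(p_pert_bootstrap(hub, c(zz = 1)), "no DE gene")
})

test_that("global probability combines the two evidence streams", {
  expect_equal(combine_global(1, 1), 1)
  expect_equal(combine_global(0.1, 0.1), 0.01 - 0.01 * log(0.01))
  expect_equal(combine_global(0.3, 0.7), combine_global(0.7, 0.3))
  # monotone increasing in each argument
  grid <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(combine_global(grid, 0.4)) > 0))
  expect_true(all(diff(combine_global(0.4, grid)) > 0))
  expect_error(combine_global(0, 0.5), "\\(0, 1\\]")
})

test_that("pathway impact calls direction from coherent perturbation", {
  # cascade of activations with all planted changes negative: inhibited
  n <- 12
  beta <- matrix(0, n, n)
  for (i in 1:(n - 1)) beta[i + 1, i] <- 1
  casc <- pathway_topology("cascade", sprintf("g%02d", 1:n), beta)
  de_records <- data.frame(
    gene_symbol = c(sprintf("g%02d", 1:4), sprintf("x%02d", 1:40)),
    q_value = c(rep(0.01, 4), rep(0.9, 40)),
    log2_fc = c(rep(-2, 4), stats::rnorm(40)),
    stringsAsFactors = FALSE)
  res <- run_spia(de_records, casc, n_boot = 500, seed = 21,
                  background = 500)
  expect_equal(nrow(res), 1L)
  expect_equal(res$status, "inhibited")
  expect_lt(res$t_a, 0)
  # same magnitudes planted positive: activated
  de_records$log2_fc[1:4] <- 2
  res2 <- run_spia(de_records, casc, n_boot = 500, seed = 21,
                   background = 500)
  expect_equal(res2$status, "activated")
  # pathways with no DE genes are skipped entirely
  lonely <- pathway_topology("lonely", c("zz1", "zz2"),
                             matrix(0, 2, 2))
  res3 <- run_spia(de_records[5:44, ], list(lonely = lonely),
                   n_boot = 100, seed = 5)
  expect_equal(nrow(res3), 0L)
})

test_that("run_spia orders by adjusted global probability and is seeded", {
  set.seed(33)
  tps <- lapply(1:4, function(i)
    simulate_pathway_topology(n_genes = 15, edge_density = 0.1,
                              pathway_id = paste0("pw", i), seed = 40 + i))
  names(tps) <- vapply(tps, `[[`, "", "pathway_id")
  genes <- unlist(lapply(tps, `[[`, "genes"))
  de_records <- data.frame(
    gene_symbol = genes,
    q_value = stats::runif(length(genes)),
    log2_fc = stats::rnorm(length(genes)),
    stringsAsFactors = FALSE)
  r1 <- run_spia(de_records, tps, de_threshold = 0.3, n_boot = 200,
                 seed = 77)
  r2 <- run_spia(de_records, tps, de_threshold = 0.3, n_boot = 200,
                 seed = 77)
  expect_identical(r1, r2)
  expect_true(!is.unsorted(r1$p_g_fdr))
  expect_true(all(r1$p_g_fdr >= r1$p_g))
  expect_true(all(r1$status[r1$t_a < 0] == "inhibited"))
})
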