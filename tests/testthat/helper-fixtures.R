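# Small in-code fixtures shared across test files.

# Hand-built 2-line, 2-bio x 2-tech design around explicit counts.
make_tiny_matrix <- function(counts, genes = NULL) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  if (is.null(genes)) genes <- sprintf("G%02d", seq_len(n))
  samples <- data.frame(
    sample_id = c("T_b1_t1", "T_b1_t2", "T_b2_t1", "T_b2_t2",
                  "N_b1_t1", "N_b1_t2", "N_b2_t1", "N_b2_t2"),
    cell_line = rep(c("malignant", "non_malignant"), each = 4),
    bio_rep = rep(c(1L, 1L, 2L, 2L), 2),
    tech_rep = rep(c(1L, 2L), 4), stringsAsFactors = FALSE)
  stopifnot(ncol(counts) == 8L)
  proteins <- data.frame(accession = paste0("P_", genes),
                         gene_symbol = genes,
                         gene_id = seq_len(n), stringsAsFactors = FALSE)
  spectral_count_matrix(counts, proteins, samples)
}

# Raw count TSV with isoform duplicates and fractional counts, written to a
# temp file; returns the path and the expected consolidated gene count.
write_raw_fixture_tsv <- function(path) {
  header <- c("accession", "gene_symbol", "gene_id",
              "T_b1_t1", "T_b1_t2", "N_b1_t1", "N_b1_t2")
  rows <- list(
    c("P1", "ALPHA", "1", "1", "2", "3", "4"),
    c("P2", "ALPHA", "1", "0.5", "1.2", "0", "1"),   # isoform of ALPHA
    c("P3", "BETA",  "2", "3.2", "0", "5", "5"),
    c("P4", "GAMMA", "3", "0", "0", "2", "2"),
    c("P5", "",      "",  "7", "7", "7", "7"))       # unmapped protein
  lines <- c(paste(header, collapse = "\t"),
             vapply(rows, paste, "", collapse = "\t"))
  writeLines(lines, path)
  path
}

# Two-gene activating chain A -> B used in perturbation tests.
chain_topology <- function(sign = 1) {
  beta <- matrix(0, 2, 2)
  beta[2, 1] <- sign
  pathway_topology("chain", c("A", "B"), beta)
}
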