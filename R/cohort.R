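#' Construct a cohort table
#'
#' Clinical specimen records plus a specimen-by-gene expression matrix for
#' one layer (RNA or protein) of a two-race tumor/non-malignant cohort.
#'
#' @param specimens data.frame with columns `specimen_id`, `race`, `age`,
#'   `gleason`, `tissue` (`"tumor"` or `"non_malignant"`).
#' @param expression Numeric matrix, specimens in rows (rownames =
#'   specimen ids), genes in columns.
#' @return Object of class `"cohort_table"`.
#' @export
cohort_table <- function(specimens, expression) {
  specimens <- as.data.frame(specimens, stringsAsFactors = FALSE)
  expression <- as.matrix(expression)
  need <- c("specimen_id", "race", "age", "gleason", "tissue")
  if (!all(need %in% names(specimens)))
    stop("specimens must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(specimens$specimen_id))
    stop("duplicate specimen id")
  if (!all(specimens$tissue %in% c("tumor", "non_malignant")))
    stop("tissue must be 'tumor' or 'non_malignant'")
  if (is.null(rownames(expression)))
    stop("expression must have specimen ids as rownames")
  if (!all(rownames(expression) %in% specimens$specimen_id))
    stop("expression row without a specimen record")
  structure(list(specimens = specimens, expression = expression),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("cohort_table:", nrow(x$specimens), "specimens,",
      ncol(x$expression), "genes\n")
  print(table(x$specimens$race, x$specimens$tissue))
  invisible(x)
}

#' Read a cohort from clinical + expression TSVs
#'
#' @param clinical_path TSV with the specimen columns of [cohort_table()].
#' @param expression_path TSV, first column `specimen_id`, remaining
#'   columns genes.
#' @return A [cohort_table()].
#' @export
read_cohort <- function(clinical_path, expression_path) {
  clin <- utils::read.delim(clinical_path, stringsAsFactors = FALSE)
  ex <- utils::read.delim(expression_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(ex[, -1, drop = FALSE])
  rownames(m) <- ex[[1]]
  cohort_table(clin, m)
}

#' Filter a cohort by Gleason score
#'
#' Retains specimens whose Gleason score is at most `max_gleason`
#' (inclusive); specimens without a recorded score (e.g. some non-malignant
#' tissue) are retained.
#'
#' @param x A [cohort_table()].
#' @param max_gleason Maximum Gleason score (default 7, i.e. lower-grade
#'   tumors only).
#' @return Filtered [cohort_table()].
#' @export
filter_cohort <- function(x, max_gleason = 7) {
  stopifnot(inherits(x, "cohort_table"))
  keep <- is.na(x$specimens$gleason) | x$specimens$gleason <= max_gleason
  sp <- x$specimens[keep, , drop = FALSE]
  rownames(sp) <- NULL
  ex <- x$expression[rownames(x$expression) %in% sp$specimen_id, ,
                     drop = FALSE]
  cohort_table(sp, ex)
}

#' Match cross-race tumor specimen pairs by age within Gleason stratum
#'
#' Greedy nearest-age matching: within each Gleason score, candidate
#' cross-race pairs are ordered by absolute age difference and accepted
#' smallest-difference first, each specimen used at most once, subject to
#' the age tolerance. Never pairs specimens of the same race.
#'
#' @param x A [cohort_table()] whose tumor specimens span exactly two
#'   races.
#' @param tolerance_years Maximum allowed age difference (default 5).
#' @return List with `pairs` (data.frame `specimen_a`, `specimen_b`,
#'   `race_a`, `race_b`, `gleason`, `age_diff`) and `unmatched` (specimen
#'   ids).
#' @export
match_pairs <- function(x, tolerance_years = 5) {
  stopifnot(inherits(x, "cohort_table"))
  tum <- x$specimens[x$specimens$tissue == "tumor", , drop = FALSE]
  races <- sort(unique(tum$race))
  if (length(races) != 2L)
    stop("tumor specimens must span exactly two races")
  pairs <- NULL
  used <- character(0)
  for (g in sort(unique(tum$gleason))) {
    a <- tum[tum$gleason == g & tum$race == races[1], , drop = FALSE]
    b <- tum[tum$gleason == g & tum$race == races[2], , drop = FALSE]
    if (nrow(a) == 0L || nrow(b) == 0L) {
      warning("no cross-race pairs possible in Gleason ", g, " stratum")
      next
    }
    cand <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
    cand$diff <- abs(a$age[cand$i] - b$age[cand$j])
    cand <- cand[cand$diff <= tolerance_years, , drop = FALSE]
    cand <- cand[order(cand$diff, cand$i, cand$j), , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      ia <- a$specimen_id[cand$i[r]]
      ib <- b$specimen_id[cand$j[r]]
      if (ia %in% used || ib %in% used) next
      used <- c(used, ia, ib)
      pairs <- rbind(pairs, data.frame(
        specimen_a = ia, specimen_b = ib,
        race_a = races[1], race_b = races[2],
        gleason = g, age_diff = cand$diff[r],
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(pairs))
    pairs <- data.frame(specimen_a = character(), specimen_b = character(),
                        race_a = character(), race_b = character(),
                        gleason = integer(), age_diff = numeric(),
                        stringsAsFactors = FALSE)
  list(pairs = pairs, unmatched = setdiff(tum$specimen_id, used))
}

#' Welch two-sample test of expression between races
#'
#' Two-sided unequal-variance (Welch) t-test per gene; the pooled-variance
#' variant is available via `pooled = TRUE`. When both groups have zero
#' variance and equal means the p-value is 1 by convention.
#'
#' @param values_by_race List of two numeric vectors (one per race), or a
#'   matrix plus `race` factor via `race_group_test_matrix`.
#' @param pooled Use the pooled-variance (classical) t-test.
#' @return Two-sided p-value.
#' @export
race_group_test <- function(values_by_race, pooled = FALSE) {
  stopifnot(is.list(values_by_race), length(values_by_race) == 2L)
  a <- values_by_race[[1]]; b <- values_by_race[[2]]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(1)
    stop("zero variance in both groups with unequal means")
  }
  stats::t.test(a, b, alternative = "two.sided",
                var.equal = pooled)$p.value
}

#' Race-specific non-malignant mean subtraction
#'
#' For each gene and race, computes the arithmetic mean expression over
#' that race's non-malignant specimens and subtracts it from every tumor
#' specimen of the same race. Negative normalized values therefore mean
#' "below the race-matched normal mean" (downregulated relative to
#' race-specific non-malignant tissue).
#'
#' @param x A [cohort_table()] containing tumor and non-malignant
#'   specimens; every tumor's race must have at least one non-malignant
#'   specimen.
#' @return List with `normalized` (tumor specimen x gene matrix),
#'   `reference_means` (race x gene matrix) and `specimens` (the tumor
#'   clinical records, aligned to `normalized` rows).
#' @export
subtract_race_normal <- function(x) {
  stopifnot(inherits(x, "cohort_table"))
  sp <- x$specimens
  tum <- sp[sp$tissue == "tumor", , drop = FALSE]
  nor <- sp[sp$tissue == "non_malignant", , drop = FALSE]
  missing <- setdiff(unique(tum$race), unique(nor$race))
  if (length(missing))
    stop("no non-malignant reference specimens for race: ",
         paste(missing, collapse = ", "))
  races <- sort(unique(tum$race))
  ref <- t(vapply(races, function(r) {
    ids <- nor$specimen_id[nor$race == r]
    colMeans(x$expression[ids, , drop = FALSE])
  }, numeric(ncol(x$expression))))
  rownames(ref) <- races
  tum_ex <- x$expression[tum$specimen_id, , drop = FALSE]
  normalized <- tum_ex - ref[tum$race, , drop = FALSE]
  rownames(normalized) <- tum$specimen_id
  list(normalized = normalized, reference_means = ref, specimens = tum)
}

#' Per-gene race comparison across a cohort
#'
#' Runs [race_group_test()] on every gene of an expression matrix split by
#' race, optionally after race-specific non-malignant mean subtraction.
#'
#' @param x A [cohort_table()].
#' @param subtract_normal Subtract race-specific non-malignant means from
#'   tumor specimens first (tumor specimens only are then compared).
#' @param pooled See [race_group_test()].
#' @param bh Add Benjamini-Hochberg adjusted q-values.
#' @return data.frame `gene`, `p_value` (and `q_value` when `bh = TRUE`).
#' @export
cohort_race_comparison <- function(x, subtract_normal = FALSE,
                                   pooled = FALSE, bh = FALSE) {
  stopifnot(inherits(x, "cohort_table"))
  if (subtract_normal) {
    sn <- subtract_race_normal(x)
    expr <- sn$normalized
    race <- sn$specimens$race
  } else {
    tum <- x$specimens[x$specimens$tissue == "tumor", , drop = FALSE]
    expr <- x$expression[tum$specimen_id, , drop = FALSE]
    race <- tum$race
  }
  races <- sort(unique(race))
  if (length(races) != 2L) stop("need exactly two races")
  p <- vapply(seq_len(ncol(expr)), function(j)
    race_group_test(list(expr[race == races[1], j],
                         expr[race == races[2], j]),
                    pooled = pooled), numeric(1))
  out <- data.frame(gene = colnames(expr), p_value = p,
                    stringsAsFactors = FALSE)
  if (bh) out$q_value <- bh_adjust(out$p_value)
  out
}
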