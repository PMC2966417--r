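#' Functional coordination rate of partner assignments
#'
#' A gene with a full list of `k` partners is *evaluable* when it and every
#' partner carry at least one annotation in the working collection (sets
#' larger than `max_set_size` are discarded first — very large categories
#' would make coordination trivially easy). An evaluable gene is
#' *coordinated* when at least `min_shared` members of the group formed by
#' the gene and its partners fall into one common set. Under-filled partner
#' lists are excluded from the analysis.
#'
#' @param nfps an `nfp_table` (typically k = 3).
#' @param gene_sets a [gene_set_collection].
#' @param max_set_size largest annotation set considered.
#' @param min_shared members of the (k + 1)-gene group that must share one
#'   set.
#' @return An object of class `coordination_result`:
#'   list(evaluable, coordinated, rate).
#' @export
coordination_rate <- function(nfps, gene_sets, max_set_size = 200,
                              min_shared = 3) {
  sets <- gene_sets$sets[lengths(gene_sets$sets) <= max_set_size]
  annotated <- unique(unlist(sets, use.names = FALSE))
  evaluable <- 0L
  coordinated <- 0L
  for (g in names(nfps$partners)) {
    if (nfps$underfilled[[g]]) next
    group <- c(g, nfps$partners[[g]])
    if (!all(group %in% annotated)) next
    evaluable <- evaluable + 1L
    hit <- any(vapply(sets, function(s) sum(group %in% s) >= min_shared,
                      NA))
    if (hit) coordinated <- coordinated + 1L
  }
  structure(list(evaluable = evaluable, coordinated = coordinated,
                 rate = if (evaluable) coordinated / evaluable else NA_real_),
            class = "coordination_result")
}

#' @export
print.coordination_result <- function(x, ...) {
  cat(sprintf("coordination: %d / %d evaluable genes (rate %.3f)\n",
              x$coordinated, x$evaluable, x$rate))
  invisible(x)
}

#' Null distribution of the coordination rate
#'
#' Repeatedly assigns random partners and recomputes the coordination rate,
#' yielding the baseline attributable to the annotation collection itself
#' (`"uniform"` mode: partners drawn from the whole universe) or to the
#' network topology (`"network"` mode: partners drawn from first-order
#' neighbours).
#'
#' @param mode `"uniform"` or `"network"`.
#' @param gene_universe character vector of gene IDs.
#' @param network a [gene_network] (used in `"network"` mode).
#' @param gene_sets a [gene_set_collection].
#' @param reps number of randomizations.
#' @param seed integer seed; each repetition derives its own sub-seed.
#' @param k partners per gene.
#' @param max_set_size,min_shared passed to [coordination_rate].
#' @return Numeric vector of `reps` coordination rates.
#' @export
null_coordination <- function(mode = c("uniform", "network"),
                              gene_universe, network = NULL, gene_sets,
                              reps = 100, seed = NULL, k = 3,
                              max_set_size = 200, min_shared = 3) {
  mode <- match.arg(mode)
  if (reps < 1) stopf("reps must be >= 1")
  vapply(seq_len(reps), function(r) {
    sub_seed <- if (is.null(seed)) NULL else (seed + r) %% .Machine$integer.max
    nfps <- random_nfps(gene_universe, network, k = k, mode = mode,
                        seed = sub_seed)
    coordination_rate(nfps, gene_sets, max_set_size, min_shared)$rate
  }, 0)
}

#' One-sample t-test of null rates against an observed rate
#'
#' Two-sided test of whether the mean of the null coordination rates equals
#' the observed rate; a tiny p-value says the observed rate cannot be
#' explained by the null's built-in structure.
#'
#' @param null_rates numeric vector of null rates (length >= 2, non-zero
#'   variance).
#' @param observed_rate the observed rate.
#' @return The two-sided p-value.
#' @export
one_sample_ttest <- function(null_rates, observed_rate) {
  if (length(null_rates) < 2L) stopf("need >= 2 null rates")
  if (stats::sd(null_rates) == 0) stopf("null rates have zero variance")
  stats::t.test(null_rates, mu = observed_rate)$p.value
}

#' Hallmark-gene recovery of a ranking
#'
#' Counts how many externally curated disease-associated ("hallmark")
#' genes appear among the `top_n` best-ranked genes. Hallmarks outside the
#' ranked universe are ignored with a warning.
#'
#' @param ranking a `gene_ranking`.
#' @param hallmark_ids character vector of hallmark gene IDs.
#' @param top_n size of the selection.
#' @return Integer count.
#' @export
hallmark_recovery <- function(ranking, hallmark_ids, top_n) {
  m <- nrow(ranking$table)
  if (top_n > m) stopf("top_n = %d exceeds the %d ranked genes", top_n, m)
  outside <- setdiff(hallmark_ids, ranking$table$gene)
  if (length(outside)) {
    warnf("%d hallmark gene(s) outside the ranked universe ignored",
          length(outside))
  }
  sum(top_genes(ranking, top_n) %in% hallmark_ids)
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' `P(X >= x)` for X hypergeometric with population `N`, `K` successes, and
#' a sample of size `n`: the chance that a random selection of `n` genes
#' from the universe overlaps the set by at least `x`.
#'
#' @param N universe size.
#' @param K set size within the universe.
#' @param n selection size.
#' @param x observed overlap.
#' @return p-value in \[0, 1\].
#' @export
hypergeometric_p <- function(N, K, n, x) {
  if (any(c(N, K, n, x) < 0) || K > N || n > N || x > min(K, n)) {
    stopf("inconsistent counts: N=%d K=%d n=%d x=%d", N, K, n, x)
  }
  stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment (monotone, capped at 1), delegated to
#' `stats::p.adjust` after validation.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE) || anyNA(p_values)) {
    stopf("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Gene-set enrichment scan of a selection
#'
#' For every collection set whose size within the analysis universe falls
#' in `[min_size, max_size]`, tests the selection's overlap with the
#' hypergeometric upper tail and adjusts across all tested sets with
#' Benjamini-Hochberg. Set sizes are computed within the universe of genes
#' actually ranked — the hypergeometric population must match the sampling
#' frame.
#'
#' @param selected character vector of selected gene IDs (subset of
#'   `universe`).
#' @param collection a [gene_set_collection].
#' @param universe character vector: the analysis universe.
#' @param min_size,max_size set-size window (within the universe).
#' @param alpha adjusted-p significance threshold.
#' @return Data frame (class `enrichment_table`): set, source, N, K, n, x,
#'   p, p_adj, significant; ordered by p.
#' @export
enrichment_scan <- function(selected, collection, universe,
                            min_size = 10, max_size = 200, alpha = 0.1) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stopf("empty universe")
  stray <- setdiff(selected, universe)
  if (length(stray)) stopf("selected gene(s) outside the universe: %s",
                           paste(utils::head(stray, 5L), collapse = ", "))
  N <- length(universe)
  n <- length(unique(selected))
  members <- lapply(collection$sets, intersect, universe)
  K <- lengths(members)
  test <- K >= min_size & K <= max_size
  nm <- names(collection$sets)[test]
  rows <- data.frame(
    set = nm,
    source = unname(collection$source[nm]),
    N = N,
    K = unname(K[test]),
    n = n,
    x = vapply(members[test], function(s) sum(selected %in% s), 0L),
    stringsAsFactors = FALSE)
  rows$p <- mapply(hypergeometric_p, rows$N, rows$K, rows$n, rows$x)
  rows$p_adj <- bh_adjust(rows$p)
  rows$significant <- rows$p_adj < alpha
  rows <- rows[order(rows$p, rows$set), ]
  rownames(rows) <- NULL
  class(rows) <- c("enrichment_table", "data.frame")
  rows
}
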