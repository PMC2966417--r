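# Internal constructor shared by the selection rules and the null
# generators.
nfp_table <- function(partners, scores, rule, k) {
  underfilled <- lengths(partners) < k
  structure(list(partners = partners, scores = scores, rule = rule,
                 k = as.integer(k), underfilled = underfilled),
            class = "nfp_table")
}

#' @export
print.nfp_table <- function(x, ...) {
  cat(sprintf("nfp_table (%s, k = %d): %d genes, %d under-filled\n",
              x$rule, x$k, length(x$partners), sum(x$underfilled)))
  invisible(x)
}

#' Nearest functional partners by diffusion distance
#'
#' For every gene, selects the `k` other genes at smallest finite diffusion
#' distance. A small `k` keeps partners within the gene's own pathway;
#' large `k` links genes across unrelated pathways. Because diffusion
#' distance is defined between any two genes of a connected component, the
#' rule fills all `k` slots for every gene whose component has more than
#' `k` members — the advantage over first-order selection. Ties (distances
#' equal to 10 significant digits, which absorbs eigen-solver noise) are
#' broken by lexicographic gene ID.
#'
#' @param distance_table symmetric pairwise distance matrix from
#'   [pairwise_diffusion_distances].
#' @param k number of partners per gene.
#' @return An `nfp_table`: ordered partner lists with their distances.
#' @export
select_nfps_diffusion <- function(distance_table, k = 3) {
  if (k < 1) stopf("k must be >= 1")
  genes <- rownames(distance_table)
  partners <- vector("list", length(genes))
  scores <- vector("list", length(genes))
  names(partners) <- names(scores) <- genes
  for (g in genes) {
    d <- distance_table[g, ]
    d <- d[names(d) != g & is.finite(d)]
    ord <- order(signif(d, 10), names(d))
    take <- utils::head(ord, k)
    partners[[g]] <- names(d)[take]
    scores[[g]] <- unname(d[take])
  }
  nfp_table(partners, scores, "diffusion", k)
}

#' Nearest functional partners from first-order neighbours
#'
#' The first-order rule (MiGS): for every gene, the `k` directly-connected
#' neighbours with the highest combined correlation. Genes with fewer than
#' `k` neighbours receive all of them and are flagged under-filled;
#' downstream analyses decide whether to exclude them. Ties are broken by
#' lexicographic gene ID.
#'
#' @param network a [gene_network].
#' @param correlations an `edge_correlation_table` covering the network's
#'   edges.
#' @param k number of partners per gene.
#' @return An `nfp_table` with correlations as scores.
#' @export
select_nfps_first_order <- function(network, correlations, k = 3) {
  if (k < 1) stopf("k must be >= 1")
  genes <- network$gene_ids
  inc <- rbind(
    data.frame(g = correlations$from, nb = correlations$to,
               c = correlations$combined, stringsAsFactors = FALSE),
    data.frame(g = correlations$to, nb = correlations$from,
               c = correlations$combined, stringsAsFactors = FALSE))
  by_gene <- split(inc[c("nb", "c")], factor(inc$g, levels = genes))
  partners <- vector("list", length(genes))
  scores <- vector("list", length(genes))
  names(partners) <- names(scores) <- genes
  for (g in genes) {
    tab <- by_gene[[g]]
    if (is.null(tab) || nrow(tab) == 0L) {
      partners[[g]] <- character()
      scores[[g]] <- numeric()
      next
    }
    ord <- order(-tab$c, tab$nb)
    take <- utils::head(ord, k)
    partners[[g]] <- tab$nb[take]
    scores[[g]] <- tab$c[take]
  }
  nfp_table(partners, scores, "first_order", k)
}

#' Random partner assignments (null models)
#'
#' Generates the randomized partner tables used as nulls for the
#' coordination analysis: `"uniform"` samples `k` genes without replacement
#' from the whole universe (minus the gene itself); `"network"` samples `k`
#' of the gene's first-order neighbours (all of them, flagged under-filled,
#' when the degree is below `k`).
#'
#' @param gene_universe character vector of gene IDs.
#' @param network a [gene_network] (required for mode `"network"`).
#' @param k partners per gene.
#' @param mode `"uniform"` or `"network"`.
#' @param seed optional integer seed for reproducibility.
#' @return An `nfp_table` with `NA` scores.
#' @export
random_nfps <- function(gene_universe, network = NULL, k = 3,
                        mode = c("uniform", "network"), seed = NULL) {
  mode <- match.arg(mode)
  if (k < 1) stopf("k must be >= 1")
  if (mode == "network" && is.null(network)) {
    stopf("mode \"network\" needs a network")
  }
  with_seed(seed, {
    nbrs <- if (mode == "network") network_neighbors(network) else NULL
    partners <- lapply(stats::setNames(gene_universe, gene_universe),
                       function(g) {
      pool <- if (mode == "uniform") setdiff(gene_universe, g) else nbrs[[g]]
      if (length(pool) <= k) sort(pool)
      else sort(sample(pool, k))
    })
    scores <- lapply(partners, function(p) rep(NA_real_, length(p)))
    nfp_table(partners, scores, paste0("random_", mode), k)
  })
}

#' Write an NFP table as TSV
#'
#' Columns: gene, rule, partner_1, score_1, ..., partner_k, score_k,
#' flag_underfilled.
#'
#' @param nfps an `nfp_table`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_nfps <- function(nfps, path) {
  genes <- names(nfps$partners)
  df <- data.frame(gene = genes, rule = nfps$rule,
                   stringsAsFactors = FALSE)
  for (i in seq_len(nfps$k)) {
    df[[paste0("partner_", i)]] <- vapply(genes, function(g) {
      p <- nfps$partners[[g]]
      if (length(p) >= i) p[[i]] else NA_character_
    }, "")
    df[[paste0("score_", i)]] <- vapply(genes, function(g) {
      s <- nfps$scores[[g]]
      if (length(s) >= i) s[[i]] else NA_real_
    }, 0)
  }
  df$flag_underfilled <- unname(nfps$underfilled[genes])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
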