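#' Mutual information between an expression profile and the phenotype
#'
#' Plug-in (maximum-likelihood) estimator from a joint histogram: the range
#' of `x` is divided into `bins` equal-width intervals (top bin
#' right-closed, so the maximum lands in the last bin), the joint counts
#' with the discrete label are tabulated, and
#' `MI = sum p(b, c) log2( p(b, c) / (p(b) p(c)) )` over non-empty cells.
#' Reported in bits; the log base only rescales scores and cannot change a
#' ranking.
#'
#' @param x numeric, non-constant expression profile (length n >= 2).
#' @param y discrete phenotype labels of the same length.
#' @param bins number of equal-width histogram bins for `x`.
#' @return Nonnegative MI in bits.
#' @export
mutual_information <- function(x, y, bins = 10) {
  if (length(x) != length(y)) stopf("x and y differ in length")
  if (length(x) < 2L) stopf("need >= 2 samples")
  if (min(x) == max(x)) stopf("MI undefined for a constant profile")
  if (bins < 1) stopf("bins must be >= 1")
  edges <- seq(min(x), max(x), length.out = bins + 1L)
  b <- cut(x, breaks = edges, include.lowest = TRUE, right = TRUE)
  joint <- table(b, factor(y))
  n <- sum(joint)
  p_xy <- joint / n
  p_x <- rowSums(p_xy)
  p_y <- colSums(p_xy)
  terms <- p_xy * log2(p_xy / outer(p_x, p_y))
  sum(terms[is.finite(terms) & p_xy > 0])
}

# MI for every gene of a dataset (named vector).
gene_mi_scores <- function(expr, bins = 10) {
  vapply(rownames(expr$values), function(g) {
    mutual_information(expr$values[g, ], expr$labels, bins = bins)
  }, 0)
}

#' Gene-phenotype association: partner-averaged mutual information
#'
#' A gene rarely acts alone; the association of gene i with the phenotype
#' is taken as the mean MI of the gene together with its nearest functional
#' partners: `GPA_i = (MI_i + sum_{j in NFP(i)} MI_j) / (1 + |NFP(i)|)`.
#' A gene with an empty partner list keeps its own MI.
#'
#' @param mi_scores named numeric vector of per-gene MI values.
#' @param nfps an `nfp_table` whose partners all appear in `mi_scores`.
#' @return Named numeric vector of GPA values over `names(nfps$partners)`.
#' @export
gene_phenotype_association <- function(mi_scores, nfps) {
  vapply(stats::setNames(names(nfps$partners), names(nfps$partners)),
         function(g) {
    members <- c(g, nfps$partners[[g]])
    unknown <- setdiff(members, names(mi_scores))
    if (length(unknown)) stopf("no MI score for gene(s): %s",
                               paste(utils::head(unknown, 5L),
                                     collapse = ", "))
    mean(mi_scores[members])
  }, 0)
}

#' Rank genes by association score
#'
#' Descending GPA; exact ties are broken by lexicographic gene ID so the
#' ranking is deterministic and invariant to input order.
#'
#' @param gpa named numeric vector of association scores.
#' @param mi_scores optional named vector of the underlying MI values
#'   (reported alongside; defaults to `gpa`).
#' @param model model tag recorded in the result.
#' @return An object of class `gene_ranking`: list(table, model), `table` a
#'   data frame (gene, mi, gpa, rank) sorted by rank.
#' @export
rank_genes <- function(gpa, mi_scores = gpa, model = "classic") {
  if (anyNA(gpa) || any(!is.finite(gpa))) stopf("non-finite GPA value")
  ord <- order(-gpa, names(gpa))
  tab <- data.frame(gene = names(gpa)[ord],
                    mi = unname(mi_scores[names(gpa)[ord]]),
                    gpa = unname(gpa[ord]),
                    rank = seq_along(gpa),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, model = model), class = "gene_ranking")
}

#' @export
print.gene_ranking <- function(x, ...) {
  cat(sprintf("gene_ranking (%s): %d genes; top: %s\n", x$model,
              nrow(x$table),
              paste(utils::head(x$table$gene, 5L), collapse = ", ")))
  invisible(x)
}

#' Top-n genes of a ranking
#'
#' @param ranking a `gene_ranking`.
#' @param n number of genes.
#' @return Character vector of the n best-ranked gene IDs.
#' @export
top_genes <- function(ranking, n) {
  utils::head(ranking$table$gene, n)
}

#' Run a gene-selection model end to end
#'
#' The four variants differ in how gene-gene correlation is estimated and
#' how partners are selected:
#' \describe{
#'   \item{classic}{every gene on its own; ranking = descending MI.}
#'   \item{MiGS}{microRNA-integrated correlations (PCC x Jaccard), partners
#'     from first-order neighbours only.}
#'   \item{NeGS}{expression-only correlations, partners by diffusion
#'     distance.}
#'   \item{MiNeGS}{microRNA-integrated correlations, partners by diffusion
#'     distance — the full model.}
#' }
#' For the diffusion variants, edges whose combined correlation is zero
#' (a microRNA-bound gene linked to an unbound one under the integrated
#' similarity) carry no diffusion mass and are dropped from the weighted
#' graph; genes thereby isolated form singleton components and fall back to
#' their own MI.
#'
#' @param expr preprocessed, aligned [expression_dataset] (both classes
#'   present, no constant genes).
#' @param binding aligned [binding_matrix] (ignored by classic and NeGS).
#' @param network aligned, edge-filtered [gene_network].
#' @param model one of `"classic"`, `"MiGS"`, `"NeGS"`, `"MiNeGS"`.
#' @param k partners per gene.
#' @param t diffusion time (positive integer).
#' @param bins histogram bins for the MI estimator.
#' @param L retained embedding components, or `"auto"`.
#' @return A `gene_ranking`; for the partnered models the `nfp_table` used
#'   is attached as attribute `"nfp_table"`.
#' @export
run_model <- function(expr, binding, network,
                      model = c("MiNeGS", "classic", "MiGS", "NeGS"),
                      k = 3, t = 1, bins = 10, L = "auto") {
  model <- match.arg(model)
  mi <- gene_mi_scores(expr, bins = bins)
  if (model == "classic") {
    return(rank_genes(mi, mi, model = "classic"))
  }
  mode <- if (model == "NeGS") "expression_only" else "integrated"
  cors <- edge_correlations(expr, binding, network, mode = mode)
  if (model == "MiGS") {
    nfps <- select_nfps_first_order(network, cors, k = k)
  } else {
    pos <- cors$combined > 0
    if (!all(pos)) {
      warnf("%d zero-weight edge(s) dropped before diffusion", sum(!pos))
    }
    net_pos <- gene_network(network$gene_ids,
                            network$edges[pos, , drop = FALSE])
    wg <- build_weighted_graph(net_pos, cors[pos, , drop = FALSE])
    emb <- diffusion_embedding(wg, t = t, L = L)
    dists <- pairwise_diffusion_distances(emb)
    nfps <- select_nfps_diffusion(dists, k = k)
  }
  gpa <- gene_phenotype_association(mi, nfps)
  out <- rank_genes(gpa, mi, model = model)
  attr(out, "nfp_table") <- nfps
  out
}
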