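#' Pearson correlation between two expression profiles
#'
#' Thin validated wrapper around the sample Pearson correlation: equal
#' length, at least two samples, neither profile constant.
#'
#' @param x,y numeric vectors of equal length.
#' @return Correlation in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stopf("vectors differ in length")
  if (length(x) < 2L) stopf("need >= 2 samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stopf("correlation undefined for a constant profile")
  }
  stats::cor(x, y)
}

#' Jaccard similarity of two binary microRNA-binding profiles
#'
#' J = M11 / (M11 + M10 + M01), the fraction of microRNAs binding at least
#' one of the genes that bind both. Two genes bound by no microRNA at all
#' are treated as maximally similar (J = 1): both are free of
#' post-transcriptional regulation. A bound and an unbound gene are
#' maximally dissimilar (J = 0).
#'
#' @param zi,zj equal-length 0/1 vectors (one row of the binding matrix
#'   each).
#' @return Similarity in \[0, 1\].
#' @export
jaccard_binding <- function(zi, zj) {
  if (length(zi) != length(zj)) stopf("binding profiles differ in length")
  if (!all(zi %in% c(0, 1)) || !all(zj %in% c(0, 1))) {
    stopf("binding profiles must be binary")
  }
  si <- sum(zi); sj <- sum(zj)
  if (si == 0 && sj == 0) return(1)
  if (si == 0 || sj == 0) return(0)
  m11 <- sum(zi == 1 & zj == 1)
  m11 / (m11 + sum(zi == 1 & zj == 0) + sum(zi == 0 & zj == 1))
}

#' Per-edge gene-gene correlations
#'
#' For every edge of the network computes the expression Pearson
#' correlation, the binding-profile Jaccard similarity, and the combined
#' correlation. In `"integrated"` mode (MiGS/MiNeGS) the combined value is
#' the product PCC * J — two genes are functionally correlated when their
#' transcript levels co-vary *and* they face similar microRNA regulation.
#' In `"expression_only"` mode (NeGS) the combined value is the PCC alone
#' and the binding matrix is ignored.
#'
#' Correlations are evaluated only on network edges: the models consume
#' them exclusively as edge weights, which keeps the cost linear in the
#' edge count.
#'
#' @param expr an [expression_dataset].
#' @param binding a [binding_matrix] over the same genes (may be `NULL` in
#'   `expression_only` mode).
#' @param network a [gene_network] over the same genes.
#' @param mode `"integrated"` or `"expression_only"`.
#' @return A data frame of class `edge_correlation_table` with columns
#'   `from`, `to`, `pcc`, `jaccard`, `combined`.
#' @export
edge_correlations <- function(expr, binding, network,
                              mode = c("integrated", "expression_only")) {
  mode <- match.arg(mode)
  ed <- network$edges
  pcc <- vapply(seq_len(nrow(ed)), function(i) {
    pearson(expr$values[ed$from[i], ], expr$values[ed$to[i], ])
  }, 0)
  if (mode == "integrated") {
    jac <- vapply(seq_len(nrow(ed)), function(i) {
      jaccard_binding(binding$Z[ed$from[i], ], binding$Z[ed$to[i], ])
    }, 0)
  } else {
    jac <- rep(NA_real_, nrow(ed))
  }
  combined <- if (mode == "integrated") pcc * jac else pcc
  out <- data.frame(from = ed$from, to = ed$to, pcc = pcc,
                    jaccard = jac, combined = combined,
                    stringsAsFactors = FALSE)
  class(out) <- c("edge_correlation_table", "data.frame")
  attr(out, "mode") <- mode
  out
}
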