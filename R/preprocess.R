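#' Remove unexpressed genes
#'
#' Drops genes whose mean expression across all samples is strictly below
#' `floor` (raw-intensity scale by default; values under the floor are
#' treated as absent transcripts).
#'
#' @param expr an [expression_dataset].
#' @param floor expression floor; genes with mean < `floor` are removed.
#' @return list(expression = filtered dataset, report = [filter_report]).
#' @export
filter_unexpressed <- function(expr, floor = 100) {
  mu <- rowMeans(expr$values)
  removed <- rownames(expr$values)[mu < floor]
  kept <- setdiff(rownames(expr$values), removed)
  out <- if (length(kept)) subset_expression(expr, genes = kept) else NULL
  list(expression = out,
       report = filter_report("unexpressed", removed, length(kept)))
}

#' Remove low-variance genes
#'
#' Drops genes whose sample standard deviation (n - 1 denominator) across
#' samples is strictly below `min_sd`; for such genes measurement noise
#' dominates any biological variation.
#'
#' @param expr an [expression_dataset] with at least two samples.
#' @param min_sd minimum standard deviation.
#' @return list(expression, report).
#' @export
filter_low_variance <- function(expr, min_sd = 0.2) {
  if (ncol(expr$values) < 2L) stopf("need >= 2 samples to estimate SD")
  sds <- apply(expr$values, 1L, stats::sd)
  removed <- rownames(expr$values)[sds < min_sd]
  kept <- setdiff(rownames(expr$values), removed)
  out <- if (length(kept)) subset_expression(expr, genes = kept) else NULL
  list(expression = out,
       report = filter_report("low_variance", removed, length(kept)))
}

#' Remove sparsely-annotated microRNAs
#'
#' Drops microRNA columns with fewer than `min_targets` target genes; such
#' microRNAs are considered too little studied for their binding profile to
#' be informative.
#'
#' @param binding a [binding_matrix].
#' @param min_targets minimum number of targets to retain a microRNA.
#' @return list(binding, report).
#' @export
filter_sparse_mirnas <- function(binding, min_targets = 100) {
  n_targets <- colSums(binding$Z)
  removed <- colnames(binding$Z)[n_targets < min_targets]
  kept <- setdiff(colnames(binding$Z), removed)
  Z <- binding$Z[, kept, drop = FALSE]
  list(binding = binding_matrix(Z),
       report = filter_report("sparse_mirnas", removed, length(kept)))
}

#' Remove network edges with non-positive expression correlation
#'
#' Interaction databases pool evidence across many tissues and conditions;
#' edges whose endpoints are not positively correlated in the studied data
#' are treated as irrelevant to the condition and removed. The boundary is
#' PCC <= 0: a zero-correlation edge would carry no diffusion weight.
#' Edges with a constant-expression endpoint (correlation undefined) are
#' also removed and reported.
#'
#' @param network a [gene_network] whose genes all appear in `expr`.
#' @param expr an [expression_dataset].
#' @return list(network, report); removed edges are reported as
#'   `"from|to"` strings.
#' @export
filter_negative_edges <- function(network, expr) {
  missing <- setdiff(network$gene_ids, rownames(expr$values))
  if (length(missing)) {
    stopf("network gene(s) missing from expression data: %s",
          paste(utils::head(missing, 5L), collapse = ", "))
  }
  ed <- network$edges
  if (nrow(ed) == 0L) {
    return(list(network = network,
                report = filter_report("negative_edges", character(), 0L)))
  }
  sds <- apply(expr$values[unique(c(ed$from, ed$to)), , drop = FALSE],
               1L, stats::sd)
  pcc <- vapply(seq_len(nrow(ed)), function(i) {
    if (sds[[ed$from[i]]] == 0 || sds[[ed$to[i]]] == 0) return(NA_real_)
    stats::cor(expr$values[ed$from[i], ], expr$values[ed$to[i], ])
  }, 0)
  keep <- !is.na(pcc) & pcc > 0
  removed <- paste(ed$from[!keep], ed$to[!keep], sep = "|")
  list(network = gene_network(network$gene_ids, ed[keep, , drop = FALSE]),
       report = filter_report("negative_edges", removed, sum(keep)))
}

#' Remove genes left without any network interaction
#'
#' After edge filtering some genes may have no surviving edges; a
#' network-embedded model has nothing to say about them, so they are
#' removed from the expression data, the network, and the binding matrix.
#'
#' @param expr an [expression_dataset].
#' @param network a [gene_network] over the same universe.
#' @param binding a [binding_matrix] over the same universe.
#' @return list(expression, network, binding, report).
#' @export
drop_isolated_genes <- function(expr, network, binding) {
  deg <- network_degrees(network)
  removed <- names(deg)[deg == 0L]
  kept <- setdiff(network$gene_ids, removed)
  if (length(kept) == 0L) stopf("no gene retains a network interaction")
  aligned <- align_inputs(subset_expression(expr, genes = intersect(
    rownames(expr$values), kept)), binding, network)
  c(aligned, list(report = filter_report("isolated_genes", removed,
                                         length(kept))))
}

#' Run the full preprocessing pipeline
#'
#' Applies, in order: expression floor, variance filter, alignment onto the
#' network, edge-sign filter, isolation filter, and microRNA sparsity
#' filter.
#'
#' @param expr an [expression_dataset].
#' @param binding a [binding_matrix].
#' @param network a [gene_network].
#' @param floor,min_sd,min_targets filter thresholds (see the individual
#'   filters).
#' @param log2_transform apply `log2(x + 1)` to the expression values after
#'   the floor filter (the floor applies to the raw scale).
#' @return list(expression, binding, network, reports) where `reports` is a
#'   list of [filter_report]s in application order.
#' @export
preprocess_pipeline <- function(expr, binding, network,
                                floor = 100, min_sd = 0.2,
                                min_targets = 100,
                                log2_transform = FALSE) {
  reports <- list()
  f1 <- filter_unexpressed(expr, floor)
  reports$unexpressed <- f1$report
  if (is.null(f1$expression)) stopf("all genes fall below the expression floor")
  expr <- f1$expression
  if (log2_transform) {
    expr <- expression_dataset(log2(expr$values + 1), expr$labels)
  }
  f2 <- filter_low_variance(expr, min_sd)
  reports$low_variance <- f2$report
  if (is.null(f2$expression)) stopf("all genes fall below the variance floor")
  expr <- f2$expression
  al <- align_inputs(expr, binding, network)
  f3 <- filter_negative_edges(al$network, al$expression)
  reports$negative_edges <- f3$report
  f4 <- drop_isolated_genes(al$expression, f3$network, al$binding)
  reports$isolated_genes <- f4$report
  f5 <- filter_sparse_mirnas(f4$binding, min_targets)
  reports$sparse_mirnas <- f5$report
  list(expression = f4$expression, binding = f5$binding,
       network = f4$network, reports = reports)
}

#' Serialize filter reports
#'
#' Writes a TSV of (stage, removed_id) rows and returns the per-stage kept
#' counts as a named list (suitable for JSON serialization).
#'
#' @param reports list of [filter_report]s.
#' @param path output TSV path.
#' @return Named list of kept counts, invisibly.
#' @export
write_filter_reports <- function(reports, path) {
  rows <- do.call(rbind, lapply(reports, function(r) {
    if (length(r$removed) == 0L) return(NULL)
    data.frame(stage = r$stage, removed_id = r$removed)
  }))
  if (is.null(rows)) rows <- data.frame(stage = character(),
                                        removed_id = character())
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(lapply(reports, function(r)
    list(removed = length(r$removed), kept = r$kept)))
}
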