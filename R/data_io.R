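#' Read a gene expression table with phenotype labels
#'
#' Expects a tab-separated table whose header row holds sample IDs and whose
#' first column holds gene IDs; all remaining cells must be numeric. Labels
#' come from a two-column sidecar TSV (sample ID, class), or as a named
#' vector/factor supplied directly.
#'
#' @param path path to the expression TSV.
#' @param labels either the path of a two-column (sample, class) TSV without
#'   header, or a vector of class labels named by sample ID.
#' @return An [expression_dataset].
#' @export
read_expression <- function(path, labels) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    stopf("'%s': empty data section", path)
  }
  gids <- raw[[1L]]
  assert_unique(gids, "gene IDs")
  sids <- colnames(raw)[-1L]
  assert_unique(sids, "sample IDs")
  num <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw))))
  num <- matrix(num, nrow = nrow(raw),
                dimnames = list(gids, sids))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stopf("'%s': non-numeric value at gene '%s', sample '%s'",
          path, gids[bad[1L]], sids[bad[2L]])
  }
  if (length(labels) == 1L && is.character(labels) && file.exists(labels)) {
    lab_tab <- utils::read.delim(labels, header = FALSE, sep = "\t",
                                 colClasses = "character")
    if (ncol(lab_tab) < 2L) stopf("label file '%s' needs 2 columns", labels)
    labels <- stats::setNames(lab_tab[[2L]], lab_tab[[1L]])
  }
  if (is.null(names(labels))) stopf("labels must be named by sample ID")
  missing <- setdiff(sids, names(labels))
  if (length(missing)) {
    stopf("no label for sample(s): %s",
          paste(utils::head(missing, 5L), collapse = ", "))
  }
  expression_dataset(num, labels[sids])
}

#' Write an expression dataset as TSV plus label sidecar
#'
#' @param expr an [expression_dataset].
#' @param path output path for the expression TSV.
#' @param labels_path output path for the (sample, class) sidecar TSV.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path,
                             labels_path = paste0(path, ".labels")) {
  df <- data.frame(gene = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = colnames(expr$values),
               class = as.character(expr$labels)),
    labels_path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read microRNA-to-gene target pairs into a binding matrix
#'
#' Each file is a headerless two-column TSV of (microRNA, target gene)
#' pairs. Several files (e.g. experimental evidence plus independent
#' prediction tools) are combined by union: a gene is considered bound by a
#' microRNA when any source reports the pair. Pairs mentioning genes outside
#' `all_gene_ids` are ignored; genes never mentioned get all-zero rows.
#'
#' @param paths one or more paths of pair TSVs.
#' @param all_gene_ids the gene universe defining the row space.
#' @return A [binding_matrix] over `all_gene_ids`.
#' @export
read_mirna_targets <- function(paths, all_gene_ids) {
  all_gene_ids <- as.character(all_gene_ids)
  assert_unique(all_gene_ids, "gene IDs")
  pairs <- list()
  for (path in paths) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nfield <- lengths(parts)
    if (any(nfield < 2L)) {
      stopf("'%s': malformed line %d (expected 2 tab-separated fields)",
            path, which(nfield < 2L)[1L])
    }
    pairs[[length(pairs) + 1L]] <-
      data.frame(mirna = vapply(parts, `[[`, "", 1L),
                 gene  = vapply(parts, `[[`, "", 2L),
                 stringsAsFactors = FALSE)
  }
  pairs <- unique(do.call(rbind, pairs))
  pairs <- pairs[pairs$gene %in% all_gene_ids, , drop = FALSE]
  mirnas <- sort(unique(pairs$mirna))
  Z <- matrix(0, nrow = length(all_gene_ids), ncol = length(mirnas),
              dimnames = list(all_gene_ids, mirnas))
  if (nrow(pairs)) Z[cbind(pairs$gene, pairs$mirna)] <- 1
  binding_matrix(Z)
}

#' Write a binding matrix as microRNA-gene pairs
#'
#' @param binding a [binding_matrix].
#' @param path output TSV path (microRNA, gene; no header).
#' @return `path`, invisibly.
#' @export
write_mirna_targets <- function(binding, path) {
  idx <- which(binding$Z == 1, arr.ind = TRUE)
  df <- data.frame(mirna = colnames(binding$Z)[idx[, 2L]],
                   gene = rownames(binding$Z)[idx[, 1L]])
  df <- df[order(df$mirna, df$gene), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene-network edge list
#'
#' Headerless two-column (optionally three-column, scored) TSV of undirected
#' interactions. The network is deduplicated and symmetric by construction;
#' self-loops are dropped; edges with an endpoint outside `all_gene_ids` are
#' dropped with a warning (interaction databases routinely export IDs
#' outside the expression platform).
#'
#' @param path edge TSV path.
#' @param all_gene_ids the gene universe (vertex set).
#' @return A [gene_network].
#' @export
read_network_edges <- function(path, all_gene_ids) {
  all_gene_ids <- as.character(all_gene_ids)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 2L)) {
    stopf("'%s': malformed line %d (expected >= 2 tab-separated fields)",
          path, which(nfield < 2L)[1L])
  }
  a <- vapply(parts, `[[`, "", 1L)
  b <- vapply(parts, `[[`, "", 2L)
  score <- ifelse(nfield >= 3L,
                  suppressWarnings(as.numeric(
                    vapply(parts, function(p) if (length(p) >= 3L) p[[3L]]
                           else NA_character_, ""))),
                  NA_real_)
  inside <- a %in% all_gene_ids & b %in% all_gene_ids
  if (any(!inside)) {
    warnf("'%s': dropped %d edge(s) with endpoints outside the gene universe",
          path, sum(!inside))
  }
  ed <- data.frame(from = a[inside], to = b[inside],
                   stringsAsFactors = FALSE)
  if (any(!is.na(score[inside]))) ed$score <- score[inside]
  gene_network(all_gene_ids, ed)
}

#' Write a gene network as an edge TSV
#'
#' @param network a [gene_network].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_network_edges <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, `name TAB description TAB member1 TAB
#' member2 ...`. Duplicate members within a line are stored once; a
#' duplicated set name is an error.
#'
#' @param path GMT file path.
#' @return A [gene_set_collection]; the GMT description field becomes the
#'   source tag.
#' @export
read_gene_sets_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 3L)) {
    stopf("'%s': line %d has fewer than 3 fields", path, which(nfield < 3L)[1L])
  }
  nm <- vapply(parts, `[[`, "", 1L)
  assert_unique(nm, "gene-set names")
  src <- vapply(parts, `[[`, "", 2L)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  gene_set_collection(stats::setNames(sets, nm), src)
}

#' Write a gene-set collection in GMT format
#'
#' @param collection a [gene_set_collection].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$source[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Align expression, binding, and network onto one gene universe
#'
#' The downstream universe is the set of genes present in the expression
#' data that have at least one network edge; microRNA binding is optional
#' per gene, so genes absent from the binding data keep all-zero rows rather
#' than being dropped. All three structures are returned restricted to the
#' same ordered universe. Applying the function twice is a no-op.
#'
#' @param expr an [expression_dataset].
#' @param binding a [binding_matrix] (possibly over a different universe).
#' @param network a [gene_network] (possibly over a different universe).
#' @return A list with elements `expression`, `binding`, `network`.
#' @export
align_inputs <- function(expr, binding, network) {
  deg <- network_degrees(network)
  connected <- names(deg)[deg > 0L]
  universe <- intersect(rownames(expr$values), connected)
  if (length(universe) == 0L) {
    stopf("no gene is shared between the expression data and the network")
  }
  universe <- rownames(expr$values)[rownames(expr$values) %in% universe]
  expr2 <- subset_expression(expr, genes = universe)
  Z <- matrix(0, nrow = length(universe), ncol = ncol(binding$Z),
              dimnames = list(universe, colnames(binding$Z)))
  common <- intersect(universe, rownames(binding$Z))
  Z[common, ] <- binding$Z[common, , drop = FALSE]
  keep <- network$edges$from %in% universe & network$edges$to %in% universe
  net2 <- gene_network(universe, network$edges[keep, , drop = FALSE])
  list(expression = expr2, binding = binding_matrix(Z), network = net2)
}

#' Write a gene ranking as TSV
#'
#' Columns: gene, mi, gpa, rank, then the NFP partner IDs (`nfp_1..k`) when
#' an NFP table is attached to the ranking.
#'
#' @param ranking a `gene_ranking` as returned by [rank_genes] or
#'   [run_model].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  df <- ranking$table
  nfp <- attr(ranking, "nfp_table")
  if (!is.null(nfp)) {
    k <- nfp$k
    for (i in seq_len(k)) {
      df[[paste0("nfp_", i)]] <- vapply(df$gene, function(g) {
        p <- nfp$partners[[g]]
        if (length(p) >= i) p[[i]] else NA_character_
      }, "")
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
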