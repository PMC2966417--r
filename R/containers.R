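#' Expression dataset with two-class phenotype labels
#'
#' Bundles a genes-by-samples numeric expression matrix with a phenotype
#' label per sample. Gene and sample identifiers are opaque, case-sensitive
#' strings carried as dimnames; labels must take one or two distinct values
#' (one is allowed so that degenerate subsets can still be represented, but
#' every modelling function requires both classes).
#'
#' @param values numeric matrix, genes in rows, samples in columns; rownames
#'   are gene IDs, colnames are sample IDs.
#' @param labels character or factor of length `ncol(values)` giving the
#'   phenotype class of each sample.
#' @return An object of class `expression_dataset` with elements `values`
#'   (the matrix) and `labels` (a factor).
#' @export
expression_dataset <- function(values, labels) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stopf("`values` must carry gene IDs as rownames and sample IDs as colnames")
  }
  if (nrow(values) == 0L || ncol(values) == 0L) {
    stopf("expression matrix is empty")
  }
  assert_unique(rownames(values), "gene IDs")
  assert_unique(colnames(values), "sample IDs")
  if (length(labels) != ncol(values)) {
    stopf("got %d labels for %d samples", length(labels), ncol(values))
  }
  if (anyNA(values)) stopf("expression values contain NA")
  labels <- factor(as.character(labels))
  if (nlevels(labels) > 2L) {
    stopf("labels must take at most 2 distinct values, got %d", nlevels(labels))
  }
  structure(list(values = values, labels = labels),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d samples; classes: %s\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s (%d)", levels(x$labels),
                            tabulate(x$labels)), collapse = ", ")))
  invisible(x)
}

gene_ids <- function(x) UseMethod("gene_ids")
#' @export
gene_ids.expression_dataset <- function(x) rownames(x$values)
#' @export
gene_ids.binding_matrix <- function(x) rownames(x$Z)
#' @export
gene_ids.gene_network <- function(x) x$gene_ids

# Subset an expression dataset by gene IDs and/or sample IDs (keeps order
# of the supplied vectors).
subset_expression <- function(expr, genes = NULL, samples = NULL) {
  v <- expr$values
  lab <- expr$labels
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(v))
    if (length(missing)) stopf("unknown gene IDs: %s",
                               paste(utils::head(missing, 5L), collapse = ", "))
    v <- v[genes, , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(v))
    if (length(missing)) stopf("unknown sample IDs: %s",
                               paste(utils::head(missing, 5L), collapse = ", "))
    lab <- lab[match(samples, colnames(v))]
    v <- v[, samples, drop = FALSE]
  }
  expression_dataset(v, droplevels(lab))
}

#' Binary microRNA binding matrix
#'
#' Genes-by-microRNAs 0/1 matrix: `Z[i, q] = 1` means gene `i` carries a
#' (verified or predicted) binding site for microRNA `q`. Genes with no
#' known regulator keep an all-zero row; they remain first-class citizens of
#' the analysis universe.
#'
#' @param Z numeric 0/1 matrix with gene IDs as rownames and microRNA IDs as
#'   colnames.
#' @return An object of class `binding_matrix`.
#' @export
binding_matrix <- function(Z) {
  if (!is.matrix(Z)) stopf("`Z` must be a matrix")
  if (is.null(rownames(Z)) || is.null(colnames(Z))) {
    stopf("`Z` must carry gene and microRNA IDs as dimnames")
  }
  assert_unique(rownames(Z), "gene IDs")
  assert_unique(colnames(Z), "microRNA IDs")
  if (!all(Z %in% c(0, 1))) stopf("binding matrix entries must be 0 or 1")
  storage.mode(Z) <- "double"
  structure(list(Z = Z), class = "binding_matrix")
}

#' @export
print.binding_matrix <- function(x, ...) {
  cat(sprintf("binding_matrix: %d genes x %d microRNAs; %d bound genes\n",
              nrow(x$Z), ncol(x$Z), sum(rowSums(x$Z) > 0)))
  invisible(x)
}

#' Undirected gene network
#'
#' An undirected graph over a declared gene universe. Edges are stored as a
#' canonical data frame (`from < to` lexicographically), deduplicated, with
#' self-loops forbidden; an optional nonnegative `score` column carries
#' confidence weights from the source database (unused by the models, which
#' weight edges with expression/binding correlations instead).
#'
#' @param genes character vector of gene IDs (the vertex set; may include
#'   isolated genes).
#' @param edges two-column character matrix or data frame of endpoints, plus
#'   an optional third numeric score column.
#' @return An object of class `gene_network` with `gene_ids` and `edges`
#'   (data frame with columns `from`, `to`, and optionally `score`).
#' @export
gene_network <- function(genes, edges = NULL) {
  genes <- as.character(genes)
  assert_unique(genes, "gene IDs")
  if (is.null(edges) || NROW(edges) == 0L) {
    ed <- data.frame(from = character(), to = character(),
                     stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    a <- as.character(edges[[1L]])
    b <- as.character(edges[[2L]])
    score <- if (ncol(edges) >= 3L) as.numeric(edges[[3L]]) else NULL
    keep <- a != b                       # self-loops dropped
    a <- a[keep]; b <- b[keep]
    if (!is.null(score)) score <- score[keep]
    swap <- a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    key <- paste(a, b, sep = "\r")
    first <- !duplicated(key)
    ed <- data.frame(from = a[first], to = b[first],
                     stringsAsFactors = FALSE)
    if (!is.null(score)) ed$score <- score[first]
    bad <- setdiff(unique(c(ed$from, ed$to)), genes)
    if (length(bad)) stopf("edge endpoint(s) outside gene universe: %s",
                           paste(utils::head(bad, 5L), collapse = ", "))
  }
  structure(list(gene_ids = genes, edges = ed), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d genes, %d edges\n",
              length(x$gene_ids), nrow(x$edges)))
  invisible(x)
}

# Degree of every gene in the universe (named integer vector).
network_degrees <- function(network) {
  deg <- table(factor(c(network$edges$from, network$edges$to),
                      levels = network$gene_ids))
  stats::setNames(as.integer(deg), network$gene_ids)
}

# Named list: gene -> character vector of first-order neighbours.
network_neighbors <- function(network) {
  nb <- lapply(stats::setNames(network$gene_ids, network$gene_ids),
               function(g) character())
  if (nrow(network$edges)) {
    nb1 <- split(network$edges$to, factor(network$edges$from,
                                          levels = network$gene_ids))
    nb2 <- split(network$edges$from, factor(network$edges$to,
                                            levels = network$gene_ids))
    nb <- Map(function(a, b) sort(unique(c(a, b))), nb1, nb2)
  }
  nb
}

#' Named collection of gene sets
#'
#' Flat, named gene sets (GO categories, pathways, planted modules...).
#' Set names are unique; each set is a character vector of gene IDs with an
#' optional per-set source tag.
#'
#' @param sets named list of character vectors.
#' @param source optional character vector (length 1 or `length(sets)`)
#'   tagging each set's provenance.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, source = "unknown") {
  if (length(sets) && is.null(names(sets))) stopf("gene sets must be named")
  assert_unique(names(sets), "gene-set names")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(lengths(sets) == 0L)) stopf("empty gene set not allowed")
  source <- rep_len(as.character(source), length(sets))
  structure(list(sets = sets,
                 source = stats::setNames(source, names(sets))),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, sizes %s\n", length(x$sets),
              if (length(x$sets))
                paste(range(lengths(x$sets)), collapse = "-") else "-"))
  invisible(x)
}

#' Per-stage filter report
#'
#' @param stage name of the filtering stage.
#' @param removed character vector of removed item IDs.
#' @param kept number of items surviving the stage.
#' @return An object of class `filter_report`.
#' @export
filter_report <- function(stage, removed, kept) {
  structure(list(stage = stage, removed = as.character(removed),
                 kept = as.integer(kept)),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter '%s': removed %d, kept %d\n",
              x$stage, length(x$removed), x$kept))
  invisible(x)
}
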