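#' Correlation-weighted graph
#'
#' Assembles the symmetric weight matrix W of the gene network, with
#' `W[i, j]` equal to the combined gene-gene correlation on edge (i, j) and
#' zero elsewhere (zero diagonal). The network must already have passed the
#' edge-sign filter, so every retained edge carries a strictly positive
#' weight; a non-positive weight indicates a violated filter contract and
#' is an error.
#'
#' @param network a [gene_network].
#' @param correlations an `edge_correlation_table` from
#'   [edge_correlations] covering every network edge.
#' @return An object of class `weighted_graph`: list(gene_ids, W, degrees)
#'   where `degrees` is the vector of weighted degrees d_j = sum_i W[i, j].
#' @export
build_weighted_graph <- function(network, correlations) {
  genes <- network$gene_ids
  m <- length(genes)
  W <- matrix(0, m, m, dimnames = list(genes, genes))
  ed <- network$edges
  key_net <- paste(ed$from, ed$to, sep = "\r")
  key_cor <- paste(correlations$from, correlations$to, sep = "\r")
  idx <- match(key_net, key_cor)
  if (anyNA(idx)) stopf("correlation table is missing %d network edge(s)",
                        sum(is.na(idx)))
  w <- correlations$combined[idx]
  if (any(w <= 0)) {
    stopf("non-positive combined correlation on %d retained edge(s); %s",
          sum(w <= 0), "run the edge filters first")
  }
  W[cbind(ed$from, ed$to)] <- w
  W[cbind(ed$to, ed$from)] <- w
  structure(list(gene_ids = genes, W = W, degrees = colSums(W)),
            class = "weighted_graph")
}

#' Markov transition matrix of the weighted graph
#'
#' Normalizes the symmetric weight matrix by the diagonal degree matrix,
#' Q = W D^-1, so that every column of Q sums to one; `Q[i, j]` is the
#' probability of a one-step random walk from gene j arriving at gene i.
#' (Its transpose is the row-stochastic walk operator P = D^-1 W; both
#' conventions induce the same diffusion distances on a symmetric W.)
#'
#' @param W symmetric nonnegative weight matrix (or a `weighted_graph`).
#' @return Column-stochastic matrix of the same dimension.
#' @export
transition_matrix <- function(W) {
  if (inherits(W, "weighted_graph")) W <- W$W
  d <- colSums(W)
  if (any(d <= 0)) stopf("zero-degree column: gene(s) %s",
                         paste(utils::head(colnames(W)[d <= 0], 5L),
                               collapse = ", "))
  sweep(W, 2L, d, "/")
}

# Connected components of the positive-weight graph; integer membership
# vector aligned with rownames(W).
graph_components <- function(W) {
  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected",
                                           diag = FALSE)
  igraph::components(g)$membership
}

#' Diffusion distance by explicit matrix powering
#'
#' The t-step diffusion distance between genes i and j compares their
#' t-step random-walk transition distributions, weighting each destination
#' gene k inversely by its stationary mass phi(k) = d_k / sum(d):
#' `D_t(i, j)^2 = sum_k (p_t(i, k) - p_t(j, k))^2 / phi(k)`,
#' with P = D^-1 W the row-stochastic walk operator. Two genes are close
#' when many (possibly indirect) paths connect them. This direct
#' computation is the reference oracle for the spectral embedding.
#'
#' @param W symmetric nonnegative weight matrix (or `weighted_graph`).
#' @param t positive integer diffusion time.
#' @param i,j gene IDs or indices.
#' @return Nonnegative distance; `Inf` when i and j lie in different
#'   connected components.
#' @export
diffusion_distance_brute <- function(W, t, i, j) {
  if (inherits(W, "weighted_graph")) W <- W$W
  if (t < 1 || t != round(t)) stopf("t must be a positive integer")
  if (is.character(i)) i <- match(i, rownames(W))
  if (is.character(j)) j <- match(j, rownames(W))
  comp <- graph_components(W)
  if (comp[i] != comp[j]) return(Inf)
  in_comp <- comp == comp[i]
  Wc <- W[in_comp, in_comp, drop = FALSE]
  ic <- sum(in_comp[seq_len(i)])
  jc <- sum(in_comp[seq_len(j)])
  d <- colSums(Wc)
  P <- sweep(Wc, 1L, d, "/")              # row-stochastic
  Pt <- diag(nrow(Wc))
  for (s in seq_len(t)) Pt <- Pt %*% P
  phi <- d / sum(d)
  sqrt(sum((Pt[ic, ] - Pt[jc, ])^2 / phi))
}

#' Diffusion-map embedding of a weighted gene graph
#'
#' Spectrally embeds each connected component so that Euclidean distance in
#' the embedding approximates (and at full rank equals) the diffusion
#' distance. Computed via the symmetric conjugate S = D^-1/2 W D^-1/2
#' (numerically stable symmetric eigenproblem); eigenvectors are mapped
#' back to right eigenvectors psi of the walk operator and normalized so
#' that `sum_k phi(k) psi_l(k)^2 = 1`, which makes
#' `D_t(i, j)^2 = sum_{l>=2} lambda_l^(2t) (psi_l(i) - psi_l(j))^2`.
#' The trivial eigenpair (lambda = 1, constant psi) contributes nothing to
#' any distance and is excluded from the coordinates. Negative eigenvalues
#' are retained (lambda^t with integer t is well-defined). Eigenvector sign
#' is fixed by making the first nonzero entry positive, for reproducible
#' serialization.
#'
#' @param W symmetric nonnegative weight matrix (or `weighted_graph`).
#' @param t positive integer diffusion time.
#' @param L number of retained non-trivial components per connected
#'   component, or `"auto"` to keep every component with
#'   `|lambda_l|^t >= 1e-6 * |lambda_2|^t` (truncation error negligible).
#' @return An object of class `diffusion_embedding`: list(gene_ids, t,
#'   coords (m x Lmax matrix, rows zero-padded), eigenvalues (per
#'   component), component (membership vector)).
#' @export
diffusion_embedding <- function(W, t = 1, L = "auto") {
  if (inherits(W, "weighted_graph")) W <- W$W
  if (t < 1 || t != round(t)) stopf("t must be a positive integer")
  m <- nrow(W)
  genes <- rownames(W) %||% as.character(seq_len(m))
  comp <- graph_components(W)
  n_comp <- max(comp)
  coords_list <- vector("list", n_comp)
  evals_list <- vector("list", n_comp)
  for (c_id in seq_len(n_comp)) {
    in_comp <- which(comp == c_id)
    mc <- length(in_comp)
    if (mc == 1L) {                        # isolated vertex: point embedding
      coords_list[[c_id]] <- matrix(0, 1L, 0L)
      evals_list[[c_id]] <- numeric()
      next
    }
    Wc <- W[in_comp, in_comp, drop = FALSE]
    d <- colSums(Wc)
    inv_sqrt_d <- 1 / sqrt(d)
    S <- Wc * tcrossprod(inv_sqrt_d)       # D^-1/2 W D^-1/2
    eig <- eigen(S, symmetric = TRUE)
    ord <- order(abs(eig$values), decreasing = TRUE)
    lambda <- eig$values[ord]
    V <- eig$vectors[, ord, drop = FALSE]
    # psi_l = sqrt(sum(d)) * D^-1/2 v_l  =>  sum_k phi_k psi_l(k)^2 = 1
    Psi <- sqrt(sum(d)) * (inv_sqrt_d * V)
    # drop the trivial lambda = 1 component (constant psi)
    lambda <- lambda[-1L]
    Psi <- Psi[, -1L, drop = FALSE]
    if (identical(L, "auto")) {
      if (length(lambda) == 0L) {
        keep <- 0L
      } else {
        keep <- sum(abs(lambda)^t >= 1e-6 * abs(lambda[1L])^t)
      }
    } else {
      if (L < 1) stopf("L must be >= 1 or \"auto\"")
      keep <- min(L, length(lambda))
    }
    lambda <- lambda[seq_len(keep)]
    Psi <- Psi[, seq_len(keep), drop = FALSE]
    # deterministic sign: first nonzero entry of each psi positive
    for (l in seq_len(keep)) {
      nz <- which(abs(Psi[, l]) > 1e-12)[1L]
      if (!is.na(nz) && Psi[nz, l] < 0) Psi[, l] <- -Psi[, l]
    }
    coords_list[[c_id]] <- sweep(Psi, 2L, lambda^t, "*")
    evals_list[[c_id]] <- lambda
  }
  l_max <- max(c(0L, vapply(coords_list, ncol, 0L)))
  coords <- matrix(0, m, l_max,
                   dimnames = list(genes,
                                   if (l_max) paste0("coord_", seq_len(l_max))))
  for (c_id in seq_len(n_comp)) {
    in_comp <- which(comp == c_id)
    cc <- coords_list[[c_id]]
    if (ncol(cc)) coords[in_comp, seq_len(ncol(cc))] <- cc
  }
  structure(list(gene_ids = genes, t = t, coords = coords,
                 eigenvalues = evals_list, component = comp),
            class = "diffusion_embedding")
}

#' @export
print.diffusion_embedding <- function(x, ...) {
  cat(sprintf("diffusion_embedding: %d genes, t = %d, %d component(s), L = %d\n",
              length(x$gene_ids), x$t, max(x$component), ncol(x$coords)))
  invisible(x)
}

#' Pairwise diffusion distances from an embedding
#'
#' Euclidean distances between embedding coordinate rows; genes in
#' different connected components are at infinite distance (no path of any
#' length connects them).
#'
#' @param embedding a `diffusion_embedding`.
#' @return Symmetric m x m matrix with zero diagonal, `Inf` across
#'   components.
#' @export
pairwise_diffusion_distances <- function(embedding) {
  dm <- as.matrix(stats::dist(embedding$coords))
  dimnames(dm) <- list(embedding$gene_ids, embedding$gene_ids)
  cross <- outer(embedding$component, embedding$component, "!=")
  dm[cross] <- Inf
  dm
}
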