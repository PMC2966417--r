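# Independent oracles and tiny fixture builders, deliberately written with
# naive loops/enumeration so they share no code path with the package.

# Plug-in mutual information by explicit cell loops (bits).
mi_oracle <- function(x, y, bins = 10) {
  edges <- seq(min(x), max(x), length.out = bins + 1)
  bin_of <- integer(length(x))
  for (i in seq_along(x)) {
    b <- 1L
    for (e in 2:(bins + 1)) if (x[i] > edges[e]) b <- b + 1L
    bin_of[i] <- min(b, bins)
  }
  classes <- sort(unique(as.character(y)))
  n <- length(x)
  mi <- 0
  for (b in 1:bins) for (cl in classes) {
    nbc <- sum(bin_of == b & y == cl)
    if (nbc == 0) next
    nb <- sum(bin_of == b); nc <- sum(y == cl)
    mi <- mi + (nbc / n) * log2((nbc * n) / (nb * nc))
  }
  mi
}

# Upper-tail hypergeometric by exhaustive enumeration of all selections.
hyper_oracle <- function(N, K, n, x) {
  sel <- utils::combn(N, n)
  hits <- 0
  for (j in seq_len(ncol(sel))) {
    if (sum(sel[, j] <= K) >= x) hits <- hits + 1
  }
  hits / ncol(sel)
}

# AUC by all positive-negative pair enumeration, ties = 1/2.
auc_oracle <- function(scores, labels) {
  labels <- factor(labels)
  pos <- which(labels == levels(labels)[2])
  neg <- which(labels == levels(labels)[1])
  s <- 0
  for (i in pos) for (j in neg) {
    s <- s + if (scores[i] > scores[j]) 1 else if (scores[i] == scores[j]) 0.5 else 0
  }
  s / (length(pos) * length(neg))
}

# Benjamini-Hochberg step-up by the textbook recursion.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[ord[i]] * m / i)
    adj[ord[i]] <- val
    prev <- val
  }
  pmin(adj, 1)
}

# Random connected symmetric positively weighted graph.
rand_weighted_graph <- function(m, seed, p_edge = 0.35) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(m))
  W <- matrix(0, m, m, dimnames = list(ids, ids))
  for (i in seq_len(m - 1)) {          # random spanning tree keeps it connected
    j <- sample(seq_len(i), 1) + 0
    w <- runif(1, 0.1, 1)
    W[i + 1, j] <- W[j, i + 1] <- w
  }
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    if (W[i, j] == 0 && runif(1) < p_edge) {
      W[i, j] <- W[j, i] <- runif(1, 0.1, 1)
    }
  }
  W
}

# Small aligned toy triple: 6 genes on a path-plus-triangle network with
# hand-set expression and binding.
toy_inputs <- function() {
  genes <- c("a", "b", "c", "d", "e", "f")
  samples <- sprintf("s%d", 1:8)
  set.seed(7)
  base <- matrix(rnorm(48, 500, 5), 6, 8, dimnames = list(genes, samples))
  # a,b,c co-vary (shared shift in second class); d,e,f noise
  shift <- rep(c(0, 10), each = 4)
  base["a", ] <- base["a", ] + shift
  base["b", ] <- base["b", ] + shift
  base["c", ] <- base["c", ] + shift
  labels <- setNames(rep(c("ctl", "dis"), each = 4), samples)
  expr <- expression_dataset(base, labels)
  net <- gene_network(genes, rbind(c("a", "b"), c("b", "c"), c("a", "c"),
                                   c("c", "d"), c("d", "e"), c("e", "f")))
  Z <- matrix(0, 6, 4, dimnames = list(genes, paste0("m", 1:4)))
  Z[c("a", "b", "c"), c("m1", "m2")] <- 1
  Z["d", "m3"] <- 1
  Z["e", c("m3", "m4")] <- 1
  list(expression = expr, network = net, binding = binding_matrix(Z))
}
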