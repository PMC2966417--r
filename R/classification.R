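#' Rank-based AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic: the
#' fraction of (positive, negative) score pairs ordered correctly, ties
#' counting one half. Invariant to any strictly monotone transform of the
#' scores.
#'
#' @param scores numeric classifier scores (larger = more positive-like).
#' @param labels binary labels; the second factor level (or the larger
#'   value) is the positive class.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stopf("AUC needs exactly 2 classes present")
  pos <- labels == levels(labels)[2L]
  r <- rank(scores)
  n_pos <- sum(pos); n_neg <- sum(!pos)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Stratified cross-validation folds
#'
#' Partitions samples into `n_folds` groups, distributing each class round-
#' robin over folds after a seeded shuffle, so class counts per fold are
#' within one of proportional (e.g. 35 samples of 17 + 18 over 6 folds give
#' five folds of 6 and one of 5).
#'
#' @param labels binary labels (factor or vector) of length n.
#' @param n_folds number of folds (>= 2, <= n).
#' @param seed optional integer seed.
#' @return Integer vector of fold assignments in 1..n_folds.
#' @export
make_folds <- function(labels, n_folds = 6, seed = NULL) {
  n <- length(labels)
  if (n_folds < 2L) stopf("n_folds must be >= 2")
  if (n_folds > n) stopf("n_folds = %d exceeds n = %d samples", n_folds, n)
  labels <- factor(labels)
  if (n_folds > min(table(labels))) {
    warnf("n_folds exceeds the smaller class size; some folds lack a class")
  }
  fold <- integer(n)
  with_seed(seed, {
    offset <- 0L
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- ((seq_along(idx) - 1L + offset) %% n_folds) + 1L
      offset <- offset + length(idx)   # continue round-robin across classes
    }
  })
  fold
}

#' Reference classifier: RBF-kernel support vector machine
#'
#' Wraps `e1071::svm` with a radial-basis kernel and the library's default
#' hyperparameters; scores are signed decision values.
#'
#' @return A classifier spec: list(name, fit(x, y), score(model, x)) where
#'   `x` is a samples-by-genes matrix and `y` a two-level factor.
#' @export
classifier_svm_rbf <- function() {
  list(
    name = "svm_rbf",
    fit = function(x, y) {
      e1071::svm(x, factor(y), kernel = "radial", scale = TRUE)
    },
    score = function(model, x) {
      dv <- attr(stats::predict(model, x, decision.values = TRUE),
                 "decision.values")
      s <- as.numeric(dv[, 1L])
      # a positive decision value points at the class named first in the
      # column label; orient so larger always means the second factor level
      first <- sub("/.*$", "", colnames(dv)[1L])
      if (first == model$levels[2L]) s else -s
    })
}

#' Reference classifier: single-hidden-layer neural network
#'
#' Wraps `nnet::nnet` with `floor(sqrt(J))` hidden units for `J` input
#' genes (at least one) and entropy fitting; scores are the fitted
#' probability of the second class.
#'
#' @param maxit maximum training iterations.
#' @return A classifier spec (see [classifier_svm_rbf]).
#' @export
classifier_nnet <- function(maxit = 200) {
  list(
    name = "nnet",
    fit = function(x, y) {
      size <- max(1L, floor(sqrt(ncol(x))))
      nnet::nnet(x, stats::model.matrix(~ factor(y) - 1)[, 2L],
                 size = size, maxit = maxit, trace = FALSE,
                 entropy = TRUE, decay = 1e-3)
    },
    score = function(model, x) as.numeric(stats::predict(model, x)))
}

#' Cross-validation configuration
#'
#' @param n_folds folds per repeat.
#' @param n_repeats independent repeats of the whole cross-validation.
#' @param j_grid numbers of selected genes to evaluate.
#' @param seed integer seed; folds of repeat r use seed + r.
#' @return A `cv_config` list.
#' @export
cv_config <- function(n_folds = 6, n_repeats = 20, j_grid = 1:30,
                      seed = 1) {
  if (n_folds < 2L) stopf("n_folds must be >= 2")
  structure(list(n_folds = n_folds, n_repeats = n_repeats,
                 j_grid = as.integer(j_grid), seed = seed),
            class = "cv_config")
}

#' Cross-validated AUC of a gene-selection model
#'
#' The evaluation the selection models are judged by: within each fold of
#' each repeat, gene selection is rerun on the training samples only — the
#' selector never sees held-out expression (no information leakage; edge
#' filtering and correlations are recomputed per training fold). For every
#' J in the grid the top-J training-selected genes feed the classifier,
#' held-out samples are scored, scores are pooled across the folds of a
#' repeat, one AUC per (repeat, J) is computed, and repeats are averaged.
#'
#' @param expr preprocessed, aligned [expression_dataset].
#' @param binding aligned [binding_matrix].
#' @param network aligned [gene_network] (pre edge-sign filtering; the
#'   sign filter runs inside each training fold).
#' @param model model tag passed to [run_model], ignored when `selector`
#'   is given.
#' @param classifier a classifier spec ([classifier_svm_rbf],
#'   [classifier_nnet], or any list with `fit`/`score`).
#' @param config a [cv_config].
#' @param selector optional override: `function(expr_train)` returning a
#'   `gene_ranking`; receives only the training partition.
#' @param ... further arguments passed to [run_model] (k, t, bins, L).
#' @return List: `mean_auc` (named by J), `per_repeat` (repeats x J
#'   matrix), `config`.
#' @export
cross_validated_auc <- function(expr, binding, network, model = "MiNeGS",
                                classifier = classifier_svm_rbf(),
                                config = cv_config(), selector = NULL, ...) {
  if (any(config$j_grid > nrow(expr$values))) {
    stopf("j_grid exceeds the %d available genes", nrow(expr$values))
  }
  if (is.null(selector)) {
    selector <- function(expr_train) {
      filt <- filter_negative_edges(network, expr_train)
      run_model(expr_train, binding, filt$network, model = model, ...)
    }
  }
  samples <- colnames(expr$values)
  per_repeat <- matrix(NA_real_, config$n_repeats, length(config$j_grid),
                       dimnames = list(NULL, paste0("J", config$j_grid)))
  for (r in seq_len(config$n_repeats)) {
    fold <- make_folds(expr$labels, config$n_folds,
                       seed = (config$seed + r) %% .Machine$integer.max)
    pooled_scores <- lapply(config$j_grid, function(J) numeric())
    pooled_labels <- lapply(config$j_grid, function(J) character())
    for (f in sort(unique(fold))) {
      train_ids <- samples[fold != f]
      test_ids <- samples[fold == f]
      expr_train <- subset_expression(expr, samples = train_ids)
      if (nlevels(expr_train$labels) < 2L) next
      ranking <- selector(expr_train)
      for (ji in seq_along(config$j_grid)) {
        J <- config$j_grid[ji]
        genes <- top_genes(ranking, J)
        x_train <- t(expr_train$values[genes, , drop = FALSE])
        x_test <- t(expr$values[genes, test_ids, drop = FALSE])
        ok <- tryCatch({
          fit <- classifier$fit(x_train, expr_train$labels)
          s <- classifier$score(fit, x_test)
          pooled_scores[[ji]] <- c(pooled_scores[[ji]], s)
          pooled_labels[[ji]] <- c(pooled_labels[[ji]],
                                   as.character(expr$labels[match(
                                     test_ids, samples)]))
          TRUE
        }, error = function(e) {
          warnf("classifier failed on fold %d (J = %d): %s — fold skipped",
                f, J, conditionMessage(e))
          FALSE
        })
        if (!ok) next
      }
    }
    for (ji in seq_along(config$j_grid)) {
      lab <- factor(pooled_labels[[ji]], levels = levels(expr$labels))
      if (nlevels(droplevels(lab)) == 2L) {
        per_repeat[r, ji] <- auc(pooled_scores[[ji]], lab)
      }
    }
  }
  list(mean_auc = colMeans(per_repeat, na.rm = TRUE),
       per_repeat = per_repeat, config = config)
}
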