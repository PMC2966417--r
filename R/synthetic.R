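#' Configuration for the synthetic-data generator
#'
#' The generator emulates the structure the network-embedded models assume:
#' a scale-free background interaction network, planted functional modules
#' whose genes are densely wired and coordinately differentially expressed
#' between the two phenotype classes, and microRNA binding profiles shared
#' within modules. Defaults are the shipped study conditions: 300 genes,
#' 20 samples per class, three modules of 20 genes with a mean shift of 1.5
#' noise-SD units.
#'
#' @param m number of genes.
#' @param n_per_class samples per phenotype class (two classes).
#' @param n_modules number of planted modules.
#' @param module_size genes per module.
#' @param delta between-class mean shift of module genes, in units of the
#'   noise SD.
#' @param sigma within-class Gaussian noise SD (expression units).
#' @param pa_edges edges added per vertex by the preferential-attachment
#'   background network.
#' @param pa_power preferential-attachment exponent.
#' @param module_density probability of wiring each within-module gene
#'   pair (on top of the background network).
#' @param n_mirnas number of microRNAs.
#' @param mirnas_per_module number of regulator microRNAs assigned to each
#'   module (disjoint across modules).
#' @param sharing_prob probability that a module gene binds each of its
#'   module's regulators.
#' @param background_binding background probability of any gene-microRNA
#'   binding.
#' @param n_decoy_sets number of size-matched random decoy gene sets added
#'   to the emitted collection.
#' @param seed integer seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(m = 300, n_per_class = 20, n_modules = 3,
                             module_size = 20, delta = 1.5, sigma = 1,
                             pa_edges = 2, pa_power = 1,
                             module_density = 0.3, n_mirnas = 50,
                             mirnas_per_module = 5, sharing_prob = 0.9,
                             background_binding = 0.02,
                             n_decoy_sets = 6, seed = 1) {
  if (n_modules * module_size > m) stopf("modules cannot exceed m genes")
  if (n_modules * mirnas_per_module > n_mirnas) {
    stopf("not enough microRNAs for disjoint module regulator sets")
  }
  probs <- c(module_density, sharing_prob, background_binding)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0, 1]")
  if (delta < 0) stopf("delta must be >= 0")
  structure(as.list(environment()), class = "synthetic_config")
}

#' Generate a synthetic input bundle with planted truth
#'
#' Produces every input the pipeline consumes — expression with two-class
#' labels, gene network, binding matrix, gene-set collection, hallmark
#' list — plus the generating truth. Module genes of class "case" are
#' shifted by `delta * sigma`; the shared shift makes module genes mutually
#' positively correlated (between-class variance) while background genes
#' are class-independent noise around gene-specific baselines (uniform in
#' 300-800, so the raw-intensity filters pass by construction). The
#' background network is preferential-attachment scale-free; modules are
#' additionally wired at `module_density`. Each module owns a disjoint
#' regulator microRNA set bound at `sharing_prob` within the module;
#' binding elsewhere occurs at `background_binding`. The emitted gene sets
#' are the true modules plus size-matched random decoys; the hallmark list
#' is the planted differential genes.
#'
#' @param config a [synthetic_config].
#' @return List: expression, network, binding, gene_sets, hallmarks, truth
#'   (list with `modules`, `differential`, `regulators`), config.
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  with_seed(config$seed, {
    m <- config$m
    genes <- sprintf("g%04d", seq_len(m))
    samples <- c(sprintf("ctrl_%02d", seq_len(config$n_per_class)),
                 sprintf("case_%02d", seq_len(config$n_per_class)))
    labels <- stats::setNames(rep(c("control", "case"),
                                  each = config$n_per_class), samples)

    # planted modules on a random gene subset
    module_genes <- sample(genes, config$n_modules * config$module_size)
    modules <- split(module_genes,
                     rep(seq_len(config$n_modules),
                         each = config$module_size))
    names(modules) <- paste0("module_", seq_len(config$n_modules))

    # scale-free background + dense intra-module wiring
    g_pa <- igraph::sample_pa(m, power = config$pa_power,
                              m = config$pa_edges, directed = FALSE)
    el <- igraph::as_edgelist(g_pa, names = FALSE)
    perm <- sample(m)                      # decouple hubs from gene order
    edges <- data.frame(from = genes[perm[el[, 1L]]],
                        to = genes[perm[el[, 2L]]],
                        stringsAsFactors = FALSE)
    for (mod in modules) {
      pairs <- utils::combn(sort(mod), 2L)
      pick <- stats::runif(ncol(pairs)) < config$module_density
      if (any(pick)) {
        edges <- rbind(edges, data.frame(from = pairs[1L, pick],
                                         to = pairs[2L, pick],
                                         stringsAsFactors = FALSE))
      }
    }
    network <- gene_network(genes, edges)

    # expression: baseline + class shift for module genes + noise
    baseline <- stats::runif(m, 300, 800)
    shift <- stats::setNames(rep(0, m), genes)
    shift[module_genes] <- config$delta * config$sigma
    X <- matrix(stats::rnorm(m * length(samples), sd = config$sigma),
                m, length(samples), dimnames = list(genes, samples))
    X <- X + baseline
    X[, labels == "case"] <- X[, labels == "case"] + shift
    expr <- expression_dataset(X, labels)

    # binding: disjoint regulator sets per module + background
    mirnas <- sprintf("mir%03d", seq_len(config$n_mirnas))
    regulators <- split(
      mirnas[seq_len(config$n_modules * config$mirnas_per_module)],
      rep(seq_len(config$n_modules), each = config$mirnas_per_module))
    names(regulators) <- names(modules)
    Z <- matrix(stats::runif(m * config$n_mirnas) <
                  config$background_binding,
                m, config$n_mirnas, dimnames = list(genes, mirnas)) * 1
    for (mod_name in names(modules)) {
      for (g in modules[[mod_name]]) {
        hit <- stats::runif(config$mirnas_per_module) < config$sharing_prob
        Z[g, regulators[[mod_name]][hit]] <- 1
      }
    }
    binding <- binding_matrix(Z)

    # gene sets: truth modules + size-matched random decoys
    decoys <- lapply(seq_len(config$n_decoy_sets), function(i) {
      sample(genes, config$module_size)
    })
    names(decoys) <- paste0("decoy_", seq_len(config$n_decoy_sets))
    gene_sets <- gene_set_collection(
      c(modules, decoys),
      c(rep("module", length(modules)), rep("decoy", length(decoys))))

    differential <- stats::setNames(genes %in% module_genes &
                                      config$delta > 0, genes)
    hallmarks <- genes[differential]

    list(expression = expr, network = network, binding = binding,
         gene_sets = gene_sets, hallmarks = hallmarks,
         truth = list(modules = modules, differential = differential,
                      regulators = regulators),
         config = config)
  })
}

#' Score a pipeline run against the planted truth
#'
#' Reports (1) the fraction of planted differential genes recovered in the
#' top `top_n` of the ranking and (2) the fraction of partner assignments
#' from module genes that stay within the gene's own module — the
#' synthetic analogue of the annotation-coordination rate.
#'
#' @param truth the `truth` element of [generate_synthetic] output.
#' @param ranking a `gene_ranking` over (a subset of) the synthetic genes.
#' @param nfps optional `nfp_table` from the same run.
#' @param top_n selection size for the recovery fraction.
#' @return List: recovery, n_planted, n_recovered, intra_module_fraction
#'   (NA without `nfps`), n_assignments.
#' @export
recovery_report <- function(truth, ranking, nfps = NULL, top_n) {
  planted <- names(truth$differential)[truth$differential]
  planted_ranked <- intersect(planted, ranking$table$gene)
  top <- top_genes(ranking, min(top_n, nrow(ranking$table)))
  n_rec <- sum(planted_ranked %in% top)
  membership <- stats::setNames(
    rep(names(truth$modules), lengths(truth$modules)),
    unlist(truth$modules, use.names = FALSE))
  intra <- NA_real_
  n_assign <- 0L
  if (!is.null(nfps)) {
    hits <- 0L
    for (g in intersect(names(nfps$partners), names(membership))) {
      for (p in nfps$partners[[g]]) {
        n_assign <- n_assign + 1L
        if (!is.na(membership[p]) && membership[p] == membership[g]) {
          hits <- hits + 1L
        }
      }
    }
    intra <- if (n_assign) hits / n_assign else NA_real_
  }
  list(recovery = if (length(planted_ranked))
         n_rec / length(planted_ranked) else NA_real_,
       n_planted = length(planted_ranked), n_recovered = n_rec,
       intra_module_fraction = intra, n_assignments = n_assign)
}

#' Write a synthetic bundle to disk in the package's exchange formats
#'
#' Emits expression.tsv (+ labels sidecar), network.tsv,
#' mirna_targets.tsv, gene_sets.gmt, hallmarks.txt, and truth.json.
#'
#' @param sim output of [generate_synthetic].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(sim$expression, file.path(dir, "expression.tsv"),
                   file.path(dir, "labels.tsv"))
  write_network_edges(sim$network, file.path(dir, "network.tsv"))
  write_mirna_targets(sim$binding, file.path(dir, "mirna_targets.tsv"))
  write_gene_sets_gmt(sim$gene_sets, file.path(dir, "gene_sets.gmt"))
  writeLines(sim$hallmarks, file.path(dir, "hallmarks.txt"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(modules = sim$truth$modules,
           differential = names(sim$truth$differential)[
             sim$truth$differential],
           regulators = sim$truth$regulators),
      file.path(dir, "truth.json"), auto_unbox = FALSE, pretty = TRUE)
  }
  invisible(dir)
}
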