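test_that("generation is bit-reproducible under a fixed seed", {
  cfg <- synthetic_config(m = 80, n_per_class = 8, module_size = 10, seed = 4)
  s1 <- generate_synthetic(cfg)
  s2 <- generate_synthetic(cfg)
  expect_identical(s1$expression$values, s2$expression$values)
  expect_identical(s1$network$edges, s2$network$edges)
  expect_identical(s1$binding$Z, s2$binding$Z)
  expect_identical(s1$truth, s2$truth)
  # truth is consistent with the emitted artefacts
  expect_setequal(unlist(s1$truth$modules), names(
    s1$truth$differential)[s1$truth$differential])
  expect_setequal(s1$hallmarks, unlist(s1$truth$modules))
  expect_true(all(unlist(s1$truth$modules) %in% s1$network$gene_ids))
})

test_that("degenerate configurations behave as designed", {
  # delta = 0: nothing is truly differential
  s0 <- generate_synthetic(synthetic_config(m = 50, n_per_class = 5,
                                            module_size = 5, delta = 0,
                                            seed = 2))
  expect_false(any(s0$truth$differential))
  expect_length(s0$hallmarks, 0)
  # forced binding: within-module Jaccard 1, cross-module 0
  sf <- generate_synthetic(synthetic_config(
    m = 60, n_per_class = 5, n_modules = 2, module_size = 8,
    sharing_prob = 1, background_binding = 0, seed = 3))
  m1 <- sf$truth$modules[[1]]; m2 <- sf$truth$modules[[2]]
  expect_equal(jaccard_binding(sf$binding$Z[m1[1], ], sf$binding$Z[m1[2], ]), 1)
  expect_equal(jaccard_binding(sf$binding$Z[m1[1], ], sf$binding$Z[m2[1], ]), 0)
  expect_error(synthetic_config(m = 10, module_size = 20, n_modules = 1),
               "exceed")
})

test_that("the background network degree distribution is heavy-tailed", {
  sim <- generate_synthetic(synthetic_config(m = 500, n_per_class = 2,
                                             n_modules = 1, module_size = 10,
                                             seed = 6))
  deg <- minegs:::network_degrees(sim$network)
  deg <- sort(deg, decreasing = TRUE)
  # top 5% of genes carry a disproportionate share of edge endpoints
  top_share <- sum(deg[1:25]) / sum(deg)
  expect_gt(top_share, 0.2)
  expect_gt(max(deg), 5 * stats::median(deg))
})

test_that("the bundle round-trips through the exchange formats", {
  sim <- generate_synthetic(synthetic_config(m = 40, n_per_class = 6,
                                             module_size = 6, seed = 9))
  dir <- withr::local_tempdir()
  write_synthetic_bundle(sim, dir)
  expr <- read_expression(file.path(dir, "expression.tsv"),
                          file.path(dir, "labels.tsv"))
  expect_equal(expr$values, sim$expression$values, tolerance = 1e-9)
  expect_equal(as.character(expr$labels), as.character(sim$expression$labels))
  net <- read_network_edges(file.path(dir, "network.tsv"),
                            sim$network$gene_ids)
  expect_equal(net$edges[c("from", "to")],
               sim$network$edges[c("from", "to")])
  bind <- read_mirna_targets(file.path(dir, "mirna_targets.tsv"),
                             rownames(sim$binding$Z))
  nonzero <- colSums(sim$binding$Z) > 0   # pair format drops empty columns
  expect_equal(bind$Z, sim$binding$Z[, nonzero, drop = FALSE])
  gs <- read_gene_sets_gmt(file.path(dir, "gene_sets.gmt"))
  expect_equal(gs$sets, sim$gene_sets$sets)
  expect_equal(readLines(file.path(dir, "hallmarks.txt")), sim$hallmarks)
})

test_that("random rankings recover planted genes only at the chance rate", {
  sim <- generate_synthetic(synthetic_config(m = 100, n_per_class = 5,
                                             n_modules = 2, module_size = 10,
                                             seed = 13))
  set.seed(50)
  recs <- replicate(40, {
    fake <- rank_genes(setNames(runif(100), sim$network$gene_ids))
    recovery_report(sim$truth, fake, NULL, top_n = 20)$recovery
  })
  # E[recovery] = top_n / m = 0.2 for a uniformly random ranking
  expect_lt(abs(mean(recs) - 0.2), 0.06)
})

test_that("scrambling the network erases the MiNeGS advantage", {
  # coherent weak signal: partner averaging on the true wiring helps,
  # and cannot help once edges are randomly rewired
  cfg <- synthetic_config(m = 120, n_per_class = 15, n_modules = 2,
                          module_size = 12, delta = 1, module_density = 0.9,
                          sharing_prob = 1, background_binding = 0.01,
                          seed = 23)
  sim <- generate_synthetic(cfg)
  pp <- suppressWarnings(preprocess_pipeline(
    sim$expression, sim$binding, sim$network, min_targets = 1))
  mine <- suppressWarnings(run_model(pp$expression, pp$binding, pp$network,
                                     "MiNeGS"))
  classic <- run_model(pp$expression, pp$binding, pp$network, "classic")
  top <- 24
  rec_mine <- recovery_report(sim$truth, mine, NULL, top)$recovery
  rec_classic <- recovery_report(sim$truth, classic, NULL, top)$recovery
  expect_gte(rec_mine, rec_classic)

  # rewire: permute gene labels on the network, breaking module wiring
  set.seed(99)
  perm <- setNames(sample(pp$network$gene_ids), pp$network$gene_ids)
  scr_edges <- data.frame(from = unname(perm[pp$network$edges$from]),
                          to = unname(perm[pp$network$edges$to]))
  scr_net <- gene_network(pp$network$gene_ids, scr_edges)
  filt <- filter_negative_edges(scr_net, pp$expression)
  pp2 <- drop_isolated_genes(pp$expression, filt$network, pp$binding)
  mine_scr <- suppressWarnings(run_model(pp2$expression, pp2$binding,
                                         pp2$network, "MiNeGS"))
  classic_scr <- run_model(pp2$expression, pp2$binding, pp2$network,
                           "classic")
  rec_mine_scr <- recovery_report(sim$truth, mine_scr, NULL, top)$recovery
  rec_classic_scr <- recovery_report(sim$truth, classic_scr, NULL,
                                     top)$recovery
  # with scrambled wiring the advantage vanishes (no meaningful lift)
  expect_lte(rec_mine_scr, rec_classic_scr + 0.10)
  expect_lt(rec_mine_scr, rec_mine)
})

test_that("intra-module partner assignments exceed the uniform-null rate", {
  sim <- generate_synthetic(synthetic_config(m = 100, n_per_class = 15,
                                             n_modules = 2, module_size = 12,
                                             module_density = 0.9, seed = 31))
  pp <- suppressWarnings(preprocess_pipeline(
    sim$expression, sim$binding, sim$network, min_targets = 1))
  mine <- suppressWarnings(run_model(pp$expression, pp$binding, pp$network,
                                     "MiNeGS"))
  obs <- recovery_report(sim$truth, mine, attr(mine, "nfp_table"),
                         top_n = 24)$intra_module_fraction
  null_frac <- vapply(1:30, function(r) {
    rnd <- random_nfps(pp$network$gene_ids, k = 3, mode = "uniform",
                       seed = 1000 + r)
    recovery_report(sim$truth, mine, rnd, top_n = 24)$intra_module_fraction
  }, 0)
  expect_gt(obs, mean(null_frac))
})
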