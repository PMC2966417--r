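coord_fixture <- function() {
  # 5 genes, partners fixed by hand; 3 annotation sets
  nfps <- minegs:::nfp_table(
    list(g1 = c("g2", "g3", "g4"),   # g1,g2,g3 share set s1 -> coordinated
         g2 = c("g1", "g3", "g5"),   # g1,g2,g3 in s1 -> coordinated
         g3 = c("g4", "g5", "g1"),   # g3,g4 in s2 only (2 < 3) -> not
         g4 = c("g1", "g2", "g5"),   # g1,g2 in s1 with g4? g4 not in s1 -> not
         g5 = c("g1", "g2", "g3")),  # g1,g2,g3 in s1 -> coordinated
    rep(list(rep(NA_real_, 3)), 5), "diffusion", 3)
  sets <- gene_set_collection(list(
    s1 = c("g1", "g2", "g3"),
    s2 = c("g3", "g4"),
    s3 = c("g4", "g5")), "toy")
  list(nfps = nfps, sets = sets)
}

test_that("coordination rate matches exhaustive hand enumeration", {
  fx <- coord_fixture()
  res <- coordination_rate(fx$nfps, fx$sets, max_set_size = 200,
                           min_shared = 3)
  # every gene annotated somewhere -> all 5 evaluable; 3 coordinated by hand
  expect_equal(res$evaluable, 5L)
  expect_equal(res$coordinated, 3L)
  expect_equal(res$rate, 3 / 5)
  # full containment coordinates; 2-of-4 sharing does not
  one <- minegs:::nfp_table(list(g1 = c("g2", "g3", "g4")),
                            list(g1 = rep(NA_real_, 3)), "diffusion", 3)
  all4 <- gene_set_collection(list(s = paste0("g", 1:4)), "toy")
  expect_equal(coordination_rate(one, all4)$rate, 1)
  only2 <- gene_set_collection(list(s = c("g1", "g2"),
                                    t = c("g3", "g4", "g9")), "toy")
  expect_equal(coordination_rate(one, only2)$rate, 0)
})

test_that("coordination respects set-size discards and under-filled lists", {
  fx <- coord_fixture()
  # shrinking the window below |s1| = 3 removes both the coordinated calls
  # and (here) all annotations for g1/g2, so nothing is evaluable
  res_small <- coordination_rate(fx$nfps, fx$sets, max_set_size = 2)
  expect_equal(res_small$coordinated, 0L)
  expect_equal(res_small$evaluable, 0L)
  expect_true(is.na(res_small$rate))
  # enlarging the window can only keep or raise the rate
  r1 <- coordination_rate(fx$nfps, fx$sets, max_set_size = 3)
  r2 <- coordination_rate(fx$nfps, fx$sets, max_set_size = 200)
  expect_gte(r2$rate, r1$rate)
  # under-filled lists are not evaluable
  uf <- minegs:::nfp_table(list(g1 = c("g2", "g3")),
                           list(g1 = rep(NA_real_, 2)), "first_order", 3)
  expect_equal(coordination_rate(uf, fx$sets)$evaluable, 0L)
})

test_that("null coordination rates are seeded and sit below a structured truth", {
  sim <- generate_synthetic(synthetic_config(
    m = 60, n_per_class = 10, n_modules = 3, module_size = 10,
    module_density = 1, seed = 5))
  u <- sim$network$gene_ids
  n1 <- null_coordination("uniform", u, sim$network, sim$gene_sets,
                          reps = 10, seed = 77)
  n2 <- null_coordination("uniform", u, sim$network, sim$gene_sets,
                          reps = 10, seed = 77)
  expect_identical(n1, n2)
  expect_length(n1, 10)
  expect_error(null_coordination("uniform", u, sim$network, sim$gene_sets,
                                 reps = 0), "reps")
  # saturated annotation: every gene shares one set with every other
  allset <- gene_set_collection(list(everything = u), "toy")
  sat <- null_coordination("uniform", u, sim$network, allset,
                           reps = 3, seed = 1, max_set_size = length(u))
  expect_equal(sat, rep(1, 3))
  # structured truth: module-perfect partners beat the uniform null mean;
  # the true modules serve as both partner source and annotation
  truth_nfps <- minegs:::nfp_table(
    lapply(setNames(u, u), function(g) {
      mod <- Filter(function(m) g %in% m, sim$truth$modules)
      if (length(mod)) sort(setdiff(mod[[1]], g))[1:3] else character()
    }),
    lapply(setNames(u, u), function(g) rep(NA_real_, 3)),
    "diffusion", 3)
  obs <- coordination_rate(truth_nfps, sim$gene_sets)$rate
  expect_gt(obs, mean(n1))
})

test_that("one-sample t-test agrees with the closed form", {
  expect_equal(one_sample_ttest(c(0.1, 0.2, 0.3), 0.2), 1)  # t = 0
  null <- c(0.1, 0.2, 0.3)
  # hand closed form: t = (0.2 - 0.6) / (0.1 / sqrt(3)), df = 2
  t_stat <- (mean(null) - 0.6) / (sd(null) / sqrt(3))
  expect_equal(one_sample_ttest(null, 0.6),
               2 * pt(-abs(t_stat), df = 2))
  expect_error(one_sample_ttest(rep(0.2, 5), 0.3), "variance")
  expect_error(one_sample_ttest(0.1, 0.3), "2 null rates")
})

test_that("hallmark recovery counts top-ranked hits", {
  gpa <- setNames(seq(1, 0.1, length.out = 10), paste0("g", 1:10))
  r <- rank_genes(gpa)
  # 3 hallmarks placed at ranks 1, 2, 7 by construction
  hall <- c("g1", "g2", "g7")
  expect_equal(hallmark_recovery(r, hall, top_n = 5), 2L)
  expect_equal(hallmark_recovery(r, hall, top_n = 10), 3L)
  # all hallmarks first
  expect_equal(hallmark_recovery(r, c("g1", "g2", "g3"), top_n = 2), 2L)
  expect_warning(n <- hallmark_recovery(r, c("g1", "nope"), top_n = 10),
                 "outside")
  expect_equal(n, 1L)
  expect_error(hallmark_recovery(r, hall, top_n = 11), "exceeds")
})

test_that("hypergeometric tail matches exhaustive enumeration", {
  expect_equal(hypergeometric_p(10, 5, 5, 0), 1)
  expect_equal(hypergeometric_p(10, 5, 5, 5), 1 / choose(10, 5))
  # enumeration oracle over small universes
  for (case in list(c(8, 3, 4), c(10, 5, 5), c(12, 6, 4))) {
    N <- case[1]; K <- case[2]; n <- case[3]
    prev <- Inf
    for (x in 0:min(K, n)) {
      p <- hypergeometric_p(N, K, n, x)
      expect_equal(p, hyper_oracle(N, K, n, x), tolerance = 1e-12)
      expect_lte(p, prev)  # non-increasing in x
      prev <- p
    }
  }
  expect_error(hypergeometric_p(10, 11, 5, 1), "inconsistent")
  expect_error(hypergeometric_p(10, 5, 5, 6), "inconsistent")
})

test_that("BH adjustment matches the step-up recursion", {
  expect_equal(bh_adjust(0.4), 0.4)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(rep(0.2, 4)), rep(0.2, 4))
  set.seed(3)
  for (r in 1:20) {
    p <- runif(sample(2:12, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    # invariant to input order
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), adj[perm])
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("enrichment scan agrees per set with the hypergeometric oracle", {
  universe <- paste0("g", 1:12)
  collection <- gene_set_collection(list(
    s1 = paste0("g", 1:4),
    s2 = paste0("g", 3:8),
    s3 = paste0("g", 9:12),
    tiny = "g1",
    outside = c("x1", "x2", "x3")), "toy")
  selected <- paste0("g", c(1:3, 9))
  sc <- enrichment_scan(selected, collection, universe,
                        min_size = 2, max_size = 10, alpha = 0.1)
  # sets outside the window or the universe are not tested
  expect_setequal(sc$set, c("s1", "s2", "s3"))
  for (i in seq_len(nrow(sc))) {
    expect_equal(sc$p[i],
                 hyper_oracle(sc$N[i], sc$K[i], sc$n[i], sc$x[i]),
                 tolerance = 1e-12)
  }
  expect_equal(sc$p_adj, bh_adjust(sc$p)[order(order(sc$p, sc$set))])
  expect_true(all(sc$x <= pmin(sc$K, sc$n)))
  expect_error(enrichment_scan(selected, collection, character()), "universe")
  expect_error(enrichment_scan("zz", collection, universe), "outside")
})
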