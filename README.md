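# minegs

Network-embedded gene selection for two-class expression studies,
integrating microRNA binding information and diffusion distances on the
gene interaction network.

## The problem

Picking marker genes from a genes-by-samples expression matrix by a
per-gene statistic ignores two biological facts: (1) transcript abundance
is not expression — microRNAs repress their targets post-transcriptionally,
so two genes facing similar microRNA regulation are more comparable than
their mRNA profiles alone suggest; and (2) genes act in pathways, often
through indirect, multi-path network connections, so a gene with a subtle
marginal signal can still matter if its functional partners are strongly
phenotype-associated.

`minegs` implements a gene-selection model (MiNeGS) that addresses both,
together with its ablation variants and the evaluation machinery to judge
them.

## The model

For genes *i, j* with expression profiles **x**<sub>i</sub>,
**x**<sub>j</sub> and binary microRNA-binding rows **z**<sub>i</sub>,
**z**<sub>j</sub>:

1. **Integrated correlation.** The binding rows are compared with the
   Jaccard coefficient *J* = M₁₁ / (M₁₁ + M₁₀ + M₀₁) (with *J* = 1 for two
   unbound genes and *J* = 0 for a bound/unbound pair), and the combined
   gene–gene correlation on each network edge is
   *C*<sub>ij</sub> = PCC<sub>ij</sub> · *J*<sub>ij</sub>.
2. **Diffusion distance.** The edge-filtered network, weighted by *C*,
   defines a random walk with transition operator obtained by degree
   normalisation (every column of *Q* = *W D*⁻¹ sums to 1). The t-step
   diffusion distance
   *D*<sub>t</sub>(i,j)² = Σ<sub>k</sub>
   (p<sub>t</sub>(i,k) − p<sub>t</sub>(j,k))² / φ(k)
   compares two genes' t-step transition distributions, aggregating **all**
   paths between them; it is computed exactly through a diffusion-map
   spectral embedding. Each gene's *k* = 3 nearest functional partners
   (NFPs) are the genes at smallest diffusion distance.
3. **Ranking.** Each gene's phenotype association is the plug-in mutual
   information of its (10-bin histogrammed) expression with the class
   label; the gene-phenotype association (GPA) averages the MI of a gene
   and its NFPs, and genes are ranked by GPA.

Variants: `classic` (MI only), `MiGS` (integrated correlation, first-order
neighbours only), `NeGS` (expression-only correlation, diffusion NFPs),
`MiNeGS` (both). Evaluation tools cover annotation-coordination rates with
uniform and network-topology nulls, hallmark-gene recovery, hypergeometric
gene-set enrichment with Benjamini–Hochberg correction, and a leakage-free
repeated stratified cross-validation AUC harness with pluggable RBF-SVM and
neural-network classifiers.

## Worked example

Everything is exercisable on synthetic data with planted truth — a
scale-free network with three 20-gene modules whose members are
coordinately shifted between classes and share microRNA regulators:

```r
library(minegs)
sim <- generate_synthetic(synthetic_config(seed = 1))   # 300 genes, 20+20 samples
pp  <- preprocess_pipeline(sim$expression, sim$binding, sim$network,
                           min_targets = 1)
fit <- run_model(pp$expression, pp$binding, pp$network, model = "MiNeGS")
fit
#> gene_ranking (MiNeGS): 268 genes; top: g0025, g0176, g0230, g0160, g0156

rec <- recovery_report(sim$truth, fit, attr(fit, "nfp_table"), top_n = 60)
rec$recovery               # fraction of the 60 planted genes in the top 60
#> [1] 0.9333333
rec$intra_module_fraction  # partner assignments staying inside the module
#> [1] 1

coord <- coordination_rate(attr(fit, "nfp_table"), sim$gene_sets)
coord
#> coordination: 61 / 61 evaluable genes (rate 1.000)
nulls <- null_coordination("uniform", pp$network$gene_ids, pp$network,
                           sim$gene_sets, reps = 100, seed = 1)
mean(nulls)                              # annotation-only baseline
#> [1] 0.0658
one_sample_ttest(nulls, coord$rate)      # observed rate vs the null
#> [1] 1.34e-113
```

So at these study conditions the full model places 56 of the 60 planted
module genes in its top 60, every partner assignment stays within the
gene's own module, and the coordination rate (1.0) is far beyond what the
annotation collection alone explains (~0.07).

A command-line front end wrapping the same functions ships at
`inst/cli/minegs.R` with subcommands `simulate`, `rank`, `nfp`,
`evaluate`, and `classify`.

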