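---
title: "Methods: microRNA-integrated, network-embedded gene selection"
author: "minegs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microRNA-integrated, network-embedded gene selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minegs)
```

## The model and its assumptions

`minegs` ranks genes of a two-class expression study by combining three
ingredients:

1. **Integrated gene–gene correlation.** Transcript abundance alone is an
   imperfect surrogate for a gene's ultimate expression because microRNAs
   repress their targets post-transcriptionally. On every edge of a prior
   interaction network the package therefore combines the Pearson
   correlation of the two expression profiles with the Jaccard similarity
   of the two genes' binary microRNA-binding rows,
   $C_{ij} = \mathrm{PCC}_{ij} \cdot J_{ij}$. Two genes are considered
   functionally correlated when their transcripts co-vary *and* they face a
   similar microRNA regime. The Jaccard conventions are deliberate: two
   genes bound by no microRNA at all are maximally similar ($J = 1$; both
   are free of this regulatory layer), while a bound and an unbound gene
   are maximally dissimilar ($J = 0$).

2. **Diffusion distance on the weighted network.** Genes collaborate
   through indirect connections and along multiple parallel paths, which
   shortest-path or first-neighbour criteria ignore. The correlation-
   weighted network defines a random walk: normalising the symmetric weight
   matrix $W$ by the diagonal degree matrix $D$ gives a Markov transition
   operator whose columns each sum to one. The $t$-step diffusion distance

   $$D_t(i,j)^2 = \sum_k \frac{\left(p_t(i,k) - p_t(j,k)\right)^2}{\phi(k)},
     \qquad \phi(k) = \frac{d_k}{\sum_l d_l},$$

   compares the $t$-step transition distributions of genes $i$ and $j$,
   down-weighting high-density destinations. Two genes connected by many
   (possibly long) paths are close. Each gene's $k$ nearest functional
   partners (NFPs) are the genes at smallest diffusion distance.

3. **Mutual-information ranking.** Each gene's marginal association with
   the phenotype is the plug-in mutual information between its histogrammed
   expression and the class label. The gene–phenotype association (GPA) is
   the average MI of the gene and its NFPs, and genes are ranked by GPA —
   a gene with a subtle marginal signal is promoted when its functional
   partners carry strong signals.

The ablation variants isolate each ingredient: `classic` ranks by MI
alone; `MiGS` keeps the integrated correlation but restricts partners to
first-order neighbours; `NeGS` uses diffusion partners but expression-only
correlations; `MiNeGS` uses both. The assumptions worth stating are:
relevant co-regulation manifests as *positive* expression correlation
(negative-correlation edges are filtered out, so the models cannot exploit
antagonistic relationships); the binding matrix is binary (no binding
strength); and partner relevance is symmetric and static across samples.

## The spectral computation and its numerical choices

Diffusion distances are computed through a diffusion-map embedding rather
than by matrix powering. For each connected component the symmetric
conjugate $S = D^{-1/2} W D^{-1/2}$ is eigendecomposed (a stable symmetric
problem); eigenvectors are mapped back to right eigenvectors $\psi_l$ of
the walk operator and scaled so that $\sum_k \phi(k)\,\psi_l(k)^2 = 1$,
which makes the Euclidean distance between coordinate rows
$\left(\lambda_2^t \psi_2(i), \dots\right)$ equal — at full rank — to the
diffusion distance. The package retains an explicit brute-force
implementation of the distance (`diffusion_distance_brute`) purely as a
test oracle; the suite asserts agreement below $10^{-8}$ on random
connected graphs up to 25 nodes for $t \in \{1,2,3\}$.

Numerical/degenerate-input decisions:

* **Transition-operator convention.** The column-stochastic operator
  $Q = W D^{-1}$ (column sums exactly 1) and the row-stochastic
  $P = D^{-1} W$ are transposes of each other for symmetric $W$ and induce
  identical distances; the implementation works with $P$ internally and
  asserts the column-sum property of $Q$ in tests.
* **Trivial eigenpair.** $\lambda_1 = 1$ has a constant $\psi_1$,
  contributes nothing to any pairwise distance, and is excluded from the
  coordinates. Negative eigenvalues are retained; $\lambda^t$ with integer
  $t$ is well-defined.
* **Truncation.** `L = "auto"` keeps every component with
  $|\lambda_l|^t \ge 10^{-6} |\lambda_2|^t$, making truncation error
  negligible; truncated distances are monotone non-decreasing in $L$ and
  bounded by the full-rank distance.
* **Sign convention.** Eigenvector sign is fixed (first non-zero entry
  positive) so serialized embeddings are reproducible; distances are
  sign-invariant anyway.
* **Disconnected graphs.** Components are embedded separately; the
  distance across components is `Inf`, and partner lists simply never
  cross components.
* **Zero-weight edges.** Under the integrated similarity an edge between
  a bound and an unbound gene has $C = 0$. Such edges would carry no
  diffusion mass, so `run_model` drops them before building the weighted
  graph. A gene isolated this way becomes a singleton component with an
  empty partner list and falls back to its own MI — the same behaviour as
  an empty-NFP gene anywhere else.
* **Ties.** Partner ordering treats distances equal to 10 significant
  digits as tied (absorbing eigen-solver noise between mathematically
  equal distances — on a path graph, for instance, both leaves reach the
  middle node with probability one, so the middle node is *exactly*
  equidistant from them) and resolves ties by lexicographic gene ID.

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `k` | 3 | partners per gene; small values keep partners within one pathway, large values leak across pathways. |
| `t` | 1 | diffusion time (walk steps, dimensionless). Already at $t=1$ the spectral distance aggregates all paths; behaviour at $t \in \{1,2,3\}$ is covered by tests, and the parameter is exposed end to end. |
| `bins` | 10 | equal-width histogram bins over each gene's observed range for the MI estimator (top bin right-closed). Per-gene ranges are the natural reading of binning "the space of" one gene's values. |
| MI base | 2 | scores in bits; the base rescales all scores monotonically and cannot change a ranking. |
| `floor` | 100 | raw-intensity expression floor: genes with mean < 100 are treated as unexpressed (strict inequality). |
| `min_sd` | 0.2 | sample-SD floor ($n-1$ denominator; the conventional sample SD). Whether this threshold should act on raw or log scale is data-dependent; the pipeline applies it to whatever scale it is given and a `--log2` switch is offered in the CLI. |
| `min_targets` | 100 | microRNAs with fewer targets are considered under-studied and dropped. |
| edge filter | PCC ≤ 0 | edges with non-positive (or undefined) expression correlation are removed; the boundary includes 0 because a zero-weight edge carries no diffusion mass. |

Filters run in the order: expression floor → variance → edge sign →
isolation → microRNA sparsity, each emitting a `filter_report`.

## Evaluation procedures

* **Coordination.** With $k = 3$, a gene and its partners form a 4-gene
  group; the gene is *coordinated* when ≥ 3 group members share one
  annotation set of ≤ 200 genes (very large categories would make
  coordination trivially easy and are discarded first). A gene is
  *evaluable* only if its list is full and all four genes are annotated in
  the size-filtered collection — the same collection is deliberately used
  for both the annotation check and the shared-set test, so that
  "annotated" means "annotated with a term that could count". Under-filled
  first-order lists are excluded here (but retained for ranking, where the
  GPA simply averages over the available members). Two randomization
  nulls — partners drawn uniformly from the universe, or from first-order
  neighbours — are each repeated (default 100×), and a two-sided one-sample
  t-test compares the null rates with the observed rate; at the extreme
  p-values of interest sidedness is immaterial.
* **Hallmark recovery.** The count of externally curated disease genes in
  the top-$n$ of a ranking.
* **Enrichment.** Upper-tail hypergeometric p-values per gene set with
  set sizes computed *within the analysis universe* (the hypergeometric
  population must equal the sampling frame), a 10–200 size window,
  Benjamini–Hochberg adjustment across tested sets, and significance at
  adjusted $p < 0.1$.
* **Classification.** Stratified 6-fold cross-validation repeated 20
  times: within each fold the *selector runs on the training samples
  only* — edge filtering and correlations are recomputed per fold — the
  top-$J$ genes feed the classifier, held-out scores are pooled across a
  repeat's folds before one AUC is computed (rank-based, ties one half),
  and repeats are averaged. The reference classifiers are an RBF-kernel
  SVM with library-default hyperparameters and a single-hidden-layer
  neural network with $\lfloor\sqrt{J}\rfloor$ hidden units; both sit
  behind a plain `fit`/`score` contract so any classifier can be plugged
  in, and the same contract lets tests audit that the selector never
  receives held-out samples.

## The synthetic-data generator

Real inputs of this kind (microarray cohorts, interaction databases,
binding predictions, annotation collections) cannot ship with the package,
so `generate_synthetic` produces the full input bundle with known truth.
It emulates exactly the structure the model assumes: a preferential-
attachment (scale-free) background network; planted modules whose genes
are additionally wired at density 0.3, shifted between classes by
$\delta\sigma$ (producing both differential expression and positive
within-module correlation through the shared shift), and bound by a
module-specific disjoint regulator set at probability 0.9 over a 2%
background binding rate; baselines uniform in 300–800 so the raw-intensity
filters pass by construction; gene sets = the true modules plus
size-matched random decoys; hallmarks = the planted differential genes.

The shipped study conditions are 300 genes, 20 samples per class, three
modules of 20 genes, $\delta = 1.5$, $\sigma = 1$ — a moderate effect at a
realistic cohort size, where the classic per-gene ranking is good but
imperfect and partner averaging has room to help. These sizes also keep
every test and the end-to-end acceptance checks comfortably within a few
minutes on a single CPU, with spectral problems of at most a few hundred
genes.

What the generator does **not** emulate: probe-level measurement artefacts
and heavy-tailed intensity noise, correlated background (housekeeping)
structure, annotation incompleteness and redundancy of real GO/pathway
collections, scale-free binding degree distributions of real microRNAs,
and any antagonistic (negatively correlated) regulation. Passing tests
therefore demonstrate that the machinery is correct and that the method
behaves as designed *when its assumptions hold* — not that it will show
the same margins on real cohorts.

## Design choices where the design was open

* **Gene universe.** The analysis universe is the genes present in the
  expression data that retain at least one network edge; microRNA binding
  is optional per gene (unbound genes keep all-zero rows). Gene IDs are
  opaque case-sensitive strings; no symbol mapping is attempted.
* **Correlations only on edges.** Combined correlations are consumed
  solely as edge weights, so they are computed per edge, $O(|E| n)$,
  rather than for all $m^2$ pairs.
* **Under-filled first-order lists** are returned with a flag rather than
  dropped, letting each consumer (ranking vs coordination) apply its own
  policy.
* **Determinism.** Every stochastic entry point (`make_folds`,
  `random_nfps`, `null_coordination`, `generate_synthetic`,
  `cross_validated_auc`) takes a seed and restores the caller's RNG
  state; repeated calls are bit-identical.

## Known limitations

* Diffusion structures are recomputed per CV fold, which is exact but
  quadratic-to-cubic in the component size; very large networks (tens of
  thousands of genes) would need sparse/iterative eigensolvers, which are
  out of scope.
* The MI estimator is the uncorrected plug-in; with 10 bins and small
  $n$ it is biased upward uniformly across genes, which leaves rankings
  intact but makes absolute MI values incomparable across sample sizes.
* With $k = 0$-like degenerate settings (empty partner lists) all model
  variants collapse to the classic ranking, which is the intended
  behaviour, not an error.
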