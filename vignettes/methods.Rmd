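---
title: "Methods: cross-species comparison of pitcher-plant feeding transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species comparison of pitcher-plant feeding transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`pitchercomp` compares feeding-induced and tissue-specific gene expression
between two independently evolved carnivorous pitcher plant lineages. This
vignette is the package's account of the statistical machinery: the models,
their assumptions, the tunable parameters, the synthetic data the pipeline is
validated on, and the numerical choices that make every run reproducible.

## The comparison problem

Each species contributes a tissue-specific RNA-seq experiment: six pitcher
tissues, each sampled under a control and a fed condition (prey-mimic
treatment), with 4 control and 8 fed biological replicates per tissue.
Because the two species diverged over 100 million years ago, genes are
compared not one-to-one but through *orthogroups* — sets of genes descended
from one ancestral gene. Two flavors are supported: hierarchical orthogroups
(resolved at a named species-tree node, the default being the most recent
common ancestor of the two focal species) for set comparisons, and the
coarser nonhierarchical orthogroups for convergence screening, where
splitting distantly related branch pairs into separate groups would discard
exactly the comparisons of interest. The hierarchical node is configuration
metadata, not parsed from a tree: tree inference is outside this package's
scope.

The pipeline asks two questions. Do functionally matched tissues (the
digestive zone of one species, the gland-bearing lower pitcher wall of the
other) respond to feeding with overlapping orthogroup sets? And do
tissue-specific expression programs, summarized as self-organizing-map (SOM)
clusters, correspond across species?

## Normalization and expression summaries

Between-sample scaling uses the weighted trimmed mean of M-values (TMM). For
sample *j* against a reference *r*, per-gene log ratios
`M = log2((y_gj/N_j)/(y_gr/N_r))` and average intensities `A` are computed
over genes expressed in both samples; the most extreme 30% of M and 5% of A
are trimmed on each side (rank-based, floor rule); surviving M-values are
averaged with inverse-asymptotic-variance weights
`1/v, v = (N_j−y)/(N_j y) + (N_r−y)/(N_r y)`; the factor is `2^(weighted
mean)`, and all factors are rescaled to geometric mean 1. The reference is
the sample whose library-size-scaled 75th-percentile count is closest to the
mean of those quantiles. Degenerate cases are defined, not special-cased
away: a sample identical to the reference up to depth has factor 1 (the
`max |M| < 1e-6` short-circuit), an all-zero sample is a typed error. Each
species is normalized independently: downstream cross-species comparisons
are set-based, never value-based, so factor coupling across species would
add an assumption without changing any comparison.

FPKM is `count / (effective library/1e6) / (length/1e3)` with effective
library = column sum × TMM factor. Replicates are averaged to
tissue-by-condition means before gene selection and clustering, because the
profiles being compared are per tissue and condition, not per replicate.

Genes for clustering are chosen by coefficient of variation: CV = sample
standard deviation (n−1) / mean across the twelve tissue-by-condition mean
columns, eligibility requiring a maximum above 1 FPKM ("expressed in at
least one condition", read literally as max over columns > 1). Exactly
`ceiling(0.10 × n_eligible)` genes are selected; ties at the cutoff break
lexicographically by gene id so selection is a pure function of the input.
Whether CV should be computed on replicate-level values instead is not
determinable from the published description; means are the default and the
function accepts any column layout.

## Differential expression

Counts are modeled as negative binomial. For one tissue, per-gene dispersion
is estimated by method of moments from within-condition residuals of
depth-normalized counts, pooled over conditions, then shrunk toward the
25%-trimmed mean of the per-gene estimates with weight `df/(df + prior_df)`
(residual df = 10 at the default 4+8 design; `prior_df = 20`), floored at
1e-4. The strong shrinkage reflects the design: with 10 residual degrees of
freedom a per-gene moment estimate is noisy, and the test's type-I behavior
depends mainly on the common dispersion being right.

The test is a likelihood-ratio test of equal NB means (fed vs control) with
dispersion held fixed and log effective library sizes as offsets, referred
to chi-squared with 1 df. The mean fits use vectorized Fisher scoring across
all genes simultaneously (step clamp ±5, convergence 1e-12, 50 iterations
max; all-zero genes take the defined limit likelihood 1). The reported fold
change is `log2((mean fed CPM + 0.5)/(mean control CPM + 0.5))` — CPM on the
effective-library scale, so the estimate is invariant to global depth
changes; the pseudo-count keeps it finite at zero counts. FDR is
Benjamini–Hochberg within each tissue (the analysis unit at which DEG counts
are reported), via `stats::p.adjust`. Calls: up if FDR < 0.05 and
log2FC ≥ +1, down if ≤ −1 — FDR strictly below, fold change inclusive.

This is deliberately a single-pass test, not a reimplementation of any
iterative DEG-elimination normalization loop; externally produced DEG tables
can be substituted anywhere downstream, since every later stage consumes
only the `gene_id`/`tissue`/`log2fc`/`fdr`/`status` schema.

## Orthogroup responses and set similarity

Within an orthogroup, member genes with status up or down vote; `ns` members
abstain. Strict majority gives the call; a non-empty tie is `conflict`
(a tie is not a majority); no voters is `none`. Conflict and none never
enter shared sets. The per-tissue universe for similarity testing is every
orthogroup with at least one tested gene in that tissue — the population a
permutation can reach must be the population the observed set was drawn
from.

The Jaccard coefficient of two orthogroup sets is tested against a
constrained permutation null: each draw applies an independent uniformly
random bijection of each species' universe to that species' observed sets.
A bijection preserves set sizes and co-membership and cannot assign one
orthogroup to two mutually exclusive categories, so the no-contradiction
constraint holds by construction. For a single pair this is equivalent to
drawing uniform same-size subsets, which is how it is implemented (the
companion sets of a joint bijection do not alter one pair's JC
distribution). `p = (#{JC_perm ≥ JC_obs} + 1)/(n + 1)`: "exceeds" is
implemented as ≥, and the +1 correction keeps Monte-Carlo p-values unbiased
upward and never zero; `p_literal = TRUE` gives the uncorrected `r/n`
variant. Whether both species' sets or only one should be permuted, and
whether "exceeded" is strict, cannot be pinned down from prose alone — both
are exposed as options and the defaults documented here. BH correction is
applied per matrix (up-matrix, down-matrix, cluster matrix), matching
per-panel FDR reporting. Each pair derives its own sub-seed from the master
seed (`derive_seed`, a 31-bit polynomial hash of stage tag and seed), so any
pair can be recomputed in isolation.

## SOM clustering

The SOM is a batch fit on a hexagonal grid (offset coordinates
`x = col + 0.5·(row mod 2)`, `y = row·√3/2`, unit spacing 1; default 3×4 =
12 units; orientation of the grid is cosmetic since cluster identity is
unordered). Per epoch every gene is assigned to its best-matching unit
(minimal Euclidean distance, ties to the lowest unit index), then each
codebook vector becomes the neighborhood-weighted mean of the data, with a
Gaussian neighborhood over grid distance truncated at the current radius.
The radius decays linearly from two-thirds of the grid diameter to 0.5; at
0.5 only the BMU itself is updated, so the final epochs are exactly k-means
steps and the quantization error is provably non-increasing once the radius
freezes.

Two numerical choices matter for reliability:

- **Initialization** is a seeded, distance-weighted (k-means++-style) sample
  of distinct data rows: the first codebook is a uniform draw, each further
  one is drawn with probability proportional to squared distance from the
  nearest chosen row. A uniform sample of 12 rows routinely misses
  well-separated structure and leaves the fit in merged-cluster optima.
- **Empty units** are re-seeded on the data row worst served by its current
  BMU (standard empty-cluster repair, logged). Retaining a stranded
  codebook instead leaves permanently empty units and merges distinct
  expression programs into one cluster; re-seeding at the worst-served row
  can only decrease the quantization error, so the monotonicity property is
  unaffected.

Rows are processed in canonical gene-id order, making the fit invariant to
input row order at a fixed seed. Training length (100 epochs) and the radius
schedule are package defaults, configuration-exposed, and not claimed to
match any external tool's defaults.

Cross-species cluster matching converts each cluster to its orthogroup set
(every hierarchical orthogroup with ≥ 1 member gene in the cluster; genes
without an orthogroup are excluded and logged), with the per-species
universe being all orthogroups touched by that species' clustered genes, and
tests all cluster pairs with the permutation machinery above.

## Convergence screening

A nonhierarchical orthogroup becomes a convergence candidate if it contains,
from each species, at least one gene upregulated in a configured
gland-bearing tissue (FDR < 0.05 and log2FC strictly > 1 — upregulation
only, and deliberately a different, strict cut from the DEG status rule,
whose |log2FC| ≥ 1 is inclusive and two-sided) or assigned to a configured
gland-specific SOM cluster. In the pipeline the gland-specific clusters are
detected as units whose mean z-profile peaks in the gland tissue (either
condition); explicit cluster ids can be supplied instead. Convergence
statistics themselves (the protein convergence rate ω_C and the count of
amino-acid-changing convergent substitutions O_C^N per branch pair) are
inputs from external phylogenetic software, filtered at strictly > 3.0 on
both; the package never computes them.

## The synthetic study and what it does (not) show

The generator emulates the study design so every stage can be validated
against a known truth: two species × six tissues × (4 control + 8 fed)
replicates; 5000 genes per species of which 60% sit in 1:1 orthogroups, 15%
in 2:2, the rest species-specific; log-normal baselines (meanlog log 50,
sdlog 1.2); log-uniform gene lengths 300–10,000 bp; log-uniform NB
dispersions 0.05–0.3 (conventional bulk RNA-seq values — the real data's
dispersions are unknown, so these are config-exposed, not claimed); relative
depth factors uniform 0.7–1.4. Twelve tissue-profile module classes (one- or
two-tissue peaks, amplitude 8×) are carried by 15% of genes; 1:1 ortholog
pairs share their module class with probability 0.8. The feeding response is
planted as 150 shared-up and 75 shared-down 1:1 orthogroups in the matched
gland tissues, 20 conflict orthogroups (opposite-sign effects in two
paralogs), and a 3% background DE fraction per tissue with random direction;
planted |log2 effects| are uniform on [1.5, 3] and planted genes have their
baseline floored at 25 (responders are expressed genes). Counts are drawn
NB with mean = baseline × tissue profile × mild per-tissue jitter
(sdlog 0.1) × condition effect × depth. A design stream (orthology, modules,
planted sets) and one stream per species, all derived from the master seed,
make regeneration bit-identical and keep one species' data unchanged when
the other is regenerated.

What the generator does **not** emulate: GC/length biases, batch effects,
outlier samples, correlated genes within pathways, unbalanced designs,
isoform-level ambiguity, or any sequence evolution. Passing the synthetic
recovery tests therefore demonstrates that the statistics recover the
signals they are designed for under their own model assumptions — not that
real pitcher-plant data satisfy those assumptions.

## Validation problem sizes

The test suite exercises: TMM against an independent implementation on 100
random small tables (1e-10 agreement); the permutation null against
exhaustive enumeration on all shared universes up to size 7 and a
chi-squared fit of the unconstrained intersection-size distribution to the
hypergeometric law; majority votes against enumeration of all status
multisets up to size 4; BH against a direct step-up transcription on 1000
random vectors; DEG type-I calibration on 20 null simulations of 5000 genes
(dispersion 0.1, mean 200, 4 vs 8 replicates) and power/FDP on planted
|log2FC| = 2 at dispersion 0.05; SOM recovery of 4 planted prototypes on
2000 genes at noise 0.3 (on a 2×2 grid, so the partition granularity matches
the truth being recovered); and one full end-to-end synthetic study at the
default conditions with 10,000 permutations per pair, plus 20
shuffled-orthology null replicates at 2000 permutations (p resolution 5e-4,
ample for an FDR < 0.05 call). These sizes are the package's validation
design; all are pure functions of fixed seeds.

## Known limitations

- The NB test treats the shrunken dispersion as known; with few replicates
  this is mildly liberal, which is why calibration is asserted on
  simulation rather than assumed.
- Independent per-species TMM ignores any cross-species normalization
  coupling an external joint tool might apply; only set-based comparisons
  are made across species, so scale is never compared.
- Jaccard similarity ignores orthogroup sizes; a huge and a tiny orthogroup
  count equally. The permutation null conditions on set sizes but not on
  any orthogroup-level covariates.
- SOM cluster identity is label-free: clusters are matched by orthogroup
  composition, never by grid position.
- Genes absent from any orthogroup are recorded as unmapped and excluded
  from set comparisons (logged); the alternative — treating each as its own
  singleton group — would change universe sizes and is not what set-based
  orthology comparison means.
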