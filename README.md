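# germdiv

Two-arm characterization of crop germplasm collections in R, built for
clonally propagated crops such as yam where variety identity is
uncertain and both morphology and molecular markers are needed to sort
it out.

**Who it is for.** Curators and breeders holding a panel of accessions
(the motivating design: 113 yam accessions, 50 graded DUS traits, 19
SSR loci) who need to (a) quantify morphological diversity and shrink a
long DUS trait list to a core evaluation set, and (b) use codominant
SSR genotypes to measure diversity, test Hardy–Weinberg equilibrium,
cluster accessions, detect duplicates (synonyms) and name conflicts
(homonyms), partition variance hierarchically, and infer admixed
genetic structure.

## What it computes

**Morphological arm**

* LSD-based grading of quantitative traits
  (`LSD = t · sqrt(2·MSE/r)`; class width > 2·LSD; grand mean at the
  central grade midpoint)
* descriptive statistics (population-SD convention) and
  Shannon–Weaver diversity `H' = −Σ Pᵢ ln Pᵢ` per trait
* PCA of the trait correlation matrix, composite score
  `F = Σ wᵢ Pᵢ` with `wᵢ = λᵢ / Σ λ` over components with `λ > 1`,
  trait–F correlation screening, and forward stepwise OLS selection of
  a core trait set

**Molecular arm**

* per-locus `Na`, `Ne = 1/Σp²`, `Ho`, Nei's `h = 1 − Σp²`, unbiased
  `He = 2N·h/(2N−1)`, Shannon's `I`, and
  `PIC = 1 − Σp² − Σ_{i<j} 2pᵢ²pⱼ²`
* chi-square Hardy–Weinberg tests (`df = a(a−1)/2`), optional
  Monte-Carlo p
* allele-sharing distances, UPGMA trees with Newick export, cluster
  cuts, PCoA, duplicate groups at distance 0, homonym flagging
* allele-level AMOVA (Φ_ST, variance percentages) and island-model
  gene flow `Nm = (1 − F_ST)/(4·F_ST)`
* a STRUCTURE-style Gibbs sampler (admixture and no-admixture models,
  C++ core, seeded and bit-reproducible), Evanno ΔK model choice, and
  CLUMPP-style run alignment

**Synthetic data** — Balding–Nichols genotype panels with planted
groups, clones and homonyms, and low-rank graded trait tables — back
every stage with planted-truth tests.

## Worked example

```r
library(germdiv)

# the study-shaped synthetic bundle: 113 accessions, 19 SSR loci,
# 5 groups (75/27/6/3/2), 9 clone groups, 3 homonym groups, 50 traits
fx <- paper_scale_fixture(seed = 1)

# SSR diversity
st <- summarize_loci(fx$gm)
locus_stats_summary(st)$mean[c("na", "ne", "ho", "pic")]
#>        na        ne        ho       pic
#> 6.8947368 3.4824280 0.5365626 0.6417569

# duplicates at genetic distance 0
d <- genetic_distance_matrix(fx$gm)
find_duplicates(d)
#> duplicate_report: 9 groups, 19 redundant, 94 distinct (threshold  0 )
#>   { ACC001, ACC002, ACC003, ACC004, ACC005, ACC006 }
#>   { ACC007, ACC008, ACC009 }
#>   ...

# AMOVA against the latent groups
am <- amova(fx$gm, fx$groups)
round(c(phi_st = am$phi_st, nm = am$nm), 4)
#> phi_st     nm
#> 0.3676 0.4300

# composite score and core-trait selection on the trait table
X   <- standardize_traits(fx$traits)   # drops the 10 invariant traits
cs  <- composite_score(trait_pca(X))
sel <- stepwise_select(X, cs)
sel
#> core_trait_set: 10 traits, R^2 = 0.9084
#>    T20, T33, T5, T16, T38, T19, T34, T22, T29, T28
```

The per-locus means are diversity statistics of the simulated panel;
`find_duplicates` recovers exactly the planted clone structure (19
redundant accessions, 94 distinct genotypes); Φ_ST (0.37, near the
generator's differentiation of 0.32) is the among-group share of
allele-level variance and `nm` its island-model migrant equivalent;
the selected trait set approximates the composite score `F` with the
printed R².

Admixture inference runs the same way:

```r
sw <- sweep_k(fx$gm, 1:6, replicates = 3, seed = 7,
              burn_in = 2000, iterations = 8000)
evanno_delta_k(sw)$best_k
```

`run_pipeline()` chains every stage and writes one file per output
(trait stats, eigenvalues, F scores, core set, locus stats, HWE table,
distance matrix, Newick tree, clusters, duplicates/homonyms JSON,
AMOVA table, ΔK sweep, Q matrices) plus a manifest with parameters,
seed and content hashes.

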