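---
title: "Methods: two-arm germplasm characterization with DUS traits and SSR markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-arm germplasm characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germdiv)
```

`germdiv` implements the two standard arms of a germplasm
characterization study of a clonally propagated crop collection (the
motivating system is a 113-accession yam panel): a morphological arm
built on graded DUS (distinctness, uniformity, stability) traits, and a
molecular arm built on codominant SSR genotypes.  This vignette is the
package's account of the models, the tunable parameters, the numerical
choices, and what the synthetic-data experiments do and do not
demonstrate.

## The morphological arm

### Grading and univariate diversity

Quantitative traits are measured on replicate plants and binned into an
odd number of grades.  `build_lsd_grading()` fits a one-way ANOVA of
the replicate values on accession and sets

\[ \mathrm{LSD}_{\alpha} = t_{1-\alpha/2,\,df_e}\sqrt{2\,\mathrm{MSE}/r}, \]

with \(r\) the harmonic-mean replicate count.  The class width is the
smallest value above \(2\,\mathrm{LSD}\) that still spans the observed
range of accession means within the requested number of grades, and the
grand mean sits at the midpoint of the central grade.  Grades are
half-open intervals \([b_i, b_{i+1})\) with unbounded extreme classes;
a value exactly on a boundary takes the upper grade.  Degenerate input
(all values equal) yields a single-class scheme with zero LSD.

Per-trait summaries (`descriptive_stats()`) use the population
(divide-by-\(n\)) standard deviation.  That convention is deliberate:
for a binary trait with class counts \(a, b\) it gives
\(\mathrm{SD}^2 = ab/(a+b)^2\), which reproduces published DUS summary
rows exactly, whereas the \(n-1\) convention does not.  The coefficient
of variation of a zero-mean trait is reported as missing rather than
infinite.  Diversity per trait is the Shannon–Weaver index
\(H' = -\sum_i P_i \ln P_i\) over grade-class frequencies; it is zero
for monomorphic traits, at most \(\ln k\) for \(k\) observed classes,
and invariant under relabeling of codes.

Trait correlations are Pearson correlations on the graded codes, with
two-sided \(t\)-test p-values, pairwise deletion of missing codes, and
explicit exclusion of invariant traits.  Pearson (not Spearman) is used
because graded DUS codes are ordered scores analyzed as interval scales
throughout this field's software.

### Composite score and core-trait selection

`standardize_traits()` removes invariant traits and scales the rest to
zero mean and unit variance; `trait_pca()` eigen-decomposes the trait
correlation matrix.  Components with eigenvalue above 1 (Kaiser rule)
are retained.  Scores are standardized to unit variance, and each
loading vector's largest-magnitude entry is made positive so that
results do not depend on the eigensolver's sign conventions.  The
composite score of an accession is

\[ F = \sum_{i \le k} w_i P_i, \qquad w_i = \lambda_i \Big/ \sum_{j \le k} \lambda_j, \]

i.e. each retained component weighted by its share of the retained
variance.  Standardized scores make \(F\) scale-free: rescaling any
input trait leaves it unchanged.

`stepwise_select()` regresses \(F\) on the candidate traits — those
significantly correlated with \(F\) at the entry level — by forward
stepwise OLS with entry/removal p-value thresholds (defaults 0.05/0.10,
the common SPSS-style convention; equal thresholds are rejected to
prevent cycling).  Entry ties are broken by larger \(|r|\) with \(F\),
then trait id order.  The forward path's \(R^2\) is non-decreasing by
construction.

### Why full core-trait recovery needs a decaying spectrum

A point that shaped the synthetic design: \(F\) is a weighted sum of
*estimated* principal components.  When several factor components of
the trait correlation matrix have nearly equal eigenvalues, the sample
eigenvectors are arbitrary rotations within that eigenspace, so the
coefficient of any single latent factor inside \(F\) is effectively a
zero-mean random variable — and a trait whose factor happens to cancel
out of \(F\) fails the marginal-correlation screen no matter how
informative it is conditionally.  No sample size rescues this: the
cancellation probability is scale-free under eigen-degeneracy.  The
practical consequences are (i) the trait simulator plants an explicitly
*decaying* target spectrum (default 4.30 down to 1.35 over 14 factors),
the spiked shape real morphological panels show, and (ii) the recovery
experiment is run at a sample size (3000 accessions) where those
separated components are estimable, and its result is summarized as the
mean recovered-core count over 10 seeds.  At the 113-accession study
scale, recovery of a 14-trait core is necessarily partial — a
limitation of eigenvalue-weighted composites, not of the
implementation.

## The molecular arm

### Per-locus diversity

For allele frequencies \(p_i\) over \(N\) typed diploids:
\(N_a\) = allele count, \(N_e = 1/\sum p_i^2\),
\(H_o\) = observed heterozygote fraction, Nei's gene diversity
\(h = 1-\sum p_i^2\), unbiased \(H_e = 2Nh/(2N-1)\),
Shannon's \(I = -\sum p_i \ln p_i\), and
\(\mathrm{PIC} = 1-\sum p_i^2-\sum_{i<j} 2p_i^2p_j^2\).  The unbiased
\(H_e\) estimator was pinned down by checking that it maps published
Nei values to published \(H_e\) values exactly at \(N = 113\).  The
implementation uses the closed forms; the test suite checks them to
\(10^{-12}\) against an independent brute-force enumeration.  Allele
sizes are taken as already-binned integers — no fragment-size
clustering is attempted — and a single detected peak is recorded as a
homozygote.  Ploidy is fixed at two: even where the crop may be
polyploid, genotypes in this workflow are scored as at most two peaks.

Hardy–Weinberg equilibrium is tested by a chi-square goodness of fit of
genotype counts against \(Np_i^2\) and \(2Np_ip_j\), with
\(df = a(a-1)/2\), no rare-genotype pooling (no published procedure to
mirror), and an optional seeded Monte-Carlo p-value that re-pairs
allele copies for sparse tables.

### Distances, trees, duplicates

The default individual-level distance is allele-sharing:
\(d = 1 - \tfrac{1}{L}\sum_l s_l/2\), where \(s_l\) is the multiset
intersection of the two allele pairs.  It is zero exactly for identical
multilocus genotypes, which makes the duplicate criterion "distance 0"
coincide with genotype identity; missing loci are handled by pairwise
deletion.  Nei's (1972) standard distance is offered as an alternative
but is degenerate for single individuals (it can be zero for
non-identical heterozygotes), so it is not the default.

`upgma()` implements average-linkage agglomeration with node height
equal to half the between-cluster average distance, so the tree is
ultrametric.  Ties are broken by the lexicographically smallest pair of
minimum member labels, making output independent of input order.
`cut_clusters()` cuts by merge order (via `stats::cutree`), so every
\(k\) is attainable even under tied heights; clusters are renumbered by
decreasing size.  Newick export quotes labels containing
metacharacters; round-trips are checked against an independent parser.

Duplicate (synonym) groups are connected components of the
distance-at-most-threshold graph; homonym flagging takes an explicit
accession-to-name mapping (optionally case/whitespace-folded; no fuzzy
matching) and flags name groups whose members are not all identical.
Principal coordinates of the distance matrix come from classical
metric MDS with negative eigenvalues clipped (with a warning) when the
distance is non-Euclidean.

### AMOVA

`amova()` partitions allele-level variance into among-group,
among-individual and within-individual strata (df \(g-1\), \(N-g\),
\(N\)).  Sums of squares use the pairwise-difference identity
\(SS = (n/2)(1-\sum p^2)\) per allele-copy set and locus.  Negative
variance components are truncated at zero before percentages, the
convention of the field's standard spreadsheet tool.  \(\Phi_{ST}\) is
the among-group share of total variance; `gene_flow()` applies
\(N_m = (1-F_{ST})/(4F_{ST})\).  Published tables occasionally print a
multilocus \(F_{ST}\) inconsistent with their own variance-component
percentages; this package reports the variance-component statistic and
leaves the identity \(N_m(F_{ST})\) available for any printed value.

### Admixture inference

`run_structure()` is a Gibbs sampler for the classical Bayesian
clustering model with uncorrelated allele frequencies
(\(P_{kl} \sim \mathrm{Dirichlet}(\lambda=1)\)).  Each sweep updates
frequencies from their Dirichlet full conditional, then the origin of
every allele copy given frequencies and memberships, then memberships:
under the admixture model \(q_i \sim \mathrm{Dirichlet}(\alpha + m_i)\)
with a reflecting random-walk Metropolis step (SD 0.025) on a single
\(\alpha\) shared across individuals, uniform prior on \((0, 10)\);
under the no-admixture model each individual draws one cluster from its
likelihood.  Missing genotypes are skipped as uninformative.  The
marginal data probability is estimated by the harmonic-style
\(\widehat{\ln P} = \overline{\ln L} - \mathrm{var}(\ln L)/2\) over
post-burn-in sweeps.  Traces are thinned (every 10th sweep); posterior
mean \(Q\) uses all post-burn-in sweeps.  The sampler is written in
C++ for throughput and consumes R's RNG stream, so a seed makes runs
bit-identical.

Defaults are test-scale (burn-in 5,000 / 20,000 sweeps); production
settings of 100,000 / 200,000 are a parameter away.  `sweep_k()` runs a
contiguous K range with replicate seeds derived as
`seed + 1000*K + replicate`; `evanno_delta_k()` computes
\(\Delta K = |L(K{+}1) - 2L(K) + L(K{-}1)|/\mathrm{sd}(L(K))\) at
interior K and errors on zero replicate spread.  `align_runs()` undoes
label switching by maximizing summed column-wise dot products against
the first run — exhaustively over permutations for \(K \le 8\),
greedily beyond.

## The synthetic-data generator

`simulate_populations()` draws ancestral allele frequencies from a
symmetric Dirichlet and group frequencies from the Balding–Nichols
measure \(\mathrm{Dirichlet}(p(1-F)/F)\); individuals are two
independent copies, so Hardy–Weinberg holds within groups by
construction.  Defaults mirror the study panel: 113 accessions in five
groups (75/27/6/3/2), 19 loci with 4–15 alleles, and differentiation
\(F = 0.32\), the panel's own overall fixation level.  Clone groups are
bit-identical copies under new accession ids; homonym groups share one
variety name across distinct genotypes; missing data are masked
uniformly at a configurable rate (default 0).  `paper_scale_fixture()`
adds nine clone groups totalling 19 redundant accessions (so 94
distinct genotypes) and three homonym groups.

`simulate_traits()` is described above; its replicate design (30 plants
per accession) and 50-trait/10-invariant shape mirror the study.  Core
traits carry unique variance 0.025, satellites 0.25, so each factor's
best single marker is always its core trait.

What these simulations *show*: the estimators, the clustering, the
variance partition and the model-choice statistic recover planted truth
under the generative assumptions they were designed for.  What they do
*not* show: robustness to null alleles, stutter, scoring error,
polyploid dosage ambiguity, linkage, non-normal trait distributions, or
genotype-by-environment effects — none of which the generator emulates.

## Problem sizes and determinism

Test-suite experiment scales were chosen as the smallest that make the
statistical assertions sharp: 1,000 frequency vectors for the
diversity-statistic oracle; 100 random matrices for ultrametricity;
1,000 replicates for HWE type-I calibration; 20 seeds at \(n=200\), 19
loci for AMOVA recovery; 10 sweeps of K ∈ 1–5 at \(n=90\), 10 loci,
burn-in 2,000 / 8,000 sweeps for ΔK recovery; 10 seeds at \(n=3000\)
for core-trait recovery.  Every stochastic entry point takes a single
seed and sets R's RNG once (`set.seed`); derived per-run seeds are
simple deterministic offsets.  A counter-based stream split was
considered and rejected: R has no native counter-based generator, and
the reproducibility contract (same inputs + seed, same bytes out) is
met by the simpler idiom.

## Known limitations

* Individual-level "Nei" distances are a population-statistic applied
  to two-copy samples; interpret with care.
* The HWE chi-square is asymptotic; with many rare alleles use the
  Monte-Carlo option.
* The admixture sampler implements the uncorrelated-frequencies model
  only — no linkage model, no location priors, no correlated
  frequencies.
* Composite-score-based core selection is intrinsically unstable when
  the trait spectrum is near-degenerate (see above); published core
  sets selected this way should be read as one draw from a set of
  near-equivalent solutions.
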