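---
title: "Modelling two-locus allorecognition and the detection of reproductively isolated groups"
author: "hetrv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling two-locus allorecognition and the detection of reproductively isolated groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetrv)
```

## The biological system

Filamentous fungi discriminate self from non-self during somatic fusion
through *het* (heterokaryon incompatibility) genes: when two mycelia with
mismatched *het* alleles fuse, regulated cell death produces a visible
"barrage". In *Podospora anserina* two unlinked loci interact: *het-r*
(alleles `R`/`r`; `R` is defined by 11 WD40 repeats in a specific order)
and *het-v* (alleles `V`/`V1`). Two incompatibility systems act:

* an **allelic** system — individuals carrying different *het-v* alleles
  (`V` vs `V1`) are incompatible;
* a **non-allelic** system — `R` in one individual reacts with `V` in the
  other.

Both interactions are pleiotropic: they also impair sexual crosses, and the
combination `R`+`V` inside a single haploid individual is lethal upon
germination. Only three genotypes — `rV`, `RV1` and the recombinant `rV1` —
can therefore exist in a population, and the lethal `RV` class is produced
(and eliminated) whenever `rV` and `RV1` outcross. The package asks, and
provides the tools to answer, two questions:

1. Under what combinations of balancing selection, selfing and prezygotic
   isolation can a second incompatible genotype invade, leaving the
   population split into two reproductively isolated (RI) groups?
2. How are such groups detected from data: pairwise mating outcomes,
   whole-genome SNPs, windowed differentiation scans and linkage
   disequilibrium?

## The invasion simulator

### Life cycle and offspring law

Each generation, `N` offspring are produced. Per offspring slot:

1. a mother is drawn with probability proportional to `count * w` (fitness
   below);
2. with probability `sigma` (the selfing rate) the offspring is a selfing
   product and inherits the maternal genotype unchanged
   (pseudohomothallic selfing of a haploid parent);
3. otherwise a father is drawn the same way, independently, from the whole
   population. The cross fails before zygote formation with probability
   `iota_sys` per triggered incompatibility system; given fertilisation the
   two unlinked loci segregate independently (each inherited from either
   parent with probability 1/2), and an `RV` product dies at germination;
4. a failed attempt — prezygotic failure or `RV` germination death — is
   redrawn, keeping `N` constant (soft selection).

Step 4 is the point of the model: the redraw makes a failed attempt free
for the *population* but costly for the *pair*, because an `rV` x `RV1`
cross only delivers an offspring 3/4 of the time and, when it does, only
1/3 of the survivors carry the invader's genotype. This is what makes a
rare incompatible genotype unable to establish without selfing: the cost
acts immediately on every outcross with the resident, while the
compensating rare-genotype advantage (below) is bounded by the balancing
intensity.

Because individuals are exchangeable within genotype and only three viable
genotypes exist, the per-offspring law collapses to a closed-form
distribution `q` over genotypes, and a generation is an exact
`Multinomial(N, q)` draw. This is identical in distribution to simulating
individuals one by one (the tests verify it against brute-force enumeration
over ordered parent pairs and by chi-square on empirical draws) and makes
500 generations x 100 replicates at `N = 1000` a matter of seconds.
Monomorphic populations are absorbing — selfing and same-genotype crosses
reproduce the parental genotype exactly — so replicates stop early once
fixed.

### Fitness: rare-genotype advantage from vegetative interactions

Allorecognition genes gain from negative frequency dependence: a rare
allele meets mostly incompatible partners and profits from refusing fusion
with them. The functional form of that advantage is not uniquely
determined by the biology; the package uses the simplest linear form,

```
w(g) = 1 + b_nonallelic * x_RV(g) + b_allelic * x_VV1(g)
```

where `x_sys(g)` is the current frequency of individuals incompatible with
`g` under system `sys` and the `b` parameters are the balancing-selection
intensities (default `b_nonallelic = 0.5`, the reference intensity of the
study design this emulates). All fitnesses are >= 1; a monomorphic
population is neutral.

### Parameters and defaults

| parameter | meaning | default |
|---|---|---|
| `pop_size` | constant population size N | 1000 |
| `generations` | generations per replicate | 500 |
| `selfing` | probability an offspring is a selfing product | 0 |
| `b_nonallelic`, `b_allelic` | balancing intensities of the R/V and V/V1 systems | 0.5, 0 |
| `iota_nonallelic`, `iota_allelic` | prezygotic failure probability per triggered system | 0, 0 |
| `f0` | initial invader fraction | 0.05 |
| `replicates` | replicate simulations | 100 |

`N`, `G`, `f0` and the replicate count are study-scale conventions, not
estimates; they are all exposed. Mating types are omitted (every individual
can act as mother or father): with random mating they only halve the pool
of potential partners and do not change the two-locus genotype dynamics.
Prezygotic isolation is applied symmetrically per triggered system; the
asymmetric damage reported for the R/V interaction (the `R`-carrying
maternal structure is the damaged one) can be emulated by scaling
`iota_nonallelic`, since the simulator tracks genotypes, not cross
directions.

### The neutral limit

With `b = 0` and `iota = 0` the model is *not* neutral for the pair
`rV`/`RV1`: the `RV` lethality is itself selection (each mixed cross loses
1/4 of its products, and the surviving mass leaks into the recombinant
`rV1`). The clean neutral limit uses a genotype pair that cannot form `RV`
— resident `rV`, invader `rV1` — for which the offspring law reduces
exactly to Wright-Fisher sampling, frequencies are a martingale and the
fixation probability equals the initial frequency `f0`. The test suite and
the acceptance script use that pair for the drift calibration.

## Windowed population genomics

### Callability masking and effective window length

A VCF lists variable sites only; sites that are actually *missing* (bad
coverage, repeats) would silently deflate per-bp statistics. The masking
rule: per sample, depth quantiles of the genome-wide coverage distribution
are computed (empirical type-7), and a site is "bad" for that sample when
its depth is strictly below the 25% quantile or strictly above the 98.5%
quantile. The mask is the set of sites bad in **every** sample intersected
with the repeat annotation. Strict inequalities mean constant coverage
masks nothing. Masked sites are excluded both from the statistics and from
the window length: every per-bp statistic divides by the effective length
`L_eff` (window bp minus masked bp), and windows with `L_eff` below 5 kb
are reported as missing (`NA`, never 0).

### Estimators

Windows are 10 kb sliding by 1 kb by default, tiling from position 1 with
the final partial window kept (and subject to the `L_eff` filter).
Positions are 1-based inclusive; BED input is converted at the boundary.
Per window, over usable sites:

* `pi` — sum of per-site unbiased heterozygosity `2 j (n - j) / (n (n-1))`
  (with `j` alternate calls among `n` non-missing calls), divided by
  `L_eff`;
* `theta_w` — sum over segregating sites of `1 / a_n` at the per-site
  sample size, divided by `L_eff`;
* Tajima's `D` — computed from complete-call sites only, so the mean
  pairwise difference, the segregating-site count and the variance
  constants all refer to one sample size; undefined (NA) when `S = 0` or
  `n < 4` (at `n = 3` the variance constants vanish identically);
* `Fst` — Hudson's `1 - Hw/Hb` as a window-level ratio of averages, robust
  to low-frequency sites (a site-averaged variant would weight windows by
  their site counts). The study's tooling did not print its exact
  fixation-index formula; ratio-of-averages Hudson is the standard choice
  for windowed scans and is what the package commits to;
* `Dxy` — sum of `p1 (1 - p2) + p2 (1 - p1)`, divided by `L_eff`;
* the permutation null rearranges all samples into two groups of the
  observed sizes (without replacement), shares the permutations across
  windows within an iteration, and reports
  `p = (1 + #{perm Fst >= observed}) / (n_perm + 1)`. No multiplicity
  correction is applied (none was in the original analysis design).

### PCA and RI assignment

SNP PCA uses complete-call biallelic sites at minor allele frequency >= 1%,
centred but (by default) not scaled to unit variance; standardising is
available behind a flag since common SNP-PCA tools differ. Group
assignment thresholds PC1 at zero after orienting the axis with a labelled
anchor subset; a sample exactly at zero stays unassigned rather than being
forced to a side.

## Linkage disequilibrium

`r2` is the squared allele-frequency correlation computed on
pairwise-complete haploid calls (equal to the squared Pearson correlation
of the 0/1 site vectors — phase is known for haploid data). The decay of
`E[r2]` with distance follows the recombination-drift equilibrium
expectation with a single parameter `rho = 4 Ne c` per bp:

```
E[r2](C) = (10 + C) / ((2 + C)(11 + C)) *
           [1 + (3 + C)(12 + 12C + C^2) / (n (2 + C)(11 + C))],  C = rho * d
```

which tends to 10/22 as `C -> 0` (large `n`) and to `1/n` as `C -> oo`.
The least-squares fit profiles the sum of squares on a 121-point log-spaced
grid over `rho` (multi-start in effect) and refines the best bracket by
golden-section search; a fit whose optimum sits on the search boundary is
flagged unconverged rather than raising. The distance at which the fitted
curve crosses `r2 = 0.2` is found by root-finding. Decay pairs are sampled
as 30 random 50-kb windows per chromosome with singleton sites removed;
overlapping windows are allowed and duplicate pairs de-duplicated, the
simplest faithful reading of a "randomly sampled windows" design. Thinned
LD matrices keep sites with MAF >= 0.02 and greedily enforce >= 1 kb
spacing (keep the first site, drop anything closer than the spacing to the
last kept site).

## Mating-compatibility clustering

Cross outcomes are coded 1-6 from the per-partner observations (mature
fruiting bodies / perithecial abortion / no perithecia); the code depends
only on the unordered pair of categories, but the strain-by-strain matrix
is still non-symmetric because the two directions of a cross are scored
separately. Gower dissimilarity treats each strain (row) as an observation
whose variables are its codes against every partner, handled as
interval-scaled (range-normalised absolute difference) — mirroring the
default numeric behaviour of the classical implementation — with an
ordinal (rank-transform) option; missing cells are deleted pairwise and
strains missing more than half their cells are dropped with a warning.

PAM is the classical BUILD + SWAP algorithm with deterministic
lowest-index tie-breaking; the SWAP phase never increases the cost. The
cluster count is chosen by maximum average silhouette width (authoritative
for the pipeline) and, as a second diagnostic, by the gap statistic on the
coded observation matrix with uniform reference sets over each variable's
observed range (`B_ref = 100`) and the one-standard-error rule. The
reference construction follows the simplest published variant; the
original tooling's exact reference is not documented, which is why the
silhouette rule is the authoritative one. PCoA is classical scaling
(double-centred squared dissimilarities, eigendecomposition, axes scaled
by the square root of positive eigenvalues); negative eigenvalues are
dropped and counted. Concordance between labelings reports the
diagonal-maximised confusion matrix and the adjusted Rand index.

## Genotype utilities

WD40 repeat counts divide the amplicon size by 126 bp and round to the
nearest integer (exact half-units round down with a warning). `R` requires
exactly 11 repeats *and* the reference arrangement; with the order unknown
an 11-repeat call is a provisional `R` flagged for sequencing — and a
count other than 11 is never `R`. The substrate contingency test is a
Pearson chi-squared on the 2x2 group-by-substrate table with the Yates
correction off by default (the published statistic's provenance is
ambiguous on this point; both variants are available). Allele trajectories
suppress years with fewer than six genotyped strains. The recombination
report keeps full precision internally and rounds to one decimal only at
the reporting layer.

## The synthetic-data generators

The generators produce every input the pipeline consumes, with known
expectations, so all stages are testable end to end without sequencing
data:

* **Neutral alignments** come from the standard n-sample Kingman
  coalescent with Poisson (infinite-sites) mutations on branches, so
  `E[pi] = theta` per site and `E[S] = theta L a_n` exactly — which is what
  makes them usable as estimator calibration material. Default
  `theta = 5e-4` per site, matching the order of diversity of a dense
  local collection of a highly selfing fungus.
* **Two-group SNP matrices** plant background sites from the neutral
  frequency spectrum independent of group labels, one island of fixed
  differences (relative differentiation exactly 1) and optionally a second
  island differentiated to a target Fst via the Balding-Nichols
  allele-frequency model.
* **Coverage tracks** are negative-binomial per site (variance
  `mu + dispersion * mu^2`; `dispersion = 0` gives deterministic depth)
  with interval artifacts that scale the local mean, which is exactly the
  signal the quantile masking rule is designed to flag.
* **Mating matrices** code within-group crosses 1 and between-group
  crosses 4-6, with an optional fraction of cells re-drawn uniformly from
  1-6 as scoring noise.

What the generators do **not** emulate: recombination maps and linkage
within chromosomes for the background SNPs (background sites are drawn
independently, so the background r2 scale is the sampling floor of ~1/n,
not a decay curve), demographic history, sequencing error, or continuous
degrees of cross fertility underneath the 1-6 codes. Passing tests
therefore demonstrate estimator correctness and planted-structure
recovery, not robustness to every artefact of real short-read data.

## Problem sizes used by the tests and the acceptance script

Chosen as the package's own trade-off between statistical resolution and a
comfortable desk run: drift calibration at `N = 100` with 1000 replicates;
invasion scenarios at `N = 1000`, 500 generations, 100 replicates; neutral
calibration at `theta = 5e-4`, `n = 10`, `L = 1 Mb`, 200 replicates;
planted-partition recovery with two groups of 20 on two 300-kb
chromosomes with a 150-site island and 1000 Fst permutations; LD recovery
from 500 distance-r2 pairs. The estimator oracle checks run on 100 random
matrices of up to 6 samples and 200 sites.

## Known limitations

* The fitness form is the simplest linear frequency dependence; any
  saturating or threshold form would change the invasion boundary
  quantitatively (not the qualitative selfing requirement). It is isolated
  in `nfds_fitness` for replacement.
* The simulator tracks genotype counts, not individuals, so
  individual-level bookkeeping (e.g. per-individual mating histories,
  spatial structure) is out of reach by design.
* Hudson's Fst is reported unclipped; slightly negative window values can
  occur when within-group diversity exceeds between-group diversity and
  are meaningful as "no differentiation".
* The gap statistic depends on its reference construction; on small noisy
  matrices it can overshoot the cluster count, which is why the silhouette
  rule is authoritative.
* `two_locus_r2` reproduces published strain-table associations only when
  given such a table; the package ships none (natural-collection genotype
  tables are not redistributable here) and its synthetic stand-in is
  clearly labelled synthetic.
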