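---
title: "Genealogy-based sweep scans: models, statistics and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genealogy-based sweep scans: models, statistics and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(argscan)
```

## The problem

Convergent melanism on small satellite islands is a classic setting for
detecting recent positive selection: a large source population and one or
more small satellite populations exchange migrants, and a beneficial
variant (new or standing) sweeps through a satellite population. The
footprint of such a sweep in the *ancestral recombination graph* (ARG) is
a local genealogy in which the satellite sample coalesces unusually
recently and forms population-exclusive clades. `argscan` implements the
statistics that read this footprint off a series of local trees, the
classic site-frequency and haplotype statistics that corroborate it in
genotype data, the empirical-outlier machinery that turns both into
significance calls, and a coalescent simulator that generates matched
synthetic data so every stage can be tested without any external dataset.

## Tree statistics

A *local tree* is a rooted, binary, ultrametric genealogy of all sampled
haploid sequences at one genomic position, node ages in generations. Two
statistics are computed per tree and population:

**Species enrichment.** For a subtree with $n$ leaves of which $k$ belong
to a population sampled $K$ times out of $N$ total leaves, the probability
of a composition at least that extreme under exchangeable sampling is the
hypergeometric upper tail $P(X \ge k)$, $X \sim \mathrm{Hyp}(N, K, n)$.
The tree's score for the population is

$$\max_{\text{subtrees } v} \; -\log_{10} P\!\left(X \ge k_v\right),$$

maximized over *all* subtrees, single leaves included (a leaf contributes
the harmless floor $-\log_{10} K/N$). The upper tail rather than the point
probability makes the score monotone in $k$, so population-*exclusive*
clades score high while depleted clades do not; this choice is isolated in
one function (`hypergeometric_tail`) so the alternative reading is a
one-line swap. The statistic depends on topology only.

**RTH′.** The TMRCA-half of a leaf set is the age of the youngest node
whose subtree contains at least half (ceiling) of that set. RTH′ divides
the population's TMRCA-half by the TMRCA-half of the whole sample:

$$\mathrm{RTH}' = \frac{\mathrm{TMRCAH}(\text{population})}
{\mathrm{TMRCAH}(\text{all leaves})}.$$

The normalization cancels genome-wide variation in coalescent depth, so
low values specifically flag recent population-private common ancestry.
Ties in the youngest-subtree search are broken by smallest age, then
smallest subtree; "half" is the ceiling for both numerator and
denominator, and the root always qualifies for the denominator. Note that
RTH′ only has discriminatory power when the focal population is less than
half of the total sample (otherwise its own swept clade can satisfy the
global half); the study design this package mirrors (each satellite
population a minority of a three-island sample) guarantees that, and the
simulator's default sample sizes preserve it.

Per-tree values are averaged in non-overlapping 20-kb windows tiled from
coordinate 1 (40 trees per full window at the default 500-bp tree
spacing); partial windows keep their true tree count, and windows with no
trees are omitted. Trees within 50 kb of an ARG block boundary are
discarded first, because topologies near block edges are unreliable.

## Significance

Thresholds are empirical: for each population and statistic, the control
distribution (windows from contigs without association signals) is sorted
and the cutoff at level $q$ is the value at ascending rank
$\lceil (1-q) M \rceil$ (upper tail for enrichment, mirrored for RTH′).
Windows are flagged only when *strictly* beyond a cutoff, which bounds the
flagged fraction of the control set itself by $q$, with equality when
$(1-q)M$ is an integer (rank discreteness). Thresholds are population- and
statistic-specific and are never pooled. The only non-empirical correction
provided is the Bonferroni quotient `alpha / n_tests` used for GWAS-style
genome-wide scans.

## The simulator

The synthetic-data generator is a backward-time structured coalescent for
two populations under isolation with migration:

* **Demography.** Diploid sizes $N_{\mathrm{source}}$ and
  $N_{\mathrm{satellite}}$, split $T_{\mathrm{split}}$ generations ago,
  and unidirectional migration from source into satellite (backward in
  time, satellite lineages jump into the source at rate $m$ per lineage
  per generation). The default presets encode the study system's ratios:
  a source of 500,000; a satellite of 93,750 splitting 68,000 generations
  ago (`"sasc"`), or of 62,500 splitting six times earlier (`"ugi"`,
  about two thirds of the other satellite's size and an eighth of the
  source's). The absolute migration rate is not printed in the source
  material, so the default is chosen to give about 0.5 migrants per
  generation into the satellite — a realistic "significant but not
  swamping" level for these islands — and is a preset, not an estimate.
  Mutation and recombination rates default to $10^{-9}$/bp/generation.
* **Scaling.** Like the forward-simulation design it mirrors, the model
  is scaled 10-fold by default: sizes and times divided by 10, selection
  and migration coefficients (and the per-generation mutation and
  recombination rates) multiplied by 10. This preserves $\theta = 4N\mu$,
  $\rho$, migrants per generation and the shape of the sweep while
  cutting simulation depth; set `scale = 1` to disable.
* **Sweeps.** Selection coefficients are drawn from an equal mixture of a
  uniform and a log-uniform distribution on $[0.001, 0.025]$ (pre-scaling,
  so $[0.01, 0.25]$ as simulated), hard and soft modes with equal
  probability, and soft sweeps start from standing variation at
  $f_{\mathrm{init}} \sim U(0.01, 0.1)$; hard sweeps start from a single
  copy, $f_{\mathrm{init}} = 1/(2N_{\mathrm{satellite}})$. The allele
  frequency path is the deterministic genic-selection recursion
  $p' = p(1+s)/(1+sp)$ run to effective fixation $1 - 1/(4N)$; the onset
  is implied by the fixation time and clamped to $[250, 20000]$
  generations, the regime the downstream classifier is trained on.
  Replicates whose sampled present-day derived allele frequency falls
  below 0.2 are redrawn, and recently fixed alleles are allowed.
* **The sweep-site genealogy.** Backward from the present to the onset,
  satellite lineages are partitioned into derived and ancestral classes
  with within-class pair-coalescence rates $1/(2N x(t))$ and
  $1/(2N(1-x(t)))$ and no cross-class coalescence; the number of sampled
  derived leaves is binomial in the present-day frequency. Beyond the
  onset, any remaining derived lineages continue to coalesce within a
  background of constant size $N_{\mathrm{satellite}} f_{\mathrm{init}}$
  until their single mutational origin is reached — the backward-time
  equivalent of seeding a forward simulation by placing the mutation on
  the branch above a clade of relative size $f_{\mathrm{init}}$. This
  construction guarantees the derived leaves form a clade (single
  origin), which the feature encoder requires. Migration is active only
  in the neutral phase; suppressing it during the sweep phase is a
  desk-scale approximation (sweeps here last hundreds to a few thousand
  scaled generations, over which the expected number of migrating
  ancestral-class lineages is small).
* **Along the region.** Exact ancestral-recombination simulation is out
  of scope. Adjacent trees (every 500 bp; the sweep site at the region
  center) are produced by SMC-style updates: a Poisson
  ($r \times \text{interval} \times \text{total branch length}$) number
  of single-recombination events, each detaching a uniformly chosen point
  of the tree and re-coalescing the dangling lineage against the
  remaining tree with effective size $N_{\mathrm{satellite}}$ below
  $T_{\mathrm{split}}$ and $N_{\mathrm{source}}$ above, ignoring
  population labels. This preserves the spatial decay of genealogical
  correlation that the windowing machinery needs, at the cost of eroding
  population structure (and the sweep's footprint) with distance from the
  conditioned site — adequate for testing windowed scan statistics, not
  for studying linked-selection patterns per se.
* **Mutations.** Infinite sites: each tree carries a Poisson
  ($\mu \times \text{interval} \times \text{total branch length}$) number
  of mutations placed on branches proportionally to length; carriers are
  the leaves below. Haplotypes are emitted as a phased VCF with a constant
  depth field so the depth-based site filter is well defined on simulated
  data.

What the generator does *not* emulate: stochastic allele-frequency
trajectories (the deterministic path understates trajectory variance and
soft-shoulder effects), genotyping error and missingness, variable
mutation/recombination rates, more than two populations, and selection
outside the conditioned site. Passing tests on simulated data therefore
demonstrate the correctness and calibration of the statistics under the
stated model, not robustness to those real-data complications.

## Classic summary statistics

Sites are filtered as resequencing panels are: called in at least 80% of
individuals, mean depth within $[2, 50]$, minor allele count at least 8
(with the smallest sampled population, that MAC equals four homozygous
carriers). Nucleotide diversity uses the per-site unbiased estimator
$2\hat p\hat q\, n_c/(n_c-1)$ with per-site called-allele counts $n_c$,
summed per 5-kb window and divided by window length. Tajima's D follows
the 1989 constants with $n$ set to the window-median called haplotype
count (the 80%-presence filter bounds the distortion from missingness);
windows with no segregating sites return `NA`, never 0. Windowed
$F_{ST}$ is the Weir–Cockerham (1984) ratio of summed variance
components ("weighted" convention, matching the tools that report single
window values). Garud's H statistics use non-overlapping 100-SNP windows
and merge haplotype classes within Hamming distance 1 by absorbing, in
descending frequency order (ties by first occurrence), into the most
frequent retained class — absorb-into-largest rather than single-linkage
chaining, which would let distance-1 chains merge arbitrarily distant
haplotypes; the merge step is exposed (`hap_class_freqs`) and the
threshold configurable.

## Feature encoding

For selection-inference models that consume genealogies, the encoder
reports, on an approximately log-uniform age grid (defaults: 1 generation
to $4N_{\mathrm{source}}$ scaled, 100 points, age 0 prepended; the grid is
serialized with the features), the number of lineages crossing each age,
split into derived (lineages ancestral only to carrier leaves, the
mutation branch counting as derived up to its parent node, since the
mutation's exact age on the branch is unknown) and ancestral lineages.
Mutation ages are separately estimated as the midpoint of the carrier
clade's subtending branch; carriers that are not a clade raise an error
with an explicit opt-in fallback to the smallest containing clade.

## Numerical and design choices

* Positions are 1-based bp (VCF convention); BED inputs are 0-based
  half-open and converted on read. Windows are written 0-based half-open.
* Ultrametricity is enforced within a relative tolerance of $10^{-6}$ of
  tree height (inferred ARGs discretize time); trees with polytomies are
  rejected rather than silently resolved, because subtree enumeration
  must be unambiguous.
* Edge discarding keeps trees at positions within
  $[\text{start} + d + 1,\; \text{end} - d]$ of each block (0-based
  half-open blocks, trim $d$); the rule depends only on block bounds, so
  it is idempotent.
* The hypergeometric tail is evaluated in log space (`phyper(log.p =
  TRUE)`), exact well beyond the sample sizes used here.
* A single MCMC sample of the ARG is assumed per contig (tree series are
  taken as given); averaging statistics over posterior samples is left to
  the caller by running the scan per sample.
* Problem sizes in the tests and the analysis scripts are desk-scale
  choices: 12 + 10 haploid samples, 200–1000 replicates per property,
  4,000 simulated control windows for the calibration check, and contigs
  of 0.3–0.84 Mb in the fixture bundle. These sizes keep every suite
  reproducible in minutes while leaving all acceptance properties
  well-powered.

## Known limitations

The scan consumes inferred local trees as if they were observed;
uncertainty in ARG inference enters only through the edge-discard rule
and the empirical null, not through per-tree error models. The
empirical-threshold machinery assumes control windows are exchangeable
with focal windows under neutrality — demographic misspecification shifts
both, which is the design's strength, but linked selection on control
contigs would deflate significance. The simulator's approximations are
listed above; in particular, power estimates from SMC-extended regions
should be read as properties of the conditioned sweep-site neighborhood,
and the neutral-phase-only migration slightly understates haplotype
mixture in very long sweeps.
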