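---
title: "Simulating SNP-array design and its ascertainment bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating SNP-array design and its ascertainment bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arraybias)
library(dplyr)
```

## The problem

Genotyping arrays carry SNPs that were *chosen*: discovered in a limited set
of populations, filtered for minor allele frequency and assay quality,
thinned toward equidistant genomic spacing, and validated on a broader but
still finite population sample. Each choice preferentially retains common
variants, and variants common *in the populations that took part in the
design*. Population-genetic statistics computed from array genotypes are
therefore biased relative to whole-genome sequencing — rare alleles are
under-represented and expected heterozygosity is overestimated, more so for
populations close to the discovery panel and in the opposite direction for
a diverged outgroup species. `arraybias` packages the whole experiment:
a synthetic truth panel with controlled population structure, the five-step
array design, and the statistics that expose the bias.

## The generative model

### Site frequencies

The ancestral derived-allele frequency $x$ of each locus is drawn from a
density proportional to $1/x$ truncated to
$[t, 1-t]$ (default $t = 0.001$), the neutral-equilibrium spectrum shape.
Sampling uses the closed-form inverse CDF $x = t\,((1-t)/t)^u$ with
$u \sim U(0,1)$. This makes the truth panel rich in rare alleles — about 62%
of loci have a panel-mean derived frequency below 0.05 under the defaults —
which is the raw material the ascertainment steps then deplete.

### Population structure

Drift is modelled with the Balding–Nichols Beta distribution: given a parent
frequency $p$ and drift $F$, the child frequency is
$\mathrm{Beta}\!\left(p\frac{1-F}{F},\,(1-p)\frac{1-F}{F}\right)$, which has
mean $p$ and variance $F\,p(1-p)$. Structure has two levels — cluster around
the ancestral frequency, population around its cluster — so populations in
the same cluster are correlated beyond what they share through $x$.

The default panel emulates a diverse livestock diversity collection of 46
populations: two individually genotyped commercial layer lines and two
commercial broiler lines, four pooled near relatives, two pooled wild
populations close to the ancestral source, 35 pooled local breeds in four
clusters, and one strongly diverged pooled outgroup. Within-cluster drift is
calibrated so that simulated pairwise differentiation reproduces the anchors
reported for such panels — pairwise $F_{ST}$ of roughly 0.1 within the tight
broiler group and above 0.3 within the looser layer group — giving a
discovery-versus-application overestimation gap of about 0.15 after the
discovery step, in line with the reference analysis. The cluster-level drift
values are free parameters of the model (real relatedness structure is only
known through pairwise distances); they are set once in
`sim_populations()` / `sim_config()` and all package results use them.

The outgroup drifts around $x$ with $F = 0.85$, pushing most loci that
segregate in the ingroup near fixation, and additionally owns a 10% fraction
of *private* loci at which all ingroup populations are fixed. Both features
are needed to reproduce the characteristic outgroup behaviour: arrays
designed in the ingroup find almost no polymorphism in the outgroup, so its
heterozygosity is *under*estimated (negative OHE) at every design step.

### Observation layer

Individually sequenced populations report the genotype-based frequency
$\hat p = \mathrm{Bin}(2n, p)/2n$; pooled populations report the
allelic-depth ratio $\hat p = \mathrm{Bin}(d, p)/d$ with per-locus depth
$d \sim \max(1, \mathrm{Pois}(\bar d))$. Both are unbiased; the pool
estimator ignores the two-stage structure of pool composition (animals, then
reads), which mainly widens the variance slightly and does not affect the
relative comparisons the package makes. Per-locus quality
($\mathcal N(80, 15^2)$ truncated at 0) and total depth (Poisson at the
summed population depths) are simulated independently of frequency — no
joint model is assumed — and exonic flags come from random 2-kb intervals
covering ~5% of each chromosome.

### Genome scale

The default genome is three 0.6-Mb chromosomes at 3 cM/Mb (about 5.4 cM)
carrying 50,000 loci. This is a deliberately miniaturised genome that
*preserves the marker densities* of a whole-genome panel: roughly one SNP
per 35 bp of sequence and ~9,000 SNPs/cM of map. Preserving densities keeps
every threshold of the design meaningful at reduced size — the 2-kb backbone
spacing, the 4/10-bp cluster-removal flanks, and above all the selectivity
of the 667 SNPs/cM equal-spacing target relative to the candidate supply
(about 4:1 candidates to target, as in a real whole-genome panel). Scaling
the locus count down without scaling the genome would silently make equal
spacing non-selective. The genetic map is piecewise linear with anchors
every 50 kb and per-segment rate multipliers $\max(0, \mathcal N(1, 0.3))$,
so cM is non-decreasing with occasional flat (recombination-cold) segments.

## The design pipeline

`design_array()` chains five deterministic steps, each returning a
`snp_set` that is a subset of its predecessor:

1. **Discovery filter** — quality ≥ 60, total depth ≤ mean + 3 SD, and
   discovery-panel MAF ≥ 0.05, where the panel frequency is the *unweighted
   mean* over discovery populations (population-size agnostic, as in pooled
   discovery practice).
2. **Cluster removal** — a locus is dropped when its invariant flanks (bp
   distance to the nearest discovery-variable SNP minus one, chromosome ends
   counting as infinite) are below 4 bp on one side and below 10 bp on the
   other. Flanks are computed among the discovery-step SNPs themselves: the
   truth panel carries no per-base sequence, so neighbouring candidate SNPs
   are the only non-invariant sites.
3. **Equal spacing** — part one builds a backbone of SNPs segregating in
   *all* discovery populations at ≥ 2 kb spacing (greedy left-to-right
   scan), complemented by one *unspaced* backbone per discovery sub-cluster
   (all candidate SNPs segregating in every population of the sub-cluster).
   The sub-cluster backbones deliberately carry no distance constraint —
   their reported contributions in array remodelling are far larger than
   any 2-kb-spaced set could be. Part two iterates over discovery
   populations in a fixed order (alphabetical sub-cluster label, then panel
   order) and fills the gaps between consecutive part-one SNPs: the target
   for a gap is $\mathrm{round}(\text{density} \times \text{multiplier}
   \times \text{gap-cM})$ minus the gap-fill SNPs already selected inside
   it that segregate in the current population; ideal points are placed
   equidistantly in cM and each takes the nearest (by |cM|, ties to smaller
   bp) unselected candidate segregating in that population. Gaps are frozen
   at the part-one selection — recomputing them dynamically would make the
   already-selected subtraction vacuous and would re-fill every interval
   once per population.
4. **Validation** — keep SNPs segregating in at least 8 of 19 validation
   populations; for other validation-group sizes the threshold scales
   proportionally (`ceiling(8/19 × size)`, minimum 1), a documented
   extension since only the 8-of-19 rule is defined.
5. **Downsampling** — the part-one seed is all exonic candidates plus the
   all-population backbone (no sub-cluster backbones); gap filling then uses
   per-sub-cluster density multipliers, by default 3× for the broiler-like
   sub-cluster to compensate its lower linkage disequilibrium.

"Segregating" always means an estimated frequency strictly inside
$(\texttt{seg\_tol}, 1-\texttt{seg\_tol})$ with `seg_tol = 0` by default;
the tolerance exists for noisy pool estimates. Target counts round half
*up* (`floor(x + 0.5)`) so that allocation is unbiased over many gaps;
banker's rounding would under-allocate. Population order matters in part
two (the first population fills most gaps), which is why the order is fixed
and documented rather than arbitrary. The exact tie-breaking of the original
spacing algorithm is unpublished; nearest-cM with ties toward smaller bp is
this package's documented stand-in, and an exhaustive brute-force oracle in
the test suite verifies the implementation on random small instances.

For *random* population groupings the discovery set has no natural
layer/broiler split, so `assign_groups()` forms two sub-clusters from
relatedness-sorted halves of the discovery set, mirroring the two sub-group
backbones of the original design. Without this, sub-clusters inherit panel
cluster labels and random draws produce singleton "backbones" — SNPs
segregating in a single population — which are nearly unfiltered sets and
distort the design.

## Statistics

Expected heterozygosity for a population over a SNP set is
$H_{exp} = \frac{1}{L}\sum_l 2 p_l (1-p_l)$ with $p_l$ the reference-allele
frequency. Its overestimation is
$\mathrm{OHE} = (H_{set} - H_{ref})/H_{ref}$: zero means unbiased, one means
doubling. In synthetic mode the reference set is the full truth panel — the
whole-genome analogue; no separate "filtered" reference exists because
variant-calling and recalibration are outside the model. Loci with a missing
frequency in any population are dropped panel-wide before design, so every
statistic uses one common locus set.

The ancestral allele is inferred per locus as the weighted major allele of
three populations close to the species origin (the two wild populations and
the outgroup, the outgroup weighted twice); ties go to the reference allele.
Derived allele-frequency spectra are plain histograms (50 equal bins on
$[0,1]$, terminal bins absorbing fixed loci) of the polarized mean frequency
over a chosen population set — histograms rather than kernel densities so
every number is exactly testable; group-level spectra use the unweighted
mean frequency across the group's populations, with per-population spectra
available through the same function.

Nei's standard genetic distance is
$D = -\ln\!\left(J_{xy}/\sqrt{J_x J_y}\right)$ from the usual biallelic
homozygosity/identity means, with $+\infty$ returned when the populations
share no alleles.

Group contrasts of OHE across repeated random groupings use the mixed model
$\mathrm{OHE}_{ijk} = \mu + \mathrm{popG}_i + \mathrm{rep}_j + e_{ijk}$
fitted by REML (`lme4`), with estimated marginal means and Tukey-adjusted
pairwise contrasts (`emmeans`). When the replicate variance is estimated as
zero (singular fit) the model falls back to the fixed-effects
`OHE ~ group`, flagged in the result; with balanced data the LSMEANS then
equal raw group means. Replicate seeds are derived from the master seed plus
the replicate index, so sweeps are reproducible and independent of
execution order.

## Problem sizes used by the tests and the acceptance script

The shipped analyses run at reduced but density-preserving scale, chosen as
the package's reference conditions: the main study uses the full default
(50,000 loci, 46 or 24 populations); grouping and density sweeps use 10,000
loci on a proportionally shrunk genome (so per-bp and per-cM densities, and
hence each step's selectivity, match the full-size conditions); random
groupings are repeated 50 times in the acceptance script and 20 times per
axis point in sweeps.

## What the synthetic panel does and does not show

The generator reproduces the features the analysis depends on: a rare-rich
unfolded spectrum, hierarchical relatedness with printed-anchor
differentiation, pooled and individual observation noise, a diverged
outgroup with private variation, exonic structure and a monotone genetic
map. It deliberately omits linkage disequilibrium between loci (loci are
exchangeable given the map), coalescent-exact genealogies, sequencing error,
and admixture or hybridization between clusters. Consequences worth knowing:

* Results about *which* steps deplete rare alleles and *which* populations
  are favoured transfer qualitatively; absolute OHE magnitudes do not — they
  depend on the real panel's spectrum and depth profile.
* One reference finding is **not** reproduced by this model and its
  acceptance check is expected to fail under the package's conditions:
  in real data, running equal spacing *without* the common-SNP backbone
  left no OHE difference between discovery and non-discovery populations at
  any target density. Here the discovery filter's ~0.15 OHE gap survives
  the no-backbone gap filling at every density, because per-population
  gap filling is frequency-neutral beyond segregation and the candidate set
  carries the step-1 bias uniformly. In the real panel the gap dissolved,
  plausibly through the rich admixture history and strongly unequal
  population contributions that this exchangeable-locus model excludes by
  design. The backbone-driven sub-checks (a near-0.5 spectrum at minimal
  density; the gap shrinking as density rises) do emerge as described.

## Numerical conventions

Positions are 1-based (VCF convention); BED intervals are 0-based half-open
and converted exactly once at the BED boundary. Map interpolation is
piecewise linear, exact at anchors, clamped (with a warning) outside the
anchor range, and returns the left anchor's cM inside flat segments.
Frequencies round-trip serialization at full double precision. All
stochastic functions take explicit seeds and restore the caller's RNG state
(`withr::with_seed`); design steps contain no randomness at all, so a whole
`ArrayDesign` is a pure function of its inputs.
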