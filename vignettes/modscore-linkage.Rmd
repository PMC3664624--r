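---
title: "MOD-score linkage analysis of multiplex disease pedigrees"
author: "modlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MOD-score linkage analysis of multiplex disease pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modlink)
```

## The problem

Congenital heart defects (CHD) and other rare, clinically heterogeneous
conditions are often studied through a handful of multiplex families:
pedigrees with several affected members carrying anatomically distinct
presentations of the same underlying predisposition.  Genome-wide SNP
genotypes on such families support parametric multipoint linkage analysis,
but the trait model — disease-allele frequency and penetrances — is
unknown.  The MOD score addresses this by maximizing the parametric LOD
over the trait-model parameters separately at every genetic position.
Because that maximization inflates the type-I error relative to a fixed
model, significance is assessed empirically, by gene-dropping marker data
under the null hypothesis of no linkage and re-analyzing each replicate
exactly like the real data.

`modlink` implements this pipeline end to end: data model and PED/MAP I/O,
quality control, LD pruning, the multipoint linkage engine, the MOD scan
with optional parent-of-origin (imprinting) penetrances, gene-dropping
empirical P values, a transmission disequilibrium test for the association
follow-up in linked regions, monotone genetic-map interpolation, and a
synthetic study generator that emulates the target design (six multiplex
pedigrees of 4–13 members, 48 individuals, plus seven affected-child
trios).

## The likelihood engine

### Model

Each family's likelihood is computed with a Lander–Green inheritance-vector
hidden Markov model.  The hidden state at a locus is the inheritance
vector: one bit per non-founder meiosis recording whether the
grand-paternal or grand-maternal allele was transmitted.  Between adjacent
loci the bits flip independently with probability $\theta(d)$, by default
the Haldane map function $\theta(d) = (1 - e^{-2d/100})/2$ for $d$ in cM
(Kosambi is available; the choice is a configuration, not an inference).
Marker emissions sum founder-allele assignments under Hardy–Weinberg
equilibrium at the estimated allele frequencies, via the founder-allele
graph: homozygous genotypes force slot values, heterozygous genotypes link
two slots by an inequality constraint, and each connected component
contributes the sum over its two admissible colourings.

The parametric LOD at a position $x$ under a trait model
$(q, f_0, f_1, f_2)$ is

$$\mathrm{LOD}(x) \;=\; \log_{10}
\frac{E_{v \sim P(\cdot \mid \text{markers}, x)}\, P(\text{aff} \mid v)}
     {E_{v \sim \text{uniform}}\, P(\text{aff} \mid v)},$$

summed over families; $P(\text{aff} \mid v)$ integrates founder
disease-allele indicators (frequency $q$) against the penetrances.  Under
genomic imprinting the heterozygote penetrance is split by transmitting
parent, $f_{1,\mathrm{pat}} \ne f_{1,\mathrm{mat}}$, which the engine reads
off the parental-origin bits of the inheritance vector.

### Founder symmetry and founder heterozygotes

Swapping a founder's two (unordered) alleles leaves the likelihood
invariant, so one meiosis per founder is pinned and the state space shrinks
from $2^{2n}$ to $2^{2n-f}$ ($n$ non-founders, $f$ founders).  One subtlety
is worth recording: the reduction is exact for marker data and for
non-founders' trait classes, but a founder's *own* heterozygote class under
imprinting is not orbit-invariant — the orbit sum pairs "disease allele on
the paternal slot" with "on the maternal slot".  The exact marginalization
gives founder heterozygotes the average penetrance
$(f_{1,\mathrm{pat}} + f_{1,\mathrm{mat}})/2$, which is also the right
scientific statement: the parental origin of a founder's allele is
unknowable from pedigree data.  The engine therefore carries founder
heterozygotes as their own class.  The test suite cross-checks the full
engine (standard and imprinting) against an exhaustive enumeration oracle
to ~1e-15 relative error.

### Trait-model tables

For MOD scans the trait emission is tabulated once per family and
affection vector as sparse counts over "keys" (total founder
disease-alleles plus per-class affected/unaffected counts), after which
the LOD for *any* trait model is a dot product.  Grid scans and gene-drop
replicates reuse these tables, which is what makes 40 000 replicate scans
tractable on one CPU.

## The MOD scan

At each position the LOD is maximized over a model grid
(`modGrid()`: disease-allele frequencies
$\{10^{-4}, \dots, 0.5\}$, penetrance step 0.05 under the order constraint
$f_0 \le f_1 \le f_2$; an unordered search is a flag), optionally followed
by a box-constrained Nelder–Mead refinement from the best grid point,
parameterized through nested logistic transforms so the order constraint
holds by construction.  The refinement never returns less than the grid
maximum.  Ties across models are broken toward smaller $q$, then smaller
$f_2$, so reports are deterministic.  A degenerate equal-penetrance model
is always in the grid and scores exactly zero, which bounds the MOD below
by 0.  The imprinting search space nests the standard one, and the
imprinting refinement additionally replays the standard refinement path,
so for equal grid settings the imprinting MOD dominates the standard MOD
pointwise — an invariant the tests assert exactly.

The estimated disease-allele frequency is the least stable of the
maximized parameters (misspecification at other parameters can be
compensated by inflating it), so scan outputs should be read as evidence
for linkage and the *shape* of the model (dominant vs recessive-like), not
as a frequency estimate.

## Empirical significance

`replicateScan()` regenerates marker data under no linkage: founder
haplotypes drawn under HWE and linkage equilibrium at the estimated
frequencies, transmissions with recombination per the map, affection
status copied unchanged, and the observed missingness mask re-applied.
Each replicate is analyzed with the same positions and grid as the real
data and contributes its maximum MOD over the scanned region; the
empirical P is the tie-inclusive proportion of replicate maxima at or
above the observed maximum ($r/R$; the $(r+1)/(R+1)$ variant is a flag).
The per-replicate statistic is the scan maximum rather than a
per-position score because the maximum is what is reported from a scan,
and using it controls the multiplicity of the scanned region.  One master
seed derives all replicate streams, so reruns are bit-identical.

## Quality control

The QC stage mirrors standard pedigree-genotype practice, in order:

* **Relationship check** (`ibsRelationshipCheck`): per within-family pair,
  mean and SD of identity-by-state sharing across markers, classified by a
  Gaussian discriminant calibrated from internal gene-drop simulations of
  parent-offspring, full-sib and unrelated pairs at the study's allele
  frequencies; parent-offspring pairs must additionally show essentially
  no IBS-0 markers.  Report-only.
* **Sex consistency** (`sexConsistencyCheck`): X-marker heterozygosity
  thresholds (males flagged above 0.05, females below 0.20).
* **Mendelian screen** (`mendelCheck`): Lange–Goradia genotype-set
  elimination per family and marker.  The set recoding is exact on
  loop-free pedigrees (the package's domain; consanguineous loops are out
  of scope).  On incompatibility the whole family's genotypes at that
  marker are cleared: attributing the error to one genotype is not
  identifiable in general, so family-wise clearing is the conservative
  resolution.
* **Unlikely genotypes** (`detectUnlikelyGenotypes`): for each typed
  genotype $g$, $\Lambda(g) = \log_{10} [P(\text{data} \setminus g)\,
  P_{\mathrm{single}}(g) / P(\text{data})]$ with the multipoint engine,
  where $P_{\mathrm{single}}$ is the HWE genotype probability.  Genotypes
  implying tight double recombinants score high; the default threshold 4
  corresponds to odds of $10^4$ against the observed call.  Flagged
  genotypes can be wiped (`wipeGenotypes`), after which re-detection is
  clean.
* **Marker filters** (`filterMarkers`): missing genetic position, call
  rate below 95%, monomorphism — one primary reason per marker, assigned
  in that order; idempotent.
* **Allele frequencies** (`estimateAlleleFreqs`): allele counting over
  typed founders, which is the maximum-likelihood estimate under HWE and
  random missingness; non-founders are excluded so observations stay
  independent, with an all-individuals fallback (and warning) when no
  founder is typed.  Full-pedigree ML would couple frequency estimation to
  the linkage engine itself; the founder estimate is unbiased under random
  mating and keeps the stages independent.

## LD pruning

With missing parental genotypes, marker-marker LD biases multipoint
linkage, so the pipeline prunes rather than models it: pairwise $r^2$ from
two-locus haplotype frequencies estimated by the Excoffier–Slatkin EM on
founder genotypes (founders only, to keep observations independent), and a
greedy map-ordered scan that removes the later marker of any within-window
pair with $r^2 > 0.20$ (window 50 markers by default; LD is local and
all-pairs scanning is quadratic).  The survivors are re-verified: the
post-pruning check finds no violating pair, exactly.  The EM likelihood is
non-decreasing by construction and is cross-checked against a $10^{-3}$
grid search over the cis-haplotype frequency.

## Genetic-map interpolation

Sex-specific maps (for example in pseudoautosomal regions, where male and
female recombination rates differ sharply) are interpolated from anchor
(bp, cM) pairs by local quadratic regression (tricube weights, bandwidth a
fraction of the anchors, default 0.3) and then projected onto the nearest
non-decreasing sequence by isotonic regression — the projection is the
package's monotonization operator, chosen for its hard guarantee and
closed form.  No extrapolation is allowed beyond the anchor span; with
fewer than five anchors a single polynomial replaces the windowed fit.

## Family-based association

The association stage in linked regions is a transmission disequilibrium
test: transmissions of each allele from heterozygous parents to affected
offspring across families and trios, McNemar $\chi^2 = (b-c)^2/(b+c)$ with
1 df, Bonferroni-adjusted by the number of markers tested in the region
(markers with MOD above 2.5 by default).  The TDT is the canonical
family-based test that remains valid in the presence of linkage, which is
exactly the situation in a region selected by a linkage scan.  A joint
linkage-association likelihood model is deliberately out of scope; the
substitution is an explicit design decision of this package.

## The synthetic study generator

`simulateStudy()` emulates the study design so every stage is testable
without external data: six hand-built pedigree templates spanning 4–13
members (48 individuals; nuclear sibships and three-generation structures
with married-in founders — approximations of typical multiplex clinical
pedigrees, not copies of any real family), plus affected-child trios.
Affection is generated by dropping a diallelic trait locus through the
structures and applying the penetrances (parent-of-origin aware); families
are rejection-sampled until they are multiplex (at least two affected by
default), mirroring how such studies recruit, and trios until the child is
affected.  Markers are then dropped jointly with the trait locus, with
recombination per the map, so linked scenarios carry genuine
co-segregation signal; founder marker alleles are in linkage equilibrium
(the pipeline assumes pruned markers, so population LD is deliberately not
simulated).  Missingness and injected errors come last and are recorded
cell-by-cell in a truth registry.

Defaults are the study conditions: recessive trait with $q = 0.1$ and
penetrances $(0, 0, 0.98)$ — the strong-penetrance benchmark; the
weak-penetrance $f_2 = 0.27$ variant is available as a stress scenario —
50 markers at 2 cM on one chromosome, founder MAF uniform on
$[0.05, 0.5]$, 2% missingness.

Error injection is constructive, not random: Mendelian errors resample a
child genotype outside the offspring set of its (typed, not
double-heterozygous) parents; double-recombinant flips are placed only
where the same parent is heterozygous at three consecutive markers, the
other parent homozygous, the transmitted allele is determinable and
agrees on both flanks, and at least one sibling pins the parental phase
across the same span — so each flip demonstrably forces a tight double
recombination and cannot be absorbed by re-phasing.  Flips are kept well
separated so their likelihood signals do not overlap.

What passing tests on these data do *not* show: robustness to population
LD between markers, to genotyping-error models beyond the two injected
kinds, to pedigree loops/consanguinity, or to X-linked inheritance (the
engine is autosomal; X-specific likelihoods are out of scope).

## Validation studies and the scales used

Two seeded experiments ship with the package:

* `nullCalibration()` — 200 independent null studies (trait unlinked), 200
  gene-drop replicates each, scan over every sixth marker position with a
  compact grid (penetrance step 1/3, $q \in \{0.01, 0.1, 0.3\}$, no
  refinement).  The empirical-P rejection rate at nominal 0.05 must fall in
  the exact binomial 95% acceptance interval.  The scan configuration is
  deliberately compact: the empirical-P construction is valid for *any*
  fixed configuration applied identically to observed data and replicates,
  and these sizes keep the full calibration to a few minutes.
* `recoveryExperiment()` — 100 linked studies under the recessive
  benchmark; the grid (penetrance step 0.25, five frequencies, plus the
  generating model itself) must place the peak within 10 cM of the true
  locus in at least 80% of replicates and return a recessive-like argmax
  ($\hat f_1 - \hat f_0 < 0.2$) in at least 70%.

Both are re-run by `scripts/acceptance.R` together with the engine-vs-
oracle comparison, the LD, TDT, QC and map checks.

## Numerical choices and edge cases

* Likelihoods are computed with per-marker rescaling; transitions use the
  Walsh–Hadamard diagonalization of the bit-flip kernel (with a parity
  correction per founder group on the reduced space).
* Families whose reduced bit count $2n - f$ exceeds `bitLimit` (default
  20) are rejected, not split; the largest template (13 members) uses 11
  bits.
* Zero-probability marker data (un-removed Mendelian errors) are a hard
  error naming the marker, not a silent zero.
* Degenerate trait models return a LOD of exactly 0 by construction;
  models whose null trait probability vanishes are scored $-\infty$ and
  can never be an argmax.
* Allele frequencies must lie strictly inside (0, 1) when entering the
  engine; monomorphic markers are expected to be filtered first.
* Missing affection contributes a factor of 1 (the phenotype is
  integrated out); missing genotypes likewise.
* Scan positions default to the marker grid plus interval midpoints;
  off-grid positions interpolate linearly in cM.

## Known limitations

Autosomal, biallelic, loop-free pedigrees only; no linkage heterogeneity
(HLOD) or multi-locus trait models; LD is pruned, not modelled; the
relationship check's decision regions are simulation-calibrated rather
than theoretical; Elston–Stewart peeling for very large families is not
implemented (the bit limit is the boundary of the engine's domain).
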