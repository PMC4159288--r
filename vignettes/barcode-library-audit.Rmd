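---
title: "Auditing DNA barcode libraries: models, parameters and design choices"
author: "barcodeAudit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing DNA barcode libraries: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeAudit)
```

# The problem

A DNA barcode reference library pairs standardized mitochondrial COI-5P
sequences with expert species identifications. Whether such a library can
identify unknowns depends on the *barcoding gap*: intraspecific variation
must stay below the divergence separating species. This package audits a
library against its own labels from four angles — pairwise distances,
tree-based monophyly, haplotype networks, and distance-distribution
partitioning — and flags the two failure modes that matter in practice:
species pairs whose barcodes overlap (haplotype sharing through recent
speciation or hybridization) and species containing deeply divergent
lineages (candidate cryptic species).

# Distance model

All distances are Kimura 2-parameter (K2P), the de-facto standard for
barcode work. For two aligned sequences, sites where either is not an
unambiguous A/C/G/T are deleted pairwise; over the remaining $L$ sites,
with transition proportion $P$ and transversion proportion $Q$,

$$d = -\tfrac12 \ln\!\left[(1 - 2P - Q)\sqrt{1 - 2Q}\right].$$

Assumptions: a common coordinate frame (the package refuses unaligned
input rather than aligning it), equal rates across sites, and a single
transition/transversion rate split. Two numerical policies are deliberate:

* **Undefined, never clamped.** A pair is *undefined* when fewer than
  `minOverlap` sites survive pairwise deletion (default **300 sites**,
  roughly half the barcode — below that, a 400 bp fragment pair can share
  almost nothing and the estimate is noise), or when a logarithm argument
  is non-positive (mutational saturation). Downstream summaries skip and
  count undefined cells; clamping them to some large value would silently
  bias maximum-distance statistics.
* **Ambiguity codes equal N.** R, Y and the other IUPAC codes are deleted
  exactly like N. They carry partial information in principle, but mixing
  partially-matched sites into $P$ and $Q$ has no clean closed form.

Internally all distances are proportions; tables print percent with two
decimals.

# Threshold conventions

The audit's single divergence threshold defaults to **2.2 %**, the
conventional coarse boundary between intra- and interspecific barcode
divergence in large arthropod libraries. It drives three surfaces: the
low-divergence species-pair table (minimum interspecific distance below
threshold), the deep-divergence species tables (maximum intraspecific
distance above threshold), and single-linkage threshold clustering.

Threshold clusters are the connected components of the graph joining
pairs with $d$ below threshold. This is a *documented proxy* for
database-assigned barcode OTUs (whose production algorithms are
proprietary); every report states the proxy in its header. Single linkage
is chosen because it matches the graph-connectivity semantics of "these
barcodes cannot be told apart at this radius".

# Trees and monophyly

The neighbour-joining tree is built by the standard Saitou–Nei
agglomeration on the K2P matrix (delegated to `ape::nj`, a deterministic,
widely validated implementation). Negative branch-length estimates — an
artifact of NJ's least-squares averaging — are clamped to zero with the
deficit shifted to the adjacent edge, preserving path lengths
approximately; `keepNegative = TRUE` disables this. Specimens involved in
undefined distances are dropped greedily (fewest removals to a complete
matrix) rather than imputed: imputation would invent data on exactly the
fragments least able to support it.

Bootstrap supports resample alignment columns with replacement; one root
seed spawns one sub-seed per replicate, so runs are reproducible and
replicates independent. Replicates whose resampled matrix contains an
undefined distance are dropped and counted; supports are percentages of
kept replicates.

A species is *monophyletic* when some edge bipartition of the unrooted
tree isolates exactly its specimens. Before this test, internal edges
shorter than `tol = 1e-8` are collapsed into polytomies
(`ape::di2multi`). The reason is degeneracy, not aesthetics: specimens
with identical sequences give NJ a zero-length polytomy whose binary
resolution is an arbitrary tie-break, so without the collapse the
monophyly of haplotype-sharing species flips with input order. With it,
a species whose haplotype is also carried by another species is
consistently non-monophyletic — the reading a practitioner takes from a
printed tree. The tolerance sits many orders of magnitude below one
substitution on any realistic fragment (1/658 ≈ 1.5e-3).

# Haplotype networks

Within an analysis group (a species or genus), specimens collapse into
haplotypes if identical at every site where both are unambiguous
(ambiguity-compatible merging, the right behaviour for libraries with
unequal-quality reads; `strict = TRUE` gives exact-identity collapsing).
Merging is sequential in input order and representatives absorb resolved
sites from members; with dense ambiguity the assignment can be
order-dependent, a known limitation noted below. Haplotypes are numbered
`h1, h2, ...` by descending frequency, then first occurrence.

The **connection limit** is the largest number of mutational steps $j$
whose probability of a fully parsimonious connection still exceeds the
confidence level (default 0.95). The package computes this probability
under a finite-sites Poisson model: $j$ observed differences over $L$
sites imply a Jukes–Cantor-corrected per-site load
$\lambda = -\tfrac34\ln(1 - \tfrac43 j/L)$, and the probability that no
site carries a superimposed change is
$P(j) = [(1+\lambda)e^{-\lambda}]^{L}$. The limit is floored at one step
and is monotone non-decreasing in $L$ and non-increasing in confidence.
The package freezes its own derived constants — `connectionLimit(658,
0.95)` is 8 and `connectionLimit(658, 0.90)` is 11, each verified in the
test suite against an independent direct evaluation — rather than
asserting constants printed by historical network software, whose exact
probability recursion differs in detail.

Networks are assembled by connecting haplotype pairs in order of
increasing mutational distance (ties: higher combined frequency, then
lexicographic ids), inserting one inferred "missing" haplotype per
intermediate step. Within one distance class, every pair whose endpoints
lay in different components at the start of the class is connected, which
permits reticulations for alternative equal-length connections. Pairs
beyond the limit are never joined directly; the resulting components are
the subnetworks, and `subnetworkGap()` reports the minimum step count
between each pair of subnetworks.

# Barcode-gap partitioning and the two-parameter sweep

The partitioner re-implements automatic barcode gap discovery. All
defined pairwise distances are sorted; the gap between consecutive
distances is **significant** when its width exceeds $X$ times the local
scale, and a **candidate** when its upper endpoint exceeds the
intraspecific prior $P$. The set splits at the first candidate gap into
the components linking pairs below the gap, and the procedure recurses
within groups until nothing splits or a group has fewer than three
members (too few to discuss a distribution).

Three rule details were genuinely open and are fixed as follows:

* **Local scale.** The scale is the mean width of the *other* gaps in a
  centered rank window of $w = \max(10,\ 5\%)$ of the distances.
  Excluding the candidate from its own window matters: a dominant gap in
  a 10-gap window contributes 10 % of the window mean, so including it
  would make the extreme setting $X = 10$ unsatisfiable by construction.
* **Prior semantics.** A gap qualifies while its *upper* endpoint exceeds
  the prior. This makes the per-species estimator (below) track the
  inter-lineage divergence — the quantity of interest — rather than the
  intra-lineage noise floor that the lower endpoint would measure.
* **Grids.** The prior grid is geometric over $[0.001, 0.1]$ (it spans
  two orders of magnitude; equal log steps weight each decade equally)
  with 100 steps; the gap-width grid is linear over $[0.1, 10]$ with 100
  steps.

The sweep runs the partition at every grid cell and classifies each
species as *lumped* (all specimens in one group) or *split*. Because
significance and component structure do not depend on the prior, the
engine caches each specimen subset's sorted distances, gap scales and
dendrogram, making the full 10,000-cell sweep a few seconds on ~160
specimens. **Estimator P** for a species is the smallest grid prior at
which it is lumped, read at the gap-width column nearest 0.1 (the most
permissive setting, which finds gaps of any size and therefore isolates
the prior's effect); species lumped at the smallest prior are censored
`<0.1`, species never lumped are censored `>10`.

Group counts are monotone non-increasing in both the prior and the gap
width, and the partition at the smallest prior and smallest gap width
refines every other cell's partition; both properties are asserted over
the full grid in the test suite.

# The synthetic generator

`generateLibrary()` emits libraries whose statistical shape mirrors a
real Central-European insect barcode campaign, with a truth table for
every planted feature. Fixed study conditions:

* alignment length 658 columns; root base composition A 31.8 %, C 18.6 %,
  G 16.0 %, T 33.6 % (AT-rich arthropod COI);
* transition:transversion odds `kappa = 4`, typical for insect
  mitochondrial COI;
* species ancestors evolved 35–85 substitutions from a common root, which
  realizes interspecific distances of roughly 10–26 %;
* star-like intraspecific variation: the ancestral haplotype is the modal
  one; satellite haplotypes carry 1 to
  $\mathrm{round}(t/100 \cdot L / 2)$ substitutions for an intraspecific
  target of $t$ %;
* deep splits plant an exact substitution count between two sub-ancestors
  (the realized ancestor-pair K2P is recorded as the planted divergence);
  within-lineage satellites evolve on sites *excluding* the split sites,
  so the planted gap is never eroded by cross-lineage reversions, and the
  split species' stem is lengthened so the split stays inside the
  species;
* sharing groups give all `core` species one identical modal haplotype;
  `satellite` members sit at least one step away;
* the `mixed_full` preset (≈ 39 species, ≈ 160 specimens) adds the
  study-like nuisance structure: 30 % shorter fragments (ends replaced by
  `-`, informative length kept ≥ 410) and 5 % of records carrying 1–5 N
  sites.

Substitution *counts* are planted rather than branch times because
distances are the observable being audited; within one evolution step all
sites are hit at most once, keeping truth distances exact. What the
generator does **not** emulate: indels and misalignment, codon structure
and selection, nuclear mitochondrial pseudogenes, rate variation across
sites, and geographic sampling structure. Passing tests therefore
demonstrate correct recovery of planted distance/topology structure under
realistic fragment-length and ambiguity noise — not robustness to
alignment error or NUMT contamination.

Truth expectations are asserted only where the data determine the
outcome. Core sharing species are expected non-monophyletic (their shared
specimens sit in a polytomy with another species after zero-length
collapse); satellite species 1–2 steps off a shared blob are *not*
asserted (`NA`) because a single coincidental same-site mutation can
legitimately tip the resolution; every sharing-group member is expected
to appear in the low-divergence pair table; expected threshold-cluster
counts are 2 exactly when the planted split exceeds 2.2 %.

# Problem sizes

The test suite runs the exhaustive two-site K2P enumeration plus 1,000
random full-length pairs against a closed-form oracle at 1e-12; 50 random
additive matrices (n ≤ 12) against a brute-force quartet oracle; 50 small
random matrices against an exhaustive gap-search oracle; the full
100 × 100 sweep grid on `mixed_full`; estimator recovery over 20 seeds
per deep-split variant; and end-to-end byte-determinism with 100
bootstrap replicates. The acceptance script uses the same sizes with 200
bootstrap replicates. The audit default of 1,000 replicates remains the
recommended setting for real analyses.

# Known limitations

* Exact numeric agreement with the historical ABGD and TCS programs is a
  non-goal: both leave tie-breaking and local-scale details undocumented,
  so this package fixes its own rules (documented above) and freezes its
  own constants.
* Ambiguity-compatible haplotype collapsing is order-dependent when one
  ambiguous sequence is compatible with several mutually incompatible
  haplotypes; with realistic (sparse) ambiguity this does not arise, and
  strict collapsing is available.
* The identification-rate summary (species not non-monophyletic and
  sharing no threshold cluster) is one defensible operationalization;
  published figures built on proprietary OTU assignments mix criteria
  that cannot be reproduced exactly, so cross-study comparisons of this
  number should be tolerant.
* Monophyly after zero-length collapse treats identical haplotypes as
  unresolvable; a bootstrap-majority reading could differ for species
  separated by a single substitution.
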