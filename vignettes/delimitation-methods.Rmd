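---
title: "Methods: threshold-based rDNA taxon delimitation in pdelim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: threshold-based rDNA taxon delimitation in pdelim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdelim)
```

## The model and its assumptions

`pdelim` implements barcode-gap taxon delimitation: species and genus
boundaries are read off uncorrected pairwise distances (*p*-distances)
computed on per-locus rDNA alignments, with trees and morphology as
corroboration rather than as the primary signal. The approach assumes:

* input alignments are trustworthy (alignment itself is out of scope —
  the package consumes aligned FASTA);
* within-taxon divergence is well separated from between-taxon
  divergence at the chosen loci (a "barcode gap");
* loci diverge at different rates (ITS fastest, 28S slower, 18S nearly
  invariant), so each locus carries its own thresholds;
* type strains anchor names: no cluster can *establish* a taxon without
  one.

The *p*-distance between two aligned sequences is the proportion of
differing sites among compared sites, where a site is compared only if
both sequences carry `A`, `C`, `G` or `T` (*pairwise deletion*). IUPAC
ambiguity codes are treated as missing, not partially matched;
transitions and transversions count equally. A pair sharing no
comparable site has a *missing* distance, which propagates as missing —
never as 0 or 1 — and contributes no clustering edge. `p` is uncorrected
by design: the thresholds in use are calibrated on observed proportions,
not on model-corrected distances, so correcting (Jukes–Cantor,
Tamura–Nei, ...) would silently shift every boundary.

Before distances are computed, columns in which gaps (`-`) or missing
characters (`?`) occupy **more than** half of the records are removed
(`filterGapColumns()`). The inequality is strict: a column gapped in
exactly half of the records is retained. `?` counts as a gap for this
filter because it carries no information; ambiguity codes do not. The
filter is idempotent and records a column map back to the original
coordinates.

## Tunable parameters

All thresholds live in a `ThresholdProfile` (proportions, i.e. 0.03 =
3%):

| parameter | ITS | 28S | meaning |
|---|---|---|---|
| `speciesMax` | 0.03 | 0.01 | largest within-species distance |
| `genusLow`   | 0.08 | 0.02 | generic segregation with distinct morphology |
| `genusHigh`  | 0.12 | 0.05 | generic segregation on molecular data alone |
| `minLength`  | 450 nt | 500 nt | representative candidacy (ungapped length) |

The defaults are the divergence bars in use for marine Halosphaeriaceae
rDNA; they satisfy the invariant
`0 < speciesMax <= genusLow <= genusHigh < 1` per locus, which the class
validity enforces. The 3–8% ITS band between `speciesMax` and `genusLow`
is the *congeneric* band: distinct species, same genus. The 8–12% band
is borderline unless morphology is distinctive, in which case the lower
bar applies. Analogous logic holds for 28S, with the twist that 28S
evidence alone can never *establish* a taxon — only flag a *putative*
one — because ITS is the required locus.

## The pipeline stages

1. **Species clustering.** Single-linkage components at `p <= speciesMax`
   per locus. Single linkage (rather than complete linkage) was a
   genuinely open choice: published group descriptions are compatible
   with either. We chose single linkage because it is deterministic,
   order-free and transparent; the cost — chained groups whose
   within-range exceeds the threshold — is made visible by reporting
   each group's full within-range, and such groups automatically receive
   extra representatives per sub-cluster.
2. **Reconciliation.** The ITS partition is primary. 28S co-membership
   assigns only the strains ITS cannot resolve (strains lacking ITS
   attach to the ITS species of their lexicographically first 28S
   neighbour with ITS, or form their own species). A 28S link between
   two distinct ITS species is recorded as a conflict but *not* applied:
   28S at its 1% threshold undersplits, and letting a slower locus chain
   ITS-distinct species would undo the primary signal. This is the one
   place where we deviated from a blanket "28S may merge" reading; the
   conflict log preserves the evidence either way.
3. **Representatives.** Within each species, candidates must reach
   `minLength` ungapped nucleotides; among candidates the most distant
   pair is chosen (spanning the group's diversity), with ties broken by
   type-strain membership, then two-locus coverage, then lexicographic
   record ID. If no member reaches the bar the filter falls back to all
   members with a warning; diversity-driven *extra* representatives,
   however, are only ever drawn from qualifying candidates.
4. **Genus stage.** Between-species minimum distances are computed on
   representative strains only (ITS where available, 28S otherwise).
   Species join a genus when that minimum falls strictly below
   `genusLow`; the 8–12% borderline band therefore separates genera in
   the partition while the accompanying `RankDecision` records it as
   `borderline`/`inconclusive`. Every species pair with data gets a
   decision with an evidence trace; contradictory loci (one says
   same-species, the other distinct-genus) yield
   `borderline`/`inconclusive`.
5. **Trees.** Neighbor joining on the p-distance matrices (via `ape`),
   with support from a nonparametric column bootstrap (default 1000
   replicates; 100 in the stage drivers' defaults, where the trees are a
   sanity check rather than a result). NJ is exact on additive matrices,
   which the test suite exploits as an oracle. Negative NJ branch
   estimates are clamped to zero for display, with raw values retained.
   ML and Bayesian inference are out of scope on purpose: the
   delimitation is distance-driven, and the scaffold tree only audits
   monophyly of the inferred genera.
6. **18S.** Report-only. The 18S matrix is binned by the inferred
   partitions; the locus is called discriminative only if between-genus
   distances overlap no within-genus distance **and** clear 3%, the
   smallest 18S divergence that can be read as unambiguously
   inter-generic. Below that, identical or 1–2% 18S values occur between
   genera as readily as within them, which is exactly why 18S never
   alters partitions here.

## The simulator

`simulateDataset()` generates truth-labelled multi-locus data on a fixed
genus/species/individual hierarchy (star-like within species). Edge
lengths (expected substitutions per site) are calibrated by the
Jukes–Cantor inversion `d = -(3/4) log(1 - (4/3) p)` so that the
*expected observed* p-distance between tips of each level matches the
targets: ITS 1% within species, 5% between congeneric species, 18%
between genera, with 28S at 0.35× and 18S at 0.05× those values —
mirroring the empirical ITS > 28S >> 18S ordering. Targets at or above
75% are rejected (JC saturation).

Two numerical choices deserve emphasis:

* **Substitution planting.** Each edge substitutes a *fixed count*
  `round(q L)` of uniformly sampled distinct sites (each to a uniformly
  chosen different base), where `q = 3/4 (1 - exp(-4/3 d))` is the JC
  per-site change probability for the edge. Because `q` already folds in
  multiple hits, edges compose and the expectation over a path equals
  the JC value for the summed length. Relative to per-site Bernoulli
  draws this removes the binomial component of the variance, so realized
  divergences concentrate at their targets; that is what makes planted
  partitions exactly recoverable at the default 500 nt ITS, where the 2%
  margin between the 5% between-species target and the 3% threshold
  would otherwise be crossed by sampling noise in a substantial fraction
  of runs. The cost is mild rounding (up to half a substitution per
  edge).
* **What is and is not emulated.** The simulator has uniform rates, no
  rate heterogeneity across sites, no indels (gap and missing structure
  is injected afterwards by `degradeDataset()`, which drops loci,
  truncates sequences below the representative bar, and never touches
  retained residues), no intragenomic ITS variation and no recombination.
  Passing tests therefore demonstrate that the *pipeline logic* is
  correct under the divergence structure the method assumes — they do
  not demonstrate robustness to alignment error, rate variation or
  taxon-specific anomalies in real data.

## Numerical and degenerate-input conventions

* Report percentages are integers rounded half away from zero
  (`percentReport()`); missing values render as an em dash.
* Tie-breaks are lexicographic on record/strain IDs everywhere
  (group labels, representative selection, 28S attachment), making every
  stage deterministic and order-free; partitions are invariant to input
  order and relabelling.
* Group labels follow size, then smallest member; singleton groups have
  an undefined (NA) within-range.
* Empty alignments, duplicate record IDs, duplicate strains within one
  locus, unequal sequence lengths, all-missing pairs in tree input, and
  fewer than two loci in the concatenated stage are all hard errors with
  informative messages; a metadata-less FASTA header only warns and
  receives defaults.
* Bootstrap and simulation functions take explicit seeds and restore the
  caller's RNG state; stage outputs carry a provenance header (package
  version, seed, config hash).

## Problem sizes in the test suite

The suite validates against independent oracles at deliberately modest
sizes, chosen to exercise every code path while keeping a full run in
the tens of seconds: 100 random alignments up to 20 × 300 for the
distance oracle, 100 random matrices for the union-find clustering
oracle, 50 random 6–10-taxon additive matrices for NJ exactness, ten
seeds of the default 3 × 3 × 4 design (36 strains, three loci) for exact
partition recovery, and twenty seeds at 5000 nt for simulator
calibration (tolerance: three binomial standard errors of the mean).

## Known limitations

* Thresholds are global per locus; clade-specific barcode gaps must be
  expressed through the profile or morphology flags, and the package
  offers no automatic threshold estimation (an ABGD/ASAP-style gap
  search is a natural extension).
* Single-linkage chaining can in principle connect well-separated
  clusters through intermediates; the within-range audit and sub-cluster
  representatives mitigate but do not prevent this.
* The identity-floor pre-filter (`excludeDivergentRecords()`) only
  screens within the dataset; it cannot catch a mislabelled sequence
  whose nearest in-dataset neighbour is its own contaminant lineage, as
  an external database search would.
* The 28S-only establishment override is per-taxon and manual, matching
  how such exceptions are argued case by case in practice.
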