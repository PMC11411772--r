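---
title: "Length-binned consensus SV calling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Length-binned consensus SV calling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svconsensus)
```

## The model

No single structural-variant caller is accurate across event lengths
and sequencing depths: split-read evidence resolves short deletions at
base-pair precision but degrades for long events, while read-depth
evidence behaves in the opposite way. `svconsensus` treats this
complementarity as the object to optimize. Given call sets from several
upstream callers and a gold-standard truth set, it estimates each
caller's accuracy *per length bin*, remembers the per-bin winner in a
trained profile, and in discovery mode assembles a consensus call set
by routing each bin through its winning caller.

The method has three parts, and every quantitative claim about it in
this package is backed by a test or by `scripts/acceptance.R`.

### Breakpoint-resolution matching

A predicted call matches a truth event when both records are on the
same chromosome, have the same SV type, and both breakpoints agree
within a resolution tolerance τ:

\[ |\mathrm{start}_i - \mathrm{start}_t| \le \tau
   \quad\text{and}\quad
   |\mathrm{end}_i - \mathrm{end}_t| \le \tau . \]

The comparison is inclusive at τ. This is a *dynamic* criterion — the
permitted breakpoint error does not scale with event length, unlike
reciprocal-overlap rules — so sweeping τ over 0, 10, 100, 1000 and
10000 bp profiles breakpoint accuracy directly. 100 bp is the default
for single-number reports: tight enough to reject coincidental overlap,
loose enough to tolerate the breakpoint uncertainty of read-pair
callers.

Pairing is one-to-one and greedy: truth records are visited in the
canonical sort order (chromosome, start, end, type — radix order, so
locale-independent), and each is paired with the first not-yet-used
matching inferred record in that same order. Greedy pairing can in
principle fall short of the maximum bipartite matching, but the test
suite checks it against an exact maximum-matching oracle on fuzzed
instances and the two agree whenever candidates are unambiguous; truth
sets with events packed within 2τ of each other are where they can
differ, and the synthetic generator deliberately never produces such
fixtures (see below). The payoff of greedy-in-sorted-order is
determinism: identical inputs give byte-identical results, with no
dependence on hash ordering or input file order.

Insertions are represented as points (`end == pos`), so the rule
degenerates to a single position comparison; an optional length gate
(`|Δsvlen| ≤ τ`) can be enabled where position alone is considered too
permissive. It is off by default so that deletion and insertion
benchmarking use the same notion of breakpoint distance.

Metrics are sensitivity TP/(TP+FN), precision TP/(TP+FP) and their
harmonic mean. Zero-denominator cases return 0 rather than NaN — an
empty call set is a (maximally poor) result, not a missing one.

### Per-bin training

Length bins default to [50, 100), [100, 500), [500, 1000) and
[1000, ∞) bp: short events near the 50 bp SV definition boundary, two
medium regimes, and the long tail. Bins are half-open with the boundary
in the upper bin, making the partition exact; the edges are
configurable. Stratified benchmarking assigns each record — truth and
inferred alike — to the bin of its own length and re-matches within the
stratum. Re-matching per stratum (rather than stratifying one global
match) keeps each bin's row a self-contained benchmark; its one
artifact is that a call whose length jitters across a bin edge is
counted against the neighbouring bin, which matters only when
breakpoint noise is comparable to bin width.

Training ranks callers within each bin by F-score (precision- or
sensitivity-ranked training is available for users optimizing one
side). Ties break by higher precision, then lexicographic caller id, so
the winner is invariant to the order call sets are passed in. A bin
with no truth events cannot be ranked locally; it inherits the global
(unstratified) ranking and is flagged `untrained` in the profile
metadata rather than silently trusted. Profiles are keyed by organism
tag, coverage tier and SV type — deletions and insertions train
separately because their winning callers differ. Organism "closeness"
is deliberately just tag equality with a designated default fallback;
inventing a phylogenetic similarity for caller selection would suggest
a precision the method does not have. Coverage tiers default to
ultra-low [0, 0.5), low [0.5, 8), mid [8, 20) and high [20, ∞) ×,
separating the depth regimes where caller behaviour is known to change;
they are configurable, and the tier edges are a packaging convenience,
not a claim about sharp thresholds.

### Consensus merging

Standard (discovery) mode takes, for each bin, the records of that
bin's winning caller whose own length falls in the bin, concatenates
across bins, and deduplicates. Deduplication reuses the matching
predicate at τ = 100 bp by default — "the same event" means the same
thing when building the consensus as when scoring it — via greedy
clustering in priority order: a record is dropped when a retained
record of the same type sits within τ on both breakpoints. Among
duplicates the higher-ranked caller's record is retained unmodified; no
breakpoint averaging is attempted, because fabricating consensus
coordinates would decouple the output from any caller's evidence.
Every consensus record carries `SRC_CALLER`, `LEN_BIN` and (in
precision mode) `SUPPORT` INFO keys as provenance.

The two optimized modes bracket the standard mode. *Recall* mode is
the deduplicated union of all callers: since the output τ-contains
every input call, its sensitivity dominates every input's. *Precision*
mode keeps a record only when τ-matching records exist in at least
`min_support` distinct callers (a caller's own duplicates count once,
so a noisy caller cannot self-confirm); with `min_support = 1` it
reduces exactly to recall mode, and raising `min_support` only shrinks
the output, giving a containment chain the tests verify. `min_support`
defaults to 2 — the weakest agreement requirement that still removes
caller-private false positives, chosen because FP excess is the
dominant failure mode of individual callers; the exact agreement-based
formulation of the optimized modes is this package's interpretation,
documented as such.

## Call-set representation and I/O

Records mirror VCF: 1-based inclusive coordinates, with BED's 0-based
half-open intervals converted at the boundary by `rtracklayer`. Event
lengths are stored as magnitudes; the negative deletion `SVLEN` of VCF
convention is reconstructed on write. When `END` and `SVLEN` disagree
for a deletion, the coordinates win (`svlen` is recomputed as
`end − pos`) because matching operates on coordinates; for insertions
`SVLEN` wins, as `END` carries no length information. Multi-allelic
records split into one record per ALT. Genotypes are ignored
throughout: this is a site-level tool. Records missing both `SVLEN`
and `END`, or of unknown type, are counted and skipped with a message
— a caller's exotic records should not abort a benchmark.

The ≥ 50 bp filter is strict below threshold (a 50 bp event is an SV).
High-confidence region filtering defaults to full containment of the
event within a region, the usual convention for benchmarking against
high-confidence truth sets, with an any-overlap rule available where a
looser restriction is wanted.

## The synthetic generator

`generate_truth()` places a fixed number of events per bin, positions
uniform within disjoint slots and lengths log-uniform within each bin
(log-uniform matches the strong left skew of real SV length
distributions; the open top bin is capped at 10 kb, the largest τ in
the sweep). No two events come closer than twice the maximum event
length, so a simulated call can match only its source event and
measured sensitivity is exactly the emission rate — this is what makes
the calibration tests sharp. The default genome is five human
chromosome lengths (chr15–chr19, GRCh38), supporting chromosome-held-out
splits with `train_test_split()`.

`corrupt()` emits each truth event with its bin's detection
probability, perturbs emitted breakpoints with rounded zero-mean
Gaussian jitter (independently per breakpoint for deletions, so lengths
wobble; position only for insertions), and adds Poisson false positives
at a per-Mb rate with lengths resampled from the truth distribution so
that every bin's precision is exercised. Defaults in the test suite and
acceptance script — detection 0.9/0.3 contrasts between complementary
callers, 0.2 FP/Mb, 10 bp jitter — are plausible for modern short-read
callers at moderate depth.

What the generator does *not* emulate: clustered or repeat-associated
events, breakpoint microhomology, systematic (shared) caller errors,
correlated false positives between callers, genotype errors, or any
read-level signal. Passing the synthetic end-to-end tests therefore
demonstrates that the machinery — binning, training, routing, merging,
scoring — is correct and self-consistent, not that real-data F-scores
will match; on real data, caller errors correlate and precision-mode
gains will be smaller than the independent-FP simulation suggests.

## Numerical and degenerate-case choices

* All sorting uses radix order on (chromosome, start, end, type):
  total, stable, locale-independent.
* τ comparisons are inclusive (`≤`); bin edges are half-open with the
  boundary above.
* Zero-denominator metrics are 0; empty call sets round-trip as
  header-only VCFs.
* The downsampler decides keep/drop by a 64-bit FNV-1a hash of the
  read name mixed with the seed (implemented in C++), not a streaming
  RNG: mates met far apart in the stream get the same verdict without
  buffering, selections are byte-identical across reruns, and
  different seeds give independent selections. Secondary and
  supplementary alignments inherit their template's fate; unpaired
  reads are singleton groups at the same rate.
* Profile YAML is written at 15 significant digits so save/load
  round-trips are lossless to working precision.

## Problem sizes

The test suite and acceptance script are sized to run comfortably on a
laptop core: matcher fuzzing uses 200 instances of ≤ 50 truth / ≤ 60
inferred records; planted-winner recovery uses 500 truth events per bin
for training and 200 per bin held out, across 20 seeds in the tests and
10 in the acceptance script; calibration uses 1000 events; the
downsampler fixture has 10,000 read pairs. These sizes put binomial
confidence intervals well inside the planted effect gaps (≥ 0.2 in
F-score), so the recovery checks are statistically decisive.

## Known limitations

* Deletions and insertions are first-class; duplications and
  inversions are carried through I/O and matching but the shipped
  defaults were designed around DEL/INS behaviour.
* Greedy matching is order-deterministic, not globally optimal, in
  dense truth neighbourhoods (within 2τ).
* The consensus keeps representative records verbatim; it does not
  refine breakpoints, re-genotype, or merge attributes.
* Profile transfer across organisms is tag-based; there is no notion
  of similarity between unseen organisms beyond the declared default.
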