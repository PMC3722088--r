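---
title: "Dissecting segmental duplications into core repeat elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting segmental duplications into core repeat elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repcore)
```

## The problem

Large segmental duplications (SDs) — blocks of highly homologous duplicated
genomic DNA that can reach a megabase in the mouse genome — are built from
tangled arrays of repeated sequence in both orientations, and they are where
copy-number variable regions (CNVRs) concentrate. Annotation against known
repeat libraries explains parts of these regions, but the *units of
duplication* themselves — the sequences that were actually copied around —
are not in any library. `repcore` identifies those units ab initio, directly
from the self-similarity structure of the region, and then asks, for each
unit, whether its copy number varies between strains.

The workflow has three phases:

1. **Self-comparative dot-plot.** The region is tiled into non-overlapping
   windows and every window pair is tested for shared seed matches; runs of
   consecutive dots along (anti-)diagonals are repetitive sequences.
2. **Core-element discovery.** Repetitive sequences in an informative length
   band are reduced to a nonredundant set ("fundamental repetitive
   sequences"), clustered around representative sequences, and collapsed to
   gap-free consensus **core elements**, whose occurrences are then mapped
   back onto the region.
3. **CNV classification.** Array-CGH probe log2 ratios falling inside each
   core's occurrences are tested against zero with a one-sample *t*
   statistic, Bonferroni-corrected across cores, in two strain comparisons;
   a core is *CNV-type* if significant in both comparisons and
   *constant-type* if in neither.

## The dot criterion

Two windows form a dot when they share at least `min_seed_hits` seed matches:
offset pairs whose `seed_len`-mers (default 30 bp) differ at no more than
`max_mismatches` positions (default 2). Two presets mirror the two working
granularities:

* *fine*: 300-bp windows, one 30-bp seed suffices — used for repeat
  extraction;
* *coarse*: 3,000-bp windows, more than three seeds required — used for
  genome-scale scanning of candidate SDs.

Dots closer to the main diagonal than `min_offset_bp` are suppressed so the
trivial self-match band never appears; in fine mode the offset floor equals
one window. Seeds containing `N` never match, so assembly gaps cannot create
spurious dots.

The implementation indexes exact sub-seeds (a pigeonhole split of the seed
into `max_mismatches + 1` parts) and verifies candidates by Hamming
distance. This is a speed strategy only: the test suite holds the seeded
count to *exact* equality with an exhaustive double-loop oracle across
hundreds of random window pairs at each mismatch setting.

## From dots to fundamental repetitive sequences

Maximal runs of at least `min_run = 3` consecutive dots (forward runs step
`(i+1, j+1)`, reverse runs `(i+1, j-1)`) become repetitive sequences; with
300-bp windows the shortest is 900 bp. Runs interrupted by a missing dot are
not bridged — consecutiveness is strict. Each repetitive sequence carries
two genomic footprints, the row-axis (query) interval and the column-axis
(mate) interval, because the repeat is present at both loci; coverage
diagnostics count the union of both.

Candidates are restricted to 3–4.5 kbp. This window is a property of the
length/coverage trade-off: short repeats are abundant but uninformative,
while the coverage of the region by repeats in this band remains high (the
`coverage_curve()` diagnostics reproduce this trade-off on any input).

Redundancy is then removed on the dot-plot geometry: a selected sequence
eliminates every other sequence lying in the same row or column band —
formalized as query-or-mate interval overlap exceeding `overlap_frac = 0.5`
of the shorter interval, on either axis. The selection order (longest first,
ties by leftmost query then mate start) is a design choice the procedure
needs to be deterministic; any fixed order yields a maximal conflict-free
set under the same rule, which is what the tests verify.

## Clustering and consensus

All surviving fundamentals are aligned pairwise (local alignment through
BLASTN, match +1 / mismatch −2 / gap 5,2, no low-complexity filtering, both
orientations; the best alignment per pair is kept). Pairs sharing at least
`min_shared_bp = 2700` aligned columns at `min_identity = 0.7` count as
matches — 2.7 kbp sits just below the fundamental length band, so genuinely
co-familial sequences qualify while partial overlaps do not. Clustering is
greedy: the unassigned sequence with the most qualifying matches becomes a
group representative (ties to the lower id, which makes the procedure
order-invariant), everything matching it joins, and the process repeats;
isolated sequences form singletons.

Each group is collapsed by a star alignment of members to the
representative rather than a full multiple alignment — groups can hold many
members, and the representative is by construction the sequence the group
agrees on most. A representative column enters the consensus when more than
half the members align across it. Within such columns:

* the majority base is called when at least as many aligned members carry a
  base as carry a gap (ties between bases resolve alphabetically);
* columns where gaps predominate — insertions private to the representative
  — are *excised* without interrupting the block.

The excision rule matters numerically: with per-copy indel rates of the
order seen between repeat copies, treating every representative-private
insertion as a block break would shatter the consensus into sub-kilobase
fragments and no core would survive the `> 1 kbp` gap-free length
criterion. Excision reconstructs the majority sequence, which simply lacks
those bases. A group whose aligned blocks are all ≤ 1 kbp yields no core
(reported, not fatal); a group with two long blocks separated by
unalignable spacer yields two cores, which is why core ids carry a `.1`,
`.2` suffix in that case.

Core occurrences are then mapped by local alignment of each consensus
against both strands of the region, keeping hits with identity ≥ 0.70 that
span at least half the core, and resolving overlapping same-strand hits by
identity (ties leftmost).

## CNV classification

A probe belongs to a core when its midpoint falls inside one of the core's
occurrences; midpoint assignment is the simplest rule consistent with
probes (50–75 bp) being much shorter than cores (kilobases). Replicate
measurements are pooled per probe by mean before testing — the package's
default, exposed as `pool_replicates` — because replicate spots of one
probe are not independent observations of copy number.

For each core and strain comparison with `n ≥ 2` probe values the statistic
is

\[ t = \bar X \sqrt{n / U}, \]

with \(U\) the unbiased sample variance, referred to Student's *t* with
`n − 1` degrees of freedom, two-sided — the classical one-sample test of
mean log2 ratio zero (no copy-number difference). P-values are
Bonferroni-multiplied across cores; the family size defaults to the number
of testable cores per comparison (cores with at least `min_probes = 30`
probes) and can be pinned with `n_tests`. Cores under the 30-probe floor in
either comparison are labelled `insufficient`; otherwise `CNV` (both
comparisons significant at `alpha = 0.05`), `constant` (neither), or
`single_pair` (exactly one).

Degenerate inputs are handled explicitly: zero variance with a nonzero mean
reports `p = 0` with a `degenerate` flag; zero variance at zero mean
reports `t = 0, p = 1`.

## Divergence

The age proxy for each core is the mean pairwise divergence among its
mapped copies (minus-strand copies reverse-complemented first): per pair,
the percentage of global-alignment columns that are mismatches or gaps.
The aligner is an exact banded unit-cost global alignment whose band is
doubled until the optimum is provably inside it; for the similar sequences
within a core family the band stays narrow and all-pairs computation is
cheap. For very large families the number of aligned pairs is capped
(default 200 per core, evenly spaced deterministic subset) — a
computational cap, exposed as `divergence_max_pairs`. Class-level contrasts
use a two-sided Welch test, and the association between divergence and
duplication count is summarized by a Pearson correlation.

## The synthetic-data generator

`simulate_sd_region()` generates the conditions the pipeline is designed
for and is the basis of every end-to-end test: a uniform-random background
carrying `n_prototypes = 10` prototype sequences, each planted in 5–30
copies with 2% substitutions and 0.2% single-base indels per copy, reverse
orientation with probability 0.5, and background spacers of at least one
analysis window so runs from distinct copies cannot merge. The region sizes
itself to the planted content (≈1 Mbp under the defaults). Prototype
lengths default to 3.3–3.9 kbp so that the window-quantized diagonal-line
lengths (which can exceed a copy's length by up to one window at each end)
land inside the pipeline's own 3–4.5 kbp fundamental band — prototypes much
shorter than 3 kbp are by construction invisible to a 3–4.5 kbp selection,
which is a property of the method, not of the generator.

`simulate_acgh()` emulates two-colour tiling-array output: per prototype
and strain comparison, probe log2 ratios are drawn
`Normal(log2(copy ratio), sd = 0.3)` for 100 probes of 50–75 bp placed
inside planted occurrences, in two replicates. Each prototype is CNV-type
with probability 0.8 (copy ratio drawn from {0.5, 1.5, 2} in both
comparisons), single-pair with probability 0.05, otherwise constant —
proportions chosen to resemble an SD where most units vary between strains.

What the generator does **not** emulate: real transposon phylogenies and
nested/fragmented repeat structure, GC and mappability biases, dye and
hybridization effects beyond Gaussian noise, polymorphism between the
reference and test strains' repeat sequences, and tandem arrays (copies are
always separated by background). Passing the planted-recovery tests
therefore demonstrates the machinery is correct under the stated model; it
does not by itself guarantee the same counts on a real SD region, where
tie-breaking, nested repeats and annotation-scale heterogeneity dominate.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full pipeline on the
default ~1 Mbp simulation (about 3,400 fine windows, ~3,000 repetitive
sequences, ~90 fundamentals, 10 groups), which completes in a few minutes
on one CPU; unit tests use a 3-prototype, ~90 kbp version of the same
generator. Other fixed numerical choices: dots are counted with an
early-exit cap at `min_seed_hits` (the count is exact up to the cap);
consensus ties resolve alphabetically; occurrence merging prefers higher
identity then leftmost position; all internal coordinates are 0-based
half-open, with 1-based closed coordinates only in BLAST interchange.

## Known limitations

* The redundancy-elimination order and the clustering tie-break are
  deterministic conventions; other orders yield equally valid (and
  slightly different) fundamental sets.
* Cores shorter than the fundamental band minus alignment erosion cannot
  be discovered, and nested or composite repeat units are reported as the
  higher-order unit their diagonal lines support.
* Divergence is an uncorrected mismatch+indel percentage, not a
  substitution-model distance; it is comparable across cores within a run
  but not calibrated in time.
* Occurrence counts depend on local-alignment behavior near the identity
  threshold; a copy split by a long insertion can count twice.
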