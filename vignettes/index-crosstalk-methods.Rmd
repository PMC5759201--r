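---
title: "Simulating and quantifying sample-index cross-talk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and quantifying sample-index cross-talk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When multiplexed Illumina libraries are pooled on one flow-cell lane, each
read is assigned back to its sample through one (i7) or two (i7 + i5)
8-nt index reads. Any process that places a foreign index on a library
molecule — adapter cross-contamination during oligo synthesis or
plating, index hopping via free adapter during post-capture PCR, or
index-read sequencing error — causes *cross-talk*: reads demultiplexed to
a sample they did not come from. For sensitive assays (ctDNA, microbial
detection, low-allele-fraction somatic calling) the limit of detection is
set directly by this misassignment floor.

`crosstalksim` provides a generative model of all of these processes with
complete per-read truth, demultiplexing under the two standard adapter
schemes, estimators that quantify and diagnose the cross-talk, and a
UMI-consensus / low-frequency variant-calling arm with an
8-oxoguanine-aware threshold. Because no public data accompany the
analyses this package re-implements, the simulator is a first-class,
tested component: it *is* the experiment.

## Adapter schemes and the c versus c² model

A **combinatorial** plate builds 96 sample identities from 20 oligos
(12 column-wise i7, 8 row-wise i5), so single indices are shared across
wells. A **unique dual-matched** plate gives every well its own adapter
with identical i5 and i7 and a 6-nt UMI appended 3′ of the i7 index;
no index is shared between wells.

The central model assumption is that the i7-bearing and i5-bearing arms
of each fragment's adapter are drawn *independently* from the sample's
adapter pool (two adapter molecules take part in constructing one
fragment). If the pool contains a foreign adapter at fraction $c$,
duplexed before the contamination event, then per fragment:

* both indices foreign: $c^2$ — misassigned under dual-matched
  demultiplexing;
* exactly one foreign: $2c(1-c)$ — a mismatched i7/i5 pair, excluded
  from analysis;
* single-index demultiplexing: all $c$ contaminated fragments are
  misassigned.

With $c = 1\%$ this gives 1% misassignment under single-index reading
but only 0.01% under dual-matched indices, with 1.98% filtered — the
two-order-of-magnitude contrast the acceptance suite reproduces by
Monte-Carlo.

If instead contamination occurred while adapters were *single-stranded
oligos*, only the leaked strand's arm can be swapped. This directionality
is what the symmetry diagnostic (below) exploits.

## The generative model

`simulate_experiment()` composes, per molecule, in order: reference draw
→ variant-allele assignment → oxoG damage → adapter-arm draw → UMI
assignment → PCR amplification → index hopping → index sequencing error.
All randomness flows from one `set.seed(config$seed)` call, so identical
seeds give byte-identical FASTQ output.

Parameters, defaults, and rationale:

| parameter | unit | default | rationale |
|---|---|---|---|
| index length | nt | 8 | TruSeq HT convention |
| UMI length | nt | 6 | the adapters studied carry 6-nt UMIs |
| `fragment_length` | bp | 250 | libraries sheared to 250 bp |
| contamination `rate` | per arm | — | stated per scenario (1% in the model figures) |
| `hop_rate` | per read per index | 0 | hop to a uniformly chosen *other* pool member; the mechanism's kernel is not quantified upstream, so uniform is the minimal choice |
| `index_error_rate` | per base | 0 | substitution-only; indels would shift fixed-cycle index reads and are out of scope |
| `family_size` | reads/molecule | Poisson(2)+1 | guarantees ≥ 1 read; degenerate and geometric alternatives provided |
| `oxog_damage_rate` | per molecule | 0 | one damaged G per affected molecule at a uniformly chosen G/C reference position |
| `oxog_misread_prob` | per PCR copy | 0 | free parameter; the true misincorporation kinetics are not published |
| insert quality | Phred | flat Q30 | insert errors are not the phenomenon under study; index and oxoG errors dominate |

oxoG strandedness: damage sits on the strand carrying the G, so the
artifact surfaces as G>T at reference-G positions and C>A at reference-C
positions — the canonical C>A/G>T transversion class.

Reads are emitted in reference orientation with the originating strand
recorded; alignment is out of scope, so coordinates are carried on the
read records directly.

What the generator does **not** emulate: realistic insert error
profiles, adapter dimers, capture-bait efficiency/uniformity, basecalling
and pass-filter internals, patterned-flow-cell mechanics (platform
differences are represented only as different `hop_rate` /
contamination choices). A green test therefore establishes the
*statistical logic* of the estimators, not instrument-level realism.

## Demultiplexing

Indices are matched independently against a candidate set covering used
*and* unused indices (perfect match, or one mismatch per index). With
mismatch tolerance 1, the candidate set's minimum pairwise Hamming
distance must exceed 2, which guarantees a unique nearest candidate;
policies violating this fail at construction. Ambiguous hits resolve to
*unassigned* rather than an arbitrary winner, because false assignment is
the failure mode under study. N bases count as mismatches; UMI bases are
split off the I1 read before matching.

`build_crosstalk_matrix()` counts reads over the full index grid (e.g.
35 × 35 = 1225 combinations); its total is exactly the reads with both
indices matched, which is the denominator used by every rate in the
package (the upstream analyses' pass-filter denominators are implicit;
ours is stated).

## Estimators

**Misassignment report** — reads in cells whose well was not used in
library preparation (combinatorial), or any off-diagonal / unused
diagonal combination (dual-matched).

**Row/column decomposition** — each misassigned read is classified by
whether its well shares a row and/or column with *any* used well;
single-arm contamination can only reach same-row/same-column wells, so
the "neither" category isolates double events.

**Hop estimate** — single-plex captures cannot hop, so their
mismatched-pair rate is the adapter-contamination baseline; per pool,
`corrected = max(0, pool − baseline)` (floored: rates are physical).
Because each index hops independently at per-index rate $h$, the
mismatched-read rate is $\approx 1-(1-h)^2$; the reported
`implied_per_index_rate` $= 1-\sqrt{1-\text{corrected}}$ inverts this so
that $h$ itself is recoverable.

**Symmetry diagnostic** — the score
$\sum_{i<j}|o_{ij}-o_{ji}| \big/ \sum_{i<j}(o_{ij}+o_{ji})$
over off-diagonal pairs with nonzero sum is 0 for duplex-stage
contamination (both arms leak, cells fill symmetrically) and 1 for
oligo-stage contamination (one arm leaks). Verdict thresholds: skewed
above 0.5 with at least 50 off-diagonal reads, symmetric below 0.2,
indeterminate otherwise — chosen for clear separation at the simulated
counts and configurable.

## UMI families and consensus

Within each (position, strand) bucket, distinct UMIs form a directed
adjacency network: an edge A→B exists when Hamming(A,B) ≤ 1 and
count(A) ≥ 2·count(B) − 1. Families grow breadth-first from the
highest-count unassigned UMI (ties broken lexicographically, making the
partition deterministic). The count-ratio rule merges sequencing-error
satellites of a true UMI without chaining independent molecules; the
test suite checks the partition against an independently coded
brute-force closure on hundreds of random instances.

Consensus per position: unique plurality base over non-N member bases;
ties and zero depth give N. Quality is evidence-based: each member's
Phred is capped at 30 (`error_rate_post_umi`), and the output quality is
the agreeing evidence minus the disagreeing evidence, floored at 2.
The cap is deliberately applied *per member*, not to the output: a
Q30-output cap would contradict the downstream filter's
`min_base_quality = 40`, which expects agreement of three Q30 reads to
produce Q90. This is a simplified, fully specified stand-in for the
original tool's likelihood model and is documented as not bit-identical
to it.

Filtering (defaults `min_reads = 3`, `-E 0.05`, `-N 40`, `-e 0.1`,
`-n 0.1`): reject small or high-error consensus reads; mask individual
bases that are low-quality or locally discordant to N (quality 2); then
reject reads whose no-call fraction exceeds 10%. The "no UMI" comparator
(`raw_duplicate_collapse()`) keeps one read per coordinate key — merging
distinct molecules that share coordinates, which is exactly the
information UMIs restore.

## Variant calling and evaluation

The pileup caller reports every non-reference base at positions with
depth ≥ 100 (deep-targeted-panel context) and calls it at allele
fraction ≥ 0.2%, except C>A/G>T substitutions which must reach 0.3% —
the mutation-specific oxoG threshold. Raising a threshold can only
shrink the call set (exact set inclusion, tested). Truth matching is
exact (position, alt); multi-allelic sites are evaluated per allele; PPV
with zero calls is NA, not 0. Coordinates are 0-based half-open
internally and converted to 1-based only at the output table.

The end-to-end benchmark (`compare_consensus_raw()`) mirrors the
published design: 44 spike-ins at 0.5% and 10 at 1% allele fraction,
plus oxoG-class sites, at 2000× simulated depth with mean family size 4
and per-copy artifact probability 0.5. The acceptance suite asserts, in
every seed, fewer false positives and no worse PPV for consensus versus
coordinate deduplication, and a further FP reduction from the oxoG
threshold with no loss of non-oxoG true positives.

## Numerical and engineering choices

* Index designs are generated, not published: random 8-mers with exactly
  50% GC accepted greedily at pairwise Levenshtein distance ≥ 3
  (`design_index_set()`); equal-length Levenshtein ≥ 3 implies Hamming
  ≥ 3, so the one-mismatch demultiplexing guarantee holds automatically.
* One-mismatch matching is implemented by an exact precomputed
  neighbourhood table (every candidate plus its 1-substitution
  neighbours), with minimal-distance tie resolution, so matching is
  O(1) per read and provably identical to brute-force nearest-candidate
  search (tested exhaustively over all 4⁶ observed 6-mers).
* Consensus and pileup work on a long (read, position, base, quality)
  table built in one raw-byte pass, so the 2000×-depth benchmark runs in
  seconds per seed.
* Degenerate inputs: pools of size 1 cannot hop (warning, no-op);
  empty matrices give zero-filled reports; an all-N column gives a
  zero-depth N consensus base.

## Known limitations

* Paired-end both-end family keys are not implemented; families key on
  the 5′ start and strand only, matching the simulator's single
  coordinate.
* Duplex (double-strand) consensus is out of scope.
* The mapping-quality filter is vacuous on simulated reads (fixed Q60)
  but implemented for completeness.
* The published real-data rates (0.10–0.29% combinatorial cross-talk,
  7.1 × 10⁻⁷% dual-matched) depend on unpublished libraries and are
  treated as report formats, not reproduction targets; only the analytic
  contamination model and the directional claims are asserted.
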