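# crosstalksim

Simulation and quantification of sample-index cross-talk in multiplexed
Illumina-style sequencing, with UMI consensus calling and
low-allele-fraction variant evaluation.

## The problem

Multiplexed sequencing assigns reads to samples through 8-nt i7/i5 index
reads. Adapter cross-contamination, index hopping during multiplexed
capture, and index sequencing errors all place foreign indices on
library molecules, so some reads demultiplex to the wrong sample
("index cross-talk"). For sensitive assays — ctDNA, microbial detection,
somatic variants at 0.5–1% allele fraction — this misassignment floor
*is* the limit of detection.

The package is built around a simple analytic model. If a sample's
adapter pool contains a foreign duplexed adapter at fraction *c*, and the
i7- and i5-bearing adapter arms of each fragment are drawn independently
from the pool, then per fragment

- single-index demultiplexing misassigns a fraction *c*;
- unique dual-matched indices (i7 = i5 per well, unshared) misassign only
  *c*² — both arms must be foreign — while 2*c*(1 − *c*) of reads carry
  mismatched index pairs and are filtered out.

At *c* = 1% that is 1% misassignment versus 0.01%, the two-order-of-
magnitude advantage of unique dual-matched adapters. Around this core the
package provides:

- a seeded read simulator (`simulate_experiment()`) with adapter
  contamination at the oligo or duplex stage, index hopping, index
  sequencing error, UMI-tagged PCR duplication, low-AF spike-in variants
  and strand-asymmetric 8-oxoguanine damage, plus a complete per-read
  truth table and four-file FASTQ output;
- demultiplexing (`assign_reads()`, `build_crosstalk_matrix()`) for
  combinatorial and unique dual-matched schemes, perfect-match or
  one-mismatch, over the full used + unused index grid;
- cross-talk statistics: misassignment reports, plate row/column
  decomposition, baseline-corrected index-hopping estimates, and a
  matrix-symmetry diagnostic that separates single-stranded-oligo from
  duplexed-adapter contamination;
- UMI adjacency grouping, molecular consensus calling and filtering
  (`group_reads_by_umi()`, `consensus_from_families()`,
  `filter_consensus()`), a pileup variant caller with a 0.2% threshold
  and a 0.3% C>A/G>T (oxoG) threshold, and sensitivity/PPV evaluation
  against simulation truth (`compare_consensus_raw()`).

## Worked example

Four libraries on a 35-index unique dual-matched plate; library A1's
adapter pool is contaminated with 1% of the A2 adapter (duplex stage) and
the capture pool hops indices at 0.2% per read per index:

```r
library(crosstalksim)

set.seed(42)
plate <- make_unique_dual_plate(design_index_set(35))
sheet <- sample_sheet(paste0("lib", 1:4), c("A1", "A2", "A3", "A4"), plate)
cfg <- sim_config(
  n_fragments   = 250000,
  contamination = contamination_spec("A1", "A2", 0.01),
  hop_rate      = 0.002,
  seed          = 7)
sim <- simulate_experiment(plate, sheet, cfg)

pol <- demux_policy(plate$wells$i7, plate$wells$i5, 0, "unique_dual")
mat <- build_crosstalk_matrix(sim$reads, pol, used_wells = sheet$well,
                              plate = plate)
mat
#> <crosstalk_matrix> 35 x 35 combinations, 1000000 reads, scheme=unique_dual
misassignment_report(mat, plate)
#> <crosstalk_report> 8923 / 1000000 reads misassigned (0.8923%)
mismatched_pair_rate(mat)
#> [1] 0.008923
symmetry_diagnostic(mat)$verdict
#> [1] "symmetric"
expected_misassignment(0.01, "dual_matched")
#> misassigned    filtered
#>      0.0001      0.0198
```

Every misassigned read lands in a mismatched-index cell of the 35 × 35
grid, so it is *filtered*, not silently assigned to the wrong sample:
the 0.89% mismatched-pair rate is the sum of the contamination
(≈ 2 × 1% × ¼ of reads) and hopping (≈ 2 × 0.2%) backgrounds, and the
symmetric off-diagonal pattern identifies duplex-stage contamination.
Under single-index demultiplexing those contaminated reads would have
been misassigned outright.

## Acceptance script

`scripts/acceptance.R` recomputes the two analytic-model figures from
scratch with the installed package: it simulates the 1%-contamination
scenario on a combinatorial plate (10⁶ fragments, i7-only perfect-match
demultiplexing) and on a unique dual-matched plate (10⁷ fragments,
both-index demultiplexing), and reports the percentage of reads
misassigned to the contaminating sample in each case:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
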