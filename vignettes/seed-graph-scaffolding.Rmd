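---
title: "Seed-graph scaffolding of uncorrected long reads: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-graph scaffolding of uncorrected long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tulip)
```

## The model

Long single-molecule reads carry enough information to order a genome, but
their error rate (11–25% for the nanopore chemistries this package targets)
makes direct overlap assembly expensive. `tulip` replaces the all-versus-all
overlap with alignment to a *sparse reference*: a set of short seeds, each
unique in the genome, spaced on the order of one per kilobase. The central
object is the **seed graph**:

* **nodes** are oriented seeds — every seed appears as `(id, +)` and
  `(id, -)`, because a read can traverse a seed in either direction;
* **links** record that two seeds co-align *adjacently* to the same read. A
  link carries all observed signed gaps (read-projected distance between the
  two seed alignments; negative when the seeds overlap) and the list of
  supporting reads. Evidence = number of supporting reads.

The graph is bidirected: a link `(A,o1) -> (B,o2)` is stored together with its
reverse-complement mirror `(B,!o2) -> (A,!o1)`, with identical gap
observations. This *mirror invariant* is asserted throughout and makes
scaffold extraction a plain directed walk.

Sparse geometry follows from seed length $s$, genome size $G$ and seed count
$n$. A read can link two seeds only if it spans both: the minimum useful read
length is $\lceil 2s - f s\rceil$ at tolerated overlap fraction $f$, and the
typical linking length is $\mathrm{round}(G/n + s)$. For the default
$s = 285$, $f = 0.1$ these are 542 bp and, at one seed per ~985 bp, 1270 bp —
`seedStats()` computes them.

### Seed selection

Seeds come from merged short-read pairs: exact-match terminal overlap merging
(minimum 15 nt), canonical 25-mer counting over the merged fragments, removal
of every fragment containing a 25-mer occurring *more than* 25 times (the
boundary is strict: a count of exactly 25 is tolerated), then selection of an
exact fragment length (270 or 285 nt). An abundance cap $c$ at read coverage
$v$ tolerates genomic copy number $c / \mathrm{round}(v)$
(`occurrenceCapEstimate()`); the default cap corresponds to ~6×.

Two deliberate differences from common practice are documented here rather
than hidden: merging is exact-match by default (a mismatch-tolerant mode
exists but is off) because exactness keeps the brute-force oracle in the test
suite meaningful; and k-mers are counted canonically (strand-collapsed)
because seeds serve as *bidirected* graph nodes, so uniqueness must hold on
both strands. Fragments containing N are excluded from candidacy and N
windows are skipped in counting.

### Graph simplification

Errors produce three local ambiguity patterns, each with a local remedy:

1. **Missed alignments** (the dominant source): a read that fails to align to
   an intermediate seed B contributes a direct link A→C "spanning" B. If some
   path A→B₁→…→Bₖ→C exists whose total span (sum of path gap means plus
   $k\,s$) matches the direct link's mean gap within tolerance, the direct
   link is removed (reason `spanned`). Sweeps repeat to a fixpoint, bounded
   at 10; each sweep evaluates all links against the sweep-start state and
   removes simultaneously, which makes the operation order-independent.
2. **Repeats**: a node still branching after span resolution is arbitrated by
   evidence — if one link has at least `min_evidence_ratio` (default 3×) the
   evidence of *every* rival, the rivals are removed (`outvoted`); otherwise
   all links on that side are severed (`repeat`). Decisions are taken on the
   entry state and applied together.
3. **Spurious links** (chimeric reads, mis-alignments): these are low-evidence
   by nature and fall to the same two rules.

Removed links are never discarded: they move to an audit table with their
reason, and `neighborhood()` reproduces the local subgraph around any scaffold
or seed with removals flagged — the forensic view used to inspect individual
joins.

After severing, every oriented node has in/out-degree ≤ 1; maximal chains
become scaffolds. Each bidirected chain exists twice (once per direction) and
is emitted once, in canonical orientation: lexicographically smaller terminal
seed id first. Circular components (possible in simulation) are linearized at
their lowest-evidence link, ties broken by canonical link key, so repeated
runs produce byte-identical output.

**Long-range joining.** Scaffold pairs whose ends are co-spanned by at least
`min_join_evidence` (default 2) reads with consistent orientation and implied
gap (all observations within the span tolerance of their median) become join
candidates; a join applies only if neither end participates in a second
surviving candidate. The default of 2 reads reflects the observation that
legitimate joins are typically supported by two or more independent reads
while chimera-induced ones are singletons.

### Sequence layout ("bulb")

Scaffold models carry no sequence; `fillGaps()` adds it. Seeds contribute
their own bases (reverse-complemented per placement orientation). Each
positive gap is patched from a *single* donor read — the one whose observed
gap is closest to the link's mean, ties to the lexicographically smallest
read id — excised between its two seed alignments. A single donor (rather
than a consensus of all supporting reads) keeps the output deterministic and
leaves consensus building to the dedicated polishing stage, which receives
each scaffold's full read bundle. Negative gaps trim the *downstream* seed;
the choice of side is arbitrary but fixed and recorded here. Per-base
provenance (seed or read id for every base) is emitted as BED. No quality
strings are output: uncorrected nanopore-derived bases have no meaningful
per-base quality.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `seed_len` | 285 | nt | seed length; 270 behaves equivalently |
| `max_overlap_frac` | 0.10 | fraction of seed | deepest tolerated seed overlap on a read |
| `min_seed_cov` | 0.8 | fraction | minimum aligned fraction of a seed per hit |
| `min_mapq` | 1 | — | minimum mapping quality per hit |
| `span_tolerance_abs` / `_frac` | 50 bp / 0.2 | — | slack when testing whether a path fits under a spanning link; sized to nanopore indel noise (~10% length error ×2 for two independent alignments) |
| `max_lookahead` | 3 | seeds | longest intermediate path considered, and terminal-region depth for joins |
| `min_evidence_ratio` | 3.0 | — | margin to resolve a branch by evidence instead of severing |
| `min_join_evidence` | 2 | reads | minimum support for a long-range join |

The span tolerance, severing thresholds and join minimum are *not* dictated
by the geometry of the method; they are this package's defaults, chosen once
as stated above and exposed in `simplifyConfig()`. The overlap cap is
likewise configuration: production runs of this class of assembler have used
deeper overlaps (observable as scaffolds shorter than $2s - fs$ would allow),
so no particular minimum scaffold length is claimed beyond what the
configured cap implies.

## The simulator: what it emulates, what it does not

`simulateDataset()` generates (i) an i.i.d. random genome at a target GC with
optional implanted repeat copies; (ii) seeds sampled uniformly from loci whose
every 25-mer is genome-unique, rejecting overlaps, at a mean spacing of
700 bp — the spacing a ~0.3× seed set induces on a ~1 Gbp genome; half the
seeds are stored reverse-complemented to exercise orientation handling;
(iii) reads of log-normal length (default mean 8 kbp, sd 4 kbp) at 15×
coverage, uniform position and strand; (iv) per-base edits at the rate
implied by the chemistry preset.

Presets: R7.3 2D ≈ 75% identity (mismatch:ins:del 40:30:30), R9 1D ≈ 89%,
R9 2D ≈ 94% (35:30:35); R9.4 1D is treated like R9 1D, as its headline
improvement is throughput rather than single-read identity. Identity is
defined as matches over alignment columns, and the per-base edit rate $e$ is
solved from the preset: $\mathrm{id} = (1 - e(r_m + r_d))/(1 + e\,r_i)$, so
the simulated mean identity equals the preset by construction (the naive
$e = 1 - \mathrm{id}$ undershoots because insertions add columns). Deletions
are doubled inside homopolymers of length ≥ 4 by default, a coarse stand-in
for the characteristic homopolymer loss of nanopore data. A configurable
fraction of reads are chimeras (two unrelated fragments joined), and a
`missed_hit_rate` thins the emitted truth alignments to model aligner misses —
the dominant real-world ambiguity source.

Ground truth is emitted as a SAM file with seeds as references, exact M/I/D
CIGARs derived from the introduced edits, and soft clips for flanking read
sequence; it is consumed by the same `readSeedAlignments()` path as real
aligner output. One record is emitted per seed *fully contained* in a read's
genomic footprint; partial overlaps are omitted since they would fail the
default seed-coverage filter anyway.

Everything is deterministic under `rng_seed`, with one derived substream per
stage (genome / seeds / reads), so regenerating any stage reproduces it
byte-for-byte.

**What passing simulations do not show.** The generator is single-haplotype
(no heterozygosity), has no base-composition bias, no position-dependent error
profile, no read-length artifacts (adapter chimeras aside), and its repeat
model is a single implanted unit family. Results on it demonstrate the graph
algebra — span resolution, severing, joining, layout — not robustness to the
full error structure of real flow cells; real data additionally depend on the
external aligner's sensitivity.

## Numerical and degenerate-input conventions

* Printed integer statistics round half away from zero (R's banker's rounding
  is never used for reported values); minimum link length uses ceiling.
* Gap consensus is the arithmetic mean of the observations (median by
  option); scaffold `gap_after` values are rounded half-up.
* Coordinates are 0-based half-open everywhere; gaps may be negative down to
  one full seed overlap.
* Empty inputs: an empty chain set yields an empty graph; an empty graph
  yields empty reports; length selection with no match is an error advising a
  different seed length, and a merged-coverage of zero in the occurrence-cap
  estimate is an error rather than Inf.
* k-mer counting streams fragments in chunks and holds only the aggregated
  table; above a configurable table size, partial tables spill to disk and
  are merged per nucleotide-prefix partition, bounding peak memory.
* N50 is fixed to: the largest length $L$ such that scaffolds ≥ $L$ contain
  at least half the total length (definitions vary in the literature; this
  one is asserted against an exhaustive oracle in the tests).
* Misjoin accounting tolerance defaults to the simplification span tolerance,
  for consistency between what the simplifier accepts and what the evaluator
  flags.

## Problem sizes used in the test suite

The bundled suite exercises the full pipeline at the package's reference
desk scale: a 1 Mbp single-chromosome genome, seeds at one per ~700 bp
(~1430 seeds), 15× coverage of 8 kbp (log-normal) reads — once with perfect
chemistry (expecting exact recovery: one scaffold, true order and
orientation, zero misjoins, layout an exact genome substring) and once at
R9-1D error with 15% missed hits (expecting zero misjoins and ≥95% of seeds
scaffolded). Graph simplification is verified against an exhaustive
path-enumeration oracle on graphs of up to 12 seeds, and N50, k-mer filtering
and misjoin counts against brute-force re-computation.

## Known limitations

* Scaffolds that share no fortuitously placed seed cannot be merged, however
  long the reads; seed density, not read length, bounds contiguity.
* Large repeat regions without genome-unique seed islands are absent from the
  assembly by construction.
* The orientation model assumes seeds are short enough that a read never
  partially overlaps one in a way that flips orientation mid-seed.
* Gap patches come from single uncorrected reads; scaffold base accuracy
  before polishing is that of the raw reads.
* `readSeedAlignments()` keeps one hit per (read, seed); a genuine second
  occurrence of the same seed on one read (possible for extremely long reads
  spanning a tandem duplication of a "unique" seed) is collapsed to the
  better-scoring hit.
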