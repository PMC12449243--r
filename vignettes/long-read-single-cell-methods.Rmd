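---
title: "Methods: barcode demultiplexing and UMI deduplication for long-read single-cell RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: barcode demultiplexing and UMI deduplication for long-read single-cell RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontcells)
```

## The problem

Droplet single-cell RNA-seq reads sequenced on Oxford Nanopore devices carry
their cell barcode (16 nt) and UMI (10–12 nt) inside a noisy long read:
`adapter – barcode – UMI – poly-T – cDNA`, in either orientation. ONT error
rates (especially indels) make naive exact matching of barcodes hopeless, so
the secondary analysis must (i) find the read structure despite errors,
(ii) decide which barcodes correspond to real cells, (iii) assign each noisy
barcode to a cell probabilistically, and (iv) collapse PCR duplicates of the
same molecule via UMIs before counting. `ontcells` implements these stages
as composable functions plus a simulator that makes every stage verifiable
at desk scale.

## Structure parsing

`locate_structure()` searches for the adapter within a `search_window`
(default 100 nt) at the start of the read and of its reverse complement,
using **semi-global edit distance** (substitutions and indels, adapter
aligned in full, window ends free). Hamming matching would be brittle under
ONT indels, which shift every downstream position. The implementation
advances a small Needleman–Wunsch band column-wise across all reads at once,
so cost is proportional to `window × adapter` regardless of read count. The
best hit is the lowest distance, ties broken by the most 5′ end, and the
lower-distance strand wins (ties go to `+`). The default distance cap is 3
for the 22 nt 10X read-1 primer.

Barcode and UMI spans are laid out immediately behind the adapter. A poly-T
run directly after the UMI is accepted with at most one non-T per ten bases
(and never three consecutive non-T); it must reach `polyt_min_run`
(default 10) and end on a T. A missing poly-T is recorded but — because the
upstream behaviour is unspecified and 5′ chemistry has none — does **not**
reject the read; reads lacking poly-T are kept by default. All internal
coordinates are 0-based half-open; Phred+33 throughout, with N bases treated
as quality 0 downstream.

## Whitelist construction

Putative barcodes are counted over reads whose minimum barcode base quality
is at least 15 (low-quality observations are overwhelmingly miscalls and
would otherwise seed spurious whitelist entries), then ranked by abundance,
ties to the lexicographically smaller barcode for determinism.

With `expected_cells = N`, the abundance threshold is the count at rank
`ceiling(0.05 N)` divided by 20, keeping barcodes strictly above it — the
quantile convention used by droplet cell callers. Without it, the knee of
the log₁₀-rank / log₁₀-count curve is found as the point furthest below the
chord joining the curve's endpoints (a kneedle-style criterion; simple,
deterministic, and adequate for the sharp cliff that separates cells from
error barcodes).

## Posterior barcode correction

The acceptance rule is: a barcode is corrected when a whitelist candidate
within Hamming distance ≤ 2 reaches posterior probability ≥ 97.5%. The rule
fixes the thresholds but not the probability model, so the posterior model
is this package's design: for candidate $c$ with the observed barcode $o$ and per-base
error probabilities $p_i = 10^{-Q_i/10}$,

$$\mathcal{L}(o \mid c) = \prod_i \begin{cases} 1-p_i & o_i = c_i \\ p_i/3 & o_i \ne c_i\end{cases},
\qquad \pi(c) \propto n_c + \alpha,$$

with whitelist abundance $n_c$ (raw counts, not ranks) and pseudocount
$\alpha = 1$ to avoid zero priors; posteriors are normalised over the
Hamming ≤ 2 candidate set only. This mirrors the quality-aware correction of
the short-read droplet lineage. Computation is in log space; ties on the
posterior go to the lexicographically smaller candidate. Statuses:
`exact` (observed barcode itself is in the whitelist and reaches the
threshold), `corrected`, `ambiguous` (candidates exist but none reaches the
threshold), `no_candidate`. Candidate search is a vectorised scan of the
whitelist, contractually equal to an exhaustive linear scan; no UMI sequence
correction is attempted.

## Tagging and deduplication

`tag_bam()` joins correction results onto alignments by read id, writing
`CR`/`CY` (raw barcode + qualities), `UR`/`UY` (UMI + qualities) and `CB`
(corrected barcode, only for `exact`/`corrected` rows). Secondary and
supplementary alignments inherit the primary's tags; unmapped reads are
retained and tagged for QC. Dropping CB-less reads is an explicit flag,
default off. For parallel deduplication, genome alignments split by
chromosome and transcriptome alignments by the chromosome of their
transcript (derived from the GTF, never from FASTA headers).

Deduplication groups CB-bearing primary alignments by cell and locus:
genome mode keys on (CB, contig, strand, soft-clip-adjusted 5′ position) —
start minus leading clip on `+`, end plus trailing clip on `-` — because ONT
indels shift raw positions; transcriptome mode keys on (CB, transcript),
positions ignored. Within a group, UMIs are clustered with the
**directional** network rule: a directed edge $a \to b$ exists when
$\mathrm{hamming}(a,b) \le 1$ and $\mathrm{count}(a) \ge 2\,\mathrm{count}(b) - 1$;
nodes are visited in count-descending (then lexicographic) order and each
unclaimed node seeds a cluster of everything reachable through unclaimed
nodes. `method = "unique"` (each distinct UMI its own molecule) stands in
for MarkDuplicates-like behaviour. One representative alignment survives per
cluster: highest MAPQ, then longest aligned reference span, then smallest
read id — an invented but deterministic rule. Because keys never cross
chromosomes, deduplicating split parts and concatenating equals
deduplicating the whole file.

## Quantification and QC

The in-repo quantifier is deliberately simple so the pipeline is testable
end-to-end: model-based long-read quantifiers are out of scope and not
reproduced. Gene-level counting assigns each deduplicated record to the gene
whose exon union covers ≥ 50% of its aligned reference bases (CIGAR
M/D/=/X; introns excluded; strand ignored because ONT read strand is
ambiguous). Reads meeting the bar for two genes are `ambiguous` and dropped
rather than fractionally assigned — conservative and deterministic.
Transcript-level counting tallies primary records per (CB, reference name).
Matrices are written features × barcodes in MatrixMarket coordinate format
with `barcodes.tsv.gz`/`features.tsv.gz`, the prevailing single-cell triplet
convention, and round-trip exactly.

QC tracks a seven-stage funnel (`raw, trimmed, structured, aligned,
primary_mapped, cb_tagged, deduplicated`) into a one-row-per-sample CSV; the
exact stage list upstream tools track is unpublished, so this is a
documented superset. The funnel invariant `structured ≥ cb_tagged ≥
deduplicated` is asserted on every pipeline run. Per-cell metrics use
`stats::median` (the even-count lower-median variant adds nothing —
`median` is already deterministic — and disagrees with the natural reading
of mean/median on two cells with counts 10 and 20 both being 15).

## The simulator: a stated world

`simulate_reads()` emulates the input the pipeline is built for: 50 cells ×
40 reads by default, 16 nt barcodes sampled at pairwise Hamming ≥ 4, 12 nt
UMIs distinct within a cell, poly-T runs of 12–20 nt, fragments of 200–450 nt
from a toy two-contig reference (8 genes × 2 isoforms, both strands), half
of the reads emitted reverse-complemented. PCR duplication is modelled by a
per-cell molecule pool of `reads_per_cell × (1 − dup_rate)` molecules
(default `dup_rate` 0.2 — a modest duplication level typical of long-read
single-cell libraries) sampled with replacement; the truth matrix counts
distinct (cell, UMI, gene) molecules among emitted reads.

Errors are independent per-base substitutions/insertions/deletions — no
homopolymer bias, no ambient RNA, no doublets — which suffices to exercise
the Hamming and posterior machinery but does not establish performance on
real ONT error structure. Substituted and inserted bases receive low
basecall qualities (Q 3–12) and correct bases Q 20–40, reflecting the
quality/error correlation real basecallers exhibit; the whitelist quality
gate and the posterior model both depend on this signal existing, and a
green test shows they use it correctly, not that real basecallers provide it
perfectly. `simulate_alignments()` emits one perfect-placement primary per
read (spliced, with `N` gaps, on the mRNA strand of the gene); length
changes from indels are absorbed by soft-clipping at the transcript-3′ end
so the 5′ dedup key stays stable across duplicates. All randomness derives
from a single integer seed and outputs are byte-identical across runs.

## Numerical and degenerate-input choices

* Posterior computation in log space; an all-zero likelihood mass (possible
  with quality-0 bases) degrades to an `ambiguous` result, never `NaN`.
* Empty inputs (FASTQ, tables, matrices) produce empty, schema-valid
  outputs with zeroed statistics, not errors.
* Whitelist/candidate ties and UMI cluster ties always break
  lexicographically; dedup output preserves input (coordinate) order.
* `expected_cells` larger than the number of ranked barcodes is an error;
  an absent poly-T, an unmapped read, or a transcript missing from the GTF
  map are recorded/bucketed, not fatal (strict modes exist where the
  contract requires them).

## Known limitations

* The quantifier is an overlap counter; isoform-aware assignment and EM
  reassignment of multi-gene reads are explicitly not attempted.
* Barcode correction assumes substitution-dominated errors inside the
  barcode; a barcode containing an indel shifts the observed 16-mer and is
  usually lost (`no_candidate`) rather than rescued.
* The knee finder assumes a single cliff; bimodal rank curves (e.g. heavy
  ambient background) would need the `expected_cells` route.
* End-to-end guarantees are demonstrated on simulated data; real-data
  performance depends on basecaller quality calibration.
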