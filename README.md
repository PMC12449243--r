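# ontcells

Secondary analysis of Oxford Nanopore (ONT) single-cell / single-nuclei
RNA-seq in R: cell-barcode and UMI extraction from noisy long reads,
probabilistic barcode correction against an abundance-ranked whitelist,
SAM/BAM tagging, per-cell UMI deduplication, barcode×feature count matrices,
and multi-stage QC tracking — plus a deterministic read simulator so the
whole pipeline can be exercised and verified without sequencers, aligners or
downloads.

It is aimed at people building or validating long-read single-cell
workflows: every stage is an ordinary R function with a documented contract,
and the simulator provides ground truth for all of them.

## The method in brief

ONT reads carry the droplet structure `adapter – barcode(16) – UMI(10–12) –
poly-T – cDNA` in either orientation, corrupted by substitutions and indels.
`ontcells`:

1. **finds the structure** by semi-global edit-distance adapter search on
   both strands (lowest distance, then most 5′), emitting a barcode-free
   FASTQ and a barcode/UMI/quality table;
2. **calls cells** by ranking high-quality barcodes (min base quality ≥ 15)
   by abundance and thresholding at the expected-cells quantile rule or the
   knee of the log-log rank/abundance curve;
3. **corrects barcodes** over the Hamming-≤2 whitelist neighbourhood with a
   Bayesian score — likelihood `∏ᵢ (1−pᵢ)` over matches and `pᵢ/3` over
   mismatches with `pᵢ = 10^(−Qᵢ/10)`, prior ∝ abundance + 1 — accepting a
   candidate when its normalised posterior is ≥ 97.5%;
4. **tags alignments** with the standard `CR`/`CB`/`UR`/`CY`/`UY` tags and
   splits files by chromosome (or transcript chromosome) for parallel work;
5. **deduplicates UMIs** per (cell, locus) with the directional network
   rule (edge `a→b` iff `hamming ≤ 1` and `count(a) ≥ 2·count(b) − 1`),
   keeping one representative alignment per molecule;
6. **counts** molecules per cell at gene level (≥ 50% exonic-overlap
   assignment) or transcript level, written in MatrixMarket triplet layout
   with `barcodes.tsv.gz`/`features.tsv.gz`;
7. **tracks** the read funnel (`raw → … → deduplicated`) into a summary CSV
   and computes per-cell metrics (nCount/nFeature, mean reads per cell).

See `vignettes/long-read-single-cell-methods.Rmd` for the model details and
the design decisions behind them.

## Worked example

Simulate 20 cells × 30 reads at a 2% substitution rate, align them
perfectly, and run the pipeline:

```r
library(ontcells)

ref <- make_toy_reference(n_genes = 8, isoforms_per_gene = 2, seed = 7,
                          out_dir = "demo_ref")
sim <- simulate_reads(sim_params(n_cells = 20, reads_per_cell = 30,
                                 sub_rate = 0.02, seed = 7), ref)
sim
#> <ont_sim> 600 reads from 20 cells (347 molecules); sub/ins/del = 0.02/0/0

write_fastq(sim$reads, "reads.fastq")
sam <- simulate_alignments(sim, "genome")

res <- run_pipeline("reads.fastq", sam, annotation = ref$paths$gtf,
                    mode = "genome", expected_cells = 20, out_dir = "demo_out")
unlist(res$corrected$stats)
#>       n_rows        exact    corrected    ambiguous no_candidate
#>          599          430          156            0           13

res$matrix
#> <count_matrix> 8 features x 20 barcodes, 139 non-zero, total mass 366
res$metrics
#> <cell_metrics> 20 cells; mean reads/cell 18.30; median nCount 18; median nFeature 7
```

599 of 600 reads had a recognisable structure; 430 barcodes were already
whitelist barcodes (`exact`), 156 noisy ones were corrected to a whitelist
barcode at posterior ≥ 97.5%, and 13 (≥3 errors in the barcode) had no
Hamming-≤2 candidate. Deduplication collapsed 600 reads to 366 molecules,
and the gene-level matrix holds one count per (cell, UMI, gene) molecule.
Individual stages are equally usable on their own:

```r
correct_barcode(res$whitelist$barcode[1], strrep("?", 16), res$whitelist)
#> <correction_result exact> ATGCCAGGACTGTTAC -> ATGCCAGGACTGTTAC (posterior 1, 1 candidate)
```

A thin CLI over the same functions lives in `exec/ontcells`
(`simulate`, `extract`, `whitelist`, `correct`, `tag`, `split`, `dedup`,
`count`, `qc`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

rebuilds the toy reference, simulates the default 50 cells × 40 reads world
at 0% and at 2% substitution error under the given seed, runs the complete
pipeline on both (extraction → whitelist → correction → tagging →
deduplication → counting → QC), and logs per-run recovery statistics before
writing the JSON report.
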