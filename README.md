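# arcseq

Single-cell experiments that stain cells with **Antibody RNA-barcode
Conjugates (ARCs)** read out protein epitopes and the transcriptome from the
same sequencing library: read 1 carries either a transcript fragment or an
ARC sequence, read 2 carries the cell barcode and UMI. `arcseq` is an R
toolkit for such plate-based (CEL-Seq2-style) libraries. It is written for
computational biologists who want to quantify these libraries into matched
per-cell mRNA and antibody count tables and run the downstream multimodal
analysis — and for method developers who need a fully simulated library with
known ground truth to validate every stage against.

## The read model

An ARC read 1 (63 nt) is laid out as

```
[stagger, 1-8 nt][UMI, 15 nt][antibody barcode, 10 nt][anchor ATCAGTCAACAG][filler]
```

so the 12-nt identification anchor can only start at (0-based) positions
26–33. A read is classified as ARC when the anchor matches at one of these
positions with at most one substitution; the 10-nt barcode and 15-nt UMI are
then read off immediately upstream (the barcode + anchor together form the
22-nt identification span). Non-ARC reads are assigned to transcripts by a
unanimous unique-k-mer vote (k = 21) on the first 50 nt. Read 2 (14 nt,
6-nt UMI + 8-nt cell barcode) assigns the cell by exact whitelist match,
rejecting reads with any barcode/UMI base below Q10. Counts are
UMI-collapsed: each (cell, feature, UMI) triple contributes at most one
count, with the ARC tally keyed on the 15-nt ARC UMI.

Depth normalization draws exactly `d` UMIs per cell without replacement
(multivariate hypergeometric) and discards cells below `d`, with the
experiment presets `d_mRNA` ∈ {10000, 40000, 4500} and `d_ARC` ∈ {2750, 400}
(`depth_presets()`). The analysis layer provides `ln(1 + n·10⁴/N)`
normalization, binned-dispersion variable-gene selection, PCA/t-SNE on
components 1–8, antibody count ratios, 5%/95% display winsorization,
per-cell gene-signature scores (summed subsampled UMI counts), extreme-cell
selection (top/bottom *n* = 50 by one antibody), 10-cell × 1000 group
resampling, and Welch-t differential expression gated at |logFC| ≥ 0.25.

## Worked example

```r
library(arcseq)

# 1. Simulate a small library with known ground truth
cfg <- sim_config(n_cells_per_group = 60, n_genes = 300, n_stem_genes = 90,
                  n_diff_genes = 60, mean_mrna_molecules = 1500,
                  mean_arc_molecules = 600)
panel  <- example_panel()
truth  <- simulate_ground_truth(cfg, panel, seed = 1)
cells  <- make_cell_index(truth$cells$cell_name, seed = 2)
ref    <- simulate_reference(rownames(truth$gene_counts), seed = 3)
fq     <- write_fastq_pair(truth, arc_layout(), panel, cells, ref,
                           dir = tempfile("sim"), seed = 4)

# 2. Quantify reads into matched count tables
q <- tally_counts(fq$r1, fq$r2, arc_layout(), panel, cells,
                  build_transcript_index(ref))
print(q)
#> arc_quantification: 281065 read pairs
#>   quality-fail 0 | unassigned cell 2244 | ARC 62162 | mRNA 216017 | neither 642
#>   UMIs after collapse: 62162 ARC, 216000 mRNA

# 3. Depth-normalize both modalities by subsampling
ds <- normalize_dataset(q$mrna, q$arc, mrna_depth = 1000, arc_depth = 300,
                        seed = 5)
print(ds)
#> multimodal_dataset: 113 cells retained (7 discarded)
#>   mRNA depth 1000 | ARC depth 300

# 4. Signature scores and pFAK extremes in the treated group
grp  <- setNames(truth$cells$group, truth$cells$cell_name)[ds$cells]
stem <- signature_score(ds$mrna, truth$signatures$stem)
ex   <- select_extremes(ds$arc, "pFAK", ds$cells[grp == "treated"], n = 10)
res  <- two_sample_tests(stem[ex$high], stem[ex$low])
cat(sprintf("stem score, pFAK-high vs pFAK-low: %.1f vs %.1f (t p = %.2g)\n",
            mean(stem[ex$high]), mean(stem[ex$low]), res$t_p))
#> stem score, pFAK-high vs pFAK-low: 158.5 vs 55.8 (t p = 1.2e-10)
```

Reading the output: at a simulated 0.1% substitution error rate, ~0.8% of
pairs lose their cell barcode and a handful of reads land in no category;
UMI collapse removes the simulator's rare read-2 UMI collisions (216017 →
216000). After joint depth filtering, every retained cell holds exactly
1000 mRNA and 300 ARC UMIs. The treated cells that retain high pFAK signal
also retain markedly more stem-signature transcripts than the pFAK-low
cells — the planted association the simulator encodes.

A thin CLI over the same functions lives at
`system.file("cli/arcseq.R", package = "arcseq")` with `simulate`,
`quantify` and `normalize` subcommands.

## Acceptance script

`scripts/acceptance.R` recomputes, from scratch against the installed
package, the per-cell totals produced by the intracellular experiment's
depth normalization (ARC depth applied to a synthetic 1,000-UMI cell, mRNA
depth applied to a synthetic 10,000-UMI cell) and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
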