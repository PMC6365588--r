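---
title: "Models and methods behind arcseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind arcseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(arcseq)
```

# The measurement model

`arcseq` handles plate-based single-cell libraries in which antibodies are
covalently coupled to barcoded, polyadenylated RNAs (antibody RNA-barcode
conjugates, ARCs). Because the ARC RNA enters the same reverse-transcription
and amplification path as cellular mRNA, one sequencing library reports both
modalities, and the computational task is to split it back apart without
mixing them up.

Read 1 (63 nt) holds either a transcript fragment or the ARC cassette:

* a stagger of 1–8 nt (cluster-diversity spacer),
* a 15-nt ARC UMI,
* a 10-nt antibody-specific barcode,
* the fixed 12-nt identification anchor `ATCAGTCAACAG`,
* template filler.

Read 2 (14 nt) holds a 6-nt UMI followed by an 8-nt cell barcode (both the
order and the lengths are configurable in `cell_barcode_index()`; the
library design only fixes the 14-nt total).

Because the stagger is the only variable-length element upstream of the
anchor, the anchor start is confined to 0-based positions
`stagger + 15 + 10` = 26..33. `detect_arc()` scans exactly this window
rather than the whole read: a transcript read of 63 random-ish nucleotides
has roughly a `3.7e-4` chance per read of containing a spurious ≤1-mismatch
anchor *somewhere*, and restricting the scan to 8 positions cuts that by an
order of magnitude; the subsequent exact barcode match against the panel
removes essentially all remainder. A full-read scan can be emulated by
widening the stagger bounds.

## Decisions where the design was open

* **Tie-breaking.** When several window positions qualify, the smallest
  anchor position wins, even if a later position would match with fewer
  mismatches. This is deterministic, order-independent and cheap; with a
  correct library the true position is the only one that also yields a
  panel barcode.
* **Antibody barcode matching** is exact by default. Hamming-tolerant
  matching (`barcode_mismatches = m`) is allowed only when the panel's
  minimum pairwise Hamming distance is at least `2m + 1`
  (`validate_panel()`), the condition under which an `m`-mismatch match is
  provably unambiguous.
* **UMI collapse** is exact-identity: each (cell, feature, UMI) triple
  counts once. No directional network correction is applied, because the
  quantification this package mirrors describes plain UMI counting. ARC
  counting is keyed on the 15-nt ARC UMI and deliberately ignores the
  read-2 UMI: the ARC UMI identifies the conjugate molecule itself.
* **Transcript assignment.** The original pipeline aligned reads with a
  genome aligner. To keep the package self-contained and deterministic,
  reads are instead assigned by a unanimous vote over gene-unique 21-mers
  in the first 50 nt (`cut_length`, the published truncation setting) of
  read 1. K-mers shared between genes are dropped at index time; reads
  whose k-mers vote for two genes are discarded. On realistic transcript
  references this is slightly more conservative than an aligner (chimeras
  and shared exons are unassigned rather than resolved), which biases
  against false counts.
* **Quality gate.** `min_bc_quality = 10` is applied to every base of the
  read-2 barcode *and* UMI. The published setting's exact scope is not
  stated; covering the UMI too is the conservative choice, since a
  low-quality UMI base fabricates molecules.
* **Read-name swap.** Some upstream pipelines swap read names for
  compatibility; `tally_counts(swap_reads = TRUE)` accepts such files
  instead of replicating the hack.

# Depth normalization

`subsample_cell()` draws exactly `depth` molecules uniformly **without
replacement** from a cell's UMI pool — the multivariate hypergeometric
distribution — and discards cells under the depth. Sampling without
replacement is implied by drawing from a finite pool of distinct molecules
and guarantees the subsampled count never exceeds the raw count. The
experiment presets (`depth_presets()`) are 10000/2750 (surface experiment),
40000 (mRNA-only comparison) and 4500/400 (intracellular experiment); in
multimodal mode a cell must reach both depths or it is dropped from both
tables. Each cell gets an RNG substream derived from the global seed and
the cell's name, so results are invariant to cell order and to subsetting.

# The analysis layer

* `log_normalize()`: `ln(1 + n · scale / N)` with `scale = 10^4`. Post
  subsampling all `N` are equal, so this is a monotone per-gene transform.
* `select_variable_genes()`: genes are binned (20 equal-width bins) by mean
  of `expm1(lognorm)`; the dispersion (variance/mean) is z-scored within
  each bin; genes with z ≥ 1 and mean in [0.1, 8] are kept. The mean bounds
  are calibrated to ~4500-UMI cells at scale 10^4; at other depths pass a
  proportionally chosen `scale`. Bins with fewer than two genes get z = 0 —
  with a realistically sized gene universe every bin is well populated.
* `embed_cells()`: PCA on centered/scaled variable genes, t-SNE on
  components 1–8 under a fixed seed. Perplexity defaults to 30 and is
  lowered automatically to `(n_cells - 2) / 3` when needed; seed,
  perplexity and components are recorded in the output's `params`
  attribute.
* `clip_for_display()` winsorizes at the 5th/95th percentiles using
  inverse-CDF (type-1) quantiles, under which clipping is exactly
  idempotent (interpolating quantile types are not).
* `signature_score()` sums **subsampled raw counts** — not log values —
  over the signature genes, because equal per-cell totals already make raw
  sums comparable and the score is defined as aggregated UMI counts.
* `select_extremes()` picks the top/bottom `n = 50` cells by one
  antibody's counts from a single global ordering (count, then cell name),
  making the two sets deterministic and always disjoint for groups ≥ 2n.
* `resample_group_sums()` draws `reps = 1000` groups of `group_size = 10`
  cells without replacement within a draw and returns the per-draw sum of
  one gene's counts.
* `differential_expression()` gates genes at |logFC| ≥ 0.25, where the
  fold-change is the single-cell convention
  `ln(mean(expm1 x) + 1)` difference (configurable to log2), then applies a
  two-sided Welch t-test with Bonferroni adjustment over the tested genes.
  A restricted-universe unadjusted mode (`universe = <signature>`,
  `adjust = "none"`) mirrors screening a curated gene set at nominal
  α = 0.05. Degenerate zero-variance genes resolve to p = 1 (equal means)
  or p = 0 (unequal constants).
* `two_sample_tests()` wraps the two-sample Kolmogorov–Smirnov and Welch
  t-tests; `qc_gene_stats()` reports detection rate, mean and CV per gene.

# The simulator's stated world

`sim_config()` encodes one fixed scenario, chosen once:

| parameter | default | rationale |
|---|---|---|
| cells per group | 250 | scale of the intracellular experiment; the 50+50 extreme-cell analysis needs >100 treated cells to survive depth filtering |
| genes | 1000, of which 530 stem / 226 differentiation | signature sizes of the curated gene sets |
| counts | negative binomial; mRNA size 2, ARC size 4 | standard overdispersed scRNA-seq model; antibody counts are less bursty |
| per-cell molecules | 6000 mRNA / 800 ARC | comfortably above the 4500/400 depths so filtering removes a minority |
| treated effects | stem ×0.25, differentiation ×4, pRPS6 ×0.3, EGFR ×0.5 | strong, unambiguous differentiation response |
| pFAK mixture | 30% "retainers" keep baseline pFAK and ×0.7 stem levels; 70% "losers" drop to ×0.2 pFAK, ×0.25 stem | bimodal treated pFAK distribution with a stem-retention association |
| integrin-substrate markers | 4 stem genes at 4× mean abundance, fully retained in retainers | laminin/collagen transcripts are abundant; keeps the planted signal above the detection floor |
| substitution errors | 0.1% per base | typical Illumina error rate |
| stagger assignment | cycles 1..8 over the panel | one stagger per template, rule unspecified upstream |

Read-2 UMIs are drawn unique within each (cell, gene) by default, making the
error-free channel exactly lossless; set `unique_read2_umis = FALSE` to
study UMI collisions (6-nt UMIs collide noticeably at realistic depths).
ARC UMIs (15 nt) are drawn unique within (cell, antibody); their natural
collision probability is negligible.

**What the simulator does not emulate:** PCR amplification bias and
duplicate structure beyond UMI identity, indels, quality-score variation
(qualities are flat Q30 except deliberately planted Q9 bases), ambient
RNA, doublets, batch effects, and real transcript sequence composition
(references are uniform random, so k-mer ambiguity is rarer than in a real
transcriptome). A green end-to-end test therefore establishes the
correctness of the bookkeeping — classification, deduplication,
subsampling, scoring — not robustness to artifacts the simulator leaves
out.

# Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally where reads are sliced;
  user-facing anchor positions are reported 0-based to match the window
  definition [26, 33].
* `subsample_cell` returns the input unchanged when the total equals the
  depth (no RNG consumed), and `NULL` (discard) below it.
* Zero-total cells make `log_normalize` fail loudly rather than emit NaN.
* Welch's test falls back to p = 1 / p = 0 on zero pooled variance, as
  above; `two_sample_tests` omits the t-test (flagged) when either sample
  has fewer than 2 values or both are constant.
* `detect_arc` requires reads long enough to scan the full window; shorter
  reads are a structural error, not a no-hit.
* Seeds are 32-bit; per-cell substreams hash the cell name modulo 2^31−1.

# Known limitations

The k-mer assigner is not splice-aware and discards multi-gene evidence, so
its unassigned fraction on a real transcriptome will exceed an aligner's.
Cell identification is whitelist-only (sorted plates); no knee-point
calling for droplet data. No ambient-RNA or batch correction is provided.
t-SNE coordinates are reproducible only under a fixed seed and the same
Rtsne version.
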