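# Shared fixtures and independent brute-force oracles.

tiny_panel <- function() {
  antibody_panel(
    c("pFAK", "pRPS6", "EGFR", "ITGA6", "ITGB1", "KRT14"),
    c("AACCGGTTAA", "TTGGCCAATT", "ACACACACAC", "GTGTGTGTGT",
      "AAGGTTCCAA", "TTCCAAGGTT")
  )
}

small_sim <- function(seed = 1, dir = NULL, ...) {
  cfg <- sim_config(n_cells_per_group = 10, n_genes = 40, n_stem_genes = 12,
                    n_diff_genes = 8, mean_mrna_molecules = 120,
                    mean_arc_molecules = 60, error_rate = 0, ...)
  panel <- example_panel()
  truth <- simulate_ground_truth(cfg, panel, seed = seed)
  layout <- arc_layout()
  cells <- make_cell_index(truth$cells$cell_name, seed = seed + 1)
  ref <- simulate_reference(rownames(truth$gene_counts), seed = seed + 2)
  out <- list(truth = truth, panel = panel, layout = layout, cells = cells,
              ref = ref, index = build_transcript_index(ref))
  if (!is.null(dir)) {
    out$fastq <- write_fastq_pair(truth, layout, panel, cells, ref,
                                  dir = dir, seed = seed + 3)
  }
  out
}

# --- independent oracles (per-read loops, dictionary tallies) --------------

oracle_read_fastq <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  list(seq = lines[seq(2, length(lines), 4)],
       qual = lines[seq(4, length(lines), 4)])
}

oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Naive re-implementation of the full quantification: scans every anchor
# position in the stagger window per read, exact dictionary tallies.
oracle_tally <- function(r1, r2, layout, panel, cell_index, tindex,
                         min_bc_quality = 10, cut_length = 50) {
  f1 <- oracle_read_fastq(r1)
  f2 <- oracle_read_fastq(r2)
  cells <- cell_index$cell_name
  arc_m <- matrix(0L, nrow(panel), length(cells),
                  dimnames = list(panel$antibody_name, cells))
  mrna_m <- matrix(0L, length(tindex$genes), length(cells),
                   dimnames = list(tindex$genes, cells))
  seen <- new.env(hash = TRUE)
  win0 <- (layout$stagger_min:layout$stagger_max) +
    layout$umi_len + layout$ab_barcode_len
  ulen <- cell_index$read2_umi_len
  for (i in seq_along(f1$seq)) {
    q <- utf8ToInt(f2$qual[i]) - 33L
    region <- seq_len(cell_index$cb_len + ulen)
    if (min(q[region]) < min_bc_quality) next
    if (cell_index$read2_order == "umi_first") {
      umi2 <- substr(f2$seq[i], 1, ulen)
      bc <- substr(f2$seq[i], ulen + 1, ulen + cell_index$cb_len)
    } else {
      bc <- substr(f2$seq[i], 1, cell_index$cb_len)
      umi2 <- substr(f2$seq[i], cell_index$cb_len + 1,
                     cell_index$cb_len + ulen)
    }
    ci <- which(cell_index$barcode == bc)
    if (length(ci) != 1) next
    cell <- cells[ci]

    hit_pos <- NA
    for (p0 in win0) {
      mm <- oracle_hamming(substr(f1$seq[i], p0 + 1, p0 + nchar(layout$anchor)),
                           layout$anchor)
      if (mm <= layout$max_anchor_mismatches) { hit_pos <- p0; break }
    }
    counted <- FALSE
    if (!is.na(hit_pos)) {
      p1 <- hit_pos + 1
      abbc <- substr(f1$seq[i], p1 - layout$ab_barcode_len, p1 - 1)
      ai <- which(panel$barcode == abbc)
      if (length(ai) == 1) {
        aumi <- substr(f1$seq[i], p1 - layout$ab_barcode_len - layout$umi_len,
                       p1 - layout$ab_barcode_len - 1)
        key <- paste("A", cell, panel$antibody_name[ai], aumi)
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          arc_m[ai, ci] <- arc_m[ai, ci] + 1L
        }
        counted <- TRUE
      }
    }
    if (!counted) {
      s <- substr(f1$seq[i], 1, cut_length)
      votes <- integer(0)
      for (o in seq_len(nchar(s) - tindex$kmer_len + 1)) {
        g <- tindex$kmers[substr(s, o, o + tindex$kmer_len - 1)]
        if (!is.na(g)) votes <- c(votes, unname(g))
      }
      votes <- unique(votes)
      if (length(votes) == 1) {
        key <- paste("M", cell, votes, umi2)
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          mrna_m[votes, ci] <- mrna_m[votes, ci] + 1L
        }
      }
    }
  }
  list(mrna = mrna_m, arc = arc_m)
}

mutate_at <- function(seq, pos, base) {
  substr(seq, pos, pos) <- base
  seq
}

other_bases <- function(b) setdiff(c("A", "C", "G", "T"), b)
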