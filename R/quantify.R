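# Paired-FASTQ -> matched UMI count tables.
#
# Per read pair: assign a cell from read 2 (exact whitelist match, quality
# gate); classify read 1 as ARC (anchor match within the stagger-derived
# window) or transcript (unanimous unique-k-mer vote on the first 50 nt);
# UMI-collapse by exact identity. ARC classification takes precedence and
# an ARC read never contributes to the mRNA table.

#' Assign read pairs to cells
#'
#' Exact whitelist match on the cell-barcode substring of read 2. A read is
#' rejected as `quality_fail` when any base in the barcode+UMI region has a
#' Phred quality below `min_bc_quality`, and as `unassigned` when the
#' barcode is not on the whitelist.
#'
#' @param seq2 Character vector of read-2 sequences.
#' @param qual2 Character vector of read-2 quality strings (Phred+33).
#' @param index A [cell_barcode_index()].
#' @param min_bc_quality Minimum per-base quality (default 10).
#' @return A data.frame with columns `fate` (`assigned`/`quality_fail`/
#'   `unassigned`), `cell_name` and `read2_umi` (NA unless assigned).
#' @export
demultiplex_cell <- function(seq2, qual2, index, min_bc_quality = 10L) {
  stopifnot(inherits(index, "cell_barcode_index"),
            length(seq2) == length(qual2))
  region_len <- index$cb_len + index$read2_umi_len
  if (any(nchar(seq2) != region_len)) {
    stop("read 2 length must equal cb_len + read2_umi_len")
  }
  if (index$read2_order == "umi_first") {
    umi <- substr(seq2, 1L, index$read2_umi_len)
    bc <- substr(seq2, index$read2_umi_len + 1L, region_len)
  } else {
    bc <- substr(seq2, 1L, index$cb_len)
    umi <- substr(seq2, index$cb_len + 1L, region_len)
  }
  minq <- vapply(substr(qual2, 1L, region_len),
                 function(q) min(utf8ToInt(q)) - 33L, integer(1L),
                 USE.NAMES = FALSE)
  hit <- match(bc, index$barcode)
  fate <- rep("assigned", length(seq2))
  fate[is.na(hit)] <- "unassigned"
  fate[minq < min_bc_quality] <- "quality_fail"
  cell <- ifelse(fate == "assigned", index$cell_name[hit], NA_character_)
  data.frame(fate = fate, cell_name = cell,
             read2_umi = ifelse(fate == "assigned", umi, NA_character_),
             stringsAsFactors = FALSE)
}

#' Detect ARC reads by anchor matching
#'
#' Scans anchor-start positions in the stagger-derived window in ascending
#' order; the first position where the anchor matches with at most
#' `layout$max_anchor_mismatches` substitutions wins. The 10-nt antibody
#' barcode and 15-nt ARC UMI are then read off immediately upstream of the
#' anchor, and the barcode is matched against the panel (exactly by
#' default). Bases downstream of the anchor never influence the result.
#'
#' @param seq1 Character vector of read-1 sequences.
#' @param layout An [arc_layout()].
#' @param panel An [antibody_panel()].
#' @param barcode_mismatches Mismatches tolerated in the antibody barcode
#'   (default 0); requires the panel to pass [validate_panel()] at this
#'   tolerance.
#' @return A data.frame with one row per read: `antibody_name`, `arc_umi`,
#'   `anchor_pos` (0-based) and `anchor_mismatches`; all-NA rows mark
#'   no-hits.
#' @export
detect_arc <- function(seq1, layout, panel, barcode_mismatches = 0L) {
  stopifnot(inherits(layout, "arc_layout"), inherits(panel, "antibody_panel"))
  m <- as.integer(barcode_mismatches)
  if (m > 0L) {
    v <- validate_panel(panel, m)
    if (!v$ok) {
      stop("panel min Hamming distance ", v$min_hamming,
           " makes matching with ", m, " mismatch(es) ambiguous (needs >= ",
           v$required, ")")
    }
  }
  n <- length(seq1)
  win <- anchor_window(layout)  # 0-based inclusive anchor starts
  alen <- nchar(layout$anchor)
  need <- win[2] + alen  # minimum read length to scan the full window
  if (any(nchar(seq1) < need)) {
    stop("read 1 shorter than anchor window end + anchor length (", need, ")")
  }
  pos <- rep(NA_integer_, n)
  mm <- rep(NA_integer_, n)
  open <- rep(TRUE, n)
  for (p0 in win[1]:win[2]) {
    if (!any(open)) break
    d <- hamming_to(substr(seq1[open], p0 + 1L, p0 + alen), layout$anchor)
    ok <- d <= layout$max_anchor_mismatches
    idx <- which(open)[ok]
    pos[idx] <- p0
    mm[idx] <- d[ok]
    open[idx] <- FALSE
  }
  hit <- !is.na(pos)
  ab <- rep(NA_character_, n)
  umi <- rep(NA_character_, n)
  if (any(hit)) {
    p1 <- pos[hit] + 1L  # 1-based anchor start
    bc <- substr(seq1[hit], p1 - layout$ab_barcode_len, p1 - 1L)
    u <- substr(seq1[hit], p1 - layout$ab_barcode_len - layout$umi_len,
                p1 - layout$ab_barcode_len - 1L)
    bi <- match_barcodes(bc, panel$barcode, m)
    ab[hit] <- panel$antibody_name[bi]
    umi[hit] <- ifelse(is.na(bi), NA_character_, u)
  }
  nohit <- is.na(ab)
  data.frame(antibody_name = ab, arc_umi = umi,
             anchor_pos = ifelse(nohit, NA_integer_, pos),
             anchor_mismatches = ifelse(nohit, NA_integer_, mm),
             stringsAsFactors = FALSE)
}

match_barcodes <- function(bc, whitelist, m) {
  hit <- match(bc, whitelist)
  if (m > 0L && anyNA(hit)) {
    todo <- which(is.na(hit))
    for (i in todo) {
      d <- hamming_to(whitelist, bc[i])
      j <- which(d <= m)
      if (length(j) == 1L) hit[i] <- j
    }
  }
  hit
}

#' Assign a read to a transcript by unique-k-mer vote
#'
#' Truncates read 1 to `cut_length` nt, looks up every k-mer in the
#' unique-k-mer index, and returns the gene if and only if all matching
#' k-mers agree; zero or conflicting votes yield `NA` (unassigned).
#'
#' @param seq1 Character vector of read-1 sequences.
#' @param index A [build_transcript_index()].
#' @param cut_length Truncation length (default 50; must be at least
#'   `index$kmer_len`).
#' @return Character vector of gene names (`NA` = unassigned).
#' @export
assign_transcript <- function(seq1, index, cut_length = 50L) {
  stopifnot(inherits(index, "transcript_index"))
  cut_length <- as.integer(cut_length)
  if (cut_length < index$kmer_len) stop("cut_length must be >= kmer_len")
  n <- length(seq1)
  if (n == 0L) return(character(0))
  s <- substr(seq1, 1L, cut_length)
  n_off <- cut_length - index$kmer_len + 1L
  votes <- matrix(NA_integer_, nrow = n, ncol = n_off)
  for (o in seq_len(n_off)) {
    km <- substr(s, o, o + index$kmer_len - 1L)
    long_enough <- nchar(km) == index$kmer_len
    votes[long_enough, o] <-
      unname(index$kmers[match(km[long_enough], names(index$kmers))])
  }
  vmin <- suppressWarnings(matrixStats::rowMins(votes, na.rm = TRUE))
  vmax <- suppressWarnings(matrixStats::rowMaxs(votes, na.rm = TRUE))
  gene <- rep(NA_character_, n)
  unanimous <- is.finite(vmin) & vmin == vmax
  gene[unanimous] <- index$genes[vmin[unanimous]]
  gene
}

#' Quantify a paired-FASTQ library into matched count tables
#'
#' Runs the full pipeline over all read pairs: cell demultiplexing with a
#' base-quality gate, ARC detection (which takes precedence), transcript
#' assignment for the remainder, and exact-identity UMI collapse per
#' (cell, feature). Both output matrices carry the identical full
#' whitelist cell list, including zero-count cells. The ARC tally is keyed
#' on the 15-nt ARC UMI (the read-2 UMI is ignored for ARC reads); the mRNA
#' tally is keyed on the read-2 UMI.
#'
#' @param r1,r2 Paths to the read-1 / read-2 FASTQ files (optionally
#'   gzipped), or character vectors of equal length when `qual1`/`qual2`
#'   are given.
#' @param layout An [arc_layout()].
#' @param panel An [antibody_panel()].
#' @param cell_index A [cell_barcode_index()].
#' @param transcript_index A [build_transcript_index()].
#' @param min_bc_quality Minimum base quality in the read-2 barcode+UMI
#'   region (default 10).
#' @param cut_length Read-1 truncation for transcript assignment
#'   (default 50).
#' @param barcode_mismatches Antibody-barcode mismatch tolerance
#'   (default 0).
#' @param swap_reads Set `TRUE` when the FASTQ files have read 1 and read 2
#'   swapped (a convention of some upstream pipelines).
#' @return A list of class `arc_quantification`: `mrna` and `arc`
#'   [count_matrix()] objects and a `report` list counting read fates
#'   (`total`, `quality_fail`, `unassigned_cell`, `arc`, `mrna`,
#'   `neither`), which partition the input.
#' @export
tally_counts <- function(r1, r2, layout, panel, cell_index, transcript_index,
                         min_bc_quality = 10L, cut_length = 50L,
                         barcode_mismatches = 0L, swap_reads = FALSE) {
  f1 <- read_fastq(r1)
  f2 <- read_fastq(r2)
  if (length(f1$seq) != length(f2$seq)) {
    stop("read-1 and read-2 files hold different numbers of records")
  }
  if (swap_reads) { tmp <- f1; f1 <- f2; f2 <- tmp }

  demux <- demultiplex_cell(f2$seq, f2$qual, cell_index, min_bc_quality)
  assigned <- demux$fate == "assigned"

  arc <- detect_arc(f1$seq[assigned], layout, panel, barcode_mismatches)
  is_arc <- !is.na(arc$antibody_name)

  to_gene <- which(assigned)[!is_arc]
  gene <- assign_transcript(f1$seq[to_gene], transcript_index, cut_length)

  cells <- cell_index$cell_name
  arc_m <- tally_umi_matrix(
    demux$cell_name[assigned][is_arc], arc$antibody_name[is_arc],
    arc$arc_umi[is_arc], cells, panel$antibody_name, "ARC"
  )
  got_gene <- !is.na(gene)
  mrna_m <- tally_umi_matrix(
    demux$cell_name[to_gene][got_gene], gene[got_gene],
    demux$read2_umi[to_gene][got_gene], cells, transcript_index$genes, "mRNA"
  )

  report <- list(
    total = length(f1$seq),
    quality_fail = sum(demux$fate == "quality_fail"),
    unassigned_cell = sum(demux$fate == "unassigned"),
    arc = sum(is_arc),
    mrna = sum(got_gene),
    neither = sum(assigned) - sum(is_arc) - sum(got_gene),
    arc_umis = sum(arc_m), mrna_umis = sum(mrna_m)
  )
  structure(list(mrna = mrna_m, arc = arc_m, report = report),
            class = "arc_quantification")
}

#' @export
print.arc_quantification <- function(x, ...) {
  r <- x$report
  cat(sprintf("arc_quantification: %d read pairs\n", r$total))
  cat(sprintf("  quality-fail %d | unassigned cell %d | ARC %d | mRNA %d | neither %d\n",
              r$quality_fail, r$unassigned_cell, r$arc, r$mrna, r$neither))
  cat(sprintf("  UMIs after collapse: %d ARC, %d mRNA\n",
              r$arc_umis, r$mrna_umis))
  invisible(x)
}

read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  list(seq = as.character(x),
       qual = as.character(S4Vectors::mcols(x)$qualities),
       id = names(x))
}
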