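# Unique-k-mer transcript index: a self-contained stand-in for genome
# alignment, adequate for assigning reads to transcripts of a known
# reference. K-mers shared by more than one gene are discarded.

#' Build a unique-k-mer transcript index
#'
#' Extracts all k-mers from each reference transcript and keeps only those
#' occurring in exactly one gene; reads are later assigned by unanimous
#' k-mer vote ([assign_transcript()]). Only the forward strand is indexed
#' (the library is strand-specific by construction).
#'
#' @param reference A named `DNAStringSet`, a named character vector of
#'   transcript sequences, or the path to a FASTA file (record ID = gene
#'   name).
#' @param kmer_len K-mer length in nt (default 21; must not exceed the
#'   downstream read truncation length of 50).
#' @return A list of class `transcript_index` with elements `genes`,
#'   `kmer_len`, `kmers` (named integer vector: k-mer -> gene index) and
#'   `discarded_fraction` (fraction of distinct k-mers dropped as shared).
#' @export
build_transcript_index <- function(reference, kmer_len = 21L) {
  seqs <- load_reference(reference)
  kmer_len <- as.integer(kmer_len)
  if (length(seqs) == 0L) stop("empty reference")
  if (kmer_len < 1L) stop("kmer_len must be positive")
  if (any(nchar(seqs) < kmer_len)) {
    stop("all reference sequences must be at least kmer_len long")
  }
  genes <- names(seqs)
  if (is.null(genes) || anyDuplicated(genes)) {
    stop("reference sequences must carry unique gene names")
  }
  km_list <- lapply(seqs, function(s) {
    n <- nchar(s) - kmer_len + 1L
    unique(substring(s, seq_len(n), seq_len(n) + kmer_len - 1L))
  })
  kmer <- unlist(km_list, use.names = FALSE)
  gene_idx <- rep.int(seq_along(genes), lengths(km_list))
  shared <- kmer[duplicated(kmer)]
  keep <- !(kmer %in% shared)
  discarded_fraction <- 1 - sum(keep) / length(unique(kmer))
  if (sum(keep) == 0L) {
    warning("no gene-unique k-mers retained; every k-mer is shared")
  }
  kmers <- gene_idx[keep]
  names(kmers) <- kmer[keep]
  structure(
    list(genes = genes, kmer_len = kmer_len, kmers = kmers,
         n_discarded = length(unique(kmer)) - sum(keep),
         discarded_fraction = discarded_fraction),
    class = "transcript_index"
  )
}

#' @export
print.transcript_index <- function(x, ...) {
  cat(sprintf("transcript_index: %d genes, k = %d, %d unique k-mers (%.1f%% discarded as shared)\n",
              length(x$genes), x$kmer_len, length(x$kmers),
              100 * x$discarded_fraction))
  invisible(x)
}

# Accepts DNAStringSet, named character vector, or FASTA path.
load_reference <- function(reference) {
  if (inherits(reference, "DNAStringSet")) {
    stats::setNames(as.character(reference), names(reference))
  } else if (is.character(reference) && length(reference) == 1L &&
             file.exists(reference)) {
    x <- Biostrings::readDNAStringSet(reference)
    names(x) <- sub("\\s.*$", "", names(x))
    stats::setNames(as.character(x), names(x))
  } else if (is.character(reference)) {
    reference
  } else {
    stop("reference must be a DNAStringSet, named character vector or FASTA path")
  }
}

#' Simulate a transcript reference
#'
#' Random transcript sequences for the library simulator; at the default
#' length, 21-mers are effectively unique per gene.
#'
#' @param genes Character vector of gene names.
#' @param length Transcript length in nt (default 500).
#' @param seed Seed.
#' @return A named `DNAStringSet`.
#' @export
simulate_reference <- function(genes, length = 500L, seed = 1L) {
  seqs <- with_seed(seed, random_dna(base::length(genes), length))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- genes
  out
}
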