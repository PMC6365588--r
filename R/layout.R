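# ARC read-1 architecture: stagger / UMI / antibody barcode / anchor.

# Default in-vitro-transcription template for an ARC RNA barcode: T7 promoter,
# Illumina read primer site, an 8-nt stagger, a 15-nt UMI (N run), the 10-nt
# antibody barcode placeholder, the 12-nt identification anchor, a fixed
# downstream region and a poly(A) tail.
ARC_TEMPLATE <- paste0(
  "GGATCCTAATACGACTCACTATAGGGAGACCGACGAAACTGTTAACGTCGCACGACGC",
  "TCTTCCGATCT", "GTCAGTCA", strrep("N", 15), "[10 nt antibody barcode]",
  "ATCAGTCAACAG",
  "ATAAGCGTGAGATAGGGCATTACCGAGGCCTGGAGCATTGCCGATACCGAGAGTATTAGCTACGTTGCAGAGGATGCGACGGATGCA",
  strrep("A", 28)
)

READ_PRIMER_MOTIF <- "CTCTTCCGATCT"
STAGGER_SEQ <- "GTCAGTCA"

#' ARC read-1 layout
#'
#' Describes the architecture of read 1 for antibody RNA-barcode conjugate
#' (ARC) reads: a variable-length stagger, a UMI, the antibody-specific
#' barcode and the fixed identification anchor. The anchor plus barcode form
#' the antibody-identification span (22 nt by default).
#'
#' @param anchor Fixed identification sequence (default `ATCAGTCAACAG`).
#' @param umi_len ARC UMI length in nt (default 15).
#' @param ab_barcode_len Antibody barcode length in nt (default 10).
#' @param stagger_min,stagger_max Bounds on the stagger length in nt
#'   (defaults 1 and 8).
#' @param max_anchor_mismatches Substitutions tolerated when matching the
#'   anchor (default 1).
#'
#' @return An object of class `arc_layout`.
#' @examples
#' lay <- arc_layout()
#' anchor_window(lay)  # 0-based anchor-start search window: 26..33
#' @export
arc_layout <- function(anchor = "ATCAGTCAACAG", umi_len = 15L,
                       ab_barcode_len = 10L, stagger_min = 1L,
                       stagger_max = 8L, max_anchor_mismatches = 1L) {
  if (!is_dna(anchor)) stop("anchor must contain only A/C/G/T")
  umi_len <- as.integer(umi_len)
  ab_barcode_len <- as.integer(ab_barcode_len)
  stagger_min <- as.integer(stagger_min)
  stagger_max <- as.integer(stagger_max)
  max_anchor_mismatches <- as.integer(max_anchor_mismatches)
  if (umi_len < 1L || ab_barcode_len < 1L) {
    stop("umi_len and ab_barcode_len must be positive")
  }
  if (stagger_min < 1L) stop("stagger_min must be >= 1")
  if (stagger_max < stagger_min) stop("stagger_max must be >= stagger_min")
  if (max_anchor_mismatches < 0L) stop("max_anchor_mismatches must be >= 0")
  structure(
    list(anchor = anchor, umi_len = umi_len, ab_barcode_len = ab_barcode_len,
         stagger_min = stagger_min, stagger_max = stagger_max,
         max_anchor_mismatches = max_anchor_mismatches),
    class = "arc_layout"
  )
}

#' @export
print.arc_layout <- function(x, ...) {
  w <- anchor_window(x)
  cat("ARC read-1 layout\n")
  cat(sprintf("  anchor: %s (%d nt, <= %d mismatch%s)\n", x$anchor,
              nchar(x$anchor), x$max_anchor_mismatches,
              if (x$max_anchor_mismatches == 1L) "" else "es"))
  cat(sprintf("  UMI %d nt | antibody barcode %d nt | stagger %d-%d nt\n",
              x$umi_len, x$ab_barcode_len, x$stagger_min, x$stagger_max))
  cat(sprintf("  identification span: %d nt; anchor-start window (0-based): [%d, %d]\n",
              identification_span(x), w[1], w[2]))
  invisible(x)
}

#' Anchor-start search window
#'
#' The range of 0-based read-1 positions at which the anchor can start, as
#' implied by the stagger bounds: `stagger + umi_len + ab_barcode_len`.
#' `[26, 33]` under the default layout.
#'
#' @param layout An [arc_layout()].
#' @return Integer vector `c(first, last)`, 0-based inclusive.
#' @export
anchor_window <- function(layout) {
  stopifnot(inherits(layout, "arc_layout"))
  off <- layout$umi_len + layout$ab_barcode_len
  c(layout$stagger_min + off, layout$stagger_max + off)
}

#' Antibody-identification span (barcode + anchor), 22 nt by default.
#' @param layout An [arc_layout()].
#' @return Integer number of nucleotides.
#' @export
identification_span <- function(layout) {
  stopifnot(inherits(layout, "arc_layout"))
  layout$ab_barcode_len + nchar(layout$anchor)
}

#' Parse an ARC DNA template into a read layout
#'
#' Reads the template string used to produce ARC RNA barcodes and derives the
#' read-1 layout from it: the stagger region sits between the Illumina read
#' primer motif (`CTCTTCCGATCT`) and the UMI placeholder (a run of `N`s), the
#' antibody barcode is given as a bracketed placeholder such as
#' `[10 nt antibody barcode]`, and the identification anchor must occur
#' exactly downstream of it.
#'
#' @param template Template string (see `arcseq:::ARC_TEMPLATE` for the
#'   default design).
#' @param anchor Anchor sequence expected in the template.
#' @return An [arc_layout()].
#' @examples
#' parse_template_spec(arcseq:::ARC_TEMPLATE)
#' @export
parse_template_spec <- function(template, anchor = "ATCAGTCAACAG") {
  stopifnot(is.character(template), length(template) == 1L)
  if (!is_dna(anchor)) stop("anchor must contain only A/C/G/T")
  body <- gsub("\\[[^]]*\\]", "", template)
  if (grepl("[^ACGTUNRYSWKMBDHV]", body)) {
    stop("template contains non-IUPAC characters")
  }
  anchor_at <- regexpr(anchor, template, fixed = TRUE)
  if (anchor_at < 0L) {
    stop("malformed template: identification anchor '", anchor, "' not found")
  }
  primer_at <- regexpr(READ_PRIMER_MOTIF, template, fixed = TRUE)
  if (primer_at < 0L) {
    stop("malformed template: read primer motif '", READ_PRIMER_MOTIF,
         "' not found")
  }
  n_run <- regexpr("N+", template)
  if (n_run < 0L || n_run > anchor_at) {
    stop("malformed template: no UMI placeholder (run of N) before the anchor")
  }
  umi_len <- attr(n_run, "match.length")
  stagger_max <- as.integer(n_run) -
    (as.integer(primer_at) + nchar(READ_PRIMER_MOTIF))
  if (stagger_max < 1L) stop("malformed template: no stagger region")

  bc_ph <- regmatches(template, regexpr("\\[\\s*[0-9]+\\s*nt[^]]*\\]", template))
  if (length(bc_ph) == 1L) {
    ab_len <- as.integer(regmatches(bc_ph, regexpr("[0-9]+", bc_ph)))
  } else {
    # no placeholder: the barcode is written out between the UMI and anchor
    ab_len <- as.integer(anchor_at) - (as.integer(n_run) + umi_len)
  }
  if (is.na(ab_len) || ab_len < 1L) {
    stop("malformed template: cannot locate the antibody barcode field")
  }
  arc_layout(anchor = anchor, umi_len = umi_len, ab_barcode_len = ab_len,
             stagger_min = 1L, stagger_max = stagger_max)
}
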