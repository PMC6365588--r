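# Antibody panels and cell-barcode whitelists.

#' Antibody panel
#'
#' A whitelist mapping antibody names to their barcode sequences, as carried
#' on the ARC RNA between the UMI and the identification anchor.
#'
#' @param antibody_name Character vector of antibody names.
#' @param barcode Character vector of same-length A/C/G/T barcodes.
#' @return A data.frame of class `antibody_panel` with columns
#'   `antibody_name` and `barcode`.
#' @export
antibody_panel <- function(antibody_name, barcode) {
  stopifnot(length(antibody_name) == length(barcode), length(barcode) >= 1L)
  antibody_name <- as.character(antibody_name)
  barcode <- toupper(as.character(barcode))
  if (anyDuplicated(antibody_name)) stop("duplicate antibody names")
  if (anyDuplicated(barcode)) stop("duplicate antibody barcodes")
  if (!all(is_dna(barcode))) stop("barcodes must contain only A/C/G/T")
  if (length(unique(nchar(barcode))) != 1L) {
    stop("all barcodes must have the same length")
  }
  structure(
    data.frame(antibody_name = antibody_name, barcode = barcode,
               stringsAsFactors = FALSE),
    class = c("antibody_panel", "data.frame")
  )
}

#' Read an antibody panel from a TSV file
#'
#' Expects columns `antibody_name` and `barcode`.
#' @param path Path to a tab-separated file.
#' @return An [antibody_panel()].
#' @export
read_antibody_panel <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("antibody_name", "barcode") %in% names(df))) {
    stop("panel TSV must have columns 'antibody_name' and 'barcode'")
  }
  antibody_panel(df$antibody_name, df$barcode)
}

#' Validate an antibody panel for mismatch-tolerant matching
#'
#' Matching barcodes with up to `m` tolerated mismatches is unambiguous only
#' when every pair of whitelist barcodes differs at more than `2m` positions
#' (minimum pairwise Hamming distance `>= 2m + 1`).
#'
#' @param panel An [antibody_panel()].
#' @param tolerated_mismatches Mismatches `m` the matcher would tolerate
#'   (default 0, i.e. exact matching).
#' @return A list with `ok`, `min_hamming`, `required` and `n_antibodies`.
#' @examples
#' p <- antibody_panel(c("A", "B"), c("AAAAAAAAAA", "TTTTTTTTTT"))
#' validate_panel(p, tolerated_mismatches = 1)$ok
#' @export
validate_panel <- function(panel, tolerated_mismatches = 0L) {
  stopifnot(inherits(panel, "antibody_panel"))
  m <- as.integer(tolerated_mismatches)
  if (m < 0L) stop("tolerated_mismatches must be >= 0")
  dmin <- min_pairwise_hamming(panel$barcode)
  required <- 2L * m + 1L
  list(ok = is.infinite(dmin) || dmin >= required,
       min_hamming = dmin, required = required,
       n_antibodies = nrow(panel))
}

#' Example six-antibody panel (synthetic barcodes)
#'
#' Six intracellular/surface targets with synthetic 10-nt barcodes (the real
#' assay barcodes are user input). Generated deterministically; minimum
#' pairwise Hamming distance is at least 5, so matching with one tolerated
#' mismatch stays unambiguous.
#'
#' @return An [antibody_panel()] with antibodies pFAK, pRPS6, EGFR, ITGA6,
#'   ITGB1 and KRT14.
#' @export
example_panel <- function() {
  barcodes <- with_seed(20260918L, {
    picked <- character(0)
    while (length(picked) < 6L) {
      cand <- random_dna(1L, 10L)
      if (length(picked) == 0L || min(hamming_to(picked, cand)) >= 5L) {
        picked <- c(picked, cand)
      }
    }
    picked
  })
  antibody_panel(c("pFAK", "pRPS6", "EGFR", "ITGA6", "ITGB1", "KRT14"),
                 barcodes)
}

#' Cell barcode whitelist
#'
#' Describes read 2: a cell barcode and a UMI whose lengths sum to the read-2
#' length (6-nt UMI followed by an 8-nt cell barcode, 14 nt in total, by
#' default).
#'
#' @param cell_name Character vector of cell names.
#' @param barcode Character vector of cell barcodes, all of length `cb_len`.
#' @param cb_len Cell barcode length (default 8).
#' @param read2_umi_len Read-2 UMI length (default 6).
#' @param read2_order `"umi_first"` (default) or `"barcode_first"`.
#' @return An object of class `cell_barcode_index`.
#' @export
cell_barcode_index <- function(cell_name, barcode, cb_len = 8L,
                               read2_umi_len = 6L,
                               read2_order = c("umi_first", "barcode_first")) {
  read2_order <- match.arg(read2_order)
  stopifnot(length(cell_name) == length(barcode), length(barcode) >= 1L)
  cell_name <- as.character(cell_name)
  barcode <- toupper(as.character(barcode))
  cb_len <- as.integer(cb_len)
  read2_umi_len <- as.integer(read2_umi_len)
  if (anyDuplicated(cell_name)) stop("duplicate cell names")
  if (anyDuplicated(barcode)) stop("duplicate cell barcodes")
  if (!all(is_dna(barcode))) stop("cell barcodes must contain only A/C/G/T")
  if (!all(nchar(barcode) == cb_len)) {
    stop("all cell barcodes must have length cb_len")
  }
  structure(
    list(cell_name = cell_name, barcode = barcode, cb_len = cb_len,
         read2_umi_len = read2_umi_len, read2_order = read2_order),
    class = "cell_barcode_index"
  )
}

#' Read a cell whitelist from a TSV file with columns `cell_name`, `barcode`.
#' @param path Path to a tab-separated file.
#' @param ... Passed on to [cell_barcode_index()].
#' @return A [cell_barcode_index()].
#' @export
read_cell_index <- function(path, ...) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("cell_name", "barcode") %in% names(df))) {
    stop("cell whitelist TSV must have columns 'cell_name' and 'barcode'")
  }
  cell_barcode_index(df$cell_name, df$barcode, ...)
}

#' Generate a synthetic cell whitelist
#'
#' Deterministic set of unique random cell barcodes for simulations.
#' @param cell_name Character vector of cell names.
#' @param cb_len Barcode length (default 8).
#' @param seed Seed for barcode generation.
#' @param ... Passed on to [cell_barcode_index()].
#' @return A [cell_barcode_index()].
#' @export
make_cell_index <- function(cell_name, cb_len = 8L, seed = 1L, ...) {
  n <- length(cell_name)
  barcodes <- with_seed(seed, {
    bc <- unique(random_dna(2L * n + 16L, cb_len))
    while (length(bc) < n) bc <- unique(c(bc, random_dna(n, cb_len)))
    bc[seq_len(n)]
  })
  cell_barcode_index(cell_name, barcodes, cb_len = cb_len, ...)
}
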