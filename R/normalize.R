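# Depth normalization by random subsampling of UMI counts without
# replacement (multivariate hypergeometric), discarding cells below the
# depth threshold.

#' Subsampling depth presets of the three experiments
#'
#' The per-cell UMI depths used for the cell-surface experiment, the
#' unfixed-vs-fixed comparison (mRNA only) and the intracellular experiment.
#'
#' @return data.frame with columns `experiment`, `mrna_depth`, `arc_depth`.
#' @export
depth_presets <- function() {
  data.frame(
    experiment = c("surface", "unfixed_vs_fixed", "intracellular"),
    mrna_depth = c(10000L, 40000L, 4500L),
    arc_depth = c(2750L, NA_integer_, 400L),
    stringsAsFactors = FALSE
  )
}

#' Subsample one cell's counts to a fixed depth
#'
#' Draws exactly `depth` molecules uniformly without replacement from the
#' cell's UMI pool (multivariate hypergeometric across features). Cells with
#' fewer total counts than `depth` are discarded (`NULL`); a cell exactly at
#' the depth is returned unchanged.
#'
#' @param counts Named non-negative integer vector (feature -> count).
#' @param depth Target total (must be positive).
#' @param seed Optional seed; the caller's RNG state is left untouched.
#' @return Named integer vector totalling `depth`, or `NULL` if discarded.
#' @examples
#' subsample_cell(c(A = 300, B = 700), depth = 400, seed = 1)
#' @export
subsample_cell <- function(counts, depth, seed = NULL) {
  depth <- as.integer(depth)
  if (depth < 1L) stop("depth must be positive")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  total <- sum(counts)
  if (total < depth) return(NULL)
  out <- as.integer(counts)
  names(out) <- names(counts)
  if (total == depth) return(out)
  pool <- rep.int(seq_along(counts), counts)
  take <- with_seed(seed, sample(pool, depth, replace = FALSE))
  out <- tabulate(take, nbins = length(counts))
  names(out) <- names(counts)
  out
}

#' Depth-normalize matched count matrices
#'
#' Applies [subsample_cell()] per cell and modality. In multimodal mode a
#' cell is retained only if it reaches both depths; retained cells then
#' total exactly `mrna_depth` mRNA UMIs and `arc_depth` ARC UMIs, in
#' identical cell order across modalities. Per-cell RNG substreams are
#' derived from the single `seed` and the cell name, so results do not
#' depend on cell order.
#'
#' @param mrna mRNA [count_matrix()] (features x cells).
#' @param arc ARC [count_matrix()], or `NULL` for mRNA-only experiments.
#' @param mrna_depth mRNA subsampling depth (experiment presets 10000,
#'   40000 or 4500).
#' @param arc_depth ARC subsampling depth (presets 2750 or 400); required
#'   when `arc` is given.
#' @param seed Global seed (default 1).
#' @return A list of class `multimodal_dataset` with `mrna`, `arc`,
#'   `cells` (retained, in order), `discarded` (data.frame of cell, totals
#'   and reason) and the depths/seed used.
#' @export
normalize_dataset <- function(mrna, arc = NULL, mrna_depth, arc_depth = NULL,
                              seed = 1L) {
  if (!is.null(arc)) {
    if (is.null(arc_depth)) stop("arc_depth required when arc is given")
    common <- intersect(colnames(mrna), colnames(arc))
    if (length(common) == 0L) stop("mRNA and ARC matrices share no cells")
    if (!setequal(colnames(mrna), colnames(arc))) {
      stop("mRNA and ARC matrices must carry the same cell universe")
    }
    arc <- arc[, colnames(mrna), drop = FALSE]
  }
  mt <- colSums(mrna)
  at <- if (is.null(arc)) NULL else colSums(arc)
  keep <- mt >= mrna_depth
  if (!is.null(arc)) keep <- keep & at >= arc_depth
  kept <- colnames(mrna)[keep]

  sub_matrix <- function(m, depth, tag) {
    out <- vapply(kept, function(cl) {
      subsample_cell(m[, cl], depth, seed = stream_seed(seed, paste0(tag, cl)))
    }, integer(nrow(m)))
    out <- matrix(out, nrow = nrow(m), dimnames = list(rownames(m), kept))
    count_matrix(out, attr(m, "modality"))
  }
  mrna_sub <- sub_matrix(mrna, mrna_depth, "m:")
  arc_sub <- if (is.null(arc)) NULL else sub_matrix(arc, arc_depth, "a:")

  disc <- !keep
  mrna_low <- mt[disc] < mrna_depth
  arc_low <- if (is.null(arc)) rep(FALSE, sum(disc)) else at[disc] < arc_depth
  discarded <- data.frame(
    cell_name = colnames(mrna)[disc],
    mrna_total = unname(mt[disc]),
    arc_total = if (is.null(arc)) rep(NA_integer_, sum(disc)) else unname(at[disc]),
    reason = ifelse(mrna_low & arc_low, "both",
                    ifelse(mrna_low, "mrna_below_depth", "arc_below_depth")),
    stringsAsFactors = FALSE
  )
  if (length(kept) == 0L) warning("no cell passed the depth thresholds")
  structure(
    list(mrna = mrna_sub, arc = arc_sub, cells = kept, discarded = discarded,
         mrna_depth = as.integer(mrna_depth),
         arc_depth = if (is.null(arc_depth)) NULL else as.integer(arc_depth),
         seed = seed),
    class = "multimodal_dataset"
  )
}

#' @export
print.multimodal_dataset <- function(x, ...) {
  cat(sprintf("multimodal_dataset: %d cells retained (%d discarded)\n",
              length(x$cells), nrow(x$discarded)))
  cat(sprintf("  mRNA depth %d%s\n", x$mrna_depth,
              if (is.null(x$arc)) "" else sprintf(" | ARC depth %d", x$arc_depth)))
  invisible(x)
}
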