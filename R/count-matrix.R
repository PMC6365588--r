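# UMI count tables: features as rows, cells as columns, with a modality tag.

#' Construct a UMI count matrix
#'
#' @param counts Integer matrix, features x cells, with dimnames.
#' @param modality `"mRNA"` or `"ARC"`.
#' @return The matrix with class `count_matrix` and a `modality` attribute.
#' @export
count_matrix <- function(counts, modality = c("mRNA", "ARC")) {
  modality <- match.arg(modality)
  counts <- as.matrix(counts)
  if (is.null(dimnames(counts))) dimnames(counts) <- list(NULL, NULL)
  if (nrow(counts) > 0L && is.null(rownames(counts))) {
    stop("counts must have feature (row) names")
  }
  if (ncol(counts) > 0L && is.null(colnames(counts))) {
    stop("counts must have cell (column) names")
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    stop("duplicate feature or cell names")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  structure(counts, modality = modality,
            class = c("count_matrix", class(counts)))
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("%s count matrix: %d features x %d cells, %s total UMIs\n",
              attr(x, "modality"), nrow(x), ncol(x),
              format(sum(x), big.mark = ",")))
  invisible(x)
}

#' Write a count matrix to TSV (features as rows, cells as columns)
#'
#' @param x A [count_matrix()] or plain matrix.
#' @param path Output path; must not already exist unless `overwrite = TRUE`.
#' @param overwrite Allow clobbering an existing file.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite) {
    stop("output path exists: ", path)
  }
  df <- data.frame(feature = rownames(x) %||% character(0),
                   as.data.frame(unclass(x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix written by [write_count_table()]
#'
#' @param path Path to the TSV.
#' @param modality `"mRNA"` or `"ARC"`.
#' @return A [count_matrix()] (a plain 0-column matrix if the file holds no
#'   cells).
#' @export
read_count_table <- function(path, modality = c("mRNA", "ARC")) {
  modality <- match.arg(modality)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  count_matrix(m, modality)
}

# (cell, feature, umi) triples -> UMI-collapsed count matrix over the full
# cell and feature universes (zero-count cells/features retained).
tally_umi_matrix <- function(cell, feature, umi, all_cells, all_features,
                             modality) {
  keep <- !duplicated(paste(cell, feature, umi, sep = "\r"))
  cell <- factor(cell[keep], levels = all_cells)
  feature <- factor(feature[keep], levels = all_features)
  m <- table(feature, cell)
  m <- matrix(as.integer(m), nrow = length(all_features),
              dimnames = list(all_features, all_cells))
  count_matrix(m, modality)
}
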