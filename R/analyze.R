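# Downstream multimodal analysis: log normalization, variable genes,
# PCA/t-SNE, antibody ratios, display clipping, signature scores,
# extreme-cell selection, group resampling, differential expression and
# two-sample tests.

#' Log-normalize a depth-normalized count matrix
#'
#' `ln(1 + count * scale / cell_total)` per entry. After subsampling all
#' cell totals are equal, so within a gene the transform preserves rank
#' order across cells.
#'
#' @param counts Count matrix (features x cells).
#' @param scale Scale factor (default 10000).
#' @return Real-valued matrix of the same shape.
#' @export
log_normalize <- function(counts, scale = 1e4) {
  totals <- colSums(counts)
  if (any(totals == 0)) stop("zero-total cell(s): ",
                             paste(colnames(counts)[totals == 0], collapse = ", "))
  log1p(sweep(unclass(counts), 2L, totals / scale, "/"))
}

#' Select variable genes by binned dispersion z-score
#'
#' Genes are binned (20 equal-width bins) by mean expression on the
#' exponentiated scale; within each bin the dispersion
#' (variance/mean of `expm1(lognorm)`) is z-scored, and genes with z-score
#' at least `z_cutoff` and mean inside `mean_bounds` are kept. Fully
#' deterministic and invariant to cell order.
#'
#' @param lognorm Log-normalized matrix from [log_normalize()].
#' @param nbins Number of mean-expression bins (default 20).
#' @param z_cutoff Dispersion z-score cutoff (default 1).
#' @param mean_bounds Exponentiated-scale mean bounds (default `c(0.1, 8)`).
#' @return Character vector of selected gene names.
#' @export
select_variable_genes <- function(lognorm, nbins = 20L, z_cutoff = 1,
                                  mean_bounds = c(0.1, 8)) {
  if (ncol(lognorm) < 2L) stop("need at least 2 cells")
  e <- expm1(lognorm)
  gm <- rowMeans(e)
  gv <- matrixStats::rowVars(e)
  disp <- ifelse(gm > 0, gv / gm, 0)
  bin <- cut(gm, breaks = nbins)
  z <- stats::ave(disp, bin, FUN = function(x) {
    s <- stats::sd(x)
    if (length(x) < 2L || is.na(s) || s == 0) rep(0, length(x))
    else (x - mean(x)) / s
  })
  keep <- disp > 0 & z >= z_cutoff & gm >= mean_bounds[1] & gm <= mean_bounds[2]
  rownames(lognorm)[keep]
}

#' Embed cells by PCA and t-SNE
#'
#' Centers and scales the variable genes, runs PCA, and embeds the selected
#' principal components (1-8 by default) in two dimensions with t-SNE under
#' a fixed seed. Perplexity is lowered automatically when the cell count
#' requires it (t-SNE needs `3 * perplexity < n - 1`).
#'
#' @param lognorm Log-normalized matrix.
#' @param variable_genes Genes to use (e.g. from
#'   [select_variable_genes()]).
#' @param dims Principal components to embed (default `1:8`).
#' @param seed Seed for t-SNE (default 42).
#' @param perplexity t-SNE perplexity (default 30).
#' @return Cells x 2 coordinate matrix with a `params` attribute recording
#'   dims, perplexity and seed.
#' @export
embed_cells <- function(lognorm, variable_genes, dims = 1:8, seed = 42L,
                        perplexity = 30) {
  n_cells <- ncol(lognorm)
  if (n_cells <= max(dims)) {
    stop("fewer cells (", n_cells, ") than requested principal components")
  }
  x <- lognorm[variable_genes, , drop = FALSE]
  xs <- t(scale(t(x)))
  xs[!is.finite(xs)] <- 0
  pca <- stats::prcomp(t(xs), center = FALSE, scale. = FALSE)
  dims <- dims[dims <= ncol(pca$x)]
  scores <- pca$x[, dims, drop = FALSE]
  perp <- min(perplexity, floor((n_cells - 2) / 3))
  coords <- with_seed(seed, {
    Rtsne::Rtsne(scores, dims = 2L, pca = FALSE, perplexity = perp,
                 check_duplicates = FALSE, verbose = FALSE)$Y
  })
  dimnames(coords) <- list(colnames(lognorm), c("tSNE_1", "tSNE_2"))
  attr(coords, "params") <- list(dims = dims, perplexity = perp, seed = seed)
  coords
}

#' Per-cell ratio of two antibody counts
#'
#' `(numerator + pseudocount) / (denominator + pseudocount)` per cell, e.g.
#' the EGFR-to-ITGA6 ratio used to read out differentiation at the protein
#' level.
#'
#' @param arc ARC count matrix (antibodies x cells).
#' @param numerator,denominator Antibody names.
#' @param pseudocount Added to both counts (default 1).
#' @return Named numeric vector of per-cell ratios.
#' @export
arc_ratio <- function(arc, numerator, denominator, pseudocount = 1) {
  miss <- setdiff(c(numerator, denominator), rownames(arc))
  if (length(miss) > 0L) stop("unknown antibody: ", paste(miss, collapse = ", "))
  (arc[numerator, ] + pseudocount) / (arc[denominator, ] + pseudocount)
}

#' Winsorize values at the 5th and 95th percentiles for display
#'
#' Uses inverse-CDF (type 1) percentiles, under which clipping is exactly
#' idempotent: re-clipping an already clipped vector changes nothing.
#'
#' @param values Numeric vector.
#' @param lo_pct,hi_pct Percentile bounds (defaults 5 and 95).
#' @return Clipped vector.
#' @export
clip_for_display <- function(values, lo_pct = 5, hi_pct = 95) {
  if (length(values) == 0L) stop("need at least one value")
  qs <- stats::quantile(values, c(lo_pct, hi_pct) / 100, na.rm = TRUE,
                        names = FALSE, type = 1)
  pmin(pmax(values, qs[1]), qs[2])
}

#' Gene signature
#'
#' A named gene list used for per-cell aggregate scoring, e.g. curated stem
#' (about 530 genes) and differentiation (about 226 genes) sets.
#'
#' @param name Signature name.
#' @param genes Unique, non-empty character vector of gene names.
#' @return A list of class `gene_signature`.
#' @export
gene_signature <- function(name, genes) {
  genes <- as.character(genes)
  if (length(genes) == 0L) stop("signature must contain at least one gene")
  if (anyDuplicated(genes)) stop("signature genes must be unique")
  structure(list(name = name, genes = genes), class = "gene_signature")
}

#' Read a one-column gene list (TSV/plain text, optional `gene` header)
#' @param path File path.
#' @param name Signature name (default: file base name).
#' @return A [gene_signature()].
#' @export
read_gene_set <- function(path, name = NULL) {
  x <- readLines(path)
  x <- trimws(x[nzchar(trimws(x))])
  if (length(x) > 0L && tolower(x[1]) == "gene") x <- x[-1]
  gene_signature(name %||% sub("\\.[^.]*$", "", basename(path)), x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-cell signature score
#'
#' Sum of subsampled UMI counts over the signature genes present in the
#' matrix (computed on counts, not log values). Missing genes are ignored
#' with a warning; no overlap at all is an error.
#'
#' @param counts Depth-normalized count matrix (genes x cells).
#' @param signature A [gene_signature()] or character vector of genes.
#' @return Named numeric vector of per-cell scores.
#' @export
signature_score <- function(counts, signature) {
  genes <- if (inherits(signature, "gene_signature")) signature$genes
           else as.character(signature)
  present <- intersect(genes, rownames(counts))
  if (length(present) == 0L) {
    stop("no signature gene is present in the count matrix")
  }
  missing <- setdiff(genes, present)
  if (length(missing) > 0L) {
    warning(length(missing), " signature gene(s) absent from the matrix: ",
            paste(utils::head(missing, 5L), collapse = ", "),
            if (length(missing) > 5L) ", ..." else "")
  }
  colSums(unclass(counts)[present, , drop = FALSE])
}

#' Select extreme cells by an antibody's counts
#'
#' Within a cell group, picks the `n` cells with the highest and the `n`
#' with the lowest subsampled counts of one antibody (e.g. the 50 pFAK-high
#' and 50 pFAK-low treated cells). Ties are broken by cell name, and the
#' two sets are always disjoint.
#'
#' @param arc ARC count matrix (antibodies x cells).
#' @param antibody Antibody name.
#' @param cells Cell names forming the group (default: all columns).
#' @param n Cells per extreme set (default 50); the group must hold at
#'   least `2n` cells.
#' @return A list with character vectors `high` and `low`, each of length
#'   `n`.
#' @export
select_extremes <- function(arc, antibody, cells = colnames(arc), n = 50L) {
  if (!antibody %in% rownames(arc)) stop("unknown antibody: ", antibody)
  if (!all(cells %in% colnames(arc))) stop("unknown cell(s) in `cells`")
  n <- as.integer(n)
  if (length(cells) < 2L * n) {
    stop("group holds ", length(cells), " cells; need at least ", 2L * n)
  }
  v <- unclass(arc)[antibody, cells]
  ord <- cells[order(v, cells)]  # ascending count, name as tie-break
  list(high = rev(ord)[seq_len(n)], low = ord[seq_len(n)])
}

#' Resample fixed-size cell groups and sum a gene's counts
#'
#' Draws `reps` groups of `group_size` cells without replacement (within a
#' draw) from the given cell set and records the sum of the gene's counts
#' per draw — e.g. sums over 10 cells drawn 1000 times from the pFAK-high
#' set.
#'
#' @param counts Count matrix (genes x cells).
#' @param cells Cell set to draw from (at least `group_size` cells).
#' @param gene Gene name.
#' @param group_size Cells per draw (default 10).
#' @param reps Number of draws (default 1000).
#' @param seed Optional seed.
#' @return Numeric vector of `reps` sums.
#' @export
resample_group_sums <- function(counts, cells, gene, group_size = 10L,
                                reps = 1000L, seed = NULL) {
  if (!gene %in% rownames(counts)) stop("gene absent from matrix: ", gene)
  if (!all(cells %in% colnames(counts))) stop("unknown cell(s) in `cells`")
  if (length(cells) < group_size) {
    stop("need at least group_size (", group_size, ") cells")
  }
  x <- unclass(counts)[gene, cells]
  with_seed(seed, {
    vapply(seq_len(reps),
           function(i) sum(x[sample.int(length(x), group_size)]),
           numeric(1))
  })
}

#' Differential expression between two cell groups
#'
#' Genes whose absolute log fold-change reaches `logfc_threshold` are tested
#' with a two-sided Welch t-test on the log-normalized values; p-values are
#' Bonferroni-adjusted over the tested genes (set `adjust = "none"` with a
#' restricted `universe` to mirror an unadjusted signature-level screen).
#' The fold-change follows the common single-cell convention
#' `log(mean(expm1(x)) + 1)` per group (natural log by default; set
#' `fc_base = "log2"` for log2).
#'
#' @param lognorm Log-normalized matrix.
#' @param cells_a,cells_b Cell names of the two groups (each at least 3
#'   cells).
#' @param logfc_threshold Minimum |log fold-change| to test (default 0.25).
#' @param alpha Significance level on the adjusted p (default 0.05).
#' @param adjust `"bonferroni"` (default) or `"none"`.
#' @param universe Optional gene subset to restrict the analysis to.
#' @param fc_base `"ln"` (default) or `"log2"`.
#' @return A data.frame of class `de_result`: per gene the group means
#'   (`avg_a`, `avg_b`), `logfc`, Welch `t`/`df`/`p`, `padj` (NA when the
#'   fold-change gate was not passed) and `significant`.
#' @export
differential_expression <- function(lognorm, cells_a, cells_b,
                                    logfc_threshold = 0.25, alpha = 0.05,
                                    adjust = c("bonferroni", "none"),
                                    universe = NULL,
                                    fc_base = c("ln", "log2")) {
  adjust <- match.arg(adjust)
  fc_base <- match.arg(fc_base)
  if (length(cells_a) < 3L || length(cells_b) < 3L) {
    stop("both groups need at least 3 cells")
  }
  if (length(intersect(cells_a, cells_b)) > 0L) stop("groups overlap")
  genes <- rownames(lognorm)
  if (!is.null(universe)) genes <- intersect(genes, universe)
  xa <- lognorm[genes, cells_a, drop = FALSE]
  xb <- lognorm[genes, cells_b, drop = FALSE]
  logf <- if (fc_base == "ln") log else log2
  avg_a <- logf(rowMeans(expm1(xa)) + 1)
  avg_b <- logf(rowMeans(expm1(xb)) + 1)
  logfc <- avg_a - avg_b
  tested <- abs(logfc) >= logfc_threshold

  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- matrixStats::rowVars(xa); vb <- matrixStats::rowVars(xb)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  # degenerate variance: identical constants -> no evidence; distinct
  # constants -> infinitely strong evidence
  zero_se <- se2 == 0
  p[zero_se & ma == mb] <- 1
  tstat[zero_se & ma == mb] <- 0
  p[zero_se & ma != mb] <- 0

  padj <- rep(NA_real_, length(genes))
  padj[tested] <- stats::p.adjust(p[tested], method = adjust)
  out <- data.frame(
    gene = genes, avg_a = avg_a, avg_b = avg_b, logfc = logfc,
    t = tstat, df = df, p = ifelse(tested, p, NA_real_), padj = padj,
    significant = tested & !is.na(padj) & padj < alpha,
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("de_result", "data.frame")
  out
}

#' Two-sample KS and Welch t tests
#'
#' @param a,b Non-empty numeric vectors.
#' @return A list with `ks_statistic`, `ks_p`, `t_statistic`, `t_p` and
#'   `t_omitted` (TRUE when either sample is too small for the t-test).
#' @export
two_sample_tests <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("both samples must be non-empty")
  ks <- suppressWarnings(stats::ks.test(a, b))
  if (length(a) >= 2L && length(b) >= 2L &&
      (stats::sd(a) > 0 || stats::sd(b) > 0)) {
    tt <- stats::t.test(a, b)
    list(ks_statistic = unname(ks$statistic), ks_p = ks$p.value,
         t_statistic = unname(tt$statistic), t_p = tt$p.value,
         t_omitted = FALSE)
  } else {
    list(ks_statistic = unname(ks$statistic), ks_p = ks$p.value,
         t_statistic = NA_real_, t_p = NA_real_, t_omitted = TRUE)
  }
}

#' Per-gene QC statistics
#'
#' Detection rate (fraction of cells with count > 0), mean expression and
#' coefficient of variation (SD/mean on counts; `NA` for zero-mean genes).
#'
#' @param counts Count matrix (genes x cells, at least 2 cells).
#' @return data.frame with columns `gene`, `mean_expression`,
#'   `detection_rate`, `cv`.
#' @export
qc_gene_stats <- function(counts) {
  if (ncol(counts) < 2L) stop("need at least 2 cells")
  m <- unclass(counts)
  gm <- rowMeans(m)
  gs <- matrixStats::rowSds(m)
  data.frame(
    gene = rownames(m),
    mean_expression = gm,
    detection_rate = rowMeans(m > 0),
    cv = ifelse(gm > 0, gs / gm, NA_real_),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
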