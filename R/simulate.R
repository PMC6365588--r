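# Ground-truth simulator: per-cell molecule counts for genes and antibodies
# under a negative-binomial model with planted treatment effects, and paired
# FASTQ rendering with the ARC read architecture.

#' Simulation configuration
#'
#' The stated world of the simulator: two groups of keratinocyte-like cells
#' (untreated vs. EGFR-inhibitor treated), per-gene negative-binomial UMI
#' counts, and planted treatment effects. The treated group loses stem-cell
#' transcripts and pFAK/pRPS6 antibody signal and gains differentiation
#' transcripts; a "retainer" subpopulation of treated cells keeps high pFAK
#' and partially retains stem transcripts, including four highly expressed
#' integrin-substrate marker genes, giving the treated group a bimodal pFAK
#' distribution.
#'
#' @param n_cells_per_group Cells per group (default 250, matching the scale
#'   of the intracellular experiment, whose 50+50 extreme-cell analysis
#'   needs well over 100 treated cells to survive depth filtering).
#' @param n_genes Number of genes (default 1000).
#' @param n_stem_genes,n_diff_genes Sizes of the stem and differentiation
#'   signatures (defaults 530 and 226).
#' @param n_integrin_genes Stem genes flagged as integrin-substrate markers,
#'   planted at `integrin_abundance_boost` times the mean gene abundance
#'   (default 4 genes at 4x; laminin/collagen transcripts are abundant).
#' @param integrin_abundance_boost See above.
#' @param mean_mrna_molecules,mean_arc_molecules Mean per-cell molecule
#'   totals at baseline (defaults 6000 and 800; both comfortably above the
#'   4500/400 subsampling depths of the intracellular experiment).
#' @param mrna_nb_size,arc_nb_size Negative-binomial size (inverse
#'   overdispersion) per modality (defaults 2 and 4).
#' @param stem_fold_treated Fold on stem genes in treated non-retainer cells
#'   (default 0.25).
#' @param stem_fold_retainer Fold on stem genes in treated retainer cells
#'   (default 0.7).
#' @param diff_fold_treated Fold on differentiation genes in all treated
#'   cells (default 4).
#' @param integrin_fold_retainer Fold on integrin-substrate genes in
#'   retainer cells (default 1: fully retained).
#' @param arc_fold_treated Named numeric vector of treated-group folds per
#'   antibody (unnamed antibodies default to 1).
#' @param pfak_antibody Antibody with the bimodal treated-group effect
#'   (default `"pFAK"`).
#' @param pfak_retainer_fraction Fraction of treated cells that retain pFAK
#'   (default 0.3).
#' @param pfak_loser_fold pFAK fold in treated non-retainer cells
#'   (default 0.2).
#' @param error_rate Per-base substitution error rate in rendered reads
#'   (default 0.001).
#' @param lowq_fraction Fraction of read-2 records given one Q9 base inside
#'   the cell barcode (default 0; used to exercise the quality filter).
#' @param read_len1,read_len2 Read lengths (defaults 63 and 14).
#' @param unique_read2_umis Draw read-2 UMIs unique within each
#'   (cell, gene); set `FALSE` to allow collisions for UMI-collapse tests.
#' @param transcript_length Simulated transcript length (default 500).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cells_per_group = 250L, n_genes = 1000L,
                       n_stem_genes = 530L, n_diff_genes = 226L,
                       n_integrin_genes = 4L, integrin_abundance_boost = 4,
                       mean_mrna_molecules = 6000, mean_arc_molecules = 800,
                       mrna_nb_size = 2, arc_nb_size = 4,
                       stem_fold_treated = 0.25, stem_fold_retainer = 0.7,
                       diff_fold_treated = 4, integrin_fold_retainer = 1,
                       arc_fold_treated = c(pRPS6 = 0.3, EGFR = 0.5),
                       pfak_antibody = "pFAK",
                       pfak_retainer_fraction = 0.3, pfak_loser_fold = 0.2,
                       error_rate = 0.001, lowq_fraction = 0,
                       read_len1 = 63L, read_len2 = 14L,
                       unique_read2_umis = TRUE, transcript_length = 500L) {
  cfg <- list(
    n_cells_per_group = as.integer(n_cells_per_group),
    n_genes = as.integer(n_genes),
    n_stem_genes = as.integer(n_stem_genes),
    n_diff_genes = as.integer(n_diff_genes),
    n_integrin_genes = as.integer(n_integrin_genes),
    integrin_abundance_boost = integrin_abundance_boost,
    mean_mrna_molecules = mean_mrna_molecules,
    mean_arc_molecules = mean_arc_molecules,
    mrna_nb_size = mrna_nb_size, arc_nb_size = arc_nb_size,
    stem_fold_treated = stem_fold_treated,
    stem_fold_retainer = stem_fold_retainer,
    diff_fold_treated = diff_fold_treated,
    integrin_fold_retainer = integrin_fold_retainer,
    arc_fold_treated = arc_fold_treated,
    pfak_antibody = pfak_antibody,
    pfak_retainer_fraction = pfak_retainer_fraction,
    pfak_loser_fold = pfak_loser_fold,
    error_rate = error_rate, lowq_fraction = lowq_fraction,
    read_len1 = as.integer(read_len1), read_len2 = as.integer(read_len2),
    unique_read2_umis = isTRUE(unique_read2_umis),
    transcript_length = as.integer(transcript_length)
  )
  if (cfg$n_cells_per_group < 1L) stop("need at least one cell per group")
  if (cfg$n_genes < 1L) stop("need at least one gene")
  if (cfg$n_stem_genes + cfg$n_diff_genes > cfg$n_genes) {
    stop("signatures cannot exceed n_genes")
  }
  if (cfg$n_integrin_genes > cfg$n_stem_genes) {
    stop("integrin markers are a subset of the stem signature")
  }
  folds <- c(cfg$stem_fold_treated, cfg$stem_fold_retainer,
             cfg$diff_fold_treated, cfg$integrin_fold_retainer,
             cfg$arc_fold_treated, cfg$pfak_loser_fold)
  if (any(folds <= 0)) stop("fold effects must be > 0")
  probs <- c(cfg$pfak_retainer_fraction, cfg$error_rate, cfg$lowq_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  structure(cfg, class = "sim_config")
}

#' Simulate ground-truth molecule counts
#'
#' Draws per-cell molecule counts for every gene and antibody from the
#' negative-binomial model described in [sim_config()], applying the planted
#' treatment effects multiplicatively to the mean.
#'
#' @param config A [sim_config()].
#' @param panel An [antibody_panel()] (default [example_panel()]).
#' @param seed Seed; a fixed seed reproduces the ground truth exactly.
#' @return A list of class `ground_truth` with `cells` (data.frame of
#'   `cell_name`, `group`, `retainer`), `gene_counts` (genes x cells),
#'   `arc_counts` (antibodies x cells) and `signatures` (`stem`,
#'   `differentiation`, `integrin` gene lists).
#' @export
simulate_ground_truth <- function(config = sim_config(),
                                  panel = example_panel(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"), inherits(panel, "antibody_panel"))
  with_seed(seed, {
    n <- config$n_cells_per_group
    cells <- data.frame(
      cell_name = c(sprintf("untr_%04d", seq_len(n)),
                    sprintf("trt_%04d", seq_len(n))),
      group = rep(c("untreated", "treated"), each = n),
      stringsAsFactors = FALSE
    )
    cells$retainer <- cells$group == "treated" &
      stats::runif(nrow(cells)) < config$pfak_retainer_fraction

    genes <- sprintf("G%04d", seq_len(config$n_genes))
    stem <- genes[seq_len(config$n_stem_genes)]
    diffn <- genes[config$n_stem_genes + seq_len(config$n_diff_genes)]
    integrin <- stem[seq_len(config$n_integrin_genes)]

    w <- stats::rgamma(config$n_genes, shape = 1)
    w[genes %in% integrin] <- config$integrin_abundance_boost * mean(w)
    w <- w / sum(w)

    # genes x cells matrix of NB means, then one draw per entry
    mu <- outer(config$mean_mrna_molecules * w, rep(1, nrow(cells)))
    treated <- cells$group == "treated"
    retainer <- cells$retainer
    is_stem <- genes %in% stem
    is_diff <- genes %in% diffn
    is_integrin <- genes %in% integrin
    mu[is_stem, treated & !retainer] <-
      mu[is_stem, treated & !retainer] * config$stem_fold_treated
    mu[is_stem, retainer] <- mu[is_stem, retainer] * config$stem_fold_retainer
    mu[is_integrin, retainer] <-
      outer(config$mean_mrna_molecules * w[is_integrin] *
              config$integrin_fold_retainer, rep(1, sum(retainer)))
    mu[is_diff, treated] <- mu[is_diff, treated] * config$diff_fold_treated
    gene_counts <- matrix(
      as.integer(stats::rnbinom(length(mu), mu = mu, size = config$mrna_nb_size)),
      nrow = config$n_genes, dimnames = list(genes, cells$cell_name)
    )

    abs_ <- panel$antibody_name
    mu_arc <- matrix(config$mean_arc_molecules / length(abs_),
                     nrow = length(abs_), ncol = nrow(cells),
                     dimnames = list(abs_, cells$cell_name))
    fold <- stats::setNames(rep(1, length(abs_)), abs_)
    known <- intersect(names(config$arc_fold_treated), abs_)
    fold[known] <- config$arc_fold_treated[known]
    mu_arc[, treated] <- mu_arc[, treated] * fold
    if (config$pfak_antibody %in% abs_) {
      mu_arc[config$pfak_antibody, treated & !retainer] <-
        (config$mean_arc_molecules / length(abs_)) * config$pfak_loser_fold
      mu_arc[config$pfak_antibody, retainer] <-
        config$mean_arc_molecules / length(abs_)
    }
    arc_counts <- matrix(
      as.integer(stats::rnbinom(length(mu_arc), mu = mu_arc,
                                size = config$arc_nb_size)),
      nrow = length(abs_), dimnames = dimnames(mu_arc)
    )

    structure(
      list(cells = cells, gene_counts = gene_counts, arc_counts = arc_counts,
           signatures = list(stem = stem, differentiation = diffn,
                             integrin = integrin),
           config = config),
      class = "ground_truth"
    )
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d cells (%d untreated / %d treated), %d genes, %d antibodies\n",
              nrow(x$cells), sum(x$cells$group == "untreated"),
              sum(x$cells$group == "treated"), nrow(x$gene_counts),
              nrow(x$arc_counts)))
  cat(sprintf("  molecules: %s mRNA, %s ARC\n",
              format(sum(x$gene_counts), big.mark = ","),
              format(sum(x$arc_counts), big.mark = ",")))
  invisible(x)
}

#' Render an ARC read-1 sequence
#'
#' Lays out read 1 of an ARC molecule: stagger, ARC UMI, antibody barcode,
#' identification anchor, then template filler, truncated or padded to the
#' read length. Under the default layout the anchor starts at 0-based
#' position `stagger_len + 25`.
#'
#' @param antibody Antibody name (must be in `panel`).
#' @param layout An [arc_layout()].
#' @param panel An [antibody_panel()].
#' @param arc_umi UMI sequence of length `layout$umi_len`.
#' @param stagger_len Stagger length, within the layout bounds.
#' @param read_len Read-1 length (default 63).
#' @return A character vector of read sequences (vectorized over
#'   `antibody`/`arc_umi`/`stagger_len`).
#' @export
render_arc_read <- function(antibody, layout, panel, arc_umi, stagger_len,
                            read_len = 63L) {
  stopifnot(inherits(layout, "arc_layout"), inherits(panel, "antibody_panel"))
  idx <- match(antibody, panel$antibody_name)
  if (anyNA(idx)) {
    stop("unknown antibody: ", paste(antibody[is.na(idx)], collapse = ", "))
  }
  if (any(nchar(arc_umi) != layout$umi_len)) {
    stop("arc_umi must have length layout$umi_len")
  }
  if (any(stagger_len < layout$stagger_min | stagger_len > layout$stagger_max)) {
    stop("stagger_len outside layout bounds")
  }
  stagger_pool <- strrep(STAGGER_SEQ,
                         ceiling(max(stagger_len) / nchar(STAGGER_SEQ)))
  stagger <- substr(rep(stagger_pool, length.out = length(stagger_len)),
                    1L, stagger_len)
  # template region downstream of the anchor, padded with poly(A)
  filler_src <- sub(".*ATCAGTCAACAG", "", ARC_TEMPLATE)
  filler <- substr(paste0(filler_src, strrep("A", read_len)), 1L, read_len)
  reads <- paste0(stagger, arc_umi, panel$barcode[idx], layout$anchor, filler)
  substr(reads, 1L, read_len)
}

#' Write a simulated paired-FASTQ library
#'
#' Renders one read pair per ground-truth molecule: transcript molecules get
#' a read 1 copied from a random position of the gene's reference sequence;
#' ARC molecules get a read 1 built by [render_arc_read()] with a fresh
#' 15-nt ARC UMI and a per-antibody stagger cycling over the layout's
#' stagger range. Read 2 carries the read-2 UMI and the cell barcode in the
#' whitelist's configured order. Substitution errors are injected at the
#' configured rate; base qualities are constant Q30 except for optionally
#' planted Q9 bases inside the cell barcode.
#'
#' @param truth A [simulate_ground_truth()] result.
#' @param layout An [arc_layout()].
#' @param panel An [antibody_panel()].
#' @param cell_index A [cell_barcode_index()] covering every truth cell.
#' @param reference Transcript reference (see [build_transcript_index()] for
#'   accepted forms) covering every truth gene.
#' @param dir Output directory (created if missing).
#' @param seed Seed for read rendering (UMIs, start positions, errors).
#' @param gzip Write gzipped FASTQ (default TRUE).
#' @return Invisibly, a list with the FASTQ `r1`/`r2` paths, the
#'   `provenance` data.frame (read_id, cell, kind, feature, plus the true
#'   UMIs) and the paths of the truth/provenance TSVs written alongside.
#' @export
write_fastq_pair <- function(truth, layout, panel, cell_index, reference,
                             dir, seed = 1L, gzip = TRUE) {
  stopifnot(inherits(truth, "ground_truth"))
  config <- truth$config
  seqs <- load_reference(reference)
  genes <- rownames(truth$gene_counts)
  if (!all(genes %in% names(seqs))) {
    stop("reference is missing ", sum(!(genes %in% names(seqs))),
         " truth genes")
  }
  if (any(nchar(seqs[genes]) < config$read_len1)) {
    stop("reference sequences shorter than read 1")
  }
  cb <- stats::setNames(cell_index$barcode, cell_index$cell_name)
  if (!all(truth$cells$cell_name %in% names(cb))) {
    stop("cell whitelist is missing truth cells")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  with_seed(seed, {
    # --- expand molecules ---------------------------------------------------
    gc <- truth$gene_counts
    nz <- which(gc > 0L, arr.ind = TRUE)
    m_gene <- rep.int(genes[nz[, 1L]], gc[nz])
    m_cell_m <- rep.int(colnames(gc)[nz[, 2L]], gc[nz])

    ac <- truth$arc_counts
    nza <- which(ac > 0L, arr.ind = TRUE)
    m_ab <- rep.int(rownames(ac)[nza[, 1L]], ac[nza])
    m_cell_a <- rep.int(colnames(ac)[nza[, 2L]], ac[nza])

    n_m <- length(m_gene)
    n_a <- length(m_ab)

    # --- transcript reads ---------------------------------------------------
    tlen <- nchar(seqs[m_gene])
    start <- 1L + floor(stats::runif(n_m) * (tlen - config$read_len1 + 1L))
    r1_m <- substr(seqs[m_gene], start, start + config$read_len1 - 1L)
    r2_umi <- draw_umis(paste(m_cell_m, m_gene), cell_index$read2_umi_len,
                        config$unique_read2_umis)

    # --- ARC reads ----------------------------------------------------------
    stagger_range <- layout$stagger_min:layout$stagger_max
    ab_stagger <- stats::setNames(
      rep_len(stagger_range, nrow(panel)), panel$antibody_name)
    arc_umi <- draw_umis(paste(m_cell_a, m_ab), layout$umi_len, TRUE)
    r1_a <- if (n_a > 0L) {
      render_arc_read(m_ab, layout, panel, arc_umi, ab_stagger[m_ab],
                      config$read_len1)
    } else character(0)
    r2_umi_a <- draw_umis(rep("arc", n_a), cell_index$read2_umi_len, FALSE)

    # --- assemble pairs -----------------------------------------------------
    kind <- c(rep("mRNA", n_m), rep("ARC", n_a))
    cell <- c(m_cell_m, m_cell_a)
    feature <- c(m_gene, m_ab)
    read2_umi <- c(r2_umi, r2_umi_a)
    r1 <- unname(c(r1_m, r1_a))
    r2 <- if (cell_index$read2_order == "umi_first") {
      paste0(read2_umi, cb[cell])
    } else {
      paste0(cb[cell], read2_umi)
    }

    ord <- sample.int(length(r1))
    r1 <- r1[ord]; r2 <- r2[ord]
    kind <- kind[ord]; cell <- cell[ord]; feature <- feature[ord]
    read2_umi <- read2_umi[ord]
    arc_umi_all <- c(rep(NA_character_, n_m), arc_umi)[ord]
    read_id <- sprintf("sim_%07d", seq_along(r1))

    r1 <- inject_errors(r1, config$error_rate)
    r2 <- inject_errors(r2, config$error_rate)

    q1 <- rep(strrep("?", config$read_len1), length(r1))  # Q30
    q2 <- rep(strrep("?", config$read_len2), length(r2))
    if (config$lowq_fraction > 0) {
      n_low <- floor(config$lowq_fraction * length(r2))
      if (n_low > 0L) {
        hit <- sample.int(length(r2), n_low)
        bc_start <- if (cell_index$read2_order == "umi_first") {
          cell_index$read2_umi_len + 1L
        } else 1L
        pos <- bc_start + floor(stats::runif(n_low) * cell_index$cb_len)
        for (i in seq_len(n_low)) {
          substr(q2[hit[i]], pos[i], pos[i]) <- "*"  # Q9
        }
      }
    }

    # --- write --------------------------------------------------------------
    ext <- if (gzip) ".fastq.gz" else ".fastq"
    r1_path <- file.path(dir, paste0("R1", ext))
    r2_path <- file.path(dir, paste0("R2", ext))
    write_fastq(r1, q1, read_id, r1_path, gzip)
    write_fastq(r2, q2, read_id, r2_path, gzip)

    provenance <- data.frame(
      read_id = read_id, cell_name = cell, kind = kind, feature = feature,
      read2_umi = read2_umi, arc_umi = arc_umi_all, stringsAsFactors = FALSE
    )
    prov_path <- file.path(dir, "provenance.tsv")
    utils::write.table(provenance, prov_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    tg <- file.path(dir, "truth_genes.tsv")
    ta <- file.path(dir, "truth_arcs.tsv")
    write_count_table(truth$gene_counts, tg, overwrite = TRUE)
    write_count_table(truth$arc_counts, ta, overwrite = TRUE)

    invisible(list(r1 = r1_path, r2 = r2_path, provenance = provenance,
                   truth_genes = tg, truth_arcs = ta,
                   provenance_path = prov_path))
  })
}

write_fastq <- function(seqs, quals, ids, path, gzip) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(
    x, path, format = "fastq", qualities = Biostrings::BStringSet(quals),
    compress = gzip
  )
  invisible(path)
}

# Random fixed-width DNA UMIs; optionally redrawn until unique within the
# groups given by `key`. 4^len must stay below .Machine$integer.max.
draw_umis <- function(key, len, unique_within) {
  n <- length(key)
  if (n == 0L) return(character(0))
  space <- 4^len
  if (space > .Machine$integer.max) {
    # split a wide UMI into two independently drawn halves
    half <- len %/% 2L
    return(paste0(draw_umis(key, half, FALSE),
                  draw_umis(key, len - half, unique_within)))
  }
  ints <- sample.int(space, n, replace = TRUE)
  if (unique_within) {
    repeat {
      dup <- duplicated(paste(key, ints))
      if (!any(dup)) break
      ints[dup] <- sample.int(space, sum(dup), replace = TRUE)
    }
  }
  int_to_dna(ints, len)
}

# Uniform substitution errors at `rate` per base (equal-width reads).
inject_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  width <- nchar(seqs[1L])
  n_pos <- length(seqs) * width
  k <- stats::rbinom(1L, n_pos, rate)
  if (k == 0L) return(seqs)
  pos <- sample.int(n_pos, k)
  read_i <- (pos - 1L) %/% width + 1L
  base_i <- (pos - 1L) %% width + 1L
  for (t in seq_len(k)) {
    cur <- substr(seqs[read_i[t]], base_i[t], base_i[t])
    substr(seqs[read_i[t]], base_i[t], base_i[t]) <-
      sample(setdiff(DNA_BASES, cur), 1L)
  }
  seqs
}
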