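make_norm_fixture <- function(seed = 1) {
  sim <- small_sim(seed = seed)
  ds <- normalize_dataset(count_matrix(sim$truth$gene_counts, "mRNA"),
                          count_matrix(sim$truth$arc_counts, "ARC"),
                          mrna_depth = 60, arc_depth = 30, seed = seed)
  list(sim = sim, ds = ds)
}

test_that("log_normalize matches its closed form", {
  m <- matrix(c(45L, 4455L, 0L, 4500L), nrow = 2,
              dimnames = list(c("g1", "g2"), c("c1", "c2")))
  ln <- log_normalize(m, scale = 1e4)
  expect_equal(ln["g1", "c1"], log(1 + 45 * 1e4 / 4500))  # ln(101) ~ 4.615
  expect_equal(ln["g1", "c1"], 4.6151, tolerance = 1e-4)
  expect_equal(ln["g1", "c2"], 0)
  # doubling the scale shifts nonzero values up monotonically
  ln2 <- log_normalize(m, scale = 2e4)
  expect_true(all(ln2[m > 0] > ln[m > 0]))
  expect_error(log_normalize(matrix(0L, 1, 1, dimnames = list("g", "c"))),
               "zero-total")
})

test_that("variable-gene selection excludes constants and finds planted genes", {
  n_cells <- 80
  n_genes <- 400  # enough genes that every mean bin is well populated
  set.seed(99)
  lambdas <- runif(n_genes, 2, 10)
  found <- 0
  for (s in 1:20) {
    set.seed(1000 + s)
    m <- matrix(rpois(n_genes * n_cells, lambdas), nrow = n_genes,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("c%02d", 1:n_cells)))
    m["g001", ] <- 5L  # constant across cells
    # planted overdispersed gene: bimodal across cells, mean mid-range
    m["g400", ] <- rpois(n_cells, rep(c(1, 10), each = n_cells / 2))
    ln <- log_normalize(m, scale = 2000)  # keeps means inside the [0.1, 8] band
    vg <- select_variable_genes(ln)
    expect_false("g001" %in% vg)
    found <- found + ("g400" %in% vg)
    # invariance to cell order
    expect_setequal(select_variable_genes(ln[, sample(n_cells)]), vg)
  }
  expect_gte(found, 19)  # >= 95% of runs
})

test_that("embedding separates planted groups and is seed-stable", {
  fx <- make_norm_fixture(seed = 3)
  ln <- log_normalize(fx$ds$mrna, scale = 1e2)  # fixture depth is 60
  vg <- select_variable_genes(ln)
  expect_gte(length(vg), 2)
  emb <- embed_cells(ln, vg, dims = 1:8, seed = 42)
  expect_equal(dim(emb), c(length(fx$ds$cells), 2))
  expect_identical(emb, embed_cells(ln, vg, dims = 1:8, seed = 42))

  grp <- stats::setNames(fx$sim$truth$cells$group,
                         fx$sim$truth$cells$cell_name)[rownames(emb)]
  cen <- apply(emb, 2, function(v) tapply(v, grp, mean))
  between <- sqrt(sum((cen[1, ] - cen[2, ])^2))
  within <- mean(vapply(split(rownames(emb), grp), function(cl)
    mean(stats::dist(emb[cl, , drop = FALSE])), numeric(1)))
  expect_gt(between, within)

  expect_error(embed_cells(ln[, 1:5], vg, dims = 1:8), "fewer cells")
})

test_that("duplicated cells land on near-coincident embedding coordinates", {
  set.seed(4)
  m <- matrix(rpois(50 * 60, 8), nrow = 50,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("c%02d", 1:60)))
  m[, 58:60] <- m[, 1:3]  # three duplicated cells
  ln <- log_normalize(m, scale = 1e3)
  emb <- embed_cells(ln, rownames(m), dims = 1:5, seed = 1)
  d <- sqrt(rowSums((emb[1:3, , drop = FALSE] - emb[58:60, , drop = FALSE])^2))
  expect_lt(max(d), stats::quantile(stats::dist(emb), 0.05))
})

test_that("arc_ratio computes pseudocounted per-cell ratios", {
  arc <- count_matrix(matrix(c(99L, 49L, 5L, 5L), nrow = 2,
                             dimnames = list(c("EGFR", "ITGA6"),
                                             c("c1", "c2"))), "ARC")
  r <- arc_ratio(arc, "EGFR", "ITGA6")
  expect_equal(unname(r["c1"]), (99 + 1) / (49 + 1))  # 2.0
  expect_equal(unname(r["c2"]), 1.0)
  expect_error(arc_ratio(arc, "EGFR", "nope"), "unknown antibody")
})

test_that("treated cells lose EGFR/ITGA6 ratio in the planted world", {
  fx <- make_norm_fixture(seed = 8)
  grp <- stats::setNames(fx$sim$truth$cells$group,
                         fx$sim$truth$cells$cell_name)[fx$ds$cells]
  r <- arc_ratio(fx$ds$arc, "EGFR", "ITGA6")
  expect_lt(median(r[grp == "treated"]), median(r[grp == "untreated"]))
})

test_that("clip_for_display winsorizes at the stated percentiles", {
  x <- as.numeric(1:100)
  cl <- clip_for_display(x)
  # inverse-CDF percentiles of 1..100: 5th -> 5, 95th -> 95
  qs <- stats::quantile(x, c(0.05, 0.95), names = FALSE, type = 1)
  expect_equal(qs, c(5, 95))
  expect_equal(min(cl), qs[1])
  expect_equal(max(cl), qs[2])
  expect_equal(cl[x >= qs[1] & x <= qs[2]], x[x >= qs[1] & x <= qs[2]])
  expect_equal(clip_for_display(cl), cl)  # idempotent
  expect_equal(clip_for_display(rep(3, 10)), rep(3, 10))
})

test_that("signature scores sum subsampled counts over present genes", {
  m <- count_matrix(matrix(c(10L, 20L, 30L, 5L, 15L, 40L), nrow = 3,
                           dimnames = list(c("g1", "g2", "g3"),
                                           c("c1", "c2"))), "mRNA")
  expect_equal(signature_score(m, gene_signature("one", "g2")),
               c(c1 = 20, c2 = 15))
  expect_equal(signature_score(m, gene_signature("all", c("g1", "g2", "g3"))),
               colSums(unclass(m)))
  expect_warning(s <- signature_score(m, c("g1", "missing")), "absent")
  expect_equal(s, c(c1 = 10, c2 = 5))
  expect_error(signature_score(m, c("x", "y")), "no signature gene")
})

test_that("select_extremes partitions ties deterministically", {
  cells <- sprintf("c%02d", 1:10)
  arc <- count_matrix(matrix(c(5L, 9L, 1L, 9L, 5L, 5L, 2L, 9L, 0L, 5L),
                             nrow = 1, dimnames = list("pFAK", cells)), "ARC")
  ex <- select_extremes(arc, "pFAK", cells, n = 5)
  expect_length(ex$high, 5)
  expect_length(ex$low, 5)
  expect_length(intersect(ex$high, ex$low), 0)
  expect_setequal(c(ex$high, ex$low), cells)
  expect_true(all(unclass(arc)["pFAK", ex$high] >=
                    max(unclass(arc)["pFAK", ex$low])))

  # full ties: still a deterministic disjoint 5/5 split
  tied <- count_matrix(matrix(3L, 1, 10, dimnames = list("pFAK", cells)),
                       "ARC")
  ex2 <- select_extremes(tied, "pFAK", cells, n = 5)
  expect_length(intersect(ex2$high, ex2$low), 0)
  expect_identical(ex2, select_extremes(tied, "pFAK", sample(cells), n = 5))

  expect_error(select_extremes(arc, "pFAK", cells, n = 6), "at least")
})

test_that("resample_group_sums draws without replacement within draws", {
  cells <- sprintf("c%02d", 1:12)
  ones <- count_matrix(matrix(1L, 1, 12, dimnames = list("g1", cells)),
                       "mRNA")
  r <- resample_group_sums(ones, cells, "g1", group_size = 10, reps = 50,
                           seed = 1)
  expect_true(all(r == 10))  # every draw sums to 10

  set.seed(2)
  m <- count_matrix(matrix(as.integer(rpois(12, 20)), 1, 12,
                           dimnames = list("g1", cells)), "mRNA")
  r2 <- resample_group_sums(m, cells, "g1", group_size = 10, reps = 1000,
                            seed = 9)
  expect_length(r2, 1000)
  mu <- 10 * mean(unclass(m)["g1", ])
  expect_lt(abs(mean(r2) - mu), 3 * stats::sd(r2) / sqrt(1000))
  expect_error(resample_group_sums(m, cells, "nope"), "absent")
})

test_that("differential expression agrees with a per-gene t.test oracle", {
  set.seed(11)
  n <- 30
  ln <- matrix(rnorm(50 * 2 * n, mean = 2), nrow = 50,
               dimnames = list(sprintf("g%02d", 1:50),
                               c(sprintf("a%02d", 1:n), sprintf("b%02d", 1:n))))
  ln[1:10, 1:n] <- ln[1:10, 1:n] + 1  # shifted genes
  a <- sprintf("a%02d", 1:n); b <- sprintf("b%02d", 1:n)
  de <- differential_expression(ln, a, b, logfc_threshold = 0.25)

  for (g in rownames(ln)) {
    lfc <- log(mean(expm1(ln[g, a])) + 1) - log(mean(expm1(ln[g, b])) + 1)
    i <- match(g, de$gene)
    expect_equal(de$logfc[i], lfc)
    if (abs(lfc) >= 0.25) {
      tt <- stats::t.test(ln[g, a], ln[g, b])
      expect_equal(de$t[i], unname(tt$statistic), tolerance = 1e-10)
      expect_equal(de$p[i], tt$p.value, tolerance = 1e-10)
    } else {
      expect_true(is.na(de$p[i]))
    }
  }
  n_tested <- sum(!is.na(de$p))
  expect_equal(de$padj[!is.na(de$p)],
               pmin(1, de$p[!is.na(de$p)] * n_tested))

  # swapping groups flips every log fold-change
  de_sw <- differential_expression(ln, b, a, logfc_threshold = 0.25)
  expect_equal(de_sw$logfc, -de$logfc)

  # identical groups: nothing passes the fold-change gate
  twin <- ln[, a]
  colnames(twin) <- paste0("t", a)
  de_same <- differential_expression(cbind(ln[, a], twin), a, paste0("t", a))
  expect_equal(sum(!is.na(de_same$p)), 0)
})

test_that("a planted 4x marker is detected at 50+50 cells", {
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    counts <- matrix(rpois(40 * 100, 5), nrow = 40,
                     dimnames = list(sprintf("g%02d", 1:40),
                                     sprintf("c%03d", 1:100)))
    counts["g40", 1:50] <- rpois(50, 20)  # 4x in group A
    ln <- log_normalize(counts, scale = 1e3)
    de <- differential_expression(ln, sprintf("c%03d", 1:50),
                                  sprintf("c%03d", 51:100))
    i <- match("g40", de$gene)
    hits <- hits + (isTRUE(de$significant[i]) && de$logfc[i] > 0)
  }
  expect_gte(hits, 19)
})

test_that("restricted-universe unadjusted mode mirrors a signature-level screen", {
  set.seed(21)
  ln <- matrix(rnorm(30 * 20, 2), nrow = 30,
               dimnames = list(sprintf("g%02d", 1:30),
                               sprintf("c%02d", 1:20)))
  ln[1:3, 1:10] <- ln[1:3, 1:10] + 1.5
  de <- differential_expression(ln, sprintf("c%02d", 1:10),
                                sprintf("c%02d", 11:20),
                                adjust = "none",
                                universe = sprintf("g%02d", 1:10))
  expect_equal(nrow(de), 10)
  tested <- !is.na(de$p)
  expect_equal(de$padj[tested], de$p[tested])
})

test_that("two-sample tests behave as expected", {
  x <- rnorm(50)
  same <- two_sample_tests(x, x)
  expect_equal(same$ks_statistic, 0)

  lowp <- 0
  for (s in 1:20) {
    set.seed(s)
    res <- two_sample_tests(rnorm(200), rnorm(200, mean = 1))
    lowp <- lowp + (res$ks_p < 0.01)
  }
  expect_equal(lowp, 20)  # power ~ 1 at this n and shift

  # KS statistic invariant under strictly monotone transforms
  set.seed(5)
  a <- rexp(80); b <- rexp(80, rate = 2)
  expect_equal(two_sample_tests(a, b)$ks_statistic,
               two_sample_tests(log(a), log(b))$ks_statistic)

  res1 <- two_sample_tests(1, c(2, 3))
  expect_true(res1$t_omitted)
  expect_error(two_sample_tests(numeric(0), 1), "non-empty")
})

test_that("qc_gene_stats reports detection rate, mean and CV", {
  m <- count_matrix(matrix(c(3L, 0L, 2L, 5L, 0L, 2L, 4L, 0L, 2L), nrow = 3,
                           dimnames = list(c("g1", "g2", "g3"),
                                           paste0("c", 1:3))), "mRNA")
  qc <- qc_gene_stats(m)
  expect_equal(qc$detection_rate, c(1, 0, 1))
  expect_true(is.na(qc$cv[2]))
  expect_equal(qc$cv[3], 0)  # constant nonzero gene

  # Poisson: CV ~ lambda^(-1/2)
  set.seed(31)
  lam <- 9
  mp <- count_matrix(matrix(as.integer(rpois(2000, lam)), nrow = 1,
                            dimnames = list("g", sprintf("c%04d", 1:2000))),
                     "mRNA")
  expect_equal(qc_gene_stats(mp)$cv, 1 / sqrt(lam), tolerance = 0.1)
})
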