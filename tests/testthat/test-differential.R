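counts_tbl <- function(m) {
  dplyr::bind_cols(tibble::tibble(feature = paste0("f", seq_len(nrow(m)))),
                   tibble::as_tibble(as.data.frame(m)))
}

test_that("size factors reproduce the median-of-ratios hand computation", {
  m <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2,
              dimnames = list(NULL, c("s1", "s2")))
  sf <- size_factors(counts_tbl(m))
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-4)

  # identical columns -> unit factors
  m2 <- cbind(s1 = c(5, 8, 100), s2 = c(5, 8, 100), s3 = c(5, 8, 100))
  expect_equal(unname(size_factors(counts_tbl(m2))), c(1, 1, 1))

  # scale equivariance: scaling one column by c scales the factor *ratio* by c
  sf2 <- size_factors(counts_tbl(cbind(s1 = m[, 1], s2 = m[, 2] * 5)))
  expect_equal(unname(sf2[2] / sf2[1]), unname(5 * sf[2] / sf[1]))

  # invariant to feature and sample order up to label permutation
  sf3 <- size_factors(counts_tbl(m[c(3, 1, 2), c(2, 1)]))
  expect_equal(unname(sf3), unname(sf[c(2, 1)]))

  expect_error(size_factors(counts_tbl(cbind(a = c(0, 1), b = c(1, 0)))),
               "positive")
})

test_that("size factors agree with the DESeq2 median-of-ratios oracle", {
  skip_if_not_installed("DESeq2")
  set.seed(77)
  m <- matrix(rnbinom(200 * 6, mu = 50, size = 5), 200,
              dimnames = list(NULL, paste0("s", 1:6)))
  expect_equal(unname(size_factors(counts_tbl(m))),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-10)
})

test_that("BH adjustment matches the brute-force definition", {
  set.seed(42)
  for (i in 1:20) {
    p <- runif(sample(3:20, 1))
    expect_equal(p.adjust(p, "BH"), bh_brute(p), tolerance = 1e-12)
  }
  # monotone nondecreasing in p-rank
  de <- nb_wald_test(
    counts_tbl(matrix(rnbinom(100 * 6, mu = 80, size = 10), 100,
                      dimnames = list(NULL, paste0("s", 1:6)))),
    rep(c("WT", "KO"), each = 3))
  o <- order(de$p)
  expect_true(all(diff(de$padj[o]) >= -1e-12))
})

test_that("NB Wald test: null features flat, planted features called, signs correct", {
  set.seed(7)
  n <- 5
  m <- matrix(rnbinom(500 * 2 * n, mu = 100, size = 20), 500,
              dimnames = list(NULL, paste0("s", 1:(2 * n))))
  g <- rep(c("WT", "KO"), each = n)
  # a feature with identical normalised counts in both groups
  m[1, ] <- rep(c(60, 80, 100, 120, 140), 2)
  de <- nb_wald_test(counts_tbl(m), g, sf = setNames(rep(1, 2 * n), colnames(m)))
  expect_equal(de$log2fc[1], 0, tolerance = 1e-9)
  expect_gt(de$p[1], 0.5)

  # sign of log2FC equals sign of the pooled normalised mean difference
  # (group mean = sum of counts / sum of size factors) for every feature
  sf <- size_factors(counts_tbl(m))
  de <- nb_wald_test(counts_tbl(m), g, sf = sf)
  diffm <- rowSums(m[, g == "KO"]) / sum(sf[g == "KO"]) -
    rowSums(m[, g == "WT"]) / sum(sf[g == "WT"])
  nz <- abs(diffm) > 1e-12
  expect_true(all(sign(de$log2fc[nz]) == sign(diffm[nz])))

  # planted 8-fold feature at mean 100 is called
  m2 <- m
  m2[2, g == "KO"] <- rnbinom(n, mu = 800, size = 20)
  de2 <- call_differential(nb_wald_test(counts_tbl(m2), g))
  expect_true(de2$called[2])

  # all-zero features are excluded from testing and BH
  m3 <- m; m3[3, ] <- 0
  de3 <- nb_wald_test(counts_tbl(m3), g)
  expect_true(is.na(de3$p[3]) && is.na(de3$padj[3]))
})

test_that("planted effects agree qualitatively with the DESeq2 oracle", {
  skip_if_not_installed("DESeq2")
  sim <- simulate_count_matrix(n_genes = 300, n_per_group = 5,
                               planted = tibble::tibble(gene = 1:5, log2fc = 3),
                               nb_dispersion = 0.05, seed = 13)
  de <- call_differential(nb_wald_test(sim$counts, unname(sim$groups)))
  m <- as.matrix(sim$counts[, -1]); rownames(m) <- sim$counts$feature
  storage.mode(m) <- "integer"
  dds <- DESeq2::DESeqDataSetFromMatrix(
    m, S4Vectors::DataFrame(condition = factor(sim$groups,
                                               levels = c("WT", "KO"))),
    ~condition)
  res <- DESeq2::results(suppressMessages(DESeq2::DESeq(dds, quiet = TRUE)))
  orc <- rownames(res)[!is.na(res$padj) & res$padj < 0.05 &
                         abs(res$log2FoldChange) > 1]
  # every planted gene is found by both routes
  planted <- sim$truth$planted$gene
  expect_true(all(planted %in% de$feature[de$called]))
  expect_true(all(planted %in% orc))
  # log2FC estimates agree closely on the planted genes
  expect_equal(de$log2fc[match(planted, de$feature)],
               res[planted, "log2FoldChange"], tolerance = 0.1)
})

test_that("differential calling applies the padj and log2FC thresholds exactly", {
  fake <- structure(
    tibble::tibble(feature = c("a", "b", "c", "d"),
                   base_mean = 10, log2fc = c(1.01, 0.99, -1.5, 2),
                   lfc_se = 0.1, p = c(0.001, 0.001, 0.002, 0.2),
                   padj = c(0.049, 0.049, 0.051, 0.4)),
    class = c("tailscope_de", class(tibble::tibble())))
  called <- call_differential(fake, padj_max = 0.05, lfc_min = 1)
  expect_equal(called$called, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(attr(called, "n_up"), 1L)
  expect_equal(attr(called, "n_down"), 0L)
  # gene mode: padj alone
  gene_called <- call_differential(fake, padj_max = 0.05, lfc_min = 0)
  expect_equal(gene_called$called, c(TRUE, TRUE, FALSE, FALSE))
  # empty input -> empty call set
  expect_equal(nrow(call_differential(fake[0, ])), 0L)
})

test_that("mono(A)-vs-canonical correlation pairs per-miRNA fold changes", {
  mk <- function(mirna, iso_class, ext_seq, log2fc) {
    tibble::tibble(mirna = mirna, iso_class = iso_class, ext_seq = ext_seq,
                   log2fc = log2fc)
  }
  de <- dplyr::bind_rows(
    mk(paste0("m", 1:4), "nt_tail", "A", c(1, 2, 3, 4)),
    mk(paste0("m", 1:4), "canonical", "", c(-1, -2, -3, -4)),
    mk("m5", "nt_tail", "T", 9))  # mono(U): not usable
  r <- monoa_canonical_correlation(de)
  expect_equal(r$r, -1, tolerance = 1e-12)
  expect_equal(r$n, 4)

  # single usable miRNA -> undefined with a warning
  expect_warning(r1 <- monoa_canonical_correlation(
    dplyr::bind_rows(mk("m1", "nt_tail", "A", 1),
                     mk("m1", "canonical", "", 2))), "usable")
  expect_true(is.na(r1$r))
})

test_that("independent tailing and abundance changes give near-zero correlation", {
  set.seed(99)
  hits <- replicate(50, {
    de <- dplyr::bind_rows(
      tibble::tibble(mirna = paste0("m", 1:30), iso_class = "nt_tail",
                     ext_seq = "A", log2fc = rnorm(30)),
      tibble::tibble(mirna = paste0("m", 1:30), iso_class = "canonical",
                     ext_seq = "", log2fc = rnorm(30)))
    abs(monoa_canonical_correlation(de)$r) < 0.3
  })
  expect_gte(mean(hits), 0.8)
})
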