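# counts: tibble with `feature` column + one numeric column per sample
as_count_matrix <- function(counts) {
  stopifnot("feature" %in% names(counts))
  m <- as.matrix(counts[, setdiff(names(counts), "feature"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- counts$feature
  if (any(m < 0)) abort("count matrix has negative entries")
  m
}

#' Median-of-ratios size factors
#'
#' Per-sample normalisation constants: each feature's geometric mean across
#' samples forms a pseudo-reference; a sample's factor is the median, over
#' features with a positive geometric mean, of its count divided by the
#' pseudo-reference.
#'
#' @param counts tibble with a `feature` column and one numeric column per
#'   sample (or a plain numeric matrix, features x samples).
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(counts) {
  m <- if (is.matrix(counts)) counts else as_count_matrix(counts)
  logg <- rowMeans(log(m))             # -Inf where any zero
  use <- is.finite(logg)
  if (!any(use)) {
    abort(paste("no feature has positive counts in every sample;",
                "filter features or use a pseudo-reference"))
  }
  # median taken in log space (geometric interpolation at even counts)
  sf <- apply(m[use, , drop = FALSE], 2, function(col) {
    exp(median(log(col) - logg[use]))
  })
  setNames(sf, colnames(m))
}

#' Normalise a count matrix by size factors
#'
#' @param counts tibble as in [size_factors()].
#' @param sf optional precomputed size factors (named per sample).
#' @return Tibble of the same shape with counts divided by size factors.
#' @export
normalize_counts <- function(counts, sf = NULL) {
  m <- as_count_matrix(counts)
  sf <- sf %||% size_factors(m)
  q <- sweep(m, 2, sf[colnames(m)], "/")
  dplyr::bind_cols(tibble(feature = counts$feature), as_tibble(q))
}

#' Negative-binomial Wald test for two-group differential accumulation
#'
#' A minimal NB pipeline: median-of-ratios size factors, per-feature group
#' means on the normalised scale, a method-of-moments dispersion pooled within
#' groups (floored at `disp_floor`), and a Wald statistic on the log2 fold
#' change with standard error from the NB Fisher information. The statistic is
#' referred to a t distribution with `n1 + n2 - 2` degrees of freedom to
#' account for dispersion-estimation uncertainty at small sample sizes.
#' P-values are BH-adjusted across tested features; all-zero features are
#' excluded before adjustment and reported with `NA`.
#'
#' This is deliberately not a full DESeq2 reimplementation: there is no
#' dispersion-trend shrinkage and no log2FC shrinkage.
#'
#' @param counts tibble with `feature` column + one column per sample.
#' @param groups two-level factor or character vector, one per sample column,
#'   in column order; the first level is the reference (log2FC is second level
#'   over first).
#' @param sf optional size factors; computed from `counts` when `NULL`.
#' @param disp_floor,mean_floor numerical floors for dispersion and group
#'   means.
#' @return Tibble of class `tailscope_de`: `feature`, `base_mean`, `log2fc`,
#'   `lfc_se`, `p`, `padj`, ordered as the input. Attribute `groups` records
#'   the contrast.
#' @export
nb_wald_test <- function(counts, groups, sf = NULL,
                         disp_floor = 1e-8, mean_floor = 1e-6) {
  m <- as_count_matrix(counts)
  # character input: reference level is the first label seen, so a
  # WT-then-KO column order gives log2FC = KO over WT
  if (!is.factor(groups)) groups <- factor(groups, levels = unique(groups))
  if (nlevels(groups) != 2) abort("exactly two groups are required")
  if (length(groups) != ncol(m)) abort("one group label per sample column is required")
  if (any(table(groups) < 2)) abort("each group needs at least 2 samples")
  i1 <- which(groups == levels(groups)[1])
  i2 <- which(groups == levels(groups)[2])
  sf <- sf %||% size_factors(m)
  q <- sweep(m, 2, sf, "/")

  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowSums(m[, i1, drop = FALSE]) / sum(sf[i1])
  m2 <- rowSums(m[, i2, drop = FALSE]) / sum(sf[i2])
  v1 <- apply(q[, i1, drop = FALSE], 1, var)
  v2 <- apply(q[, i2, drop = FALSE], 1, var)
  vpool <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  # E[var(q)|group g] = m_g * mean(1/s) + alpha * m_g^2; solve for alpha
  w1 <- (n1 - 1) / (n1 + n2 - 2); w2 <- 1 - w1
  shot <- w1 * m1 * mean(1 / sf[i1]) + w2 * m2 * mean(1 / sf[i2])
  msq <- w1 * m1^2 + w2 * m2^2
  alpha <- pmax((vpool - shot) / pmax(msq, 1e-12), disp_floor)

  m1f <- pmax(m1, mean_floor); m2f <- pmax(m2, mean_floor)
  info <- function(mg, idx) {
    mu <- outer(mg, sf[idx])            # features x samples-in-group
    rowSums(mu / (1 + alpha * mu))
  }
  I1 <- info(m1f, i1); I2 <- info(m2f, i2)
  log2fc <- (log(m2f) - log(m1f)) / log(2)
  lfc_se <- sqrt(1 / I1 + 1 / I2) / log(2)
  tstat <- log2fc / lfc_se
  p <- 2 * pt(-abs(tstat), df = n1 + n2 - 2)

  tested <- rowSums(m) > 0
  p[!tested] <- NA_real_
  log2fc[!tested] <- NA_real_
  padj <- rep(NA_real_, length(p))
  padj[tested] <- p.adjust(p[tested], method = "BH")

  res <- tibble(feature = rownames(m), base_mean = unname(rowMeans(q)),
                log2fc = unname(log2fc), lfc_se = unname(lfc_se),
                p = unname(p), padj = unname(padj))
  structure(res, class = c("tailscope_de", class(tibble())),
            groups = levels(groups))
}

#' Call differentially accumulated features
#'
#' Adds a deterministic `called` column: `padj < padj_max` and
#' `|log2fc| > lfc_min`. The isomiR-mode thresholds are the defaults
#' (`padj < 0.05`, `|log2FC| > 1`); gene-level calling uses `lfc_min = 0`.
#'
#' @param results a [nb_wald_test()] result.
#' @param padj_max adjusted p-value cutoff.
#' @param lfc_min absolute log2 fold-change that must be exceeded.
#' @return The input tibble with a logical `called` column; attributes `n_up`
#'   and `n_down` count called features by log2FC sign.
#' @export
call_differential <- function(results, padj_max = 0.05, lfc_min = 1) {
  called <- !is.na(results$padj) & results$padj < padj_max &
    abs(results$log2fc) > lfc_min
  out <- results |> mutate(called = called)
  attr(out, "groups") <- attr(results, "groups")
  attr(out, "n_up") <- sum(called & results$log2fc > 0)
  attr(out, "n_down") <- sum(called & results$log2fc < 0)
  class(out) <- unique(c("tailscope_de", class(out)))
  out
}

#' Correlation between mono(A)-isomiR and canonical-isomiR changes
#'
#' For every miRNA quantified with both a mono(A)-tailed isomiR (a single
#' non-templated adenosine) and a canonical isomiR, pairs the two log2 fold
#' changes and computes their Pearson correlation: a test of whether changes
#' in 3' monoadenylation track changes in canonical miRNA abundance.
#'
#' @param de_isomirs isomiR-level differential results joined to feature
#'   annotations: a tibble with columns `mirna`, `iso_class`, `ext_seq`,
#'   `log2fc` (e.g. [nb_wald_test()] output joined to
#'   `isomir_count_matrix()$features`).
#' @return List of class `monoa_correlation`: `pairs` (tibble `mirna`,
#'   `lfc_monoA`, `lfc_canonical`), `r`, `p`, `n`. With fewer than 3 usable
#'   miRNAs, `r` and `p` are `NA` with a warning.
#' @export
monoa_canonical_correlation <- function(de_isomirs) {
  need <- c("mirna", "iso_class", "ext_seq", "log2fc")
  miss <- setdiff(need, names(de_isomirs))
  if (length(miss) > 0) {
    abort(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  }
  mono <- de_isomirs |>
    filter(.data$iso_class == "nt_tail", .data$ext_seq == "A",
           !is.na(.data$log2fc)) |>
    group_by(.data$mirna) |>
    summarise(lfc_monoA = .data$log2fc[1], .groups = "drop")
  can <- de_isomirs |>
    filter(.data$iso_class == "canonical", !is.na(.data$log2fc)) |>
    group_by(.data$mirna) |>
    summarise(lfc_canonical = .data$log2fc[1], .groups = "drop")
  pairs <- inner_join(mono, can, by = "mirna")
  if (nrow(pairs) < 3) {
    warn(sprintf("only %d miRNA(s) usable; correlation undefined", nrow(pairs)))
    return(structure(list(pairs = pairs, r = NA_real_, p = NA_real_,
                          n = nrow(pairs)),
                     class = "monoa_correlation"))
  }
  ct <- cor.test(pairs$lfc_monoA, pairs$lfc_canonical, method = "pearson")
  structure(list(pairs = pairs, r = unname(ct$estimate), p = ct$p.value,
                 n = nrow(pairs)),
            class = "monoa_correlation")
}

#' @export
print.monoa_correlation <- function(x, ...) {
  cat(sprintf("<monoa_correlation> n = %d miRNAs, Pearson r = %s, p = %s\n",
              x$n, format(x$r, digits = 3), format(x$p, digits = 3)))
  invisible(x)
}
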