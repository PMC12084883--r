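#' Load a miRNA-to-target-gene pair table
#'
#' Reads a TSV with columns `mirna` and `gene` and returns de-duplicated
#' pairs. Unknown identifiers are retained (filtering happens downstream).
#'
#' @param pairs_tsv path to the TSV.
#' @return Tibble: `mirna`, `gene`; attributes `n_interactions`, `n_mirnas`,
#'   `n_genes`.
#' @export
load_target_pairs <- function(pairs_tsv) {
  if (!file.exists(pairs_tsv)) abort(sprintf("file not found: %s", pairs_tsv))
  x <- readr::read_tsv(pairs_tsv, show_col_types = FALSE, comment = "#")
  miss <- setdiff(c("mirna", "gene"), names(x))
  if (length(miss) > 0) {
    abort(sprintf("pair table lacks required column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  bad <- which(is.na(x$mirna) | is.na(x$gene) | x$mirna == "" | x$gene == "")
  if (length(bad) > 0) {
    abort(sprintf("malformed pair row at line %d", bad[1] + 1L))
  }
  out <- distinct(x[, c("mirna", "gene")])
  structure(out, n_interactions = nrow(out),
            n_mirnas = dplyr::n_distinct(out$mirna),
            n_genes = dplyr::n_distinct(out$gene))
}

#' Restrict pairs to mono(A)-tailed miRNAs and differential genes
#'
#' Keeps interactions whose miRNA has a quantified mono(A)-tailed isoform and
#' whose target gene is differentially accumulated.
#'
#' @param pairs tibble of `mirna`, `gene` pairs.
#' @param monoa_mirnas character set of miRNAs with a mono(A)-tailed isomiR.
#' @param de_genes character set of differentially accumulated genes.
#' @return Filtered pair tibble (possibly empty, with a warning).
#' @export
filter_interactions <- function(pairs, monoa_mirnas, de_genes) {
  stopifnot(length(monoa_mirnas) > 0, length(de_genes) > 0)
  out <- pairs |>
    filter(.data$mirna %in% monoa_mirnas, .data$gene %in% de_genes)
  if (nrow(out) == 0) warn("no interaction survives the mono(A)/DE filter")
  out
}

#' Correlate miRNA and target-gene expression across samples
#'
#' For each miRNA:gene pair, computes the Pearson correlation of normalised
#' expression over matched samples (the columns shared by both matrices, or
#' an explicit `samples` vector). When fewer than 3 matched samples exist,
#' falls back to correlating per-genotype mean profiles (`groups` must then
#' map samples to genotypes) and the log2 fold-change sign concordance is the
#' primary classification; the mode used is recorded on the result.
#'
#' @param pairs tibble of `mirna`, `gene` pairs.
#' @param mirna_counts,gene_counts normalised count tibbles (`feature` column
#'   + one column per sample).
#' @param samples optional character vector of matched sample columns.
#' @param groups optional named genotype map for the group-mean mode.
#' @param mirna_lfc,gene_lfc optional tibbles (`feature`, `log2fc`) from the
#'   differential stage; copied onto the records.
#' @return Tibble of class `interaction_set`: `mirna`, `gene`, `pearson_r`,
#'   `r_p`, `lfc_mirna`, `lfc_gene`, `lfc_opposite_sign`, `sign_class`
#'   (`negative` iff r < 0, `positive` iff r > 0, `undefined` iff `NA`);
#'   attribute `mode` is `"samples"` or `"group_means"`.
#' @export
correlate_interactions <- function(pairs, mirna_counts, gene_counts,
                                   samples = NULL, groups = NULL,
                                   mirna_lfc = NULL, gene_lfc = NULL) {
  scol_m <- setdiff(names(mirna_counts), "feature")
  scol_g <- setdiff(names(gene_counts), "feature")
  samples <- samples %||% intersect(scol_m, scol_g)
  mode <- if (length(samples) >= 3) "samples" else "group_means"
  as_feature_matrix <- function(x) {
    m <- as.matrix(x[, setdiff(names(x), "feature"), drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- x$feature
    m
  }
  mm <- as_feature_matrix(mirna_counts)
  gm <- as_feature_matrix(gene_counts)
  if (mode == "samples") {
    mm <- mm[, samples, drop = FALSE]
    gm <- gm[, samples, drop = FALSE]
  } else {
    if (is.null(groups)) {
      abort(paste("fewer than 3 matched samples and no 'groups' map:",
                  "cannot correlate"))
    }
    gmean <- function(mat) {
      gl <- groups[colnames(mat)]
      gs <- sort(unique(gl))
      out <- matrix(NA_real_, nrow(mat), length(gs),
                    dimnames = list(rownames(mat), gs))
      for (g in gs) out[, g] <- rowMeans(mat[, gl == g, drop = FALSE])
      out
    }
    mm <- gmean(mm); gm <- gmean(gm)
  }
  res <- purrr::pmap_dfr(pairs, function(mirna, gene, ...) {
    r <- NA_real_; rp <- NA_real_
    if (mirna %in% rownames(mm) && gene %in% rownames(gm)) {
      x <- mm[mirna, ]; y <- gm[gene, ]
      if (stats::sd(x) > 0 && stats::sd(y) > 0) {
        r <- cor(x, y)
        rp <- if (length(x) >= 3) {
          tryCatch(cor.test(x, y)$p.value, error = function(e) NA_real_)
        } else NA_real_
      }
    }
    tibble(mirna = mirna, gene = gene, pearson_r = r, r_p = rp)
  })
  lookup <- function(tbl, keys) {
    if (is.null(tbl)) return(rep(NA_real_, length(keys)))
    tbl$log2fc[match(keys, tbl$feature)]
  }
  res$lfc_mirna <- lookup(mirna_lfc, res$mirna)
  res$lfc_gene <- lookup(gene_lfc, res$gene)
  res$lfc_opposite_sign <- sign(res$lfc_mirna) * sign(res$lfc_gene) < 0
  res$sign_class <- dplyr::case_when(
    is.na(res$pearson_r) ~ "undefined",
    res$pearson_r < 0 ~ "negative",
    TRUE ~ "positive")
  structure(res, class = c("interaction_set", class(tibble())), mode = mode)
}
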