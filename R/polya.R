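#' Read a per-read poly(A) tail-length table
#'
#' Reads a nanopolish-polya-style TSV (tab-separated, header line; required
#' columns `readname`, `contig`, `polya_length`, `qc_tag`; extra columns are
#' tolerated and ignored) and keeps only reads whose QC tag is in
#' `pass_tags`. Spike-in or carrier contigs can be excluded by name prefix.
#'
#' @param tsv path to the TSV.
#' @param pass_tags QC tags retained (default `PASS` and `SUFFCLIP`).
#' @param exclude_prefixes character vector of contig-name prefixes dropped
#'   before QC filtering (e.g. spike-in standards).
#' @return Tibble: `readname`, `contig`, `polya_length`, `qc_tag`. Attribute
#'   `n_dropped_qc` records how many rows the QC filter removed.
#' @export
read_polya_table <- function(tsv, pass_tags = c("PASS", "SUFFCLIP"),
                             exclude_prefixes = NULL) {
  if (!file.exists(tsv)) abort(sprintf("file not found: %s", tsv))
  x <- readr::read_tsv(tsv, show_col_types = FALSE, comment = "#")
  need <- c("readname", "contig", "polya_length", "qc_tag")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(sprintf("poly(A) table lacks required column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  x <- x[, need]
  if (!is.null(exclude_prefixes) && nrow(x) > 0) {
    pat <- paste0("^(", paste(exclude_prefixes, collapse = "|"), ")")
    x <- x[!grepl(pat, x$contig), ]
  }
  keep <- x$qc_tag %in% pass_tags
  n_dropped <- sum(!keep)
  x <- x[keep, ]
  neg <- which(x$polya_length < 0)
  if (length(neg) > 0) {
    abort(sprintf("negative polya_length in %d passing row(s), e.g. row %d",
                  length(neg), neg[1]))
  }
  structure(as_tibble(x), n_dropped_qc = n_dropped)
}

#' Per-transcript poly(A) tail-length comparison between two conditions
#'
#' For every transcript with at least `min_reads` passing reads in *both*
#' conditions, compares the per-read tail-length distributions with a
#' two-sided Mann-Whitney rank-sum test, adjusts p-values across tested
#' transcripts with Benjamini-Hochberg, and flags a transcript significant
#' when the median difference is at least `delta_min` nucleotides and the
#' adjusted p-value is below `padj_max`.
#'
#' @param wt,ko tibbles of per-read records (from [read_polya_table()] or the
#'   simulator), with `contig` and `polya_length`; reads are pooled across
#'   replicates within condition.
#' @param min_reads per-condition minimum read support for testing.
#' @param delta_min minimum absolute median difference (nt) for significance.
#' @param padj_max adjusted p-value cutoff.
#' @param test `"ranksum"` (default, unpaired read populations) or
#'   `"signed_rank"` (paired Wilcoxon on per-sample medians; requires a
#'   `sample` column in both inputs with matching sample pairs in order).
#' @return Tibble of class `polya_comparison`: `transcript`, `n_wt`, `n_ko`,
#'   `median_wt`, `median_ko`, `delta` (KO minus WT), `p`, `padj`,
#'   `significant`, sorted by transcript. Untested transcripts are omitted.
#' @export
per_transcript_polya_test <- function(wt, ko, min_reads = 10L, delta_min = 5,
                                      padj_max = 0.05,
                                      test = c("ranksum", "signed_rank")) {
  test <- match.arg(test)
  stopifnot(all(c("contig", "polya_length") %in% names(wt)),
            all(c("contig", "polya_length") %in% names(ko)))
  nw <- table(wt$contig); nk <- table(ko$contig)
  shared <- intersect(names(nw), names(nk))
  tested <- shared[nw[shared] >= min_reads & nk[shared] >= min_reads]
  tested <- sort(tested)
  if (length(tested) == 0) {
    warn("no transcript passes the per-condition read-support filter")
    return(structure(
      tibble(transcript = character(), n_wt = integer(), n_ko = integer(),
             median_wt = double(), median_ko = double(), delta = double(),
             p = double(), padj = double(), significant = logical()),
      class = c("polya_comparison", class(tibble()))))
  }
  res <- purrr::map_dfr(tested, function(tr) {
    xw <- wt$polya_length[wt$contig == tr]
    xk <- ko$polya_length[ko$contig == tr]
    p <- if (test == "ranksum") {
      suppressWarnings(wilcox.test(xk, xw, alternative = "two.sided"))$p.value
    } else {
      if (!("sample" %in% names(wt)) || !("sample" %in% names(ko))) {
        abort("signed_rank test requires a 'sample' column in both inputs")
      }
      mw <- tapply(xw, wt$sample[wt$contig == tr], median)
      mk <- tapply(xk, ko$sample[ko$contig == tr], median)
      n <- min(length(mw), length(mk))
      suppressWarnings(wilcox.test(as.numeric(mk)[seq_len(n)],
                                   as.numeric(mw)[seq_len(n)],
                                   paired = TRUE))$p.value
    }
    tibble(transcript = tr, n_wt = length(xw), n_ko = length(xk),
           median_wt = median(xw), median_ko = median(xk),
           delta = median(xk) - median(xw), p = p)
  })
  res$padj <- p.adjust(res$p, method = "BH")
  res$significant <- abs(res$delta) >= delta_min & res$padj < padj_max
  structure(res, class = c("polya_comparison", class(tibble())))
}

#' Global poly(A) tail-length distribution summaries
#'
#' Read-level medians and quartiles per condition (each record counted once:
#' distributions are read-weighted, not per-transcript). An optional
#' transcript subset (e.g. differentially expressed genes) restricts records
#' before summarising; subset ids absent from the data are skipped with a
#' warning.
#'
#' @param records tibble of per-read records with `contig`, `polya_length`
#'   and a `condition` column.
#' @param subset optional character vector of transcript ids to restrict to.
#' @param level `"read"` (default) or `"transcript"` (summaries over
#'   per-transcript medians).
#' @return Tibble: `condition`, `n`, `median`, `q25`, `q75`.
#' @export
polya_global_distribution <- function(records, subset = NULL,
                                      level = c("read", "transcript")) {
  level <- match.arg(level)
  stopifnot(all(c("contig", "polya_length", "condition") %in% names(records)))
  if (!is.null(subset)) {
    missing_ids <- setdiff(subset, unique(records$contig))
    if (length(missing_ids) == length(subset)) {
      abort("empty stratum: no subset transcript is present in the data")
    }
    if (length(missing_ids) > 0) {
      warn(sprintf("%d subset transcript(s) absent from the data; skipped",
                   length(missing_ids)))
    }
    records <- records[records$contig %in% subset, ]
  }
  if (nrow(records) == 0) abort("empty stratum: no records to summarise")
  if (level == "transcript") {
    records <- records |>
      group_by(.data$condition, .data$contig) |>
      summarise(polya_length = median(.data$polya_length), .groups = "drop")
  }
  records |>
    group_by(.data$condition) |>
    summarise(n = n(),
              median = median(.data$polya_length),
              q25 = quantile(.data$polya_length, 0.25, names = FALSE),
              q75 = quantile(.data$polya_length, 0.75, names = FALSE),
              .groups = "drop")
}
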