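#' Read-weighted isomiR class fractions for a sample
#'
#' Fractions of reads (default) or of distinct isomiRs falling into each of
#' the four 3'-end classes. Fractions always sum to 1 and every class appears
#' in the output, with 0 where absent.
#'
#' @param profile an `isomir_profile` from [profile_reads()].
#' @param weight `"reads"` (count-weighted, default) or `"isomirs"` (each
#'   distinct isomiR counted once).
#' @return Tibble: `sample_id`, `iso_class`, `n`, `fraction`.
#' @export
class_fractions <- function(profile, weight = c("reads", "isomirs")) {
  weight <- match.arg(weight)
  if (nrow(profile) == 0) abort("empty profile: no isomiR records")
  w <- if (weight == "reads") profile$count else rep(1L, nrow(profile))
  lev <- c("canonical", "trimmed", "nt_tail", "ambiguous")
  n <- vapply(lev, function(cl) sum(w[profile$iso_class == cl]), numeric(1))
  tibble(sample_id = attr(profile, "sample_id"), iso_class = lev,
         n = unname(n), fraction = unname(n) / sum(n))
}

nt_tail_positions <- function(profile) {
  nt <- profile[profile$iso_class == "nt_tail", ]
  if (nrow(nt) == 0) return(NULL)
  tails <- strsplit(nt$ext_seq, "", fixed = TRUE)
  tibble(
    base = unlist(tails),
    position = unlist(lapply(tails, seq_along)),
    count = rep(nt$count, nchar(nt$ext_seq))
  )
}

#' Pooled nucleotide frequencies of non-templated tails
#'
#' Read-count-weighted frequencies of each nucleotide over all positions of
#' all NT tails in a sample. `U` is stored as `T` internally; relabel on
#' output if desired.
#'
#' @param profile an `isomir_profile`.
#' @return Tibble: `sample_id`, `base` (A/C/G/T), `freq` (sums to 1).
#' @export
nt_nucleotide_freq <- function(profile) {
  if (nrow(profile) == 0) abort("empty profile: no isomiR records")
  pos <- nt_tail_positions(profile)
  if (is.null(pos)) abort("profile contains no NT-tailed reads")
  n <- vapply(DNA_BASES, function(b) sum(pos$count[pos$base == b]), numeric(1))
  tibble(sample_id = attr(profile, "sample_id"), base = DNA_BASES,
         freq = unname(n) / sum(n))
}

#' Tail-length and composition breakdown of non-templated tails
#'
#' For each NT-tail length up to `max_len` (longer tails pooled into a final
#' bin): mono-nucleotide categories at length 1, contains-A vs A-free at
#' length 2 and above, full tail-sequence (k-mer) counts at every length, and
#' per-position nucleotide frequencies over all NT tails.
#'
#' @param profile an `isomir_profile`.
#' @param max_len last individually reported tail length; longer tails are
#'   pooled as `">max_len"`.
#' @return List of class `tail_composition`: `by_length` (tibble `tail_len`,
#'   `category`, `count`), `kmers` (`tail_len`, `ext_seq`, `count`),
#'   `positions` (`position`, `base`, `freq`), plus `sample_id` attribute.
#' @export
tail_length_composition <- function(profile, max_len = 3L) {
  if (nrow(profile) == 0) abort("empty profile: no isomiR records")
  nt <- profile[profile$iso_class == "nt_tail", ]
  sample_id <- attr(profile, "sample_id")
  bin <- function(L) ifelse(L > max_len, paste0(">", max_len), as.character(L))
  if (nrow(nt) == 0) {
    out <- list(
      by_length = tibble(tail_len = character(), category = character(),
                         count = integer()),
      kmers = tibble(tail_len = character(), ext_seq = character(),
                     count = integer()),
      positions = tibble(position = integer(), base = character(),
                         freq = double()))
    return(structure(out, class = "tail_composition", sample_id = sample_id))
  }
  L <- nchar(nt$ext_seq)
  kmers <- tibble(tail_len = bin(L), ext_seq = nt$ext_seq, count = nt$count) |>
    group_by(.data$tail_len, .data$ext_seq) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    arrange(.data$tail_len, .data$ext_seq)
  category <- ifelse(L == 1L, paste0("mono(", nt$ext_seq, ")"),
                     ifelse(grepl("A", nt$ext_seq, fixed = TRUE),
                            "contains_A", "A_free"))
  by_length <- tibble(tail_len = bin(L), category = category, count = nt$count) |>
    group_by(.data$tail_len, .data$category) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    arrange(.data$tail_len, .data$category)
  pos <- nt_tail_positions(profile) |>
    group_by(.data$position, .data$base) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    group_by(.data$position) |>
    mutate(freq = .data$count / sum(.data$count)) |>
    ungroup() |>
    select("position", "base", "freq")
  structure(list(by_length = by_length, kmers = kmers, positions = pos),
            class = "tail_composition", sample_id = sample_id)
}

#' Two-group rank-sum comparison of per-sample statistics
#'
#' Two-sided Mann-Whitney rank-sum test between two groups of per-sample
#' values (e.g. per-sample NT-tail A-frequencies by genotype). The exact
#' distribution is used when the combined sample size is at most 12 and there
#' are no ties; otherwise the normal approximation with tie correction.
#' Significance is declared at alpha = 0.05 without multiplicity correction
#' (descriptive panels; differential testing applies BH separately).
#'
#' @param x,y numeric vectors of per-sample values (each of length >= 2).
#' @param statistic_name label carried into the result.
#' @param method `"auto"` (default), `"exact"` or `"normal"`.
#' @param alpha significance level.
#' @return List of class `group_comparison`: `statistic_name`, `x`, `y`,
#'   `statistic` (Mann-Whitney W), `p`, `significant`, `method`.
#' @export
compare_groups <- function(x, y, statistic_name = "statistic",
                           method = c("auto", "exact", "normal"), alpha = 0.05) {
  method <- match.arg(method)
  if (length(x) < 2 || length(y) < 2) {
    abort("each group needs at least 2 values")
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- switch(method,
    auto = (length(x) + length(y) <= 12) && !ties,
    exact = TRUE,
    normal = FALSE)
  if (exact && ties) {
    warn("exact method requested with ties; falling back to normal approximation")
    exact <- FALSE
  }
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact, correct = !exact))
  structure(
    list(statistic_name = statistic_name, x = x, y = y,
         statistic = unname(wt$statistic), p = wt$p.value,
         significant = wt$p.value < alpha,
         method = if (exact) "exact" else "normal"),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: n = %d vs %d, W = %g, p = %.4g (%s)%s\n",
              x$statistic_name, length(x$x), length(x$y), x$statistic, x$p,
              x$method, if (x$significant) " *" else ""))
  invisible(x)
}
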