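#' Assignment parameters for isomiR profiling
#'
#' Thresholds mirroring the QuagmiR-style assignment strategy: reads are
#' matched to matures by an exact internal motif at a fixed 5'-anchored
#' position, and accepted when the Levenshtein distance between the read and
#' mature 3' regions downstream of the motif is at most `edit_distance_3p`.
#' Per miRNA, a distinct read sequence (isomiR) is retained when its count is
#' at least `min_read` or its within-miRNA count fraction is at least
#' `min_ratio` (`filter_rule = "or"`, the default; `"and"` requires both).
#'
#' @param min_ratio minimum within-miRNA count fraction for retention.
#' @param min_read minimum read count for retention.
#' @param edit_distance_3p maximum 3' Levenshtein distance for assignment.
#' @param filter_rule `"or"` (default) or `"and"` combination of the two
#'   retention thresholds.
#' @param five_prime `"exact"` (default): reads must share the mature 5' end
#'   exactly; `"shift1"` additionally tolerates a 1-nt 5' offset.
#' @return A validated list of class `assign_params`.
#' @export
assign_params <- function(min_ratio = 0.1, min_read = 9L, edit_distance_3p = 3L,
                          filter_rule = c("or", "and"),
                          five_prime = c("exact", "shift1")) {
  stopifnot(min_ratio >= 0, min_read >= 0, edit_distance_3p >= 0)
  structure(
    list(min_ratio = min_ratio, min_read = as.integer(min_read),
         edit_distance_3p = as.integer(edit_distance_3p),
         filter_rule = match.arg(filter_rule),
         five_prime = match.arg(five_prime)),
    class = "assign_params")
}

#' Collapse a FASTQ file to distinct read sequences with counts
#'
#' Reads an adapter-trimmed 4-line-record FASTQ and returns one row per
#' distinct sequence. Output order is deterministic: descending count, ties
#' broken lexicographically by sequence.
#'
#' @param fastq path to a FASTQ file (uncompressed or gzipped).
#' @return Tibble with columns `seq` and `count`.
#' @export
collapse_reads <- function(fastq) {
  if (!file.exists(fastq)) abort(sprintf("file not found: %s", fastq))
  lines <- readr::read_lines(fastq)
  if (length(lines) == 0) return(tibble(seq = character(), count = integer()))
  if (length(lines) %% 4 != 0) {
    abort(sprintf("malformed FASTQ: %d lines is not a multiple of 4 (near line %d)",
                  length(lines), length(lines)))
  }
  at <- seq(1L, length(lines), by = 4L)
  bad_hdr <- at[!startsWith(lines[at], "@")]
  if (length(bad_hdr) > 0) {
    abort(sprintf("malformed FASTQ record header at line %d", bad_hdr[1]))
  }
  bad_sep <- (at + 2L)[!startsWith(lines[at + 2L], "+")]
  if (length(bad_sep) > 0) {
    abort(sprintf("malformed FASTQ separator at line %d", bad_sep[1]))
  }
  collapse_seqs(normalize_seq(lines[at + 1L]))
}

collapse_seqs <- function(seqs) {
  if (length(seqs) == 0) return(tibble(seq = character(), count = integer()))
  tb <- table(seqs)
  out <- tibble(seq = names(tb), count = as.integer(tb))
  out[order(-out$count, out$seq), ]
}

#' Assign read sequences to mature miRNAs
#'
#' A read is a candidate for a mature when the mature's motif occurs in the
#' read at the same 5'-anchored position and the bases 5' of the motif match
#' the mature. Among candidates, the Levenshtein distance between the read
#' and mature suffixes downstream of the motif is computed; the read is
#' assigned to the candidate with the smallest distance if that distance is at
#' most `params$edit_distance_3p`, ties broken by lexicographic miRNA name.
#' Non-matching reads get `NA` (unassigned).
#'
#' @param ref a [load_mirna_reference()] object.
#' @param seqs character vector of read sequences.
#' @param params an [assign_params()] object.
#' @return Character vector of mature names (`NA` = unassigned), one per input.
#' @export
assign_reads <- function(ref, seqs, params = assign_params()) {
  stopifnot(inherits(ref, "mirna_reference"))
  span <- ref$motif_span
  shifts <- if (params$five_prime == "shift1") c(0L, -1L, 1L) else 0L

  mat <- ref$matures
  mat_suffix <- setNames(substring(mat$seq, span[2] + 1L, nchar(mat$seq)), mat$name)
  mat_prefix <- setNames(substr(mat$seq, 1L, span[1]), mat$name)

  out <- rep(NA_character_, length(seqs))
  best_d <- rep(Inf, length(seqs))
  best_sh <- rep(Inf, length(seqs))
  for (sh in shifts) {
    motifs <- substr(seqs, span[1] + 1L + sh, span[2] + sh)
    # pre-motif bases must match the mature (5' anchoring; under a 5'
    # shift the comparison is over the aligned part of the prefix)
    pres <- substr(seqs, max(1L, 1L + sh), span[1] + sh)
    sfxs <- substring(seqs, span[2] + 1L + sh, nchar(seqs))
    for (motif in unique(motifs)) {
      cand <- ref$motif_index[[motif]]
      if (is.null(cand)) next
      cand <- sort(cand)
      idx <- which(motifs == motif)
      want_pre <- substr(mat_prefix[cand], max(1L, 1L - sh), span[1])
      # distances of every read suffix against every candidate suffix
      d <- utils::adist(sfxs[idx], mat_suffix[cand])  # |idx| x |cand|
      for (ci in seq_along(cand)) {
        ok <- pres[idx] == want_pre[ci]
        di <- ifelse(ok, d[, ci], Inf)
        upd <- di < best_d[idx] |
          (di == best_d[idx] & abs(sh) < best_sh[idx]) |
          (di == best_d[idx] & abs(sh) == best_sh[idx] &
             (is.na(out[idx]) | cand[ci] < out[idx]))
        upd <- which(!is.na(upd) & upd & is.finite(di))
        if (length(upd) > 0) {
          j <- idx[upd]
          out[j] <- cand[ci]
          best_d[j] <- di[upd]
          best_sh[j] <- abs(sh)
        }
      }
    }
  }
  out[best_d > params$edit_distance_3p] <- NA_character_
  out
}

#' Classify a read's 3' end relative to its assigned mature miRNA
#'
#' Implements the four-class 3'-end taxonomy against genomic context:
#' \describe{
#'   \item{canonical}{read equals the annotated mature sequence.}
#'   \item{trimmed}{read is a proper 5'-anchored prefix of the mature.}
#'   \item{nt_tail}{read extends past the mature 3' end and the extension does
#'     not match the genomic (pri) sequence downstream.}
#'   \item{ambiguous}{the extension matches the genomic downstream sequence in
#'     full (templated — indistinguishable from processing variation), or the
#'     read is shorter than the mature and carries any extension.}
#' }
#' The whole-extension rule applies: an extension is genomic only when every
#' base matches the flank; a single mismatch makes the entire extension
#' non-templated.
#'
#' @param ref a [load_mirna_reference()] object.
#' @param mirna mature name the read was assigned to.
#' @param seq read sequence (must share the mature 5' end).
#' @return A one-row tibble: `iso_class`, `trim_len`, `ext_seq`,
#'   `ext_is_genomic`.
#' @export
classify_isomir <- function(ref, mirna, seq) {
  i <- match(mirna, ref$matures$name)
  if (is.na(i)) abort(sprintf("unknown miRNA: '%s'", mirna))
  m <- ref$matures$seq[i]
  k <- common_prefix_len(seq, m)
  if (k == 0L) {
    abort(sprintf("read is not 5'-anchored to mature '%s'", mirna))
  }
  lm <- nchar(m); ls <- nchar(seq)
  if (identical(seq, m)) {
    return(tibble(iso_class = "canonical", trim_len = 0L,
                  ext_seq = "", ext_is_genomic = FALSE))
  }
  if (k == ls && ls < lm) {  # proper prefix of the mature
    return(tibble(iso_class = "trimmed", trim_len = lm - ls,
                  ext_seq = "", ext_is_genomic = FALSE))
  }
  e <- substr(seq, k + 1L, ls)
  if (k == lm) {  # full-length mature plus an extension
    g <- genomic_extension(ref, mirna, nchar(e))
    genomic <- nchar(g) == nchar(e) && identical(as.character(g), e)
    if (genomic) {
      return(tibble(iso_class = "ambiguous", trim_len = 0L,
                    ext_seq = e, ext_is_genomic = TRUE))
    }
    return(tibble(iso_class = "nt_tail", trim_len = 0L,
                  ext_seq = e, ext_is_genomic = FALSE))
  }
  # shorter than the mature (or diverging within it) with an extension:
  # ambiguous either way under the whole-extension rule
  pseq <- ref$pris[[ref$matures$pri_name[i]]]
  gstart <- ref$matures$offset[i] + k + 1L
  gcont <- substr(pseq, gstart, min(gstart + nchar(e) - 1L, nchar(pseq)))
  genomic <- nchar(gcont) == nchar(e) && identical(gcont, e)
  tibble(iso_class = "ambiguous", trim_len = lm - k,
         ext_seq = e, ext_is_genomic = genomic)
}

# vectorised batch classification; same contract as classify_isomir row-wise
classify_many <- function(ref, mirnas, seqs) {
  n <- length(seqs)
  iso_class <- character(n); trim_len <- integer(n)
  ext_seq <- character(n); ext_is_genomic <- logical(n)
  for (mir in unique(mirnas)) {
    i <- match(mir, ref$matures$name)
    if (is.na(i)) abort(sprintf("unknown miRNA: '%s'", mir))
    m <- ref$matures$seq[i]
    lm <- nchar(m)
    flank <- as.character(genomic_extension(ref, mir,
                                            max(max(nchar(seqs)) - lm, 1L)))
    idx <- which(mirnas == mir)
    sq <- seqs[idx]
    ls <- nchar(sq)
    canonical <- sq == m
    extended <- ls > lm & substr(sq, 1L, lm) == m
    trimmed <- ls < lm & sq == substring(m, 1L, ls)
    iso_class[idx[canonical]] <- "canonical"
    iso_class[idx[trimmed]] <- "trimmed"
    trim_len[idx[trimmed]] <- lm - ls[trimmed]
    if (any(extended)) {
      e <- substring(sq[extended], lm + 1L, ls[extended])
      genomic <- nchar(e) <= nchar(flank) & e == substring(flank, 1L, nchar(e))
      iso_class[idx[extended]] <- ifelse(genomic, "ambiguous", "nt_tail")
      ext_seq[idx[extended]] <- e
      ext_is_genomic[idx[extended]] <- genomic
    }
    rest <- which(!(canonical | extended | trimmed))
    for (j in rest) {
      one <- classify_isomir(ref, mir, sq[j])
      iso_class[idx[j]] <- one$iso_class
      trim_len[idx[j]] <- one$trim_len
      ext_seq[idx[j]] <- one$ext_seq
      ext_is_genomic[idx[j]] <- one$ext_is_genomic
    }
  }
  tibble(iso_class = iso_class, trim_len = trim_len, ext_seq = ext_seq,
         ext_is_genomic = ext_is_genomic)
}

#' Profile a sample: collapse, assign, classify and filter isomiRs
#'
#' Runs the full per-sample isomiR pipeline on an adapter-trimmed FASTQ:
#' reads are collapsed to distinct sequences, assigned to matures, classified
#' by 3'-end type, and retained per the [assign_params()] thresholds (within
#' each miRNA, an isomiR is kept when `count >= min_read` or
#' `count / miRNA total >= min_ratio`).
#'
#' @param ref a [load_mirna_reference()] object.
#' @param fastq path to the sample FASTQ.
#' @param params an [assign_params()] object.
#' @param sample_id,genotype sample annotations carried on the result.
#' @return A tibble of class `isomir_profile` with columns `mirna`, `seq`,
#'   `count`, `iso_class`, `trim_len`, `ext_seq`, `ext_is_genomic`, and
#'   attributes `sample_id`, `genotype`, `n_assigned` (sum of retained
#'   counts), `n_unassigned`, `dropped` (tibble logging filtered isomiRs).
#' @export
profile_sample <- function(ref, fastq, params = assign_params(),
                           sample_id = basename(fastq), genotype = NA_character_) {
  reads <- collapse_reads(fastq)
  if (nrow(reads) == 0) warn(sprintf("empty FASTQ: %s", fastq))
  profile_reads(ref, reads, params, sample_id = sample_id, genotype = genotype)
}

#' @rdname profile_sample
#' @param reads tibble with columns `seq`, `count` (e.g. from
#'   [collapse_reads()]); `profile_reads()` is the in-memory entry point.
#' @export
profile_reads <- function(ref, reads, params = assign_params(),
                          sample_id = NA_character_, genotype = NA_character_) {
  stopifnot(inherits(ref, "mirna_reference"), all(c("seq", "count") %in% names(reads)))
  reads <- collapse_seqs(rep(reads$seq, reads$count)) # idempotent; enforces order rule
  if (nrow(reads) == 0) {
    return(new_isomir_profile(empty_profile_records(), sample_id, genotype,
                              n_unassigned = 0L,
                              dropped = empty_profile_records()[0, 1:3]))
  }
  reads$mirna <- assign_reads(ref, reads$seq, params)
  unassigned <- sum(reads$count[is.na(reads$mirna)])
  rec <- reads[!is.na(reads$mirna), ]
  if (nrow(rec) == 0) {
    warn("no reads assigned to any miRNA")
    return(new_isomir_profile(empty_profile_records(), sample_id, genotype,
                              n_unassigned = unassigned,
                              dropped = empty_profile_records()[0, 1:3]))
  }
  cls <- classify_many(ref, rec$mirna, rec$seq)
  rec <- dplyr::bind_cols(rec[, c("mirna", "seq", "count")], cls)

  rec <- rec |>
    group_by(.data$mirna) |>
    mutate(.ratio = .data$count / sum(.data$count)) |>
    ungroup()
  keep <- if (params$filter_rule == "or") {
    rec$count >= params$min_read | rec$.ratio >= params$min_ratio
  } else {
    rec$count >= params$min_read & rec$.ratio >= params$min_ratio
  }
  dropped <- rec[!keep, c("mirna", "seq", "count")]
  if (nrow(dropped) > 0) {
    dropped$reason <- sprintf("count %d < min_read and ratio below min_ratio",
                              dropped$count)
  } else {
    dropped$reason <- character(0)
  }
  rec <- rec[keep, setdiff(names(rec), ".ratio")]
  rec <- rec[order(rec$mirna, -rec$count, rec$seq), ]
  new_isomir_profile(rec, sample_id, genotype,
                     n_unassigned = unassigned, dropped = dropped)
}

empty_profile_records <- function() {
  tibble(mirna = character(), seq = character(), count = integer(),
         iso_class = character(), trim_len = integer(), ext_seq = character(),
         ext_is_genomic = logical())
}

new_isomir_profile <- function(records, sample_id, genotype, n_unassigned, dropped) {
  structure(records,
            class = c("isomir_profile", class(tibble())),
            sample_id = sample_id, genotype = genotype,
            n_assigned = sum(records$count), n_unassigned = n_unassigned,
            dropped = dropped)
}

#' Build an isomiR count matrix across sample profiles
#'
#' Combines per-sample profiles into one feature-by-sample count table, with a
#' feature annotation table mapping features back to miRNA, class and tail
#' sequence. Feature ids are `"<mirna>|<seq>"`.
#'
#' @param profiles named list of [profile_reads()] results (names = sample ids;
#'   unnamed lists fall back to each profile's `sample_id` attribute).
#' @return List with `counts` (tibble: `feature` + one column per sample) and
#'   `features` (tibble: `feature`, `mirna`, `seq`, `iso_class`, `trim_len`,
#'   `ext_seq`, `ext_is_genomic`).
#' @export
isomir_count_matrix <- function(profiles) {
  ids <- names(profiles) %||% vapply(profiles, attr, "", "sample_id")
  if (is.null(names(profiles))) names(profiles) <- ids
  long <- purrr::imap_dfr(profiles, function(p, id) {
    tibble(sample = id, feature = paste(p$mirna, p$seq, sep = "|"),
           mirna = p$mirna, seq = p$seq, iso_class = p$iso_class,
           trim_len = p$trim_len, ext_seq = p$ext_seq,
           ext_is_genomic = p$ext_is_genomic, count = p$count)
  })
  features <- long |>
    distinct(.data$feature, .data$mirna, .data$seq, .data$iso_class,
             .data$trim_len, .data$ext_seq, .data$ext_is_genomic) |>
    arrange(.data$feature)
  counts <- long |>
    select("feature", "sample", "count") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "count",
                       values_fill = 0L) |>
    arrange(.data$feature)
  list(counts = counts, features = features)
}
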