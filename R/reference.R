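#' Load and validate a miRNA reference
#'
#' Reads mature miRNA sequences, pri-miRNA (primary transcript) sequences and
#' a mature-to-pri anchoring table, validates their consistency, and builds the
#' motif index used for read assignment. Sequences are stored in DNA space:
#' `U` is converted to `T` on ingest, so miRBase-style RNA FASTA files are
#' accepted directly.
#'
#' The pri-miRNA sequence provides the genomic context 3' of each mature end,
#' against which 3' extensions are later called templated or non-templated.
#' Every mature must have at least `flank_min` bases of pri sequence downstream
#' of its 3' end (tails are analysed up to that length).
#'
#' @param mature_fasta path to a FASTA file of mature miRNA sequences.
#' @param pri_fasta path to a FASTA file of pri-miRNA sequences.
#' @param mapping_tsv path to a TSV with columns `mature_name`, `pri_name`,
#'   `offset` (0-based start of the mature within its pri).
#' @param motif_span integer pair: 0-based half-open span of the assignment
#'   motif within the mature sequence. Default `c(2, 15)`, a 13-mer.
#' @param flank_min minimum downstream pri bases required per mature.
#' @return An object of class `mirna_reference`: a list with `matures`
#'   (tibble: `name`, `seq`, `pri_name`, `offset`, `motif`), `pris` (named
#'   character vector), `motif_index`, `motif_span` and `flank_min`.
#' @examples
#' ref <- simulate_reference(n_mirnas = 3, seed = 1)
#' ref$matures
#' @export
load_mirna_reference <- function(mature_fasta, pri_fasta, mapping_tsv,
                                 motif_span = c(2L, 15L), flank_min = 8L) {
  for (f in c(mature_fasta, pri_fasta, mapping_tsv)) {
    if (!file.exists(f)) abort(sprintf("file not found: %s", f))
  }
  mat <- Biostrings::readBStringSet(mature_fasta)
  pri <- Biostrings::readBStringSet(pri_fasta)
  map <- readr::read_tsv(mapping_tsv, show_col_types = FALSE, comment = "#")
  need <- c("mature_name", "pri_name", "offset")
  miss <- setdiff(need, names(map))
  if (length(miss) > 0) {
    abort(sprintf("mapping TSV lacks required column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  mat_names <- sub("\\s.*$", "", names(mat))
  pri_names <- sub("\\s.*$", "", names(pri))
  build_mirna_reference(
    matures = tibble(name = mat_names, seq = normalize_seq(as.character(mat))),
    pris = setNames(normalize_seq(as.character(pri)), pri_names),
    mapping = map,
    motif_span = motif_span, flank_min = flank_min
  )
}

# assemble and validate the reference from in-memory parts
build_mirna_reference <- function(matures, pris, mapping,
                                  motif_span = c(2L, 15L), flank_min = 8L) {
  if (anyDuplicated(matures$name)) {
    abort(sprintf("duplicate mature names: %s",
                  paste(unique(matures$name[duplicated(matures$name)]), collapse = ", ")))
  }
  if (anyDuplicated(names(pris))) abort("duplicate pri-miRNA names")
  check_dna(matures$seq, "mature sequence")
  check_dna(unname(pris), "pri-miRNA sequence")

  matures$name <- unname(as.character(matures$name))
  matures$seq <- unname(as.character(matures$seq))
  map <- mapping |>
    mutate(mature_name = as.character(.data$mature_name),
           pri_name = as.character(.data$pri_name),
           offset = as.integer(.data$offset))
  m <- matures |>
    left_join(map, by = c(name = "mature_name"))
  if (anyNA(m$pri_name)) {
    abort(sprintf("mature(s) missing from mapping: %s",
                  paste(m$name[is.na(m$pri_name)], collapse = ", ")))
  }
  unknown_pri <- setdiff(m$pri_name, names(pris))
  if (length(unknown_pri) > 0) {
    abort(sprintf("mapping names pri-miRNA(s) absent from pri FASTA: %s",
                  paste(unknown_pri, collapse = ", ")))
  }

  for (i in seq_len(nrow(m))) {
    sq <- m$seq[i]; len <- nchar(sq)
    if (len < 16L) {
      abort(sprintf("mature '%s' is shorter than 16 nt (%d)", m$name[i], len))
    }
    pseq <- pris[[m$pri_name[i]]]
    off <- m$offset[i]
    anchored <- substr(pseq, off + 1L, off + len)
    if (!identical(anchored, sq)) {
      abort(sprintf(
        "reference inconsistency: mature '%s' not found in pri '%s' at offset %d",
        m$name[i], m$pri_name[i], off))
    }
    flank <- nchar(pseq) - (off + len)
    if (flank < flank_min) {
      abort(sprintf(
        "mature '%s' has only %d downstream bases in pri '%s' (flank_min = %d)",
        m$name[i], flank, m$pri_name[i], flank_min))
    }
  }

  if (any(nchar(m$seq) < motif_span[2])) {
    abort("motif_span extends past the end of a mature sequence")
  }
  m$motif <- substr(m$seq, motif_span[1] + 1L, motif_span[2])
  motif_index <- split(m$name, m$motif)

  structure(
    list(matures = as_tibble(m[, c("name", "seq", "pri_name", "offset", "motif")]),
         pris = pris,
         motif_index = motif_index,
         motif_span = as.integer(motif_span),
         flank_min = as.integer(flank_min)),
    class = "mirna_reference"
  )
}

#' @export
print.mirna_reference <- function(x, ...) {
  cat(sprintf("<mirna_reference> %d matures in %d pri-miRNAs; motif span [%d, %d)\n",
              nrow(x$matures), length(x$pris), x$motif_span[1], x$motif_span[2]))
  invisible(x)
}

#' Genomic sequence downstream of a mature miRNA 3' end
#'
#' Returns up to `k` bases of the pri-miRNA sequence immediately 3' of the
#' mature end — the templated continuation a 3' extension is compared against.
#' If fewer than `k` bases remain in the pri, the shorter string is returned
#' with attribute `short_flank = TRUE`.
#'
#' @param ref a [load_mirna_reference()] object.
#' @param mirna mature miRNA name.
#' @param k number of downstream bases requested.
#' @return Character scalar of length at most `k`.
#' @export
genomic_extension <- function(ref, mirna, k) {
  stopifnot(inherits(ref, "mirna_reference"), k >= 1)
  i <- match(mirna, ref$matures$name)
  if (is.na(i)) abort(sprintf("unknown miRNA: '%s'", mirna))
  pseq <- ref$pris[[ref$matures$pri_name[i]]]
  start <- ref$matures$offset[i] + nchar(ref$matures$seq[i]) + 1L
  end <- min(start + k - 1L, nchar(pseq))
  out <- if (end < start) "" else substr(pseq, start, end)
  if (nchar(out) < k) attr(out, "short_flank") <- TRUE
  out
}

#' Write a miRNA reference back to FASTA + mapping TSV
#'
#' Inverse of [load_mirna_reference()]; loading the written files yields an
#' identical reference object.
#'
#' @param ref a `mirna_reference` object.
#' @param mature_fasta,pri_fasta,mapping_tsv output paths.
#' @return Named list of the three paths, invisibly.
#' @export
write_mirna_reference <- function(ref, mature_fasta, pri_fasta, mapping_tsv) {
  stopifnot(inherits(ref, "mirna_reference"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(ref$matures$seq, ref$matures$name)),
    mature_fasta)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(ref$pris), pri_fasta)
  readr::write_tsv(
    ref$matures |>
      select(mature_name = "name", pri_name = "pri_name", offset = "offset"),
    mapping_tsv)
  invisible(list(mature_fasta = mature_fasta, pri_fasta = pri_fasta,
                 mapping_tsv = mapping_tsv))
}
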