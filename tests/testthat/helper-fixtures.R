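# fixtures built in code and independent oracles used across test files

# write a handcrafted reference to temp files and load it
make_reference <- function(matures, pris, mapping, dir = withr_tempdir(),
                           ...) {
  mat_fa <- file.path(dir, "mature.fa")
  pri_fa <- file.path(dir, "pri.fa")
  map_tsv <- file.path(dir, "map.tsv")
  writeLines(as.character(rbind(paste0(">", names(matures)), matures)), mat_fa)
  writeLines(as.character(rbind(paste0(">", names(pris)), pris)), pri_fa)
  readr::write_tsv(mapping, map_tsv)
  load_mirna_reference(mat_fa, pri_fa, map_tsv, ...)
}

withr_tempdir <- function() {
  d <- tempfile("tsfix")
  dir.create(d)
  d
}

# a 20-nt mature with a known 8-nt downstream flank ("GTCAACGG")
tiny_reference <- function() {
  m1 <- "TTTAACGGCATCGAGCTAGA"
  m2 <- "CCGATCGTTAGCAATCGGTA"
  make_reference(
    matures = c(M1 = m1, M2 = m2),
    pris = c(P1 = paste0("AAA", m1, "GTCAACGG"),
             P2 = paste0("TT", m2, "ACCGGTTA")),
    mapping = tibble::tibble(mature_name = c("M1", "M2"),
                             pri_name = c("P1", "P2"),
                             offset = c(3L, 2L)))
}

# brute-force 3'-end classifier: a direct transcription of the four class
# definitions, comparing the read tail base-for-base with the pri sequence
# downstream of where the read and mature diverge
brute_classify <- function(pri, offset, mature, seq) {
  if (identical(seq, mature)) return("canonical")
  k <- 0L
  nmax <- min(nchar(seq), nchar(mature))
  while (k < nmax && substr(seq, k + 1, k + 1) == substr(mature, k + 1, k + 1)) {
    k <- k + 1L
  }
  if (k == nchar(seq) && nchar(seq) < nchar(mature)) return("trimmed")
  tail <- substr(seq, k + 1L, nchar(seq))
  genomic_ctx <- substr(pri, offset + k + 1L, offset + k + nchar(tail))
  tail_matches <- nchar(genomic_ctx) == nchar(tail) && genomic_ctx == tail
  if (nchar(seq) > nchar(mature) && k == nchar(mature)) {
    # longer than the mature
    if (tail_matches) "ambiguous" else "nt_tail"
  } else {
    # diverges before the mature 3' end: ambiguous whether or not the tail
    # is templated (whole-extension rule; templated case is a trimmed
    # isoform of the templated sequence)
    "ambiguous"
  }
}

# every 5'-anchored 3' variant of `mature`: trim up to `max_trim` then append
# every extension up to `max_ext` over ACGT
enumerate_3p_variants <- function(mature, max_trim = 4L, max_ext = 4L) {
  exts <- ""
  for (L in seq_len(max_ext)) {
    exts <- c(exts, do.call(paste0, expand.grid(
      rep(list(c("A", "C", "G", "T")), L), stringsAsFactors = FALSE)))
  }
  out <- character(0)
  for (t in 0:max_trim) {
    pre <- substr(mature, 1L, nchar(mature) - t)
    out <- c(out, paste0(pre, exts))
  }
  unique(out)
}

# 3' Levenshtein distance between a read and the mature, over the region
# downstream of the assignment motif
edit3p <- function(seq, mature, motif_end = 15L) {
  as.integer(utils::adist(substr(seq, motif_end + 1L, nchar(seq)),
                          substr(mature, motif_end + 1L, nchar(mature))))
}

# brute-force Benjamini-Hochberg adjustment
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  for (i in seq_len(n)) {
    adj[o[i]] <- min(1, min(p[o][i:n] * n / (i:n)))
  }
  adj
}

write_fastq <- function(seqs, path) {
  if (length(seqs) == 0) {
    file.create(path)
    return(path)
  }
  writeLines(as.character(rbind(paste0("@r", seq_along(seqs)), seqs, "+",
                                strrep("I", nchar(seqs)))), path)
  path
}
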