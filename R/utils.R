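# shared internal helpers

DNA_BASES <- c("A", "C", "G", "T")

# uppercase and convert RNA alphabet to DNA
normalize_seq <- function(x) chartr("u", "T", chartr("U", "T", toupper(x)))

check_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    abort(sprintf(
      "%s contains non-ACGT characters (after U->T conversion): e.g. '%s'",
      what, x[which(bad)[1]]
    ))
  }
  invisible(x)
}

# length of the longest common prefix of two strings
common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- strsplit(substr(a, 1L, n), "", fixed = TRUE)[[1]]
  bv <- strsplit(substr(b, 1L, n), "", fixed = TRUE)[[1]]
  neq <- which(av != bv)
  if (length(neq) == 0L) n else neq[1] - 1L
}

# deterministic seed stream: derived seeds stay well below 2^31
derive_seed <- function(seed, index) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(index) %% 1000L
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Write a tibble as TSV with a provenance header
#'
#' Prepends comment lines (`#`-prefixed) recording the package version and,
#' optionally, a configuration hash and seed, then the tab-separated table.
#' Files written this way are read back with `readr::read_tsv(comment = "#")`.
#'
#' @param x data frame to write.
#' @param path output file path.
#' @param config_hash optional hash string recorded in the header.
#' @param seed optional integer seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_tsv_provenance <- function(x, path, config_hash = NULL, seed = NULL) {
  hdr <- c(sprintf("# tailscope %s", as.character(packageVersion("tailscope"))))
  if (!is.null(config_hash)) hdr <- c(hdr, sprintf("# config_hash: %s", config_hash))
  if (!is.null(seed)) hdr <- c(hdr, sprintf("# seed: %s", format(seed)))
  writeLines(hdr, path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
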