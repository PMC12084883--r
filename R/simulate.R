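#' Simulation parameters for small-RNA read generation
#'
#' Defaults emulate a wild-type vs terminal-nucleotidyltransferase-knockout
#' hippocampus small-RNA experiment: about 55% canonical reads, ~26.5%
#' trimmed, and a non-templated-tail read fraction of ~11.1% (WT) vs ~9.8%
#' (KO), with NT-tail adenosine emission 0.65 in WT dropping to 0.45 in KO
#' compensated mainly by uridine. Given a read is neither canonical nor
#' trimmed-only, `p_tail` is the probability of a 3' extension; an extension
#' is genomic-templated with probability `p_templated[genotype]`, a mixed
#' templated-prefix/NT-suffix tail with probability `p_mixed`, and otherwise
#' drawn position-i.i.d. from `nt_emission[genotype, ]`.
#'
#' @param depth total reads per sample.
#' @param abundance_dispersion log-normal sigma of per-miRNA abundance.
#' @param p_canonical probability a read equals its mature sequence.
#' @param trim_geom_p geometric parameter for trim length given trimmed
#'   (lengths 1..`max_trim`, truncated and renormalised).
#' @param max_trim maximum simulated trim length.
#' @param p_tail probability of a 3' extension given not canonical.
#' @param p_templated named per-genotype (or scalar) probability an extension
#'   copies the genomic downstream flank.
#' @param p_mixed probability an extension is a templated prefix followed by a
#'   non-templated suffix (exercises the whole-extension classification rule).
#' @param tail_len_dist probability vector over extension lengths 1..3.
#' @param nt_emission 2 x 4 matrix (rows `WT`, `KO`; columns A, C, G, T) of
#'   per-position NT-tail nucleotide probabilities.
#' @param seed base seed; sample `i` of a cohort uses a stream derived from
#'   `seed` and `i`.
#' @return Validated list of class `smallrna_sim_params`.
#' @export
smallrna_sim_params <- function(depth = 1e5,
                                abundance_dispersion = 1,
                                p_canonical = 0.55,
                                trim_geom_p = 0.5,
                                max_trim = 3L,
                                p_tail = 0.41,
                                p_templated = c(WT = 0.295, KO = 0.343),
                                p_mixed = 0.01,
                                tail_len_dist = c(0.6, 0.3, 0.1),
                                nt_emission = rbind(
                                  WT = c(A = 0.65, C = 0.075, G = 0.075, T = 0.20),
                                  KO = c(A = 0.45, C = 0.10, G = 0.10, T = 0.35)),
                                seed = 1L) {
  if (length(p_templated) == 1) {
    p_templated <- c(WT = unname(p_templated), KO = unname(p_templated))
  }
  probs <- c(p_canonical, trim_geom_p, p_tail, p_templated, p_mixed)
  stopifnot(depth > 0, all(probs >= 0 & probs <= 1),
            all(tail_len_dist >= 0), length(tail_len_dist) == 3,
            is.matrix(nt_emission), nrow(nt_emission) == 2,
            ncol(nt_emission) == 4,
            all(abs(rowSums(nt_emission) - 1) < 1e-8))
  tail_len_dist <- tail_len_dist / sum(tail_len_dist)
  rownames(nt_emission) <- c("WT", "KO")
  colnames(nt_emission) <- DNA_BASES
  structure(
    list(depth = as.integer(depth), abundance_dispersion = abundance_dispersion,
         p_canonical = p_canonical, trim_geom_p = trim_geom_p,
         max_trim = as.integer(max_trim), p_tail = p_tail,
         p_templated = p_templated, p_mixed = p_mixed,
         tail_len_dist = tail_len_dist, nt_emission = nt_emission,
         seed = as.integer(seed)),
    class = "smallrna_sim_params")
}

#' Generate a random synthetic miRNA reference
#'
#' Builds `n_mirnas` random mature sequences embedded in random pri-miRNA
#' context with a uniform-composition downstream flank, guaranteeing distinct
#' assignment motifs. Deterministic given `seed`.
#'
#' @param n_mirnas number of matures.
#' @param mature_len range of mature lengths (inclusive).
#' @param flank_len downstream pri bases per mature.
#' @param upstream_len pri bases 5' of each mature.
#' @param seed integer seed.
#' @return A `mirna_reference` object.
#' @export
simulate_reference <- function(n_mirnas = 30L, mature_len = c(20L, 23L),
                               flank_len = 10L, upstream_len = 5L, seed = 1L) {
  stopifnot(flank_len >= 8L, n_mirnas >= 1L)
  with_seed(derive_seed(seed, 0L), {
    repeat {
      lens <- sample(seq(mature_len[1], mature_len[2]), n_mirnas, replace = TRUE)
      matures <- vapply(lens, function(L) {
        paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
      }, character(1))
      motifs <- substr(matures, 3L, 15L)
      if (!anyDuplicated(motifs)) break
    }
    names <- sprintf("mir-%03d", seq_len(n_mirnas))
    up <- vapply(seq_len(n_mirnas), function(i) {
      paste(sample(DNA_BASES, upstream_len, replace = TRUE), collapse = "")
    }, character(1))
    down <- vapply(seq_len(n_mirnas), function(i) {
      paste(sample(DNA_BASES, flank_len, replace = TRUE), collapse = "")
    }, character(1))
    pris <- setNames(paste0(up, matures, down), sprintf("pri-%03d", seq_len(n_mirnas)))
    build_mirna_reference(
      matures = tibble(name = names, seq = matures),
      pris = pris,
      mapping = tibble(mature_name = names, pri_name = names(pris),
                       offset = upstream_len),
      flank_min = 8L)
  })
}

# enumerate the finite outcome universe for one miRNA: every read sequence the
# generator can emit, its branch probability, and its classification truth
enumerate_outcomes <- function(ref, mirna, params, genotype) {
  i <- match(mirna, ref$matures$name)
  m <- ref$matures$seq[i]
  lm <- nchar(m)
  pt <- unname(params$p_templated[genotype])
  em <- params$nt_emission[genotype, ]
  tl <- params$tail_len_dist

  rows <- list()
  add <- function(seq, prob) rows[[length(rows) + 1L]] <<- list(seq = seq, prob = prob)

  add(m, params$p_canonical)
  p_rest <- 1 - params$p_canonical

  # trimmed-only branch: truncated geometric trim lengths 1..max_trim
  gp <- params$trim_geom_p
  tp <- gp * (1 - gp)^(seq_len(params$max_trim) - 1L)
  tp <- tp / sum(tp)
  for (t in seq_len(params$max_trim)) {
    add(substr(m, 1L, lm - t), p_rest * (1 - params$p_tail) * tp[t])
  }

  p_ext <- p_rest * params$p_tail
  flank <- genomic_extension(ref, mirna, 3L)
  p_nt <- max(1 - pt - params$p_mixed, 0)

  kmers <- function(L) {
    if (L == 0L) return("")
    do.call(paste0, expand.grid(rep(list(DNA_BASES), L),
                                stringsAsFactors = FALSE)[, L:1, drop = FALSE])
  }
  kprob <- function(s, emis) {
    prod(emis[strsplit(s, "", fixed = TRUE)[[1]]])
  }

  for (L in 1:3) {
    pl <- p_ext * tl[L]
    # templated: copy the genomic flank; if the flank were shorter than L the
    # mass is re-routed to the NT branch (cannot happen at flank_min >= 8)
    if (nchar(flank) >= L) {
      add(paste0(m, substr(flank, 1L, L)), pl * pt)
    } else {
      p_nt_L <- pt
      for (s in kmers(L)) add(paste0(m, s), pl * p_nt_L * kprob(s, em))
    }
    # non-templated: position-i.i.d. emission
    for (s in kmers(L)) add(paste0(m, s), pl * p_nt * kprob(s, em))
    # mixed templated-prefix + NT-suffix (needs L >= 2; L = 1 falls back to NT)
    if (params$p_mixed > 0) {
      if (L == 1L) {
        for (s in kmers(1L)) add(paste0(m, s), pl * params$p_mixed * kprob(s, em))
      } else {
        for (k in seq_len(L - 1L)) {
          pref <- substr(flank, 1L, k)
          for (s in kmers(L - k)) {
            add(paste0(m, pref, s),
                pl * params$p_mixed / (L - 1) * kprob(s, em))
          }
        }
      }
    }
  }

  out <- tibble(
    seq = vapply(rows, `[[`, character(1), "seq"),
    prob = vapply(rows, `[[`, numeric(1), "prob")
  ) |>
    group_by(.data$seq) |>
    summarise(prob = sum(.data$prob), .groups = "drop")
  out$mirna <- mirna
  cls <- classify_many(ref, out$mirna, out$seq)
  dplyr::bind_cols(out, cls)
}

# abundance-weighted outcome table for a whole reference, plus the analytic
# expected summaries recorded in the truth manifest; the (abundance-free)
# enumeration is memoised per (reference, params, genotype)
.outcome_cache <- new.env(parent = emptyenv())

outcome_universe <- function(ref, params, genotype, abundance) {
  key <- rlang::hash(list(ref$matures$seq, ref$pris,
                          params[setdiff(names(params),
                                         c("depth", "seed",
                                           "abundance_dispersion"))],
                          genotype))
  uni <- .outcome_cache[[key]]
  if (is.null(uni)) {
    uni <- purrr::map_dfr(ref$matures$name, enumerate_outcomes,
                          ref = ref, params = params, genotype = genotype)
    .outcome_cache[[key]] <- uni
  }
  uni$weight <- abundance[uni$mirna] * uni$prob
  uni$weight <- uni$weight / sum(uni$weight)
  uni
}

expected_summaries <- function(universe, genotype) {
  cls <- universe |>
    group_by(.data$iso_class) |>
    summarise(fraction = sum(.data$weight), .groups = "drop")
  nt <- universe[universe$iso_class == "nt_tail", ]
  base_w <- setNames(numeric(4), DNA_BASES)
  for (i in seq_len(nrow(nt))) {
    for (b in strsplit(nt$ext_seq[i], "", fixed = TRUE)[[1]]) {
      base_w[b] <- base_w[b] + nt$weight[i]
    }
  }
  list(genotype = genotype,
       class_fractions = setNames(cls$fraction, cls$iso_class),
       nt_base_freq = base_w / sum(base_w))
}

#' Draw per-miRNA abundance weights for a cohort
#'
#' Log-normal relative abundances shared by every sample of a cohort.
#'
#' @param ref a `mirna_reference`.
#' @param params a [smallrna_sim_params()] object.
#' @return Named numeric vector summing to 1.
#' @export
simulate_abundance <- function(ref, params) {
  with_seed(derive_seed(params$seed, 0L), {
    w <- rlnorm(nrow(ref$matures), 0, params$abundance_dispersion)
    setNames(w / sum(w), ref$matures$name)
  })
}

#' Simulate one small-RNA sample
#'
#' Draws `params$depth` reads from the enumerated outcome universe of the
#' reference (canonical / trimmed / templated-tail / NT-tail / mixed-tail
#' structure per [smallrna_sim_params()]), deterministically given
#' `(params$seed, sample_index)`. Optionally writes a 4-line-record FASTQ
#' with constant quality strings (`"I"`); the pipeline entry point is
#' adapter-trimmed reads, so qualities are ignored downstream.
#'
#' @param ref a `mirna_reference`.
#' @param params a [smallrna_sim_params()] object.
#' @param genotype `"WT"` or `"KO"`.
#' @param sample_index integer >= 1; selects the sample's RNG stream.
#' @param abundance per-miRNA weights (from [simulate_abundance()]); drawn
#'   fresh when `NULL`.
#' @param fastq optional path; when given, reads are written there.
#' @return List of class `smallrna_sim`: `reads` (tibble `seq`, `count`),
#'   `fastq` (path or `NULL`), `truth` (genotype, abundance, params echo, and
#'   analytic expected class fractions / NT base frequencies).
#' @export
simulate_smallrna_sample <- function(ref, params, genotype = c("WT", "KO"),
                                     sample_index = 1L, abundance = NULL,
                                     fastq = NULL) {
  genotype <- match.arg(genotype)
  abundance <- abundance %||% simulate_abundance(ref, params)
  uni <- outcome_universe(ref, params, genotype, abundance)
  counts <- with_seed(derive_seed(params$seed, sample_index), {
    as.integer(rmultinom(1, params$depth, uni$weight))
  })
  reads <- collapse_seqs(rep(uni$seq, counts))
  if (!is.null(fastq)) {
    emitted <- uni[counts > 0, ]
    seqs <- rep(emitted$seq, counts[counts > 0])
    recs <- character(4L * length(seqs))
    recs[seq(1, length(recs), 4)] <- sprintf("@sim_%07d", seq_along(seqs))
    recs[seq(2, length(recs), 4)] <- seqs
    recs[seq(3, length(recs), 4)] <- "+"
    recs[seq(4, length(recs), 4)] <- strrep("I", nchar(seqs))
    writeLines(recs, fastq)
  }
  truth <- c(list(abundance = abundance, sample_index = sample_index,
                  seed = params$seed),
             expected_summaries(uni, genotype))
  structure(list(reads = reads, fastq = fastq, truth = truth),
            class = "smallrna_sim")
}

#' Simulate a small-RNA cohort
#'
#' One abundance draw shared across samples; one RNG stream per sample.
#'
#' @inheritParams simulate_smallrna_sample
#' @param genotypes character vector of `"WT"`/`"KO"`, one per sample.
#' @param dir optional directory: when given, sample FASTQs are written as
#'   `<sample_id>.fastq`.
#' @return List with `samples` (named list of [simulate_smallrna_sample()]
#'   results; names `WT1..`, `KO1..`), `genotypes`, `truth` (shared abundance
#'   and per-genotype expected summaries).
#' @export
simulate_smallrna_cohort <- function(ref, params,
                                     genotypes = c(rep("WT", 3), rep("KO", 5)),
                                     dir = NULL) {
  abundance <- simulate_abundance(ref, params)
  ids <- paste0(genotypes, stats::ave(seq_along(genotypes), genotypes,
                                      FUN = seq_along))
  samples <- purrr::map(seq_along(genotypes), function(i) {
    fq <- if (!is.null(dir)) file.path(dir, paste0(ids[i], ".fastq")) else NULL
    simulate_smallrna_sample(ref, params, genotypes[i], sample_index = i,
                             abundance = abundance, fastq = fq)
  })
  names(samples) <- ids
  expected <- purrr::map(c(WT = "WT", KO = "KO"), function(g) {
    expected_summaries(outcome_universe(ref, params, g, abundance), g)
  })
  list(samples = samples, genotypes = setNames(genotypes, ids),
       truth = list(abundance = abundance, expected = expected,
                    seed = params$seed))
}

#' Simulation parameters for per-read poly(A) tail tables
#'
#' Baseline tail lengths are log-normal; transcripts in `shifted_set` get an
#' additive median shift (nt) in KO. A fraction of reads is tagged with
#' non-passing QC labels to exercise the QC filter.
#'
#' @param n_transcripts number of transcripts.
#' @param reads_mean,reads_size negative-binomial mean and size for reads per
#'   transcript per condition.
#' @param baseline_logmean,baseline_logsd log-normal parameters of tail length.
#' @param shifted_set integer or character indices of shifted transcripts.
#' @param shift_nt additive KO median shift (nt) for `shifted_set`.
#' @param qc_fail_rate fraction of reads tagged with a non-passing QC label.
#' @param seed integer seed.
#' @return Validated list of class `polya_sim_params`.
#' @export
polya_sim_params <- function(n_transcripts = 50L, reads_mean = 60,
                             reads_size = 5, baseline_logmean = log(80),
                             baseline_logsd = 0.25, shifted_set = integer(),
                             shift_nt = -10, qc_fail_rate = 0.1, seed = 1L) {
  stopifnot(n_transcripts >= 1, reads_mean > 0, reads_size > 0,
            baseline_logsd > 0, qc_fail_rate >= 0, qc_fail_rate <= 1)
  structure(
    list(n_transcripts = as.integer(n_transcripts), reads_mean = reads_mean,
         reads_size = reads_size, baseline_logmean = baseline_logmean,
         baseline_logsd = baseline_logsd, shifted_set = shifted_set,
         shift_nt = shift_nt, qc_fail_rate = qc_fail_rate,
         seed = as.integer(seed)),
    class = "polya_sim_params")
}

FAIL_TAGS <- c("ADAPTER", "READ_FAILED_LOAD", "NOREGION")

#' Simulate per-read poly(A) tail-length tables for two conditions
#'
#' Emits nanopolish-polya-dialect rows (`readname`, `contig`, `position`,
#' `polya_length`, `qc_tag`) for a WT and a KO condition. Transcripts in
#' `params$shifted_set` receive the stated additive median shift in KO.
#' Deterministic given the seed.
#'
#' @param params a [polya_sim_params()] object.
#' @param wt_tsv,ko_tsv optional output TSV paths.
#' @return List of class `polya_sim`: `wt`, `ko` (tibbles), `truth` (per-
#'   transcript baseline medians, shifted set, shift size, seed), and the
#'   paths when written.
#' @export
simulate_polya_tables <- function(params, wt_tsv = NULL, ko_tsv = NULL) {
  stopifnot(inherits(params, "polya_sim_params"))
  trs <- sprintf("tx-%04d", seq_len(params$n_transcripts))
  shifted <- if (is.numeric(params$shifted_set)) trs[params$shifted_set]
             else as.character(params$shifted_set)
  with_seed(derive_seed(params$seed, 1L), {
    base_med <- rlnorm(params$n_transcripts, params$baseline_logmean,
                       params$baseline_logsd)
    names(base_med) <- trs
    draw <- function(condition, stream) {
      nreads <- rnbinom(params$n_transcripts, mu = params$reads_mean,
                        size = params$reads_size)
      contig <- rep(trs, nreads)
      med <- rep(base_med, nreads)
      shift <- if (condition == "KO") {
        ifelse(contig %in% shifted, params$shift_nt, 0)
      } else 0
      len <- pmax(med * exp(rnorm(length(contig), 0, params$baseline_logsd)) +
                    shift, 0)
      fails <- runif(length(contig)) < params$qc_fail_rate
      tag <- ifelse(fails,
                    FAIL_TAGS[1 + (seq_along(contig) %% length(FAIL_TAGS))],
                    sample(c("PASS", "SUFFCLIP"), length(contig),
                           replace = TRUE, prob = c(0.9, 0.1)))
      tibble(readname = sprintf("%s_read_%06d", condition, seq_along(contig)),
             contig = contig, position = 0L,
             polya_length = round(len, 2), qc_tag = tag)
    }
    wt <- draw("WT"); ko <- draw("KO")
    if (!is.null(wt_tsv)) readr::write_tsv(wt, wt_tsv)
    if (!is.null(ko_tsv)) readr::write_tsv(ko, ko_tsv)
    structure(
      list(wt = wt, ko = ko,
           truth = list(baseline_median = base_med, shifted_set = shifted,
                        shift_nt = params$shift_nt,
                        qc_fail_rate = params$qc_fail_rate, seed = params$seed),
           wt_tsv = wt_tsv, ko_tsv = ko_tsv),
      class = "polya_sim")
  })
}

#' Simulate a negative-binomial gene count matrix with planted effects
#'
#' Gene-wise log-normal baseline means, log-normal library-size factors
#' (recorded in the truth manifest), and NB counts; planted genes get a group
#' mean ratio of `2^log2fc` in KO.
#'
#' @param n_genes number of genes.
#' @param n_per_group samples per group (WT and KO).
#' @param planted tibble with columns `gene` (id or index) and `log2fc`.
#' @param nb_dispersion NB dispersion (`size = 1/nb_dispersion`).
#' @param mean_logmean,mean_logsd log-normal parameters of baseline means.
#' @param libsize_logsd log-normal sigma of library-size factors.
#' @param seed integer seed.
#' @param tsv optional output TSV path.
#' @return List of class `counts_sim`: `counts` (tibble `feature` + samples),
#'   `groups` (named vector), `truth` (baseline means, true size factors,
#'   planted table, seed).
#' @export
simulate_count_matrix <- function(n_genes = 2000L, n_per_group = 5L,
                                  planted = tibble(gene = character(),
                                                   log2fc = numeric()),
                                  nb_dispersion = 0.05,
                                  mean_logmean = log(100), mean_logsd = 1.5,
                                  libsize_logsd = 0.2, seed = 1L, tsv = NULL) {
  genes <- sprintf("gene-%05d", seq_len(n_genes))
  planted <- as_tibble(planted)
  if (nrow(planted) > 0 && is.numeric(planted$gene)) {
    planted$gene <- genes[planted$gene]
  }
  if (!all(planted$gene %in% genes)) abort("planted genes outside gene universe")
  with_seed(derive_seed(seed, 2L), {
    mu <- rlnorm(n_genes, mean_logmean, mean_logsd)
    names(mu) <- genes
    nsam <- 2L * n_per_group
    sf <- rlnorm(nsam, 0, libsize_logsd)
    groups <- rep(c("WT", "KO"), each = n_per_group)
    ids <- paste0(groups, rep(seq_len(n_per_group), 2))
    names(sf) <- ids
    lfc <- setNames(rep(0, n_genes), genes)
    lfc[planted$gene] <- planted$log2fc
    mumat <- outer(mu, sf)
    mumat[, groups == "KO"] <- mumat[, groups == "KO"] * 2^lfc
    k <- matrix(rnbinom(n_genes * nsam, mu = mumat, size = 1 / nb_dispersion),
                n_genes, dimnames = list(genes, ids))
    counts <- dplyr::bind_cols(tibble(feature = genes),
                               as_tibble(as.data.frame(k)))
    if (!is.null(tsv)) readr::write_tsv(counts, tsv)
    structure(
      list(counts = counts, groups = setNames(groups, ids),
           truth = list(baseline_mean = mu, size_factors = sf,
                        planted = planted, nb_dispersion = nb_dispersion,
                        seed = seed)),
      class = "counts_sim")
  })
}

#' Write a cohort truth manifest to a structured text file
#'
#' Serialises the generator ground truth (abundances, expected summaries,
#' planted effects, seeds) as versioned JSON, sufficient to recompute every
#' expected summary without re-reading the generated files.
#'
#' @param truth a truth list from any of the simulators.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_manifest <- function(truth, path) {
  # named atomic vectors become JSON objects, not bare arrays
  listify <- function(x) {
    if (is.list(x)) lapply(x, listify)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  jsonlite::write_json(
    list(manifest_version = 1L, truth = listify(truth)), path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}
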