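default_pipeline_config <- function() {
  list(
    seed = 1L,
    out_dir = "tailscope-out",
    reference = list(n_mirnas = 30L, mature_fasta = NULL, pri_fasta = NULL,
                     mapping_tsv = NULL),
    smallrna = list(depth = 20000L, n_wt = 3L, n_ko = 5L),
    assign = list(min_ratio = 0.1, min_read = 9L, edit_distance_3p = 3L),
    thresholds = list(padj = 0.05, lfc = 1, delta_min = 5, min_reads = 10L),
    polya = list(n_transcripts = 40L, n_shifted = 5L, shift_nt = -10,
                 qc_fail_rate = 0.1),
    genes = list(n_genes = 500L, n_per_group = 3L, n_planted_up = 8L,
                 n_planted_down = 8L, planted_lfc = 2)
  )
}

#' Read and validate a pipeline configuration
#'
#' Loads a YAML configuration (or takes a list), fills defaults, and rejects
#' unknown keys or invalid values before any stage runs.
#'
#' @param config path to a YAML file, or a named list.
#' @return Validated configuration list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  def <- default_pipeline_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  for (sec in names(config)) {
    if (is.list(def[[sec]])) {
      bad <- setdiff(names(config[[sec]]), names(def[[sec]]))
      if (length(bad) > 0) {
        abort(sprintf("unknown config key(s) in '%s': %s", sec,
                      paste(bad, collapse = ", ")))
      }
      def[[sec]] <- modifyList(def[[sec]], config[[sec]])
    } else {
      def[[sec]] <- config[[sec]]
    }
  }
  with(def$thresholds, stopifnot(padj > 0, padj <= 1, lfc >= 0,
                                 delta_min >= 0, min_reads >= 1))
  stopifnot(def$smallrna$depth > 0, def$smallrna$n_wt >= 2,
            def$smallrna$n_ko >= 2, def$genes$n_per_group >= 2)
  structure(def, class = "pipeline_config")
}

config_hash <- function(config) {
  x <- unclass(config)
  # stable serialisation-independent digest of the config content
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  # small deterministic FNV-1a hash (hex) so no digest dependency is needed
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) h <- ((bitwXor(h, b)) * 16777619) %% 4294967296
  sprintf("%08x", h)
}

stage_log <- function(stage, msg) {
  message(sprintf("[tailscope] %s: %s", stage, msg))
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Config-driven orchestration of every stage: reference (loaded from files
#' if configured, otherwise simulated), small-RNA cohort simulation, isomiR
#' profiling, tail summaries and group tests, isomiR differential
#' accumulation, the mono(A)-vs-canonical correlation, poly(A) table
#' simulation and per-transcript testing, gene-count simulation and
#' differential testing, and miRNA:target integration. Every output TSV
#' carries a provenance header (package version, config hash, seed); the run
#' is a pure function of the configuration.
#'
#' @param config a [read_pipeline_config()] input (path, list or validated
#'   object).
#' @return Invisibly, a list with `manifest` (tibble of produced files),
#'   `config_hash`, and the in-memory stage results.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else read_pipeline_config(config)
  hash <- config_hash(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)
  wr <- function(x, f) write_tsv_provenance(x, out(f), config_hash = hash,
                                            seed = cfg$seed)
  t0 <- Sys.time()

  stage_log("reference", "building")
  ref <- if (!is.null(cfg$reference$mature_fasta)) {
    load_mirna_reference(cfg$reference$mature_fasta, cfg$reference$pri_fasta,
                         cfg$reference$mapping_tsv)
  } else {
    simulate_reference(n_mirnas = cfg$reference$n_mirnas, seed = cfg$seed)
  }

  stage_log("smallrna", "simulating cohort and profiling")
  sp <- smallrna_sim_params(depth = cfg$smallrna$depth, seed = cfg$seed)
  genotypes <- c(rep("WT", cfg$smallrna$n_wt), rep("KO", cfg$smallrna$n_ko))
  cohort <- simulate_smallrna_cohort(ref, sp, genotypes)
  ap <- assign_params(min_ratio = cfg$assign$min_ratio,
                      min_read = cfg$assign$min_read,
                      edit_distance_3p = cfg$assign$edit_distance_3p)
  profiles <- purrr::imap(cohort$samples, function(s, id) {
    profile_reads(ref, s$reads, ap, sample_id = id,
                  genotype = cohort$genotypes[[id]])
  })

  stage_log("tails", "summaries and group tests")
  fracs <- purrr::map_dfr(profiles, class_fractions)
  wr(fracs, "class_fractions.tsv")
  freqs <- purrr::map_dfr(profiles, nt_nucleotide_freq)
  wr(freqs, "nt_freq.tsv")
  comp <- purrr::imap_dfr(profiles, function(p, id) {
    tc <- tail_length_composition(p)
    mutate(tc$by_length, sample_id = id)
  })
  wr(comp, "tail_composition.tsv")
  afreq <- freqs |> filter(.data$base == "A")
  wt_ids <- names(cohort$genotypes)[cohort$genotypes == "WT"]
  gc <- compare_groups(afreq$freq[afreq$sample_id %in% wt_ids],
                       afreq$freq[!afreq$sample_id %in% wt_ids],
                       statistic_name = "nt_tail_A_frequency")
  wr(tidy(gc), "group_tests.tsv")

  stage_log("differential", "isomiR differential accumulation")
  icm <- isomir_count_matrix(profiles)
  de_iso <- nb_wald_test(icm$counts, unname(cohort$genotypes[
    setdiff(names(icm$counts), "feature")]))
  de_iso <- call_differential(de_iso, cfg$thresholds$padj, cfg$thresholds$lfc)
  wr(as_tibble(de_iso), "isomir_de.tsv")
  mono <- monoa_canonical_correlation(
    de_iso |> left_join(icm$features, by = "feature"))
  wr(mono$pairs, "monoa_canonical_pairs.tsv")

  stage_log("polya", "tail-length simulation and testing")
  pp <- polya_sim_params(n_transcripts = cfg$polya$n_transcripts,
                         shifted_set = seq_len(cfg$polya$n_shifted),
                         shift_nt = cfg$polya$shift_nt,
                         qc_fail_rate = cfg$polya$qc_fail_rate,
                         seed = cfg$seed)
  psim <- simulate_polya_tables(pp)
  pass <- c("PASS", "SUFFCLIP")
  wtr <- psim$wt[psim$wt$qc_tag %in% pass, ]
  kor <- psim$ko[psim$ko$qc_tag %in% pass, ]
  ptest <- per_transcript_polya_test(wtr, kor,
                                     min_reads = cfg$thresholds$min_reads,
                                     delta_min = cfg$thresholds$delta_min,
                                     padj_max = cfg$thresholds$padj)
  wr(as_tibble(ptest), "polya_per_transcript.tsv")
  glob <- polya_global_distribution(
    bind_rows(mutate(wtr, condition = "WT"), mutate(kor, condition = "KO")))
  wr(glob, "polya_global.tsv")

  stage_log("genes", "count simulation and differential expression")
  gcfg <- cfg$genes
  planted <- tibble(
    gene = seq_len(gcfg$n_planted_up + gcfg$n_planted_down),
    log2fc = c(rep(gcfg$planted_lfc, gcfg$n_planted_up),
               rep(-gcfg$planted_lfc, gcfg$n_planted_down)))
  gsim <- simulate_count_matrix(n_genes = gcfg$n_genes,
                                n_per_group = gcfg$n_per_group,
                                planted = planted, seed = cfg$seed)
  de_gene <- nb_wald_test(gsim$counts, unname(gsim$groups))
  de_gene <- call_differential(de_gene, cfg$thresholds$padj, lfc_min = 0)
  wr(as_tibble(de_gene), "gene_de.tsv")

  stage_log("integrate", "miRNA:target correlation")
  monoa_mirnas <- unique(icm$features$mirna[
    icm$features$iso_class == "nt_tail" & icm$features$ext_seq == "A"])
  de_genes <- de_gene$feature[de_gene$called]
  pairs <- make_synthetic_pairs(monoa_mirnas, de_genes, seed = cfg$seed)
  inter <- if (nrow(pairs) > 0) {
    mirna_norm <- normalize_counts(icm$counts)
    mirna_norm <- mirna_norm |>
      left_join(icm$features[, c("feature", "mirna", "iso_class", "ext_seq")],
                by = "feature") |>
      filter(.data$iso_class == "nt_tail", .data$ext_seq == "A") |>
      mutate(feature = .data$mirna) |>
      select(-"mirna", -"iso_class", -"ext_seq")
    gene_norm <- normalize_counts(gsim$counts)
    correlate_interactions(
      filter_interactions(pairs, monoa_mirnas, de_genes),
      mirna_norm, gene_norm, groups = c(cohort$genotypes, gsim$groups),
      mirna_lfc = de_iso |>
        left_join(icm$features, by = "feature") |>
        filter(.data$iso_class == "nt_tail", .data$ext_seq == "A") |>
        mutate(feature = .data$mirna) |>
        select("feature", "log2fc"),
      gene_lfc = de_gene[, c("feature", "log2fc")])
  } else {
    tibble()
  }
  wr(as_tibble(inter), "interactions.tsv")

  manifest <- tibble(
    file = c("class_fractions.tsv", "nt_freq.tsv", "tail_composition.tsv",
             "group_tests.tsv", "isomir_de.tsv", "monoa_canonical_pairs.tsv",
             "polya_per_transcript.tsv", "polya_global.tsv", "gene_de.tsv",
             "interactions.tsv"),
    path = out(c("class_fractions.tsv", "nt_freq.tsv", "tail_composition.tsv",
                 "group_tests.tsv", "isomir_de.tsv",
                 "monoa_canonical_pairs.tsv", "polya_per_transcript.tsv",
                 "polya_global.tsv", "gene_de.tsv", "interactions.tsv")))
  jsonlite::write_json(
    list(config_hash = hash, seed = cfg$seed, files = manifest$file),
    out("manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  stage_log("done", sprintf("%.1f s elapsed",
                            as.numeric(Sys.time() - t0, units = "secs")))
  invisible(list(manifest = manifest, config_hash = hash, reference = ref,
                 profiles = profiles, class_fractions = fracs,
                 nt_freq = freqs, group_test = gc, isomir_de = de_iso,
                 monoa_correlation = mono, polya = ptest,
                 polya_global = glob, gene_de = de_gene,
                 interactions = inter))
}

# deterministic synthetic miRNA:target pair table linking the two cohorts
make_synthetic_pairs <- function(mirnas, genes, pairs_per_mirna = 3L, seed = 1L) {
  if (length(mirnas) == 0 || length(genes) == 0) {
    return(tibble(mirna = character(), gene = character()))
  }
  with_seed(derive_seed(seed, 9L), {
    purrr::map_dfr(sort(mirnas), function(m) {
      tibble(mirna = m,
             gene = sample(genes, min(pairs_per_mirna, length(genes))))
    }) |> distinct()
  })
}
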