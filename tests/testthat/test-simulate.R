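test_that("small-RNA generation is a pure function of seed and params", {
  ref <- simulate_reference(n_mirnas = 5, seed = 11)
  p <- smallrna_sim_params(depth = 2000, seed = 11)
  d <- withr_tempdir()
  a <- simulate_smallrna_sample(ref, p, "WT", fastq = file.path(d, "a.fastq"))
  b <- simulate_smallrna_sample(ref, p, "WT", fastq = file.path(d, "b.fastq"))
  expect_identical(readLines(file.path(d, "a.fastq")),
                   readLines(file.path(d, "b.fastq")))
  expect_identical(a$reads, b$reads)
  # different sample index -> different stream
  c2 <- simulate_smallrna_sample(ref, p, "WT", sample_index = 2L)
  expect_false(identical(a$reads, c2$reads))
})

test_that("degenerate p_canonical = 1 yields only mature sequences", {
  ref <- simulate_reference(n_mirnas = 4, seed = 5)
  p <- smallrna_sim_params(depth = 1000, p_canonical = 1, seed = 5)
  sim <- simulate_smallrna_sample(ref, p, "WT")
  expect_true(all(sim$reads$seq %in% ref$matures$seq))
  expect_equal(sum(sim$reads$count), 1000L)
})

test_that("empirical NT emission tracks the generator parameters at depth 1e5", {
  ref <- simulate_reference(n_mirnas = 20, seed = 2)
  em <- rbind(WT = c(A = 0.7, C = 0.05, G = 0.05, T = 0.2),
              KO = c(A = 0.45, C = 0.1, G = 0.1, T = 0.35))
  p <- smallrna_sim_params(depth = 1e5, nt_emission = em, p_mixed = 0, seed = 2)
  sim <- simulate_smallrna_sample(ref, p, "WT")
  prof <- profile_reads(ref, sim$reads,
                        assign_params(min_ratio = 0, min_read = 1))
  f <- nt_nucleotide_freq(prof)
  # compare against the analytic expectation from the truth manifest, which
  # accounts for flank-coincident tails classified ambiguous
  expect_equal(f$freq[f$base == "A"],
               unname(sim$truth$nt_base_freq["A"]), tolerance = 0.02 / 0.65)
  # the expectation deviates from the nominal emission (flank-matching NT
  # tails are unobservable; direction depends on the realised flanks) but
  # stays within a plausible band of it
  expect_lt(abs(unname(sim$truth$nt_base_freq["A"]) - 0.7), 0.1)
})

test_that("class fractions converge to the analytic mixture expectation", {
  ref <- simulate_reference(n_mirnas = 20, seed = 8)
  p <- smallrna_sim_params(depth = 1e5, seed = 8)
  sim <- simulate_smallrna_sample(ref, p, "WT")
  prof <- profile_reads(ref, sim$reads,
                        assign_params(min_ratio = 0, min_read = 1))
  cf <- class_fractions(prof)
  for (cl in names(sim$truth$class_fractions)) {
    expect_lt(abs(cf$fraction[cf$iso_class == cl] -
                    sim$truth$class_fractions[[cl]]), 0.01)
  }
  expect_lt(abs(cf$fraction[cf$iso_class == "canonical"] - 0.55), 0.01)
})

test_that("poly(A) simulation respects QC rate, shifts and determinism", {
  p0 <- polya_sim_params(n_transcripts = 30, qc_fail_rate = 0.3, seed = 4)
  s1 <- simulate_polya_tables(p0)
  s2 <- simulate_polya_tables(p0)
  expect_identical(s1$wt, s2$wt)
  expect_identical(s1$ko, s2$ko)
  frac_fail <- mean(!c(s1$wt$qc_tag, s1$ko$qc_tag) %in% c("PASS", "SUFFCLIP"))
  n <- nrow(s1$wt) + nrow(s1$ko)
  expect_lt(abs(frac_fail - 0.3), 3 * sqrt(0.3 * 0.7 / n) + 0.01)

  # null: no planted shift, medians differ only stochastically
  pn <- polya_sim_params(n_transcripts = 20, shifted_set = integer(),
                         qc_fail_rate = 0, seed = 6)
  sn <- simulate_polya_tables(pn)
  res <- per_transcript_polya_test(sn$wt, sn$ko)
  expect_true(all(!res$significant))

  # planted -10 nt shift with ~200 reads/side is flagged
  ps <- polya_sim_params(n_transcripts = 10, reads_mean = 200, reads_size = 50,
                         shifted_set = 1L, shift_nt = -10, qc_fail_rate = 0,
                         seed = 7)
  ss <- simulate_polya_tables(ps)
  res2 <- per_transcript_polya_test(ss$wt, ss$ko)
  expect_true(res2$significant[res2$transcript == "tx-0001"])
  expect_lt(res2$delta[res2$transcript == "tx-0001"], -5)
})

test_that("count simulation plants fold changes and records library factors", {
  # no planted effects: per-gene group means agree within sampling noise
  s0 <- simulate_count_matrix(n_genes = 300, n_per_group = 50,
                              nb_dispersion = 0.01, seed = 9)
  m <- as.matrix(s0$counts[, -1])
  qn <- sweep(m, 2, s0$truth$size_factors, "/")
  g <- s0$groups
  ratio <- rowMeans(qn[, g == "KO"]) / rowMeans(qn[, g == "WT"])
  expect_lt(median(abs(log2(ratio))), 0.1)

  # planted log2FC = 3 is recovered by the differential stage
  s1 <- simulate_count_matrix(n_genes = 400, n_per_group = 5,
                              planted = tibble::tibble(gene = 1L, log2fc = 3),
                              nb_dispersion = 0.05, seed = 10)
  de <- call_differential(nb_wald_test(s1$counts, unname(s1$groups)))
  expect_true(de$called[de$feature == "gene-00001"])
  expect_equal(de$log2fc[de$feature == "gene-00001"], 3, tolerance = 0.25)

  # same seed reproducibility
  s2 <- simulate_count_matrix(n_genes = 400, n_per_group = 5,
                              planted = tibble::tibble(gene = 1L, log2fc = 3),
                              nb_dispersion = 0.05, seed = 10)
  expect_identical(s1$counts, s2$counts)
})

test_that("truth manifests serialise to structured text", {
  ref <- simulate_reference(n_mirnas = 4, seed = 12)
  sim <- simulate_smallrna_sample(ref, smallrna_sim_params(depth = 500, seed = 12),
                                  "KO")
  d <- withr_tempdir()
  path <- write_truth_manifest(sim$truth, file.path(d, "truth.json"))
  back <- jsonlite::read_json(path)
  expect_equal(back$manifest_version, 1L)
  expect_equal(back$truth$genotype, "KO")
  expect_equal(unlist(back$truth$nt_base_freq["A"]),
               unname(sim$truth$nt_base_freq["A"]), ignore_attr = TRUE)
})
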