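# handcrafted profile wrapper for statistics tests
fake_profile <- function(records, sample_id = "S1", genotype = "WT") {
  structure(tibble::as_tibble(records),
            class = c("isomir_profile", class(tibble::tibble())),
            sample_id = sample_id, genotype = genotype,
            n_assigned = sum(records$count), n_unassigned = 0L,
            dropped = records[0, c("mirna", "seq", "count")])
}

rec <- function(mirna, seq, count, iso_class, ext_seq = "", trim_len = 0L,
                ext_is_genomic = FALSE) {
  tibble::tibble(mirna = mirna, seq = seq, count = as.integer(count),
                 iso_class = iso_class, trim_len = as.integer(trim_len),
                 ext_seq = ext_seq, ext_is_genomic = ext_is_genomic)
}

test_that("class fractions are read-weighted and complete", {
  p <- fake_profile(dplyr::bind_rows(
    rec("m1", "A1", 50, "canonical"),
    rec("m1", "A2", 30, "trimmed", trim_len = 1L),
    rec("m1", "A3", 10, "nt_tail", ext_seq = "A"),
    rec("m1", "A4", 10, "ambiguous", ext_seq = "G", ext_is_genomic = TRUE)))
  cf <- class_fractions(p)
  expect_equal(cf$fraction,
               c(canonical = 0.5, trimmed = 0.3, nt_tail = 0.1,
                 ambiguous = 0.1), ignore_attr = TRUE)
  expect_equal(sum(cf$fraction), 1)

  # isomiR-weighted variant counts each distinct sequence once
  p2 <- fake_profile(dplyr::bind_rows(
    rec("m1", "B1", 90, "canonical"),
    rec("m1", "B2", 10, "nt_tail", ext_seq = "T")))
  expect_equal(class_fractions(p2, weight = "isomirs")$fraction,
               c(0.5, 0, 0.5, 0))
  expect_error(class_fractions(fake_profile(rec("m", "x", 1, "canonical")[0, ])),
               "empty")
})

test_that("NT nucleotide frequencies are pooled position counts", {
  p <- fake_profile(dplyr::bind_rows(
    rec("m1", "S1", 3, "nt_tail", ext_seq = "A"),
    rec("m1", "S2", 1, "nt_tail", ext_seq = "TT"),
    rec("m1", "S3", 100, "canonical")))
  f <- nt_nucleotide_freq(p)
  expect_equal(f$freq[f$base == "A"], 3 / 5)
  expect_equal(f$freq[f$base == "T"], 2 / 5)
  expect_equal(sum(f$freq), 1)

  f2 <- nt_nucleotide_freq(fake_profile(rec("m1", "S", 1, "nt_tail",
                                            ext_seq = "ACGT")))
  expect_equal(f2$freq, rep(0.25, 4))

  # distinct errors for empty profile vs no NT tails
  expect_error(nt_nucleotide_freq(fake_profile(rec("m", "x", 1, "canonical")[0, ])),
               "empty")
  expect_error(nt_nucleotide_freq(fake_profile(rec("m", "x", 5, "canonical"))),
               "NT-tailed")
})

test_that("tail composition table categorises lengths and re-aggregates", {
  p <- fake_profile(dplyr::bind_rows(
    rec("m1", "S1", 4, "nt_tail", ext_seq = "A"),
    rec("m1", "S2", 2, "nt_tail", ext_seq = "AT"),
    rec("m1", "S3", 1, "nt_tail", ext_seq = "AA"),
    rec("m1", "S4", 3, "nt_tail", ext_seq = "GG"),
    rec("m1", "S5", 1, "nt_tail", ext_seq = "TTTT"),
    rec("m1", "S6", 10, "canonical")))
  tc <- tail_length_composition(p, max_len = 3)
  bl <- tc$by_length
  expect_equal(bl$count[bl$tail_len == "1" & bl$category == "mono(A)"], 4L)
  expect_equal(bl$count[bl$tail_len == "2" & bl$category == "contains_A"], 3L)
  expect_equal(bl$count[bl$tail_len == "2" & bl$category == "A_free"], 3L)
  expect_equal(bl$count[bl$tail_len == ">3"], 1L)
  # per-length categories cover all NT reads of that length
  expect_equal(sum(bl$count), 11L)
  expect_setequal(tc$kmers$ext_seq, c("A", "AT", "AA", "GG", "TTTT"))

  # mono(A) count is definitionally the reads with ext_seq == "A"
  expect_equal(bl$count[bl$category == "mono(A)"],
               sum(p$count[p$iso_class == "nt_tail" & p$ext_seq == "A"]))

  # marginal consistency: pooling k-mer base counts reproduces nt_nucleotide_freq
  f <- nt_nucleotide_freq(p)
  pooled <- setNames(numeric(4), c("A", "C", "G", "T"))
  for (i in seq_len(nrow(tc$kmers))) {
    for (b in strsplit(tc$kmers$ext_seq[i], "")[[1]]) {
      pooled[b] <- pooled[b] + tc$kmers$count[i]
    }
  }
  expect_equal(unname(pooled / sum(pooled)), f$freq)

  # no NT tails: all-zero table
  tc0 <- tail_length_composition(fake_profile(rec("m", "x", 5, "canonical")))
  expect_equal(nrow(tc0$by_length), 0L)
})

test_that("rank-sum comparison: exact enumeration, symmetry, tie fallback", {
  # complete separation, 3 vs 5, no ties: two-sided p = 2 / choose(8, 3)
  x <- c(10, 11, 12); y <- c(1, 2, 3, 4, 5)
  gc <- compare_groups(x, y)
  expect_equal(gc$method, "exact")
  expect_equal(gc$p, 2 / choose(8, 3))
  expect_true(gc$significant)

  # symmetry under group exchange
  expect_equal(compare_groups(y, x)$p, gc$p)

  # identical groups: p = 1
  gi <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(gi$p, 1)

  # ties force the normal approximation
  expect_warning(gt <- compare_groups(c(1, 1, 2), c(1, 2, 2), method = "exact"),
                 "ties")
  expect_equal(gt$method, "normal")

  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})

test_that("fractions and frequencies normalise on random synthetic profiles", {
  ref <- simulate_reference(n_mirnas = 6, seed = 21)
  for (s in 1:10) {
    p <- smallrna_sim_params(depth = 2000, seed = 20 + s)
    sim <- simulate_smallrna_sample(ref, p, sample(c("WT", "KO"), 1))
    prof <- profile_reads(ref, sim$reads, assign_params(min_ratio = 0, min_read = 1))
    expect_equal(sum(class_fractions(prof)$fraction), 1, tolerance = 1e-9)
    expect_equal(sum(nt_nucleotide_freq(prof)$freq), 1, tolerance = 1e-9)
    tc <- tail_length_composition(prof)
    expect_equal(sum(tc$by_length$count), sum(tc$kmers$count))
  }
})

test_that("emission difference between genotypes is detected across a cohort", {
  ref <- simulate_reference(n_mirnas = 10, seed = 31)
  p <- smallrna_sim_params(depth = 2e4, seed = 31)
  cohort <- simulate_smallrna_cohort(ref, p)
  af <- purrr::imap_dbl(cohort$samples, function(s, id) {
    prof <- profile_reads(ref, s$reads, assign_params(min_ratio = 0, min_read = 1),
                          sample_id = id)
    f <- nt_nucleotide_freq(prof)
    f$freq[f$base == "A"]
  })
  g <- cohort$genotypes
  gc <- compare_groups(af[g == "WT"], af[g == "KO"])
  expect_equal(gc$p, 2 / choose(8, 3))  # complete separation at this depth
  expect_true(gc$significant)
})
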