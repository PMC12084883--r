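# tailscope

RNA 3′-end analysis for a terminal-nucleotidyltransferase knockout design.
TENT2 (GLD2) is a non-canonical cytoplasmic poly(A) polymerase that adds
single adenosines to miRNA 3′ ends and adenylates mRNA poly(A) tails; losing
it should deplete mono(A)-tailed miRNA isoforms and may shift mRNA tail
lengths. `tailscope` implements the statistical pipeline such a study needs,
for bioinformaticians analysing small-RNA sequencing plus nanopore
direct-RNA tail estimates in a two-genotype (e.g. KO vs WT) design:

* **isomiR engine** — collapse adapter-trimmed small-RNA reads, assign them
  to mature miRNAs by an exact 13-mer motif with a 3′ Levenshtein gate
  (distance ≤ 3), and classify every 3′ end against pri-miRNA genomic
  context into *canonical*, *trimmed*, *nt_tail* (non-templated) or
  *ambiguous* (templated or trimmed-with-tail), under a whole-extension
  rule: one mismatch anywhere makes the whole extension non-templated.
* **tail statistics** — read-weighted class fractions, pooled NT-tail
  nucleotide frequencies, tail-length × composition tables, and two-group
  Mann–Whitney rank-sum comparisons (exact when n₁+n₂ ≤ 12 without ties).
* **differential accumulation** — a minimal negative-binomial Wald pipeline:
  median-of-ratios size factors, method-of-moments dispersion, Wald log₂FC
  statistic on a *t* reference with n₁+n₂−2 df, Benjamini–Hochberg
  adjustment; isomiR calls at padj < 0.05 and |log₂FC| > 1.
* **poly(A) comparison** — per-read nanopolish-style tail tables filtered to
  PASS/SUFFCLIP, per-transcript rank-sum tests (≥ 10 reads per condition),
  BH adjustment, significance at |Δmedian| ≥ 5 nt and padj < 0.05, plus
  global distribution summaries.
* **integration** — Pearson correlation of mono(A)-isomiR vs target-mRNA
  expression with sign classification and log₂FC concordance.
* **synthetic-data generator** — ground-truthed FASTQ, poly(A) tables,
  count matrices and pair tables for every stage, with analytic expected
  summaries in a truth manifest.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` on result objects, `autoplot()` / `plot_*()` for figures.

## Worked example

Simulate a 3 WT vs 5 KO cohort at the package's default study conditions
(NT-tail adenosine emission 0.65 in WT vs 0.45 in KO), profile it, and test:

```r
library(tailscope)
ref     <- simulate_reference(n_mirnas = 10, seed = 42)
params  <- smallrna_sim_params(depth = 50000, seed = 42)
cohort  <- simulate_smallrna_cohort(ref, params)
profiles <- purrr::imap(cohort$samples, function(s, id)
  profile_reads(ref, s$reads, assign_params(), sample_id = id,
                genotype = cohort$genotypes[[id]]))

glance(profiles$WT1)
#> # A tibble: 1 × 7
#>   sample_id genotype n_isomirs n_mirnas n_assigned n_unassigned n_dropped
#> 1 WT1       WT             138       10      49403            0       247

af <- purrr::map_dfr(profiles, nt_nucleotide_freq)
a  <- dplyr::filter(af, base == "A")
g  <- cohort$genotypes[a$sample_id]
compare_groups(a$freq[g == "WT"], a$freq[g == "KO"], "NT-tail A frequency")
#> <group_comparison> NT-tail A frequency: n = 3 vs 5, W = 15, p = 0.03571 (exact) *

icm <- isomir_count_matrix(profiles)
de  <- call_differential(nb_wald_test(icm$counts, unname(cohort$genotypes)))
glance(de)
#> # A tibble: 1 × 5
#>   n_features n_tested n_called  n_up n_down
#> 1        177      177       17     8      9
```

The group comparison is the complete-separation exact rank-sum p-value
(2/56 ≈ 0.0357): every WT sample has a higher NT-tail A-frequency than every
KO sample, as planted. The differential stage recovers isomiR accumulation
changes driven by the emission difference (A-rich tails depleted in KO).
`run_pipeline()` orchestrates all stages end-to-end from a YAML config (see
`inst/scripts/tailscope-run.R` for a command-line wrapper), writing every
table with a provenance header (version, config hash, seed).

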