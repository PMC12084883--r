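---
title: "Methods: isomiR 3'-end classification, tail statistics and poly(A) comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isomiR 3'-end classification, tail statistics and poly(A) comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tailscope)
```

tailscope analyses the 3' ends of RNAs in a knockout-vs-wild-type design
built around a non-canonical poly(A) polymerase (TENT2/GLD2-type enzymes that
monoadenylate miRNA 3' ends and adenylate mRNA poly(A) tails). It covers four
statistical stages — isomiR 3'-end decomposition, non-templated (NT) tail
composition, count-based differential accumulation, and per-transcript
poly(A) tail-length comparison — plus a miRNA:target integration step, and a
synthetic-data generator that provides ground truth for every stage.

## IsomiR assignment and 3'-end classification

Reads (adapter-trimmed small-RNA FASTQ) are collapsed to distinct sequences
and assigned to mature miRNAs by an exact internal **motif**: the 13-mer at
0-based positions [2, 15) of the mature. A read is a candidate for a mature
when that motif occurs at the same 5'-anchored position in the read and the
bases 5' of the motif match the mature. Among candidates, the Levenshtein
distance between read and mature 3' regions downstream of the motif decides
the assignment (accepted up to `edit_distance_3p = 3`, ties broken by
smaller distance then lexicographic name). The motif coordinates are a
deterministic, documented choice exposed in `load_mirna_reference()`
(`motif_span`); published motif-based assigners do not pin the coordinates,
so we fix ours and make them configurable.

5' handling: reads must share the mature 5' end exactly. We interpret
"5' variation filtering off" in the upstream tool as *5' variation not
analysed*, so 5'-shifted reads are unassigned; `assign_params(five_prime =
"shift1")` tolerates a 1-nt offset for sensitivity analyses.

Each assigned read is classified against the pri-miRNA genomic context:

* **canonical** — equals the annotated mature sequence;
* **trimmed** — a proper 5'-anchored prefix of the mature;
* **nt_tail** — longer than the mature and the extension does *not* match
  the genomic sequence downstream of the mature 3' end;
* **ambiguous** — longer than the mature with a fully templated extension
  (indistinguishable from processing variation), or shorter than the mature
  with any extension.

The **whole-extension rule** applies throughout: an extension is genomic
only when every base matches the downstream flank; one mismatch anywhere
makes the entire extension non-templated (`ext_seq` is the full extension).
The four-class taxonomy is phrased on whole tails and no published split of
mixed templated-prefix/NT-suffix tails exists, so we do not split them. A
trimmed read with a templated continuation is a trimmed isoform of the
templated sequence and is likewise ambiguous.

Per miRNA, an isomiR is retained when `count >= min_read` (default 9) *or*
its within-miRNA count fraction is `>= min_ratio` (default 0.1). The OR
combination mirrors the retention semantics of the cited profiling tool;
`filter_rule = "and"` is available. All tie-breaks (collapse order,
assignment) are deterministic: count descending, then lexicographic.

## NT-tail statistics

`class_fractions()` reports read-weighted class fractions by default
(per-read populations are what published class-percentage panels show); an
isomiR-weighted variant is available via `weight = "isomirs"`.
`nt_nucleotide_freq()` pools nucleotide counts over all NT-tail positions,
read-count-weighted. `tail_length_composition()` breaks NT tails down by
length (mono-nucleotide categories at length 1; contains-A vs A-free plus
full k-mer counts at length >= 2; lengths beyond `max_len` pooled).
Internally U is stored as T; display functions relabel.

Between-genotype contrasts of per-sample statistics use the two-sided
Mann-Whitney rank-sum test (`compare_groups()`): exact when the combined n
is at most 12 without ties, otherwise the normal approximation with tie
correction. Descriptive panels use alpha = 0.05 without multiplicity
correction; differential testing (below) adjusts with Benjamini-Hochberg.

## Differential accumulation

`nb_wald_test()` is a deliberately minimal negative-binomial pipeline
authored here (the analysis stages are the package's own): median-of-ratios
size factors (log-space median, matching the standard convention at even
feature counts), pooled within-group method-of-moments dispersion with floor
`1e-8`, group means on the pooled normalised scale (sum of counts / sum of
size factors, floored at `1e-6`), and a Wald statistic on the log2 fold
change with standard error from the NB Fisher information. The statistic is
referred to a *t* distribution with `n1 + n2 - 2` degrees of freedom: with
2-5 samples per group the dispersion estimate is noisy and the normal
reference is anticonservative (~0.085 null rate at 5 vs 5 in our
calibration), while the t reference is nominal (~0.049). There is no
dispersion-trend or fold-change shrinkage; this is documented divergence
from full DESeq2-style estimation, and acceptance is on synthetic data only.
IsomiR calls use adjusted p < 0.05 and |log2FC| > 1; gene-level calls use
the adjusted p-value alone.

`monoa_canonical_correlation()` pairs, per miRNA, the log2 fold change of
the mono(A)-tailed isomiR (single non-templated adenosine — the signature
addition of the enzyme) with that of the canonical isomiR and reports the
Pearson correlation, asking whether tailing changes track abundance changes.

## Poly(A) tail-length comparison

Per-read tail-length estimates (nanopolish-polya-dialect TSV) are filtered
to QC tags PASS and SUFFCLIP; spike-in/carrier contigs can be excluded by
name prefix. Reads are pooled across replicate animals within genotype (the
per-condition >= 10 read rule implies pooling); transcripts with fewer than
10 passing reads in either condition are excluded. Each tested transcript is
compared with a two-sided Mann-Whitney rank-sum test, BH-adjusted, and
called significant when the median difference is >= 5 nt and adjusted
p < 0.05. The upstream description names a "Wilcoxon signed-rank" test, but
a signed-rank test is paired and read populations are unpaired; rank-sum is
the applicable default and `test = "signed_rank"` (paired per-sample
medians) is exposed for fidelity experiments. Global distribution summaries
are read-weighted by default (`level = "transcript"` gives per-transcript
medians), because published global-distribution panels plot read-level
distributions; both are available.

## miRNA:target integration

A pair table (miRNA, target gene) is filtered to miRNAs with a quantified
mono(A)-tailed isomiR and differentially accumulated target genes. When at
least 3 matched samples are shared by the miRNA and gene matrices, each
pair's Pearson correlation is computed across them; otherwise the cohorts
are unmatched (the motivating design has 3+5 small-RNA and 3+3 RNA-seq
animals) and the fallback correlates per-genotype mean profiles, making
log2FC sign concordance the primary classification; the mode used is
recorded on the result. Records are classified negative (r < 0), positive
(r > 0) or undefined (constant vectors), and the three fractions sum to 1.

## Synthetic-data generator

The generator is first-class, tested code. Its defaults are the study
conditions the package targets:

* cohort 3 WT vs 5 KO samples, depth 1e5 reads/sample;
* `p_canonical = 0.55` (a bit over half of reads canonical) and trimmed
  reads ~26.5% via `p_tail = 0.41` applied to the non-canonical remainder;
* NT-tail emission per position i.i.d. over A/C/G/U with A = 0.65 (WT)
  vs 0.45 (KO), the deficit compensated mainly by U — the monoadenylation
  loss / uridylation gain signature;
* `p_templated` = 0.295 (WT) / 0.343 (KO). These were derived analytically
  so that the *measured* NT-class read fraction is ~11.1% (WT) and ~9.8%
  (KO): a drawn NT tail that happens to equal the genomic flank is
  classified ambiguous (correctly so — no observer can call it), removing
  an expected `sum(tail_len_dist * 0.25^L)` ~ 17% of drawn NT mass, so the
  branch probability must exceed the target measured fraction;
* tail lengths 1:2:3 at 0.6/0.3/0.1; trim lengths truncated-geometric
  (p = 0.5) over 1-3 so that every generated read passes the distance-3
  assignment gate and measured class fractions equal the mixture analytics;
* mixed templated-prefix/NT-suffix tails at `p_mixed = 0.01` of the
  extension branch, specifically to exercise the whole-extension rule.

Rather than sampling reads one by one, the generator enumerates the finite
per-miRNA outcome universe (tail length <= 3 with i.i.d. emission) and draws
counts with one multinomial — equivalent in distribution, deterministic
given the seed (one RNG stream per sample, derived from `seed` and the
sample index), and fast. The same enumeration yields the truth manifest's
*analytic expected measured summaries*: every outcome sequence is classified
against the reference, so expected class fractions and NT base frequencies
account exactly for flank-coincident tails. Parameter recovery is judged
against these expectations, not the nominal emission, which is unrecoverable
in principle (the expected measured A-frequency deviates from the emission
probability by a reference- and abundance-dependent amount).

What the generator does *not* emulate: sequencing error, adapters, PCR
duplication, 5' heterogeneity, correlated (non-i.i.d.) tail emission,
nanopore signal artefacts. Passing tests therefore demonstrate the
statistical machinery on clean structural ground truth, not robustness to
platform noise.

Poly(A) tables: per-transcript baseline medians are log-normal
(median ~ 80 nt, log-sd 0.25), per-read lengths log-normal around them,
planted transcripts get an additive KO median shift, and a configurable
fraction of rows carries non-passing QC tags. Count matrices: log-normal
baseline means and library-size factors (recorded in the truth manifest),
NB counts, planted genes with exact group mean ratios `2^log2FC`.

## Numerical and design notes

* Coordinates are 0-based half-open at interfaces (`offset`, `motif_span`);
  R-internal code uses 1-based `substr`/`substring`.
* References require >= 8 downstream pri bases per mature (`flank_min`),
  matching the maximum analysed extension length; longer extensions fail
  the distance gate anyway at the default threshold.
* Degenerate inputs are errors, not silent results: empty profiles, no NT
  tails (distinct error), groups with < 2 samples, no all-positive feature
  for size factors, empty strata in subsets.
* Detection of a -10 nt planted median shift under the >= 5 nt rule is
  limited by the sample median difference SE (~ `1.25 * sd * sqrt(2/n)`);
  with tail-length sd = 0.25 x median, >= 95% detection needs several
  hundred reads per side, which is what the power checks use (the >= 10
  read support floor is a validity rule, not a power guarantee).

## Problem sizes used in the checks

The test-suite and acceptance script run, per invocation: the classifier
oracle over ~1,700 enumerated 3' variants; 200 random profiles for
normalisation invariants; 100 cohorts of 8 samples at depth 1e5 for
emission recovery and rank-sum power; 50 null simulations of 2,000 features
(5 vs 5) plus 100 planted-power simulations for the differential stage; 100
poly(A) simulations with planted -10 nt shifts plus a 200-replicate
permutation null; and 50 replicates of 50 repressive miRNA:target pairs.
These sizes make every stochastic criterion a high-probability event under
the stated conditions while keeping a full run in the minutes range.

## Limitations

The NB stage is not a DESeq2 substitute on real data (no dispersion trend,
no shrinkage, no outlier handling). The classifier assumes 5'-exact reads
and terminal-only variation; internal editing is out of scope. The
integration step consumes a pair table; it performs no target prediction.
Nanopore tail estimation itself (basecalling, segmentation) is upstream of
the package: we consume its per-read table.
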