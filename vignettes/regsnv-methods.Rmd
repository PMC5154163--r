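---
title: "Methods: scoring regulatory SNVs in transcription-factor binding sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring regulatory SNVs in transcription-factor binding sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regsnv)
```

## The problem

ChIP-seq reads carry the genotype of the cells they come from. A
single-nucleotide variant (SNV) that falls inside a transcription-factor
binding site can strengthen or weaken the sequence motif the factor
recognizes, and thereby change binding occupancy and the expression of
nearby genes. `regsnv` implements a desk-scale pipeline for nominating such
*regulatory SNVs* (regSNVs) from standard inputs — variant calls, per-dataset
peak files, a reference sequence, position matrices, gene models, and
(optionally) allele pileups and a tumor expression cohort — with the
estrogen receptor (ER) and its estrogen response element (ERE) as the
motivating system.

## The motif-impact statistic

A motif of width $w$ is a position count matrix $c_{jb}$. Against a
background base distribution $q_b$ and total pseudocount $\lambda$ we form
the log-odds score

$$ s(j,b) \;=\; \log_2 \frac{(c_{jb} + \lambda q_b) / (\sum_b c_{jb} + \lambda)}{q_b}. $$

The score of a $w$-mer is the sum of its per-position scores. Because every
$s(j,b)$ is rounded to an integer multiple of a granularity $g$, the exact
distribution of the score of a random background $w$-mer is computable by
position-wise convolution over the integer grid
(`score_distribution()`), and any observed score converts to an exact tail
p-value $P(S \ge s)$ (`score_pvalue()`). This dynamic program is the exact
counterpart of enumerating all $4^w$ sequences and is validated against that
enumeration in the test suite.

For a variant with reference allele $r$ and alternative allele $a$ we build
the two in-silico sequences of length $2w-1$ centered on the variant
(`build_contexts()`); every motif window that overlaps the variant lies
inside this context. Each allele's context is *independently* scanned — all
windows covering the variant, both strands — for its best hit
(`best_hit()`), giving p-values $p_{ref}$ and $p_{alt}$, and the statistic

$$ T \;=\; \log_{10} (p_{ref} / p_{alt}), $$

positive when the alternative allele is the stronger predicted binder.
Significance of $T$ is assessed against its own null: draw a context
i.i.d. from the background, substitute a uniformly chosen alternative base
at the center, and recompute $T$ (`build_ratio_null()`). The null can be
enumerated exactly for small $w$ and is sampled (seeded, reproducible) for
realistic widths. The reported null p-value is the two-sided tail
$P(|T_{null}| \ge |T|)$ with an add-one correction $(k+1)/(n+1)$ in
Monte-Carlo mode so it is never zero; a variant is called a regSNV when this
p-value is below 0.05, and the direction (increase/decrease of binding) is
reported separately.

### Design choices that the problem left open

* **Background model.** Uniform $q_b = 0.25$ by default, overridable. A
  uniform background keeps the score distribution symmetric between strands
  and makes results reproducible without a genome-composition estimate.
* **Pseudocount.** $\lambda = 0.8$ distributed proportionally to the
  background — a common default for count matrices of depth ~100; it only
  matters for zero-count cells.
* **Granularity.** $g = 10^{-3}$ bits. Discretization is the *sole* source
  of approximation in the p-values: each total score moves by at most
  $w g / 2$, and for any matrix the DP probabilities are exact on the
  rounded grid. Halving $g$ doubles memory/time linearly.
* **Null conditioning.** The substituted position is fixed at the context
  center and the alternative base is uniform over the three non-reference
  bases. This is the most direct construction that mirrors how observed
  variants are scored (anchor always covered) and it is testable by full
  enumeration at small $w$.
* **Two-sided null.** Both strengthening and weakening calls are retained,
  with `direction` carrying the sign; a one-sided variant would halve the
  p-values but discard the weakened-site half of the biology.
* **Multiplicity across matrices.** The per-variant `adjusted_p` is a
  Bonferroni correction over the matrices tested (typically two: one JASPAR,
  one TRANSFAC encoding). With correlated matrices this is conservative;
  the raw `null_p` is always reported alongside. Sources whose matrices
  independently call a variant are listed in `databases_supporting`.
* **Tie-breaking.** `best_hit()` prefers the lowest window offset, then the
  '+' strand; `rank_regsnvs()` breaks adjusted-p ties by larger
  $|T|$, then genomic coordinate. Ranking is therefore a deterministic
  permutation of its input.
* **Degenerate sequence.** Windows containing non-ACGT characters are
  skipped; a context in which every window is ambiguous raises an error
  rather than returning a silent zero score.

## Consensus binding sites

Peak sets from $n$ ChIP-seq datasets are combined at base resolution: a
genomic position belongs to the consensus when at least $k$ datasets cover
it (each dataset counted once per base after merging its own overlapping
peaks). Maximal runs of qualifying positions become intervals whose
`support` is the minimum dataset coverage across the run — runs split where
coverage crosses $k$, not at every coverage change, keeping intervals
maximal. The default $k = 6$ reflects the design of requiring six of nine
replicate datasets. Base-level coverage (rather than whole-peak reciprocal
overlap) was chosen because it has an unambiguous per-base counting oracle,
against which the implementation is tested exhaustively.

## Variant filtering

Calls pass when read depth $\ge 10$, site quality $\ge$ Q20, both alleles
are single bases, and the position lies inside the consensus peak set —
the strict "< 10 reads / < Q20 fail" reading of the thresholds. The
quality filter applies to site QUAL (not genotype quality), and indels are
excluded from motif assessment. Each failing call is attributed to the
first rule it fails (depth, quality, type, peak); the order affects only the
report breakdown, never the pass set, which is idempotent and monotone in
the thresholds.

## Annotation and the proximity filter

Positions are classified with precedence exonic > ncRNA > intronic >
promoter > upstream > intergenic. Promoter and upstream are strand-aware
windows upstream of the TSS; their sizes (1 kb and 5 kb) are conventional
values, configurable, since the category labels do not define them. The
nearest gene on each genomic side is found by gene-body distance (0 when
the variant is inside a gene; ties broken lexicographically); the
estrogen-regulated-gene filter keeps binding-increasing calls whose nearest
gene on either side is on the supplied E2 list at a distance strictly
below 5 kb.

## Allele-specific binding and expression association

At heterozygous sites, reads (or cloned colonies) carrying each allele are
counted, and allele enrichment is tested by a 1-df chi-square
goodness-of-fit against 50:50 — the heterozygous null; genotype-informed
expectations can be supplied. Sites with fewer than 10 informative reads
are flagged and not tested, and bases matching neither allele are excluded
as sequencing error. The uncorrected statistic is the default (for counts
21:9 it equals 4.8, p ≈ 0.028); a Yates-corrected variant is exposed as an
option and is the one that tracks the exact binomial test closely (within
0.002 for totals ≥ 30, verified by enumeration).

Carrier status (heterozygous or homozygous variant) is compared with
wild-type within ER-positive samples: the target gene's log2 TPM is tested
with the Mann-Whitney U test (exact when $n+m \le 12$ and tie-free, normal
approximation with tie and continuity correction otherwise), the fold
change is reported as the difference of group means of log2 TPM, and
p-values are Benjamini-Hochberg adjusted across all testable
(regSNV, gene) pairs. Missing genotypes are dropped, not imputed.

## What the synthetic fixtures emulate — and what they do not

`make_fixture()` generates every pipeline input with known truth: an
i.i.d. background genome hosting planted ERE-like motif instances
(width 13, ten high-information columns); *weak-to-strong* variants whose
alternative allele completes the consensus, and strong-to-weak variants in
the opposite direction; nine peak datasets with boundary jitter (sd 20 bp)
and site dropout (15%, floored so every true site keeps $\ge k$ datasets);
a VCF whose depths and qualities straddle the 10-read/Q20 thresholds in
known counts; pileups biased 70:30 toward the stronger-binding allele at
depth 30; and an expression cohort of 200 ER+ (and 50 ER−) samples with 30
carriers per regSNV and a 2 log2-TPM shift for true associations under unit
noise. All randomness derives from one seed through per-file sub-streams,
so outputs are byte-reproducible and adding an output never perturbs the
others.

The fixtures deliberately do **not** model read-level sequencing (no
FASTQ/BAM simulation), reference-allele mapping bias, linkage between
variants, genome composition bias, overdispersed allele counts, or
copy-number effects. Passing the planted-signal tests therefore
demonstrates that the statistics and plumbing are correct, not that the
pipeline's calls on real tumor ChIP-seq are accurate at any particular
rate; on real data, coverage, mapping bias and matrix quality dominate.

## Validation strategy and problem sizes

Every exact computation is tested against an independent brute-force
oracle: score distributions against enumeration of all $4^w$ sequences
($w \le 6$), ratio nulls against enumeration of all contexts and
substitutions ($w \le 4$), consensus against per-base counting on small
genomes, Mann-Whitney against enumeration of all rank arrangements
($n+m \le 12$), and Benjamini-Hochberg against a hand step-up. The
end-to-end checks use a 40-site, 320 kb synthetic study (110 variants, two
matrices, Monte-Carlo nulls of $10^4$ samples) and 100 replicate expression
cohorts — sizes chosen so the full suite completes in a few minutes while
keeping every binomial error bar tight enough for the stated thresholds
(AUROC > 0.9, neutral call rate ≤ 0.05 + 3 SE, power ≥ 0.8, FDR ≤ 0.08).

## Known limitations

* Only single-base substitutions are scored; indels and multi-variant
  haplotypes within one motif window are out of scope.
* One motif width per run: contexts are built for the widest matrix and
  re-scanned per matrix; matrices of very different widths are better run
  separately.
* The Bonferroni "adjusted p" across matrices is conservative when the
  matrices encode nearly the same motif.
* The consensus definition is base-level; pipelines built on whole-peak
  reciprocal overlap will produce different (usually larger) intervals.
* Exact nulls are limited by enumeration size ($4^{2w-1} \times 3$); wider
  motifs use the seeded Monte-Carlo mode, whose resolution is bounded below
  by $1/(n+1)$.
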