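---
title: "Methods: strain genomes, allele-specific expression and the bench statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strain genomes, allele-specific expression and the bench statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainase)
library(dplyr)
```

strainase packages the computational core of a diet-by-genotype study in two
inbred mouse strains (the LG/J x SM/J cross is the motivating system): build
strain-specific genomes from a reference plus per-strain variant calls, lift
annotations onto them, assign F1-hybrid RNA-seq reads to parental haplotypes,
test per-gene allelic bias, test whether a candidate gene set (iron-homeostasis
genes) is enriched inside metabolic QTL, and run the small bench statistics
around the wet-lab assays (relative qPCR quantification, glucose-tolerance
AUC, outlier and normality screens). Because no public sequencing data
accompanies the design, a synthetic-data module generates every input with
recorded ground truth; all statistical guarantees quoted here are properties
the test suite actually computes on that synthetic data.

## Strain genomes and indel-aware liftover

A strain genome is the reference with the strain's alleles substituted in
(`apply_variants()`). Substitutions leave coordinates alone; insertions and
deletions shift everything downstream, so the builder returns a coordinate
map — a piecewise-constant offset function with one breakpoint per indel.
`lift_intervals()` shifts interval boundaries by the cumulative offset at
each coordinate and `invert_coord_map()` gives the reverse direction.

Conventions, fixed once at the I/O boundary: interval tibbles are BED-style
0-based half-open, variant positions are 1-based VCF anchors, and the
internal lift operates on 0-based boundaries so one rule serves starts and
ends alike.

Two boundary questions have no single right answer and are handled
explicitly:

* **Endpoints inside a deleted segment.** Such a coordinate has no image.
  The default policy clamps it to the deletion's edge and flags the interval
  (`lift_flagged`); a strict mode errors instead. Both are offered because
  the treatment of annotations whose boundaries fall inside indels is a
  genuine policy choice, not a derivable fact.
* **Endpoints exactly at an indel.** An interval start sitting at an
  insertion point is pushed past the inserted bases while an end stays
  before them. This tie-break is what makes lift-then-inverse-lift the exact
  identity for every interval that does not intersect an indel footprint — a
  property the suite verifies on a thousand random genomes, alongside an
  independent oracle that relocates a flanking 21-mer in the edited sequence
  by string search.

## Diagnostic sites and read assignment

F1 hybrids are heterozygous wherever the parents differ, so a read can be
assigned to a parent only at *diagnostic sites*: positions where the two
strains carry different alleles, including positions variant in only one
strain (`diagnostic_sites()`). Assignment (`assign_reads()`) compares the
read base against each strain haplotype at the diagnostic SNVs inside the
read's span, after lifting the span onto each haplotype's frame; the
haplotype with fewer mismatches wins, and a tie — or a read covering no
diagnostic site — is called ambiguous rather than forced, the analogue of
disallowing multimapped reads.

Only single-base (SNV-type) differences are scored. An indel difference
inside a read shifts the two alignment frames against each other, so a
base-to-base comparison downstream of it is uninformative: in that regime a
read covering a single diagnostic SNV matches the wrong haplotype by chance
about a quarter of the time and ties into ambiguity. The package accepts
this as an ambiguity cost rather than mis-assigning: with sequencing errors
off, wrongly-assigned reads are rare (bounded by reads whose own span is
distorted by an indel at their start) and with SNV-only variant sets
assignment of covering reads is exact — both are tested. A second known
error floor: a sequencing error at a read's only diagnostic site flips or
ties the call, so the per-read error rate is approximately the per-base
error rate; no base-quality weighting is attempted.

The simulator emits each read with its true origin span ("seeded
alignment"), which is why the pipeline needs no external aligner: spliced
alignment, fragment-length modelling and mapping-bias correction are out of
scope, and the bespoke computation under study is the assignment logic, not
alignment.

## Allelic bias

Per gene, reads assigned to either haplotype form the denominator; the bias
is `n_A / (n_A + n_B)` with ambiguous reads reported but excluded (they
carry no allelic information). Deviation from 0.5 is tested with the exact
binomial test and a Clopper-Pearson 95% interval; the exact test is used
because per-gene counts can be small. A mid-p option halves the point
probability to counteract discreteness; at n = 2000 reads and a balanced
truth the mid-p values are uniform to a Kolmogorov-Smirnov check, and the
intervals' exact coverage (integrated over the binomial pmf) is 0.952-0.956
across true fractions 0.1-0.9. Cross-animal comparisons of per-animal bias
values are a plain two-sample t-test (`compare_bias_groups()`).

Count matrices are normalized by upper-quartile scaling
(`uq_normalize()`): each sample is divided by a factor proportional to the
75th percentile of its nonzero counts, anchored so the factors' geometric
mean is one. This is the definitional form — equalize nonzero upper
quartiles — implemented directly and tested against that defining property.

## QTL enrichment by permutation

`permutation_test()` counts candidate genes overlapping the QTL set (any
shared base; half-open semantics, so abutting intervals do not overlap) and
compares that against `n_perm` redraws of *matched random non-QTL regions*:
one region per QTL, same length, same chromosome, uniform over all start
positions whose full extent avoids the QTL, mutually non-overlapping. The
null keeps genes fixed and randomizes regions. The empirical p-value uses
the +1 correction `(1 + sum(null >= observed)) / (n_perm + 1)`, so the
smallest attainable p at 999 permutations is exactly 1/1000. One-sided
enrichment is the default; matched-length/same-chromosome sampling is the
strictest reading of "random regions of similar size" and removes length
and chromosome composition as confounders (`same_chrom = FALSE` allows
genome-wide placement for sensitivity analysis).

At desk scale the overlap count takes only a handful of distinct values, so
the permutation p is *sub*-uniform under the null — `P(p <= q) <= q` — which
is exactly the validity guarantee a discrete permutation p provides. The
suite checks the 5% rejection bound, sub-uniformity across the scale, and
uniformity of the sampler's start positions by chi-square; no GC, gap or
gene-density covariate matching is attempted.

## Bench statistics

**Relative qPCR quantification** (`delta_delta_ct()`): technical replicates
are averaged on the Ct scale (duplicate assays; the averaging scale is a
choice, made here on Ct), `dCt = target - reference`, `ddCt` is relative to
the control-group mean, and fold change is `efficiency^(-ddCt)` with
efficiency fixed at 2 (the classic method assumes complete amplification; an
efficiency argument exists but defaults to 2). Two consequences are tested:
the control group's geometric-mean fold is exactly 1 by construction, and a
noise-free generated table returns every planted fold — including the
study's 3.6-fold liver induction scenario — to machine precision.

**Glucose tolerance** (`gtt_auc()`): trapezoidal AUC over the recorded
times (protocol: 0, 15, 30, 60, 120 min). Whether total or
baseline-subtracted AUC was meant is not derivable, so both are returned;
the incremental variant clips below-baseline excursions at zero by default
(values are clipped before integration; zero-crossings inside a segment are
not interpolated). AUC is invariant to collinear refinements and additive
over partitions of the time axis.

**Outlier screen** (`grubbs_screen()`): two-sided Grubbs test,
`G = max|x - mean|/sd` against the t-based critical value
`((n-1)/sqrt(n)) * sqrt(t^2/(n-2+t^2))` with `t = qt(1 - alpha/(2n), n-2)`.
The default is the classical single-outlier pass; iterative
remove-and-retest is opt-in. Fewer than three values or zero variance give
an explicit "not applicable" result. Simulated size at n = 15 is 0.050.

**Transform policy** (`log10_policy()`): a Shapiro-Wilk screen at
alpha = 0.05 gates a log10 transform — the normality test backing "log10
transform non-normal parameters" had to be chosen, and Shapiro-Wilk is that
documented choice, not a derived fact. Non-positive values with a transform
indicated raise an error; no silent offsets.

## The synthetic study

`sim_config()` holds every tunable. The defaults describe the emulated
study and were chosen once:

| parameter | default | rationale |
|---|---|---|
| genome | 2 chromosomes x 200 kb | smallest scale at which QTL, genes and promoters coexist comfortably |
| `snv_rate` / `indel_rate` | 0.008 / 0.0008 per base per strain | gives tens of diagnostic sites per gene-plus-promoter region, the density at which the motivating locus shows 58 SNVs in coding + 1 kb proximal promoter; the real genome-wide LG/J-SM/J density is not published, so this is a documented synthetic choice |
| `allelic_fraction` | 0.75 | the focal-gene scenario: ~75% of reads from one parental allele |
| `n_reads` / `read_len` | 2000 / 100 | bulk RNA-seq depth over a single locus |
| `seq_error_rate` | 0.001 | Illumina-like substitution rate |
| `n_qtl` / `qtl_len_range` | 8 / 3-8 kb | ~11% QTL footprint; a scaled-down stand-in for 59 metabolic QTL genome-wide (a 59-QTL placement is exercised in the tests) |
| `n_genes` / `n_candidate_genes` | 40 / 15 | candidate set small relative to the gene complement |
| `enrichment_fraction` | 0.6 | a clearly enriched default study; `NA` places candidates uniformly for null calibration |
| `ct_noise_sd` | 0.15 cycles | typical qPCR duplicate scatter |
| `gtt_noise_sd` | 10 mg/dL | glucometer-scale noise around a baseline-plus-peak-decay curve sampled at the protocol's timepoints |

Every generator draws from a stream split deterministically from one global
seed, records all ground truth (variant positions, read origins, gene/QTL
placements, planted folds), and regenerating with the same config is
byte-identical. What the generator does *not* emulate — and what passing
tests therefore cannot vouch for on real data — includes alignment artefacts
and mapping bias, splicing, fragment-length effects, overdispersed
biological replication of counts (no negative-binomial transcriptome is
simulated), batch structure, and reference-strain bias in variant calling.

## Problem sizes and numerical choices

The acceptance-grade checks run at: 1000 random 2-kb genomes for the lift
round trip with ~200 k-mer oracle anchors; 10,000 error-free reads for
assignment accuracy; exact CI coverage at n = 2000 plus 200-replicate
samples per fraction; 200 null studies at 199 permutations each plus one
fully-enriched study at 999; 10,000 sampler draws for uniformity; 10,000
Gaussian replicates for the Grubbs size. These sizes are the package's own
balance between resolution and a test suite that stays pleasant to run;
the whole suite completes in a few minutes on one core.

Numerical details worth knowing: empirical p-values are +1-corrected and
never zero; `allele_bias()` returns an explicit non-estimable row (not NaN)
for genes with zero assigned reads; `uq_normalize()` errors on an all-zero
sample naming it; region sampling and annotation placement are
rejection-based with bounded retries and raise a packing error rather than
degrade; the read simulator floors nothing and the GTT simulator floors
glucose at 1 mg/dL to keep values physical; variant simulation resolves
overlapping candidate variants by rejecting the later conflicting candidate,
which biases realized density slightly below the nominal rate at these
settings (immaterial at the default rates).

## End-to-end demo

`run_demo(outdir, seed)` chains every stage on the default synthetic study
and writes FASTA/VCF/BED/FASTQ/TSV outputs, a plain-text summary and a JSON
manifest with content digests. The same seed reproduces every output file
byte-for-byte (the manifest's timestamp aside). `scripts/acceptance.R`
recomputes the headline quantities from scratch at an arbitrary seed.
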