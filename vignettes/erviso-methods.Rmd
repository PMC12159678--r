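---
title: "Methods: locus-level ERV quantification and contribution decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: locus-level ERV quantification and contribution decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erviso)
```

## The quantification model

The locus under study carries three overlapping transcript structures:
a long isoform whose first exon lies far upstream of the provirus, a
short isoform initiated at a nearby solo LTR, and the canonical form
initiated at the provirus's own 5' LTR.  Because the isoforms share
most of their exonic sequence and the locus is repetitive, `erviso`
avoids isoform deconvolution entirely.  Each isoform is quantified
over a *unique region* — the exonic bases covered by that isoform and
no other (`derive_unique_regions()`, an interval set-difference on
`GenomicRanges`) — while the composite gene is quantified over the
repeat body as annotated by RepeatMasker.  This trades statistical
efficiency (most of each transcript's bases are discarded) for
unbiasedness: a read counted for an isoform can only have come from
that isoform.

Counting follows the conventions of overlap-based counters: a read is
assigned to a feature when its aligned blocks overlap the feature's
interval union by at least one base; reads overlapping two or more
features are discarded as ambiguous unless multi-overlap counting is
requested; only unique alignments (`NH == 1`, MAPQ ≥ 30) are counted
by default.  At a repeat locus the multimapping policy is the single
most consequential parameter, so it is explicit and the default is
conservative; `unique_only = FALSE` re-admits all alignments for
sensitivity analysis.  Counting is unstranded by default (all features
of interest are co-located on one strand); a same-strand mode exists.
TPM follows the standard two-step definition — per-kilobase rates
rescaled to one million per sample over the full annotation supplied.

Canonical 5' LTR promoter activity is scored by *junction reads*:
reads with at least one aligned block overlapping the 5' LTR and at
least one block (possibly the same block, for contiguous read-through)
overlapping the internal coding region.  A sample is called active at
one junction read or more — activity is a presence/absence screen, and
junction CPM conveys magnitude.

## The contribution model

Assuming the composite gene signal derives solely from the two
isoforms, the model is

    a · long + b · short + c = gene

fitted by ordinary least squares with the two predictors z-scored
(sample sd, n−1), so that `a` and `b` are comparable and can serve as
per-transcript normalization factors.  Each sample then receives

    log2((a · TPM_long + ε) / (b · TPM_short + ε))

with pseudocount ε = 0.01 TPM by default (the data contain exact
zeros; ε is configurable and reported).  Positive values mean the long
isoform drives the composite signal in that sample.

Three conventions deserve a note:

* **Outcome scaling.** The predictors are z-scored; the outcome is
  centered through the intercept but left on its own scale by default
  (`scale_outcome = FALSE`).  Z-scoring the outcome as well divides
  both coefficients by the same constant — the outcome's residual
  scale — which cancels identically from the log ratio and from the
  dominance calls.  Leaving the outcome unscaled makes the
  coefficients directly interpretable as mixing weights and makes
  generator closure exact (a cohort simulated with weights
  (0.7, 0.3) is recovered as (0.7, 0.3), not as a rescaling of them);
  `scale_outcome = TRUE` restores the fully standardized convention,
  and nothing downstream changes.
* **Fit population.** The model is fitted on the pooled cohort (all
  groups together) so a single pair of normalization factors applies
  to every sample, and per-sample ratios are then summarized by group;
  `fit_on` restricts the fit to a subset when a per-cohort fit is
  wanted.
* **Degenerate coefficients.** A non-positive fitted coefficient means
  the model failed to attribute signal to that isoform.  The ratio is
  still computed — the normalized terms are clamped at zero so the
  pseudocount keeps the logarithm finite — but the samples are flagged
  and group summaries exclude them by default.

The driver regression relates a z-scored expression outcome to a
binary amplification indicator (copy number ≥ 3, the conventional
cutoff for calling the 1q22 gain) plus z-scored pathway scores
(ssGSEA-style per-sample enrichment values, consumed as inputs, never
computed here).  Two-sided p-values come from the coefficient t
distribution.  Group contrasts use the two-tailed pooled-variance
Student t test; correlation uses Spearman's rank with average ranks
for ties and the t approximation for p-values.

## LTR silencing assessments

CpG methylation over the promoter is summarized from bedMethyl-style
per-site calls.  A site counts when its coverage reaches `min_cov`
(default 5) and is called methylated at modified fraction ≥ 0.5; the
region is called methylated when at least half of covered sites are
methylated.  The paper-scale data report only a qualitative
"mostly methylated" state, so both thresholds are explicit arguments
rather than constants.  5mC and 5hmC fractions, when reported
separately, are summed by default.  CpG strand collapsing (merging the
+/− calls of one dinucleotide, coverage-weighted) is available but off
by default, since typical minus-strand tracks should not be silently
averaged with plus-strand calls.

Sequence divergence screens the query LTR against reported-active LTR
references: references shorter than 900 ungapped bases (strictly) are
discarded as too truncated to align informatively; within the MSA,
each column's consensus is the modal non-gap reference base, and a
call is emitted where the query differs from a consensus supported at
frequency ≥ 0.8.  Columns where the query is gapped are skipped;
all-gap reference columns are tallied.  Lowering the frequency
threshold can only add calls.

## Single-cell summaries

Cell-type labels, patient assignments and feature-level raw counts are
inputs (clustering and quantification happen upstream).  "Expressing"
means raw count ≥ 1.  Per-type expressing fractions include only types
with more than 600 cells — strictly more, matching the stated
inclusion rule — and the omitted types are reported.  The high/low
stratification splits at 10 raw reads (count ≥ 10 is high), optionally
restricted to tumor cells from tumor tissue, as that contrast uses
primary tumor cells only.  Per-patient percentages of cells in a
designated expressing-type set are compared between tissues with the
Student t test.

## What the generators emulate

The synthetic module exists so that every analysis step can be
validated by parameter recovery, and its defaults *are* the study
conditions:

* `simulate_cohort()`: three groups sized like the TCGA lung cohorts
  (500/480/100), log-normal latent TPMs — long isoform
  tumor-enriched (meanlog 1.6/2.0 in the tumor groups vs −0.7 in
  normal), short isoform roughly flat with a slight normal excess —
  and a composite signal `0.7·z(long) + 0.3·z(short) + noise`
  (sd 0.1) shifted onto a positive scale.  About 10% of samples carry
  the amplification.  These values were chosen once to mimic the
  qualitative group pattern of the motivating analysis (long dominant
  in tumors, short dominant in normal) and are not tuned thereafter.
* `simulate_reads()`: a 10 kb toy locus reproducing the geometry that
  matters — a 500 bp distal exon unique to the long isoform, a 111 bp
  region unique to the short one, a 7000 bp repeat body, and an
  LTR-initiated form reading through the LTR/internal boundary; the
  long/short isoforms enter the provirus downstream of the 5' LTR, so
  junction reads can only come from the canonical form.  Reads are
  drawn uniformly along each spliced transcript, so expected feature
  counts have a closed form (abundance × fraction of start positions
  overlapping the feature × unique fraction) against which observed
  counts are checked with binomial bands.
* `simulate_methylation()`: Poisson coverage, binomial modified calls
  at a fixed true methylation level.
* `simulate_cell_matrix()`: per-type expressing probabilities for the
  long feature taken from the reported detailed fractions (tumor
  0.107, fibroblast 0.0372, AT2 0.0108, zero elsewhere), short/gene
  features expressed in all types, and a bimodal high/low count
  mixture for the long feature in tumor cells.
* `simulate_msa()`: references drawn from a shared consensus with
  small noise, query equal to the consensus except at planted
  substitution columns (the shipped fixture plants the T>C pattern).

What the generators deliberately do **not** model: alignment error,
fragment-length and paired-end structure, sequencing error,
multimapping ambiguity that depends on sequence identity (multimappers
are flagged, not misplaced), batch effects, doublets, and overdispersed
methylation (the beta-binomial site distribution is a point mass).
Passing recovery tests therefore demonstrates correctness of the
interval algebra, counting policies, model fitting and summaries — not
robustness to upstream artifacts of real libraries.

## Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open; GTF I/O converts to and
  from the format's 1-based inclusive convention, and book-ended exons
  merge on parse.  Zero-length intervals are rejected.
* A unique-region rule that resolves to an empty union is an error
  naming the feature (silent empty features would poison every
  downstream count).
* Reads on chromosomes absent from the annotation are skipped and
  tallied, not fatal — a BAM routinely carries contigs the annotation
  lacks.
* A sample with zero total rate TPM-normalizes to an all-zero column
  with a warning; CPM with zero mapped reads is an error.
* `zscore()` refuses constant vectors by name; the contribution fit
  refuses perfectly collinear predictors; the driver model drops a
  constant amplification indicator with a warning rather than failing.
* Determinism: every generator is exactly reproducible under a fixed
  seed, and one master seed fans out to independent substreams via a
  Lehmer step (`derive_stream_seed()`), keeping derived seeds inside
  the 32-bit range.  The pipeline report contains no timestamps, so
  identical inputs give byte-identical outputs.

## Validation problem sizes

The shipped test-suite exercises the interval algebra against a
per-base boolean-mask oracle on 1000 random ≤10 kb loci; counting
against a naive per-read double-loop oracle on 10,000 reads × 10
features under all four policy combinations; coefficient recovery over
100 seeded cohorts of n = 500 (mean absolute error ≤ 0.02 at noise
sd 0.1, exactness at 1e−8 without noise); the group sign pattern over
100 seeded cohorts; junction counts against their analytic binomial
expectation over 200 replicates plus a 114-sample screen with 11
active samples; methylation closure over 100 seeds; planted-MSA
recovery over 100 alignments; and Student-t size calibration over 1000
null simulations.  These sizes keep the whole suite within a few
minutes on one core while leaving Monte-Carlo error comfortably inside
each tolerance.

## Known limitations

* Unique-region counting discards shared bases, so low-abundance
  isoforms with small unique regions (here, 111 bp) have noisy TPMs;
  the decomposition inherits that noise.
* The contribution model is correlational; with strongly correlated
  isoform TPMs the coefficient split is ill-conditioned even when the
  fit is exact.
* Junction scoring assumes the annotation's LTR/internal boundary is
  correct to the base; a mis-annotated boundary shifts counts.
* The consensus screen detects substitutions only — indels surface as
  gap columns and are skipped rather than called.
* Sample-level metadata (groups, copy number, pathway scores, cell
  labels) are trusted inputs; no attempt is made to infer or correct
  them.
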