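---
title: "smipseq: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{smipseq: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the statistics and the design
choices behind them. It states no empirical result beyond what the test
suite and `scripts/acceptance.R` themselves compute.

## The measurement model

An smMIP captures a fixed window of a transcript between two targeting
arms; a random unique molecule identifier (UMI) tags every captured cDNA
molecule before PCR. A sequenced read therefore has a deterministic layout,
which this package fixes as

```
[UMI (umi_length nt)] [extension arm] [gap fill] [ligation arm]
```

with the UMI leading (the upstream chemistry guarantees only that the UMI
is random and of fixed length; a shared, documented geometry between
simulator and quantifier is what matters, and this is it). The default
`umi_length` is 8 nt, i.e. a 4^8 = 65,536-tag space per probe.

Quantification proceeds in three steps:

* **Assignment.** A read is assigned to the unique probe whose extension
  arm matches the post-UMI bases and whose ligation arm matches the read
  tail, each within `max_arm_mismatches` (default 1) Hamming errors. Ties
  and non-matches are tallied (`ambiguous`, `no_match`, `too_short`) but
  excluded downstream — the FPM denominator is the *assigned, deduplicated*
  read total, because "total unique read count" only exists for reads that
  map to a probe.
* **Deduplication.** Reads sharing (probe, UMI) collapse to one consensus
  "unique read" by per-position majority vote. A tied position emits the
  reference base when it is among the tied candidates and `N` otherwise —
  deliberately conservative, so consensus never invents a variant allele.
  Two distinct molecules that draw the same UMI collapse to one group; at
  desk depths (hundreds of molecules per probe against 65,536 tags) this
  undercount is a fraction of a percent and is surfaced explicitly: the
  simulator's ground truth carries both the true molecule counts and the
  distinct-(probe, UMI) counts, and the test suite asserts exact recovery
  of the latter while bounding the gap to the former. No 1-mismatch UMI
  merging is attempted; it would trade a well-defined count for a
  heuristic one.
* **Normalization.** FPM(p, s) = count(p, s) / sum_p count(p, s) x 10^6,
  so every sample column sums to one million by construction. Transcript
  expression is the arithmetic mean FPM over *all* probes targeting the
  transcript, zero-count probes included — dropping silent probes would
  bias transcript means upward.

## Variant calling

Consensus fills are anchored to their probe's window, so substitutions are
read off positionally. Fills whose length differs from the window are
aligned to it globally (gap opening 4, extension 1; groups beyond a net
length difference of `max_gap` = 20 are skipped and counted), and indels
are reported VCF-style as anchored ref/alt runs, left-aligned within the
window so that homopolymer indels aggregate at a single canonical
position. Every unique read spanning a position contributes exactly one
allele there (its base, `N`, a spanning-deletion mark `*`, or an anchored
indel), so allele counts always sum to coverage.

A call requires VAF = variant unique reads / total unique reads >= `min_vaf`
(default 0.10, the panel's reporting threshold — read as an allele-fraction
filter, consistent with reporting variants as "% of reads") and coverage of
at least `min_coverage` unique reads. The coverage floor (default 10) is
this package's addition: sparse loci otherwise yield confidently wrong
answers, so matched-normal comparison returns `not_evaluable` rather than a
silent verdict when the healthy sample has fewer than `min_coverage` unique
reads. A tumor call is `somatic` when the same allele sits at or below
`max_normal_vaf` (default 0.02) in the matched healthy pileup, and
`not_somatic` (germline or artifact) otherwise. Raising `min_vaf` can only
shrink the call set; this monotonicity is asserted in the tests.

## Clustering and differential expression

Expression is transformed as `log2(FPM + 0.01)`; the pseudocount keeps
absent transcripts finite (log2(0.01) ~ -6.64). Samples are clustered on
pairwise Manhattan distances with average linkage (UPGMA) via
`stats::hclust`, giving an ultrametric tree whose merge heights are
non-decreasing — asserted on every simulated run. Exact ties between merge
candidates are resolved by `hclust`'s deterministic merge order; with
continuous FPM data ties have probability zero, so no bespoke tie rule was
implemented. The two head clusters come from cutting at k = 2; when tissue
labels exist, cluster *a* is the side holding the larger share of healthy
samples (the convention of a healthy-versus-tumor design), otherwise the
side containing the first sample.

Per transcript, the two clusters are compared with a two-sided Wilcoxon
Mann-Whitney test — exact enumeration when both groups have at most 8
observations and no ties, the normal approximation with tie and continuity
correction otherwise (`stats::wilcox.test`; the test suite verifies exact
agreement with brute-force enumeration over all group assignments for all
tie-free cases up to 6 vs 6). The test runs on untransformed FPM: rank
tests are invariant under the monotone log transform, so the choice cannot
change p-values, and the cluster means reported alongside belong on the
FPM scale. Benjamini-Hochberg correction runs across all tested
transcripts (`stats::p.adjust`). A transcript is flagged significant when
both p < `alpha_p` (default 0.05) and FDR < `alpha_fdr`. The FDR default is
0.05; 0.01 is equally defensible for this design (both thresholds are far
above the FDRs that strong effects produce) and the knob is exposed rather
than hard-wired.

Fold changes follow the signed convention: `FC = mean_b/mean_a` when the
ratio is at least 1, else `-mean_a/mean_b`, so |FC| >= 1 always and the
sign encodes direction. A zero mean on one side yields a signed infinity;
both-zero is an error, and constant transcripts short-circuit to
p = 1, FC = 1.

## Median-effect synergy analysis

Each dose-response curve is fitted to the median-effect model
fa/(1-fa) = (D/Dm)^m by least squares on the linearized scale
log10(fa/(1-fa)) vs log10(D). Readouts are clipped to
[1e-6, 1 - 1e-6] before the (0, 1) filter — exact 0/1 viability readings
carry no information on this scale and standard practice excludes them —
and replicate measurements at the same dose are averaged before fitting
(pooling would only re-weight doses by replicate count). Noise-free data
regenerate (Dm, m) to relative error below 1e-10 (asserted).

For a constant-ratio a:b combination, the combination curve is fitted on
total dose; at each fraction-affected level the total dose is split into
components d_a, d_b, and

* CI = d_a/Dx_a + d_b/Dx_b (the mutually-exclusive two-term form, the
  classic default; the non-exclusive third term d_a d_b/(Dx_a Dx_b) is
  available behind `exclusive = FALSE`),
* DRI_i = Dx_i/d_i, so CI = 1/DRI_a + 1/DRI_b holds by construction and is
  asserted on every computation.

The verbal classification bands (0.1-0.3 strong synergism, 0.3-0.7
synergism, 0.7-0.85 moderate synergism, 0.85-0.9 slight synergism, 0.9-1.1
additive, 1.1-1.2 slight antagonism, 1.2-1.45 moderate antagonism,
1.45-3.3 antagonism) overlap at their printed endpoints, so a convention is
mandatory: intervals are half-open on the upper end, values below 0.1 read
as strong synergism and at or above 3.3 as antagonism.

## What the simulator emulates — and what it does not

`sim_config()` defaults encode the cohort design the package targets: five
patients, each with one healthy sample and three tumor biopsies (20
samples), a panel of 898 probes over 150 transcripts, UMI length 8, and a
baseline of 1200 molecules per probe — roughly the million unique reads per
sample a production run yields. PCR duplication is 1 + Geometric with mean
3 and the per-base error rate 0.001; neither is dictated by the design, and
both are single-knob approximations chosen once as realistic for a
well-behaved Illumina library. Tumor effects multiply (or divide, for
negative signed values) the Poisson mean of every probe of an affected
transcript; spiked variants flip molecules to the alt allele with
probability equal to the target VAF, in tumor samples only when
`tumor_only`.

Not modeled: per-probe capture-efficiency variation beyond the shared
baseline (real panels show substantial probe-to-probe spread), quality
scores (constant 'I'), UMI errors, index hopping, strand effects, and
overdispersion beyond Poisson. Passing tests therefore demonstrate the
*pipeline's* correctness under a clean generative model, not robustness to
every artifact of real libraries; the per-probe Poisson assumption in
particular is a documented configuration choice, not a claim about smMIP
chemistry.

Test and acceptance problem sizes are deliberate package choices: the
quantification oracle runs at 50 probes x 4 samples x ~100 molecules per
probe; cluster recovery uses 50 seeds of a 20-sample, 150-transcript cohort
with |FC| = 4 on 40 transcripts; the null calibration uses 200 replicates
of 150 transcripts at 5-vs-15 samples; median-effect recovery uses 200
noisy curves at sigma = 0.05. These sizes give the stochastic assertions
comfortable Monte-Carlo margins while keeping a full test run in well under
a minute.

## Known limitations

* Variant calls are nucleotide-level in transcript coordinates; protein
  (HGVS p.) nomenclature and genome liftover are out of scope.
* Arm matching is Hamming-only: an indel inside an arm defeats assignment.
  Arms are short (~20 nt), so the loss is bounded and visible in the
  `no_match` tally.
* Indels that cannot be anchored inside the probed window (at its very
  edge) are kept as spanning marks but not called.
* The FPM denominator is panel-relative: global expression shifts between
  tissues move all FPM values, which is inherent to panel-normalized
  counts and the reason cluster interpretation leans on relative patterns.
* CI/DRI values inherit the uncertainty of three separate curve fits; no
  confidence intervals are propagated (CompuSyn-style point estimates).
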