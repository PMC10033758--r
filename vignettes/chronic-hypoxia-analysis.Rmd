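---
title: "Quantifying genomic and transcriptomic instability under chronic hypoxia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying genomic and transcriptomic instability under chronic hypoxia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypoxigen)
```

## The analysis in one paragraph

Solid tumors contain chronically hypoxic regions, and cancer cell lines
differ in how strongly they respond to low oxygen. This package
implements a complete, testable pipeline for the question *what does
long-term hypoxia do to the genome and transcriptome of cancer cells,
and does inherent hypoxia sensitivity modulate the damage?* Cell lines
are ranked by a signature-based hypoxia score and split into
hypoxia-high (HH) and hypoxia-low (HL) groups; after simulated long
passaging, the two groups are compared for tumor mutational burden
(TMB), variant spectra, windowed copy-number changes, differential
expression, alternative splicing, and — in a patient cohort —
gene-alteration frequencies. Every input is produced by a synthetic-data
module with planted ground truth, so each stage's sensitivity and
false-positive behavior can be measured without any external download.

## Hypoxia scoring

For each cell line, the fold change (hypoxia vs normoxia) of each of
eight signature genes is averaged over replicate experiments, and the
**hypoxia score** is the geometric mean of the eight gene means —
computed as `exp(mean(log(x)))`, which is exact in log space and
homogeneous of degree one (scaling all fold changes by *c* scales every
score by *c*). The **relative score** is the score minus the geometric
mean of all scores; lines with a positive relative score form the HH
group.

The sign convention deserves a note: read literally, "subtract the score
from the grand geometric mean" would make the most responsive line the
most *negative*, which contradicts the stratification rule that positive
relative scores are hypoxia-high. We define
`relative = score - geometric_mean(scores)` so that responsive lines are
positive, consistent with the grouping rule.

In patient cohorts, where fold changes are unavailable, the score is
rank-based: for each signature gene the cohort median is computed
(midpoint convention for even cohorts), each patient scores +1 if their
expression is strictly above the median and −1 otherwise, and the sum
over genes is the cohort hypoxia score; patients with a positive sum are
HH. Ties at the median score −1: the stratification rule is
HL-inclusive (score ≤ 0 is HL), so boundary expression is treated as
"not above". The construction is invariant under any strictly
increasing per-gene transformation, so normalization choices upstream
cannot change the calls.

## Differential expression and splicing

Testing runs on log2 intensities with a moderated two-sample statistic:
the per-transcript pooled variance $s^2$ (with $d = n_1 + n_2 - 2$
degrees of freedom) is shrunk toward the across-transcript mean variance
$s_0^2$,

$$\tilde s^2 = \frac{d_0 s_0^2 + d s^2}{d_0 + d},
\qquad t = \frac{\bar x_1 - \bar x_2}{\tilde s \sqrt{1/n_1 + 1/n_2}},$$

referred to a t distribution on $d + d_0$ degrees of freedom. The prior
degrees of freedom $d_0$ (default 4) control the strength of
moderation; at $d_0 = 0$ the statistic reduces exactly to the classical
pooled t, which the test suite verifies against `stats::t.test`. This
is the standard moderated-t construction; the commercial array software
whose analysis it mirrors does not publish its exact empirical-Bayes
variant, so equivalence with that implementation is not claimed.

Fold changes are reported in the signed linear dialect of array
software: $r$ when $r \ge 1$ and $-1/r$ otherwise, so 2-fold down is −2
and $|FC| \ge 1$ always. A transcript is significant when
$FC \le -2$ or $FC \ge 2$ **and** its Benjamini–Hochberg FDR is ≤ 0.05
(`stats::p.adjust`). Splicing uses the same machinery after
normalization: each probe-selection-region (PSR) signal is divided by
its gene-level signal per sample — cancelling transcript-wide expression
changes — and the **splicing index** is the signed fold change of the
normalized means, with the transcript inheriting the probe of maximal
$|SI|$. Splicing significance uses strict inequalities ($|SI| > 2$,
exon FDR < 0.05); the boundary difference from the expression rule is
deliberate and preserved as printed by the upstream convention. Each
significant transcript's splicing event is the candidate with the
highest event score in $[0,1]$ (ties broken by a fixed label order,
cassette exon first); transcripts with no scored candidate are excluded
from final reports.

The group-level DEG algebra defines `common_all` as the intersection of
significant sets over *all* cell lines, and each group's specific set as
the intersection over that group's lines minus `common_all`; the three
sets are pairwise disjoint. A stricter reading would additionally
exclude genes significant in *some* lines of the other group; the
published counts cannot distinguish the two, and we use the simpler,
set-algebraically clean rule.

## Mutational landscape

Variants arrive as MAF tables. The central operation is **paired
subtraction**: for each matched pair, only hypoxia records whose
identity key — chromosome, start, end, reference allele, alternate
allele, variant type — is absent from the normoxia control are retained.
Annotations (gene symbol, classification) are deliberately excluded from
the key so that annotation drift between files cannot resurrect shared
variants. Duplicate keys within a sample are collapsed with a warning
first; subtraction is idempotent.

TMB is the retained count divided by the sequenced footprint in
megabases. The footprint is configurable with default 57.7 Mb, the
published design size of the exome panel emulated here; the true
per-sample callable footprint of the original pipeline is not published,
so all reports echo the denominator used. By default all retained
variants count; a `nonsilent_only` flag excludes Silent records.

SNV spectra use the standard six-class pyrimidine-reference convention
(purine-reference substitutions are complemented), with C>T and T>C as
transitions. Top-gene tables rank genes by the number of samples with at
least one retained variant, then total variant count, then label.

## Windowed copy number

Case (hypoxia) and control (normoxia) depth tracks on a fixed 50 kb
window grid are filtered (mappability ≥ 0.85; control depth ≥ 10
reads/window, which prevents ratio blow-ups) and each track is divided
by the median depth of its retained windows; the per-window ratio of the
two normalized depths is invariant to uniform depth scaling of either
track, and GC bias largely cancels because case and control share it.

Segmentation of log2 ratios is **split-then-merge**: regions are first
split recursively at the squared-error-optimal point down to a 3-window
floor, then adjacent segments are merged agglomeratively. A boundary is
retained only when the difference of the adjacent segment means reaches
`breakpoint_threshold` (default 0.8) multiples of their pooled
within-segment standard deviation, is nonzero, and exceeds three
standard errors of the mean difference. The two-phase form matters: a
purely top-down rule cannot detect a short copy-number segment embedded
in a long neutral stretch, because the candidate split's mean difference
is diluted by the flank while the flank's bimodal variance inflates the
pooled SD; splitting finely first and testing boundaries locally
recovers interior segments, and the three-standard-error guard prevents
chance fluctuations between short fine segments from surviving. Exactly
constant tracks yield a single segment (zero difference never splits),
and ratios are floored at $10^{-3}$ before the log so zero-depth windows
cannot produce infinities.

Ploidy is selected over candidates {2, 3, 4}: for each candidate $P$,
the explained fraction is the share of windows whose per-window
segment-mean ratio times $P$ lies within 0.1 of an integer. Segment
means rather than raw window ratios are scored because Poisson counting
noise at depth 100 (±14% per window) never resolves to integers at that
tolerance for any ploidy, which would reduce selection to the tie rule.
Explained fractions within 2% of the maximum count as ties, resolved
toward the smallest ploidy — without this margin a handful of spurious
segments can flip the selection to a higher ploidy, which tightens the
neutral band and inflates false copy-number calls. Integer copy number
is `round(mean_ratio * ploidy)` with halves rounded away from zero;
gain/loss status is relative to the selected ploidy, and CNV / CNG /
CNL counts are window counts over called segments. The
`breakpoint_threshold` scale (multiples of pooled SD of log2 ratios) is
this package's definition; the original windowed CNV tool the analysis
emulates does not document its internal scale, and no equivalence with
it is claimed.

## Group statistics

Two-group comparisons use the unpaired two-sided t-test, pooled-variance
by default (the default "unpaired t-test" of common statistics
software) with Welch as an option, and means are reported with t-based
95% confidence intervals. Multi-group log-FC comparisons use ordinary
one-way ANOVA with Sidak-corrected pairwise p-values,
$p' = 1 - (1-p)^m$, with pairwise t statistics built on the ANOVA
residual mean square. Degenerate zero-variance inputs follow the
convention $p = 1$ when means agree. The unit of analysis is the sample
pair throughout, matching a design where each symbol in a TMB plot is
one sample. Cohort concordance counts, among a gene list, the genes
whose alteration frequency is strictly higher in HH than in HL patients.

## What the generator emulates — and what it does not

The synthetic-data module reproduces the statistical structure of the
study design: 12 cell lines scored from 8 signature genes with three
replicate fold changes each and a 4-fold latent separation between
sensitive and resistant lines; 3 cell lines per group with 2 biological
× 2 technical replicates, giving 24 matched normoxia/hypoxia MAF pairs;
hypoxia-private mutation counts Poisson with rates 3.0 (HH) and 1.6
(HL) mutations/Mb over a 57.7 Mb footprint, matching the magnitude and
direction of the reported group difference; a variant-class mixture led
by frameshift insertions (0.35) over missense mutations (0.30),
mirroring the reported class ordering without claiming its counts; 70%
transition bias among SNVs; 2,000 50-kb coverage windows at mean depth
100 with planted segments (defaults: a 200-window single-copy loss and
a 150-window single-copy gain at ploidy 2); 2,000 transcript clusters
with 5% planted 4-fold expression changes and 5% planted cassette
exons in 4-vs-4 arrays; and a 50-patient cohort whose signature-gene
expression tracks a latent hypoxia factor, with alteration odds
multiplied 5-fold in factor-high patients. The per-pair shared
background (100 variants) is a free parameter — the real sharing level
is not published — chosen as a plausible clonal/germline background for
matched cell-line samples.

Depth noise is Poisson, the simplest count model for shallow windowed
sequencing; overdispersion, GC waves, mappability structure, subclonal
copy-number states and allele-frequency information are not modeled.
Variants are uniform over a single synthetic contig with unique
positions per sample; there is no mutational-signature structure beyond
the class mixture and transition bias, and no read-level (FASTQ/BAM)
simulation. Array intensities are log-normal with homoscedastic noise;
real arrays show intensity-dependent variance. Passing the planted-truth
tests therefore demonstrates that each algorithm recovers the effects it
is designed for under its stated noise model — not that it is robust to
every artifact of real instruments.

Every generator is a pure function of its configuration, including the
seed; generators for different modalities use distinct seed offsets so
the data streams are mutually independent under one configuration.

## Problem sizes and reproducibility

The test suite and the acceptance script measure recovery at the study
scale described above, using 20 replicate seeds for the
planted-recovery and null-calibration rates, 100 seeds for the group-TMB
direction/rejection rates and score-ranking checks, 5,000 replicates
for the t-test type-I error and 1,000 for confidence-interval coverage
— sizes at which the Monte-Carlo error of each rate is well below the
margin it is compared against. `run_pipeline()` on a fixed
configuration writes byte-identical summary JSON across runs.

## Known limitations

* The eight signature genes are configurable inputs; the package does
  not derive the signature, and defaults use synthetic gene labels.
* The moderated test is a fixed-prior construction; it does not
  estimate $d_0$ from the data.
* Segmentation assumes piecewise-constant log ratios with roughly
  homogeneous noise; very short segments (< 3 windows) are
  undetectable by design, and boundary placement is resolved to the
  fine-partition granularity.
* The splicing stage consumes probe-level summary signals and candidate
  event labels; it thresholds and selects among them but does not
  re-derive events from probe geometry.
* Survival analysis, pathway enrichment and plotting are out of scope.
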