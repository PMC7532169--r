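---
title: "Models and methods behind hmeripr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hmeripr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

hmeripr implements a complete analysis pipeline for hydroxymethylated RNA
immunoprecipitation sequencing (hMeRIP-Seq): an antibody pulls down RNA
fragments carrying 5-hydroxymethylcytosine (5hmC), the pulled-down (IP)
library is sequenced next to a matched input library, and enrichment of IP
over input coverage localizes the modification on transcripts. Downstream
stages quantify differential marking between conditions, profile where
peaks fall on transcripts, discover the sequence motif at peak centers,
call Tet-protein-bound transcripts from RIP-Seq tables, and relate 5hmC
marking to transcript half-life, translation efficiency, and intron
retention. This vignette documents the models, the parameters that
matter, the numerical choices, and the limits of what the synthetic
benchmark can show.

## Coordinates and data model

All internal coordinates are 0-based half-open (`[start, end)`); GTF and
GRanges conversions happen only at the I/O boundary. This removes the
ambiguity of mixing 1-based inclusive and 0-based half-open conventions
mid-pipeline. User-facing containers are tibbles — peaks, counts, calls
and fate records are all plain tables that pipe through dplyr — while
interval arithmetic runs on GenomicRanges/IRanges underneath. Duplicate
fragments are not removed: with strong local enrichment, duplicate-level
pileups are signal, not artifact, in antibody-enrichment data.

## The peak caller

Peak detection is a windowed local-Poisson scan restricted to the genomic
union of transcript spans (the "effective transcriptome": the sum of all
transcript lengths, exons and introns, counting shared regions once).
For a window of width $W$ containing $k$ IP fragment starts, the
background is

$$\lambda = \max\left(\lambda_{\mathrm{bg}} W,\;
  \hat\lambda_{1\mathrm{k}} W,\; \hat\lambda_{5\mathrm{k}} W\right),$$

where $\lambda_{\mathrm{bg}}$ is the genome-wide IP start rate over the
effective transcriptome size and $\hat\lambda_{\ell}$ are local input
rates in windows of $\ell$ bases centered on the candidate, truncated at
transcript-union boundaries and scaled to IP depth. The test is the
Poisson upper tail $P(X \ge k)$ computed through the log survival
function; Benjamini–Hochberg correction is applied across all tested
windows transcriptome-wide (one family of hypotheses, not per
chromosome). Fragment starts, not pileup, are the counted events: starts
of a homogeneous fragment process are exactly Poisson, so the test is
calibrated without an overdispersion fudge.

Significant windows (q < 0.05 by default) are merged into regions. Within
a region, summits are the local pileup maxima (leftmost base on ties),
clustered so two candidates within one flank of each other yield a single
summit. A local maximum is only reported if its pileup reaches
`summit_min_frac` (default 0.5) of the region's maximum — the
"significance contour" that separates genuine secondary summits from
noise maxima in the low-coverage tails of merged regions. Every peak is
then resized to 100 bp on both sides of its summit (201 bp total), so
extremely long raw regions never propagate. Overlapping resized peaks
from adjacent summits are kept as-is (deduplicated only when identical).
Fold enrichment is the depth-normalized IP/input pileup ratio at the
summit, with the input pileup floored at its genome-wide rate to keep the
ratio finite in input-sparse regions.

"Expected peaks" run the identical scan with the input library as signal
against the analytic uniform background alone. They are the regions most
likely to generate peaks by sheer read abundance, and serve as negative
controls for the distribution and motif analyses. Under the synthetic
uniform input they are (by design) nearly absent at q < 0.05; analyses
that need a control set of positions use windows drawn at random
transcript positions, which is exactly what input-derived expected peaks
converge to under a uniform background.

Replicated peaks are the maximal regions covered by at least one peak
from *every* replicate; the emitted interval is the intersection of the
contributing peaks and statistics come from the contributor with the
smallest q-value (its summit is clamped into the interval in the rare
case it falls outside). Requiring all replicates is deliberately
conservative — it is the same philosophy as the all-replicates rule used
for the RIP bound calls.

## Differential marking

Replicates of each condition are pooled into metasamples. Fragments are
counted per replicated peak (a fragment counts toward every peak it
overlaps by one base or more), normalized as RPKM, and each condition's
enrichment ratio is IP RPKM over input RPKM. When either raw count is
zero, one read is added to both counts before normalization — mirroring
the 1-TPM pseudocount used for RIP enrichment — so ratios are always
defined. A peak is differentially marked when the two conditions' ratios
differ by at least 1.5-fold; there is no count-model test here, by
design: the decision rule is a pure fold-change rule. At the transcript
level, a transcript is "reduced" when at least one of its peaks loses
marking and none gains (symmetrically "increased"; both directions make
it "mixed").

By default peaks from both conditions' final lists are quantified as one
union, so a peak absent in one condition remains comparable; a
reference-condition-only mode covers the alternative reading.

## Structural annotation

Assignment is summit-based: exon if the summit lies inside an annotated
exon of an overlapping coding transcript, intron if inside the transcript
but outside its exons, and unannotated when no coding transcript overlaps
or when overlapping transcripts disagree. Concordant multi-transcript
overlaps count as annotated (the ambiguity exclusion targets
*disagreement*, not mere overlap); this is switch-free but documented, as
the alternative (dropping all multi-overlaps) is defensible too. The same
uniqueness rule maps summits to 5'UTR/CDS/3'UTR, strand-aware. The
distribution enrichment of a region is the observed minus expected
percentage of peaks in it (percentage points over all peaks, unannotated
included), so enrichments always sum to zero.

## Motif discovery

Peak sequences are the peak centers extended 250 bp on both sides,
extracted on the strand of the associated transcript (peaks overlapping
transcripts of both strands are used once per strand; unassociated peaks
are dropped). The background is a first-order Markov model with additive
smoothing ($\alpha = 1$) fitted to control sequences.

Discovery is a seeded ZOOPS (zero-or-one-occurrence-per-sequence)
expectation-maximization: at every width in the search window (5–12),
observed k-mers are scored by log observed-frequency over Markov-expected
probability, the top seeds per width initialize PWMs (0.7 on the
consensus base), and EM refines each. The EM monitors the MAP objective
(mixture log-likelihood relative to background plus the Dirichlet(1.25)
log-prior matching the smoothed M-step), which is guaranteed
non-decreasing and is asserted at every iteration; convergence is a gain
below $10^{-4}$ or 100 iterations. All refined candidates then compete on
their enrichment in positives versus controls — the log-odds of carrying
a site scoring at least 75% of the maximum attainable PWM log-odds —
so widths are compared on refined evidence, not raw seed scores. Up to
10 motifs are reported; the sites of each reported motif are masked
before the next round. Seeds are ordered by score then lexicographically
and best sites take the leftmost position on ties, making discovery fully
deterministic (and keeping the centrality test unbiased: breaking ties
toward the center would rig it).

Centrality is a one-sided binomial test of the number of best sites
lying fully inside the central 100 bases of each 501-base sequence,
against the null proportion $(100 - w + 1)/(501 - w + 1)$; motifs with
$p \ge 0.05$ are "decentered" and excluded from the final report. The
100-base central window is a package default, config-exposed. Motifs are
reported in the RNA alphabet (U), stored internally as DNA (T).

## RIP enrichment and the overlap partition

TPM columns are computed from counts and effective lengths
($\mathrm{TPM}_i = 10^6 (c_i/\ell_i)/\sum_j (c_j/\ell_j)$). With a
pseudocount of 1 TPM on both sides, a transcript is Tet-bound when its IP
TPM strictly exceeds its input TPM. Replicates combine by intersection (a
transcript must be bound in every replicate pair; a mean-TPM mode is
available), and the universe is restricted to transcripts expressed
(input TPM > 1) in every replicate. The 5hmC-by-binding partition is
exact set algebra over that universe.

## Transcript fate

Expressed transcripts (TPM > 1) are stratified by the presence of at
least one final 5hmC peak. Half-life and translation efficiency are
compared between strata with a Wilcoxon rank-sum test implemented in the
package: midranks for ties, the exact Mann-Whitney null distribution when
$\min(n, m) \le 8$ with no ties, and the normal approximation with tie
and continuity corrections otherwise.

The transcription-shutoff decay analysis normalizes counts at 0 h and
4 h with median-of-ratios size factors (rescaled to geometric mean 1),
then per transcript tests the per-replicate normalized log2 abundances
between time points with a two-sided t-test, BH-adjusted. The calls use
the fold-change-plus-significance rule: destabilized when
$\log_2\mathrm{FC} \le -\log_2 1.5$ and adjusted $p < 0.05$. A
negative-binomial GLM with dispersion shrinkage would give different
p-values transcript by transcript; the decision rule, which is what the
downstream claims rest on, is preserved exactly, and the planted-truth
benchmark asserts recovery of the rule's output rather than agreement of
p-values. With only two time points, first-order decay is the only
identifiable model, giving $t_{1/2} = 4\ln 2 / \ln(N_0/N_4)$ hours when
abundance falls; the estimate is scale-invariant by construction. Note
that median-of-ratios normalization anchors to the majority of
transcripts: if most transcripts are stable the normalization is
benign, but a global decay shared by all transcripts is absorbed into
the size factors — an intrinsic limitation of shutoff designs without
spike-ins.

The decay analysis applies no additional TPM-based expression filter:
transcripts with zero counts at both time points are skipped, and the
size-factor reference already excludes rows with any zero. Callers who
want the TPM > 1 filter can subset the count table with the stratified
records first — keeping the filter outside the estimator leaves the
choice visible in the analysis script.

Splicing is the unspliced/spliced read ratio per transcript and time
point, normalized to the same transcript's 0 h ratio (so the 0 h value
is exactly 1); records with zero spliced counts are skipped with a flag.
The analysis is meant to run on expressed genes with intronic 5hmC
peaks; the function takes that transcript set as an argument rather than
hard-coding the filter.

## The synthetic benchmark

The generator produces a transcriptome of 200 non-overlapping multi-exon
genes (3–5 exons of 200–400 bp, introns of 300–600 bp) on two synthetic
chromosomes with a uniform-ACGT genome. Exon and intron lengths were
chosen once so the exonic and intronic genomic shares are comparable —
with realistically long introns the intron share approaches 90% and the
observed-versus-expected contrast of the distribution analysis becomes
uninformative at this scale. One hundred 5hmC peaks of 200 bp are
planted, at most one per gene (so 100 genes stay unmarked and every
downstream two-group comparison has both strata), with 80% of centers in
introns and the consensus UUCUU written into the genome at each center
on the transcript's strand.

Reads are pre-aligned fragment intervals (alignment is upstream of this
pipeline and error simulation would only blur coverage): lengths uniform
in 200–300 bp, background starts a homogeneous Poisson process along
each transcript span, fragments truncated at the transcript 3' end.
Keeping the start process exactly homogeneous matters — it is what makes
the caller's Poisson null exact on simulated input, so the null
calibration checks test the caller rather than a simulator artifact. IP
samples add enrichment as extra fragments whose midpoints fall uniformly
in the peak, with the extra count calibrated so the IP/input pileup
ratio at the peak center equals the configured fold (8 by default; the
study design gives no measured IP efficiency, so the default is a free,
recorded choice). Midpoint placement concentrates coverage at the peak
center, giving the summit a defined location — a uniformly-overlapping
placement would produce a 200-bp plateau with no identifiable summit.
Every sample draws from its own RNG stream keyed by (seed, condition,
replicate, role), so partial re-runs are reproducible.

The two conditions are WT (multiplier 1) and TKO (multiplier 0.4 on a
70% "changed" subset of peaks, true enrichment ratio 2.5; the remaining
30% keep full enrichment in both conditions and act as true negatives
for the differential rule). Fate tables plant a twofold half-life
deficit for marked transcripts (log-normal noise, sdlog 0.5, baseline
6 h), translation efficiency under the null, a doubling of the
unspliced/spliced ratio for marked transcripts at 4 h in WT, and decay
time courses with half-lives of 2 h (marked, WT) versus 20 h. RIP
tables bind every marked transcript (plus 10% random extras per
protein) at twofold IP enrichment.

What passing these benchmarks does *not* show: real hMeRIP data have
non-uniform input coverage (expression-correlated), GC and fragmentation
biases, overlapping gene models, isoform ambiguity, and an antibody with
finite specificity. The synthetic tests demonstrate that each stage
recovers what was planted under its own model assumptions and that the
statistics are calibrated under the matching null — necessary conditions,
not field validation.

## Problem sizes and determinism

All simulation-backed checks run at the study conditions above
(3 IP + 3 input replicates at 200,000 fragments per sample for the main
experiment; 20 independent 30-gene simulations for null calibration;
1,000 redraws of a 60-transcript fate table for the type-I calibration;
300 versus 300 transcripts for the rank-sum power check). These sizes
are the package's chosen benchmark conditions and are stated in the
acceptance script, which reruns everything from scratch from a single
command-line seed.
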