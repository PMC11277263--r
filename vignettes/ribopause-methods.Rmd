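---
title: "Methods: pause detection, translation metrics, and the synthetic study design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pause detection, translation metrics, and the synthetic study design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical procedures implemented in
`ribopause`, the modelling assumptions behind them, the design choices
that were genuinely open, and what the synthetic-data tests do and do not
demonstrate about real Ribo-seq data.

## Coordinates and data model

All internal coordinates are 0-based, half-open; every written report is
1-based inclusive. A transcript model is a spliced transcript sequence
with a CDS interval `[cds_start, cds_end)` whose length must be a
multiple of 3 (models violating this are rejected by name). Footprint
alignments live in transcript coordinates as
`(transcript_id, start5, length, count)` rows; genome-space alignment and
read preprocessing are upstream concerns outside this package. Transcript
sequences are stored 5'→3' and no strand information exists downstream.

Coverage comes in two modes. *P-site mode* adds each alignment's count at
`start5 + offset(length)` and conserves mass (the depth vector sums to
the transcript's footprint count); it drives pause detection and
periodicity. *Body mode* adds the count along the whole footprint and
drives translation intensity, whose coverage term is about how much of
the CDS footprints physically occupy.

## P-site offsets and metagene diagnostics

Initiating ribosomes accumulate over start codons, so the 5' ends of
footprints of a given length pile up one offset upstream of the start
codon. `estimate_psite_offsets()` scans the pooled 5'-end metagene in the
window −18..−6 nt relative to the start codon and takes the negated peak
as the offset, per read length (lengths behave differently, so one global
offset is not assumed; the default fallback is 12 nt). Two guards make
the estimate honest: a length needs at least 200 reads (configurable),
and the peak must exceed twice the mean of the remaining window
positions — otherwise the length is flagged unreliable and the default is
used. Ties break toward the smaller offset. The peak-to-background test
is a ratio of small counts at low depth; with fewer than a few thousand
reads per length the flag is noisy, which the tests account for by using
deep null libraries.

Frame periodicity is the fraction of offset-corrected P-sites in each
codon frame, over CDS positions only. Metagene profiles sum raw signal
across transcripts that contain the full window (a per-transcript-mean
normalization is available to keep high-expression transcripts from
dominating); the stop-codon anchor is the first base of the stop codon.

## Pause scoring and calling

The pause score of a position with nonzero P-site depth is its depth over
the mean depth of a `W`-nt window centered on it, clipped at transcript
ends and including the site itself. `W` defaults to 1001 nt (forced odd;
on typical transcripts the clipped window is the whole transcript), so
uniform coverage scores ≈ 1 and a site that concentrates half a
transcript's reads scores in the hundreds. Scores are scale-invariant:
multiplying all depths by a constant changes nothing.

Raw scores are not comparable across coverage regimes — at low coverage a
single read over a sparse window already scores high — so scores are
z-standardized within coverage bins: deciles of the window read total
(10 bins by default). Bins with fewer than two sites or zero variance get
`z = 0` with a warning rather than an undefined value. Calling uses three
strict inequalities: `score > 50`, `z > 1.65`, `depth > 20`. The depth
cutoff is applied to P-site depth at the position in the active site
mode.

Per time point, the maximum score over all positions of a transcript
summarizes its pausing; transcripts called in at least one time point
form the pause matrix. Rows are z-scored across time points (constant
rows become zeros) and clustered with k-means (`nstart = 10`, seeded) —
chosen as the default over hierarchical clustering for determinism and
testability, with Ward.D2 available as `method = "hward"`. Labels are
renumbered by descending cluster size so a fixed seed gives stable
labels; if fewer distinct profiles than `k` exist, `k` collapses with a
warning. Time-point analysis operates on replicate-merged libraries;
per-replicate pausing is possible by passing each replicate separately,
but merged is the default because pause calling is depth-hungry.

## Translation metrics

*Normalization* is median-of-ratios: size factors are medians of
per-sample ratios to per-gene geometric means over genes positive
everywhere (a test cross-checks the factors against an independent
implementation). *Differential expression* is a transparent filter, not a
shrinkage estimator: log2 fold changes of group means of normalized
counts with pseudocount 0.5, p-values from a negative-binomial Wald test
with pooled method-of-moments dispersion (floored at 1e-4), and
significance requiring both `|log2FC| > 1` and raw `p < 0.05` — raw
p-values, because the downstream decision rule is a dual filter, not an
FDR ranking. The RPF assay additionally requires a mean raw count of at
least 5.

*Translation efficiency* is the ratio of TPM-like RPF density to RNA
density per gene, CDS-restricted, with genes masked below an expression
floor or at zero RNA. Delta-TE between conditions is standardized
robustly across genes, `z = (log2 dTE − median) / (1.4826·MAD)`, with a
strict `|z| > 1.5` cut; on a symmetric normal null this flags ≈ 13.4% of
genes, which the tests verify. A posterior-based dTE estimator is a
deliberate non-goal: the downstream decisions here use only the z cut.

*Translation intensity* multiplies the median depth over covered bases by
the fraction of the region covered. The median is the standard order
statistic, averaging the two central values at even counts. Two
denominator conventions are defensible — whole transcript or CDS — and
both are implemented; the CDS is the default because translation occupies
the CDS and UTR lengths vary independently of it. With no covered base,
TI is 0 and the median is undefined (`NA`). Group contrasts (paused vs
not, with-motif vs without) use the two-sided Wilcoxon rank-sum test,
exact when both groups have ≤ 20 observations and no ties, normal
approximation with tie correction otherwise.

## Sequence features

Logos are position probability matrices over anchors with complete
windows (incomplete ones are dropped and counted); columns always sum
to 1. GC metaplots come in an absolute flavor (±500 nt by default, each
position averaging the anchors whose transcript reaches it) and a scaled
flavor: the CDS is cut into 50 equal-width bins from start codon to pause
site and 50 from pause site to stop codon, the last bin absorbing the
integer remainder; bins narrower than one base are `NA` and averages skip
them. An anchor at the CDS start has no upstream segment and is an error.

Nascent-peptide context maps an anchor to its codon — any of the three
nucleotides of a codon marks that codon — translates the CDS in frame,
and reports amino-acid frequencies and a net charge over the codon
window with K, R = +1, D, E = −1 and H = 0 at physiological pH (the map
is configurable; histidine's partial protonation is deliberately rounded
to zero).

PWM scanning scores windows with `sum(log2((p + 1e-3) / q))` against a
0-order background (pooled base composition of the scanned set by
default). The 1e-3 pseudo-probability bounds the log-odds instead of
producing −∞ on zero-probability bases. Hit p-values are exact tails of
the score distribution under the background, computed by dynamic
programming over columns: for motifs up to 12 columns the partial sums
are kept as exact doubles (accumulated left-to-right, so the distribution
is bitwise identical to brute-force enumeration); wider motifs use a
discretized grid with step 1e-4, bounding the p-value error far below the
1e-4 hit threshold. Higher-order backgrounds are a documented extension
point, not implemented, because the exact DP is what makes the p-values
testable. De novo motif discovery is out of scope; the shipped
`cgc_motif.ppm` is a synthetic 16-column matrix with 0.85 on the repeated
CGC consensus and 0.05 elsewhere, built in code.

Ensemble free energy delegates to ViennaRNA's `RNAfold -p` (partition
function at 37 °C, default nearest-neighbor parameters), mapping T→U
first. Reverse complements fold to their own values; no strand symmetry
is expected or used.

## The synthetic study

The generator emulates the statistical structure the analyses assume, at
desk scale: transcripts of 30–80 nt 5'UTR, 150–400 codons, 40–120 nt
3'UTR; baseline GC 0.45 with a −0.10 linear 5'→3' gradient (GC falls
toward the stop codon), per-transcript jitter 0.02, and a +0.08 GC
elevation for the paused group; lognormal expression (sdlog 1). Footprint
lengths 27–31 nt with probabilities (0.15, 0.20, 0.30, 0.20, 0.15), true
P-site offset 12 nt for every length, frame fidelity 0.95 (off-frame
P-sites shift ±1 nt), and an initiation-codon weight of 5, which creates
the start-codon accumulation that any 5'-end offset estimator needs.

Pauses are planted at codon granularity — ribosome dwell is a codon-level
phenomenon — on an exact half of transcripts by default: the pause
codon's sampling weight is multiplied by λ (default 200) and codons
downstream are down-weighted by a depletion factor d ∈ (0, 1] (default 1;
the coupling analyses use 0.5) modelling run-off scarcity downstream of a
long dwell. The upstream C signal is planted so its *marginal* frequency
equals the configured probability (C with probability 0.6, otherwise a
non-C base from the renormalized background) — naive planting on top of
background C would inflate the recovered frequency. The CGC motif is
written in frame 9 nt downstream of the pause on a random half of paused
transcripts. Because the motif is GC-rich, it adds its own GC near pause
sites; the GC-offset recovery analyses therefore disable motif planting
to isolate the group-offset knob. RNA and RPF counts are negative
binomial (dispersion 0.05) with planted fold changes and TE multipliers;
protein abundance is `base × (1/λ)^γ × lognormal(0.3)`, exchangeable
between groups at γ = 0.

Every generator is a pure function of its configuration and seed;
identical seeds give byte-identical outputs, and `run_all()` fans a
single base seed out to fixed per-stage seeds so partial reruns
reproduce.

What passing these tests shows: the estimators recover what they claim to
measure when their assumptions hold, with correctly calibrated error
rates (PWM p-values exact; pause false-calls ≤ 1e-3 per scored position
on null libraries; DE null within its nominal level). What they do not
show: robustness to features real libraries have and the generator does
not — sequencing error, ligation and nuclease biases, multimapping,
isoform ambiguity, codon-usage-dependent dwell variation, rRNA
contamination, or batch structure. Conclusions about real data still
require the diagnostics (periodicity, offset reliability flags, length
histogram) to look healthy first.

## Problem sizes and time points

The tests run the full stack at sizes chosen to keep sampling error well
inside the asserted tolerances while remaining quick: 200 transcripts and
20,000–40,000 reads for recovery and coupling analyses (about 100 reads
per transcript, i.e. deeply covered transcripts, matching the regime in
which TI and pause calling are meaningful), 600–2,000 transcripts where a
±0.02–0.03 tolerance on recovered frequencies demands it, 1,000 random
profiles for the oracle-equivalence checks, and 20 seeds for the
coupling and power claims. The default five time points with a pause
release schedule of (1, 0.10, 0.05, 0.02, 0.02) emulate pausing that is
strong in darkness and largely released within half an hour of light.

## Known limitations

- Pause scores at very low coverage are dominated by the z-filter; the
  depth > 20 cutoff makes calls on shallow transcripts impossible by
  construction, so recall is only defined for adequately expressed
  transcripts.
- The offset estimator needs a visible initiation peak; libraries
  depleted of initiating ribosomes (e.g. run-off protocols) will fall
  back to the default offset with the unreliable flag set.
- The NB Wald test with moment dispersion is anti-conservative for very
  few replicates and very low counts; it is a filter component here, not
  an inference engine.
- The 0-order PWM background understates p-values on strongly
  autocorrelated sequence; hits near the threshold deserve skepticism on
  such transcripts.
- `gc_absolute` averages whatever anchors reach each flank position, so
  flank tails mix transcript subsets; comparisons should use matched
  flanks (the bundled analyses do).
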