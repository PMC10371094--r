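---
title: "Methods: fragment-level cfDNA analysis in cffrag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fragment-level cfDNA analysis in cffrag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cffrag)
```

## The measurement model

`cffrag` treats a sequenced cfDNA sample as a set of aligned,
deduplicated fragments: half-open 0-based genomic intervals with strand
and optional mapping quality and sequence. Everything downstream is a
deterministic function of that set plus a handful of parameters, which
is why the whole stack can be exercised with simulated fragments.

Assumptions inherited from upstream processing: alignment is already
done (BAM/SAM input, or a fragment TSV exported from it), duplicates
are removed (UMI-based or positional), and for paired-end data the
proper-pair reference span *is* the fragment — appropriate when reads
are long relative to fragments or pairs were merged before alignment.
Default filters keep mapping quality ≥ 20 and lengths in 20–400 bp on
the primary chromosomes; these are conventional, not fitted, and all
configurable through `frag_filters()`.

## Jagged peak-valley index

The fragment-length histogram is percent of in-range reads per 1-bp
length. Salivary cfDNA shows a comb of peaks spaced ~10 bp below
100 bp; the jagged peak-valley index quantifies its depth as the mean
drop from each detected peak to the first valley on its right,

$$J = \frac{1}{n}\sum_{i=1}^{n} (P_i - V_i),$$

in percent-of-reads units. Peaks and valleys come from an alternating
extremum detector with two tuning values: `lookahead` (grid points the
detector scans past a candidate before confirming it; default 1) and
`delta` (minimum amplitude drop, in % reads, to count as a real
extremum; default 1e-4). At these defaults every strict local extremum
of the histogram is resolved, which is the regime the index is defined
in; larger `delta` suppresses shallow wiggles, larger `lookahead`
tolerates short counter-movements.

Numerical conventions, chosen once and tested:

* the detector runs on the histogram exactly as built — no smoothing;
* a candidate extremum sitting on the first grid point is treated as a
  boundary artefact: it flips the search mode but is not reported;
* a trailing candidate valley after the last reported peak *is*
  reported, so a histogram that ends on a descent contributes its final
  drop;
* a final peak with no valley to its right never enters the pairs;
* a histogram with no pairs scores 0 — a featureless profile has no
  jaggedness.

At `delta = 0` the detector provably reduces to the brute-force
neighbour rule (a point strictly above both neighbours is a peak,
strictly below is a valley) on interior points; the test suite checks
this equivalence on 1000 random series.

## Binned fragmentomics

`make_bins()` tiles each chromosome from 0 in fixed windows (default
1 Mb), truncating the last bin, so a chromosome of length $L$ yields
$\lceil L/10^6 \rceil$ bins; the bundled GRCh38 sizes give 2887
autosomal bins. Fragments are assigned to exactly one bin by midpoint
$\lfloor (start+end)/2 \rfloor$ — midpoint rather than leftmost base so
long fragments near a boundary are not systematically pushed into the
left bin. Per-bin coverage is a read-count percentage (not base-level
depth): at ~1 Mb resolution and low coverage the two are nearly
proportional and counts are exactly conserved, which the tests verify.

The fragmentomic score is `count(length < 100) / count(length >= 100)`.
A fragment of exactly 100 bp counts as long, so the two classes
partition the data. Bins with no long fragments get `NaN` rather than a
score, and such features are masked rather than propagated into the
cohort tests. The mitochondrial fraction is the chrM percentage of all
human-mapped fragments (nuclear + mitochondrial), matching its use as a
"share of the human signal" measure.

## End motifs, entropy, G-quadruplexes

Each duplex fragment has two 5' ends; `extract_end_motifs()` takes the
k (default 4) reference bases at the left end and the reverse
complement of the k bases at the right end, pooling both into one
profile over the $4^k = 256$ vocabulary. Reading the reference rather
than the read bases makes the profile insensitive to sequencing error
and lets sequence-free fragment TSVs participate; the cost is that only
reference Ns can produce discarded motifs. Both-end pooling is the
dominant convention for duplex fragments; nothing in the statistics
depends on it beyond doubling the counts.

Entropy is Shannon's $H = -\sum_m f_m \log_2 f_m$, reported in bits so
the ceiling is the interpretable 8 bits of a uniform 256-motif profile;
any other base is a monotone rescale.

The G-quadruplex scanner uses the canonical sequence definition —
four runs of ≥ 3 Gs separated by 1–7-base loops,
`G{3,}([ACGT]{1,7}G{3,}){3}` — on both strands by default, and reports
the percent of fragments containing at least one match. Per-fragment
prevalence (rather than per-kilobase density) was chosen because the
fragment is the biological unit the assay samples; run lengths, loop
bounds and strand handling are all parameters of `gquad_params()`.

## Peaks, elements, coverage profiles

Peak calls enter as narrowPeak; a summit offset of −1 falls back to the
interval midpoint. Peaks-per-read is the raw ratio (also scaled per
million). Category assignment is by the element overlapping the summit,
with precedence promoter > 5utr > exon > intron and uncovered summits
intergenic; expected shares are the precedence-resolved fractions of
the genome so observed/expected is exactly share-of-peaks over
share-of-genome, and the genome-share-weighted mean of O/E is 1 for
uniformly placed peaks (tested statistically). Relative coverage
profiles accumulate per-base fragment coverage in ±2-kb windows around
element centers (flipped for minus-strand elements), average across
elements, and divide by the window mean, so flat coverage reads 1.0 by
construction; elements whose window leaves the contig are dropped with
a tally rather than zero-padded.

## Microbiome summaries

Taxa tables are classifier output: counts per taxon per sample with a
semicolon lineage (kingdom through genus). Rows flagged `host`
(secondary human alignments) are excluded from every microbial
quantity. Rank aggregation sums counts over the lineage label at the
requested rank, pooling taxa whose lineage stops short into
`unclassified`, which keeps per-sample totals exactly conserved. Alpha
diversity is Shannon's index in nats (ecology convention, via vegan);
read-origin percentages are simple shares of total reads.

## Cohort statistics

Per-feature comparisons use Welch's unequal-variance t test
(Satterthwaite df, two-sided). Two all-constant equal groups return
t = 0, p = 1 by convention rather than erroring, so degenerate features
stay in the table.

Multiplicity is controlled with the two-stage step-up of Benjamini,
Krieger and Yekutieli at Q (default 0.05): stage 1 runs the linear
step-up at $q' = q/(1+q)$, estimates the null count $m_0 = m - r_1$,
and stage 2 reruns the step-up at $q' m/m_0$; zero or full stage-1
rejection short-circuits. Alongside the binary mask the scan reports
per-feature q values — BH-adjusted p values rescaled by $m_0/m$ — so
volcano-style output (difference vs q) is reproducible. The suite
verifies the mask against an independently coded step-by-step oracle
and checks null false-rejection control by simulation.

ROC AUC is computed from midranks as the Mann–Whitney U statistic over
$n_1 n_2$, so ties count half and the value is invariant under strictly
monotone transforms; an `oriented` attribute carries
$\max(AUC, 1-AUC)$ for direction-free reporting.

PCA integration centres and unit-variance-scales features (so scores in
different units are commensurable), drops zero-variance features with a
record, and decomposes by SVD; the ln-transform some tools apply is
deliberately not used because the inputs are already comparable scores,
not raw intensities. Up to 20 components are kept by default, and a
Welch test on PC1 summarises group separation. Sample clustering, when
wanted, is correlation-distance average linkage over the feature matrix
(`cluster_order()`), reported as a leaf order rather than an image.

## The synthetic cohort generator

`simulate_fragments()` draws lengths from an analytic mixture on
20–400 bp: a Normal(short_mode = 60, spread = 12) short component whose
density is multiplied by a truncated cosine comb
$(1 + a\cos(2\pi L/10))_+$ and renormalised, plus a `mono_weight` share
of Normal(167, 15). The truncated cosine was chosen because its mass is
computable in closed form, so sampled histograms can be tested against
exact expectations. Placement is a telomere-weighted multinomial over
bins with uniform position within the bin; a binomial `mito_fraction`
share lands on chrM; an optional `motif_bias` snaps a fraction of left
ends onto reference positions carrying favoured 4-mers, which is what
makes entropy differences plantable; microbial communities are
Dirichlet-multinomial draws from group compositions over a small
built-in oral-like genus taxonomy.

The default two-group templates (`cohort_templates()`) plant:
comb amplitude 0.8 vs 0.1, mononucleosome weight 0.05 vs 0.30,
mitochondrial fraction 0.02 vs 0.08, telomeric placement bias 2 vs 1,
end-motif snap weight 0.1 vs 0.4, and an even vs skewed community —
directions that mirror the case/control contrasts the toolkit is meant
to detect (less jagged, longer, more mitochondrial, lower-entropy,
lower-diversity disease samples). Per-sample heterogeneity is a
lognormal jitter (s.d. 0.1 on the log scale) of the continuous
parameters.

What the generator does *not* emulate: GC and mappability bias,
sequencing error, chimeric or duplicate fragments, copy-number
structure, strand asymmetries of nuclease cleavage, and any real
genome sequence (the toy reference is random-composition). Passing
tests therefore demonstrate that the estimators recover what was
planted under the stated statistical model — not that real salivary
cohorts will separate, which depends on effect sizes the model takes
as inputs.

## Problem sizes and determinism

Simulated checks use 50,000 fragments per sample on a ~5-Mb two-contig
toy genome (plus chrM), cohorts of 10 samples per group over 20 seeds
for recovery checks, and 100–200 replicate null cohorts of 1000
features for FDR calibration — sizes at which every statistical check
is stable yet the whole suite runs in minutes on a laptop. All
generators are deterministic given a seed; cohort outputs written twice
with the same seed are byte-identical, and the acceptance script
threads a single `--seed` through every stochastic step.

## Known limitations

* Fragment definition trusts the aligner: soft-clipped bases shorten
  the apparent fragment, and no re-alignment or clip-rescue is done.
* Coverage quantities are read-count based; base-resolution coverage
  differs slightly in truncated terminal bins.
* The element annotator assigns one category per summit; peaks spanning
  category boundaries contribute only their summit position.
* The BKY q values are a Prism-style reporting convenience tied to the
  stage-1 $m_0$ estimate; the decision-relevant object is the mask.
* With very few features (< ~10) the adaptive FDR step loses its
  advantage over plain BH; the scan is meant for wide feature sets
  (bins, motifs, taxa).
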