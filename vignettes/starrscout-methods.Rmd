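---
title: "Enhancer discovery and compartment characterization from STARR-seq fragment libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enhancer discovery and compartment characterization from STARR-seq fragment libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The assay and the statistical model

STARR-seq (self-transcribing active regulatory region sequencing) clones
randomly sheared genomic fragments downstream of a basal promoter; a fragment
that acts as an enhancer drives transcription of itself, so its abundance in
the cDNA (reporter transcript) library, relative to its abundance in the
plasmid input library, measures its enhancer activity. `starrscout`
implements the downstream analysis of such a screen: it consumes mapped
fragment intervals for the two channels across biological replicates and
produces a catalog of replicate-consensus candidate enhancers together with a
characterization of the enhancer sequence compartment.

## Peak detection

Candidate peaks are fixed-width windows (`peak_width`, default 500 bp) placed
on maxima of the per-base cDNA fragment coverage. Only positions whose
coverage reaches the `min_quantile` (default 0.99) quantile of the positive
coverage values genome-wide are eligible; windows are chosen greedily in
order of descending coverage (ties to the lowest coordinate) and any window
overlapping an already selected one is suppressed, so per-replicate windows
are non-overlapping. Y, unplaced and mitochondrial sequences are excluded
from analysis before calling.

Each window is tested with an upper-tail binomial test. Writing $k_c$ and
$N_c$ for the cDNA fragment count overlapping the window (one or more bases)
and the cDNA library size, and $k_i$, $N_i$ for the input channel, the null
success probability under the default model 2 is $p_0 = k_i / N_i$ and

$$p = P(X \ge k_c), \quad X \sim \mathrm{Binomial}(N_c,\ p_0).$$

Model 1 instead uses $p_0 = \text{peak width} / G_e$ with $G_e$ the non-N,
non-excluded genome length. Windows are retained when $p \le$ `max_pval`
(default 0.001, uncorrected — the method's convention, kept deliberately)
**and** the library-size-normalized enrichment
$(k_c/N_c)\,/\,(\max(k_i,1)/N_i)$ is at least `min_enrichment` (default 3).
A zero input count is floored by a pseudocount of one fragment and the peak
is flagged. No multiple-testing correction is applied; both filters together
define the operating point.

A consensus enhancer requires one peak from *every* replicate with pairwise
mutual overlap of at least `min_consensus_overlap` (default 250) bases. For
intervals, the minimum pairwise overlap of a tuple equals the width of its
common intersection, so the rule is implemented as: join peaks across
replicates, keep tuples whose common intersection is at least 250 bp, and
report that intersection. Reporting the intersection (rather than the union
or a representative peak) guarantees that every reported base is supported
by all replicates. Activity is the mean across replicates of the supporting
peaks' log2 enrichment; a log2 value of 2 corresponds to 4-fold activity.

## Genomic classification

Each consensus enhancer receives UTR, exon and mRNA scores: the fraction of
the enhancer covered by the single best feature of that type (the max rule;
overlapping two exons by 100 and 250 bp of a 500-bp enhancer scores 0.5, not
0.7). Classification is hierarchical: no gene overlap → `intergenic`;
UTR/CDS overlap → the class with the higher score (`exon` means CDS; an
exact tie goes to UTR and is flagged); gene overlap with neither → `intron`,
labelled with the ordinal of its intron. Intron ordinals are computed on the
longest transcript per gene and are strand-aware: a gap upstream of the
first coding exon is the `5utr_intron`, the gap after the k-th coding exon
is `intron_k`. The chromosome-level statistics are a Pearson chi-square of
call counts against non-N chromosome lengths and a one-way ANOVA of activity
by chromosome.

## Matched controls and the ten-control consensus procedure

Every composition statistic is referenced to ten control sets. For each
enhancer, each set contains one window of identical length drawn uniformly
on the same chromosome with start within 0.5 Mb of the enhancer's start
(clipped to chromosome bounds); draws overlapping an exon or a candidate
peak, or containing more than 1% N, are rejected and redrawn, up to
`max_attempts` (default 1000) before the pipeline aborts — we fail loudly
rather than silently widening the band, because relaxing the locality
constraint would change the null. Controls may overlap each other and
non-exonic gene parts; only exons and candidate peaks are excluded.

A metric (GC content, repeat presence, repeat counts, ...) is compared with
a gatekeeping procedure: (1) Kruskal–Wallis across the ten control sets — if
they differ at p < 0.001 the controls are heterogeneous and no verdict is
issued; (2) Kruskal–Wallis across all eleven groups — stop if not
significant; (3) ten two-sided Mann–Whitney U tests of enhancers against
each control set. The metric is called enriched (or depleted) only when all
ten post-hoc tests are significant at p < 0.001 *and* all ten control means
shift in the same direction. The all-ten rule is strict by construction: a
metric significant in nine of ten comparisons is reported as not
significant. Mann–Whitney uses the normal approximation with tie correction
(set sizes here are large); direction is measured on means, with medians
also reported.

## Perfect repeats and dinucleotide classes

Perfect microsatellites are maximal uninterrupted runs of a 1-, 2- or 3-base
unit, at least 6 bases long — equivalently at least 6, 3 and 2 full units;
the two thresholds coincide at 6 bp. Runs are read at their leftmost phase
and counted in full units (`ATATATA` is one AT run of 3 units and 6 bases;
the trailing A is not part of the run). Units that are repetitions of a
shorter unit (AA, GGG, ...) are never reported, and scanning is
hierarchical: bases inside mononucleotide runs are masked before the
dinucleotide scan, and mono- plus dinucleotide runs before the trinucleotide
scan. Dinucleotide enrichment is summarized over four reverse-complement
classes — CA = {CA, AC, TG, GT}, GA = {GA, AG, TC, CT}, GC = {GC, CG},
TA = {TA, AT} — as `log2(enhancer fraction / control fraction)` per control
set, reported as mean ± sd over the ten sets. Each self-complementary class
(GC, TA) is counted once per sequence; double counting would scale the
fractions without changing any comparison, so the single count is used.

## Motif enrichment

JASPAR-format PFMs are converted to log2-odds matrices with a total
pseudocount of 0.8 per column split by the background frequencies. A
sequence matches a motif when some window on either strand scores at least
`threshold` (default 0.8) of the motif's maximum attainable score; windows
containing N are skipped. Enrichment per control set is a one-sided Fisher
exact test on sequence-level presence (enhancers vs that control set) at
alpha 0.05, and a motif is called enriched overall when it is enriched in at
least 8 of the 10 comparisons. This presence-based Fisher test is this
package's own replacement for a rank-based motif enrichment tool whose exact
internal statistic is not part of the method's published description; the
8-of-10 consensus rule, which carries the robustness, is unchanged. The
repeat content of motif matches is computed per sequence after merging
overlapping match intervals: fraction of matched bases inside repeat runs,
with zero-match sequences excluded.

# The synthetic study generator

The generator exists so that every stage can be tested against known truth
without any external download. Its defaults are the package's reference
study conditions:

* five chromosome arms of 1 Mb plus a 15-kb excluded mitochondrial
  sequence; 0.5% of each arm in N-gap blocks placed outside genes and
  enhancers;
* background GC 0.44 with independent and identically distributed bases; 60
  single-isoform genes of 3–6 exons with explicit 5′/3′ UTRs (half the genes
  have a UTR-only first exon so the 5′UTR-intron class is exercised);
* 60 planted enhancers of 600–1000 bp — about 12 per Mb, the genome-wide
  density a saturating screen reports — placed in intergenic or intronic
  space (53:47), rewritten at GC 0.50, each carrying one planted
  dinucleotide repeat run (7–10 units of CA or GC) and one instance of each
  planted motif (two synthetic PFMs; four further synthetic PFMs serve as
  decoys);
* fragment libraries of 800–1000 bp with 380,000 fragments per channel per
  replicate — about 68× median genome coverage, the depth a genome-wide
  screen attains after cloning — in three biological replicates. Input
  fragments are uniform over the non-N genome; cDNA fragment rates are
  multiplied by `enhancer_fold` (default 8) where the fragment *midpoint*
  falls inside a planted enhancer, implemented by thinning a uniform
  proposal.

Midpoint attribution at generation differs intentionally from the ≥1-bp
overlap rule used when counting fragments in windows: the midpoint rule is
symmetric and avoids edge double-counting at generation time, while overlap
counting is what a peak caller observes. One consequence is dilution — a
500-bp window catches many fragments whose midpoints lie outside the
enhancer, so the observable window-level enrichment at `enhancer_fold = 8`
is roughly 4–5, comfortably above the ≥3 filter at the default depth but
well below 8. Interpreting the fold parameter as the observable ratio would
be a mistake.

What the generator does *not* emulate: sequencing errors and read-level
artifacts, PCR duplicates, mappability structure, GC-dependent coverage
bias, overdispersion beyond Poisson (negative-binomial noise is deliberately
off so the null calibration stays clean), realistic gene density, repeat
landscapes or isoform complexity. Passing tests on synthetic data therefore
demonstrate the correctness of the algorithms under the stated model, not
performance on real libraries.

# Numerical and design choices

* Coordinates are `GRanges` (1-based, closed) everywhere inside the package
  — the native Bioconductor convention — with BED (0-based, half-open)
  converted at the I/O boundary. BED round trips are bit-exact.
* Merging follows `bedtools merge` default semantics: bookended intervals
  are unified. Reciprocal overlap follows `-f x -r -u`: the fraction must be
  met on both intervals and each query is reported once.
* Closest-feature distances are gaps in bases (0 for touching intervals);
  overlap is distance 0. Ties break to the lowest feature start, then
  lexicographic id, for determinism.
* Greedy window selection breaks coverage ties to the lowest coordinate.
  Windows near chromosome ends are shifted inward to keep the fixed width;
  a shifted window that would collide with a higher-coverage window is
  dropped.
* The coverage quantile is computed from run-length tables (type-1 weighted
  quantile), never by decoding whole-genome vectors.
* Determinism: every stochastic stage takes an explicit seed; per-replicate
  fragment streams use `seed + replicate`, per-control-set streams use
  `seed + 1009 * set`. Identical seeds give byte-identical artifacts.
* Degenerate inputs: all-N sequences give `NA` GC; zero-coverage libraries
  give no windows; zero within-group variance makes the activity ANOVA
  return a flagged `NA` rather than an error; a control set with zero class
  fraction is excluded from the log2 mean with a warning.

## Problem sizes in the test-suite and acceptance runs

The bundled tests exercise the full reference conditions (5 Mb, 68×, three
replicates) once for recovery and twenty times at `enhancer_fold = 1` for
null calibration, and use reduced configurations (0.4–0.8 Mb arms,
proportional depth) for the per-module tests; oracle comparisons run on
hundreds of random intervals and a thousand random kilobase sequences.
These sizes were chosen so that statistical assertions have the power they
claim while the whole suite stays interactive.

# Known limitations

* The candidate-window internals of the original peak-calling tool are not
  published beyond its parameter names; the quantile basis and the greedy
  maxima selection used here are this package's own definitions and are not
  asserted to be byte-identical to that tool.
* Whether the published enrichment filter used raw or library-size
  normalized ratios is ambiguous; the normalized form is implemented (the
  two coincide at equal library sizes).
* The motif stage tests sequence-level presence, not rank-based enrichment;
  motifs whose signal is a shift in match *counts* without a shift in
  presence would be missed.
* Enhancer-to-target-gene assignment is out of scope: closest genes are
  reported, but the nearest gene is frequently not the regulated gene.
* Control sampling excludes exons and candidate peaks only; if UTR-only
  regions should also be excluded, pass an extended exclusion set as
  `peaks`.
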