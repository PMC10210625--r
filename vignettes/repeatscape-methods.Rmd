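---
title: "Methods: satellite landscapes, centromeres, hotspots and self-alignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: satellite landscapes, centromeres, hotspots and self-alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`repeatscape` implements the computational core of a satellite-centric
analysis of a chromosome-scale rodent genome: locating the single putative
centromere per chromosome from a sequence-complexity trough; resolving its
satellite composition down to monomer families, arrays and a three-way
centromere classification; detecting telomere-motif arrays including
interstitial relics of ancient fusions; estimating local recombination
rates from a genetic map and calling hotspots; testing whether a flagged
gene set (GC-content outliers, candidates for GC-biased gene conversion)
clusters near those features; and quantifying how much of a chromosome is
present in multiple copies via exact self-alignment. Every stage is
exercised against a synthetic genome whose features are planted with
machine-readable truth, so the pipeline is testable end to end without any
external data.

# The satellite model

The satellite hierarchy mirrors what long-read assemblies of gerbil-like
genomes show. Four monomer families are modelled: a 6-bp family whose
sequence is the telomere motif TTAGGG, and families of 37, 127 and
1747 bp. Monomers assemble into arrays of four kinds: composite "A-C"
arrays in which roughly 10-50 copies of the 6-bp family alternate with
5-10 copies of the 127-bp family; and homogeneous B, C and D arrays made
of one family only. A centromere is one to three consecutive arrays and is
classed *simple* (one array), *asymmetric* (two arrays of different type)
or *symmetric* (a middle array sandwiched between two arrays of a shared,
different type). Within an array all copies usually share one orientation;
some arrays instead consist of large same-orientation blocks separated by
strand switches, and an extreme case is an intra-arm megabase-scale B
expansion whose orientation switches every ~10^5 bp.

# Synthetic genomes as study conditions

`simulate_genome()` generates four chromosomes (5-8 Mb at default
settings, one seed in two minutes on a laptop) chosen to exercise every
downstream stage:

* **chr1** - simple centromere (single A-C array, ~600 alternation
  rounds, ~0.7 Mb), one 10x recombination hotspot, one 70-copy
  interstitial telomere array.
* **chr2** - asymmetric centromere (A-C plus a 15 000-copy B array), a
  69-copy interstitial telomere array (just under the reporting
  threshold), no hotspots.
* **chr3** - symmetric centromere (A-C / B / A-C with the flanks in
  opposite orientation), a 2.5-Mb intra-arm B expansion carrying 20
  orientation blocks (~125 kb each), and two hotspots.
* **chr4** - grown from a 1.2-Mb seed by three breakage-fusion-bridge
  cycles (each appends the reverse complement of a random 70-95% suffix),
  yielding a chromosome almost entirely present in multiple copies and no
  satellite centromere.

Design choices worth recording:

* **Background model.** Non-repetitive sequence is i.i.d. at GC 0.42.
  That suffices for window metrics and exact-match nulls but carries no
  transposable elements, gene structure or GC isochores - passing tests
  demonstrate correctness of the measurements, not realism of the null
  landscape.
* **Mutation.** Monomer-copy mutation is substitution-only and defaults
  to 0 so that planted copy counts, coordinates and orientation blocks
  are base-exact; the rate is a parameter and the test-suite re-runs the
  annotation path at 5% substitution. Indels are deliberately excluded
  from the default model to keep truth coordinates exact.
* **Monomer drawing.** Random monomers are rejection-sampled until
  primitive (no shorter unit tiles them), free of the telomere motif and
  its reverse complement, and sharing no 15-bp substring with any other
  family, keeping family assignment unambiguous.
* **Hotspot folds.** The hotspot caller thresholds at 5x the *pooled
  genome-average* rate, which the planted hotspots themselves inflate
  above the base rate (by ~24% at default settings). Planted folds are
  specified relative to the base rate, so defaults of 8-10x are used:
  they stay above 5x the inflated average. A planted fold of 5-6x over
  base would sit below the callable threshold by construction - a
  property of the definition, not a detection failure.
* **Telomere planting.** Terminal arrays of 200-500 exact motif copies at
  both chromosome ends (left end in reverse-complement orientation), and
  interstitial arrays of exactly 70 and 69 copies to exercise both sides
  of the copy-number filter. Flanking bases are adjusted so no accidental
  aligned extra copy extends a planted run.

# Window tracks

GC and gene density use 1-kb and 1-Mb windows; Shannon entropy and
linguistic complexity use 10-kb windows; all step 1 kb by default. Windows
are half-open `[start, start + window)`; at most one trailing truncated
window is emitted and flagged rather than dropped, because troughs can
abut chromosome ends on telocentric chromosomes. Windows with more than
50% N are undefined; k-mers containing N are skipped.

Linguistic complexity is the vocabulary-usage ratio
\(\sum_{k\le k_{max}} V_k \big/ \sum_{k\le k_{max}} \min(4^k, L-k+1)\)
with \(V_k\) the number of distinct k-mers in the window. The default
\(k_{max}\) is the smallest k with \(4^k \ge\) window length (7 for 10-kb
windows), capped at 12 by the 4^k lookup tables of the scan kernel.
Absolute values of complexity metrics differ between published
implementations; only the relative trough behaviour is consumed
downstream, and the tests assert exactly that (satellite windows score
below i.i.d. windows of the same GC for every seed tried).

# Centromere localization

The caller median-smooths the complexity track (5 windows), marks trough
windows, merges marked windows separated by at most 10 windows, filters
merged regions to a length band, and returns the region with the lowest
mean complexity; a call requires a depth (chromosome median minus region
mean) of at least 0.1. Ties go to the larger, then leftmost region.

Two numerical choices deserve explanation:

* **Half-height marking.** Windows are marked below
  \(q + 0.5\,( \mathrm{median} - q)\) where \(q\) is the 5% quantile. A
  bare quantile cutoff marks only the deepest ~5% of windows; a broad
  trough (often 10%+ of a small chromosome) would be truncated at an
  arbitrary interior point and its plateau split. Interpolating halfway
  to the median keeps whole plateaus marked while background windows,
  whose complexity distribution is tight, stay unmarked.
* **Floor-level boundary refinement.** Inside the trough the track sits
  on a flat floor, and any background sequence entering a 10-kb window
  lifts its value sharply (roughly 3 vocabulary units per background
  bp). The reported boundaries are therefore the outermost windows still
  at floor level (region median plus 5% of the depth). On planted arrays
  this recovers boundaries to within a few hundred bp - well inside one
  window - where interpolating a half-depth crossing is biased by the
  nonlinearity of vocabulary saturation.

The length band defaults to 0.5-12 Mb, matching megabase-scale
centromeres on ~100-Mb chromosomes; for the desk-scale synthetic genome
the simulator's config carries proportionally scaled bounds (0.5-2 Mb).
The upper bound is load-bearing on chromosomes that carry both a
centromere and a larger intra-arm expansion: the expansion is the deeper,
*longer* trough, and the band excludes it so the centromere is still
found; the expansion is then recovered explicitly by
`detect_expansions()`. An optional externally known prior interval (e.g.
a karyotype constriction) can simply be intersected with the calls by the
user; the caller itself does not require one.

# Periodicity spectrum and monomer consensus

`interval_spectrum()` tallies, for every k-mer occurring at least 3 times
(k = 8), the distances between consecutive occurrences. A tandem array of
period p repeats each of its k-mers at spacing p, so the tally
concentrates at p; the detector reports the arg-max lag at or above 2
(lag 1 is the homopolymer shift), with ties toward the smaller lag and a
minimum total tally of 50. On exact arrays every consecutive spacing
equals the period, so no harmonic appears; substitutions knock out
occasional k-mer copies and surface skipped-copy harmonics at integer
multiples - both behaviours are asserted against a brute-force
occurrence-list oracle. The aggregate tally (rather than a per-k-mer
spectral matrix) is sufficient because downstream only dominant and
co-dominant periods are consumed.

Monomer consensus extraction anchors on the most frequent k-mer whose
modal occurrence spacing tiles the requested period, slices the array at
anchors one period apart, and majority-votes columns. The result is a
cyclic rotation of the planted monomer (rotation-set equality is the
tested contract; at 2% substitution the consensus lands within Hamming
distance 2 of a rotation).

# Telomere arrays

Runs of exact tandem motif copies (TTAGGG and its reverse complement,
scanned separately) are located by maximal-run matching; runs of at least
70 copies are reported, and runs starting or ending within 10 kb of a
chromosome end are *terminal*, the rest *interstitial*. Exact-copy
counting makes the 69/70 boundary crisp and testable. Copy-number
filters of this kind are often stated ambiguously (inclusive versus
exclusive); the inclusive reading is implemented - a 70-copy array is
reported - and the threshold is an ordinary parameter for anyone who
wants the other convention.

# Monomer mapping and array segmentation

`map_monomers()` places family consensi by greedy non-overlapping
tiling: candidates are anchored at exact shared k-mers with the doubled
consensus (k = min(8, monomer length), both strands), scored by Hamming
divergence, accepted greedily - longest family first, then best score -
and finally extended in tandem steps of one monomer length so that
mutated copies inside arrays are rescued even when no seed k-mer
survives in them. Longest-first ordering matters once copies are
mutated: a substitution inside a 127-bp monomer occasionally recreates
an exact 6-bp telomere-motif word, and a zero-divergence 6-bp placement
must not be allowed to displace the surrounding long-monomer copy, while
an acceptable long placement is near-certainly a true copy. Hamming (substitution-only) scoring
matches the simulator's mutation model; at the default divergence cap of
0.2 a 6-bp monomer admits one mismatch, so for heavily mutated material a
cap of 0.34 (two mismatches on a 6-mer) is the appropriate setting and is
what the 5%-substitution tests use.

Segmentation merges same-family hits within 500 bp into runs, recognizes
maximal alternating short/long-family chains of at least 3 alternations
as composite AC arrays (alternation, not the descriptive 10-50/5-10 copy
ranges, is the defining rule), and types remaining runs of at least 10
copies by family. Array orientation blocks are maximal same-strand hit
runs; for AC arrays the long family carries the orientation signal.
Classification then reads the array sequence overlapping the centromere
call: one array - simple; two differing - asymmetric; a sandwich with
matching flanks - symmetric; anything else unclassified.

Isolated background hits (a 6-bp monomer recurs by chance every few
hundred bp of random sequence) are controlled by the copy threshold, but
a handful can adjoin a true array within the 500-bp gap; planted copy
counts are therefore verified as hits *within* the truth interval, which
the tests require to be exact at zero mutation and within 2% at 5%
substitution.

# Marey maps and hotspots

Local recombination rate is the OLS slope of cM on Mb in sliding windows
of 8 consecutive markers stepping one marker. The genome average is the
pooled total map length over the pooled marker span (robust to uneven
marker density; slopes are invariant to constant cM shifts, and negative
noise slopes are retained in output but never hotspot-eligible). Windows
at or above 5x the average merge - overlapping and adjacent qualifying
windows into one region - since reported per-chromosome hotspot counts
suggest merged regions rather than window counts. Chromosomes flagged
non-recombining (a Y) can be excluded from the average.

# Spatial permutation tests

Four observed statistics over the flagged gene subset: nearest
same-chromosome flagged neighbour distance; distance to the nearest
hotspot; distance to the nearest telomere array (interstitial or
otherwise); and position along the chromosome arm from the centromere
edge (0%) to the telomere end (100%). Gene location is the midpoint,
the only choice symmetric under strand. Distances are same-chromosome
only; genes
alone on their chromosome, on feature-free chromosomes, or inside the
centromere are excluded and the used count reported, so the exclusion
policy is auditable.

The null resamples subsets of the same size from the whole annotated gene
universe without replacement, recomputes the statistic with identical
exclusion rules, and reports
\(p = (1 + \#\{\text{null at least as extreme}\}) / (n_{perm} + 1)\),
one-sided with the direction fixed per statistic (distances: less; arm
position: greater). The pseudocount makes the smallest attainable p
exactly \(1/(n_{perm}+1)\) - the floor reported when an observed value
beats a million draws. Calibration is tested by drawing the "flagged" set
itself from the null (200 replicates at 500 permutations must give
p <= 0.05 between 2% and 9% of the time) and power by planting flagged
genes at hotspot centres with 100-kb Laplace offsets.

# Self-alignment

`find_self_matches()` enumerates maximal exact matches (MEMs) of at least
1000 bp between a chromosome and itself (identity diagonal excluded, each
unordered pair once) and between the chromosome and its reverse
complement, from a suffix array with LCP over the sequence concatenated
with its reverse complement. A pair of suffixes in the same
high-LCP block is a MEM when its LCP reaches the threshold and the
preceding characters differ; inverted pairs found twice are
deduplicated after canonical ordering. The brute-force oracle in the test
suite re-derives segment sets per diagonal with run-length encoding and
must agree exactly for min_len in {5, 10, 20} on sequences up to 2 kb.

`duplicated_fraction()` is the fraction of positions covered by either
side of any segment passing the length filter - both copies of a
duplication count, because being in multiple copies is a property of
positions. On breakage-fusion-bridge chromosomes of three or more cycles
this exceeds 0.9 at zero mutation (suffix fractions of 0.7-0.95 leave at
most ~6% of the seed uncopied), echoing the >90% duplicated-base figures
reported for real heterochromatic chromosomes, while i.i.d. chromosomes
score exactly 0 at the 1-kb filter. Exact matching is deliberate: the
statistic is coverage by long alignments, and sensitivity to diverged
duplications is recovered by lowering the length filter rather than by
gapped alignment. Satellite arrays harbour quadratically many MEMs, so
the finder carries a segment budget and aborts with advice (raise
min_len, or mask satellite regions first) rather than exhausting memory.

# Problem sizes used by the automated checks

The test-suite runs the full recovery pipeline on 20 seeds of the default
four-chromosome genome (boundary, class, copy-count, orientation,
hotspot and telomere checks), 20 seeds of 5%-substitution arrays for the
divergence-tolerant counts, 100 random instances up to 2 kb for the two
oracle-equivalence checks, and 200 replicate permutation tests at 500
permutations for calibration. These sizes were chosen so the whole suite
completes in well under half an hour on one core while every check
retains enough replication to be meaningful; all of them are plain
parameters in the tests and scale up directly.

# Known limitations

* The background model is i.i.d.; no transposons, segmental duplication
  background, or GC heterogeneity, so false-positive behaviour of the
  centromere caller on real genomes is not characterized here.
* Monomer placement is substitution-only; indel-diverged satellite
  families would need the (slower) edit-distance mode that is left as an
  explicit non-goal.
* Absolute linguistic-complexity values are implementation-specific;
  only ordering and trough geometry are contracted.
* The spectrum kernel caps k at 12 (4^k tables); period detection is
  k-invariant on tandem arrays across the tested 6-12 range.
* Self-alignment reports exact matches only; a diverged duplication
  appears as several shorter segments, which the coverage statistic
  absorbs but a segment count would not.
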