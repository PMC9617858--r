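---
title: "Reconstructing complex germline rearrangements from breakpoint calls and Hi-C"
author: "CGRecon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing complex germline rearrangements from breakpoint calls and Hi-C}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CGRecon)
```

# The problem

Germline chromoanagenesis — chromothripsis (shattering of one or a few
chromosomal regions followed by imperfect rejoining with frequent fragment
loss) and chromoplexy (balanced exchange of large fragments among several
chromosomes) — produces derivative chromosomes whose structure cannot be
read off any single data type. Long-read and short-read structural-variant
callers each emit hundreds of candidate *novel adjacencies* (pairs of
oriented breakends fused by the rearrangement), most of them artifacts,
while Hi-C contact maps show the large-scale consequences of true junctions
as *ectopic* interaction signal but lack base-pair resolution.

CGRecon implements the integrative workflow: rule-based filtering and
two-technology merging of novel-adjacency calls, reconstruction of
derivative chromosomes as paths in a fragment graph, Hi-C-guided grouping
and ordering of incomplete scaffolds through an explicit permutation score,
recomposition of contact maps along a reconstruction, junction-sequence
signatures (microhomology, untemplated insertion, local InDel) from
soft-clipped reads, breakpoint-based haplotype labeling feeding
allele-specific expression, and empirical permutation null models for
breakpoint enrichment in chromatin features. A fully ground-truthed
simulator generates every input the pipeline consumes, so each component is
tested against planted truth.

# Call filtering and merging

Novel adjacencies enter as BEDPE (`readBedpe()`): the breakend position is
the BEDPE start, strand `+` maps to side `tail` (the reference segment
*ending* at the position is fused) and `-` to `head` (the segment
*starting* there). All coordinates are 0-based half-open.

Five filters remove characteristic false-positive classes, each returning a
`kept`/`removed` partition:

* `filterSupport()` — read support below 5% of the genome-wide mean
  alignment coverage (a deliberately lenient, sample-specific threshold).
  Calls without a support count (typically short-read calls) pass.
* `filterHighCoverage()` — a breakend in a 10 kb window whose coverage
  exceeds 3 times the genome mean (collapsed repeats attract spurious
  split alignments).
* `filterNearGaps()` — a breakend closer than 10 kb to an assembly gap.
  The distance is the number of bases strictly between breakend and gap,
  0 inside; the boundary case (exactly 10 kb) is kept.
* `filterSegdup()` — a breakend inside an annotated segmental duplication.
  The single-bp breakend position is tested; padding is configurable but
  defaults to none. This filter can discard true calls near duplications;
  no rescue rule is attempted.
* `filterCohort()` — adjacencies clustered across samples (single linkage;
  two calls link when chromosome pair and sides match and both breakend
  distances are within 1 kb) and present in more than one sample: shared
  calls are alignment artifacts or population polymorphisms, not the
  patient-specific event.

`mergeTechnologies()` pairs long- and short-read calls (both breakends
within 1 kb, sides equal — the scale of the cohort cutoff; the matching
tolerance is not dictated by the data and is exposed as an argument) and
keeps the short-read representative when its caller flagged it *precise*
(base-exact), otherwise the long-read call. `selectLargeScale()` restricts
the working set to trans calls and cis calls spanning strictly more than
100 kb — the events visible in Hi-C — and `attachSmallScale()` re-admits
1–100 kb calls whose breakends coincide (±50 bp) with curated anchor
points.

# Fragment graph and derivative chromosomes

`simplifyBreakpoints()` snaps breakends on the same chromosome closer than
50 bp to a common coordinate (single-linkage groups, leftmost
representative) so complementary junction calls define one fragment
boundary instead of spurious micro-fragments. `makeFragments()` cuts each
chromosome at the snapped breakpoints; `buildGraph()` gives every fragment
a 5' and a 3' node (telomeric sides carry no node), connects the two nodes
of a fragment implicitly, and adds each adjacency as an edge (tail → the
3' node of the fragment ending at the position, head → the 5' node of the
fragment starting there).

A traversable graph needs at most one edge per node.
`resolveConflicts()` ranks competing edges lexicographically: detected by
both technologies, strand concordance with the Hi-C pattern, Hi-C support
score, adjacency id; explicit per-node overrides take precedence (the
counterpart of manual curation). `traverseGraph()` then emits every
maximal path: entering a fragment through its 5' node lists it forward,
through the 3' node inverted. Paths with telomeres at both outer ends are
complete derivative chromosomes, others scaffolds; cycles are emitted as
circular scaffolds with a warning rather than silently broken. A layout
and its whole reversal (orientations flipped) are the same molecule; the
emitted direction is canonicalized to the smaller (chromosome, start) of
the first fragment, and output does not depend on input order.

Fragments without any junction edge are *singletons*.
`classifySingletons()` interprets their normalized short-read coverage:
≤ 0.6 deleted, ≥ 0.85 retained but unplaced, otherwise ambiguous. The
thresholds are this package's choice (coverage near 0.5 is the
heterozygous-deletion expectation, near 1.0 the retained expectation);
they are arguments, not constants. Note that when both junctions flanking
a deleted fragment are themselves lost, adjacent deleted fragments merge
into one singleton interval — the intervening breakpoint has no evidence.

`emitCustomGenome()` materializes layouts as FASTA (reverse-complementing
inverted fragments) with a junction table at the fragment-length prefix
sums, and `junctionSupport()` counts reads whose *single contiguous*
alignment covers ±100 bp around each junction — the package's
reconstruction self-check.

# Hi-C model, recomposition and the permutation score

`ContactMatrix` stores binned genome-wide raw counts as a sparse upper
triangle (25 kb and 100 kb are the working resolutions). Fragment starts
round *up* to the next bin start and ends round *down*; fragments smaller
than one bin are dropped from all map operations. `recompose()` cuts the
map at all fragment boundaries and reorders/reorients rows and columns
according to a set of layouts; it refuses overlapping fragments (copy
gains are outside the model). `subtractControl()` scales a wild-type
control map to 50% of the sample's signal — the expected contribution of
the unrearranged allele — excluding the main diagonal (or additionally the
first subdiagonal) from the scaling sums, subtracts, and clips negatives
to zero (counts are nonnegative; the clip is this package's choice).

`fitDecay()` estimates the expected cis contact count as the mean over all
bin pairs at each distance, isotonically smoothed to be nonincreasing and
floored at a small positive value; the trans expectation is the mean over
all trans pairs. `ectopicScore()` rates a tile (a cell of the breakpoint
grid, `gridPartition()`) by its mean observed/expected ratio and flags it
at ratio ≥ 3 with ≥ 4 nonzero cells. Both numbers are package choices
(the underlying study curated maps visually) and are exposed as arguments.
The whole-tile mean is a blunt instrument: it separates junction tiles
from background cleanly when fragments are small (shatter-region scale,
up to a few hundred kb at 25 kb bins) but dilutes toward 1 for tiles
involving megabase fragments, whose junction signal occupies a corner of a
large tile. `groupScaffolds()` unions scaffolds that share any flagged
tile — in practice the trans tiles between shattered chromosomes — into
derivative-chromosome groups.

For a group with exactly two telomere-bearing scaffolds and at most five
members, `enumerateLayouts()` fixes the telomeric scaffolds at the ends
(telomere outward) and enumerates all `(N-2)! * 2^(N-2)` orders and
orientations of the middle scaffolds (1, 8, 48 candidates for N = 2, 4,
5). Groups with another telomere count are reported, not guessed.

Each candidate is scored on its recomposed map. The tile subscore weights
the signal at (i, j) by the distance to the main diagonal |i − j| and sums
the weighted values in the four w×w corners of the tile (w = 5, shrunk to
the tile extent per dimension; corners of small tiles may overlap and
overlapping pixels then count once per corner term — the literal reading
of the definition; the fourth corner's row limit is taken symmetric to the
others). `layoutScore()` sums the subscore over all unordered fragment
pairs; a correct arrangement concentrates signal at the diagonal where the
weight vanishes, so `selectBest()` returns the arg-min, persisting the
full ranked table and reporting ties (broken canonically).

One modeling point matters in practice: a patient map overlays the
rearranged and wild-type alleles roughly 50/50, and the wild-type half
rewards the *reference* order of the fragments. On simulated overlays the
raw-map arg-min recovers the planted order in only ~25% of replicates,
whereas scoring the control-subtracted map recovers it in ≥95%. The
recommended workflow is therefore `selectBest(candidates,
subtractControl(sample, control))` whenever a control is available; the
scoring functions accept any matrix.

# Junction sequence signatures

For each breakend, soft-clipped short reads (≥10 clipped bases,
MAPQ ≥ 20) within 10 bp of the call are fetched — the window doubles up to
10 kb while a side is empty — and split into L (aligned left, clipped at
the junction on their right) and R groups. The local InDel size is the
signed distance between the median clip positions of the two groups,
reported only when each side has ≥3 reads clipped at one identical
position; reciprocal junctions at the same breakpoint locus provide the
second group.

Microhomology is measured by consensus alignment: the 50 bp source
consensus (25 aligned + 25 clipped around the median clip position, read
in the direction crossing the junction) is aligned to the 25 bp aligned
consensus at the target breakend under local alignment with +2 match, −1
mismatch, −1 for the first column of a gap and −0.1 per further column.
Because a local aligner extends target-side alignments *through* a
homologous stretch, the target clips shift by the homology length h, and a
perfect alignment (entire target matched, no mismatch or gap) starting at
query position 26 − h reveals h; start 26 is a blunt junction. Imperfect
alignments are re-examined with a 50 bp clipped-only consensus: the offset
of the best alignment start measures the untemplated insertion. Homology
and insertion are reported separately and combined. Per-column consensus
takes the majority base, with N on ties — consensus construction is not
specified by the underlying procedure, so the conservative tie rule is
used and flagged via a QC column instead of silent discard.

The alignment routine is implemented in the package (with deterministic
lowest-start tie-breaks) because the blunt/homology calls depend on exact
start positions under exactly this scoring; tests cross-check it against
an independent score-only dynamic program (1e-9) and a general-purpose
aligner (1e-4; its single-precision arithmetic differs in the sixth
decimal).

# Haplotype labeling and allelic imbalance

At each breakpoint a long read is wild-type evidence when one contiguous
alignment spans ±90 bp at MAPQ ≥ 20; rearranged (CGR) evidence when it
passes only one side and continues elsewhere as a supplementary
alignment; reads ending inside the margin without a supplementary are
uninformative. Within a phase set, reads carrying both a haplotype tag and
a breakpoint class vote for "CGR on H1" or "CGR on H2"; the majority
scenario labels the set (ties unresolved; conflicting votes counted, with
a warning fraction of 0.2 rather than automatic invalidation — the
underlying procedure gives no invalidation rule). Labels are then expanded
genome-wide under the single-allele assumption.

`countAlleles()` aggregates phased RNA-seq reads per gene/allele/replicate
and drops genes with fewer than 16 phased reads. `callAig()` flags allelic
imbalance genes at |log2FC| > 1 and adjusted p < 0.05 from an external
differential-expression table (the supported path; the model fit itself is
consumed, not reimplemented); genes without a computable adjusted p are
excluded, as are sex-chromosome genes via an exclusion list. A
self-contained stand-in — pooled exact binomial test against 50/50,
BH-adjusted — exists for testing and is flagged in its output; it ignores
replicate dispersion and is anticonservative relative to a count model
with dispersion, though its raw type-I error is near nominal on null
simulations.

# Empirical background models

Three null models support right-sided empirical tests with
p = #(null ≥ observed) / n_iter — literally, with no pseudocount, so p = 0
is attainable, and without multiplicity adjustment:

* `nullShift()` — all coordinates on a chromosome shift by one uniform
  offset with wrap-around, preserving relative distances; configurations
  touching an assembly gap are rejected whole and redrawn. Used for
  TAD-boundary, compartment, LAD, repeat and AIG-proximity statistics.
* `nullRewire()` — breakend coordinates fixed, pairings permuted; used for
  compartment and LAD fusion-type counts (marginal label counts are
  invariant by construction).
* `nullExpression()` — expression values permuted over genes, coordinates
  fixed; the alternative null for the AIG distance curve.

Expected-by-chance baselines come from `expectedFraction()`: feature
length over genome length, both gap-excluded. `aigDistanceCurve()` bins
informative genes by the distance of their most-5' TSS to the nearest
breakpoint (bp or TAD units) and reports per-bin AIG fractions with a
5th/50th/95th-percentile null envelope and per-bin empirical p.

Calibration note: with the ≥-rule, empirical p-values are exactly valid
but *super-uniform* when the statistic is coarsely discrete. A single
case's few dozen breakpoints make the LAD fraction take few values and
p-values pile up conservatively; at the pooled cohort scale of several
hundred breakpoints — the level at which these tests are aggregated — the
p distribution is indistinguishable from uniform (KS) in the package's
calibration checks.

# The simulator

`simConfig()` freezes the desk-scale study conditions: five 10 Mb
chromosomes with one assembly gap, segmental duplication and
high-coverage region each; chromoplexy as a five-chromosome cyclic
exchange (5 junctions) or chromothripsis as 24 breakpoints clustered in
shatter regions covering ~35% of two chromosomes, internal fragments
deleted with probability 0.2 and the rest rejoined in random order and
orientation across the shattered chromosomes. Hi-C is a 50/50 overlay of
the wild-type and rearranged alleles with cis contacts ∝ (1 + d)^(−1)
(standard polymer-scaling exponent; a simulator-only choice), a small
trans constant, Poisson counts at depth 10 per diagonal bin, 25 kb bins.
Breakpoints sit on bin boundaries — map operations are bin-resolution, and
base-pair uncertainty is modeled separately as Gaussian caller jitter
(sd 10 bp), false negatives, and ten planted false positives per
filterable class with a decoy cohort sample. Junction reads plant
microhomology (0–10 bp), untemplated insertions and reciprocal InDel
offsets (−20..20 bp) in junction-local sequence context; expression
plants an AIG rate of 0.5 within 100 kb of a breakpoint against a 0.05
background; phase sets plant the rearranged allele on H2.

What the simulator does *not* emulate — and what passing tests therefore
do not show about real data: mappability structure and alignment bias,
copy-number gains (rejected by the reconstruction contract), Hi-C
normalization artifacts and domain structure (the decay is smooth, so
TAD-scale texture is absent), replicate-level expression dispersion, and
whole-genome sequence (junction context is local). `simulateJunctions()`
additionally isolates junction loci so planted signatures are exactly
recoverable; layout-derived junction reads overlap at shared breakpoints
exactly as real reciprocal junctions do.

Problem sizes in the test-suite and acceptance runs — 10 Mb chromosomes,
25 kb bins, 100-replicate reconstruction and permutation sweeps, 200
permutation iterations per empirical test, 200 meta-replicates for
calibration — are the package's chosen desk-scale study conditions.

# Numerical choices and limitations

* Tie-breaks: consensus ties → N; alignment ties → lowest start; score
  ties in candidate selection → canonical layout order, reported.
* Isotonic decay smoothing is unweighted; the expected curve is floored
  at a small positive value so observed/expected ratios stay finite.
* `recompose()` conserves total signal over retained bins exactly; the
  inverse-layout identity holds exactly for bin-aligned, loss-free
  layouts.
* Degenerate inputs: empty call sets, wild-type truth (no breakpoints),
  zero matrices, empty read groups and missing coverage all return
  defined values (empty partitions, identity layouts, score 0, NA) rather
  than errors; errors are reserved for contract violations (unknown
  chromosomes, overlapping fragments, sub-bin tiles, unresolved
  conflicts).
* Known limitations: copy-number gains and duplicated fragments are
  rejected, not modeled; the ectopic-tile mean is insensitive for
  megabase fragments; raw-map permutation scoring is confounded by the
  wild-type allele (use the control-subtracted map); the binomial AIG
  stand-in is not a replacement for a dispersion-aware model.
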