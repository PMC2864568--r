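---
title: "Detecting false segmental duplications caused by haplotype mis-assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting false segmental duplications caused by haplotype mis-assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(falsedup)
```

## The problem

Whole-genome shotgun assemblers treat reads as if they came from a single
clonal chromosome.  In a diploid genome, a heterozygous region whose two
haplotypes have diverged enough can defeat the overlap criteria that merge
reads into one consensus: the assembler builds two contigs, one per
haplotype, and the scaffolder — guided by mate pairs that genuinely link
both contigs to the same flanking sequence — places them side by side.  The
published assembly then shows a recent, high-identity segmental duplication
that does not exist, and the SNPs and indels that distinguish the two
haplotypes are silently lost.

Two geometries arise, depending on where the flanking homozygous sequence
ended up:

* **DCC** (duplicated contained contig): a short contig consisting of one
  haplotype's copy of the heterozygous tract, aligning over essentially its
  whole length to the interior of a longer nearby contig that carries the
  other haplotype plus both homozygous flanks.
* **DOC** (duplicated overlapping contigs): two contigs that share the
  heterozygous tract at their facing ends, each continuing into homozygous
  sequence on the opposite side.

`falsedup` detects both patterns and decides, for each, whether the mate
pairs of the reads involved are more probable at the contig's current
location or at the alternative, merged location implied by the alignment.

## Candidate detection

Every placed contig is compared against the other contigs whose placements
lie within a 50 kb window, measured as the gap between the nearest contig
ends.  The window is wide enough to cover common clone insert sizes, and
deliberately over-collects: the mate-pair likelihood is the real filter.
Alignment is done by an internal seed-and-extend aligner (exact 15-mer
seeds, diagonal clustering, then a banded local extension), always between
the *chromosomally oriented* sequences, so that a genuine haplotype
duplication appears as a same-strand hit and end proximity can be read off
directly.  Users analyzing a real genome can instead supply the output of
an external whole-genome aligner (PAF or `show-coords`-style); those hits
carry linearly interpolated coordinate maps, accurate to a few bp inside
gapped regions, which is tolerable against library SDs of hundreds of bp.

A hit marks a DCC when it covers more than 93% of the shorter contig at
more than 95% identity; a DOC when it exceeds 300 bp at more than 95%
identity and reaches within 300 bp of the facing ends of both contigs.
Identity is counted over alignment columns (matches / columns, gaps
included).  DOC candidates are further required to be adjacent on the
chromosome, or separated by exactly one contig that was itself called a
mis-assembled DCC.  Within-contig duplications are out of scope: the read
overlap graph has already resolved those paths, and intra-contig problems
are better detected with compression/expansion statistics.

## Fragment-size models

Each sequencing library nominally follows a normal fragment-size
distribution with a submitted mean and SD (Trace-Archive style).  Real
libraries deviate, so the pipeline re-measures each library from the
assembly itself: the 5'-to-5' distances of all properly oriented mate
pairs placed on one chromosome.  A one-sample Kolmogorov–Smirnov test
compares these sizes with the nominal normal; if it rejects at
*P* < 0.01 **and** at least 500 observations are available, the density is
re-estimated as a cubic smoothing spline (generalized cross-validation
smoothing, the `stats::smooth.spline` default) over a 1 bp histogram,
after a two-pass trim that drops sizes more than 4 SD from an initial
fit.  Negative spline values are clamped to zero and the density is
renormalized.  Below 500 observations the spline would overfit and the KS
test rarely rejects, so the nominal normal is kept.

Every model carries a **probability floor**: the largest value *m* such
that the total mass of fragment sizes with probability below *m* is at
most a prescribed tail (10^-4^ for the placed-contig analysis).  For a
normal model this corresponds to a symmetric interval of half-width ~3.89
SD — roughly four standard deviations.  Disoriented pairs (reads not
facing each other) receive the floor, and no fragment can score below it,
so a single absurd distance can never dominate a likelihood comparison and
all log-likelihoods stay finite.  "Far distant outliers" are excluded from
the floor computation by restricting the support to the trimmed grid
(empirical) or ±8 SD (normal).

## The placement likelihood

For a DCC, the relevant reads are all reads in the moved contig with a
mate in another contig; for a DOC, only the pairs whose link crosses the
overlap junction — pairs pointing away from the overlap are assumed to have
determined the neighboring gap sizes and are left untouched.  Treating
pairs as independent, the log-likelihood of a contig at a location is the
sum over relevant pairs of the log probability of the implied fragment
size under the pair's library model.  The likelihood is evaluated at the
original location and at the merged location (the moved contig's reads
re-projected through the anchoring alignment's gapped path; for DOCs the
downstream coordinates also shift left by overlap + removed gap).  The
verdict is *mis-assembled* iff the merged-location likelihood is strictly
greater; ties are kept, biasing toward leaving the assembly unchanged.
External mates hold their positions — no re-scaffolding is attempted.
When one contig qualifies through several anchors, each candidate is
evaluated independently and the relocation with the highest
merged-location likelihood wins.

## Coverage check

Reads sample the genome roughly uniformly, so the read count over a span
of length *L* distinguishes single-copy from duplicated sequence.  The
A-statistic is the Poisson log-odds
*A = L·R/G − k·ln 2*, with *R* placed reads genome-wide, *G* the placed
sequence length, and *k* the reads from **both** contigs whose 5' ends
fall in the alignment span (counting 5' ends avoids double-counting
straddlers).  *A* > 0 favors single copy — i.e. supports the mis-assembly
interpretation.  The statistic is an independent annotation, not a gate on
the verdict: short spans are noisy, and genuinely repetitive mis-assembled
sequence is exactly the case only mate pairs can resolve.

## Unplaced contigs

Contigs not assigned to a chromosome are screened with stricter criteria,
because no 50 kb locality prior exists: DCC requires ≥96% identity over
≥94% of the unplaced contig, DOC ≥96% over ≥400 bp at a contig end (all
placed contigs are candidate anchors).  A mate pair is *consistent* when
it is properly oriented and its implied fragment size in the anchored
location has probability strictly above the 0.05-tail floor (about two
SDs for a normal).  The contig is called a haplotype variant iff at least
2 pairs are consistent and at least 30% of the pairs with an outside mate
are consistent.  Threshold comparisons are ≥, pinned for testability.
When several anchors qualify, the one with the best consistent fraction
wins.

## Variant recovery

For each confirmed mis-assembly the reads of both contigs are realigned
onto the anchor through the candidate's alignment path, giving per-column
pileups over the merged span.  The layout format records read intervals,
not read bases, so each read contributes its contig's consensus base; a
column's observation multiset is therefore the two contig bases weighted
by their read depths.  A column with two disagreeing base alleles, each
supported by at least 2 reads, yields a SNP; runs of gap-on-one-side
columns merge into a single indel, anchored on the preceding base and
left-aligned (VCF convention).  One read per haplotype is
indistinguishable from sequencing error, hence the depth floor of 2.
Variants with any other discordant column within 5 bp are dropped
(neighborhood quality filter), and variants are only reported for calls
whose A-statistic indicates single copy, filtering out mis-assembled
repeats.  An externally computed multiple alignment can be substituted for
the anchor-projection realignment via the alignment-ingest hook.

## The synthetic data generator

`simulate_assembly()` emulates the generative picture: a haploid random
reference with localized heterozygous tracts mutated on a second haplotype
(SNPs at 1%/bp, 1–3 bp indels at 0.1%/bp — alignment identities around
98–99%, matching the identities typical of real false duplications), and
an "assembler" that separates the haplotypes.  Defaults are Sanger-era:
700 bp reads, a 4 kb ± 400 bp and a 10 kb ± 1 kb library totalling 7×
coverage, 5 Mb genome, 220 heterozygous tracts (100 DCC, 100 DOC, 20
unplaced patterns) and 200 true duplications planted as diverged copies
2–8 kb apart.  Specific modeling choices:

* Haplotype contigs carry one read length (700 bp) of homozygous overhang
  on each side of the tract, as real haplotype contigs break roughly a
  read length beyond the divergence; this also means every read
  overlapping the tract is assignable to one haplotype contig.
* Read partitioning by haplotype inside mis-assembled regions is total —
  the worst case for an assembler and the canonical false-duplication
  geometry.
* Reads straddling a contig boundary are dropped (their mate is kept,
  unmated), mimicking reads lost at contig ends.
* DCC haplotype contigs are inserted immediately after their host contig
  with a 100 bp gap; 25% are placed on the minus strand.
* Inter-feature spacing is uniform on 3.5–6.5 kb, chosen so the default
  feature load fits a 5 Mb genome while keeping each relocation several
  library SDs long.

The generator does **not** emulate: per-base sequencing errors (the layout
carries intervals only, so read errors would be unobservable anywhere in
the pipeline — the natural place they would surface, variant calling, is
protected by the depth-2 rule), mapping ambiguity between true repeat
copies (reads are assigned by their true origin), chimeric clones, quality
values, or scaffold re-construction.  Passing the benchmark therefore
demonstrates the geometry, the likelihood machinery and the bookkeeping —
not robustness to base-call noise or repeat-induced mis-mapping.

Two further properties of the synthetic assemblies deserve note, because
they are *harder* than the real-genome setting in one way and easier in
another.  First, mis-assembled material is ~10% of the synthetic genome
(versus well under 1% in real vertebrate assemblies), so the
genome-average read arrival rate R/G is underestimated and the
A-statistic becomes conservative: in the default benchmark about 85% of
true mis-assemblies get A > 0 (the acceptance script reports the exact
fraction).  Second, ~20% of fragment observations
span an inserted duplicate and are stretched by a few kb, so the KS test
correctly rejects the nominal normal for every library and the spline
densities acquire a small secondary mode — the likelihood comparison
tolerates this because the main mode still dominates.

## Benchmark metrics

`benchmark_pipeline()` scores the pipeline against the truth labels:
sensitivity per pattern, false-call rate on true duplications, and
variant-recovery precision/recall/F1.  Variant recall is measured on the
*callable* planted variants — both alleles covered by ≥2 fully contained
reads at the planted column and no other planted variant within the 5 bp
quality flank, computed independently from the read layout — within calls
that passed the coverage filter.  Conditioning on the coverage filter
keeps the metric about the variant caller rather than about the
(deliberately conservative) A-statistic gate; the unconditional recall
over all callable variants in mis-assembled tracts is reported alongside,
the difference being exactly the A ≤ 0 calls.

## Numerical and implementation choices

* All likelihoods are computed and compared in log space; the per-pair
  product underflows double precision at realistic pair counts.
* The normal density is evaluated at integer sizes as a discretized pmf;
  the floor search uses the same discretization.
* Tie-break: equal likelihoods ⇒ kept; equal merged likelihoods across
  anchors ⇒ first in candidate order.
* Seed k-mer size 15 (exact 2-bit rolling codes); random 15-mer
  collisions between unrelated contigs are negligible at contig scale, so
  unrelated neighbor pairs are rejected without alignment.
* Internal coordinates are 0-based half-open everywhere; AGP (1-based
  inclusive) and VCF (1-based, anchored indels) are converted at the
  boundary.
* Degenerate inputs: libraries with <2 observations keep the nominal
  model; an all-identical fragment library yields a single-atom spike
  model whose floor is a small fraction of the atom's mass; candidates
  with zero relevant pairs are kept with flag `no_evidence`.
* Every stochastic element flows from one explicit integer seed; two runs
  with the same seed produce byte-identical output files.

## Problem sizes used by the tests

The unit suite exercises a 400 kb bundle (22 planted features); the
acceptance suite runs the full default benchmark (5 Mb, 200 planted
mis-assemblies, 200 true duplications, ~50,000 reads), KS calibration
with 1,000 replicate libraries of 1,000 pairs, and parameter recovery at
10,000 fragments.  These sizes keep a complete run in a few minutes on
one CPU while leaving every rate estimate with comfortable statistical
resolution.

## Known limitations

* Candidates are evaluated independently and greedily; interacting
  mis-assemblies on one region are not jointly optimized, and gaps are
  not re-estimated after a move.
* The original-location likelihood of a DOC takes the intervening gap at
  its current size.
* Fragment models are fit on the assembly as-is, including its
  mis-assemblies; in heavily corrupted regions the empirical densities
  absorb the distortion as minor modes.
* The quality filter's "high quality neighboring sequence" rule is
  implemented as concordance of the 5 bp flank, the natural analogue when
  observations derive from contig consensus.
* Ingested external alignments lack the gapped path, so merged-location
  projections through them carry a few bp of interpolation error.
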