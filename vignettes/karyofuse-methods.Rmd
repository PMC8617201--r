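---
title: "Methods: fusion detection, comparative Hi-C and the neo-Y chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fusion detection, comparative Hi-C and the neo-Y chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records how each stage of karyofuse works, which choices
were genuinely open, and what the synthetic data do and do not establish
about real data. It is the package's design record; the README shows the
user-facing workflow.

## Coordinates and containers

All internal coordinates are 0-based half-open; BED files keep that
convention on disk and only VCF-like output is 1-based. Genomes, contact
matrices and bin maps are light S3 records wrapping tibbles
(`sim_genome`, `contact_matrix`, `bin_map`), so every analysis step takes
and returns plain data frames and composes with the pipe. A `bin_grid`
tiles each chromosome left to right with fixed-width bins (the last bin
may be short) and assigns contiguous global indices.

## The synthetic genome and fusion model

`build_ancestral_genome()` puts, from the centromeric (left) tip inward:
a telomere array (TTAGGG)n of ~2 kb, a satellite II array (4 × 700 bp
monomers), a satellite IV array (3 × 1000 bp), a truncated telomeric
tract of ~38 bp flanked by two 200 bp palindrome arms (exact reverse
complements), and a satellite I array (6 × 800 bp); the body is unique
pseudo-random sequence and the right end carries a distal telomere.
Satellite monomers are pseudo-random sequences of fixed per-class length:
the analyses only need *distinguishable* monomer classes, not real cervid
monomers, so none are embedded. The 38 bp default for the truncated tract
matches the length scale at which such internal tracts concentrate in
unfused karyotypes; telomere arrays are exact tandem repeats.

`apply_fusion_plan()` executes fusions in order. A tandem fusion deletes
the centromeric partner's head arrays up to its satI array, cuts the
distal partner's terminal telomere back to a retained tract drawn
uniformly from 20–300 bp, and joins the two across a remnant gap drawn
uniformly from 0–400 bp — so every junction carries a satI array and a
partial telomere separated by < 500 bp, and junction-telomere lengths
scatter rather than taking one value. Both draws are seeded, making the
scattered-length signature reproducible. Neither the retained-telomere
range nor the gap range is observable directly from published assemblies;
both are package choices fixed once (the 500 bp juxtaposition rule is the
only downstream constant they must respect, and they respect it by
construction). A Robertsonian fusion concatenates two centromeric heads
without deletion; its product has two distal ends and therefore can only
act as the distal partner of later fusions — plans violating that are
rejected, which is how the chromosome-state invariant ("a chromosome
appears as a partner consistently with its current state") is enforced.

One representational point: a Robertsonian fusion needs two chromosomes
even though only one "distal partner" field exists in a plan row; in
Robertsonian rows the second field names the second centromeric partner.

The truth object records the derived-coordinate layout of ancestral
segments and one row per junction (position = remnant-gap midpoint, type,
age class, gap width). `truth_synteny_blocks()` converts the layout into
the noise-free block table an aligner would ideally emit; block erosion
or alignment noise is not simulated (see Limitations).

## Fusion detection and classification

`detect_fusion_events()` scans length-filtered blocks along each derived
chromosome and emits one event per adjacent pair with different ancestral
chromosomes, placing the event at the midpoint of the inter-block gap —
unbiased if the two flanking blocks erode symmetrically, and exact on
noise-free blocks up to gap rounding. Filtering before adjacency scanning
(default cutoffs 8/14/35/55 kb by pair divergence) prevents short
interleaved fragments from splitting one junction into several events.

Classification reads, from each flanking block's orientation, which
ancestral end faces the junction, and compares that end against the
per-chromosome centromere annotation under the acrocentric assumption
(the centromere occupies one chromosome end): centromeric + distal →
tandem, centromeric + centromeric → Robertsonian, distal + distal →
"other". "Other" is retained rather than rejected because the two named
classes do not exhaust the geometry. The rule is symmetric in the two
partners by construction.

Age classes encode nested sharing across an ordered species list
(earliest-diverging first, focal last): a fusion present in the last k
species and absent from the rest is class Ck; non-suffix patterns are
flagged `unassigned` with a warning rather than guessed. The fusion rate
is exposed as the pure function events / branch-time; no attempt is made
to reproduce any particular published interval, because the branch-time
denominators behind such intervals are not stated.

## Homologous bin map

`build_bin_map()` projects every source bin base-by-base through the
alignment blocks (orientation-aware, so inversions project with
decreasing offsets) and maps it to the target bin receiving the plurality
of bases, accepting the assignment only when at least `min_match`
(default 0.85; 0.7 for more diverged pairs) of the *bin length* lands in
the winner's ±1-bin neighbourhood on a single target chromosome. Using
bin length rather than aligned span as the denominator makes a
half-projectable bin unmappable at 0.85, which is the intended reading of
the threshold. The ±1-bin absorption mirrors the ±1-bin slack used for
interaction homology downstream. Contradictory overlapping blocks are
resolved longest-first (the shorter block keeps only uncovered
remainder), and bins whose winning neighbourhood would straddle a target
chromosome boundary simply fail the threshold — such bins are declared
unmapped. Fusion-junction bins mix two ancestries and are therefore
intrinsically unmappable; coverage statements about the map are made on
chromosomes long enough (1 Mb at 40 kb bins in the tests) that junction
bins are a small minority, which is also the regime of real genomes.

## Contact matrices, ICE, compartments

`bin_pairs()` counts each valid pair into one upper-triangle cell.
`ice_normalize()` masks zero-coverage bins plus bins strictly below the
2% coverage quantile (the masking quantile is not a published constant;
2% is the package default) and then rescales rows and columns until the
coefficient of variation of non-masked row sums drops below `tol`
(10⁻⁶ default, usually a few dozen iterations), preserving total mass.
Renormalizing a normalized matrix keeps the existing mask — this is what
makes the operation idempotent; re-deriving the quantile mask from
balanced (all-equal) row sums would re-mask bins on numerical noise.

`observed_expected()` divides each cell by its diagonal mean; empty
diagonals become NA, not zero. `compute_pc1()` takes the leading
eigenvector of the Pearson correlation matrix of the whole-chromosome O/E
matrix — always the whole chromosome, never a restricted submatrix,
because compartment structure is defined by the full interaction profile.
Constant (degenerate) matrices give all-NA tracks. `orient_and_label()`
flips the sign per chromosome so eigenvalue correlates positively with GC
content (gene density as tie-break), then labels positive bins A,
negative B; an exactly zero eigenvalue gets NA (a boundary rule the data
cannot decide), and zero-variance covariates leave the chromosome
unoriented with a warning.

Switch regions between genomes are runs of at least 3 consecutive focal
bins whose mapped partners all carry the opposite label, with the run
direction held constant; unmapped or unlabelled bins break runs (runs are
not allowed to jump mapping discontinuities, and never cross focal
chromosome boundaries). Shorter discordant runs fall into the "other"
category, so the five per-bin categories partition all focal bins. The
near-fusion partition uses bin-midpoint distance with a closed interval
at the 5 Mb flank, and the proportion test is Pearson's chi-squared on
the 2×2 table without continuity correction (`stats::chisq.test`; the
closed form is kept as the independent oracle in the tests).

## Insulation, TADs, conservation

The insulation score of bin b is the mean of the window × window square
upstream/downstream of b (rows b−w..b−1, columns b+1..b+w), log2-ratioed
to the chromosome mean; it is NA wherever the window does not fit. The
default window of 10 bins (400 kb at 40 kb) follows common insulation
practice; the package's TAD simulations are called with smaller windows
matched to their planted TAD sizes. Boundaries are local minima with
prominence ≥ `delta` (default 0.1 log2 units); between two adjacent equal
minima the leftmost wins, and a boundary bin starts the next TAD so TADs
never overlap. On a two-block toy the two bins flanking the junction tie
exactly (the window excludes the bin itself), which is why recovery
statements use a ±1-bin tolerance.

TAD conservation requires mapped overlap strictly greater than 70% of
*both* TAD lengths, after removing unmapped bins from both denominators
(focal side: bins with no homolog; partner side: bins absent from the
map's image). The strictness at exactly 70% and the missing-bin exclusion
are the two load-bearing details; both are covered by constructed
69/70/71% cases in the tests. Genome-specific TADs are those conserved
with every "confirm" genome and no "absent" genome.

## Significant interactions

The caller follows the Fit-Hi-C logic on raw intra-chromosomal counts:
contact probabilities per pair are estimated in equal-occupancy distance
strata (consecutive distances grouped to roughly equal total counts,
default ~50 strata) and smoothed monotone non-increasing in distance by
weighted pool-adjacent-violators — isotonic smoothing replaces the
original spline because it has no tuning parameters and preserves the
test-statistic form. Each observed pair then gets the binomial upper-tail
probability of at least its count given the total intra count, BH
correction is applied across all tested pairs of the genome (the
correction scope is not published; genome-wide is the conservative
choice), and calls must satisfy p ≤ 0.01, q ≤ 0.01 and count ≥ 10. The
support threshold reads "more than nine" literally as ≥ 10;
`min_reads = 9` selects the inclusive reading.

Length profiles count intra-chromosomal calls in log10 windows of width
0.1 and min-max scale them, which makes the profile invariant under
duplicating every call. Long-range calls (> 5 Mb, strict) are classed
A-A / B-B / A-B / others by their anchor labels, with any unlabelled end
going to "others". Homology partitioning marks a focal call shared when
some partner-genome call maps with both anchors within ±1 bin. Calls
spanning exactly one fusion junction record that junction's flanking
ancestral chromosomes and age class; the age gradient is the Pearson
correlation of age rank (C1 = 1 … C5 = 5, so "older fusions carry more
interactions" appears as r > 0) against mean spanning calls per site.
`transform_matrix()` re-addresses a partner matrix onto focal
coordinates, dropping cells with unmapped anchors, for combined
two-genome heatmaps around junctions.

## Read patterns and palindromes

Satellite hits use exact k-mer seeds (k = 12) drawn from the *doubled*
monomer — so seeds spanning the tandem-unit junction exist — on both
strands, merged across gaps up to 50 bp; identity is estimated as seed
coverage of the merged interval and hits need identity ≥ 0.7 and width
≥ 20 bp. Seeded matching replaces an external aligner's e-value logic
because the monomer library is closed and small. Telomere tracts are
exact unit matches (TTAGGG / CCCTAA) merged across up to two disrupted
units, kept at ≥ 3 units, so isolated chance hexamers in unique sequence
(expected every few kb) cannot masquerade as telomeric sequence.

The 4-bit pattern sets a class bit when the merged per-class total
exceeds 30 bp, in the order satI, satII, satIV, telomere; the threshold
is applied to telomeric sequence too (the published rule states it for
satellites; applying it uniformly keeps the code a pure function of the
hit table, and is configurable). The satI–telomere distance is the
minimum edge-to-edge gap over all hit pairs (0 when overlapping), split
as < 500 vs ≥ 500 bp exactly. A telomere hit is "near-end" within
max(1 kb, 5% of read length) of a read terminus — the middle-vs-end
contrast needs *some* cutoff and none is published; this one scales with
read length and bottoms out at the length of a typical adapter/quality
ragged end.

Palindrome detection compares the read with its own reverse complement
through exact k-mer seed pairs; all seed pairs of one inverted repeat
share a constant anti-diagonal (left position + partner position), since
the error model is substitution-only, so clustering on it yields arm
pairs directly. Arms need ≥ 30 bp, spacer ≤ 2 kb, seed-coverage identity
≥ 0.9; overlapping reports keep the longest arm. On uniform-random 10 kb
reads the expected seed pairs are scattered across distinct
anti-diagonals and no cluster reaches 30 bp, so the detector is clean on
null reads by design, not by thresholding after the fact.

## The neo-Y chain

The male-specific filter is a pure conjunction — all six depths in
[15, 100], both males 0/1, both females and both outgroup samples 0/0 —
and any missing genotype skips the site. Non-reference-homozygous (1/1)
females or outgroups disqualify a site just as heterozygous ones do: the
rule's "homozygous and same as the reference" is read literally. SV
validation keeps candidates with a reliable SNP within a closed 1 kb
window of the interval; this proximity form replaces a read-level
re-calling procedure with the same intent and is testable without
alignment files. Enrichment compares the in-neo-Y call fraction against
the neo-Y genome fraction by a 1-df chi-squared goodness-of-fit test and
refuses the degenerate case where the neo-Y is the whole genome.

Curation walks candidate sites through the neo-X/neo-Y alignment and
substitutes the alternate allele wherever the neo-Y base still equals the
neo-X base; sites already carrying the alternate are untouched (hence
idempotence) and alignment gaps are skipped and logged. Effect annotation
is a deliberately minimal four-class classifier over toy single-transcript
models (premature stop / frameshift / splice-site → HIGH, missense →
MODERATE, synonymous → LOW, else MODIFIER): downstream use only consumes
the four categories, so wrapping an external annotator would add a heavy
dependency without adding information. Allele-specific expression tests
genes with ≥ 2 informative sites by a paired two-sided t-test (the
sidedness is not published; two-sided is the conservative default);
zero-variance nonzero differences take the limiting p of 0, and all-zero
genes are skipped. Coverage normalization is min–max on the log2 scale
with the genome mean as the maximum anchor and a 1-read pseudocount for
zero-coverage windows (unpublished corner; the pseudocount pins them to
the scale minimum).

## What the simulations establish — and what they do not

The generator reproduces the *structural* features the detectors key on:
ordered centromeric repeat cassettes, junction remnants under 500 bp,
power-law Hi-C decay with plaid/TAD/loop enrichments under Poisson
sampling, substitution-only read errors, rule-consistent genotype tables,
binomially split allele counts. Passing tests therefore show the
algorithms are correct against their own models and exact rules. They do
not show robustness to what the generator omits: alignment/block erosion
noise, Hi-C overdispersion beyond Poisson (a config extension, off by
default), indel and homopolymer read errors, segmental duplications or
satellite library ambiguity, mapping bias in allele counts. Conclusions
about real data still need the usual external controls.

Problem sizes in the tests and acceptance script — 35 × 0.4 Mb
chromosomes for fusion recovery, 500 × 100 kb bins for compartments,
250 × 40 kb bins for TADs, 200 × 20 kb bins for loop recall, 50–100
Monte-Carlo replicates for null-FDR and age-gradient statements, 150–600
reads per read-pattern experiment — are the package's chosen
demonstration scale: large enough that the recovery statements hold with
comfortable margin under the stated signal strengths, small enough to
re-run on a laptop in minutes.

## Known limitations

* Fusion-event positions are only as precise as the inter-block gap;
  with eroded alignments the midpoint convention biases nothing but
  widens the uncertainty.
* The bin map is bin-granular by design; base-level liftover of
  arbitrary intervals is out of scope.
* Trans-chromosomal interaction calling is not implemented.
* `assign_age_classes()` presumes a ladder-shaped species tree (nested
  presence sets); reticulate histories need external handling.
* The effect annotator handles single-transcript, all-coding toy models
  only.
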