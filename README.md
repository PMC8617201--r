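# karyofuse

Chromosome fusion detection and comparative 3D-genome analysis in R.

## The problem

Muntjac deer underwent one of the fastest karyotype collapses known in
mammals: an ancestral complement of ~35 acrocentric chromosome pairs
(2n = 70) was repeatedly joined — mostly by **tandem fusions** (the
centromeric, "apical" end of one chromosome onto the distal telomere of
another) plus a few **Robertsonian fusions** (two centromeric ends) — down
to as few as 3/4 chromosome pairs, and an autosome was captured into a
**neo-X/neo-Y** sex-chromosome system. Studying what those fusions did to
the genome requires a chain of analyses that this package implements as
tested, reusable R functions:

* **Fusion detection and classification from synteny.** Filtered synteny
  blocks between a derived and an ancestral-like genome are scanned for
  adjacent blocks from different ancestral chromosomes; each junction is
  classified tandem / Robertsonian / other from the centromere annotation,
  dated into nested phylogenetic **age classes C1–C5** (C5 shared by all
  five species, C1 private to the focal species), and summarized as a
  fusion rate in events per million years.
* **Hi-C**: valid read-pairs are binned into sparse symmetric contact
  matrices, balanced by **iterative correction** (ICE; row-sum
  equalization with low-coverage masking), and transformed to
  observed/expected. **A/B compartments** are the leading eigenvector
  (PC1) of the whole-chromosome O/E correlation matrix, oriented so that
  the gene-dense, GC-rich compartment is A; **TADs** come from
  insulation-score minima; **significant interactions** are called
  Fit-Hi-C-style from distance-stratified binomial tails with BH
  correction (p ≤ 0.01, q ≤ 0.01, ≥ 10 read-pairs at 20 kb).
* **Cross-genome comparison** runs through a **homologous bin map**
  (fractional-overlap projection of bins through alignment blocks,
  minimum-match thresholds 0.85/0.7): compartment **switch regions** are
  ≥ 3 consecutive homologous bins with opposite labels; TADs are
  **conserved** when mapped overlap exceeds 70% of *both* lengths
  (missing bins excluded); interactions are **shared** when both anchors
  land within ±1 bin of a mapped partner call, and calls spanning exactly
  one fusion site feed the fusion-**age gradient** (Pearson r of age rank
  vs mean spanning calls per site).
* **Long-read repeat mining**: satellite I/II/IV and telomeric (TTAGGG)n
  content per read is encoded as a **4-bit pattern** (bit order satI,
  satII, satIV, telomere, each set when the class total exceeds 30 bp);
  satI–telomere juxtaposition is split at 500 bp; internal **truncated
  telomeric tracts** and their flanking **palindromes** (inverted repeats
  found by self reverse-complement alignment) are detected directly in
  reads.
* **Neo-Y chain**: candidate **male-specific variants** are sites with
  15 ≤ DP ≤ 100 in all six samples, heterozygous in both males and
  homozygous-reference in both females and both outgroup samples; SVs are
  validated by a reliable SNP within 1 kb; enrichment of calls in the
  neo-Y region is chi-squared–tested against the neo-Y genome fraction;
  the neo-Y sequence is **curated** by substituting the alternate allele
  where neo-Y still equals neo-X; **allele-specific expression** uses a
  paired two-sided t-test over ≥ 2 informative sites per gene (p < 0.05).

Every input the pipeline consumes can be generated by the built-in
**synthetic-data module** with complete ground truth: acrocentric
chromosomes with the centromeric cassette telomere–satII–satIV–
palindrome–truncated-telomere–palindrome–satI, fusion plans with known
junctions, Hi-C counts with power-law decay plus compartment/TAD/loop
enrichments (Poisson), long reads with configurable substitution error,
six-sample genotype tables, and per-gene allele counts. Every analysis
stage is therefore testable offline, with no downloads.

## Worked example

```r
library(karyofuse)
library(dplyr)

# 1. simulate a 6-chromosome acrocentric ancestor and fuse three
#    chromosomes into one by tandem fusions
anc  <- build_ancestral_genome(n_chrom = 6, chrom_length = 3e5, seed = 1)
plan <- tibble::tibble(
  centromeric_partner = c("anc2", "anc3"),
  distal_partner      = "anc1",
  type                = "tandem",
  age_class           = c("C1", "C5")
)
fused <- apply_fusion_plan(anc, plan, seed = 2)
fused$truth$sites
#> # A tibble: 2 × 7
#>   chrom position type   age_class   gap upstream_ancestral downstream_ancestral
#>   <chr>    <dbl> <chr>  <chr>     <dbl> <chr>              <chr>
#> 1 anc1    298349 tandem C1          261 anc1               anc2
#> 2 anc1    588549 tandem C5          297 anc2               anc3

# 2. recover the fusions from synteny blocks
events <- truth_synteny_blocks(fused$truth) |>
  filter_blocks(min_len = 8e3) |>
  detect_fusion_events() |>
  classify_fusion_type(
    centromeres = tibble::tibble(chrom = names(anc$seqs),
                                 centromeric_end = "left"),
    ancestral_lengths = anc$chrom_lengths
  )
events |> select(derived_chrom, position, type)
#> # A tibble: 2 × 3
#>   derived_chrom position type
#>   <chr>            <dbl> <chr>
#> 1 anc1            298349 tandem
#> 2 anc1            588549 tandem

# 3. Hi-C: simulate a plaid contact map, balance it, call compartments
grid  <- bin_grid(c(chr1 = 5e7), resolution = 1e5)
truth <- tibble::tibble(bin = grid$bin,
                        label = ifelse(((grid$bin - 1) %/% 20) %% 2 == 0,
                                       "A", "B"))
m  <- simulate_contact_map(grid, compartments = truth,
                           params = hic_sim_params(compartment_boost = 0.3,
                                                   depth = 1e6, seed = 3))
mn <- ice_normalize(m)
glance(mn)
#> # A tibble: 1 × 8
#>   n_bins resolution n_cells  total normalized n_bad_bins ice_iterations   ice_cv
#>    <int>      <dbl>   <int>  <dbl> <lgl>           <int>          <int>    <dbl>
#> 1    500     100000  102406 998628 TRUE               10             35  8.64e-7

comp <- compute_pc1(observed_expected(mn), grid) |>
  orient_and_label(simulate_covariates(grid, truth, seed = 4))
mean(comp$label == truth$label, na.rm = TRUE)
#> [1] 0.9857143
```

The two recovered junctions sit at the truth positions (the midpoint of
each remnant gap, < 500 bp wide, separating the surviving satI array from
the partial telomere); iterative correction converges in 35 iterations to
a row-sum coefficient of variation below 10⁻⁶; and the compartment caller
relabels ~99% of bins correctly at a 0.3 plaid contrast and one million
read pairs over 500 bins.

`run_full(config)` chains every stage (simulate → fusions → bin map →
matrix → compartments/TADs → interactions → read patterns → neo-Y) at
demonstration scale, writes each stage's output files, and returns a
manifest of file digests that is reproducible from the config and seed.
`karyofuse_thresholds()` documents every numeric constant; plotting
helpers (`plot_compartments()`, `plot_insulation()`,
`plot_length_profile()`, `plot_pattern_census()`, `plot_age_gradient()`)
cover the main result types.

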