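# capbias

Allele-specific capture bias in F1 hybrid exome sequencing, evaluated
end-to-end on synthetic data.

## The problem

Hybridization-based exome capture designs its probes against one reference
genome. When the sample is an F1 hybrid between a reference-matched strain
and a divergent strain, every target is heterozygous and the probes capture
the reference-matched allele more efficiently — the more SNVs and indels a
target carries, the stronger the bias. A second artefact, *mapping bias*
(divergent-allele reads failing to align to a single reference), can mimic
capture bias and must be filtered out before asking how capture bias
affects heterozygous variant detection at a given sequencing depth.

`capbias` rebuilds this whole evaluation as a tested, seeded pipeline for
people who work on allele-specific sequencing analyses: synthetic parental
genomes with a truth variant table, a capture-read simulator with a
controllable allelic bias, a dual-genome read mapper, allelic-origin
assignment, per-target bias statistics, the mapping-bias filter, and a
depth-sensitivity analysis of heterozygous SNV calling.

## The model

For a target *t* with `nSNV(t)` SNVs and `nIndel(t)` indels between the
strains, a simulated read picks its (target, allele) source with
probability

    P(t, allele) ∝ length(t, allele) × w(t, allele),
    w(t, A) = 1,   w(t, B) = exp(−β_snv·nSNV(t) − β_indel·nIndel(t)),

then a uniform start over all placements overlapping the target, a
fair-coin strand, and an error-free 101-nt copy at Q40. With
β_snv = β_indel = 0 this is exactly length-proportional sampling — the
unbiased control.

Reads are mapped separately to both genomes (seed-and-extend, banded
edit-distance, all minimal-distance loci, max edit distance 5); a read's
allelic origin is the genome with the smaller edit distance, with
equal-distance reads excluded and multi-mapping reads discarded. Capture
bias per target is measured as

    M(t) = log2((count_A(t) + c) / (count_B(t) + c)),   c = 0.5,

grouped by divergence and compared between groups with a two-sided
Mann-Whitney U test. A β_snv of 0.15 corresponds to a slope of
0.15/ln 2 ≈ 0.216 in M per SNV, which the pipeline recovers.

## Worked example

```r
library(capbias)

# 1. a synthetic strain pair with known divergence
genome_a <- generate_base_genome(n_chrom = 2, chrom_length = 100000, seed = 42)
div <- derive_divergent_genome(genome_a, divergence_config(seed = 43))
table(div$truth$kind)
#>  deletion insertion       SNV
#>        86       129      1598

# 2. capture targets and their strain-B orthologues
targets <- define_targets(genome_a, n_targets = 120, seed = 44)
orth <- establish_orthology(targets, genome_a, div$genome)
orth
#> <orthology_result: 120 retained, 0 dropped>
ret <- annotate_target_divergence(orth$retained, div$truth)

# 3. simulate a biased capture, map to both genomes, count alleles
reads <- simulate_exome_reads(ret, genome_a, div$genome, n_reads = 150000,
                              beta_snv = 0.2, seed = 1)
index_a <- build_index(genome_a)
index_b <- build_index(div$genome)
mc <- map_and_count(reads, index_a, index_b, ret, capbias_config())

# 4. the capture-bias fit
fit <- capture_bias_fit(mc$counts, ret)
glance(fit)
#> # A tibble: 1 × 5
#>   n_targets n_usable grand_median n_groups n_significant
#> 1       120       95        0.808       14            10
print(tidy(fit), n = 6)
#> # A tibble: 14 × 7
#>   nSNV_group has_indel n_targets  median     q1    q3     p_value
#> 1          0 FALSE            12 0.00937 -0.138 0.205 NA
#> 2          1 FALSE            11 0.337    0.137 0.478  0.0156
#> 3          2 FALSE             9 0.435    0.351 0.560  0.000939
#> 4          3 FALSE             6 0.903    0.807 0.957  0.000108
#> 5          4 FALSE             9 1.19     1.15  1.29   0.00000680
#> 6          5 FALSE             3 1.58     1.47  1.59   0.00440
```

The 0-SNV group sits at a median log2 ratio of ~0 (no bias between
identical alleles), and the medians climb with the SNV count — the
injected per-SNV penalty of 0.2 predicts a slope of 0.2/ln 2 ≈ 0.29 per
SNV, matching the fitted group medians. `autoplot(fit)` draws the grouped
boxplots, `plot_ma()` the MA plot of per-target counts, and
`plot_sensitivity()` the sensitivity-versus-depth curves.

`run_full_experiment(capbias_config(), out_dir)` runs the entire study —
orthology, three biased and three unbiased replicates, a WGS control,
outlier and mapping-bias filters, bias statistics, variant calling and the
depth grid — and writes every table as TSV plus a run manifest.

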