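---
title: "Quantifying allele-specific capture bias in hybrid exome sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying allele-specific capture bias in hybrid exome sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Hybridization-based exome capture enriches sequencing libraries with
oligonucleotide probes designed against one reference genome. In an F1
hybrid between a reference-matched strain and a divergent wild-derived
strain, every locus is heterozygous, and two systematic artefacts distort
allele-specific read counts:

* **capture bias** — probes hybridize less efficiently to the divergent
  allele, so the reference-matched allele is over-represented in proportion
  to the local SNV and indel load of the probe target;
* **mapping bias** — reads from the divergent allele align poorly (or not
  at all) to a single reference, mimicking capture bias if not separated
  from it.

`capbias` re-creates this situation entirely in silico, at desk scale: a
pair of synthetic parental genomes with a known truth variant table, a
capture-read simulator with a controllable allelic bias, a dual-genome
read mapper, and the downstream statistics that recover the injected bias
and its consequences for heterozygous SNV detection.

Because the ground truth is synthetic and fully known, every stage of the
analysis can be checked against an oracle: the derived genome against the
truth table, aligner placements against a liftover map, edit distances
against an independent dynamic-programming alignment, and the caller
against the planted variants.

## Synthetic genomes and targets

`generate_base_genome()` draws i.i.d. bases at a configurable GC fraction
(default 0.5). `derive_divergent_genome()` applies random SNVs and indels:

* `snv_rate = 1/70` per base and `indel_rate = 1/550` per base outside
  conserved blocks, with geometric indel lengths of mean 2. These rates
  emulate the divergence between a laboratory reference strain and a
  wild-derived strain, whose genome-wide totals are roughly 35 million
  SNVs and 4.5 million indels over ~2.5 Gb.
* a **conserved-block mosaic**: 45% of 400-bp blocks carry no variants at
  all. Exome targets are protein-coding and under purifying selection, so
  a realistic fraction of them — about a third of targets here, matching
  what is observed for this strain pair — is identical between the two
  genomes, while their flanking (intronic-like) sequence carries typical
  divergence. Block length is set at probe scale (400 bp) deliberately:
  with kilobase-scale conserved blocks an identical target would sit in an
  entirely variant-free neighbourhood and none of its reads could ever be
  assigned an allele, which is not what happens in real data where
  divergent flanks inform edge-overlapping reads.

Variants never overlap on strain-A coordinates; indel placements that
would collide are resampled. The generator also returns a liftover map
(per-chromosome colinear blocks with offsets) used as coordinate truth in
tests. N bases are never generated; `insert_n_block()` builds explicit
assembly-gap fixtures for the N filter.

`define_targets()` places non-overlapping 120-bp capture targets (the
probe length of the commercial mouse exome design) with a minimum gap of
250 bp, so the later 100-nt extensions never overlap, and a 500-bp margin
from chromosome ends, so simulated reads seldom run off the sequence.

## Orthologous target mapping

Before any simulation, each target must have a one-to-one orthologous
interval on strain B. `establish_orthology()` mirrors the standard
procedure:

1. align the target's strain-A sequence to strain B with the built-in
   aligner, keeping placements with edit distance at most 25% of the
   target length (a full-length alignment standing in for a BLAST search);
2. keep targets with exactly one placement, on the same chromosome
   (`multi_or_unmapped`, `wrong_chrom`);
3. keep targets that lie in the same 5'-to-3' order as their neighbours.
   "Same order" is formalized as the longest strictly-increasing
   subsequence of strain-B start positions within each chromosome, the
   canonical globally-consistent version of the local neighbour rule;
   reverse-strand placements are orientation-flipped and dropped as
   non-syntenic;
4. extend both intervals by 100 nt per side and drop targets whose
   extension contains an N in either genome or crosses a chromosome end
   (`n_extension`); a missing flank means an incomparable capture context,
   so boundary-crossing targets are treated like N-containing ones.

Every dropped target records exactly one reason, and on a
rearrangement-free genome pair the chain drops nothing.

## Read simulation

`simulate_exome_reads()` draws single-end, error-free 101-nt reads:

1. pick a (target, allele) source with probability proportional to its
   extended-interval length times an allelic weight;
2. pick the read start uniformly over `[start - (read_length - 1),
   end - 1]` on the source genome, so every placement overlapping the
   target is equally likely (starts that would run past a chromosome end
   are resampled within the same source, preserving the per-source
   marginal);
3. pick the strand by a fair coin; reverse-strand reads are
   reverse-complemented;
4. qualities are constant Q40.

The allelic weight of the strain-B copy of a target with `nSNV` SNVs and
`nIndel` indels is `exp(-beta_snv * nSNV - beta_indel * nIndel)`; strain A
always has weight 1. With both betas zero the selection probability is
exactly length-proportional over all `2 x n_targets` sources — an
unbiased capture — which is the control condition. The betas give the
pipeline a known ground-truth bias to recover; `beta_snv = 0.15`
corresponds to a log2 ratio slope of `0.15 / ln 2 ~ 0.216` per SNV.

`simulate_wgs_reads()` is the no-capture control channel: strain by fair
coin, start uniform over the genome, same read length and qualities.

An optional uniform substitution-error rate exists but defaults to 0; the
simulator is deliberately error-free so that allelic origin assignment
has no noise floor.

## The aligner

No installed package exposes a desk-scale read mapper with the contract
needed here (all minimal-edit-distance loci, uniqueness flags, CIGARs and
NM-style edit distances on both genomes), so the package implements one in
C++:

* an exact k-mer index (`k = 20` by default; k-mers containing N are
  skipped);
* per read and strand, 4 evenly spaced non-overlapping seeds; each seed
  hit proposes a candidate locus. By pigeonhole, any alignment with at
  most 3 edits of a 101-nt read is guaranteed to retain an intact seed;
  4-5-edit reads are found with near-certainty. This is a documented
  approximation of production aligners, not a reimplementation of one;
* each candidate window is scored by a semi-global edit-distance DP (read
  global, window local). Costs are combined as 256 per mismatch and 257
  per gap base: minimizing the combined cost minimizes the edit distance
  first and, among equal-edit alignments, the number of indels. This
  tie-break matters: without it a substitution at a read edge can be
  reported as an indel, shifting the reported interval by one base and
  breaking the exact agreement with the liftover truth;
* all loci at the minimal edit distance `<= max_edit` (default 5) are
  reported; a read is unique iff exactly one such locus exists. Reads
  needing more than `max_edit` edits are unmapped, which reproduces the
  observed cliff where divergent-allele reads carrying more than 5
  variants cannot be placed on the other genome.

`remove_duplicates()` collapses records sharing (genome, chromosome,
position, strand) to the lexicographically smallest read id — the
single-end PCR-duplicate rule, made deterministic.

## Allelic origin and capture-bias statistics

A read's allelic origin follows the edit-distance rule: discarded if
multi-mapping on either genome; otherwise the genome it maps to, or the
genome with the smaller edit distance when it maps to both; equal
distances leave the read `ambiguous` and excluded. Per-target counts take
any one-base overlap between the alignment and the (extended) target
interval on the origin genome, and the bias measure is
`log2((count_A + c) / (count_B + c))`.

Numerical choices:

* pseudocount `c = 0.5`, so ratios stay finite when one count is zero;
  targets with no assigned reads at all are excluded from ratio analyses
  rather than imputed;
* positive ratios mean bias toward strain A (the probe-design strain);
* two outlier filters precede the group statistics: per-replicate
  0.5%/99.5% quantile flags on three unbiased simulated replicates, with
  targets flagged in at least two replicates discarded; and the same
  quantile rule on the WGS channel plus a total-count cap. The published
  analysis capped WGS sums at an absolute 110 reads, which is specific to
  that sequencing depth; the default here is the 99.5% quantile of the
  sums (scale-invariant), with an absolute override available;
* group comparisons use the two-sided Mann-Whitney U test with no
  multiple-testing correction, matching the per-comparison convention of
  the original analysis; the test and the zero-count policy are exposed in
  the configuration since the original work names neither;
* targets are grouped by SNV count (capped at 6), separately for
  indel-free and indel-bearing targets; a spacing analysis bins the
  2-SNV/0-indel targets by the distance between their two SNVs
  (1, 2-10, 11-30, 31-60, >60).

## Mapping-bias filter and variant detection

To isolate capture from mapping bias, each unbiased replicate is counted
two ways: reads mapping uniquely to at least one genome and overlapping
the target on whichever genome they are placed (dual strategy), versus
reads mapping uniquely to strain A alone (single-reference strategy).
Deduplication keys on the strain-A placement when one exists so both
strategies collapse duplicates identically on undiverged targets. Only
targets where the two counts agree exactly in all three replicates are
retained for variant detection. The dual strategy is implemented as the
union of per-genome unique mappings rather than as one concatenated
two-genome index: the read-level outcome is the same, it reuses the
aligner, and it avoids the cross-genome multi-mapping artefacts a
concatenated index would create at undiverged loci.

Variant detection uses strain-A-only alignments, a CIGAR-aware pileup and
a deliberately simple heterozygous SNV caller (a declared stand-in for a
production pipeline): a call requires depth >= 5, alternate count >= 3,
alternate fraction >= 0.2, and compatibility with heterozygosity (the
reference base still observed, or alternate fraction <= 0.8). These
thresholds give a detection probability around 0.75-0.9 for a balanced
heterozygote at mean depth 10, the regime where capture bias should
matter; sensitivity values are therefore comparable to the published ones
in shape, not in absolute value. Depth subsampling is read-level
Bernoulli thinning with probability `requested / current` over the
retained targets — global, not per-target, so the capture-bias structure
being studied survives the thinning. Indel calling is not attempted.

## Study conditions and problem sizes

The default configuration — the package's definition of the experiment —
uses two 400-kb chromosomes, 600 targets, three 300k-read replicates per
channel (a scaled-down counterpart of three ~75M-read lanes), a 150k-read
WGS control, and the depth grid 10-80 in steps of 10. At these sizes the
full-depth mean coverage over retained targets is ~90, comfortably above
the top of the grid, and the whole experiment runs in minutes on one CPU.
The depth-10 significance contrast simulates a fresh replicate per seed
(ten seeds per condition) rather than only re-thinning one replicate;
with a fixed truth table, re-thinning alone would inherit that one
replicate's positional quirks and the unbiased control would not be a
true null.

## What the synthetic data does and does not show

The generator reproduces the features the analysis depends on: known
divergence per target with a realistic zero-inflated distribution,
length-proportional unbiased sampling, a tunable monotone bias in SNV and
indel load, and exact ground truth for every read and variant. It does
not model GC-biased coverage, probe thermodynamics, repeats or segmental
duplications, sequencing error, PCR duplicates (beyond spike-in
fixtures), or fragment-length effects. Passing tests therefore
demonstrate that the pipeline's inference machinery is correct and
well-calibrated — an unbiased simulation yields no spurious bias, an
injected bias is recovered quantitatively — not that any particular real
capture platform shows a particular bias magnitude.

## Known limitations

* The seed-and-extend heuristic can miss 4-5-edit placements whose seeds
  are all disrupted; such reads are reported unmapped, slightly
  understating multi-mapping ambiguity relative to an exhaustive search.
* Orthologous interval endpoints under an indel spanning a target
  boundary are genuinely ambiguous; the aligner's gap-penalized tie-break
  makes a deterministic choice that can differ from the liftover by the
  indel length at such boundaries.
* The caller is intentionally minimal; its absolute sensitivities should
  not be compared against production variant callers.
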