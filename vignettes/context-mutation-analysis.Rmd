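---
title: "Guanine-centred sequence-context analysis of single-base substitutions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guanine-centred sequence-context analysis of single-base substitutions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutmotif)
```

## The question the package answers

Single-base substitutions (SBSs) in somatic and germline catalogs fall
preferentially at G:C pairs, and within G:C sites the local sequence
context modulates the rate by up to an order of magnitude. One mechanistic
reading is electron transfer: oxidation creates an electron hole that
migrates along the base stack and is trapped at guanines whose neighbours
confer a low ionization energy, and the resulting guanine radical cation
resolves into a mutation. `mutmotif` operationalizes that reading as a
reusable pipeline: canonical context classification, mappability-normalized
counting, group contrasts, recurrence enrichment, strand and splice-site
asymmetries, physicochemical correlations, and dataset clustering.

## Canonical motifs and counting

The context of a mutated G:C pair is the double-stranded tetranucleotide
written 5'→3' on the strand carrying the mutated guanine at position 2
(P2): one of 64 **NGNN** classes. A substitution observed at a cytosine is
the same physical event seen from the other strand, so its forward 4-mer is
reverse-complemented before classification. This folding makes four
palindromic classes (AGCT, CGCG, GGCC, TGCA) special: each duplex
occurrence carries a mutable guanine on both strands, and per-site counting
naturally credits them twice — exactly the doubling rule a sliding-tetramer
scan must apply by hand. The package ships both routes
(`count_genome_motifs()`, per-site; `count_motifs_tetramerwise()`, scan
with explicit doubling) and tests them against each other exactly; the scan
exists only as an independent oracle.

Denominators are restricted to a mappability mask when one is supplied.
Two choices were genuinely open:

- **Mask granularity.** Only the mutated base must fall inside the mask,
  not the whole 4-mer. This matches per-site variant calling, where a call
  is made or withheld at a position, and keeps numerator and denominator
  semantics identical. Tetramers straddling a mask boundary are therefore
  counted whenever their G/C site is mappable.
- **Edge and N handling.** 4-mers overhanging a sequence end or containing
  N are excluded from both numerators and denominators; soft-masked
  (lowercase) bases are uppercased by default, with
  `drop_soft_masked = TRUE` to exclude them instead.

Coordinates are 1-based inclusive at every interface (the VCF convention);
BED inputs are 0-based half-open as the format requires.

## Fractions and contrasts

`motif_fractions()` forms f = m/t, with m counted after deduplication: a
coordinate mutated repeatedly *within a dataset* is one count, regardless
of alternate allele or zygosity. Deduplication is across samples by
default (a per-sample switch exists) — the recurrence module is the place
where per-sample multiplicity matters, and it consumes the raw catalog.

`compare_groups()` contrasts mean f between motif subsets by a two-tailed
Welch t-test across motif-level fractions. For sparse catalogs in which
some motif has no observed mutation the motif-level route degenerates, so
the default `test = "auto"` falls back to a pooled two-proportion z-test
(all m and t summed within each group, pooled-variance normal statistic).
The z-test construction is a design choice; the pooled form was picked
because it is the textbook two-proportion test and reduces to the same
quantity the t-test estimates when counts are dense. −log₁₀P is capped at
308 with an `underflow` flag rather than printing `Inf`.

`p4_adenine_ratio()` implements the purine-bridged fourth-position
contrast: for each of the 8 stems (P1, G, R) with R a purine, the fraction
with P4 = A divided by the mean fraction over P4 ∈ {C, G, T}. It is
computed on fractions f, not raw counts, so unequal motif abundances cancel.

## Physicochemical descriptors

The 12 vertical ionization potentials of G-centred DGN trimers are
embedded data (`vip_table()`, eV, with the free-guanine reference at
8.02 eV), and the package asserts their three physical regularities as
invariants: GGG minimal, GG-doublet trimers below all single-G trimers,
and 3'-purine below 3'-pyrimidine at fixed 5' base.

Stacking free energies are different: the published ΔG(ν) step values are
not embedded here. The shipped table
(`inst/extdata/stacking_steps_synthetic.tsv`, source label
`synthetic-placeholder`) honors only the qualitative class ordering
purine–purine ≫ purine–pyrimidine > pyrimidine–purine >
pyrimidine–pyrimidine, with small deterministic within-class offsets.
It supports plumbing and recovery tests; users reproduce published axes by
supplying the published values through `read_stacking_table()`. The motif
descriptor is the mean over the three ordered steps P1P2, P2P3, P3P4, and
is restricted to DGNN motifs by default because a 5'-C makes the first
step a CpG step whose mutation signal is dominated by methylation-driven
deamination rather than stacking.

`fit_log_linear()` regresses ln f on the descriptor by OLS (natural log;
zero fractions are dropped with a warning, not imputed). The significance
persistence P(α) is not a standard quantity; it is implemented as the
fraction of B = 1000 nonparametric bootstrap resamples of the points whose
refitted slope keeps p < α, seeded and bit-reproducible. Combined-dataset
correlations normalize per dataset first and then average, with a switch
for the reverse order.

## Recurrence, tissues, pathways

A coordinate is recurrent when ≥ 2 *distinct samples* carry a substitution
there (across datasets when pooling); alternate alleles are ignored,
consistent with coordinate-level counting, and a coordinate counts once no
matter how many samples hit it. Enrichment E = (d/Σd)/(t/Σt) is scale-free
in t and ≈ 1 under context independence — the property the acceptance
script recomputes. Tissue shares divide recurrent hits by each tissue's
total catalog size before rescaling to unit sum, so eight statistically
identical tissues contribute 12.5% each. Pathway ranking scores each
pathway-tissue pair as the percentage of samples with ≥ 1 mutated member
gene; cross-tissue combination uses the unweighted mean of per-tissue
percentages (the combination rule was unspecified; the unweighted mean
keeps small tissues from being swamped, and the per-tissue columns are
returned so any other rule can be applied downstream). Gene sets arrive in
GMT form; no pathway database is bundled.

## Transcription strand and splice junctions

A record's mutated guanine lies on the non-transcribed (sense) strand when
its G-strand equals the gene's strand: reference G in a plus-strand gene is
NT, reference C is T. Overlapping genes on opposite strands make a site
ambiguous; records at A:T pairs inside genes have no G-strand and are
reported as a fifth category, `unoriented`, so that the orientation
categories always partition the catalog exactly.

Splice positions are transcription-oriented with no position 0. For donors
the last exonic base is −1 and the first intronic base +1, putting the
canonical GT at +1/+2; for acceptors intronic bases are negative
approaching the junction (canonical AG at −2/−1) and exonic bases positive.
This convention is declared, not inferred — the alternative (numbering
acceptor exonic bases negatively) is equally defensible, and the choice is
localized in two small helpers. A mutation inside the window of two
junctions is counted at the nearest; exact ties are counted at both and
flagged. Junction conservation tabulates per-position base fractions over
unique junctions in transcription orientation.

## Clustering

Dataset spectra (unit-sum rows of f over 64 tetramers or 16 trimers) are
compared by Manhattan distance and clustered agglomeratively, average
linkage by default (the linkage was unspecified; average linkage is the
common default for profile data and single/complete remain available).
Cluster confidence is an ordinary bootstrap support: columns are resampled
with replacement B times and each original cluster's support is the
fraction of replicate trees reproducing its exact leaf set; clusters at
support ≥ 0.90 are flagged. Multiscale bootstrap was deliberately not
implemented — plain support is transparent, seeded and sufficient for the
flagging use here. A two-column matrix of regression coefficients
(slope, intercept) clusters through the same path.

## The synthetic generator

`synth_config()` fixes the study conditions: i.i.d. bases at configurable
GC content (default 0.41, the genome-wide background), optional 1 kb-tile
mappability masks, non-overlapping genes with canonical GT..AG intron ends
written into the sequence, and per-site Bernoulli mutations at rate μ
times the product of applicable multipliers (CpG, 3'-purine, purine-bridged
P4-A, a log-linear VIP term for DGNN sites, a non-transcribed-strand factor
inside genes, per-position splice weights). Alternate alleles are uniform
over the three non-reference bases. A clustered-burst variant exists but
defaults off; the site-independent model is the null everything is
calibrated against. All randomness derives from the mandatory seed (genome
at `seed`, genes at `seed + 1`, mutations at `seed + 2`), so every output
is byte-reproducible.

What the generator does *not* emulate: chromatin and replication-timing
covariates, regional mutation-rate heterogeneity, realistic exon/intron
length distributions, substitution-type spectra, and correlated errors
between samples. Passing recovery tests therefore demonstrates that the
estimators are consistent and unbiased under the stated model — not that
real catalogs satisfy that model.

## Problem sizes and numerical choices

The shipped tests run the type-I calibration of the group contrast at
1,000 replicates on a 50 kb genome (empirically ≈ 0.05 rejection at
α = 0.05), parameter recovery at 4–6 × 10⁵ sites per scenario (each
estimate within two standard errors of its injected value), the
counting-oracle equivalence on 100 random kilobase sequences (exact), and
the null-recurrence enrichment at 5,000 recurrent coordinates on 1 Mb
(d-weighted mean E within ±0.05 of 1). Welch fallback, −logP capping,
undefined-fraction flagging (t = 0), and tie handling at splice junctions
are all exercised directly.

Known limitations: the per-site counting is plain R and comfortable up to
tens of megabases, not whole mammalian genomes; the z-test's pooled form
is one of several reasonable constructions; bootstrap cluster support is
not a confidence level in the frequentist sense; and the stacking table is
synthetic until the user substitutes published values.
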