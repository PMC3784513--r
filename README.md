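# mutmotif

Sequence-context analysis of single-base substitutions (SBSs) at G:C base
pairs.

Large mutation catalogs — cancer genome screens, pathogenic germline
variants, population SNVs — show that substitutions do not strike bases
uniformly: the identity of the neighbours of a mutated guanine strongly
modulates its mutation rate, in ways that track the physics of one-electron
oxidation and charge transfer along the DNA stack. `mutmotif` implements the
full analysis pipeline for this question, for anyone who has a reference
sequence, a substitution catalog and (optionally) gene models and a
mappability mask.

## The model

Every substitution at a G:C pair is assigned to one of 64 canonical
**5'-NGNN-3' motifs**: the double-stranded tetranucleotide around the site,
written on the strand that carries the mutated guanine at position 2 (P2).
A substitution reported at a cytosine is folded onto the opposite strand by
reverse complementation. Four motifs (AGCT, CGCG, GGCC, TGCA) are their own
reverse complement and contain two mutable guanines per duplex occurrence,
so their genomic site counts are doubled relative to a naive tetramer scan.

For motif *i* with *m<sub>i</sub>* mutated sites (one count per coordinate
per dataset, regardless of allele or zygosity) and *t<sub>i</sub>* mappable
genomic occurrences,

- *f<sub>i</sub>* = *m<sub>i</sub>* / *t<sub>i</sub>* — the
  mappability-normalized mutated fraction;
- *F<sub>i</sub>* = *f<sub>i</sub>* / Σ*f<sub>i</sub>* over a stated subset
  (so ΣF = 1);
- group contrasts (CGNN vs DGNN, DGRN vs DGYN, DGAN vs DGBN, with
  D = A/G/T, B = C/G/T, R purine, Y pyrimidine) by two-tailed Welch t-test
  across motif-level fractions, or a pooled two-proportion z-test for sparse
  catalogs; reported as −log₁₀P;
- *E<sub>i</sub>* = (*d<sub>i</sub>*/Σ*d*) / (*t<sub>i</sub>*/Σ*t*) — the
  enrichment of motif *i* among coordinates mutated in ≥2 samples, ≈1 when
  substitutions are independent of flanking sequence;
- tissue shares *S* = *s<sub>n</sub>*/Σ*s<sub>n</sub>* with
  *s<sub>n</sub>* = *t<sub>n</sub>*/*c<sub>n</sub>*, normalizing recurrent
  hits by each tissue's total catalog size;
- log-linear correlations ln *f* = a + b·x of fractions against embedded
  physicochemical descriptors: vertical ionization potentials (VIPs, eV) of
  the 12 G-centred DGN trimers, and mean base-stacking free energies
  ⟨ΔG(ν)⟩ = (DpG + GpN + NpN)/3 over a pluggable dinucleotide-step table;
- transcription-strand ratios r = NT/T per motif, splice-junction
  positional profiles (±20 nt, no position 0, donor G/T at +1/+2) and
  junction base conservation (±25 nt);
- Manhattan-distance agglomerative clustering of context spectra with
  bootstrap cluster support.

A first-class synthetic-data module generates genomes, gene models with
canonical GT..AG introns, mappability masks and context-biased catalogs
with known multipliers (CpG, 3'-purine, P4-adenine, VIP-log-linear,
strand bias, recurrent injections), so every statistic above is
recovery-testable without downloading anything.

## Worked example

A synthetic catalog with a 6-fold CpG hotspot and a 2-fold 3'-purine
enhancement, analysed end to end:

```r
library(mutmotif)

cfg <- synth_config(genome_length = 2e5, gc = 0.41, mu = 1e-3,
                    kappa_cpg = 6, kappa_gpr = 2, n_samples = 4,
                    tissues = c("lung", "skin"), seed = 42)
gen  <- make_genome(cfg)
raw  <- simulate_mutations(gen$genome, NULL, NULL, cfg)
muts <- deduplicate(raw)
#> 4 duplicate coordinate record(s) collapsed

gc_fraction(muts)
#>   dataset       n  n_gc fraction background  p_value
#> 1 synthetic  1225   774    0.632       0.41 6.64e-55

t_tbl <- count_genome_motifs(gen$genome)
ft <- muts |>
  annotate_contexts(gen$genome) |>
  motif_mutation_counts() |>
  motif_fractions(t_tbl) |>
  normalize_fractions("DGNN")

compare_groups(ft, "CGNN", "DGNN")
#>   group_a group_b test              n_a n_b mean_a  sd_a    mean_b  sd_b    statistic
#> 1 CGNN    DGNN    two_proportion_z   16  48 0.0234  0.00437 0.00576 0.00279      21.0
```

(The pooled z-test was auto-selected here because at least one motif had no
observed mutation; pass `test = "welch_t"` to force the t-test.)

63% of substitutions sit at G:C pairs against a 41% genome-wide background
(exact binomial P ≈ 7×10⁻⁵⁵), and the CGNN mean fraction exceeds the DGNN
mean about 4-fold — the injected CpG hotspot, compressed slightly by
coordinate deduplication across the four samples. The three most mutated
motifs are all CpG-led (`CGTT` f = 0.032, `CGGG` 0.030, `CGGC` 0.029).

Correlating trimer-aggregated fractions with the embedded ionization
potentials:

```r
tr  <- dplyr::inner_join(aggregate_to_trimers(ft), vip_table(), by = "trimer")
fit <- fit_log_linear(tr, "f", "vip_ev", bootstrap_B = 500, seed = 1)
fit
#> log-linear fit: ln(f) ~ vip_ev
#>   slope -1.5  intercept 3.275
#>   r2 0.408  p 0.0253  P(alpha)_0.05 0.690  (n = 12, dropped 0)
autoplot(fit)
```

The negative slope says lower-ionization-energy trimers (GGG, GGA, ...)
mutate more — here driven by the CpG/GpR biases the generator injected, not
by an explicit VIP term. Recurrence works on the raw (pre-deduplication)
catalog:

```r
rec <- find_recurrent_sites(raw, genome = gen$genome)   # 4 coordinates
e   <- motif_enrichment(recurrence_counts(rec), t_tbl)
```

With only four recurrent coordinates the per-motif `E` values are extreme
(tens); at realistic catalog sizes the tests show they concentrate near 1
under context independence.

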