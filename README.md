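# barcodeval

Species-discrimination analysis for plant DNA barcodes.

DNA barcoding identifies species from short standardized plastid regions —
typically the slow-evolving coding gene *rbc*L and the fast-evolving
intergenic spacer trnH-psbA. Whether a marker actually *discriminates* the
species in a community is an empirical question, and field surveys answer it
with three complementary criteria applied to aligned sequences plus a
sample-to-taxonomy table:

1. **Haplotype uniqueness.** Sequences are clustered at 100% identity
   (exact string equality on the common alignment). A species sharing even
   one haplotype with another species is precluded from discrimination.
2. **Barcoding gap.** From uncorrected p-distance matrices
   (p = mismatches / compared sites), each species gets
   `gap = min_inter − max_intra`, where `min_inter` is its minimum distance
   to a congeneric sample and `max_intra` its maximum intraspecific
   distance. A species has a barcoding gap only when the difference is
   strictly positive.
3. **Best-match identification.** Each query is scored against a reference
   library (match counts on the common alignment — a deterministic, local
   surrogate for a database bit-score). A query is identified only when a
   *unique* top-scoring species equals the true species; ties are failures,
   and species absent from the library are evaluable only at genus level.

`barcodeval` implements all three, plus species-diagnostic indel detection
(gap runs fixed within one species and absent in congeners — discrete
characters that distance analyses discard), leave-one-out evaluation, a
cross-method summary with per-method efficacies, and a seeded simulator of
aligned multi-genus communities for calibration and testing.

## Worked example

Simulate a one-genus community of 5 species × 3 individuals at a 1000-column
marker, with interspecific divergence (0.02 substitutions/site) well above
intraspecific (0.001), then run the three criteria:

```r
library(barcodeval)

cfg <- sim_config(genera = data.frame(genus = "G", n_species = 5L,
                                      n_individuals = 3L),
                  markers = c(m1 = 1000L),
                  m_species = 0.02, m_individual = 0.001, seed = 7)
sim <- simulate_community(cfg)

species_distance_summary(p_distance_matrix(sim$alignments$m1), sim$records)
#>   species n_samples max_intra min_inter   gap has_gap
#> 1   G_sp1         3     0.002     0.043 0.041    TRUE
#> 2   G_sp2         3     0.003     0.047 0.044    TRUE
#> 3   G_sp3         3     0.004     0.041 0.037    TRUE
#> 4   G_sp4         3     0.004     0.041 0.037    TRUE
#> 5   G_sp5         3     0.001     0.044 0.043    TRUE

loo <- leave_one_out(sim$alignments$m1, sim$records)
identification_summary(loo, sim$records)$efficacy_represented_pct
#> [1] 100
```

Every species shows a positive barcoding gap (min_inter exceeds max_intra
by ~0.04) and leave-one-out identification is perfect. Forcing two species
to share a haplotype (`share_pairs = list(c("G_sp1", "G_sp2"))`,
`m_individual = 0`) flips both to non-discriminated and turns all their
queries `ambiguous` — the tie-is-failure rule at work.

The package also bundles summary tables from a barcode survey of 68
Mediterranean forest trees (24 species, 10 genera; `survey_samples()`,
`survey_haplotypes()`, `survey_gaps()`, `survey_methods()`). On those,

```r
mc <- method_comparison(hap_status_from_counts(), gap_summary_from_table(),
                        ref_status_from_table())
mc$efficacy
#> haplotype       gap reference
#>      66.7      26.3      55.0
```

i.e. haplotype uniqueness discriminates 16/24 species, a positive barcoding
gap exists for 5/19 evaluable species, and the reference database correctly
identifies 11/20 represented species (45.8% of all 24).

A thin command line (`inst/exec/barcodeval`) exposes the same pipeline:
`barcodeval simulate|cluster|gap|indels|loo`.

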