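---
title: "Evaluating species discrimination with plant DNA barcodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating species discrimination with plant DNA barcodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeval)
```

## The problem

A DNA barcode is useful only if the variation it captures separates
species: intraspecific divergence must stay below the divergence between a
species and its closest sampled relative, and the database used for
matching must actually contain the species. `barcodeval` evaluates a
sampled community of sequenced individuals — each with a species, genus
and family label — against three criteria that probe different failure
modes:

* **haplotype uniqueness** fails when congeneric species share identical
  sequences (hybridization, incomplete lineage sorting, low mutation
  rate);
* the **barcoding gap** fails when intraspecific variability overlaps
  interspecific divergence, even without exact sharing;
* **best-match identification** additionally fails when the reference
  library is incomplete or carries misleading near-ties.

The three views are deliberately kept separate and then rolled up by
`method_comparison()`, because a species can pass one and fail another:
a species with private but barely-divergent haplotypes passes the
haplotype criterion and fails the gap criterion.

## Models and rules

### Haplotypes at 100% identity

`cluster_haplotypes()` partitions aligned rows by exact string equality.
Because the input is a common alignment of equal-length rows, identity
clustering with full length coverage degenerates to string equality, which
is the only deterministic, transitive reading. Two consequences are
intentional: gap characters participate in identity (two sequences
differing only by an indel are different haplotypes — indels carry signal
here), and ambiguity codes must match literally (a compatibility rule such
as "N matches anything" is rejected because it makes identity
non-transitive and would break the partition property). A species is
*discriminated* when no cluster containing it contains another species.

`discrimination_rates()` reports this at three levels: individuals not
carrying a shared haplotype; species discriminated; and species
discriminated after dropping genera with a single sampled species.
The third level exists because a genus-singleton cannot share a congeneric
haplotype by construction, so keeping it inflates the species-level rate —
dropping always-discriminated singletons can *lower* the rate, which is
why the two species-level numbers must be read together.

### Uncorrected p-distances and the gap

`p_distance_matrix()` computes p = mismatches / compared sites, with no
multiple-hit correction: at barcode-scale divergences (p ≤ 0.03 in typical
plastid data) corrections are negligible, and uncorrected p keeps the
arithmetic exactly reproducible from printed tables. Only the four
unambiguous bases are compared; gaps, `N` and IUPAC ambiguity codes are
missing data. The default `complete_deletion` policy removes every column
containing missing data in *any* row before any comparison — the distance
analysis therefore "sees" no indels at all, which is precisely why the
indel module exists as a separate source of characters.
`pairwise_deletion` (per-pair column removal) is available by flag.
For combined markers the concatenation is built first
(`concatenate_markers()`, common samples only, no gap-padding — padding
would fabricate haplotypes) and complete deletion is applied across the
concatenation; applying it per marker is a defensible alternative, but the
cross-concatenation rule is the stricter and simpler default.

`species_distance_summary()` gives each species `max_intra` (undefined for
singletons) and `min_inter`, restricted to *congeners by the metadata
genus column* — not by sequence similarity, so a misassembled genus shows
up as a failure rather than being silently repaired. The barcoding gap is
`min_inter − max_intra`, and `has_gap` demands **strict** positivity: a
species whose extremes are equal has no gap. Undefined inputs propagate to
an undefined gap (`n.d.` in reports), never to a silent zero; undefined
species are excluded from the gap-efficacy denominator. Reports round to
4 decimals; full precision is kept internally.

### Diagnostic indels

`gap_runs()` extracts maximal runs of `-` per row (0-based, half-open
internally; 1-based inclusive in reports). `diagnostic_indels()` promotes
an interval to a diagnostic character when it is fixed (present in every
sample) in at least one species and absent from every sample of at least
one congener. Two choices matter:

* *Identical interval, not overlap.* Homologous gaps on a common alignment
  share coordinates; merging near-miss intervals would manufacture
  characters, so overlapping-but-unequal runs stay separate.
* *`min_length = 20`, terminal runs excluded.* Short gaps (1–19 bp) are
  typically intraspecifically variable noise in fast spacers, and terminal
  gaps depend on trimming rather than biology; both defaults are
  configurable, and the terminal-gap exclusion is recorded in output
  metadata as an assumption.

Intraspecifically variable runs are never diagnostic, whatever their
length.

### Best-match identification

`score_pair()` counts positions where both rows carry the same unambiguous
base, over columns where both are unambiguous. This is a deterministic,
database-version-independent surrogate for an alignment bit-score, and it
is exactly consistent with the pairwise-deletion distance
(matches = compared − mismatches), which the tests assert. It is monotone
in identity for near-full-length queries — the regime of a barcode
scenario; it is *not* a substitute for local alignment of partial queries,
which is out of scope. Results are labelled as a local surrogate, never as
database output.

`identify_query()` never breaks ties: if several species attain the top
score the status is `ambiguous`, a failure, with no score-margin or
E-value heuristics. `wrong` means the true species is represented but
outscored; `unrepresented` means it has no library entry at all, in which
case only `genus_correct` (all top species in the true genus) is
meaningful. `leave_one_out()` queries each sample against all others —
removing only the query itself, so conspecifics remain, as in a database
scenario; `leave_species_out = TRUE` (or `mask_species` in the simulator)
models total database absence. `identification_summary()` counts a species
correct only when **all** its queries are correct, and reports success
both over represented species and over all species; the second rate's
denominator includes unrepresented species as failures, so the pair of
numbers quantifies how much of the failure is the library's fault.

## The bundled survey tables

`survey_samples()`, `survey_haplotypes()`, `survey_gaps()` and
`survey_methods()` transcribe the summary tables of a barcode survey of 68
Mediterranean forest trees (24 species, 10 genera, 9 families; rbcL +
trnH-psbA). They drive the reporting side of every module without sequence
downloads — the `*_from_*` converters produce the same layouts as the
computing functions, so transcribed and computed results flow through
`method_comparison()` identically.

```{r survey}
mc <- method_comparison(hap_status_from_counts(),
                        gap_summary_from_table(),
                        ref_status_from_table())
mc$efficacy
mc$counts
sum(mc$rows$n_methods_ok >= 2)
```

Two transcription notes. First, the individual-level discrimination rate
needs per-species counts of individuals carrying shared haplotypes; the
source tables print cluster counts, but the counts are recoverable by
combining the listed sharing pairs (3+4+2+5 = 14 individuals) with the
unique-haplotype columns (a species with zero unique haplotypes has all
its samples in shared clusters), giving the `shared_samples` column.
Second, the source tables disagree on a few per-species sample counts
(n = 4 vs 3 for *Crataegus azarolus*, and the *C. monogyna* /
*C. oxyacantha* counts are swapped between tables); each fixture
transcribes its own table as printed and the discrepancy is left visible
rather than resolved.

## The simulator

`simulate_community()` generates what the analysis assumes and nothing
more: a star phylogeny within each genus and species (no coalescent),
with one uniformly random ancestor per genus and marker, species ancestors
at per-site substitution probability `m_species`, individuals at
`m_individual`, each substituted site moving uniformly to one of the three
other bases, at most one hit per branch. Star trees plus the single-hit
model keep the pairwise expectation in closed form —
`expected_pairwise_distance(m_a, m_b) = 1 − [(1−m_a)(1−m_b) + m_a·m_b/3]`
— which the tests verify by exhaustive enumeration of the one-site outcome
space and by Monte-Carlo within 3 standard errors. At barcode-scale
divergences the no-multiple-hit simplification is numerically negligible.

Haplotype sharing is modelled as exact identity: `share_pairs` makes the
second species copy the first's ancestral sequence. Observed shared
haplotypes *are* identical sequences, so sharing experiments run with
`m_individual = 0` for determinism — with individual-level substitution
switched on, "sharing" would decay into near-identity and the failure
signatures (shared clusters, zero `min_inter`, ambiguous queries) would
become probabilistic. Indels are species-fixed deletions applied after
substitution; `mask_species` removes species from the reference library
while keeping them as queries. Defaults emulate a small temperate-tree
survey: a few genera with 1–4 congeneric species and a handful of
individuals each, one slow (688-column) and one fast (500-column) marker,
`m_species = 0.02` vs `m_individual = 0.001` — interspecific p ≈ 0.04
against intraspecific p ≈ 0.002, the regime where barcoding is expected to
work.

What the simulator does **not** model: coalescent variance and incomplete
lineage sorting, hybridization, sequencing error, alignment error, length
variation between markers' true sequences (rows are born aligned), and
database taxonomic noise. Passing tests on simulated communities therefore
show the *machinery* is correct under the stated statistical structure,
not that any real marker will discriminate any real flora; the bundled
survey tables illustrate how far real communities sit from the clean
regime (66.7% haplotype efficacy, 26.3% gap efficacy there).

## Numerical and edge-case choices

* Sequences are uppercased and `U → T` at read time; alphabet violations,
  ragged rows, all-gap rows, duplicate ids and metadata mismatches are
  errors, never silent drops.
* A pair (or dataset) with zero comparable sites is an error naming the
  pair — a distance of 0/0 must not masquerade as identity.
* Cluster ids number clusters by first-member input order; permuting input
  changes ids only, never the partition, and tests assert this.
* Percentages are `round(100·num/den, 1)`; gap reports round to 4
  decimals; both keep full precision internally.
* The test suite's simulation sizes (communities of 10–15 individuals at
  1000 columns, 100 seeds for calibration loops, 60 Monte-Carlo replicates
  per setting) were chosen to keep the full suite under a minute while the
  3-standard-error calibration bands remain meaningful at those counts.

## Limitations

Identification scores assume near-full-length queries on the common
alignment; partial or unaligned queries need an aligner upstream. The
diagnostic-indel rule requires coordinate-identical runs, so alignment
ambiguity around repeats can split a biologically single indel into
near-miss intervals (reported separately, not merged). No model-corrected
distances are offered — at these divergences they would change nothing,
and the uncorrected scale is what printed gap tables use.
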