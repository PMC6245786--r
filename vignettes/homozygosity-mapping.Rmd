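---
title: "Homozygosity-based linkage mapping of recessive mutations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homozygosity-based linkage mapping of recessive mutations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homozymap)
```

## The mapping problem

A fully penetrant recessive point mutation segregates in an F2 incross of two
heterozygous carriers.  Offspring are sorted by phenotype into a mutant pool
(homozygous for the causal allele) and a sibling pool (heterozygous or
homozygous wild-type, 2:1), and each pool is sequenced as bulk DNA at shallow
coverage (~8–9x).  Background SNP markers that distinguish the two parental
strains segregate freely everywhere except near the causal locus: in the
mutant pool, markers tightly linked to the causal allele approach fixation
for the carrier haplotype, so the pool genotype is called homozygous
non-reference there, while unlinked markers sit near allele frequency 0.5
and are called heterozygous.  Scanning for the region of excess homozygosity
in the mutant pool localises the mutation; annotating the variants inside
that region against transcript models and filtering by predicted impact
produces a short candidate list.

`homozymap` implements this whole chain — quality filters, the mapping
statistic, region extraction, consequence annotation, and the candidate
cascade — together with a cross/sequencing simulator that generates pooled
variant tables with a known injected causal variant, so every stage is
testable without raw sequencing data.

## The simulator

The simulator (`simulate_f2_pools()`) is explicit about its genetic model:

* **Meiosis.** Each F1 parent is heterozygous at every marker, with the
  causal allele in coupling with one complete parental haplotype.  A gamete
  starts on either haplotype with probability 1/2 and switches phase between
  adjacent markers independently with the interval's recombination fraction
  (`simulate_meiosis()`).  Recombination fractions come from the Haldane map
  function, `r = ½(1 − e^(−2d))` — crossovers are a Poisson process with no
  interference.  This is the simplest analytically tractable model; it
  slightly overestimates double crossovers at short distances compared to
  interference-aware maps, which is immaterial at the marker spacings used
  here.
* **Physical-to-genetic scale.** Map distance accrues at `cm_per_mb = 2`
  centimorgans per megabase by default, a zebrafish-scale average
  (roughly 2,700 cM over a ~1.35 Gb genome).  It is a single global rate;
  real recombination landscapes have hot and cold spots the simulator does
  not attempt to model.
* **Phenotype sorting.** Individuals homozygous for the causal alternate
  allele go to the mutant pool, everyone else to the sibling pool —
  full penetrance, no misphenotyping.  Pool sizes default to 40 + 40
  embryos, a realistic clutch-scale sort; the source study does not state
  its pool sizes, so this is a package choice exposed in the configuration.
* **Sequencing.** Per marker and pool, read depth is Poisson (means 9 and 8
  for mutant and sibling pools, matching shallow whole-genome coverage) and
  alternate read counts are binomial with the pool allele frequency
  perturbed by a per-read miscall probability (`base_error = 0.01`).  Each
  pool is then genotyped as one *pseudo-diploid* sample (`call_genotype()`):
  likelihoods for 0/0, 0/1 and 1/1 use per-read alternate probabilities
  `e`, `0.5` and `1 − e`, the call is the maximum-likelihood genotype, and
  GQ is the phred-scaled gap to the runner-up (floored, capped at 99).
  This mirrors how pooled DNA is genotyped in practice: a homozygous call is
  a statement that the pool allele frequency is near 0 or 1.
* **Default genome.** 25 chromosomes of 50 Mb with 2 markers per Mb and the
  causal variant injected at position 29,288,858 of the 13th chromosome —
  small enough for desk-scale runs while shaped like the zebrafish setting.
* **Determinism.** The seed is a mandatory field of the genome
  specification; identical configuration and seed reproduce byte-identical
  VCF output.  There is no hidden global RNG state.

What the simulator deliberately omits: read-level artifacts (mapping error,
duplicates, indel misalignment), multi-allelic sites, position-dependent
error rates, ENU mutation-spectrum modelling, and misphenotyped embryos.
Passing tests on simulated data therefore demonstrate that the *statistical
machinery* recovers a recessive locus under Mendelian segregation and
binomial sequencing noise — not that the pipeline is robust to every
alignment pathology of real data.

## Quality filters

`apply_hard_filters()` removes records that are multi-allelic, carry a
missing genotype, fail the VCF FILTER column, or have genotype quality below
5 in *either* sample (strict inequality: GQ exactly 5 survives).  The GQ
rule removes the whole record rather than masking the failing sample,
because a half-missing record would silently change the genotype-pattern
extraction downstream.  Each removed record is attributed to exactly one
named rule, in a fixed order, so the tally always sums to the number
removed.  At 8–9x, genuinely ambiguous read draws (e.g. 7 reference + 1
alternate read at a heterozygous site) produce GQ < 5 and are dropped; this
is intended behaviour of the filter, and the reason candidate extraction
happens on a separate table (below).

## The mapping statistic

1. **Chromosome selection.** For every chromosome and sample the
   *homozygosity score* is the fraction of markers called 1/1
   (`chromosome_homozygosity_scores()`).  The candidate chromosome is the
   argmax of the mutant-pool score; ties break to the first chromosome in
   table order, with a warning.  The sibling track is computed for plotting
   and sanity checks only.  An `informative_only` switch restricts the
   score to markers heterozygous in the sibling pool, an alternative
   definition some pipelines use; the default counts all markers.
2. **Windowed ratio.** Along the candidate chromosome, fixed windows
   (default 5 Mb, stride 0.5 Mb, internally 0-based half-open, reported
   1-based) collect mutant-pool marker calls, and each window scores
   `ratio = (n_hom + 1) / (n_het + 1)`.  The pseudocount (default 1) keeps
   fully homozygous windows finite; a window with equal counts scores
   exactly 1 for any pseudocount.  Windows without markers are omitted.
3. **Smoothing.** The ratio track is smoothed by locally weighted
   regression implemented in the package (`loess_fit()`): at each window
   centre, a degree-1 polynomial is fitted over the `⌈span · n⌉` nearest
   points (default span 0.3) with tricube weights
   `w = (1 − (|x−x₀|/h)³)³`, `h` the distance to the farthest neighbour;
   optional robustness iterations reweight by the bisquare of scaled
   residuals (default 0).  The smoother is implemented in-package so its
   numerical contract can be tested point-by-point against an independent
   weighted-least-squares oracle; the test suite holds it to 1e−10 relative
   agreement and to exact reproduction of lines and constants.
4. **Region extraction.** The critical region is the maximal contiguous run
   of windows around the fitted maximum whose fitted value stays above
   `threshold_frac` (default 0.95) of the peak
   (`critical_region_from_fit()`).  A pure argmax would give a point, not
   an interval, so a peak-neighbourhood rule is necessary; the threshold is
   configurable and echoed in every output.  A peak below `min_fit_floor`
   (default 1: homozygous and heterozygous calls in balance) means no
   chromosome shows real homozygosity enrichment and the pipeline reports
   "no linkage detected" as a distinct, non-error exit path.
5. **Pattern extraction.** Inside the region, candidate variants are those
   homozygous alternate in the mutant pool and heterozygous or homozygous
   reference in the sibling pool (`extract_linked_variants()`).

### Why the window default is 5 Mb

The ratio of two small counts only carries signal if the window holds
enough markers.  At the default density of 2 markers per Mb, roughly 80% of
which survive QC, a 1 Mb window holds about 2 markers and the pseudocount
ratio saturates at (2+1)/(0+1) = 3 — the linked plateau becomes nearly
flat, and on simulated crosses the extracted region then missed the true
locus in about a third of runs.  A 5 Mb window holds ~8 usable markers,
giving the ratio a dynamic range of roughly 9 (fully homozygous) versus
0.3 (unlinked), and the mapped region contains the injected causal position
in ≥ 90% of seeded runs, with a median width of ~7.5 Mb — the same scale as
the intervals such screens report.  As a rule of thumb the window should
hold at least ~8 post-QC markers; both window and stride are configuration
parameters, so denser marker sets can (and should) use narrower windows.

### Two-stage filtering

The GQ filter exists to keep unreliable *markers* out of the mapping
statistic, where a wrong call merely adds noise to a window count.  Applied
to candidate extraction it would do real damage: one ambiguous read draw in
the sibling pool (GQ 3–4) can silently delete the causal variant itself —
in simulation this happened in ~15% of default runs.  `run_pipeline()`
therefore maps on the GQ-filtered table but extracts candidates from a
second-stage table subject only to structural filters (biallelic,
non-missing, FILTER pass).  This mirrors the two-stage design of
mapping-by-sequencing studies, where the final candidate call set is derived
with more information than the marker scan.

## Consequence annotation

Transcript models (exon/CDS/strand) load from GFF3 with their genomic
sequence from FASTA; minus-strand CDS are reverse-complemented
(`load_transcripts()`).  The genome loader also accepts region FASTA records
(`>chr13:29288749-29289263`, the `samtools faidx` convention), so a short
locus extract can stand in for a long chromosome when only that locus is
annotated — this is how the simulated study annotates its synthetic causal
gene without shipping a 50 Mb sequence.

A variant's CDS coordinate counts from the initiator ATG; on minus-strand
transcripts position 1 is the 3′-most genomic CDS base, and the projection
and its inverse are tested as mutual inverses on every coding base of toy
transcripts.  The codon containing the variant is rebuilt with the
strand-adjusted alternate base and translated with the standard genetic
code: same residue → `synonymous` (LOW); new stop → `stop_gained` (HIGH);
lost stop → `stop_lost` (HIGH); otherwise `missense` (MODERATE).  Intronic
positions within 2 bp of an exon boundary are `splice_site` (HIGH) — the
canonical donor/acceptor dinucleotides; exonic, non-coding positions are
`UTR` and everything else `intron`/`intergenic` (MODIFIER).  Positions are
always reported with their transcript identifier, because a protein position
is only meaningful relative to a specific isoform's initiator methionine —
the same residue can carry different numbers in different isoforms.
Selenocysteine recoding and non-standard genetic codes are out of scope.

Protein-level conservation of a candidate residue can be quantified from an
aligned FASTA as the fraction of non-gap residues matching the column
majority (`conservation_score()`); ties report the lexicographically
smallest majority residue and all-gap columns are flagged undefined.

## The candidate cascade

Annotated region variants pass through two per-record predicates, in either
order (they commute; the tally reports both stages): exact-key
`(chrom, pos, alt)` exclusion against a known-sites set (e.g. a dbSNP
extract — a record at a known position with a *different* alternate allele
is retained), then retention of HIGH and MODERATE impacts only.  The report
sorts survivors by impact severity, then conservation (descending, missing
last), then position, and carries all survivors plus a stage-by-stage tally
— ranking is presentation, not exclusion, so no candidate is hidden.

## Numerical and degenerate-input choices

* GQ is `floor` of the phred-scaled likelihood gap, capped at 99; zero
  depth gives a missing call with GQ 0; `base_error = 0` is legal (the
  0·log 0 = 0 convention).
* Genotype-likelihood ties resolve to the first genotype in
  (0/0, 0/1, 1/1) order with GQ 0 — such calls never survive the GQ filter.
* The smoother forces each neighbourhood to hold at least `degree + 2`
  points; if robustness weights zero out a whole neighbourhood (possible
  when the fit is exact elsewhere), it falls back to plain kernel weights.
* An exactly constant fitted track is a degenerate "peak": the region spans
  all windows and the peak reports at the first maximum.  Separated
  equal-height peaks keep the leftmost, with a warning.
* Chromosome sort contract: chromosome blocks must be contiguous with
  strictly increasing positions; no lexicographic order is imposed across
  chromosome names, so `chr10` never sorts between `chr1` and `chr2`.
* All user-facing coordinates are 1-based inclusive (VCF convention); BED
  output converts to 0-based half-open.

## Problem sizes used in the tests

The packaged validation runs at desk scale: the default simulated genome
(25 × 50 Mb, 2 markers/Mb, ~2,500 markers, 40 + 40 individuals) completes a
full pipeline run in about a second, and the recovery suite repeats it over
20 seeds.  Property checks (meiosis symmetry, segregation fractions,
linkage decay) use 10³–10⁴ gametes with 3σ binomial tolerances; the codon
classifier is checked exhaustively over all 64 × 9 single-base codon
changes against a hand-coded genetic-code oracle.

## Known limitations

* The homozygosity score and the window ratio assume a *single* recessive
  locus; oligogenic traits or synthetic-lethal pairs will produce multiple
  or diffuse peaks that the single-region extractor summarises poorly.
* Pseudo-diploid pool genotyping discards within-pool allele-frequency
  detail; allele-frequency–difference methods (G′-type statistics) can be
  more powerful at higher coverage but are out of scope here.
* The simulator's uniform recombination rate and marker grid make the
  mapped-region width more regular than real data would be.
* Known-site exclusion is exact-key only; it does not consult allele
  frequencies or population databases beyond the supplied file.
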