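---
title: "Second-hit screening: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Second-hit screening: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secondhit)
library(dplyr)
```

## The problem

In a suspected autosomal-recessive case where clinical testing has found
one pathogenic variant ("the first hit"), the diagnosis hinges on finding
the second pathogenic allele. Second hits are often cryptic: structural
variants (SVs) missed by targeted assays, deep-intronic variants that
create splice sites, or homozygous variants hidden inside runs of
homozygosity (ROH) in consanguineous families. `secondhit` implements a
systematic screen for such alleles from short-read WGS call sets: it
aggregates SV calls across samples and callers, prioritises rare SV
clusters and rare small variants in a window around the first-hit gene,
phases candidate pairs by trio inheritance, estimates mosaic fractions for
parental deletions from read depth, and annotates splice-altering variants
with length/frame arithmetic.

Because the cohorts this kind of screen runs on are access-controlled, the
package ships a synthetic-cohort generator with planted truth
(`simulate_cohort()`). Every pipeline stage is exercised end-to-end
against that truth in the test suite.

## SV aggregation

Two callers reporting the same deletion rarely agree to the base pair.
Calls are therefore grouped by *reciprocal overlap* (RO): the overlap
length divided by the length of the **longer** interval. Two calls match
when they share an SV type and achieve RO at or above the threshold
(default 0.8). Dividing by the longer interval matters: one-way overlap
would merge a 1 kb deletion nested inside a 100 kb deletion, which is not
"the same variant with slightly different breakpoints".

Clusters are single-linkage connected components of the match relation,
computed with an interval-overlap index (`IRanges::findOverlaps()`) plus
graph components (`igraph::components()`), and verified in the tests
against a brute-force transitive closure. Single linkage is the right
model for aggregation across thousands of samples (matching must be
transitive to give each variant one identity), at the documented cost that
a chain of pairwise matches can connect two calls whose direct RO is below
the threshold.

Insertions get their own rule: RO is undefined for a point-like breakpoint,
so two insertions match when their breakpoints lie within `ins_tol_bp`
(default 50 bp) and their inserted lengths agree within 20%. This rule is a
package convention, not a reimplementation of any particular caller's
merging logic.

A cluster's *cohort frequency* is the fraction of participants carrying it
— carriers, not alleles, so heterozygous and homozygous carriers count
once. "Rare" means strictly below 1% (`rare_clusters()`); a cluster at
exactly 1% is not rare.

## The per-case screen

`screen_case()` anchors on the first-hit gene and considers, in priority
order but always reporting both:

1. rare SV clusters whose representative interval falls within 1 kb of the
   gene body (the window is exactly 1000 bp by default, boundary
   inclusive, and configurable) and whose carriers include the proband;
2. rare small variants in the same window carried by the proband,
   excluding the first-hit variant itself.

Population allele frequency is the **only** hard filter for small variants
(every AF present must be below 1%; an absent AF counts as 0, i.e. novel).
CADD and splice delta scores enter a ranking score
(`cadd_weight * CADD + splice_weight * max(AG, AL, DG, DL)`) that orders
candidates but never removes one. This is a deliberate lesson from
practice: pathogenic deep-intronic variants with near-zero predicted
splice-gain scores exist, and a screen that gates on in-silico scores
silently loses them. The AF threshold and both weights live in
`evidence_weights()`.

Candidates are phased against the first hit by inheritance when a trio is
available: maternal iff the mother carries and the father does not,
paternal symmetrically, with ambiguous (both parents carry), de-novo and
no-trio cases giving an unknown phase. Trans-phased candidates rank first,
unknown next, cis last — cis candidates are flagged, never dropped,
because inheritance-based phase can be wrong and is supporting evidence
rather than a gate. Proband-homozygous rare variants inside a detected ROH
are emitted on a separate `HOMOZYGOUS_IN_ROH` path that ranks alongside
trans (both are complete biallelic explanations); this promotion happens
even when a heterozygous first hit was recorded, because a recorded first
hit can be misleading in consanguineous cases. Homozygous variants
*without* a containing ROH stay on the compound-het path with a note.

## Mosaic fraction from read depth

A heterozygous deletion present in a fraction $f$ of cells leaves expected
depth $d_{in} = d_{flank}\,(1 - f/2)$ over the deleted region, so

$$\hat f = 2\left(1 - \frac{d_{in}}{d_{flank}}\right),$$

clamped to $[0, 1]$ and reported as a percentage (`mosaic_fraction()`).
A constitutive heterozygote reads as 100%. The estimator is defined for
deletions only; duplication mosaicism is out of scope. Flank depth is
averaged over windows of the SV's own length on each side, excluding a
1 kb guard zone at each breakpoint where read evidence is unreliable
(`estimate_mosaic()`); both window and guard are configurable. The
formula, the clamping and the flank definition are package contracts —
depth comparisons of this kind are usually reported without an explicit
estimator, so the contract is stated here instead of left implicit.
At 60x coverage over a 10 kb deletion the estimator recovers planted
fractions within ±5 percentage points in >95% of replicates (tested).

## ROH detection

`detect_roh()` slides a 50-site window along one sample's ordered
genotypes and flags windows with at most 2 heterozygotes; overlapping
flagged windows merge. Site-count windows (rather than fixed-bp windows)
keep behaviour stable under variant-density variation. Merged regions
below 2 Mb, or with fewer than 100 sites, or above 5% heterozygosity, are
discarded.

Window merging alone systematically over-extends regions into flanking
sequence: a window straddling the block edge tolerates two heterozygotes,
and the flanking sites it drags in are homozygous-enriched *by selection*,
so threshold-based trimming cannot identify them. Boundaries are therefore
refined by a score scan outward from the region interior — +1 per
homozygous site, −9 per heterozygous site, boundary at the outward score
maximum. The penalty is the rounded log-likelihood ratio of observing a
heterozygote inside a true ROH (genotyping error, ~0.5%) versus outside
(common markers, ~40% heterozygosity): a boundary only crosses a
heterozygous site when at least nine homozygous sites lie beyond it. With
this refinement, planted blocks of 5–20 Mb are recovered at ≥90%
reciprocal overlap in ≥99% of seeds (tested over 100 seeds).

The detector is a stand-in with a stated contract: production cohorts
usually come with ROH calls from dedicated tooling, and `screen_case()`
accepts precomputed regions via `roh_regions=`.

## Splice-consequence arithmetic

Only length and reading-frame arithmetic is computed; no sequence-level
splice scoring (delta scores are consumed from an annotation table, the
models that produce them are never run):

* a gained acceptor whose AG ends at intronic offset −k retains
  $k - 1$ intronic nucleotides (`acceptor_gain_retention()`; offsets −1/−2
  are the canonical acceptor dinucleotide and are rejected as a different
  variant category);
* a pseudoexon spanning positions $a..b$ inserts $b - a + 1$ nt;
* a skipped exon `c.START_ENDdel` removes $END - START + 1$ nt;
* frameshift iff the altered length is not a multiple of 3.

Protein-level consequences (`p.(...fs*N)`) are deliberately not generated:
the termination offset requires the transcript sequence, which is out of
scope. HGVS parsing is limited to the three patterns the screen needs
(`c.POS-OFFSETREF>ALT`, `c.START_ENDdel`, `c.START_ENDinsN`); anything
else is rejected with a clear error. SV sizes quoted from printed
breakpoints use the coordinate difference (`span_kb()`), matching the
convention in which chr2:135,165,337–135,511,837 is "a 346.5 kb deletion".

## The synthetic cohort

`simulate_cohort()` generates, deterministically from one seed: trio
pedigrees; Hardy–Weinberg marker genotypes (Mendelian within each trio) on
two synthetic 250 Mb chromosomes; 40 non-overlapping genes of 10–30 exons;
per-family novel first-hit variants; planted second hits that are
genuinely in trans (the two variants of each pair descend from different
parents by construction); background SV clusters at configured carrier
fractions spanning common (>1%) and rare (<1%); two callers per true SV
with independent rounded-Normal(0, 20 bp) breakpoint jitter and 5%
per-caller dropout; one mosaic paternal deletion (true fraction 44%)
genotyped heterozygous but depleted in the depth table; and
consanguinity-style ROH blocks realised as founder-haplotype homozygosity
with 0.5% heterozygote contamination.

Choices worth knowing about:

* **Marker spacing is 25 kb.** ROH boundary precision is limited by marker
  spacing; 25 kb supports the ≥90%-overlap recovery contract for ≥5 Mb
  blocks while keeping a 200-family cohort fast to simulate. Real WGS
  callsets are far denser; the detector only gets easier there.
* **Dropout never removes both callers' support for a true carrier.** A
  variant missed by every caller is simply absent from the call set — that
  is a sensitivity problem of the upstream callers, not of aggregation,
  and modelling it would make "recover every planted variant" an
  impossible contract. One caller per carrier is the guaranteed minimum;
  which one survives is random.
* **Jitter is Normal, rounded to integer bp, sd 20 bp** — enough to
  exercise the 80% RO tolerance without encoding any specific caller's
  error model; no public breakpoint-discrepancy statistics exist for the
  emulated callers, so this is a configurable assumption, not an estimate.
* **Mosaic SVs appear only in parents** (the one pattern of clinical
  interest here: recurrence-risk assessment), with the proband fully
  heterozygous.
* **REF/ALT are placeholder nucleotides** and no reads are simulated; the
  screen consumes genotypes, intervals and depth summaries, so sequence
  content would add nothing the pipeline reads.

What passing on this cohort does **not** show: robustness to caller false
positives with systematic biases, to pedigree errors, to population
structure in allele frequencies, or to the long tail of real SV geometry
(nested, multi-allelic, translocated). The generator is a contract for the
pipeline's logic, not a WGS emulator.

## Problem sizes in the test suite

The end-to-end acceptance property screens the default cohort — 200 trio
families, 30 background SV clusters, 10 planted cases covering all four
planted kinds — across 20 seeds and requires the planted second hit to
rank first with correct phase (TRANS) or zygosity path
(HOMOZYGOUS_IN_ROH) in 100% of planted cases, with the false-positive rate
among unplanted families reported and bounded at 10%. Clustering is
verified against the brute-force oracle on 500 random instances of up to
50 calls; the mosaic estimator on 1,000 replicates per planted fraction;
ROH recovery on 100 seeds of the focused site-level generator
(`simulate_roh_sites()`), which reproduces the cohort's marker spacing,
flank heterozygosity and contamination rate — the full-cohort ROH path is
covered by the end-to-end property, whose two planted ROH cases must be
recovered from cohort genotypes every seed.

## A small worked example

```{r example}
cfg <- sim_config(
  n_families = 120, n_planted_cases = 4,
  planted_kinds = c("second_hit_SV", "second_hit_intronic_SNV",
                    "homozygous_in_ROH", "mosaic_parent_SV"),
  seed = 42)
cohort <- simulate_cohort(cfg)

clusters <- cluster_sv_calls(cohort$sv_calls) |>
  cohort_frequency(n_participants = nrow(cohort$pedigree))

screen <- screen_cohort(cohort$cases, cohort$genes, clusters,
                        cohort$variants, cohort$gt, cohort$pedigree,
                        cohort$depth)
glance(screen)
tidy(screen) |>
  filter(rank == 1) |>
  select(case_id, candidate_type, zygosity_path, phase, notes)
```

## Known limitations

* Breakend/translocation records are not parsed; complex SVs appear only
  through their simple-interval footprints.
* Cohort frequency is carrier-based; allele-count frequencies and
  stratified (sub-population) frequencies are out of scope.
* Phasing is genotype-only; read-backed or population phasing would
  resolve the `AMBIGUOUS` cases this package reports as unknown.
* No confidence intervals on the mosaic fraction.
* Solved/unsolved adjudication is a clinical judgement; the report carries
  evidence, not verdicts.
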