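---
title: "Designing transgene regulator siRNAs: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing transgene regulator siRNAs: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(trsirna)
```

## The problem

An siRNA used to regulate a vector-delivered transgene must satisfy an
unusual design goal: instead of maximising complementarity to a chosen
endogenous target, it must *minimise* complementarity to **every**
transcript in the host (and in the preclinical species used on the path to
the clinic), because its intended target is an artificial site that will be
cloned into the transgene's 3'UTR. Two failure modes matter:

* **Seed-mediated repression.** Guide positions 2–8 behave like a microRNA
  seed; 3'UTR sites complementary to them (the canonical 8mer, 7mer-m8 and
  7mer-A1 site classes) can recruit RISC and repress host genes even with
  extensive 3' mismatches.
* **Near-full-length complementarity.** A transcript window pairing well
  along the whole guide can be sliced directly.

The cascade attacks both: seed-level filters first (they prune the space
fastest), then full-length alignment screening of extended candidates.

## Stage-by-stage model

### Enumeration and seed exclusion

All `4^10` decamers — candidate guide positions 1–10, which contain the
entire seed — are enumerated (`enumerate_decamers()`). Any decamer whose
positions 2–7 equal the seed of a supplied mature miRNA is removed
(`filter_mirna_seeds()`): a guide sharing a miRNA seed would inherit that
miRNA's entire target repertoire. Seed comparison is exact string equality
after U→T normalisation; no wobble pairing is modelled, because seed
recognition in the canonical site model is Watson–Crick. Which species'
matures to supply is a property of the input FASTA, keeping the stage
database-version independent.

### Quiescence

Each surviving decamer is annotated with a *quiescence score*: a prediction
of how little off-target silencing it will cause, with **lower = more
quiescent**, and the lowest quartile is retained. Proprietary or published
off-target predictors can be plugged in through the scorer slot of
`pipeline_config()` (any deterministic `f(decamers, utrs) -> numeric` with
that orientation). The package default, `score_quiescence_surrogate()`, is
deliberately transparent: the number of genes whose 3'UTR contains at least
one occurrence of the seed-complementary 7-mer `revcomp(guide[2..8])`. This
is the simplest quantity that is monotone in the mechanism the filter
exists to control (seed-site abundance), and it is exactly reproducible by
a reader. The orientation (lower = safer) is this package's reading of the
filter's purpose; scorers with a different scale can be substituted without
touching the pipeline.

### Heptamer frequency over collapsed genes

The frequency filter asks how often the guide's seed-complementary heptamer
occurs in the reference transcriptome. Counting raw transcripts would count
a shared exon once per isoform, overweighting genes with many isoforms, so
isoforms of each gene are first collapsed (`collapse_gene()`): progressive
global multiple alignment, longest isoform first, each subsequent isoform
aligned to the running consensus with match +1, mismatch −1, gap −2, then
one base per column — the majority among non-gap characters, ties resolved
toward the earliest-added isoform. Columns covered by a single isoform keep
that isoform's base, so isoform-specific regions are preserved verbatim.
These alignment parameters are a package choice (no standard exists for
this step); any reasonable scoring preserves the intent, which is to count
shared exons once. All overlapping 7-mer windows of the collapsed sequences
are tabulated (`heptamer_table()`), giving a total of
`sum over genes of max(0, length − 6)` windows.

Two deliberately open choices, both settable:

* **Orientation.** The frequency is computed by default for the
  seed-*complementary* heptamer counted on transcript sense sequences — the
  actual mRNA site a loaded guide engages (TargetScan convention) —
  because the design goal is minimising target sites. `orientation =
  "guide"` counts the guide's own heptamer instead.
* **Decile reference.** The decile threshold is computed over the surviving
  decamers' annotated frequencies, not over the full heptamer distribution;
  the filter is a ranking among live candidates.

### Quantile filters and ties

Both the quartile and decile filters use the tie-inclusive nearest-rank
rule (`nearest_rank_retain()`): with `n` records the threshold is the
`ceiling(fraction * n)`-th smallest score and everything `<=` threshold is
kept. Surrogate scores and heptamer counts are small integers with heavy
ties, so retained fractions routinely exceed the nominal fraction — that is
the intended behaviour of a threshold filter on discrete scores (discarding
records that tie with retained ones would make the outcome depend on input
order). The filters are monotone: lowering a record's score can never evict
it.

### Match counting and ranking

Exact occurrences of `revcomp(decamer)` in transcript sense sequences are
counted per species, overlapping occurrences included, every isoform
counted (`count_complementary_matches()`). For full-length, ungapped,
100%-identity matches, exact substring counting is mathematically identical
to a short-read aligner run with gaps and mismatches disabled, so the count
is implemented directly on the sequences. Decamers are then sorted
ascending on total matches, quiescence, and reference seed frequency
(`rank_decamers()`), with residual ties broken lexicographically so the
ranking is reproducible.

### Extension and the alignment profile

Each ranked decamer is extended with `n_extensions` uniform random 13-mers
(duplicates permitted) into 23-mer candidates. A candidate is scored
against a transcript window by the position-weighted ungapped penalty

| guide positions | penalty per mismatch |
|---|---|
| 2–9 | 2.8 |
| 10–11 | 1.2 |
| 12–19 | 1.0 |
| 1, 20–23 | 0.0 |

(maximum 32.8), pairing antiparallel: guide position `p` against window
position `24 − p`. The *alignment profile* of a candidate is the **minimum**
penalty over all windows of all transcripts of all species — the single
best potential off-target site anywhere. This scalar-minimum reading is a
design choice: the quantity being minimised by the whole cascade is the
risk from a guide's worst-case site, and a per-species vector of minima is
emitted alongside for inspection. `select_worst_aligned()` keeps the `k`
candidates with the *largest* profiles; ties are broken by fewer windows
attaining the minimum (fewer equally-dangerous sites), then
lexicographically. If a reference offers no length-23 window at all the
profile is `+Inf`: such a candidate has no possible full-length off-target
and sorts as maximally safe.

The final ranking (`final_rank()`) is descending profile, then ascending
parent-decamer quiescence, then sequence. How many finalists to take
forward is left to the user — the full ranked table is emitted.

### Duplex and reporters

`make_duplex()` applies the therapeutic duplex convention: 21-nt sense
strand = `revcomp(antisense[1..21])`, leaving a 2-nt 3' overhang on the
guide. `build_reporter_insert()` constructs the validation inserts: the
on-target reporter carries one site fully complementary to the 23-mer
antisense; the off-target reporters carry one or four sites complementary
to antisense positions 2–9, tandem sites separated by the 19-nt spacer
`TAATATTACATAAATAAAA` (89 nt total for four sites). Restriction-site
flanks are not appended by default — cloning context is vector-specific —
but `flank5`/`flank3` wrap the insert when needed.

## Numerical choices

* **Integer penalty arithmetic.** Window penalties are sums of values like
  2.8 and 1.2; accumulating them as doubles would make exact tie detection
  (needed for the window-count tie-break) unreliable. The C++ scan works in
  integer units of 1e−4, so sums and equality comparisons are exact; the
  public API still takes and returns the natural scale.
* **Prefix-factored scanning.** All candidates from one decamer share
  positions 1–10, which carry the heaviest penalties. The batch scan
  computes each window's prefix penalty once, sorts windows by it, and
  stops scanning a candidate as soon as the prefix penalty alone exceeds
  its current best total — windows are visited in an order that makes the
  bound tight. The generic early-exit scan and the batch scan are
  cross-checked against each other and against an R brute-force oracle in
  the test suite.
* **Deterministic sorts.** All ranking sorts use radix ordering (C-locale
  byte order for sequences), so results do not depend on the session
  locale.
* **Seeding.** Every stochastic step (synthetic data, decamer subsampling,
  extension) derives its seed from a single configured `rng_seed`;
  per-decamer extension seeds are derived arithmetically so that resuming
  from a checkpoint reproduces downstream outputs byte-identically.
* **Degenerate inputs.** Empty miRNA sets make the seed filter vacuous;
  empty score vectors return empty retentions; genes with one isoform
  collapse to themselves; transcripts shorter than the window contribute
  nothing to counts or profiles.

## The synthetic study

`generate_study()` emulates the structure the cascade assumes, not real
genomes: four species (labelled human, mouse, rat, cyno — the species set
relevant to a clinical programme), 50 genes per species, 1–4 isoforms per
gene spliced from shared exon blocks of 100–300 nt, a 150–300 nt terminal
block recorded as the 3'UTR, uniform base composition, and 500 mature
miRNAs of 19–24 nt. Shared exon blocks give the collapsing stage real work;
the terminal-block UTR makes the "UTR is a suffix of an isoform" invariant
true by construction. These defaults were chosen once as a realistic
desk-scale stand-in and are not tuned to any expected output.

What the generator does **not** emulate — and therefore what passing tests
do not show about real data: real k-mer composition bias (CpG depletion,
AT-rich UTRs), real isoform complexity and paralogy, real miRNA seed usage
(which is far from uniform), expression levels, and genome coordinates.
Funnel *percentages* on synthetic data will not match runs against RefSeq
transcriptomes with miRBase matures; the structural behaviour (monotone
funnel, tie-inclusive quantiles, oracle-exact scoring) is what is
validated.

## Problem sizes used in the checks

The unit suite runs the filters and scanners against brute-force oracles on
fixtures of tens of transcripts and hundreds of random cases. The
end-to-end check runs the complete cascade at 4 species × 50 genes with a
seeded 2,000-decamer subsample, 1,000 extensions per survivor and `k = 10`
— about half a minute on one CPU — and the acceptance script uses a
500-decamer subsample with 100 extensions. Full enumeration (no subsample)
is the default for real runs; the enumeration itself takes seconds, and the
stage cost is dominated by extension scanning, which scales linearly in
survivors × extensions × total transcript length.

## Known limitations

* The quiescence surrogate is intentionally simple; it captures seed-site
  abundance but no pairing thermodynamics, conservation, or expression
  weighting. The scorer slot exists precisely so a stronger model can be
  substituted.
* Only perfect-complementarity decamer matches are counted at stage 5;
  near-matches are handled later, at the 23-mer stage, by the weighted
  scan.
* Site annotation implements the three canonical classes only; 6-mer and
  non-canonical (bulged, 3'-supplementary) sites are out of scope.
* On-target efficacy (thermodynamic asymmetry, position-specific base
  preferences) is not modelled: the cascade optimises specificity, and
  candidates would still be screened experimentally for potency.
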