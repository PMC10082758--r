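# trsirna

Design of **transgene regulator siRNAs (TR-siRNAs)**: guide strands that
silence an artificial target site carried on a vector-delivered transgene
(for example in the 3'UTR of an AAV-expressed therapeutic) while having as
little complementarity as possible to any endogenous transcript in human or
in the standard preclinical species. Such guides let RNAi act as a dosage
rheostat for gene therapy — knock the transgene down with the siRNA, recover
it with a complementary antidote oligonucleotide — without microRNA-like
off-target silencing of host genes.

The package is aimed at computational biologists designing or auditing such
sequences. It implements the complete design cascade as tested, reusable R
functions, annotates canonical seed-matched 3'UTR sites, constructs the
dual-luciferase reporter inserts used to validate candidates, and ships a
seeded synthetic-transcriptome generator so the whole cascade can be
exercised end to end without any external databases.

## The design cascade

Guide positions are numbered 1–23 from the antisense 5' end; the *seed* is
positions 2–7 (6-mer) or 2–8 (heptamer), the dominant determinant of
microRNA-like off-target binding.

1. **Enumeration** — all 4^10 = 1,048,576 decamers, representing the first
   10 bases of a candidate guide.
2. **miRNA seed exclusion** — decamers whose seed (positions 2–7) equals the
   seed of any supplied mature miRNA are removed, so the guide cannot
   phenocopy an endogenous miRNA.
3. **Quiescence quartile** — each decamer gets a quiescence score (predicted
   off-target silencing propensity; lower = safer) from a pluggable scorer;
   the lowest (most quiescent) quartile is retained. The default scorer
   counts genes whose 3'UTR contains the seed-complementary 7-mer
   `revcomp(guide[2..8])`.
4. **Heptamer-frequency decile** — the frequency of that seed-complementary
   heptamer is tabulated over the reference transcriptome with isoforms of
   each gene collapsed by progressive global alignment (shared exons counted
   once); decamers in the lowest decile are retained.
5. **Complementary-match ranking** — exact occurrences of
   `revcomp(decamer)` are counted in every species' transcripts; decamers
   sort ascending on (total matches, quiescence, reference seed frequency).
6. **Extension and profile scoring** — each surviving decamer is extended
   with random 13-mers into 23-mer candidates. Every candidate is scored
   against every length-23 transcript window with a position-weighted
   ungapped mismatch penalty (positions 2–9: 2.8; 10–11: 1.2; 12–19: 1.0;
   1 and 20–23: 0; maximum 32.8). The candidate's *alignment profile* is the
   minimum penalty over all windows — its single best potential off-target
   site — and the candidates with the **largest** profiles (most poorly
   aligned anywhere) are retained and ranked.

The final duplex follows the therapeutic convention: 23-nt antisense strand,
21-nt sense strand equal to `revcomp(antisense[1..21])`, leaving a 2-nt 3'
overhang on the guide.

## Worked example

```r
library(trsirna)

study <- generate_study(species = c("human", "mouse"),
                        params = synthetic_params(n_genes = 20),
                        n_mirnas = 200, rng_seed = 11)
cfg <- pipeline_config(study$species, study$mirnas,
                       max_decamers = 500, n_extensions = 200,
                       k_worst = 5, rng_seed = 11)
run <- run_pipeline(cfg)
run
```

```
<design_run> scorer: seed_complement_gene_count | seed: 11

Funnel:
               stage n_in n_out
           enumerate  500   500
   mirna_seed_filter  500   484
 quiescence_quartile  484   376
     heptamer_decile  376   158
          match_rank  158   158
       extend_select  158   790

Top candidates:
 rank               antisense                 sense profile quiescence
    1 GGTTTACACTAAAGTATGTGTCC ACACATACTTTAGTGTAAACC    10.6          0
    2 GGTTTACACTGCAGACCCGCCCC GGCGGGTCTGCAGTGTAAACC    10.6          0
```

Reading the funnel: 500 sampled decamers enter; 16 share a seed with one of
the 200 synthetic miRNAs and are removed; the quartile and decile filters are
tie-inclusive nearest-rank quantiles, so 376 (ties at quiescence 0) and then
158 survive; each survivor is extended into 200 random 23-mers of which the 5
with the largest alignment profiles are kept (790 = 158 × 5). The top
candidate's best match anywhere in the two transcriptomes still carries a
10.6 mismatch penalty (out of 32.8), with quiescence 0 — no gene's 3'UTR
contains its seed complement.

```r
top <- run$candidates$antisense[1]
make_duplex(top)
#> <sirna_duplex>
#>  antisense 5'-GGTTTACACTAAAGTATGTGTCC-3' (23 nt)
#>  sense     5'-ACACATACTTTAGTGTAAACC-3' (21 nt; 2-nt guide 3' overhang)

build_reporter_insert(top, "seed_4x")
#> <reporter_insert> kind: seed_4x | 89 nt
#>  GTGTAAACTAATATTACATAAATAAAAGTGTAAAC...  (4 seed sites, 19-nt spacers)

head(classify_genes(top, utr_seqs(study$species$human)), 3)
#>       gene_id n_8mer n_7mer_m8 n_7mer_a1 n_sites has_site
#> 1 human_g0001      0         0         0       0    FALSE
#> 2 human_g0002      0         0         0       0    FALSE
#> 3 human_g0003      0         0         0       0    FALSE
```

`classify_genes()` / `annotate_utr_sites()` report canonical seed-matched
sites (8mer, 7mer-m8, 7mer-A1, with 8mer > 7mer-m8 > 7mer-A1 precedence) per
gene, ready to join to a differential-expression table.

A thin command-line front end with verbs `simulate`, `design`,
`annotate-sites` and `build-reporter` is installed under
`inst/scripts/trsirna`.

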