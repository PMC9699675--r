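# cephamir

Analyses of the post-transcriptional regulatory landscape of cephalopod
(octopus) transcriptomes, built around four questions:

1. **Are miRNA target sites conserved between octopus species, and is
   conservation higher when the miRNA and its target are coexpressed?**
   cephamir derives miRNA response elements (MREs) — 8mer sites: the
   Watson–Crick complement of miRNA seed positions 2–8 written 5'→3' on
   the mRNA plus a trailing adenosine — scans orthologous 3'UTR pairs,
   and scores each occurrence as conserved only when the identical
   octamer sits at the homologous (gap-free, same alignment columns)
   position of the ortholog. Sites are conditioned on codetection
   (miRNA ≥ 100 CPM and mRNA ≥ 10 CPM in at least one shared tissue),
   scored per arm as matches/(matches+mismatches), standardised to Z
   scores against dinucleotide-preserving shuffled controls, and
   compared with Mann–Whitney U tests under Bonferroni correction.
2. **How much A-to-I editing do transcripts and target sites carry?**
   Editing sites are reference-A positions with > 10 reads, ≥ 3 of them
   G, not present in a DNA-variant exclusion set; the per-feature
   editing index is ΣG/Σ(A+G) over reference-A positions; conserved
   MREs are intersected with called sites under a coverage filter, and
   "one-off MREs" (8-mers one editing event away from an MRE) are
   scored against shuffled and G-to-A substitution controls.
3. **How often are exons skipped and introns retained?** From exon and
   intron junction triplets (42+42 nt junction sequences), with
   effective mappability m = number of contained 50-mers unique across
   the junction set (max 35) and counts adjusted by 35/m:
   `rES = N_E1E3 / ((N_E1E2+N_E2E3)/2 + N_E1E3)` and
   `rIR = mean(N_E1I,N_IE2) / (mean(N_E1I,N_IE2) + N_E1E2)`,
   plus a subsampling protocol (1000 triplets, 25,000 reads, 100
   repetitions) that equalises depth before comparing tissues.
4. **Where do transcripts end?** Long-read 3'-end tags are clustered
   (merge < 20 bp, then representatives < 40 nt), filtered by linkage
   to an upstream stop codon, and assigned polyadenylation-signal
   hexamers (AATAAA-headed motif table, dataset-abundance tie-break).

A synthetic-data generator with known planted parameters (ortholog UTR
pairs with planted MREs and a conservation differential between
codetected and non-codetected pairs, CPM matrices, editing pileups,
junction counts, clustered tags) makes the whole pipeline testable
without external data. See the methods vignette
(`vignettes/cephamir-methods.Rmd`) for the models, defaults and design
decisions.

## Worked example

```r
library(cephamir)

deriveMre("UGAGGUAGUAGGUUGUAUAGUU")   # let-7
#> [1] "CTACCTCA"

cfg <- SyntheticConfig(nGenes = 250, nMirnas = 6, rngSeed = 1)
res <- runConservationAnalysis(cfg)

round(res$armRates, 3)
#>    codetected noncodetected
#>         0.602         0.414
res$groupTests
#>        groupA         groupB  U       pRaw pBonferroni label
#> 1 coexpressed noncoexpressed 33 0.01515152  0.01515152     *
head(res$scores, 3)
#>         mirna nSites scoreCodetected scoreNoncodetected
#> 1 syn-mir-001     86       0.5000000          0.4583333
#> 2 syn-mir-002     87       0.4285714          0.4444444
#> 3 syn-mir-003     86       0.7368421          0.3333333
```

The generator planted site conservation 0.6 for codetected pairs and
0.4 for non-codetected pairs; the pooled arm rates (0.602, 0.414)
recover them, and the per-miRNA score contrast is significant already at
this small scale (at the scale the test suite runs — about 2200 sites
per arm — the contrast is `***`). `runAll(cfg, outdir)` additionally
runs the editing, splicing and 3'-end stages and writes TSV tables plus
a JSON report, every file carrying the seed and a config hash.

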