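---
title: "Methods: miRNA target-site conservation, editing, splicing and 3' ends in cephamir"
author: "cephamir maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA target-site conservation, editing, splicing and 3' ends in cephamir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cephamir)
```

# Scope

cephamir implements the computational core of a post-transcriptional
regulation analysis for cephalopod (octopus) transcriptomes: conservation
of miRNA response elements (MREs) across orthologous 3'UTRs conditioned on
miRNA–mRNA codetection; A-to-I editing site calling, editing indices and
the editing/MRE intersection; mappability-adjusted exon-skipping and
intron-retention rates with a cross-tissue subsampling protocol; and
clustering of long-read 3'-end tags into cleavage sites with
polyadenylation-signal assignment. A synthetic-data generator with known
planted parameters makes every stage testable without any external data.

# The MRE conservation model

## Site definition

A miRNA recognises targets primarily through its seed, nucleotides 2–8 of
the mature sequence. The strongest canonical site class is the 8mer: the
Watson–Crick complement of the seed written 5'→3' on the mRNA, followed by
an adenosine across from miRNA position 1. `deriveMre()` therefore returns
`revcomp(seed) + "A"`; for let-7 (`UGAGGUAGUAGGUUGUAUAGUU`) this is
`CTACCTCA`. The trailing adenosine is a positional feature recognised by
Argonaute, not a base-pairing one, which is why it is pinned to `A`
regardless of miRNA position 1, and why the one-off enumeration (below)
never substitutes it. Mature miRNAs are held in the RNA alphabet and UTRs
in DNA, matching the conventions of miRNA databases versus genome FASTA;
converters are provided.

## Conservation of an occurrence

Orthologous 3'UTR pairs are aligned globally. An occurrence of an octamer
in the reference UTR counts as *conserved* only when its eight positions
map to eight consecutive, gap-free alignment columns whose ortholog row
spells exactly the same octamer. "Same position" is thus defined by the
alignment columns — only the alignment defines positional homology — and
any indel inside the window breaks the site even when the flanks match.
Scanning is exact and sense-strand only (MREs act on the mRNA), reports
overlapping occurrences, and windows containing `N` never match (assembly
gaps are treated conservatively as non-sites). Occurrences truncated by
the UTR end cannot form a full window and are therefore never counted.

Per-octamer rates are the fraction of conserved occurrences, with every
occurrence evaluated independently (a gene may contribute several).
Octamers seen fewer than 10 times across the alignment set are flagged
`excluded`: a rate estimated from a handful of sites is too noisy to
compare across octamers.

## Alignment engine

`alignUtrPair()` is a deterministic Needleman–Wunsch–Gotoh global aligner
(compiled code) with affine gaps: match +1, mismatch −1, gap open −10, gap
extension −0.5, a gap of length $k$ costing $\mathrm{open} + k\,
\mathrm{ext}$. Traceback ties are broken diagonal, then gap-in-ortholog,
then gap-in-reference, so identical inputs always produce the identical
alignment. The defaults favour few, long gaps, appropriate for closely
related species. Externally produced alignments (e.g. from a standard
multiple-alignment tool) can be supplied as aligned FASTA through
`readAlignedFasta()` and used everywhere an internal alignment can; the
test suite cross-checks the engine's scores against an independent
pairwise-alignment implementation.

## Codetection and scores

A miRNA and an mRNA are *codetected* when at least one tissue carries the
miRNA at ≥ 100 CPM and the mRNA at ≥ 10 CPM simultaneously. Thresholds are
inclusive; CPM is consumed as given (an auxiliary `cpmFromCounts()` exists
for raw counts). Sites of one miRNA are partitioned into the 2×2
codetection-by-conservation table, and each arm's conservation score is
matches/(matches+mismatches); empty arms yield `NA`, never 0. Because the
per-miRNA table reports both sites and distinct host genes,
`conservationScores()` can score either level; the site level is the
default, and both are available where duplicated sites within a gene might
matter.

For display, per-miRNA scores and control rates are standardised jointly:
`zscorePanel()` subtracts the mean and divides by the SD of all defined
rates in the panel. Treating each plotted panel (MRE scores plus their
shuffled controls) as one reference population centres the control
distribution near zero; the panel membership is explicit in the API, so
other choices are one argument away.

Group contrasts (coexpressed vs non-coexpressed vs controls) use the
two-sided Mann–Whitney U test with Bonferroni correction over the pairs
actually tested, labelled n.s. (p > 0.05), `*`, `**`, `***` (p < 0.001) on
the corrected value.

## Controls

Control octamers preserve the source MRE's dinucleotide multiset: valid
controls are exactly the Euler paths of the de Bruijn multigraph whose
edges are the seven observed dinucleotides. For 8-mers this feasible set
is small enough to enumerate exhaustively, so `dinucleotideShuffle()`
enumerates it, keeps permutations that end in A (matching the trailing A
of MREs), removes the source and any annotated MRE, and samples without
replacement. A homopolymer has no valid permutation and returns an empty
set with a warning rather than a silent fallback.

One-off MREs are 8-mers one A-to-I event away from an MRE: each G of the
MRE, replaced by A, gives one precursor. The control direction replaces
one non-terminal A with G. Conservation of one-off sets against shuffled
and G-to-A controls is assembled by `oneOffConservationComparison()`.

# A-to-I editing

Editing sites are reference-A positions with strictly more than 10 reads
of which at least 3 are G, absent from a precomputed DNA-variant set (a
variant also present in genomic DNA is a SNP, not editing; variant calling
itself is out of scope). "More than 10" is read strictly (≥ 11) and
applied uniformly across the package. The per-feature editing index is
$\sum G / \sum (A+G)$ over reference-A positions — the coverage-weighted
mean of the per-site G fractions; C/T reads there are treated as
sequencing error and excluded from the denominator by default
(configurable). miRNA seed editing reports, per miRNA, the maximum G
proportion over covered (> 10 reads) reference-A seed positions 2–8.

For the editing/MRE intersection, only conserved MRE windows with
sufficient coverage enter the denominator, so that an absence of observed
editing cannot be an artefact of missing data. The source analysis says
"total RNA-seq coverage of more than 10 mapping reads" per 8-mer without
fixing per-position minimum versus mean versus window reads; the mean over
the eight positions is the default and the minimum is available behind the
`summarise` flag.

# Splicing rates

Exon triplets (E1, E2, E3) give three junctions — E1E2, E2E3 and the skip
junction E1E3 — each concatenating up to 42 nt from either side; intron
triplets (E1, I, E2) give E1I, IE2 and the spliced junction E1E2.
Junctions are nonredundant by coordinates. Effective mappability $m$ of a
junction is the number of its contained 50-mers that occur exactly once
across the whole junction set — a deterministic exact-match emulation of
mapping 50-mers back with a unique-hit requirement; the maximum for an
84 nt junction is $84-50+1 = 35$. Read counts are adjusted by $35/m$, and
triplets with any $m < 20$ are excluded. The rates on adjusted counts are

$$rES = \frac{N_{E1E3}}{(N_{E1E2}+N_{E2E3})/2 + N_{E1E3}}, \qquad
  rIR = \frac{\bar N_I}{\bar N_I + N_{E1E2}},\;
  \bar N_I = \frac{N_{E1I}+N_{IE2}}{2},$$

the only bracketing under which both are proportions in [0, 1]. The
eligibility rule for cross-tissue comparison requires at least five raw
reads on the two major junctions (E1E2 + E2E3 for ES, E1I + IE2 for IR)
plus the mappability filter.

The subsampling protocol equalises depth and triplet sets before
comparing tissues: per repetition, 1000 eligible triplets are drawn
without replacement and exactly 25,000 reads are allocated multinomially
over their junction counts (reads are resampled with replacement; the
source protocol does not state this, and the multinomial is the standard
choice), rates are computed and averaged, and the repetition is repeated
100 times per tissue. One caveat discovered during design: when two
tissues are generated *independently* with identical planted parameters,
their realised tissue-level mean rates differ by an amount comparable to
the between-repetition spread, and a rank test over 2×100 repetition
means will detect that generation noise. Exchangeability — and hence a
null-distributed comparison — holds when the same tissue data are
subsampled twice, which is what the test suite exercises; with
independent realisations the protocol is a depth-normalisation device,
not a null-preserving one.

# 3'-end tag clustering

Cleavage-site clustering is two-pass: tags strictly closer than 20 bp are
merged by single linkage and their counts assigned to the most implicated
site — the member with the highest count, ties broken toward the 3'-most
position on the tag's strand so output is deterministic; then clusters
whose representatives are strictly closer than 40 nt are merged, keeping
the higher-count representative. Distances in pass 2 are measured between
representatives (cluster edges would be an alternative; representatives
are what downstream PAS assignment uses). Single-linkage chains can exceed
20 bp total span — the rule is pairwise. Counts are conserved exactly
through both passes. Cluster retention requires a link to an upstream
gene: continuous short-read coverage ≥ 5 from the representative to the
stop codon, or a member read overlapping the stop codon.

PAS assignment scans the 50 nt upstream of the cleavage site for hexamers
from a configurable table (default: AATAAA, ATTAAA and ten further
single-substitution metazoan variants — the canonical list is not fixed in
the literature, so the table is data, not code); among multiple hits the
motif more abundant across the whole dataset wins, with table order
breaking ties.

# The synthetic-data generator

The generator is first-class, tested code whose defaults are the study
conditions of the analyses above:

* UTR lengths: log-normal with median 350 nt (sdlog 0.4), matching the
  median 3'UTR length scale of octopus transcriptomes; floored at 30 nt.
* Inter-species divergence: substitution rate 0.05/site, indel rate
  0.01/site, single-nucleotide indels — a plausible closely-related-pair
  regime that leaves background 8-mers conserved at roughly
  $0.95^8 \cdot 0.99^8 \approx 0.6$.
* Planted site conservation: 0.6 for codetected pairs, 0.4 for
  non-codetected, the effect direction expected if codetected sites are
  under selection; the inverted direction requires an explicit override.
* Codetection: each gene carries sites of one miRNA and a fair-coin
  codetection label — codetection is a property of the miRNA–gene pair,
  so all sites of a pair share it. Expression matrices realise every
  label exactly under the 100/10 CPM thresholds, for any number of
  tissues including one.
* Editing: 5% of reference-A positions edited at per-site levels drawn
  from [0.02, 0.2], coverage 50, with 5% of edited positions mirrored
  into the DNA-variant set to exercise the SNP exclusion.
* Splicing: junction probabilities are inverted from the planted rate
  ($s = r/(2-r)$ for ES, $q = 2r/(1+r)$ for IR) so the expected computed
  rate equals the planted one; junction sequences are random, hence
  effectively always uniquely mappable.

Mutations are planted outside site windows (conservation is defined on
gap-free aligned octamers, so a "conserved" site must survive verbatim;
a non-conserved site receives one forced substitution inside the window).
Consequently the realised conservation of planted sites is exactly
Bernoulli at the planted rate, and parameter recovery is a clean binomial
check. Chance (non-planted) occurrences of MRE octamers arise at the
background rate $4^{-8}$ per window and dilute recovered rates by about a
percent at the scales used — well inside the three-standard-error
tolerance the tests assert.

Everything is deterministic given the configuration and its seed: each
generator derives its stream from the config seed plus a fixed offset, so
stages can be regenerated independently and whole runs are byte-identical.

What the generator does *not* emulate: raw reads, sequencing error,
aligner artefacts, expression correlation structure across tissues,
phylogenetic rate variation along the UTR, or selection gradients within
sites. Passing tests therefore demonstrate that the statistics recover
what was planted under the stated noise model — not that the biological
effect sizes of real octopus data would be reproduced.

# Numerical and interface choices

* 0-based, half-open coordinates for all sequence positions; 1-based
  inclusive coordinates only in exon annotations (the GFF convention).
* Undefined quantities (empty score arms, zero denominators, features
  without covered positions) are `NA` markers, never silently 0.
* Strict thresholds: coverage "more than 10" is ≥ 11 everywhere.
* `conservationRates()` deduplicates octamers by default; identical MREs
  from paralogous miRNAs can be kept as repeated entries with
  `deduplicate = FALSE`.
* Problem sizes in the test suite: parameter recovery uses 1100 genes ×
  4 sites (≈ 2200 sites per codetection arm) over 20 seeds; the
  subsampling null uses 1200 triplets, 1000 sampled, 25,000 reads, 100
  repetitions. These sizes put three-standard-error checks comfortably
  above the noise floor while keeping a full run in the minutes range on
  one core.

# Worked example

```{r example}
cfg <- SyntheticConfig(nGenes = 250, nMirnas = 6, rngSeed = 1)
res <- runConservationAnalysis(cfg)
res$armRates
res$groupTests
head(res$scores)
```

The pooled arm rates recover the planted 0.6/0.4, and the coexpressed
arm separates from the non-coexpressed one.

# Known limitations

* The aligner is pairwise-global only; very diverged or
  rearrangement-containing UTR pairs should be aligned externally and
  supplied as aligned FASTA.
* Splicing triplets assume plus-strand, non-overlapping exon models;
  strandedness of gene models is the caller's responsibility.
* The editing module consumes pileups and a variant exclusion set; it
  does not call variants from DNA-seq nor model mapping bias.
* Mann–Whitney p-values come from the standard R implementation
  (exact for small untied samples, normal approximation otherwise).
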