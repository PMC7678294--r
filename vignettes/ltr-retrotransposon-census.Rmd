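---
title: "Counting LTR retrotransposons: structural detection, read censuses and dilution-standard quantification"
author: "ltrcensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting LTR retrotransposons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltrcensus)
library(GenomicRanges)
```

## The problem

LTR retrotransposons are class I transposable elements that copy themselves
through an RNA intermediate. A full-length element is a pair of long
terminal repeats (LTRs) flanking an internal coding region (gag and pol:
protease, reverse transcriptase, RNase H, integrase). The two LTRs are
identical at the moment of insertion and diverge afterwards by random
mutation, and integration duplicates a few bases of host sequence on either
side (the target-site duplication, TSD). Unequal recombination between the
two LTRs of one element later deletes the internal region together with one
repeat, leaving a solo LTR. These three facts drive everything this package
computes: near-identical repeat pairs at element-scale separation are the
structural signature used for detection; the LTR:CDS copy-number ratio
separates populations of intact elements (ratio near 2) from populations
dominated by solo LTRs (ratio well above 2); and the TSD pins element
boundaries to base precision.

In large plant genomes — the motivating system is the *Phalaenopsis*
(moth orchid) genus, with genome sizes from 1.5 to 7 Gbp — such elements
reach tens of thousands of copies and a substantial fraction of the genome.
Copy numbers of high-copy families cannot be read off an assembly, because
near-identical copies collapse during assembly. The package therefore
implements two assembly-independent estimators alongside structural
annotation:

1. **Read census.** The fraction of unassembled shotgun reads attributable
   to a family estimates its genome proportion; multiplied by genome size
   it gives bp per genome, divided by element length, copies per genome.
2. **Slot-blot dilution calculus.** A plasmid standard with a known mass of
   probe target is serially diluted next to genomic DNA; the pair of slots
   with equal hybridization intensity ties a known target mass to a known
   mass of genomic DNA, giving ng of target per microgram of genomic DNA
   and, through genome size, copies per genome.

Every stage is testable offline against a synthetic-genome module that
plants element families with an exact coordinate ledger.

## The synthetic-data generator

`genBackground()` draws i.i.d. bases at a chosen GC content.
`plantFamily()` builds a random family template (LTR + internal + LTR; the
default geometry, 707 bp LTRs and a 12,671 bp total, matches a canonical
high-copy orchid Gypsy-like element), then inserts mutated copies at
uniform positions, each flanked by an exact TSD (default 5 bp; insertion
grows the genome, so planted intervals never overlap). Copies are mutated
independently at a per-site substitution rate, so the two LTRs of one copy
have expected pairwise identity $(1-d)^2$. Substitutions-only is the
default because it keeps the coordinate ledger exact; single-base indels
are available behind `indel_rate`. `simulateReads()` draws fixed-length
reads uniformly from both strands with i.i.d. substitution errors —
deliberately simpler than real 454/Illumina error profiles, which is the
main reason passing recovery tests here do not certify performance on real
reads (no homopolymer errors, no quality gradients, no insert-size
structure). `simulateSlotBlot()` makes intensities proportional to loaded
target mass down a geometric dilution ladder with multiplicative log-normal
noise of chosen coefficient of variation; blot physics beyond
proportionality (saturation, background) is not modelled.

```{r generator}
g <- genBackground(50000, seed = 11)
spec <- familySpec("rt1", ltr_len = 707, internal_len = 11257,
                   n_full = 1, divergence = 0.02)
planted <- plantFamily(g, spec, seed = 12)
planted$truth
```

## Structural detection

`findLTRElements()` re-implements, at desk scale, the role a dedicated LTR
finder plays in a genome project. The contract: (1) index all k-words
(default k = 13); (2) collect word-match pairs whose separation is
compatible with the element-length window; (3) group pairs into diagonal
bands (drift tolerance 20 bp) and chain them; (4) extend each chain with an
X-drop scan into two maximal terminal blocks; (5) score the block pair by
Needleman–Wunsch global identity; (6) apply the length and identity
windows; (7) require and annotate an exact 4–6 bp TSD; overlapping
candidates are resolved by identity, then length, then position.

Defaults (`detectParams()`): LTR window 100–3000 bp, element window
1500–20,000 bp, minimum identity 0.80. These bracket reported plant
Gypsy/Copia geometries (LTRs of roughly 0.7–2.6 kb, elements of 8.7–16.6
kb) with margin on both sides.

Two numerical choices deserve explanation:

* **Boundary refinement.** The X-drop boundary is a max-score changepoint;
  when mutations cluster at an LTR end it genuinely stops short (a run with
  one-third mismatches is net-negative under any sensible scoring), and
  when a flank base matches by chance it overshoots. The TSD search
  therefore scores every exact 4–6 bp duplication within ±20 bp of the raw
  boundaries by a changepoint log-likelihood (positions claimed as element
  should match their partner copy at ~0.9, positions claimed as flank at
  the background 0.25, plus log 4 per exact TSD base) and snaps the element
  onto the best-supported duplication. Wide shifts are admitted only
  outward and only for 5–6 bp duplications, so chance 4-mers deep in the
  flank cannot move a correct boundary. On planted elements at divergence
  up to 0.05 this yields boundary errors of 0–2 bp in the typical case.
  One ambiguity is irreducible: when the element's own first bases happen
  to duplicate the sequence just past its end, a boundary slid by up to
  TSD-length + 1 bp carries a genuinely equal-or-better duplication and
  likelihood, and no detector can tell the two apart; occasional 6 bp
  errors at 5 bp TSDs are of this kind.
* **Strand.** A terminal-repeat pair reads the same on both strands, so a
  single forward scan covers both orientations; candidates carry strand
  `*` because orientation would require internal signals (PBS/PPT) that
  are out of scope.

A known limitation, shared with the tools this emulates: two nearby copies
of one family offer a structurally valid "chimera" (3′ LTR of one copy
paired with the 5′ LTR of the next). The exact-TSD requirement rejects
nearly all of them — a chimera's flanks are unrelated pieces of the
internal region — but a chance duplication can occasionally let one
through. The generator's `min_gap` option plants copies farther apart than
the element window when a fixture needs to exclude the case.

```{r detect}
cand <- findLTRElements(planted$genome)
as.data.frame(cand)[, c("start", "end", "width", "ltr_len", "ltr_identity", "tsd")]
```

## Family clustering and consensus

The reference workflow grouped elements by eyeballing dot plots. The
package quantifies "looks the same in a dot plot" as the shared-word
fraction (`pairwiseWordSimilarity()`, word = 12, both strands, symmetrized
by averaging), and `clusterElements()` applies single linkage at threshold
0.5: families are connected components, ordered by size. Unrelated random
sequences score below 0.01, so the graph is effectively empty between
families. The word statistic is steep in divergence: at per-copy divergence
$d$ the expected intra-family similarity is roughly $((1-d)^2)^{12}$,
which is 0.62 at $d = 0.02$ but only 0.29 at $d = 0.05$ — word-based
similarity at this threshold groups recently amplified (high-identity)
families, which is precisely the population the census targets; older,
more diverged families fall apart into singletons rather than being
wrongly merged. Raising the threshold can only refine the partition, never
merge families, which the tests assert as a property.

`buildConsensus()` builds the per-family reference by star alignment to
the longest member (pairwise global alignments via Biostrings) and
per-column majority vote, ties broken alphabetically, insertions relative
to the reference dropped. `classifySuperfamily()` applies the standard
domain-order rule: integrase downstream of reverse transcriptase is
Gypsy-like, upstream is Copia-like; missing domains give "unknown".
Domain annotations are supplied as input — translated-motif scanning
against protein databases is deliberately out of scope, so superfamily
calls are only as good as the annotations provided.

## Read census

`assignReads()` assigns a read to the element whose word set contains the
highest fraction of the read's words (best of both strands), requiring at
least half of them (k = 13, containment ≥ 0.5), ties to the smallest
element id, one element per read. The matching rule is the package's own
design: the published censuses do not state one, and this rule is simple
enough to check against an exhaustive nested-loop oracle, which the test
suite does. Fractions are reported at 3 decimals (`censusFractions()`),
with the raw value retained; `copiesFromFraction()` multiplies by genome
size and divides by element length, rounding copies half-up.

The estimator has a small, understood bias: reads overlapping an element
end by less than about `0.5 * (read_len + k)` bases fail the containment
threshold, so the effective target is shorter than the element by a few
dozen bases — under 1% for multi-kb elements at 100 bp reads. Recovery
tests at 2× coverage and 1% read error ask for copy numbers within 10% of
planted truth, comfortably above the binomial sampling error at the
problem sizes used (100 kb genomes, six planted copies, ~2000 reads).

## Slot-blot calculus

The quantification chain is exact arithmetic, implemented in five small
functions so each printed intermediate is reproducible:

* `insertMass(10, 707, 3015)` — a 10 ng plasmid carrying a 707 bp insert
  in a 3015 bp vector holds 1.9 ng of insert.
* `matchDilution()` — the plasmid/genomic exponent pair with the closest
  log intensities. In a noiseless full geometric ladder every pair along
  the matching diagonal ties exactly and the tie rule takes the smallest
  exponents; the recovered concentration is identical along the whole
  diagonal, so this degeneracy is harmless. Real blots match within their
  usable intensity range, represented here by truncating the ladder.
* `ngPerUg(1.9, 3^-2, 3^-1, 1)` — 0.63 ng of target per µg genomic DNA.
* `copiesPerGenome(0.63, 1.6e9, 707)` — 1.008 Mbp and 1426 copies.
* `interpretLtrCds()` / `foldChange()` — ratio flags with tolerance 0.25
  around the 2:1 intact-element expectation (so an observed 2.18 counts as
  "mostly full length"), solo-LTR estimate `max(LTR - 2*CDS, 0)`, and
  integer-rounded fold changes.

`slotBlotTable()` applies the chain to a panel; the bundled
`phalaenopsisSlotBlot()` panel (four species × six probes) regresses 47 of
its 48 printed cells exactly — one copy-number cell computes 1084 against
a printed 1083, a documented rounding discrepancy in the source table that
the tests assert rather than hide. The bundled read-census table has an
analogous single misprint (a fraction printing 0.000 where the counts give
0.002). Genome sizes are taken as given in bp; a pg→bp conversion is not
applied because the published pg/Gbp pairs do not follow the usual
978 Mbp/pg constant.

```{r slotblot}
cfg <- phalaenopsisSlotBlot()
tab <- slotBlotTable(cfg$ng_table, cfg$genomes)
head(tab[, c("species", "segment", "ng_per_ug", "mb_per_genome", "copies")])
interpretLtrCds(1115, 219)
```

## Insertion context

`mapConsensusHits()` maps a consensus onto an annotated genome with the
same seed–band–extend machinery as detection (defaults: blocks ≥ 100 bp at
identity ≥ 0.8, best hit per locus). `classifyInsertion()` calls each hit
exonic if it overlaps any exon by ≥ 1 bp, else intronic if fully inside a
gene span, else intergenic; exon overlap deliberately takes precedence for
boundary-straddling hits, a case the source analysis never had to define.
"Within a gene" means within the gene's genomic span; UTRs are not
modelled because gene models here are exon lists. `summarizeContexts()`
partitions hits by context and by contig class (chromosome vs unplaced
scaffold, by name pattern).

## Problem sizes and what the tests show

The test and acceptance fixtures use 40–200 kb genomes, elements of 1.6–14
kb, 20-replicate fixed-seed suites, ~2000–4000 reads per census replicate
and 200-replicate noise sweeps for the blot round trip — sizes chosen so
the full suite exercises every stage in a few minutes while keeping
binomial sampling errors several times smaller than the tolerances being
asserted. Passing them shows the algorithms are correct on data matching
the generator's assumptions (uniform composition, substitution-only
divergence, uniform reads, proportional intensities); they do not certify
recall on real genomes with nested insertions, segmental duplications,
tandem repeats or platform-specific read artifacts.

## Known limitations

* Nested and chimeric same-family configurations are resolved by a
  winner-takes-interval rule plus the TSD filter, not by a full nesting
  model.
* Orientation, PBS/PPT signals, insertion-age dating from LTR divergence
  and protein-level annotation are out of scope.
* The word-similarity threshold targets high-identity families; deeply
  diverged families fragment into singletons.
* At exactly the edge of the element-length window, 1 bp of boundary
  ambiguity (a TSD base indistinguishable from the element's first base)
  can move a true element just outside the window; fixtures therefore
  plant with margin.
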