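---
title: "Positional modelling of baculovirus 3'-end processing signals"
author: "baculoPolyA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Positional modelling of baculovirus 3'-end processing signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baculoPolyA)
```

## The problem

Baculoviruses are insect viruses with circular double-stranded DNA genomes of
roughly 88–200 kbp carrying 90–180 protein genes on both strands. Their
messenger RNAs are cleaved and polyadenylated, and the region downstream of
each gene's stop codon carries the same kind of cis-acting signal cassette
known from eukaryotic 3'-end processing: an upstream U-rich element (USE), an
optional UGUA motif recognized by cleavage factor I, the polyadenylation
signal hexamer (PAS, canonically AAUAAA, with AUUAAA as a lepidopteran
alternative), a cleavage site (CS) typically just after a CA dinucleotide, a
U/GU-rich downstream sequence element (DSE) bound by CstF, and a G-rich
auxiliary DSE. What distinguishes the viral cassette is its geometry: the
elements cluster tightly around the stop codon, in an AU-rich sequence
context, at characteristic distances from one another.

`baculoPolyA` implements this positional view of the cassette as a testable
pipeline: extract the downstream gene region of every gene, scan it for the
six element classes, assemble the hits into cassettes under an explicit
distance model, characterize the secondary-structure context of the cleavage
site, and summarize the recovered element contexts as sequence logos. A
synthetic-genome generator with planted cassettes provides ground truth for
every stage, so the pipeline is benchmarked end to end without any external
download.

## The DGR coordinate convention

The unit of analysis is the downstream gene region (DGR): the window from 100
nt upstream to 350 nt downstream of the stop codon, read 5'→3' in gene
orientation (minus-strand genes are reverse-complemented; circular genomes
wrap across the origin). Relative coordinates run −100..−1 over the gene tail
and +1..+350 past it, with **no position 0**; positions −3..−1 carry the stop
codon. The anchor is therefore the stop codon's 3' boundary. The window
boundaries are not defined to base precision by the biology, so the package
treats the anchor as a convention: it is applied uniformly by the extractor,
the model, and the generator, and `extractDGR()` accepts other window sizes.
Truncated windows (linear sequence ends, genes shorter than 100 nt) are always
flagged, never silent.

Internally all sequences are DNA (U is transliterated to T at the boundary)
and all coordinates are 1-based; `relToIdx()`/`idxToRel()` convert between
relative coordinates and string indices. GenBank and GFF3 input are converted
to this convention when read; ambiguity code N is carried through and never
matches any motif position or base pair (a conservative choice: an ambiguous
base can neither support nor refute a signal).

## Element classes and motifs

```{r}
str(elementDefs(), max.level = 2)
```

The defaults are the most frequent element sequences reported for
baculovirus 3' ends: USE UUUU (a U-rich rule, ≥4 U in any 6-nt window, is
available by configuration), UGUA, PAS AAUAAA/AUUAAA, CS after a CA
dinucleotide, DSE UUUUU or GUUGU. The auxiliary DSE has no published
consensus beyond "G-rich"; the package's operational rule is **any 6-nt
window containing ≥4 G** (window length and threshold configurable). CS
candidate hits are reported at the CA dinucleotide itself; where a cleavage
*point* is needed (structure analysis) it is the position immediately 3' of
the A. Scanning is plain IUPAC degenerate matching with overlapping hits
retained — deduplication and selection are the model layer's job.

## The positional models

Two presets ship as YAML under `extdata/models/`:

```{r}
modelSpec("improved2020")
modelSpec("initial2003")
```

Distances between elements are **gaps**: the number of nucleotides strictly
between the two elements, so adjacency is 0. The sole exception is
UGUA→PAS, a start-to-start offset of 0–8 nt, because the UGUA motif may
overlap the PAS ("immediately upstream or overlaid"). The source ranges are
given as prose ("5–30 nt upstream"), which does not pin down the measuring
points; the gap reading is applied consistently across the model, the
generator and the validator, so planted distances are recovered exactly. The
PAS anchor window (start between −12 and +7 of the stop boundary in the
improved model; +1..+50 in the initial one) deliberately reaches into the
coding sequence — the improved model demands it, so PAS hits inside the CDS
end are allowed.

### Cassette assignment

`assignCassette()` returns the placement of element classes that, in order:

1. maximizes the number of classes placed consistently with every distance
   window among them;
2. minimizes the summed deviation of realized distances from their window
   centres;
3. prefers the PAS closest to the stop anchor (smallest |relative position|);
4. prefers the leftmost CS; and finally the leftmost hit per remaining class
   in USE, UGUA, DSE, AuxDSE order.

This is a deterministic total order — re-running on the same hits always
yields the same cassette. Two design choices deserve emphasis because the
positional model alone does not force them. First, the tie-breaking order is
the package's own; nothing in the underlying biology dictates how competing
placements are resolved, so the rules above were chosen to be simple,
anchored on the two required classes, and fully deterministic. Second, an
optional element is only placed when at least one distance window ties it to
another *placed* element. Without this rule, count-maximization degenerates:
an Aux-DSE without a DSE participates in no window and would be "consistently
placeable" anywhere for free. PAS and CS are always required; a DGR where
they cannot be placed consistently yields no cassette. The search is
exhaustive over (PAS, CS, DSE) cores with per-core optimal choice of the
independent optional elements, and the test suite verifies it against a
brute-force enumeration of all class-wise hit combinations under the same
total order.

`checkAssignment()` re-derives every window distance from the recorded
positions alone and is used as an independent soundness check on each emitted
assignment.

### Hotspots, AU content and validation

`positionalDistribution()` pools hits of one class across DGRs and reports
the hotspot: the smallest contiguous window containing at least a fraction
*q* of all hits (default q = 0.75, leftmost window on ties). The mass
fraction behind published "hot spots" is not stated anywhere; q = 0.75 is a
documented default, not a claim of fidelity. `auContent()` reports the A+U
fraction of a window (default 40 nt) around a position, matching the
AU-enrichment statistic (80% AU in the 40 nt adjacent to the PAS).

`classifySets()` runs scan + assignment over named sequence sets (e.g. core
DGRs, non-core DGRs, random sequences, coding sequences) and tabulates how
many sequences place 0–6 classes. "Detection" means a **complete** cassette —
all six classes placed. Whether published detection counts required all six
elements is not stated; all-six is this package's documented definition, and
the per-element-count breakdown is always reported alongside so any other
cutoff can be read off the same table.

## Secondary structure

The structural question is whether the cleavage site sits in the loop or the
stem of a local hairpin, with the PAS region typically structured. That
classification consumes only the pairing state of each base, not folding
energies, so the fold engine is a **maximum base-pairing** dynamic program
(Nussinov-style): it maximizes Watson–Crick pair count (G:U wobble optional,
off by default) over all nested structures with a minimum loop of 3 unpaired
bases, with a deterministic traceback (rightmost base paired whenever pairing
achieves the optimum, leftmost admissible partner on ties). Thermodynamic
nearest-neighbour folding is deliberately out of scope — the engine sits
behind a single function (`foldMaxPairing()`) so an energy-based backend can
be substituted without touching the classification logic, and conclusions
drawn from pair-count folds should be read as structural *tendencies*, not
minimum-free-energy predictions. Pseudoknots are not modelled.

`findComplementarity()` reports every maximal reverse-complementary stretch
between two element sequences (the USE–PAS, USE–CS, PAS–CS, PAS–DSE and
CS–DSE pairings of interest), clipped to 4–6 nt by default;
`classifyCsContext()` labels the CS as stem / loop / unpaired-external and
combines it with the modal state of the PAS span into labels such as
`PAS-stem/CS-loop`. A frequency table over these label pairs serves as the
consensus-structure summary; it is an approximation of pictorial structure
classes, not a reproduction of them.

## Sequence logos

`buildPFM()` builds a position frequency matrix over aligned element windows
(default: element ± 10 nt of context, anchored on the element start), with N
excluded column-wise; `informationContent()` is the plain 2 − H(column) in
bits with no small-sample correction. `pfmConsensus()`, `writePFMMeme()` and
`plotLogo()` cover export and a schematic logo rendering.

## The synthetic data generator

`plantCassette()` builds one 450-nt DGR: background sequence, a stop codon at
−3..−1, an AU-enriched 40-nt window centred on the PAS (target 0.80 AU,
enforced to within 0.1 by resampling), and verbatim element motifs with every
inter-element distance drawn independently and uniformly from the model's
windows. Defaults are the study conditions: PAS drawn as AAUAAA with
probability 0.8 and AUUAAA with 0.2 (the two reported variants, with a
dominant canonical form; exact frequencies are not published), stop codons
uniform over TAA/TAG/TGA, background composition 59% AU (the genome-wide
figure reported for AcMNPV) with all of these configurable.

Geometry forces two documented trims. The stop codon occupies −3..−1 and
planted motifs must remain verbatim, so a planted PAS never overlaps the stop
triplet: within the improved model's −12..+7 anchor window the generator
draws PAS starts from {−12..−9} ∪ {+1, +2, +5, +6, +7} (positions +3/+4
additionally cannot host a non-overlapping UGUA). Likewise the UGUA offset is
confined to 4..8 of its 0..8 window so the motif clears the PAS. The *model*
windows are untouched — only the planted positions avoid impossible overlaps.
Similarly, the PAS→CS distance is geometrically capped near 28 nt by the
joint PAS→DSE (21–29) and CS→DSE (0–50) windows, even though the model window
allows 0–75.

`generateGenomeSet()` lays out genes on both strands, each with a private
450-nt downstream buffer, fills gene bodies with stop-free random codons, and
writes FASTA + GFF3 (with an `Is_circular` region attribute), a ground-truth
TSV and a JSON parameter sidecar, byte-identically for identical seeds. The
terminal 100 nt of a planted gene mirror the cassette's upstream window
rather than clean codons, because the positional model places PAS bases
inside the CDS end. Each circular genome is rotated so that one gene's DGR
wraps the origin, exercising the wrap-around path. The genomes are
statistical stand-ins: they reproduce the cassette geometry, strandedness,
AU context and circular topology of baculovirus genomes, but none of their
gene content, homology, codon usage or phylogeny — so passing benchmarks
demonstrate that the pipeline recovers what the positional model describes,
not that the model itself is biologically complete.

## Numerical choices and problem sizes

* Hotspot mass fraction q = 0.75; minimum fold loop 3 nt; G-rich rule ≥4 G
  in 6 nt; complementarity lengths 4–6 nt; logo flanks ±10 nt.
* All randomized procedures consume the caller's RNG stream (or an explicit
  seed) and are reproducible; file outputs carry no timestamps.
* The package's benchmark scripts and tests use 500 planted cassettes for
  recovery and detection experiments (2000 where every integer distance of a
  100-value window must be observed), 200 cases per algorithmic oracle
  comparison (10^4 for the IUPAC scanner), and 50 designed hairpin fixtures —
  sizes at which all the binomial margins involved are decisive while a full
  run stays within a few minutes on one CPU.

## Known limitations

* No de-novo motif discovery: the element definitions are fixed IUPAC
  motifs or composition rules supplied by configuration.
* No thermodynamic folding, pseudoknots or G-quadruplexes; structure labels
  come from a pair-count fold.
* Spliced (joined) gene features are rejected rather than handled —
  baculovirus genes are unspliced.
* Early and late gene classes are not modelled separately: the positional
  searches this package reproduces detected no difference between them.
* Core-gene identity is configuration (a shipped 38-name table), since the
  canonical membership list depends on the annotation source.
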