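# baculoPolyA

Positional modelling of the cis-acting signals that direct 3'-end cleavage
and polyadenylation of baculovirus mRNAs.

Baculoviruses (circular dsDNA insect viruses, 88–200 kbp, genes on both
strands) polyadenylate their transcripts using signal cassettes much like the
eukaryotic USE–PAS–DSE pattern, but packed tightly around the stop codon in
AU-rich sequence. `baculoPolyA` is for anyone who wants to detect and
characterize these cassettes on annotated genomes — or to benchmark a
positional model of them with full ground truth. It implements:

* **DGR extraction** — the downstream gene region, −100..+350 around each
  stop codon, strand-aware and circular-origin-aware (`readGenome`,
  `extractDGR`; GenBank flat files or FASTA + GFF3).
* **Element scanning** — overlapping IUPAC matches for USE (`UUUU`), UGUA,
  PAS (`AAUAAA`/`AUUAAA`), CS (`CA`), DSE (`UUUUU`/`GUUGU`) and a G-rich
  Aux-DSE rule (≥4 G in 6 nt), with positional histograms and hotspot windows
  (`findElements`, `positionalDistribution`).
* **Cassette assembly** — assignment of hits to a cassette under explicit
  distance windows. The improved model places the PAS start within −12..+7
  of the stop boundary, the USE 5–30 nt upstream of the PAS, the CS 0–75 nt
  downstream of the PAS, the DSE 21–29 nt from the PAS and 0–50 nt from the
  CS, UGUA overlapping/just upstream of the PAS, and the Aux-DSE downstream
  of the DSE. Assignments maximize placed elements, then minimize distance
  deviation from window centres, with a deterministic total order
  (`modelSpec`, `assignCassette`, `classifySets`).
* **Structure context** — maximum base-pairing folds (Nussinov-style DP),
  inter-element complementarity (4–6 nt reverse-complement stretches), and
  stem/loop classification of the cleavage site (`foldMaxPairing`,
  `findComplementarity`, `classifyCsContext`).
* **Logos** — position frequency matrices and information content over the
  recovered element contexts (`buildPFM`, `informationContent`, `plotLogo`).
* **Synthetic genomes** — annotated circular genomes with planted cassettes
  drawn uniformly from the model windows, AU-enriched PAS context (0.80 in
  the 40 nt around the PAS), both strands, and a ground-truth table
  (`SimParams`, `plantCassette`, `generateGenomeSet`).

See the methods vignette (`vignettes/baculoPolyA-methods.Rmd`) for the model
definitions, the distance conventions, and every documented design choice.

## Worked example

Simulate one annotated genome, extract its DGRs, and assemble cassettes under
the improved positional model:

```r
library(baculoPolyA)

params <- SimParams(nGenomes = 1, genesPerGenome = 10, seed = 42)
sim    <- generateGenomeSet(params, tempdir())
genome <- sim$genomes[[1]]
genome
#> GenomeRecord synthgenome001: 14115 nt, circular, 10 genes (0 core)

dgrs  <- extractDGRs(genome)
model <- modelSpec("improved2020")
hits  <- findElements(dgrs[[1]])
assignCassette(hits, model, dgrId = "g001")
#> CassetteAssignment g001: 6 elements (complete), deviation 70.5
#>   USE     TTTT   at rel -34
#>   UGUA    TGTA   at rel -14
#>   PAS     ATTAAA at rel -9
#>   CS      CA     at rel +15
#>   DSE     GTTGT  at rel +19
#>   AuxDSE  TCGGGG at rel +93
```

All six element classes were placed: this gene's PAS is the alternative
hexamer AUUAAA, starting 9 nt before the stop boundary (the model window
reaches into the CDS end), with the cleavage-site CA 15 nt past the stop and
the GU-rich DSE 3 nt after it. The deviation is the summed distance of each
realized spacing from its window centre — the tie-breaking score, smaller
meaning more central. Aggregating over all ten genes gives the PAS context
logo:

```r
asn <- lapply(seq_along(dgrs), function(i)
  assignCassette(findElements(dgrs[[i]]), model, dgrId = i))
pfm <- buildPFM(elementWindows(asn, as.list(dgrs), "PAS"), "PAS")
pfmConsensus(pfm)
#> [1] "AUUAGUGUAAAAUAAAAAUAAUUAUA"
```

Columns 11–16 (the hexamer itself) read `AAUAAA`; the flanks show the
planted AU-rich context. Folding the cassette region of the first DGR and
classifying the cleavage site:

```r
f <- foldMaxPairing(substr(dgrSequence(dgrs[[1]]), 89, 160))
# ... classifyCsContext(f, <CS index>, pasSpan = <PAS indices>)
#> structure class: PAS-stem/CS-loop
```

i.e. the PAS sits in a paired (stem) region while the cleavage site is in a
loop.

A thin command-line front end over the same functions ships at
`inst/scripts/baculopolya.R` (`simulate`, `extract`, `scan`, `predict`,
`validate`, `fold`, `logo`). It can also run the pipeline on user-supplied
real genomes (GenBank or FASTA+GFF3) via `extract --genome ...`; outputs on
real data carry no benchmark guarantee.

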