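#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata isSingleString
#' @importFrom stats setNames
NULL

ELEMENT_CLASSES <- c("USE", "UGUA", "PAS", "CS", "DSE", "AuxDSE")

#' GenomeRecord: an annotated (possibly circular) genome
#'
#' Holds one nucleotide sequence together with its gene annotations,
#' normalized to a single internal convention: plus-strand frame, 1-based
#' closed intervals (the `GRanges` convention). All file formats are
#' converted at the I/O boundary by [readGenome()].
#'
#' @slot id genome identifier.
#' @slot sequence a [Biostrings::DNAString] over A,C,G,T,N.
#' @slot circular logical; `TRUE` for covalently closed circular genomes.
#' @slot genes a [GenomicRanges::GRanges] with metadata columns
#'   `gene_id`, `name` and `is_core`.
#'
#' @export
setClass("GenomeRecord",
  representation(id = "character", sequence = "ANY",
                 circular = "logical", genes = "ANY"))

setValidity("GenomeRecord", function(object) {
  msg <- character()
  if (length(object@sequence) < 1L) msg <- c(msg, "sequence must be non-empty")
  if (!is(object@sequence, "DNAString")) msg <- c(msg, "sequence must be a DNAString")
  if (!is(object@genes, "GRanges")) msg <- c(msg, "genes must be a GRanges")
  if (is(object@genes, "GRanges") && length(object@genes)) {
    needed <- c("gene_id", "name", "is_core")
    if (!all(needed %in% colnames(S4Vectors::mcols(object@genes))))
      msg <- c(msg, "genes needs mcols gene_id, name, is_core")
    if (any(GenomicRanges::start(object@genes) < 1L) ||
        any(GenomicRanges::end(object@genes) > length(object@sequence)))
      msg <- c(msg, "gene intervals must lie within the genome")
    if (any(GenomicRanges::width(object@genes) < 6L))
      msg <- c(msg, "genes must be at least 6 nt (start + stop codon)")
  }
  if (length(msg)) msg else TRUE
})

#' DGR: a downstream gene region in gene orientation
#'
#' A window around a gene's stop codon, reported 5'->3' in the orientation
#' of the gene (minus-strand genes are reverse-complemented). Relative
#' coordinates: -upstream..-1 cover the tail of the gene so that -3..-1 is
#' the stop codon; +1..+downstream the region immediately 3' of it; there
#' is no position 0.
#'
#' @slot genomeId,geneId identifiers.
#' @slot strand "+" or "-".
#' @slot sequence character; the window sequence in gene orientation.
#' @slot upstreamLen integer; number of bases at relative positions < 0
#'   actually present (100 unless truncated).
#' @slot truncated5,truncated3 logical truncation flags for linear genomes.
#' @slot genomicPos integer vector, one 1-based plus-strand genome
#'   coordinate per DGR base (wraps across the origin for circular genomes).
#'
#' @export
setClass("DGR",
  representation(genomeId = "character", geneId = "character",
                 strand = "character", sequence = "character",
                 upstreamLen = "integer",
                 truncated5 = "logical", truncated3 = "logical",
                 genomicPos = "integer"))

setValidity("DGR", function(object) {
  msg <- character()
  n <- nchar(object@sequence)
  if (!object@strand %in% c("+", "-")) msg <- c(msg, "strand must be + or -")
  if (length(object@genomicPos) != n)
    msg <- c(msg, "genomicPos must map every DGR base")
  if (object@upstreamLen > n) msg <- c(msg, "upstreamLen exceeds sequence")
  if (length(msg)) msg else TRUE
})

#' DGRSet: a list of DGR objects
#' @export
setClass("DGRSet", contains = "SimpleList",
         prototype = prototype(elementType = "DGR"))

#' ModelSpec: a positional polyadenylation model
#'
#' Distance windows between element classes plus a PAS anchor window
#' relative to the stop codon. Two metrics are used: `"gap"` windows count
#' the nucleotides strictly between two elements (adjacency = 0);
#' `"start"` windows measure start-to-start offsets (used for UGUA->PAS,
#' where overlap with the PAS is allowed).
#'
#' @slot name model name ("improved2020", "initial2003" or custom).
#' @slot windows named list; each entry `list(min=, max=, metric=)` keyed
#'   `"A->B"` by the upstream/downstream element pair.
#' @slot anchorWindow numeric(2); allowed PAS start in DGR relative
#'   coordinates (e.g. c(-12, 7)).
#' @slot required,optional character; element classes that must / may be
#'   placed. `required` always contains PAS and CS.
#'
#' @export
setClass("ModelSpec",
  representation(name = "character", windows = "list",
                 anchorWindow = "numeric",
                 required = "character", optional = "character"))

setValidity("ModelSpec", function(object) {
  msg <- character()
  for (nm in names(object@windows)) {
    w <- object@windows[[nm]]
    if (!all(c("min", "max", "metric") %in% names(w)))
      msg <- c(msg, sprintf("window %s needs min, max, metric", nm))
    else {
      if (w$min > w$max) msg <- c(msg, sprintf("window %s has min > max", nm))
      if (!w$metric %in% c("gap", "start"))
        msg <- c(msg, sprintf("window %s has unknown metric", nm))
    }
    cls <- strsplit(nm, "->", fixed = TRUE)[[1]]
    if (length(cls) != 2L || !all(cls %in% ELEMENT_CLASSES))
      msg <- c(msg, sprintf("window key %s is not an element pair", nm))
  }
  if (!all(c("PAS", "CS") %in% object@required))
    msg <- c(msg, "required elements must include PAS and CS")
  if (length(object@anchorWindow) != 2L ||
      object@anchorWindow[1] > object@anchorWindow[2])
    msg <- c(msg, "anchorWindow must be c(lo, hi) with lo <= hi")
  # joint feasibility: gap(PAS->DSE) = gap(PAS->CS) + width(CS) + gap(CS->DSE)
  wn <- object@windows
  if (all(c("PAS->CS", "CS->DSE", "PAS->DSE") %in% names(wn))) {
    csw <- 2L  # CA dinucleotide
    lo <- wn[["PAS->CS"]]$min + csw + wn[["CS->DSE"]]$min
    hi <- wn[["PAS->CS"]]$max + csw + wn[["CS->DSE"]]$max
    if (hi < wn[["PAS->DSE"]]$min || lo > wn[["PAS->DSE"]]$max)
      msg <- c(msg, "contradictory windows: PAS->CS + CS->DSE incompatible with PAS->DSE")
  }
  if (length(msg)) msg else TRUE
})

#' CassetteAssignment: one consistent placement of cassette elements
#'
#' @slot dgrId identifier of the source DGR.
#' @slot hits named list, element class -> list(idx_start, rel_start,
#'   motif, length) for each placed element.
#' @slot nElements number of classes placed.
#' @slot deviation total |distance - window centre| over satisfied windows.
#' @slot satisfiedWindows data.frame(window, distance, min, max) of every
#'   window constraint between placed elements.
#' @slot complete `TRUE` when all six classes are placed.
#'
#' @export
setClass("CassetteAssignment",
  representation(dgrId = "character", hits = "list", nElements = "integer",
                 deviation = "numeric", satisfiedWindows = "data.frame",
                 complete = "logical"))

#' Fold: a nested secondary structure
#'
#' @slot sequence the folded sequence (DNA alphabet internally; T == U).
#' @slot pairs integer matrix with columns i, j (i < j), each index in at
#'   most one pair, no pseudoknots.
#' @slot dotBracket dot-bracket string consistent with `pairs`.
#' @slot minLoop minimum number of unpaired bases enclosed by a pair.
#'
#' @export
setClass("Fold",
  representation(sequence = "character", pairs = "matrix",
                 dotBracket = "character", minLoop = "integer"))

setValidity("Fold", function(object) {
  msg <- character()
  n <- nchar(object@sequence)
  p <- object@pairs
  if (ncol(p) != 2L) return("pairs must have two columns (i, j)")
  if (nrow(p)) {
    if (any(p[, 1] >= p[, 2])) msg <- c(msg, "pairs must have i < j")
    if (any(p < 1) || any(p > n)) msg <- c(msg, "pair index out of range")
    if (anyDuplicated(as.vector(p))) msg <- c(msg, "index in more than one pair")
    if (any(p[, 2] - p[, 1] <= object@minLoop))
      msg <- c(msg, "pair violates minimum loop length")
    # nestedness: no i < k < j < l for pairs (i,j), (k,l)
    o <- order(p[, 1])
    pi <- p[o, 1]; pj <- p[o, 2]
    if (nrow(p) > 1L) {
      for (a in seq_len(nrow(p) - 1L)) {
        b <- which(pi > pi[a] & pi < pj[a] & pj > pj[a])
        if (length(b)) { msg <- c(msg, "pseudoknotted pairs"); break }
      }
    }
  }
  if (nchar(object@dotBracket) != n)
    msg <- c(msg, "dotBracket length must equal sequence length")
  if (length(msg)) msg else TRUE
})

#' PFM: a position frequency matrix
#'
#' @slot elementClass label of the aligned element windows.
#' @slot mat 4 x L matrix (rows A, C, G, U) of column frequencies; each
#'   column sums to 1 (columns with no informative bases are uniform and
#'   flagged in `metadata`).
#' @slot nSequences number of aligned windows.
#' @slot anchor description of the alignment rule.
#'
#' @export
setClass("PFM",
  representation(elementClass = "character", mat = "matrix",
                 nSequences = "integer", anchor = "character"))

setValidity("PFM", function(object) {
  msg <- character()
  if (!identical(rownames(object@mat), c("A", "C", "G", "U")))
    msg <- c(msg, "rows must be A, C, G, U")
  if (object@nSequences < 1L) msg <- c(msg, "nSequences must be >= 1")
  cs <- colSums(object@mat)
  if (ncol(object@mat) && any(abs(cs - 1) > 1e-9))
    msg <- c(msg, "columns must sum to 1")
  if (length(msg)) msg else TRUE
})

#' PositionalDistribution: where an element class occurs across DGRs
#'
#' @slot elementClass element class label.
#' @slot histogram named integer vector, relative position -> hit count.
#' @slot nSequences number of DGRs contributing.
#' @slot hotspot numeric(2) smallest contiguous relative-coordinate window
#'   holding at least a fraction `q` of all hits, or `c(NA, NA)` when there
#'   are no hits.
#' @slot q the hotspot mass fraction used.
#'
#' @export
setClass("PositionalDistribution",
  representation(elementClass = "character", histogram = "integer",
                 nSequences = "integer", hotspot = "numeric", q = "numeric"))

#' ValidationReport: detection of the cassette model across sequence sets
#'
#' @slot summary data.frame with one row per input set: `set`, `n`,
#'   `n_complete`, `detection_fraction`.
#' @slot countsByN integer matrix, sets x element counts (0..6): how many
#'   sequences had an assignment placing exactly that many classes
#'   (column "0" counts sequences with no viable assignment).
#' @slot model name of the model used.
#'
#' @export
setClass("ValidationReport",
  representation(summary = "data.frame", countsByN = "matrix",
                 model = "character"))

#' SimParams: parameters of the synthetic genome generator
#'
#' @slot nGenomes,genesPerGenome counts.
#' @slot genomeLength target genome length in nt (`NA` = just large enough
#'   for the gene layout); must fit all genes plus a 450-nt downstream
#'   buffer per gene.
#' @slot fracMinusStrand fraction of genes placed on the minus strand.
#' @slot auFracCassette AU fraction of the 40-nt window centred on each
#'   planted PAS (default 0.80).
#' @slot backgroundComposition named numeric (A, C, G, T) summing to 1.
#' @slot model the [ModelSpec] whose windows planted distances are drawn
#'   from.
#' @slot cassetteRate fraction of genes receiving a full planted cassette.
#' @slot geneLengthRange numeric(2) gene length bounds (rounded to codons).
#' @slot pasMotifProbs named numeric; sampling probabilities of the planted
#'   PAS hexamer.
#' @slot seed integer RNG seed.
#'
#' @export
setClass("SimParams",
  representation(nGenomes = "integer", genesPerGenome = "integer",
                 genomeLength = "numeric", fracMinusStrand = "numeric",
                 auFracCassette = "numeric", backgroundComposition = "numeric",
                 model = "ModelSpec", cassetteRate = "numeric",
                 geneLengthRange = "numeric", pasMotifProbs = "numeric",
                 seed = "integer"))

setValidity("SimParams", function(object) {
  msg <- character()
  fr <- c(object@fracMinusStrand, object@auFracCassette, object@cassetteRate)
  if (any(fr < 0 | fr > 1)) msg <- c(msg, "fractions must lie in [0, 1]")
  bc <- object@backgroundComposition
  if (!identical(sort(names(bc)), c("A", "C", "G", "T")))
    msg <- c(msg, "backgroundComposition needs names A, C, G, T")
  else if (abs(sum(bc) - 1) > 1e-9)
    msg <- c(msg, "backgroundComposition must sum to 1")
  if (any(bc < 0)) msg <- c(msg, "base frequencies must be non-negative")
  if (object@nGenomes < 1L || object@genesPerGenome < 1L)
    msg <- c(msg, "need at least one genome and one gene")
  if (any(object@geneLengthRange < 120) ||
      object@geneLengthRange[1] > object@geneLengthRange[2])
    msg <- c(msg, "geneLengthRange must be increasing and >= 120 nt")
  if (!is.na(object@genomeLength)) {
    need <- object@genesPerGenome * (object@geneLengthRange[2] + 450)
    if (object@genomeLength < need)
      msg <- c(msg, sprintf(
        "genomeLength %d too small for %d genes plus 450-nt buffers (need >= %d)",
        object@genomeLength, object@genesPerGenome, need))
  }
  if (abs(sum(object@pasMotifProbs) - 1) > 1e-9)
    msg <- c(msg, "pasMotifProbs must sum to 1")
  if (length(msg)) msg else TRUE
})
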