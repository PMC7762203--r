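#' DGR relative coordinates
#'
#' A DGR of `upstreamLen + downstream` bases uses relative coordinates
#' `-upstreamLen..-1` (tail of the gene, `-3..-1` the stop codon) and
#' `+1..+downstream` (immediately 3' of it). There is no position 0.
#' These helpers convert between relative coordinates and 1-based indices
#' into the DGR string.
#'
#' @param rel integer vector of relative coordinates (non-zero).
#' @param idx integer vector of 1-based string indices.
#' @param upstreamLen number of bases at relative positions < 0 (100 for a
#'   full DGR).
#' @return integer vector of converted coordinates.
#' @examples
#' relToIdx(c(-100, -1, 1, 350), 100)  # 1, 100, 101, 450
#' idxToRel(c(1, 100, 101, 450), 100)
#' @export
relToIdx <- function(rel, upstreamLen = 100L) {
  rel <- as.integer(rel)
  if (any(rel == 0L)) stop("relative coordinate 0 does not exist")
  ifelse(rel < 0L, rel + upstreamLen + 1L, rel + upstreamLen)
}

#' @rdname relToIdx
#' @export
idxToRel <- function(idx, upstreamLen = 100L) {
  idx <- as.integer(idx)
  if (any(idx < 1L)) stop("index must be >= 1")
  ifelse(idx <= upstreamLen, idx - upstreamLen - 1L, idx - upstreamLen)
}

# distance between two placed elements under a model window metric.
# gap: nucleotides strictly between A and B (adjacency = 0).
# start: startIdx(B) - startIdx(A).
elementDistance <- function(startA, lenA, startB, metric) {
  if (metric == "gap") startB - (startA + lenA - 1L) - 1L
  else startB - startA
}

# normalize a nucleotide string: uppercase, RNA -> DNA alphabet
normalizeSeq <- function(x) {
  x <- chartr("u", "U", toupper(x))
  chartr("U", "T", x)
}

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
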