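#' @include AllClasses.R
NULL

#' Accessors
#'
#' Small accessor generics for the package's S4 containers.
#'
#' @param x an object.
#' @return the slot value (see each method).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))
#' @rdname accessors
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))
#' @rdname accessors
#' @export
setGeneric("isCircularGenome", function(x) standardGeneric("isCircularGenome"))
#' @rdname accessors
#' @export
setGeneric("geneAnnotations", function(x) standardGeneric("geneAnnotations"))
#' @rdname accessors
#' @export
setGeneric("dgrSequence", function(x) standardGeneric("dgrSequence"))
#' @rdname accessors
#' @export
setGeneric("isTruncated", function(x) standardGeneric("isTruncated"))
#' @rdname accessors
#' @export
setGeneric("pairCount", function(x) standardGeneric("pairCount"))
#' @rdname accessors
#' @export
setGeneric("dotBracket", function(x) standardGeneric("dotBracket"))
#' @rdname accessors
#' @export
setGeneric("foldPairs", function(x) standardGeneric("foldPairs"))
#' @rdname accessors
#' @export
setGeneric("pfmMatrix", function(x) standardGeneric("pfmMatrix"))
#' @rdname accessors
#' @export
setGeneric("hotspot", function(x) standardGeneric("hotspot"))
#' @rdname accessors
#' @export
setGeneric("elementClass", function(x) standardGeneric("elementClass"))
#' @rdname accessors
#' @export
setGeneric("cassetteHits", function(x) standardGeneric("cassetteHits"))
#' @rdname accessors
#' @export
setGeneric("isComplete", function(x) standardGeneric("isComplete"))

#' @rdname accessors
setMethod("genomeId", "GenomeRecord", function(x) x@id)
#' @rdname accessors
setMethod("genomeId", "DGR", function(x) x@genomeId)
#' @rdname accessors
setMethod("genomeSeq", "GenomeRecord", function(x) x@sequence)
#' @rdname accessors
setMethod("isCircularGenome", "GenomeRecord", function(x) x@circular)
#' @rdname accessors
setMethod("geneAnnotations", "GenomeRecord", function(x) x@genes)
#' @rdname accessors
setMethod("dgrSequence", "DGR", function(x) x@sequence)
#' @rdname accessors
setMethod("isTruncated", "DGR", function(x) x@truncated5 || x@truncated3)
#' @rdname accessors
setMethod("pairCount", "Fold", function(x) nrow(x@pairs))
#' @rdname accessors
setMethod("dotBracket", "Fold", function(x) x@dotBracket)
#' @rdname accessors
setMethod("foldPairs", "Fold", function(x) x@pairs)
#' @rdname accessors
setMethod("pfmMatrix", "PFM", function(x) x@mat)
#' @rdname accessors
setMethod("hotspot", "PositionalDistribution", function(x) x@hotspot)
#' @rdname accessors
setMethod("elementClass", "PFM", function(x) x@elementClass)
#' @rdname accessors
setMethod("elementClass", "PositionalDistribution", function(x) x@elementClass)
#' @rdname accessors
setMethod("cassetteHits", "CassetteAssignment", function(x) x@hits)
#' @rdname accessors
setMethod("isComplete", "CassetteAssignment", function(x) x@complete)

setMethod("show", "GenomeRecord", function(object) {
  cat(sprintf("GenomeRecord %s: %d nt, %s, %d genes (%d core)\n",
              object@id, length(object@sequence),
              if (object@circular) "circular" else "linear",
              length(object@genes),
              sum(S4Vectors::mcols(object@genes)$is_core)))
})

setMethod("show", "DGR", function(object) {
  cat(sprintf("DGR %s|%s (%s): %d nt (%d upstream incl. stop)%s\n",
              object@genomeId, object@geneId, object@strand,
              nchar(object@sequence), object@upstreamLen,
              if (isTruncated(object)) " [truncated]" else ""))
})

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec '%s': PAS anchor window [%d, %d] nt of stop\n",
              object@name, object@anchorWindow[1], object@anchorWindow[2]))
  for (nm in names(object@windows)) {
    w <- object@windows[[nm]]
    cat(sprintf("  %-12s %3d..%3d nt (%s)\n", nm, w$min, w$max, w$metric))
  }
  cat("  required:", paste(object@required, collapse = ", "),
      "| optional:", paste(object@optional, collapse = ", "), "\n")
})

setMethod("show", "CassetteAssignment", function(object) {
  cat(sprintf("CassetteAssignment %s: %d elements%s, deviation %.1f\n",
              object@dgrId, object@nElements,
              if (object@complete) " (complete)" else "",
              object@deviation))
  for (cl in names(object@hits)) {
    h <- object@hits[[cl]]
    cat(sprintf("  %-7s %-6s at rel %+d\n", cl, h$motif, h$rel_start))
  }
})

setMethod("show", "Fold", function(object) {
  cat(sprintf("Fold: %d nt, %d pairs (min loop %d)\n",
              nchar(object@sequence), nrow(object@pairs), object@minLoop))
  if (nchar(object@sequence) <= 80) {
    cat(" ", object@sequence, "\n ", object@dotBracket, "\n")
  }
})

setMethod("show", "PFM", function(object) {
  cat(sprintf("PFM %s: %d columns from %d sequences (anchor: %s)\n",
              object@elementClass, ncol(object@mat), object@nSequences,
              object@anchor))
})

setMethod("show", "PositionalDistribution", function(object) {
  hs <- if (anyNA(object@hotspot)) "undefined"
        else sprintf("[%+d, %+d]", object@hotspot[1], object@hotspot[2])
  cat(sprintf("PositionalDistribution %s: %d hits over %d DGRs, hotspot %s (q=%.2f)\n",
              object@elementClass, sum(object@histogram),
              object@nSequences, hs, object@q))
})

setMethod("show", "ValidationReport", function(object) {
  cat(sprintf("ValidationReport (model %s)\n", object@model))
  print(object@summary, row.names = FALSE)
})

setMethod("show", "SimParams", function(object) {
  cat(sprintf(
    "SimParams: %d genome(s) x %d genes, cassette rate %.2f, AU %.2f, seed %d\n",
    object@nGenomes, object@genesPerGenome, object@cassetteRate,
    object@auFracCassette, object@seed))
})
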