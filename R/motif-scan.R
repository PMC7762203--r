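#' @include AllClasses.R coords.R
NULL

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

#' Scan a sequence for an IUPAC degenerate pattern
#'
#' Reports every (possibly overlapping) occurrence of `pattern` in
#' `sequence`. T and U are interchangeable on both sides; an N in the
#' *sequence* matches nothing (conservative handling of ambiguous bases),
#' while N in the *pattern* matches any unambiguous base.
#'
#' @param sequence a nucleotide string over A, C, G, T, U, N (case
#'   insensitive).
#' @param pattern an IUPAC string (A,C,G,T,U,R,Y,S,W,K,M,B,D,H,V,N).
#' @return a data.frame with columns `start` (1-based) and `match`
#'   (the matched substring, DNA alphabet); zero rows when there is no
#'   match.
#' @examples
#' scanIUPAC("GGAATAAAGG", "AATAAA")   # one hit at 3
#' scanIUPAC("ATTAAA", "AWTAAA")       # W = A or T
#' scanIUPAC("TTTTTT", "TTTT")         # overlapping hits at 1, 2, 3
#' @export
scanIUPAC <- function(sequence, pattern) {
  stopifnot(isSingleString(sequence), isSingleString(pattern))
  s <- strsplit(normalizeSeq(sequence), "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(s), c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop("invalid sequence character(s): ", paste(bad, collapse = ", "))
  p <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(p), names(IUPAC_SETS))
  if (length(bad))
    stop("invalid IUPAC symbol(s) in pattern: ", paste(bad, collapse = ", "))
  n <- length(s); k <- length(p)
  if (k == 0L || n < k)
    return(data.frame(start = integer(), match = character()))
  ok <- rep(TRUE, n - k + 1L)
  for (m in seq_len(k)) {
    allowed <- IUPAC_SETS[[p[m]]]
    ok <- ok & (s[m:(n - k + m)] %in% allowed)  # N never in any set
  }
  starts <- which(ok)
  if (!length(starts)) return(data.frame(start = integer(), match = character()))
  data.frame(start = starts,
             match = substring(paste(s, collapse = ""), starts, starts + k - 1L))
}

#' Element definitions for the cassette element classes
#'
#' Returns the default definition of each cis-element class as a list of
#' IUPAC motifs, following the most frequent sequences reported for
#' baculovirus 3'-end processing: USE "UUUU", UGUA "UGUA", PAS "AAUAAA" or
#' "AUUAAA", cleavage site after a "CA" dinucleotide, DSE "UUUUU" or
#' "GUUGU", and a G-rich auxiliary DSE. The Aux-DSE has no published
#' consensus; the sentinel motif `"G-RICH"` triggers a windowed rule (any
#' `gWindow`-long stretch with at least `gMin` G).
#'
#' @param useURich if `TRUE`, USE uses a U-rich rule (>= 4 T in any 6-nt
#'   window) instead of the literal UUUU motif.
#' @param gWindow,gMin window length and minimum G count of the G-rich
#'   Aux-DSE rule.
#' @param uRichTerm include the optional U-rich late-gene terminator class
#'   (motif UUUUUU); excluded from cassette assembly by default.
#' @return named list of element definitions (`motifs`, `description`).
#' @export
elementDefs <- function(useURich = FALSE, gWindow = 6L, gMin = 4L,
                        uRichTerm = FALSE) {
  defs <- list(
    USE  = list(motifs = if (useURich) "RICH:T" else "TTTT",
                description = "upstream sequence element (U-rich)"),
    UGUA = list(motifs = "TGTA",
                description = "CFIm-recognized UGUA motif"),
    PAS  = list(motifs = c("AATAAA", "ATTAAA"),
                description = "polyadenylation signal hexamer"),
    CS   = list(motifs = "CA",
                description = "cleavage after a CA dinucleotide"),
    DSE  = list(motifs = c("TTTTT", "GTTGT"),
                description = "downstream sequence element (U/GU-rich)"),
    AuxDSE = list(motifs = "G-RICH",
                  description = sprintf("G-rich auxiliary DSE (>=%d G in %d nt)",
                                        gMin, gWindow)))
  if (uRichTerm)
    defs$URichTerm <- list(motifs = "TTTTTT",
                           description = "U-rich late-gene terminator")
  attr(defs, "gWindow") <- as.integer(gWindow)
  attr(defs, "gMin") <- as.integer(gMin)
  defs
}

#' Load element definitions from a YAML configuration
#'
#' Reads a YAML file of the shape shipped in `extdata/elements.yaml`
#' (per-class motif lists plus the G-rich rule parameters).
#'
#' @param path YAML file; default the shipped configuration.
#' @return element definitions as produced by [elementDefs()].
#' @export
readElementDefs <- function(path = system.file("extdata", "elements.yaml",
                                               package = "baculoPolyA")) {
  y <- yaml::read_yaml(path)
  defs <- lapply(y$elements, function(e)
    list(motifs = as.character(e$motifs),
         description = if (is.null(e$description)) "" else e$description))
  attr(defs, "gWindow") <- as.integer(if (is.null(y$g_window)) 6L else y$g_window)
  attr(defs, "gMin") <- as.integer(if (is.null(y$g_min)) 4L else y$g_min)
  defs
}

# all starts of windows of length win with >= minCount of `base`
richWindows <- function(s, base, win, minCount) {
  x <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(x)
  if (n < win) return(integer())
  isb <- as.integer(x == base)
  cs <- cumsum(c(0L, isb))
  counts <- cs[(win + 1L):(n + 1L)] - cs[1:(n - win + 1L)]
  which(counts >= minCount)
}

#' Find all element-class occurrences in a DGR
#'
#' Scans a DGR for every element class in `defs` and reports the hits in
#' DGR relative coordinates. Literal / IUPAC motifs go through
#' [scanIUPAC()]; the sentinels `"G-RICH"` (Aux-DSE) and `"RICH:T"`
#' (U-rich USE rule) use a windowed composition rule instead.
#'
#' @param dgr a [DGR] object (or a plain character sequence, in which case
#'   `upstreamLen` gives the coordinate anchor).
#' @param defs element definitions from [elementDefs()].
#' @param upstreamLen used only when `dgr` is a character string.
#' @return a [S4Vectors::DataFrame] with columns `element`, `motif`,
#'   `idx_start`, `rel_start`, `length`.
#' @export
findElements <- function(dgr, defs = elementDefs(), upstreamLen = 100L) {
  if (is(dgr, "DGR")) {
    s <- dgr@sequence
    up <- dgr@upstreamLen
  } else {
    s <- normalizeSeq(dgr)
    up <- as.integer(upstreamLen)
  }
  gWindow <- attr(defs, "gWindow"); if (is.null(gWindow)) gWindow <- 6L
  gMin <- attr(defs, "gMin"); if (is.null(gMin)) gMin <- 4L
  out <- list()
  for (cl in names(defs)) {
    for (motif in defs[[cl]]$motifs) {
      if (motif == "G-RICH") {
        st <- richWindows(s, "G", gWindow, gMin)
        if (length(st))
          out[[length(out) + 1L]] <- data.frame(
            element = cl, motif = substring(s, st, st + gWindow - 1L),
            idx_start = st, length = gWindow)
      } else if (motif == "RICH:T") {
        st <- richWindows(s, "T", 6L, 4L)
        if (length(st))
          out[[length(out) + 1L]] <- data.frame(
            element = cl, motif = substring(s, st, st + 5L),
            idx_start = st, length = 6L)
      } else {
        h <- scanIUPAC(s, motif)
        if (nrow(h))
          out[[length(out) + 1L]] <- data.frame(
            element = cl, motif = h$match, idx_start = h$start,
            length = nchar(motif))
      }
    }
  }
  if (!length(out)) {
    return(DataFrame(element = character(), motif = character(),
                     idx_start = integer(), rel_start = integer(),
                     length = integer()))
  }
  df <- do.call(rbind, out)
  df <- df[order(match(df$element, names(defs)), df$idx_start), , drop = FALSE]
  DataFrame(element = df$element, motif = df$motif,
            idx_start = as.integer(df$idx_start),
            rel_start = idxToRel(df$idx_start, up),
            length = as.integer(df$length))
}

#' Positional distribution and hotspot of an element class
#'
#' Pools hits of one element class across many scanned DGRs, builds a
#' histogram over relative positions, and reports the hotspot: the
#' smallest contiguous window containing at least a fraction `q` of all
#' hits (ties broken towards the leftmost window).
#'
#' @param hits a [S4Vectors::DataFrame] (or data.frame) of hits as
#'   returned by [findElements()], possibly concatenated over DGRs; must
#'   contain `element` and `rel_start`.
#' @param element the element class to summarise.
#' @param nSequences how many DGRs were scanned.
#' @param q hotspot mass fraction (default 0.75).
#' @param upstreamLen coordinate anchor used for the rel/index conversion.
#' @return a [PositionalDistribution]. With zero hits the histogram is
#'   empty and the hotspot undefined (`NA`), with a warning.
#' @export
positionalDistribution <- function(hits, element, nSequences, q = 0.75,
                                   upstreamLen = 100L) {
  stopifnot(q > 0, q <= 1)
  rel <- as.integer(hits$rel_start[hits$element == element])
  if (!length(rel)) {
    warning("no hits for element class ", element, "; hotspot undefined")
    return(new("PositionalDistribution", elementClass = element,
               histogram = setNames(integer(), character()),
               nSequences = as.integer(nSequences),
               hotspot = c(NA_real_, NA_real_), q = q))
  }
  tab <- table(rel)
  hist <- setNames(as.integer(tab), names(tab))
  # hotspot search in gapless index space
  idx <- sort(relToIdx(rel, upstreamLen))
  need <- as.integer(ceiling(q * length(idx)))
  widths <- idx[need:length(idx)] - idx[seq_len(length(idx) - need + 1L)]
  i <- which.min(widths)  # leftmost minimal window
  lo <- idx[i]; hi <- idx[i + need - 1L]
  new("PositionalDistribution", elementClass = element, histogram = hist,
      nSequences = as.integer(nSequences),
      hotspot = as.numeric(idxToRel(c(lo, hi), upstreamLen)), q = q)
}
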