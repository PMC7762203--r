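#' @include AllClasses.R coords.R
NULL

#' Build a position frequency matrix from aligned windows
#'
#' Columns are per-position base frequencies (rows A, C, G, U; DNA input
#' is transliterated) computed over the non-N bases of each column. A
#' column consisting only of N is set uniform and listed in
#' `metadata(pfm)$allN` -- it carries zero information.
#'
#' @param windows character vector of equal-length aligned strings over
#'   A, C, G, T, U, N.
#' @param elementClass label stored in the PFM.
#' @param anchor description of the alignment rule.
#' @return a [PFM].
#' @examples
#' buildPFM(c("AC", "CA"))
#' @export
buildPFM <- function(windows, elementClass = "element",
                     anchor = "element start") {
  stopifnot(length(windows) >= 1)
  windows <- vapply(windows, normalizeSeq, "", USE.NAMES = FALSE)
  L <- unique(nchar(windows))
  if (length(L) != 1L) stop("all windows must have the same length")
  chars <- matrix(unlist(strsplit(windows, "", fixed = TRUE)),
                  nrow = length(windows), byrow = TRUE)
  bad <- setdiff(unique(as.vector(chars)), c("A", "C", "G", "T", "N"))
  if (length(bad)) stop("invalid characters: ", paste(bad, collapse = ", "))
  mat <- matrix(0, nrow = 4L, ncol = L,
                dimnames = list(c("A", "C", "G", "U"), NULL))
  allN <- integer()
  for (j in seq_len(L)) {
    col <- chars[, j]
    col <- col[col != "N"]
    if (!length(col)) {
      mat[, j] <- 0.25
      allN <- c(allN, j)
    } else {
      counts <- c(A = sum(col == "A"), C = sum(col == "C"),
                  G = sum(col == "G"), U = sum(col == "T"))
      mat[, j] <- counts / sum(counts)
    }
  }
  pfm <- new("PFM", elementClass = elementClass, mat = mat,
             nSequences = length(windows), anchor = anchor)
  if (length(allN)) S4Vectors::metadata(pfm) <- list(allN = allN)
  pfm
}

#' Per-column information content of a PFM
#'
#' Shannon information in bits: `2 - H(column)` with entropy in base 2
#' (0 log 0 = 0). Range 0 (uniform) to 2 (a single base). No small-sample
#' correction is applied.
#'
#' @param pfm a [PFM].
#' @return numeric vector, one value per column.
#' @examples
#' ic <- informationContent(buildPFM(c("AA", "AC")))
#' @export
informationContent <- function(pfm) {
  apply(pfm@mat, 2, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
}

#' Consensus string of a PFM
#'
#' Column-wise argmax base (ties broken in A, C, G, U order).
#'
#' @param pfm a [PFM].
#' @return a string in the RNA alphabet.
#' @export
pfmConsensus <- function(pfm) {
  paste(rownames(pfm@mat)[apply(pfm@mat, 2, which.max)], collapse = "")
}

#' Export a PFM in MEME minimal motif format
#'
#' @param pfm a [PFM].
#' @param path output file.
#' @param background background letter frequencies for the header.
#' @return invisibly the path.
#' @export
writePFMMeme <- function(pfm, path, background = rep(0.25, 4)) {
  m <- pfm@mat
  lines <- c("MEME version 4", "",
             "ALPHABET= ACGU", "",
             sprintf("Background letter frequencies"),
             sprintf("A %.5f C %.5f G %.5f U %.5f",
                     background[1], background[2], background[3], background[4]),
             "",
             sprintf("MOTIF %s", pfm@elementClass),
             sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                     ncol(m), pfm@nSequences),
             vapply(seq_len(ncol(m)), function(j)
               sprintf(" %.6f %.6f %.6f %.6f", m[1, j], m[2, j], m[3, j], m[4, j]),
               ""))
  writeLines(lines, path)
  invisible(path)
}

#' Export a PFM as TSV
#'
#' @param pfm a [PFM].
#' @param path output file.
#' @return invisibly the path.
#' @export
writePFMTsv <- function(pfm, path) {
  df <- data.frame(position = seq_len(ncol(pfm@mat)), t(pfm@mat),
                   ic_bits = informationContent(pfm))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Schematic sequence logo of a PFM
#'
#' Letters stacked per column, scaled by frequency times column
#' information content (base-graphics rendering; heights are schematic,
#' not typographically exact).
#'
#' @param pfm a [PFM].
#' @param main plot title.
#' @return invisibly `NULL`; draws on the active device.
#' @export
plotLogo <- function(pfm, main = pfm@elementClass) {
  m <- pfm@mat
  ic <- informationContent(pfm)
  L <- ncol(m)
  cols <- c(A = "#2e7d32", C = "#1565c0", G = "#ef6c00", U = "#c62828")
  graphics::plot(NA, xlim = c(0.5, L + 0.5), ylim = c(0, 2),
                 xlab = "position", ylab = "bits", main = main, xaxs = "i")
  for (j in seq_len(L)) {
    h <- m[, j] * ic[j]
    ord <- order(h)  # tallest on top
    y0 <- 0
    for (b in ord) {
      if (h[b] <= 0) next
      graphics::text(j, y0 + h[b] / 2, rownames(m)[b],
                     col = cols[rownames(m)[b]],
                     cex = 0.6 + 2.2 * h[b] / 2, font = 2)
      y0 <- y0 + h[b]
    }
  }
  invisible(NULL)
}

#' Extract aligned element context windows from cassette assignments
#'
#' For each assignment placing `element`, takes the element's sequence
#' plus `flank` nt of context on both sides from the corresponding source
#' sequence. Assignments lacking the element or running past a sequence
#' end are skipped.
#'
#' @param assignments list of [CassetteAssignment] (NULLs allowed).
#' @param seqs character vector (or [DGRSet]) of the source windows, in
#'   the order the assignments refer to them.
#' @param element element class to align on.
#' @param flank context width in nt (default 10 on each side).
#' @return character vector of equal-length windows.
#' @export
elementWindows <- function(assignments, seqs, element = "PAS", flank = 10L) {
  getSeq <- function(k) {
    x <- seqs[[k]]
    if (is(x, "DGR")) dgrSequence(x) else as.character(x)
  }
  out <- character()
  for (k in seq_along(assignments)) {
    a <- assignments[[k]]
    if (is.null(a) || is.null(a@hits[[element]])) next
    h <- a@hits[[element]]
    s <- getSeq(k)
    lo <- h$idx_start - flank
    hi <- h$idx_start + h$length - 1L + flank
    if (lo < 1L || hi > nchar(s)) next
    out <- c(out, substr(s, lo, hi))
  }
  out
}

#' Emit a run-level report bundle
#'
#' Aggregates the artifacts of a pipeline run (hits, cassettes, positional
#' distributions, folds, validation, PFMs) into `report.json` plus TSV
#' side files in `outDir`. Sections not supplied are marked missing
#' rather than omitted. Output is deterministic for identical inputs
#' (no timestamps), so repeated emission is byte-identical.
#'
#' @param outDir output directory (created if needed).
#' @param hits optional hit table ([findElements()] output or data.frame).
#' @param cassettes optional list of [CassetteAssignment].
#' @param distributions optional list of [PositionalDistribution].
#' @param folds optional named list of [Fold].
#' @param validation optional [ValidationReport].
#' @param pfms optional list of [PFM].
#' @param meta named list of run metadata (seed, configuration, ...).
#' @return invisibly the report list.
#' @export
emitReport <- function(outDir, hits = NULL, cassettes = NULL,
                       distributions = NULL, folds = NULL,
                       validation = NULL, pfms = NULL, meta = list()) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  missingMark <- list(status = "missing")
  rep <- list(schema = "baculoPolyA-report/1",
              package_version = as.character(utils::packageVersion("baculoPolyA")),
              meta = meta)
  if (!is.null(hits)) {
    df <- as.data.frame(hits)
    utils::write.table(df, file.path(outDir, "hits.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    rep$hits <- list(status = "present", n = nrow(df),
                     by_class = as.list(table(df$element)))
  } else rep$hits <- missingMark
  if (!is.null(cassettes)) {
    tab <- cassetteTable(cassettes)
    utils::write.table(tab, file.path(outDir, "cassettes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    nel <- vapply(cassettes, function(a) if (is.null(a)) 0L else a@nElements, 0L)
    rep$cassettes <- list(status = "present", n = length(cassettes),
                          n_complete = sum(vapply(cassettes, function(a)
                            !is.null(a) && a@complete, TRUE)),
                          by_n_elements = as.list(table(nel)))
  } else rep$cassettes <- missingMark
  if (!is.null(distributions)) {
    rep$distributions <- list(status = "present", hotspots = lapply(
      distributions, function(d) list(element = d@elementClass,
                                      hotspot = unname(d@hotspot),
                                      n_hits = sum(d@histogram))))
  } else rep$distributions <- missingMark
  if (!is.null(folds)) {
    writeFolds(folds, file.path(outDir, "folds.txt"))
    rep$folds <- list(status = "present", n = length(folds),
                      mean_pairs = mean(vapply(folds, pairCount, 0L)))
  } else rep$folds <- missingMark
  if (!is.null(validation)) {
    utils::write.table(validation@summary,
                       file.path(outDir, "validation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    rep$validation <- list(status = "present", model = validation@model,
                           summary = validation@summary)
  } else rep$validation <- missingMark
  if (!is.null(pfms)) {
    for (p in pfms)
      writePFMTsv(p, file.path(outDir, sprintf("pfm_%s.tsv", p@elementClass)))
    rep$pfms <- list(status = "present",
                     consensus = lapply(pfms, pfmConsensus))
  } else rep$pfms <- missingMark
  jsonlite::write_json(rep, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(rep)
}
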