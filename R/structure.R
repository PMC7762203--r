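#' @include AllClasses.R coords.R
NULL

.pairOK <- function(a, b, wobble = FALSE) {
  wc <- (a == "A" & b == "T") | (a == "T" & b == "A") |
        (a == "C" & b == "G") | (a == "G" & b == "C")
  if (wobble) wc <- wc | (a == "G" & b == "T") | (a == "T" & b == "G")
  wc  # N pairs with nothing
}

#' Maximum base-pairing fold of a nucleotide sequence
#'
#' Computes a nested secondary structure maximizing the number of
#' Watson-Crick (optionally also G:U wobble) base pairs, subject to a
#' minimum loop length: a pair (i, j) requires `j - i > minLoop`.
#' Pseudoknots are excluded; N never pairs. This is a thermodynamics-free
#' fold: it optimizes pair count, not free energy, and is used here
#' because the downstream structural classification (stem/loop context of
#' the cleavage site) only consumes the pairing state, not energies. The
#' traceback is deterministic: the rightmost base of an interval is paired
#' whenever pairing achieves the optimum, with the leftmost admissible
#' partner on ties.
#'
#' @param sequence string over A, C, G, T, U, N (T and U equivalent).
#' @param minLoop minimum number of unpaired bases a pair must enclose
#'   (default 3).
#' @param wobble allow G:U pairs (off by default).
#' @return a [Fold].
#' @examples
#' fold <- foldMaxPairing("GGGAAACCC")
#' dotBracket(fold)   # "(((...)))"
#' @export
foldMaxPairing <- function(sequence, minLoop = 3L, wobble = FALSE) {
  s <- strsplit(normalizeSeq(sequence), "", fixed = TRUE)[[1]]
  n <- length(s)
  minLoop <- as.integer(minLoop)
  if (n > 2000L) stop("sequence longer than 2000 nt; fold a window instead")
  emptyFold <- function() new("Fold", sequence = paste(s, collapse = ""),
                              pairs = matrix(integer(), ncol = 2,
                                             dimnames = list(NULL, c("i", "j"))),
                              dotBracket = strrep(".", n),
                              minLoop = minLoop)
  if (n <= minLoop + 1L) return(emptyFold())
  # partners[[j]]: all k < j that can pair with j
  partners <- vector("list", n)
  for (j in seq_len(n)) {
    k <- seq_len(max(0L, j - minLoop - 1L))
    if (length(k)) partners[[j]] <- k[.pairOK(s[k], s[j], wobble)]
  }
  M <- matrix(0L, n, n)
  for (span in (minLoop + 1L):(n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- M[i, j - 1L]
      ks <- partners[[j]]
      ks <- ks[ks >= i]
      if (length(ks)) {
        left <- ifelse(ks > i, M[cbind(pmax(i, 1L), pmax(ks - 1L, 1L))], 0L)
        left[ks == i] <- 0L
        inner <- M[cbind(pmin(ks + 1L, j), rep(j - 1L, length(ks)))]
        inner[ks + 1L > j - 1L] <- 0L
        best <- max(best, max(left + 1L + inner))
      }
      M[i, j] <- best
    }
  }
  # deterministic traceback
  pairs <- matrix(integer(), ncol = 2)
  stack <- list(c(1L, n))
  out <- list()
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    while (j - i > minLoop) {
      target <- M[i, j]
      if (target == 0L) break
      ks <- partners[[j]]
      ks <- ks[ks >= i]
      paired <- FALSE
      if (length(ks)) {
        left <- vapply(ks, function(k) if (k > i) M[i, k - 1L] else 0L, 0L)
        inner <- vapply(ks, function(k) if (k + 1L <= j - 1L) M[k + 1L, j - 1L] else 0L, 0L)
        hit <- which(left + 1L + inner == target)
        if (length(hit)) {
          k <- ks[hit[1]]   # leftmost admissible partner
          out[[length(out) + 1L]] <- c(k, j)
          if (k > i && M[i, k - 1L] > 0L) stack[[length(stack) + 1L]] <- c(i, k - 1L)
          i <- k + 1L; j <- j - 1L
          paired <- TRUE
        }
      }
      if (!paired) j <- j - 1L
    }
  }
  if (length(out)) pairs <- do.call(rbind, out)
  colnames(pairs) <- c("i", "j")
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  db <- rep(".", n)
  if (nrow(pairs)) { db[pairs[, 1]] <- "("; db[pairs[, 2]] <- ")" }
  new("Fold", sequence = paste(s, collapse = ""), pairs = pairs,
      dotBracket = paste(db, collapse = ""), minLoop = minLoop)
}

#' Parse a dot-bracket string into a pair set
#'
#' @param db dot-bracket string over `(`, `)`, `.`.
#' @return integer matrix with columns i, j, sorted by i.
#' @export
parseDotBracket <- function(db) {
  x <- strsplit(db, "", fixed = TRUE)[[1]]
  if (!all(x %in% c("(", ")", ".")))
    stop("dot-bracket may only contain '(', ')' and '.'")
  stack <- integer()
  out <- list()
  for (p in seq_along(x)) {
    if (x[p] == "(") stack <- c(stack, p)
    else if (x[p] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket at position ", p)
      out[[length(out) + 1L]] <- c(stack[length(stack)], p)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket: unclosed '('")
  pairs <- if (length(out)) do.call(rbind, out)
           else matrix(integer(), ncol = 2)
  colnames(pairs) <- c("i", "j")
  pairs[order(pairs[, 1]), , drop = FALSE]
}

#' Complementary stretches between two sequences
#'
#' Finds every maximal stretch where a substring of `seqA` is the reverse
#' complement of a substring of `seqB` (optionally allowing G:U wobble
#' pairs). Maximal runs shorter than `minLen` are dropped; runs longer
#' than `maxLen` are reported once, clipped to `maxLen` from the run start
#' on the A side. Output is deterministic, sorted by (startA, startB).
#'
#' @param seqA,seqB nucleotide strings (T and U equivalent).
#' @param minLen,maxLen reported stretch length bounds (defaults 4 and 6).
#' @param allowWobble also count G:U as complementary.
#' @return a [S4Vectors::DataFrame] with columns `start_a`, `start_b`,
#'   `length`, `wobble_used`, `seq_a`, `seq_b`.
#' @export
findComplementarity <- function(seqA, seqB, minLen = 4L, maxLen = 6L,
                                allowWobble = FALSE) {
  if (minLen > maxLen) stop("minLen must not exceed maxLen")
  a <- strsplit(normalizeSeq(seqA), "", fixed = TRUE)[[1]]
  b <- strsplit(normalizeSeq(seqB), "", fixed = TRUE)[[1]]
  if (!length(a) || !length(b)) stop("both sequences must be non-empty")
  na <- length(a); nb <- length(b)
  P <- outer(seq_len(na), seq_len(nb),
             function(p, q) .pairOK(a[p], b[q], allowWobble))
  W <- outer(seq_len(na), seq_len(nb),
             function(p, q) .pairOK(a[p], b[q], TRUE) & !.pairOK(a[p], b[q], FALSE))
  rows <- list()
  for (d in 2:(na + nb)) {  # anti-diagonal: p + q = d
    ps <- max(1L, d - nb):min(na, d - 1L)
    if (!length(ps)) next
    vals <- P[cbind(ps, d - ps)]
    r <- rle(vals)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (t in which(r$values & r$lengths >= minLen)) {
      runLen <- r$lengths[t]
      i <- ps[starts[t]]                  # a-side start of the maximal run
      L <- min(runLen, maxLen)
      jEnd <- d - (i + L - 1L)            # b-side start of the clipped stretch
      idx <- cbind(i:(i + L - 1L), (d - i):jEnd)
      rows[[length(rows) + 1L]] <- data.frame(
        start_a = i, start_b = jEnd, length = L,
        wobble_used = allowWobble && any(W[idx]),
        seq_a = paste(a[i:(i + L - 1L)], collapse = ""),
        seq_b = paste(b[jEnd:(d - i)], collapse = ""))
    }
  }
  if (!length(rows))
    return(DataFrame(start_a = integer(), start_b = integer(),
                     length = integer(), wobble_used = logical(),
                     seq_a = character(), seq_b = character()))
  df <- do.call(rbind, rows)
  df <- df[order(df$start_a, df$start_b), , drop = FALSE]
  DataFrame(df, row.names = NULL)
}

#' Structural context of the cleavage site
#'
#' Classifies a position in a fold as `"stem"` (paired), `"loop"`
#' (unpaired but enclosed by at least one pair) or `"unpaired_external"`
#' (unpaired, outside every pair), and combines it with the modal pairing
#' state of the PAS span into a structure-class label such as
#' `"PAS-stem/CS-loop"`.
#'
#' @param fold a [Fold].
#' @param csPosition 1-based index of the cleavage position in the folded
#'   sequence.
#' @param pasSpan optional c(start, end) indices of the PAS within the
#'   folded sequence.
#' @return list with `cs_position`, `state`, `pas_state` (or `NA`) and
#'   `structure_class`.
#' @export
classifyCsContext <- function(fold, csPosition, pasSpan = NULL) {
  n <- nchar(fold@sequence)
  if (csPosition < 1L || csPosition > n)
    stop("csPosition out of range (1..", n, ")")
  p <- fold@pairs
  stateOf <- function(pos) {
    if (nrow(p) && any(p[, 1] == pos | p[, 2] == pos)) return("stem")
    if (nrow(p) && any(p[, 1] < pos & p[, 2] > pos)) return("loop")
    "unpaired_external"
  }
  cs <- stateOf(csPosition)
  pasState <- NA_character_
  if (!is.null(pasSpan)) {
    if (pasSpan[1] < 1L || pasSpan[2] > n || pasSpan[1] > pasSpan[2])
      stop("pasSpan out of range")
    st <- vapply(pasSpan[1]:pasSpan[2], stateOf, "")
    tab <- table(factor(st, levels = c("stem", "loop", "unpaired_external")))
    pasState <- names(tab)[which.max(tab)]  # ties: stem > loop > external
  }
  cls <- if (is.na(pasState)) paste0("CS-", cs)
         else sprintf("PAS-%s/CS-%s", pasState, cs)
  list(cs_position = as.integer(csPosition), state = cs,
       pas_state = pasState, structure_class = cls)
}

#' Write folds in Vienna-style text form
#'
#' One block per fold: `>id`, sequence, dot-bracket.
#'
#' @param folds named list of [Fold].
#' @param path output file.
#' @return invisibly the path.
#' @export
writeFolds <- function(folds, path) {
  ids <- names(folds)
  if (is.null(ids)) ids <- as.character(seq_along(folds))
  lines <- unlist(lapply(seq_along(folds), function(i)
    c(paste0(">", ids[i]), folds[[i]]@sequence, folds[[i]]@dotBracket)))
  writeLines(lines, path)
  invisible(path)
}
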