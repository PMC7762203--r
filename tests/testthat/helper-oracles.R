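# Independent oracles used by the property and acceptance tests. These are
# deliberately naive re-implementations that share no code with the package
# beyond its public API surface.

IUPAC_ORACLE <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

# per-position set-membership scan
naiveScanOracle <- function(sequence, pattern) {
  s <- strsplit(chartr("Uu", "Tt", toupper(sequence)), "")[[1]]
  p <- strsplit(toupper(pattern), "")[[1]]
  hits <- integer()
  if (length(s) >= length(p)) {
    for (i in seq_len(length(s) - length(p) + 1L)) {
      all_ok <- TRUE
      for (k in seq_along(p)) {
        if (!(s[i + k - 1L] %in% IUPAC_ORACLE[[p[k]]])) { all_ok <- FALSE; break }
      }
      if (all_ok) hits <- c(hits, i)
    }
  }
  hits
}

# maximum pair count by explicit enumeration of all nested structures
canPairOracle <- function(a, b)
  (a == "A" & b == "T") | (a == "T" & b == "A") |
  (a == "C" & b == "G") | (a == "G" & b == "C")

enumMaxPairs <- function(s, minLoop = 3L) {
  x <- strsplit(chartr("U", "T", toupper(s)), "")[[1]]
  rec <- function(avail) {
    if (length(avail) < 2L) return(0L)
    i <- avail[1]
    best <- rec(avail[-1])                       # leave i unpaired
    for (j in avail[avail - i > minLoop]) {
      if (canPairOracle(x[i], x[j])) {
        inside <- avail[avail > i & avail < j]
        outside <- avail[avail > j]
        best <- max(best, 1L + rec(inside) + rec(outside))
      }
    }
    best
  }
  rec(seq_along(x))
}

# exhaustive cassette search over every class-wise hit combination under
# the documented total order (count desc; deviation; PAS anchor proximity;
# PAS, CS, USE, UGUA, DSE, AuxDSE starts, absent = Inf). An optional
# element may only be placed when a window ties it to a placed partner.
bruteAssignOracle <- function(hits, model, upstreamLen = 100L) {
  hits <- as.data.frame(hits)
  cls <- c("USE", "UGUA", "PAS", "CS", "DSE", "AuxDSE")
  hl <- lapply(cls, function(cl) hits[hits$element == cl, , drop = FALSE])
  names(hl) <- cls
  opts <- lapply(hl, function(h) 0:nrow(h))
  grid <- do.call(expand.grid, opts)
  grid <- grid[grid$PAS > 0 & grid$CS > 0, , drop = FALSE]
  if (!nrow(grid)) return(NULL)
  val <- function(cl, col) {
    idx <- grid[[cl]]; idx[idx == 0] <- NA
    hl[[cl]][[col]][idx]
  }
  st <- lapply(cls, function(cl) val(cl, "idx_start")); names(st) <- cls
  ln <- lapply(cls, function(cl) val(cl, "length")); names(ln) <- cls
  rel <- hl$PAS$rel_start[grid$PAS]
  keep <- rel >= model@anchorWindow[1] & rel <= model@anchorWindow[2]
  dev <- rep(0, nrow(grid))
  anchored <- matrix(FALSE, nrow(grid), length(cls), dimnames = list(NULL, cls))
  for (nm in names(model@windows)) {
    w <- model@windows[[nm]]
    ab <- strsplit(nm, "->", fixed = TRUE)[[1]]
    d <- if (w$metric == "gap")
      st[[ab[2]]] - (st[[ab[1]]] + ln[[ab[1]]] - 1) - 1
    else st[[ab[2]]] - st[[ab[1]]]
    bad <- !is.na(d) & (d < w$min | d > w$max)
    keep <- keep & !bad
    dd <- abs(d - (w$min + w$max) / 2); dd[is.na(dd)] <- 0
    dev <- dev + dd
    both <- grid[[ab[1]]] > 0 & grid[[ab[2]]] > 0
    anchored[, ab[1]] <- anchored[, ab[1]] | both
    anchored[, ab[2]] <- anchored[, ab[2]] | both
  }
  for (cl in cls) keep <- keep & !(grid[[cl]] > 0 & !anchored[, cl])
  if (!any(keep)) return(NULL)
  grid <- grid[keep, , drop = FALSE]
  dev <- dev[keep]; rel <- rel[keep]
  st <- lapply(st, function(v) v[keep])
  cnt <- rowSums(!is.na(do.call(cbind, st)))
  inf <- function(v) ifelse(is.na(v), Inf, v)
  o <- order(-cnt, dev, abs(rel), st$PAS, st$CS,
             inf(st$USE), inf(st$UGUA), inf(st$DSE), inf(st$AuxDSE))[1]
  sel <- grid[o, ]
  placed <- list()
  for (cl in cls) {
    if (sel[[cl]] > 0) {
      h <- hl[[cl]][sel[[cl]], ]
      placed[[cl]] <- list(idx_start = h$idx_start, rel_start = h$rel_start,
                           motif = h$motif, length = h$length)
    }
  }
  list(placed = placed, dev = dev[o], n = cnt[o])
}

# brute-force maximal complementary stretches by substring comparison
DNA_COMP_ORACLE <- c(A = "T", C = "G", G = "C", T = "A")

bruteComplementOracle <- function(a, b, minLen = 4L, maxLen = 6L) {
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  pairok <- function(x, y) !is.na(DNA_COMP_ORACLE[x]) && DNA_COMP_ORACLE[x] == y
  rows <- list()
  for (i in seq_along(av)) for (jend in seq_along(bv)) {
    if (!pairok(av[i], bv[jend])) next
    if (i > 1 && jend < length(bv) && pairok(av[i - 1], bv[jend + 1])) next
    L <- 0L
    while (i + L <= length(av) && jend - L >= 1 && pairok(av[i + L], bv[jend - L]))
      L <- L + 1L
    if (L < minLen) next
    Lc <- min(L, maxLen)
    rows[[length(rows) + 1L]] <-
      data.frame(start_a = i, start_b = jend - Lc + 1L, length = Lc)
  }
  if (!length(rows))
    return(data.frame(start_a = integer(), start_b = integer(),
                      length = integer()))
  d <- unique(do.call(rbind, rows))
  d <- d[order(d$start_a, d$start_b), , drop = FALSE]
  rownames(d) <- NULL
  d
}

# shared fixture builders -------------------------------------------------

randomDNA <- function(n, alphabet = c("A", "C", "G", "T"))
  paste(sample(alphabet, n, replace = TRUE), collapse = "")

auRichComposition <- function() c(A = 0.4, C = 0.1, G = 0.1, T = 0.4)

# a designed hairpin window: A fillers, all-G left arm, CA-led loop,
# all-C right arm; the unique maximum pairing is the full arm helix
designedHairpin <- function(fillerLen, loopTailLen) {
  seq <- paste0(strrep("A", fillerLen), "GGGGG", "CA",
                strrep("A", loopTailLen), "CCCCC", strrep("A", fillerLen))
  list(sequence = seq,
       pasSpan = c(fillerLen + 1L, fillerLen + 5L),   # left arm
       csPoint = fillerLen + 8L)                      # base 3' of the CA
}
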