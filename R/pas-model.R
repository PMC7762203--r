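#' @include AllClasses.R coords.R motif-scan.R
NULL

#' Load or build a positional polyadenylation model
#'
#' The two shipped presets encode the positional models for baculovirus
#' 3'-end processing signals:
#'
#' * `improved2020`: USE 5-30 nt upstream of the PAS; PAS starting between
#'   12 nt upstream and 7 nt downstream of the stop codon, 0-75 nt upstream
#'   of the cleavage site; DSE 21-29 nt downstream of the PAS and 0-50 nt
#'   downstream of the CS; UGUA immediately upstream of / overlapping the
#'   PAS; G-rich Aux-DSE downstream of the DSE.
#' * `initial2003`: PAS 0-50 nt downstream of the stop codon and 12-42 nt
#'   upstream of the CS; CS 4-40 nt upstream of the DSE; USE 5-30 nt
#'   upstream of the PAS.
#'
#' Distances are gaps (nucleotides strictly between two elements) except
#' UGUA->PAS, which is the start-to-start offset so that overlap is
#' expressible. Presets live as YAML under `inst/extdata/models/` and any
#' YAML file of the same shape can be loaded as a custom model.
#'
#' @param name `"improved2020"`, `"initial2003"`, or a path to a YAML file.
#' @return a validated [ModelSpec].
#' @examples
#' modelSpec("improved2020")
#' @export
modelSpec <- function(name = "improved2020") {
  path <- if (file.exists(name)) name else
    system.file("extdata", "models", paste0(name, ".yaml"),
                package = "baculoPolyA")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown model preset and no such file: ", name)
  y <- yaml::read_yaml(path)
  windows <- lapply(y$windows, function(w)
    list(min = as.integer(w$min), max = as.integer(w$max),
         metric = if (is.null(w$metric)) "gap" else w$metric))
  new("ModelSpec", name = y$name, windows = windows,
      anchorWindow = as.numeric(y$anchor_window),
      required = as.character(y$required),
      optional = as.character(y$optional))
}

# distance of a placed pair under a window; hits are list(idx_start, length)
.windowDistance <- function(hitA, hitB, metric) {
  elementDistance(hitA$idx_start, hitA$length, hitB$idx_start, metric)
}

.windowCenter <- function(w) (w$min + w$max) / 2

#' Assemble element hits into a cassette under a positional model
#'
#' Searches the hits of one DGR for the placement of element classes that
#' (1) maximizes the number of classes placed consistently with every
#' distance window among them, then (2) minimizes the summed deviation of
#' the realized distances from their window centres, then (3) prefers the
#' PAS closest to the stop-codon anchor, then (4) the leftmost CS, and
#' finally the leftmost hit per remaining class (USE, UGUA, DSE, AuxDSE
#' order) -- a deterministic total order. PAS and CS (and any other class
#' the model marks required) must be placeable; otherwise `NULL` is
#' returned. An optional element is only placed when at least one distance
#' window ties it to another placed element (so an Aux-DSE cannot float
#' free without a DSE).
#'
#' @param hits hit table from [findElements()] for a single DGR.
#' @param model a [ModelSpec].
#' @param dgrId identifier recorded in the assignment.
#' @param upstreamLen coordinate anchor of the DGR (100 for full DGRs).
#' @return a [CassetteAssignment], or `NULL` when no consistent placement
#'   of the required classes exists.
#' @export
assignCassette <- function(hits, model, dgrId = "", upstreamLen = 100L) {
  hl <- .hitsByClass(hits)
  wn <- model@windows
  pas <- hl$PAS
  if (!is.null(pas)) {
    inAnchor <- pas$rel_start >= model@anchorWindow[1] &
      pas$rel_start <= model@anchorWindow[2]
    pas <- pas[inAnchor, , drop = FALSE]
  }
  cs <- hl$CS
  if (is.null(pas) || !nrow(pas) || is.null(cs) || !nrow(cs)) return(NULL)

  pickBest <- function(cand, dist, w) {
    ok <- which(dist >= w$min & dist <= w$max)
    if (!length(ok)) return(NULL)
    dev <- abs(dist[ok] - .windowCenter(w))
    sel <- ok[order(dev, cand$idx_start[ok])[1]]
    list(row = cand[sel, , drop = FALSE], dev = min(dev))
  }
  hitRec <- function(row) list(idx_start = row$idx_start[1],
                               rel_start = row$rel_start[1],
                               motif = row$motif[1],
                               length = row$length[1])

  best <- NULL
  bestKey <- NULL
  for (p in seq_len(nrow(pas))) {
    ph <- hitRec(pas[p, , drop = FALSE])
    # optional picks that depend only on the PAS
    useBest <- NULL; uguaBest <- NULL
    if (!is.null(hl$USE) && !is.null(wn[["USE->PAS"]])) {
      w <- wn[["USE->PAS"]]
      d <- elementDistance(hl$USE$idx_start, hl$USE$length, ph$idx_start, w$metric)
      useBest <- pickBest(hl$USE, d, w)
    }
    if (!is.null(hl$UGUA) && !is.null(wn[["UGUA->PAS"]])) {
      w <- wn[["UGUA->PAS"]]
      d <- elementDistance(hl$UGUA$idx_start, hl$UGUA$length, ph$idx_start, w$metric)
      uguaBest <- pickBest(hl$UGUA, d, w)
    }
    for (q in seq_len(nrow(cs))) {
      ch <- hitRec(cs[q, , drop = FALSE])
      devPC <- 0
      if (!is.null(wn[["PAS->CS"]])) {
        w <- wn[["PAS->CS"]]
        d <- .windowDistance(ph, ch, w$metric)
        if (d < w$min || d > w$max) next
        devPC <- abs(d - .windowCenter(w))
      }
      # DSE candidates consistent with both PAS and CS
      dseOptions <- list(NULL)
      if (!is.null(hl$DSE)) {
        keep <- rep(TRUE, nrow(hl$DSE))
        devD <- numeric(nrow(hl$DSE))
        for (key in c("PAS->DSE", "CS->DSE")) {
          if (is.null(wn[[key]])) next
          w <- wn[[key]]
          from <- if (key == "PAS->DSE") ph else ch
          d <- elementDistance(from$idx_start, from$length,
                               hl$DSE$idx_start, w$metric)
          keep <- keep & d >= w$min & d <= w$max
          devD <- devD + abs(d - .windowCenter(w))
        }
        for (r in which(keep))
          dseOptions[[length(dseOptions) + 1L]] <-
            list(row = hl$DSE[r, , drop = FALSE], dev = devD[r])
      }
      for (dse in dseOptions) {
        auxBest <- NULL
        if (!is.null(dse) && !is.null(hl$AuxDSE) &&
            !is.null(wn[["DSE->AuxDSE"]])) {
          w <- wn[["DSE->AuxDSE"]]
          dh <- hitRec(dse$row)
          d <- elementDistance(dh$idx_start, dh$length,
                               hl$AuxDSE$idx_start, w$metric)
          auxBest <- pickBest(hl$AuxDSE, d, w)
        }
        placed <- list(PAS = ph, CS = ch)
        dev <- devPC
        if (!is.null(useBest)) { placed$USE <- hitRec(useBest$row); dev <- dev + useBest$dev }
        if (!is.null(uguaBest)) { placed$UGUA <- hitRec(uguaBest$row); dev <- dev + uguaBest$dev }
        if (!is.null(dse)) { placed$DSE <- hitRec(dse$row); dev <- dev + dse$dev }
        if (!is.null(auxBest)) { placed$AuxDSE <- hitRec(auxBest$row); dev <- dev + auxBest$dev }
        key <- .assignmentKey(placed, dev)
        if (is.null(bestKey) || .keyLess(key, bestKey)) {
          bestKey <- key
          best <- placed
          attr(best, "deviation") <- dev
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  if (!all(model@required %in% names(best))) return(NULL)
  .buildAssignment(best, attr(best, "deviation"), model, dgrId)
}

# total-order key: fewer elements lose; then deviation; then PAS anchor
# proximity; then PAS, CS, USE, UGUA, DSE, AuxDSE start (absent = +Inf)
.assignmentKey <- function(placed, dev) {
  idxOf <- function(cl) if (is.null(placed[[cl]])) Inf else placed[[cl]]$idx_start
  c(-length(placed), dev, abs(placed$PAS$rel_start),
    placed$PAS$idx_start, placed$CS$idx_start,
    idxOf("USE"), idxOf("UGUA"), idxOf("DSE"), idxOf("AuxDSE"))
}

.keyLess <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

.hitsByClass <- function(hits) {
  hits <- as.data.frame(hits)
  split(hits, hits$element)
}

.buildAssignment <- function(placed, dev, model, dgrId) {
  placed <- placed[intersect(ELEMENT_CLASSES, names(placed))]
  sw <- .satisfiedWindows(placed, model)
  new("CassetteAssignment", dgrId = as.character(dgrId), hits = placed,
      nElements = length(placed), deviation = dev,
      satisfiedWindows = sw,
      complete = all(ELEMENT_CLASSES %in% names(placed)))
}

.satisfiedWindows <- function(placed, model) {
  rows <- list()
  for (nm in names(model@windows)) {
    cls <- strsplit(nm, "->", fixed = TRUE)[[1]]
    a <- placed[[cls[1]]]; b <- placed[[cls[2]]]
    if (is.null(a) || is.null(b)) next
    w <- model@windows[[nm]]
    d <- .windowDistance(a, b, w$metric)
    rows[[length(rows) + 1L]] <-
      data.frame(window = nm, distance = d, min = w$min, max = w$max)
  }
  if (!length(rows))
    return(data.frame(window = character(), distance = integer(),
                      min = integer(), max = integer()))
  do.call(rbind, rows)
}

#' Independently verify a cassette assignment against its model
#'
#' Recomputes, from the recorded element positions alone, every distance
#' window among the placed classes plus the PAS anchor window, and checks
#' the recorded deviation. Used as the soundness check on the search in
#' [assignCassette()]; shares no code with it beyond the distance metric
#' definition.
#'
#' @param assignment a [CassetteAssignment].
#' @param model the [ModelSpec] it was produced under.
#' @return `TRUE`, or a character vector of violations.
#' @export
checkAssignment <- function(assignment, model) {
  placed <- assignment@hits
  bad <- character()
  pr <- placed$PAS$rel_start
  if (pr < model@anchorWindow[1] || pr > model@anchorWindow[2])
    bad <- c(bad, sprintf("PAS rel %+d outside anchor window", pr))
  dev <- 0
  for (nm in names(model@windows)) {
    cls <- strsplit(nm, "->", fixed = TRUE)[[1]]
    a <- placed[[cls[1]]]; b <- placed[[cls[2]]]
    if (is.null(a) || is.null(b)) next
    w <- model@windows[[nm]]
    d <- elementDistance(a$idx_start, a$length, b$idx_start, w$metric)
    if (d < w$min || d > w$max)
      bad <- c(bad, sprintf("%s distance %d outside [%d, %d]", nm, d, w$min, w$max))
    dev <- dev + abs(d - (w$min + w$max) / 2)
  }
  if (abs(dev - assignment@deviation) > 1e-9)
    bad <- c(bad, sprintf("recorded deviation %.3f != recomputed %.3f",
                          assignment@deviation, dev))
  if (length(bad)) bad else TRUE
}

#' AU content of a window around a DGR position
#'
#' Fraction of A/U (A/T on the DNA strand) bases in the `2*halfwidth`-nt
#' window centred on a relative position, clipped to the DGR.
#'
#' @param dgr a [DGR] or a plain sequence string.
#' @param center relative coordinate of the window centre (no position 0).
#' @param halfwidth half the window width in nt (default 20, a 40-nt
#'   window).
#' @param upstreamLen coordinate anchor when `dgr` is a string.
#' @return the AU fraction; errors if the window misses the DGR entirely.
#' @export
auContent <- function(dgr, center, halfwidth = 20L, upstreamLen = 100L) {
  if (is(dgr, "DGR")) { s <- dgr@sequence; up <- dgr@upstreamLen }
  else { s <- normalizeSeq(dgr); up <- as.integer(upstreamLen) }
  ci <- relToIdx(center, up)
  lo <- max(1L, ci - halfwidth)
  hi <- min(nchar(s), ci + halfwidth - 1L)
  if (lo > hi) stop("window does not intersect the DGR")
  x <- strsplit(substr(s, lo, hi), "", fixed = TRUE)[[1]]
  mean(x %in% c("A", "T"))
}

#' Detection of the cassette model across positive and control sets
#'
#' Runs [findElements()] + [assignCassette()] over every sequence of every
#' named set and tabulates, per set, how many sequences yielded an
#' assignment placing 0..6 element classes. The detection fraction is the
#' fraction of sequences with a *complete* cassette (all six classes).
#'
#' @param sets named list; each entry a [DGRSet], a list of [DGR]s, or a
#'   character vector of window sequences.
#' @param model a [ModelSpec].
#' @param defs element definitions ([elementDefs()]).
#' @param upstreamLen anchor for character-vector sets.
#' @return a [ValidationReport]. Sequences appearing in several sets are
#'   counted in each, with a warning.
#' @export
classifySets <- function(sets, model, defs = elementDefs(),
                         upstreamLen = 100L) {
  stopifnot(length(sets) > 0, !is.null(names(sets)))
  keyOf <- function(x) {
    if (is(x, "DGRSet") || is.list(x))
      vapply(x, function(d) if (is(d, "DGR")) dgrSequence(d) else as.character(d), "")
    else as.character(x)
  }
  keys <- lapply(sets, keyOf)
  for (i in seq_along(keys)) for (j in seq_len(i - 1L)) {
    if (length(intersect(keys[[i]], keys[[j]])))
      warning(sprintf("sets '%s' and '%s' share sequences; counted in each",
                      names(sets)[i], names(sets)[j]))
  }
  countsByN <- matrix(0L, nrow = length(sets), ncol = 7L,
                      dimnames = list(names(sets), as.character(0:6)))
  for (si in seq_along(sets)) {
    set <- sets[[si]]
    n <- length(set)
    for (k in seq_len(n)) {
      x <- set[[k]]
      h <- if (is(x, "DGR")) findElements(x, defs)
           else findElements(as.character(x), defs, upstreamLen = upstreamLen)
      a <- assignCassette(h, model, dgrId = as.character(k),
                          upstreamLen = upstreamLen)
      nel <- if (is.null(a)) 0L else a@nElements
      countsByN[si, nel + 1L] <- countsByN[si, nel + 1L] + 1L
    }
  }
  nseq <- vapply(sets, length, 0L)
  ncomp <- countsByN[, "6"]
  summary <- data.frame(set = names(sets), n = as.integer(nseq),
                        n_complete = as.integer(ncomp),
                        detection_fraction = ifelse(nseq > 0, ncomp / nseq, NA_real_),
                        row.names = NULL)
  new("ValidationReport", summary = summary, countsByN = countsByN,
      model = model@name)
}

#' Tabulate a list of cassette assignments
#'
#' Flattens assignments (as produced by [assignCassette()] over many DGRs)
#' into one row per placed element, convenient for export and reporting.
#'
#' @param assignments list of [CassetteAssignment] (NULLs allowed and
#'   skipped).
#' @return a data.frame with columns `dgr_id`, `element`, `motif`,
#'   `rel_start`, `length`, `n_elements`, `complete`, `deviation`.
#' @export
cassetteTable <- function(assignments) {
  rows <- list()
  for (a in assignments) {
    if (is.null(a)) next
    for (cl in names(a@hits)) {
      h <- a@hits[[cl]]
      rows[[length(rows) + 1L]] <- data.frame(
        dgr_id = a@dgrId, element = cl, motif = h$motif,
        rel_start = h$rel_start, length = h$length,
        n_elements = a@nElements, complete = a@complete,
        deviation = a@deviation)
    }
  }
  if (!length(rows))
    return(data.frame(dgr_id = character(), element = character(),
                      motif = character(), rel_start = integer(),
                      length = integer(), n_elements = integer(),
                      complete = logical(), deviation = numeric()))
  do.call(rbind, rows)
}
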