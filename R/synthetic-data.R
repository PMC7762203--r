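#' @include AllClasses.R coords.R pas-model.R genome-io.R
NULL

#' Default background base composition (59% AU)
#'
#' The genome-wide AU content reported for AcMNPV is 59%; the default
#' background draws A/T at 0.295 each and G/C at 0.205 each. Configurable
#' everywhere it is used.
#' @return named numeric over A, C, G, T.
#' @export
defaultComposition <- function() c(A = 0.295, C = 0.205, G = 0.205, T = 0.295)

.bgVec <- function(n, composition) {
  if (n == 0L) return(character())
  sample(names(composition), n, replace = TRUE, prob = composition)
}

#' Generate a random background sequence
#'
#' @param length number of nucleotides (>= 0).
#' @param composition named base frequencies (A, C, G, T) summing to 1.
#' @param seed optional integer seed; when `NULL` the current RNG stream
#'   is used.
#' @return a string over A, C, G, T; reproducible for a fixed seed.
#' @examples
#' generateBackground(10, c(A = 1, C = 0, G = 0, T = 0), seed = 1)
#' @export
generateBackground <- function(length, composition = defaultComposition(),
                               seed = NULL) {
  if (length < 0) stop("length must be non-negative")
  stopifnot(identical(sort(names(composition)), c("A", "C", "G", "T")),
            abs(sum(composition) - 1) < 1e-9)
  if (!is.null(seed)) set.seed(seed)
  paste(.bgVec(as.integer(length), composition), collapse = "")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# integer positions covered by an element starting at `start` with length `len`
.span <- function(start, len) start:(start + len - 1L)

.overlaps <- function(start, len, lo, hi) start <= hi && (start + len - 1L) >= lo

# uniform draw from a set, immune to R's sample(scalar) expansion
.draw <- function(v) if (length(v) == 1L) v else v[sample.int(length(v), 1L)]

#' Plant one polyadenylation cassette into a synthetic DGR
#'
#' Builds a `upstream + downstream` (default 450) nt window: background
#' sequence, a stop codon at relative -3..-1, an AU-enriched 40-nt window
#' centred on the PAS, and verbatim USE / UGUA / PAS / CS / DSE / Aux-DSE
#' motifs whose inter-element distances are drawn independently and
#' uniformly from the model's windows. The planted PAS start avoids
#' overlapping the fixed stop codon (the motifs must remain verbatim), so
#' within the anchor window some relative positions are never drawn; the
#' model window itself is unchanged.
#'
#' @param model the [ModelSpec] whose windows distances are drawn from.
#' @param auFrac target AU fraction of the 40-nt PAS-centred window
#'   (default 0.80); enforced to within 0.1 by resampling.
#' @param background base composition outside the AU window.
#' @param pasMotifProbs sampling weights of the PAS hexamer (AAUAAA is
#'   drawn at 0.8, the lepidopteran alternative AUUAAA at 0.2).
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @param upstream,downstream window geometry (100/350 by default).
#' @return list with `sequence` (the window string), `truth` (data.frame
#'   `element`, `rel_pos`, `idx`, `sequence`) and `stopCodon`.
#' @export
plantCassette <- function(model = modelSpec("improved2020"), auFrac = 0.8,
                          background = defaultComposition(),
                          pasMotifProbs = c(AATAAA = 0.8, ATTAAA = 0.2),
                          seed = NULL, upstream = 100L, downstream = 350L) {
  if (!is.null(seed)) set.seed(seed)
  up <- as.integer(upstream); n <- up + as.integer(downstream)
  wn <- model@windows
  needed <- c("USE->PAS", "UGUA->PAS", "CS->DSE", "DSE->AuxDSE")
  missing <- setdiff(needed, names(wn))
  if (length(missing) || !("PAS->DSE" %in% names(wn) || "PAS->CS" %in% names(wn)))
    stop("model lacks windows needed to plant a full cassette: ",
         paste(missing, collapse = ", "))
  stopLo <- up - 2L; stopHi <- up  # stop codon indices (rel -3..-1)

  pasMotif <- sample(names(pasMotifProbs), 1L, prob = pasMotifProbs)
  pasLen <- nchar(pasMotif)

  # PAS start candidates: anchor window minus stop-codon overlap, and with
  # room for a non-overlapping UGUA and USE
  anchorRel <- setdiff(seq(model@anchorWindow[1], model@anchorWindow[2]), 0L)
  cand <- relToIdx(anchorRel, up)
  cand <- cand[!vapply(cand, .overlaps, TRUE, len = pasLen,
                       lo = stopLo, hi = stopHi)]
  wU <- wn[["UGUA->PAS"]]; wUse <- wn[["USE->PAS"]]
  layoutFor <- function(pasStart) {
    # feasible UGUA offsets: inside window, not overlapping PAS or stop
    o <- seq(max(wU$min, 4L), wU$max)    # offset >= 4: TGTA must clear the PAS
    o <- o[!vapply(pasStart - o, .overlaps, TRUE, len = 4L,
                   lo = stopLo, hi = stopHi)]
    o <- o[pasStart - o >= 1L]
    # feasible USE gaps: window, clear of stop, leaving room for UGUA
    g <- seq(wUse$min, wUse$max)
    useStart <- pasStart - g - 4L
    keep <- useStart >= 1L &
      !vapply(seq_along(g), function(k)
        .overlaps(useStart[k], 4L, stopLo, stopHi), TRUE)
    g <- g[keep]
    # USE must end before the leftmost admissible UGUA can start
    if (!length(o) || !length(g)) return(NULL)
    ok <- expand.grid(g = g, o = o)
    ok <- ok[ok$o <= ok$g, , drop = FALSE]   # UGUA strictly right of USE
    if (!nrow(ok)) return(NULL)
    ok
  }
  feas <- lapply(cand, layoutFor)
  cand <- cand[!vapply(feas, is.null, TRUE)]
  feas <- feas[!vapply(feas, is.null, TRUE)]
  if (!length(cand))
    stop("unsatisfiable windows: no PAS start admits USE->PAS and UGUA->PAS ",
         "placements clear of the stop codon")
  pick <- sample.int(length(cand), 1L)
  pasStart <- cand[pick]
  # uniform over feasible USE gaps, then uniform UGUA offset given the gap
  lay <- feas[[pick]]
  g1 <- .draw(unique(lay$g))
  o <- .draw(lay$o[lay$g == g1])
  useStart <- pasStart - g1 - 4L
  uguaStart <- pasStart - o
  pasEnd <- pasStart + pasLen - 1L

  # downstream geometry: DSE via PAS->DSE when the model has it (improved
  # model), otherwise sequentially PAS->CS then CS->DSE (initial model)
  csClear <- function(cs) !vapply(cs, .overlaps, TRUE, len = 2L,
                                  lo = stopLo, hi = stopHi)
  if (!is.null(wn[["PAS->DSE"]])) {
    g2 <- .draw(seq(wn[["PAS->DSE"]]$min, wn[["PAS->DSE"]]$max))
    dseStart <- pasEnd + g2 + 1L
    csLo <- max(pasEnd + 1L, dseStart - wn[["CS->DSE"]]$max - 2L)
    if (!is.null(wn[["PAS->CS"]]))
      csLo <- max(csLo, pasEnd + wn[["PAS->CS"]]$min + 1L)
    csHi <- dseStart - wn[["CS->DSE"]]$min - 2L
    csOpts <- if (csLo > csHi) integer() else (csLo:csHi)[csClear(csLo:csHi)]
    if (!length(csOpts))
      stop("unsatisfiable windows: PAS->DSE vs CS->DSE leaves no room for the CS")
    csStart <- .draw(csOpts)
  } else {
    gpcOpts <- seq(wn[["PAS->CS"]]$min, wn[["PAS->CS"]]$max)
    gpcOpts <- gpcOpts[csClear(pasEnd + gpcOpts + 1L)]
    if (!length(gpcOpts))
      stop("unsatisfiable windows: PAS->CS leaves no room for the CS")
    csStart <- pasEnd + .draw(gpcOpts) + 1L
    gcd <- .draw(seq(wn[["CS->DSE"]]$min, wn[["CS->DSE"]]$max))
    dseStart <- csStart + 2L + gcd
  }
  dseMotif <- .draw(c("TTTTT", "GTTGT"))
  dseEnd <- dseStart + 4L
  g3 <- .draw(seq(wn[["DSE->AuxDSE"]]$min, wn[["DSE->AuxDSE"]]$max))
  auxStart <- dseEnd + g3 + 1L
  if (auxStart + 5L > n)
    stop("unsatisfiable windows: Aux-DSE beyond the DGR (needs <= ", n, " nt)")

  x <- .bgVec(n, background)
  # AU enrichment of the 40-nt window centred on the PAS
  auComp <- c(A = auFrac / 2, C = (1 - auFrac) / 2,
              G = (1 - auFrac) / 2, T = auFrac / 2)
  ci <- pasStart + 3L
  auWin <- max(1L, ci - 20L):min(n, ci + 19L)
  x[auWin] <- .bgVec(length(auWin), auComp)
  stopCodon <- sample(STOP_CODONS, 1L)
  write1 <- function(x, start, motif) {
    x[.span(start, nchar(motif))] <- strsplit(motif, "", fixed = TRUE)[[1]]
    x
  }
  plant <- function(x) {
    x <- write1(x, stopLo, stopCodon)
    x <- write1(x, useStart, "TTTT")
    x <- write1(x, uguaStart, "TGTA")
    x <- write1(x, pasStart, pasMotif)
    x <- write1(x, csStart, "CA")
    x <- write1(x, dseStart, dseMotif)
    write1(x, auxStart, "GGGGGG")
  }
  x <- plant(x)
  for (try in 1:25) {   # enforce AU >= auFrac - 0.1 by resampling background
    if (mean(x[auWin] %in% c("A", "T")) >= auFrac - 0.1) break
    x[auWin] <- .bgVec(length(auWin), auComp)
    x <- plant(x)
  }
  truth <- data.frame(
    element = c("USE", "UGUA", "PAS", "CS", "DSE", "AuxDSE"),
    idx = c(useStart, uguaStart, pasStart, csStart, dseStart, auxStart),
    sequence = c("TTTT", "TGTA", pasMotif, "CA", dseMotif, "GGGGGG"))
  truth$rel_pos <- idxToRel(truth$idx, up)
  truth <- truth[, c("element", "rel_pos", "idx", "sequence")]
  list(sequence = paste(x, collapse = ""), truth = truth,
       stopCodon = stopCodon)
}

#' Simulation parameters
#'
#' See [SimParams-class] for the meaning of each field; this constructor
#' applies the study defaults (AU 0.80 around the PAS, 59% AU background,
#' AAUAAA:AUUAAA = 0.8:0.2, improved positional model).
#'
#' @param nGenomes,genesPerGenome layout counts.
#' @param genomeLength `NA` = just large enough.
#' @param fracMinusStrand,auFracCassette,cassetteRate fractions in `[0,1]`.
#' @param backgroundComposition named A/C/G/T frequencies.
#' @param model a [ModelSpec].
#' @param geneLengthRange gene length bounds (nt, rounded to codons).
#' @param pasMotifProbs PAS hexamer sampling weights.
#' @param seed integer seed.
#' @return a validated [SimParams].
#' @export
SimParams <- function(nGenomes = 5L, genesPerGenome = 30L, genomeLength = NA,
                      fracMinusStrand = 0.5, auFracCassette = 0.8,
                      backgroundComposition = defaultComposition(),
                      model = modelSpec("improved2020"), cassetteRate = 1.0,
                      geneLengthRange = c(300, 1500),
                      pasMotifProbs = c(AATAAA = 0.8, ATTAAA = 0.2),
                      seed = 1L) {
  new("SimParams", nGenomes = as.integer(nGenomes),
      genesPerGenome = as.integer(genesPerGenome),
      genomeLength = as.numeric(genomeLength),
      fracMinusStrand = fracMinusStrand, auFracCassette = auFracCassette,
      backgroundComposition = backgroundComposition[c("A", "C", "G", "T")],
      model = model, cassetteRate = cassetteRate,
      geneLengthRange = as.numeric(geneLengthRange),
      pasMotifProbs = pasMotifProbs, seed = as.integer(seed))
}

# a stop-free random coding body of `len` nt ending in `stopCodon`
.codingSeq <- function(len, stopCodon, composition) {
  ncod <- len %/% 3L
  body <- character(ncod - 1L)
  for (i in seq_len(ncod - 1L)) {
    repeat {
      cod <- paste(.bgVec(3L, composition), collapse = "")
      if (!cod %in% STOP_CODONS) break
    }
    body[i] <- cod
  }
  body[1] <- "ATG"
  paste0(paste(body, collapse = ""), stopCodon)
}

#' Generate a set of annotated synthetic genomes with planted cassettes
#'
#' Lays out `genesPerGenome` genes per genome on both strands, each with a
#' private 450-nt downstream buffer; a fraction `cassetteRate` of genes
#' receives a full planted polyadenylation cassette (via
#' [plantCassette()]), the rest plain background. The terminal
#' `upstream` nt of a planted gene mirror the cassette's upstream window
#' (the positional model places PAS bases inside the CDS end); the rest of
#' each gene body is stop-free random codons so coding control sequences
#' can be harvested from the same files. Circular genomes are rotated so
#' that one gene's DGR wraps the origin. Writes one FASTA + GFF3 pair per
#' genome, a ground-truth TSV and a JSON parameter sidecar; outputs are
#' byte-identical for identical parameters.
#'
#' @param params a [SimParams].
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with `genomes` (list of [GenomeRecord]),
#'   `truth` (data.frame: genome_id, gene_id, strand, planted, element,
#'   rel_pos, sequence) and `files`.
#' @export
generateGenomeSet <- function(params, outDir) {
  stopifnot(is(params, "SimParams"))
  set.seed(params@seed)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  comp <- params@backgroundComposition
  genomes <- list()
  truthRows <- list()
  files <- character()
  for (gi in seq_len(params@nGenomes)) {
    gid <- sprintf("synthgenome%03d", gi)
    segs <- list()
    geneRows <- list()
    offset <- 0L
    for (ki in seq_len(params@genesPerGenome)) {
      geneId <- sprintf("%s_g%03d", gid, ki)
      L <- 3L * (sample(seq(params@geneLengthRange[1],
                            params@geneLengthRange[2]), 1L) %/% 3L)
      minus <- stats::runif(1) < params@fracMinusStrand
      planted <- stats::runif(1) < params@cassetteRate
      if (planted) {
        pc <- plantCassette(params@model, params@auFracCassette, comp,
                            params@pasMotifProbs)
        dgrSeq <- pc$sequence
        stopCodon <- pc$stopCodon
      } else {
        stopCodon <- sample(STOP_CODONS, 1L)
        dgrSeq <- paste0(generateBackground(97L, comp), stopCodon,
                         generateBackground(350L, comp))
      }
      gene <- .codingSeq(L, stopCodon, comp)
      # gene tail mirrors the DGR upstream window (PAS may precede the stop)
      gene <- paste0(substr(gene, 1L, L - 100L), substr(dgrSeq, 1L, 100L))
      down <- substr(dgrSeq, 101L, 450L)
      pad <- generateBackground(100L, comp)
      if (!minus) {
        segSeq <- paste0(gene, down, pad)
        geneStart <- offset + 1L; geneEnd <- offset + L
      } else {
        segSeq <- paste0(pad, revComp(down), revComp(gene))
        geneStart <- offset + 451L; geneEnd <- offset + 450L + L
      }
      segs[[ki]] <- segSeq
      geneRows[[ki]] <- data.frame(
        gene_id = geneId, name = geneId, start = geneStart, end = geneEnd,
        strand = if (minus) "-" else "+", planted = planted)
      if (planted) {
        tr <- pc$truth
        truthRows[[length(truthRows) + 1L]] <- data.frame(
          genome_id = gid, gene_id = geneId,
          strand = if (minus) "-" else "+", planted = TRUE,
          element = tr$element, rel_pos = tr$rel_pos, sequence = tr$sequence)
      } else {
        truthRows[[length(truthRows) + 1L]] <- data.frame(
          genome_id = gid, gene_id = geneId,
          strand = if (minus) "-" else "+", planted = FALSE,
          element = ".", rel_pos = NA_integer_, sequence = ".")
      }
      offset <- offset + nchar(segSeq)
    }
    seq <- paste(segs, collapse = "")
    if (!is.na(params@genomeLength) && params@genomeLength > nchar(seq))
      seq <- paste0(seq, generateBackground(params@genomeLength - nchar(seq), comp))
    genesDf <- do.call(rbind, geneRows)
    Lg <- nchar(seq)
    # rotate the circle so the first plus-strand gene's DGR wraps the origin
    plusIdx <- which(genesDf$strand == "+")
    if (length(plusIdx)) {
      r <- genesDf$end[plusIdx[1]] + 175L
      seq <- paste0(substr(seq, r + 1L, Lg), substr(seq, 1L, r))
      genesDf$start <- ((genesDf$start - r - 1L) %% Lg) + 1L
      genesDf$end <- ((genesDf$end - r - 1L) %% Lg) + 1L
    }
    genome <- GenomeRecord(gid, seq, circular = TRUE,
                           genes = genesDf[, c("gene_id", "name", "start",
                                               "end", "strand")])
    genomes[[gid]] <- genome
    fa <- file.path(outDir, paste0(gid, ".fasta"))
    gf <- file.path(outDir, paste0(gid, ".gff3"))
    writeGenome(genome, fa, gf)
    files <- c(files, fa, gf)
  }
  truth <- do.call(rbind, truthRows)
  truthPath <- file.path(outDir, "truth.tsv")
  utils::write.table(truth, truthPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sidecar <- file.path(outDir, "params.json")
  jsonlite::write_json(list(
    n_genomes = params@nGenomes, genes_per_genome = params@genesPerGenome,
    genome_length = params@genomeLength,
    frac_minus_strand = params@fracMinusStrand,
    au_frac_cassette = params@auFracCassette,
    background_composition = as.list(params@backgroundComposition),
    model = params@model@name, cassette_rate = params@cassetteRate,
    gene_length_range = params@geneLengthRange,
    pas_motif_probs = as.list(params@pasMotifProbs),
    seed = params@seed), sidecar, auto_unbox = TRUE, digits = NA)
  invisible(list(genomes = genomes, truth = truth,
                 files = c(files, truthPath, sidecar)))
}
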