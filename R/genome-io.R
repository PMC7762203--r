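#' @include AllClasses.R coords.R
#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   writeXStringSet reverseComplement
#' @importFrom GenomicRanges GRanges start end strand width
#' @importFrom IRanges IRanges
NULL

#' Construct a GenomeRecord
#'
#' @param id genome identifier.
#' @param sequence character or [Biostrings::DNAString].
#' @param circular logical topology flag.
#' @param genes a [GenomicRanges::GRanges] (1-based closed, plus-strand
#'   frame) with mcols `gene_id`, `name`, `is_core`; or a data.frame with
#'   columns `gene_id`, `name`, `start`, `end`, `strand` (and optionally
#'   `is_core`).
#' @return a validated [GenomeRecord].
#' @export
GenomeRecord <- function(id, sequence, circular = FALSE, genes = NULL) {
  if (is.character(sequence)) sequence <- DNAString(normalizeSeq(sequence))
  if (is.null(genes)) {
    genes <- GRanges(seqnames = character(), IRanges())
    S4Vectors::mcols(genes) <- DataFrame(gene_id = character(),
                                         name = character(),
                                         is_core = logical())
  } else if (is.data.frame(genes)) {
    gr <- GRanges(seqnames = id,
                  IRanges(start = genes$start, end = genes$end),
                  strand = genes$strand)
    S4Vectors::mcols(gr) <- DataFrame(
      gene_id = as.character(genes$gene_id),
      name = as.character(if (is.null(genes$name)) genes$gene_id else genes$name),
      is_core = if (is.null(genes$is_core)) rep(FALSE, nrow(genes))
                else as.logical(genes$is_core))
    genes <- gr
  }
  new("GenomeRecord", id = as.character(id), sequence = sequence,
      circular = isTRUE(circular), genes = genes)
}

#' Read an annotated genome
#'
#' Supports GenBank flat files (topology taken from the LOCUS line;
#' `gene`/`CDS` features with plain or `complement()` locations; `join()`
#' locations are rejected -- baculovirus genes are unspliced) and FASTA +
#' GFF3 (1-based closed intervals converted at the boundary; circularity
#' from an `Is_circular=true` attribute on a `region` feature). Records
#' without any topology information are read as linear with a warning.
#'
#' @param path genome file (GenBank flat file, or FASTA when
#'   `format = "fasta"`).
#' @param format `"auto"` (sniffed), `"genbank"`, or `"fasta"`.
#' @param gff GFF3 annotation path for the FASTA route; defaults to `path`
#'   with its extension replaced by `.gff3`.
#' @return a [GenomeRecord].
#' @export
readGenome <- function(path, format = c("auto", "genbank", "fasta"),
                       gff = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(first, "LOCUS")) "genbank" else "fasta"
  }
  if (format == "genbank") return(.readGenBank(path))
  if (is.null(gff)) gff <- paste0(sub("\\.[^.]*$", "", path), ".gff3")
  .readFastaGff(path, gff)
}

.readFastaGff <- function(fasta, gff) {
  if (!file.exists(gff)) stop("no such annotation file: ", gff)
  seqs <- readDNAStringSet(fasta)
  if (length(seqs) != 1L) stop("expected exactly one sequence in ", fasta)
  id <- sub("\\s.*", "", names(seqs)[1])
  ann <- rtracklayer::import(gff)
  circular <- FALSE
  reg <- ann[as.character(ann$type) %in% c("region", "chromosome")]
  if (length(reg) && "Is_circular" %in% colnames(S4Vectors::mcols(reg))) {
    circular <- isTRUE(tolower(as.character(reg$Is_circular[1])) == "true")
  } else {
    warning("no topology information in ", gff, "; assuming linear")
  }
  feats <- ann[as.character(ann$type) %in% c("gene", "CDS")]
  if (any(as.character(feats$type) == "gene"))
    feats <- feats[as.character(feats$type) == "gene"]
  ids <- if ("ID" %in% colnames(S4Vectors::mcols(feats)))
    as.character(feats$ID) else paste0("gene", seq_along(feats))
  if (anyDuplicated(ids))
    stop("multi-part (joined) features are not supported: ",
         ids[duplicated(ids)][1])
  nms <- if ("Name" %in% colnames(S4Vectors::mcols(feats)))
    as.character(feats$Name) else ids
  nms[is.na(nms)] <- ids[is.na(nms)]
  genes <- GRanges(seqnames = id,
                   IRanges(start = start(feats), end = end(feats)),
                   strand = strand(feats))
  S4Vectors::mcols(genes) <- DataFrame(gene_id = ids, name = nms,
                                       is_core = rep(FALSE, length(feats)))
  GenomeRecord(id, as.character(seqs[[1]]), circular, genes)
}

# minimal GenBank flat-file reader: LOCUS topology, single-interval
# gene/CDS features, ORIGIN sequence
.readGenBank <- function(path) {
  lines <- readLines(path)
  locus <- lines[startsWith(lines, "LOCUS")]
  if (!length(locus)) stop("not a GenBank flat file (no LOCUS line): ", path)
  id <- strsplit(trimws(sub("^LOCUS", "", locus[1])), "\\s+")[[1]][1]
  circular <- grepl("\\bcircular\\b", locus[1], ignore.case = TRUE)
  if (!circular && !grepl("\\blinear\\b", locus[1], ignore.case = TRUE))
    warning("no topology on LOCUS line of ", path, "; assuming linear")
  oi <- which(startsWith(lines, "ORIGIN"))
  if (!length(oi)) stop("no ORIGIN section in ", path)
  seqlines <- lines[(oi[1] + 1L):length(lines)]
  seqlines <- seqlines[!startsWith(seqlines, "//")]
  seq <- toupper(gsub("[^acgtnACGTN]", "", paste(seqlines, collapse = "")))
  fi <- which(startsWith(lines, "FEATURES"))
  rows <- list()
  if (length(fi)) {
    feat <- lines[(fi[1] + 1L):(oi[1] - 1L)]
    starts <- grep("^     (gene|CDS)\\s", feat)
    bounds <- c(grep("^     \\S", feat), length(feat) + 1L)
    for (s in starts) {
      endl <- min(bounds[bounds > s]) - 1L
      block <- feat[s:endl]
      key <- sub("^\\s+", "", sub("\\s.*", "", trimws(block[1])))
      loc <- trimws(sub("^\\s*\\S+\\s+", "", block[1]))
      if (grepl("join|order", loc))
        stop("joined locations are not supported (locus ", id, ", ", key, " ", loc, ")")
      minus <- grepl("^complement\\(", loc)
      nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1]]
      if (length(nums) != 2L)
        stop("unparseable location in ", path, " (locus ", id, "): ", loc)
      qual <- paste(block[-1], collapse = " ")
      getq <- function(q) {
        m <- regmatches(qual, regexec(paste0("/", q, '="([^"]*)"'), qual))[[1]]
        if (length(m) == 2L) m[2] else NA_character_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        key = key, start = as.integer(nums[1]), end = as.integer(nums[2]),
        strand = if (minus) "-" else "+",
        gene_id = getq("locus_tag"), name = getq("gene"))
    }
  }
  genes <- NULL
  if (length(rows)) {
    df <- do.call(rbind, rows)
    # prefer gene features; fall back to CDS
    if (any(df$key == "gene")) df <- df[df$key == "gene", , drop = FALSE]
    df$gene_id[is.na(df$gene_id)] <-
      ifelse(is.na(df$name[is.na(df$gene_id)]),
             paste0("gene", which(is.na(df$gene_id))),
             df$name[is.na(df$gene_id)])
    df$name[is.na(df$name)] <- df$gene_id[is.na(df$name)]
    df <- df[!duplicated(df$gene_id), , drop = FALSE]
    genes <- data.frame(gene_id = df$gene_id, name = df$name,
                        start = df$start, end = df$end, strand = df$strand)
  }
  GenomeRecord(id, seq, circular, genes)
}

#' Write a GenomeRecord as FASTA + GFF3
#'
#' The GFF3 carries a `region` feature whose `Is_circular` attribute
#' records the topology, and one `gene` feature per annotation (1-based
#' closed, strand column). Output is deterministic (byte-identical for
#' identical inputs).
#'
#' @param genome a [GenomeRecord].
#' @param fasta,gff output paths.
#' @return invisibly, the two paths.
#' @export
writeGenome <- function(genome, fasta, gff) {
  seqs <- DNAStringSet(setNames(list(genome@sequence), genome@id))
  writeXStringSet(seqs, fasta, width = 70L)
  L <- length(genome@sequence)
  g <- genome@genes
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", genome@id, L),
             sprintf("%s\tbaculoPolyA\tregion\t1\t%d\t.\t+\t.\tID=%s;Is_circular=%s",
                     genome@id, L, genome@id,
                     if (genome@circular) "true" else "false"))
  if (length(g)) {
    mc <- S4Vectors::mcols(g)
    lines <- c(lines, sprintf(
      "%s\tbaculoPolyA\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
      genome@id, start(g), end(g), as.character(strand(g)),
      mc$gene_id, mc$name))
  }
  writeLines(lines, gff)
  invisible(c(fasta = fasta, gff = gff))
}

#' Extract the downstream gene region (DGR) of a gene
#'
#' Returns the window `-upstream..-1, +1..+downstream` around the gene's
#' stop codon, 5'->3' in gene orientation (minus-strand genes are
#' reverse-complemented). Relative positions `-3..-1` carry the stop codon
#' when the annotation is a true CDS end. For circular genomes the window
#' wraps the origin; for linear genomes it is truncated at the sequence
#' end with `truncated3` set. Genes shorter than `upstream` contribute
#' only their own length upstream (`truncated5` set). Truncation is always
#' flagged, never silent.
#'
#' @param genome a [GenomeRecord].
#' @param gene a gene_id present in the genome's annotations.
#' @param upstream,downstream window sizes in nt (defaults 100 and 350,
#'   the -100..+350 convention).
#' @return a [DGR].
#' @export
extractDGR <- function(genome, gene, upstream = 100L, downstream = 350L) {
  g <- genome@genes
  i <- match(gene, S4Vectors::mcols(g)$gene_id)
  if (is.na(i)) stop("gene ", gene, " not found in genome ", genome@id)
  L <- length(genome@sequence)
  gs <- start(g)[i]; ge <- end(g)[i]
  minus <- as.character(strand(g)[i]) == "-"
  glen <- ge - gs + 1L
  up <- min(as.integer(upstream), glen)
  truncated5 <- up < upstream
  if (!minus) {
    pos <- (ge - up + 1L):(ge + downstream)
  } else {
    pos <- (gs + up - 1L):(gs - downstream)
  }
  truncated3 <- FALSE
  if (genome@circular) {
    pos <- ((pos - 1L) %% L) + 1L
  } else {
    inside <- pos >= 1L & pos <= L
    if (!all(inside)) {
      truncated3 <- TRUE
      pos <- pos[inside]
      up <- sum(if (!minus) pos <= ge else pos >= gs)  # re-count upstream part
    }
  }
  base <- strsplit(as.character(genome@sequence), "", fixed = TRUE)[[1]][pos]
  if (minus) base <- DNA_COMPLEMENT[base]
  new("DGR", genomeId = genome@id,
      geneId = S4Vectors::mcols(g)$gene_id[i],
      strand = if (minus) "-" else "+",
      sequence = paste(base, collapse = ""),
      upstreamLen = as.integer(up),
      truncated5 = truncated5, truncated3 = truncated3,
      genomicPos = as.integer(pos))
}

#' Extract DGRs for all (or all core) genes of a genome
#'
#' @param genome a [GenomeRecord].
#' @param coreOnly only genes flagged `is_core`.
#' @param upstream,downstream window sizes, see [extractDGR()].
#' @return a [DGRSet].
#' @export
extractDGRs <- function(genome, coreOnly = FALSE,
                        upstream = 100L, downstream = 350L) {
  ids <- S4Vectors::mcols(genome@genes)$gene_id
  if (coreOnly) ids <- ids[S4Vectors::mcols(genome@genes)$is_core]
  out <- lapply(ids, function(gid)
    extractDGR(genome, gid, upstream, downstream))
  names(out) <- ids
  new("DGRSet", SimpleList(out))
}

#' Map a DGR relative coordinate back to the genome
#'
#' @param dgr a [DGR].
#' @param rel relative coordinate(s) (no position 0).
#' @return 1-based plus-strand genome coordinate(s).
#' @export
dgrToGenomic <- function(dgr, rel) {
  dgr@genomicPos[relToIdx(rel, dgr@upstreamLen)]
}

#' Flag core genes by name
#'
#' Marks genes whose name matches any pattern of a case-insensitive
#' name table as core. Core-gene identity is configuration, not
#' computation: a default table of 38 names shared by all baculovirus
#' species ships with the package ([coreGeneNames()]).
#'
#' @param genome a [GenomeRecord] (or a GRanges with the standard mcols).
#' @param coreNames character vector of regular expressions.
#' @return the input with `is_core` updated.
#' @export
selectCore <- function(genome, coreNames = coreGeneNames()) {
  gr <- if (is(genome, "GenomeRecord")) genome@genes else genome
  if (!length(coreNames)) {
    message("empty core-name table: no genes flagged core")
    S4Vectors::mcols(gr)$is_core <- rep(FALSE, length(gr))
  } else {
    nm <- S4Vectors::mcols(gr)$name
    hit <- rep(FALSE, length(gr))
    for (p in coreNames) hit <- hit | grepl(p, nm, ignore.case = TRUE)
    S4Vectors::mcols(gr)$is_core <- hit
  }
  if (is(genome, "GenomeRecord")) { genome@genes <- gr; genome } else gr
}

#' Default core-gene name table
#'
#' @return character vector of gene-name patterns shipped in
#'   `extdata/core_genes.txt`.
#' @export
coreGeneNames <- function() {
  path <- system.file("extdata", "core_genes.txt", package = "baculoPolyA")
  x <- readLines(path)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Write a DGR set as FASTA plus an index table
#'
#' Headers follow `genomeID|geneID|strand|trunc` with `trunc` 0/1.
#'
#' @param dgrs a [DGRSet] or list of [DGR].
#' @param fasta output FASTA path.
#' @param index optional TSV index path.
#' @return invisibly the FASTA path.
#' @export
writeDGRFasta <- function(dgrs, fasta, index = NULL) {
  hdr <- vapply(dgrs, function(d)
    sprintf("%s|%s|%s|%d", d@genomeId, d@geneId, d@strand,
            as.integer(isTruncated(d))), "")
  seqs <- DNAStringSet(setNames(vapply(dgrs, dgrSequence, ""), hdr))
  writeXStringSet(seqs, fasta, width = 70L)
  if (!is.null(index)) {
    df <- data.frame(
      genome_id = vapply(dgrs, function(d) d@genomeId, ""),
      gene_id = vapply(dgrs, function(d) d@geneId, ""),
      strand = vapply(dgrs, function(d) d@strand, ""),
      length = vapply(dgrs, function(d) nchar(d@sequence), 0L),
      upstream_len = vapply(dgrs, function(d) d@upstreamLen, 0L),
      truncated = vapply(dgrs, isTruncated, TRUE))
    utils::write.table(df, index, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(fasta)
}
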