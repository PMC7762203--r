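# small fixtures built in code
makeGenome <- function(seq, genes, circular = FALSE, id = "gtest")
  GenomeRecord(id, seq, circular = circular, genes = genes)

test_that("DGR extraction arithmetic: plus, minus, circular wrap", {
  set.seed(2)
  s <- generateBackground(2000)
  gen <- makeGenome(s, data.frame(
    gene_id = c("gp", "gm"), name = c("gp", "gm"),
    start = c(1, 1001), end = c(1000, 2000), strand = c("+", "-")))

  dp <- extractDGR(gen, "gp")   # plus-strand gene [1, 1000]
  expect_equal(nchar(dgrSequence(dp)), 450)
  expect_equal(range(dp@genomicPos), c(901, 1350))
  expect_identical(dgrSequence(dp), substr(s, 901, 1350))
  expect_false(isTruncated(dp))

  dm <- extractDGR(gen, "gm")   # minus-strand gene [1001, 2000]
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(s, 651, 1100))))
  expect_identical(dgrSequence(dm), rc)
  expect_equal(nchar(dgrSequence(dm)), 450)

  # circular: plus-strand gene ending at 995 of a 1000-nt genome wraps
  gc <- makeGenome(substr(s, 1, 1000), data.frame(
    gene_id = "g", name = "g", start = 200, end = 995, strand = "+"),
    circular = TRUE)
  dc <- extractDGR(gc, "g")
  expect_identical(dgrSequence(dc),
                   paste0(substr(s, 896, 1000), substr(s, 1, 345)))
  expect_false(isTruncated(dc))
})

test_that("strand involution: minus-strand DGR equals plus-strand DGR of the flipped genome", {
  set.seed(8)
  for (i in 1:5) {
    L <- 1500L
    s <- generateBackground(L)
    gs <- sample(500:700, 1); ge <- gs + sample(300:500, 1)
    gen <- makeGenome(s, data.frame(gene_id = "g", name = "g",
                                    start = gs, end = ge, strand = "-"),
                      circular = TRUE)
    flipped <- makeGenome(
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
      data.frame(gene_id = "g", name = "g",
                 start = L - ge + 1, end = L - gs + 1, strand = "+"),
      circular = TRUE)
    expect_identical(dgrSequence(extractDGR(gen, "g")),
                     dgrSequence(extractDGR(flipped, "g")))
  }
})

test_that("relative coordinates round-trip to genomic positions", {
  set.seed(4)
  p <- SimParams(nGenomes = 1, genesPerGenome = 4, seed = 31)
  d <- withr::local_tempdir()
  res <- generateGenomeSet(p, d)
  g <- res$genomes[[1]]
  sv <- strsplit(as.character(genomeSeq(g)), "")[[1]]
  for (dgr in as.list(extractDGRs(g))) {
    rels <- c(-100L, -3L, -1L, 1L, 175L, 350L)
    for (rel in rels) {
      idx <- relToIdx(rel, dgr@upstreamLen)
      gp <- dgrToGenomic(dgr, rel)
      base <- sv[gp]
      if (dgr@strand == "-") base <- chartr("ACGT", "TGCA", base)
      expect_identical(substr(dgrSequence(dgr), idx, idx), base)
    }
  }
})

test_that("linear truncation is flagged, never silent", {
  set.seed(6)
  s <- generateBackground(1200)
  gen <- makeGenome(s, data.frame(gene_id = c("gend", "gshort"),
                                  name = c("gend", "gshort"),
                                  start = c(500, 30), end = c(1100, 119),
                                  strand = c("+", "+")))
  dend <- extractDGR(gen, "gend")  # downstream runs off the linear end
  expect_true(dend@truncated3)
  expect_equal(nchar(dgrSequence(dend)), 100 + 100)
  dshort <- extractDGR(gen, "gshort")  # 90-nt gene: upstream truncated
  expect_true(dshort@truncated5)
  expect_equal(dshort@upstreamLen, 90L)
})

test_that("relToIdx/idxToRel skip position zero and invert each other", {
  expect_equal(relToIdx(c(-100, -1, 1, 350), 100), c(1, 100, 101, 450))
  expect_equal(idxToRel(c(1, 100, 101, 450), 100), c(-100, -1, 1, 350))
  expect_error(relToIdx(0), "0")
  idx <- 1:450
  expect_equal(relToIdx(idxToRel(idx, 100), 100), idx)
})

test_that("GenBank flat files parse: topology, complement locations, qualifiers", {
  gb <- c(
    "LOCUS       TESTG                 60 bp    DNA     circular VRL 01-JAN-2020",
    "DEFINITION  synthetic test genome.",
    "FEATURES             Location/Qualifiers",
    "     gene            complement(10..39)",
    "                     /gene=\"polh\"",
    "                     /locus_tag=\"TG_001\"",
    "ORIGIN",
    "        1 acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt",
    "//")
  tf <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, tf)
  g <- readGenome(tf)
  expect_true(isCircularGenome(g))
  expect_equal(length(genomeSeq(g)), 60)
  ga <- geneAnnotations(g)
  expect_length(ga, 1)
  expect_equal(GenomicRanges::start(ga), 10)
  expect_equal(GenomicRanges::end(ga), 39)
  expect_equal(as.character(GenomicRanges::strand(ga)), "-")
  expect_identical(S4Vectors::mcols(ga)$name, "polh")

  # joined locations rejected
  gb2 <- sub("complement\\(10\\.\\.39\\)", "join(10..20,30..39)", gb)
  tf2 <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb2, tf2)
  expect_error(readGenome(tf2), "join")

  # missing topology -> linear with warning
  gb3 <- sub(" circular ", " ", gb)
  tf3 <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb3, tf3)
  expect_warning(g3 <- readGenome(tf3), "topology")
  expect_false(isCircularGenome(g3))
})

test_that("FASTA+GFF3 round trip preserves coordinates, strand and topology", {
  set.seed(9)
  gen <- makeGenome(generateBackground(3000), data.frame(
    gene_id = c("a", "b"), name = c("lef-8", "other"),
    start = c(101, 1500), end = c(700, 2300), strand = c("+", "-")),
    circular = TRUE, id = "rt1")
  d <- withr::local_tempdir()
  fa <- file.path(d, "rt1.fasta"); gf <- file.path(d, "rt1.gff3")
  writeGenome(gen, fa, gf)
  g2 <- readGenome(fa, format = "fasta")
  expect_true(isCircularGenome(g2))
  expect_identical(as.character(genomeSeq(g2)), as.character(genomeSeq(gen)))
  ga <- geneAnnotations(g2)
  expect_equal(GenomicRanges::start(ga), c(101, 1500))
  expect_equal(GenomicRanges::end(ga), c(700, 2300))
  expect_equal(as.character(GenomicRanges::strand(ga)), c("+", "-"))
})

test_that("core-gene selection matches name patterns case-insensitively", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3"),
                      name = c("POLH", "gp64", "lef-8"),
                      start = c(1, 200, 400), end = c(150, 350, 600),
                      strand = "+")
  gen <- makeGenome(generateBackground(1000, seed = 1), genes)
  g1 <- selectCore(gen, c("polh"))
  expect_equal(sum(S4Vectors::mcols(geneAnnotations(g1))$is_core), 1)
  g2 <- selectCore(gen, coreGeneNames())
  core <- S4Vectors::mcols(geneAnnotations(g2))$is_core
  expect_true(core[1] && core[3] && !core[2])
  expect_message(g0 <- selectCore(gen, character()), "empty")
  expect_equal(sum(S4Vectors::mcols(geneAnnotations(g0))$is_core), 0)
})
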