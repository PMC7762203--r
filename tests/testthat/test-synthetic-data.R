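test_that("background generation honours length, composition and seed", {
  expect_identical(generateBackground(0, seed = 1), "")
  expect_identical(generateBackground(10, c(A = 1, C = 0, G = 0, T = 0), seed = 1),
                   "AAAAAAAAAA")
  expect_error(generateBackground(-1), "non-negative")
  expect_error(generateBackground(10, c(A = 0.5, C = 0.5, G = 0.5, T = 0.5)))
  s1 <- generateBackground(5000, seed = 7)
  s2 <- generateBackground(5000, seed = 7)
  expect_identical(s1, s2)
  # law of large numbers: uniform composition recovered within 0.01
  big <- generateBackground(1e5, c(A = .25, C = .25, G = .25, T = .25), seed = 7)
  freq <- table(strsplit(big, "")[[1]]) / 1e5
  expect_true(all(abs(freq - 0.25) < 0.01))
})

test_that("planted cassettes carry verbatim motifs at the recorded positions", {
  m <- modelSpec("improved2020")
  set.seed(3)
  for (i in 1:40) {
    pc <- plantCassette(m, 0.8)
    expect_equal(nchar(pc$sequence), 450)
    # stop codon at relative -3..-1
    expect_true(substr(pc$sequence, 98, 100) %in% c("TAA", "TAG", "TGA"))
    for (r in seq_len(nrow(pc$truth))) {
      idx <- pc$truth$idx[r]
      motif <- pc$truth$sequence[r]
      expect_identical(substr(pc$sequence, idx, idx + nchar(motif) - 1L), motif)
    }
    # AU fraction of the 40-nt PAS-centred window within tolerance
    pasRel <- pc$truth$rel_pos[pc$truth$element == "PAS"]
    expect_gte(auContent(pc$sequence, pasRel, 20L), 0.7)
  }
})

test_that("planted distances respect the generating windows", {
  m <- modelSpec("improved2020")
  set.seed(5)
  dist <- function(tr, a, b, metric = "gap") {
    ia <- tr$idx[tr$element == a]; ib <- tr$idx[tr$element == b]
    la <- nchar(tr$sequence[tr$element == a])
    if (metric == "gap") ib - (ia + la - 1L) - 1L else ib - ia
  }
  for (i in 1:60) {
    tr <- plantCassette(m, 0.8)$truth
    expect_true(dist(tr, "USE", "PAS") >= 5 && dist(tr, "USE", "PAS") <= 30)
    expect_true(dist(tr, "UGUA", "PAS", "start") >= 0 &&
                dist(tr, "UGUA", "PAS", "start") <= 8)
    expect_true(dist(tr, "PAS", "CS") >= 0 && dist(tr, "PAS", "CS") <= 75)
    expect_true(dist(tr, "PAS", "DSE") >= 21 && dist(tr, "PAS", "DSE") <= 29)
    expect_true(dist(tr, "CS", "DSE") >= 0 && dist(tr, "CS", "DSE") <= 50)
    expect_true(dist(tr, "DSE", "AuxDSE") >= 1 && dist(tr, "DSE", "AuxDSE") <= 100)
    pasRel <- tr$rel_pos[tr$element == "PAS"]
    expect_true(pasRel >= -12 && pasRel <= 7)
  }
})

test_that("uniform window sampling realizes every inter-element distance", {
  # USE->PAS, PAS->DSE and DSE->AuxDSE gaps are drawn uniformly from their
  # windows; over 2000 cassettes every integer value must appear
  m <- modelSpec("improved2020")
  set.seed(17)
  g1 <- integer(); g2 <- integer(); g3 <- integer()
  for (i in 1:2000) {
    tr <- plantCassette(m, 0.8)$truth
    idx <- setNames(tr$idx, tr$element)
    len <- setNames(nchar(tr$sequence), tr$element)
    g1 <- c(g1, idx["PAS"] - (idx["USE"] + len["USE"] - 1L) - 1L)
    g2 <- c(g2, idx["DSE"] - (idx["PAS"] + len["PAS"] - 1L) - 1L)
    g3 <- c(g3, idx["AuxDSE"] - (idx["DSE"] + len["DSE"] - 1L) - 1L)
  }
  expect_setequal(unique(g1), 5:30)
  expect_setequal(unique(g2), 21:29)
  expect_setequal(unique(g3), 1:100)
})

test_that("genome sets conserve truth counts and are byte-deterministic", {
  p <- SimParams(nGenomes = 1, genesPerGenome = 5, cassetteRate = 1.0, seed = 11)
  d1 <- withr::local_tempdir()
  res <- generateGenomeSet(p, d1)
  planted <- unique(res$truth$gene_id[res$truth$planted])
  expect_length(planted, 5)

  p0 <- SimParams(nGenomes = 1, genesPerGenome = 4, cassetteRate = 0.0, seed = 11)
  d0 <- withr::local_tempdir()
  res0 <- generateGenomeSet(p0, d0)
  expect_false(any(res0$truth$planted))

  # same parameters twice -> byte-identical files
  p2 <- SimParams(nGenomes = 2, genesPerGenome = 3, seed = 42)
  da <- withr::local_tempdir(); db <- withr::local_tempdir()
  generateGenomeSet(p2, da); generateGenomeSet(p2, db)
  for (f in list.files(da)) {
    expect_identical(readLines(file.path(da, f)), readLines(file.path(db, f)),
                     info = f)
  }
})

test_that("truth sequences re-read from emitted genomes match, both strands and across the origin", {
  p <- SimParams(nGenomes = 2, genesPerGenome = 8, seed = 23)
  d <- withr::local_tempdir()
  res <- generateGenomeSet(p, d)
  tr <- res$truth[res$truth$planted & res$truth$element != ".", ]
  sawMinus <- FALSE; sawWrap <- FALSE
  for (gid in unique(tr$genome_id)) {
    g <- readGenome(file.path(d, paste0(gid, ".fasta")), format = "fasta")
    expect_true(isCircularGenome(g))
    dgrs <- extractDGRs(g)
    sub <- tr[tr$genome_id == gid, ]
    for (r in seq_len(nrow(sub))) {
      dgr <- dgrs[[sub$gene_id[r]]]
      idx <- relToIdx(sub$rel_pos[r], 100L)
      got <- substr(dgrSequence(dgr), idx, idx + nchar(sub$sequence[r]) - 1L)
      expect_identical(got, sub$sequence[r],
                       info = paste(sub$gene_id[r], sub$element[r]))
      if (dgr@strand == "-") sawMinus <- TRUE
      if (any(diff(dgr@genomicPos) != ifelse(dgr@strand == "-", -1L, 1L)))
        sawWrap <- TRUE
    }
  }
  expect_true(sawMinus)
  expect_true(sawWrap)  # at least one DGR wraps the circular origin
})

test_that("invalid simulation parameters are rejected", {
  expect_error(SimParams(cassetteRate = 1.5), "fractions")
  expect_error(SimParams(backgroundComposition = c(A = .5, C = .5, G = .2, T = -.2)))
  expect_error(SimParams(genomeLength = 1000, genesPerGenome = 30), "too small")
})
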