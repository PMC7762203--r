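test_that("IUPAC scanning: literal, degenerate and overlapping matches", {
  expect_equal(scanIUPAC("GGAATAAAGG", "AATAAA"),
               data.frame(start = 3L, match = "AATAAA"))
  # W covers both PAS hexamer variants
  expect_equal(scanIUPAC("ATTAAA", "AWTAAA")$start, 1L)
  expect_equal(scanIUPAC("AATAAA", "AWTAAA")$start, 1L)
  # overlapping matches are all reported
  expect_equal(scanIUPAC("TTTTTT", "TTTT")$start, 1:3)
  # empty results
  expect_equal(nrow(scanIUPAC("CCCC", "AATAAA")), 0L)
  expect_equal(nrow(scanIUPAC("AC", "AATAAA")), 0L)
})

test_that("IUPAC scanning errors and edge semantics", {
  expect_error(scanIUPAC("ACGT", "AXGT"), "X")
  expect_error(scanIUPAC("ACXT", "ACGT"), "X")
  # N in the sequence matches nothing, N in the pattern matches any base
  expect_equal(nrow(scanIUPAC("ANGT", "ANGT")), 0L)
  expect_equal(scanIUPAC("ACGT", "ANGT")$start, 1L)
  # T/U symmetry on both sides
  expect_equal(scanIUPAC("AUUAAA", "ATTAAA")$start, 1L)
  expect_equal(scanIUPAC("ATTAAA", "AUUAAA")$start, 1L)
})

test_that("scanIUPAC agrees with the naive per-position oracle", {
  set.seed(101)
  for (i in 1:500) {
    n <- sample(1:200, 1)
    s <- paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
                      prob = c(.24, .24, .24, .24, .04)), collapse = "")
    k <- sample(1:8, 1)
    p <- paste(sample(names(IUPAC_ORACLE), k, replace = TRUE), collapse = "")
    expect_identical(as.integer(scanIUPAC(s, p)$start),
                     as.integer(naiveScanOracle(s, p)),
                     info = paste(s, p))
  }
})

test_that("T/U transliteration of a sequence leaves hits unchanged", {
  set.seed(33)
  for (i in 1:50) {
    s <- randomDNA(120)
    u <- chartr("T", "U", s)
    for (p in c("TTTT", "AWTAAA", "KGTA", "TGTA"))
      expect_identical(scanIUPAC(s, p), scanIUPAC(u, p))
  }
})

test_that("element scanning covers all classes and the G-rich rule", {
  # all-C window: no hits for any class
  h0 <- findElements(strrep("C", 450))
  expect_equal(nrow(h0), 0L)
  # CA dinucleotide yields a cleavage-site candidate at its own position
  s <- paste0(strrep("G", 122), "CA", strrep("G", 326))
  h <- findElements(s)
  cs <- h[h$element == "CS", ]
  expect_equal(cs$rel_start, 23L)  # idx 123 -> rel +23
  # the G homopolymer sets off G-rich Aux-DSE windows, not DSE motifs
  expect_true(all(h$element %in% c("CS", "AuxDSE")))
  # planted cassette: every class hit at (at least) the truth position
  set.seed(3)
  pc <- plantCassette(modelSpec("improved2020"), 0.8)
  hits <- findElements(pc$sequence)
  for (r in seq_len(nrow(pc$truth))) {
    el <- pc$truth$element[r]
    expect_true(pc$truth$idx[r] %in% hits$idx_start[hits$element == el],
                info = el)
  }
})

test_that("G-rich rule: any 6-nt window with >= 4 G, configurable", {
  s <- paste0(strrep("A", 100), "GGAGGG", strrep("A", 344))
  h <- findElements(s)
  aux <- h[h$element == "AuxDSE", ]
  # overlapping qualifying windows are all retained
  expect_equal(aux$idx_start, c(100L, 101L, 102L))
  expect_true("GGAGGG" %in% aux$motif)
  # stricter threshold keeps only the 5-G window
  h5 <- findElements(s, elementDefs(gMin = 5L))
  expect_equal(h5$idx_start[h5$element == "AuxDSE"], 101L)
  h6 <- findElements(s, elementDefs(gMin = 6L))
  expect_equal(nrow(h6[h6$element == "AuxDSE", ]), 0L)
})

test_that("positional distributions: histogram, hotspot, degenerate cases", {
  mkhits <- function(rel) DataFrame(element = rep("PAS", length(rel)),
                                    motif = rep("AATAAA", length(rel)),
                                    idx_start = relToIdx(rel, 100L),
                                    rel_start = as.integer(rel),
                                    length = rep(6L, length(rel)))
  # all hits at one position -> zero-width hotspot
  d1 <- positionalDistribution(mkhits(rep(8, 20)), "PAS", 20)
  expect_equal(hotspot(d1), c(8, 8))
  expect_equal(sum(d1@histogram), 20)
  # uniform hits on +1..+100, q = 0.75 -> window of 75 +- 1 positions
  d2 <- positionalDistribution(mkhits(1:100), "PAS", 100, q = 0.75)
  width <- hotspot(d2)[2] - hotspot(d2)[1] + 1
  expect_true(abs(width - 75) <= 1)
  # zero hits: flagged, not an exception
  expect_warning(d0 <- positionalDistribution(mkhits(integer()), "PAS", 5),
                 "undefined")
  expect_true(anyNA(hotspot(d0)))
  expect_length(d0@histogram, 0)
})

test_that("adding sequences never shrinks a histogram bin", {
  set.seed(55)
  seqs <- vapply(1:30, function(i)
    generateBackground(450, auRichComposition()), "")
  hits1 <- do.call(rbind, lapply(seqs[1:15], function(s)
    as.data.frame(findElements(s))))
  hits2 <- do.call(rbind, lapply(seqs, function(s)
    as.data.frame(findElements(s))))
  d1 <- positionalDistribution(hits1, "USE", 15)
  d2 <- positionalDistribution(hits2, "USE", 30)
  common <- intersect(names(d1@histogram), names(d2@histogram))
  expect_true(all(names(d1@histogram) %in% names(d2@histogram)))
  expect_true(all(d2@histogram[common] >= d1@histogram[common]))
})

test_that("element definitions load from YAML identically to the defaults", {
  defs <- readElementDefs()
  ref <- elementDefs()
  expect_setequal(names(defs), names(ref))
  for (cl in names(ref))
    expect_identical(defs[[cl]]$motifs, ref[[cl]]$motifs)
  expect_equal(attr(defs, "gWindow"), 6L)
})
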