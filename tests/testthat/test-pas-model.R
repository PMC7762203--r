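test_that("model presets encode the documented windows and load-time checks", {
  m <- modelSpec("improved2020")
  expect_equal(m@anchorWindow, c(-12, 7))
  expect_equal(m@windows[["USE->PAS"]][c("min", "max")], list(min = 5L, max = 30L))
  expect_equal(m@windows[["PAS->DSE"]][c("min", "max")], list(min = 21L, max = 29L))
  expect_equal(m@windows[["PAS->CS"]][c("min", "max")], list(min = 0L, max = 75L))
  expect_equal(m@windows[["CS->DSE"]][c("min", "max")], list(min = 0L, max = 50L))
  m0 <- modelSpec("initial2003")
  expect_equal(m0@anchorWindow, c(1, 50))
  expect_equal(m0@windows[["PAS->CS"]][c("min", "max")], list(min = 12L, max = 42L))
  expect_equal(m0@windows[["CS->DSE"]][c("min", "max")], list(min = 4L, max = 40L))
  # contradictory windows rejected when the model is constructed
  bad <- m
  bad@windows[["PAS->DSE"]]$min <- 60L
  bad@windows[["PAS->DSE"]]$max <- 70L
  bad@windows[["PAS->CS"]]$max <- 5L
  bad@windows[["CS->DSE"]]$max <- 10L
  expect_error(validObject(bad), "contradictory")
  rev <- m
  rev@windows[["USE->PAS"]]$min <- 40L
  expect_error(validObject(rev), "min > max")
})

emptyHits <- function() DataFrame(element = character(), motif = character(),
                                  idx_start = integer(), rel_start = integer(),
                                  length = integer())

hitRow <- function(element, rel, motif) {
  len <- if (motif %in% c("G-RICH")) 6L else nchar(motif)
  DataFrame(element = element, motif = motif,
            idx_start = relToIdx(rel, 100L), rel_start = as.integer(rel),
            length = len)
}

test_that("cassette assignment basics: empty input, minimal PAS+CS pair", {
  m <- modelSpec("improved2020")
  expect_null(assignCassette(emptyHits(), m))
  hits <- rbind(hitRow("PAS", 2L, "AATAAA"), hitRow("CS", 40L, "CA"))
  a <- assignCassette(hits, m)
  expect_s4_class(a, "CassetteAssignment")
  expect_equal(a@nElements, 2L)
  expect_false(isComplete(a))
  sw <- a@satisfiedWindows
  d <- sw$distance[sw$window == "PAS->CS"]
  expect_equal(d, 32L)  # gap between PAS end (+7) and the CA at +40
  expect_true(d >= 0 && d <= 75)
  expect_true(isTRUE(checkAssignment(a, m)))
  # PAS outside the anchor window cannot anchor a cassette
  far <- rbind(hitRow("PAS", 60L, "AATAAA"), hitRow("CS", 80L, "CA"))
  expect_null(assignCassette(far, m))
})

test_that("assignment equals exhaustive combination search under the total order", {
  set.seed(7)
  for (modelName in c("improved2020", "initial2003")) {
    m <- modelSpec(modelName)
    for (i in 1:60) {
      s <- if (i %% 2) plantCassette(m, 0.8)$sequence
           else generateBackground(450, auRichComposition())
      h <- as.data.frame(findElements(s))
      h <- do.call(rbind, lapply(split(h, h$element), function(d)
        utils::head(d[order(d$idx_start), ], 8)))  # <= 8 hits per class
      a <- assignCassette(DataFrame(h), m, dgrId = i)
      b <- bruteAssignOracle(h, m)
      if (is.null(b)) {
        expect_null(a)
      } else {
        expect_false(is.null(a))
        expect_identical(lapply(a@hits, function(x) x$idx_start),
                         lapply(b$placed, function(x) x$idx_start))
        expect_equal(a@deviation, b$dev)
        expect_equal(a@nElements, b$n)
      }
    }
  }
})

test_that("every emitted assignment satisfies its windows on independent re-check", {
  m <- modelSpec("improved2020")
  set.seed(19)
  for (i in 1:60) {
    pc <- plantCassette(m, 0.8)
    a <- assignCassette(findElements(pc$sequence), m, dgrId = i)
    expect_false(is.null(a))
    expect_true(isTRUE(checkAssignment(a, m)))
  }
})

test_that("AU content computation and degenerate windows", {
  s <- paste0(strrep("AT", 100), strrep("GC", 125))
  expect_equal(auContent(s, -50L, 10L), 1.0)
  expect_equal(auContent(s, 200L, 10L), 0.0)
  # window clipped at the DGR edge
  expect_equal(auContent(s, -100L, 20L), 1.0)
  expect_error(auContent("ACGT", 300L, 2L, upstreamLen = 2L), "intersect")
})

test_that("set classification is deterministic and flags shared sequences", {
  m <- modelSpec("improved2020")
  set.seed(29)
  pos <- vapply(1:30, function(i) plantCassette(m, 0.8)$sequence, "")
  allc <- rep(strrep("C", 450), 10)
  r1 <- classifySets(list(pos = pos, flat = allc), m)
  r2 <- classifySets(list(pos = pos, flat = allc), m)
  expect_identical(r1@summary, r2@summary)
  expect_equal(r1@summary$detection_fraction[r1@summary$set == "flat"], 0)
  expect_equal(r1@summary$n_complete[r1@summary$set == "pos"], 30)
  expect_equal(sum(r1@countsByN["pos", ]), 30)
  # same set passed under two names: identical fractions plus a warning
  expect_warning(r3 <- classifySets(list(a = pos, b = pos), m), "share")
  expect_equal(r3@summary$detection_fraction[1],
               r3@summary$detection_fraction[2])
})

test_that("cassette tables flatten assignments faithfully", {
  m <- modelSpec("improved2020")
  set.seed(41)
  pc <- plantCassette(m, 0.8)
  a <- assignCassette(findElements(pc$sequence), m, dgrId = "d1")
  tab <- cassetteTable(list(a, NULL))
  expect_equal(nrow(tab), a@nElements)
  expect_setequal(tab$element, names(a@hits))
  expect_true(all(tab$dgr_id == "d1"))
  expect_equal(nrow(cassetteTable(list(NULL))), 0L)
})
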