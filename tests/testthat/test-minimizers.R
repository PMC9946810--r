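# one shared spectrum for the hash behind minimizer selection
spQ <- local({
  set.seed(55)
  reads <- stats::setNames(vapply(1:30, function(i) randSeq(400),
                                  character(1)), paste0("r", 1:30))
  buildSpectrum(reads)
})
setupSpectrum <- function() spQ

test_that("w = 1 emits every k-mer position; homopolymers collapse", {
  sp <- setupSpectrum()
  s <- randSeq(300)
  m <- computeMinimizers(s, k = 25, w = 1, spectrum = sp)
  expect_equal(m$pos, 0:(300 - 25))

  hom <- strrep("A", 100)
  mh <- computeMinimizers(hom, k = 15, w = 10, spectrum = sp)
  expect_equal(unique(mh$code), 0)

  # too short for one full window: empty result
  short <- randSeq(25 + 40 - 2)
  expect_equal(nrow(computeMinimizers(short, 25, 40, sp)), 0L)
})

test_that("minimizer sets equal the brute-force per-window argmin", {
  sp <- setupSpectrum()
  set.seed(66)
  for (i in 1:12) {
    s <- randSeq(2000)
    m <- computeMinimizers(s, k = 25, w = 40, spectrum = sp)
    expect_equal(sort(m$pos), oracleMinimizers(s, 25, 40, sp))
  }
})

test_that("minimizer selection is deterministic and strand-symmetric", {
  sp <- setupSpectrum()
  s <- randSeq(1500)
  m1 <- computeMinimizers(s, 25, 40, sp)
  m2 <- computeMinimizers(s, 25, 40, sp)
  expect_identical(m1, m2)
  # the selected (hash, code) multiset is strand-invariant
  mr <- computeMinimizers(olca:::revcompChar(s), 25, 40, sp)
  expect_equal(sort(m1$code), sort(mr$code))
})

test_that("sequences sharing a long exact substring share a minimizer", {
  sp <- setupSpectrum()
  set.seed(77)
  k <- 25L; w <- 40L
  for (i in 1:10) {
    core <- randSeq(k + w - 1)  # exactly one full window
    s1 <- paste0(randSeq(200), core, randSeq(200))
    s2 <- paste0(randSeq(150), core, randSeq(250))
    m1 <- computeMinimizers(s1, k, w, sp)
    m2 <- computeMinimizers(s2, k, w, sp)
    expect_gt(length(intersect(m1$code, m2$code)), 0)
  }
})

test_that("the minimizer table returns its own entries and applies the cap", {
  sp <- setupSpectrum()
  s <- randSeq(1200)
  tab <- buildMinimizerTable(c(a = s), spectrum = sp)
  m <- computeMinimizers(s, 25, 40, sp)
  hits <- queryMinimizerTable(tab, s)
  expect_equal(sort(unique(hits$subjectPos)), sort(m$pos))
  expect_true(all(hits$subject == 1))
  self <- hits[hits$subjectPos == hits$queryPos, ]
  expect_equal(nrow(self), nrow(m))
  expect_true(all(!self$reverse))

  # two identical reads: every minimizer has exactly two entries
  tab2 <- buildMinimizerTable(c(a = s, b = s), spectrum = sp)
  h2 <- queryMinimizerTable(tab2, s)
  expect_equal(nrow(h2), 2L * nrow(m))

  # heavily repetitive reference with a low cap: entries are purged
  repseq <- strrep("ACGT", 10000)
  tab3 <- buildMinimizerTable(c(r = repseq), k = 15, w = 5,
                              spectrum = buildSpectrum(c(r = repseq)),
                              maxFrequency = 1000)
  st <- olca:::olca_table_stats(tab3@ptr)
  expect_gt(st$nPurged, 0)
  expect_equal(nrow(queryMinimizerTable(tab3, strrep("ACGT", 100))), 0L)
})

test_that("the reference aligner recovers exact and reverse extractions", {
  g <- simulateGenome(40000, seed = 501, name = "ref")
  tab <- buildMinimizerTable(g, maxFrequency = 1000)
  sub <- substr(as.character(g), 5001, 7000)
  aln <- alignReads(tab, c(fwd = sub, rev = olca:::revcompChar(sub)))
  expect_true(all(aln$aligned))
  expect_equal(aln$contig, c("ref", "ref"))
  expect_lt(abs(aln$start[1] - 5000), 25 + 1)
  expect_lt(abs(aln$start[2] - 5000), 25 + 1)
  expect_false(aln$reverse[1])
  expect_true(aln$reverse[2])

  # a foreign sequence stays unmapped
  set.seed(502)
  aln2 <- alignReads(tab, c(junk = randSeq(2000)))
  expect_false(aln2$aligned[1])

  # SAM dialect output is parseable and 1-based
  d <- withr::local_tempdir()
  samPath <- file.path(d, "x.sam")
  writeSam(aln, c(fwd = sub, rev = olca:::revcompChar(sub)),
           c(ref = nchar(as.character(g))), samPath)
  lines <- readLines(samPath)
  expect_true(any(grepl("^@SQ\tSN:ref\tLN:40000$", lines)))
  body <- strsplit(grep("^[^@]", lines, value = TRUE), "\t")
  expect_equal(as.integer(vapply(body, `[[`, character(1), 2)), c(0L, 16L))
  expect_equal(as.integer(vapply(body, `[[`, character(1), 4)),
               aln$start + 1L)
})
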