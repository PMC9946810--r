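test_that("15-mer counting matches a brute-force substring scan", {
  # homopolymer read: 20 - 15 + 1 = 6 positions of the single 15-mer
  sp <- buildSpectrum(c(r1 = strrep("A", 20)), orientation = "canonical")
  h <- spectrumHistogram(sp)
  expect_equal(h$count, 6)
  expect_equal(h$distinct, 1)
  expect_equal(kmerCount(sp, strrep("A", 15)), 6L)

  # both-strand counting also credits the reverse complement
  sp2 <- buildSpectrum(c(r1 = strrep("A", 20)), orientation = "both")
  expect_equal(kmerCount(sp2, strrep("A", 15)), 6L)
  expect_equal(kmerCount(sp2, strrep("T", 15)), 6L)
  expect_equal(sum(spectrumHistogram(sp2)$count *
                   spectrumHistogram(sp2)$distinct), sp2@totalInstances)

  expect_error(buildSpectrum(character(0)), "no reads")
  expect_error(buildSpectrum(c(r1 = "ACGT")), "15-mer")

  # random reads vs. explicit substring counting on sampled 15-mers
  set.seed(11)
  genome <- randSeq(2000)
  starts <- sample(1800, 60, replace = TRUE)
  reads <- stats::setNames(substring(genome, starts, starts + 199),
                           paste0("r", seq_len(60)))
  sp3 <- buildSpectrum(reads, orientation = "both")
  countOcc <- function(km, s) {
    n <- 0L
    for (i in seq_len(nchar(s) - 14))
      if (substr(s, i, i + 14) == km) n <- n + 1L
    n
  }
  for (p in sample(186, 8)) {
    km <- substr(reads[[1]], p, p + 14)
    expected <- sum(vapply(reads, function(s)
      countOcc(km, s) + countOcc(olca:::revcompChar(km), s), integer(1)))
    expect_equal(kmerCount(sp3, km), expected)
  }
})

test_that("mode detection excludes the error peak and sizes the genome", {
  # dense histogram with an error peak at 1 and a coverage peak at 10
  h <- data.frame(count = c(1, 2, 10, 11), distinct = c(1000, 50, 400, 380))
  ms <- estimateModeAndSize(h)
  expect_equal(ms$mode, 10L)
  expect_false(ms$warning)

  # monotonically decreasing histogram: fallback with warning flag
  ms2 <- estimateModeAndSize(data.frame(count = 1, distinct = 100))
  expect_equal(ms2$mode, 1L)
  expect_true(ms2$warning)

  # error-free 30x reads of a 50-kb genome: size within 5% of the truth
  g <- simulateGenome(50000, seed = 301)
  reads <- simulateReads(g, depth = 30, meanLen = 2000, sdLen = 400,
                         substRate = 0, indelRate = 0, seed = 302)
  sp <- buildSpectrum(reads)
  expect_lt(abs(genomeSize(sp) - 50000) / 50000, 0.05)
  expect_equal(spectrumMode(sp), 30L, tolerance = 4)

  # 10x error-free coverage: histogram peak (counts >= 3) close to depth
  g2 <- simulateGenome(10000, seed = 303)
  reads2 <- simulateReads(g2, numReads = 100, meanLen = 1000, sdLen = 100,
                          substRate = 0, indelRate = 0, seed = 304)
  h2 <- spectrumHistogram(buildSpectrum(reads2))
  h2 <- h2[h2$count >= 3, ]
  peak <- h2$count[which.max(h2$distinct)]
  expect_lt(abs(peak - 10), 3)
})

test_that("rank and prime helpers follow their definitions", {
  expect_equal(kmerRank(20, 20), 0L)
  expect_equal(kmerRank(25, 20), 10L)
  expect_equal(kmerRank(15, 20), 10L)
  expect_error(kmerRank(-1, 5), ">= 0")

  expect_equal(smallestPrimeAbove(1), 2L)
  expect_equal(smallestPrimeAbove(7), 11L)
  expect_equal(smallestPrimeAbove(10), 11L)
  expect_equal(smallestPrimeAbove(0), 2L)
  expect_equal(smallestPrimeAbove(32767), 32771L)
  for (x in sample(0:32767, 25))
    expect_equal(smallestPrimeAbove(x), oraclePrimeAbove(x))
})

test_that("h(b) equals the brute-force (rank, cumBelow, mod) construction", {
  set.seed(21)
  for (rep in 1:5) {
    genome <- randSeq(1500)
    starts <- sample(1300, 40, replace = TRUE)
    reads <- stats::setNames(substring(genome, starts, starts + 149),
                             paste0("r", seq_len(40)))
    sp <- buildSpectrum(reads)
    oracle <- oracleHashTable(sp)
    sub <- oracle[sample(nrow(oracle), min(200, nrow(oracle))), ]
    kms <- decodeKmer(sub$code, 15)
    got <- vapply(kms, function(km) hashKmers(km, 15, sp)$hash, numeric(1))
    expect_equal(unname(got), sub$hash)
    # cumBelow accessor agrees with explicit counting
    expect_equal(cumBelow(sp, 0), 0)
    rk <- sample(sub$rank, 5)
    expect_equal(cumBelow(sp, rk),
                 vapply(rk, function(r) sum(oracle$rank < r), numeric(1)))
  }
})

test_that("modal-suffix k-mers hash below repeat-like k-mers", {
  set.seed(31)
  genome <- randSeq(8000)
  # plant a strong repeat
  rep40 <- substr(genome, 101, 400)
  genome <- paste0(genome, strrep(rep40, 40))
  starts <- sample(nchar(genome) - 500, 400, replace = TRUE)
  reads <- stats::setNames(substring(genome, starts, starts + 499),
                           paste0("r", seq_len(400)))
  sp <- buildSpectrum(reads)
  hk <- hashKmers(substr(genome, 1, 6000), 25, sp)
  mode <- spectrumMode(sp)
  modal <- hk$hash[hk$suffixCount == mode]
  repeatish <- hk$hash[hk$suffixCount >= 2 * mode]
  expect_gt(length(modal), 10)
  expect_gt(length(repeatish), 10)
  expect_lt(mean(modal), mean(repeatish))
})

test_that("substitution error correction fixes isolated planted errors", {
  set.seed(41)
  g <- simulateGenome(20000, seed = 401)
  reads <- simulateReads(g, depth = 30, meanLen = 1500, sdLen = 200,
                         substRate = 0, indelRate = 0, seed = 402)
  sp <- buildSpectrum(reads)

  # an exact genome substring stays unchanged
  clean <- substr(as.character(g), 5001, 5060)
  expect_equal(as.character(correctReads(c(x = clean), sp)[[1]]), clean)

  # one planted substitution in a well-covered context is reverted
  mut <- clean
  orig <- substr(mut, 30, 30)
  alt <- setdiff(BASES, orig)[1]
  substr(mut, 30, 30) <- alt
  fixed <- as.character(correctReads(c(x = mut), sp)[[1]])
  expect_equal(fixed, clean)

  # two adjacent substitutions may stay uncorrected, but must not corrupt
  mut2 <- clean
  substr(mut2, 30, 30) <- alt
  substr(mut2, 31, 31) <- setdiff(BASES, substr(clean, 31, 31))[1]
  out2 <- as.character(correctReads(c(x = mut2), sp)[[1]])
  expect_equal(nchar(out2), nchar(clean))
})
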