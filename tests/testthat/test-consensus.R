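test_that("two reads cut from one template reconstruct it exactly", {
  set.seed(91)
  tpl <- randSeq(6000)
  A <- substr(tpl, 1, 3500)
  B <- substr(tpl, 2501, 6000)
  path <- data.frame(read = c("A", "B"), reverse = c(FALSE, FALSE),
                     overlapToNext = c(1000, NA))
  pc <- buildPathConsensus(path, c(A = A, B = B))
  expect_equal(length(pc$contigs), 1L)
  expect_equal(pc$contigs[[1]], tpl)
  expect_equal(pc$placements$offset, c(0, 2500))

  # singleton path: the contig is the read
  pc2 <- buildPathConsensus(data.frame(read = "A", reverse = FALSE,
                                       overlapToNext = NA),
                            c(A = A))
  expect_equal(pc2$contigs[[1]], A)

  # a reversed read is stitched through its reverse complement
  path3 <- data.frame(read = c("A", "B"), reverse = c(FALSE, TRUE),
                      overlapToNext = c(1000, NA))
  pc3 <- buildPathConsensus(path3, c(A = A, B = olca:::revcompChar(B)))
  expect_equal(pc3$contigs[[1]], tpl)
})

test_that("noisy junction reads keep the consensus length near the truth", {
  set.seed(92)
  tpl <- randSeq(6000)
  A <- substr(tpl, 1, 3500)
  B <- substr(tpl, 2501, 6000)
  # plant ~1% indels into B
  b <- strsplit(B, "")[[1]]
  pos <- sort(sample(length(b), 30), decreasing = TRUE)
  for (p in pos) {
    if (stats::runif(1) < 0.5) b <- append(b, sample(BASES, 1), after = p)
    else b <- b[-p]
  }
  path <- data.frame(read = c("A", "B"), reverse = FALSE,
                     overlapToNext = c(1000, NA))
  pc <- buildPathConsensus(path, c(A = A, B = paste(b, collapse = "")))
  expect_equal(length(pc$contigs), 1L)
  expect_lt(abs(nchar(pc$contigs[[1]]) - 6000) / 6000, 0.01)

  # an unrelated "next read" fails the identity floor and splits the path
  set.seed(93)
  junk <- randSeq(3500)
  pcS <- buildPathConsensus(data.frame(read = c("A", "J"), reverse = FALSE,
                                       overlapToNext = c(1000, NA)),
                            c(A = A, J = junk))
  expect_equal(length(pcS$contigs), 2L)
})

test_that("active regions dilate and merge indel calls", {
  ins <- integer(300); del <- integer(300)
  ins[101] <- 2L  # 0-based position 100
  r1 <- detectActiveRegions(ins, del)
  expect_equal(r1, data.frame(start = 95, end = 106))

  del2 <- integer(300); del2[109] <- 3L
  r2 <- detectActiveRegions(ins, del2)
  expect_equal(r2, data.frame(start = 95, end = 114))

  # single-read support is below the default threshold
  ins3 <- integer(300); ins3[50] <- 1L
  expect_equal(nrow(detectActiveRegions(ins3, integer(300))), 0L)
  expect_equal(nrow(detectActiveRegions(integer(300), integer(300))), 0L)
})

test_that("polishing fixes planted substitutions and small indels", {
  set.seed(94)
  tpl <- randSeq(3000)
  reads <- stats::setNames(
    vapply(seq_len(20), function(i) tpl, character(1)),
    paste0("r", 1:20))
  placements <- data.frame(read = names(reads), contig = 1L, offset = 0,
                           reverse = FALSE, stringsAsFactors = FALSE)

  # planted substitution: fixed by the pileup majority pass
  bad <- tpl
  substr(bad, 1500, 1500) <- setdiff(BASES, substr(tpl, 1500, 1500))[1]
  out <- polishContigs(bad, reads, placements, rounds = 1)
  expect_equal(out$contigs[[1]], tpl)

  # planted 2-bp deletion: fixed by the active-region mini-assembly
  bad2 <- paste0(substr(tpl, 1, 1499), substr(tpl, 1502, 3000))
  out2 <- polishContigs(bad2, reads, placements, rounds = 1)
  expect_equal(out2$contigs[[1]], tpl)

  # planted 2-bp insertion: removed
  bad3 <- paste0(substr(tpl, 1, 1500), "GG", substr(tpl, 1501, 3000))
  out3 <- polishContigs(bad3, reads, placements, rounds = 1)
  expect_equal(out3$contigs[[1]], tpl)

  # an already-perfect consensus with error-free reads is untouched
  out4 <- polishContigs(tpl, reads, placements, rounds = 2)
  expect_equal(out4$contigs[[1]], tpl)

  # coverage 1: nothing to correct against, contig unchanged
  out5 <- polishContigs(bad, reads[1], placements[1, ], rounds = 1)
  expect_equal(out5$contigs[[1]], bad)
})

test_that("circularisation rotates and orients on the origin sequence", {
  set.seed(95)
  circ <- randSeq(9000)
  origin <- substr(circ, 1, 1500)
  rotated <- paste0(substr(circ, 4001, 9000), substr(circ, 1, 4000))
  out <- circularizeContigs(c(ctg = rotated), c(ori = origin))
  expect_equal(substr(out[[1]], 1, 1500), origin)
  expect_equal(nchar(out[[1]]), 9000)

  # reverse-strand origin: the contig is reverse-complemented first
  out2 <- circularizeContigs(c(ctg = olca:::revcompChar(rotated)),
                             c(ori = origin))
  expect_equal(substr(out2[[1]], 1, 1500), origin)

  # absent origin leaves the contig unchanged
  set.seed(96)
  out3 <- circularizeContigs(c(ctg = rotated), c(ori = randSeq(1500)))
  expect_equal(out3[["ctg"]], rotated)
})

test_that("embedded reads are placed through their hosts", {
  set.seed(97)
  tpl <- randSeq(8000)
  reads <- c(A = substr(tpl, 1, 4500),
             B = substr(tpl, 3001, 8000),
             E = substr(tpl, 1000, 2500))   # embedded in A
  res <- assembleReads(reads, minReadLength = 0)
  expect_equal(length(res$contigs), 1L)
  pl <- res$placements
  expect_setequal(pl$read, names(reads))
  eRow <- pl[pl$read == "E", ]
  expect_lt(abs(eRow$offset - 999), 60)
  expect_false(eRow$reverse)
})
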