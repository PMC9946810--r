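mkHits <- function(predStarts, reverse = FALSE, k = 25L) {
  # forward: predictedSubjectStart = subjectPos - queryPos
  qpos <- seq_along(predStarts) * 30L
  data.frame(queryPos = qpos, subjectPos = predStarts + qpos,
             reverse = reverse)
}

test_that("hit clustering groups consistent predicted starts", {
  # one tight group (centroid 100): geometry implies containment here
  cl <- clusterHits(mkHits(c(100, 102, 98)), queryLen = 3000,
                    subjectLen = 10000, minSharedKmers = 1L)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$centroid, 100)
  expect_equal(cl$n, 3L)

  # two well-separated groups of sizes 3 and 2, distinct configurations
  h <- rbind(mkHits(c(-200, -198, -202)), mkHits(c(2800, 2803)))
  cl2 <- clusterHits(h, queryLen = 3000, subjectLen = 3100,
                     minSharedKmers = 1L)
  expect_equal(nrow(cl2), 2L)
  expect_equal(cl2$n, c(3L, 2L))
  expect_equal(cl2$endS, c("s", "e"))

  # three clusters: only the two largest with distinct configurations kept
  h3 <- rbind(mkHits(c(2800, 2803, 2797, 2805)),
              mkHits(c(-200, -198, -202)),
              mkHits(c(-1500, -1498)))
  cl3 <- clusterHits(h3, queryLen = 3000, subjectLen = 3100,
                     minSharedKmers = 1L)
  expect_equal(nrow(cl3), 2L)
  expect_equal(cl3$n, c(4L, 3L))

  # two clusters supporting the SAME configuration: only the largest kept
  h4 <- rbind(mkHits(c(2800, 2803, 2797)), mkHits(c(2400, 2403)))
  cl4 <- clusterHits(h4, queryLen = 3000, subjectLen = 3100,
                     minSharedKmers = 1L, delta = 100)
  expect_equal(nrow(cl4), 1L)
  expect_equal(cl4$n, 3L)

  emptyHits <- data.frame(queryPos = integer(0), subjectPos = integer(0),
                          reverse = logical(0))
  expect_equal(nrow(clusterHits(emptyHits, 100, 200)), 0L)
})

test_that("cluster statistics follow their definitions", {
  k <- 25L
  h <- data.frame(queryPos = c(0L, 40L, 100L),
                  subjectPos = c(2800L, 2840L, 2900L), reverse = FALSE)
  cl <- clusterHits(h, queryLen = 3000, subjectLen = 3100,
                    minSharedKmers = 1L)
  expect_equal(cl$centroid, 2800)
  expect_equal(cl$overlap, 3100 - 2800)        # subjectLen - predicted start
  # csk: union of 25-bp k-mer footprints at 2800, 2840, 2900
  expect_equal(cl$csk, 25 + 25 + 25)
  expect_equal(cl$firstSubj, 2800)
  expect_equal(cl$lastSubj, 2900)
  expect_equal(cl$propEvidence, (2900 - 2800 + k) / 300)
  # overlapping k-mer footprints merge in the union
  h2 <- data.frame(queryPos = c(0L, 10L), subjectPos = c(2800L, 2810L),
                   reverse = FALSE)
  cl2 <- clusterHits(h2, queryLen = 3000, subjectLen = 3100,
                     minSharedKmers = 1L)
  expect_equal(cl2$csk, 10 + 25)
})

test_that("configuration classification covers the four cases + containment", {
  # forward, subject end over query start
  c1 <- classifyConfiguration(8000, FALSE, 9000, 10000)
  expect_false(c1$embedded)
  expect_equal(c(c1$endS, c1$endQ), c("e", "s"))
  # forward, query end over subject start
  c2 <- classifyConfiguration(-500, FALSE, 9000, 10000)
  expect_equal(c(c2$endS, c2$endQ), c("s", "e"))
  # reverse at the subject end pairs the two 3' vertices
  c3 <- classifyConfiguration(8000, TRUE, 9000, 10000)
  expect_equal(c(c3$endS, c3$endQ), c("e", "e"))
  # reverse at the subject start pairs the two 5' vertices
  c4 <- classifyConfiguration(-500, TRUE, 9000, 10000)
  expect_equal(c(c4$endS, c4$endQ), c("s", "s"))
  # containment (with tolerance at the boundaries)
  c5 <- classifyConfiguration(500, FALSE, 2000, 10000, tol = 50)
  expect_true(c5$embedded)
  c6 <- classifyConfiguration(-20, FALSE, 2000, 10000, tol = 50)
  expect_true(c6$embedded)
})

test_that("two overlapping reads produce the expected edge", {
  set.seed(611)
  tpl <- randSeq(6000)
  A <- substr(tpl, 1, 3500)
  B <- substr(tpl, 2501, 6000)
  gr <- buildAssemblyGraph(c(A = A, B = B))
  e <- graphEdges(gr)
  expect_equal(nrow(e), 1L)
  # subject is the first by name among equal lengths
  expect_equal(paste0(e$readA, "^", e$endA), "A^e")
  expect_equal(paste0(e$readB, "^", e$endB), "B^s")
  expect_lt(abs(e$overlap - 1000), 25 + 1)
  expect_false(e$reverse)

  # the same overlap with B reverse-complemented pairs the two 3' ends
  gr2 <- buildAssemblyGraph(c(A = A, B = olca:::revcompChar(B)))
  e2 <- graphEdges(gr2)
  expect_equal(nrow(e2), 1L)
  expect_true(e2$reverse)
  expect_equal(sort(paste0(c(e2$readA, e2$readB), "^", c(e2$endA, e2$endB))),
               c("A^e", "B^e"))

  # a read that is an exact substring is embedded, not a vertex
  gr3 <- buildAssemblyGraph(c(A = A, B = substr(tpl, 1000, 2800)))
  expect_equal(embeddedReads(gr3)$read, "B")
  expect_equal(embeddedReads(gr3)$host, "A")
  expect_lt(abs(embeddedReads(gr3)$relStart - 999), 2 * 25 + 1)
  expect_equal(nonEmbeddedReads(gr3), "A")
  expect_equal(nrow(graphEdges(gr3)), 0L)
})

test_that("graph construction is strand-symmetric and simple", {
  g <- simulateGenome(20000, seed = 621)
  reads <- simulateReads(g, depth = 12, meanLen = 2500, sdLen = 300,
                         substRate = 0, indelRate = 0, seed = 622)
  ss <- as.character(reads)
  gr <- buildAssemblyGraph(ss)
  # no multigraph: unordered vertex pairs are unique
  e <- graphEdges(gr)
  vA <- paste0(e$readA, "^", e$endA)
  vB <- paste0(e$readB, "^", e$endB)
  key <- ifelse(vA < vB, paste(vA, vB), paste(vB, vA))
  expect_equal(anyDuplicated(key), 0L)

  # reverse-complementing every read yields the same graph with ends swapped
  rc <- olca:::revcompChar(ss)
  names(rc) <- names(ss)
  gr2 <- buildAssemblyGraph(rc)
  e2 <- graphEdges(gr2)
  flipEnd <- function(x) ifelse(x == "s", "e", "s")
  key2 <- {
    vA2 <- paste0(e2$readA, "^", flipEnd(e2$endA))
    vB2 <- paste0(e2$readB, "^", flipEnd(e2$endB))
    ifelse(vA2 < vB2, paste(vA2, vB2), paste(vB2, vA2))
  }
  expect_setequal(key2, key)
  expect_equal(nrow(embeddedReads(gr2)), nrow(embeddedReads(gr)))
})

test_that("the diagnostic edge dump is a parseable TSV", {
  set.seed(641)
  tpl <- randSeq(6000)
  gr <- buildAssemblyGraph(c(A = substr(tpl, 1, 3500),
                             B = substr(tpl, 2501, 6000)))
  d <- withr::local_tempdir()
  p <- file.path(d, "edges.tsv")
  writeGraphEdges(gr, p)
  df <- read.table(p, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(nrow(df), nrow(graphEdges(gr)))
  expect_true(all(c("readA", "endA", "overlap", "csk") %in% names(df)))
})

test_that("overlap estimates track the simulator truth on error-free data", {
  g <- simulateGenome(20000, seed = 631)
  reads <- simulateReads(g, depth = 15, meanLen = 2500, sdLen = 300,
                         substRate = 0, indelRate = 0, seed = 632)
  gr <- buildAssemblyGraph(as.character(reads))
  tr <- readTruth(names(reads))
  rownames(tr) <- tr$readName
  e <- graphEdges(gr)
  expect_gt(nrow(e), 10)
  trueOv <- pmin(tr[e$readA, "end"], tr[e$readB, "end"]) -
    pmax(tr[e$readA, "start"], tr[e$readB, "start"])
  ok <- abs(e$overlap - trueOv) <= 25
  expect_gte(mean(ok), 0.95)
})
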