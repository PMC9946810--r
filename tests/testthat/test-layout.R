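mkEdge <- function(a, ea, b, eb, ov, csk = ov * 0.4, n = 20L, prop = 0.9) {
  data.frame(readA = a, endA = ea, readB = b, endB = eb, overlap = ov,
             csk = csk, nSharedKmers = n, propEvidence = prop,
             reverse = FALSE, centroid = 0, stringsAsFactors = FALSE)
}

test_that("safe edges are reciprocal best in overlap AND csk", {
  lens <- c(A = 5000L, B = 5000L, C = 5000L)
  # single mutual edge: trivially reciprocal best
  g1 <- makeGraph(mkEdge("A", "e", "B", "s", 1000), lens)
  expect_equal(selectSafeEdges(g1), 1L)

  # u's best-overlap edge differs from u's best-csk edge: neither is safe
  e <- rbind(mkEdge("A", "e", "B", "s", 2000, csk = 300),
             mkEdge("A", "e", "C", "s", 1500, csk = 800))
  g2 <- makeGraph(e, lens)
  expect_equal(selectSafeEdges(g2), integer(0))

  # dominating edge is safe even with a competitor
  e3 <- rbind(mkEdge("A", "e", "B", "s", 2000, csk = 900),
              mkEdge("A", "e", "C", "s", 1500, csk = 500))
  g3 <- makeGraph(e3, lens)
  expect_equal(selectSafeEdges(g3), 1L)
})

test_that("high-degree hub vertices are excluded from safe edges", {
  # a star: hub H^e connects to many reads, plus a clean mutual pair X-Y
  spokes <- paste0("S", 1:12)
  e <- do.call(rbind, lapply(spokes, function(s)
    mkEdge("H", "e", s, "s", 1000 + match(s, spokes), csk = 400 +
             match(s, spokes))))
  e <- rbind(e, mkEdge("X", "e", "Y", "s", 1500, csk = 600))
  lens <- stats::setNames(rep(5000L, 15), c("H", spokes, "X", "Y"))
  g <- makeGraph(e, lens)
  safe <- selectSafeEdges(g)
  # hub degree 12 is far beyond mean + 3 SD; only X-Y can be safe
  expect_equal(safe, nrow(e))
})

test_that("feature distributions are fitted as specified", {
  lens <- stats::setNames(rep(6000L, 40), paste0("R", 1:40))
  # degenerate overlaps: sd floored at 1
  e <- do.call(rbind, lapply(1:19, function(i)
    mkEdge(paste0("R", i), "e", paste0("R", i + 1), "s", 10000,
           csk = 4000, prop = 0.9)))
  g <- makeGraph(e, lens)
  m <- fitEdgeModel(g, seq_len(nrow(e)))
  expect_false(m@fallback)
  expect_equal(m@overlapMean, 10000)
  expect_equal(m@overlapSD, 1.0)

  # beta method of moments: alpha = m (m(1-m)/v - 1)
  set.seed(71)
  props <- pmin(1 - 1e-6, pmax(1e-6, rnorm(19, 0.9, 0.09)))
  e$propEvidence <- props
  m2 <- fitEdgeModel(makeGraph(e, lens), seq_len(nrow(e)))
  mm <- mean(props); vv <- var(props)
  expect_equal(m2@propAlpha, mm * (mm * (1 - mm) / vv - 1), tolerance = 1e-6)
  expect_equal(m2@propAlpha / (m2@propAlpha + m2@propBeta), mm,
               tolerance = 1e-6)

  # < 10 safe edges: fallback flag
  m3 <- fitEdgeModel(g, 1:5)
  expect_true(m3@fallback)

  # large-sample normal fit recovers the generating parameters
  set.seed(72)
  ovs <- rnorm(10000, 5000, 500)
  lens2 <- stats::setNames(rep(9000L, 10001), paste0("Q", 1:10001))
  e2 <- do.call(rbind, lapply(seq_along(ovs), function(i)
    mkEdge(paste0("Q", i), "e", paste0("Q", i + 1), "s", ovs[i],
           csk = 2000, prop = 0.9)))
  m4 <- fitEdgeModel(makeGraph(e2, lens2), seq_along(ovs))
  expect_lt(abs(m4@overlapMean - 5000) / 5000, 0.01)
  expect_lt(abs(m4@overlapSD - 500) / 500, 0.05)
})

test_that("edge scores are summed lower-tail log P-values", {
  m <- new("EdgeFeatureModel", overlapMean = 1000, overlapSD = 100,
           cskMean = 400, cskSD = 50, propAlpha = 2, propBeta = 2,
           fallback = FALSE, nSafe = 20L)
  # at the model medians the score is 3 * log(0.5) (symmetric beta)
  at <- data.frame(overlap = 1000, csk = 400, propEvidence = 0.5)
  expect_equal(edgeLogLikelihood(at, m), 3 * log(0.5), tolerance = 1e-9)

  # monotonicity: raising any one feature never lowers the score
  base <- data.frame(overlap = 900, csk = 380, propEvidence = 0.6)
  s0 <- edgeLogLikelihood(base, m)
  for (col in names(base)) {
    up <- base
    up[[col]] <- up[[col]] * 1.2
    if (col == "propEvidence") up[[col]] <- min(up[[col]], 0.99)
    expect_gte(edgeLogLikelihood(up, m), s0)
  }

  # strict dominance implies a strictly better score
  dom <- data.frame(overlap = 1200, csk = 500, propEvidence = 0.8)
  expect_gt(edgeLogLikelihood(dom, m), s0)
})

test_that("layout selects safe chains and rejects cycles", {
  lens <- c(A = 5000L, B = 5000L, C = 5000L)
  chain <- rbind(mkEdge("A", "e", "B", "s", 1000),
                 mkEdge("B", "e", "C", "s", 900))
  closing <- mkEdge("A", "s", "C", "e", 800)
  g <- makeGraph(rbind(chain, closing), lens)
  lay <- buildLayout(g, safe = 1:2,
                     model = new("EdgeFeatureModel", overlapMean = 900,
                                 overlapSD = 100, cskMean = 380, cskSD = 50,
                                 propAlpha = 2, propBeta = 2,
                                 fallback = FALSE, nSafe = 10L))
  expect_equal(lay@selectedEdges, 1:2)  # the cycle-closing edge is rejected
  expect_equal(length(lay@paths), 1L)
  p <- lay@paths[[1]]
  expect_equal(p$read, c("A", "B", "C"))
  expect_equal(p$reverse, c(FALSE, FALSE, FALSE))
  expect_equal(p$overlapToNext, c(1000, 900, NA))
})

test_that("paths orient reads from the edge end labels", {
  # A^e-B^e means B runs reverse-complemented after A
  lens <- c(A = 5000L, B = 5000L)
  g <- makeGraph(mkEdge("A", "e", "B", "e", 1000), lens)
  lay <- buildLayout(g, safe = 1L, model = fitEdgeModel(g, integer(0)))
  p <- lay@paths[[1]]
  expect_equal(p$read, c("A", "B"))
  expect_equal(p$reverse, c(FALSE, TRUE))

  # canonicalisation: the first read name is the lexicographically smaller
  g2 <- makeGraph(mkEdge("Z", "e", "B", "s", 1000), c(Z = 5000L, B = 5000L))
  lay2 <- buildLayout(g2, safe = 1L, model = fitEdgeModel(g2, integer(0)))
  expect_equal(lay2@paths[[1]]$read[1], "B")
})

test_that("every vertex joins at most one selected edge (matching property)", {
  set.seed(81)
  g <- simulateGenome(20000, seed = 811)
  reads <- simulateReads(g, depth = 15, meanLen = 2500, sdLen = 300,
                         substRate = 0, indelRate = 0, seed = 812)
  gr <- buildAssemblyGraph(as.character(reads))
  lay <- buildLayout(gr)
  e <- graphEdges(gr)[lay@selectedEdges, ]
  vs <- c(paste0(e$readA, "^", e$endA), paste0(e$readB, "^", e$endB))
  expect_equal(anyDuplicated(vs), 0L)
  # paths partition the non-embedded reads
  inPaths <- unlist(lapply(lay@paths, `[[`, "read"))
  expect_setequal(inPaths, nonEmbeddedReads(gr))
  expect_equal(anyDuplicated(inPaths), 0L)
})
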