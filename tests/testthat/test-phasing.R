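mkFM <- function(M, positions = seq_len(ncol(M)) * 100) {
  new("FragmentMatrix", alleles = M,
      readNames = paste0("f", seq_len(nrow(M))),
      contig = "c1", positions = as.numeric(positions))
}

test_that("noiseless complementary fragments phase perfectly", {
  M <- rbind(c(0L, 0L, 0L), c(0L, 0L, 0L), c(1L, 1L, 1L), c(1L, 1L, 1L))
  ph <- phaseFragments(mkFM(M), seed = 1)
  expect_equal(length(ph), 1L)
  b <- ph[[1]]
  expect_equal(b$mec, 0)
  expect_equal(b$sides, c(1L, 1L, 2L, 2L))
  expect_equal(b$hap1, c(0L, 0L, 0L))
  expect_equal(b$hap2, c(1L, 1L, 1L))

  # single-fragment block: trivial phasing, MEC 0
  ph1 <- phaseFragments(mkFM(matrix(c(0L, 1L), 1)), seed = 1)
  expect_equal(ph1[[1]]$mec, 0)
  expect_equal(ph1[[1]]$sides, 1L)
})

test_that("disconnected variants split into blocks", {
  # fragments 1-2 cover variants 1-2; fragments 3-4 cover variants 3-4
  M <- rbind(c(0L, 0L, NA, NA), c(1L, 1L, NA, NA),
             c(NA, NA, 0L, 1L), c(NA, NA, 1L, 0L))
  ph <- phaseFragments(mkFM(M), seed = 1)
  expect_equal(length(ph), 2L)
  expect_equal(sort(vapply(ph, function(b) length(b$variantIdx),
                           integer(1))), c(2L, 2L))
})

test_that("the heuristic reaches the exhaustive minimum MEC", {
  set.seed(141)
  for (i in 1:40) {
    M <- randomFragmentMatrix(sample(4:10, 1), sample(3:6, 1),
                              flipRate = stats::runif(1, 0, 0.25))
    ph <- phaseFragments(mkFM(M), seed = i)
    expect_equal(attr(ph, "mec"), oracleMinMec(M),
                 info = paste("instance", i))
  }
})

test_that("flipping all alleles flips the labels, not the bipartition", {
  set.seed(151)
  for (i in 1:10) {
    M <- randomFragmentMatrix(8, 5, flipRate = 0.1)
    ph1 <- phaseFragments(mkFM(M), seed = 3)
    M2 <- 1L - M
    ph2 <- phaseFragments(mkFM(M2), seed = 3)
    expect_equal(length(ph1), length(ph2))
    for (b in seq_along(ph1)) {
      expect_equal(ph1[[b]]$sides, ph2[[b]]$sides)
      same <- !is.na(ph1[[b]]$hap1) & !is.na(ph2[[b]]$hap1)
      expect_equal(ph1[[b]]$hap1[same], 1L - ph2[[b]]$hap1[same])
      expect_equal(attr(ph1, "mec"), attr(ph2, "mec"))
    }
  }
})

test_that("het calling applies the depth and allele-fraction rules", {
  set.seed(161)
  tpl <- randSeq(3000)
  alt <- tpl
  substr(alt, 1500, 1500) <- setdiff(BASES, substr(tpl, 1500, 1500))[1]
  # 15 reads per haplotype: a clean 50/50 het at position 1499 (0-based)
  reads <- c(stats::setNames(rep(tpl, 15), paste0("a", 1:15)),
             stats::setNames(rep(alt, 15), paste0("b", 1:15)))
  placements <- data.frame(read = names(reads), contig = 1L, offset = 0,
                           reverse = FALSE, stringsAsFactors = FALSE)
  het <- callHetSites(c(c1 = tpl), reads, placements)
  expect_equal(het$pos, 1499)
  expect_setequal(c(het$allele0, het$allele1),
                  c(substr(tpl, 1500, 1500), substr(alt, 1500, 1500)))

  # a 29:1 column is not heterozygous
  reads2 <- c(stats::setNames(rep(tpl, 29), paste0("a", 1:29)),
              stats::setNames(alt, "b1"))
  placements2 <- data.frame(read = names(reads2), contig = 1L, offset = 0,
                            reverse = FALSE, stringsAsFactors = FALSE)
  expect_equal(nrow(callHetSites(c(c1 = tpl), reads2, placements2)), 0L)
})

test_that("planted SNVs are recovered from simulated diploid reads", {
  h1 <- simulateGenome(30000, seed = 171, name = "hap")
  dip <- buildDiploid(h1, snvRate = 0.01, seed = 172)
  reads <- simulateReads(dip, depth = 30, meanLen = 4000, sdLen = 500,
                         seed = 173)
  res <- assembleReads(as.character(reads))
  het <- callHetSites(res$contigs, as.character(reads), res$placements)
  # compare het density: planted variants should largely be rediscovered
  expect_gte(nrow(het) / nrow(dip$variants), 0.9)
})

test_that("the fragment matrix reflects read alleles at het sites", {
  set.seed(181)
  tpl <- randSeq(4000)
  alt <- tpl
  vpos <- c(800L, 1600L, 2400L, 3200L)
  for (p in vpos)
    substr(alt, p + 1, p + 1) <- setdiff(BASES, substr(tpl, p + 1, p + 1))[1]
  reads <- c(stats::setNames(rep(tpl, 6), paste0("a", 1:6)),
             stats::setNames(rep(alt, 6), paste0("b", 1:6)))
  placements <- data.frame(read = names(reads), contig = 1L, offset = 0,
                           reverse = FALSE, stringsAsFactors = FALSE)
  het <- callHetSites(c(c1 = tpl), reads, placements)
  expect_equal(het$pos, vpos)
  fms <- buildFragmentMatrix(c(c1 = tpl), reads, placements, het)
  fm <- fms[["c1"]]
  expect_equal(dim(fm@alleles), c(12L, 4L))
  aRows <- grepl("^a", fm@readNames)
  # per site: template reads carry one allele, mutant reads the other
  for (v in 1:4) {
    expect_equal(length(unique(fm@alleles[aRows, v])), 1L)
    expect_true(all(fm@alleles[!aRows, v] == 1L - fm@alleles[aRows, v][1]))
  }

  ph <- phaseFragments(fm, seed = 2)
  expect_equal(attr(ph, "mec"), 0)
  bl <- classifyBlocks(ph, nchar(tpl), meanReadLength = 4000)
  expect_equal(bl$class[!is.na(bl$block)], "phased")
  # the classification tiles the contig
  expect_equal(bl$start[1], 0)
  expect_equal(bl$end[nrow(bl)], nchar(tpl))
  expect_true(all(bl$start[-1] == bl$end[-nrow(bl)]))
})

test_that("unbalanced clusters classify as heterozygous deletion", {
  M <- rbind(matrix(0L, 9, 3), matrix(1L, 1, 3))
  ph <- phaseFragments(mkFM(M, positions = c(500, 1000, 1500)), seed = 1)
  bl <- classifyBlocks(ph, 2000, meanReadLength = 1800)
  expect_equal(bl$class[!is.na(bl$block)], "heterozygousDeletion")

  # no phasing at all: the whole contig is homozygous
  bl0 <- classifyBlocks(list(), 2000, meanReadLength = 500)
  expect_equal(bl0$class, "homozygous")

  # long het-free gaps between blocks become homozygous filler
  M2 <- rbind(c(0L, 0L, NA, NA), c(1L, 1L, NA, NA),
              c(NA, NA, 0L, 0L), c(NA, NA, 1L, 1L))
  ph2 <- phaseFragments(mkFM(M2, positions = c(100, 200, 5100, 5200)),
                        seed = 1)
  bl2 <- classifyBlocks(ph2, 5400, meanReadLength = 1000)
  expect_true("homozygous" %in% bl2$class)
  expect_true(all(bl2$start[-1] == bl2$end[-nrow(bl2)]))
})

test_that("homozygous read sets fall back to the haploid assembly", {
  g <- simulateGenome(20000, seed = 191)
  reads <- simulateReads(g, depth = 25, meanLen = 3000, sdLen = 300,
                         substRate = 0, indelRate = 0, seed = 192)
  res <- assembleDiploid(as.character(reads), seed = 1)
  expect_true(res$haploid)
  expect_equal(as.character(res$contigs), as.character(res$haploidContigs))
})

test_that("the het-site TSV adapter round-trips", {
  d <- withr::local_tempdir()
  het <- data.frame(contig = "c1", pos = c(10, 20), allele0 = c("A", "C"),
                    allele1 = c("G", "T"), stringsAsFactors = FALSE)
  p <- file.path(d, "het.tsv")
  write.table(het, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(readHetSitesTsv(p), het)
  writeLines("contig\tpos", p)
  expect_error(readHetSitesTsv(p), "columns")
})

test_that("het VCF dialect output carries phased genotypes", {
  d <- withr::local_tempdir()
  het <- data.frame(contig = "c1", pos = c(99, 199),
                    allele0 = c("A", "C"), allele1 = c("G", "T"),
                    stringsAsFactors = FALSE)
  phasing <- list(c1 = list(list(positions = c(99, 199), hap1 = c(0L, 1L),
                                 hap2 = c(1L, 0L))))
  p <- file.path(d, "x.vcf")
  writeHetVcf(het, p, phasing)
  lines <- readLines(p)
  body <- strsplit(grep("^[^#]", lines, value = TRUE), "\t")
  expect_equal(vapply(body, `[[`, character(1), 2), c("100", "200"))
  expect_equal(vapply(body, `[[`, character(1), 10), c("0|1", "1|0"))
})
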