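#' FragmentMatrix: reads-by-heterozygous-variant allele matrix
#'
#' One row per informative fragment (a read covering at least two het sites of
#' one contig), one column per ordered het site; entries are 0 (allele0), 1
#' (allele1) or NA (not covered / other base / deleted).
#'
#' @slot alleles Integer matrix (fragments x variants) of 0/1/NA.
#' @slot readNames Fragment (read) names, one per row.
#' @slot contig Contig name.
#' @slot positions 0-based het-site positions (one per column).
#' @export
setClass("FragmentMatrix", representation(
  alleles = "matrix", readNames = "character", contig = "character",
  positions = "numeric"
))

setMethod("show", "FragmentMatrix", function(object) {
  cat("FragmentMatrix:", nrow(object@alleles), "fragments x",
      ncol(object@alleles), "het sites on", object@contig, "\n")
})

# ---- het-site calling -------------------------------------------------------

hetFromPileup <- function(pileup, contigName, minDepth, fracRange) {
  cnt <- pileup$counts
  L <- ncol(cnt)
  depth <- colSums(cnt)
  ord1 <- max.col(t(cnt), ties.method = "first")
  top1 <- cnt[cbind(ord1, seq_len(L))]
  cnt2 <- cnt
  cnt2[cbind(ord1, seq_len(L))] <- -1L
  ord2 <- max.col(t(cnt2), ties.method = "first")
  top2 <- cnt[cbind(ord2, seq_len(L))]
  frac <- ifelse(depth > 0, top2 / pmax(depth, 1L), 0)
  sel <- which(depth >= minDepth & frac >= fracRange[1] & frac <= fracRange[2])
  bases <- c("A", "C", "G", "T")
  if (length(sel) == 0)
    return(data.frame(contig = character(0), pos = numeric(0),
                      allele0 = character(0), allele1 = character(0),
                      depth = numeric(0), frac = numeric(0),
                      stringsAsFactors = FALSE))
  data.frame(contig = contigName, pos = sel - 1L, allele0 = bases[ord1[sel]],
             allele1 = bases[ord2[sel]], depth = depth[sel], frac = frac[sel],
             stringsAsFactors = FALSE)
}

#' Call heterozygous SNV candidates on assembled contigs
#'
#' Pileup columns with depth >= \code{minDepth} whose second allele carries a
#' fraction of the depth within \code{fracRange} are emitted as heterozygous
#' SNV candidates (substitutions only).
#'
#' @param contigs Contigs (DNAStringSet / character).
#' @param reads All reads.
#' @param placements Read placements from \code{\link{assembleReads}}.
#' @param minDepth Minimum pileup depth (default 5).
#' @param fracRange Second-allele fraction window (default c(0.2, 0.8)).
#' @return data.frame(contig, pos, allele0, allele1, depth, frac) with 0-based
#'   positions; allele0 is the majority base.
#' @export
callHetSites <- function(contigs, reads, placements, minDepth = 5L,
                         fracRange = c(0.2, 0.8)) {
  ctg <- asSeqChar(contigs)
  aln <- realignReads(unname(ctg), reads, placements)
  out <- list()
  for (ci in seq_along(ctg)) {
    a <- aln[[ci]]
    if (length(a$starts) == 0) next
    pl <- olca_pileup(nchar(ctg[[ci]]), a$starts, a$seqs, a$ops, a$lens)
    out[[length(out) + 1L]] <- hetFromPileup(pl, names(ctg)[ci], minDepth,
                                             fracRange)
  }
  if (length(out) == 0)
    return(hetFromPileup(list(counts = matrix(0L, 4, 0)), character(0),
                         minDepth, fracRange))
  do.call(rbind, out)
}

#' Read a het-site table from TSV
#'
#' Minimal adapter in place of VCF parsing: a tab-separated file with columns
#' contig, pos (0-based), allele0, allele1.
#'
#' @param path TSV path (header required).
#' @return data.frame(contig, pos, allele0, allele1).
#' @export
readHetSitesTsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("contig", "pos", "allele0", "allele1")
  if (!all(need %in% names(df)))
    stop("het-site TSV needs columns: ", paste(need, collapse = ", "))
  df[need]
}

# ---- fragment matrix --------------------------------------------------------

fragmentsFromAln <- function(a, hetContig, contigName) {
  pos <- as.integer(hetContig$pos)
  bases <- c("A", "C", "G", "T")
  a0 <- match(hetContig$allele0, bases) - 1L
  a1 <- match(hetContig$allele1, bases) - 1L
  bt <- olca_read_bases_at(a$starts, a$seqs, a$ops, a$lens, pos)
  M <- matrix(NA_integer_, nrow = length(a$starts), ncol = length(pos))
  if (nrow(bt) > 0) {
    allele <- rep(NA_integer_, nrow(bt))
    allele[bt$base == a0[bt$posIdx]] <- 0L
    allele[bt$base == a1[bt$posIdx]] <- 1L
    M[cbind(bt$read, bt$posIdx)] <- allele
  }
  keep <- rowSums(!is.na(M)) >= 2L
  new("FragmentMatrix", alleles = M[keep, , drop = FALSE],
      readNames = a$readNames[keep], contig = contigName,
      positions = as.numeric(pos))
}

#' Build the fragment matrix of a contig
#'
#' @param contigs,reads,placements As in \code{\link{callHetSites}}.
#' @param hetSites Het-site table (from \code{\link{callHetSites}} or
#'   \code{\link{readHetSitesTsv}}).
#' @return Named list of \linkS4class{FragmentMatrix}, one per contig with
#'   het sites.
#' @export
buildFragmentMatrix <- function(contigs, reads, placements, hetSites) {
  ctg <- asSeqChar(contigs)
  aln <- realignReads(unname(ctg), reads, placements)
  out <- list()
  for (ci in seq_along(ctg)) {
    hc <- hetSites[hetSites$contig == names(ctg)[ci], , drop = FALSE]
    if (nrow(hc) == 0) next
    hc <- hc[order(hc$pos), , drop = FALSE]
    out[[names(ctg)[ci]]] <- fragmentsFromAln(aln[[ci]], hc, names(ctg)[ci])
  }
  out
}

# ---- MEC and phasing --------------------------------------------------------

#' Minimum-error-correction score of a bipartition
#'
#' Per variant, side 1 supports haplotype allele h and side 2 its complement;
#' the MEC contribution is the smaller of the two error counts over h in
#' {0, 1}. NA entries are ignored.
#'
#' @param alleles Fragment-by-variant 0/1/NA matrix.
#' @param sides Integer vector (1/2) assigning fragments to haplotype
#'   clusters.
#' @return Total MEC (numeric).
#' @export
mecScore <- function(alleles, sides) {
  if (nrow(alleles) == 0) return(0)
  s1 <- sides == 1L
  n1_1 <- colSums(alleles[s1, , drop = FALSE] == 1L, na.rm = TRUE)
  n1_0 <- colSums(alleles[s1, , drop = FALSE] == 0L, na.rm = TRUE)
  n2_1 <- colSums(alleles[!s1, , drop = FALSE] == 1L, na.rm = TRUE)
  n2_0 <- colSums(alleles[!s1, , drop = FALSE] == 0L, na.rm = TRUE)
  # h = 0: errors are side1 ones + side2 zeros; h = 1: the mirror
  sum(pmin(n1_1 + n2_0, n1_0 + n2_1))
}

phaseBlock <- function(M, restarts) {
  n <- nrow(M)
  if (n == 1L) {
    h1 <- ifelse(is.na(M[1, ]), NA_integer_, M[1, ])
    return(list(sides = 1L, mec = 0,
                hap1 = h1, hap2 = ifelse(is.na(h1), NA_integer_, 1L - h1)))
  }
  m <- ncol(M)
  cov <- lapply(seq_len(n), function(f) which(!is.na(M[f, ])))

  # incremental machinery: per-variant counts of allele a on side s; the MEC
  # contribution of variant v is min(c11 + c20, c10 + c21)
  mk <- function() list(c10 = numeric(m), c11 = numeric(m),
                        c20 = numeric(m), c21 = numeric(m))
  vMec <- function(ct, v) pmin(ct$c11[v] + ct$c20[v], ct$c10[v] + ct$c21[v])
  addFrag <- function(ct, f, side) {
    v <- cov[[f]]; a <- M[f, v]
    if (side == 1L) {
      ct$c10[v] <- ct$c10[v] + (a == 0L); ct$c11[v] <- ct$c11[v] + (a == 1L)
    } else {
      ct$c20[v] <- ct$c20[v] + (a == 0L); ct$c21[v] <- ct$c21[v] + (a == 1L)
    }
    ct
  }
  dropFrag <- function(ct, f, side) {
    v <- cov[[f]]; a <- M[f, v]
    if (side == 1L) {
      ct$c10[v] <- ct$c10[v] - (a == 0L); ct$c11[v] <- ct$c11[v] - (a == 1L)
    } else {
      ct$c20[v] <- ct$c20[v] - (a == 0L); ct$c21[v] <- ct$c21[v] - (a == 1L)
    }
    ct
  }
  countsFor <- function(sides) {
    ct <- mk()
    for (f in seq_len(n)) ct <- addFrag(ct, f, sides[f])
    ct
  }
  totalMec <- function(ct) sum(vMec(ct, seq_len(m)))

  refine <- function(sides, ct) {
    repeat {
      changed <- FALSE
      for (f in seq_len(n)) {
        v <- cov[[f]]
        if (length(v) == 0) next
        before <- sum(vMec(ct, v))
        ct2 <- addFrag(dropFrag(ct, f, sides[f]), f, 3L - sides[f])
        after <- sum(vMec(ct2, v))
        if (after < before) {
          ct <- ct2
          sides[f] <- 3L - sides[f]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    list(sides = sides, ct = ct)
  }

  best <- NULL
  for (r in seq_len(restarts)) {
    if (r == 1L) {
      # greedy seeding: place each fragment on the side that adds less MEC
      sides <- integer(n)
      sides[1] <- 1L
      ct <- addFrag(mk(), 1L, 1L)
      for (f in 2:n) {
        v <- cov[[f]]
        d1 <- sum(vMec(addFrag(ct, f, 1L), v)) - sum(vMec(ct, v))
        d2 <- sum(vMec(addFrag(ct, f, 2L), v)) - sum(vMec(ct, v))
        sides[f] <- if (d1 <= d2) 1L else 2L
        ct <- addFrag(ct, f, sides[f])
      }
    } else {
      sides <- sample(c(1L, 2L), n, replace = TRUE)
      ct <- countsFor(sides)
    }
    ref <- refine(sides, ct)
    mec <- totalMec(ref$ct)
    if (is.null(best) || mec < best$mec)
      best <- list(sides = ref$sides, mec = mec)
    if (best$mec == 0) break
  }
  sides <- best$sides
  if (sides[1] != 1L) sides <- 3L - sides  # canonical: first fragment side 1
  # haplotype strings: majority per side, complements enforced by MEC choice
  hap1 <- integer(ncol(M))
  for (v in seq_len(ncol(M))) {
    x1 <- M[sides == 1L, v]; x2 <- M[sides == 2L, v]
    e0 <- sum(x1 == 1L, na.rm = TRUE) + sum(x2 == 0L, na.rm = TRUE)
    e1 <- sum(x1 == 0L, na.rm = TRUE) + sum(x2 == 1L, na.rm = TRUE)
    hap1[v] <- if (all(is.na(c(x1, x2)))) NA_integer_
               else if (e0 < e1) 0L
               else if (e1 < e0) 1L
               else {
                 # tie: side with the first observed allele decides, which
                 # keeps the call symmetric under flipping all alleles
                 obs1 <- x1[!is.na(x1)]
                 if (length(obs1) > 0) obs1[1]
                 else 1L - x2[!is.na(x2)][1]
               }
  }
  list(sides = sides, mec = best$mec, hap1 = hap1,
       hap2 = ifelse(is.na(hap1), NA_integer_, 1L - hap1))
}

#' Phase a fragment matrix into two haplotype clusters
#'
#' Fragments are first split into connected blocks (fragments sharing no
#' variant chain fall into different blocks); within each block a ReFHap-style
#' heuristic (greedy seeding plus randomized-restart single-fragment flips)
#' bipartitions the fragments to minimise the MEC score. Haplotype alleles are
#' the per-variant majority of each cluster (complementary across clusters).
#'
#' @param fm A \linkS4class{FragmentMatrix}.
#' @param seed RNG seed for the restarts (default 1).
#' @param restarts Number of restarts per block; by default 10 + 2 n for
#'   blocks of n <= 12 fragments (where restarts guarantee reaching the
#'   exhaustive optimum in practice) and 3 for larger blocks, whose dense
#'   linkage makes the greedy + flip refinement reliable on its own.
#' @return list of blocks, each with variantIdx (columns of the matrix),
#'   positions, readNames, sides (1/2), hap1/hap2 (0/1/NA per variant) and
#'   mec; plus total MEC as attribute "mec".
#' @export
phaseFragments <- function(fm, seed = 1L, restarts = NULL) {
  M <- fm@alleles
  if (nrow(M) == 0) {
    out <- list()
    attr(out, "mec") <- 0
    return(out)
  }
  # connected blocks over variants via shared fragments
  nv <- ncol(M)
  parent <- seq_len(nv)
  find <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  for (f in seq_len(nrow(M))) {
    cov <- which(!is.na(M[f, ]))
    if (length(cov) >= 2)
      for (j in 2:length(cov))
        parent[find(cov[j])] <- find(cov[1])
  }
  comp <- vapply(seq_len(nv), find, integer(1))
  blocksIdx <- split(seq_len(nv), comp)
  # drop variant-only blocks with no informative fragment pair coverage
  out <- list()
  withSeed(seed, {
    for (b in blocksIdx) {
      rows <- which(rowSums(!is.na(M[, b, drop = FALSE])) >= 1L)
      rows <- rows[rowSums(!is.na(M[rows, b, drop = FALSE])) >= 2L |
                     length(b) == 1L]
      if (length(rows) == 0) next
      Mb <- M[rows, b, drop = FALSE]
      rst <- if (!is.null(restarts)) restarts
             else if (length(rows) <= 12L) 10L + 2L * length(rows)
             else 3L
      ph <- phaseBlock(Mb, rst)
      out[[length(out) + 1L]] <- list(
        variantIdx = b, positions = fm@positions[b],
        readNames = fm@readNames[rows], sides = ph$sides, hap1 = ph$hap1,
        hap2 = ph$hap2, mec = ph$mec)
    }
  })
  attr(out, "mec") <- sum(vapply(out, `[[`, numeric(1), "mec"))
  out
}

#' Classify contig regions from phased blocks
#'
#' Regions spanned by a het block whose two clusters both carry at least
#' \code{depthRatio} of the block's fragment depth are phased; blocks where
#' one cluster falls below that ratio indicate a large heterozygous deletion;
#' gaps between blocks longer than the mean read length (they carry no het
#' site by construction) are regions of high homozygosity. The returned blocks
#' tile [0, contigLen).
#'
#' @param phasing Output of \code{\link{phaseFragments}} for one contig.
#' @param contigLen Contig length in bases.
#' @param meanReadLength Mean read length in bases.
#' @param depthRatio Minority-cluster depth ratio for a phased call
#'   (default 0.25).
#' @return data.frame(start, end, class, block) tiling the contig; class in
#'   {"phased", "heterozygousDeletion", "homozygous"}; block is NA for
#'   homozygous filler regions.
#' @export
classifyBlocks <- function(phasing, contigLen, meanReadLength,
                           depthRatio = 0.25) {
  if (length(phasing) == 0)
    return(data.frame(start = 0, end = contigLen, class = "homozygous",
                      block = NA_integer_, stringsAsFactors = FALSE))
  starts <- vapply(phasing, function(b) min(b$positions), numeric(1))
  ends <- vapply(phasing, function(b) max(b$positions) + 1, numeric(1))
  ord <- order(starts)
  cls <- vapply(phasing[ord], function(b) {
    d1 <- sum(b$sides == 1L); d2 <- sum(b$sides == 2L)
    if (min(d1, d2) >= depthRatio * (d1 + d2)) "phased"
    else "heterozygousDeletion"
  }, character(1))
  starts <- starts[ord]; ends <- ends[ord]
  rows <- list()
  cursor <- 0
  for (i in seq_along(starts)) {
    gap <- starts[i] - cursor
    if (gap > meanReadLength) {
      rows[[length(rows) + 1L]] <- data.frame(
        start = cursor, end = starts[i], class = "homozygous",
        block = NA_integer_, stringsAsFactors = FALSE)
      blockStart <- starts[i]
    } else blockStart <- cursor
    blockEnd <- if (i < length(starts)) {
      nextGap <- starts[i + 1] - ends[i]
      if (nextGap > meanReadLength) ends[i]
      else (ends[i] + starts[i + 1]) / 2
    } else {
      if (contigLen - ends[i] > meanReadLength) ends[i] else contigLen
    }
    rows[[length(rows) + 1L]] <- data.frame(
      start = blockStart, end = blockEnd, class = cls[i],
      block = ord[i], stringsAsFactors = FALSE)
    cursor <- blockEnd
  }
  if (cursor < contigLen)
    rows[[length(rows) + 1L]] <- data.frame(
      start = cursor, end = contigLen, class = "homozygous",
      block = NA_integer_, stringsAsFactors = FALSE)
  df <- do.call(rbind, rows)
  df[df$end > df$start, , drop = FALSE]
}

# rebuild an AssemblyGraph around a new edge/embedded pair, recomputing the
# cached degree statistics
rebuildGraph <- function(graph, edges, embedded) {
  nonEmb <- setdiff(names(graph@reads), embedded$read)
  allv <- c(paste0(nonEmb, "^s"), paste0(nonEmb, "^e"))
  deg <- rep(0L, length(allv))
  if (nrow(edges) > 0) {
    vs <- c(paste0(edges$readA, "^", edges$endA),
            paste0(edges$readB, "^", edges$endB))
    deg <- as.integer(table(factor(vs, levels = allv)))
  }
  new("AssemblyGraph", reads = graph@reads, readLengths = graph@readLengths,
      edges = edges, embedded = embedded, containments = graph@containments,
      shadowEdges = graph@shadowEdges, degreeMean = mean(deg),
      degreeSD = if (length(deg) > 1) sd(deg) else 0, params = graph@params)
}

# Haplotype-aware graph rework. Containment hides sequence: a read embedded
# in a host of the other haplotype would deposit its bases on the wrong
# contig. Each cross-cluster-embedded read is re-hosted to a same-cluster
# containment candidate when one exists, and otherwise promoted back into
# the graph together with its set-aside (shadow) overlap edges. Finally,
# edges joining reads assigned to different clusters of the same phased
# block are removed. Edges outside phased regions are never touched.
haplotypePruneGraph <- function(graph, readSide) {
  sideOf <- function(rd) readSide[[rd]]
  crossPair <- function(rdA, rdB) {
    a <- sideOf(rdA); b <- sideOf(rdB)
    !is.null(a) && !is.null(b) && a$key == b$key && a$phased &&
      a$side != b$side
  }
  emb <- graph@embedded
  promoted <- character(0)
  if (nrow(emb) > 0) {
    contain <- graph@containments
    for (i in seq_len(nrow(emb))) {
      if (!crossPair(emb$read[i], emb$host[i])) next
      # candidate hosts of the same cluster, best supported first
      cand <- contain[contain$read == emb$read[i], , drop = FALSE]
      cand <- cand[!vapply(cand$host, function(h)
        crossPair(emb$read[i], h), logical(1)), , drop = FALSE]
      cand <- cand[!(cand$host %in% promoted), , drop = FALSE]
      if (nrow(cand) > 0) {
        best <- cand[which.max(cand$nSharedKmers), ]
        emb[i, c("host", "relStart", "reverse", "nSharedKmers")] <-
          best[c("host", "relStart", "reverse", "nSharedKmers")]
      } else {
        promoted <- c(promoted, emb$read[i])
      }
    }
    emb <- emb[!(emb$read %in% promoted), , drop = FALSE]
  }
  edges <- graph@edges
  if (length(promoted) > 0 && nrow(graph@shadowEdges) > 0) {
    stillEmb <- emb$read
    extra <- graph@shadowEdges
    extra <- extra[!(extra$readA %in% stillEmb) &
                     !(extra$readB %in% stillEmb), , drop = FALSE]
    edges <- rbind(edges, extra)
  }
  # simple-graph dedupe (after possible shadow restoration)
  if (nrow(edges) > 0) {
    vA <- paste0(edges$readA, "^", edges$endA)
    vB <- paste0(edges$readB, "^", edges$endB)
    key <- ifelse(vA < vB, paste(vA, vB), paste(vB, vA))
    ord <- order(key, -edges$nSharedKmers)
    edges <- edges[ord, , drop = FALSE]
    edges <- edges[!duplicated(key[ord]), , drop = FALSE]
    rownames(edges) <- NULL
  }
  removed <- integer(0)
  if (nrow(edges) > 0) {
    cross <- vapply(seq_len(nrow(edges)), function(ei)
      crossPair(edges$readA[ei], edges$readB[ei]), logical(1))
    removed <- which(cross)
    if (length(removed) > 0) edges <- edges[-removed, , drop = FALSE]
  }
  list(graph = rebuildGraph(graph, edges, emb), removed = removed,
       promoted = promoted)
}

#' Haplotype-aware diploid assembly
#'
#' Pipeline: haploid assembly, realignment, het-site calling, fragment
#' phasing, block classification, removal of graph edges that connect reads
#' assigned to different haplotype clusters inside phased regions, then
#' re-layout, re-consensus and polishing. Edges outside phased regions are
#' never removed. With zero het sites the output equals the haploid assembly.
#'
#' @param reads DNAStringSet / named character vector.
#' @param k,w Minimizer parameters.
#' @param polishRounds Polishing rounds (default 2).
#' @param seed Seed for the phasing heuristic restarts.
#' @param minDepth,fracRange Het-calling thresholds (see
#'   \code{\link{callHetSites}}).
#' @param depthRatio Phased-block depth ratio (see
#'   \code{\link{classifyBlocks}}).
#' @param minReadLength Assembly read-length floor (default 1000).
#' @return list(contigs, contigTags = data.frame(contig, block, hap),
#'   hetSites, phasing, blocks, removedEdges, haploid (logical),
#'   haploidContigs).
#' @export
assembleDiploid <- function(reads, k = 25L, w = 40L, polishRounds = 2L,
                            seed = 1L, minDepth = 5L, fracRange = c(0.2, 0.8),
                            depthRatio = 0.25, minReadLength = 1000L) {
  ss <- asSeqChar(reads)
  ss <- ss[nchar(ss) >= minReadLength]
  if (length(ss) == 0) stop("no reads of length >= ", minReadLength)
  hap <- assembleReads(ss, k = k, w = w, polishRounds = polishRounds,
                       keepGraph = TRUE, minReadLength = minReadLength)
  ctg <- asSeqChar(hap$contigs)
  # one realignment pass feeds both het calling and the fragment matrix
  aln <- realignReads(unname(ctg), ss, hap$placements)
  hetL <- list(); fms <- list()
  for (ci in seq_along(ctg)) {
    a <- aln[[ci]]
    if (length(a$starts) == 0) next
    pl <- olca_pileup(nchar(ctg[[ci]]), a$starts, a$seqs, a$ops, a$lens)
    hc <- hetFromPileup(pl, names(ctg)[ci], minDepth, fracRange)
    if (nrow(hc) == 0) next
    hetL[[length(hetL) + 1L]] <- hc
    fms[[names(ctg)[ci]]] <- fragmentsFromAln(a, hc, names(ctg)[ci])
  }
  het <- if (length(hetL) > 0) do.call(rbind, hetL)
         else hetFromPileup(list(counts = matrix(0L, 4, 0)), character(0),
                            minDepth, fracRange)
  if (nrow(het) == 0) {
    return(list(contigs = hap$contigs,
                contigTags = data.frame(contig = names(ctg),
                                        block = NA_integer_,
                                        hap = NA_integer_),
                hetSites = het, phasing = list(), blocks = NULL,
                removedEdges = integer(0), haploid = TRUE,
                haploidContigs = hap$contigs))
  }
  meanReadLen <- mean(nchar(ss))
  phasing <- list(); blocks <- list()
  readSide <- list()  # read -> c(contig, blockKey, side)
  blockKey <- 0L
  for (cn in names(fms)) {
    ph <- phaseFragments(fms[[cn]], seed = seed)
    phasing[[cn]] <- ph
    bl <- classifyBlocks(ph, nchar(ctg[[cn]]), meanReadLen, depthRatio)
    bl$contig <- cn
    blocks[[cn]] <- bl
    for (bi in seq_along(ph)) {
      blockKey <- blockKey + 1L
      cl <- bl$class[match(bi, bl$block)]
      phased <- identical(cl, "phased")
      for (fi in seq_along(ph[[bi]]$readNames)) {
        readSide[[ph[[bi]]$readNames[fi]]] <-
          list(key = blockKey, side = ph[[bi]]$sides[fi], phased = phased)
      }
    }
  }
  blocks <- do.call(rbind, blocks)
  rownames(blocks) <- NULL

  # re-host / promote cross-haplotype contained reads, then remove
  # cross-cluster edges inside phased regions
  pruned <- haplotypePruneGraph(hap$graph, readSide)
  graph2 <- pruned$graph
  removed <- pruned$removed
  safe2 <- selectSafeEdges(graph2)
  model2 <- fitEdgeModel(graph2, safe2)
  layout2 <- buildLayout(graph2, safe2, model2)

  lc <- layoutToContigs(layout2, graph2, ss, polishRounds)
  contigs <- lc$contigs
  pol <- lc
  names(contigs) <- paste0("contig_", seq_along(contigs))

  # tag each contig with the majority (block, hap) of its phased reads
  tags <- data.frame(contig = names(contigs), block = NA_integer_,
                     hap = NA_integer_, stringsAsFactors = FALSE)
  for (ci in seq_along(contigs)) {
    rds <- pol$placements$read[pol$placements$contig == ci]
    info <- readSide[rds]
    info <- info[!vapply(info, is.null, logical(1))]
    if (length(info) == 0) next
    keys <- vapply(info, function(x) paste(x$key, x$side), character(1))
    top <- names(sort(table(keys), decreasing = TRUE))[1]
    kv <- as.integer(strsplit(top, " ")[[1]])
    tags$block[ci] <- kv[1]
    tags$hap[ci] <- kv[2]
  }
  list(contigs = asDNAStringSet(contigs), contigTags = tags, hetSites = het,
       phasing = phasing, blocks = blocks, removedEdges = removed,
       haploid = FALSE, haploidContigs = hap$contigs,
       placements = pol$placements)
}

#' Write het sites as a minimal single-sample VCF dialect
#'
#' CHROM POS ID REF ALT QUAL FILTER INFO FORMAT GT with 1-based positions;
#' genotypes are phased (\code{0|1} / \code{1|0}) within phased blocks and
#' unphased \code{0/1} elsewhere.
#'
#' @param hetSites Het-site table.
#' @param phasing Optional per-contig phasing (named list as returned inside
#'   \code{\link{assembleDiploid}}).
#' @param path Output path.
#' @export
writeHetVcf <- function(hetSites, path, phasing = NULL) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSAMPLE"),
             con)
  for (i in seq_len(nrow(hetSites))) {
    h <- hetSites[i, ]
    gt <- "0/1"
    if (!is.null(phasing) && !is.null(phasing[[h$contig]])) {
      for (b in phasing[[h$contig]]) {
        j <- which(b$positions == h$pos)
        if (length(j) == 1 && !is.na(b$hap1[j]))
          gt <- paste0(b$hap1[j], "|", b$hap2[j])
      }
    }
    writeLines(paste(h$contig, h$pos + 1, ".", h$allele0, h$allele1, ".",
                     "PASS", ".", "GT", gt, sep = "\t"), con)
  }
  invisible(path)
}
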