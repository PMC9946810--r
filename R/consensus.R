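#' Build the consensus of one layout path
#'
#' The consensus starts as the first (oriented) read; for each following read
#' the path edge's predicted overlap seeds a banded end-alignment of the
#' consensus tail against the read's prefix, the true overlap is recomputed,
#' and the consensus is augmented with the read's overhang. If the
#' end-alignment identity falls below \code{minIdentity} the overlap is
#' rejected and the path is split into two contigs.
#'
#' @param path data.frame(read, reverse, overlapToNext) from a
#'   \linkS4class{Layout}.
#' @param reads Named character vector (or DNAStringSet) of all reads.
#' @param band Banded-alignment bandwidth in bases (default 500).
#' @param minIdentity Identity floor for accepting an overlap (default 0.65).
#' @return list(contigs = character vector, placements = data.frame(read,
#'   contig, offset, reverse)) with 0-based offsets; \code{contig} indexes the
#'   returned contigs.
#' @export
buildPathConsensus <- function(path, reads, band = 500L, minIdentity = 0.65) {
  ss <- asSeqChar(reads)
  contigs <- character(0)
  rows <- list()
  cons <- NULL
  contigIdx <- 1L
  prevOffset <- 0
  prevLen <- 0

  finish <- function() {
    if (!is.null(cons)) contigs[contigIdx] <<- cons
  }
  startNew <- function(seq, read, rev) {
    if (!is.null(cons)) {
      contigs[contigIdx] <<- cons
      contigIdx <<- contigIdx + 1L
    }
    cons <<- seq
    rows[[length(rows) + 1L]] <<- list(read = read, contig = contigIdx,
                                       offset = 0, reverse = rev)
    prevOffset <<- 0
    prevLen <<- nchar(seq)
  }

  for (i in seq_len(nrow(path))) {
    rd <- path$read[i]
    rev <- path$reverse[i]
    s <- ss[[rd]]
    if (rev) s <- revcompChar(s)
    if (i == 1L) { startNew(s, rd, rev); next }
    ov <- path$overlapToNext[i - 1L]
    expectedStart <- prevOffset + prevLen - ov
    expOv <- nchar(cons) - expectedStart
    if (!is.finite(expOv) || expOv < 1) expOv <- min(nchar(cons), 200)
    expOv <- min(expOv, nchar(cons), nchar(s) + band)
    tailLen <- min(nchar(cons), ceiling(expOv) + 3L * band)
    aTail <- substr(cons, nchar(cons) - tailLen + 1L, nchar(cons))
    res <- olca_end_overlap(aTail, s, as.integer(round(min(expOv, tailLen))),
                            as.integer(band))
    if (res$identity < minIdentity || res$alnLen < 30) {
      startNew(s, rd, rev)  # overlap rejected: split the path
      next
    }
    trueOv <- res$overlapA
    offset <- nchar(cons) - trueOv
    if (res$bUsed < nchar(s))
      cons <- paste0(cons, substr(s, res$bUsed + 1L, nchar(s)))
    rows[[length(rows) + 1L]] <- list(read = rd, contig = contigIdx,
                                      offset = offset, reverse = rev)
    prevOffset <- offset
    prevLen <- nchar(s)
  }
  finish()
  placements <- data.frame(
    read = vapply(rows, `[[`, character(1), "read"),
    contig = vapply(rows, `[[`, integer(1), "contig"),
    offset = vapply(rows, `[[`, numeric(1), "offset"),
    reverse = vapply(rows, `[[`, logical(1), "reverse"),
    stringsAsFactors = FALSE)
  list(contigs = contigs, placements = placements)
}

# place embedded reads on contigs via their host placements (chains resolved
# iteratively); returns additional placement rows
placeEmbedded <- function(embedded, placements, readLengths) {
  if (nrow(embedded) == 0) return(placements[0, ])
  placed <- placements
  out <- list()
  pending <- embedded
  repeat {
    idx <- match(pending$host, placed$read)
    ready <- which(!is.na(idx))
    if (length(ready) == 0) break
    for (j in ready) {
      h <- placed[idx[j], ]
      lh <- readLengths[[pending$host[j]]]
      le <- readLengths[[pending$read[j]]]
      rs <- pending$relStart[j]
      if (!h$reverse) off <- h$offset + rs
      else off <- h$offset + max(0, lh - (rs + le))
      row <- data.frame(read = pending$read[j], contig = h$contig,
                        offset = max(0, off),
                        reverse = xor(h$reverse, pending$reverse[j]),
                        stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <- row
      placed <- rbind(placed, row)
    }
    pending <- pending[-ready, , drop = FALSE]
    if (nrow(pending) == 0) break
  }
  if (length(out) == 0) placements[0, ] else do.call(rbind, out)
}

# banded glocal realignment of placed reads against their contig
realignReads <- function(contigs, reads, placements, pad = 150L,
                         bandFrac = 0.025, minBand = 100L,
                         minIdentity = 0.5) {
  ss <- asSeqChar(reads)
  out <- vector("list", length(contigs))
  for (ci in seq_along(contigs)) {
    ctg <- contigs[[ci]]
    L <- nchar(ctg)
    pl <- placements[placements$contig == ci, , drop = FALSE]
    starts <- integer(0); seqs <- character(0)
    opsL <- list(); lensL <- list(); rdn <- character(0); idents <- numeric(0)
    if (nrow(pl) > 0) for (ri in seq_len(nrow(pl))) {
      rd <- pl$read[ri]
      s <- ss[[rd]]
      if (pl$reverse[ri]) s <- revcompChar(s)
      rl <- nchar(s)
      ws <- max(0L, as.integer(round(pl$offset[ri])) - pad)
      we <- min(L, as.integer(round(pl$offset[ri])) + rl + pad)
      if (we - ws < 30) next
      win <- substr(ctg, ws + 1L, we)
      band <- as.integer(max(minBand, ceiling(bandFrac * rl)) + pad)
      res <- olca_glocal(s, win, as.integer(round(pl$offset[ri])) - ws, band)
      if (!isTRUE(res$ok) || res$identity < minIdentity) next
      starts <- c(starts, ws + res$start)
      seqs <- c(seqs, s)
      opsL[[length(opsL) + 1L]] <- res$ops
      lensL[[length(lensL) + 1L]] <- res$lens
      rdn <- c(rdn, rd)
      idents <- c(idents, res$identity)
    }
    out[[ci]] <- list(starts = starts, seqs = seqs, ops = opsL, lens = lensL,
                      readNames = rdn, identity = idents)
  }
  out
}

#' Detect indel-active regions from pileup indel calls
#'
#' Columns where at least \code{minSupport} reads report an insertion or a
#' deletion are indel calls; every call is dilated by \code{dilation} bases on
#' both sides and overlapping intervals are merged, so that every base of an
#' active region is at most \code{dilation} bp away from an indel call.
#'
#' @param insCounts,delCounts Integer vectors (per contig column) of reads
#'   reporting an insertion / deletion at that column.
#' @param minSupport Minimum supporting reads per call (default 2).
#' @param dilation Dilation radius in bases (default 5).
#' @return data.frame(start, end), 0-based half-open, merged and sorted.
#' @export
detectActiveRegions <- function(insCounts, delCounts, minSupport = 2L,
                                dilation = 5L) {
  L <- length(insCounts)
  calls <- which(insCounts >= minSupport | delCounts >= minSupport) - 1L
  if (length(calls) == 0)
    return(data.frame(start = integer(0), end = integer(0)))
  s <- pmax(0L, calls - dilation)
  e <- pmin(L, calls + dilation + 1L)
  # merge overlapping dilated intervals
  ms <- s[1]; me <- e[1]
  outS <- integer(0); outE <- integer(0)
  if (length(s) > 1) for (i in 2:length(s)) {
    if (s[i] <= me) me <- max(me, e[i])
    else { outS <- c(outS, ms); outE <- c(outE, me); ms <- s[i]; me <- e[i] }
  }
  outS <- c(outS, ms); outE <- c(outE, me)
  data.frame(start = outS, end = outE)
}

# cumulative reference / read offsets per op run, computed once per alignment
alnCoordIndex <- function(start, ops, lens) {
  list(cumRef = c(start, start + cumsum(lens * (ops != 2L))),
       cumRead = c(0L, cumsum(lens * (ops != 3L))),
       ops = ops)
}

# read coordinates corresponding to contig positions [rs, re) for one
# alignment; returns c(readLo, readHi) or NULL when the read does not span
segmentReadCoords <- function(idx, rs, re) {
  cumRef <- idx$cumRef
  n <- length(idx$ops)
  if (cumRef[1] > rs || cumRef[n + 1L] < re) return(NULL)
  mapOne <- function(p) {
    run <- findInterval(p, cumRef)
    run <- min(max(run, 1L), n)
    if (idx$ops[run] <= 1L) idx$cumRead[run] + (p - cumRef[run])
    else idx$cumRead[run + 1L]  # inside D (or at an I boundary): run end
  }
  lo <- mapOne(rs); hi <- mapOne(re)
  if (is.na(lo) || is.na(hi) || hi <= lo) return(NULL)
  c(lo, hi)
}

# heaviest anchored path through a de Bruijn graph of read segments;
# returns the corrected sequence from anchorL to anchorR (inclusive of both
# k-mers) or NULL (no anchors, no path, or a cycle)
miniAssemble <- function(segments, anchorL, anchorR, k = 15L,
                         maxNodes = 20000L) {
  if (length(segments) < 2) return(NULL)
  edges <- new.env(hash = TRUE)
  for (s in segments) {
    n <- nchar(s)
    if (n < k + 1) next
    kmers <- substring(s, 1:(n - k), k:(n - 1))
    nexts <- substring(s, 2:(n - k + 1), (k + 1):n)
    for (i in seq_along(kmers)) {
      key <- kmers[i]
      cur <- edges[[key]]
      if (is.null(cur)) cur <- integer(0)
      nb <- nexts[i]
      cur[nb] <- if (is.na(cur[nb])) 1L else cur[nb] + 1L
      edges[[key]] <- cur
    }
  }
  if (is.null(edges[[anchorL]]) && anchorL != anchorR) return(NULL)

  best <- new.env(hash = TRUE)   # node -> list(weight, next)
  state <- new.env(hash = TRUE)  # 1 = on stack, 2 = done
  cyclic <- FALSE
  nVisited <- 0L
  visit <- function(node) {
    if (cyclic) return(-Inf)
    if (node == anchorR) return(0)
    st <- state[[node]]
    if (!is.null(st)) {
      if (st == 1L) { cyclic <<- TRUE; return(-Inf) }
      b <- best[[node]]
      return(if (is.null(b)) -Inf else b$weight)
    }
    state[[node]] <- 1L
    nVisited <<- nVisited + 1L
    if (nVisited > maxNodes) { cyclic <<- TRUE; return(-Inf) }
    out <- edges[[node]]
    w <- -Inf; nx <- NULL
    if (!is.null(out)) for (i in seq_along(out)) {
      sub <- visit(names(out)[i])
      if (cyclic) break
      cand <- out[[i]] + sub
      if (is.finite(cand) && cand > w) { w <- cand; nx <- names(out)[i] }
    }
    state[[node]] <- 2L
    if (is.finite(w)) best[[node]] <- list(weight = w, nxt = nx)
    return(w)
  }
  w <- try(visit(anchorL), silent = TRUE)
  if (inherits(w, "try-error") || cyclic || !is.finite(w)) return(NULL)
  # reconstruct
  seqOut <- anchorL
  node <- anchorL
  while (node != anchorR) {
    b <- best[[node]]
    if (is.null(b)) return(NULL)
    node <- b$nxt
    seqOut <- paste0(seqOut, substr(node, nchar(node), nchar(node)))
  }
  seqOut
}

#' Polish contigs by pileup majority and active-region reassembly
#'
#' Each round realigns the placed reads to their contig with a banded
#' alignment anchored at the layout-predicted positions, then (pass 1)
#' replaces each consensus base with the pileup-majority base (ties keep the
#' consensus) and (pass 2) rebuilds indel-active regions: read segments
#' spanning the flanked region feed a de Bruijn graph (k = 15) and the
#' heaviest path between consensus anchor k-mers (present in at least half of
#' the spanning segments) replaces the region. Regions with no anchored
#' acyclic path are left unchanged. Polishing an already-perfect consensus
#' with error-free reads is a no-op.
#'
#' @param contigs Character vector (or DNAStringSet) of contigs.
#' @param reads Named character vector / DNAStringSet of all reads.
#' @param placements Placement table (read, contig, offset, reverse).
#' @param rounds Number of polish rounds (default 2).
#' @param minIndelSupport Reads required to call an indel column (default 2).
#' @param dilation Active-region dilation radius (default 5).
#' @param flank Region flank used for anchors and segments (default 20).
#' @param dbK De Bruijn k-mer size for the mini-assembly (default 15).
#' @return list(contigs = character vector, placements = adjusted placements).
#' @export
polishContigs <- function(contigs, reads, placements, rounds = 2L,
                          minIndelSupport = 2L, dilation = 5L, flank = 20L,
                          dbK = 15L) {
  contigs <- unname(asSeqChar(contigs))
  for (round in seq_len(rounds)) {
    aln <- realignReads(contigs, reads, placements)
    for (ci in seq_along(contigs)) {
      a <- aln[[ci]]
      if (length(a$starts) == 0) next
      L <- nchar(contigs[[ci]])
      pl <- olca_pileup(L, a$starts, a$seqs, a$ops, a$lens)
      cnt <- pl$counts
      # pass 1: per-column majority base (ties keep consensus)
      cur <- utf8ToInt(contigs[[ci]])
      codeOf <- integer(128)
      codeOf[utf8ToInt("A")] <- 1L; codeOf[utf8ToInt("C")] <- 2L
      codeOf[utf8ToInt("G")] <- 3L; codeOf[utf8ToInt("T")] <- 4L
      curCode <- codeOf[cur]
      bestVal <- pmax(cnt[1, ], cnt[2, ], cnt[3, ], cnt[4, ])
      bestBase <- max.col(t(cnt), ties.method = "first")
      curCnt <- ifelse(curCode >= 1L,
                       cnt[cbind(pmax(curCode, 1L), seq_len(L))], 0L)
      # a single disagreeing read is no evidence against the consensus
      repl <- bestVal > curCnt & bestVal >= 2L
      if (any(repl)) {
        baseInt <- utf8ToInt("ACGT")
        cur[repl] <- baseInt[bestBase[repl]]
        contigs[[ci]] <- intToUtf8(cur)
      }
      # pass 2: active regions
      regions <- detectActiveRegions(pl$ins, pl$del, minIndelSupport,
                                     dilation)
      if (nrow(regions) == 0) next
      coordIdx <- lapply(seq_along(a$starts), function(ri)
        alnCoordIndex(a$starts[ri], a$ops[[ri]], a$lens[[ri]]))
      alnStartsV <- a$starts
      alnEndsV <- vapply(coordIdx, function(x) x$cumRef[length(x$cumRef)],
                         numeric(1))
      shifts <- numeric(0); shiftPos <- numeric(0)
      for (rg in rev(seq_len(nrow(regions)))) {
        rs <- max(0L, regions$start[rg] - flank)
        re <- min(L, regions$end[rg] + flank)
        if (re - rs < dbK + 2L) next
        segs <- character(0)
        for (ri in which(alnStartsV <= rs & alnEndsV >= re)) {
          co <- segmentReadCoords(coordIdx[[ri]], rs, re)
          if (is.null(co)) next
          segs <- c(segs, substr(a$seqs[ri], co[1] + 1L, co[2]))
        }
        if (length(segs) < 2) next
        fixed <- fixRegion(contigs[[ci]], rs, re, regions$start[rg],
                           regions$end[rg], segs, dbK)
        if (is.null(fixed)) next
        delta <- nchar(fixed$seq) - (fixed$to - fixed$from)
        if (delta == 0 &&
            fixed$seq == substr(contigs[[ci]], fixed$from + 1L, fixed$to))
          next
        contigs[[ci]] <- paste0(substr(contigs[[ci]], 1L, fixed$from),
                                fixed$seq,
                                substr(contigs[[ci]], fixed$to + 1L, L))
        L <- nchar(contigs[[ci]])
        if (delta != 0) { shifts <- c(shifts, delta)
                          shiftPos <- c(shiftPos, fixed$from) }
      }
      if (length(shifts) > 0) {
        sel <- placements$contig == ci
        for (si in seq_along(shifts)) {
          adj <- sel & placements$offset > shiftPos[si]
          placements$offset[adj] <- placements$offset[adj] + shifts[si]
        }
        placements$offset <- pmax(0, placements$offset)
      }
    }
  }
  list(contigs = contigs, placements = placements)
}

# anchor search + mini-assembly for one active region; returns
# list(from, to, seq) in contig coordinates or NULL
fixRegion <- function(contig, rs, re, callStart, callEnd, segs, dbK) {
  inHalf <- function(kmer) {
    if (grepl("N", kmer, fixed = TRUE)) return(FALSE)
    mean(vapply(segs, function(s) grepl(kmer, s, fixed = TRUE), logical(1))) >=
      0.5
  }
  anchorLPos <- NA_integer_
  for (p in rs:max(rs, callStart - dbK)) {
    km <- substr(contig, p + 1L, p + dbK)
    if (nchar(km) == dbK && inHalf(km)) { anchorLPos <- p; break }
  }
  if (is.na(anchorLPos)) return(NULL)
  rHi <- re - dbK
  rLo <- max(callEnd, anchorLPos + dbK)
  if (rHi < rLo) return(NULL)
  anchorRPos <- NA_integer_
  for (p in rHi:rLo) {  # descending: prefer the outermost right anchor
    km <- substr(contig, p + 1L, p + dbK)
    if (nchar(km) == dbK && inHalf(km)) { anchorRPos <- p; break }
  }
  if (is.na(anchorRPos) || anchorRPos <= anchorLPos) return(NULL)
  aL <- substr(contig, anchorLPos + 1L, anchorLPos + dbK)
  aR <- substr(contig, anchorRPos + 1L, anchorRPos + dbK)
  fixedSeq <- miniAssemble(segs, aL, aR, dbK)
  if (is.null(fixedSeq)) return(NULL)
  list(from = anchorLPos, to = anchorRPos + dbK, seq = fixedSeq)
}

#' Rotate and orient circular contigs on an origin sequence
#'
#' Each contig whose best alignment of an origin sequence passes the mapping
#' threshold is reverse-complemented if the match is on the reverse strand and
#' rotated so the origin match starts at position 0. Contigs without a
#' passing origin alignment are returned unchanged.
#'
#' @param contigs DNAStringSet or character vector of contigs.
#' @param origins DNAStringSet / named character vector of origin sequences.
#' @param k,w Minimizer parameters for the origin alignment.
#' @param minScore Minimum cluster size for a trusted origin hit (default 4).
#' @return Character vector of (possibly rotated) contigs, names kept.
#' @export
circularizeContigs <- function(contigs, origins, k = 25L, w = 40L,
                               minScore = 4L) {
  ctg <- asSeqChar(contigs)
  org <- asSeqChar(origins)
  out <- ctg
  for (ci in seq_along(ctg)) {
    s <- ctg[[ci]]
    if (nchar(s) < k + w - 1) next
    tab <- buildMinimizerTable(stats::setNames(s, "ctg"), k = k, w = w,
                               maxFrequency = 1000)
    alns <- alignReads(tab, org, minClusterSize = minScore)
    alns <- alns[alns$aligned, , drop = FALSE]
    if (nrow(alns) == 0) next
    best <- alns[which.max(alns$score), ]
    if (isTRUE(best$reverse)) {
      s <- revcompChar(s)
      tab <- buildMinimizerTable(stats::setNames(s, "ctg"), k = k, w = w,
                                 maxFrequency = 1000)
      aln2 <- alignReads(tab, org[best$readName], minClusterSize = minScore)
      if (!isTRUE(aln2$aligned[1])) next
      best <- aln2[1, ]
    }
    rot <- min(max(0, round(best$start)), nchar(s) - 1)
    if (rot > 0)
      s <- paste0(substr(s, rot + 1, nchar(s)), substr(s, 1, rot))
    out[[ci]] <- s
  }
  out
}

#' Assemble long reads (haploid pipeline)
#'
#' Full pipeline: 15-mer spectrum, overlap graph, safe-edge + likelihood
#' layout, per-path consensus, embedded-read placement and polishing
#' (optionally circularisation against origin sequences).
#'
#' @param reads DNAStringSet or named character vector of reads.
#' @param k,w Minimizer parameters (defaults 25, 40).
#' @param spectrum Optional prebuilt \linkS4class{KmerSpectrum}.
#' @param polishRounds Polishing rounds (default 2).
#' @param circularOrigins Optional origin sequences for circularisation.
#' @param keepGraph Keep the graph/layout in the result (default TRUE).
#' @param minReadLength Reads shorter than this are excluded from assembly
#'   (default 1000, the usual long-read assembler floor); very short reads
#'   carry too few minimizers to place reliably.
#' @return list(contigs = DNAStringSet named contig_1.., placements, graph,
#'   layout, model, stats = \code{\link{assemblyStats}} output).
#' @export
assembleReads <- function(reads, k = 25L, w = 40L, spectrum = NULL,
                          polishRounds = 2L, circularOrigins = NULL,
                          keepGraph = TRUE, minReadLength = 1000L) {
  ss <- asSeqChar(reads)
  ss <- ss[nchar(ss) >= minReadLength]
  if (length(ss) == 0) stop("no reads of length >= ", minReadLength)
  if (is.null(spectrum)) spectrum <- buildSpectrum(ss)
  graph <- buildAssemblyGraph(ss, k = k, w = w, spectrum = spectrum)
  safe <- selectSafeEdges(graph)
  model <- fitEdgeModel(graph, safe)
  layout <- buildLayout(graph, safe, model)

  lc <- layoutToContigs(layout, graph, ss, polishRounds)
  contigs <- lc$contigs
  placements <- lc$placements
  if (!is.null(circularOrigins))
    contigs <- circularizeContigs(contigs, circularOrigins, k = k, w = w)

  names(contigs) <- paste0("contig_", seq_along(contigs))
  placements$contigName <- names(contigs)[placements$contig]
  res <- list(contigs = asDNAStringSet(contigs), placements = placements,
              stats = assemblyStats(contigs))
  if (keepGraph) {
    res$graph <- graph
    res$layout <- layout
    res$model <- model
  }
  res
}

# consensus + embedded placement + singleton absorption + polishing for a
# computed layout; shared by the haploid and diploid pipelines
layoutToContigs <- function(layout, graph, ss, polishRounds) {
  contigs <- character(0)
  placements <- NULL
  for (p in layout@paths) {
    pc <- buildPathConsensus(p, ss)
    pc$placements$contig <- pc$placements$contig + length(contigs)
    contigs <- c(contigs, pc$contigs)
    placements <- rbind(placements, pc$placements)
  }
  ab <- absorbRedundantContigs(contigs, placements, graph)
  contigs <- ab$contigs
  placements <- ab$placements
  embPlaced <- placeEmbedded(graph@embedded, placements, graph@readLengths)
  placements <- rbind(placements, embPlaced)
  pol <- polishContigs(contigs, ss, placements, rounds = polishRounds)
  list(contigs = pol$contigs, placements = pol$placements)
}

# Paths the greedy matching bypassed produce small contigs that are redundant
# with the main paths (their reads still have overlap edges into them). Like
# embedded reads, such reads are mapped onto their best partner's contig and
# the redundant contig is dropped. A contig is only absorbed when EVERY one of
# its reads has an edge to a read of a longer kept contig, so genuine extra
# contigs (coverage gaps, separated haplotypes after edge pruning) are kept.
absorbRedundantContigs <- function(contigs, placements, graph) {
  edges <- graph@edges
  if (length(contigs) < 2 || nrow(edges) == 0)
    return(list(contigs = contigs, placements = placements))
  lens <- graph@readLengths
  drop <- integer(0)

  bestPartnerEdge <- function(rd, ownContig) {
    cand <- which(edges$readA == rd | edges$readB == rd)
    best <- NULL
    for (j in cand) {
      pn <- if (edges$readA[j] == rd) edges$readB[j] else edges$readA[j]
      pj <- which(placements$read == pn)
      if (length(pj) != 1) next
      tc <- placements$contig[pj]
      if (tc %in% drop || tc == ownContig) next
      if (nchar(contigs[tc]) <= nchar(contigs[ownContig])) next
      if (is.null(best) || edges$nSharedKmers[j] > best$n)
        best <- list(edge = j, partner = pn, pj = pj,
                     n = edges$nSharedKmers[j])
    }
    best
  }

  repeat {
    progress <- FALSE
    ord <- setdiff(order(nchar(contigs)), drop)
    for (ci in ord) {
      ri <- which(placements$contig == ci)
      moves <- vector("list", length(ri))
      ok <- TRUE
      for (m in seq_along(ri)) {
        mv <- bestPartnerEdge(placements$read[ri[m]], ci)
        if (is.null(mv)) { ok <- FALSE; break }
        moves[[m]] <- mv
      }
      if (!ok) next
      for (m in seq_along(ri)) {
        rd <- placements$read[ri[m]]
        e <- edges[moves[[m]]$edge, ]
        # position of rd relative to the partner's forward strand
        if (e$readB == rd) {
          relStart <- e$centroid
        } else {
          relStart <- if (e$reverse) lens[[e$readB]] - lens[[e$readA]] +
                        e$centroid else -e$centroid
        }
        relRev <- e$reverse
        hp <- placements[moves[[m]]$pj, ]
        lp <- lens[[moves[[m]]$partner]]
        lr <- lens[[rd]]
        off <- if (!hp$reverse) hp$offset + relStart
               else hp$offset + (lp - (relStart + lr))
        placements$contig[ri[m]] <- hp$contig
        placements$offset[ri[m]] <- max(0, off)
        placements$reverse[ri[m]] <- xor(hp$reverse, relRev)
      }
      drop <- c(drop, ci)
      progress <- TRUE
      break  # placements changed: recompute ordering
    }
    if (!progress) break
  }
  if (length(drop) > 0) {
    keep <- setdiff(seq_along(contigs), drop)
    placements$contig <- match(placements$contig, keep)
    contigs <- contigs[keep]
  }
  list(contigs = contigs, placements = placements)
}
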