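#' @include spectrum.R
NULL

#' MinimizerTable: minimizer index
#'
#' Maps each minimizer k-mer (its orientation-canonical code, selected by the
#' rank-based hash) to its (sequence, position, orientation) entries, so hits
#' are exact k-mer matches. In reference-aligner mode, minimizers appearing
#' \code{maxFrequency} (default 1,000) or more times in the reference are
#' purged to keep the index tractable over repetitive references.
#'
#' @slot ptr External pointer to the hash map.
#' @slot seqNames Names of the indexed sequences.
#' @slot seqLengths Lengths of the indexed sequences.
#' @slot k,w Minimizer parameters.
#' @slot maxFrequency Occurrence cap (Inf disables purging).
#' @slot spectrum The \linkS4class{KmerSpectrum} driving the hash.
#' @export
setClass("MinimizerTable", representation(
  ptr = "externalptr", seqNames = "character", seqLengths = "integer",
  k = "integer", w = "integer", maxFrequency = "numeric",
  spectrum = "KmerSpectrum"
))

setMethod("show", "MinimizerTable", function(object) {
  st <- olca_table_stats(object@ptr)
  cat("MinimizerTable: k =", object@k, " w =", object@w, "\n")
  cat("  sequences:", length(object@seqNames),
      " entries:", st$nEntries, " distinct minimizers:", st$nMinimizers, "\n")
  if (is.finite(object@maxFrequency))
    cat("  purged entries (minimizer frequency >=", object@maxFrequency, "):",
        st$nPurged, "\n")
})

#' Compute the minimizers of a sequence
#'
#' Standard minimizer sampling over the rank-based hash: the minimum-hash
#' k-mer of every window of \code{w} consecutive k-mer positions is emitted
#' once. Each position contributes the orientation (forward vs reverse
#' complement) with the smaller hash (ties: smaller code), which makes the
#' scheme strand-symmetric. The module is fully deterministic. Sequences
#' shorter than k + w - 1 yield an empty set.
#'
#' @param seq A single sequence.
#' @param k k-mer length (15..31, default 25).
#' @param w Window size in k-mer positions (default 40).
#' @param spectrum A \linkS4class{KmerSpectrum}.
#' @return data.frame(pos, hash, code, reverse); \code{pos} is the 0-based
#'   forward-strand start, \code{reverse} marks a reverse-complement-selected
#'   orientation.
#' @export
computeMinimizers <- function(seq, k = 25L, w = 40L, spectrum) {
  s <- asSeqChar(seq)
  if (length(s) != 1) stop("computeMinimizers expects a single sequence")
  olca_minimizers(spectrum@ptr, spectrum@mode, spectrum@primeAbove,
                  spectrum@cumByRank, s[[1]], as.integer(k), as.integer(w))
}

#' Build a minimizer table over a set of sequences
#'
#' @param seqs DNAStringSet or named character vector.
#' @param k,w Minimizer parameters.
#' @param spectrum \linkS4class{KmerSpectrum}; by default built from
#'   \code{seqs} themselves (reference mode).
#' @param maxFrequency Hashes seen at least this many times are purged
#'   (use 1000 for reference mode, Inf for read-vs-read mode).
#' @return A \linkS4class{MinimizerTable}.
#' @export
buildMinimizerTable <- function(seqs, k = 25L, w = 40L,
                                spectrum = buildSpectrum(seqs),
                                maxFrequency = Inf) {
  ss <- asSeqChar(seqs)
  ptr <- olca_table_new(as.integer(k), as.integer(w), maxFrequency)
  for (i in seq_along(ss))
    olca_table_insert(ptr, spectrum@ptr, spectrum@mode, spectrum@primeAbove,
                      spectrum@cumByRank, ss[[i]], i - 1L)
  olca_table_finalize(ptr)
  new("MinimizerTable", ptr = ptr, seqNames = names(ss),
      seqLengths = nchar(ss), k = as.integer(k), w = as.integer(w),
      maxFrequency = maxFrequency, spectrum = spectrum)
}

#' Query a minimizer table
#'
#' @param table A \linkS4class{MinimizerTable}.
#' @param seq A single query sequence.
#' @return data.frame(subject, subjectPos, queryPos, reverse) with 0-based
#'   positions; \code{subject} indexes \code{table@seqNames}.
#' @export
queryMinimizerTable <- function(table, seq) {
  s <- asSeqChar(seq)
  sp <- table@spectrum
  olca_table_query(table@ptr, sp@ptr, sp@mode, sp@primeAbove, sp@cumByRank,
                   s[[1]])
}

#' Align reads against a reference minimizer table
#'
#' Minimizer hits are interpreted as ungapped k-mer alignments and clustered
#' by the reference start they predict for the read; the largest cluster is
#' reported as the alignment. The mapping quality is a proxy computed from the
#' two largest cluster sizes: 60 * (1 - second/first), capped to [0, 60].
#'
#' @param table A \linkS4class{MinimizerTable} built in reference mode.
#' @param reads DNAStringSet or named character vector.
#' @param minClusterSize Minimum number of minimizer hits supporting an
#'   alignment (default 4).
#' @return data.frame(readName, contig, start, reverse, score, mapq, aligned);
#'   \code{start} is the 0-based predicted reference start (NA if unmapped).
#' @export
alignReads <- function(table, reads, minClusterSize = 4L) {
  ss <- asSeqChar(reads)
  sp <- table@spectrum
  k <- table@k
  out <- vector("list", length(ss))
  for (i in seq_along(ss)) {
    hits <- olca_table_query(table@ptr, sp@ptr, sp@mode, sp@primeAbove,
                             sp@cumByRank, ss[[i]])
    rec <- data.frame(readName = names(ss)[i], contig = NA_character_,
                      start = NA_real_, reverse = NA, score = 0L,
                      mapq = 0L, aligned = FALSE, stringsAsFactors = FALSE)
    if (nrow(hits) > 0) {
      qlen <- nchar(ss[[i]])
      best <- NULL; second <- 0L
      for (subj in unique(hits$subject)) {
        for (rv in unique(hits$reverse[hits$subject == subj])) {
          h <- hits[hits$subject == subj & hits$reverse == rv, , drop = FALSE]
          ps <- predictedStart(h$queryPos, h$subjectPos, rv, qlen, k)
          cl <- clusterStarts(ps, delta = max(100, 0.01 * qlen))
          sizes <- tabulate(cl)
          for (ci in seq_along(sizes)) {
            if (sizes[ci] == 0) next
            if (is.null(best) || sizes[ci] > best$n) {
              if (!is.null(best)) second <- max(second, best$n)
              best <- list(n = sizes[ci], subj = subj, rev = rv,
                           start = mean(ps[cl == ci]))
            } else second <- max(second, sizes[ci])
          }
        }
      }
      if (!is.null(best) && best$n >= minClusterSize) {
        mapq <- max(0L, min(60L, as.integer(round(60 * (1 - second / best$n)))))
        rec <- data.frame(readName = names(ss)[i],
                          contig = table@seqNames[best$subj],
                          start = max(0, round(best$start)),
                          reverse = best$rev, score = best$n, mapq = mapq,
                          aligned = TRUE, stringsAsFactors = FALSE)
      }
    }
    out[[i]] <- rec
  }
  do.call(rbind, out)
}

# predicted subject start of the (oriented) query, per hit
predictedStart <- function(queryPos, subjectPos, reverse, queryLen, k) {
  ifelse(rep(reverse, length.out = length(queryPos)),
         subjectPos - (queryLen - queryPos - k),
         subjectPos - queryPos)
}

# 1-D gap clustering of predicted starts; returns integer cluster ids
clusterStarts <- function(x, delta) {
  n <- length(x)
  if (n == 0) return(integer(0))
  ord <- order(x)
  cl <- integer(n)
  cid <- 1L
  cl[ord[1]] <- 1L
  if (n > 1) for (i in 2:n) {
    if (x[ord[i]] - x[ord[i - 1]] > delta) cid <- cid + 1L
    cl[ord[i]] <- cid
  }
  cl
}

#' Write alignments in SAM-dialect text
#'
#' Emits @HD/@SQ headers and one line per read with QNAME, FLAG (4 unmapped,
#' 16 reverse), RNAME, 1-based POS, MAPQ and a soft-clipped ungapped-match
#' CIGAR covering the read span on the reference.
#'
#' @param alignments Output of \code{\link{alignReads}}.
#' @param reads The reads that were aligned (for sequence output).
#' @param refLengths Named integer vector of reference lengths.
#' @param path Output path.
#' @export
writeSam <- function(alignments, reads, refLengths, path) {
  ss <- asSeqChar(reads)
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (i in seq_along(refLengths))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(refLengths)[i],
                       as.integer(refLengths[i])), con)
  for (i in seq_len(nrow(alignments))) {
    a <- alignments[i, ]
    seq <- ss[[a$readName]]
    if (!isTRUE(a$aligned)) {
      writeLines(paste(a$readName, 4L, "*", 0L, 0L, "*", "*", 0L, 0L,
                       seq, "*", sep = "\t"), con)
      next
    }
    flag <- if (isTRUE(a$reverse)) 16L else 0L
    if (isTRUE(a$reverse)) seq <- revcompChar(seq)
    rl <- refLengths[[a$contig]]
    start0 <- max(0, min(a$start, rl - 1))
    span <- min(nchar(seq), rl - start0)
    clip <- nchar(seq) - span
    cigar <- paste0(span, "M", if (clip > 0) paste0(clip, "S") else "")
    writeLines(paste(a$readName, flag, a$contig, as.integer(start0) + 1L,
                     a$mapq, cigar, "*", 0L, 0L, seq, "*", sep = "\t"), con)
  }
  invisible(path)
}
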