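#' Assembly contiguity statistics (Nx / N50 / NG50)
#'
#' Nx is the length of the contig at which the cumulative length of contigs
#' sorted in decreasing order first reaches x% of the total assembly length;
#' NGx uses the genome size instead of the assembly length and is 0 when the
#' cumulative length never reaches the target.
#'
#' @param contigs DNAStringSet / character vector of contigs, or a numeric
#'   vector of contig lengths.
#' @param genomeSize Optional genome size in bases for NGx.
#' @return list(totalLength, numContigs, N50, NG50, nxCurve =
#'   data.frame(x, Nx, NGx)).
#' @export
assemblyStats <- function(contigs, genomeSize = NULL) {
  lens <- if (is.numeric(contigs)) as.numeric(contigs)
          else nchar(asSeqChar(contigs))
  if (length(lens) == 0) stop("at least one contig required")
  lens <- sort(unname(lens), decreasing = TRUE)
  total <- sum(lens)
  cum <- cumsum(lens)
  nxAt <- function(target) {
    i <- which(cum >= target)
    if (length(i) == 0) 0 else lens[i[1]]
  }
  x <- 1:100
  nx <- vapply(x / 100 * total, nxAt, numeric(1))
  ngx <- if (is.null(genomeSize)) rep(NA_real_, 100)
         else vapply(x / 100 * genomeSize, nxAt, numeric(1))
  list(totalLength = total, numContigs = length(lens),
       N50 = nx[50], NG50 = if (is.null(genomeSize)) NA_real_ else ngx[50],
       nxCurve = data.frame(x = x, Nx = nx, NGx = ngx))
}

#' Alignment accuracy against name-encoded truth
#'
#' Per aligned read the positional error is |alignedStart - trueStart|; the
#' RMSE is the square root of the mean squared error over aligned reads.
#' Unmapped reads count in the alignment-rate denominator only; reads with
#' unparseable names are skipped (and counted).
#'
#' @param alignments Output of \code{\link{alignReads}} (readName, start,
#'   aligned).
#' @return list(alignedFraction, rmse (NA when nothing aligned), n, nAligned,
#'   nSkipped, errors = per-read absolute errors of aligned reads).
#' @export
alignmentAccuracy <- function(alignments) {
  truth <- readTruth(alignments$readName)
  bad <- is.na(truth$start)
  if (any(bad))
    warning(sum(bad), " read name(s) not truth-encoded; skipped")
  aln <- alignments[!bad, , drop = FALSE]
  truth <- truth[!bad, , drop = FALSE]
  aligned <- which(aln$aligned)
  err <- abs(aln$start[aligned] - truth$start[aligned])
  list(alignedFraction = if (nrow(aln) > 0) length(aligned) / nrow(aln)
                         else NA_real_,
       rmse = if (length(err) > 0) sqrt(mean(err^2)) else NA_real_,
       n = nrow(aln), nAligned = length(aligned), nSkipped = sum(bad),
       errors = err)
}

#' Count switch errors with parental-specific k-mers
#'
#' The assembly is divided into overlapping windows of \code{windowSize}
#' (default 20 kbp) advancing by \code{step} (default 10 kbp, i.e. 10-kbp
#' overlap). Each window is assigned to the parent contributing more
#' parental-specific (canonical) k-mers, or left ambiguous when the counts tie
#' or both fall below \code{minHits}. A switch error is a pair of consecutive
#' assigned windows of one contig with different parents (ambiguous windows
#' are transparent).
#'
#' @param assembly DNAStringSet / character vector of contigs.
#' @param parent1,parent2 Parental haplotype sequences.
#' @param k k-mer size (default 21).
#' @param minHits Minimum parental-specific k-mers to assign a window
#'   (default 10).
#' @param windowSize,step Window geometry in bases.
#' @return list(windows = data.frame(contig, start, end, hits1, hits2,
#'   parent), switchCount, perContig).
#' @export
countSwitchErrors <- function(assembly, parent1, parent2, k = 21L,
                              minHits = 10L, windowSize = 20000L,
                              step = 10000L) {
  ctg <- asSeqChar(assembly)
  p1 <- asSeqChar(parent1)
  p2 <- asSeqChar(parent2)
  kmersOf <- function(seqs) {
    out <- lapply(seqs, function(s) olca_kmer_codes_canonical(s, k)$code)
    unique(unlist(out, use.names = FALSE))
  }
  set1 <- kmersOf(p1)
  set2 <- kmersOf(p2)
  spec1 <- setdiff(set1, set2)
  spec2 <- setdiff(set2, set1)
  identicalParents <- length(spec1) == 0 && length(spec2) == 0
  if (identicalParents)
    warning("parents share all k-mers; all windows ambiguous")

  rows <- list()
  for (ci in seq_along(ctg)) {
    s <- ctg[[ci]]
    L <- nchar(s)
    km <- olca_kmer_codes_canonical(s, k)
    in1 <- km$code %in% spec1
    in2 <- km$code %in% spec2
    starts <- seq(0L, max(0L, L - step), by = step)
    if (length(starts) == 0) starts <- 0L
    for (ws in starts) {
      we <- min(L, ws + windowSize)
      sel <- km$pos >= ws & km$pos < we
      h1 <- sum(in1[sel]); h2 <- sum(in2[sel])
      parent <- if (h1 == h2 || max(h1, h2) < minHits) "ambiguous"
                else if (h1 > h2) "P1" else "P2"
      rows[[length(rows) + 1L]] <- data.frame(
        contig = names(ctg)[ci], start = ws, end = we, hits1 = h1,
        hits2 = h2, parent = parent, stringsAsFactors = FALSE)
    }
  }
  windows <- do.call(rbind, rows)
  perContig <- vapply(unique(windows$contig), function(cn) {
    pa <- windows$parent[windows$contig == cn]
    pa <- pa[pa != "ambiguous"]
    if (length(pa) < 2) 0L else sum(pa[-1] != pa[-length(pa)])
  }, integer(1))
  list(windows = windows, switchCount = sum(perContig),
       perContig = perContig)
}

#' Global sequence identity via banded edit distance
#'
#' identity = 1 - editDistance / max(length(a), length(b)), with the band
#' automatically widened to cover the length difference.
#'
#' @param a,b Sequences (character or DNAStringSet of 1).
#' @param band Extra bandwidth beyond the length difference (default 400).
#' @return Identity in [0, 1] (NA when the band was insufficient).
#' @export
sequenceIdentity <- function(a, b, band = 400L) {
  sa <- asSeqChar(a)[[1]]
  sb <- asSeqChar(b)[[1]]
  d <- olca_banded_edit(sa, sb, as.integer(band))
  if (is.na(d)) return(NA_real_)
  1 - d / max(nchar(sa), nchar(sb))
}

#' Identity of an assembly against a known truth sequence
#'
#' Each contig is globally aligned to the truth with free terminal gaps on the
#' truth side (so genome ends the read set did not cover are not penalised,
#' while every base of the contig is): identity = matches / alignment columns.
#' Both orientations are tried and the better one kept; the assembly identity
#' is the contig-length-weighted mean.
#'
#' @param contigs DNAStringSet / character vector.
#' @param truth Single truth sequence.
#' @param band Extra bandwidth beyond the length difference (default 500).
#' @return list(perContig, identity).
#' @export
assemblyIdentity <- function(contigs, truth, band = 500L) {
  ctg <- asSeqChar(contigs)
  tr <- asSeqChar(truth)[[1]]
  glocalIdent <- function(s) {
    b <- as.integer(abs(nchar(s) - nchar(tr)) + band)
    res <- olca_glocal(s, tr, 0L, b)
    if (!isTRUE(res$ok)) return(NA_real_)
    res$identity
  }
  per <- vapply(ctg, function(s)
    max(glocalIdent(s), glocalIdent(revcompChar(s)), na.rm = TRUE),
    numeric(1))
  w <- nchar(ctg)
  list(perContig = per, identity = sum(per * w) / sum(w))
}
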