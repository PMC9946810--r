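#' KmerSpectrum: fixed-array 15-mer count table
#'
#' Holds an external pointer to the fixed 2^30-entry saturating count array
#' (counters cap at 2^15 - 1), together with the derived histogram, the
#' spectrum mode (the single-copy peak, reflecting sequencing depth) and the
#' genome-size estimate. The array size is fixed regardless of input size.
#'
#' @slot ptr External pointer to the count array.
#' @slot histogram data.frame with columns \code{count}, \code{distinct}.
#' @slot instances Number of 15-mer instances scanned (each instance once).
#' @slot totalInstances Sum of all counters (= sum(count * distinct)); equals
#'   \code{2 * instances} under both-strand counting.
#' @slot mode Count value of the single-copy peak.
#' @slot genomeSizeEstimate Estimated assembly size in bases.
#' @slot modeWarning TRUE when the histogram had no secondary peak and the
#'   mode fell back to 1.
#' @slot orientation "both" (each instance counted forward and as its reverse
#'   complement) or "canonical" (min of the two codes counted once).
#' @slot primeAbove Integer lookup: smallest prime > x, x in 0..32767.
#' @slot cumByRank Numeric lookup: number of distinct observed 15-mers with
#'   rank strictly smaller than r.
#' @export
setClass("KmerSpectrum", representation(
  ptr = "externalptr", histogram = "data.frame", instances = "numeric",
  totalInstances = "numeric", mode = "integer", genomeSizeEstimate = "numeric",
  modeWarning = "logical", orientation = "character",
  primeAbove = "integer", cumByRank = "numeric"
))

setValidity("KmerSpectrum", function(object) {
  h <- object@histogram
  if (nrow(h) == 0) return("empty histogram")
  if (abs(sum(h$count * h$distinct) - object@totalInstances) > 0.5)
    return("histogram does not sum to totalInstances")
  if (object@mode < 1L) return("mode must be >= 1")
  TRUE
})

#' Build the 15-mer spectrum of a read set
#'
#' Counts every N-free 15-mer instance of the reads in the fixed 2^30-entry
#' array. Under the default orientation policy each instance is counted both
#' as read and as its reverse complement, so the count of a genomic locus
#' approximates its total (strand-combined) read depth. The mode and the
#' genome size are estimated from the count histogram.
#'
#' @param reads DNAStringSet or named character vector of reads.
#' @param orientation "both" (default) or "canonical".
#' @return A \linkS4class{KmerSpectrum}.
#' @export
buildSpectrum <- function(reads, orientation = c("both", "canonical")) {
  orientation <- match.arg(orientation)
  seqs <- asSeqChar(reads)
  if (length(seqs) == 0) stop("no reads: cannot build a 15-mer spectrum")
  ptr <- olca_spectrum_build(seqs, orientation == "both")
  info <- olca_spectrum_info(ptr)
  if (info$nObserved == 0) stop("no countable 15-mer in the input reads")
  hist <- olca_spectrum_histogram(ptr)
  ms <- estimateModeAndSize(hist,
                            instances = info$instances)
  tabs <- olca_rank_tables(ptr, ms$mode)
  new("KmerSpectrum", ptr = ptr, histogram = hist,
      instances = info$instances,
      totalInstances = sum(hist$count * hist$distinct),
      mode = as.integer(ms$mode), genomeSizeEstimate = ms$genomeSize,
      modeWarning = ms$warning, orientation = orientation,
      primeAbove = tabs$primeAbove, cumByRank = tabs$cumByRank)
}

#' Estimate the spectrum mode and genome size from a count histogram
#'
#' The error peak at low counts is excluded by scanning the (dense) histogram
#' upwards from count 1 until the first rise (local minimum); the mode is the
#' most populous count beyond that point. When the histogram decreases
#' monotonically (no second peak) the mode falls back to 1 with a warning
#' flag. The genome size is the number of 15-mer instances divided by the
#' mode.
#'
#' @param histogram data.frame with columns \code{count} and \code{distinct}.
#' @param instances Number of 15-mer instances (defaults to
#'   \code{sum(count * distinct)}, correct for canonical-orientation counts;
#'   both-strand spectra pass their instance count explicitly because each
#'   instance increments two counters).
#' @return list(mode, genomeSize, warning)
#' @export
estimateModeAndSize <- function(histogram,
                                instances = sum(histogram$count *
                                                histogram$distinct)) {
  if (nrow(histogram) == 0) stop("empty histogram")
  maxc <- max(histogram$count)
  dens <- numeric(maxc)
  dens[histogram$count] <- histogram$distinct
  # first rise marks the end of the error peak
  valley <- NA_integer_
  if (maxc >= 2) {
    rises <- which(dens[-1] > dens[-maxc])  # dens[x+1] > dens[x]
    if (length(rises) > 0) valley <- rises[1]
  }
  if (is.na(valley)) {
    mode <- 1L
    warning_flag <- TRUE
  } else {
    beyond <- (valley + 1):maxc
    mode <- beyond[which.max(dens[beyond])]
    warning_flag <- FALSE
  }
  list(mode = as.integer(mode), genomeSize = round(instances / mode),
       warning = warning_flag)
}

#' @describeIn KmerSpectrum histogram accessor (count vs distinct 15-mers)
#' @param spectrum A \linkS4class{KmerSpectrum}.
#' @export
spectrumHistogram <- function(spectrum) spectrum@histogram

#' @describeIn KmerSpectrum mode (single-copy peak count)
#' @export
spectrumMode <- function(spectrum) spectrum@mode

#' @describeIn KmerSpectrum estimated genome size in bases
#' @export
genomeSize <- function(spectrum) spectrum@genomeSizeEstimate

setMethod("show", "KmerSpectrum", function(object) {
  cat("KmerSpectrum (fixed 2^30-entry 15-mer table)\n")
  cat("  orientation:      ", object@orientation, "\n")
  cat("  15-mer instances: ", format(object@instances, big.mark = ","), "\n")
  cat("  distinct 15-mers: ",
      format(sum(object@histogram$distinct), big.mark = ","), "\n")
  cat("  mode (depth):     ", object@mode,
      if (object@modeWarning) " [fallback: no secondary peak]" else "", "\n")
  cat("  genome size est.: ", format(object@genomeSizeEstimate,
                                     big.mark = ","), " bp\n")
})

#' Count lookups in a spectrum
#'
#' @param spectrum A \linkS4class{KmerSpectrum}.
#' @param kmers Character vector of 15-mers.
#' @return Integer counts under the spectrum's orientation policy.
#' @export
kmerCount <- function(spectrum, kmers) {
  if (any(nchar(kmers) != 15)) stop("spectrum lookups require 15-mers")
  codes <- olca_encode_kmer(as.character(kmers), 15L)
  olca_spectrum_counts(spectrum@ptr, codes)
}

#' Rank of a k-mer count
#'
#' The priority measure behind the hash: twice the distance of the count from
#' the spectrum mode, so modal (single-copy) k-mers get rank 0.
#'
#' @param x Count value(s), >= 0.
#' @param mode Spectrum mode.
#' @return Integer rank 2 * |x - mode|.
#' @export
kmerRank <- function(x, mode) {
  if (any(x < 0)) stop("counts must be >= 0")
  as.integer(2L * abs(as.integer(x) - as.integer(mode)))
}

#' Smallest prime strictly greater than x
#'
#' @param x Non-negative integer(s), up to 2^15 - 1.
#' @return Integer prime(s) > x.
#' @export
smallestPrimeAbove <- function(x) {
  x <- as.integer(x)
  if (any(x < 0 | x > 32767L)) stop("x must be in 0..32767")
  sieveMax <- 32831L
  isComp <- logical(sieveMax)
  for (i in 2:181) if (!isComp[i]) isComp[seq(i * i, sieveMax, by = i)] <- TRUE
  primes <- which(!isComp)[-1]  # drop 1
  primes[findInterval(x, primes) + 1L]
}

#' Cumulative distinct 15-mers below a rank
#'
#' Number of distinct observed 15-mers whose rank is strictly smaller than
#' \code{rank} -- the first term of the hash.
#'
#' @param spectrum A \linkS4class{KmerSpectrum}.
#' @param rank Integer rank(s) >= 0.
#' @return Numeric count(s).
#' @export
cumBelow <- function(spectrum, rank) {
  rank <- as.integer(rank)
  if (any(rank < 0)) stop("rank must be >= 0")
  idx <- pmin(rank, length(spectrum@cumByRank) - 1L) + 1L
  spectrum@cumByRank[idx]
}

#' Rank-based hash of the k-mers of a sequence
#'
#' For every N-free k-mer (forward strand) of \code{seq}, returns the hash
#' h(b) = cumBelow(r(x)) + (b mod primeAbove(x)), where b is the 2-bit k-mer
#' code and x is the spectrum count of the 15-mer suffix of b. Modal-suffix
#' k-mers therefore hash lowest and win minimizer selection.
#'
#' @param seq A single sequence (character or DNAString).
#' @param k k-mer length, 15..31 (codes reported exactly for k <= 26).
#' @param spectrum A \linkS4class{KmerSpectrum}.
#' @return data.frame(pos, code, hash, suffixCount) with 0-based \code{pos}.
#' @export
hashKmers <- function(seq, k, spectrum) {
  if (k < 15 || k > 31) stop("hashing requires 15 <= k <= 31")
  s <- asSeqChar(seq)
  if (length(s) != 1) stop("hashKmers expects a single sequence")
  olca_hash_kmers(spectrum@ptr, spectrum@mode, spectrum@primeAbove,
                  spectrum@cumByRank, s[[1]], as.integer(k))
}

#' Spectrum-based substitution error correction
#'
#' Scans each read left to right; at every position where all overlapping
#' 15-mers have count < \code{minSolid}, the three substitutions are tried and
#' the unique one lifting all overlapping 15-mers to >= \code{minSolid} is
#' accepted. Unfixable positions (including adjacent double errors) are left
#' unchanged.
#'
#' @param reads DNAStringSet or named character vector.
#' @param spectrum Spectrum built from the same read set.
#' @param minSolid Solidity threshold; default max(3, mode/4).
#' @return DNAStringSet of corrected reads (same names, same order).
#' @export
correctReads <- function(reads, spectrum,
                         minSolid = max(3, spectrum@mode %/% 4)) {
  seqs <- asSeqChar(reads)
  out <- vapply(seqs, function(s)
    olca_correct_read(spectrum@ptr, s, as.integer(minSolid)), character(1))
  names(out) <- names(seqs)
  asDNAStringSet(out)
}
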