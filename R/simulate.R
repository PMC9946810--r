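#' Simulate a random genome sequence
#'
#' Bases are drawn i.i.d. with P(G) + P(C) = \code{gc}; deterministic per
#' seed.
#'
#' @param length Genome length in bases (>= 1000).
#' @param gc GC content in [0, 1] (default 0.5).
#' @param seed RNG seed.
#' @param name Sequence name (default "genome").
#' @return Named character vector of length 1.
#' @export
simulateGenome <- function(length, gc = 0.5, seed = 1L, name = "genome") {
  if (length < 1000) stop("genome length must be >= 1000")
  withSeed(seed, {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    s <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
                      prob = p), collapse = "")
  })
  stats::setNames(s, name)
}

#' Build a diploid template
#'
#' Either two explicit haplotypes, or a second haplotype derived from the
#' first by planting SNVs (and optionally short indels) at the given rates.
#' During read simulation each read draws its haplotype with probability 1/2.
#'
#' @param hap1 First haplotype (named character or DNAStringSet of 1).
#' @param hap2 Second haplotype; NULL to derive it from \code{hap1}.
#' @param snvRate Per-base SNV rate used to derive hap2 (default 0.01).
#' @param indelRate Per-base indel rate for derivation (default 0).
#' @param seed RNG seed for derivation.
#' @return list(haplotypes = named character vector of 2, variants =
#'   data.frame(pos, ref, alt) of planted SNVs in hap1 coordinates, NULL when
#'   hap2 was given explicitly).
#' @export
buildDiploid <- function(hap1, hap2 = NULL, snvRate = 0.01, indelRate = 0,
                         seed = 1L) {
  h1 <- asSeqChar(hap1)
  if (length(h1) != 1) stop("hap1 must be a single sequence")
  if (!is.null(hap2)) {
    h2 <- asSeqChar(hap2)
    if (length(h2) != 1) stop("hap2 must be a single sequence")
    haps <- c(h1, h2)
    if (names(haps)[1] == names(haps)[2])
      names(haps) <- paste0(names(haps), c("_1", "_2"))
    return(list(haplotypes = haps, variants = NULL))
  }
  s <- h1[[1]]
  n <- nchar(s)
  withSeed(seed, {
    r <- charToRaw(s)
    nSnv <- rbinom(1, n, snvRate)
    pos <- sort(sample.int(n, nSnv))
    baseRaw <- charToRaw("ACGT")
    code <- integer(256)
    code[as.integer(baseRaw) + 1L] <- 0:3
    refCode <- code[as.integer(r[pos]) + 1L]
    altCode <- (refCode + sample.int(3, nSnv, replace = TRUE)) %% 4L
    r2 <- r
    r2[pos] <- baseRaw[altCode + 1L]
    variants <- data.frame(pos = pos - 1L,
                           ref = strsplit(rawToChar(r[pos]), "")[[1]],
                           alt = strsplit(rawToChar(r2[pos]), "")[[1]],
                           stringsAsFactors = FALSE)
    s2 <- rawToChar(r2)
    if (indelRate > 0) {
      nInd <- rbinom(1, n, indelRate)
      if (nInd > 0) {
        ipos <- sort(sample.int(nchar(s2), nInd), decreasing = TRUE)
        for (p in ipos) {
          if (runif(1) < 0.5) {
            ins <- paste(sample(c("A", "C", "G", "T"), 1 + rgeom(1, 0.5),
                                replace = TRUE), collapse = "")
            s2 <- paste0(substr(s2, 1, p), ins, substr(s2, p + 1, nchar(s2)))
          } else {
            dl <- 1 + rgeom(1, 0.5)
            s2 <- paste0(substr(s2, 1, p - 1),
                         substr(s2, min(nchar(s2), p + dl) + 1, nchar(s2)))
          }
        }
      }
    }
  })
  haps <- c(h1, stats::setNames(s2, paste0(names(h1), "_hap2")))
  names(haps)[1] <- paste0(names(h1), "_hap1")
  list(haplotypes = haps, variants = variants)
}

#' Simulate long reads from a (possibly diploid) template
#'
#' Per read: haplotype ~ Bernoulli(1/2) (diploid templates), start ~ uniform,
#' length ~ Normal(meanLen, sdLen) truncated to [200, templateLen - start],
#' strand ~ Bernoulli(1/2); substitution errors are i.i.d. at
#' \code{substRate}; indels occur at \code{indelRate}, split evenly between
#' insertions and deletions, with length 1 + Geometric(0.5). Read names encode
#' the ground truth as
#' \code{r<i>:<template>:<start>-<end>:<strand>:<hap>} with a 0-based
#' half-open [start, end) span on the originating haplotype.
#'
#' @param template Named character vector of 1 or 2 haplotypes, or the list
#'   returned by \code{\link{buildDiploid}}.
#' @param numReads Number of reads; alternatively give \code{depth}.
#' @param depth Total sequencing depth (converted to numReads via the mean
#'   haplotype length and meanLen).
#' @param meanLen,sdLen Read length distribution (defaults 20000, 5000).
#' @param substRate Substitution error rate (default 0.005).
#' @param indelRate Indel error rate (default 0.01).
#' @param seed RNG seed.
#' @return DNAStringSet of reads with truth-encoded names.
#' @export
simulateReads <- function(template, numReads = NULL, depth = NULL,
                          meanLen = 20000, sdLen = 5000, substRate = 0.005,
                          indelRate = 0.01, seed = 1L) {
  if (is.list(template) && !is.null(template$haplotypes))
    template <- template$haplotypes
  haps <- asSeqChar(template)
  if (!(length(haps) %in% 1:2)) stop("template must have 1 or 2 haplotypes")
  if (any(grepl(":", names(haps), fixed = TRUE)))
    stop("template names must not contain ':'")
  if (substRate < 0 || substRate >= 0.5 || indelRate < 0 || indelRate >= 0.5)
    stop("error rates must be in [0, 0.5)")
  hapLens <- nchar(haps)
  if (min(hapLens) < meanLen / 4)
    stop("template shorter than meanLen/4")
  if (is.null(numReads) == is.null(depth))
    stop("give exactly one of numReads / depth")
  if (is.null(numReads))
    numReads <- round(depth * mean(hapLens) / meanLen)
  if (numReads < 1) stop("numReads must be >= 1")

  baseRaw <- charToRaw("ACGT")
  code <- integer(256)
  code[as.integer(baseRaw) + 1L] <- 0:3
  hapRaws <- lapply(haps, charToRaw)

  out <- character(numReads)
  nms <- character(numReads)
  withSeed(seed, {
    for (i in seq_len(numReads)) {
      hi <- if (length(haps) == 2) sample.int(2L, 1L) else 1L
      L <- hapLens[hi]
      start <- sample.int(L - 199L, 1L) - 1L  # 0-based; keeps L - start >= 200
      len <- round(rnorm(1, meanLen, sdLen))
      len <- min(max(len, 200L), L - start)  # truncate to [200, L - start]
      r <- hapRaws[[hi]][(start + 1L):(start + len)]
      strand <- if (runif(1) < 0.5) "+" else "-"
      # substitutions
      nS <- rbinom(1, len, substRate)
      if (nS > 0) {
        pos <- sample.int(len, nS)
        refCode <- code[as.integer(r[pos]) + 1L]
        altCode <- (refCode + sample.int(3L, nS, replace = TRUE)) %% 4L
        r[pos] <- baseRaw[altCode + 1L]
      }
      # indels: one left-to-right pass assembling pieces, concatenated once
      nI <- rbinom(1, len, indelRate)
      if (nI > 0) {
        ipos <- sort(sample.int(len, nI))
        isIns <- runif(nI) < 0.5
        ilen <- 1L + rgeom(nI, 0.5)
        pieces <- vector("list", 2L * nI + 1L)
        np <- 0L
        prev <- 1L
        for (j in seq_len(nI)) {
          p <- ipos[j]
          if (p < prev) next  # swallowed by a previous deletion
          if (isIns[j]) {     # insertion after position p
            np <- np + 1L; pieces[[np]] <- r[prev:p]
            np <- np + 1L
            pieces[[np]] <- baseRaw[sample.int(4L, ilen[j], replace = TRUE)]
            prev <- p + 1L
          } else {            # deletion of positions p .. p + ilen - 1
            if (p > prev) { np <- np + 1L; pieces[[np]] <- r[prev:(p - 1L)] }
            prev <- min(length(r), p + ilen[j] - 1L) + 1L
          }
        }
        if (prev <= length(r)) {
          np <- np + 1L
          pieces[[np]] <- r[prev:length(r)]
        }
        r <- unlist(pieces[seq_len(np)], use.names = FALSE)
      }
      s <- rawToChar(r)
      if (strand == "-") s <- revcompChar(s)
      out[i] <- s
      nms[i] <- sprintf("r%d:%s:%d-%d:%s:%d", i, names(haps)[hi], start,
                        start + len, strand, hi)
    }
  })
  asDNAStringSet(stats::setNames(out, nms))
}

#' Parse truth-encoded read names
#'
#' @param names Read names produced by \code{\link{simulateReads}}.
#' @return data.frame(readName, template, start, end, strand, hap); rows with
#'   unparseable names carry NAs.
#' @export
readTruth <- function(names) {
  pat <- "^r[0-9]+:(.+):([0-9]+)-([0-9]+):([+-]):([12])$"
  ok <- grepl(pat, names)
  out <- data.frame(
    readName = names, template = NA_character_, start = NA_real_,
    end = NA_real_, strand = NA_character_, hap = NA_integer_,
    stringsAsFactors = FALSE)
  if (any(ok)) {
    out$template[ok] <- sub(pat, "\\1", names[ok])
    out$start[ok] <- as.numeric(sub(pat, "\\2", names[ok]))
    out$end[ok] <- as.numeric(sub(pat, "\\3", names[ok]))
    out$strand[ok] <- sub(pat, "\\4", names[ok])
    out$hap[ok] <- as.integer(sub(pat, "\\5", names[ok]))
  }
  out
}

# evaluate an expression under a local RNG seed, restoring global state
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  eval.parent(substitute(expr))
}
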