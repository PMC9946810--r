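# Shared fixtures and independent oracles, all built in code.

BASES <- c("A", "C", "G", "T")

randSeq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# trial-division primality; independent of the package's sieve
oraclePrimeAbove <- function(x) {
  isPrime <- function(p) {
    if (p < 2) return(FALSE)
    if (p < 4) return(TRUE)
    for (d in 2:floor(sqrt(p))) if (p %% d == 0) return(FALSE)
    TRUE
  }
  q <- x + 1
  while (!isPrime(q)) q <- q + 1
  q
}

# brute-force hash of distinct observed 15-mers: rank from the mode, cumBelow
# by sorting the k-mers by rank and counting the strictly smaller ones, the
# prime by trial division
oracleHashTable <- function(spectrum) {
  codes <- olca:::olca_spectrum_observed(spectrum@ptr)
  x <- olca:::olca_spectrum_counts(spectrum@ptr, codes)
  mode <- spectrumMode(spectrum)
  r <- 2L * abs(x - mode)
  ur <- sort(unique(r))
  nAt <- vapply(ur, function(ri) sum(r == ri), numeric(1))
  below <- c(0, cumsum(nAt))[match(r, ur)]
  primes <- vapply(unique(x), oraclePrimeAbove, numeric(1))
  names(primes) <- unique(x)
  data.frame(code = codes, count = x, rank = r,
             hash = below + codes %% primes[as.character(x)])
}

# brute-force per-window argmin minimizers over the package hash values
oracleMinimizers <- function(s, k, w, spectrum) {
  hf <- hashKmers(s, k, spectrum)
  hr <- hashKmers(olca:::revcompChar(s), k, spectrum)
  n <- nchar(s)
  idx <- n - k - hf$pos
  hrr <- hr[match(idx, hr$pos), ]
  selHash <- pmin(hf$hash, hrr$hash)
  selCode <- ifelse(hf$hash < hrr$hash, hf$code,
             ifelse(hrr$hash < hf$hash, hrr$code, pmin(hf$code, hrr$code)))
  npos <- n - k + 1
  stopifnot(nrow(hf) == npos)
  out <- integer(npos)
  nOut <- 0L
  for (wstart in 0:(npos - w)) {
    j <- (wstart + 1L):(wstart + w)
    cand <- j[selHash[j] == min(selHash[j])]
    if (length(cand) > 1) cand <- cand[selCode[cand] == min(selCode[cand])]
    nOut <- nOut + 1L
    out[nOut] <- cand[1] - 1L
  }
  sort(unique(out[seq_len(nOut)]))
}

# exhaustive maximum-total-score edge subset under the layout feasibility
# rules (matching on vertices, acyclic over reads)
oracleBestEdgeSet <- function(edges, scores) {
  nE <- nrow(edges)
  vA <- paste0(edges$readA, "^", edges$endA)
  vB <- paste0(edges$readB, "^", edges$endB)
  best <- list(score = -Inf, sel = integer(0))
  reads <- unique(c(edges$readA, edges$readB))
  recurse <- function(i, sel, used, parent, score) {
    if (i > nE) {
      if (score > best$score) best <<- list(score = score, sel = sel)
      return(invisible())
    }
    # exclude edge i
    recurse(i + 1L, sel, used, parent, score)
    # include edge i if feasible
    if (!(vA[i] %in% used) && !(vB[i] %in% used)) {
      find <- function(r) { while (parent[[r]] != r) r <- parent[[r]]; r }
      fa <- find(edges$readA[i]); fb <- find(edges$readB[i])
      if (fa != fb) {
        p2 <- parent; p2[[fa]] <- fb
        recurse(i + 1L, c(sel, i), c(used, vA[i], vB[i]), p2,
                score + scores[i])
      }
    }
  }
  parent0 <- as.list(stats::setNames(reads, reads))
  recurse(1L, integer(0), character(0), parent0, 0)
  sort(best$sel)
}

# naive MEC: per variant and haplotype allele choice, count minority entries
oracleMec <- function(M, sides) {
  tot <- 0
  for (v in seq_len(ncol(M))) {
    e0 <- 0; e1 <- 0
    for (f in seq_len(nrow(M))) {
      a <- M[f, v]
      if (is.na(a)) next
      h <- if (sides[f] == 1L) 0L else 1L  # haplotype allele under h1 = 0
      if (a != h) e0 <- e0 + 1
      h <- 1L - h                          # haplotype allele under h1 = 1
      if (a != h) e1 <- e1 + 1
    }
    tot <- tot + min(e0, e1)
  }
  tot
}

# exhaustive minimum MEC over all bipartitions (first fragment fixed)
oracleMinMec <- function(M) {
  n <- nrow(M)
  if (n == 1) return(0)
  best <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    sides <- c(1L, 1L + as.integer(intToBits(mask))[seq_len(n - 1)])
    best <- min(best, oracleMec(M, sides))
  }
  best
}

# graph construction helper for hand-built layout instances
makeGraph <- function(edges, readLens) {
  edges$centroid <- if (is.null(edges$centroid)) 0 else edges$centroid
  edges$reverse <- if (is.null(edges$reverse)) FALSE else edges$reverse
  nonEmb <- names(readLens)
  vs <- c(paste0(edges$readA, "^", edges$endA),
          paste0(edges$readB, "^", edges$endB))
  allv <- c(paste0(nonEmb, "^s"), paste0(nonEmb, "^e"))
  deg <- as.integer(table(factor(vs, levels = allv)))
  new("AssemblyGraph", reads = stats::setNames(strrep("A", readLens),
                                               names(readLens)),
      readLengths = stats::setNames(as.integer(readLens), names(readLens)),
      edges = edges,
      embedded = data.frame(read = character(0), host = character(0),
                            relStart = numeric(0), reverse = logical(0),
                            nSharedKmers = integer(0)),
      degreeMean = mean(deg), degreeSD = if (length(deg) > 1) sd(deg) else 0,
      params = list())
}

# random fragment matrix with planted haplotypes, noise and missing entries
randomFragmentMatrix <- function(nFrag, nVar, flipRate = 0.1) {
  h1 <- sample(0:1, nVar, replace = TRUE)
  M <- matrix(NA_integer_, nFrag, nVar)
  for (f in seq_len(nFrag)) {
    span <- sort(sample(nVar, max(2, sample(2:nVar, 1))))
    span <- span[1]:span[length(span)]
    hap <- sample(1:2, 1)
    al <- if (hap == 1) h1[span] else 1L - h1[span]
    flip <- stats::runif(length(al)) < flipRate
    al[flip] <- 1L - al[flip]
    M[f, span] <- al
  }
  M
}
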