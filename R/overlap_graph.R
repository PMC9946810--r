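#' AssemblyGraph: undirected overlap graph with two vertices per read
#'
#' Every non-embedded read X contributes two vertices, X^s (5'-end) and X^e
#' (3'-end). An overlap between the end of A and the start of B is the edge
#' {A^e, B^s}; an overlap with the reverse complement of B is {A^e, B^e}. The
#' graph is simple (one edge per unordered vertex pair, the one with the most
#' shared k-mers) and completely undirected, reflecting that reads come from
#' both strands with equal probability. Reads fully contained in a longer read
#' are recorded as embedded and carry no vertices.
#'
#' @slot reads Named character vector of all input reads.
#' @slot readLengths Named integer vector.
#' @slot edges data.frame of overlap edges with feature statistics
#'   (readA/endA = subject side, readB/endB = query side, overlap, csk,
#'   nSharedKmers, propEvidence).
#' @slot embedded data.frame(read, host, relStart, reverse, nSharedKmers);
#'   one row per embedded read (its best-supported host).
#' @slot containments All containment records observed during construction
#'   (an embedded read may have several candidate hosts).
#' @slot shadowEdges Overlap edges that were dropped because they touch an
#'   embedded read; haplotype-aware reassembly can restore them when a
#'   contained read has to be returned to the graph.
#' @slot degreeMean,degreeSD Cached total-vertex-degree statistics.
#' @slot params List of construction parameters (k, w, delta, ...).
#' @export
setClass("AssemblyGraph", representation(
  reads = "character", readLengths = "integer", edges = "data.frame",
  embedded = "data.frame", containments = "data.frame",
  shadowEdges = "data.frame", degreeMean = "numeric", degreeSD = "numeric",
  params = "list"
))

setMethod("show", "AssemblyGraph", function(object) {
  cat("AssemblyGraph:", length(object@reads), "reads (",
      nrow(object@embedded), "embedded ),", nrow(object@edges), "edges\n")
  cat("  vertex degree mean:", round(object@degreeMean, 2),
      " sd:", round(object@degreeSD, 2), "\n")
})

#' @describeIn AssemblyGraph edge table accessor
#' @param graph An \linkS4class{AssemblyGraph}.
#' @export
graphEdges <- function(graph) graph@edges

#' @describeIn AssemblyGraph embedded-read table accessor
#' @export
embeddedReads <- function(graph) graph@embedded

#' @describeIn AssemblyGraph names of reads that carry vertices
#' @export
nonEmbeddedReads <- function(graph)
  setdiff(names(graph@reads), graph@embedded$read)

# default clustering tolerance for predicted overlap starts
defaultDelta <- function(queryLen) max(100, 0.01 * queryLen)

# Lloyd refinement of 1-D gap clusters (<= maxIter rounds)
refineClusters <- function(x, delta, maxIter = 10L) {
  cl <- clusterStarts(x, delta)
  if (max(cl) == 1L) return(cl)
  for (it in seq_len(maxIter)) {
    cent <- vapply(split(x, cl), mean, numeric(1))
    newcl <- apply(abs(outer(x, cent, "-")), 1, which.min)
    # renumber consecutively
    newcl <- match(newcl, sort(unique(newcl)))
    if (identical(as.integer(newcl), as.integer(cl))) break
    cl <- as.integer(newcl)
    if (max(cl) == 1L) break
  }
  cl
}

# Core per-pair clustering on bare vectors. Returns a list of equal-length
# vectors, one element per retained cluster.
pairClusters <- function(qpos, spos, rev, qlen, slen, k, w, delta,
                         minShared, contTol) {
  empty <- list(type = character(0), endS = character(0), endQ = character(0),
                overlap = numeric(0), csk = numeric(0), n = integer(0),
                propEvidence = numeric(0), relStart = numeric(0),
                reverse = logical(0), centroid = numeric(0),
                firstSubj = integer(0), lastSubj = integer(0),
                firstQuery = integer(0), lastQuery = integer(0))
  dup <- duplicated(paste(qpos, spos, rev))
  qpos <- qpos[!dup]; spos <- spos[!dup]; rev <- rev[!dup]
  if (length(qpos) == 0) return(empty)

  rows <- list()
  for (rv in unique(rev)) {
    sel <- rev == rv
    ps <- predictedStart(qpos[sel], spos[sel], rv, qlen, k)
    cl <- refineClusters(ps, delta)
    for (ci in seq_len(max(cl))) {
      idx <- which(cl == ci)
      if (length(idx) == 0) next
      q <- qpos[sel][idx]; s <- spos[sel][idx]; p <- ps[idx]
      centroid <- mean(p)
      ovHit <- pmin(slen, p + qlen) - pmax(0, p)
      overlap <- mean(ovHit)
      su <- sort(unique(s))
      csk <- if (length(su) > 1) sum(pmin(diff(su), k)) + k else k
      prop <- (max(s) - min(s) + k) / max(overlap, 1)
      prop <- min(1, max(1e-6, prop))
      rows[[length(rows) + 1L]] <- list(
        n = length(idx), reverse = rv, centroid = centroid, overlap = overlap,
        csk = csk, propEvidence = prop, firstSubj = min(s), lastSubj = max(s),
        firstQuery = min(q), lastQuery = max(q))
    }
  }
  if (length(rows) == 0) return(empty)
  # sort by shared k-mer count descending
  ord <- order(-vapply(rows, `[[`, numeric(1), "n"))
  rows <- rows[ord]

  out <- empty
  takenConfigs <- character(0)
  for (r in rows) {
    cls <- classifyClusterGeometry(r$centroid, r$reverse, qlen, slen, contTol)
    if (r$n < minShared || r$overlap < w + k - 1) next  # below evidence floor
    if (length(out$type) >= 2L) break
    if (!cls$embedded && cls$config %in% takenConfigs) next
    if (length(out$type) >= 1L && cls$embedded) break  # containment only as top
    out$type <- c(out$type, if (cls$embedded) "embedded" else "edge")
    out$endS <- c(out$endS, if (cls$embedded) NA_character_ else cls$endS)
    out$endQ <- c(out$endQ, if (cls$embedded) NA_character_ else cls$endQ)
    out$overlap <- c(out$overlap, r$overlap)
    out$csk <- c(out$csk, r$csk)
    out$n <- c(out$n, r$n)
    out$propEvidence <- c(out$propEvidence, r$propEvidence)
    out$relStart <- c(out$relStart, if (cls$embedded) max(0, r$centroid)
                      else NA_real_)
    out$reverse <- c(out$reverse, r$reverse)
    out$centroid <- c(out$centroid, r$centroid)
    out$firstSubj <- c(out$firstSubj, r$firstSubj)
    out$lastSubj <- c(out$lastSubj, r$lastSubj)
    out$firstQuery <- c(out$firstQuery, r$firstQuery)
    out$lastQuery <- c(out$lastQuery, r$lastQuery)
    if (cls$embedded) break  # a contained query forms no edges
    takenConfigs <- c(takenConfigs, cls$config)
  }
  out
}

# geometry of a cluster: containment vs which ends meet
classifyClusterGeometry <- function(centroid, reverse, queryLen, subjectLen,
                                    tol) {
  if (centroid >= -tol && centroid + queryLen <= subjectLen + tol)
    return(list(embedded = TRUE, config = "contained",
                endS = NA_character_, endQ = NA_character_))
  endS <- if (centroid > 0) "e" else "s"
  endQ <- if (!reverse) { if (centroid > 0) "s" else "e" }
          else { if (centroid > 0) "e" else "s" }
  list(embedded = FALSE, config = paste0(endS, endQ), endS = endS, endQ = endQ)
}

#' Cluster minimizer hits of one read pair
#'
#' Groups the k-mer hits shared by a subject (longer) and a query (shorter)
#' read by the subject start they predict for the query, using 1-D gap
#' clustering refined by up to 10 k-means (Lloyd) rounds. Hits of opposite
#' relative orientations are clustered separately. Per cluster the overlap is
#' the mean of per-hit inferences, CSK is the number of subject bases covered
#' by the shared k-mers, and the proportion of evidence is
#' (lastSubj - firstSubj + k) / overlap clamped to (0, 1]. Up to two clusters
#' with the largest hit counts are retained, and only when they support two
#' distinct alignment configurations; clusters implying containment of the
#' query mark it embedded instead.
#'
#' @param hits data.frame(queryPos, subjectPos, reverse) of minimizer hits
#'   between one subject/query pair (0-based positions).
#' @param queryLen,subjectLen Read lengths (query must be the shorter read).
#' @param k,w Minimizer parameters used to generate the hits.
#' @param delta Clustering tolerance in bases; default max(100, 1% of query).
#' @param minSharedKmers Minimum hits per retained cluster (default 5).
#' @param containmentTol Slack in bases before declaring containment
#'   (default 2k).
#' @return data.frame with one row per retained cluster: type ("edge" or
#'   "embedded"), endS/endQ (which subject/query ends meet), overlap, csk, n,
#'   propEvidence, relStart (containment offset), reverse, centroid and
#'   evidence-span endpoints.
#' @export
clusterHits <- function(hits, queryLen, subjectLen, k = 25L, w = 40L,
                        delta = defaultDelta(queryLen), minSharedKmers = 5L,
                        containmentTol = 2L * k) {
  res <- pairClusters(hits$queryPos, hits$subjectPos, hits$reverse,
                      queryLen, subjectLen, k, w, delta, minSharedKmers,
                      containmentTol)
  as.data.frame(res, stringsAsFactors = FALSE)
}

#' Classify the alignment configuration of a hit cluster
#'
#' From the cluster centroid (predicted subject start of the oriented query)
#' and orientation: a positive centroid with forward hits means the subject
#' end overlaps the query start ({S^e, Q^s}); reverse-orientation hits flip
#' the query end ({S^e, Q^e} at the subject end). Centroids placing the whole
#' query inside the subject (within tolerance) flag containment.
#'
#' @param centroid Mean predicted subject start.
#' @param reverse Orientation of the cluster's hits.
#' @param queryLen,subjectLen Read lengths.
#' @param tol Containment slack in bases.
#' @return list(embedded, config, endS, endQ); config is one of "ss", "se",
#'   "es", "ee" or "contained".
#' @export
classifyConfiguration <- function(centroid, reverse, queryLen, subjectLen,
                                  tol = 50L) {
  classifyClusterGeometry(centroid, reverse, queryLen, subjectLen, tol)
}

#' Build the overlap graph of a read set
#'
#' Reads are sorted by decreasing length; each read is queried as a minimizer
#' query against the table of the longer reads seen so far, so every candidate
#' pair has the longer read as subject. Hit clusters become feature-annotated
#' edges (or containment records) without any base-level pairwise alignment.
#'
#' @param reads DNAStringSet or named character vector.
#' @param k,w Minimizer parameters (defaults 25 and 40).
#' @param spectrum Optional prebuilt \linkS4class{KmerSpectrum} of the reads.
#' @param delta Hit-clustering tolerance; default max(100, 1% of query length).
#' @param minSharedKmers Minimum shared k-mers per edge (default 5).
#' @param containmentTol Containment slack, default 2k.
#' @return An \linkS4class{AssemblyGraph}.
#' @export
buildAssemblyGraph <- function(reads, k = 25L, w = 40L, spectrum = NULL,
                               delta = NULL, minSharedKmers = 5L,
                               containmentTol = 2L * k) {
  ss <- asSeqChar(reads)
  if (length(ss) == 0) stop("no reads")
  lens <- nchar(ss)
  if (is.null(spectrum)) spectrum <- buildSpectrum(ss)

  emptyEdges <- data.frame(readA = character(0), endA = character(0),
                           readB = character(0), endB = character(0),
                           overlap = numeric(0), csk = numeric(0),
                           nSharedKmers = integer(0),
                           propEvidence = numeric(0), reverse = logical(0),
                           centroid = numeric(0), stringsAsFactors = FALSE)
  emptyEmb <- data.frame(read = character(0), host = character(0),
                         relStart = numeric(0), reverse = logical(0),
                         nSharedKmers = integer(0), stringsAsFactors = FALSE)
  params <- list(k = as.integer(k), w = as.integer(w), delta = delta,
                 minSharedKmers = as.integer(minSharedKmers),
                 containmentTol = as.integer(containmentTol))
  finishGraph <- function(edges, emb, containments = emb,
                          shadow = emptyEdges) {
    nonEmb <- setdiff(names(ss), emb$read)
    deg <- rep(0L, 2L * length(nonEmb))
    if (nrow(edges) > 0) {
      vs <- c(paste0(edges$readA, "^", edges$endA),
              paste0(edges$readB, "^", edges$endB))
      allv <- c(paste0(nonEmb, "^s"), paste0(nonEmb, "^e"))
      deg <- as.integer(table(factor(vs, levels = allv)))
    }
    new("AssemblyGraph", reads = ss, readLengths = lens, edges = edges,
        embedded = emb, containments = containments, shadowEdges = shadow,
        degreeMean = mean(deg),
        degreeSD = if (length(deg) > 1) sd(deg) else 0, params = params)
  }
  if (length(ss) < 2) return(finishGraph(emptyEdges, emptyEmb))

  ord <- order(-lens, names(ss))
  sorted <- ss[ord]
  sortedLens <- lens[ord]
  hits <- olca_overlap_candidates(spectrum@ptr, spectrum@mode,
                                  spectrum@primeAbove, spectrum@cumByRank,
                                  sorted, as.integer(k), as.integer(w))
  if (nrow(hits) == 0) return(finishGraph(emptyEdges, emptyEmb))

  dt <- as.data.table(hits)
  dt[, qLen := sortedLens[query]]
  dt[, sLen := sortedLens[subject]]
  kk <- as.integer(k); ww <- as.integer(w)
  useDelta <- delta
  clusters <- dt[, {
    d <- if (is.null(useDelta)) defaultDelta(qLen[1]) else useDelta
    pairClusters(queryPos, subjectPos, reverse, qLen[1], sLen[1], kk, ww, d,
                 minSharedKmers, containmentTol)
  }, by = .(query, subject)]
  if (nrow(clusters) == 0) return(finishGraph(emptyEdges, emptyEmb))

  nms <- names(sorted)
  clusters[, readA := nms[subject]]
  clusters[, readB := nms[query]]

  contain <- clusters[type == "embedded",
                      .(read = readB, host = readA, relStart = relStart,
                        reverse = reverse, nSharedKmers = n)]
  # keep the best-supported host per embedded read; remember the rest
  emb <- contain
  if (nrow(emb) > 0) {
    setorder(emb, read, -nSharedKmers)
    emb <- emb[!duplicated(emb$read)]
  }

  edges <- clusters[type == "edge",
                    .(readA, endA = endS, readB, endB = endQ, overlap,
                      csk, nSharedKmers = n, propEvidence, reverse,
                      centroid)]
  shadow <- edges[0]
  if (nrow(edges) > 0) {
    # set aside edges touching embedded reads
    touches <- edges$readA %in% emb$read | edges$readB %in% emb$read
    shadow <- edges[touches]
    edges <- edges[!touches]
  }
  if (nrow(edges) > 0) {
    vA <- paste0(edges$readA, "^", edges$endA)
    vB <- paste0(edges$readB, "^", edges$endB)
    key <- ifelse(vA < vB, paste(vA, vB), paste(vB, vA))
    edges[, pairKey := key]
    setorder(edges, pairKey, -nSharedKmers)
    edges <- edges[!duplicated(edges$pairKey)]
    edges[, pairKey := NULL]
  }
  finishGraph(as.data.frame(edges), as.data.frame(emb),
              as.data.frame(contain), as.data.frame(shadow))
}

#' Dump graph edges as a tab-separated file
#'
#' Diagnostic, non-standard format: readA, endA, readB, endB, overlap, csk,
#' nSharedKmers, propEvidence.
#'
#' @param graph An \linkS4class{AssemblyGraph}.
#' @param path Output path.
#' @export
writeGraphEdges <- function(graph, path) {
  write.table(graph@edges[, c("readA", "endA", "readB", "endB", "overlap",
                              "csk", "nSharedKmers", "propEvidence")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
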