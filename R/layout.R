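#' EdgeFeatureModel: feature distributions fitted from safe edges
#'
#' Normal distributions for the overlap length and CSK (coverage of shared
#' k-mers), and a beta distribution for the proportion of the overlap
#' supported by evidence. The model is fitted only from safe edges; when fewer
#' than 10 safe edges exist a fallback flag is set and edges are ranked
#' lexicographically by (overlap, csk) instead.
#'
#' @slot overlapMean,overlapSD Normal fit of edge overlaps (sd floored at 1).
#' @slot cskMean,cskSD Normal fit of CSK.
#' @slot propAlpha,propBeta Method-of-moments beta fit of propEvidence.
#' @slot fallback TRUE when too few safe edges were available.
#' @slot nSafe Number of safe edges used.
#' @export
setClass("EdgeFeatureModel", representation(
  overlapMean = "numeric", overlapSD = "numeric", cskMean = "numeric",
  cskSD = "numeric", propAlpha = "numeric", propBeta = "numeric",
  fallback = "logical", nSafe = "integer"
))

setMethod("show", "EdgeFeatureModel", function(object) {
  if (object@fallback) {
    cat("EdgeFeatureModel: fallback (only", object@nSafe, "safe edges)\n")
  } else {
    cat(sprintf(
      "EdgeFeatureModel from %d safe edges:\n  overlap ~ N(%.1f, %.1f)  csk ~ N(%.1f, %.1f)  prop ~ Beta(%.2f, %.2f)\n",
      object@nSafe, object@overlapMean, object@overlapSD, object@cskMean,
      object@cskSD, object@propAlpha, object@propBeta))
  }
})

#' Layout: ordered, oriented read paths
#'
#' @slot paths List of data.frames (read, reverse, overlapToNext); the last
#'   read of a path has overlapToNext = NA.
#' @slot safeEdges Integer indices (into the graph edge table) of safe edges.
#' @slot selectedEdges Integer indices of all selected layout edges.
#' @export
setClass("Layout", representation(
  paths = "list", safeEdges = "integer", selectedEdges = "integer"
))

setMethod("show", "Layout", function(object) {
  sizes <- vapply(object@paths, nrow, integer(1))
  cat("Layout:", length(object@paths), "paths;",
      sum(sizes > 1), "non-singleton; largest:", max(sizes), "reads\n")
})

# vertex labels of both edge endpoints
edgeVertices <- function(edges) {
  list(vA = paste0(edges$readA, "^", edges$endA),
       vB = paste0(edges$readB, "^", edges$endB))
}

#' Select safe edges
#'
#' An edge {u, v} is safe when it is the reciprocal best of both endpoints in
#' both overlap length AND CSK, and both endpoint vertices have a total degree
#' below mean + 3 standard deviations (computed over all vertices). Safe
#' edges seed the layout paths and the feature distributions.
#'
#' @param graph An \linkS4class{AssemblyGraph}.
#' @return Integer vector of safe edge row indices.
#' @export
selectSafeEdges <- function(graph) {
  edges <- graph@edges
  if (nrow(edges) == 0) return(integer(0))
  v <- edgeVertices(edges)
  long <- data.table(edgeId = rep(seq_len(nrow(edges)), 2L),
                     vertex = c(v$vA, v$vB),
                     overlap = rep(edges$overlap, 2L),
                     csk = rep(edges$csk, 2L))
  long[, degree := .N, by = vertex]
  long[, `:=`(bestOv = max(overlap), bestCsk = max(csk)), by = vertex]
  cutoff <- graph@degreeMean + 3 * graph@degreeSD
  long[, ok := overlap >= bestOv & csk >= bestCsk & degree < cutoff]
  agg <- long[, .(safe = all(ok)), by = edgeId]
  sort(agg$edgeId[agg$safe])
}

#' Fit feature distributions from safe edges
#'
#' Overlap and CSK are fitted as normals via sample mean / SD (SD floored at
#' 1.0 to survive degenerate safe-edge sets); the proportion of evidence is
#' fitted as a beta via the method of moments on values clipped to
#' [1e-6, 1 - 1e-6]. With fewer than \code{minSafe} safe edges an
#' uninformative fallback model is flagged.
#'
#' @param graph An \linkS4class{AssemblyGraph}.
#' @param safe Safe edge indices from \code{\link{selectSafeEdges}}.
#' @param minSafe Minimum number of safe edges for a fit (default 10).
#' @return An \linkS4class{EdgeFeatureModel}.
#' @export
fitEdgeModel <- function(graph, safe = selectSafeEdges(graph), minSafe = 10L) {
  n <- length(safe)
  if (n < minSafe) {
    return(new("EdgeFeatureModel", overlapMean = NA_real_, overlapSD = 1,
               cskMean = NA_real_, cskSD = 1, propAlpha = 1, propBeta = 1,
               fallback = TRUE, nSafe = as.integer(n)))
  }
  e <- graph@edges[safe, ]
  ovSD <- max(1.0, sd(e$overlap))
  cskSD <- max(1.0, sd(e$csk))
  p <- pmin(1 - 1e-6, pmax(1e-6, e$propEvidence))
  m <- mean(p)
  vr <- var(p)
  # method-of-moments guards: variance must sit inside (0, m(1-m))
  vr <- min(max(vr, 1e-8), m * (1 - m) * 0.999)
  common <- m * (1 - m) / vr - 1
  alpha <- max(1e-3, m * common)
  beta <- max(1e-3, (1 - m) * common)
  new("EdgeFeatureModel", overlapMean = mean(e$overlap), overlapSD = ovSD,
      cskMean = mean(e$csk), cskSD = cskSD, propAlpha = alpha,
      propBeta = beta, fallback = FALSE, nSafe = as.integer(n))
}

#' Log-likelihood score of edges
#'
#' Per feature, the likelihood is the lower-tail P-value under the safe-edge
#' distribution (larger overlap / CSK / evidence proportion is more credible);
#' the three log P-values are summed. Each term is floored at log(1e-300).
#'
#' @param edges Edge data.frame (columns overlap, csk, propEvidence).
#' @param model An \linkS4class{EdgeFeatureModel}.
#' @return Numeric score per edge (larger = better).
#' @export
edgeLogLikelihood <- function(edges, model) {
  if (nrow(edges) == 0) return(numeric(0))
  if (model@fallback)
    stop("fallback model has no likelihood; rank by (overlap, csk) instead")
  floorLog <- log(1e-300)
  l1 <- pmax(floorLog, pnorm(edges$overlap, model@overlapMean,
                             model@overlapSD, log.p = TRUE))
  l2 <- pmax(floorLog, pnorm(edges$csk, model@cskMean, model@cskSD,
                             log.p = TRUE))
  p <- pmin(1 - 1e-9, pmax(1e-9, edges$propEvidence))
  l3 <- pmax(floorLog, pbeta(p, model@propAlpha, model@propBeta,
                             log.p = TRUE))
  l1 + l2 + l3
}

#' Build the layout by greedy edge selection
#'
#' Safe edges initialise the paths; the remaining edges are traversed in
#' decreasing log-likelihood order and selected when neither endpoint vertex
#' is already used by a selected edge and the edge does not close a cycle
#' (disjoint-set over reads, the two vertices of a read being pre-united).
#' Paths are read off by walking from free ends; isolated reads become
#' singleton paths. Each path is canonicalised so its first read name is
#' lexicographically smaller than its last.
#'
#' @param graph An \linkS4class{AssemblyGraph}.
#' @param safe Safe edge indices (default: computed).
#' @param model Feature model (default: fitted from the safe edges).
#' @return A \linkS4class{Layout}.
#' @export
buildLayout <- function(graph, safe = selectSafeEdges(graph),
                        model = fitEdgeModel(graph, safe)) {
  edges <- graph@edges
  nonEmb <- nonEmbeddedReads(graph)
  nE <- nrow(edges)

  # ranking: safe edges first; then by score (or (overlap, csk) fallback)
  if (nE > 0) {
    if (model@fallback) {
      ord <- order(-edges$overlap, -edges$csk, edges$readA, edges$readB)
      score <- rank(edges$overlap) + rank(edges$csk)  # diagnostic only
    } else {
      score <- edgeLogLikelihood(edges, model)
      ord <- order(-score, -edges$overlap, -edges$csk, edges$readA,
                   edges$readB)
    }
    isSafe <- seq_len(nE) %in% safe
    ord <- c(ord[isSafe[ord]], ord[!isSafe[ord]])
  } else ord <- integer(0)

  # disjoint set over reads
  parent <- seq_along(nonEmb)
  names(parent) <- nonEmb
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  used <- new.env(hash = TRUE, size = 2L * length(nonEmb))
  v <- edgeVertices(edges)
  selected <- integer(0)
  for (ei in ord) {
    va <- v$vA[ei]; vb <- v$vB[ei]
    if (!is.null(used[[va]]) || !is.null(used[[vb]])) next
    ra <- match(edges$readA[ei], nonEmb)
    rb <- match(edges$readB[ei], nonEmb)
    fa <- find(ra); fb <- find(rb)
    if (fa == fb) next  # would close a cycle
    parent[fa] <- fb
    used[[va]] <- ei
    used[[vb]] <- ei
    selected <- c(selected, ei)
  }

  # walk paths from free ends
  edgeAt <- function(read, end) used[[paste0(read, "^", end)]]
  otherSide <- function(ei, read) {
    if (edges$readA[ei] == read)
      list(read = edges$readB[ei], end = edges$endB[ei])
    else list(read = edges$readA[ei], end = edges$endA[ei])
  }
  visited <- new.env(hash = TRUE, size = length(nonEmb))
  paths <- list()
  degreeOf <- function(read)
    sum(!is.null(edgeAt(read, "s")), !is.null(edgeAt(read, "e")))
  walkOrder <- nonEmb[order(vapply(nonEmb, degreeOf, numeric(1)))]
  for (start in walkOrder) {
    if (!is.null(visited[[start]])) next
    eS <- edgeAt(start, "s"); eE <- edgeAt(start, "e")
    if (!is.null(eS) && !is.null(eE)) next  # internal read, reached by a walk
    # orient so the used port (if any) is the exit
    revFirst <- !is.null(eS) && is.null(eE)
    rows <- list(list(read = start, reverse = revFirst,
                      overlapToNext = NA_real_))
    visited[[start]] <- TRUE
    cur <- start
    curRev <- revFirst
    repeat {
      exitEnd <- if (curRev) "s" else "e"
      ei <- edgeAt(cur, exitEnd)
      if (is.null(ei)) break
      nxt <- otherSide(ei, cur)
      rows[[length(rows)]]$overlapToNext <- edges$overlap[ei]
      nxtRev <- nxt$end == "e"  # entering at 'e' means the read runs reversed
      rows[[length(rows) + 1L]] <- list(read = nxt$read, reverse = nxtRev,
                                        overlapToNext = NA_real_)
      visited[[nxt$read]] <- TRUE
      cur <- nxt$read
      curRev <- nxtRev
    }
    df <- data.frame(read = vapply(rows, `[[`, character(1), "read"),
                     reverse = vapply(rows, `[[`, logical(1), "reverse"),
                     overlapToNext = vapply(rows, `[[`, numeric(1),
                                            "overlapToNext"),
                     stringsAsFactors = FALSE)
    paths[[length(paths) + 1L]] <- canonicalPath(df)
  }
  new("Layout", paths = paths, safeEdges = as.integer(safe),
      selectedEdges = sort(as.integer(selected)))
}

# full reversal canonicalised by lexicographically smaller first read name
canonicalPath <- function(df) {
  n <- nrow(df)
  if (n > 1 && df$read[n] < df$read[1]) {
    ov <- df$overlapToNext
    df <- df[n:1, ]
    df$reverse <- !df$reverse
    df$overlapToNext <- c(rev(ov[-n]), NA_real_)
    rownames(df) <- NULL
  }
  df
}

#' @describeIn Layout list of path data.frames
#' @param layout A \linkS4class{Layout}.
#' @export
layoutPaths <- function(layout) layout@paths
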