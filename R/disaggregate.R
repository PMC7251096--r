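## Pipeline step 4: disaggregation of two touching worms by exhaustive
## search over skeleton-edge partitions minimising the mean distance of
## measured (length, width) to the theoretical worm shape.

skeletonTooComplex <- function(nEdges, maxEdges) {
  stop(structure(class = c("wormspanSkeletonError", "error", "condition"),
                 list(message = sprintf(
                   "skeleton too complex (%d edges > %d): blob rejected as aggregate of more than two worms",
                   nEdges, maxEdges), call = sys.call(-1))))
}

## Is a set of edge indices a valid possible worm (simple connected path)?
## Single edges (including loops) qualify; multi-edge blocks must be
## connected, acyclic, loop-free and nowhere of degree > 2 (a worm cannot
## pass through the same cross twice).
isPathBlock <- function(edgeIdx, edges) {
  k <- length(edgeIdx)
  if (k == 0L) return(FALSE)
  if (k == 1L) return(TRUE)
  ends <- lapply(edges[edgeIdx], function(e) c(e$from, e$to))
  if (any(vapply(ends, function(x) x[1] == x[2], TRUE))) return(FALSE)
  nodes <- unique(unlist(ends))
  if (length(nodes) != k + 1L) return(FALSE)           # tree condition
  deg <- table(factor(unlist(ends), levels = nodes))
  if (any(deg > 2L)) return(FALSE)
  ## connectivity: union-find over the k edges
  parent <- seq_along(nodes)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (e in ends) {
    a <- find(match(e[1], nodes)); b <- find(match(e[2], nodes))
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(seq_along(nodes), find, 1L))) == 1L
}

#' Enumerate candidate partitions of a skeleton graph
#'
#' A possible worm is a simple connected path of skeleton edges; a
#' candidate set is a partition of all edges into one or two possible
#' worms (aggregates of more than two worms are out of scope: their
#' probability at 10-15 worms per plate is practically zero). Enumeration
#' is exhaustive over such partitions.
#'
#' @param graph a [SkeletonGraph-class].
#' @param maxEdges graphs with more edges raise a "skeleton too complex"
#'   error.
#' @return List of partitions; each partition is a list of integer edge
#'   index vectors (blocks ordered by smallest member, members sorted).
#' @examples
#' ## a 2-edge path has two candidate partitions: joined, or split
#' @export
enumeratePartitions <- function(graph, maxEdges = 12L) {
  nE <- length(graph@edges)
  if (nE == 0L) return(list())
  if (nE > maxEdges) skeletonTooComplex(nE, maxEdges)
  all <- seq_len(nE)
  out <- list()
  ## every unordered 2-partition has edge 1 in its first block; the full
  ## set as a single block is the complement-empty case
  rest <- all[-1]
  for (bits in 0:(2^(nE - 1L) - 1L)) {
    block1 <- c(1L, rest[bitwAnd(bits, 2^(seq_len(nE - 1L) - 1L)) > 0L])
    block2 <- setdiff(all, block1)
    if (!isPathBlock(block1, graph@edges)) next
    if (length(block2) == 0L) {
      out[[length(out) + 1L]] <- list(block1)
    } else if (isPathBlock(block2, graph@edges)) {
      out[[length(out) + 1L]] <- list(block1, block2)
    }
  }
  out
}

## Measured (length, width) of a possible worm: edge lengths add up along
## the path; the width is the length-weighted mean of edge widths.
measureBlock <- function(edgeIdx, edges) {
  ln <- vapply(edges[edgeIdx], function(e) e$length, 1)
  wd <- vapply(edges[edgeIdx], function(e) e$width, 1)
  L <- sum(ln)
  W <- if (L > 0) sum(wd * ln) / L else mean(wd)
  c(length = L, width = W)
}

#' Shape cost of a possible worm
#'
#' Euclidean distance between the measured (length, width) of a possible
#' worm and the theoretical worm shape.
#'
#' @param length,width measured dimensions in pixels.
#' @param model a [WormModel-class].
#' @return Non-negative cost.
#' @examples
#' m <- WormModel(theoreticalLength = 85, theoreticalWidth = 2.8)
#' wormCost(88, 6.8, m)   # off by (3, 4) -> 5
#' @export
wormCost <- function(length, width, model) {
  sqrt((length - model@theoreticalLength)^2 +
       (width - model@theoreticalWidth)^2)
}

#' Cost of a candidate set of possible worms
#'
#' The arithmetic mean of the member costs.
#'
#' @param costs numeric vector of per-worm costs (non-empty).
#' @return Mean cost.
#' @export
setCost <- function(costs) {
  if (length(costs) == 0L) stop("a candidate set must be non-empty")
  mean(costs)
}

## Deterministic canonical key for tie-breaking among partitions.
partitionKey <- function(partition) {
  paste(vapply(partition, function(b) paste(b, collapse = ","), ""),
        collapse = "|")
}

#' Select the minimum-cost partition of a skeleton graph
#'
#' Evaluates every candidate partition from [enumeratePartitions()] and
#' returns the one minimising the mean worm cost. Ties are broken in
#' favour of fewer worms (prefer not splitting), then by deterministic
#' lexicographic order of the canonical edge-index blocks.
#'
#' @param graph a [SkeletonGraph-class].
#' @param model a [WormModel-class].
#' @param maxEdges passed to [enumeratePartitions()].
#' @return List with elements \code{blocks} (the chosen partition),
#'   \code{cost}, and \code{measures} (per-block length/width matrix).
#' @export
selectPartition <- function(graph, model, maxEdges = model@maxSkeletonEdges) {
  parts <- enumeratePartitions(graph, maxEdges = maxEdges)
  if (length(parts) == 0L) {
    if (length(graph@edges) == 0L)
      stop("skeleton graph has no edges")
    skeletonTooComplex(length(graph@edges), maxEdges)
  }
  costs <- numeric(length(parts))
  sizes <- integer(length(parts))
  keys <- character(length(parts))
  for (i in seq_along(parts)) {
    ms <- vapply(parts[[i]], measureBlock, c(length = 1, width = 1),
                 edges = graph@edges)
    costs[i] <- setCost(wormCost(ms["length", ], ms["width", ], model))
    sizes[i] <- length(parts[[i]])
    keys[i] <- partitionKey(parts[[i]])
  }
  best <- order(costs, sizes, keys)[1]
  ms <- vapply(parts[[best]], measureBlock, c(length = 1, width = 1),
               edges = graph@edges)
  list(blocks = parts[[best]], cost = costs[best], measures = ms)
}

#' Disaggregate a blob into one or two worms
#'
#' Blobs small enough to be a single worm (area below
#' \code{aggregateMinArea}) are returned as-is. Larger blobs are thinned
#' to a skeleton graph and split by the minimum-cost partition into one or
#' two possible worms, each carrying its measured skeleton length and
#' width; blob pixels are attributed to the nearest block skeleton.
#'
#' @param blob a size-filtered [WormBlob-class].
#' @param model a [WormModel-class].
#' @param frame optional grayscale frame to recompute per-worm mean
#'   intensities of a split blob; without it, split worms inherit the blob
#'   mean.
#' @return List of 1 or 2 [WormBlob-class] objects.
#' @export
disaggregate <- function(blob, model = WormModel(), frame = NULL) {
  if (blob@area < model@aggregateMinArea) return(list(blob))
  graph <- buildSkeletonGraph(blob)
  graph <- pruneSkeletonGraph(graph,
                              minLen = max(3, 0.15 * model@theoreticalLength),
                              bridgeLen = 0.45 * model@theoreticalLength)
  if (length(graph@edges) == 0L) return(list(blob))
  sel <- selectPartition(graph, model)
  if (length(sel$blocks) == 1L) {
    blob@length <- sel$measures["length", 1]
    blob@width <- sel$measures["width", 1]
    return(list(blob))
  }
  ## assign every blob pixel to the nearest block skeleton pixel
  rc <- idxToRowCol(blob@pixels, blob@dim)
  skelFrame <- lapply(sel$blocks, function(b) {
    px <- do.call(rbind, lapply(graph@edges[b], function(e) e$pixels))
    cbind(px[, 1] + graph@offset[1], px[, 2] + graph@offset[2])
  })
  dists <- vapply(skelFrame, function(sp) {
    d2 <- outer(rc[, 1], sp[, 1], "-")^2 + outer(rc[, 2], sp[, 2], "-")^2
    apply(d2, 1, min)
  }, numeric(nrow(rc)))
  assign <- max.col(-dists, ties.method = "first")
  out <- vector("list", length(sel$blocks))
  for (k in seq_along(sel$blocks)) {
    px <- blob@pixels[assign == k]
    if (length(px) == 0L) px <- blob@pixels   # degenerate; keep whole blob
    rck <- idxToRowCol(px, blob@dim)
    out[[k]] <- new("WormBlob", pixels = as.integer(px), dim = blob@dim,
                    area = length(px),
                    centroid = c(mean(rck[, 1]), mean(rck[, 2])),
                    meanIntensity = if (is.null(frame)) blob@meanIntensity
                                    else mean(frame[px]),
                    length = sel$measures["length", k],
                    width = sel$measures["width", k],
                    frameIndex = blob@frameIndex)
  }
  out
}
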