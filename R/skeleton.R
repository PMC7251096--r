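## Topological skeletons: Zhang-Suen thinning and skeleton-graph
## extraction (endpoints, crosses, arcs with geodesic length and local
## width). Used by the two-worm disaggregation optimiser.

## Zhang-Suen binary thinning; `mask` logical/0-1 matrix, returns logical.
## Vectorised over the whole image with shifted copies of the mask.
thinSkeleton <- function(mask) {
  m <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      p2 <- shiftMat(m, 1, 0);  p3 <- shiftMat(m, 1, -1)
      p4 <- shiftMat(m, 0, -1); p5 <- shiftMat(m, -1, -1)
      p6 <- shiftMat(m, -1, 0); p7 <- shiftMat(m, -1, 1)
      p8 <- shiftMat(m, 0, 1);  p9 <- shiftMat(m, 1, 1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) +
           (p4 == 0 & p5 == 1) + (p5 == 0 & p6 == 1) +
           (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (pass == 1) {
        cond <- m == 1 & b >= 2 & b <= 6 & a == 1 &
          p2 * p4 * p6 == 0 & p4 * p6 * p8 == 0
      } else {
        cond <- m == 1 & b >= 2 & b <= 6 & a == 1 &
          p2 * p4 * p8 == 0 & p2 * p6 * p8 == 0
      }
      if (any(cond)) {
        m[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}

## Count of foreground 8-neighbours for every pixel.
neighbourCount <- function(m) {
  mi <- matrix(as.integer(m), nrow(m), ncol(m))
  shiftMat(mi, 1, 0) + shiftMat(mi, -1, 0) + shiftMat(mi, 0, 1) +
    shiftMat(mi, 0, -1) + shiftMat(mi, 1, 1) + shiftMat(mi, 1, -1) +
    shiftMat(mi, -1, 1) + shiftMat(mi, -1, -1)
}

## Order the pixels of a degree<=2 arc into a chain by walking from an end
## (or from an arbitrary pixel for a closed cycle). `pix` is n x 2.
orderChain <- function(pix) {
  n <- nrow(pix)
  if (n <= 2L) return(pix)
  adj <- vector("list", n)
  for (i in seq_len(n - 1)) {
    d <- pmax(abs(pix[(i + 1):n, 1] - pix[i, 1]),
              abs(pix[(i + 1):n, 2] - pix[i, 2]))
    nb <- which(d == 1L) + i
    for (j in nb) {
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  deg <- lengths(adj)
  start <- if (any(deg == 1L)) which(deg == 1L)[1] else 1L
  ord <- integer(n)
  visited <- logical(n)
  cur <- start
  for (k in seq_len(n)) {
    ord[k] <- cur
    visited[cur] <- TRUE
    nxt <- adj[[cur]][!visited[adj[[cur]]]]
    if (length(nxt) == 0L) break
    cur <- nxt[1]
  }
  pix[ord[ord > 0L], , drop = FALSE]
}

## Geodesic length of an ordered pixel chain (1 per axial step, sqrt(2)
## per diagonal step).
chainLength <- function(pix) {
  if (nrow(pix) <= 1L) return(as.numeric(nrow(pix) == 1L) * 0)
  sum(sqrt(rowSums((pix[-1, , drop = FALSE] -
                    pix[-nrow(pix), , drop = FALSE])^2)))
}

#' Build the skeleton graph of a blob
#'
#' Thins the blob to its topological skeleton and partitions it into nodes
#' (degree-1 endpoints and degree >= 3 crosses; adjacent cross pixels are
#' merged into one node to suppress thinning artefacts) and edges (arcs of
#' skeleton pixels between nodes). Every edge carries its geodesic length
#' (including the attachment steps to its nodes) and a local width, twice
#' the mean distance-transform value of the blob along the arc.
#'
#' A closed skeleton loop with no endpoint or cross is represented by one
#' virtual node with a single loop edge. A single-pixel skeleton yields a
#' one-node graph with no edges.
#'
#' @param blob a [WormBlob-class].
#' @return A [SkeletonGraph-class] in blob-crop coordinates.
#' @export
buildSkeletonGraph <- function(blob) {
  rc <- idxToRowCol(blob@pixels, blob@dim)
  r0 <- min(rc[, 1]) - 2L; c0 <- min(rc[, 2]) - 2L
  h <- max(rc[, 1]) - r0 + 2L; w <- max(rc[, 2]) - c0 + 2L
  mask <- matrix(FALSE, h, w)
  mask[cbind(rc[, 1] - r0, rc[, 2] - c0)] <- TRUE
  skel <- thinSkeleton(mask)
  dmap <- matrix(EBImage::distmap(matrix(as.numeric(mask), h, w)), h, w)
  emptyNodes <- data.frame(id = integer(), row = numeric(), col = numeric(),
                           type = character(), stringsAsFactors = FALSE)
  if (!any(skel))    # blob thinned away entirely (should not happen)
    return(new("SkeletonGraph", nodes = emptyNodes, edges = list(),
               dim = c(h, w), offset = c(r0, c0)))
  deg <- neighbourCount(skel)
  deg[!skel] <- -1L
  crossPix <- skel & deg >= 3L
  endPix <- skel & deg <= 1L   # includes isolated single-pixel skeletons
  ## node clusters: each endpoint its own node, crosses merged when adjacent
  nodes <- emptyNodes
  nodeLab <- matrix(0L, h, w)
  nid <- 0L
  if (any(crossPix)) {
    cl <- label8(crossPix)
    for (i in seq_len(max(cl))) {
      px <- which(cl == i, arr.ind = TRUE)
      nid <- nid + 1L
      nodes <- rbind(nodes, data.frame(id = nid, row = mean(px[, 1]),
                                       col = mean(px[, 2]), type = "cross",
                                       stringsAsFactors = FALSE))
      nodeLab[px] <- nid
    }
  }
  if (any(endPix)) {
    px <- which(endPix, arr.ind = TRUE)
    for (i in seq_len(nrow(px))) {
      nid <- nid + 1L
      nodes <- rbind(nodes, data.frame(id = nid, row = px[i, 1],
                                       col = px[i, 2], type = "end",
                                       stringsAsFactors = FALSE))
      nodeLab[px[i, 1], px[i, 2]] <- nid
    }
  }
  arcMask <- skel & nodeLab == 0L
  edges <- list()
  if (any(arcMask)) {
    arcs <- label8(arcMask)
    for (i in seq_len(max(arcs))) {
      pix <- which(arcs == i, arr.ind = TRUE)
      pix <- orderChain(pix)
      ## nodes adjacent to the chain ends (8-neighbourhood)
      endNodes <- integer(0)
      attachLen <- 0
      for (e in unique(c(1L, nrow(pix)))) {
        pr <- pix[e, 1]; pc <- pix[e, 2]
        win <- nodeLab[max(1, pr - 1):min(h, pr + 1),
                       max(1, pc - 1):min(w, pc + 1)]
        ids <- setdiff(unique(as.vector(win)), 0L)
        for (id in ids) {
          endNodes <- c(endNodes, id)
          attachLen <- attachLen + 1
        }
      }
      endNodes <- endNodes[seq_len(min(2L, length(endNodes)))]
      if (length(endNodes) == 0L) {
        ## closed loop: attach a virtual node at the first chain pixel
        nid <- nid + 1L
        nodes <- rbind(nodes, data.frame(id = nid, row = pix[1, 1],
                                         col = pix[1, 2], type = "cross",
                                         stringsAsFactors = FALSE))
        endNodes <- c(nid, nid)
        attachLen <- 0
      } else if (length(endNodes) == 1L) {
        endNodes <- c(endNodes, endNodes)
      }
      edges[[length(edges) + 1L]] <- list(
        from = endNodes[1], to = endNodes[2],
        pixels = pix,
        length = chainLength(pix) + attachLen,
        width = 2 * mean(dmap[pix]))
    }
  } else if (nrow(nodes) == 2L && nodes$type[1] == "end" &&
             nodes$type[2] == "end" &&
             max(abs(nodes$row[1] - nodes$row[2]),
                 abs(nodes$col[1] - nodes$col[2])) <= 1) {
    ## two adjacent endpoints, no arc pixels: a 2-pixel skeleton
    pix <- cbind(nodes$row, nodes$col)
    edges[[1]] <- list(from = 1L, to = 2L, pixels = pix,
                       length = chainLength(pix),
                       width = 2 * mean(dmap[pix]))
  }
  new("SkeletonGraph", nodes = nodes, edges = edges, dim = c(h, w),
      offset = c(r0, c0))
}

## Edge-incidence degree per node id (loops count twice).
nodeDegrees <- function(graph) {
  ids <- graph@nodes$id
  deg <- stats::setNames(integer(length(ids)), ids)
  for (e in graph@edges) {
    deg[as.character(e$from)] <- deg[as.character(e$from)] + 1L
    deg[as.character(e$to)] <- deg[as.character(e$to)] + 1L
  }
  deg
}

## TRUE if edge i's endpoints remain connected after removing it (i.e. the
## edge lies on a cycle); BFS over the remaining edges.
edgeOnCycle <- function(edges, i) {
  a <- edges[[i]]$from; b <- edges[[i]]$to
  rest <- edges[-i]
  reached <- a
  repeat {
    nxt <- unique(unlist(lapply(rest, function(e) {
      if (e$from %in% reached || e$to %in% reached) c(e$from, e$to)
      else NULL
    })))
    nxt <- union(reached, nxt)
    if (length(nxt) == length(reached)) break
    reached <- nxt
  }
  b %in% reached
}

#' Prune skeleton spurs and merge pass-through nodes
#'
#' Thinning a rasterised blob leaves short spur edges at crossings and
#' body bulges that inflate the partition search space and can make a true
#' two-worm crossing unpartitionable. Pruning iteratively removes terminal
#' edges shorter than \code{minLen} (while more than one edge remains) and
#' merges any node left with exactly two incident edges into a single
#' longer edge (lengths add; width is length-weighted).
#'
#' When two worms overlap along a stretch of body rather than at a point,
#' thinning yields two crosses joined by a bridge arc (the shared
#' stretch); bridges up to \code{bridgeLen} are contracted into a single
#' cross so the blob reads as one crossing.
#'
#' @param graph a [SkeletonGraph-class].
#' @param minLen spur length threshold in pixels.
#' @param bridgeLen maximum cross-to-cross bridge length to contract.
#' @return The pruned [SkeletonGraph-class].
#' @export
pruneSkeletonGraph <- function(graph, minLen = 4, bridgeLen = minLen) {
  repeat {
    changed <- FALSE
    deg <- nodeDegrees(graph)
    ## merge pass-through nodes (exactly two distinct incident edges)
    for (nid in graph@nodes$id) {
      if (is.na(deg[as.character(nid)]) || deg[as.character(nid)] != 2L) next
      inc <- which(vapply(graph@edges, function(e)
        e$from == nid || e$to == nid, TRUE))
      if (length(inc) != 2L) next               # a loop at this node
      e1 <- graph@edges[[inc[1]]]; e2 <- graph@edges[[inc[2]]]
      a <- if (e1$from == nid) e1$to else e1$from
      b <- if (e2$from == nid) e2$to else e2$from
      if (a == nid || b == nid) next            # loop component
      L <- e1$length + e2$length
      merged <- list(from = a, to = b,
                     pixels = rbind(e1$pixels, e2$pixels),
                     length = L,
                     width = (e1$width * e1$length + e2$width * e2$length) /
                       max(L, 1e-9))
      graph@edges[[inc[1]]] <- merged
      graph@edges <- graph@edges[-inc[2]]
      graph@nodes <- graph@nodes[graph@nodes$id != nid, , drop = FALSE]
      changed <- TRUE
      break
    }
    if (changed) next
    ## handle the shortest artefact edge: remove terminal spurs, tiny
    ## loops and redundant cycle arcs; contract short bridges between two
    ## crosses (a crossing split in two by thinning) into one cross
    if (length(graph@edges) > 1L) {
      lens <- vapply(graph@edges, function(e) e$length, 1)
      action <- vapply(seq_along(graph@edges), function(i) {
        e <- graph@edges[[i]]
        if (e$from != e$to &&
            deg[as.character(e$from)] >= 3L &&
            deg[as.character(e$to)] >= 3L &&
            lens[i] < bridgeLen) return("contract")
        if (lens[i] >= minLen) return("")
        if (e$from == e$to) return("remove")                 # tiny loop
        if (deg[as.character(e$from)] == 1L ||
            deg[as.character(e$to)] == 1L) return("remove")  # spur
        if (edgeOnCycle(graph@edges, i)) return("remove")    # parallel arc
        ""
      }, "")
      cand <- which(action != "")
      if (length(cand)) {
        i <- cand[which.min(lens[cand])]
        e <- graph@edges[[i]]
        if (action[i] == "contract") {
          a <- e$from; b <- e$to
          graph@edges <- lapply(graph@edges[-i], function(ed) {
            if (ed$from == b) ed$from <- a
            if (ed$to == b) ed$to <- a
            ed
          })
          graph@nodes <- graph@nodes[graph@nodes$id != b, , drop = FALSE]
        } else {
          graph@edges <- graph@edges[-i]
        }
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  keep <- graph@nodes$id %in% unlist(lapply(graph@edges,
                                            function(e) c(e$from, e$to)))
  if (length(graph@edges)) graph@nodes <- graph@nodes[keep, , drop = FALSE]
  graph
}
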