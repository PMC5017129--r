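# Morphological skeleton of a binary object by Zhang-Suen thinning, plus the
# skeleton statistics (calibrated length, branch-point count) used as shape
# descriptors.

shiftPad <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  si <- seq_len(nr) - di; sj <- seq_len(nc) - dj
  ok_i <- si >= 1L & si <= nr; ok_j <- sj >= 1L & sj <= nc
  out[ok_i, ok_j] <- m[si[ok_i], sj[ok_j]]
  out
}

# Crossing number per pixel: transitions 0 -> 1 when walking the 8
# neighbours in circular order. 1 = endpoint, 2 = path, >= 3 = junction.
# Robust against staircase double pixels, which inflate plain neighbour
# counts.
crossingNumber <- function(sk) {
  p2 <- shiftPad(sk, -1L, 0L);  p3 <- shiftPad(sk, -1L, 1L)
  p4 <- shiftPad(sk, 0L, 1L);   p5 <- shiftPad(sk, 1L, 1L)
  p6 <- shiftPad(sk, 1L, 0L);   p7 <- shiftPad(sk, 1L, -1L)
  p8 <- shiftPad(sk, 0L, -1L);  p9 <- shiftPad(sk, -1L, -1L)
  (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
    (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
}

# Remove terminal spurs of at most maxSteps pixels: walk inward from each
# endpoint; if a junction (crossing number >= 3) is reached within maxSteps,
# delete the walked pixels. Repeated until stable so nested twigs collapse
# too.
pruneSpurs <- function(sk, maxSteps) {
  if (maxSteps < 1L || sum(sk) < 3L) return(sk)
  nbrOffsets <- cbind(di = c(-1, -1, -1, 0, 0, 1, 1, 1),
                      dj = c(-1, 0, 1, -1, 1, -1, 0, 1))
  neighbours <- function(i, j) {
    ii <- i + nbrOffsets[, 1]; jj <- j + nbrOffsets[, 2]
    ok <- ii >= 1 & ii <= nrow(sk) & jj >= 1 & jj <= ncol(sk)
    cbind(ii, jj)[ok, , drop = FALSE][sk[cbind(ii, jj)[ok, , drop = FALSE]], ,
                                      drop = FALSE]
  }
  repeat {
    cn <- crossingNumber(sk)
    ends <- which(sk & cn == 1L, arr.ind = TRUE)
    removedAny <- FALSE
    for (e in seq_len(nrow(ends))) {
      path <- ends[e, , drop = FALSE]
      if (!sk[path]) next
      prev <- c(-1L, -1L)
      repeat {
        cur <- path[nrow(path), ]
        nb <- neighbours(cur[1], cur[2])
        nb <- nb[!(nb[, 1] == prev[1] & nb[, 2] == prev[2]), , drop = FALSE]
        if (nrow(path) > 1L) {
          p2 <- path[nrow(path) - 1L, ]
          nb <- nb[!(nb[, 1] == p2[1] & nb[, 2] == p2[2]), , drop = FALSE]
        }
        if (cn[cur[1], cur[2]] >= 3L) {
          # junction reached within the spur budget: drop the twig
          sk[path[-nrow(path), , drop = FALSE]] <- FALSE
          removedAny <- TRUE
          break
        }
        if (nrow(path) > maxSteps || nrow(nb) == 0L) break
        prev <- cur
        path <- rbind(path, nb[1, ])
      }
    }
    if (!removedAny) break
  }
  sk
}

#' Thin a binary mask to its skeleton
#'
#' Zhang-Suen iterative thinning: the classical two-subiteration scheme that
#' deletes border pixels while preserving 8-connectivity, leaving a
#' one-pixel-wide medial line.
#'
#' @param mask logical matrix.
#' @return logical matrix of the same size: the skeleton.
#' @examples
#' m <- matrix(FALSE, 9, 20); m[4:6, 3:18] <- TRUE
#' sum(thinMask(m))   # roughly the bar length in pixels
#' @export
thinMask <- function(mask) {
  stopifnot(is.logical(mask))
  m <- mask
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours P2..P9, clockwise from north (row-1)
      p2 <- shiftPad(m, -1L, 0L);  p3 <- shiftPad(m, -1L, 1L)
      p4 <- shiftPad(m, 0L, 1L);   p5 <- shiftPad(m, 1L, 1L)
      p6 <- shiftPad(m, 1L, 0L);   p7 <- shiftPad(m, 1L, -1L)
      p8 <- shiftPad(m, 0L, -1L);  p9 <- shiftPad(m, -1L, -1L)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (step == 1L) {
        cond <- !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      del <- m & B >= 2 & B <= 6 & A == 1 & cond
      if (any(del)) { m[del] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

#' Skeleton length and branch points of a binary object
#'
#' Thins the mask, then measures the skeleton's geodesic length as the total
#' weight of a minimum spanning tree over the skeleton-pixel adjacency graph
#' (unit weight for 4-neighbour steps, sqrt(2) for diagonal steps; the MST
#' drops the redundant diagonal shortcuts that raw adjacency counting would
#' double-count at staircase corners), plus a tip extension: thinning erodes
#' each end of an elongated object by about its local half-width, so the
#' Euclidean distance to the background at every skeleton leaf is added
#' back. Branch points are 8-connected clusters of skeleton pixels whose
#' circular-neighbourhood crossing number is three or more, i.e. where at
#' least three skeleton arms meet.
#'
#' Before measuring, short terminal spurs are pruned: thinning converts any
#' boundary roughness of the mask into sub-width side twigs that would
#' otherwise masquerade as branches. An endpoint whose path reaches a
#' junction within \code{pruneUm} is removed; genuine side branches are much
#' longer than the tube width and survive.
#'
#' @param mask logical matrix, one object.
#' @param pixelSize micrometres per pixel.
#' @param pruneUm terminal spurs shorter than this are removed (default
#'   0.35 um, about one tube radius plus discretization).
#' @return list: \code{lengthUm}, \code{branchPoints}, \code{skeleton}
#'   (logical matrix, after pruning).
#' @examples
#' m <- matrix(FALSE, 9, 30); m[4:6, 3:28] <- TRUE
#' skeletonStats(m, 0.1)$lengthUm
#' @export
skeletonStats <- function(mask, pixelSize = 0.1, pruneUm = 0.35) {
  sk <- pruneSpurs(thinMask(mask), maxSteps = ceiling(pruneUm / pixelSize))
  n <- sum(sk)
  # local half-width from the Euclidean distance map (distance to background;
  # pad so the object border is seen even on a tight crop)
  dm <- as.matrix(EBImage::distmap(rbind(0, cbind(0, mask * 1, 0), 0)))
  dm <- dm[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L), drop = FALSE]
  tipExt <- function(ij) sum(pmax(dm[ij] - 0.5, 0)) * pixelSize
  if (n <= 1L) {
    len <- if (n == 1L) tipExt(which(sk, arr.ind = TRUE)) * 2 else 0
    return(list(lengthUm = len, branchPoints = 0L, skeleton = sk))
  }
  idx <- which(sk, arr.ind = TRUE)
  id <- matrix(0L, nrow(sk), ncol(sk))
  id[sk] <- seq_len(n)
  edges <- NULL; weights <- NULL
  for (d in list(c(1L, 0L, 1), c(0L, 1L, 1), c(1L, 1L, sqrt(2)),
                 c(1L, -1L, sqrt(2)))) {
    nb <- idx
    nb[, 1] <- nb[, 1] + d[1]; nb[, 2] <- nb[, 2] + d[2]
    ok <- nb[, 1] >= 1 & nb[, 1] <= nrow(sk) &
      nb[, 2] >= 1 & nb[, 2] <= ncol(sk)
    ok[ok] <- sk[nb[ok, , drop = FALSE]]
    if (any(ok)) {
      edges <- rbind(edges, cbind(id[idx[ok, , drop = FALSE]],
                                  id[nb[ok, , drop = FALSE]]))
      weights <- c(weights, rep(d[3], sum(ok)))
    }
  }
  len <- 0
  if (!is.null(edges)) {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    igraph::E(g)$weight <- weights
    tree <- igraph::mst(g)
    len <- sum(igraph::E(tree)$weight) * pixelSize
    leaves <- which(igraph::degree(tree) == 1L)
    len <- len + tipExt(idx[leaves, , drop = FALSE])
  }
  branch <- sk & crossingNumber(sk) >= 3
  nb <- if (any(branch)) max(.label8(branch)) else 0L
  list(lengthUm = len, branchPoints = as.integer(nb), skeleton = sk)
}
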