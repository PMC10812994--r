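# Connected-component labeling of suprathreshold voxel sets.
#
# Works on the linear indices of a logical 3D array. Connectivity is the
# usual 6 (faces), 18 (faces+edges) or 26 (faces+edges+corners)
# neighborhood; 26 is the package default for cluster inference.

neighbor_offsets <- function(connectivity = 26L) {
  stopifnot(connectivity %in% c(6L, 18L, 26L))
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  ord <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord <= 2, "26" = rep(TRUE, nrow(g)))
  as.matrix(g[keep, , drop = FALSE])
}

#' Label connected components of a logical 3D array
#'
#' Deterministic labeling: components are numbered by the smallest linear
#' array index they contain, so the result does not depend on traversal
#' order.
#'
#' @param flag Logical 3D array.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return Integer 3D array; 0 outside components, 1..k inside, plus an
#'   attribute `sizes` with component voxel counts.
#' @export
label_clusters <- function(flag, connectivity = 26L) {
  d <- dim(flag)
  stopifnot(length(d) == 3L)
  labels <- array(0L, dim = d)
  idx <- which(flag)
  if (!length(idx)) return(structure(labels, sizes = integer(0)))
  off <- neighbor_offsets(as.integer(connectivity))
  coords <- arrayInd(idx, d)
  # map linear index -> position in idx for O(1) membership tests
  lut <- integer(prod(d))
  lut[idx] <- seq_along(idx)
  comp <- integer(length(idx))  # 0 = unvisited
  ncomp <- 0L
  sizes <- integer(0)
  for (s in seq_along(idx)) {
    if (comp[s] != 0L) next
    ncomp <- ncomp + 1L
    queue <- s
    comp[s] <- ncomp
    size <- 0L
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      size <- size + length(cur)
      cc <- coords[cur, , drop = FALSE]
      for (o in seq_len(nrow(off))) {
        nb <- cc
        nb[, 1] <- nb[, 1] + off[o, 1]
        nb[, 2] <- nb[, 2] + off[o, 2]
        nb[, 3] <- nb[, 3] + off[o, 3]
        ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] &
              nb[, 2] >= 1L & nb[, 2] <= d[2] &
              nb[, 3] >= 1L & nb[, 3] <= d[3]
        if (!any(ok)) next
        lin <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1L) +
               d[1] * d[2] * (nb[ok, 3] - 1L)
        pos <- lut[lin]
        pos <- pos[pos != 0L]
        pos <- pos[comp[pos] == 0L]
        if (length(pos)) {
          comp[pos] <- ncomp
          queue <- c(queue, pos)
        }
      }
      queue <- unique(queue)
    }
    sizes <- c(sizes, size)
  }
  labels[idx] <- comp
  structure(labels, sizes = sizes)
}

# Max cluster extent of a logical 3D array (fast path for simulations).
max_cluster_extent <- function(flag, connectivity = 26L) {
  n <- sum(flag)
  if (n == 0L) return(0L)
  if (n == 1L) return(1L)
  sizes <- attr(label_clusters(flag, connectivity), "sizes")
  max(sizes)
}
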