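# Neighbor-joining from a distance matrix.

#' Neighbor-joining tree from a p-distance matrix
#'
#' Saitou-Nei agglomeration: at each step the pair minimizing
#' `Q(i,j) = (r-2) d(i,j) - R(i) - R(j)` is joined (ties broken
#' deterministically by the lowest index pair in scan order), branch lengths
#' are `d(i,j)/2 +- (R(i)-R(j)) / (2(r-2))`, and distances to the new node
#' are `(d(i,k) + d(j,k) - d(i,j)) / 2`. Negative branch lengths are clamped
#' to zero with the deficit compensated on the sibling branch so path
#' lengths through the join are preserved. On an additive matrix the
#' generating topology and branch lengths are recovered exactly.
#'
#' @param d square symmetric distance matrix (>= 3 taxa) with zero diagonal;
#'   rownames become tip labels.
#' @return An unrooted `phylo` tree (ape format) with branch lengths.
#' @export
#' @examples
#' d <- matrix(c(0, 5, 9, 9, 5, 0, 10, 10, 9, 10, 0, 8, 9, 10, 8, 0), 4, 4)
#' rownames(d) <- colnames(d) <- letters[1:4]
#' tr <- neighbor_joining(d)
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stopf("need at least 3 taxa")
  if (ncol(d) != n) stopf("distance matrix must be square")
  if (anyNA(d) || any(!is.finite(d))) stopf("distances must be finite")
  if (max(abs(d - t(d))) > 1e-12) stopf("distance matrix must be symmetric")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))

  active <- seq_len(n)        # phylo node ids of active clusters
  D <- d
  next_internal <- 2L * n - 2L
  edge <- matrix(0L, 0L, 2L)
  elen <- numeric(0)

  while (length(active) > 3L) {
    r <- length(active)
    R <- rowSums(D)
    # lowest-index-pair tie break: scan i<j in order, keep first strict min
    best <- c(NA_integer_, NA_integer_)
    bestQ <- Inf
    for (i in seq_len(r - 1L)) {
      Qi <- (r - 2) * D[i, (i + 1L):r] - R[i] - R[(i + 1L):r]
      k <- which.min(Qi)
      if (Qi[k] < bestQ - 1e-12) {
        bestQ <- Qi[k]
        best <- c(i, i + k)
      }
    }
    i <- best[1L]; j <- best[2L]
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- D[i, j]; li <- 0 }
    if (lj < 0) { li <- D[i, j]; lj <- 0 }
    u <- next_internal
    next_internal <- next_internal - 1L
    edge <- rbind(edge, c(u, active[i]), c(u, active[j]))
    elen <- c(elen, li, lj)
    newd <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    active <- c(active[keep], u)
  }

  # final trifurcation at node n+1
  u <- n + 1L
  x <- active[1L]; y <- active[2L]; z <- active[3L]
  lx <- max(0, (D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  ly <- max(0, (D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  lz <- max(0, (D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  edge <- rbind(edge, c(u, x), c(u, y), c(u, z))
  elen <- c(elen, lx, ly, lz)

  tree <- structure(
    list(edge = edge, edge.length = elen, tip.label = labels,
         Nnode = n - 2L),
    class = "phylo", order = NULL
  )
  ape::reorder.phylo(tree, "cladewise")
}
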