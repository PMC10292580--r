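# k-means over fragment embeddings in latent Euclidean space, plus the
# second clustering pass on the fragments left over after high-scoring
# precursor-fragment pairs are removed.
#
# Implemented as explicit Lloyd iterations with k-means++ seeding so the
# contract is fully specified: inertia is asserted nonincreasing per
# iteration, equidistant points go to the lowest-index centroid, and empty
# clusters are re-seeded at the point farthest from its assigned centroid.

#' k-means clustering of embeddings
#'
#' @param embeddings numeric matrix, one embedding per row.
#' @param k number of clusters, `1 <= k <= nrow(embeddings)`.
#' @param seed RNG seed for the k-means++ initialization; the same seed
#'   yields an identical assignment.
#' @param maxIter iteration cap (default 100).
#' @param tol convergence threshold on the maximum centroid shift
#'   (default 1e-6).
#' @return list of class `ClusterAssignment`: `labels` (1..k per row),
#'   `centroids` (k x d), `inertia` (total within-cluster sum of squares),
#'   `iterations`.
#' @export
kmeansCluster <- function(embeddings, k, seed = 1, maxIter = 100,
                          tol = 1e-6) {
  X <- asMatrixRow(embeddings)
  n <- nrow(X)
  if (k < 1 || k > n) stop("k must be in [1, number of points]")
  set.seed(seed)
  centroids <- kppInit(X, k)
  prevInertia <- Inf
  labels <- integer(n)
  for (it in seq_len(maxIter)) {
    D <- distToCentroids(X, centroids)
    labels <- max.col(-D, ties.method = "first")
    # re-seed empty clusters at the farthest point from its centroid
    for (c in which(tabulate(labels, k) == 0L)) {
      far <- which.max(D[cbind(seq_len(n), labels)])
      centroids[c, ] <- X[far, ]
      D <- distToCentroids(X, centroids)
      labels <- max.col(-D, ties.method = "first")
    }
    inertia <- sum(D[cbind(seq_len(n), labels)])
    stopifnot(inertia <= prevInertia + 1e-8 * max(1, prevInertia))
    newC <- centroids
    for (c in seq_len(k)) {
      m <- labels == c
      if (any(m)) newC[c, ] <- colMeans(X[m, , drop = FALSE])
    }
    shift <- max(abs(newC - centroids))
    centroids <- newC
    prevInertia <- inertia
    if (shift < tol) break
  }
  D <- distToCentroids(X, centroids)
  labels <- max.col(-D, ties.method = "first")
  structure(list(labels = labels, centroids = centroids,
                 inertia = sum(D[cbind(seq_len(n), labels)]),
                 iterations = it),
            class = "ClusterAssignment")
}

# squared Euclidean distances, n x k
distToCentroids <- function(X, C) {
  xx <- rowSums(X^2)
  cc <- rowSums(C^2)
  D <- outer(xx, cc, "+") - 2 * tcrossprod(X, C)
  pmax(D, 0)
}

# k-means++ seeding (uses the current RNG stream)
kppInit <- function(X, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- rowSums((X - rep(X[idx[1], ], each = n))^2)
    for (j in 2:k) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      idx[j] <- sample.int(n, 1L, prob = p)
      d2 <- pmin(d2, rowSums((X - rep(X[idx[j], ], each = n))^2))
    }
  }
  X[idx, , drop = FALSE]
}

#' Second clustering pass on unassigned fragments
#'
#' Removes the fragments of accepted precursor-fragment pairs and clusters
#' the remainder again. `k2` is clamped to `[1, remaining]`; an empty
#' remainder yields an empty assignment.
#'
#' @param embeddings full embedding matrix of the slider's fragments.
#' @param accepted integer ids (row indexes) of fragments already assigned.
#' @param k2 target cluster count for the remainder (e.g. number of
#'   unmatched precursors).
#' @param seed RNG seed.
#' @return list with `assignment` (a `ClusterAssignment` or NULL when the
#'   remainder is empty) and `ids` mapping assignment rows back to original
#'   fragment ids.
#' @export
secondPassCluster <- function(embeddings, accepted, k2, seed = 1) {
  X <- asMatrixRow(embeddings)
  ids <- setdiff(seq_len(nrow(X)), accepted)
  if (!length(ids)) return(list(assignment = NULL, ids = integer()))
  k2 <- max(1L, min(as.integer(k2), length(ids)))
  list(assignment = kmeansCluster(X[ids, , drop = FALSE], k2, seed = seed),
       ids = ids)
}
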