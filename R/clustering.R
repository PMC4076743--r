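# Clustering routines producing parcellations of the voxel domain.
# Convention: feature matrices are stored features-in-rows, voxels-in-
# columns (like the signal matrix Y); internally the clusterers work on
# the transposed Q x m "points" layout.

# Accepts parcel_signal, reduced_features or a plain features x voxels
# matrix and returns voxels-in-rows points.
feature_points <- function(x) {
  if (inherits(x, "parcel_signal")) return(t(x$values))
  if (inherits(x, "reduced_features")) return(t(x$values))
  if (is.matrix(x)) return(t(x))
  stop_bad_arg("unsupported feature input of class '%s'", class(x)[1])
}

#' Parcellation of a voxel domain
#'
#' @param labels integer vector assigning each voxel to a parcel; values
#'   are canonicalized to 1..K in order of first occurrence.
#' @param centroids optional K x m matrix of per-parcel mean feature
#'   vectors.
#' @param method character tag of the producing algorithm.
#' @param connected logical: does the algorithm guarantee spatially
#'   connected parcels?
#'
#' @return An object of class `parcellation` with elements `labels`, `K`,
#'   `centroids`, `method`, `connected`.
#' @export
new_parcellation <- function(labels, centroids = NULL, method = "manual",
                             connected = FALSE) {
  labels <- relabel_first_occurrence(as.integer(labels))
  structure(
    list(labels = labels, K = length(unique(labels)),
         centroids = centroids, method = method, connected = connected),
    class = "parcellation"
  )
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation> %d voxels in %d parcels (%s%s)\n",
              length(x$labels), x$K, x$method,
              if (isTRUE(x$connected)) ", connected" else ""))
  invisible(x)
}

#' @describeIn new_parcellation one row per voxel with its parcel label.
#' @param x a `parcellation`.
#' @param ... unused.
#' @export
tidy.parcellation <- function(x, ...) {
  tibble(voxel = seq_along(x$labels), parcel = x$labels)
}

# Per-parcel means of the supplied features (Eq. 2 centroids).
parcel_centroids <- function(points, labels) {
  counts <- tabulate(labels, max(labels))
  rowsum(points, labels) / counts
}

#' Reduce a signal matrix by PCA over voxels
#'
#' Principal-component reduction of the voxel feature vectors (voxels as
#' samples, the n images as features), used before k-means and Ward
#' clustering. `m` is silently capped at the matrix rank bound
#' `min(n, Q)`.
#'
#' @param signal a [parcel_signal()] or a features x voxels matrix.
#' @param m number of components to retain (default 100).
#'
#' @return An object of class `reduced_features`: list with `values`
#'   (m x Q score matrix), `m`, `explained_variance_fraction`.
#' @export
pca_reduce <- function(signal, m = 100L) {
  if (m < 1) stop_bad_arg("`m` must be at least 1")
  X <- feature_points(signal)   # Q x n
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  m_eff <- min(m, ncol(pc$x))
  total <- sum(pc$sdev^2)
  frac <- if (total > 0) sum(pc$sdev[seq_len(m_eff)]^2) / total else 1
  structure(
    list(values = t(pc$x[, seq_len(m_eff), drop = FALSE]),
         m = m_eff,
         explained_variance_fraction = frac),
    class = "reduced_features"
  )
}

#' @export
print.reduced_features <- function(x, ...) {
  cat(sprintf(
    "<reduced_features> %d components x %d voxels (%.1f%% variance)\n",
    x$m, ncol(x$values), 100 * x$explained_variance_fraction))
  invisible(x)
}

# ---- k-means (Lloyd iterations, k-means++ seeding) -----------------------

kmeanspp_centers <- function(X, xx, K) {
  n <- nrow(X)
  centers <- integer(K)
  centers[1] <- sample.int(n, 1L)
  if (K > 1L) {
    c1 <- centers[1]
    d2 <- pmax(xx + xx[c1] - 2 * as.vector(X %*% X[c1, ]), 0)
    for (k in 2:K) {
      if (all(d2 <= 0)) {
        centers[k] <- sample.int(n, 1L)
      } else {
        centers[k] <- sample.int(n, 1L, prob = d2)
      }
      ck <- centers[k]
      d2 <- pmin(d2, pmax(xx + xx[ck] - 2 * as.vector(X %*% X[ck, ]), 0))
    }
  }
  X[centers, , drop = FALSE]
}

# One Lloyd run from a given centroid matrix; exactly K non-empty
# clusters are maintained by reseeding an empty cluster at the point
# currently farthest from its assigned centroid.
lloyd_once <- function(X, xx, C, max_iter = 100L) {
  n <- nrow(X)
  K <- nrow(C)
  assign_old <- integer(n)
  D <- NULL
  for (iter in seq_len(max_iter)) {
    # squared distances minus the constant xx term (irrelevant for argmin)
    D <- matrix(rowSums(C^2), n, K, byrow = TRUE) - 2 * tcrossprod(X, C)
    assign <- max.col(-D, ties.method = "first")
    empty <- setdiff(seq_len(K), unique(assign))
    if (length(empty) > 0) {
      cur <- D[cbind(seq_len(n), assign)] + xx
      for (k in empty) {
        j <- which.max(cur)
        assign[j] <- k
        cur[j] <- -Inf
      }
    }
    if (identical(assign, assign_old)) break
    assign_old <- assign
    C <- rowsum(X, assign) / tabulate(assign, K)
  }
  inertia <- sum(pmax(D[cbind(seq_len(n), assign)] + xx, 0))
  list(assign = assign, centers = C, inertia = inertia)
}

# Best-of-n_init Lloyd k-means; deterministic given the RNG state.
kmeans_lloyd <- function(X, K, n_init = 10L, max_iter = 100L) {
  n <- nrow(X)
  if (K > n) stop_bad_arg("K (%d) exceeds the number of points (%d)", K, n)
  if (K == n) {
    return(list(assign = seq_len(n), centers = X, inertia = 0))
  }
  xx <- rowSums(X^2)
  best <- NULL
  for (s in seq_len(n_init)) {
    fit <- lloyd_once(X, xx, kmeanspp_centers(X, xx, K), max_iter)
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  best
}

#' K-means parcellation of the functional features
#'
#' Alternates nearest-centroid assignment and centroid re-estimation
#' (Lloyd iterations) on the voxel feature vectors, with k-means++
#' seeding and `n_init` restarts keeping the lowest-inertia solution.
#' The result is not guaranteed spatially connected.
#'
#' @param features a [pca_reduce()] result, a [parcel_signal()], or a
#'   features x voxels matrix.
#' @param K number of parcels.
#' @param seed optional integer seed (result is deterministic given it).
#' @param n_init number of random restarts.
#'
#' @return A [new_parcellation()] with the achieved inertia in
#'   `$inertia`.
#' @export
kmeans_parcellation <- function(features, K, seed = NULL, n_init = 10L) {
  X <- feature_points(features)
  if (K > nrow(X))
    stop_bad_arg("K (%d) exceeds the number of voxels (%d)", K, nrow(X))
  fit <- with_seed_if(seed, kmeans_lloyd(X, K, n_init = n_init))
  out <- new_parcellation(fit$assign, method = "kmeans", connected = FALSE)
  out$centroids <- parcel_centroids(X, out$labels)
  out$inertia <- fit$inertia
  out
}

# ---- spatially constrained Ward agglomeration ----------------------------

#' Ward merge cost between two clusters
#'
#' The increase in within-cluster sum of squares caused by merging two
#' clusters, in closed form:
#' \deqn{\Delta(c_1, c_2) = \frac{|c_1||c_2|}{|c_1|+|c_2|}
#'   \lVert \langle Y\rangle_{c_1} - \langle Y\rangle_{c_2} \rVert^2}
#'
#' @param size1,size2 cluster sizes (positive).
#' @param centroid1,centroid2 numeric centroid vectors.
#' @return The scalar merge cost.
#' @export
#' @examples
#' ward_merge_cost(1, 0, 1, 2)  # 2
ward_merge_cost <- function(size1, centroid1, size2, centroid2) {
  if (size1 <= 0 || size2 <= 0)
    stop_bad_arg("cluster sizes must be positive")
  size1 * size2 / (size1 + size2) * sum((centroid1 - centroid2)^2)
}

#' Spatially constrained Ward merge tree
#'
#' Agglomerative variance-minimizing clustering in which only clusters
#' sharing at least one adjacency edge may merge. At each step the
#' adjacent pair with the smallest Ward cost is merged (ties broken by the
#' lexicographically smallest cluster-index pair). The full tree is built
#' once and can be cut at any K with [cut_ward()].
#'
#' @param features a [pca_reduce()] result, [parcel_signal()], or a
#'   features x voxels matrix.
#' @param adjacency a [grid_adjacency()] graph over the same voxels.
#'
#' @return An object of class `ward_tree`: list with `merges`
#'   ((Q-1) x 2 matrix of merged cluster ids, hclust-style ids Q+1..2Q-1
#'   for internal nodes), `heights` (merge costs), `Q`, `n_components`.
#' @export
ward_tree <- function(features, adjacency) {
  X <- feature_points(features)
  Q <- nrow(X)
  if (adjacency$n_vertices != Q)
    stop_bad_arg("adjacency covers %d voxels but features have %d",
                 adjacency$n_vertices, Q)
  m <- ncol(X)
  n_nodes <- 2L * Q - 1L

  size <- numeric(n_nodes)
  size[seq_len(Q)] <- 1
  cent <- matrix(0, nrow = n_nodes, ncol = m)
  cent[seq_len(Q), ] <- X
  active <- c(rep(TRUE, Q), rep(FALSE, Q - 1L))

  e <- adjacency$edges
  nb <- vector("list", n_nodes)
  nb[seq_len(Q)] <- split(c(e[, 2L], e[, 1L]),
                          factor(c(e[, 1L], e[, 2L]), levels = seq_len(Q)))

  cap <- max(4L * nrow(e), 64L)
  pa <- integer(cap); pb <- integer(cap); pcost <- rep(Inf, cap)
  np <- 0L
  pairs_of <- vector("list", n_nodes)

  add_pairs <- function(i, js) {
    k <- length(js)
    if (k == 0L) return(invisible())
    while (np + k > cap) {
      cap <<- 2L * cap
      pa <<- c(pa, integer(cap - length(pa)))
      pb <<- c(pb, integer(cap - length(pb)))
      pcost <<- c(pcost, rep(Inf, cap - length(pcost)))
    }
    w <- size[i] * size[js] / (size[i] + size[js])
    d2 <- colSums((t(cent[js, , drop = FALSE]) - cent[i, ])^2)
    idx <- np + seq_len(k)
    pa[idx] <<- i
    pb[idx] <<- js
    pcost[idx] <<- w * d2
    np <<- np + k
    pairs_of[[i]] <<- c(pairs_of[[i]], idx)
    for (t in seq_len(k)) {
      pairs_of[[js[t]]] <<- c(pairs_of[[js[t]]], idx[t])
    }
    invisible()
  }
  for (v in seq_len(Q)) {
    js <- nb[[v]]
    add_pairs(v, js[js > v])
  }

  merges <- matrix(0L, nrow = Q - 1L, ncol = 2L)
  heights <- numeric(Q - 1L)
  n_merged <- 0L

  for (t in seq_len(Q - 1L)) {
    if (np == 0L) break
    live <- pcost[seq_len(np)]
    idx <- which.min(live)
    v <- live[idx]
    if (!is.finite(v)) break  # disconnected: no mergeable pair left
    ties <- which(live == v)
    if (length(ties) > 1L) {
      lo <- pmin(pa[ties], pb[ties])
      hi <- pmax(pa[ties], pb[ties])
      idx <- ties[order(lo, hi)][1L]
    }
    a <- pa[idx]; b <- pb[idx]
    new_id <- Q + t
    merges[t, ] <- c(a, b)
    heights[t] <- v
    n_merged <- t

    size[new_id] <- size[a] + size[b]
    cent[new_id, ] <- (size[a] * cent[a, ] + size[b] * cent[b, ]) /
      size[new_id]
    active[c(a, b)] <- FALSE
    active[new_id] <- TRUE

    dead <- unique(c(pairs_of[[a]], pairs_of[[b]]))
    pcost[dead] <- Inf
    pairs_of[a] <- list(integer(0))
    pairs_of[b] <- list(integer(0))

    nbs <- unique(c(nb[[a]], nb[[b]]))
    nbs <- nbs[active[nbs]]
    nb[[new_id]] <- nbs
    for (k in nbs) nb[[k]] <- c(nb[[k]], new_id)
    add_pairs(new_id, nbs)
  }

  structure(
    list(merges = merges, heights = heights, Q = Q,
         n_components = Q - n_merged),
    class = "ward_tree"
  )
}

#' Cut a Ward merge tree at K clusters
#'
#' Replays the first Q - K merges and returns the resulting labeling.
#'
#' @param tree a [ward_tree()].
#' @param K number of clusters, between the number of connected
#'   components of the adjacency graph and Q.
#' @return Integer labels 1..K over voxels.
#' @export
cut_ward <- function(tree, K) {
  Q <- tree$Q
  if (K > Q) stop_bad_arg("K (%d) exceeds the number of voxels (%d)", K, Q)
  if (K < tree$n_components)
    stop_bad_arg(paste0(
      "the adjacency graph has %d connected components; ",
      "cannot merge below K = %d"), tree$n_components, tree$n_components)
  n_merges <- Q - K
  parent <- integer(2L * Q - 1L)
  for (t in seq_len(n_merges)) {
    parent[tree$merges[t, ]] <- Q + t
  }
  roots <- seq_len(Q)
  for (v in seq_len(Q)) {
    r <- v
    while (parent[r] != 0L) r <- parent[r]
    roots[v] <- r
  }
  relabel_first_occurrence(roots)
}

#' Spatially constrained Ward parcellation
#'
#' Builds the constrained merge tree with [ward_tree()] and cuts it at K,
#' yielding exactly K spatially connected parcels.
#'
#' @inheritParams ward_tree
#' @param K number of parcels.
#' @return A [new_parcellation()] with `connected = TRUE`.
#' @export
ward_parcellation <- function(features, adjacency, K) {
  tree <- ward_tree(features, adjacency)
  labels <- cut_ward(tree, K)
  out <- new_parcellation(labels, method = "ward", connected = TRUE)
  out$centroids <- parcel_centroids(feature_points(features), out$labels)
  out
}

# ---- geometric clustering ------------------------------------------------

#' Geometric (signal-free) parcellation
#'
#' K-means clustering of the voxel spatial coordinates only; the result is
#' independent of the functional signal and serves as a reference for
#' comparison.
#'
#' @param x a [parcel_signal()] (its coordinates are used) or a Q x d
#'   coordinate matrix.
#' @param K number of parcels.
#' @param seed optional integer seed.
#' @param n_init number of k-means restarts.
#' @return A [new_parcellation()].
#' @export
geometric_parcellation <- function(x, K, seed = NULL, n_init = 10L) {
  coords <- if (inherits(x, "parcel_signal")) x$coords else as.matrix(x)
  storage.mode(coords) <- "double"
  if (K > nrow(coords))
    stop_bad_arg("K (%d) exceeds the number of voxels (%d)", K, nrow(coords))
  fit <- with_seed_if(seed, kmeans_lloyd(coords, K, n_init = n_init))
  out <- new_parcellation(fit$assign, method = "geometric",
                          connected = FALSE)
  out$centroids <- parcel_centroids(coords, out$labels)
  out$inertia <- fit$inertia
  out
}
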