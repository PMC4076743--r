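# Spectral clustering on the functionally weighted voxel adjacency graph.

#' Functionally weighted affinity graph
#'
#' Weights each adjacency edge by the similarity of the voxel feature
#' vectors: `W_ij = exp(-||y_i - y_j||^2 / sigma_f^2)` for neighbors,
#' 0 otherwise, with `sigma_f^2` the mean squared feature distance over
#' all adjacent pairs.
#'
#' @param signal a [parcel_signal()] or a features x voxels matrix.
#' @param adjacency a [grid_adjacency()] graph over the same voxels.
#'
#' @return An object of class `affinity_graph`: list with `edges`,
#'   `weights` (per edge, in (0, 1]), `sigma_f2`, `degree` (row sums of
#'   W), `Q`.
#' @export
spectral_affinity <- function(signal, adjacency) {
  Y <- if (inherits(signal, "parcel_signal")) signal$values
       else as.matrix(signal)
  Q <- ncol(Y)
  if (adjacency$n_vertices != Q)
    stop_bad_arg("adjacency covers %d voxels but the signal has %d",
                 adjacency$n_vertices, Q)
  e <- adjacency$edges
  if (nrow(e) == 0L) stop_bad_arg("adjacency graph has no edges")
  d2 <- colSums((Y[, e[, 1L], drop = FALSE] -
                   Y[, e[, 2L], drop = FALSE])^2)
  sigma_f2 <- mean(d2)
  if (sigma_f2 <= 0)
    stop_bad_arg(paste0("degenerate input: all neighboring voxels are ",
                        "identical (sigma_f^2 = 0)"))
  w <- exp(-d2 / sigma_f2)
  degree <- as.vector(rowsum(c(w, w), c(e[, 1L], e[, 2L]))) # every voxel
  # rowsum drops absent groups; rebuild a dense degree vector
  deg <- numeric(Q)
  grp <- sort(unique(c(e[, 1L], e[, 2L])))
  deg[grp] <- degree
  structure(
    list(edges = e, weights = w, sigma_f2 = sigma_f2, degree = deg, Q = Q),
    class = "affinity_graph"
  )
}

#' @export
print.affinity_graph <- function(x, ...) {
  cat(sprintf("<affinity_graph> %d voxels, %d weighted edges, sigma_f2 = %.4g\n",
              x$Q, length(x$weights), x$sigma_f2))
  invisible(x)
}

#' Spectral embedding of an affinity graph
#'
#' Solves the generalized eigenproblem `W xi = lambda D_W xi` (random-walk
#' normalization) and returns the `m` eigenvectors of largest eigenvalue,
#' including the trivial constant one with lambda = 1. Computed through
#' the symmetric normalization `D^{-1/2} W D^{-1/2}`; eigenvector signs
#' are fixed so each column's largest-magnitude entry is positive.
#'
#' @param affinity an [spectral_affinity()] graph; must be connected.
#' @param m number of eigenvectors, capped at Q - 1.
#'
#' @return List with `vectors` (Q x m matrix of generalized eigenvectors)
#'   and `values` (eigenvalues, non-increasing, all within unit
#'   magnitude).
#' @export
spectral_embedding <- function(affinity, m = 100L) {
  Q <- affinity$Q
  e <- affinity$edges
  comp <- graph_components(Q, e)
  if (length(unique(comp)) > 1L)
    stop_bad_arg(paste0("affinity graph is disconnected; ",
                        "process each connected component separately"))
  m <- min(m, Q - 1L)
  d <- affinity$degree
  S <- matrix(0, Q, Q)
  S[cbind(e[, 1L], e[, 2L])] <- affinity$weights
  S[cbind(e[, 2L], e[, 1L])] <- affinity$weights
  inv_sqrt_d <- 1 / sqrt(d)
  S <- S * tcrossprod(inv_sqrt_d)
  es <- eigen(S, symmetric = TRUE)
  keep <- seq_len(m)
  vec <- es$vectors[, keep, drop = FALSE] * inv_sqrt_d
  # deterministic sign convention
  for (j in seq_len(ncol(vec))) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  list(vectors = vec, values = es$values[keep])
}

#' Spectral parcellation
#'
#' K-means clustering of the voxels in the spectral embedding of the
#' functionally weighted adjacency graph. By default the embedding uses
#' as many eigenvectors as clusters, capped at 100 (the convention of
#' standard spectral-clustering implementations): eigenvectors beyond the
#' leading ones carry increasingly fine oscillations that drown the
#' cluster structure when K is small.
#'
#' @param signal a [parcel_signal()] or features x voxels matrix.
#' @param adjacency a [grid_adjacency()] graph.
#' @param K number of parcels.
#' @param m embedding dimension; `NULL` (default) uses `min(K, 100)`.
#'   Always capped at Q - 1.
#' @param seed optional integer seed for the k-means stage.
#' @param n_init number of k-means restarts.
#' @return A [new_parcellation()].
#' @export
spectral_parcellation <- function(signal, adjacency, K, m = NULL,
                                  seed = NULL, n_init = 10L) {
  if (is.null(m)) m <- min(K, 100L)
  aff <- spectral_affinity(signal, adjacency)
  if (K > aff$Q)
    stop_bad_arg("K (%d) exceeds the number of voxels (%d)", K, aff$Q)
  emb <- spectral_embedding(aff, m)
  fit <- with_seed_if(seed, kmeans_lloyd(emb$vectors, K, n_init = n_init))
  out <- new_parcellation(fit$assign, method = "spectral",
                          connected = FALSE)
  out$centroids <- parcel_centroids(feature_points(signal), out$labels)
  out$inertia <- fit$inertia
  out
}
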