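# A small specification object describing how to turn a signal into a
# labeling, shared by cross-validation, bootstrap stability and the
# model-selection experiment.

#' Clustering method specification
#'
#' Bundles a clustering algorithm with its tuning parameters so that
#' resampling procedures (cross-validation, bootstrap) can re-run it on
#' perturbed data. The internal `inner_seed` is fixed so that across
#' resamples only the data vary, never the algorithm's own randomness.
#'
#' @param method one of `"ward"`, `"kmeans"`, `"spectral"`, `"geometric"`.
#' @param m PCA dimension for k-means/Ward, and the cap on the spectral
#'   embedding dimension (which is `min(K, m)`); always limited by the
#'   data.
#' @param n_init k-means restarts.
#' @param inner_seed fixed seed for the stochastic clustering stages.
#'
#' @return A list of class `clusterer`.
#' @export
clusterer <- function(method = c("ward", "kmeans", "spectral", "geometric"),
                      m = 100L, n_init = 10L, inner_seed = 1L) {
  method <- match.arg(method)
  structure(
    list(method = method, m = as.integer(m), n_init = as.integer(n_init),
         inner_seed = as.integer(inner_seed)),
    class = "clusterer"
  )
}

#' @export
print.clusterer <- function(x, ...) {
  cat(sprintf("<clusterer> %s (m = %d, n_init = %d)\n",
              x$method, x$m, x$n_init))
  invisible(x)
}

as_clusterer <- function(x) {
  if (inherits(x, "clusterer")) x else clusterer(x)
}

# Labelings of `signal` at every K in `K_values`. Hierarchy-based methods
# build their structure once and cut it at each K; embedding-based methods
# embed once and re-run k-means per K.
run_clusterer <- function(spec, signal, adjacency, K_values) {
  spec <- as_clusterer(spec)
  labels <- switch(
    spec$method,
    ward = {
      red <- pca_reduce(signal, spec$m)
      tree <- ward_tree(red, adjacency)
      lapply(K_values, cut_ward, tree = tree)
    },
    kmeans = {
      red <- pca_reduce(signal, spec$m)
      lapply(K_values, function(K) {
        kmeans_parcellation(red, K, seed = spec$inner_seed,
                            n_init = spec$n_init)$labels
      })
    },
    spectral = {
      aff <- spectral_affinity(signal, adjacency)
      # leading eigenvectors are nested: embed once at the largest
      # dimension needed, slice per K (embedding dim = min(K, m))
      m_top <- min(max(K_values), spec$m)
      emb <- spectral_embedding(aff, m_top)
      lapply(K_values, function(K) {
        vecs <- emb$vectors[, seq_len(min(K, m_top)), drop = FALSE]
        fit <- with_seed_if(spec$inner_seed,
                            kmeans_lloyd(vecs, K, n_init = spec$n_init))
        relabel_first_occurrence(fit$assign)
      })
    },
    geometric = {
      lapply(K_values, function(K) {
        geometric_parcellation(signal, K, seed = spec$inner_seed,
                               n_init = spec$n_init)$labels
      })
    }
  )
  names(labels) <- as.character(K_values)
  labels
}

#' Parcellate a signal with a clusterer specification
#'
#' @param signal a [parcel_signal()].
#' @param method a [clusterer()] or method name.
#' @param K number of parcels.
#' @param adjacency optional [grid_adjacency()]; derived from the
#'   signal's grid when omitted.
#' @return A [new_parcellation()].
#' @export
parcellate <- function(signal, method, K, adjacency = NULL) {
  spec <- as_clusterer(method)
  if (is.null(adjacency)) adjacency <- default_adjacency(signal)
  labels <- run_clusterer(spec, signal, adjacency, K)[[1L]]
  out <- new_parcellation(labels, method = spec$method,
                          connected = spec$method == "ward")
  out$centroids <- parcel_centroids(t(signal$values), out$labels)
  out
}
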