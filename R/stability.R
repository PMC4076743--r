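# Chance-corrected partition agreement and bootstrap reproducibility.

contingency_margins <- function(u1, u2) {
  if (length(u1) != length(u2))
    stop_bad_arg("labelings must have equal length (%d vs %d)",
                 length(u1), length(u2))
  tab <- table(u1, u2)
  list(tab = tab, a = rowSums(tab), b = colSums(tab), n = length(u1))
}

#' Adjusted Rand index
#'
#' Permutation-model chance-corrected Rand index between two labelings of
#' the same items: 1 for identical partitions (up to label permutation),
#' approximately 0 for independent ones, possibly negative, never above 1.
#'
#' @param u1,u2 equal-length label vectors.
#' @return The scalar index.
#' @export
#' @examples
#' adjusted_rand(c(1, 1, 2, 2), c(1, 2, 1, 2))  # -0.5
adjusted_rand <- function(u1, u2) {
  m <- contingency_margins(u1, u2)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(as.vector(m$tab)))
  sum_a <- sum(ch2(m$a))
  sum_b <- sum(ch2(m$b))
  total <- ch2(m$n)
  expected <- sum_a * sum_b / total
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

entropy_counts <- function(counts, n) {
  p <- counts[counts > 0] / n
  -sum(p * log(p))
}

# Expected mutual information of two labelings with the given margins
# under the permutation (hypergeometric) null model.
expected_mutual_info <- function(a, b, n) {
  emi <- 0
  for (i in seq_along(a)) {
    ai <- a[i]
    for (j in seq_along(b)) {
      bj <- b[j]
      lo <- max(1, ai + bj - n)
      hi <- min(ai, bj)
      if (hi < lo) next
      nij <- seq.int(lo, hi)
      w <- dhyper(nij, ai, n - ai, bj)
      emi <- emi + sum(w * (nij / n) * log(n * nij / (ai * bj)))
    }
  }
  emi
}

#' Adjusted mutual information
#'
#' Mutual information between two labelings minus its expectation under
#' the permutation null model, normalized by the larger of the two
#' entropies (max normalization). Identical partitions score 1,
#' statistically independent ones score approximately 0; label
#' permutations leave the value unchanged.
#'
#' @param u1,u2 equal-length label vectors.
#' @return The scalar index (at most 1).
#' @export
adjusted_mutual_info <- function(u1, u2) {
  m <- contingency_margins(u1, u2)
  n <- m$n
  hu <- entropy_counts(m$a, n)
  hv <- entropy_counts(m$b, n)
  if (hu == 0 && hv == 0) return(1)  # two identical trivial partitions
  tab <- as.vector(m$tab)
  nz <- tab > 0
  outer_ab <- as.vector(outer(m$a, m$b))
  mi <- sum((tab[nz] / n) * log(n * tab[nz] / outer_ab[nz]))
  emi <- expected_mutual_info(m$a, m$b, n)
  denom <- max(hu, hv) - emi
  if (abs(denom) < .Machine$double.eps) return(0)
  (mi - emi) / denom
}

#' Bootstrap reproducibility of a clustering method
#'
#' Draws B bootstrap resamples of the subjects (with replacement; all
#' contrast images of a drawn subject are included, duplicates
#' concatenated as distinct subjects), re-clusters each resample at the
#' same K, and scores the agreement of every pair of resulting labelings
#' with ARI or AMI over the common voxel set. The clusterer's internal
#' seed is held fixed so that only the data resampling drives
#' variability.
#'
#' @param signal a [parcel_signal()].
#' @param method a [clusterer()] or method name.
#' @param K number of parcels.
#' @param B number of bootstrap resamples (>= 2).
#' @param metric `"ami"` or `"ari"`.
#' @param adjacency optional [grid_adjacency()].
#' @param seed optional integer seed for the resampling.
#'
#' @return An object of class `stability_estimate`: list with `B`,
#'   `metric`, `pairwise_scores` (length B(B-1)/2) and `mean_score`.
#' @export
bootstrap_reproducibility <- function(signal, method, K, B = 10L,
                                      metric = c("ami", "ari"),
                                      adjacency = NULL, seed = NULL) {
  metric <- match.arg(metric)
  if (B < 2L) stop_bad_arg("`B` must be at least 2")
  if (is.null(adjacency)) adjacency <- default_adjacency(signal)
  labelings <- bootstrap_labelings(signal, method, K, B, adjacency, seed)
  scores <- pairwise_agreement(lapply(labelings, `[[`, 1L), metric)
  structure(
    list(B = as.integer(B), metric = metric, K = as.integer(K),
         pairwise_scores = scores, mean_score = mean(scores)),
    class = "stability_estimate"
  )
}

#' @export
print.stability_estimate <- function(x, ...) {
  cat(sprintf("<stability_estimate> B = %d, mean %s = %.4f\n",
              x$B, toupper(x$metric), x$mean_score))
  invisible(x)
}

#' @describeIn bootstrap_reproducibility pairwise scores as a tibble.
#' @param x a `stability_estimate`.
#' @param ... unused.
#' @export
tidy.stability_estimate <- function(x, ...) {
  pairs <- utils::combn(x$B, 2L)
  tibble(rep1 = pairs[1L, ], rep2 = pairs[2L, ],
         metric = x$metric, score = x$pairwise_scores)
}

#' @describeIn bootstrap_reproducibility one-row summary.
#' @export
glance.stability_estimate <- function(x, ...) {
  tibble(B = x$B, K = x$K, metric = x$metric,
         mean_score = x$mean_score, sd_score = sd(x$pairwise_scores))
}

# One list element per bootstrap resample, each a named list of labelings
# (one per K in K_values).
bootstrap_labelings <- function(signal, method, K_values, B, adjacency,
                                seed = NULL) {
  spec <- as_clusterer(method)
  subjects <- sort(unique(signal$subject))
  lapply(seq_len(B), function(b) {
    draw <- with_seed_if(
      if (is.null(seed)) NULL else derive_seed(seed, b),
      sample(subjects, length(subjects), replace = TRUE))
    run_clusterer(spec, subset_subjects(signal, draw), adjacency, K_values)
  })
}

pairwise_agreement <- function(labelings, metric) {
  score_fun <- switch(metric, ami = adjusted_mutual_info,
                      ari = adjusted_rand)
  B <- length(labelings)
  pairs <- utils::combn(B, 2L)
  vapply(seq_len(ncol(pairs)), function(p) {
    score_fun(labelings[[pairs[1L, p]]], labelings[[pairs[2L, p]]])
  }, numeric(1))
}
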