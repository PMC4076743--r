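# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive (dense algebra, exhaustive enumeration, greedy
# re-derivation) and never share code with the implementation paths they
# check.

# Dense multivariate-normal log-density under the compound-symmetry
# covariance sigma1_sq * I + sigma2_sq * X X'.
dense_loglik_oracle <- function(y, subject, mu, sigma1_sq, sigma2_sq) {
  subject <- as.integer(factor(subject))
  p <- length(y)
  X <- outer(subject, sort(unique(subject)), "==") * 1
  Sigma <- sigma1_sq * diag(p) + sigma2_sq * tcrossprod(X)
  e <- y - mu
  ld <- as.numeric(determinant(Sigma, logarithm = TRUE)$modulus)
  -0.5 * (p * log(2 * pi) + ld + drop(crossprod(e, solve(Sigma, e))))
}

# Exhaustive (sigma1_sq, sigma2_sq) grid search maximizing the marginal
# likelihood with mu profiled out by GLS; two refinement stages.
grid_search_mixed_oracle <- function(y, subject, n_grid = 60L) {
  subject <- as.integer(factor(subject))
  s <- tabulate(subject)
  ybar <- as.vector(rowsum(y, subject)) / s
  eval_ll <- function(s1, s2) {
    w <- s / (s1 + s * s2)
    mu <- sum(w * ybar) / sum(w)
    loglik_parcel(y, subject, mu, s1, s2)
  }
  v <- var(y)
  lo1 <- v / 50; hi1 <- 3 * v
  lo2 <- 1e-6; hi2 <- 3 * v
  best <- c(NA, NA, -Inf)
  for (stage in 1:2) {
    g1 <- seq(lo1, hi1, length.out = n_grid)
    g2 <- seq(lo2, hi2, length.out = n_grid)
    for (s1 in g1) for (s2 in g2) {
      ll <- eval_ll(s1, s2)
      if (ll > best[3]) best <- c(s1, s2, ll)
    }
    step1 <- g1[2] - g1[1]; step2 <- g2[2] - g2[1]
    lo1 <- max(best[1] - step1, v / 1000); hi1 <- best[1] + step1
    lo2 <- max(best[2] - step2, 0); hi2 <- best[2] + step2
  }
  list(sigma1_sq = best[1], sigma2_sq = best[2], loglik = best[3])
}

# Exhaustive minimum-inertia K-partition of a small point set
# (points in rows). Enumerates all K^n assignments.
best_partition_oracle <- function(X, K) {
  n <- nrow(X)
  stopifnot(K^n <= 3e5)
  grid <- do.call(expand.grid, rep(list(seq_len(K)), n))
  best <- list(inertia = Inf, assign = NULL)
  for (r in seq_len(nrow(grid))) {
    a <- as.integer(grid[r, ])
    if (length(unique(a)) < K) next
    C <- rowsum(X, a) / tabulate(a, K)
    inert <- sum((X - C[a, , drop = FALSE])^2)
    if (inert < best$inertia - 1e-12) best <- list(inertia = inert,
                                                   assign = a)
  }
  best
}

# Greedy constrained agglomeration computing the merge cost explicitly
# as the within-cluster sum-of-squares increase from the raw points.
greedy_ward_oracle <- function(X, edges, K) {
  n <- nrow(X)
  clusters <- as.list(seq_len(n))
  inertia_of <- function(idx) {
    if (length(idx) == 1L) return(0)
    sum(scale(X[idx, , drop = FALSE], scale = FALSE)^2)
  }
  adjacent <- function(c1, c2) {
    any(edges[, 1] %in% c1 & edges[, 2] %in% c2) ||
      any(edges[, 1] %in% c2 & edges[, 2] %in% c1)
  }
  costs <- c()
  while (length(clusters) > K) {
    best <- list(cost = Inf, i = NA, j = NA)
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in seq.int(i + 1L, length(clusters))) {
        if (!adjacent(clusters[[i]], clusters[[j]])) next
        cost <- inertia_of(c(clusters[[i]], clusters[[j]])) -
          inertia_of(clusters[[i]]) - inertia_of(clusters[[j]])
        if (cost < best$cost - 1e-12) best <- list(cost = cost, i = i,
                                                   j = j)
      }
    }
    if (!is.finite(best$cost)) stop("oracle: graph disconnected")
    costs <- c(costs, best$cost)
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  labels <- integer(n)
  for (k in seq_along(clusters)) labels[clusters[[k]]] <- k
  list(labels = labels, costs = costs)
}

# Contingency-table ARI written independently of the package's version.
ari_oracle <- function(u1, u2) {
  tab <- table(u1, u2)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  ex <- sa * sb / choose(n, 2)
  ((sij - ex) / ((sa + sb) / 2 - ex))
}

random_labeling <- function(n, K) sample.int(K, n, replace = TRUE)
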