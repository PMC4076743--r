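# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' `seed = NULL` leaves the caller's RNG stream untouched.
#' @noRd
with_seed_if <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    withr::with_seed(as.integer(seed), force(code))
  }
}

# Deterministic sub-seed derivation; stays below 2^31 - 1.
derive_seed <- function(seed, i, j = 0L) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(i) +
                7919 * as.numeric(j)) %% 2147483629)
}

stop_bad_arg <- function(...) stop(sprintf(...), call. = FALSE)

# Connected components via union-find with path halving.
# `edges` is an E x 2 integer matrix of 1-based vertex indices.
graph_components <- function(n_vertices, edges) {
  parent <- seq_len(n_vertices)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (!is.null(edges) && nrow(edges) > 0) {
    for (e in seq_len(nrow(edges))) {
      ra <- find(edges[e, 1L])
      rb <- find(edges[e, 2L])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(n_vertices), find, integer(1))
  match(roots, unique(roots))
}

# TRUE when every parcel induces a single connected component.
labels_are_connected <- function(labels, edges) {
  keep <- labels[edges[, 1L]] == labels[edges[, 2L]]
  comp <- graph_components(length(labels), edges[keep, , drop = FALSE])
  all(vapply(split(comp, labels), function(x) length(unique(x)) == 1L,
             logical(1)))
}

# Canonical 1..K labeling in order of first occurrence.
relabel_first_occurrence <- function(labels) {
  match(labels, unique(labels))
}
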