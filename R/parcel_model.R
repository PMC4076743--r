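# Per-parcel Gaussian mixed-effects model:
#   y = mu * 1 + X beta + eps,   beta_i ~ N(0, sigma2^2),  eps ~ N(0, sigma1^2)
# so that marginally y ~ N(mu 1, sigma1^2 I + sigma2^2 X X'), a
# compound-symmetry covariance that is block diagonal across subjects.

VAR_FLOOR <- 1e-8

#' Marginal log-likelihood of pooled parcel values
#'
#' Exact Gaussian log-density of the pooled within-parcel values under the
#' compound-symmetry covariance `sigma1^2 I + sigma2^2 X X'`, computed per
#' subject block: for a subject with s values the block determinant is
#' `(sigma1^2)^(s-1) (sigma1^2 + s sigma2^2)` and the inverse follows from
#' a rank-one update, so no dense covariance is ever formed.
#'
#' @param y numeric vector of pooled values (all voxels of the parcel,
#'   concatenated across subjects).
#' @param subject integer vector mapping each value to its subject.
#' @param mu mean parameter.
#' @param sigma1_sq within-subject variance (> 0).
#' @param sigma2_sq between-subject variance (>= 0).
#' @return The scalar log-likelihood.
#' @export
loglik_parcel <- function(y, subject, mu, sigma1_sq, sigma2_sq) {
  if (sigma1_sq <= 0) stop_bad_arg("`sigma1_sq` must be positive")
  if (sigma2_sq < 0) stop_bad_arg("`sigma2_sq` must be non-negative")
  subject <- as.integer(factor(subject))
  s <- tabulate(subject)
  e <- y - mu
  esum <- as.vector(rowsum(e, subject))
  e2sum <- as.vector(rowsum(e^2, subject))
  p <- length(y)
  tau <- sigma1_sq + s * sigma2_sq
  logdet <- sum((s - 1) * log(sigma1_sq) + log(tau))
  quad <- sum((e2sum - esum^2 / s) / sigma1_sq + (esum^2 / s) / tau)
  -0.5 * (p * log(2 * pi) + logdet + quad)
}

#' Fit the mixed-effects model of one parcel by EM
#'
#' Maximum-likelihood estimation of (mu, sigma1^2, sigma2^2) by
#' Expectation-Maximization over the latent subject effects: the E-step
#' computes the posterior mean and variance of each subject effect, the
#' M-step updates the three parameters in closed form. The marginal
#' log-likelihood is non-decreasing across iterations (checked at every
#' step); variances are floored at 1e-8.
#'
#' @inheritParams loglik_parcel
#' @param tol convergence tolerance on the log-likelihood gain.
#' @param max_iter maximum EM iterations.
#' @return A list with `mu`, `sigma1_sq`, `sigma2_sq`, `loglik`,
#'   `n_iter`, `converged`, and the per-iteration `loglik_trace`.
#' @export
fit_parcel_mixed_effects <- function(y, subject, tol = 1e-6,
                                     max_iter = 200L) {
  subject <- as.integer(factor(subject))
  N <- max(subject)
  p <- length(y)
  if (p < 2L) stop_bad_arg("need at least 2 pooled values")
  s <- tabulate(subject)
  ysum <- as.vector(rowsum(y, subject))
  ybar <- ysum / s
  y2sum <- sum(y^2)

  single_subject <- N < 2L
  if (single_subject)
    warn(paste("fewer than 2 subjects: sigma2 is unidentifiable and",
               "held at the variance floor"))

  mu <- mean(y)
  ss_within <- sum(y^2) - sum(s * ybar^2)
  sigma1_sq <- max(ss_within / max(p - N, 1L), VAR_FLOOR)
  sigma2_sq <- if (single_subject) VAR_FLOOR else
    max(var(ybar) - sigma1_sq * mean(1 / s), VAR_FLOOR)

  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # E-step: posterior moments of the subject effects
    v <- 1 / (1 / sigma2_sq + s / sigma1_sq)
    b <- v * s * (ybar - mu) / sigma1_sq
    # M-step (joint closed form)
    mu <- (sum(y) - sum(s * b)) / p
    if (!single_subject) sigma2_sq <- max(mean(b^2 + v), VAR_FLOOR)
    rss <- y2sum - 2 * sum((mu + b) * ysum) + sum(s * (mu + b)^2)
    sigma1_sq <- max((rss + sum(s * v)) / p, VAR_FLOOR)

    ll <- loglik_parcel(y, subject, mu, sigma1_sq, sigma2_sq)
    trace <- c(trace, ll)
    if (ll < ll_old - 1e-6 * (1 + abs(ll_old)))
      stop(sprintf(
        "internal error: EM log-likelihood decreased (%.10g -> %.10g)",
        ll_old, ll))
    if (is.finite(ll_old) && ll - ll_old < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(mu = mu, sigma1_sq = sigma1_sq, sigma2_sq = sigma2_sq,
       loglik = trace[length(trace)], n_iter = iter,
       converged = converged, loglik_trace = trace)
}

#' Score a fixed parcellation with the mixed-effects model
#'
#' Fits one scalar mixed-effects model per (parcel, contrast) — the model
#' decouples across contrasts conditional on the parcellation — and
#' reports the per-fit estimates, log-likelihoods and BIC terms. Any
#' fixed labeling (e.g. an external atlas volume) can be scored this way.
#'
#' @param signal a [parcel_signal()].
#' @param parcellation a [new_parcellation()] or a bare integer labeling
#'   over the voxels.
#' @param tol,max_iter EM control parameters.
#'
#' @return A tibble of class `parcel_fit` with one row per
#'   (parcel, contrast): `parcel`, `contrast`, `size` (voxels), `p`
#'   (pooled values), `mu`, `sigma1_sq`, `sigma2_sq`, `loglik`, `bic`.
#'   Totals are available via [glance()] or [bic_score()].
#' @export
fit_parcellation_model <- function(signal, parcellation, tol = 1e-6,
                                   max_iter = 200L) {
  labels <- if (inherits(parcellation, "parcellation"))
    parcellation$labels else relabel_first_occurrence(parcellation)
  if (length(labels) != n_voxels(signal))
    stop_bad_arg("parcellation covers %d voxels but the signal has %d",
                 length(labels), n_voxels(signal))
  K <- max(labels)
  contrasts <- sort(unique(signal$contrast))
  rows <- list()
  for (f in contrasts) {
    in_f <- signal$contrast == f
    subj_f <- signal$subject[in_f]
    vals_f <- signal$values[in_f, , drop = FALSE]
    for (k in seq_len(K)) {
      cols <- which(labels == k)
      y <- as.vector(vals_f[, cols, drop = FALSE])
      subject <- rep(subj_f, times = length(cols))
      fit <- fit_parcel_mixed_effects(y, subject, tol = tol,
                                      max_iter = max_iter)
      rows[[length(rows) + 1L]] <- tibble(
        parcel = k, contrast = f, size = length(cols), p = length(y),
        mu = fit$mu, sigma1_sq = fit$sigma1_sq,
        sigma2_sq = fit$sigma2_sq, loglik = fit$loglik,
        bic = -2 * fit$loglik + 3 * log(length(y)),
        n_iter = fit$n_iter, converged = fit$converged
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "K") <- K
  attr(out, "n_subjects") <- n_subjects(signal)
  class(out) <- c("parcel_fit", class(out))
  out
}

#' @export
print.parcel_fit <- function(x, ...) {
  cat(sprintf(
    "<parcel_fit> %d parcels x %d contrast(s); total loglik %.2f, BIC %.2f\n",
    attr(x, "K"), length(unique(x$contrast)), sum(x$loglik), sum(x$bic)))
  NextMethod()
}

#' @describeIn fit_parcellation_model the per-(parcel, contrast) table as
#'   a plain tibble.
#' @param x a `parcel_fit`.
#' @param ... unused.
#' @export
tidy.parcel_fit <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "parcel_fit")
  as_tibble(out)
}

#' @describeIn fit_parcellation_model one-row summary with the summed
#'   log-likelihood and BIC.
#' @export
glance.parcel_fit <- function(x, ...) {
  tibble(
    K = attr(x, "K"),
    n_fits = nrow(x),
    loglik = sum(x$loglik),
    bic = sum(x$bic),
    mean_sigma1 = mean(sqrt(x$sigma1_sq)),
    mean_sigma2 = mean(sqrt(x$sigma2_sq))
  )
}

#' Total BIC of a scored parcellation
#'
#' Sums the per-(parcel, contrast) terms `-2 loglik + 3 log(p)`, where 3
#' counts the parameters (mu, sigma1, sigma2) and p is the pooled value
#' count of the fit. Lower is better.
#'
#' @param fit a `parcel_fit` from [fit_parcellation_model()].
#' @return The scalar total BIC.
#' @export
bic_score <- function(fit) {
  stopifnot(inherits(fit, "parcel_fit"))
  sum(fit$bic)
}

# Log-likelihood of (possibly held-out) data under an already-fitted
# per-(parcel, contrast) parameter table, summed across parcels and
# contrasts.
loglik_under_fit <- function(signal, labels, fit) {
  total <- 0
  for (r in seq_len(nrow(fit))) {
    in_f <- signal$contrast == fit$contrast[r]
    cols <- which(labels == fit$parcel[r])
    y <- as.vector(signal$values[in_f, cols, drop = FALSE])
    subject <- rep(signal$subject[in_f], times = length(cols))
    total <- total + loglik_parcel(y, subject, fit$mu[r],
                                   fit$sigma1_sq[r], fit$sigma2_sq[r])
  }
  total
}

#' Cross-validated log-likelihood of a clustering method at a given K
#'
#' Shuffle-split cross-validation over subjects: per split, a random
#' `train_fraction` of the subjects is used to estimate both the
#' clustering and the per-parcel mixed-effects parameters; the marginal
#' log-likelihood of the held-out subjects' data under those parameters
#' is summed across parcels and contrasts. The mean across splits is
#' returned.
#'
#' @param signal a [parcel_signal()].
#' @param method a [clusterer()] specification.
#' @param K number of parcels.
#' @param adjacency optional [grid_adjacency()]; derived from the
#'   signal's grid when omitted.
#' @param n_splits number of random splits.
#' @param train_fraction fraction of subjects in the training set,
#'   in (0, 1).
#' @param seed optional integer seed; the result is deterministic given
#'   it.
#' @return The mean held-out log-likelihood (scalar).
#' @export
cv_loglik <- function(signal, method, K, adjacency = NULL,
                      n_splits = 10L, train_fraction = 0.8, seed = NULL) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_bad_arg("`train_fraction` must be strictly between 0 and 1")
  if (is.null(adjacency)) adjacency <- default_adjacency(signal)
  subjects <- sort(unique(signal$subject))
  N <- length(subjects)
  n_train <- round(train_fraction * N)
  if (n_train < 2L || N - n_train < 2L)
    stop_bad_arg("need at least 2 subjects in both train and test sets")
  lls <- vapply(seq_len(n_splits), function(split) {
    perm <- with_seed_if(
      if (is.null(seed)) NULL else derive_seed(seed, split),
      sample(subjects))
    train <- subset_subjects(signal, perm[seq_len(n_train)])
    test <- subset_subjects(signal, perm[seq.int(n_train + 1L, N)])
    labels <- run_clusterer(method, train, adjacency, K)[[1L]]
    fit <- fit_parcellation_model(train, labels)
    loglik_under_fit(test, labels, fit)
  }, numeric(1))
  mean(lls)
}
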