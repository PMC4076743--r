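# Orchestration of the model-selection experiment: K sweeps x methods x
# criteria x replications, K* selection, and recovery scoring.

CRITERION_DIRECTIONS <- c("LL" = "max", "CV-LL" = "max", "BIC" = "min",
                          "B-AMI" = "max", "B-ARI" = "max")

#' Criterion curve over a K grid
#'
#' @param K integer vector of candidate parcel numbers.
#' @param value criterion value at each K.
#' @param criterion one of `"LL"`, `"CV-LL"`, `"BIC"`, `"B-AMI"`,
#'   `"B-ARI"`.
#' @param method optional clustering method tag.
#' @return A tibble of class `criterion_curve` with attributes
#'   `criterion` and `direction`.
#' @export
criterion_curve <- function(K, value, criterion, method = NA_character_) {
  criterion <- match.arg(criterion, names(CRITERION_DIRECTIONS))
  out <- tibble(K = as.integer(K), value = as.numeric(value),
                criterion = criterion, method = method)
  out <- dplyr::arrange(out, .data$K)
  attr(out, "criterion") <- criterion
  attr(out, "direction") <- unname(CRITERION_DIRECTIONS[criterion])
  class(out) <- c("criterion_curve", class(out))
  out
}

#' Select the number of parcels from a criterion curve
#'
#' Argmax for log-likelihood, cross-validated likelihood and
#' reproducibility criteria; argmin for BIC. Ties are broken toward the
#' smallest K.
#'
#' @param curve a [criterion_curve()].
#' @return The selected K (integer).
#' @export
select_K <- function(curve) {
  stopifnot(inherits(curve, "criterion_curve"))
  if (nrow(curve) == 0L) stop_bad_arg("empty criterion curve")
  if (any(!is.finite(curve$value)))
    stop_bad_arg("criterion curve contains non-finite values")
  v <- if (attr(curve, "direction") == "min") -curve$value else curve$value
  # curve is sorted by K, so the first extremum is the smallest K
  curve$K[which.max(v)]
}

#' Configuration of the model-selection experiment
#'
#' @param simulation a [simulation_config()].
#' @param methods clustering methods to benchmark.
#' @param criteria selection criteria to evaluate.
#' @param K_grid sorted candidate parcel numbers (all >= 2).
#' @param replications number of simulated replications.
#' @param n_boot bootstrap resamples per reproducibility curve.
#' @param cv_splits shuffle-splits per cross-validated likelihood value.
#' @param seed base seed; per-replication seeds are derived from it.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(simulation = simulation_config(),
                              methods = c("ward", "kmeans", "spectral"),
                              criteria = c("BIC", "B-AMI"),
                              K_grid = c(2:10, 15L, 20L, 30L),
                              replications = 20L,
                              n_boot = 10L, cv_splits = 5L, seed = 1L) {
  methods <- match.arg(methods, c("ward", "kmeans", "spectral",
                                  "geometric"), several.ok = TRUE)
  criteria <- match.arg(criteria, names(CRITERION_DIRECTIONS),
                        several.ok = TRUE)
  K_grid <- sort(unique(as.integer(K_grid)))
  if (length(K_grid) == 0L || any(K_grid < 2L))
    stop_bad_arg("`K_grid` must be non-empty with all values >= 2")
  if (replications < 1L) stop_bad_arg("`replications` must be >= 1")
  structure(
    list(simulation = simulation, methods = methods, criteria = criteria,
         K_grid = K_grid, replications = as.integer(replications),
         n_boot = as.integer(n_boot), cv_splits = as.integer(cv_splits),
         seed = as.integer(seed)),
    class = "experiment_config"
  )
}

# Criterion curves for one dataset and one method, given precomputed
# full-data labelings per K.
method_criterion_values <- function(signal, spec, adjacency, K_grid,
                                    labels_by_K, criteria, n_boot,
                                    cv_splits, seed) {
  values <- list()
  if (any(c("LL", "BIC") %in% criteria)) {
    fits <- lapply(labels_by_K, function(l)
      fit_parcellation_model(signal, l))
    if ("LL" %in% criteria)
      values[["LL"]] <- vapply(fits, function(f) sum(f$loglik), numeric(1))
    if ("BIC" %in% criteria)
      values[["BIC"]] <- vapply(fits, bic_score, numeric(1))
  }
  if ("CV-LL" %in% criteria) {
    values[["CV-LL"]] <- vapply(K_grid, function(K) {
      cv_loglik(signal, spec, K, adjacency = adjacency,
                n_splits = cv_splits, seed = derive_seed(seed, K, 1L))
    }, numeric(1))
  }
  repro <- intersect(c("B-AMI", "B-ARI"), criteria)
  if (length(repro) > 0) {
    boots <- bootstrap_labelings(signal, spec, K_grid, n_boot, adjacency,
                                 seed = derive_seed(seed, 0L, 2L))
    for (crit in repro) {
      metric <- if (crit == "B-AMI") "ami" else "ari"
      values[[crit]] <- vapply(seq_along(K_grid), function(ki) {
        mean(pairwise_agreement(lapply(boots, `[[`, ki), metric))
      }, numeric(1))
    }
  }
  values
}

#' Run the simulation-based model-selection experiment
#'
#' For each replication: simulate a multi-subject dataset with its
#' ground-truth labeling; for each clustering method, parcellate at every
#' K of the grid; for each criterion, build the criterion curve, select
#' K*, and score recovery as the ARI between the ground truth and the
#' parcellation at K*. Fully deterministic given the base seed. Failures
#' of individual (replication, method) stages are recorded and the run
#' continues.
#'
#' @param config an [experiment_config()].
#' @param verbose print per-replication progress.
#'
#' @return An object of class `parcel_experiment`: list with `results`
#'   (tibble: replication, method, criterion, K_star, recovery),
#'   `curves` (tibble: replication, method, criterion, K, value),
#'   `errors` (tibble of recorded failures) and `config`.
#' @export
run_model_selection_experiment <- function(config = experiment_config(),
                                           verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  results <- list()
  curves <- list()
  errors <- list()
  for (rep in seq_len(config$replications)) {
    seed_r <- derive_seed(config$seed, rep)
    ds <- simulate_parcel_dataset(config$simulation, seed = seed_r)
    adjacency <- grid_adjacency(config$simulation$grid_shape)
    for (method in config$methods) {
      spec <- clusterer(method)
      res <- tryCatch({
        labels_by_K <- run_clusterer(spec, ds$signal, adjacency,
                                     config$K_grid)
        values <- method_criterion_values(
          ds$signal, spec, adjacency, config$K_grid, labels_by_K,
          config$criteria, config$n_boot, config$cv_splits, seed_r)
        rows <- lapply(config$criteria, function(crit) {
          curve <- criterion_curve(config$K_grid, values[[crit]], crit,
                                   method)
          K_star <- select_K(curve)
          ki <- match(K_star, config$K_grid)
          tibble(replication = rep, method = method, criterion = crit,
                 K_star = K_star,
                 recovery = adjusted_rand(ds$truth$labeling,
                                          labels_by_K[[ki]]))
        })
        curve_rows <- lapply(config$criteria, function(crit) {
          tibble(replication = rep, method = method, criterion = crit,
                 K = config$K_grid, value = values[[crit]])
        })
        list(rows = dplyr::bind_rows(rows),
             curves = dplyr::bind_rows(curve_rows))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        errors[[length(errors) + 1L]] <- tibble(
          replication = rep, method = method,
          message = conditionMessage(res))
      } else {
        results[[length(results) + 1L]] <- res$rows
        curves[[length(curves) + 1L]] <- res$curves
      }
    }
    if (verbose)
      message(sprintf("replication %d/%d done", rep, config$replications))
  }
  structure(
    list(results = dplyr::bind_rows(results),
         curves = dplyr::bind_rows(curves),
         errors = dplyr::bind_rows(errors),
         config = config),
    class = "parcel_experiment"
  )
}

#' @export
print.parcel_experiment <- function(x, ...) {
  cat(sprintf(
    "<parcel_experiment> %d replications x {%s} x {%s}\n",
    x$config$replications, paste(x$config$methods, collapse = ", "),
    paste(x$config$criteria, collapse = ", ")))
  s <- glance(x)
  print(as.data.frame(s), row.names = FALSE)
  invisible(x)
}

#' @describeIn run_model_selection_experiment the per-record selection
#'   table.
#' @param x a `parcel_experiment`.
#' @param ... unused.
#' @export
tidy.parcel_experiment <- function(x, ...) x$results

#' @describeIn run_model_selection_experiment median selected K and mean
#'   recovery per (method, criterion).
#' @export
glance.parcel_experiment <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x$results, .data$method, .data$criterion),
    median_K_star = median(.data$K_star),
    mean_recovery = mean(.data$recovery),
    .groups = "drop")
}

#' Variance components as a function of the number of parcels
#'
#' For each K of the grid: parcellate, fit the mixed-effects model, and
#' average the estimated within-subject (sigma1) and between-subject
#' (sigma2) standard deviations across parcels and contrasts. On data
#' with spatial jitter or smoothing, sigma1 typically decreases with K
#' while sigma2 increases: finer parcellations re-allocate variance from
#' the within- to the between-subject component.
#'
#' @param signal a [parcel_signal()].
#' @param method a [clusterer()] or method name.
#' @param K_grid candidate parcel numbers.
#' @param adjacency optional [grid_adjacency()].
#' @return A tibble with columns `K`, `sigma1`, `sigma2`, `loglik`,
#'   `bic`.
#' @export
variance_component_curve <- function(signal, method, K_grid,
                                     adjacency = NULL) {
  spec <- as_clusterer(method)
  if (is.null(adjacency)) adjacency <- default_adjacency(signal)
  K_grid <- sort(unique(as.integer(K_grid)))
  labels_by_K <- run_clusterer(spec, signal, adjacency, K_grid)
  purrr::map2_dfr(K_grid, labels_by_K, function(K, labels) {
    fit <- fit_parcellation_model(signal, labels)
    tibble(K = K, sigma1 = mean(sqrt(fit$sigma1_sq)),
           sigma2 = mean(sqrt(fit$sigma2_sq)),
           loglik = sum(fit$loglik), bic = bic_score(fit))
  })
}

#' Joint accuracy and reproducibility table
#'
#' For every (method, K) pair, computes an accuracy score (total
#' log-likelihood of the full-data fit, or cross-validated
#' log-likelihood) together with the bootstrap reproducibility, enabling
#' the accuracy-reproducibility trade-off plot. No selection is applied.
#'
#' @param signal a [parcel_signal()].
#' @param methods clustering method names.
#' @param K_grid candidate parcel numbers.
#' @param B bootstrap resamples.
#' @param metric reproducibility metric, `"ami"` or `"ari"`.
#' @param accuracy `"ll"` (in-sample) or `"cv"` (cross-validated).
#' @param adjacency optional [grid_adjacency()].
#' @param seed optional integer seed.
#' @return A tibble with one row per (method, K): columns `method`, `K`,
#'   `accuracy`, `reproducibility`.
#' @export
accuracy_reproducibility_table <- function(signal, methods, K_grid,
                                           B = 10L, metric = "ami",
                                           accuracy = c("ll", "cv"),
                                           adjacency = NULL, seed = NULL) {
  accuracy <- match.arg(accuracy)
  if (is.null(adjacency)) adjacency <- default_adjacency(signal)
  K_grid <- sort(unique(as.integer(K_grid)))
  purrr::map_dfr(methods, function(method) {
    spec <- clusterer(method)
    labels_by_K <- run_clusterer(spec, signal, adjacency, K_grid)
    acc <- if (accuracy == "ll") {
      vapply(labels_by_K, function(l)
        sum(fit_parcellation_model(signal, l)$loglik), numeric(1))
    } else {
      vapply(K_grid, function(K)
        cv_loglik(signal, spec, K, adjacency = adjacency,
                  seed = if (is.null(seed)) NULL
                         else derive_seed(seed, K)), numeric(1))
    }
    boots <- bootstrap_labelings(signal, spec, K_grid, B, adjacency,
                                 seed = seed)
    rep_scores <- vapply(seq_along(K_grid), function(ki) {
      mean(pairwise_agreement(lapply(boots, `[[`, ki), metric))
    }, numeric(1))
    tibble(method = method, K = K_grid, accuracy = acc,
           reproducibility = rep_scores)
  })
}
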