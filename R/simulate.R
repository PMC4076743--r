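#' Configuration of the 2D multi-subject simulator
#'
#' The simulator draws multi-subject images from the per-parcel
#' mixed-effects model: a piecewise-constant mean map over a ground-truth
#' parcellation, a subject-level random shift shared by all pixels of a
#' subject, and i.i.d. pixel noise. Optional integer spatial jitter and
#' Gaussian smoothing deliberately break the model assumptions, emulating
#' imperfect spatial normalization and data smoothness.
#'
#' Defaults reproduce the reference simulation design: a 20 x 25 pixel
#' grid, 5 connected ground-truth parcels, 10 subjects, one contrast,
#' parcel means drawn from N(0, 1), sigma1 = sigma2 = 1.
#'
#' @param grid_shape integer pair, image dimensions in pixels.
#' @param K_true number of ground-truth parcels.
#' @param n_subjects number of subjects N.
#' @param n_contrasts functional images per subject F.
#' @param sigma1 within-subject (pixel) noise standard deviation.
#' @param sigma2 between-subject standard deviation of the random effect.
#' @param mu_sd standard deviation of the per-parcel means.
#' @param jitter maximum integer displacement per axis, in pixels
#'   (0 = no deformation).
#' @param fwhm full width at half maximum of the Gaussian smoothing kernel,
#'   in pixels (0 = no smoothing).
#'
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(grid_shape = c(20L, 25L), K_true = 5L,
                              n_subjects = 10L, n_contrasts = 1L,
                              sigma1 = 1, sigma2 = 1, mu_sd = 1,
                              jitter = 0L, fwhm = 0) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape < 1L))
    stop_bad_arg("`grid_shape` must be two positive integers")
  if (K_true < 1L || K_true > prod(grid_shape))
    stop_bad_arg("`K_true` must be between 1 and the number of pixels")
  if (sigma1 < 0 || sigma2 < 0 || mu_sd < 0 || fwhm < 0)
    stop_bad_arg("sigma1, sigma2, mu_sd and fwhm must be non-negative")
  if (jitter < 0 || jitter != round(jitter))
    stop_bad_arg("`jitter` must be a non-negative integer")
  if (n_subjects < 1L || n_contrasts < 1L)
    stop_bad_arg("`n_subjects` and `n_contrasts` must be positive")
  structure(
    list(grid_shape = grid_shape, K_true = as.integer(K_true),
         n_subjects = as.integer(n_subjects),
         n_contrasts = as.integer(n_contrasts),
         sigma1 = sigma1, sigma2 = sigma2, mu_sd = mu_sd,
         jitter = as.integer(jitter), fwhm = fwhm),
    class = "simulation_config"
  )
}

#' Ground-truth labeling of the simulation grid
#'
#' Generates K_true random connected parcels by running the spatially
#' constrained Ward agglomeration on i.i.d. standard-normal signals
#' (10 feature channels per pixel), so that every parcel is connected under
#' 4-neighbor adjacency by construction.
#'
#' @param grid_shape integer pair of pixel dimensions.
#' @param K_true number of parcels.
#' @param seed optional integer seed; the labeling is deterministic given
#'   the seed.
#' @param n_channels number of random feature channels fed to Ward.
#'
#' @return A list of class `ground_truth` with elements `labeling`
#'   (integer vector over pixels, values 1..K_true), `grid_shape`, `K_true`.
#' @export
make_ground_truth <- function(grid_shape, K_true, seed = NULL,
                              n_channels = 10L) {
  grid_shape <- as.integer(grid_shape)
  Q <- prod(grid_shape)
  if (K_true < 1L || K_true > Q)
    stop_bad_arg("`K_true` must be between 1 and the number of pixels (%d)", Q)
  adj <- grid_adjacency(grid_shape)
  labeling <- with_seed_if(seed, {
    G <- matrix(rnorm(Q * n_channels), nrow = n_channels, ncol = Q)
    tree <- ward_tree(G, adj)
    cut_ward(tree, K_true)
  })
  structure(
    list(labeling = labeling, grid_shape = grid_shape,
         K_true = as.integer(K_true)),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %s grid, %d parcels\n",
              paste(x$grid_shape, collapse = " x "), x$K_true))
  invisible(x)
}

#' Translate an image by an integer offset, replicating edges
#' @noRd
translate_image <- function(image, offset) {
  d <- dim(image)
  ri <- pmin(pmax(seq_len(d[1]) - offset[1], 1L), d[1])
  ci <- pmin(pmax(seq_len(d[2]) - offset[2], 1L), d[2])
  image[ri, ci, drop = FALSE]
}

#' Random integer spatial jitter
#'
#' Translates the image by an offset drawn uniformly from
#' \{-magnitude, ..., magnitude\} independently per axis. Pixels shifted in
#' from outside the frame are filled by edge replication. Magnitude 0 is
#' the identity.
#'
#' @param image numeric matrix.
#' @param magnitude maximum absolute displacement per axis (integer).
#' @param seed optional integer seed.
#' @return The translated matrix.
#' @export
apply_jitter <- function(image, magnitude, seed = NULL) {
  if (magnitude < 0 || magnitude != round(magnitude))
    stop_bad_arg("`magnitude` must be a non-negative integer")
  if (magnitude == 0) return(image)
  offset <- with_seed_if(seed,
    sample.int(2L * magnitude + 1L, 2L, replace = TRUE) - magnitude - 1L)
  translate_image(image, offset)
}

# Discrete Gaussian kernel, normalized to sum 1.
gaussian_kernel <- function(fwhm) {
  sigma <- fwhm / sqrt(8 * log(2))
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# 1D convolution along vector with mirror ("symmetric") boundary.
convolve_reflect <- function(v, kernel) {
  r <- (length(kernel) - 1L) / 2L
  n <- length(v)
  pad_lo <- rev(v[seq_len(min(r, n))])
  pad_hi <- rev(v[seq.int(n - min(r, n) + 1L, n)])
  # extend by full cycles if the kernel radius exceeds the signal length
  while (length(pad_lo) < r) pad_lo <- c(pad_lo, rev(pad_lo))[seq_len(r)]
  while (length(pad_hi) < r) pad_hi <- c(rev(pad_hi), pad_hi)[seq_len(r)]
  ext <- c(pad_lo, v, pad_hi)
  out <- numeric(n)
  for (i in seq_along(kernel)) {
    out <- out + kernel[i] * ext[seq.int(i, i + n - 1L)]
  }
  out
}

#' Isotropic Gaussian smoothing of a 2D image
#'
#' Separable convolution with a discrete Gaussian of standard deviation
#' `fwhm / sqrt(8 log 2)` pixels, mirror boundary handling. `fwhm = 0`
#' returns the input unchanged; constant images are conserved exactly.
#'
#' @param image numeric matrix.
#' @param fwhm kernel full width at half maximum, in pixels.
#' @return The smoothed matrix.
#' @export
apply_smoothing <- function(image, fwhm) {
  if (fwhm < 0) stop_bad_arg("`fwhm` must be non-negative")
  if (fwhm == 0) return(image)
  k <- gaussian_kernel(fwhm)
  out <- apply(image, 2L, convolve_reflect, kernel = k)
  t(apply(out, 1L, convolve_reflect, kernel = k))
}

#' Sample multi-subject images from a ground-truth labeling
#'
#' For each subject i, contrast f and pixel j the generated value is
#' `mu[f, label(j)] + beta[i] + eps`, with per-parcel means
#' `mu ~ N(0, mu_sd^2)`, subject random effects `beta ~ N(0, sigma2^2)`
#' constant across parcels and contrasts, and pixel noise
#' `eps ~ N(0, sigma1^2)`. Each subject's images are then translated by a
#' shared random integer offset of at most `jitter` pixels per axis and
#' smoothed with a Gaussian of the configured fwhm.
#'
#' @param truth a `ground_truth` labeling.
#' @param config a [simulation_config()].
#' @param seed optional integer seed.
#'
#' @return A list with `signal` (a [parcel_signal()]), `parcel_means`
#'   (F x K_true matrix), `subject_effects` (length-N vector) and
#'   `offsets` (N x 2 integer matrix of applied jitter offsets).
#' @export
sample_subject_images <- function(truth, config, seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(config, "simulation_config"))
  if (!all(truth$grid_shape == config$grid_shape))
    stop_bad_arg("truth and config disagree on the grid shape")
  gs <- config$grid_shape
  Q <- prod(gs)
  N <- config$n_subjects
  F_ <- config$n_contrasts
  K <- truth$K_true
  with_seed_if(seed, {
    mu <- matrix(rnorm(F_ * K, sd = config$mu_sd), nrow = F_, ncol = K)
    beta <- rnorm(N, sd = config$sigma2)
    values <- matrix(0, nrow = N * F_, ncol = Q)
    subject <- rep(seq_len(N), each = F_)
    contrast <- rep(seq_len(F_), times = N)
    offsets <- matrix(0L, nrow = N, ncol = 2L)
    row <- 0L
    for (i in seq_len(N)) {
      if (config$jitter > 0) {
        offsets[i, ] <- sample.int(2L * config$jitter + 1L, 2L,
                                   replace = TRUE) - config$jitter - 1L
      }
      for (f in seq_len(F_)) {
        img <- matrix(mu[f, truth$labeling] + beta[i] +
                        rnorm(Q, sd = config$sigma1),
                      nrow = gs[1], ncol = gs[2])
        if (config$jitter > 0) img <- translate_image(img, offsets[i, ])
        if (config$fwhm > 0) img <- apply_smoothing(img, config$fwhm)
        row <- row + 1L
        values[row, ] <- as.vector(img)
      }
    }
    list(
      signal = parcel_signal(values, subject = subject, contrast = contrast,
                             grid_shape = gs),
      parcel_means = mu,
      subject_effects = beta,
      offsets = offsets
    )
  })
}

#' Simulate a complete multi-subject dataset
#'
#' Convenience wrapper: draws a ground-truth labeling and then samples
#' subject images from it. The returned `truth` carries the generator-side
#' parcel means and subject effects alongside the labeling.
#'
#' @param config a [simulation_config()].
#' @param seed optional integer seed controlling both stages.
#' @return A list with elements `signal` ([parcel_signal()]) and `truth`
#'   (a `ground_truth` augmented with `parcel_means`, `subject_effects`,
#'   `offsets`).
#' @export
#' @examples
#' ds <- simulate_parcel_dataset(simulation_config(), seed = 1)
#' ds$signal
simulate_parcel_dataset <- function(config = simulation_config(),
                                    seed = NULL) {
  truth <- make_ground_truth(config$grid_shape, config$K_true,
                             seed = if (is.null(seed)) NULL
                                    else derive_seed(seed, 1L))
  draws <- sample_subject_images(truth, config,
                                 seed = if (is.null(seed)) NULL
                                        else derive_seed(seed, 2L))
  truth$parcel_means <- draws$parcel_means
  truth$subject_effects <- draws$subject_effects
  truth$offsets <- draws$offsets
  list(signal = draws$signal, truth = truth)
}
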