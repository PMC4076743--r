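#' Multi-subject signal matrix
#'
#' Container for the n x Q matrix \eqn{Y} of standardized effects: one row
#' per (subject, contrast) functional image, one column per voxel. This is
#' the input of every clustering routine and of the per-parcel mixed-effects
#' model.
#'
#' @param values numeric matrix, n rows (images) by Q columns (voxels).
#' @param subject integer vector of length n giving the subject of each row.
#' @param contrast integer vector of length n giving the contrast of each
#'   row; defaults to a single contrast.
#' @param coords numeric Q x d matrix of voxel coordinates (pixels or mm).
#'   Derived from `grid_shape` when omitted.
#' @param grid_shape optional integer vector of image dimensions when the
#'   voxels form a full regular grid stored in column-major order.
#'
#' @return An object of class `parcel_signal`: a list with elements
#'   `values`, `subject`, `contrast`, `coords`, `grid_shape`.
#' @export
parcel_signal <- function(values, subject, contrast = NULL, coords = NULL,
                          grid_shape = NULL) {
  values <- as.matrix(values)
  if (anyNA(values)) stop_bad_arg("`values` must not contain missing values")
  n <- nrow(values)
  subject <- as.integer(subject)
  if (length(subject) != n)
    stop_bad_arg("`subject` must have one entry per row of `values`")
  if (is.null(contrast)) contrast <- rep(1L, n)
  contrast <- as.integer(contrast)
  if (length(contrast) != n)
    stop_bad_arg("`contrast` must have one entry per row of `values`")
  if (anyDuplicated(cbind(subject, contrast)))
    stop_bad_arg("each (subject, contrast) pair may appear at most once")
  if (!is.null(grid_shape)) {
    grid_shape <- as.integer(grid_shape)
    if (prod(grid_shape) != ncol(values))
      stop_bad_arg("prod(grid_shape) must equal the number of voxels")
  }
  if (is.null(coords)) {
    if (is.null(grid_shape))
      stop_bad_arg("either `coords` or `grid_shape` is required")
    coords <- arrayInd(seq_len(ncol(values)), grid_shape)
  }
  coords <- as.matrix(coords)
  if (nrow(coords) != ncol(values))
    stop_bad_arg("`coords` must have one row per voxel")
  structure(
    list(values = values, subject = subject, contrast = contrast,
         coords = coords, grid_shape = grid_shape),
    class = "parcel_signal"
  )
}

#' @export
print.parcel_signal <- function(x, ...) {
  cat(sprintf(
    "<parcel_signal> %d images (%d subjects x %d contrasts) over %d voxels\n",
    nrow(x$values), n_subjects(x), length(unique(x$contrast)),
    ncol(x$values)))
  if (!is.null(x$grid_shape))
    cat("  grid:", paste(x$grid_shape, collapse = " x "), "\n")
  invisible(x)
}

n_subjects <- function(signal) length(unique(signal$subject))
n_voxels <- function(signal) ncol(signal$values)

# Rows of `signal` for the given subjects, in the given order; subjects are
# renumbered 1..length(subjects) so that bootstrap duplicates count as
# distinct subjects.
subset_subjects <- function(signal, subjects) {
  rows <- unlist(lapply(seq_along(subjects), function(i) {
    which(signal$subject == subjects[i])
  }))
  new_subject <- rep(seq_along(subjects),
                     times = vapply(subjects, function(s)
                       sum(signal$subject == s), integer(1)))
  parcel_signal(signal$values[rows, , drop = FALSE],
                subject = new_subject,
                contrast = signal$contrast[rows],
                coords = signal$coords,
                grid_shape = signal$grid_shape)
}

#' @describeIn parcel_signal long-format view: one row per
#'   (subject, contrast, voxel) with coordinates and signal value.
#' @param x a `parcel_signal`.
#' @param ... unused.
#' @export
tidy.parcel_signal <- function(x, ...) {
  Q <- ncol(x$values)
  n <- nrow(x$values)
  coord_names <- c("x", "y", "z")[seq_len(ncol(x$coords))]
  coords <- as_tibble(as.data.frame(x$coords))
  names(coords) <- coord_names
  out <- tibble(
    subject = rep(x$subject, times = Q),
    contrast = rep(x$contrast, times = Q),
    voxel = rep(seq_len(Q), each = n),
    value = as.vector(x$values)
  )
  dplyr::bind_cols(out, coords[out$voxel, , drop = FALSE])
}
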